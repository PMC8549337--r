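# Descriptive statistics per (injected volume, kV) group: mean, sample SD,
# the norm interval mean +/- 1.96*SD (the range expected to contain 95% of
# observations under a normal model), and the segmented/injected volume
# ratio; plus the paired tube-voltage comparison.

#' A per-group sample of segmented marker volumes
#'
#' @param injected_volume Injected volume of the group, ul.
#' @param kv Tube voltage the group was scanned at.
#' @param values Segmented volumes in ul (non-negative).
#' @param marker_ids Identifiers aligned with `values`; must be unique.
#'   Defaults to `1..n`.
#' @return Object of class `volume_sample`.
#' @export
volume_sample <- function(injected_volume, kv, values, marker_ids = NULL) {
  stopifnot(is.numeric(values), all(values >= 0), injected_volume > 0)
  if (is.null(marker_ids)) marker_ids <- as.character(seq_along(values))
  marker_ids <- as.character(marker_ids)
  stopifnot(length(marker_ids) == length(values), !anyDuplicated(marker_ids))
  structure(list(injected_volume = injected_volume, kv = kv,
                 values = as.numeric(values), marker_ids = marker_ids),
            class = "volume_sample")
}

#' Norm interval
#'
#' `mean +/- 1.96 * sd`: under a normal model the range containing 95% of
#' observations.
#'
#' @param mean,sd Group mean and standard deviation.
#' @return Numeric vector `c(lower, upper)`.
#' @export
norm_interval <- function(mean, sd) {
  stopifnot(sd >= 0)
  c(lower = mean - 1.96 * sd, upper = mean + 1.96 * sd)
}

#' Group summary from moments
#'
#' Builds a `volume_summary` directly from a mean and SD — e.g. from a
#' published summary table — without access to the raw values.
#'
#' @param mean Group mean segmented volume, ul.
#' @param sd Group standard deviation, ul.
#' @param n Number of markers in the group.
#' @param injected_volume Injected volume, ul.
#' @param kv Tube voltage (optional metadata).
#' @return Object of class `volume_summary` with fields `mean`, `sd`, `n`,
#'   `norm_interval`, `ratio` (= mean / injected volume), `injected_volume`,
#'   `kv`.
#' @examples
#' s <- volume_summary(67.48, 7.33, 25, injected_volume = 10, kv = 120)
#' s$norm_interval  # 53.1132 81.8468
#' @export
volume_summary <- function(mean, sd, n, injected_volume, kv = NA) {
  stopifnot(sd >= 0, injected_volume > 0, n >= 1)
  structure(
    list(mean = mean, sd = sd, n = as.integer(n),
         norm_interval = norm_interval(mean, sd),
         ratio = mean / injected_volume,
         injected_volume = injected_volume, kv = kv),
    class = "volume_summary")
}

#' Summarise a volume sample
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator), norm
#' interval and segmented/injected ratio for one (injected volume, kV) group.
#' Values are kept at full precision; rounding (two decimals for volumes and
#' interval bounds, one for the ratio) happens only in the print method.
#'
#' @param sample A [volume_sample()]; at least two values (the SD is
#'   undefined for n = 1).
#' @return A [volume_summary()].
#' @examples
#' summarize_volumes(volume_sample(10, 120, c(80, 90, 100)))
#' @export
summarize_volumes <- function(sample) {
  stopifnot(inherits(sample, "volume_sample"))
  n <- length(sample$values)
  if (n == 0L) stop("cannot summarise an empty sample")
  if (n == 1L) stop("sample standard deviation undefined for n = 1")
  volume_summary(mean(sample$values), stats::sd(sample$values), n,
                 sample$injected_volume, sample$kv)
}

#' @export
summary.volume_sample <- function(object, ...) summarize_volumes(object)

#' @export
print.volume_summary <- function(x, ...) {
  cat(sprintf(
    "<volume_summary> %g ul @ %s kV (n = %d): mean %.2f, SD %.2f, norm interval %.2f-%.2f, ratio %.1f\n",
    x$injected_volume, format(x$kv), x$n, x$mean, x$sd,
    x$norm_interval[1], x$norm_interval[2], x$ratio))
  invisible(x)
}

#' @export
as.data.frame.volume_summary <- function(x, ...) {
  data.frame(injected_ul = x$injected_volume, kv = x$kv, n = x$n,
             mean_ul = x$mean, sd_ul = x$sd,
             norm_lower = unname(x$norm_interval[1]),
             norm_upper = unname(x$norm_interval[2]),
             ratio = x$ratio)
}

#' Pairwise comparison of two tube-voltage settings
#'
#' Compares segmented volumes of the same injected volume across two kV
#' settings. The repeated-measures design (each physical marker scanned at
#' every kV) makes a paired two-sided t-test on within-marker differences the
#' default; `paired = FALSE` gives a Welch two-sample comparison.
#'
#' @param sample_a,sample_b [volume_sample()] objects with equal injected
#'   volume; in paired mode, identical `marker_ids` sets.
#' @param paired Logical, default `TRUE`.
#' @param bonferroni_m Optional number of comparisons for a Bonferroni
#'   adjustment of the p-value; `NULL` (default) reports the raw p-value.
#' @return List with `statistic`, `p_value`, `df`, `mean_difference`,
#'   `method`, class `kv_comparison`.
#' @export
pairwise_kv_test <- function(sample_a, sample_b, paired = TRUE,
                             bonferroni_m = NULL) {
  stopifnot(inherits(sample_a, "volume_sample"),
            inherits(sample_b, "volume_sample"))
  if (sample_a$injected_volume != sample_b$injected_volume)
    stop("samples must share the injected volume")
  if (paired) {
    if (length(sample_a$values) != length(sample_b$values) ||
        !setequal(sample_a$marker_ids, sample_b$marker_ids))
      stop("paired comparison requires matching marker_ids")
    b <- sample_b$values[match(sample_a$marker_ids, sample_b$marker_ids)]
    diffs <- sample_a$values - b
    if (stats::sd(diffs) < 1e-12) {
      res <- list(statistic = 0, p_value = 1,
                  df = length(diffs) - 1, mean_difference = mean(diffs),
                  method = "paired t-test")
    } else {
      tt <- stats::t.test(diffs)
      res <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                  df = unname(tt$parameter), mean_difference = mean(diffs),
                  method = "paired t-test")
    }
  } else {
    tt <- stats::t.test(sample_a$values, sample_b$values, var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                df = unname(tt$parameter),
                mean_difference = mean(sample_a$values) - mean(sample_b$values),
                method = "Welch two-sample t-test")
  }
  if (!is.null(bonferroni_m))
    res$p_value <- min(1, res$p_value * bonferroni_m)
  res$kv_a <- sample_a$kv; res$kv_b <- sample_b$kv
  res$injected_volume <- sample_a$injected_volume
  structure(res, class = "kv_comparison")
}

#' @export
print.kv_comparison <- function(x, ...) {
  cat(sprintf(
    "<kv_comparison> %g ul, %s vs %s kV (%s): mean diff %.2f ul, t = %.2f, p = %.3g\n",
    x$injected_volume, format(x$kv_a), format(x$kv_b), x$method,
    x$mean_difference, x$statistic, x$p_value))
  invisible(x)
}
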