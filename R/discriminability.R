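# Discriminability of two injection volumes from their segmented-volume
# distributions. The statistic: Delta = min(large-group volumes) -
# max(small-group volumes) (positive iff the observed ranges do not overlap);
# the border line = lower norm-interval limit of the large group - Delta/2;
# and, under a normal model of the small group, the probability that a
# small-volume marker falls on the small side of the border. Differentiation
# is considered reliable when that probability exceeds 95%.

#' Observed gap between two volume groups
#'
#' `min(large values) - max(small values)`: positive when the observed ranges
#' of the two groups do not overlap, negative when they do.
#'
#' @param sample_small,sample_large Non-empty [volume_sample()] objects with
#'   `sample_small$injected_volume < sample_large$injected_volume`.
#' @return Delta in ul.
#' @examples
#' compute_delta(volume_sample(10, 70, c(80, 90)),
#'               volume_sample(30, 70, c(150, 200)))  # 60
#' @export
compute_delta <- function(sample_small, sample_large) {
  stopifnot(inherits(sample_small, "volume_sample"),
            inherits(sample_large, "volume_sample"))
  if (length(sample_small$values) == 0L || length(sample_large$values) == 0L)
    stop("empty sample")
  if (!(sample_small$injected_volume < sample_large$injected_volume))
    stop("sample_small must have the smaller injected volume")
  min(sample_large$values) - max(sample_small$values)
}

#' Border line between two volume groups
#'
#' The lower norm-interval limit of the large group minus half the observed
#' gap Delta. A negative Delta (overlapping ranges) moves the border upward.
#'
#' @param summary_large A [volume_summary()] of the large-volume group.
#' @param delta Observed gap from [compute_delta()], ul.
#' @return Border in ul.
#' @export
compute_border <- function(summary_large, delta) {
  stopifnot(inherits(summary_large, "volume_summary"), is.finite(delta))
  unname(summary_large$norm_interval[1]) - delta / 2
}

#' Probability of separation under a normal model
#'
#' Probability that a small-volume marker falls on the small side of the
#' border line, `pnorm((border - mean) / sd)` with the small group's sample
#' mean and SD. Differentiation is considered reliable when this probability
#' exceeds 0.95 (the norm-interval logic: more than 95% of observations
#' outside the contested region).
#'
#' @param summary_small A [volume_summary()] of the small-volume group.
#' @param border Border line in ul.
#' @return Probability in `[0, 1]`. With `sd = 0` the model degenerates:
#'   returns 1 when the mean lies below the border, 0 otherwise.
#' @export
separation_probability <- function(summary_small, border) {
  stopifnot(inherits(summary_small, "volume_summary"), is.finite(border))
  if (summary_small$sd == 0)
    return(if (summary_small$mean < border) 1 else 0)
  stats::pnorm((border - summary_small$mean) / summary_small$sd)
}

#' Assess discriminability of two injection volumes
#'
#' Chains [compute_delta()], [compute_border()] and
#' [separation_probability()] and applies the > 95% reliability cutoff. The
#' complementary tail (probability of a small-volume marker exceeding the
#' border) is reported alongside for transparency.
#'
#' @inheritParams compute_delta
#' @param summary_small,summary_large Optional precomputed
#'   [volume_summary()] objects; computed from the samples when omitted.
#' @return Object of class `discriminability_result`: `delta`, `border`,
#'   `separation_probability`, `prob_above_border`, `reliable`, `kv`.
#' @examples
#' small <- volume_sample(10, 70, rnorm(25, 90, 10))
#' large <- volume_sample(30, 70, rnorm(25, 215, 37))
#' assess_discriminability(small, large)
#' @export
assess_discriminability <- function(sample_small, sample_large,
                                    summary_small = NULL,
                                    summary_large = NULL) {
  if (is.null(summary_small)) summary_small <- summarize_volumes(sample_small)
  if (is.null(summary_large)) summary_large <- summarize_volumes(sample_large)
  delta <- compute_delta(sample_small, sample_large)
  border <- compute_border(summary_large, delta)
  p <- separation_probability(summary_small, border)
  structure(
    list(delta = delta, border = border, separation_probability = p,
         prob_above_border = 1 - p, reliable = p > 0.95,
         kv = sample_small$kv,
         summary_small = summary_small, summary_large = summary_large),
    class = "discriminability_result")
}

#' @export
print.discriminability_result <- function(x, ...) {
  cat(sprintf(
    "<discriminability_result> %g vs %g ul @ %s kV\n",
    x$summary_small$injected_volume, x$summary_large$injected_volume,
    format(x$kv)))
  cat(sprintf("  Delta = %.2f ul, border = %.2f ul\n", x$delta, x$border))
  cat(sprintf("  separation probability = %.2f%% -> %s\n",
              100 * x$separation_probability,
              if (x$reliable) "reliable differentiation"
              else "NOT reliably differentiable"))
  invisible(x)
}
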