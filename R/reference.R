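# Published reference values shipped with the package: the per-group summary
# statistics of the ex-vivo porcine-mandible evaluation and the clinical
# injection counts. Raw per-marker scans were never published, so these
# printed summaries are the inputs to the arithmetic checks (norm-interval
# bounds, ratio row, visibility percentages).

#' Reference per-group volume summaries
#'
#' Published summary statistics (mean, SD, printed norm-interval bounds and
#' printed ratio) of segmented marker volumes per (injected volume, kV) group
#' from an ex-vivo evaluation of low-dose liquid fiducial injections in
#' porcine mandible segments: 25 markers per injected volume (10/20/30 ul),
#' each scanned at 70, 100 and 120 kV.
#'
#' @return Data frame with columns `injected_ul`, `kv`, `n`, `mean_ul`,
#'   `sd_ul`, `norm_lower_printed`, `norm_upper_printed`, `ratio_printed`.
#' @examples
#' head(reference_volume_summaries())
#' @export
reference_volume_summaries <- function() {
  utils::read.csv(system.file("extdata", "reference_volume_summaries.csv",
                              package = "fidvol"))
}

#' Reference clinical injection counts
#'
#' Published counts of intraoperative marker injections and how many were
#' well identifiable in postoperative CT: 57 of 66 (single-energy patient)
#' and 43 of 52 (dual-energy patient).
#'
#' @return Data frame with columns `patient`, `mode`, `n_injected`,
#'   `n_identifiable`.
#' @export
reference_clinical_counts <- function() {
  utils::read.csv(system.file("extdata", "reference_clinical_counts.csv",
                              package = "fidvol"))
}

#' Reference summaries as volume_summary objects
#'
#' @return Named list of [volume_summary()] objects keyed `"<ul>@<kV>"`.
#' @export
reference_summaries_as_objects <- function() {
  df <- reference_volume_summaries()
  out <- lapply(seq_len(nrow(df)), function(i)
    volume_summary(df$mean_ul[i], df$sd_ul[i], df$n[i],
                   injected_volume = df$injected_ul[i], kv = df$kv[i]))
  stats::setNames(out, paste0(df$injected_ul, "@", df$kv))
}
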