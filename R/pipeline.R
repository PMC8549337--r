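# End-to-end replications: the preclinical multi-segment / multi-kV
# experiment producing a summary-table report with discriminability
# decisions, and a clinical-simulation mode with marker loss, confounders and
# optional dual-energy classification.

#' Configuration of the preclinical experiment
#'
#' Defaults replicate the study design: 25 injections each of 10, 20 and
#' 30 ul distributed over 9 mandible-segment phantoms (8 or 9 markers per
#' segment), every segment scanned at 70, 100 and 120 kV.
#'
#' @param n_segments Number of phantom segments.
#' @param injections_per_volume Injections per nominal volume.
#' @param volumes Injected volumes, ul.
#' @param kv_list Tube voltages; each must have a default protocol
#'   ([default_protocols()]) unless `protocols` is supplied.
#' @param seed Integer seed governing every random draw of the run.
#' @param protocols Optional named list of [acquisition_protocol()]s keyed by
#'   energy label.
#' @param marker_pitch,include_bone Passed to [scene_config()].
#' @return Object of class `preclinical_config`.
#' @export
preclinical_config <- function(n_segments = 9, injections_per_volume = 25,
                               volumes = c(10, 20, 30),
                               kv_list = c(70, 100, 120), seed = 1,
                               protocols = NULL, marker_pitch = 10,
                               include_bone = TRUE) {
  stopifnot(n_segments >= 1, injections_per_volume >= 1,
            length(volumes) >= 1, all(volumes > 0), length(kv_list) >= 1)
  if (anyDuplicated(volumes)) stop("duplicated injected volumes")
  if (is.null(protocols)) protocols <- default_protocols()
  labels <- as.character(kv_list)
  missing_p <- setdiff(labels, names(protocols))
  if (length(missing_p))
    stop("no acquisition protocol for kV: ", paste(missing_p, collapse = ", "))
  structure(
    list(n_segments = as.integer(n_segments),
         injections_per_volume = as.integer(injections_per_volume),
         volumes = volumes, kv_list = kv_list, seed = as.integer(seed),
         protocols = protocols[labels], marker_pitch = marker_pitch,
         include_bone = include_bone),
    class = "preclinical_config")
}

# deterministic allocation of markers to segments: 8-or-9-per-segment style
# split, volumes interleaved so every segment holds a mix
.allocate_markers <- function(config) {
  total <- config$injections_per_volume * length(config$volumes)
  per_seg <- rep(total %/% config$n_segments, config$n_segments)
  extra <- total %% config$n_segments
  if (extra > 0) per_seg[seq_len(extra)] <- per_seg[seq_len(extra)] + 1L
  vols <- rep(config$volumes, times = config$injections_per_volume)
  data.frame(marker_id = paste0("S", rep(seq_len(config$n_segments), per_seg),
                                "M", sequence(per_seg)),
             segment = rep(seq_len(config$n_segments), per_seg),
             injected_ul = vols)
}

#' Run the preclinical experiment
#'
#' Builds one phantom scene per segment, acquires it at every configured kV,
#' segments every marker from its known injection site, and assembles the
#' per-group summaries, the paired kV comparisons and the per-kV
#' discriminability assessment of the smallest versus the largest injected
#' volume. Fully reproducible from the configuration seed.
#'
#' @param config A [preclinical_config()].
#' @param params [segmentation_params()] for the volumetry.
#' @return Object of class `run_report`: `measurements` (long data frame:
#'   marker_id, segment, injected_ul, kv, volume_ul, visible),
#'   `summary_table` (one row per (volume, kV) group), `summaries` (list of
#'   [volume_summary()]), `pairwise_tests`, `discriminability` (list per kV,
#'   `NULL` with fewer than two volumes), `visibility`, `config`.
#' @export
run_preclinical <- function(config, params = segmentation_params()) {
  stopifnot(inherits(config, "preclinical_config"))
  alloc <- .allocate_markers(config)
  set.seed(config$seed)
  scene_seeds <- sample.int(.Machine$integer.max - 1L, config$n_segments)
  acq_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 config$n_segments * length(config$kv_list)),
                      config$n_segments, length(config$kv_list))

  meas <- vector("list", config$n_segments)
  for (s in seq_len(config$n_segments)) {
    seg_alloc <- alloc[alloc$segment == s, ]
    markers <- lapply(seg_alloc$injected_ul, marker_spec)
    scene <- build_scene(scene_config(
      markers, seed = scene_seeds[s], marker_pitch = config$marker_pitch,
      include_bone = config$include_bone))
    rows <- vector("list", length(config$kv_list))
    for (k in seq_along(config$kv_list)) {
      protocol <- config$protocols[[as.character(config$kv_list[k])]]
      vol <- acquire_ct(scene, protocol, acq_seeds[s, k])
      segres <- lapply(seq_len(nrow(scene$markers)), function(m)
        segment_marker(vol, unlist(scene$markers[m, c("x", "y", "z")]),
                       params))
      rows[[k]] <- data.frame(
        marker_id = seg_alloc$marker_id,
        segment = s,
        injected_ul = seg_alloc$injected_ul,
        kv = config$kv_list[k],
        volume_ul = vapply(segres, function(r)
          if (is_visible(r)) r$volume_ul else NA_real_, numeric(1)),
        visible = vapply(segres, is_visible, logical(1)))
    }
    meas[[s]] <- do.call(rbind, rows)
  }
  measurements <- do.call(rbind, meas)
  rownames(measurements) <- NULL

  samples <- list()
  summaries <- list()
  for (v in config$volumes) for (kv in config$kv_list) {
    sub <- measurements[measurements$injected_ul == v &
                          measurements$kv == kv & measurements$visible, ]
    key <- paste0(v, "@", kv)
    samples[[key]] <- volume_sample(v, kv, sub$volume_ul, sub$marker_id)
    summaries[[key]] <- summarize_volumes(samples[[key]])
  }
  summary_table <- do.call(rbind, lapply(summaries, as.data.frame))
  rownames(summary_table) <- NULL

  pairwise <- list()
  if (length(config$kv_list) >= 2) {
    for (v in config$volumes) {
      pairs <- utils::combn(config$kv_list, 2, simplify = FALSE)
      for (p in pairs) {
        key <- sprintf("%g ul: %g vs %g kV", v, p[1], p[2])
        pairwise[[key]] <- pairwise_kv_test(
          samples[[paste0(v, "@", p[1])]], samples[[paste0(v, "@", p[2])]])
      }
    }
  }

  discr <- NULL
  if (length(config$volumes) >= 2) {
    v_lo <- min(config$volumes); v_hi <- max(config$volumes)
    discr <- lapply(stats::setNames(config$kv_list,
                                    as.character(config$kv_list)),
                    function(kv)
      assess_discriminability(samples[[paste0(v_lo, "@", kv)]],
                              samples[[paste0(v_hi, "@", kv)]]))
  }

  n_inj <- nrow(measurements)
  n_det <- sum(measurements$visible)
  structure(
    list(measurements = measurements, summary_table = summary_table,
         summaries = summaries, samples = samples,
         pairwise_tests = pairwise, discriminability = discr,
         visibility = list(n_injected = n_inj, n_detected = n_det,
                           percent = visibility_percent(n_det, n_inj)),
         mode = "preclinical", config = config),
    class = "run_report")
}

#' Visibility percentage
#'
#' `round(100 * n_detected / n_injected)` to the nearest integer.
#'
#' @param n_detected,n_injected Counts.
#' @return Integer percentage.
#' @examples
#' visibility_percent(57, 66)  # 86
#' visibility_percent(43, 52)  # 83
#' @export
visibility_percent <- function(n_detected, n_injected) {
  stopifnot(n_injected > 0, n_detected >= 0, n_detected <= n_injected)
  as.integer(round(100 * n_detected / n_injected))
}

#' Configuration of the clinical simulation
#'
#' Emulates intraoperative marking of a tumour-bed resection surface: `n`
#' injections of mostly the 10 ul basis volume, each lost with a Bernoulli
#' failure probability (manipulation at the resection surface during flap
#' insertion, or injection failure), imaged at a routine protocol (or in
#' dual-energy mode) and recovered by unseeded detection.
#'
#' @param n_markers Number of injections (default 66; the dual-energy
#'   scenario used 52).
#' @param volumes_ul Per-injection volumes; default 10 ul everywhere except
#'   two 30 ul focal markers, scaled to `n_markers`.
#' @param failure_prob Per-marker loss probability in `[0, 1]` (default 0.15,
#'   bracketing the observed 83-86% visibility).
#' @param seed Integer seed.
#' @param dual_energy Acquire with the 80 kV / tin-filtered 150 kV pair and
#'   classify detections via [classify_hyperdense()].
#' @param confounders List of [confounder_spec()]s (clips, calcifications)
#'   placed among the markers.
#' @param kv Tube voltage of the single-energy acquisition (default 100).
#' @param marker_pitch Injection grid pitch, mm.
#' @return Object of class `clinical_config`.
#' @export
clinical_config <- function(n_markers = 66, volumes_ul = NULL,
                            failure_prob = 0.15, seed = 1,
                            dual_energy = FALSE, confounders = list(),
                            kv = 100, marker_pitch = 8) {
  stopifnot(n_markers >= 1)
  if (failure_prob < 0 || failure_prob > 1)
    stop("failure probability must be in [0, 1]")
  if (is.null(volumes_ul)) {
    volumes_ul <- rep(10, n_markers)
    if (n_markers >= 2) volumes_ul[seq_len(2)] <- 30
  }
  stopifnot(length(volumes_ul) == n_markers, all(volumes_ul > 0))
  structure(
    list(n_markers = as.integer(n_markers), volumes_ul = volumes_ul,
         failure_prob = failure_prob, seed = as.integer(seed),
         dual_energy = dual_energy, confounders = confounders,
         kv = kv, marker_pitch = marker_pitch),
    class = "clinical_config")
}

#' Run the clinical simulation
#'
#' Draws per-marker survival (seeded Bernoulli), optionally simulates the
#' acquisition and recovers markers by unseeded [detect_markers()] on the
#' (mixed-energy, in dual-energy mode) image, matching detections to the
#' known injection sites. Every injected marker is accounted for exactly
#' once as detected or not detected.
#'
#' @param config A [clinical_config()].
#' @param params [segmentation_params()] for detection.
#' @param image Simulate the full acquisition and detection (`TRUE`,
#'   default). With `image = FALSE` only the Bernoulli marker-loss stage is
#'   run and surviving markers count as detected — the lightweight mode for
#'   replicate studies of the visibility rate; at default contrast settings
#'   full detection recovers exactly the surviving markers.
#' @param min_volume_ul,max_volume_ul Detection volume window, ul; the upper
#'   bound screens out large bony components.
#' @return A `run_report` with `markers` (per-injection data frame:
#'   injected_ul, survived, detected), `visibility`, and in dual-energy mode
#'   `classification` (see [classify_hyperdense()]) plus `dect`.
#' @export
run_clinical_sim <- function(config, params = segmentation_params(),
                             image = TRUE, min_volume_ul = 2,
                             max_volume_ul = 1000) {
  stopifnot(inherits(config, "clinical_config"))
  set.seed(config$seed)
  survived <- stats::runif(config$n_markers) >= config$failure_prob
  scene_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  acq_seed <- sample.int(.Machine$integer.max - 1L, 1L)

  markers_df <- data.frame(
    marker_id = paste0("M", seq_len(config$n_markers)),
    injected_ul = config$volumes_ul, survived = survived)

  classification <- NULL
  dect <- NULL
  if (image) {
    n_c <- length(config$confounders)
    # one layout over all injection sites plus confounders; failed markers
    # keep their slot (no deposit), so positions stay comparable across runs
    layout_cfg <- scene_config(
      lapply(config$volumes_ul, marker_spec), seed = scene_seed,
      confounders = config$confounders, marker_pitch = config$marker_pitch,
      include_bone = FALSE)
    pos <- .grid_positions(config$n_markers + n_c, layout_cfg$dim,
                           layout_cfg$spacing, config$marker_pitch,
                           layout_cfg$margin)
    surv_idx <- which(survived)
    scene <- build_scene(scene_config(
      lapply(surv_idx, function(i)
        marker_spec(config$volumes_ul[i], center = pos[i, ])),
      seed = scene_seed,
      confounders = lapply(seq_len(n_c), function(j) {
        cs <- config$confounders[[j]]
        confounder_spec(cs$material, cs$volume,
                        center = if (is.null(cs$center))
                          pos[config$n_markers + j, ] else cs$center,
                        depth = cs$depth)
      }),
      dim = layout_cfg$dim, marker_pitch = config$marker_pitch,
      include_bone = FALSE))

    if (config$dual_energy) {
      prot <- default_protocols()
      acq <- acquire_dect(scene, prot[["80"]], prot[["150Sn"]], acq_seed)
      dect <- decompose_dect(acq$a, acq$b)
      hu_img <- structure(list(hu = dect$mixed, spacing = scene$spacing,
                               protocol = NULL, seed = acq_seed),
                          class = "ct_volume")
    } else {
      protocol <- default_protocols()[[as.character(config$kv)]]
      if (is.null(protocol))
        stop("no default protocol for kV ", config$kv)
      hu_img <- acquire_ct(scene, protocol, acq_seed)
    }
    detections <- detect_markers(hu_img, params, min_volume_ul,
                                 max_volume_ul)
    cent <- t(vapply(detections, `[[`, numeric(3), "centroid"))
    match_site <- function(xy) {
      if (length(detections) == 0L) return(NA_integer_)
      dd <- sqrt((cent[, 1] - xy[1])^2 + (cent[, 2] - xy[2])^2)
      j <- which.min(dd)
      if (dd[j] <= config$marker_pitch / 2) j else NA_integer_
    }
    det_idx <- vapply(seq_len(config$n_markers),
                      function(i) match_site(pos[i, ]), integer(1))
    markers_df$detected <- !is.na(det_idx)
    if (config$dual_energy && length(detections) > 0) {
      classification <- classify_hyperdense(dect, detections)
      conf_idx <- if (n_c > 0)
        vapply(seq_len(n_c),
               function(j) match_site(pos[config$n_markers + j, ]),
               integer(1)) else integer(0)
      classification$truth <- "iodine_marker"
      classification$truth[stats::na.omit(conf_idx)] <- "clip_or_calcification"
    }
  } else {
    markers_df$detected <- survived
  }

  n_det <- sum(markers_df$detected)
  structure(
    list(markers = markers_df,
         visibility = list(n_injected = config$n_markers, n_detected = n_det,
                           percent = visibility_percent(n_det,
                                                        config$n_markers)),
         classification = classification, dect = dect,
         mode = if (config$dual_energy) "clinical_dual_energy"
                else "clinical_single_energy",
         config = config),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> mode: %s\n", x$mode))
  if (!is.null(x$summary_table)) {
    cat(sprintf("  %d measurements, %d summary rows\n",
                nrow(x$measurements), nrow(x$summary_table)))
    st <- x$summary_table
    st$mean_ul <- round(st$mean_ul, 2); st$sd_ul <- round(st$sd_ul, 2)
    st$norm_lower <- round(st$norm_lower, 2)
    st$norm_upper <- round(st$norm_upper, 2)
    st$ratio <- round(st$ratio, 1)
    print(st, row.names = FALSE)
    if (!is.null(x$discriminability)) {
      cat("  discriminability (smallest vs largest injected volume):\n")
      for (kv in names(x$discriminability)) {
        d <- x$discriminability[[kv]]
        cat(sprintf("    %s kV: Delta %.2f ul, border %.2f ul, separation %.2f%% -> %s\n",
                    kv, d$delta, d$border, 100 * d$separation_probability,
                    if (d$reliable) "reliable" else "not reliable"))
      }
    }
  }
  cat(sprintf("  visibility: %d/%d markers (%d%%)\n",
              x$visibility$n_detected, x$visibility$n_injected,
              x$visibility$percent))
  if (!is.null(x$classification)) {
    tab <- table(x$classification$label)
    cat("  dual-energy classification: ",
        paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write the summary table and discriminability results of a run
#'
#' @param report A `run_report` from [run_preclinical()].
#' @param csv_path Output CSV for the per-group summary table.
#' @param json_path Optional output JSON for the per-kV discriminability
#'   results.
#' @return `csv_path`, invisibly.
#' @export
write_report <- function(report, csv_path, json_path = NULL) {
  stopifnot(inherits(report, "run_report"),
            !is.null(report$summary_table))
  utils::write.csv(report$summary_table, csv_path, row.names = FALSE)
  if (!is.null(json_path) && !is.null(report$discriminability)) {
    out <- lapply(report$discriminability, function(d)
      list(delta = d$delta, border = d$border,
           separation_probability = d$separation_probability,
           reliable = d$reliable))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
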