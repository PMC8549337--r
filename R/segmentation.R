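# Two-step threshold-based segmentation and volumetry.
#
# Step 1 (suggest_lower_level) automates the visual greyscale-window setting:
# the smallest integer HU level excluding at least 99.9% of the soft-tissue
# background. Step 2 (segment_marker / detect_markers) thresholds the volume
# at the lower level (140 HU by default, inclusive) and extracts 3D connected
# components; each marker's volume is its voxel count times the voxel volume
# (1 mm^3 = 1 ul exactly), with partial-volume voxels counted fully.

#' Segmentation parameters
#'
#' @param lower_threshold Lower HU threshold, inclusive (default 140).
#' @param connectivity Voxel adjacency: 6 (faces), 18 (faces+edges) or 26
#'   (full 3D adjacency; default — "coherent voxels" read as any 3D contact).
#' @param roi_radius Radius in mm of the spherical region of interest around
#'   the seed point for seeded segmentation (default 8 mm: covers the largest
#'   blurred 30 ul marker without touching neighbours at the default 10 mm
#'   marker pitch).
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(lower_threshold = 140, connectivity = 26,
                                roi_radius = 8) {
  stopifnot(is.finite(lower_threshold), roi_radius > 0)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  structure(list(lower_threshold = lower_threshold,
                 connectivity = connectivity, roi_radius = roi_radius),
            class = "segmentation_params")
}

# neighbour displacement matrix for a connectivity
.neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

# Connected component of `fg` containing seed voxel (i,j,k): vectorised
# frontier BFS. fg: logical 3D array. Returns n x 3 integer index matrix.
.flood_component <- function(fg, seed_ijk, connectivity) {
  d <- dim(fg)
  offs <- .neighbor_offsets(connectivity)
  K <- nrow(offs)
  comp <- array(FALSE, d)
  seed_ijk <- rbind(as.integer(seed_ijk))
  comp[.sub2ind(seed_ijk, d)] <- TRUE
  frontier <- seed_ijk
  out <- list(seed_ijk)
  while (nrow(frontier) > 0L) {
    m <- nrow(frontier)
    cand <- frontier[rep(seq_len(m), each = K), , drop = FALSE] +
      offs[rep(seq_len(K), m), , drop = FALSE]
    ok <- cand[, 1L] >= 1L & cand[, 1L] <= d[1L] &
          cand[, 2L] >= 1L & cand[, 2L] <= d[2L] &
          cand[, 3L] >= 1L & cand[, 3L] <= d[3L]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) break
    lin <- .sub2ind(cand, d)
    keep <- fg[lin] & !comp[lin] & !duplicated(lin)
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) break
    comp[.sub2ind(cand, d)] <- TRUE
    out[[length(out) + 1L]] <- cand
    frontier <- cand
  }
  do.call(rbind, out)
}

.as_hu_array <- function(volume) {
  if (inherits(volume, "ct_volume")) volume$hu
  else if (is.array(volume) && length(dim(volume)) == 3L) volume
  else stop("expected a ct_volume or a 3D array")
}

#' Suggest a lower greyscale level excluding the soft-tissue background
#'
#' Automated surrogate for visually raising the lower window level until the
#' soft tissue surrounding the markers is excluded: returns the smallest
#' integer HU value below which at least 99.9% of the background voxels fall.
#'
#' @param volume A `ct_volume` or 3D HU array.
#' @param background_mask Optional logical array selecting the background
#'   voxels. By default the soft-tissue background is located robustly: the
#'   median and MAD of all voxels, then every voxel within
#'   `median +/- max(6 * MAD-sd, 25)` HU — a window wide enough for tissue
#'   inhomogeneity and noise, but excluding bone, metal and marker halos.
#' @return Integer HU threshold. With the default phantom settings (soft
#'   tissue near 50 HU, noise SD at most 8 HU) this is well below 140.
#' @export
suggest_lower_level <- function(volume, background_mask = NULL) {
  hu <- .as_hu_array(volume)
  if (length(hu) == 0L) stop("empty volume")
  bg <- if (is.null(background_mask)) {
    soft <- hu[hu > -300 & hu < 300]           # drop air and dense objects
    if (length(soft) == 0L) soft <- hu         # e.g. a pure-air volume
    m <- stats::median(soft)
    w <- max(6 * stats::mad(soft), 25)
    hu[hu >= m - w & hu <= m + w]
  } else hu[background_mask]
  if (length(bg) == 0L) stop("no background voxels selected")
  k <- ceiling(0.999 * length(bg))
  vk <- sort(bg, partial = k)[k]
  as.integer(floor(vk)) + 1L
}

.make_segmented_marker <- function(ijk, hu, spacing, seed_point, params) {
  voxvol <- prod(spacing)
  lin <- .sub2ind(ijk, dim(hu))
  centroid <- colMeans(voxel_to_world(ijk, spacing))
  structure(
    list(voxels = ijk, voxel_idx = lin,
         volume_ul = nrow(ijk) * voxvol,
         centroid = centroid, seed_point = seed_point,
         peak_hu = max(hu[lin]), params = params),
    class = "segmented_marker")
}

#' @export
print.segmented_marker <- function(x, ...) {
  cat(sprintf(
    "<segmented_marker> %.2f ul (%d voxels), peak %.0f HU, centroid (%.1f, %.1f, %.1f) mm\n",
    x$volume_ul, nrow(x$voxels), x$peak_hu,
    x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' @export
print.marker_not_visible <- function(x, ...) {
  cat(sprintf("<marker_not_visible> seed (%.1f, %.1f, %.1f) mm below %s HU\n",
              x$seed_point[1], x$seed_point[2], x$seed_point[3],
              format(x$threshold)))
  invisible(x)
}

#' Test whether a segmentation result is a visible marker
#'
#' @param x Result of [segment_marker()].
#' @return `TRUE` for a `segmented_marker`, `FALSE` for `marker_not_visible`.
#' @export
is_visible <- function(x) inherits(x, "segmented_marker")

#' Segment one marker from a seed point
#'
#' Extracts the connected component (under the configured connectivity) of
#' voxels with HU at or above the lower threshold that contains the seed
#' point, restricted to the sphere of `roi_radius` around the seed. The
#' marker volume is the voxel count times the voxel volume.
#'
#' @param volume A `ct_volume` or 3D HU array (then `spacing` is required).
#' @param seed_point World coordinates (x, y, z) in mm.
#' @param params A [segmentation_params()].
#' @param spacing Voxel spacing, only for bare arrays.
#' @return A `segmented_marker`, or a `marker_not_visible` result when the
#'   seed voxel lies below the threshold (distinguished from an error).
#' @examples
#' hu <- array(0, c(5, 5, 5)); hu[2:4, 2:4, 2:4] <- 200
#' m <- segment_marker(hu, c(2.5, 2.5, 2.5), segmentation_params(140),
#'                     spacing = c(1, 1, 1))
#' m$volume_ul  # 27
#' @export
segment_marker <- function(volume, seed_point,
                           params = segmentation_params(), spacing = NULL) {
  hu <- .as_hu_array(volume)
  if (is.null(spacing))
    spacing <- if (inherits(volume, "ct_volume")) volume$spacing
               else stop("spacing required for a bare array")
  stopifnot(inherits(params, "segmentation_params"), length(seed_point) == 3L)
  d <- dim(hu)
  seed_ijk <- drop(world_to_voxel(seed_point, spacing))
  if (any(seed_ijk < 1L) || any(seed_ijk > d))
    stop("seed point outside the grid")
  if (hu[seed_ijk[1], seed_ijk[2], seed_ijk[3]] < params$lower_threshold)
    return(structure(list(seed_point = seed_point,
                          threshold = params$lower_threshold),
                     class = "marker_not_visible"))
  # crop to the ROI bounding box for speed, then mask to the ROI sphere
  r_vox <- ceiling(params$roi_radius / spacing)
  lo <- pmax(seed_ijk - r_vox, 1L)
  hi <- pmin(seed_ijk + r_vox, d)
  sub <- hu[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)
  cx <- (lo[1]:hi[1] - 0.5) * spacing[1] - seed_point[1]
  cy <- (lo[2]:hi[2] - 0.5) * spacing[2] - seed_point[2]
  cz <- (lo[3]:hi[3] - 0.5) * spacing[3] - seed_point[3]
  in_roi <- outer(outer(cx^2, cy^2, "+"), cz^2, "+") <= params$roi_radius^2
  fg <- (sub >= params$lower_threshold) & in_roi
  comp <- .flood_component(fg, seed_ijk - lo + 1L, params$connectivity)
  ijk <- sweep(comp, 2, lo - 1L, "+")
  .make_segmented_marker(ijk, hu, spacing, seed_point, params)
}

#' Detect all markers in a volume
#'
#' Unseeded detection: labels every connected component of voxels at or above
#' the lower threshold and keeps those with volume at least `min_volume_ul`
#' (and at most `max_volume_ul` when given), sorted by decreasing volume.
#' Touching voxels always belong to one component, so nothing is
#' double-counted.
#'
#' @inheritParams segment_marker
#' @param min_volume_ul Minimum component volume to report, in ul.
#' @param max_volume_ul Optional maximum component volume (screens out large
#'   bony structures in clinical-simulation scenes); `Inf` keeps everything.
#' @return List of `segmented_marker` objects (possibly empty).
#' @export
detect_markers <- function(volume, params = segmentation_params(),
                           min_volume_ul = 1, max_volume_ul = Inf,
                           spacing = NULL) {
  hu <- .as_hu_array(volume)
  if (is.null(spacing))
    spacing <- if (inherits(volume, "ct_volume")) volume$spacing
               else stop("spacing required for a bare array")
  d <- dim(hu)
  fg <- hu >= params$lower_threshold
  remaining <- fg
  out <- list()
  repeat {
    nxt <- which(remaining)
    if (length(nxt) == 0L) break
    seed_lin <- nxt[1L]
    seed_ijk <- c(arrayInd(seed_lin, d))
    comp <- .flood_component(fg, seed_ijk, params$connectivity)
    remaining[.sub2ind(comp, d)] <- FALSE
    vol <- nrow(comp) * prod(spacing)
    if (vol >= min_volume_ul && vol <= max_volume_ul) {
      sp <- drop(voxel_to_world(seed_ijk, spacing))
      out[[length(out) + 1L]] <- .make_segmented_marker(comp, hu, spacing,
                                                        sp, params)
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "volume_ul"), decreasing = TRUE)]
}
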