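# File interfaces: NIfTI-1 volumes (spacing in the header), YAML scene
# configuration, CSV seed-point and per-marker tables, JSON results.

#' Write a CT volume as NIfTI-1
#'
#' @param volume A `ct_volume` (or a bare 3D array with `spacing` supplied).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing, required when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing = NULL) {
  if (inherits(volume, "ct_volume")) {
    arr <- volume$hu
    spacing <- volume$spacing
  } else {
    arr <- volume
    if (is.null(spacing)) stop("spacing required for a bare array")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return List with `hu` (3D array) and `spacing` (mm), class `ct_volume`
#'   (protocol metadata absent).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  structure(list(hu = array(as.numeric(img), dim(img)[1:3]),
                 spacing = as.numeric(spacing),
                 protocol = NULL, seed = NA_integer_),
            class = "ct_volume")
}

#' Read a scene configuration from YAML
#'
#' The YAML mirrors [scene_config()]: top-level keys `seed` (required),
#' `spacing`, `dim`, `marker_pitch`, `depth_range`, `air_thickness`,
#' `flap_thickness`, `include_bone`, `bone_depth`, `margin`, a `markers` list
#' (each with `nominal_volume` and optionally `center`, `shape`, `n_lobes`,
#' `iodine_concentration`, `depth`) and an optional `confounders` list (each
#' with `material`, `volume`, optionally `center`, `depth`).
#'
#' @param path YAML file path.
#' @return A [scene_config()].
#' @export
read_scene_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("scene configuration must contain a 'seed' key")
  markers <- lapply(y$markers, function(m)
    do.call(marker_spec, m[intersect(names(m),
      c("nominal_volume", "center", "shape", "n_lobes",
        "iodine_concentration", "depth"))]))
  confs <- lapply(y$confounders, function(cn)
    do.call(confounder_spec, cn[intersect(names(cn),
      c("material", "volume", "center", "depth"))]))
  args <- y[intersect(names(y),
    c("seed", "spacing", "dim", "marker_pitch", "depth_range",
      "air_thickness", "flap_thickness", "include_bone", "bone_depth",
      "margin"))]
  args$markers <- markers
  args$confounders <- confs
  if (!is.null(args$spacing)) args$spacing <- as.numeric(args$spacing)
  if (!is.null(args$dim)) args$dim <- as.integer(args$dim)
  do.call(scene_config, args)
}

#' Read seed points from CSV
#'
#' Expects columns `x_mm`, `y_mm`, `z_mm` and optionally `label`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `x_mm`, `y_mm`, `z_mm`, `label`.
#' @export
read_seed_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("seed-point CSV must contain columns x_mm, y_mm, z_mm")
  if (is.null(df$label)) df$label <- as.character(seq_len(nrow(df)))
  df[c("x_mm", "y_mm", "z_mm", "label")]
}

#' Write a per-marker segmentation table as CSV
#'
#' @param markers List of `segmented_marker` objects (entries that are
#'   `marker_not_visible` are written with `NA` volume).
#' @param path Output CSV path.
#' @param labels Optional character labels, one per marker.
#' @return The table, invisibly.
#' @export
write_marker_table <- function(markers, path, labels = NULL) {
  rows <- lapply(seq_along(markers), function(i) {
    m <- markers[[i]]
    lab <- if (!is.null(labels)) labels[i] else as.character(i)
    if (inherits(m, "marker_not_visible"))
      data.frame(label = lab, volume_ul = NA_real_, centroid_x = NA_real_,
                 centroid_y = NA_real_, centroid_z = NA_real_,
                 peak_hu = NA_real_, visible = FALSE)
    else
      data.frame(label = lab, volume_ul = m$volume_ul,
                 centroid_x = m$centroid[1], centroid_y = m$centroid[2],
                 centroid_z = m$centroid[3], peak_hu = m$peak_hu,
                 visible = TRUE)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
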