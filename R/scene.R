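# Digital phantom scenes: a flat soft-tissue block covered by a muscle flap,
# with superficially injected iodine markers, optional mandible bone slab with
# teeth, and non-iodine hyperdense confounders (titanium clips,
# calcifications). Stands in for the ex-vivo porcine mandible segments and for
# the clinical tumour-bed situation.

#' Specify an injectable liquid marker
#'
#' Describes one injected marker deposit. Small injections (10 ul) form
#' compact, rounded deposits; larger ones (30 ul) spread into heterogeneous,
#' multilobular shapes; the default shape follows the nominal volume.
#'
#' @param nominal_volume Injected volume in ul. `10`, `20` and `30` replicate
#'   the study conditions; any positive volume is accepted.
#' @param center Optional world (x, y) mm position, or (x, y, z). When `NULL`
#'   (or when z is omitted) [build_scene()] places the marker on a regular
#'   grid pattern at the configured injection depth.
#' @param shape `"rounded"` (single lobe) or `"multilobular"` (2-4
#'   overlapping ellipsoidal lobes with jittered centres). Default: rounded
#'   up to 15 ul, multilobular above.
#' @param n_lobes Number of lobes; must be 1 for rounded markers and 2-4 for
#'   multilobular ones. Default: 1 / 2 / 3 for <= 15 / <= 25 / > 25 ul.
#' @param iodine_concentration Iodine concentration inside the deposit, in
#'   mg/ml (relative units). The default of 25 keeps the noise-free marker
#'   peak comfortably above the 140 HU threshold at every default energy
#'   (at 120 kV: 50 + 25 x 22 = 600 HU).
#' @param depth Depth of the deposit centre below the soft-tissue surface in
#'   mm, or `NULL` to draw uniformly from the scene's injection depth range
#'   (default 1-2 mm, the superficial injection technique).
#' @return Object of class `marker_spec`.
#' @examples
#' marker_spec(10)
#' marker_spec(30, shape = "multilobular", n_lobes = 3)
#' @export
marker_spec <- function(nominal_volume, center = NULL, shape = NULL,
                        n_lobes = NULL, iodine_concentration = 25,
                        depth = NULL) {
  stopifnot(is.numeric(nominal_volume), length(nominal_volume) == 1L,
            nominal_volume > 0, iodine_concentration > 0)
  if (is.null(shape))
    shape <- if (nominal_volume <= 15) "rounded" else "multilobular"
  shape <- match.arg(shape, c("rounded", "multilobular"))
  if (is.null(n_lobes))
    n_lobes <- if (shape == "rounded") 1L
               else if (nominal_volume <= 25) 2L else 3L
  n_lobes <- as.integer(n_lobes)
  if (shape == "rounded" && n_lobes != 1L)
    stop("rounded markers have exactly one lobe")
  if (shape == "multilobular" && (n_lobes < 2L || n_lobes > 4L))
    stop("multilobular markers have 2-4 lobes")
  if (!is.null(depth)) stopifnot(depth > 0)
  if (!is.null(center)) stopifnot(length(center) %in% c(2L, 3L))
  structure(
    list(nominal_volume = nominal_volume, center = center, shape = shape,
         n_lobes = n_lobes, iodine_concentration = iodine_concentration,
         depth = depth),
    class = "marker_spec")
}

#' Specify a non-iodine hyperdense confounder
#'
#' A titanium clip or calcification placed in the soft tissue; hyperdense in
#' CT but containing no iodine, so it persists in virtual non-contrast
#' reconstructions.
#'
#' @param material `"titanium_clip"` or `"calcification"`.
#' @param volume Object volume in ul.
#' @param center Optional world (x, y) or (x, y, z) mm; gridded with the
#'   markers when `NULL`.
#' @param depth Depth below the tissue surface in mm (default 3).
#' @return Object of class `confounder_spec`.
#' @export
confounder_spec <- function(material = c("titanium_clip", "calcification"),
                            volume = 20, center = NULL, depth = 3) {
  material <- match.arg(material)
  stopifnot(volume > 0, depth > 0)
  structure(list(material = material, volume = volume, center = center,
                 depth = depth),
            class = "confounder_spec")
}

#' Scene configuration
#'
#' Describes the phantom geometry: grid, layer structure (air above a muscle
#' flap above soft tissue, optional bone slab with teeth at depth), the marker
#' list, confounders and the RNG seed that fixes all geometric jitter.
#'
#' @param markers List of [marker_spec()] objects.
#' @param seed Integer RNG seed (required); fixes marker placement jitter,
#'   injection depths and lobe geometry.
#' @param confounders List of [confounder_spec()] objects.
#' @param spacing Voxel spacing (dx, dy, dz) mm. Default `c(0.4, 0.4, 0.6)`:
#'   0.6 mm reconstructed slice thickness with a typical head in-plane pitch.
#' @param dim Optional grid dimensions (nx, ny, nz); computed from the marker
#'   layout when `NULL`.
#' @param marker_pitch Centre-to-centre spacing of the regular marker grid,
#'   mm (uniform distances between markers).
#' @param depth_range Injection depth range below the tissue surface, mm.
#' @param air_thickness,flap_thickness Thickness of the air gap and the
#'   covering muscle flap, mm.
#' @param include_bone Add a mandible bone slab (with two teeth) at
#'   `bone_depth` below the tissue surface.
#' @param bone_depth Depth of the bone slab top below the tissue surface, mm.
#' @param margin In-plane margin around the marker grid, mm.
#' @param material_table Material HU table, see [default_material_table()].
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(markers, seed, confounders = list(),
                         spacing = c(0.4, 0.4, 0.6), dim = NULL,
                         marker_pitch = 10, depth_range = c(1, 2),
                         air_thickness = 3, flap_thickness = 5,
                         include_bone = TRUE, bone_depth = 18,
                         margin = 8, material_table = default_material_table()) {
  stopifnot(is.list(markers),
            all(vapply(markers, inherits, logical(1), "marker_spec")),
            all(vapply(confounders, inherits, logical(1), "confounder_spec")),
            length(spacing) == 3L, all(spacing > 0),
            length(depth_range) == 2L, all(depth_range > 0),
            diff(depth_range) >= 0, marker_pitch > 0, margin > 0)
  if (missing(seed) || !is.numeric(seed))
    stop("scene_config requires an integer 'seed'")
  seed <- as.integer(seed)
  n_obj <- length(markers) + length(confounders)
  if (is.null(dim)) {
    ncols <- max(1L, ceiling(sqrt(n_obj)))
    nrows <- max(1L, ceiling(n_obj / max(ncols, 1L)))
    ext_x <- (ncols - 1) * marker_pitch + 2 * margin
    ext_y <- (nrows - 1) * marker_pitch + 2 * margin
    depth_mm <- air_thickness + flap_thickness +
      (if (include_bone) bone_depth + 8 else 16)
    dim <- c(ceiling(ext_x / spacing[1]), ceiling(ext_y / spacing[2]),
             ceiling(depth_mm / spacing[3]))
  }
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim > 0))
  structure(
    list(markers = markers, confounders = confounders, seed = seed,
         spacing = spacing, dim = dim, marker_pitch = marker_pitch,
         depth_range = depth_range, air_thickness = air_thickness,
         flap_thickness = flap_thickness, include_bone = include_bone,
         bone_depth = bone_depth, margin = margin,
         material_table = material_table),
    class = "scene_config")
}

# regular grid of in-plane positions for n objects, row-major, centred
.grid_positions <- function(n, dim, spacing, pitch, margin) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  ncols <- max(1L, ceiling(sqrt(n)))
  nrows <- max(1L, ceiling(n / ncols))
  size <- dim[1:2] * spacing[1:2]
  x0 <- (size[1] - (ncols - 1) * pitch) / 2
  y0 <- (size[2] - (nrows - 1) * pitch) / 2
  pos <- expand.grid(col = seq_len(ncols), row = seq_len(nrows))[seq_len(n), ]
  cbind(x0 + (pos$col - 1) * pitch, y0 + (pos$row - 1) * pitch)
}

# deposit geometry: lobe offsets (n x 3, mm, relative to centre) and
# semiaxes (n x 3, mm) before calibration; uses the current RNG stream
.draw_lobes <- function(spec) {
  r0 <- (3 * spec$nominal_volume / (4 * pi))^(1 / 3)
  n <- spec$n_lobes
  if (spec$shape == "rounded") {
    ax <- r0 * stats::runif(3, 0.92, 1.08)
    return(list(offsets = matrix(0, 1, 3), semiaxes = rbind(ax)))
  }
  rl <- r0 * n^(-1 / 4)   # lobes overlap; calibration fixes the total volume
  offsets <- matrix(stats::runif(3 * n, -0.6, 0.6) * rl, n, 3)
  offsets <- sweep(offsets, 2, colMeans(offsets))  # keep the centroid put
  semiaxes <- matrix(rl * stats::runif(3 * n, 0.8, 1.2), n, 3)
  list(offsets = offsets, semiaxes = semiaxes)
}

#' Build a phantom scene
#'
#' Rasterises the configured scene: layered background (air, muscle flap,
#' soft tissue, optional bone slab with teeth), markers placed on a regular
#' grid pattern at their injection depth below the flat tissue surface, and
#' confounders. Marker geometric volumes match their nominal volume within
#' 5% before any blur. All jitter (sub-voxel placement, depth, lobe shapes)
#' is drawn from the configuration seed, so the scene is reproducible.
#'
#' @param config A [scene_config()].
#' @return Object of class `phantom_scene` with elements `label` (integer
#'   material-code array), `iodine` (mg/ml array, positive only inside marker
#'   voxels), `spacing`, `markers` (data frame: id, nominal_ul, x, y, z,
#'   shape, n_lobes, raster_ul), `marker_voxels` (list of linear voxel index
#'   vectors), `confounders` (data frame), `config`.
#' @examples
#' sc <- build_scene(scene_config(list(marker_spec(10)), seed = 1))
#' sc$markers$raster_ul
#' @export
build_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  dim <- config$dim; spacing <- config$spacing
  codes <- .material_codes
  label <- array(codes[["soft_tissue"]], dim)
  zc <- (seq_len(dim[3]) - 0.5) * spacing[3]
  air_z <- zc < config$air_thickness
  flap_z <- !air_z & zc < config$air_thickness + config$flap_thickness
  if (any(air_z)) label[, , air_z] <- codes[["air"]]
  if (any(flap_z)) label[, , flap_z] <- codes[["muscle_flap"]]
  surface_z <- config$air_thickness + config$flap_thickness

  if (config$include_bone) {
    bone_z <- zc >= surface_z + config$bone_depth
    if (any(bone_z)) label[, , bone_z] <- codes[["bone"]]
    # two teeth: cylinders rising 5 mm proud of the bone slab, near one edge
    tooth_z <- zc >= surface_z + config$bone_depth - 5 & !air_z & !flap_z
    if (any(tooth_z)) {
      xs <- (seq_len(dim[1]) - 0.5) * spacing[1]
      ys <- (seq_len(dim[2]) - 0.5) * spacing[2]
      for (tx in c(0.25, 0.75) * dim[1] * spacing[1]) {
        ty <- 2.5
        in_xy <- outer((xs - tx)^2, (ys - ty)^2, "+") <= 2^2
        for (k in which(tooth_z)) {
          sl <- label[, , k]
          sl[in_xy] <- codes[["tooth"]]
          label[, , k] <- sl
        }
      }
    }
  }

  set.seed(config$seed)
  n_m <- length(config$markers); n_c <- length(config$confounders)
  grid_xy <- .grid_positions(n_m + n_c, dim, spacing, config$marker_pitch,
                             config$margin)
  iodine <- array(0, dim)
  assigned <- array(FALSE, dim)
  marker_voxels <- vector("list", n_m)
  mrec <- vector("list", n_m)

  place_center <- function(spec, slot) {
    if (!is.null(spec$center) && length(spec$center) == 3L)
      return(as.numeric(spec$center))
    xy <- if (!is.null(spec$center)) as.numeric(spec$center[1:2])
          else grid_xy[slot, ] + stats::runif(2, -0.5, 0.5) * spacing[1:2]
    depth <- if (!is.null(spec$depth)) spec$depth
             else stats::runif(1, config$depth_range[1], config$depth_range[2])
    c(xy, surface_z + depth)
  }

  for (m in seq_len(n_m)) {
    spec <- config$markers[[m]]
    center <- place_center(spec, m)
    lob <- .draw_lobes(spec)
    ras <- .rasterize_calibrated(center, lob$offsets, lob$semiaxes,
                                 spec$nominal_volume, dim, spacing)
    if (any(assigned[ras$indices]))
      stop("overlapping markers in scene (markers ", m, " and an earlier one)")
    assigned[ras$indices] <- TRUE
    iodine[ras$indices] <- spec$iodine_concentration
    marker_voxels[[m]] <- ras$indices
    mrec[[m]] <- data.frame(
      id = m, nominal_ul = spec$nominal_volume, x = center[1], y = center[2],
      z = center[3], shape = spec$shape, n_lobes = spec$n_lobes,
      raster_ul = ras$volume_ul)
  }

  crec <- vector("list", n_c)
  for (cc in seq_len(n_c)) {
    spec <- config$confounders[[cc]]
    center <- if (!is.null(spec$center) && length(spec$center) == 3L)
      as.numeric(spec$center)
    else {
      xy <- if (!is.null(spec$center)) as.numeric(spec$center[1:2])
            else grid_xy[n_m + cc, ]
      c(xy, surface_z + spec$depth)
    }
    r <- (3 * spec$volume / (4 * pi))^(1 / 3)
    ras <- .rasterize_calibrated(center, matrix(0, 1, 3), rbind(rep(r, 3)),
                                 spec$volume, dim, spacing)
    if (any(assigned[ras$indices]))
      stop("confounder ", cc, " overlaps a previously placed object")
    assigned[ras$indices] <- TRUE
    label[ras$indices] <- codes[[spec$material]]
    crec[[cc]] <- data.frame(
      id = cc, material = spec$material, x = center[1], y = center[2],
      z = center[3], volume_ul = ras$volume_ul)
  }

  structure(
    list(label = label, iodine = iodine, spacing = spacing,
         markers = if (n_m) do.call(rbind, mrec) else
           data.frame(id = integer(0), nominal_ul = numeric(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      shape = character(0), n_lobes = integer(0),
                      raster_ul = numeric(0)),
         marker_voxels = marker_voxels,
         confounders = if (n_c) do.call(rbind, crec) else
           data.frame(id = integer(0), material = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      volume_ul = numeric(0)),
         config = config),
    class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  d <- dim(x$label)
  cat(sprintf("<phantom_scene> %d x %d x %d voxels @ %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  markers: %d (%s ul), confounders: %d\n",
              nrow(x$markers),
              paste(sort(unique(x$markers$nominal_ul)), collapse = "/"),
              nrow(x$confounders)))
  invisible(x)
}
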