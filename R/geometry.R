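# 3D geometry helpers: voxel/world coordinate conversion, separable Gaussian
# blur, and rasterisation of marker shapes with volume calibration.
#
# Conventions: arrays are indexed 1-based in R; voxel (i, j, k) has its centre
# at world coordinates ((i - 0.5) dx, (j - 0.5) dy, (k - 0.5) dz), i.e. world
# coordinates are mm from the grid origin corner.

#' Convert voxel indices to world coordinates (voxel centres)
#'
#' @param ijk Integer matrix (n x 3) or vector of length 3 of 1-based voxel
#'   indices.
#' @param spacing Numeric length-3 voxel spacing (dx, dy, dz) in mm.
#' @return Numeric matrix (n x 3) of world coordinates in mm.
#' @export
voxel_to_world <- function(ijk, spacing) {
  ijk <- rbind(ijk)
  sweep(ijk - 0.5, 2, spacing, "*")
}

#' Convert world coordinates to voxel indices
#'
#' Returns the 1-based index of the voxel whose cell contains the point
#' (half-open cells).
#'
#' @inheritParams voxel_to_world
#' @param xyz Numeric matrix (n x 3) or vector of length 3, world mm.
#' @return Integer matrix (n x 3).
#' @export
world_to_voxel <- function(xyz, spacing) {
  xyz <- rbind(xyz)
  ijk <- floor(sweep(xyz, 2, spacing, "/")) + 1L
  storage.mode(ijk) <- "integer"
  ijk
}

# linear index (1-based) from an n x 3 index matrix
.sub2ind <- function(ijk, dim) {
  (ijk[, 3L] - 1L) * (dim[1L] * dim[2L]) + (ijk[, 2L] - 1L) * dim[1L] + ijk[, 1L]
}

.gauss_kernel_1d <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Band matrix realising 1D convolution with edge renormalisation, so a
# constant field is preserved exactly at the boundaries.
.conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- kernel[ok]
    K[i, ] <- K[i, ] / sum(K[i, ])
  }
  K
}

.convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  K <- .conv_matrix(da[1L], kernel)
  a <- array(K %*% matrix(a, nrow = da[1L]), dim = da)
  aperm(a, order(perm))
}

#' Separable 3D Gaussian blur
#'
#' Convolves a 3D array with an isotropic (in world units) Gaussian kernel of
#' the given full width at half maximum. The kernel is applied separably along
#' each axis with its width expressed in voxels of that axis' spacing;
#' boundary rows are renormalised so constant fields are preserved.
#'
#' @param arr 3D numeric array.
#' @param fwhm Full width at half maximum in mm; `0` returns `arr` unchanged.
#' @param spacing Voxel spacing (dx, dy, dz) in mm.
#' @return Blurred array of the same dimensions.
#' @export
gaussian_blur3 <- function(arr, fwhm, spacing) {
  stopifnot(length(dim(arr)) == 3L, fwhm >= 0, length(spacing) == 3L,
            all(spacing > 0))
  if (fwhm == 0) return(arr)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    s <- sigma_mm / spacing[ax]
    if (s > 1e-6) arr <- .convolve_axis(arr, .gauss_kernel_1d(s), ax)
  }
  arr
}

# --- marker rasterisation ---------------------------------------------------

# Rasterise a union of ellipsoidal lobes. centers: n x 3 world mm,
# semiaxes: n x 3 mm. Returns 1-based linear voxel indices of the union.
# Errors if the union's bounding box leaves the grid.
.rasterize_lobes <- function(centers, semiaxes, dim, spacing) {
  centers <- rbind(centers)
  semiaxes <- rbind(semiaxes)
  lo_w <- apply(centers - semiaxes, 2, min)
  hi_w <- apply(centers + semiaxes, 2, max)
  lo <- floor(lo_w / spacing) + 1L
  hi <- ceiling(hi_w / spacing)
  if (any(lo < 1L) || any(hi > dim))
    stop("marker extends outside the grid")
  xs <- (lo[1]:hi[1] - 0.5) * spacing[1]
  ys <- (lo[2]:hi[2] - 0.5) * spacing[2]
  zs <- (lo[3]:hi[3] - 0.5) * spacing[3]
  mask <- array(FALSE, c(length(xs), length(ys), length(zs)))
  for (l in seq_len(nrow(centers))) {
    mx <- ((xs - centers[l, 1]) / semiaxes[l, 1])^2
    my <- ((ys - centers[l, 2]) / semiaxes[l, 2])^2
    mz <- ((zs - centers[l, 3]) / semiaxes[l, 3])^2
    mask <- mask | (outer(outer(mx, my, "+"), mz, "+") <= 1)
  }
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(integer(0))
  ijk <- cbind(w[, 1L] + lo[1L] - 1L, w[, 2L] + lo[2L] - 1L,
               w[, 3L] + lo[3L] - 1L)
  .sub2ind(ijk, dim)
}

# Calibrate a lobe union so its rasterised volume matches target_ul.
# Scales semiaxes and lobe-centre offsets jointly (shape-preserving) by
# bisection on the monotone voxel count. Returns list(indices, volume_ul).
.rasterize_calibrated <- function(center, lobe_offsets, lobe_semiaxes,
                                  target_ul, dim, spacing, tol_frac = 0.02) {
  voxvol <- prod(spacing)
  target_n <- max(1L, round(target_ul / voxvol))
  tol_n <- max(1L, floor(tol_frac * target_n))
  count_at <- function(s) {
    centers <- sweep(lobe_offsets * s, 2, center, "+")
    idx <- .rasterize_lobes(centers, lobe_semiaxes * s, dim, spacing)
    list(n = length(idx), idx = idx)
  }
  lo <- 0.5; hi <- 2.0
  # ensure the bracket straddles the target
  while (count_at(hi)$n < target_n && hi < 8) hi <- hi * 1.5
  while (count_at(lo)$n > target_n && lo > 0.05) lo <- lo / 1.5
  best <- NULL
  for (it in 1:48) {
    mid <- (lo + hi) / 2
    res <- count_at(mid)
    if (is.null(best) || abs(res$n - target_n) < abs(best$n - target_n))
      best <- res
    if (abs(res$n - target_n) <= tol_n) break
    if (res$n < target_n) lo <- mid else hi <- mid
  }
  vol <- best$n * voxvol
  if (abs(vol - target_ul) / target_ul > 0.05)
    stop(sprintf(
      "could not rasterise marker to within 5%% of %.2f ul (got %.2f ul); grid too coarse?",
      target_ul, vol))
  list(indices = best$idx, volume_ul = vol)
}
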