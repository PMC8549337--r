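# Forward model: scene -> CT volume. Noise-free, blur-free acquisition is an
# exact HU lookup (material baseline + iodine concentration x contrast);
# partial-volume effects are modelled by an isotropic Gaussian PSF and noise
# as additive Gaussian HU, both per acquisition protocol.

#' Simulate a single-energy CT acquisition
#'
#' Computes `hu = blur(material HU at the protocol energy + iodine x
#' iodine_hu_per_unit, psf_fwhm) + N(0, noise_sd)`. The result is bit-identical
#' for identical `(scene, protocol, seed)`.
#'
#' @param scene A [build_scene()] result.
#' @param protocol An [acquisition_protocol()].
#' @param seed Integer seed for the noise stream.
#' @return Object of class `ct_volume`: `hu` (3D array), `spacing`,
#'   `protocol`, `seed`.
#' @examples
#' sc <- build_scene(scene_config(list(marker_spec(10)), seed = 1))
#' vol <- acquire_ct(sc, default_protocols()[["120"]], seed = 2)
#' range(vol$hu)
#' @export
acquire_ct <- function(scene, protocol, seed) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(protocol, "acquisition_protocol"))
  seed <- as.integer(seed)
  hu_lut <- .material_hu_vector(scene$config$material_table,
                                protocol$energy_label)
  base <- array(hu_lut[scene$label], dim(scene$label))
  base <- base + scene$iodine * protocol$iodine_hu_per_unit
  hu <- gaussian_blur3(base, protocol$psf_fwhm, scene$spacing)
  if (protocol$noise_sd > 0) {
    set.seed(seed)
    hu <- hu + array(stats::rnorm(length(hu), 0, protocol$noise_sd), dim(hu))
  }
  structure(list(hu = hu, spacing = scene$spacing, protocol = protocol,
                 seed = seed),
            class = "ct_volume")
}

#' Simulate a dual-energy CT acquisition
#'
#' Acquires the same scene with the low-energy A-tube and the (tin-filtered)
#' high-energy B-tube on a shared grid, with independent noise streams derived
#' from `seed`. The A-tube iodine contrast must exceed the B-tube's.
#'
#' @inheritParams acquire_ct
#' @param protocol_a,protocol_b A- and B-tube protocols; `protocol_a$kv` must
#'   be below `protocol_b$kv`.
#' @return Object of class `dect_acquisition`: list with `a` and `b`
#'   [acquire_ct()] volumes.
#' @export
acquire_dect <- function(scene, protocol_a, protocol_b, seed) {
  stopifnot(inherits(protocol_a, "acquisition_protocol"),
            inherits(protocol_b, "acquisition_protocol"))
  if (!(protocol_a$kv < protocol_b$kv))
    stop("protocol_a must be the low-energy tube (kv_a < kv_b)")
  if (!(protocol_a$iodine_hu_per_unit > protocol_b$iodine_hu_per_unit))
    stop("A-tube iodine contrast must exceed the B-tube's")
  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max - 1L, 2L)
  structure(list(a = acquire_ct(scene, protocol_a, sub[1L]),
                 b = acquire_ct(scene, protocol_b, sub[2L])),
            class = "dect_acquisition")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf(
    "<ct_volume> %d x %d x %d @ %.2f x %.2f x %.2f mm, %s kV%s, HU [%.0f, %.0f]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    format(x$protocol$kv), if (x$protocol$tin_filter) " (Sn)" else "",
    min(x$hu), max(x$hu)))
  invisible(x)
}
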