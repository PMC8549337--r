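# Material attenuation tables and acquisition protocols.
#
# Energies are keyed by a label ("70", "80", "100", "120", "150Sn"): the tin-
# filtered high-energy tube of a dual-source scanner behaves like a distinct
# effective energy and gets its own column.

.MATERIALS <- c("air", "soft_tissue", "muscle_flap", "bone", "tooth",
                "titanium_clip", "calcification")

.material_codes <- stats::setNames(seq_along(.MATERIALS), .MATERIALS)

.ENERGY_LABELS <- c("70", "80", "100", "120", "150Sn")

#' Default material attenuation table
#'
#' Baseline Hounsfield units per material at the tube energies used by the
#' default protocols. Absolute values are nominal; the quantities the package
#' relies on are the orderings (bone above soft tissue, everything hyperdense
#' well above the 140 HU segmentation threshold, kV-dependence of bone and
#' calcification much weaker than that of iodine) rather than any single entry.
#'
#' @return Named list mapping material name to a named numeric vector of HU,
#'   keyed by energy label (`"70"`, `"80"`, `"100"`, `"120"`, `"150Sn"`).
#' @examples
#' default_material_table()$soft_tissue
#' @export
default_material_table <- function() {
  lab <- .ENERGY_LABELS
  list(
    air           = stats::setNames(rep(-1000, 5), lab),
    soft_tissue   = stats::setNames(rep(50, 5), lab),
    muscle_flap   = stats::setNames(rep(55, 5), lab),
    bone          = stats::setNames(c(1200, 1100, 900, 800, 700), lab),
    tooth         = stats::setNames(c(1900, 1800, 1600, 1500, 1400), lab),
    titanium_clip = stats::setNames(rep(3000, 5), lab),
    calcification = stats::setNames(c(600, 520, 480, 450, 430), lab)
  )
}

#' Default iodine contrast per energy
#'
#' HU produced by one concentration unit (mg/ml) of iodine at each tube
#' energy. Contrast decreases strictly with energy, modelling the loss of
#' iodine k-edge contrast at higher kV.
#'
#' @return Named numeric vector keyed by energy label.
#' @export
default_iodine_contrast <- function() {
  stats::setNames(c(38, 34, 26, 22, 12), .ENERGY_LABELS)
}

.energy_label <- function(kv, tin_filter = FALSE) {
  paste0(format(kv, trim = TRUE), if (tin_filter) "Sn" else "")
}

#' Acquisition protocol
#'
#' Bundles the acquisition settings of a simulated CT scan: tube voltage,
#' tube current-time product (metadata only), iodine contrast at this energy,
#' point-spread-function width, noise level and nominal slice thickness.
#'
#' @param kv Tube voltage in kV.
#' @param mas Tube current-time product in mAs. Metadata only; it does not
#'   enter the forward model beyond the default noise mapping of
#'   [default_protocols()].
#' @param iodine_hu_per_unit HU per mg/ml iodine at this energy. Defaults to
#'   the entry of [default_iodine_contrast()] for the energy label.
#' @param psf_fwhm Full width at half maximum of the isotropic Gaussian
#'   point-spread function, in mm. This is the mechanism producing
#'   partial-volume blooming of small high-contrast objects.
#' @param noise_sd Standard deviation of additive Gaussian noise, in HU.
#' @param slice_thickness Nominal reconstruction slice thickness in mm
#'   (metadata).
#' @param tin_filter Logical; `TRUE` for the tin-filtered high-energy tube of
#'   a dual-source scanner (energy label gets an `"Sn"` suffix).
#' @return An object of class `acquisition_protocol`.
#' @examples
#' acquisition_protocol(70, mas = 500, noise_sd = 4)
#' @export
acquisition_protocol <- function(kv, mas = NA_real_, iodine_hu_per_unit = NULL,
                                 psf_fwhm = 1.2, noise_sd = 6,
                                 slice_thickness = 0.6, tin_filter = FALSE) {
  stopifnot(is.numeric(kv), length(kv) == 1L, kv > 0,
            psf_fwhm >= 0, noise_sd >= 0, slice_thickness > 0)
  label <- .energy_label(kv, tin_filter)
  if (is.null(iodine_hu_per_unit)) {
    contrast <- default_iodine_contrast()
    if (!label %in% names(contrast))
      stop("no default iodine contrast for energy '", label,
           "'; supply iodine_hu_per_unit explicitly")
    iodine_hu_per_unit <- unname(contrast[label])
  }
  stopifnot(is.finite(iodine_hu_per_unit), iodine_hu_per_unit > 0)
  structure(
    list(kv = kv, tin_filter = tin_filter, energy_label = label, mas = mas,
         iodine_hu_per_unit = iodine_hu_per_unit, psf_fwhm = psf_fwhm,
         noise_sd = noise_sd, slice_thickness = slice_thickness),
    class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf(
    "<acquisition_protocol> %s kV%s, %s mAs, iodine %.1f HU/(mg/ml), PSF FWHM %.2f mm, noise SD %.1f HU\n",
    format(x$kv), if (x$tin_filter) " (Sn)" else "",
    ifelse(is.na(x$mas), "-", format(x$mas)),
    x$iodine_hu_per_unit, x$psf_fwhm, x$noise_sd))
  invisible(x)
}

#' Default acquisition protocols
#'
#' The three single-energy head-and-neck protocols (70 kV / 500 mAs,
#' 100 kV / 200 mAs, 120 kV / 120 mAs) plus the dual-source pair
#' (80 kV A-tube, tin-filtered 150 kV B-tube). Noise SD follows the preset
#' coupling of kV and mAs (500 mAs -> 4 HU, 200 mAs -> 6 HU, 120 mAs -> 8 HU);
#' the dual-energy tubes use 6 HU.
#'
#' @return Named list of [acquisition_protocol()] objects keyed by energy
#'   label.
#' @export
default_protocols <- function() {
  list(
    "70"    = acquisition_protocol(70,  mas = 500, noise_sd = 4),
    "80"    = acquisition_protocol(80,  noise_sd = 6),
    "100"   = acquisition_protocol(100, mas = 200, noise_sd = 6),
    "120"   = acquisition_protocol(120, mas = 120, noise_sd = 8),
    "150Sn" = acquisition_protocol(150, noise_sd = 6, tin_filter = TRUE)
  )
}

# HU lookup vector (indexed by material code) for one energy label.
.material_hu_vector <- function(material_table, energy_label) {
  hu <- vapply(.MATERIALS, function(m) {
    row <- material_table[[m]]
    if (is.null(row) || !energy_label %in% names(row))
      stop("material table has no entry for material '", m,
           "' at energy '", energy_label, "'")
    unname(row[energy_label])
  }, numeric(1))
  if (any(!is.finite(hu))) stop("non-finite HU in material table")
  hu
}
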