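#' Configure the synthetic microscope
#'
#' Acquisition model for rendered fields. Each nucleus is drawn as a
#' truncated 2D Gaussian disk (truncation at 3 sigma, i.e. at the nucleus
#' radius) whose total pre-noise signal is
#' `gain * exposure_ms * sat(content)`, where
#' `sat(c) = c * saturation_K / (c + saturation_K)` emulates dye-binding
#' saturation (`saturation_K = Inf` is the linear staining regime; lower
#' values compress the 4N:2N signal ratio toward 1, the mechanism by which
#' over-concentrated dye collapses the two-peak histogram). Per-pixel noise
#' is Poisson shot noise on the signal plus Gaussian read noise/offset
#' (`background_mean`, `background_sd`), and pixels are clipped to
#' `[0, detector_max]`.
#'
#' Magnification is emulated jointly by `nucleus_radius_px` (up with
#' magnification) and `cells_per_field` (down with magnification).
#'
#' @param exposure_ms Exposure time in milliseconds.
#' @param gain Counts per N-unit of DNA content per millisecond.
#' @param detector_max Full-scale detector value (4095 for a 12-bit CCD).
#' @param background_mean,background_sd Gaussian background level and spread
#'   in counts.
#' @param saturation_K Half-saturation constant in N units; `Inf` disables
#'   staining saturation.
#' @param nucleus_radius_px,nucleus_radius_sd Mean and SD of nucleus radius
#'   in pixels (radius `>= 2`).
#' @param field_shape Integer `c(rows, cols)` of the rendered field.
#' @param cells_per_field Nuclei per field.
#' @param clump_prob Probability that a nucleus is placed touching a
#'   previously placed one (segmented clumps).
#' @param seed Integer seed for rendering.
#'
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(exposure_ms = 5, gain = 400, detector_max = 4095,
                          background_mean = 10, background_sd = 3,
                          saturation_K = Inf,
                          nucleus_radius_px = 6, nucleus_radius_sd = 0.5,
                          field_shape = c(512L, 512L),
                          cells_per_field = 150L,
                          clump_prob = 0, seed = 1L) {
  if (detector_max <= background_mean || background_mean < 0) {
    cyto_abort("Need detector_max > background_mean >= 0.", "cyto_error_input")
  }
  if (gain <= 0) cyto_abort("`gain` must be > 0.", "cyto_error_input")
  if (exposure_ms <= 0) cyto_abort("`exposure_ms` must be > 0.", "cyto_error_input")
  if (nucleus_radius_px < 2) {
    cyto_abort("`nucleus_radius_px` must be >= 2 px.", "cyto_error_input")
  }
  if (clump_prob < 0 || clump_prob > 1) {
    cyto_abort("`clump_prob` must lie in [0, 1].", "cyto_error_input")
  }
  if (length(field_shape) != 2 || any(field_shape < 16)) {
    cyto_abort("`field_shape` must be two dimensions >= 16.", "cyto_error_input")
  }
  if (!is.finite(saturation_K) && !identical(saturation_K, Inf)) {
    cyto_abort("`saturation_K` must be positive or Inf.", "cyto_error_input")
  }
  if (saturation_K <= 0) cyto_abort("`saturation_K` must be > 0.", "cyto_error_input")
  structure(
    list(exposure_ms = exposure_ms, gain = gain, detector_max = detector_max,
         background_mean = background_mean, background_sd = background_sd,
         saturation_K = saturation_K,
         nucleus_radius_px = nucleus_radius_px,
         nucleus_radius_sd = nucleus_radius_sd,
         field_shape = as.integer(field_shape),
         cells_per_field = as.integer(cells_per_field),
         clump_prob = clump_prob, seed = as.integer(seed)),
    class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config>\n")
  cat(sprintf("  exposure %.3g ms, gain %.4g counts/N/ms, detector max %d\n",
              x$exposure_ms, x$gain, as.integer(x$detector_max)))
  cat(sprintf("  background %.3g +/- %.3g counts, saturation K = %s N\n",
              x$background_mean, x$background_sd, format(x$saturation_K)))
  cat(sprintf("  field %d x %d px, %d cells/field, radius %.3g +/- %.3g px, clump prob %.3g\n",
              x$field_shape[1], x$field_shape[2], x$cells_per_field,
              x$nucleus_radius_px, x$nucleus_radius_sd, x$clump_prob))
  invisible(x)
}

#' Staining-saturation transfer function
#'
#' Michaelis-Menten-like compression of DNA content into effective bound-dye
#' signal: `sat(c) = c * K / (c + K)`, with `sat(c) -> c` as `K -> Inf`.
#'
#' @param content DNA content in N units.
#' @param saturation_K Half-saturation constant in N units (`Inf` = linear).
#' @return Effective signal content in N units.
#' @export
saturate_content <- function(content, saturation_K) {
  if (is.infinite(saturation_K)) return(content)
  content * saturation_K / (content + saturation_K)
}

#' Map dye concentration to a saturation half-constant
#'
#' Staining chemistry is not modelled; dye concentration is mapped
#' monotonically onto the saturation half-constant as
#' `K = K_ref * (conc_ref / conc)^2`, anchored so that `conc_ref` (default
#' 0.6 ug/mL) maps to `K_ref = 8` N units — the strongest saturation at
#' which the 4N:2N signal ratio (1.67) still supports 2N/4N peak pairing.
#' The mapping shape is arbitrary by construction; only its direction and
#' the anchor are meaningful.
#'
#' @param concentration Dye concentration in ug/mL.
#' @param K_ref,conc_ref Anchor point of the map.
#' @return Saturation half-constant in N units.
#' @export
saturation_for_concentration <- function(concentration, K_ref = 8,
                                         conc_ref = 0.6) {
  if (any(concentration <= 0)) {
    cyto_abort("`concentration` must be > 0.", "cyto_error_input")
  }
  K_ref * (conc_ref / concentration)^2
}
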