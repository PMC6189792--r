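#' Acquisition exposure quality control
#'
#' Classifies a segmented field as over-exposed, under-exposed or ok.
#' Over-exposure ("flat peaks") is detected as detector clipping: the
#' fraction of in-nucleus pixels sitting at `detector_max` exceeding
#' `clip_threshold`. Under-exposure ("missing peaks") is a low peak
#' signal-to-noise ratio: the median over nuclei of
#' `(peak pixel - background) / background_sd` below `snr_threshold`.
#' Over-exposure takes precedence; every field receives exactly one status.
#'
#' @param image A `cyto_field` or pixel matrix.
#' @param labels Label matrix from [segment_nuclei()].
#' @param clip_threshold Maximum tolerated clipped in-nucleus pixel fraction
#'   (default 0.01).
#' @param snr_threshold Minimum tolerated peak SNR (default 3).
#' @return An `exposure_report`: list with `status` (one of `"ok"`,
#'   `"over_exposed"`, `"under_exposed"`), `clipped_pixel_fraction` and
#'   `peak_snr`.
#' @export
exposure_check <- function(image, labels, clip_threshold = 0.01,
                           snr_threshold = 3) {
  px <- field_pixels(image)
  dmax <- field_detector_max(image)
  ids <- unique(labels[labels > 0])
  if (length(ids) == 0) {
    warn("No nuclei segmented; field classified as under-exposed.")
    rep <- list(status = "under_exposed", clipped_pixel_fraction = 0,
                peak_snr = 0)
    class(rep) <- "exposure_report"
    return(rep)
  }
  bg <- estimate_background(image, foreground_mask = labels)
  bg_sd <- estimate_background_sd(image, foreground_mask = labels)
  in_nuc <- labels > 0
  clipped <- mean(px[in_nuc] >= dmax)
  peaks <- vapply(split(as.numeric(px[in_nuc]), labels[in_nuc]),
                  max, numeric(1))
  snr <- median((peaks - bg) / bg_sd)
  status <- if (clipped > clip_threshold) {
    "over_exposed"
  } else if (snr < snr_threshold) {
    "under_exposed"
  } else "ok"
  structure(list(status = status, clipped_pixel_fraction = clipped,
                 peak_snr = as.numeric(snr)),
            class = "exposure_report")
}

#' @export
print.exposure_report <- function(x, ...) {
  cat(sprintf("<exposure_report> %s | clipped %.4f | peak SNR %.1f\n",
              x$status, x$clipped_pixel_fraction, x$peak_snr))
  invisible(x)
}

#' Block-maximum intensity surface
#'
#' Downsamples a field by taking the maximum over `downsample` x
#' `downsample` blocks. Maximum (not mean) pooling preserves the flat-top
#' signature of clipped nuclei, which is what intensity surface plots are
#' inspected for when calibrating exposure.
#'
#' @param image A `cyto_field` or pixel matrix.
#' @param downsample Integer block size (`>= 1`; 1 returns a copy).
#' @return A numeric matrix of block maxima.
#' @export
intensity_surface <- function(image, downsample = 4L) {
  px <- field_pixels(image)
  ds <- as.integer(downsample)
  if (ds < 1) cyto_abort("`downsample` must be >= 1.", "cyto_error_input")
  if (ds == 1) return(px + 0)
  nr <- nrow(px); nc <- ncol(px)
  ri <- ceiling(seq_len(nr) / ds)
  ci <- ceiling(seq_len(nc) / ds)
  out <- t(vapply(split(seq_len(nr), ri), function(rr) {
    m <- px[rr, , drop = FALSE]
    colmax <- apply(m, 2, max)
    vapply(split(seq_len(nc), ci), function(cc) max(colmax[cc]), numeric(1))
  }, numeric(max(ci))))
  matrix(out, nrow = max(ri), ncol = max(ci))
}
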