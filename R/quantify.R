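#' Estimate the per-pixel background level of a field
#'
#' Median of the pixels outside the foreground. If no foreground mask is
#' given, a provisional mask is built from Otsu's threshold (dilated by a
#' small margin so dim nucleus rims do not leak into the background sample).
#' The median of a Gaussian background equals its mean, and is robust to
#' residual bright pixels. Background subtraction matters most at long
#' exposures, where the offset is a large share of each integrated intensity.
#'
#' @param image A `cyto_field` (or bare pixel matrix).
#' @param foreground_mask Optional label or logical matrix; nonzero/`TRUE`
#'   pixels are excluded from the background sample.
#' @return Background level in counts per pixel.
#' @export
estimate_background <- function(image, foreground_mask = NULL) {
  px <- field_pixels(image)
  if (is.null(foreground_mask)) {
    thr <- otsu_threshold(image)
    fg <- px > thr
    fg <- EBImage::dilate(fg, EBImage::makeBrush(7, "disc")) > 0
  } else {
    fg <- foreground_mask > 0
    if (!identical(dim(fg), dim(px))) {
      cyto_abort("`foreground_mask` must match the image dimensions.",
                 "cyto_error_input")
    }
  }
  bgpx <- px[!fg]
  if (length(bgpx) == 0) {
    cyto_abort("All pixels are foreground; field unusable for background estimation.",
               "cyto_error_qc")
  }
  as.numeric(median(bgpx))
}

## Robust background spread (counts): MAD of the background sample.
estimate_background_sd <- function(image, foreground_mask = NULL) {
  px <- field_pixels(image)
  fg <- if (is.null(foreground_mask)) {
    thr <- otsu_threshold(image)
    EBImage::dilate(px > thr, EBImage::makeBrush(7, "disc")) > 0
  } else foreground_mask > 0
  bgpx <- px[!fg]
  max(mad(bgpx), .Machine$double.eps)
}

field_pixels <- function(image) {
  if (inherits(image, "cyto_field")) image$pixels else image
}
field_detector_max <- function(image, default = 4095) {
  if (inherits(image, "cyto_field")) image$detector_max else default
}

otsu_threshold <- function(image) {
  px <- field_pixels(image)
  dmax <- field_detector_max(image, default = max(px, 1))
  levels <- as.integer(dmax) + 1L
  EBImage::otsu(px / dmax, range = c(0, 1), levels = levels) * dmax
}

#' Segment nuclei in a fluorescence field
#'
#' Global-threshold segmentation: pixels above an automatically chosen
#' threshold (Otsu's method by default) form nucleus cores; holes are filled,
#' cores are grown by a binary dilation of `grow_px` pixels (so each label
#' captures the dim rim of its nucleus) and connected components are
#' labelled; regions with area below `min_area` (noise specks) or above
#' `max_area` are discarded and labels renumbered consecutively. Two nuclei
#' whose grown cores touch are deliberately merged into a single label
#' (clumps are flagged downstream by [flag_clumps()], not split).
#'
#' @param image A `cyto_field` or pixel matrix.
#' @param min_area Minimum core area in pixels (smaller cores are noise).
#' @param max_area Optional maximum label area; larger labels are dropped.
#' @param threshold_method `"otsu"` (default) or a fixed numeric threshold.
#' @param grow_px Dilation radius applied to cores before labelling.
#' @return An integer label matrix; labels are consecutive positive
#'   integers, 0 is background. A blank field yields zero labels.
#' @export
segment_nuclei <- function(image, min_area = 30, max_area = Inf,
                           threshold_method = "otsu", grow_px = 3) {
  px <- field_pixels(image)
  thr <- if (is.numeric(threshold_method)) {
    threshold_method
  } else if (identical(threshold_method, "otsu")) {
    otsu_threshold(image)
  } else {
    cyto_abort("`threshold_method` must be \"otsu\" or a numeric threshold.",
               "cyto_error_input")
  }
  core <- px > thr
  # A global threshold is only meaningful when bright objects occupy a
  # minority of the field; on signal-free fields Otsu merely splits the
  # noise band and "foreground" covers about half the pixels. Treat such
  # fields (and empty ones) as blank.
  if (!any(core) || mean(core) > 0.3) {
    return(matrix(0L, nrow(px), ncol(px)))
  }
  core <- EBImage::fillHull(core)
  grown <- if (grow_px > 0) {
    EBImage::dilate(core, EBImage::makeBrush(2L * as.integer(grow_px) + 1L,
                                             "disc")) > 0
  } else {
    core
  }
  labels <- EBImage::bwlabel(grown)
  areas <- tabulate(labels[labels > 0])
  drop <- which(areas < min_area | areas > max_area)
  if (length(drop) > 0) {
    labels[labels %in% drop] <- 0L
  }
  old <- sort(unique(as.integer(labels[labels > 0])))
  lab <- matrix(match(as.integer(labels), old, nomatch = 0L),
                nrow(px), ncol(px))
  lab
}

#' Measure per-nucleus integrated intensities
#'
#' For each label: background-subtracted integrated intensity
#' `sum(pixel - background)` over the label's pixels (negative sums clamped
#' to 0), intensity-weighted-free centroid, and area. Quality flags:
#' `saturated` when more than `sat_frac` of the label's pixels sit at
#' `detector_max` (detector clipping), `edge` when the label touches the
#' field border (partial nuclei bias DNA content low).
#'
#' @param image A `cyto_field` or pixel matrix.
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param background Background level in counts per pixel (e.g. from
#'   [estimate_background()]).
#' @param sat_frac Saturated-pixel fraction above which a nucleus is flagged.
#' @return A tibble with columns `id`, `centroid_row`, `centroid_col`,
#'   `area_px`, `integrated_intensity`, `flag_edge`, `flag_saturated`,
#'   `flag_clump` (initialised `FALSE`; see [flag_clumps()]).
#' @export
measure_nuclei <- function(image, labels, background = 0, sat_frac = 0.05) {
  px <- field_pixels(image)
  if (!identical(dim(px), dim(labels))) {
    cyto_abort("`labels` must match the image dimensions.", "cyto_error_input")
  }
  dmax <- field_detector_max(image)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    return(tibble(id = integer(), centroid_row = numeric(),
                  centroid_col = numeric(), area_px = integer(),
                  integrated_intensity = numeric(), flag_edge = logical(),
                  flag_saturated = logical(), flag_clump = logical()))
  }
  sel <- labels > 0
  lab_v <- labels[sel]
  px_v <- as.numeric(px[sel])
  rows_v <- row(labels)[sel]
  cols_v <- col(labels)[sel]

  area <- tabulate(lab_v, nbins = max(ids))[ids]
  ii <- vapply(split(px_v, lab_v), sum, numeric(1))[as.character(ids)]
  ii <- pmax(ii - background * area, 0)
  cr <- vapply(split(rows_v, lab_v), mean, numeric(1))[as.character(ids)]
  cc <- vapply(split(cols_v, lab_v), mean, numeric(1))[as.character(ids)]
  nsat <- vapply(split(px_v >= dmax, lab_v), sum, numeric(1))[as.character(ids)]
  on_edge <- rows_v == 1 | rows_v == nrow(px) | cols_v == 1 | cols_v == ncol(px)
  edge <- vapply(split(on_edge, lab_v), any, logical(1))[as.character(ids)]

  tibble(id = as.integer(ids),
         centroid_row = as.numeric(cr), centroid_col = as.numeric(cc),
         area_px = as.integer(area),
         integrated_intensity = as.numeric(ii),
         flag_edge = as.logical(edge),
         flag_saturated = nsat / area > sat_frac,
         flag_clump = FALSE)
}

#' Flag probable clumps by area
#'
#' Two touching nuclei segmented as one object carry roughly double the area
#' (and the summed DNA signal) of a singleton; such objects are flagged and
#' excluded rather than split. A record is flagged when its area exceeds
#' `clump_factor` times the median area of all records.
#'
#' @param records Tibble from [measure_nuclei()].
#' @param clump_factor Area ratio threshold (default 1.8).
#' @return `records` with `flag_clump` updated.
#' @export
flag_clumps <- function(records, clump_factor = 1.8) {
  n_unflagged <- sum(!records$flag_edge & !records$flag_saturated)
  if (n_unflagged < 3) {
    warn("Fewer than 3 unflagged nuclei; clump flagging skipped.")
    return(records)
  }
  med <- median(records$area_px)
  dplyr::mutate(records,
                flag_clump = .data$area_px > clump_factor * med)
}

#' Quantify one field end to end
#'
#' Convenience wrapper: background estimation, segmentation, measurement and
#' clump flagging with one call.
#'
#' @param image A `cyto_field` or pixel matrix.
#' @param min_area,max_area,threshold_method,grow_px See [segment_nuclei()].
#' @param sat_frac See [measure_nuclei()].
#' @param clump_factor See [flag_clumps()].
#' @return A list with `records` (tibble), `labels` (matrix), `background`
#'   (counts/pixel) and `background_sd`.
#' @export
quantify_field <- function(image, min_area = 30, max_area = Inf,
                           threshold_method = "otsu", grow_px = 3,
                           sat_frac = 0.05, clump_factor = 1.8) {
  labels <- segment_nuclei(image, min_area = min_area, max_area = max_area,
                           threshold_method = threshold_method,
                           grow_px = grow_px)
  bg <- estimate_background(image, foreground_mask = labels)
  bg_sd <- estimate_background_sd(image, foreground_mask = labels)
  rec <- measure_nuclei(image, labels, background = bg, sat_frac = sat_frac)
  if (nrow(rec) > 0) rec <- flag_clumps(rec, clump_factor = clump_factor)
  list(records = rec, labels = labels, background = bg, background_sd = bg_sd)
}

#' Keep records usable for cytometry
#'
#' Drops records carrying any of the `edge`, `saturated` or `clump` flags;
#' flagged nuclei are excluded from DNA-content histograms by default.
#'
#' @param records Tibble from [measure_nuclei()]/[flag_clumps()].
#' @return Filtered tibble.
#' @export
unflagged_records <- function(records) {
  dplyr::filter(records,
                !.data$flag_edge, !.data$flag_saturated, !.data$flag_clump)
}
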