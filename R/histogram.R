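#' Build a fixed-interval DNA-content histogram
#'
#' Converts per-nucleus integrated intensities into frequency counts with a
#' fixed bin interval (default 60 intensity counts, the conventional
#' interval for these histograms). Bin `i` covers
#' `[origin + i*interval, origin + (i+1)*interval)` with bin center
#' `origin + (i + 0.5)*interval`; binning happens on raw integrated
#' intensities, before any axis normalization. Trailing empty bins are
#' trimmed.
#'
#' @param intensities Non-negative integrated intensities (counts).
#' @param interval Bin width in intensity counts (default 60).
#' @param origin Intensity at the first bin edge (default 0).
#' @return A `cyto_histogram`: a tibble with columns `bin_center`, `count`,
#'   `normalized_count` and `relative_dna` (the latter two `NA` until
#'   [normalize_axes()] is applied), with attributes `interval`, `origin`
#'   and `n`.
#' @export
#' @examples
#' build_histogram(c(30, 90, 150), interval = 60)
build_histogram <- function(intensities, interval = 60, origin = 0) {
  if (length(intensities) == 0) {
    cyto_abort("No intensities: nothing to analyze.", "cyto_error_input")
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    cyto_abort("Intensities must be finite and >= 0.", "cyto_error_input")
  }
  if (!is.numeric(interval) || interval <= 0) {
    cyto_abort("`interval` must be > 0.", "cyto_error_input")
  }
  idx <- floor((intensities - origin) / interval)
  if (any(idx < 0)) {
    cyto_abort("Intensities below the histogram origin.", "cyto_error_input")
  }
  counts <- tabulate(idx + 1, nbins = max(idx) + 1)
  centers <- origin + (seq_along(counts) - 0.5) * interval
  out <- tibble(bin_center = centers, count = as.integer(counts),
                normalized_count = NA_real_, relative_dna = NA_real_)
  new_cyto_histogram(out, interval = interval, origin = origin,
                     n = length(intensities))
}

new_cyto_histogram <- function(tbl, interval, origin, n) {
  structure(tbl, interval = interval, origin = origin, n = n,
            class = c("cyto_histogram", class(tibble())))
}

#' @export
print.cyto_histogram <- function(x, ...) {
  cat(sprintf("<cyto_histogram> %d events, %d bins, interval %g from %g\n",
              attr(x, "n"), nrow(x), attr(x, "interval"), attr(x, "origin")))
  NextMethod()
}

#' Normalize histogram axes
#'
#' Fills `normalized_count` (counts divided by the total event count, so the
#' y axis reads as a fraction of cells) and `relative_dna`
#' (`2 * bin_center / g1_peak_intensity`, so the G1 peak maps to 2 N units
#' and the G2/M peak is expected near 4 N).
#'
#' @param hist A `cyto_histogram`.
#' @param g1_peak_intensity Intensity of the G1 (2N) peak, e.g. from
#'   [find_g1_g2_peaks()].
#' @return The histogram with both normalized axes filled.
#' @export
normalize_axes <- function(hist, g1_peak_intensity) {
  if (!is.numeric(g1_peak_intensity) || g1_peak_intensity <= 0) {
    cyto_abort("`g1_peak_intensity` must be > 0.", "cyto_error_input")
  }
  total <- sum(hist$count)
  hist$normalized_count <- hist$count / total
  hist$relative_dna <- 2 * hist$bin_center / g1_peak_intensity
  hist
}

## Centered moving average, window 3, partial at the edges.
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  s <- x
  s[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  s[1] <- (x[1] + x[2]) / 2
  s[n] <- (x[n - 1] + x[n]) / 2
  s
}

local_maxima <- function(s) {
  n <- length(s)
  if (n < 3) return(integer())
  which(s[2:(n - 1)] >= s[1:(n - 2)] & s[2:(n - 1)] > s[3:n]) + 1L
}

#' Locate the G1 (2N) and G2/M (4N) histogram peaks
#'
#' Smooths the counts with a 3-bin centered moving average, finds local
#' maxima, and pairs the two peaks whose bin-center ratio is consistent with
#' DNA doubling (`g2/g1` in `[1.6, 2.4]`). Among qualifying pairs the one
#' maximizing the product of the two smoothed heights, weighted by a
#' Gaussian prior on the ratio centered at 2 (DNA content doubles from G1
#' to G2/M), wins; the prior keeps a weak but genuine 4N peak from losing
#' to noise bumps on the S-phase plateau when the G2/M population is small.
#' Failure to find any qualifying pair is the saturated-staining failure
#' mode in which the two-peak distribution has collapsed.
#'
#' @param hist A `cyto_histogram` with at least 6 bins.
#' @return A named numeric vector `c(g1 = ..., g2 = ...)` of peak bin
#'   centers (intensity counts).
#' @export
find_g1_g2_peaks <- function(hist) {
  if (nrow(hist) < 6) {
    cyto_abort("Histogram must have at least 6 bins.", "cyto_error_input")
  }
  s <- smooth3(hist$count)
  cand <- local_maxima(s)
  # prominence guards: a credible peak is not a stray count (>= 5% of the
  # tallest mode and >= 2 smoothed counts), and the 2N peak must be a major
  # mode (>= 50% of the tallest), since G1 dominates these histograms
  smax <- max(s)
  cand <- cand[s[cand] >= pmax(2, 0.05 * smax)]
  cand_g1 <- cand[s[cand] >= 0.5 * smax]
  best <- NULL; best_h <- -Inf
  if (length(cand) >= 2) {
    for (a in cand_g1) {
      for (b in cand) {
        if (b <= a) next
        ratio <- hist$bin_center[b] / hist$bin_center[a]
        if (ratio >= 1.6 && ratio <= 2.4) {
          h <- s[a] * s[b] * exp(-((ratio - 2) / 0.4)^2)
          if (h > best_h) { best_h <- h; best <- c(a, b) }
        }
      }
    }
  }
  if (is.null(best)) {
    cyto_abort(paste0(
      "Unimodal histogram: no 2N/4N peak pair with ratio in [1.6, 2.4] ",
      "(two-peak distribution collapsed, e.g. dye saturation)."),
      "cyto_error_unimodal")
  }
  c(g1 = hist$bin_center[best[1]], g2 = hist$bin_center[best[2]])
}

#' Score the two-peak character of a histogram
#'
#' `1 - valley/min(peaks)` on the smoothed counts, clamped to `[0, 1]`,
#' where `valley` is the minimum smoothed count strictly between the
#' detected 2N and 4N peaks and `min(peaks)` the smaller smoothed peak
#' height. A cleanly bimodal DNA histogram with an empty inter-peak region
#' scores 1; as staining saturation squeezes the peaks together their
#' flanks fill the valley and the score degrades; when no valid peak pair
#' exists at all (collapsed distribution) the score is 0.
#'
#' @param hist A `cyto_histogram`.
#' @return Score in `[0, 1]`.
#' @export
two_peak_score <- function(hist) {
  peaks <- tryCatch(find_g1_g2_peaks(hist),
                    cyto_error_unimodal = function(e) NULL,
                    cyto_error_input = function(e) NULL)
  if (is.null(peaks)) return(0)
  s <- smooth3(hist$count)
  i1 <- which.min(abs(hist$bin_center - peaks["g1"]))
  i2 <- which.min(abs(hist$bin_center - peaks["g2"]))
  if (i2 - i1 < 2) return(0)
  valley <- min(s[(i1 + 1):(i2 - 1)])
  smaller <- min(s[i1], s[i2])
  if (smaller <= 0) return(0)
  max(0, min(1, 1 - valley / smaller))
}
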