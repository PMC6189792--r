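#' Define phase gates on the intensity axis
#'
#' Three half-open intensity windows `[lo, hi)` for G1, S and G2/M. Windows
#' must be pairwise disjoint and ordered (`G1.hi <= S.lo`, `S.hi <= G2M.lo`);
#' events outside all three windows are left ungated (sub-G1 debris,
#' super-G2/M doublets, inter-gate events).
#'
#' @param g1,s,g2m Numeric `c(lo, hi)` windows in intensity counts.
#' @return An object of class `phase_gates`.
#' @export
#' @examples
#' phase_gates(g1 = c(240, 360), s = c(360, 480), g2m = c(480, 720))
phase_gates <- function(g1, s, g2m) {
  win <- list(G1 = as.numeric(g1), S = as.numeric(s), G2M = as.numeric(g2m))
  for (nm in names(win)) {
    w <- win[[nm]]
    if (length(w) != 2 || any(!is.finite(w)) || any(w < 0) || w[1] > w[2]) {
      cyto_abort(sprintf("Gate %s must be c(lo, hi) with 0 <= lo <= hi.", nm),
                 "cyto_error_input")
    }
  }
  if (win$G1[2] > win$S[1] || win$S[2] > win$G2M[1]) {
    cyto_abort("Gates must be ordered and disjoint: G1.hi <= S.lo, S.hi <= G2M.lo.",
               "cyto_error_input")
  }
  structure(win, class = "phase_gates")
}

#' @export
print.phase_gates <- function(x, ...) {
  cat("<phase_gates> [lo, hi) in intensity counts\n")
  for (nm in names(x)) {
    cat(sprintf("  %-3s [%g, %g)\n", nm, x[[nm]][1], x[[nm]][2]))
  }
  invisible(x)
}

#' Place automatic gates around the detected 2N and 4N peaks
#'
#' Symmetric multiplicative bands: G1 = `g1_peak * (1 +/- width_frac)`,
#' G2/M = `g2_peak * (1 +/- width_frac)`, and S the residual interval
#' between them. Sub-G1 and super-G2/M intensities remain ungated, which is
#' why gated fractions sum to less than 100% on real data. Manually set
#' gates (via [phase_gates()]) take precedence over automatic ones wherever
#' both are accepted.
#'
#' @param g1_peak,g2_peak Peak intensities, `g2_peak > g1_peak > 0`.
#' @param width_frac Half-width of the bands (default 0.15; must satisfy
#'   `0 < width_frac < 0.5` and leave a nonempty S window).
#' @return A [phase_gates()] object.
#' @export
#' @examples
#' auto_gates(300, 600, width_frac = 0.2)
auto_gates <- function(g1_peak, g2_peak, width_frac = 0.15) {
  if (!(g2_peak > g1_peak) || g1_peak <= 0) {
    cyto_abort("Need g2_peak > g1_peak > 0.", "cyto_error_input")
  }
  if (width_frac <= 0 || width_frac >= 0.5) {
    cyto_abort("`width_frac` must lie in (0, 0.5).", "cyto_error_input")
  }
  w <- width_frac
  g1_hi <- g1_peak * (1 + w)
  g2_lo <- g2_peak * (1 - w)
  if (g1_hi > g2_lo) {
    cyto_abort("`width_frac` too large: G1 and G2M windows overlap.",
               "cyto_error_input")
  }
  phase_gates(g1 = c(g1_peak * (1 - w), g1_hi),
              s = c(g1_hi, g2_lo),
              g2m = c(g2_lo, g2_peak * (1 + w)))
}

#' Compute gated phase fractions
#'
#' Assigns each intensity to the gate window containing it (half-open
#' `[lo, hi)` semantics, so boundary events are handled deterministically)
#' or to the ungated remainder. Fractions always satisfy
#' `pG1 + pS + pG2M + pUngated = 1`.
#'
#' @param intensities Integrated intensities (counts).
#' @param gates A [phase_gates()] object.
#' @return A `phase_fractions` object: list with `pG1`, `pS`, `pG2M`,
#'   `pUngated`, `n_total`. Use [generics::tidy()] for a tibble.
#' @export
gate_fractions <- function(intensities, gates) {
  if (length(intensities) == 0) {
    cyto_abort("No intensities to gate.", "cyto_error_input")
  }
  if (!inherits(gates, "phase_gates")) {
    cyto_abort("`gates` must be a phase_gates object.", "cyto_error_input")
  }
  in_win <- function(w) intensities >= w[1] & intensities < w[2]
  g1 <- in_win(gates$G1); s <- in_win(gates$S); g2 <- in_win(gates$G2M)
  n <- length(intensities)
  structure(
    list(pG1 = sum(g1) / n, pS = sum(s) / n, pG2M = sum(g2) / n,
         pUngated = sum(!(g1 | s | g2)) / n, n_total = n),
    class = "phase_fractions")
}

#' @export
print.phase_fractions <- function(x, ...) {
  cat(sprintf(
    "<phase_fractions> n = %d | G1 %.2f%% | S %.2f%% | G2M %.2f%% | ungated %.2f%%\n",
    x$n_total, 100 * x$pG1, 100 * x$pS, 100 * x$pG2M, 100 * x$pUngated))
  invisible(x)
}

#' Full cytometry step: histogram, peaks, gates, fractions
#'
#' Bins the intensities, locates the 2N/4N peaks, places gates (manual
#' gates, when given, take precedence over automatic ones), and computes
#' phase fractions plus the two-peak score.
#'
#' @param intensities Integrated intensities of unflagged nuclei.
#' @param interval,origin Histogram binning (see [build_histogram()]).
#' @param width_frac Auto-gate half-width (see [auto_gates()]).
#' @param gates Optional manual [phase_gates()]; overrides auto-gating.
#' @return A list with `histogram` (normalized when peaks were found),
#'   `peaks`, `gates`, `fractions` and `score`.
#' @export
analyze_intensities <- function(intensities, interval = 60, origin = 0,
                                width_frac = 0.15, gates = NULL) {
  hist <- build_histogram(intensities, interval = interval, origin = origin)
  score <- two_peak_score(hist)
  peaks <- NULL
  if (is.null(gates)) {
    peaks <- find_g1_g2_peaks(hist)  # propagates cyto_error_unimodal
    gates <- auto_gates(peaks["g1"], peaks["g2"], width_frac = width_frac)
  } else {
    peaks <- tryCatch(find_g1_g2_peaks(hist),
                      cyto_error_unimodal = function(e) NULL)
  }
  if (!is.null(peaks)) hist <- normalize_axes(hist, peaks[["g1"]])
  list(histogram = hist, peaks = peaks, gates = gates,
       fractions = gate_fractions(intensities, gates), score = score)
}
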