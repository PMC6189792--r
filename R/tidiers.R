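#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy phase fractions into a tibble
#'
#' @param x A `phase_fractions` object.
#' @param ... Unused.
#' @return Tibble with columns `phase`, `fraction`, `count`.
#' @export
tidy.phase_fractions <- function(x, ...) {
  tibble(phase = factor(c("G1", "S", "G2M", "ungated"),
                        levels = c("G1", "S", "G2M", "ungated")),
         fraction = c(x$pG1, x$pS, x$pG2M, x$pUngated),
         count = as.integer(round(c(x$pG1, x$pS, x$pG2M, x$pUngated) * x$n_total)))
}

#' @rdname tidy.phase_fractions
#' @export
glance.phase_fractions <- function(x, ...) {
  tibble(n_total = x$n_total, p_gated = x$pG1 + x$pS + x$pG2M,
         p_ungated = x$pUngated)
}

#' Tidy a one-way ANOVA result
#'
#' @param x A `cyto_anova` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p.value`, `df1`, `df2`.
#' @export
tidy.cyto_anova <- function(x, ...) {
  tibble(statistic = x$F, p.value = x$p, df1 = x$df1, df2 = x$df2)
}

#' @rdname tidy.cyto_anova
#' @export
glance.cyto_anova <- tidy.cyto_anova

#' Tidy an exposure QC report
#'
#' @param x An `exposure_report`.
#' @param ... Unused.
#' @return One-row tibble with `status`, `clipped_pixel_fraction`, `peak_snr`.
#' @export
tidy.exposure_report <- function(x, ...) {
  tibble(status = x$status,
         clipped_pixel_fraction = x$clipped_pixel_fraction,
         peak_snr = x$peak_snr)
}
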