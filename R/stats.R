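#' Summarize phase fractions across replicates
#'
#' Per-phase sample mean and sample standard deviation (n - 1 denominator)
#' across independent replicate analyses, optionally grouped by condition.
#'
#' @param fractions A list of `phase_fractions` objects (see
#'   [gate_fractions()]), or a tibble with columns `phase` and `fraction`
#'   (and optionally `condition`).
#' @param condition Optional character vector of condition labels, one per
#'   replicate (recycled against the list of fractions).
#' @return A tibble with columns `condition` (if any), `phase`, `mean`,
#'   `sd`, `n_replicates`. With a single replicate the SD is `NA` and a
#'   warning is raised.
#' @export
replicate_stats <- function(fractions, condition = NULL) {
  tbl <- fractions_to_tbl(fractions, condition)
  grp <- intersect(c("condition", "phase"), names(tbl))
  out <- dplyr::summarise(
    dplyr::group_by(tbl, dplyr::across(dplyr::all_of(grp))),
    mean = mean(.data$fraction),
    sd = if (dplyr::n() >= 2) sd(.data$fraction) else NA_real_,
    n_replicates = dplyr::n(),
    .groups = "drop")
  if (any(out$n_replicates < 2)) {
    warn("Single replicate: SD omitted (reported as NA).")
  }
  out
}

fractions_to_tbl <- function(fractions, condition = NULL) {
  if (inherits(fractions, "phase_fractions")) fractions <- list(fractions)
  if (is.data.frame(fractions)) return(as_tibble(fractions))
  if (length(fractions) == 0) {
    cyto_abort("Need at least one replicate.", "cyto_error_input")
  }
  tbl <- purrr::imap_dfr(fractions, function(f, i) {
    tibble(replicate = i,
           phase = factor(c("G1", "S", "G2M", "ungated"),
                          levels = c("G1", "S", "G2M", "ungated")),
           fraction = c(f$pG1, f$pS, f$pG2M, f$pUngated),
           n_total = f$n_total)
  })
  if (!is.null(condition)) {
    cond <- rep_len(condition, length(fractions))
    tbl$condition <- cond[tbl$replicate]
  }
  tbl
}

#' Classical one-way ANOVA across conditions
#'
#' Fixed-effects one-way analysis of variance with `(k - 1, N - k)` degrees
#' of freedom, as used to compare per-phase fractions between treatment
#' conditions (no multiple-testing correction is applied, matching common
#' practice of reporting per-phase ANOVA p-values directly).
#'
#' Degenerate inputs are handled as limits: when every value in every group
#' is identical, `F = 0` and `p = 1`; when group means differ but the
#' within-group variance is zero, `F = Inf` and `p = 0`.
#'
#' @param groups A list of numeric vectors, one per condition (`>= 2`
#'   groups, each with `>= 2` values).
#' @return A `cyto_anova` object: list with `F`, `p`, `df1`, `df2`.
#' @export
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7)))
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(vapply(groups, length, integer(1)) < 2)) {
    cyto_abort("Need >= 2 groups with >= 2 values each.", "cyto_error_input")
  }
  k <- length(groups)
  N <- sum(lengths(groups))
  df1 <- k - 1; df2 <- N - k
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), lengths(groups)))
  means <- vapply(groups, mean, numeric(1))
  ss_within <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ss_within <= .Machine$double.eps * sum(values^2)) {
    eq_means <- max(means) - min(means) <= .Machine$double.eps * max(abs(means), 1)
    out <- if (eq_means) list(F = 0, p = 1) else list(F = Inf, p = 0)
    return(structure(c(out, list(df1 = df1, df2 = df2)), class = "cyto_anova"))
  }
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  structure(list(F = unname(ht$statistic), p = unname(ht$p.value),
                 df1 = df1, df2 = df2),
            class = "cyto_anova")
}

#' @export
print.cyto_anova <- function(x, ...) {
  cat(sprintf("<cyto_anova> F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Per-phase ANOVA across conditions
#'
#' Runs [one_way_anova()] on each phase's replicate fractions grouped by
#' condition.
#'
#' @param fractions List of `phase_fractions` (or tibble; see
#'   [replicate_stats()]).
#' @param condition Condition label per replicate.
#' @return Tibble with columns `phase`, `F`, `p`, `df1`, `df2`.
#' @export
condition_anova <- function(fractions, condition) {
  tbl <- fractions_to_tbl(fractions, condition)
  purrr::map_dfr(split(tbl, tbl$phase), function(d) {
    groups <- split(d$fraction, d$condition)
    a <- one_way_anova(groups)
    tibble(phase = d$phase[1], F = a$F, p = a$p, df1 = a$df1, df2 = a$df2)
  })
}
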