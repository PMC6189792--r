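#' Define a ground-truth cell-cycle DNA-content mixture
#'
#' A `cell_cycle_mixture` describes the population a synthetic field of nuclei
#' is drawn from, in "N units" of DNA content: G0/G1 cells carry 2N, S-phase
#' cells are replicating (2N--4N), and G2/M cells carry 4N. Two nuisance
#' components complete the mixture: `debris` (sub-G1 fragments, content below
#' 2N) and `doublet` (two nuclei quantified as one, content the sum of two
#' independent cell draws). Measured content is perturbed multiplicatively by
#' a Gaussian coefficient of variation `cv`, emulating staining and
#' quantification spread.
#'
#' @param fG1,fS,fG2M,fDebris,fDoublet Non-negative fractions summing to 1.
#' @param cv Coefficient of variation of measured DNA content (unitless,
#'   `>= 0`). Typical image-cytometry G1 peak CVs are 0.04--0.08.
#'
#' @return An object of class `cell_cycle_mixture` (a named list).
#' @seealso [sample_dna_contents()], [calibrate_gated_mixture()]
#' @export
#' @examples
#' cell_cycle_mixture(fG1 = 0.6, fS = 0.15, fG2M = 0.25, cv = 0.05)
cell_cycle_mixture <- function(fG1 = 0.55, fS = 0.20, fG2M = 0.17,
                               fDebris = 0.06, fDoublet = 0.02, cv = 0.06) {
  f <- c(G1 = fG1, S = fS, G2M = fG2M, debris = fDebris, doublet = fDoublet)
  if (any(!is.finite(f)) || any(f < 0)) {
    cyto_abort("All mixture fractions must be finite and >= 0.",
               "cyto_error_input")
  }
  if (abs(sum(f) - 1) > 1e-8) {
    cyto_abort(
      sprintf("Mixture fractions must sum to 1 (got %.6f).", sum(f)),
      "cyto_error_input")
  }
  if (!is.finite(cv) || cv < 0) {
    cyto_abort("`cv` must be finite and >= 0.", "cyto_error_input")
  }
  structure(
    list(fG1 = fG1, fS = fS, fG2M = fG2M,
         fDebris = fDebris, fDoublet = fDoublet, cv = cv),
    class = "cell_cycle_mixture")
}

#' @export
print.cell_cycle_mixture <- function(x, ...) {
  cat("<cell_cycle_mixture>\n")
  cat(sprintf("  G1 %.3f | S %.3f | G2M %.3f | debris %.3f | doublet %.3f\n",
              x$fG1, x$fS, x$fG2M, x$fDebris, x$fDoublet))
  cat(sprintf("  content cv: %.3f\n", x$cv))
  invisible(x)
}

draw_one_cell <- function(n, phase_is_g1, cv) {
  base <- ifelse(phase_is_g1, 2, 4)
  base * (1 + rnorm(n, 0, cv))
}

#' Sample ground-truth DNA contents from a mixture
#'
#' Draws per-nucleus phase labels i.i.d. from the mixture fractions and
#' assigns true DNA contents in N units: G1 = `2 * (1 + e)`, G2/M =
#' `4 * (1 + e)` with `e ~ Normal(0, cv)`; S uniform on (2, 4) then perturbed
#' by the same multiplicative factor; debris uniform on (0.5, 1.8); doublets
#' are the sum of two independent G1/G2M-like cell draws (components chosen
#' in proportion to `fG1 : fG2M`).
#'
#' @param mixture A [cell_cycle_mixture()].
#' @param n Number of nuclei to draw (`>= 1`).
#' @param seed Integer seed; the same seed reproduces the draw exactly.
#'
#' @return A tibble with columns `phase` (factor: G1, S, G2M, debris,
#'   doublet) and `content` (N units, `> 0`).
#' @export
#' @examples
#' sample_dna_contents(cell_cycle_mixture(), n = 5, seed = 1)
sample_dna_contents <- function(mixture, n, seed = 1L) {
  if (!inherits(mixture, "cell_cycle_mixture")) {
    cyto_abort("`mixture` must be a cell_cycle_mixture.", "cyto_error_input")
  }
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1) {
    cyto_abort("`n` must be a single integer >= 1.", "cyto_error_input")
  }
  n <- as.integer(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  probs <- c(mixture$fG1, mixture$fS, mixture$fG2M,
             mixture$fDebris, mixture$fDoublet)
  levs <- c("G1", "S", "G2M", "debris", "doublet")
  phase <- sample(levs, n, replace = TRUE, prob = probs)
  cv <- mixture$cv

  content <- numeric(n)
  iG1 <- phase == "G1"; iS <- phase == "S"; iG2 <- phase == "G2M"
  iDe <- phase == "debris"; iDo <- phase == "doublet"
  content[iG1] <- 2 * (1 + rnorm(sum(iG1), 0, cv))
  content[iG2] <- 4 * (1 + rnorm(sum(iG2), 0, cv))
  content[iS]  <- runif(sum(iS), 2, 4) * (1 + rnorm(sum(iS), 0, cv))
  content[iDe] <- runif(sum(iDe), 0.5, 1.8)
  if (any(iDo)) {
    nd <- sum(iDo)
    rG <- if (mixture$fG1 + mixture$fG2M > 0) {
      mixture$fG1 / (mixture$fG1 + mixture$fG2M)
    } else 0.5
    a <- draw_one_cell(nd, runif(nd) < rG, cv)
    b <- draw_one_cell(nd, runif(nd) < rG, cv)
    content[iDo] <- a + b
  }
  content <- pmax(content, 1e-6)
  tibble(phase = factor(phase, levels = levs), content = content)
}

# Preserve the caller's RNG state across seeded draws.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Classify true DNA contents by ideal phase gates
#'
#' Ground-truth gating oracle: applies the ideal content-space counterparts of
#' the multiplicative auto-gates — G1 `[2(1-w), 2(1+w))`, S
#' `[2(1+w), 4(1-w))`, G2/M `[4(1-w), 4(1+w))` — to true contents in N units.
#' Everything outside the three windows is `ungated`.
#'
#' @param content Numeric vector of DNA contents (N units).
#' @param width_frac Half-width of the multiplicative gate bands (default
#'   0.15; see [auto_gates()]).
#' @return Factor with levels G1, S, G2M, ungated.
#' @export
classify_content <- function(content, width_frac = 0.15) {
  w <- width_frac
  out <- rep("ungated", length(content))
  out[content >= 2 * (1 - w) & content < 2 * (1 + w)] <- "G1"
  out[content >= 2 * (1 + w) & content < 4 * (1 - w)] <- "S"
  out[content >= 4 * (1 - w) & content < 4 * (1 + w)] <- "G2M"
  factor(out, levels = c("G1", "S", "G2M", "ungated"))
}

## Probability that one mixture component falls in [lo, hi) of content space.
## G1/G2M: Gaussian about 2 or 4; S: numeric integration over Uniform(2,4)
## with multiplicative Gaussian spread; debris: Uniform(0.5, 1.8) overlap.
.p_gauss_in <- function(base, cv, lo, hi) {
  if (cv == 0) return(as.numeric(base >= lo & base < hi))
  pnorm((hi / base - 1) / cv) - pnorm((lo / base - 1) / cv)
}
.p_s_in <- function(cv, lo, hi) {
  if (cv == 0) {
    return(max(0, min(hi, 4) - max(lo, 2)) / 2)
  }
  f <- function(u) pnorm((hi / u - 1) / cv) - pnorm((lo / u - 1) / cv)
  integrate(f, 2, 4, rel.tol = 1e-9)$value / 2
}
.p_debris_in <- function(lo, hi) {
  max(0, min(hi, 1.8) - max(lo, 0.5)) / 1.3
}

#' Calibrate a mixture to hit target gated phase fractions
#'
#' Finds mixture fractions (`fG1`, `fS`, `fG2M`, `fDebris`; `fDoublet` fixed)
#' such that the *expected gated* fractions under the ideal content-space
#' gates of [classify_content()] equal the requested targets. This is how a
#' synthetic experiment is pinned to published gated percentages, which sum
#' to less than 100% because debris, doublets and inter-gate events are left
#' ungated.
#'
#' The inversion uses exact component probabilities (Gaussian tail formulas
#' for G1/G2M, numeric integration for the uniform S population, interval
#' overlap for debris, and the two-component convolution for doublets) and
#' solves an iterated 3x3 linear system; it involves no simulation.
#'
#' @param pG1,pS,pG2M Target gated fractions (unitless, e.g. 0.5102).
#' @param cv Content coefficient of variation (default 0.06).
#' @param width_frac Gate half-width (default 0.15).
#' @param doublet_frac Fixed doublet fraction (default 0.02).
#' @return A [cell_cycle_mixture()].
#' @export
#' @examples
#' m <- calibrate_gated_mixture(0.5102, 0.1230, 0.2736)
#' table(classify_content(sample_dna_contents(m, 5000, seed = 7)$content))
calibrate_gated_mixture <- function(pG1, pS, pG2M, cv = 0.06,
                                    width_frac = 0.15, doublet_frac = 0.02) {
  w <- width_frac
  tg <- c(pG1, pS, pG2M)
  if (any(tg < 0) || sum(tg) >= 1) {
    cyto_abort("Target gated fractions must be >= 0 and sum to < 1.",
               "cyto_error_input")
  }
  gates <- list(G1 = c(2 * (1 - w), 2 * (1 + w)),
                S = c(2 * (1 + w), 4 * (1 - w)),
                G2M = c(4 * (1 - w), 4 * (1 + w)))
  # component-by-gate probability matrix (rows: gates, cols: G1, S, G2M cells)
  A <- sapply(list(
    G1  = function(lo, hi) .p_gauss_in(2, cv, lo, hi),
    S   = function(lo, hi) .p_s_in(cv, lo, hi),
    G2M = function(lo, hi) .p_gauss_in(4, cv, lo, hi)),
    function(p) vapply(gates, function(g) p(g[1], g[2]), numeric(1)))
  d_in <- vapply(gates, function(g) .p_debris_in(g[1], g[2]), numeric(1))

  fDub <- doublet_frac
  rG <- 0.7 # doublet G1-component share; refined below
  f <- NULL
  for (it in 1:50) {
    # doublet lands in a gate essentially only as a G1+G1 pair near 4N
    p4 <- .p_gauss_in(4, cv / sqrt(2), gates$G2M[1], gates$G2M[2])
    dub_in <- c(0, 0, rG^2 * p4)
    # substitute fDebris = 1 - fDub - fG1 - fS - fG2M
    M <- A - matrix(d_in, 3, 3)
    rhs <- tg - d_in * (1 - fDub) - dub_in * fDub
    f_new <- solve(M, rhs)
    rG_new <- if (f_new[1] + f_new[3] > 0) f_new[1] / (f_new[1] + f_new[3]) else 0.5
    done <- !is.null(f) && max(abs(f_new - f)) < 1e-12
    f <- f_new; rG <- rG_new
    if (done) break
  }
  fDeb <- 1 - fDub - sum(f)
  if (any(f < -1e-9) || fDeb < -1e-9) {
    cyto_abort(paste0(
      "Target gated fractions are not reachable with these gates: the ",
      "implied mixture has a negative component. Try a smaller `width_frac` ",
      "or `doublet_frac`."), "cyto_error_input")
  }
  cell_cycle_mixture(fG1 = max(f[1], 0), fS = max(f[2], 0),
                     fG2M = max(f[3], 0), fDebris = max(fDeb, 0),
                     fDoublet = fDub, cv = cv)
}
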