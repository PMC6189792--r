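# Shared fixtures and independent oracles, all built in code at test time.

# A bright-only mixture: every nucleus is easily segmentable (no sub-G1
# debris, no doublets), handy when a test needs every truth nucleus found.
bright_mixture <- function(cv = 0.06) {
  cell_cycle_mixture(fG1 = 0.6, fS = 0.2, fG2M = 0.2,
                     fDebris = 0, fDoublet = 0, cv = cv)
}

# Render a dataset and pool quantified records across fields.
quantify_dataset <- function(fields, ...) {
  dplyr::bind_rows(lapply(fields, function(f) quantify_field(f, ...)$records))
}

# Full pipeline on a simulated dataset: returns analyze_intensities() output.
recover_from_mixture <- function(mixture, n, seed, optics = optics_config(),
                                 ...) {
  fields <- simulate_dataset(mixture, optics, n, seed = seed)
  rec <- quantify_dataset(fields)
  analyze_intensities(unflagged_records(rec)$integrated_intensity, ...)
}

# Independent 4-connected flood-fill labelling oracle (breadth-first),
# deliberately naive: used to cross-check segmentation labelling.
flood_fill_labels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc) {
          q <- (c2 - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nxt
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Brute-force bin assignment oracle for histograms.
brute_force_bins <- function(x, interval, origin = 0) {
  idx <- floor((x - origin) / interval)
  table(factor(idx, levels = 0:max(idx)))
}

# Event-by-event gate classification oracle ([lo, hi) semantics).
brute_force_gate <- function(x, gates) {
  vapply(x, function(v) {
    if (v >= gates$G1[1] && v < gates$G1[2]) "G1"
    else if (v >= gates$S[1] && v < gates$S[2]) "S"
    else if (v >= gates$G2M[1] && v < gates$G2M[2]) "G2M"
    else "ungated"
  }, character(1))
}

# Textbook sum-of-squares one-way ANOVA oracle.
anova_ss_oracle <- function(groups) {
  N <- sum(lengths(groups)); k <- length(groups)
  grand <- mean(unlist(groups))
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  F <- (ss_between / (k - 1)) / (ss_within / (N - k))
  list(F = F, p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

# Printed phase percentages used for synthetic parameter-recovery studies
# (gated fractions of the untreated / 24 h / 48 h rapamycin conditions).
rapamycin_conditions <- list(
  untreated = c(G1 = 51.02, S = 12.30, G2M = 27.36),
  h24 = c(G1 = 59.09, S = 15.35, G2M = 17.90),
  h48 = c(G1 = 67.21, S = 15.10, G2M = 11.68))
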