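test_that("auto-gate arithmetic and limits are exact", {
  g <- auto_gates(300, 600, width_frac = 0.2)
  expect_equal(g$G1, c(240, 360))
  expect_equal(g$S, c(360, 480))
  expect_equal(g$G2M, c(480, 720))
  tiny <- auto_gates(300, 600, width_frac = 1e-9)
  expect_equal(tiny$S[1], 300, tolerance = 1e-6)
  expect_equal(tiny$S[2], 600, tolerance = 1e-6)
  expect_error(auto_gates(300, 400, width_frac = 0.4),
               class = "cyto_error_input")
  expect_error(auto_gates(600, 300), class = "cyto_error_input")
})

test_that("gate windows validate ordering and disjointness", {
  expect_error(phase_gates(c(100, 300), c(250, 400), c(400, 500)),
               class = "cyto_error_input")
  expect_s3_class(phase_gates(c(100, 200), c(200, 400), c(400, 500)),
                  "phase_gates")
})

test_that("gated fractions partition every event exactly once", {
  g <- phase_gates(c(50, 150), c(150, 150), c(150, 250))
  f <- gate_fractions(c(100, 100, 100, 200), g)
  expect_equal(f$pG1, 0.75)
  expect_equal(f$pG2M, 0.25)
  expect_equal(f$pS, 0)
  expect_equal(f$pUngated, 0)
  low <- gate_fractions(c(1, 2, 3), phase_gates(c(50, 100), c(100, 200),
                                                c(200, 300)))
  expect_equal(low$pUngated, 1)
  expect_equal(f$pG1 + f$pS + f$pG2M + f$pUngated, 1)
})

test_that("gating matches an event-by-event classification oracle", {
  m <- cell_cycle_mixture()
  cc <- sample_dna_contents(m, 1e5, seed = 37)
  x <- round(2000 * cc$content)
  g <- auto_gates(2000 * 2, 2000 * 4, width_frac = 0.15)
  f <- gate_fractions(x, g)
  oracle <- table(factor(brute_force_gate(x, g),
                         levels = c("G1", "S", "G2M", "ungated"))) / length(x)
  expect_equal(f$pG1, unname(oracle[["G1"]]))
  expect_equal(f$pS, unname(oracle[["S"]]))
  expect_equal(f$pG2M, unname(oracle[["G2M"]]))
  expect_equal(f$pUngated, unname(oracle[["ungated"]]))
})

test_that("fractions are invariant to a common intensity scale", {
  x <- c(120, 240, 260, 480, 520, 900)
  g <- auto_gates(250, 500, width_frac = 0.2)
  f1 <- gate_fractions(x, g)
  c_scale <- 3.7
  g2 <- phase_gates(g$G1 * c_scale, g$S * c_scale, g$G2M * c_scale)
  f2 <- gate_fractions(x * c_scale, g2)
  expect_equal(tidy(f1)$fraction, tidy(f2)$fraction)
})

test_that("auto-gated pipeline recovers true gated fractions within 2 pp", {
  m <- cell_cycle_mixture()
  res <- recover_from_mixture(m, 2000, seed = 29)
  cc <- sample_dna_contents(m, 2e5, seed = 29)
  truth <- prop.table(table(classify_content(cc$content)))
  expect_lt(abs(res$fractions$pG1 - truth[["G1"]]), 0.02)
  expect_lt(abs(res$fractions$pS - truth[["S"]]), 0.02)
  expect_lt(abs(res$fractions$pG2M - truth[["G2M"]]), 0.02)
})

test_that("manual gates take precedence over automatic gating", {
  manual <- phase_gates(c(100, 200), c(200, 400), c(400, 500))
  res <- analyze_intensities(c(150, 150, 450, 999), gates = manual)
  expect_identical(res$gates, manual)
  expect_equal(res$fractions$pG1, 0.5)
  expect_equal(res$fractions$pUngated, 0.25)
})

test_that("tidiers expose fractions as tibbles", {
  f <- gate_fractions(c(100, 300, 700),
                      phase_gates(c(50, 150), c(150, 500), c(500, 800)))
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$fraction), 1)
  gl <- glance(f)
  expect_equal(gl$n_total, 3)
  expect_equal(gl$p_gated + gl$p_ungated, 1)
})
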