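test_that("mixture constructor enforces its invariants", {
  expect_s3_class(cell_cycle_mixture(), "cell_cycle_mixture")
  expect_error(cell_cycle_mixture(fG1 = 0.9), class = "cyto_error_input")
  expect_error(cell_cycle_mixture(fG1 = -0.1, fDebris = 0.16),
               class = "cyto_error_input")
  expect_error(cell_cycle_mixture(cv = -1), class = "cyto_error_input")
})

test_that("degenerate G1-only mixture yields exact 2N contents", {
  m <- cell_cycle_mixture(fG1 = 1, fS = 0, fG2M = 0, fDebris = 0,
                          fDoublet = 0, cv = 0)
  cc <- sample_dna_contents(m, 5, seed = 1)
  expect_equal(nrow(cc), 5)
  expect_true(all(cc$content == 2))
  expect_true(all(cc$phase == "G1"))
})

test_that("noise-free G2M to G1 content ratio is exactly 2", {
  m <- cell_cycle_mixture(fG1 = 0.5, fS = 0, fG2M = 0.5, fDebris = 0,
                          fDoublet = 0, cv = 0)
  cc <- sample_dna_contents(m, 400, seed = 7)
  r <- mean(cc$content[cc$phase == "G2M"]) / mean(cc$content[cc$phase == "G1"])
  expect_equal(r, 2)
})

test_that("empirical phase frequencies converge to the mixture fractions", {
  m <- cell_cycle_mixture(fG1 = 0.6, fS = 0.15, fG2M = 0.25, fDebris = 0,
                          fDoublet = 0, cv = 0.05)
  cc <- sample_dna_contents(m, 1e5, seed = 42)
  freq <- prop.table(table(cc$phase))
  expect_lt(abs(freq[["G1"]] - 0.6), 0.01)
  expect_lt(abs(freq[["S"]] - 0.15), 0.01)
  expect_lt(abs(freq[["G2M"]] - 0.25), 0.01)
})

test_that("sampling is reproducible and rejects bad input", {
  m <- cell_cycle_mixture()
  expect_identical(sample_dna_contents(m, 100, seed = 3),
                   sample_dna_contents(m, 100, seed = 3))
  expect_error(sample_dna_contents(m, 0, seed = 1), class = "cyto_error_input")
  expect_error(sample_dna_contents(list(), 5, seed = 1),
               class = "cyto_error_input")
})

test_that("content draws respect the phase-specific supports", {
  m <- cell_cycle_mixture()
  cc <- sample_dna_contents(m, 2e4, seed = 11)
  expect_true(all(cc$content > 0))
  s <- cc$content[cc$phase == "S"]
  expect_true(all(s > 2 * (1 - 5 * m$cv) & s < 4 * (1 + 5 * m$cv)))
  d <- cc$content[cc$phase == "debris"]
  expect_true(all(d >= 0.5 & d <= 1.8))
  do <- cc$content[cc$phase == "doublet"]
  expect_true(all(do > 3.5))
})

test_that("calibrated mixtures reproduce target gated fractions", {
  for (nm in names(rapamycin_conditions)) {
    tg <- rapamycin_conditions[[nm]] / 100
    m <- calibrate_gated_mixture(tg[["G1"]], tg[["S"]], tg[["G2M"]])
    cc <- sample_dna_contents(m, 2e5, seed = 5)
    got <- prop.table(table(classify_content(cc$content)))
    expect_lt(abs(got[["G1"]] - tg[["G1"]]), 0.005)
    expect_lt(abs(got[["S"]] - tg[["S"]]), 0.005)
    expect_lt(abs(got[["G2M"]] - tg[["G2M"]]), 0.005)
  }
})

test_that("unreachable gated targets are rejected", {
  # gated S of 30% cannot be reached: the residual S window only captures
  # about half of a uniform S population, and fractions would exceed 1
  expect_error(calibrate_gated_mixture(0.55, 0.30, 0.25),
               class = "cyto_error_input")
})
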