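test_that("rendering is bit-identical under a fixed seed", {
  cc <- sample_dna_contents(bright_mixture(), 40, seed = 2)
  op <- optics_config(cells_per_field = 40, seed = 2)
  a <- render_field(cc, op)
  b <- render_field(cc, op)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$truth, b$truth)
  expect_identical(a$mask, b$mask)
})

test_that("ground truth has one row per placed nucleus", {
  cc <- sample_dna_contents(cell_cycle_mixture(), 60, seed = 4)
  fld <- render_field(cc, optics_config(cells_per_field = 60, seed = 4))
  expect_equal(nrow(fld$truth), 60)
  expect_setequal(unique(fld$mask[fld$mask > 0]), seq_len(60))
})

test_that("integrated signal over the truth mask matches the analytic total", {
  # single dim nucleus: total pre-noise signal is gain * exposure * content;
  # Monte-Carlo noise SD = sqrt(shot variance + read variance over the mask)
  op <- optics_config(seed = 9, cells_per_field = 1)
  one <- tibble::tibble(
    phase = factor("G1", levels = c("G1", "S", "G2M", "debris", "doublet")),
    content = 2)
  fld <- render_field(one, op)
  msk <- fld$mask > 0
  est <- sum(fld$pixels[msk]) - op$background_mean * sum(msk)
  expected <- op$gain * op$exposure_ms * 2
  noise_sd <- sqrt(expected + op$background_sd^2 * sum(msk))
  expect_lt(abs(est - expected), 3 * noise_sd)
})

test_that("over-driven exposure clips pixels exactly at detector_max", {
  cc <- sample_dna_contents(bright_mixture(), 30, seed = 3)
  fld <- render_field(cc, optics_config(exposure_ms = 300,
                                        cells_per_field = 30, seed = 3))
  expect_identical(max(fld$pixels), as.integer(fld$detector_max))
})

test_that("linear regime preserves the 2x signal ratio of 4N over 2N", {
  two <- tibble::tibble(
    phase = factor(c("G1", "G2M"), levels = c("G1", "S", "G2M", "debris", "doublet")),
    content = c(2, 4))
  fld <- render_field(two, optics_config(cells_per_field = 2, seed = 6,
                                         saturation_K = Inf))
  sums <- vapply(1:2, function(i) {
    msk <- fld$mask == i
    sum(fld$pixels[msk]) - 10 * sum(msk)
  }, numeric(1))
  expect_lt(abs(sums[2] / sums[1] - 2), 0.1)
})

test_that("integrated signal increases with content when unclipped", {
  cc <- tibble::tibble(
    phase = factor(rep("S", 8), levels = c("G1", "S", "G2M", "debris", "doublet")),
    content = seq(1, 8, by = 1))
  fld <- render_field(cc, optics_config(cells_per_field = 8, seed = 12))
  sums <- vapply(seq_len(8), function(i) {
    msk <- fld$mask == i
    sum(fld$pixels[msk]) - 10 * sum(msk)
  }, numeric(1))
  expect_true(all(diff(sums[order(fld$truth$content)]) > 0))
})

test_that("saturation compresses the 4N:2N signal ratio toward 1", {
  ratios <- vapply(c(Inf, 16, 8, 4, 2), function(K)
    saturate_content(4, K) / saturate_content(2, K), numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_equal(ratios[1], 2)
  expect_gt(ratios[length(ratios)], 1)
})

test_that("impossible placements raise a placement error", {
  cc <- sample_dna_contents(bright_mixture(), 200, seed = 1)
  expect_error(
    render_field(cc, optics_config(field_shape = c(64, 64),
                                   cells_per_field = 200, seed = 1)),
    class = "cyto_error_placement")
})

test_that("simulate_dataset splits nuclei across fields deterministically", {
  m <- bright_mixture()
  flds <- simulate_dataset(m, optics_config(cells_per_field = 50), 120,
                           seed = 8)
  expect_length(flds, 3)
  expect_equal(sum(vapply(flds, function(f) nrow(f$truth), numeric(1))), 120)
  flds2 <- simulate_dataset(m, optics_config(cells_per_field = 50), 120,
                            seed = 8)
  expect_identical(lapply(flds, `[[`, "pixels"),
                   lapply(flds2, `[[`, "pixels"))
})
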