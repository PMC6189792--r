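make_disk_image <- function(nr = 64, nc = 64, centers, radius = 5,
                            value = 200, background = 10) {
  px <- matrix(background, nr, nc)
  for (k in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(nr) - centers[k, 1])^2,
                (seq_len(nc) - centers[k, 2])^2, "+")
    px[d2 <= radius^2] <- value
  }
  storage.mode(px) <- "integer"
  px
}

test_that("background estimate is the median outside the foreground", {
  px <- matrix(17L, 64, 64)
  expect_equal(estimate_background(px, foreground_mask = matrix(0L, 64, 64)),
               17)
  disk <- make_disk_image(centers = cbind(32, 32), radius = 6, value = 300,
                          background = 17)
  expect_equal(estimate_background(disk), 17)
})

test_that("background estimate recovers the configured level on rendered fields", {
  cc <- sample_dna_contents(bright_mixture(), 100, seed = 5)
  fld <- render_field(cc, optics_config(cells_per_field = 100, seed = 5))
  expect_lt(abs(estimate_background(fld) - 10), 2)
})

test_that("a fully-foreground field is rejected", {
  px <- matrix(100L, 32, 32)
  expect_error(estimate_background(px, foreground_mask = matrix(1L, 32, 32)),
               class = "cyto_error_qc")
})

test_that("adding a constant shifts the background and not the intensities", {
  cc <- sample_dna_contents(bright_mixture(), 60, seed = 14)
  fld <- render_field(cc, optics_config(cells_per_field = 60, seed = 14))
  labels <- segment_nuclei(fld)
  shift <- 25L
  fld2 <- field_image(fld$pixels + shift, detector_max = fld$detector_max)
  b1 <- estimate_background(fld, foreground_mask = labels)
  b2 <- estimate_background(fld2, foreground_mask = labels)
  expect_equal(b2 - b1, shift)
  r1 <- measure_nuclei(fld, labels, background = b1)
  r2 <- measure_nuclei(fld2, labels, background = b2)
  expect_equal(r1$integrated_intensity, r2$integrated_intensity)
})

test_that("well-separated disks produce one label each, blank fields none", {
  centers <- cbind(c(12, 12, 32, 52, 52), c(12, 52, 32, 12, 52))
  disk <- make_disk_image(centers = centers)
  lab <- segment_nuclei(disk, grow_px = 1)
  expect_equal(max(lab), 5)
  blank <- matrix(10L, 64, 64)
  expect_equal(max(segment_nuclei(blank)), 0)
})

test_that("segmentation finds every bright truth nucleus exactly once", {
  cc <- sample_dna_contents(bright_mixture(), 120, seed = 6)
  fld <- render_field(cc, optics_config(cells_per_field = 120, seed = 6))
  lab <- segment_nuclei(fld)
  expect_equal(max(lab), 120)
  at <- lab[cbind(round(fld$truth$centroid_row), round(fld$truth$centroid_col))]
  expect_true(all(at > 0))
  expect_equal(length(unique(at)), 120)
})

test_that("labelling matches a brute-force flood-fill oracle exactly", {
  centers <- cbind(c(15, 40, 50), c(15, 30, 55))
  disk <- make_disk_image(centers = centers)
  lab <- segment_nuclei(disk, threshold_method = 100, grow_px = 0,
                        min_area = 1)
  oracle <- flood_fill_labels(disk > 100)
  expect_equal(max(lab), max(oracle))
  # same partition: every oracle region maps to exactly one label and the
  # per-object pixel sums agree
  for (k in seq_len(max(oracle))) {
    ids <- unique(lab[oracle == k])
    expect_length(ids, 1)
    expect_equal(sum(disk[lab == ids]), sum(disk[oracle == k]))
  }
})

test_that("per-label measurement arithmetic is exact", {
  px <- matrix(10L, 20, 20)
  px[5:6, 5:6] <- 110L
  lab <- matrix(0L, 20, 20); lab[5:6, 5:6] <- 1L
  rec <- measure_nuclei(px, lab, background = 10)
  expect_equal(rec$integrated_intensity, 400)
  expect_equal(rec$area_px, 4L)
  expect_equal(rec$centroid_row, 5.5)
  expect_false(rec$flag_saturated)
})

test_that("saturated and edge flags trigger as specified", {
  px <- matrix(10L, 20, 20)
  px[5:8, 5:8] <- 4095L
  lab <- matrix(0L, 20, 20); lab[5:8, 5:8] <- 1L
  rec <- measure_nuclei(px, lab, background = 10)
  expect_true(rec$flag_saturated)
  px2 <- matrix(10L, 20, 20); px2[1:3, 5:8] <- 200L
  lab2 <- matrix(0L, 20, 20); lab2[1:3, 5:8] <- 1L
  expect_true(measure_nuclei(px2, lab2)$flag_edge)
  expect_error(measure_nuclei(px, matrix(0L, 5, 5)),
               class = "cyto_error_input")
})

test_that("negative background-subtracted sums clamp to zero", {
  px <- matrix(5L, 20, 20)
  lab <- matrix(0L, 20, 20); lab[2:4, 2:4] <- 1L
  rec <- measure_nuclei(px, lab, background = 50)
  expect_equal(rec$integrated_intensity, 0)
})

test_that("every nonzero label yields exactly one record", {
  cc <- sample_dna_contents(cell_cycle_mixture(), 80, seed = 10)
  fld <- render_field(cc, optics_config(cells_per_field = 80, seed = 10))
  lab <- segment_nuclei(fld)
  rec <- measure_nuclei(fld, lab, background = estimate_background(fld, lab))
  expect_setequal(rec$id, unique(lab[lab > 0]))
})

test_that("measured intensity regresses on true content with the configured gain", {
  op <- optics_config(cells_per_field = 120, seed = 15)
  cc <- sample_dna_contents(bright_mixture(), 120, seed = 15)
  fld <- render_field(cc, op)
  q <- quantify_field(fld)
  at <- q$labels[cbind(round(fld$truth$centroid_row),
                       round(fld$truth$centroid_col))]
  df <- dplyr::tibble(content = fld$truth$content,
                      ii = q$records$integrated_intensity[match(at, q$records$id)])
  slope <- stats::coef(stats::lm(ii ~ content, data = df))[["content"]]
  expect_lt(abs(slope / (op$gain * op$exposure_ms) - 1), 0.05)
})

test_that("area-based clump flagging follows the clump_factor rule", {
  rec <- tibble::tibble(id = 1:4, centroid_row = 0, centroid_col = 0,
                        area_px = c(100L, 100L, 100L, 250L),
                        integrated_intensity = 0,
                        flag_edge = FALSE, flag_saturated = FALSE,
                        flag_clump = FALSE)
  out <- flag_clumps(rec, clump_factor = 2.0)
  expect_equal(out$flag_clump, c(FALSE, FALSE, FALSE, TRUE))
  same <- dplyr::mutate(rec, area_px = 100L)
  expect_false(any(flag_clumps(same)$flag_clump))
  expect_warning(flag_clumps(rec[1:2, ]), "Fewer than 3")
})

test_that("merged clump placements are flagged, singletons are not", {
  fl <- simulate_dataset(cell_cycle_mixture(),
                         optics_config(clump_prob = 0.1), 1500, seed = 13)
  merged <- 0; merged_flagged <- 0; singles <- 0; singles_flagged <- 0
  for (f in fl) {
    q <- quantify_field(f)
    tr <- f$truth
    at <- q$labels[cbind(round(tr$centroid_row), round(tr$centroid_col))]
    flg <- q$records$flag_clump[match(at, q$records$id)]
    pairs <- tr[!is.na(tr$clump_with), ]
    for (k in seq_len(nrow(pairs))) {
      la <- at[pairs$id[k]]; lb <- at[pairs$clump_with[k]]
      if (!is.na(la) && la > 0 && identical(la, lb)) {
        merged <- merged + 1
        merged_flagged <- merged_flagged + isTRUE(flg[pairs$id[k]])
      }
    }
    solo <- is.na(tr$clump_with) & !(tr$id %in% tr$clump_with)
    singles <- singles + sum(solo & !is.na(flg))
    singles_flagged <- singles_flagged + sum(solo & !is.na(flg) & flg)
  }
  expect_gt(merged, 20)
  expect_gte(merged_flagged / merged, 0.8)
  expect_lte(singles_flagged / singles, 0.05)
})
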