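#' Construct a field image
#'
#' Wraps a single-channel pixel matrix with its acquisition metadata. Pixel
#' values are non-negative integers clipped at `detector_max`.
#'
#' @param pixels Integer matrix (rows x cols), dimensions at least 16 x 16.
#' @param exposure_ms Exposure time in milliseconds (metadata).
#' @param detector_max Full-scale detector value.
#' @param magnification,dye Free-text acquisition labels.
#' @param truth Optional ground-truth tibble (simulated fields).
#' @param mask Optional ground-truth label matrix (simulated fields).
#' @return An object of class `cyto_field`.
#' @export
field_image <- function(pixels, exposure_ms = NA_real_, detector_max = 4095,
                        magnification = NA_character_, dye = NA_character_,
                        truth = NULL, mask = NULL) {
  if (!is.matrix(pixels) || any(dim(pixels) < 16)) {
    cyto_abort("`pixels` must be a matrix with dimensions >= 16 x 16.",
               "cyto_error_input")
  }
  if (any(pixels < 0) || any(pixels > detector_max)) {
    cyto_abort("Pixels must lie in [0, detector_max].", "cyto_error_input")
  }
  structure(
    list(pixels = pixels, exposure_ms = exposure_ms,
         detector_max = detector_max, magnification = magnification,
         dye = dye, truth = truth, mask = mask),
    class = "cyto_field")
}

#' @export
print.cyto_field <- function(x, ...) {
  cat(sprintf("<cyto_field> %d x %d px, exposure %s ms, detector max %d\n",
              nrow(x$pixels), ncol(x$pixels), format(x$exposure_ms),
              as.integer(x$detector_max)))
  if (!is.null(x$truth)) {
    cat(sprintf("  ground truth: %d nuclei\n", nrow(x$truth)))
  }
  invisible(x)
}

## Truncated-Gaussian disk profile: weights over a (2R+1)^2 patch centred on
## (cy, cx), zero beyond `radius`, normalized to sum to 1 so the disk carries
## exactly the requested total signal.
.disk_patch <- function(radius, frac_row, frac_col) {
  R <- ceiling(radius)
  sigma <- radius / 3
  dr <- (-R):R
  d2 <- outer((dr - frac_row)^2, (dr - frac_col)^2, "+")
  w <- exp(-d2 / (2 * sigma^2))
  w[sqrt(d2) > radius] <- 0
  w / sum(w)
}

#' Render a fluorescence field from ground-truth DNA contents
#'
#' Draws each nucleus as a truncated 2D Gaussian disk whose total pre-noise,
#' pre-clip signal is `gain * exposure_ms * sat(content)` (see
#' [saturate_content()]), places nuclei without overlap (except deliberate
#' clumps, placed tangent to a previously placed nucleus with probability
#' `clump_prob`), adds Poisson shot noise and Gaussian background, and clips
#' to `[0, detector_max]`. Rendering is fully reproducible from
#' `optics$seed`.
#'
#' @param contents A tibble with columns `phase` and `content` (N units),
#'   e.g. from [sample_dna_contents()], or a bare numeric vector of contents.
#' @param optics An [optics_config()].
#' @return A `cyto_field` whose `truth` tibble records, per nucleus: `id`,
#'   `phase`, `content`, `sat_content`, `signal_total`, `centroid_row`,
#'   `centroid_col`, `radius_px`, and `clump_with` (partner id for clump
#'   placements, `NA` otherwise); `mask` is the ground-truth label image.
#' @export
#' @examples
#' cc <- sample_dna_contents(cell_cycle_mixture(), 25, seed = 2)
#' fld <- render_field(cc, optics_config(cells_per_field = 25, seed = 2))
render_field <- function(contents, optics = optics_config()) {
  if (is.numeric(contents)) {
    contents <- tibble(phase = factor(rep("G1", length(contents)),
                                      levels = c("G1", "S", "G2M", "debris", "doublet")),
                       content = contents)
  }
  n <- nrow(contents)
  if (is.null(n) || n < 1) {
    cyto_abort("`contents` must contain at least one nucleus.",
               "cyto_error_input")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(optics$seed)

  nr <- optics$field_shape[1]; nc <- optics$field_shape[2]
  radii <- pmax(rnorm(n, optics$nucleus_radius_px, optics$nucleus_radius_sd), 2)
  # Non-clump nuclei keep centers >= r_i + r_j + gap apart. Threshold cores
  # never exceed the disk radius, so with a 3 px segmentation growth a gap of
  # 8 px guarantees grown masks of separate nuclei stay disjoint, while
  # tangent clump pairs (distance r_i + r_j) always merge.
  gap <- 8

  cy <- numeric(n); cx <- numeric(n); clump_with <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    m <- ceiling(radii[i]) + gap
    if (nr - 2 * m < 1 || nc - 2 * m < 1) {
      cyto_abort("Field too small for the nucleus size.", "cyto_error_placement")
    }
    placed <- FALSE
    as_clump <- i > 1 && runif(1) < optics$clump_prob
    prev <- seq_len(i - 1)
    eligible <- prev[is.na(clump_with[prev]) & !(prev %in% clump_with)]
    if (as_clump && length(eligible) > 0) {
      for (try in 1:200) {
        j <- eligible[sample.int(length(eligible), 1)]
        th <- runif(1, 0, 2 * pi)
        yy <- cy[j] + (radii[i] + radii[j]) * cos(th)
        xx <- cx[j] + (radii[i] + radii[j]) * sin(th)
        if (yy < m + 1 || yy > nr - m || xx < m + 1 || xx > nc - m) next
        others <- setdiff(seq_len(i - 1), j)
        if (length(others) > 0) {
          d <- sqrt((cy[others] - yy)^2 + (cx[others] - xx)^2)
          if (any(d < radii[others] + radii[i] + gap)) next
        }
        cy[i] <- yy; cx[i] <- xx
        clump_with[i] <- j
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clump_with[i] <- NA_integer_
      for (try in 1:2000) {
        yy <- runif(1, m + 1, nr - m)
        xx <- runif(1, m + 1, nc - m)
        if (i > 1) {
          d <- sqrt((cy[seq_len(i - 1)] - yy)^2 + (cx[seq_len(i - 1)] - xx)^2)
          if (any(d < radii[seq_len(i - 1)] + radii[i] + gap)) next
        }
        cy[i] <- yy; cx[i] <- xx
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cyto_abort(sprintf(
        "Could not place nucleus %d of %d: field too small or too crowded.",
        i, n), "cyto_error_placement")
    }
  }

  sat_content <- saturate_content(contents$content, optics$saturation_K)
  totals <- optics$gain * optics$exposure_ms * sat_content

  signal <- matrix(0, nr, nc)
  mask <- matrix(0L, nr, nc)
  wmap <- matrix(0, nr, nc)
  for (i in seq_len(n)) {
    r0 <- round(cy[i]); c0 <- round(cx[i])
    R <- ceiling(radii[i])
    w <- .disk_patch(radii[i], cy[i] - r0, cx[i] - c0)
    rows <- (r0 - R):(r0 + R); cols <- (c0 - R):(c0 + R)
    signal[rows, cols] <- signal[rows, cols] + totals[i] * w
    sel <- w > 0 & totals[i] * w > wmap[rows, cols]
    sub <- mask[rows, cols]
    sub[sel] <- i
    mask[rows, cols] <- sub
    wsub <- wmap[rows, cols]
    wsub[sel] <- (totals[i] * w)[sel]
    wmap[rows, cols] <- wsub
  }

  npx <- nr * nc
  pix <- rpois(npx, as.vector(signal)) +
    rnorm(npx, optics$background_mean, optics$background_sd)
  pix <- matrix(pmin(pmax(round(pix), 0), optics$detector_max), nr, nc)
  storage.mode(pix) <- "integer"

  truth <- tibble(
    id = seq_len(n),
    phase = contents$phase,
    content = contents$content,
    sat_content = sat_content,
    signal_total = totals,
    centroid_row = cy, centroid_col = cx,
    radius_px = radii,
    clump_with = clump_with)

  field_image(pix, exposure_ms = optics$exposure_ms,
              detector_max = optics$detector_max,
              truth = truth, mask = mask)
}

#' Simulate a multi-field dataset for one acquisition condition
#'
#' Samples `n_nuclei` ground-truth DNA contents from `mixture` and renders
#' them across as many fields as needed (at most `optics$cells_per_field`
#' nuclei per field), with deterministic per-field seeds derived from `seed`.
#'
#' @param mixture A [cell_cycle_mixture()].
#' @param optics An [optics_config()].
#' @param n_nuclei Total nuclei across fields.
#' @param seed Integer seed for both sampling and rendering.
#' @return A list of `cyto_field` objects; the combined ground truth is
#'   available via `dplyr::bind_rows(lapply(fields, function(f) f$truth))`.
#' @export
simulate_dataset <- function(mixture, optics, n_nuclei, seed = 1L) {
  cc <- sample_dna_contents(mixture, n_nuclei, seed = seed)
  idx <- split(seq_len(n_nuclei),
               ceiling(seq_len(n_nuclei) / optics$cells_per_field))
  purrr::imap(idx, function(ix, k) {
    op <- optics
    op$seed <- as.integer(seed + 7919L * as.integer(k))
    render_field(cc[ix, ], op)
  })
}
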