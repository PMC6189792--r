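#' Write a field as a 16-bit grayscale TIFF
#'
#' Pixel counts are stored as 16-bit samples (values up to 65535); label
#' images can be written the same way for audit.
#'
#' @param image A `cyto_field` or integer matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(image, path) {
  px <- field_pixels(image)
  if (max(px) > 65535) {
    cyto_abort("Pixel values exceed 16-bit range.", "cyto_error_input")
  }
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a single-channel grayscale TIFF as a field
#'
#' Accepts 8/16-bit single-channel TIFFs; sample values are rescaled back to
#' integer counts. Metadata can be supplied from a sidecar (see
#' [read_field_metadata()]).
#'
#' @param path TIFF path.
#' @param detector_max Full-scale detector value of the acquisition.
#' @param exposure_ms,magnification,dye Optional acquisition metadata.
#' @return A `cyto_field`.
#' @export
read_field_tiff <- function(path, detector_max = 4095, exposure_ms = NA_real_,
                            magnification = NA_character_,
                            dye = NA_character_) {
  if (!file.exists(path)) {
    cyto_abort(sprintf("TIFF not found: %s", path), "cyto_error_input")
  }
  raw <- tryCatch(tiff::readTIFF(path, as.is = FALSE),
                  error = function(e) {
                    cyto_abort(sprintf("Unreadable TIFF: %s", path),
                               "cyto_error_input")
                  })
  if (length(dim(raw)) == 3) {
    if (dim(raw)[3] != 1) {
      cyto_abort("Expected a single-channel TIFF.", "cyto_error_input")
    }
    raw <- raw[, , 1]
  }
  px <- round(raw * 65535)
  storage.mode(px) <- "integer"
  field_image(px, exposure_ms = exposure_ms,
              detector_max = max(detector_max, max(px)),
              magnification = magnification, dye = dye)
}

#' Read a metadata sidecar for a field
#'
#' YAML sidecar with any of: `exposure_ms`, `magnification`,
#' `dye_concentration`, `detector_max`.
#'
#' @param path YAML path.
#' @return Named list of metadata.
#' @export
read_field_metadata <- function(path) {
  if (!file.exists(path)) {
    cyto_abort(sprintf("Metadata sidecar not found: %s", path),
               "cyto_error_input")
  }
  yaml::read_yaml(path)
}

#' Write per-nucleus records to CSV
#'
#' Columns: `id`, `centroid_row`, `centroid_col`, `area_px`,
#' `integrated_intensity`, `flags` (semicolon-joined subset of
#' `edge;saturated;clump`).
#'
#' @param records Tibble from [measure_nuclei()]/[flag_clumps()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nuclei_csv <- function(records, path) {
  flags <- apply(cbind(
    ifelse(records$flag_edge, "edge", NA),
    ifelse(records$flag_saturated, "saturated", NA),
    ifelse(records$flag_clump, "clump", NA)), 1,
    function(r) paste(stats::na.omit(r), collapse = ";"))
  out <- dplyr::select(records, "id", "centroid_row", "centroid_col",
                       "area_px", "integrated_intensity")
  out$flags <- flags
  readr::write_csv(out, path)
  invisible(path)
}

#' Read per-nucleus records from CSV
#'
#' Accepts the [write_nuclei_csv()] layout, or any CSV with an
#' `integrated_intensity` (or single) column for plain intensity input.
#'
#' @param path CSV path.
#' @return Tibble of records (missing columns filled with defaults).
#' @export
read_nuclei_csv <- function(path) {
  if (!file.exists(path)) {
    cyto_abort(sprintf("CSV not found: %s", path), "cyto_error_input")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (!"integrated_intensity" %in% names(tbl)) {
    if (ncol(tbl) == 1) {
      names(tbl) <- "integrated_intensity"
    } else {
      cyto_abort("CSV lacks an `integrated_intensity` column.",
                 "cyto_error_input")
    }
  }
  flags <- if ("flags" %in% names(tbl)) as.character(tbl$flags) else ""
  flags[is.na(flags)] <- ""
  tbl$flag_edge <- grepl("edge", flags)
  tbl$flag_saturated <- grepl("saturated", flags)
  tbl$flag_clump <- grepl("clump", flags)
  tbl$flags <- NULL
  if (!"id" %in% names(tbl)) tbl$id <- seq_len(nrow(tbl))
  as_tibble(tbl)
}

#' Write gate definitions to JSON
#' @param gates A [phase_gates()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gates_json <- function(gates, path) {
  jsonlite::write_json(lapply(unclass(gates), function(w)
    list(lo = w[1], hi = w[2])), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read gate definitions from JSON
#' @param path JSON path written by [write_gates_json()].
#' @return A [phase_gates()] object.
#' @export
read_gates_json <- function(path) {
  g <- jsonlite::read_json(path)
  phase_gates(g1 = c(g$G1$lo, g$G1$hi), s = c(g$S$lo, g$S$hi),
              g2m = c(g$G2M$lo, g$G2M$hi))
}

#' Write a histogram to CSV
#' @param hist A `cyto_histogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  readr::write_csv(as_tibble(hist), path)
  invisible(path)
}

#' Write phase fractions to JSON
#' @param fractions A `phase_fractions` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fractions_json <- function(fractions, path) {
  jsonlite::write_json(unclass(fractions), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
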