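merge_defaults <- function(user, defaults) {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  defaults
}

default_config <- function() {
  list(
    seed = 1L,
    mode = "simulate",
    out_dir = "cytocycle-run",
    write_images = FALSE,
    conditions = list(list(name = "condition1", n_nuclei = 500L,
                           replicates = 1L)),
    optics = list(),
    quant = list(min_area = 30, max_area = Inf, threshold_method = "otsu",
                 grow_px = 3, sat_frac = 0.05, clump_factor = 1.8),
    gating = list(interval = 60, origin = 0, width_frac = 0.15,
                  manual_gates = NULL),
    qc = list(clip_threshold = 0.01, snr_threshold = 3, strict = FALSE))
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys mirror [run_pipeline()]'s configuration list
#' (`seed`, `mode`, `out_dir`, `conditions`, `optics`, `quant`, `gating`,
#' `qc`, `write_images`).
#'
#' @param path YAML path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    cyto_abort(sprintf("Config not found: %s", path), "cyto_error_input")
  }
  yaml::read_yaml(path)
}

condition_mixture <- function(cond) {
  if (!is.null(cond$gated_targets)) {
    gt <- cond$gated_targets
    args <- list(pG1 = gt$G1 / 100, pS = gt$S / 100, pG2M = gt$G2M / 100)
    extra <- cond$mixture[c("cv")]
    if (!is.null(extra$cv)) args$cv <- extra$cv
    do.call(calibrate_gated_mixture, args)
  } else if (!is.null(cond$mixture)) {
    do.call(cell_cycle_mixture, cond$mixture)
  } else {
    cell_cycle_mixture()
  }
}

quantify_with <- function(field, quant) {
  quantify_field(field,
                 min_area = quant$min_area, max_area = quant$max_area,
                 threshold_method = quant$threshold_method,
                 grow_px = quant$grow_px, sat_frac = quant$sat_frac,
                 clump_factor = quant$clump_factor)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> segment -> integrate -> QC -> gate ->
#' report for one or more conditions with replicates, writing a run
#' directory with per-replicate nucleus CSVs, histogram CSVs, gate and
#' fraction JSONs, per-field QC, a cross-replicate summary (means, SDs and
#' per-phase one-way ANOVA across conditions) and a manifest listing every
#' output file with its MD5 checksum. The run is deterministic given the
#' configuration and seed.
#'
#' In `simulate` mode each condition specifies its ground-truth mixture
#' either directly (`mixture:` fields of [cell_cycle_mixture()]) or as
#' target gated percentages (`gated_targets: {G1: 51.02, S: 12.30,
#' G2M: 27.36}`, inverted by [calibrate_gated_mixture()]). In `analyze`
#' mode each condition lists TIFF paths per replicate (`tiffs:`).
#'
#' @param config Configuration list or path to a YAML file (see
#'   [read_pipeline_config()]).
#' @param out_dir,seed Optional overrides of the config values.
#' @param strict Override QC strictness: when `TRUE`, any over-/under-
#'   exposed field aborts the run (condition class `cyto_error_qc`).
#' @return Invisibly, a list with `summary` (replicate stats tibble),
#'   `anova` (per-phase tibble or `NULL`), `fractions` (nested list of
#'   `phase_fractions`), `qc` (tibble) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, strict = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- merge_defaults(config, default_config())
  cfg$quant <- merge_defaults(config$quant, default_config()$quant)
  cfg$gating <- merge_defaults(config$gating, default_config()$gating)
  cfg$qc <- merge_defaults(config$qc, default_config()$qc)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(strict)) cfg$qc$strict <- strict

  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  add_output <- function(p) outputs <<- c(outputs, p)

  manual <- NULL
  if (!is.null(cfg$gating$manual_gates)) {
    mg <- cfg$gating$manual_gates
    manual <- phase_gates(g1 = unlist(mg$G1), s = unlist(mg$S),
                          g2m = unlist(mg$G2M))
  }

  all_fracs <- list(); cond_labels <- character(); qc_rows <- list()
  log_counts <- list()
  for (ci in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[[ci]]
    cname <- cond$name %||% paste0("condition", ci)
    n_rep <- as.integer(cond$replicates %||% 1L)
    for (ri in seq_len(n_rep)) {
      rep_dir <- file.path(out, cname, sprintf("rep%d", ri))
      dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
      rep_seed <- as.integer(cfg$seed + 100000L * ci + 1000L * ri)

      fields <- if (identical(cfg$mode, "analyze")) {
        paths <- cond$tiffs[[ri]]
        if (is.null(paths)) {
          cyto_abort(sprintf("No TIFFs listed for %s replicate %d.",
                             cname, ri), "cyto_error_input")
        }
        opt <- merge_defaults(cfg$optics, as.list(optics_config()))
        lapply(unlist(paths), read_field_tiff,
               detector_max = opt$detector_max)
      } else {
        optics <- do.call(optics_config,
                          c(cfg$optics, list(seed = rep_seed)))
        mixture <- condition_mixture(cond)
        simulate_dataset(mixture, optics,
                         n_nuclei = as.integer(cond$n_nuclei %||% 500L),
                         seed = rep_seed)
      }

      recs <- list()
      for (fi in seq_along(fields)) {
        fld <- fields[[fi]]
        q <- quantify_with(fld, cfg$quant)
        qc <- exposure_check(fld, q$labels,
                             clip_threshold = cfg$qc$clip_threshold,
                             snr_threshold = cfg$qc$snr_threshold)
        qc_rows[[length(qc_rows) + 1]] <- dplyr::mutate(
          tidy(qc), condition = cname, replicate = ri, field = fi,
          .before = 1)
        if (cfg$qc$strict && qc$status != "ok") {
          cyto_abort(sprintf(
            "QC failure (%s) in %s replicate %d field %d (strict mode).",
            qc$status, cname, ri, fi), "cyto_error_qc")
        }
        if (isTRUE(cfg$write_images)) {
          fp <- file.path(rep_dir, sprintf("field%02d.tif", fi))
          lp <- file.path(rep_dir, sprintf("field%02d_labels.tif", fi))
          write_field_tiff(fld, fp); add_output(fp)
          write_field_tiff(q$labels, lp); add_output(lp)
        }
        recs[[fi]] <- q$records
      }
      records <- dplyr::bind_rows(recs, .id = "field")
      nuc_path <- file.path(rep_dir, "nuclei.csv")
      write_nuclei_csv(records, nuc_path); add_output(nuc_path)

      usable <- unflagged_records(records)
      log_counts[[paste(cname, ri)]] <- c(found = nrow(records),
                                          flagged = nrow(records) - nrow(usable))
      res <- analyze_intensities(usable$integrated_intensity,
                                 interval = cfg$gating$interval,
                                 origin = cfg$gating$origin,
                                 width_frac = cfg$gating$width_frac,
                                 gates = manual)
      write_histogram_csv(res$histogram, file.path(rep_dir, "histogram.csv"))
      add_output(file.path(rep_dir, "histogram.csv"))
      write_gates_json(res$gates, file.path(rep_dir, "gates.json"))
      add_output(file.path(rep_dir, "gates.json"))
      write_fractions_json(res$fractions, file.path(rep_dir, "fractions.json"))
      add_output(file.path(rep_dir, "fractions.json"))

      all_fracs[[length(all_fracs) + 1]] <- res$fractions
      cond_labels <- c(cond_labels, cname)
    }
  }

  qc_tbl <- dplyr::bind_rows(qc_rows)
  qc_path <- file.path(out, "qc.json")
  jsonlite::write_json(qc_tbl, qc_path, auto_unbox = TRUE, digits = NA)
  add_output(qc_path)

  stats_tbl <- suppressWarnings(replicate_stats(all_fracs, cond_labels))
  anova_tbl <- NULL
  if (length(unique(cond_labels)) >= 2 &&
      all(table(cond_labels) >= 2)) {
    anova_tbl <- condition_anova(all_fracs, cond_labels)
  }
  summary_path <- file.path(out, "summary.json")
  jsonlite::write_json(
    list(phase_stats = stats_tbl, anova = anova_tbl,
         stage_counts = log_counts),
    summary_path, auto_unbox = TRUE, digits = NA)
  add_output(summary_path)

  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(cfg, cfg_path); add_output(cfg_path)
  manifest <- list(
    version = as.character(utils::packageVersion("cytocycle")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = lapply(setNames(outputs, basename2(outputs, out)), function(p)
      unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(summary = stats_tbl, anova = anova_tbl,
                 fractions = split(all_fracs, cond_labels),
                 qc = qc_tbl, out_dir = out))
}

basename2 <- function(paths, root) {
  sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", root), "/?"), "",
      paths)
}
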