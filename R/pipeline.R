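# Orchestration: configuration, logging, and a reproducible end-to-end run
# (QC -> positioning -> gene filter -> per-gene fits -> spatial calling ->
# pathway scan), with every stochastic step seeded from one run seed.

#' Assemble a pipeline run configuration
#'
#' Collects input locations (paths or in-memory objects) and every
#' threshold of the analysis; the configuration is echoed verbatim into the
#' run metadata so a run can be reproduced from its output directory alone.
#'
#' @param counts Count matrix, or path to one (`.mtx` / `.tsv`).
#' @param cells Cell metadata tibble or TSV path.
#' @param gmt Optional GMT path or gene set collection for the pathway scan.
#' @param out_dir Output directory for tables, metadata, and the log.
#' @param seed Integer master seed; all stochastic stages derive child
#'   seeds from it.
#' @param dialect Count file dialect, see [read_counts()].
#' @param min_depth,min_genes_detected Cell QC thresholds (permissive
#'   defaults; tighten for real protocols, see [qc_filter_cells()]).
#' @param clip_quantiles Radial scaling clip, see
#'   [compute_radial_position()].
#' @param min_mean_umis Gene filter, see [filter_expressed_genes()].
#' @param fdr_max,mag_min,loglik_per_cell,delta,tau,sig_level Spatial
#'   calling thresholds, see [call_spatial_genes()].
#' @param min_genes,n_bins Pathway scan settings.
#' @param downsample_ps Optional vector of retention probabilities; when
#'   set, a [downsampling_curve()] is appended to the run.
#' @return Named list of class `run_config`.
#' @export
pipeline_config <- function(counts, cells, gmt = NULL, out_dir = tempfile("sphereg_run_"),
                            seed = 1, dialect = "mtx_triplet",
                            min_depth = 100, min_genes_detected = 1,
                            clip_quantiles = c(0, 0), min_mean_umis = 1,
                            fdr_max = 0.1, mag_min = 0.3, loglik_per_cell = -4.91,
                            delta = 0.1, tau = 0.1, sig_level = 0.05,
                            min_genes = 5, n_bins = 10, downsample_ps = NULL) {
  stopifnot(fdr_max > 0, fdr_max <= 1, mag_min >= 0, mag_min < 1,
            delta >= 0, delta < 0.5, tau >= 0, n_bins >= 2, min_genes >= 1)
  structure(list(counts = counts, cells = cells, gmt = gmt, out_dir = out_dir,
                 seed = as.integer(seed), dialect = dialect,
                 min_depth = min_depth, min_genes_detected = min_genes_detected,
                 clip_quantiles = clip_quantiles, min_mean_umis = min_mean_umis,
                 fdr_max = fdr_max, mag_min = mag_min,
                 loglik_per_cell = loglik_per_cell, delta = delta, tau = tau,
                 sig_level = sig_level, min_genes = min_genes, n_bins = n_bins,
                 downsample_ps = downsample_ps),
            class = "run_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error. Paths are kept as given.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
  do.call(pipeline_config, raw)
}

#' Run the full spatial regulation pipeline
#'
#' Stages: load inputs, QC-filter cells, derive radial positions from dye
#' intensity (skipped when positions are supplied), filter the gene
#' universe, fit and call spatial genes, scan pathways (when gene sets are
#' given), and optionally compute a downsampling curve. All tables are
#' written tab-separated with headers into `config$out_dir`, together with
#' `run_metadata.json` (config echo, package version, seed, per-stage
#' counts and timings) and `run.log`. Reruns with an identical
#' configuration reproduce identical tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the output directory; the loaded results are attached
#'   as attributes `calls`, `cells`, `counts`, `pathways`, `downsampling`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  meta <- list(config = config_echo(config),
               package_version = as.character(utils::packageVersion("sphereg")),
               seed = config$seed, stages = list(), status = "incomplete")
  log_line <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), msg)
    inform(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      meta$status <<- paste0("failed at stage: ", name)
      jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      log_line(sprintf("stage '%s' FAILED: %s", name, conditionMessage(e)))
      abort(sprintf("Pipeline failed at stage '%s': %s", name, conditionMessage(e)))
    })
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    meta$stages[[name]] <<- c(meta$stages[[name]], list(seconds = round(el, 2)))
    log_line(sprintf("stage '%s' done in %.1fs", name, el))
    out
  }

  inputs <- stage("load", {
    counts <- if (is.character(config$counts)) {
      read_counts(config$counts, dialect = config$dialect)
    } else validate_counts(config$counts)
    cells <- if (is.character(config$cells)) {
      read_cell_metadata(config$cells)
    } else validate_cells(config$cells, need_position = FALSE)
    list(counts = counts, cells = cells)
  })
  qc <- stage("qc_filter", {
    out <- qc_filter_cells(inputs$cells, inputs$counts,
                           min_depth = config$min_depth,
                           min_genes_detected = config$min_genes_detected)
    meta$stages$qc_filter$n_cells_kept <- nrow(out$cells)
    meta$stages$qc_filter$n_cells_dropped <- out$n_dropped
    out
  })
  cells <- stage("position", {
    if ("radial_position" %in% names(qc$cells)) validate_cells(qc$cells)
    else add_radial_position(qc$cells, clip_quantiles = config$clip_quantiles)
  })
  counts <- stage("gene_filter", {
    out <- filter_expressed_genes(qc$counts, config$min_mean_umis)
    meta$stages$gene_filter$n_genes_kept <- nrow(out)
    out
  })
  calls <- stage("spatial_calling", {
    out <- call_spatial_genes(counts, cells,
                              fdr_max = config$fdr_max, mag_min = config$mag_min,
                              loglik_per_cell = config$loglik_per_cell,
                              delta = config$delta, tau = config$tau,
                              sig_level = config$sig_level,
                              keep_fits = TRUE, verbose = FALSE)
    meta$stages$spatial_calling$n_spatial <- sum(out$spatial)
    meta$stages$spatial_calling$patterns <-
      as.list(table(out$pattern[out$spatial]))
    out
  })
  pathways <- NULL
  if (!is.null(config$gmt)) {
    pathways <- stage("pathway_scan", {
      gs <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
      out <- pathway_spatial_scan(counts, cells, gs,
                                  min_genes = config$min_genes,
                                  fdr_max = config$fdr_max,
                                  n_bins = config$n_bins,
                                  seed = config$seed + 1000L)
      meta$stages$pathway_scan$n_significant <- sum(out$significant)
      out
    })
  }
  curve <- NULL
  if (!is.null(config$downsample_ps)) {
    curve <- stage("downsampling", {
      downsampling_curve(counts, cells, ps = config$downsample_ps,
                         seed = config$seed + 2000L,
                         fdr_max = config$fdr_max, mag_min = config$mag_min,
                         loglik_per_cell = config$loglik_per_cell,
                         delta = config$delta, tau = config$tau,
                         sig_level = config$sig_level, keep_fits = FALSE)
    })
  }
  stage("write_output", {
    readr::write_tsv(cells, file.path(config$out_dir, "cells_qc.tsv"), progress = FALSE)
    readr::write_tsv(dplyr::select(tibble::as_tibble(calls), -dplyr::any_of("fit")),
                     file.path(config$out_dir, "spatial_calls.tsv"), progress = FALSE)
    if (!is.null(pathways)) {
      readr::write_tsv(pathways, file.path(config$out_dir, "pathways.tsv"), progress = FALSE)
    }
    if (!is.null(curve)) {
      readr::write_tsv(curve, file.path(config$out_dir, "downsampling.tsv"), progress = FALSE)
    }
  })
  meta$status <- "complete"
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  log_line("run complete")
  out <- config$out_dir
  attr(out, "calls") <- calls
  attr(out, "cells") <- cells
  attr(out, "counts") <- counts
  attr(out, "pathways") <- pathways
  attr(out, "downsampling") <- curve
  invisible(out)
}

# Config echo with in-memory objects replaced by short descriptions.
config_echo <- function(config) {
  lapply(unclass(config), function(v) {
    if (is.matrix(v)) sprintf("<in-memory matrix %d x %d>", nrow(v), ncol(v))
    else if (is.data.frame(v)) sprintf("<in-memory table, %d rows>", nrow(v))
    else v
  })
}

#' Summarize a completed pipeline run from its output directory
#'
#' Self-contained: reads only the run directory. Refuses incomplete runs,
#' pointing at the failed stage.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return List with `metadata`, `pattern_counts` (tibble), `calls`,
#'   `pathways_head`.
#' @export
report_run <- function(run_dir) {
  meta_path <- file.path(run_dir, "run_metadata.json")
  if (!file.exists(meta_path)) abort("Not a run directory (no run_metadata.json).")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$status, "complete")) {
    abort(sprintf("Run is incomplete (%s); re-run the pipeline.", meta$status))
  }
  calls <- readr::read_tsv(file.path(run_dir, "spatial_calls.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  pat <- dplyr::count(dplyr::filter(calls, .data$spatial), .data$pattern,
                      name = "n_genes")
  pw_path <- file.path(run_dir, "pathways.tsv")
  pw <- if (file.exists(pw_path)) {
    head(dplyr::arrange(readr::read_tsv(pw_path, show_col_types = FALSE,
                                        progress = FALSE), .data$q), 10)
  }
  list(metadata = meta, pattern_counts = pat, calls = calls, pathways_head = pw)
}
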