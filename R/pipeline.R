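# End-to-end orchestration: simulate -> segment -> index -> correlate.
#
# Three mutually exclusive run modes:
#   * frames mode       — segment existing frame files listed in a manifest;
#   * synthetic mode    — generate a seeded synthetic study and stream each
#                         frame through segmentation without keeping rasters;
#   * reproduction mode — skip imagery entirely and run the correlation
#                         analysis on the packaged published summary tables.

#' Segment every frame of a study
#'
#' Runs [segment_frame()] over all frames of a manifest (reading files from
#' `frames_dir`) or over an in-memory list of frames, and returns the
#' per-frame segmentation table.
#'
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @param frames_dir directory containing the frame files named in
#'   `manifest$file`; ignored when `frames` is given.
#' @param frames optional list of [thermal_frame()] in manifest order.
#' @param ... segmentation parameters passed to [segment_frame()].
#' @param log optional connection or path; one line per frame is written
#'   (threshold, method, counts).
#' @return data.frame with one row per frame: manifest columns plus `t_th`,
#'   `method`, `p_w`, `p_s`, `t_w_mean`, `t_s_mean`.
#' @export
segment_study <- function(manifest, frames_dir = NULL, frames = NULL, ...,
                          log = NULL) {
  if (nrow(manifest) == 0)
    stop("empty manifest: nothing to segment", call. = FALSE)
  logline <- make_logger(log)
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    fr <- if (!is.null(frames)) frames[[i]]
          else read_frame(file.path(frames_dir, manifest$file[i]))
    seg <- tryCatch(segment_frame(fr, ...), error = function(e)
      stop("segmentation failed for frame '", manifest$file[i], "': ",
           conditionMessage(e), call. = FALSE))
    logline(sprintf("frame %s: T_TH=%.2f (%s) P_W=%d P_S=%d",
                    manifest$file[i], seg$t_th, seg$method, seg$p_w,
                    seg$p_s))
    rows[[i]] <- cbind(manifest[i, , drop = FALSE],
                       data.frame(t_th = seg$t_th, method = seg$method,
                                  p_w = seg$p_w, p_s = seg$p_s,
                                  t_w_mean = seg$t_w_mean,
                                  t_s_mean = seg$t_s_mean))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

make_logger <- function(log) {
  if (is.null(log)) return(function(msg) invisible(NULL))
  if (is.character(log)) {
    con <- file(log, "a")
    return(function(msg) writeLines(msg, con))
  }
  function(msg) writeLines(msg, log)
}

#' Run a synthetic study through the full pipeline
#'
#' Generates the study frame-by-frame (streaming: rasters are segmented as
#' produced and discarded), computes per-frame indices, and aggregates into
#' the summary tables.
#'
#' @param config cell table as returned by [study_config()].
#' @param ... generation parameters passed to [generate_study()]
#'   (`frames_per_session`, `sessions_per_stage`, `height`, `width`,
#'   `session_sd`, ...).
#' @param seed integer seed for all randomness.
#' @param segmentation named list of [segment_frame()] parameters.
#' @return List with `records` (per-frame segmentation + indices), `truth`
#'   (per-frame generator ground truth), and `tables` (per-species
#'   `index_table`s from [aggregate_indices()]).
#' @export
run_synthetic_study <- function(config, ..., seed = 1,
                                segmentation = list()) {
  seg_rows <- new.env(parent = emptyenv())
  seg_rows$rows <- list()
  cb <- function(frame, truth, row) {
    seg <- do.call(segment_frame, c(list(frame), segmentation))
    seg_rows$rows[[length(seg_rows$rows) + 1]] <-
      cbind(row, data.frame(t_th = seg$t_th, method = seg$method,
                            p_w = seg$p_w, p_s = seg$p_s,
                            t_w_mean = seg$t_w_mean,
                            t_s_mean = seg$t_s_mean))
  }
  gen <- generate_study(config, ..., seed = seed, callback = cb)
  seg <- do.call(rbind, seg_rows$rows)
  rownames(seg) <- NULL
  records <- index_records(seg)
  list(records = records, truth = gen$truth,
       tables = aggregate_indices(records))
}

#' Pipeline configuration
#'
#' Exactly one of the three run modes must be requested: `frames_dir` +
#' `manifest` (frames mode), `generation` (synthetic mode), or
#' `reproduction = TRUE` (published-tables mode). Can also be read from a
#' YAML file via [read_pipeline_config()].
#'
#' @param frames_dir,manifest frame directory and manifest CSV path.
#' @param generation either `"default"` (the [study_config()] defaults) or
#'   a named list with an optional `cells` data.frame and generation
#'   scalars (`frames_per_session`, `sessions_per_stage`, `height`,
#'   `width`, `session_sd`).
#' @param reproduction run on the packaged published tables instead of
#'   imagery.
#' @param species species to analyse.
#' @param segmentation named list of [segment_frame()] parameters.
#' @param seed integer seed.
#' @param out_dir output directory for report CSVs and the run log, or
#'   `NULL` to skip writing.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(frames_dir = NULL, manifest = NULL,
                            generation = NULL, reproduction = FALSE,
                            species = c("durum", "common"),
                            segmentation = list(), seed = 1,
                            out_dir = NULL) {
  modes <- c(frames = !is.null(manifest), synthetic = !is.null(generation),
             reproduction = isTRUE(reproduction))
  if (sum(modes) != 1)
    stop("exactly one of manifest+frames_dir, generation, or reproduction ",
         "must drive a run (got ", sum(modes), ")", call. = FALSE)
  structure(list(frames_dir = frames_dir, manifest = manifest,
                 generation = generation, reproduction = isTRUE(reproduction),
                 species = match.arg(species, several.ok = TRUE),
                 segmentation = segmentation, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generation) && is.list(y$generation) &&
      !is.null(y$generation$cells))
    y$generation$cells <- as.data.frame(y$generation$cells)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the configured mode and always finishes with the correlation of
#' `wsi_m` and `wci_m` against the packaged yield-component tables (each
#' index x component, with and without the modern cultivars). When
#' `out_dir` is set, writes `segmentation.csv`, `index_records.csv`,
#' per-species `wsi_table_*.csv` / `wci_table_*.csv`, `correlations.csv`
#' and `run_log.txt`. Deterministic given the seed (the log carries a
#' timestamp).
#'
#' @param config a [pipeline_config()].
#' @return List with `records`, `tables`, `summaries` (per species:
#'   `variety`, `wsi_m`, `wci_m`) and `correlations`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  note("run started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  note("mode: %s", if (config$reproduction) "reproduction"
       else if (!is.null(config$generation)) "synthetic" else "frames")
  note("seed: %d", config$seed)

  records <- NULL; tables <- NULL; truth <- NULL
  if (config$reproduction) {
    summaries <- lapply(config$species, function(sp) {
      w <- reference_wsi_table(sp)
      cbind(w["variety"], wsi_m = w$wsi_m,
            wci_m = reference_wci_table(sp)$wci_m[
              match(w$variety, reference_wci_table(sp)$variety)])
    })
    names(summaries) <- config$species
  } else if (!is.null(config$generation)) {
    gen <- config$generation
    if (identical(gen, "default")) gen <- list()
    cells <- gen$cells %||% study_config(config$species)
    gen_args <- gen[setdiff(names(gen), "cells")]
    run <- do.call(run_synthetic_study,
                   c(list(cells), gen_args,
                     list(seed = config$seed,
                          segmentation = config$segmentation)))
    records <- run$records; tables <- run$tables; truth <- run$truth
    summaries <- summaries_from_tables(tables)
  } else {
    man <- if (is.character(config$manifest)) read_manifest(config$manifest)
           else config$manifest
    seg <- do.call(segment_study,
                   c(list(man, frames_dir = config$frames_dir),
                     config$segmentation))
    records <- index_records(seg)
    tables <- aggregate_indices(records)
    summaries <- summaries_from_tables(tables)
  }

  correlations <- do.call(rbind, lapply(names(summaries), function(sp) {
    yt <- reference_yield_table(sp)
    n_ancient <- sum(!yt$is_modern[yt$variety %in% summaries[[sp]]$variety])
    variants <- if (n_ancient >= 3) c(FALSE, TRUE) else FALSE
    if (n_ancient < 3)
      note("%s: modern-variety exclusion skipped (only %d landrace/mixture varieties present)",
           sp, n_ancient)
    do.call(rbind, lapply(variants, function(excl) {
      res <- run_correlation_suite(summaries[[sp]], yt,
                                   exclude_modern = excl)
      cbind(species = sp, res)
    }))
  }))
  for (i in seq_len(nrow(correlations)))
    note("correlation %s %s~%s n=%d r=%.3f p=%.4g %s",
         correlations$species[i], correlations$index[i],
         correlations$target[i], correlations$n[i], correlations$r[i],
         correlations$p_two_tailed[i], correlations$significance_bin[i])

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(records))
      utils::write.csv(records, file.path(out_dir, "index_records.csv"),
                       row.names = FALSE)
    if (!is.null(tables)) for (sp in names(tables)) {
      utils::write.csv(render_index_table(tables[[sp]]),
                       file.path(out_dir, paste0("wsi_table_", sp, ".csv")),
                       row.names = FALSE)
      utils::write.csv(tables[[sp]]$wci,
                       file.path(out_dir, paste0("wci_table_", sp, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  list(records = records, tables = tables, truth = truth,
       summaries = summaries, correlations = correlations,
       log = log_lines)
}

summaries_from_tables <- function(tables) {
  out <- lapply(tables, function(tab) {
    data.frame(variety = tab$wsi_m$variety, wsi_m = tab$wsi_m$wsi_m,
               wci_m = tab$wci$wci_m[match(tab$wsi_m$variety,
                                           tab$wci$variety)])
  })
  names(out) <- names(tables)
  out
}
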