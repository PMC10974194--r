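# Seeded synthetic thermal-field generator.
#
# Emulates the study's proximal thermography protocol: per-plot frames whose
# pixels fall into two spatially coherent temperature classes, wheat (cool)
# and bare soil (warm). Wheat is laid out as vertical crop-row bands of
# jittered width so that frame histograms are bimodal and masks resemble
# drilled rows rather than salt-and-pepper noise. The wheat class mean is
# never free: it is derived from the soil mean and the target stress index,
#   wheat_mean = soil_mean * (1 - target_wsi),
# which inverts WSI = (T_S - T_W)/T_S, so a requested index is recoverable
# by the downstream pipeline.

# Boolean wheat indicator over image columns: alternating wheat bands of
# jittered width with soil gaps distributed (with jitter) between and around
# them. The total wheat-column count is exactly round(cover * width), so the
# realised cover fraction matches the request at one-column granularity.
wheat_columns <- function(width, cover, band_widths = 4:12) {
  n_w <- round(cover * width)
  if (n_w <= 0) return(rep(FALSE, width))
  if (n_w >= width) return(rep(TRUE, width))
  widths <- integer(0)
  while (sum(widths) < n_w)
    widths <- c(widths, sample(band_widths, 1))
  excess <- sum(widths) - n_w
  widths[length(widths)] <- widths[length(widths)] - excess
  widths <- widths[widths > 0]
  k <- length(widths)
  gaps <- as.vector(stats::rmultinom(1, width - n_w, rep(1, k + 1)))
  cols <- logical(0)
  for (i in seq_len(k))
    cols <- c(cols, rep(FALSE, gaps[i]), rep(TRUE, widths[i]))
  c(cols, rep(FALSE, gaps[k + 1]))
}

#' Generate one synthetic thermal frame with ground truth
#'
#' Draws a wheat/soil mask as vertical crop-row bands meeting
#' `cover_fraction` exactly at one-column granularity, then adds independent
#' Gaussian temperature noise per class.
#'
#' @param soil_mean,wheat_mean class mean temperatures (degrees C);
#'   `soil_mean` must exceed `wheat_mean` unless one class is absent.
#' @param soil_sd,wheat_sd within-class temperature standard deviations
#'   (degrees C), both positive.
#' @param cover_fraction target wheat cover in `[0, 1]`.
#' @param height,width frame size in pixels (native detector 240 x 320).
#' @param band_widths integer pool of wheat row-band widths (pixels).
#' @param seed optional integer seed; the session RNG state is restored.
#' @param meta optional [frame_meta()].
#' @return List with `frame` (a [thermal_frame()]) and `truth` (list with
#'   the boolean wheat `mask`, realised `cover`, class sample means `t_w`
#'   and `t_s`, and the configured `wheat_mean` and `soil_mean`).
#' @export
generate_frame <- function(soil_mean, wheat_mean, soil_sd = 0.5,
                           wheat_sd = 0.5, cover_fraction,
                           height = 240, width = 320, band_widths = 4:12,
                           seed = NULL, meta = NULL) {
  if (cover_fraction < 0 || cover_fraction > 1)
    stop("`cover_fraction` must lie in [0, 1]", call. = FALSE)
  if (soil_sd <= 0 || wheat_sd <= 0)
    stop("class standard deviations must be positive", call. = FALSE)
  if (cover_fraction > 0 && cover_fraction < 1 && soil_mean <= wheat_mean)
    stop("`soil_mean` must exceed `wheat_mean`", call. = FALSE)
  with_seed(seed, {
    cols <- wheat_columns(width, cover_fraction, band_widths)
    mask <- matrix(rep(cols, each = height), nrow = height)
    px <- matrix(NA_real_, height, width)
    nw <- sum(mask)
    ns <- length(mask) - nw
    if (nw > 0) px[mask] <- stats::rnorm(nw, wheat_mean, wheat_sd)
    if (ns > 0) px[!mask] <- stats::rnorm(ns, soil_mean, soil_sd)
    truth <- list(
      mask = mask,
      cover = nw / length(mask),
      t_w = if (nw > 0) mean(px[mask]) else NA_real_,
      t_s = if (ns > 0) mean(px[!mask]) else NA_real_,
      wheat_mean = wheat_mean, soil_mean = soil_mean
    )
    list(frame = thermal_frame(px, meta = meta), truth = truth)
  })
}

#' Default synthetic study configuration
#'
#' One row per species x variety x phenological stage, giving the cell-level
#' generation parameters. Stress targets (`target_wsi`) are the published
#' per-stage WSI values; stem-elongation cover fractions are the published
#' WCI means; later-stage cover defaults to `cover_late` (the canopy has
#' closed and WCI is no longer estimated). Soil means follow the
#' field-season progression April -> late June.
#'
#' @param species species to include (default both).
#' @param soil_means named numeric vector of soil mean temperature (degrees
#'   C) per stage.
#' @param cover_late wheat cover fraction assumed for the three post
#'   stem-elongation stages.
#' @param soil_sd,wheat_sd within-class standard deviations (degrees C).
#' @return data.frame with columns `species`, `variety`, `stage`,
#'   `soil_mean`, `target_wsi`, `cover_fraction`, `soil_sd`, `wheat_sd`.
#' @export
study_config <- function(species = c("durum", "common"),
                         soil_means = c(stem_elongation = 18,
                                        heading_begins = 26,
                                        milky_waxy = 30,
                                        full_ripening = 32),
                         cover_late = 0.85, soil_sd = 0.5, wheat_sd = 0.5) {
  species <- match.arg(species, several.ok = TRUE)
  stopifnot(all(stage_levels() %in% names(soil_means)))
  rows <- list()
  for (sp in species) {
    wsi <- reference_wsi_table(sp)
    wci <- reference_wci_table(sp)
    for (stage in stage_levels()) {
      cover <- if (stage == "stem_elongation")
        wci$wci_m[match(wsi$variety, wci$variety)]
      else rep(cover_late, nrow(wsi))
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, variety = wsi$variety, stage = stage,
        soil_mean = unname(soil_means[stage]), target_wsi = wsi[[stage]],
        cover_fraction = cover, soil_sd = soil_sd, wheat_sd = wheat_sd
      )
    }
  }
  do.call(rbind, rows)
}

#' Generate a full synthetic study
#'
#' Expands a cell-level configuration (see [study_config()]) into
#' `sessions_per_stage` measurement sessions of `frames_per_session` frames
#' per cell, reproducibly from `seed`. Each session carries an additive
#' temperature offset (shared by both classes, so the target WSI is
#' preserved in expectation) emulating morning/afternoon conditions.
#'
#' Frames are either written to `dir` (with `manifest.csv` and `truth.csv`),
#' streamed to `callback(frame, truth, manifest_row)` without being
#' retained, or returned in-memory — choose streaming for full-size studies.
#'
#' @param config cell table as returned by [study_config()].
#' @param frames_per_session frames acquired per session and cell.
#' @param sessions_per_stage measurement sessions per stage (2 per day on 2
#'   consecutive days in the emulated protocol).
#' @param height,width frame size in pixels.
#' @param session_sd standard deviation (degrees C) of the per-session
#'   additive temperature offset.
#' @param band_widths wheat row-band width pool (pixels).
#' @param seed integer seed governing all randomness.
#' @param dir output directory for frame files, or `NULL`.
#' @param format frame file format when writing (`"csv"` or `"tiff"`).
#' @param callback optional `function(frame, truth, row)` invoked per frame.
#' @return List with `manifest` (data.frame), `truth` (per-frame data.frame
#'   with realised cover and class means), and `frames` (list of
#'   [thermal_frame()], only when neither `dir` nor `callback` is given).
#' @export
generate_study <- function(config, frames_per_session = 10,
                           sessions_per_stage = 4, height = 240, width = 320,
                           session_sd = 0.5, band_widths = 4:12, seed = 1,
                           dir = NULL, format = c("csv", "tiff"),
                           callback = NULL) {
  format <- match.arg(format)
  key <- paste(config$species, config$variety, config$stage)
  if (anyDuplicated(key))
    stop("duplicate species/variety/stage rows in config", call. = FALSE)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  keep <- is.null(dir) && is.null(callback)

  with_seed(seed, {
    # one shared offset per species x stage x session (all plots of a species
    # are imaged in the same session)
    sess_key <- unique(data.frame(
      species = rep(config$species, each = sessions_per_stage),
      stage = rep(config$stage, each = sessions_per_stage),
      session = rep(seq_len(sessions_per_stage), times = nrow(config))
    ))
    sess_key$offset <- stats::rnorm(nrow(sess_key), 0, session_sd)

    n_frames <- nrow(config) * sessions_per_stage * frames_per_session
    manifest <- vector("list", n_frames)
    truth <- vector("list", n_frames)
    frames <- if (keep) vector("list", n_frames) else NULL
    i <- 0L
    for (ci in seq_len(nrow(config))) {
      cell <- config[ci, ]
      wheat_mean <- cell$soil_mean * (1 - cell$target_wsi)
      for (sess in seq_len(sessions_per_stage)) {
        off <- sess_key$offset[sess_key$species == cell$species &
                               sess_key$stage == cell$stage &
                               sess_key$session == sess]
        for (fr in seq_len(frames_per_session)) {
          i <- i + 1L
          fname <- sprintf("%s_%s_%s_s%d_f%02d.%s", cell$species,
                           cell$variety, cell$stage, sess, fr,
                           if (format == "tiff") "tif" else "csv")
          meta <- frame_meta(cell$species, cell$variety, cell$stage,
                             session = sess,
                             replicate = (fr - 1L) %% 3L + 1L,
                             frame_index = fr)
          g <- generate_frame(cell$soil_mean + off, wheat_mean + off,
                              cell$soil_sd, cell$wheat_sd,
                              cell$cover_fraction, height, width,
                              band_widths, seed = NULL, meta = meta)
          row <- data.frame(
            file = fname, species = cell$species, variety = cell$variety,
            stage = cell$stage, session = sess,
            replicate = meta$replicate, frame_index = fr
          )
          manifest[[i]] <- row
          truth[[i]] <- data.frame(
            file = fname, species = cell$species, variety = cell$variety,
            stage = cell$stage, session = sess, frame_index = fr,
            cover_true = g$truth$cover, t_w_true = g$truth$t_w,
            t_s_true = g$truth$t_s, target_wsi = cell$target_wsi,
            cover_target = cell$cover_fraction, session_offset = off
          )
          if (!is.null(dir))
            write_frame(g$frame, file.path(dir, fname), format)
          if (!is.null(callback))
            callback(g$frame, g$truth, row)
          if (keep) frames[[i]] <- g$frame
        }
      }
    }
    manifest <- do.call(rbind, manifest)
    truth <- do.call(rbind, truth)
    if (!is.null(dir)) {
      utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                       row.names = FALSE)
      utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    }
    list(manifest = manifest, truth = truth, frames = frames)
  })
}
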