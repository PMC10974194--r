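# Wheat Stress Index and Wheat Cover Index, and their aggregation into the
# per-variety x per-stage summary structure of the study.
#
#   WSI = (T_S - T_W) / T_S       soil-normalised stress index
#   WCI = P_W / (P_W + P_S)       thermal fractional-cover index
#
# Both are computed on Celsius temperatures and are NOT unit-invariant.
# In the observed regime T_S > T_W > 0 the WSI lies in (0, 1); LOWER values
# indicate HIGHER crop stress (a cool canopy relative to its soil signals a
# transpiring, unstressed crop). The WCI is only meaningful at stem
# elongation, before canopy closure hides the soil, and is restricted to
# that stage during aggregation.

#' Wheat Stress Index
#'
#' `(t_s - t_w) / t_s`, the canopy-to-soil temperature contrast normalised
#' by the soil temperature of the same frame.
#'
#' @param t_s soil class mean temperature, degrees C (> 0).
#' @param t_w wheat class mean temperature, degrees C (> 0).
#' @return Numeric WSI. Guaranteed in (0, 1) iff `0 < t_w < t_s`; if
#'   `t_w >= t_s` (outside the observed regime) the value is returned with
#'   a warning.
#' @export
compute_wsi <- function(t_s, t_w) {
  if (any(!is.finite(t_s)) || any(!is.finite(t_w)))
    stop("temperatures must be finite", call. = FALSE)
  if (any(t_s <= 0))
    stop("WSI undefined: soil temperature must be positive (degrees C); ",
         "the index is not defined near or below 0 degC", call. = FALSE)
  if (any(t_w <= 0))
    stop("WSI undefined: wheat temperature must be positive (degrees C)",
         call. = FALSE)
  if (any(t_w >= t_s))
    warning("t_w >= t_s: WSI outside the observed regime (T_S > T_W > 0)",
            call. = FALSE)
  (t_s - t_w) / t_s
}

#' Wheat Cover Index
#'
#' `p_w / (p_w + p_s)`, the fraction of classified pixels labelled wheat.
#'
#' @param p_w wheat pixel count.
#' @param p_s soil pixel count.
#' @return Numeric WCI in `[0, 1]`.
#' @export
compute_wci <- function(p_w, p_s) {
  if (any(p_w < 0) || any(p_s < 0))
    stop("pixel counts must be non-negative", call. = FALSE)
  if (any(p_w + p_s == 0))
    stop("WCI undefined: no classified pixels", call. = FALSE)
  p_w / (p_w + p_s)
}

#' Per-frame index records from segmentation results
#'
#' Computes one WSI per frame from that frame's class means, and one WCI
#' per stem-elongation frame from its pixel counts. Frames where one class
#' is empty cannot yield a WSI and are recorded as `NA` with a warning.
#'
#' @param seg_table data.frame with one row per frame: columns `file`,
#'   `species`, `variety`, `stage`, `session`, `p_w`, `p_s`, `t_w_mean`,
#'   `t_s_mean` (the per-frame output of [segment_study()]).
#' @return The same data.frame with `wsi` and `wci` columns appended (`wci`
#'   is `NA` outside stem elongation).
#' @export
index_records <- function(seg_table) {
  n <- nrow(seg_table)
  wsi <- rep(NA_real_, n)
  ok <- seg_table$p_w > 0 & seg_table$p_s > 0 &
    is.finite(seg_table$t_s_mean) & is.finite(seg_table$t_w_mean) &
    seg_table$t_s_mean > 0 & seg_table$t_w_mean > 0
  if (any(!ok))
    warning(sum(!ok), " frame(s) without both temperature classes: ",
            "WSI not computable and recorded as NA", call. = FALSE)
  wsi[ok] <- compute_wsi(seg_table$t_s_mean[ok], seg_table$t_w_mean[ok])
  wci <- rep(NA_real_, n)
  se <- seg_table$stage == "stem_elongation"
  wci[se] <- compute_wci(seg_table$p_w[se], seg_table$p_s[se])
  seg_table$wsi <- wsi
  seg_table$wci <- wci
  seg_table
}

#' Aggregate frame-level indices into the study summary tables
#'
#' Stage cells are unweighted means of all frame-level WSI values for a
#' variety x stage (pooled over sessions and replicates). `wsi_m` is the
#' per-variety mean over the four stage cells (row mean), `pp_wsi_m` the
#' per-stage mean over varieties (column mean); on a complete table their
#' grand means coincide. `wci_m` is the mean frame-level WCI over
#' stem-elongation frames only, with its standard error. Values are kept at
#' full precision; rounding happens only at report time (see
#' [render_index_table()]).
#'
#' @param records data.frame from [index_records()].
#' @param species species to aggregate (default: those present).
#' @return Named list (one element per species), each a list of class
#'   `index_table` with: `stage_wsi` (data.frame variety x stage), `wsi_m`,
#'   `pp_wsi_m`, `wci` (data.frame `variety`, `wci_m`, `wci_se`, `n`), and
#'   `n_frames` (cell counts).
#' @export
aggregate_indices <- function(records, species = unique(records$species)) {
  out <- lapply(species, function(sp) {
    rec <- records[records$species == sp, , drop = FALSE]
    varieties <- unique(rec$variety)
    stages <- stage_levels()[stage_levels() %in% unique(rec$stage)]
    cell <- matrix(NA_real_, length(varieties), length(stages),
                   dimnames = list(varieties, stages))
    n_cell <- cell
    for (v in varieties) for (s in stages) {
      w <- rec$wsi[rec$variety == v & rec$stage == s]
      w <- w[!is.na(w)]
      n_cell[v, s] <- length(w)
      if (length(w) > 0) cell[v, s] <- mean(w)
    }
    if (any(n_cell == 0))
      warning(sp, ": ", sum(n_cell == 0),
              " empty variety x stage cell(s); excluded from means",
              call. = FALSE)
    wsi_m <- rowMeans(cell, na.rm = TRUE)
    pp_wsi_m <- colMeans(cell, na.rm = TRUE)
    se_rec <- rec[rec$stage == "stem_elongation" & !is.na(rec$wci), ,
                  drop = FALSE]
    wci <- do.call(rbind, lapply(varieties, function(v) {
      x <- se_rec$wci[se_rec$variety == v]
      data.frame(variety = v,
                 wci_m = if (length(x)) mean(x) else NA_real_,
                 wci_se = if (length(x) > 1)
                   stats::sd(x) / sqrt(length(x)) else NA_real_,
                 n = length(x))
    }))
    structure(
      list(species = sp,
           stage_wsi = data.frame(variety = varieties,
                                  as.data.frame(cell, optional = TRUE),
                                  row.names = NULL, check.names = FALSE),
           wsi_m = data.frame(variety = varieties, wsi_m = unname(wsi_m)),
           pp_wsi_m = data.frame(stage = stages,
                                 pp_wsi_m = unname(pp_wsi_m)),
           wci = wci, n_frames = n_cell),
      class = "index_table")
  })
  names(out) <- species
  out
}

#' Render an index table at report precision
#'
#' Applies half-away-from-zero rounding to 2 decimals (the precision of the
#' published summaries) to the stage cells, row and column means.
#'
#' @param tab an `index_table` from [aggregate_indices()].
#' @param digits decimal places.
#' @return data.frame in the published layout: one row per variety with its
#'   four stage values and `wsi_m`, plus a final `PP-WSI_m` row of column
#'   means.
#' @export
render_index_table <- function(tab, digits = 2) {
  stages <- setdiff(names(tab$stage_wsi), "variety")
  body <- tab$stage_wsi
  body[stages] <- lapply(body[stages], round_half_up, digits)
  body$wsi_m <- round_half_up(tab$wsi_m$wsi_m, digits)
  foot <- c(list(variety = "PP-WSI_m"),
            as.list(round_half_up(tab$pp_wsi_m$pp_wsi_m, digits)),
            list(wsi_m = NA_real_))
  names(foot)[2:(1 + length(stages))] <- stages
  rbind(body, as.data.frame(foot))
}
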