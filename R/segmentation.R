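# Wheat/soil segmentation by temperature-histogram thresholding.
#
# Frames with both crop and bare soil in view show a bimodal temperature
# distribution: a cool vegetation mode and a warm soil mode. The threshold
# T_TH is taken as the mean of the two mode temperatures when a double peak
# is detected; when the distribution is continuous/unimodal the fallback is
# Otsu's between-class variance maximisation over the histogram (the field
# procedure of comparing against a visible-light image is not automatable;
# Otsu formalises "maximise the separation of the two temperature classes").
# Pixels at or below T_TH are labelled wheat, pixels above it soil.

#' Build a uniform temperature histogram of a frame
#'
#' Bins span the valid-pixel range with uniform width. The default width of
#' 0.1 degrees C reflects the camera's ~60 mK noise-equivalent temperature
#' difference: finer bins would resolve nothing but sensor noise.
#'
#' @param frame a [thermal_frame()] with at least one valid pixel.
#' @param bin_width bin width in degrees C (> 0).
#' @return List of class `temperature_histogram` with `bin_edges` (length
#'   `n + 1`, strictly increasing, uniform), `counts` (length `n`, summing
#'   to the valid-pixel count), `mids` and `bin_width`.
#' @export
build_histogram <- function(frame, bin_width = 0.1) {
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  v <- frame$pixels[!is.na(frame$pixels)]
  if (length(v) == 0)
    stop("cannot build a histogram: frame has no valid pixels", call. = FALSE)
  lo <- floor(min(v) / bin_width) * bin_width
  n_bins <- max(1L, ceiling((max(v) - lo) / bin_width + 1e-9))
  # guard against the max landing exactly on the last edge
  while (lo + n_bins * bin_width <= max(v)) n_bins <- n_bins + 1L
  idx <- pmin(floor((v - lo) / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  edges <- lo + bin_width * (0:n_bins)
  structure(
    list(bin_edges = edges, counts = counts,
         mids = (edges[-1] + edges[-length(edges)]) / 2,
         bin_width = bin_width),
    class = "temperature_histogram"
  )
}

# Centered moving-average smoothing with shrinking windows at the edges, so
# boundary bins keep their magnitude (a boundary mode must stay detectable).
smooth_counts <- function(counts, window) {
  if (window <= 1 || length(counts) == 1) return(as.numeric(counts))
  half <- (window - 1) %/% 2
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    j <- max(1, i - half):min(n, i + half)
    mean(counts[j])
  }, numeric(1))
}

# Topographic prominence of a local maximum at index i of series s: height
# above the higher of the two saddles reached before meeting a taller bin on
# each side. A side that runs to the series boundary without meeting a
# taller bin contributes its minimum; an empty side (peak at the boundary)
# contributes nothing, so a boundary mode of a monotone histogram keeps its
# full drop as prominence.
peak_prominence <- function(s, i) {
  n <- length(s)
  side_min <- function(from, to, step) {
    if (from * step > to * step) return(-Inf)   # empty side
    m <- Inf
    for (j in seq(from, to, by = step)) {
      if (s[j] > s[i]) return(m)
      m <- min(m, s[j])
    }
    m
  }
  left <- side_min(i - 1, 1, -1L)
  right <- side_min(i + 1, n, 1L)
  if (is.infinite(left) && is.infinite(right)) return(s[i])
  s[i] - max(left, right)
}

#' Detect temperature modes in a histogram
#'
#' Local maxima of the moving-average-smoothed counts are kept if their
#' topographic prominence reaches `min_prominence` of the tallest smoothed
#' bin; peaks closer than `min_separation` are resolved in favour of the
#' more prominent one. Boundary bins count as candidate maxima (a monotone
#' histogram has its mode at the end).
#'
#' @param hist a [build_histogram()] result.
#' @param smoothing_window moving-average window in bins.
#' @param min_prominence required prominence as a fraction of the maximum
#'   smoothed count.
#' @param min_separation minimum distance between retained peaks, degrees C.
#' @return data.frame with columns `temperature` (bin center, ascending),
#'   `height` (smoothed count) and `prominence`. Zero rows is a legal
#'   result.
#' @export
detect_peaks <- function(hist, smoothing_window = 5, min_prominence = 0.05,
                         min_separation = 1.0) {
  s <- smooth_counts(hist$counts, smoothing_window)
  n <- length(s)
  if (n == 1)
    return(data.frame(temperature = hist$mids, height = s, prominence = s))
  # candidate local maxima, plateaus represented by their center bin
  ext <- c(-Inf, s, -Inf)
  cand <- integer(0)
  i <- 1
  while (i <= n) {
    if (ext[i] < ext[i + 1] && ext[i + 1] >= ext[i + 2]) {
      j <- i
      while (j < n && ext[j + 2] == ext[i + 1]) j <- j + 1
      if (ext[j + 1] > ext[j + 2]) cand <- c(cand, (i + j) %/% 2)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(cand) == 0) return(empty_peaks())
  prom <- vapply(cand, function(k) peak_prominence(s, k), numeric(1))
  keep <- prom >= min_prominence * max(s)
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0) return(empty_peaks())
  # greedy separation filter, most prominent first
  ord <- order(-prom, -s[cand])
  sel <- integer(0)
  for (k in ord) {
    if (all(abs(hist$mids[cand[k]] - hist$mids[cand[sel]]) >= min_separation))
      sel <- c(sel, k)
  }
  sel <- sel[order(cand[sel])]
  data.frame(temperature = hist$mids[cand[sel]], height = s[cand[sel]],
             prominence = prom[sel])
}

empty_peaks <- function() {
  data.frame(temperature = numeric(0), height = numeric(0),
             prominence = numeric(0))
}

# Otsu threshold on a histogram: exhaustive search over interior bin edges
# for the split maximising the between-class variance w0*w1*(mu0 - mu1)^2,
# with bin mids as class values. Returns the best edge temperature.
otsu_threshold <- function(hist) {
  counts <- hist$counts
  n <- length(counts)
  if (n < 2)
    stop("threshold undefined: histogram has a single bin", call. = FALSE)
  total <- sum(counts)
  w0 <- cumsum(counts)[-n]
  sum0 <- cumsum(counts * hist$mids)[-n]
  w1 <- total - w0
  mu0 <- sum0 / w0
  mu1 <- (sum(counts * hist$mids) - sum0) / w1
  bcv <- (w0 / total) * (w1 / total) * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  hist$bin_edges[which.max(bcv) + 1L]
}

#' Select the segmentation threshold T_TH
#'
#' With exactly two detected temperature modes, T_TH is their arithmetic
#' mean (`mean_of_peaks`). With more than two, the two most prominent modes
#' are used. With fewer than two (continuous/unimodal distribution), the
#' Otsu between-class-variance criterion over all bin edges is the fallback
#' (`otsu_fallback`). A `manual` override, when supplied, always wins.
#'
#' @param hist a [build_histogram()] result.
#' @param peaks optional precomputed [detect_peaks()] result.
#' @param manual optional manual threshold in degrees C.
#' @param ... passed on to [detect_peaks()] when `peaks` is not supplied.
#' @return List with `t_th` (degrees C) and `method` (one of
#'   `"mean_of_peaks"`, `"otsu_fallback"`, `"manual"`).
#' @export
select_threshold <- function(hist, peaks = NULL, manual = NULL, ...) {
  if (!is.null(manual)) {
    if (!is.finite(manual)) stop("manual threshold must be finite", call. = FALSE)
    return(list(t_th = manual, method = "manual"))
  }
  if (is.null(peaks)) peaks <- detect_peaks(hist, ...)
  if (nrow(peaks) > 2)
    peaks <- peaks[order(-peaks$prominence, -peaks$height)[1:2], ]
  if (nrow(peaks) == 2)
    return(list(t_th = mean(peaks$temperature), method = "mean_of_peaks"))
  list(t_th = otsu_threshold(hist), method = "otsu_fallback")
}

#' Classify frame pixels into wheat and soil
#'
#' Wheat pixels have temperature below the threshold, soil pixels above it;
#' pixels exactly at `t_th` are labelled wheat (the published rule uses
#' strict inequalities on both sides and leaves equality undefined; a fixed
#' tie rule preserves count conservation). Missing pixels are excluded from
#' counts and means.
#'
#' @param frame a [thermal_frame()] with at least one valid pixel.
#' @param t_th finite threshold temperature, degrees C.
#' @param method how the threshold was obtained (recorded in the result).
#' @return List of class `segmentation_result`: `mask` (logical matrix, TRUE
#'   = wheat, NA = missing), `t_th`, `method`, counts `p_w` and `p_s`, and
#'   class means `t_w_mean`, `t_s_mean` (NA for an empty class).
#' @export
classify_pixels <- function(frame, t_th, method = "manual") {
  if (!is.finite(t_th)) stop("`t_th` must be finite", call. = FALSE)
  px <- frame$pixels
  if (all(is.na(px)))
    stop("cannot classify: frame has no valid pixels", call. = FALSE)
  mask <- px <= t_th                      # ties -> wheat
  p_w <- sum(mask, na.rm = TRUE)
  p_s <- sum(!mask, na.rm = TRUE)
  structure(
    list(mask = mask, t_th = t_th, method = method, p_w = p_w, p_s = p_s,
         t_w_mean = if (p_w > 0) mean(px[which(mask)]) else NA_real_,
         t_s_mean = if (p_s > 0) mean(px[which(!mask)]) else NA_real_),
    class = "segmentation_result"
  )
}

#' Segment a frame end-to-end
#'
#' Convenience wrapper: histogram, peak detection, threshold selection and
#' pixel classification in one call.
#'
#' @param frame a [thermal_frame()].
#' @param bin_width histogram bin width, degrees C.
#' @param smoothing_window,min_prominence,min_separation see
#'   [detect_peaks()].
#' @param threshold optional manual threshold override, degrees C.
#' @return A `segmentation_result` (see [classify_pixels()]) with the
#'   histogram and detected peaks attached as `histogram` and `peaks`.
#' @export
segment_frame <- function(frame, bin_width = 0.1, smoothing_window = 5,
                          min_prominence = 0.05, min_separation = 1.0,
                          threshold = NULL) {
  hist <- build_histogram(frame, bin_width)
  peaks <- detect_peaks(hist, smoothing_window, min_prominence,
                        min_separation)
  sel <- select_threshold(hist, peaks, manual = threshold)
  res <- classify_pixels(frame, sel$t_th, sel$method)
  res$histogram <- hist
  res$peaks <- peaks
  res
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> T_TH = %.2f degC (%s); P_W = %d, P_S = %d\n",
    x$t_th, x$method, x$p_w, x$p_s))
  if (!is.na(x$t_w_mean))
    cat(sprintf("  T_W = %.2f degC", x$t_w_mean))
  if (!is.na(x$t_s_mean))
    cat(sprintf("  T_S = %.2f degC", x$t_s_mean))
  cat("\n")
  invisible(x)
}
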