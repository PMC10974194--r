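# Shared fixtures and independent oracles for the test suite.

const_frame <- function(value, h = 3, w = 3) {
  thermal_frame(matrix(value, h, w))
}

# Frame built directly from a vector of pixel values (one row).
vec_frame <- function(values) {
  thermal_frame(matrix(values, nrow = 1))
}

# Independent brute-force Otsu oracle: plain loops over every interior bin
# edge, recomputing class weights and means from scratch each time. Coded
# deliberately unlike the package implementation (no cumsum).
brute_force_otsu <- function(hist) {
  n <- length(hist$counts)
  total <- sum(hist$counts)
  best <- -Inf
  best_edge <- NA_real_
  for (k in seq_len(n - 1)) {
    c0 <- hist$counts[1:k]
    c1 <- hist$counts[(k + 1):n]
    w0 <- sum(c0); w1 <- sum(c1)
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(c0 * hist$mids[1:k]) / w0
    mu1 <- sum(c1 * hist$mids[(k + 1):n]) / w1
    bcv <- (w0 / total) * (w1 / total) * (mu0 - mu1)^2
    if (bcv > best) {
      best <- bcv
      best_edge <- hist$bin_edges[k + 1]
    }
  }
  best_edge
}

stage_levels_acc <- function() {
  c("stem_elongation", "heading_begins", "milky_waxy", "full_ripening")
}

# Per-variety index summary (wsi_m, wci_m) from the packaged published
# tables of one species.
summaries_for <- function(sp) {
  wsi <- reference_wsi_table(sp)
  wci <- reference_wci_table(sp)
  data.frame(variety = wsi$variety, wsi_m = wsi$wsi_m,
             wci_m = wci$wci_m[match(wsi$variety, wci$variety)])
}

# A peak table with no detected modes (forces the Otsu fallback).
empty_peaks_df <- function() {
  data.frame(temperature = numeric(0), height = numeric(0),
             prominence = numeric(0))
}

# Two-class frame sampled i.i.d. per pixel from the mixture (no spatial
# structure needed when only the histogram matters).
mixture_frame <- function(mu1, mu2, sd1 = 0.5, sd2 = 0.5, n1 = 2000,
                          n2 = 2000) {
  vec_frame(c(rnorm(n1, mu1, sd1), rnorm(n2, mu2, sd2)))
}
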