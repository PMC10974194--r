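test_that("histograms conserve pixel counts and span the data range", {
  f <- const_frame(20.0, 4, 5)
  h <- build_histogram(f)
  expect_equal(sum(h$counts), 20)
  expect_equal(sum(h$counts > 0), 1)

  f2 <- vec_frame(c(10, 10, 20, 20))
  h2 <- build_histogram(f2, bin_width = 1.0)
  expect_equal(sum(h2$counts > 0), 2)
  expect_equal(as.vector(h2$counts[h2$counts > 0]), c(2, 2))
  expect_equal(sum(h2$counts), 4)

  set.seed(3)
  f3 <- vec_frame(rnorm(5000, 22, 2))
  h3 <- build_histogram(f3)
  expect_equal(sum(h3$counts), 5000)
  expect_lte(h3$bin_edges[1], min(f3$pixels))
  expect_gt(h3$bin_edges[length(h3$bin_edges)], max(f3$pixels))
  d <- diff(h3$bin_edges)
  expect_true(all(abs(d - 0.1) < 1e-9))

  expect_error(build_histogram(thermal_frame(matrix(NA_real_, 2, 2))),
               "no valid pixels")
  expect_error(build_histogram(f, bin_width = 0), "positive")
})

test_that("peak detection recovers the modes of known mixtures", {
  set.seed(11)
  f <- mixture_frame(14.0, 18.4, n1 = 2000, n2 = 2000)
  pk <- detect_peaks(build_histogram(f, 0.1))
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$temperature[1] - 14.0), 0.2)
  expect_lt(abs(pk$temperature[2] - 18.4), 0.2)

  f1 <- vec_frame(rnorm(4000, 16, 0.5))
  pk1 <- detect_peaks(build_histogram(f1, 0.1))
  expect_equal(nrow(pk1), 1)
  expect_lt(abs(pk1$temperature - 16), 0.2)
})

test_that("a monotone histogram has its single peak at the boundary", {
  h <- structure(list(bin_edges = seq(10, 11, 0.1),
                      counts = 1:10,
                      mids = seq(10.05, 10.95, 0.1),
                      bin_width = 0.1), class = "temperature_histogram")
  pk <- detect_peaks(h, smoothing_window = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$temperature, 10.95)
})

test_that("mean-of-peaks threshold averages the two mode temperatures", {
  set.seed(21)
  f <- mixture_frame(14.0, 18.4, n1 = 3000, n2 = 3000)
  h <- build_histogram(f, 0.1)
  sel <- select_threshold(h)
  expect_equal(sel$method, "mean_of_peaks")
  expect_equal(sel$t_th, 16.2, tolerance = 0.02)

  # symmetric bimodal: threshold at the midpoint of the modes
  set.seed(22)
  fs <- mixture_frame(15, 19, n1 = 4000, n2 = 4000)
  sels <- select_threshold(build_histogram(fs, 0.1))
  expect_equal(sels$t_th, 17, tolerance = 0.1)

  # manual override always wins
  selm <- select_threshold(h, manual = 17.5)
  expect_equal(selm, list(t_th = 17.5, method = "manual"))
})

test_that("with more than two modes the two most prominent are used", {
  set.seed(33)
  f <- vec_frame(c(rnorm(3000, 14, 0.4), rnorm(3000, 18.4, 0.4),
                   rnorm(300, 22, 0.3)))
  h <- build_histogram(f, 0.1)
  pk <- detect_peaks(h, min_prominence = 0.01)
  expect_gte(nrow(pk), 3)
  sel <- select_threshold(h, pk)
  expect_equal(sel$method, "mean_of_peaks")
  expect_equal(sel$t_th, (14 + 18.4) / 2, tolerance = 0.2)
})

test_that("unimodal histograms fall back to the Otsu criterion, matching brute force", {
  set.seed(44)
  frames <- list(
    vec_frame(rnorm(5000, 20, 1.5)),
    vec_frame(rexp(5000, 1) + 15),
    vec_frame(c(rnorm(4000, 18, 2), rnorm(500, 23, 1))),
    vec_frame(runif(3000, 12, 28))
  )
  for (f in frames) {
    h <- build_histogram(f, 0.1)
    sel <- select_threshold(h, peaks = empty_peaks_df())
    expect_equal(sel$method, "otsu_fallback")
    expect_equal(sel$t_th, brute_force_otsu(h))
  }
})

test_that("a single-bin histogram has no defined threshold", {
  h <- build_histogram(const_frame(20))
  expect_error(select_threshold(h, peaks = empty_peaks_df()),
               "single bin")
})

test_that("pixel classification follows the threshold with ties labelled wheat", {
  f <- vec_frame(c(14, 14, 18, 18))
  seg <- classify_pixels(f, 16)
  expect_equal(seg$p_w, 2)
  expect_equal(seg$p_s, 2)
  expect_equal(seg$t_w_mean, 14)
  expect_equal(seg$t_s_mean, 18)

  tie <- classify_pixels(vec_frame(c(15, 16, 17)), 16)
  expect_equal(tie$p_w, 2)   # 16 == t_th -> wheat

  below <- classify_pixels(vec_frame(c(14, 15)), 20)
  expect_equal(below$p_s, 0)
  expect_true(is.na(below$t_s_mean))

  expect_error(classify_pixels(thermal_frame(matrix(NA_real_, 1, 2)), 16),
               "no valid pixels")
  expect_error(classify_pixels(f, Inf), "finite")
})

test_that("classification conserves counts and is monotone in the threshold", {
  set.seed(55)
  for (i in 1:5) {
    n <- sample(50:500, 1)
    v <- rnorm(n, 20, 3)
    v[sample(n, 5)] <- NA
    f <- vec_frame(v)
    ths <- sort(runif(4, 12, 28))
    pw <- vapply(ths, function(t) classify_pixels(f, t)$p_w, numeric(1))
    seg <- classify_pixels(f, ths[1])
    expect_equal(seg$p_w + seg$p_s, n_valid_pixels(f))
    expect_true(all(diff(pw) >= 0))
    if (seg$p_w > 0 && seg$p_s > 0) {
      expect_lt(seg$t_w_mean, seg$t_th)
      expect_gt(seg$t_s_mean, seg$t_th)
    }
  }
})

test_that("mean-of-peaks segmentation recovers the ground-truth mask", {
  g <- generate_frame(25, 20, soil_sd = 0.5, wheat_sd = 0.5,
                      cover_fraction = 0.7, seed = 66)
  seg <- segment_frame(g$frame)
  expect_equal(seg$method, "mean_of_peaks")
  miss <- mean(seg$mask != g$truth$mask, na.rm = TRUE)
  expect_lt(miss, 0.01)
  expect_lt(abs(compute_wci(seg$p_w, seg$p_s) - g$truth$cover), 0.02)
  expect_lt(abs(seg$t_w_mean - 20), 0.1)
})
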