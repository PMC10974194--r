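test_that("least-squares fits recover exact lines and reject degeneracy", {
  x <- 1:6
  expect_equal(linear_fit(x, 2 * x + 1), c(a = 1, b = 2))
  expect_equal(linear_fit(x, rep(3.5, 6)), c(a = 3.5, b = 0))
  expect_error(linear_fit(rep(2, 5), 1:5), "constant")
  expect_error(linear_fit(1:3, 1:4), "equal length")
})

test_that("published durum WSI_m-yield pairing gives the frozen fit and R", {
  wsi <- reference_wsi_table("durum")$wsi_m
  y <- reference_yield_table("durum")$yield_t_ha
  fit <- linear_fit(wsi, y)
  # frozen from direct cov/var arithmetic on the printed tables
  expect_equal(fit[["b"]], 11.3333, tolerance = 1e-4)
  expect_equal(fit[["a"]], -0.1911, tolerance = 1e-3)
  expect_equal(pearson_r(wsi, y), 0.9273, tolerance = 1e-4)
})

test_that("Pearson R is invariant under positive affine transforms", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    r <- pearson_r(x, y)
    expect_equal(pearson_r(2.3 * x + 7, 0.4 * y - 2), r)
  }
  expect_equal(pearson_r(1:8, 3 * (1:8) + 2), 1)
  expect_error(pearson_r(1:5, rep(1, 5)), "constant")
})

test_that("t-test significance follows the Student-t tail and bins", {
  s0 <- correlation_significance(0, 9)
  expect_equal(s0$t_stat, 0)
  expect_equal(s0$p_two_tailed, 1)
  expect_equal(s0$significance_bin, "N.S.")
  expect_equal(s0$df, 7)

  wsi <- reference_wsi_table("durum")$wsi_m
  y <- reference_yield_table("durum")$yield_t_ha
  s <- correlation_significance(pearson_r(wsi, y), 9)
  expect_lt(s$p_two_tailed, 0.001)
  expect_equal(s$significance_bin, "<0.001")
  # cross-check against the stats implementation of the same test
  expect_equal(s$p_two_tailed, cor.test(wsi, y)$p.value)

  expect_warning(s1 <- correlation_significance(1, 5), "degenerate")
  expect_equal(s1$p_two_tailed, 0)
  expect_error(correlation_significance(0.5, 2), "at least 3")
})

test_that("significance bins are monotone in p", {
  ps <- c(1e-5, 0.0009, 0.003, 0.008, 0.02, 0.04, 0.07, 0.5)
  bins <- significance_bin(ps)
  expect_equal(bins, c("<0.001", "<0.001", "<0.005", "<0.01", "<0.025",
                       "<0.05", "N.S.", "N.S."))
  lvl <- c("<0.001", "<0.005", "<0.01", "<0.025", "<0.05", "N.S.")
  expect_true(all(diff(match(bins, lvl)) >= 0))
})

test_that("exact permutation p validates the t-based inference", {
  # the stress-index/yield pairing: t approximation good to Monte-Carlo-level
  wsi <- reference_wsi_table("durum")$wsi_m
  y <- reference_yield_table("durum")$yield_t_ha
  pt_ <- correlation_significance(pearson_r(wsi, y), 9)$p_two_tailed
  pp <- permutation_pvalue(wsi, y)
  expect_true(pp$exact)
  expect_lt(abs(pt_ - pp$p), 0.005)
  # across every index x component pairing, the two tests reach the same
  # decision at the 0.05 level
  for (sp in c("durum", "common")) {
    summ <- summaries_for(sp)
    yt <- reference_yield_table(sp)
    for (ix in c("wsi_m", "wci_m"))
      for (tg in c("yield_t_ha", "culms_m2", "spikes_m2", "biomass_t_ha")) {
        x <- summ[[ix]]
        yy <- yt[[tg]][match(summ$variety, yt$variety)]
        p_t <- correlation_significance(pearson_r(x, yy), 9)$p_two_tailed
        p_perm <- permutation_pvalue(x, yy)$p
        expect_equal(p_t < 0.05, p_perm < 0.05)
      }
  }
})

test_that("sampled permutation branch matches the exact one within MC error", {
  set.seed(20)
  x <- rnorm(12); y <- x + rnorm(12, sd = 2)
  ps <- permutation_pvalue(x, y, n_perm = 20000, seed = 4)
  expect_false(ps$exact)
  pt_ <- correlation_significance(pearson_r(x, y), 12)$p_two_tailed
  expect_lt(abs(ps$p - pt_), 4 * sqrt(pt_ * (1 - pt_) / 20000) + 0.01)
})

test_that("the correlation suite excludes modern varieties without touching the rest", {
  summ <- data.frame(variety = reference_wsi_table("durum")$variety,
                     wsi_m = reference_wsi_table("durum")$wsi_m)
  yt <- reference_yield_table("durum")
  all9 <- run_correlation_suite(summ, yt, targets = "yield")
  excl <- run_correlation_suite(summ, yt, targets = "yield",
                                exclude_modern = TRUE)
  expect_equal(all9$n, 9)
  expect_equal(excl$n, 7)
  expect_equal(excl$df, 5)
  expect_equal(excl$excluded, "PG+SV")
  # remaining varieties carry identical values: recompute by hand
  keep <- !yt$is_modern
  expect_equal(excl$r, pearson_r(summ$wsi_m[keep], yt$yield_t_ha[keep]))

  bad <- summ; bad$variety[1] <- "ZZ"
  expect_error(run_correlation_suite(bad, yt), "align")
  idx <- match(c("SC", "MZ", "PG", "SV"), summ$variety)
  expect_error(run_correlation_suite(summ[idx, ],
                                     yt[match(summ$variety[idx], yt$variety), ],
                                     exclude_modern = TRUE), "fewer than 3")
})
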