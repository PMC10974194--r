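test_that("WSI follows its defining ratio and domain restrictions", {
  expect_equal(compute_wsi(20, 16), 0.20)
  # equal canopy and soil temperature: index 0, but outside T_S > T_W
  expect_warning(w0 <- compute_wsi(17.3, 17.3), "regime")
  expect_equal(w0, 0, tolerance = 1e-12)
  expect_error(compute_wsi(-1, 5), "positive")
  expect_error(compute_wsi(0, 5), "positive")
  expect_error(compute_wsi(20, -2), "positive")
  expect_warning(compute_wsi(16, 20), "regime")
})

test_that("WSI lies in (0,1) on the valid regime and is monotone in T_W", {
  set.seed(8)
  for (i in 1:20) {
    t_s <- runif(1, 10, 35)
    t_w <- sort(runif(5, 0.1, t_s - 1e-6))
    w <- compute_wsi(rep(t_s, 5), t_w)
    expect_true(all(w > 0 & w < 1))
    expect_true(all(diff(w) < 0))   # warmer canopy -> lower index
  }
})

test_that("WCI is the wheat pixel fraction with exact complement", {
  expect_equal(compute_wci(930, 70), 0.93)
  expect_equal(compute_wci(0, 500), 0)
  expect_equal(compute_wci(61, 39), 0.61)
  expect_error(compute_wci(0, 0), "no classified pixels")
  set.seed(9)
  for (i in 1:10) {
    pw <- sample(0:500, 1); ps <- sample(1:500, 1)
    expect_identical(compute_wci(pw, ps) + compute_wci(ps, pw), 1)
  }
})

test_that("full pipeline WSI matches the ground-truth class means", {
  g <- generate_frame(25, 20, soil_sd = 0.5, wheat_sd = 0.5,
                      cover_fraction = 0.7, seed = 14)
  seg <- segment_frame(g$frame)
  wsi <- compute_wsi(seg$t_s_mean, seg$t_w_mean)
  expect_lt(abs(wsi - 0.20), 0.005)
  expect_lt(abs(wsi - compute_wsi(g$truth$t_s, g$truth$t_w)), 0.005)
})

test_that("row and column means reproduce the published aggregation rule", {
  expect_equal(mean(c(0.21, 0.31, 0.27, 0.21)), 0.25)
  se_durum <- c(0.21, 0.16, 0.18, 0.14, 0.18, 0.15, 0.14, 0.23, 0.24)
  expect_equal(round_half_up(mean(se_durum)), 0.18)
})

test_that("aggregation pools frames into cells, rows and columns", {
  rec <- expand.grid(variety = c("A", "B"), stage = stages <- c(
    "stem_elongation", "heading_begins", "milky_waxy", "full_ripening"),
    rep = 1:3, stringsAsFactors = FALSE)
  rec$species <- "durum"
  set.seed(10)
  rec$wsi <- runif(nrow(rec), 0.1, 0.3)
  rec$wci <- ifelse(rec$stage == "stem_elongation",
                    runif(nrow(rec), 0.6, 0.95), NA)
  tab <- aggregate_indices(rec)$durum

  cellA <- mean(rec$wsi[rec$variety == "A" & rec$stage == "heading_begins"])
  expect_equal(tab$stage_wsi$heading_begins[tab$stage_wsi$variety == "A"],
               cellA)
  rowA <- mean(vapply(stages, function(s)
    mean(rec$wsi[rec$variety == "A" & rec$stage == s]), numeric(1)))
  expect_equal(tab$wsi_m$wsi_m[tab$wsi_m$variety == "A"], rowA)
  # grand-mean consistency: rows and columns average to the same value
  expect_equal(mean(tab$wsi_m$wsi_m), mean(tab$pp_wsi_m$pp_wsi_m))
  # WCI aggregated over stem-elongation frames only
  wciA <- rec$wci[rec$variety == "A" & rec$stage == "stem_elongation"]
  expect_equal(tab$wci$wci_m[tab$wci$variety == "A"], mean(wciA))
  expect_equal(tab$wci$wci_se[tab$wci$variety == "A"],
               sd(wciA) / sqrt(3))
  expect_equal(tab$wci$n[tab$wci$variety == "A"], 3)
})

test_that("a single record propagates to every mean", {
  rec <- data.frame(species = "durum", variety = "SC",
                    stage = "stem_elongation", wsi = 0.21, wci = 0.93)
  tab <- aggregate_indices(rec)$durum
  expect_equal(tab$wsi_m$wsi_m, 0.21)
  expect_equal(tab$pp_wsi_m$pp_wsi_m, 0.21)
  expect_equal(tab$wci$wci_m, 0.93)
})

test_that("empty variety x stage cells are flagged and excluded from means", {
  rec <- data.frame(
    species = "durum",
    variety = c("A", "A", "B"),
    stage = c("stem_elongation", "heading_begins", "stem_elongation"),
    wsi = c(0.2, 0.3, 0.1), wci = NA_real_)
  expect_warning(tabs <- aggregate_indices(rec), "empty")
  tab <- tabs$durum
  expect_true(is.na(
    tab$stage_wsi$heading_begins[tab$stage_wsi$variety == "B"]))
  expect_equal(tab$pp_wsi_m$pp_wsi_m[tab$pp_wsi_m$stage == "heading_begins"],
               0.3)
})

test_that("frames lacking a temperature class yield NA WSI with a warning", {
  seg <- data.frame(species = "durum", variety = "SC",
                    stage = "stem_elongation",
                    p_w = c(100, 0), p_s = c(50, 150),
                    t_w_mean = c(20, NA), t_s_mean = c(25, 25))
  expect_warning(rec <- index_records(seg), "without both")
  expect_equal(rec$wsi[1], 0.2)
  expect_true(is.na(rec$wsi[2]))
  expect_equal(rec$wci, c(100, 0) / c(150, 150))
})

test_that("report rounding is half away from zero at two decimals", {
  expect_equal(round_half_up(0.185), 0.19)
  expect_equal(round_half_up(0.205), 0.21)
  expect_equal(round_half_up(0.2849), 0.28)
  expect_equal(round_half_up(-0.185), -0.19)
})
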