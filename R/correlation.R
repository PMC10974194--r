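# Index-vs-yield correlation analysis: ordinary least squares y = a + b*x,
# Pearson R, and two-tailed significance via the t-test (non-directional
# hypotheses), with an exact/sampled permutation test as an independent
# check. Significance is reported in the discrete bins used in the study's
# figures. No multiple-testing correction is applied by default, matching
# the original analysis; p.adjust can be applied by the caller.

paper_p_bounds <- c(0.001, 0.005, 0.01, 0.025, 0.05)

#' Ordinary least-squares line fit
#'
#' @param x,y numeric vectors of equal length >= 2; `x` must not be
#'   constant.
#' @return Named numeric `c(a = intercept, b = slope)`.
#' @export
linear_fit <- function(x, y) {
  check_xy(x, y)
  if (stats::var(x) == 0)
    stop("degenerate fit: x is constant", call. = FALSE)
  co <- stats::coef(stats::lm(y ~ x))
  c(a = unname(co[1]), b = unname(co[2]))
}

#' Pearson product-moment correlation
#'
#' @inheritParams linear_fit
#' @return Pearson R in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  check_xy(x, y)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: constant vector", call. = FALSE)
  stats::cor(x, y)
}

check_xy <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2)
    stop("at least two observations required", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  invisible(TRUE)
}

#' Two-tailed significance of a Pearson correlation
#'
#' Student-t test of R under non-directional hypotheses:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom.
#' The significance bin is the smallest of the study's reporting bounds
#' (0.001, 0.005, 0.01, 0.025, 0.05) that exceeds p, or `"N.S."`.
#'
#' @param r Pearson correlation.
#' @param n sample size (>= 3).
#' @return List with `t_stat`, `df`, `p_two_tailed`, `significance_bin` and
#'   `degenerate` (TRUE when `|r| = 1`, for which p is exactly 0).
#' @export
correlation_significance <- function(r, n) {
  if (n < 3) stop("n must be at least 3", call. = FALSE)
  if (abs(r) > 1) stop("|r| cannot exceed 1", call. = FALSE)
  df <- n - 2
  if (abs(r) == 1) {
    warning("|r| = 1: degenerate (exactly collinear) correlation, p = 0",
            call. = FALSE)
    return(list(t_stat = Inf * sign(r), df = df, p_two_tailed = 0,
                significance_bin = significance_bin(0), degenerate = TRUE))
  }
  t_stat <- r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t_stat = t_stat, df = df, p_two_tailed = p,
       significance_bin = significance_bin(p), degenerate = FALSE)
}

#' Map a p-value to the study's reporting bin
#'
#' @param p two-tailed p-value.
#' @return `"<0.001"`, `"<0.005"`, `"<0.01"`, `"<0.025"`, `"<0.05"` or
#'   `"N.S."`; monotone in `p`.
#' @export
significance_bin <- function(p) {
  vapply(p, function(pi) {
    hit <- paper_p_bounds[pi < paper_p_bounds]
    if (length(hit)) paste0("<", format(hit[1], scientific = FALSE))
    else "N.S."
  }, character(1))
}

# All n! permutations of 1..n as an n!-row integer matrix (n <= 9 keeps this
# within ~26 MB). Used only by the permutation oracle.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_permutations(n - 1L)
  m <- nrow(p)
  out <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    q <- p
    q[q >= i] <- q[q >= i] + 1L
    out[((i - 1L) * m + 1L):(i * m), ] <- cbind(i, q)
  }
  out
}

#' Permutation test of a Pearson correlation
#'
#' Two-tailed permutation p-value of R: the proportion of permutations of
#' `y` whose |R| reaches the observed |R|. Exact (all `n!` orderings,
#' including the identity) for `n <= 9`; Monte-Carlo with `n_perm` sampled
#' permutations (plus-one corrected) otherwise. This is the model-free
#' check of the Student-t p-value.
#'
#' @inheritParams linear_fit
#' @param n_perm permutations to sample in the Monte-Carlo branch.
#' @param seed seed for the Monte-Carlo branch.
#' @return List with `p` and `exact` (logical).
#' @export
permutation_pvalue <- function(x, y, n_perm = 1e5, seed = NULL) {
  check_xy(x, y)
  n <- length(x)
  r_obs <- abs(pearson_r(x, y))
  xc <- x - mean(x)
  sx <- sqrt(sum(xc^2))
  r_of <- function(yp) {
    yc <- yp - mean(yp)
    sum(xc * yc) / (sx * sqrt(sum(yc^2)))
  }
  if (n <= 9) {
    pm <- all_permutations(n)
    yp <- matrix(y[pm], nrow(pm))
    ypc <- yp - rowMeans(yp)
    r_all <- as.vector(ypc %*% xc) / (sx * sqrt(rowSums(ypc^2)))
    list(p = mean(abs(r_all) >= r_obs - 1e-12), exact = TRUE)
  } else {
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm),
                 function(i) abs(r_of(y[sample.int(n)])) >= r_obs - 1e-12,
                 logical(1)))
    })
    list(p = (1 + hits) / (1 + n_perm), exact = FALSE)
  }
}

#' Correlate index summaries with yield components
#'
#' One ordinary least-squares fit and Pearson correlation per requested
#' index x yield-component pairing, with two-tailed t significance and the
#' study's reporting bin. Optionally excludes the modern cultivars before
#' fitting (they were bred for yield under different selection pressure
#' than the landraces and can dominate or mask a correlation).
#'
#' @param index_summary data.frame with a `variety` column and one column
#'   per index (e.g. `wsi_m`, `wci_m`).
#' @param yield_table a `yield_table` (see [read_yield_table()] /
#'   [reference_yield_table()]).
#' @param indices index columns to use.
#' @param targets yield components among `"yield"`, `"culms"`, `"spikes"`,
#'   `"biomass"`.
#' @param exclude_modern drop varieties flagged modern before fitting.
#' @return data.frame with one row per pairing: `index`, `target`, `n`,
#'   `a`, `b`, `r`, `t_stat`, `df`, `p_two_tailed`, `significance_bin`,
#'   `excluded`.
#' @export
run_correlation_suite <- function(index_summary, yield_table,
                                  indices = intersect(c("wsi_m", "wci_m"),
                                                      names(index_summary)),
                                  targets = c("yield", "culms", "spikes",
                                              "biomass"),
                                  exclude_modern = FALSE) {
  targets <- match.arg(targets, several.ok = TRUE)
  target_cols <- c(yield = "yield_t_ha", culms = "culms_m2",
                   spikes = "spikes_m2", biomass = "biomass_t_ha")
  merged <- merge(index_summary, yield_table, by = "variety")
  if (nrow(merged) < nrow(index_summary))
    stop("variety codes do not align between index and yield tables",
         call. = FALSE)
  excluded <- character(0)
  if (exclude_modern) {
    excluded <- merged$variety[merged$is_modern]
    merged <- merged[!merged$is_modern, , drop = FALSE]
  }
  if (nrow(merged) < 3)
    stop("fewer than 3 varieties remain after exclusion", call. = FALSE)
  rows <- list()
  for (ix in indices) for (tg in targets) {
    x <- merged[[ix]]
    y <- merged[[target_cols[tg]]]
    fit <- linear_fit(x, y)
    r <- pearson_r(x, y)
    sig <- correlation_significance(r, length(x))
    rows[[length(rows) + 1]] <- data.frame(
      index = ix, target = tg, n = length(x),
      a = fit[["a"]], b = fit[["b"]], r = r,
      t_stat = sig$t_stat, df = sig$df, p_two_tailed = sig$p_two_tailed,
      significance_bin = sig$significance_bin,
      excluded = paste(excluded, collapse = "+")
    )
  }
  do.call(rbind, rows)
}
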