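# Shared fixtures and independent oracles for the test suite.

# independent logistic curve (deliberately re-derived here, not calling
# package internals)
logistic_vals <- function(t_s, rate_h, K, n0) {
  e <- exp(rate_h * t_s / 3600)
  K * n0 * e / (K + n0 * (e - 1))
}

# experiment of exact (optionally noisy) logistic curves
make_logistic_experiment <- function(n_curves = 5, rate_h = 0.6, K = 0.8,
                                     n0 = 0.001, dt = 1200,
                                     t_total = 172800, noise_sd = 0,
                                     strain = "TST", condition = "with_TE",
                                     seed = NULL) {
  t_s <- seq(0, t_total, by = dt)
  if (!is.null(seed)) set.seed(seed)
  rates <- rep_len(rate_h, n_curves)
  curves <- lapply(seq_len(n_curves), function(i) {
    od <- logistic_vals(t_s, rates[i], K, n0)
    if (noise_sd > 0) od <- od + rnorm(length(t_s), 0, noise_sd)
    growth_curve(sprintf("A%d", i), "P1", t_s, od)
  })
  growth_experiment(strain, condition, curves)
}

# quick curve from raw OD values (times 0, 1200, 2400, ...)
make_curve <- function(ods, well = "A1", dt = 1200) {
  growth_curve(well, "P1", seq(0, by = dt, length.out = length(ods)), ods)
}

# linear-interpolation percentile, fraction (n - 1) q, written directly
# from the definition as an oracle for the package's convention
pctl_oracle <- function(x, q) {
  s <- sort(x)
  h <- (length(s) - 1) * q
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

# long-format data frame for IO tests
make_long_df <- function(strains = c("S1", "S2"),
                         conditions = c("with_TE", "without_TE"),
                         wells = c("A1", "A2", "A3"),
                         times = c(0, 1200, 2400, 3600)) {
  grid <- expand.grid(strain = strains, condition = conditions,
                      well = wells, time_s = times,
                      stringsAsFactors = FALSE)
  grid$plate <- "P1"
  grid$od <- 0.1 + grid$time_s / 36000 +
    0.001 * as.integer(factor(grid$well))
  grid[, c("strain", "condition", "plate", "well", "time_s", "od")]
}
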