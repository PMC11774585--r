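test_that("windowed yield is the 98th percentile of in-window ODs", {
  cv <- make_curve(rep(0.8, 10))
  expect_equal(yield_of_curve(cv, c(0, 1e6)), 0.8)
  # whole-curve window reproduces the preliminary yield
  set.seed(2)
  cv2 <- make_curve(runif(30))
  expect_equal(yield_of_curve(cv2, range(cv2$times)),
               preliminary_yield(cv2))
  cv3 <- make_curve(c(0.5, 0.6, 0.7))
  expect_equal(yield_of_curve(cv3, range(cv3$times)), 0.696)
  expect_warning(y <- yield_of_curve(cv3, c(0, 100)), "skipped")
  expect_true(is.na(y))
})

test_that("yield objective composes CoV and mean r^2 as defined", {
  # flat identical curves: CoV = 0 and zero-variance OD counts r^2 = 0
  flat <- growth_experiment("S", "with_TE", lapply(1:3, function(i)
    make_curve(rep(0.5, 5), well = sprintf("A%d", i))))
  expect_equal(yield_objective(flat, c(0, 1e6)), 0)
  # strictly linear curves: mean r^2 = 1, objective equals the CoV of the
  # in-window yields
  lin <- growth_experiment("S", "with_TE", lapply(1:3, function(i)
    make_curve((1:5) * 0.1 * i, well = sprintf("A%d", i))))
  ys <- vapply(lin$curves, function(cv) pctl_oracle(cv$ods, 0.98),
               numeric(1))
  expect_equal(yield_objective(lin, c(0, 1e6)),
               sd(ys) / mean(ys))
  # direct-formula oracle on three irregular curves and a short window
  set.seed(5)
  odm <- matrix(runif(15, 0.2, 1), nrow = 3)
  exp3 <- growth_experiment("S", "with_TE", lapply(1:3, function(i)
    make_curve(odm[i, ], well = sprintf("A%d", i))))
  win <- c(1200, 3600) # points 2..4
  yo <- vapply(1:3, function(i) pctl_oracle(odm[i, 2:4], 0.98), numeric(1))
  r2o <- vapply(1:3, function(i) cor(1:3, odm[i, 2:4])^2, numeric(1))
  expect_equal(yield_objective(exp3, win),
               (sd(yo) / mean(yo)) * mean(r2o))
  # fewer than two curves with two in-window points: infeasible
  expect_equal(yield_objective(exp3, c(0, 100)), Inf)
})

test_that("logistic fit recovers rates on clean, exponential and flat data", {
  t_s <- seq(0, 172800, by = 1200)
  # noise-free logistic: rate to 0.1%, r^2 essentially 1
  cv <- make_curve(logistic_vals(t_s, 0.6, 0.8, 0.001))
  cv$times <- t_s
  fit <- fit_growth_rate(cv, c(0.008, 0.4))
  expect_equal(fit$fit_type, "logistic")
  expect_lt(abs(fit$rate - 0.6) / 0.6, 0.001)
  expect_gte(fit$r_squared, 0.9999)
  # pure exponential data: the K cap keeps the logistic in its
  # exponential limit and the rate matches the log-space slope
  ode <- 0.001 * exp(0.5 * t_s / 3600)
  cve <- growth_curve("A1", "P1", t_s, ode)
  fite <- fit_growth_rate(cve, c(0.005, 0.5))
  sel <- ode >= 0.005 & ode <= 0.5
  slope <- coef(lm(log(ode[sel]) ~ I(t_s[sel] / 3600)))[[2]]
  expect_lt(abs(fite$rate - slope) / slope, 0.001)
  # constant segment: logistic unidentifiable, fallback reports slope ~ 0
  cvf <- make_curve(rep(0.3, 20))
  fitf <- fit_growth_rate(cvf, c(0.2, 0.4))
  expect_equal(fitf$fit_type, "exponential_fallback")
  expect_equal(fitf$rate, 0)
  # too few points in window (entirely above the curve)
  expect_warning(r <- fit_growth_rate(cv, c(0.9, 1.0)), "skipped")
  expect_null(r)
})

test_that("rate objective composes CoV and mean badness of fit", {
  t_s <- seq(0, 172800, by = 1200)
  # identical curves: CoV 0 regardless of fit quality
  same <- growth_experiment("S", "with_TE", lapply(1:3, function(i) {
    growth_curve(sprintf("A%d", i), "P1", t_s,
                 logistic_vals(t_s, 0.5, 0.7, 0.001))
  }))
  expect_equal(rate_objective(same, c(0.007, 0.35)), 0)
  # three curves with different rates: match hand-composed value
  rates <- c(0.4, 0.5, 0.6)
  mix <- growth_experiment("S", "with_TE", lapply(1:3, function(i) {
    growth_curve(sprintf("A%d", i), "P1", t_s,
                 logistic_vals(t_s, rates[i], 0.7, 0.001))
  }))
  fits <- lapply(mix$curves, fit_growth_rate, interval = c(0.007, 0.35))
  rr <- vapply(fits, `[[`, numeric(1), "rate")
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  expect_equal(rate_objective(mix, c(0.007, 0.35)),
               (sd(rr) / mean(rr)) * mean(1 - r2))
  expect_equal(rate_objective(mix, c(0.71, 0.9)), Inf) # too few points
})

test_that("selected windows satisfy their constraints", {
  set.seed(14)
  ex <- make_logistic_experiment(n_curves = 6, noise_sd = 0.004, seed = 14)
  yw <- select_yield_interval(ex, grid_steps = 12)
  expect_gte(yw$interval[1], yw$min_start)
  expect_gte(yw$interval[1], 0.5 * yw$interval[2])
  expect_lte(yw$interval[1], 0.9 * yw$interval[2])
  expect_lte(yw$interval[2], 172800)
  expect_lte(yw$objective_value, yw$grid_objective) # finisher never worse

  ys <- vapply(ex$curves, yield_of_curve, numeric(1),
               interval = yw$interval)
  my <- median(ys)
  rw <- select_rate_interval(ex, my, grid_steps = 12)
  expect_gte(rw$interval[1], 0.001 * my * (1 - 1e-9))
  expect_lte(rw$interval[1], 0.1 * my * (1 + 1e-9))
  expect_lte(rw$interval[2], my * (1 + 1e-9))
  span <- log10(rw$interval[2] / rw$interval[1])
  expect_gte(span, 0.7 - 1e-9)
  expect_lte(span, 3 + 1e-9)
  expect_lte(rw$objective_value, rw$grid_objective)
})

test_that("identical saturating curves put the yield window in the plateau", {
  ex <- make_logistic_experiment(n_curves = 4)
  yw <- select_yield_interval(ex, grid_steps = 15)
  expect_equal(yw$objective_value, 0)
  # the window sits where growth has stagnated: all in-window ODs are
  # within 1% of the carrying capacity
  cv <- ex$curves[[1]]
  sel <- cv$times >= yw$interval[1] & cv$times <= yw$interval[2]
  expect_true(all(cv$ods[sel] > 0.99 * 0.8))
})

test_that("characteristics are invariant to time shifts and scale with OD", {
  set.seed(31)
  ex <- make_logistic_experiment(n_curves = 5, noise_sd = 0.003, seed = 31)
  ch <- experiment_characteristics(ex, grid_steps = 10)
  # time shift by 2 h
  ex_sh <- ex
  ex_sh$curves <- lapply(ex$curves, function(cv) {
    cv$times <- cv$times + 7200
    cv
  })
  ch_sh <- experiment_characteristics(ex_sh, grid_steps = 10)
  expect_equal(ch_sh$yield_window$interval,
               ch$yield_window$interval + 7200, tolerance = 1e-8)
  expect_equal(ch_sh$table$yield, ch$table$yield, tolerance = 1e-10)
  expect_equal(ch_sh$table$growth_rate_per_h, ch$table$growth_rate_per_h,
               tolerance = 1e-6)
  # OD rescale by 3: yields scale, rates and CoVs unchanged
  ex_sc <- ex
  ex_sc$curves <- lapply(ex$curves, function(cv) {
    cv$ods <- cv$ods * 3
    cv
  })
  ch_sc <- experiment_characteristics(ex_sc, grid_steps = 10)
  expect_equal(ch_sc$table$yield, 3 * ch$table$yield, tolerance = 1e-10)
  expect_equal(ch_sc$table$growth_rate_per_h, ch$table$growth_rate_per_h,
               tolerance = 1e-6)
  cvy <- function(tb) sd(tb$yield) / mean(tb$yield)
  expect_equal(cvy(ch_sc$table), cvy(ch$table), tolerance = 1e-10)
})
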