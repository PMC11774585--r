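test_that("baseline is the median of per-curve minima", {
  mk <- function(mins) {
    curves <- lapply(seq_along(mins), function(i)
      make_curve(mins[i] + c(0, 0.1, 0.3, 0.5), well = sprintf("A%d", i)))
    growth_experiment("S1", "with_TE", curves)
  }
  expect_equal(compute_baseline(mk(c(0.01, 0.02, 0.03))), 0.02)
  expect_equal(compute_baseline(mk(0.05)), 0.05)
  expect_equal(compute_baseline(mk(c(0.01, 0.03))), 0.02)
  shifted <- subtract_baseline(mk(c(0.01, 0.02, 0.03)))
  expect_equal(shifted$baseline_od, 0.02)
  expect_equal(min(shifted$curves[[2]]$ods), 0)
})

test_that("trimming starts curves at their first local minimum", {
  expect_equal(trim_to_first_local_minimum(
    make_curve(c(0.1, 0.2, 0.3, 0.4)))$ods, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(trim_to_first_local_minimum(
    make_curve(c(0.5, 0.2, 0.3, 0.6)))$ods, c(0.2, 0.3, 0.6))
  # plateau of the minimum: trimming keeps the plateau's first point,
  # matching an exhaustive scan of the definition
  expect_equal(trim_to_first_local_minimum(
    make_curve(c(0.5, 0.2, 0.2, 0.3)))$ods, c(0.2, 0.2, 0.3))
  # idempotence over random wiggly curves
  set.seed(11)
  for (i in 1:25) {
    cv <- make_curve(abs(cumsum(rnorm(12))) + 0.05)
    t1 <- trim_to_first_local_minimum(cv)
    expect_identical(trim_to_first_local_minimum(t1), t1)
  }
  # too few surviving points marks the curve unusable
  cv <- make_curve(c(0.5, 0.4, 0.3, 0.25, 0.2))
  tr <- trim_to_first_local_minimum(cv)
  expect_true(tr$excluded)
  expect_equal(tr$exclusion_reason, "unusable")
})

test_that("median filter smooths spikes, preserves constants and monotone series", {
  expect_equal(median_filter(rep(0.3, 10)), rep(0.3, 10))
  expect_equal(median_filter(c(0, 0, 10, 0, 0))[3], 0)
  # shrinking-window sliding-median oracle
  med_oracle <- function(x, w) {
    h <- (w - 1) %/% 2
    vapply(seq_along(x), function(i) {
      k <- min(h, i - 1, length(x) - i)
      median(x[(i - k):(i + k)])
    }, numeric(1))
  }
  set.seed(3)
  for (w in c(3, 5, 7)) {
    x <- rnorm(20)
    expect_equal(median_filter(x, w), med_oracle(x, w))
    xm <- sort(x)
    expect_equal(median_filter(xm, w), xm) # monotone unchanged
  }
  expect_error(median_filter(1:5, window = 4), "odd")
})

test_that("preliminary yield follows the linear-interpolation percentile", {
  expect_equal(preliminary_yield(make_curve(rep(0.7, 50))), 0.7)
  expect_equal(preliminary_yield(make_curve(1:100)), 98.02)
  expect_equal(preliminary_yield(make_curve(c(0, 1, 0.5))),
               pctl_oracle(c(0, 1, 0.5), 0.98))
  set.seed(8)
  x <- runif(37)
  expect_equal(preliminary_yield(make_curve(x)), pctl_oracle(x, 0.98))
})

test_that("well flags catch condensation and outlier yields", {
  # nine wells with preliminary yield ~1, one with ~2: 90th percentile of
  # prelim yields is 1.1, threshold 1.65, so only the high well is flagged
  curves <- c(lapply(1:9, function(i)
    make_curve(c(0.001, 0.5, 1.0, 1.0), well = sprintf("A%d", i))),
    list(make_curve(c(0.001, 1.0, 2.0, 2.0), well = "B1")))
  ex <- growth_experiment("S1", "with_TE", curves)
  fl <- flag_wells(ex)
  expect_equal(fl$well_id[fl$outlier_yield], "B1")
  expect_false(any(fl$condensation))

  # identical wells: nothing flagged
  ex2 <- growth_experiment("S1", "with_TE", lapply(1:5, function(i)
    make_curve(c(0.001, 0.5, 1, 1), well = sprintf("A%d", i))))
  expect_false(any(unlist(flag_wells(ex2)[, c("condensation",
                                              "outlier_yield")])))

  # minimum OD above 0.01 after baseline subtraction: condensation flag
  curves3 <- c(lapply(1:4, function(i)
    make_curve(c(0, 0.5, 1, 1), well = sprintf("A%d", i))),
    list(make_curve(c(0.02, 0.5, 1, 1), well = "B1")))
  fl3 <- flag_wells(growth_experiment("S1", "with_TE", curves3))
  expect_equal(fl3$well_id[fl3$condensation], "B1")
  expect_error(flag_wells(growth_experiment("S1", "with_TE",
                                            curves3[1])), "2")
})

test_that("constant OD offsets cancel out of the preprocessed experiment", {
  set.seed(21)
  base <- lapply(1:6, function(i)
    make_curve(0.08 + logistic_vals(seq(0, 86400, 1200), 0.5, 0.6, 0.001) +
                 rnorm(73, 0, 0.003), well = sprintf("A%d", i)))
  ex <- growth_experiment("S1", "with_TE", base)
  shiftex <- ex
  shiftex$curves <- lapply(ex$curves, function(cv) {
    cv$ods <- cv$ods + 0.37
    cv
  })
  p1 <- preprocess_experiment(ex)
  p2 <- preprocess_experiment(shiftex)
  expect_equal(p2$baseline_od, p1$baseline_od + 0.37)
  expect_equal(p1$flags, p2$flags)
  for (i in seq_along(p1$experiment$curves))
    expect_equal(p1$experiment$curves[[i]]$ods,
                 p2$experiment$curves[[i]]$ods)
})

test_that("auto-exclusion applies candidate flags with their reasons", {
  curves <- c(lapply(1:8, function(i)
    make_curve(c(0.001, 0.5, 1, 1), well = sprintf("A%d", i))),
    list(make_curve(c(0.05, 0.5, 1, 1), well = "B1"),        # condensation
         make_curve(c(0.001, 1.5, 2.5, 2.5), well = "B2")))  # outlier
  ex <- growth_experiment("S1", "with_TE", curves)
  pp <- preprocess_experiment(ex, auto_exclude = TRUE)
  exc <- Filter(function(cv) cv$excluded, pp$experiment$curves)
  reasons <- setNames(vapply(exc, `[[`, character(1), "exclusion_reason"),
                      vapply(exc, `[[`, character(1), "well_id"))
  expect_equal(reasons[["B1"]], "condensation")
  expect_equal(reasons[["B2"]], "outlier_yield")
  # default leaves flags as candidates only
  pp2 <- preprocess_experiment(ex)
  expect_false(any(vapply(pp2$experiment$curves, `[[`, logical(1),
                          "excluded")))
})
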