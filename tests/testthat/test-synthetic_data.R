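test_that("dose response hits its limits and midpoint", {
  expect_equal(dose_response(0, 0.2, 0.6, 1), 0.2)
  expect_equal(dose_response(1, 0.2, 0.6, 1), 0.4)
  expect_equal(dose_response(100, 0.2, 0.6, 1), 0.6, tolerance = 0.01)
  expect_true(all(diff(dose_response(seq(0, 50, 0.5), 0.1, 1, 2)) > 0))
  expect_error(dose_response(1, 0, 1, 0), "positive")
  expect_error(dose_response(-1, 0, 1, 1), "non-negative")
})

test_that("generation is deterministic and matched across conditions", {
  cfg <- synthetic_config(n_wells = 6, seed = 13)
  p1 <- generate_experiment_pair(cfg)
  p2 <- generate_experiment_pair(cfg)
  expect_identical(p1, p2)
  # matched pairs: identical contamination draws in both conditions
  tw <- p1$truth[p1$truth$condition == "with_TE", ]
  wo <- p1$truth[p1$truth$condition == "without_TE", ]
  expect_identical(tw$contamination, wo$contamination)
  # only the supplement differs, so with_TE grows at least as fast
  expect_true(all(tw$true_rate >= wo$true_rate))
})

test_that("noiseless configuration produces identical wells and zero CoV", {
  cfg <- synthetic_config(n_wells = 5, contam_log_sd = 0, od_noise_sd = 0,
                          p_condensation = 0, p_bio_contam = 0, seed = 2)
  pair <- generate_experiment_pair(cfg)
  ods <- vapply(pair$without_TE$curves, `[[`, numeric(145), "ods")
  expect_equal(max(apply(ods, 1, sd)), 0)
  tr <- pair$truth
  expect_equal(sd(tr$true_rate[tr$condition == "with_TE"]), 0)
})

test_that("supplementation reduces the true CoV for nearly every seed", {
  # strong supplement far above half-saturation, heavy-tailed contamination
  wins <- 0L
  for (s in 1:100) {
    cfg <- synthetic_config(n_wells = 30, supplement_conc = 50,
                            contam_log_sd = 1, seed = s)
    tr <- generate_experiment_pair(cfg)$truth
    cw <- with(tr[tr$condition == "with_TE", ],
               sd(true_rate) / mean(true_rate))
    co <- with(tr[tr$condition == "without_TE", ],
               sd(true_rate) / mean(true_rate))
    if (cw < co) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("a wider contamination distribution raises the without-TE CoV", {
  mean_cov <- function(sdlog) {
    covs <- vapply(1:40, function(s) {
      cfg <- synthetic_config(n_wells = 40, contam_log_sd = sdlog,
                              seed = 1000 + s)
      tr <- generate_experiment_pair(cfg)$truth
      with(tr[tr$condition == "without_TE", ],
           sd(true_yield) / mean(true_yield))
    }, numeric(1))
    mean(covs)
  }
  levels <- vapply(c(0.3, 0.8, 1.3), mean_cov, numeric(1))
  expect_true(all(diff(levels) > 0))
})

test_that("artifact wells carry the configured signatures", {
  cfg <- synthetic_config(n_wells = 40, p_condensation = 0.5,
                          p_bio_contam = 0.5, od_noise_sd = 0, seed = 5)
  pair <- generate_experiment_pair(cfg)
  tr <- pair$truth[pair$truth$condition == "with_TE", ]
  expect_gt(sum(tr$condensation), 0)
  expect_gt(sum(tr$bio_contam), 0)
  # condensation wells start elevated above baseline + inoculum
  i_c <- which(tr$condensation)[1]
  i_n <- which(!tr$condensation & !tr$bio_contam)[1]
  expect_gt(pair$with_TE$curves[[i_c]]$ods[1],
            pair$with_TE$curves[[i_n]]$ods[1] + 0.02)
  # biologically contaminated wells reach higher yields
  i_b <- which(tr$bio_contam & !tr$condensation)[1]
  expect_gt(max(pair$with_TE$curves[[i_b]]$ods),
            max(pair$with_TE$curves[[i_n]]$ods) * 1.5)
})

test_that("full pipeline recovers the configured rate and yield without noise", {
  cfg <- synthetic_config(n_wells = 5, rate_min = 0.6, rate_max = 0.6,
                          yield_min = 0.8, yield_max = 0.8,
                          contam_log_sd = 0, od_noise_sd = 0,
                          p_condensation = 0, p_bio_contam = 0, seed = 3)
  pair <- generate_experiment_pair(cfg)
  prep <- preprocess_experiment(pair$without_TE, auto_exclude = TRUE)
  ch <- experiment_characteristics(prep$experiment, grid_steps = 12)
  tb <- ch$table
  # identical wells: CoVs at numerical zero
  expect_lt(sd(tb$yield) / mean(tb$yield), 1e-6)
  expect_lt(sd(tb$growth_rate_per_h) / mean(tb$growth_rate_per_h), 1e-6)
  # recovery within 1%: the baseline estimate absorbs the inoculum OD
  # (median of minima = baseline + N0), which bounds the attainable
  # accuracy at about N0 / OD_window
  expect_lt(abs(mean(tb$yield) - 0.8) / 0.8, 0.01)
  expect_lt(abs(mean(tb$growth_rate_per_h) - 0.6) / 0.6, 0.01)
})

test_that("element panel censors below-LOD values and keeps true folds", {
  panel <- generate_element_panel(seed = 3, lod = 0.05)
  al <- panel[panel$element == "Al", ]
  expect_true(all(al$below_lod))
  expect_true(all(is.na(al$concentration_ugL)))
  b <- panel[panel$element == "B", ]
  expect_false(any(b$below_lod))
  # with mild noise the sample/control median ratio sits near the true fold
  fold <- median(b$concentration_ugL[b$group == "sample"]) /
    median(b$concentration_ugL[b$group == "control"])
  expect_gt(fold, 2)
  # round-trip through the element-table CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_element_table(panel, path)
  back <- read_element_table(path)
  expect_equal(nrow(back), nrow(panel))
  expect_equal(sort(back$concentration_ugL),
               sort(panel$concentration_ugL[!panel$below_lod]),
               tolerance = 1e-6)
})
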