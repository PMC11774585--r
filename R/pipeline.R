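# End-to-end orchestration: preprocess -> windows -> characteristics ->
# variability statistics -> report, with deterministic seeding throughout.

#' Run the full growth-variability analysis
#'
#' Takes all experiments of a study (each strain in both conditions),
#' preprocesses them, selects analysis windows, computes per-well yield
#' and growth rate, and summarizes variability: per strain and measure the
#' CoVs, their ratio kappa and a mean-normalized permutation test; at
#' study level the median kappa with a two-sided Wilcoxon signed-rank test
#' on log kappa (separately for yield and growth rate, avoiding
#' pseudoreplication) and a permutation test for a correlation between
#' means and variabilities. Identical inputs, parameters and seed give
#' identical output.
#'
#' @param experiments List of [growth_experiment()]s, or the path of a
#'   canonical time-series CSV.
#' @param grid_steps Lattice size of the window searches (default 100).
#' @param n_permutations Permutations per test (default 10000).
#' @param alpha Significance level for the per-strain decisions
#'   (default 0.05, two-sided, uncorrected - the study-level claim rests
#'   on the single Wilcoxon test per measure).
#' @param seed Master seed; all permutation tests draw sub-seeds from it.
#' @param auto_exclude Automatically exclude flagged candidate wells
#'   (default `TRUE`; set `FALSE` to only report flags, mirroring a
#'   manual-review workflow).
#' @param condensation_threshold,outlier_factor,flag_percentile
#'   Preprocessing parameters, see [preprocess_experiment()].
#' @param percentile,prelim_fraction,start_end_ratio,lower_frac,span_decades,k_cap_factor,badness_transform
#'   Window/fit parameters, see [experiment_characteristics()].
#' @param out_dir If non-`NULL`, write the characteristics table, window
#'   report, flag table, strain summary (CSV) and study summary (JSON)
#'   there.
#' @return A `growth_study_report`: list with `characteristics`,
#'   `windows`, `flags`, `strain_summary`, `study_summary`,
#'   `skipped_strains` and `params`.
#' @export
run_analysis <- function(experiments, grid_steps = 100,
                         n_permutations = 10000, alpha = 0.05, seed = 1L,
                         auto_exclude = TRUE,
                         condensation_threshold = 0.01,
                         outlier_factor = 1.5, flag_percentile = 90,
                         percentile = 98, prelim_fraction = 0.7,
                         start_end_ratio = c(0.5, 0.9),
                         lower_frac = c(0.001, 0.1),
                         span_decades = c(0.7, 3), k_cap_factor = 1000,
                         badness_transform = "identity", out_dir = NULL) {
  if (is.character(experiments))
    experiments <- read_timeseries_table(experiments)
  stopifnot(is.list(experiments),
            all(vapply(experiments, inherits, logical(1),
                       "growth_experiment")))
  strains <- vapply(experiments, `[[`, character(1), "strain")
  conditions <- vapply(experiments, `[[`, character(1), "condition")
  complete <- intersect(strains[conditions == "with_TE"],
                        strains[conditions == "without_TE"])
  skipped <- setdiff(unique(strains), complete)
  if (length(skipped))
    warning("strain(s) present in only one condition, skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  complete <- sort(complete)
  seeds <- derive_seeds(seed, 2L * length(complete) + 2L)
  chars <- list()
  windows <- list()
  flags <- list()
  strain_rows <- list()
  for (si in seq_along(complete)) {
    st <- complete[si]
    per_cond <- list()
    for (cond in c("with_TE", "without_TE")) {
      exp_i <- experiments[[which(strains == st & conditions == cond)[1]]]
      prep <- preprocess_experiment(
        exp_i, condensation_threshold = condensation_threshold,
        outlier_factor = outlier_factor,
        yield_percentile = flag_percentile, auto_exclude = auto_exclude)
      ch <- experiment_characteristics(
        prep$experiment, grid_steps = grid_steps, percentile = percentile,
        prelim_fraction = prelim_fraction,
        start_end_ratio = start_end_ratio, lower_frac = lower_frac,
        span_decades = span_decades, k_cap_factor = k_cap_factor,
        badness_transform = badness_transform)
      per_cond[[cond]] <- ch$table
      chars[[paste(st, cond)]] <- ch$table
      fl <- prep$flags
      fl$strain <- st
      fl$condition <- cond
      flags[[paste(st, cond)]] <- fl
      windows[[paste(st, cond)]] <- data.frame(
        strain = st, condition = cond,
        window_type = c("yield", "rate"),
        start_or_lower = c(ch$yield_window$interval[1],
                           ch$rate_window$interval[1]),
        end_or_upper = c(ch$yield_window$interval[2],
                         ch$rate_window$interval[2]),
        objective = c(ch$yield_window$objective_value,
                      ch$rate_window$objective_value),
        n_curves_used = c(ch$yield_window$n_curves_used,
                          ch$rate_window$n_curves_used),
        stringsAsFactors = FALSE)
    }
    for (mi in 1:2) {
      measure <- c("yield", "growth_rate")[mi]
      col <- c("yield", "growth_rate_per_h")[mi]
      vw <- per_cond$with_TE[[col]]
      vw <- vw[!per_cond$with_TE$excluded & !is.na(vw)]
      vo <- per_cond$without_TE[[col]]
      vo <- vo[!per_cond$without_TE$excluded & !is.na(vo)]
      row <- data.frame(strain = st, measure = measure,
                        mean_with = NA_real_, mean_without = NA_real_,
                        cov_with = NA_real_, cov_without = NA_real_,
                        kappa = NA_real_,
                        p_permutation_one_sided = NA_real_,
                        p_permutation_two_sided = NA_real_,
                        significant = NA,
                        n_with = length(vw), n_without = length(vo),
                        stringsAsFactors = FALSE)
      if (length(vw) >= 2L && length(vo) >= 2L &&
          mean(vw) > 0 && mean(vo) > 0) {
        row$mean_with <- mean(vw)
        row$mean_without <- mean(vo)
        row$cov_with <- coefficient_of_variation(vw)
        row$cov_without <- coefficient_of_variation(vo)
        if (sd(vw) > 0 && sd(vo) > 0)
          row$kappa <- kappa_ratio(sd(vw), mean(vw), sd(vo), mean(vo))
        pt1 <- permutation_cov_test(vw, vo, n_permutations = n_permutations,
                                    sided = "one",
                                    seed = seeds[2L * si - 2L + mi])
        pt2 <- permutation_cov_test(vw, vo, n_permutations = n_permutations,
                                    sided = "two",
                                    seed = seeds[2L * si - 2L + mi])
        row$p_permutation_one_sided <- pt1$p.value
        row$p_permutation_two_sided <- pt2$p.value
        row$significant <- pt2$p.value < alpha
      }
      strain_rows[[paste(st, measure)]] <- row
    }
  }
  strain_summary <- do.call(rbind, strain_rows)
  rownames(strain_summary) <- NULL
  study_summary <- list()
  for (measure in c("yield", "growth_rate")) {
    sub <- strain_summary[strain_summary$measure == measure, ]
    ks <- sub$kappa[is.finite(sub$kappa) & sub$kappa > 0]
    wl <- if (length(ks) >= 2L) wilcoxon_log_kappa(ks)
          else list(median_kappa = if (length(ks)) median(ks) else NA_real_,
                    p.value = NA_real_, n_used = length(ks))
    ok <- complete.cases(sub[, c("mean_with", "mean_without",
                                 "cov_with", "cov_without")])
    means <- c(sub$mean_with[ok], sub$mean_without[ok])
    covs <- c(sub$cov_with[ok], sub$cov_without[ok])
    ct <- if (length(means) >= 3L && sd(means) > 0 && sd(covs) > 0)
      correlation_permutation_test(
        means, covs, n_permutations = n_permutations,
        seed = seeds[2L * length(complete) +
                       match(measure, c("yield", "growth_rate"))])
    else list(correlation = NA_real_, p.value = NA_real_)
    study_summary[[measure]] <- list(
      median_kappa = wl$median_kappa, p_wilcoxon = wl$p.value,
      n_strains = nrow(sub), n_kappa = length(ks),
      n_significant = sum(sub$significant, na.rm = TRUE),
      median_cov_pct = 100 * median(c(sub$cov_with, sub$cov_without),
                                    na.rm = TRUE),
      correlation_mean_cov = list(r = ct$correlation, p = ct$p.value))
  }
  ysub <- strain_summary[strain_summary$measure == "yield", ]
  study_summary$yield_fold_with_vs_without <-
    median(ysub$mean_with / ysub$mean_without, na.rm = TRUE)
  report <- structure(
    list(characteristics = do.call(rbind, chars),
         windows = do.call(rbind, windows),
         flags = do.call(rbind, flags),
         strain_summary = strain_summary,
         study_summary = study_summary,
         skipped_strains = skipped,
         params = list(grid_steps = grid_steps,
                       n_permutations = n_permutations, alpha = alpha,
                       seed = seed, auto_exclude = auto_exclude,
                       condensation_threshold = condensation_threshold,
                       outlier_factor = outlier_factor,
                       flag_percentile = flag_percentile,
                       percentile = percentile,
                       prelim_fraction = prelim_fraction,
                       start_end_ratio = start_end_ratio,
                       lower_frac = lower_frac,
                       span_decades = span_decades,
                       k_cap_factor = k_cap_factor,
                       badness_transform = badness_transform)),
    class = "growth_study_report")
  rownames(report$characteristics) <- NULL
  rownames(report$windows) <- NULL
  rownames(report$flags) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_characteristics_table(report$characteristics,
                                file.path(out_dir, "characteristics.csv"))
    write.csv(report$windows, file.path(out_dir, "windows.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(report$flags, file.path(out_dir, "flags.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(report$strain_summary,
              file.path(out_dir, "strain_summary.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      c(report$study_summary, list(params = report$params)),
      file.path(out_dir, "study_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.growth_study_report <- function(x, ...) {
  cat("<growth_study_report>\n")
  for (m in c("yield", "growth_rate")) {
    s <- x$study_summary[[m]]
    cat(sprintf(
      "  %-11s median kappa %.3f (Wilcoxon p = %.4g, %d strains, %d significant)\n",
      m, s$median_kappa, s$p_wilcoxon, s$n_strains, s$n_significant))
  }
  cat(sprintf("  yield fold with/without: %.2f\n",
              x$study_summary$yield_fold_with_vs_without))
  if (length(x$skipped_strains))
    cat("  skipped strains:", paste(x$skipped_strains, collapse = ", "),
        "\n")
  invisible(x)
}

#' Repeated generate-and-analyze calibration runs
#'
#' Generates `n_replicate_studies` independent synthetic studies and runs
#' the full analysis on each, collecting the study-level decisions - an
#' empirical check of type-I error (null configuration) or power
#' (effect configuration).
#'
#' @param n_replicate_studies Number of studies.
#' @param n_strains Strains per study (default 11).
#' @param config Base [synthetic_config()] for the generator.
#' @param seed Master seed.
#' @param alpha Study-level significance threshold (default 0.05).
#' @param ... Passed to [run_analysis()] (e.g. `grid_steps`,
#'   `n_permutations`).
#' @return Data frame with one row per study (`study, median_kappa_yield,
#'   p_wilcoxon_yield, reject_yield, median_kappa_rate, p_wilcoxon_rate,
#'   reject_rate`); the rejection rates are attached as attribute
#'   `"rejection_rates"`.
#' @export
run_simulation_study <- function(n_replicate_studies, n_strains = 11,
                                 config = synthetic_config(), seed = 1L,
                                 alpha = 0.05, ...) {
  stopifnot(n_replicate_studies >= 1)
  seeds <- derive_seeds(seed, n_replicate_studies)
  rows <- lapply(seq_len(n_replicate_studies), function(i) {
    study <- generate_study(n_strains = n_strains, config = config,
                            seed = seeds[i])
    rep <- run_analysis(study$experiments, seed = seeds[i], ...)
    sy <- rep$study_summary$yield
    sr <- rep$study_summary$growth_rate
    data.frame(study = i,
               median_kappa_yield = sy$median_kappa,
               p_wilcoxon_yield = sy$p_wilcoxon,
               reject_yield = isTRUE(sy$p_wilcoxon < alpha),
               median_kappa_rate = sr$median_kappa,
               p_wilcoxon_rate = sr$p_wilcoxon,
               reject_rate = isTRUE(sr$p_wilcoxon < alpha))
  })
  out <- do.call(rbind, rows)
  attr(out, "rejection_rates") <- c(yield = mean(out$reject_yield),
                                    growth_rate = mean(out$reject_rate))
  out
}
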