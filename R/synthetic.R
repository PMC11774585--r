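# Synthetic-data generator.
#
# Mechanism: each well carries a heavy-tailed (log-normal) trace-element
# contamination; the effective concentration (supplement + contamination)
# sets the well's growth rate and carrying capacity through a saturating
# dose-response. Because the slope of the dose-response falls with
# concentration, the same contamination spread produces more growth
# variability at zero supplement than at a supplemented working point -
# the error-propagation mechanism the analysis pipeline is built to
# detect. Measurement noise, a baseline OD offset, sporadic initial
# condensation and sporadic biologically contaminated high-yield wells are
# layered on top.

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the target study design: 80 replicate wells per
#' condition, OD sampled every 20 min for 48 h, inoculum OD 0.001 and a
#' medium baseline of 0.08. The dose-response/contamination defaults are
#' calibrated (by Monte-Carlo on the generator's closed-form truth, before
#' any growth curves are involved) so that the *true* per-well rate and
#' yield CoV is about 17% without supplement and the with/without CoV
#' ratio is about 2/3 - the variability scale and reduction observed in
#' trace-element supplementation experiments.
#'
#' Concentrations are in units of the dose-response half-saturation
#' (`half_sat_* = 1`): the median per-well contamination is 0.2 of
#' half-saturation and the supplement working point is 0.19 above it.
#'
#' @param n_wells Replicate wells per condition (default 80).
#' @param dt Sampling interval in seconds (default 1200 = 20 min).
#' @param t_total Total observation time in seconds (default 172800 = 48 h).
#' @param n0 Inoculum OD (default 0.001).
#' @param baseline Medium OD offset (default 0.08).
#' @param rate_min,rate_max Growth-rate range (per hour) spanned by the
#'   dose-response.
#' @param yield_min,yield_max Carrying-capacity (OD) range.
#' @param half_sat_rate,half_sat_yield Half-saturation concentrations.
#' @param supplement_conc Supplement concentration added in the
#'   `with_TE` condition (0 in `without_TE`).
#' @param contam_log_mean,contam_log_sd Log-normal parameters of the
#'   per-well contamination.
#' @param od_noise_sd Additive OD measurement noise (default 0.005).
#' @param p_condensation Probability of an initial-condensation well.
#' @param p_bio_contam Probability of a biologically contaminated
#'   high-yield well.
#' @param bio_contam_factor Carrying-capacity multiplier of such wells
#'   (> 1.5 so the outlier-yield filter can catch them).
#' @param seed Integer seed; every generator draw flows from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_wells = 80, dt = 1200, t_total = 172800,
                             n0 = 0.001, baseline = 0.08,
                             rate_min = 0.2, rate_max = 0.6,
                             yield_min = 0.2, yield_max = 0.6,
                             half_sat_rate = 1, half_sat_yield = 1,
                             supplement_conc = 0.19,
                             contam_log_mean = log(0.2),
                             contam_log_sd = 0.8,
                             od_noise_sd = 0.005,
                             p_condensation = 0.02,
                             p_bio_contam = 0.01,
                             bio_contam_factor = 2,
                             seed = 1L) {
  cfg <- list(n_wells = as.integer(n_wells), dt = dt, t_total = t_total,
              n0 = n0, baseline = baseline,
              rate_min = rate_min, rate_max = rate_max,
              yield_min = yield_min, yield_max = yield_max,
              half_sat_rate = half_sat_rate, half_sat_yield = half_sat_yield,
              supplement_conc = supplement_conc,
              contam_log_mean = contam_log_mean,
              contam_log_sd = contam_log_sd,
              od_noise_sd = od_noise_sd,
              p_condensation = p_condensation,
              p_bio_contam = p_bio_contam,
              bio_contam_factor = bio_contam_factor,
              seed = as.integer(seed))
  stopifnot(cfg$n_wells >= 1L, cfg$dt > 0, cfg$t_total > cfg$dt,
            cfg$n0 > 0, cfg$rate_min <= cfg$rate_max,
            cfg$yield_min <= cfg$yield_max,
            cfg$half_sat_rate > 0, cfg$half_sat_yield > 0,
            cfg$supplement_conc >= 0, cfg$contam_log_sd >= 0,
            cfg$od_noise_sd >= 0,
            cfg$p_condensation >= 0, cfg$p_condensation <= 1,
              cfg$p_bio_contam >= 0, cfg$p_bio_contam <= 1,
            cfg$bio_contam_factor > 1.5)
  structure(cfg, class = "synthetic_config")
}

#' Saturating dose-response
#'
#' `v_min + (v_max - v_min) * c / (c + half_sat)`: monotone increasing and
#' saturating, so its derivative - and with it the impact of concentration
#' variability - is largest at zero concentration.
#'
#' @param effective_conc Non-negative concentration(s).
#' @param v_min,v_max Response limits.
#' @param half_sat Half-saturation concentration (> 0).
#' @return Response value(s); `v_min` at 0, midpoint at `half_sat`,
#'   approaching `v_max` as the concentration grows.
#' @export
dose_response <- function(effective_conc, v_min, v_max, half_sat) {
  if (half_sat <= 0) stop("`half_sat` must be positive", call. = FALSE)
  if (any(effective_conc < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  v_min + (v_max - v_min) * effective_conc / (effective_conc + half_sat)
}

# logistic biomass curve; rate per hour, times in seconds
logistic_od <- function(t_s, rate_h, K, n0) {
  ert <- exp(rate_h * t_s / 3600)
  K * n0 * ert / (K + n0 * (ert - 1))
}

# deterministic sub-seeds derived from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  with_local_seed(as.integer(seed %% 2147483646L),
                  sample.int(2147483646L, n))
}

#' Generate a matched pair of synthetic experiments
#'
#' Draws one set of per-well contaminations and artifact assignments and
#' uses it for both conditions, so that the with/without comparison
#' isolates the supplement effect (a matched-pairs design). Per well,
#' effective concentration = supplement + contamination sets rate and
#' carrying capacity via [dose_response()]; the measured OD is baseline +
#' logistic growth + Gaussian noise, plus a decaying condensation bump in
#' condensation wells; biologically contaminated wells have their carrying
#' capacity multiplied by `bio_contam_factor`. Bit-identical output for
#' identical seeds.
#'
#' @param config A [synthetic_config()].
#' @param strain Strain label attached to both experiments.
#' @return List with `with_TE` and `without_TE` ([growth_experiment()]s)
#'   and `truth`: a data frame of per-well ground truth (`condition, well,
#'   contamination, true_rate, true_yield, condensation, bio_contam`).
#' @export
generate_experiment_pair <- function(config = synthetic_config(),
                                     strain = "SYN 1") {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_wells
  seeds <- derive_seeds(config$seed, 3)
  shared <- with_local_seed(seeds[1], {
    list(contam = rlnorm(n, config$contam_log_mean, config$contam_log_sd),
         condensation = runif(n) < config$p_condensation,
         bio = runif(n) < config$p_bio_contam,
         bump0 = runif(n, 0.03, 0.08),
         bump_tau = runif(n, 2, 4) * 3600)
  })
  times <- seq(0, config$t_total, by = config$dt)
  wells <- sprintf("%s%d", LETTERS[(seq_len(n) - 1L) %/% 12L + 1L],
                   (seq_len(n) - 1L) %% 12L + 1L)
  make_cond <- function(supplement, noise_seed, condition) {
    e <- supplement + shared$contam
    rate <- dose_response(e, config$rate_min, config$rate_max,
                          config$half_sat_rate)
    K <- dose_response(e, config$yield_min, config$yield_max,
                       config$half_sat_yield)
    K[shared$bio] <- K[shared$bio] * config$bio_contam_factor
    noise <- with_local_seed(noise_seed,
      matrix(rnorm(n * length(times), 0, config$od_noise_sd),
             nrow = n))
    curves <- lapply(seq_len(n), function(i) {
      od <- config$baseline + logistic_od(times, rate[i], K[i], config$n0)
      if (shared$condensation[i])
        od <- od + shared$bump0[i] * exp(-times / shared$bump_tau[i])
      od <- od + noise[i, ]
      growth_curve(well_id = wells[i],
                   plate_id = sprintf("P%d", (i - 1L) %/% 96L + 1L),
                   times = times, ods = od)
    })
    list(experiment = growth_experiment(strain, condition, curves),
         truth = data.frame(condition = condition, well = wells,
                            contamination = shared$contam,
                            true_rate = rate, true_yield = K,
                            condensation = shared$condensation,
                            bio_contam = shared$bio,
                            stringsAsFactors = FALSE))
  }
  w <- make_cond(config$supplement_conc, seeds[2], "with_TE")
  wo <- make_cond(0, seeds[3], "without_TE")
  list(with_TE = w$experiment, without_TE = wo$experiment,
       truth = rbind(w$truth, wo$truth))
}

#' Generate a multi-strain synthetic study
#'
#' Repeats [generate_experiment_pair()] for several strains, varying each
#' strain's growth-rate and yield scales by independent log-normal factors
#' (biological strain-to-strain differences) while keeping the
#' contamination mechanism identical. Since the dose-response limits are
#' scaled jointly, the *true* with/without CoV ratio is the same for every
#' strain.
#'
#' @param n_strains Number of strains (default 11).
#' @param config Base [synthetic_config()].
#' @param seed Master seed (default: the config's seed).
#' @param strain_sd Log-scale SD of the per-strain scale factors
#'   (default 0.15).
#' @return List with `experiments` (flat list of [growth_experiment()]s,
#'   two per strain) and `truth` (data frame with a `strain` column).
#' @export
generate_study <- function(n_strains = 11, config = synthetic_config(),
                           seed = config$seed, strain_sd = 0.15) {
  stopifnot(inherits(config, "synthetic_config"), n_strains >= 1)
  seeds <- derive_seeds(seed, n_strains + 1L)
  factors <- with_local_seed(seeds[n_strains + 1L], {
    list(rate = rlnorm(n_strains, 0, strain_sd),
         yield = rlnorm(n_strains, 0, strain_sd))
  })
  experiments <- list()
  truth <- list()
  for (i in seq_len(n_strains)) {
    cfg <- config
    cfg$rate_min <- config$rate_min * factors$rate[i]
    cfg$rate_max <- config$rate_max * factors$rate[i]
    cfg$yield_min <- config$yield_min * factors$yield[i]
    cfg$yield_max <- config$yield_max * factors$yield[i]
    cfg$seed <- seeds[i]
    pair <- generate_experiment_pair(cfg, strain = sprintf("SYN %02d", i))
    experiments <- c(experiments, list(pair$with_TE, pair$without_TE))
    tr <- pair$truth
    tr$strain <- sprintf("SYN %02d", i)
    truth[[i]] <- tr
  }
  list(experiments = experiments, truth = do.call(rbind, truth))
}

#' Generate a synthetic element-concentration panel
#'
#' Emulates an ICP-MS comparison of procedure samples against negative
#' controls: control concentrations are log-normal around per-element
#' baselines, sample concentrations are scaled by a per-element true fold
#' change, and values below the detection limit are censored. The default
#' panel has supplement elements with elevated samples (strongest for
#' boron and manganese), three supplement elements entirely below the LOD,
#' and additional elements including three lead isotopes.
#'
#' @param n_samples,n_controls Tubes per group (default 4 each).
#' @param elements Data frame with columns `element`, `isotope`,
#'   `baseline_ugL`, `true_fold`; `NULL` for the default panel.
#' @param noise_cv Coefficient of variation of the log-normal measurement
#'   scatter (default 0.2).
#' @param lod Limit of detection in the same units (default 0.05).
#' @param seed Integer seed.
#' @return Data frame in the canonical element-table format.
#' @export
generate_element_panel <- function(n_samples = 4, n_controls = 4,
                                   elements = NULL, noise_cv = 0.2,
                                   lod = 0.05, seed = 1L) {
  if (is.null(elements)) {
    elements <- rbind(
      data.frame(element = c("B", "Mn", "Fe", "Zn", "Co", "Cu", "Ni", "W"),
                 isotope = "",
                 baseline_ugL = c(0.4, 0.5, 2.0, 1.5, 0.2, 0.6, 0.4, 0.2),
                 true_fold = c(4.5, 2.4, 1.6, 1.6, 1.4, 1.4, 1.4, 1.3)),
      data.frame(element = c("Al", "Se", "Mo"), isotope = "",
                 baseline_ugL = lod / 10, true_fold = 1),
      data.frame(element = c("Li", "V", "Cr", "As", "Sr", "Cd", "Pt"),
                 isotope = "",
                 baseline_ugL = c(0.3, 0.2, 0.5, 0.2, 1.0, 0.1, 0.1),
                 true_fold = 1.2),
      data.frame(element = "Pb", isotope = c("206", "207", "208"),
                 baseline_ugL = 0.3, true_fold = 1.5))
  }
  stopifnot(all(c("element", "isotope", "baseline_ugL", "true_fold") %in%
                  names(elements)), all(elements$true_fold > 0))
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_local_seed(seed, {
    rows <- lapply(seq_len(nrow(elements)), function(i) {
      el <- elements[i, ]
      draw <- function(level, group, ids) {
        conc <- rlnorm(length(ids), log(level) - sdlog^2 / 2, sdlog)
        below <- conc < lod
        data.frame(element = el$element, isotope = el$isotope,
                   group = group, replicate = ids,
                   concentration_ugL = ifelse(below, NA_real_, conc),
                   below_lod = below, stringsAsFactors = FALSE)
      }
      rbind(draw(el$baseline_ugL * el$true_fold, "sample",
                 sprintf("S%d", seq_len(n_samples))),
            draw(el$baseline_ugL, "control",
                 sprintf("C%d", seq_len(n_controls))))
    })
    do.call(rbind, rows)
  })
}
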