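# Preprocessing: baseline correction, condensation trimming, display
# smoothing and the two well-exclusion filters.

#' Baseline OD of an experiment
#'
#' The baseline (expected OD of the sterile medium) is estimated as the
#' median over curves of each curve's minimum OD.
#'
#' @param experiment A [growth_experiment()].
#' @return A single OD value.
#' @export
compute_baseline <- function(experiment) {
  stopifnot(inherits(experiment, "growth_experiment"))
  if (!length(experiment$curves)) stop("empty experiment", call. = FALSE)
  median(vapply(experiment$curves, function(cv) min(cv$ods), numeric(1)))
}

#' Subtract a baseline OD from all curves of an experiment
#'
#' @param experiment A [growth_experiment()].
#' @param baseline Baseline OD; defaults to [compute_baseline()].
#' @return The experiment with shifted ODs and `baseline_od` set.
#' @export
subtract_baseline <- function(experiment, baseline = compute_baseline(experiment)) {
  experiment$curves <- lapply(experiment$curves, function(cv) {
    cv$ods <- cv$ods - baseline
    cv
  })
  experiment$baseline_od <- baseline
  experiment
}

# Index of the first local minimum: smallest i with
# ods[i] <= ods[j] for every j <= min(i + 1, n), i.e. the point is the
# minimum of its whole prefix and not above its successor. Monotone
# non-decreasing curves give index 1; a leading plateau of the minimum
# returns the plateau's first point.
first_local_minimum_index <- function(ods) {
  n <- length(ods)
  pref_min <- cummin(ods)
  for (i in seq_len(n)) {
    if (ods[i] <= pref_min[i] && (i == n || ods[i] <= ods[i + 1]))
      return(i)
  }
  n # unreachable: the global-minimum position always qualifies
}

#' Trim a curve to its first local minimum
#'
#' Time points before the first local minimum do not capture the growth
#' dynamics and typically stem from initial condensation on the plate; they
#' are removed. Strictly increasing curves are returned unchanged. The
#' operation is idempotent.
#'
#' If fewer than 3 points survive, the curve is marked unusable
#' (`excluded = TRUE`, reason `"unusable"`) instead of erroring.
#'
#' @param curve A [growth_curve()].
#' @return The trimmed [growth_curve()].
#' @export
trim_to_first_local_minimum <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  i <- first_local_minimum_index(curve$ods)
  if (i > 1L) {
    if (length(curve$ods) - i + 1L < 3L) {
      curve$excluded <- TRUE
      curve$exclusion_reason <- "unusable"
      return(curve)
    }
    curve$times <- curve$times[i:length(curve$times)]
    curve$ods <- curve$ods[i:length(curve$ods)]
  }
  curve
}

#' Running median filter (display smoothing)
#'
#' Running median with an odd window; at the edges the window shrinks
#' symmetrically. Used for plotting only - estimation always runs on raw
#' values.
#'
#' @param x A numeric vector or a [growth_curve()].
#' @param window Odd window length (default 5).
#' @return Smoothed object of the same type.
#' @export
median_filter <- function(x, window = 5L) {
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd positive integer", call. = FALSE)
  if (inherits(x, "growth_curve")) {
    x$ods <- median_filter(x$ods, window)
    return(x)
  }
  n <- length(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1L, n - i) # shrink symmetrically at the edges
    median(x[(i - k):(i + k)])
  }, numeric(1))
}

#' Preliminary yield of a curve
#'
#' The 98th percentile of all OD values of the (trimmed, baseline-
#' subtracted) curve, with the linear-interpolation percentile convention
#' (fraction `(n - 1) * q`; R's type 7). Used by the exclusion filters and
#' window constraints before any analysis window exists.
#'
#' @param curve A [growth_curve()].
#' @param percentile Percentile to use (default 98).
#' @return An OD value.
#' @export
preliminary_yield <- function(curve, percentile = 98) {
  stopifnot(inherits(curve, "growth_curve"))
  unname(quantile(curve$ods, percentile / 100, type = 7, names = FALSE))
}

#' Flag candidate wells for exclusion
#'
#' Two filters mark candidates: (1) *condensation*: the well's pre-trim,
#' baseline-subtracted minimum OD exceeds `condensation_threshold`;
#' (2) *outlier yield* (likely biological contamination): the well's
#' preliminary yield exceeds the experiment's `yield_percentile`-th
#' percentile of preliminary yields by more than a factor `outlier_factor`.
#' Flags are candidates - they are applied automatically only when
#' requested ([preprocess_experiment()] with `auto_exclude = TRUE`) or
#' exported for manual review.
#'
#' @param experiment A baseline-subtracted, untrimmed
#'   [growth_experiment()] (only non-manually-excluded wells are flagged).
#' @param condensation_threshold OD threshold for the condensation flag
#'   (default 0.01).
#' @param outlier_factor Multiplicative factor over the reference
#'   percentile (default 1.5).
#' @param yield_percentile Reference percentile of preliminary yields
#'   (default 90).
#' @return Data frame `well_id, plate_id, min_od, preliminary_yield,
#'   condensation, outlier_yield`.
#' @export
flag_wells <- function(experiment, condensation_threshold = 0.01,
                       outlier_factor = 1.5, yield_percentile = 90) {
  stopifnot(inherits(experiment, "growth_experiment"))
  curves <- active_curves(experiment)
  if (length(curves) < 2L)
    stop("need at least 2 non-excluded wells to compute the yield percentile",
         call. = FALSE)
  min_od <- vapply(curves, function(cv) min(cv$ods), numeric(1))
  prelim <- vapply(curves, function(cv) {
    tcv <- trim_to_first_local_minimum(cv)
    if (tcv$excluded) NA_real_ else preliminary_yield(tcv)
  }, numeric(1))
  ref <- quantile(prelim, yield_percentile / 100, type = 7,
                  names = FALSE, na.rm = TRUE)
  data.frame(
    well_id = vapply(curves, `[[`, character(1), "well_id"),
    plate_id = vapply(curves, `[[`, character(1), "plate_id"),
    min_od = min_od,
    preliminary_yield = prelim,
    condensation = min_od > condensation_threshold,
    outlier_yield = !is.na(prelim) & prelim > outlier_factor * ref,
    stringsAsFactors = FALSE)
}

#' Preprocess an experiment
#'
#' Runs the full preparation sequence: baseline subtraction (median of
#' per-curve minima), candidate flagging ([flag_wells()]) on the untrimmed
#' curves, trimming of every curve to its first local minimum, and -
#' optionally - automatic exclusion of all flagged candidates. By default
#' flags are only reported, mirroring a manual-review workflow; automated
#' pipelines set `auto_exclude = TRUE`.
#'
#' @inheritParams flag_wells
#' @param auto_exclude Exclude all flagged candidates (default `FALSE`).
#' @return A list with elements `experiment` (preprocessed
#'   [growth_experiment()]), `flags` (data frame from [flag_wells()]) and
#'   `baseline_od`.
#' @export
preprocess_experiment <- function(experiment, condensation_threshold = 0.01,
                                  outlier_factor = 1.5, yield_percentile = 90,
                                  auto_exclude = FALSE) {
  experiment <- subtract_baseline(experiment)
  flags <- flag_wells(experiment,
                      condensation_threshold = condensation_threshold,
                      outlier_factor = outlier_factor,
                      yield_percentile = yield_percentile)
  experiment$curves <- lapply(experiment$curves, function(cv) {
    if (cv$excluded) return(cv)
    cv <- trim_to_first_local_minimum(cv)
    if (auto_exclude && !cv$excluded) {
      i <- which(flags$well_id == cv$well_id & flags$plate_id == cv$plate_id)
      if (length(i) == 1L) {
        if (flags$condensation[i]) {
          cv$excluded <- TRUE
          cv$exclusion_reason <- "condensation"
        } else if (flags$outlier_yield[i]) {
          cv$excluded <- TRUE
          cv$exclusion_reason <- "outlier_yield"
        }
      }
    }
    cv
  })
  list(experiment = experiment, flags = flags,
       baseline_od = experiment$baseline_od)
}
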