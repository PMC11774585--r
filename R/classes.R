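#' Construct a single-well growth curve
#'
#' A growth curve is one well's optical-density (OD600) time series together
#' with its provenance (well and plate labels) and an exclusion state set by
#' the quality filters.
#'
#' @param well_id Well label, e.g. `"A1"`.
#' @param plate_id Plate label, e.g. `"P1"`.
#' @param times Numeric vector of measurement times in seconds; non-negative
#'   and strictly increasing.
#' @param ods Numeric vector of OD values, same length as `times`.
#' @param excluded Logical; whether the well is excluded from analysis.
#' @param exclusion_reason One of `"none"`, `"condensation"`,
#'   `"outlier_yield"`, `"manual"`, `"unusable"`. Must be `"none"` iff
#'   `excluded` is `FALSE`.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(well_id, plate_id, times, ods,
                         excluded = FALSE, exclusion_reason = "none") {
  stopifnot(is.character(well_id), length(well_id) == 1L,
            is.character(plate_id), length(plate_id) == 1L)
  times <- as.numeric(times)
  ods <- as.numeric(ods)
  if (length(times) != length(ods))
    stop("`times` and `ods` must have the same length", call. = FALSE)
  if (length(times) < 3L)
    stop("a growth curve needs at least 3 time points (well ",
         well_id, ")", call. = FALSE)
  if (any(times < 0))
    stop("negative times in well ", well_id, call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing in well ", well_id, call. = FALSE)
  exclusion_reason <- match.arg(
    exclusion_reason,
    c("none", "condensation", "outlier_yield", "manual", "unusable"))
  if (identical(excluded, FALSE) && exclusion_reason != "none")
    stop("non-excluded curve cannot carry an exclusion reason", call. = FALSE)
  if (identical(excluded, TRUE) && exclusion_reason == "none")
    stop("excluded curve needs an exclusion reason", call. = FALSE)
  structure(
    list(well_id = well_id, plate_id = plate_id,
         times = times, ods = ods,
         excluded = isTRUE(excluded), exclusion_reason = exclusion_reason),
    class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> well %s (plate %s): %d points, %.2f h%s\n",
              x$well_id, x$plate_id, length(x$times),
              diff(range(x$times)) / 3600,
              if (x$excluded) paste0(", EXCLUDED (", x$exclusion_reason, ")")
              else ""))
  invisible(x)
}

#' Construct an experiment (all replicate curves of one strain x condition)
#'
#' An *experiment* is the collection of all replicate growth curves of one
#' strain grown under one condition (medium with or without trace-element
#' supplement).
#'
#' @param strain Strain code, e.g. `"JUb 134"`.
#' @param condition `"with_TE"` or `"without_TE"`.
#' @param curves List of [growth_curve()] objects.
#' @param baseline_od Baseline OD of the medium; `NA` until set by
#'   [preprocess_experiment()].
#' @return An object of class `growth_experiment`.
#' @export
growth_experiment <- function(strain, condition, curves,
                              baseline_od = NA_real_) {
  stopifnot(is.character(strain), length(strain) == 1L)
  condition <- match.arg(condition, c("with_TE", "without_TE"))
  if (!is.list(curves) || length(curves) < 1L ||
      !all(vapply(curves, inherits, logical(1), "growth_curve")))
    stop("`curves` must be a non-empty list of growth_curve objects",
         call. = FALSE)
  structure(
    list(strain = strain, condition = condition, curves = curves,
         baseline_od = as.numeric(baseline_od)),
    class = "growth_experiment")
}

#' @export
print.growth_experiment <- function(x, ...) {
  n_ex <- sum(vapply(x$curves, `[[`, logical(1), "excluded"))
  cat(sprintf("<growth_experiment> %s, %s: %d curves (%d excluded)%s\n",
              x$strain, x$condition, length(x$curves), n_ex,
              if (is.na(x$baseline_od)) ""
              else sprintf(", baseline OD %.4g", x$baseline_od)))
  invisible(x)
}

#' Non-excluded curves of an experiment
#'
#' @param experiment A [growth_experiment()].
#' @return List of the curves with `excluded = FALSE`.
#' @export
active_curves <- function(experiment) {
  stopifnot(inherits(experiment, "growth_experiment"))
  Filter(function(cv) !cv$excluded, experiment$curves)
}

#' @export
as.data.frame.growth_experiment <- function(x, ...) {
  do.call(rbind, lapply(x$curves, function(cv) {
    data.frame(strain = x$strain, condition = x$condition,
               plate = cv$plate_id, well = cv$well_id,
               time_s = cv$times, od = cv$ods,
               stringsAsFactors = FALSE)
  }))
}
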