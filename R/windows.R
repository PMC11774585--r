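# Experiment-wide analysis-window selection for yield and growth rate.
#
# The yield window is a time interval; per curve, the yield is the 98th
# percentile of OD inside it, and the window minimizes
#   CoV(yields) * mean(r^2 of OD vs time)
# so that low-variability, stagnant (saturated) regions win. The rate
# window is an OD interval, searched in log10 OD; per curve, the rate comes
# from the logistic fit inside it, and the window minimizes
#   CoV(rates) * mean(1 - r^2 of the fit).
# Both searches evaluate a full lattice and then refine with a Powell-style
# finisher under a quadratic constraint penalty; the finisher can only
# improve on the lattice optimum.

#' Yield of a curve within a time interval
#'
#' The 98th percentile (linear-interpolation convention) of the curve's OD
#' values at times inside the closed interval.
#'
#' @param curve A [growth_curve()].
#' @param interval Numeric `c(start, end)` in seconds.
#' @param percentile Percentile to use (default 98).
#' @return An OD value, or `NA` with a warning when fewer than 2
#'   observations fall inside the interval.
#' @export
yield_of_curve <- function(curve, interval, percentile = 98) {
  stopifnot(inherits(curve, "growth_curve"), length(interval) == 2L)
  sel <- curve$times >= interval[1] & curve$times <= interval[2]
  if (sum(sel) < 2L) {
    warning("well ", curve$well_id,
            ": fewer than 2 points in the yield interval; curve skipped",
            call. = FALSE)
    return(NA_real_)
  }
  unname(quantile(curve$ods[sel], percentile / 100, type = 7, names = FALSE))
}

# squared Pearson correlation of od vs time; 0 for zero-variance od
.r2_od_time <- function(t, od) {
  if (length(od) < 2L) return(NA_real_)
  so <- sd(od)
  st <- sd(t)
  if (!is.finite(so) || so <= 0 || st <= 0) return(0)
  cor(t, od)^2
}

# internal: objective together with number of curves used
yield_objective_impl <- function(curves, start, end, percentile = 98) {
  yields <- numeric(0)
  r2s <- numeric(0)
  for (cv in curves) {
    sel <- cv$times >= start & cv$times <= end
    if (sum(sel) < 2L) next
    yields <- c(yields,
                quantile(cv$ods[sel], percentile / 100, type = 7,
                         names = FALSE))
    r2s <- c(r2s, .r2_od_time(cv$times[sel], cv$ods[sel]))
  }
  if (length(yields) < 2L) return(list(value = Inf, n = length(yields)))
  m <- mean(yields)
  if (!is.finite(m) || m <= 0) return(list(value = Inf, n = length(yields)))
  list(value = (sd(yields) / m) * mean(r2s), n = length(yields))
}

#' Yield-window objective
#'
#' `CoV(per-curve yields within the interval) x mean(r^2 of OD vs time)`
#' over the experiment's non-excluded curves; `Inf` when fewer than two
#' curves have at least two points inside the interval (infeasible).
#' Curves with zero OD variance in the interval contribute `r^2 = 0`.
#'
#' @param experiment A preprocessed [growth_experiment()].
#' @param interval Numeric `c(start, end)` in seconds.
#' @param percentile Yield percentile (default 98).
#' @return A non-negative number, or `Inf`.
#' @export
yield_objective <- function(experiment, interval, percentile = 98) {
  stopifnot(inherits(experiment, "growth_experiment"))
  yield_objective_impl(active_curves(experiment), interval[1], interval[2],
                       percentile)$value
}

#' Select the yield time window for an experiment
#'
#' Minimizes [yield_objective()] over `(start, end)` subject to: `start`
#' not earlier than the median over curves of the first time each curve
#' exceeds `prelim_fraction` of its preliminary yield; `start` between
#' `start_end_ratio[1]` and `start_end_ratio[2]` of `end`; `end` within the
#' observation span. The objective is evaluated on a `grid_steps^2` lattice
#' and the lattice optimum is refined by a Powell-style finisher with a
#' constraint penalty; the returned interval satisfies all constraints and
#' is never worse than the lattice optimum. Exact objective ties (which
#' arise only in degenerate zero-variability experiments) are broken toward
#' the latest, then longest window, i.e. the stagnation region.
#'
#' @param experiment A preprocessed [growth_experiment()].
#' @param grid_steps Lattice size per dimension (default 100).
#' @param percentile Yield percentile (default 98).
#' @param prelim_fraction Fraction of the preliminary yield whose median
#'   crossing time bounds the window start (default 0.7).
#' @param start_end_ratio Allowed `start/end` range (default `c(0.5, 0.9)`).
#' @param refine Run the Powell finisher (default `TRUE`).
#' @return A `window_search` object: list with `type`, `interval`,
#'   `objective_value`, `grid_best`, `grid_objective`, `feasible`,
#'   `n_curves_used` and `min_start`.
#' @export
select_yield_interval <- function(experiment, grid_steps = 100,
                                  percentile = 98, prelim_fraction = 0.7,
                                  start_end_ratio = c(0.5, 0.9),
                                  refine = TRUE) {
  stopifnot(inherits(experiment, "growth_experiment"), grid_steps >= 2)
  curves <- active_curves(experiment)
  if (length(curves) < 2L)
    stop("need at least 2 non-excluded curves", call. = FALSE)
  r_lo <- start_end_ratio[1]
  r_hi <- start_end_ratio[2]
  # the start/end ratio constraint counts time from the beginning of the
  # observation; re-zero internally so results are shift-invariant
  t0 <- min(vapply(curves, function(cv) cv$times[1], numeric(1)))
  if (t0 != 0)
    curves <- lapply(curves, function(cv) {
      cv$times <- cv$times - t0
      cv
    })
  crossings <- vapply(curves, function(cv) {
    thr <- prelim_fraction * preliminary_yield(cv, percentile)
    i <- which(cv$ods > thr)
    if (!length(i)) max(cv$times) else cv$times[i[1]]
  }, numeric(1))
  t_min <- median(crossings)
  t_max <- max(vapply(curves, function(cv) max(cv$times), numeric(1)))
  if (t_min / r_hi > t_max)
    stop("empty feasible region: start/end ratio constraint cannot be met ",
         "(median crossing time too late)", call. = FALSE)
  feas <- function(s, e) {
    s >= t_min && e <= t_max && s >= r_lo * e && s <= r_hi * e
  }
  fn <- function(s, e) {
    if (!feas(s, e)) return(Inf)
    yield_objective_impl(curves, s, e, percentile)$value
  }
  starts <- seq(t_min, r_hi * t_max, length.out = grid_steps)
  ends <- seq(t_min / r_hi, t_max, length.out = grid_steps)
  # iterate ends descending: ties go to the latest window, then the
  # earliest start (longest window)
  grid <- grid_search_2d(ends, starts, function(e, s) fn(s, e),
                         descending1 = TRUE)
  if (is.null(grid))
    stop("empty feasible region: no window holds 2 points of 2 curves",
         call. = FALSE)
  best <- list(par = rev(grid$par), value = grid$value) # (start, end)
  result <- best
  if (refine) {
    clip <- function(p) {
      e <- min(max(p[2], t_min / r_hi), t_max)
      s <- min(max(p[1], max(t_min, r_lo * e)), r_hi * e)
      c(s, e)
    }
    pen_fn <- function(p) {
      q <- clip(p)
      viol <- sum((p - q)^2) / (t_max - t_min + 1)^2
      v <- fn(q[1], q[2])
      if (!is.finite(v)) v <- best$value + 1
      v + 1e6 * viol
    }
    pw <- powell_minimize(pen_fn, best$par,
                          scale = rep((t_max - t_min) / grid_steps, 2))
    q <- clip(pw$par)
    vq <- fn(q[1], q[2])
    if (is.finite(vq) && vq < result$value)
      result <- list(par = q, value = vq)
  }
  n_used <- yield_objective_impl(curves, result$par[1], result$par[2],
                                 percentile)$n
  structure(list(type = "yield", interval = result$par + t0,
                 objective_value = result$value,
                 grid_best = best$par + t0, grid_objective = best$value,
                 feasible = TRUE, n_curves_used = n_used,
                 min_start = t_min + t0),
            class = "window_search")
}

#' @export
print.window_search <- function(x, ...) {
  u <- if (x$type == "yield") "s" else "OD"
  cat(sprintf("<window_search> %s window [%.6g, %.6g] %s, objective %.4g (%d curves)\n",
              x$type, x$interval[1], x$interval[2], u, x$objective_value,
              x$n_curves_used))
  invisible(x)
}

# internal rate objective; memo is an environment caching per-curve fits
# keyed by the point subset the OD window selects
rate_objective_impl <- function(curves, lower, upper, memo = NULL,
                                k_cap_factor = 1000,
                                badness_transform = "identity") {
  rates <- numeric(0)
  r2s <- numeric(0)
  for (j in seq_along(curves)) {
    cv <- curves[[j]]
    fit <- NULL
    if (!is.null(memo)) {
      key <- sprintf("%d.%d.%d", j, sum(cv$ods < lower), sum(cv$ods > upper))
      if (!is.null(memo[[key]])) {
        fit <- memo[[key]]
        if (identical(fit, "none")) fit <- NULL
      } else {
        fit <- fit_logistic_window(cv$times, cv$ods, lower, upper,
                                   k_cap_factor = k_cap_factor)
        memo[[key]] <- if (is.null(fit)) "none" else fit
      }
    } else {
      fit <- fit_logistic_window(cv$times, cv$ods, lower, upper,
                                 k_cap_factor = k_cap_factor)
    }
    if (is.null(fit)) next
    rates <- c(rates, fit$rate)
    r2s <- c(r2s, fit$r_squared)
  }
  if (length(rates) < 2L) return(list(value = Inf, n = length(rates)))
  m <- mean(rates)
  if (!is.finite(m) || m <= 0) return(list(value = Inf, n = length(rates)))
  bad <- mean(1 - r2s)
  if (badness_transform == "sqrt") bad <- sqrt(max(bad, 0))
  list(value = (sd(rates) / m) * bad, n = length(rates))
}

#' Rate-window objective
#'
#' `CoV(per-curve fitted rates) x mean(1 - r^2)` over the experiment's
#' non-excluded curves, where each rate and `r^2` come from the logistic
#' fit of [fit_growth_rate()] restricted to the OD interval. Curves with
#' fewer than 4 points inside the window are omitted; the objective is
#' `Inf` when fewer than two curves remain.
#'
#' @param experiment A preprocessed [growth_experiment()].
#' @param interval Numeric `c(lower, upper)` OD bounds.
#' @param k_cap_factor Carrying-capacity cap factor (default 1000).
#' @param badness_transform `"identity"` (default) for
#'   `CoV x mean(1 - r^2)`, or `"sqrt"` for `CoV x sqrt(mean(1 - r^2))`.
#' @return A non-negative number, or `Inf`.
#' @export
rate_objective <- function(experiment, interval, k_cap_factor = 1000,
                           badness_transform = c("identity", "sqrt")) {
  stopifnot(inherits(experiment, "growth_experiment"))
  badness_transform <- match.arg(badness_transform)
  rate_objective_impl(active_curves(experiment), interval[1], interval[2],
                      k_cap_factor = k_cap_factor,
                      badness_transform = badness_transform)$value
}

#' Select the growth-rate OD window for an experiment
#'
#' Minimizes [rate_objective()] over OD intervals `(lower, upper)`,
#' searched in log10 OD, subject to: `lower` between `lower_frac[1]` and
#' `lower_frac[2]` of the experiment's median yield; `upper` at most the
#' median yield; a span of `span_decades[1]` to `span_decades[2]` powers of
#' ten. Lattice search plus Powell finisher as in
#' [select_yield_interval()]. Exact objective ties (degenerate
#' zero-variability experiments) are broken toward the highest window
#' (largest `lower`, then largest `upper`), where the signal is strongest
#' and baseline subtraction matters least.
#'
#' @param experiment A preprocessed [growth_experiment()].
#' @param median_yield The experiment's median per-well yield (from the
#'   yield window).
#' @param grid_steps Lattice size per dimension (default 100).
#' @param lower_frac Allowed `lower / median_yield` range
#'   (default `c(0.001, 0.1)`).
#' @param span_decades Allowed `log10(upper/lower)` range
#'   (default `c(0.7, 3)`).
#' @param k_cap_factor Carrying-capacity cap factor (default 1000).
#' @param badness_transform See [rate_objective()].
#' @param refine Run the Powell finisher (default `TRUE`).
#' @return A `window_search` object (interval in OD units).
#' @export
select_rate_interval <- function(experiment, median_yield, grid_steps = 100,
                                 lower_frac = c(0.001, 0.1),
                                 span_decades = c(0.7, 3),
                                 k_cap_factor = 1000,
                                 badness_transform = c("identity", "sqrt"),
                                 refine = TRUE) {
  stopifnot(inherits(experiment, "growth_experiment"), grid_steps >= 2)
  badness_transform <- match.arg(badness_transform)
  if (!is.finite(median_yield) || median_yield <= 0)
    stop("empty feasible region: median yield must be positive",
         call. = FALSE)
  curves <- active_curves(experiment)
  if (length(curves) < 2L)
    stop("need at least 2 non-excluded curves", call. = FALSE)
  ll_lo <- log10(lower_frac[1] * median_yield)
  ll_hi <- log10(lower_frac[2] * median_yield)
  lu_hi <- log10(median_yield)
  if (ll_lo + span_decades[1] > lu_hi)
    stop("empty feasible region: minimum span exceeds the available OD range",
         call. = FALSE)
  memo <- new.env(parent = emptyenv())
  feas <- function(ll, lu) {
    ll >= ll_lo && ll <= ll_hi && lu <= lu_hi &&
      (lu - ll) >= span_decades[1] && (lu - ll) <= span_decades[2]
  }
  fn <- function(ll, lu) {
    if (!feas(ll, lu)) return(Inf)
    rate_objective_impl(curves, 10^ll, 10^lu, memo = memo,
                        k_cap_factor = k_cap_factor,
                        badness_transform = badness_transform)$value
  }
  lls <- seq(ll_lo, ll_hi, length.out = grid_steps)
  lus <- seq(ll_lo + span_decades[1], lu_hi, length.out = grid_steps)
  # descending in both axes: ties go to the highest window
  grid <- grid_search_2d(lls, lus, fn,
                         descending1 = TRUE, descending2 = TRUE)
  if (is.null(grid))
    stop("empty feasible region: no OD window holds 4 points of 2 curves",
         call. = FALSE)
  best <- grid
  result <- best
  if (refine) {
    clip <- function(p) {
      ll <- min(max(p[1], ll_lo), ll_hi)
      lu <- min(max(p[2], ll + span_decades[1]), min(lu_hi, ll + span_decades[2]))
      c(ll, lu)
    }
    pen_fn <- function(p) {
      q <- clip(p)
      v <- fn(q[1], q[2])
      if (!is.finite(v)) v <- best$value + 1
      v + 1e6 * sum((p - q)^2)
    }
    pw <- powell_minimize(pen_fn, best$par,
                          scale = rep((lu_hi - ll_lo) / grid_steps, 2))
    q <- clip(pw$par)
    vq <- fn(q[1], q[2])
    if (is.finite(vq) && vq < result$value)
      result <- list(par = q, value = vq)
  }
  n_used <- rate_objective_impl(curves, 10^result$par[1], 10^result$par[2],
                                memo = memo, k_cap_factor = k_cap_factor,
                                badness_transform = badness_transform)$n
  structure(list(type = "rate", interval = 10^result$par,
                 objective_value = result$value,
                 grid_best = 10^best$par, grid_objective = best$value,
                 feasible = TRUE, n_curves_used = n_used,
                 median_yield = median_yield),
            class = "window_search")
}

#' Per-well growth characteristics of an experiment
#'
#' Selects the yield time window and the rate OD window for the experiment,
#' then computes per-well yield (98th percentile of OD inside the time
#' window) and growth rate (logistic fit inside the OD window). Excluded
#' wells appear with empty values and their exclusion reason.
#'
#' @param experiment A preprocessed [growth_experiment()].
#' @param grid_steps Lattice size for both window searches (default 100).
#' @param percentile Yield percentile (default 98).
#' @param prelim_fraction,start_end_ratio See [select_yield_interval()].
#' @param lower_frac,span_decades,k_cap_factor,badness_transform See
#'   [select_rate_interval()].
#' @param refine Run the Powell finishers (default `TRUE`).
#' @return A list with `table` (data frame, one row per well),
#'   `yield_window` and `rate_window` (both `window_search` objects).
#' @export
experiment_characteristics <- function(experiment, grid_steps = 100,
                                       percentile = 98,
                                       prelim_fraction = 0.7,
                                       start_end_ratio = c(0.5, 0.9),
                                       lower_frac = c(0.001, 0.1),
                                       span_decades = c(0.7, 3),
                                       k_cap_factor = 1000,
                                       badness_transform = "identity",
                                       refine = TRUE) {
  yw <- select_yield_interval(experiment, grid_steps = grid_steps,
                              percentile = percentile,
                              prelim_fraction = prelim_fraction,
                              start_end_ratio = start_end_ratio,
                              refine = refine)
  curves <- active_curves(experiment)
  yields <- vapply(curves, function(cv) {
    suppressWarnings(yield_of_curve(cv, yw$interval, percentile))
  }, numeric(1))
  med_yield <- median(yields, na.rm = TRUE)
  rw <- select_rate_interval(experiment, med_yield, grid_steps = grid_steps,
                             lower_frac = lower_frac,
                             span_decades = span_decades,
                             k_cap_factor = k_cap_factor,
                             badness_transform = badness_transform,
                             refine = refine)
  rows <- lapply(experiment$curves, function(cv) {
    row <- data.frame(strain = experiment$strain,
                      condition = experiment$condition,
                      plate = cv$plate_id, well = cv$well_id,
                      yield = NA_real_, growth_rate_per_h = NA_real_,
                      fit_type = "", r2 = NA_real_,
                      excluded = cv$excluded,
                      exclusion_reason = cv$exclusion_reason,
                      stringsAsFactors = FALSE)
    if (cv$excluded) return(row)
    row$yield <- suppressWarnings(yield_of_curve(cv, yw$interval, percentile))
    fit <- fit_logistic_window(cv$times, cv$ods, rw$interval[1],
                               rw$interval[2], k_cap_factor = k_cap_factor)
    if (!is.null(fit)) {
      row$growth_rate_per_h <- fit$rate
      row$fit_type <- fit$fit_type
      row$r2 <- fit$r_squared
    }
    row
  })
  list(table = do.call(rbind, rows), yield_window = yw, rate_window = rw)
}
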