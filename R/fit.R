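# Logistic growth-rate fitting inside an OD window.
#
# The rate is the low-density exponential rate r of
#   N(t) = K N0 e^{r t} / (K + N0 (e^{r t} - 1)),
# fit by least squares on log OD over the points whose baseline-subtracted
# OD falls inside [lower, upper]. K is bounded above by a liberal cap
# (k_cap_factor x the curve's maximum OD) so that simple exponential growth
# is included as a special case; the same straight-line regression of
# log OD on time is the fallback when the logistic fit does not converge.

# slope (per hour) and r2 of log od vs time; fast path without lm()
.log_slope <- function(t_h, y) {
  tm <- mean(t_h)
  ym <- mean(y)
  stt <- sum((t_h - tm)^2)
  sst <- sum((y - ym)^2)
  if (stt <= 0) return(list(slope = 0, r2 = 0, sst = sst))
  slope <- sum((t_h - tm) * (y - ym)) / stt
  sse <- sst - slope^2 * stt
  r2 <- if (sst <= 1e-300) 0 else max(0, min(1, 1 - sse / sst))
  list(slope = slope, r2 = r2, sst = sst)
}

# Core fit shared by the exported function and the window search.
# Returns NULL when fewer than min_points usable observations fall inside
# the window; otherwise a list(rate, r_squared, fit_type, k, n_points).
fit_logistic_window <- function(times_s, ods, lower, upper,
                                k_cap_factor = 1000, min_points = 4L) {
  sel <- which(ods >= lower & ods <= upper & ods > 0)
  if (length(sel) < min_points) return(NULL)
  t_h <- times_s[sel] / 3600
  y <- log(ods[sel])
  lin <- .log_slope(t_h, y)
  if (lin$sst <= 1e-20) { # flat segment: logistic cannot be identified
    return(list(rate = 0, r_squared = 0, fit_type = "exponential_fallback",
                k = NA_real_, n_points = length(sel)))
  }
  logk_cap <- log(k_cap_factor * max(ods))
  r0 <- max(lin$slope, 0.02)
  lr0 <- log(r0)
  # half-saturation time guesses: at/after the window, and further out for
  # windows far below saturation
  tm_cands <- c(max(t_h), max(t_h) + 2 / r0)
  best <- NULL
  for (tm0 in tm_cands) {
    f <- c_fit_logistic_profile(t_h, y, lr0, tm0, logk_cap)
    if (is.null(best) || f$sse < best$sse) best <- f
  }
  # one polish restart from the best vertex
  f <- c_fit_logistic_profile(t_h, y, log(best$rate), best$tm, logk_cap)
  if (f$sse < best$sse) best <- f
  ok <- isTRUE(best$converged) && is.finite(best$sse) &&
    is.finite(best$rate) && best$rate > 1e-8
  if (!ok) {
    r2 <- lin$r2
    return(list(rate = lin$slope, r_squared = r2,
                fit_type = "exponential_fallback", k = NA_real_,
                n_points = length(sel)))
  }
  r2 <- max(0, min(1, 1 - best$sse / lin$sst))
  list(rate = best$rate, r_squared = r2, fit_type = "logistic",
       k = exp(best$log_k), n_points = length(sel))
}

# Linear-OD-space variant (configurable alternative): minimizes squared
# residuals on OD itself over (log r, tm, log K) with optim.
fit_logistic_window_linear <- function(times_s, ods, lower, upper,
                                       k_cap_factor = 1000, min_points = 4L) {
  sel <- which(ods >= lower & ods <= upper & ods > 0)
  if (length(sel) < min_points) return(NULL)
  t_h <- times_s[sel] / 3600
  od <- ods[sel]
  y <- log(od)
  lin <- .log_slope(t_h, y)
  if (lin$sst <= 1e-20)
    return(list(rate = 0, r_squared = 0, fit_type = "exponential_fallback",
                k = NA_real_, n_points = length(sel)))
  logk_cap <- log(k_cap_factor * max(ods))
  obj <- function(p) {
    r <- exp(p[1])
    lk <- min(p[3], logk_cap)
    pred <- exp(lk - log1p(exp(pmin(-r * (t_h - p[2]), 35))))
    sum((od - pred)^2)
  }
  p0 <- c(log(max(lin$slope, 0.02)), max(t_h), log(max(od)))
  f <- tryCatch(stats::optim(p0, obj, control = list(maxit = 1000)),
                error = function(e) NULL)
  sst <- sum((od - mean(od))^2)
  if (is.null(f) || f$convergence != 0 || !is.finite(f$value) ||
      exp(f$par[1]) <= 1e-8) {
    return(list(rate = lin$slope, r_squared = lin$r2,
                fit_type = "exponential_fallback", k = NA_real_,
                n_points = length(sel)))
  }
  list(rate = exp(f$par[1]),
       r_squared = max(0, min(1, 1 - f$value / sst)),
       fit_type = "logistic", k = exp(min(f$par[3], logk_cap)),
       n_points = length(sel))
}

#' Fit a growth rate inside an OD window
#'
#' Fits logistic growth to the points of `curve` whose (baseline-
#' subtracted) OD lies inside the closed interval `interval`, by least
#' squares on log OD. The carrying capacity is capped at `k_cap_factor`
#' times the curve's maximum OD, which makes simple exponential growth a
#' special case; on non-convergence the fit falls back to a straight-line
#' regression of log OD on time (`fit_type = "exponential_fallback"`).
#'
#' @param curve A [growth_curve()], baseline-subtracted.
#' @param interval Numeric `c(lower, upper)` OD bounds, `0 < lower < upper`.
#' @param k_cap_factor Carrying-capacity cap as a multiple of the curve's
#'   maximum OD (default 1000).
#' @param fit_space `"log"` (default; residuals in log OD) or `"linear"`.
#' @return A list with `rate` (per hour), `r_squared` (coefficient of
#'   determination in the fitting space), `fit_type`, `k` and `n_points`;
#'   or `NULL` with a warning when fewer than 4 points fall in the window.
#' @export
fit_growth_rate <- function(curve, interval, k_cap_factor = 1000,
                            fit_space = c("log", "linear")) {
  stopifnot(inherits(curve, "growth_curve"),
            length(interval) == 2L, interval[1] > 0,
            interval[1] < interval[2])
  fit_space <- match.arg(fit_space)
  fitter <- if (fit_space == "log") fit_logistic_window
            else fit_logistic_window_linear
  res <- fitter(curve$times, curve$ods, interval[1], interval[2],
                k_cap_factor = k_cap_factor)
  if (is.null(res)) {
    warning("well ", curve$well_id,
            ": fewer than 4 points in OD window; curve skipped",
            call. = FALSE)
    return(NULL)
  }
  res
}
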