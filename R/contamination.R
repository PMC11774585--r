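# Element-contamination statistics: per-element comparison of procedure
# samples against negative controls (exact Mann-Whitney U), fold changes,
# and logit-based p-value combination (Mudholkar-George).

#' Fold change of element concentrations (samples vs controls)
#'
#' Ratio of group medians (configurable to means). Below-LOD values are
#' passed as `NA` and excluded. When every control is censored the true
#' control level is at most the LOD, so the ratio against `lod` is
#' reported as a lower bound.
#'
#' @param samples,controls Concentrations; `NA` marks below-LOD values.
#' @param lod Limit of detection, used for the lower-bound case.
#' @param method `"median"` (default) or `"mean"`.
#' @return List with `fold_change`, `is_lower_bound` and `evaluable`.
#' @export
element_fold_change <- function(samples, controls, lod = NA,
                                method = c("median", "mean")) {
  method <- match.arg(method)
  avg <- if (method == "median") median else mean
  qs <- samples[!is.na(samples)]
  qc <- controls[!is.na(controls)]
  if (!length(qs))
    return(list(fold_change = NA_real_, is_lower_bound = FALSE,
                evaluable = FALSE))
  if (!length(qc)) {
    fc <- if (is.na(lod) || lod <= 0) NA_real_ else avg(qs) / lod
    return(list(fold_change = fc, is_lower_bound = TRUE,
                evaluable = !is.na(fc)))
  }
  ref <- avg(qc)
  if (ref <= 0)
    return(list(fold_change = NA_real_, is_lower_bound = FALSE,
                evaluable = FALSE))
  list(fold_change = avg(qs) / ref, is_lower_bound = FALSE,
       evaluable = TRUE)
}

#' Mann-Whitney U test
#'
#' Compares two small groups of concentrations. For a combined sample size
#' of at most 20 the permutation distribution of the rank sum is
#' enumerated exactly, with mid-ranks for ties; larger samples use the
#' normal approximation with continuity and tie correction. Default is
#' one-sided with the alternative that samples exceed controls (the
#' procedure adds contamination).
#'
#' @param samples,controls Numeric vectors (>= 2 values each).
#' @param sided `"one"` (default) or `"two"`.
#' @return The p-value.
#' @export
mwu_test <- function(samples, controls, sided = c("one", "two")) {
  sided <- match.arg(sided)
  x <- as.numeric(samples)
  y <- as.numeric(controls)
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  n <- n1 + n2
  rk <- rank(c(x, y)) # mid-ranks
  robs <- sum(rk[seq_len(n1)])
  if (n <= 20L) {
    splits <- combn(n, n1)
    dist <- colSums(matrix(rk[splits], nrow = n1))
    pg <- mean(dist >= robs - 1e-9)
    pl <- mean(dist <= robs + 1e-9)
    if (sided == "one") pg else min(1, 2 * min(pg, pl))
  } else {
    alt <- if (sided == "one") "greater" else "two.sided"
    suppressWarnings(
      wilcox.test(x, y, alternative = alt, exact = FALSE,
                  correct = TRUE)$p.value)
  }
}

#' Combine independent p-values by the Mudholkar-George method
#'
#' The logit-based combination: the statistic
#' \deqn{t = -\sqrt{\frac{15k + 12}{(5k + 4)\,k\,\pi^2}}
#'       \sum_i \log\frac{p_i}{1 - p_i}}
#' is referred to a Student-t distribution with `5k + 4` degrees of
#' freedom; the upper-tail probability is returned. Symmetric around 0.5:
#' combining any number of p = 0.5 values gives 0.5, and lowering any
#' input never raises the result.
#'
#' @param p_values Probabilities in (0, 1); boundary values are clipped to
#'   the open interval with a warning.
#' @return The combined p-value.
#' @export
mudholkar_george_combine <- function(p_values) {
  p <- as.numeric(p_values)
  k <- length(p)
  if (k < 1L) stop("need at least one p-value", call. = FALSE)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  eps <- 1e-12
  if (any(p <= 0 | p >= 1)) {
    warning("boundary p-values clipped into (0, 1)", call. = FALSE)
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  stat <- -sqrt((15 * k + 12) / ((5 * k + 4) * k * pi^2)) *
    sum(log(p / (1 - p)))
  pt(stat, df = 5 * k + 4, lower.tail = FALSE)
}

#' Combine the isotope results of one element
#'
#' Single per-element result from several isotope-level results
#' (e.g. 206/207/208 for lead): the p-values are combined by
#' [mudholkar_george_combine()], the fold change is the median of the
#' isotope fold changes.
#'
#' @param results Data frame with columns `element`, `p_mwu`,
#'   `fold_change` (one row per isotope of a single element).
#' @return One-row data frame of the same shape with `isotope = ""`.
#' @export
combine_isotopes <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  if (length(unique(results$element)) != 1L)
    stop("all rows must belong to one element", call. = FALSE)
  out <- results[1, , drop = FALSE]
  out$isotope <- ""
  if (nrow(results) > 1L) {
    ps <- results$p_mwu[!is.na(results$p_mwu)]
    out$p_mwu <- if (length(ps)) mudholkar_george_combine(ps) else NA_real_
    out$fold_change <- median(results$fold_change, na.rm = TRUE)
    out$is_lower_bound <- any(results$is_lower_bound, na.rm = TRUE)
  }
  rownames(out) <- NULL
  out
}

#' Analyze an element-concentration panel
#'
#' Per element (and isotope): fold change and Mann-Whitney p-value of
#' samples against negative controls; isotope-level results of the same
#' element are then merged via [combine_isotopes()]. Elements whose
#' measurements are entirely below the detection limit, or with fewer than
#' 2 quantified values in either group, are reported as not evaluable
#' rather than p = 1. Finally, one overall p-value is computed separately
#' for the elements contained in the supplement and for the additional
#' elements ([mudholkar_george_combine()] over the evaluable per-element
#' p-values).
#'
#' @param measurements Data frame as returned by [read_element_table()] or
#'   [generate_element_panel()].
#' @param supplement_elements Elements contained in the trace-element
#'   supplement (defaults to the standard Mn/Fe/Zn/Co/B/Cu/Al/Ni/Mo/W/Se
#'   mix).
#' @param sided Sidedness of the per-element test (default `"one"`).
#' @param lod Limit of detection used for lower-bound fold changes.
#' @param fold_method `"median"` (default) or `"mean"`.
#' @return List with `per_element` (data frame: `element, in_supplement,
#'   fold_change, fold_is_lower_bound, p_mwu, n_samples, n_controls,
#'   evaluable`) and `combined_p` (list with `supplement`, `additional`).
#' @export
analyze_element_panel <- function(measurements,
                                  supplement_elements = c("Mn", "Fe", "Zn",
                                                          "Co", "B", "Cu",
                                                          "Al", "Ni", "Mo",
                                                          "W", "Se"),
                                  sided = "one", lod = NA,
                                  fold_method = "median") {
  stopifnot(all(.el_columns %in% names(measurements)))
  conc <- ifelse(measurements$below_lod, NA_real_,
                 measurements$concentration_ugL)
  key <- interaction(measurements$element, measurements$isotope,
                     drop = TRUE, sep = "\r")
  iso_rows <- lapply(split(seq_len(nrow(measurements)), key), function(idx) {
    sub <- measurements[idx, ]
    cs <- conc[idx][sub$group == "sample"]
    cc <- conc[idx][sub$group == "control"]
    fc <- element_fold_change(cs, cc, lod = lod, method = fold_method)
    ok <- sum(!is.na(cs)) >= 2L && sum(!is.na(cc)) >= 2L
    p <- if (ok) mwu_test(cs[!is.na(cs)], cc[!is.na(cc)], sided = sided)
         else NA_real_
    data.frame(element = sub$element[1], isotope = sub$isotope[1],
               fold_change = fc$fold_change,
               is_lower_bound = fc$is_lower_bound,
               p_mwu = p, n_samples = sum(sub$group == "sample"),
               n_controls = sum(sub$group == "control"),
               evaluable = ok || fc$evaluable,
               stringsAsFactors = FALSE)
  })
  iso <- do.call(rbind, iso_rows)
  per_el <- do.call(rbind, lapply(split(iso, iso$element), combine_isotopes))
  per_el$in_supplement <- per_el$element %in% supplement_elements
  per_el <- per_el[order(!per_el$in_supplement, per_el$element),
                   c("element", "in_supplement", "fold_change",
                     "is_lower_bound", "p_mwu", "n_samples", "n_controls",
                     "evaluable")]
  names(per_el)[names(per_el) == "is_lower_bound"] <- "fold_is_lower_bound"
  rownames(per_el) <- NULL
  comb <- function(sel) {
    ps <- per_el$p_mwu[sel & !is.na(per_el$p_mwu)]
    if (length(ps)) mudholkar_george_combine(ps) else NA_real_
  }
  list(per_element = per_el,
       combined_p = list(supplement = comb(per_el$in_supplement),
                         additional = comb(!per_el$in_supplement)))
}
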