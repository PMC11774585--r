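# Variability statistics: coefficient of variation, mean-normalized
# permutation test, per-strain CoV ratio (kappa), Wilcoxon signed-rank test
# on log kappa, and the mean-vs-variability correlation permutation test.

# run expr with a locally seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean. The
#' package's replicability measure; a ranked alternative is deliberately
#' not offered because trace-element contamination is expected to produce
#' meaningful outliers.
#'
#' @param values Numeric vector, at least 2 values with non-zero mean.
#' @return A dimensionless number.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m == 0)
    stop("coefficient of variation undefined for zero mean", call. = FALSE)
  sd(values) / m
}

#' Permutation test for a difference in coefficients of variation
#'
#' Each group is first normalized by its own mean; the normalized values
#' are then pooled and randomly re-assigned to two groups of the original
#' sizes, recomputing the CoV difference each time. The test statistic is
#' `CoV(b) - CoV(a)`, so with `a` = supplemented and `b` = unsupplemented
#' replicates the one-sided test addresses whether omission increases
#' variability. Monte-Carlo p-values use the add-one (observed-included)
#' convention and are never 0; with `exhaustive = TRUE` all
#' `choose(na + nb, na)` splits are enumerated instead.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @param n_permutations Number of random re-assignments (default 10000).
#' @param sided `"one"` (default: statistic at least as large as observed)
#'   or `"two"` (absolute statistic).
#' @param seed Optional integer seed; the caller's RNG stream is restored.
#' @param exhaustive Enumerate all splits exactly (only sensible for small
#'   groups; limit `choose(na+nb, na) <= 2e5`).
#' @return List with `statistic`, `p.value`, `sided` and `n_permutations`.
#' @export
permutation_cov_test <- function(a, b, n_permutations = 10000,
                                 sided = c("one", "two"), seed = NULL,
                                 exhaustive = FALSE) {
  sided <- match.arg(sided)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  an <- a / mean(a)
  bn <- b / mean(b)
  pool <- c(an, bn)
  na <- length(a)
  n <- length(pool)
  if (sd(pool) == 0) {
    warning("degenerate groups: pooled values have zero variance; p = 1",
            call. = FALSE)
    return(list(statistic = 0, p.value = 1, sided = sided,
                n_permutations = 0L))
  }
  obs <- coefficient_of_variation(bn) - coefficient_of_variation(an)
  stat_of <- function(idx_a) {
    ga <- pool[idx_a]
    gb <- pool[-idx_a]
    (sd(gb) / mean(gb)) - (sd(ga) / mean(ga))
  }
  if (exhaustive) {
    if (choose(n, na) > 2e5)
      stop("too many splits for exhaustive enumeration", call. = FALSE)
    splits <- combn(n, na)
    stats <- apply(splits, 2, stat_of)
    p <- if (sided == "one") mean(stats >= obs - 1e-12)
         else mean(abs(stats) >= abs(obs) - 1e-12)
    return(list(statistic = obs, p.value = p, sided = sided,
                n_permutations = ncol(splits)))
  }
  B <- as.integer(n_permutations)
  stats <- with_local_seed(seed, {
    idx <- replicate(B, sample.int(n))
    m <- matrix(pool[idx], nrow = n)
    ga <- m[seq_len(na), , drop = FALSE]
    gb <- m[-seq_len(na), , drop = FALSE]
    ma <- colMeans(ga)
    mb <- colMeans(gb)
    sda <- sqrt((colSums(ga^2) - na * ma^2) / (na - 1))
    sdb <- sqrt((colSums(gb^2) - (n - na) * mb^2) / (n - na - 1))
    sdb / mb - sda / ma
  })
  k <- if (sided == "one") sum(stats >= obs - 1e-12)
       else sum(abs(stats) >= abs(obs) - 1e-12)
  list(statistic = obs, p.value = (k + 1) / (B + 1), sided = sided,
       n_permutations = B)
}

#' Ratio of coefficients of variation between paired conditions
#'
#' `kappa = (sd_with / mean_with) / (sd_without / mean_without)`; values
#' below 1 mean the supplemented condition is less variable.
#'
#' @param sd_with,mean_with,sd_without,mean_without Positive numbers.
#' @return A positive dimensionless ratio.
#' @export
kappa_ratio <- function(sd_with, mean_with, sd_without, mean_without) {
  if (any(c(sd_with, mean_with, sd_without, mean_without) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  (sd_with * mean_without) / (sd_without * mean_with)
}

#' Wilcoxon signed-rank test on log CoV ratios
#'
#' Tests the null hypothesis that the median of `log(kappa)` over strains
#' is zero. The logarithm makes the distribution symmetric under the null,
#' as the signed-rank test requires. Ratios exactly equal to 1 are dropped
#' before ranking. The exact signed-rank distribution is used for up to 25
#' strains (exhaustive sign enumeration when absolute log ratios tie); the
#' normal approximation takes over beyond that.
#'
#' @param kappas Positive CoV ratios, one per strain.
#' @return List with `median_kappa`, `p.value`, `n_used` and `method`.
#' @export
wilcoxon_log_kappa <- function(kappas) {
  kappas <- as.numeric(kappas)
  if (length(kappas) < 2L) stop("need at least 2 ratios", call. = FALSE)
  if (any(!is.finite(kappas) | kappas <= 0))
    stop("all ratios must be positive and finite", call. = FALSE)
  x <- log(kappas)
  x <- x[abs(x) > 1e-12]
  n <- length(x)
  med <- median(kappas)
  if (n == 0L)
    return(list(median_kappa = med, p.value = 1, n_used = 0L,
                method = "degenerate"))
  rk <- rank(abs(x))
  W <- sum(rk[x > 0])
  ties <- anyDuplicated(abs(x)) > 0
  if (!ties && n <= 25L) {
    pl <- psignrank(W, n)
    pg <- psignrank(W - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(pl, pg))
    method <- "exact"
  } else if (ties && n <= 15L) {
    # subset sums of the mid-ranks = all 2^n sign assignments
    ws <- 0
    for (r in rk) ws <- c(ws, ws + r)
    pl <- mean(ws <= W + 1e-9)
    pg <- mean(ws >= W - 1e-9)
    p <- min(1, 2 * min(pl, pg))
    method <- "exact_enumeration"
  } else {
    p <- suppressWarnings(
      wilcox.test(x, mu = 0, exact = FALSE, correct = TRUE)$p.value)
    method <- "normal_approximation"
  }
  list(median_kappa = med, p.value = p, n_used = n, method = method)
}

#' Permutation test for a correlation between means and variabilities
#'
#' Pearson correlation of the paired values, with a two-sided p-value from
#' randomly re-pairing the two vectors (shuffling `covs` against fixed
#' `means`). Used to rule out artefactual couplings such as larger yields
#' simply being measured more precisely.
#'
#' @param means,covs Numeric vectors of equal length (>= 3).
#' @param n_permutations Number of re-pairings (default 10000).
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all `n!` re-pairings (n <= 8).
#' @return List with `correlation`, `p.value` and `n_permutations`.
#' @export
correlation_permutation_test <- function(means, covs,
                                         n_permutations = 10000,
                                         seed = NULL, exhaustive = FALSE) {
  means <- as.numeric(means)
  covs <- as.numeric(covs)
  n <- length(means)
  if (n != length(covs) || n < 3L)
    stop("need two equal-length vectors of at least 3 values", call. = FALSE)
  if (sd(means) == 0 || sd(covs) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  obs <- cor(means, covs)
  xc <- means - mean(means)
  yc <- covs - mean(covs)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  if (exhaustive) {
    if (n > 8L) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    rs <- vapply(perms, function(p) sum(xc * yc[p]) / denom, numeric(1))
    p <- mean(abs(rs) >= abs(obs) - 1e-12)
    return(list(correlation = obs, p.value = p,
                n_permutations = length(perms)))
  }
  B <- as.integer(n_permutations)
  rs <- with_local_seed(seed, {
    idx <- replicate(B, sample.int(n))
    colSums(xc * matrix(yc[idx], nrow = n)) / denom
  })
  k <- sum(abs(rs) >= abs(obs) - 1e-12)
  list(correlation = obs, p.value = (k + 1) / (B + 1), n_permutations = B)
}

# all permutations of 1..n as a list (insert n into every position of each
# (n-1)-permutation); n <= 8
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in 0:(n - 1L)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos)
  }
  out
}
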