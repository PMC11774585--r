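# Constrained 2-D minimization used by the window searches: exhaustive
# lattice evaluation followed by a Powell-style direction-set finisher with
# a quadratic penalty on constraint violations.

# Exhaustive lattice search. `fn(x, y)` returns the objective (may be Inf).
# `order1`/`order2` give the axis iteration orders; iteration order encodes
# the tie-break (the first strictly-best point encountered wins).
grid_search_2d <- function(xs, ys, fn, descending1 = FALSE,
                           descending2 = FALSE) {
  if (descending1) xs <- rev(xs)
  if (descending2) ys <- rev(ys)
  best <- NULL
  for (x in xs) for (y in ys) {
    v <- fn(x, y)
    if (is.finite(v) && (is.null(best) || v < best$value))
      best <- list(par = c(x, y), value = v)
  }
  best
}

# Powell's direction-set method: cyclic line minimizations along a set of
# directions, replacing the direction of largest single-step decrease with
# the cycle's total displacement. Line searches use golden-section
# (stats::optimize) on a bracket scaled per direction. `tol` is a relative
# convergence tolerance on the objective; `maxit` caps the number of line
# minimizations.
powell_minimize <- function(fn, par, scale = pmax(abs(par), 1),
                            tol = 1e-6, maxit = 500L) {
  np <- length(par)
  dirs <- diag(scale, np)
  x <- par
  fx <- fn(x)
  nlm <- 0L
  line_min <- function(x0, f0, d) {
    g <- function(a) fn(x0 + a * d)
    o <- optimize(g, c(-1, 1), tol = 1e-4)
    if (o$objective < f0) list(x = x0 + o$minimum * d, f = o$objective)
    else list(x = x0, f = f0)
  }
  repeat {
    x0 <- x
    f0 <- fx
    biggest <- 0
    ibig <- 1L
    for (i in seq_len(np)) {
      res <- line_min(x, fx, dirs[, i])
      if (fx - res$f > biggest) {
        biggest <- fx - res$f
        ibig <- i
      }
      x <- res$x
      fx <- res$f
      nlm <- nlm + 1L
      if (nlm >= maxit) break
    }
    if (nlm >= maxit) break
    if (2 * (f0 - fx) <= tol * (abs(f0) + abs(fx) + 1e-12)) break
    d_new <- x - x0
    if (sqrt(sum(d_new^2)) > 0) {
      res <- line_min(x, fx, d_new)
      x <- res$x
      fx <- res$f
      nlm <- nlm + 1L
      dirs[, ibig] <- d_new
    }
  }
  list(par = x, value = fx, n_line_min = nlm)
}
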