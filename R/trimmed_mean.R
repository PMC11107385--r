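# Trimmed-mean machinery: the alpha-trimmed mean, Jaeckel's discrete
# estimate of its asymptotic variance, and data-driven selection of the trim
# fraction by minimizing that estimate over the order-statistic grid.

# Number of observations trimmed from each tail. [alpha*n] is floor(alpha*n);
# the small nudge keeps alpha = t/n mapping to exactly t when t/n is not
# representable in binary floating point.
trim_count <- function(alpha, n) {
  as.integer(floor(alpha * n + 1e-9))
}

check_alpha <- function(alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0 || alpha >= 0.5) {
    stop("alpha must be a single value in [0, 0.5)")
  }
}

#' Alpha-trimmed mean
#'
#' Sorts `x`, removes `floor(alpha * n)` observations from each tail, and
#' returns the arithmetic mean of the remainder.
#'
#' @param x numeric vector.
#' @param alpha trim fraction in `[0, 0.5)`.
#' @return scalar trimmed mean.
#' @examples
#' alpha_trimmed_mean(c(1, 2, 3, 4, 100), 0.2) # 3
#' @export
alpha_trimmed_mean <- function(x, alpha) {
  check_alpha(alpha)
  x <- as.numeric(x)
  if (length(x) < 1L || anyNA(x)) stop("x must be a non-empty numeric vector without NA")
  n <- length(x)
  t <- trim_count(alpha, n)
  if (n - 2L * t < 1L) {
    stop(sprintf("trimming removes all data (n = %d, alpha = %g)", n, alpha))
  }
  s <- sort(x)
  mean(s[(t + 1L):(n - t)])
}

#' Jaeckel's estimate of the trimmed mean's asymptotic variance
#'
#' The discrete plug-in estimator
#' \deqn{V_n(\alpha) = \frac{1}{(1-2\alpha)^2}\left\{\frac{1}{n}
#'   \sum_{i=t+1}^{n-t}(x_{(i)} - \mu_n(\alpha))^2
#'   + \alpha (x_{(t+1)} - \mu_n(\alpha))^2
#'   + \alpha (x_{(n-t)} - \mu_n(\alpha))^2\right\}}
#' with \eqn{t = \lfloor\alpha n\rfloor}, \eqn{x_{(i)}} the order statistics
#' and \eqn{\mu_n(\alpha)} the alpha-trimmed mean. At `alpha = 0` this is the
#' mean squared deviation.
#'
#' @inheritParams alpha_trimmed_mean
#' @return non-negative scalar.
#' @export
jaeckel_variance <- function(x, alpha) {
  check_alpha(alpha)
  x <- as.numeric(x)
  if (length(x) < 1L || anyNA(x)) stop("x must be a non-empty numeric vector without NA")
  n <- length(x)
  t <- trim_count(alpha, n)
  if (n - 2L * t < 1L) {
    stop(sprintf("trimming removes all data (n = %d, alpha = %g)", n, alpha))
  }
  s <- sort(x)
  win <- s[(t + 1L):(n - t)]
  mu <- mean(win)
  core <- sum((win - mu)^2) / n +
    alpha * (s[t + 1L] - mu)^2 +
    alpha * (s[n - t] - mu)^2
  core / (1 - 2 * alpha)^2
}

#' Data-driven trim fraction by Jaeckel variance minimization
#'
#' Evaluates \eqn{V_n(\alpha)} on the grid of order-statistic breakpoints
#' `alpha = t/n` for integer trim counts `t` with
#' `t/n < min(delta, (n - 1) / (2 * n))` and returns the minimizer. Between
#' breakpoints the trimmed window is constant, so the grid covers every
#' distinct trim; ties are broken toward the smallest alpha (least data
#' discarded). The sweep uses prefix sums (O(n) after one sort); the
#' returned `vmin` is recomputed with [jaeckel_variance()] so that
#' `vmin == jaeckel_variance(x, alpha)` exactly.
#'
#' @param x numeric vector, length >= 3.
#' @param delta upper bound of the search interval, in `(0, 0.5]`.
#' @return list with elements `alpha` (optimal trim fraction) and `vmin`
#'   (the minimized variance estimate).
#' @export
optimal_alpha <- function(x, delta = 0.5) {
  grid <- jaeckel_grid(x, delta)
  # ties and sweep-vs-direct rounding: re-evaluate near-minimal candidates
  # directly so the argmin (smallest alpha on ties) matches a literal
  # evaluation of V_n
  vmin_sweep <- min(grid$v)
  cand <- which(grid$v - vmin_sweep <= 1e-9 * max(abs(vmin_sweep), 1e-12))
  vd <- vapply(grid$alpha[cand], function(a) jaeckel_variance(x, a), numeric(1))
  a_opt <- grid$alpha[cand[which.min(vd)]]
  list(alpha = a_opt, vmin = jaeckel_variance(x, a_opt))
}

# V_n(alpha) over the whole order-statistic grid {t/n : t/n < min(delta,
# (n-1)/(2n))} in one O(n) prefix-sum sweep after sorting. Returns the grid
# and the variance estimates, plus the window size n - 2t per candidate.
jaeckel_grid <- function(x, delta = 0.5) {
  if (length(delta) != 1L || !is.finite(delta) || delta <= 0 || delta > 0.5) {
    stop("delta must be a single value in (0, 0.5]")
  }
  x <- as.numeric(x)
  if (length(x) < 3L || anyNA(x)) stop("x must have length >= 3 with no NA")
  n <- length(x)
  bound <- min(delta, (n - 1) / (2 * n))
  t_max <- as.integer(ceiling(bound * n) - 1L)
  while (t_max >= 0L && t_max / n >= bound) t_max <- t_max - 1L
  if (t_max < 0L) stop("no admissible trim fraction below delta")

  s <- sort(x)
  cs <- cumsum(s)
  cs2 <- cumsum(s * s)
  ts <- 0L:t_max
  cnt <- n - 2L * ts
  sw <- cs[n - ts] - c(0, cs)[ts + 1L]
  ssw <- cs2[n - ts] - c(0, cs2)[ts + 1L]
  mu <- sw / cnt
  css <- pmax(ssw - cnt * mu^2, 0)
  alpha <- ts / n
  v <- (css / n + alpha * (s[ts + 1L] - mu)^2 + alpha * (s[n - ts] - mu)^2) /
    (1 - 2 * alpha)^2
  list(alpha = alpha, v = v, window = cnt)
}
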