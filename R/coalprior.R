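# Predata coalescent model: waiting-time simulation, closed-form moments,
# the Watterson ancestor probability, and the Poisson mutation-count law.

#' Sample coalescent waiting times
#'
#' Draws the waiting times `w_j`, `j = 2..n`, of Kingman's coalescent:
#' independent exponentials with rate `j(j-1)/2`, in units of `N`
#' generations.  Sampling uses the inverse-CDF transform
#' `w_j = -2/(j(j-1)) * log(1 - u)` with one fresh `u ~ U(0,1)` per `j`,
#' drawn in the fixed order `j = 2, ..., n` from R's RNG stream (seed with
#' [set.seed()]).
#'
#' @param n Sample size, `n >= 2`.
#' @return An object of class `waiting_times`: `n`, `w` (named vector,
#'   `w["2"] ... w["n"]`), `t_n = sum(w)` (tree height, TMRCA) and
#'   `l_n = sum(j * w_j)` (tree length).
#' @export
sample_waiting_times <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("n must be a single integer >= 2")
  j <- 2:n
  u <- stats::runif(n - 1L)
  w <- -2 / (j * (j - 1)) * log1p(-u)
  waiting_times(w, n = n)
}

#' Construct a waiting-times object from a vector
#'
#' @param w Positive vector of waiting times `(w_2, ..., w_n)`.
#' @param n Sample size; defaults to `length(w) + 1`.
#' @return A `waiting_times` object (see [sample_waiting_times()]).
#' @export
waiting_times <- function(w, n = length(w) + 1L) {
  w <- as.numeric(w)
  if (length(w) != n - 1L)
    stop("w must have length n - 1 (one entry per j = 2..n)")
  if (any(w < 0)) stop("waiting times must be positive")
  j <- 2:n
  names(w) <- j
  structure(list(n = as.integer(n), w = w,
                 t_n = sum(w), l_n = sum(j * w)),
            class = "waiting_times")
}

#' @export
print.waiting_times <- function(x, ...) {
  cat(sprintf("waiting_times: n = %d, t_n = %.4f, l_n = %.4f (N generations)\n",
              x$n, x$t_n, x$l_n))
  invisible(x)
}

#' Vectorised predata simulation of tree height and length
#'
#' Simulates `M` independent replicates of `(t_n, l_n)` using the same
#' inverse-CDF transform as [sample_waiting_times()], accumulating over
#' `j = 2..n` without storing the full waiting-time matrix.
#'
#' @param n Sample size, `>= 2`.
#' @param M Number of replicates.
#' @return List with numeric vectors `t` and `l` of length `M`.
#' @export
simulate_predata <- function(n, M) {
  if (n < 2) stop("n must be >= 2")
  t_acc <- numeric(M)
  l_acc <- numeric(M)
  for (j in 2:n) {
    w <- -2 / (j * (j - 1)) * log1p(-stats::runif(M))
    t_acc <- t_acc + w
    l_acc <- l_acc + j * w
  }
  list(t = t_acc, l = l_acc)
}

#' Closed-form predata moments of tree height and length
#'
#' Kingman's moments for the TMRCA `t_n` and tree length `l_n` of a sample
#' of size `n`, in units of `N` generations:
#' `E(t_n) = 2(1 - 1/n)`,
#' `Var(t_n) = 8 * sum_{j=2}^{n} 1/j^2 - 4 (1 - 1/n)^2`,
#' `E(l_n) = 2 * sum_{j=1}^{n-1} 1/j`,
#' `Var(l_n) = 4 * sum_{j=1}^{n-1} 1/j^2`.
#'
#' @param n Sample size, `>= 2`.
#' @return List of class `predata_moments` with `mean_t`, `var_t`,
#'   `mean_l`, `var_l`.
#' @export
predata_moments <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("n must be a single integer >= 2")
  j2 <- 2:n
  j1 <- 1:(n - 1)
  structure(
    list(n = as.integer(n),
         mean_t = 2 * (1 - 1 / n),
         var_t = 8 * sum(1 / j2^2) - 4 * (1 - 1 / n)^2,
         mean_l = 2 * sum(1 / j1),
         var_l = 4 * sum(1 / j1^2)),
    class = "predata_moments")
}

#' @export
print.predata_moments <- function(x, ...) {
  cat(sprintf(paste0(
    "predata moments (n = %d, units of N generations):\n",
    "  E(t_n) = %.6f   Var(t_n) = %.6f\n",
    "  E(l_n) = %.6f   Var(l_n) = %.6f\n"),
    x$n, x$mean_t, x$var_t, x$mean_l, x$var_l))
  invisible(x)
}

#' Probability that the whole population coalesces with the sample
#'
#' Watterson's probability that, at the TMRCA of a random sample of size
#' `n` from a population of size `N`, the population has a single ancestor:
#' `P = (n-1)(N+1) / ((n+1)(N-1))`.
#'
#' @param n Sample size, `2 <= n <= N`.
#' @param N Population size, `> 1`.
#' @return The probability.
#' @export
ancestor_probability <- function(n, N) {
  if (n < 2) stop("n must be >= 2")
  if (N <= 1) stop("N must exceed 1")
  if (n > N) stop("sample size n cannot exceed population size N")
  (n - 1) * (N + 1) / ((n + 1) * (N - 1))
}

#' Poisson law of the mutation count given tree length
#'
#' Given tree length `l` (units of `N` generations) and scaled mutation
#' rate `theta`, the number of mutations in the sample is
#' `Poisson(theta * l / 2)`.
#'
#' @param k Non-negative integer count(s).
#' @param l Tree length(s), `> 0`; `k` and `l` are vectorised together.
#' @param theta Scaled mutation rate `2 N mu`, `>= 0`.
#' @return `P(s_n = k | l_n = l)`.
#' @export
mutation_count_pmf <- function(k, l, theta) {
  if (any(k < 0) || any(k != round(k))) stop("k must be non-negative integer")
  if (any(l <= 0)) stop("l must be positive")
  if (theta < 0) stop("theta must be non-negative")
  stats::dpois(k, theta * l / 2)
}

#' Convert coalescent time to years
#'
#' Times are in units of `N` generations throughout the package; this is
#' the one explicit conversion, `t * N * Y`, where `Y` is the average
#' generation time in years (commonly 20-25 for humans).  No default `Y` is
#' applied.
#'
#' @param t Time in units of `N` generations.
#' @param N Population size.
#' @param Y Years per generation.
#' @return Time in years.
#' @export
to_years <- function(t, N, Y) {
  if (N <= 0 || Y <= 0) stop("N and Y must be positive")
  if (any(t < 0)) stop("t must be non-negative")
  t * N * Y
}
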