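#' Distribution of the maximum clonal size before extinction
#'
#' Builds the probability mass function of \eqn{X_{i_0}^{max}}, the largest
#' size the clonotype ever attains starting from `i0` cells, truncated so
#' that at least a fraction `q_max` of the probability mass is covered. The
#' pmf follows from the reach probabilities by
#' \eqn{P(X^{max} \ge i_\varrho) = v_{i_0,i_\varrho}} (equal to 1 for
#' \eqn{i_\varrho \le i_0}), so
#' \eqn{P(X^{max} = i_\varrho) = v_{i_0,i_\varrho} - v_{i_0,i_\varrho+1}}.
#' The support is grown until the cumulative mass strictly exceeds `q_max`;
#' its top point is the `100*q_max` percentile \eqn{K_{q_{max}}}.
#'
#' In friendly niches this pmf is bimodal — one mode at (or near) `i0`
#' corresponding to early extinction, the other far away corresponding to
#' establishment in the periphery.
#'
#' @inheritParams reach_probability
#' @param i0 Initial clonal size, >= 1 (1 for a recent thymic emigrant).
#' @param q_max Truncation quantile in (0, 1); default 0.99 (0.999 is useful
#'   when `K_0.99` collapses to `i0`).
#' @return An object of class `xmax_distribution`: list with `pmf` (tibble
#'   of `size`, `pmf`, `survival` \eqn{= P(X^{max} \ge size)}, `cdf`), `i0`,
#'   `q_max`, `covered_mass`, `surv_next` \eqn{= v_{i_0,K+1}}, and the
#'   `ladder` used.
#' @examples
#' xd <- xmax_distribution(clone_params(phi = 5), i0 = 1)
#' xmax_mean(xd)
#' xmax_percentile(xd, c(0.25, 0.5, 0.75, 0.99))
#' @export
xmax_distribution <- function(params, i0 = 1, q_max = 0.99, ladder = NULL) {
  params <- as_clone_params(params)
  stopifnot(i0 >= 1, i0 == floor(i0))
  if (length(q_max) != 1L || q_max <= 0 || q_max >= 1)
    stop("`q_max` must be in (0, 1)", call. = FALSE)
  cap <- max(2 * i0 + 10, 20)
  repeat {
    ladder <- if (is.null(ladder)) rate_ladder(params, cap + 1)
              else ladder_extend(ladder, cap + 1)
    # v_{i0, x} for x = i0..cap+1: shared numerator, prefix-sum denominators
    lz <- ladder$log_zeta
    num <- logsumexp(lz[1:i0])
    den <- cumlogsumexp(lz[1:(cap + 1)])       # den[x] over zeta_0..zeta_{x-1}
    v <- c(rep(1, i0), exp(num - den[(i0 + 1):(cap + 1)])) # v at x = 1..cap+1
    cdf <- 1 - v[(i0 + 1):(cap + 1)]           # P(Xmax <= x), x = i0..cap
    if (cdf_above(cdf[length(cdf) - 1], q_max)) break
    cap <- 2 * cap
  }
  xs <- i0:cap
  K <- xs[which(cdf_above(cdf, q_max))[1]] # strict: first x with cdf > q_max
  keep <- 1:(K - i0 + 1)
  sizes <- xs[keep]
  surv <- v[sizes]
  pmf <- surv - v[sizes + 1]
  structure(
    list(pmf = tibble::tibble(size = sizes, pmf = pmf, survival = surv,
                              cdf = cdf[keep]),
         i0 = as.integer(i0), q_max = q_max,
         covered_mass = 1 - v[K + 1], surv_next = v[K + 1],
         params = params, ladder = ladder),
    class = "xmax_distribution"
  )
}

#' @export
print.xmax_distribution <- function(x, ...) {
  cat(sprintf(
    "<xmax_distribution> i0 = %d, support %d..%d, covered mass %.5f (q_max = %g)\n",
    x$i0, x$pmf$size[1], max(x$pmf$size), x$covered_mass, x$q_max))
  invisible(x)
}

#' Percentiles of the maximum clonal size
#'
#' \eqn{K_q} is the first size \eqn{x \ge 1} whose cumulative probability
#' \eqn{P(X^{max} \le x)} strictly exceeds `q` (ties at the cumulative value
#' are pushed to the next size, the convention under which the percentile
#' marks a size actually exceeded with probability `> 1 - q`).
#'
#' @param dist An [xmax_distribution()].
#' @param q Probability level(s), each `<= q_max` of `dist`.
#' @return Integer percentile(s) \eqn{K_q}.
#' @export
xmax_percentile <- function(dist, q) {
  stopifnot(inherits(dist, "xmax_distribution"))
  if (any(q <= 0)) stop("`q` must be positive", call. = FALSE)
  if (any(q > dist$q_max))
    stop("`q` exceeds the truncation level `q_max`; rebuild the ",
         "distribution with a larger `q_max`", call. = FALSE)
  vapply(q, function(qq) dist$pmf$size[which(cdf_above(dist$pmf$cdf, qq))[1]],
         integer(1))
}

# strict comparison with a guard so that exact ties (cdf == q up to float
# rounding of the zeta sums) are pushed to the next size, never resolved by
# the sign of a ~1e-16 error
cdf_above <- function(cdf, q) cdf > q + 1e-12

#' Truncated mean of the maximum clonal size
#'
#' \eqn{E[X^{max}]} computed over the truncated support
#' \eqn{i_0 \le i_\varrho \le K_{q_{max}}} (the residual tail series has no
#' tractable closed form; the neglected mass is below `1 - q_max`).
#'
#' @param dist An [xmax_distribution()].
#' @return The truncated expectation (cells).
#' @export
xmax_mean <- function(dist) {
  stopifnot(inherits(dist, "xmax_distribution"))
  sum(dist$pmf$size * dist$pmf$pmf)
}

#' Truncated probability of the maximum reaching a percentile size
#'
#' \eqn{\tilde P(X^{max} \ge K_q) = P(K_{q_{max}} \ge X^{max} \ge K_q)
#' = v_{i_0,K_q} - v_{i_0,K_{q_{max}}+1}}: the version of the reach
#' probability consistent with the truncated support, which for
#' \eqn{K_q = i_0} equals the total truncated mass.
#'
#' @param dist An [xmax_distribution()].
#' @param q Probability level(s), each `<= q_max`.
#' @return Truncated probabilities.
#' @export
xmax_truncated_prob <- function(dist, q) {
  K <- xmax_percentile(dist, q)
  dist$pmf$survival[match(K, dist$pmf$size)] - dist$surv_next
}

#' Truncated moments of the time to the maximum clonal size
#'
#' Moments of \eqn{T_{i_0}^{max}} by conditioning on the maximum:
#' \deqn{m^{max,(k)}_{i_0} \approx \sum_{i_\varrho=i_0+1}^{K_{q_{max}}}
#'   m^{(k)}_{i_0,i_\varrho}
#'   \Bigl(1 - \frac{v_{i_0,i_\varrho+1}}{v_{i_0,i_\varrho}}\Bigr),}
#' the finite-sum truncation of the exact series at the `q_max` percentile,
#' leaving a global error bounded by the neglected mass `1 - q_max` (times
#' the tail conditional moments).
#'
#' @inheritParams xmax_distribution
#' @param k_max Highest moment order.
#' @return Numeric vector of length `k_max`, the orders `1..k_max`.
#' @examples
#' tmax_moments(clone_params(phi = 0.1), i0 = 1, k_max = 1) # 0.07834
#' @export
tmax_moments <- function(params, i0 = 1, k_max = 1, q_max = 0.99,
                         ladder = NULL) {
  dist <- xmax_distribution(params, i0 = i0, q_max = q_max, ladder = ladder)
  restricted_max_sum(dist, k_max, expansion_moments)
}

# shared truncated-series accumulator for Tmax (restricted time moments)
# and Nmax (restricted factorial division moments)
restricted_max_sum <- function(dist, k_max, moment_fun) {
  i0 <- dist$i0
  K <- max(dist$pmf$size)
  out <- numeric(k_max)
  if (K <= i0) return(out)
  surv <- c(dist$pmf$survival, dist$surv_next) # v at i0..K+1
  for (i_rho in (i0 + 1):K) {
    w <- 1 - surv[i_rho - i0 + 2] / surv[i_rho - i0 + 1]
    mm <- moment_fun(dist$params, i_rho, k_max = k_max, ladder = dist$ladder)
    out <- out + mm$m[2:(k_max + 1), i0 + 1] * w
  }
  out
}
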