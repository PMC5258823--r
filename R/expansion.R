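#' Probability of expansion to a target clonal size before extinction
#'
#' The reach probability \eqn{v_{i,i_\varrho} = P(T_{i,i_\varrho} < \infty)}
#' that a clonotype starting at size `i` attains size `i_rho` before
#' absorption at 0. By the gambler's-ruin closed form,
#' \deqn{v_{i,i_\varrho} = \frac{\sum_{k=0}^{i-1} \zeta_k}
#'                              {\sum_{m=0}^{i_\varrho-1} \zeta_m},}
#' evaluated in log space via the [rate_ladder()]. It equals
#' \eqn{P(X_i^{max} \ge i_\varrho)}, the survival function of the maximum
#' clonal size, and also \eqn{P(N_{i,i_\varrho} < \infty)} for the division
#' count.
#'
#' @inheritParams birth_rate
#' @param i Starting clonal size, `0 <= i <= i_rho`.
#' @param i_rho Target clonal size, >= 1.
#' @param ladder Optional pre-built [rate_ladder()] (saves re-tabulation).
#' @return A probability in `[0, 1]`.
#' @examples
#' # hard niche phi = mu = 1: zeta_k = k!, v_{1,5} = 1/(1+1+2+6+24)
#' reach_probability(clone_params(phi = 1), 1, 5)
#' @export
reach_probability <- function(params, i, i_rho, ladder = NULL) {
  params <- as_clone_params(params)
  stopifnot(length(i) == 1L, length(i_rho) == 1L, i_rho >= 1)
  if (i < 0) stop("`i` must be >= 0", call. = FALSE)
  if (i > i_rho)
    stop("`i` > `i_rho`: reaching a smaller size is certain; ",
         "see contraction_moments() for its timing", call. = FALSE)
  if (i == 0) return(0)
  if (i == i_rho) return(1)
  if (is.null(ladder)) ladder <- rate_ladder(params, i_rho)
  reach_prob_vec(ladder, i_rho)[i + 1]
}

# v_{i,i_rho} for i = 0..i_rho (vector indexed i + 1), log-space sums
reach_prob_vec <- function(ladder, i_rho) {
  lz <- ladder$log_zeta[1:i_rho] # log zeta_0 .. zeta_{i_rho - 1}
  den <- logsumexp(lz)
  num <- cumlogsumexp(lz)
  c(0, exp(num - den))
}

# running log-sum-exp of a vector (streaming pairwise update; a single
# global shift would underflow the early prefixes when the ladder spans
# hundreds of orders of magnitude)
cumlogsumexp <- function(x) {
  out <- numeric(length(x))
  acc <- -Inf
  for (k in seq_along(x)) {
    m <- max(acc, x[k])
    acc <- if (is.infinite(m) && m < 0) -Inf
           else m + log(exp(acc - m) + exp(x[k] - m))
    out[k] <- acc
  }
  out
}

#' Restricted Laplace-Stieltjes transform of the expansion time
#'
#' \eqn{\phi_{i,i_\varrho}(s) = E[e^{-sT_{i,i_\varrho}}
#' 1\{T_{i,i_\varrho}<\infty\}]}, the transform of the (defective) time to
#' expand from `i` to `i_rho`, restricted to the event that `i_rho` is
#' reached. Evaluated by the continued-fraction product form
#' \deqn{\phi_{i,i_\varrho}(s) = \prod_{k=i}^{i_\varrho - 1}
#'       \frac{\lambda_k}{s + g_k(s) + \lambda_k},}
#' where \eqn{g_1(s) = \mu_1} and
#' \eqn{g_k(s) = \mu_k (s + g_{k-1}(s))/(s + \lambda_{k-1} + g_{k-1}(s))},
#' obtained from forward elimination of the first-step tridiagonal system.
#' At `s = 0` this reduces to [reach_probability()].
#'
#' @inheritParams reach_probability
#' @param s Transform argument, >= 0.
#' @return The transform value in `[0, 1]`.
#' @export
expansion_lst <- function(params, i, i_rho, s, ladder = NULL) {
  params <- as_clone_params(params)
  stopifnot(length(s) == 1L, is.finite(s))
  if (s < 0) stop("`s` must be >= 0", call. = FALSE)
  if (i < 0 || i > i_rho) stop("need 0 <= i <= i_rho", call. = FALSE)
  if (i == 0) return(0)
  if (i == i_rho) return(1)
  if (is.null(ladder)) ladder <- rate_ladder(params, i_rho)
  lam <- ladder$birth
  dth <- ladder$death
  g <- dth[2] # g_1 = mu_1
  logphi <- 0
  for (k in 1:(i_rho - 1)) {
    if (k >= 2) g <- dth[k + 1] * (s + g) / (s + lam[k] + g)
    if (k >= i) logphi <- logphi + log(lam[k + 1]) - log(s + g + lam[k + 1])
  }
  exp(logphi)
}

#' Restricted moments of the time to expansion
#'
#' Computes \eqn{m^{(k)}_{i,i_\varrho} = E[T_{i,i_\varrho}^k;
#' T_{i,i_\varrho} < \infty]} for all starting sizes `0 <= i <= i_rho` and
#' orders `0 <= k <= k_max`. Order 0 is the reach probability. Orders are
#' solved ascending: each satisfies the tridiagonal first-step system
#' \deqn{(\lambda_i+\mu_i) m^{(k)}_i = \mu_i m^{(k)}_{i-1} +
#'       \lambda_i m^{(k)}_{i+1} + k\, m^{(k-1)}_i,}
#' with \eqn{m^{(k)}_0 = m^{(k)}_{i_\varrho} = 0} for `k >= 1`, solved by a
#' forward-elimination sweep in which every intermediate quantity is
#' positive, so no cancellation occurs even when the moments span forty
#' orders of magnitude.
#'
#' @inheritParams reach_probability
#' @param k_max Highest moment order, >= 1.
#' @return An object of class `restricted_moments`: list with `m` (a
#'   `(k_max+1) x (i_rho+1)` matrix, entry `[k+1, i+1]` holding
#'   \eqn{m^{(k)}_{i,i_\varrho}}), `v` (the reach probabilities), `i_rho`,
#'   `k_max`.
#' @export
expansion_moments <- function(params, i_rho, k_max = 2, ladder = NULL) {
  params <- as_clone_params(params)
  stopifnot(i_rho >= 1, k_max >= 1)
  if (is.null(ladder)) ladder <- rate_ladder(params, i_rho)
  v <- reach_prob_vec(ladder, i_rho)
  m <- matrix(0, k_max + 1, i_rho + 1)
  m[1, ] <- v
  for (k in seq_len(k_max)) {
    rhs <- k * m[k, ] # k * m^{(k-1)}_i at interior states
    m[k + 1, ] <- tridiag_sweep(ladder, i_rho, rhs)
  }
  structure(list(m = m, v = v, i_rho = as.integer(i_rho),
                 k_max = as.integer(k_max)),
            class = "restricted_moments")
}

# solve (lam_i+mu_i) x_i = mu_i x_{i-1} + lam_i x_{i+1} + r_i,
# x_0 = x_{i_rho} = 0, by forward elimination + back substitution;
# all coefficients positive -> stable. r is indexed i + 1.
tridiag_sweep <- function(ladder, i_rho, r) {
  if (i_rho == 1) return(c(0, 0))
  lam <- ladder$birth
  dth <- ladder$death
  A <- numeric(i_rho - 1) # x_i = A_i x_{i+1} + B_i
  B <- numeric(i_rho - 1)
  Aprev <- 0; Bprev <- 0
  for (i in 1:(i_rho - 1)) {
    den <- lam[i + 1] + dth[i + 1] - dth[i + 1] * Aprev
    A[i] <- lam[i + 1] / den
    B[i] <- (r[i + 1] + dth[i + 1] * Bprev) / den
    Aprev <- A[i]; Bprev <- B[i]
  }
  x <- numeric(i_rho + 1)
  for (i in (i_rho - 1):1) x[i + 1] <- A[i] * x[i + 2] + B[i]
  x
}

#' @export
print.restricted_moments <- function(x, ...) {
  cat(sprintf("<restricted_moments> target i_rho = %d, orders 0..%d\n",
              x$i_rho, x$k_max))
  invisible(x)
}

#' Conditional mean and standard deviation of the expansion time
#'
#' Mean and standard deviation of \eqn{T_{i_0,i_\varrho}} *given* that size
#' `i_rho` is reached before extinction: the restricted moments divided by
#' the reach probability. For `i_rho = i0 + 1 = 2` the conditional time is
#' exactly exponential with rate \eqn{\lambda_1 + \mu_1}, so mean and sd
#' coincide.
#'
#' @inheritParams reach_probability
#' @param i0 Starting clonal size, `< i_rho`.
#' @return A tibble with columns `i0`, `i_rho`, `prob` (reach probability),
#'   `mean`, `sd`.
#' @export
conditional_passage_stats <- function(params, i0, i_rho, ladder = NULL) {
  params <- as_clone_params(params)
  stopifnot(i0 >= 0, i0 < i_rho)
  em <- expansion_moments(params, i_rho, k_max = 2, ladder = ladder)
  v <- em$v[i0 + 1]
  if (v == 0) stop("reach probability is 0: conditioning undefined", call. = FALSE)
  mean <- em$m[2, i0 + 1] / v
  var <- em$m[3, i0 + 1] / v - mean^2
  tibble::tibble(i0 = i0, i_rho = i_rho, prob = v,
                 mean = mean, sd = sqrt(max(var, 0)))
}
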