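#' Probability mass function of the division count to a target size
#'
#' \eqn{N_{i,i_\varrho}} is the number of proliferation (birth) events the
#' clonotype registers before first touching size `i_rho`; it is defective
#' (infinite if extinction intervenes), with total finite mass equal to the
#' reach probability \eqn{v_{i,i_\varrho}}. The pmf is computed by the
#' embedded-chain first-step recursion
#' \deqn{\tilde x^j_i = \frac{\mu_i}{\lambda_i+\mu_i}\tilde x^j_{i-1} +
#'       \frac{\lambda_i}{\lambda_i+\mu_i}\tilde x^{j-1}_{i+1},}
#' swept with `j` ascending and `i` ascending inside each `j`, from the
#' boundaries \eqn{\tilde x^j_0 = 0}, \eqn{\tilde x^j_{i_\varrho} = 1\{j=0\}}.
#' At least `i_rho - i` births are needed, so the pmf vanishes below that.
#'
#' `j_max` is chosen adaptively: the recursion is extended until the missing
#' mass `v - sum_j P(N = j)` at every start size falls below `tol`, or the
#' hard cap is hit.
#'
#' @inheritParams reach_probability
#' @param j_max Optional fixed number of divisions to tabulate; default
#'   adaptive.
#' @param tol Mass deficit tolerance for the adaptive rule.
#' @param j_cap Hard cap on the adaptive extension.
#' @return An object of class `division_count_pmf`: list with `probs`
#'   (matrix, rows `i = 0..i_rho`, cols `j = 0..j_max`), `v`, `i_rho`,
#'   `j_max`, `deficit` (per start size).
#' @export
division_count_pmf <- function(params, i_rho, j_max = NULL, tol = 1e-8,
                               j_cap = 100000L, ladder = NULL) {
  params <- as_clone_params(params)
  stopifnot(i_rho >= 1)
  if (is.null(ladder)) ladder <- rate_ladder(params, i_rho)
  v <- reach_prob_vec(ladder, i_rho)
  lam <- ladder$birth
  dth <- ladder$death
  pb <- lam / (lam + dth) # birth probability of the embedded chain
  pb[1] <- 0
  adaptive <- is.null(j_max)
  jm <- if (adaptive) max(4L * i_rho, 32L) else j_max
  if (jm < i_rho - 1) stop("`j_max` must be >= i_rho - i births", call. = FALSE)
  repeat {
    probs <- matrix(0, i_rho + 1, jm + 1)
    probs[i_rho + 1, 1] <- 1 # already at target: N = 0
    if (i_rho >= 2 || jm >= 1) {
      for (j in seq_len(jm)) {
        prev <- probs[, j]
        if (i_rho >= 2) {
          for (i in 1:(i_rho - 1)) {
            probs[i + 1, j + 1] <- (1 - pb[i + 1]) * probs[i, j + 1] +
              pb[i + 1] * prev[i + 2]
          }
        }
      }
    }
    deficit <- v - rowSums(probs)
    deficit[i_rho + 1] <- 0
    if (!adaptive || max(deficit) < tol || jm >= j_cap) break
    jm <- min(2L * jm, j_cap)
  }
  structure(list(probs = probs, v = v, i_rho = as.integer(i_rho),
                 j_max = as.integer(jm), deficit = deficit),
            class = "division_count_pmf")
}

#' @export
print.division_count_pmf <- function(x, ...) {
  cat(sprintf("<division_count_pmf> target i_rho = %d, j up to %d (max mass deficit %.2e)\n",
              x$i_rho, x$j_max, max(x$deficit)))
  invisible(x)
}

#' Restricted factorial moments of the division count
#'
#' \eqn{\tilde m^{(k)}_{i,i_\varrho} = E[N(N-1)\cdots(N-k+1);
#' N_{i,i_\varrho} < \infty]}, computed with orders ascending from the
#' first-step system
#' \deqn{(\lambda_i+\mu_i)\tilde m^{(k)}_i = \mu_i \tilde m^{(k)}_{i-1} +
#'       \lambda_i \tilde m^{(k)}_{i+1} +
#'       \lambda_i k\, \tilde m^{(k-1)}_{i+1},}
#' solved by the same stable forward-elimination sweep as
#' [expansion_moments()] (only the inhomogeneous term differs: the counted
#' transition contributes through the post-birth state).
#'
#' @inheritParams expansion_moments
#' @return An object of class `restricted_moments` (factorial moments in
#'   `m`).
#' @export
division_factorial_moments <- function(params, i_rho, k_max = 2,
                                       ladder = NULL) {
  params <- as_clone_params(params)
  stopifnot(i_rho >= 1, k_max >= 1)
  if (is.null(ladder)) ladder <- rate_ladder(params, i_rho)
  v <- reach_prob_vec(ladder, i_rho)
  m <- matrix(0, k_max + 1, i_rho + 1)
  m[1, ] <- v
  lam <- ladder$birth[1:(i_rho + 1)]
  for (k in seq_len(k_max)) {
    prev <- c(m[k, -1], 0) # m^{(k-1)}_{i+1}, with target boundary 0
    prev[i_rho + 1] <- 0   # r at i = i_rho unused by the sweep
    rhs <- lam * k * prev
    m[k + 1, ] <- tridiag_sweep(ladder, i_rho, rhs)
  }
  structure(list(m = m, v = v, i_rho = as.integer(i_rho),
                 k_max = as.integer(k_max)),
            class = "restricted_moments")
}

#' Truncated factorial moments of the divisions to the maximum size
#'
#' Factorial moments of \eqn{N_{i_0}^{max}}, the number of proliferation
#' events in \eqn{[0, T_{i_0}^{max}]}, by the same percentile-truncated
#' conditioning sum as [tmax_moments()] with the restricted factorial
#' moments \eqn{\tilde m^{(k)}_{i_0,i_\varrho}} in place of the time
#' moments.
#'
#' @inheritParams tmax_moments
#' @return Numeric vector, factorial moment orders `1..k_max`.
#' @examples
#' nmax_moments(clone_params(phi = 1), i0 = 1, k_max = 1) # 1.07984
#' @export
nmax_moments <- function(params, i0 = 1, k_max = 1, q_max = 0.99,
                         ladder = NULL) {
  dist <- xmax_distribution(params, i0 = i0, q_max = q_max, ladder = ladder)
  restricted_max_sum(dist, k_max, division_factorial_moments)
}

#' Conditional mean and standard deviation of the division count
#'
#' Mean and sd of \eqn{N_{i_0,i_\varrho}} given that size `i_rho` is reached
#' before extinction. With conditional factorial moments
#' \eqn{f_k = \tilde m^{(k)}/v}, the mean is \eqn{f_1} and the variance
#' \eqn{f_2 + f_1 - f_1^2}. For a single initial cell and `i_rho = 2` the
#' count is exactly 1 on the reach event (the only alternative to the birth
#' is absorption), so the sd is 0.
#'
#' @inheritParams conditional_passage_stats
#' @return A tibble with columns `i0`, `i_rho`, `prob`, `mean`, `sd`.
#' @export
conditional_division_stats <- function(params, i0, i_rho, ladder = NULL) {
  params <- as_clone_params(params)
  stopifnot(i0 >= 0, i0 <= i_rho)
  if (i0 == i_rho)
    return(tibble::tibble(i0 = i0, i_rho = i_rho, prob = 1, mean = 0, sd = 0))
  fm <- division_factorial_moments(params, i_rho, k_max = 2, ladder = ladder)
  v <- fm$v[i0 + 1]
  if (v == 0) stop("reach probability is 0: conditioning undefined", call. = FALSE)
  f1 <- fm$m[2, i0 + 1] / v
  f2 <- fm$m[3, i0 + 1] / v
  var <- f2 + f1 - f1^2
  tibble::tibble(i0 = i0, i_rho = i_rho, prob = v,
                 mean = f1, sd = sqrt(max(var, 0)))
}
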