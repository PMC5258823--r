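#' Moments of the time to contraction to a smaller clonal size
#'
#' For a start size `i` above the target `i_rho` (including `i_rho = 0`,
#' extinction), contraction is certain, and the moments of the absorption
#' time \eqn{T_{i,i_\varrho}} follow the Karlin-McGregor series
#' \deqn{E[T_{i,i_\varrho}^k] = k \sum_{n=i_\varrho}^{i-1} \rho_n
#'       \sum_{j=n+1}^{\infty}
#'       \frac{E[T_{j,i_\varrho}^{k-1}]}{\lambda_j \rho_j},}
#' with \eqn{\rho_{i_\varrho} = 1} and
#' \eqn{\rho_n = \prod_{k=i_\varrho+1}^{n} \mu_k/\lambda_k} (taken from the
#' log-scale [rate_ladder()]). The inner series converges factorially, since
#' \eqn{\lambda_j} is bounded by `phi` while \eqn{\mu_j = \mu j} grows, and
#' is truncated adaptively once the running term drops below
#' `tail_tol` times the partial sum. Moments of order `k` at one state need
#' order `k - 1` at *all larger* states, so each order is stored on a grid
#' up to the adaptive cap.
#'
#' @inheritParams reach_probability
#' @param i Start size, `> i_rho`.
#' @param i_rho Lower target size, `>= 0` (0 = extinction).
#' @param k_max Highest moment order.
#' @param tail_tol Relative tail-truncation tolerance of the inner series.
#' @return An object of class `contraction_moments`: list with `grid`
#'   (matrix, rows orders `1..k_max`, cols start sizes `i_rho..j_cap`,
#'   entry `[k, j - i_rho + 1]` holding \eqn{E[T_{j,i_\varrho}^k]}), `i`,
#'   `i_rho`, `k_max`, `j_cap`, `tail_tol`.
#' @examples
#' # near-pure-death: E[T_{3,1}] -> 1/(2 mu) + 1/(3 mu)
#' contraction_moments(clone_params(phi = 1e-8), i = 3, i_rho = 1)
#' @export
contraction_moments <- function(params, i, i_rho = 0, k_max = 2,
                                tail_tol = 1e-12, ladder = NULL) {
  params <- as_clone_params(params)
  stopifnot(length(i) == 1L, length(i_rho) == 1L, k_max >= 1)
  if (i_rho >= i)
    stop("`i_rho` must be < `i`: for expansion targets use the ",
         "expansion descriptors", call. = FALSE)
  if (i_rho < 0) stop("`i_rho` must be >= 0", call. = FALSE)

  # choose the series cap from the order-1 inner terms 1/(lambda_j rho_j)
  cap <- i + 20L
  if (is.null(ladder)) ladder <- rate_ladder(params, cap)
  repeat {
    ladder <- ladder_extend(ladder, cap)
    lrho <- ladder$log_zeta - ladder$log_zeta[i_rho + 1] # log rho_n at n+1
    lterm <- -(log(ladder$birth[-1]) + lrho[-1])         # log 1/(lam_j rho_j), j>=1
    js <- (i_rho + 1):cap
    lt <- lterm[js]
    if (lt[length(lt)] < log(tail_tol) + logsumexp(lt)) break
    cap <- cap + max(20L, cap %/% 2L)
  }
  # margin so that order-k values near the cap (used by order k+1 with
  # factorially small weights) are themselves accurate
  cap <- cap + 10L * k_max
  ladder <- ladder_extend(ladder, cap)
  lrho <- ladder$log_zeta - ladder$log_zeta[i_rho + 1]

  ns <- i_rho:cap            # grid of start sizes
  grid <- matrix(0, k_max, length(ns))
  prev <- rep(1, length(ns)) # E[T^0] = 1
  j <- (i_rho + 1):cap
  for (k in seq_len(k_max)) {
    # log c_j = log prev_j - log(lambda_j rho_j); rho_n and S_n are paired in
    # log space so a factorially large rho never meets a tiny S in linear form
    lt <- log(prev[j - i_rho + 1]) - log(ladder$birth[j + 1]) - lrho[j + 1]
    L <- rev(cumlogsumexp(rev(lt)))  # L[n - i_rho] = log sum_{j > n} c_j
    inc <- k * exp(lrho[(i_rho:(cap - 1)) + 1] + L)
    grid[k, ] <- c(0, cumsum(inc))
    prev <- grid[k, ]
  }
  structure(list(grid = grid, i = as.integer(i), i_rho = as.integer(i_rho),
                 k_max = as.integer(k_max), j_cap = as.integer(cap),
                 tail_tol = tail_tol, sizes = ns, params = params),
            class = "contraction_moments")
}

#' @export
print.contraction_moments <- function(x, ...) {
  st <- contraction_stats(x)
  cat(sprintf("<contraction_moments> %d -> %d: mean %.6g, sd %.6g (series cap %d)\n",
              x$i, x$i_rho, st$mean, st$sd, x$j_cap))
  invisible(x)
}

#' Mean and standard deviation of the contraction time
#'
#' Convenience summary of [contraction_moments()]: since contraction is
#' certain the moments are ordinary (non-defective), and
#' \eqn{sd = \sqrt{E[T^2] - E[T]^2}}.
#'
#' @param x A `contraction_moments` object, or a [clone_params()] (in which
#'   case `i`, `i_rho`, `...` are forwarded to [contraction_moments()]).
#' @param ... Forwarded to [contraction_moments()] when `x` is parameters.
#' @return A tibble with columns `i`, `i_rho`, `mean`, `sd`.
#' @export
contraction_stats <- function(x, ...) {
  if (!inherits(x, "contraction_moments"))
    x <- contraction_moments(x, ...)
  at <- x$i - x$i_rho + 1
  m1 <- x$grid[1, at]
  m2 <- if (x$k_max >= 2) x$grid[2, at] else NA_real_
  tibble::tibble(i = x$i, i_rho = x$i_rho, mean = m1,
                 sd = sqrt(max(m2 - m1^2, 0)))
}
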