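#' Augmented-chain descriptors of the time to D division events
#'
#' The time \eqn{T_{i_0}^D} to accumulate `D` proliferation events is
#' analysed on the augmented process \eqn{(X(t), D(t))} of (clonal size,
#' divisions so far). Layers `d = 0..D-1` hold the transient states
#' \eqn{1 \le i \le i_0 + d}; the states \eqn{(0, d)} (extinction before D
#' divisions) and the layer `d = D` (target reached) are absorbing. The
#' first-step equations for the restricted Laplace-Stieltjes transform,
#' \deqn{\Phi_{(i,d)}(s) = \frac{\mu_i}{s+\lambda_i+\mu_i}\Phi_{(i-1,d)}(s)
#'   + \frac{\lambda_i}{s+\lambda_i+\mu_i}\Phi_{(i+1,d+1)}(s),}
#' couple each state only to its same-layer neighbour below and the
#' next-layer neighbour above, so sweeping layers from `d = D - 1` down to
#' `0` and sizes upward inside a layer resolves the whole system by forward
#' substitution, with no matrix solve. The same order, with moment orders
#' ascending, solves the derivative system for the restricted moments.
#'
#' `division_time_reach_prob()` returns \eqn{w = P(T_{i_0}^D < \infty)}
#' (the transform at `s = 0`) together with the full grid;
#' `division_time_lst()` evaluates the transform at `s`;
#' `division_time_moments()` returns restricted moments at the initial
#' state and the conditional mean and sd given that D divisions occur.
#'
#' @inheritParams reach_probability
#' @param i0 Initial clonal size, >= 1.
#' @param D Target number of division events, >= 0 (`D = 0` is immediate).
#' @param s Transform argument, >= 0.
#' @param k_max Highest moment order.
#' @return `division_time_reach_prob()`: list with `prob` and `grid` (a
#'   tibble of `size`, `divisions`, `w` over the transient layers).
#'   `division_time_lst()`: the scalar transform value.
#'   `division_time_moments()`: a tibble with `i0`, `D`, `prob`, `m1`,
#'   `m2`, ..., `mean`, `sd` (conditional).
#' @examples
#' p <- clone_params(phi = 1000, nu = 200, n_mean = 1, regime = "soft")
#' division_time_reach_prob(p, i0 = 1, D = 1)$prob # 0.83264
#' @name division_time
NULL

# layered forward-substitution solve of the transform/moment systems.
# value[i + 1] indexes size i; returns list of per-layer solutions d = 0..D-1
divtime_sweep <- function(ladder, i0, D, s = 0, rhs_layers = NULL,
                          next_top = NULL) {
  lam <- ladder$birth
  dth <- ladder$death
  layers <- vector("list", D)
  # layer D: transform = 1 (or, for moment orders k >= 1, 0 via next_top)
  nxt <- if (is.null(next_top)) rep(1, i0 + D + 1) else next_top
  for (d in (D - 1):0) {
    cur <- numeric(i0 + d + 1)
    r <- if (is.null(rhs_layers)) NULL else rhs_layers[[d + 1]]
    for (i in seq_len(i0 + d)) {
      tot <- s + lam[i + 1] + dth[i + 1]
      cur[i + 1] <- (dth[i + 1] * cur[i] + lam[i + 1] * nxt[i + 2] +
                       (if (is.null(r)) 0 else r[i + 1])) / tot
    }
    layers[[d + 1]] <- cur
    nxt <- cur
  }
  layers
}

#' @rdname division_time
#' @export
division_time_reach_prob <- function(params, i0, D, ladder = NULL) {
  params <- as_clone_params(params)
  stopifnot(i0 >= 1, D >= 0, i0 == floor(i0), D == floor(D))
  if (D == 0)
    return(list(prob = 1,
                grid = tibble::tibble(size = integer(), divisions = integer(),
                                      w = numeric())))
  if (is.null(ladder)) ladder <- rate_ladder(params, i0 + D + 1)
  layers <- divtime_sweep(ladder, i0, D, s = 0)
  grid <- purrr::map_dfr(seq_len(D), function(dp1) {
    w <- layers[[dp1]]
    tibble::tibble(size = seq_len(length(w) - 1L),
                   divisions = dp1 - 1L, w = w[-1])
  })
  list(prob = layers[[1]][i0 + 1], grid = grid)
}

#' @rdname division_time
#' @export
division_time_lst <- function(params, i0, D, s, ladder = NULL) {
  params <- as_clone_params(params)
  stopifnot(i0 >= 1, D >= 0, length(s) == 1L)
  if (s < 0) stop("`s` must be >= 0", call. = FALSE)
  if (D == 0) return(1)
  if (is.null(ladder)) ladder <- rate_ladder(params, i0 + D + 1)
  divtime_sweep(ladder, i0, D, s = s)[[1]][i0 + 1]
}

#' @rdname division_time
#' @export
division_time_moments <- function(params, i0, D, k_max = 2, ladder = NULL) {
  params <- as_clone_params(params)
  stopifnot(i0 >= 1, D >= 0, k_max >= 1)
  if (D == 0) {
    out <- tibble::tibble(i0 = i0, D = D, prob = 1)
    for (k in seq_len(k_max)) out[[paste0("m", k)]] <- 0
    out$mean <- 0; out$sd <- 0
    return(out)
  }
  if (is.null(ladder)) ladder <- rate_ladder(params, i0 + D + 1)
  w_layers <- divtime_sweep(ladder, i0, D, s = 0)
  w <- w_layers[[1]][i0 + 1]
  if (w == 0) stop("P(T^D < infinity) = 0: conditioning undefined", call. = FALSE)
  zero_top <- rep(0, i0 + D + 1) # moment orders k >= 1 vanish on absorbing sets
  prev <- w_layers
  ms <- numeric(k_max)
  for (k in seq_len(k_max)) {
    rhs <- purrr::map(prev, function(layer) k * layer)
    prev <- divtime_sweep(ladder, i0, D, s = 0, rhs_layers = rhs,
                          next_top = zero_top)
    ms[k] <- prev[[1]][i0 + 1]
  }
  out <- tibble::tibble(i0 = i0, D = D, prob = w)
  for (k in seq_len(k_max)) out[[paste0("m", k)]] <- ms[k]
  out$mean <- ms[1] / w
  out$sd <- if (k_max >= 2) sqrt(max(ms[2] / w - (ms[1] / w)^2, 0)) else NA_real_
  out
}
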