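#' Per-state birth (proliferation) rate
#'
#' Rate at which a clonotype of size `i` gains one cell through homeostatic
#' proliferation. In the `exact` regime the Poisson-weighted competition sum
#' is evaluated over the central window of the Poisson(`nu`) distribution
#' holding at least `1 - 1e-12` of its mass, with the weights computed by
#' [stats::dpois()] (log-scale internally), so the truncation error is
#' negligible even for `nu` of several hundred.
#'
#' @param params A [clone_params()] object.
#' @param i Clonal size(s); non-negative integer(s). Vectorised.
#' @return Birth rate(s), same length as `i` (1/time). Always 0 at `i = 0`.
#' @examples
#' birth_rate(clone_params(phi = 5), 1)        # hard niche: 5
#' birth_rate(clone_params(phi = 50, nu = 1), 1) # 50 * (1 - exp(-1))
#' @export
birth_rate <- function(params, i) {
  params <- as_clone_params(params)
  if (any(i < 0)) stop("clonal size `i` must be >= 0", call. = FALSE)
  if (any(i != floor(i))) stop("clonal size `i` must be integer", call. = FALSE)
  out <- switch(params$regime,
    hard = rep(params$phi, length(i)),
    soft = params$phi * i / (params$nu * params$n_mean + i),
    exact = {
      r <- poisson_window(params$nu)
      w <- stats::dpois(r, params$nu)
      vapply(i, function(ii) {
        if (ii == 0) return(0)
        params$phi * sum(w * ii / (r * params$n_mean + ii))
      }, numeric(1))
    }
  )
  out[i == 0] <- 0
  out
}

# central Poisson(nu) window containing >= 1 - 1e-12 of the mass
poisson_window <- function(nu) {
  if (nu == 0) return(0L)
  lo <- stats::qpois(5e-13, nu)
  hi <- stats::qpois(5e-13, nu, lower.tail = FALSE)
  seq.int(lo, hi)
}

#' Per-state death rate
#'
#' Linear death: every cell of the clonotype dies independently at rate `mu`,
#' so a clonotype of size `i` loses a cell at rate `mu * i`.
#'
#' @inheritParams birth_rate
#' @return Death rate(s) `mu * i` (1/time).
#' @export
death_rate <- function(params, i) {
  params <- as_clone_params(params)
  if (any(i < 0)) stop("clonal size `i` must be >= 0", call. = FALSE)
  params$mu * i
}

#' Tabulated rate ladder with log-scale products
#'
#' Tabulates the birth and death rates up to a working cap `i_max` together
#' with the log-scale ladder \eqn{\log\zeta_i}, where \eqn{\zeta_0 = 1} and
#' \eqn{\zeta_i = \prod_{k=1}^i \mu_k/\lambda_k}. Every downstream recursion
#' (reach probabilities, restricted moments, contraction series) consumes
#' these tabulated values; ratios \eqn{\rho_n = \zeta_n/\zeta_{i_\varrho}}
#' are recovered as differences of `log_zeta`. Keeping \eqn{\zeta} on the log
#' scale matters: a hard niche with `phi = 100` drives \eqn{\zeta} through
#' hundreds of orders of magnitude.
#'
#' @inheritParams birth_rate
#' @param i_max State cap (>= 1).
#' @return A `rate_ladder`: list with `birth`, `death`, `log_zeta` (each of
#'   length `i_max + 1`, index `i + 1` holding state `i`), `i_max`, `params`.
#' @examples
#' ld <- rate_ladder(clone_params(phi = 1), 6)
#' exp(ld$log_zeta[5])  # hard phi = mu = 1: zeta_4 = 4! = 24
#' @export
rate_ladder <- function(params, i_max) {
  params <- as_clone_params(params)
  if (length(i_max) != 1L || i_max < 1 || i_max != floor(i_max))
    stop("`i_max` must be an integer >= 1", call. = FALSE)
  i <- 0:i_max
  lam <- birth_rate(params, i)
  dth <- death_rate(params, i)
  log_zeta <- c(0, cumsum(log(dth[-1]) - log(lam[-1])))
  structure(
    list(birth = lam, death = dth, log_zeta = log_zeta,
         i_max = as.integer(i_max), params = params),
    class = "rate_ladder"
  )
}

# grow an existing ladder to a new cap, reusing the tabulated prefix
ladder_extend <- function(ladder, i_max) {
  if (i_max <= ladder$i_max) return(ladder)
  i_new <- (ladder$i_max + 1):i_max
  lam <- birth_rate(ladder$params, i_new)
  dth <- death_rate(ladder$params, i_new)
  lz <- ladder$log_zeta[ladder$i_max + 1] + cumsum(log(dth) - log(lam))
  ladder$birth <- c(ladder$birth, lam)
  ladder$death <- c(ladder$death, dth)
  ladder$log_zeta <- c(ladder$log_zeta, lz)
  ladder$i_max <- as.integer(i_max)
  ladder
}

#' @export
print.rate_ladder <- function(x, ...) {
  cat(sprintf("<rate_ladder> up to i_max = %d (%s niche, phi = %g, mu = %g)\n",
              x$i_max, x$params$regime, x$params$phi, x$params$mu))
  invisible(x)
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
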