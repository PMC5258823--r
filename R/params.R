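#' Model parameters for a naive T cell clonotype
#'
#' Bundles the four parameters of the birth-death model of a naive T cell
#' clonotype competing for homeostatic proliferation signals, together with
#' the competition regime. Time is measured in units of the mean T cell
#' lifetime when `mu = 1`.
#'
#' The clonotype of size \eqn{i} proliferates at rate
#' \deqn{\lambda_i = \varphi e^{-\nu} \sum_{r \ge 0} \frac{\nu^r}{r!}
#'       \frac{i}{r\langle n\rangle + i},}
#' and dies at rate \eqn{\mu_i = \mu i}. Two limits of the Poisson-weighted
#' competition sum have closed forms: the *hard* niche (no competitors,
#' \eqn{\nu \ll 1}) where \eqn{\lambda_i = \varphi} for \eqn{i \ge 1}, and the
#' *soft* niche (many competitors, \eqn{\nu \gg 1}) where
#' \eqn{\lambda_i = \varphi i / (\nu\langle n\rangle + i)}. State 0 is
#' absorbing in every regime (\eqn{\lambda_0 = 0}).
#'
#' If `regime` is not supplied it is resolved automatically: `"hard"` when
#' `nu == 0` and `"exact"` (the full Poisson sum, i.e. the intermediate
#' niche) otherwise. The soft limit is used only on explicit request.
#'
#' @param phi Per-cell homeostatic signalling (proliferation) rate, > 0.
#' @param mu Per-cell death rate, > 0. Defaults to 1, which fixes the time
#'   unit to the mean T cell lifetime.
#' @param nu Mean number of competing clonotypes, >= 0.
#' @param n_mean Characteristic clonal size \eqn{\langle n\rangle} of the
#'   competing clonotypes (cells), >= 1.
#' @param regime One of `"exact"`, `"hard"`, `"soft"`, or `NULL` for
#'   automatic resolution.
#'
#' @return An object of class `clone_params`.
#' @examples
#' clone_params(phi = 5)                      # hard niche
#' clone_params(phi = 50, nu = 1, n_mean = 10) # intermediate niche, exact rates
#' clone_params(phi = 1000, nu = 200, regime = "soft")
#' @export
clone_params <- function(phi, mu = 1, nu = 0, n_mean = 1, regime = NULL) {
  stopifnot(is.numeric(phi), length(phi) == 1L, is.finite(phi),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(nu), length(nu) == 1L, is.finite(nu),
            is.numeric(n_mean), length(n_mean) == 1L, is.finite(n_mean))
  if (phi <= 0) stop("`phi` must be > 0", call. = FALSE)
  if (mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  if (nu < 0) stop("`nu` must be >= 0", call. = FALSE)
  if (n_mean < 1) stop("`n_mean` must be >= 1", call. = FALSE)
  if (is.null(regime)) {
    regime <- if (nu == 0) "hard" else "exact"
  }
  regime <- match.arg(regime, c("exact", "hard", "soft"))
  structure(
    list(phi = phi, mu = mu, nu = nu, n_mean = n_mean, regime = regime),
    class = "clone_params"
  )
}

#' @export
print.clone_params <- function(x, ...) {
  cat("<clone_params> ", x$regime, " niche\n", sep = "")
  cat(sprintf("  phi = %g, mu = %g, nu = %g, <n> = %g\n",
              x$phi, x$mu, x$nu, x$n_mean))
  invisible(x)
}

as_clone_params <- function(x) {
  if (inherits(x, "clone_params")) return(x)
  if (is.list(x)) {
    return(clone_params(phi = x$phi,
                        mu = if (is.null(x$mu)) 1 else x$mu,
                        nu = if (is.null(x$nu)) 0 else x$nu,
                        n_mean = if (is.null(x$n_mean)) 1 else x$n_mean,
                        regime = x$regime))
  }
  stop("cannot interpret `params`; use clone_params()", call. = FALSE)
}
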