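#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the maximum-clonal-size distribution
#'
#' @param x An [xmax_distribution()].
#' @param ... Unused.
#' @return The pmf tibble (`size`, `pmf`, `survival`, `cdf`).
#' @export
tidy.xmax_distribution <- function(x, ...) x$pmf

#' One-row summary of the maximum-clonal-size distribution
#'
#' @inheritParams tidy.xmax_distribution
#' @return A tibble with `i0`, `q_max`, `k_qmax` (top of the truncated
#'   support), `e_xmax` (truncated mean), `covered_mass`, and
#'   `p_establish`, the mass beyond twice the initial size — a crude
#'   establishment probability separating the extinction mode from the
#'   expansion mode of the (often bimodal) pmf.
#' @export
glance.xmax_distribution <- function(x, ...) {
  tibble::tibble(
    i0 = x$i0, q_max = x$q_max, k_qmax = max(x$pmf$size),
    e_xmax = xmax_mean(x), covered_mass = x$covered_mass,
    p_establish = sum(x$pmf$pmf[x$pmf$size > 2 * x$i0]) + x$surv_next
  )
}

#' Tidy a simulation run into descriptor estimates
#'
#' @param x A `clone_sim` tibble from [simulate_clonotype()].
#' @param ... Passed to [estimate_descriptors()].
#' @return The tibble of Monte Carlo estimates with standard errors.
#' @export
tidy.clone_sim <- function(x, ...) estimate_descriptors(x, ...)

#' One-row summary of a simulation run
#'
#' @inheritParams tidy.clone_sim
#' @return A tibble with replicate count, censored fraction, seed, and the
#'   mean maximum clonal size with its standard error.
#' @export
glance.clone_sim <- function(x, ...) {
  st <- attr(x, "settings")
  tibble::tibble(
    n_reps = nrow(x), censored_frac = mean(x$censored), seed = st$seed,
    i0 = st$i0, e_xmax = mean(x$xmax),
    se_xmax = stats::sd(x$xmax) / sqrt(nrow(x))
  )
}

#' Tidy contraction-time moments into a per-start-size table
#'
#' @param x A [contraction_moments()] object.
#' @param ... Unused.
#' @return A tibble with `i` (start size up to the requested one), `i_rho`,
#'   `mean` and `sd` of the contraction time.
#' @export
tidy.contraction_moments <- function(x, ...) {
  keep <- which(x$sizes <= x$i)
  m1 <- x$grid[1, keep]
  m2 <- if (x$k_max >= 2) x$grid[2, keep] else rep(NA_real_, length(keep))
  tibble::tibble(i = x$sizes[keep], i_rho = x$i_rho, mean = m1,
                 sd = sqrt(pmax(m2 - m1^2, 0)))
}
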