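#' Exact stochastic simulation of the clonotype birth-death chain
#'
#' Gillespie simulation: waiting times are exponential with total rate
#' \eqn{\lambda_i + \mu_i} and each event is a birth with the embedded-chain
#' probability \eqn{\lambda_i/(\lambda_i+\mu_i)}. Paths run from `i0` until
#' extinction, or until a cap (`max_time`, `max_events`, or the tabulated
#' size cap `i_cap`) censors them; censoring is flagged, never silently
#' dropped. One root `seed` spawns an independent, bit-reproducible RNG
#' stream per trajectory, so increasing `n_reps` extends — rather than
#' reshuffles — an earlier run.
#'
#' Per trajectory the recorded summaries are the running maximum `xmax`,
#' the first time `tmax` at which it was attained, the number of births
#' `nmax` before that time, the total `births` and `events`, the extinction
#' time, and (optionally) the first-passage time `t_reach` to size `i_rho`
#' — above or below the start — with the division count `n_at_reach` at
#' that moment, and the time `t_divisions` of the `D`-th division.
#'
#' In regimes where the clonotype establishes itself (e.g. a hard niche
#' with large `phi`), extinction times grow astronomically; simulate such
#' regimes with explicit caps and expect censoring — the analytic
#' descriptors remain available there.
#'
#' @inheritParams xmax_distribution
#' @param n_reps Number of trajectories.
#' @param seed Integer root seed (determinism contract).
#' @param i_rho Optional expansion target whose first-passage time is
#'   recorded.
#' @param D Optional division count whose completion time is recorded.
#' @param max_time,max_events Per-trajectory caps.
#' @param i_cap Size cap up to which birth rates are tabulated; hitting it
#'   censors the path. Default scales with the quasi-stationary size
#'   `phi/mu`.
#' @return A tibble of per-trajectory summaries, class `clone_sim`, with
#'   the simulation settings in attributes.
#' @examples
#' sim <- simulate_clonotype(clone_params(phi = 1), n_reps = 100, seed = 1)
#' mean(sim$xmax)
#' @export
simulate_clonotype <- function(params, i0 = 1, n_reps = 1000, seed = 1,
                               i_rho = NA, D = NA, max_time = Inf,
                               max_events = 1e7, i_cap = NULL) {
  params <- as_clone_params(params)
  stopifnot(i0 >= 1, n_reps >= 1)
  if (is.null(i_cap))
    i_cap <- max(1000, ceiling(10 * params$phi / params$mu), 4 * i0)
  lambda <- birth_rate(params, 0:i_cap)
  out <- simulate_paths_cpp(lambda, params$mu, as.integer(i0),
                            as.integer(n_reps), as.numeric(seed),
                            as.integer(if (is.na(i_rho)) 0L else i_rho),
                            as.numeric(if (is.na(D)) -1 else D),
                            as.numeric(max_time), as.numeric(max_events))
  out <- tibble::as_tibble(out)
  if (!is.na(D) && D == 0) out$t_divisions <- 0
  attr(out, "params") <- params
  attr(out, "settings") <- list(i0 = i0, seed = seed, i_rho = i_rho, D = D,
                                max_time = max_time, max_events = max_events,
                                i_cap = i_cap)
  class(out) <- c("clone_sim", class(out))
  out
}

#' Simulate a single clonotype trajectory with its full event log
#'
#' @inheritParams simulate_clonotype
#' @return A tibble of class `clone_trajectory` with columns `time`, `size`
#'   and `type` (`"birth"`/`"death"`), starting with the initial state at
#'   time 0; the censoring flag is in `attr(x, "censored")`.
#' @export
simulate_trajectory <- function(params, i0 = 1, seed = 1, max_time = Inf,
                                max_events = 1e6, i_cap = NULL) {
  params <- as_clone_params(params)
  stopifnot(i0 >= 1)
  if (is.null(i_cap))
    i_cap <- max(1000, ceiling(10 * params$phi / params$mu), 4 * i0)
  lambda <- birth_rate(params, 0:i_cap)
  ev <- simulate_events_cpp(lambda, params$mu, as.integer(i0),
                            as.numeric(seed), as.numeric(max_time),
                            as.numeric(max_events))
  out <- tibble::tibble(
    time = c(0, ev$time),
    size = as.integer(c(i0, ev$size)),
    type = c("initial", ifelse(ev$type == 1, "birth", "death"))
  )
  attr(out, "params") <- params
  attr(out, "censored") <- ev$censored
  class(out) <- c("clone_trajectory", class(out))
  out
}

#' Monte Carlo estimates of the clonal-fate descriptors
#'
#' Summarises a [simulate_clonotype()] run (or runs one) into point
#' estimates with standard errors for every descriptor the simulation
#' recorded: the mean maximum clonal size, time and divisions to the
#' maximum, extinction time, and — when targets were set — the probability
#' of reaching `i_rho` (or of `D` divisions) with the conditional mean of
#' the corresponding passage time. Conditional summaries use only the
#' trajectories on which the event occurred; the standard error is the
#' sample sd over \eqn{\sqrt{n}}.
#'
#' @param sim A `clone_sim` tibble, or a [clone_params()] object (in which
#'   case `...` is passed to [simulate_clonotype()]).
#' @param ... Forwarded to [simulate_clonotype()] when `sim` is parameters.
#' @param censored_warn Warn if the censored fraction exceeds this.
#' @return A tibble with columns `descriptor`, `estimate`, `se`, `n`,
#'   `censored_frac`.
#' @export
estimate_descriptors <- function(sim, ..., censored_warn = 0.01) {
  if (!inherits(sim, "clone_sim")) sim <- simulate_clonotype(sim, ...)
  cf <- mean(sim$censored)
  if (cf > censored_warn)
    warning(sprintf("%.1f%% of trajectories censored; estimates may be biased",
                    100 * cf), call. = FALSE)
  st <- attr(sim, "settings")
  one <- function(name, x) {
    x <- x[is.finite(x)]
    n <- length(x)
    tibble::tibble(descriptor = name,
                   estimate = if (n) mean(x) else NA_real_,
                   se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
                   n = n, censored_frac = cf)
  }
  one_sd <- function(name, x) {
    x <- x[is.finite(x)]
    n <- length(x)
    tibble::tibble(descriptor = name,
                   estimate = if (n > 1) stats::sd(x) else NA_real_,
                   # large-sample se of a sample sd
                   se = if (n > 1) stats::sd(x) / sqrt(2 * (n - 1)) else NA_real_,
                   n = n, censored_frac = cf)
  }
  out <- dplyr::bind_rows(
    one("E[Xmax]", sim$xmax),
    one("E[Tmax]", sim$tmax),
    one("E[Nmax]", sim$nmax),
    one("E[T_extinction]", sim$t_extinction)
  )
  if (!is.na(st$i_rho)) {
    reached <- is.finite(sim$t_reach)
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(descriptor = "P(reach i_rho)", estimate = mean(reached),
                     se = sqrt(mean(reached) * (1 - mean(reached)) / nrow(sim)),
                     n = nrow(sim), censored_frac = cf),
      one("E[T_reach | reached]", sim$t_reach),
      one_sd("SD[T_reach | reached]", sim$t_reach)
    )
  }
  if (!is.na(st$D) && st$D >= 0) {
    done <- is.finite(sim$t_divisions)
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(descriptor = "P(T^D < Inf)", estimate = mean(done),
                     se = sqrt(mean(done) * (1 - mean(done)) / nrow(sim)),
                     n = nrow(sim), censored_frac = cf),
      one("E[T^D | finite]", sim$t_divisions),
      one_sd("SD[T^D | finite]", sim$t_divisions)
    )
  }
  out
}
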