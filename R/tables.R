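#' Descriptor summaries over a grid of parameter sets
#'
#' Data-frame-first driver for the analytic descriptors: takes one row per
#' parameter set and returns one row per set with the maximum-clonal-size
#' summaries — the truncated means `e_xmax`, `e_tmax`, `e_nmax`, the
#' percentiles \eqn{K_q}, the truncated probabilities
#' \eqn{\tilde P(X^{max} \ge K_q)}, and the conditional mean/sd of the time
#' and of the division count to reach each \eqn{K_q}.
#'
#' @param grid A data frame with columns `phi` and optionally `mu` (1),
#'   `nu` (0), `n_mean` (1), `regime` (auto), `i0` (1), `q_max`
#'   (the `q_max` argument). Missing columns take the defaults in
#'   parentheses.
#' @param q Percentile levels to report.
#' @param q_max Default truncation quantile for rows without a `q_max`
#'   column.
#' @return A tibble, one row per grid row: the parameter columns followed
#'   by `e_xmax`, `e_tmax`, `e_nmax`, `covered_mass`, and per level
#'   `k_q<q>`, `p_trunc_q<q>`, `t_mean_q<q>`, `t_sd_q<q>`, `n_mean_q<q>`,
#'   `n_sd_q<q>`.
#' @examples
#' descriptor_table(data.frame(phi = c(0.1, 1)))
#' @export
descriptor_table <- function(grid, q = c(0.25, 0.5, 0.75, 0.99),
                             q_max = 0.99) {
  grid <- normalize_grid(grid, q_max)
  if (nrow(grid) == 0) return(tibble::as_tibble(grid))
  rows <- purrr::pmap_dfr(grid, function(phi, mu, nu, n_mean, regime, i0,
                                         q_max, ...) {
    p <- clone_params(phi = phi, mu = mu, nu = nu, n_mean = n_mean,
                      regime = if (is.na(regime)) NULL else regime)
    dist <- xmax_distribution(p, i0 = i0, q_max = q_max)
    Kq <- xmax_percentile(dist, q)
    Pt <- xmax_truncated_prob(dist, q)
    cond <- purrr::map_dfr(Kq, function(kq) {
      if (kq == i0)
        return(tibble::tibble(t_mean = 0, t_sd = 0, n_mean = 0, n_sd = 0))
      ps <- conditional_passage_stats(p, i0, kq, ladder = dist$ladder)
      ds <- conditional_division_stats(p, i0, kq, ladder = dist$ladder)
      tibble::tibble(t_mean = ps$mean, t_sd = ps$sd,
                     n_mean = ds$mean, n_sd = ds$sd)
    })
    out <- tibble::tibble(
      e_xmax = xmax_mean(dist),
      e_tmax = restricted_max_sum(dist, 1, expansion_moments),
      e_nmax = restricted_max_sum(dist, 1, division_factorial_moments),
      covered_mass = dist$covered_mass
    )
    qlab <- sub("^0\\.", "", formatC(q, format = "g"))
    for (ii in seq_along(q)) {
      out[[paste0("k_q", qlab[ii])]] <- Kq[ii]
      out[[paste0("p_trunc_q", qlab[ii])]] <- Pt[ii]
      out[[paste0("t_mean_q", qlab[ii])]] <- cond$t_mean[ii]
      out[[paste0("t_sd_q", qlab[ii])]] <- cond$t_sd[ii]
      out[[paste0("n_mean_q", qlab[ii])]] <- cond$n_mean[ii]
      out[[paste0("n_sd_q", qlab[ii])]] <- cond$n_sd[ii]
    }
    out
  })
  dplyr::bind_cols(tibble::as_tibble(grid)[setdiff(names(grid), "D")], rows)
}

#' Reach-probability table for a target number of divisions
#'
#' Mirrors the layout of the division-potential experiments: one row per
#' (initial size, division target, parameter set) with
#' \eqn{P(T_{i_0}^D < \infty)} and the conditional mean and sd of the
#' completion time.
#'
#' @param grid A data frame with columns `i0`, `D`, `phi`, and optionally
#'   `mu`, `nu`, `n_mean`, `regime` as in [descriptor_table()].
#' @return A tibble: the grid columns plus `prob`, `cond_mean`, `cond_sd`.
#' @examples
#' division_time_table(data.frame(i0 = 1, D = 1:2, phi = 1000, nu = 200,
#'                                regime = "soft"))
#' @export
division_time_table <- function(grid) {
  grid <- normalize_grid(grid, q_max = NA_real_, need = c("i0", "D"))
  if (nrow(grid) == 0) return(tibble::as_tibble(grid))
  rows <- purrr::pmap_dfr(grid, function(phi, mu, nu, n_mean, regime, i0, D,
                                         ...) {
    p <- clone_params(phi = phi, mu = mu, nu = nu, n_mean = n_mean,
                      regime = if (is.na(regime)) NULL else regime)
    mm <- division_time_moments(p, i0 = i0, D = D, k_max = 2)
    tibble::tibble(prob = mm$prob, cond_mean = mm$mean, cond_sd = mm$sd)
  })
  dplyr::bind_cols(tibble::as_tibble(grid)[setdiff(names(grid), "q_max")],
                   rows)
}

# fill in grid defaults and validate
normalize_grid <- function(grid, q_max, need = character()) {
  stopifnot(is.data.frame(grid))
  if (nrow(grid) > 0 && !"phi" %in% names(grid))
    stop("grid needs a `phi` column", call. = FALSE)
  for (nm in need)
    if (nrow(grid) > 0 && !nm %in% names(grid))
      stop(sprintf("grid needs a `%s` column", nm), call. = FALSE)
  defaults <- list(phi = NA_real_, mu = 1, nu = 0, n_mean = 1,
                   regime = NA_character_, i0 = 1L, D = NA_integer_,
                   q_max = q_max)
  for (nm in names(defaults))
    if (!nm %in% names(grid))
      grid[[nm]] <- rep(defaults[[nm]], length.out = nrow(grid))
  grid[c("phi", "mu", "nu", "n_mean", "regime", "i0", "D", "q_max")]
}

#' Write descriptor records to CSV or JSON
#'
#' Round-trip-safe serialisation of any descriptor tibble: CSV via readr at
#' full precision, JSON via jsonlite (column-major data frame encoding,
#' `digits = NA` so values re-parse identically).
#'
#' @param x A data frame of results.
#' @param path Output file; the extension picks the format unless `format`
#'   is given.
#' @param format `"csv"` or `"json"`.
#' @return `x`, invisibly.
#' @export
write_descriptors <- function(x, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    readr::write_csv(as.data.frame(x), path)
  } else {
    jsonlite::write_json(as.data.frame(x), path, digits = NA, dataframe = "columns")
  }
  invisible(x)
}

#' Read descriptor records written by [write_descriptors()]
#'
#' @inheritParams write_descriptors
#' @return A tibble.
#' @export
read_descriptors <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
}
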