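test_that("seeded runs are reproducible and extend without reshuffling", {
  p <- clone_params(phi = 1)
  a <- simulate_clonotype(p, n_reps = 500, seed = 42)
  b <- simulate_clonotype(p, n_reps = 500, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # per-trajectory streams: the first 500 of a longer run are unchanged
  c <- simulate_clonotype(p, n_reps = 800, seed = 42)
  expect_identical(as.data.frame(c)[1:500, ], as.data.frame(a))
  d <- simulate_clonotype(p, n_reps = 500, seed = 43)
  expect_false(identical(a$xmax, d$xmax))
})

test_that("the near-pure-death limit never proliferates", {
  p <- clone_params(phi = 1e-12, mu = 1)
  sim <- simulate_clonotype(p, i0 = 4, n_reps = 300, seed = 1)
  expect_true(all(sim$xmax == 4))
  expect_true(all(sim$nmax == 0))
  expect_true(all(sim$births == 0))
  expect_true(all(is.finite(sim$t_extinction)))
  expect_true(all(sim$tmax == 0))
})

test_that("the embedded chain picks births with probability lambda/(lambda+mu)", {
  p <- clone_params(phi = 5, mu = 1)
  first_birth <- vapply(1:800, function(s) {
    tr <- simulate_trajectory(p, i0 = 1, seed = s, max_events = 1)
    tr$type[2] == "birth"
  }, logical(1))
  phat <- mean(first_birth)
  expect_lt(abs(phat - 5 / 6), 3 * sqrt((5 / 6) * (1 / 6) / 800))
})

test_that("trajectories are valid sample paths", {
  p <- clone_params(phi = 2, mu = 1)
  tr <- simulate_trajectory(p, i0 = 3, seed = 9)
  expect_true(all(abs(diff(tr$size)) == 1)) # one cell at a time
  expect_true(all(diff(tr$time) > 0))
  expect_identical(tr$size[length(tr$size)], 0L) # uncensored path ends extinct
  expect_false(attr(tr, "censored"))
  # censoring is flagged when a cap bites
  trc <- simulate_trajectory(clone_params(phi = 50), seed = 2, max_events = 10)
  expect_true(attr(trc, "censored"))
})

test_that("Monte Carlo estimates agree with the analytic descriptors", {
  p <- clone_params(phi = 2, mu = 1)
  n <- 30000
  sim <- simulate_clonotype(p, n_reps = n, seed = 5, i_rho = 4)
  est <- estimate_descriptors(sim)
  pick <- function(d) est[est$descriptor == d, ]

  # P(reach 4) is exact binomial vs v_{1,4}
  v <- reach_probability(p, 1, 4)
  expect_lt(abs(pick("P(reach i_rho)")$estimate - v), 3 * sqrt(v * (1 - v) / n))

  # conditional passage time mean
  ps <- conditional_passage_stats(p, 1, 4)
  row <- pick("E[T_reach | reached]")
  expect_lt(abs(row$estimate - ps$mean), 3 * row$se)

  # E[Xmax] and E[Tmax]: simulated (untruncated) vs truncated analytic; the
  # truncation only drops tail mass, so analytic <= simulated + 3 SE, and
  # with q_max = 0.9999 the gap shrinks inside the Monte Carlo band
  xr <- pick("E[Xmax]")
  d <- xmax_distribution(p, q_max = 0.9999)
  expect_lt(abs(xr$estimate - xmax_mean(d)), 3 * xr$se)
  expect_lt(xmax_mean(xmax_distribution(p, q_max = 0.99)),
            xr$estimate + 3 * xr$se)
  tr <- pick("E[Tmax]")
  expect_lt(abs(tr$estimate - tmax_moments(p, q_max = 0.9999)), 3 * tr$se)
  nr <- pick("E[Nmax]")
  expect_lt(abs(nr$estimate - nmax_moments(p, q_max = 0.9999)), 3 * nr$se)

  # extinction time vs the contraction series to 0
  er <- pick("E[T_extinction]")
  expect_lt(abs(er$estimate - contraction_stats(p, i = 1, i_rho = 0)$mean),
            3 * er$se)
})

test_that("simulated division counts reproduce the analytic pmf", {
  p <- clone_params(phi = 1, mu = 1)
  i_rho <- 3
  n <- 20000
  sim <- simulate_clonotype(p, n_reps = n, seed = 8, i_rho = i_rho)
  pmf <- division_count_pmf(p, i_rho, tol = 1e-10)
  counts <- sim$n_at_reach[is.finite(sim$n_at_reach)]
  for (j in c(2, 3, 4, 6)) {
    prob <- pmf$probs[2, j + 1] # start size 1
    phat <- mean(counts == j) * length(counts) / n
    expect_lt(abs(phat - prob), 3 * sqrt(prob * (1 - prob) / n) + 1e-9)
  }
})

test_that("heavy censoring is surfaced, not hidden", {
  p <- clone_params(phi = 20, mu = 1) # establishment regime: huge lifetimes
  sim <- simulate_clonotype(p, n_reps = 50, seed = 1, max_events = 500)
  expect_gt(mean(sim$censored), 0.2)
  expect_warning(estimate_descriptors(sim), "censored")
})
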