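soft <- clone_params(phi = 1000, nu = 200, n_mean = 1, regime = "soft")

test_that("degenerate division targets are immediate", {
  expect_equal(division_time_reach_prob(soft, 1, 0)$prob, 1)
  expect_equal(division_time_lst(soft, 1, 0, 3), 1)
  mm <- division_time_moments(soft, 1, 0)
  expect_equal(c(mm$m1, mm$m2, mm$mean, mm$sd), c(0, 0, 0, 0))
})

test_that("a single transient state gives the competing-exponentials form", {
  # i0 = 1, D = 1: Phi = lambda_1 / (s + lambda_1 + mu_1)
  l1 <- birth_rate(soft, 1)
  s <- 0.7
  expect_equal(division_time_lst(soft, 1, 1, s), l1 / (s + l1 + 1),
               tolerance = 1e-12)
  mm <- division_time_moments(soft, 1, 1)
  expect_equal(mm$mean, 1 / (l1 + 1), tolerance = 1e-10)
  expect_equal(mm$mean, 0.167361, tolerance = 1e-5)
})

test_that("the D = 1 reach probability matches the all-deaths-path closed form", {
  # w = 1 - prod_{j=1}^{i0} mu_j / (lambda_j + mu_j)
  for (i0 in c(1, 4, 10)) {
    lam <- birth_rate(soft, 1:i0)
    dth <- death_rate(soft, 1:i0)
    w_closed <- 1 - prod(dth / (lam + dth))
    expect_equal(division_time_reach_prob(soft, i0, 1)$prob, w_closed,
                 tolerance = 1e-12)
  }
})

test_that("layered forward substitution agrees with a dense solve", {
  set.seed(7)
  for (rep in 1:6) {
    p <- clone_params(phi = runif(1, 0.5, 20), mu = runif(1, 0.5, 2),
                      nu = sample(0:3, 1), n_mean = sample(1:10, 1))
    i0 <- sample(1:3, 1); D <- sample(1:3, 1); s <- runif(1, 0, 1.5)
    expect_equal(division_time_lst(p, i0, D, s), dense_divtime_lst(p, i0, D, s),
                 tolerance = 1e-10)
  }
})

test_that("reach probabilities reproduce the printed soft-niche grid", {
  # mu = 1, phi = 1000, nu = 200 (values printed truncated to 5 decimals)
  cases <- list( # i0, D, n_mean, printed
    list(1, 1, 1, 0.83263), list(1, 1, 10, 0.33322),
    list(1, 1, 100, 0.04761), list(1, 1, 1000, 0.00497),
    list(1, 5, 1, 0.79944), list(1, 10, 1, 0.79876),
    list(10, 1, 10, 0.98249), list(10, 5, 10, 0.74816),
    list(100, 5, 100, 0.58648), list(100, 1, 1000, 0.39263)
  )
  for (cs in cases) {
    p <- clone_params(phi = 1000, nu = 200, n_mean = cs[[3]], regime = "soft")
    expect_lt(abs(division_time_reach_prob(p, cs[[1]], cs[[2]])$prob - cs[[4]]),
              1.1e-5)
  }
})

test_that("reach probability is monotone in D and in the initial size", {
  p <- clone_params(phi = 1000, nu = 200, n_mean = 10, regime = "soft")
  wD <- vapply(0:6, function(D) division_time_reach_prob(p, 5, D)$prob,
               numeric(1))
  expect_true(all(diff(wD) <= 1e-14))
  wi <- vapply(1:8, function(i0) division_time_reach_prob(p, i0, 3)$prob,
               numeric(1))
  expect_true(all(diff(wi) >= -1e-14))
  # grid invariants: w is 1 on the target layer side, 0 when extinct
  gr <- division_time_reach_prob(p, 3, 2)$grid
  expect_true(all(gr$w > 0 & gr$w < 1))
})

test_that("D = 1 from one cell coincides with the size-2 passage descriptors", {
  p <- clone_params(phi = 6, mu = 1, nu = 1, n_mean = 4)
  mm <- division_time_moments(p, 1, 1)
  expect_equal(mm$prob, reach_probability(p, 1, 2), tolerance = 1e-12)
  ps <- conditional_passage_stats(p, 1, 2)
  expect_equal(mm$mean, ps$mean, tolerance = 1e-10)
  expect_equal(mm$sd, ps$sd, tolerance = 1e-8)
})

test_that("division completion times agree with conditioned Gillespie paths", {
  p <- clone_params(phi = 1000, nu = 200, n_mean = 10, regime = "soft")
  mm <- division_time_moments(p, 10, 5)
  sim <- simulate_clonotype(p, i0 = 10, n_reps = 20000, seed = 3, D = 5)
  td <- sim$t_divisions[is.finite(sim$t_divisions)]
  phat <- length(td) / nrow(sim)
  expect_lt(abs(phat - mm$prob),
            3 * sqrt(mm$prob * (1 - mm$prob) / nrow(sim)))
  expect_lt(abs(mean(td) - mm$mean), 3 * stats::sd(td) / sqrt(length(td)))
  expect_lt(abs(stats::sd(td) - mm$sd), 3 * se_sd(td))
})
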