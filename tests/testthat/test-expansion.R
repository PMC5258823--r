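test_that("reach probabilities match the gambler's-ruin closed form", {
  p <- clone_params(phi = 1)
  # zeta_k = k!: v_{1,5} = 1 / (1 + 1 + 2 + 6 + 24)
  expect_equal(reach_probability(p, 1, 5), 1 / 34, tolerance = 1e-12)
  expect_equal(reach_probability(p, 5, 5), 1)
  expect_equal(reach_probability(p, 0, 5), 0)
  expect_error(reach_probability(p, 6, 5), "contraction")

  # soft niche, printed table entry (truncated to 5 decimals there)
  soft <- clone_params(phi = 1000, nu = 200, n_mean = 1, regime = "soft")
  expect_lt(abs(reach_probability(soft, 1, 2) - 0.83263), 1.1e-5)
})

test_that("closed forms agree with a dense solve of the first-step system", {
  set.seed(42)
  for (rep in 1:8) {
    p <- clone_params(phi = runif(1, 0.2, 30), mu = runif(1, 0.5, 3),
                      nu = sample(0:4, 1), n_mean = sample(1:20, 1))
    i_rho <- sample(3:12, 1)
    s <- runif(1, 0, 2)
    ora_v <- dense_lst(p, i_rho, 0)
    ora_s <- dense_lst(p, i_rho, s)
    ld <- rate_ladder(p, i_rho)
    for (i in 0:i_rho) {
      expect_close(reach_probability(p, i, i_rho, ladder = ld), ora_v[i + 1])
      expect_close(expansion_lst(p, i, i_rho, s, ladder = ld), ora_s[i + 1])
    }
    mm <- expansion_moments(p, i_rho, k_max = 2, ladder = ld)
    expect_equal(mm$m, dense_moments(p, i_rho, 2), tolerance = 1e-10)
  }
})

test_that("the transform interpolates between its boundary values", {
  p <- clone_params(phi = 2, mu = 1)
  expect_equal(expansion_lst(p, 1, 4, 0), reach_probability(p, 1, 4),
               tolerance = 1e-12)
  expect_equal(expansion_lst(p, 4, 4, 3.7), 1)
  # single-factor product: phi_{1,2}(s) = lambda_1 / (s + mu_1 + lambda_1)
  s <- 1.3
  expect_equal(expansion_lst(p, 1, 2, s), 2 / (s + 1 + 2), tolerance = 1e-12)
  expect_error(expansion_lst(p, 1, 2, -1), "`s`")
})

test_that("restricted first moment equals the transform derivative at 0", {
  p <- clone_params(phi = 3, mu = 1.5, nu = 2, n_mean = 5)
  i_rho <- 6
  mm <- expansion_moments(p, i_rho, k_max = 1)
  h <- 1e-5
  for (i in 1:(i_rho - 1)) {
    deriv <- (expansion_lst(p, i, i_rho, h) -
                expansion_lst(p, i, i_rho, 0)) / h
    d2 <- (expansion_lst(p, i, i_rho, 2 * h) -
             expansion_lst(p, i, i_rho, 0)) / (2 * h)
    richardson <- 2 * deriv - d2 # kills the O(h) error term
    expect_equal(mm$m[2, i + 1], -richardson, tolerance = 1e-6)
  }
})

test_that("reach probability is monotone in the target and in phi", {
  p <- clone_params(phi = 5)
  v <- vapply(2:15, function(ir) reach_probability(p, 1, ir), numeric(1))
  expect_true(all(diff(v) <= 0))
  vphi <- vapply(c(0.5, 1, 2, 5, 10),
                 function(phi) reach_probability(clone_params(phi = phi), 1, 6),
                 numeric(1))
  expect_true(all(diff(vphi) > 0))
})

test_that("moment boundaries and the exponential single-step limit hold", {
  p <- clone_params(phi = 4, mu = 2)
  mm <- expansion_moments(p, 5, k_max = 2)
  expect_equal(mm$m[1, ], mm$v)
  expect_equal(mm$m[2:3, 1], c(0, 0))
  expect_equal(mm$m[2:3, 6], c(0, 0))
  expect_true(all(mm$m >= 0))
  # conditional T_{1,2} is exponential(lambda_1 + mu_1): mean == sd
  st <- conditional_passage_stats(p, 1, 2)
  expect_equal(st$mean, 1 / 6, tolerance = 1e-12)
  expect_equal(st$sd, 1 / 6, tolerance = 1e-8)
})

test_that("the maximum-size distribution telescopes and is summarised correctly", {
  p <- clone_params(phi = 0.1)
  d <- xmax_distribution(p, i0 = 1)
  # telescoping: total pmf mass equals 1 - v_{i0, K+1}
  expect_equal(sum(d$pmf$pmf), 1 - d$surv_next, tolerance = 1e-12)
  expect_equal(d$covered_mass, sum(d$pmf$pmf), tolerance = 1e-12)
  expect_gte(d$covered_mass, d$q_max)
  # pmf(1) = 1 - 1/11, pmf(2) = v_{1,2} - v_{1,3} with zeta = k! 10^k
  expect_equal(d$pmf$pmf[1], 1 - 1 / 11, tolerance = 1e-10)
  expect_equal(d$pmf$pmf[2], 1 / 11 - 1 / 211, tolerance = 1e-10)
  expect_equal(d$pmf$survival[2], reach_probability(p, 1, 2), tolerance = 1e-12)
  expect_error(xmax_distribution(p, q_max = 1.2), "q_max")

  # percentile at tiny q collapses to the initial size
  expect_identical(xmax_percentile(d, 0.01), 1L)
  expect_error(xmax_percentile(d, 0.999), "q_max")
})

test_that("percentile-truncated summaries reproduce the hard-niche reference rows", {
  # mu = 1, i0 = 1, q_max = 0.99; five printed decimals
  p01 <- clone_params(phi = 0.1)
  d01 <- xmax_distribution(p01)
  expect_identical(xmax_percentile(d01, c(0.25, 0.5, 0.75, 0.99)),
                   c(1L, 1L, 1L, 2L))
  expect_equal(xmax_mean(d01), 1.08143, tolerance = 1e-5)
  expect_equal(tmax_moments(p01), 0.07834, tolerance = 2e-4)

  p1 <- clone_params(phi = 1)
  d1 <- xmax_distribution(p1)
  expect_identical(xmax_percentile(d1, c(0.25, 0.5, 0.75, 0.99)),
                   c(1L, 2L, 3L, 5L))
  expect_equal(xmax_mean(d1), 1.84694, tolerance = 1e-5)
  expect_equal(xmax_truncated_prob(d1, c(0.25, 0.5, 0.75, 0.99)),
               c(0.99351, 0.49351, 0.24351, 0.02292), tolerance = 1e-4)
  st <- conditional_passage_stats(p1, 1, 3)
  expect_equal(st$mean, 1.25, tolerance = 1e-5)
  expect_equal(st$sd, 1.03078, tolerance = 1e-5)

  p5 <- clone_params(phi = 5)
  d5 <- xmax_distribution(p5)
  expect_identical(xmax_percentile(d5, c(0.25, 0.5, 0.75, 0.99)),
                   c(4L, 10L, 12L, 16L))
  expect_equal(xmax_mean(d5), 8.40494, tolerance = 1e-5)
})
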