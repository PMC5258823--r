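# Dense linear-system oracles, independent of the package's sweep/ladder
# code paths: they build the full first-step system and call base solve().

# restricted LST phi_{i,irho}(s) for all i = 0..irho
dense_lst <- function(params, i_rho, s) {
  lam <- birth_rate(params, 0:i_rho)
  dth <- death_rate(params, 0:i_rho)
  n <- i_rho - 1
  if (n == 0) return(c(0, 1))
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in 1:n) {
    A[i, i] <- s + lam[i + 1] + dth[i + 1]
    if (i > 1) A[i, i - 1] <- -dth[i + 1]
    if (i < n) A[i, i + 1] <- -lam[i + 1]
  }
  b[n] <- lam[i_rho] # boundary term lambda_{irho-1} * phi_{irho} = lambda_{irho-1}
  c(0, solve(A, b), 1)
}

# restricted moments by solving the derivative systems densely, k ascending
dense_moments <- function(params, i_rho, k_max) {
  lam <- birth_rate(params, 0:i_rho)
  dth <- death_rate(params, 0:i_rho)
  v <- dense_lst(params, i_rho, 0)
  out <- matrix(0, k_max + 1, i_rho + 1)
  out[1, ] <- v
  n <- i_rho - 1
  if (n == 0) return(out)
  A <- matrix(0, n, n)
  for (i in 1:n) {
    A[i, i] <- lam[i + 1] + dth[i + 1]
    if (i > 1) A[i, i - 1] <- -dth[i + 1]
    if (i < n) A[i, i + 1] <- -lam[i + 1]
  }
  for (k in 1:k_max) out[k + 1, 2:i_rho] <- solve(A, k * out[k, 2:i_rho])
  out
}

# full dense solve of the augmented (size, divisions) transform system
dense_divtime_lst <- function(params, i0, D, s) {
  if (D == 0) return(1)
  imax <- i0 + D
  lam <- birth_rate(params, 0:(imax + 1))
  dth <- death_rate(params, 0:(imax + 1))
  idx <- function(i, d) sum(i0 + 0:d) - (i0 + d) + i # states (1..i0+d, d)
  n <- sum(i0 + 0:(D - 1))
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (d in 0:(D - 1)) {
    for (i in 1:(i0 + d)) {
      r <- idx(i, d)
      A[r, r] <- s + lam[i + 1] + dth[i + 1]
      if (i > 1) A[r, idx(i - 1, d)] <- -dth[i + 1]
      if (d < D - 1) A[r, idx(i + 1, d + 1)] <- -lam[i + 1]
      else b[r] <- lam[i + 1] # next layer is absorbing with transform 1
    }
  }
  solve(A, b)[idx(i0, 0)]
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}

# scale-aware closeness for probabilities/transforms: the dense oracle keeps
# absolute (not relative) accuracy in its smallest components
expect_close <- function(actual, expected, tol = 1e-10) {
  expect_true(all(abs(actual - expected) <= tol * pmax(abs(expected), 1e-4)))
}

# large-sample standard error of a sample sd, fourth-moment (skew-robust) form
se_sd <- function(x) {
  n <- length(x)
  s2 <- stats::var(x)
  m4 <- mean((x - mean(x))^4)
  sqrt(max(m4 - s2^2, 0) / (4 * s2 * n))
}
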