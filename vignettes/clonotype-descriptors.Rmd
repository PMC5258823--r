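---
title: "Birth-death descriptors of naive T cell clonotype fate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Birth-death descriptors of naive T cell clonotype fate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonofate)
```

## The model and its assumptions

A naive T cell clonotype of size $i$ gains one cell at rate
$$\lambda_i \;=\; \varphi\, e^{-\nu} \sum_{r\ge 0} \frac{\nu^r}{r!}\,
\frac{i}{r\langle n\rangle + i},\qquad
\mu_i = \mu\, i,$$
and loses one cell at rate $\mu_i$. The Poisson weights summarise
competition: the clonotype shares each homeostatic survival signal with a
Poisson($\nu$) number of competitor clonotypes of characteristic size
$\langle n\rangle$, which are not modelled explicitly — collapsing the
multivariate competition process into this univariate chain is the key
modelling assumption inherited from the underlying homeostasis model.
Rates are time-homogeneous: no ageing, no niche remodelling, no thymic
replenishment of the clonotype itself. State $0$ is absorbing
($\lambda_0 = 0$; the hard-niche display $\lambda_i = \varphi$ applies to
occupied states $i \ge 1$ only), and extinction is certain from every
state, which is why the interesting quantities are transient descriptors.

Parameters, with units and defaults:

| parameter | meaning | unit | default |
|---|---|---|---|
| `phi` | homeostatic signalling (proliferation) rate; proxy for TCR affinity x cross-reactivity | 1/time | — |
| `mu`  | per-cell death rate; `mu = 1` makes the time unit one mean T cell lifetime | 1/time | 1 |
| `nu`  | mean number of competing clonotypes | — | 0 |
| `n_mean` | characteristic competitor clonal size $\langle n\rangle$ | cells | 1 |
| `regime` | `exact` (full Poisson series), `hard` ($\nu \ll 1$), `soft` ($\nu \gg 1$) | — | auto |

Regime auto-resolution uses `hard` when `nu == 0` and `exact` otherwise;
the `soft` limit is applied only on explicit request, because at any
finite $\nu$ it is an approximation the user should opt into. The Poisson
series is evaluated over the central window holding at least
$1 - 10^{-12}$ of the Poisson($\nu$) mass (the weights themselves come
from `dpois`, computed on the log scale), so the series truncation is
far below every other error source even at $\nu$ of several hundred.

## Descriptors

All descriptors derive from the defective passage time
$T_{i,i_\varrho}$ to a target size and its division-count analogue
$N_{i,i_\varrho}$:

* **Reach probability.** $v_{i,i_\varrho} =
  \left(\sum_{m<i_\varrho}\zeta_m\right)^{-1}\sum_{k<i}\zeta_k$ with
  $\zeta_i = \prod_{k\le i}\mu_k/\lambda_k$. The ladder $\log\zeta$ is
  tabulated once (`rate_ladder()`) and all sums are log-sum-exp: a hard
  niche at $\varphi = 100$ drives $\zeta$ through hundreds of orders of
  magnitude, and the cumulative sums are computed by a streaming pairwise
  update because a single global shift would underflow the early
  prefixes.
* **Restricted transforms and moments.** The first-step equations for
  the restricted Laplace–Stieltjes transform form a tridiagonal system;
  forward elimination gives a continued-fraction product
  (`expansion_lst()`). Moments of order $k$ satisfy the same tridiagonal
  system with inhomogeneity $k\,m^{(k-1)}$ and are solved by a sweep
  $x_i = A_i x_{i+1} + B_i$ in which every intermediate quantity is
  positive — no cancellation even when moments span forty orders of
  magnitude. The equivalent explicit $\zeta$-series solution is kept in
  the test suite as an oracle, together with dense `solve()` checks.
* **Maximum clonal size.** $P(X^{max}_{i_0} \ge i_\varrho) =
  v_{i_0,i_\varrho}$ turns reach probabilities into the pmf of the
  running maximum before extinction. Means of $X^{max}$, $T^{max}$ and
  $N^{max}$ are truncated at the percentile $K_{q}$ with $q = 0.99$ by
  default (`q_max`), the untruncated series having no tractable closed
  form; the neglected mass is below $1-q$. `q_max = 0.999` is the
  documented alternative when $K_{0.99}$ collapses to the initial size.
* **Contraction.** For targets below the start, absorption is certain
  and the Karlin–McGregor series applies; the inner series is truncated
  when the running term falls below `tail_tol` ($10^{-12}$ by default)
  times the partial sum, which the factorial decay of
  $1/(\lambda_j\rho_j)$ makes cheap. Order $k$ needs order $k-1$ on a
  grid of larger states, so the grid cap carries a margin of
  $10\,k_{max}$ states beyond the adaptive cap; halving `tail_tol`
  changes the mean by less than `tail_tol` relative (tested).
* **Time to $D$ divisions.** The augmented chain over (size, divisions)
  couples each transient state only to its same-layer neighbour below
  and its next-layer neighbour above, so the transform and moment
  systems resolve by pure forward substitution, sweeping layers
  $d = D-1,\dots,0$ and sizes upward within a layer — no matrix is ever
  formed or inverted. A dense solve of the full system is the test
  oracle on small grids. Probabilities are carried in linear doubles;
  values below about $10^{-300}$ underflow to 0, far beyond the
  $10^{-18}$ scale of any quantity reported here.

## Numerical choices and tie-breaks

* **Percentiles.** $K_q$ is the first size whose cumulative probability
  *strictly* exceeds $q$, with a $10^{-12}$ guard so that exact rational
  ties (e.g. a cdf of exactly $1/2$ at $q = 0.5$) are pushed to the next
  size rather than resolved by the sign of a $10^{-16}$ rounding error.
  The strict convention is the one consistent with the reference
  tabulations this package reproduces; under the non-strict reading a
  cdf exactly equal to $q$ would already qualify.
* **Truncated summaries.** The truncated mean of $X^{max}$ includes the
  $i_\varrho = i_0$ term; truncated probabilities are reported as
  $\tilde P(X^{max}\ge K_q) = v_{i_0,K_q} - v_{i_0,K_{q_{max}}+1}$, so
  that for $K_q = i_0$ they equal the total truncated mass.
* **Defective conditioning.** Standard deviations of defective variables
  are always reported conditionally on the finite event; variance is
  clipped at 0 before the square root to absorb rounding at degenerate
  cases (e.g. the exactly-exponential single-step passage).
* **Division-count pmf.** The embedded-chain recursion is extended in
  $j$ until the missing mass $v - \sum_j P(N=j)$ drops below $10^{-8}$
  (no stopping rule is inherent to the recursion itself).
* **One division from one cell.** From $i_0 = 1$, reaching size 2 given
  non-extinction involves exactly one birth, so the conditional division
  count is 1 with sd 0. This does *not* generalise to larger $i_0$: from
  $i_0 > 1$ the chain can dip below its start and register births on the
  way back up before first touching $i_0 + 1$.

## The simulator as synthetic-data generator

`simulate_clonotype()` draws exact Gillespie paths of the same chain the
analytic code solves — its defaults (a single initial cell, paths run to
extinction, rates from the same `clone_params`) *are* the study
conditions, not tuning knobs. One root seed spawns per-trajectory
splitmix64-seeded mt19937 streams with inverse-transform exponentials, so
runs are bit-reproducible across platforms and extending the replicate
count leaves earlier trajectories unchanged. What the simulation shares
with real data is only what the model itself assumes: it emulates
demographic stochasticity of a single clonotype under constant rates, not
measurement noise, not explicit competitor dynamics, not thymic export or
ageing. Agreement between simulation and the analytic descriptors
therefore validates the implementation, and says nothing beyond the model
about real repertoires.

Establishment regimes (hard niche with $\varphi \gtrsim 10$) have
extinction times of $10^4$–$10^{41}$ lifetimes; full-path simulation is
infeasible there and the simulator censors at explicit caps
(`max_time`, `max_events`, and the rate-table cap `i_cap`), reporting the
censored fraction rather than silently biasing estimates. The Monte Carlo
test grid is restricted to regimes with modest extinction times; the
large-$\varphi$ descriptors are exercised analytically only.

## Problem sizes

The test suite solves dense oracles up to target sizes ~12 and augmented
grids up to $D = 3$, and uses $2\times 10^4$–$3\times 10^4$ simulated
paths for the 3-standard-error agreement checks; the reproducibility
script uses $10^5$ paths for the simulated mean maximum. These sizes give
Monte Carlo standard errors comfortably below the effects being checked
while keeping a full run in seconds.

## Known limitations

* Moments of $T^{max}$/$N^{max}$ are percentile-truncated by
  construction; in extreme-establishment regimes the reported means are
  lower bounds whose bias is controlled by $1-q_{max}$ times the tail
  conditional moments, not by a hard error bound.
* The `exact` regime evaluates the Poisson series per state; building
  ladders to $10^5$ states at $\nu$ of several hundred is noticeably
  slower than the closed-form regimes (though still linear).
* The augmented division-time grid grows as $i_0 D + D^2/2$ states;
  very large $(i_0, D)$ pairs are better bounded by the monotonicity
  properties than solved outright.
* Censored simulation estimates are flagged, not corrected; no attempt
  is made to extrapolate beyond caps.
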