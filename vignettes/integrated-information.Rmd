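---
title: "Measuring integrated information by mismatched decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring integrated information by mismatched decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phistar)
```

## The quantity being measured

Integrated information asks how much information a system generates *as a
whole, above and beyond its parts*. The package works with the intrinsic
information a system carries about itself across time: the mutual
information $I(X^{t-\tau}; X^t)$ between the state of $N$ channels at time
$t-\tau$ and at time $t$. Given a partition of the channels into parts
$M_1, \dots, M_m$, an integrated-information measure should satisfy two
bounds to be interpretable: it should be $0$ when the system carries no
information or when the parts are independent, and it should never exceed
the whole-system information $I$.

The measure at the core of this package, $\Phi^*$, is built from
*mismatched decoding*. Decoding the past from the present by maximum
likelihood with the true conditional distribution
$p(X^t \mid X^{t-\tau})$ extracts the full $I$. Decoding instead with the
partitioned distribution

$$q(X^t \mid X^{t-\tau}) = \prod_{i=1}^{m} p(M_i^t \mid M_i^{t-\tau}),$$

which pretends the parts do not interact, extracts at most

$$I^* = \max_{\beta > 0} \left[
  -\sum_{X^t} p(X^t) \log \sum_{X^{t-\tau}} p(X^{t-\tau})\,
    q(X^t|X^{t-\tau})^{\beta}
  + \sum_{X^{t-\tau}, X^t} p(X^{t-\tau}, X^t) \log q(X^t|X^{t-\tau})^{\beta}
\right],$$

where $\beta$ tilts how strongly the decoder weights its (wrong) model.
Then $\Phi^* = I - I^*$ is the information *lost* by ignoring the
interactions between parts. By construction $0 \le I^* \le I$, so $\Phi^*$
satisfies both bounds.

Two earlier practical measures are implemented for comparison, because
each fails one bound and the package's validation suite demonstrates this:

* $\Phi_I = I - \sum_i I(M_i^{t-\tau}; M_i^t)$ can be **negative** when
  parts are redundant (correlated), violating the lower bound;
* $\Phi_H = \sum_i H(M_i^{t-\tau}|M_i^t) - H(X^{t-\tau}|X^t)$ (stochastic
  interaction) is never negative but is **positive even for systems that
  carry no information at all**, violating the upper bound.

For small discrete systems the package also provides the original
maximum-entropy measure $\Phi$, which imposes a uniform distribution on
the past states. Under that prior $\Phi$ and $\Phi^*$ coincide; the test
suite verifies the equivalence numerically on random transition matrices
rather than assuming it.

## The Gaussian engine

Summing over all states is exponential in $N$, so for continuous
recordings the package assumes jointly Gaussian past and present states,
described by a covariance triple $\Sigma(X^{t-\tau})$, $\Sigma(X^t)$,
$\Sigma(X^{t-\tau}, X^t)$ (`lagged_gaussian()`). Then

$$I = \tfrac12 \log \frac{|\Sigma(X^{t-\tau})|}{|\Sigma(X^{t-\tau}|X^t)|},
\qquad
\Sigma(X^{t-\tau}|X^t) = \Sigma(X^{t-\tau}) -
\Sigma(X^{t-\tau},X^t)\,\Sigma(X^t)^{-1}\,\Sigma(X^{t-\tau},X^t)^{\top},$$

and $I^*(\beta)$ has a closed form in the block-diagonal within-part
covariances $\Sigma_D(X^{t-\tau})$, $\Sigma_D(X^t, X^{t-\tau})$,
$\Sigma_D(X^t|X^{t-\tau})$ (`assemble_block_diagonals()`):

$$I^*(\beta) = \tfrac12 \operatorname{Tr}\!\big(\Sigma(X^t) R\big)
  + \tfrac12 \log\big(|Q|\,|\Sigma(X^{t-\tau})|\big) - \frac{\beta N}{2},$$

with $Q = \Sigma(X^{t-\tau})^{-1} + \beta\,G$,
$G = \Sigma_D(X^{t-\tau})^{-1} \Sigma_D(X^t,X^{t-\tau})^{\top}
\Sigma_D(X^t|X^{t-\tau})^{-1} \Sigma_D(X^t,X^{t-\tau})
\Sigma_D(X^{t-\tau})^{-1}$ and
$R = \beta\,\Sigma_D(X^t|X^{t-\tau})^{-1} - \beta^2 K Q^{-1} K^{\top}$,
$K = \Sigma_D(X^t|X^{t-\tau})^{-1} \Sigma_D(X^t,X^{t-\tau})
\Sigma_D(X^{t-\tau})^{-1}$. The analytic derivative
$dI^*/d\beta$ (`mismatched_information_deriv()`) follows by matrix
calculus and is cross-checked against central finite differences in the
tests.

A useful consistency check, exercised throughout the suite: with the
single-block partition $q = p$, the derivative vanishes at $\beta = 1$ and
$I^*(1) = I$, so $\Phi^*$ of an unpartitioned system is exactly zero.

### Maximizing over the tilt

`solve_beta_star()` finds the stationary point of $I^*(\beta)$ on
$\beta \in [10^{-6}, 100]$ by evaluating the analytic derivative on a
log-spaced bracket grid and refining the sign change with Brent root
finding (tolerance $10^{-12}$). Choices worth recording:

* **$\beta$ is not constrained to $[0, 1]$.** Nothing in the derivation
  requires $\beta^* \le 1$, so the solver searches broadly; in practice the
  benchmark systems give $\beta^*$ between roughly $0.5$ and $1$.
* A claimed algebraic reduction of $dI^*/d\beta = 0$ to a quadratic in
  $\beta$ is not used: $Q^{-1}$ depends on $\beta$ non-polynomially, and
  the numeric stationary-point solver is treated as authoritative. The
  test suite instead verifies the solver against dense grid search over
  $\beta$ at $10^{-4}$ resolution (to $10^{-6}$ nats).
* **Flat objectives.** When the system carries no information, or the
  partition matches the true dependency structure, $I^*(\beta)$ is
  constant ($\equiv 0$ resp. linear effects cancel) and every $\beta$ is a
  maximizer; the solver detects a numerically zero derivative everywhere
  and reports $\beta^* = 1$, the matched-decoding convention.
* The discrete engine has no analytic derivative and uses golden-section
  search (`stats::optimize`) on $I^*$ itself, with the same interval.

### Numerical hygiene

All covariance inputs are symmetrized as $(S + S^{\top})/2$;
log-determinants are computed from Cholesky factors in log space; matrix
inverses go through an eigenvalue floor of $10^{-12} \cdot
\mathrm{tr}(S)/N$, below which the computation *stops with the offending
matrix and its condition number* rather than silently ridging (a `ridge`
argument exists but is opt-in). Exactly singular joints — e.g. perfectly
correlated channels at $c = 1$ — are rejected at construction; limiting
behavior is studied at $c = 1 - \varepsilon$ with
$\varepsilon = 10^{-6}$, where $\Phi^*$ has a finite (vanishing) limit
even though $I$ itself diverges. Bound violations beyond $10^{-8}$ nats
raise errors instead of being clipped, so defects (such as $\Phi_I < 0$,
which is *expected*) remain observable. All values are in nats;
`in_bits()` and the `value_bits` JSON field convert.

## The discrete engine

`discrete_joint()` stores the full table $p(X^{t-\tau}, X^t)$ over
composite states (lexicographic order, unit 1 most significant) and
evaluates every quantity by exact summation, with $0 \log 0 := 0$. The
mismatched decoder $q$ is assembled from the joint's own per-part
marginals, so $q > 0$ wherever $p > 0$ and no smoothing is ever needed.
Past states with zero prior probability simply contribute nothing. The
composite state space is capped at $2^{12}$ states because the sums grow
exponentially in the number of units. The tests pin all discrete
quantities to a brute-force oracle that loops over every state pair with
string-keyed tables — an independent code path from the vectorized
implementation.

## The autoregressive validation system

Because real recordings have no ground truth, correctness is demonstrated
on the stable first-order autoregressive model
$X^t = A X^{t-1} + E^t$ (`var_system()`), whose steady-state covariance
solves the discrete Lyapunov equation
$\Sigma(X) = A \Sigma(X) A^{\top} + \Sigma(E)$ — solved exactly here by
the Kronecker vectorization $(I - A \otimes A)\,\mathrm{vec}(\Sigma) =
\mathrm{vec}(\Sigma(E))$, which is cheap at these sizes and leaves a
residual below $10^{-10}$. The lag-$\tau$ cross covariance is
$\Sigma(X)\,(A^{\tau})^{\top}$, with the orientation fixed as
$\mathrm{cov}(X_i^{t-\tau}, X_j^t)$: for the symmetric benchmark systems
a transposition would be invisible, but for asymmetric $A$ it is not, so
the convention is stated here and in the constructor documentation.

The two-unit benchmark (`build_two_unit_system()`) has $A = a\,\mathbf{1}
\mathbf{1}^{\top}$ and unit-variance noise with correlation $c$ — the
study conditions under which each measure's failure mode is visible:

* $a = 0$, $c = 0.9$: no information at all ($I = 0$), yet strong
  instantaneous correlation. $\Phi^*$ and $\Phi_I$ are $0$; $\Phi_H
  \approx 0.830$ nats is not.
* $a = 0.4$, $c$ swept to $1$: $\Phi^*$ decreases monotonically to $0$;
  $\Phi_I$ turns negative once $c$ exceeds $\approx 0.15$; $\Phi_H$ keeps
  growing.

`simulate_var()` draws the initial state from the steady-state
distribution, shapes noise by the Cholesky factor of $\Sigma(E)$, and
discards a 1000-step burn-in — redundant given the steady-state start,
but costless insurance. One integer seed (R's default Mersenne–Twister)
fully determines a trajectory.

What the generator emulates is the *covariance structure* of multichannel
recordings: stationary Gaussian signals with controllable temporal and
instantaneous dependence. What it does not emulate: non-stationarity,
non-Gaussian amplitude distributions, line noise and movement artifacts,
volume conduction, or oscillatory spectra of real electrophysiology.
Passing tests therefore establish that the estimators and formulas are
correct under the model's assumptions, not that those assumptions hold
for any particular recording.

## From recordings to covariances

`estimate_lagged_covariance()` mirrors standard practice for long
electrophysiological recordings: split the recording into windows
(defaults chosen by the caller; 2 s windows with 2 s steps averaged over
600 s is typical at 1 kHz), form lagged pairs $(X^{t-\tau}, X^t)$ *within*
each window only, subtract each window's mean, compute maximum-likelihood
($1/n$) covariances, and average the three matrices across windows. Where
the field's conventions are genuinely underdetermined, the package's
choices are: per-window mean subtraction; $1/n$ rather than $1/(n-1)$
denominators, for consistency with the plug-in Gaussian formulas; past
and present marginals estimated separately (their steady-state equality
is checkable, not assumed); and windows shorter than $2\tau$ samples
rejected. `bipolar_rereference()` implements the neighboring-electrode
subtraction used to suppress common noise before covariance estimation,
and `ms_to_samples()` converts millisecond lags at a given sampling rate.

## Partitions and the MIP

`enumerate_partitions()` generates all set partitions (Bell-number many,
guarded at $N \le 12$); `find_mip()` evaluates a measure over candidates
and returns the minimum — the partition across which the system is least
integrated. Two open issues are deliberately left open: no normalization
across partition granularities is applied (the known entropy-based
normalization can be negative for continuous variables, so `find_mip()`
compares raw values and merely exposes a `normalize` hook), and no
heuristic search is attempted (candidates are evaluated exhaustively;
ties break to the canonically smallest partition). The atomic partition
— every channel its own part — upper-bounds $\Phi^*$ over all partitions
and is the default throughout.

## Problem sizes used in validation

The shipped suite validates on: the analytic two-unit benchmarks (exact,
sub-second); random stable systems of 2–4 units across all non-trivial
partitions (200 systems in the bound suite); $10^6$-step simulations for
Monte-Carlo and estimation-recovery checks (agreement within 1–2%, the
sampling accuracy such lengths support); and dense $\beta$ grids at
$10^{-4}$ resolution for the maximizer cross-check. These sizes were
chosen to make sampling error comfortably smaller than the tolerances
being asserted.

## Known limitations

* The Gaussian engine is exact only for Gaussian data; for heavy-tailed
  or strongly nonlinear signals the quantities are those of the
  best-fitting Gaussian, no more. No kernel or copula estimators are
  provided.
* The discrete engine is exponential in the number of units by nature.
* Only first-order autoregressive generators are included, and the
  package does not estimate $A$ from data — only covariances.
* Exact MIP search is exponential in $N$; for the 64-channel atomic
  analyses the atomic partition is used directly, as is standard.
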