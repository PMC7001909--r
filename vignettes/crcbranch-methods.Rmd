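---
title: "Modelling colorectal adenoma-carcinoma progression with crcbranch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling colorectal adenoma-carcinoma progression with crcbranch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcbranch)
```

## The model

Colorectal cancer develops through benign adenomatous polyps. `crcbranch`
describes the cellular natural history of one individual's colon as a
continuous-time two-type branching process with immigration:

* adenoma (type A) cells are initiated from the colonic stem-cell pool at a
  constant rate $\mu_1$ (cells/year), divide at rate $b_1$ and die at rate
  $d_1$ (both per cell per year);
* each adenoma cell transforms into a malignant (type M) cell at rate
  $\mu_2$; malignant cells divide at $b_2$ and die at $d_2$.

The net growth rates $\gamma_1 = b_1 - d_1$ and $\gamma_2 = b_2 - d_2$
control the exponential mean growth of the two compartments.  A fraction
$\lambda$ of the population never develops adenomas at all, which enters
the likelihood as a zero-inflation mixture.  Compartment sizes are related
to endoscopist-reported lesion dimensions by treating a lesion as a
half-ellipsoid with all semi-axes equal to half the reported diameter
($N(d) = 10^8 \cdot \pi d^3 / 12$ cells for $d$ in cm), the convention that
also reproduces the published growth-timing figures (21.9 years from 3 mm
to 10 mm at $\gamma_1 = 0.165$; under 7.35 years from one cell to 2.5 mm at
$\gamma_2 = 1.76$).

### The adenoma compartment

With the transformation drain ignored ($\mu_2 = 0$), the adenoma
compartment is a linear birth-death process with immigration whose size at
age $t$ is negative binomial with dispersion $r = \mu_1/b_1$ and success
probability $p(t) = b_1(e^{\gamma_1 t}-1)/(b_1 e^{\gamma_1 t}-d_1)$.
Binned observations $(L, U]$ then have likelihood
$I_p(L+1, r) - I_p(U+1, r)$ in terms of the regularized incomplete beta
function (`pbeta`); the orientation of the tail identity is pinned in the
test suite by comparison with brute-force pmf sums rather than assumed.
Setting $\mu_2 = 0$ here mirrors the closed-form derivation; the exact
marginal (effective death rate $d_1 + \mu_2$) is available through
`include_mu2 = TRUE` and matters only when $\mu_2$ is not small.

### The carcinoma compartment

No closed-form size distribution exists for the malignant compartment.
All computations go through the probability generating function.  The
single-ancestor PGF $f(s, u) = E[s^{M(u)}]$ (one fresh adenoma cell)
solves the backward Kolmogorov equation
$$\partial_u f = b_1 f^2 - (b_1+d_1+\mu_2) f + d_1 + \mu_2 h(s,u),\qquad
f(s,0)=1,$$
with $h$ the linear birth-death PGF of one malignant cell.  Immigration
exponentiates it:
$\log G(s,t) = \mu_1 \int_0^t (f(s,u)-1)\,du.$
The integral (and up to four $s$-derivatives, obtained from companion
ODEs, never finite differences) is carried as augmented state of an
adaptive Cash-Karp RK45 integrator written in C++, vectorized over PGF
argument nodes and capable of complex arguments.  Two independent routes
to $\log G$ (augmented ODE state vs composite Gauss-Legendre quadrature
of $f-1$, plus `deSolve::lsoda` in the tests) agree to better than
$10^{-6}$ relative.

The cumulative probability $P(M(t)\le N)$ is the $N$-th Taylor coefficient
of $G(s,t)/(1-s)$:

* **exact contour extraction** (`exact_cdf_small`): trapezoidal quadrature
  on a circle of radius $\rho = e^{-3/(N+1)}$ with $\max(64, 6(N+1))$
  nodes.  This radius keeps the $\rho^{-N}$ round-off amplification
  bounded at $e^3$ while pushing aliasing below $10^{-8}$; radii far from
  1 are numerically catastrophic at large $N$, which is why the default is
  tied to $N$.  Cost grows linearly in $N$, so this is the small-$N$ tool
  (default switch-over at 100 cells) and the oracle for the approximation.
* **saddle-point approximation** (`cancer_cdf_approx`): the large-$N$
  route writes the coefficient as $\oint e^{V(s)} ds$ with
  $V(s) = -\log(1-s) + \log G(s,t) - (N+1)\log s$, locates the unique root
  of $V'$ in $(0,1)$ by safeguarded Newton iteration (bisection fallback;
  $V'$ is strictly increasing), and evaluates the Gaussian integral at the
  saddle.  The implementation multiplies the leading order
  $e^{V(s^*)}/\sqrt{2\pi V''(s^*)}$ by the next-order stationary-phase
  factor $1 + V''''/(8V''^2) - 5V'''^2/(24V''^3)$.  The correction matters:
  the bare leading order carries an irreducible bias that reaches
  $e/\sqrt{2\pi}-1 \approx 8.4\%$ when the integrand is dominated by the
  pole at $s=1$ (extinction-plateau regimes), whereas the corrected form
  stays within about half a percent of the exact coefficients for
  $N \ge 100$ across the tested parameter range — the accuracy contract
  asserted in the acceptance suite.  Below roughly 50-100 cells the
  asymptotics degrade (9% at $N=1$) and the package silently switches to
  the exact contour.  Values marginally above 1 are clipped; bin
  probabilities are floored at 0.

Inside the composite likelihood the per-parameter cost is kept flat by a
profile cache: one vectorized ODE solve over a fixed logit-spaced $s$-grid
records $\log G$ and its derivatives at every observation age, monotone
splines interpolate them, and all bin-bound saddle points are found by
vectorized bisection.  The fast path agrees with the direct per-$N$ solver
to $10^{-6}$ relative and is itself covered by tests.  Grid nodes whose
derivative states saturate the double range (they grow like
$e^{4\gamma_2 t}$ near $s=1$ for aggressive growth rates) are dropped
before interpolation; saddle points never lie in that region.

### Conditional risk of synchronous cancer

The clinically interesting quantity is $P(M(t)>0 \mid A(t)\in(L,U])$, the
probability that a patient with an adenoma finding of a given size already
harbours cancer cells.  Bayes' theorem needs the joint mass
$P(A=k, M=0)$, i.e. the Taylor coefficients of the sliced PGF
$G_A(x) = G(x, s{=}0, t)$.  Two regimes:

* below 4,000 cells the coefficients are extracted exactly by FFT on a
  contour;
* above, singularity analysis takes over.  $G_A$ has an algebraic branch
  point of exponent $-r$ (the same $r=\mu_1/b_1$ as the adenoma marginal,
  because the Riccati blow-up of $f$ contributes $-\log(\cdot)/b_1$ to the
  immigration integral) at a radius $x_c$ slightly beyond the marginal's
  singularity $1/p$.  Consequently the conditional
  $q(k)=P(M{=}0\mid A{=}k)$ is asymptotically a pure exponential
  $B\,(p\,x_c)^{-k}$, with $O(1/k)$ corrections.  $x_c$ is located to
  machine precision by bisection on ODE divergence, $B$ is calibrated in
  the FFT-exact window, and range sums reduce to negative-binomial tail
  differences with the tilted success probability $1/x_c$.  This route was
  chosen after two alternatives failed quantitatively: Gaussian saddle
  points carry 5-11% errors in the small-$r$ power-law regime
  ($N$ far below the compartment mean), and numerical steepest descent
  needs $O(N)$ contour nodes there because the integrand decays only like
  $\theta^{-r}$ along the circle.  The hybrid matches a 32,768-coefficient
  FFT oracle to about $10^{-3}$ or better everywhere tested.

Conditioning on a detected adenoma ($k \ge 1$) makes $\lambda$ cancel from
the Bayes ratio — the resistant subpopulation sits entirely at
$A=M=0$ — so it enters `cancer_risk_given_adenoma` only for
zero-containing ranges.  This is easy to get wrong and is covered by a
dedicated test.

## Simulation

`gillespie_run` is an exact stochastic simulation of the six-reaction
scheme.  Exact simulation of $10^8$-cell compartments is infeasible, so
`hybrid_cohort` switches to tau-leaping above 300 cells per compartment
(leap length bounded by a 3% relative propensity change and 0.25 years).
Two refinements proved necessary to pass the distributional oracles:

* leap propensities are evaluated at the deterministic midpoint state,
  removing the $O(\tau)$ weak (Euler) bias that otherwise compounds to
  tens of percent over the many leaps of an exponentially growing
  compartment;
* the transformation exposure within a leap uses the *realized*
  trapezoidal midpoint of $A$ (with exact binomial thinning when a leap is
  truncated), so that the correlation between adenoma-path fluctuations
  and cancer seeding survives conditioning on atypical adenoma sizes.
  Without this, conditional cancer frequencies given mid-size adenomas
  were biased by several standard errors.

Whichever compartment is still below the threshold keeps an exact
sub-clock inside each leap.  All randomness flows through R's RNG, so
seeded runs are bit-reproducible.

The synthetic-cohort generator mirrors the structure of endoscopy and
registry extracts: the default rates are the biologically motivated
simulation set ($\mu_1=3.1$, $b_1=9$, $d_1=8.8$, $\mu_2=10^{-5}$,
$b_2=9.2$, $d_2=8.8$, i.e. $\gamma_1=0.2$, $\gamma_2=0.4$), with a
resistant fraction defaulting to 0.4 in the recovery studies (the value
used for the joint-fit validation; an alternative reading of 0.45 appears
in the protocol description and 0.55 for registry-style fits — the
difference is a documented source ambiguity and the parameter is always
explicit here).  Sizes are reported to the nearest mm (0 mm below the
0.5 mm detection scale, roughly $3.3\times10^3$ cells) and mapped to
half-open $\pm 0.5$ mm cell-count bins; rare masses above 100 mm are
top-coded into an open bin, as registries do.  A consequence worth noting:
every carcinoma bin bound is then in the saddle-point validity range, so
the composite likelihood never needs the small-$N$ contour path.  What the
generator does *not* emulate: multiple synchronous lesions per patient
(the model tracks compartment totals), reporting heaped at round sizes,
detection that depends on location or endoscopist, or secular trends —
passing recovery tests therefore shows the inference machinery is
self-consistent at realistic scale, not that real registries satisfy the
model.

## Registry preparation

Cancer registries censor prevalent cases.  `impute_prevalence` runs the
normalized recursion
$\hat R(t) = \hat R(t-1)\,(1 - I(t)/(R(t)+I(t)))$ anchored at
$\hat R = 1$ at the youngest observed age (the anchor age is a
documented choice; the recursion itself is scale invariant), derives the
incident and prevalent proportions, and rescales by the estimated total
population $T(t) = I(t)/\hat I(t)$.  Imputed prevalent counts are rounded
to integer weights and placed in the open bin above 40 mm (configurable),
matching how censored prevalent cancers enter the size likelihood.

## Inference

Fits run over $(\mu_1, \mu_1/b_1, \gamma_1, \mu_2, \gamma_2)$ plus
optionally $\lambda$, on log scale (logit for $\lambda$), with $d_2 = d_1$
tied — the search vector contains no independent $d_2$, which also matches
the simulation parameter set.  The composite log-likelihood adds the
per-row binned log-likelihoods of both compartments, each passed through
the resistant-fraction mixture; weights multiply log terms; any
zero-probability row yields $-\infty$ (a large finite penalty inside the
optimizer keeps the simplex mobile).  `mle_fit` uses Nelder-Mead (Brent
for one-dimensional problems); `adaptive_mcmc` is a random-walk Metropolis
whose global scale follows a Robbins-Monro recursion targeting 30%
acceptance and whose per-coordinate scales track the running standard
deviation of the chain, both frozen after half the chain so the second
half is a fixed-kernel sample.  The classic protocol is 10,000 steps; the
packaged studies use 700-2,000 steps at reduced data scale, which the
recovery tests show is sufficient for interval coverage there.

Two lognormal priors are available (off by default): initiation rate with
median 3,100/year and $\text{sdlog} = 1/25$, birth rate with median
9/year and $\text{sdlog} = 1/3$.  The published prior spreads are stated
as plain standard deviations without a scale; reading them as standard
deviations of the natural logarithm (with the stated central values as
medians) is the only interpretation under which both densities are
well-defined and tight in the intended way, and is what `log_prior`
implements.  Priors must be off for simulation-study fits — a prior
centred at 3,100 would overwhelm data generated at $\mu_1 = 3.1$.

A prevalence-only likelihood (cancer yes/no per observation, Bernoulli
with $P = (1-\lambda)\,P(M(t) > n_0)$ at the detection scale $n_0$ implied
by the data's zero bins) is provided to demonstrate *why* the size-based
likelihood matters: on synthetic data its $(\mu_2, \gamma_2)$ surface is a
flat ridge of compensating parameter pairs, while the size-based surface
has an interior maximum at the generating values.  The acceptance suite
asserts exactly this contrast.

## Numerical choices and problem sizes

Tolerances: ODE `rtol` $10^{-10}$ / `atol` $10^{-12}$; saddle root solved
to $10^{-9}$ relative on $V'$; contour residual imaginary parts above
$10^{-6}$ raise an error rather than being silently dropped.  The study
sizes shipped in the tests and the acceptance script — about $10^4$
adenoma observations for the marginal fit, $2\times10^4$ individuals for
the joint fit with a 2,000-step chain, $10^4$ exact simulation runs for
the distributional comparison, and 99.5% binomial intervals across the
nine conditioning ranges at age 60 with $1.5\times10^4$ individuals — are
the package's chosen reduced-scale study conditions; they keep every
quantity's Monte-Carlo error well below the effects being checked.

## Known limitations

* The composite likelihood treats the two compartments of the same
  individual as independent; with a fitted $\lambda$ the zero-inflation
  information is counted once per compartment.
* Interval coverage for $\lambda$ is sharp: with $n$ individuals the
  posterior interval has width comparable to the binomial fluctuation of
  the realized resistant fraction, so 95% intervals genuinely miss the
  population value about 5% of the time.
* Time-varying rates, per-lesion (clone-level) size distributions,
  multiple synchronous lesions, and future-risk prediction are out of
  scope; the model is deliberately the time-homogeneous two-type process.
* The conditional-risk tail calibration inherits $O(1/k)$ corrections;
  relative errors up to a few tenths of a percent at $k \sim 10^6$ cells
  are possible.
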