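---
title: "Methods: lesion kinetics, the system-size expansion, and its numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion kinetics, the system-size expansion, and its numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsm2)
```

## The model

A cell nucleus carries two lesion populations after irradiation: sublethal
lesions $X$ (reparable) and lethal lesions $Y$ (irreversible). Three
first-order channels act, each consuming sublethal lesions:

$$X \xrightarrow{\;r\;} \emptyset, \qquad
  X \xrightarrow{\;a\;} Y, \qquad
  X + X \xrightarrow{\;b\;} Y.$$

The joint probability $p(t, y, x)$ obeys a chemical master equation whose
pairwise-channel propensity is $\tilde b\, x(x-1)$ — the exact
combinatorial count of ordered pairs, with **no** $1/2$ symmetry factor.
This convention is used identically in the propensities, the lattice
generator and the expansion, so all three representations describe the
same process; choosing the halved convention would simply rescale $b$.

Assumptions worth making explicit:

* rates are constant in time (no dose-rate or repair-saturation effects);
* lethal lesions are absorbing — nothing removes them;
* the state $x = 0$ is absorbing for the whole process, since every
  channel needs at least one sublethal lesion;
* initial damage is supplied by the user, either as fixed counts or as an
  independent bivariate Gaussian (see below). No energy-deposition model
  is included.

## Parameters

| parameter | meaning | units | reference value |
|---|---|---|---|
| `r` | repair rate | 1/time | 4 |
| `a` | direct lethal conversion | 1/time | 0.1 |
| `b_tilde` | pairwise rate, count scale | 1/time | 0.01 |
| `a_logistic` | optional state-dependent death increment (death propensity $x(a + \bar a x)$) | 1/(time·lesion) | 0 |
| `K` | system size | — | $x_0$ |
| `x0`, `y0` | initial counts | lesions | 100, 0 |

Times are in arbitrary units throughout; the macroscopic relaxation time is
$1/(a+r) \approx 0.24$ at the reference rates, which is why the classic
observation times 0.5, 0.7, 0.9 straddle the decay of the sublethal pool.

**The system size `K`.** The expansion writes $X = K\bar x + \sqrt K\,\xi$
and assumes the macroscopic pairwise rate $b = \tilde b K$ is order 1. The
reference configuration states $\tilde b$ and $x_0$ but not $K$; the
package adopts the convention $K = x_0$, which makes $\bar x(0) = 1$ —
order one, as the expansion assumes. Every count-scale quantity is
invariant to this choice (the kinetic and moment ODEs are
scale-equivariant; the test suite checks this numerically), so the
convention affects presentation only.

## The expansion

Substituting the ansatz into the master equation and collecting powers of
$K$ gives, at order $\sqrt K$, the deterministic kinetic system

$$\frac{d\bar y}{dt} = a\bar x + b\bar x^2, \qquad
  \frac{d\bar x}{dt} = -(a+r)\bar x - 2b\bar x^2,$$

i.e. the classical deterministic equations of the microdosimetric kinetic
model, recovered here as a law of large numbers. The sublethal equation is
a Bernoulli ODE with closed form
$\bar x(t) = (a+r)/(c\,e^{(a+r)t} - 2b)$, $c = (a+r)/\bar x_0 + 2b$
(`xbar_closed_form()`). At order 1 the fluctuations solve a **linear**
Fokker–Planck equation with drift and diffusion (on the
$(\upsilon, \xi)$ ordering)

$$A(t) = \begin{pmatrix} 0 & -(2b\bar x + a)\\ 0 & 4b\bar x + a + r \end{pmatrix},
\qquad
D(t) = \begin{pmatrix} a\bar x + b\bar x^2 & -(a\bar x + 2b\bar x^2)\\
-(a\bar x + 2b\bar x^2) & (a+r)\bar x + 4b\bar x^2 \end{pmatrix},$$

so the fluctuation law is Gaussian and its moments obey
$\dot C = -AC - CA^\top + D$ — the covariance system integrated by
`solve_lna()`. `covariance_rhs()` exposes the right-hand side, and the
test suite verifies it against an independent evaluation of the Lyapunov
form built from `ou_coefficients()`.

Two printed-formula issues were resolved in favour of re-derivation from
the Fokker–Planck operator, with numerical integration as the authority:

* the closed-form expressions for the stationary lethal mean and for the
  sublethal covariance trajectories are not used in computation. The
  stationary mean is instead obtained by quadrature over the sublethal
  variable,
  $\bar y_\infty = y_0 + \tfrac{x_0}{2} + \tfrac{a-r}{4b}
  \log(1 + \tfrac{2bx_0}{a+r})$,
  which the tests confirm against long-horizon ODE integration to 1e-6
  (both give 11.263 lesions under the reference configuration);
* in the Gaussian-initial-condition variant of the covariance system only
  the initial values ($c_{\upsilon\upsilon}(0), c_{\xi\xi}(0)$ from the
  initial count covariance, cross term zero) are taken from the printed
  system; the coefficients themselves are those re-derived from the
  Fokker–Planck equation, which the deterministic-start system also uses.

The low-LET simplified kinetics (`solve_simplified()`) replace the
sublethal decay by a pure exponential while keeping the quadratic lethal
production; its lethal closed form is obtained by direct integration,
$\bar y(t) = y_0 + \tfrac{a x_0}{a+r}(1 - e^{-(a+r)t})
+ \tfrac{b x_0^2}{2(a+r)}(1 - e^{-2(a+r)t})$, and validated against the
ODE solution rather than trusted from print.

## The under-dispersion result

With a deterministic start the first moments of $(\xi, \upsilon)$ are
identically zero and the lethal variance satisfies

$$c_{\upsilon\upsilon}(t) = \bar y(t) - \delta(t), \qquad
\delta(t) = -\int_0^t 2(2b\bar x + a)\, c_{\xi\upsilon}(s)\, ds.$$

Because lethal production consumes sublethal lesions, $c_{\xi\upsilon} < 0$
for all $t > 0$, hence $\delta \ge 0$: the lethal count has variance
strictly below its mean. A Gaussian with matched mean approximates a
Poisson law only when variance equals mean, so this is a genuine,
mechanistically derived departure from Poisson statistics. Notably the
deficit survives even with $b = 0$: a deterministic initial count already
makes the lethal yield Binomial$(x_0, p)$ rather than Poisson, with
variance gap $x_0 p^2$ — the test suite uses this closed form as an
oracle. Under the reference configuration the computed dispersion index
$\mathrm{Var}[Y]/\mathrm{E}[Y]$ settles near 0.68.

**δ as an ODE state.** The identity above is enforced to 1e-6 in the
acceptance checks, which rules out post-hoc quadrature on the output grid
(trapezoid error on a practical grid is orders of magnitude larger).
$\delta$ is therefore integrated as an auxiliary state alongside the
covariance ODEs — same integrator, same tolerances — so the identity holds
to solver accuracy by construction *of the integration*, while remaining a
real consistency check of the implementation (a sign or coefficient error
in either right-hand side breaks it). `delta_correction()` retains a
trapezoidal route for grid-refinement cross-checks.

## Initial conditions

Two initial laws are supported.

* **Deterministic**: point mass at $(x_0, y_0)$; fluctuation moments start
  at zero.
* **Gaussian**: independent normal counts with mean $(x_0, y_0)$ and
  variances $\sigma = (\sigma_x, \sigma_y)$, defaulting to the
  Poisson-like choice $\sigma = (x_0, y_0)$ — variance equal to mean per
  coordinate, the natural stand-in for a Poisson initial lesion number.
  On the fluctuation scale the initial covariance is $\sigma / K$, so the
  count-scale variances reproduce $\sigma$ exactly; under the count-scale
  convention $K = 1$ the fluctuation and count covariances coincide.
  Samplers that need integer states (Gillespie, lattice) round the normal
  draw and clamp at zero — an approximation documented here; the lattice
  discretisation folds sub-zero mass into the zero state.

The OU sampler centres its initial fluctuation at zero (mean-zero Gaussian
with covariance $\sigma/K$): fluctuations are centred by construction, so
a mean-$(x_0, y_0)$ start on the fluctuation scale would double-count the
macroscopic mean.

## Numerical choices

* **Exact lattice solver** (`cme_solve()`): states enumerated row-major
  over $(y, x)$ with $x$ fastest (contiguous $x$ transitions); sparse
  generator built by `cme_generator()` with column sums zero by
  construction; default bounds $x \le x_0$, $y \le y_0 + x_0$ are
  reachability-tight, so no truncation error exists. Integration uses
  `deSolve::lsodes` (sparse stiff BDF) with the generator's own pattern as
  the Jacobian structure, `rtol = 1e-8`, `atol = 1e-10`; mass drift beyond
  1e-9 or solver failure raises an error, never a silent clip. The
  reference lattice for $x_0 = 100$ has 10 201 states and solves in a few
  seconds; beyond $x_0 \approx 200$ use simulation or the Gaussian
  approximation instead.
* **Gillespie sampler**: direct method in a small C++ loop using R's RNG.
  Every path draws its own seed from the master seed via `sample.int`, so
  ensembles are reproducible and order-independent. Event-driven storage;
  observation grids are filled by right-continuous step lookup.
* **Moment/kinetic ODEs**: `deSolve::ode` (lsoda) with `rtol = 1e-10`,
  `atol = 1e-12` (first moments tighter still), tolerances chosen so that
  the 1e-6 oracle-agreement checks are limited by the model, not the
  integrator.
* **OU sampler**: Euler–Maruyama with default `dt = 1e-3` (about 1/240 of
  the relaxation time); $\bar x(t)$ evaluated at every substep via the
  closed form, never interpolated. The noise factor is the closed-form
  $2\times2$ Cholesky of $D$; $\det D = \bar x^2(ar + b\bar x(a+r)) \ge 0$
  guarantees validity, with $D = 0$ at $\bar x = 0$. Only $QQ^\top$
  matters for the law, so any factor is equivalent; the printed factor in
  the source material is typographically corrupted and was not used.
  Weak convergence is checked by step-halving against Monte-Carlo error.
* **Absorbing boundary**: with `boundary = "absorb"`, once the count-scale
  $X$ of a path touches 0 the path is frozen: $\xi$ tracks
  $-\sqrt K \bar x(t)$ (pinning $X$ at 0) and $\upsilon$ stops moving,
  because no channel can fire without sublethal lesions. Freezing
  $\upsilon$ is an interpretation — only absorption of $X$ is prescribed —
  but it is the only choice consistent with the generator.
* **Degenerate inputs**: $x_0 = 0$ or all-zero rates yield constant
  trajectories/laws across every module; $\bar x_0 = 0$ short-circuits
  the closed form to the zero function.

## What the verification suite does and does not show

The package generates its own data; there is no external dataset. The
checks are: exact lattice integration vs closed-form binomial laws for the
linear network; Gillespie ensembles vs the lattice (total variation ≤ 0.05
at $10^4$ paths, moments within 4 standard errors); the Gaussian
approximation vs both (KS ≤ 0.05 on the lethal marginal at $x_0 = 100$,
lethal variance within 5% of exact); OU ensembles vs the covariance ODEs.
Problem sizes were fixed in advance at the study conditions
($x_0 = 100$ with the lattice oracle, $x_0 = 20$ where tighter
moment agreement is asserted, $10^4$ paths).

Passing these says the five representations of *this model* are mutually
consistent and that the under-dispersion is real within the model. It says
nothing about whether constant-rate, well-mixed two-species kinetics
describe any particular cell line or radiation quality — rates here are
not fitted to data, spatial lesion structure is ignored, and the initial
damage law is an input, not a prediction.

## Known limitations

* The Gaussian approximation degrades when counts approach zero (late
  times for the sublethal marginal); the absorbing OU variant mitigates
  but does not remove this.
* The exact solver is memory/time-bound near $x_0 \approx 200$.
* The logistic death variant is available in the simulation and lattice
  modules only; the expansion modules assume the constant-rate network.
* Euler–Maruyama is weak order 1; pushing OU moment accuracy below the
  default Monte-Carlo error requires shrinking `dt` as well as growing the
  ensemble.
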