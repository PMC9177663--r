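---
title: "Hyperbolic modifier kinetics: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperbolic modifier kinetics: models, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modkin)
```

## The kinetic model

The package is built around the general (nonessential, hyperbolic)
modifier mechanism. A modifier X binds free enzyme E with dissociation
constant $K_X$ and the enzyme–substrate complex ES with $\alpha K_X$; the
ternary complex EXS turns over at $\beta k_{cat}$. Under rapid-equilibrium
binding the normalized velocity is

$$
\frac{v}{E_t} \;=\;
\frac{k_{cat}\,\dfrac{S}{K_m}\left(1 + \dfrac{\beta X}{\alpha K_X}\right)}
     {1 + \dfrac{S}{K_m} + \dfrac{X}{K_X} + \dfrac{S X}{\alpha K_m K_X}}.
$$

Two coefficients carry the biology. $\alpha$ couples modifier binding to
substrate binding: $\alpha > 1$ means the modifier and substrate disfavour
each other on the enzyme (a specific, competitive-like effect), $\alpha <
1$ the opposite. $\beta$ rescales catalysis from the ternary complex:
$\beta < 1$ is partial catalytic inhibition, $\beta > 1$ catalytic
activation, $\beta = 0$ the classical complete-inhibition limit (outside
the hyperbolic family). Useful exact consequences, each enforced by the
test suite:

* at fixed $X$ the law is Michaelis–Menten with
  $k_{cat}^{app} = k_{cat}(1+\beta X/\alpha K_X)/(1+X/\alpha K_X)$ and
  $K_m^{app} = K_m(1+X/K_X)/(1+X/\alpha K_X)$;
* at fixed $S$, $v(X)$ is a monotone hyperbola from $v(0)$ to
  $v(\infty)=\beta k_{cat} S/(\alpha K_m + S)$ with exact midpoint
  $X_{50} = \alpha K_X (K_m+S)/(\alpha K_m+S)$ — the quantity reported as
  an AC50 or IC50;
* when $\alpha = \beta$ the efficiency $k_{cat}^{app}/K_m^{app}$ is
  independent of $X$ (purely "uncompetitive-like" modification).

### Parameterization: $K_m$, not $K_S$

The four-state scheme distinguishes the equilibrium constant
$K_S = k_2/k_1$ from the steady-state constant $K_m = (k_2+k_3)/k_1$. The
closed-form law here is parameterized with $K_m$, because $K_m$ is what
per-level Michaelis–Menten tables report, making fitted and tabulated
quantities directly comparable. The cost is that the closed form is exact
only in the rapid-equilibrium limit $k_2 \gg k_3$. The package quantifies
this with an independent mass-action ODE oracle (`ode_velocity()`): with
binding rates a factor $s$ above $k_3$ (`rates_for(p, scale = s)`), the
measured closed-form/steady-state discrepancy is $O(1/s)$ — about
$8\times10^{-5}$ relative at $s=10^4$ and $8\times10^{-7}$ at $s=10^6$.
Oracle-equivalence tests therefore use $s=10^6$ as the operational
rapid-equilibrium limit. The oracle declares steady state when
$\max|d[\mathrm{species}]/dt| < 10^{-9}\,E_t\,k_3$; normalizing by the
catalytic flux scale keeps the criterion attainable in double precision
even when binding rates are scaled six decades above catalysis.

### Substrate-induced (SES) inhibition

Substrates such as PGP show a velocity maximum followed by decline,
consistent with a second substrate molecule forming a dead-end
substrate–enzyme–substrate complex:
$v/E_t = V_{max} S/(K_m + S + S^2/K_{si})$, peaking at
$S^* = \sqrt{K_m K_{si}}$. How a modifier accentuates this inhibition is
not constrained by the available data beyond its dose dependence, so the
package adopts the minimal one-parameter coupling — the $S^2/K_{si}$ term
is multiplied by $(1 + X/K_x)$ — which reproduces dose-dependent
accentuation with a single new constant. This is a modelling choice of
this package, not an established mechanism, and is flagged as such here.

## From raw signal to velocities

Chromogenic assays are calibrated by an ordinary least-squares standard
curve (`fit_standard_curve()`); signals convert to product via its inverse,
with negatives within three blank-SDs clipped to zero and larger negatives
treated as calibration errors. Initial velocities use the standard
percent-consumption criterion: the series is truncated at the last read
where product/$S_0$ stays at or below `max_consumption` (default 0.10, the
conventional initial-rate cutoff; configurable, at most 0.2) and at least
`min_points` (default 5) reads must remain.

Within even a 10% window the rate declines measurably as substrate
depletes — by up to $\text{max\_consumption}\cdot K_m/(K_m+S_0)$ of itself
— so a plain linear slope is biased low by several percent when
$S_0 \ll K_m$. The default estimator (`degree = 2`) fits a quadratic in
time and reports its derivative at $t=0$, removing the first-order bias
(measured residual error $\le 0.1\%$ on noise-free synthetic curves);
`degree = 1` gives the uncorrected slope. Replicate velocities are kept
separate, never averaged, so downstream fits can weight by replicate
spread.

## Fitting strategy

All parameters are strictly positive, so every fit runs on the log scale
with unconstrained Levenberg–Marquardt (minpack.lm), from a model-based
seed plus three deterministic multiplicative companions; the lowest
converged cost wins, ties broken by the smallest log-parameter norm.
Convergence tolerances are `ftol = ptol = 1e-12`.

* `fit_mm()` seeds from the Lineweaver–Burk linearization.
* `fit_modifier()` (the primary analysis) fits all five parameters to the
  full $(S, X)$ grid at once; seeds come from Michaelis–Menten fits at the
  extreme modifier levels ($\alpha$ from the apparent-$K_m$ ratio, $\beta$
  from the apparent-$k_{cat}$ ratio, $K_X$ from the half-change level of
  the apparent $K_m$). With complete replication it uses inverse-variance
  weights from per-condition replicate SDs — appropriate because the noise
  is multiplicative — and otherwise falls back to unweighted least
  squares. Relative standard errors above 100% set a `poorly_determined`
  flag naming the parameters, the fingerprint of structural
  non-identifiability (e.g. no modifier coverage near $K_X$).
* `fit_dose_response()` fits the mechanistic hyperbola
  $v(X) = (v_0 + v_\infty X/X_{50})/(1+X/X_{50})$ — not an empirical Hill
  curve, because the modifier law is exactly hyperbolic in $X$. The
  asymptotes enter linearly, so $X_{50}$ is profiled on a log grid and
  refined by 1-D optimization; this makes the fit deterministic and
  start-free. Constant input, or asymptote separation below the caller's
  noise floor, raises a "no modification detected" error rather than
  returning a meaningless midpoint.
* `fit_ses()` checks that the observed maximum is interior before trusting
  $K_{si}$, flagging `ksi_unidentifiable` otherwise.

`classify_mechanism()` maps fitted $(\alpha, \beta)$ to the hyperbolic
taxonomy. Approximate equality is relative with tolerance `epsilon`
(default 0.05); $\alpha \approx \beta$ is checked first so that
efficiency-preserving fits land on the purely catalytic label. When both
components are present, dominance goes to the coefficient farther from
neutrality on the log scale — the simplest rule consistent with the
reference exemplars ($|\ln 30.39| > |\ln 0.09|$ gives specific dominance;
$|\ln 25.4| > |\ln 0.82|$ catalytic). For discordant components the net
direction is the sign of $\beta(K_m+S) - (\alpha K_m + S)$ at a
caller-supplied reference $S$, which is required in that branch.

## The synthetic generator

`assay_designs()` encodes the emulated assay conditions: three pNA designs
(substrate doubling series 0.5–8 mM; substrate-specific 4MDM grids up to
100, 10 and 2000 µM; six replicates; A405 reads every 10 s for 30 min;
enzyme 10 µg/mL at 69.3 kDa) and the PGP design (100–1000 µM substrate,
0–0.32 µM modifier, twenty replicates, stopped-time endpoints; enzyme
31.25 ng/mL). Velocity noise is multiplicative Gaussian with CV 5%,
truncated at $\pm4\sigma$ so values stay positive. Reference truths use
the tabulated $k_{cat}$, $K_m$, $\alpha$, $\beta$ for each substrate;
$K_X$ is not derivable from those tables and is fixed at a round 50 µM
simulation default. The PGP truth ($V_{max} = 0.5$ s⁻¹, $K_m = 300$ µM,
$K_{si} = 400$ µM, $K_x = 0.1$ µM) is synthetic, chosen to put the
velocity peak ($\approx 346$ µM) inside the design range.

Two different noise scales matter. The 5% CV describes replicate
*velocity* scatter; applying it per read would swamp the early window with
photometric noise far beyond what any plate reader produces. Progress
curves therefore use a separate per-read noise of 0.5% (typical
photometric precision), which yields replicate velocity CVs of roughly
0.5–1.5% through the extraction pipeline — comfortably within the 5%
assay specification. Progress curves integrate
$dP/dt = E_t \cdot \text{law}(S_0 - P, X)$, so substrate depletion is real
and the window logic is genuinely exercised. Not modelled: plate-position
effects, evaporation, enzyme inactivation over 30 min, pipetting error
(concentrations are nominal). Passing tests on these simulations therefore
validate the estimators under the stated statistical model, not the
instrumental pathologies of any particular reader.

## Known limitations

* **$\alpha$ under narrow modifier coverage.** With the Arg-pNA reference
  values, $\alpha K_X \approx 1519$ µM while the design titrates X only to
  100 µM; $\alpha$'s only data signature, the $SX/(\alpha K_m K_X)$ term,
  stays below a few percent of the denominator. Noise-free fits still
  recover $\alpha$ to numerical precision, but under 5% replicate noise
  its sampling error is of order the estimate itself and the dominance
  component of the mechanism label becomes unstable, while $k_{cat}$,
  $K_m$, $K_X$ and the net direction (inhibition) remain solid. This is a
  property of the design, not the optimizer; the `poorly_determined` flag
  and the large $\alpha$ standard error report it honestly. Extending the
  titration toward $\alpha K_X$ restores identifiability.
* The closed-form laws assume rapid-equilibrium binding; systems where
  binding and catalysis compete on the same timescale need the ODE route.
* Degenerate inputs are legal where the algebra is: $S = 0$ or $X = 0$
  everywhere; $\alpha = \infty$ or $K_X = \infty$ route to the linear
  no-ternary-complex limit with a `linear_case` flag.

## Problem sizes used by the test suite

Unit and property tests run on noise-free grids of 25–40 conditions and
Monte-Carlo loops of 20–50 repeats of the six-replicate designs; the
oracle-equivalence sweeps use three random parameter sets on 3×3
$(S, X)$ grids. These sizes were chosen to exercise every code path with
comfortably stable statistics while keeping the default suite fast.

```{r example}
truth <- reference_parameters()$ala_pna
grid <- generate_velocity_grid(assay_designs()$ala_pna, truth, seed = 1)
fit <- fit_modifier(grid)
summary(fit)
```
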