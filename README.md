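# modkin

Hyperbolic enzyme–modifier kinetics for plate-reader assays.

## The problem

Small molecules that bind an enzyme without fully blocking it can either
activate or inhibit catalysis, and the direction can flip with the
substrate. The textbook example motivating this package is the
aminopeptidase activity of leukotriene A4 hydrolase (LTA4H): the modulator
4-methoxydiphenylmethane (4MDM) inhibits hydrolysis of Arg-*p*NA, activates
Ala-*p*NA and Pro-*p*NA, and accentuates the substrate-induced inhibition
of the tripeptide PGP. Resolving such behaviour requires the **general
(hyperbolic, nonessential) modifier mechanism** rather than classical
complete-inhibition models.

In that mechanism a modifier X binds free enzyme E with dissociation
constant K_X and the ES complex with α·K_X, and the ternary EXS complex
turns over at β·k_cat:

    v / E_t = k_cat (S/K_m) (1 + β X / (α K_X))
              ─────────────────────────────────────────────
              1 + S/K_m + X/K_X + S X / (α K_m K_X)

* α > 1 weakens substrate binding in the presence of X (specific,
  competitive-like component); α < 1 strengthens it.
* β < 1 slows turnover of EXS (catalytic, uncompetitive-like component);
  β > 1 accelerates it.
* At fixed X the law is exactly Michaelis–Menten with apparent parameters;
  at fixed S it is a monotone hyperbola in X whose exact midpoint is
  X50 = α K_X (K_m + S)/(α K_m + S) — the AC50/IC50.

High-substrate (substrate-induced) inhibition via a dead-end SES complex is
modelled as v/E_t = V_max S / (K_m + S + S²/K_si), with an optional modifier
coupling that multiplies the S²/K_si term by (1 + X/K_x).

The package covers the full chain: closed-form rate laws plus a mass-action
ODE oracle; conversion of raw A405/fluorescence progress curves into initial
velocities through a standard curve with a percent-consumption window;
per-modifier-level Michaelis–Menten tables; global five-parameter fits of
(k_cat, K_m, K_X, α, β); classification of fitted (α, β) into the
hyperbolic-mechanism taxonomy; hyperbolic dose–response (AC50/IC50) fits;
and a synthetic plate-assay generator so every stage is testable without
external data.

## Worked example

Simulate the Ala-pNA assay design (substrate 0.5–8 mM, 4MDM 0–10 µM, six
replicates, 5% velocity CV) from its reference truth and re-estimate the
mechanism:

```r
library(modkin)
truth <- reference_parameters()$ala_pna
des   <- assay_designs()$ala_pna
grid  <- generate_velocity_grid(des, truth, seed = 42)
fit   <- fit_modifier(grid)
summary(fit)
#> General (hyperbolic) modifier mechanism -- global fit
#>
#>       Estimate Std. Error
#> kcat    1.7120    0.01480
#> Km      1.5481    0.02939
#> KX     48.5289    9.96654
#> alpha   0.8089    0.17602
#> beta   24.4845    2.62937
#>
#> Residual sum of squares: 0.309 on 175 degrees of freedom
#> Mechanism: hyperbolic predominantly catalytic activation
```

The generating values (k_cat = 1.74 s⁻¹, K_m = 1.60 mM, K_X = 50 µM,
α = 0.82, β = 25.4) are recovered within their standard errors, and the
mechanism call — activation dominated by the catalytic (β) component — is
the expected one for this substrate. The per-level view mirrors a
kinetic-table layout, with the catalytic efficiency k_cat/K_m rising as the
activator is titrated in:

```r
format_efficiency_table(efficiency_table(fit_mm_family(grid)))
#>      X         kcat          Km efficiency
#> 1  0.0  1.74 ± 0.02 1.61 ± 0.06       1.08
#> 2  0.1  1.78 ± 0.04 1.48 ± 0.09       1.20
#> 3  0.5  2.20 ± 0.04 1.54 ± 0.07       1.43
#> 4  1.0  2.76 ± 0.06 1.64 ± 0.09       1.68
#> 5  5.0  6.47 ± 0.13 1.59 ± 0.09       4.06
#> 6 10.0 10.00 ± 0.15 1.52 ± 0.06       6.57

half_effect(1, as_kinetic_params(fit))   # analytic AC50 at S = 1 mM, in uM
#> [1] 44.41167
```

`classify_mechanism()` can be used directly on published coefficient pairs:

```r
classify_mechanism(30.39, 0.09)$label
#> [1] "hyperbolic predominantly specific inhibition"
```

A config-driven front end (`run_simulate()`, `run_analyze()`, and the
`inst/scripts/modkin` Rscript) writes plate/layout CSVs, efficiency tables
and parameter JSONs for shell pipelines. See the methods vignette
(`vignettes/modifier-kinetics.Rmd`) for the model assumptions, numerical
choices and known identifiability limits.

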