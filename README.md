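# tcellflux

Compartmentalized ¹³C metabolic flux analysis (¹³C-MFA) of central
carbon metabolism in activated T cells traced with [U-¹³C]glucose.

Activated T cells choose between aerobic glycolysis (glucose →
lactate) and oxidative phosphorylation (pyruvate → TCA cycle), and
that choice can be quantified by feeding cells uniformly ¹³C-labeled
glucose, measuring the mass isotopomer distributions (MIDs) of
intracellular metabolites by GC-MS, measuring uptake/secretion rates
from spent media, and fitting both to a metabolic network model.  The
package implements the whole analysis for whom it is written:
researchers doing isotope-tracing metabolomics who need a tested,
scriptable flux-estimation pipeline rather than opaque point
estimates.

## What it computes

At isotopic steady state the labeling of every metabolite fragment is
determined by the flux state **v** of a carbon-atom-mapped reaction
network spanning the extracellular space, cytosol and mitochondrion.
Fluxes are estimated by variance-weighted least squares,

SSR(v) = Σᵢ [(xᵢˢⁱᵐ(v) − xᵢᵐᵉᵃˢ) / σᵢ]² + Σⱼ [(rⱼ(v) − rⱼᵐᵉᵃˢ) / σⱼ]²,

over all corrected MID mass fractions xᵢ (whitened per fragment by
their propagated covariance) and the four measured exchange rates rⱼ
(glucose, glutamine, pyruvate uptake; lactate secretion), subject to
the steady-state balance S·v = 0.  The simulator uses the elementary
metabolite unit (EMU) decomposition; estimation is repeated from ≥ 50
random start points; goodness of fit is judged by a two-sided χ² test
at SSR's degrees of freedom; and per-flux 95% confidence intervals
are obtained by profiling the SSR to the χ²₀.₉₅,₁ = 3.841 threshold.
A synthetic-data module generates complete experiments (MID tables,
media time courses, growth curves) from known flux states, including
glycolysis-high ("WT-like") and OxPhos-high ("KO-like") presets, so
every stage is testable without external data.

## Worked example

```r
library(tcellflux)
sc  <- make_scenario("WT-like", seed = 42)     # 75% [U-13C]glucose, 3 replicates
exp <- generate_experiment(sc)                 # MIDs + media + growth
fit <- fit_experiment(exp, config = fit_config(n_starts = 10, seed = 1),
                      replicate_mode = "blocks")
print(fit)
#> <nm_fit> condition WT-like: SSR = 108.3 on 108 dof (chi2 accept [81.13, 138.65]: PASS)
#>   10 starts, best = #10, wall 2.1s
fit <- add_confidence_intervals(fit, c("v_glut", "v_pdh", "v_lacs"))
print(fit$ci, digits = 4)
#>     flux  value  lower upper lower_at_bound upper_at_bound
#> 1 v_glut 352.50 343.11 367.4          FALSE          FALSE
#> 2  v_pdh  75.58  58.44 106.3          FALSE          FALSE
#> 3 v_lacs 633.50 617.58 649.4          FALSE          FALSE
```

The fit reproduces the generating truth (glucose uptake 360, PDH flux
95, lactate secretion 630 nmol·(10⁶ cells)⁻¹·h⁻¹): the SSR lands in
the χ² acceptance region, and each 95% profile interval covers the
true value.  `compare_conditions()` on a WT-like and a KO-like fit
tabulates per-reaction differences and flags fluxes whose confidence
intervals are disjoint — the glycolysis-versus-OxPhos contrast shows
up as disjoint lactate-secretion and PDH intervals.

A command-line interface wraps the same pipeline
(`inst/cli/tcellflux`): `tcellflux synth --preset WT-like --seed 7
--out dir/`, then `tcellflux fit --dir dir/ --out result.json`.

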