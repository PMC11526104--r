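---
title: "Compartmentalized 13C metabolic flux analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmentalized 13C metabolic flux analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Activated T cells rewire central carbon metabolism; the balance
between aerobic glycolysis and oxidative phosphorylation can be read
out quantitatively by tracing [U-13C]glucose and fitting the resulting
isotope-labeling patterns to a metabolic network model (13C-MFA).
`tcellflux` implements this analysis end to end for the typical
experimental design: cells activated in medium containing 5 mM
unlabeled glucose are supplemented with 15 mM uniformly labeled
glucose (75% enrichment), spent media are sampled at 0/6/24 h in three
biological replicate cultures, and intracellular metabolites are
extracted, derivatized with MOX-TBDMS and measured by GC-MS in SIM
mode.

# The model

The bundled network (`tcell_model()`) spans three compartments --
extracellular (`.x`), cytosol (`.c`), mitochondrion (`.m`) -- and
covers glycolysis, the glycerol-3-phosphate shunt, lactate/alanine
exchange, mitochondrial pyruvate metabolism (PDH, pyruvate
carboxylase, malic enzyme), the TCA cycle, glutamine anaplerosis, and
citrate export through ATP-citrate lyase into cytosolic
OAA/malate/aspartate.  Pyruvate, citrate, malate, alanine, glutamate
and aspartate are metabolically active in both the cytosol and the
mitochondrion, so each is represented by two pools.  Because
extraction homogenizes those pools, the measured labeling of these
metabolites is modeled through flux-free *mixing pseudo-reactions*
that blend the two pools into a `.obs` measurement pool with a fitted
mixing fraction f (the cytosolic share).  Dilution of intracellular
labeling is modeled by two reversible exchanges with unlabeled
material: ambient CO2 (`v_co2x`) and extracellular pyruvate
(`v_pyrx`).

The exact reaction list of the original study is unpublished; this
network is a documented reconstruction that houses every measured
metabolite and every mixing/dilution term the design names.  Points
where the reconstruction required judgment:

* **Pentose-phosphate pathway** is omitted.  With uniformly labeled
  glucose, oxidative PPP mainly relabels the same M0/M+n patterns and
  none of the measured fragments isolates PPP-specific scrambling, so
  it would be unidentifiable here.
* **Upper glycolysis is irreversible.**  With a [U-13C]glucose tracer
  the exchange fluxes of PGI/aldolase/TPI/GAPDH/enolase move no
  measured MID (both triose pools carry the same labeling), so those
  exchanges would be pure nuisance parameters.
* **Succinate/fumarate rotational symmetry** is encoded as two atom-map
  variants at a 50/50 split, once where succinate is formed and once
  at fumarase; this is required for correct malate/aspartate MIDs.
* **The glycerol-3-phosphate pool is a flux-free readout.**  A pool
  with a single producer carries its parent's MID at any flux, so the
  shunt flux from DHAP is unidentifiable from these data; G3P is
  modeled as a `measurement-pool` pseudo-reaction reporting the DHAP
  labeling, not as a fitted flux.
* **Citrate, aspartate and glutamate mixing are not fitted.**
  Cytosolic citrate is a pure transport image of the mitochondrial
  pool (zero sensitivity), and for aspartate and glutamate the
  observed MID constrains only the product of the mixing fraction with
  pool-composition exchange fluxes that are themselves unidentifiable
  (verified by locating exact alternative optima of the noiseless
  problem).  These three fractions are pinned at 0.5
  (`fit_config(fixed_mixing=)`); pyruvate, alanine and malate mixing
  are fitted.
* **Biomass/secretion drains are pinned.**  The effluxes of alanine,
  aspartate, glutamate and lipogenic acetyl-CoA carry no labeling
  signature and trade off exactly against TCA rerouting, so -- as is
  standard in 13C-MFA -- they are constrained to assumed values from
  growth requirements (`fit_config(pinned_fluxes=)`) rather than
  fitted.
* Flux units are nmol per 1e6 cells per hour throughout, matching the
  cell-density-normalized rate measurements.

# Simulation

MIDs are simulated at isotopic steady state (the 24 h timepoint; the
6 h data serve as a consistency check, selectable via `time_h=`) by
EMU decomposition: the minimal set of carbon-subset balance systems is
derived per measured fragment, grouped by subset size, and solved as a
cascade of small dense linear systems (LU, in compiled code).
Reversible reactions are simulated as forward = exchange + max(net, 0)
and backward = exchange + max(-net, 0); an exchange floor of 1e-9
keeps every level system nonsingular.  Tracer impurity is applied
per-atom binomially at the tracer EMUs (default purity 0.99).

Natural 13C abundance of unlabeled material is *not* simulated:
simulation happens in tracer-atom space, and all natural-isotope
effects are carried by the measurement-correction layer.  This
separation makes the EMU simulator exactly comparable with the
brute-force full-isotopomer oracle (`brute_force_isotopomer_mids()`),
which solves the complete isotopomer balances by iterated direct
linear solves (bilinear condensation terms re-evaluated from the
previous sweep, per-metabolite renormalization to stay off the
spurious mass-deficient roots of the quadratic system).

# Measurement processing

Each fragment's correction matrix convolves the natural isotope
distributions (standard IUPAC abundances, overridable) of all
*non-skeleton* atoms -- derivatization carbons, H, N, O, Si, S, P --
so that `raw = C %*% skeleton_mid`.  Correction solves this by
Lawson-Hanson non-negative least squares and renormalizes; SDs are
propagated through the unconstrained pseudo-inverse.  A floor of 0.003
mol fraction (the conventional GC-MS accuracy floor) is applied to all
SDs used in fitting.  Replicates are either averaged in raw space
(default; SD = max(sample SD/sqrt(n), floor)) or kept as separate
residual blocks (`replicate_mode = "blocks"`), which matches fitting
all replicate experiments jointly and keeps each residual's SD equal
to the per-measurement noise; the calibration tests use block mode for
exactly that reason.

The monitored SIM ions of the original study are unpublished; the
bundled fragment library is a reconstruction with one full-skeleton
MOX-TBDMS fragment per measured metabolite and plausible ion formulas.

For fitting, each corrected MID block is by default *whitened* with
its propagated covariance (`fit_config(weighting =)`): the correction
pseudo-inverse and the renormalization correlate the mass channels,
and plain per-channel z-scores overstate the information content --
in synthetic calibration runs the diagonal scheme shrinks profile
confidence intervals enough to drop their coverage to 50-70%.

# Rates

Uptake/secretion rates are the through-origin regression slope of
cumulative consumption (nmol) against integrated viable cell density
(1e6 cell h), pooling replicates; growth is interpolated
exponentially between samples with the closed-form segment integral
N0 (e^(mu dt) - 1)/mu.  Positive = uptake.  The t = 0 samples are
pooled across replicates (they draw on one shared starting medium).
Rate SDs deserve care on a 0/6/24 h design: the late timepoints carry
almost all the leverage and the shared t = 0 error moves the slope
without leaving residuals, so naive residual SEs underestimate badly
and, with only a few degrees of freedom, plugging them into weighted
fitting inflates standardized errors several-fold.
`estimate_rates()` therefore pools a single concentration-noise CV
across all metabolites (media assays share one measurement process)
and propagates it analytically into each rate's SD; the per-metabolite
leverage-corrected (HC2) SE remains available in `estimate_rate()`.
Evaporation and spontaneous glutamine degradation are not modeled.  The exact formula
of the method cited by the study is not reprinted; this integrated-
density regression is the standard spent-media formulation for a
0/6/24 h design.

# Fitting

The objective stacks variance-weighted residuals over all MID mass
fractions (dropping one redundant fraction per normalized MID block,
so the degrees of freedom count only independent residuals) and the
four exchange rates.  Parameters are the free net fluxes of the
stoichiometric null space (non-pivot columns of the row-reduced
balance matrix), exchange fluxes in the compactified coordinate
u = vex/(vex + 100), and the fitted mixing fractions.  Estimation is
repeated from (at least) 50 seeded random start points -- free fluxes
uniform in bounds, exchanges log-uniform in [1e-3, 1000], mixing
uniform -- and the lowest-SSR solution wins, ties broken by earliest
start.

The local solver is a box-constrained Levenberg-Marquardt with
Marquardt column scaling, an active-set treatment of the bounds and
Nielsen's damping schedule.  Jacobians are exact: forward
sensitivities are propagated through the EMU cascade in compiled code
(each level is solved once and its inverse reused for all parameter
directions), with the non-smooth pieces -- net-flux sign switches, the
exchange floor, the compactification -- handled by subgradient masks
on the R side.  Finite-difference Jacobians were tried first and carry
about 1% relative noise on this problem, enough to stall the solver
inside its sloppy, curved, ill-conditioned valleys (JtJ condition
numbers beyond 1e15); with exact derivatives the same landscapes are
crossed in tens of iterations.  Three robustness layers are on by
default: an interior continuation phase first optimizes with all
parameters held strictly inside their bounds (avoiding collapse onto
boundary traps) before releasing the true bounds; each start is re-run
from its own endpoint with reset damping (`chain_restarts`); and the
best candidates receive a deep chained polish (`polish_top`,
`polish_budget`).  On the noiseless bundled problem, 48 of 50 random
starts reach the global optimum.

Goodness of fit is judged by a two-sided chi-square test at alpha =
0.05 on SSR with dof = independent residuals - parameters (an
upper-tail-only option exists).  Confidence intervals follow the
SSR-sensitivity construction: the target flux is stepped away from the
optimum with all other parameters re-optimized -- the linear constraint
is imposed exactly by eliminating one free flux -- until SSR crosses
SSR_min + qchisq(0.95, 1) = 3.841, then bisected to 0.5% of the flux
magnitude (floor 0.01).  Directions that never cross inside the flux
bounds are flagged `at_bound`.

# Synthetic data

`make_scenario()` states the emulated world: 0.75/0.25
[U-13C]/unlabeled glucose at purity 0.99; MID noise SD 0.003 mol
fraction; concentration noise CV 2%; three biological replicates;
sampling at 0/6/24 h; 0.5e6 cells at t = 0 with an 18 h doubling time
in 1 mL; initial concentrations 20 mM glucose (5 medium + 15 tracer),
4 mM glutamine, 1 mM pyruvate, 0 lactate.  The two presets encode the
study's qualitative contrast -- `"WT-like"` glycolysis-high versus
`"KO-like"` OxPhos-high with elevated glutamine/pyruvate uptake --
with magnitudes that are order-of-magnitude realistic choices for
activated T cells, not reproductions of the published flux map.
Generation forward-convolves each fragment's natural-abundance
signature (the exact inverse of the correction step), adds truncated
Gaussian noise and renormalizes; media are integrated forward from the
true rates.  Ground truth travels in a `_TRUTH.json` sidecar that the
fitting path never reads.

What a green test therefore establishes: the pipeline is
self-consistent (simulation = oracle, correction inverts generation,
rates invert media integration) and statistically calibrated under
Gaussian, independent, floor-limited noise at isotopic steady state.
What it does not establish: robustness to real-data pathologies --
retention-time drift, detector nonlinearity, naturally correlated
channel noise, incomplete metabolic steady state, or a wrong network
topology.

# Known limitations

* Global optimality is not guaranteed; multi-start plus deep polishing
  is a heuristic.  On noiseless data the fitted landscape contains a
  broad boundary trap (all weakly identified drain fluxes collapsed to
  zero) whose SSR is small in absolute terms; reaching the exact
  generating optimum from fully random starts can require many starts.
* Several exchange fluxes (e.g. mitochondrial GOT, the alanine
  transaminases) are structurally inert -- the connected pools carry
  identical labeling regardless -- and are reported with unbounded
  confidence intervals.
* Isotopically nonstationary MFA, multi-element tracing, SBML import,
  and thermodynamic constraints are out of scope.
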