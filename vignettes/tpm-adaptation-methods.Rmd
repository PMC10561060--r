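---
title: "Methods: tethered-particle-motion models of chemotactic adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tethered-particle-motion models of chemotactic adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmadapt)
```

## The scientific problem

*Escherichia coli* adapts to attractant by covalent modification of its
chemoreceptors: the methyltransferase CheR methylates up to four glutamate
sites per Tar receptor monomer (five for Tsr), the methylesterase CheB
removes the methyl groups, and both enzymes reach the sites while docked to
a C-terminal pentapeptide (NWETF) through a flexible ~30-residue tether.
Precise adaptation requires the net modification rate to depend on kinase
activity only — not on the methylation level itself. In Tar-only strains,
however, the methylation rate falls sharply as the methylation level rises.
This package implements a quantitative explanation: the tethered CheR
explores space as a tethered particle, its position follows a translated
Gaussian distribution, and because the distribution's peak lies beyond the
most distant methylation site, successive (closer) sites sit progressively
deeper in the Gaussian tail. The same geometry yields encounter-rate
matching across the sequentially methylated sites, which a closed-form
multisite model shows to be the optimal strategy for avoiding methylation
saturation.

## Model components

### MWC receptor cluster

A cluster of `N` receptors is jointly active with probability

$$a = \frac{1}{1 + e^{N (f_m + f_L)}}, \qquad
  f_m = \alpha\,(m - m_0), \qquad
  f_L = \ln\frac{1 + L/K_\mathrm{off}}{1 + L/K_\mathrm{on}},$$

with energies in kT and concentrations in mM throughout. The defaults are
the MeAsp/Tar calibration `alpha = -1.875`, `m0 = 1`, `Koff = 0.0182` mM,
`Kon = 3` mM, and the Tar-only cluster size `N = 8.7`;
`fit_cluster_size()` re-estimates `N` (jointly with the pre-stimulus
methylation level) from a dose-response table while the other four
parameters stay fixed, because they are calibrated quantities rather than
free parameters of any single experiment. The fit is unweighted least
squares; no per-dose weights are modelled.

The logistic is evaluated through `plogis`, so exponents of several
hundred kT do not overflow. `invert_activity()` is the exact algebraic
inverse and deliberately does **not** clamp its output to the physical
range [0, 4]: measured activities carry noise, and clamping would bias
downstream regression. Values outside [-0.2, 4.2] trigger a warning
instead. The simulator (`simulate_adaptation()`), by contrast, does clamp
`m` to [0, 4], because it represents real receptors with a finite number
of sites. Numerically, the inversion is exact only while the activity is
representable away from 0 and 1; beyond roughly 35 kT of free energy the
logistic saturates in double precision and the round trip degrades, which
is why the identity tests restrict themselves to that domain.

### Adaptation kinetics

The canonical feedback model is `dm/dt = kR (1 - a) - kB a` (linear
variant) with the alternative `dm/dt = kR (1 - a) - kB a^3` (cubic
variant) that makes demethylation much more sensitive to activity. The
steady state is `a* = kR/(kR + kB)` in closed form for the linear variant;
for the cubic variant `a*^3/(1 - a*) = kR/kB` is solved by bracketed root
finding (the left side is strictly increasing from 0 to infinity, so the
root is unique; tolerance 1e-14). An optional scarce-sites correction
multiplies each rate by `M/(M + M_sat)`; we interpret `M` as the number of
sites still available for the direction in question (`4 - m` for
methylation, `m` for demethylation), which is one reading of "available
sites for methylation or demethylation" — the correction then vanishes at
the appropriate boundary for each reaction. This interpretation is an
assumption, stated here because the alternative (a single shared `M`)
does not shut the rates at the boundaries.

`simulate_adaptation()` integrates the ODE with `deSolve::lsoda`
(tolerances 1e-9 absolute / 1e-7 relative) and restarts the integrator at
every protocol event, so a discontinuous change in ligand concentration
never straddles a solver step.

Absolute rate constants in 1/s are not identifiable from steady-state
ratios, and are not reported by the measurements this package models. The
defaults (`kR0 = 0.002`/s at `m = 0`, with `kB` derived from the
pre-stimulus activity) were chosen once so that two observable timescales
are respected simultaneously: a step response to 25 uM MeAsp adapts over
several hundred seconds, and the zero-activity assay stays inside its
validity range (recovery activity below 0.9) out to the 257 s duration cap
of Tar-only strains. Both constraints pin the rate scale to within a
factor of ~2; everything downstream of the generators is invariant to it.

### Tether geometry

`contour_length()` applies the 0.36 nm peptide-bond rule (34 residues →
12.24 nm). The Tar site distances from the tethering point (R514) are
stored as printed — 6.75, 5.70, 4.65, 3.45 nm in the sequential
methylation order #3 → #2 → #1 → #4 — because the axial projection used
for the sites on the non-tether helix is not derivable from the available
structural description; only site #4 can be checked independently
(23 residues x 0.15 nm/residue = 3.45 nm). `fit_site_distance()` gives the
linear map `R = k m + R0` with `k ≈ -1.10` nm/level, `R0 ≈ 7.86` nm.
`count_tether_residues()` is calibrated against the published construct
table: the NWETF pentapeptide is excluded, dashes (deletion markers) and
whitespace are skipped, and the five constructs reproduce the printed
chain lengths 34/29/22/46/30 exactly.

### Translated-Gaussian TPM model

A freely jointed chain of contour length `L` and Kuhn length `b` has a
Gaussian end density `exp(-3R^2 / 2Lb)`. Volume exclusion shifts the peak
of the tethered ball's position outward, giving

$$\frac{a^*}{1-a^*} = c \exp\!\left(-\frac{3 (R - x_0)^2}{2 L b}\right),$$

fit by `fit_tpm()` in `(c, x0)` with `L` and `b` fixed. We take
`b = 0.76` nm — twice the 0.38 nm persistence length. The sentence
defining the Kuhn length in the source literature can be parsed either
way ("the Kuhn length, which is equal to twice the persistence length
(0.38 nm)"); `b = 0.76` nm is adopted because only that choice reproduces
the published encounter-matched probabilities (0.7809, 0.1856, 0.0309,
0.0026) at the Tar site distances with `x0 = 10.5` nm — a check the test
suite enforces to better than 1% absolute per component.

Fitting choices: the loss is unweighted on the ratio scale (the scale on
which the data are plotted and fitted); a log-ratio loss is available but
off by default. The `x0` start is `max(R) + 2` nm — the data regime is the
rising Gaussian tail (`R < x0`), so starting beyond the largest distance
avoids the reflected local optimum. Convergence tolerances are 1e-15
(function and parameter); fits with `x0` outside `[0, 3L]` are flagged
rather than rejected. The cubic-variant fit is identical with
`a*^3/(1-a*)` on the left-hand side; its published alternative
chain-length line (slope 0.233 nm/aa, intercept 7.4 nm) derives from
experimental data we do not have, so it is exercised only as a
parameter-recovery property.

Substituting `m = fm/alpha + m0` and `R = k m + R0` into the steady-state
condition yields the closed-form quadratic `fL = q2 fm^2 + q1 fm + f0`
with

$$q_2 = \frac{3 k^2}{2 L b \alpha^2 N}, \qquad
  q_1 = -1 + \frac{3 (k/\alpha) (R_0 + k m_0 - x_0)}{L b N},$$

numerically `q2 ≈ 0.006`, `q1 ≈ -1.07`: adaptation is imprecise by a
nearly constant factor, a line of slope magnitude `1/1.07 ≈ 0.93` between
`fm` and `fL`.

### Sequential multisite model

With sequential methylation, site-independent CheB and equilibrium
constant, and the CheR proportion `P_i` at site `i`, detailed balance
gives the stationary law `P(m=i) ∝ prod_{j<=i} (theta P_j)` with
`theta = Keq [R_tot]/[B_tot]`. `stationary_distribution()` evaluates the
products in log space (so extreme `theta` cannot overflow), and the test
suite checks it against an independent birth-death null-space oracle to
1e-12 over random cases. The implementation is n-site generic; the
five-site Tsr geometry runs through the same code. Degenerate inputs:
`theta = 0` returns all mass at `m = 0`; probabilities that do not sum to
1 within 1e-9 are renormalised with a warning; negative entries are
rejected.

The Hill coefficient uses the standard 10-90 rule,
`H = ln 81 / ln(theta_0.9/theta_0.1)`, with the thresholds found by
bracketed root finding on the log-theta scale (the saturation curve is
strictly monotone, so the roots are unique). The published values never
state the formula; the 10-90 rule is adopted because it reproduces the
published 1.7 / 1.3 / 2.2 / 1.1 and degenerates to exactly `H = 1` for a
single site. The reported standard deviation `sigma_m` is the square root
of the published variance expression (whose printed form omits the root —
the text calls it a standard deviation, so we treat the omission as
typesetting). Two small print-level deviations are asserted explicitly in
the tests rather than hidden by loose tolerances: the case-2 10% threshold
computes to ~5.21 against the printed 5.3 (~2%), and at mean methylation 2
the matched case has `P(m=0) = 0.019` — "near zero" relative to the
0.11-0.34 of the other cases, but not below 0.01.

### FRET-trace processing

Calibration follows the experimental convention: activity
`a(t) = a0 (F - F_sat)/(F_pre - F_sat)`, with `F_pre` the pre-stimulus
mean and `F_sat` a robust minimum over the saturating-stimulus window.
The robust extrema are minima/maxima of a 21-sample rolling mean rather
than raw order statistics: a low percentile resists spikes but sits about
two noise standard deviations into the tail on the long windows used
here, which measurably inflates `a0` and propagates into every
downstream estimate, whereas the rolling-mean extremum is unbiased on
plateaus and still ignores isolated spikes (at the cost of a fraction of
a percent of bias on sharply decaying peaks). `a0`
itself comes from a full add/adapt/remove cycle spanning activities 0 to
1. An addition counts as saturating above 0.03 mM, the dose-response
saturation threshold. Steady state is declared when the trailing-window
drift is below 1e-4/s; "zero activity" means calibrated activity below
0.02 (no numeric threshold is published; 0.02 is well above the noise
floor of the default generator and well below any recovery signal). Event
times come from the event list; inferring them from the signal is out of
scope. Zero-activity durations above the strain caps (114 s wild-type,
257 s Tar-only) and recovery peaks at or above 0.9 are flagged with
warnings, mirroring the published validity limits.

## The synthetic-data generator

No raw traces are publicly deposited, so the generators stand in for the
experiments, with the statistical structure the analysis assumes and
nothing more: MWC activity coupled to the adaptation ODE with the TPM
rate modifier as ground truth, piecewise-constant stimulus protocols,
an affine map from activity to a FRET-style ratio, and additive iid
Gaussian measurement noise. Defaults, chosen once as the study
conditions:

* pre-stimulus activity `a0 = 0.35`, a typical FRET-assay operating
  point; the demethylation rate is derived from it for self-consistency;
* ratio map `ratio = 0.8 + 0.2 a`. The gain sign makes the pre-stimulus
  FRET exceed the saturated-stimulus value, which the calibration
  convention requires (FRET falls when attractant suppresses kinase
  activity);
* noise sd 2% of the full FRET range (`0.004` on the ratio), visually
  consistent with published example traces; sampling at 1 Hz;
* every generator is a pure function of `(truth, protocol, seed)` —
  identical inputs give byte-identical outputs, and each trace carries
  its hidden noise-free truth as an attribute that no estimator reads.

What the generator does **not** emulate: cell-to-cell variability,
photobleaching and channel drift, CheB tether dynamics, assistance
neighborhoods between receptor species, and stochastic (finite-copy)
methylation events. Passing end-to-end tests therefore demonstrates that
the estimators are consistent under the model's own assumptions — not
that real traces satisfy those assumptions.

For the dose-response fixtures used to test `fit_cluster_size()`, the
pre-stimulus activity is raised to 0.85: the fit's design requirement is
doses spanning the activity transition, and a baseline of 0.35 leaves the
upper half of the logistic unobservable, making `(N, m_pre)` nearly
unidentifiable regardless of noise. This mirrors the wild-type-like
operating point at which cluster sizes are actually measured.

## Problem sizes and runtime

All headline quantities (Hill coefficients, saturation thresholds, mean
levels, encounter probabilities, the `fL`-`fm` coefficients) are closed
form or one-dimensional root finds and evaluate in milliseconds. The
simulation-based checks use: step-response protocols of 2,000-8,400 s of
simulated time at 1 Hz sampling (the slowest dose, 250 uM, needs ~8,000 s
to settle under the default rate scale), five doses per pipeline run, 50
replicate TPM fits for the noise-recovery checks, 1,000 random cases for
the birth-death oracle, and 20 replicates for the dose-response and
chain-length recoveries. The full suite runs in about half a minute on
one core.

## Known limitations

* The site distances for Tar sites #1-#3 are taken as printed; they
  cannot be recomputed from first principles with the information
  available, so any revision of the underlying structural projection
  would change the geometry fit.
* The local-adaptation variant of the multisite model (activity dependent
  on the individual receptor's level) and Ising-type dose-response
  simulations of receptor cooperativity are out of scope; only the
  global-adaptation closed form is implemented.
* The estimators assume ensemble-averaged traces; single-cell noise
  structure (multiplicative, correlated) would require different
  calibration robustness choices.
* `theta_at_saturation()` brackets on the log scale down to exp(-700);
  saturation targets requiring doses outside that range (never the case
  for the standard geometries) would need rescaling.
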