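# tpmadapt

Quantitative models of methylation-dependent adaptation in bacterial
chemotaxis, built around the tethered-particle-motion (TPM) picture of the
methyltransferase CheR.

## The problem

*E. coli* adapts to attractant by methylating its chemoreceptors: CheR adds
methyl groups at up to four sites per Tar monomer (five for Tsr), CheB
removes them, and both enzymes work while tethered to the receptor's
C-terminus through a flexible peptide chain. Precise adaptation requires the
net methylation rate to be independent of the methylation level — yet in
Tar-only strains the rate drops sharply as methylation accumulates. This
package implements the model that explains why, and what the cell gains
from it. It is aimed at quantitative microbiologists and systems biologists
analysing FRET-based kinase-activity measurements or modelling receptor
modification kinetics.

Four model layers, all exposed as tidyverse-style functions over data
frames:

* **MWC receptor cluster** — activity
  `a = 1 / (1 + exp(N(f_m + f_L)))` with `f_m = α(m − m₀)` and
  `f_L = ln[(1 + L/K_off)/(1 + L/K_on)]`; exact inversion from activity to
  methylation level; cluster-size fitting
  (`mwc_params()`, `receptor_activity()`, `invert_activity()`,
  `fit_cluster_size()`).
* **Adaptation kinetics** — `dm/dt = k_R(1−a) − k_B a` (or `a³` for the
  cubic variant), steady states, stiff-safe protocol simulation, and the
  zero-activity assay estimator `⟨dm/dt⟩ = (m_r − m₀)/Δt`
  (`adaptation_params()`, `simulate_adaptation()`, `zero_activity_rate()`).
* **Tether geometry and TPM** — contour lengths (0.36 nm/residue), the Tar
  and Tsr site-distance tables, the linear `R = k·m + R₀` fit, and the
  translated-Gaussian model
  `a*/(1−a*) = c·exp(−3(R−x₀)²/2L_total·b)` with encounter probabilities
  `P_i ∝ exp(−3(R_i−x₀)²/2L_total·b)`
  (`fit_site_distance()`, `fit_tpm()`, `encounter_probabilities()`,
  `fl_fm_relation()`).
* **Sequential multisite model** — closed-form stationary distribution
  `P(m=i) ∝ ∏_{j≤i} θP_j` with dose `θ = K_eq[R_tot]/[B_tot]`, saturation
  thresholds θ₀.₁, Hill coefficients `H = ln81 / ln(θ₀.₉/θ₀.₁)`, and
  methylation-level moments
  (`standard_cases()`, `stationary_distribution()`, `multisite_report()`).

A synthetic-experiment generator (`ground_truth()`,
`generate_step_experiment()`, `generate_zero_activity_assay()`,
`generate_dose_response()`) produces FRET-style traces with known ground
truth, and a processing chain (`calibrate_activity()`, `extract_a0()`,
`adapted_activity()`, `removal_peak()`, `precision_pairs()`,
`run_tpm_pipeline()`) analyses them exactly as one would analyse real
traces.

## Worked example

The multisite robustness table — for each CheR encounter-probability
scenario, the dose at which 10%/90% of receptors are fully methylated, the
Hill coefficient of that saturation curve, and the mean methylation level
at the 10% threshold:

```r
library(tpmadapt)
multisite_report()
#> # A tibble: 4 × 5
#>   case  theta_01 theta_09  hill   m_01
#>   <chr>    <dbl>    <dbl> <dbl>  <dbl>
#> 1 case1    2.958    40.00 1.687 1.419
#> 2 case2    5.208   149.3  1.310 2.144
#> 3 case3    3.155    24.27 2.154 0.8885
#> 4 case4   65.59   3494.   1.105 2.762
```

Case 4 — the encounter-matched probabilities produced by the tethered-CheR
geometry — needs a ~22× larger dose than the uniform case before
saturation sets in, responds with the shallowest (most robust) Hill
coefficient, and leaves the most methylation headroom. Those probabilities
come straight from the tether geometry:

```r
fit_site_distance()
#> <geometry_fit> R(m) = -1.095 * m + 7.875  (se 0.026, 0.071) nm

round(encounter_probabilities(tar_site_distances()$R_nm), 4)
#> [1] 0.7830 0.1841 0.0303 0.0025

fl_fm_relation()
#> # A tibble: 1 × 3
#>         q2     q1 implied_slope
#>      <dbl>  <dbl>         <dbl>
#> 1 0.006321 -1.081        -0.9255
```

The last line is the model's signature of imprecise adaptation: the
adapted methylation free energy tracks the ligand free energy with slope
magnitude ≈ 0.93 instead of 1.

End to end on synthetic data — generate step-response experiments at five
MeAsp doses, process the traces, and recover the tether translation `x₀`
and the precision slope:

```r
truth <- ground_truth(seed = 42L)   # ground-truth x0 = 10.5 nm
run_tpm_pipeline(truth)
#> <tpm_pipeline> 5 doses: a0 = 0.355, x0 = 10.324 nm, fm~fL slope = -0.9185
```

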