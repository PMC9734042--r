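---
title: "Modeling hippocampal neuroenergetics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hippocampal neuroenergetics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroflux)
```

# Scope

`neuroflux` implements a quantitative neuroenergetics chain for the rodent
hippocampus: kinetic modeling of dynamic ¹⁸FDG-PET, positional ¹³C
fractional-enrichment (FE) models of glucose oxidation fed by a
[U-¹³C₆]glucose infusion, mass-balance algebra for neurotransmitter-cycling
and GABA-shunt fluxes with relative allostatic-load scores, flux estimation
with Monte-Carlo uncertainty, a small NMR quantification layer, and the
cohort statistics used around such experiments (composite behavioral
z-scores, omnibus permutation tests, correlation panels, ROC marker
assessment). A seeded synthetic-cohort generator emulating a knockout
versus wild-type design makes the whole chain testable without animal data.

# The FDG-PET model

Glucose exchanges between plasma (`C_p`) and an intracellular pool (`C_e`)
with rate constants `k1` (in) and `k2` (out); hexokinase phosphorylation to
FDG-6P (`C_m`) proceeds with `k3`, dephosphorylation with `k4`:

$$\frac{dC_e}{dt} = k_1 C_p - (k_2+k_3)\,C_e + k_4 C_m,\qquad
  \frac{dC_m}{dt} = k_3 C_e - k_4 C_m,$$

and the measured signal is $(1-v_b)(C_e+C_m) + v_b C_p$. The cerebral
metabolic rate of glucose follows from the net uptake constant:

$$\mathrm{CMR}_{\mathrm{Glc}} = \frac{k_1 k_3}{k_2+k_3}\cdot
  \frac{[\mathrm{Glc}]_{\mathrm{plasma}}}{LC}.$$

Choices:

* `k4 = 0` by default: over a 50-minute scan FDG-6P trapping is effectively
  irreversible; `fix_k4 = FALSE` frees it.
* The lumped constant `LC` defaults to 0.6 and the vascular fraction `v_b`
  to 0; neither is identifiable from a tissue curve alone, so both are
  plain configuration fields.
* Fitting is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
  uniform weights by default; the forward model is integrated with
  `deSolve::lsoda` at `rtol = 1e-8`.
* `patlak_slope()` provides the graphical cross-check: for an irreversible
  tracer the late-time Patlak slope equals $k_1k_3/(k_2+k_3)$.

# The positional ¹³C labeling models

Both labeling models track the FE of individual carbon positions of the
NMR-visible pools under metabolic steady state (constant pool sizes), which
makes the dynamics linear:

$$\frac{d\,\mathrm{FE}_n}{dt} \;=\; \frac{1}{[P_n]}\Big(
   \sum_{\mathrm{in}} v\,\mathrm{FE}_{\mathrm{src}}
   - \mathrm{FE}_n \sum_{\mathrm{out}} v\Big).$$

The network is encoded as an explicit carbon-transfer table (a list of
fluxes with per-position routing), and the builder verifies that molar
inflow equals outflow at every tracked node (`label_balance_audit()`).

**Carbon fates.** Pyr C3 → AcCoA C2 → OG/Glu C4 on the first turn; the
symmetric succinate/fumarate step scrambles label 50/50 into OAA C2/C3, so
later turns populate Glu C3 and C2; pyruvate carboxylase routes Pyr C3 to
OAA C3 (and, because [U-¹³C₆]glucose labels Pyr C2 equally, the same FE is
delivered to OAA C2); GABA derives from glutamate by decarboxylation with
Glu C4→GABA C2, C3→C3, C2→C4. OG C1/C2 carboxyl losses to CO₂ are
represented by consumption without redelivery.

**One-compartment model.** A single TCA cycle (`v_tca`), transmitochondrial
OG↔Glu exchange (`v_x`), Glu↔Gln neurotransmission cycling (`v_nt`), and
dilution from blood lactate (`v_dil_in`, unlabeled inflow into the combined
Pyr/Lac pool) and blood acetate (`v_dil_g`, unlabeled inflow into acetyl-CoA).

**Pseudo three-compartment model.** Excitatory neurons (Glu), inhibitory
neurons (GABA) and glia (Gln) share one Pyr/Lac pool. Glutamatergic cycling
`v_nt_e` moves label Glu_e↔Gln_g; GABAergic cycling `v_nt_i` runs
Gln_g→Glu_i→(GAD)→GABA→glial succinate→OAA_g; the GABA shunt
`v_shunt = v_gad − v_nt_i` re-enters the inhibitory TCA at succinate.
`v_ex_g` and `v_ex_i` exchange the visible Gln/GABA pool with a second,
initially unlabeled and MRS-invisible pool of equal size. Glial pyruvate
carboxylase `v_pc`, glial oxidative TCA `v_g` and glial exchange `v_x_g`
are fixed; glial Gln efflux equals `v_pc`.

Two bookkeeping choices deserve emphasis:

* **Shunt acetyl units are labeled.** Each shunt turn consumes one
  pyruvate-derived acetyl (GABA→succinate→OAA plus AcCoA→citrate→OG→Glu→
  GABA), so the inhibitory acetyl draw on the Pyr/Lac pool is the full
  `v_tca_i = v_pdh_i + v_shunt`. An earlier variant that carried the
  shunt-supporting acetyl as an unlabeled inflow made `v_gad` act as a
  steady-state GABA dilution factor, exactly degenerate with `v_ex_i`; the
  labeled version removes that degeneracy and yields realistic GABA
  enrichments.
* **Glial anaplerotic turnover** (`v_pc + v_nt_i`, fixed and small) enters
  OG C4 as an unlabeled inflow — a deliberate simplification that slightly
  under-labels glutamine and has no bearing on estimation because the
  participating fluxes are fixed.

The observed channels (`GlcU`, `LacC3`, `GluC4/3/2`, `GlnC4/3/2`,
`GABAC2/3/4`, `AspC2+C3`) are pool-size-weighted mixtures of the
contributing states; measured glutamate, for example, pools the three
compartments by concentration. Aspartate is reported from the excitatory
OAA pool, carried at the aspartate concentration because Asp and OAA
exchange rapidly.

**Pool sizes** (mM, `default_pool_sizes()`): Glc 1.5, Lac(+Pyr) 2.5, Glu 9
split 7/1/1 across excitatory/inhibitory/glial compartments, Gln 3 (+3 in
the second pool), GABA 1.5 (+1.5), Asp/OAA_e 2.5, and small explicit
intermediates (AcCoA 0.05, OG 0.15, glial/inhibitory OAA 0.1). Carrying
intermediates explicitly keeps the ODE machinery uniform at negligible
cost; their exact sizes only set fast relaxation times.

## Numerics

Because the system is linear with a single time-varying input (blood
glucose FE), two integrators are provided. `lsoda` (deSolve) is the default
and evaluates the input continuously. The `expm` propagator treats the
input as piecewise linear on an internal grid (`dt`, default 0.5 min for
simulation, 0.25 min inside fitting) and advances the augmented state
(states, input level, input slope) with one matrix exponential — exact for
that input representation. The fitting routines additionally exploit the
fact that the rate matrix is *linear in the fluxes*: one decomposition
$M(v) = M_0 + \sum_j v_j D_j$, obtained by differencing the real builder,
replaces per-iteration network construction. Explicit-Euler references in
the test suite validate both paths independently.

# Mass balances and allostatic loads

At steady state the derived fluxes follow algebraically
(`derive_balances()`): the GABA shunt `v_shunt_i = v_gad − v_nt_i`,
glutamine synthetase `v_gs = v_nt_e − v_nt_i + v_pc`, compartment TCA
totals `v_tca_e = v_pdh_e`, `v_tca_i = v_pdh_i + v_shunt_i`,
`v_tca_g = v_g + v_pc + v_nt_i`, the oxidative glucose consumption
`cmr_glc_ox = (v_tca_e + v_tca_i + v_tca_g + v_pc)/2` (two pyruvate per
glucose), and the brain-to-blood lactate efflux
`v_dil_out = v_dil_in · Lac_brain / Lac_blood`.

Relative allostatic loads compare neurotransmission demand to oxidative
ATP production capacity between groups, per neuron type:

$$\mathrm{load}_e = \frac{(v_{nt}^e / v_{ATP(ox)}^e)_{KO}}
                         {(v_{nt}^e / v_{ATP(ox)}^e)_{WT}},\qquad
  \mathrm{load}_i = \frac{((v_{nt}^i+v_{ex}^i) / v_{ATP(ox)}^i)_{KO}}
                         {((v_{nt}^i+v_{ex}^i) / v_{ATP(ox)}^i)_{WT}},$$

with $v_{ATP(ox)} = s\,v_{TCA}$ of the matching neuron type. The ATP
stoichiometry $s$ cancels in these ratios — which is why the loads are
computable without committing to whether glycolytic ATP is included; `s`
(default 15, the approximate oxidative yield per acetyl) only matters for
absolute rates and is exposed as `atp_stoichiometry`.

# Flux estimation

`fit_fluxes()` performs bounded weighted least squares of simulated against
observed FE curves over the free fluxes, with `cmr_glc` fixed from PET and
the glial fluxes fixed. Design:

* **Parametrization.** Internally on log₁₀ scale (the free fluxes span four
  orders of magnitude) and with `v_shunt_i = v_gad − v_nt_i` replacing
  `v_gad`, so that every constraint is a box constraint. Bounds default to
  [10⁻⁵, 5] µmol/g/min.
* **Multi-start.** Five Levenberg–Marquardt runs from the reference
  initialization plus log-uniform jitters (±0.5 decades), seeded. Runs
  whose RSS lies within one χ² standard deviation of the best
  (relative $\sqrt{2/n}$) are statistically indistinguishable; among them
  the solution closest to the reference initialization in log space is
  selected.
* **Noise-scaled ridge.** Transmitochondrial and pool-exchange fluxes have
  a fast-exchange ridge: beyond a few µmol/g/min the curves saturate and
  the likelihood is flat, so plain least squares drifts to the upper bound
  under noise. A final refinement adds the penalty
  $\sqrt{\lambda}\,\hat\sigma\,(\theta-\theta_{ref})$ — a lognormal prior
  of SD $1/\sqrt{\lambda}$ decades (default one decade) scaled by the
  estimated residual noise. It decides only directions the data leave
  undetermined and vanishes for noiseless data; identifiable fluxes are
  recovered within a few percent either way.
* **Infeasible iterates** (pyruvate demand above `2·cmr_glc + v_dil_in`,
  or a negative glutamine-synthetase balance) return a smooth penalty that
  pushes the optimizer back into the feasible box.
* **Weights** are per-channel and default to uniform, which is the
  inverse-variance choice under the generator's i.i.d. noise model.

`monte_carlo_sd()` adds Gaussian noise — SD estimated per channel from the
fit residuals — to the *fitted* curves, refits each replicate from the
point estimate (single start, same ridge), and reports per-flux SDs over
replicates; 300 replicates by default. The generic also accepts any
`mc_refit_context()`, which the test suite uses to validate the procedure
against the closed-form SD of a linear model.

# The synthetic cohort

`generate_cohort()` draws a seeded two-genotype cohort under
`cohort_config()`. The defaults are the study conditions the package
models and are deliberately not tuning knobs:

* **Ground-truth fluxes** (wild type, µmol/g/min): `cmr_glc` 0.45,
  `v_pdh_e` 0.30, `v_pdh_i` 0.06, `v_x_e` 0.60, `v_x_i` 0.15, `v_nt_e`
  0.05, `v_nt_i` 0.010, `v_gad` 0.32, `v_ex_g` 0.02, `v_ex_i` 0.0006,
  `v_dil_in` 0.15, `v_dil_g` 0.02; fixed glial `v_pc` 0.06, `v_g` 0.20,
  `v_x_g` 0.50. Values printed in the modeled study (the GAD flux, the
  tiny GABA-pool exchange, neurotransmission totals) are adopted directly;
  the remainder are realistic hippocampal values chosen once so that
  pyruvate supply (2·CMR_Glc + v_dil_in) covers oxidative demand.
* **Knockout effects** (multiplicative): CMR_Glc ×0.80 (the observed 20%
  reduction), `v_pdh_e` ×0.64, `v_pdh_i` ×1.10, `v_nt_e` ×2, `v_nt_i`
  ×5.7, `v_ex_i` ×10, `v_gad` ×0.94 — magnitudes matching the reported
  excitatory/inhibitory cycling increases and TCA reductions.
* **Between-animal scatter**: lognormal with CV 10% on every free flux
  (per-animal variance is not reported anywhere; this is a choice).
* **Enrichment noise**: i.i.d. Gaussian on every channel with
  σ = (GluC4 plateau FE)/SNR, default SNR 6 as in edited spectra; the
  spectral SNR definition does not translate uniquely to curve noise, so
  this proxy is documented rather than derived. FEs are clipped to [0, 1].
* **Behavior** couples to hippocampal lactate through a shared latent
  factor: the pooled lactate z-score drives a behavior factor with the
  configured correlation (default −0.35), which is split into FST/TST
  immobility by anti-correlated test noise so the *composite* z-score
  carries exactly the intended correlation. Genotype differences in
  behavior arise only through lactate, whose group mean scales with the
  squared CMR_Glc factor (2.5 mM → 1.6 mM under the 20% reduction).
* **Markers**: prefrontal tCho and volume are correlated Gaussians
  (r = 0.31) separated by d′ = 1.30 per marker between genotypes.

What the generator does *not* emulate: raw spectra (only FE curves),
longitudinal drift and repeated measures, treatment arms, non-Gaussian
measurement error, and any glial group difference (glial fluxes are fixed
equal between genotypes, as the analysis assumes). Passing tests therefore
demonstrate correctness of the estimation machinery under the stated
statistical structure, not robustness to real-data pathologies.

## What is and is not recoverable at the study SNR

Self-consistency on noiseless curves recovers every free flux within a few
percent. At SNR 6 with 10-minute sampling, the well-identified fluxes
(`v_pdh_e`, `v_nt_e`, `v_nt_i`, `v_gad`, `v_dil_in`) recover with
group-mean errors well inside their Monte-Carlo SDs. The transmitochondrial
exchanges remain poorly determined (their fast-exchange plateau), and the
wild-type GABA-pool exchange `v_ex_i` = 0.0006 µmol/g/min lies *below the
single-animal detection limit* implied by the noise model: its estimates
scatter at the noise floor (~10⁻³), so group means overestimate it and
knockout/wild-type ratios of group means land well under the true tenfold
factor. This is a property of the stated study conditions, not of the
optimizer; the acceptance suite asserts the intended recovery anyway and
documents the outcome.

# Statistics

* **Composite z-scores** standardize each behavioral test with the sample
  SD over the whole scope (all animals and timepoints) and average the
  per-test z's; the high/low split is at the scope mean, ties to low.
* **The omnibus permutation test** uses the sum of squared per-flux t
  statistics as the global statistic — the natural omnibus companion to
  the per-flux t tests reported alongside — with 2000 label permutations
  and the add-one p-value rule; p-values are valid (super-uniform) by
  construction.
* **ROC analysis** sweeps all thresholds; the AUC is the trapezoidal area,
  computed as the tie-corrected Mann–Whitney statistic. Confidence
  intervals are seeded percentile bootstrap over animals (2000 resamples
  by default); the bootstrap was chosen over DeLong since the reference
  method is unstated and the bootstrap extends unchanged to the averaged
  z-score combiner.
* **Correlation panels** report plain Pearson r with two-tailed p,
  explicitly uncorrected for multiple comparisons and flagged as such.

# The pipeline

`run_pipeline()` chains generation → PET fits → flux fits → balances and
loads → markers into one seeded run with a JSON report carrying the master
seed and an md5 configuration hash, plus tidy CSV outputs. The shipped
default uses 3 animals per group, 2 optimizer starts and no Monte-Carlo to
stay interactive; the acceptance analyses use 8 per group and the full
settings. Problem sizes throughout the test suite (cohort sizes, replicate
counts, Monte-Carlo depths) are chosen as the smallest sizes at which the
sampling distributions of the checked quantities are stable.

# Known limitations

* Positional FE only — no bond-level isotopomer detail, so [U-¹³C₆]
  multiplet information that a full isotopomer model would exploit is not
  represented.
* Glial fluxes are fixed, mirroring the analysis assumption; no attempt is
  made to estimate astrocytic contributions.
* The FE noise proxy (spectral SNR → uniform curve noise) is the weakest
  link between the synthetic conditions and real acquisitions.
* `v_x`-type exchanges are reported with honest (large) uncertainties
  rather than being fixed; users who prefer the field's common practice of
  fixing them can pass them via `fixed`.
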