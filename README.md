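# neuroflux

Compartmental modeling of brain energy metabolism from dynamic ¹⁸FDG-PET
and indirect ¹³C magnetic resonance spectroscopy, written for quantitative
neuroenergetics studies of the rodent hippocampus — in particular designs
that compare a metabolically impaired genotype against wild-type
littermates and relate the flux phenotype to depressive-like behavior and
imaging biomarkers.

## What it computes

**FDG-PET kinetics.** The two-tissue compartment model
(`dC_e/dt = k₁C_p − (k₂+k₃)C_e + k₄C_m`, `dC_m/dt = k₃C_e − k₄C_m`) is
simulated and fitted to tissue time-activity curves; the cerebral metabolic
rate of glucose follows as
`CMR_Glc = k₁k₃/(k₂+k₃) · [Glc]_plasma / LC`. Standardized uptake values
and the Patlak graphical limit are included.

**Positional ¹³C labeling models.** Fractional enrichments of individual
carbon positions (GluC4/C3/C2, GlnC4/C3/C2, GABAC2/C3/C4, LacC3, AspC2+C3)
under a [U-¹³C₆]glucose infusion are propagated through explicit
carbon-transfer networks, either as one lumped compartment
(V_TCA, V_x, V_NT, V_dil) or as the pseudo three-compartment model
separating excitatory neurons, inhibitory neurons and glia (V_PDH^e,
V_PDH^i, V_x^e, V_x^i, V_NT^e, V_NT^i, V_GAD, V_ex^g, V_ex^i, with fixed
glial V_PC, V_g, V_x^g). Steady-state mass balances yield the GABA shunt
`V_shunt^i = V_GAD − V_NT^i`, glutamine synthetase
`V_GS = V_NT^e − V_NT^i + V_PC`, compartment TCA totals, the oxidative
glucose consumption `CMR_Glc(ox)`, the lactate efflux
`V_dil^out = V_dil^in·Lac_brain/Lac_blood`, and relative allostatic loads
(neurotransmission over oxidative ATP production, knockout relative to
control).

**Estimation and statistics.** Free fluxes are estimated by multi-start
bounded least squares with CMR_Glc fixed from PET; uncertainties come from
300 seeded Monte-Carlo refits. Group comparisons use an omnibus
permutation test (2000 permutations, sum of squared per-flux t statistics)
with per-flux t tests; behavior is summarized as composite z-scores
(FST/TST immobility); markers are assessed with ROC curves, trapezoidal
AUC and bootstrap confidence intervals; correlation panels report
uncorrected Pearson r.

**Synthetic cohorts.** `generate_cohort()` draws seeded two-genotype
cohorts — blood inputs, PET curves, noisy enrichment curves, metabolite
levels, behavior correlated with hippocampal lactate, and marker panels —
with the statistical structure the analysis assumes, so the entire chain
is testable without animal data.

## Worked example

```r
library(neuroflux)

out <- run_pipeline(run_config(
  seed = 1,
  cohort = list(n_per_group = 8),
  flux = list(kind = "pseudo_three_compartment", n_starts = 5),
  stats = list(n_perm = 2000, n_boot = 2000)))

rep <- out$report
round(100 * (1 - rep$cmr_glc$ko / rep$cmr_glc$wt), 1)
#> [1] 20.4
round(unlist(rep$allostatic_loads), 2)
#>       relative_excitatory_load       relative_inhibitory_load
#>                           2.83                           5.48
#> inhibitory_to_excitatory_ratio
#>                           1.94
signif(rep$permutation$global_p, 3)
#> [1] 0.001
round(c(marker_auc = rep$roc_genotype_auc,
        behavior_auc = rep$roc_high_low_auc,
        behavior_lac_r = rep$behavior_lac_r), 3)
#>     marker_auc   behavior_auc behavior_lac_r
#>          0.875          0.667         -0.349
```

Reading: the knockout group's PET-fitted glucose consumption is 20.4%
below wild type; the omnibus permutation test detects the flux phenotype
(p ≈ 0.001); excitatory neurons carry a ~2.8-fold and inhibitory neurons a
~5.5-fold relative allostatic load (neurotransmission demand relative to
oxidative ATP production, knockout over wild type); the two-marker panel
separates genotypes with AUC 0.875; hippocampal lactate correlates with
composite behavioral despair at r = −0.35, and the lactate/PCr panel
separates high from low despair animals with AUC 0.667.

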