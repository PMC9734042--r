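# Flux configurations for the labeling models (all fluxes in umol/g/min).

#' One-compartment flux configuration
#'
#' Free and fixed fluxes of the lumped ("whole brain") labeling model:
#' glucose oxidation through a single TCA cycle (`v_tca`), transmitochondrial
#' oxoglutarate/glutamate exchange (`v_x`), glutamate/glutamine
#' neurotransmission cycling (`v_nt`), and label dilution from blood lactate
#' (`v_dil_in`) and blood acetate (`v_dil_g`). `cmr_glc` is the cerebral
#' metabolic rate of glucose, fixed from the PET experiment.
#'
#' @param cmr_glc,v_tca,v_x,v_nt,v_dil_in,v_dil_g nonnegative fluxes
#'   (umol/g/min).
#' @return A `flux_config_1c` object (named list).
#' @export
flux_config_1c <- function(cmr_glc = 0.45, v_tca = 0.85, v_x = 0.60,
                           v_nt = 0.06, v_dil_in = 0.15, v_dil_g = 0.02) {
  fx <- list(cmr_glc = cmr_glc, v_tca = v_tca, v_x = v_x, v_nt = v_nt,
             v_dil_in = v_dil_in, v_dil_g = v_dil_g)
  for (nm in names(fx)) check_number(fx[[nm]], nm, 0)
  if (v_dil_g > v_tca)
    stop_invalid("v_dil_g (%g) cannot exceed v_tca (%g)", v_dil_g, v_tca)
  structure(fx, class = c("flux_config_1c", "flux_config"))
}

#' Pseudo three-compartment flux configuration
#'
#' Free and fixed fluxes of the excitatory-neuron / inhibitory-neuron / glia
#' labeling model. Free: pyruvate dehydrogenase of excitatory (`v_pdh_e`) and
#' inhibitory (`v_pdh_i`) neurons, transmitochondrial exchanges (`v_x_e`,
#' `v_x_i`), glutamatergic and GABAergic neurotransmission cycling (`v_nt_e`,
#' `v_nt_i`), glutamate decarboxylase (`v_gad`), exchange with a second
#' glutamine (`v_ex_g`) or GABA (`v_ex_i`) pool, and dilution from blood
#' lactate (`v_dil_in`) and acetate (`v_dil_g`). Fixed: glial pyruvate
#' carboxylase (`v_pc`), glial oxidative TCA (`v_g`) and glial
#' transmitochondrial exchange (`v_x_g`); glial glutamine efflux is tied to
#' `v_pc` (`v_eff = v_pc`). `cmr_glc` is fixed from PET.
#'
#' Validity requires `v_gad >= v_nt_i` (nonnegative GABA shunt) and
#' `v_nt_e + v_pc >= v_nt_i` (nonnegative glutamine synthetase flux).
#'
#' @param cmr_glc,v_pdh_e,v_pdh_i,v_x_e,v_x_i,v_nt_e,v_nt_i,v_gad,v_ex_g,v_ex_i,v_dil_in,v_dil_g
#'   free fluxes (umol/g/min, >= 0).
#' @param v_pc,v_g,v_x_g fixed glial fluxes (umol/g/min, >= 0).
#' @return A `flux_config_3c` object (named list, includes `v_eff = v_pc`).
#' @export
flux_config_3c <- function(cmr_glc = 0.45,
                           v_pdh_e = 0.30, v_pdh_i = 0.06,
                           v_x_e = 0.60, v_x_i = 0.15,
                           v_nt_e = 0.05, v_nt_i = 0.010,
                           v_gad = 0.32, v_ex_g = 0.02, v_ex_i = 0.0006,
                           v_dil_in = 0.15, v_dil_g = 0.02,
                           v_pc = 0.06, v_g = 0.20, v_x_g = 0.50) {
  fx <- list(cmr_glc = cmr_glc, v_pdh_e = v_pdh_e, v_pdh_i = v_pdh_i,
             v_x_e = v_x_e, v_x_i = v_x_i, v_nt_e = v_nt_e, v_nt_i = v_nt_i,
             v_gad = v_gad, v_ex_g = v_ex_g, v_ex_i = v_ex_i,
             v_dil_in = v_dil_in, v_dil_g = v_dil_g,
             v_pc = v_pc, v_g = v_g, v_x_g = v_x_g)
  for (nm in names(fx)) check_number(fx[[nm]], nm, 0)
  if (v_gad < v_nt_i)
    stop_invalid("v_gad (%g) must be >= v_nt_i (%g): the GABA shunt v_gad - v_nt_i cannot be negative",
                 v_gad, v_nt_i)
  if (v_nt_e + v_pc < v_nt_i)
    stop_invalid("v_nt_e + v_pc must be >= v_nt_i: glutamine synthetase flux cannot be negative")
  if (v_dil_g > v_g)
    stop_invalid("v_dil_g (%g) cannot exceed the glial TCA flux v_g (%g)",
                 v_dil_g, v_g)
  fx$v_eff <- v_pc
  structure(fx, class = c("flux_config_3c", "flux_config"))
}

#' @export
print.flux_config <- function(x, ...) {
  kind <- if (inherits(x, "flux_config_3c")) "pseudo 3-compartment"
          else "1-compartment"
  cat(sprintf("<%s flux configuration (umol/g/min)>\n", kind))
  print(unlist(x))
  invisible(x)
}

#' Names of the free fluxes of a labeling model
#'
#' The fluxes estimated by [fit_fluxes()] for each model kind, in reporting
#' order.
#'
#' @param kind `"one_compartment"` or `"pseudo_three_compartment"`.
#' @return Character vector of flux names.
#' @export
free_flux_names <- function(kind) {
  switch(kind,
    one_compartment = c("v_tca", "v_x", "v_nt", "v_dil_in", "v_dil_g"),
    pseudo_three_compartment = c("v_pdh_e", "v_pdh_i", "v_x_e", "v_x_i",
                                 "v_nt_e", "v_nt_i", "v_gad", "v_ex_g",
                                 "v_ex_i", "v_dil_in", "v_dil_g"),
    stop_invalid("unknown model kind '%s'", kind))
}

#' Default metabolite pool sizes (mM)
#'
#' Pool concentrations used by the labeling models. Glutamate is split across
#' compartments in the three-compartment model (excitatory neurons carry the
#' bulk); the aspartate/oxaloacetate pool of excitatory neurons is carried at
#' the NMR-visible aspartate concentration since the two exchange rapidly.
#' Second glutamine and GABA pools default to the size of the visible pool.
#'
#' @param kind `"one_compartment"` or `"pseudo_three_compartment"`.
#' @return Named numeric vector of pool sizes in mM.
#' @export
default_pool_sizes <- function(kind = c("pseudo_three_compartment",
                                        "one_compartment")) {
  kind <- match.arg(kind)
  if (kind == "one_compartment") {
    c(Glc = 1.5, Lac = 2.5, AcCoA = 0.05, OG = 0.20, OAA = 2.5,
      Glu = 9.0, Gln = 4.0)
  } else {
    c(Glc = 1.5, Lac = 2.5,
      AcCoA_e = 0.05, AcCoA_i = 0.05, AcCoA_g = 0.05,
      OG_e = 0.15, OG_i = 0.15, OG_g = 0.15,
      OAA_e = 2.5, OAA_i = 0.10, OAA_g = 0.10,
      Glu_e = 7.0, Glu_i = 1.0, Glu_g = 1.0,
      Gln_g = 3.0, Gln2 = 3.0, GABA = 1.5, GABA2 = 1.5)
  }
}
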