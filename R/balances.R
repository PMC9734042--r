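# Mass-balance-derived fluxes and relative allostatic loads.

#' Derive mass-balance fluxes from a three-compartment configuration
#'
#' Applies the steady-state mass-balance identities to a fitted (or
#' constructed) pseudo three-compartment flux configuration:
#' GABA shunt `v_shunt_i = v_gad - v_nt_i`; glutamine synthetase
#' `v_gs = v_nt_e - v_nt_i + v_pc`; inhibitory TCA
#' `v_tca_i = v_pdh_i + v_shunt_i`; glial TCA
#' `v_tca_g = v_g + v_pc + v_nt_i`; excitatory TCA `v_tca_e = v_pdh_e`;
#' oxidative glucose consumption
#' `cmr_glc_ox = (v_tca_i + v_tca_e + v_tca_g + v_pc) / 2`; and brain-to-blood
#' lactate efflux `v_dil_out = v_dil_in * lac_brain / lac_blood`.
#'
#' @param fx a [flux_config_3c()] object.
#' @param lac_brain brain (hippocampal) lactate concentration, mM.
#' @param lac_blood blood lactate concentration, mM (> 0).
#' @return A `derived_fluxes` list with the seven derived fluxes (umol/g/min).
#' @examples
#' derive_balances(flux_config_3c(), lac_brain = 2.5, lac_blood = 7.7)
#' @export
derive_balances <- function(fx, lac_brain, lac_blood) {
  if (!inherits(fx, "flux_config_3c"))
    stop_invalid("`fx` must be a flux_config_3c")
  check_number(lac_brain, "lac_brain", 0)
  check_number(lac_blood, "lac_blood", 0, strict_lower = TRUE)
  if (fx$v_gad < fx$v_nt_i)
    stop_invalid("v_gad < v_nt_i: the GABA shunt would be negative")
  v_shunt_i <- fx$v_gad - fx$v_nt_i
  v_gs <- fx$v_nt_e - fx$v_nt_i + fx$v_pc
  v_tca_i <- fx$v_pdh_i + v_shunt_i
  v_tca_e <- fx$v_pdh_e
  v_tca_g <- fx$v_g + fx$v_pc + fx$v_nt_i
  cmr_glc_ox <- (v_tca_i + v_tca_e + v_tca_g + fx$v_pc) / 2
  v_dil_out <- fx$v_dil_in * lac_brain / lac_blood
  structure(list(v_shunt_i = v_shunt_i, v_gs = v_gs, v_tca_i = v_tca_i,
                 v_tca_e = v_tca_e, v_tca_g = v_tca_g,
                 cmr_glc_ox = cmr_glc_ox, v_dil_out = v_dil_out),
            class = "derived_fluxes")
}

#' @export
print.derived_fluxes <- function(x, ...) {
  cat("<derived fluxes (umol/g/min)>\n")
  print(unlist(x))
  invisible(x)
}

#' Relative oxidative allostatic loads
#'
#' Compares neurotransmission demand to oxidative ATP production capacity
#' between a knockout-like and a control group, separately for excitatory and
#' inhibitory neurons:
#' relative excitatory load `= (v_nt_e / v_atp_ox_e)_ko / (v_nt_e / v_atp_ox_e)_wt`
#' and relative inhibitory load
#' `= ((v_nt_i + v_ex_i) / v_atp_ox_i)_ko / ((v_nt_i + v_ex_i) / v_atp_ox_i)_wt`,
#' with `v_atp_ox = atp_stoichiometry * v_tca` of the corresponding neuron
#' type. The ATP stoichiometry cancels in these ratios (it matters only for
#' absolute rates), which is why the loads are computable without knowing it.
#'
#' @param fx_ko,fx_wt [flux_config_3c()] objects for the two groups.
#' @param atp_stoichiometry ATP produced per TCA turnover (dimensionless
#'   proportionality; default 15, approximately oxidative phosphorylation
#'   yield per acetyl oxidized).
#' @return List with `relative_excitatory_load`, `relative_inhibitory_load`
#'   and `inhibitory_to_excitatory_ratio`.
#' @export
compute_allostatic_loads <- function(fx_ko, fx_wt, atp_stoichiometry = 15) {
  check_number(atp_stoichiometry, "atp_stoichiometry", 0, strict_lower = TRUE)
  pieces <- function(fx) {
    d <- derive_balances(fx, lac_brain = 1, lac_blood = 1)
    list(nt_e = fx$v_nt_e, nt_i = fx$v_nt_i + fx$v_ex_i,
         atp_e = atp_stoichiometry * d$v_tca_e,
         atp_i = atp_stoichiometry * d$v_tca_i)
  }
  ko <- pieces(fx_ko); wt <- pieces(fx_wt)
  if (wt$nt_e <= 0 || wt$nt_i <= 0)
    stop_invalid("control neurotransmission fluxes must be positive to form relative loads")
  if (wt$atp_e <= 0 || wt$atp_i <= 0 || ko$atp_e <= 0 || ko$atp_i <= 0)
    stop_invalid("oxidative ATP production must be positive in both groups")
  exc <- (ko$nt_e / ko$atp_e) / (wt$nt_e / wt$atp_e)
  inh <- (ko$nt_i / ko$atp_i) / (wt$nt_i / wt$atp_i)
  list(relative_excitatory_load = exc,
       relative_inhibitory_load = inh,
       inhibitory_to_excitatory_ratio = inh / exc)
}
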