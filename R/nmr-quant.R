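# Deterministic NMR quantification algebra.

#' Resolve NADH and NAD+ from overlapping 31P resonances
#'
#' The left part of the NAD+ quadruplet integrates to
#' `X = 2 NADH + NAD+ + UDPGlc`, the right part to `Y = NAD+`, and the
#' -9.83 ppm resonance to `Z = UDPGlc`; hence
#' `NADH = (X - Y - Z) / 2` and `NAD+ = Y`.
#'
#' @param x,y,z the three integrals (same arbitrary units, `x >= y + z >= 0`).
#' @return List with `nadh`, `nad_plus` and `ratio` (NADH/NAD+).
#' @examples
#' nadh_nad_from_overlap(10, 4, 2) # nadh 2, ratio 0.5
#' @export
nadh_nad_from_overlap <- function(x, y, z) {
  for (v in c("x", "y", "z")) check_number(get(v), v, 0)
  if (x < y + z)
    stop_invalid("inconsistent integrals: X (%g) < Y + Z (%g)", x, y + z)
  if (y == 0)
    stop_invalid("NAD+ integral Y is zero: NADH/NAD+ ratio undefined")
  nadh <- (x - y - z) / 2
  list(nadh = nadh, nad_plus = y, ratio = nadh / y)
}

#' Convert fractional enrichment to 13C concentration
#'
#' Pointwise product of an FE curve with the total metabolite concentration
#' measured in the non-edited spectra.
#'
#' @param fe fractional enrichment values in \[0, 1\].
#' @param total_concentration total metabolite concentration, mM (>= 0).
#' @return 13C concentration curve, mM.
#' @export
fe_to_concentration <- function(fe, total_concentration) {
  if (any(!is.finite(fe)) || any(fe < 0) || any(fe > 1))
    stop_invalid("`fe` values must lie in [0, 1]")
  check_number(total_concentration, "total_concentration", 0)
  fe * total_concentration
}

#' Quantify a peak against an internal reference
#'
#' Concentration by ratio referencing:
#' `conc = (peak / reference) * reference_concentration`, after optional
#' per-proton normalization of both integrals (quantitative NMR integrals
#' scale with the number of contributing protons).
#'
#' @param peak_integral integral of the resonance of interest (>= 0).
#' @param reference_integral integral of the reference resonance (> 0).
#' @param reference_concentration assumed reference concentration, mM
#'   (e.g. 7 mM NAA in dorsal hippocampus).
#' @param peak_protons,reference_protons protons contributing to each
#'   resonance (default 1; e.g. 3 for the creatine methyl singlet).
#' @return Concentration, mM.
#' @export
reference_ratio <- function(peak_integral, reference_integral,
                            reference_concentration,
                            peak_protons = 1, reference_protons = 1) {
  check_number(reference_integral, "reference_integral", 0,
               strict_lower = TRUE)
  check_number(reference_concentration, "reference_concentration", 0)
  check_number(peak_protons, "peak_protons", 0, strict_lower = TRUE)
  check_number(reference_protons, "reference_protons", 0,
               strict_lower = TRUE)
  if (any(peak_integral < 0)) stop_invalid("`peak_integral` must be >= 0")
  (peak_integral / peak_protons) /
    (reference_integral / reference_protons) * reference_concentration
}
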