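# Blood input functions: 13C-glucose enrichment and 18FDG plasma activity.

#' Simulate a blood input function
#'
#' Builds the arterial input driving either kinetic experiment: for
#' `kind = "mrs"`, the fractional enrichment (FE) of blood glucose during a
#' \[U-13C6\]glucose infusion, modeled as a single-exponential saturation
#' `fe(t) = fe_plateau * (1 - exp(-t / rise_tau))`; for `kind = "pet"`, the
#' decay-corrected plasma activity after an i.v. FDG bolus, modeled as a
#' gamma-variate rise followed by bi-exponential clearance.
#'
#' @param times sampling grid in minutes, strictly increasing, starting at or
#'   after 0.
#' @param kind `"mrs"` (blood glucose FE) or `"pet"` (plasma activity).
#' @param fe_plateau asymptotic blood glucose FE reached by the infusion
#'   (fraction in \[0, 1\]; default 0.70, typical for a controlled
#'   \[U-13C6\]glucose infusion).
#' @param rise_tau time constant of the enrichment rise (minutes, > 0).
#' @param peak_activity peak plasma activity of the PET bolus (kBq/cc).
#' @param bolus_alpha,bolus_beta shape and time-scale (minutes) of the
#'   gamma-variate bolus rise.
#' @param clearance_frac,clearance_fast,clearance_slow bi-exponential tail:
#'   fraction of the fast component and the two clearance rate constants
#'   (1/min).
#'
#' @return An object of class `input_function` with elements `times`, `values`
#'   (`blood_fe` for MRS, `plasma_activity` for PET), the generating
#'   parameters, and a continuous evaluator `fun(t)`.
#' @examples
#' inp <- simulate_blood_input(seq(0, 230, by = 10), kind = "mrs")
#' inp$fun(3) # = 0.7 * (1 - exp(-1))
#' @export
simulate_blood_input <- function(times, kind = c("mrs", "pet"),
                                 fe_plateau = 0.70, rise_tau = 3,
                                 peak_activity = 1500, bolus_alpha = 2,
                                 bolus_beta = 0.25, clearance_frac = 0.6,
                                 clearance_fast = 0.25,
                                 clearance_slow = 0.01) {
  kind <- match.arg(kind)
  times <- check_times(times)
  if (min(times) < 0) stop_invalid("`times` must be nonnegative")

  if (kind == "mrs") {
    check_number(rise_tau, "rise_tau", 0, strict_lower = TRUE)
    check_number(fe_plateau, "fe_plateau", 0, 1)
    fun <- function(t) fe_plateau * (1 - exp(-pmax(t, 0) / rise_tau))
    values <- fun(times)
    out <- list(times = times, blood_fe = values, fe_plateau = fe_plateau,
                rise_tau = rise_tau, kind = "mrs", fun = fun)
  } else {
    check_number(peak_activity, "peak_activity", 0)
    check_number(bolus_beta, "bolus_beta", 0, strict_lower = TRUE)
    # gamma-variate bolus, unit peak at t = alpha * beta, then additional
    # bi-exponential washout so late activity decays like real plasma curves
    tpk <- bolus_alpha * bolus_beta
    gv <- function(t) (pmax(t, 0) / tpk)^bolus_alpha *
      exp(bolus_alpha * (1 - pmax(t, 0) / tpk))
    tail_fun <- function(t) clearance_frac * exp(-clearance_fast * pmax(t, 0)) +
      (1 - clearance_frac) * exp(-clearance_slow * pmax(t, 0))
    fun <- function(t) peak_activity * gv(t) * tail_fun(t)
    values <- fun(times)
    out <- list(times = times, plasma_activity = values,
                peak_activity = peak_activity, kind = "pet", fun = fun)
  }
  class(out) <- "input_function"
  out
}

#' @export
print.input_function <- function(x, ...) {
  lab <- if (x$kind == "mrs") "blood glucose FE" else "plasma activity"
  cat(sprintf("<input_function: %s, %d samples over %.4g-%.4g min>\n",
              lab, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

# Evaluate an input function (or a sampled curve) at arbitrary times.
input_eval <- function(input, at) {
  if (inherits(input, "input_function") && is.function(input$fun))
    return(input$fun(at))
  vals <- if (!is.null(input$blood_fe)) input$blood_fe else input$plasma_activity
  interp_curve(input$times, vals, at)
}
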