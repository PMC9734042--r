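# Two-tissue compartment modeling of 18FDG kinetics.

#' PET kinetic parameters
#'
#' Rate constants of the irreversible-by-default two-tissue FDG model:
#' glucose exchanges between plasma (`C_p`) and an intracellular pool (`C_e`)
#' with `k1` (in) and `k2` (out); phosphorylation to FDG-6P (`C_m`) proceeds
#' with `k3` and dephosphorylation with `k4`. `vb` is the vascular volume
#' fraction mixed into the measured signal. The net uptake constant is
#' `Ki = k1 k3 / (k2 + k3)` (for `k4 = 0`) and
#' `cmr_glc = Ki * plasma_glucose / lumped_constant`.
#'
#' @param k1,k2,k3,k4 rate constants (1/min, >= 0).
#' @param vb vascular volume fraction in \[0, 1).
#' @param lumped_constant FDG-to-glucose lumped constant (> 0; default 0.6).
#' @param plasma_glucose plasma glucose (mM).
#' @return A `pet_kinetic_params` object; `$cmr_glc` holds the derived
#'   metabolic rate (umol/g/min).
#' @export
pet_kinetic_params <- function(k1 = 0.1, k2 = 0.2, k3 = 0.05, k4 = 0,
                               vb = 0, lumped_constant = 0.6,
                               plasma_glucose = 7.7) {
  for (nm in c("k1", "k2", "k3", "k4"))
    check_number(get(nm), nm, 0)
  check_number(vb, "vb", 0, 1)
  if (vb >= 1) stop_invalid("`vb` must be < 1")
  check_number(lumped_constant, "lumped_constant", 0, strict_lower = TRUE)
  check_number(plasma_glucose, "plasma_glucose", 0)
  p <- list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, vb = vb,
            lumped_constant = lumped_constant,
            plasma_glucose = plasma_glucose)
  p$cmr_glc <- pet_cmr_glc(p)
  structure(p, class = "pet_kinetic_params")
}

pet_cmr_glc <- function(p) {
  if (p$k2 + p$k3 <= 0) return(NA_real_)
  (p$k1 * p$k3 / (p$k2 + p$k3)) * p$plasma_glucose / p$lumped_constant
}

#' @export
print.pet_kinetic_params <- function(x, ...) {
  cat("<PET two-tissue kinetic parameters>\n")
  print(round(unlist(x), 6))
  invisible(x)
}

#' Simulate a tissue time-activity curve
#'
#' Integrates `dC_e/dt = k1 C_p - (k2 + k3) C_e + k4 C_m` and
#' `dC_m/dt = k3 C_e - k4 C_m` against a plasma input and returns the
#' measured mixture `(1 - vb) (C_e + C_m) + vb C_p`.
#'
#' @param params a [pet_kinetic_params()] object.
#' @param input an `input_function` of kind `"pet"` (plasma activity), whose
#'   support must cover `times` when sampled.
#' @param times output times, minutes.
#' @param roi_label label carried through to the output.
#' @param rtol,atol integrator tolerances.
#' @return A `tissue_tac`: list with `times`, `tissue_activity` (kBq/cc) and
#'   `roi_label`.
#' @export
simulate_tac <- function(params, input, times, roi_label = "hippocampus",
                         rtol = 1e-8, atol = 1e-10) {
  times <- check_times(times)
  if (!inherits(params, "pet_kinetic_params"))
    stop_invalid("`params` must be pet_kinetic_params")
  if (inherits(input, "input_function") && !identical(input$kind, "pet"))
    stop_invalid("TAC simulation needs a PET plasma input")
  if (!is.function(input$fun))
    interp_curve(input$times, input$plasma_activity, times,
                 "plasma input")  # errors on extrapolation
  cp <- function(t) input_eval(input, t)
  rhs <- function(t, x, p) {
    u <- cp(t)
    list(c(p$k1 * u - (p$k2 + p$k3) * x[1] + p$k4 * x[2],
           p$k3 * x[1] - p$k4 * x[2]))
  }
  tgrid <- if (min(times) > 0) c(0, times) else times
  sol <- deSolve::lsoda(c(0, 0), tgrid, rhs, parms = params,
                        rtol = rtol, atol = atol)
  X <- sol[match(times, tgrid), -1, drop = FALSE]
  act <- (1 - params$vb) * rowSums(X) + params$vb * cp(times)
  structure(list(times = times, tissue_activity = pmax(act, 0),
                 roi_label = roi_label),
            class = "tissue_tac")
}

#' @export
print.tissue_tac <- function(x, ...) {
  cat(sprintf("<tissue_tac: %s, %d samples over %.3g-%.3g min>\n",
              x$roi_label, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Fit the two-tissue FDG model to a tissue curve
#'
#' Weighted least squares over `k1, k2, k3` (and `k4` unless `fix_k4`) by
#' bounded Levenberg-Marquardt. `k4` is fixed to 0 by default: over a 50-min
#' scan FDG-6P trapping is effectively irreversible.
#'
#' @param tac a `tissue_tac` (>= 8 time points).
#' @param input the PET plasma `input_function` used to acquire it.
#' @param init starting [pet_kinetic_params()]; also supplies `vb`,
#'   `lumped_constant` and `plasma_glucose`, which are not estimated.
#' @param fix_k4 hold `k4` at `init$k4` (default TRUE).
#' @param weights optional per-point weights (defaults to uniform).
#' @param max_iter maximum optimizer iterations.
#' @return A `pet_fit`: `$params` ([pet_kinetic_params()] with fitted rates
#'   and derived `cmr_glc`), `$residual_norm`, `$converged`, `$diagnostics`
#'   (iterations, relative gradient/step measures), and a Monte-Carlo context
#'   usable by [monte_carlo_sd()].
#' @export
fit_pet_model <- function(tac, input, init = pet_kinetic_params(),
                          fix_k4 = TRUE, weights = NULL, max_iter = 100) {
  if (length(tac$times) < 8)
    stop_invalid("PET fitting needs at least 8 time points")
  y <- tac$tissue_activity
  if (is.null(weights)) weights <- rep(1, length(y))
  sw <- sqrt(weights)
  par_names <- c("k1", "k2", "k3", if (!fix_k4) "k4")
  start <- unlist(init[par_names])
  model_curve <- function(par) {
    p <- init
    p[par_names] <- as.list(pmax(par, 0))
    p <- do.call(pet_kinetic_params,
                 p[names(formals(pet_kinetic_params))])
    simulate_tac(p, input, tac$times, tac$roi_label,
                 rtol = 1e-8)$tissue_activity
  }
  resid_fn <- function(par) sw * (model_curve(par) - y)
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            lower = rep(0, length(start)),
                            upper = rep(2, length(start)),
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-12,
                              ptol = 1e-12))
  converged <- fit$info %in% 1:4
  best <- init
  best[par_names] <- as.list(unname(fit$par))
  best <- do.call(pet_kinetic_params,
                  best[names(formals(pet_kinetic_params))])
  fitted_curve <- model_curve(fit$par)
  out <- list(params = best,
              residual_norm = sqrt(sum(fit$fvec^2)),
              converged = converged,
              diagnostics = list(info = fit$info, message = fit$message,
                                 iterations = fit$niter,
                                 deviance = fit$deviance),
              observed = y, fitted = fitted_curve, times = tac$times,
              par_names = par_names,
              refit = function(y_new) {
                f2 <- minpack.lm::nls.lm(
                  par = fit$par, fn = function(par) sw * (model_curve(par) - y_new),
                  lower = rep(0, length(start)), upper = rep(2, length(start)),
                  control = minpack.lm::nls.lm.control(maxiter = max_iter))
                setNames(as.numeric(f2$par), par_names)
              })
  if (!converged)
    warning("PET fit did not converge; returning last iterate")
  class(out) <- c("pet_fit", "mc_refittable")
  out
}

#' @export
print.pet_fit <- function(x, ...) {
  cat(sprintf("<pet_fit: %s, residual norm %.4g>\n",
              if (x$converged) "converged" else "NOT converged",
              x$residual_norm))
  print(x$params)
  invisible(x)
}

#' Standardized uptake value
#'
#' `SUV = mean ROI activity / (injected dose / body weight)`.
#'
#' @param mean_roi_activity mean ROI activity, kBq/cc (>= 0).
#' @param injected_dose injected dose, kBq (> 0).
#' @param body_weight body weight, g (> 0).
#' @return SUV (dimensionless, g/cc scale).
#' @examples
#' compute_suv(500, 50000, 25) # 0.25
#' @export
compute_suv <- function(mean_roi_activity, injected_dose, body_weight) {
  check_number(injected_dose, "injected_dose", 0, strict_lower = TRUE)
  check_number(body_weight, "body_weight", 0, strict_lower = TRUE)
  if (any(mean_roi_activity < 0))
    stop_invalid("`mean_roi_activity` must be >= 0")
  mean_roi_activity / (injected_dose / body_weight)
}

#' Patlak graphical analysis
#'
#' Linear regression of `C_t(t)/C_p(t)` on the normalized time
#' `int_0^t C_p ds / C_p(t)` over a late-time window; for an irreversible
#' tracer (`k4 = 0`) the slope converges to `Ki = k1 k3 / (k2 + k3)`.
#'
#' @param tac a `tissue_tac`.
#' @param input the plasma `input_function`.
#' @param t_start start of the linear window (minutes).
#' @return List with `slope` (`Ki`, 1/min) and `intercept`.
#' @export
patlak_slope <- function(tac, input, t_start = 20) {
  tt <- tac$times
  cp <- input_eval(input, tt)
  # cumulative integral of the plasma curve on a fine grid
  fine <- seq(0, max(tt), length.out = 2001)
  cpf <- input_eval(input, fine)
  cum <- c(0, cumsum((head(cpf, -1) + tail(cpf, -1)) / 2 * diff(fine)))
  cint <- approxfun(fine, cum)(tt)
  keep <- tt >= t_start & cp > 0
  if (sum(keep) < 3) stop_invalid("too few points in the Patlak window")
  xx <- cint[keep] / cp[keep]
  yy <- tac$tissue_activity[keep] / cp[keep]
  co <- stats::coef(stats::lm(yy ~ xx))
  list(slope = unname(co[2]), intercept = unname(co[1]))
}
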