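# Estimation of free metabolic fluxes from enrichment curves.

# Run code with a private, restored RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# Internal parametrization: v_gad is replaced by the GABA shunt
# v_shunt_i = v_gad - v_nt_i so all constraints become box constraints, and
# the optimizer works on log10 fluxes (the free fluxes span four orders of
# magnitude; multiplicative steps keep small exchange fluxes recoverable).
internal_par_names <- function(kind) {
  nm <- free_flux_names(kind)
  if (kind == "pseudo_three_compartment") nm[nm == "v_gad"] <- "v_shunt_i"
  nm
}

default_flux_init <- function(kind) {
  if (kind == "one_compartment")
    c(v_tca = 0.6, v_x = 0.5, v_nt = 0.05, v_dil_in = 0.15, v_dil_g = 0.03)
  else
    c(v_pdh_e = 0.25, v_pdh_i = 0.08, v_x_e = 0.5, v_x_i = 0.2,
      v_nt_e = 0.05, v_nt_i = 0.02, v_gad = 0.30, v_ex_g = 0.01,
      v_ex_i = 0.001, v_dil_in = 0.15, v_dil_g = 0.03)
}

natural_to_internal <- function(est, kind) {
  nm <- internal_par_names(kind)
  out <- est
  if (kind == "pseudo_three_compartment") {
    out[["v_gad"]] <- NULL
    out <- c(out, v_shunt_i = est[["v_gad"]] - est[["v_nt_i"]])
  }
  unlist(out)[nm]
}

internal_to_natural <- function(par, kind) {
  par <- as.list(par)
  if (kind == "pseudo_three_compartment") {
    par$v_gad <- par$v_shunt_i + par$v_nt_i
    par$v_shunt_i <- NULL
  }
  unlist(par)[free_flux_names(kind)]
}

# Cached forward model for fitting. The labeling-system matrices are linear
# in the flux values, so one decomposition M(v) = M_const + sum_j v_j D_j
# (obtained by differencing the real builder around the starting point, exact
# for a linear map) replaces per-iteration system construction; propagation is
# one matrix exponential of the augmented system plus matrix-vector steps.
forward_factory <- function(kind, make_config, pool_sizes, base_nat, input,
                            times, dt, obs_channels) {
  build <- function(nat) build_labeling_system(kind, make_config(nat),
                                               pool_sizes)
  sys0 <- build(base_nat)
  fx0 <- sys0$fluxes
  int_nm <- internal_par_names(kind)
  int0 <- natural_to_internal(as.list(base_nat), kind)
  M0 <- sys0$M; w0 <- sys0$w
  h <- 0.01
  DM <- vector("list", length(int_nm)); Dw <- DM
  for (j in seq_along(int_nm)) {
    sys_j <- NULL
    for (hh in c(h, -h)) {
      intj <- int0; intj[j] <- intj[j] + hh
      sys_j <- tryCatch(build(internal_to_natural(intj, kind)),
                        error = function(e) NULL)
      if (!is.null(sys_j)) break
    }
    if (is.null(sys_j))
      stop_invalid("cannot linearize the labeling system around the start (parameter '%s')",
                   int_nm[j])
    DM[[j]] <- (sys_j$M - M0) / hh
    Dw[[j]] <- (sys_j$w - w0) / hh
  }
  Mc <- M0; wc <- w0
  for (j in seq_along(int_nm)) {
    Mc <- Mc - int0[[j]] * DM[[j]]
    wc <- wc - int0[[j]] * Dw[[j]]
  }

  sizes <- sys0$sizes; n <- length(sizes)
  t_end <- max(times)
  grid <- seq(0, t_end, by = dt)
  if (tail(grid, 1) < t_end) grid <- c(grid, t_end)
  u <- input_eval(input, grid)
  hseg <- diff(grid); mseg <- diff(u) / hseg
  uniform <- all(abs(hseg - dt) < 1e-12)
  lo <- pmin(pmax(findInterval(times, grid, rightmost.closed = TRUE), 1),
             length(grid) - 1)
  frac <- (times - grid[lo]) / (grid[lo + 1] - grid[lo])
  C <- sys0$channels[obs_channels, , drop = FALSE]

  predict <- function(int) {
    M <- Mc; w <- wc
    for (j in seq_along(int)) {
      M <- M + int[[j]] * DM[[j]]
      w <- w + int[[j]] * Dw[[j]]
    }
    G <- matrix(0, n + 2, n + 2)
    G[1:n, 1:n] <- M / sizes
    G[1:n, n + 1] <- w / sizes
    G[n + 1, n + 2] <- 1
    En <- mat_expm(G * dt)[1:n, , drop = FALSE]
    X <- matrix(0, length(grid), n)
    x <- numeric(n)
    for (k in seq_along(hseg)) {
      Ek <- if (uniform || abs(hseg[k] - dt) < 1e-12) En
            else mat_expm(G * hseg[k])[1:n, , drop = FALSE]
      x <- as.numeric(Ek %*% c(x, u[k], mseg[k]))
      X[k + 1, ] <- x
    }
    Xi <- X[lo, , drop = FALSE] * (1 - frac) +
      X[lo + 1, , drop = FALSE] * frac
    Xi <- pmin(pmax(Xi, 0), 1)
    fe <- Xi %*% t(C)
    colnames(fe) <- obs_channels
    fe
  }

  violation <- function(nat) {
    viol <- 0
    if (kind == "one_compartment") {
      v_pdh <- nat[["v_tca"]] - nat[["v_dil_g"]]
      viol <- viol + max(0, -v_pdh)
      viol <- viol + max(0, v_pdh -
                           (2 * fx0$cmr_glc + nat[["v_dil_in"]]))
    } else {
      v_pdh_g <- fx0$v_g - nat[["v_dil_g"]]
      viol <- viol + max(0, -v_pdh_g)
      demand <- nat[["v_pdh_e"]] + nat[["v_pdh_i"]] +
        (nat[["v_gad"]] - nat[["v_nt_i"]]) + max(v_pdh_g, 0) + fx0$v_pc
      viol <- viol + max(0, demand -
                           (2 * fx0$cmr_glc + nat[["v_dil_in"]]))
      viol <- viol + max(0, nat[["v_nt_i"]] - nat[["v_nt_e"]] - fx0$v_pc)
    }
    viol
  }
  list(predict = predict, violation = violation, system0 = sys0)
}

#' Fit free metabolic fluxes to enrichment curves
#'
#' Bounded weighted least squares of simulated versus observed fractional
#' enrichment over the free fluxes of the chosen labeling model, with
#' `cmr_glc` fixed (from the PET experiment in the same voxel) and the glial
#' fluxes held at their fixed values. Multi-start Levenberg-Marquardt with
#' jittered initializations guards against local minima; the best run by
#' residual norm is kept. Deterministic given `seed`, data and settings.
#'
#' @param curves observed `labeling_curve_set` (FE matrix, time by channel).
#' @param kind `"one_compartment"` or `"pseudo_three_compartment"`; must
#'   match the channels present in `curves`.
#' @param input the blood glucose FE `input_function` of the experiment.
#' @param cmr_glc cerebral metabolic rate of glucose (umol/g/min, > 0),
#'   fixed during fitting.
#' @param fixed named list overriding fixed fluxes (`v_pc`, `v_g`, `v_x_g`
#'   for the three-compartment model).
#' @param init optional named vector of starting free fluxes.
#' @param bounds length-2 vector, common \[lower, upper\] bounds on every
#'   free flux (umol/g/min); the lower bound is kept strictly positive.
#' @param pool_sizes optional pool-size override (mM).
#' @param weights optional named per-channel weights.
#' @param n_starts number of jittered multi-start initializations.
#' @param seed integer seed controlling the jitter (reproducible).
#' @param dt internal propagation step in minutes.
#' @param max_iter optimizer iteration cap per start.
#' @param reg_lambda strength of a noise-scaled ridge in log-flux space
#'   applied in a final refinement: equivalent to a lognormal prior of SD
#'   `1/sqrt(reg_lambda)` decades around the reference initialization,
#'   multiplied by the estimated residual noise. It pins down only
#'   directions the data leave flat (the fast-exchange ridges of `v_x` and
#'   `v_ex`) and vanishes for noiseless data. Set to 0 to disable.
#' @return A `flux_estimate`: `$estimates` (named free fluxes, umol/g/min),
#'   `$residual_norm`, `$converged`, `$rsstrace` (objective at accepted
#'   steps), per-channel `$sigma`, `$fitted`/`$observed` matrices, and a
#'   refit closure consumed by [monte_carlo_sd()].
#' @export
fit_fluxes <- function(curves, kind = c("pseudo_three_compartment",
                                        "one_compartment"),
                       input, cmr_glc, fixed = list(), init = NULL,
                       bounds = c(1e-5, 5), pool_sizes = NULL,
                       weights = NULL, n_starts = 5, seed = 1,
                       dt = 0.25, max_iter = 60, reg_lambda = 1) {
  kind <- match.arg(kind)
  check_number(cmr_glc, "cmr_glc", 0, strict_lower = TRUE)
  if (!inherits(curves, "labeling_curve_set") && is.null(curves$fe))
    stop_invalid("`curves` must be a labeling_curve_set")
  free_nm <- free_flux_names(kind)
  int_nm <- internal_par_names(kind)
  lb <- max(bounds[1], 1e-5); ub <- bounds[2]

  make_config <- function(nat) {
    args <- c(as.list(nat), list(cmr_glc = cmr_glc), fixed)
    if (kind == "one_compartment") do.call(flux_config_1c, args)
    else do.call(flux_config_3c, args)
  }

  if (is.null(init)) init <- default_flux_init(kind)
  init <- pmin(pmax(init[free_nm], lb * 1.01), ub * 0.99)
  # repair a starting point that violates the pyruvate supply constraint
  for (rep_i in 1:20) {
    ok <- tryCatch({build_labeling_system(kind, make_config(init),
                                          pool_sizes); TRUE},
                   error = function(e) FALSE)
    if (ok) break
    init[grepl("^v_pdh|^v_tca", names(init))] <-
      init[grepl("^v_pdh|^v_tca", names(init))] * 0.8
    if ("v_gad" %in% names(init))
      init[["v_gad"]] <- init[["v_nt_i"]] +
        0.8 * (init[["v_gad"]] - init[["v_nt_i"]])
  }

  # observed data and channel bookkeeping
  obs <- curves$fe
  times <- curves$times
  probe <- build_labeling_system(kind, make_config(init), pool_sizes)
  model_channels <- rownames(probe$channels)
  missing <- setdiff(colnames(obs), model_channels)
  if (length(missing))
    stop_invalid("curves contain channels unknown to the %s model: %s",
                 kind, paste(missing, collapse = ", "))
  if (is.null(weights)) weights <- setNames(rep(1, ncol(obs)), colnames(obs))
  wmat <- matrix(sqrt(weights[colnames(obs)]), nrow(obs), ncol(obs),
                 byrow = TRUE)

  fwd <- forward_factory(kind, make_config, pool_sizes, init, input,
                         times, dt, colnames(obs))

  theta0 <- log10(natural_to_internal(as.list(init), kind))
  theta0 <- pmin(pmax(theta0, log10(lb)), log10(ub))

  # Objective with an optional noise-scaled ridge in log-flux space.
  # Exchange fluxes have likelihood-flat fast-exchange ridges on which plain
  # least squares drifts to a bound (leaving zero Monte-Carlo variance
  # there). With ridge weight sqrt(reg_lambda) * sigma-hat the penalty acts
  # as a lognormal prior of SD 1/sqrt(reg_lambda) decades around the
  # reference initialization, scaled by the estimated data noise: it decides
  # only directions the data leave undetermined and vanishes for noiseless
  # data. The multistart search runs unridged; the ridge enters in a final
  # refinement from the selected optimum (and in Monte-Carlo refits).
  resid_fn_at <- function(ridge_w, data) function(theta) {
    int <- setNames(10^theta, int_nm)
    nat <- internal_to_natural(int, kind)
    viol <- fwd$violation(nat)
    if (viol > 0) {
      # infeasible interior point (pyruvate supply exceeded or negative
      # glutamine synthetase flux): smooth penalty pushing back inside
      return(rep(1 + 10 * viol, length(data) + length(theta)))
    }
    c(as.numeric(wmat * (fwd$predict(int) - data)),
      ridge_w * (theta - theta0))
  }
  resid_fn <- resid_fn_at(0, obs)

  starts <- with_seed(seed, {
    jit <- lapply(seq_len(max(n_starts - 1, 0)), function(i)
      pmin(pmax(theta0 + runif(length(theta0), -0.5, 0.5),
                log10(lb)), log10(ub)))
    c(list(theta0), jit)
  })

  runs <- list()
  for (th in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th, fn = resid_fn,
                         lower = rep(log10(lb), length(th)),
                         upper = rep(log10(ub), length(th)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) runs[[length(runs) + 1]] <- fit
  }
  if (!length(runs)) stop_invalid("all optimizer starts failed")
  # Exchange fluxes sit on flat likelihood ridges (a very fast exchange with
  # a proportionally larger turnover is data-equivalent to no exchange), so
  # several starts can end at statistically indistinguishable optima. Among
  # runs whose weighted RSS is within one chi-square standard deviation of
  # the best (relative sqrt(2/n_obs)), report the solution closest to the
  # reference initialization in log-flux space.
  devs <- vapply(runs, function(f) f$deviance, numeric(1))
  tie_window <- 1 + sqrt(2 / length(obs))
  cand <- which(devs <= min(devs) * tie_window)
  dist0 <- vapply(runs[cand],
                  function(f) sum((f$par - theta0)^2), numeric(1))
  best <- runs[[cand[which.min(dist0)]]]

  rss_trace <- best$rsstrace
  sigma_hat <- sqrt(best$deviance / length(obs))
  ridge_w <- if (reg_lambda > 0) sqrt(reg_lambda) * sigma_hat else 0
  if (ridge_w > 0) {
    refined <- tryCatch(
      minpack.lm::nls.lm(par = best$par, fn = resid_fn_at(ridge_w, obs),
                         lower = rep(log10(lb), length(theta0)),
                         upper = rep(log10(ub), length(theta0)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(refined)) best <- refined
  }

  est_int <- setNames(10^best$par, int_nm)
  estimates <- internal_to_natural(est_int, kind)
  fitted <- fwd$predict(est_int)
  resid <- obs - fitted
  sigma <- apply(resid, 2, function(r) sqrt(mean(r^2)))
  converged <- best$info %in% 1:4

  out <- list(kind = kind, estimates = estimates,
              residual_norm = sqrt(sum(resid^2 * wmat^2)),
              converged = converged,
              rsstrace = rss_trace,
              diagnostics = list(info = best$info, message = best$message,
                                 iterations = best$niter,
                                 n_starts = length(starts)),
              sigma = sigma, observed = obs, fitted = fitted,
              times = times, cmr_glc = cmr_glc, fixed = fixed, seed = seed,
              refit = function(obs_new) {
                f2 <- tryCatch(
                  minpack.lm::nls.lm(
                    par = best$par, fn = resid_fn_at(ridge_w, obs_new),
                    lower = rep(log10(lb), length(int_nm)),
                    upper = rep(log10(ub), length(int_nm)),
                    control = minpack.lm::nls.lm.control(maxiter = 30)),
                  error = function(e) NULL)
                if (is.null(f2)) return(estimates)
                internal_to_natural(setNames(10^f2$par, int_nm), kind)
              })
  if (!converged)
    warning("flux fit did not converge; estimates are the last iterate")
  class(out) <- c("flux_estimate", "mc_refittable")
  out
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf("<flux_estimate: %s, %s, residual norm %.4g>\n", x$kind,
              if (x$converged) "converged" else "NOT converged",
              x$residual_norm))
  print(signif(x$estimates, 4))
  if (!is.null(x$monte_carlo_sd)) {
    cat("Monte-Carlo SD:\n")
    print(signif(x$monte_carlo_sd, 3))
  }
  invisible(x)
}

#' Monte-Carlo context for an arbitrary fit
#'
#' Wraps any least-squares fit into the interface [monte_carlo_sd()] needs:
#' the observed and fitted values and a closure refitting perturbed data.
#'
#' @param observed observed data (vector or matrix).
#' @param fitted fitted model values, same shape.
#' @param refit `function(new_observed)` returning the parameter vector.
#' @param sigma optional noise SD (scalar or per-column); estimated from the
#'   residuals when omitted.
#' @return An `mc_refittable` object.
#' @export
mc_refit_context <- function(observed, fitted, refit, sigma = NULL) {
  structure(list(observed = observed, fitted = fitted, refit = refit,
                 sigma = sigma),
            class = "mc_refittable")
}

#' Monte-Carlo standard deviations of fitted parameters
#'
#' Adds Gaussian noise, with SD estimated from the fit residuals (per channel
#' for curve fits), to the fitted model values; refits each replicate from
#' the point estimate; and returns the per-parameter SD over replicates.
#' Seeded and reproducible.
#'
#' @param fit a `flux_estimate`, `pet_fit` or [mc_refit_context()] object.
#' @param n number of Monte-Carlo replicates (>= 2; 300 by default, matching
#'   standard practice for flux SDs).
#' @param seed integer seed.
#' @return Named vector of per-parameter SDs. The replicate draws are
#'   attached as attribute `"replicates"`.
#' @export
monte_carlo_sd <- function(fit, n = 300, seed = 1) {
  if (!inherits(fit, "mc_refittable"))
    stop_invalid("`fit` must be a refittable fit object")
  if (!is.numeric(n) || n < 2)
    stop_invalid("`n` must be at least 2 Monte-Carlo replicates")
  obs <- fit$observed; fitted <- fit$fitted
  sigma <- fit$sigma
  if (is.null(sigma)) {
    r <- obs - fitted
    sigma <- if (is.matrix(r)) apply(r, 2, function(z) sqrt(mean(z^2)))
             else sqrt(mean(r^2))
  }
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      noise <- if (is.matrix(fitted))
        matrix(rnorm(length(fitted)), nrow(fitted)) %*% diag(sigma, ncol(fitted))
      else rnorm(length(fitted), sd = sigma)
      fit$refit(fitted + noise)
    })
  })
  reps <- do.call(rbind, lapply(draws, function(d) unlist(d)))
  sds <- apply(reps, 2, sd)
  attr(sds, "replicates") <- reps
  sds
}
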