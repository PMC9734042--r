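# Independent reference integrators used as oracles. They work directly from
# the assembled rate matrices / hand-written right-hand sides with explicit
# Euler stepping, independent of the integrators inside the package.

euler_enrichment <- function(system, input, times, dt = 0.01) {
  n <- length(system$states)
  x <- numeric(n)
  t_now <- 0
  out <- matrix(0, length(times), n)
  ti <- 1
  if (times[1] <= 0) {
    out[1, ] <- x
    ti <- 2
  }
  t_end <- max(times)
  while (t_now < t_end - 1e-12 && ti <= length(times)) {
    u <- input$fun(t_now)
    dx <- (as.numeric(system$M %*% x) + system$w * u) / system$sizes
    step <- min(dt, times[ti] - t_now)
    x <- x + step * dx
    t_now <- t_now + step
    if (abs(t_now - times[ti]) < 1e-9) {
      out[ti, ] <- x
      ti <- ti + 1
    }
  }
  out <- pmin(pmax(out, 0), 1)
  colnames(out) <- system$states
  fe <- out %*% t(system$channels)
  fe
}

euler_tac <- function(params, input, times, dt = 0.002) {
  ce <- 0; cm <- 0; t_now <- 0
  out <- numeric(length(times)); ti <- 1
  if (times[1] <= 0) { out[1] <- 0; ti <- 2 }
  while (ti <= length(times)) {
    u <- input$fun(t_now)
    dce <- params$k1 * u - (params$k2 + params$k3) * ce + params$k4 * cm
    dcm <- params$k3 * ce - params$k4 * cm
    step <- min(dt, times[ti] - t_now)
    ce <- ce + step * dce
    cm <- cm + step * dcm
    t_now <- t_now + step
    if (abs(t_now - times[ti]) < 1e-9) {
      out[ti] <- (1 - params$vb) * (ce + cm) + params$vb * input$fun(t_now)
      ti <- ti + 1
    }
  }
  out
}

# A random valid pseudo three-compartment configuration (used by the
# mass-balance and audit property tests).
random_flux_config_3c <- function() {
  v_nt_i <- runif(1, 0, 0.2)
  flux_config_3c(
    cmr_glc = runif(1, 0.2, 0.8),
    v_pdh_e = runif(1, 0, 0.5), v_pdh_i = runif(1, 0, 0.3),
    v_x_e = runif(1, 0, 2), v_x_i = runif(1, 0, 2),
    v_nt_e = v_nt_i + runif(1, 0, 0.3), v_nt_i = v_nt_i,
    v_gad = v_nt_i + runif(1, 0, 0.5),
    v_ex_g = runif(1, 0, 0.1), v_ex_i = runif(1, 0, 0.1),
    v_dil_in = runif(1, 0, 0.3), v_dil_g = runif(1, 0, 0.1),
    v_pc = runif(1, 0, 0.1), v_g = runif(1, 0.1, 0.4),
    v_x_g = runif(1, 0, 1))
}

# The same configuration constrained to satisfy the pyruvate supply bound, so
# a labeling system can actually be built from it.
random_buildable_config_3c <- function() {
  for (i in 1:100) {
    fx <- random_flux_config_3c()
    ok <- tryCatch({
      build_labeling_system("pseudo_three_compartment", fx)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(fx)
  }
  flux_config_3c()
}
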