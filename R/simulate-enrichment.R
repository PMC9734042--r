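# Forward simulation of fractional-enrichment time courses.

#' Simulate fractional-enrichment curves
#'
#' Integrates a labeling system from the all-unlabeled initial condition under
#' a blood glucose enrichment input and returns the FE time courses of the
#' NMR-observable channels (pool-size-weighted over contributing states).
#'
#' Two integrators are available: `"lsoda"` (adaptive, stiff-capable, from
#' deSolve, evaluating the input continuously) and `"expm"`, an exact
#' matrix-exponential propagator for the linear system under a
#' piecewise-linear input sampled on an internal fine grid (`dt` minutes).
#' The latter is what the fitting routines use internally, being one matrix
#' exponential plus cheap matrix-vector steps per parameter set.
#'
#' @param system a [build_labeling_system()] object.
#' @param input an `input_function` of kind `"mrs"` (blood glucose FE).
#' @param times output times in minutes (strictly increasing, >= 0).
#' @param pool_sizes optional override of the system's pool sizes (mM).
#' @param method `"lsoda"` or `"expm"`.
#' @param rtol,atol integration tolerances for `"lsoda"`.
#' @param dt internal step (minutes) for `"expm"`.
#' @param states if `TRUE`, also return the full state trajectories.
#' @return A `labeling_curve_set`: list with `times`, `fe` (matrix, time by
#'   channel, values in \[0, 1\]), `pool_sizes`, `kind`, and optionally
#'   `state_fe`.
#' @export
simulate_enrichment <- function(system, input, times, pool_sizes = NULL,
                                method = c("lsoda", "expm"),
                                rtol = 1e-8, atol = 1e-10, dt = 0.5,
                                states = FALSE) {
  method <- match.arg(method)
  times <- check_times(times)
  if (min(times) < 0) stop_invalid("`times` must be nonnegative")
  if (!inherits(system, "labeling_system"))
    stop_invalid("`system` must be a labeling_system")
  if (!is.null(pool_sizes))
    system <- build_labeling_system(system$kind, system$fluxes, pool_sizes)
  if (inherits(input, "input_function") && !identical(input$kind, "mrs"))
    stop_invalid("enrichment simulation needs an MRS (blood FE) input")

  n <- length(system$states)
  sizes <- system$sizes
  x0 <- numeric(n)
  tgrid <- if (min(times) > 0) c(0, times) else times

  if (method == "lsoda") {
    rhs <- function(t, x, parms) {
      u <- input_eval(input, t)
      list(as.numeric(system$M %*% x + system$w * u) / sizes)
    }
    sol <- deSolve::lsoda(x0, tgrid, rhs, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop_invalid("ODE integration failed near t = %.3g min",
                   max(sol[, 1], na.rm = TRUE))
    X <- sol[match(times, tgrid), -1, drop = FALSE]
  } else {
    X <- propagate_linear(system, input, times, dt)
  }
  X <- pmin(pmax(X, 0), 1)
  colnames(X) <- system$states

  fe <- X %*% t(system$channels)
  out <- list(times = times, fe = fe, pool_sizes = system$pool_sizes,
              kind = system$kind)
  if (states) out$state_fe <- X
  class(out) <- "labeling_curve_set"
  out
}

# Exact propagation of dx/dt = (M x + w u(t))/sizes for piecewise-linear u on
# a uniform grid, via one augmented matrix exponential: z = (x, u, du/dt),
# z' = G z with constant G, so z(t+dt) = expm(G dt) z(t); u and its slope are
# reset to their sampled values at every node.
propagate_linear <- function(system, input, times, dt = 0.5) {
  n <- length(system$states)
  t_end <- max(times)
  grid <- seq(0, t_end, by = dt)
  if (tail(grid, 1) < t_end) grid <- c(grid, t_end)
  u <- input_eval(input, grid)
  nseg <- length(grid) - 1L

  Ahat <- system$M / system$sizes
  bhat <- system$w / system$sizes
  G <- matrix(0, n + 2, n + 2)
  G[1:n, 1:n] <- Ahat
  G[1:n, n + 1] <- bhat
  G[n + 1, n + 2] <- 1
  E <- mat_expm(G * dt)
  En <- E[1:n, , drop = FALSE]

  X <- matrix(0, length(grid), n)
  x <- numeric(n)
  for (k in seq_len(nseg)) {
    h <- grid[k + 1] - grid[k]
    m <- (u[k + 1] - u[k]) / h
    Ek <- if (abs(h - dt) < 1e-12) En else mat_expm(G * h)[1:n, , drop = FALSE]
    x <- as.numeric(Ek %*% c(x, u[k], m))
    X[k + 1, ] <- x
  }
  # linear interpolation onto requested times (exact when times are on grid)
  out <- matrix(0, length(times), n)
  for (j in seq_len(n)) out[, j] <- approxfun(grid, X[, j])(times)
  out
}

#' @export
print.labeling_curve_set <- function(x, ...) {
  cat(sprintf("<labeling_curve_set: %s, %d times x %d channels>\n",
              x$kind, length(x$times), ncol(x$fe)))
  invisible(x)
}

#' @export
as.data.frame.labeling_curve_set <- function(x, ...) {
  data.frame(time_min = rep(x$times, ncol(x$fe)),
             channel = rep(colnames(x$fe), each = length(x$times)),
             fe = as.vector(x$fe), row.names = NULL)
}
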