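times_fit <- seq(0, 230, by = 10)

test_that("noiseless curves return the generating fluxes", {
  fx <- flux_config_3c()
  sys <- build_labeling_system("pseudo_three_compartment", fx)
  inp <- simulate_blood_input(times_fit, "mrs")
  curves <- simulate_enrichment(sys, inp, times_fit)
  fit <- fit_fluxes(curves, "pseudo_three_compartment", inp,
                    cmr_glc = fx$cmr_glc, n_starts = 3, seed = 1)
  truth <- unlist(fx[names(fit$estimates)])
  expect_true(all(abs(fit$estimates / truth - 1) < 0.05))
  expect_true(fit$converged)
})

test_that("fitting from the generating point is a fixed point", {
  fx <- flux_config_1c()
  sys <- build_labeling_system("one_compartment", fx)
  inp <- simulate_blood_input(times_fit, "mrs")
  curves <- simulate_enrichment(sys, inp, times_fit, method = "expm",
                                dt = 0.25)
  init <- unlist(fx[free_flux_names("one_compartment")])
  fit <- fit_fluxes(curves, "one_compartment", inp, cmr_glc = fx$cmr_glc,
                    init = init, n_starts = 1, seed = 1)
  expect_true(all(abs(fit$estimates / init - 1) < 1e-4))
})

test_that("the objective decreases monotonically over accepted steps", {
  fx <- flux_config_1c()
  sys <- build_labeling_system("one_compartment", fx)
  inp <- simulate_blood_input(times_fit, "mrs")
  curves <- simulate_enrichment(sys, inp, times_fit)
  set.seed(2)
  curves$fe <- pmin(pmax(curves$fe +
    matrix(rnorm(length(curves$fe), sd = 0.02), nrow(curves$fe)), 0), 1)
  fit <- fit_fluxes(curves, "one_compartment", inp, cmr_glc = fx$cmr_glc,
                    n_starts = 1, seed = 4)
  expect_true(all(diff(fit$rsstrace) <= 1e-9))
})

test_that("estimates are stable under time-grid refinement", {
  fx <- flux_config_1c()
  sys <- build_labeling_system("one_compartment", fx)
  inp <- simulate_blood_input(seq(0, 230, 5), "mrs")
  c10 <- simulate_enrichment(sys, inp, seq(0, 230, 10))
  c5 <- simulate_enrichment(sys, inp, seq(0, 230, 5))
  f10 <- fit_fluxes(c10, "one_compartment", inp, cmr_glc = fx$cmr_glc,
                    n_starts = 2, seed = 6)
  f5 <- fit_fluxes(c5, "one_compartment", inp, cmr_glc = fx$cmr_glc,
                   n_starts = 2, seed = 6)
  expect_true(all(abs(f5$estimates / f10$estimates - 1) < 0.02))
})

test_that("missing channels and invalid inputs raise errors", {
  fx <- flux_config_3c()
  sys <- build_labeling_system("pseudo_three_compartment", fx)
  inp <- simulate_blood_input(times_fit, "mrs")
  curves <- simulate_enrichment(sys, inp, times_fit)
  curves$fe <- cbind(curves$fe, bogus = curves$fe[, 1])
  expect_error(fit_fluxes(curves, "one_compartment", inp, cmr_glc = 0.45),
               "unknown")
  expect_error(fit_fluxes(curves, "pseudo_three_compartment", inp,
                          cmr_glc = 0), "cmr_glc")
})

test_that("Monte-Carlo SDs match the closed form on a linear toy model", {
  set.seed(3)
  tt <- 1:20; a <- 0.7; sig <- 0.05
  y <- a * tt + rnorm(20, sd = sig)
  ahat <- sum(tt * y) / sum(tt^2)
  ctx <- mc_refit_context(y, ahat * tt,
                          function(yn) c(a = sum(tt * yn) / sum(tt^2)))
  sds <- monte_carlo_sd(ctx, n = 300, seed = 5)
  expect_equal(as.numeric(sds), sig / sqrt(sum(tt^2)), tolerance = 0.1)
  # determinism and zero-residual degeneracy
  expect_identical(as.numeric(monte_carlo_sd(ctx, n = 300, seed = 5)),
                   as.numeric(sds))
  ctx0 <- mc_refit_context(a * tt, a * tt,
                           function(yn) c(a = sum(tt * yn) / sum(tt^2)))
  expect_lt(max(monte_carlo_sd(ctx0, n = 20, seed = 1)), 1e-8)
  expect_error(monte_carlo_sd(ctx, n = 1), "at least 2")
})

test_that("Monte-Carlo SDs of a flux fit are seeded and nonnegative", {
  fx <- flux_config_1c()
  sys <- build_labeling_system("one_compartment", fx)
  inp <- simulate_blood_input(times_fit, "mrs")
  curves <- simulate_enrichment(sys, inp, times_fit)
  set.seed(10)
  curves$fe <- pmin(pmax(curves$fe +
    matrix(rnorm(length(curves$fe), sd = 0.02), nrow(curves$fe)), 0), 1)
  fit <- fit_fluxes(curves, "one_compartment", inp, cmr_glc = fx$cmr_glc,
                    n_starts = 2, seed = 8)
  sds <- monte_carlo_sd(fit, n = 25, seed = 13)
  expect_named(sds, names(fit$estimates))
  expect_true(all(sds >= 0))
  expect_identical(as.numeric(monte_carlo_sd(fit, n = 25, seed = 13)),
                   as.numeric(sds))
})
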