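pet_grid <- c(seq(0.25, 3, by = 0.25), seq(3.5, 10, by = 0.5),
              seq(11, 50, by = 1))
pet_input <- function() {
  simulate_blood_input(
    sort(unique(c(seq(0, 5, 0.05), seq(5.25, 50, 0.25)))), "pet")
}

test_that("zero plasma input gives zero tissue activity", {
  inp <- pet_input()
  inp$fun <- function(t) rep(0, length(t))
  tac <- simulate_tac(pet_kinetic_params(), inp, pet_grid)
  expect_true(all(tac$tissue_activity == 0))
})

test_that("one-compartment equilibrium under constant input is k1/k2", {
  cp <- 100
  const_input <- list(times = seq(0, 500, 1), kind = "pet",
                      plasma_activity = rep(cp, 501),
                      fun = function(t) rep(cp, length(t)))
  class(const_input) <- "input_function"
  p <- pet_kinetic_params(k1 = 0.1, k2 = 0.5, k3 = 0, k4 = 0)
  tac <- simulate_tac(p, const_input, c(100, 400))
  expect_equal(tac$tissue_activity[2], (0.1 / 0.5) * cp, tolerance = 1e-4)
})

test_that("tissue curve matches a fine-grid explicit-Euler reference", {
  inp <- pet_input()
  p <- pet_kinetic_params(k1 = 0.1, k2 = 0.2, k3 = 0.05, k4 = 0, vb = 0)
  tac <- simulate_tac(p, inp, pet_grid)
  ref <- euler_tac(p, inp, pet_grid, dt = 0.001)
  expect_lt(max(abs(tac$tissue_activity - ref)) / max(ref), 1e-3)
})

test_that("model fitting recovers the generating rate constants", {
  inp <- pet_input()
  p <- pet_kinetic_params(k1 = 0.1, k2 = 0.2, k3 = 0.05, k4 = 0)
  tac <- simulate_tac(p, inp, pet_grid)
  fit <- fit_pet_model(tac, inp,
                       init = pet_kinetic_params(k1 = 0.05, k2 = 0.1,
                                                 k3 = 0.02, k4 = 0))
  expect_true(fit$converged)
  for (k in c("k1", "k2", "k3"))
    expect_equal(fit$params[[k]], p[[k]], tolerance = 0.01)
  expect_equal(fit$params$cmr_glc, p$cmr_glc, tolerance = 0.01)
  # fitting from the generating parameters is a fixed point
  fit0 <- fit_pet_model(tac, inp, init = p)
  for (k in c("k1", "k2", "k3"))
    expect_equal(fit0$params[[k]], p[[k]], tolerance = 1e-6)
})

test_that("an imposed group CMRglc ratio is recovered from noiseless fits", {
  inp <- pet_input()
  p_wt <- neuroflux:::pet_params_for_cmr(0.45)
  p_ko <- neuroflux:::pet_params_for_cmr(0.45 * 0.8)
  init <- pet_kinetic_params(k1 = 0.05, k2 = 0.1, k3 = 0.02, k4 = 0)
  f_wt <- fit_pet_model(simulate_tac(p_wt, inp, pet_grid), inp, init)
  f_ko <- fit_pet_model(simulate_tac(p_ko, inp, pet_grid), inp, init)
  expect_equal(f_ko$params$cmr_glc / f_wt$params$cmr_glc, 0.8,
               tolerance = 0.02)
})

test_that("Patlak slope approaches the net uptake constant for k4 = 0", {
  inp <- pet_input()
  p <- pet_kinetic_params(k1 = 0.12, k2 = 0.25, k3 = 0.06, k4 = 0)
  tac <- simulate_tac(p, inp, pet_grid)
  ki <- p$k1 * p$k3 / (p$k2 + p$k3)
  expect_equal(patlak_slope(tac, inp, t_start = 20)$slope, ki,
               tolerance = 0.02)
})

test_that("SUV follows the dose-normalized formula", {
  expect_equal(compute_suv(500, 50000, 25), 0.25)
  expect_equal(compute_suv(0, 50000, 25), 0)
  # doubling activity and dose together leaves SUV unchanged
  expect_equal(compute_suv(1000, 100000, 25), compute_suv(500, 50000, 25))
  expect_error(compute_suv(500, 0, 25), "injected_dose")
  expect_error(compute_suv(500, 100, -2), "body_weight")
})

test_that("CMRglc is invariant under joint activity rescaling", {
  inp <- pet_input()
  p <- pet_kinetic_params(k1 = 0.1, k2 = 0.2, k3 = 0.05, k4 = 0)
  tac <- simulate_tac(p, inp, pet_grid)
  init <- pet_kinetic_params(k1 = 0.05, k2 = 0.1, k3 = 0.02, k4 = 0)
  f1 <- fit_pet_model(tac, inp, init)
  inp2 <- inp
  sc <- 3.7
  inp2$fun <- function(t) sc * inp$fun(t)
  inp2$plasma_activity <- sc * inp$plasma_activity
  tac2 <- tac
  tac2$tissue_activity <- sc * tac$tissue_activity
  f2 <- fit_pet_model(tac2, inp2, init)
  expect_equal(f2$params$cmr_glc, f1$params$cmr_glc, tolerance = 1e-3)
})
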