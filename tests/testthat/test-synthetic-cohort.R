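test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_per_group = 2, seed = 31)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$animals[["wt01"]]$labeling$fe,
                   b$animals[["wt01"]]$labeling$fe)
  expect_identical(a$animals[["ko02"]]$tac$tissue_activity,
                   b$animals[["ko02"]]$tac$tissue_activity)
  c_ <- generate_cohort(cohort_config(n_per_group = 2, seed = 32))
  expect_false(identical(a$cohort$lac, c_$cohort$lac))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_per_group = 1), "n_per_group")
  expect_error(cohort_config(enrichment_noise_snr = 0), "snr")
  expect_error(cohort_config(behavior_lactate_correlation = -1.2),
               "behavior_lactate_correlation")
  expect_error(cohort_config(group_flux_effects = c(v_bogus = 2)),
               "unknown flux")
  expect_error(cohort_config(group_flux_effects = c(v_nt_e = -1)),
               "positive")
})

test_that("knockout truths carry the configured multiplicative effects", {
  cfg <- cohort_config(n_per_group = 2, seed = 3)
  syn <- generate_cohort(cfg, curves = FALSE)
  eff <- cfg$group_flux_effects
  for (nm in names(eff))
    expect_equal(syn$truth$ko[[nm]] / syn$truth$wt[[nm]], unname(eff[[nm]]),
                 tolerance = 1e-12)
})

test_that("infinite SNR reproduces the noiseless curves and noise scales with 1/SNR", {
  cfg0 <- cohort_config(n_per_group = 2, seed = 5,
                        enrichment_noise_snr = Inf)
  syn0 <- generate_cohort(cfg0)
  a <- syn0$animals[[1]]
  expect_identical(a$labeling$fe, a$labeling_clean$fe)
  cfg6 <- cohort_config(n_per_group = 2, seed = 5, enrichment_noise_snr = 6)
  syn6 <- generate_cohort(cfg6)
  b <- syn6$animals[[1]]
  resid <- b$labeling$fe - b$labeling_clean$fe
  sigma_target <- max(b$labeling_clean$fe[, "GluC4"]) / 6
  expect_gt(sd(resid), sigma_target * 0.7)
  expect_lt(sd(resid), sigma_target * 1.2)
  expect_true(all(b$labeling$fe >= 0 & b$labeling$fe <= 1))
})

test_that("null flux effects leave hippocampal lactate exchangeable between groups", {
  null_cfg <- function(seed)
    cohort_config(n_per_group = 50,
                  group_flux_effects = c(cmr_glc = 1),
                  seed = seed)
  pvals <- vapply(1:100, function(s) {
    syn <- generate_cohort(null_cfg(s), curves = FALSE)
    t.test(lac ~ genotype, data = syn$cohort)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("the configured behavior-lactate correlation is recovered at n = 200", {
  syn <- generate_cohort(cohort_config(n_per_group = 100, seed = 17),
                         curves = FALSE)
  z <- composite_zscore(syn$cohort)
  r <- cor(syn$cohort$lac, z$z_composite)
  expect_gt(r, -0.50)
  expect_lt(r, -0.20)
})

test_that("behavior stays within session limits and markers separate genotypes", {
  syn <- generate_cohort(cohort_config(n_per_group = 40, seed = 23),
                         curves = FALSE)
  tab <- syn$cohort
  expect_true(all(tab$immobility_fst >= 0 & tab$immobility_fst <= 300))
  expect_true(all(tab$immobility_tst >= 0 & tab$immobility_tst <= 300))
  expect_true(all(tab$immobility_osfst >= 0 & tab$immobility_osfst <= 900))
  expect_true(all(tab$lac >= 0))
  expect_gt(mean(tab$tcho[tab$genotype == "KO"]),
            mean(tab$tcho[tab$genotype == "WT"]))
})
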