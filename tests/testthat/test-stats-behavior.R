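make_cohort_df <- function(fst, tst) {
  data.frame(id = seq_along(fst), immobility_fst = fst, immobility_tst = tst)
}

test_that("z-scores use the sample SD over the whole scope", {
  df <- make_cohort_df(c(1, 3), c(5, 5.5))
  z <- composite_zscore(df)
  expect_equal(z$z_fst, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(mean(z$z_tst), 0, tolerance = 1e-12)
  expect_equal(sd(z$z_tst), 1, tolerance = 1e-12)
  # identical columns: composite equals either z column
  df2 <- make_cohort_df(c(2, 5, 9, 4), c(2, 5, 9, 4))
  z2 <- composite_zscore(df2)
  expect_equal(z2$z_composite, z2$z_fst)
})

test_that("z-scores are invariant to affine transforms of the raw scores", {
  set.seed(4)
  fst <- rnorm(30, 100, 20); tst <- rnorm(30, 150, 30)
  z1 <- composite_zscore(make_cohort_df(fst, tst))
  z2 <- composite_zscore(make_cohort_df(3 * fst + 17, tst))
  expect_equal(z1$z_fst, z2$z_fst, tolerance = 1e-12)
  expect_error(composite_zscore(make_cohort_df(rep(1, 5), rnorm(5))),
               "variance")
})

test_that("high/low classification splits at the scope mean", {
  expect_equal(classify_depressive(c(0.5, -0.01, 0, 2)),
               c("high", "low", "low", "high"))
  set.seed(8)
  df <- make_cohort_df(rnorm(40, 100, 20), rnorm(40, 150, 30))
  lab <- classify_depressive(composite_zscore(df))
  expect_equal(length(lab), 40)
  expect_setequal(unique(lab), c("high", "low"))
})

test_that("permutation test is calibrated and reproducible", {
  set.seed(15)
  a <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("v", 1:5)))
  # duplicated groups: observed statistic is in the bulk of the null
  dup <- permutation_flux_test(a, a, n_perm = 500, seed = 2)
  expect_gt(dup$global_p, 0.9)
  r1 <- permutation_flux_test(a, a + 0.1, n_perm = 500, seed = 9)
  r2 <- permutation_flux_test(a, a + 0.1, n_perm = 500, seed = 9)
  expect_identical(r1$global_p, r2$global_p)
  expect_identical(r1$per_flux$p, r2$per_flux$p)
  expect_equal(nrow(r1$per_flux), 5)
  # a strong shift in one flux is detected
  b <- a; b[, 1] <- b[, 1] + 5
  shift <- permutation_flux_test(a, b, n_perm = 999, seed = 3)
  expect_lt(shift$global_p, 0.01)
  expect_lt(shift$per_flux$p[1], 0.001)
  small <- permutation_flux_test(a, b, n_perm = 50, seed = 1)
  expect_match(small$warning, "permutations")
  expect_error(permutation_flux_test(a[1, , drop = FALSE], b), "2 animals")
})

test_that("permutation p-values are valid under the null", {
  set.seed(99)
  p <- replicate(120, {
    x <- matrix(rnorm(24), 6, 4)
    y <- matrix(rnorm(24), 6, 4)
    permutation_flux_test(x, y, n_perm = 200,
                          seed = sample.int(1e6, 1))$global_p
  })
  expect_gte(mean(p <= 0.05), 0)
  expect_lte(mean(p <= 0.05), 0.12)
  # super-uniformity at several thresholds
  for (alpha in c(0.1, 0.25, 0.5))
    expect_lte(mean(p <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 120))
})

test_that("ROC analysis reproduces separability and handles combination", {
  # perfectly separated scores
  perfect <- roc_analysis(c(1:5, 11:15), rep(c("WT", "KO"), each = 5),
                          positive = "KO", n_boot = 50, seed = 1)
  expect_equal(perfect$auc, 1)
  expect_true(perfect$ci_low <= perfect$auc &&
                perfect$auc <= perfect$ci_high)
  # labels independent of scores: AUC near 1/2
  set.seed(12)
  x <- rnorm(200); lab <- sample(rep(c("a", "b"), 100))
  null_auc <- roc_analysis(x, lab, positive = "b", n_boot = 50,
                           direction = ">")$auc
  expect_gt(null_auc, 0.40)
  expect_lt(null_auc, 0.60)
  expect_error(roc_analysis(x, rep("a", 200)), "two classes")
})

test_that("averaged-z combination does not lose separability on exchangeable markers", {
  set.seed(77)
  n <- 400; dp <- 1.0
  lab <- rep(c("neg", "pos"), each = n / 2)
  shift <- ifelse(lab == "pos", dp, 0)
  m1 <- rnorm(n) + shift; m2 <- rnorm(n) + shift
  a1 <- roc_analysis(m1, lab, positive = "pos", n_boot = 50)$auc
  a2 <- roc_analysis(m2, lab, positive = "pos", n_boot = 50)$auc
  comb <- roc_analysis(cbind(m1, m2), lab, positive = "pos",
                       combine = "averaged_z", n_boot = 50)$auc
  expect_gte(comb, max(a1, a2) - 0.02)
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  x <- rnorm(120); lab <- rep(c("n", "p"), each = 60)
  x[lab == "p"] <- x[lab == "p"] + 0.8
  ours <- roc_analysis(x, lab, positive = "p", n_boot = 50,
                       direction = ">")$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(lab, x, levels = c("n", "p"),
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("correlation panel reports uncorrected Pearson r", {
  set.seed(6)
  df <- data.frame(x1 = rnorm(50))
  df$y1 <- df$x1
  df$y2 <- rnorm(50)
  df$y3 <- c(rnorm(2), rep(NA, 48))
  res <- correlation_panel(df, "x1", c("y1", "y2", "y3"))
  expect_equal(res$r[res$y == "y1"], 1, tolerance = 1e-12)
  expect_lt(res$p[res$y == "y1"], 1e-10)
  expect_true(is.na(res$r[res$y == "y3"]))
  expect_match(attr(res, "p_adjustment"), "uncorrected")
  ct <- cor.test(df$x1, df$y2)
  expect_equal(res$r[res$y == "y2"], unname(ct$estimate))
  expect_equal(res$p[res$y == "y2"], ct$p.value)
})
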