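# Composite behavioral z-scores, permutation flux comparison, correlation
# panels, and ROC marker assessment.

#' Composite behavioral z-score
#'
#' Standardizes each behavioral test (sample SD, computed over the stated
#' scope) and averages the per-test z-scores into a composite despair score.
#' With `scope = "all"` the overall mean and SD across all animals and
#' timepoints are used (the convention for a longitudinal FST + TST design);
#' `scope = "per_test"` standardizes each test column on its own, which is
#' the scope to use when different assays must be made comparable.
#'
#' @param cohort data.frame with one row per animal x timepoint.
#' @param tests character vector of immobility columns (default
#'   `c("immobility_fst", "immobility_tst")`).
#' @param scope `"all"` (single mean/SD per test over every row) or
#'   `"per_test"` (identical here; the distinction matters when timepoint
#'   subsets would otherwise be standardized separately). Both use sample SD.
#' @return data.frame with the per-test z columns (`z_<test>`) and
#'   `z_composite`, row-aligned with `cohort`.
#' @export
composite_zscore <- function(cohort,
                             tests = c("immobility_fst", "immobility_tst"),
                             scope = c("all", "per_test")) {
  scope <- match.arg(scope)
  missing <- setdiff(tests, names(cohort))
  if (length(missing))
    stop_invalid("cohort lacks behavioral columns: %s",
                 paste(missing, collapse = ", "))
  zs <- lapply(tests, function(tn) {
    x <- cohort[[tn]]
    if (sum(is.finite(x)) < 2 || sd(x, na.rm = TRUE) == 0)
      stop_invalid("test '%s' has no variance; z-score undefined", tn)
    (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  })
  names(zs) <- paste0("z_", sub("^immobility_", "", tests))
  out <- as.data.frame(zs)
  out$z_composite <- rowMeans(out)
  out
}

#' Classify animals into high/low depressive-like behavior
#'
#' Splits at the scope mean: composite z above 0 is `"high"`, at or below 0
#' is `"low"` (ties go to low).
#'
#' @param z a data.frame from [composite_zscore()] or a numeric vector of
#'   composite z-scores.
#' @return Character vector of `"high"` / `"low"` labels.
#' @export
classify_depressive <- function(z) {
  zc <- if (is.data.frame(z)) z$z_composite else z
  if (is.null(zc)) stop_invalid("no composite z-score found")
  ifelse(zc > 0, "high", "low")
}

#' Omnibus permutation test for group flux differences
#'
#' Compares two groups of per-animal flux vectors with a global statistic,
#' the sum over fluxes of squared two-sample t statistics, whose null
#' distribution is obtained by randomly permuting group labels. The global
#' p-value uses the add-one rule `(1 + #{perm >= observed}) / (n_perm + 1)`.
#' Per-flux two-tailed Student t tests are reported alongside (uncorrected).
#'
#' @param group_a,group_b matrices or data.frames, one row per animal, one
#'   column per flux (>= 2 animals each, same columns).
#' @param n_perm number of random permutations (default 2000; below 100 a
#'   warning is attached to the result).
#' @param seed integer seed.
#' @return List with `global_stat`, `global_p`, `per_flux` (data.frame of t
#'   and p per flux), `n_perm`, and `warning` (NULL or text).
#' @export
permutation_flux_test <- function(group_a, group_b, n_perm = 2000, seed = 1) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  if (nrow(A) < 2 || nrow(B) < 2)
    stop_invalid("each group needs at least 2 animals")
  if (ncol(A) != ncol(B))
    stop_invalid("groups must share the same flux columns")
  warn <- NULL
  if (n_perm < 100)
    warn <- sprintf("only %d permutations: p-value resolution is poor", n_perm)

  X <- rbind(A, B)
  na <- nrow(A); n <- nrow(X)
  tstat_cols <- function(ia) {
    xa <- X[ia, , drop = FALSE]; xb <- X[-ia, , drop = FALSE]
    ma <- colMeans(xa); mb <- colMeans(xb)
    va <- apply(xa, 2, stats::var); vb <- apply(xb, 2, stats::var)
    se <- sqrt(va / nrow(xa) + vb / nrow(xb))
    se[se == 0] <- NA
    (ma - mb) / se
  }
  t_obs <- tstat_cols(seq_len(na))
  stat_obs <- sum(t_obs^2, na.rm = TRUE)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ia <- sample.int(n, na)
      sum(tstat_cols(ia)^2, na.rm = TRUE)
    }, numeric(1))
  })
  global_p <- (1 + sum(perm_stats >= stat_obs)) / (n_perm + 1)

  per_flux <- do.call(rbind, lapply(seq_len(ncol(X)), function(j) {
    tt <- tryCatch(t.test(A[, j], B[, j]), error = function(e) NULL)
    data.frame(flux = colnames(X)[j] %||% paste0("flux", j),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value)
  }))
  list(global_stat = stat_obs, global_p = global_p, per_flux = per_flux,
       n_perm = n_perm, warning = warn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROC analysis of neuroimaging markers
#'
#' Empirical ROC curve over all score thresholds with the area computed by
#' the trapezoidal rule (ties handled, equal to the Mann-Whitney statistic).
#' With `combine = "averaged_z"`, multi-column scores are z-scored per marker
#' (whole-sample mean/SD) and averaged before the sweep. The confidence
#' interval is a seeded percentile bootstrap over animals.
#'
#' @param scores numeric vector, or matrix/data.frame of marker columns when
#'   combining.
#' @param labels two-class labels; `positive` names the positive class.
#' @param positive the positive-class label (default the alphabetically
#'   later class, so a `"WT"`/`"KO"` factor yields KO-positive... explicitly
#'   pass it in real analyses).
#' @param n_boot bootstrap resamples for the CI (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param combine `"single"` or `"averaged_z"`.
#' @param direction `">"` if larger scores indicate the positive class,
#'   `"<"` to flip, `"auto"` to pick the side with AUC >= 0.5.
#' @return A `roc_result`: `auc`, `ci_low`, `ci_high`, `thresholds` with
#'   sensitivity/specificity pairs, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, positive = NULL, n_boot = 2000,
                         seed = 1, combine = c("single", "averaged_z"),
                         direction = c("auto", ">", "<")) {
  combine <- match.arg(combine)
  direction <- match.arg(direction)
  if (combine == "averaged_z") {
    S <- as.matrix(scores)
    Z <- scale(S)  # whole-sample mean/SD per marker
    x <- rowMeans(Z)
  } else {
    x <- as.numeric(scores)
  }
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2)
    stop_invalid("`labels` must contain exactly two classes (got %d)",
                 length(cls))
  if (is.null(positive)) positive <- cls[2]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop_invalid("both classes must be present")

  auc_raw <- function(x, pos) {
    # Mann-Whitney with tie correction == trapezoidal area
    r <- rank(x)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }
  if (direction == "auto")
    direction <- if (auc_raw(x, pos) >= 0.5) ">" else "<"
  xx <- if (direction == ">") x else -x
  auc <- auc_raw(xx, pos)

  thr <- sort(unique(xx), decreasing = TRUE)
  sweep <- do.call(rbind, lapply(c(Inf, thr, -Inf), function(t0) {
    pred <- xx >= t0
    data.frame(threshold = t0,
               sensitivity = sum(pred & pos) / n_pos,
               specificity = sum(!pred & !pos) / n_neg)
  }))

  ci <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(xx), replace = TRUE)
      p2 <- pos[idx]
      if (!any(p2) || all(p2)) return(NA_real_)
      auc_raw(xx[idx], p2)
    }, numeric(1))
    quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  })

  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 thresholds = sweep, n_pos = n_pos, n_neg = n_neg,
                 positive = positive, direction = direction,
                 combine = combine, n_boot = n_boot),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg>\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Pairwise Pearson correlation panel
#'
#' Pearson r with two-tailed p for every (x, y) variable pair; p-values are
#' reported uncorrected for multiple comparisons (and flagged as such).
#' Pairs with fewer than 3 complete observations yield an NA entry rather
#' than an error.
#'
#' @param cohort data.frame of per-animal measurements.
#' @param x_vars,y_vars column names to correlate.
#' @return data.frame with `x`, `y`, `r`, `p`, `n`; attribute
#'   `"p_adjustment"` is `"none (uncorrected)"`.
#' @export
correlation_panel <- function(cohort, x_vars, y_vars) {
  bad <- setdiff(c(x_vars, y_vars), names(cohort))
  if (length(bad))
    stop_invalid("unknown columns: %s", paste(bad, collapse = ", "))
  grid <- expand.grid(x = x_vars, y = y_vars, stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    xv <- cohort[[grid$x[i]]]; yv <- cohort[[grid$y[i]]]
    ok <- is.finite(xv) & is.finite(yv)
    if (sum(ok) < 3)
      return(data.frame(x = grid$x[i], y = grid$y[i], r = NA_real_,
                        p = NA_real_, n = sum(ok)))
    ct <- cor.test(xv[ok], yv[ok], method = "pearson")
    data.frame(x = grid$x[i], y = grid$y[i], r = unname(ct$estimate),
               p = ct$p.value, n = sum(ok))
  }))
  attr(res, "p_adjustment") <- "none (uncorrected)"
  res
}
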