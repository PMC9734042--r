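# Run configuration, file I/O and the end-to-end seeded driver.

#' Assemble a run configuration
#'
#' Bundles every knob of the pipeline into one validated object: the cohort
#' generation settings, PET fitting options, flux-model settings and the
#' statistics settings. All randomness downstream derives from `seed`.
#'
#' @param seed integer master seed.
#' @param cohort named list of [cohort_config()] arguments (without `seed`).
#' @param pet list: `fix_k4`, `lumped_constant`, `plasma_glucose`, `init`
#'   (starting rate constants).
#' @param flux list: `kind`, `fixed` (fixed-flux overrides), `n_starts`,
#'   `monte_carlo` (replicates per representative fit; 0 disables).
#' @param stats list: `n_perm` (permutations), `n_boot` (bootstrap
#'   resamples).
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1,
                       cohort = list(n_per_group = 3),
                       pet = list(fix_k4 = TRUE),
                       flux = list(kind = "pseudo_three_compartment",
                                   n_starts = 2, monte_carlo = 0),
                       stats = list(n_perm = 2000, n_boot = 1000)) {
  cohort$seed <- NULL
  cc <- do.call(cohort_config, c(cohort, list(seed = seed)))
  flux$kind <- match.arg(flux$kind %||% "pseudo_three_compartment",
                         c("pseudo_three_compartment", "one_compartment"))
  flux$n_starts <- flux$n_starts %||% 2
  flux$monte_carlo <- flux$monte_carlo %||% 0
  pet$fix_k4 <- pet$fix_k4 %||% TRUE
  stats$n_perm <- stats$n_perm %||% 2000
  stats$n_boot <- stats$n_boot %||% 1000
  structure(list(seed = as.integer(seed), cohort = cc, pet = pet,
                 flux = flux, stats = stats),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with top-level keys `seed`, `cohort`, `pet`,
#'   `flux`, `stats` (all optional except `seed`).
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file '%s' does not exist", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop_invalid("config must provide a `seed`")
  for (nm in names(y$cohort))
    if (nm == "group_flux_effects") y$cohort[[nm]] <- unlist(y$cohort[[nm]])
  run_config(seed = y$seed,
             cohort = y$cohort %||% list(n_per_group = 3),
             pet = y$pet %||% list(fix_k4 = TRUE),
             flux = y$flux %||% list(kind = "pseudo_three_compartment",
                                     n_starts = 2, monte_carlo = 0),
             stats = y$stats %||% list(n_perm = 2000, n_boot = 1000))
}

#' Write tidy curve CSVs for a synthetic cohort
#'
#' One row per (animal, time, channel): enrichment curves, tissue activity
#' and blood inputs, in plain CSV.
#'
#' @param cohort a `synthetic_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(cohort, path) {
  rows <- lapply(cohort$animals, function(a) {
    lab <- as.data.frame(a$labeling)
    rbind(data.frame(id = a$id, time_min = lab$time_min,
                     channel = lab$channel, value = lab$fe),
          data.frame(id = a$id, time_min = a$tac$times,
                     channel = "tissue_activity",
                     value = a$tac$tissue_activity),
          data.frame(id = a$id, time_min = a$input_mrs$times,
                     channel = "blood_fe", value = a$input_mrs$blood_fe))
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# Stable fingerprint of a configuration (md5 of its serialized YAML).
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(cfg), unclass, how = "replace")
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Chains cohort generation, per-animal PET fitting, per-animal flux
#' fitting, mass-balance derivation and allostatic loads, the omnibus
#' permutation comparison, behavioral z-scores with high/low classification,
#' the correlation panel and the ROC marker assessment into one seeded run.
#' Outputs (cohort CSV, tidy curves CSV, JSON report) are written under
#' `out_dir` when given; the report is returned either way and is identical
#' for identical configurations and seeds.
#'
#' @param cfg a [run_config()] (or a path to a YAML config).
#' @param out_dir optional output directory (created if missing).
#' @return The report list (invisibly carries the output paths when
#'   written).
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) stop_invalid("`cfg` must be a run_config")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_invalid("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)))
  }

  syn <- stage("simulate", generate_cohort(cfg$cohort))
  tab <- syn$cohort

  pet_fits <- stage("fit-pet", lapply(syn$animals, function(a) {
    init <- pet_kinetic_params(
      k1 = 0.1, k2 = 0.2, k3 = 0.03, k4 = 0,
      lumped_constant = cfg$pet$lumped_constant %||% 0.6,
      plasma_glucose = cfg$pet$plasma_glucose %||% 7.7)
    fit_pet_model(a$tac, a$input_pet, init, fix_k4 = cfg$pet$fix_k4)
  }))
  cmr_fit <- vapply(pet_fits, function(f) f$params$cmr_glc, numeric(1))

  flux_fits <- stage("fit-flux", {
    ids <- names(syn$animals)
    fits <- lapply(seq_along(ids), function(i) {
      a <- syn$animals[[i]]
      fit_fluxes(a$labeling, cfg$flux$kind, a$input_mrs,
                 cmr_glc = cmr_fit[[i]], fixed = cfg$flux$fixed %||% list(),
                 n_starts = cfg$flux$n_starts,
                 seed = cfg$seed + 1000L + i)
    })
    names(fits) <- ids
    fits
  })
  flux_mat <- do.call(rbind, lapply(flux_fits, function(f) f$estimates))

  mc <- NULL
  if ((cfg$flux$monte_carlo %||% 0) >= 2) {
    idx <- c(which(tab$genotype == "WT")[1], which(tab$genotype == "KO")[1])
    mc <- stage("monte-carlo", lapply(flux_fits[idx], monte_carlo_sd,
                                      n = cfg$flux$monte_carlo,
                                      seed = cfg$seed + 77L))
  }

  balances <- stage("balances", {
    grp_cfg <- function(g) {
      est <- colMeans(flux_mat[tab$genotype == g, , drop = FALSE])
      est["v_gad"] <- max(est[["v_gad"]], est[["v_nt_i"]])
      do.call(flux_config_3c,
              c(as.list(est), list(cmr_glc = mean(cmr_fit[tab$genotype == g]))))
    }
    wt_fx <- grp_cfg("WT"); ko_fx <- grp_cfg("KO")
    list(wt = derive_balances(wt_fx, lac_brain = mean(tab$lac[tab$genotype == "WT"]),
                              lac_blood = 7.7),
         ko = derive_balances(ko_fx, lac_brain = mean(tab$lac[tab$genotype == "KO"]),
                              lac_blood = 7.9),
         loads = compute_allostatic_loads(ko_fx, wt_fx))
  })

  markers <- stage("markers", {
    z <- composite_zscore(tab)
    labels_hl <- classify_depressive(z)
    perm <- permutation_flux_test(flux_mat[tab$genotype == "KO", , drop = FALSE],
                                  flux_mat[tab$genotype == "WT", , drop = FALSE],
                                  n_perm = cfg$stats$n_perm,
                                  seed = cfg$seed + 7L)
    roc_geno <- roc_analysis(tab[, c("tcho", "pfc_volume")], tab$genotype,
                             positive = "KO", combine = "averaged_z",
                             n_boot = cfg$stats$n_boot, seed = cfg$seed + 8L)
    roc_behav <- tryCatch(
      roc_analysis(tab[, c("lac", "pcr")], labels_hl, positive = "high",
                   combine = "averaged_z", n_boot = cfg$stats$n_boot,
                   seed = cfg$seed + 9L),
      error = function(e) NULL)
    corr <- correlation_panel(cbind(tab, z_composite = z$z_composite),
                              x_vars = c("lac", "pcr"),
                              y_vars = "z_composite")
    list(z = z, high_low = labels_hl, permutation = perm,
         roc_genotype = roc_geno, roc_high_low = roc_behav,
         correlations = corr)
  })

  report <- list(
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    n_animals = nrow(tab),
    cmr_glc = list(wt = mean(cmr_fit[tab$genotype == "WT"]),
                   ko = mean(cmr_fit[tab$genotype == "KO"])),
    flux_group_means = list(
      wt = as.list(colMeans(flux_mat[tab$genotype == "WT", , drop = FALSE])),
      ko = as.list(colMeans(flux_mat[tab$genotype == "KO", , drop = FALSE]))),
    monte_carlo_sd = if (!is.null(mc)) lapply(mc, as.list) else NULL,
    derived = list(wt = unclass(balances$wt), ko = unclass(balances$ko)),
    allostatic_loads = balances$loads,
    permutation = list(global_p = markers$permutation$global_p,
                       global_stat = markers$permutation$global_stat),
    roc_genotype_auc = markers$roc_genotype$auc,
    roc_high_low_auc = if (!is.null(markers$roc_high_low))
      markers$roc_high_low$auc else NA,
    behavior_lac_r = markers$correlations$r[markers$correlations$x == "lac"])

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cbind(tab, markers$z, high_low = markers$high_low),
              file.path(out_dir, "cohort.csv"), row.names = FALSE)
    write_curves_csv(syn, file.path(out_dir, "curves.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(list(report = report, cohort = tab, flux_fits = flux_fits,
                 pet_fits = pet_fits, balances = balances,
                 markers = markers, synthetic = syn))
}
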