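# Seeded synthetic cohorts emulating a knockout vs wild-type neuroenergetics
# study: per-animal blood inputs, PET time-activity curves, 13C enrichment
# curves, metabolite profiles, behavior and marker panels.

#' Cohort generation configuration
#'
#' Defines the study conditions of a synthetic two-genotype cohort. The
#' defaults emulate the reference design this package models: a ~230-min
#' \[U-13C6\]glucose infusion sampled every 10 min, a 50-min dynamic FDG-PET
#' scan, edited-spectra SNR around 6, a behavior-lactate correlation of
#' -0.35, and knockout flux effects of the reported magnitudes (20% lower
#' glucose consumption, -36% excitatory pyruvate dehydrogenase, about
#' twofold higher glutamatergic and about sixfold higher GABAergic
#' neurotransmission cycling, driven mainly by a tenfold larger GABA-pool
#' exchange).
#'
#' @param n_per_group animals per genotype (>= 2).
#' @param group_flux_effects named multiplicative factors applied to the
#'   wild-type ground-truth fluxes to form the knockout truth; names must be
#'   fields of [flux_config_3c()] (including `cmr_glc`).
#' @param enrichment_noise_snr signal-to-noise of the edited enrichment
#'   curves; noise SD is the GluC4 plateau FE divided by this (> 0; may be
#'   `Inf` for noiseless curves).
#' @param behavior_lactate_correlation target Pearson r between hippocampal
#'   lactate and the composite behavioral z-score, in \[-1, 1\].
#' @param marker_separation_dprime Gaussian separation (d') of each
#'   genotype-discriminating marker (prefrontal tCho and volume).
#' @param marker_correlation correlation between the two markers.
#' @param flux_cv between-animal coefficient of variation of the true fluxes
#'   (lognormal; default 0.10).
#' @param seed integer seed; identical configurations produce identical
#'   cohorts.
#' @param time_grid_mrs,time_grid_pet sampling grids in minutes.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_per_group = 8,
                          group_flux_effects = c(cmr_glc = 0.80,
                                                 v_pdh_e = 0.64,
                                                 v_pdh_i = 1.10,
                                                 v_nt_e = 2.0,
                                                 v_nt_i = 5.7,
                                                 v_ex_i = 10.0,
                                                 v_gad = 0.94),
                          enrichment_noise_snr = 6,
                          behavior_lactate_correlation = -0.35,
                          marker_separation_dprime = 1.30,
                          marker_correlation = 0.31,
                          flux_cv = 0.10,
                          seed = 1,
                          time_grid_mrs = seq(0, 230, by = 10),
                          time_grid_pet = c(seq(0.25, 3, by = 0.25),
                                            seq(3.5, 10, by = 0.5),
                                            seq(11, 50, by = 1))) {
  check_number(n_per_group, "n_per_group", 2)
  if (!is.numeric(enrichment_noise_snr) || enrichment_noise_snr <= 0)
    stop_invalid("`enrichment_noise_snr` must be > 0")
  check_number(behavior_lactate_correlation,
               "behavior_lactate_correlation", -1, 1)
  check_number(marker_separation_dprime, "marker_separation_dprime", 0)
  check_number(marker_correlation, "marker_correlation", -1, 1)
  check_number(flux_cv, "flux_cv", 0)
  known <- names(formals(flux_config_3c))
  bad <- setdiff(names(group_flux_effects), known)
  if (length(bad))
    stop_invalid("unknown flux name(s) in group_flux_effects: %s",
                 paste(bad, collapse = ", "))
  if (any(group_flux_effects <= 0))
    stop_invalid("group_flux_effects must be positive factors")
  check_times(time_grid_mrs, "time_grid_mrs")
  check_times(time_grid_pet, "time_grid_pet")
  structure(list(n_per_group = as.integer(n_per_group),
                 group_flux_effects = group_flux_effects,
                 enrichment_noise_snr = enrichment_noise_snr,
                 behavior_lactate_correlation = behavior_lactate_correlation,
                 marker_separation_dprime = marker_separation_dprime,
                 marker_correlation = marker_correlation,
                 flux_cv = flux_cv, seed = as.integer(seed),
                 time_grid_mrs = time_grid_mrs,
                 time_grid_pet = time_grid_pet),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config: %d/group, SNR %.3g, seed %d>\n",
              x$n_per_group, x$enrichment_noise_snr, x$seed))
  invisible(x)
}

# Wild-type ground-truth fluxes of the synthetic study.
wt_truth_fluxes <- function() flux_config_3c()

# Cheap pyruvate-supply feasibility check, equivalent to the constraint the
# system builder enforces.
feasible_3c <- function(fx) {
  demand <- fx$v_pdh_e + (fx$v_gad - fx$v_nt_i) + fx$v_pdh_i +
    (fx$v_g - fx$v_dil_g) + fx$v_pc
  demand <= 2 * fx$cmr_glc + fx$v_dil_in
}

apply_flux_effects <- function(wt, effects) {
  args <- unclass(wt)
  args$v_eff <- NULL
  for (nm in names(effects)) args[[nm]] <- args[[nm]] * effects[[nm]]
  do.call(flux_config_3c, args)
}

# PET rate constants consistent with a target CMRglc: k1, k2 fixed at
# physiological values and k3 solved from Ki = cmr * LC / plasma_glucose.
pet_params_for_cmr <- function(cmr_glc, plasma_glucose = 7.7,
                               lumped_constant = 0.6, k1 = 0.15, k2 = 0.30) {
  ki <- cmr_glc * lumped_constant / plasma_glucose
  if (ki >= k1) stop_invalid("target CMRglc unreachable with k1 = %g", k1)
  k3 <- k2 * ki / (k1 - ki)
  pet_kinetic_params(k1 = k1, k2 = k2, k3 = k3, k4 = 0,
                     lumped_constant = lumped_constant,
                     plasma_glucose = plasma_glucose)
}

#' Generate a synthetic cohort
#'
#' Draws a seeded two-genotype cohort under a [cohort_config()]: per-animal
#' ground-truth fluxes (wild-type truth times the knockout effects, with
#' lognormal between-animal scatter), blood input functions, PET
#' time-activity curves, noisy enrichment curves, hippocampal metabolite
#' concentrations, behavioral immobility scores sharing a latent factor with
#' lactate (so that the lactate-behavior Pearson r matches the configured
#' value in expectation), and a correlated two-marker genotype panel.
#'
#' @param cfg a [cohort_config()].
#' @param curves if `FALSE`, only the cohort table and per-animal ground
#'   truths are generated (no ODE simulation); useful for behavioral or
#'   marker statistics at large n.
#' @return A `synthetic_cohort`: `$cohort` (one row per animal), `$animals`
#'   (named list with per-animal `fluxes`, `pet_params`, `input_mrs`,
#'   `input_pet`, `tac`, `labeling` and noiseless `labeling_clean`),
#'   `$truth` (`wt`/`ko` central flux configurations) and `$config`.
#' @export
generate_cohort <- function(cfg, curves = TRUE) {
  if (!inherits(cfg, "cohort_config"))
    stop_invalid("`cfg` must be a cohort_config")
  wt <- wt_truth_fluxes()
  ko <- apply_flux_effects(wt, cfg$group_flux_effects)
  n <- cfg$n_per_group
  genotype <- rep(c("WT", "KO"), each = n)
  ids <- sprintf("%s%02d", tolower(genotype), c(seq_len(n), seq_len(n)))

  with_seed(cfg$seed, {
    r <- cfg$behavior_lactate_correlation
    # hippocampal lactate tracks glycolytic capacity: mean scales with the
    # squared group CMRglc factor (2.5 mM at the wild-type CMRglc of 0.25,
    # 1.6 mM when glucose consumption is 20% lower); the pooled z-score then
    # drives the shared behavior factor
    cmr_factor <- ifelse(genotype == "KO", ko$cmr_glc / wt$cmr_glc, 1)
    lac_group_mu <- 2.5 * cmr_factor^2
    lac_sd <- 0.45
    lac <- pmax(rnorm(2 * n, lac_group_mu, lac_sd), 0.05)
    pool_mu <- mean(unique(lac_group_mu))
    pool_sd <- sqrt(lac_sd^2 +
                      if (length(unique(lac_group_mu)) > 1)
                        stats::var(unique(lac_group_mu)) / 2 else 0)
    z_lac <- (lac - pool_mu) / pool_sd
    behav <- r * z_lac + sqrt(1 - r^2) * rnorm(2 * n)
    split_noise <- rnorm(2 * n, sd = 0.6)
    z_fst <- (behav + split_noise) / sqrt(1 + 0.6^2)
    z_tst <- (behav - split_noise) / sqrt(1 + 0.6^2)
    immobility_fst <- pmin(pmax(120 + 35 * z_fst, 0), 300)
    immobility_tst <- pmin(pmax(140 + 35 * z_tst, 0), 300)
    immobility_osfst <- pmin(pmax(400 + 90 * behav + rnorm(2 * n, sd = 40),
                                  0), 900)

    # genotype marker panel (prefrontal tCho, mM-scale, and volume, a.u.)
    dp <- cfg$marker_separation_dprime
    rho <- cfg$marker_correlation
    e1 <- rnorm(2 * n)
    e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(2 * n)
    is_ko <- as.numeric(genotype == "KO")
    tcho <- 1.20 + 0.15 * (e1 + dp * is_ko)
    pfc_volume <- 3.0 + 0.30 * (e2 + dp * is_ko)

    pcr <- pmax(rnorm(2 * n, 3.0 * cmr_factor^0.7, 0.35), 0.1)
    cr <- pmax(rnorm(2 * n, 3.6, 0.3), 0.5)
    glc_brain <- pmax(rnorm(2 * n, 1.5, 0.3), 0.1)
    body_weight <- pmax(rnorm(2 * n, ifelse(genotype == "KO", 32, 28), 2), 15)

    animals <- vector("list", 2 * n)
    names(animals) <- ids
    for (i in seq_len(2 * n)) {
      base <- if (genotype[i] == "KO") ko else wt
      jitter_nat <- function(v) v * rlnorm(1, -cfg$flux_cv^2 / 2, cfg$flux_cv)
      fx <- base
      for (try_i in 1:10) {
        args <- unclass(base); args$v_eff <- NULL
        for (nm in c("cmr_glc", free_flux_names("pseudo_three_compartment")))
          args[[nm]] <- jitter_nat(args[[nm]])
        cand <- tryCatch({
          fxc <- do.call(flux_config_3c, args)
          if (!feasible_3c(fxc)) NULL else fxc
        }, error = function(e) NULL)
        if (!is.null(cand)) { fx <- cand; break }
      }
      petp <- pet_params_for_cmr(fx$cmr_glc)
      animals[[i]] <- list(id = ids[i], genotype = genotype[i],
                           fluxes = fx, pet_params = petp)

      if (curves) {
        input_mrs <- simulate_blood_input(cfg$time_grid_mrs, "mrs")
        input_pet <- simulate_blood_input(
          sort(unique(c(seq(0, 5, 0.05),
                        seq(5.25, max(cfg$time_grid_pet), 0.25)))),
          "pet")
        tac <- simulate_tac(petp, input_pet, cfg$time_grid_pet)
        tac$tissue_activity <- pmax(
          tac$tissue_activity + rnorm(length(tac$times),
                                      sd = max(tac$tissue_activity) / 100), 0)

        sys <- build_labeling_system("pseudo_three_compartment", fx)
        clean <- simulate_enrichment(sys, input_mrs, cfg$time_grid_mrs)
        noisy <- clean
        if (is.finite(cfg$enrichment_noise_snr)) {
          sigma <- max(clean$fe[, "GluC4"]) / cfg$enrichment_noise_snr
          noisy$fe <- pmin(pmax(clean$fe +
            matrix(rnorm(length(clean$fe), sd = sigma), nrow(clean$fe)),
            0), 1)
        }
        animals[[i]] <- c(animals[[i]],
                          list(input_mrs = input_mrs, input_pet = input_pet,
                               tac = tac, labeling = noisy,
                               labeling_clean = clean))
      }
    }

    cohort <- data.frame(
      id = ids, genotype = genotype, treatment = "none", timepoint_weeks = 6,
      immobility_fst = immobility_fst, immobility_tst = immobility_tst,
      immobility_osfst = immobility_osfst,
      lac = lac, pcr = pcr, cr = cr, glc = glc_brain, tcho = tcho,
      pfc_volume = pfc_volume, body_weight = body_weight,
      cmr_glc_true = vapply(animals, function(a) a$fluxes$cmr_glc,
                            numeric(1)),
      stringsAsFactors = FALSE)

    structure(list(cohort = cohort, animals = animals,
                   truth = list(wt = wt, ko = ko), config = cfg),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d animals (%d WT, %d KO), seed %d>\n",
              nrow(x$cohort), sum(x$cohort$genotype == "WT"),
              sum(x$cohort$genotype == "KO"), x$config$seed))
  invisible(x)
}
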