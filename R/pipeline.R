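# End-to-end in-silico experiment: simulate a trio cohort, degrade the
# embryos through each amplification profile, compute the QC tables,
# sex the embryos, repair the best profile's genotypes by
# correction + imputation, and compare embryo vs calf genetic merit.
#
# One user seed fans out into per-stage seeds (see stage_seed), so each
# stage is individually reproducible.

#' Default experiment configuration
#'
#' @return Nested list mirroring the config-file schema: sections
#'   `cohort`, `replicates`, `effects`, `imputation`, `sexing`.
#' @export
default_experiment_config <- function() {
  list(cohort = list(n_loci = 5000, n_autosomes = 29, x_fraction = 0.03,
                     n_founders = 100, n_trios = 50, maf_low = 0.05,
                     maf_high = 0.5, ld_rho = 0.9, recomb_cM_per_Mb = 1.0,
                     chrom_length_mb = 100),
       replicates = list(k = 3),
       effects = list(n_traits = 3, effect_sd = 1, index_weights = c(1, 1, 1),
                      index_scale = 100, index_offset = 1000),
       imputation = list(channel_inflation = 1.3, switch_floor = 0.002,
                         override_posterior = 0.5, phasing_clusters = 20,
                         phasing_persistence = 0.98, phasing_em_iter = 8,
                         phasing_restarts = 3),
       sexing = list(ratio_threshold = 0.2, min_x_loci = 10))
}

#' Load an experiment configuration file
#'
#' YAML with the sections of [default_experiment_config()]; missing
#' keys fall back to the defaults.  Unknown keys are an error (they are
#' usually typos).
#'
#' @param path Path to a YAML config, or `NULL` for pure defaults.
#' @return Config list.
#' @export
load_experiment_config <- function(path = NULL) {
  cfg <- default_experiment_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (sec in names(user)) {
    if (!sec %in% names(cfg))
      stop("unknown config section: ", sec)
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key: ", sec, "$", key)
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  cfg
}

#' Run the full in-silico experiment
#'
#' @param config Config list from [load_experiment_config()] (or
#'   `NULL` for defaults).
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when given, every table of the
#'   report bundle is written there as a TSV.
#' @param profiles Optional named list of [wga_error_model()] objects;
#'   default [default_wga_profiles()] calibrated to the cohort's
#'   heterozygosity.
#' @return A list of class `experiment_report`; see the elements
#'   written by the function (`fig_metrics`, `concordance`,
#'   `locus_effect`, `callrate_error`, `quality_curve`, `sexing`,
#'   `consensus_check`, `imputation`, `merit`).
#' @export
run_experiment <- function(config = NULL, seed, out_dir = NULL,
                           profiles = NULL) {
  if (is.character(config)) config <- load_experiment_config(config)
  if (is.null(config)) config <- default_experiment_config()
  cc <- do.call(cohort_config, c(config$cohort, list(seed = seed)))
  founders <- simulate_founders(cc)
  trios <- simulate_trios(founders, cc)
  truth <- trios$embryos
  ped <- trios$pedigree
  emb_ids <- rownames(truth$calls)
  emb_sex <- ped$sex[match(emb_ids, ped$individual_id)]
  k <- config$replicates$k

  het_frac <- mean(truth$calls == 1L)
  if (is.null(profiles)) profiles <- default_wga_profiles(het_frac)

  # --- degrade: k replicate runs per profile -------------------------
  inj_seed <- stage_seed(seed, "inject")
  runs <- lapply(seq_along(profiles), function(pi) {
    lapply(seq_len(k), function(r)
      inject_wga_errors(truth, profiles[[pi]], inj_seed + 131L * pi + r,
                        locus_seed = inj_seed + 131L * pi))
  })
  names(runs) <- names(profiles)

  # --- per-profile error taxonomy (first replicate run) --------------
  fig_rows <- lapply(names(profiles), function(nm) {
    tall <- lapply(seq_len(k), function(r) tally_all(truth, runs[[nm]][[r]]$degraded))
    per_rep <- t(vapply(tall, function(tt)
      c(call_rate = mean(tt$call_rate), error_rate = mean(tt$error_rate),
        correct_prop = mean(tt$correct_prop),
        ado_rate = sum(tt$n_ado) / sum(tt$n_called),
        hetgain_rate = sum(tt$n_hetgain) / sum(tt$n_called),
        homrev_rate = sum(tt$n_homrev) / sum(tt$n_called)), numeric(6)))
    data.frame(profile = nm, replicate = seq_len(k), per_rep,
               stringsAsFactors = FALSE)
  })
  fig_metrics <- do.call(rbind, fig_rows)

  gh <- games_howell(fig_metrics$correct_prop, fig_metrics$profile)

  # --- replicate concordance vs binomial expectation -----------------
  conc_rows <- list(); obs_all_call <- c(); exp_all_call <- c()
  obs_all_err <- c(); exp_all_err <- c()
  n_samples_conc <- min(10L, length(emb_ids))
  for (nm in names(profiles)) {
    f <- matrix(0, n_samples_conc, 6)
    for (i in seq_len(n_samples_conc)) {
      reps <- lapply(seq_len(k), function(r)
        gm_subset(runs[[nm]][[r]]$degraded, samples = i))
      cs <- replicate_concordance(reps, gm_subset(truth, samples = i))
      f[i, ] <- c(cs$f_all, cs$f_atleast2, cs$f_any,
                  cs$e_all, cs$e_atleast2, cs$e_any)
    }
    fm <- colMeans(f)
    conc_rows[[nm]] <- data.frame(
      profile = nm, coverage_all = fm[1], coverage_atleast2 = fm[2],
      coverage_any = fm[3], error_all = fm[4], error_atleast2 = fm[5],
      error_any = fm[6], stringsAsFactors = FALSE)
    n_cells <- n_samples_conc * cc$n_loci
    p_call <- mean(fig_metrics$call_rate[fig_metrics$profile == nm])
    p_err_marg <- mean(fig_metrics$call_rate[fig_metrics$profile == nm] *
                         fig_metrics$error_rate[fig_metrics$profile == nm])
    obs_all_call <- c(obs_all_call, fm[1] * n_cells)
    exp_all_call <- c(exp_all_call,
                      expected_binomial_concordance(p_call, k, n_cells)$all)
    obs_all_err <- c(obs_all_err, fm[4] * n_cells)
    exp_all_err <- c(exp_all_err,
                     expected_binomial_concordance(p_err_marg, k, n_cells)$all)
  }
  concordance <- do.call(rbind, conc_rows)
  rownames(concordance) <- NULL
  n_cells <- n_samples_conc * cc$n_loci
  locus_effect <- list(
    call = locus_effect_test(obs_all_call, exp_all_call, n_cells),
    error = locus_effect_test(obs_all_err, exp_all_err, n_cells))

  # --- call-rate vs error-rate correlation ---------------------------
  cec <- callrate_error_correlation(fig_metrics$call_rate,
                                    fig_metrics$error_rate)

  # --- quality scores on the calibrated drop-out-dominant profile ----
  main_profile <- if ("genomiphi_like" %in% names(profiles))
    "genomiphi_like" else names(profiles)[1]
  main_run <- runs[[main_profile]][[1]]
  scored <- simulate_quality_scores(main_run$degraded, main_run$mask,
                                    seed = stage_seed(seed, "quality"))
  called <- !is.na(scored$calls)
  qcurve <- quality_threshold_curve(
    scored$quality[called],
    !(main_run$mask[called] %in% c("correct", "no_call")))

  # --- sexing --------------------------------------------------------
  sx <- sex_table(main_run$degraded,
                  ratio_threshold = config$sexing$ratio_threshold,
                  min_x_loci = config$sexing$min_x_loci)
  sx$true_sex <- emb_sex
  sx$correct <- sx$sex_call == sx$true_sex

  # --- consensus of reference-like replicates ------------------------
  ref_reps <- lapply(seq_len(k), function(r)
    runs[["reference_like"]][[r]]$degraded)
  consensus_check <- if (!is.null(ref_reps[[1]])) {
    cons <- build_consensus(ref_reps)
    mean(cons$calls == truth$calls, na.rm = TRUE)
  } else NA_real_

  # --- correction + imputation on the main profile -------------------
  library_haps <- build_library(
    founders, n_clusters = config$imputation$phasing_clusters,
    persistence = config$imputation$phasing_persistence,
    n_em = config$imputation$phasing_em_iter,
    n_restarts = config$imputation$phasing_restarts,
    seed = stage_seed(seed, "misc"))
  channel <- inflate_channel(profiles[[main_profile]],
                             config$imputation$channel_inflation)
  imputed_calls <- matrix(NA_integer_, nrow(truth$calls), ncol(truth$calls),
                          dimnames = dimnames(truth$calls))
  n_mendel <- integer(length(emb_ids))
  for (i in seq_along(emb_ids)) {
    res <- correct_and_impute(
      main_run$degraded$calls[i, ], trios$sires[i], trios$dams[i],
      library_haps, truth$loci, embryo_sex = emb_sex[i],
      error_rate = channel,
      switch_floor = config$imputation$switch_floor,
      override_posterior = config$imputation$override_posterior)
    imputed_calls[i, ] <- res$calls
    n_mendel[i] <- res$n_mendel
  }
  imputed <- genotype_matrix(imputed_calls, truth$loci, emb_ids)
  err_mask <- !(main_run$mask %in% c("correct", "no_call")) &
    !is.na(main_run$degraded$calls)
  pre_errors <- sum(main_run$degraded$calls != truth$calls, na.rm = TRUE)
  post_errors <- sum(imputed$calls != truth$calls)
  corrected_frac <- mean(imputed$calls[err_mask] == truth$calls[err_mask])
  report <- imputation_report(main_run$degraded, imputed, ped,
                              library_haps$freqs, truth = truth)

  # --- genetic merit -------------------------------------------------
  effects <- do.call(assign_marker_effects,
                     c(list(loci = truth$loci),
                       config$effects[c("n_traits", "effect_sd",
                                        "index_weights", "index_scale",
                                        "index_offset")],
                       list(seed = stage_seed(seed, "effects"))))
  idx_truth <- compute_index(compute_dgv(truth, effects), effects)
  idx_emb <- compute_index(compute_dgv(imputed, effects), effects)
  merit <- compare_merit(idx_emb, idx_truth)

  out <- structure(list(
    config = config, seed = seed, profiles = profiles,
    het_fraction = het_frac,
    fig_metrics = fig_metrics, games_howell = gh,
    concordance = concordance, locus_effect = locus_effect,
    callrate_error = cec, quality_curve = qcurve, sexing = sx,
    consensus_check = consensus_check,
    imputation = list(report = report, n_mendel = n_mendel,
                      pre_errors = pre_errors, post_errors = post_errors,
                      corrected_frac = corrected_frac,
                      main_profile = main_profile),
    merit = merit,
    indices = data.frame(sample_id = emb_ids, embryo_index = idx_emb,
                         calf_index = idx_truth)),
    class = "experiment_report")
  if (!is.null(out_dir)) write_experiment_report(out, out_dir)
  out
}

#' Write the tabular parts of an experiment report as TSVs
#'
#' @param report An `experiment_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_experiment_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(report$fig_metrics, "profile_metrics.tsv")
  wt(report$concordance, "replicate_concordance.tsv")
  wt(report$sexing, "sexing.tsv")
  wt(report$imputation$report, "imputation_report.tsv")
  wt(report$indices, "merit_indices.tsv")
  wt(report$quality_curve$curve, "quality_threshold_curve.tsv")
  summary_df <- data.frame(
    quantity = c("het_fraction", "consensus_vs_truth",
                 "callrate_error_r", "locus_effect_call_P",
                 "pre_imputation_errors", "post_imputation_errors",
                 "errors_corrected_frac", "merit_pearson_r",
                 "merit_mean_abs_divergence"),
    value = c(report$het_fraction, report$consensus_check,
              report$callrate_error$r, report$locus_effect$call$p_value,
              report$imputation$pre_errors, report$imputation$post_errors,
              report$imputation$corrected_frac, report$merit$pearson_r,
              report$merit$mean_abs_divergence))
  wt(summary_df, "summary.tsv")
  invisible(out_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report\n")
  cat(sprintf("  cohort: %d trios x %d loci (het fraction %.3f)\n",
              x$config$cohort$n_trios, x$config$cohort$n_loci,
              x$het_fraction))
  cat(sprintf("  call-rate/error-rate correlation r = %.3f\n",
              x$callrate_error$r))
  cat(sprintf("  %s: %d errors pre-imputation, %d post (%.1f%% corrected)\n",
              x$imputation$main_profile, x$imputation$pre_errors,
              x$imputation$post_errors,
              100 * x$imputation$corrected_frac))
  cat(sprintf("  merit concordance r = %.4f, mean |divergence| = %.1f pts\n",
              x$merit$pearson_r, x$merit$mean_abs_divergence))
  invisible(x)
}
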