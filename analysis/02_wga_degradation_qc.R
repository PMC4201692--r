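#!/usr/bin/env Rscript
# Degrade the embryo genotypes through the eight amplification
# profiles (three replicate runs each) and compute the QC battery:
# per-profile call rate / error taxonomy / correct-call proportion
# with Games-Howell letters, replicate-concordance tables with their
# binomial expectations and the paired locus-effect test, the
# call-rate vs error-rate correlation, and the quality-score
# threshold sweep.  Requires 01_simulate_cohort.R (same seed).

library(embryoMerit)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 20260930L
dir.create("results", showWarnings = FALSE)

report <- run_experiment(config = NULL, seed = seed, out_dir = "results/qc")

cat("\nPer-profile metrics (replicate means):\n")
agg <- aggregate(cbind(call_rate, error_rate, correct_prop) ~ profile,
                 report$fig_metrics, mean)
agg$letters <- report$games_howell$letters[agg$profile]
print(agg, digits = 3)

cat("\nReplicate concordance (coverage / error, all-of-3, >=2/3, any):\n")
print(report$concordance, digits = 3)

le <- report$locus_effect$call
cat(sprintf("\nLocus-effect paired t-test on all-replicate coverage: P = %.3f, 95%% CI [%.3f, %.3f]\n",
            le$p_value, le$conf_int[1], le$conf_int[2]))
cat(sprintf("Call-rate vs error-rate: r = %.3f (P = %.2g)\n",
            report$callrate_error$r, report$callrate_error$p_value))
bt <- report$quality_curve$best_threshold
cv <- report$quality_curve$curve
i <- which(cv$threshold == bt)
cat(sprintf("Best quality threshold %.2f removes %.0f%% of errors but loses %.0f%% of correct calls\n",
            bt, 100 * cv$error_removal[i], 100 * (1 - cv$correct_retention[i])))
message("tables written under results/qc/")
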