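#!/usr/bin/env Rscript
# Simulate the study cohort: 100 founders (50 sires, 50 dams), 50
# sire-dam-embryo trios on a ~5,000-locus panel (29 autosomes + X),
# and write it out in PLINK text format together with the pedigree and
# simulated marker effects.  The embryo genotypes written here are the
# clean truth -- the "calf" genotypes of the downstream comparison.

library(embryoMerit)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 20260930L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cc <- cohort_config(seed = seed)
founders <- simulate_founders(cc)
trios <- simulate_trios(founders, cc)

write_plink(founders$genotypes, trios$pedigree,
            file.path(out, "founders"))
write_plink(trios$embryos, trios$pedigree, file.path(out, "embryos_truth"))
write_pedigree(trios$pedigree, file.path(out, "pedigree.tsv"))

effects <- assign_marker_effects(founders$loci, n_traits = 3,
                                 effect_sd = 1, index_weights = c(1, 1, 1),
                                 seed = seed + 1L)
write_marker_effects(effects, file.path(out, "marker_effects.tsv"))

het <- mean(trios$embryos$calls == 1L)
message(sprintf("cohort: %d founders, %d embryos, %d loci (%d on X)",
                cc$n_founders, cc$n_trios, cc$n_loci,
                sum(is_x_locus(founders$loci))))
message(sprintf("embryo heterozygosity %.3f; files under %s/", het, out))
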