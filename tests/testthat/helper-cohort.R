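# Shared fixtures: all built in code at test time.

# A minimal locus map: n_auto autosomal loci on chr 1 then n_x on X,
# evenly spaced at 1 Mb.
tiny_loci <- function(n_auto = 4, n_x = 0) {
  n <- n_auto + n_x
  data.frame(locus_id = sprintf("L%03d", seq_len(n)),
             chromosome = c(rep("1", n_auto), rep("X", n_x)),
             position_bp = as.integer(seq_len(n) * 1e4),
             allele_a = "A", allele_b = "B",
             cM = seq_len(n) * 1.0,
             stringsAsFactors = FALSE)
}

tiny_gm <- function(calls, n_x = 0) {
  calls <- rbind(calls)
  genotype_matrix(calls, tiny_loci(ncol(calls) - n_x, n_x))
}

# A small simulated cohort shared by several tests.
small_cohort <- function(seed = 7, n_loci = 600, n_trios = 10,
                         n_founders = 24, n_autosomes = 5, ...) {
  cc <- cohort_config(n_loci = n_loci, n_autosomes = n_autosomes,
                      x_fraction = 0.1, n_founders = n_founders,
                      n_trios = n_trios, seed = seed, ...)
  fo <- simulate_founders(cc)
  tr <- simulate_trios(fo, cc)
  list(config = cc, founders = fo, trios = tr)
}

# Random valid genotype matrix for round-trip tests.
random_gm <- function(n, L, miss = 0.1, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    calls <- matrix(sample(c(0:2, NA), n * L, replace = TRUE,
                           prob = c((1 - miss) / 3, (1 - miss) / 3,
                                    (1 - miss) / 3, miss)),
                    n, L)
    loci <- data.frame(locus_id = sprintf("rs%04d", seq_len(L)),
                       chromosome = sample(c(as.character(1:29), "X"), L,
                                           replace = TRUE),
                       position_bp = sample.int(1e8, L),
                       allele_a = sample(c("A", "C"), L, replace = TRUE),
                       allele_b = sample(c("G", "T"), L, replace = TRUE),
                       stringsAsFactors = FALSE)
    genotype_matrix(calls, loci)
  })
}
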