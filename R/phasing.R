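# Haplotype library: statistical phasing of a reference population
# with a haplotype-cluster model.
#
# Cattle have a small effective population, so chromosomes are mosaics
# of a limited set of ancestral haplotype segments.  The phaser fits
# exactly that structure: a hidden Markov model in which each of an
# individual's two haplotypes copies one of K latent template
# haplotypes, switching templates with a small per-locus probability,
# and each template k carries an allele-B frequency theta[k, l] at
# every locus (the haplotype-cluster model of the fastPHASE family).
# EM estimates theta from the unphased genotypes; joint Viterbi
# decoding of the template pair then splits each genotype into two
# haplotypes.  Phase information lives in the joint template path --
# per-locus marginals are symmetric in the two haplotype labels and
# carry none.

#' Build a phased haplotype library from population genotypes
#'
#' Fits the haplotype-cluster model by EM and phases every individual
#' by Viterbi decoding of its template pair.  Several independent EM
#' restarts are combined by majority vote on the cis/trans pairing of
#' neighbouring heterozygous loci: restarts land in different local
#' optima, so their phasing mistakes are largely independent and the
#' vote cancels them, while the pairing representation makes the vote
#' immune to the arbitrary haplotype labelling of each restart.
#'
#' @param genotypes A [genotype_matrix()] of reference individuals
#'   (e.g. the founders), or a `founder_set`.  Must be fully called.
#' @param n_clusters Number of latent haplotype templates K.
#' @param persistence Per-locus probability that a haplotype keeps its
#'   current template (1 - persistence is the switch rate; switches
#'   may land on the same template).
#' @param n_em EM iterations for the template allele frequencies.
#' @param n_restarts Independent EM restarts entering the pairing
#'   vote.
#' @param seed Integer seed for the EM initialisations; the library is
#'   identical across runs with the same input and seed.
#' @param min_match Compatibility threshold stored for
#'   [impute_population()] window matching.
#' @param window_lengths Descending window lengths used later by
#'   [impute_population()]; stored with the library.
#' @return A list of class `haplotype_library`: `h1`, `h2` (0/1
#'   matrices, complementary at heterozygous loci), `resolved`
#'   (logical matrix: decoding confidence at heterozygous loci),
#'   `phase_conf` (per-locus probability that the `h1` assignment is
#'   correct; 1 at homozygous loci), `freqs` (allele-B frequencies),
#'   `loci`, `sample_ids`, `window_lengths`, `min_match`.
#' @export
build_library <- function(genotypes, n_clusters = 20, persistence = 0.98,
                          n_em = 8, n_restarts = 3, seed = 1,
                          min_match = 0.9,
                          window_lengths = c(200, 100, 50, 20, 10, 5, 1)) {
  if (inherits(genotypes, "founder_set")) genotypes <- genotypes$genotypes
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (any(diff(window_lengths) >= 0))
    stop("window_lengths must be strictly descending")
  g <- genotypes$calls
  if (anyNA(g))
    stop("library genotypes must be fully called")
  n <- nrow(g); L <- ncol(g)
  if (n < 1) stop("need at least 2 haplotypes")
  loci <- genotypes$loci
  freqs <- colMeans(g) / 2

  h1 <- (g >= 1L) + 0L
  h2 <- (g == 2L) + 0L
  het <- g == 1L
  resolved <- !het
  phase_conf <- matrix(1, n, L)   # P(h1 assignment correct); 0.5 = unknown
  phase_conf[het] <- 0.5

  K <- n_clusters
  aof <- rep(seq_len(K), K)          # template of haplotype slot a
  bof <- rep(seq_len(K), each = K)   # template of haplotype slot b

  chrs <- split(seq_len(L), loci$chromosome)
  h1_runs <- vector("list", n_restarts)
  conf_runs <- vector("list", n_restarts)
  with_seed(seed, {
    for (run in seq_len(n_restarts)) {
    for (chr_idx in chrs) {
      m <- length(chr_idx)
      G <- g[, chr_idx, drop = FALSE]
      # seed templates on randomly chosen individuals' half-dosages --
      # much closer to the haplotype structure than a flat start
      seed_rows <- sample.int(n, K, replace = K > n)
      theta <- pmin(pmax(G[seed_rows, , drop = FALSE] / 2 +
                           matrix(stats::runif(K * m, -0.1, 0.1), K, m),
                         0.02), 0.98)

      theta <- em_theta_cpp(G, theta, persistence, n_em)

      # joint Viterbi decoding of the template pair, per individual
      for (i in seq_len(n)) {
        hh <- which(het[i, chr_idx])
        if (!length(hh)) next
        path <- viterbi_pair_cpp(G[i, ], theta, persistence)
        # phase the heterozygous loci from the decoded template pair
        ta <- theta[cbind(aof[path[hh]], hh)]
        tb <- theta[cbind(bof[path[hh]], hh)]
        pA <- ta * (1 - tb) / pmax(ta * (1 - tb) + (1 - ta) * tb, 1e-12)
        jj <- chr_idx[hh]
        h1[i, jj] <- as.integer(pA >= 0.5)
        phase_conf[i, jj] <- pmax(pA, 1 - pA)
      }
    }
    h1_runs[[run]] <- h1
    conf_runs[[run]] <- phase_conf
    }
  })

  # combine the restarts: majority vote on the cis/trans pairing of
  # each pair of neighbouring het loci, then rebuild the phase chain
  if (n_restarts == 1) {
    h1 <- h1_runs[[1]]
    phase_conf <- conf_runs[[1]]
    h2[het] <- 1L - h1[het]
    resolved[het] <- phase_conf[het] >= 0.8
  } else {
    for (chr_idx in chrs) {
      for (i in seq_len(n)) {
        hh <- chr_idx[het[i, chr_idx]]
        if (!length(hh)) next
        if (length(hh) == 1) {
          h1[i, hh] <- h1_runs[[1]][i, hh]
          phase_conf[i, hh] <- 0.5
          next
        }
        same_votes <- rep(0L, length(hh) - 1L)
        for (run in seq_len(n_restarts)) {
          hr <- h1_runs[[run]][i, hh]
          same_votes <- same_votes + (hr[-1] == hr[-length(hr)])
        }
        maj_same <- same_votes * 2L > n_restarts
        tie <- same_votes * 2L == n_restarts
        if (any(tie)) {
          hr <- h1_runs[[1]][i, hh]
          maj_same[tie] <- (hr[-1] == hr[-length(hr)])[tie]
        }
        chain <- integer(length(hh))
        chain[1] <- h1_runs[[1]][i, hh[1]]
        for (t in seq_along(maj_same))
          chain[t + 1] <- if (maj_same[t]) chain[t] else 1L - chain[t]
        h1[i, hh] <- chain
        vs <- pmax(same_votes, n_restarts - same_votes) / n_restarts
        conf <- c(vs[1], (vs[-1] + vs[-length(vs)]) / 2, vs[length(vs)])
        phase_conf[i, hh] <- conf
      }
    }
    h2[het] <- 1L - h1[het]
    resolved[het] <- phase_conf[het] >= 0.8
  }

  structure(list(h1 = h1, h2 = h2, resolved = resolved,
                 phase_conf = phase_conf, freqs = freqs,
                 loci = loci, sample_ids = rownames(g),
                 window_lengths = window_lengths, min_match = min_match),
            class = "haplotype_library")
}

#' Phase accuracy of a library against known truth
#'
#' Diagnostic for simulated cohorts where the true phase is known.
#' For every heterozygous locus, the assignment is counted correct if
#' it agrees with the majority orientation of the surrounding
#' `2 * flank + 1` heterozygous loci (local flips are what damage
#' downstream haplotype tracking; global orientation per chromosome is
#' arbitrary).
#'
#' @param library A `haplotype_library`.
#' @param truth_h1,truth_h2 True haplotype matrices (same layout).
#' @param flank Heterozygous loci on each side used for the local
#'   orientation.
#' @return List `het_accuracy` (fraction of het loci consistent with
#'   the local orientation), `pairing_accuracy` (fraction of
#'   consecutive het pairs whose cis/trans call matches truth),
#'   `resolved_frac` and `n_het`.
#' @export
phase_accuracy <- function(library, truth_h1, truth_h2, flank = 5) {
  g <- library$h1 + library$h2
  het <- g == 1L
  ok <- 0L; tot <- 0L; pair_ok <- 0L; pair_tot <- 0L
  chrs <- split(seq_len(ncol(g)), library$loci$chromosome)
  for (i in seq_len(nrow(g))) {
    for (chr_idx in chrs) {
      hj <- chr_idx[het[i, chr_idx]]
      if (length(hj) < 2) next
      o <- library$h1[i, hj] == truth_h1[i, hj]
      pair_ok <- pair_ok + sum(o[-1] == o[-length(o)])
      pair_tot <- pair_tot + length(o) - 1L
      for (k in seq_along(hj)) {
        nb <- setdiff(max(1, k - flank):min(length(hj), k + flank), k)
        if (!length(nb)) next
        maj <- mean(o[nb]) >= 0.5
        ok <- ok + as.integer(o[k] == maj)
        tot <- tot + 1L
      }
    }
  }
  list(het_accuracy = ok / tot, pairing_accuracy = pair_ok / pair_tot,
       resolved_frac = mean(library$resolved[het]),
       n_het = tot)
}
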