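# embryoMerit

Can the genomic breeding value of a pre-transfer cattle embryo be
estimated reliably from a 15-cell trophoblast biopsy?  A biopsy holds
about 90 pg of genomic DNA (15 cells x 6 pg), a thousandth of what a
SNP array needs, so the sample must pass through whole-genome
amplification (WGA) — and WGA trades completeness for errors: missing
calls, allele drop-out (AB called AA/BB), heterozygosity gain (AA
called AB) and rare homozygous reversal (AA called BB).

`embryoMerit` is an in-silico laboratory for this question, aimed at
livestock-genomics researchers and method developers.  It simulates
BovineSNP50-style trio cohorts with realistic haplotype sharing,
degrades the embryo genotypes through configurable WGA error
channels, quantifies the damage with the standard QC battery, repairs
it with Mendelian-inconsistency correction plus combined family and
population haplotype imputation, and measures what the damage and its
repair do to genomic selection decisions.

The quantities at its core, in the field's usual notation:

* per-sample **call rate** `n_called / n_ref_called`, **error rate**
  `(n_ADO + n_hetgain + n_homrev) / n_called` (relative to the calls
  the method delivered) and **correct-call proportion**
  `n_correct / n_ref_called`, computed against a replicate-consensus
  reference;
* replicate concordance (loci covered by all / at least 2 / any of k
  replicates) against its binomial expectation
  `n·p^k`, `n·Σ_{j≥2} C(k,j) p^j (1−p)^{k−j}`, `n·(1−(1−p)^k)`,
  compared by a paired t-test (a locus-effect detector);
* Games–Howell pairwise comparisons (Welch SE/df, studentized-range
  reference distribution) with compact-letter displays;
* sex from X-vs-autosomal heterozygosity (a male's single coded X
  should be nearly HET-free);
* direct genomic values `DGV(i,t) = Σ_l a_{l,t} · x_{i,l}` (additive
  effect times allele-B dosage) combined into a profit-style index,
  and the embryo-vs-calf concordance `r`, `rho`, mean |divergence|.

## Worked example

The numbered scripts under `analysis/` form the full study arc; each
is a thin driver over the package functions.  With the default seed:

```sh
Rscript analysis/01_simulate_cohort.R     # 100 founders, 50 trios, 5,000 loci
Rscript analysis/02_wga_degradation_qc.R  # 8 WGA profiles x 3 replicates + QC
Rscript analysis/03_sexing.R              # X-heterozygosity sexing vs drop-out
Rscript analysis/04_impute_and_merit.R    # repair + genetic-merit concordance
```

`02` prints the per-profile metrics (three replicate degradations
each; letters from the Games–Howell comparison of correct-call
proportions):

```
          profile call_rate error_rate correct_prop letters
1  genomiphi_like     0.880   0.124044        0.771       b
5       qpls_like     0.700   0.209046        0.553       c
7     replig_like     0.550   0.300441        0.385       d
8       spia_like     0.500   0.449382        0.275       e
2 lma_expresslink     0.400   0.529303        0.188       f
3    lma_ligafast     0.350   0.580092        0.147       g
4        lma_like     0.300   0.608540        0.118       h
6  reference_like     0.997   0.000958        0.996       a

Locus-effect paired t-test on all-replicate coverage: P = 0.601,
  95% CI [-0.001, 0.001]
Call-rate vs error-rate: r = -0.985 (P = 3.4e-18)
Best quality threshold 0.69 removes 63% of errors but loses 18% of
  correct calls
```

Reading it: the drop-out-dominant profile calibrated to a 12% no-call
rate and 12.4%-of-calls error sits at the top of the amplified
methods; the ligation-style profiles approach the 2/3 error floor of
random genotypes; call rate and error rate are strongly negatively
correlated (shared template-loss cause); with locus-homogeneous
errors the paired t-test finds no locus effect (P ≈ 0.6, CI spanning
zero); and no GC-score threshold separates errors from good calls.

`04` then repairs the calibrated profile's damage against the phased
founder library and compares genetic merit:

```
errors: 27484 pre-imputation -> 5090 post (92.9% of injected errors restored)
Mendelian inconsistencies flagged per embryo: mean 287.1
merit concordance: r = 0.9766 (P = 1e-33), rho = 0.9762
mean |index divergence| = 32.7 +/- 26.7 pts; top-5 overlap 80%
```

So at desk scale — 5,000 loci, a tenth of the real chip — family plus
population imputation finds and fixes the large majority of injected
errors and the embryo-derived index tracks the calf-derived index
closely; the methods vignette
(`vignettes/embryo-genotyping-fidelity.Rmd`) discusses why the last
few points of correction are information-limited at this marker
density.

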