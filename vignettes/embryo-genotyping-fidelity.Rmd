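---
title: "Genotyping fidelity and genomic merit of whole-genome-amplified embryo biopsies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping fidelity and genomic merit of whole-genome-amplified embryo biopsies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A cattle embryo biopsy removes about 15 trophoblast cells.  A diploid
cell holds roughly 6 pg of genomic DNA, so the whole biopsy yields
about 90 pg (`biopsy_dna_pg()`), a thousand times less than the input
most SNP-array protocols expect.  Whole-genome amplification (WGA)
bridges that gap, but at a price: template loss and mis-priming turn
into missing calls, allele drop-out (a true AB called AA or BB),
heterozygosity gain (a true AA called AB) and, rarely, homozygous
reversal (AA called BB).  The practical question for embryo selection
is whether a genomic breeding value computed from such degraded
genotypes still ranks embryos the way the clean genotype of the
resulting calf would.

This package is an in-silico laboratory for that question.  No real
genotypes ship with it; a synthetic-cohort generator produces the
statistical structure the analysis needs, an error channel degrades
it, and the QC / repair / valuation stages measure what survives.

## What the generator emulates -- and what it does not

`simulate_founders()` + `simulate_trios()` produce an Illumina
BovineSNP50-like panel, scaled to desk size:

* **Panel**: 5,000 biallelic loci (about a tenth of the real chip)
  over 29 autosomes plus X, evenly spaced on 100-Mb chromosomes with a
  uniform 1 cM/Mb genetic map.  The real chip's map is neither uniform
  nor evenly spaced; nothing downstream depends on that.
* **Allele frequencies**: allele-B frequency per locus drawn once from
  Uniform(0.05, 0.5), giving a mean heterozygosity near 0.36 --
  typical for a chip ascertained to be polymorphic.
* **Linkage disequilibrium and haplotype sharing**: each founder
  haplotype is a first-order Markov mosaic over a pool of
  `n_ancestral = 20` ancestral haplotypes, keeping its current
  template with probability `copy_persistence = 0.98` per locus
  (shared segments of ~50 loci), while the ancestral haplotypes carry
  adjacent-locus correlation `ld_rho = 0.9` through a latent Gaussian
  autoregression that preserves the drawn marginal frequencies
  exactly.  This mirrors the two facts about dairy-cattle genomes the
  repair stage depends on: strong local LD, and long haplotype
  segments shared identical-by-descent across a breed with small
  effective population size.  It does **not** model demography,
  selection, mutation, or realistic recombination hotspots.
* **Trios**: 50 sire-dam pairs drawn from 100 founders, one embryo
  each; gametes recombine with Poisson crossover counts (1 Morgan per
  chromosome), embryo sex is Bernoulli(0.5), and the male X is
  hemizygous -- arrays report the single allele as a homozygous call.
  Trios are Mendelian-consistent by construction, which the test
  suite asserts.
* **Quality scores**: correct calls draw from Beta(8, 2), erroneous
  calls from Beta(3, 2).  The two densities overlap across the whole
  unit interval, reproducing the situation where no GC-score
  threshold removes most errors without discarding most good calls;
  the exact shapes are a design choice, not an estimate.

Passing tests on this cohort therefore show that the *methods* behave
correctly under the assumed structure; they do not certify
performance on any particular real chip or breed.

## The WGA error channel

`wga_error_model()` applies, per cell and mutually exclusively:
no-call with probability `miss_rate` (drawn first, so the error rates
are conditional on a call being made -- matching how array error
rates are reported relative to the number of calls); then allele
drop-out for true heterozygotes (`ado_rate`, losing either allele
with equal probability), heterozygosity gain (`hetgain_rate`) or
homozygous reversal (`reversal_rate`) for true homozygotes.  With
`locus_dispersion > 0` the per-locus miss rate becomes
Beta-distributed, creating the locus-specific call-rate bias that the
binomial locus-effect test (`locus_effect_test()`) is designed to
detect.

`calibrate_wga_profile()` solves the rates so that the overall
erroneous fraction of calls hits a target given the cohort's
heterozygosity.  The default profile ("genomiphi_like") uses a 12%
no-call rate and a 12.4%-of-calls conditional error, 80% of it allele
drop-out -- the signature of the better isothermal chemistries on
15-cell inputs.  `default_wga_profiles()` adds seven contrasting
profiles down to ligation-mediated methods whose error rate
approaches the floor of completely random genotypes; that floor is
2/3, because a uniform random draw over {AA, AB, BB} matches any
reference one time in three.  The split of the composite error rate
among categories is only qualitatively constrained by the systems
being emulated, so the profile shares are documented assumptions.

## QC metrics

`error_tally()` classifies every call against a reference
(`build_consensus()` of replicate runs, with the modal-call rule and
no-call on disagreement), excluding loci where the reference itself
is uncalled.  Identities `n_called = n_correct + n_ado + n_hetgain +
n_homrev` and `n_ref_called = n_called + n_nocall_vs_ref` are
asserted on every tally.  `replicate_concordance()` compiles the
all/at-least-2/any coverage and error fractions;
`expected_binomial_concordance()` gives their expectations under
locus-homogeneity, and `locus_effect_test()` compares the two by a
paired t-test across methods, on fractions rather than counts (the
confidence interval is then on the same scale for methods with
different locus counts).  `games_howell()` performs the
heteroscedasticity-robust pairwise comparisons (Welch SE and df, the
studentized-range distribution via R's `ptukey`, accurate well below
1e-4 in P) with a deterministic insert-and-absorb compact-letter
display, ties broken by descending group mean.

## Sexing

The 50K panel has no Y-specific loci, so `call_sex()` compares X to
autosomal heterozygosity: a male's single X (coded homozygous) should
show essentially none.  The threshold is a *ratio* (default: X
heterozygosity below 0.2 of autosomal) rather than an absolute level,
making it invariant to the panel's frequency spectrum; no published
cutoff exists, so the default is exposed as a parameter.  Drop-out
erodes heterozygosity everywhere and X calls are few, so under heavy
ADO some true females fall under the ratio -- the test suite checks
that this misclassification is monotone in the drop-out rate and
absent at zero error.

## Correction and imputation

The repair stage is the package's core and is deliberately
family-first, population-second:

1. **Mendelian screen** (`find_mendelian_inconsistencies()`): a call
   impossible given the called parents is blanked.  The X is handled
   sex-aware (a male embryo's X allele must come from the dam; a
   heterozygous male X call is itself an error).
2. **Family rules** (`impute_family()`): missing genotypes forced by
   homozygous parents are filled; a single homozygous parent fixes
   one allele as a half-resolved constraint.
3. **Transmission tracing** (`correct_and_impute()`): a small hidden
   Markov model runs along each chromosome over the four (sire
   haplotype, dam haplotype) transmission states, with switch
   probabilities from the genetic map (Haldane) plus a small floor
   (default 0.002) absorbing residual phase switches in the library.
   Emissions come from the WGA channel itself -- ideally the fitted
   `wga_error_model`, so that allele drop-out is modelled as far more
   likely than reversal.  The posterior genotype distribution fills
   every missing locus and *overrides* a called genotype whose
   posterior falls below that of an alternative.  This is how
   Mendelian-consistent errors (e.g. drop-outs under HET x HET
   parents) are found: the surrounding haplotype contradicts them.
4. **Population fallback** (`impute_population()`): samples without
   genotyped parents are completed by longest-to-shortest window
   matching against the haplotype library, with a single-locus
   allele-frequency fallback guaranteeing zero missing output.

The widely used family/population imputation programs for livestock
follow this same design; the implementation here is inspired by that
school but is this package's own, and no claim of equivalence to any
specific program is made.

### The haplotype library

`build_library()` phases the founders with a haplotype-cluster model
(the fastPHASE family): each haplotype copies one of K = 20 latent
templates, switching with probability 0.02 per locus, and template k
carries an allele-B frequency per locus.  EM estimates the template
frequencies from unphased genotypes; joint Viterbi decoding of the
template pair then splits each genotype.  Because per-locus marginals
are exactly symmetric in the two haplotype labels, phase information
lives only in the joint path -- hence Viterbi rather than posterior
marginals.  Several independent EM restarts (default 3) are combined
by majority vote on the cis/trans pairing of neighbouring
heterozygous loci; pairings are invariant to each restart's arbitrary
labelling, and restarts land in different local optima, so the vote
cancels a large share of their individual mistakes.  K, the
persistence and the restart count are tunable; the defaults suit
panels with strong haplotype sharing and are the ones used throughout
the analysis scripts.

### Numerical choices

* HMM arithmetic in log space with per-locus renormalisation;
  emission probabilities floored at 1e-300.
* Viterbi ties broken toward the first state index; phase-vote ties
  toward the first restart -- all outputs are deterministic under a
  fixed seed.
* The emission channel is the calibrated degradation profile when
  known (the analysis scripts pass it); a single symmetric error rate
  is accepted otherwise.  The channel rates are inflated by 1.3 in
  the drivers relative to the nominal profile: treating the observed
  call as slightly less reliable than nominal compensates for the
  HMM's assumption that library haplotypes are exact.
* `cohort_config()` seeds fan out deterministically per pipeline
  stage, so any stage can be re-run in isolation.

## Genetic merit

`compute_dgv()` is the plain additive sum of per-locus marker effects
times allele-B dosage; effects are *inputs* (simulated
Normal(0, `effect_sd`^2) by `assign_marker_effects()`, or a TSV), as
they would come from a national evaluation.  X effects enter with
dosage as coded (males 0/2) -- the simplest consistent convention,
flagged here because evaluation systems differ on it.
`compute_index()` standardises each trait over the evaluated cohort,
applies the economic weights and maps onto an affine published scale
(default: offset 1000, scale 100 points); the affine freedom cannot
affect the correlation or rank statistics that `compare_merit()`
reports, which is why cohort-standardisation is acceptable even
though a real national index is anchored to a population base the
package has no access to.  The index-point scale of the mean
embryo-vs-calf divergence is therefore meaningful only relative to
this synthetic scale, not to any published national index.

## Problem sizes and what the bundled analyses run

The analysis scripts and the acceptance checks use 50 trios by 5,000
loci -- about a tenth of the real chip and a quarter of the real
embryo count -- with three replicate degradations per profile.  At
this size the full QC battery runs in a few minutes and the phasing +
repair stage in under fifteen on one core; the sizes are configurable
upward through `cohort_config()`.  Error-rate and concordance
quantities at this scale carry Monte-Carlo noise of roughly one
percentage point, which the tests' tolerances reflect.

## Known limitations

* The generator's LD/sharing model is stylised; real chips show
  frequency-dependent LD decay, hotspots, and assay artefacts
  (cluster-file effects) that are out of scope.
* Phasing accuracy, and with it error-correction power, degrades for
  cohorts without strong haplotype sharing; the library model assumes
  a small effective population.
* The pseudo-autosomal region of the X is not modelled; sexing and
  X imputation treat the X as fully hemizygous in males.
* Marker-effect estimation (SNP-BLUP/GBLUP) is out of scope; effects
  are exogenous.
* A residual share of injected errors -- those at loci where the
  relevant parent is heterozygous and the local haplotype evidence is
  genuinely ambiguous (near crossovers and template-switch points) --
  survives repair; the acceptance report quantifies it on every run.
  This share is governed by the linkage information per marker
  interval and therefore by panel density: at the desk-scale 5,000-locus
  panel the repair stage recovers most but not all injected errors
  even when the parents' true phase is supplied, so results at this
  scale bound, rather than reproduce, what the same machinery achieves
  on a full-density chip with a large reference population.
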