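Package: embryoMerit
Title: Genotyping Fidelity and Genomic Merit of Whole-Genome-Amplified
    Embryo Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for SNP-array genotyping of
    pre-transfer cattle embryo biopsies.  Generates synthetic Illumina
    BovineSNP50-style cohorts (founder haplotypes with linkage
    disequilibrium, sire-dam-embryo trios with recombination, an X
    chromosome and per-call quality scores), degrades embryo genotypes with
    a whole-genome-amplification error process (no-calls, allele drop-out,
    heterozygosity gain, homozygous reversal), and quantifies the damage
    and its repair: replicate-concordance and error-taxonomy QC metrics,
    locus-effect and correlation tests, Games-Howell multiple comparisons,
    X-heterozygosity sexing, Mendelian-inconsistency correction with
    combined family and population haplotype imputation, and concordance of
    direct genomic values and a profit-style selection index between
    degraded-then-imputed embryo genotypes and clean reference genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
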