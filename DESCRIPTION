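Package: admixscan
Title: Local Ancestry Deviation Scans and Post-Admixture Selection Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the distribution of local ancestry along the genome of
    recently admixed cohorts and to search for signals of post-admixture selection.
    Provides per-SNP ancestry-proportion tracks with a genome-wide standard-deviation
    deviation scan, five neutrality statistics (|iHS|, |diHH|, |diHH_derived|, XP-EHH
    and PBS on Hudson's Fst) combined into a Fisher combined score with rank-based
    outlier calling over 100-SNP blocks, inversion genotyping by identity-by-state
    MDS with a three-component EM mixture, Procrustes comparison of regional MDS
    configurations with a permutation test, SNP- and individual-level quality-control
    filters, and a synthetic-data generator (Balding-Nichols reference panels, Markov
    ancestry-tract admixed cohorts, planted ancestry-deviation and inversion-like
    polymorphisms) so the whole pipeline runs against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
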