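---
title: "Methods: local ancestry deviation scans and post-admixture selection"
author: "admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local ancestry deviation scans and post-admixture selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`admixscan` analyses recently admixed diploid cohorts with three ancestral
components (EUR, AFR, NAT). Its inputs are phased haplotypes (VCF), a
genetic map, and per-haplotype local-ancestry calls with tract posteriors
(msp-style tables, as produced by random-forest local-ancestry callers);
its outputs are ancestry-proportion tracks, deviation calls, inversion
genotypes, five neutrality statistics combined into a Fisher combined
score (FCS) with block-level region calls, and Procrustes comparisons of
regional MDS configurations. A synthetic-data generator produces all of
these inputs with known ground truth, which is how the package tests
itself end to end.

## The deviation scan

For ancestry $a$ and SNP $j$, $\mathrm{prop}_a(j)$ is the fraction of
included haplotypes labelled $a$. The scan standardizes each ancestry's
track with its genome-wide mean and SD (computed over all autosomal SNPs of
the analysis set, not per chromosome) and flags SNPs two-sidedly at
$|z| > 4.42$. The threshold is a config default, not derived internally:
under a standard-normal null it corresponds to a two-sided tail of
$2(1-\Phi(4.42)) \approx 9.9\times10^{-6}$, i.e. below the conventional
$10^{-5}$ significance bound used for such scans. Adjacent flagged SNPs of
one ancestry, direction and chromosome merge into intervals. If an
ancestry's track has zero SD (degenerate input), nothing is flagged.

Two artefact audits accompany a flagged locus. The tract-posterior audit
counts tracts intersecting the region and those with posterior below 0.9 —
the tract, not the SNP, is the unit, matching how local-ancestry callers
report uncertainty. The concordance check correlates genome-wide means of
the local calls against externally estimated global ancestry per
individual.

## Inversion genotyping and stratified rescans

A polymorphic inversion suppresses recombination between orientation
classes, so over the inverted region individuals separate by the number of
inverted haplotypes they carry (0/1/2). The package computes pairwise IBS
over the region's dosages, embeds $1-\mathrm{IBS}$ by classical MDS
(`stats::cmdscale`), and fits a three-component univariate Gaussian mixture
to axis 1 by EM (tolerance $10^{-6}$ on the log-likelihood, iteration cap
$10^6$, variances floored at $10^{-12}\,\mathrm{var}(x)$ to survive
single-member clusters). Mixing weights can optionally be tied to
Hardy-Weinberg form $(q^2, 2q(1-q), (1-q)^2)$.

Initialization is deterministic and seedless. The fit is run from two fixed
starts — component means at the 10th/50th/90th percentiles of the axis, and
at 5%/50%/95% of the axis range — keeping the higher final log-likelihood.
The percentile start alone proved fragile in development: with a skewed
class frequency the two lower percentiles fall into one large cluster and
EM converges to a local optimum that splits it; the range-based start
recovers the correct geometry in exactly those cases.

After ordering the component means, the extreme components are the
homozygote classes. Which homozygote is "non-inverted" cannot be decided
from geometry, so the larger cluster is labelled NI/NI by default, and an
`anchors` argument accepts individuals of known genotype to override the
orientation (mirroring how external inversion-frequency knowledge is used
in practice). Deviation scans are then re-run separately in the NI/NI and
I/I strata; NI/I heterozygotes are always excluded because phasing cannot
assign the inverted haplotype to a chromosome.

## Selection statistics

EHH for allele class $c$ at offset $x$ from a core SNP is the probability
that two random carrier haplotypes are identical over the interval from the
core to $x$ ($\sum_h \binom{n_h}{2}/\binom{n}{2}$ over extended-haplotype
groups). iHH integrates EHH over cM by the trapezoid rule, both directions,
truncated where EHH drops below 0.05; integration is censored at chromosome
ends and at physical gaps above 200 kb. These are the conventional defaults
of the EHH literature and are all exposed as arguments. Censored SNPs are
excluded from standardization by default to avoid edge-of-chromosome
inflation.

* $\mathrm{uniHS} = \ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$ and
  $\mathrm{u\Delta iHH} = \mathrm{iHH}_A - \mathrm{iHH}_D$ are standardized
  within equal-count derived-allele-frequency bins (default 50; bins with
  fewer than two usable SNPs merge leftward) and reported as absolute
  values. SNPs with MAF < 0.05, fewer than two carriers, censoring, or zero
  iHH are missing with a recorded reason.
* XP-EHH $= \ln(\mathrm{iHH}_{all}(\mathrm{target})/\mathrm{iHH}_{all}(\mathrm{ref}))$,
  standardized genome-wide and kept signed (positive = longer haplotypes in
  the target; an absolute-value mode exists behind a flag).
  $\Delta\mathrm{iHH}_{derived}$ is the target-minus-reference derived-allele
  iHH difference, standardized genome-wide, absolute value taken. The exact
  published definition of the latter is not fully specified in the scan
  literature; the target-minus-reference reading adopted here is recorded
  as an interpretation.
* Hudson's Fst uses the unbiased two-population estimator
  $\hat N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$,
  $\hat D = p_1(1-p_2)+p_2(1-p_1)$, with 1-Mb windows aggregated as the
  ratio of averages. PBS uses $T = -\ln(1-F_{st})$ with Fst clipped to
  $[0, 1-10^{-6}]$ and negatives to 0; $\mathrm{PBS}_A = (T_{AB}+T_{AC}-T_{BC})/2$,
  computed per SNP because the FCS is per SNP. In the pipeline each
  reference configuration uses its reference panel as population B and one
  of the remaining panels as the outgroup C.

## The Fisher combined score and region calls

Each statistic's evidence becomes an empirical p-value
$p_i = \mathrm{rank}/N$ (rank 1 = most extreme in the selection direction;
ties take the maximum rank of their group, which keeps $p_i \in [1/N, 1]$
and treats ties conservatively). Missing statistics contribute $p = 1$
rather than dropping the SNP, keeping $N$ stable across the five tracks.
$\mathrm{FCS} = \sum_{i=1}^{k} -\log_{10}(p_i)$; under independent uniform
p-values $2\ln(10)\,\mathrm{FCS} \sim \chi^2_{2k}$, which the test suite
verifies on 50,000 simulated SNPs.

Outliers are the top $\lfloor 0.01N \rfloor$ SNPs by FCS rank — exactly 1%
for tie-free values with $N$ divisible by 100. Blocks of 100 consecutive
SNPs tile each chromosome separately (the final partial block keeps its
actual size), so no block is chimeric across chromosomes. A block is called
when its outlier proportion strictly exceeds the higher-type 99.5th
empirical percentile of all block proportions; because proportions live on
a grid of multiples of 1/100, the strictly-greater rule keeps the called
fraction at or below 0.5% under heavy ties — and with fewer than ~200
blocks the percentile is the maximum itself, so nothing is called at toy
scale. Called blocks are labelled by the reference configuration(s) whose
scan called them, with compound "X or Y" labels for multi-configuration
hits; this per-configuration labelling rule is an interpretation and is
flagged as such in output headers.

## Procrustes corroboration

The focal region's MDS configuration is compared against random regions of
exactly the same coordinate length (uniformly placed within chromosome
spans, avoiding the focal region; overlap among random regions is allowed
by default, with a flag to forbid). Both configurations are centered,
optimally scaled and rotated; $m^2 = 1 - (\sum \sigma_i)^2/(ss_X\,ss_Y)$,
correlation $=\sqrt{1-m^2}$, and significance comes from shuffling rows of
the second configuration with the add-one estimator
$p = (\#\{corr_{perm} \ge corr\}+1)/(n_{perm}+1)$, so $p$ is never 0. The
implementation is cross-checked against an independent community
implementation of the protest statistic in the test suite.

## The synthetic-data generator

Reference panels follow the Balding-Nichols model: ancestral frequency
$p \sim U(0.05, 0.95)$, population frequency
$\sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with per-population drift $F$
(default 0.15; $F=0$ shares $p$ exactly). This choice — rather than a
coalescent simulator — gives a free analytic oracle: windowed Hudson Fst
between two panels estimates $F$ directly. Within-population LD comes from
building each panel haplotype as a mosaic of $K$ founder haplotypes with
switch rate $\rho = 1$ per Morgan. $K$ defaults to 100: founder resampling
adds drift of order $(1-F)/K$ on top of $F$, so small founder counts
(e.g. 20) push windowed Fst visibly above the nominal $F$ (measured 0.187
for $F = 0.15$), while $K = 100$ keeps the excess under a point
(measured 0.149). The flip side is that background haplotype sharing is
about $1/K$; with very small $K$ it exceeds the 0.05 EHH floor and every
EHH integration censors, so $K$ should stay well above 20 whenever the
haplotype statistics are in play.

Admixed haplotypes are Markov ancestry processes along the map: over a map
increment $\Delta$ Morgans, ancestry is redrawn from the admixture
proportions $\pi$ with probability $1-e^{-g\Delta}$ (redraws may silently
keep the same ancestry, so the expected number of visible switches per
haplotype is $\approx g \times L_{Morgans} \times (1-\sum_a \pi_a^2)$).
Alleles are copied from a uniformly chosen reference haplotype of the
segment's ancestry, preserving within-ancestry LD for the EHH statistics.
Defaults emulate a European-majority three-way cohort:
$\pi = (0.77, 0.14, 0.09)$ and $g = 15$ generations — the admixture time is
a placeholder exposed in config, as no estimate is asserted for any real
cohort.

Two plantable signals make the scans testable. The deviation locus is
post-hoc tract resampling: inside the region each haplotype's ancestry is
redrawn from the target proportions and alleles are re-copied — this
targets the scan's detection contract, not evolutionary realism (no
forward-in-time selection dynamics are simulated). The inversion-like
polymorphism builds two haplotype classes differing at a fraction $d$ of
region SNPs (default 0.3), with a small within-class mismatch rate
(default 0.03) for realism, per-population class frequencies, and
suppressed recombination: every haplotype's region is a whole copy of a
class-consistent reference haplotype.

What the generator does **not** emulate: genotyping error (a flip-rate hook
exists but defaults to 0), sex chromosomes, background selection,
population growth, or realistic recombination-map heterogeneity. Passing
tests therefore demonstrate the statistical machinery's correctness and
calibration, not robustness to every artefact of real array data.

## Numerical choices and degenerate inputs

* Coordinates are 1-based with inclusive printed endpoints; region length
  is `end − start` (so the 20116146-20564575 bp locus is 448.4 kb),
  matching how such loci are reported.
* Ancestral-allele orientation happens once at VCF load (via the `AA` INFO
  field); all downstream statistics assume 0 = ancestral.
* One global seed; every stochastic stage derives a child seed
  deterministically from it plus a stage tag, so pipeline outputs are
  bit-for-bit reproducible.
* QC filters run in a fixed order (unmapped, non-autosomal, ambiguous,
  HWE, missingness, MAF) and the ledger attributes each SNP to the first
  filter it fails, so category counts are sequential, sum to the total
  removed, and `remaining = start − Σ removals` always holds. The HWE test
  is the exact conditional test by default (chi-square behind a flag, since
  published pipelines rarely say which they used). Duplicate removal keeps
  the lower-index individual; greedy relatedness pruning breaks degree ties
  by higher missingness, then higher index — fixed rules where the
  published strategy names only "greedy". LD pruning uses composite
  (dosage) correlation because the filter runs pre-phasing.
* The deviation scan, FCS ranking and block percentile all guard their
  degenerate cases explicitly: zero-SD tracks flag nothing, all-tied
  statistics give $p = 1$ everywhere, and an all-identical MDS axis
  returns a flagged degenerate single-cluster fit (all NI/NI,
  `converged = FALSE`).

## Problem sizes

The test and acceptance suites run at deliberately desk-sized scales chosen
so the asymptotics they check actually hold: 2,000-SNP/100-haplotype panels
for Fst recovery; 20 null cohorts of 5,000 SNPs for the deviation scan's
false-positive bound; 250 individuals for inversion-genotyping accuracy at
$d = 0.2$; 50,000 simulated SNPs for FCS calibration; and 10,000
permutations at $n = 100$ for Procrustes. Planted deviation loci span 1-3%
of the simulated genome — large enough to flag, small enough not to
contaminate the genome-wide mean and SD the scan standardizes against (a
planted locus spanning a fifth of a toy genome inflates $\sigma_a$ and
defeats any threshold; real loci are a vanishing fraction of a genome).

## Known limitations

* Local-ancestry inference itself is out of scope: calls are inputs, and
  the truth calls of the generator are perfectly accurate — real callers
  are not, especially near centromeres and inside inversions.
* The per-SNP Hudson Fst estimator is unbiased in its numerator and
  denominator separately, but the mean of per-SNP ratios is not an unbiased
  estimate of $F$ (Jensen bias; about 0.117 for a true $F = 0.15$ at these
  sizes). Windowed ratio-of-averages is the supported estimator for
  parameter-level statements.
* EM inversion genotyping assumes three dosage clusters separate along MDS
  axis 1; a 2-axis mode exists but projects onto the leading principal
  axis. Regions without suppressed recombination will not cluster and the
  genotypes are then meaningless (the degenerate-fit flag catches only the
  extreme case).
* FCS combines dependent statistics; its χ² null is exact only under
  independence. The empirical-percentile outlier scheme is what makes the
  genome-wide calls calibrated, not the χ² form.
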