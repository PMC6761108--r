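#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  Defaults emulate a
#' recently admixed, European-majority three-way cohort: admixture
#' proportions around 77/14/9 percent EUR/AFR/NAT, admixture g = 15
#' generations ago, and Balding-Nichols differentiation F = 0.15 between the
#' three ancestral populations.
#'
#' @param nSnps SNPs per chromosome.
#' @param chromLengthBp,chromLengthCm physical / genetic chromosome length.
#' @param chromosomes chromosome labels (each gets nSnps SNPs).
#' @param panelSize reference haplotypes per ancestral population.
#' @param cohortSize admixed individuals.
#' @param pops ancestry labels.
#' @param fDrift per-population Balding-Nichols drift parameter F in [0,1).
#' @param admixtureProps admixture proportions, must sum to 1.
#' @param generations generations since admixture (g >= 1).
#' @param founders founder haplotypes per population (within-population LD
#'   is created by copying panel haplotypes as founder mosaics).
#' @param founderSwitchRate founder switch rate, per Morgan.
#' @param deviationRegion,deviationProps optional planted ancestry-deviation
#'   locus: a \code{GRanges} and the target ancestry proportions inside it.
#' @param inversionRegion optional inversion-like polymorphism region.
#' @param inversionFreqs per-population inverted-class frequency.
#' @param inversionDivergence fraction d of region SNPs at which the two
#'   haplotype classes differ.
#' @param inversionNoise per-SNP within-class mismatch rate in the region.
#' @param seed global seed; every stage derives its own child seed from it.
#' @return a \code{simConfig} list.
#' @export
simConfig <- function(nSnps = 2000, chromLengthBp = 1e8, chromLengthCm = 100,
                      chromosomes = "1", panelSize = 50, cohortSize = 100,
                      pops = c("EUR", "AFR", "NAT"),
                      fDrift = c(0.15, 0.15, 0.15),
                      admixtureProps = c(0.77, 0.14, 0.09),
                      generations = 15,
                      founders = 100, founderSwitchRate = 1,
                      deviationRegion = NULL, deviationProps = NULL,
                      inversionRegion = NULL,
                      inversionFreqs = c(0.25, 0.1, 0.02),
                      inversionDivergence = 0.3, inversionNoise = 0.03,
                      seed = 1) {
  stopifnot(length(pops) == length(fDrift), length(pops) == length(admixtureProps))
  if (abs(sum(admixtureProps) - 1) > 1e-12) stop("admixtureProps must sum to 1")
  if (any(fDrift < 0 | fDrift >= 1)) stop("fDrift must lie in [0,1)")
  if (generations < 1) stop("generations must be >= 1")
  structure(list(nSnps = nSnps, chromLengthBp = chromLengthBp,
                 chromLengthCm = chromLengthCm, chromosomes = chromosomes,
                 panelSize = panelSize, cohortSize = cohortSize, pops = pops,
                 fDrift = fDrift,
                 admixtureProps = setNames(admixtureProps, pops),
                 generations = generations, founders = founders,
                 founderSwitchRate = founderSwitchRate,
                 deviationRegion = deviationRegion,
                 deviationProps = deviationProps,
                 inversionRegion = inversionRegion,
                 inversionFreqs = setNames(inversionFreqs, pops),
                 inversionDivergence = inversionDivergence,
                 inversionNoise = inversionNoise, seed = seed),
            class = "simConfig")
}

# shared SNP metadata for all simulated panels: sorted uniform positions,
# constant cM/bp rate, random A/C/G/T alleles, ancestral = ref by construction
simSnpMeta <- function(config) {
  set.seed(deriveSeed(config$seed, "snp-meta"))
  out <- lapply(config$chromosomes, function(ch) {
    pos <- sort(sample.int(config$chromLengthBp - 2L, config$nSnps)) + 1L
    # unambiguous ref/alt pairs only (array QC drops A/T and G/C sites anyway)
    pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
    pick <- pairs[sample.int(4, config$nSnps, replace = TRUE), , drop = FALSE]
    swap <- runif(config$nSnps) < 0.5
    alle <- rbind(ifelse(swap, pick[, 2], pick[, 1]),
                  ifelse(swap, pick[, 1], pick[, 2]))
    data.frame(chrom = ch, pos = pos,
               id = paste0("snp_", ch, "_", seq_len(config$nSnps)),
               ref = alle[1, ], alt = alle[2, ], ancestral = "ref",
               cm = pos / config$chromLengthBp * config$chromLengthCm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# one population's haplotypes: founders drawn Bernoulli(popFreq), panel
# haplotypes are founder mosaics with switch rate rho per Morgan
mosaicPanel <- function(popFreq, nHap, nFounders, rho, cm) {
  M <- length(popFreq)
  founders <- matrix(rbinom(nFounders * M, 1L, rep(popFreq, each = nFounders)),
                     nrow = nFounders)
  dMorgan <- c(0, diff(cm)) / 100
  h <- matrix(0L, nrow = nHap, ncol = M)
  for (i in seq_len(nHap)) {
    sw <- c(TRUE, runif(M - 1) < 1 - exp(-rho * dMorgan[-1]))
    fid <- sample.int(nFounders, sum(sw), replace = TRUE)
    idx <- cumsum(sw)
    h[i, ] <- founders[cbind(fid[idx], seq_len(M))]
  }
  h
}

#' Simulate ancestral reference panels
#'
#' Draws per-population allele frequencies under the Balding-Nichols model
#' (ancestral frequency p ~ Uniform(0.05, 0.95); population frequency ~
#' Beta(p(1-F)/F, (1-p)(1-F)/F), with F = 0 meaning the populations share p
#' exactly), then builds each panel haplotype as a mosaic of founder
#' haplotypes so the panels carry within-population LD.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with one \linkS4class{HaplotypePanel} per population
#'   (\code{$panels}), the shared SNP table (\code{$snps}), and the true
#'   per-population allele frequencies (\code{$popFreqs}).
#' @export
simulateReferencePanels <- function(config) {
  snps <- simSnpMeta(config)
  M <- nrow(snps)
  set.seed(deriveSeed(config$seed, "panel-freqs"))
  pAnc <- runif(M, 0.05, 0.95)
  popFreqs <- sapply(seq_along(config$pops), function(k) {
    F <- config$fDrift[k]
    if (F == 0) pAnc else rbeta(M, pAnc * (1 - F) / F, (1 - pAnc) * (1 - F) / F)
  })
  colnames(popFreqs) <- config$pops
  panels <- lapply(seq_along(config$pops), function(k) {
    set.seed(deriveSeed(config$seed, paste0("panel-", config$pops[k])))
    h <- mosaicPanel(popFreqs[, k], config$panelSize, config$founders,
                     config$founderSwitchRate, snps$cm)
    HaplotypePanel(h, snps,
                   individualIds = paste0(config$pops[k], seq_len(config$panelSize / 2)),
                   pop = config$pops[k])
  })
  names(panels) <- config$pops
  list(panels = panels, snps = snps, popFreqs = popFreqs)
}
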