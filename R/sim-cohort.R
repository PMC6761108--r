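#' Simulate an admixed cohort with known ancestry tracts
#'
#' Each admixed haplotype's local ancestry is a Markov process along the
#' genetic map: over a map increment of D Morgans the ancestry is redrawn
#' from the admixture proportions with probability 1 - exp(-gD) (so a redraw
#' may silently keep the same ancestry; the expected number of observed
#' switches per haplotype is about g x map length x (1 - sum(pi^2))).
#' Alleles are copied from a uniformly chosen reference haplotype of the
#' segment's ancestry, so within-ancestry LD is preserved.
#'
#' @param panels named list of reference \linkS4class{HaplotypePanel}s (one
#'   per ancestry, as from \code{\link{simulateReferencePanels}}).
#' @param config a \code{\link{simConfig}}.
#' @return list with the admixed \code{$cohort} (\linkS4class{HaplotypePanel})
#'   and the ground-truth \code{$truth} (\linkS4class{AncestryCalls}, all
#'   posteriors 1).
#' @export
simulateAdmixedCohort <- function(panels, config) {
  pi <- config$admixtureProps
  for (k in seq_along(pi))
    if (pi[k] > 0 && nrow(haplotypes(panels[[config$pops[k]]])) == 0)
      stop("admixture proportion > 0 for ", config$pops[k], " but its panel is empty")
  snps <- snpInfo(panels[[1]])
  M <- nrow(snps)
  nHap <- 2L * config$cohortSize
  chromId <- as.integer(factor(snps$chrom, levels = unique(snps$chrom)))
  dMorgan <- c(0, diff(snps$cm)) / 100
  dMorgan[c(TRUE, diff(chromId) != 0)] <- Inf   # independent across chromosomes
  g <- config$generations
  set.seed(deriveSeed(config$seed, "cohort"))
  codes <- matrix(0L, nrow = nHap, ncol = M)
  h <- matrix(0L, nrow = nHap, ncol = M)
  pSwitch <- 1 - exp(-g * dMorgan[-1])
  for (i in seq_len(nHap)) {
    redraw <- c(TRUE, runif(M - 1) < pSwitch)
    seg <- cumsum(redraw)
    anc <- sample.int(length(pi), max(seg), replace = TRUE, prob = pi)
    codes[i, ] <- anc[seg]
    donor <- vapply(seq_len(max(seg)), function(s) {
      sample.int(nrow(haplotypes(panels[[anc[s]]])), 1L)
    }, integer(1))
    for (s in seq_len(max(seg))) {
      jj <- which(seg == s)
      h[i, jj] <- haplotypes(panels[[anc[s]]])[donor[s], jj]
    }
  }
  cohort <- HaplotypePanel(h, snps,
                           individualIds = paste0("adm", seq_len(config$cohortSize)),
                           pop = "ADMIXED")
  truth <- AncestryCalls(codes, snps, labels = config$pops)
  list(cohort = cohort, truth = truth)
}

#' Plant an ancestry-deviation locus
#'
#' Post-hoc tract resampling: inside the region each selected haplotype's
#' ancestry is redrawn from \code{targetProps} and its alleles re-copied from
#' a random reference haplotype of the new ancestry; outside the region
#' nothing changes.  This targets the deviation scan's detection contract
#' (an ancestry-proportion shift), not evolutionary realism.
#'
#' @param cohort admixed \linkS4class{HaplotypePanel}.
#' @param truth ground-truth \linkS4class{AncestryCalls}.
#' @param panels reference panels (allele source).
#' @param region \code{GRanges} to modify.
#' @param targetProps target ancestry proportions inside the region (sums to 1).
#' @param haplotypes haplotype row indices to modify (default all; used to
#'   plant signals confined to one inversion stratum).
#' @param seed RNG seed.
#' @return list with modified \code{$cohort} and \code{$truth}.
#' @export
injectAncestryDeviation <- function(cohort, truth, panels, region, targetProps,
                                    haplotypes = NULL, seed = 1) {
  if (abs(sum(targetProps) - 1) > 1e-12) stop("targetProps must sum to 1")
  snps <- snpInfo(cohort)
  j <- snpsInRegion(snps, region)
  if (!length(j)) return(list(cohort = cohort, truth = truth))
  h <- cohort@haplotypes
  codes <- truth@codes
  if (is.null(haplotypes)) haplotypes <- seq_len(nrow(h))
  set.seed(deriveSeed(seed, "deviation"))
  for (i in haplotypes) {
    a <- sample.int(length(targetProps), 1L, prob = targetProps)
    donor <- sample.int(nrow(panels[[a]]@haplotypes), 1L)
    h[i, j] <- panels[[a]]@haplotypes[donor, j]
    codes[i, j] <- a
  }
  list(cohort = HaplotypePanel(h, snps, individualIds = cohort@individualIds,
                               pop = cohort@pop),
       truth = AncestryCalls(codes, snps, labels = truth@labels))
}

#' Plant an inversion-like long-range-LD polymorphism
#'
#' Builds two deeply diverged haplotype classes (NI and I) that differ at a
#' fraction \code{d} of the region's SNPs and suppresses recombination
#' between them: every reference haplotype is assigned a class with its
#' population's inverted-class frequency and has its region alleles rewritten
#' as a copy of the class haplotype (with a small per-SNP mismatch rate for
#' within-class diversity), and every cohort haplotype re-copies the whole
#' region from a class-consistent reference haplotype of its local ancestry
#' at the region.
#'
#' @param panels reference panels (modified in the output).
#' @param cohort admixed cohort panel.
#' @param truth ground-truth \linkS4class{AncestryCalls}.
#' @param region inversion region (\code{GRanges}).
#' @param classFreqs named per-population inverted-class frequency.
#' @param d fraction of region SNPs at which the classes differ, in (0,1].
#' @param noise per-SNP within-class mismatch rate (default 0.03).
#' @param seed RNG seed.
#' @return list with modified \code{$panels}, \code{$cohort}, \code{$truth},
#'   per-haplotype panel classes \code{$panelClass}, cohort haplotype classes
#'   \code{$invClass} ("NI"/"I"), per-individual \code{$invGenotypes}
#'   (factor NI/NI, NI/I, I/I) and the divergent site indices.
#' @export
injectInversion <- function(panels, cohort, truth, region, classFreqs, d,
                            noise = 0.03, seed = 1) {
  if (d <= 0 || d > 1) stop("d must lie in (0,1]")
  snps <- snpInfo(cohort)
  j <- snpsInRegion(snps, region)
  if (!length(j)) stop("inversion region contains no SNPs")
  set.seed(deriveSeed(seed, "inversion"))
  nDiv <- max(1L, round(d * length(j)))
  divIdx <- sort(sample.int(length(j), nDiv))
  baseNI <- rbinom(length(j), 1L, 0.5)
  baseI <- baseNI
  baseI[divIdx] <- 1L - baseI[divIdx]
  classHap <- function(cls, n) {
    base <- if (cls == "I") baseI else baseNI
    flips <- matrix(rbinom(n * length(j), 1L, noise), nrow = n)
    (matrix(base, nrow = n, ncol = length(j), byrow = TRUE) + flips) %% 2L
  }
  panelClass <- list()
  for (p in names(panels)) {
    nH <- nrow(panels[[p]]@haplotypes)
    cls <- ifelse(runif(nH) < classFreqs[[p]], "I", "NI")
    for (cl in c("NI", "I")) {
      rows <- which(cls == cl)
      if (length(rows))
        panels[[p]]@haplotypes[rows, j] <- classHap(cl, length(rows))
    }
    panelClass[[p]] <- cls
  }
  h <- cohort@haplotypes
  codes <- truth@codes
  nHap <- nrow(h)
  invClass <- character(nHap)
  for (i in seq_len(nHap)) {
    a <- codes[i, j[1]]                 # region inherited as one ancestry tract
    donor <- sample.int(nrow(panels[[a]]@haplotypes), 1L)
    h[i, j] <- panels[[a]]@haplotypes[donor, j]
    codes[i, j] <- a
    invClass[i] <- panelClass[[a]][donor]
  }
  nI <- (invClass[seq(1, nHap, 2)] == "I") + (invClass[seq(2, nHap, 2)] == "I")
  invGenotypes <- factor(c("NI/NI", "NI/I", "I/I")[nI + 1L],
                         levels = c("NI/NI", "NI/I", "I/I"))
  names(invGenotypes) <- cohort@individualIds
  list(panels = panels,
       cohort = HaplotypePanel(h, snps, individualIds = cohort@individualIds,
                               pop = cohort@pop),
       truth = AncestryCalls(codes, snps, labels = truth@labels),
       panelClass = panelClass, invClass = invClass,
       invGenotypes = invGenotypes, divergentSites = j[divIdx], regionSnps = j)
}
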