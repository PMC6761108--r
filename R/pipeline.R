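#' Run the full post-admixture selection pipeline
#'
#' Orchestrates the stages in their analysis order: QC, per-SNP ancestry
#' proportions and the deviation scan, inversion genotyping, stratified
#' rescans, the five selection statistics per reference configuration, the
#' Fisher-combined-score scan with region labelling, and the Procrustes
#' comparison of the focal region against random length-matched regions.
#' All stochastic stages derive child seeds deterministically from the
#' config seed, so identical configs give identical output.
#'
#' @param config either a \code{\link{simConfig}} (synthetic run with ground
#'   truth), a path to a YAML file, or a list with an \code{inputs} block
#'   naming a phased cohort VCF, a genetic map TSV and an msp-style
#'   ancestry-calls TSV.
#' @param selection run the selection-statistic + FCS stages (default TRUE).
#' @param procrustes run the random-region Procrustes stage (needs an
#'   inversion/focal region; default TRUE).
#' @param nRandomRegions regions for the Procrustes stage (default 7).
#' @param nPerm Procrustes permutations (default 999 inside the pipeline).
#' @param globalProps optional individuals x ancestry global-ancestry matrix
#'   for the concordance check (defaults to the truth means on synthetic
#'   runs).
#' @return a named list report bundle.
#' @export
runPipeline <- function(config, selection = TRUE, procrustes = TRUE,
                        nRandomRegions = 7, nPerm = 999, globalProps = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sim <- NULL
  if (inherits(config, "simConfig")) {
    sim <- config
  } else if (!is.null(config$simulation)) {
    simArgs <- config$simulation
    for (rg in c("deviationRegion", "inversionRegion"))
      if (!is.null(simArgs[[rg]]) && !is(simArgs[[rg]], "GRanges"))
        simArgs[[rg]] <- do.call(regionInterval, simArgs[[rg]])
    # YAML scalars like 1.0e7 arrive as strings; coerce the numeric fields
    numFields <- c("nSnps", "chromLengthBp", "chromLengthCm", "panelSize",
                   "cohortSize", "fDrift", "admixtureProps", "generations",
                   "founders", "founderSwitchRate", "deviationProps",
                   "inversionFreqs", "inversionDivergence", "inversionNoise",
                   "seed")
    for (f in intersect(numFields, names(simArgs)))
      simArgs[[f]] <- as.numeric(unlist(simArgs[[f]]))
    sim <- do.call(simConfig, simArgs)
  }
  if (!is.null(sim)) {
    ref <- simulateReferencePanels(sim)
    adm <- simulateAdmixedCohort(ref$panels, sim)
    panels <- ref$panels; cohort <- adm$cohort; truth <- adm$truth
    inv <- NULL
    if (!is.null(sim$inversionRegion)) {
      inv <- injectInversion(panels, cohort, truth, sim$inversionRegion,
                             sim$inversionFreqs, sim$inversionDivergence,
                             sim$inversionNoise, seed = sim$seed)
      panels <- inv$panels; cohort <- inv$cohort; truth <- inv$truth
    }
    if (!is.null(sim$deviationRegion)) {
      dev <- injectAncestryDeviation(cohort, truth, panels, sim$deviationRegion,
                                     sim$deviationProps, seed = sim$seed)
      cohort <- dev$cohort; truth <- dev$truth
    }
    calls <- truth
    focalRegion <- sim$inversionRegion %||% sim$deviationRegion
    devRegion <- sim$deviationRegion
  } else {
    inp <- config$inputs
    if (is.null(inp)) stop("config needs a simulation block or an inputs block")
    if (is.null(inp$map)) stop("config missing genetic map")
    if (is.null(inp$vcf)) stop("config missing phased cohort VCF")
    if (is.null(inp$calls)) stop("config missing ancestry calls")
    cohort <- parsePhasedVcf(inp$vcf, pop = "cohort")
    cohort <- attachGeneticMap(cohort, readGeneticMap(inp$map))
    calls <- readAncestryCalls(inp$calls, snpInfo(cohort),
                               posteriorPath = inp$posteriors)
    if (nrow(calls@codes) != 2L * nIndividuals(cohort))
      stop("inconsistent inputs: calls cover ", nrow(calls@codes),
           " haplotypes but the VCF has ", 2L * nIndividuals(cohort))
    if (nSnps(calls) != nSnps(cohort))
      stop("inconsistent SNP sets between VCF and ancestry calls")
    panels <- lapply(inp$panels %||% list(), parsePhasedVcf)
    truth <- NULL; inv <- NULL
    focalRegion <- if (!is.null(inp$focalRegion))
      do.call(regionInterval, inp$focalRegion) else NULL
    devRegion <- focalRegion
  }
  report <- list(config = config, snps = snpInfo(cohort))

  ## QC ledger (site filters on the cohort)
  report$qc <- applySiteFilters(cohort)

  ## ancestry-proportion track and deviation scan
  track <- ancestryProportions(calls)
  report$track <- track
  report$scan <- deviationScan(track)
  if (!is.null(devRegion))
    report$audit <- tractPosteriorAudit(calls, devRegion)
  localMeans <- individualAncestryMeans(calls)
  if (is.null(globalProps) && !is.null(sim)) globalProps <- localMeans
  if (!is.null(globalProps))
    report$concordance <- globalLocalConcordance(localMeans, globalProps)

  ## inversion genotyping + stratified rescans
  if (!is.null(sim) && !is.null(sim$inversionRegion)) {
    j <- snpsInRegion(snpInfo(cohort), sim$inversionRegion)
    emb <- classicalMds(1 - ibsMatrix(cohort, j)$ibs, k = 2)
    geno <- emInversionGenotypes(emb, individualIds = individualIds(cohort))
    acc <- mean(as.character(genotypeCalls(geno)) ==
                as.character(inv$invGenotypes))
    report$inversion <- list(genotypes = geno, truthAccuracy = acc,
                             truthGenotypes = inv$invGenotypes)
    report$stratified <- lapply(setNames(c("NI/NI", "I/I"), c("NI/NI", "I/I")),
      function(st) {
        n <- sum(as.character(genotypeCalls(geno)) == st)
        if (n == 0) return(NULL)
        stratifiedScan(calls, genotypeCalls(geno), st)
      })
  }

  ## selection statistics + FCS per reference configuration
  if (selection) {
    pops <- names(panels)
    intra <- intrapopScan(cohort, config = "shared")
    cohortFreq <- alleleFreqs(cohort)
    panelFreq <- lapply(panels, alleleFreqs)
    report$statTracks <- list()
    report$fcs <- list()
    for (ref in pops) {
      inter <- interpopScan(cohort, panels[[ref]], config = ref)
      outgroup <- setdiff(pops, ref)[1]
      fstTR <- hudsonFst(cohortFreq$p, cohortFreq$n,
                         panelFreq[[ref]]$p, panelFreq[[ref]]$n)
      fstTO <- hudsonFst(cohortFreq$p, cohortFreq$n,
                         panelFreq[[outgroup]]$p, panelFreq[[outgroup]]$n)
      fstRO <- hudsonFst(panelFreq[[ref]]$p, panelFreq[[ref]]$n,
                         panelFreq[[outgroup]]$p, panelFreq[[outgroup]]$n)
      pbsRaw <- pbs(fstTR, fstTO, fstRO)
      pbsTrack <- StatTrack("PBS", ref, snpInfo(cohort), pbsRaw, pbsRaw)
      tracks <- list(iHS = intra$iHS, diHH = intra$diHH,
                     XPEHH = inter$XPEHH, diHH_derived = inter$diHH_derived,
                     PBS = pbsTrack)
      report$statTracks[[ref]] <- tracks
      report$fcs[[ref]] <- fcsScan(tracks, snpInfo(cohort))
    }
    report$regionLabels <- labelRegions(report$fcs)
  }

  ## Procrustes corroboration against random length-matched regions
  if (procrustes && !is.null(focalRegion)) {
    lenBp <- regionLength(focalRegion, "bp")
    jF <- snpsInRegion(snpInfo(cohort), focalRegion)
    embF <- classicalMds(1 - ibsMatrix(cohort, jF)$ibs, k = 2)
    rnd <- sampleRandomRegions(snpInfo(cohort), lenBp, n = nRandomRegions,
                               exclude = focalRegion,
                               seed = deriveSeed(config$seed %||% 1, "regions"))
    report$procrustes <- do.call(rbind, lapply(seq_along(rnd), function(k) {
      jr <- snpsInRegion(snpInfo(cohort), rnd[k])
      if (length(jr) < 3) return(NULL)
      embR <- classicalMds(1 - ibsMatrix(cohort, jr)$ibs, k = 2)
      pr <- procrustesProtest(embF$points, embR$points, nPerm = nPerm,
                              seed = deriveSeed(config$seed %||% 1,
                                                paste0("protest", k)))
      data.frame(chrom = as.character(GenomicRanges::seqnames(rnd[k])),
                 startBp = GenomicRanges::start(rnd[k]),
                 endBp = GenomicRanges::end(rnd[k]),
                 correlation = pr@correlation, pValue = pr@pValue,
                 nPerm = pr@nPerm)
    }))
  }
  class(report) <- "admixscanReport"
  report
}

#' @export
print.admixscanReport <- function(x, ...) {
  cat("admixscan pipeline report\n")
  cat(sprintf("  SNPs: %d; QC remaining: %d\n", nrow(x$snps),
              remaining(x$qc$ledger)))
  cat(sprintf("  deviation intervals: %d\n", length(x$scan$intervals)))
  if (!is.null(x$inversion))
    cat(sprintf("  inversion genotyping accuracy vs truth: %.3f\n",
                x$inversion$truthAccuracy))
  if (!is.null(x$fcs))
    for (ref in names(x$fcs))
      cat(sprintf("  FCS [%s]: %d called blocks\n", ref,
                  sum(x$fcs[[ref]]@blocks$called)))
  if (!is.null(x$procrustes))
    cat(sprintf("  Procrustes correlations vs %d random regions: %s\n",
                nrow(x$procrustes),
                paste(sprintf("%.3f", x$procrustes$correlation), collapse = ", ")))
  invisible(x)
}

#' Write a pipeline report bundle as TSV tables
#'
#' @param report a \code{runPipeline} result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writePipelineReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  led <- report$qc$ledger
  w(data.frame(category = c(names(removals(led)), "remaining"),
               count = c(removals(led), remaining(led))), "qc_ledger.tsv")
  w(cbind(report$track$snps, report$track$props), "ancestry_track.tsv")
  iv <- report$scan$intervals
  if (length(iv))
    w(data.frame(chrom = as.character(GenomicRanges::seqnames(iv)),
                 startBp = GenomicRanges::start(iv),
                 endBp = GenomicRanges::end(iv),
                 as.data.frame(GenomicRanges::mcols(iv))),
      "deviation_intervals.tsv")
  if (!is.null(report$inversion))
    w(data.frame(id = individualIds(report$inversion$genotypes),
                 call = as.character(genotypeCalls(report$inversion$genotypes)),
                 classPosteriors(report$inversion$genotypes)),
      "inversion_genotypes.tsv")
  if (!is.null(report$fcs))
    for (ref in names(report$fcs)) {
      w(report$fcs[[ref]]@perSnp, paste0("fcs_", ref, ".tsv"))
      w(report$fcs[[ref]]@blocks, paste0("fcs_blocks_", ref, ".tsv"))
    }
  if (!is.null(report$regionLabels)) w(report$regionLabels, "called_regions.tsv")
  if (!is.null(report$procrustes)) w(report$procrustes, "procrustes.tsv")
  invisible(dir)
}
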