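#' @name admixscan-accessors
#' @title Accessors for admixscan classes
#' @param x,object an admixscan object.
#' @param ... unused.
NULL

#' @rdname admixscan-accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname admixscan-accessors
#' @export
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)

#' @rdname admixscan-accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname admixscan-accessors
#' @export
setMethod("snpInfo", "HaplotypePanel", function(x) x@snps)
#' @rdname admixscan-accessors
#' @export
setMethod("snpInfo", "AncestryCalls", function(x) x@snps)
#' @rdname admixscan-accessors
#' @export
setMethod("snpInfo", "StatTrack", function(x) x@snps)

#' @rdname admixscan-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @rdname admixscan-accessors
#' @export
setMethod("individualIds", "HaplotypePanel", function(x) x@individualIds)
#' @rdname admixscan-accessors
#' @export
setMethod("individualIds", "InversionGenotypes", function(x) x@individualIds)

#' @rdname admixscan-accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname admixscan-accessors
#' @export
setMethod("nIndividuals", "HaplotypePanel", function(x) length(x@individualIds))

#' @rdname admixscan-accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname admixscan-accessors
#' @export
setMethod("nSnps", "HaplotypePanel", function(x) ncol(x@haplotypes))
#' @rdname admixscan-accessors
#' @export
setMethod("nSnps", "AncestryCalls", function(x) ncol(x@codes))

#' Diploid dosage matrix of a panel
#'
#' Sums the two haplotype rows of each individual: dosages count the
#' non-ancestral (or ALT, when the ancestral state is unknown) allele, so
#' values lie in 0/1/2.
#'
#' @param x a \linkS4class{HaplotypePanel}.
#' @return integer matrix, individuals x SNPs.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname dosages
#' @export
setMethod("dosages", "HaplotypePanel", function(x) {
  h <- x@haplotypes
  d <- h[seq(1L, nrow(h), by = 2L), , drop = FALSE] +
       h[seq(2L, nrow(h), by = 2L), , drop = FALSE]
  rownames(d) <- x@individualIds
  d
})

#' @rdname admixscan-accessors
#' @export
setGeneric("ancestryCodes", function(x) standardGeneric("ancestryCodes"))
#' @rdname admixscan-accessors
#' @export
setMethod("ancestryCodes", "AncestryCalls", function(x) x@codes)

#' @rdname admixscan-accessors
#' @export
setGeneric("ancestryLabels", function(x) standardGeneric("ancestryLabels"))
#' @rdname admixscan-accessors
#' @export
setMethod("ancestryLabels", "AncestryCalls", function(x) x@labels)

#' @rdname admixscan-accessors
#' @export
setGeneric("tracts", function(x) standardGeneric("tracts"))
#' @rdname admixscan-accessors
#' @export
setMethod("tracts", "AncestryCalls", function(x) x@tracts)

#' @rdname admixscan-accessors
#' @export
setGeneric("statValues", function(x) standardGeneric("statValues"))
#' @rdname admixscan-accessors
#' @export
setMethod("statValues", "StatTrack", function(x) x@std)

#' @rdname admixscan-accessors
#' @export
setGeneric("rawValues", function(x) standardGeneric("rawValues"))
#' @rdname admixscan-accessors
#' @export
setMethod("rawValues", "StatTrack", function(x) x@raw)

#' @rdname admixscan-accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname admixscan-accessors
#' @export
setMethod("genotypeCalls", "InversionGenotypes", function(x) x@calls)

#' @rdname admixscan-accessors
#' @export
setGeneric("classPosteriors", function(x) standardGeneric("classPosteriors"))
#' @rdname admixscan-accessors
#' @export
setMethod("classPosteriors", "InversionGenotypes", function(x) x@posteriors)

#' @rdname admixscan-accessors
#' @export
setGeneric("removals", function(x) standardGeneric("removals"))
#' @rdname admixscan-accessors
#' @export
setMethod("removals", "QcLedger", function(x) x@removals)

#' @rdname admixscan-accessors
#' @export
setGeneric("remaining", function(x) standardGeneric("remaining"))
#' @rdname admixscan-accessors
#' @export
setMethod("remaining", "QcLedger", function(x) x@remaining)

#' Subset a panel by individuals and/or SNPs
#'
#' @param x a \linkS4class{HaplotypePanel}.
#' @param i individual indices (not haplotype rows).
#' @param j SNP (column) indices.
#' @param ... unused.
#' @param drop ignored.
#' @export
setMethod("[", "HaplotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nIndividuals(x))
  if (missing(j)) j <- seq_len(nSnps(x))
  if (is.logical(i)) i <- which(i)
  rows <- as.vector(rbind(2L * i - 1L, 2L * i))
  HaplotypePanel(x@haplotypes[rows, j, drop = FALSE],
                 x@snps[j, , drop = FALSE],
                 individualIds = x@individualIds[i], pop = x@pop)
})

#' Subset ancestry calls by individuals and/or SNPs
#'
#' @param x an \linkS4class{AncestryCalls}.
#' @param i individual indices (pairs of haplotype rows are kept together).
#' @param j SNP indices.
#' @param ... unused.
#' @param drop ignored.
#' @export
setMethod("[", "AncestryCalls", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@codes) / 2L)
  if (missing(j)) j <- seq_len(ncol(x@codes))
  if (is.logical(i)) i <- which(i)
  rows <- as.vector(rbind(2L * i - 1L, 2L * i))
  AncestryCalls(x@codes[rows, j, drop = FALSE], x@snps[j, , drop = FALSE],
                labels = x@labels)
})

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel '%s': %d individuals (%d haplotypes) x %d SNPs on %s\n",
              object@pop, nIndividuals(object), nrow(object@haplotypes),
              nSnps(object), paste(unique(object@snps$chrom), collapse = ",")))
})

setMethod("show", "AncestryCalls", function(object) {
  cat(sprintf("AncestryCalls: %d haplotypes x %d SNPs, %d tracts, labels %s\n",
              nrow(object@codes), ncol(object@codes), nrow(object@tracts),
              paste(object@labels, collapse = "/")))
})

setMethod("show", "StatTrack", function(object) {
  cat(sprintf("StatTrack %s [ref %s]: %d SNPs (%d missing)\n",
              object@statistic, object@config, nrow(object@snps),
              sum(is.na(object@std))))
})

setMethod("show", "FcsResult", function(object) {
  cat(sprintf("FcsResult: %d SNPs, %d outliers, %d/%d blocks called, %d regions\n",
              nrow(object@perSnp), sum(object@perSnp$outlier),
              sum(object@blocks$called), nrow(object@blocks),
              length(object@regions)))
})

setMethod("show", "InversionGenotypes", function(object) {
  tab <- table(object@calls)
  cat(sprintf("InversionGenotypes: %s; converged=%s\n",
              paste(names(tab), tab, sep = "=", collapse = ", "),
              object@converged))
})

setMethod("show", "ProcrustesResult", function(object) {
  cat(sprintf("Procrustes: correlation=%.4f (m2=%.4f), p=%.4g (%d permutations)\n",
              object@correlation, object@mSquared, object@pValue, object@nPerm))
})

setMethod("show", "QcLedger", function(object) {
  cat(sprintf("QcLedger: start=%d, remaining=%d\n", object@start, object@remaining))
  for (nm in names(object@removals))
    cat(sprintf("  - %-14s %d\n", nm, object@removals[[nm]]))
  if (nrow(object@individualRemovals))
    cat(sprintf("  individuals removed: %d\n", nrow(object@individualRemovals)))
})
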