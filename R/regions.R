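#' Genomic region interval
#'
#' Regions follow the printed-coordinate convention of locus reports in the
#' admixture-scan literature: 1-based inclusive endpoints, with length defined
#' as \code{end - start} (so the 15cen-q11.2 locus 20116146-20564575 bp has
#' length 448.4 kb).
#'
#' @param chrom chromosome label.
#' @param startBp,endBp 1-based endpoints, \code{startBp < endBp}.
#' @return A length-1 \code{GRanges}.
#' @examples
#' r <- regionInterval("8", 8092025, 11859740)
#' regionLength(r, "bp")
#' @export
regionInterval <- function(chrom, startBp, endBp) {
  startBp <- as.numeric(startBp)    # tolerate YAML strings like "4.0e6"
  endBp <- as.numeric(endBp)
  if (any(is.na(startBp)) || any(is.na(endBp))) stop("non-numeric coordinates")
  if (any(startBp >= endBp)) stop("startBp must be < endBp")
  GenomicRanges::GRanges(as.character(chrom), IRanges::IRanges(startBp, endBp))
}

#' Region length in bp, kb or Mb
#'
#' Length is \code{end - start} (coordinate difference, not inclusive width);
#' kb and Mb values are rounded to one decimal place as printed in locus
#' reports.
#'
#' @param region a \code{GRanges}.
#' @param unit one of "bp", "kb", "Mb".
#' @return numeric vector of lengths.
#' @examples
#' regionLength(regionInterval("15", 20116146, 20564575), "kb")  # 448.4
#' @export
regionLength <- function(region, unit = c("bp", "kb", "Mb")) {
  unit <- match.arg(unit)
  len <- GenomicRanges::end(region) - GenomicRanges::start(region)
  switch(unit,
         bp = len,
         kb = round(len / 1e3, 1),
         Mb = round(len / 1e6, 1))
}

# SNP column indices falling inside a region (inclusive endpoints)
snpsInRegion <- function(snps, region) {
  ch <- as.character(GenomicRanges::seqnames(region))[1]
  which(snps$chrom == ch &
        snps$pos >= GenomicRanges::start(region)[1] &
        snps$pos <= GenomicRanges::end(region)[1])
}

#' Sample random length-matched regions
#'
#' Draws \code{n} regions of exactly \code{lengthBp} coordinate length,
#' each fully within one chromosome of the SNP set's span, avoiding an
#' excluded interval.  Used to build the null set of regions against which a
#' focal locus's MDS configuration is compared by Procrustes rotation.
#'
#' @param snps data.frame with chrom and pos (defines per-chromosome spans).
#' @param lengthBp exact coordinate length of each region.
#' @param n number of regions (default 7).
#' @param exclude optional \code{GRanges} the sampled regions must not overlap.
#' @param seed RNG seed (sampling is deterministic given the seed).
#' @param allowOverlap may sampled regions overlap each other (default TRUE).
#' @param maxTries attempts before giving up (default 10000).
#' @return \code{GRanges} of \code{n} regions.
#' @export
sampleRandomRegions <- function(snps, lengthBp, n = 7, exclude = NULL,
                                seed = 1, allowOverlap = TRUE,
                                maxTries = 10000) {
  spans <- do.call(rbind, lapply(split(snps$pos, snps$chrom), range))
  spans <- data.frame(chrom = rownames(spans), lo = spans[, 1], hi = spans[, 2])
  spans <- spans[spans$hi - spans$lo >= lengthBp, , drop = FALSE]
  if (!nrow(spans)) stop("no chromosome long enough to fit a region of ", lengthBp, " bp")
  set.seed(deriveSeed(seed, "random-regions"))
  got <- GenomicRanges::GRanges()
  tries <- 0L
  while (length(got) < n) {
    tries <- tries + 1L
    if (tries > maxTries) stop("could not place ", n, " regions in ", maxTries, " attempts")
    i <- sample.int(nrow(spans), 1, prob = spans$hi - spans$lo - lengthBp + 1)
    s <- spans$lo[i] + floor(runif(1) * (spans$hi[i] - spans$lo[i] - lengthBp + 1))
    cand <- regionInterval(spans$chrom[i], s, s + lengthBp)
    # seqlevels may legitimately differ between candidate and exclude/got;
    # disjoint levels simply mean no overlap
    if (!is.null(exclude) &&
        length(suppressWarnings(GenomicRanges::findOverlaps(cand, exclude))) > 0)
      next
    if (!allowOverlap && length(got) &&
        length(suppressWarnings(GenomicRanges::findOverlaps(cand, got))) > 0)
      next
    got <- suppressWarnings(c(got, cand))
  }
  got
}
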