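#' Empirical p-values from a statistic track
#'
#' p = genomic rank / N, where rank 1 is the most extreme value in the
#' selection direction and tied values take the maximum rank of their tie
#' group (so p is always in [1/N, 1] and never 0).  Missing statistic values
#' get p = 1 (no evidence) so the SNP set stays stable across statistics.
#'
#' @param track a \linkS4class{StatTrack} or numeric vector of standardized
#'   values.
#' @param tail "upper" (large values = selection, the default) or "lower".
#' @return numeric vector of empirical p-values.
#' @export
empiricalPvalues <- function(track, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  x <- if (is(track, "StatTrack")) track@std else as.numeric(track)
  if (tail == "lower") x <- -x
  ok <- !is.na(x)
  if (sum(ok) < 1) stop("no usable values")
  p <- rep(1, length(x))
  N <- sum(ok)
  p[ok] <- rank(-x[ok], ties.method = "max") / N
  p
}

#' Fisher combined score
#'
#' FCS = sum over statistics of -log10(p_i).  Under independent uniform
#' p-values, 2 ln(10) FCS follows a chi-square distribution with 2k degrees
#' of freedom.
#'
#' @param p matrix of p-values (SNPs x statistics), all in (0, 1].
#' @return numeric FCS per SNP (non-negative, finite).
#' @examples
#' fisherCombinedScore(matrix(c(0.1, 0.01, 1, 1, 1), nrow = 1))  # 3
#' @export
fisherCombinedScore <- function(p) {
  p <- as.matrix(p)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  rowSums(-log10(p))
}

#' Outlier SNPs and 100-SNP block scan
#'
#' Flags the top \code{floor((1 - outlierQ) * N)} SNPs by FCS rank as
#' outliers (exactly 1\% for tie-free values with the default
#' \code{outlierQ = 0.99}), tiles each chromosome into consecutive
#' \code{blockSize}-SNP blocks (final partial block kept; its proportion
#' uses its actual size), and calls a block a selection region when its
#' outlier proportion strictly exceeds the higher-type
#' \code{blockPct}-percentile of all block proportions.
#'
#' @param fcs numeric FCS per SNP, ordered by chromosome and position.
#' @param snps data.frame with chrom and pos (same order).
#' @param pMatrix optional p-value matrix stored alongside.
#' @param blockSize SNPs per block (default 100).
#' @param outlierQ outlier quantile (default 0.99: top 1\%).
#' @param blockPct percentile of block proportions for region calls
#'   (default 99.5).
#' @return an \linkS4class{FcsResult}.
#' @export
outlierBlockScan <- function(fcs, snps, pMatrix = NULL, blockSize = 100,
                             outlierQ = 0.99, blockPct = 99.5) {
  N <- length(fcs)
  if (N < blockSize) stop("need at least ", blockSize, " SNPs genome-wide")
  nOut <- floor((1 - outlierQ) * N)
  outlier <- rep(FALSE, N)
  outlier[order(-fcs)[seq_len(nOut)]] <- TRUE
  chromId <- as.integer(factor(snps$chrom, levels = unique(snps$chrom)))
  blockId <- paste(chromId, ave(seq_len(N), chromId,
                                FUN = function(i) (seq_along(i) - 1) %/% blockSize))
  blockId <- factor(blockId, levels = unique(blockId))
  idx <- split(seq_len(N), blockId)
  blocks <- do.call(rbind, lapply(idx, function(i) {
    data.frame(chrom = snps$chrom[i[1]], startBp = snps$pos[i[1]],
               endBp = snps$pos[i[length(i)]], size = length(i),
               nOutlier = sum(outlier[i]))
  }))
  rownames(blocks) <- NULL
  blocks$prop <- blocks$nOutlier / blocks$size
  thr <- sort(blocks$prop)[ceiling(blockPct / 100 * nrow(blocks))]
  blocks$called <- blocks$prop > thr
  regions <- if (any(blocks$called)) {
    b <- blocks[blocks$called, ]
    gr <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$startBp, b$endBp))
    GenomicRanges::mcols(gr)$prop <- b$prop
    gr
  } else GenomicRanges::GRanges()
  perSnp <- data.frame(chrom = snps$chrom, pos = snps$pos, fcs = fcs,
                       outlier = outlier)
  if (!is.null(pMatrix)) perSnp <- cbind(perSnp, as.data.frame(pMatrix))
  new("FcsResult", perSnp = perSnp, blocks = blocks, blockThreshold = thr,
      regions = regions)
}

#' Combine the five statistic tracks of one configuration into an FCS scan
#'
#' @param tracks list of \linkS4class{StatTrack}s sharing one SNP set.
#' @param snps SNP table (chrom, pos) in scan order.
#' @param ... passed to \code{\link{outlierBlockScan}}.
#' @return an \linkS4class{FcsResult}.
#' @export
fcsScan <- function(tracks, snps, ...) {
  p <- sapply(tracks, empiricalPvalues)
  colnames(p) <- paste0("p_", vapply(tracks, function(t) t@statistic, ""))
  outlierBlockScan(fisherCombinedScore(p), snps, pMatrix = p, ...)
}

#' Label called regions by reference configuration
#'
#' Region calls obtained under the configuration using reference panel X are
#' labelled X; blocks called under several configurations get compound
#' "X or Y" labels.  All configurations must share one block tiling.
#'
#' @param results named list of \linkS4class{FcsResult}s, one per
#'   reference-configuration label.
#' @return data.frame of called blocks (chrom, startBp, endBp) with an
#'   \code{ancestry} label column.
#' @export
labelRegions <- function(results) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  b0 <- results[[1]]@blocks
  for (r in results)
    if (!identical(r@blocks[, c("chrom", "startBp", "endBp")],
                   b0[, c("chrom", "startBp", "endBp")]))
      stop("configurations must share one block tiling")
  calls <- sapply(results, function(r) r@blocks$called)
  hit <- rowSums(calls) > 0
  if (!any(hit)) return(data.frame(chrom = character(0), startBp = integer(0),
                                   endBp = integer(0), ancestry = character(0)))
  lab <- apply(calls[hit, , drop = FALSE], 1, function(v)
    paste(names(results)[v], collapse = " or "))
  data.frame(b0[hit, c("chrom", "startBp", "endBp")], ancestry = lab,
             row.names = NULL)
}
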