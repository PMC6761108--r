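#' Per-SNP ancestry-proportion track
#'
#' For each SNP, the fraction of included haplotypes assigned to each
#' ancestry (rows of the matrix sum to 1).
#'
#' @param calls an \linkS4class{AncestryCalls}.
#' @param subset optional individual indices; both haplotypes of each
#'   selected individual are included.
#' @return list with \code{snps}, \code{props} (SNP x ancestry matrix) and
#'   \code{nHaplotypes}.
#' @export
ancestryProportions <- function(calls, subset = NULL) {
  codes <- calls@codes
  if (!is.null(subset)) {
    if (!length(subset)) stop("empty individual subset")
    rows <- as.vector(rbind(2L * subset - 1L, 2L * subset))
    codes <- codes[rows, , drop = FALSE]
  }
  A <- length(calls@labels)
  props <- sapply(seq_len(A), function(a) colMeans(codes == a))
  colnames(props) <- calls@labels
  list(snps = calls@snps, props = props, nHaplotypes = nrow(codes))
}

#' Genome-wide ancestry-deviation scan
#'
#' Standardizes each ancestry's proportion track against its genome-wide
#' mean and SD and flags SNPs beyond \code{thresholdSd} standard deviations
#' in either direction (excess or deficit).  Under a standard-normal null
#' the default threshold of 4.42 SD corresponds to a two-sided per-SNP
#' false-positive rate below 1e-5.  Adjacent flagged SNPs of the same
#' ancestry, direction and chromosome are merged into intervals.
#'
#' @param track output of \code{\link{ancestryProportions}}.
#' @param thresholdSd flagging threshold in genome-wide SDs (default 4.42).
#' @return list with per-ancestry \code{mean} and \code{sd}, the z-score
#'   matrix \code{z}, logical \code{flagged}, a \code{direction} matrix
#'   ("excess"/"deficit"/NA), and merged \code{intervals} (\code{GRanges}
#'   with ancestry, direction, nSnps and maxAbsZ columns).
#' @export
deviationScan <- function(track, thresholdSd = 4.42) {
  props <- track$props
  if (nrow(props) < 2) stop("need at least 2 SNPs")
  mu <- colMeans(props)
  sig <- apply(props, 2, sd)
  z <- sweep(sweep(props, 2, mu), 2, ifelse(sig > 0, sig, Inf), "/")
  flagged <- abs(z) > thresholdSd
  direction <- matrix(NA_character_, nrow(z), ncol(z), dimnames = dimnames(z))
  direction[flagged & z > 0] <- "excess"
  direction[flagged & z < 0] <- "deficit"
  intervals <- GenomicRanges::GRanges()
  snps <- track$snps
  for (a in colnames(props)) {
    for (dir in c("excess", "deficit")) {
      hit <- !is.na(direction[, a]) & direction[, a] == dir
      if (!any(hit)) next
      key <- paste(snps$chrom, hit)
      r <- rle(key)
      e <- cumsum(r$lengths)
      s <- c(1L, head(e, -1L) + 1L)
      runs <- which(hit[s])
      for (k in runs) {
        iv <- GenomicRanges::GRanges(snps$chrom[s[k]],
                                     IRanges::IRanges(snps$pos[s[k]], snps$pos[e[k]]))
        GenomicRanges::mcols(iv) <- data.frame(
          ancestry = a, direction = dir, nSnps = e[k] - s[k] + 1L,
          maxAbsZ = max(abs(z[s[k]:e[k], a])))
        intervals <- c(intervals, iv)
      }
    }
  }
  list(mean = mu, sd = sig, z = z, flagged = flagged, direction = direction,
       thresholdSd = thresholdSd, intervals = intervals)
}

#' Audit tract posterior probabilities over a region
#'
#' Counts the ancestry tracts intersecting a region and how many of them
#' carry a posterior probability below the cutoff — low-posterior tracts in
#' a flagged region suggest an inference artefact (e.g. near a centromere)
#' rather than a real ancestry shift.
#'
#' @param calls an \linkS4class{AncestryCalls}.
#' @param region a \code{GRanges}.
#' @param cutoff posterior cutoff (default 0.9).
#' @return list with \code{nTracts} and \code{nBelow}.
#' @export
tractPosteriorAudit <- function(calls, region, cutoff = 0.9) {
  j <- snpsInRegion(calls@snps, region)
  if (!length(j)) stop("region overlaps no SNPs")
  tr <- calls@tracts
  hit <- tr$startSnp <= max(j) & tr$endSnp >= min(j)
  list(nTracts = sum(hit), nBelow = sum(hit & tr$posterior < cutoff))
}

#' Per-individual mean local ancestry
#'
#' @param calls an \linkS4class{AncestryCalls}.
#' @return individuals x ancestry matrix of genome-wide mean local-ancestry
#'   proportions (both haplotypes averaged).
#' @export
individualAncestryMeans <- function(calls) {
  codes <- calls@codes
  n <- nrow(codes) / 2L
  out <- sapply(seq_along(calls@labels), function(a) {
    perHap <- rowMeans(codes == a)
    (perHap[seq(1L, 2L * n, 2L)] + perHap[seq(2L, 2L * n, 2L)]) / 2
  })
  colnames(out) <- calls@labels
  out
}

#' Global vs local ancestry concordance
#'
#' Pearson correlation, per ancestry, between externally estimated global
#' ancestry proportions and genome-wide means of the local-ancestry calls.
#'
#' @param localMeans individuals x ancestry matrix
#'   (\code{\link{individualAncestryMeans}}).
#' @param globalProps individuals x ancestry matrix from a global-ancestry
#'   method, same individuals and column order.
#' @return named numeric vector of correlations (NA where a vector has zero
#'   variance, reported as undefined).
#' @export
globalLocalConcordance <- function(localMeans, globalProps) {
  stopifnot(nrow(localMeans) == nrow(globalProps))
  out <- vapply(seq_len(ncol(localMeans)), function(a) {
    x <- localMeans[, a]; y <- globalProps[, a]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  names(out) <- colnames(localMeans)
  out
}

#' Inversion-genotype-stratified deviation scan
#'
#' Re-runs the deviation scan on the individuals homozygous for one
#' inversion class.  Heterozygous (NI/I) individuals are always excluded
#' because the inverted haplotype cannot be matched to a phased chromosome.
#'
#' @param calls an \linkS4class{AncestryCalls}.
#' @param invGenotypes factor of NI/NI, NI/I, I/I per individual (same
#'   individual order as the calls).
#' @param stratum "NI/NI" or "I/I".
#' @param thresholdSd deviation threshold in SDs.
#' @return a \code{\link{deviationScan}} result for the stratum.
#' @export
stratifiedScan <- function(calls, invGenotypes, stratum = c("NI/NI", "I/I"),
                           thresholdSd = 4.42) {
  stratum <- match.arg(stratum)
  idx <- which(as.character(invGenotypes) == stratum)
  if (!length(idx)) stop("stratum '", stratum, "' is empty")
  deviationScan(ancestryProportions(calls, subset = idx), thresholdSd)
}
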