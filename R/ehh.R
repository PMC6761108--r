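#' Extended haplotype homozygosity and integrated haplotype homozygosity
#'
#' EHH at offset x from a core SNP is the probability that two randomly
#' chosen carrier haplotypes of the core allele are identical over the whole
#' interval from the core to x: with carriers partitioned into extended
#' haplotype groups of sizes n_h, EHH = sum C(n_h,2) / C(n,2).  iHH is the
#' trapezoidal integral of the EHH curve over genetic distance (cM), summed
#' over both directions, truncated where EHH drops below \code{ehhFloor}.
#' Integration is censored (flagged) when a chromosome end or a physical gap
#' larger than \code{maxGapBp} is reached before the floor.
#'
#' @param panel a \linkS4class{HaplotypePanel} (single population).
#' @param coreSnp column index of the core SNP.
#' @param alleleClass which haplotypes carry the curve: "ancestral" (allele
#'   0), "derived" (allele 1), or "all" (site-level EHH over everyone).
#' @param ehhFloor truncation level for the EHH curve (default 0.05).
#' @param maxGapBp physical gap that censors integration (default 200 kb).
#' @return list with \code{curve} (data.frame: side, offsetCm, ehh),
#'   \code{ihh}, \code{censored} (either direction), \code{nCarriers};
#'   or, with fewer than two carriers, \code{missing = reason}.
#' @export
ehh <- function(panel, coreSnp, alleleClass = c("ancestral", "derived", "all"),
                ehhFloor = 0.05, maxGapBp = 200000) {
  alleleClass <- match.arg(alleleClass)
  h <- panel@haplotypes
  s <- panel@snps
  carriers <- switch(alleleClass,
                     ancestral = which(h[, coreSnp] == 0L),
                     derived   = which(h[, coreSnp] == 1L),
                     all       = seq_len(nrow(h)))
  n <- length(carriers)
  if (n < 2) return(list(missing = "fewer than 2 carriers", nCarriers = n))
  chromSnps <- which(s$chrom == s$chrom[coreSnp])
  sub <- h[carriers, , drop = FALSE]
  denom <- n * (n - 1) / 2
  oneSide <- function(idx) {        # idx: SNP columns outward from core
    off <- numeric(0); val <- numeric(0)
    g <- rep(1L, n)
    censored <- TRUE                # stays TRUE if floor never reached
    lastPos <- s$pos[coreSnp]
    for (j in idx) {
      if (abs(s$pos[j] - lastPos) > maxGapBp) break
      lastPos <- s$pos[j]
      g <- g * 2L + sub[, j]
      g <- match(g, unique(g))      # re-factor to keep integers small
      cnt <- tabulate(g)
      e <- sum(cnt * (cnt - 1) / 2) / denom
      if (e < ehhFloor) { censored <- FALSE; break }
      off <- c(off, abs(s$cm[j] - s$cm[coreSnp]))
      val <- c(val, e)
    }
    list(off = off, val = val, censored = censored)
  }
  left <- oneSide(rev(chromSnps[chromSnps < coreSnp]))
  right <- oneSide(chromSnps[chromSnps > coreSnp])
  trapz <- function(off, val) {
    off <- c(0, off); val <- c(1, val)
    if (length(off) < 2) return(0)
    sum(diff(off) * (head(val, -1) + tail(val, -1)) / 2)
  }
  curve <- rbind(
    data.frame(side = "left", offsetCm = -c(0, left$off), ehh = c(1, left$val)),
    data.frame(side = "right", offsetCm = c(0, right$off), ehh = c(1, right$val)))
  list(curve = curve,
       ihh = trapz(left$off, left$val) + trapz(right$off, right$val),
       censored = left$censored || right$censored,
       nCarriers = n)
}

# per-SNP iHH values for one allele class over a whole panel
ihhTrack <- function(panel, alleleClass, ehhFloor = 0.05, maxGapBp = 200000) {
  M <- nSnps(panel)
  ihh <- rep(NA_real_, M)
  censored <- rep(FALSE, M)
  reason <- rep(NA_character_, M)
  for (j in seq_len(M)) {
    r <- ehh(panel, j, alleleClass, ehhFloor, maxGapBp)
    if (!is.null(r$missing)) { reason[j] <- r$missing; next }
    ihh[j] <- r$ihh
    censored[j] <- r$censored
  }
  list(ihh = ihh, censored = censored, reason = reason)
}
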