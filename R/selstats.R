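#' Standardize values within derived-allele-frequency bins
#'
#' Splits usable SNPs into \code{nBins} equal-count DAF bins, merges bins
#' with fewer than two usable SNPs into their left neighbour, and returns
#' (x - bin mean) / bin SD.
#'
#' @param x raw values (NA allowed).
#' @param daf derived allele frequencies.
#' @param nBins requested number of equal-count bins (default 50).
#' @return list with \code{std} and the bin assignment \code{bin}.
#' @keywords internal
binStandardize <- function(x, daf, nBins = 50) {
  ok <- which(!is.na(x))
  std <- rep(NA_real_, length(x))
  if (!length(ok)) return(list(std = std, bin = rep(NA_integer_, length(x))))
  nBins <- max(1L, min(nBins, floor(length(ok) / 2)))
  r <- rank(daf[ok], ties.method = "first")
  bin <- ceiling(r / (length(ok) / nBins))
  # merge under-filled bins leftward so every bin has >= 2 SNPs
  repeat {
    cnt <- table(factor(bin, levels = sort(unique(bin))))
    small <- names(cnt)[cnt < 2]
    if (!length(small)) break
    b <- as.integer(small[1])
    lev <- sort(unique(bin))
    tgt <- if (b == min(lev)) lev[lev > b][1] else max(lev[lev < b])
    bin[bin == b] <- tgt
  }
  for (b in unique(bin)) {
    i <- ok[bin == b]
    s <- sd(x[i])
    std[i] <- if (s > 0) (x[i] - mean(x[i])) / s else 0
  }
  full <- rep(NA_integer_, length(x))
  full[ok] <- bin
  list(std = std, bin = full)
}

#' Intrapopulation haplotype-score scan (|iHS| and |diHH|)
#'
#' For each SNP with MAF >= \code{mafMin}: unstandardized iHS =
#' ln(iHH_ancestral / iHH_derived) and diHH = iHH_ancestral - iHH_derived.
#' Both are standardized within equal-count derived-allele-frequency bins
#' and reported as absolute values.  SNPs with censored integration, too few
#' carriers, or iHH_derived = 0 are missing with a reason.
#'
#' @param panel a phased \linkS4class{HaplotypePanel} with cm attached and
#'   ancestral-aligned alleles.
#' @param mafMin minor-allele-frequency floor (default 0.05).
#' @param nBins DAF bins for standardization (default 50).
#' @param ehhFloor,maxGapBp see \code{\link{ehh}}.
#' @param excludeCensored drop censored-iHH SNPs from standardization
#'   (default TRUE; prevents edge-of-chromosome inflation).
#' @param config reference-configuration label carried into the tracks.
#' @return list of two \linkS4class{StatTrack}s: \code{iHS} and \code{diHH}.
#' @export
intrapopScan <- function(panel, mafMin = 0.05, nBins = 50, ehhFloor = 0.05,
                         maxGapBp = 200000, excludeCensored = TRUE,
                         config = "NA") {
  s <- panel@snps
  daf <- colMeans(panel@haplotypes == 1L)
  tA <- ihhTrack(panel, "ancestral", ehhFloor, maxGapBp)
  tD <- ihhTrack(panel, "derived", ehhFloor, maxGapBp)
  reason <- rep(NA_character_, nrow(s))
  reason[pmin(daf, 1 - daf) < mafMin] <- "maf"
  reason[is.na(reason) & (!is.na(tA$reason) | !is.na(tD$reason))] <- "carriers"
  if (excludeCensored)
    reason[is.na(reason) & (tA$censored | tD$censored)] <- "censored"
  reason[is.na(reason) & (tD$ihh == 0 | tA$ihh == 0)] <- "zero-ihh"
  ok <- is.na(reason)
  rawIhs <- rawDihh <- rep(NA_real_, nrow(s))
  rawIhs[ok] <- log(tA$ihh[ok] / tD$ihh[ok])
  rawDihh[ok] <- tA$ihh[ok] - tD$ihh[ok]
  list(iHS = StatTrack("iHS", config, s, rawIhs,
                       abs(binStandardize(rawIhs, daf, nBins)$std), reason),
       diHH = StatTrack("diHH", config, s, rawDihh,
                        abs(binStandardize(rawDihh, daf, nBins)$std), reason))
}

#' Interpopulation haplotype-score scan (XP-EHH and |diHH_derived|)
#'
#' XP-EHH = ln(iHH_all(target) / iHH_all(reference)), standardized
#' genome-wide and kept signed (positive = longer haplotypes in the target);
#' diHH_derived = iHH_derived(target) - iHH_derived(reference), standardized
#' genome-wide, absolute value reported.
#'
#' @param target,reference \linkS4class{HaplotypePanel}s over the same SNP
#'   set and map.
#' @param ehhFloor,maxGapBp see \code{\link{ehh}}.
#' @param excludeCensored drop censored SNPs (default TRUE).
#' @param absXpehh report |XP-EHH| instead of signed values (default FALSE).
#' @param config reference-configuration label.
#' @return list of two \linkS4class{StatTrack}s: \code{XPEHH} and
#'   \code{diHH_derived}.
#' @export
interpopScan <- function(target, reference, ehhFloor = 0.05, maxGapBp = 200000,
                         excludeCensored = TRUE, absXpehh = FALSE,
                         config = "NA") {
  stopifnot(nSnps(target) == nSnps(reference))
  s <- target@snps
  aT <- ihhTrack(target, "all", ehhFloor, maxGapBp)
  aR <- ihhTrack(reference, "all", ehhFloor, maxGapBp)
  dT <- ihhTrack(target, "derived", ehhFloor, maxGapBp)
  dR <- ihhTrack(reference, "derived", ehhFloor, maxGapBp)
  gwStd <- function(x) {
    m <- mean(x, na.rm = TRUE); sg <- sd(x, na.rm = TRUE)
    if (is.na(sg) || sg == 0) return(ifelse(is.na(x), NA_real_, 0))
    (x - m) / sg
  }
  mono <- colMeans(target@haplotypes) %in% c(0, 1) &
          colMeans(reference@haplotypes) %in% c(0, 1)
  rx <- rep(NA_character_, nrow(s))
  rx[mono] <- "monomorphic"
  if (excludeCensored) rx[is.na(rx) & (aT$censored | aR$censored)] <- "censored"
  rx[is.na(rx) & (is.na(aT$ihh) | is.na(aR$ihh) | aT$ihh == 0 | aR$ihh == 0)] <- "zero-ihh"
  okX <- is.na(rx)
  rawX <- rep(NA_real_, nrow(s))
  rawX[okX] <- log(aT$ihh[okX] / aR$ihh[okX])
  stdX <- gwStd(rawX)
  if (absXpehh) stdX <- abs(stdX)
  rd <- rep(NA_character_, nrow(s))
  rd[mono] <- "monomorphic"
  rd[is.na(rd) & (!is.na(dT$reason) | !is.na(dR$reason))] <- "carriers"
  if (excludeCensored) rd[is.na(rd) & (dT$censored | dR$censored)] <- "censored"
  okD <- is.na(rd)
  rawD <- rep(NA_real_, nrow(s))
  rawD[okD] <- dT$ihh[okD] - dR$ihh[okD]
  list(XPEHH = StatTrack("XPEHH", config, s, rawX, stdX, rx),
       diHH_derived = StatTrack("diHH_derived", config, s, rawD,
                                abs(gwStd(rawD)), rd))
}

#' Hudson's Fst estimator
#'
#' Per-SNP unbiased estimator: numerator
#' \code{(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)}, denominator
#' \code{p1(1-p2) + p2(1-p1)}; SNPs where both populations are fixed for the
#' same allele (denominator 0) are skipped (NA).  Windowed mode returns the
#' ratio of averages over each window.
#'
#' @param p1,p2 allele frequencies in the two populations.
#' @param n1,n2 allele (haplotype) counts, >= 2.
#' @return numeric vector of per-SNP Fst (may be slightly negative).
#' @examples
#' hudsonFst(0.6, 10, 0.2, 10)   # ~0.2063
#' @export
hudsonFst <- function(p1, n1, p2, n2) {
  if (any(c(n1, n2) < 2)) stop("allele counts must be >= 2")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(den == 0, NA_real_, num / den)
}

#' @rdname hudsonFst
#' @param snps data.frame with chrom and pos aligned with the frequencies.
#' @param windowBp window size in bp (default 1 Mb tiles from position 1).
#' @return \code{hudsonFstWindows} returns a data.frame with chrom, startBp,
#'   endBp, fst (ratio of averages) and nSnps.
#' @export
hudsonFstWindows <- function(p1, n1, p2, n2, snps, windowBp = 1e6) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  win <- floor((snps$pos - 1) / windowBp)
  key <- paste(snps$chrom, win)
  out <- lapply(split(which(keep), key[keep]), function(i) {
    data.frame(chrom = snps$chrom[i[1]],
               startBp = win[i[1]] * windowBp + 1,
               endBp = (win[i[1]] + 1) * windowBp,
               fst = sum(num[i]) / sum(den[i]), nSnps = length(i))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$startBp), ]
}

#' Allele frequencies of a panel
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @return list with \code{p} (frequency of allele 1 per SNP) and \code{n}
#'   (haplotype count).
#' @export
alleleFreqs <- function(panel) {
  list(p = colMeans(panel@haplotypes), n = nrow(panel@haplotypes))
}

#' Population branch statistic
#'
#' PBS for focal population A given pairwise Fst values:
#' \code{T = -ln(1 - Fst)} (Fst clipped to [0, 1 - 1e-6] first, negatives to
#' 0), \code{PBS_A = (T_AB + T_AC - T_BC) / 2}.  Values may be negative and
#' are reported as-is.
#'
#' @param fstAB,fstAC,fstBC aligned pairwise Fst vectors.
#' @return numeric PBS values.
#' @examples
#' pbs(0.1, 0.1, 0)   # -log(0.9)
#' @export
pbs <- function(fstAB, fstAC, fstBC) {
  tt <- function(f) -log(1 - pmin(pmax(f, 0), 1 - 1e-6))
  (tt(fstAB) + tt(fstAC) - tt(fstBC)) / 2
}
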