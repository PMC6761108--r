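#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the allele counts, the p-value is the sum of
#' the probabilities of all heterozygote counts no more likely than the
#' observed one.  A chi-square goodness-of-fit alternative is available
#' behind \code{method = "chisq"}.
#'
#' @param nHomRef,nHet,nHomAlt genotype counts.
#' @param method "exact" (default) or "chisq".
#' @return p-value in (0, 1].
#' @examples
#' hweExactTest(1, 0, 1)   # 1/3
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt, method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (any(c(nHomRef, nHet, nHomAlt) < 0)) stop("counts must be non-negative")
  n <- nHomRef + nHet + nHomAlt
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * nHomRef + nHet      # rarer-or-not is irrelevant; test is symmetric
  if (method == "chisq") {
    p <- nA / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(e == 0)) return(1)
    x2 <- sum((c(nHomRef, nHet, nHomAlt) - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  nB <- 2 * n - nA
  m <- min(nA, nB)
  hets <- seq(m %% 2, m, by = 2)        # feasible heterozygote counts
  # log P(het | n, nA) up to a constant: n! 2^het / (homA! het! homB!)
  lp <- vapply(hets, function(het) {
    homA <- (nA - het) / 2
    homB <- (nB - het) / 2
    het * log(2) - lfactorial(homA) - lfactorial(het) - lfactorial(homB)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(nHet, hets)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' SNP-level quality-control filters
#'
#' Applies the standard site filters in a fixed order — unmapped,
#' non-autosomal, strand-ambiguous (A/T or G/C alleles), Hardy-Weinberg
#' disequilibrium, missingness, minor allele frequency — attributing each
#' removed SNP to the first filter it fails, and returns the kept SNP
#' indices together with an auditable \linkS4class{QcLedger}.
#'
#' @param geno individuals x SNPs dosage matrix (0/1/2, NA allowed), or a
#'   \linkS4class{HaplotypePanel}.
#' @param snps SNP metadata data.frame (taken from the panel if omitted);
#'   needs chrom, pos, ref, alt.
#' @param hwePcut Hardy-Weinberg p-value cutoff (remove p < cutoff).
#' @param missMax maximum per-SNP missing fraction.
#' @param mafMin minimum minor allele frequency (remove MAF < mafMin).
#' @param autosomes chromosome labels counted as autosomal.
#' @param hweMethod passed to \code{\link{hweExactTest}}.
#' @return list with \code{kept} (SNP indices) and \code{ledger}.
#' @export
applySiteFilters <- function(geno, snps = NULL, hwePcut = 0.01, missMax = 0.02,
                             mafMin = 0.01,
                             autosomes = as.character(1:22),
                             hweMethod = "exact") {
  if (is(geno, "HaplotypePanel")) {
    if (is.null(snps)) snps <- snpInfo(geno)
    geno <- dosages(geno)
  }
  M <- nrow(snps)
  fate <- rep(NA_character_, M)
  flag <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    fate[is.na(fate) & cond] <<- label
  }
  flag(is.na(snps$pos) | snps$pos <= 0 | is.na(snps$chrom) | snps$chrom == "0",
       "unmapped")
  flag(!(snps$chrom %in% autosomes), "non-autosomal")
  pair <- paste(pmin(snps$ref, snps$alt), pmax(snps$ref, snps$alt))
  flag(pair %in% c("A T", "C G"), "ambiguous")
  hweP <- vapply(seq_len(M), function(j) {
    if (!is.na(fate[j])) return(1)
    g <- geno[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hweExactTest(sum(g == 0), sum(g == 1), sum(g == 2), method = hweMethod)
  }, numeric(1))
  flag(hweP < hwePcut, "HWE")
  flag(colMeans(is.na(geno)) > missMax, "missingness")
  p <- colMeans(geno, na.rm = TRUE) / 2
  flag(pmin(p, 1 - p) < mafMin, "MAF")
  cats <- c("unmapped", "non-autosomal", "ambiguous", "HWE", "missingness", "MAF")
  counts <- vapply(cats, function(cc) sum(fate == cc, na.rm = TRUE), integer(1))
  list(kept = which(is.na(fate)),
       ledger = QcLedger(M, setNames(counts, cats)),
       fate = fate)
}

#' Heterozygosity-rate outlier individuals
#'
#' Flags individuals whose heterozygosity rate differs from the cohort mean
#' by more than \code{k} standard deviations (low rates suggest inbreeding,
#' high rates contamination).  With zero SD nothing is flagged.
#'
#' @param geno individuals x SNPs dosage matrix or \linkS4class{HaplotypePanel}.
#' @param k SD multiplier (default 2).
#' @return list with \code{rates}, \code{mean}, \code{sd} and \code{flagged}
#'   (individual indices).
#' @export
heterozygosityOutliers <- function(geno, k = 2) {
  if (is(geno, "HaplotypePanel")) geno <- dosages(geno)
  if (nrow(geno) < 2) stop("need at least two individuals")
  rates <- rowMeans(geno == 1, na.rm = TRUE)
  m <- mean(rates)
  s <- sd(rates)
  flagged <- if (s == 0) integer(0) else which(abs(rates - m) > k * s)
  list(rates = rates, mean = m, sd = s, flagged = flagged)
}

#' Greedy duplicate and relatedness pruning
#'
#' Pairs above \code{dupThreshold} (identity-by-state, suggesting duplicated
#' samples) are resolved first by dropping the higher-index member.  Then,
#' among pairs with relatedness strictly above \code{relThreshold} (0.125 is
#' the expectation for third-degree relatives, which are therefore kept),
#' the individual with the most remaining above-threshold partners is
#' removed repeatedly until no pair remains; ties prefer higher missingness,
#' then higher index.
#'
#' @param rel symmetric relatedness (or IBS) matrix.
#' @param relThreshold relatedness cutoff (strictly greater is pruned).
#' @param dupThreshold duplicate cutoff on the same matrix.
#' @param missingness optional per-individual missingness for tie-breaking.
#' @return list with \code{kept} indices and a \code{removed} data.frame
#'   (id, reason).
#' @export
greedyRelatednessPrune <- function(rel, relThreshold = 0.125,
                                   dupThreshold = 0.85, missingness = NULL) {
  if (!isSymmetric(unname(rel), tol = 1e-8)) stop("matrix must be symmetric")
  n <- nrow(rel)
  if (is.null(missingness)) missingness <- rep(0, n)
  alive <- rep(TRUE, n)
  removed <- data.frame(id = integer(0), reason = character(0))
  adj <- rel
  diag(adj) <- -Inf
  dup <- which(adj > dupThreshold & upper.tri(adj), arr.ind = TRUE)
  if (nrow(dup)) for (k in order(dup[, 1])) {
    hi <- max(dup[k, ])
    if (alive[dup[k, 1]] && alive[dup[k, 2]] && alive[hi]) {
      alive[hi] <- FALSE
      removed <- rbind(removed, data.frame(id = hi, reason = "duplicate"))
    }
  }
  repeat {
    a <- which(alive)
    deg <- rowSums(adj[a, a, drop = FALSE] > relThreshold)
    if (!any(deg > 0)) break
    worst <- a[order(-deg, -missingness[a], -a)][1]
    alive[worst] <- FALSE
    removed <- rbind(removed, data.frame(id = worst, reason = "relatedness"))
  }
  list(kept = which(alive), removed = removed)
}

#' Window-based LD pruning
#'
#' Slides a window of \code{window} SNPs in steps of \code{step} SNPs; within
#' each window, whenever a retained pair's squared dosage correlation exceeds
#' \code{r2}, the later-index SNP is removed.  Correlations use composite
#' (dosage-level) r-squared, the convention for pre-phasing LD pruning.
#'
#' @param geno individuals x SNPs dosage matrix or \linkS4class{HaplotypePanel}.
#' @param window window size in SNPs.
#' @param step window shift in SNPs.
#' @param r2 squared-correlation cutoff (strictly greater is pruned).
#' @return integer vector of kept SNP indices.
#' @export
ldPrune <- function(geno, window = 50, step = 5, r2 = 0.5) {
  if (is(geno, "HaplotypePanel")) geno <- dosages(geno)
  M <- ncol(geno)
  keep <- rep(TRUE, M)
  starts <- unique(c(seq(1L, max(1L, M - window + 1L), by = step)))
  for (s in starts) {
    idx <- seq(s, min(s + window - 1L, M))
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    cc <- suppressWarnings(cor(geno[, idx, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    cc[is.na(cc)] <- 0
    for (ai in seq_along(idx)) {
      if (!keep[idx[ai]]) next
      for (bi in seq_along(idx)) {
        if (bi <= ai || !keep[idx[bi]]) next
        if (cc[ai, bi] > r2) keep[idx[bi]] <- FALSE
      }
    }
  }
  which(keep)
}
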