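#' Phased haplotype panel
#'
#' A 0/1 haplotype-by-SNP matrix with SNP metadata.  Rows come in pairs: rows
#' 2i-1 and 2i are the two phased haplotypes of individual i.  Allele coding is
#' ancestral-aligned where the ancestral allele is known: 0 means the
#' ancestral-aligned allele (see the \code{ancestral} column of \code{snps});
#' when the ancestral state is unknown, 0 is the REF allele.
#'
#' @slot haplotypes integer matrix of 0/1, 2N x M.
#' @slot individualIds character vector of length N.
#' @slot snps data.frame with columns \code{chrom}, \code{pos} (1-based bp),
#'   \code{id}, \code{ref}, \code{alt}, \code{ancestral} (one of
#'   \code{"ref"}, \code{"alt"}, \code{"unknown"}) and \code{cm} (genetic
#'   position, centimorgans; may be NA before a map is attached).
#' @slot pop single population label.
#' @export
setClass("HaplotypePanel",
  representation(haplotypes = "matrix", individualIds = "character",
                 snps = "data.frame", pop = "character"),
  validity = function(object) {
    h <- object@haplotypes
    s <- object@snps
    msg <- character(0)
    if (nrow(h) %% 2L != 0L) msg <- c(msg, "haplotype row count must be even")
    if (nrow(h) != 2L * length(object@individualIds))
      msg <- c(msg, "need exactly two haplotype rows per individual")
    if (ncol(h) != nrow(s)) msg <- c(msg, "haplotype columns must align with snps")
    if (length(h) && !all(h %in% c(0L, 1L))) msg <- c(msg, "haplotype entries must be 0/1")
    need <- c("chrom", "pos", "id", "ref", "alt", "ancestral", "cm")
    if (!all(need %in% names(s))) {
      msg <- c(msg, paste("snps must have columns:", paste(need, collapse = ", ")))
    } else if (nrow(s)) {
      for (ch in unique(s$chrom)) {
        p <- s$pos[s$chrom == ch]
        if (any(diff(p) <= 0)) msg <- c(msg, sprintf("positions not strictly increasing on %s", ch))
        cmv <- s$cm[s$chrom == ch]
        if (!anyNA(cmv) && any(diff(cmv) < 0))
          msg <- c(msg, sprintf("cm not non-decreasing on %s", ch))
      }
      if (!all(s$ref %in% c("A", "C", "G", "T")) || !all(s$alt %in% c("A", "C", "G", "T")))
        msg <- c(msg, "alleles must be A/C/G/T")
      if (!all(s$ancestral %in% c("ref", "alt", "unknown")))
        msg <- c(msg, "ancestral must be ref/alt/unknown")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a HaplotypePanel
#'
#' @param haplotypes 0/1 matrix, two rows per individual.
#' @param individualIds individual identifiers (default ind1..indN).
#' @param snps SNP metadata data.frame (see \linkS4class{HaplotypePanel}).
#' @param pop population label.
#' @return A \linkS4class{HaplotypePanel}.
#' @export
HaplotypePanel <- function(haplotypes, snps, individualIds = NULL, pop = "pop") {
  haplotypes <- matrix(as.integer(haplotypes), nrow = nrow(haplotypes))
  if (is.null(individualIds))
    individualIds <- paste0("ind", seq_len(nrow(haplotypes) / 2))
  rownames(snps) <- NULL
  new("HaplotypePanel", haplotypes = haplotypes, individualIds = as.character(individualIds),
      snps = snps, pop = pop)
}

#' Genetic map
#'
#' Ordered (bp, cM) anchor pairs per chromosome, interpolated by
#' \code{\link{cmAt}}.
#'
#' @slot anchors data.frame with columns \code{chrom}, \code{bp}, \code{cm}.
#' @export
setClass("GeneticMap", representation(anchors = "data.frame"),
  validity = function(object) {
    a <- object@anchors
    if (!all(c("chrom", "bp", "cm") %in% names(a)))
      return("anchors must have columns chrom, bp, cm")
    for (ch in unique(a$chrom)) {
      sub <- a[a$chrom == ch, ]
      if (any(diff(sub$bp) <= 0)) return(sprintf("bp not strictly increasing on %s", ch))
      if (any(diff(sub$cm) < 0)) return(sprintf("cm not non-decreasing on %s", ch))
    }
    TRUE
  })

#' @rdname GeneticMap-class
#' @param anchors data.frame with columns chrom, bp, cm.
#' @return A \linkS4class{GeneticMap}.
#' @export
GeneticMap <- function(anchors) {
  anchors <- anchors[order(anchors$chrom, anchors$bp), , drop = FALSE]
  rownames(anchors) <- NULL
  new("GeneticMap", anchors = anchors)
}

#' Per-haplotype local-ancestry calls
#'
#' Stores the per-haplotype, per-SNP ancestry code matrix together with the
#' tract decomposition (maximal single-ancestry runs per haplotype within a
#' chromosome) and a posterior probability per tract.
#'
#' @slot codes integer matrix (haplotype x SNP) of ancestry codes, indexing
#'   into \code{labels}.
#' @slot labels ancestry labels, e.g. \code{c("EUR","AFR","NAT")}.
#' @slot tracts data.frame with columns \code{hap}, \code{startSnp},
#'   \code{endSnp}, \code{ancestry} (code), \code{posterior}.
#' @slot snps data.frame with columns \code{chrom}, \code{pos}.
#' @export
setClass("AncestryCalls",
  representation(codes = "matrix", labels = "character",
                 tracts = "data.frame", snps = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    if (ncol(object@codes) != nrow(object@snps))
      msg <- c(msg, "codes columns must align with snps")
    if (length(object@codes) && !all(object@codes %in% seq_along(object@labels)))
      msg <- c(msg, "codes outside declared label set")
    tr <- object@tracts
    if (nrow(tr)) {
      if (any(tr$posterior < 0 | tr$posterior > 1))
        msg <- c(msg, "posteriors must lie in [0,1]")
      cov <- tapply(tr$endSnp - tr$startSnp + 1L, tr$hap, sum)
      if (any(cov != ncol(object@codes)))
        msg <- c(msg, "tracts must tile every haplotype exactly once")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct AncestryCalls from a code matrix
#'
#' Tracts are derived as maximal runs of one ancestry per haplotype, never
#' crossing a chromosome boundary.
#'
#' @param codes haplotype x SNP integer matrix of ancestry codes.
#' @param snps data.frame with chrom and pos columns.
#' @param labels ancestry labels the codes index into.
#' @param posteriors optional numeric vector of tract posteriors in tract
#'   order (hap-major); default all 1.
#' @return An \linkS4class{AncestryCalls}.
#' @export
AncestryCalls <- function(codes, snps, labels = c("EUR", "AFR", "NAT"),
                          posteriors = NULL) {
  codes <- matrix(as.integer(codes), nrow = nrow(codes))
  tr <- tractsFromCodes(codes, snps$chrom)
  tr$posterior <- if (is.null(posteriors)) 1 else as.numeric(posteriors)
  if (length(tr$posterior) != nrow(tr))
    stop("posteriors must have one value per tract (", nrow(tr), " tracts)")
  new("AncestryCalls", codes = codes, labels = labels, tracts = tr,
      snps = snps[, c("chrom", "pos")])
}

# maximal runs of constant ancestry per haplotype, split at chromosome bounds
tractsFromCodes <- function(codes, chrom) {
  chromId <- as.integer(factor(chrom, levels = unique(chrom)))
  out <- vector("list", nrow(codes))
  for (h in seq_len(nrow(codes))) {
    key <- paste(chromId, codes[h, ])
    r <- rle(key)
    e <- cumsum(r$lengths)
    s <- c(1L, head(e, -1L) + 1L)
    out[[h]] <- data.frame(hap = h, startSnp = s, endSnp = e,
                           ancestry = codes[h, s])
  }
  do.call(rbind, out)
}

#' Per-SNP track of one selection statistic
#'
#' @slot statistic one of \code{"iHS"}, \code{"diHH"}, \code{"diHH_derived"},
#'   \code{"XPEHH"}, \code{"PBS"} (absolute-value variants share the name; see
#'   \code{raw} vs \code{std}).
#' @slot config reference-configuration label (which reference panel the
#'   interpopulation statistics used).
#' @slot snps data.frame with chrom, pos.
#' @slot raw raw statistic values (NA where missing).
#' @slot std standardized values entering the scan (NA where missing).
#' @slot missingReason character, NA where the SNP is usable.
#' @export
setClass("StatTrack",
  representation(statistic = "character", config = "character",
                 snps = "data.frame", raw = "numeric", std = "numeric",
                 missingReason = "character"),
  validity = function(object) {
    n <- nrow(object@snps)
    if (length(object@raw) != n || length(object@std) != n ||
        length(object@missingReason) != n)
      return("raw, std and missingReason must have one entry per SNP")
    bad <- !is.na(object@std) & !is.finite(object@std)
    if (any(bad)) return("standardized values must be finite where not missing")
    TRUE
  })

StatTrack <- function(statistic, config, snps, raw, std, missingReason = NULL) {
  if (is.null(missingReason)) {
    missingReason <- rep(NA_character_, nrow(snps))
    missingReason[is.na(std)] <- "missing"
  }
  new("StatTrack", statistic = statistic, config = config,
      snps = snps[, c("chrom", "pos")], raw = as.numeric(raw),
      std = as.numeric(std), missingReason = as.character(missingReason))
}

#' Fisher-combined-score scan result
#'
#' @slot perSnp data.frame: chrom, pos, one p column per statistic, fcs,
#'   outlier flag.
#' @slot blocks data.frame: chrom, startBp, endBp, size, nOutlier, prop,
#'   called.
#' @slot blockThreshold the higher-type 99.5th percentile of block outlier
#'   proportions (calls require strictly greater).
#' @slot regions \code{GRanges} of called regions with an \code{ancestry}
#'   label column.
#' @export
setClass("FcsResult",
  representation(perSnp = "data.frame", blocks = "data.frame",
                 blockThreshold = "numeric", regions = "GRanges"),
  validity = function(object) {
    if (any(object@perSnp$fcs < 0)) return("FCS must be non-negative")
    TRUE
  })

#' Inversion genotype calls
#'
#' @slot individualIds individual identifiers.
#' @slot calls factor with levels \code{NI/NI}, \code{NI/I}, \code{I/I}.
#' @slot posteriors N x 3 matrix of class posteriors (columns in call-level
#'   order), rows summing to 1.
#' @slot params fitted mixture parameters (means, variances, weights,
#'   orientation, degeneracy flag).
#' @slot converged logical.
#' @slot llTrace log-likelihood trace of the EM run.
#' @export
setClass("InversionGenotypes",
  representation(individualIds = "character", calls = "factor",
                 posteriors = "matrix", params = "list",
                 converged = "logical", llTrace = "numeric"),
  validity = function(object) {
    if (nrow(object@posteriors) != length(object@calls))
      return("posteriors must have one row per individual")
    if (any(abs(rowSums(object@posteriors) - 1) > 1e-6))
      return("posteriors must sum to 1")
    TRUE
  })

#' Procrustes comparison result
#'
#' @slot rotation optimal rotation matrix.
#' @slot scale optimal uniform scale.
#' @slot translation translation applied to the target.
#' @slot mSquared Procrustes statistic in [0,1].
#' @slot correlation sqrt(1 - mSquared).
#' @slot pValue permutation p-value (add-one estimator).
#' @slot nPerm number of permutations.
#' @export
setClass("ProcrustesResult",
  representation(rotation = "matrix", scale = "numeric", translation = "numeric",
                 mSquared = "numeric", correlation = "numeric",
                 pValue = "numeric", nPerm = "integer"),
  validity = function(object) {
    if (object@correlation < -1e-12 || object@correlation > 1 + 1e-12)
      return("correlation must lie in [0,1]")
    TRUE
  })

#' Quality-control removal ledger
#'
#' Ordered SNP-removal categories plus per-individual removals; the remaining
#' count is always \code{start - sum(removals)}.
#'
#' @slot start starting SNP count.
#' @slot removals named integer vector of removal counts in filter order.
#' @slot remaining SNPs left after all categories.
#' @slot individualRemovals data.frame (id, reason).
#' @export
setClass("QcLedger",
  representation(start = "integer", removals = "integer", remaining = "integer",
                 individualRemovals = "data.frame"),
  validity = function(object) {
    if (any(object@removals < 0)) return("removal counts must be non-negative")
    if (object@remaining != object@start - sum(object@removals))
      return("remaining must equal start minus total removals")
    TRUE
  })

#' @rdname QcLedger-class
#' @param start starting SNP count.
#' @param removals named integer vector of per-category removal counts.
#' @param individualRemovals optional data.frame with columns id, reason.
#' @return A \linkS4class{QcLedger}; \code{remaining} is computed, never supplied.
#' @export
QcLedger <- function(start, removals,
                     individualRemovals = data.frame(id = character(0),
                                                     reason = character(0))) {
  removals <- setNames(as.integer(removals), names(removals))
  new("QcLedger", start = as.integer(start), removals = removals,
      remaining = as.integer(start - sum(removals)),
      individualRemovals = individualRemovals)
}
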