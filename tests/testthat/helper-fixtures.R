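# small in-code fixtures and independent oracles shared across test files

# minimal SNP metadata table: evenly spaced positions, constant cM rate
snpMeta <- function(M, chrom = "1", spacingBp = 1000, cmPerBp = 1e-6,
                    ref = "A", alt = "G", ancestral = "ref") {
  pos <- seq(spacingBp, by = spacingBp, length.out = M)
  data.frame(chrom = chrom, pos = as.integer(pos),
             id = paste0("rs", seq_len(M)), ref = ref, alt = alt,
             ancestral = ancestral, cm = pos * cmPerBp * 1000,
             stringsAsFactors = FALSE)
}

# panel from an explicit haplotype matrix
makePanel <- function(h, snps = NULL, pop = "pop", cmStep = 0.1) {
  if (is.null(snps)) {
    snps <- snpMeta(ncol(h))
    snps$cm <- (seq_len(ncol(h)) - 1) * cmStep
  }
  HaplotypePanel(h, snps, pop = pop)
}

# brute-force EHH oracle: directly counts identical haplotype pairs over the
# interval extending from (but excluding) the core to column j, among the
# given carriers; at j == core the value is 1 by definition
bruteEhh <- function(h, carriers, core, j) {
  if (j == core) return(1)
  cols <- if (j > core) (core + 1):j else j:(core - 1)
  key <- apply(h[carriers, cols, drop = FALSE], 1, paste, collapse = "")
  cnt <- table(key)
  n <- length(carriers)
  sum(cnt * (cnt - 1) / 2) / (n * (n - 1) / 2)
}

# textbook exact-HWE oracle: full normalized probability of each feasible
# heterozygote count given the allele counts, then sum of probs <= observed
hweOracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nB <- 2 * n - nA
  m <- min(nA, nB)
  hets <- seq(m %% 2, m, by = 2)
  pr <- vapply(hets, function(het) {
    homA <- (nA - het) / 2
    homB <- (nB - het) / 2
    exp(lfactorial(n) - lfactorial(homA) - lfactorial(het) - lfactorial(homB) +
        het * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(nAB, hets)]
  sum(pr[pr <= obs + 1e-12])
}

# fully independent HWE check for tiny n: exhaustive enumeration of all
# perfect matchings of the 2n alleles into n unordered diploid genotypes
hweMatchings <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  alleles <- c(rep(1L, 2 * nAA + nAB), rep(0L, nAB + 2 * nBB))
  hetCounts <- integer(0)
  recurse <- function(rem, het) {
    if (!length(rem)) {
      hetCounts[length(hetCounts) + 1L] <<- het
      return(invisible())
    }
    a <- rem[1]
    for (k in seq_along(rem[-1])) {
      b <- rem[-1][k]
      recurse(rem[-c(1, k + 1)], het + as.integer(a != b))
    }
  }
  recurse(alleles, 0L)
  tab <- table(hetCounts) / length(hetCounts)
  obs <- tab[as.character(nAB)]
  sum(tab[tab <= obs + 1e-12])
}

# write a small phased VCF by hand (independent of writePhasedVcf)
writeTinyVcf <- function(path, rows, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}
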