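#' Parse a phased VCF into a HaplotypePanel
#'
#' Reads a VCF with phased diploid GT fields (via \pkg{vcfR}) and returns the
#' haplotypes ancestral-aligned: when the record carries an \code{AA} INFO
#' field matching REF or ALT, allele 0 in the panel is the ancestral allele
#' (columns whose ancestral allele is ALT are flipped relative to REF coding);
#' otherwise 0 is REF and the ancestral state is recorded as unknown.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param pop population label for the resulting panel.
#' @param dropMultiallelic drop multi-allelic records instead of erroring.
#' @return A \linkS4class{HaplotypePanel} with two haplotype rows per sample,
#'   in sample order (\code{cm} is NA until a map is attached).
#' @export
parsePhasedVcf <- function(path, pop = "pop", dropMultiallelic = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt[, -1, drop = FALSE]
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (!dropMultiallelic)
      stop("multi-allelic record(s) at ",
           paste(fix$CHROM[multi], fix$POS[multi], sep = ":", collapse = ", "),
           " (set dropMultiallelic = TRUE to drop)")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  gtOnly <- sub(":.*$", "", gt)
  unphased <- grepl("/", gtOnly, fixed = TRUE)
  if (any(unphased)) {
    bad <- which(rowSums(matrix(unphased, nrow = nrow(gtOnly))) > 0)
    stop("unphased genotype(s) at ",
         paste(fix$CHROM[bad], fix$POS[bad], sep = ":", collapse = ", "))
  }
  hapA <- t(matrix(as.integer(sub("\\|.*$", "", gtOnly)), nrow = nrow(gtOnly)))
  hapB <- t(matrix(as.integer(sub("^.*\\|", "", gtOnly)), nrow = nrow(gtOnly)))
  n <- ncol(gt)
  h <- matrix(0L, nrow = 2L * n, ncol = nrow(fix))
  h[seq(1L, 2L * n, 2L), ] <- hapA
  h[seq(2L, 2L * n, 2L), ] <- hapB
  aa <- rep(NA_character_, nrow(fix))
  hasAA <- grepl("(^|;)AA=", fix$INFO)
  aa[hasAA] <- toupper(sub(".*AA=([^;]+).*", "\\1", fix$INFO[hasAA]))
  ancestral <- ifelse(!is.na(aa) & aa == fix$ALT, "alt",
                      ifelse(!is.na(aa) & aa == fix$REF, "ref", "unknown"))
  flip <- ancestral == "alt"
  h[, flip] <- 1L - h[, flip]
  snps <- data.frame(chrom = as.character(fix$CHROM), pos = as.integer(fix$POS),
                     id = as.character(fix$ID), ref = as.character(fix$REF),
                     alt = as.character(fix$ALT), ancestral = ancestral,
                     cm = rep(NA_real_, nrow(fix)), stringsAsFactors = FALSE)
  HaplotypePanel(h, snps, individualIds = colnames(gt), pop = pop)
}

#' Write a HaplotypePanel as a phased VCF
#'
#' Inverse of \code{\link{parsePhasedVcf}}: alleles are re-expressed on REF
#' coding and the ancestral allele, where known, is emitted as an \code{AA}
#' INFO field so a round-trip restores the ancestral-aligned matrix exactly.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param path output path (plain-text VCF).
#' @return the path, invisibly.
#' @export
writePhasedVcf <- function(panel, path) {
  s <- panel@snps
  h <- panel@haplotypes
  flip <- s$ancestral == "alt"
  h[, flip] <- 1L - h[, flip]
  aaChar <- ifelse(s$ancestral == "alt", s$alt,
                   ifelse(s$ancestral == "ref", s$ref, NA))
  info <- ifelse(is.na(aaChar), ".", paste0("AA=", aaChar))
  n <- nIndividuals(panel)
  a <- h[seq(1L, 2L * n, 2L), , drop = FALSE]
  b <- h[seq(2L, 2L * n, 2L), , drop = FALSE]
  gtBody <- matrix(paste0(a, "|", b), nrow = n)
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel@individualIds), collapse = "\t"))
  body <- apply(cbind(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", info,
                      "GT", t(gtBody)), 1, paste, collapse = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}
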