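#' Read / write a genetic map
#'
#' The on-disk format is a 3-column whitespace-delimited table
#' (chrom, bp, cM) with a header line.
#'
#' @param path file path.
#' @return \code{readGeneticMap} returns a \linkS4class{GeneticMap}.
#' @export
readGeneticMap <- function(path) {
  a <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(a)[1:3] <- c("chrom", "bp", "cm")
  a$chrom <- as.character(a$chrom)
  GeneticMap(a)
}

#' @rdname readGeneticMap
#' @param map a \linkS4class{GeneticMap}.
#' @export
writeGeneticMap <- function(map, path) {
  write.table(map@anchors, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genetic position at a physical position
#'
#' Linear interpolation between flanking map anchors; beyond the terminal
#' anchors the chromosome's mean cM/bp rate is used for linear extrapolation
#' (so cM stays monotone in bp everywhere).
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param chrom chromosome label (scalar).
#' @param posBp physical position(s), bp.
#' @return numeric cM value(s).
#' @export
cmAt <- function(map, chrom, posBp) {
  a <- map@anchors[map@anchors$chrom == as.character(chrom), , drop = FALSE]
  if (!nrow(a)) stop("chromosome '", chrom, "' not in genetic map")
  if (nrow(a) == 1L) return(rep(a$cm, length(posBp)))
  rate <- (a$cm[nrow(a)] - a$cm[1]) / (a$bp[nrow(a)] - a$bp[1])
  out <- stats::approx(a$bp, a$cm, xout = posBp, rule = 1)$y
  lo <- posBp < a$bp[1]
  hi <- posBp > a$bp[nrow(a)]
  out[lo] <- a$cm[1] - (a$bp[1] - posBp[lo]) * rate
  out[hi] <- a$cm[nrow(a)] + (posBp[hi] - a$bp[nrow(a)]) * rate
  out
}

#' Attach genetic positions to a panel
#'
#' Fills the \code{cm} column of the panel's SNP table from a genetic map.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param map a \linkS4class{GeneticMap}.
#' @return the panel with \code{cm} populated.
#' @export
attachGeneticMap <- function(panel, map) {
  s <- panel@snps
  for (ch in unique(s$chrom)) {
    i <- s$chrom == ch
    s$cm[i] <- cmAt(map, ch, s$pos[i])
  }
  HaplotypePanel(panel@haplotypes, s, individualIds = panel@individualIds,
                 pop = panel@pop)
}
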