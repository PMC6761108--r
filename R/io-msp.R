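#' Write / read local-ancestry calls (msp-style TSV)
#'
#' The on-disk format follows the msp convention of local-ancestry callers:
#' a code-map header line (\code{#Subpopulation order/codes: EUR=0 ...}), a
#' column header, then one row per genome span within which no haplotype
#' switches ancestry: chrom, span start/end bp, span start/end cM, number of
#' SNPs, and one 0-based ancestry-code column per haplotype.  Tract-level
#' posterior probabilities travel in an optional companion TSV
#' (hap, startSnp, endSnp, posterior); when absent, posteriors default to 1.
#'
#' @param calls an \linkS4class{AncestryCalls}.
#' @param path msp TSV path.
#' @param posteriorPath optional companion posterior TSV path.
#' @return \code{writeAncestryCalls} returns \code{path} invisibly;
#'   \code{readAncestryCalls} returns an \linkS4class{AncestryCalls}.
#' @export
writeAncestryCalls <- function(calls, path, posteriorPath = NULL) {
  codes <- calls@codes
  snps <- calls@snps
  chromId <- as.integer(factor(snps$chrom, levels = unique(snps$chrom)))
  key <- apply(rbind(chromId, codes), 2, paste, collapse = ",")
  r <- rle(key)
  e <- cumsum(r$lengths)
  s <- c(1L, head(e, -1L) + 1L)
  rows <- data.frame(chm = snps$chrom[s], spos = snps$pos[s], epos = snps$pos[e],
                     sgpos = 0, egpos = 0, n_snps = e - s + 1L)
  body <- cbind(rows, t(codes[, s, drop = FALSE]) - 1L)
  names(body)[-(1:6)] <- paste0("hap", seq_len(nrow(codes)))
  con <- file(path, "w")
  writeLines(paste0("#Subpopulation order/codes: ",
                    paste(calls@labels, seq_along(calls@labels) - 1L,
                          sep = "=", collapse = " ")), con)
  writeLines(paste(names(body), collapse = "\t"), con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  if (!is.null(posteriorPath))
    write.table(calls@tracts[, c("hap", "startSnp", "endSnp", "posterior")],
                posteriorPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAncestryCalls
#' @param snps data.frame with chrom and pos for the SNP set the spans tile.
#' @export
readAncestryCalls <- function(path, snps, posteriorPath = NULL) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#Subpopulation", first)) stop("missing code-map header line")
  pairs <- strsplit(sub("^#Subpopulation order/codes: *", "", first), " ")[[1]]
  labels <- sub("=.*$", "", pairs)
  codesDecl <- as.integer(sub("^.*=", "", pairs))
  tab <- read.table(path, header = FALSE, sep = "\t", skip = 2L,
                    stringsAsFactors = FALSE)
  names(tab)[1:6] <- c("chm", "spos", "epos", "sgpos", "egpos", "n_snps")
  hapCols <- as.matrix(tab[, -(1:6), drop = FALSE])
  if (!all(hapCols %in% codesDecl))
    stop("ancestry code outside declared code map: ",
         paste(setdiff(unique(as.vector(hapCols)), codesDecl), collapse = ", "))
  nHap <- ncol(hapCols)
  codes <- matrix(NA_integer_, nrow = nHap, ncol = nrow(snps))
  covered <- rep(0L, nrow(snps))
  for (k in seq_len(nrow(tab))) {
    j <- which(snps$chrom == as.character(tab$chm[k]) &
               snps$pos >= tab$spos[k] & snps$pos <= tab$epos[k])
    if (length(j) != tab$n_snps[k])
      stop("span ", tab$chm[k], ":", tab$spos[k], "-", tab$epos[k],
           " covers ", length(j), " SNPs but declares ", tab$n_snps[k])
    if (any(covered[j] > 0L))
      stop("overlapping spans at ", tab$chm[k], ":", tab$spos[k])
    covered[j] <- 1L
    codes[, j] <- match(hapCols[k, ], codesDecl)
  }
  if (any(covered == 0L))
    stop("spans do not tile the SNP set (", sum(covered == 0L), " SNPs uncovered)")
  out <- AncestryCalls(codes, snps, labels = labels)
  if (!is.null(posteriorPath) && file.exists(posteriorPath)) {
    post <- read.table(posteriorPath, header = TRUE, sep = "\t")
    tr <- out@tracts
    key <- function(d) paste(d$hap, d$startSnp, d$endSnp)
    m <- match(key(tr), key(post))
    if (anyNA(m)) stop("posterior file tracts do not match call tracts")
    tr$posterior <- post$posterior[m]
    if (any(tr$posterior < 0 | tr$posterior > 1))
      stop("posteriors must lie in [0,1]")
    out@tracts <- tr
    validObject(out)
  }
  out
}
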