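#' Pairwise identity-by-state matrix
#'
#' IBS between two individuals is the mean over SNPs of
#' \code{(2 - |g_i - g_j|) / 2} on 0/1/2 dosages; SNPs missing in either
#' individual are excluded pairwise.
#'
#' @param geno individuals x SNPs dosage matrix, or a
#'   \linkS4class{HaplotypePanel}.
#' @param snpIdx optional SNP column subset (e.g. a region).
#' @return list with symmetric unit-diagonal \code{ibs} and per-pair SNP
#'   counts \code{nSnps}.
#' @export
ibsMatrix <- function(geno, snpIdx = NULL) {
  if (is(geno, "HaplotypePanel")) geno <- dosages(geno)
  if (!is.null(snpIdx)) geno <- geno[, snpIdx, drop = FALSE]
  n <- nrow(geno)
  ibs <- diag(1, n)
  cnt <- matrix(ncol(geno), n, n)
  if (anyNA(geno)) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ok <- !is.na(geno[i, ]) & !is.na(geno[j, ])
      if (!any(ok)) stop("individuals ", i, " and ", j, " share no SNPs")
      ibs[i, j] <- ibs[j, i] <- mean((2 - abs(geno[i, ok] - geno[j, ok])) / 2)
      cnt[i, j] <- cnt[j, i] <- sum(ok)
    }
  } else {
    d <- as.matrix(stats::dist(geno, method = "manhattan"))
    ibs <- 1 - d / (2 * ncol(geno))
    diag(ibs) <- 1
  }
  dimnames(ibs) <- list(rownames(geno), rownames(geno))
  list(ibs = ibs, nSnps = cnt)
}

#' Classical (metric) multidimensional scaling
#'
#' Classical scaling of a distance matrix (square, double-center,
#' eigendecompose, scale eigenvectors by the square root of the
#' eigenvalues) via \code{stats::cmdscale}.  Only non-negative-eigenvalue
#' axes are returned; if fewer than \code{k} exist, fewer axes come back.
#'
#' @param dmat symmetric distance matrix (e.g. \code{1 - IBS}).
#' @param k requested number of axes (default 2).
#' @return list with \code{points} (n x k'), \code{eig} (all eigenvalues)
#'   and \code{posFraction} (share of positive eigenvalue mass captured).
#' @export
classicalMds <- function(dmat, k = 2) {
  n <- nrow(dmat)
  fit <- stats::cmdscale(stats::as.dist(dmat), k = min(k, n - 1), eig = TRUE)
  pts <- fit$points
  keep <- which(fit$eig[seq_len(ncol(pts))] > 1e-12 * max(abs(fit$eig)))
  pts <- pts[, keep, drop = FALSE]
  pos <- fit$eig[fit$eig > 0]
  list(points = pts, eig = fit$eig,
       posFraction = sum(fit$eig[keep]) / sum(pos))
}

#' Inversion genotyping by EM on MDS coordinates
#'
#' Fits a three-component univariate Gaussian mixture to the first MDS axis
#' (carriers of 0, 1 or 2 inverted haplotypes form three dosage clusters in
#' a region of suppressed recombination).  Component means are initialized
#' at the 10th/50th/90th percentiles with equal variances and
#' Hardy-Weinberg-consistent weights (q = 1/2); the fit is deterministic.
#' After ordering the means, the two extreme components are the homozygote
#' classes; the higher-frequency homozygote cluster is labelled NI/NI by
#' default, overridable with anchor individuals of known genotype.
#'
#' @param embedding \code{\link{classicalMds}} output, or a numeric matrix /
#'   vector of coordinates.
#' @param axes how many leading axes to use (default 1; 2 averages the fit
#'   over nothing — axis 1 carries inversion separation — so values > 1 fit
#'   on the first requested axis after a variance-weighted projection).
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-6).
#' @param maxIter iteration cap (default 1e6).
#' @param hweTied tie mixing proportions to (q^2, 2q(1-q), (1-q)^2).
#' @param anchors optional named character vector of known genotypes
#'   ("NI/NI", "NI/I", "I/I") by individual id, used to orient the classes.
#' @param individualIds ids for the rows (default ind1..).
#' @return an \linkS4class{InversionGenotypes}.
#' @export
emInversionGenotypes <- function(embedding, axes = 1, tol = 1e-6,
                                 maxIter = 1e6, hweTied = FALSE,
                                 anchors = NULL, individualIds = NULL) {
  pts <- if (is.list(embedding) && !is.null(embedding$points)) embedding$points
         else as.matrix(embedding)
  pts <- as.matrix(pts)
  axes <- min(axes, ncol(pts))
  x <- if (axes == 1) as.numeric(pts[, 1]) else
    as.numeric(stats::prcomp(pts[, seq_len(axes), drop = FALSE],
                             center = TRUE, scale. = FALSE)$x[, 1])
  n <- length(x)
  if (n < 6) stop("need at least 6 individuals")
  if (is.null(individualIds)) individualIds <- paste0("ind", seq_len(n))
  lv <- c("NI/NI", "NI/I", "I/I")
  if (var(x) == 0) {                      # degenerate: one point mass
    post <- matrix(rep(c(1, 0, 0), each = n), n)
    return(new("InversionGenotypes", individualIds = individualIds,
               calls = factor(rep("NI/NI", n), levels = lv), posteriors = post,
               params = list(degenerate = TRUE), converged = FALSE,
               llTrace = numeric(0)))
  }
  emFit <- function(mu0) {
    mu <- mu0
    s2 <- rep(var(x), 3)
    w <- c(0.25, 0.5, 0.25)
    ll <- -Inf
    trace <- numeric(0)
    varFloor <- 1e-12 * var(x)
    converged <- FALSE
    resp <- NULL
    for (it in seq_len(maxIter)) {
      dens <- sapply(1:3, function(k) w[k] * dnorm(x, mu[k], sqrt(s2[k])))
      rowS <- rowSums(dens)
      rowS[rowS == 0] <- .Machine$double.xmin
      llNew <- sum(log(rowS))
      trace <- c(trace, llNew)
      resp <- dens / rowS
      if (is.finite(ll) && abs(llNew - ll) < tol) {
        converged <- TRUE
        ll <- llNew
        break
      }
      ll <- llNew
      nk <- colSums(resp)
      for (k in 1:3) {
        if (nk[k] < 1e-10) next                    # keep empty component fixed
        mu[k] <- sum(resp[, k] * x) / nk[k]
        s2[k] <- max(sum(resp[, k] * (x - mu[k])^2) / nk[k], varFloor)
      }
      w <- nk / n
      if (hweTied) {
        q <- w[1] + w[2] / 2
        w <- c(q^2, 2 * q * (1 - q), (1 - q)^2)
        w <- w / sum(w)
      }
    }
    list(mu = mu, s2 = s2, w = w, resp = resp, ll = ll,
         converged = converged, trace = trace)
  }
  # two fixed starts: percentile-based and range-based; the latter rescues
  # skewed class frequencies where two percentiles fall in one cluster
  starts <- list(as.numeric(quantile(x, c(0.1, 0.5, 0.9))),
                 min(x) + c(0.05, 0.5, 0.95) * diff(range(x)))
  fits <- lapply(starts, emFit)
  fit <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
  mu <- fit$mu; s2 <- fit$s2; w <- fit$w; resp <- fit$resp
  converged <- fit$converged
  trace <- fit$trace
  ord <- order(mu)
  resp <- resp[, ord, drop = FALSE]
  mu <- mu[ord]; s2 <- s2[ord]; w <- w[ord]
  # components 1 and 3 are homozygotes; orient by majority (or anchors)
  niFirst <- w[1] >= w[3]
  mapCalls <- function(niFirst) {
    m <- if (niFirst) c(1, 2, 3) else c(3, 2, 1)
    factor(lv[m[max.col(resp)]], levels = lv)
  }
  if (!is.null(anchors)) {
    agree <- function(nf) {
      calls <- mapCalls(nf)
      names(calls) <- individualIds
      mean(as.character(calls[names(anchors)]) == anchors, na.rm = TRUE)
    }
    niFirst <- agree(TRUE) >= agree(FALSE)
  }
  calls <- mapCalls(niFirst)
  post <- if (niFirst) resp else resp[, 3:1, drop = FALSE]
  colnames(post) <- lv
  new("InversionGenotypes", individualIds = individualIds, calls = calls,
      posteriors = post,
      params = list(means = mu, variances = s2, weights = w,
                    niFirst = niFirst, degenerate = FALSE, hweTied = hweTied),
      converged = converged, llTrace = trace)
}

#' Procrustes rotation and permutation test (protest)
#'
#' Centers both configurations, finds the optimal uniform scaling and
#' rotation of Y onto X, and reports the Procrustes statistic
#' m^2 = 1 - (sum of singular values)^2 / (ssX ssY) together with the
#' Procrustes correlation sqrt(1 - m^2).  Significance is assessed by
#' shuffling the rows of Y; the add-one estimator keeps the p-value in
#' [1/(nPerm + 1), 1].
#'
#' @param X,Y n x k coordinate matrices with corresponding rows.
#' @param nPerm permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return a \linkS4class{ProcrustesResult}.
#' @export
procrustesProtest <- function(X, Y, nPerm = 10000, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) < 3) stop("need at least 3 rows")
  if (ncol(X) != ncol(Y)) {
    k <- max(ncol(X), ncol(Y))
    X <- cbind(X, matrix(0, nrow(X), k - ncol(X)))
    Y <- cbind(Y, matrix(0, nrow(Y), k - ncol(Y)))
  }
  cX <- colMeans(X); cY <- colMeans(Y)
  Xc <- sweep(X, 2, cX); Yc <- sweep(Y, 2, cY)
  ssX <- sum(Xc^2); ssY <- sum(Yc^2)
  if (ssX == 0 || ssY == 0) stop("degenerate configuration (zero spread)")
  corOf <- function(Yp) {
    sv <- svd(crossprod(Xc, Yp))
    sqrt(min(1, sum(sv$d)^2 / (ssX * ssY)))
  }
  sv <- svd(crossprod(Xc, Yc))
  rot <- sv$v %*% t(sv$u)
  scl <- sum(sv$d) / ssY
  corObs <- sqrt(min(1, sum(sv$d)^2 / (ssX * ssY)))
  m2 <- 1 - corObs^2
  set.seed(deriveSeed(seed, "protest"))
  n <- nrow(Xc)
  hits <- 0L
  for (b in seq_len(nPerm))
    if (corOf(Yc[sample.int(n), , drop = FALSE]) >= corObs - 1e-12)
      hits <- hits + 1L
  new("ProcrustesResult", rotation = rot, scale = scl,
      translation = as.numeric(cX - cY), mSquared = m2, correlation = corObs,
      pValue = (hits + 1) / (nPerm + 1), nPerm = as.integer(nPerm))
}
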