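test_that("EHH is 1 everywhere for identical carriers and integrates the span", {
  h <- rbind(matrix(0L, 5, 7), matrix(1L, 5, 7))   # derived carriers identical
  p <- makePanel(h, cmStep = 0.1)
  r <- ehh(p, 4, "derived")
  expect_true(all(r$curve$ehh == 1))
  expect_true(r$censored)
  expect_equal(r$ihh, 0.6)    # 0.3 cM each side
})

test_that("hand-built four-haplotype fixture gives iHH_D = 0.2", {
  snps <- snpMeta(3)
  snps$cm <- c(0, 0.1, 0.2)
  h <- rbind(c(0L, 1L, 0L), c(1L, 0L, 1L),      # ancestral at core, differ
             c(1L, 1L, 1L), c(1L, 1L, 1L))      # derived carriers identical
  h[1, 2] <- 0L; h[2, 2] <- 0L                  # core SNP2: rows 1,2 ancestral
  p <- HaplotypePanel(h, snps)
  r <- ehh(p, 2, "derived")
  expect_equal(r$ihh, 0.2)
  expect_true(all(r$curve$ehh == 1))
})

test_that("optimized EHH equals the brute-force pairwise-identity oracle", {
  set.seed(33)
  for (rep in 1:20) {
    M <- sample(8:15, 1)
    h <- matrix(rbinom(10 * M, 1, runif(1, 0.3, 0.7)), nrow = 10)
    core <- sample(2:(M - 1), 1)
    if (sum(h[, core] == 1) < 2 || sum(h[, core] == 0) < 2) next
    p <- makePanel(h, cmStep = 0.05)
    for (cls in c("ancestral", "derived", "all")) {
      r <- ehh(p, core, cls, ehhFloor = 0, maxGapBp = 1e9)
      carriers <- switch(cls, ancestral = which(h[, core] == 0),
                         derived = which(h[, core] == 1), all = 1:10)
      for (k in seq_len(nrow(r$curve))) {
        j <- core + round(r$curve$offsetCm[k] / 0.05)
        expect_equal(r$curve$ehh[k], bruteEhh(h, carriers, core, j),
                     tolerance = 1e-12)
      }
      expect_true(all(diff(r$curve$ehh[r$curve$side == "right"]) <= 1e-12))
    }
  }
})

test_that("EHH handles carrier shortage and gap censoring", {
  h <- matrix(0L, 4, 5)
  h[3, 3] <- 1L                                   # single derived carrier
  p <- makePanel(h)
  expect_equal(ehh(p, 3, "derived")$missing, "fewer than 2 carriers")
  snps <- snpMeta(4)
  snps$pos <- as.integer(c(1e5, 2e5, 9e5, 1e6))   # 700 kb gap
  snps$cm <- snps$pos / 1e6
  p2 <- HaplotypePanel(matrix(rep(c(0L, 1L), 8), nrow = 4), snps)
  r <- ehh(p2, 2, "all", ehhFloor = 0, maxGapBp = 2e5)
  expect_true(r$censored)
  expect_true(all(r$curve$offsetCm <= 0.1 + 1e-12))
})

test_that("intrapopulation scan standardizes within DAF bins", {
  cfg <- simConfig(nSnps = 1200, chromLengthBp = 4e7, chromLengthCm = 40,
                   panelSize = 60, cohortSize = 5, founders = 30, seed = 91)
  ref <- simulateReferencePanels(cfg)
  tr <- intrapopScan(ref$panels$EUR, nBins = 10)
  z <- statValues(tr$iHS)
  expect_true(all(is.finite(z[!is.na(z)])))
  raw <- rawValues(tr$iHS)
  daf <- colMeans(haplotypes(ref$panels$EUR) == 1)
  bs <- admixscan:::binStandardize(raw, daf, 10)
  for (b in unique(bs$bin[!is.na(bs$bin)])) {
    i <- which(bs$bin == b)
    if (length(i) < 100) next
    expect_lt(abs(mean(bs$std[i])), 0.05)
    expect_lt(abs(sd(bs$std[i]) - 1), 0.05)
  }
  # missing reasons are attributed
  expect_true(all(is.na(raw) == !is.na(tr$iHS@missingReason)))
})

test_that("XP-EHH is zero against itself and antisymmetric between panels", {
  # founder count keeps background haplotype sharing (~1/K) below the EHH
  # floor, so curves can actually terminate instead of censoring everywhere
  cfg <- simConfig(nSnps = 400, chromLengthBp = 2e7, chromLengthCm = 20,
                   panelSize = 30, cohortSize = 5, founders = 60, seed = 95)
  ref <- simulateReferencePanels(cfg)
  a <- ref$panels$EUR; b <- ref$panels$AFR
  self <- interpopScan(a, a)
  expect_true(all(rawValues(self$XPEHH)[!is.na(rawValues(self$XPEHH))] == 0))
  ab <- rawValues(interpopScan(a, b)$XPEHH)
  ba <- rawValues(interpopScan(b, a)$XPEHH)
  ok <- !is.na(ab) & !is.na(ba)
  expect_gt(sum(ok), 50)
  expect_equal(ab[ok], -ba[ok], tolerance = 1e-12)
})

test_that("Hudson Fst matches closed-form values and is exchangeable", {
  expect_equal(hudsonFst(1, 10, 0, 10), 1)
  expect_equal(hudsonFst(0.6, 10, 0.2, 10),
               (0.16 - 0.6 * 0.4 / 9 - 0.2 * 0.8 / 9) / 0.56)
  expect_equal(round(hudsonFst(0.6, 10, 0.2, 10), 4), 0.2063)
  expect_true(is.na(hudsonFst(0, 10, 0, 10)))    # both fixed, skipped
  expect_error(hudsonFst(0.5, 1, 0.5, 10), ">= 2")
  set.seed(44)
  p1 <- runif(100); p2 <- runif(100)
  expect_equal(hudsonFst(p1, 30, p2, 50), hudsonFst(p2, 50, p1, 30))
  # windowed mode tiles 1 Mb and excludes doubly-fixed sites
  snps <- data.frame(chrom = "1", pos = c(5e5, 7e5, 1.5e6))
  w <- hudsonFstWindows(c(1, 1, 0.5), 20, c(0, 1, 0.5), 20, snps)
  expect_equal(nrow(w), 2)
  expect_equal(w$nSnps, c(1, 1))   # the doubly-fixed SNP is dropped
  expect_equal(w$fst[1], 1)
})

test_that("PBS matches closed forms and is additive in branch lengths", {
  expect_equal(pbs(0, 0, 0), 0)
  expect_equal(pbs(0.1, 0.1, 0), -log(0.9))
  expect_equal(pbs(0.1, 0.1, 0.1), -log(0.9) / 2)
  # with T_AB = a+b, T_AC = a+c, T_BC = b+c, PBS recovers a exactly
  set.seed(55)
  for (r in 1:20) {
    abc <- runif(3, 0, 0.5)
    f <- function(t) 1 - exp(-t)   # invert T = -ln(1 - Fst)
    expect_equal(pbs(f(abc[1] + abc[2]), f(abc[1] + abc[3]),
                     f(abc[2] + abc[3])), abc[1], tolerance = 1e-12)
  }
  # negative Fst clipped to zero before the log
  expect_equal(pbs(-0.05, 0, 0), 0)
})
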