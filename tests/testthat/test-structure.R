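test_that("IBS matches hand values and is symmetric with unit diagonal", {
  g <- rbind(a = c(0, 1, 2), b = c(0, 1, 0), c = c(2, 1, 0))
  m <- ibsMatrix(g)$ibs
  expect_equal(m["a", "b"], 2 / 3)
  expect_equal(m["a", "c"], (0 + 1 + 0) / 3)
  expect_equal(diag(m), setNames(c(1, 1, 1), c("a", "b", "c")))
  expect_equal(m, t(m))
  expect_equal(ibsMatrix(rbind(c(0, 2), c(2, 0)))$ibs[1, 2], 0)
  expect_equal(ibsMatrix(rbind(g[1, ], g[1, ]))$ibs[1, 2], 1)
  # pairwise-complete with missing data
  gm <- rbind(c(0, NA, 2, 1), c(0, 1, 2, NA))
  r <- ibsMatrix(gm)
  expect_equal(r$ibs[1, 2], 1)
  expect_equal(r$nSnps[1, 2], 2)
  expect_error(ibsMatrix(rbind(c(NA, 1), c(1, NA))), "share no SNPs")
  expect_true(all(ibsMatrix(matrix(rbinom(60, 2, 0.5), 6))$ibs >= 0))
})

test_that("classical MDS embeds exact configurations", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)      # collinear points
  pts <- classicalMds(d, k = 2)$points
  expect_equal(ncol(pts), 1)                        # 1-D geometry
  x <- sort(pts[, 1])
  expect_equal(x - x[2], c(-1, 0, 1), tolerance = 1e-9)
  # planted 2-D cloud is recovered up to rotation (self-consistency)
  set.seed(41)
  X <- matrix(rnorm(40), 20, 2)
  emb <- classicalMds(as.matrix(dist(X)), k = 2)
  expect_equal(as.matrix(dist(emb$points)), as.matrix(dist(X)),
               tolerance = 1e-9, ignore_attr = TRUE)
  pr <- procrustesProtest(X, emb$points, nPerm = 99, seed = 1)
  expect_gt(pr@correlation, 0.999)
  # duplicate rows land on coincident coordinates
  d4 <- as.matrix(dist(rbind(X[1:3, ], X[3, ])))
  emb4 <- classicalMds(d4, k = 2)$points
  expect_equal(emb4[3, ], emb4[4, ], tolerance = 1e-9)
})

test_that("EM genotyping recovers planted Gaussian clusters", {
  set.seed(47)
  n <- c(170, 100, 30)                   # skewed HWE-ish class counts
  x <- c(rnorm(n[1], -1, 0.01), rnorm(n[2], 0, 0.01), rnorm(n[3], 1, 0.01))
  truth <- rep(c("NI/NI", "NI/I", "I/I"), n)
  g <- emInversionGenotypes(cbind(x))
  expect_true(g@converged)
  expect_gte(mean(as.character(genotypeCalls(g)) == truth), 0.99)
  expect_gte(mean(apply(classPosteriors(g), 1, max) > 0.99), 0.99)
  # log-likelihood never decreases along the trace
  expect_true(all(diff(g@llTrace) > -1e-8))
  # HWE-tied weights give the same calls here
  gt <- emInversionGenotypes(cbind(x), hweTied = TRUE)
  expect_gte(mean(genotypeCalls(gt) == genotypeCalls(g)), 0.99)
})

test_that("EM genotyping handles degenerate and anchored cases", {
  g0 <- emInversionGenotypes(cbind(rep(0.5, 10)))
  expect_false(g0@converged)
  expect_true(g0@params$degenerate)
  expect_true(all(genotypeCalls(g0) == "NI/NI"))
  expect_error(emInversionGenotypes(cbind(rnorm(5))), "at least 6")
  # anchors can flip the orientation chosen by majority
  set.seed(53)
  x <- c(rnorm(30, -1, 0.01), rnorm(10, 1, 0.01))
  ids <- paste0("s", 1:40)
  gMaj <- emInversionGenotypes(cbind(x), individualIds = ids)
  expect_equal(as.character(genotypeCalls(gMaj)[1]), "NI/NI")
  gAnc <- emInversionGenotypes(cbind(x), individualIds = ids,
                               anchors = c(s1 = "I/I"))
  expect_equal(as.character(genotypeCalls(gAnc)[1]), "I/I")
})

test_that("planted inversions are genotyped from region IBS end to end", {
  cfg <- simConfig(nSnps = 600, panelSize = 60, cohortSize = 250, seed = 57)
  ref <- simulateReferencePanels(cfg)
  adm <- simulateAdmixedCohort(ref$panels, cfg)
  reg <- regionInterval("1", 3e7, 6e7)
  inv <- injectInversion(ref$panels, adm$cohort, adm$truth, reg,
                         c(EUR = 0.3, AFR = 0.2, NAT = 0.05), d = 0.2,
                         seed = 59)
  emb <- classicalMds(1 - ibsMatrix(inv$cohort, inv$regionSnps)$ibs, k = 2)
  g <- emInversionGenotypes(emb, individualIds = individualIds(inv$cohort))
  acc <- mean(as.character(genotypeCalls(g)) == as.character(inv$invGenotypes))
  expect_gte(acc, 0.95)
})

test_that("random regions are length-matched, exclusion-aware, deterministic", {
  snps <- rbind(snpMeta(500, chrom = "1", spacingBp = 10000),
                snpMeta(500, chrom = "2", spacingBp = 10000))
  r <- sampleRandomRegions(snps, 1883857, n = 7, seed = 5)
  expect_length(r, 7)
  expect_true(all(regionLength(r, "bp") == 1883857))
  r2 <- sampleRandomRegions(snps, 1883857, n = 7, seed = 5)
  expect_identical(as.data.frame(r), as.data.frame(r2))
  # excluding all of chromosome 1 keeps every region on chromosome 2
  excl <- regionInterval("1", 1, 6e6)
  r3 <- sampleRandomRegions(snps, 1883857, n = 5, exclude = excl, seed = 7)
  expect_true(all(as.character(GenomicRanges::seqnames(r3)) == "2"))
  expect_error(sampleRandomRegions(snps, 1e9, n = 1), "long enough")
})

test_that("Procrustes correlation is transformation-invariant with add-one p", {
  set.seed(61)
  X <- matrix(rnorm(60), 30, 2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Y <- 3.2 * X %*% R + matrix(rep(c(5, -2), each = 30), 30)
  pr <- procrustesProtest(X, Y, nPerm = 200, seed = 3)
  expect_equal(pr@correlation, 1, tolerance = 1e-10)
  expect_equal(pr@mSquared, 0, tolerance = 1e-10)
  expect_equal(pr@pValue, 1 / 201)
  # independent configurations: low correlation, non-significant
  Z <- matrix(rnorm(60), 30, 2)
  pr2 <- procrustesProtest(X, Z, nPerm = 200, seed = 5)
  expect_lt(pr2@correlation, 0.6)
  expect_gt(pr2@pValue, 0.01)
  expect_error(procrustesProtest(X[1:2, ], Y[1:2, ]), "at least 3")
})

test_that("Procrustes statistic agrees with the vegan protest oracle", {
  set.seed(67)
  for (r in 1:5) {
    X <- matrix(rnorm(50), 25, 2)
    Y <- X + matrix(rnorm(50, sd = c(0.1, 0.5, 1)[1 + r %% 3]), 25, 2)
    ours <- procrustesProtest(X, Y, nPerm = 49, seed = 1)
    ref <- vegan::protest(X, Y, permutations = 49)
    expect_equal(ours@correlation, sqrt(1 - ref$ss), tolerance = 1e-10)
  }
})
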