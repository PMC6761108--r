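test_that("reference panels are deterministic and share SNP metadata", {
  cfg <- simConfig(nSnps = 300, panelSize = 20, cohortSize = 10, seed = 11)
  a <- simulateReferencePanels(cfg)
  b <- simulateReferencePanels(cfg)
  expect_identical(a, b)
  expect_identical(snpInfo(a$panels$EUR), snpInfo(a$panels$NAT))
  expect_true(all(haplotypes(a$panels$AFR) %in% 0:1))
})

test_that("F = 0 makes every population share the ancestral frequency", {
  cfg <- simConfig(nSnps = 200, panelSize = 20, cohortSize = 10,
                   fDrift = c(0, 0, 0), seed = 5)
  ref <- simulateReferencePanels(cfg)
  expect_equal(ref$popFreqs[, "EUR"], ref$popFreqs[, "AFR"])
  expect_equal(ref$popFreqs[, "EUR"], ref$popFreqs[, "NAT"])
})

test_that("windowed Hudson Fst between panels recovers the drift parameter", {
  cfg <- simConfig(nSnps = 2000, panelSize = 100, cohortSize = 10, seed = 7)
  ref <- simulateReferencePanels(cfg)
  f1 <- alleleFreqs(ref$panels$EUR)
  f2 <- alleleFreqs(ref$panels$AFR)
  w <- hudsonFstWindows(f1$p, f1$n, f2$p, f2$n, snpInfo(ref$panels$EUR))
  expect_lt(abs(weighted.mean(w$fst, w$nSnps) - 0.15), 0.03)
  # per-SNP mean-of-ratios agrees with an independent frequency-level
  # simulation of the same Balding-Nichols model (no haplotype structure)
  perSnp <- mean(hudsonFst(f1$p, f1$n, f2$p, f2$n), na.rm = TRUE)
  set.seed(99)
  M <- 20000; F <- 0.15; n <- 100
  pa <- runif(M, 0.05, 0.95)
  q1 <- rbeta(M, pa * (1 - F) / F, (1 - pa) * (1 - F) / F)
  q2 <- rbeta(M, pa * (1 - F) / F, (1 - pa) * (1 - F) / F)
  p1 <- rbinom(M, n, q1) / n; p2 <- rbinom(M, n, q2) / n
  oracle <- mean(hudsonFst(p1, n, p2, n), na.rm = TRUE)
  expect_lt(abs(perSnp - oracle), 0.02)
})

test_that("admixed cohorts follow the admixture proportions and tract model", {
  cfg <- simConfig(nSnps = 1000, chromLengthCm = 50, panelSize = 30,
                   cohortSize = 100, admixtureProps = c(0.77, 0.14, 0.09),
                   seed = 13)
  ref <- simulateReferencePanels(cfg)
  adm <- simulateAdmixedCohort(ref$panels, cfg)
  props <- colMeans(ancestryProportions(adm$truth)$props)
  # genome-wide proportions near pi (haplotype-level draws are correlated
  # along the genome; allow a generous band around the binomial SD)
  nHap <- 200
  for (k in 1:3) {
    se <- sqrt(cfg$admixtureProps[k] * (1 - cfg$admixtureProps[k]) / nHap)
    expect_lt(abs(props[k] - cfg$admixtureProps[k]), 6 * se)
  }
  # every SNP of every haplotype covered by exactly one tract
  tr <- tracts(adm$truth)
  expect_true(all(tapply(tr$endSnp - tr$startSnp + 1L, tr$hap, sum) == 1000))
  expect_true(all(tr$posterior == 1))
})

test_that("pi = (1,0,0) gives an all-EUR cohort", {
  cfg <- simConfig(nSnps = 200, panelSize = 10, cohortSize = 5,
                   admixtureProps = c(1, 0, 0), seed = 2)
  ref <- simulateReferencePanels(cfg)
  adm <- simulateAdmixedCohort(ref$panels, cfg)
  expect_true(all(ancestryCodes(adm$truth) == 1L))
})

test_that("switch counts match the Markov expectation and scale with g", {
  countSwitches <- function(truth) {
    codes <- ancestryCodes(truth)
    sum(apply(codes, 1, function(r) sum(diff(r) != 0)))
  }
  pi <- c(0.77, 0.14, 0.09)
  base <- simConfig(nSnps = 800, chromLengthCm = 100, panelSize = 20,
                    cohortSize = 250, admixtureProps = pi, generations = 10,
                    seed = 21)
  ref <- simulateReferencePanels(base)
  adm10 <- simulateAdmixedCohort(ref$panels, base)
  obs10 <- countSwitches(adm10$truth) / 500
  expected <- 10 * 1 * (1 - sum(pi^2))   # g x Morgans x P(redraw changes state)
  expect_lt(abs(obs10 - expected) / expected, 0.1)
  cfg20 <- base; cfg20$generations <- 20; cfg20$seed <- 22
  adm20 <- simulateAdmixedCohort(ref$panels, cfg20)
  ratio <- (countSwitches(adm20$truth) / 500) / obs10
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("emitted alleles are copied from panels of the true ancestry", {
  cfg <- simConfig(nSnps = 150, panelSize = 10, cohortSize = 8, seed = 31)
  ref <- simulateReferencePanels(cfg)
  adm <- simulateAdmixedCohort(ref$panels, cfg)
  h <- haplotypes(adm$cohort)
  codes <- ancestryCodes(adm$truth)
  # every emitted allele exists among the donor-ancestry panel's alleles
  for (i in sample(nrow(h), 4)) {
    for (j in sample(ncol(h), 30)) {
      pool <- haplotypes(ref$panels[[codes[i, j]]])[, j]
      expect_true(h[i, j] %in% pool)
    }
  }
})

test_that("planted ancestry deviation hits its target proportions", {
  cfg <- simConfig(nSnps = 600, panelSize = 30, cohortSize = 250, seed = 41)
  ref <- simulateReferencePanels(cfg)
  adm <- simulateAdmixedCohort(ref$panels, cfg)
  reg <- regionInterval("1", 4e7, 5e7)
  dev <- injectAncestryDeviation(adm$cohort, adm$truth, ref$panels, reg,
                                 targetProps = c(0.025, 0.025, 0.95), seed = 43)
  j <- admixscan:::snpsInRegion(snpInfo(adm$cohort), reg)
  natIn <- mean(ancestryCodes(dev$truth)[, j] == 3L)
  expect_gte(natIn, 0.93)   # binomial 99% interval at n = 500
  expect_lte(natIn, 0.97)
  # outside the region nothing changes
  out <- setdiff(seq_len(600), j)
  expect_identical(ancestryCodes(dev$truth)[, out], ancestryCodes(adm$truth)[, out])
  expect_identical(haplotypes(dev$cohort)[, out], haplotypes(adm$cohort)[, out])
  # empty region is a byte-for-byte no-op
  reg0 <- regionInterval("1", 2, 5)
  dev0 <- injectAncestryDeviation(adm$cohort, adm$truth, ref$panels, reg0,
                                  targetProps = c(0.025, 0.025, 0.95))
  expect_identical(dev0$cohort, adm$cohort)
  expect_error(injectAncestryDeviation(adm$cohort, adm$truth, ref$panels, reg,
                                       targetProps = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("planted inversions create diverged classes in HWE-consistent doses", {
  cfg <- simConfig(nSnps = 600, panelSize = 60, cohortSize = 500, seed = 51)
  ref <- simulateReferencePanels(cfg)
  adm <- simulateAdmixedCohort(ref$panels, cfg)
  reg <- regionInterval("1", 3e7, 5e7)
  freqs <- c(EUR = 0.2, AFR = 0.5, NAT = 0.02)
  inv <- injectInversion(ref$panels, adm$cohort, adm$truth, reg, freqs,
                         d = 0.3, seed = 53)
  # within-class vs between-class IBS separation on truth-labelled haplotypes
  j <- inv$regionSnps
  h <- haplotypes(inv$cohort)[, j]
  hapIbs <- function(a, b) mean(a == b)
  set.seed(1)
  iHaps <- which(inv$invClass == "I"); nHaps <- which(inv$invClass == "NI")
  win <- mean(replicate(200, {
    p <- sample(nHaps, 2); hapIbs(h[p[1], ], h[p[2], ]) }))
  btw <- mean(replicate(200, hapIbs(h[sample(iHaps, 1), ], h[sample(nHaps, 1), ])))
  expect_gte(win - btw, 0.2)
  # genotype counts consistent with admixture-weighted HWE expectation
  anc <- ancestryCodes(inv$truth)[, j[1]]
  qBar <- sum(vapply(1:3, function(a) mean(anc == a) * freqs[a], 0))
  expHwe <- c((1 - qBar)^2, 2 * qBar * (1 - qBar), qBar^2) * 500
  obs <- as.vector(table(inv$invGenotypes))
  expect_gt(stats::chisq.test(obs, p = expHwe / 500)$p.value, 0.01)
  # zero inverted-class frequency -> everyone NI/NI
  inv0 <- injectInversion(ref$panels, adm$cohort, adm$truth, reg,
                          c(EUR = 0, AFR = 0, NAT = 0), d = 0.3, seed = 55)
  expect_true(all(inv0$invGenotypes == "NI/NI"))
  expect_error(injectInversion(ref$panels, adm$cohort, adm$truth, reg,
                               freqs, d = 0), "d must")
})
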