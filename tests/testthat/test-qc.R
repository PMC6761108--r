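test_that("exact HWE test matches enumeration oracles", {
  expect_equal(hweExactTest(5, 0, 0), 1)           # monomorphic
  expect_equal(hweExactTest(1, 0, 1), 1 / 3)       # 2+2 alleles, het in {0,2}
  # textbook-formula oracle over random counts up to n = 20
  set.seed(8)
  for (r in 1:40) {
    n <- sample(2:20, 1)
    nA <- sample(0:(2 * n), 1)
    m <- min(nA, 2 * n - nA)
    het <- sample(seq(m %% 2, m, by = 2), 1)
    cnt <- c((nA - het) / 2, het, (2 * n - nA - het) / 2)
    expect_equal(hweExactTest(cnt[1], cnt[2], cnt[3]),
                 hweOracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
  # fully independent perfect-matching enumeration for tiny n
  for (cnt in list(c(1, 0, 1), c(2, 1, 0), c(1, 2, 1), c(0, 3, 1), c(2, 0, 2)))
    expect_equal(hweExactTest(cnt[1], cnt[2], cnt[3]),
                 unname(hweMatchings(cnt[1], cnt[2], cnt[3])), tolerance = 1e-12)
  expect_error(hweExactTest(0, 0, 0), "zero")
})

test_that("site filters attribute each SNP to its first failing category", {
  snps <- snpMeta(10)
  snps$ref <- c("A", "A", "G", "A", "A", "C", "A", "A", "A", "A")
  snps$alt <- c("G", "T", "C", "G", "G", "G", "G", "G", "G", "G")
  snps$pos[9] <- NA                      # unmapped
  snps$chrom[10] <- "X"                  # non-autosomal
  set.seed(3)
  geno <- matrix(rbinom(50 * 10, 1, 0.4) + rbinom(50 * 10, 1, 0.4), nrow = 50)
  geno[, 2] <- c(rep(0, 25), rep(2, 25)) # HWE failure, but SNP2 is ambiguous
  geno[, 4] <- c(rep(0, 25), rep(2, 25)) # HWE failure only
  geno[, 5] <- c(1, rep(0, 49))          # rare: MAF = 0.01 exactly -> kept
  geno[, 7] <- c(rep(NA, 3), geno[4:50, 7])  # 6% missing
  res <- applySiteFilters(geno, snps)
  expect_equal(unname(removals(res$ledger)),
               c(1L, 1L, 3L, 1L, 1L, 0L))  # unmapped, non-aut, ambig, HWE, miss, MAF
  expect_equal(res$fate[2], "ambiguous")   # doubly-failing SNP counts as ambiguous
  expect_equal(res$fate[4], "HWE")
  expect_equal(res$fate[7], "missingness")
  expect_true(5 %in% res$kept)
  expect_equal(remaining(res$ledger), length(res$kept))
})

test_that("ledger arithmetic is conserved", {
  led <- QcLedger(906600, c(unmapped = 1428, nonautosomal = 37149,
                            ambiguous = 134006, hwe = 128380))
  expect_equal(remaining(led), 906600 - sum(removals(led)))
  expect_error(new("QcLedger", start = 10L, removals = c(a = 2L),
                   remaining = 9L, individualRemovals = data.frame()),
               "remaining")
})

test_that("heterozygosity outliers follow the k-SD contract", {
  set.seed(5)
  geno <- do.call(rbind, lapply(c(rep(0.31, 20), 0.9), function(r)
    as.integer(runif(200) < r)))
  out <- heterozygosityOutliers(geno, k = 2)
  expect_equal(out$flagged, 21L)
  # all rates equal -> SD = 0 guard, no flags
  same <- matrix(1L, nrow = 5, ncol = 50)
  expect_length(heterozygosityOutliers(same)$flagged, 0)
  # k = 0 flags every individual off the mean
  out0 <- heterozygosityOutliers(geno, k = 0)
  expect_setequal(out0$flagged, which(out$rates != out$mean))
  expect_error(heterozygosityOutliers(geno[1, , drop = FALSE]), "two individuals")
})

test_that("greedy relatedness pruning removes hubs and keeps boundary pairs", {
  rel <- diag(1, 4)
  expect_equal(greedyRelatednessPrune(rel)$kept, 1:4)
  # path graph A-B 0.3, B-C 0.2: the degree-2 node B goes
  rel2 <- diag(1, 3)
  rel2[1, 2] <- rel2[2, 1] <- 0.3
  rel2[2, 3] <- rel2[3, 2] <- 0.2
  pr <- greedyRelatednessPrune(rel2)
  expect_equal(pr$kept, c(1, 3))
  expect_equal(pr$removed$id, 2)
  # exactly at the third-degree expectation 2 x (1/2)^4 = 0.125 -> kept
  rel3 <- diag(1, 2)
  rel3[1, 2] <- rel3[2, 1] <- 2 * (1 / 2)^4
  expect_equal(greedyRelatednessPrune(rel3)$kept, 1:2)
  # duplicates removed first, keeping the lower index
  rel4 <- diag(1, 3)
  rel4[1, 3] <- rel4[3, 1] <- 0.9
  pr4 <- greedyRelatednessPrune(rel4)
  expect_equal(pr4$kept, 1:2)
  expect_equal(pr4$removed$reason, "duplicate")
  bad <- rel2; bad[1, 2] <- 0.9
  expect_error(greedyRelatednessPrune(bad), "symmetric")
  # termination + no remaining edge on random matrices
  set.seed(9)
  for (r in 1:5) {
    n <- 12
    m <- matrix(runif(n * n, 0, 0.4), n); m <- (m + t(m)) / 2; diag(m) <- 1
    kept <- greedyRelatednessPrune(m)$kept
    sub <- m[kept, kept]; diag(sub) <- 0
    expect_true(all(sub <= 0.125))
  }
})

test_that("LD pruning drops the later SNP of correlated pairs and audits clean", {
  set.seed(12)
  base <- rbinom(60, 1, 0.5) + rbinom(60, 1, 0.5)
  geno <- cbind(base, base, rbinom(60, 1, 0.5) + rbinom(60, 1, 0.5))
  expect_equal(ldPrune(geno, window = 3, step = 1), c(1, 3))
  indep <- sapply(1:8, function(i) rbinom(100, 2, 0.5))
  expect_equal(ldPrune(indep, window = 5, step = 2), 1:8)
  # post-condition audit on random LD-structured fixtures
  for (r in 1:3) {
    h <- matrix(rbinom(40 * 30, 1, 0.5), nrow = 40)
    h[, seq(2, 30, 3)] <- h[, seq(1, 29, 3)]   # inject strong pairwise LD
    g <- h[seq(1, 39, 2), ] + h[seq(2, 40, 2), ]
    kept <- ldPrune(g, window = 6, step = 2, r2 = 0.5)
    for (s in seq(1, 25, 2)) {
      idx <- intersect(s:(s + 5), kept)
      if (length(idx) < 2) next
      cc <- suppressWarnings(cor(g[, idx]))^2
      cc[is.na(cc)] <- 0
      diag(cc) <- 0
      expect_true(all(cc <= 0.5 + 1e-12))
    }
  }
})
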