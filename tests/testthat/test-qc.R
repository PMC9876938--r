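test_that("SNP missingness filter applies the strict per-wave/merged rule", {
  set.seed(1)
  G <- matrix(0L, 100, 4)
  ## site 1: 6% missing in wave 1 only; site 2: clean; site 3: exactly 5%
  ## everywhere; site 4: 6% merged
  co <- cohortFromMatrix(G, waves = 2L)
  w1 <- which(sampleInfo(co)$wave == "w1")
  co@genotypes[w1[1:3], 1] <- NA_integer_       # 3/50 = 6% in wave 1
  co@genotypes[c(w1[1:2], setdiff(1:100, w1)[1:3]), 3] <- NA_integer_
  co@genotypes[co@genotypes[, 3] == 99L, 3] <- NA_integer_
  co@genotypes[, 3] <- 0L
  co@genotypes[c(w1[seq_len(round(0.05 * 50))],
                 setdiff(1:100, w1)[seq_len(round(0.05 * 50))]), 3] <-
    NA_integer_                                  # exactly 5% per wave
  co@genotypes[sample(1:100, 6), 4] <- NA_integer_   # 6% merged
  r <- snpMissingnessFilter(co, 0.05)
  expect_true(1L %in% excludedSites(r))
  expect_false(2L %in% excludedSites(r))
  expect_false(3L %in% excludedSites(r))          # strict '>' boundary
  expect_true(4L %in% excludedSites(r))
  ## idempotence on survivors
  co2 <- dropSites(co, excludedSites(r))
  expect_length(excludedSites(snpMissingnessFilter(co2, 0.05)), 0)
})

test_that("differential missingness matches the closed-form 2x2 chi-square", {
  G <- matrix(1L, 200, 2)
  case <- rep(c(TRUE, FALSE), each = 100)
  co <- cohortFromMatrix(G, case = case)
  co@genotypes[1:10, 1] <- NA_integer_            # 10/100 missing in cases
  r <- differentialMissingnessTest(co, 0.2)
  ## hand-computed Pearson chi-square for (10,90 / 0,100)
  a <- 10; b <- 90; cc <- 0; dd <- 100; n <- 200
  stat <- n * (a * dd - b * cc)^2 / ((a + b) * (cc + dd) * (a + cc) * (b + dd))
  expect_equal(qcStats(r)$stat[1], stat, tolerance = 1e-12)
  expect_equal(qcStats(r)$stat[2], 0)
  expect_equal(qcStats(r)$p[2], 1)
  expect_true(1L %in% excludedSites(r))
  expect_false(2L %in% excludedSites(r))
  expect_error(differentialMissingnessTest(
    cohortFromMatrix(G, case = rep(TRUE, 200))), "cases and controls")
})

test_that("null differential missingness rarely excludes under BH", {
  frac <- replicate(20, {
    G <- matrix(1L, 150, 50)
    G[matrix(runif(length(G)) < 0.05, 150, 50)] <- NA_integer_
    co <- cohortFromMatrix(G, case = rep_len(c(TRUE, FALSE), 150))
    r <- differentialMissingnessTest(co, 0.2)
    length(excludedSites(r)) / 50
  })
  expect_lte(mean(frac), 0.25)
})

test_that("HWE chi-square matches closed forms and skips monomorphic sites", {
  ## perfect proportions (25, 50, 25), extreme (0, 100, 0), monomorphic
  G <- cbind(rep(c(0L, 1L, 2L), c(25, 50, 25)),
             rep(1L, 100),
             rep(0L, 100))
  co <- cohortFromMatrix(G, case = rep(FALSE, 100))
  r <- hweTest(co, fdrThreshold = 0.2)
  expect_equal(qcStats(r)$stat[1], 0)
  expect_equal(qcStats(r)$p[1], 1)
  expect_equal(qcStats(r)$stat[2], 100)
  expect_equal(qcStats(r)$p[3], 1)
  expect_true(2L %in% excludedSites(r))
  expect_false(3L %in% excludedSites(r))
})

test_that("BH adjustment agrees with the brute-force step-up oracle", {
  set.seed(20)
  for (k in 1:5) {
    p <- runif(sample(5:1000, 1))^2
    expect_lt(max(abs(p.adjust(p, "BH") - bhStepUp(p))), 1e-12)
  }
})

test_that("minp null CDF is exact and matches Monte-Carlo minima", {
  expect_equal(minpNullCdf(0.3, 1), 0.3)
  expect_equal(minpNullCdf(0.5, 2), 0.75)
  expect_error(minpNullCdf(1.2, 3), "y must")
  set.seed(5)
  for (m in c(2, 6, 26)) {
    mins <- matrixStats <- apply(matrix(runif(100000 * 1), ncol = 1), 1, min)
    mins <- vapply(seq_len(20000), function(i) min(runif(m)), 0)
    for (y in c(0.01, 0.05, 0.2)) {
      phat <- mean(mins <= y)
      p0 <- minpNullCdf(y, m)
      se <- sqrt(p0 * (1 - p0) / length(mins))
      expect_lt(abs(phat - p0), 3.5 * se)
    }
  }
})

test_that("Eq-3 quantiles plugged into the minimum CDF recover i/n", {
  n <- 57; m <- 26
  i <- seq_len(n)
  q <- 1 - (1 - i / n)^(1 / m)
  expect_lt(max(abs(minpNullCdf(q, m) - i / n)), 1e-12)
})

test_that("batch-artifact scan: null behavior and power on a shifted wave", {
  set.seed(77)
  ## null: no wave effect
  fracs <- replicate(8, {
    p <- runif(300, 0.1, 0.9)
    G <- matrix(rbinom(200 * 300, 2, rep(p, each = 200)), 200, 300)
    co <- cohortFromMatrix(G, waves = 6L)
    r <- batchArtifactScan(co, 0.1)
    length(excludedSites(r)) / 300
  })
  expect_lte(mean(fracs), 0.05)
  ## a strong wave-specific frequency shift is caught
  hits <- replicate(10, {
    p <- runif(100, 0.2, 0.8)
    G <- matrix(rbinom(600 * 100, 2, rep(p, each = 600)), 600, 100)
    co <- cohortFromMatrix(G, waves = 6L)
    w1 <- sampleInfo(co)$wave == "w1"
    G2 <- genotypes(co)
    G2[w1, 1] <- rbinom(sum(w1), 2, min(p[1] + 0.3, 1))
    co@genotypes <- G2
    r <- batchArtifactScan(co, 0.1)
    1L %in% excludedSites(r)
  })
  expect_gte(mean(hits), 0.95)
  ## p = 0 maps to adjusted 0
  expect_equal(0 * minpNullCdf(0, 6), 0)
  expect_error(batchArtifactScan(cohortFromMatrix(matrix(1L, 10, 5),
                                                  waves = 1L)), "2 waves")
})

test_that("site-order permutation permutes per-site QC results identically", {
  set.seed(42)
  G <- matrix(rbinom(600, 2, 0.4), 60, 10)
  G[sample(length(G), 30)] <- NA_integer_
  co <- cohortFromMatrix(G, waves = 2L)
  perm <- sample(10)
  coP <- cohortFromMatrix(G[, perm], waves = 2L)
  coP@siteIndices <- as.integer(perm)      # keep panel identity per column
  coP@samples <- sampleInfo(co)            # same samples/waves/case flags
  r1 <- qcStats(differentialMissingnessTest(co, 0.2))
  r2 <- qcStats(differentialMissingnessTest(coP, 0.2))
  expect_equal(r2$p, r1$p[perm])
  h1 <- qcStats(hweTest(co))
  h2 <- qcStats(hweTest(coP))
  expect_equal(h2$stat, h1$stat[perm])
})

test_that("MAF censoring uses a strict lower bound", {
  G <- cbind(rep(0L, 1000),                       # monomorphic, MAF 0
             c(rep(1L, 2), rep(0L, 998)),         # MAF 0.001 exactly
             rbinom(1000, 2, 0.3))                # common
  co <- cohortFromMatrix(G)
  r <- mafCensor(co, 0.001)
  expect_true(1L %in% excludedSites(r))
  expect_false(2L %in% excludedSites(r))
  expect_false(3L %in% excludedSites(r))
})

test_that("PCA separates populations, is orthogonal, and duplicates map together", {
  panel <- simulatePanel(populationModel(2L, c(0.1, 0.1)), 300, 400,
                         mapLengthCm = 60, nGenerations = 10L, seed = 11,
                         popWeights = c(0.5, 0.5), nFounders = 40L)
  d <- makeArrayDesigns(panel, 250, 250, 250, seed = 2)
  co <- genotypeCohort(panel, d[[1]], 150, c(pop1 = 0.5, pop2 = 0.5),
                       perWaveMissingRate = 0.01, seed = 5)
  pca <- genoPCA(genotypes(co), 4L)
  lab <- sampleInfo(co)$pop
  sgn <- sign(pca$scores[, 1])
  acc <- max(mean((sgn > 0) == (lab == "pop1")),
             mean((sgn > 0) == (lab == "pop2")))
  expect_gte(acc, 0.95)
  expect_lt(max(abs(crossprod(pca$loadings) - diag(4))), 1e-8)
  Gdup <- rbind(genotypes(co), genotypes(co)[1, , drop = FALSE])
  pd <- genoPCA(Gdup, 3L)
  expect_equal(pd$scores[151, ], pd$scores[1, ], tolerance = 1e-8)
})

test_that("heterozygosity outlier detection flags injected contamination", {
  set.seed(8)
  G <- matrix(rbinom(200 * 400, 2, 0.4), 200, 400)
  co <- cohortFromMatrix(G)
  pcs <- matrix(rnorm(200 * 4, 0, 1e-3), 200, 4)
  ## near-zero PCs: adjusted het is essentially the centered observed het
  r0 <- ancestryAdjustedHeterozygosity(co, pcs)
  het <- rowMeans(G == 1)
  expect_lt(max(abs(qcStats(r0)$adjHet - (het - mean(het)))), 0.02)
  ## inject a sample with wildly inflated heterozygosity
  G2 <- G
  G2[7, ] <- 1L
  co2 <- cohortFromMatrix(G2)
  r <- ancestryAdjustedHeterozygosity(co2, pcs)
  expect_true("s7" %in% excludedSamples(r))
  expect_false("s8" %in% excludedSamples(r))
  ## perfectly PC-explained heterozygosity leaves nothing flagged
  expect_error(ancestryAdjustedHeterozygosity(
    co, cbind(pcs[, 1], pcs[, 1], pcs[, 3:4])), "collinear")
})

test_that("Mahalanobis subset excludes exactly past the chi-square boundary", {
  set.seed(3)
  n <- 400
  S <- matrix(rnorm(n * 10), n, 10)
  rownames(S) <- paste0("s", seq_len(n))
  cut <- qchisq(1 - 5.73e-7, df = 10)
  ## place one sample just inside and one just outside the boundary
  mu <- colMeans(S[1:n, ]); V <- cov(S)
  dirv <- rep(1, 10) / sqrt(10)
  ev <- eigen(V)
  mk <- function(d2) mu + sqrt(d2) * ev$vectors %*% (sqrt(ev$values) * dirv)
  S[1, ] <- mk(cut * 0.8); S[2, ] <- mk(cut * 1.3)
  keep <- homogeneousSubset(S, rownames(S)[3:n], 5.73e-7)
  expect_true("s1" %in% keep)
  expect_false("s2" %in% keep)
  ## standard-normal anchors: essentially nothing excluded at 5.73e-7
  S2 <- matrix(rnorm(10000 * 10), 10000, 10)
  rownames(S2) <- paste0("x", 1:10000)
  expect_gte(length(homogeneousSubset(S2, rownames(S2))), 9995)
  expect_error(homogeneousSubset(S[, 1:10] %*% matrix(0, 10, 10) + S[, c(1, 1, 1:8)] * 0,
                                 rownames(S)), "singular|anchor")
})

test_that("kinship proxy recovers duplicate, parent-offspring, and unrelated levels", {
  set.seed(14)
  p <- runif(800, 0.1, 0.9)
  hap <- function() rbinom(800, 1, p)
  f1 <- hap(); f2 <- hap(); m1 <- hap(); m2 <- hap()
  child <- f1 + m1
  ## 40 unrelated background samples stabilize the frequency estimates
  bg <- t(replicate(40, hap() + hap()))
  G <- rbind(f1 + f2, m1 + m2, child, bg[1, ], f1 + f2, bg[-1, ])
  K <- kinshipProxy(G)
  expect_gt(K[1, 5], 0.45)                       # duplicate pair
  expect_lt(abs(K[1, 3] - 0.25), 3 * 0.25 / sqrt(800) + 0.05)  # parent-child
  expect_lt(abs(K[1, 4]), 3 / sqrt(800) + 0.05)  # unrelated
  co <- cohortFromMatrix(G, case = c(TRUE, rep(FALSE, nrow(G) - 1)))
  r <- duplicateRelatednessFilter(co, 0.0825, 0.45)
  st <- qcStats(r)
  dup <- st[st$type == "duplicate", ]
  expect_true(nrow(dup) >= 1)
  ## the case member of the duplicate pair is kept
  expect_true("s5" %in% excludedSamples(r))
  expect_false("s1" %in% excludedSamples(r))
  ## parent-offspring pair flagged for GWAS exclusion
  expect_true(any(st$type == "related" &
                  ((st$id1 == "s1" & st$id2 == "s3") |
                   (st$id1 == "s3" & st$id2 == "s1"))))
})

test_that("sample missingness uses a strict bound and pruneRelated clears all pairs", {
  G <- matrix(1L, 3, 100)
  G[2, 1:6] <- NA_integer_      # 6%
  G[3, 1:5] <- NA_integer_      # exactly 5%
  co <- cohortFromMatrix(G)
  r <- sampleMissingnessFilter(co, 0.05)
  expect_identical(excludedSamples(r), "s2")
  pairs <- data.frame(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"))
  drop <- pruneRelated(pairs)
  expect_true(length(drop) <= 2)
  left <- pairs[!(pairs$id1 %in% drop | pairs$id2 %in% drop), ]
  expect_identical(nrow(left), 0L)
})

test_that("snp QC chain is idempotent on its survivors", {
  set.seed(50)
  panel <- tinyPanel()
  d <- makeArrayDesigns(panel, 120, 120, 60, seed = 2)
  co <- genotypeCohort(panel, d[[1]], 120, c(pop1 = 1), waves = 3L,
                       perWaveMissingRate = c(0.002, 0.01, 0.06),
                       errorRate = 1e-3, seed = 4)
  res <- snpQCPipeline(co)
  res2 <- snpQCPipeline(res$cohort)
  expect_identical(siteIndices(res2$cohort), siteIndices(res$cohort))
})
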