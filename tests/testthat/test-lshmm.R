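test_that("forward-backward equals path-pair enumeration on random tiny instances", {
  set.seed(91)
  worst <- 0
  for (rep in 1:50) {
    S <- sample(2:6, 1)
    K <- sample(2:4, 1)
    if (K^S > 5000) K <- 2L
    H <- matrix(rbinom(S * K, 1, 0.5), S, K)
    g <- sample(c(0L, 1L, 2L, NA), S, replace = TRUE)
    theta <- runif(S - 1, 0.01, 0.8)
    err <- runif(1, 0.001, 0.2)
    fb <- diploidPosterior(g, H, theta, err)$posterior
    bf <- bruteForcePosterior(g, H, theta, err)
    worst <- max(worst, max(abs(fb - bf)))
  }
  expect_lt(worst, 1e-10)
})

test_that("genotype posteriors normalize and match single-site closed form", {
  H <- matrix(c(1L, 0L, 1L), 1, 3)
  err <- 0.05
  post <- diploidPosterior(1L, H, numeric(0), err)$posterior
  expect_equal(sum(post), 1, tolerance = 1e-12)
  ## single site: emission-weighted mixture over state pairs
  m <- ifelse(H[1, ] == 1, 1 - err, err)
  E <- outer(m, 1 - m) + outer(1 - m, m)
  W <- E / sum(E)
  expect_equal(post[1, 1], sum(W * outer(1 - m, 1 - m)), tolerance = 1e-12)
  expect_equal(post[3, 1], sum(W * outer(m, m)), tolerance = 1e-12)
  ## multi-site normalization within 1e-12
  set.seed(2)
  H2 <- matrix(rbinom(12, 1, 0.5), 4, 3)
  p2 <- diploidPosterior(c(0L, NA, 2L, 1L), H2, rep(0.2, 3), 0.01)$posterior
  expect_lt(max(abs(colSums(p2) - 1)), 1e-12)
})

test_that("phasing is deterministic, genotype-consistent, and exact with a truth reference", {
  set.seed(5)
  ## construct a sample whose two haplotypes sit in the reference
  S <- 60
  h1 <- rbinom(S, 1, 0.5); h2 <- rbinom(S, 1, 0.5)
  noise <- matrix(rbinom(S * 6, 1, 0.5), 6, S)
  panel <- panelFromMatrix(rbind(h1, h2, noise), cm = seq(0, 0.5, length.out = S))
  co <- cohortFromMatrix(rbind(h1 + h2, h1 + h2))
  co@sites$cm <- seq(0, 0.5, length.out = S)
  par <- hmmParams(nStates = 8, ne = 5, errorRate = 1e-6, nIterations = 2,
                   seed = 3)
  ph <- phase(co, panel, par)
  h <- haplotypes(ph)
  expect_true(all(h$hap1 + h$hap2 == genotypes(co)))
  het <- which(h1 + h2 == 1)
  ## phase matches truth at all het sites, up to one global label swap
  z <- h$hap1[1, het] == h1[het]
  expect_true(all(z) || all(!z))
  ## identical seeds give identical output
  ph2 <- phase(co, panel, par)
  expect_identical(haplotypes(ph2), h)

  ## <= 1 het site: determined up to label swap, certainty 1
  g1 <- c(0L, 2L, 1L, 0L)
  co1 <- cohortFromMatrix(rbind(g1, g1))
  ph1 <- phase(co1, panelFromMatrix(matrix(rbinom(16, 1, 0.5), 4, 4)),
               hmmParams(nStates = 4, seed = 1))
  expect_true(all(haplotypes(ph1)$hap1 + haplotypes(ph1)$hap2 ==
                  genotypes(co1)))
  expect_error(phase(cohortFromMatrix(matrix(1L, 1, 4)), NULL,
                     hmmParams(seed = 1)), "condition")
})

test_that("imputation degenerate cases and hand-checked dr2", {
  ## every reference haplotype carries alt at the target -> DS = 2
  H <- cbind(rep(1L, 6), matrix(rbinom(18, 1, 0.5), 6, 3))
  panel <- panelFromMatrix(H)
  co <- cohortFromMatrix(matrix(c(1L, 0L, 2L,
                                  0L, 1L, 2L), 2, 3, byrow = TRUE),
                         siteIdx = 2:4)
  ph <- phase(co, panel, hmmParams(nStates = 4, errorRate = 1e-6, seed = 2))
  dm <- impute(ph, panel, targetSites = 1L,
               hmmParams(nStates = 4, errorRate = 1e-6))
  expect_true(all(abs(dosages(dm) - 2) < 1e-4))
  expect_error(impute(ph, panel, targetSites = 99L), "absent")
  ## typed observed sites pass through as genotypes
  dm2 <- impute(ph, panel, targetSites = c(2L, 3L),
                hmmParams(nStates = 4, errorRate = 1e-6))
  expect_equal(dosages(dm2), matrix(as.numeric(genotypes(co)[, 1:2]), 2, 2),
               tolerance = 1e-12)
  ## dr2 arithmetic oracle
  ds <- c(0, 1, 2, 1)
  expect_equal(dr2Quality(ds), min(1, var(ds) * 3 / 4 / 0.5))
  expect_equal(dr2Quality(rep(1.3, 5)), 0)
  expect_error(dr2Quality(1), ">= 2")
})

test_that("no-recombination copy of a reference haplotype imputes its alleles", {
  set.seed(9)
  S <- 30
  ref <- matrix(rbinom(S * 6, 1, 0.5), 6, S)
  panel <- panelFromMatrix(ref, cm = rep(0, S))   # zero map: no switching
  typed <- seq(2, S, by = 2)
  hap <- ref[3, ]
  co <- cohortFromMatrix(matrix(hap[typed] * 2L, 1, length(typed)),
                         siteIdx = typed, cm = rep(0, length(typed)))
  ph <- phasedFromMatrices(matrix(hap[typed], 1), matrix(hap[typed], 1),
                           siteIdx = typed)
  dm <- impute(ph, panel, targetSites = seq_len(S),
               hmmParams(nStates = 5, errorRate = 1e-6))
  expect_lt(max(abs(dosages(dm) / 2 - matrix(hap, 1, S))), 1e-3)
})

test_that("imputation accuracy degrades as the copy error rate rises", {
  set.seed(44)
  means <- sapply(1:10, function(k) {
    panel <- tinyPanel(nSites = 120, nHaps = 160, seed = 400 + k)
    d <- makeArrayDesigns(panel, 70, 70, 70, seed = k)
    co <- genotypeCohort(panel, d[[1]], 30, c(pop1 = 1), seed = k,
                         usedRows = 1:60, perWaveMissingRate = 0)
    ref <- subsetHaplotypes(panel, 1:60)
    msk <- setdiff(seq_len(120), siteIndices(co))[1:20]
    meta <- sampleInfo(co)
    H <- haplotypes(panel)
    tru <- H[meta$hapRow1, msk] + H[meta$hapRow2, msk]
    vapply(c(1e-3, 0.1), function(er) {
      ph <- phase(co, ref, hmmParams(20, errorRate = er, seed = 7))
      dm <- impute(ph, ref, msk, hmmParams(20, errorRate = er))
      cor(as.numeric(tru), as.numeric(dosages(dm)))^2
    }, numeric(1))
  })
  expect_gte(mean(means[1, ]), mean(means[2, ]))
})

test_that("consensus voting follows the majority at each inter-het interval", {
  g <- c(1L, 0L, 1L, 2L, 1L)
  mk <- function(o1, o2, o3) {
    h1 <- c(o1, 0L, o2, 1L, o3)
    phasedFromMatrices(matrix(h1, 1), matrix(g - h1, 1))
  }
  ## three estimates, two agree everywhere
  eA <- mk(1L, 1L, 1L)   # no switches
  eB <- mk(1L, 1L, 1L)
  eC <- mk(1L, 0L, 1L)   # switch between het1-het2 and het2-het3
  cons <- consensusHaplotypes(list(eA, eB, eC))
  expect_identical(cons@hap1[1, ], eA@hap1[1, ])
  ## all identical -> identical
  consSame <- consensusHaplotypes(list(eA, eA, eA))
  expect_identical(consSame@hap1, eA@hap1)
  ## engineered 4-vs-2 split at the middle interval
  six <- list(mk(1L, 1L, 1L), mk(1L, 1L, 1L), mk(1L, 1L, 1L),
              mk(1L, 1L, 1L), mk(1L, 0L, 1L), mk(1L, 0L, 1L))
  cons6 <- consensusHaplotypes(six)
  expect_identical(cons6@hap1[1, ], eA@hap1[1, ])
  ## genotype disagreement is an error
  bad <- phasedFromMatrices(matrix(c(1L, 1L, 1L, 1L, 1L), 1),
                            matrix(c(0L, 0L, 0L, 1L, 0L), 1))
  expect_error(consensusHaplotypes(list(eA, eB, bad)), "genotypes")
  expect_error(consensusHaplotypes(list(eA, eB)), ">= 3")
})

test_that("label symmetry: swapping every sample's haplotypes leaves dosages unchanged", {
  set.seed(17)
  panel <- tinyPanel(nSites = 80, nHaps = 100)
  typed <- seq(2, 80, by = 2)
  h1 <- haplotypes(panel)[71, typed]; h2 <- haplotypes(panel)[72, typed]
  phA <- phasedFromMatrices(matrix(h1, 1), matrix(h2, 1), siteIdx = typed)
  phB <- phasedFromMatrices(matrix(h2, 1), matrix(h1, 1), siteIdx = typed)
  ref <- subsetHaplotypes(panel, 1:60)
  msk <- seq(1, 79, by = 2)
  dA <- impute(phA, ref, msk, hmmParams(20))
  dB <- impute(phB, ref, msk, hmmParams(20))
  expect_equal(dosages(dA), dosages(dB), tolerance = 1e-12)
})
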