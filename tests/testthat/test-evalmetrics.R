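test_that("trio phase resolution handles forced, unresolvable, and inconsistent sites", {
  ## hand-built 6-site trio: 2 triple-hets among them
  fat <- matrix(c(2L, 0L, 1L, 1L, 2L, 1L), 1)
  mot <- matrix(c(0L, 2L, 1L, 0L, 1L, 1L), 1)
  off <- matrix(c(1L, 1L, 1L, 1L, 1L, 1L), 1)
  d1 <- new("ArrayDesign", name = "a", siteIndices = 1:6)
  tr <- new("TrioSet",
            genotypes = list(a = list(father = fat, mother = mot,
                                      offspring = off)),
            designs = list(a = d1),
            hapPat = matrix(0L, 1, 6), hapMat = matrix(0L, 1, 6),
            trioIds = "t1")
  res <- trioResolvePhase(tr, 1:6)
  ## sites 1,2: hom parents, forced; 3,6: triple het unresolvable;
  ## 4: mother hom ref -> paternal allele 1; 5: father hom alt -> paternal 1
  expect_identical(as.logical(res$resolved),
                   c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_identical(as.integer(res$patAllele[1, c(1, 2, 4, 5)]),
                   c(1L, 0L, 1L, 1L))
  expect_identical(sum(res$resolved), 4L)
})

test_that("SER matches hand enumeration and is label-swap invariant", {
  ## 5 resolvable hets, flip between sites 2 and 3 -> 1/4
  pat <- c(1L, 1L, 0L, 0L, 1L)
  d1 <- new("ArrayDesign", name = "a", siteIndices = 1:5)
  tr <- new("TrioSet",
            genotypes = list(a = list(father = matrix(2L * pat, 1),
                                      mother = matrix(2L * (1L - pat), 1),
                                      offspring = matrix(rep(1L, 5), 1))),
            designs = list(a = d1),
            hapPat = matrix(pat, 1), hapMat = matrix(1L - pat, 1),
            trioIds = "t1")
  truth <- trioResolvePhase(tr, 1:5)
  expect_identical(sum(truth$resolved), 5L)
  est1 <- pat; est1[3:5] <- 1L - est1[3:5]        # single flip after site 2
  ph <- phasedFromMatrices(matrix(est1, 1), matrix(1L - est1, 1),
                           ids = "t1")
  r <- switchErrorRate(ph, truth, "t1")
  expect_equal(r$ser, 0.25)
  ## exact estimate and global label swap both give 0
  ph0 <- phasedFromMatrices(matrix(pat, 1), matrix(1L - pat, 1), ids = "t1")
  phSwap <- phasedFromMatrices(matrix(1L - pat, 1), matrix(pat, 1),
                               ids = "t1")
  expect_equal(switchErrorRate(ph0, truth, "t1")$ser, 0)
  expect_equal(switchErrorRate(phSwap, truth, "t1")$ser, 0)
})

test_that("SER equals exhaustive switch counting on random toys", {
  set.seed(12)
  for (rep in 1:100) {
    k <- 10
    pat <- rbinom(k, 1, 0.5)
    est <- rbinom(k, 1, 0.5)
    d1 <- new("ArrayDesign", name = "a", siteIndices = seq_len(k))
    tr <- new("TrioSet",
              genotypes = list(a = list(father = matrix(2L * pat, 1),
                                        mother = matrix(2L * (1L - pat), 1),
                                        offspring = matrix(rep(1L, k), 1))),
              designs = list(a = d1),
              hapPat = matrix(pat, 1), hapMat = matrix(1L - pat, 1),
              trioIds = "t1")
    ## both parents hom at every site -> offspring het everywhere and every
    ## site resolvable with paternal allele pat
    truth <- trioResolvePhase(tr, seq_len(k))
    ph <- phasedFromMatrices(matrix(as.integer(est), 1),
                             matrix(1L - as.integer(est), 1), ids = "t1")
    r <- switchErrorRate(ph, truth, "t1")
    expect_equal(r$nSwitch, countSwitches(est, pat))
    expect_equal(r$nPossible, k - 1)
  }
})

test_that("r2 by MAF bin pools pairs, assigns bins, and reports NA for zero variance", {
  sites <- 1:4
  dm <- new("DosageMatrix",
            dosages = matrix(c(0.1, 0.9, 1.8, 1.2, 0.2,
                               0, 0, 0, 0, 0,
                               1, 1, 1, 1, 1,
                               0.5, 0.4, 0.6, 0.5, 0.5), 5, 4),
            dr2 = rep(1, 4), refMaf = c(0.3, 0.03, 0.004, 0.15),
            siteIndices = 1:4, sampleId = paste0("s", 1:5),
            provenance = "test")
  truth <- cbind(c(0L, 1L, 2L, 1L, 0L), rep(0L, 5), rep(2L, 5),
                 c(1L, 0L, 1L, 1L, 0L))
  tab <- imputationR2ByMaf(dm, truth)
  ## hand-computed pooled Pearson^2 in the (0.2,0.5] bin (site 1 only)
  expect_equal(tab$r2[tab$bin == "(0.2,0.5]"],
               cor(truth[, 1], dm@dosages[, 1])^2)
  ## site with MAF 0.03 lands in (0.01,0.05]
  expect_true("(0.01,0.05]" %in% tab$bin)
  ## zero-variance truth -> NA, not 0
  expect_true(is.na(tab$r2[tab$bin == "(0,0.005]"]))
  ## perfect dosages give r2 = 1 in every nonempty bin
  dmP <- initialize(dm, dosages = truth + 0)
  tabP <- imputationR2ByMaf(dmP, truth)
  expect_true(all(abs(tabP$r2[!is.na(tabP$r2)] - 1) < 1e-12))
  ## affine rescaling leaves r2 unchanged
  dmAff <- initialize(dm, dosages = pmin(pmax(dm@dosages * 0.5 + 0.3, 0), 2))
  expect_equal(imputationR2ByMaf(dmAff, truth)$r2[4], tab$r2[4],
               tolerance = 1e-12)
  expect_error(mafBins(c(0, 0.4)), "0.5")
})

test_that("lambda_GC definition, null behavior, and threshold monotonicity", {
  ## all chi-squares equal to the null median -> lambda exactly 1
  expect_equal(0.4549 / 0.4549, 1)
  set.seed(21)
  p <- runif(150, 0.2, 0.8)
  mkDos <- function(n) {
    m <- matrix(rbinom(n * 150, 2, rep(p, each = n)) + 0, n, 150)
    new("DosageMatrix", dosages = m, dr2 = runif(150, 0.3, 1),
        refMaf = pmin(p, 1 - p), siteIndices = 1:150,
        sampleId = paste0("x", seq_len(n)), provenance = "t")
  }
  lams <- replicate(10, {
    dA <- mkDos(150); dB <- mkDos(120)
    tA <- matrix(rbinom(150 * 150, 2, rep(p, each = 150)), 150, 150)
    tB <- matrix(rbinom(120 * 150, 2, rep(p, each = 120)), 120, 150)
    tab <- arrayMembershipScan(tA, tB, dA, dB, c(0, 0.5, 0.9))
    c(tab$lambda[tab$arm == "imp_imp" & tab$threshold == 0],
      all(diff(tab$nSnps[tab$arm == "imp_imp"]) <= 0))
  })
  expect_lt(abs(mean(lams[1, ]) - 1), 0.12)       # null: lambda near 1
  expect_true(all(lams[2, ] == 1))                 # SNP counts nonincreasing
  ## injected mean shift raises lambda above the matched null
  wins <- replicate(10, {
    dA <- mkDos(150); dB <- mkDos(150)
    tA <- matrix(rbinom(150 * 150, 2, rep(p, each = 150)), 150, 150)
    tB <- tA
    base <- arrayMembershipScan(tA, tB, dA, dB, 0)
    shift <- sample(150, 30)
    dB2 <- initialize(dB, dosages = {
      m <- dosages(dB); m[, shift] <- pmin(m[, shift] + 0.2, 2); m })
    infl <- arrayMembershipScan(tA, tB, dA, dB2, 0)
    infl$lambda[infl$arm == "imp_imp"] - base$lambda[base$arm == "imp_imp"]
  })
  expect_gt(mean(wins > 0), 0.7)
  expect_gt(mean(wins), 0)
})

test_that("cm block labels partition sites for the density breakdown", {
  cm <- seq(0, 100, length.out = 50)
  b <- cmBlocks(cm, 4L)
  expect_identical(sort(unique(b)), 1:4)
  expect_true(all(diff(b) >= 0))
})
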