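test_that("panel generator respects invariants and degenerate limits", {
  panel <- tinyPanel()
  st <- siteInfo(panel)
  expect_true(all(diff(st$pos) > 0))
  expect_true(all(diff(st$cm) >= 0))
  expect_true(all(haplotypes(panel) %in% c(0L, 1L)))
  expect_identical(nHaplotypes(panel) %% 2L, 0L)

  ## no generations -> founders returned unchanged in distribution terms
  p0 <- simulatePanel(populationModel(1L, 0), 50, 20, nGenerations = 0L,
                      seed = 4)
  expect_true(all(p0@founder))

  ## no recombination, no mutation -> every haplotype equals one founder
  set.seed(7)
  pm <- populationModel(1L, 0)
  pNoRec <- simulatePanel(pm, 40, 30, mapLengthCm = 0, mutationRate = 0,
                          nGenerations = 5L, seed = 8, nFounders = 6L)
  founders <- simulatePanel(pm, 40, 6, mapLengthCm = 0, mutationRate = 0,
                            nGenerations = 0L, seed = 8, nFounders = 6L)
  fset <- apply(haplotypes(founders), 1L, paste, collapse = "")
  hset <- apply(haplotypes(pNoRec), 1L, paste, collapse = "")
  expect_true(all(hset %in% fset))

  ## determinism
  p1 <- tinyPanel(seed = 99)
  p2 <- tinyPanel(seed = 99)
  expect_identical(haplotypes(p1), haplotypes(p2))
})

test_that("fst = 0 gives no systematic frequency difference; divergence is monotone in fst", {
  diffs <- replicate(12, {
    p <- simulatePanel(populationModel(2L, c(0, 0)), 400, 200,
                       nGenerations = 0L, seed = sample.int(1e6, 1))
    f1 <- colMeans(haplotypes(p)[popLabels(p) == "pop1", ])
    f2 <- colMeans(haplotypes(p)[popLabels(p) == "pop2", ])
    mean(f1 - f2)
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-12)

  msd <- vapply(c(0, 0.01, 0.1), function(f) {
    m <- replicate(6, {
      p <- simulatePanel(populationModel(2L, c(f, f)), 300, 200,
                         nGenerations = 0L, seed = sample.int(1e6, 1))
      f1 <- colMeans(haplotypes(p)[popLabels(p) == "pop1", ])
      f2 <- colMeans(haplotypes(p)[popLabels(p) == "pop2", ])
      mean((f1 - f2)^2)
    })
    mean(m)
  }, 0)
  expect_true(all(diff(msd) >= 0))
})

test_that("copying process induces distance-decaying LD", {
  set.seed(31)
  wins <- replicate(20, {
    p <- simulatePanel(populationModel(1L, 0), 100, 120, mapLengthCm = 1,
                       mutationRate = 1e-4, nGenerations = 8L,
                       seed = sample.int(1e6, 1), nFounders = 80L)
    H <- haplotypes(p)
    v <- apply(H, 2L, var)
    poly <- which(v > 0)
    r2 <- function(j, k) cor(H[, j], H[, k])^2
    r2adj <- mean(vapply(intersect(poly, poly - 1L), function(j)
      r2(j, j + 1L), 0), na.rm = TRUE)
    farPairs <- poly[poly > 50 & (poly - 50L) %in% poly]
    r2far <- mean(vapply(farPairs, function(j) r2(j, j - 50L), 0),
                  na.rm = TRUE)
    c(r2adj, r2far)
  })
  ## averaged over the 20 seeds, adjacent-pair LD exceeds distant-pair LD
  expect_gt(mean(wins[1, ]), mean(wins[2, ]))
  expect_gte(mean(wins[1, ] > wins[2, ]), 0.6)
})

test_that("array designs have exact sizes, overlap, and bounds", {
  panel <- tinyPanel()
  d <- makeArrayDesigns(panel, 90, 120, 40, seed = 5)
  expect_identical(nSites(d[[1]]), 90L)
  expect_identical(nSites(d[[2]]), 120L)
  expect_identical(length(intersect(siteIndices(d[[1]]),
                                    siteIndices(d[[2]]))), 40L)
  expect_identical(length(union(siteIndices(d[[1]]), siteIndices(d[[2]]))),
                   90L + 120L - 40L)
  ## identical and disjoint corner cases
  dAll <- makeArrayDesigns(panel, 200, 200, 200, seed = 1)
  expect_identical(siteIndices(dAll[[1]]), siteIndices(dAll[[2]]))
  dDis <- makeArrayDesigns(panel, 60, 80, 0, seed = 1)
  expect_length(intersect(siteIndices(dDis[[1]]), siteIndices(dDis[[2]])), 0)
  expect_error(makeArrayDesigns(panel, 150, 150, 10, seed = 1),
               "do not fit")
  expect_error(makeArrayDesigns(panel, 20, 30, 25, seed = 1), "overlap")
})

test_that("genotyping preserves haplotype sums and injects wave missingness", {
  panel <- tinyPanel()
  d <- makeArrayDesigns(panel, 90, 120, 40, seed = 5)
  co <- genotypeCohort(panel, d[[1]], 40, c(pop1 = 1), waves = 2L,
                       perWaveMissingRate = c(0, 0.08), errorRate = 0,
                       seed = 3)
  meta <- sampleInfo(co)
  H <- haplotypes(panel)
  truth <- H[meta$hapRow1, siteIndices(co)] + H[meta$hapRow2, siteIndices(co)]
  obs <- genotypes(co)
  expect_true(all(obs[!is.na(obs)] == truth[!is.na(obs)]))
  ## allele counts preserved exactly when no error/missingness
  co0 <- genotypeCohort(panel, d[[1]], 40, c(pop1 = 1), waves = 1L,
                        perWaveMissingRate = 0, errorRate = 0, seed = 3)
  m0 <- sampleInfo(co0)
  t0 <- H[m0$hapRow1, siteIndices(co0)] + H[m0$hapRow2, siteIndices(co0)]
  expect_identical(colSums(genotypes(co0)), colSums(t0))
  ## binomial check on the lossy wave
  w2 <- meta$wave == paste0(d[[1]]@name, "_w2")
  rate <- mean(is.na(obs[w2, ]))
  nCalls <- sum(w2) * ncol(obs)
  se <- sqrt(0.08 * 0.92 / nCalls)
  expect_lt(abs(rate - 0.08), 3 * se)
  ## admixed samples combine one gamete per population
  coAdm <- genotypeCohort(panel, d[[1]], 20,
                          c(pop1 = 0.5, `pop1+pop2` = 0.5), seed = 9)
  adm <- sampleInfo(coAdm)[sampleInfo(coAdm)$pop == "pop1+pop2", ]
  expect_true(all(popLabels(panel)[adm$hapRow1] == "pop1"))
  expect_true(all(popLabels(panel)[adm$hapRow2] == "pop2"))
})

test_that("trios are Mendelian-consistent recombinant gametes", {
  panel <- tinyPanel()
  d <- makeArrayDesigns(panel, 90, 120, 40, seed = 5)
  tr <- makeTrios(panel, 8, d, seed = 21)
  for (nm in names(tr@designs)) {
    g <- tr@genotypes[[nm]]
    minOff <- (g$father == 2) + (g$mother == 2)
    maxOff <- 2 - ((g$father == 0) + (g$mother == 0))
    expect_true(all(g$offspring >= minOff & g$offspring <= maxOff))
    ## forced transmission: father hom-alt x mother hom-ref -> het child
    forced <- g$father == 2 & g$mother == 0
    expect_true(all(g$offspring[forced] == 1))
  }
  ## offspring genotypes equal transmitted haplotype sums
  si <- siteIndices(tr@designs[[1]])
  expect_identical(tr@genotypes[[1]]$offspring,
                   tr@hapPat[, si] + tr@hapMat[, si])
  ## zero map length -> offspring haplotypes are exact parental copies
  tr0 <- makeTrios(panel, 5, d, mapLengthCm = 0, seed = 4)
  expect_identical(dim(tr0@hapPat), c(5L, nSites(panel)))
})

test_that("gamete crossover counts follow the map length in Morgans", {
  H <- rbind(rep(0L, 400), rep(1L, 400))
  cm <- seq(0, 200, length.out = 400)   # 2 Morgans
  set.seed(12)
  counts <- replicate(400, {
    g <- GenoPhase:::recombineGamete(H[1, ], H[2, ], cm)
    sum(g[-1] != g[-400])
  })
  ## observable switches are close to the Poisson(2) draw
  expect_lt(abs(mean(counts) - 2), 3 * sqrt(2 / 400) + 0.1)
})

test_that("phenotype heritability scaling behaves across h2", {
  panel <- tinyPanel(nSites = 300, nHaps = 600)
  d <- makeArrayDesigns(panel, 150, 150, 150, seed = 2)
  co <- genotypeCohort(panel, d[[1]], 200, c(pop1 = 1), seed = 6,
                       perWaveMissingRate = 0)
  causal <- sort(sample(nSites(panel), 60))
  ph1 <- simulatePhenotype(co, panel, causal, h2 = 1, seed = 3)
  expect_equal(cor(ph1@g, ph1@y), 1)
  ph0 <- simulatePhenotype(co, panel, causal, h2 = 0, seed = 3)
  expect_lt(abs(cor(ph0@g, ph0@y)), 3 / sqrt(length(ph0@y)))
  ratios <- vapply(1:8, function(k) {
    ph <- simulatePhenotype(co, panel, causal, h2 = 0.5, seed = 100 + k)
    var(ph@g) / var(ph@y)
  }, 0)
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.5), 3 * se + 0.01)
  expect_error(simulatePhenotype(co, panel, causal, h2 = 1.2), "h2")
})
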