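## Shared fixtures built in code. Everything is seeded; nothing is stored
## on disk.

## A small structured panel reused across test files.
tinyPanel <- function(nSites = 200, nHaps = 300, seed = 11,
                      fst = c(0.01, 0.1), nGenerations = 10L) {
  simulatePanel(populationModel(2L, fst), nSites, nHaps,
                mapLengthCm = 60, mutationRate = 1e-4,
                nGenerations = nGenerations, seed = seed,
                popWeights = c(0.8, 0.2), nFounders = 40L)
}

## Build a HaplotypePanel directly from an explicit haplotype matrix.
panelFromMatrix <- function(H, cm = NULL) {
  S <- ncol(H)
  sites <- data.frame(chrom = "1", pos = seq_len(S) * 10L,
                      cm = if (is.null(cm)) seq(0, 1, length.out = S) else cm,
                      ref = "A", alt = "G", id = paste0("snp", seq_len(S)),
                      stringsAsFactors = FALSE)
  storage.mode(H) <- "integer"
  new("HaplotypePanel", sites = sites, haplotypes = H,
      popLabel = rep("pop1", nrow(H)), founder = rep(TRUE, nrow(H)))
}

## Minimal CohortDataset around a genotype matrix.
cohortFromMatrix <- function(G, waves = 1L, case = NULL, pop = "pop1",
                             siteIdx = seq_len(ncol(G)), cm = NULL) {
  n <- nrow(G)
  storage.mode(G) <- "integer"
  sites <- data.frame(chrom = "1", pos = siteIdx * 10L,
                      cm = if (is.null(cm))
                        seq(0, 1, length.out = ncol(G)) else cm,
                      ref = "A", alt = "G",
                      id = paste0("snp", siteIdx), stringsAsFactors = FALSE)
  samples <- data.frame(
    id = paste0("s", seq_len(n)),
    wave = paste0("w", rep_len(seq_len(waves), n)),
    case = if (is.null(case)) rep_len(c(TRUE, FALSE), n) else case,
    pop = pop, age = 30, sex = "F",
    hapRow1 = NA_integer_, hapRow2 = NA_integer_,
    stringsAsFactors = FALSE)
  new("CohortDataset", genotypes = G, siteIndices = as.integer(siteIdx),
      sites = sites, samples = samples, provenance = "test")
}

## Brute-force Benjamini-Hochberg step-up, used as the oracle for p.adjust.
bhStepUp <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## Exhaustive switch counting oracle on explicit orientation vectors.
countSwitches <- function(estOrient, truthOrient) {
  z <- estOrient == truthOrient
  sum(z[-1] != z[-length(z)])
}

## PhasedHaplotypes wrapper for explicit haplotype matrices.
phasedFromMatrices <- function(h1, h2, siteIdx = seq_len(ncol(h1)),
                               ids = paste0("s", seq_len(nrow(h1)))) {
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  sites <- data.frame(chrom = "1", pos = siteIdx * 10L,
                      cm = seq(0, 1, length.out = ncol(h1)),
                      ref = "A", alt = "G", id = paste0("snp", siteIdx),
                      stringsAsFactors = FALSE)
  samples <- data.frame(id = ids, wave = "w1", case = FALSE, pop = "pop1",
                        age = 30, sex = "F", hapRow1 = NA_integer_,
                        hapRow2 = NA_integer_, stringsAsFactors = FALSE)
  new("PhasedHaplotypes", hap1 = h1, hap2 = h2,
      certainty = matrix(1, nrow(h1), ncol(h1)),
      imputed = matrix(FALSE, nrow(h1), ncol(h1)),
      siteIndices = as.integer(siteIdx), sites = sites, samples = samples,
      provenance = "test")
}
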