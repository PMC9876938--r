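## Synthetic-biobank generator: haplotype panel with LD and population
## structure, array manifests, genotyped cohorts with waves and missingness,
## parent-offspring trios, and a heritable quantitative trait.

#' Construct a population model
#'
#' Per-population allele frequencies follow a Balding-Nichols draw: for
#' ancestral frequency p and divergence F, the population frequency is
#' Beta(p(1-F)/F, (1-p)(1-F)/F). F = 0 means the population frequency equals
#' the ancestral frequency exactly.
#'
#' @param nPops number of populations.
#' @param fst per-population divergence in [0,1); recycled to nPops.
#' @param ancestralShape Beta(shape1, shape2) parameters of the ancestral
#'   allele-frequency law (rescaled to [0.05, 0.95] so founder sites are
#'   polymorphic).
#' @param admixture data.frame(popA, popB, label) of admixed groups, each
#'   individual formed from one gamete of popA and one of popB.
#' @return A [PopulationModel-class] object.
#' @export
populationModel <- function(nPops = 2L, fst = c(0.01, 0.1),
                            ancestralShape = c(1, 1),
                            admixture = data.frame(popA = "pop1",
                                                   popB = "pop2",
                                                   label = "adm_1_2")) {
  if (nPops < 2L && nrow(admixture))
    admixture <- admixture[0, , drop = FALSE]
  new("PopulationModel", nPops = as.integer(nPops),
      fst = rep_len(as.numeric(fst), nPops),
      ancestralShape = as.numeric(ancestralShape),
      admixture = admixture)
}

popNames <- function(model) paste0("pop", seq_len(model@nPops))

## One recombinant gamete from a pair of parental haplotypes.
## Crossover count ~ Poisson(map length in Morgans); breakpoints uniform on
## the cM map; starting strand chosen at random.
recombineGamete <- function(h1, h2, cm) {
  L <- max(cm) - min(cm)
  k <- rpois(1L, L / 100)
  strand <- rbinom(1L, 1L, 0.5)
  if (k == 0L) return(if (strand == 0L) h1 else h2)
  bp <- sort(runif(k, min(cm), max(cm)))
  seg <- findInterval(cm, bp)           # 0..k, strand alternates per segment
  use2 <- (seg + strand) %% 2L == 1L
  g <- h1
  g[use2] <- h2[use2]
  g
}

#' Simulate a haplotype reference/study panel
#'
#' Founder haplotypes are drawn site-wise Bernoulli from Balding-Nichols
#' per-population frequencies; linkage disequilibrium is then induced by a
#' generational copying process in which each new haplotype is a recombinant
#' mosaic of two haplotypes of the previous generation (within population),
#' with crossover counts proportional to map length and symmetric per-site
#' mutation.
#'
#' @param model a [PopulationModel-class].
#' @param nSites number of biallelic sites (>= 2).
#' @param nHaplotypes total haplotypes (even); split across populations per
#'   popWeights.
#' @param mapLengthCm genetic map length of the single simulated chromosome.
#' @param mutationRate per-site, per-copy flip probability.
#' @param nGenerations copying generations (0 returns the founders).
#' @param seed RNG seed.
#' @param popWeights haplotype share per population (recycled, normalized).
#' @param nFounders founder haplotypes per population; each population
#'   grows geometrically from this bottleneck to its target size over the
#'   generations, which concentrates ancestry and yields the deep segment
#'   sharing that haplotype-copying methods exploit.
#' @return A [HaplotypePanel-class].
#' @export
simulatePanel <- function(model, nSites, nHaplotypes, mapLengthCm = 100,
                          mutationRate = 1e-4, nGenerations = 8L, seed = 1L,
                          popWeights = NULL, nFounders = 32L) {
  stopifnot(nSites >= 2L)
  if (nHaplotypes %% 2L != 0L)
    stop("nHaplotypes must be even (haplotypes pair into diploids)")
  validObject(model)
  set.seed(seed)
  nPops <- model@nPops
  if (is.null(popWeights)) popWeights <- rep(1, nPops)
  popWeights <- rep_len(popWeights, nPops) / sum(rep_len(popWeights, nPops))
  hapPer <- diff(round(cumsum(c(0, popWeights)) * nHaplotypes))
  hapPer <- pmax(hapPer, 2L)
  hapPer[nPops] <- hapPer[nPops] + (nHaplotypes - sum(hapPer))

  pos <- sort(sample.int(nSites * 50L, nSites))
  cm <- seq(0, mapLengthCm, length.out = nSites)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, nSites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
  sites <- data.frame(chrom = "1", pos = pos, cm = cm, ref = ref, alt = alt,
                      id = paste0("snp", seq_len(nSites)),
                      stringsAsFactors = FALSE)

  pAnc <- rbeta(nSites, model@ancestralShape[1], model@ancestralShape[2]) *
    0.9 + 0.05
  popFreq <- matrix(0, nPops, nSites)
  for (p in seq_len(nPops)) {
    F <- model@fst[p]
    popFreq[p, ] <- if (F == 0) pAnc else
      rbeta(nSites, pAnc * (1 - F) / F, (1 - pAnc) * (1 - F) / F)
  }

  growPop <- function(freq, target) {
    n0 <- if (nGenerations > 0L) nFounders else target
    Hp <- matrix(rbinom(n0 * nSites, 1L, rep(freq, each = n0)), n0, nSites)
    if (nGenerations == 0L) return(list(H = Hp, founder = TRUE))
    ## constant-size ancestral population, with the final generation
    ## producing exactly the requested number of haplotypes; a larger
    ## nFounders lowers background relatedness at the cost of weaker
    ## haplotype sharing
    sizes <- c(rep(n0, nGenerations - 1L), target)
    for (gen in seq_len(nGenerations)) {
      Hn <- matrix(0L, sizes[gen], nSites)
      for (i in seq_len(sizes[gen])) {
        par <- sample(nrow(Hp), 2L, replace = TRUE)
        gmt <- recombineGamete(Hp[par[1], ], Hp[par[2], ], cm)
        if (mutationRate > 0) {
          nMut <- rbinom(1L, nSites, mutationRate)
          if (nMut > 0L) {
            flip <- sample.int(nSites, nMut)
            gmt[flip] <- 1L - gmt[flip]
          }
        }
        Hn[i, ] <- gmt
      }
      Hp <- Hn
    }
    list(H = Hp, founder = FALSE)
  }

  out <- lapply(seq_len(nPops), function(p) growPop(popFreq[p, ], hapPer[p]))
  H <- do.call(rbind, lapply(out, `[[`, "H"))
  popLabel <- rep(popNames(model), hapPer)
  founder <- rep(vapply(out, `[[`, TRUE, "founder"), hapPer)
  storage.mode(H) <- "integer"
  new("HaplotypePanel", sites = sites, haplotypes = H,
      popLabel = popLabel, founder = founder)
}

#' Create two array manifests with partial overlap
#'
#' Emulates two genotyping-array manifests sharing a subset of markers; the
#' default desk-scale sizes follow the ~251k/450k/117k marker-count ratios
#' of a two-array biobank.
#'
#' @param panel a [HaplotypePanel-class].
#' @param sizeA,sizeB manifest sizes.
#' @param overlapCount number of shared sites.
#' @param seed RNG seed.
#' @param names array names.
#' @return list of two [ArrayDesign-class] objects.
#' @export
makeArrayDesigns <- function(panel, sizeA, sizeB, overlapCount, seed = 1L,
                             names = c("arrayA", "arrayB")) {
  n <- nSites(panel)
  if (overlapCount > min(sizeA, sizeB))
    stop("overlapCount exceeds the smaller design size")
  if (sizeA + sizeB - overlapCount > n)
    stop("designs do not fit in the panel: sizeA + sizeB - overlap > nSites")
  set.seed(seed)
  pool <- sample.int(n, sizeA + sizeB - overlapCount)
  shared <- pool[seq_len(overlapCount)]
  onlyA <- pool[overlapCount + seq_len(sizeA - overlapCount)]
  onlyB <- pool[sizeA + seq_len(sizeB - overlapCount)]
  list(new("ArrayDesign", name = names[1],
           siteIndices = sort(as.integer(c(shared, onlyA)))),
       new("ArrayDesign", name = names[2],
           siteIndices = sort(as.integer(c(shared, onlyB)))))
}

## Allocate diploid haplotype-row pairs for a cohort. Pure-population
## individuals are consecutive row pairs within their population; admixed
## individuals pair one row from each parent population.
allocateHapRows <- function(panel, popMix, nSamples, usedRows = integer()) {
  props <- popMix / sum(popMix)
  counts <- diff(round(cumsum(c(0, props)) * nSamples))
  names(counts) <- names(popMix)
  lab <- popLabels(panel)
  avail <- function(p) setdiff(which(lab == p), usedRows)
  rows <- matrix(0L, nSamples, 2L)
  sampPop <- character(nSamples)
  i <- 0L
  for (k in seq_along(counts)) {
    nm <- names(counts)[k]
    if (counts[k] == 0L) next
    if (grepl("\\+", nm)) {
      parts <- strsplit(nm, "+", fixed = TRUE)[[1]]
      a <- avail(parts[1]); b <- avail(parts[2])
      if (length(a) < counts[k] || length(b) < counts[k])
        stop("not enough haplotypes for admixed group ", nm)
      ra <- a[seq_len(counts[k])]; rb <- b[seq_len(counts[k])]
      rows[i + seq_len(counts[k]), ] <- cbind(ra, rb)
      usedRows <- c(usedRows, ra, rb)
    } else {
      a <- avail(nm)
      a <- a[seq_len(2L * (length(a) %/% 2L))]
      if (length(a) < 2L * counts[k])
        stop("not enough haplotype pairs in population ", nm)
      pick <- a[seq_len(2L * counts[k])]
      rows[i + seq_len(counts[k]), ] <- matrix(pick, ncol = 2L, byrow = TRUE)
      usedRows <- c(usedRows, pick)
    }
    sampPop[i + seq_len(counts[k])] <- nm
    i <- i + counts[k]
  }
  list(rows = rows[seq_len(i), , drop = FALSE], pop = sampPop[seq_len(i)],
       used = usedRows)
}

#' Genotype a cohort on an array design
#'
#' Diploid genotypes are the allele sums of the two underlying panel
#' haplotypes; symmetric per-allele genotyping error and wave-specific
#' missingness are then applied.
#'
#' @param panel a [HaplotypePanel-class].
#' @param design an [ArrayDesign-class].
#' @param nSamples number of individuals.
#' @param popMix named proportions over population labels; names of the form
#'   "pop1+pop2" create admixed individuals (one gamete from each).
#' @param waves number of genotyping waves (samples split evenly).
#' @param perWaveMissingRate missingness probability per wave (recycled).
#' @param errorRate per-allele flip probability.
#' @param seed RNG seed.
#' @param usedRows panel haplotype rows already consumed elsewhere.
#' @param caseFraction fraction of samples flagged as cases.
#' @param idPrefix sample id prefix.
#' @return A [CohortDataset-class]; sampleInfo() records wave, pop, case,
#'   age, sex and the underlying panel rows (hapRow1/hapRow2).
#' @export
genotypeCohort <- function(panel, design, nSamples, popMix = c(pop1 = 1),
                           waves = 1L, perWaveMissingRate = 0.005,
                           errorRate = 0, seed = 1L,
                           usedRows = integer(), caseFraction = 0.5,
                           idPrefix = "s") {
  stopifnot(all(perWaveMissingRate >= 0), all(perWaveMissingRate <= 1),
            errorRate >= 0, errorRate <= 1)
  set.seed(seed)
  alloc <- allocateHapRows(panel, popMix, nSamples, usedRows)
  rows <- alloc$rows
  n <- nrow(rows)
  si <- siteIndices(design)
  H <- haplotypes(panel)
  A1 <- H[rows[, 1], si, drop = FALSE]
  A2 <- H[rows[, 2], si, drop = FALSE]
  if (errorRate > 0) {   # symmetric flip of each underlying allele call
    f1 <- matrix(runif(length(A1)) < errorRate, nrow(A1), ncol(A1))
    f2 <- matrix(runif(length(A2)) < errorRate, nrow(A2), ncol(A2))
    A1 <- abs(A1 - f1); A2 <- abs(A2 - f2)
  }
  G <- A1 + A2
  waveId <- rep(seq_len(waves), length.out = n)[order(runif(n))]
  rate <- rep_len(perWaveMissingRate, waves)
  miss <- matrix(runif(length(G)), n, length(si)) < rate[waveId]
  G[miss] <- NA_integer_
  storage.mode(G) <- "integer"
  samples <- data.frame(
    id = paste0(idPrefix, seq_len(n)),
    wave = paste0(design@name, "_w", waveId),
    case = runif(n) < caseFraction,
    pop = alloc$pop,
    age = round(rnorm(n, 30, 6), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    hapRow1 = rows[, 1], hapRow2 = rows[, 2],
    stringsAsFactors = FALSE)
  new("CohortDataset", genotypes = G, siteIndices = si,
      sites = siteInfo(panel)[si, , drop = FALSE], samples = samples,
      provenance = paste0("genotyped:", design@name))
}

#' Simulate parent-offspring trios genotyped on both arrays
#'
#' Parents are diploids formed from unused panel haplotype pairs; each
#' offspring haplotype is a recombinant parental gamete. The transmitted
#' haplotypes are stored over the full panel site grid so phase estimates
#' can be scored. Genotypes are emitted on both array designs.
#'
#' @param panel a [HaplotypePanel-class].
#' @param nTrios number of trios.
#' @param designs list of two [ArrayDesign-class] objects.
#' @param mapLengthCm map length used for gamete crossovers.
#' @param seed RNG seed.
#' @param usedRows panel haplotype rows already consumed.
#' @param errorRate per-allele genotyping error (0 keeps trios Mendelian
#'   consistent everywhere).
#' @return A [TrioSet-class].
#' @export
makeTrios <- function(panel, nTrios, designs, mapLengthCm = NULL, seed = 1L,
                      usedRows = integer(), errorRate = 0) {
  set.seed(seed)
  lab <- popLabels(panel)
  H <- haplotypes(panel)
  cm <- siteInfo(panel)$cm
  if (!is.null(mapLengthCm)) cm <- cm * (mapLengthCm / max(max(cm), 1e-12))
  free <- setdiff(seq_len(nrow(H)), usedRows)
  if (length(free) < 4L * nTrios)
    stop("not enough free panel haplotypes for ", nTrios, " trios")
  free <- free[seq_len(4L * nTrios)]
  S <- ncol(H)
  fat <- matrix(0L, nTrios, S); mot <- matrix(0L, nTrios, S)
  hp <- matrix(0L, nTrios, S); hm <- matrix(0L, nTrios, S)
  fatRows <- matrix(free, ncol = 4L, byrow = TRUE)
  for (t in seq_len(nTrios)) {
    fr <- fatRows[t, 1:2]; mr <- fatRows[t, 3:4]
    hp[t, ] <- recombineGamete(H[fr[1], ], H[fr[2], ], cm)
    hm[t, ] <- recombineGamete(H[mr[1], ], H[mr[2], ], cm)
    fat[t, ] <- H[fr[1], ] + H[fr[2], ]
    mot[t, ] <- H[mr[1], ] + H[mr[2], ]
  }
  off <- hp + hm
  emit <- function(M, si) {
    G <- M[, si, drop = FALSE]
    if (errorRate > 0) {   # approximate allele flip on the genotype call
      f <- matrix(rbinom(length(G), 1L, errorRate), nrow(G), ncol(G))
      G <- abs(G - f)      # perturb by one allele with prob errorRate
    }
    storage.mode(G) <- "integer"
    G
  }
  geno <- lapply(designs, function(d) {
    si <- siteIndices(d)
    list(father = emit(fat, si), mother = emit(mot, si),
         offspring = emit(off, si))
  })
  names(geno) <- vapply(designs, function(d) d@name, "")
  dl <- designs
  names(dl) <- names(geno)
  storage.mode(hp) <- "integer"; storage.mode(hm) <- "integer"
  new("TrioSet", genotypes = geno, designs = dl, hapPat = hp, hapMat = hm,
      trioIds = paste0("trio", seq_len(nTrios), "_off"))
}

#' Simulate a heritable quantitative trait
#'
#' Genetic values are weighted sums of standardized true genotypes at the
#' causal sites with standard-normal effect sizes; environmental noise is
#' scaled so var(g)/var(y) equals h2 in expectation.
#'
#' @param cohorts list of [CohortDataset-class] objects whose samples carry
#'   hapRow1/hapRow2 metadata linking to the truth panel.
#' @param panel the truth [HaplotypePanel-class].
#' @param causalSites panel site indices of causal loci (may be masked from
#'   the arrays).
#' @param h2 target heritability in [0,1].
#' @param seed RNG seed.
#' @return A [PhenotypeSet-class] covering all samples of all cohorts.
#' @export
simulatePhenotype <- function(cohorts, panel, causalSites, h2 = 0.5,
                              seed = 1L) {
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0,1]")
  if (any(causalSites < 1L | causalSites > nSites(panel)))
    stop("causalSites outside panel bounds")
  set.seed(seed)
  if (inherits(cohorts, "CohortDataset")) cohorts <- list(cohorts)
  meta <- do.call(rbind, lapply(cohorts, function(co)
    sampleInfo(co)[, c("id", "hapRow1", "hapRow2")]))
  H <- haplotypes(panel)
  X <- H[meta$hapRow1, causalSites, drop = FALSE] +
       H[meta$hapRow2, causalSites, drop = FALSE]
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  beta <- rnorm(length(causalSites))
  Xs <- scale(X[, keep, drop = FALSE],
              center = 2 * p[keep], scale = sqrt(2 * p[keep] * (1 - p[keep])))
  g <- as.numeric(Xs %*% beta[keep])
  vg <- var(g)
  if (h2 == 0) {
    y <- rnorm(length(g), 0, sqrt(max(vg, 1)))  # pure noise, g retained
  } else {
    e <- if (h2 == 1 || vg == 0) numeric(length(g)) else
      rnorm(length(g), 0, sqrt(vg * (1 - h2) / h2))
    y <- g + e
  }
  new("PhenotypeSet", sampleId = meta$id, g = g, y = y,
      causalSites = as.integer(causalSites), beta = beta, h2 = h2)
}
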