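## The four data-integration protocols (separate, intersection, union,
## two-stage) and the masked-SNP evaluation design.

#' Mask evaluation SNPs before phasing
#'
#' Randomly selects k QC-passed sites shared by both cohorts (and both
#' array designs), removes them from both cohorts' genotyped site sets, and
#' stores truth genotypes (from the simulation panel) for scoring only.
#'
#' @param cohortA,cohortB [CohortDataset-class] objects after QC.
#' @param k number of sites to mask.
#' @param panel the truth [HaplotypePanel-class].
#' @param seed RNG seed (a fixed seed gives an identical mask across runs).
#' @return list(mask = [MaskSet-class], cohortA, cohortB) with the masked
#'   sites removed from both cohorts.
#' @export
maskSnps <- function(cohortA, cohortB, k, panel, seed = 1L) {
  shared <- intersect(siteIndices(cohortA), siteIndices(cohortB))
  if (k > length(shared))
    stop("k = ", k, " exceeds the ", length(shared), " shared QC-passed sites")
  set.seed(seed)
  masked <- sort(sample(shared, k))
  H <- haplotypes(panel)
  truthOf <- function(co) {
    meta <- sampleInfo(co)
    H[meta$hapRow1, masked, drop = FALSE] +
      H[meta$hapRow2, masked, drop = FALSE]
  }
  mask <- new("MaskSet", siteIndices = as.integer(masked),
              truth = list(A = truthOf(cohortA), B = truthOf(cohortB)),
              seed = as.integer(seed))
  list(mask = mask,
       cohortA = dropSites(cohortA, masked),
       cohortB = dropSites(cohortB, masked))
}

## Trio offspring as a cohort on one array design, mask removed.
trioAsCohort <- function(trios, designName, maskIndices = integer(),
                         panelSites) {
  d <- trios@designs[[designName]]
  keep <- !(siteIndices(d) %in% maskIndices)
  si <- siteIndices(d)[keep]
  G <- trios@genotypes[[designName]]$offspring[, keep, drop = FALSE]
  samples <- data.frame(
    id = trios@trioIds,
    wave = paste0(designName, "_trio"),
    case = FALSE, pop = "trio", age = NA_real_, sex = NA_character_,
    hapRow1 = NA_integer_, hapRow2 = NA_integer_,
    stringsAsFactors = FALSE)
  new("CohortDataset", genotypes = G, siteIndices = si,
      sites = panelSites[si, , drop = FALSE], samples = samples,
      provenance = paste0("trios:", designName))
}

appendSamples <- function(cohort, extra) {
  if (is.null(extra)) return(cohort)
  if (!identical(siteIndices(cohort), siteIndices(extra)))
    stop("cannot append samples genotyped on a different site set")
  initialize(cohort,
             genotypes = rbind(genotypes(cohort), genotypes(extra)),
             samples = rbind(sampleInfo(cohort), sampleInfo(extra)))
}

## Restrict a cohort to a site subset (panel indices, kept sorted).
restrictSites <- function(cohort, panelIndices) {
  keep <- siteIndices(cohort) %in% panelIndices
  initialize(cohort,
             genotypes = cohort@genotypes[, keep, drop = FALSE],
             siteIndices = cohort@siteIndices[keep],
             sites = cohort@sites[keep, , drop = FALSE])
}

#' Separate protocol: phase and impute each cohort on its own
#'
#' Pass-through with provenance tags; dual-genotyped trio offspring are
#' appended to both cohorts (each on its own array's genotypes).
#'
#' @param cohortA,cohortB masked [CohortDataset-class] objects.
#' @param trios optional [TrioSet-class].
#' @param mask optional [MaskSet-class] (trio genotypes lose masked sites).
#' @param panel the truth panel (site annotation for trio cohorts).
#' @return list of two CohortDatasets tagged separate:A / separate:B.
#' @export
buildSeparate <- function(cohortA, cohortB, trios = NULL, mask = NULL,
                          panel = NULL) {
  mi <- if (is.null(mask)) integer() else siteIndices(mask)
  out <- list(A = cohortA, B = cohortB)
  if (!is.null(trios)) {
    nmA <- names(trios@designs)[1]; nmB <- names(trios@designs)[2]
    tA <- restrictSites(trioAsCohort(trios, nmA, mi, siteInfo(panel)),
                        siteIndices(cohortA))
    tB <- restrictSites(trioAsCohort(trios, nmB, mi, siteInfo(panel)),
                        siteIndices(cohortB))
    out$A <- appendSamples(cohortA, tA)
    out$B <- appendSamples(cohortB, tB)
  }
  out$A@provenance <- "separate:A"
  out$B@provenance <- "separate:B"
  out
}

## Merge two cohorts on an explicit site set; samples missing at sites not
## on their own array.
mergeOnSites <- function(cohortA, cohortB, sites, tag) {
  n <- length(sites)
  fill <- function(co) {
    G <- matrix(NA_integer_, nSamples(co), n)
    pos <- match(siteIndices(co), sites)
    keep <- !is.na(pos)
    G[, pos[keep]] <- genotypes(co)[, keep, drop = FALSE]
    G
  }
  G <- rbind(fill(cohortA), fill(cohortB))
  samples <- rbind(sampleInfo(cohortA), sampleInfo(cohortB))
  sitesTab <- rbind(siteInfo(cohortA), siteInfo(cohortB))
  sitesTab <- sitesTab[!duplicated(rownames(sitesTab)), , drop = FALSE]
  ord <- match(sites, c(siteIndices(cohortA),
                        siteIndices(cohortB))[!duplicated(
                          c(siteIndices(cohortA), siteIndices(cohortB)))])
  st <- sitesTab[ord, , drop = FALSE]
  new("CohortDataset", genotypes = G, siteIndices = as.integer(sites),
      sites = st, samples = samples, provenance = tag)
}

## Choose which array's genotypes each trio offspring contributes to a
## merged protocol (seeded, shared across protocols).
chooseTrioArrays <- function(trios, seed) {
  set.seed(seed)
  nm <- names(trios@designs)
  sample(nm, length(trios@trioIds), replace = TRUE)
}

trioMergedCohort <- function(trios, trioAssign, sites, maskIndices,
                             panelSites) {
  nm <- names(trios@designs)
  parts <- lapply(nm, function(d) {
    idx <- which(trioAssign == d)
    if (!length(idx)) return(NULL)
    co <- trioAsCohort(trios, d, maskIndices, panelSites)
    initialize(co, genotypes = co@genotypes[idx, , drop = FALSE],
               samples = co@samples[idx, , drop = FALSE])
  })
  parts <- Filter(Negate(is.null), parts)
  n <- length(sites)
  G <- do.call(rbind, lapply(parts, function(co) {
    M <- matrix(NA_integer_, nSamples(co), n)
    pos <- match(siteIndices(co), sites)
    keep <- !is.na(pos)
    M[, pos[keep]] <- genotypes(co)[, keep, drop = FALSE]
    M
  }))
  samples <- do.call(rbind, lapply(parts, sampleInfo))
  ord <- match(samples$id, paste0("trio", seq_len(length(trioAssign)), "_off"))
  list(G = G[order(ord), , drop = FALSE],
       samples = samples[order(ord), , drop = FALSE])
}

#' Intersection protocol: merge on the shared site set
#'
#' Samples from both cohorts are concatenated at the QC-passed sites common
#' to both arrays (masked sites removed); each dual-genotyped trio
#' offspring contributes one array's genotypes, chosen at random.
#'
#' @param cohortA,cohortB masked cohorts.
#' @param trios optional [TrioSet-class].
#' @param trioAssign per-offspring array name (from [chooseTrioArrays]).
#' @param mask optional [MaskSet-class].
#' @param panel truth panel for site annotation.
#' @return one merged [CohortDataset-class].
#' @export
buildIntersection <- function(cohortA, cohortB, trios = NULL,
                              trioAssign = NULL, mask = NULL, panel = NULL) {
  shared <- intersect(siteIndices(cohortA), siteIndices(cohortB))
  if (!length(shared)) stop("cohorts share no sites: empty intersection")
  out <- mergeOnSites(restrictSites(cohortA, shared),
                      restrictSites(cohortB, shared), sort(shared),
                      "intersection")
  if (!is.null(trios)) {
    mi <- if (is.null(mask)) integer() else siteIndices(mask)
    tm <- trioMergedCohort(trios, trioAssign, sort(shared), mi,
                           siteInfo(panel))
    if (any(is.na(tm$G)))
      tm$G[] <- tm$G   # shared sites exist on both arrays; no structural NA
    out@genotypes <- rbind(out@genotypes, tm$G)
    out@samples <- rbind(out@samples, tm$samples)
  }
  validObject(out)
  out
}

#' Union protocol: merge on all sites of either array
#'
#' Samples are merged at the union of the two site sets (masked sites
#' removed); cohort-A samples are structurally missing at B-only sites and
#' vice versa. The structural missingness fraction is recorded in the log
#' attribute of the provenance.
#'
#' @inheritParams buildIntersection
#' @return one merged [CohortDataset-class].
#' @export
buildUnion <- function(cohortA, cohortB, trios = NULL, trioAssign = NULL,
                       mask = NULL, panel = NULL) {
  sites <- sort(union(siteIndices(cohortA), siteIndices(cohortB)))
  out <- mergeOnSites(cohortA, cohortB, sites, "union")
  if (!is.null(trios)) {
    mi <- if (is.null(mask)) integer() else siteIndices(mask)
    tm <- trioMergedCohort(trios, trioAssign, sites, mi, siteInfo(panel))
    out@genotypes <- rbind(out@genotypes, tm$G)
    out@samples <- rbind(out@samples, tm$samples)
  }
  sm <- mean(is.na(out@genotypes))
  out@provenance <- sprintf("union(structural_missingness=%.4f)", sm)
  validObject(out)
  out
}

#' Two-stage protocol: impute to the union, merge, re-phase
#'
#' Stage 1 takes the separately phased cohorts, imputes each to the union
#' site set (minus mask) against the reference, and hard-calls the most
#' probable genotype at sites the cohort did not genotype (observed calls
#' are never overwritten). The merged dataset has zero missingness and is
#' intended for a second stage of phasing, after which [splitBack()]
#' restores the original per-cohort genotyped site sets.
#'
#' @param phasedA,phasedB [PhasedHaplotypes-class] from the separate
#'   protocol.
#' @param referencePanel reference [HaplotypePanel-class].
#' @param params [HMMParams-class] for stage-1 imputation.
#' @param dropIdsA,dropIdsB sample ids to drop from each side before the
#'   merge (the non-chosen copies of dual-genotyped trio offspring).
#' @return one merged zero-missingness [CohortDataset-class] tagged
#'   two_stage.
#' @export
buildTwoStage <- function(phasedA, phasedB, referencePanel,
                          params = hmmParams(), dropIdsA = character(),
                          dropIdsB = character()) {
  if (is.null(phasedA) || is.null(phasedB))
    stop("two-stage needs the phased outputs of the separate protocol")
  sites <- sort(union(siteIndices(phasedA), siteIndices(phasedB)))
  hardCall <- function(ph) {
    dm <- impute(ph, referencePanel, sites, params, returnStrandProbs = TRUE)
    p1 <- attr(dm, "strand1"); p2 <- attr(dm, "strand2")
    P0 <- (1 - p1) * (1 - p2)
    P1 <- p1 * (1 - p2) + (1 - p1) * p2
    P2 <- p1 * p2
    G <- (P1 > P0 & P1 >= P2) + 2L * (P2 > P0 & P2 > P1)
    ## observed genotyped sites pass through exactly
    typedPos <- match(siteIndices(ph), sites)
    h <- haplotypes(ph)
    obs <- h$hap1 + h$hap2
    obs[ph@imputed] <- NA_integer_
    for (j in seq_along(typedPos)) {
      ok <- !is.na(obs[, j])
      G[ok, typedPos[j]] <- obs[ok, j]
    }
    storage.mode(G) <- "integer"
    G
  }
  keepA <- !(sampleInfo(phasedA)$id %in% dropIdsA)
  keepB <- !(sampleInfo(phasedB)$id %in% dropIdsB)
  GA <- hardCall(phasedA)[keepA, , drop = FALSE]
  GB <- hardCall(phasedB)[keepB, , drop = FALSE]
  sitesTab <- rbind(siteInfo(phasedA), siteInfo(phasedB))
  key <- c(siteIndices(phasedA), siteIndices(phasedB))
  sitesTab <- sitesTab[!duplicated(key), , drop = FALSE]
  st <- sitesTab[match(sites, key[!duplicated(key)]), , drop = FALSE]
  samples <- rbind(sampleInfo(phasedA)[keepA, , drop = FALSE],
                   sampleInfo(phasedB)[keepB, , drop = FALSE])
  new("CohortDataset", genotypes = rbind(GA, GB),
      siteIndices = as.integer(sites), sites = st, samples = samples,
      provenance = "two_stage")
}

#' Split a jointly phased merged dataset back to per-cohort site sets
#'
#' After second-stage phasing of the merged two-stage dataset, each
#' cohort's haplotypes are restricted back to its original genotyped site
#' set (ready for imputation to the full reference).
#'
#' @param phasedMerged [PhasedHaplotypes-class] of the merged dataset.
#' @param cohortA,cohortB the original (pre-merge) cohorts whose site sets
#'   and sample ids define the split.
#' @return list of two [PhasedHaplotypes-class] objects.
#' @export
splitBack <- function(phasedMerged, cohortA, cohortB) {
  one <- function(co, tag) {
    rows <- match(intersect(sampleInfo(co)$id, sampleInfo(phasedMerged)$id),
                  sampleInfo(phasedMerged)$id)
    cols <- match(siteIndices(co), siteIndices(phasedMerged))
    if (anyNA(cols)) stop("merged phasing lacks cohort sites")
    new("PhasedHaplotypes",
        hap1 = phasedMerged@hap1[rows, cols, drop = FALSE],
        hap2 = phasedMerged@hap2[rows, cols, drop = FALSE],
        certainty = phasedMerged@certainty[rows, cols, drop = FALSE],
        imputed = phasedMerged@imputed[rows, cols, drop = FALSE],
        siteIndices = siteIndices(co), sites = siteInfo(co),
        samples = sampleInfo(phasedMerged)[rows, , drop = FALSE],
        provenance = paste0("two_stage|split:", tag))
  }
  list(A = one(cohortA, "A"), B = one(cohortB, "B"))
}

#' Protocol manifest
#'
#' @param cohorts named list of protocol [CohortDataset-class] outputs.
#' @return data.frame(protocol, nSamples, nSites, missingness).
#' @export
protocolManifest <- function(cohorts) {
  do.call(rbind, lapply(names(cohorts), function(nm) {
    co <- cohorts[[nm]]
    data.frame(protocol = nm, nSamples = nSamples(co), nSites = nSites(co),
               missingness = mean(is.na(genotypes(co))))
  }))
}
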