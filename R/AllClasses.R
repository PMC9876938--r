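#' @import methods
#' @importFrom stats rnorm runif rbinom rpois pchisq qchisq p.adjust var cor
#'   median lm resid complete.cases setNames mahalanobis cov quantile sd
#'   pnorm pt rbeta
#' @importFrom utils head tail write.table read.table
#' @useDynLib GenoPhase, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## Central containers. All matrices are sample-major (rows = samples) except
## the haplotype panel, which is haplotype-major (rows = haplotypes) so that
## consecutive row pairs form diploid individuals with known truth phase.
## ---------------------------------------------------------------------------

#' HaplotypePanel: phased ground-truth haplotypes
#'
#' Holds an ordered set of biallelic loci (base-pair and centimorgan
#' coordinates) and a binary haplotype matrix (alt allele = 1). Consecutive
#' haplotype row pairs (1,2), (3,4), ... form diploid individuals, so the
#' true phase of every simulated sample is known. Every downstream accuracy
#' metric is scored against this object.
#'
#' @slot sites data.frame with columns chrom, pos (bp, strictly increasing),
#'   cm (non-decreasing genetic map position), ref, alt, id.
#' @slot haplotypes integer matrix, haplotypes x sites, entries in {0,1}.
#' @slot popLabel character vector, population label per haplotype.
#' @slot founder logical vector, TRUE for founder-generation haplotypes.
#' @export
setClass("HaplotypePanel",
  representation(sites = "data.frame", haplotypes = "matrix",
                 popLabel = "character", founder = "logical"))

setValidity("HaplotypePanel", function(object) {
  s <- object@sites; h <- object@haplotypes
  msg <- character()
  need <- c("chrom", "pos", "cm", "ref", "alt", "id")
  if (!all(need %in% names(s)))
    msg <- c(msg, paste("sites must have columns", paste(need, collapse = ", ")))
  else {
    if (nrow(s) != ncol(h)) msg <- c(msg, "ncol(haplotypes) != nrow(sites)")
    if (nrow(s) > 1 && any(diff(s$pos) <= 0))
      msg <- c(msg, "bp positions must be strictly increasing")
    if (nrow(s) > 1 && any(diff(s$cm) < 0))
      msg <- c(msg, "cM positions must be non-decreasing")
    if (any(s$cm < 0)) msg <- c(msg, "cM positions must be non-negative")
  }
  if (!all(h %in% c(0L, 1L))) msg <- c(msg, "haplotype alleles must be 0/1")
  if (nrow(h) %% 2L != 0L) msg <- c(msg, "number of haplotypes must be even")
  if (length(object@popLabel) != nrow(h))
    msg <- c(msg, "popLabel length != number of haplotypes")
  if (length(object@founder) != nrow(h))
    msg <- c(msg, "founder length != number of haplotypes")
  if (length(msg)) msg else TRUE
})

#' PopulationModel: structured-population parameters
#'
#' Balding-Nichols style divergence: per-population allele frequencies are
#' drawn around an ancestral frequency with variance governed by Fst.
#' Admixed groups are formed by pairing one gamete from each of two
#' populations.
#'
#' @slot nPops integer number of populations.
#' @slot fst numeric vector in [0,1), one per population.
#' @slot ancestralShape numeric length-2, Beta(shape1, shape2) law of the
#'   ancestral allele frequency.
#' @slot admixture data.frame with columns popA, popB, label; each row
#'   defines an admixed group with one gamete from each parent population.
#' @export
setClass("PopulationModel",
  representation(nPops = "integer", fst = "numeric",
                 ancestralShape = "numeric", admixture = "data.frame"))

setValidity("PopulationModel", function(object) {
  msg <- character()
  if (object@nPops < 1L) msg <- c(msg, "nPops must be >= 1")
  if (length(object@fst) != object@nPops)
    msg <- c(msg, "fst must have one entry per population")
  if (any(object@fst < 0) || any(object@fst >= 1))
    msg <- c(msg, "fst must lie in [0,1)")
  if (length(object@ancestralShape) != 2 || any(object@ancestralShape <= 0))
    msg <- c(msg, "ancestralShape must be two positive Beta parameters")
  if (nrow(object@admixture) &&
      !all(c("popA", "popB", "label") %in% names(object@admixture)))
    msg <- c(msg, "admixture needs columns popA, popB, label")
  if (length(msg)) msg else TRUE
})

#' ArrayDesign: one genotyping array's manifest
#'
#' A named, ordered subset of panel site indices representing the QC-passed
#' marker manifest of a single genotyping array.
#'
#' @slot name character scalar.
#' @slot siteIndices strictly increasing integer indices into the panel.
#' @export
setClass("ArrayDesign",
  representation(name = "character", siteIndices = "integer"))

setValidity("ArrayDesign", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  si <- object@siteIndices
  if (length(si) && (any(si < 1L) || any(diff(si) <= 0L)))
    msg <- c(msg, "siteIndices must be strictly increasing and positive")
  if (length(msg)) msg else TRUE
})

#' CohortDataset: diploid genotypes for one cohort on one site set
#'
#' @slot genotypes integer matrix, samples x sites, values 0/1/2 or NA for
#'   missing calls.
#' @slot siteIndices panel site indices (sorted) the columns refer to.
#' @slot sites data.frame of site annotation rows matching siteIndices.
#' @slot samples data.frame with columns id, wave, case, pop, age, sex and
#'   (for simulated cohorts) hapRow1/hapRow2 linking back to panel rows.
#' @slot provenance character tag recording which stage/protocol produced it.
#' @export
setClass("CohortDataset",
  representation(genotypes = "matrix", siteIndices = "integer",
                 sites = "data.frame", samples = "data.frame",
                 provenance = "character"))

setValidity("CohortDataset", function(object) {
  msg <- character()
  g <- object@genotypes
  if (!all(g %in% c(0L, 1L, 2L, NA)))
    msg <- c(msg, "genotypes must be 0/1/2 or NA")
  if (ncol(g) != length(object@siteIndices))
    msg <- c(msg, "ncol(genotypes) != length(siteIndices)")
  if (length(object@siteIndices) > 1 && any(diff(object@siteIndices) <= 0L))
    msg <- c(msg, "siteIndices must be sorted strictly increasing")
  if (nrow(object@sites) != length(object@siteIndices))
    msg <- c(msg, "sites table does not match siteIndices")
  if (nrow(g) != nrow(object@samples))
    msg <- c(msg, "nrow(genotypes) != nrow(samples)")
  if (anyDuplicated(object@samples$id))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' TrioSet: parent-offspring trios genotyped on both arrays
#'
#' Offspring haplotypes are recombinant parental gametes; the true
#' transmitted haplotypes are retained (over the full panel site grid) for
#' scoring phase estimates.
#'
#' @slot genotypes named list, one element per array design, each a list
#'   with father/mother/offspring genotype matrices (trios x design sites).
#' @slot designs named list of the two ArrayDesign objects.
#' @slot hapPat integer matrix trios x panel sites: transmitted paternal
#'   haplotype of each offspring.
#' @slot hapMat integer matrix: transmitted maternal haplotype.
#' @slot trioIds character vector of offspring ids.
#' @export
setClass("TrioSet",
  representation(genotypes = "list", designs = "list",
                 hapPat = "matrix", hapMat = "matrix", trioIds = "character"))

setValidity("TrioSet", function(object) {
  msg <- character()
  n <- length(object@trioIds)
  if (nrow(object@hapPat) != n || nrow(object@hapMat) != n)
    msg <- c(msg, "transmitted haplotype matrices must have one row per trio")
  if (!identical(dim(object@hapPat), dim(object@hapMat)))
    msg <- c(msg, "hapPat and hapMat dimensions differ")
  if (!identical(sort(names(object@genotypes)), sort(names(object@designs))))
    msg <- c(msg, "genotypes and designs must be keyed by the same array names")
  if (length(msg)) msg else TRUE
})

#' PhenotypeSet: simulated heritable quantitative trait
#'
#' y = g + e where g is a weighted sum of standardized causal genotypes with
#' standard-normal effect sizes and e is scaled so var(g)/var(y) equals the
#' target heritability in expectation.
#'
#' @slot sampleId character.
#' @slot g numeric genetic values.
#' @slot y numeric phenotypes.
#' @slot causalSites integer panel site indices of causal loci.
#' @slot beta numeric per-causal-site effects (standard normal draws).
#' @slot h2 numeric target heritability.
#' @export
setClass("PhenotypeSet",
  representation(sampleId = "character", g = "numeric", y = "numeric",
                 causalSites = "integer", beta = "numeric", h2 = "numeric"))

setValidity("PhenotypeSet", function(object) {
  msg <- character()
  n <- length(object@sampleId)
  if (length(object@g) != n || length(object@y) != n)
    msg <- c(msg, "g and y must match sampleId length")
  if (length(object@beta) != length(object@causalSites))
    msg <- c(msg, "beta must match causalSites length")
  if (object@h2 < 0 || object@h2 > 1) msg <- c(msg, "h2 must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' HMMParams: Li-Stephens engine settings
#'
#' The conditioning-set size plays the role of the accuracy/compute knobs of
#' production phasing tools (phase states, PBWT depth); larger sets trade
#' run time for accuracy.
#'
#' @slot nStates integer, number of conditioning haplotypes (>= 2).
#' @slot ne numeric, effective-population-size scale of the recombination
#'   rate: the per-interval switch probability is 1-exp(-0.04*ne*dcm/K).
#' @slot errorRate numeric in (0, 0.5), per-site copying mismatch rate.
#' @slot nIterations integer, phasing refinement sweeps (>= 1).
#' @slot seed integer RNG seed for the engine.
#' @export
setClass("HMMParams",
  representation(nStates = "integer", ne = "numeric", errorRate = "numeric",
                 nIterations = "integer", seed = "integer"))

setValidity("HMMParams", function(object) {
  msg <- character()
  if (object@nStates < 2L) msg <- c(msg, "nStates must be >= 2")
  if (object@errorRate <= 0 || object@errorRate >= 0.5)
    msg <- c(msg, "errorRate must be in (0, 0.5)")
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (object@ne <= 0) msg <- c(msg, "ne must be positive")
  if (length(msg)) msg else TRUE
})

#' PhasedHaplotypes: estimated diplotypes for a cohort
#'
#' @slot hap1,hap2 integer matrices samples x sites, entries 0/1; at every
#'   non-missing genotype hap1+hap2 equals the observed call.
#' @slot certainty numeric matrix, per-site phase/imputation confidence.
#' @slot imputed logical matrix, TRUE where the genotype was missing and the
#'   alleles were filled from the copying posterior.
#' @slot siteIndices,sites,samples,provenance as in CohortDataset.
#' @export
setClass("PhasedHaplotypes",
  representation(hap1 = "matrix", hap2 = "matrix", certainty = "matrix",
                 imputed = "matrix", siteIndices = "integer",
                 sites = "data.frame", samples = "data.frame",
                 provenance = "character"))

setValidity("PhasedHaplotypes", function(object) {
  msg <- character()
  if (!identical(dim(object@hap1), dim(object@hap2)))
    msg <- c(msg, "hap1/hap2 dimensions differ")
  if (!all(object@hap1 %in% c(0L, 1L)) || !all(object@hap2 %in% c(0L, 1L)))
    msg <- c(msg, "haplotype alleles must be 0/1")
  if (ncol(object@hap1) != length(object@siteIndices))
    msg <- c(msg, "site dimension mismatch")
  if (nrow(object@hap1) != nrow(object@samples))
    msg <- c(msg, "sample dimension mismatch")
  if (length(msg)) msg else TRUE
})

#' DosageMatrix: imputed alt-allele dosages with per-site quality
#'
#' DS = p(RA) + 2 p(AA) in [0,2]; dr2 is the estimated-vs-expected
#' dosage-variance ratio (MaCH-Rsq form) clipped to [0,1].
#'
#' @slot dosages numeric matrix samples x target sites.
#' @slot dr2 numeric per-site quality in [0,1].
#' @slot refMaf numeric per-site minor allele frequency in the reference.
#' @slot siteIndices integer panel indices of the target sites.
#' @slot sampleId character.
#' @slot provenance character.
#' @export
setClass("DosageMatrix",
  representation(dosages = "matrix", dr2 = "numeric", refMaf = "numeric",
                 siteIndices = "integer", sampleId = "character",
                 provenance = "character"))

setValidity("DosageMatrix", function(object) {
  msg <- character()
  d <- object@dosages
  if (any(d < -1e-9 | d > 2 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "dosages must lie in [0,2]")
  if (length(object@dr2) != ncol(d)) msg <- c(msg, "dr2 length != n sites")
  if (any(object@dr2 < 0 | object@dr2 > 1, na.rm = TRUE))
    msg <- c(msg, "dr2 must lie in [0,1]")
  if (length(object@refMaf) != ncol(d)) msg <- c(msg, "refMaf length != n sites")
  if (nrow(d) != length(object@sampleId)) msg <- c(msg, "sampleId length != n samples")
  if (length(msg)) msg else TRUE
})

#' QCReport: result of one QC filter stage
#'
#' @slot filter character, name of the filter.
#' @slot stats data.frame of per-site or per-sample statistics (statistic,
#'   p, p.adjusted where applicable).
#' @slot excludedSites integer panel site indices excluded by this stage.
#' @slot excludedSamples character sample ids excluded by this stage.
#' @slot log character lines describing what was applied.
#' @export
setClass("QCReport",
  representation(filter = "character", stats = "data.frame",
                 excludedSites = "integer", excludedSamples = "character",
                 log = "character"))

#' MaskSet: held-out evaluation SNPs
#'
#' Sites randomly drawn from the QC-passed intersection of the two array
#' designs, removed from every phasing input; truth genotypes retained for
#' scoring only.
#'
#' @slot siteIndices integer panel indices of masked sites.
#' @slot truth named list of truth genotype matrices (samples x masked
#'   sites), one per cohort.
#' @slot seed integer.
#' @export
setClass("MaskSet",
  representation(siteIndices = "integer", truth = "list", seed = "integer"))

#' GwasResult: per-site association summary statistics
#'
#' @slot table data.frame with columns site, beta, se, stat, p, n,
#'   estimated (FALSE where the predictor was constant/collinear).
#' @slot covariates character descriptor of the covariate set.
#' @export
setClass("GwasResult",
  representation(table = "data.frame", covariates = "character"))

#' EvalReport: consolidated metrics for protocol x engine-setting runs
#'
#' @slot table tidy data.frame, one row per protocol x setting x metric x
#'   stratum (columns protocol, setting, metric, stratum, value, n).
#' @slot details list of richer per-metric objects.
#' @export
setClass("EvalReport",
  representation(table = "data.frame", details = "list"))

#' PgsExperimentResult: polygenic-score attenuation experiment
#'
#' @slot table tidy data.frame (discovery, scoring, arm, protocol, metric,
#'   value).
#' @slot concordance list of percentile-concordance matrices.
#' @export
setClass("PgsExperimentResult",
  representation(table = "data.frame", concordance = "list"))
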