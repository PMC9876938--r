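## Pre-phasing QC battery: SNP- and sample-level filters, the
## order-statistic minimum-p batch-artifact FDR, ancestry-adjusted
## heterozygosity, Mahalanobis homogeneous-subset selection, and a
## genotype-correlation relatedness proxy.

#' Default QC thresholds
#'
#' @param snpMissingMax max per-wave/merged SNP missingness (strict >).
#' @param diffmissFdr BH-FDR cutoff for differential missingness.
#' @param hweFdr BH-FDR cutoff for the Hardy-Weinberg test.
#' @param batchFdr order-statistic FDR cutoff for the batch-artifact scan.
#' @param mafMin minor-allele-frequency censoring threshold (strict <).
#' @param hetSd standard-deviation multiple for heterozygosity outliers.
#' @param mahalanobisP chi-square upper-tail probability cutoff for
#'   population outliers.
#' @param sampleMissingMax max per-sample missingness (strict >).
#' @param kinshipMax relatedness cutoff for GWAS/PGS subsets.
#' @param duplicateKinship kinship proxy above which a pair is treated as a
#'   duplicate / monozygotic twin.
#' @return named list of thresholds.
#' @export
qcThresholds <- function(snpMissingMax = 0.05, diffmissFdr = 0.2,
                         hweFdr = 0.2, batchFdr = 0.1, mafMin = 0.001,
                         hetSd = 4, mahalanobisP = 5.73e-7,
                         sampleMissingMax = 0.05, kinshipMax = 0.0825,
                         duplicateKinship = 0.45) {
  list(snpMissingMax = snpMissingMax, diffmissFdr = diffmissFdr,
       hweFdr = hweFdr, batchFdr = batchFdr, mafMin = mafMin,
       hetSd = hetSd, mahalanobisP = mahalanobisP,
       sampleMissingMax = sampleMissingMax, kinshipMax = kinshipMax,
       duplicateKinship = duplicateKinship)
}

## Vectorized 2x2 Pearson chi-square (no continuity correction).
chisq2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  den <- r1 * r2 * c1 * c2
  stat <- ifelse(den > 0, n * (a * d - b * c)^2 / den, 0)
  list(stat = stat, p = pchisq(stat, 1L, lower.tail = FALSE))
}

qcReport <- function(filter, stats = data.frame(),
                     excludedSites = integer(),
                     excludedSamples = character(), log = character()) {
  new("QCReport", filter = filter, stats = stats,
      excludedSites = as.integer(excludedSites),
      excludedSamples = excludedSamples, log = log)
}

#' Remove sites (by panel index) from a cohort
#' @param cohort a [CohortDataset-class].
#' @param panelIndices panel site indices to drop.
#' @export
dropSites <- function(cohort, panelIndices) {
  keep <- !(siteIndices(cohort) %in% panelIndices)
  initialize(cohort,
             genotypes = cohort@genotypes[, keep, drop = FALSE],
             siteIndices = cohort@siteIndices[keep],
             sites = cohort@sites[keep, , drop = FALSE])
}

#' Remove samples (by id) from a cohort
#' @param cohort a [CohortDataset-class].
#' @param ids sample ids to drop.
#' @export
dropSamples <- function(cohort, ids) {
  keep <- !(sampleInfo(cohort)$id %in% ids)
  initialize(cohort,
             genotypes = cohort@genotypes[keep, , drop = FALSE],
             samples = cohort@samples[keep, , drop = FALSE])
}

#' SNP missingness filter (per wave, then merged)
#'
#' A site is excluded if its missing fraction exceeds the threshold in any
#' single genotyping wave or in the merged cohort (strict >).
#'
#' @param cohort a [CohortDataset-class] with wave metadata.
#' @param threshold maximum tolerated missing fraction.
#' @param comparator ">" (default) or ">=".
#' @return A [QCReport-class].
#' @export
snpMissingnessFilter <- function(cohort, threshold = 0.05, comparator = ">") {
  G <- genotypes(cohort)
  waves <- sampleInfo(cohort)$wave
  if (any(table(waves) == 0)) stop("empty genotyping wave")
  cmp <- match.fun(comparator)
  missMat <- is.na(G)
  merged <- colMeans(missMat)
  byWave <- vapply(unique(waves), function(w)
    colMeans(missMat[waves == w, , drop = FALSE]), numeric(ncol(G)))
  worstWave <- apply(byWave, 1L, max)
  bad <- cmp(worstWave, threshold) | cmp(merged, threshold)
  stats <- data.frame(site = siteIndices(cohort), missMerged = merged,
                      missWorstWave = worstWave, excluded = bad)
  qcReport("snp_missingness", stats,
           excludedSites = siteIndices(cohort)[bad],
           log = sprintf("snp_missingness: %d/%d sites excluded (%s %.3g, %d waves)",
                         sum(bad), ncol(G), comparator, threshold,
                         length(unique(waves))))
}

#' Differential missingness between cases and controls
#'
#' Per site, a 2x2 (missing/observed x case/control) Pearson chi-square;
#' Benjamini-Hochberg adjustment; exclusion at adjusted p <= fdrThreshold.
#'
#' @param cohort a [CohortDataset-class] with case metadata.
#' @param fdrThreshold BH-FDR cutoff.
#' @return A [QCReport-class].
#' @export
differentialMissingnessTest <- function(cohort, fdrThreshold = 0.2) {
  G <- genotypes(cohort)
  case <- sampleInfo(cohort)$case
  if (all(case) || !any(case)) stop("need both cases and controls")
  missMat <- is.na(G)
  mCase <- colSums(missMat[case, , drop = FALSE])
  mCtrl <- colSums(missMat[!case, , drop = FALSE])
  nCase <- sum(case); nCtrl <- sum(!case)
  ts <- chisq2x2(mCase, nCase - mCase, mCtrl, nCtrl - mCtrl)
  padj <- p.adjust(ts$p, method = "BH")
  bad <- padj <= fdrThreshold
  stats <- data.frame(site = siteIndices(cohort), stat = ts$stat,
                      p = ts$p, p.adjusted = padj, excluded = bad)
  qcReport("differential_missingness", stats,
           excludedSites = siteIndices(cohort)[bad],
           log = sprintf("differential_missingness: %d/%d sites excluded (FDR <= %.3g)",
                         sum(bad), ncol(G), fdrThreshold))
}

## Vectorized 1-df HWE chi-square from genotype counts.
hweChisq <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- ifelse(n > 0, (n1 + 2 * n2) / (2 * n), 0)
  e0 <- n * (1 - p)^2; e1 <- 2 * n * p * (1 - p); e2 <- n * p^2
  mono <- p <= 0 | p >= 1 | n == 0
  stat <- ifelse(mono, 0,
                 (n0 - e0)^2 / pmax(e0, .Machine$double.xmin) +
                 (n1 - e1)^2 / pmax(e1, .Machine$double.xmin) +
                 (n2 - e2)^2 / pmax(e2, .Machine$double.xmin))
  pval <- ifelse(mono, 1, pchisq(stat, 1L, lower.tail = FALSE))
  list(stat = stat, p = pval)
}

#' Hardy-Weinberg equilibrium test in controls
#'
#' One-degree-of-freedom chi-square on genotype counts computed in control
#' samples (optionally restricted to a homogeneous subset); monomorphic
#' sites are defined to have p = 1 and are never excluded here.
#'
#' @param cohort a [CohortDataset-class].
#' @param controlIds optional sample ids to restrict to (e.g. homogeneous
#'   controls); defaults to all non-case samples.
#' @param fdrThreshold BH-FDR cutoff; exclusion at adjusted p <= cutoff.
#' @return A [QCReport-class].
#' @export
hweTest <- function(cohort, controlIds = NULL, fdrThreshold = 0.2) {
  meta <- sampleInfo(cohort)
  use <- !meta$case
  if (!is.null(controlIds)) use <- use & meta$id %in% controlIds
  if (!any(use)) stop("no control samples available for the HWE test")
  G <- genotypes(cohort)[use, , drop = FALSE]
  n0 <- colSums(G == 0L, na.rm = TRUE)
  n1 <- colSums(G == 1L, na.rm = TRUE)
  n2 <- colSums(G == 2L, na.rm = TRUE)
  ts <- hweChisq(n0, n1, n2)
  padj <- p.adjust(ts$p, method = "BH")
  bad <- padj <= fdrThreshold & ts$p < 1
  stats <- data.frame(site = siteIndices(cohort), stat = ts$stat, p = ts$p,
                      p.adjusted = padj, excluded = bad)
  qcReport("hwe", stats, excludedSites = siteIndices(cohort)[bad],
           log = sprintf("hwe: %d/%d sites excluded (FDR <= %.3g, %d controls)",
                         sum(bad), ncol(genotypes(cohort)), fdrThreshold,
                         sum(use)))
}

#' Null CDF of the minimum of independent uniform p-values
#'
#' For Y = min(p_1, ..., p_m) with p_i ~ Uniform(0,1) independent,
#' P(Y <= y) = 1 - (1 - y)^m.
#'
#' @param y probability (vectorized).
#' @param nBatches number of tests m >= 1.
#' @return P(min <= y).
#' @export
minpNullCdf <- function(y, nBatches) {
  if (any(y < 0 | y > 1)) stop("y must lie in [0,1]")
  if (nBatches < 1) stop("nBatches must be >= 1")
  1 - (1 - y)^nBatches
}

#' Order-statistic batch-artifact scan
#'
#' For each genotyping wave, a one-vs-rest allele-count association test is
#' run at every site; the per-site minimum p across waves is compared to
#' its theoretical null (the minimum of independent uniforms). The
#' empirical-FDR adjustment is
#' nSnps * (1 - (1 - p)^nBatches) / #\{minp <= p\},
#' i.e. expected over observed counts below the threshold; sites are
#' excluded at adjusted value <= fdrThreshold.
#'
#' @param cohort a [CohortDataset-class] with >= 2 waves.
#' @param fdrThreshold cutoff on the adjusted value.
#' @return A [QCReport-class]; stats carries minp, p.adjusted and the
#'   theoretical QQ quantiles 1-(1-i/n)^(1/nBatches).
#' @export
batchArtifactScan <- function(cohort, fdrThreshold = 0.1) {
  G <- genotypes(cohort)
  waves <- sampleInfo(cohort)$wave
  uw <- unique(waves)
  if (length(uw) < 2L) stop("batch-artifact scan needs >= 2 waves")
  nB <- length(uw)
  altAll <- colSums(G, na.rm = TRUE)
  nAll <- colSums(!is.na(G)) * 2L
  minp <- rep(1, ncol(G))
  for (w in uw) {
    inw <- waves == w
    altW <- colSums(G[inw, , drop = FALSE], na.rm = TRUE)
    nW <- colSums(!is.na(G[inw, , drop = FALSE])) * 2L
    ts <- chisq2x2(altW, nW - altW, altAll - altW,
                   (nAll - nW) - (altAll - altW))
    minp <- pmin(minp, ts$p)
  }
  nSnps <- ncol(G)
  below <- rank(minp, ties.method = "max")   # #{minp_j <= minp_i}
  padj <- ifelse(minp == 0, 0, nSnps * minpNullCdf(minp, nB) / below)
  bad <- padj <= fdrThreshold
  i <- seq_len(nSnps)
  qq <- 1 - (1 - i / nSnps)^(1 / nB)
  stats <- data.frame(site = siteIndices(cohort), minp = minp,
                      p.adjusted = padj, excluded = bad,
                      qqExpected = qq[rank(minp, ties.method = "first")])
  qcReport("batch_artifacts", stats,
           excludedSites = siteIndices(cohort)[bad],
           log = sprintf("batch_artifacts: %d/%d sites excluded (FDR <= %.3g, %d waves)",
                         sum(bad), nSnps, fdrThreshold, nB))
}

#' Minor allele frequency censoring
#'
#' Sites with MAF strictly below mafMin (computed from non-missing calls)
#' are excluded; monomorphic sites have MAF 0 and are always censored.
#'
#' @param cohort a [CohortDataset-class].
#' @param mafMin censoring threshold.
#' @return A [QCReport-class].
#' @export
mafCensor <- function(cohort, mafMin = 0.001) {
  G <- genotypes(cohort)
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  bad <- maf < mafMin
  stats <- data.frame(site = siteIndices(cohort), maf = maf, excluded = bad)
  qcReport("maf_censor", stats, excludedSites = siteIndices(cohort)[bad],
           log = sprintf("maf_censor: %d/%d sites excluded (MAF < %.3g)",
                         sum(bad), ncol(G), mafMin))
}

#' Principal component analysis of a genotype matrix
#'
#' Missing genotypes are mean-imputed; columns are centered at 2p and
#' scaled by sqrt(2p(1-p)); components come from the exact singular value
#' decomposition and are variance-ordered with a deterministic sign
#' convention (largest-magnitude loading positive).
#'
#' @param G samples x sites genotype matrix (0/1/2, NA allowed).
#' @param nComponents number of components to return.
#' @return list(scores, loadings, varExplained).
#' @export
genoPCA <- function(G, nComponents = 10L) {
  G <- as.matrix(G)
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  G <- G[, keep, drop = FALSE]; p <- p[keep]
  Z <- sweep(G, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  k <- min(nComponents, nrow(Z) - 1L, ncol(Z))
  sv <- svd(Z, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]; sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(sv$u, 2L, sv$d[seq_len(k)] * flip, "*")
  loadings <- sweep(sv$v, 2L, flip, "*")
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = loadings,
       varExplained = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}

#' Per-sample runs of homozygosity
#'
#' Sum of lengths of stretches of consecutive homozygous calls of at least
#' minRun sites (missing calls break a run).
#'
#' @param cohort a [CohortDataset-class].
#' @param minRun minimum run length in sites.
#' @return numeric vector, one value per sample.
#' @export
runsOfHomozygosity <- function(cohort, minRun = 25L) {
  G <- genotypes(cohort)
  apply(G, 1L, function(g) {
    hom <- !is.na(g) & g != 1L
    r <- rle(hom)
    sum(r$lengths[r$values & r$lengths >= minRun])
  })
}

#' Ancestry-adjusted heterozygosity outliers
#'
#' Observed per-sample heterozygosity is regressed on the first four
#' principal components, their squares, and all pairwise products; the
#' residual is the ancestry-adjusted heterozygosity. Observed and adjusted
#' heterozygosity are each further regressed on runs of homozygosity. A
#' sample is flagged when all four quantities (observed, adjusted, and both
#' ROH-regression residuals) lie more than sdThreshold standard deviations
#' from their means (set conjunctive = FALSE for the any-of-four reading).
#'
#' @param cohort a [CohortDataset-class].
#' @param pcs samples x >=4 matrix of principal component scores.
#' @param roh per-sample runs-of-homozygosity (default computed internally).
#' @param sdThreshold standard-deviation multiple.
#' @param conjunctive flag only when all four criteria exceed the threshold.
#' @return A [QCReport-class]; stats has per-sample het, adjusted het,
#'   residuals and z-scores.
#' @export
ancestryAdjustedHeterozygosity <- function(cohort, pcs, roh = NULL,
                                           sdThreshold = 4,
                                           conjunctive = TRUE) {
  G <- genotypes(cohort)
  het <- rowMeans(G == 1L, na.rm = TRUE)
  if (is.null(roh)) roh <- runsOfHomozygosity(cohort)
  P <- as.matrix(pcs)[, 1:4, drop = FALSE]
  colnames(P) <- paste0("PC", 1:4)
  X <- cbind(1, P, P^2, P[, 1] * P[, 2], P[, 2] * P[, 3], P[, 3] * P[, 4],
             P[, 4] * P[, 1], P[, 1] * P[, 3], P[, 2] * P[, 4])
  colnames(X) <- c("(Intercept)", colnames(P), paste0(colnames(P), "^2"),
                   "PC1*PC2", "PC2*PC3", "PC3*PC4", "PC4*PC1", "PC1*PC3",
                   "PC2*PC4")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear heterozygosity design matrix; offending term(s): ",
         paste(dropped, collapse = ", "))
  }
  adj <- qr.resid(qx, het)
  residObs <- resid(lm(het ~ roh))
  residAdj <- resid(lm(adj ~ roh))
  z <- function(x) if (sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / sd(x)
  zs <- cbind(zHet = z(het), zAdj = z(adj), zResObs = z(residObs),
              zResAdj = z(residAdj))
  exceed <- abs(zs) > sdThreshold
  flag <- if (conjunctive) rowSums(exceed) == 4L else rowSums(exceed) > 0L
  stats <- data.frame(id = sampleInfo(cohort)$id, het = het, adjHet = adj,
                      residObs = residObs, residAdj = residAdj, zs,
                      flagged = flag)
  qcReport("abnormal_heterozygosity", stats,
           excludedSamples = sampleInfo(cohort)$id[flag],
           log = sprintf("abnormal_heterozygosity: %d/%d samples flagged (%s, %.3g SD)",
                         sum(flag), nrow(G),
                         if (conjunctive) "all-of-4" else "any-of-4",
                         sdThreshold))
}

#' Mahalanobis homogeneous-subset selection
#'
#' Mean and covariance of the first principal components (10 when
#' available) are estimated on anchor samples; a sample is kept when the
#' chi-square upper-tail probability of its squared Mahalanobis distance is
#' at least pCutoff.
#'
#' @param pcScores samples x components score matrix with rownames = ids.
#' @param anchorIds sample ids defining the anchor distribution (>= 11).
#' @param pCutoff upper-tail probability cutoff.
#' @return character vector of inlier sample ids.
#' @export
homogeneousSubset <- function(pcScores, anchorIds, pCutoff = 5.73e-7) {
  S <- as.matrix(pcScores)[, seq_len(min(10L, ncol(pcScores))), drop = FALSE]
  anchors <- S[rownames(S) %in% anchorIds, , drop = FALSE]
  if (nrow(anchors) < ncol(S) + 1L)
    stop("need more anchor samples than PC dimensions")
  mu <- colMeans(anchors)
  V <- cov(anchors)
  if (rcond(V) < 1e-12) stop("singular anchor covariance matrix")
  d2 <- mahalanobis(S, mu, V)
  keep <- pchisq(d2, df = ncol(S), lower.tail = FALSE) >= pCutoff
  rownames(S)[keep]
}

#' Kinship proxy matrix
#'
#' Standardized genotype covariance: K = Z Z' / (2 S) with Z the
#' 2p-centered, sqrt(2p(1-p))-scaled genotype matrix (mean-imputed).
#' Expected values: ~0.5 for duplicates/MZ twins, ~0.25 for first-degree
#' relatives, ~0 for unrelated pairs.
#'
#' @param G samples x sites genotype matrix.
#' @return symmetric samples x samples matrix.
#' @export
kinshipProxy <- function(G) {
  G <- as.matrix(G)
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  G <- G[, keep, drop = FALSE]; p <- p[keep]
  Z <- sweep(G, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  tcrossprod(Z) / (2 * ncol(Z))
}

#' Duplicate and relatedness handling
#'
#' Pairs with kinship proxy above the duplicate threshold are resolved by
#' keeping the case when the flags differ, otherwise the lower-missingness
#' sample. Pairs at or above kinshipMax are additionally recorded so that
#' one member of each can be excluded from GWAS/PGS subsets.
#'
#' @param cohorts one [CohortDataset-class] or a list (stacked on shared
#'   sites).
#' @param kinshipMax relatedness cutoff for GWAS/PGS subsets.
#' @param duplicateThreshold kinship proxy above which a pair is a
#'   duplicate.
#' @return A [QCReport-class]: excludedSamples are the duplicates to drop
#'   from the dataset; stats lists all flagged pairs with a removeForGwas
#'   column naming the member to exclude from association subsets.
#' @export
duplicateRelatednessFilter <- function(cohorts, kinshipMax = 0.0825,
                                       duplicateThreshold = 0.45) {
  if (inherits(cohorts, "CohortDataset")) cohorts <- list(cohorts)
  shared <- Reduce(intersect, lapply(cohorts, siteIndices))
  if (!length(shared)) stop("cohorts share no sites")
  meta <- do.call(rbind, lapply(cohorts, function(co)
    sampleInfo(co)[, c("id", "case")]))
  nPer <- vapply(cohorts, nSamples, 0L)
  offset <- cumsum(c(0L, head(nPer, -1L)))
  nAll <- sum(nPer)
  missing <- unlist(lapply(cohorts, function(co)
    rowMeans(is.na(genotypes(co)))))
  ## within-cohort kinship on the cohort's own (denser) site set; pairs
  ## across cohorts on the shared sites only — each pair is scored on the
  ## largest marker set available for it
  K <- matrix(-Inf, nAll, nAll)
  for (i in seq_along(cohorts)) {
    idx <- offset[i] + seq_len(nPer[i])
    K[idx, idx] <- kinshipProxy(genotypes(cohorts[[i]]))
  }
  if (length(cohorts) > 1L) {
    Gs <- do.call(rbind, lapply(cohorts, function(co)
      genotypes(co)[, match(shared, siteIndices(co)), drop = FALSE]))
    Ks <- kinshipProxy(Gs)
    for (i in seq_along(cohorts)) for (j in seq_along(cohorts)) {
      if (i == j) next
      K[offset[i] + seq_len(nPer[i]), offset[j] + seq_len(nPer[j])] <-
        Ks[offset[i] + seq_len(nPer[i]), offset[j] + seq_len(nPer[j])]
    }
  }
  ut <- which(upper.tri(K) & K > kinshipMax, arr.ind = TRUE)
  if (nrow(ut) == 0L)
    return(qcReport("duplicates_relatedness",
                    data.frame(id1 = character(), id2 = character(),
                               kinship = numeric(), type = character(),
                               crossCohort = logical(),
                               removeForGwas = character()),
                    log = "duplicates_relatedness: no pairs flagged"))
  k <- K[ut]
  cohortIdx <- rep(seq_along(cohorts), nPer)
  type <- ifelse(k > duplicateThreshold, "duplicate", "related")
  pick <- function(i, j) {
    ## element to REMOVE: keep case if flags differ, else lower missingness
    if (meta$case[i] != meta$case[j]) return(if (meta$case[i]) j else i)
    if (missing[i] != missing[j]) return(if (missing[i] < missing[j]) j else i)
    max(i, j)
  }
  rm_idx <- mapply(pick, ut[, 1], ut[, 2])
  stats <- data.frame(id1 = meta$id[ut[, 1]], id2 = meta$id[ut[, 2]],
                      kinship = k, type = type,
                      crossCohort = cohortIdx[ut[, 1]] != cohortIdx[ut[, 2]],
                      removeForGwas = meta$id[rm_idx],
                      stringsAsFactors = FALSE)
  dup <- unique(meta$id[rm_idx[type == "duplicate"]])
  qcReport("duplicates_relatedness", stats, excludedSamples = dup,
           log = sprintf("duplicates_relatedness: %d duplicate, %d related pairs",
                         sum(type == "duplicate"), sum(type == "related")))
}

#' Greedy relatedness pruning
#'
#' Given the flagged pair table of [duplicateRelatednessFilter()], removes
#' the minimum practical set of samples so that no flagged pair survives:
#' iteratively drop the sample involved in the most remaining pairs
#' (ties by id order). Optionally restricted to pairs whose members both
#' lie in an analysis subset.
#'
#' @param pairTable data.frame with columns id1, id2 (and optionally type).
#' @param within optional id universe; only pairs inside it count.
#' @return character ids to exclude.
#' @export
pruneRelated <- function(pairTable, within = NULL) {
  p <- pairTable
  if (!is.null(within)) p <- p[p$id1 %in% within & p$id2 %in% within, ]
  drop <- character()
  while (nrow(p)) {
    deg <- sort(table(c(p$id1, p$id2)), decreasing = TRUE)
    worst <- names(deg)[deg == max(deg)]
    worst <- sort(worst)[1]
    drop <- c(drop, worst)
    p <- p[p$id1 != worst & p$id2 != worst, ]
  }
  drop
}

#' Sample missingness filter
#'
#' Samples whose overall missing fraction strictly exceeds the threshold
#' are removed.
#'
#' @param cohort a [CohortDataset-class].
#' @param threshold maximum tolerated missing fraction.
#' @return A [QCReport-class].
#' @export
sampleMissingnessFilter <- function(cohort, threshold = 0.05) {
  G <- genotypes(cohort)
  frac <- rowMeans(is.na(G))
  bad <- frac > threshold
  stats <- data.frame(id = sampleInfo(cohort)$id, missing = frac,
                      excluded = bad)
  qcReport("sample_missingness", stats,
           excludedSamples = sampleInfo(cohort)$id[bad],
           log = sprintf("sample_missingness: %d/%d samples excluded (> %.3g)",
                         sum(bad), nrow(G), threshold))
}

#' Run the per-cohort SNP-level QC chain
#'
#' Applies, in order: wave/merged missingness, differential missingness,
#' Hardy-Weinberg (controls), batch-artifact scan, and MAF censoring, each
#' on the survivors of the previous stage.
#'
#' @param cohort a [CohortDataset-class].
#' @param thresholds list from [qcThresholds()].
#' @param hweControlIds optional homogeneous-control ids for the HWE test.
#' @return list(cohort = filtered cohort, reports = list of QCReport).
#' @export
snpQCPipeline <- function(cohort, thresholds = qcThresholds(),
                          hweControlIds = NULL) {
  reports <- list()
  r <- snpMissingnessFilter(cohort, thresholds$snpMissingMax)
  reports$snp_missingness <- r
  cohort <- dropSites(cohort, excludedSites(r))
  r <- differentialMissingnessTest(cohort, thresholds$diffmissFdr)
  reports$differential_missingness <- r
  cohort <- dropSites(cohort, excludedSites(r))
  r <- hweTest(cohort, hweControlIds, thresholds$hweFdr)
  reports$hwe <- r
  cohort <- dropSites(cohort, excludedSites(r))
  if (length(unique(sampleInfo(cohort)$wave)) >= 2L) {
    r <- batchArtifactScan(cohort, thresholds$batchFdr)
    reports$batch_artifacts <- r
    cohort <- dropSites(cohort, excludedSites(r))
  }
  r <- mafCensor(cohort, thresholds$mafMin)
  reports$maf_censor <- r
  cohort <- dropSites(cohort, excludedSites(r))
  list(cohort = cohort, reports = reports)
}
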