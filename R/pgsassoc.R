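## Polygenic-score experiment: cross-cohort GWAS at the masked sites,
## scoring, variance explained, error-in-discovery vs error-in-scoring
## arms, and percentile rank concordance.

#' Per-site quantitative-trait GWAS
#'
#' Ordinary least squares of the phenotype on each site's genotype/dosage
#' plus covariates, fitted by residualizing both sides on the covariates
#' (Frisch-Waugh); constant or covariate-collinear predictors are flagged
#' as not estimated.
#'
#' @param X samples x sites genotype or dosage matrix (colnames = site
#'   ids).
#' @param y phenotype vector.
#' @param covariates data.frame or matrix of covariates (age, sex, PCs);
#'   NULL for none.
#' @return A [GwasResult-class].
#' @export
gwasQuantitative <- function(X, y, covariates = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (is.null(covariates)) {
    C <- matrix(1, n, 1L)
  } else {
    C <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  qx <- qr(C)
  yr <- qr.resid(qx, y)
  Xr <- qr.resid(qx, X)
  dfRes <- n - qx$rank - 1L
  ssx <- colSums(Xr^2)
  estimable <- ssx > 1e-10
  beta <- se <- stat <- p <- rep(NA_real_, ncol(X))
  beta[estimable] <- colSums(Xr[, estimable, drop = FALSE] * yr) /
    ssx[estimable]
  rss <- colSums((yr - sweep(Xr, 2L, ifelse(estimable, beta, 0), "*"))^2)
  sigma2 <- rss / dfRes
  se[estimable] <- sqrt(sigma2[estimable] / ssx[estimable])
  stat[estimable] <- beta[estimable] / se[estimable]
  p[estimable] <- 2 * pt(abs(stat[estimable]), dfRes, lower.tail = FALSE)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("site", seq_len(ncol(X)))
  tab <- data.frame(site = ids, beta = beta, se = se, stat = stat, p = p,
                    n = n, estimated = estimable, stringsAsFactors = FALSE)
  new("GwasResult", table = tab,
      covariates = if (is.null(covariates)) "none" else
        paste(colnames(as.data.frame(covariates)), collapse = "+"))
}

#' Polygenic score
#'
#' score_j = sum_i beta_i X_ij over the scored site set; sites are aligned
#' by name and any mismatch is an error listing the offending sites.
#' Non-estimated betas contribute zero.
#'
#' @param gwas a [GwasResult-class] or a named numeric vector of effects.
#' @param X samples x sites matrix of dosages or genotype counts with
#'   matching colnames.
#' @return numeric score per sample.
#' @export
pgsScore <- function(gwas, X) {
  beta <- if (is(gwas, "GwasResult")) {
    setNames(ifelse(gwas@table$estimated, gwas@table$beta, 0),
             gwas@table$site)
  } else gwas
  X <- as.matrix(X)
  if (is.null(colnames(X)) && length(beta) == ncol(X)) {
    colnames(X) <- names(beta)
  }
  missing <- setdiff(names(beta), colnames(X))
  if (length(missing))
    stop("effect sites absent from target matrix: ",
         paste(head(missing, 10), collapse = ", "))
  as.numeric(X[, names(beta), drop = FALSE] %*% beta)
}

rsq <- function(fit) summary(fit)$r.squared

#' Incremental variance explained by a PGS
#'
#' Default: R2 of phenotype ~ covariates + PGS minus R2 of phenotype ~
#' covariates (nested, hence nonnegative). The literal two-model
#' comparison (PGS-only vs PGS + covariates) is available via
#' literal = TRUE.
#'
#' @param scores per-sample PGS.
#' @param y phenotype.
#' @param covariates data.frame of covariates or NULL.
#' @param literal use the PGS-only vs PGS+covariates contrast.
#' @return delta R2.
#' @export
varianceExplained <- function(scores, y, covariates = NULL,
                              literal = FALSE) {
  dat <- data.frame(y = y, pgs = scores)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  covNames <- setdiff(names(dat), c("y", "pgs"))
  if (length(y) <= length(covNames) + 2L)
    stop("too few samples for the nested model comparison")
  fmlFull <- stats::as.formula(paste("y ~ pgs",
    if (length(covNames)) paste("+", paste(covNames, collapse = "+")) else ""))
  full <- lm(fmlFull, data = dat)
  if (literal) {
    reduced <- lm(y ~ pgs, data = dat)
    return(rsq(full) - rsq(reduced))
  }
  fmlRed <- stats::as.formula(paste("y ~",
    if (length(covNames)) paste(covNames, collapse = "+") else "1"))
  reduced <- lm(fmlRed, data = dat)
  rsq(full) - rsq(reduced)
}

#' Percentile rank concordance and top-quantile overlap
#'
#' Samples are ranked into nQuantiles bins under each score vector (ties
#' broken by stable sample-id order); returns the joint occupancy matrix
#' and the proportion of the truth-score top topQ percent recovered by the
#' comparison score.
#'
#' @param scoresTruth,scoresOther score vectors over the same samples.
#' @param ids sample ids for stable tie-breaking.
#' @param nQuantiles number of rank bins (percentiles by default).
#' @param topQ size of the top tail, in quantile units.
#' @return list(matrix, topOverlap, quantilesTruth, quantilesOther).
#' @export
rankConcordance <- function(scoresTruth, scoresOther, ids = NULL,
                            nQuantiles = 100L, topQ = 5L) {
  n <- length(scoresTruth)
  if (length(scoresOther) != n) stop("score vectors differ in length")
  if (is.null(ids)) ids <- seq_len(n)
  qt <- function(s) {
    q <- integer(n)
    q[order(s, ids)] <- ceiling(seq_len(n) * nQuantiles / n)
    q
  }
  qTruth <- qt(scoresTruth); qOther <- qt(scoresOther)
  M <- table(factor(qTruth, seq_len(nQuantiles)),
             factor(qOther, seq_len(nQuantiles)))
  topT <- qTruth > nQuantiles - topQ
  topO <- qOther > nQuantiles - topQ
  overlap <- if (any(topT)) sum(topT & topO) / sum(topT) else NA_real_
  list(matrix = unclass(M), topOverlap = overlap,
       quantilesTruth = qTruth, quantilesOther = qOther)
}

#' Run the PGS error-localization arms
#'
#' For each discovery/scoring direction and each protocol: the reference
#' arm uses true genotypes for both GWAS and scoring; the
#' imputed-discovery arm runs the GWAS on imputed dosages and scores with
#' truth; the imputed-scoring arm runs the GWAS on truth and scores with
#' imputed dosages. Reports delta R2, percentile rank concordance with the
#' reference scores, and top-percentile overlap.
#'
#' @param truthA,truthB truth genotype matrices at the masked sites
#'   (analysis samples only), colnames = site ids.
#' @param dosByProtocol named list: protocol -> list(A =, B = ) dosage
#'   matrices aligned to truthA/truthB.
#' @param yA,yB phenotype vectors.
#' @param covA,covB covariate data.frames (or NULL).
#' @param idsA,idsB sample ids.
#' @param topQ top tail size in percentiles.
#' @return A [PgsExperimentResult-class].
#' @export
runPgsArms <- function(truthA, truthB, dosByProtocol, yA, yB,
                       covA = NULL, covB = NULL, idsA = NULL, idsB = NULL,
                       topQ = 5L) {
  dirs <- list(
    AtoB = list(Xd = truthA, yd = yA, cd = covA, Xs = truthB, ys = yB,
                cs = covB, ids = idsB, d = "A", s = "B"),
    BtoA = list(Xd = truthB, yd = yB, cd = covB, Xs = truthA, ys = yA,
                cs = covA, ids = idsA, d = "B", s = "A"))
  rows <- list(); conc <- list()
  for (dn in names(dirs)) {
    dd <- dirs[[dn]]
    gTruth <- gwasQuantitative(dd$Xd, dd$yd, dd$cd)
    sTruth <- pgsScore(gTruth, dd$Xs)
    refR2 <- varianceExplained(sTruth, dd$ys, dd$cs)
    rows[[length(rows) + 1L]] <- data.frame(
      direction = dn, arm = "truth_truth", protocol = "none",
      metric = "deltaR2", value = refR2)
    for (pn in names(dosByProtocol)) {
      dA <- dosByProtocol[[pn]][[dd$d]]
      dS <- dosByProtocol[[pn]][[dd$s]]
      ## imputation error in the discovery GWAS
      gImp <- gwasQuantitative(dA, dd$yd, dd$cd)
      sImpDisc <- pgsScore(gImp, dd$Xs)
      r2d <- varianceExplained(sImpDisc, dd$ys, dd$cs)
      ## imputation error in the scoring genotypes
      sImpScore <- pgsScore(gTruth, dS)
      r2s <- varianceExplained(sImpScore, dd$ys, dd$cs)
      rc <- rankConcordance(sTruth, sImpScore, dd$ids, topQ = topQ)
      conc[[paste(dn, pn, sep = ".")]] <- rc$matrix
      rows[[length(rows) + 1L]] <- data.frame(
        direction = dn, arm = "imputed_discovery", protocol = pn,
        metric = "deltaR2", value = r2d)
      rows[[length(rows) + 1L]] <- data.frame(
        direction = dn, arm = "imputed_scoring", protocol = pn,
        metric = "deltaR2", value = r2s)
      rows[[length(rows) + 1L]] <- data.frame(
        direction = dn, arm = "imputed_scoring", protocol = pn,
        metric = "topOverlap", value = rc$topOverlap)
    }
  }
  new("PgsExperimentResult", table = do.call(rbind, rows),
      concordance = conc)
}
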