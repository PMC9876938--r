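## Scoring: trio-resolved switch error rates, imputation r2 by MAF bin and
## ancestry group, and the array-membership association scan with genomic
## control across imputation-quality thresholds.

## Median of a chi-square(1) variate, to 4 decimals; lambda_GC divides the
## observed median chi-square by this.
CHISQ1_MEDIAN <- 0.4549

#' Default minor-allele-frequency bin edges
#'
#' Produces bins (0,0.005], (0.005,0.01], (0.01,0.05], (0.05,0.1],
#' (0.1,0.2], (0.2,0.5].
#'
#' @param edges strictly increasing numeric vector ending at 0.5.
#' @return the validated edge vector.
#' @export
mafBins <- function(edges = c(0, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5)) {
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (tail(edges, 1) != 0.5) stop("final edge must be 0.5")
  edges
}

binLabel <- function(edges) {
  paste0("(", head(edges, -1), ",", tail(edges, -1), "]")
}

#' Resolve offspring phase by Mendelian transmission
#'
#' For each offspring heterozygous site, the transmitted parental origin of
#' the alt allele is determined when at least one parent is homozygous;
#' triple-heterozygous sites are unresolvable and Mendelian-inconsistent
#' sites are dropped (counted).
#'
#' @param trios a [TrioSet-class].
#' @param panelIndices panel site indices to resolve at (must be genotyped
#'   on at least one of the trio arrays).
#' @return list(resolved = trios x sites logical, patAllele = trios x sites
#'   integer (paternal allele, NA where unresolved), nInconsistent,
#'   siteIndices).
#' @export
trioResolvePhase <- function(trios, panelIndices) {
  nms <- names(trios@designs)
  pick <- function(role) {
    M <- matrix(NA_integer_, length(trios@trioIds), length(panelIndices))
    for (d in nms) {
      si <- siteIndices(trios@designs[[d]])
      pos <- match(panelIndices, si)
      ok <- !is.na(pos)
      M[, ok] <- trios@genotypes[[d]][[role]][, pos[ok], drop = FALSE]
    }
    if (anyNA(M)) stop("some requested sites are on neither trio array")
    M
  }
  fat <- pick("father"); mot <- pick("mother"); off <- pick("offspring")
  ## Mendelian consistency: a hom parent forces one transmitted allele
  minOff <- (fat == 2) + (mot == 2)
  maxOff <- 2 - ((fat == 0) + (mot == 0))
  consistent <- off >= minOff & off <= maxOff
  het <- off == 1L
  patKnown <- fat != 1L
  matKnown <- mot != 1L
  pat <- matrix(NA_integer_, nrow(off), ncol(off))
  pat[het & patKnown] <- (fat %/% 2L)[het & patKnown]
  idx <- het & !patKnown & matKnown
  pat[idx] <- 1L - (mot %/% 2L)[idx]
  resolved <- het & consistent & !is.na(pat)
  pat[!resolved] <- NA_integer_
  list(resolved = resolved, patAllele = pat,
       nInconsistent = sum(!consistent),
       siteIndices = as.integer(panelIndices),
       trioIds = trios@trioIds)
}

#' Switch error rate against trio-resolved truth
#'
#' For each offspring, adjacent resolvable heterozygous-site pairs whose
#' relative phase orientation disagrees between estimate and truth count as
#' switches; SER = total switches / total possible switches (sum over
#' offspring of k-1). A global haplotype relabeling of an offspring leaves
#' the count unchanged. Offspring with fewer than two usable sites
#' contribute nothing.
#'
#' @param estimated [PhasedHaplotypes-class] containing the offspring
#'   samples (matched by id to truth$ids or trio order).
#' @param truth result of [trioResolvePhase()].
#' @param trioIds offspring ids in the order of truth rows.
#' @param blocks optional per-site block labels (over truth siteIndices)
#'   for a per-region SER breakdown.
#' @return list(ser, nSwitch, nPossible, perBlock data.frame or NULL).
#' @export
switchErrorRate <- function(estimated, truth, trioIds = truth$trioIds,
                            blocks = NULL) {
  estPos <- match(truth$siteIndices, siteIndices(estimated))
  rows <- match(trioIds, sampleInfo(estimated)$id)
  truthRows <- match(trioIds, truth$trioIds)
  if (anyNA(rows)) stop("offspring ids missing from the phased estimate")
  if (anyNA(truthRows)) stop("offspring ids missing from the truth set")
  nSwitch <- 0L; nPossible <- 0L
  blockTab <- NULL
  if (!is.null(blocks)) {
    ub <- unique(blocks)
    blockTab <- data.frame(block = ub, nSwitch = 0L, nPossible = 0L)
  }
  for (t in seq_along(trioIds)) {
    tr <- truthRows[t]
    use <- which(truth$resolved[tr, ] & !is.na(estPos))
    if (length(use) < 2L) next
    cols <- estPos[use]
    estGeno <- estimated@hap1[rows[t], cols] + estimated@hap2[rows[t], cols]
    use <- use[estGeno == 1L]
    if (length(use) < 2L) next
    cols <- estPos[use]
    z <- as.integer(estimated@hap1[rows[t], cols] ==
                    truth$patAllele[tr, use])
    sw <- z[-1] != z[-length(z)]
    nSwitch <- nSwitch + sum(sw)
    nPossible <- nPossible + length(z) - 1L
    if (!is.null(blocks)) {
      b <- blocks[use]
      samePair <- b[-1] == b[-length(b)]
      for (k in seq_len(nrow(blockTab))) {
        inb <- samePair & b[-1] == blockTab$block[k]
        blockTab$nSwitch[k] <- blockTab$nSwitch[k] + sum(sw[inb])
        blockTab$nPossible[k] <- blockTab$nPossible[k] + sum(inb)
      }
    }
  }
  if (!is.null(blockTab))
    blockTab$ser <- ifelse(blockTab$nPossible > 0,
                           blockTab$nSwitch / blockTab$nPossible, NA_real_)
  list(ser = if (nPossible > 0) nSwitch / nPossible else NA_real_,
       nSwitch = nSwitch, nPossible = nPossible, perBlock = blockTab)
}

#' Imputation accuracy by minor-allele-frequency bin
#'
#' Squared Pearson correlation between true genotypes and imputed dosages,
#' pooling (sample, site) pairs within each reference-MAF bin (the
#' per-SNP-averaged variant is available via perSnp = TRUE). Bins where
#' the truth has no variance are reported as NA, never 0.
#'
#' @param dosage a [DosageMatrix-class] at masked sites.
#' @param truth matching truth genotype matrix (samples x masked sites).
#' @param bins MAF bin edges from [mafBins()].
#' @param groupLabels optional per-sample stratification (e.g. ancestry).
#' @param perSnp average per-SNP r2 within bins instead of pooling.
#' @return data.frame(bin, group, r2, n) with n the number of pooled pairs
#'   (or SNPs when perSnp).
#' @export
imputationR2ByMaf <- function(dosage, truth, bins = mafBins(),
                              groupLabels = NULL, perSnp = FALSE) {
  DS <- dosages(dosage)
  stopifnot(identical(dim(DS), dim(truth)))
  maf <- dosage@refMaf
  binId <- cut(maf, bins, labels = binLabel(bins))
  groups <- if (is.null(groupLabels)) rep("all", nrow(DS)) else groupLabels
  out <- list()
  for (g in unique(groups)) {
    rows <- groups == g
    for (b in levels(binId)) {
      cols <- which(binId == b)
      if (!length(cols)) next
      tv <- as.numeric(truth[rows, cols, drop = FALSE])
      dv <- as.numeric(DS[rows, cols, drop = FALSE])
      if (perSnp) {
        r2s <- vapply(cols, function(j) {
          tt <- truth[rows, j]; dd <- DS[rows, j]
          if (var(tt) == 0 || var(dd) == 0) NA_real_ else cor(tt, dd)^2
        }, 0)
        out[[length(out) + 1L]] <- data.frame(
          bin = b, group = g, r2 = mean(r2s, na.rm = TRUE),
          n = sum(!is.na(r2s)))
      } else {
        r2 <- if (var(tv) == 0 || var(dv) == 0) NA_real_ else cor(tv, dv)^2
        out[[length(out) + 1L]] <- data.frame(bin = b, group = g, r2 = r2,
                                              n = length(tv))
      }
    }
  }
  do.call(rbind, out)
}

## 1-df allele-dosage trend chi-square of a binary outcome.
trendChisq <- function(x, y) {
  n <- length(x)
  if (var(x) == 0 || var(y) == 0) return(0)
  n * cor(x, y)^2
}

#' Array-membership association scan with genomic control
#'
#' Tests each masked site for association with cohort membership across
#' four arms: both sides true genotypes (baseline), genotypes vs imputed
#' dosages (both directions), and imputed vs imputed. lambda_GC is the
#' median association chi-square divided by the chi-square(1) median
#' (0.4549), per imputation-quality threshold (thresholds apply to the
#' arm's imputed side(s); surviving-SNP counts are reported).
#'
#' @param truthA,truthB truth genotype matrices at masked sites for the
#'   analysis samples of each cohort.
#' @param dosA,dosB [DosageMatrix-class] objects for the same samples and
#'   sites.
#' @param dr2Thresholds numeric thresholds on DR2.
#' @return data.frame(arm, threshold, lambda, nSnps).
#' @export
arrayMembershipScan <- function(truthA, truthB, dosA, dosB,
                                dr2Thresholds = c(0, 0.5, 0.9)) {
  if (!nrow(truthA) || !nrow(truthB)) stop("empty comparison arm")
  y <- c(rep(0L, nrow(truthA)), rep(1L, nrow(truthB)))
  dsA <- dosages(dosA); dsB <- dosages(dosB)
  arms <- list(
    geno_geno = list(a = truthA, b = truthB, q = NULL),
    genoA_impB = list(a = truthA, b = dsB, q = dr2(dosB)),
    impA_genoB = list(a = dsA, b = truthB, q = dr2(dosA)),
    imp_imp = list(a = dsA, b = dsB, q = pmin(dr2(dosA), dr2(dosB))))
  out <- list()
  for (nm in names(arms)) {
    arm <- arms[[nm]]
    X <- rbind(arm$a, arm$b)
    chi <- vapply(seq_len(ncol(X)), function(j) trendChisq(X[, j], y), 0)
    for (thr in dr2Thresholds) {
      keep <- if (is.null(arm$q)) rep(TRUE, ncol(X)) else arm$q >= thr
      if (!any(keep)) {
        out[[length(out) + 1L]] <- data.frame(arm = nm, threshold = thr,
                                              lambda = NA_real_, nSnps = 0L)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        arm = nm, threshold = thr,
        lambda = median(chi[keep]) / CHISQ1_MEDIAN, nSnps = sum(keep))
    }
  }
  do.call(rbind, out)
}

#' Equal-cM block labels for a per-region SER breakdown
#'
#' Partitions the simulated chromosome into equal-cM blocks (a
#' per-chromosome analog) so that SER can be related to target SNP density
#' per centimorgan.
#'
#' @param cm cM positions of the sites being scored.
#' @param nBlocks number of blocks.
#' @return integer block label per site.
#' @export
cmBlocks <- function(cm, nBlocks = 4L) {
  br <- seq(min(cm), max(cm), length.out = nBlocks + 1L)
  pmin(pmax(findInterval(cm, br, rightmost.closed = TRUE), 1L), nBlocks)
}
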