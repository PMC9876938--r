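## Li & Stephens haplotype-copying engine: iterative Viterbi phasing with
## missing-data handling, reference-based dosage imputation with a
## DR2-style quality metric, consensus voting, and a brute-force
## enumeration oracle for tests.

#' Construct engine parameters
#'
#' One engine with a conditioning-set-size knob stands in for the
#' accuracy/compute parameter grids of production phasing tools. The
#' desk-scale "default" and "high-resolution" settings are nStates = 40 and
#' 80.
#'
#' @param nStates conditioning haplotypes per sample (>= 2).
#' @param ne effective-population-size scale: the switch probability over a
#'   map interval of d cM is 1 - exp(-0.04 * ne * d / nStates).
#' @param errorRate per-site copying mismatch probability in (0, 0.5).
#' @param nIterations phasing refinement sweeps.
#' @param seed engine RNG seed.
#' @return An [HMMParams-class].
#' @export
hmmParams <- function(nStates = 40L, ne = 100, errorRate = 0.003,
                      nIterations = 2L, seed = 1L) {
  new("HMMParams", nStates = as.integer(nStates), ne = as.numeric(ne),
      errorRate = as.numeric(errorRate),
      nIterations = as.integer(nIterations), seed = as.integer(seed))
}

## Per-interval switch probabilities from cM positions.
switchProb <- function(cm, ne, K) {
  d <- diff(cm)
  1 - exp(-0.04 * ne * pmax(d, 0) / K)
}

## Reference haplotypes restricted to a set of panel site indices.
refMatrixAt <- function(referencePanel, panelIndices) {
  if (is.null(referencePanel)) return(NULL)
  pos <- match(panelIndices, seq_len(nSites(referencePanel)))
  if (anyNA(pos)) stop("reference panel does not cover requested sites")
  haplotypes(referencePanel)[, panelIndices, drop = FALSE]
}

## Hamming-style distance between diploid dosage vectors and candidate
## haplotypes: dist(i,c) = sum_s |g_is - 2 h_cs|, computed by one matrix
## product. G complete (no NA), H binary candidates x sites.
dosageHapDistance <- function(G, H) {
  M <- G %*% t(H)
  outer(rowSums(G), 2 * rowSums(H), "+") - 2 * M
}

#' Phase a cohort with the haplotype-copying engine
#'
#' Iterative conditional phasing: phase is initialized at random consistent
#' with the genotypes, then each sweep re-estimates every sample's
#' diplotype with the diploid copying HMM conditioned on the nStates
#' closest haplotypes among the reference panel and the current estimates
#' of the other samples. The update is the jointly most probable copying
#' path (Viterbi); at heterozygous sites the orientation maximizing the
#' path-conditional emission is taken, and missing genotypes are filled
#' with the path's copied alleles (flagged, never overwriting observed
#' calls).
#'
#' @param cohort a [CohortDataset-class].
#' @param referencePanel a [HaplotypePanel-class] of reference haplotypes
#'   covering the cohort's sites, or NULL for within-cohort phasing.
#' @param params an [HMMParams-class].
#' @return A [PhasedHaplotypes-class].
#' @export
phase <- function(cohort, referencePanel = NULL, params = hmmParams()) {
  validObject(params)
  G <- genotypes(cohort)
  N <- nrow(G); S <- ncol(G)
  if (N < 1L) stop("cohort has no samples")
  if (is.null(referencePanel) && N == 1L)
    stop("nothing to condition on: single sample and no reference panel")
  cm <- siteInfo(cohort)$cm
  R <- refMatrixAt(referencePanel, siteIndices(cohort))
  set.seed(params@seed)

  ## initial phase: random orientation at het sites, frequency draw at
  ## missing sites
  p <- colMeans(G, na.rm = TRUE) / 2
  p[is.na(p)] <- 0.5
  hap1 <- matrix(0L, N, S); hap2 <- matrix(0L, N, S)
  het <- !is.na(G) & G == 1L
  hom <- !is.na(G) & G != 1L
  hap1[hom] <- G[hom] %/% 2L; hap2[hom] <- G[hom] %/% 2L
  flip <- matrix(runif(N * S) < 0.5, N, S)
  hap1[het] <- as.integer(flip[het]); hap2[het] <- 1L - as.integer(flip[het])
  mis <- is.na(G)
  if (any(mis)) {
    pm <- matrix(rep(p, each = N), N, S)
    hap1[mis] <- as.integer(runif(sum(mis)) < pm[mis])
    hap2[mis] <- as.integer(runif(sum(mis)) < pm[mis])
  }

  Gna <- G; Gna[is.na(Gna)] <- -1L
  K <- params@nStates
  certainty <- matrix(1, N, S)
  imputedM <- mis

  nR <- if (is.null(R)) 0L else nrow(R)
  for (it in seq_len(params@nIterations)) {
    cand <- rbind(R, hap1, hap2)
    Gd <- hap1 + hap2
    D <- dosageHapDistance(Gd, cand)
    ## the first sweep conditions on the reference alone (the current
    ## estimates are still random phase); later sweeps use both, with
    ## estimates refreshed in place as samples are updated (Gauss-Seidel)
    refOnly <- it == 1L && nR >= 2L
    for (i in seq_len(N)) {
      d <- D[i, ]
      d[c(nR + i, nR + N + i)] <- Inf      # never condition on yourself
      if (refOnly && N > 1L) d[(nR + 1L):length(d)] <- Inf
      ord <- order(d, seq_along(d))
      use <- ord[seq_len(min(K, sum(is.finite(d))))]
      if (length(use) < 2L) stop("fewer than 2 conditioning haplotypes")
      Hc <- cand[use, , drop = FALSE]      # states x sites
      theta <- switchProb(cm, params@ne, ncol(Hc))
      vit <- cpp_diploid_viterbi(Gna[i, ], Hc, theta, params@errorRate)
      hap1[i, ] <- vit$hap1; hap2[i, ] <- vit$hap2
      cand[nR + i, ] <- vit$hap1; cand[nR + N + i, ] <- vit$hap2
      certainty[i, ] <- vit$certainty
      imputedM[i, ] <- vit$imputed
    }
  }
  new("PhasedHaplotypes", hap1 = hap1, hap2 = hap2, certainty = certainty,
      imputed = imputedM, siteIndices = siteIndices(cohort),
      sites = siteInfo(cohort), samples = sampleInfo(cohort),
      provenance = paste0(provenance(cohort), "|phased"))
}

#' Impute dosages against a reference panel
#'
#' Each phased haplotype is run through the haploid copying HMM against the
#' reference over the full reference site grid (observing its typed
#' alleles); the two allele posteriors combine into the genotype posterior
#' and DS = p(RA) + 2 p(AA). Sites typed and observed in the input pass
#' through with DS equal to the genotype. Per-site quality is the
#' estimated-vs-expected dosage-variance ratio (MaCH-Rsq form).
#'
#' @param phased a [PhasedHaplotypes-class].
#' @param referencePanel a [HaplotypePanel-class].
#' @param targetSites panel site indices to report dosages at.
#' @param params an [HMMParams-class]; conditioning uses up to 2 * nStates
#'   reference haplotypes closest to each sample.
#' @return A [DosageMatrix-class].
#' @export
impute <- function(phased, referencePanel, targetSites,
                   params = hmmParams(), returnStrandProbs = FALSE) {
  refAll <- haplotypes(referencePanel)
  nPanelSites <- nSites(referencePanel)
  bad <- targetSites[targetSites < 1L | targetSites > nPanelSites]
  if (length(bad))
    stop("target sites absent from reference: ",
         paste(head(bad, 10), collapse = ", "))
  typed <- siteIndices(phased)
  ## the copying chain is Markov with a distance-compounding switch
  ## kernel, so sites that neither emit (untyped) nor need reporting can
  ## be dropped from the grid without changing any posterior
  grid <- sort(unique(c(typed, as.integer(targetSites))))
  S <- length(grid)
  N <- nSamples(phased)
  cm <- siteInfo(referencePanel)$cm[grid]
  h <- haplotypes(phased)
  typedPos <- match(typed, grid)
  targetPos <- match(targetSites, grid)

  ## conditioning subset per sample: closest reference haplotypes by
  ## dosage distance on typed sites
  Kimp <- min(nrow(refAll), 2L * params@nStates)
  Gd <- h$hap1 + h$hap2
  D <- dosageHapDistance(Gd, refAll[, typed, drop = FALSE])
  theta <- switchProb(cm, params@ne, Kimp)
  refGrid <- refAll[, grid, drop = FALSE]

  DS <- matrix(0, N, S)
  P1 <- if (returnStrandProbs) matrix(0, N, S) else NULL
  P2 <- if (returnStrandProbs) matrix(0, N, S) else NULL
  obs1 <- matrix(-1L, N, S); obs2 <- matrix(-1L, N, S)
  obs1[, typedPos] <- h$hap1; obs2[, typedPos] <- h$hap2
  for (i in seq_len(N)) {
    ord <- order(D[i, ], seq_len(ncol(D)))
    use <- ord[seq_len(Kimp)]
    Hc <- refGrid[use, , drop = FALSE]
    p1 <- cpp_haploid_posterior(obs1[i, ], Hc, theta, params@errorRate)
    p2 <- cpp_haploid_posterior(obs2[i, ], Hc, theta, params@errorRate)
    DS[i, ] <- p1 + p2
    if (returnStrandProbs) { P1[i, ] <- p1; P2[i, ] <- p2 }
  }
  ## observed genotyped sites pass through exactly
  genoTyped <- h$hap1 + h$hap2
  genoTyped[phased@imputed] <- NA_integer_
  for (j in seq_along(typedPos)) {
    ok <- !is.na(genoTyped[, j])
    DS[ok, typedPos[j]] <- genoTyped[ok, j]
  }
  DS <- DS[, targetPos, drop = FALSE]
  refMafAll <- colMeans(refAll)
  refMaf <- pmin(refMafAll, 1 - refMafAll)[targetSites]
  qual <- if (nrow(DS) >= 2L) apply(DS, 2L, dr2Quality) else
    rep(NA_real_, ncol(DS))
  out <- new("DosageMatrix", dosages = DS, dr2 = qual, refMaf = refMaf,
             siteIndices = as.integer(targetSites),
             sampleId = sampleInfo(phased)$id,
             provenance = paste0(provenance(phased), "|imputed"))
  if (returnStrandProbs) {
    attr(out, "strand1") <- P1[, targetPos, drop = FALSE]
    attr(out, "strand2") <- P2[, targetPos, drop = FALSE]
  }
  out
}

#' DR2-style imputation quality of a dosage vector
#'
#' Ratio of the observed dosage variance to the variance expected of hard
#' genotypes in Hardy-Weinberg proportions at the estimated frequency,
#' var(DS) / (2 p (1-p)) with p = mean(DS)/2, clipped to [0,1]. Constant
#' dosages give 0.
#'
#' @param ds numeric dosage vector (length >= 2).
#' @return quality in [0,1].
#' @export
dr2Quality <- function(ds) {
  if (length(ds) < 2L) stop("need >= 2 samples")
  p <- mean(ds) / 2
  denom <- 2 * p * (1 - p)
  if (denom <= 0) return(0)
  v <- var(ds) * (length(ds) - 1) / length(ds)
  min(max(v / denom, 0), 1)
}

#' Majority-vote consensus across phase estimates
#'
#' For each sample, heterozygous sites are walked in order; in each
#' inter-het interval every estimate votes "switch" or "no switch" relative
#' to the previous het site and the majority wins (ties keep the current
#' orientation). The first het site anchors the orientation by majority.
#' Estimates must agree on the genotypes themselves; sites an estimate
#' imputed differently abstain from voting.
#'
#' @param estimates list of >= 3 [PhasedHaplotypes-class] on identical
#'   samples and sites (an odd count is recommended).
#' @return A [PhasedHaplotypes-class].
#' @export
consensusHaplotypes <- function(estimates) {
  if (length(estimates) < 3L) stop("need >= 3 estimates")
  e1 <- estimates[[1]]
  N <- nSamples(e1); S <- nSites(e1)
  for (e in estimates[-1]) {
    if (!identical(siteIndices(e), siteIndices(e1)) ||
        !identical(sampleInfo(e)$id, sampleInfo(e1)$id))
      stop("estimates must cover identical samples and sites")
  }
  genos <- lapply(estimates, function(e) e@hap1 + e@hap2)
  observed <- Reduce(`&`, lapply(estimates, function(e) !e@imputed))
  for (e in seq_along(estimates)[-1]) {
    if (any(genos[[e]][observed] != genos[[1]][observed]))
      stop("estimates disagree on observed genotypes, not just phase")
  }
  ## per-site consensus genotype: majority (observed sites are unanimous)
  Gsum <- Reduce(`+`, lapply(seq_along(genos), function(k)
    matrix(as.numeric(genos[[k]]), N, S)))
  Gcons <- round(Gsum / length(genos))
  hap1 <- matrix(0L, N, S); hap2 <- matrix(0L, N, S)
  cert <- matrix(1, N, S)
  nE <- length(estimates)
  for (i in seq_len(N)) {
    g <- Gcons[i, ]
    hom <- g != 1
    hap1[i, hom] <- as.integer(g[hom] %/% 2)
    hap2[i, hom] <- as.integer(g[hom] %/% 2)
    hets <- which(g == 1)
    if (!length(hets)) next
    ## orientation per estimate at consensus-het sites (NA = abstain when
    ## that estimate's genotype at the site is not het)
    om <- vapply(estimates, function(e) as.numeric(e@hap1[i, hets]),
                 numeric(length(hets)))
    om <- matrix(om, nrow = length(hets))
    for (k in seq_len(nE)) om[genos[[k]][i, hets] != 1, k] <- NA
    first <- om[1, ]
    v1 <- sum(first == 1, na.rm = TRUE); v0 <- sum(first == 0, na.rm = TRUE)
    o <- as.integer(v1 >= v0)
    hap1[i, hets[1]] <- o; hap2[i, hets[1]] <- 1L - o
    if (length(hets) > 1) {
      for (t in seq_len(length(hets) - 1L)) {
        sw <- om[t, ] != om[t + 1, ]          # NA propagates = abstain
        nsw <- sum(sw, na.rm = TRUE); nst <- sum(!sw, na.rm = TRUE)
        if (nsw > nst) o <- 1L - o
        tot <- nsw + nst
        cert[i, hets[t + 1]] <- if (tot) max(nsw, nst) / tot else 0.5
        hap1[i, hets[t + 1]] <- o; hap2[i, hets[t + 1]] <- 1L - o
      }
    }
  }
  imputed <- !observed
  new("PhasedHaplotypes", hap1 = hap1, hap2 = hap2, certainty = cert,
      imputed = imputed, siteIndices = siteIndices(e1),
      sites = siteInfo(e1), samples = sampleInfo(e1),
      provenance = paste0(provenance(e1), "|consensus", nE))
}

#' Forward-backward genotype posteriors (diploid copying HMM)
#'
#' @param g genotype vector (0/1/2, NA missing) over the site grid of H.
#' @param H conditioning haplotypes, sites x states (or states x sites from
#'   a panel via t()).
#' @param theta per-interval switch probabilities (length nrow(H) - 1).
#' @param errorRate copying mismatch probability.
#' @return list(posterior = 3 x S matrix of P(true genotype), loglik).
#' @export
diploidPosterior <- function(g, H, theta, errorRate) {
  g <- as.integer(g); g[is.na(g)] <- -1L
  cpp_diploid_posterior(g, t(H), theta, errorRate)
}

#' Brute-force path-pair enumeration oracle
#'
#' Exhaustively sums over all pairs of copying paths to compute exact
#' genotype posteriors on tiny instances; used to validate the
#' forward-backward recursion.
#'
#' @param g genotype vector (0/1/2, NA missing).
#' @param H sites x states haplotype matrix; K^S must stay enumerable.
#' @param theta per-interval switch probabilities.
#' @param errorRate copying mismatch probability.
#' @return 3 x S matrix of exact genotype posteriors.
#' @export
bruteForcePosterior <- function(g, H, theta, errorRate) {
  S <- nrow(H); K <- ncol(H)
  if (K^S > 5000) stop("instance too large to enumerate")
  e <- errorRate
  ## all K^S copying paths
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), S)))[, , drop = FALSE]
  P <- nrow(paths)
  w <- rep(1 / K, P)
  if (S > 1) for (s in 2:S) {
    stay <- paths[, s] == paths[, s - 1]
    w <- w * ifelse(stay, 1 - theta[s - 1] + theta[s - 1] / K,
                    theta[s - 1] / K)
  }
  ## per-site per-path emitted-allele probabilities
  m <- sapply(seq_len(S), function(s) {
    h <- H[s, paths[, s]]
    (1 - e) * h + e * (1 - h)
  })
  m <- matrix(m, P, S)
  ## joint emission over all sites for every ordered path pair
  E <- matrix(1, P, P)
  for (s in seq_len(S)) {
    if (is.na(g[s])) next
    if (g[s] == 0) E <- E * outer(1 - m[, s], 1 - m[, s])
    else if (g[s] == 2) E <- E * outer(m[, s], m[, s])
    else E <- E * (outer(m[, s], 1 - m[, s]) + outer(1 - m[, s], m[, s]))
  }
  W <- outer(w, w) * E
  Z <- sum(W)
  post <- matrix(0, 3, S)
  for (s in seq_len(S)) {
    p0 <- sum(W * outer(1 - m[, s], 1 - m[, s]))
    p2 <- sum(W * outer(m[, s], m[, s]))
    p1 <- sum(W * (outer(m[, s], 1 - m[, s]) + outer(1 - m[, s], m[, s])))
    post[, s] <- c(p0, p1, p2) / Z
  }
  post
}
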