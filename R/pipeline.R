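## End-to-end experiment driver: simulate -> QC -> integrate -> phase ->
## impute -> evaluate -> PGS, with per-stage RNG streams derived from one
## master seed.

#' Stage-specific RNG seed
#'
#' Derives a deterministic per-stage seed from the master seed by hashing
#' the stage name, so adding stages never perturbs the draws of earlier
#' stages. Result is a positive integer below 2^31.
#'
#' @param master master seed (integer).
#' @param stage stage name.
#' @return integer seed.
#' @export
stageSeed <- function(master, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 1117) %% 2147483587
  as.integer((abs(master) %% 1048573 * 2039 + h) %% 2147483587 + 1)
}

#' Subset a panel to a set of haplotype rows
#'
#' @param panel a [HaplotypePanel-class].
#' @param rows haplotype row indices (even count).
#' @return A [HaplotypePanel-class] over the same sites.
#' @export
subsetHaplotypes <- function(panel, rows) {
  new("HaplotypePanel", sites = panel@sites,
      haplotypes = panel@haplotypes[rows, , drop = FALSE],
      popLabel = panel@popLabel[rows], founder = panel@founder[rows])
}

#' Truth genotypes of cohort samples at panel sites
#'
#' @param panel the truth [HaplotypePanel-class].
#' @param cohort a simulated [CohortDataset-class] (hapRow metadata).
#' @param sites panel site indices.
#' @return samples x sites integer matrix with site-id colnames.
#' @export
truthGenotypes <- function(panel, cohort, sites) {
  H <- haplotypes(panel)
  meta <- sampleInfo(cohort)
  G <- H[meta$hapRow1, sites, drop = FALSE] +
    H[meta$hapRow2, sites, drop = FALSE]
  colnames(G) <- siteInfo(panel)$id[sites]
  rownames(G) <- meta$id
  G
}

#' Desk-scale default run configuration
#'
#' One simulated chromosome of 2,000 sites; a reference panel of 400
#' haplotypes, 90 percent from the majority population; two cohorts of 600
#' and 400 samples genotyped on arrays of 840 and 1,510 sites sharing 400
#' (the marker-count ratios of a two-array biobank); six genotyping waves;
#' 40 dual-genotyped parent-offspring trios; 100 masked evaluation sites
#' that double as causal loci of an h2 = 0.5 quantitative trait.
#'
#' @param seed master seed.
#' @return named list of configuration values; fields can be overridden
#'   before passing to [runAll()].
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(seed = as.integer(seed),
       nSites = 2000L, nHaplotypes = 2700L, mapLengthCm = 100,
       mutationRate = 1e-4, nGenerations = 14L, nFounders = 2000L,
       popModel = populationModel(2L, fst = c(0.01, 0.1)),
       popWeights = c(0.87, 0.13),
       refSize = 400L, refMajorityFrac = 0.9,
       arraySizeA = 840L, arraySizeB = 1510L, arrayOverlap = 400L,
       nA = 600L, nB = 400L, waves = 6L,
       missingRates = c(0.002, 0.003, 0.004, 0.005, 0.006, 0.01),
       genoError = 1e-3,
       popMix = c(pop1 = 0.8, pop2 = 0.1, `pop1+pop2` = 0.1),
       nTrios = 40L, maskK = 100L, h2 = 0.5,
       nStates = c(small = 40L, large = 80L),
       ne = 100, hmmError = 0.003, nIterations = 2L,
       dr2Thresholds = c(0, 0.5, 0.9),
       thresholds = qcThresholds())
}

phaseMaybeConsensus <- function(cohort, refPanel, params, consensus) {
  if (!consensus) return(phase(cohort, refPanel, params))
  est <- lapply(1:3, function(k)
    phase(cohort, refPanel,
          initialize(params, seed = params@seed + k)))
  consensusHaplotypes(est)
}

subsetDosageRows <- function(dos, ids) {
  rows <- match(ids, dos@sampleId)
  initialize(dos, dosages = dos@dosages[rows, , drop = FALSE],
             sampleId = dos@sampleId[rows])
}

#' Run the full benchmarking pipeline
#'
#' Generates the synthetic biobank, applies the QC battery, builds the
#' four data-integration protocols, phases and imputes each with the
#' copying engine, and scores trio switch error rates, masked-site
#' imputation r2 (overall, by MAF bin, by ancestry group), array-membership
#' lambda_GC across DR2 thresholds, and the PGS attenuation arms.
#'
#' @param config list from [defaultRunConfig()].
#' @param outDir optional directory for TSV/VCF artifacts.
#' @param setting engine setting name ("small" or "large").
#' @param consensus use a consensus of three engine runs per protocol.
#' @return list with the [EvalReport-class] ("report") and all
#'   intermediate objects ("details").
#' @export
runAll <- function(config = defaultRunConfig(), outDir = NULL,
                   setting = "small", consensus = FALSE) {
  seed <- config$seed
  panel <- simulatePanel(config$popModel, config$nSites, config$nHaplotypes,
                         config$mapLengthCm, config$mutationRate,
                         config$nGenerations, stageSeed(seed, "panel"),
                         config$popWeights, config$nFounders)
  lab <- popLabels(panel)
  nMaj <- round(config$refSize * config$refMajorityFrac)
  refRows <- c(which(lab == "pop1")[seq_len(nMaj)],
               which(lab == "pop2")[seq_len(config$refSize - nMaj)])
  refPanel <- subsetHaplotypes(panel, refRows)

  designs <- makeArrayDesigns(panel, config$arraySizeA, config$arraySizeB,
                              config$arrayOverlap,
                              stageSeed(seed, "designs"),
                              names = c("arrayA", "arrayB"))
  cohortA <- genotypeCohort(panel, designs[[1]], config$nA, config$popMix,
                            config$waves, config$missingRates,
                            config$genoError, stageSeed(seed, "cohortA"),
                            usedRows = refRows, idPrefix = "A")
  usedA <- c(refRows, sampleInfo(cohortA)$hapRow1,
             sampleInfo(cohortA)$hapRow2)
  cohortB <- genotypeCohort(panel, designs[[2]], config$nB, config$popMix,
                            config$waves, config$missingRates,
                            config$genoError, stageSeed(seed, "cohortB"),
                            usedRows = usedA, idPrefix = "B")
  usedAB <- c(usedA, sampleInfo(cohortB)$hapRow1,
              sampleInfo(cohortB)$hapRow2)
  trios <- makeTrios(panel, config$nTrios, designs, config$mapLengthCm,
                     stageSeed(seed, "trios"), usedRows = usedAB)

  ## --- QC ---------------------------------------------------------------
  thr <- config$thresholds
  qcA <- snpQCPipeline(cohortA, thr)
  qcB <- snpQCPipeline(cohortB, thr)
  cohortA <- qcA$cohort; cohortB <- qcB$cohort
  smA <- sampleMissingnessFilter(cohortA, thr$sampleMissingMax)
  smB <- sampleMissingnessFilter(cohortB, thr$sampleMissingMax)
  cohortA <- dropSamples(cohortA, excludedSamples(smA))
  cohortB <- dropSamples(cohortB, excludedSamples(smB))
  dupRel <- duplicateRelatednessFilter(list(cohortA, cohortB),
                                       thr$kinshipMax, thr$duplicateKinship)
  cohortA <- dropSamples(cohortA, excludedSamples(dupRel))
  cohortB <- dropSamples(cohortB, excludedSamples(dupRel))

  shared <- intersect(siteIndices(cohortA), siteIndices(cohortB))
  Gcomb <- rbind(genotypes(cohortA)[, match(shared, siteIndices(cohortA)),
                                    drop = FALSE],
                 genotypes(cohortB)[, match(shared, siteIndices(cohortB)),
                                    drop = FALSE])
  metaComb <- rbind(sampleInfo(cohortA), sampleInfo(cohortB))
  pca <- genoPCA(Gcomb, 10L)
  rownames(pca$scores) <- metaComb$id
  homIds <- homogeneousSubset(pca$scores,
                              metaComb$id[metaComb$pop == "pop1"],
                              thr$mahalanobisP)
  ## GWAS/PGS relatedness pruning acts within each cohort's analysis
  ## subset; cross-cohort kinship rests on the small shared-marker set and
  ## is used for duplicate detection only
  relPairs <- qcStats(dupRel)[qcStats(dupRel)$type == "related" &
                                !qcStats(dupRel)$crossCohort, ,
                              drop = FALSE]
  gwasExclude <- pruneRelated(relPairs, within = homIds)
  hetA <- ancestryAdjustedHeterozygosity(
    cohortA, pca$scores[seq_len(nSamples(cohortA)), , drop = FALSE],
    sdThreshold = thr$hetSd)
  hetB <- ancestryAdjustedHeterozygosity(
    cohortB, pca$scores[nSamples(cohortA) + seq_len(nSamples(cohortB)), ,
                        drop = FALSE], sdThreshold = thr$hetSd)
  cohortA <- dropSamples(cohortA, excludedSamples(hetA))
  cohortB <- dropSamples(cohortB, excludedSamples(hetB))

  ## --- mask, phenotype, protocols ---------------------------------------
  mk <- maskSnps(cohortA, cohortB, config$maskK, panel,
                 stageSeed(seed, "mask"))
  mask <- mk$mask; cohortA <- mk$cohortA; cohortB <- mk$cohortB
  pheno <- simulatePhenotype(list(cohortA, cohortB), panel,
                             siteIndices(mask), config$h2,
                             stageSeed(seed, "pheno"))
  trioAssign <- chooseTrioArrays(trios, stageSeed(seed, "trioassign"))
  sep <- buildSeparate(cohortA, cohortB, trios, mask, panel)
  inter <- buildIntersection(cohortA, cohortB, trios, trioAssign, mask,
                             panel)
  uni <- buildUnion(cohortA, cohortB, trios, trioAssign, mask, panel)

  ## --- phase and impute --------------------------------------------------
  K <- config$nStates[[setting]]
  par0 <- hmmParams(K, config$ne, config$hmmError, config$nIterations, 1L)
  parFor <- function(tag) initialize(par0, seed = stageSeed(seed, tag))
  phSepA <- phaseMaybeConsensus(sep$A, refPanel, parFor("phase-sepA"),
                                consensus)
  phSepB <- phaseMaybeConsensus(sep$B, refPanel, parFor("phase-sepB"),
                                consensus)
  phInter <- phaseMaybeConsensus(inter, refPanel, parFor("phase-inter"),
                                 consensus)
  phUnion <- phaseMaybeConsensus(uni, refPanel, parFor("phase-union"),
                                 consensus)
  nmA <- names(trios@designs)[1]
  ts <- buildTwoStage(phSepA, phSepB, refPanel, parFor("twostage-impute"),
                      dropIdsA = trios@trioIds[trioAssign != nmA],
                      dropIdsB = trios@trioIds[trioAssign == nmA])
  phTS <- phaseMaybeConsensus(ts, refPanel, parFor("phase-twostage"),
                              consensus)
  tsSplit <- splitBack(phTS, sep$A, sep$B)   # trio offspring stay with
                                             # their assigned side

  mSites <- siteIndices(mask)
  imp <- function(ph, tag) impute(ph, refPanel, mSites, parFor(tag))
  idsA <- sampleInfo(cohortA)$id; idsB <- sampleInfo(cohortB)$id
  dosSep <- list(A = subsetDosageRows(imp(phSepA, "imp-sepA"), idsA),
                 B = subsetDosageRows(imp(phSepB, "imp-sepB"), idsB))
  dInter <- imp(phInter, "imp-inter")
  dosInter <- list(A = subsetDosageRows(dInter, idsA),
                   B = subsetDosageRows(dInter, idsB))
  dUnion <- imp(phUnion, "imp-union")
  dosUnion <- list(A = subsetDosageRows(dUnion, idsA),
                   B = subsetDosageRows(dUnion, idsB))
  dosTS <- list(A = subsetDosageRows(imp(tsSplit$A, "imp-tsA"), idsA),
                B = subsetDosageRows(imp(tsSplit$B, "imp-tsB"), idsB))
  dosByProtocol <- list(separate = dosSep, intersection = dosInter,
                        union = dosUnion, two_stage = dosTS)

  ## --- evaluation ---------------------------------------------------------
  scoreSites <- setdiff(intersect(siteIndices(cohortA),
                                  siteIndices(cohortB)), mSites)
  truthPhase <- trioResolvePhase(trios, scoreSites)
  blocks <- cmBlocks(siteInfo(panel)$cm[scoreSites], 4L)
  serOf <- function(ph, ids = trios@trioIds)
    switchErrorRate(ph, truthPhase, ids, blocks)
  combineSer <- function(a, b) {
    poss <- a$nPossible + b$nPossible
    list(ser = if (poss) (a$nSwitch + b$nSwitch) / poss else NA_real_,
         nSwitch = a$nSwitch + b$nSwitch, nPossible = poss,
         perBlock = NULL)
  }
  serSepA <- serOf(phSepA); serSepB <- serOf(phSepB)
  serInter <- serOf(phInter); serUnion <- serOf(phUnion)
  idsTsA <- trios@trioIds[trioAssign == nmA]
  idsTsB <- trios@trioIds[trioAssign != nmA]
  serTS <- combineSer(
    if (length(idsTsA)) switchErrorRate(tsSplit$A, truthPhase, idsTsA)
    else list(ser = NA, nSwitch = 0L, nPossible = 0L),
    if (length(idsTsB)) switchErrorRate(tsSplit$B, truthPhase, idsTsB)
    else list(ser = NA, nSwitch = 0L, nPossible = 0L))
  sers <- list(separate_A = serSepA, separate_B = serSepB,
               intersection = serInter, union = serUnion,
               two_stage = serTS)

  truthA <- truthGenotypes(panel, cohortA, mSites)
  truthB <- truthGenotypes(panel, cohortB, mSites)
  pops <- c(sampleInfo(cohortA)$pop, sampleInfo(cohortB)$pop)
  stackDos <- function(d) rbind(dosages(d$A), dosages(d$B))
  r2tab <- do.call(rbind, lapply(names(dosByProtocol), function(pn) {
    d <- dosByProtocol[[pn]]
    dm <- initialize(d$A, dosages = stackDos(d),
                     sampleId = c(d$A@sampleId, d$B@sampleId))
    tab <- imputationR2ByMaf(dm, rbind(truthA, truthB))
    tab$protocol <- pn
    tab
  }))
  dSep <- dosByProtocol$separate
  dmSep <- initialize(dSep$A, dosages = stackDos(dSep),
                      sampleId = c(dSep$A@sampleId, dSep$B@sampleId))
  r2group <- imputationR2ByMaf(dmSep, rbind(truthA, truthB),
                               groupLabels = pops)
  r2group$protocol <- "separate"

  ## homogeneous unrelated samples for the membership scan; simulated
  ## case labels are genotype-independent, so unlike a real register-based
  ## cohort there is no confounding reason to drop cases here
  ctrlA <- idsA[idsA %in% homIds & !(idsA %in% gwasExclude)]
  ctrlB <- idsB[idsB %in% homIds & !(idsB %in% gwasExclude)]
  lamTab <- do.call(rbind, lapply(names(dosByProtocol), function(pn) {
    d <- dosByProtocol[[pn]]
    tab <- arrayMembershipScan(
      truthA[match(ctrlA, idsA), , drop = FALSE],
      truthB[match(ctrlB, idsB), , drop = FALSE],
      subsetDosageRows(d$A, ctrlA), subsetDosageRows(d$B, ctrlB),
      config$dr2Thresholds)
    tab$protocol <- pn
    tab
  }))

  ## PGS arms on homogeneous unrelated samples
  pgsA <- idsA[idsA %in% homIds & !(idsA %in% gwasExclude)]
  pgsB <- idsB[idsB %in% homIds & !(idsB %in% gwasExclude)]
  covOf <- function(co, ids) {
    meta <- sampleInfo(co)[match(ids, sampleInfo(co)$id), ]
    cv <- data.frame(age = meta$age, sex = as.integer(meta$sex == "M"))
    cbind(cv, as.data.frame(pca$scores[match(ids, metaComb$id), ,
                                       drop = FALSE]))
  }
  yOf <- function(ids) pheno@y[match(ids, pheno@sampleId)]
  dosPgs <- lapply(dosByProtocol, function(d) {
    dA <- dosages(subsetDosageRows(d$A, pgsA))
    dB <- dosages(subsetDosageRows(d$B, pgsB))
    colnames(dA) <- colnames(dB) <- colnames(truthA)
    list(A = dA, B = dB)
  })
  pgs <- runPgsArms(truthA[match(pgsA, idsA), , drop = FALSE],
                    truthB[match(pgsB, idsB), , drop = FALSE],
                    dosPgs, yOf(pgsA), yOf(pgsB),
                    covOf(cohortA, pgsA), covOf(cohortB, pgsB),
                    pgsA, pgsB)

  ## --- consolidated report -------------------------------------------------
  rows <- list()
  addRow <- function(metric, stratum, value, n = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(
      protocol = sub("_[AB]$", "", stratum), setting = setting,
      metric = metric, stratum = stratum, value = value, n = n)
  for (nm in names(sers))
    addRow("ser", nm, sers[[nm]]$ser, sers[[nm]]$nPossible)
  for (i in seq_len(nrow(r2tab)))
    addRow("r2", paste0(r2tab$protocol[i], ":", r2tab$bin[i]),
           r2tab$r2[i], r2tab$n[i])
  for (i in seq_len(nrow(r2group)))
    addRow("r2_group", paste0("separate:", r2group$group[i], ":",
                              r2group$bin[i]),
           r2group$r2[i], r2group$n[i])
  for (i in seq_len(nrow(lamTab)))
    addRow("lambda", paste0(lamTab$protocol[i], ":", lamTab$arm[i], ":",
                            lamTab$threshold[i]),
           lamTab$lambda[i], lamTab$nSnps[i])
  ptab <- reportTable(pgs)
  for (i in seq_len(nrow(ptab)))
    addRow(paste0("pgs_", ptab$metric[i]),
           paste0(ptab$protocol[i], ":", ptab$direction[i], ":",
                  ptab$arm[i]), ptab$value[i])
  report <- new("EvalReport", table = do.call(rbind, rows),
                details = list(sers = sers, r2 = r2tab, r2group = r2group,
                               lambda = lamTab, pgs = pgs,
                               manifest = protocolManifest(
                                 list(separate_A = sep$A, separate_B = sep$B,
                                      intersection = inter, union = uni,
                                      two_stage = ts)),
                               qcReports = list(A = qcA$reports,
                                                B = qcB$reports)))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) write.table(
      x, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(reportTable(report), "eval_report.tsv")
    wt(report@details$manifest, "protocol_manifest.tsv")
    wt(reportTable(pgs), "pgs_results.tsv")
    wt(lamTab, "lambda_gc.tsv")
    wt(r2tab, "imputation_r2.tsv")
  }

  list(report = report,
       details = list(panel = panel, refPanel = refPanel, designs = designs,
                      cohortA = cohortA, cohortB = cohortB, trios = trios,
                      mask = mask, pheno = pheno, pca = pca,
                      homIds = homIds, protocols = list(
                        separate = sep, intersection = inter, union = uni,
                        two_stage = ts),
                      phased = list(separate_A = phSepA, separate_B = phSepB,
                                    intersection = phInter, union = phUnion,
                                    two_stage = phTS, tsSplit = tsSplit),
                      dosages = dosByProtocol, truth = list(A = truthA,
                                                            B = truthB),
                      pgs = pgs, analysisIds = list(
                        pgsA = pgsA, pgsB = pgsB, ctrlA = ctrlA,
                        ctrlB = ctrlB, gwasExclude = gwasExclude)))
}
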