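# GenoPhase

Biobanks are rarely genotyped in one batch on one array. When two cohorts
arrive on different genotyping arrays with only partial marker overlap,
the analyst must decide how to integrate them before haplotype phasing
and whole-genome imputation: phase and impute each cohort **separately**,
merge at the **intersection** of the marker sets, merge at the **union**
(accepting structural missingness), or run a **two-stage** scheme that
imputes each cohort to the union, merges without missingness, re-phases
jointly, and splits back. The choice propagates into everything
downstream: trio-measured switch error rates (SER), masked-SNP imputation
accuracy (r² between true genotypes and imputed dosages by minor-allele
frequency bin and by ancestry group), batch artifacts measurable as
genomic-control inflation (λ_GC = median χ²/0.4549) in array-membership
association scans, and the variance explained and rank stability of
polygenic scores (PGS).

GenoPhase implements that whole evaluation as a reusable, fully seeded R
package, driven by a synthetic-biobank generator with exact ground truth:

* **simulation** — a haplotype panel with Balding–Nichols population
  structure and copying-process LD; array manifests with partial overlap;
  cohorts with genotyping waves, error and missingness; dual-genotyped
  parent–offspring trios; admixed samples; a heritable quantitative trait
  (h² = 0.5) with masked causal SNPs;
* **QC** — missingness filters, differential-missingness and
  Hardy–Weinberg tests under BH-FDR, an order-statistic minimum-p
  batch-artifact FDR, MAF censoring, ancestry-adjusted heterozygosity,
  Mahalanobis homogeneous-subset selection, and a kinship proxy with
  duplicate/relatedness handling;
* **integration** — the four protocols plus masked-SNP bookkeeping;
* **engine** — a desk-scale Li–Stephens haplotype-copying HMM (Rcpp) for
  iterative phasing with missing-data handling, reference-based dosage
  imputation (DS = p(RA) + 2·p(AA)) with a MaCH-Rsq-style DR2 quality
  metric, consensus voting, and a brute-force enumeration oracle;
* **evaluation** — trio-resolved SER, r² by MAF bin and ancestry group,
  λ_GC across DR2 thresholds, and the PGS error-localization experiment
  (imputation error in the discovery GWAS versus in the scored
  genotypes), with percentile rank concordance and top-5% overlap.

The core model is the Li & Stephens mosaic: a haplotype is copied from K
conditioning haplotypes with switch probability 1 − exp(−0.04·ne·Δcm/K)
per map interval and per-site copy error λ; phasing decodes the diploid
pair HMM, imputation the haploid HMM against a reference panel.

## Worked example

```r
library(GenoPhase)

model <- populationModel(2, fst = c(0.01, 0.1))
panel <- simulatePanel(model, nSites = 600, nHaplotypes = 1200,
                       mapLengthCm = 60, nGenerations = 10,
                       seed = 7, popWeights = c(0.8, 0.2), nFounders = 400)
designs <- makeArrayDesigns(panel, sizeA = 250, sizeB = 400,
                            overlapCount = 120, seed = 7)
ref <- subsetHaplotypes(panel, 1:200)
cohort <- genotypeCohort(panel, designs[[1]], nSamples = 150,
                         popMix = c(pop1 = 0.9, pop2 = 0.1),
                         waves = 3, perWaveMissingRate = 0.01,
                         errorRate = 1e-3, seed = 7, usedRows = 1:200)
cohort
#> CohortDataset [genotyped:arrayA]: 150 samples x 250 sites, 0.96% missing

phased <- phase(cohort, ref, hmmParams(nStates = 40, seed = 1))
masked <- setdiff(seq_len(600), siteIndices(cohort))[1:50]
dosage <- impute(phased, ref, masked, hmmParams(nStates = 40))
dosage
#> DosageMatrix [genotyped:arrayA|phased|imputed]: 150 samples x 50 sites,
#>   median DR2 = 0.867

truth <- truthGenotypes(panel, cohort, masked)
cor(as.numeric(truth), as.numeric(dosages(dosage)))^2
#> [1] 0.8143522
```

The r² of ~0.81 says that at these desk-scale settings the engine
recovers most of the variance of the held-out genotypes from the phased
scaffold plus the reference panel; `imputationR2ByMaf()` breaks the same
quantity down by reference MAF bin, where rare bins are visibly harder.

The full experiment — simulate, QC, build all four protocols, phase,
impute, and score everything — is one call:

```r
res <- runAll(defaultRunConfig(seed = 1))
head(reportTable(res$report))
```

A thin command-line wrapper is provided in
`inst/scripts/genophase-cli.R` (subcommands `simulate`, `qc`, `run-all`).

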