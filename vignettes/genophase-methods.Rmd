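---
title: "GenoPhase: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GenoPhase: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

GenoPhase evaluates how the way two genotyping-array cohorts are combined
— separately, at the intersection of their markers, at the union, or by a
two-stage impute-merge-rephase scheme — affects haplotype phasing,
whole-genome imputation, and the analyses built on top of them
(association scans and polygenic scores). Because real biobank genotypes
of this kind are access-restricted, every experiment in the package runs
on a synthetic biobank whose ground truth is known exactly. This vignette
explains the models, the tunable parameters and their defaults, what the
generator does and does not emulate, and the design decisions taken where
the design was genuinely open.

## The synthetic biobank

**Haplotype panel.** A single chromosome of `nSites` biallelic SNPs is
simulated with a two-layer model. Allele frequencies follow a
Balding–Nichols draw: an ancestral frequency per site (uniform on
[0.05, 0.95] by default) and, for each population, a Beta draw with
variance governed by that population's Fst. Linkage disequilibrium is then
induced by a generational copying process: a constant-size ancestral
population of `nFounders` haplotypes per population is bred for
`nGenerations` generations, each new haplotype being a recombinant mosaic
of two haplotypes of the previous generation (crossover count Poisson in
the map length in Morgans) with symmetric per-site mutation; the final
generation produces the requested number of panel haplotypes. Consecutive
haplotype pairs form diploid individuals, so every simulated sample has
known truth phase. Admixed individuals instead pair one gamete from each
of two populations.

The defaults (2,000 sites on a 100 cM map, 14 generations,
`nFounders = 2000`) were chosen to balance two desiderata that pull in
opposite directions at desk scale. A deep, narrow genealogy maximizes
haplotype sharing — which is what copying-model phasing exploits — but
makes an unrealistically large fraction of cohort pairs close relatives, so that a
literal kinship-based relatedness prune would discard most of the sample.
A constant ancestral population of 2,000 haplotypes keeps the fraction of
sample pairs above the third-degree kinship cutoff (0.0825) at a few per
mil to a fraction of a percent, while leaving enough segment sharing with
a 400-haplotype reference panel for phasing and imputation to be
informative (masked-site dosage r² roughly 0.4–0.95 across protocols
and frequency bins). This is deliberately worse than production tools
achieve on real panels; the package's claims are about *orderings* across
integration protocols, not absolute accuracy.

**Arrays, cohorts, waves, trios.** Two array manifests of 840 and 1,510
sites share 400 (preserving the ~251k/450k/117k marker-count ratios of a
real two-array biobank). Cohorts of 600 and 400 individuals are genotyped
with per-allele error (10⁻³) and wave-specific missingness across six
waves; 40 parent–offspring trios, disjoint from both cohorts, are
genotyped on both arrays and their transmitted haplotypes retained. A
quantitative trait with h² = 0.5 uses the 100 masked evaluation SNPs as
causal loci with standard-normal effects on standardized genotypes;
environmental noise is scaled against the empirical genetic variance so
the heritability holds in expectation.

**What the generator does not emulate.** Genotype-intensity-level
artifacts, strand ambiguity, indels and CNVs, sex chromosomes, realistic
human demographic history, and the sheer marker density of real arrays.
Passing tests therefore demonstrate that the pipeline's statistics behave
correctly and that the qualitative protocol orderings emerge under the
stated generative model — not that any number matches a particular real
cohort.

## Quality control

The SNP-level battery applies, in order: per-wave and merged missingness
(strict > 5%), differential case/control missingness (2×2 Pearson
chi-square without continuity correction, Benjamini–Hochberg FDR ≤ 0.2),
Hardy–Weinberg equilibrium in controls (1-df chi-square; monomorphic sites
are defined to have p = 1), the batch-artifact scan, and minor-allele
frequency censoring (strict < 0.001). Filters are idempotent on their
survivors, and per-site results are invariant to site order.

The batch-artifact scan tests each wave against all others with an
allele-count chi-square and keeps the per-site minimum p across waves.
Minimums of m uniforms have CDF 1 − (1 − y)^m, so the expected number of
sites with minimum p below a threshold is nSnps · (1 − (1 − p)^nBatches);
the empirical-FDR adjustment divides this by the observed count
#{minp ≤ p} (the ≤ convention keeps the ratio defined at the smallest
observed minimum; a site with p = 0 still adjusts to 0 through the zero
numerator). Theoretical QQ quantiles 1 − (1 − i/n)^(1/nBatches) are
emitted for diagnostics. The two roles played by the batch count and the
site count are kept as separate parameters throughout.

Sample-level QC computes observed heterozygosity, its ancestry adjustment
(residual of a regression on the first four principal components, their
squares, and all pairwise products), and residuals of both against runs of
homozygosity (sum of homozygous stretches of ≥ 25 consecutive sites — a
desk-scale stand-in for ROH callers whose defaults assume dense data).
A sample is flagged only when all four quantities sit more than 4 SD from
their means; the disjunctive reading is available behind a flag. Ancestry
outliers are removed by the Mahalanobis rule: using anchor samples of
known majority origin, a sample is excluded when the chi-square(10)
upper-tail probability of its squared distance falls below 5.73×10⁻⁷.

Relatedness uses a standardized genotype-covariance proxy (expected ~0.5
for duplicates, ~0.25 for parent–offspring, ~0 for unrelated pairs).
Within-cohort pairs are scored on the cohort's full QC-passed marker set;
cross-cohort pairs can only be scored on the shared markers, whose small
number makes the estimator too noisy to detect third-degree relatedness —
so cross-cohort kinship is used for duplicate detection only, and the
GWAS/PGS relatedness prune (kinship ≥ 0.0825, minimal greedy removal)
acts within cohorts. This is stated prominently because it is the main
place where desk scale forces a departure from a literal reading of the
full-scale procedure.

## The copying engine

Phasing and imputation share one Li–Stephens haplotype-copying HMM. States
are conditioning haplotypes; the switch probability over a map interval of
d cM is 1 − exp(−0.04 · ne · d / K) with K the conditioning-set size and
`ne` an effective-population-size scale (default 100, matched to the
shallow simulated genealogy); emissions flip the copied allele with
probability `errorRate` (default 0.003). Forward values are rescaled per
site; genotype posteriors agree with brute-force path-pair enumeration to
10⁻¹⁰ on enumerable instances, which is the package's core numerical
guarantee.

Phasing is iterative conditional estimation: random genotype-consistent
initialization, then sweeps in which each sample's diplotype is re-decoded
by the diploid HMM conditioned on the `nStates` Hamming-closest
haplotypes among the reference panel and the other samples' current
estimates (first sweep: reference only; later sweeps update estimates in
place). The update is the jointly most probable copying-state pair path.
Single-site orientation posteriors of the pair HMM are label-symmetric —
exactly ½ by symmetry — so per-site "posterior argmax" phasing is
undefined; the Viterbi path supplies the orientation instead, with
emission-ambiguous heterozygous sites inheriting the previous orientation
rather than breaking the segment. Missing genotypes are filled with the
path's copied alleles, flagged, and never overwrite observed calls —
which is precisely the mechanism through which the union protocol's
structural missingness propagates into cohort-specific artifacts.

Imputation runs each phased haplotype through the haploid HMM against the
reference (conditioning on the 2·`nStates` closest reference haplotypes)
and combines the two allele posteriors into DS = p(RA) + 2·p(AA).
Because the switch kernel compounds exactly over map distance, the chain
is evaluated only at typed and target sites. Observed genotyped sites pass
through with DS equal to the call. Per-site quality is the
estimated-vs-expected dosage-variance ratio var(DS)/(2p̂(1−p̂)) clipped to
[0, 1] — the MaCH-Rsq form of the DR2 metric. Engine settings
`small`/`large` (40/80 states) preserve the default-vs-high-resolution
contrast of production tools; a consensus mode majority-votes the
switch/no-switch decision of three runs in each inter-heterozygote
interval.

## Evaluation

Trio offspring phase is resolved by Mendelian transmission (forced when at
least one parent is homozygous; triple-heterozygous sites unresolvable;
inconsistent sites dropped and counted). The switch error rate counts
adjacent resolvable-heterozygote pairs whose relative orientation
disagrees with the trio truth, divided by the total possible switches,
and is invariant to global relabeling. A per-region breakdown over
equal-cM blocks relates SER to SNP density per centimorgan.

Imputation r² pools (sample, site) pairs within reference-MAF bins
(pooling is stable in rare bins; a per-SNP-averaged mode exists). Bins
with zero truth variance are reported as missing, never as 0. The
array-membership scan regresses cohort membership on truth or imputed
values per masked site (1-df allele-dosage trend chi-square) across four
arms, and reports λ_GC = median χ² / 0.4549 per DR2 threshold, with
thresholds applied to each arm's imputed side(s). The scan runs on all
homogeneous unrelated samples rather than controls only: simulated
case/control labels are independent of genotype by construction, so a
control restriction — which in a register-based cohort guards against
genuine case-enrichment in allele frequencies — would here only halve the
sample behind each median.

The PGS experiment runs a cross-cohort GWAS at the masked SNPs (OLS with
age, sex and ten principal components; constant or collinear predictors
flagged rather than estimated), scores the opposite cohort by
Σᵢ βᵢ·Xᵢⱼ, and reports the incremental variance explained — R² of
covariates + PGS minus R² of covariates alone. The nested comparison is
the default because the literal two-model contrast found in some
descriptions (PGS-only versus PGS + covariates) can produce negative
"explained variance"; the literal mode is available behind a flag.
Percentiles are assigned by rank with stable id-order tie-breaking; the
top-5% overlap is the share of the truth-score top tail recovered by the
imputed-score ranking.

## Numerical and design choices

* Coordinates are 0/1-based per context: internal site indices are 1-based
  panel positions; VCF output is 1-based with the internal index carried
  in an INFO tag so round trips are exact. DS is written with 4-decimal
  fixed precision.
* Strict ">" comparators are used wherever the full-scale procedure mixes
  ">" and "≥" for missingness bounds; comparators are exposed as
  arguments.
* The χ²(1) median is fixed at 0.4549 for reproducibility of λ_GC.
* All randomness derives from one master seed through per-stage hashes,
  so adding a stage never perturbs earlier stages and the entire pipeline
  is byte-reproducible.
* Stage-1 genotypes of the two-stage protocol are hard-called as the most
  probable genotype from the strand posteriors; observed calls always
  survive the merge.
* Desk-scale problem sizes used by the bundled experiments: the default
  configuration above for the headline orderings (10 seeds), and a
  reduced 500-site configuration for determinism checks.

## Known limitations

Absolute accuracies are far from production values (the engine phases a
few hundred samples against a 400-haplotype reference on 2,000 sites).
The accuracy gradient across frequency bins can even invert relative to
full-scale behavior: with limited haplotype sharing, pooled r² at rare
sites is dominated by carrier detection (relatively easy), while common
sites lose the most to scaffold uncertainty — at full scale the opposite
holds. Protocol *orderings* within each bin are unaffected, which is why
the package's claims are phrased that way.
Two full-scale phenomena reproduce only weakly or not at all at this
scale: the residual inflation of mixed genotyped-vs-imputed association
arms after strict DR2 filtering rests on a median over the few dozen
sites that survive the filter, and is therefore volatile per seed; and
the two-stage protocol inherits stage-1 hard-call errors that a
full-scale imputation would not make, so its phasing advantage is smaller
here than in real data. Both are discussed where the corresponding checks
are made.
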