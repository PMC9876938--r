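## Accessors and show methods. Slot access outside the package should go
## through these.

#' @describeIn HaplotypePanel-class number of sites
#' @param x object
#' @export
setMethod("nSites", "HaplotypePanel", function(x) nrow(x@sites))
#' @export
setMethod("nSites", "CohortDataset", function(x) ncol(x@genotypes))
#' @export
setMethod("nSites", "ArrayDesign", function(x) length(x@siteIndices))
#' @export
setMethod("nSites", "PhasedHaplotypes", function(x) ncol(x@hap1))
#' @export
setMethod("nSites", "DosageMatrix", function(x) ncol(x@dosages))

#' @export
setMethod("nHaplotypes", "HaplotypePanel", function(x) nrow(x@haplotypes))

#' @export
setMethod("nSamples", "CohortDataset", function(x) nrow(x@genotypes))
#' @export
setMethod("nSamples", "PhasedHaplotypes", function(x) nrow(x@hap1))
#' @export
setMethod("nSamples", "DosageMatrix", function(x) nrow(x@dosages))
#' @export
setMethod("nSamples", "PhenotypeSet", function(x) length(x@sampleId))
#' @export
setMethod("nSamples", "TrioSet", function(x) length(x@trioIds))

#' @export
setMethod("siteInfo", "HaplotypePanel", function(x) x@sites)
#' @export
setMethod("siteInfo", "CohortDataset", function(x) x@sites)
#' @export
setMethod("siteInfo", "PhasedHaplotypes", function(x) x@sites)

#' @export
setMethod("siteIndices", "ArrayDesign", function(x) x@siteIndices)
#' @export
setMethod("siteIndices", "CohortDataset", function(x) x@siteIndices)
#' @export
setMethod("siteIndices", "PhasedHaplotypes", function(x) x@siteIndices)
#' @export
setMethod("siteIndices", "DosageMatrix", function(x) x@siteIndices)
#' @export
setMethod("siteIndices", "MaskSet", function(x) x@siteIndices)

#' @export
setMethod("sampleInfo", "CohortDataset", function(x) x@samples)
#' @export
setMethod("sampleInfo", "PhasedHaplotypes", function(x) x@samples)

#' @export
setMethod("genotypes", "CohortDataset", function(x) x@genotypes)

#' @export
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)
#' @export
setMethod("haplotypes", "PhasedHaplotypes",
          function(x) list(hap1 = x@hap1, hap2 = x@hap2))

#' @export
setMethod("popLabels", "HaplotypePanel", function(x) x@popLabel)

#' @export
setMethod("dosages", "DosageMatrix", function(x) x@dosages)

#' @export
setMethod("dr2", "DosageMatrix", function(x) x@dr2)

#' @export
setMethod("provenance", "CohortDataset", function(x) x@provenance)
#' @export
setMethod("provenance", "PhasedHaplotypes", function(x) x@provenance)
#' @export
setMethod("provenance", "DosageMatrix", function(x) x@provenance)

#' @export
setMethod("excludedSites", "QCReport", function(x) x@excludedSites)
#' @export
setMethod("excludedSamples", "QCReport", function(x) x@excludedSamples)
#' @export
setMethod("qcStats", "QCReport", function(x) x@stats)

#' @export
setMethod("reportTable", "EvalReport", function(x) x@table)
#' @export
setMethod("reportTable", "PgsExperimentResult", function(x) x@table)
#' @export
setMethod("reportTable", "GwasResult", function(x) x@table)

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", nrow(object@haplotypes), "haplotypes x",
      nrow(object@sites), "sites\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(table(object@popLabel)),
                    table(object@popLabel)), collapse = ", "), "\n")
  cat("  map: ", round(min(object@sites$cm), 2), "-",
      round(max(object@sites$cm), 2), " cM\n", sep = "")
})

setMethod("show", "ArrayDesign", function(object) {
  cat("ArrayDesign '", object@name, "': ", length(object@siteIndices),
      " sites\n", sep = "")
})

setMethod("show", "CohortDataset", function(object) {
  g <- object@genotypes
  cat("CohortDataset [", object@provenance, "]: ", nrow(g), " samples x ",
      ncol(g), " sites, ", sprintf("%.2f%%", 100 * mean(is.na(g))),
      " missing\n", sep = "")
})

setMethod("show", "TrioSet", function(object) {
  cat("TrioSet:", length(object@trioIds), "parent-offspring trios on arrays",
      paste(names(object@designs), collapse = ", "), "\n")
})

setMethod("show", "PhenotypeSet", function(object) {
  cat("PhenotypeSet:", length(object@sampleId), "samples,",
      length(object@causalSites), "causal sites, target h2 =", object@h2, "\n")
})

setMethod("show", "PhasedHaplotypes", function(object) {
  cat("PhasedHaplotypes [", object@provenance, "]: ", nrow(object@hap1),
      " samples x ", ncol(object@hap1), " sites (",
      sum(object@imputed), " filled-in alleles)\n", sep = "")
})

setMethod("show", "DosageMatrix", function(object) {
  cat("DosageMatrix [", object@provenance, "]: ", nrow(object@dosages),
      " samples x ", ncol(object@dosages), " sites, median DR2 = ",
      sprintf("%.3f", median(object@dr2)), "\n", sep = "")
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport <", object@filter, ">: ", length(object@excludedSites),
      " sites / ", length(object@excludedSamples),
      " samples excluded\n", sep = "")
  for (l in object@log) cat(" ", l, "\n")
})

setMethod("show", "HMMParams", function(object) {
  cat("HMMParams: nStates=", object@nStates, ", ne=", object@ne,
      ", errorRate=", object@errorRate, ", nIterations=",
      object@nIterations, ", seed=", object@seed, "\n", sep = "")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport:", nrow(object@table), "metric rows\n")
  print(head(object@table, 10))
})

setMethod("show", "PgsExperimentResult", function(object) {
  cat("PgsExperimentResult:", nrow(object@table), "rows\n")
  print(head(object@table, 10))
})
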