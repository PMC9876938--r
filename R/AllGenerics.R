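#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @export
setGeneric("siteIndices", function(x) standardGeneric("siteIndices"))

#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))

#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setGeneric("dr2", function(x) standardGeneric("dr2"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setGeneric("excludedSites", function(x) standardGeneric("excludedSites"))

#' @export
setGeneric("excludedSamples", function(x) standardGeneric("excludedSamples"))

#' @export
setGeneric("qcStats", function(x) standardGeneric("qcStats"))

#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))
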