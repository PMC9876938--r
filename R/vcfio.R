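## VCF 4.2 input/output. Reading goes through vcfR; writing emits plain
## text so outputs stay uncompressed and diffable. Internal site indexing
## is carried in the PX INFO tag so round trips restore panel coordinates
## exactly; VCF POS stays 1-based per the standard.

vcfHeader <- function(source, extra = character()) {
  c("##fileformat=VCFv4.2",
    paste0("##source=GenoPhase_", source),
    "##INFO=<ID=PX,Number=1,Type=Integer,Description=\"Panel site index\">",
    extra,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
}

#' Write a cohort as an unphased VCF 4.2
#'
#' Unphased GT with "./." for missing calls; the PX INFO tag records the
#' internal (1-based) panel site index.
#'
#' @param cohort a [CohortDataset-class].
#' @param path output file.
#' @export
writeCohortVcf <- function(cohort, path) {
  G <- genotypes(cohort)
  st <- siteInfo(cohort)
  ids <- sampleInfo(cohort)$id
  gtCode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(st)), function(j) {
    g <- G[, j]
    gt <- ifelse(is.na(g), "./.", gtCode[as.character(g)])
    paste(c(st$chrom[j], st$pos[j], st$id[j], st$ref[j], st$alt[j], ".",
            "PASS", paste0("PX=", siteIndices(cohort)[j]), "GT", gt),
          collapse = "\t")
  }, "")
  writeLines(c(vcfHeader("cohort"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t"),
               body), path)
  invisible(path)
}

#' Write phased haplotypes as a VCF with "|" separated GT
#'
#' @param phased a [PhasedHaplotypes-class].
#' @param path output file.
#' @export
writePhasedVcf <- function(phased, path) {
  st <- siteInfo(phased)
  ids <- sampleInfo(phased)$id
  h <- haplotypes(phased)
  body <- vapply(seq_len(nrow(st)), function(j) {
    gt <- paste0(h$hap1[, j], "|", h$hap2[, j])
    paste(c(st$chrom[j], st$pos[j], st$id[j], st$ref[j], st$alt[j], ".",
            "PASS", paste0("PX=", siteIndices(phased)[j]), "GT", gt),
          collapse = "\t")
  }, "")
  writeLines(c(vcfHeader("phased"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t"),
               body), path)
  invisible(path)
}

#' Write imputed dosages as a VCF with DS format and DR2 INFO
#'
#' DS values are written with 4-decimal fixed precision.
#'
#' @param dosage a [DosageMatrix-class].
#' @param sites site annotation rows matching the dosage columns.
#' @param path output file.
#' @export
writeDosageVcf <- function(dosage, sites, path) {
  DS <- dosages(dosage)
  ids <- dosage@sampleId
  body <- vapply(seq_len(nrow(sites)), function(j) {
    paste(c(sites$chrom[j], sites$pos[j], sites$id[j], sites$ref[j],
            sites$alt[j], ".", "PASS",
            sprintf("PX=%d;DR2=%.4f", siteIndices(dosage)[j],
                    dosage@dr2[j]),
            "DS", sprintf("%.4f", DS[, j])),
          collapse = "\t")
  }, "")
  hdr <- vcfHeader("dosage",
    "##INFO=<ID=DR2,Number=1,Type=Float,Description=\"Estimated squared dosage correlation\">")
  hdr <- c(hdr,
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Imputed alt dosage\">")
  writeLines(c(hdr,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t"),
               body), path)
  invisible(path)
}

infoField <- function(info, key) {
  m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
  as.numeric(sub(paste0(key, "="), "", m))
}

#' Read a cohort VCF written by [writeCohortVcf()]
#'
#' Biallelic SNP records only; multi-allelic or indel records are skipped
#' with a count (or rejected with strict = TRUE).
#'
#' @param path VCF file.
#' @param metadata optional sample-metadata data.frame (id, wave, case,
#'   pop, age, sex) to attach.
#' @param strict error instead of skipping non-SNP records.
#' @return A [CohortDataset-class].
#' @export
readCohortVcf <- function(path, metadata = NULL, strict = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!snp)) {
    if (strict) stop(sum(!snp), " non-biallelic-SNP records in ", path)
    message("skipping ", sum(!snp), " non-SNP records")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  code <- function(x) {
    out <- rep(NA_integer_, length(x))
    x <- gsub("|", "/", x, fixed = TRUE)
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  G <- t(apply(gt, 2L, code))
  if (ncol(gt) == 1L) G <- matrix(G, ncol = 1L)
  dimnames(G) <- NULL
  px <- as.integer(infoField(fix$INFO, "PX"))
  if (!length(px) || anyNA(px)) px <- seq_len(nrow(fix))
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      cm = NA_real_, ref = fix$REF, alt = fix$ALT,
                      id = fix$ID, stringsAsFactors = FALSE)
  ids <- colnames(gt)
  samples <- if (is.null(metadata)) {
    data.frame(id = ids, wave = "w1", case = FALSE, pop = "unknown",
               age = NA_real_, sex = NA_character_,
               hapRow1 = NA_integer_, hapRow2 = NA_integer_,
               stringsAsFactors = FALSE)
  } else metadata[match(ids, metadata$id), , drop = FALSE]
  new("CohortDataset", genotypes = G, siteIndices = px, sites = sites,
      samples = samples, provenance = paste0("vcf:", basename(path)))
}

#' Read a phased VCF written by [writePhasedVcf()]
#'
#' @param path VCF file.
#' @return list(hap1, hap2, sites, siteIndices, sampleIds); haplotype order
#'   within "a|b" genotypes is preserved.
#' @export
readPhasedVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- apply(gt, 2L, function(x) as.integer(substr(x, 1L, 1L)))
  a2 <- apply(gt, 2L, function(x) as.integer(substr(x, 3L, 3L)))
  h1 <- t(a1); h2 <- t(a2)
  dimnames(h1) <- dimnames(h2) <- NULL
  px <- as.integer(infoField(fix$INFO, "PX"))
  list(hap1 = h1, hap2 = h2,
       sites = data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT, id = fix$ID,
                          stringsAsFactors = FALSE),
       siteIndices = px, sampleIds = colnames(gt))
}

#' Read a dosage VCF written by [writeDosageVcf()]
#'
#' @param path VCF file.
#' @return list(dosages, dr2, siteIndices, sampleIds).
#' @export
readDosageVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS")
  DS <- t(apply(ds, 2L, as.numeric))
  if (ncol(ds) == 1L) DS <- matrix(DS, ncol = 1L)
  dimnames(DS) <- NULL
  list(dosages = DS, dr2 = infoField(fix$INFO, "DR2"),
       siteIndices = as.integer(infoField(fix$INFO, "PX")),
       sampleIds = colnames(ds))
}

#' Write sample metadata / array manifest / QC report TSVs
#'
#' @param cohort a [CohortDataset-class].
#' @param path output file.
#' @export
writeSampleMetadata <- function(cohort, path) {
  write.table(sampleInfo(cohort)[, c("id", "wave", "case", "pop", "age",
                                     "sex")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleMetadata
#' @param design an [ArrayDesign-class].
#' @param panel the [HaplotypePanel-class] supplying site annotation.
#' @export
writeArrayManifest <- function(design, panel, path) {
  st <- siteInfo(panel)[siteIndices(design), , drop = FALSE]
  st$array <- design@name
  write.table(st[, c("id", "chrom", "pos", "ref", "alt", "array")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleMetadata
#' @param report a [QCReport-class].
#' @export
writeQCReport <- function(report, path) {
  write.table(qcStats(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
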