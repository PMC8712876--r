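# Serialization of the package's objects to standard plain-text formats:
# FASTA/BED/JSON for gene models, FASTA for haplotypes, FASTQ + truth TSV
# for read sets, TSV for band patterns and assays, JSON for diagnoses.

#' Export a gene model as FASTA + BED + JSON
#'
#' Writes \code{<gene>.fasta} (locus sequence), \code{<gene>.bed} (exon
#' intervals, 0-based half-open, as BED requires) and \code{<gene>.json}
#' (CDS coordinate map).
#'
#' @param model a \linkS4class{GeneModel}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
exportGeneModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, geneName(model))
  seqs <- Biostrings::DNAStringSet(modelSequence(model))
  names(seqs) <- geneName(model)
  Biostrings::writeXStringSet(seqs, paste0(base, ".fasta"))
  ex <- exonRanges(model)
  bed <- data.frame(chrom = geneName(model),
                    start = IRanges::start(ex) - 1L,   # BED is 0-based half-open
                    end = IRanges::end(ex),
                    name = paste0("exon", seq_along(ex)))
  utils::write.table(bed, paste0(base, ".bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(gene = geneName(model),
         exon_start = IRanges::start(ex), exon_end = IRanges::end(ex),
         cds_offsets = cdsOffsets(model), cds_length = cdsLength(model)),
    paste0(base, ".json"), auto_unbox = TRUE)
  invisible(paste0(base, c(".fasta", ".bed", ".json")))
}

#' Export the allele knowledge base as JSON
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
exportAlleleKb <- function(path) {
  jsonlite::write_json(alleleKb(), path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Export a cohort as JSON metadata plus per-haplotype FASTA
#'
#' @param samples list of \linkS4class{RhdSample}s.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
exportCohort <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- lapply(samples, function(s) {
    haps <- haplotypes(s)
    list(sample_id = sampleId(s), genotype = genotypeName(s),
         serology = serologyLabel(s),
         haplotypes = lapply(haps, function(h)
           list(structural_class = structuralClass(h),
                variants = variantTable(h)$cdot,
                rhesus_box = rhesusBoxType(h))))
  })
  metaPath <- file.path(dir, "cohort.json")
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, pretty = TRUE)
  seqs <- list(); nms <- character(0)
  for (s in samples) {
    haps <- haplotypes(s)
    for (nm in names(haps)) {
      if (!nzchar(hapSequence(haps[[nm]]))) next
      seqs[[length(seqs) + 1L]] <- hapSequence(haps[[nm]])
      nms <- c(nms, paste(sampleId(s), nm, sep = "|"))
    }
  }
  fastaPath <- file.path(dir, "haplotypes.fasta")
  if (length(seqs)) {
    dss <- Biostrings::DNAStringSet(unlist(seqs))
    names(dss) <- nms
    Biostrings::writeXStringSet(dss, fastaPath)
  }
  invisible(c(metaPath, fastaPath))
}

#' Export a read set as FASTQ plus a truth TSV
#'
#' Reads get the constant quality "I" (error-free simulation).
#'
#' @param readset a \linkS4class{ReadSet}.
#' @param fastqPath,truthPath output file paths.
#' @return invisibly, the paths written.
#' @export
exportReadSet <- function(readset, fastqPath, truthPath) {
  reads <- readSequences(readset)
  dss <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(dss, fastqPath, format = "fastq",
                              qualities = quals)
  utils::write.table(readTruth(readset), truthPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fastqPath, truthPath))
}

#' Export amplicons as FASTA with sample|haplotype|exon headers
#' @param amplicons data.frame from [extractAmplicons()].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
exportAmplicons <- function(amplicons, path) {
  dss <- Biostrings::DNAStringSet(amplicons$seq)
  names(dss) <- sprintf("%s|hap%s|exon%d", amplicons$sample,
                        amplicons$haplotype, amplicons$exon)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Export a band pattern as TSV
#' @param pattern data.frame from [simulatePcrSsp()].
#' @param sampleId sample identifier column value.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
exportBandPattern <- function(pattern, sampleId, path) {
  out <- cbind(sample_id = sampleId, pattern)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export cffDNA assays as TSV
#' @param assays data.frame as produced by [makeNiptFixture()].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
exportAssays <- function(assays, path) {
  utils::write.table(assays, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export diagnoses as JSON
#' @param diagnoses list of \linkS4class{Diagnosis} objects.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
exportDiagnoses <- function(diagnoses, path) {
  out <- lapply(diagnoses, function(d) list(
    sample_id = sampleId(d), tier = tier(d),
    genotype_call = genotypeCall(d), isbt_alleles = isbtAlleles(d),
    zygosity_call = zygosityCall(d), management = management(d),
    notes = diagnosisNotes(d)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(path)
}
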