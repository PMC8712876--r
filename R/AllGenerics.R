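# Accessor generics.  Slot access from user code is discouraged; these are
# the supported surface.

#' @describeIn GeneModel gene identifier.
#' @param object,x an object of the documented class.
#' @export
setGeneric("geneName", function(object) standardGeneric("geneName"))
#' @export
setMethod("geneName", "GeneModel", function(object) object@geneName)

#' @describeIn GeneModel exon intervals as an \code{IRanges}.
#' @export
setGeneric("exonRanges", function(object) standardGeneric("exonRanges"))
#' @export
setMethod("exonRanges", "GeneModel", function(object) object@exons)

#' @describeIn GeneModel CDS coordinate of each exon's first base.
#' @export
setGeneric("cdsOffsets", function(object) standardGeneric("cdsOffsets"))
#' @export
setMethod("cdsOffsets", "GeneModel", function(object) object@cdsOffsets)

#' @describeIn GeneModel locus sequence as a \code{DNAString}.
#' @export
setGeneric("modelSequence", function(object) standardGeneric("modelSequence"))
#' @export
setMethod("modelSequence", "GeneModel", function(object) object@sequence)

#' Intron intervals of a gene model
#'
#' @param model a \linkS4class{GeneModel}.
#' @return an \code{IRanges} with one interval per intron (none for a
#'   single-exon model).
#' @export
intronRanges <- function(model) {
  ex <- exonRanges(model)
  if (length(ex) < 2L) return(IRanges::IRanges())
  IRanges::IRanges(
    start = IRanges::end(ex)[-length(ex)] + 1L,
    end   = IRanges::start(ex)[-1L] - 1L
  )
}

#' Number of coding bases in a gene model
#' @param model a \linkS4class{GeneModel}.
#' @export
cdsLength <- function(model) sum(IRanges::width(exonRanges(model)))

#' @describeIn RhdSample sample identifier.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @export
setMethod("sampleId", "RhdSample", function(object) object@sampleId)
#' @export
setMethod("sampleId", "Diagnosis", function(object) object@sampleId)

#' @describeIn RhdSample generator genotype label.
#' @export
setGeneric("genotypeName", function(object) standardGeneric("genotypeName"))
#' @export
setMethod("genotypeName", "RhdSample", function(object) object@genotypeName)

#' @describeIn RhdSample the two haplotypes as a list \code{(A, B)}.
#' @export
setGeneric("haplotypes", function(object) standardGeneric("haplotypes"))
#' @export
setMethod("haplotypes", "RhdSample", function(object)
  list(A = object@haplotypeA, B = object@haplotypeB))

#' @describeIn RhdSample carried serology metadata label.
#' @export
setGeneric("serologyLabel", function(object) standardGeneric("serologyLabel"))
#' @export
setMethod("serologyLabel", "RhdSample", function(object) object@serologyLabel)

#' @describeIn Haplotype structural class.
#' @export
setGeneric("structuralClass", function(object) standardGeneric("structuralClass"))
#' @export
setMethod("structuralClass", "Haplotype", function(object) object@structuralClass)

#' @describeIn Haplotype point-variant table.
#' @export
setGeneric("variantTable", function(object) standardGeneric("variantTable"))
#' @export
setMethod("variantTable", "Haplotype", function(object) object@variants)

#' @describeIn Haplotype Rhesus-box type (\code{"intact"} or \code{"hybrid"}).
#' @export
setGeneric("rhesusBoxType", function(object) standardGeneric("rhesusBoxType"))
#' @export
setMethod("rhesusBoxType", "Haplotype", function(object) object@rhesusBox)

#' @describeIn Haplotype realized locus sequence (empty for a deletion).
#' @export
setGeneric("hapSequence", function(object) standardGeneric("hapSequence"))
#' @export
setMethod("hapSequence", "Haplotype", function(object) object@sequence)

#' @describeIn ReadSet read sequences (named character vector).
#' @export
setGeneric("readSequences", function(object) standardGeneric("readSequences"))
#' @export
setMethod("readSequences", "ReadSet", function(object) object@reads)

#' @describeIn ReadSet per-read truth annotation.
#' @export
setGeneric("readTruth", function(object) standardGeneric("readTruth"))
#' @export
setMethod("readTruth", "ReadSet", function(object) object@truth)

#' @describeIn RetentionReport supported retention events.
#' @export
setGeneric("retentionEvents", function(object) standardGeneric("retentionEvents"))
#' @export
setMethod("retentionEvents", "RetentionReport", function(object) object@events)

#' @describeIn RetentionReport mean depth per intron.
#' @export
setGeneric("intronCoverage", function(object) standardGeneric("intronCoverage"))
#' @export
setMethod("intronCoverage", "RetentionReport", function(object) object@intronCoverage)

#' @describeIn RetentionReport mean depth over exonic bases.
#' @export
setGeneric("exonicCoverage", function(object) standardGeneric("exonicCoverage"))
#' @export
setMethod("exonicCoverage", "RetentionReport", function(object) object@exonicMeanCoverage)

#' @describeIn RetentionReport report flags (e.g. \code{"intron2_enriched"}).
#' @export
setGeneric("reportFlags", function(object) standardGeneric("reportFlags"))
#' @export
setMethod("reportFlags", "RetentionReport", function(object) object@flags)

#' @describeIn Diagnosis tier that resolved the sample.
#' @export
setGeneric("tier", function(object) standardGeneric("tier"))
#' @export
setMethod("tier", "Diagnosis", function(object) object@tier)

#' @describeIn Diagnosis genotype call (kit class or allele-pair string).
#' @export
setGeneric("genotypeCall", function(object) standardGeneric("genotypeCall"))
#' @export
setMethod("genotypeCall", "Diagnosis", function(object) object@genotypeCall)

#' @describeIn Diagnosis supporting ISBT allele designations.
#' @export
setGeneric("isbtAlleles", function(object) standardGeneric("isbtAlleles"))
#' @export
setMethod("isbtAlleles", "Diagnosis", function(object) object@isbtAlleles)

#' @describeIn Diagnosis diploid genotype string, \code{NA} if not typed.
#' @export
setGeneric("zygosityCall", function(object) standardGeneric("zygosityCall"))
#' @export
setMethod("zygosityCall", "Diagnosis", function(object) object@zygosityCall)

#' @describeIn Diagnosis management advice list.
#' @export
setGeneric("management", function(object) standardGeneric("management"))
#' @export
setMethod("management", "Diagnosis", function(object) object@management)

#' @describeIn Diagnosis decision-tree audit notes.
#' @export
setGeneric("diagnosisNotes", function(object) standardGeneric("diagnosisNotes"))
#' @export
setMethod("diagnosisNotes", "Diagnosis", function(object) object@notes)

## show methods ---------------------------------------------------------------

setMethod("show", "GeneModel", function(object) {
  ex <- exonRanges(object)
  cat("GeneModel <", object@geneName, ">: ",
      length(ex), " exons, CDS ", cdsLength(object), " bp, locus ",
      length(object@sequence), " bp\n", sep = "")
})

setMethod("show", "RhdLocusSet", function(object) {
  cat("RhdLocusSet: RHD + RHCE mini-loci\n")
  show(object@rhd)
  show(object@rhce)
  cat("Rhesus boxes: upstream/downstream/hybrid (",
      nchar(object@boxes$hybrid), " bp hybrid construct)\n", sep = "")
})

setMethod("show", "Haplotype", function(object) {
  v <- if (nrow(object@variants)) paste(object@variants$cdot, collapse = ",")
       else "none"
  cat("Haplotype [", object@structuralClass, "] variants: ", v,
      "; Rhesus box: ", object@rhesusBox, "\n", sep = "")
})

setMethod("show", "RhdSample", function(object) {
  cat("RhdSample ", object@sampleId, " (", object@genotypeName,
      ", serology ", object@serologyLabel, ")\n", sep = "")
  cat("  A: "); show(object@haplotypeA)
  cat("  B: "); show(object@haplotypeB)
})

setMethod("show", "ReadSet", function(object) {
  nret <- sum(object@truth$category == "retains_intron")
  cat("ReadSet: ", length(object@reads), " reads (", nret,
      " with intron retention in truth)\n", sep = "")
})

setMethod("show", "RetentionReport", function(object) {
  cat("RetentionReport\n")
  if (nrow(object@events)) {
    cat("  retained lengths:",
        paste(sprintf("intron%d:%dbp(x%d)", object@events$intron,
                      object@events$length, object@events$supporting_reads),
              collapse = " "), "\n")
  } else cat("  no supported retention events\n")
  cat("  intron coverage:",
      paste(sprintf("%.1f", object@intronCoverage), collapse = " "), "\n")
  cat("  exonic mean coverage:", sprintf("%.1f", object@exonicMeanCoverage), "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "Diagnosis", function(object) {
  cat("Diagnosis ", object@sampleId, " [tier ", object@tier, "]: ",
      object@genotypeCall, "\n", sep = "")
  cat("  ISBT: ", paste(object@isbtAlleles, collapse = " / "), "\n", sep = "")
  if (!is.na(object@zygosityCall))
    cat("  zygosity: ", object@zygosityCall, "\n", sep = "")
  m <- object@management
  cat("  RhIG candidate: ", if (isTRUE(m$rhig_candidate)) "Yes" else "No",
      "; donor ", m$donor, "; recipient ", m$recipient,
      if (isTRUE(m$manual_review)) " [manual review]" else "", "\n", sep = "")
})

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary of", object@nSamples, "samples\n")
  print(object@classTable, row.names = FALSE)
  cat(sprintf("  identified by PCR-SSP: %.1f%%\n", object@pctIdentifiedPcrSsp))
  cat(sprintf("  identified in total:   %.1f%%\n", object@pctIdentifiedTotal))
  cat(sprintf("  RhIG exempt:           %.1f%%\n", object@pctRhigExempt))
})
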