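#' @import methods
#' @importFrom IRanges IRanges start end width
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom Biostrings DNAString
NULL

#' GeneModel: exon/intron structure of a miniature gene locus
#'
#' Holds the exon intervals (1-based closed, \code{IRanges}), the CDS
#' coordinate of the first base of each exon, and the full locus sequence
#' (exons + introns + flanks).  CDS positions are contiguous across exons,
#' so HGVS-style c. coordinates map exactly onto the locus.
#'
#' @slot geneName single identifier, e.g. \code{"RHD"}.
#' @slot exons \code{IRanges} of exon intervals in locus coordinates.
#' @slot cdsOffsets integer, CDS position of the first base of each exon.
#' @slot sequence \code{DNAString} of the whole locus.
#' @export
setClass("GeneModel",
  representation(
    geneName   = "character",
    exons      = "IRanges",
    cdsOffsets = "integer",
    sequence   = "DNAString"
  )
)

setValidity("GeneModel", function(object) {
  ex <- object@exons
  msg <- character(0)
  if (length(object@geneName) != 1L) msg <- c(msg, "geneName must be length 1")
  if (length(ex) != length(object@cdsOffsets))
    msg <- c(msg, "cdsOffsets must have one entry per exon")
  if (length(ex) > 1L) {
    if (any(diff(IRanges::start(ex)) <= 0))
      msg <- c(msg, "exons must be strictly ordered")
    if (any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping with introns between them")
    contig <- object@cdsOffsets[-1L] ==
      object@cdsOffsets[-length(ex)] + IRanges::width(ex)[-length(ex)]
    if (!all(contig))
      msg <- c(msg, "CDS positions must be contiguous across exons")
  }
  if (length(ex) > 0L && IRanges::end(ex)[length(ex)] > length(object@sequence))
    msg <- c(msg, "exons extend past the locus sequence")
  if (length(msg)) msg else TRUE
})

#' RhdLocusSet: the paired RHD/RHCE mini-loci plus assay constructs
#'
#' Container for everything the in-silico assays need: the RHD and RHCE
#' \linkS4class{GeneModel}s, the stylized Rhesus-box sequences (upstream,
#' downstream, and the hybrid box diagnostic of RHD deletion), a constant
#' internal-control amplification target, and the table of RHD-vs-RHCE
#' diagnostic CDS positions.
#'
#' @slot rhd,rhce \linkS4class{GeneModel}s of the two loci.
#' @slot boxes named list of character sequences: \code{upstream},
#'   \code{downstream}, \code{hybrid}.
#' @slot control character, internal-control locus present in every genome.
#' @slot diagnostics list of integer CDS positions (one vector per exon) at
#'   which RHCE differs from RHD.
#' @export
setClass("RhdLocusSet",
  representation(
    rhd         = "GeneModel",
    rhce        = "GeneModel",
    boxes       = "list",
    control     = "character",
    diagnostics = "list"
  )
)

#' Haplotype: one chromosome's RHD state
#'
#' @slot structuralClass one of \code{"intact"}, \code{"deletion"},
#'   \code{"hybrid_CE_2_9"}, \code{"hybrid_CE_3_6"} (DVI III),
#'   \code{"hybrid_CE_5"} (DVa (Hus)).
#' @slot variants data.frame of point variants with columns
#'   \code{cds}, \code{offset}, \code{ref}, \code{alt}, \code{cdot}.
#' @slot rhesusBox \code{"intact"} (upstream + downstream boxes) or
#'   \code{"hybrid"} (the deletion-diagnostic hybrid box).
#' @slot sequence realized locus sequence; empty string for a deletion.
#' @export
setClass("Haplotype",
  representation(
    structuralClass = "character",
    variants        = "data.frame",
    rhesusBox       = "character",
    sequence        = "character"
  )
)

setValidity("Haplotype", function(object) {
  msg <- character(0)
  ok <- c("intact", "deletion", "hybrid_CE_2_9", "hybrid_CE_3_6", "hybrid_CE_5")
  if (!object@structuralClass %in% ok)
    msg <- c(msg, paste("structuralClass must be one of:", paste(ok, collapse = ", ")))
  if (!object@rhesusBox %in% c("intact", "hybrid"))
    msg <- c(msg, "rhesusBox must be 'intact' or 'hybrid'")
  isDel <- identical(object@structuralClass, "deletion")
  if (isDel != identical(object@rhesusBox, "hybrid"))
    msg <- c(msg, "deletion haplotypes (and only those) carry the hybrid Rhesus box")
  if (isDel && nzchar(object@sequence))
    msg <- c(msg, "deletion haplotypes have an empty sequence")
  if (isDel && nrow(object@variants) > 0L)
    msg <- c(msg, "point variants are only allowed on non-deleted backbones")
  if (length(msg)) msg else TRUE
})

#' RhdSample: a diploid subject
#'
#' @slot sampleId identifier.
#' @slot genotypeName generator label the sample was built from.
#' @slot haplotypeA,haplotypeB \linkS4class{Haplotype}s.
#' @slot serologyLabel carried metadata, one of \code{"D_pos"},
#'   \code{"D_neg"}, \code{"DEL"}; never computed by the pipeline.
#' @export
setClass("RhdSample",
  representation(
    sampleId      = "character",
    genotypeName  = "character",
    haplotypeA    = "Haplotype",
    haplotypeB    = "Haplotype",
    serologyLabel = "character"
  )
)

#' ReadSet: simulated mRNA reads with per-read truth
#'
#' @slot reads named character vector of read sequences.
#' @slot truth data.frame with one row per read: \code{read_id},
#'   \code{haplotype}, \code{category} (\code{"spliced"} or
#'   \code{"retains_intron"}), \code{intron}, \code{retained_bp},
#'   \code{offset} (1-based start of the read in its transcript).
#' @export
setClass("ReadSet",
  representation(reads = "character", truth = "data.frame")
)

setValidity("ReadSet", function(object) {
  msg <- character(0)
  if (nrow(object@truth) != length(object@reads))
    msg <- c(msg, "truth must have one row per read")
  ret <- object@truth$category == "retains_intron"
  if (any(ret) && any(object@truth$retained_bp[ret] <= 0))
    msg <- c(msg, "retained lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' RetentionReport: intron-retention summary of a mapped read set
#'
#' @slot events data.frame of supported retention events: \code{intron},
#'   \code{length}, \code{supporting_reads}.
#' @slot intronCoverage named numeric, mean read depth per intron.
#' @slot exonicMeanCoverage mean depth over exonic bases.
#' @slot anomalous data.frame of junctions into an intron that do not start
#'   at an exon end (reported, never treated as retention).
#' @slot flags character, e.g. \code{"intron2_enriched"}.
#' @slot alignedBases total aligned bases (equals the coverage sum).
#' @slot unmappedReads ids of reads with no placement.
#' @slot clippedBases total soft-clipped bases across reads.
#' @export
setClass("RetentionReport",
  representation(
    events             = "data.frame",
    intronCoverage     = "numeric",
    exonicMeanCoverage = "numeric",
    anomalous          = "data.frame",
    flags              = "character",
    alignedBases       = "numeric",
    unmappedReads      = "character",
    clippedBases       = "numeric"
  )
)

#' Diagnosis: the decision tree's product for one sample
#'
#' @slot sampleId identifier.
#' @slot tier \code{"pcr_ssp"}, \code{"sanger"}, or \code{"unresolved"}.
#' @slot genotypeCall the PCR-SSP kit class, or an allele-pair string when
#'   resolved at the sequencing tier.
#' @slot isbtAlleles ISBT designations supporting the call.
#' @slot zygosityCall diploid genotype string when zygosity was typed,
#'   otherwise \code{NA}.
#' @slot management list: \code{rhig_candidate}, \code{donor},
#'   \code{recipient}, \code{manual_review}.
#' @slot notes audit trail of tree transitions.
#' @export
setClass("Diagnosis",
  representation(
    sampleId     = "character",
    tier         = "character",
    genotypeCall = "character",
    isbtAlleles  = "character",
    zygosityCall = "character",
    management   = "list",
    notes        = "character"
  )
)

setValidity("Diagnosis", function(object) {
  msg <- character(0)
  if (!object@tier %in% c("pcr_ssp", "sanger", "unresolved"))
    msg <- c(msg, "tier must be pcr_ssp, sanger or unresolved")
  if (identical(object@tier, "pcr_ssp") &&
      identical(object@genotypeCall, "undetectable"))
    msg <- c(msg, "a pcr_ssp-tier diagnosis cannot be undetectable")
  need <- c("rhig_candidate", "donor", "recipient", "manual_review")
  if (!all(need %in% names(object@management)))
    msg <- c(msg, "management must be fully populated")
  if (length(msg)) msg else TRUE
})

#' CohortSummary: per-class counts and pipeline identification rates
#'
#' @slot classTable data.frame: tier-1 genotype class, \code{n}, \code{pct}.
#' @slot pctIdentifiedPcrSsp percent of samples resolved by PCR-SSP alone.
#' @slot pctIdentifiedTotal percent resolved after the sequencing tier.
#' @slot pctRhigExempt percent whose management marks them not candidates
#'   for RhIG.
#' @slot nSamples cohort size.
#' @export
setClass("CohortSummary",
  representation(
    classTable          = "data.frame",
    pctIdentifiedPcrSsp = "numeric",
    pctIdentifiedTotal  = "numeric",
    pctRhigExempt       = "numeric",
    nSamples            = "integer"
  )
)
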