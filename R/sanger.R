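# Sanger-style tier: 10-exon (+ flanking intron) amplicons, exact-anchor
# variant calling against the RHD*01 reference, ISBT allele assignment.
#
# Amplicons are clean per-haplotype consensus strings (no chromatograms,
# no heterozygous base ambiguity) and the generator introduces
# substitutions only, so alignment reduces to exact flank anchoring.

.ANCHOR_LEN <- 12L

#' Extract per-exon sequencing amplicons from a sample
#'
#' One amplicon per exon per non-deleted haplotype, covering the exon plus
#' \code{flank_bp} of flanking intron (or locus flank for the terminal
#' exons).  Deletion haplotypes yield none.
#'
#' @param sample an \linkS4class{RhdSample}.
#' @param model the reference \linkS4class{GeneModel} (RHD).
#' @param flank_bp flanking bases per side; must be >= 2 so splice sites
#'   are always covered.  Default 30.
#' @return data.frame: \code{sample}, \code{haplotype}, \code{exon},
#'   \code{start}, \code{end} (reference coordinates), \code{seq}.
#' @examples
#' nrow(extractAmplicons(makeSample("deletion_hom")))  # 0
#' @export
extractAmplicons <- function(sample, model = rhdModel(), flank_bp = 30L) {
  flank_bp <- as.integer(flank_bp)
  if (flank_bp < 2L) stop("flank_bp must be >= 2 to cover splice sites")
  ex <- exonRanges(model)
  locusLen <- length(modelSequence(model))
  haps <- haplotypes(sample)
  out <- list()
  for (nm in names(haps)) {
    h <- haps[[nm]]
    if (structuralClass(h) == "deletion") next
    seqchar <- hapSequence(h)
    for (k in seq_along(ex)) {
      a <- max(1L, IRanges::start(ex)[k] - flank_bp)
      b <- min(locusLen, IRanges::end(ex)[k] + flank_bp)
      out[[length(out) + 1L]] <- data.frame(
        sample = sampleId(sample), haplotype = nm, exon = k,
        start = a, end = b, seq = substr(seqchar, a, b),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sample = character(0), haplotype = character(0),
                      exon = integer(0), start = integer(0), end = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Call point variants from amplicons against the reference
#'
#' Each amplicon is anchored to its reference region by exact match of its
#' terminal bases; every internal mismatch is then reported in HGVS-style
#' coding coordinates (with signed intron offsets for splice-region
#' positions).
#'
#' @param amplicons data.frame from [extractAmplicons()].
#' @param model the reference \linkS4class{GeneModel}.
#' @return data.frame: \code{sample}, \code{haplotype}, \code{exon},
#'   \code{cds}, \code{offset}, \code{ref}, \code{alt}, \code{cdot},
#'   \code{region}; zero rows when all amplicons match the reference.
#' @section Errors:
#' An amplicon whose terminal anchors do not match the reference (or whose
#' length differs from its region) raises an alignment error.
#' @export
callVariants <- function(amplicons, model = rhdModel()) {
  refchar <- as.character(modelSequence(model))
  empty <- data.frame(sample = character(0), haplotype = character(0),
                      exon = integer(0), cds = integer(0), offset = integer(0),
                      ref = character(0), alt = character(0),
                      cdot = character(0), region = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(amplicons) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(amplicons))) {
    a <- amplicons[i, ]
    refseq <- substr(refchar, a$start, a$end)
    if (nchar(a$seq) != nchar(refseq))
      stop("alignment error: amplicon length differs from its reference ",
           "region (exon ", a$exon, ")")
    k <- min(.ANCHOR_LEN, nchar(refseq))
    if (substr(a$seq, 1L, k) != substr(refseq, 1L, k) ||
        substr(a$seq, nchar(a$seq) - k + 1L, nchar(a$seq)) !=
          substr(refseq, nchar(refseq) - k + 1L, nchar(refseq)))
      stop("alignment error: amplicon not anchorable to the reference ",
           "(exon ", a$exon, ")")
    for (p in mismatchPositions(a$seq, refseq)) {
      g <- a$start + p - 1L
      cc <- tryCatch(genomicToCds(model, g),
                     error = function(e) NULL)
      if (is.null(cc)) {      # locus flank beyond the CDS/intron span
        out[[length(out) + 1L]] <- data.frame(
          sample = a$sample, haplotype = a$haplotype, exon = a$exon,
          cds = NA_integer_, offset = NA_integer_,
          ref = substr(refseq, p, p), alt = substr(a$seq, p, p),
          cdot = sprintf("g.%d%s>%s", g, substr(refseq, p, p),
                         substr(a$seq, p, p)),
          region = "flank", stringsAsFactors = FALSE)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        sample = a$sample, haplotype = a$haplotype, exon = a$exon,
        cds = cc$cds, offset = cc$offset,
        ref = substr(refseq, p, p), alt = substr(a$seq, p, p),
        cdot = formatCdot(cc$cds, cc$offset, substr(refseq, p, p),
                          substr(a$seq, p, p)),
        region = cc$region, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  unique(res)
}

#' Assign an ISBT allele to a haplotype's variant calls
#'
#' Delegates to [lookupAllele()]: an empty call set is the reference
#' RHD*01, a variant set matching a knowledge-base record (exact set
#' match) returns that allele, anything else the sentinel.
#'
#' @param variants character vector of c. strings, or a data.frame from
#'   [callVariants()] (its \code{cdot} column is used).
#' @return one-row knowledge-base data.frame.
#' @examples
#' assignAllele("c.336-1G>A")$designation   # RHD*01N.25
#' assignAllele(character(0))$designation   # RHD*01
#' @export
assignAllele <- function(variants) {
  cdots <- if (is.data.frame(variants)) variants$cdot else variants
  cdots <- cdots[grepl("^c\\.", cdots)]
  lookupAllele(unique(cdots))
}
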