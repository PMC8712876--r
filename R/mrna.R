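# mRNA read simulation.  Haplotypes carrying the c.336-1G>A splice-acceptor
# mutation emit, for a configurable fraction of transcripts, mRNAs that
# retain a 3'-terminal segment of intron 2 (the segment abuts the exon-3
# start, matching an activated cryptic acceptor upstream of the mutated
# constitutive site); every other intron is spliced correctly.  Wild-type
# haplotypes emit fully spliced transcripts.  Reads are error-free.

.SPLICE_CDOT <- "c.336-1G>A"

## mature transcript of a haplotype, optionally retaining the 3'-terminal
## `retainBp` bases of intron `intron`
.transcriptOf <- function(hapSeq, model, retainBp = 0L, intron = 2L) {
  ex <- exonRanges(model)
  pieces <- substring(hapSeq, IRanges::start(ex), IRanges::end(ex))
  if (retainBp > 0L) {
    ir <- intronRanges(model)[intron]
    tail <- substr(hapSeq, IRanges::end(ir) - retainBp + 1L, IRanges::end(ir))
    pieces[intron + 1L] <- paste0(tail, pieces[intron + 1L])
  }
  paste(pieces, collapse = "")
}

#' Simulate mRNA reads for a diploid sample
#'
#' Reads are uniform random error-free substrings of the sample's mature
#' transcripts.  For haplotypes carrying c.336-1G>A, each transcript
#' retains (with probability \code{retentionFraction}) a 3'-terminal
#' intron-2 segment whose length is drawn uniformly from
#' \code{retentionLengths}; the remaining transcripts, and all transcripts
#' of other haplotypes, are fully spliced.
#'
#' @param sample an \linkS4class{RhdSample}; deletion haplotypes emit no
#'   transcripts.
#' @param nReads number of reads.
#' @param readLength read length in bp (default 150).
#' @param retentionLengths retained-segment lengths in bp; the default
#'   spans the observed 31-197 bp range with two interior values.
#' @param retentionFraction per-transcript retention probability for the
#'   splice allele (default 0.8).
#' @param seed integer seed; generation is deterministic given the seed.
#' @param locusSet the \linkS4class{RhdLocusSet}.
#' @return a \linkS4class{ReadSet}.
#' @section Errors:
#' A retention length exceeding the intron-2 length is a generation error.
#' @examples
#' rs <- makeMrnaReads(makeSample("c336_1A_het_del"), nReads = 50, seed = 1)
#' table(readTruth(rs)$category)
#' @export
makeMrnaReads <- function(sample, nReads = 600L, readLength = 150L,
                          retentionLengths = c(31L, 90L, 144L, 197L),
                          retentionFraction = 0.8, seed = 42L,
                          locusSet = rhdLocusSet()) {
  model <- rhdModel(locusSet)
  intron2Len <- IRanges::width(intronRanges(model))[2L]
  if (any(retentionLengths > intron2Len))
    stop("generation error: retention length exceeds the intron-2 length (",
         intron2Len, " bp)")
  if (any(retentionLengths <= 0L)) stop("retention lengths must be positive")
  haps <- haplotypes(sample)
  expressed <- names(haps)[vapply(haps, function(h)
    structuralClass(h) != "deletion", logical(1))]
  if (length(expressed) == 0L)
    stop("generation error: no expressed (non-deleted) haplotype")
  hasSplice <- vapply(haps, function(h)
    .SPLICE_CDOT %in% variantTable(h)$cdot, logical(1))

  withSeed(seed, {
    hapDraw <- expressed[sample.int(length(expressed), nReads, replace = TRUE)]
    retain <- hasSplice[hapDraw] & stats::runif(nReads) < retentionFraction
    lenPool <- as.integer(retentionLengths)
    lenDraw <- ifelse(retain,
                      lenPool[sample.int(length(lenPool), nReads,
                                         replace = TRUE)],
                      0L)
    reads <- character(nReads)
    offsets <- integer(nReads)
    for (i in seq_len(nReads)) {
      tx <- .transcriptOf(hapSequence(haps[[hapDraw[i]]]), model, lenDraw[i])
      if (nchar(tx) < readLength)
        stop("generation error: transcript shorter than the read length")
      offsets[i] <- sample.int(nchar(tx) - readLength + 1L, 1L)
      reads[i] <- substr(tx, offsets[i], offsets[i] + readLength - 1L)
    }
    ids <- sprintf("%s_r%04d", sampleId(sample), seq_len(nReads))
    names(reads) <- ids
    truth <- data.frame(
      read_id = ids,
      haplotype = hapDraw,
      category = ifelse(retain, "retains_intron", "spliced"),
      intron = ifelse(retain, 2L, NA_integer_),
      retained_bp = ifelse(retain, lenDraw, NA_integer_),
      offset = offsets,
      stringsAsFactors = FALSE)
    new("ReadSet", reads = reads, truth = truth)
  })
}

#' Rebuild a read's sequence from its truth annotation
#'
#' Used by the truth-conservation checks: every simulated read must be
#' re-derivable from the gene model, its haplotype and its truth row.
#'
#' @param sample the \linkS4class{RhdSample} the reads came from.
#' @param truthRow one row of [readTruth()].
#' @param readLength read length used at generation time.
#' @param locusSet the \linkS4class{RhdLocusSet}.
#' @return the reconstructed read sequence.
#' @export
rebuildRead <- function(sample, truthRow, readLength = 150L,
                        locusSet = rhdLocusSet()) {
  model <- rhdModel(locusSet)
  hap <- haplotypes(sample)[[truthRow$haplotype]]
  retained <- if (identical(truthRow$category, "retains_intron"))
    truthRow$retained_bp else 0L
  tx <- .transcriptOf(hapSequence(hap), model, retained)
  substr(tx, truthRow$offset, truthRow$offset + readLength - 1L)
}
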