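# ISBT allele knowledge base with transfusion/RhIG management attributes.
#
# The "detected" block mirrors the alleles found in the 76-subject cohort
# and the family study; the "guidance" block carries the weak-D alleles
# managed as D positive under current guidance.  Management is total: every
# record has RhIG candidacy plus suggested donor and recipient phenotypes,
# and unknown lesions fall back to a conservative sentinel.

.SENTINEL_DESIGNATION <- "RHD*novel (unassigned)"

.kbRow <- function(designation, category, lesionType, lesionKey, label,
                   rhig, donor, recipient, altDesignation = NA_character_) {
  data.frame(designation = designation, alt_designation = altDesignation,
             category = category, lesion_type = lesionType,
             lesion_key = lesionKey, label = label,
             rhig_candidate = rhig, donor = donor, recipient = recipient,
             stringsAsFactors = FALSE)
}

.variantKey <- function(cdots) paste(sort(cdots), collapse = "+")

.buildAlleleKb <- function() {
  rows <- list(
    ## reference allele
    .kbRow("RHD*01", "normal", "none", "", "RHD+",
           FALSE, "Positive", "Positive"),
    ## detected alleles (management verified cell-for-cell against the
    ## published guidance table)
    .kbRow("RHD*01N.01", "null", "structural", "deletion", "RHD-",
           TRUE, "Negative", "Negative"),
    .kbRow("RHD*01N.03", "null", "structural", "hybrid_CE_2_9",
           "RHD-CE(2-9)-D", TRUE, "Negative", "Negative"),
    .kbRow("RHD*01EL.01", "el", "variants", .variantKey("c.1227G>A"),
           "1227G>A", FALSE, "Positive", "Positive"),
    .kbRow("RHD*06.03.01", "partial", "structural", "hybrid_CE_3_6",
           "DVI III", TRUE, "Positive", "Negative"),
    .kbRow("RHD*10.08", "partial", "variants", .variantKey("c.340C>T"),
           "340C>T", TRUE, "Positive", "Negative",
           altDesignation = "RHD*01W.17"),
    .kbRow("RHD*01EL.02", "el", "variants", .variantKey("c.3G>A"),
           "3G>A", TRUE, "Positive", "Negative"),
    .kbRow("RHD*01N.25", "null", "variants", .variantKey("c.336-1G>A"),
           "336-1G>A", TRUE, "Positive", "Negative"),
    ## kit classes without a cohort detection: kit label kept for DVa (no
    ## verified ISBT designation is attached), standard name for weak D15
    .kbRow("DVa(Hus)", "partial", "structural", "hybrid_CE_5",
           "DVa(Hus)", TRUE, "Positive", "Negative"),
    .kbRow("RHD*01W.15", "weak", "variants", .variantKey("c.845G>A"),
           "845G>A", TRUE, "Positive", "Negative"),
    ## guidance block: alleles managed as D positive
    .kbRow("RHD*01W.1", "weak", "variants", .variantKey("c.809T>G"),
           "809T>G", FALSE, "Positive", "Positive"),
    .kbRow("RHD*01W.1.1", "weak", "variants",
           .variantKey(c("c.52C>G", "c.712G>A")), "52C>G+712G>A",
           FALSE, "Positive", "Positive"),
    .kbRow("RHD*01W.2", "weak", "variants", .variantKey("c.1154G>C"),
           "1154G>C", FALSE, "Positive", "Positive"),
    .kbRow("RHD*01W.2.1", "weak", "variants", .variantKey("c.301T>A"),
           "301T>A", FALSE, "Positive", "Positive"),
    .kbRow("RHD*01W.2.2", "weak", "variants",
           .variantKey(c("c.916G>A", "c.932A>G")), "916G>A+932A>G",
           FALSE, "Positive", "Positive"),
    .kbRow("RHD*01W.3", "weak", "variants", .variantKey("c.8C>G"),
           "8C>G", FALSE, "Positive", "Positive"),
    .kbRow("RHD*01W.3.1", "weak", "variants", .variantKey("c.178A>C"),
           "178A>C", FALSE, "Positive", "Positive"),
    .kbRow("RHD*09.03.01", "partial", "variants",
           .variantKey(c("c.602C>G", "c.667T>G", "c.819G>A")),
           "602C>G+667T>G+819G>A", TRUE, "Positive", "Negative"),
    .kbRow("RHD*09.04", "partial", "variants",
           .variantKey(c("c.48G>C", "c.819G>A")), "48G>C+819G>A",
           FALSE, "Positive", "Positive")
  )
  kb <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(kb$designation))
  kb
}

#' The ISBT allele knowledge base
#'
#' One row per allele: ISBT designation (plus an alternate designation
#' where nomenclature lists two, e.g. RHD*10.08 / RHD*01W.17 for c.340C>T),
#' category, defining lesion (a structural class or a canonical sorted
#' variant-set key), a short label used in diploid genotype strings, and
#' the three management attributes (RhIG candidacy, suggested donor and
#' recipient phenotypes).
#'
#' @return data.frame; see Details.
#' @examples
#' kb <- alleleKb()
#' kb[kb$designation == "RHD*01EL.01", ]
#' @export
alleleKb <- function() {
  if (is.null(.rhdtyper_cache$kb)) .rhdtyper_cache$kb <- .buildAlleleKb()
  .rhdtyper_cache$kb
}

.sentinelRow <- function() {
  .kbRow(.SENTINEL_DESIGNATION, "novel", "sentinel", "", "novel",
         TRUE, "Positive", "Negative")
}

#' Look up the ISBT allele for a lesion
#'
#' A lesion is either a structural class name (\code{"deletion"},
#' \code{"hybrid_CE_2_9"}, \code{"hybrid_CE_3_6"}, \code{"hybrid_CE_5"}) or
#' a character vector of c. variant strings.  An empty variant vector is
#' the reference allele RHD*01.  The lookup is total: a lesion matching no
#' record returns the conservative sentinel ("novel/unassigned") rather
#' than failing.
#'
#' @param lesion structural class name or character vector of c. strings.
#' @return a one-row data.frame (a row of [alleleKb()] or the sentinel).
#' @examples
#' lookupAllele("c.1227G>A")$designation      # RHD*01EL.01
#' lookupAllele("c.336-1G>A")$designation     # RHD*01N.25
#' lookupAllele(character(0))$designation     # RHD*01
#' @export
lookupAllele <- function(lesion) {
  kb <- alleleKb()
  if (length(lesion) == 0L) {
    return(kb[kb$designation == "RHD*01", , drop = FALSE])
  }
  if (length(lesion) == 1L && !grepl("^c\\.", lesion)) {
    hit <- kb[kb$lesion_type == "structural" & kb$lesion_key == lesion, ,
              drop = FALSE]
    if (nrow(hit) == 1L) return(hit)
    return(.sentinelRow())
  }
  key <- .variantKey(lesion)
  hit <- kb[kb$lesion_type == "variants" & kb$lesion_key == key, ,
            drop = FALSE]
  if (nrow(hit) == 1L) return(hit)
  .sentinelRow()
}

#' Management advice for an allele
#'
#' Returns the transfusion/RhIG management attributes for an ISBT
#' designation (or a knowledge-base row).  The sentinel allele gets the
#' conservative default — RhIG candidate, manage as a positive donor and a
#' negative recipient — flagged for manual review.
#'
#' @param allele an ISBT designation string or a one-row knowledge-base
#'   data.frame as returned by [lookupAllele()].
#' @return list with \code{rhig_candidate} (logical), \code{donor},
#'   \code{recipient} (phenotype strings) and \code{manual_review}.
#' @examples
#' managementFor("RHD*01EL.01")   # not an RhIG candidate
#' managementFor("RHD*01N.01")    # RhIG candidate, Negative/Negative
#' @export
managementFor <- function(allele) {
  if (is.data.frame(allele)) {
    row <- allele
  } else {
    kb <- alleleKb()
    row <- kb[kb$designation == allele, , drop = FALSE]
    if (nrow(row) == 0L && identical(allele, .SENTINEL_DESIGNATION))
      row <- .sentinelRow()
    if (nrow(row) == 0L) row <- .sentinelRow()
  }
  list(rhig_candidate = row$rhig_candidate[1L],
       donor          = row$donor[1L],
       recipient      = row$recipient[1L],
       manual_review  = identical(row$designation[1L], .SENTINEL_DESIGNATION))
}

#' Short genotype-string label for an allele designation
#' @param designation ISBT designation string.
#' @return label such as \code{"RHD+"}, \code{"336-1G>A"}.
#' @export
alleleLabel <- function(designation) {
  kb <- alleleKb()
  hit <- kb$label[kb$designation == designation]
  if (length(hit) == 1L) hit else "novel"
}
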