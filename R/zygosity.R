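# Rhesus-box zygosity typing.  Deletion haplotypes carry a hybrid Rhesus
# box; its 2,700 bp amplicon (with a 1,009 bp internal control) diagnoses
# complete RHD gene deletion, and combining box status with per-haplotype
# allele calls yields the diploid genotype string.

#' Simulate the hybrid Rhesus box PCR
#'
#' Two primer pairs: one amplifying the 2,700 bp hybrid-box product (only
#' present on a deletion haplotype's box construct) and one amplifying the
#' 1,009 bp internal control.
#'
#' @param sample an \linkS4class{RhdSample}.
#' @param locusSet the \linkS4class{RhdLocusSet}.
#' @return list: \code{hybrid_product} (logical), \code{hybrid_size} (2700
#'   or NA), \code{control_product} (logical), \code{control_size}.
#' @examples
#' simulateBoxPcr(makeSample("deletion_hom"))$hybrid_product  # TRUE
#' @export
simulateBoxPcr <- function(sample, locusSet = rhdLocusSet()) {
  panel <- defaultPanel(locusSet)
  boxWell <- panel[panel$well == 7L, ]
  tmpl <- .sampleTemplates(sample, locusSet)
  hybrid <- any(vapply(tmpl, function(t)
    .pairAmplifies(boxWell$fwd, boxWell$rev, t, boxWell$product_size),
    logical(1)))
  control <- .pairAmplifies(boxWell$control_fwd, boxWell$control_rev,
                            tmpl$control, boxWell$control_size)
  list(hybrid_product = hybrid,
       hybrid_size = if (hybrid) 2700L else NA_integer_,
       control_product = control, control_size = 1009L)
}

#' Combine box status and allele calls into a diploid genotype string
#'
#' Interpretation rules: a hybrid box plus one variant allele gives
#' \code{"RHD-/<variant>"}; a hybrid box plus only normal RHD products
#' gives \code{"RHD+/RHD-"}; a hybrid box with no RHD products at all is a
#' deletion homozygote \code{"RHD-/RHD-"}; without a hybrid box the two
#' per-haplotype calls are reported directly (\code{"RHD+/RHD+"},
#' \code{"RHD+/<variant>"}, or \code{"<variant>/<variant>"}).
#'
#' @param box result of [simulateBoxPcr()] (or a logical scalar giving
#'   hybrid-box status, in which case the control is assumed valid).
#' @param alleleCalls character vector of ISBT designations, one per
#'   haplotype that produced amplicons (deletion haplotypes contribute
#'   none).
#' @return the diploid genotype string.
#' @section Errors:
#' A missing control raises an assay-invalid error; an absent hybrid box
#' combined with zero RHD allele calls is contradictory evidence and
#' raises an inconsistency error.
#' @examples
#' combineZygosity(TRUE, "RHD*01N.25")            # "RHD-/336-1G>A"
#' combineZygosity(FALSE, c("RHD*01", "RHD*01N.25"))  # "RHD+/336-1G>A"
#' @export
combineZygosity <- function(box, alleleCalls) {
  if (is.list(box)) {
    if (!isTRUE(box$control_product)) {
      stop(errorCondition("assay invalid: Rhesus-box internal control absent",
                          class = c("rhdAssayInvalidError", "error",
                                    "condition")))
    }
    hybrid <- isTRUE(box$hybrid_product)
  } else {
    hybrid <- isTRUE(box)
  }
  labels <- vapply(alleleCalls, alleleLabel, character(1), USE.NAMES = FALSE)
  variantLabels <- labels[labels != "RHD+"]
  nNormal <- sum(labels == "RHD+")
  if (hybrid) {
    if (length(variantLabels) >= 1L) return(paste0("RHD-/", variantLabels[1L]))
    if (nNormal >= 1L) return("RHD+/RHD-")
    return("RHD-/RHD-")
  }
  if (length(labels) == 0L) {
    stop(errorCondition(
      paste("inconsistent evidence: no hybrid Rhesus box detected but no",
            "RHD amplification products either"),
      class = c("rhdInconsistencyError", "error", "condition")))
  }
  if (length(variantLabels) == 0L) return("RHD+/RHD+")
  if (nNormal >= 1L) return(paste0("RHD+/", variantLabels[1L]))
  if (length(variantLabels) >= 2L)
    return(paste(variantLabels[1L], variantLabels[2L], sep = "/"))
  paste(variantLabels[1L], variantLabels[1L], sep = "/")
}

#' The documented zygosity truth table
#'
#' Reads the packaged JSON truth table enumerating the nine diploid
#' combinations of {intact, deletion, variant} haplotypes, the expected
#' hybrid-box status and the expected diploid call (with the c.336-1G>A
#' splice allele as the worked variant).
#'
#' @return data.frame: \code{hapA}, \code{hapB}, \code{hybrid_box},
#'   \code{diploid_call}.
#' @export
zygosityTruthTable <- function() {
  path <- system.file("extdata", "zygosity_truth.json",
                      package = "rhdtyper", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)$cases
}
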