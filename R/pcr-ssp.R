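# In-silico eight-well PCR-SSP assay.
#
# A specific band forms when both primers of a well match a template
# exactly (allele-specific primers carry the discriminating base at the 3'
# terminus; since matching is exact over the whole footprint, any covered
# mismatch — 3'-terminal or internal — kills the product) in convergent
# orientation within 1.5x the expected product size.  Every well carries an
# internal-control primer pair against a constant control locus.

.PRIMER_LEN <- 20L

## forward primer whose 3' end is at locus position `end3`
.fwdPrimerAt <- function(seqchar, end3, len = .PRIMER_LEN) {
  substr(seqchar, end3 - len + 1L, end3)
}

## reverse primer whose 3' end anneals at locus position `start3`
.revPrimerAt <- function(seqchar, start3, len = .PRIMER_LEN) {
  revComp(substr(seqchar, start3, start3 + len - 1L))
}

## reverse primer for an allele-specific 3' base `alt` at `start3`
.revPrimerAllele <- function(seqchar, start3, alt, len = .PRIMER_LEN) {
  revComp(paste0(alt, substr(seqchar, start3 + 1L, start3 + len - 1L)))
}

#' The default eight-well PCR-SSP panel
#'
#' Wells 1-4 test RHD exon presence (exons 1, 3, 5, 7; each primer
#' footprint covers an RHD-vs-RHCE diagnostic base or RHD intron/flank
#' sequence, so RHCE and hybrid exons never amplify).  The exon-1 primer
#' ends at c.3 and the exon-3 primer spans the intron-2 acceptor ending at
#' c.340, so the cohort's three point mutations (c.3G>A, c.340C>T,
#' c.336-1G>A) each extinguish a presence well and drop the pattern out of
#' every kit signature.  Wells 5/6 are the c.1227 G/A allele-specific pair,
#' well 7 amplifies the hybrid Rhesus box (RHD deletion), and well 8 is the
#' c.845A allele-specific well (weak D15).
#'
#' @param locusSet the \linkS4class{RhdLocusSet} the primers are designed
#'   against.
#' @return data.frame with one row per well: \code{well}, \code{target},
#'   \code{fwd}, \code{rev}, \code{product_size}, plus the shared control
#'   primers \code{control_fwd}, \code{control_rev}, \code{control_size}.
#' @export
defaultPanel <- function(locusSet = rhdLocusSet()) {
  if (!is.null(.rhdtyper_cache$panel)) return(.rhdtyper_cache$panel)
  model <- rhdModel(locusSet)
  s <- as.character(modelSequence(model))
  g <- function(cds, off = 0L) cdsToGenomic(model, cds, off)
  len <- .PRIMER_LEN
  well <- function(id, target, fwd3, rev3, alt = NULL) {
    fwd <- .fwdPrimerAt(s, g(fwd3))
    rev <- if (is.null(alt)) .revPrimerAt(s, g(rev3))
           else .revPrimerAllele(s, g(rev3), alt)
    size <- (g(rev3) + len - 1L) - (g(fwd3) - len + 1L) + 1L
    data.frame(well = id, target = target, fwd = fwd, rev = rev,
               product_size = size, stringsAsFactors = FALSE)
  }
  hyb <- rhesusBoxes(locusSet)$hybrid
  boxFwd <- substr(hyb, 101L, 120L)
  boxRev <- revComp(substr(hyb, 2781L, 2800L))
  panel <- rbind(
    well(1L, "RHD exon 1 presence", 3L, 120L),
    well(2L, "RHD exon 3 presence (acceptor-spanning)", 340L, 460L),
    well(3L, "RHD exon 5 presence", 654L, 770L),
    well(4L, "RHD exon 7 presence", 960L, 1050L),
    well(5L, "c.1227G allele-specific", 1173L, 1227L, alt = "G"),
    well(6L, "c.1227A allele-specific", 1173L, 1227L, alt = "A"),
    data.frame(well = 7L, target = "hybrid Rhesus box (RHD deletion)",
               fwd = boxFwd, rev = boxRev, product_size = 2700L,
               stringsAsFactors = FALSE),
    well(8L, "c.845A allele-specific (weak D15)", 821L, 845L, alt = "A")
  )
  ctrl <- locusSet@control
  panel$control_fwd  <- substr(ctrl, 96L, 115L)
  panel$control_rev  <- revComp(substr(ctrl, 1085L, 1104L))
  panel$control_size <- 1009L
  .rhdtyper_cache$panel <- panel
  panel
}

## does a primer pair yield a product on a template within the size window?
.pairAmplifies <- function(fwd, rev, template, expectedSize) {
  if (!nzchar(template)) return(FALSE)
  fpos <- findExact(fwd, template)
  if (length(fpos) == 0L) return(FALSE)
  rsite <- revComp(rev)
  rpos <- findExact(rsite, template)
  if (length(rpos) == 0L) return(FALSE)
  maxSize <- 1.5 * expectedSize
  for (i in fpos) {
    ends <- rpos + nchar(rsite) - 1L
    size <- ends - i + 1L
    if (any(rpos >= i & size >= nchar(fwd) + nchar(rsite) & size <= maxSize))
      return(TRUE)
  }
  FALSE
}

## all template sequences carried by a sample's genome (both RHD-locus
## haplotypes, the ever-present RHCE background, the Rhesus-box constructs
## of each haplotype, and the internal control)
.sampleTemplates <- function(sample, locusSet) {
  haps <- haplotypes(sample)
  boxes <- rhesusBoxes(locusSet)
  tmpl <- list(rhce1 = as.character(modelSequence(rhceModel(locusSet))),
               rhce2 = as.character(modelSequence(rhceModel(locusSet))),
               control = locusSet@control)
  for (nm in names(haps)) {
    h <- haps[[nm]]
    tmpl[[paste0("locus_", nm)]] <- hapSequence(h)
    if (rhesusBoxType(h) == "hybrid") {
      tmpl[[paste0("box_", nm)]] <- boxes$hybrid
    } else {
      tmpl[[paste0("boxU_", nm)]] <- boxes$upstream
      tmpl[[paste0("boxD_", nm)]] <- boxes$downstream
    }
  }
  tmpl
}

#' Simulate the PCR-SSP assay on a diploid sample
#'
#' @param sample an \linkS4class{RhdSample}.
#' @param panel primer panel data.frame; defaults to [defaultPanel()].
#' @param locusSet the \linkS4class{RhdLocusSet}.
#' @return a band pattern: data.frame with columns \code{well},
#'   \code{target}, \code{specific}, \code{control}.
#' @examples
#' simulatePcrSsp(makeSample("deletion_hom"))
#' @export
simulatePcrSsp <- function(sample, panel = NULL,
                           locusSet = rhdLocusSet()) {
  if (is.null(panel)) panel <- defaultPanel(locusSet)
  if (nrow(panel) != 8L) stop("the panel must have exactly 8 wells")
  tmpl <- .sampleTemplates(sample, locusSet)
  specific <- logical(8L)
  control <- logical(8L)
  for (i in seq_len(8L)) {
    specific[i] <- any(vapply(tmpl, function(t)
      .pairAmplifies(panel$fwd[i], panel$rev[i], t, panel$product_size[i]),
      logical(1)))
    control[i] <- .pairAmplifies(panel$control_fwd[i], panel$control_rev[i],
                                 tmpl$control, panel$control_size[i])
  }
  data.frame(well = panel$well, target = panel$target,
             specific = specific, control = control,
             stringsAsFactors = FALSE)
}

#' The kit's signature table
#'
#' Loaded from the packaged JSON (\code{extdata/pcr_ssp_signatures.json});
#' the table is data, not code, so alternative kit layouts are pluggable.
#' Each signature gives the expected specific-band state of the 8 wells as
#' \code{"+"}, \code{"-"} or \code{"*"} (either).
#'
#' @param path optional path to an alternative signature JSON.
#' @return named list: kit genotype class -> character vector of 8 states.
#' @export
defaultSignatures <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.rhdtyper_cache$signatures)) return(.rhdtyper_cache$signatures)
    path <- system.file("extdata", "pcr_ssp_signatures.json",
                        package = "rhdtyper", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sigs <- lapply(raw$classes, function(x)
    unlist(x, use.names = TRUE)[as.character(1:8)])
  if (is.null(.rhdtyper_cache$signatures))
    .rhdtyper_cache$signatures <- sigs
  sigs
}

#' Interpret a band pattern into a kit genotype class
#'
#' @param pattern band-pattern data.frame from [simulatePcrSsp()].
#' @param signatures signature table from [defaultSignatures()].
#' @return the kit class as a length-1 character (one of the 8 kit
#'   genotypes, or \code{"undetectable"} when no — or more than one —
#'   signature matches; ambiguity is flagged in the \code{"ambiguous"}
#'   attribute).
#' @section Errors:
#' A missing control band means the assay itself failed; this raises an
#' error of class \code{rhdAssayInvalidError}, distinct from an
#' undetectable genotype.
#' @examples
#' interpretBandPattern(simulatePcrSsp(makeSample("deletion_hom")))
#' @export
interpretBandPattern <- function(pattern, signatures = defaultSignatures()) {
  stopifnot(is.data.frame(pattern), nrow(pattern) == 8L)
  if (!all(pattern$control)) {
    stop(errorCondition(
      "assay invalid: internal control band missing in at least one well",
      class = c("rhdAssayInvalidError", "error", "condition")))
  }
  obs <- ifelse(pattern$specific[order(pattern$well)], "+", "-")
  hits <- names(signatures)[vapply(signatures, function(sig)
    all(sig == "*" | sig == obs), logical(1))]
  if (length(hits) == 1L) {
    return(structure(hits, ambiguous = FALSE))
  }
  structure("undetectable", ambiguous = length(hits) > 1L)
}

#' Simulate-then-interpret round trip for a kit genotype class
#'
#' @param kitClass one of the 8 kit genotype classes.
#' @param locusSet the \linkS4class{RhdLocusSet}.
#' @return TRUE iff simulating a representative sample of the class and
#'   interpreting its band pattern returns the same class.
#' @export
roundtripCheck <- function(kitClass, locusSet = rhdLocusSet()) {
  rep <- c(RHD_positive = "intact", RHD_deletion = "deletion_hom",
           RHD_CE_2_9_D = "CE29_carrier", DVa_Hus = "DVa_Hus",
           DVI_III = "DVI_III", weakD15 = "weakD15",
           DEL_1227A_hom = "1227A_hom", DEL_1227A_het = "1227A_het")
  if (!kitClass %in% names(rep))
    stop("not a kit genotype class: ", kitClass)
  s <- makeSample(rep[[kitClass]], locusSet = locusSet)
  call <- interpretBandPattern(simulatePcrSsp(s, locusSet = locusSet))
  identical(as.character(call), kitClass)
}
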