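# The diagnostic decision tree: PCR-SSP first; samples the kit cannot
# classify go to 10-exon sequencing with ISBT allele assignment; zygosity
# typing resolves the diploid genotype when a variant allele is found.
# Every diagnosis carries management advice; anything unresolved after
# both tiers is referred for extended analysis under the conservative
# sentinel management.

## kit class -> supporting ISBT designations (first = management source)
.CLASS_ALLELES <- list(
  RHD_positive  = "RHD*01",
  RHD_deletion  = "RHD*01N.01",
  RHD_CE_2_9_D  = "RHD*01N.03",
  DVa_Hus       = "DVa(Hus)",
  DVI_III       = "RHD*06.03.01",
  weakD15       = "RHD*01W.15",
  DEL_1227A_hom = "RHD*01EL.01",
  DEL_1227A_het = c("RHD*01EL.01", "RHD*01N.01")
)

#' Run the diagnostic decision tree on one sample
#'
#' Stage 1 simulates and interprets the PCR-SSP assay; a definitive kit
#' class stops there (the tree never sequences a sample the kit already
#' classified).  An undetectable pattern goes to stage 2: 10-exon
#' amplicons, variant calls and ISBT allele assignment per haplotype.
#' Stage 3 (Rhesus-box zygosity) runs when a variant allele needs diploid
#' resolution (\code{zygosity = "auto"}), always, or never.
#'
#' @param sample an \linkS4class{RhdSample}.
#' @param locusSet the \linkS4class{RhdLocusSet}.
#' @param panel,signatures PCR-SSP panel and signature table; package
#'   defaults when NULL.
#' @param zygosity \code{"auto"} (default), \code{"always"} or
#'   \code{"never"}.
#' @return a \linkS4class{Diagnosis}.
#' @examples
#' diagnose(makeSample("deletion_hom"))
#' diagnose(makeSample("c340T"))
#' @export
diagnose <- function(sample, locusSet = rhdLocusSet(), panel = NULL,
                     signatures = NULL,
                     zygosity = c("auto", "always", "never")) {
  zygosity <- match.arg(zygosity)
  if (is.null(panel)) panel <- defaultPanel(locusSet)
  if (is.null(signatures)) signatures <- defaultSignatures()
  notes <- character(0)

  pattern <- simulatePcrSsp(sample, panel, locusSet)
  call <- interpretBandPattern(pattern, signatures)   # assay-invalid errors propagate
  notes <- c(notes, paste0("tier1:pcr_ssp=", as.character(call)))

  if (!identical(as.character(call), "undetectable")) {
    alleles <- .CLASS_ALLELES[[as.character(call)]]
    zcall <- NA_character_
    if (zygosity == "always") {
      box <- simulateBoxPcr(sample, locusSet)
      zcall <- combineZygosity(box, alleles)
      notes <- c(notes, paste0("zygosity:", zcall))
    }
    return(new("Diagnosis", sampleId = sampleId(sample), tier = "pcr_ssp",
               genotypeCall = as.character(call), isbtAlleles = alleles,
               zygosityCall = zcall,
               management = managementFor(alleles[1L]), notes = notes))
  }

  ## stage 2: 10-exon sequencing
  amplicons <- extractAmplicons(sample, rhdModel(locusSet))
  calls <- callVariants(amplicons, rhdModel(locusSet))
  perHap <- lapply(split(calls, calls$haplotype), assignAllele)
  ampHaps <- unique(amplicons$haplotype)
  for (h in setdiff(ampHaps, names(perHap))) {
    perHap[[h]] <- assignAllele(character(0))    # reference haplotype
  }
  designations <- vapply(perHap, function(x) x$designation, character(1))
  notes <- c(notes, paste0("tier2:sanger=",
                           paste(sort(designations), collapse = "+")))

  variantAlleles <- designations[designations != "RHD*01"]
  unresolved <- length(designations) == 0L ||
    all(designations == .SENTINEL_DESIGNATION)

  zcall <- NA_character_
  if (zygosity == "always" ||
      (zygosity == "auto" && length(designations) > 0L)) {
    box <- simulateBoxPcr(sample, locusSet)
    zcall <- tryCatch(combineZygosity(box, designations),
                      rhdInconsistencyError = function(e) NA_character_)
    if (!is.na(zcall)) notes <- c(notes, paste0("zygosity:", zcall))
  }

  if (unresolved) {
    notes <- c(notes, "unresolved: refer for extended analysis")
    mg <- managementFor(.sentinelRow())
    return(new("Diagnosis", sampleId = sampleId(sample), tier = "unresolved",
               genotypeCall = if (is.na(zcall)) "unresolved" else zcall,
               isbtAlleles = unique(designations),
               zygosityCall = zcall, management = mg, notes = notes))
  }

  primary <- if (length(variantAlleles)) variantAlleles[1L]
             else designations[1L]
  mg <- managementFor(primary)
  if (identical(primary, .SENTINEL_DESIGNATION))
    notes <- c(notes, "manual review: variant set matches no known allele")
  genotype <- if (!is.na(zcall)) zcall
              else paste(sort(designations), collapse = "/")
  new("Diagnosis", sampleId = sampleId(sample), tier = "sanger",
      genotypeCall = genotype, isbtAlleles = unique(designations),
      zygosityCall = zcall, management = mg, notes = notes)
}

#' Summarize a cohort of diagnoses
#'
#' Tier-1 genotype-class counts and percentages (undetectable samples are
#' tabulated as \code{"undetectable"}), the tier-1 and total
#' identification rates, and the fraction of women whose management marks
#' them not candidates for RhIG.  Percentages are reported to one decimal
#' place.
#'
#' @param diagnoses list of \linkS4class{Diagnosis} objects.
#' @return a \linkS4class{CohortSummary}.
#' @export
summarizeCohort <- function(diagnoses) {
  if (length(diagnoses) == 0L) stop("cannot summarize an empty cohort")
  n <- length(diagnoses)
  tier1Class <- vapply(diagnoses, function(d)
    if (identical(tier(d), "pcr_ssp")) genotypeCall(d) else "undetectable",
    character(1))
  tab <- as.data.frame(table(class = tier1Class), stringsAsFactors = FALSE)
  names(tab) <- c("class", "n")
  tab$pct <- round(100 * tab$n / n, 1L)
  tab <- tab[order(-tab$n), , drop = FALSE]
  rownames(tab) <- NULL
  tiers <- vapply(diagnoses, tier, character(1))
  rhig <- vapply(diagnoses, function(d)
    isTRUE(management(d)$rhig_candidate), logical(1))
  new("CohortSummary",
      classTable = tab,
      pctIdentifiedPcrSsp = round(100 * mean(tiers == "pcr_ssp"), 1L),
      pctIdentifiedTotal  = round(100 * mean(tiers != "unresolved"), 1L),
      pctRhigExempt       = round(100 * mean(!rhig), 1L),
      nSamples = as.integer(n))
}

#' Full molecular work-up of the family fixture
#'
#' Runs the sequencing tier and Rhesus-box zygosity on every family member
#' (the family study typed all members regardless of kit classification)
#' and returns the diploid genotype strings next to the study-reported
#' expectations.
#'
#' @param family result of [makeFamily()].
#' @param locusSet the \linkS4class{RhdLocusSet}.
#' @return data.frame: \code{member}, \code{diploid_call},
#'   \code{expected_genotype}, \code{concordant} (NA where no expectation
#'   was reported).
#' @export
typeFamily <- function(family, locusSet = rhdLocusSet()) {
  model <- rhdModel(locusSet)
  calls <- vapply(family$samples, function(s) {
    amplicons <- extractAmplicons(s, model)
    vars <- callVariants(amplicons, model)
    perHap <- lapply(split(vars, vars$haplotype), assignAllele)
    for (h in setdiff(unique(amplicons$haplotype), names(perHap))) {
      perHap[[h]] <- assignAllele(character(0))
    }
    designations <- vapply(perHap, function(x) x$designation, character(1))
    box <- simulateBoxPcr(s, locusSet)
    combineZygosity(box, designations)
  }, character(1))
  out <- family$pedigree
  out$diploid_call <- unname(calls[out$member])
  out$concordant <- ifelse(is.na(out$expected_genotype), NA,
                           out$diploid_call == out$expected_genotype)
  out[, c("member", "diploid_call", "expected_genotype", "concordant")]
}
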