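# Synthetic diploid samples: haplotype realization, named genotypes,
# cohorts with the study composition, and the c.336-1G>A family.

.GENOTYPE_DEFS <- list(
  intact          = list(a = list(class = "intact"),
                         b = list(class = "intact"),        serology = "D_pos"),
  intact_het      = list(a = list(class = "intact"),
                         b = list(class = "deletion"),      serology = "D_pos"),
  deletion_hom    = list(a = list(class = "deletion"),
                         b = list(class = "deletion"),      serology = "D_neg"),
  CE29_carrier    = list(a = list(class = "hybrid_CE_2_9"),
                         b = list(class = "deletion"),      serology = "D_neg"),
  `1227A_hom`     = list(a = list(class = "intact", variants = "c.1227G>A"),
                         b = list(class = "intact", variants = "c.1227G>A"),
                         serology = "DEL"),
  `1227A_het`     = list(a = list(class = "intact", variants = "c.1227G>A"),
                         b = list(class = "deletion"),      serology = "DEL"),
  DVI_III         = list(a = list(class = "hybrid_CE_3_6"),
                         b = list(class = "deletion"),      serology = "D_neg"),
  DVa_Hus         = list(a = list(class = "hybrid_CE_5"),
                         b = list(class = "deletion"),      serology = "D_neg"),
  weakD15         = list(a = list(class = "intact", variants = "c.845G>A"),
                         b = list(class = "deletion"),      serology = "D_neg"),
  c340T           = list(a = list(class = "intact", variants = "c.340C>T"),
                         b = list(class = "deletion"),      serology = "D_neg"),
  c3A             = list(a = list(class = "intact", variants = "c.3G>A"),
                         b = list(class = "deletion"),      serology = "D_neg"),
  c336_1A_het_del = list(a = list(class = "deletion"),
                         b = list(class = "intact", variants = "c.336-1G>A"),
                         serology = "D_neg")
)

#' Genotype labels understood by the sample generator
#' @return character vector of labels accepted by [makeSample()].
#' @export
genotypeNames <- function() names(.GENOTYPE_DEFS)

#' Realize one haplotype of the RHD locus
#'
#' Builds the chromosome-level sequence for a structural class, applies
#' point variants, and attaches the matching Rhesus-box type (a deletion
#' haplotype carries the hybrid box and an empty locus sequence; hybrid
#' RHD-CE classes carry RHCE sequence at the diagnostic positions of the
#' replaced exons and RHD sequence elsewhere).
#'
#' @param structuralClass one of \code{"intact"}, \code{"deletion"},
#'   \code{"hybrid_CE_2_9"}, \code{"hybrid_CE_3_6"}, \code{"hybrid_CE_5"}.
#' @param variants character vector of c. variant strings (must be empty
#'   for a deletion).
#' @param locusSet the \linkS4class{RhdLocusSet} to realize against.
#' @return a \linkS4class{Haplotype}.
#' @export
makeHaplotype <- function(structuralClass = "intact", variants = character(0),
                          locusSet = rhdLocusSet()) {
  model <- rhdModel(locusSet)
  emptyVar <- variantTableFromCdot(model, character(0))
  if (structuralClass == "deletion") {
    if (length(variants) > 0L)
      stop("a deletion haplotype cannot carry point variants")
    return(new("Haplotype", structuralClass = "deletion", variants = emptyVar,
               rhesusBox = "hybrid", sequence = ""))
  }
  replaced <- switch(structuralClass,
    intact        = integer(0),
    hybrid_CE_2_9 = 2:9,
    hybrid_CE_3_6 = 3:6,
    hybrid_CE_5   = 5L,
    stop("unknown structural class: ", structuralClass)
  )
  seqchar <- as.character(modelSequence(model))
  for (k in replaced) {
    for (pos in diagnosticPositions(locusSet)[[k]]) {
      g <- cdsToGenomic(model, pos)
      seqchar <- substrReplace(seqchar, g, swapBase(substr(seqchar, g, g)))
    }
  }
  vt <- variantTableFromCdot(model, variants)
  for (i in seq_len(nrow(vt))) {
    g <- cdsToGenomic(model, vt$cds[i], vt$offset[i])
    if (substr(seqchar, g, g) != vt$ref[i])
      stop("variant ", vt$cdot[i], " collides with the structural class")
    seqchar <- substrReplace(seqchar, g, vt$alt[i])
  }
  new("Haplotype", structuralClass = structuralClass, variants = vt,
      rhesusBox = "intact", sequence = seqchar)
}

#' A canonical key identifying a haplotype's lesion (used for Mendelian
#' transmission checks)
#' @param hap a \linkS4class{Haplotype}.
#' @export
haplotypeKey <- function(hap) {
  paste(structuralClass(hap),
        paste(sort(variantTable(hap)$cdot), collapse = "+"),
        rhesusBoxType(hap), sep = "|")
}

#' Generate one diploid sample from a named genotype
#'
#' The generator is deterministic: sequences are fully determined by the
#' locus set and the genotype label, so a fixed \code{seed} always yields a
#' bitwise-identical sample.
#'
#' @param genotypeName one of [genotypeNames()], e.g. \code{"deletion_hom"},
#'   \code{"1227A_hom"}, \code{"c336_1A_het_del"}.
#' @param seed integer seed (kept for interface symmetry with the other
#'   generators; sample realization is deterministic given the label).
#' @param sampleId identifier; defaults to the genotype label.
#' @param locusSet the \linkS4class{RhdLocusSet}.
#' @return an \linkS4class{RhdSample}.
#' @examples
#' s <- makeSample("c336_1A_het_del")
#' haplotypes(s)$B
#' @export
makeSample <- function(genotypeName, seed = 42L, sampleId = genotypeName,
                       locusSet = rhdLocusSet()) {
  def <- .GENOTYPE_DEFS[[genotypeName]]
  if (is.null(def))
    stop("configuration error: unknown genotype label '", genotypeName,
         "'; see genotypeNames()")
  mk <- function(h) makeHaplotype(h$class,
                                  if (is.null(h$variants)) character(0)
                                  else h$variants,
                                  locusSet)
  new("RhdSample", sampleId = sampleId, genotypeName = genotypeName,
      haplotypeA = mk(def$a), haplotypeB = mk(def$b),
      serologyLabel = def$serology)
}

#' Default cohort composition
#'
#' Genotype counts of the 76-subject RhD-negative pregnancy cohort: 48 RHD
#' deletion homozygotes, 11 RHD-CE(2-9)-D carriers, 12 RHD 1227A
#' homozygotes, 2 DVI III, and one each of the three point-mutation cases
#' (c.340C>T, c.3G>A, c.336-1G>A over a deletion).
#'
#' @return named integer vector of counts (sums to 76).
#' @export
defaultCohortCounts <- function() {
  c(deletion_hom = 48L, CE29_carrier = 11L, `1227A_hom` = 12L,
    DVI_III = 2L, c340T = 1L, c3A = 1L, c336_1A_het_del = 1L)
}

#' Generate a cohort of diploid samples
#'
#' @param counts named integer vector: genotype label -> number of samples.
#' @param seed integer seed controlling the (deterministic) shuffle.
#' @param locusSet the \linkS4class{RhdLocusSet}.
#' @return list of \linkS4class{RhdSample}s, of length \code{sum(counts)}.
#' @examples
#' cohort <- makeCohort(c(deletion_hom = 2, `1227A_hom` = 1), seed = 1)
#' @export
makeCohort <- function(counts = defaultCohortCounts(), seed = 42L,
                       locusSet = rhdLocusSet()) {
  stopifnot(all(counts >= 0))
  labels <- rep(names(counts), times = counts)
  if (length(labels) == 0L) return(list())
  labels <- withSeed(seed, sample(labels))
  ids <- sprintf("S%03d", seq_along(labels))
  mapply(function(lab, id) makeSample(lab, seed = seed, sampleId = id,
                                      locusSet = locusSet),
         labels, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' The c.336-1G>A family
#'
#' Builds the two-generation pedigree around the splice-mutation proband:
#' generation II couples (II-1 x II-2 and II-3 x II-4) and their children
#' (III-1, III-3 and III-5 proband, III-7), with haplotypes transmitted
#' Mendelianly.  The expected diploid genotype strings of the serologically
#' typed members are attached for downstream checks.
#'
#' @param seed integer seed (pedigree structure is fixed; kept for
#'   interface symmetry).
#' @param locusSet the \linkS4class{RhdLocusSet}.
#' @return list with \code{samples} (named list of \linkS4class{RhdSample})
#'   and \code{pedigree} (data.frame: member, father, mother, serology,
#'   expected_genotype; \code{NA} where the study reported none).
#' @export
makeFamily <- function(seed = 42L, locusSet = rhdLocusSet()) {
  intact <- makeHaplotype("intact", locusSet = locusSet)
  del    <- makeHaplotype("deletion", locusSet = locusSet)
  splice <- makeHaplotype("intact", "c.336-1G>A", locusSet = locusSet)
  mk <- function(id, hapA, hapB, serology) {
    new("RhdSample", sampleId = id, genotypeName = "family",
        haplotypeA = hapA, haplotypeB = hapB, serologyLabel = serology)
  }
  samples <- list(
    `II-1`  = mk("II-1", intact, del,    "D_pos"),
    `II-2`  = mk("II-2", intact, splice, "D_pos"),
    `II-3`  = mk("II-3", intact, splice, "D_pos"),
    `II-4`  = mk("II-4", intact, del,    "D_pos"),
    `III-1` = mk("III-1", del,   splice, "D_neg"),  # from II-1 x II-2
    `III-3` = mk("III-3", del,   splice, "D_neg"),  # from II-1 x II-2
    `III-5` = mk("III-5", splice, del,   "D_neg"),  # proband, II-3 x II-4
    `III-7` = mk("III-7", intact, del,   "D_pos")   # from II-3 x II-4
  )
  pedigree <- data.frame(
    member   = names(samples),
    father   = c(NA, NA, NA, NA, "II-1", "II-1", "II-3", "II-3"),
    mother   = c(NA, NA, NA, NA, "II-2", "II-2", "II-4", "II-4"),
    serology = vapply(samples, serologyLabel, character(1)),
    expected_genotype = c("RHD+/RHD-", "RHD+/336-1G>A", "RHD+/336-1G>A",
                          "RHD+/RHD-", "RHD-/336-1G>A", NA,
                          "RHD-/336-1G>A", NA),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(samples = samples, pedigree = pedigree)
}
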