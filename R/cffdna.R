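# Non-invasive fetal RHD genotyping from cell-free fetal DNA.
#
# The assay scores five RHD exons (1, 5, 6, 7, 9) as positive/negative in
# maternal plasma.  An exon is positive when the maternal genome itself
# carries the RHD exon, or when the fetal genome carries it and a
# fetal-fraction-dependent detection succeeds.  Interpretation is
# conditioned on the maternal genotype: for deletion-homozygous mothers
# every exon is informative; for RHD-CE(2-9)-D mothers exon 1 is maternal
# background and only exons 5, 6, 7, 9 are informative.  A first draw
# with all informative exons negative triggers resampling; only a second
# all-negative draw reports a D-negative fetus.

.CFF_EXONS <- c(1L, 5L, 6L, 7L, 9L)

## detection probability as a function of fetal fraction: a simple ramp
## with full sensitivity from 4% fetal fraction and none at 0
.pDetect <- function(fetalFraction) pmin(1, fetalFraction / 0.04)

## does any haplotype of the sample carry the RHD version of an exon?
.hasRhdExon <- function(sample, exon) {
  any(vapply(haplotypes(sample), function(h) {
    switch(structuralClass(h),
      deletion      = FALSE,
      intact        = TRUE,
      hybrid_CE_2_9 = exon %in% c(1L, 10L),
      hybrid_CE_3_6 = !exon %in% 3:6,
      hybrid_CE_5   = exon != 5L,
      FALSE)
  }, logical(1)))
}

#' Simulate a cffDNA exon-positivity assay
#'
#' @param maternal D-negative maternal \linkS4class{RhdSample}.
#' @param fetal fetal \linkS4class{RhdSample} (the truth).
#' @param fetalFraction fetal fraction of cell-free DNA, in [0, 0.3].
#' @param drawIndex 1 for the first plasma draw, 2 for a resample.
#' @param seed integer seed for the per-exon detection draws.
#' @return data.frame with one row per assayed exon: \code{exon},
#'   \code{positive}, \code{draw_index}, \code{fetal_fraction}.
#' @examples
#' makeCffdnaAssay(makeSample("deletion_hom"), makeSample("intact_het"),
#'                 fetalFraction = 0.1, seed = 1)
#' @export
makeCffdnaAssay <- function(maternal, fetal, fetalFraction, drawIndex = 1L,
                            seed = 42L) {
  if (serologyLabel(maternal) == "D_pos")
    stop("the cffDNA assay is defined for D-negative mothers")
  if (fetalFraction < 0 || fetalFraction > 0.3)
    stop("fetalFraction must be in [0, 0.3]")
  if (!drawIndex %in% c(1L, 2L)) stop("drawIndex must be 1 or 2")
  p <- .pDetect(fetalFraction)
  withSeed(seed, {
    pos <- vapply(.CFF_EXONS, function(e) {
      .hasRhdExon(maternal, e) ||
        (.hasRhdExon(fetal, e) && stats::runif(1) < p)
    }, logical(1))
    data.frame(exon = .CFF_EXONS, positive = pos,
               draw_index = as.integer(drawIndex),
               fetal_fraction = fetalFraction, stringsAsFactors = FALSE)
  })
}

#' Is a mother eligible for non-invasive fetal RHD genotyping?
#'
#' Fetal genotyping from maternal plasma is only feasible when the mother
#' carries no RHD sequence at the informative exons: deletion homozygotes
#' and RHD-CE(2-9)-D carriers qualify; every variant-allele mother (1227A,
#' point mutations) would produce false positives and is ineligible.
#'
#' @param maternalDiagnosis a \linkS4class{Diagnosis}, or a kit-class
#'   string.
#' @return logical.
#' @section Errors:
#' An unresolved diagnosis raises an eligibility error.
#' @examples
#' eligibleForNipt("RHD_deletion")    # TRUE
#' eligibleForNipt("DEL_1227A_hom")   # FALSE
#' @export
eligibleForNipt <- function(maternalDiagnosis) {
  cls <- if (methods::is(maternalDiagnosis, "Diagnosis")) {
    if (identical(tier(maternalDiagnosis), "unresolved"))
      stop("eligibility error: maternal diagnosis is unresolved")
    genotypeCall(maternalDiagnosis)
  } else maternalDiagnosis
  cls %in% c("RHD_deletion", "RHD_CE_2_9_D")
}

.informativeExons <- function(maternalClass) {
  switch(maternalClass,
    RHD_deletion = c(1L, 5L, 6L, 7L, 9L),
    RHD_CE_2_9_D = c(5L, 6L, 7L, 9L),
    stop("no informative-exon rule for maternal class ", maternalClass))
}

#' Predict fetal RhD status from one plasma draw
#'
#' The fetus is predicted RhD positive when any informative exon is
#' positive.  A first draw with all informative exons negative is not
#' reported negative: the action is \code{"resample"}; only an
#' all-negative second draw reports \code{"report_negative"}.
#'
#' @param assay data.frame from [makeCffdnaAssay()] (one draw; exon keys
#'   must be exactly 1, 5, 6, 7, 9).
#' @param maternalClass \code{"RHD_deletion"} or \code{"RHD_CE_2_9_D"}
#'   (or a \linkS4class{Diagnosis} whose call is one of those).
#' @return list: \code{prediction} (\code{"RhD_positive"},
#'   \code{"RhD_negative"}, \code{"uncertain"}), \code{action}
#'   (\code{"report_positive"}, \code{"resample"},
#'   \code{"report_negative"}), \code{informative_exons},
#'   \code{draw_index}.
#' @export
predictFetalRhd <- function(assay, maternalClass) {
  if (methods::is(maternalClass, "Diagnosis"))
    maternalClass <- genotypeCall(maternalClass)
  if (!eligibleForNipt(maternalClass))
    stop("maternal genotype ", maternalClass, " is not eligible for NIPT")
  if (!setequal(assay$exon, .CFF_EXONS) || nrow(assay) != 5L)
    stop("malformed assay: exon keys must be exactly {1, 5, 6, 7, 9}")
  info <- .informativeExons(maternalClass)
  drawIndex <- assay$draw_index[1L]
  anyPos <- any(assay$positive[assay$exon %in% info])
  if (anyPos) {
    return(list(prediction = "RhD_positive", action = "report_positive",
                informative_exons = info, draw_index = drawIndex))
  }
  if (drawIndex < 2L) {
    return(list(prediction = "uncertain", action = "resample",
                informative_exons = info, draw_index = drawIndex))
  }
  list(prediction = "RhD_negative", action = "report_negative",
       informative_exons = info, draw_index = drawIndex)
}

#' Build the NIPT cohort fixture
#'
#' 31 pregnancies — 28 deletion-homozygous and 3 RHD-CE(2-9)-D mothers,
#' every fetus truly D positive — yielding 33 plasma draws: two deletion
#' pregnancies are sampled in early gestation at a fetal fraction below
#' assay detection, give an all-negative first draw and are resampled a
#' few weeks later.
#'
#' @param seed integer seed driving fetal-fraction draws, the choice of
#'   resampled pregnancies and per-exon detection.
#' @param locusSet the \linkS4class{RhdLocusSet}.
#' @return list: \code{assays} (data.frame: \code{pregnancy_id},
#'   \code{maternal_class}, \code{draw_index}, \code{exon},
#'   \code{positive}, \code{fetal_fraction}) and \code{truth} (data.frame:
#'   \code{pregnancy_id}, \code{fetal_rhd_positive}).
#' @export
makeNiptFixture <- function(seed = 42L, locusSet = rhdLocusSet()) {
  motherDel <- makeSample("deletion_hom", locusSet = locusSet)
  motherCe  <- makeSample("CE29_carrier", locusSet = locusSet)
  fetus     <- makeSample("intact_het", locusSet = locusSet)
  ids <- sprintf("P%02d", 1:31)
  maternalClass <- c(rep("RHD_deletion", 28L), rep("RHD_CE_2_9_D", 3L))
  withSeed(seed, {
    resampled <- sample(ids[maternalClass == "RHD_deletion"], 2L)
    ffDraws <- stats::runif(33L, min = 0.06, max = 0.15)
    subSeeds <- sample.int(.Machine$integer.max, 33L)
  })
  assays <- list()
  j <- 0L
  for (i in seq_along(ids)) {
    mother <- if (maternalClass[i] == "RHD_deletion") motherDel else motherCe
    if (ids[i] %in% resampled) {
      j <- j + 1L
      a1 <- makeCffdnaAssay(mother, fetus, fetalFraction = 0,
                            drawIndex = 1L, seed = subSeeds[j])
      j <- j + 1L
      a2 <- makeCffdnaAssay(mother, fetus, fetalFraction = ffDraws[j],
                            drawIndex = 2L, seed = subSeeds[j])
      draws <- rbind(a1, a2)
    } else {
      j <- j + 1L
      draws <- makeCffdnaAssay(mother, fetus, fetalFraction = ffDraws[j],
                               drawIndex = 1L, seed = subSeeds[j])
    }
    draws$pregnancy_id <- ids[i]
    draws$maternal_class <- maternalClass[i]
    assays[[i]] <- draws
  }
  assays <- do.call(rbind, assays)
  assays <- assays[, c("pregnancy_id", "maternal_class", "draw_index",
                       "exon", "positive", "fetal_fraction")]
  list(assays = assays,
       truth = data.frame(pregnancy_id = ids, fetal_rhd_positive = TRUE,
                          stringsAsFactors = FALSE))
}

#' Interpret a cohort of cffDNA assays
#'
#' Applies [predictFetalRhd()] per draw in draw order and resolves each
#' pregnancy: positive at any draw reports positive; an all-negative first
#' draw requires a second draw (pregnancies left without one are
#' uncertain); an all-negative second draw reports negative.
#'
#' @param assays long-format assay data.frame as produced by
#'   [makeNiptFixture()] (\code{pregnancy_id}, \code{maternal_class},
#'   \code{draw_index}, \code{exon}, \code{positive}).
#' @param truth optional data.frame (\code{pregnancy_id},
#'   \code{fetal_rhd_positive}) for concordance.
#' @return list: \code{per_pregnancy} (data.frame: \code{pregnancy_id},
#'   \code{maternal_class}, \code{n_draws}, \code{resampled},
#'   \code{prediction}) and \code{summary} (list of counts:
#'   \code{n_pregnancies}, \code{n_plasma_samples}, \code{n_positive},
#'   \code{n_negative}, \code{n_uncertain}, \code{n_resampled}, counts by
#'   maternal class, and \code{concordance} when truth is given).
#' @export
runNiptCohort <- function(assays, truth = NULL) {
  per <- lapply(split(assays, assays$pregnancy_id), function(d) {
    cls <- d$maternal_class[1L]
    final <- "uncertain"
    resampled <- FALSE
    for (dr in sort(unique(d$draw_index))) {
      res <- predictFetalRhd(d[d$draw_index == dr, ], cls)
      if (res$action == "report_positive") { final <- "RhD_positive"; break }
      if (res$action == "resample") { resampled <- TRUE; next }
      if (res$action == "report_negative") { final <- "RhD_negative"; break }
    }
    data.frame(pregnancy_id = d$pregnancy_id[1L], maternal_class = cls,
               n_draws = length(unique(d$draw_index)),
               resampled = resampled, prediction = final,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  summary <- list(
    n_pregnancies    = nrow(per),
    n_plasma_samples = sum(per$n_draws),
    n_positive       = sum(per$prediction == "RhD_positive"),
    n_negative       = sum(per$prediction == "RhD_negative"),
    n_uncertain      = sum(per$prediction == "uncertain"),
    n_resampled      = sum(per$resampled),
    by_maternal_class = table(per$maternal_class, per$prediction)
  )
  if (!is.null(truth)) {
    m <- merge(per, truth, by = "pregnancy_id")
    expected <- ifelse(m$fetal_rhd_positive, "RhD_positive", "RhD_negative")
    summary$concordance <- mean(m$prediction == expected)
  }
  list(per_pregnancy = per, summary = summary)
}
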