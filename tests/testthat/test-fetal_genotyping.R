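# cffDNA fetal RhD prediction: eligibility, the informative-exon rule,
# resampling, and the cohort fixture.

test_that("eligibility is restricted to deletion and hybrid mothers", {
  expect_true(eligibleForNipt("RHD_deletion"))
  expect_true(eligibleForNipt("RHD_CE_2_9_D"))
  expect_false(eligibleForNipt("DEL_1227A_hom"))
  expect_false(eligibleForNipt("RHD_positive"))
  expect_true(eligibleForNipt(diagnose(makeSample("deletion_hom"))))
  expect_false(eligibleForNipt(diagnose(makeSample("1227A_hom"))))
})

mkAssay <- function(positiveExons, draw = 1L) {
  data.frame(exon = c(1L, 5L, 6L, 7L, 9L),
             positive = c(1L, 5L, 6L, 7L, 9L) %in% positiveExons,
             draw_index = draw, fetal_fraction = NA_real_)
}

test_that("the informative-exon rule is conditioned on maternal genotype", {
  # deletion mother: any of exons 1,5,6,7,9 calls the fetus positive
  res <- predictFetalRhd(mkAssay(7L), "RHD_deletion")
  expect_identical(res$prediction, "RhD_positive")
  expect_identical(res$informative_exons, c(1L, 5L, 6L, 7L, 9L))
  # hybrid mother: exon 1 is maternal background and must be ignored
  res <- predictFetalRhd(mkAssay(1L), "RHD_CE_2_9_D")
  expect_identical(res$prediction, "uncertain")
  expect_identical(res$action, "resample")
  expect_identical(res$informative_exons, c(5L, 6L, 7L, 9L))
  # but any informative exon still calls positive
  res <- predictFetalRhd(mkAssay(c(1L, 9L)), "RHD_CE_2_9_D")
  expect_identical(res$prediction, "RhD_positive")
})

test_that("negative calls need the second draw", {
  res <- predictFetalRhd(mkAssay(integer(0), draw = 1L), "RHD_deletion")
  expect_identical(res$action, "resample")
  expect_identical(res$prediction, "uncertain")
  res <- predictFetalRhd(mkAssay(integer(0), draw = 2L), "RHD_deletion")
  expect_identical(res$action, "report_negative")
  expect_identical(res$prediction, "RhD_negative")
})

test_that("malformed assays and ineligible mothers are rejected", {
  bad <- mkAssay(5L); bad$exon[1L] <- 2L
  expect_error(predictFetalRhd(bad, "RHD_deletion"), "malformed assay")
  expect_error(predictFetalRhd(mkAssay(5L), "DEL_1227A_hom"),
               "not eligible")
})

test_that("at saturating fetal fraction the rule recovers informative truth", {
  # exhaustive over eligible mothers and generator fetal genotypes: with
  # p = 1 the prediction is positive exactly when the fetal genome carries
  # an informative RHD exon
  fetalLabels <- c("intact", "intact_het", "deletion_hom", "CE29_carrier",
                   "1227A_hom", "DVI_III", "DVa_Hus", "c336_1A_het_del")
  for (mom in c("deletion_hom", "CE29_carrier")) {
    maternal <- makeSample(mom)
    cls <- if (mom == "deletion_hom") "RHD_deletion" else "RHD_CE_2_9_D"
    info <- if (mom == "deletion_hom") c(1L, 5L, 6L, 7L, 9L)
            else c(5L, 6L, 7L, 9L)
    for (fl in fetalLabels) {
      fetal <- makeSample(fl)
      a <- makeCffdnaAssay(maternal, fetal, fetalFraction = 0.2, seed = 4)
      res <- predictFetalRhd(a, cls)
      fetalHasInformative <- any(vapply(info, function(e)
        rhdtyper:::.hasRhdExon(fetal, e), logical(1)))
      expect_identical(res$prediction == "RhD_positive",
                       fetalHasInformative, label = paste(mom, fl))
    }
  }
})

test_that("a truly D-negative fetus is never called from maternal background", {
  # deletion-homozygous fetus, every maternal genotype, any fraction/draws
  for (mom in c("deletion_hom", "CE29_carrier")) {
    maternal <- makeSample(mom)
    cls <- if (mom == "deletion_hom") "RHD_deletion" else "RHD_CE_2_9_D"
    for (ff in c(0, 0.1, 0.3)) {
      a <- makeCffdnaAssay(maternal, makeSample("deletion_hom"),
                           fetalFraction = ff, seed = 11)
      expect_false(predictFetalRhd(a, cls)$prediction == "RhD_positive",
                   label = paste(mom, ff))
    }
  }
})

test_that("the 31-pregnancy fixture reproduces the cohort outcome", {
  for (seed in c(1L, 42L, 2024L)) {
    nipt <- makeNiptFixture(seed = seed)
    res <- runNiptCohort(nipt$assays, nipt$truth)
    s <- res$summary
    expect_identical(s$n_pregnancies, 31L)
    expect_identical(s$n_plasma_samples, 33L)
    expect_identical(s$n_positive, 31L)
    expect_identical(s$n_negative, 0L)
    expect_identical(s$n_uncertain, 0L)
    expect_identical(s$n_resampled, 2L)
    expect_identical(s$concordance, 1)
    # resampled pregnancies are deletion-mother pregnancies with two draws
    rp <- res$per_pregnancy[res$per_pregnancy$resampled, ]
    expect_identical(nrow(rp), 2L)
    expect_true(all(rp$n_draws == 2L))
  }
})

test_that("an all-negative two-draw pregnancy resolves RhD negative", {
  assays <- rbind(
    cbind(mkAssay(integer(0), 1L), pregnancy_id = "PX",
          maternal_class = "RHD_deletion"),
    cbind(mkAssay(integer(0), 2L), pregnancy_id = "PX",
          maternal_class = "RHD_deletion"))
  res <- runNiptCohort(assays)
  expect_identical(res$per_pregnancy$prediction, "RhD_negative")
  expect_true(res$per_pregnancy$resampled)
})
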