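# Synthetic diploid samples, cohorts, the family fixture, mRNA reads.

test_that("named genotypes realize the documented haplotype pairs", {
  s <- makeSample("deletion_hom")
  expect_identical(structuralClass(haplotypes(s)$A), "deletion")
  expect_identical(rhesusBoxType(haplotypes(s)$A), "hybrid")
  expect_identical(rhesusBoxType(haplotypes(s)$B), "hybrid")

  s <- makeSample("c336_1A_het_del")
  cls <- sort(vapply(haplotypes(s), structuralClass, character(1)))
  expect_identical(unname(cls), c("deletion", "intact"))
  vars <- unlist(lapply(haplotypes(s), function(h) variantTable(h)$cdot))
  expect_identical(unname(vars), "c.336-1G>A")

  s <- makeSample("1227A_hom")
  for (h in haplotypes(s)) {
    expect_identical(structuralClass(h), "intact")
    expect_identical(variantTable(h)$cdot, "c.1227G>A")
  }
  expect_error(makeSample("no_such_label"), "configuration error")
})

test_that("deletion haplotypes cannot carry variants", {
  expect_error(makeHaplotype("deletion", "c.3G>A"), "cannot carry")
})

test_that("hybrid RHD-CE(2-9)-D matches RHCE in exons 2-9 and RHD in 1,10", {
  h <- makeHaplotype("hybrid_CE_2_9")
  hseq <- hapSequence(h)
  rhceChar <- as.character(modelSequence(rhce))
  for (k in 1:10) {
    for (pos in diagnosticPositions(locus)[[k]]) {
      gD <- cdsToGenomic(rhd, pos)
      gC <- cdsToGenomic(rhce, pos)
      if (k %in% 2:9) {
        expect_identical(substr(hseq, gD, gD), substr(rhceChar, gC, gC))
      } else {
        expect_identical(substr(hseq, gD, gD), substr(rhdSeqChar, gD, gD))
      }
    }
  }
})

test_that("cohort generation is deterministic and sized by its counts", {
  expect_length(makeCohort(defaultCohortCounts(), seed = 42), 76L)
  expect_length(makeCohort(c(deletion_hom = 0L)), 0L)
  c1 <- makeCohort(c(deletion_hom = 3L, `1227A_hom` = 2L), seed = 7)
  c2 <- makeCohort(c(deletion_hom = 3L, `1227A_hom` = 2L), seed = 7)
  key <- function(co) vapply(co, function(s)
    paste(sampleId(s), genotypeName(s),
          haplotypeKey(haplotypes(s)$A), haplotypeKey(haplotypes(s)$B)),
    character(1))
  expect_identical(key(c1), key(c2))
  expect_identical(
    vapply(c1, function(s) hapSequence(haplotypes(s)$A), character(1)),
    vapply(c2, function(s) hapSequence(haplotypes(s)$A), character(1)))
})

test_that("family haplotypes are transmitted Mendelianly", {
  fam <- makeFamily()
  ped <- fam$pedigree
  for (i in which(!is.na(ped$father))) {
    child <- fam$samples[[ped$member[i]]]
    fatherKeys <- vapply(haplotypes(fam$samples[[ped$father[i]]]),
                         haplotypeKey, character(1))
    motherKeys <- vapply(haplotypes(fam$samples[[ped$mother[i]]]),
                         haplotypeKey, character(1))
    childKeys <- vapply(haplotypes(child), haplotypeKey, character(1))
    # each child haplotype matches one haplotype of one parent, and both
    # parents are represented
    expect_true(all(childKeys %in% c(fatherKeys, motherKeys)))
    expect_true(any(childKeys %in% fatherKeys) &&
                  any(childKeys %in% motherKeys))
  }
  expect_identical(
    ped$expected_genotype[ped$member == "III-5"], "RHD-/336-1G>A")
})

test_that("mRNA reads are re-derivable from their truth annotations", {
  s <- makeSample("c336_1A_het_del")
  rs <- makeMrnaReads(s, nReads = 120, retentionLengths = c(31L, 197L),
                      seed = 5)
  truth <- readTruth(rs)
  reads <- readSequences(rs)
  expect_identical(nrow(truth), 120L)
  for (i in seq_len(nrow(truth))) {
    expect_identical(rebuildRead(s, truth[i, ]), unname(reads[[i]]))
  }
  # both planted retention lengths appear in the truth
  expect_setequal(unique(stats::na.omit(truth$retained_bp)), c(31L, 197L))
  # retention only ever on the splice haplotype
  spliceHap <- names(haplotypes(s))[vapply(haplotypes(s), function(h)
    "c.336-1G>A" %in% variantTable(h)$cdot, logical(1))]
  expect_true(all(truth$haplotype[truth$category == "retains_intron"] ==
                    spliceHap))
})

test_that("wild-type samples emit only spliced transcripts", {
  rs <- makeMrnaReads(makeSample("intact"), nReads = 60, seed = 2)
  expect_true(all(readTruth(rs)$category == "spliced"))
})

test_that("mRNA generation is deterministic and validates lengths", {
  s <- makeSample("c336_1A_het_del")
  r1 <- makeMrnaReads(s, nReads = 40, seed = 9)
  r2 <- makeMrnaReads(s, nReads = 40, seed = 9)
  expect_identical(readSequences(r1), readSequences(r2))
  expect_identical(readTruth(r1), readTruth(r2))
  expect_error(makeMrnaReads(s, retentionLengths = 10000L),
               "generation error")
  expect_error(makeMrnaReads(makeSample("deletion_hom")),
               "generation error")
})

test_that("cffDNA assays honor maternal background and detection limits", {
  motherDel <- makeSample("deletion_hom")
  motherCe <- makeSample("CE29_carrier")
  fetusPos <- makeSample("intact_het")
  # fetal fraction 0: nothing fetal is detectable
  a <- makeCffdnaAssay(motherDel, fetusPos, fetalFraction = 0, seed = 1)
  expect_false(any(a$positive))
  # hybrid mothers always show exon 1 (their own RHD exon 1)
  a <- makeCffdnaAssay(motherCe, makeSample("deletion_hom"),
                       fetalFraction = 0, seed = 1)
  expect_true(a$positive[a$exon == 1L])
  expect_false(any(a$positive[a$exon != 1L]))
  # deletion mother, deletion fetus: nothing at any fraction
  a <- makeCffdnaAssay(motherDel, makeSample("deletion_hom"),
                       fetalFraction = 0.3, seed = 1)
  expect_false(any(a$positive))
  # D-positive mothers are rejected
  expect_error(makeCffdnaAssay(makeSample("intact"), fetusPos, 0.1),
               "D-negative")
})
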