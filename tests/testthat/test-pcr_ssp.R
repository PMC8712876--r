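# In-silico PCR-SSP assay and band-pattern interpretation.

test_that("simulate-interpret round trip holds for all 8 kit classes", {
  classes <- c("RHD_positive", "RHD_deletion", "RHD_CE_2_9_D", "DVa_Hus",
               "DVI_III", "weakD15", "DEL_1227A_hom", "DEL_1227A_het")
  for (cls in classes) expect_true(roundtripCheck(cls), label = cls)
  expect_error(roundtripCheck("undetectable"), "not a kit genotype class")
})

test_that("deletion homozygotes light no RHD-specific exon wells", {
  p <- simulatePcrSsp(makeSample("deletion_hom"))
  expect_false(any(p$specific[p$well %in% c(1:6, 8L)]))
  expect_true(p$specific[p$well == 7L])      # hybrid Rhesus box
  expect_true(all(p$control))
})

test_that("the 1227 allele-specific pair discriminates G from A", {
  pHom <- simulatePcrSsp(makeSample("1227A_hom"))
  expect_false(pHom$specific[pHom$well == 5L])   # G well
  expect_true(pHom$specific[pHom$well == 6L])    # A well
  pWt <- simulatePcrSsp(makeSample("intact"))
  expect_true(pWt$specific[pWt$well == 5L])
  expect_false(pWt$specific[pWt$well == 6L])
})

test_that("the three point-mutation samples are undetectable at tier 1", {
  for (g in c("c340T", "c3A", "c336_1A_het_del")) {
    call <- interpretBandPattern(simulatePcrSsp(makeSample(g)))
    expect_identical(as.character(call), "undetectable", label = g)
    expect_false(attr(call, "ambiguous"))
  }
})

test_that("variants outside every primer footprint never change the pattern", {
  # positions in exons 2, 3, 5 clear of all primer and diagnostic footprints
  clear <- c(200L, 400L, 700L)
  base <- simulatePcrSsp(makeSample("intact"))
  for (pos in clear) {
    hap <- makeHaplotype("intact", cdotAt(pos))
    s <- pairSample("mono", hap, makeHaplotype("intact"))
    expect_identical(simulatePcrSsp(s), base, label = paste("cds", pos))
  }
})

test_that("a missing control band is an assay-invalid error, not a call", {
  p <- simulatePcrSsp(makeSample("deletion_hom"))
  p$control[3L] <- FALSE
  expect_error(interpretBandPattern(p), class = "rhdAssayInvalidError")
  # all-wells-negative controls likewise
  p$control <- FALSE
  expect_error(interpretBandPattern(p), class = "rhdAssayInvalidError")
})

test_that("a 1227A allele over an intact haplotype matches no signature", {
  # the heterozygote signature demands deletion evidence (hybrid box);
  # without it the kit reports undetectable
  s <- pairSample("amb", makeHaplotype("intact", "c.1227G>A"),
                  makeHaplotype("intact"), serology = "DEL")
  call <- interpretBandPattern(simulatePcrSsp(s))
  expect_identical(as.character(call), "undetectable")
})

test_that("the RHCE background never amplifies in RHD wells", {
  # an RHD-null genome: every specific well except the box must be dark
  # even though two RHCE copies are present in the template pool
  p <- simulatePcrSsp(makeSample("deletion_hom"))
  expect_false(any(p$specific[p$well != 7L]))
})
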