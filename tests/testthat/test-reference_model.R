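# Gene models and the coding coordinate system.

test_that("the RHD model has the constrained exon architecture", {
  ex <- exonRanges(rhd)
  expect_length(ex, 10L)
  expect_identical(cdsLength(rhd), 1254L)
  # c.335|c.336 falls on the intron2/exon3 junction
  expect_identical(cdsToGenomic(rhd, 336L), IRanges::start(ex)[3L])
  expect_identical(cdsToGenomic(rhd, 335L), IRanges::end(ex)[2L])
  # c.3 in exon 1, c.340 in exon 3, c.1227 in exon 9 (its last base)
  expect_identical(genomicToCds(rhd, cdsToGenomic(rhd, 3L))$exon, 1L)
  expect_identical(genomicToCds(rhd, cdsToGenomic(rhd, 340L))$exon, 3L)
  expect_identical(genomicToCds(rhd, cdsToGenomic(rhd, 1227L))$exon, 9L)
  expect_identical(cdsToGenomic(rhd, 1227L), IRanges::end(ex)[9L])
  # introns leave room for the longest retained segment
  expect_true(all(IRanges::width(intronRanges(rhd)) >= 250L))
})

test_that("locus builds are deterministic", {
  fresh <- rhdtyper:::.buildLocusSet()
  expect_identical(as.character(modelSequence(rhdModel(fresh))), rhdSeqChar)
  expect_identical(as.character(modelSequence(rhceModel(fresh))),
                   as.character(modelSequence(rhce)))
  expect_identical(rhesusBoxes(fresh)$hybrid, rhesusBoxes(locus)$hybrid)
})

test_that("c.336-1 is the last base of intron 2 and carries the acceptor G", {
  g <- cdsToGenomic(rhd, 336L, -1L)
  expect_identical(g, IRanges::end(intronRanges(rhd))[2L])
  expect_identical(substr(rhdSeqChar, g, g), "G")
})

test_that("coordinate round-trip is the identity over every locus base", {
  ex <- exonRanges(rhd)
  span <- IRanges::start(ex)[1L]:IRanges::end(ex)[length(ex)]
  ok <- vapply(span, function(g) {
    cc <- genomicToCds(rhd, g)
    cdsToGenomic(rhd, cc$cds, cc$offset) == g
  }, logical(1))
  expect_true(all(ok))
})

test_that("invalid coding positions raise coordinate errors", {
  expect_error(cdsToGenomic(rhd, 0L), "coordinate error")
  expect_error(cdsToGenomic(rhd, 1255L), "coordinate error")
  # offsets are only valid from exon-boundary CDS bases
  expect_error(cdsToGenomic(rhd, 100L, 5L), "coordinate error")
  expect_error(cdsToGenomic(rhd, 100L, -5L), "coordinate error")
  # offsets cannot run past the intron
  expect_error(cdsToGenomic(rhd, 335L, 10000L), "coordinate error")
  expect_error(genomicToCds(rhd, 1L), "coordinate error")
})

test_that("c. variant strings parse and format round-trip", {
  cases <- c("c.1227G>A", "c.336-1G>A", "c.3G>A", "c.335+2T>C")
  for (cd in cases) {
    p <- parseCdot(cd)
    expect_identical(formatCdot(p$cds, p$offset, p$ref, p$alt), cd)
  }
  expect_error(parseCdot("c.12del"), "cannot parse")
})

test_that("RHCE differs from RHD exactly at the diagnostic positions", {
  rhceChar <- as.character(modelSequence(rhce))
  for (k in 1:10) {
    for (pos in diagnosticPositions(locus)[[k]]) {
      gD <- cdsToGenomic(rhd, pos)
      gC <- cdsToGenomic(rhce, pos)
      expect_false(substr(rhdSeqChar, gD, gD) == substr(rhceChar, gC, gC))
    }
  }
  # non-diagnostic exonic bases agree between the paralogs
  exonic <- setdiff(1:1254, unlist(diagnosticPositions(locus)))
  sameAt <- vapply(exonic, function(pos) {
    gD <- cdsToGenomic(rhd, pos); gC <- cdsToGenomic(rhce, pos)
    substr(rhdSeqChar, gD, gD) == substr(rhceChar, gC, gC)
  }, logical(1))
  expect_true(all(sameAt))
})
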