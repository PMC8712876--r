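# Sanger tier: amplicon extraction, variant calling, allele assignment.

test_that("amplicon counts follow haplotype structure", {
  expect_identical(nrow(extractAmplicons(makeSample("deletion_hom"))), 0L)
  amp <- extractAmplicons(makeSample("intact"), flank_bp = 30L)
  expect_identical(nrow(amp), 20L)     # 10 exons x 2 haplotypes
  w <- IRanges::width(exonRanges(rhd))
  expect_identical(nchar(amp$seq), rep(w + 60L, 2L))
  # single non-deleted haplotype: 10 amplicons
  amp <- extractAmplicons(makeSample("c336_1A_het_del"))
  expect_identical(nrow(amp), 10L)
  expect_error(extractAmplicons(makeSample("intact"), flank_bp = 1L),
               "flank_bp")
})

test_that("reference amplicons yield zero variant calls", {
  amp <- extractAmplicons(makeSample("intact"))
  expect_identical(nrow(callVariants(amp)), 0L)
})

test_that("the three study point mutations are called and assigned", {
  cases <- list(
    c340T           = c("c.340C>T",   "RHD*10.08"),
    c3A             = c("c.3G>A",     "RHD*01EL.02"),
    c336_1A_het_del = c("c.336-1G>A", "RHD*01N.25"))
  for (g in names(cases)) {
    v <- callVariants(extractAmplicons(makeSample(g)))
    expect_identical(nrow(v), 1L, label = g)
    expect_identical(v$cdot, cases[[g]][1L], label = g)
    expect_identical(assignAllele(v)$designation, cases[[g]][2L], label = g)
  }
  # the splice variant is reported with its intron offset
  v <- callVariants(extractAmplicons(makeSample("c336_1A_het_del")))
  expect_identical(v$offset, -1L)
  expect_identical(v$region, "intronic")
})

test_that("spike-recovery: any planted substitution is called exactly", {
  # property-based: random exonic and splice-site positions across seeds
  ir <- intronRanges(rhd)
  spliceSites <- do.call(rbind, lapply(seq_along(ir), function(k) {
    lastCds <- cdsOffsets(rhd)[k] + IRanges::width(exonRanges(rhd))[k] - 1L
    firstCds <- cdsOffsets(rhd)[k + 1L]
    rbind(c(lastCds, 1L), c(lastCds, 2L), c(firstCds, -1L), c(firstCds, -2L))
  }))
  set.seed(20240915)
  nIter <- 1000L
  pickSplice <- stats::runif(nIter) < 0.3
  exonicPos <- sample.int(1254L, nIter, replace = TRUE)
  spliceIdx <- sample.int(nrow(spliceSites), nIter, replace = TRUE)
  del <- makeHaplotype("deletion")
  ok <- vapply(seq_len(nIter), function(i) {
    if (pickSplice[i]) {
      cd <- cdotAt(spliceSites[spliceIdx[i], 1L], spliceSites[spliceIdx[i], 2L])
    } else {
      cd <- cdotAt(exonicPos[i])
    }
    s <- pairSample("spike", makeHaplotype("intact", cd), del)
    v <- callVariants(extractAmplicons(s))
    nrow(v) == 1L && v$cdot == cd
  }, logical(1))
  expect_true(all(ok))
})

test_that("unanchorable or length-shifted amplicons raise alignment errors", {
  amp <- extractAmplicons(makeSample("intact"))[1L, ]
  bad <- amp; bad$seq <- paste0("A", bad$seq)
  expect_error(callVariants(bad), "alignment error")
  bad <- amp
  substr(bad$seq, 1L, 12L) <- strrep(
    if (substr(bad$seq, 1L, 1L) == "A") "C" else "A", 12L)
  expect_error(callVariants(bad), "alignment error")
})

test_that("multi-variant haplotypes fall back over exact-set matching", {
  s <- pairSample("w94", makeHaplotype("intact", c("c.48G>C", "c.819G>A")),
                  makeHaplotype("deletion"))
  v <- callVariants(extractAmplicons(s))
  expect_identical(assignAllele(v)$designation, "RHD*09.04")
  # an unknown combination is the sentinel
  s <- pairSample("nov", makeHaplotype("intact", c("c.48G>C", "c.809T>G")),
                  makeHaplotype("deletion"))
  v <- callVariants(extractAmplicons(s))
  expect_identical(assignAllele(v)$designation,
                   rhdtyper:::.SENTINEL_DESIGNATION)
})
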