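# Read mapping, intron-retention detection, frame consequences,
# segment uniqueness.

spliceModel <- personalizeModel(rhd, "c.336-1G>A")
ex <- exonRanges(rhd)
ir <- intronRanges(rhd)

test_that("reads decompose into the expected exact-match blocks", {
  loc <- as.character(modelSequence(rhd))
  # fully exonic read: one block inside exon 2
  r <- substr(loc, IRanges::start(ex)[2L] + 5L, IRanges::start(ex)[2L] + 84L)
  m <- mapReads(c(exonic = r), rhd)
  expect_identical(nrow(m$placements), 1L)
  expect_identical(m$placements$start, IRanges::start(ex)[2L] + 5L)
  # spliced exon2|exon3 junction read: two blocks flanking intron 2
  r <- paste0(substr(loc, IRanges::end(ex)[2L] - 39L, IRanges::end(ex)[2L]),
              substr(loc, IRanges::start(ex)[3L], IRanges::start(ex)[3L] + 39L))
  m <- mapReads(c(junction = r), rhd)
  expect_identical(nrow(m$placements), 2L)
  expect_identical(m$placements$end[1L], IRanges::end(ex)[2L])
  expect_identical(m$placements$start[2L], IRanges::start(ex)[3L])
  # read across a retained intron-2 tail into exon 3: one contiguous block
  locP <- as.character(modelSequence(spliceModel))
  r <- substr(locP, IRanges::end(ir)[2L] - 30L, IRanges::end(ir)[2L] + 49L)
  m <- mapReads(c(retained = r), spliceModel)
  expect_identical(nrow(m$placements), 1L)
  expect_true(m$placements$start <= IRanges::end(ir)[2L] &&
                m$placements$end > IRanges::end(ir)[2L])
  # garbage is reported unmapped, never dropped silently
  m <- mapReads(c(junk = strrep("ACGT", 30L)), rhd)
  expect_identical(m$unmapped, "junk")
})

test_that("planted retention lengths are recovered exactly", {
  s <- makeSample("c336_1A_het_del")
  rs <- makeMrnaReads(s, nReads = 1500, retentionLengths = c(31L, 197L),
                      seed = 101)
  rep <- detectRetention(mapReads(rs, spliceModel), spliceModel)
  ev <- retentionEvents(rep)
  expect_identical(sort(ev$length), c(31L, 197L))
  expect_true(all(ev$intron == 2L))
  expect_true(all(ev$supporting_reads >= 10L))
  expect_true("intron2_enriched" %in% reportFlags(rep))
})

test_that("wild-type read sets never yield retention (specificity 1)", {
  rs <- makeMrnaReads(makeSample("intact"), nReads = 400, seed = 33)
  rep <- detectRetention(mapReads(rs, rhd), rhd)
  expect_identical(nrow(retentionEvents(rep)), 0L)
  expect_false("intron2_enriched" %in% reportFlags(rep))
  expect_length(rep@unmappedReads, 0L)
})

test_that("length recovery matches the truth-derived support oracle", {
  # property across seeds and length sets: a planted length is recoverable
  # iff the truth contains >= 2 junction reads with >= seed-length overhang
  # on each side of the exon-2 junction, plus acceptor-spanning coverage
  s <- makeSample("c336_1A_het_del")
  exon2TxEnd <- sum(IRanges::width(ex)[1:2])  # transcript position of exon-2 end
  readLength <- 150L
  seedLen <- 20L
  for (seed in c(7L, 19L, 77L)) {
    lens <- sort(sample(c(25L, 31L, 57L, 90L, 120L, 144L, 197L, 260L), 4L))
    rs <- makeMrnaReads(s, nReads = 1500, retentionLengths = lens,
                        seed = seed)
    truth <- readTruth(rs)
    ret <- truth[truth$category == "retains_intron", ]
    junctionSupport <- vapply(lens, function(L) {
      span <- ret$retained_bp == L &
        ret$offset <= exon2TxEnd - seedLen + 1L &
        ret$offset + readLength - 1L >= exon2TxEnd + seedLen
      sum(span)
    }, integer(1))
    acceptorReads <- any(
      ret$offset <= exon2TxEnd + ret$retained_bp &
        ret$offset + readLength - 1L >= exon2TxEnd + ret$retained_bp + 1L)
    expected <- lens[junctionSupport >= 2L]
    if (!acceptorReads) expected <- integer(0)
    rep <- detectRetention(mapReads(rs, spliceModel), spliceModel)
    expect_identical(sort(retentionEvents(rep)$length), expected,
                     label = paste("seed", seed))
  }
})

test_that("coverage is conserved: depth sums equal aligned bases", {
  rs <- makeMrnaReads(makeSample("c336_1A_het_del"), nReads = 300, seed = 3)
  m <- mapReads(rs, spliceModel)
  rep <- detectRetention(m, spliceModel)
  expect_identical(rep@alignedBases,
                   sum(m$placements$end - m$placements$start + 1))
  # aligned + clipped bases account for every mapped read's full length
  mappedIds <- setdiff(readTruth(rs)$read_id, m$unmapped)
  expect_identical(rep@alignedBases + rep@clippedBases,
                   150 * length(mappedIds))
})

test_that("frame consequences follow retained length mod 3", {
  fc <- frameConsequence(30L)
  expect_true(fc$in_frame); expect_identical(fc$inserted_aa, 10L)
  fc <- frameConsequence(197L)
  expect_true(fc$frameshift); expect_identical(fc$inserted_aa, 65L)
  fc <- frameConsequence(198L)
  expect_true(fc$in_frame); expect_identical(fc$inserted_aa, 66L)
  expect_error(frameConsequence(0L), "positive")
})

test_that("segment uniqueness separates intronic from shared exonic k-mers", {
  loc <- as.character(modelSequence(rhd))
  # the 197 bp acceptor-proximal intron-2 segment is unique across loci
  seg <- substr(loc, IRanges::end(ir)[2L] - 196L, IRanges::end(ir)[2L])
  expect_true(uniquenessCheck(seg))
  # an exonic 25-mer clear of diagnostic positions is shared with RHCE
  g1 <- cdsToGenomic(rhd, 40L)
  expect_false(uniquenessCheck(substr(loc, g1, g1 + 24L)))
  expect_error(uniquenessCheck(substr(loc, g1, g1 + 10L)), "at least 20")
})
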