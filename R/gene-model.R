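# Miniature RHD/RHCE gene models and the HGVS-style coding coordinate map.
#
# The mini-locus keeps the real RHD CDS exon boundary structure (10 coding
# exons; c.335|c.336 at the intron2/exon3 junction, c.3 in exon 1, c.340 in
# exon 3, c.1227 the last base of exon 9) while exon/intron sequences are
# synthetic.  Intron lengths are free parameters kept >= 250 bp so a 197 bp
# retained acceptor-proximal segment always fits inside intron 2.

## CDS length of each of the 10 coding exons; cumulative ends are
## 148, 335, 486, 634, 801, 939, 1073, 1153, 1227, 1254.
.EXON_CDS_LEN <- c(148L, 187L, 151L, 148L, 167L, 138L, 134L, 80L, 74L, 27L)
.INTRON_LEN   <- c(312L, 310L, 285L, 301L, 274L, 296L, 288L, 307L, 293L)
.FLANK_LEN    <- 200L

## CDS positions at which RHCE differs from RHD (two per exon); c.338 is
## deliberately inside the exon-3 presence-primer footprint so hybrid
## alleles lose that well.
.DIAGNOSTIC_CDS <- list(
  c(30L, 110L),  c(180L, 300L),  c(338L, 450L),  c(520L, 600L),
  c(654L, 770L), c(830L, 910L),  c(960L, 1050L), c(1090L, 1140L),
  c(1170L, 1215L), c(1232L, 1250L)
)

## Reference bases pinned after random generation so the alleles of the
## knowledge base are realizable with their published ref/alt bases.
.PINNED_REF <- c(
  "3" = "G", "8" = "C", "48" = "G", "52" = "C", "178" = "A", "301" = "T",
  "340" = "C", "602" = "C", "667" = "T", "712" = "G", "809" = "T",
  "819" = "G", "845" = "G", "916" = "G", "932" = "A", "1154" = "G",
  "1227" = "G"
)

## The locus is a package constant: a fixed internal seed makes every build
## bitwise identical, independently of user-facing seeds.
.MODEL_SEED <- 19050617L

.newGeneModel <- function(geneName, exonSeqs, intronSeqs, flank5, flank3) {
  n <- length(exonSeqs)
  pieces <- character(2L * n)
  pieces[seq(1L, 2L * n, by = 2L)] <- exonSeqs
  if (n > 1L) pieces[seq(2L, 2L * n - 2L, by = 2L)] <- intronSeqs
  pieces[2L * n] <- flank3
  seqchar <- paste0(flank5, paste(pieces, collapse = ""))
  lens <- nchar(exonSeqs)
  starts <- integer(n)
  starts[1L] <- nchar(flank5) + 1L
  if (n > 1L) {
    for (k in 2L:n) {
      starts[k] <- starts[k - 1L] + lens[k - 1L] + nchar(intronSeqs[k - 1L])
    }
  }
  new("GeneModel",
      geneName   = geneName,
      exons      = IRanges::IRanges(start = starts, width = lens),
      cdsOffsets = as.integer(cumsum(c(1L, lens[-n]))[seq_len(n)]),
      sequence   = Biostrings::DNAString(seqchar))
}

.buildLocusSet <- function() {
  withSeed(.MODEL_SEED, {
    exD  <- vapply(.EXON_CDS_LEN, randomDna, character(1))
    inD  <- vapply(.INTRON_LEN, randomDna, character(1))
    ## canonical GT..AG splice sites; the intron-2 acceptor G is the base
    ## mutated by c.336-1G>A
    inD  <- vapply(inD, function(s) {
      s <- substrReplace(s, 1L, "GT")
      substrReplace(s, nchar(s) - 1L, "AG")
    }, character(1), USE.NAMES = FALSE)
    fl5D <- randomDna(.FLANK_LEN)
    fl3D <- randomDna(.FLANK_LEN)

    ## pin published reference bases into the RHD CDS
    cdsEnd <- cumsum(.EXON_CDS_LEN)
    cdsOff <- cumsum(c(1L, .EXON_CDS_LEN[-10L]))
    for (p in names(.PINNED_REF)) {
      pos <- as.integer(p)
      k <- which(pos <= cdsEnd)[1L]
      rel <- pos - cdsOff[k] + 1L
      exD[k] <- substrReplace(exD[k], rel, .PINNED_REF[[p]])
    }

    ## RHCE exons: RHD exons with a base swap at each diagnostic position;
    ## introns and flanks are unrelated sequence
    exC <- exD
    for (k in seq_along(exC)) {
      for (pos in .DIAGNOSTIC_CDS[[k]]) {
        rel <- pos - cdsOff[k] + 1L
        exC[k] <- substrReplace(exC[k], rel, swapBase(substr(exC[k], rel, rel)))
      }
    }
    inC  <- vapply(.INTRON_LEN, randomDna, character(1))
    fl5C <- randomDna(.FLANK_LEN)
    fl3C <- randomDna(.FLANK_LEN)

    up   <- randomDna(3000L)
    down <- randomDna(3000L)
    hyb  <- paste0(substr(up, 1L, 1500L), substr(down, 1501L, 3000L))
    ctrl <- randomDna(1200L)

    new("RhdLocusSet",
        rhd  = .newGeneModel("RHD",  exD, inD, fl5D, fl3D),
        rhce = .newGeneModel("RHCE", exC, inC, fl5C, fl3C),
        boxes = list(upstream = up, downstream = down, hybrid = hyb),
        control = ctrl,
        diagnostics = .DIAGNOSTIC_CDS)
  })
}

#' The package's RHD/RHCE mini-locus set
#'
#' Builds (once per session; the result is cached) the synthetic RHD and
#' RHCE gene models, the stylized Rhesus-box constructs and the internal
#' amplification control that all simulated assays run against.  The build
#' is deterministic: repeated calls, and calls across sessions, return the
#' identical locus.
#'
#' @return an \linkS4class{RhdLocusSet}.
#' @examples
#' ls <- rhdLocusSet()
#' rhdModel(ls)
#' @export
rhdLocusSet <- function() {
  if (is.null(.rhdtyper_cache$locusSet)) {
    .rhdtyper_cache$locusSet <- .buildLocusSet()
  }
  .rhdtyper_cache$locusSet
}

#' @describeIn rhdLocusSet the RHD \linkS4class{GeneModel}.
#' @param locusSet an \linkS4class{RhdLocusSet}.
#' @export
rhdModel <- function(locusSet = rhdLocusSet()) locusSet@rhd

#' @describeIn rhdLocusSet the RHCE \linkS4class{GeneModel}.
#' @export
rhceModel <- function(locusSet = rhdLocusSet()) locusSet@rhce

#' @describeIn rhdLocusSet the Rhesus-box construct sequences.
#' @export
rhesusBoxes <- function(locusSet = rhdLocusSet()) locusSet@boxes

#' @describeIn rhdLocusSet RHD-vs-RHCE diagnostic CDS positions per exon.
#' @export
diagnosticPositions <- function(locusSet = rhdLocusSet()) locusSet@diagnostics

## Coordinate mapping ---------------------------------------------------------

#' Map an HGVS-style coding position to a locus coordinate
#'
#' Coding positions are 1-based CDS coordinates with an optional signed
#' intron offset: \code{c.336-1} (\code{cds = 336, offset = -1}) is the
#' last base of the intron upstream of CDS position 336, i.e. the intron-2
#' splice acceptor.
#'
#' @param model a \linkS4class{GeneModel}.
#' @param cds positive integer CDS coordinate.
#' @param offset signed intron offset; 0 for exonic positions.  A positive
#'   offset is only valid from the last CDS base of an exon, a negative one
#'   only from the first CDS base of an exon.
#' @return integer locus coordinate (1-based).
#' @seealso [genomicToCds()], [parseCdot()]
#' @examples
#' m <- rhdModel()
#' cdsToGenomic(m, 336)            # first base of exon 3
#' cdsToGenomic(m, 336, -1)        # last base of intron 2
#' @export
cdsToGenomic <- function(model, cds, offset = 0L) {
  cds <- as.integer(cds); offset <- as.integer(offset)
  ex <- exonRanges(model); off <- cdsOffsets(model)
  w <- IRanges::width(ex)
  if (length(cds) != 1L || is.na(cds) || cds < 1L || cds > sum(w))
    stop("coordinate error: CDS position out of range")
  k <- findInterval(cds, off)
  rel <- cds - off[k]
  if (offset == 0L) return(IRanges::start(ex)[k] + rel)
  if (offset > 0L) {
    if (rel != w[k] - 1L || k == length(ex))
      stop("coordinate error: positive offset requires the last CDS base of ",
           "an exon upstream of an intron")
    g <- IRanges::end(ex)[k] + offset
    if (g >= IRanges::start(ex)[k + 1L])
      stop("coordinate error: offset runs past the intron")
    return(g)
  }
  if (rel != 0L || k == 1L)
    stop("coordinate error: negative offset requires the first CDS base of ",
         "an exon downstream of an intron")
  g <- IRanges::start(ex)[k] + offset
  if (g <= IRanges::end(ex)[k - 1L])
    stop("coordinate error: offset runs past the intron")
  g
}

#' Map a locus coordinate to an HGVS-style coding position
#'
#' Exonic positions get offset 0; intronic positions are expressed relative
#' to the nearest exon boundary (ties go to the upstream donor side, the
#' HGVS convention for the intron midpoint).
#'
#' @param model a \linkS4class{GeneModel}.
#' @param genomic integer locus coordinate (1-based).
#' @return list with elements \code{cds}, \code{offset}, \code{region}
#'   (\code{"exonic"} or \code{"intronic"}) and \code{exon} (the exon
#'   number, or the upstream exon number for intronic positions).
#' @export
genomicToCds <- function(model, genomic) {
  g <- as.integer(genomic)
  ex <- exonRanges(model); off <- cdsOffsets(model)
  s <- IRanges::start(ex); e <- IRanges::end(ex); w <- IRanges::width(ex)
  if (length(g) != 1L || is.na(g) || g < s[1L] || g > e[length(ex)])
    stop("coordinate error: position outside the exon/intron span")
  hit <- which(g >= s & g <= e)
  if (length(hit) == 1L) {
    return(list(cds = off[hit] + (g - s[hit]), offset = 0L,
                region = "exonic", exon = hit))
  }
  k <- max(which(e < g))           # intron k: between exon k and exon k+1
  d1 <- g - e[k]
  d2 <- s[k + 1L] - g
  if (d1 <= d2) {
    list(cds = off[k] + w[k] - 1L, offset = d1, region = "intronic", exon = k)
  } else {
    list(cds = off[k + 1L], offset = -d2, region = "intronic", exon = k)
  }
}

#' Parse an HGVS-style c. variant string
#'
#' @param cdot string such as \code{"c.1227G>A"} or \code{"c.336-1G>A"}.
#' @return list with \code{cds}, \code{offset}, \code{ref}, \code{alt}.
#' @export
parseCdot <- function(cdot) {
  m <- regmatches(cdot,
    regexec("^c\\.(\\d+)([+-]\\d+)?([ACGT])>([ACGT])$", cdot))[[1L]]
  if (length(m) == 0L) stop("cannot parse coding variant: ", cdot)
  list(cds    = as.integer(m[2L]),
       offset = if (nzchar(m[3L])) as.integer(m[3L]) else 0L,
       ref    = m[4L],
       alt    = m[5L])
}

#' Format a coding variant as an HGVS-style c. string
#'
#' @param cds CDS coordinate.
#' @param offset signed intron offset (0 for exonic).
#' @param ref,alt single reference/alternate bases.
#' @export
formatCdot <- function(cds, offset, ref, alt) {
  offstr <- if (offset == 0L) "" else sprintf("%+d", offset)
  sprintf("c.%d%s%s>%s", cds, offstr, ref, alt)
}

#' Build a variant table from c. strings
#'
#' Validates each variant's reference base against the model and returns
#' the package-standard variant data.frame.
#' @param model a \linkS4class{GeneModel}.
#' @param cdots character vector of c. variant strings.
#' @return data.frame with columns \code{cds}, \code{offset}, \code{ref},
#'   \code{alt}, \code{cdot}.
#' @export
variantTableFromCdot <- function(model, cdots) {
  if (length(cdots) == 0L) {
    return(data.frame(cds = integer(0), offset = integer(0),
                      ref = character(0), alt = character(0),
                      cdot = character(0), stringsAsFactors = FALSE))
  }
  seqchar <- as.character(modelSequence(model))
  rows <- lapply(cdots, function(cd) {
    p <- parseCdot(cd)
    g <- cdsToGenomic(model, p$cds, p$offset)
    have <- substr(seqchar, g, g)
    if (have != p$ref)
      stop("reference mismatch for ", cd, ": model has ", have)
    data.frame(cds = p$cds, offset = p$offset, ref = p$ref, alt = p$alt,
               cdot = cd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
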