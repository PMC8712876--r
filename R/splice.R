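# Intron-retention analysis of mRNA read sets.
#
# The mapper decomposes each error-free read into exact-match blocks
# against the locus, greedily extending a seeded anchor and re-seeding
# after each splice.  Junctions are canonicalized to annotated exon
# boundaries: maximal extension can overshoot an exon end when the first
# intronic base happens to match the transcript's next base
# (micro-homology), and the overshot bases are shifted onto the downstream
# block, exactly as splice-aware aligners do with known splice sites.

.SEED_LEN <- 20L

#' Substitute known variants into a gene model's sequence
#'
#' Produces a personalized reference: the model with a sample's known
#' point variants applied (coordinates are unchanged — substitutions
#' only).  mRNA reads from a variant carrier are mapped against this
#' personalized model so the variant base does not fragment exact-match
#' blocks.
#'
#' @param model a \linkS4class{GeneModel}.
#' @param cdots character vector of c. variant strings.
#' @return a new \linkS4class{GeneModel}.
#' @export
personalizeModel <- function(model, cdots) {
  vt <- variantTableFromCdot(model, cdots)
  seqchar <- as.character(modelSequence(model))
  for (i in seq_len(nrow(vt))) {
    g <- cdsToGenomic(model, vt$cds[i], vt$offset[i])
    seqchar <- substrReplace(seqchar, g, vt$alt[i])
  }
  new("GeneModel", geneName = geneName(model), exons = exonRanges(model),
      cdsOffsets = cdsOffsets(model),
      sequence = Biostrings::DNAString(seqchar))
}

## maximal exact extension of read[from..] at locus position g
.extendMatch <- function(read, from, locus, g) {
  n <- min(nchar(read) - from, nchar(locus) - g) + 1L
  i <- 0L
  while (i < n &&
         substr(read, from + i, from + i) == substr(locus, g + i, g + i)) {
    i <- i + 1L
  }
  i
}

.mapOneRead <- function(read, locus, exonEnds, seedLen) {
  blocks <- list()
  pos <- 1L
  lastEnd <- 0L
  clipped <- 0L
  n <- nchar(read)
  while (n - pos + 1L >= seedLen) {
    seed <- substr(read, pos, pos + seedLen - 1L)
    hits <- findExact(seed, locus)
    hits <- hits[hits > lastEnd]
    if (length(hits) == 0L) {
      if (length(blocks) == 0L && clipped < seedLen) {
        ## a junction inside the very first seed: slide right, clip the head
        pos <- pos + 1L
        clipped <- clipped + 1L
        next
      }
      if (length(blocks) == 0L) return(NULL)     # unplaceable read
      clipped <- clipped + (n - pos + 1L)
      return(list(blocks = do.call(rbind, blocks), clipped = clipped))
    }
    ext <- vapply(hits, function(g) .extendMatch(read, pos, locus, g),
                  integer(1))
    best <- hits[which.max(ext)]
    extLen <- max(ext)
    blocks[[length(blocks) + 1L]] <- c(start = best, end = best + extLen - 1L)
    pos <- pos + extLen
    lastEnd <- best + extLen - 1L
  }
  if (length(blocks) == 0L) return(NULL)
  clipped <- clipped + (n - pos + 1L)
  res <- do.call(rbind, blocks)
  ## canonicalize junction micro-homology onto exon boundaries
  if (nrow(res) > 1L) {
    for (i in seq_len(nrow(res) - 1L)) {
      e <- exonEnds[exonEnds >= res[i, "start"] & exonEnds < res[i, "end"]]
      if (length(e) == 0L) next
      e <- max(e)
      delta <- res[i, "end"] - e
      if (delta >= res[i + 1L, "end"] - res[i + 1L, "start"] + 1L) next
      shiftSrc <- substr(locus, e + 1L, res[i, "end"])
      shiftDst <- substr(locus, res[i + 1L, "start"] - delta,
                         res[i + 1L, "start"] - 1L)
      if (shiftSrc == shiftDst) {
        res[i, "end"] <- e
        res[i + 1L, "start"] <- res[i + 1L, "start"] - delta
      }
    }
  }
  list(blocks = res, clipped = clipped)
}

#' Map error-free mRNA reads onto a gene model
#'
#' @param reads a \linkS4class{ReadSet} or a named character vector of
#'   read sequences.
#' @param model the \linkS4class{GeneModel} to map against (use
#'   [personalizeModel()] for samples with known DNA variants).
#' @param seedLen anchor seed length (default 20); read segments shorter
#'   than this beyond a junction are soft-clipped.
#' @return list with \code{placements} (data.frame: \code{read_id},
#'   \code{block}, \code{start}, \code{end}), \code{unmapped} (read ids
#'   with no placement — reported, never silently dropped) and
#'   \code{clipped} (data.frame: \code{read_id}, \code{bases}).
#' @export
mapReads <- function(reads, model, seedLen = .SEED_LEN) {
  if (methods::is(reads, "ReadSet")) reads <- readSequences(reads)
  locus <- as.character(modelSequence(model))
  exonEnds <- IRanges::end(exonRanges(model))
  place <- vector("list", length(reads))
  clip <- numeric(length(reads))
  unmapped <- character(0)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%04d", seq_along(reads))
  for (i in seq_along(reads)) {
    m <- .mapOneRead(reads[[i]], locus, exonEnds, seedLen)
    if (is.null(m)) {
      unmapped <- c(unmapped, ids[i])
      next
    }
    b <- m$blocks
    place[[i]] <- data.frame(read_id = ids[i], block = seq_len(nrow(b)),
                             start = as.integer(b[, "start"]),
                             end = as.integer(b[, "end"]),
                             stringsAsFactors = FALSE)
    clip[i] <- m$clipped
  }
  placements <- do.call(rbind, place[!vapply(place, is.null, logical(1))])
  if (is.null(placements)) {
    placements <- data.frame(read_id = character(0), block = integer(0),
                             start = integer(0), end = integer(0),
                             stringsAsFactors = FALSE)
  }
  list(placements = placements,
       unmapped = unmapped,
       clipped = data.frame(read_id = ids, bases = clip,
                            stringsAsFactors = FALSE))
}

#' Detect and quantify intron retention from read placements
#'
#' A retention event of length L is recorded for intron k when a read
#' splices from the end of exon k directly to the 3'-terminal L bases of
#' intron k (an exon-k-end junction into the intron), and at least one
#' read covers the intron/exon-(k+1) boundary contiguously.  Events need
#' \code{minSupport} junction reads.  Junctions into an intron that do not
#' start at an exon end are reported as anomalous, never as retention.
#' Per-intron mean coverage is computed over intron bases, and the
#' \code{"intron2_enriched"} flag is set when intron 2's mean coverage
#' exceeds every other intron's by \code{enrichFactor}.
#'
#' @param mapping result of [mapReads()].
#' @param model the \linkS4class{GeneModel} the reads were mapped to.
#' @param minSupport minimum junction reads per retained length (default 2).
#' @param enrichFactor intron-2 enrichment ratio threshold (default 3).
#' @return a \linkS4class{RetentionReport}.
#' @export
detectRetention <- function(mapping, model, minSupport = 2L,
                            enrichFactor = 3) {
  pl <- mapping$placements
  ex <- exonRanges(model)
  ir <- intronRanges(model)
  locusLen <- length(modelSequence(model))
  cov <- numeric(locusLen)
  for (i in seq_len(nrow(pl))) {
    cov[pl$start[i]:pl$end[i]] <- cov[pl$start[i]:pl$end[i]] + 1
  }
  intronCov <- vapply(seq_along(ir), function(k)
    mean(cov[IRanges::start(ir)[k]:IRanges::end(ir)[k]]), numeric(1))
  names(intronCov) <- paste0("intron", seq_along(ir))
  exBases <- unlist(lapply(seq_along(ex), function(k)
    IRanges::start(ex)[k]:IRanges::end(ex)[k]))
  exonicMean <- mean(cov[exBases])

  exonEnd <- IRanges::end(ex)
  iStart <- IRanges::start(ir); iEnd <- IRanges::end(ir)
  events <- list(); anomalous <- list()
  for (rid in unique(pl$read_id)) {
    b <- pl[pl$read_id == rid, ]
    if (nrow(b) < 2L) next
    b <- b[order(b$block), ]
    for (j in seq_len(nrow(b) - 1L)) {
      nxt <- b$start[j + 1L]
      k <- which(nxt >= iStart & nxt <= iEnd)   # junction lands in intron k
      if (length(k) != 1L) next
      if (b$end[j] == exonEnd[k]) {
        events[[length(events) + 1L]] <- data.frame(
          intron = k, length = iEnd[k] - nxt + 1L, read_id = rid,
          stringsAsFactors = FALSE)
      } else {
        anomalous[[length(anomalous) + 1L]] <- data.frame(
          read_id = rid, from = b$end[j], to = nxt,
          stringsAsFactors = FALSE)
      }
    }
  }
  evDf <- if (length(events)) do.call(rbind, events) else
    data.frame(intron = integer(0), length = integer(0),
               read_id = character(0), stringsAsFactors = FALSE)
  anDf <- if (length(anomalous)) do.call(rbind, anomalous) else
    data.frame(read_id = character(0), from = integer(0), to = integer(0),
               stringsAsFactors = FALSE)

  ## contiguous coverage across the intron/exon boundary (the acceptor)
  acceptorContig <- vapply(seq_along(ir), function(k)
    any(pl$start <= iEnd[k] & pl$end > iEnd[k] & pl$start > exonEnd[k]),
    logical(1))

  supported <- if (nrow(evDf)) {
    agg <- stats::aggregate(read_id ~ intron + length, data = evDf,
                            FUN = function(x) length(unique(x)))
    names(agg)[3L] <- "supporting_reads"
    agg <- agg[agg$supporting_reads >= minSupport &
                 acceptorContig[agg$intron], , drop = FALSE]
    agg[order(agg$intron, agg$length), , drop = FALSE]
  } else {
    data.frame(intron = integer(0), length = integer(0),
               supporting_reads = integer(0))
  }
  rownames(supported) <- NULL

  flags <- character(0)
  if (length(intronCov) >= 2L) {
    others <- intronCov[-2L]
    if (intronCov[2L] > 0 && intronCov[2L] > enrichFactor * max(others))
      flags <- c(flags, "intron2_enriched")
  }

  new("RetentionReport",
      events = supported,
      intronCoverage = intronCov,
      exonicMeanCoverage = exonicMean,
      anomalous = anDf,
      flags = flags,
      alignedBases = sum(cov),
      unmappedReads = mapping$unmapped,
      clippedBases = sum(mapping$clipped$bases))
}

#' Reading-frame consequence of a retained segment
#'
#' A retained length divisible by 3 inserts \code{length/3} amino acids in
#' frame; any other length is a frameshift (the approximate inserted
#' length before the shift is still reported).
#'
#' @param retained_length retained segment length in bp (> 0).
#' @return list: \code{in_frame}, \code{inserted_aa}, \code{frameshift}.
#' @examples
#' frameConsequence(30)    # in frame, 10 aa
#' frameConsequence(197)   # frameshift
#' @export
frameConsequence <- function(retained_length) {
  if (length(retained_length) != 1L || is.na(retained_length) ||
      retained_length <= 0)
    stop("retained_length must be a single positive number")
  inFrame <- retained_length %% 3 == 0
  list(in_frame = inFrame,
       inserted_aa = as.integer(retained_length %/% 3),
       frameshift = !inFrame)
}

#' Is a sequence segment unique across the RHD and RHCE loci?
#'
#' Exact substring search over both locus models (an in-silico stand-in
#' for a BLAT paralog check): returns TRUE iff the segment occurs exactly
#' once in total.
#'
#' @param segment sequence of length >= 20.
#' @param models list of \linkS4class{GeneModel}s to search; defaults to
#'   RHD + RHCE.
#' @examples
#' m <- rhdModel()
#' i2 <- intronRanges(m)[2]
#' seg <- substr(as.character(modelSequence(m)),
#'               IRanges::end(i2) - 196, IRanges::end(i2))
#' uniquenessCheck(seg)   # the 197 bp acceptor-proximal segment is unique
#' @export
uniquenessCheck <- function(segment,
                            models = list(rhdModel(), rhceModel())) {
  if (nchar(segment) < 20L)
    stop("segment must be at least 20 bp for a meaningful uniqueness check")
  n <- sum(vapply(models, function(m)
    length(findExact(segment, as.character(modelSequence(m)))), integer(1)))
  n == 1L
}
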