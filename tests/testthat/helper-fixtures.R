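# Shared fixtures: the locus set is deterministic and cached by the
# package, so repeated accessor calls are cheap.

locus <- rhdLocusSet()
rhd <- rhdModel(locus)
rhce <- rhceModel(locus)

rhdSeqChar <- as.character(modelSequence(rhd))

## base at an HGVS-style coding position of the reference
refBaseAt <- function(cds, offset = 0L) {
  g <- cdsToGenomic(rhd, cds, offset)
  substr(rhdSeqChar, g, g)
}

## a c. substitution string at a position, with the swapped alternate base
cdotAt <- function(cds, offset = 0L) {
  ref <- refBaseAt(cds, offset)
  alt <- c(A = "G", G = "A", C = "T", T = "C")[[ref]]
  offstr <- if (offset == 0L) "" else sprintf("%+d", offset)
  sprintf("c.%d%s%s>%s", cds, offstr, ref, alt)
}

## diploid sample assembled directly from haplotypes
pairSample <- function(id, hapA, hapB, serology = "D_neg") {
  new("RhdSample", sampleId = id, genotypeName = "custom",
      haplotypeA = hapA, haplotypeB = hapB, serologyLabel = serology)
}
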