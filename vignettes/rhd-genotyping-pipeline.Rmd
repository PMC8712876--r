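---
title: "Molecular RHD genotyping of RhD-negative pregnancy: models and methods"
author: "rhdtyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular RHD genotyping of RhD-negative pregnancy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhdtyper)
```

## The clinical problem

Serologically RhD-negative pregnant women are candidates for Rh
immunoglobulin (RhIG) prophylaxis against anti-D alloimmunization and
hemolytic disease of the fetus and newborn. In East Asian populations,
however, a large fraction of serological D-negatives are not true *RHD*
deletions: the Asian DEL allele (*RHD* c.1227G>A) expresses trace amounts
of antigen and its carriers neither form anti-D nor need RhIG, while hybrid
(RHD-CE(2-9)-D), partial-D (DVI III) and rare point-mutation alleles each
demand their own transfusion and prophylaxis management. Genotype, not
serology, therefore drives management. This package implements the
complete molecular work-up as a simulated, fully testable pipeline:

1. an eight-well PCR with sequence-specific primers (PCR-SSP) resolving
   the common genotype classes;
2. Sanger-style sequencing of the 10 *RHD* exons with HGVS-style variant
   calling and ISBT allele assignment for samples the kit cannot classify;
3. hybrid Rhesus-box PCR for *RHD* zygosity;
4. a decision tree attaching per-allele management advice;
5. mRNA-level intron-retention analysis for the c.336-1G>A splice-acceptor
   allele; and
6. cell-free fetal DNA (cffDNA) based fetal RhD prediction with a
   two-draw resampling policy.

Everything runs on a synthetic locus, so the full pipeline is exercisable
and verifiable without any external data.

## The synthetic mini-locus

`rhdLocusSet()` builds (deterministically — the locus is a package
constant, produced under a fixed internal seed and cached) a pair of
miniature gene models:

* **RHD**: 10 coding exons with the real CDS exon boundary structure
  (exon CDS lengths 148, 187, 151, 148, 167, 138, 134, 80, 74, 27; total
  1254 bp). This pins every position the pipeline needs: c.3 in exon 1,
  the c.335|c.336 boundary on the intron-2/exon-3 junction (so c.336-1 is
  the intron-2 splice acceptor), c.340 in exon 3, and c.1227 as the last
  base of exon 9. Exon and intron sequences themselves are synthetic;
  intron lengths (274–312 bp) are free parameters kept ≥ 250 bp so the
  longest observed retained segment (197 bp) always fits inside intron 2.
  Splice sites are canonical (GT..AG), and the bases at knowledge-base
  variant positions are pinned to their published reference alleles so
  variants such as c.1227G>A are realizable verbatim.
* **RHCE**: the same architecture, with exonic sequence differing from RHD
  at two *diagnostic positions per exon* and entirely unrelated introns
  and flanks. Hybrid alleles (RHD-CE(2-9)-D, DVI III as D-CE(3-6)-D, DVa
  (Hus) as D-CE(5)-D) substitute the RHCE base at the diagnostic positions
  of the replaced exons.
* **Rhesus boxes**: stylized upstream and downstream boxes (3 kb each) and
  a hybrid box built as upstream head + downstream tail. Primer sites are
  placed so the hybrid box yields the published 2,700 bp deletion
  diagnostic product and the internal control yields 1,009 bp; the product
  sizes are the only published constraint, and they are honored exactly.

Internally all coordinates are 1-based closed intervals (the
R/Bioconductor `IRanges` convention); 0-based half-open coordinates appear
only in BED export, and HGVS-style 1-based coding coordinates only at the
`cdsToGenomic()`/`genomicToCds()` boundary. The coordinate map is exact
and is tested by an exhaustive round trip over every locus base.

Both loci are modeled on the plus strand of their own mini-locus; the real
genes' opposite genomic orientation is out of scope, as is any population
allele-frequency modeling.

## Haplotypes, samples, and the generator's defaults

A `Haplotype` is one chromosome's *RHD* state: a structural class
(`intact`, `deletion`, or one of the three RHD-CE hybrids), a point-variant
table, and the matching Rhesus-box type — a deletion haplotype, and only a
deletion haplotype, carries the hybrid box. `makeSample()` assembles named
diploid genotypes; `makeCohort()` with `defaultCohortCounts()` reproduces the
study cohort composition: 48 deletion homozygotes, 11 RHD-CE(2-9)-D, 12
1227A homozygotes, 2 DVI III and the three point-mutation cases
(c.340C>T, c.3G>A, c.336-1G>A — each over a deletion haplotype) in 76
women. These counts are the study's conditions, not tuning knobs.

Two generator choices were genuinely open and are fixed here once:

* RHD-CE(2-9)-D cohort members are modeled hemizygous (hybrid over
  deletion); their zygosity is not reported, and
  hemizygosity is the common configuration for this allele.
* DVI III and the point-mutation carriers are likewise modeled over a
  deletion haplotype, consistent with their D-negative serology labels.

The family fixture (`makeFamily()`) encodes the two-generation c.336-1G>A
pedigree — II-1/II-4 are *RHD+/RHD-*, II-2/II-3 are *RHD+/336-1G>A*, and
III-1/III-5 (the proband) are *RHD-/336-1G>A* — with haplotypes
transmitted Mendelianly from the recorded parent couples. The two members
without a reported genotype (III-3, III-7) are generated
pedigree-consistently but carry `NA` expectations.

## The in-silico PCR-SSP assay

The real kit's primer sequences are proprietary, so the default panel
(`defaultPanel()`) is designed against the synthetic locus, subject to the
kit's documented behavior:

* wells 1–4 test RHD exon presence (exons 1, 3, 5, 7), each footprint
  covering RHD-specific sequence (a diagnostic base, or RHD intron/flank),
  so the ever-present RHCE background and hybrid exons never amplify;
* wells 5/6 are the c.1227 G/A allele-specific pair (3'-terminal
  discriminating base);
* well 7 amplifies the hybrid Rhesus box; well 8 is the c.845A
  (weak D15) allele-specific well.

Amplification requires both primers of a well to match a template exactly
in convergent orientation within 1.5× the expected product size; since
matching is exact over the whole footprint, a 3'-terminal mismatch or any
covered internal mismatch kills the product. Thermocycling parameters do
not affect matching and are not modeled. Two placements are deliberate:
the exon-1 primer ends at c.3 and the exon-3 primer spans the intron-2
acceptor ending at c.340. This reproduces the kit's observed blind spot:
c.3G>A, c.340C>T and c.336-1G>A each extinguish a presence well, match no
signature, and fall through to sequencing — the 3/76 "undetectable"
fraction.

The signature table is data (`extdata/pcr_ssp_signatures.json`), not code.
One interpretive rule is worth stating: the DEL-1227A heterozygote
signature requires both the 1227A well *and* the hybrid-box well, so the
heterozygote call is only issued when a second, deletion-class allele is
evidenced; a 1227A allele over an intact haplotype is reported
undetectable rather than guessed.

## Sequencing tier and zygosity

`extractAmplicons()` produces per-haplotype exon amplicons with 30 bp
flanks (configurable, minimum 2 so splice sites are always covered);
amplicons are clean consensus strings because the wet-lab mixed-trace
problem is an artifact of chromatograms, which are out of scope.
`callVariants()` anchors each amplicon by exact terminal match (12 bp) and
reports every mismatch in HGVS-style coding coordinates, with signed
intron offsets at splice regions; indels are a non-goal (the generator
introduces substitutions only). A property-based test plants 1,000 random
exonic and splice-site substitutions and requires exact single-variant
recovery.

`assignAllele()` maps variant sets onto the ISBT knowledge base by exact
set match; the c.340C>T record carries both published designations
(RHD*10.08 / RHD*01W.17) rather than choosing between them. Unknown
lesions return a sentinel "novel/unassigned" allele whose management is
deliberately conservative (RhIG candidate, manage as positive donor and
negative recipient) and flagged for manual review.

Zygosity (`simulateBoxPcr()` + `combineZygosity()`) is the deletion
discriminator: the hybrid-box product appears iff at least one haplotype
is a deletion, which separates *RHD+/RHD+* from *RHD+/RHD-*. The nine
diploid combinations of {intact, deletion, variant} and their expected
calls ship as a JSON truth table and are verified end-to-end.

## Decision tree and management

`diagnose()` runs PCR-SSP first and stops on any definitive kit class (the
tree never sequences a sample the kit classified); undetectable samples
get the sequencing tier, and zygosity runs when a variant allele needs
diploid resolution (`zygosity = "auto"`; the study applied zygosity to the
family investigation rather than the whole cohort, so it is a triggered
stage, not a mandatory branch). Samples unresolved after both tiers are
referred for extended analysis under the sentinel management. Management
for the DEL-1227A heterozygous kit class is taken from the RHD*01EL.01
row: the antigen-expressing DEL allele governs RhIG need.

`summarizeCohort()` reports class percentages to one decimal place,
tier-1 and total identification rates, and the RhIG-exempt fraction. On
the default cohort these are 96.1% (73/76), 100% (76/76) and 15.8% —
exactly the 1227A-homozygous fraction.

## Intron-retention analysis

The c.336-1G>A mutation destroys the intron-2 constitutive acceptor; a
cryptic acceptor upstream is activated, so transcripts retain a
3'-terminal segment of intron 2 that abuts the exon-3 start.
`makeMrnaReads()` models exactly that: for splice-allele haplotypes a
configurable fraction of transcripts (default 0.8; only the qualitative
observation that retention dominates is available) retains a 3'-terminal
segment with length drawn
from `retentionLengths` (default 31, 90, 144, 197 bp: the observed span's
endpoints plus two interior values, one of them frame-preserving); all
other introns, and all wild-type transcripts, splice correctly. Reads are
150 bp and error-free; sequencing-error modeling is a non-goal. Whether
the distinct product lengths arise from one cryptic acceptor or several is
not asserted — the lengths are free parameters of the generator.

`mapReads()` decomposes each read into exact-match blocks (20 bp seed,
maximal extension, re-seed after each junction). Two mapper details
matter for exactness:

* junction micro-homology is canonicalized to annotated exon boundaries
  (maximal extension can overshoot an exon end when the first intronic
  base coincides with the transcript's next base; the overshot bases are
  shifted onto the downstream block exactly as splice-aware aligners do
  with known sites), which makes retained-length recovery exact rather
  than off-by-micro-homology;
* reads from variant carriers are mapped against a *personalized*
  reference (`personalizeModel()`), since the mutated acceptor base lies
  inside the retained segment and would otherwise fragment exact-match
  blocks. Read tails shorter than the seed beyond a junction are
  soft-clipped and accounted for; unplaceable reads are reported in an
  unmapped bucket, never dropped.

`detectRetention()` records a retention event of length L for intron k
when a read splices from the end of exon k directly to the 3'-terminal L
bases of intron k, requires ≥ 2 supporting junction reads per length
(configurable; whole-blood mRNA yields few informative reads) plus contiguous
coverage across the acceptor, reports junctions not starting at an exon
end as anomalous rather than as retention, and sets the
`intron2_enriched` flag when intron-2 mean coverage exceeds every other
intron's threefold. No hypothesis test is performed — the enrichment
criterion is a logged ratio threshold, because only a qualitative
statement of intron-2 excess is available to model.
`frameConsequence()` translates retained lengths into inserted amino acids
(L/3 when in frame; frameshift otherwise), and `uniquenessCheck()` is the
in-silico stand-in for a BLAT paralog check: exact substring uniqueness
across the RHD + RHCE loci.

## Fetal RhD prediction from cffDNA

`makeCffdnaAssay()` scores exons 1, 5, 6, 7, 9: an exon is positive iff
the maternal genome carries the RHD exon, or the fetal genome carries it
and a per-exon Bernoulli detection succeeds with probability
p(f) = min(1, f/0.04) — a simple ramp in fetal fraction f with p(0) = 0 and
full sensitivity from 4%, chosen because no detection model is published
("likely due to the lower fetal fraction content or PCR bias" is the only
clue) and because it produces early-gestation dropout. Interpretation is
conditioned on the maternal genotype: all five exons are informative for
deletion-homozygous mothers, while exon 1 is maternal background for
RHD-CE(2-9)-D mothers (their hybrid retains RHD exon 1) and only exons
5/6/7/9 are informative. Mothers carrying any variant allele (1227A,
point mutations) are ineligible — their own RHD sequence would make every
draw positive. A first all-negative draw is never reported: the action is
resampling, and only a second all-negative draw reports a D-negative
fetus. "Uncertain" is reserved for pregnancies left without the required
second draw, since the study reports the category with a zero count and
no trigger definition.

`makeNiptFixture()` rebuilds the published fetal cohort: 31 pregnancies
(28 deletion, 3 hybrid mothers; every fetus truly D-positive), 33 plasma
draws. The two resampled pregnancies get a first-draw fetal fraction of 0
— below assay detection under the ramp model, making the reported
early-gestation failure deterministic — and all other draws use fractions
in [0.06, 0.15], where detection is certain. The fixture therefore
reproduces 31/31 positive, 0 negative, 0 uncertain with 2 resamples at
any seed, while fraction values themselves stay stochastic.

One caveat the tests make explicit: the exon rule detects fetal *RHD DNA*,
not antigen. A hypothetical fetus carrying a hybrid or splice-mutation
allele would be flagged positive by design; in the modeled cohort all
fetuses are genuinely D-positive, and a deletion-homozygous (truly
D-negative) fetus is never called positive from maternal background alone.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at the study's own desk
scale: the 76-subject cohort, the 8-member family, 31 pregnancies/33
draws, and mRNA read sets of 300–2,000 reads at 150 bp (2,000 reads give
every default retained length ≥ 30 junction reads, far above the
2-read support threshold). The spike-recovery property uses 1,000 random
substitutions; the retained-length property uses three seeds with random
4-length subsets, checked against a truth-derived support oracle rather
than a fixed expectation, so read-sampling fluctuations cannot produce
spurious failures. Ties and degenerate inputs are handled explicitly:
empty cohorts, deletion-only samples (no transcripts, no amplicons),
all-control-negative assays (assay-invalid, distinct from undetectable),
and contradictory zygosity evidence (inconsistency error) all have
defined, tested behavior.

## Known limitations

* The panel is a synthetic stand-in honoring the kit's published behavior
  (8 classes, the undetectable trio, product sizes); the true well-target
  mapping is unpublished, and any panel satisfying the round-trip
  invariant is equally valid.
* Reads are error-free and single-end; noisy-read alignment, transcript
  assembly and identification of the actual cryptic acceptor motif are out
  of scope.
* Serology is carried as a metadata label only; no serological reflex
  logic beyond the management table is modeled.
* Passing tests demonstrate correctness of the pipeline's logic on data
  generated under this model's assumptions — clean substitution-only
  variation, exact primer chemistry, binary band calls — not performance
  on real traces, gels or plasma.
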