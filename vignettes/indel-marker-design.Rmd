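---
title: "Designing agarose-scorable Indel markers: models and choices"
author: "IndelMarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing agarose-scorable Indel markers: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IndelMarkers)
```

## The problem

Fine-mapping a locus in a crop like maize needs a steady supply of cheap,
co-dominant markers inside an ever-shrinking interval. When two inbred
lines (say the reference line and a diverged line such as Mo17) have a
dense catalog of annotated insertion–deletion polymorphisms, each Indel of
sufficient size is a candidate marker: amplify a short product spanning
it, run the PCR on a high-percentage agarose gel, and read the allele
straight off the fragment length. Heterozygotes are scorable both by the
two allelic bands and by a slow-migrating heteroduplex band.

`IndelMarkers` turns that strategy into a pipeline: filter a polymorphism
track to scorable Indels, design flanking primers, check primer
specificity in silico, predict what each inbred's allele will do
(amplify, at what size, or fail and why), classify the marker for any
inbred pair, and pick evenly spaced candidates inside a mapping interval.

## Data model and coordinates

All coordinates are 1-based and closed, the Bioconductor convention:
tracks are `GRanges` under the hood, genomes are `DNAStringSet`, and the
only 0-based, half-open representation is the BED output, converted by
`rtracklayer` at the boundary. A variant record follows the VCF
convention: position of the first (shared) REF base; its reference
footprint is `pos .. pos + nchar(ref) - 1`. The size of a variant is its
*net length*, `|nchar(ref) - nchar(alt)|`. An alternative reading of an
Indel's "size" is its gapped alignment length; we use net allele-length
difference throughout because that is the quantity that shifts an
amplicon's length on a gel, which is what the marker scores.

The default filter keeps Indels with net length ≥ 7 bp (inclusive). That
threshold is the practical floor for calling a fragment-length difference
on 4% agarose when products are kept short; it is a parameter
(`minNetLength`) everywhere it is used.

## Haplotype arithmetic

`buildHaplotype()` applies a track to the reference; overlapping variants
are rejected at construction because their joint application order is
undefined. `segmentSize()` returns the haplotype length of a reference
interval as `interval length + Σ signed net lengths` of the contained
Indels, and `haplotypeSeq()` splices the actual sequence. A variant whose
footprint straddles an interval boundary raises an error instead of being
truncated: silently clipping an Indel would corrupt every downstream size
prediction, and the primer designer guarantees the situation cannot arise
for designed amplicons (primers never sit on variants unless the user
disables linkage avoidance, and then failure is modeled, not ignored).
Insertions anchor VCF-style: the inserted bases fall after the anchor
base, and containment tests use the reference footprint.

## Primer design

The designer enumerates every primer placement strictly flanking the
target footprint whose reference amplicon is 80–300 bp, applies hard
constraints, and ranks survivors by a deterministic penalty. Defaults,
all tunable in `designConfig()`:

| parameter | default | why |
|---|---|---|
| amplicon length | 80–300 bp | short products resolve small Indels on 4% agarose |
| primer length | 18–27 nt | standard PCR practice |
| Tm | 55–63 °C, pair within 3 °C | conventional touchdown-free cycling window |
| GC | 30–70 % | avoids pathological annealing |
| homopolymer | ≤ 5 nt | slippage-prone runs |
| 3' clamp | last 5 nt variant-free, always | a 3'-terminal mismatch kills extension |
| `avoidLinked` | `TRUE` | primer sites free of known linked variants, so the non-reference allele is not silently lost |

Melting temperatures come from the unified nearest-neighbor
thermodynamic model (SantaLucia & Hicks parameters) with an entropic salt
correction `0.368 (N−1) ln[Na+]`, at 50 mM monovalent salt and 25 nM per
strand; self-complementary oligos get the symmetry entropy term and the
undiluted strand concentration. These constants are printed in report
headers for provenance. The model is strand-symmetric, which the
implementation exploits to screen reverse-primer candidates on the top
strand.

The ranking penalty is a weighted sum of |Tm − range midpoint| for each
primer, the pair Tm difference, |GC − midpoint|, the longest homopolymer
run, and the longest 3'-terminal cross-complementary run between the two
primers (a primer-dimer heuristic, capped at 8 nt — anything longer is
equally disqualifying). Ties break toward the smaller reference amplicon,
then the leftmost forward primer: smaller products make small size
differences easier to resolve, so when two designs score equally the
shorter one is the better marker. The search is exact: a branch-and-bound
over per-primer penalty parts prunes pairs that provably cannot reach the
requested top list, and the returned ranking equals full enumeration.

The amplicon bounds are the one pair of constraints treated as
load-bearing; primer length/Tm/GC defaults are ordinary PCR practice with
no external ground truth to validate against, and are therefore exposed
as free parameters rather than baked in.

## In-silico PCR and the specificity criterion

Genome-wide specificity replaces an alignment-based search with direct
primer-site scanning: every site of either primer on either strand with
at most 2 mismatches — but none in the 3'-terminal 5 bases — is found,
and every convergent site pair within 2,000 bp is reported as a potential
product. A pair is *specific* when exactly one product exists genome-wide
(`isSpecific()`); the designed locus itself always appears as the
self-hit. The criteria (2 mismatches, exact 3' pentamer, 2 kb scan) are
configurable; they encode the observation that PCR tolerates a couple of
internal mismatches but almost never a 3'-terminal one.

## Predicting per-inbred amplicons and failures

`predictAmplicon()` runs a primer pair against one inbred haplotype and
applies the failure model in a fixed order:

1. any variant under a primer's 3' clamp → `PRIMER_SITE_VARIANT_3PRIME`;
2. a deletion removing part of a primer footprint → `PRIMER_SITE_DELETED`;
3. more than `maxMismatches` (default 2) variants in one primer site →
   `PRIMER_SITE_DIVERGENCE`;
4. otherwise the product amplifies at the reference length shifted by the
   interior Indels, and the surviving primer-site mismatches are counted
   as the `competitionHandicap`.

An insertion strictly inside a primer footprint counts as one mismatch
(it interrupts the annealed duplex without removing template); an
insertion anchored exactly at a primer's last base falls outside the
footprint and is treated as interior sequence.

Dominance deserves a caveat. Whether one allele out-competes the other in
a heterozygous template is a kinetic property of the reaction that
sequence alone cannot fully predict. The package models it through the
handicap: when both alleles amplify but one primer site carries more
sub-lethal mismatches, the cleaner allele is called `DOMINANT` over the
other. This reproduces the observed direction — primers designed on the
reference genome favor the reference allele — but it is a model of the
mechanism, not a claim about it, and the one reported case of the
polarity reversing has no sequence-level explanation to implement.

## The gel model and classification

Two products are resolvable on the modeled 4% gel when their difference
is at least `max(4, 0.05 × mean length)`. The relative term encodes the
small-product rule: a 7-bp difference reads easily at ~100 bp and not at
all at ~300 bp. The constants are calibrated so that 11–19 bp differences
on 143–255 bp products resolve while 7 bp on 300 bp does not, and both
are `gelModel()` parameters. The heteroduplex band's apparent size is the
larger allele plus a fixed cosmetic offset; only its presence (both
alleles amplify at distinct sizes) is contract-tested, because gels
position heteroduplexes too idiosyncratically to model further.

`classifyMarker()` then maps a pair of predictions to the five-way
verdict: `FAILED` (neither), `PAV` (one), `DOMINANT` (both, unequal
handicap), `CO_DOMINANT` (both, clean, resolvable), `NON_POLYMORPHIC`
(both, clean, unresolvable). `validateAnnotation()` audits an annotation
against observed sizes into `CONCORDANT` / `WRONG_DIRECTION` /
`SAME_SIZE` / `NO_PRODUCT`; a size change in the annotated direction but
of unexpected magnitude still counts as `CONCORDANT`, since gel-read
sizes are approximate and the audit's purpose is to flag annotations
whose direction or existence is contradicted.

## Spacing and interval selection

`spacingStats()` pools successive-position gaps within chromosomes (never
across), reporting per-chromosome and aggregate mean/median. Pooling —
rather than averaging per-chromosome means — is what a single
genome-wide "average marker distance" figure refers to; the per-chromosome
table is there when the distinction matters.

`selectEvenlySpaced()` places `k` ideal anchors at interior positions
`start + i (end − start)/(k + 1)` and assigns each the nearest unused
candidate (ties to the lower coordinate). Interior anchors, excluding the
endpoints, reflect practice: the interval's ends are usually the already
genotyped flanking markers of the previous round. `refineInterval()`
shrinks the interval to the tightest flanking pair consistent with the
recombinants' genotypes and errors on contradictions, which indicate a
genotyping problem upstream; iterating select → genotype → refine is the
fine-mapping loop.

## The simulator: what it does and does not emulate

`simulateGenome()` generates an i.i.d. uniform-composition genome,
optional verbatim segmental duplications (so specificity rejection has
real work to do), and per-inbred non-overlapping SNPs and Indels at
configurable per-base rates, with every planted variant recorded in a
manifest. Defaults — 2 chromosomes, 100 kb each, SNP rate 1.5 × 10⁻³/bp,
Indel rate 5 × 10⁻⁴/bp, net lengths geometrically decaying over 1–50 bp
(ratio 0.85) — give about two variants per kb, the density scale of a
diverged-inbred polymorphism track, with enough ≥ 7 bp Indels to design
against. The seed is mandatory; identical configurations give
byte-identical FASTA/VCF output.

What the simulator does *not* reproduce: real base composition,
repeat and transposon structure, linkage disequilibrium, clustering of
polymorphism density (pericentromeric deserts), or annotation error.
Passing tests on simulated data therefore demonstrate the pipeline's
internal correctness — sizes, classifications and specificity follow
exactly from the planted truth — not that any particular wet-lab success
rate will be achieved on real germplasm, where annotation disagreement
alone affects a noticeable fraction of loci.

`plantFig1Fixtures()` complements the random simulator with six
deterministic loci reproducing the canonical marker behavior classes
(three-allele co-dominance, primer-site deletion PAV, handicap-driven
dominance, and an annotation that the haplotype contradicts). The
sequences are generated, not copied from any real genome; only the size
arithmetic and verdicts are meaningful.

## Problem sizes used in the shipped checks

The package's own validation runs at sizes chosen to make every check
exact yet quick on a laptop: the recovery experiment simulates two 3-Mb
chromosomes (~1,000 designable ≥ 7 bp Indels), designs one pair per
target and requires the predicted size shift to equal the manifest's
planted shift for 100% of designed markers; the sliding-scan PCR oracle
runs on ≤ 20 kb genomes where the naive scan is affordable; the synthetic
spacing catalog uses 38,223 markers with log-normal gaps (10-kb median,
53.7-kb mean) to mirror the scale and skew of a genome-wide Indel table.

## Known limitations

- No thermodynamic secondary-structure folding (hairpins) beyond the
  homopolymer and 3'-dimer heuristics; no multiplex compatibility.
- Inbreds are fully homozygous by assumption; there is no diploid
  phasing.
- In-silico PCR counts substitution mismatches only; a primer site
  interrupted by a small Indel is handled by the failure model, not by
  gapped site matching.
- The dominance model is a proxy (see above); wet-lab dominance rates
  will not match simulation-derived ones.
- Percentage reporting rounds half-up to integers, which is how such
  panel tables are conventionally printed; recover exact fractions from
  the counts, which are always emitted alongside.
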