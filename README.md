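# IndelMarkers

Design and in-silico evaluation of agarose-scorable insertion–deletion
(Indel) markers for fine-mapping in inbred crops.

## Why

Positional cloning in a species like maize lives or dies on cheap markers
inside the current mapping interval. When a dense catalog of annotated
SNP/Indel polymorphisms between two inbred lines exists (e.g. the
reference line and a resequenced line such as Mo17), every Indel with a
net allele-length difference of at least ~7 bp is a candidate marker: PCR
a short product across it and read the genotype as a fragment-length
polymorphism on a 4% agarose gel. Heterozygotes show both allelic bands
plus a slow heteroduplex band. `IndelMarkers` implements that strategy end
to end, for people running fine-mapping projects and for anyone who wants
to simulate and stress-test the marker-design logic offline.

## What it computes

For a variant record with reference allele `R` and alternate allele `A`
at position `p` (VCF convention), the package works with the net length
`ℓ = |len(R) − len(A)|` and the signed shift `s = len(A) − len(R)`. The
haplotype length of a reference interval `[a, b]` is

    size(a, b) = (b − a + 1) + Σ s_i   over Indels contained in [a, b],

which is what a gel sees. Primer pairs flanking a target Indel are
enumerated under hard constraints (80–300 bp reference amplicon, 18–27 nt,
Tm 55–63 °C by the unified nearest-neighbor model, GC 30–70 %,
homopolymers ≤ 5 nt, variant-free 3' clamps) and ranked by a deterministic
penalty. Specificity is checked by in-silico PCR: all convergent
primer-site pairs genome-wide with ≤ 2 mismatches per site and an exact
3'-terminal pentamer, within 2 kb. Per-inbred predictions classify each
marker for an inbred pair as

    CO_DOMINANT | DOMINANT | PAV | NON_POLYMORPHIC | FAILED

where resolvability on the gel requires `|Δsize| ≥ max(4, 0.05 × mean
size)`. Spacing statistics and evenly spaced in-interval selection support
the iterative fine-mapping loop. A seeded simulator generates toy genomes
and variant tracks with a full ground-truth manifest, so everything is
testable with no downloads.

## Worked example

```r
library(IndelMarkers)

sim    <- simulateGenome(simConfig(nChroms = 1, chromLength = 50000,
                                   inbredNames = "Mo17",
                                   indelRate = 1e-3, seed = 7))
track  <- sim$tracks$Mo17
targets <- filterIndels(track, 7)          # scorable Indels, net length >= 7
pair   <- designPrimers(sim$genome, targets[2],
                        linkedTrack = track, maxPairs = 1)[[1]]
pair
#> PrimerPair 'sim_Mo17_chr1_006325' (chr1): 122-bp reference amplicon
#>   F chr1:6256-6280 ACCTAGTCGCCAGTACAAGGTGCTA (Tm 59.0, GC 52%)
#>   R chr1:6351-6377 TCACTTAGACTGGAGGAGAGTAAGCCG (Tm 58.9, GC 52%)

isSpecific(insilicoPcr(sim$genome, pair))
#> [1] TRUE

ref   <- buildHaplotype(sim$genome, polymorphismTrack(
           character(), integer(), character(), character(), character(),
           inbredName = "B73"))
mo17  <- buildHaplotype(sim$genome, track)
predictAmplicon(pair, ref)
#> AmpliconPrediction 'B73': 122-bp product (handicap 0)
predictAmplicon(pair, mo17)
#> AmpliconPrediction 'Mo17': 137-bp product (handicap 0)
classifyMarker(predictAmplicon(pair, ref), predictAmplicon(pair, mo17))
#> MarkerClassification: CO_DOMINANT, heteroduplex expected
```

The target is a planted 15-bp insertion: the reference allele amplifies
at 122 bp, the Mo17 allele at 137 bp, the pair is unique in the genome,
and the 15-bp difference on a ~130-bp product is comfortably resolvable —
a co-dominant marker, with a heteroduplex band expected in heterozygotes.

`spacingStats(track)` and `selectEvenlySpaced(track,
mappingInterval("chr1:10000-40000", k = 5))` then drive the
select-genotype-refine loop; see the vignette
(`vignettes/indel-marker-design.Rmd`) for the models and their
assumptions.

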