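#' @import methods
#' @importFrom stats median rbinom runif
#' @importFrom utils read.table write.table packageVersion
NULL

VERDICT_LEVELS <- c("CO_DOMINANT", "DOMINANT", "PAV", "NON_POLYMORPHIC", "FAILED")
FAILURE_LEVELS <- c("NONE", "PRIMER_SITE_VARIANT_3PRIME",
                    "PRIMER_SITE_DIVERGENCE", "PRIMER_SITE_DELETED")
ANNOTATION_LEVELS <- c("CONCORDANT", "WRONG_DIRECTION", "SAME_SIZE", "NO_PRODUCT")

#' Per-inbred polymorphism track
#'
#' Ordered collection of SNP and Indel records annotated on a reference
#' genome for one inbred line. Records are held as a [GenomicRanges::GRanges]
#' whose ranges are the reference footprint of each variant (VCF convention:
#' the first REF base is shared, `start` is the VCF POS, `width` is
#' `nchar(ref)`), with metadata columns `ref`, `alt`, `id` and `netLength`
#' (`abs(nchar(ref) - nchar(alt))`; 0 for SNPs).
#'
#' @slot records `GRanges` of variant footprints, sorted by (chrom, pos).
#' @slot inbredName single string naming the inbred the track describes.
#' @seealso [polymorphismTrack()], [readTrack()], [filterIndels()]
#' @exportClass PolymorphismTrack
setClass("PolymorphismTrack",
         slots = c(records = "GRanges", inbredName = "character"))

setValidity("PolymorphismTrack", function(object) {
  gr <- object@records
  msg <- character()
  if (length(object@inbredName) != 1L || is.na(object@inbredName))
    msg <- c(msg, "inbredName must be a single non-NA string")
  need <- c("ref", "alt", "id", "netLength")
  if (!all(need %in% names(S4Vectors::mcols(gr))))
    return(paste("records must carry mcols:", paste(need, collapse = ", ")))
  if (length(gr)) {
    m <- S4Vectors::mcols(gr)
    if (any(grepl("[^ACGTN]", m$ref)) || any(grepl("[^ACGTN]", m$alt)))
      msg <- c(msg, "alleles restricted to A/C/G/T/N")
    if (!identical(GenomicRanges::width(gr), nchar(m$ref)))
      msg <- c(msg, "range width must equal nchar(ref)")
    if (!identical(as.integer(m$netLength),
                   as.integer(abs(nchar(m$ref) - nchar(m$alt)))))
      msg <- c(msg, "netLength must be abs(nchar(ref) - nchar(alt))")
    o <- order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr))
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "records must be sorted by (chrom, pos)")
    key <- paste(GenomicRanges::seqnames(gr), GenomicRanges::start(gr), m$ref, m$alt)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chrom, pos, ref, alt) records")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Inbred haplotype: reference genome plus an applied variant track
#'
#' Represents the (fully homozygous) genome of one inbred line as the
#' reference sequence with the track's SNPs and Indels applied. Variants
#' within the track must not overlap one another; an empty track yields the
#' reference verbatim. Sequence over any reference interval is materialised
#' lazily by [haplotypeSeq()]; sizes come from [segmentSize()].
#'
#' @slot genome `DNAStringSet` reference chromosomes.
#' @slot track [PolymorphismTrack-class] applied to the reference.
#' @seealso [buildHaplotype()]
#' @exportClass InbredHaplotype
setClass("InbredHaplotype",
         slots = c(genome = "DNAStringSet", track = "PolymorphismTrack"))

#' Primer design configuration
#'
#' Hard constraints, thermodynamic constants and ranking weights used by
#' [designPrimers()] and [scorePair()]. Amplicon bounds default to the
#' 80-300 bp window that keeps products resolvable on 4% agarose; primer
#' length, melting temperature (Tm) and GC bounds are standard PCR practice
#' and fully configurable.
#'
#' @slot ampliconMin,ampliconMax reference amplicon length bounds (bp).
#' @slot primerLenMin,primerLenMax primer length bounds (nt).
#' @slot tmMin,tmMax allowed primer Tm range (degrees C).
#' @slot tmPairMaxDiff maximum |Tm_fwd - Tm_rev| (degrees C).
#' @slot gcMin,gcMax allowed GC content (%).
#' @slot maxHomopolymer longest tolerated single-base run (nt).
#' @slot avoidLinked if `TRUE`, no primer footprint may overlap any linked
#'   track variant; the 3'-terminal clamp is kept variant-free regardless.
#' @slot clamp3p number of 3'-terminal bases that must be polymorphism-free
#'   and match the template exactly (nt).
#' @slot saltMolar monovalent cation concentration for Tm (mol/L).
#' @slot primerNanomolar per-strand oligo concentration for Tm (nM).
#' @slot wTm,wTmDiff,wGc,wHomopolymer,wDimer penalty weights (see
#'   [scorePair()]).
#' @seealso [designConfig()]
#' @exportClass DesignConfig
setClass("DesignConfig",
         slots = c(ampliconMin = "integer", ampliconMax = "integer",
                   primerLenMin = "integer", primerLenMax = "integer",
                   tmMin = "numeric", tmMax = "numeric",
                   tmPairMaxDiff = "numeric",
                   gcMin = "numeric", gcMax = "numeric",
                   maxHomopolymer = "integer", avoidLinked = "logical",
                   clamp3p = "integer", saltMolar = "numeric",
                   primerNanomolar = "numeric",
                   wTm = "numeric", wTmDiff = "numeric", wGc = "numeric",
                   wHomopolymer = "numeric", wDimer = "numeric"))

setValidity("DesignConfig", function(object) {
  msg <- character()
  if (object@ampliconMin >= object@ampliconMax)
    msg <- c(msg, "ampliconMin must be < ampliconMax")
  if (object@primerLenMin > object@primerLenMax)
    msg <- c(msg, "primer length range empty")
  if (object@tmMin > object@tmMax) msg <- c(msg, "tm range empty")
  if (object@gcMin > object@gcMax) msg <- c(msg, "gc range empty")
  if (object@clamp3p < 1L) msg <- c(msg, "clamp3p must be >= 1")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' A primer pair flanking a target Indel
#'
#' Two oligos on the reference top strand: `forwardSeq` equals the reference
#' over `forwardRange`; `reverseSeq` is the reverse complement of the
#' reference over `reverseRange`. The target variant's reference footprint
#' lies strictly between the two footprints, so the reference amplicon spans
#' `start(forwardRange)` .. `end(reverseRange)`.
#'
#' @slot targetId id of the Indel the pair was designed for.
#' @slot chrom chromosome name.
#' @slot forwardSeq,reverseSeq primer sequences, 5'->3'.
#' @slot forwardRange,reverseRange `IRanges` reference footprints (1-based,
#'   closed).
#' @slot tmF,tmR nearest-neighbor melting temperatures (degrees C).
#' @slot gcF,gcR GC content (%).
#' @slot refAmpliconLen reference product length (bp).
#' @seealso [designPrimers()], [insilicoPcr()], [predictAmplicon()]
#' @exportClass PrimerPair
setClass("PrimerPair",
         slots = c(targetId = "character", chrom = "character",
                   forwardSeq = "character", reverseSeq = "character",
                   forwardRange = "IRanges", reverseRange = "IRanges",
                   tmF = "numeric", tmR = "numeric",
                   gcF = "numeric", gcR = "numeric",
                   refAmpliconLen = "integer"))

setValidity("PrimerPair", function(object) {
  msg <- character()
  if (nchar(object@forwardSeq) != IRanges::width(object@forwardRange))
    msg <- c(msg, "forwardSeq length must match forwardRange width")
  if (nchar(object@reverseSeq) != IRanges::width(object@reverseRange))
    msg <- c(msg, "reverseSeq length must match reverseRange width")
  if (IRanges::end(object@forwardRange) >= IRanges::start(object@reverseRange))
    msg <- c(msg, "forward footprint must lie left of reverse footprint")
  span <- IRanges::end(object@reverseRange) - IRanges::start(object@forwardRange) + 1L
  if (object@refAmpliconLen != span)
    msg <- c(msg, "refAmpliconLen inconsistent with primer footprints")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Agarose gel resolvability model
#'
#' Two products are called resolvable on a high-percentage (4%) agarose gel
#' when their length difference is at least
#' `max(minAbsDiff, relDiffFrac * mean(lengths))`. The relative term encodes
#' the practical rule that small differences resolve only on small products;
#' defaults are calibrated so 11-19 bp differences on 143-255 bp products
#' resolve while a 7 bp difference on a ~300 bp product does not.
#'
#' @slot minAbsDiff absolute floor on the resolvable difference (bp).
#' @slot relDiffFrac required difference as a fraction of mean length.
#' @slot heteroduplexOffset apparent extra size of the slow heteroduplex
#'   band relative to the larger allele (bp, cosmetic).
#' @seealso [gelModel()], [resolvableOnGel()]
#' @exportClass GelModel
setClass("GelModel",
         slots = c(minAbsDiff = "numeric", relDiffFrac = "numeric",
                   heteroduplexOffset = "numeric"))

setValidity("GelModel", function(object) {
  if (object@minAbsDiff < 1) return("minAbsDiff must be >= 1")
  if (object@relDiffFrac <= 0 || object@relDiffFrac >= 1)
    return("relDiffFrac must be in (0, 1)")
  TRUE
})

#' Predicted PCR product for one inbred
#'
#' Outcome of running a primer pair against one inbred haplotype in silico.
#' When amplification fails, `failureReason` is one of
#' `PRIMER_SITE_VARIANT_3PRIME` (a variant falls under a primer's 3' clamp),
#' `PRIMER_SITE_DELETED` (a deletion removes part of a primer footprint) or
#' `PRIMER_SITE_DIVERGENCE` (more mismatches in one primer site than PCR
#' tolerates). Sub-lethal primer-site mismatches are tallied in
#' `competitionHandicap`; in mixed template the allele with the larger
#' handicap is out-competed.
#'
#' @slot inbredName inbred the prediction refers to.
#' @slot amplifies does the pair produce a product?
#' @slot productLen product length (bp); `NA` when no product.
#' @slot failureReason `"NONE"` or the failure mode above.
#' @slot competitionHandicap total sub-lethal primer-site mismatches.
#' @seealso [predictAmplicon()], [classifyMarker()]
#' @exportClass AmpliconPrediction
setClass("AmpliconPrediction",
         slots = c(inbredName = "character", amplifies = "logical",
                   productLen = "integer", failureReason = "character",
                   competitionHandicap = "integer"))

setValidity("AmpliconPrediction", function(object) {
  msg <- character()
  if (!object@failureReason %in% FAILURE_LEVELS)
    msg <- c(msg, "unknown failureReason")
  if (!object@amplifies && object@failureReason == "NONE")
    msg <- c(msg, "failed amplification requires a failure reason")
  if (object@amplifies != !is.na(object@productLen))
    msg <- c(msg, "productLen must be present iff amplifies")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Pairwise marker verdict
#'
#' Classification of one marker for a pair of inbreds:
#' `CO_DOMINANT` (both amplify, sizes resolvable on gel), `DOMINANT` (both
#' amplify singly but one allele is suppressed in mixed template), `PAV`
#' (presence-absence: exactly one amplifies), `NON_POLYMORPHIC` (both
#' amplify, indistinguishable) or `FAILED` (neither amplifies).
#' `favoredAllele` names the preferentially amplifying (DOMINANT) or sole
#' amplifying (PAV) inbred.
#'
#' @slot verdict one of the five classes above.
#' @slot favoredAllele inbred name or `NA`.
#' @slot resolvable are the two product sizes gel-resolvable?
#' @slot heteroduplexExpected do both alleles amplify with distinct sizes
#'   (heterozygous template then shows a slow heteroduplex band)?
#' @seealso [classifyMarker()], [summarizeClassifications()]
#' @exportClass MarkerClassification
setClass("MarkerClassification",
         slots = c(verdict = "character", favoredAllele = "character",
                   resolvable = "logical", heteroduplexExpected = "logical"))

setValidity("MarkerClassification", function(object) {
  msg <- character()
  if (!object@verdict %in% VERDICT_LEVELS) msg <- c(msg, "unknown verdict")
  if (object@verdict %in% c("DOMINANT", "PAV") && is.na(object@favoredAllele))
    msg <- c(msg, "DOMINANT/PAV require favoredAllele")
  if (!object@verdict %in% c("DOMINANT", "PAV") && !is.na(object@favoredAllele))
    msg <- c(msg, "favoredAllele only set for DOMINANT/PAV")
  if (object@verdict == "CO_DOMINANT" && !isTRUE(object@resolvable))
    msg <- c(msg, "CO_DOMINANT requires resolvable sizes")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Fine-mapping interval
#'
#' A reference interval (1-based, closed) within which `k` evenly spaced
#' candidate markers are requested for the next round of fine-mapping.
#'
#' @slot chrom chromosome name.
#' @slot start,end interval bounds (bp, 1-based closed, `start < end`).
#' @slot k number of markers requested.
#' @seealso [mappingInterval()], [selectEvenlySpaced()], [refineInterval()]
#' @exportClass MappingInterval
setClass("MappingInterval",
         slots = c(chrom = "character", start = "numeric", end = "numeric",
                   k = "integer"))

setValidity("MappingInterval", function(object) {
  msg <- character()
  if (object@start >= object@end) msg <- c(msg, "start must be < end")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Inter-polymorphism spacing statistics
#'
#' Gaps are successive position differences between consecutive records
#' within a chromosome; no gap spans two chromosomes. The aggregate pools
#' all within-chromosome gaps genome-wide.
#'
#' @slot perChrom data.frame with columns `chrom`, `nMarkers`, `nGaps`,
#'   `meanGap`, `medianGap` (chromosomes with >= 2 records only).
#' @slot aggregate named numeric: `nMarkers`, `nGaps`, `meanGap`, `medianGap`.
#' @seealso [spacingStats()]
#' @exportClass SpacingStats
setClass("SpacingStats",
         slots = c(perChrom = "data.frame", aggregate = "numeric"))

#' Simulation configuration
#'
#' Parameters of the seeded toy-genome simulator. Per-base SNP and Indel
#' rates, the Indel net-length distribution and the duplicated fraction of
#' the genome control the statistical structure of the generated tracks;
#' `seed` is mandatory so every simulation is reproducible.
#'
#' @slot nChroms number of chromosomes.
#' @slot chromLength length of each chromosome (bp).
#' @slot inbredNames names of the non-reference inbreds to generate tracks
#'   for.
#' @slot snpRate per-base SNP probability.
#' @slot indelRate per-base Indel probability.
#' @slot indelLengthProbs probability weights over net lengths 1..50 bp.
#' @slot duplicationFraction fraction of the genome copied verbatim
#'   elsewhere (exercises specificity rejection).
#' @slot dupSegmentLength length of each duplicated segment (bp).
#' @slot seed RNG seed (mandatory).
#' @seealso [simConfig()], [simulateGenome()]
#' @exportClass SimConfig
setClass("SimConfig",
         slots = c(nChroms = "integer", chromLength = "integer",
                   inbredNames = "character", snpRate = "numeric",
                   indelRate = "numeric", indelLengthProbs = "numeric",
                   duplicationFraction = "numeric",
                   dupSegmentLength = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@snpRate < 0 || object@snpRate > 1 ||
      object@indelRate < 0 || object@indelRate > 1)
    msg <- c(msg, "rates must lie in [0, 1]")
  if (length(object@indelLengthProbs) != 50L ||
      any(object@indelLengthProbs < 0) || sum(object@indelLengthProbs) <= 0)
    msg <- c(msg, "indelLengthProbs must be 50 non-negative weights")
  if (object@duplicationFraction < 0 || object@duplicationFraction >= 1)
    msg <- c(msg, "duplicationFraction must lie in [0, 1)")
  if (is.na(object@seed)) msg <- c(msg, "seed is mandatory")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
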