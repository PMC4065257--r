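#' Create an agarose gel resolvability model
#'
#' @param minAbsDiff absolute floor on resolvable size difference (bp).
#' @param relDiffFrac required difference as a fraction of the mean product
#'   length.
#' @param heteroduplexOffset apparent extra size of the slow heteroduplex
#'   band (bp).
#' @return a [GelModel-class].
#' @export
gelModel <- function(minAbsDiff = 4, relDiffFrac = 0.05,
                     heteroduplexOffset = 25) {
  new("GelModel", minAbsDiff = minAbsDiff, relDiffFrac = relDiffFrac,
      heteroduplexOffset = heteroduplexOffset)
}

## Byte-wise mismatch positions between two equal-length ACGT strings.
mismatchPositions <- function(a, b) {
  which(charToRaw(a) != charToRaw(b))
}

## Primer binding sites of `primer` on one chromosome string.
## role "plus": primer sequence equals the top strand, 3' end on the right
## (primes rightward). role "minus": primer equals the bottom strand
## (revcomp on top), 3' end on the left of the top-strand match (primes
## leftward). Sites must have <= maxMismatches total and none in the
## 3'-terminal exact3p bases.
primerSites <- function(chromSeq, primer, role, maxMismatches, exact3p) {
  pat <- if (role == "plus") primer else revcomp(primer)
  m <- Biostrings::matchPattern(Biostrings::DNAString(pat), chromSeq,
                                max.mismatch = maxMismatches)
  if (!length(m)) return(NULL)
  L <- nchar(pat)
  starts <- BiocGenerics::start(m)
  matched <- as.character(m)
  keep <- logical(length(m))
  nmis <- integer(length(m))
  for (i in seq_along(m)) {
    mp <- mismatchPositions(pat, matched[i])
    nmis[i] <- length(mp)
    clampOk <- if (role == "plus") all(mp <= L - exact3p) else all(mp > exact3p)
    keep[i] <- clampOk && nmis[i] <= maxMismatches
  }
  if (!any(keep)) return(NULL)
  data.frame(start = starts[keep], end = starts[keep] + L - 1L,
             mismatches = nmis[keep], stringsAsFactors = FALSE)
}

#' In-silico PCR: genome-wide products of a primer pair
#'
#' Scans every chromosome for binding sites of both primers on both
#' strands (allowing up to `maxMismatches` per primer but none in the
#' 3'-terminal `exact3p` bases) and reports every convergent site pair
#' within `maxProductScan` bp as a potential product. The designed locus
#' itself always appears as a self-hit; a pair is *specific* when it is
#' the only hit genome-wide (see [isSpecific()]).
#'
#' @param genome `DNAStringSet`.
#' @param pair a [PrimerPair-class].
#' @param maxMismatches tolerated mismatches per primer site.
#' @param exact3p 3'-terminal bases that must match exactly (nt).
#' @param maxProductScan largest product considered amplifiable (bp).
#' @return data.frame of hits: `chrom`, `start`, `end`, `productLen`,
#'   `fwdMismatches`/`revMismatches` (mismatches at the left/plus and
#'   right/minus primer site), `orientation` (which primer primes
#'   rightward/leftward, e.g. `"F>R"` for the designed orientation).
#' @export
insilicoPcr <- function(genome, pair, maxMismatches = 2L, exact3p = 5L,
                        maxProductScan = 2000L) {
  hits <- list()
  for (chrom in names(genome)) {
    chromSeq <- genome[[chrom]]
    plus <- list(F = primerSites(chromSeq, pair@forwardSeq, "plus",
                                 maxMismatches, exact3p),
                 R = primerSites(chromSeq, pair@reverseSeq, "plus",
                                 maxMismatches, exact3p))
    minus <- list(F = primerSites(chromSeq, pair@forwardSeq, "minus",
                                  maxMismatches, exact3p),
                  R = primerSites(chromSeq, pair@reverseSeq, "minus",
                                  maxMismatches, exact3p))
    for (pRole in c("F", "R")) for (mRole in c("F", "R")) {
      a <- plus[[pRole]]; b <- minus[[mRole]]
      if (is.null(a) || is.null(b)) next
      for (i in seq_len(nrow(a))) {
        ok <- b$start > a$end[i] & b$end - a$start[i] + 1L <= maxProductScan
        if (!any(ok)) next
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = a$start[i], end = b$end[ok],
          productLen = b$end[ok] - a$start[i] + 1L,
          fwdMismatches = a$mismatches[i], revMismatches = b$mismatches[ok],
          orientation = paste0(pRole, ">", mRole),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      productLen = integer(), fwdMismatches = integer(),
                      revMismatches = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' @rdname insilicoPcr
#' @param hits data.frame returned by `insilicoPcr()`.
#' @return `isSpecific()`: `TRUE` when exactly one product is predicted
#'   genome-wide.
#' @export
isSpecific <- function(hits) nrow(hits) == 1L

## Effect of a variant on a primer site, as reference coordinates:
## SNP -> substituted base; deletion -> the deleted bases (anchor excluded);
## insertion -> the junction it interrupts (empty range at pos, encoded as
## [pos, pos] with type "ins" and tested against junctions).
variantEffects <- function(gr) {
  m <- S4Vectors::mcols(gr)
  pos <- GenomicRanges::start(gr)
  endp <- GenomicRanges::end(gr)
  refLen <- nchar(m$ref); altLen <- nchar(m$alt)
  type <- ifelse(refLen > 1L, "del", ifelse(altLen > 1L, "ins", "snp"))
  effStart <- ifelse(type == "del", pos + 1L, pos)
  effEnd <- ifelse(type == "del", endp, pos)
  data.frame(pos = pos, effStart = effStart, effEnd = effEnd, type = type,
             net = altLen - refLen, id = m$id, stringsAsFactors = FALSE)
}

## Does the variant effect disturb bases (or the junctions between bases)
## of [lo, hi]? Insertions interrupt the junction (pos, pos+1): they only
## disturb the window when pos in [lo, hi-1].
effectOverlaps <- function(eff, lo, hi) {
  ifelse(eff$type == "ins",
         eff$pos >= lo & eff$pos <= hi - 1L,
         eff$effEnd >= lo & eff$effStart <= hi)
}

#' Predict the PCR product of a primer pair on one inbred haplotype
#'
#' Applies the amplification-failure model to the variants overlapping the
#' pair's locus: a variant under a primer's 3'-terminal clamp kills
#' extension (`PRIMER_SITE_VARIANT_3PRIME`); a deletion removing part of a
#' primer footprint leaves nothing to anneal to
#' (`PRIMER_SITE_DELETED`); more than `maxMismatches` sub-lethal mismatches
#' in one primer site models failure by nucleotide divergence
#' (`PRIMER_SITE_DIVERGENCE`). Otherwise the product amplifies with length
#' equal to the reference amplicon shifted by the signed net lengths of the
#' Indels between the primers, and `competitionHandicap` counts the
#' surviving primer-site mismatches (in mixed template the allele with the
#' larger handicap is out-competed).
#'
#' @param pair a [PrimerPair-class].
#' @param haplotype an [InbredHaplotype-class] built over the pair's locus.
#' @param maxMismatches tolerated mismatches per primer site.
#' @param exact3p 3'-terminal clamp length (nt).
#' @return an [AmpliconPrediction-class].
#' @export
predictAmplicon <- function(pair, haplotype, maxMismatches = 2L, exact3p = 5L) {
  chrom <- pair@chrom
  fs <- IRanges::start(pair@forwardRange); fe <- IRanges::end(pair@forwardRange)
  rs <- IRanges::start(pair@reverseRange); re <- IRanges::end(pair@reverseRange)
  gr <- trackRecords(haplotype@track)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  inbred <- inbredName(haplotype)
  fail <- function(reason) new("AmpliconPrediction", inbredName = inbred,
                               amplifies = FALSE, productLen = NA_integer_,
                               failureReason = reason,
                               competitionHandicap = 0L)
  if (!length(gr))
    return(new("AmpliconPrediction", inbredName = inbred, amplifies = TRUE,
               productLen = pair@refAmpliconLen, failureReason = "NONE",
               competitionHandicap = 0L))
  eff <- variantEffects(gr)
  relevant <- effectOverlaps(eff, fs, re)
  eff <- eff[relevant, , drop = FALSE]
  if (!nrow(eff))
    return(new("AmpliconPrediction", inbredName = inbred, amplifies = TRUE,
               productLen = pair@refAmpliconLen, failureReason = "NONE",
               competitionHandicap = 0L))
  ## 3' clamps: forward primer's clamp is its rightmost bases, reverse
  ## primer's clamp is the leftmost bases of its top-strand footprint
  clampF <- c(fe - exact3p + 1L, fe)
  clampR <- c(rs, rs + exact3p - 1L)
  if (any(effectOverlaps(eff, clampF[1], clampF[2])) ||
      any(effectOverlaps(eff, clampR[1], clampR[2])))
    return(fail("PRIMER_SITE_VARIANT_3PRIME"))
  onF <- effectOverlaps(eff, fs, fe)
  onR <- effectOverlaps(eff, rs, re)
  if (any(eff$type == "del" & (onF | onR)))
    return(fail("PRIMER_SITE_DELETED"))
  if (sum(onF) > maxMismatches || sum(onR) > maxMismatches)
    return(fail("PRIMER_SITE_DIVERGENCE"))
  interior <- !onF & !onR
  productLen <- pair@refAmpliconLen + sum(eff$net[interior])
  new("AmpliconPrediction", inbredName = inbred, amplifies = TRUE,
      productLen = as.integer(productLen), failureReason = "NONE",
      competitionHandicap = as.integer(sum(onF) + sum(onR)))
}

setMethod("show", "AmpliconPrediction", function(object) {
  if (object@amplifies)
    cat(sprintf("AmpliconPrediction '%s': %d-bp product (handicap %d)\n",
                object@inbredName, object@productLen, object@competitionHandicap))
  else
    cat(sprintf("AmpliconPrediction '%s': no product (%s)\n",
                object@inbredName, object@failureReason))
})

#' Can two product sizes be told apart on the gel?
#'
#' `TRUE` iff `|lenA - lenB| >= max(minAbsDiff, relDiffFrac * mean)`.
#' Symmetric in its arguments and vectorised.
#'
#' @param lenA,lenB product lengths (bp).
#' @param gel a [GelModel-class].
#' @return logical.
#' @examples
#' resolvableOnGel(154, 137)            # TRUE: 17 bp apart on small products
#' resolvableOnGel(300, 293)            # FALSE: 7 bp lost on large products
#' resolvableOnGel(100, 93)             # TRUE: same 7 bp resolves when small
#' @export
resolvableOnGel <- function(lenA, lenB, gel = gelModel()) {
  stopifnot(all(lenA >= 1), all(lenB >= 1))
  abs(lenA - lenB) >= pmax(gel@minAbsDiff, gel@relDiffFrac * (lenA + lenB) / 2)
}

#' Classify a marker for a pair of inbreds
#'
#' Combines the two per-inbred predictions for the same primer pair:
#' `FAILED` when neither amplifies; `PAV` when exactly one does (favoring
#' the amplifying inbred); `DOMINANT` when both amplify but with unequal
#' competition handicaps (the cleaner primer sites win the mixed-template
#' competition); otherwise `CO_DOMINANT` when the sizes resolve on the gel
#' and `NON_POLYMORPHIC` when they do not. A heteroduplex band is expected
#' whenever both alleles amplify with distinct sizes.
#'
#' @param predA,predB [AmpliconPrediction-class] for the two inbreds.
#' @param gel a [GelModel-class].
#' @return a [MarkerClassification-class].
#' @export
classifyMarker <- function(predA, predB, gel = gelModel()) {
  if (!predA@amplifies && !predB@amplifies)
    return(new("MarkerClassification", verdict = "FAILED",
               favoredAllele = NA_character_, resolvable = FALSE,
               heteroduplexExpected = FALSE))
  if (xor(predA@amplifies, predB@amplifies)) {
    winner <- if (predA@amplifies) predA@inbredName else predB@inbredName
    return(new("MarkerClassification", verdict = "PAV",
               favoredAllele = winner, resolvable = FALSE,
               heteroduplexExpected = FALSE))
  }
  distinct <- predA@productLen != predB@productLen
  res <- resolvableOnGel(predA@productLen, predB@productLen, gel)
  if (predA@competitionHandicap != predB@competitionHandicap) {
    winner <- if (predA@competitionHandicap < predB@competitionHandicap)
      predA@inbredName else predB@inbredName
    return(new("MarkerClassification", verdict = "DOMINANT",
               favoredAllele = winner, resolvable = res,
               heteroduplexExpected = distinct))
  }
  new("MarkerClassification",
      verdict = if (res) "CO_DOMINANT" else "NON_POLYMORPHIC",
      favoredAllele = NA_character_, resolvable = res,
      heteroduplexExpected = distinct)
}

setMethod("show", "MarkerClassification", function(object) {
  cat(sprintf("MarkerClassification: %s%s%s\n", object@verdict,
              if (!is.na(object@favoredAllele))
                paste0(" (favored: ", object@favoredAllele, ")") else "",
              if (object@heteroduplexExpected) ", heteroduplex expected" else ""))
})

#' Audit an Indel annotation against observed product sizes
#'
#' Compares the signed size shift implied by an annotated Indel with the
#' product sizes actually observed (or predicted) per inbred:
#' `CONCORDANT` when the non-reference product differs from the reference
#' product in the annotated direction; `WRONG_DIRECTION` when a deletion
#' yields a larger product or an insertion a smaller one; `SAME_SIZE` when
#' the products are equal despite the annotated difference; `NO_PRODUCT`
#' when the non-reference allele failed to amplify.
#'
#' @param annotation single-record [PolymorphismTrack-class] carrying the
#'   annotated Indel (signed shift `nchar(alt) - nchar(ref)`).
#' @param observedSizes named numeric of product sizes in bp (`NA` for no
#'   product); must contain `refInbred`.
#' @param refInbred name of the reference inbred in `observedSizes`.
#' @return named character vector, one verdict per non-reference inbred.
#' @export
validateAnnotation <- function(annotation, observedSizes, refInbred = "B73") {
  stopifnot(is(annotation, "PolymorphismTrack"), length(annotation) == 1L)
  if (!refInbred %in% names(observedSizes))
    stop("observedSizes must contain the reference inbred '", refInbred, "'")
  refSize <- observedSizes[[refInbred]]
  if (is.na(refSize)) stop("reference inbred has no observed product size")
  m <- S4Vectors::mcols(trackRecords(annotation))
  net <- nchar(m$alt) - nchar(m$ref)
  if (net == 0L) stop("annotation is not an Indel (net length 0)")
  others <- setdiff(names(observedSizes), refInbred)
  verdicts <- vapply(others, function(inbred) {
    obs <- observedSizes[[inbred]]
    if (is.na(obs)) return("NO_PRODUCT")
    diff <- obs - refSize
    if (diff == 0) return("SAME_SIZE")
    if (sign(diff) != sign(net)) return("WRONG_DIRECTION")
    "CONCORDANT"
  }, character(1))
  names(verdicts) <- others
  verdicts
}
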