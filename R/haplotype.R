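#' Build an inbred haplotype from a reference genome and a variant track
#'
#' Validates every record against the reference (REF allele match, within
#' chromosome bounds) and rejects tracks whose variant footprints overlap
#' one another: overlapping variants have no unambiguous joint application
#' order and would corrupt size predictions.
#'
#' @param genome `DNAStringSet` reference.
#' @param track [PolymorphismTrack-class] of homozygous variants.
#' @return an [InbredHaplotype-class].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGTACGTACGT"))
#' tr <- polymorphismTrack("chr1", 5, "A", "G", "s1", "Mo17")
#' hap <- buildHaplotype(g, tr)
#' haplotypeSeq(hap, "chr1", 1, 8)  # "ACGTGCGT"
#' @export
buildHaplotype <- function(genome, track) {
  stopifnot(is(genome, "DNAStringSet"), is(track, "PolymorphismTrack"))
  validateTrackAgainstGenome(track, genome)
  gr <- trackRecords(track)
  if (length(gr) > 1L) {
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits)) {
      i <- S4Vectors::queryHits(hits)[1]
      j <- S4Vectors::subjectHits(hits)[1]
      stop(sprintf(
        "overlapping variants in track '%s': %s (%s:%d) clashes with %s (%s:%d)",
        inbredName(track),
        S4Vectors::mcols(gr)$id[i], GenomicRanges::seqnames(gr)[i],
        GenomicRanges::start(gr)[i],
        S4Vectors::mcols(gr)$id[j], GenomicRanges::seqnames(gr)[j],
        GenomicRanges::start(gr)[j]))
    }
  }
  new("InbredHaplotype", genome = genome, track = track)
}

#' @rdname PolymorphismTrack-class
#' @export
setMethod("inbredName", "InbredHaplotype", function(x) inbredName(x@track))

setMethod("show", "InbredHaplotype", function(object) {
  cat(sprintf("InbredHaplotype '%s': %d variant(s) on a %d-chromosome reference\n",
              inbredName(object), length(object@track), length(object@genome)))
})

## Variants of the haplotype's track whose footprints are fully contained
## in [start, end] on chrom; errors on footprints straddling a boundary.
containedVariants <- function(haplotype, chrom, start, end, context = "interval") {
  gr <- trackRecords(haplotype@track)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  if (!length(gr)) return(gr)
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  touches <- e >= start & s <= end
  within <- s >= start & e <= end
  straddle <- touches & !within
  if (any(straddle))
    stop(sprintf(
      "variant(s) straddle the %s boundary %s:%d-%d: %s; widen or shift the interval",
      context, chrom, start, end,
      paste(S4Vectors::mcols(gr)$id[straddle], collapse = ", ")))
  gr[within]
}

#' Haplotype sequence over a reference interval
#'
#' Materialises the inbred's sequence corresponding to the reference
#' interval `chrom:start-end` (1-based, closed) by splicing each contained
#' variant's ALT allele over its reference footprint. A variant footprint
#' partially overlapping an interval boundary is an error rather than a
#' silent truncation.
#'
#' @param haplotype an [InbredHaplotype-class].
#' @param chrom chromosome name.
#' @param start,end reference interval bounds (1-based, closed).
#' @return a character string.
#' @export
setMethod("haplotypeSeq", "InbredHaplotype", function(haplotype, chrom, start, end) {
  checkInterval(haplotype@genome, chrom, start, end)
  refseq <- haplotype@genome[[chrom]]
  vars <- containedVariants(haplotype, chrom, start, end)
  if (!length(vars))
    return(as.character(Biostrings::subseq(refseq, start, end)))
  vs <- GenomicRanges::start(vars); ve <- GenomicRanges::end(vars)
  alts <- S4Vectors::mcols(vars)$alt
  pieces <- character(2L * length(vars) + 1L)
  cur <- start
  for (k in seq_along(vars)) {
    pieces[2L * k - 1L] <- if (vs[k] > cur)
      as.character(Biostrings::subseq(refseq, cur, vs[k] - 1L)) else ""
    pieces[2L * k] <- alts[k]
    cur <- ve[k] + 1L
  }
  pieces[2L * length(vars) + 1L] <- if (cur <= end)
    as.character(Biostrings::subseq(refseq, cur, end)) else ""
  paste(pieces, collapse = "")
})

#' Haplotype size of a reference interval
#'
#' Length in the inbred haplotype of the segment corresponding to the
#' reference interval `chrom:start-end` (1-based, closed): the reference
#' length plus the sum of signed net lengths of contained Indels
#' (insertions add, deletions subtract). Variants straddling an interval
#' boundary are an error.
#'
#' @param haplotype an [InbredHaplotype-class].
#' @param chrom chromosome name.
#' @param start,end reference interval bounds (1-based, closed).
#' @return integer size in bp.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 100), collapse = "")))
#' # 17-bp deletion: REF footprint 50..67, ALT keeps the shared first base
#' tr <- polymorphismTrack("chr1", 50, as.character(
#'   Biostrings::subseq(g[[1]], 50, 67)), as.character(
#'   Biostrings::subseq(g[[1]], 50, 50)), "iv1", "Mo17")
#' hap <- buildHaplotype(g, tr)
#' segmentSize(hap, "chr1", 1, 154)  # 154 - 17 = 137
#' @export
setMethod("segmentSize", "InbredHaplotype", function(haplotype, chrom, start, end) {
  checkInterval(haplotype@genome, chrom, start, end)
  vars <- containedVariants(haplotype, chrom, start, end)
  refLen <- end - start + 1L
  if (!length(vars)) return(as.integer(refLen))
  m <- S4Vectors::mcols(vars)
  as.integer(refLen + sum(nchar(m$alt) - nchar(m$ref)))
})

checkInterval <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  if (start < 1L || end > Biostrings::width(genome)[match(chrom, names(genome))])
    stop(sprintf("interval %s:%d-%d outside chromosome bounds", chrom, start, end))
  if (start > end) stop("interval start must be <= end")
  invisible(TRUE)
}
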