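#' Construct a polymorphism track
#'
#' Builds a [PolymorphismTrack-class] from parallel vectors of variant
#' fields. Records are sorted by (chrom, pos); `netLength` is computed as
#' the absolute allele-length difference. When a reference genome is
#' supplied every `ref` allele is checked against it.
#'
#' @param chrom,pos,ref,alt,id parallel vectors describing the variants
#'   (VCF convention: `pos` is the 1-based position of the first REF base).
#' @param inbredName name of the inbred the track describes.
#' @param genome optional `DNAStringSet`; when given, REF alleles are
#'   validated against it.
#' @return a `PolymorphismTrack`.
#' @examples
#' polymorphismTrack("chr1", 100, "ACGTACGTA", "AC", "iv1", "Mo17")
#' @export
polymorphismTrack <- function(chrom, pos, ref, alt, id = NULL,
                              inbredName = "unknown", genome = NULL) {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (is.null(id)) id <- sprintf("%s_%d", chrom, as.integer(pos))
  stopifnot(length(ref) == n, length(alt) == n, length(id) == n)
  o <- order(chrom, pos)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[o],
    ranges = IRanges::IRanges(start = as.integer(pos)[o],
                              width = nchar(ref)[o]),
    ref = ref[o], alt = alt[o], id = as.character(id)[o],
    netLength = abs(nchar(ref) - nchar(alt))[o])
  track <- new("PolymorphismTrack", records = gr, inbredName = inbredName)
  if (!is.null(genome)) validateTrackAgainstGenome(track, genome)
  track
}

## REF alleles and footprints must agree with the reference sequence.
validateTrackAgainstGenome <- function(track, genome) {
  gr <- track@records
  if (!length(gr)) return(invisible(TRUE))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  bad <- !chroms %in% names(genome)
  if (any(bad))
    stop("track chromosome(s) absent from genome: ",
         paste(unique(chroms[bad]), collapse = ", "))
  ends <- GenomicRanges::end(gr)
  over <- ends > Biostrings::width(genome)[match(chroms, names(genome))]
  if (any(over))
    stop("record(s) beyond chromosome end: ",
         paste(utils::head(S4Vectors::mcols(gr)$id[over], 5L), collapse = ", "))
  obs <- vapply(seq_along(gr), function(i) {
    as.character(Biostrings::subseq(genome[[chroms[i]]],
                                    GenomicRanges::start(gr)[i],
                                    GenomicRanges::end(gr)[i]))
  }, character(1))
  mism <- obs != S4Vectors::mcols(gr)$ref
  if (any(mism))
    stop("REF allele mismatch against genome for record(s): ",
         paste(sprintf("%s (%s:%d %s!=%s)",
                       S4Vectors::mcols(gr)$id[mism],
                       chroms[mism], GenomicRanges::start(gr)[mism],
                       S4Vectors::mcols(gr)$ref[mism], obs[mism])[
                         seq_len(min(5L, sum(mism)))],
               collapse = "; "))
  invisible(TRUE)
}

#' @rdname PolymorphismTrack-class
#' @export
setMethod("inbredName", "PolymorphismTrack", function(x) x@inbredName)

#' @rdname PolymorphismTrack-class
#' @export
setMethod("trackRecords", "PolymorphismTrack", function(x) x@records)

#' @rdname PolymorphismTrack-class
#' @export
setMethod("trackTable", "PolymorphismTrack", function(x) {
  gr <- x@records
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr),
             ref = S4Vectors::mcols(gr)$ref,
             alt = S4Vectors::mcols(gr)$alt,
             id = S4Vectors::mcols(gr)$id,
             netLength = S4Vectors::mcols(gr)$netLength,
             stringsAsFactors = FALSE)
})

#' @rdname PolymorphismTrack-class
#' @export
setMethod("length", "PolymorphismTrack", function(x) length(x@records))

#' @rdname PolymorphismTrack-class
#' @param i index into the track's records.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PolymorphismTrack", function(x, i, j, ..., drop = FALSE) {
  initialize(x, records = x@records[i], inbredName = x@inbredName)
})

setMethod("show", "PolymorphismTrack", function(object) {
  gr <- object@records
  nIndel <- sum(S4Vectors::mcols(gr)$netLength >= 1L)
  cat(sprintf("PolymorphismTrack '%s': %d records (%d SNP, %d Indel) on %d chromosome(s)\n",
              object@inbredName, length(gr), length(gr) - nIndel, nIndel,
              length(unique(as.character(GenomicRanges::seqnames(gr))))))
  if (length(gr)) {
    print(utils::head(trackTable(object), 5L))
    if (length(gr) > 5L) cat("...\n")
  }
})

#' Filter a track down to scorable Indels
#'
#' Keeps only Indel records whose net allele-length difference is at least
#' `minNetLength` (inclusive). SNPs (`netLength == 0`) are always removed;
#' record order is preserved. The default of 7 bp is the smallest length
#' difference reliably scorable as a fragment-length polymorphism on 4%
#' agarose.
#'
#' @param track a [PolymorphismTrack-class].
#' @param minNetLength minimum net length difference (bp, inclusive, >= 1).
#' @return a `PolymorphismTrack` containing the retained Indels.
#' @examples
#' tr <- polymorphismTrack(c("chr1", "chr1"), c(10, 50),
#'                         c("ACGTACGTA", "A"), c("AC", "G"),
#'                         c("iv1", "snp1"), "Mo17")
#' length(filterIndels(tr))  # 1: the SNP is dropped
#' @export
filterIndels <- function(track, minNetLength = 7L) {
  stopifnot(is(track, "PolymorphismTrack"))
  minNetLength <- as.integer(minNetLength)
  if (is.na(minNetLength) || minNetLength < 1L)
    stop("minNetLength must be an integer >= 1")
  keep <- S4Vectors::mcols(track@records)$netLength >= minNetLength
  track[keep]
}

## Concatenate tracks for the same inbred (used by the simulator).
bindTracks <- function(tracks) {
  grl <- lapply(tracks, trackRecords)
  gr <- suppressWarnings(do.call(c, unname(grl)))
  tb <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   pos = GenomicRanges::start(gr))
  polymorphismTrack(tb$chrom, tb$pos,
                    S4Vectors::mcols(gr)$ref, S4Vectors::mcols(gr)$alt,
                    S4Vectors::mcols(gr)$id,
                    inbredName = tracks[[1]]@inbredName)
}
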