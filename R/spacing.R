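#' Inter-polymorphism spacing statistics
#'
#' Gaps are successive position differences between consecutive records
#' within each chromosome; chromosomes with fewer than two records
#' contribute no gaps, and no gap ever spans two chromosomes. The
#' aggregate statistics pool all within-chromosome gaps genome-wide, so a
#' single mean/median inter-marker distance can be quoted for a whole
#' track.
#'
#' @param track a sorted [PolymorphismTrack-class].
#' @return a [SpacingStats-class].
#' @examples
#' tr <- polymorphismTrack(rep("chr1", 3), c(100, 200, 400),
#'                         rep("ACGTACGTA", 3), rep("A", 3),
#'                         paste0("iv", 1:3), "Mo17")
#' spacingStats(tr)@aggregate  # mean gap 150, median 150
#' @export
spacingStats <- function(track) {
  stopifnot(is(track, "PolymorphismTrack"))
  tb <- trackTable(track)
  byChrom <- split(tb$pos, tb$chrom)
  gaps <- lapply(byChrom, function(p) if (length(p) >= 2L) diff(p) else numeric())
  pooled <- unlist(gaps, use.names = FALSE)
  if (!length(pooled))
    stop("no gaps defined: every chromosome has fewer than 2 records")
  withGaps <- names(gaps)[lengths(gaps) > 0L]
  perChrom <- data.frame(
    chrom = withGaps,
    nMarkers = vapply(byChrom[withGaps], length, integer(1)),
    nGaps = lengths(gaps[withGaps]),
    meanGap = vapply(gaps[withGaps], mean, numeric(1)),
    medianGap = vapply(gaps[withGaps], stats::median, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  new("SpacingStats", perChrom = perChrom,
      aggregate = c(nMarkers = nrow(tb), nGaps = length(pooled),
                    meanGap = mean(pooled), medianGap = stats::median(pooled)))
}

setMethod("show", "SpacingStats", function(object) {
  a <- object@aggregate
  cat(sprintf("SpacingStats: %d markers, %d gaps; mean gap %.1f bp, median %.1f bp\n",
              a["nMarkers"], a["nGaps"], a["meanGap"], a["medianGap"]))
})

#' Create or parse a fine-mapping interval
#'
#' Accepts either explicit fields or a samtools-style region string
#' `"chrom:start-end"` (1-based, closed; commas in numbers tolerated).
#'
#' @param chrom chromosome name, or a region string when `start` is
#'   missing.
#' @param start,end interval bounds.
#' @param k number of markers requested (default 5: enough to expect one
#'   to three informative co-dominant markers per round).
#' @return a [MappingInterval-class].
#' @examples
#' mappingInterval("chr1:100000-600000")
#' @export
mappingInterval <- function(chrom, start = NULL, end = NULL, k = 5L) {
  if (is.null(start)) {
    m <- regmatches(chrom, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", chrom))[[1]]
    if (length(m) != 4L)
      stop("cannot parse interval '", chrom, "'; expected chrom:start-end")
    start <- as.numeric(gsub(",", "", m[3]))
    end <- as.numeric(gsub(",", "", m[4]))
    chrom <- m[2]
  }
  new("MappingInterval", chrom = chrom, start = as.numeric(start),
      end = as.numeric(end), k = as.integer(k))
}

setMethod("show", "MappingInterval", function(object) {
  cat(sprintf("MappingInterval %s:%s-%s (k = %d)\n", object@chrom,
              format(object@start, big.mark = ",", scientific = FALSE),
              format(object@end, big.mark = ",", scientific = FALSE),
              object@k))
})

#' Select evenly spaced candidate markers in a mapping interval
#'
#' Places `k` ideal anchor positions at `start + i (end - start) / (k + 1)`
#' for `i = 1..k` (interior anchors only: the interval endpoints are
#' normally already-genotyped flanking markers) and greedily assigns each
#' anchor the nearest in-interval candidate not already chosen, breaking
#' distance ties toward the lower coordinate. When fewer than `k`
#' candidates exist, all are returned.
#'
#' @param track a [PolymorphismTrack-class] of candidate markers.
#' @param interval a [MappingInterval-class].
#' @return a `PolymorphismTrack` of at most `k` selected records, sorted
#'   by position.
#' @export
selectEvenlySpaced <- function(track, interval) {
  stopifnot(is(track, "PolymorphismTrack"), is(interval, "MappingInterval"))
  tb <- trackTable(track)
  inInt <- which(tb$chrom == interval@chrom &
                   tb$pos >= interval@start & tb$pos <= interval@end)
  if (!length(inInt)) {
    warning(sprintf("no candidate markers in %s:%.0f-%.0f",
                    interval@chrom, interval@start, interval@end))
    return(track[integer()])
  }
  k <- interval@k
  if (length(inInt) <= k) return(track[inInt])
  anchors <- interval@start +
    seq_len(k) * (interval@end - interval@start) / (k + 1)
  pos <- tb$pos[inInt]
  chosen <- integer()
  for (a in anchors) {
    avail <- setdiff(seq_along(pos), chosen)
    d <- abs(pos[avail] - a)
    ## ties go to the lower coordinate: order by (distance, position)
    best <- avail[order(d, pos[avail])][1]
    chosen <- c(chosen, best)
  }
  track[sort(inInt[chosen])]
}

#' Refine a mapping interval from recombinant genotypes
#'
#' Each informative marker reports on which side of it the causal locus
#' lies (`"left"` or `"right"`, from the recombinant individuals'
#' genotypes). The smallest sub-interval consistent with all sides runs
#' from the rightmost right-voting marker to the leftmost left-voting
#' marker; those flanking markers become the new interval bounds.
#' Contradictory sides (a left-voting marker at or below a right-voting
#' one) signal a genotyping error upstream and raise an error. Iterating
#' the select/genotype/refine cycle monotonically shrinks the interval.
#'
#' @param interval the current [MappingInterval-class].
#' @param sides named character vector: names are marker positions (bp,
#'   coercible to numeric), values `"left"` or `"right"`.
#' @return the refined `MappingInterval` (same `k`).
#' @examples
#' iv <- mappingInterval("chr1", 0, 400000)
#' refineInterval(iv, c(`100000` = "right", `200000` = "right",
#'                      `300000` = "left"))  # chr1:200000-300000
#' @export
refineInterval <- function(interval, sides) {
  stopifnot(is(interval, "MappingInterval"))
  if (!length(sides)) return(interval)
  if (!all(sides %in% c("left", "right")))
    stop("sides must be 'left' or 'right'")
  pos <- as.numeric(names(sides))
  if (any(is.na(pos))) stop("side names must be marker positions")
  newStart <- max(c(interval@start, pos[sides == "right"]))
  newEnd <- min(c(interval@end, pos[sides == "left"]))
  if (newStart >= newEnd)
    stop(sprintf(
      "contradictory marker sides: locus right of %.0f but left of %.0f; check genotyping",
      newStart, newEnd))
  new("MappingInterval", chrom = interval@chrom, start = newStart,
      end = newEnd, k = interval@k)
}
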