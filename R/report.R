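## Commercial rounding: exact halves go up, matching how marker-summary
## percentages are conventionally printed (49.03 -> 49, 21.9 -> 22).
roundHalfUp <- function(x) floor(x + 0.5)

#' Summarize marker classifications per inbred pair
#'
#' Tallies verdicts into the standard marker-panel summary: one row per
#' inbred pair with counts of co-dominant, PAV, dominant and
#' non-polymorphic markers and the derived integer percentages
#' (`pctCoDominant`, `pctPav`, `pctDominant`, `pctNonPolymorphic`, plus
#' `pctPolymorphic` = 100 (nTested - nonPolymorphic) / nTested and
#' `pctSingleAllele` = 100 (pav + dominant) / nTested, all rounded
#' half-up). Markers classified `FAILED` (no product from either inbred)
#' are excluded from `nTested` and reported in `nFailed`.
#'
#' @param pair character vector of inbred-pair labels (e.g. `"B73/Mo17"`),
#'   parallel to `classifications`.
#' @param classifications list of [MarkerClassification-class] (or a
#'   character vector of verdicts).
#' @return data.frame, one row per pair.
#' @examples
#' v <- rep(c("CO_DOMINANT", "PAV", "DOMINANT", "NON_POLYMORPHIC"),
#'          c(127, 80, 44, 8))
#' summarizeClassifications(rep("B73/Mo17", length(v)), v)
#' @export
summarizeClassifications <- function(pair, classifications) {
  verdicts <- if (is.character(classifications)) classifications
  else vapply(classifications, function(x) x@verdict, character(1))
  if (!all(verdicts %in% VERDICT_LEVELS))
    stop("unknown verdict(s): ",
         paste(setdiff(unique(verdicts), VERDICT_LEVELS), collapse = ", "))
  stopifnot(length(pair) == length(verdicts))
  if (!length(verdicts)) stop("no classifications to summarize")
  out <- do.call(rbind, lapply(split(verdicts, pair), function(v) {
    n <- sum(v != "FAILED")
    if (n == 0L)
      stop("no successfully tested markers for a pair (all FAILED)")
    counts <- c(coDominant = sum(v == "CO_DOMINANT"),
                pav = sum(v == "PAV"),
                dominant = sum(v == "DOMINANT"),
                nonPolymorphic = sum(v == "NON_POLYMORPHIC"))
    data.frame(nTested = n, t(counts), nFailed = sum(v == "FAILED"),
               pctCoDominant = roundHalfUp(100 * counts[["coDominant"]] / n),
               pctPav = roundHalfUp(100 * counts[["pav"]] / n),
               pctDominant = roundHalfUp(100 * counts[["dominant"]] / n),
               pctNonPolymorphic = roundHalfUp(100 * counts[["nonPolymorphic"]] / n),
               pctPolymorphic = roundHalfUp(100 * (n - counts[["nonPolymorphic"]]) / n),
               pctSingleAllele = roundHalfUp(
                 100 * (counts[["pav"]] + counts[["dominant"]]) / n))
  }))
  out <- cbind(pair = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Classify a set of markers across inbred pairs
#'
#' End-to-end convenience wrapper: for each primer pair and each requested
#' inbred pair, predicts both amplicons ([predictAmplicon()]) and
#' classifies the marker ([classifyMarker()]).
#'
#' @param genome `DNAStringSet` reference.
#' @param pairs list of [PrimerPair-class].
#' @param tracks named list of [PolymorphismTrack-class], one per inbred
#'   (an empty track represents the reference inbred itself).
#' @param inbredPairs character vector like `"B73/Mo17"`; defaults to all
#'   unordered pairs of `names(tracks)`.
#' @param gel a [GelModel-class].
#' @param maxMismatches,exact3p see [predictAmplicon()].
#' @return data.frame, one row per (marker, inbred pair): verdict, product
#'   sizes, failure reasons, heteroduplex flag.
#' @export
classifyMarkers <- function(genome, pairs, tracks, inbredPairs = NULL,
                            gel = gelModel(), maxMismatches = 2L,
                            exact3p = 5L) {
  if (is.null(inbredPairs)) {
    nm <- names(tracks)
    inbredPairs <- apply(utils::combn(nm, 2L), 2L, paste, collapse = "/")
  }
  haps <- lapply(tracks, function(tr) buildHaplotype(genome, tr))
  rows <- list()
  for (p in pairs) {
    preds <- lapply(haps, function(h)
      predictAmplicon(p, h, maxMismatches, exact3p))
    for (ip in inbredPairs) {
      ab <- strsplit(ip, "/", fixed = TRUE)[[1]]
      if (length(ab) != 2L || !all(ab %in% names(tracks)))
        stop("unknown inbred pair: ", ip)
      cls <- classifyMarker(preds[[ab[1]]], preds[[ab[2]]], gel)
      rows[[length(rows) + 1L]] <- data.frame(
        targetId = p@targetId, inbredPair = ip,
        verdict = cls@verdict, favoredAllele = cls@favoredAllele,
        sizeA = preds[[ab[1]]]@productLen, sizeB = preds[[ab[2]]]@productLen,
        failureA = preds[[ab[1]]]@failureReason,
        failureB = preds[[ab[2]]]@failureReason,
        heteroduplexExpected = cls@heteroduplexExpected,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a classification or summary table as TSV
#'
#' Prepends `#` provenance lines (tool version plus any caller-supplied
#' parameter echo) so reports are self-describing.
#'
#' @param tab data.frame.
#' @param path output file.
#' @param header extra provenance lines (prefixed with `#`).
#' @return `path`, invisibly.
#' @export
writeReport <- function(tab, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# IndelMarkers %s", utils::packageVersion("IndelMarkers")),
               paste0("# ", header),
               paste0("# ", paste(names(tab), collapse = "\t"))), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
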