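#' Create a primer design configuration
#'
#' Defaults target short reference amplicons (80-300 bp) scorable on 4%
#' agarose, 18-27 nt primers, Tm 55-63 degrees C with at most 3 degrees
#' between the pair, 30-70% GC and no homopolymer longer than 5 nt. The
#' 3'-terminal `clamp3p` bases of every primer are kept polymorphism-free
#' unconditionally; with `avoidLinked = TRUE` (default) the whole primer
#' footprint must avoid linked variants, so known SNP/short-Indel
#' divergence cannot silently kill the non-reference allele.
#'
#' @param ampliconMin,ampliconMax reference amplicon bounds (bp).
#' @param primerLenMin,primerLenMax primer length bounds (nt).
#' @param tmMin,tmMax primer Tm range (degrees C).
#' @param tmPairMaxDiff max Tm difference within a pair (degrees C).
#' @param gcMin,gcMax GC bounds (%).
#' @param maxHomopolymer longest tolerated single-base run (nt).
#' @param avoidLinked keep primer footprints clear of linked variants?
#' @param clamp3p 3'-terminal bases required variant-free (nt).
#' @param saltMolar,primerNanomolar Tm thermodynamic constants (see
#'   [meltingTemperature()]).
#' @param wTm,wTmDiff,wGc,wHomopolymer,wDimer ranking penalty weights.
#' @return a [DesignConfig-class].
#' @export
designConfig <- function(ampliconMin = 80L, ampliconMax = 300L,
                         primerLenMin = 18L, primerLenMax = 27L,
                         tmMin = 55, tmMax = 63, tmPairMaxDiff = 3,
                         gcMin = 30, gcMax = 70, maxHomopolymer = 5L,
                         avoidLinked = TRUE, clamp3p = 5L,
                         saltMolar = 0.05, primerNanomolar = 25,
                         wTm = 1, wTmDiff = 1, wGc = 0.05,
                         wHomopolymer = 0.2, wDimer = 0.5) {
  new("DesignConfig",
      ampliconMin = as.integer(ampliconMin), ampliconMax = as.integer(ampliconMax),
      primerLenMin = as.integer(primerLenMin), primerLenMax = as.integer(primerLenMax),
      tmMin = tmMin, tmMax = tmMax, tmPairMaxDiff = tmPairMaxDiff,
      gcMin = gcMin, gcMax = gcMax, maxHomopolymer = as.integer(maxHomopolymer),
      avoidLinked = avoidLinked, clamp3p = as.integer(clamp3p),
      saltMolar = saltMolar, primerNanomolar = primerNanomolar,
      wTm = wTm, wTmDiff = wTmDiff, wGc = wGc,
      wHomopolymer = wHomopolymer, wDimer = wDimer)
}

#' Construct a primer pair explicitly
#'
#' Builds a [PrimerPair-class] from reference footprints, deriving primer
#' sequences, Tm and GC from the genome. Mostly used by fixtures and IO;
#' [designPrimers()] is the normal entry point.
#'
#' @param genome `DNAStringSet` reference.
#' @param chrom chromosome name.
#' @param forwardStart,forwardEnd,reverseStart,reverseEnd primer footprints
#'   (1-based closed, on the reference top strand).
#' @param targetId id of the targeted variant.
#' @param cfg [DesignConfig-class] supplying thermodynamic constants.
#' @return a `PrimerPair`.
#' @export
primerPair <- function(genome, chrom, forwardStart, forwardEnd,
                       reverseStart, reverseEnd, targetId = "",
                       cfg = designConfig()) {
  checkInterval(genome, chrom, forwardStart, reverseEnd)
  fwd <- as.character(Biostrings::subseq(genome[[chrom]], forwardStart, forwardEnd))
  revTop <- as.character(Biostrings::subseq(genome[[chrom]], reverseStart, reverseEnd))
  rev <- revcomp(revTop)
  new("PrimerPair", targetId = targetId, chrom = chrom,
      forwardSeq = fwd, reverseSeq = rev,
      forwardRange = IRanges::IRanges(forwardStart, forwardEnd),
      reverseRange = IRanges::IRanges(reverseStart, reverseEnd),
      tmF = meltingTemperature(fwd, cfg@saltMolar, cfg@primerNanomolar),
      tmR = meltingTemperature(rev, cfg@saltMolar, cfg@primerNanomolar),
      gcF = gcContent(fwd), gcR = gcContent(rev),
      refAmpliconLen = as.integer(reverseEnd - forwardStart + 1L))
}

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair '%s' (%s): %d-bp reference amplicon\n",
              object@targetId, object@chrom, object@refAmpliconLen))
  cat(sprintf("  F %s:%d-%d %s (Tm %.1f, GC %.0f%%)\n", object@chrom,
              IRanges::start(object@forwardRange), IRanges::end(object@forwardRange),
              object@forwardSeq, object@tmF, object@gcF))
  cat(sprintf("  R %s:%d-%d %s (Tm %.1f, GC %.0f%%)\n", object@chrom,
              IRanges::start(object@reverseRange), IRanges::end(object@reverseRange),
              object@reverseSeq, object@tmR, object@gcR))
})

#' Rank penalty for a primer pair
#'
#' Deterministic weighted sum (lower is better): deviation of each Tm from
#' the Tm-range midpoint, the within-pair Tm difference, deviation of each
#' GC from the GC-range midpoint, the longest homopolymer run in each
#' primer, and the longest 3'-terminal cross-complementary run between the
#' two primers (primer-dimer heuristic). Weights live in the
#' [DesignConfig-class]. A pair sitting exactly at both range midpoints
#' contributes zero from the Tm and GC terms.
#'
#' @param pair a [PrimerPair-class].
#' @param cfg a [DesignConfig-class].
#' @return single numeric penalty.
#' @export
scorePair <- function(pair, cfg = designConfig()) {
  tmMid <- (cfg@tmMin + cfg@tmMax) / 2
  gcMid <- (cfg@gcMin + cfg@gcMax) / 2
  cfg@wTm * (abs(pair@tmF - tmMid) + abs(pair@tmR - tmMid)) +
    cfg@wTmDiff * abs(pair@tmF - pair@tmR) +
    cfg@wGc * (abs(pair@gcF - gcMid) + abs(pair@gcR - gcMid)) +
    cfg@wHomopolymer * (maxHomopolymerRun(pair@forwardSeq) +
                          maxHomopolymerRun(pair@reverseSeq)) +
    cfg@wDimer * cross3pRun(pair@forwardSeq, pair@reverseSeq)
}

## Candidate primers on one side of the target footprint, as a data.frame
## with hard per-primer constraints already applied. `side` is "fwd" or
## "rev"; coordinates are reference top-strand footprints. GC and the
## nearest-neighbor stack sums are taken from cumulative sums over the
## search region, so the cost is linear in the region, not in
## candidates x primer length; the model's strand symmetry (a duplex and
## its reverse complement share dH/dS) lets reverse candidates be screened
## on the top strand. Tm screening uses the no-symmetry-correction value
## with a 2 degree guard band, then survivors are re-checked exactly with
## meltingTemperature().
candidatePrimers <- function(chromStr, lo, hi, side, cfg, linkedGr) {
  if (hi < lo || hi - lo + 1L < cfg@primerLenMin) return(NULL)
  region <- substring(chromStr, lo, hi)
  L <- nchar(region)
  bases <- strsplit(region, "")[[1]]
  gcCum <- c(0L, cumsum(bases %in% c("G", "C")))
  dn <- paste0(bases[-L], bases[-1L])
  dhCum <- c(0, cumsum(NN_DH[dn]))
  dsCum <- c(0, cumsum(NN_DS[dn]))
  isAT <- bases %in% c("A", "T")
  grid <- expand.grid(s = seq_len(L - cfg@primerLenMin + 1L),
                      len = seq.int(cfg@primerLenMin, cfg@primerLenMax))
  grid$e <- grid$s + grid$len - 1L
  grid <- grid[grid$e <= L, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  gc <- 100 * (gcCum[grid$e + 1L] - gcCum[grid$s]) / grid$len
  ok <- gc >= cfg@gcMin & gc <= cfg@gcMax
  ## homopolymer: a candidate is bad iff it covers >= maxHomopolymer + 1
  ## bases of some maximal single-base run in the region
  runs <- rle(bases)
  runEnd <- cumsum(runs$lengths)
  runStart <- runEnd - runs$lengths + 1L
  for (r in which(runs$lengths > cfg@maxHomopolymer))
    ok <- ok & !(pmax(grid$s, runStart[r]) + cfg@maxHomopolymer <=
                   pmin(grid$e, runEnd[r]))
  ## clamp: 3'-terminal bases on the reference footprint
  clampStart <- if (side == "fwd") grid$e - cfg@clamp3p + 1L else grid$s
  clampEnd <- if (side == "fwd") grid$e else grid$s + cfg@clamp3p - 1L
  if (length(linkedGr)) {
    linked <- IRanges::shift(IRanges::ranges(linkedGr), 1L - lo)
    win <- if (cfg@avoidLinked) IRanges::IRanges(grid$s, grid$e)
    else IRanges::IRanges(clampStart, clampEnd)
    ok <- ok & !IRanges::overlapsAny(win, linked)
  }
  grid <- grid[ok, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  ## screening Tm from cumulative stacks (ignores the rare symmetry case)
  terminalAT <- isAT[grid$s] + isAT[grid$e]
  dh <- dhCum[grid$e] - dhCum[grid$s] + terminalAT * INIT_AT[["dh"]] +
    (2L - terminalAT) * INIT_GC[["dh"]]
  ds <- dsCum[grid$e] - dsCum[grid$s] + terminalAT * INIT_AT[["ds"]] +
    (2L - terminalAT) * INIT_GC[["ds"]] +
    0.368 * (grid$len - 1L) * log(cfg@saltMolar)
  tm0 <- 1000 * dh /
    (ds + GAS_CONSTANT * log(cfg@primerNanomolar * 1e-9 / 2)) - 273.15
  ## tm0 is exact except for self-complementary candidates (symmetry and
  ## concentration corrections shift those by well under 0.1 degree)
  near <- tm0 >= cfg@tmMin - 0.1 & tm0 <= cfg@tmMax + 0.1
  grid <- grid[near, , drop = FALSE]
  tm <- tm0[near]
  if (!nrow(grid)) return(NULL)
  top <- substring(region, grid$s, grid$e)
  rcTop <- revcomp(top)
  seqs <- if (side == "fwd") top else rcTop
  selfcomp <- top == rcTop
  if (any(selfcomp))
    tm[selfcomp] <- meltingTemperature(seqs[selfcomp], cfg@saltMolar,
                                       cfg@primerNanomolar)
  keep <- tm >= cfg@tmMin & tm <= cfg@tmMax
  if (!any(keep)) return(NULL)
  ## longest single-base run per kept candidate, from the region's runs
  maxRun <- rep(1L, sum(keep))
  ks <- grid$s[keep]; ke <- grid$e[keep]
  for (r in which(runs$lengths >= 2L)) {
    ov <- pmin(ke, runEnd[r]) - pmax(ks, runStart[r]) + 1L
    maxRun <- pmax(maxRun, ov)
  }
  out <- data.frame(start = lo + ks - 1L, end = lo + ke - 1L,
                    seq = seqs[keep], top = top[keep], tm = tm[keep],
                    gc = 100 * (gcCum[grid$e + 1L] - gcCum[grid$s])[keep] / grid$len[keep],
                    homo = maxRun, stringsAsFactors = FALSE)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Design ranked primer pairs flanking a target Indel
#'
#' Enumerates all primer placements strictly flanking the target variant's
#' reference footprint whose reference amplicon lies within the configured
#' bounds, applies the hard constraints in `cfg` (length, Tm, GC,
#' homopolymer, pair Tm difference, linked-polymorphism avoidance) and
#' returns the surviving pairs ranked by [scorePair()] penalty, breaking
#' ties by smaller reference amplicon and then leftmost forward primer
#' (smaller products resolve small Indels better on agarose). The design is
#' fully deterministic; an empty list means no legal design exists under
#' `cfg`.
#'
#' @param genome `DNAStringSet` reference.
#' @param target a single-record [PolymorphismTrack-class] (the Indel to
#'   span), e.g. `filterIndels(track)[i]`.
#' @param linkedTrack optional [PolymorphismTrack-class] of linked
#'   polymorphisms the primers should avoid (usually the full unfiltered
#'   track of the non-reference inbred).
#' @param cfg a [DesignConfig-class].
#' @param maxPairs return at most this many top-ranked pairs.
#' @return list of [PrimerPair-class], best first (possibly empty).
#' @export
designPrimers <- function(genome, target, linkedTrack = NULL,
                          cfg = designConfig(), maxPairs = 10L) {
  stopifnot(is(target, "PolymorphismTrack"))
  if (length(target) != 1L)
    stop("target must contain exactly one record; got ", length(target))
  validateTrackAgainstGenome(target, genome)
  gr <- trackRecords(target)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  fs <- GenomicRanges::start(gr); fe <- GenomicRanges::end(gr)
  targetId <- S4Vectors::mcols(gr)$id
  chromSeq <- genome[[chrom]]
  chromLen <- length(chromSeq)
  ## amplicon spans fwdStart..revEnd and must contain the footprint strictly
  loF <- max(1L, fe - cfg@ampliconMax + 1L)
  hiF <- fs - 1L
  loR <- fe + 1L
  hiR <- min(chromLen, fs + cfg@ampliconMax - 1L)
  linkedGr <- if (is.null(linkedTrack)) GenomicRanges::GRanges() else {
    lg <- trackRecords(linkedTrack)
    lg[as.character(GenomicRanges::seqnames(lg)) == chrom]
  }
  chromStr <- as.character(chromSeq)
  fwd <- candidatePrimers(chromStr, loF, hiF, "fwd", cfg, linkedGr)
  rev <- candidatePrimers(chromStr, loR, hiR, "rev", cfg, linkedGr)
  if (is.null(fwd) || is.null(rev)) {
    message("no legal primer design for target ", targetId,
            " (no candidate ", if (is.null(fwd)) "forward" else "reverse",
            " primer satisfies the constraints)")
    return(list())
  }
  ## Rank pairs without touching the full forward x reverse cross product.
  ## The pair penalty decomposes as fwdPart + revPart + interaction
  ## (Tm-difference and 3'-dimer terms, both >= 0), so fwdPart + revPart
  ## lower-bounds the penalty: scanning forward candidates in fwdPart
  ## order, any pair whose bound exceeds the running maxPairs-th best full
  ## penalty can be skipped exactly.
  tmMid <- (cfg@tmMin + cfg@tmMax) / 2
  gcMid <- (cfg@gcMin + cfg@gcMax) / 2
  fwdPart <- cfg@wTm * abs(fwd$tm - tmMid) + cfg@wGc * abs(fwd$gc - gcMid) +
    cfg@wHomopolymer * fwd$homo
  revPart <- cfg@wTm * abs(rev$tm - tmMid) + cfg@wGc * abs(rev$gc - gcMid) +
    cfg@wHomopolymer * rev$homo
  ## 3'-dimer runs via integer 8-mer codes (revcomp(reverse primer) is its
  ## top-strand footprint, already in hand)
  fCode <- encode8(substring(fwd$seq, nchar(fwd$seq) - 7L, nchar(fwd$seq)))
  rCode <- encode8(substring(rev$top, 1L, 8L))
  minRevPart <- min(revPart)
  tau <- Inf
  acc <- list()
  nAcc <- 0L
  pens <- numeric()
  for (f in order(fwdPart, fwd$start, fwd$end)) {
    if (nAcc >= maxPairs && fwdPart[f] + minRevPart > tau) break
    rIdx <- which(rev$end >= fwd$start[f] + cfg@ampliconMin - 1L &
                    rev$end <= fwd$start[f] + cfg@ampliconMax - 1L)
    if (!length(rIdx)) next
    rIdx <- rIdx[abs(fwd$tm[f] - rev$tm[rIdx]) <= cfg@tmPairMaxDiff]
    if (nAcc >= maxPairs)
      rIdx <- rIdx[fwdPart[f] + revPart[rIdx] <= tau]
    if (!length(rIdx)) next
    pen <- fwdPart[f] + revPart[rIdx] +
      cfg@wTmDiff * abs(fwd$tm[f] - rev$tm[rIdx]) +
      cfg@wDimer * dimerRunFromCodes(rep(fCode[f], length(rIdx)), rCode[rIdx])
    acc[[length(acc) + 1L]] <- data.frame(fi = f, ri = rIdx, penalty = pen)
    nAcc <- nAcc + length(rIdx)
    pens <- c(pens, pen)
    if (is.finite(maxPairs) && nAcc >= maxPairs) {
      pens <- sort(pens)[seq_len(min(length(pens), maxPairs))]
      tau <- pens[min(length(pens), maxPairs)]
    }
  }
  if (!length(acc)) {
    message("no legal primer design for target ", targetId,
            " (no compatible forward/reverse combination)")
    return(list())
  }
  pairsTab <- do.call(rbind, acc)
  fi <- pairsTab$fi; ri <- pairsTab$ri
  ampLen <- rev$end[ri] - fwd$start[fi] + 1L
  o <- order(pairsTab$penalty, ampLen, fwd$start[fi], rev$end[ri])
  if (is.finite(maxPairs)) o <- utils::head(o, maxPairs)
  lapply(o, function(i) {
    new("PrimerPair", targetId = targetId, chrom = chrom,
        forwardSeq = fwd$seq[fi[i]], reverseSeq = rev$seq[ri[i]],
        forwardRange = IRanges::IRanges(fwd$start[fi[i]], fwd$end[fi[i]]),
        reverseRange = IRanges::IRanges(rev$start[ri[i]], rev$end[ri[i]]),
        tmF = fwd$tm[fi[i]], tmR = rev$tm[ri[i]],
        gcF = fwd$gc[fi[i]], gcR = rev$gc[ri[i]],
        refAmpliconLen = as.integer(ampLen[i]))
  })
}

#' Tabulate primer pairs
#'
#' @param pairs list of [PrimerPair-class].
#' @return data.frame, one row per pair.
#' @export
primerTable <- function(pairs) {
  if (is(pairs, "PrimerPair")) pairs <- list(pairs)
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(targetId = p@targetId, chrom = p@chrom,
               forwardSeq = p@forwardSeq, reverseSeq = p@reverseSeq,
               forwardStart = IRanges::start(p@forwardRange),
               forwardEnd = IRanges::end(p@forwardRange),
               reverseStart = IRanges::start(p@reverseRange),
               reverseEnd = IRanges::end(p@reverseRange),
               tmF = p@tmF, tmR = p@tmR, gcF = p@gcF, gcR = p@gcR,
               refAmpliconLen = p@refAmpliconLen,
               stringsAsFactors = FALSE)
  }))
}

#' Write and read primer-pair tables
#'
#' TSV with a provenance `#` header; columns as in [primerTable()].
#'
#' @param pairs list of [PrimerPair-class].
#' @param path TSV file.
#' @param header extra `#`-prefixed provenance lines to prepend.
#' @return `path` (write) / list of `PrimerPair` (read).
#' @export
writePrimerPairs <- function(pairs, path, header = character()) {
  tab <- primerTable(pairs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# IndelMarkers %s primer pairs",
                       utils::packageVersion("IndelMarkers")),
               paste0("# ", header),
               paste0("# ", paste(names(tab), collapse = "\t"))), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePrimerPairs
#' @export
readPrimerPairs <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("targetId", "chrom", "forwardSeq",
                                         "reverseSeq", "forwardStart",
                                         "forwardEnd", "reverseStart",
                                         "reverseEnd", "tmF", "tmR",
                                         "gcF", "gcR", "refAmpliconLen"))
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    new("PrimerPair", targetId = r$targetId, chrom = r$chrom,
        forwardSeq = r$forwardSeq, reverseSeq = r$reverseSeq,
        forwardRange = IRanges::IRanges(r$forwardStart, r$forwardEnd),
        reverseRange = IRanges::IRanges(r$reverseStart, r$reverseEnd),
        tmF = r$tmF, tmR = r$tmR, gcF = r$gcF, gcR = r$gcR,
        refAmpliconLen = as.integer(r$refAmpliconLen))
  })
}
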