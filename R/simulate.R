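BASES <- c("A", "C", "G", "T")

## Run code under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, fun) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fun()
}

#' Default net-length distribution for simulated Indels
#'
#' Geometric decay over 1-50 bp (ratio 0.85), mirroring the strong skew of
#' real Indel catalogs toward short events while leaving enough mass above
#' 7 bp for marker design to have material to work with.
#'
#' @return numeric vector of 50 probabilities summing to 1.
#' @export
defaultIndelLengthProbs <- function() {
  w <- 0.85^(0:49)
  w / sum(w)
}

#' Create a simulation configuration
#'
#' Defaults emulate the statistical structure of a dense inbred-vs-inbred
#' polymorphism track at toy scale: a multi-chromosome genome with per-base
#' SNP and Indel rates of the order seen between diverged inbreds (about 2
#' variants per kb in total) and short-skewed Indel lengths. `seed` has no
#' default: every simulation must state one.
#'
#' @param nChroms number of chromosomes.
#' @param chromLength chromosome length (bp).
#' @param inbredNames non-reference inbreds to generate tracks for.
#' @param snpRate per-base SNP probability.
#' @param indelRate per-base Indel probability.
#' @param indelLengthProbs probability weights over net lengths 1-50 bp.
#' @param duplicationFraction fraction of the genome copied verbatim to a
#'   second location (makes primer pairs designed there non-specific).
#' @param dupSegmentLength length of each duplicated segment (bp).
#' @param seed mandatory RNG seed.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nChroms = 2L, chromLength = 100000L,
                      inbredNames = c("inbredA", "inbredB"),
                      snpRate = 0.0015, indelRate = 5e-4,
                      indelLengthProbs = defaultIndelLengthProbs(),
                      duplicationFraction = 0, dupSegmentLength = 2000L,
                      seed) {
  if (missing(seed)) stop("simConfig requires an explicit seed")
  new("SimConfig", nChroms = as.integer(nChroms),
      chromLength = as.integer(chromLength), inbredNames = inbredNames,
      snpRate = snpRate, indelRate = indelRate,
      indelLengthProbs = indelLengthProbs,
      duplicationFraction = duplicationFraction,
      dupSegmentLength = as.integer(dupSegmentLength),
      seed = as.integer(seed))
}

randomBases <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

## Variants for one inbred on one chromosome string; greedy left-to-right
## placement keeps footprints non-overlapping.
placeVariants <- function(chromStr, chromName, inbred, cfg) {
  len <- nchar(chromStr)
  nSnp <- rbinom(1L, len, cfg@snpRate)
  nInd <- rbinom(1L, len, cfg@indelRate)
  cand <- data.frame(pos = integer(), type = character(), L = integer())
  if (nSnp > 0L)
    cand <- rbind(cand, data.frame(pos = sample.int(len, nSnp),
                                   type = "snp", L = 0L))
  if (nInd > 0L) {
    L <- sample.int(50L, nInd, replace = TRUE, prob = cfg@indelLengthProbs)
    cand <- rbind(cand, data.frame(
      pos = sample.int(len, nInd), L = L,
      type = ifelse(runif(nInd) < 0.5, "ins", "del")))
  }
  if (!nrow(cand)) return(NULL)
  ## deletions need their footprint inside the chromosome
  cand <- cand[!(cand$type == "del" & cand$pos + cand$L > len), , drop = FALSE]
  cand <- cand[order(cand$pos), , drop = FALSE]
  footEnd <- ifelse(cand$type == "del", cand$pos + cand$L, cand$pos)
  keep <- logical(nrow(cand))
  lastEnd <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$pos[i] > lastEnd) {
      keep[i] <- TRUE
      lastEnd <- footEnd[i]
    }
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  n <- nrow(cand)
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    p <- cand$pos[i]
    anchor <- substring(chromStr, p, p)
    if (cand$type[i] == "snp") {
      ref[i] <- anchor
      alt[i] <- sample(setdiff(BASES, anchor), 1L)
    } else if (cand$type[i] == "ins") {
      ref[i] <- anchor
      alt[i] <- paste0(anchor, randomBases(cand$L[i]))
    } else {
      ref[i] <- substring(chromStr, p, p + cand$L[i])
      alt[i] <- anchor
    }
  }
  data.frame(inbred = inbred, chrom = chromName, pos = cand$pos,
             ref = ref, alt = alt,
             id = sprintf("sim_%s_%s_%06d", inbred, chromName, cand$pos),
             type = cand$type, signedNet = nchar(alt) - nchar(ref),
             stringsAsFactors = FALSE)
}

#' Simulate a toy genome with per-inbred variant tracks and ground truth
#'
#' Generates an i.i.d. random reference genome, optionally copies segments
#' verbatim elsewhere (so primer specificity has something to reject), and
#' plants non-overlapping SNPs and Indels independently for each inbred.
#' The manifest records every planted variant with its signed net length,
#' so downstream recovery can be checked exactly. Output is byte-identical
#' for identical configurations (seed included); the caller's RNG state is
#' left untouched.
#'
#' @param cfg a [SimConfig-class].
#' @return list with elements `genome` (`DNAStringSet`), `tracks` (named
#'   list of [PolymorphismTrack-class]), `manifest` (data.frame of planted
#'   variants), `duplications` (data.frame of copied segments) and `config`.
#' @examples
#' sim <- simulateGenome(simConfig(nChroms = 1, chromLength = 5000, seed = 1))
#' nrow(sim$manifest)
#' @export
simulateGenome <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  meanL <- sum(seq_len(50L) * cfg@indelLengthProbs / sum(cfg@indelLengthProbs))
  if (cfg@snpRate + cfg@indelRate * (meanL + 1) > 0.2)
    stop("variant rates imply overlap saturation; lower snpRate/indelRate")
  withSeed(cfg@seed, function() {
    chromNames <- paste0("chr", seq_len(cfg@nChroms))
    seqs <- vapply(chromNames, function(x) randomBases(cfg@chromLength),
                   character(1))
    ## verbatim duplications to exercise specificity rejection
    dup <- data.frame(srcChrom = character(), srcStart = integer(),
                      tgtChrom = character(), tgtStart = integer(),
                      length = integer(), stringsAsFactors = FALSE)
    if (cfg@duplicationFraction > 0) {
      segLen <- min(cfg@dupSegmentLength, cfg@chromLength %/% 4L)
      nSegs <- max(1L, floor(cfg@duplicationFraction * cfg@nChroms *
                               cfg@chromLength / segLen))
      used <- GenomicRanges::GRanges()
      for (i in seq_len(nSegs)) {
        srcChrom <- sample(chromNames, 1L)
        srcStart <- sample.int(cfg@chromLength - segLen + 1L, 1L)
        tgtChrom <- sample(chromNames, 1L)
        tgtStart <- sample.int(cfg@chromLength - segLen + 1L, 1L)
        cand <- GenomicRanges::GRanges(
          c(srcChrom, tgtChrom),
          IRanges::IRanges(c(srcStart, tgtStart), width = segLen))
        ## segments must not touch each other or earlier copies, or a
        ## later overwrite would silently corrupt an earlier duplication
        if (length(GenomicRanges::findOverlaps(cand, drop.self = TRUE)) ||
            length(GenomicRanges::findOverlaps(cand, used))) next
        used <- c(used, cand)
        segment <- substring(seqs[[srcChrom]], srcStart, srcStart + segLen - 1L)
        substring(seqs[[tgtChrom]], tgtStart, tgtStart + segLen - 1L) <- segment
        dup <- rbind(dup, data.frame(srcChrom = srcChrom, srcStart = srcStart,
                                     tgtChrom = tgtChrom, tgtStart = tgtStart,
                                     length = segLen, stringsAsFactors = FALSE))
      }
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chromNames
    manifest <- do.call(rbind, unlist(lapply(cfg@inbredNames, function(inbred) {
      lapply(chromNames, function(chrom)
        placeVariants(seqs[[chrom]], chrom, inbred, cfg))
    }), recursive = FALSE))
    if (is.null(manifest))
      manifest <- data.frame(inbred = character(), chrom = character(),
                             pos = integer(), ref = character(),
                             alt = character(), id = character(),
                             type = character(), signedNet = integer(),
                             stringsAsFactors = FALSE)
    tracks <- lapply(cfg@inbredNames, function(inbred) {
      m <- manifest[manifest$inbred == inbred, , drop = FALSE]
      polymorphismTrack(m$chrom, m$pos, m$ref, m$alt, m$id,
                        inbredName = inbred, genome = genome)
    })
    names(tracks) <- cfg@inbredNames
    list(genome = genome, tracks = tracks, manifest = manifest,
         duplications = dup, config = cfg)
  })
}

#' Write a simulation to standard formats
#'
#' Emits `genome.fa`, one `<inbred>.vcf` per track and `manifest.tsv`
#' under `dir`, so simulated fixtures double as format-IO round-trip
#' material.
#'
#' @param sim result of [simulateGenome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  for (inbred in names(sim$tracks))
    writeTrack(sim$tracks[[inbred]], file.path(dir, paste0(inbred, ".vcf")),
               dialect = "vcf")
  utils::write.table(sim$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

## One fixture locus: amplicon [s, s + refLen - 1] with 20-nt primers at
## both ends of the amplicon.
fig1Locus <- function(genome, s, refLen, id) {
  primerPair(genome, "chrF", s, s + 19L, s + refLen - 20L, s + refLen - 1L,
             targetId = id)
}

#' Plant the six worked-example marker loci
#'
#' Builds a deterministic synthetic chromosome carrying six marker loci
#' that reproduce the canonical behaviour classes of Indel markers scored
#' on inbred panels (reference role "B73", non-reference "Mo17" and
#' "W22"):
#' * A - 154-bp reference product, 17-bp Mo17 deletion; B73 = W22.
#'   Co-dominant with Mo17 (137 bp).
#' * B - 255-bp product, 19-bp Mo17 deletion (236 bp) and a 40-bp W22
#'   deletion (215 bp): three resolvable co-dominant alleles.
#' * C - 143-bp product, 13-bp Mo17 deletion (130 bp); a W22 deletion
#'   removes part of the forward primer site, so W22 shows
#'   presence-absence with both other inbreds.
#' * D - 168-bp product, 14-bp Mo17 insertion (182 bp) plus a sub-lethal
#'   Mo17 primer-site mismatch: B73/W22 alleles dominant over Mo17.
#' * E - 201-bp product, 11-bp deletion shared by Mo17 and W22 (190 bp)
#'   with a primer-site mismatch: the B73 allele is dominant.
#' * F - 192-bp product from all three inbreds; the annotated 24-bp Mo17
#'   deletion is absent from the actual haplotype (annotation
#'   disagreement, audited as SAME_SIZE).
#'
#' Sequences are generated, not taken from any real genome; only the size
#' arithmetic and classification outcomes are meaningful.
#'
#' @return list with `genome`, `tracks` (named list: B73 empty, Mo17, W22),
#'   `pairs` (named list of [PrimerPair-class] A-F), `annotations` (named
#'   list of single-record annotation tracks A-F) and `expected`
#'   (data.frame of per-locus reference product sizes and annotated signed
#'   nets).
#' @export
plantFig1Fixtures <- function() {
  withSeed(1404L, function() {
    chromLen <- 17000L
    chromStr <- randomBases(chromLen)
    genome <- Biostrings::DNAStringSet(c(chrF = chromStr))
    refLens <- c(A = 154L, B = 255L, C = 143L, D = 168L, E = 201L, F = 192L)
    starts <- 1000L + (seq_along(refLens) - 1L) * 2500L
    names(starts) <- names(refLens)
    pairs <- lapply(names(refLens), function(nm)
      fig1Locus(genome, starts[[nm]], refLens[[nm]], paste0("fig", nm)))
    names(pairs) <- names(refLens)

    deletionAt <- function(anchor, L)
      c(ref = substring(chromStr, anchor, anchor + L),
        alt = substring(chromStr, anchor, anchor))
    snpAt <- function(p) {
      refBase <- substring(chromStr, p, p)
      c(ref = refBase, alt = sample(setdiff(BASES, refBase), 1L))
    }
    insertionAt <- function(anchor, L) {
      refBase <- substring(chromStr, anchor, anchor)
      c(ref = refBase, alt = paste0(refBase, randomBases(L)))
    }

    mo17 <- list(); w22 <- list(); anno <- list()
    addVar <- function(lst, pos, al, id)
      c(lst, list(data.frame(pos = pos, ref = al[["ref"]], alt = al[["alt"]],
                             id = id, stringsAsFactors = FALSE)))

    ## A: 17-bp Mo17 deletion mid-amplicon
    a <- deletionAt(starts[["A"]] + 60L, 17L)
    mo17 <- addVar(mo17, starts[["A"]] + 60L, a, "figA")
    anno <- addVar(anno, starts[["A"]] + 60L, a, "figA")
    ## B: 19-bp Mo17 deletion; independent 40-bp W22 deletion
    b <- deletionAt(starts[["B"]] + 80L, 19L)
    mo17 <- addVar(mo17, starts[["B"]] + 80L, b, "figB")
    anno <- addVar(anno, starts[["B"]] + 80L, b, "figB")
    bW <- deletionAt(starts[["B"]] + 110L, 40L)
    w22 <- addVar(w22, starts[["B"]] + 110L, bW, "figB_w22")
    ## C: 13-bp Mo17 deletion; W22 deletion inside the forward primer site
    cc <- deletionAt(starts[["C"]] + 50L, 13L)
    mo17 <- addVar(mo17, starts[["C"]] + 50L, cc, "figC")
    anno <- addVar(anno, starts[["C"]] + 50L, cc, "figC")
    cW <- deletionAt(starts[["C"]] + 2L, 8L)
    w22 <- addVar(w22, starts[["C"]] + 2L, cW, "figC_w22")
    ## D: 14-bp Mo17 insertion plus a sub-lethal primer-site SNP
    d <- insertionAt(starts[["D"]] + 70L, 14L)
    mo17 <- addVar(mo17, starts[["D"]] + 70L, d, "figD")
    anno <- addVar(anno, starts[["D"]] + 70L, d, "figD")
    dSnp <- snpAt(starts[["D"]] + 7L)
    mo17 <- addVar(mo17, starts[["D"]] + 7L, dSnp, "figD_snp")
    ## E: 11-bp deletion and a reverse-primer SNP shared by Mo17 and W22
    e <- deletionAt(starts[["E"]] + 90L, 11L)
    eSnpPos <- starts[["E"]] + refLens[["E"]] - 20L + 11L  # mid reverse site
    eSnp <- snpAt(eSnpPos)
    mo17 <- addVar(mo17, starts[["E"]] + 90L, e, "figE")
    mo17 <- addVar(mo17, eSnpPos, eSnp, "figE_snp")
    w22 <- addVar(w22, starts[["E"]] + 90L, e, "figE")
    w22 <- addVar(w22, eSnpPos, eSnp, "figE_snp")
    anno <- addVar(anno, starts[["E"]] + 90L, e, "figE")
    ## F: annotated 24-bp deletion absent from every actual haplotype
    f <- deletionAt(starts[["F"]] + 100L, 24L)
    anno <- addVar(anno, starts[["F"]] + 100L, f, "figF")

    mkTrack <- function(lst, inbred) {
      if (!length(lst))
        return(polymorphismTrack(character(), integer(), character(),
                                 character(), character(), inbredName = inbred))
      tb <- do.call(rbind, lst)
      polymorphismTrack("chrF", tb$pos, tb$ref, tb$alt, tb$id,
                        inbredName = inbred, genome = genome)
    }
    annotations <- lapply(anno, function(a)
      polymorphismTrack("chrF", a$pos, a$ref, a$alt, a$id,
                        inbredName = "Mo17", genome = genome))
    names(annotations) <- names(refLens)
    list(genome = genome,
         tracks = list(B73 = mkTrack(list(), "B73"),
                       Mo17 = mkTrack(mo17, "Mo17"),
                       W22 = mkTrack(w22, "W22")),
         pairs = pairs,
         annotations = annotations,
         expected = data.frame(
           locus = names(refLens), refLen = unname(refLens),
           annotatedNet = c(-17L, -19L, -13L, 14L, -11L, -24L),
           stringsAsFactors = FALSE))
  })
}
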