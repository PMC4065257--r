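test_that("a designed pair always reports its own locus, exactly once on clean genomes", {
  fx <- plantFig1Fixtures()
  for (nm in names(fx$pairs)) {
    p <- fx$pairs[[nm]]
    hits <- insilicoPcr(fx$genome, p)
    expect_identical(nrow(hits), 1L)
    expect_true(isSpecific(hits))
    expect_identical(hits$start, IRanges::start(p@forwardRange))
    expect_identical(hits$end, IRanges::end(p@reverseRange))
    expect_identical(hits$productLen, p@refAmpliconLen)
    expect_identical(hits$orientation, "F>R")
  }
})

test_that("a verbatim duplicated locus defeats specificity", {
  fx <- singleIndelLocus()
  ## the copied window covers every legal amplicon around the target
  dupStr <- paste0(randomSeq(300, 101),
                   substring(fx$chromStr, 700, 1320),
                   randomSeq(300, 102))
  genome <- toyGenome(chr1 = fx$chromStr, chr2 = dupStr)
  pairs <- designPrimers(genome, fx$target, maxPairs = 1L)
  hits <- insilicoPcr(genome, pairs[[1]])
  expect_identical(nrow(hits), 2L)
  expect_false(isSpecific(hits))
  expect_setequal(hits$chrom, c("chr1", "chr2"))
  expect_identical(unique(hits$productLen), pairs[[1]]@refAmpliconLen)
})

test_that("a locus present only on the opposite strand is found with swapped orientation", {
  fx <- plantFig1Fixtures()
  p <- fx$pairs$A
  flipped <- toyGenome(chrR = naiveRevcomp(as.character(fx$genome[["chrF"]])))
  hits <- insilicoPcr(flipped, p)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$orientation, "R>F")
  expect_identical(hits$productLen, p@refAmpliconLen)
})

test_that("allowing mismatches only ever adds hits", {
  fx <- singleIndelLocus(seed = 55)
  ## plant a two-mismatch copy of the target's forward/reverse sites
  seg <- substring(fx$chromStr, 850, 1250)
  segChars <- strsplit(seg, "")[[1]]
  segChars[c(10, 380)] <- chartr("ACGT", "GTAC", segChars[c(10, 380)])
  genome <- toyGenome(chr1 = fx$chromStr,
                      chr2 = paste0(randomSeq(200, 103),
                                    paste(segChars, collapse = ""),
                                    randomSeq(200, 104)))
  pair <- designPrimers(genome, fx$target, maxPairs = 1L)[[1]]
  h0 <- insilicoPcr(genome, pair, maxMismatches = 0L)
  h2 <- insilicoPcr(genome, pair, maxMismatches = 2L)
  expect_gte(nrow(h2), nrow(h0))
  key <- function(h) paste(h$chrom, h$start, h$end, h$orientation)
  expect_true(all(key(h0) %in% key(h2)))
})

test_that("hits agree with a naive all-positions sliding scan", {
  sim <- simulateGenome(simConfig(nChroms = 2L, chromLength = 6000L,
                                  inbredNames = "Mo17", indelRate = 2e-3,
                                  duplicationFraction = 0.3,
                                  dupSegmentLength = 1000L, seed = 33L))
  targets <- filterIndels(sim$tracks$Mo17, 7L)
  expect_gt(length(targets), 0L)
  tested <- 0L
  for (i in seq_len(min(3L, length(targets)))) {
    pairs <- designPrimers(sim$genome, targets[i],
                           linkedTrack = sim$tracks$Mo17, maxPairs = 1L)
    if (!length(pairs)) next
    p <- pairs[[1]]
    for (mm in c(0L, 2L)) {
      mine <- insilicoPcr(sim$genome, p, maxMismatches = mm)
      oracle <- naivePcrScan(sim$genome, p@forwardSeq, p@reverseSeq,
                             maxMis = mm)
      expect_identical(nrow(mine), nrow(oracle))
      for (col in c("chrom", "start", "end", "productLen", "fwdMismatches",
                    "revMismatches", "orientation"))
        expect_identical(unname(mine[[col]]), unname(oracle[[col]]))
    }
    tested <- tested + 1L
  }
  expect_gt(tested, 0L)
})

test_that("the amplification-failure model triggers in documented order", {
  fx <- singleIndelLocus(seed = 60)
  pair <- designPrimers(fx$genome, fx$target, maxPairs = 1L)[[1]]
  fs <- IRanges::start(pair@forwardRange); fe <- IRanges::end(pair@forwardRange)
  rs <- IRanges::start(pair@reverseRange)
  snp <- function(p) {
    b <- substring(fx$chromStr, p, p)
    list(pos = p, ref = b, alt = chartr("ACGT", "GTAC", b))
  }
  mkHap <- function(vars) {
    tb <- do.call(rbind, lapply(vars, as.data.frame))
    buildHaplotype(fx$genome, polymorphismTrack(
      "chr1", tb$pos, tb$ref, tb$alt, paste0("v", seq_len(nrow(tb))),
      "Mo17", genome = fx$genome))
  }
  ## SNP at the forward primer's 3'-terminal base
  p1 <- predictAmplicon(pair, mkHap(list(snp(fe))))
  expect_false(p1@amplifies)
  expect_identical(p1@failureReason, "PRIMER_SITE_VARIANT_3PRIME")
  ## deletion chewing into the reverse primer footprint
  del <- list(pos = rs + 6L,
              ref = substring(fx$chromStr, rs + 6L, rs + 14L),
              alt = substring(fx$chromStr, rs + 6L, rs + 6L))
  p2 <- predictAmplicon(pair, mkHap(list(del)))
  expect_false(p2@amplifies)
  expect_identical(p2@failureReason, "PRIMER_SITE_DELETED")
  ## three interior mismatches in one primer exceed the PCR tolerance
  p3 <- predictAmplicon(pair, mkHap(list(snp(fs + 1L), snp(fs + 4L),
                                         snp(fs + 7L))))
  expect_false(p3@amplifies)
  expect_identical(p3@failureReason, "PRIMER_SITE_DIVERGENCE")
  ## one interior mismatch is sub-lethal: amplifies with a handicap
  p4 <- predictAmplicon(pair, mkHap(list(snp(fs + 1L))))
  expect_true(p4@amplifies)
  expect_identical(p4@competitionHandicap, 1L)
  expect_identical(p4@productLen, pair@refAmpliconLen)
})
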