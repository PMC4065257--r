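# Frozen expected Tm values, computed once with an independent
# implementation of the same unified nearest-neighbor model (SantaLucia &
# Hicks parameters; 50 mM Na+, 25 nM per strand, entropic salt correction).
TM_ORACLE <- c(
  ACGTACGTACGTACGTACGT = 53.081667,   # self-complementary
  GGGGGGGGGGGGGGGGGGGG = 71.220220,
  AAAAAAAAAAAAAAAAAAAA = 35.961021,
  ATGCTTGCATGGAAACCTGGT = 54.855062,
  CCGGAATTCCGGAACCGGTT = 56.968265,
  ACGTACGT = 12.424655)               # self-complementary

test_that("nearest-neighbor Tm matches an independent parameter-table summation", {
  for (s in names(TM_ORACLE))
    expect_equal(meltingTemperature(s), unname(TM_ORACLE[s]), tolerance = 1e-6)
  ## vectorised call agrees with scalar calls
  expect_equal(meltingTemperature(names(TM_ORACLE)), unname(TM_ORACLE),
               tolerance = 1e-6)
})

test_that("Tm is deterministic, stability-monotone and strand-symmetric", {
  s <- "ATGCTTGCATGGAAACCTGGT"
  expect_identical(meltingTemperature(s), meltingTemperature(s))
  expect_gt(meltingTemperature(strrep("G", 20)),
            meltingTemperature(strrep("A", 20)))
  set.seed(31)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1))
  rc <- naiveRevcomp(seqs)
  expect_equal(meltingTemperature(seqs), meltingTemperature(rc),
               tolerance = 1e-9)
  expect_error(meltingTemperature("ACGTACG"), "at least 8")
  expect_error(meltingTemperature("ACGTACGTNN"), "non-ACGT")
})

test_that("designed pairs satisfy every hard constraint", {
  fx <- singleIndelLocus()
  cfg <- designConfig()
  pairs <- designPrimers(fx$genome, fx$target, cfg = cfg, maxPairs = 10L)
  expect_gte(length(pairs), 1L)
  foot <- trackRecords(fx$target)
  for (p in pairs) {
    expect_gte(p@refAmpliconLen, cfg@ampliconMin)
    expect_lte(p@refAmpliconLen, cfg@ampliconMax)
    ## target footprint strictly between the primer footprints
    expect_lt(IRanges::end(p@forwardRange), GenomicRanges::start(foot))
    expect_gt(IRanges::start(p@reverseRange), GenomicRanges::end(foot))
    ## sequences derive from the reference strands
    expect_identical(p@forwardSeq,
                     substring(fx$chromStr, IRanges::start(p@forwardRange),
                               IRanges::end(p@forwardRange)))
    expect_identical(p@reverseSeq,
                     naiveRevcomp(substring(fx$chromStr,
                                            IRanges::start(p@reverseRange),
                                            IRanges::end(p@reverseRange))))
    for (tm in c(p@tmF, p@tmR)) {
      expect_gte(tm, cfg@tmMin); expect_lte(tm, cfg@tmMax)
    }
    expect_lte(abs(p@tmF - p@tmR), cfg@tmPairMaxDiff)
    for (gc in c(p@gcF, p@gcR)) {
      expect_gte(gc, cfg@gcMin); expect_lte(gc, cfg@gcMax)
    }
    expect_equal(p@tmF, meltingTemperature(p@forwardSeq), tolerance = 1e-9)
    expect_false(any(grepl("([ACGT])\\1{5,}",
                           c(p@forwardSeq, p@reverseSeq))))
  }
  ## determinism: identical inputs, identical ranked output
  again <- designPrimers(fx$genome, fx$target, cfg = cfg, maxPairs = 10L)
  expect_identical(primerTable(pairs), primerTable(again))
})

test_that("linked-polymorphism avoidance makes saturated loci infeasible", {
  fx <- singleIndelLocus()
  ## SNPs every 6 bp: every candidate primer window (>= 18 nt) overlaps at
  ## least three of them, but one placement in six keeps its 5-nt 3' clamp
  ## clean
  snpPos <- setdiff(seq(650, 1350, by = 6), 1000:1017)
  refB <- vapply(snpPos, function(p) substring(fx$chromStr, p, p), character(1))
  altB <- chartr("ACGT", "GTAC", refB)
  linked <- polymorphismTrack("chr1", snpPos, refB, altB,
                              sprintf("s%d", snpPos), "Mo17",
                              genome = fx$genome)
  expect_message(
    dense <- designPrimers(fx$genome, fx$target, linkedTrack = linked,
                           cfg = designConfig(avoidLinked = TRUE)),
    "no legal primer design")
  expect_length(dense, 0L)
  ## ignoring linkage rescues the design, but the divergence model then
  ## predicts failure of the non-reference allele (> 2 mismatches per
  ## primer site)
  loose <- designPrimers(fx$genome, fx$target, linkedTrack = linked,
                         cfg = designConfig(avoidLinked = FALSE))
  expect_gte(length(loose), 1L)
  hapTrack <- polymorphismTrack(
    "chr1", c(snpPos, 1000), c(refB, trackTable(fx$target)$ref),
    c(altB, trackTable(fx$target)$alt), c(sprintf("s%d", snpPos), "d17"),
    "Mo17", genome = fx$genome)
  hap <- buildHaplotype(fx$genome, hapTrack)
  pred <- predictAmplicon(loose[[1]], hap)
  expect_false(pred@amplifies)
  expect_identical(pred@failureReason, "PRIMER_SITE_DIVERGENCE")
  ## and the marker comes out one-sided in favor of the reference inbred
  refPred <- predictAmplicon(loose[[1]], buildHaplotype(
    fx$genome, polymorphismTrack(character(), integer(), character(),
                                 character(), character(), "B73")))
  cls <- classifyMarker(refPred, pred)
  expect_identical(cls@verdict, "PAV")
  expect_identical(cls@favoredAllele, "B73")
})

test_that("pair penalties are monotone, zero at range midpoints, and rank-consistent", {
  fx <- singleIndelLocus()
  cfg <- designConfig()
  pairs <- designPrimers(fx$genome, fx$target, cfg = cfg, maxPairs = 10L)
  pens <- vapply(pairs, scorePair, numeric(1), cfg = cfg)
  ## ranking agrees with exhaustive penalty recomputation
  expect_false(is.unsorted(pens))
  ## synthetic pairs: only the Tm difference differs
  mk <- function(tmF, tmR) {
    p <- pairs[[1]]
    p@tmF <- tmF; p@tmR <- tmR
    p
  }
  expect_lt(scorePair(mk(59, 59), cfg), scorePair(mk(57.5, 60.5), cfg))
  ## at all range midpoints the Tm and GC terms vanish
  noStructure <- designConfig(wHomopolymer = 0, wDimer = 0)
  p <- mk(59, 59)
  p@gcF <- 50; p@gcR <- 50
  expect_equal(scorePair(p, noStructure), 0)
})

test_that("widening Tm or GC bounds never loses a design", {
  fx <- singleIndelLocus(seed = 77)
  ## fixed primer length and a tight amplicon window keep full enumeration
  ## small enough to compare as sets
  base <- function(...) designConfig(primerLenMin = 20, primerLenMax = 20,
                                     ampliconMax = 140, ...)
  key <- function(ps) vapply(ps, function(p)
    paste(IRanges::start(p@forwardRange), IRanges::end(p@forwardRange),
          IRanges::start(p@reverseRange), IRanges::end(p@reverseRange)),
    character(1))
  narrow <- designPrimers(fx$genome, fx$target,
                          cfg = base(tmMin = 57, tmMax = 61), maxPairs = Inf)
  wide <- designPrimers(fx$genome, fx$target,
                        cfg = base(tmMin = 55, tmMax = 63), maxPairs = Inf)
  expect_gt(length(narrow), 0L)
  expect_gt(length(wide), length(narrow) - 1L)
  expect_true(all(key(narrow) %in% key(wide)))
  narrowGc <- designPrimers(fx$genome, fx$target,
                            cfg = base(gcMin = 45, gcMax = 55), maxPairs = Inf)
  wideGc <- designPrimers(fx$genome, fx$target,
                          cfg = base(gcMin = 30, gcMax = 70), maxPairs = Inf)
  expect_true(all(key(narrowGc) %in% key(wideGc)))
})

test_that("primer pairs round-trip through the TSV report", {
  fx <- singleIndelLocus()
  pairs <- designPrimers(fx$genome, fx$target, maxPairs = 3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writePrimerPairs(pairs, f, header = "locus: chr1 d17")
  back <- readPrimerPairs(f)
  expect_equal(primerTable(back), primerTable(pairs), tolerance = 1e-9)
})
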