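test_that("identical configurations give byte-identical outputs", {
  cfg <- simConfig(nChroms = 2L, chromLength = 8000L,
                   inbredNames = c("Mo17", "W22"),
                   duplicationFraction = 0.1, seed = 5L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(simulateGenome(cfg), d1)
  writeSimulation(simulateGenome(cfg), d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  expect_setequal(list.files(d1),
                  c("genome.fa", "Mo17.vcf", "W22.vcf", "manifest.tsv"))
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(simulateGenome(simConfig(nChroms = 1L, chromLength = 2000L,
                                     seed = 9L)))
  expect_identical(runif(1), before)
})

test_that("rate knobs behave: no Indels means nothing passes the filter", {
  sim <- simulateGenome(simConfig(nChroms = 1L, chromLength = 20000L,
                                  inbredNames = "Mo17", indelRate = 0,
                                  seed = 14L))
  expect_true(all(sim$manifest$type == "snp"))
  expect_identical(length(filterIndels(sim$tracks$Mo17, 7L)), 0L)
  expect_error(simulateGenome(simConfig(chromLength = 1000L, snpRate = 0.3,
                                        seed = 1L)),
               "overlap saturation")
})

test_that("the filter recovers exactly the planted long Indels", {
  sim <- simulateGenome(simConfig(nChroms = 2L, chromLength = 60000L,
                                  inbredNames = "Mo17", indelRate = 2e-3,
                                  seed = 17L))
  planted <- sim$manifest[abs(sim$manifest$signedNet) >= 7L, ]
  got <- trackTable(filterIndels(sim$tracks$Mo17, 7L))
  expect_gt(nrow(planted), 20L)
  expect_identical(sort(got$id), sort(planted$id))
  ## planted variants never overlap within a track
  gr <- trackRecords(sim$tracks$Mo17)
  expect_identical(length(GenomicRanges::findOverlaps(gr, drop.self = TRUE)),
                   0L)
})

test_that("duplicated segments are copied verbatim and break specificity there", {
  sim <- simulateGenome(simConfig(nChroms = 2L, chromLength = 30000L,
                                  inbredNames = "Mo17",
                                  duplicationFraction = 0.1,
                                  dupSegmentLength = 2000L, seed = 19L))
  dup <- sim$duplications
  expect_gt(nrow(dup), 0L)
  for (i in seq_len(nrow(dup)))
    expect_identical(
      as.character(Biostrings::subseq(sim$genome[[dup$srcChrom[i]]],
                                      dup$srcStart[i],
                                      dup$srcStart[i] + dup$length[i] - 1L)),
      as.character(Biostrings::subseq(sim$genome[[dup$tgtChrom[i]]],
                                      dup$tgtStart[i],
                                      dup$tgtStart[i] + dup$length[i] - 1L)))
  ## a primer pair designed wholly inside a copied segment hits both copies
  s <- dup$srcStart[1]
  pair <- primerPair(sim$genome, dup$srcChrom[1], s + 200L, s + 219L,
                     s + 380L, s + 399L, targetId = "dup-probe")
  expect_gte(nrow(insilicoPcr(sim$genome, pair)), 2L)
})

test_that("planted worked-example loci reproduce their marker classes end to end", {
  fx <- plantFig1Fixtures()
  haps <- lapply(fx$tracks, function(t) buildHaplotype(fx$genome, t))
  predict3 <- function(nm) lapply(haps, function(h)
    predictAmplicon(fx$pairs[[nm]], h))
  ## locus A: B73 = W22, both co-dominant with Mo17
  pA <- predict3("A")
  expect_identical(pA$B73@productLen, 154L)
  expect_identical(pA$Mo17@productLen, 137L)
  expect_identical(classifyMarker(pA$B73, pA$Mo17)@verdict, "CO_DOMINANT")
  expect_identical(classifyMarker(pA$B73, pA$W22)@verdict, "NON_POLYMORPHIC")
  expect_identical(classifyMarker(pA$Mo17, pA$W22)@verdict, "CO_DOMINANT")
  ## locus B: three resolvable alleles
  pB <- predict3("B")
  expect_identical(c(pB$B73@productLen, pB$Mo17@productLen, pB$W22@productLen),
                   c(255L, 236L, 215L))
  expect_true(all(vapply(list(c("B73", "Mo17"), c("B73", "W22"),
                              c("Mo17", "W22")), function(ab)
    classifyMarker(pB[[ab[1]]], pB[[ab[2]]])@verdict, character(1)) ==
      "CO_DOMINANT"))
  ## locus C: W22 primer site deleted, presence-absence against both
  pC <- predict3("C")
  expect_identical(pC$Mo17@productLen, 130L)
  expect_identical(pC$W22@failureReason, "PRIMER_SITE_DELETED")
  cBW <- classifyMarker(pC$B73, pC$W22)
  cMW <- classifyMarker(pC$Mo17, pC$W22)
  expect_identical(cBW@verdict, "PAV"); expect_identical(cBW@favoredAllele, "B73")
  expect_identical(cMW@verdict, "PAV"); expect_identical(cMW@favoredAllele, "Mo17")
  ## locus D: insertion plus handicapped Mo17 site, dominant B73/W22 alleles
  pD <- predict3("D")
  expect_identical(pD$Mo17@productLen, 182L)
  expect_identical(pD$Mo17@competitionHandicap, 1L)
  cBM <- classifyMarker(pD$B73, pD$Mo17)
  expect_identical(cBM@verdict, "DOMINANT")
  expect_identical(cBM@favoredAllele, "B73")
  cWM <- classifyMarker(pD$W22, pD$Mo17)
  expect_identical(cWM@verdict, "DOMINANT")
  expect_identical(cWM@favoredAllele, "W22")
  ## locus E: shared deletion with handicap; B73 dominant over both
  pE <- predict3("E")
  expect_identical(pE$Mo17@productLen, 190L)
  expect_identical(classifyMarker(pE$B73, pE$Mo17)@verdict, "DOMINANT")
  expect_identical(classifyMarker(pE$B73, pE$Mo17)@favoredAllele, "B73")
  expect_identical(classifyMarker(pE$Mo17, pE$W22)@verdict, "NON_POLYMORPHIC")
  ## locus F: annotated deletion absent in fact
  pF <- predict3("F")
  expect_identical(pF$Mo17@productLen, 192L)
  expect_identical(classifyMarker(pF$B73, pF$Mo17)@verdict, "NON_POLYMORPHIC")
  expect_identical(
    unname(validateAnnotation(fx$annotations$F,
                              c(B73 = pF$B73@productLen,
                                Mo17 = pF$Mo17@productLen))), "SAME_SIZE")
  ## the fixture is deterministic
  expect_identical(as.character(plantFig1Fixtures()$genome),
                   as.character(fx$genome))
})
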