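pred <- function(inbred, len = NA, handicap = 0L,
                 reason = if (is.na(len)) "PRIMER_SITE_DIVERGENCE" else "NONE") {
  new("AmpliconPrediction", inbredName = inbred, amplifies = !is.na(len),
      productLen = as.integer(len), failureReason = reason,
      competitionHandicap = as.integer(handicap))
}

test_that("gel resolvability combines an absolute floor with a relative rule", {
  expect_true(resolvableOnGel(154, 137))    # 17 bp on ~146-bp products
  expect_false(resolvableOnGel(150, 150))
  ## the same 7-bp difference resolves on small products only
  expect_false(resolvableOnGel(300, 293))   # needs >= 14.8
  expect_true(resolvableOnGel(100, 93))     # needs >= 4.8
  ## symmetric and vectorised
  expect_identical(resolvableOnGel(c(154, 300), c(137, 293)),
                   resolvableOnGel(c(137, 293), c(154, 300)))
  ## configurable model
  expect_true(resolvableOnGel(300, 293, gelModel(minAbsDiff = 2,
                                                 relDiffFrac = 0.01)))
})

test_that("marker verdicts follow the amplification pattern", {
  gel <- gelModel()
  ## both amplify, clean sites, resolvable sizes: co-dominant with a
  ## heteroduplex band expected in heterozygotes
  cls <- classifyMarker(pred("B73", 154), pred("Mo17", 137), gel)
  expect_identical(cls@verdict, "CO_DOMINANT")
  expect_true(cls@heteroduplexExpected)
  expect_true(is.na(cls@favoredAllele))
  ## only one allele amplifies: presence-absence
  cls <- classifyMarker(pred("B73", 143),
                        pred("W22", NA, reason = "PRIMER_SITE_DELETED"), gel)
  expect_identical(cls@verdict, "PAV")
  expect_identical(cls@favoredAllele, "B73")
  ## both amplify but one carries a handicap: dominant, cleaner site wins
  cls <- classifyMarker(pred("B73", 201), pred("Mo17", 190, handicap = 1L), gel)
  expect_identical(cls@verdict, "DOMINANT")
  expect_identical(cls@favoredAllele, "B73")
  expect_true(cls@heteroduplexExpected)
  ## identical clean products: not polymorphic
  cls <- classifyMarker(pred("B73", 192), pred("Mo17", 192), gel)
  expect_identical(cls@verdict, "NON_POLYMORPHIC")
  expect_false(cls@heteroduplexExpected)
  ## both amplify but too close to resolve
  expect_identical(classifyMarker(pred("B73", 300), pred("Mo17", 293),
                                  gel)@verdict, "NON_POLYMORPHIC")
  ## nothing amplifies
  expect_identical(classifyMarker(pred("a", NA), pred("b", NA), gel)@verdict,
                   "FAILED")
})

test_that("classification is symmetric up to the favored allele", {
  cases <- list(
    list(pred("B73", 154), pred("Mo17", 137)),
    list(pred("B73", 201), pred("Mo17", 190, handicap = 1L)),
    list(pred("B73", 143), pred("W22", NA)),
    list(pred("B73", 192), pred("Mo17", 192)),
    list(pred("a", NA), pred("b", NA)))
  for (cs in cases) {
    ab <- classifyMarker(cs[[1]], cs[[2]])
    ba <- classifyMarker(cs[[2]], cs[[1]])
    expect_identical(ab@verdict, ba@verdict)
    expect_identical(ab@favoredAllele, ba@favoredAllele)
    expect_identical(ab@heteroduplexExpected, ba@heteroduplexExpected)
  }
})

test_that("equal-size alleles transfer co-dominance across inbred pairs", {
  ## if A/B resolve and A and C amplify the same clean size, B/C must
  ## resolve identically
  a <- pred("B73", 154); b <- pred("Mo17", 137); c3 <- pred("W22", 154)
  expect_identical(classifyMarker(a, b)@verdict, "CO_DOMINANT")
  expect_identical(classifyMarker(a, c3)@verdict, "NON_POLYMORPHIC")
  expect_identical(classifyMarker(b, c3)@verdict, "CO_DOMINANT")
})

test_that("annotation audits bin observed sizes into the four outcomes", {
  chromStr <- randomSeq(500, 12)
  genome <- toyGenome(chr1 = chromStr)
  del17 <- polymorphismTrack("chr1", 100, substring(chromStr, 100, 117),
                             substring(chromStr, 100, 100), "d17", "Mo17",
                             genome = genome)
  expect_identical(
    unname(validateAnnotation(del17, c(B73 = 154, Mo17 = 137))), "CONCORDANT")
  expect_identical(
    unname(validateAnnotation(del17, c(B73 = 192, Mo17 = 192))), "SAME_SIZE")
  ## a deletion that yields a LARGER product contradicts the annotation
  expect_identical(
    unname(validateAnnotation(del17, c(B73 = 154, Mo17 = 160))),
    "WRONG_DIRECTION")
  expect_identical(
    unname(validateAnnotation(del17, c(B73 = 154, Mo17 = NA))), "NO_PRODUCT")
  ## insertions flip the expected direction
  base <- substring(chromStr, 200, 200)
  ins14 <- polymorphismTrack("chr1", 200, base,
                             paste0(base, randomSeq(14, 13)), "i14", "Mo17",
                             genome = genome)
  expect_identical(
    unname(validateAnnotation(ins14, c(B73 = 168, Mo17 = 182))), "CONCORDANT")
  expect_identical(
    unname(validateAnnotation(ins14, c(B73 = 168, Mo17 = 160))),
    "WRONG_DIRECTION")
  expect_error(validateAnnotation(del17, c(Mo17 = 137)), "reference inbred")
  ## multiple non-reference inbreds audited at once
  v <- validateAnnotation(del17, c(B73 = 154, Mo17 = 137, W22 = 154))
  expect_identical(v[["Mo17"]], "CONCORDANT")
  expect_identical(v[["W22"]], "SAME_SIZE")
})
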