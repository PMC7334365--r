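# build a raw visit row at given component z-scores (defaults: all at norm
# means)
rawAt <- function(n = 1, sdstZ = 0) {
  nm <- defaultCognitiveNorms()
  satSec <- function(key, correct) correct / nm[[key]]["mean"]
  data.frame(
    subject_id = paste0("S", seq_len(n)), visit = 1,
    ppmst_1letter_correct = 20,
    ppmst_1letter_seconds = satSec("sat_ppmst_1letter", 20),
    ppmst_2letter_correct = 20,
    ppmst_2letter_seconds = satSec("sat_ppmst_2letter", 20),
    ppmst_3letter_correct = 20,
    ppmst_3letter_seconds = satSec("sat_ppmst_3letter", 20),
    stroop_reading_correct = 48,
    stroop_reading_seconds = satSec("sat_stroop_reading", 48),
    stroop_naming_correct = 48,
    stroop_naming_seconds = satSec("sat_stroop_naming", 48),
    stroop_colorword_correct = 48,
    stroop_colorword_seconds = 48 /
      (nm$stroop_interference["mean"] *
         (nm$sat_stroop_reading["mean"] + nm$sat_stroop_naming["mean"]) / 2),
    vsat_correct = 30, vsat_seconds = satSec("sat_vsat", 30),
    sdst_score = nm$sdst_score["mean"] + sdstZ * nm$sdst_score["sd"],
    ravlt_trials_mean = nm$ravlt_trials_mean["mean"],
    ravlt_delayed = nm$ravlt_delayed["mean"],
    rcft_immediate = nm$rcft_immediate["mean"],
    rcft_delayed = nm$rcft_delayed["mean"],
    fluency_score = nm$fluency_score["mean"],
    row.names = NULL
  )
}

test_that("SAT scores are correct-per-second and ratio invariant", {
  expect_equal(satScore(20, 40), 0.5)
  expect_equal(satScore(0, 30), 0)
  expect_equal(satScore(40, 80), satScore(20, 40))
  expect_error(satScore(20, 0), "positive")
})

test_that("z-scoring against baseline norms behaves as a location-scale map", {
  expect_equal(zscoreVsBaseline(5, 5, 2), 0)
  expect_equal(zscoreVsBaseline(7, 5, 2), 1)
  expect_error(zscoreVsBaseline(1, 0, 0), "SD")
  x <- rnorm(50, 3, 1.4)
  z <- zscoreVsBaseline(x, mean(x), sd(x))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("raw scores at baseline means give all-zero composites", {
  cs <- compositeScores(rawAt())
  expect_equal(unlist(cs), c(ci = 0, pms = 0, memory = 0, aef = 0))
})

test_that("raising SDST by one SD moves PMS by 1/3 and CI by 1/4", {
  cs <- compositeScores(rawAt(sdstZ = 1))
  expect_equal(cs$pms, 1 / 3)
  expect_equal(cs$ci, 1 / 4)
  expect_equal(cs$memory, 0)
  expect_equal(cs$aef, 0)
})

test_that("composites are invariant to affine rescaling of a raw test", {
  raw <- rawAt()
  raw$sdst_score <- 75  # z = 2.5 under default norms
  base <- compositeScores(raw)
  # the same test reported in units u' = 3u + 10, with norms transformed
  nm <- defaultCognitiveNorms()
  nm$sdst_score <- c(mean = 3 * nm$sdst_score[["mean"]] + 10,
                     sd = 3 * nm$sdst_score[["sd"]])
  raw2 <- raw
  raw2$sdst_score <- 3 * raw$sdst_score + 10
  expect_equal(compositeScores(raw2, nm), base, tolerance = 1e-12)
})

test_that("worse Stroop interference lowers the attention-executive score", {
  raw <- rawAt()
  raw$stroop_colorword_seconds <- raw$stroop_colorword_seconds * 1.5
  cs <- compositeScores(raw)
  expect_lt(cs$aef, 0)
  expect_equal(cs$ci, 0)
})

test_that("decline is the componentwise difference and antisymmetric", {
  a <- data.frame(ci = 0.1, pms = 0.2, memory = -0.1, aef = 0)
  b <- data.frame(ci = -0.5, pms = 0.1, memory = -0.4, aef = 0.2)
  expect_equal(declineScores(a, a), a - a)
  expect_equal(declineScores(a, b)$ci, -0.6)
  expect_equal(declineScores(a, b), -declineScores(b, a))
})

test_that("emitted raw batteries reproduce the generated composites", {
  cfg <- simulationConfig(nSubjects = 40L, nRetained = c(40L, 39L, 28L),
                          nNodes = 30L, baseDegree = 6L, seed = 3L)
  sim <- simulateCohort(cfg)
  raw <- emitRawScores(sim$cohort, seed = 17L)
  expect_true(all(as.matrix(raw[, grepl("_seconds$", names(raw))]) > 0))
  rec <- compositeScores(raw)
  expect_equal(as.matrix(rec),
               as.matrix(sim$cohort[, c("ci", "pms", "memory", "aef")]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("partially missing composites follow the half-rule", {
  raw <- rawAt()
  raw$sdst_score <- NA  # PMS has 2/3 components, CI 3/4 -> both kept
  cs <- compositeScores(raw)
  expect_equal(cs$pms, 0)
  expect_equal(cs$ci, 0)
  raw$ppmst_1letter_seconds <- NA
  raw$stroop_reading_seconds <- NA  # PMS now 0/3 -> missing
  cs2 <- compositeScores(raw)
  expect_true(is.na(cs2$pms))
})
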