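# planted-signal feature matrix: 21 correlated "measures", one carrying the
# outcome signal
plantedData <- function(n = 200, signalCol = 3, beta = 1, noiseSd = 0.3,
                        seed = 42) {
  set.seed(seed)
  Z <- matrix(rnorm(n * 21), n, 21)
  colnames(Z) <- paste0("measure_", 1:21)
  covs <- cbind(age = rnorm(n, 65, 9), sex = rbinom(n, 1, 0.5))
  y <- beta * scale(Z[, signalCol])[, 1] + rnorm(n, 0, noiseSd)
  list(Z = Z, covs = covs, y = y)
}

test_that("elastic net recovers a planted signal measure", {
  d <- plantedData()
  sel <- elasticNetSelect(d$Z, d$y, d$covs, seed = 7)
  expect_equal(sel$selected, "measure_3")
  expect_gt(abs(sel$coefficients["measure_3"]), 0.5)
})

test_that("a null outcome shrinks all measure coefficients", {
  d <- plantedData()
  set.seed(8)
  y0 <- rnorm(length(d$y))
  sel1 <- elasticNetSelect(d$Z, d$y, d$covs, seed = 7)
  sel0 <- elasticNetSelect(d$Z, y0, d$covs, seed = 7)
  expect_gte(max(abs(sel1$coefficients)), 5 * max(abs(sel0$coefficients)))
})

test_that("duplicated predictors share the signal under a ridge-like mix", {
  d <- plantedData(noiseSd = 0.2)
  Z2 <- d$Z
  Z2[, 4] <- d$Z[, 3]  # exact duplicate of the signal column
  colnames(Z2)[4] <- "measure_dup"
  sel <- elasticNetSelect(Z2, d$y, d$covs, seed = 7)
  co <- sel$coefficients[c("measure_3", "measure_dup")]
  expect_true(all(abs(co) > 0.2))
  expect_equal(unname(co[1]), unname(co[2]), tolerance = 0.05)
})

test_that("selection is invariant to affine rescaling of a feature", {
  d <- plantedData()
  sel1 <- elasticNetSelect(d$Z, d$y, d$covs, seed = 7)
  Z2 <- d$Z
  Z2[, 3] <- 100 * Z2[, 3] + 5
  sel2 <- elasticNetSelect(Z2, d$y, d$covs, seed = 7)
  expect_equal(sel2$selected, sel1$selected)
  expect_equal(sel2$coefficients, sel1$coefficients, tolerance = 1e-6)
})

test_that("constant measure columns are dropped with a warning", {
  d <- plantedData(n = 100)
  d$Z[, 7] <- 1
  expect_warning(sel <- elasticNetSelect(d$Z, d$y, d$covs, seed = 7),
                 "constant")
  expect_equal(sel$dropped, "measure_7")
  expect_false("measure_7" %in% names(sel$coefficients))
})

test_that("near-noise-free cohorts identify the mixed-model fixed effects", {
  cfg <- simulationConfig(
    nSubjects = 60L, nRetained = c(60L, 60L, 60L), nNodes = 30L,
    baseDegree = 6L, seed = 15L, residSd = 1e-4,
    randomEffectsCov = matrix(0, 2, 2)
  )
  sim <- simulateCohort(cfg)
  d <- merge(sim$cohort, sim$subjects[, c("subject_id", "efficiency_z")])
  fit <- fitLme(d, "ci", "efficiency_z", withInteraction = TRUE)
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  expect_equal(unname(est["time_years"]), cfg@fixedEffects[["time"]],
               tolerance = 1e-4)
  expect_equal(unname(est["efficiency_z:time_years"]),
               cfg@interactionBeta[["ci"]], tolerance = 1e-4)
})

test_that("likelihood-ratio identities and nesting checks hold", {
  cfg <- simulationConfig(nSubjects = 50L, nRetained = c(50L, 49L, 35L),
                          nNodes = 30L, baseDegree = 6L, seed = 33L)
  sim <- simulateCohort(cfg)
  d <- merge(sim$cohort, sim$subjects[, c("subject_id", "efficiency_z")])
  f0 <- fitLme(d, "ci", "efficiency_z", FALSE)
  f1 <- fitLme(d, "ci", "efficiency_z", TRUE)
  same <- likelihoodRatioTest(f0, f0)
  expect_equal(same$chiSq, 0)
  expect_equal(same$p, 1)
  lrt <- likelihoodRatioTest(f0, f1)
  expect_equal(lrt$chiSq, 2 * (f1$logLik - f0$logLik), tolerance = 1e-10)
  expect_equal(lrt$df, 1)
  expect_gte(lrt$chiSq, 0)
  expect_error(likelihoodRatioTest(f1, f0), "nested")
  fr <- fitLme(d, "ci", "efficiency_z", FALSE, reml = TRUE)
  expect_error(likelihoodRatioTest(fr, f1), "ML")
})

test_that("Wald intervals bracket their estimates", {
  cfg <- simulationConfig(nSubjects = 50L, nRetained = c(50L, 49L, 35L),
                          nNodes = 30L, baseDegree = 6L, seed = 34L)
  sim <- simulateCohort(cfg)
  d <- merge(sim$cohort, sim$subjects[, c("subject_id", "efficiency_z")])
  fit <- fitLme(d, "memory", "efficiency_z", TRUE)
  expect_true(all(fit$fixed$ci_lo < fit$fixed$estimate))
  expect_true(all(fit$fixed$ci_hi > fit$fixed$estimate))
  ev <- eigen(fit$ranefCov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
})

test_that("severity-ranked attrition does not bias the interaction estimate", {
  # dropout depends only on latent severity, which enters the model through
  # the covariates and the efficiency predictor, so the ML estimator stays
  # consistent; attrition costs precision, not accuracy
  ests <- vapply(1:8, function(s) {
    cfg <- simulationConfig(nSubjects = 120L,
                            nRetained = c(120L, 119L, 85L),
                            nNodes = 30L, baseDegree = 6L, seed = 40L + s)
    sim <- simulateCohort(cfg)
    d <- merge(sim$cohort, sim$subjects[, c("subject_id", "efficiency_z")])
    fit <- fitLme(d, "ci", "efficiency_z", TRUE)
    fit$fixed$estimate[grepl(":", fit$fixed$term)]
  }, numeric(1))
  mcse <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.04), 4 * mcse + 1e-8)
})
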