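smallCfg <- function(seed = 21L, ...) {
  simulationConfig(nSubjects = 40L, nRetained = c(40L, 39L, 28L),
                   nNodes = 30L, baseDegree = 6L, seed = seed, ...)
}

test_that("identical seeds give bit-identical cohorts", {
  s1 <- simulateCohort(smallCfg())
  s2 <- simulateCohort(smallCfg())
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(lapply(s1$connectomes, connWeights),
                   lapply(s2$connectomes, connWeights))
  s3 <- simulateCohort(smallCfg(seed = 22L))
  expect_false(identical(s1$cohort, s3$cohort))
})

test_that("a cohort prefix is reproducible regardless of total size", {
  big <- simulateCohort(simulationConfig(nSubjects = 12L,
                                         nRetained = c(12L, 12L, 9L),
                                         nNodes = 20L, baseDegree = 4L,
                                         seed = 5L))
  small <- simulateCohort(simulationConfig(nSubjects = 8L,
                                           nRetained = c(8L, 8L, 6L),
                                           nNodes = 20L, baseDegree = 4L,
                                           seed = 5L))
  expect_identical(connWeights(big$connectomes[[3]]),
                   connWeights(small$connectomes[[3]]))
  expect_identical(big$subjects$lesion_severity[1:8],
                   small$subjects$lesion_severity)
})

test_that("generated connectomes are symmetric, zero-diagonal, non-negative", {
  cfg <- smallCfg()
  for (sev in c(0, 0.3, 0.7, 1)) {
    W <- connWeights(simulateConnectome(cfg, sev, seed = 31L))
    expect_equal(W, t(W))
    expect_true(all(diag(W) == 0))
    expect_true(all(W >= 0))
  }
  expect_error(simulateConnectome(cfg, -0.1), "severity")
  expect_error(simulateConnectome(cfg, 1.2), "severity")
})

test_that("zero severity leaves the network unlesioned; full deletion empties it", {
  cfg0 <- smallCfg(edgeDeletionScale = 0.4)
  W0 <- connWeights(simulateConnectome(cfg0, 0, seed = 8L))
  # severity 0: every lattice edge survives with its drawn weight
  expect_equal(sum(W0[upper.tri(W0)] > 0), 30 * 6 / 2)
  cfg1 <- smallCfg(edgeDeletionScale = 1)
  W1 <- connWeights(simulateConnectome(cfg1, 1, seed = 8L))
  expect_true(all(W1 == 0))
  expect_equal(globalEfficiency(W1), 0)
})

test_that("mean global efficiency decreases with severity", {
  cfg <- smallCfg()
  effAt <- function(sev) {
    mean(vapply(1:12, function(i) {
      globalEfficiency(connWeights(simulateConnectome(cfg, sev,
                                                      seed = 900 + i)))
    }, numeric(1)))
  }
  e <- c(effAt(0.1), effAt(0.5), effAt(0.9))
  expect_true(all(diff(e) < 0))
})

test_that("covariates track latent severity", {
  sim <- simulateCohort(simulationConfig(nSubjects = 150L,
                                         nRetained = c(150L, 149L, 106L),
                                         nNodes = 30L, baseDegree = 6L,
                                         seed = 13L))
  sub <- sim$subjects
  ct <- cor.test(sub$lesion_severity, sub$wmh_ml)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  expect_lt(cor(sub$lesion_severity, sub$tbv_ml), 0)
  expect_lt(cor(sub$lesion_severity, sub$efficiency), 0)
})

test_that("noise-free cohorts equal the fixed-effect linear predictor", {
  cfg <- smallCfg(residSd = 0,
                  randomEffectsCov = matrix(0, 2, 2))
  sim <- simulateCohort(cfg)
  sub <- sim$subjects
  covNames <- c("age", "sex", "education", "depression", "wmh_ml",
                "n_lacunes", "n_microbleeds", "tbv_ml")
  X <- scale(as.matrix(sub[, covNames]))
  fe <- cfg@fixedEffects
  lp <- fe[["intercept"]] +
    drop(X %*% fe[c("age", "sex", "education", "depression", "wmh",
                    "lacunes", "microbleeds", "tbv")])
  d <- sim$cohort
  i <- match(d$subject_id, sub$subject_id)
  for (o in c("ci", "pms", "memory", "aef")) {
    expected <- lp[i] + fe[["efficiency"]] * sub$efficiency_z[i] +
      fe[["time"]] * d$time_years +
      cfg@interactionBeta[[o]] * sub$efficiency_z[i] * d$time_years
    expect_equal(d[[o]], expected, tolerance = 1e-12)
  }
})

test_that("a null interaction leaves subject slopes independent of efficiency", {
  cfg <- simulationConfig(
    nSubjects = 150L, nRetained = c(150L, 150L, 150L), nNodes = 30L,
    baseDegree = 6L, seed = 77L,
    interactionBeta = c(ci = 0, pms = 0, memory = 0, aef = 0)
  )
  sim <- simulateCohort(cfg)
  slopes <- vapply(split(sim$cohort, sim$cohort$subject_id), function(d) {
    unname(coef(lm(ci ~ time_years, data = d))[2])
  }, numeric(1))
  ez <- sim$subjects$efficiency_z[match(names(slopes),
                                        sim$subjects$subject_id)]
  co <- summary(lm(slopes ~ ez))$coefficients
  expect_lt(abs(co["ez", "Estimate"]), 2.5 * co["ez", "Std. Error"])
})

test_that("severity-ranked attrition retains the least severe subjects", {
  sim <- simulateCohort(smallCfg())
  lastIds <- unique(sim$cohort$subject_id[sim$cohort$visit == 3])
  sev <- sim$subjects$lesion_severity
  retained <- sim$subjects$subject_id %in% lastIds
  expect_equal(sum(retained), 28)
  expect_lt(max(sev[retained]), min(sev[!retained]) + 1e-12)
  # random attrition keeps retention counts but not the severity ranking
  simR <- simulateCohort(smallCfg(attritionMode = "random"))
  expect_equal(sum(simR$cohort$visit == 3), 28)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(visitTimes = c(0, 5.3, 5.3)), "increasing")
  expect_error(simulationConfig(nRetained = c(436L, 440L, 308L)),
               "non-increasing")
  expect_error(simulationConfig(baseDegree = 7L), "even")
  expect_error(simulationConfig(rewireProb = 1.2), "rewireProb")
  expect_error(
    simulationConfig(randomEffectsCov = matrix(c(1, 2, 2, 1), 2, 2)),
    "semi-definite"
  )
})

test_that("configuration YAML round-trips", {
  dir <- withr::local_tempdir()
  cfg <- smallCfg(rewireProb = 0.2, residSd = 0.5)
  p <- file.path(dir, "cfg.yaml")
  writeSimulationConfig(cfg, p)
  cfg2 <- readSimulationConfig(p)
  for (sl in slotNames(cfg)) {
    expect_equal(slot(cfg2, sl), slot(cfg, sl), info = sl)
  }
})
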