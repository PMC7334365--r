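# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: per
# subject a latent lesion-severity s in [0,1] drives (i) edge deletion and
# weight attenuation of a small-world weighted connectome, (ii) noisy
# monotone covariate links (WMH volume, lacune and microbleed counts rise
# with severity, total brain volume falls), and (iii) informative attrition
# (worst-severity subjects drop out first). Cognitive composite trajectories
# follow a random-intercept-and-slope mixed model whose slope depends on the
# standardized baseline network efficiency. Everything is driven by
# per-subject child seeds, so a cohort prefix is reproducible independent of
# the total cohort size.

#' Construct a simulation configuration
#'
#' Defaults describe the emulated cohort: 436 subjects with visits at 0,
#' 5.3 and 8.7 years retaining 436/434/308, 90-node connectomes with an even
#' base degree of 14 and rewiring probability 0.11 (calibrated so that the
#' cohort mean null-normalized weighted efficiencies sit near the study's
#' descriptive values of 0.91 global and 3.2 local), log-normal edge
#' weights, Beta(2, 6) latent severity, edge deletion probability 0.4 s and
#' weight attenuation 1 - 0.5 s, and per-outcome efficiency-by-time
#' interaction coefficients of 0.04 (cognitive index), 0.04 (psychomotor
#' speed), 0.08 (memory) and 0.08 (attention-executive function) z-units per
#' year per SD of the predictor.
#'
#' @param nSubjects baseline sample size.
#' @param visitTimes visit times in years.
#' @param nRetained retained sample size per visit.
#' @param nNodes connectome nodes.
#' @param baseDegree even ring-lattice degree.
#' @param rewireProb rewiring probability in [0, 1].
#' @param weightMeanlog,weightSdlog log-normal weight parameters.
#' @param severityShape1,severityShape2 Beta severity parameters.
#' @param edgeDeletionScale severity multiplier for edge deletion.
#' @param weightAttenuationScale severity multiplier for weight attenuation.
#' @param fixedEffects named coefficients (z-units) on the standardized
#'   covariates, the standardized predictor (\code{efficiency}) and
#'   \code{time} (z-units/year).
#' @param interactionBeta named per-outcome interaction coefficients.
#' @param randomEffectsCov 2 x 2 covariance of (intercept, slope).
#' @param residSd residual SD.
#' @param attritionMode \code{"severity"} or \code{"random"}.
#' @param efficiencyMeasure predictor driving the outcome model: one of
#'   \code{"global_efficiency_w"}, \code{"global_efficiency_b"},
#'   \code{"local_efficiency_w"}, \code{"local_efficiency_b"}.
#' @param seed base seed.
#' @return A \code{\linkS4class{SimulationConfig}}.
#' @export
simulationConfig <- function(nSubjects = 436L,
                             visitTimes = c(0, 5.3, 8.7),
                             nRetained = c(436L, 434L, 308L),
                             nNodes = 90L,
                             baseDegree = 14L,
                             rewireProb = 0.11,
                             weightMeanlog = log(0.3),
                             weightSdlog = 0.5,
                             severityShape1 = 2,
                             severityShape2 = 6,
                             edgeDeletionScale = 0.4,
                             weightAttenuationScale = 0.5,
                             fixedEffects = c(
                               intercept = 0, age = -0.1, sex = 0.05,
                               education = 0.15, depression = -0.1,
                               wmh = -0.1, lacunes = -0.05,
                               microbleeds = -0.05, tbv = 0.1,
                               efficiency = 0.15, time = -0.03
                             ),
                             interactionBeta = c(
                               ci = 0.04, pms = 0.04, memory = 0.08,
                               aef = 0.08
                             ),
                             randomEffectsCov = matrix(
                               c(0.3, -0.006, -0.006, 0.004), 2, 2
                             ),
                             residSd = 0.35,
                             attritionMode = "severity",
                             efficiencyMeasure = "global_efficiency_w",
                             seed = 1L) {
  new("SimulationConfig",
    nSubjects = as.integer(nSubjects), visitTimes = as.numeric(visitTimes),
    nRetained = as.integer(round(nRetained)), nNodes = as.integer(nNodes),
    baseDegree = as.integer(baseDegree), rewireProb = rewireProb,
    weightMeanlog = weightMeanlog, weightSdlog = weightSdlog,
    severityShape1 = severityShape1, severityShape2 = severityShape2,
    edgeDeletionScale = edgeDeletionScale,
    weightAttenuationScale = weightAttenuationScale,
    fixedEffects = fixedEffects, interactionBeta = interactionBeta,
    randomEffectsCov = randomEffectsCov, residSd = residSd,
    attritionMode = attritionMode, efficiencyMeasure = efficiencyMeasure,
    seed = as.integer(seed)
  )
}

# Ring lattice of even degree k on n nodes.
ringLattice <- function(n, k) {
  A <- matrix(0, n, n)
  for (d in seq_len(k / 2)) {
    idx <- cbind(seq_len(n), ((seq_len(n) - 1 + d) %% n) + 1)
    A[idx] <- 1
    A[idx[, c(2, 1)]] <- 1
  }
  A
}

# Watts-Strogatz-style rewiring: each lattice edge is, with probability p,
# re-attached from its first endpoint to a uniformly chosen non-neighbour.
wattsStrogatz <- function(n, k, p) {
  A <- ringLattice(n, k)
  eu <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  for (e in seq_len(nrow(eu))) {
    if (stats::runif(1) < p) {
      i <- eu[e, 1]
      j <- eu[e, 2]
      cand <- setdiff(which(A[i, ] == 0), i)
      if (length(cand)) {
        jn <- cand[sample.int(length(cand), 1)]
        A[i, j] <- A[j, i] <- 0
        A[i, jn] <- A[jn, i] <- 1
      }
    }
  }
  A
}

#' Simulate one lesioned small-world connectome
#'
#' Starts from a Watts-Strogatz-style small-world binary topology, assigns
#' log-normal edge weights, then lesions the network: each edge is deleted
#' independently with probability \code{edgeDeletionScale * severity} and
#' surviving weights are multiplied by
#' \code{1 - weightAttenuationScale * severity}.
#'
#' @param config a \code{SimulationConfig}.
#' @param severity latent lesion severity in [0, 1].
#' @param seed RNG seed for this subject's network.
#' @return A \code{\linkS4class{Connectome}} with unit node volumes
#'   (1 cm^3).
#' @export
simulateConnectome <- function(config, severity, seed = config@seed) {
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  if (config@baseDegree < 2L) stop("baseDegree must be >= 2")
  W <- withSeed(seed, {
    A <- wattsStrogatz(config@nNodes, config@baseDegree, config@rewireProb)
    eu <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    w <- stats::rlnorm(nrow(eu), config@weightMeanlog, config@weightSdlog)
    keep <- stats::runif(nrow(eu)) >= config@edgeDeletionScale * severity
    eu <- eu[keep, , drop = FALSE]
    w <- w[keep] * (1 - config@weightAttenuationScale * severity)
    M <- matrix(0, config@nNodes, config@nNodes)
    M[eu] <- w
    M + t(M)
  })
  new("Connectome",
    weights = W, nodeVolumes = rep(1000, config@nNodes),
    streamlineCounts = matrix(as.integer(W > 0), nrow(W), ncol(W))
  )
}

# Severity-linked covariates for one subject. zs standardizes severity by
# its theoretical Beta moments so the link is independent of cohort size.
simulateCovariates <- function(severity, config) {
  a <- config@severityShape1
  b <- config@severityShape2
  mu <- a / (a + b)
  sdv <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  zs <- (severity - mu) / sdv
  age <- 65.2 + 8.8 * (0.35 * zs + sqrt(1 - 0.35^2) * stats::rnorm(1))
  sex <- stats::rbinom(1, 1, 0.456)
  education <- min(7, max(1, round(5 - 0.6 * zs + 1.2 * stats::rnorm(1))))
  depression <- max(0, 11 + 7 * (0.3 * zs + sqrt(1 - 0.3^2) * stats::rnorm(1)))
  wmh <- exp(log(6.4) + 0.8 * zs + 0.6 * stats::rnorm(1))
  lacunes <- stats::rpois(1, exp(-2.6 + 4.5 * severity))
  microbleeds <- stats::rpois(1, exp(-3.2 + 4.5 * severity))
  tbv <- 1097.8 + 120.8 * (-0.35 * zs + sqrt(1 - 0.35^2) * stats::rnorm(1))
  data.frame(
    age = age, sex = sex, education = education, depression = depression,
    wmh_ml = wmh, n_lacunes = lacunes, n_microbleeds = microbleeds,
    tbv_ml = tbv
  )
}

# Network predictor named by the config.
predictorValue <- function(connectome, measure) {
  W <- connWeights(connectome)
  switch(measure,
    global_efficiency_w = globalEfficiency(W),
    global_efficiency_b = globalEfficiency((W > 0) * 1),
    local_efficiency_w = localEfficiency(W),
    local_efficiency_b = localEfficiency((W > 0) * 1),
    stop("unsupported efficiencyMeasure: ", measure)
  )
}

#' Simulate a full longitudinal cohort
#'
#' Per subject: draw latent severity, build the lesioned connectome, derive
#' covariates, compute the baseline network predictor; then standardize the
#' predictor across the cohort and generate the four composite trajectories
#' (ci, pms, memory, aef) from the mixed model
#' \deqn{y_{ij} = \beta_0 + \beta' x_i + \beta_E E_i + \beta_t t_{ij} +
#'   \beta_{Et} E_i t_{ij} + b_{0i} + b_{1i} t_{ij} + \epsilon_{ij}}
#' with per-outcome interaction coefficients, subject random effects drawn
#' per outcome from \code{randomEffectsCov}, and attrition truncating each
#' visit to the configured retention (severity-ranked by default: the
#' worst-severity subjects drop out first; completely-at-random dropout is
#' available via \code{attritionMode = "random"}).
#'
#' @param config a \code{SimulationConfig}.
#' @return A list with elements \code{config}, \code{subjects} (one row per
#'   subject: covariates, latent severity, raw and standardized predictor),
#'   \code{connectomes} (list of \code{Connectome}), and \code{cohort}
#'   (long-format data.frame with one row per retained subject-visit).
#' @export
simulateCohort <- function(config) {
  n <- config@nSubjects
  outcomes <- c("ci", "pms", "memory", "aef")
  covNames <- c("age", "sex", "education", "depression", "wmh_ml",
                "n_lacunes", "n_microbleeds", "tbv_ml")

  connectomes <- vector("list", n)
  rows <- vector("list", n)
  sev <- effRaw <- numeric(n)
  ranef <- vector("list", n)
  resid <- vector("list", n)
  nT <- length(config@visitTimes)
  for (i in seq_len(n)) {
    si <- childSeed(config@seed, i)
    sev[i] <- withSeed(si, stats::rbeta(1, config@severityShape1,
                                        config@severityShape2))
    connectomes[[i]] <- simulateConnectome(config, sev[i],
                                           seed = childSeed(si, 1L))
    rows[[i]] <- withSeed(childSeed(si, 2L),
                          simulateCovariates(sev[i], config))
    effRaw[i] <- predictorValue(connectomes[[i]], config@efficiencyMeasure)
    ranef[[i]] <- withSeed(childSeed(si, 3L), {
      re <- MASS::mvrnorm(length(outcomes), mu = c(0, 0),
                          Sigma = config@randomEffectsCov)
      matrix(re, ncol = 2, dimnames = list(outcomes, c("b0", "b1")))
    })
    resid[[i]] <- withSeed(childSeed(si, 4L), {
      matrix(stats::rnorm(length(outcomes) * nT, 0, config@residSd),
             nrow = length(outcomes), dimnames = list(outcomes, NULL))
    })
  }
  subjects <- do.call(rbind, rows)
  subjects <- cbind(
    data.frame(subject_id = sprintf("S%04d", seq_len(n))),
    subjects,
    data.frame(lesion_severity = sev, efficiency = effRaw)
  )
  subjects$efficiency_z <- as.numeric(scale(effRaw))

  # standardized covariates for outcome generation
  X <- scale(as.matrix(subjects[, covNames]))
  X[is.nan(X)] <- 0
  fe <- config@fixedEffects
  covBeta <- fe[c("age", "sex", "education", "depression", "wmh", "lacunes",
                  "microbleeds", "tbv")]
  lpCov <- fe[["intercept"]] + drop(X %*% covBeta)

  # retained subject set per visit
  retainedAt <- vector("list", nT)
  retainedAt[[1]] <- seq_len(n)[order(sev)][seq_len(config@nRetained[1])]
  for (j in seq_len(nT)[-1]) {
    prev <- retainedAt[[j - 1]]
    m <- config@nRetained[j]
    retainedAt[[j]] <- if (config@attritionMode == "severity") {
      prev[order(sev[prev])][seq_len(m)]
    } else {
      withSeed(childSeed(config@seed, 100000L + j),
               sort(sample(prev, m)))
    }
  }

  long <- list()
  for (j in seq_len(nT)) {
    t <- config@visitTimes[j]
    ids <- sort(retainedAt[[j]])
    Ez <- subjects$efficiency_z[ids]
    block <- data.frame(
      subject_id = subjects$subject_id[ids],
      visit = j, time_years = t
    )
    for (o in outcomes) {
      bEt <- config@interactionBeta[[o]]
      b0 <- vapply(ranef[ids], function(m) m[o, "b0"], numeric(1))
      b1 <- vapply(ranef[ids], function(m) m[o, "b1"], numeric(1))
      eps <- vapply(resid[ids], function(m) m[o, j], numeric(1))
      block[[o]] <- lpCov[ids] + fe[["efficiency"]] * Ez +
        fe[["time"]] * t + bEt * Ez * t + b0 + b1 * t + eps
    }
    long[[j]] <- cbind(block, subjects[ids, covNames])
  }
  cohort <- do.call(rbind, long)
  rownames(cohort) <- NULL
  cohort <- cohort[, c("subject_id", "visit", "time_years", outcomes,
                       covNames)]

  list(config = config, subjects = subjects, connectomes = connectomes,
       cohort = cohort)
}

#' Write a simulated cohort to CSV
#'
#' Long format, one row per retained subject-visit, with the composite
#' scores and covariates.
#'
#' @param sim result of \code{\link{simulateCohort}}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeCohortCSV <- function(sim, path) {
  utils::write.csv(sim$cohort, path, row.names = FALSE)
  invisible(path)
}
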