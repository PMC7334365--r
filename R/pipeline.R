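# Pipeline orchestration: simulate -> metrics -> cognition -> select -> lme,
# with a run manifest recording the resolved configuration, seeds, stage
# outputs and row counts.

#' Cohort metrics table
#'
#' Computes the 21-measure panel for every connectome of a simulated cohort.
#'
#' @param sim result of \code{\link{simulateCohort}}.
#' @param nNulls nulls per subject for the normalized efficiencies.
#' @param swapsPerEdge swaps per edge in the null rewiring.
#' @param seed base seed; each subject uses a derived child seed.
#' @return data.frame: \code{subject_id}, the 21 measures, and a
#'   \code{disconnected} flag.
#' @export
cohortMetrics <- function(sim, nNulls = 20L, swapsPerEdge = 10L, seed = 42L) {
  n <- length(sim$connectomes)
  M <- matrix(NA_real_, n, length(metricNames()),
              dimnames = list(NULL, metricNames()))
  disc <- logical(n)
  for (i in seq_len(n)) {
    v <- computeAllMetrics(sim$connectomes[[i]], nNulls = nNulls,
                           swapsPerEdge = swapsPerEdge,
                           seed = childSeed(seed, i))
    M[i, ] <- v
    disc[i] <- attr(v, "disconnected")
  }
  if (any(disc))
    message(sprintf("cohortMetrics: %d/%d subject(s) with disconnected nodes",
                    sum(disc), n))
  cbind(data.frame(subject_id = sim$subjects$subject_id), as.data.frame(M),
        data.frame(disconnected = disc))
}

# Measure panel ready for regression: path-length sentinels imputed by the
# cohort maximum, any remaining non-finite entry (undefined assortativity
# or normalization on heavily lesioned subjects) imputed by its column mean.
pipelineFeatures <- function(met) {
  feat <- imputePathLengthSentinels(as.matrix(met[, metricNames()]))
  for (j in seq_len(ncol(feat))) {
    bad <- !is.finite(feat[, j])
    if (any(bad)) {
      fill <- if (all(bad)) 0 else mean(feat[!bad, j])
      feat[bad, j] <- fill
    }
  }
  feat
}

# Per-subject decline score of one outcome: last available follow-up minus
# baseline. Subjects without a follow-up visit are NA.
declineFromCohort <- function(cohort, outcome) {
  base <- cohort[cohort$visit == 1, c("subject_id", outcome)]
  fu <- cohort[cohort$visit > 1, c("subject_id", "visit", outcome)]
  fu <- fu[order(fu$subject_id, -fu$visit), ]
  fu <- fu[!duplicated(fu$subject_id), ]
  m <- merge(base, fu, by = "subject_id", suffixes = c("_base", "_fu"))
  stats::setNames(
    m[[paste0(outcome, "_fu")]] - m[[paste0(outcome, "_base")]],
    m$subject_id
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate, metrics, cognition (raw battery emission and composite
#' round-trip), elastic-net selection and the null/full LME comparison, in
#' order, writing all tabular outputs and a JSON manifest under
#' \code{outDir}. With \code{resume = TRUE} a stage whose outputs already
#' exist is skipped.
#'
#' @param config a \code{SimulationConfig} or path to a YAML configuration.
#' @param outDir output directory (created if needed).
#' @param outcome cognitive domain for selection and modelling.
#' @param nNulls nulls per subject in the metrics stage.
#' @param enetOutcome \code{"decline"} (default) to select on the decline
#'   score, or \code{"baseline"}.
#' @param resume skip stages whose outputs exist.
#' @return The manifest, invisibly (also written as \code{manifest.json}).
#' @export
runPipeline <- function(config = simulationConfig(), outDir, outcome = "ci",
                        nNulls = 20L, enetOutcome = c("decline", "baseline"),
                        resume = FALSE) {
  enetOutcome <- match.arg(enetOutcome)
  if (is.character(config)) {
    if (!file.exists(config)) stop("stage simulate: config not found: ",
                                   config)
    config <- readSimulationConfig(config)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outDir, f)
  manifest <- list(
    version = as.character(utils::packageVersion("netcog")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config@seed, outcome = outcome, stages = list()
  )
  writeSimulationConfig(config, pth("config_resolved.yaml"))

  skippable <- function(name, outputs) {
    ok <- resume && all(file.exists(vapply(outputs, pth, character(1))))
    if (ok) message(sprintf("[%s] outputs exist, skipped (resume)", name))
    ok
  }
  stage <- function(name, fn) {
    message(sprintf("[%s] running", name))
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # simulate: always recomputed (deterministic and cheap relative to the
  # metric stage); writes are skipped under resume
  sim <- stage("simulate", function() simulateCohort(config))
  if (!skippable("simulate-write", c("cohort.csv", "subjects.csv"))) {
    writeCohortCSV(sim, pth("cohort.csv"))
    utils::write.csv(sim$subjects, pth("subjects.csv"), row.names = FALSE)
  }
  manifest$stages$simulate <- list(
    outputs = c("cohort.csv", "subjects.csv"),
    n_subjects = nrow(sim$subjects), n_rows = nrow(sim$cohort)
  )

  # metrics
  if (skippable("metrics", "metrics.csv")) {
    met <- utils::read.csv(pth("metrics.csv"))
  } else {
    met <- stage("metrics", function() {
      cohortMetrics(sim, nNulls = nNulls, seed = childSeed(config@seed, 555L))
    })
    utils::write.csv(met, pth("metrics.csv"), row.names = FALSE)
  }
  manifest$stages$metrics <- list(
    outputs = "metrics.csv", n_rows = nrow(met), n_nulls = nNulls,
    n_disconnected = sum(met$disconnected)
  )

  # cognition: emit a raw battery consistent with the generated composites
  if (!skippable("cognition", "raw_scores.csv")) {
    raw <- stage("cognition", function() {
      emitRawScores(sim$cohort, seed = childSeed(config@seed, 777L))
    })
    utils::write.csv(raw, pth("raw_scores.csv"), row.names = FALSE)
    rec <- compositeScores(raw)
    maxErr <- max(abs(
      as.matrix(rec) -
        as.matrix(sim$cohort[, c("ci", "pms", "memory", "aef")])
    ))
    manifest$stages$cognition <- list(
      outputs = "raw_scores.csv", n_rows = nrow(raw),
      composite_roundtrip_max_abs_err = maxErr
    )
  } else {
    manifest$stages$cognition <- list(outputs = "raw_scores.csv",
                                      skipped = TRUE)
  }

  # elastic-net selection
  sel <- stage("select", function() {
    feat <- pipelineFeatures(met)
    base <- sim$cohort[sim$cohort$visit == 1, ]
    y <- if (enetOutcome == "baseline") {
      stats::setNames(base[[outcome]], base$subject_id)
    } else {
      declineFromCohort(sim$cohort, outcome)
    }
    ids <- intersect(names(y), met$subject_id)
    rows <- match(ids, met$subject_id)
    brow <- match(ids, base$subject_id)
    covs <- cbind(
      age = base$age[brow], sex = base$sex[brow],
      education = base$education[brow], depression = base$depression[brow],
      wmh_ml = base$wmh_ml[brow],
      lacunes_present = as.numeric(base$n_lacunes[brow] > 0),
      microbleeds_present = as.numeric(base$n_microbleeds[brow] > 0),
      tbv_ml = base$tbv_ml[brow]
    )
    elasticNetSelect(feat[rows, , drop = FALSE], y[ids], covs,
                     seed = childSeed(config@seed, 888L))
  })
  jsonlite::write_json(
    list(selected = sel$selected, lambda = sel$lambda,
         coefficients = as.list(sel$coefficients)),
    pth("selection.json"), auto_unbox = TRUE, digits = NA
  )
  manifest$stages$select <- list(outputs = "selection.json",
                                 selected = sel$selected,
                                 enet_outcome = enetOutcome)

  # LME with the selected measure
  lme <- stage("lme", function() {
    feat <- pipelineFeatures(met)
    mz <- as.numeric(scale(feat[, sel$selected]))
    dat <- merge(
      sim$cohort,
      data.frame(subject_id = met$subject_id, measure_z = mz),
      by = "subject_id"
    )
    nullFit <- fitLme(dat, outcome, "measure_z", withInteraction = FALSE)
    fullFit <- fitLme(dat, outcome, "measure_z", withInteraction = TRUE)
    list(nullFit = nullFit, fullFit = fullFit,
         lrt = likelihoodRatioTest(nullFit, fullFit))
  })
  jsonlite::write_json(
    list(
      outcome = outcome, predictor = sel$selected,
      null = list(logLik = lme$nullFit$logLik,
                  fixed = lme$nullFit$fixed),
      full = list(logLik = lme$fullFit$logLik,
                  fixed = lme$fullFit$fixed),
      lrt = list(chi_square = lme$lrt$chiSq, df = lme$lrt$df, p = lme$lrt$p)
    ),
    pth("lme.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  manifest$stages$lme <- list(
    outputs = "lme.json",
    interaction = lme$fullFit$fixed$estimate[
      grepl(":", lme$fullFit$fixed$term)],
    chi_square = lme$lrt$chiSq, p = lme$lrt$p
  )

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Write the canonical test fixtures
#'
#' Straight and 90-degree-bend bundle phantoms (NIfTI), three 12-node
#' example graphs with the package's metric panel, and a 30-subject
#' mini-cohort, all regenerated deterministically from pinned seeds.
#'
#' @param outDir output directory.
#' @return Invisibly, the vector of paths written.
#' @export
makeFixtures <- function(outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  ph1 <- makeBundlePhantom(c(16, 9, 9))
  ph2 <- makeBundlePhantom(c(16, 16, 9), bendAngle = 90)
  paths <- c(paths, writePhantom(ph1, file.path(outDir, "straight")))
  paths <- c(paths, writePhantom(ph2, file.path(outDir, "bent90")))

  gdf <- list()
  mv <- list()
  for (g in 1:3) {
    A <- withSeed(1000L + g, {
      n <- 12L
      M <- matrix(0, n, n)
      M[upper.tri(M)] <- stats::rbinom(n * (n - 1) / 2, 1, 0.35)
      M + t(M)
    })
    eu <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    gdf[[g]] <- data.frame(graph = g, from = eu[, 1], to = eu[, 2])
    mv[[g]] <- cbind(data.frame(graph = g),
                     as.data.frame(t(computeAllMetrics(A, nNulls = 20L,
                                                       seed = 2000L + g))))
  }
  p <- file.path(outDir, "oracle_graphs.tsv")
  utils::write.table(do.call(rbind, gdf), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(outDir, "oracle_metrics.tsv")
  utils::write.table(do.call(rbind, mv), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)

  cfg <- simulationConfig(nSubjects = 30L, nRetained = c(30L, 29L, 21L),
                          seed = 11L)
  sim <- simulateCohort(cfg)
  p <- file.path(outDir, "mini_cohort.csv")
  writeCohortCSV(sim, p)
  paths <- c(paths, p)
  invisible(paths)
}
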