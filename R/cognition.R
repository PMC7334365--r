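# Composite cognitive scoring: speed-accuracy trade-off (SAT) scores,
# z-scoring against baseline norms, the four composite domains (cognitive
# index, psychomotor speed, memory, attention-executive function) and
# decline scores.
#
# Conventions the battery leaves open and this module fixes: SAT =
# correct/seconds (any monotone variant only rescales before z-scoring, so
# the composites are insensitive to this choice); the Stroop interference
# ratio (color-word SAT over the mean of reading and naming SAT) is already
# higher = less interference = better, so it enters the composite
# un-negated and every composite reads "higher = better"; follow-up visits
# are standardized against baseline norms so decline is in baseline-SD
# units.

#' Speed-accuracy trade-off score
#'
#' @param correct number of correct responses (>= 0).
#' @param seconds completion time (> 0).
#' @return \code{correct / seconds}.
#' @export
satScore <- function(correct, seconds) {
  if (any(seconds <= 0, na.rm = TRUE)) stop("seconds must be positive")
  correct / seconds
}

#' Z-score against baseline norms
#'
#' @param values raw values.
#' @param baselineMean,baselineSd baseline norming constants.
#' @return \code{(values - baselineMean) / baselineSd}.
#' @export
zscoreVsBaseline <- function(values, baselineMean, baselineSd) {
  if (baselineSd == 0) stop("baseline SD must be non-zero")
  (values - baselineMean) / baselineSd
}

#' Default baseline norms for the synthetic battery
#'
#' Means and SDs per raw test (SAT scores in correct/second, counts in
#' points), used both to z-score raw visits and to invert composites into
#' raw scores when the generator emits a raw battery.
#'
#' @return A named list of \code{c(mean, sd)} pairs.
#' @export
defaultCognitiveNorms <- function() {
  list(
    sat_ppmst_1letter = c(mean = 0.90, sd = 0.20),
    sat_ppmst_2letter = c(mean = 0.55, sd = 0.12),
    sat_ppmst_3letter = c(mean = 0.40, sd = 0.10),
    sat_stroop_reading = c(mean = 1.10, sd = 0.20),
    sat_stroop_naming = c(mean = 0.90, sd = 0.18),
    stroop_interference = c(mean = 2.00, sd = 0.30),
    sdst_score = c(mean = 50, sd = 10),
    ravlt_trials_mean = c(mean = 8, sd = 2),
    ravlt_delayed = c(mean = 7, sd = 3),
    rcft_immediate = c(mean = 18, sd = 6),
    rcft_delayed = c(mean = 17, sd = 6),
    fluency_score = c(mean = 22, sd = 6),
    sat_vsat = c(mean = 0.80, sd = 0.15)
  )
}

# z against a named norm entry
zNorm <- function(x, norms, key) {
  zscoreVsBaseline(x, norms[[key]]["mean"], norms[[key]]["sd"])
}

# mean of available components when at least half are present, else NA
halfMean <- function(zs) {
  ok <- is.finite(zs)
  if (sum(ok) * 2 >= length(zs) && any(ok)) mean(zs[ok]) else NA_real_
}

#' Composite cognitive scores from a raw visit
#'
#' Computes the four composite z-scores from one or more raw visit rows:
#' \itemize{
#'   \item cognitive index (ci): mean of z(SAT one-letter PPMST),
#'     z(SAT Stroop reading), z(SDST) and the mean of z(RAVLT trials) and
#'     z(RAVLT delayed);
#'   \item psychomotor speed (pms): mean of the first three of those;
#'   \item memory: mean of z(RAVLT trials), z(RAVLT delayed),
#'     z(RCFT immediate), z(RCFT delayed), z(SAT 2-letter) and
#'     z(SAT 3-letter PPMST);
#'   \item attention-executive function (aef): mean of z(Stroop
#'     interference = SAT color-word / mean SAT of reading and naming;
#'     higher ratio = less interference), z(fluency) and z(SAT VSAT).
#' }
#' Composites with fewer than half their components available are NA.
#'
#' @param visit data.frame with columns \code{ppmst_1letter_correct},
#'   \code{ppmst_1letter_seconds}, ... (see \code{\link{emitRawScores}} for
#'   the full schema).
#' @param norms baseline norms (default \code{defaultCognitiveNorms()}).
#' @return data.frame with columns \code{ci}, \code{pms}, \code{memory},
#'   \code{aef}.
#' @export
compositeScores <- function(visit, norms = defaultCognitiveNorms()) {
  sat <- function(stub) satScore(visit[[paste0(stub, "_correct")]],
                                 visit[[paste0(stub, "_seconds")]])
  zP1 <- zNorm(sat("ppmst_1letter"), norms, "sat_ppmst_1letter")
  zP2 <- zNorm(sat("ppmst_2letter"), norms, "sat_ppmst_2letter")
  zP3 <- zNorm(sat("ppmst_3letter"), norms, "sat_ppmst_3letter")
  zSR <- zNorm(sat("stroop_reading"), norms, "sat_stroop_reading")
  zSDST <- zNorm(visit$sdst_score, norms, "sdst_score")
  zTr <- zNorm(visit$ravlt_trials_mean, norms, "ravlt_trials_mean")
  zDel <- zNorm(visit$ravlt_delayed, norms, "ravlt_delayed")
  zRI <- zNorm(visit$rcft_immediate, norms, "rcft_immediate")
  zRD <- zNorm(visit$rcft_delayed, norms, "rcft_delayed")
  zFl <- zNorm(visit$fluency_score, norms, "fluency_score")
  zVS <- zNorm(sat("vsat"), norms, "sat_vsat")
  interf <- sat("stroop_colorword") /
    ((sat("stroop_reading") + sat("stroop_naming")) / 2)
  zInt <- zNorm(interf, norms, "stroop_interference")

  n <- nrow(visit)
  out <- data.frame(ci = numeric(n), pms = numeric(n), memory = numeric(n),
                    aef = numeric(n))
  for (r in seq_len(n)) {
    out$ci[r] <- halfMean(c(zP1[r], zSR[r], zSDST[r],
                            mean(c(zTr[r], zDel[r]))))
    out$pms[r] <- halfMean(c(zP1[r], zSR[r], zSDST[r]))
    out$memory[r] <- halfMean(c(zTr[r], zDel[r], zRI[r], zRD[r],
                                zP2[r], zP3[r]))
    out$aef[r] <- halfMean(c(zInt[r], zFl[r], zVS[r]))
  }
  if (all(is.na(out))) stop("all composite components missing")
  out
}

#' Componentwise decline score
#'
#' Follow-up minus baseline, so negative values mean decline when higher
#' scores are better.
#'
#' @param baseline,followup data.frames (or rows) of composite scores.
#' @return \code{followup - baseline}.
#' @export
declineScores <- function(baseline, followup) {
  stopifnot(identical(names(baseline), names(followup)))
  followup - baseline
}

#' Emit a raw test battery consistent with generated composites
#'
#' Inverts the composite definitions: free components are drawn near the
#' target composite (so derived components stay in range) and one component
#' per composite is solved so that \code{\link{compositeScores}} reproduces
#' the cohort's ci/pms/memory/aef exactly. Timed tests are emitted as
#' (correct, seconds) pairs with fixed item counts.
#'
#' @param cohort long cohort data.frame with columns \code{subject_id},
#'   \code{visit}, \code{ci}, \code{pms}, \code{memory}, \code{aef}.
#' @param norms baseline norms used for the inversion.
#' @param seed RNG seed for the free component draws.
#' @param freeSd SD of free component draws around the composite target.
#' @return data.frame of raw scores, one row per subject-visit, with the
#'   schema consumed by \code{compositeScores}.
#' @export
emitRawScores <- function(cohort, norms = defaultCognitiveNorms(),
                          seed = 1L, freeSd = 0.3) {
  n <- nrow(cohort)
  withSeed(seed, {
    # free draws for timed tests are clamped so the implied SAT score stays
    # positive; residual components are solved on untimed score tests, which
    # tolerate any real value
    rn <- function(center, key = NULL) {
      z <- stats::rnorm(n, center, freeSd)
      if (!is.null(key)) {
        m <- norms[[key]]["mean"]
        s <- norms[[key]]["sd"]
        z <- pmax(z, (0.05 * m - m) / s)
      }
      z
    }
    zP1 <- rn(cohort$pms, "sat_ppmst_1letter")
    zSR <- rn(cohort$pms, "sat_stroop_reading")
    zSDST <- 3 * cohort$pms - zP1 - zSR
    zRv <- 4 * cohort$ci - 3 * cohort$pms  # mean of trials & delayed z
    zTr <- rn(zRv)
    zDel <- 2 * zRv - zTr
    zP2 <- rn(cohort$memory, "sat_ppmst_2letter")
    zP3 <- rn(cohort$memory, "sat_ppmst_3letter")
    zRD <- rn(cohort$memory)
    zRI <- 6 * cohort$memory - (zTr + zDel + zRD + zP2 + zP3)
    zInt <- rn(cohort$aef, "stroop_interference")
    zVS <- rn(cohort$aef, "sat_vsat")
    zFl <- 3 * cohort$aef - zInt - zVS
    zSN <- pmax(stats::rnorm(n, 0, freeSd), -4)  # denominator of interference

    unz <- function(z, key) norms[[key]]["mean"] + z * norms[[key]]["sd"]
    satP1 <- unz(zP1, "sat_ppmst_1letter")
    satP2 <- unz(zP2, "sat_ppmst_2letter")
    satP3 <- unz(zP3, "sat_ppmst_3letter")
    satSR <- unz(zSR, "sat_stroop_reading")
    satSN <- unz(zSN, "sat_stroop_naming")
    satVS <- unz(zVS, "sat_vsat")
    interf <- unz(zInt, "stroop_interference")
    satCW <- interf * (satSR + satSN) / 2

    timed <- function(sat, correct) {
      data.frame(correct = rep(correct, n), seconds = correct / sat)
    }
    raw <- data.frame(subject_id = cohort$subject_id, visit = cohort$visit)
    add <- function(raw, stub, tm) {
      raw[[paste0(stub, "_correct")]] <- tm$correct
      raw[[paste0(stub, "_seconds")]] <- tm$seconds
      raw
    }
    raw <- add(raw, "ppmst_1letter", timed(satP1, 20))
    raw <- add(raw, "ppmst_2letter", timed(satP2, 20))
    raw <- add(raw, "ppmst_3letter", timed(satP3, 20))
    raw <- add(raw, "stroop_reading", timed(satSR, 48))
    raw <- add(raw, "stroop_naming", timed(satSN, 48))
    raw <- add(raw, "stroop_colorword", timed(satCW, 48))
    raw <- add(raw, "vsat", timed(satVS, 30))
    raw$sdst_score <- unz(zSDST, "sdst_score")
    raw$ravlt_trials_mean <- unz(zTr, "ravlt_trials_mean")
    raw$ravlt_delayed <- unz(zDel, "ravlt_delayed")
    raw$rcft_immediate <- unz(zRI, "rcft_immediate")
    raw$rcft_delayed <- unz(zRD, "rcft_delayed")
    raw$fluency_score <- unz(zFl, "fluency_score")
    raw
  })
}
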