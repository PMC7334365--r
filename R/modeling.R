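# Statistical modelling: elastic-net selection of the most predictive
# network measure, and linear mixed-effects models of cognitive change with
# likelihood-ratio testing.

#' Elastic-net selection of the most predictive network measure
#'
#' Fits a penalized linear model of the outcome on the 21 network measures
#' (standardized to mean 0, SD 1) with the adjustment covariates included
#' unpenalized, mixing parameter alpha = 0.05 by default (nearly ridge, so
#' collinear measures share signal rather than being arbitrarily dropped),
#' and the penalty weight chosen by seeded 10-fold cross-validation with
#' folds stratified by outcome quartile. Coefficients are reported on the
#' standardized scale; the selected measure attains the largest absolute
#' coefficient.
#'
#' @param features numeric matrix, subjects x network measures (named
#'   columns).
#' @param outcome numeric outcome vector.
#' @param covariates numeric matrix of unpenalized adjustment covariates
#'   (may have zero columns).
#' @param alphaMix elastic-net mixing parameter (default 0.05).
#' @param nFolds cross-validation folds (default 10).
#' @param lambdaRule \code{"lambda.min"} (default) or \code{"lambda.1se"}.
#' @param seed fold-assignment seed.
#' @return A list of class \code{"enetSelection"}: \code{coefficients}
#'   (named, standardized scale), \code{selected}, \code{lambda},
#'   \code{dropped} (constant columns removed).
#' @export
elasticNetSelect <- function(features, outcome, covariates = NULL,
                             alphaMix = 0.05, nFolds = 10L,
                             lambdaRule = c("lambda.min", "lambda.1se"),
                             seed = 7L) {
  lambdaRule <- match.arg(lambdaRule)
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("m", seq_len(ncol(features)))
  sds <- apply(features, 2, stats::sd)
  dropped <- colnames(features)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant measure column(s): ",
            paste(dropped, collapse = ", "))
    features <- features[, sds > 0, drop = FALSE]
  }
  Z <- scale(features)
  if (!is.null(covariates) && ncol(as.matrix(covariates)) > 0) {
    covariates <- as.matrix(covariates)
    x <- cbind(Z, covariates)
    pf <- c(rep(1, ncol(Z)), rep(0, ncol(covariates)))
  } else {
    x <- Z
    pf <- rep(1, ncol(Z))
  }
  if (nFolds > length(outcome)) stop("nFolds exceeds the number of subjects")
  foldid <- withSeed(seed, {
    q <- cut(outcome, stats::quantile(outcome, probs = seq(0, 1, 0.25)),
             include.lowest = TRUE, labels = FALSE)
    f <- integer(length(outcome))
    for (g in unique(q)) {
      idx <- which(q == g)
      f[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    f
  })
  cvfit <- glmnet::cv.glmnet(x, outcome, alpha = alphaMix, foldid = foldid,
                             standardize = FALSE, penalty.factor = pf,
                             grouped = length(outcome) >= 3 * nFolds)
  lam <- cvfit[[lambdaRule]]
  co <- stats::coef(cvfit, s = lam)
  co <- stats::setNames(as.numeric(co)[-1], rownames(co)[-1])
  measureCo <- co[colnames(Z)]
  structure(
    list(
      coefficients = measureCo,
      selected = names(measureCo)[which.max(abs(measureCo))],
      lambda = lam,
      dropped = dropped
    ),
    class = "enetSelection"
  )
}

#' @export
print.enetSelection <- function(x, ...) {
  cat(sprintf("Elastic-net selection: '%s' (|coef| = %.4g, lambda = %.4g)\n",
              x$selected, max(abs(x$coefficients)), x$lambda))
  invisible(x)
}

lmeCovariates <- c("age", "sex", "education", "depression", "wmh_ml",
                   "n_lacunes", "n_microbleeds", "tbv_ml")

#' Linear mixed-effects model of longitudinal cognition
#'
#' Maximum-likelihood fit (REML optional for reporting, but ML is required
#' for valid likelihood-ratio comparison of fixed effects) of
#' \code{outcome ~ covariates + predictor + time (+ predictor:time)} with a
#' correlated subject random intercept and slope on time (unstructured
#' 2 x 2 covariance). A singular random-effects fit is retried with a
#' diagonal covariance and flagged.
#'
#' @param data long-format data.frame; must contain the outcome, predictor,
#'   \code{time_years}, \code{subject_id} and the adjustment covariates.
#' @param outcome outcome column name (e.g. \code{"ci"}).
#' @param predictor predictor column name (baseline network measure,
#'   constant within subject).
#' @param withInteraction add the predictor-by-time interaction.
#' @param covariates adjustment covariate names.
#' @param reml fit by REML instead of ML (default FALSE).
#' @return A list of class \code{"lmeFit"}: \code{fixed} (data.frame with
#'   estimate, se, 95\% Wald CI, z and p per term), \code{ranefCov},
#'   \code{residSd}, \code{logLik}, \code{df}, \code{nObs},
#'   \code{nSubjects}, \code{singular}, \code{terms}, \code{model} (the
#'   lme4 fit).
#' @export
fitLme <- function(data, outcome, predictor, withInteraction = FALSE,
                   covariates = lmeCovariates, reml = FALSE) {
  keep <- stats::complete.cases(
    data[, c(outcome, predictor, "time_years", "subject_id", covariates)]
  )
  data <- data[keep, , drop = FALSE]
  rhs <- c(covariates, predictor, "time_years")
  if (withInteraction) rhs <- c(rhs, paste0(predictor, ":time_years"))
  fml <- stats::as.formula(paste(
    outcome, "~", paste(rhs, collapse = " + "),
    "+ (1 + time_years | subject_id)"
  ))
  fit <- lme4::lmer(fml, data = data, REML = reml,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    fml2 <- stats::as.formula(paste(
      outcome, "~", paste(rhs, collapse = " + "),
      "+ (1 + time_years || subject_id)"
    ))
    fit <- lme4::lmer(fml2, data = data, REML = reml,
                      control = lme4::lmerControl(calc.derivs = FALSE))
  }
  sf <- summary(fit)
  est <- sf$coefficients[, "Estimate"]
  se <- sf$coefficients[, "Std. Error"]
  z <- est / se
  fixed <- data.frame(
    term = rownames(sf$coefficients), estimate = est, se = se,
    ci_lo = est - stats::qnorm(0.975) * se,
    ci_hi = est + stats::qnorm(0.975) * se,
    z = z, p = 2 * stats::pnorm(-abs(z)),
    row.names = NULL
  )
  vc <- lme4::VarCorr(fit)$subject_id
  reCov <- matrix(0, 2, 2, dimnames = list(c("(Intercept)", "time_years"),
                                           c("(Intercept)", "time_years")))
  if (!is.null(vc) && all(dim(vc) == c(2, 2))) {
    reCov[] <- vc[1:2, 1:2]
  } else {
    # diagonal refit stores the two variance components separately
    vcs <- lme4::VarCorr(fit)
    for (b in vcs) {
      nm <- rownames(b)
      reCov[nm, nm] <- reCov[nm, nm] + b[seq_along(nm), seq_along(nm)]
    }
  }
  ll <- stats::logLik(fit)
  structure(
    list(
      fixed = fixed, ranefCov = reCov,
      residSd = stats::sigma(fit),
      logLik = as.numeric(ll), df = attr(ll, "df"),
      nObs = nrow(data),
      nSubjects = length(unique(data$subject_id)),
      singular = singular, reml = reml,
      terms = rhs, outcome = outcome, predictor = predictor,
      model = fit
    ),
    class = "lmeFit"
  )
}

#' @export
print.lmeFit <- function(x, ...) {
  cat(sprintf(
    "LME fit (%s): %s on %s%s; %d obs / %d subjects; logLik %.2f%s\n",
    if (x$reml) "REML" else "ML", x$outcome, x$predictor,
    if (any(grepl(":", x$terms))) " with interaction" else "",
    x$nObs, x$nSubjects, x$logLik,
    if (x$singular) " [singular RE fit, diagonal refit]" else ""
  ))
  print(x$fixed, digits = 3)
  invisible(x)
}

#' Likelihood-ratio test between nested ML mixed-model fits
#'
#' chi^2 = 2 (logLik_full - logLik_null) on the difference in parameter
#' count (1 for the single interaction term). Small negative statistics
#' (optimizer noise) are clipped to zero; larger ones raise a warning.
#'
#' @param nullFit,fullFit \code{lmeFit} objects; the null terms must nest in
#'   the full terms, both fitted by ML on the same rows.
#' @return A list of class \code{"lrtResult"}: \code{chiSq}, \code{df},
#'   \code{p}.
#' @export
likelihoodRatioTest <- function(nullFit, fullFit) {
  if (nullFit$reml || fullFit$reml)
    stop("likelihood-ratio testing requires ML fits")
  if (!all(nullFit$terms %in% fullFit$terms))
    stop("models are not nested (term sets differ)")
  if (nullFit$nObs != fullFit$nObs)
    stop("models were fitted on different rows")
  if (isTRUE(nullFit$singular) != isTRUE(fullFit$singular))
    warning("random-effects structures differ after a singular refit; ",
            "the statistic may be conservative")
  chi <- 2 * (fullFit$logLik - nullFit$logLik)
  if (chi < -1e-6)
    warning("negative LRT statistic beyond tolerance; refit advised")
  chi <- max(chi, 0)
  # degrees of freedom: number of added fixed-effect terms (1 for the
  # single interaction), robust to diagonal random-effects refits
  df <- length(setdiff(fullFit$terms, nullFit$terms))
  structure(
    list(chiSq = chi, df = df, p = stats::pchisq(chi, df, lower.tail = FALSE)),
    class = "lrtResult"
  )
}

#' @export
print.lrtResult <- function(x, ...) {
  cat(sprintf("LRT: chi^2(%d) = %.3f, p = %.4g\n", x$df, x$chiSq, x$p))
  invisible(x)
}
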