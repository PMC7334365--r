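# YAML (de)serialization of the simulation configuration, so pipeline runs
# are driven by a single structured text file and every run can log the
# resolved configuration alongside its seed.

#' Write a simulation configuration as YAML
#'
#' @param config a \code{SimulationConfig}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeSimulationConfig <- function(config, path) {
  lst <- list(
    cohort = list(
      n_subjects = config@nSubjects,
      visit_times = as.list(config@visitTimes),
      n_retained = as.list(config@nRetained),
      attrition_mode = config@attritionMode
    ),
    network = list(
      n_nodes = config@nNodes,
      base_degree = config@baseDegree,
      rewire_prob = config@rewireProb,
      weight_meanlog = config@weightMeanlog,
      weight_sdlog = config@weightSdlog
    ),
    lesion = list(
      severity_shape1 = config@severityShape1,
      severity_shape2 = config@severityShape2,
      edge_deletion_scale = config@edgeDeletionScale,
      weight_attenuation_scale = config@weightAttenuationScale
    ),
    outcome = list(
      fixed_effects = as.list(config@fixedEffects),
      interaction_beta = as.list(config@interactionBeta),
      random_effects_cov = list(
        var_intercept = config@randomEffectsCov[1, 1],
        var_slope = config@randomEffectsCov[2, 2],
        cov = config@randomEffectsCov[1, 2]
      ),
      resid_sd = config@residSd,
      efficiency_measure = config@efficiencyMeasure
    ),
    seed = config@seed
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Missing keys fall back to the package defaults.
#'
#' @param path YAML file written by \code{\link{writeSimulationConfig}} (or
#'   hand-edited with the same structure).
#' @return A \code{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  d <- simulationConfig()
  gv <- function(x, default) if (is.null(x)) default else x
  rec <- gv(y$outcome$random_effects_cov, NULL)
  reCov <- if (is.null(rec)) d@randomEffectsCov else
    matrix(c(rec$var_intercept, rec$cov, rec$cov, rec$var_slope), 2, 2)
  simulationConfig(
    nSubjects = gv(y$cohort$n_subjects, d@nSubjects),
    visitTimes = unlist(gv(y$cohort$visit_times, d@visitTimes)),
    nRetained = unlist(gv(y$cohort$n_retained, d@nRetained)),
    attritionMode = gv(y$cohort$attrition_mode, d@attritionMode),
    nNodes = gv(y$network$n_nodes, d@nNodes),
    baseDegree = gv(y$network$base_degree, d@baseDegree),
    rewireProb = gv(y$network$rewire_prob, d@rewireProb),
    weightMeanlog = gv(y$network$weight_meanlog, d@weightMeanlog),
    weightSdlog = gv(y$network$weight_sdlog, d@weightSdlog),
    severityShape1 = gv(y$lesion$severity_shape1, d@severityShape1),
    severityShape2 = gv(y$lesion$severity_shape2, d@severityShape2),
    edgeDeletionScale = gv(y$lesion$edge_deletion_scale,
                           d@edgeDeletionScale),
    weightAttenuationScale = gv(y$lesion$weight_attenuation_scale,
                                d@weightAttenuationScale),
    fixedEffects = unlist(gv(y$outcome$fixed_effects,
                             as.list(d@fixedEffects))),
    interactionBeta = unlist(gv(y$outcome$interaction_beta,
                                as.list(d@interactionBeta))),
    randomEffectsCov = reCov,
    residSd = gv(y$outcome$resid_sd, d@residSd),
    efficiencyMeasure = gv(y$outcome$efficiency_measure,
                           d@efficiencyMeasure),
    seed = gv(y$seed, d@seed)
  )
}
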