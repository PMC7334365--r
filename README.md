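# netcog

Structural brain network efficiency and longitudinal cognitive decline in
cerebral small vessel disease (SVD).

In SVD, diffuse white matter damage (hyperintensities, lacunes,
microbleeds) degrades the brain's white matter network long before any
single lesion explains a cognitive deficit. A productive way to quantify
that degradation is graph-theoretic: build a structural connectome from
diffusion tractography — nodes are atlas regions, edge weights summarize
the white matter connecting them — and ask whether whole-network summaries
such as **global efficiency**

$$E_{glob} = \frac{1}{n(n-1)} \sum_{i \neq j} \frac{1}{d_{ij}}$$

(mean inverse shortest-path distance, with weighted distances along edge
lengths $1/w$) predict the *rate* of subsequent cognitive decline, over and
above conventional MRI markers.

netcog implements that analysis end to end, for researchers in imaging
neuroscience and anyone who wants a fully testable reference
implementation:

* **Tractography** — deterministic FACT-style streamline tracking on
  tensor-field phantoms: seeds at voxel centers with FA > 0.2, fixed-step
  propagation along per-voxel principal directions, termination on mask
  exit, FA < 0.2, or a turning angle above 60°.
* **Connectome construction** — streamline endpoints mapped to a
  parcellation; edge weight = mean streamline FA × streamline count,
  normalized by endpoint-region volume; undirected weighted 90 × 90
  matrices with TSV I/O.
* **Network measures** — a 21-measure panel on binarized and weighted
  networks (efficiencies, path length, clustering, transitivity,
  modularity, betweenness, assortativity, rich club) plus normalized
  global/local efficiency against Maslov–Sneppen degree-preserving null
  ensembles carrying the observed weight multiset.
* **Cognitive composites** — speed–accuracy trade-off scores, baseline-norm
  z-scoring, the cognitive-index / psychomotor-speed / memory /
  attention–executive composites, and decline scores.
* **Modelling** — elastic-net selection (α = 0.05, 10-fold CV, covariates
  unpenalized) of the most predictive measure, then linear mixed-effects
  models with subject random intercept and slope: a null model (covariates
  + measure + time) against a full model adding measure × time, compared by
  likelihood-ratio test.
* **Synthetic cohort** — a generator emulating an SVD cohort (436 subjects,
  visits at 0/5.3/8.7 years retaining 436/434/308, lesion-severity-linked
  covariates and small-world connectomes, severity-ranked attrition) whose
  outcome model plants known efficiency-by-time interactions, so the whole
  pipeline is testable without patient data.

## Worked example

Simulate a small cohort, inspect a connectome, and test whether baseline
global efficiency predicts decline of the cognitive index:

```r
library(netcog)

cfg <- simulationConfig(nSubjects = 60L, nRetained = c(60L, 59L, 42L),
                        seed = 7L)
sim <- simulateCohort(cfg)

sim$connectomes[[1]]
#> Connectome: 90 nodes, 575 edges, density 0.144, mean weight 0.2999

round(normalizedEfficiencies(connWeights(sim$connectomes[[1]]),
                             nNulls = 20L, seed = 1L), 3)
#> normGlobal  normLocal
#>      0.912      2.743
```

The network is small-world: local efficiency well above degree-matched
random networks (2.74), global efficiency slightly below (0.912). Now the
longitudinal model:

```r
d  <- merge(sim$cohort, sim$subjects[, c("subject_id", "efficiency_z")])
f0 <- fitLme(d, "ci", "efficiency_z", withInteraction = FALSE)
f1 <- fitLme(d, "ci", "efficiency_z", withInteraction = TRUE)
f1$fixed[grepl("efficiency|time", f1$fixed$term), c("term", "estimate", "p")]
#>                       term    estimate           p
#> 10            efficiency_z  0.06643675 0.552929841
#> 11              time_years -0.03439590 0.004492489
#> 12 efficiency_z:time_years  0.03012753 0.032814939

likelihoodRatioTest(f0, f1)
#> LRT: chi^2(1) = 4.315, p = 0.03778
```

Cognition declines over time (−0.034 z/year), and subjects with lower
baseline efficiency decline faster: the efficiency × time interaction
(0.030 z/year per SD of efficiency; generated with a true value of 0.04)
improves model fit (χ²(1) = 4.3, p = 0.038). At the full 436-subject design
the estimate tightens around the planted coefficient.

`runPipeline(cfg, "out/")` chains simulate → metrics → cognition →
elastic-net selection → LME/LRT with a JSON manifest;
`inst/scripts/netcog-cli.R` exposes the same stages as shell subcommands.

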