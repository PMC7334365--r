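---
title: "Methods: structural network efficiency and cognitive decline"
author: "netcog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural network efficiency and cognitive decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

netcog implements a complete analysis chain for studying how white matter
network organization relates to longitudinal cognitive decline in cerebral
small vessel disease (SVD): deterministic tractography on tensor-field
phantoms, construction of weighted structural connectomes, a panel of 21
graph-theoretic network measures with null-model normalization, composite
cognitive z-scores, elastic-net selection of the most predictive measure,
and linear mixed-effects (LME) modelling with likelihood-ratio testing.
Because individual patient data of this kind are not publicly deposited,
the package ships a synthetic cohort generator that reproduces the
statistical structure the analysis assumes, so every stage is exercised and
tested end to end.

## The data-generating model

Each synthetic subject carries a latent lesion-severity $s_i \in [0,1]$
drawn from Beta(2, 6). Severity drives three things:

1. **Connectome.** A 90-node Watts–Strogatz-style small-world topology
   (even base degree $k = 14$, rewiring probability $p = 0.11$) receives
   log-normal edge weights (meanlog $\log 0.3$, sdlog $0.5$). Lesioning
   deletes each edge independently with probability $0.4\,s_i$ and
   multiplies surviving weights by $1 - 0.5\,s_i$. Deletion alters the
   topology (and hence the normalized efficiencies); the attenuation factor
   is a uniform rescaling that cancels from every normalized ratio but
   depresses raw weighted measures, as diffuse white matter damage does.
2. **Covariates.** Age, white matter hyperintensity (WMH) volume, lacune
   and microbleed counts rise with severity; total brain volume falls;
   education falls weakly; sex is independent. Links are linear-Gaussian
   for continuous covariates and log-linear Poisson for counts, with
   location/scale chosen to match the descriptive statistics of a typical
   elderly SVD cohort (mean age 65.2 y (SD 8.8), median WMH 6.4 ml,
   ~22% with lacunes, ~15% with microbleeds, TBV 1097.8 ml (SD 120.8)).
3. **Attrition.** Three visits at 0, 5.3 and 8.7 years retain 436, 434 and
   308 subjects. By default dropout is severity-ranked (the most severe
   subjects leave first), mirroring the clinical observation that
   non-completers are older and sicker; completely-at-random dropout is
   available via `attritionMode = "random"` for sensitivity analyses.

Cognitive composites $y_{ij}$ (cognitive index ci, psychomotor speed pms,
memory, attention–executive function aef) follow a random-intercept-and-
slope model

$$y_{ij} = \beta_0 + \beta^\top x_i + \beta_E E_i + \beta_t t_{ij}
  + \beta_{Et} E_i t_{ij} + b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij},$$

where $E_i$ is the baseline network predictor standardized to mean 0, SD 1
across the cohort (so $\beta_{Et}$ is in z-units per year per SD of the
predictor; the scaling of the predictor is this package's choice, made so
the interaction is unit-free), $(b_{0i}, b_{1i})$ is bivariate normal with
unstructured covariance (defaults: intercept variance 0.3, slope variance
0.004, covariance −0.006), and $\varepsilon_{ij} \sim N(0, 0.35^2)$.
Default interaction coefficients are 0.04 (ci), 0.04 (pms), 0.08 (memory)
and 0.08 (aef) z-units/year per SD, with the weighted global efficiency as
the default predictor and binary local efficiency selectable for the
attention–executive domain. The time slope is −0.03 z/year.

Random effects and residuals are drawn per outcome, so the four composites
are generated on a shared covariate/predictor backbone but with independent
subject trajectories. Every subject is generated under a child seed derived
from the base seed, which makes a cohort prefix reproducible regardless of
the total cohort size.

**Why severity-ranked attrition does not bias the interaction estimate.**
Dropout depends only on $s_i$, which influences outcomes solely through
covariates and $E_i$ — all of which are in the fitted model. The
missingness is therefore covariate-dependent (ignorable), and the ML
estimator of $\beta_{Et}$ remains consistent; attrition costs precision,
not accuracy. The test suite checks exactly this (no inflation of the
estimate within Monte-Carlo error) rather than an attenuation that this
generating mechanism does not produce. Attenuation would require dropout to
depend on the subject's own trajectory (e.g. on $b_{1i}$), which the
generator deliberately does not assume because no quantitative attrition
mechanism is available to calibrate it.

## Calibration of the generator

The two free topology parameters (base degree, rewiring probability) were
calibrated once, before the defaults were frozen, so that the cohort means
of the null-normalized weighted efficiencies sit at the descriptive values
reported for real SVD connectomes: normalized global efficiency ≈ 0.91 and
normalized local efficiency ≈ 3.2 against 20 degree-preserving nulls. At
$k = 14$, $p = 0.11$ with the default lesioning, a default cohort yields
approximately 0.90 and 3.0. Every network in the cohort shows the
small-world signature (normalized local efficiency > 1, normalized global
efficiency < 1).

## Tractography

Tracking is deterministic FACT-style streamline propagation on a
tensor-field phantom: seeds at the centers of all masked voxels with
FA > 0.2; fixed steps of half a voxel along the current voxel's principal
direction, sign-aligned with the previous step; termination on mask exit,
on entering a voxel with FA < 0.2, or when the turning angle between the
principal directions of successive distinct voxels exceeds 60°. Tracking is
bidirectional from each seed (mono-directional by flag); the two branches
are concatenated through the seed center. Fixed-step nearest-voxel lookup
is an approximation to exact voxel-boundary crossing; with step ≤ half the
voxel size no voxel is skipped along axis-aligned bundles, which is the
regime the phantoms exercise. A branch that exits the mask ends at its last
in-mask point, so endpoints are always assignable to a parcel. Streamlines
with fewer than two points are discarded; no minimum-length filter is
applied beyond that.

## Connectome construction

Two regions are connected when a streamline's endpoints fall in both: the
endpoint voxel's parcel label decides containment (no dilation), background
endpoints and same-parcel pairs are discarded (the reported matrix has a
zero diagonal, which forces the self-loop exclusion). The raw connection
strength of a region pair is the mean streamline FA times the number of
connecting streamlines; the edge weight divides this by the mean of the two
endpoint-region volumes in cm³. The normalization denominator is ambiguous
in the literature between one volume, the sum and the mean; the mean keeps
weights on the raw FA×count-per-cm³ scale and the variant is exposed
(`volumeNorm = "mean" | "sum" | "product-root"`). Matrices are written as
full 90×90 TSV with at least 12 significant digits.

## Network measures

The 21-measure panel spans the families commonly reported for structural
connectomes — integration (global efficiency, characteristic path length),
segregation (clustering, transitivity, modularity, local efficiency),
centrality (mean betweenness), topology (degree assortativity, rich club)
— each on the binarized and the weighted network, plus the two
null-normalized weighted efficiencies. The precise panel composition is
this package's definition; it is fixed, named, and exposed as
`netcog:::metricNames()`.

Conventions:

* Weighted shortest paths use edge lengths $1/w$ (the standard convention
  for FA-weighted connectomes), so binary input reduces to hop counts.
* Global efficiency counts unreachable pairs as zero; characteristic path
  length returns an `Inf` sentinel when any pair is unreachable and the
  subject is flagged. For regression input the sentinel is imputed by the
  cohort maximum finite value (`imputePathLengthSentinels`), reflecting the
  usual argument that efficiency, not path length, is the quantity that
  remains well-behaved on disconnected networks.
* Local efficiency of a node is the global efficiency of the subgraph
  induced by its neighbours (nodes with < 2 neighbours contribute 0). This
  neighbour-subgraph definition is implemented in-package; igraph's
  `local_efficiency()` uses a different neighborhood convention and is not
  used.
* Clustering and transitivity rescale weights by the maximum and give each
  triangle the geometric mean of its rescaled weights, so the binary case
  is the classical triangle count.
* Modularity reports the better of a greedy agglomerative and a seeded
  multilevel (Louvain) partition. It is deterministic given the seed, but
  as a search heuristic its partition can depend on node label order;
  relabelling a network can move Q by a small amount, unlike every other
  measure in the panel, which is exactly permutation invariant.
* The rich-club coefficient is the mean over degree levels $k$ (retaining
  at least two nodes) of the edge density among nodes of degree > k,
  reported raw: null normalization is reserved for the two efficiency
  ratios, which are the quantities interpreted against a reference.
* Null models are Maslov–Sneppen degree-preserving edge swaps (10 attempted
  swaps per edge) with the observed weight multiset re-assigned randomly to
  the rewired edges; normalized efficiency = observed / null-ensemble mean.
  The default ensemble size is 100 for single-network use; cohort-level
  runs in this package use 20 nulls per subject, which puts the Monte-Carlo
  error of a cohort mean well below the differences of interest.

## Cognitive composites

Raw timed tests are summarized as speed–accuracy trade-off (SAT) scores,
defined here as correct responses per second. Any monotone variant of this
definition only rescales the raw score before z-scoring, so composites are
insensitive to the choice. All z-scores use baseline norms, including at
follow-up visits, so a decline score (follow-up minus baseline) is in
baseline-SD units. The Stroop interference score divides the color-word SAT
by the mean SAT of the reading and naming tasks; since SAT is higher-better,
a higher interference ratio means *less* interference, and the ratio's
z-score enters the attention–executive composite un-negated — every
composite reads higher = better. A composite with fewer than half of its
components available is missing; otherwise it is the mean of the available
component z-scores.

The generator writes composites directly (they are the model outcome); when
a raw battery is required, `emitRawScores()` inverts the composite
definitions — free components drawn near the composite target, one untimed
score per composite solved exactly — so that recomputing composites from
the emitted raw table reproduces the generated values to ~1e-15. Timed-test
draws are clamped so implied SAT scores stay positive.

## Selection and modelling

The elastic net (mixing parameter α = 0.05, i.e. nearly ridge) regresses
the outcome on the 21 standardized measures with the adjustment covariates
included *unpenalized* — the standard way to "adjust for" covariates in a
penalized regression, preferred here to residualizing them out. The penalty
weight is chosen by 10-fold cross-validation at the CV minimum
(`lambda.1se` by option), with seeded folds stratified by outcome quartile
for stability. Because α is small, collinear measures share the signal
instead of being arbitrarily dropped — the behaviour wanted when many
network measures are strongly correlated. The selected measure is the one
with the largest absolute standardized coefficient. Whether covariates are
standardized too is immaterial for selection (they are unpenalized); the
pipeline passes them raw. The pipeline's default selection outcome is the
decline score (last follow-up minus baseline); the baseline score is
selectable. Lacunes and microbleeds enter the elastic net as presence
indicators and the LME as counts, matching how such covariates are usually
coded in each context.

The LME fits `outcome ~ covariates + measure + time (+ measure:time)` with
correlated random intercept and slope (unstructured 2×2 covariance) by
maximum likelihood — not REML, because the null and full model differ in
fixed effects and the likelihood-ratio test is only valid for ML fits; a
REML option exists for estimate reporting. A singular random-effects fit is
retried with a diagonal covariance and flagged. Wald 95% intervals and
normal-approximation p-values are reported per fixed effect; the LRT
statistic is $2(\ell_{full} - \ell_{null})$ with degrees of freedom equal
to the number of added fixed-effect terms (1 for the single interaction),
which stays correct when a singular refit changes the variance-parameter
count. Small negative statistics from optimizer noise are clipped to zero.

## Numerical and scale choices in the tests

Brute-force oracles (Floyd–Warshall by exhaustive relaxation, triangle and
shortest-path enumeration) verify every graph measure on 50 random graphs
of up to 12 nodes. The LME type-I calibration uses 200 replicate null
cohorts of 60 subjects on 30-node networks; interaction-recovery checks use
12 replicate full-size cohorts (436 subjects, 90 nodes) per planted
coefficient, with tolerances tied to the observed Monte-Carlo standard
error. The acceptance script scales the recovery runs to 50 replicates and
computes cohort normalized efficiencies for all 436 subjects at 20 nulls
each. These sizes were chosen so that a complete run remains a desk-scale
computation on a single CPU while keeping Monte-Carlo error well inside the
tolerances being checked.

## Limitations

The generator emulates the *statistical* structure the analysis consumes,
not the physics upstream of it: no diffusion-weighted signal, scanner
noise, registration error, or spatial lesion maps are simulated, and the
connectome model assigns weights independently of topology. Passing tests
therefore validate the analysis machinery and its statistical behaviour
under the assumed model — they do not certify tractography accuracy on real
diffusion data, nor that real SVD cohorts satisfy the generating
assumptions (in particular, real attrition may well depend on unobserved
trajectory components, in which case interaction estimates would be
attenuated rather than unbiased). Crossing-fiber geometry is out of scope
for the single-direction-per-voxel phantoms.
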