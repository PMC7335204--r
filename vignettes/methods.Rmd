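---
title: "Methods: weighted graph analysis of resting-state networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted graph analysis of resting-state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restnet)
```

This vignette documents the model, the parameter choices, and the
numerical decisions behind the package, in the order the pipeline runs.

## The analysis model

The pipeline treats each subject's resting-state recording as an
$T \times N$ matrix of ROI-averaged BOLD signals over a fixed node set
(by default 45 nodes: 22 bilateral pain-matrix and default-mode regions
plus the midline periaqueductal gray). Its object of inference is the
*conditional* dependence structure among nodes: partial correlations
from the inverse correlation matrix, so that an edge between two nodes
reflects coupling not explained by the remaining 43. Absolute values of
the partial correlations become edge weights in $[0,1]$ — a deliberate
conflation of positive and negative coupling of equal magnitude — and
all graph measures operate on this fully weighted graph with edge length
$1/w$. No thresholding or binarization is applied anywhere.

Because every weighted graph measure depends strongly on the weight
distribution, raw global measures are not comparable across subjects.
Each subject's measures are therefore divided by their mean over an
ensemble of *random equivalent graphs*: graphs with the same node count
and the exact multiset of edge weights, randomly re-assigned to
positions. A normalized value of 1 means "indistinguishable from a graph
with the same weights but no topological organisation"; values above 1
for clustering and characteristic path length indicate segregated,
modular weight placement.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `run_translation_limit` | 1 | mm | per-axis position limit relative to the reference volume |
| `run_rotation_limit` | 1 | degrees | compared in radians internally |
| `fd_limit` | 1 | mm | scan-to-scan framewise displacement cut |
| `min_interval` | 300 | s | minimum clean acquisition window |
| `max_censored_fraction` | 0.10 | — | tolerated censoring inside the window |
| `band` | 0.009–0.1 | Hz | standard resting-state fluctuation band |
| `n_null` | 1000 | graphs | null-ensemble size for normalization |
| hub `quantile` | 0.20 | — | top/bottom slice defining each hub criterion |
| `within_r`, `between_r` | 0.3, 0.05 | correlation | generator's planted modular structure |
| `group_effect` | 0 | correlation | added to IBS `between_r`; 0 = null regime |

The FD formula multiplies rotation differences by 50: rotations are
expressed in radians and projected to arc displacement on a 50 mm
sphere, which is why the rotation *censoring* threshold (1°) must be
converted to radians rather than reusing the FD scale.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not the physics of MRI. Per subject it draws multivariate Gaussian time
series from a planted block covariance (unit diagonal, `within_r` inside
modules, `between_r` across; three 15-node modules by default, echoing
the roughly three-community organisation seen in group modularity
tables), mixes in three autocorrelated nuisance series (WM, CSF, global)
and a small linear trend, and overlays a motion trace of slow
sinusoidal drift plus Bernoulli spikes. Questionnaire scores come from
truncated Gaussians parameterized by published group medians and IQRs
for the two cohort presets (Sendai: IBS-SSS, STAI-T, SDS, VSI;
Gothenburg: IBS-SSS colonic/extracolonic, HADS anxiety/depression, VSI),
truncated to instrument ranges (IBS-SSS 0–500, VSI 0–75, HADS 0–21 per
subscale). The Gothenburg preset acquires 300 volumes and analyses the
first 250, matching the paired-design constraint of equal volume counts
across cohorts.

Two points deserve emphasis. First, the group contrast in *network*
structure defaults to zero: the reference analyses found no group
difference in normalized global measures, and the null regime is what
calibration tests need. A nonzero `group_effect` is injected as an
*increase of between-module correlation* in patients (reduced
segregation) — a configurable modelling choice, not an empirical claim.
Second, the generator omits physiological noise spectra, scanner drift
nonlinearity, spatial smoothness and voxel-level artifacts; passing
tests therefore demonstrate correctness of the estimators on data
satisfying their assumptions, not robustness to real-scanner artifacts.

## Numerical choices

* **FD of the first volume is 0** (no predecessor), and FD depends only
  on parameter differences, hence is invariant to constant offsets.
* **Inclusion window discretization.** The minimal window is
  `floor(min_interval / tr)` volumes: a window short of the requested
  interval by less than one TR still qualifies. This makes the rule
  independent of whether `min_interval` is a whole multiple of the TR
  (at TR 1.8 s the minimal window is 166 volumes ≈ 298.8 s). All window
  lengths are scanned, since a longer window can satisfy the censoring
  fraction when no minimal-length window does.
* **Filter realization.** The band is implemented as a forward-backward
  (zero-phase) 4th-order Butterworth. The series is demeaned and
  mirror-padded to full length on both sides before `filtfilt`, which
  suppresses edge transients that would otherwise dominate short runs at
  the 0.009 Hz edge. Censored frames are linearly interpolated between
  nearest uncensored neighbours (edges held constant) before filtering
  and re-flagged afterwards; they are excluded by mask (listwise) from
  all covariance computations rather than deleted.
* **Detrending is folded into the nuisance design** (intercept + linear
  term + WM + CSF + global + 6 motion parameters), equivalent under OLS
  to a separate detrending pass. Constant regressors (e.g. a motionless
  trace) are dropped; genuinely collinear regressors raise an error
  naming the columns. The global-signal regressor is always included.
* **Partial correlation estimator.** Plain inversion of the sample
  correlation matrix by default; with 45 nodes and ~250 volumes this is
  well posed. A Ledoit–Wolf-style shrinkage toward the identity (with
  the Schafer–Strimmer analytic intensity) engages automatically when
  the condition number exceeds 1e8 or the number of uncensored volumes
  is at most $2N$; the estimator used is recorded per subject. Working
  on the correlation scale makes the result invariant to per-node affine
  rescaling. Conditioning is always on all remaining nodes.
* **Shortest paths and betweenness** are computed in compiled code
  (Dijkstra / Brandes) with path-length ties detected at an absolute
  tolerance of 1e-10, so equal-length alternatives with exactly
  representable weights are counted correctly.
* **Clustering families.** The default nodal clustering is the
  geometric-mean (Onnela-family) triangle intensity with weights
  rescaled by the graph maximum; a probabilistic generalization
  (weights as connection probabilities) is selectable as
  `clustering_family = "prob"` and is used consistently for local
  efficiency. Both reduce exactly to the binary coefficients on 0/1
  weights; the family in use is recorded in outputs.
* **Global betweenness** is the mean of nodal betweenness (max
  selectable); the aggregation is a reporting convention, not a
  statistical claim.
* **Null normalization** permutes the complete upper triangle including
  zero weights (zeros are part of the weight distribution), aggregates
  by the ensemble mean (median selectable), and normalizes the four
  global measures only — nodal measures stay raw, matching how nodal
  results are reported (hub frequencies, not normalized nodal values).
  If a null aggregate is exactly 0 while the raw value is also 0 (a
  uniform-weight graph's betweenness), the ratio is defined as 1; a zero
  aggregate with a nonzero raw value is reported as undefined. Each
  subject gets an independent ensemble seeded from the master seed plus
  the subject index.
* **Hub criteria** use strict inequality against the 80th/20th
  percentile (type-7 quantiles), so an all-tied graph has no hubs and,
  for 45 tie-free values, exactly 9 nodes hit each criterion.
  Betweenness can tie exactly (it is a sum of path-count fractions), in
  which case fewer than 9 hit. The "highest degree" criterion is
  evaluated on strength: a partial-correlation graph is complete, so
  binary degree is constant and uninformative.
* **Modularity search.** Newman spectral bisection (exhaustive
  bisection below 13 vertices, leading-eigenvector plus Kernighan–Lin
  otherwise) with recursive subdivision under the generalized modularity
  matrix, followed by greedy node-move/merge refinement; small graphs
  additionally get a two-eigenvector multiway seed, an agglomerative
  start and full Kernighan–Lin passes that accept tentative
  non-improving moves. The procedure is deterministic — ties break by
  index order — and matches exhaustive partition enumeration on every
  random graph of up to 8 nodes in the test suite.
* **Group-level "hubs versus equivalent random networks"** are reported
  as nodes whose within-group hub frequency exceeds the mean + 2 SD of
  per-node hub frequencies under one subject-matched weight-permutation
  null per subject. This is one defensible operationalization of a
  procedure whose exact form is underdetermined; the output labels it
  as interpretive. Group-level modularity tables use the Newman
  partition of the group-mean weight matrix.
* **Statistics.** Welch t (never pooled-variance) for group comparisons
  of normalized measures; Kruskal–Wallis with the χ² approximation for
  descriptives; Fisher exact (two-sided by probability summation) for
  hub and co-module frequencies; Spearman with tie-corrected ranks for
  symptom associations in patients only; ANCOVA `measure ~ group + z +
  group:z` with the covariate standardized and a normality gate
  (|skewness| > 1 or Shapiro p < 0.05 on residuals) triggering Box-Cox
  transformation (profile likelihood on λ ∈ [−3, 3], step 0.01);
  Benjamini–Hochberg FDR within each reporting family (4 global
  measures; 45 hub tests; 990 pair tests; symptom-association family).
  Degrees of freedom are always reported.

## Validation design and problem sizes

The test suite validates every estimator against an independent oracle
implemented differently: Floyd–Warshall and exhaustive path enumeration
for distances and betweenness (200 random graphs of ≤ 8 nodes), triple
enumeration for clustering, exhaustive set-partition search for
modularity, hypergeometric enumeration for Fisher (all
2×2 tables with margins ≤ 12), the step-up recursion for FDR, and
rank-then-Pearson for Spearman. Monte-Carlo checks use $T = 5000$
volumes for covariance recovery and 1000 simulated cohorts of 30 + 30
subjects for the type-I calibration and interaction-power properties;
the calibration simulators operate on the statistical layer directly
(Gaussian measures and covariates), which is the quantity those
properties concern. Full-pipeline tests run on compact cohorts (12
nodes, 180 volumes, ensembles of 20–100 nulls) — sizes chosen so the
entire suite exercises every stage end to end in well under two minutes
while the dedicated 45-node, 1000-null ensemble is timed explicitly.

With the stated calibration parameters (slope gap 0.5 SD, noise SD 1,
29 within-group degrees of freedom per slope), the noncentrality of the
interaction test is ≈ 1.9 against a critical t of ≈ 2.0, putting its
theoretical power near 47%; the measured power over 1000 cohorts is
0.455. This is a property of the stated effect size, not of the
implementation — the same test reaches > 90% power at a 1.5-SD gap, and
its type-I error is calibrated (0.051 at nominal 0.05).

## Known limitations

* The pipeline starts at ROI time series; spatial preprocessing
  (realignment, normalization, segmentation) is out of scope, and the
  optional NIfTI extraction helper assumes already-aligned grids.
* The generator's Gaussianity means heavy-tailed BOLD artifacts,
  physiological oscillations and distance-dependent motion artifacts are
  not represented; censoring-threshold behaviour is exercised by planted
  spikes only.
* Weight-permutation nulls preserve the weight multiset but not degree
  or strength sequences; they answer "is the weight placement
  organised?", not "is the topology unusual given node strengths?"
  (Maslov–Sneppen rewiring is deliberately not implemented).
* Cohorts are analysed separately by design; no cross-cohort pooling or
  mixed-effects model is provided.
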