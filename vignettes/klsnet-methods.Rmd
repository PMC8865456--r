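---
title: "Individual metabolic connectivity networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual metabolic connectivity networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(klsnet)
```

## The model

Group-level metabolic connectivity correlates regional FDG-PET uptake
*across* subjects, so it cannot produce a network for an individual. klsnet
implements the alternative single-subject construction: two brain regions
are considered strongly connected when the *distributions* of voxel
intensities inside them are similar. Concretely, for each parcel $p$ of an
atlas the voxel intensities (normalized to the grey-matter mean) are
summarized by a probability density $P_p(x)$ estimated on one standardized
grid shared by all parcels and subjects. The edge weight between parcels $p$
and $q$ is the Kullback–Leibler similarity

$$\mathrm{KLS}(P,Q) = e^{-D_{KL}(P,Q)}, \qquad
D_{KL}(P,Q) = \int_x \left( P(x)\log\frac{P(x)}{Q(x)}
 + Q(x)\log\frac{Q(x)}{P(x)} \right) dx,$$

the symmetrized KL divergence. Identical densities give weight 1; strongly
divergent ones give weights near 0. The resulting matrix is undirected,
fully weighted and never thresholded or binarized; all graph metrics operate
on the complete weighted graph.

The assumptions worth keeping in mind:

* a parcel's voxel intensities are treated as an i.i.d. sample from a
  smooth univariate density — spatial autocorrelation within the parcel is
  ignored;
* similarity of intensity distributions is taken as the operational
  definition of metabolic connectivity; homogeneous uptake across regions
  therefore reads as high connectivity;
* comparability across parcels and subjects rests on the shared
  standardized grid and on grey-matter-mean normalization.

## Density estimation

Each parcel's density is a Gaussian-kernel KDE evaluated on the
standardized grid, computed by linear binning of the sample onto the grid
followed by discrete Gaussian smoothing — the same histogram-plus-smoothing
strategy used by diffusion-KDE tools, accurate here because bandwidths
exceed the grid spacing. After smoothing, each density is renormalized so
its trapezoidal integral over the grid is exactly 1; kernel mass falling
outside the grid is thereby folded back in and the probability axioms
required by the divergence are guaranteed regardless of truncation.

The bandwidth is selected per parcel by the diffusion (Botev) plug-in: the
sample is histogrammed on a dyadic grid over its own slightly expanded
range, transformed by a DCT, and the squared bandwidth solves the fixed
point $t = \xi\gamma^{[\ell]}(t)$ with the customary $\ell = 7$ stages. The
root is bracketed by a geometric scan and bisected to a relative tolerance
of $10^{-9}$; if no bracket is found (e.g. pathological samples) Silverman's
rule $1.06\,\hat\sigma N^{-1/5}$ is used instead and the fallback is
recorded. The selector is deterministic given the sample.

Tunables, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| grid range | [0, 3] | normalized-uptake units; covers plausible GM-normalized uptake |
| grid points | 256 | balances KDE resolution against integration noise |
| `min_voxels` | 800 | parcels with fewer voxels give unstable PDFs and are excluded (reported, and excluded cohort-wide so all matrices share one node set) |
| `epsilon` | 1e-12 | density floor before logs; keeps divergences finite and weights strictly positive |
| bandwidth | `"botev"` | `"silverman"` available as a sensitivity switch |

The exact histogram range and bin size behind the published analyses are
not stated there; [0, 3] with 256 points is this package's choice and both
are configurable. Normalization "to grey matter" is implemented as division
by the pooled mean over retained parcels' voxels (the atlas defines grey
matter here), applied after parcel exclusion.

## Graph metrics

Edge lengths for path-based metrics are $\ell_{ij} = 1/w_{ij}$ (the
brain-connectivity-toolbox convention; $-\log w$ was rejected because
weights of exactly 1 would create zero-length edges). On this graph:

* **mean connectivity strength** — average weight over node pairs within a
  scope, or across two scopes for between-network strength (diagonal always
  excluded);
* **characteristic path length** — mean shortest distance over ordered
  pairs (Dijkstra on $1/w$); subnetwork values use the induced submatrix;
* **clustering coefficient** — Onnela geometric-mean form on max-normalized
  weights, so $C_i \in [0,1]$;
* **local efficiency** — efficiency of each node's neighbour subgraph with
  distances computed inside that subgraph;
* **betweenness centrality** — Brandes accumulation on $1/w$, endpoints
  excluded;
* **degree** — implemented as strength (sum of weights): on a complete
  weighted graph the binary degree is constant and uninformative.

The exact weighted clustering/efficiency variants cited in the source
literature are not spelled out there; the Onnela and Rubinov–Sporns forms
are adopted, and both are validated against brute-force
(Floyd–Warshall, triple-loop, path-counting) oracles in the test suite.

**Hubs.** A node is scored on four criteria — top 20% highest degree,
lowest nodal path length, lowest clustering, highest betweenness — and is a
hub when it meets at least two. Each criterion flags exactly
$\mathrm{round}(0.2\,n)$ nodes (half away from zero), with ties at the
cutoff broken by ascending node order so results are deterministic. Hub
sets are invariant under uniform weight rescaling. The 0.80 edge threshold
exported for connectome visualization keeps edges with weight $\ge 0.80$
and is never used in any metric.

## Aging analysis

Every metric in every scope is regressed on age with both a linear and a
quadratic model (OLS). The quadratic term is kept only when the
extra-sum-of-squares F test

$$F = \frac{SSE_{lin} - SSE_{quad}}{SSE_{quad} / (n-3)}$$

is significant at $\alpha = 0.05$; if both models interpolate exactly the
simpler linear model is retained. The chosen model is reported with its
overall p, the multiple correlation $r = \sqrt{1 - SSE/SST}$, its
predictions at 20 and 80 years and the lifespan change
$100\,(\hat Y(80)-\hat Y(20))/\hat Y(20)$. Rows with overall $p \ge 0.05$
are printed as "/" with predictions withheld. No multiple-testing
correction is applied, mirroring the per-test $\alpha$ convention of the
source analyses. Report rounding (2 decimals for predictions, 1 for
percentages, halves away from zero) happens only at the report layer;
internal values keep full precision.

One statistical subtlety is made explicit: because model selection tries
two nested models, the chosen-model p-value has a null false-positive rate
of roughly 7–8%, not 5%. Null behaviour of the pipeline (e.g. in the
phantom validation below) is therefore judged on the *linear slope test*,
whose rate is the nominal 5%, while the report keeps the selected-model
convention used in published tables.

Age groups for hub-count comparisons are age-sorted tertiles with sizes as
equal as possible and the remainder assigned from the oldest group down
(67 subjects → 22/22/23). The published analyses never state their age
cutoffs; explicit cutoffs can be supplied instead. Between-network analysis
covers the $\binom{8}{2} = 28$ pairs of the eight named networks.

## The phantom generator

Real cohort data behind the published results are not publicly available,
so validation uses synthetic phantoms whose ground truth is known:

* the atlas is a 100-parcel, 8-network layout (frontoparietal 4, visual 13,
  somatomotor 14, dorsal attention 13, ventral attention 14, limbic 5,
  control 16, default mode 21), each parcel a contiguous block of exactly
  800 voxels — geometry is irrelevant because no metric uses spatial
  adjacency;
* voxels of parcel $p$ are drawn from
  $N\!\big(1 + (\delta_p + \varepsilon_p)\, s_g(\mathrm{age}),\ \sigma_p\big)$
  truncated at 0 by redrawing (clipping would put a point mass at 0 and
  distort the KDE), then the volume is recentred to a global labelled mean
  of 1;
* $\delta_p \sim N(0, 0.05)$ are fixed per-atlas parcel offsets,
  $\sigma_p = 0.1$, and $\varepsilon_p \sim N(0, 0.008)$ is a small
  subject-level perturbation providing inter-subject variability of the
  regional pattern. Without it the cohort regressions would have
  implausibly small residuals and the F selection would latch onto the mild
  curvature that the exponential KLS mapping imprints on any linear
  dispersion trend. The magnitude is a design choice: the published work
  reports no inter-subject variance components, so the generator is
  calibrated only to produce detectable trends at $n = 67$, not to match an
  unpublished covariance structure;
* aging enters through the network-wise dispersion scaling $s_g$: `none`
  (constant), `linear` ($s = a + b\,\mathrm{age}$) or `quadratic`. Growing
  $s$ pulls parcel means apart, which raises pairwise divergence and lowers
  KLS strength — for equal variances the analytic symmetric KL between two
  parcels' generating Gaussians is $(\Delta\mu/\sigma)^2$, which is the
  oracle used throughout the tests. Defaults grow $s$ from 1 at age 20 to
  1.3 at age 82 (linearly, or purely quadratically with the same
  endpoints), giving baseline within-network strengths around 0.5–0.7 and
  lifespan strength declines of roughly 8–18%, comparable in magnitude to
  published values. The default network assignment is linear decline in
  default mode, control, dorsal and ventral attention, quadratic in
  frontoparietal, and no effect in somatomotor, limbic and visual.

What the phantom does *not* emulate: scanner physics, partial-volume
blurring, spatial smoothing, anatomical geometry, non-Gaussian intensity
distributions, and any realistic between-subject covariance of regional
uptake. Passing phantom tests therefore demonstrates that the pipeline
recovers the statistical structure it assumes — not that real data meet
those assumptions.

## Numerical choices

* Divergences integrate $ (P-Q)(\log P - \log Q)$ by the trapezoidal rule
  on the standardized grid after flooring both densities at `epsilon` and
  renormalizing; the floor choice is recorded in every matrix's metadata.
* Matrix assembly uses the expansion
  $D_{ij} = S_i + S_j - C_{ij} - C_{ji}$ with
  $S_i = \int P_i \log P_i$ and $C_{ij} = \int P_i \log P_j$ (one matrix
  product per subject); the combination is ordered so the result is
  bit-exactly symmetric, tiny negative divergences from rounding are
  clamped to 0, and the diagonal is fixed at 1 and excluded from every
  average.
* Degenerate inputs fail loudly: constant samples (no bandwidth), samples
  entirely outside the grid, non-positive weights in path metrics,
  singleton scopes, rank-deficient regressions.

## Problem sizes used in validation

The test suite exercises the full study-scale configuration where the
claims require it: the parameter-recovery check runs 50 cohorts of 67
subjects on the full 100-parcel, 800-voxel atlas; the quadratic-preference
check uses 15 cohorts on a 26-parcel atlas and the null-cohort check 50
cohorts on a 16-parcel atlas (both still $n = 67$) so the whole suite stays
affordable; metric oracles run on 100
random 6–10-node graphs. A single-subject 100-parcel analysis (density →
network → metrics) takes a few seconds.

## Limitations

* The KLS weight compares whole distributions but, like the underlying
  method, cannot distinguish which moments differ between parcels.
* The standardized grid and `min_voxels` threshold are analysis choices
  that must be held fixed across subjects for comparability.
* The significance conventions replicate per-test $\alpha = 0.05$
  reporting; with 37 scopes × 4 metrics, a corrected analysis (switchable)
  is stricter.
* Phantom-based power statements do not transfer to real cohorts whose
  inter-subject variance is unknown.
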