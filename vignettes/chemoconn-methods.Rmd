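---
title: "Methods: weighted connectome and cohort analysis for a mouse chemobrain model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted connectome and cohort analysis for a mouse chemobrain model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoconn)
```

# Scope

`chemoconn` implements the computational chain of a chemotherapy-induced
cognitive impairment ("chemobrain") study in mice: weighted functional
connectomes built from regional resting-state time series and their
graph-theoretic summary; group inference with a network-density covariate;
scoring of the three cognitive tests (puzzle box, novel object/place
recognition, Y-maze); and the bioenergetic, morphometric, tumor-growth and
transcriptomic endpoints. A synthetic cohort generator produces every input
the pipeline consumes, with known injected group effects, so that the whole
chain can be exercised and validated without animal data.

# The connectome pipeline

## From time series to a weighted network

Each subject contributes a timepoints-by-regions matrix (62 regions and 450
volumes at TR = 2 s in the original acquisition). The analysis restricts
the signal to the low-frequency band below 0.1 Hz, where intrinsic
functional networks live. `lowpass_restrict()` implements this as a
moving-average smoother whose window spans one period of the cutoff,
`ceiling(1 / (cutoff_hz * tr_seconds))` samples (5 samples at TR = 2 s).
No specific filter is prescribed for this step by common practice, only the
band; a boxcar is the simplest length-preserving choice, and edges use
partial windows so constant signals pass unchanged. The cutoff must lie
below the Nyquist frequency `1/(2 TR)`.

`correlation_matrix()` computes the Pearson correlation of every region
pair. The diagonal is stored as 0, never 1: self-edges must not enter edge
counts, density, or clustering. `to_weighted_network()` zeroes negative
correlations — negative-correlation networks have different properties and
are excluded from this analysis — and keeps all positive weights with no
magnitude threshold, giving a fully weighted network with density
`D = E / [N (N - 1) / 2]`.

## Graph measures

* **Nodal clustering** uses the geometric-mean-of-triangle-weights
  (Onnela) formulation on weights normalized by the maximum weight, the
  default of the standard brain-connectivity toolboxes. Other weighted
  clustering variants produce different absolute values; the normalized
  ratio `gamma` is less sensitive to the choice.
* **Characteristic path length** maps each weight to a length `1/w`
  (stronger connections are shorter), computes all-pairs shortest paths
  (Dijkstra in compiled code), and averages the finite off-diagonal
  distances. Disconnected pairs are excluded from the mean and reported as
  a count rather than forcing L to infinity on sparse networks.
* **Global efficiency** is the mean inverse distance over ordered pairs
  (`1/Inf = 0`); **local efficiency** averages the global efficiency of
  each node's neighborhood subgraph, with nodes of fewer than two
  neighbors contributing 0.
* **Null models**: the normalization references are degree-preserving
  double-edge-swap randomizations of the binary topology with the original
  weights reshuffled among the surviving edges. Node count, edge count,
  density, and the binary degree sequence are preserved exactly. Defaults —
  20 nulls, 10 swap attempts per edge — are unstated in the source study
  and therefore configurable and recorded in every `global_metrics`
  result. `gamma = C / C_rand`, `lambda = L / L_rand`,
  `sigma = gamma / lambda`.
* **Density matching**: regional (nodal) comparisons are run after
  thresholding every subject's network to the density of the sparsest
  subject ("minimum connection density"), retaining the top-weighted edges
  with lexicographic tie-breaking for determinism. This is an
  interpretation — the standard reading that equalizes edge counts across
  subjects before nodal comparison.

## Group inference

Subjects whose small-worldness index is strictly below 1 lack small-world
organization and are excluded with a machine-readable reason (a subject at
exactly 1 is included). Because individual variation in network density
affects every other connectome property, group comparisons of global
metrics use an ordinary-least-squares model `metric ~ group + density`,
with the categorical group term tested by the extra-sum-of-squares F
against the density-only model — matching the single F per metric that the
study reports. Regional clustering is compared per region by a two-sided
Wilcoxon rank-sum test, exact for small samples without ties and
tie-corrected normal otherwise, with raw per-region p-values by default
(the original regional table reports raw p in the 0.01–0.05 range);
Benjamini–Hochberg adjustment is available but off by default. Behavioral
and assay endpoints use the 2x2 factorial ANOVA (chemotherapy x treatment)
with Tukey honest-significant-difference contrasts for all six cell pairs.

# Behavioral scoring

* **Puzzle box**: the fixed 11-trial schedule spans 4 days and 3
  difficulty tiers (trials 1–4 easy, 5–7 intermediate, 8–11 difficult, with
  days 1–3 holding three trials each and day 4 two). Escape times are
  summarized per subject and tier; per-trial values are preserved because
  it is not fully specified whether the original contrasts used per-trial
  repeated measures or tier means, so both exports are provided. No
  escape-time ceiling is imposed.
* **Novel object/place recognition**: discrimination index
  `(T_novel - T_familiar) / (T_novel + T_familiar)`, bounded in [-1, 1],
  0 meaning no novelty preference; total interaction time is the
  motivation control. A trial with zero total time is surfaced as a
  flagged undefined value, not silently dropped.
* **Y-maze**: a perfect alternation is a run of three consecutive arm
  entries visiting all three arms. The denominator is the overlapping
  window count `entries - 2` — the standard spontaneous-alternation
  convention; the source defines only the numerator event. Sequences
  shorter than 3 entries are flagged undefined. Chance level is 50% for
  memoryless no-repeat arm choice, which the test suite verifies by
  simulation.

# Assay endpoints

Mitochondrial stress-test traces carry four phases (baseline, oligomycin,
FCCP, rotenone + antimycin A). All values are corrected for
non-mitochondrial oxygen consumption (the post-rotenone/antimycin
plateau); `basal` and `max` are the corrected baseline and FCCP phase
means and spare respiratory capacity is exactly `max - basal`. The phase
summary is the within-phase arithmetic mean by default; the
maximal-FCCP-measurement convention is available as an option but off, for
determinism. Atypical mitochondria are those with width strictly greater
than 300 nm AND opacity strictly below 50%. Tumor volume is the ellipsoid
formula `(pi/6) d1 d2 d3` from three mutually orthogonal diameters.
Differential-expression reversal logic intersects the significant sets of
the two contrasts at adjusted p < 0.05 (no fold-change cutoff — the source
states none) and splits the overlap into up-reversed, down-reversed, and
same-direction genes; the three parts partition the overlap exactly.

# The synthetic cohort: what it emulates and what it does not

`cohort_spec()` states the world: four groups (PBS, Cisplatin, MSC,
Cisplatin+MSC), 8 subjects per group, 62 regions, 450 volumes, TR = 2 s —
the dimensions of the original acquisition. Group labels carry meaning:
`Cisplatin` receives the full injected effect, `Cisplatin+MSC` the effect
scaled by `1 - rescue_fraction` (default 1, i.e. full rescue, which makes
that group's latent structure *identical* to PBS — the observed outcome of
the study), and all other labels none.

## Latent connectome structure

Control subjects are drawn from a correlation structure built on a
Watts–Strogatz small-world backbone (6 neighbors, rewiring probability
0.02) with uniform(0.35, 0.85) edge weights, plus a weak uniform background
anticorrelation (-0.04) on all non-backbone pairs. The covariance is the
Gram construction `(I + 0.7 (W + eps0 C))^2 + 0.25 I`, positive definite by
construction, yielding backbone correlations of roughly 0.3–0.7 (the range
of strong resting-state functional edges), genuine weaker two-hop
correlations, and negative background correlations such as denoised
resting-state matrices show. After the pipeline zeroes negative edges, the
measured networks have density near 0.37 and small-worldness sigma between
about 1.0 and 1.25, so control subjects pass the sigma >= 1 inclusion rule
while occasional subjects fall just below it — as happened to two animals
in the original cohort.

The cisplatin effect is injected as strong (weight 0.95) cross-links
placed greedily between the currently most *distant* region pairs —
aberrant long-range couplings between normally segregated systems, the
Watts–Strogatz shortcut move toward a more random, noisy, hyperconnected
network. Links are added one at a time until the **measured** path length
falls by `path_length_effect` (default 0.15) relative to controls. Two
choices deserve emphasis:

* **Calibration targets the measured, not the latent, metric.** With 450
  band-limited volumes the sampling noise of a single correlation is about
  0.09, and spurious positive edges floor the measured path length; an
  effect injected only into the unobservable latent metric is partially
  compressed on the way to the estimate. The generator therefore evaluates
  the expected measured path length by a small common-random-number Monte
  Carlo proxy (3 pseudo-subjects, deterministic given the seed) and
  calibrates the link count against it. The injected "15%" is thus a 15%
  shift of the quantity the pipeline actually measures, which is what any
  power statement about the pipeline refers to.
* **Far-pair placement keeps the effect off the density axis.** Greedy
  farthest-pair placement makes each link maximally effective, so only a
  handful (typically 3–20 out of ~1,900 possible pairs) are needed and the
  group difference in measured density stays well below the
  density–path-length coupling induced by sampling noise. This matters
  because the downstream GLM covaries density: an effect carried by edge
  count alone would (correctly) be absorbed by the covariate.

Link sequences are nested, so a partially rescued group uses a prefix of
the full-effect sequence and `rescue_fraction = 1` reproduces the control
structure exactly. Subject draws are temporally smoothed with the same
moving-average window the analysis uses, so the signal is band-limited
below 0.1 Hz. Identical specs produce byte-identical cohorts, and the
generator restores the caller's RNG state.

The generator does **not** emulate: spatial structure or atlas geometry,
scanner physics, motion or physiological artifacts, subject-level
variation in the latent network (all subjects of a group share one latent
structure; between-subject variance is purely sampling noise), or
hemispheric/homotopic organization. A green pipeline test therefore
establishes that the statistical machinery recovers a known effect under
idealized sampling — not that the effect size or variance components match
real mouse data.

## Behavioral and assay effects

Stated world for the remaining endpoints (values chosen once as typical of
the rodent literature, since the source reports figures, not parameters):
log-normal escape times with tier medians 15/40/80 s and an additive 60 s
cisplatin delay on difficult trials only; gamma interaction times with the
control discrimination index centered at 0.3 and cisplatin at 0 (no
novelty preference); Y-maze sequences from a no-immediate-repeat Markov
walk completing alternations with probability 0.7 in controls and 0.5
(chance) under cisplatin; OCR phase means 100/40/180/15 with a 55-unit
cisplatin drop of the FCCP plateau only (basal unaffected — the pattern of
the source's 48-h data); mitochondrial atypia fractions 8% versus 35%;
tumor growth 10%/day versus 4%/day under cisplatin with MSC having no
effect on tumors; and differential-expression tables constructed with
exactly 45 up-reversed, 30 down-reversed and 30 same-direction overlapping
significant genes (the structure of the reported 105-gene overlap), plus
285 cisplatin-only, 1230 MSC-only and 200 null genes to mirror the
reported 390- and 1335-gene contrast sizes. `rescue_fraction` moves every
Cisplatin+MSC effect linearly back toward the control value.

# Numerical choices and degenerate inputs

Weight-to-length mapping is the reciprocal (toolbox convention). Density
thresholding breaks weight ties by lexicographic node-pair order, making
it deterministic. Null-network generation is seeded and never perturbs the
caller's RNG. A correlation matrix with a zero-variance region raises an
error naming the region. An empty network has efficiency 0; a network with
no connected pair has undefined path length (an error, since L cannot be
reported). The discrimination index with zero total time and alternation
scores with fewer than 3 entries are flagged undefined and excluded
listwise from factorial ANOVA. The rank-sum test is exact whenever both
groups have fewer than 50 observations and no ties occur, which covers the
cohort sizes of interest.

# Known limitations

* The absolute values of weighted clustering and sigma depend on the
  chosen clustering variant and null model; only the conventions above are
  implemented, configurable where the source is silent.
* The generator's between-subject variance is sampling-only, so pipeline
  power estimates are upper bounds relative to real cohorts with
  biological heterogeneity.
* The measured-scale calibration ties the injected connectome effect to
  the default analysis settings (0.1 Hz cutoff, moving-average smoother);
  analyzing synthetic cohorts with different settings will recover a
  slightly different effect size.
* Real-data headline statistics of the source study (its F and p values,
  regional tables, group means) derive from real animals and are not
  reproducible from synthetic data; the package validates formulas,
  invariants, and recovery of known injected effects instead.
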