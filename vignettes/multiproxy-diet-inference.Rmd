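---
title: "Multi-proxy dietary inference for fossil birds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-proxy dietary inference for fossil birds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleotroph)
```

## The problem

The diet of an extinct bird cannot be observed, but several independent
anatomical systems record it indirectly: body size constrains what a bird can
profitably eat; the shape of the pedal claws records how (and whether) the
feet were used on prey; the lever geometry of the jaw records how forcefully
and how quickly it could close; and the distribution of strain in a loaded
jaw model records what the jaw could withstand. `paleotroph` implements each
of these proxies as a quantitative pipeline against a reference sample of
living birds of known diet, and combines the per-proxy predictions into
likely and unlikely diet sets for fossil taxa. Because living species are
related, every comparative statistic in the package can condition on a
time-calibrated phylogeny through the Brownian-motion covariance matrix.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, what the synthetic-data generators do and do
not emulate, and the package's known limitations.

## Phylogenetic machinery

Trees are `ape` `"phylo"` objects read from Newick text (`read_newick()`),
with two invariants enforced at the boundary: unique tip labels, and strictly
positive branch lengths. Zero or missing branch lengths are replaced by
`1e-8` Ma (configurable) because the Brownian covariance must remain positive
definite: the phylogenetic GLS mean, the K statistics, and the pFDA whitener
all invert it.

`bm_covariance()` returns the matrix \(C\) with \(C_{ij}\) the shared
root-to-MRCA path length and \(C_{ii}\) the root-to-tip distance — the
trait covariance, up to a rate constant, under Brownian motion. Two details
matter:

* `prune_to()` keeps the path from the original root to the retained clade's
  MRCA as a *root edge*, and `bm_covariance()` adds it to every entry. This
  makes pruning commute with taking the covariance submatrix, so statistics
  computed on a pruned tree equal those computed on the full tree restricted
  to the same taxa.
* `graft_fossil_tips()` works in absolute ages (Ma before present, with the
  deepest host tip as the present). Fossil tips terminate at their own ages;
  divergences inside a grafted clade are spaced by a configurable duration
  defaulting to 0.001 Ma (a thousand years), the convention for fossils whose
  internal divergence times are unknown. `scale_clade_depth()` rescales a
  clade (for instance, the crown-bird portion of a supertree to a 94 Ma
  depth) linearly, leaving the rest of the tree untouched. The order in which
  grafting and scaling are applied is a modelling choice the package does not
  impose: both operations are exposed separately and compose in either order.

## Phylogenetic signal: K and its multivariate extension

For a single trait \(y\) on \(N\) tips, Blomberg's
\[
K \;=\; \frac{(y-\hat a)'(y-\hat a)\,/\,(y-\hat a)'C^{-1}(y-\hat a)}
             {\bigl(\operatorname{tr} C - N/\mathbf 1'C^{-1}\mathbf 1\bigr)/(N-1)},
\]
with \(\hat a\) the phylogenetic GLS mean, equals 1 in expectation under
Brownian motion and exactly 1 on a star phylogeny. The multivariate statistic
sums squared deviations across trait columns in both the numerator and the
\(C^{-1}\)-weighted denominator; for a single column it reduces to \(K\)
exactly, which the tests assert to \(10^{-10}\). Significance comes from
permuting rows of the data across tips; p-values use the
\((1+\#\{K^\ast \ge K\})/(1+n_{\mathrm{perm}})\) convention, so they are
never zero and never smaller than \(1/(1+n_{\mathrm{perm}})\). The default
1,000 permutations follow common practice in the field.

## Pairwise comparison of group means

`phylogenetic_hsd()` is a residual-randomization permutation test: data and
design are premultiplied by \(C^{-1/2}\), group least-squares means are
estimated by ordinary least squares in the transformed space (i.e.
phylogenetic GLS), and the statistic for each pair of groups is the Euclidean
distance between their mean vectors. The null distribution comes from
randomizing residuals of the *intercept-only* reduced model — the standard
choice when the effect under test is the whole group structure, and the one
used here since nothing in the procedure's definition requires full-model
residuals. \(C^{-1/2}\) is computed by symmetric eigendecomposition rather
than Cholesky so the transform does not depend on taxon ordering. Groups with
a single member carry no within-group information and are dropped with a
warning. With \(C = I\) the procedure reduces to an ordinary permutation
test of mean differences, which the test suite verifies against a
brute-force implementation. No multiple-testing correction is applied beyond
the raw pairwise permutation p-values. `tukey_hsd()` provides the classical
studentized-range analogue on a one-way layout for side-by-side reporting.

Calibration is checked by simulation: with no group effect and data drawn
under the assumed Brownian model on a fresh random tree per replicate, the
empirical type-I rate at \(\alpha = 0.05\) sits near nominal (the acceptance
suite requires it in \([0.02, 0.08]\) over 200 replicates). The Brownian
null is the right design here: feeding the transform data that violate its
covariance assumption yields arbitrarily mis-calibrated rates, which is a
property of GLS itself, not of the permutation scheme.

## Ordination: PCA, FDA, pFDA

All ordinations follow one hard rule: **fossils never influence the fitted
transform**. Fitting functions refuse rows flagged as fossil; `project()` and
`discriminant_predict()` apply the extant-fitted transform to new rows, so
adding or removing fossils cannot change the model.

`pca_correlation()` z-scores by the extant means and standard deviations and
eigendecomposes the correlation matrix, which puts variables measured in
degrees, ratios and percentages on the same scale. The stored transform
projects fossils independently; projecting the extant centroid gives the
origin.

`fda_fit()` implements flexible discriminant analysis in its canonical,
non-penalized form: optimal scoring with a linear regression backend. Class
indicator columns are regressed on the predictors; the non-trivial
eigenvectors of the resulting class-space problem give at most
\(J-1\) discriminant directions, ordered by discrimination. The trivial
constant-score direction is removed by exact deflation (subtracting the
known rank-one component) rather than by numerical detection, which matters
when classes are perfectly separable and eigenvalues collide at 1. The
discriminant variates are then whitened against the pooled within-class
covariance, which makes Gaussian posteriors in discriminant space —
\(\Pr(g \mid x) \propto \pi_g \exp(-\tfrac12\lVert z(x)-\mu_g\rVert^2)\) —
coincide with the classical linear discriminant rule when its assumptions
hold; the suite requires at least 98% agreement with an independent LDA
implementation on shared-covariance Gaussian data. Priors default to the
training class proportions and are configurable to equal; this choice
affects fossil posteriors and is therefore an explicit, stored model field.
Argmax ties break toward the first class in sorted label order.

`pfda_fit()` adds phylogenetic GLS to FDA. The Brownian covariance has its
off-diagonal entries scaled by Pagel's \(\lambda\); the resulting
\(C(\lambda)\) is normalized to unit mean self-variance and its symmetric
inverse square root is applied to the extant predictor rows before the FDA
fit. The normalization is a deliberate design choice: it makes
\(\lambda = 0\) on an ultrametric tree give an exactly-identity whitener, so
pFDA degenerates to plain FDA bit-for-bit (and likewise for \(C = I\)),
and it keeps the scale of whitened extant rows commensurate with fossil
rows. Fossils have no row in the extant covariance and no principled
whitener; they are projected with *unit self-variance* — their raw values
pass through the extant-fitted centering and axes with no phylogenetic
transform. This is an approximation, stated here openly: it treats each
fossil as phylogenetically independent with unit variance, which is exactly
right at \(\lambda = 0\) and increasingly approximate as \(\lambda \to 1\).

\(\lambda\) is chosen by `optimal_lambda()`: for each grid value (default 0
to 1 in steps of 0.01) the Brownian GLS log-likelihood of each predictor
column is computed with the mean and rate profiled out analytically, summed
across columns, and maximized; ties break toward the smaller value. This is
the standard profile approach for Pagel's \(\lambda\); recovery simulations
in the acceptance suite require the correct extreme (\(0\) or \(\ge 0.7\))
to be selected in at least 80% of replicates under data simulated at
\(\lambda \in \{0, 1\}\).

## Body mass

`estimate_log_mass()` evaluates a published regression from six log10
skeletal measurements to log10 body mass and is deliberately nothing more:
the coefficients are data, not estimated here. The measurement fields are
log10 millimetres and the output log10 grams, a units convention inherited
from the source regression rather than restated by this package — the
intercept check (all predictors zero gives \(-2.626\)) is unit-free.

`youden_cutpoint()` chooses the threshold between two groups (typically
log10 masses of two lumped diet pools) by exhaustively scanning the
midpoints of adjacent sorted pooled values and maximizing Youden's
\(J = \text{sensitivity} + \text{specificity} - 1\), with the larger-mean
group as "positive" and ties broken toward the smaller threshold for
determinism. The lumping maps follow the two contrasts used for bird diets:
invertivores against vertivores (piscivores, scavengers, tetrapod hunters),
and folivores + frugivores against granivores + nectarivores. Thresholds are
reported both in log10 grams and back-transformed to grams.
`classify_by_mass()` then compares a fossil's mass *interval* to each
cut-point, returning "inconclusive" whenever the interval straddles it —
point estimates of fossil mass are rarely honest.

## Claw morphometrics

The claw proxy reduces each ungual to its outer arc, operationalized as
three planar landmarks (base, midpoint, tip) through which a unique circle
is fitted. Curvature is the central angle of the base-to-tip arc passing
through the midpoint, in degrees; arc length is \(r\theta\). This
three-point scheme is the minimal faithful reading of the landmark protocols
used in the field (which this package does not re-derive from photographs),
and it is exactly invertible — `claw_from_parameters()` constructs landmarks
from a given angle and radius, giving sharp round-trip oracles down to
half-degree arcs. Near-collinear landmark sets (circumradius above
\(10^6\times\) the chord) are treated as collinear: zero curvature, chord
length. Both quantities are invariant to similarity transforms of the
coordinates, so digitization scale and orientation never matter. The
assembled record per specimen is the 7-variable set — four curvatures plus
the arc lengths of digits I, II and IV as ratios to digit III — with
incomplete specimens flagged rather than silently dropped or imputed, since
fossils commonly preserve only some digits. Precomputed curvature/length
values are accepted in place of landmarks.

## Jaw mechanics

All jaw quantities are ratios of linear measurements, so no absolute scale
is ever required. `jaw_indices()` computes anterior/posterior closing and
opening mechanical advantage for the upper and lower jaw (in-lever over
out-lever about the articulation) and the size-free shape indices: articular
offset over lower-jaw length, average cranium height over an explicit
cranium-length denominator field (the denominator is data, not a hidden code
choice), and maximum/average mandibular height over lower-jaw length.
Missing fields degrade index-by-index. `quadrate_sensitivity()` re-measures
every lever from alternative articulation points — typically the extreme
anterior and posterior ends of the preserved articular surface — with the
muscle insertions and bite points fixed, quantifying how sensitive
diet-relevant indices are to uncertainty in quadrate position.

## Finite-element strain: the intervals method

A solved FE model enters the package as a table of element areas and maximum
in-plane principal strains (microstrain). Model construction and solving are
upstream and out of scope; strain values are comparative quantities only,
meaningful among models built under the same assumptions.

Two summaries are computed. The mesh-weighted arithmetic mean (MWAM),
\(\sum \epsilon_i a_i / \sum a_i\), is a scalar jaw-strength summary bounded
by the element extremes. The intervals method represents each model as the
percentage of its area falling in each of \(N\) equal-width strain
intervals spanning the pooled \([\min,\max]\) of *all* models — shared bins
are required for comparability — with the top bin closed (optionally open
above the range). The interval count is chosen by convergence testing:
\(N\) increases stepwise, at each step the compositions are imputed,
ilr-transformed and ordinated, and the search stops when the Pearson
correlation between consecutive pairwise-distance matrices reaches a
threshold (default 0.99), returning the earlier count of the converged pair.
Zero-variance distance matrices (identical models) are defined as converged,
avoiding a 0/0 correlation. The distance-correlation rule itself is this
package's operationalization of "convergence"; published analyses using the
intervals method report only the converged counts, not their rule, so exact
agreement with any particular prior analysis is not claimed.
Non-convergence by `max_n` warns and is reported, never silent.

Interval rows are compositions (non-negative, summing to 100), so Euclidean
statistics apply only after log-ratio transformation, and zeros must be
replaced first. Zero replacement is multiplicative: zeros become
\(\delta = 0.65 \times\) the row's smallest positive part (fraction
configurable), and non-zero parts are rescaled by a common factor so the row
again sums to 100 — preserving all ratios among observed parts. This is a
simplification of the EM-based lognormal expected-value replacement used in
some published workflows; that method requires a fitted lognormal model per
column whose details are not available here, and the multiplicative rule is
transparent and deterministic. One guard applies: if a row has many zeros
and a large minimum part, the nominal \(\delta\) could exceed the row
total, so \(\delta\) is capped such that imputed parts never take more than
half the row's mass. `clr()` is the centered log-ratio
(\(\log x - \overline{\log x}\), rows summing to zero, used for
interpretable variable weights); `ilr()` uses a fixed Helmert-type
orthonormal basis with parts in bin order, so coordinates are bit-exactly
reproducible, and satisfies the isometry (ilr Euclidean distance equals
Aitchison distance) and exact inversion (`ilr_inverse()` after closure)
checked in the tests.

## Diet categories and synthesis

Extant reference diets come from EltonTraits-style percentage columns
through fixed cut-offs: 60% for folivore, frugivore, invertivore,
nectarivore and tetrapod hunter (ectotherm + endotherm summed), 70% for
granivore, 50% for piscivore and scavenger, and "generalist" when no
category exceeds 40%. Because the thresholds sum pairwise above 100, two
rules can only fire together at an exact 50/50 fish/scavenge split; the
higher percentage wins and an exact tie is "unclassified", as is any row
meeting no rule. Behavioral splits (husking versus swallowing granivores,
small- versus large-prey raptors) are observational annotations supplied as
data columns, never computed. Classifier agreement with known diets is
scored by Fleiss' kappa; with exactly two "raters" (predicted and true) a
two-rater kappa would be conventional, but the Fleiss form is implemented as
the field uses it, and the two coincide in structure for the balanced
two-rater case.

`evidence_summary()` operationalizes the final synthesis transparently: a
diet is "likely" under a proxy when its posterior reaches a threshold
(default 0.10, configurable), "agreed" when likely under every proxy whose
category set contains it, and "unlikely" when below threshold everywhere it
is covered. The published syntheses this mirrors are partly editorial
(weighing tooth shape, preserved gut contents, and other qualitative
evidence); the package makes no attempt to replicate that judgment, only to
make the quantitative part reproducible.

## Synthetic data: what it emulates, and what it does not

The generators produce inputs with the statistical structure each stage
assumes: Brownian traits on a tree with tunable \(\lambda\) and rate;
labeled Gaussian classes with shared covariance for the discriminant
stages; diet-stratified log10-normal species masses; and strain fields with
log-normal element areas and strains rescaled so the realized MWAM hits its
target *exactly* (a deliberate choice — exact targets give sharp oracles,
where distributional targets would only give approximate ones). The default
mass generator uses the study design of a broad extant bird sample (141
species in ten diet categories, the category sizes of the reference
dataset) with group means chosen once on the log10-gram scale to reflect
typical adult masses — nectarivores near 20 g, granivores 50–60 g,
invertivores near 80 g, vertebrate-eaters and large herbivores near
800–2000 g — and within-group SD 0.5 log10 units. Pipeline-scale runs use
60 extant taxa, 3 fossils, 150-element meshes and 199–1,000 permutations;
these sizes were chosen so the full test suite and the acceptance script
each run in about a minute while keeping Monte-Carlo error well inside the
asserted bands.

Passing tests on synthetic data show that the machinery is correct — the
statistics are calibrated, the transforms invert, fossils are projected
independently, the pipeline is deterministic under a seed. They do not show
that real measurements are this clean: real claw landmarks carry
digitization error, real masses carry subspecies weighting and sexual
dimorphism, real strain fields have spatially correlated elements and
mesh-refinement artefacts, and real diets are not conditionally Gaussian
given category. Conclusions about any particular fossil require the real
reference datasets.

## Numerical choices and degenerate inputs

* Permutation p-values: observed included, \((1+c)/(1+n)\); never zero.
* \(C^{-1/2}\): symmetric eigendecomposition; errors on eigenvalues below
  \(10^{-10}\times\) the maximum rather than silently regularizing.
* Youden ties: smaller threshold. Argmax ties in classification: first
  class in sorted order. \(\lambda\) grid ties: smaller value.
* Collinear claw landmarks: curvature 0, length = chord; the collinearity
  cut is circumradius \(> 10^6 \times\) chord.
* All-zero composition rows, constant trait columns, singleton groups,
  classes with one member, zero out-levers, coincident landmarks and
  articulation points: explicit errors (or a warning plus drop, for
  singleton groups), with `pathological_presets()` providing ready-made
  degenerate inputs for testing.
* Every stochastic function takes a seed; pipeline stages write their seed
  and input hashes to a JSON run log, and reruns with the same config and
  seed are byte-identical.

## Known limitations

The claw-geometry backend is a stand-in for the field's landmark protocols,
faithful to their published parameters (curvature in degrees, arc-length
ratios) but not to unpublished placement details. The pFDA fossil
projection ignores fossil phylogenetic position (unit self-variance). The
interval-count convergence rule is this package's own. The EM-based zero
replacement is simplified to multiplicative replacement. Mass cut-points
computed from synthetic data characterize the method, not any real fauna.
And the package deliberately stops where editorial judgment begins: it
reports per-proxy posteriors and their intersections, not a final verbal
diet assignment.
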