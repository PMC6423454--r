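---
title: "Landmark-based wing morphometrics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based wing morphometrics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmorph)
```

wingmorph implements the classical landmark-based geometric-morphometric
toolchain for comparing insect wing size and shape between populations.
This vignette is the package's account of the underlying models, the
conventions it commits to where the literature offers several, and the
design decisions that were genuinely open. Nothing here reports an
empirical result that the test suite or the acceptance script does not
itself compute.

## The data model

A specimen is an ordered set of K two-dimensional landmarks — wing-vein
junctions and termini digitized from a photograph — with sex and site
metadata. Landmark order is semantic: landmark *i* must be the same
anatomical point on every specimen, but the package treats the
anatomical identities themselves as opaque. K is constant within a
dataset; the emulated survey design uses K = 14. Coordinates are 2-D
only (a third column is rejected), in a Cartesian y-up convention: no
image-row flip is applied at read time. This matters because files
digitized y-down differ from y-up data by a reflection, and the
superimposition here deliberately does not absorb reflections (below);
mixed-convention datasets must be flipped before import.

The TPS reader is a tolerant one: `IMAGE=`, `SCALE=` and `COMMENT=`
keys are honoured (`SCALE=` converts pixels to mm at read time), and
unknown keys are skipped with a warning rather than an error, since TPS
dialects in the wild vary.

## Size: centroid size

Centroid size, CS = √Σᵢ‖xᵢ − x̄‖², is the standard size measure: it is
invariant to translation and rotation and scales linearly under
isotropic scaling. Sizes are reported in mm assuming mm input. A
single-specimen group in the size summary is reported with SD 0 and a
`degenerate` flag instead of an error — sparse cells are a fact of
field collections, and a hard failure would be worse than a flagged
row.

## Superimposition: partial GPA without reflections

Generalized Procrustes analysis centres every configuration, scales it
to unit centroid size, rotates it onto the current consensus by the
optimal orthogonal rotation, re-estimates the consensus as the rescaled
mean, and iterates to convergence (tolerance 1e-10 on the RMS change of
the consensus, compared after aligning consecutive consensus estimates;
maximum 100 iterations, with non-convergence flagged rather than
fatal — in practice the loop converges in a handful of iterations).

Two conventions are fixed deliberately:

- **Proper rotations only** (determinant +1). Wing chirality is
  biologically meaningful and surveys digitize a single wing side, so
  allowing reflections could silently collapse a real left/right
  distinction or mask a y-axis convention error.
- **Partial Procrustes**: no residual rescaling after rotation, the
  convention of the lineage of morphometric tools this package follows.
  Distances and residuals are therefore "partial Procrustes" throughout.

## Shape variables: partial warps with α = 0

The thin-plate-spline bending-energy matrix of the consensus is
computed with kernel U(r) = r² ln r². The literature also writes
2 r² ln r; the factor of 2 rescales the bending-energy eigenvalues but
not the eigenvectors, and since scores here use no energy weighting
(weight exponent α = 0) the choice does not affect any score. The
matrix is formed on the non-affine subspace as B = Q (QᵀKQ)⁻¹ Qᵀ with Q
an orthonormal null-space basis of the affine design [1 x y] — the same
matrix as the upper-left block of the inverted bordered TPS system, but
numerically better behaved. B has exactly K − 3 positive eigenvalues;
their eigenvectors (principal warps, ordered from largest-scale to
smallest-scale deformation) give 2(K − 3) partial-warp scores per
specimen, x and y separately.

The **uniform (affine) component** is estimated by the complement
method: the orthogonal complement of the non-uniform warps within the
2K − 4 dimensional tangent space (orthogonal to both translations, the
rotation and the scale direction of the consensus). It is included by
default because discrimination should see the full shape space.

One numerical caveat is documented rather than hidden: after partial
Procrustes alignment a residual r = x − consensus retains a
second-order component (‖r‖²/2) along the scale direction, which the
2K − 4 basis does not span. Score norms therefore match residual norms,
and consensus-plus-scores reconstructs the aligned shape, to O(‖r‖²) —
exact for tangent-space deviations, and far below digitizing noise for
realistic residuals. The test suite asserts both the exact
tangent-space identity and the second-order bound on aligned data.

Principal components are computed on the covariance matrix of the
scores (they share one scale, so correlation-standardization would be
wrong); PCA is an orthogonal rotation and conserves total variance, and
because the Mahalanobis machinery is affine-invariant, using PCs versus
raw partial warps changes nothing when all dimensions are kept.

## Discrimination: Mahalanobis distances, CVA, validated reclassification

Group separation uses D(g,h) = √((m_g − m_h)ᵀ S⁻¹ (m_g − m_h)) with the
within-group covariance pooled with weights (n_g − 1)/(N − G). Sexes
are analyzed separately throughout; they are never pooled for
discrimination.

**Dimension retention.** With 24 shape variables and field-sized groups
(n ≈ 30–40), S can be ill-conditioned or singular, and nothing in the
classical method prescribes a remedy. The package makes its policy
explicit and configurable: scores are rotated to their principal axes
and the leading m components are kept, where m is the largest dimension
satisfying m ≤ N − G − 1 and condition(S_retained) < 1e8 (default).
Every result object records the dimensionality it used.

**Plug-in versus unbiased D.** The classical plug-in estimator is what
morphometric software conventionally tabulates, and it is the default.
But it is strongly biased upward in small samples:
E[D̂²] = ν/(ν − p − 1) · (Δ² + p(1/n_g + 1/n_h)) with ν = N − G and p
retained dimensions. At p = 24 and n ≈ 32 per group this inflates D by
roughly a third — a property of the estimator, not a bug. When the goal
is to *recover a population separation* (as in the package's own
parameter-recovery studies), `correction = "unbiased"` inverts the
relation, Δ̂² = (ν − p − 1)/ν · D̂² − p(1/n_g + 1/n_h), truncated at
zero. The recovery studies in the acceptance script use the unbiased
estimator for exactly this reason.

**Validated reclassification** is read as leave-one-out
cross-validation, the standard meaning in this literature: each
specimen is withheld, group means *and* pooled covariance are
re-estimated without it, and it is assigned to the nearest group in
Mahalanobis distance (ties, a measure-zero event, break toward the
earlier group in sort order; the retention cap uses one extra degree of
freedom so every fold stays invertible). Resubstitution mode exists for
comparison and is, as expected, optimistic.

## Permutation tests and repeatability

Size differences are tested with the absolute difference of group mean
centroid sizes; sidedness is two-sided by construction. Shape
differences use the two-group Mahalanobis D, fully re-estimated —
means and pooled covariance — under every relabeling (conservative and
internally consistent), in a retained subspace fixed from the pooled
observed scores, which depends on the labels only through the group
sizes and so preserves exchangeability. P-values follow
(b + 1)/(cycles + 1) with ties counted as exceedances: never zero,
granularity 1/1001 at the default 1000 cycles. An exact mode enumerates
all splits when feasible (the 3 + 3 toy case has 20 splits and
p = 2/20 for a maximal separation). At α = 0.05 the rule is exactly
calibrated whenever α(cycles + 1) is an integer; the calibration suite
uses 199 cycles for this reason, while the analysis default stays 1000.

Repeatability of digitization is the intraclass correlation from a
balanced Model-II one-way ANOVA on repeated measures:
s²_among = max(0, (MS_among − MS_within)/n₀) and
R = s²_among/(s²_among + MS_within), with 1 − R the measurement-error
fraction; the truncation keeps R in [0, 1]. The estimator applies to
any scalar measure; centroid size and the first shape PC are the
natural choices, and the simulator drives it at the scalar level where
the true ICC is controlled exactly.

## Phenograms

Neighbor-joining (Saitou–Nei, Q-criterion, standard branch lengths,
closed-form final star) is deterministic given the matrix, with ties
broken toward the earliest pair. On additive inputs the induced path
distances reproduce the input exactly — the canonical consistency
check, which the tests exercise together with a reference NJ
implementation. Negative branch lengths, possible on non-additive
input, are clamped to zero with the deficit moved to the sibling edge
so path lengths through the parent are preserved; the count of clamped
edges is recorded on the tree.

Both tree metrics are supported — partial Procrustes distances between
group mean shapes, and Mahalanobis distances between group mean scores
under a covariance pooled over all six sex × site groups — because
the two are used interchangeably in this literature and genuinely
differ; the choice is a documented switch (`tree_metric`), with
Procrustes as the default. The six leaves are the sex × site means;
sexes are not pooled before tree building.

## The synthetic generator

The generator exists so that every stage has known ground truth. Its
defaults emulate a three-site, two-sex survey: cell sizes
(female 32/40/31, male 36/42/39; 220 specimens), per-cell centroid-size
normals (means 2.04/2.06/1.95 and 1.57/1.62/1.54 mm, SDs
0.11–0.21 mm; truncation at zero is recorded but has negligible
probability, < 1e-15, at these parameters), within-sex site separations
of 2.53/3.80/3.13 (females) and 2.06/2.63/1.79 (males) Mahalanobis
units, and isotropic per-landmark digitizing-plus-biological noise of
0.008 shape units — a Procrustes residual scale of order 1e-2 per
coordinate, typical for wing landmarks.

Group shape offsets are specified in the orthonormal shape-variable
basis of the template. Because the basis is orthonormal and the noise
isotropic, the score covariance is σ²I and the population Mahalanobis
separation between two groups is simply the Euclidean distance of
their offsets divided by σ — so target separations are realized in
closed form by classical MDS of the target distance matrix. The
between-sex separation defaults to 8 units, chosen once on the grounds
that wing sexual dimorphism in mosquitoes is far stronger than
site-level divergence; it makes the sex split dominate the phenogram,
as a two-sex wing survey expects.

What the generator does *not* emulate — and what passing tests
therefore do not demonstrate about real data: anisotropic or spatially
correlated landmark covariance (real digitizing error varies by
landmark), allometry (no size–shape covariance is induced),
directional/fluctuating asymmetry, digitization outliers, and
non-Gaussian size distributions. Parameter recovery here validates the
estimators under the stated model, not the model itself.

## Problem sizes and reproducibility

The package's own validation runs at deliberate scales: full-design
simulations (220 specimens) for structure and size recovery; 200
study-sized replicates (n = 32/31) for separation recovery; 200
replicates of 30 × 2 for repeatability; 500 small-design replicates at
199 cycles for null calibration of both permutation tests; and
n = 2000/group for the closed-form separation check (a single draw at
that size still has ~1.3% sampling SD on D̂, so the check averages
three replicates). All randomness flows through explicit seeds
(`withr::with_seed`), so identical seeds give bit-identical runs; the
default analysis seed is surfaced in the CLI.

## Known limitations

- Strictly 2-D; no 3-D landmarks, semilandmarks or curve sliding.
- Balanced designs only for repeatability (unequal repeat counts are
  rejected rather than approximated).
- The dimension-retention policy is a pragmatic default, not an
  optimality claim; severe ill-conditioning may warrant an explicit
  PCA truncation chosen by the analyst.
- No bootstrap support values or alternative agglomerations (UPGMA) for
  the phenogram; rooted interpretations are the reader's
  responsibility, as NJ trees are unrooted.
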