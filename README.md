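# wingmorph

Landmark-based geometric morphometrics for comparing insect wing **size**
and **shape** across populations, built around the study design used for
*Aedes aegypti* surveys: several collection sites crossed with sex, 14
two-dimensional wing landmarks per specimen. It is aimed at medical
entomologists and morphometricians who want the classical
superimposition → shape-variable → discrimination toolchain as plain,
scriptable R functions, plus a synthetic data generator so every stage
can be exercised and validated without specimen data.

## What it computes

- **Centroid size.** For a configuration X with landmarks x_1..x_K and
  centroid x̄, CS(X) = √Σᵢ‖xᵢ − x̄‖² — the standard geometric-morphometric
  size measure.
- **Generalized Procrustes analysis (GPA).** Iterative centring, scaling
  to unit centroid size, and proper rotation (det +1; reflections are
  disallowed because wing chirality is meaningful) of all configurations
  onto a consensus; partial Procrustes convention.
- **Shape variables.** Thin-plate-spline partial-warp scores (kernel
  U(r) = r² ln r², no bending-energy weighting) of the Procrustes
  residuals, plus the two-dimensional uniform (affine) component, and
  their principal components.
- **Discrimination.** Between-group Mahalanobis distances
  D(g,h) = √((m_g − m_h)ᵀ S⁻¹ (m_g − m_h)) with pooled within-group
  covariance S (optionally the small-sample unbiased estimator of D²),
  canonical (factor-map) axes, and leave-one-out validated
  reclassification.
- **Inference.** Non-parametric permutation tests (default 1000 cycles,
  p = (b + 1)/(cycles + 1)) for size and shape differences, and the
  repeatability index R (intraclass correlation from a Model-II one-way
  ANOVA on repeated digitizations; 1 − R is measurement error).
- **Phenograms.** Neighbor-joining trees on between-group Procrustes or
  Mahalanobis distances, exported as Newick.
- **Synthetic data.** A generator emulating the survey design (3 sites ×
  2 sexes, 220 specimens, per-cell size distributions, controlled
  between-group shape separations, duplicate digitizations) with known
  ground truth.

## Worked example

```r
library(wingmorph)
ds <- simulate_dataset(synthetic_config(seed = 20161001))
report <- run_full_analysis(ds, cycles = 1000, seed = 20161001)
print(report)
```

Excerpts of the printed report (full output includes both sexes):

```
Centroid size by sex and site:
    sex        site  n     mean        sd      min      max degenerate
 female     coastal 32 2.025242 0.1103810 1.791788 2.230225      FALSE
 female  cultivated 31 1.946694 0.1157809 1.765337 2.156129      FALSE
 female residential 40 2.008828 0.2182940 1.513636 2.474159      FALSE
 ...

== female ==
<distance_matrix> mahalanobis, 3 groups (24 retained dimensions)
            coastal cultivated residential
coastal       0.000
cultivated    4.332      0.000
residential   3.159      4.543           0
...
<reclassification_report> loo, 24 retained dimensions
       group   formatted
     coastal 78% (25/32)
  cultivated 87% (27/31)
 residential 88% (35/40)
```

Reading it: the per-cell means and SDs recover the configured size
distributions; the female cultivated–coastal pair is the most separated
in shape (plug-in D = 4.33 for a generating separation of 3.80 — the
classical estimator inflates D in small samples, see the vignette); all
pairwise shape permutation tests reject at 1000 cycles (p = 0.001); and
leave-one-out reclassification lands in the 70–90% range typical of
moderately overlapping wild populations. The phenogram's deepest split
separates the three female from the three male groups, because the
generator's sexual shape dimorphism dominates site-level divergence.

A command-line wrapper is installed with the package
(`exec/wingmorph`): subcommands `simulate`, `analyze`, `repeatability`,
`tree`, `classify` over TPS landmark files and metadata CSVs.

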