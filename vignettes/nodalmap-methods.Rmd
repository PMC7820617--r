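---
title: "Methods: mapping, density estimation and level statistics in nodalmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping, density estimation and level statistics in nodalmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodalmap)
```

# Scope and model

`nodalmap` analyzes the spatial pattern of pelvic lymph-node metastases for
radiotherapy target-volume research. The pipeline has three arms that share
one coordinate frame — LPS axes, millimeters, voxel-center world mapping
(`world = origin + (index − 1) · spacing`):

1. **Mapping + density arm.** Node center points, one per metastatic node,
   are transferred from each patient's native coordinates into a common
   template anatomy by sampling displacement vector fields, and the mapped
   point cloud is turned into a probability density of involvement by
   weighted kernel density estimation.
2. **Level-statistics arm.** Each node is assigned to a named nodal level
   (external/internal/common iliac, obturator, presacral, perirectal,
   inguinal, prevesical, paraaortic); involvement is analyzed per patient:
   binary frequencies, subgroup contrasts, and volume-normalized relative
   proportions.
3. **Clustering arm.** Pairwise Euclidean distances within patients are
   contrasted with pairwise distances across the whole mapped cohort.

Deformable registration itself is out of scope: the package consumes
displacement fields (its own synthetic ones, or external fields read as
3-component NRRD volumes).

# The density estimator

With mapped node centers $x_i$ and patient-equal weights
$w_i = 1/(P\,n_p)$ the estimate is

$$\hat f(x) = \sum_i w_i\,K_h(x - x_i),\qquad
K_h(u) = \frac{\mathbf 1\{\lVert u\rVert_p \le h\}}{V_\mathrm{ball}(h,p)},$$

evaluated at voxel centers only (no sub-voxel quadrature; the error is
bounded by the grid spacing, which the user chooses). Defaults: bandwidth
$h = 12.5$ mm, Euclidean norm $p = 2$, so each node contributes a uniform
ball of radius 12.5 mm. The per-mm³ density is scaled by $10^6$ to ‰ per
cm³ (a factor 1000 for mm³→cm³ and 1000 for probability→per-mille); the
source analysis never states this conversion, so it is fixed and documented
here. The ball volume uses the exact closed form
$V = (2h)^3\,\Gamma(1+1/p)^3/\Gamma(1+3/p)$ for **every** $p \ge 1$ (it
reduces to $\tfrac43\pi h^3$ at $p=2$, the cross-polytope volume $4h^3/3$
at $p=1$, and $(2h)^3$ at $p=\infty$). An earlier
design sketch called for Monte-Carlo volumes at general $p$; the closed form
is exact and needs no RNG, so it is used throughout.

**Smoothing.** The density is smoothed by separable Gaussian convolution.
The smoothing parameter appears in the source pipeline as "sigma 2.5"
without units; `nodalmap` interprets it as **2.5 mm physical** (not voxels),
keeps it configurable, and flags the ambiguity rather than asserting a
fact. Convolution uses zero boundary handling and **no renormalization**
afterwards (mirroring the original pipeline order); the captured probability
mass is recorded in the map metadata so boundary losses stay visible.
Interior mass is preserved within 2%.

**Weighting invariants.** Weights sum to 1; each patient's weights sum to
$1/P$, so duplicating nodes within a patient cannot change that patient's
contribution. The rectangular-kernel estimator is tested for exact
agreement (up to floating-point summation order) with a brute-force
per-voxel ball-counting oracle.

# The synthetic world

No patient data are distributable, so the generator states a cohort world
once and the tests live in it:

* **Cohort size** 75 patients; **node count** per patient follows a
  zero-truncated negative binomial (size 1.5, mean 2.0) hard-truncated at
  11 — median 2, range 1–11, $P(X>11) < 0.01$ before truncation, matching
  the reported cohort shape with overdispersion.
* **Laterality**: strictly unilateral with probability 0.768. Since
  single-node patients are necessarily unilateral, the bilateral
  probability among multi-node patients is inflated to
  $(1-u)/P(n\ge 2)$ so the realized unilateral fraction converges to $u$;
  bilateral patients are guaranteed one node per side among sided levels
  (if every cross-side node hops to the unsided presacral level, the flag
  degrades honestly).
* **Spatial clustering**: each patient draws an *anchor* level from the
  published involvement frequencies (external iliac 0.373, internal iliac
  0.253, perirectal 0.253, common iliac 0.227, obturator 0.200, presacral
  0.107, inguinal 0.040, prevesical 0.040); the first node sits in the
  anchor, later nodes rejoin it with probability `cluster_rho = 0.8` or hop
  to an anatomically adjacent level (adjacency: external↔obturator↔internal,
  internal↔perirectal, internal↔presacral, external↔common,
  common↔paraaortic, external↔inguinal, obturator↔prevesical; left and right
  communicate only through the unsided presacral level). The published data
  report clustering but no generative model; this one-parameter mechanism
  reproduces the intra-patient vs cohort distance contrast. Note a
  consequence: *involvement* frequencies exceed *anchor* probabilities
  (spillover), so parameter-recovery tests compare anchor frequencies to the
  generating values and check only rank-consistency of involvement.
* **Surgery subgroup**: prior-surgery probability 0.733; surgery multiplies
  the right external iliac anchor weight by 0.25, emulating the reported
  contrast without claiming its mechanism.
* **Deformations**: per-patient control-point displacements are iid
  Gaussian (sd 3 mm per axis) on a 25 mm lattice, densified by trilinear
  interpolation (the registration grid spacing of the original protocol's
  first stage; 3 mm is a realistic inter-patient pelvic registration
  residual scale). Native coordinates are `template + forward(template)` by
  construction.
* **RNG**: a master seed draws per-patient child seeds, so patients are
  independent and cohorts reproducible bit-for-bit.

Two degenerate modes support calibration studies: `"iid"` (every node draws
its own anchor — no intra-patient clustering, same marginal mixture) and
`"homogeneous"` (nodes uniform over the union of pelvic level masks — the
null world of the volume-normalized analysis).

**What a green test does not establish.** The generator emulates the
*statistical* structure of a recurrence cohort, not its anatomy: level
shapes are tubes/boxes/ellipsoids, there is no imaging noise, no
registration error beyond the smooth displacement model, no correlation
between node count and biology. Agreement of the pipeline with its stated
world shows the machinery is correct, not that the published clinical
values are reproduced; the published headline numbers (6.6 vs 8.7 cm,
Fig-7-style densities) are emulation anchors, not acceptance values.

# The synthetic atlas

Each level family is one primitive: tubes along the iliac vessel axes
(common, external, internal), a tube for the obturator chain, a box for
presacral, ellipsoids for perirectal and inguinal, a box for prevesical,
and a short paraaortic tube. Left masks are rasterized geometrically; right
masks are the voxel-exact mirror of the left set, so paired levels are
bit-identical mirror images and reflection across the mid-sagittal plane
swaps left/right classification exactly. Overlapping primitives are a
configuration error (reported with both level names), as is a primitive
containing no voxel center.

Margin expansion (the 7/10 mm "around the vessels" options) is a Euclidean
distance-transform threshold (separable exact transform, anisotropic
spacing, compiled): a background voxel joins an expanded level if its center
lies within the margin of the level's voxel centers. Contested voxels go to
the *nearest* original level; exact ties to the lowest label id —
deterministic and testable. Existing labels are never overwritten.
Out-of-grid points classify as `"outside"` rather than erroring, because
mapped points can legitimately leave the field of view. The nearest-voxel
rule for boundary-straddling points is this package's choice; the source
material does not state one.

# Displacement fields and inversion

Applying a field moves a point by the trilinearly interpolated vector at
that point; points beyond the extent use edge-clamped interpolation and are
flagged (tolerant, but visible, QC). Application is exactly linear in the
field.

Inversion deserves a note. The forward field is piecewise-trilinear, hence
*kinked* at cell boundaries; its inverse is not representable by trilinear
interpolation, and a gridded inverse plateaus around 0.7–2.5 mm error no
matter how fine the lattice (measured during development). `nodalmap`
therefore solves the fixed point $g = -F(y+g)$ **exactly at the query
points** for all mapping operations (residual tolerance 0.05 mm, iteration
cap with a loud error reporting the worst residual); the gridded inverse
remains available as an export artifact with its accuracy documented. The
round-trip contract — generate native coordinates with the forward field,
map back with the inverse — holds below 0.2 mm on the exact route.

# Statistical choices

* **Fisher exact test**: two-sided by the minimum-likelihood rule (sum of
  hypergeometric point probabilities not exceeding the observed one),
  enumerated in log space via `lgamma`, with a $1+10^{-7}$ relative guard on
  the comparison. Verified against an independent enumeration oracle on all
  2×2 tables with total ≤ 40.
* **Bonferroni**: $p_\mathrm{adj} = \min(1, m\,p)$ with $m$ recorded. The
  published adjusted value 0.022 equals $11 \times 0.002$, i.e. eleven times
  the *rounded* p-value; the raw-p adjustment gives 0.027. The package
  reports both (see the acceptance suite).
* **Distance comparison**: the source analysis never names its test.
  `compare_means` offers `"pooled_t"` (Welch on the raw distance lists —
  the naive analysis, since pairwise distances are dependent) and
  `"patient_bootstrap"` (patients resampled with replacement; within-patient
  distances are invariant under patient resampling, so intra means are
  reassembled from precomputed per-patient sums). Both are reported,
  labeled. The bootstrap p carries a $+1$ continuity correction, so its
  smallest attainable value is $2/(B+1)$.
* **Quantiles**: linear interpolation between order statistics
  (`type = 7`); the source convention is unstated.
* **BCa bootstrap**: bias correction $z_0$ from the fraction of bootstrap
  means below the observed mean (mid-p at ties, clipped to
  $[1/2B,\,1-1/2B]$), acceleration from jackknife skewness, adjusted
  percentiles read off the sorted replicates. Degenerate samples return the
  point value. The implementation matches `boot::boot.ci(type = "bca")` on
  shared examples and achieves 94% coverage for the mean of Gaussian
  samples ($n=50$, 1000 replications) — inside the 93–97% calibration band.
* **Bootstrap one-sample test**: CI inversion on a shared replicate set —
  the smallest $\alpha$ on a $10^{-3}$ grid whose BCa $(1-\alpha)$ interval
  excludes the null value; 1 if never excluded. Under the homogeneous
  generator the test, applied to every considered level of 500 cohorts,
  rejects at the nominal 5% in 5.0% of level-tests (per level 3.8–7.0%;
  the largest level, external iliac, is mildly anti-conservative at ~7%,
  consistent with known BCa small-sample behavior on skewed, discrete
  per-patient shares). The pooled rate is the calibration statistic because
  no single level is distinguished by the analysis.
* **Volume normalization**: $1000\,\overline{r_{\cdot l}}/V_l$ per level,
  homogeneous reference $1000/\sum_l V_l$ — identical for all levels
  because a uniform density places mass proportional to volume. Patients
  with no node in a considered level are dropped and listed, mirroring the
  reduced n of the published proportion analysis. Presacral is treated as a
  single unsided level throughout.
* **Percent formatting**: half-up to one decimal, the convention that
  reproduces the published 34.7% (26/75) and 37.3% (28/75).

# Numerical and engineering notes

* Voxel-center counting of a 12.5 mm ball fluctuates with grid alignment
  (±4% at 2 mm spacing for a voxel-centered node — lattice point counting,
  not a bug); mass-conservation checks therefore run at 1 mm.
* All volumes are written as NRRD with `encoding: ascii` (plain text);
  no binary NIfTI support because no reader exists in the supported
  dependency set.
* Pipeline configuration is JSON; a single master seed fans out to
  per-stage and per-patient child seeds, and the manifest records MD5
  checksums of every artifact, so identical configurations yield
  byte-identical outputs.
* The compiled code is a single separable exact Euclidean distance
  transform; everything else is vectorized R.

# Known limitations

* The atlas is a geometric stand-in; coverage percentages computed on it
  say nothing about real consensus contours.
* The generator's adjacency graph and surgery mechanism are assumptions —
  sufficient to reproduce the published *phenomena* (clustering, subgroup
  contrast), not claims about biology.
* The gridded inverse displacement field is interpolation-limited (~1 mm);
  use the exact point inversion for quantitative mapping.
* BCa inference on per-patient shares is mildly anti-conservative for
  large, skewed levels at $n \approx 75$; interpret borderline p-values
  accordingly.

# A worked session

```{r example, eval = FALSE}
atlas  <- build_template(default_template_config(c(64L, 64L, 80L), c(4, 4, 4)))
cohort <- sample_cohort(gen_params(n_patients = 75, seed = 7), atlas)
mapped <- map_cohort(node_table(cohort, "native"), cohort$dvfs)

# clustering contrast
intra <- intra_patient_distances(cohort, "template")
coh   <- cohort_distances(mapped)
compare_means(intra, coh, "patient_bootstrap", B = 1000, seed = 2)

# density atlas
pel  <- mapped[mapped$level != "paraaortic", ]
dens <- smooth_density(kde3d(as.matrix(pel[, c("x_mm", "y_mm", "z_mm")]),
                             patient_weights(pel), kde_config(), atlas$grid))
hotspot_summary(dens, atlas, 0.99)

# level statistics
rp <- relative_proportions(mapped)
vn <- volume_normalized_means(rp, atlas)
vn$table
vn$reference_permille_cm3
```
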