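---
title: "Probabilistic maps and stereological volumetry of paired subcortical nuclei"
author: "cytoatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic maps and stereological volumetry of paired subcortical nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoatlas)
```

# Scope and model

`cytoatlas` implements the quantitative pipeline used to characterize small
paired subcortical nuclei — prototypically the medial and lateral geniculate
bodies (MGB, LGB) of the metathalamus — from serial histological
delineations:

1. **Stereological volumetry.** A structure delineated on systematically
   sampled serial sections of thickness $T$ (every $k$-th section kept) has
   the Cavalieri volume estimate
   $$\hat V = d \sum_i A_i, \qquad d = kT,$$
   with $A_i$ the delineated profile areas. Volumes measured in processed
   tissue are corrected by a volumetric shrinkage factor $f \ge 1$
   ($V_\mathrm{corr} = f\,\hat V$) and normalized by total fresh brain
   volume to a dimensionless proportion.
2. **Group statistics.** Hemisphere, sex and sex-by-hemisphere effects on
   the normalized volumes are tested with Monte-Carlo permutation tests
   (difference of group means as contrast, random relabeling as null);
   nucleus-vs-nucleus mean volumes with a paired two-sided $t$-test.
3. **Probabilistic maps.** Each subject's binary delineation volume is
   resampled into a common reference grid through its affine; the voxel-wise
   percentage of subjects covering a voxel (0–100%) is the probability map,
   summarized by its per-hemisphere centre of mass in mm.
4. **Surface models.** Closed triangle meshes of each structure are
   extracted from the label grid, smoothed along vertex normals, and their
   enclosed volume computed by the divergence theorem as a cross-check on
   voxel counting.

Because real delineation stacks of this kind are not redistributable, the
package ships a first-class synthetic cohort generator with analytic ground
truth, so that every estimator can be validated end-to-end against known
volumes.

# The synthetic cohort

`generateCohort(cohortSpec())` emulates a ten-subject cohort (five female,
five male) of bilateral nuclei:

* **Shapes.** Each structure is an ellipsoid; the analytic volume
  $\tfrac43\pi abc$ of the realized semi-axes is the oracle for estimator
  validation. Real nuclei are not ellipsoids, but shape realism is
  irrelevant for validating volume estimators, which is the generator's
  purpose.
* **Layout.** One ellipsoid per structure in the left hemisphere of a
  common reference layout, mirrored about the midsagittal plane
  ($x = 0$). The label volumes represent processed (shrunken) tissue:
  default sizes are chosen so that *shrinkage-corrected* volumes land in
  the published fresh-scale range (MGB subdivisions ~20–44 mm³, LGB
  ~170 mm³ per hemisphere). Structures are spaced with enough clearance
  that per-subject size variability cannot make labels collide; the
  generator verifies this at voxelization time and errors on collision.
* **Size variability.** A per-subject isotropic lognormal volume factor
  with mean 1 and CV 0.25. At $n = 10$ this reproduces the roughly
  two-fold max/min volume range reported for these nuclei; the realized CV
  is itself a tested invariant.
* **Jitter.** One rigid + isotropic-scale affine per subject (rotation sd
  2°, translation sd 1 mm, log-scale sd 0.02) maps the reference layout
  into subject space; its inverse is the subject-to-reference transform
  used downstream. Jitter is whole-brain, as in reality, so relative
  nucleus topology is preserved.
* **Metadata.** Fresh brain volume ~N(1.25·10⁶, 1.4·10⁵) mm³ (consistent
  with fresh weights of ~1.0–1.45 kg at unit density), shrinkage factor
  ~N(2.0, 0.1) truncated at 1 (paraffin histology roughly halves tissue
  volume), ages uniform over 59–85 (female) and 30–75 (male) years. These
  are generator conventions, not measured values.
* **Reproducibility.** Every subject draws from its own stream seeded
  deterministically from the master seed, so subject `i` is identical in
  any cohort of size ≥ `i` with the same seed and sex assignment.
* **Null by default.** Sex and hemisphere have no true effect unless the
  `sexEffect`/`hemisphereEffect` knobs are set, so default cohorts are
  valid null cohorts for type-I-error studies.

Subject grids are 0.5 mm isotropic — coarse against the 1 μm scans of real
histology but sufficient to keep ellipsoid digitization error near 1%, and
cheap enough that hundreds of cohorts can be simulated in tests. Sectioning
then emulates the 20 μm microtome independently of the grid pitch.

# Sectioning and volumetry choices

Sections are modelled as infinitesimally thin planes at each section's front
face, not as 20 μm slabs: delineation happens on a section surface, and the
plane model keeps the Cavalieri estimator textbook-exact. The sampling
lattice phase (`offset`) is explicit; where the user does not fix it, it is
drawn uniformly from $[0, k)$ per subject, since a real sectioning run
starts at an arbitrary phase. With $T = 20\,\mu m$ and $k = 15$ the
inter-section distance is $d = 300\,\mu m$.

The estimator is unbiased over the lattice phase: averaged over all $k$
offsets it reproduces the voxel-count volume of the digitized structure
exactly when $T$ equals the grid pitch, and recovers analytic sphere
volumes to a fraction of a percent on finer grids. On the default cohort,
shrinkage-corrected Cavalieri estimates recover the analytic ellipsoid
volumes with a mean relative error well under 2% for nuclei ≥ 100 mm³
(tested).

Shrinkage correction is a single multiplicative volumetric factor per brain;
its derivation (fresh vs. embedded volume) is upstream of this package.
Normalized volumes are reported as raw proportions; statistics are invariant
under the alternative convention of rescaling by the cohort-mean brain
volume, which is why the proportion is the default.

Per-hemisphere estimates restrict the label grid at the world $x = 0$
midplane; voxel centres exactly on the midline (measure zero for jittered
cohorts) belong to neither hemisphere.

# Permutation tests

The contrast is the difference of group means. The null is Monte-Carlo:
values are randomly redistributed into two groups of the original sizes
(default $10^6$ iterations for production runs; tests run $10^4$–$10^5$).
Three conventions deserve note:

* **p-value.** The add-one estimator $(1 + \#\{|C^*| \ge |C|\})/(1 + B)$
  avoids $p = 0$ and is standard Monte-Carlo practice. Ties count as
  exceedances (conservative).
* **Sidedness.** The classical randomization criterion — the observed
  contrast exceeds 95% of the null draws — is one-sided; the package
  defaults to the two-sided version on $|C|$ and exposes the one-sided rule
  via `sided = "one"`. The type-I validation uses the one-sided rule and
  confirms a 5% rejection rate on null cohorts within the binomial 99%
  band over 1000 cohorts.
* **Exchangeable units.** For the sex test the default analyzes one
  bilateral volume per subject (`mode = "per_subject"`). Using the two
  per-hemisphere values of each subject as if independent doubles the
  apparent sample size while the values are strongly correlated through
  the subject's overall nucleus size; empirically this inflates the
  type-I error several-fold. The per-hemisphere mode is retained for
  comparison but should not be used for inference. The hemisphere test
  does group the paired per-hemisphere values, which errs in the opposite,
  conservative direction (positive within-subject correlation shrinks the
  true contrast variance below the permutation null); a subject-paired
  alternative is the interaction-style difference test.
* **Interaction.** The sex-by-hemisphere interaction permutes sex labels
  across subjects while keeping each subject's left/right pair intact, with
  the contrast mean(left−right | male) − mean(left−right | female).

Small-sample agreement with exhaustive enumeration (2v2, 3v3 designs) is
tested to three Monte-Carlo standard errors.

# Reconstruction and probability maps

`stackToVolume` rebuilds a 3D volume from the sparse sections, with two
interpolants:

* **block** — each sampled mask is extruded over the gap to the next
  sampled section. This reproduces the Cavalieri sum, so its net volume is
  unbiased over the lattice phase, but boundaries are misplaced by up to
  $d$.
* **shape_based** — between consecutive sections the two signed Euclidean
  distance transforms are blended linearly and thresholded at zero. Where a
  structure ends between sections, the empty neighbour acts as a uniform
  negative plateau so the boundary tapers to extinction instead of being
  cut off. This places boundaries about 2–3× better (symmetric-difference
  error on sphere phantoms) but its net volume carries a small one-signed
  bias on convex shapes, because linearly interpolating the distance field
  of a concave-profiled solid underestimates the mid-gap radius. For
  volumetry, therefore, use the Cavalieri estimate (or block); shape-based
  reconstruction is for morphology and visualization.

Resampling to the reference grid is nearest-neighbour pull-back through the
inverse subject-to-reference affine: label identity is never blended.
Probability maps store exact overlap fractions; `percentMap()` rounds to
integer percent (steps of 10 for ten subjects) only at export. The centre
of mass is probability-weighted by default (an unweighted variant exists)
and reported rounded to integer mm, the convention for published
stereotaxic coordinates. The reference grid defaults to 1 mm isotropic,
the resolution at which such maps are published.

# Meshing

Isosurfaces are extracted by marching tetrahedra: each cell is split into
six tetrahedra sharing the cell's main diagonal (Kuhn subdivision). The
subdivision is face-consistent across neighbouring cells and a tetrahedron
has no ambiguous sign configurations, so the surface is closed and
orientable *by construction* — the property that motivates
topology-consistent variants of marching cubes, obtained here without case
tables. The volume is padded by one background layer first, so structures
touching the grid edge still yield closed meshes. On a digitized ball
(r = 5 mm at 0.25 mm voxels) the mesh volume is within 0.5% of the
analytic value and within the half-voxel surface bound of the voxel count;
a single voxel yields a closed mesh of about half the voxel volume, the
expected bias of midpoint surfaces at single-voxel scale.

"Smoothing along the normal direction" is implemented as the
normal-projected uniform-Laplacian flow: each vertex moves along its
area-weighted normal by `step` times the normal component of the vector to
its neighbour centroid. The magnitude is proportional to local mean
curvature, so planar regions are exact fixed points (tested) and the flow
is structure-preserving; tangential drift is suppressed by the projection.
Defaults (10 iterations, step 0.1) shrink a sphere mesh by well under 1% in
volume. If an iteration would create a zero-area face the smoother stops
and returns the last valid mesh with a warning. This operator is one
reasonable reading of curvature-based normal-direction smoothing; the
package treats the exact operator as a configuration detail, not a
scientific claim.

Mesh volume uses the divergence theorem on the consistently oriented
surface. Shrinkage-corrected mesh volumes are obtained by multiplying by
$f$ (equivalently, scaling the grid spacing by $f^{1/3}$ before
extraction).

# Pipeline and problem sizes

`runPipeline()` chains all stages from one configuration (R list or YAML;
`inst/extdata/default-config.yaml` documents every default), writes NIfTI
label volumes and probability maps, tidy CSV volume tables, JSON test
results, OBJ meshes, and a manifest with MD5 content hashes. Runs are
deterministic given the configured seeds; reruns produce identical hashes.

Default problem sizes were chosen so a full pipeline run takes seconds and
the whole validation suite a few minutes on one CPU: 10 subjects on
161×53×65 grids at 0.5 mm, permutation tests at $10^4$ iterations
(production default $10^6$), 1000 null cohorts for the type-I check via the
generator's metadata-only fast path (`volumesOnly = TRUE`, which draws from
the same per-subject RNG streams as full voxelization).

# What passing tests do and do not show

The synthetic cohort validates the *estimators*: unbiasedness of the
systematic sampling design, correctness of the shrinkage and normalization
arithmetic, type-I control of the permutation tests, exactness of the
overlap-percentage semantics, and the voxel/mesh volume consistency. It
does not emulate delineation disagreement between observers, section
distortion or registration error, staining variation, or non-ellipsoidal
nucleus shapes — so passing tests certify the computational pipeline, not
the histological workflow upstream of it. Known limitations: shape-based
interpolation's volume bias on convex structures (use Cavalieri for
volumes); nearest-neighbour resampling quantizes masks at the reference
grid resolution (volume preserved only to ~2% under rotation at 1 mm);
and the permutation hemisphere test inherits the conservative grouped
design discussed above.
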