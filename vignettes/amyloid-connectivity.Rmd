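---
title: "Within-patient coupling of amyloid burden and intrinsic network connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-patient coupling of amyloid burden and intrinsic network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

`amynet` quantifies, within a single participant, how the spatial pattern of
amyloid-beta plaque load relates to the spatial pattern of intrinsic
functional connectivity. The inputs are per-subject 3-D maps on one common
grid: a PiB-PET standardized-uptake-ratio (SUVR) map, one connectivity
z-score map per intrinsic network (back-projected ICA component maps), and a
grey-matter density map, plus scalar covariates (age, gender, group, a
neocortical composite SUVR).

For each subject $k$ and network $j$ the pipeline:

1. **Selects network voxels** — all voxels with connectivity $z > 1$
   (strict inequality; ties have measure zero on continuous maps, and the
   threshold is configurable). Typical networks contain thousands of voxels.
2. **Log-transforms connectivity.** Thresholding at $z > 1$ right-skews the
   retained values; the natural log reduces the skew. All retained values
   exceed 1, so the log is positive.
3. **Summarises burden and coupling** —
   the median PiB uptake over the network; the *global* spatial correlation
   $r_{GLOBAL} = \mathrm{cor}(\log z,\ \mathrm{PiB})$ over all network
   voxels, Fisher-transformed ($\operatorname{atanh}$, clipped at
   $\pm(1-10^{-7})$) for averaging and t-tests; and the median
   (log-transformed) z-score as a conservative connectivity score.
4. **Decorrelates the two modalities** by Gram–Schmidt projection: both
   vectors are demeaned and the projection of one onto the other is removed,
   forcing the whole-network correlation to exactly zero. This removes the
   network-scale coupling so that the subsequent local analysis cannot
   simply re-detect it.
5. **Runs a searchlight** — for every network voxel, the neighbourhood is
   the set of *in-network* voxels within a 6-mm radius (a closed ball on the
   lattice, central voxel included; at 2-mm voxels this stencil holds 123
   sites, the "about a hundred voxels" scale). Voxels with fewer than 25
   in-network neighbours are skipped as unreliable boundary estimates. The
   Pearson correlation of the decorrelated pair over the neighbourhood is
   Fisher-transformed and recorded at the centre, giving an $r_{LOCAL}$ map.
   Because orthogonalization is asymmetric, the searchlight runs twice (PiB
   decorrelated with respect to connectivity, and the reverse) and the two
   Fisher-z maps are averaged over voxels recorded in both. The median
   $r_{LOCAL}$ over recorded voxels summarises each subject-network.
6. **Residualizes** each scalar metric (median PiB, Fisher-z $r_{GLOBAL}$,
   median $r_{LOCAL}$) against median grey-matter density, age and gender
   (F = 1, M = 0) by OLS with intercept, separately per network.
7. **Tests at the cohort level** — a classical mixed between/within-subject
   ANOVA (group × network; group tested against subjects-within-groups,
   network and interaction against the subject-by-network stratum; no
   sphericity correction), post hoc two-sample Student t-tests with explicit
   Bonferroni families, one-sample t-tests of median $r_{LOCAL}$ against 0,
   the across-subject correlation of median PiB with $r_{GLOBAL}$,
   voxel-wise group t-maps with 26-connected cluster-extent thresholding and
   permutation family-wise correction, and a subsampling control that
   repeatedly draws patient subgroups matched in size to the control group.

## Design choices where the convention was open

* **Covariate scope.** Fitting the nuisance model separately per group (with
  its own intercept) would zero each group's residual mean and annihilate
  exactly the group effects the ANOVA is meant to test. The default is
  therefore a single pooled fit across groups; `scope = "per_group"` is
  available for sensitivity analyses. Note that when a covariate is strongly
  confounded with group (e.g. age in small cohorts), the pooled fit absorbs
  part of the group difference — visible in the worked examples, and a real
  property of covariate residualization rather than an artefact.
* **Template matching.** Networks of interest are selected by regressing
  each binary template mask (as response) on all candidate component maps
  jointly, assigning the component with the largest positive coefficient;
  assignment is greedy one-to-one with ties broken toward the lower
  component index. The regression direction (mask on components) is the
  template-matching convention; the alternative direction is not
  implemented.
* **Averaging scale.** The two directional searchlight maps are averaged on
  the Fisher-z scale, the scale on which values are recorded and on which
  downstream t-tests operate.
* **Student vs Welch.** Post hoc group tests are pooled-variance Student
  t-tests by default (`var_equal = FALSE` gives Welch).
* **Cluster inference.** Group t-maps are thresholded two-sided at the
  voxel-level height p; clusters are 26-connected components per sign, and
  family-wise corrected p-values come from a permutation null of the maximum
  cluster extent pooled over signs — an exact, dependency-free alternative
  to random-field theory.
* **Degenerate inputs.** Neighbourhoods with zero variance are skipped and
  tallied (`n_skipped_variance`), not raised as errors, because flat patches
  occur legitimately in null simulations. Networks below 200 voxels raise a
  degenerate-network error: searchlights and spatial correlations are not
  meaningful below that. Perfect correlations are clipped before
  $\operatorname{atanh}$.

## The synthetic cohort generator

No patient data ship with the package; `cohort_design()` /
`generate_cohort()` create cohorts that carry, by construction, the
statistical structure the analysis assumes, so every stage is testable
end-to-end. The default design mirrors the target study conditions: 23
patients and 12 controls (the asymmetry keeps the subsampling control
meaningful), seven networks — six coupled heteromodal analogues and one
uncoupled control network standing in for primary auditory cortex — on a
40 × 48 × 38 lattice of 2-mm voxels, with networks of a few thousand
supra-threshold voxels built from pairs of Gaussian blobs (SD 10 mm,
amplitude 3.5).

The two couplings are injected at **separate spatial scales** so each is
independently recoverable:

* the **global** term adds `b_global` times a wide-smoothed (20-mm FWHM)
  aggregate of the coupled templates to the PiB map. The aggregate is the
  pointwise maximum of the templates (so each network's own core drives its
  coupling) and is faded to zero where the uncoupled template exceeds 0.2 —
  well below the $z > 1$ selection threshold — so the control network sees a
  locally flat coupling field. This drives a positive whole-network
  correlation between PiB and connectivity in patients.
* the **local** term subtracts `c_local` times the template-weighted local
  fluctuation of the subject's connectivity noise, $e - S_{6mm}(e)$, where
  $e$ is the subject-specific noise component of the z-map. Using the full
  map's fluctuation $z - S(z)$ instead would fold in the deterministic
  template curvature, which correlates with the template itself and leaks a
  negative coupling into the global scale — breaking the independence of the
  two injected effects. The template weighting concentrates the negative
  coupling in network cores, where the searchlight then finds it.

Noise fields are white Gaussian noise smoothed at 8-mm FWHM and rescaled so
the stated SD is the marginal SD of the smoothed field (comparable across
smoothness settings). The connectivity noise SD defaults to 0.35: large
enough for realistic subject variability, small enough that voxels crossing
the $z > 1$ threshold by noise alone (scattered across the grid, outside any
network) remain a negligible fraction of each voxel set. Grey-matter density
declines linearly with age plus a subject-level offset — the offset keeps
grey matter from being a deterministic function of age, which would make the
nuisance model ill-conditioned. Ages and genders follow the target cohort's
demographics; neocortical SUVR is drawn above the 1.15 positivity cut-off
for every patient and below it for every control, always.

**What the generator does not emulate:** PET count statistics, tracer
kinetics, partial-volume effects, BOLD time series, head motion,
registration error, or anatomically realistic network shapes. Passing tests
show that the pipeline recovers the statistical structure it claims to
measure — signs, approximate magnitudes, null calibration — not that it is
robust to acquisition artefacts absent from the simulation.

## Numerical conventions

* Volumes are NIfTI-1, one 3-D image per file, written as 64-bit doubles so
  values round-trip bitwise; the sentinel for out-of-brain voxels is `NaN`.
* Gaussian smoothing is separable with half-sample-symmetric (reflect)
  boundaries, which preserves both constants and total mass; sentinel voxels
  are excluded by normalized convolution and restored.
* Lattice indices are 1-based (R convention); world coordinates enter only
  through the voxel size and origin.
* Cohorts are bitwise reproducible from the design seed; pipeline-level
  randomness (subsampling draws, permutations) is governed by the run
  config's seed, and identical config plus seed yields a byte-identical
  report.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the statistical
checks sharp: null calibration runs 50 seeded coupling-free cohorts of 20
subjects each on a one-network 26³ grid and checks that the grand means of
$r_{GLOBAL}$ and median $r_{LOCAL}$ sit within two standard errors of zero
and that one-sample tests reject at the nominal 5% rate; pattern
reproduction runs the full 23 + 12 default design once and checks the
qualitative group × network pattern (elevated residual PiB everywhere,
positive $r_{GLOBAL}$ coupling and negative median $r_{LOCAL}$ in coupled
networks only); monotonicity of the recovered effects in `b_global` and
`c_local` is checked across three levels each on reduced eight-patient
cohorts, sharing the design seed across levels so the comparison is paired.

## Known limitations

* All maps must share one grid; there is no registration or resampling.
* The mixed ANOVA is the classical decomposition, not a REML mixed model;
  no sphericity correction is applied.
* Searchlights are volumetric only.
* The uncoupled control network in the generator is kept clean by
  construction; in real data, primary sensory networks may carry weak
  coupling that this design deliberately sets to zero.
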