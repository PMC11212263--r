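---
title: "Groupwise diffeomorphic templates and deformation metrics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Groupwise diffeomorphic templates and deformation metrics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmplkit)
```

## The problem

Spatial normalization warps each subject's brain image onto a common
template so that homologous structures coincide.  Every normalization
deforms the subject's anatomy, and the residual deformation is smaller when
the template matches the population being normalized -- in sample size, age
and ancestry.  `tmplkit` implements the full computational chain needed to
study this question quantitatively: a synthetic population generator with
known ground-truth warps, a diffeomorphic registration core, an iterative
groupwise template builder, per-voxel deformation metrics, and paired
region-wise statistics for comparing templates.

## Deformation model

All nonlinear warps are parameterized by a stationary velocity field (SVF)
$v$: a per-voxel 3-vector field whose exponential
$\varphi = \exp(v)$ is a diffeomorphism with inverse $\exp(-v)$.
`exp_velocity()` computes the exponential by scaling and squaring: $v$ is
halved $N$ times until the largest step displaces at most half a voxel,
then the small deformation is self-composed $N$ times.  Displacement fields
use the backward (pull-back) convention throughout: a warped image's value
at voxel $x$ is sampled from the source at $x + u(x)$, which makes
`warp_volume(warp_volume(I, inner), outer)` equal to warping once through
`compose_fields(outer, inner)`.

Two per-voxel metrics quantify a deformation:

* **displacement magnitude** $\lVert u(x) \rVert$ in mm
  (`displacement_map()`), the Euclidean distance between a voxel's original
  and normalized positions;
* **log-Jacobian determinant** $\log \det (I + \nabla u)$
  (`jacobian_map()`), the local volume change: positive for expansion,
  negative for contraction, zero for preservation.  Region summaries use
  the absolute value $|\log J|$ (`abs_log_jacobian()`) so expansion and
  contraction cannot cancel within a region.  The log is natural; absolute
  values make comparisons base-invariant up to a constant factor.

## Registration

`register_pair()` is a greedy multiresolution diffeomorphic demons scheme
on the SVF: at each iteration the warped moving channels generate a demons
force $\delta = -r\,\nabla M / (\lVert\nabla M\rVert^2 + r^2)$ per channel
(with $r$ the residual), channel-weighted and Gaussian-smoothed at
`velocity_smoothing_mm`; a candidate $v + s\,\delta$ is accepted only if
the channel-weighted mean squared difference does not increase, otherwise
the step is halved (five times at most, after which the level is declared
converged).  The accumulated velocity is smoothed on entry to each pyramid
level; within a level the velocity remains smooth automatically because
every accepted update is smooth.  We deliberately do **not** re-smooth the
accumulated velocity inside the line search: doing so shrinks an
already-converged field by more than a single demons step can gain, and the
optimization stalls before recovering the warp.

Defaults: 3 pyramid levels, 30/20/10 iterations (coarsest first), unit
step, smoothing at twice the voxel spacing, automatic squaring depth.  The
similarity trace returned with every fit is non-increasing within each
level by construction.

The exact objective and solver of SPM's DARTEL (tissue-class multinomial
likelihood with membrane energy, full multigrid) are not reimplemented;
the properties the downstream analysis relies on -- diffeomorphic,
invertible, Jacobian-computable, groupwise-averageable -- are provided by
this simpler and fully testable scheme.

### Channel weighting

Phantom subjects carry a T1-like channel plus three tissue probability
channels.  By default the experiment pipeline drives registration with the
tissue channels alone (`phantom_channel_weights()`, T1 weight 0): an SSD
demons force converts any residual intensity inhomogeneity in T1 into
spurious geometry, while the probability channels are intensity-calibrated
by construction.  This mirrors DARTEL, which estimates its flows from
tissue classes; the T1 channel is still warped and averaged into every
template.  Equal weighting remains available through
`registration_params(channel_weights = ...)`.

## Groupwise template construction

`build_template()` implements mean-and-register with recentring:

1. the initial template is the voxelwise mean of the imported channels;
2. each outer iteration registers every subject to the current template
   (the schedule's *inner* count sets the demons iterations per level),
   averages the warped channels, and
3. recentres: the mean subject velocity $\bar v$ is subtracted from every
   subject velocity and the template is warped by $\exp(-\bar v)$, driving
   the population-average deformation toward zero (an *unbiased* template
   that sits at the population's geometric centre).

Outer iteration 1 runs the full multiresolution pyramid; subsequent outer
iterations refine each subject's warm-started velocity at the finest level
only.  This removes pyramid down/upsampling churn from the convergence
trace, so the recorded residual (`mean_displacement_mm`: the brain-mask
mean magnitude of the mean pre-recentring subject deformation) decreases
cleanly across outer iterations.  The default schedule is six outer by six
inner iterations; intermediate templates can be kept with
`keep_intermediate = TRUE`.

`initial_import()` supplies the rigid part: moments-based alignment
(centroid, principal axes, isotropic brain-volume scale) of all subjects
onto the first subject's grid, the analogue of a rigid/scale import step
before nonlinear iteration.

## Synthetic phantom population

`phantom_spec()` describes a population of T1-like head phantoms.  The
mean anatomy is analytic: a head/brain ellipsoid (default semi-axes 66,
81, 50 mm, giving width 132, length 162, height 100 mm -- sizes typical of
elderly East-Asian cohorts), a gray-matter shell, a central
ventricle-like fluid space, and bilateral thalamus-, hippocampus- and
parahippocampal-like blobs plus a cerebellum-like mass, all with soft
(logistic) edges.  A subject is produced by:

1. optional per-structure size scaling (the population mean-shape dial
   used as an ethnicity analogue) -- part of the spec, so a "population"
   is simply a spec;
2. a global isotropic scale: 1.04 for male subjects (brains of men are
   consistently longer, wider and higher in the cohorts this emulates) and
   an optional linear age shrink (0 by default: extents are stable across
   age strata in those data);
3. a random subject warp: white noise smoothed at `warp_smoothness_mm`
   (10 mm), scaled so the mean displacement over the brain is
   `warp_sd_mm` (2 mm -- a free parameter; no quantitative inter-subject
   deformation scale is available for the target population), and
   exponentiated.  The anatomy is evaluated analytically at the warped
   coordinates, so rendering is exact, and the inverse warp
   $\exp(-v)$ is stored as ground truth in the same direction as
   registration outputs (template grid into subject);
4. intensity rendering (fluid 0.25, gray 0.6, white 0.9), multiplication
   by a smooth bias field ($\exp$ of a random degree-2 polynomial, log-sd
   `bias_amplitude` = 0.1), and additive Gaussian noise (sd 0.02).

Default grids are 64³ voxels at 3 mm (tests and desk-scale studies);
resolution is configuration, not anatomy -- 1 mm studies only change
`grid_shape`/`spacing_mm`.  `make_atlas()` gives a deterministic 16-region
parcellation (8 named structures + 8 octants of remaining brain tissue)
with exact voxel-count volumes, standing in for an anatomical atlas.

What the generator does **not** emulate: cortical folding, MRI physics
(k-space, sequences, partial Fourier), pathology, skull/scalp tissue, and
segmentation noise -- subject tissue maps are analytic, so registration
sees idealized, noise-free class images.  Passing tests therefore
demonstrate the correctness and the statistical logic of the pipeline, not
its performance on real MRI.

## Preprocessing

The preprocessing chain mirrors a standard structural pipeline:
principal-axis reorientation (`reorient_principal_axes()`; phantoms have
no anatomical landmarks, so the mask's principal axes provide the
canonical orientation), isotropic reslicing (`resample_isotropic()`),
polynomial log-bias correction (`bias_correct()`), Gaussian-mixture
segmentation (`segment_tissues()`: k-means initialization, EM to 1e-6 or
200 iterations, posteriors ordered by class mean), and whole-brain extent
measurement (`measure_extent()`: height/length/width as world distances
spanned by the thresholded mask along grid axes, with W/L, H/L, H/W
ratios).  The default mask threshold is 10% of the 99th intensity
percentile.

Bias estimation deserves a note: fitting the log-polynomial over the whole
head absorbs genuine radial anatomy (the gray shell is itself roughly
quadratic), which *reduces* contrast.  `preprocess_phantom()` therefore
fits the polynomial only inside the brightest intensity class (k-means
cores), where the true intensity is approximately flat, and divides the
estimated field out of the whole image.  Residual bias after correction is
on the order of 2%, one reason the experiment pipeline drives registration
with tissue channels.

## Region statistics and template comparison

`region_summary()` averages the displacement and $|\log J|$ maps over each
atlas region, after excluding regions smaller than 500 mm³ (the
conventional cutoff for stable region means at ~1 mm resolutions; the
filter is exact on the region table's voxel-count volumes).
`compare_templates()` runs the full validation loop: each held-out subject
is registered to each template, metric maps are computed in template space
and transported to a common reference space through a bridge deformation
(obtained by registering the template to the reference), and per-region
per-subject means feed a paired t-test per region,
Bonferroni-corrected with $m$ = the number of retained regions per metric
family.  `paired_t()` and `bonferroni_threshold()` are exact, closed-form
implementations; with $\alpha = 0.05$ and 160 tests the threshold is
$3.125\times10^{-4}$.

`compare_templates()` defaults its common reference to template A, but
`run_template_experiment()` passes the analytic mean anatomy instead:
referencing one of the *compared* templates leaves that template's maps
untransported while the other's are interpolated once, a measurable
asymmetry in $|\log J|$ means.  A neutral reference treats both arms
identically.

### What a paired comparison can and cannot conclude

The paired design cancels subject effects and is therefore maximally
sensitive to *template-level* differences.  For deliberately different
templates (sample-size or population-mismatch designs) that is exactly the
point.  But two templates built from disjoint finite samples of one
population also differ -- by sampling noise of the mean shape, on the
order of `warp_sd_mm`/√n -- and the paired test will detect those
differences too, because the subject-level noise it measures against does
not include template sampling variability.  Family-wise error against the
*marginal* null ("the templates are draws from the same construction
process") is consequently inflated at small construction sizes, most
visibly for $|\log J|$, whose subject-level variance is small.  The
acceptance suite measures this directly in a 20-repetition null
simulation; treat region significance as a statement about *these two
templates*, not about the populations behind them, unless the
construction samples are large.

## Simulation scales

The test suite and the acceptance script run at desk scale, chosen to keep
a complete run in tens of minutes on one CPU: oracle checks on 24³--32³
grids; warp recovery and the n = 10, schedule (6, 6) template build at the
generator's default 64³/3 mm; template-comparison experiments at 48³/4 mm
with schedule (2, 3), construction samples of 6--24 subjects and 5--10
held-out validation subjects; 20 repetitions for the null calibration.
The same code paths scale to 1 mm grids unchanged.

## Numerical choices and degenerate inputs

* Interpolation is trilinear (nearest-neighbour mandatory for labels, which
  provably introduces no new label values); out-of-grid samples clamp to
  the edge and are flagged in a validity mask.
* Jacobians use central differences, one-sided at the boundary; boundary
  voxels are excluded from "interior" guarantees.  Determinants at or
  below 1e-6 are set missing and counted; a field with more than 1% of
  nonpositive interior determinants is rejected as non-diffeomorphic.
* The subject generator retries a non-invertible warp up to five times
  with the amplitude reduced 20% per attempt (practically never needed at
  the default 2 mm scale).
* `paired_t()` returns $t=0,\,p=1$ for identically zero differences, and
  $p=0$ with a warning for degenerate nonzero differences; empty masks,
  constant images, mismatched grids, and overlapping validation/
  construction sets are all hard errors naming the offender.
* All computation is double precision; on-disk storage is 32-bit float
  (scalars, metrics, vector fields) or the smallest sufficient unsigned
  integer (labels), through the NIfTI-1 format via RNifti.

## Known limitations

* SSD demons has an aperture problem: inside homogeneous tissue the warp
  is unobservable, so ground-truth recovery plateaus around half a voxel
  of mean endpoint error even with clean data.  Displacement *comparisons*
  between templates remain valid; absolute recovered magnitudes
  underestimate the truth in flat regions.
* The greedy monotone line search can stop at a level plateau rather than
  the global optimum; the multiresolution pyramid and warm starts
  mitigate, not eliminate, this.
* The phantom anatomy is ellipsoidal and smooth; effect sizes measured on
  it do not transfer quantitatively to real cortex.
* Paired template comparisons inherit the conditional-inference caveat
  described above.
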