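# tmplkit

Groupwise diffeomorphic brain-template construction and quantitative
validation of spatial normalization, in R.

Spatial normalization — warping each subject's brain image onto a common
template — inevitably deforms the subject's anatomy, and the deformation
is smaller when the template matches the population being normalized in
sample size, age and ancestry. `tmplkit` is for researchers who want to
study that effect quantitatively and reproducibly: it provides a synthetic
3D head-phantom population generator with known ground-truth warps, a
diffeomorphic registration core, an unbiased iterative template builder,
per-voxel deformation metrics with atlas-region summaries, and paired
statistics for comparing templates on held-out subjects.

## The model in brief

* Warps are **stationary velocity fields** `v`; the deformation is the
  exponential `φ = exp(v)` (computed by scaling and squaring), a
  diffeomorphism with inverse `exp(−v)`. Displacement fields use the
  backward convention: a warped image samples its source at `x + u(x)`.
* **Registration** (`register_pair()`) is multiresolution diffeomorphic
  demons on the velocity field, with channel-weighted sum-of-squared
  differences and a monotone accept/reject step rule.
* **Template construction** (`build_template()`) iterates
  register-to-mean: average the warped subjects, then recentre by the
  inverse mean velocity `exp(−v̄)` so the population-average deformation is
  driven to zero (an unbiased template). The default schedule is six outer
  by six inner iterations.
* **Deformation metrics**: per-voxel displacement magnitude `‖u‖` in mm
  and the log-Jacobian determinant `log det(I + ∇u)` (volume change;
  `|log J|` for region means so expansion and contraction cannot cancel).
  Region means are taken over an atlas after excluding regions smaller
  than 500 mm³.
* **Template comparison** (`compare_templates()`): register held-out
  subjects to each template, transport the metric maps to a common space,
  and run a paired t-test per region with Bonferroni correction
  (`α/m`; e.g. 0.05/160 = 3.125×10⁻⁴).

See the methods vignette (`vignettes/template-deformation-methods.Rmd`)
for the full account, including every tunable parameter and the known
limitations.

## Worked example

Build a template from six synthetic subjects and inspect its convergence:

```r
library(tmplkit)

spec <- phantom_spec(grid_shape = c(48, 48, 48), spacing_mm = 4,
                     strata = data.frame(label = "60-64",
                                         n_men = 3, n_women = 3))
pop    <- lapply(generate_population(spec, seed = 42), preprocess_phantom)
params <- registration_params(pyramid_levels = 2,
                              iterations_per_level = c(3, 3),
                              channel_weights = phantom_channel_weights())
tpl <- build_template(initial_import(pop), schedule = c(3, 3),
                      params = params)
tpl
#> <brain_template> 6 subjects, 4 channels, 48 x 48 x 48 grid
#>   schedule (3, 3); final mean displacement 0.052 mm
measure_extent(tpl$channels$t1)
#> # A tibble: 1 × 6
#>   height_mm length_mm width_mm wl_ratio hl_ratio hw_ratio
#>       <dbl>     <dbl>    <dbl>    <dbl>    <dbl>    <dbl>
#> 1       112       176      144    0.818    0.636    0.778
```

The final mean displacement (0.052 mm) is the residual of the recentring
step — the distance between the template and the population's geometric
centre, driven toward zero across outer iterations (`tidy(tpl)` returns
the full trace; `autoplot(tpl)` plots it). The measured extents sit at the
generated anatomy's scale (the import step aligns all subjects to the
first subject's size, here a male phantom at scale 1.04, and template
blurring adds roughly a voxel per side); the width-to-length ratio 0.82 is
the shape signature the generator targets.

A full comparison experiment — two populations, two templates, held-out
validation, paired region statistics — is one call:

```r
cmp <- run_template_experiment("ethnicity",
                               spec = phantom_spec(grid_shape = c(48, 48, 48),
                                                   spacing_mm = 4),
                               n_a = 10, n_b = 10, n_validation = 10,
                               seed = 1, schedule = c(2, 3), params = params)
glance(cmp)    # regions tested, significant counts per direction, threshold
tidy(cmp)      # per-region means, t statistics, p values, direction flags
```

At this scale the run takes about half a minute; with seed 1 the
population-matched template shows lower mean displacement in 11 of 16
regions (1.47 vs 1.61 mm overall) with 11 regions Bonferroni-significant
in its favour across the two metric families.

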