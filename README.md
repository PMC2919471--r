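# bcdgeom

Quantitative analysis of how embryo geometry shapes the Bicoid (Bcd)
morphogen gradient in early *Drosophila* embryos.

Position along the anterior-posterior axis of an embryo can be measured two
ways: as the **projected distance** `x` onto the axis, or as the **contour
distance** `c`, the arc length along the dorsal or ventral perimeter from
the anterior pole. The two sides of the embryo have different curvatures, so
the ventral perimeter is longer than the dorsal one and the two coordinate
systems disagree side-dependently. Comparing the Bcd gradient and its target
Hunchback (Hb) between sides in both coordinate systems tests which distance
the gradient actually encodes; the package also ships a 3-D nuclear-cycle
reaction-diffusion simulator showing that the curvature difference alone
reproduces the observed dorsoventral gradient differences.

The package is aimed at quantitative developmental biologists and modellers
who need:

* dual distance systems on midsagittal embryo outlines
  (`cumulative_contour_distance`, `project_to_axis`,
  `delta_c_embryo_profile`, `average_embryo_frame`);
* sliding-window cortical intensity extraction with background subtraction,
  expression normalization and dual-axis binning (`scan_cortical_layer`,
  `bin_profiles`);
* gradient statistics: exponential fits of `B = B0 e^(-c/lambda)`,
  half-maximal boundary detection, Hill input-output fits
  `H = (B/K_d)^n / (1 + (B/K_d)^n)`, intensity-noise profiles, positional
  error `sigma_c = deltaB / |dB/dc|`, bootstrap SDs, per-bin side
  comparisons, iso-concentration contours and target-slant statistics;
* a synthetic embryo cohort generator with known ground truth
  (`cohort_spec`, `generate_cohort`, `rasterize_embryo`);
* a 3-D explicit reaction-diffusion simulator of gradient formation on an
  asymmetric semi-ellipsoid embryo with nuclear-cycle-dependent equilibrium
  DNA binding (`sim_params`, `run_simulation`,
  `extract_simulated_profiles`).

## Worked example

Generate a wild-type-like cohort of 28 embryos and run the full
dorsal-ventral comparison:

```r
library(bcdgeom)

spec <- cohort_spec(n_embryos = 28, window_spacing = 2, seed = 1)
cohort <- generate_cohort(spec)
res <- analyze_cohort(cohort_traces(cohort),
                      contours = lapply(cohort, `[[`, "contour"))

res$fit_summary
#>   side      axis lambda_mean lambda_sd lambda_se  B0_mean
#> 1    D   contour    105.0899  2.237440 0.4228364 73.56733
#> 2    V   contour    115.7590  4.097868 0.7744242 52.74611
#> 3    D projected    103.9442  2.667406 0.5040923 61.18540
#> 4    V projected    112.7009  4.237119 0.8007403 38.53664
```

The contour-distance length constants (105.1 and 115.8 um) recover the
generating values (104.8 and 115.5 um), and the ventral gradient is shallower
than the dorsal one on both axes, as in the real cohorts.

```r
res$slant$delta_x$mean   # 26.3  um: Hb boundary separation in projected x
res$slant$delta_c$mean   #  5.39 um: the same boundaries in contour distance
```

The two sides' Hb boundaries are far apart in `x` but nearly coincide in
`c` (generating truth 5.5 um) — the boundary-convergence effect that marks
contour distance as the coordinate in which positional information is laid
down.

```r
res$io_summary$Kd   # mean_D 5.23, mean_V 5.07, p = 0.59
res$io_summary$n    # mean_D 5.37, mean_V 5.43, p = 0.62
res$sigma_c         # positional error at the boundary: D 27.7 um, V 29.3 um
```

Both sides share the same input-output relationship (K_d near 5, Hill
coefficient near 5, no significant dorsoventral difference), while the
ventral side carries the larger positional error, reflecting its larger
window-level intensity noise.

Run the simulator at the reference parameters and extract analysis-ready
cortical profiles:

```r
p <- sim_params(grid_h = 5, dt = 0.5)
state <- run_simulation(p)
prof <- extract_simulated_profiles(state, p)
```

## Package layout

* `R/geometry.R` — outlines, distance systems, average frames
* `R/synthetic_cohort.R` — cohort generator and rasterizer
* `R/profile_extraction.R` — scanning windows, normalization, binning
* `R/gradient_stats.R` — fits, boundaries, noise, contours, tests
* `R/simulator3d.R` + `src/diffusion.cpp` — the 3-D nuclear-cycle model
* `R/pipeline.R` — end-to-end orchestration and TSV/JSON I/O
* `vignettes/embryo-geometry-methods.Rmd` — models, assumptions, design
  decisions and limitations
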