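# shapecurv

A hierarchical, biologically based model of 2D shape representation in
the ventral visual stream, for computational neuroscientists studying
how intermediate visual areas (V2/V4) could encode contour curvature and
shape from oriented V1 responses.

The model is a five-layer feedforward hierarchy:

1. **Simple cells** — oriented difference-of-Gaussians filters
   $D(u, v) = A\left[G(u, v;\, \sigma_l, \sigma_w) -
   G(u, v;\, \sigma_l, WR\,\sigma_w)\right]$ at 12 orientations × 4
   sizes (40, 60, 88, 120 px), a 48-member bank.
2. **Complex cells** — Gaussian-weighted sums of 5 laterally displaced
   simple cells, $C = R\!\left(\sum_i w_i R(S_i)\right)$, displaced
   perpendicular to the preferred orientation.
3. **Endstopped cells** — $E = g\!\left(R(c_c S - c_f C_{+d} - c_f
   C_{-d})\right)$, with $R$ half-wave rectification and $g$ a
   saturating sigmoid. Same-orientation flankers displaced along the
   orientation give *degree-of-curvature* selectivity (small cells
   prefer arcs of radius ≈ 6–11 px, the largest ≈ 140–300 px);
   ±45°-rotated flankers placed obliquely give *sign-of-curvature*
   selectivity (convex vs concave).
4. **Local-curvature cells** — degree responses routed by the winning
   sign into 4 scales × 2 signs = 8 signed curvature classes per
   location, with straight segments flagged as zero curvature.
5. **Shape-selective cells** — "curvature by parts": weights over
   (radial bin × angular bin × curvature class) on a polar grid
   (20 × 90 bins over a 400 × 400 canvas, hence 1,800 position bins and
   14,400 addressable curvature parts), read out with Gaussian position
   and curvature tolerance and normalized so the isolating template
   scores 1.

The package also provides the synthetic stimulus generator (bars,
circular arcs, and closed shapes composed of sharp convex corners and
medium/high convex/concave boundary elements, rotated in 45° steps),
tuning-curve tooling, neuron isolation from response profiles, and
machinery for comparing normalized model responses against external
reference responses (CSV). See `vignette("shape-representation")` for
the model account, parameter calibration and limitations.

## Worked example

```r
library(shapecurv)

cfg <- model_config()
cfg
#> <sc_config>
#>   canvas      : 400 x 400 px
#>   bank        : 12 orientations x 4 sizes = 48 filters
#>   sizes       : 40, 60, 88, 120 px
#>   polar grid  : 20 radial x 90 angular bins

# curvature tuning of the smallest degree-of-curvature endstopped cell
curve <- curvature_tuning_curve(1, 4:20, cfg)
attr(curve, "band")
#>      low     high
#> 5.095094 9.797158
```

The band says the smallest cell responds at ≥90% of its maximum to arcs
of radius ≈ 5–10 px — sharp curvature, as expected for a 40 px cell
(the published range for this architecture is 6–11 px).

```r
# isolate a shape neuron from a teardrop silhouette and probe rotations
img <- render_closed_shape(default_shape_specs()$teardrop)
neuron <- isolate_shape_neuron(img, cfg)
neuron
#> <shape_neuron> 4147 active curvature parts, origin = center, normalization = 1.354

battery <- stimulus_battery(specs = default_shape_specs()["teardrop"],
                            rotations = 4)
response_profile(neuron, battery)
#> # A tibble: 4 x 2
#>   id            response
#>   <chr>            <dbl>
#> 1 teardrop_r000    1
#> 2 teardrop_r090    0.612
#> 3 teardrop_r180    0.860
#> 4 teardrop_r270    0.612
```

The template itself scores exactly 1; rotations score less, with the
180° rotation closest because the teardrop's sharp apex and its broad
base exchange angular positions that partially match the template's
curvature classes. `autoplot()` methods visualize tuning curves,
curvature maps, profiles and comparison reports; `tidy()`/`glance()`
return the underlying tables.

A thin command-line interface over the same functions ships in
`inst/cli/shapecurv.R` (`render`, `battery`, `respond`, `tuning`,
`curvature`, `isolate`, `profile`, `compare`).

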