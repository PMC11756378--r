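# tipshape

Quantification of microtubule (MT) tip architecture and tip-bound protein
stoichiometry.

Growing MT plus ends terminate in protofilaments (PFs) that peel away from
the lattice — "flares" — and centriolar capping factors of the CP110/CEP97
family bind the luminal face of the tip, suppress flaring and stall growth.
Measuring that behaviour takes three very different assays, and `tipshape`
implements the quantitative pipeline for each of them:

1. **PF flare geometry from cryo-ET contour models.** Manually traced 3D
   PF contours are resampled at uniform arc length (default step
   *s* = 2 nm), smoothed coordinate-wise by quadratic LOESS with a 10-point
   tricube window, and summarised by discrete curvature. Curvature at
   interior point *i* is the 3D turn angle
   θᵢ = ∠(pᵢ − pᵢ₋₁, pᵢ₊₁ − pᵢ), reported per nm as θᵢ/s; for equal-arc
   samples of a circle of radius *R* this is exactly *s*/*R* radians per
   joint. Per-end statistics (mean flare length, mean and terminal
   curvature over PFs with nonzero flares), tip-aligned mean ± SEM
   curvature profiles with an OLS line, Pearson curvature–length
   correlation and per-grid capping fractions follow the conventions used
   in cryo-ET studies of MT ends.
2. **Single-molecule photometry.** Diffraction-limited spots are detected
   as thresholded local maxima and fitted with an isotropic 2D Gaussian
   *A*·exp(−((x−x₀)² + (y−y₀)²)/2σ²) + *b*; peak intensities *A* of
   single fluorophores are modelled as lognormal(μ, σ_log) with fitted mean
   exp(μ + σ_log²/2). Molecules per tip spot = tip intensity / fitted
   single-fluorophore mean; monomer/dimer standards are separated by the
   ratio of fitted means.
3. **Kymograph dynamics.** Traced segments (Δx px over Δt frames) become
   events with rate Δx·(µm/px)/(Δt·(s/frame))·60 µm/min. A segment is a
   pause iff |rate| ≤ 0.05 µm/min **and** duration ≥ 15 s (inclusive);
   shorter stalls are merged into the longer neighbour without losing
   time. Catastrophe frequency = transitions into shrinkage ÷ total time
   in growth + pause. Ends are categorised as no-pauses / occasional
   pauses / fully blocked; time-weighted rate distributions weight each
   event by its share of total time. FRAP traces are normalised to the
   pre-bleach mean.

Synthetic-data generators (`gen_flared_end()`, `gen_spot_field()`,
`gen_event_series()`) emulate each input with known ground truth, so every
pipeline is testable end to end, and `run_report()` drives the analyses
from CSV inputs to CSV/JSON outputs with a provenance block.

## Worked example

```r
library(tipshape)

# a 14-PF MT end with 40-nm flares of curvature radius 25 nm
end <- gen_flared_end(radius = 25, flare_arc_length = 40, noise_sigma = 0.3,
                      n_pf = 14, cap_state = "none", seed = 42)
per_end_stats(end)
#> <per_end_stats g1/mt1 (plus, cap none): L=40.29 nm, k=2.425 deg/nm, kt=2.441 deg/nm, 14/14 PFs>

# single-fluorophore calibration and molecule counting at blocked tips
ref <- fit_lognormal_intensities(rlnorm(2000, 5, 0.3))
ref
#> <intensity_model: mu=5.018, sigma_log=0.304, fitted mean=158.3 (n=2000)>
molecules_per_spot(replicate(200, sum(rlnorm(6, 5, 0.3))), ref)
#> <stoichiometry_result: mean 5.83 molecules (range 3.67-7.53, n=200)>

# kymograph segments -> classified dynamic events
ev <- segments_to_events(data.frame(mt_id = "mt1", dx_px = c(50, 0, -300),
                                    dt_frames = c(100, 6, 10)),
                         kymo_calibration(0.064, 3))
ev
#>   mt_id     class rate_um_min duration_min tip_marker
#> 1   mt1    growth        0.64          5.0          0
#> 2   mt1     pause        0.00          0.3          0
#> 3   mt1 shrinkage      -38.40          0.5          0
end_category(ev)
#> [1] "occasional_pauses"
```

The per-end summary reads: mean flare length 40.3 nm (truth 40), mean
curvature 2.43°/nm against the analytic 2.29°/nm for a 25-nm radius
(mild upward bias from point noise folding into unsigned angles), all 14
PFs flared. The six-fluorophore tip spots count as 5.8 molecules against
the single-fluorophore standard, and the kymograph trace parses into a
0.64 µm/min growth phase, an 18-s pause and a catastrophe.

## Layout

- `R/pf-trace.R`, `R/pf-geometry.R` — contour types and the flare pipeline
- `R/spot-photometry.R` — detection, Gaussian fits, lognormal calibration
- `R/kymo-dynamics.R` — events, pauses, catastrophes, FRAP
- `R/synthetic-data.R` — ground-truth generators
- `R/io.R`, `R/report.R` — CSV schemas and the end-to-end report
- `vignettes/tipshape-methods.Rmd` — models, assumptions, numerical choices
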