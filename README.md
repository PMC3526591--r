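# gradchamber

Quantitative analysis for direct-viewing gradient-chamber chemotaxis assays
in 3D collagen gels.

In these assays a chemoattractant reservoir is separated from a cell-seeded
collagen gel by a porous membrane. Injecting the chemoattractant (e.g. IL-8,
with neutrophils embedded in the gel) sets up a diffusive gradient; cells are
imaged once per minute before and after the injection, so every experiment
carries its own unstimulated control. Two questions must be answered
quantitatively: *what gradient did the cells actually see*, and *how did
their motility change*. `gradchamber` answers both, for experimentalists
running such chambers and for anyone building or validating trajectory-based
chemotaxis metrics.

## What it computes

**Gradient characterization.** The concentration in the gel follows Fick's
second law; with the membrane held at half the reservoir concentration the
semi-infinite-slab solution is

    C(y, t) / C0 = 1/2 · erfc( y / (2·√(D·t)) )

(`closed_form_profile()`). `solve_chamber_1d()` solves the finite
three-section chamber (reservoir–membrane–gel, no-flux walls, piecewise
diffusivity) with a mass-conserving Crank–Nicolson scheme,
`fit_diffusion_coefficient()` estimates D from concentration time series by
bounded least squares on log10(D), and `fit_calibration()` /
`gray_to_concentration()` map epifluorescence mean gray levels to tracer
concentration through the linear calibration.

**Motility statistics.** From tracked positions (`track_set()`,
`read_tracks()`): the cumulative chemotactic index — per cell, net
displacement along the gradient over curvilinear path length, in [-1, 1];
per population, the path-length-weighted mean, reported at 5-min steps
(`chemotactic_index_series()`) — plus the motile fraction (net 10-min
displacement strictly exceeding the cell's own diameter,
`motile_fraction()`), binned velocity components and modulus
(`velocity_series()`), per-cell pre/post-stimulus speeds
(`per_cell_mean_speed()`), and the percentage of cells whose velocity
distribution rejects the unbiased null under a per-cell t-test
(`biased_fraction_ttest()`).

**Synthetic experiments.** `simulate_tracks()` generates biased persistent
random walks coupled to the simulated gradient (drift proportional to the
local normalized concentration gradient, switching on only when the
diffusing front reaches each cell), with known ground truth;
`make_fixture_experiment()` packages three profiles ("donorA-like",
"donorB-like", "isotropic"). `run_full_pipeline()` chains everything from a
validated JSON configuration.

## Worked example

```r
library(gradchamber)

# gradient after 2 h, default chamber, D = 2e-6 cm^2/s
field <- solve_chamber_1d()
round(eval_field(field, c(0, 2, 3, 5), 7200), 4)
#> [1] 0.5000 0.1193 0.0386 0.0031
closed_form_profile(2, 7200)
#> [1] 0.1192964

# recover D from noisy observations at the imaged distances
obs <- expand.grid(y_mm = c(2, 3, 5), t_s = seq(300, 7200, 300))
set.seed(1)
obs$c_norm <- closed_form_profile(obs$y_mm, obs$t_s) + rnorm(nrow(obs), sd = 0.01)
fit_diffusion_coefficient(obs)
#> Diffusion fit (closed_form model): D = 2.07e-06 cm^2/s, RMSE = 0.00907 (n = 72)

# synthetic 70-cell experiment, stimulus at 30 min, and its index series
ex <- make_fixture_experiment("donorA-like", seed = 30)
ci <- chemotactic_index_series(ex$tracks)
tail(ci, 3)
#>    t_min        ci n_cells
#> 20   100 0.3079413      70
#> 21   105 0.3294829      70
#> 22   110 0.3491271      70
round(motile_fraction(ex$tracks)$fraction, 2)
#>  [1] 0.00 0.00 0.00 0.40 0.33 0.41 0.43 0.44 0.51 0.51 0.51
```

Reading the numbers: the membrane–gel interface sits at C/C0 = 0.5 while the
profile decays into the gel (0.119 at 2 mm after 2 h); the fitted D lands
within a few percent of the generating 2e-6 cm²/s at realistic noise; and
the donor-A-like population is unbiased and immotile before the stimulus
(index ≈ 0, motile fraction 0 in the first three 10-min windows) and becomes
directed and motile afterwards (index rising to ≈ 0.35, motile fraction
≈ 0.5).

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data and
write tables under `results/` (bulky grids and figures go to `scratch/`):

1. `01_gradient_field.R` — chamber solve, interface series, closed-form vs
   numeric comparison, mass-conservation audit.
2. `02_calibration_and_D_fit.R` — calibration fit, emulated gray-level
   series, D recovery with both forward models.
3. `03_simulate_experiments.R` — the three fixture experiments with ground
   truth.
4. `04_motility_statistics.R` — motility reports, pre/post speed
   histograms, figures rebuilt from the CSVs alone.
5. `05_full_pipeline.R` — the seeded end-to-end pipeline.

Run each with `Rscript analysis/01_gradient_field.R` (etc.) from the
repository root, in order.

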