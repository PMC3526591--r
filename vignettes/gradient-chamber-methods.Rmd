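---
title: "Models and methods behind gradchamber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gradchamber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradchamber)
```

# The assay this package quantifies

In a direct-viewing gradient chamber, a chemoattractant reservoir is
separated from a cell-seeded 3D collagen gel by a porous membrane. After the
chemoattractant is injected into the reservoir (30 min into time-lapse
acquisition in the emulated experiment), it diffuses through the membrane and
establishes a concentration gradient in the gel; cells — neutrophils
responding to IL-8 in the motivating application — are tracked once per
minute, and their motility is quantified before and after the stimulus, so
each experiment carries its own unstimulated control. `gradchamber`
implements the two quantitative halves of that workflow: characterizing the
gradient, and reducing trajectories to motility statistics. A biased
persistent random-walk generator supplies synthetic experiments with known
ground truth so every estimator can be validated without experimental data.

# Gradient physics

## Closed form

Treating the gel as a semi-infinite medium whose boundary (the membrane) is
held at half the reservoir concentration, Fick's second law with zero initial
concentration gives

$$\frac{C(y,t)}{C_0} \;=\; \tfrac{1}{2}\,
  \mathrm{erfc}\!\left(\frac{y}{2\sqrt{D t}}\right),$$

with $y$ the distance from the membrane (mm here), $t$ the time since
chemoattractant addition and $D$ the diffusion coefficient (quoted in
cm^2/s, the customary unit for small solutes; all unit conversions are
centralized in the package). The factor 1/2 at the boundary arises because
the membrane sits between a reservoir at $C_0$ and an initially empty
half-space of equal diffusivity. `closed_form_profile()` implements this via
the `pnorm` identity for erfc; the test suite cross-checks it against an
independent erfc implementation and verifies the PDE residual under central
differences on a fine grid. The corner $y = 0, t = 0$ returns 0.5 (the right
limit in $t$), matching the imposed boundary value.

## Finite chamber

`solve_chamber_1d()` drops the semi-infinite idealization: the full axis —
reservoir (20 mm by default), membrane (0.15 mm), gel (5 mm) — is discretized
(default $\Delta y$ = 0.05 mm, $\Delta t$ = 10 s) with no-flux boundaries at
both outer walls and a piecewise diffusivity (a configurable multiplier
inside the membrane, 1 by default: 0.22 µm pores do not hinder a ~10 kDa
tracer). The 1D reduction is justified by the observation that the profile in
this geometry depends on the membrane distance only; lateral effects of the
frame windows are confined to the immediate vicinity of the membrane and are
out of scope. The spatial operator is written in conservative flux form with
harmonic-mean face diffusivities, so discrete total mass is conserved to
machine precision (the tests require relative drift below 1e-6; measured
drift is ~1e-13). Time stepping is Crank–Nicolson with the constant system
matrix factored once; an explicit scheme is available and refuses to run,
with the offending numbers, when its CFL condition fails.

Two numerical choices deserve explanation:

* **Wetted membrane initial condition.** By default the membrane pore volume
  starts at the reservoir concentration. An initially dry 0.15 mm membrane
  would hold the membrane–gel interface near 0.38 C0 at 10 min and only
  ~0.46 C0 after 2 h — at odds with the assay's observed behaviour, where
  the interface sits at C0/2 essentially from the start and the semi-infinite
  solution matches the full solve closely. Physically, the membrane floods
  during the ~1 min injection of chemoattractant solution. The alternative
  (`membrane_initial = "empty"`) is retained for sensitivity analysis.
* **Volume-fraction initialization.** The initial concentration jump is
  assigned to nodes by the filled fraction of each control volume, so the
  jump sits exactly at the section boundary whatever the grid alignment;
  without this the profile inherits a half-cell offset (an error of ~0.02 on
  C/C0 at the interface for $\Delta y$ = 0.1 mm).

With the defaults, the interface stays at 0.500 throughout 0–2 h and the
finite solve differs from the closed form by at most ~1.5e-3 on the C/C0
scale at the imaged distances (2, 3, 5 mm). Note on comparison metrics: at
5 mm the profile is ~0.002 C0 at 2 h and the no-flux far wall roughly doubles
it, so a *relative* comparison there is meaningless; the package's checks
bound the absolute discrepancy on the normalized scale everywhere and the
relative discrepancy wherever the profile exceeds 0.05.

## Estimating D, and the fluorescence calibration

`fit_diffusion_coefficient()` minimizes the sum of squared residuals between
observed normalized concentrations and either forward model, over
$\log_{10} D$ on $[10^{-8}, 10^{-4}]$ cm^2/s by golden-section search —
deterministic, and well-conditioned because the single parameter enters
through $y/\sqrt{Dt}$ only (the tests verify the resulting diffusive-scaling
invariance $t \to kt,\ y \to \sqrt{k}\,y$). Degenerate inputs (fewer than 3
points, no time spread, all-zero concentrations) are refused with
diagnostics.

Concentration is observed through epifluorescence: mean image gray level is
linear in tracer concentration over the working range (0.2–120 µM in the
emulated calibration), so `fit_calibration()` is ordinary least squares
(through `stats::lm`; the tests verify equality with the textbook closed
form) and `gray_to_concentration()` inverts it, flagging — not rejecting —
values outside the fitted range.

# Trajectory statistics

All statistics default to the XY projection: the imaging z-step is coarse
(tens of µm) and low-precision, so including z mainly adds noise; `"xyz"` is
available throughout. Time bins are half-open $[t_0, t_0 + w)$; windows and
cumulative-index intervals are closed so the sample at a window's right edge
closes its displacement.

* **Chemotactic index.** Per cell, net displacement along the gradient
  direction divided by curvilinear path length, in $[-1, 1]$. The population
  value is the mean weighted by each cell's path length; stationary cells
  carry zero weight (rather than an index of 0), which the weighted mean
  enforces automatically. The cumulative index accumulates from the
  experiment start by default (`t_origin` is configurable for
  from-stimulus sensitivity analyses) and is reported at 5-min steps.
* **Motile fraction.** A cell is motile in a 10-min window when its net
  displacement *strictly* exceeds its own diameter ("exceeds" is read as
  strict; the boundary case is non-motile). The threshold screens out stage
  repositioning error. Cells missing from a window leave its denominator.
  Cells without a recorded diameter default to 10 µm, a typical neutrophil.
* **Velocities.** Backward differences per frame (the first frame has no
  velocity); gaps are averaged over the actual elapsed time and flagged when
  longer than twice the frame interval. The binned modulus is the mean of
  per-frame moduli — a speed — not the norm of the mean velocity.
* **Biased-cell fraction.** Per 5-min bin and per cell with at least 3
  velocity samples, a two-sided one-sample t-test at $\alpha$ = 0.05 (no
  multiple-testing correction; the statistic *is* the per-cell tally of
  rejections). Components are tested against zero. The modulus cannot be
  tested against zero (it is positive under any null); it is tested against
  the bin's population-mean modulus, a delta-from-baseline reading that is
  flagged as an interpretation in the documentation.

A caveat the tests document deliberately: curvilinear length depends on
sampling resolution — subsampling frames can only shorten the measured path,
which inflates the index's denominator less and so biases the index upward at
coarser sampling. Comparisons across acquisitions should use matched frame
rates.

# The synthetic-data generator

`simulate_tracks()` draws mover cells with probability `motile_fraction_pre`
(re-drawn with `motile_fraction_post` at the stimulus, reproducing the
observed rise), seeds all cells uniformly in a 1 mm × 1 mm × 100 µm imaging
volume centred 2 mm from the membrane, and evolves mover velocities by the
AR(1) persistent walk

$$v(t + \Delta t) \;=\; \alpha\,v(t) + (1 - \alpha)\,
  \big(d(t)\,\hat g + s\,\eta\big),$$

with spherical standard-normal noise $\eta$, speed scale $s$ per period, and
drift magnitude $d(t) = b + \chi\,|\partial (C/C_0)/\partial y|\,e^{-(t -
t_s)/\tau}$ evaluated at the cell's own current membrane distance — cells
feel nothing until the diffusing front reaches them. Non-movers jitter
around an anchor with 0.3 µm amplitude (stage error scale). Velocities are
initialized from the AR(1) stationary distribution. All randomness flows
from one seed, the caller's RNG state is restored, and identical seeds give
identical experiments byte for byte.

Default conditions are those of the emulated experiment: 70 cells, 110 min
at 1 frame/min, stimulus at 30 min, gradient direction $(0,-1,0)$,
$D = 2\times10^{-6}$ cm^2/s. Basal mover speed scale is 0.65 µm/min (the
emulated donor A's basal mean velocity) rising to 3 µm/min, putting
stimulated movers in the 2–7 µm/min band; motile fraction rises 0.2 → 0.6;
persistence $\alpha$ = 0.5. The transient decay of the response (plausibly
receptor saturation) is modelled purely phenomenologically by the
exponential envelope on $\chi$ — no mechanism is claimed.

The packaged fixtures set these dials to three profiles: `donorA-like`
(low basal motility, basal index ≈ 0, sustained post-stimulus response,
$\chi$ = 20), `donorB-like` (higher basal motility with a pre-existing bias
— basal index ≈ 0.25, reproduced by an explicit 0.5 µm/min baseline drift, a
modelling choice — and a transient response that peaks and decays), and
`isotropic` (no response; the control). For donor B the envelope must be
fast and the coupling strong ($\tau$ = 12 min, $\chi$ = 600 µm/min per unit
normalized gradient): the diffusive front at 2 mm builds its gradient only
tens of minutes after addition, so the drift — the product of a growing
gradient and a decaying envelope — peaks where
$\mathrm{d}\ln g/\mathrm{d}t = 1/\tau$, about 30 min post-stimulus, and then
fades, giving the rise-to-≈0.5-then-decay index shape this profile exists to
emulate.

What the generator does *not* emulate: cell–cell interaction, chemoattractant
consumption or degradation, matrix remodelling and contact guidance,
segmentation/tracking errors other than isotropic jitter, and z-resolution
anisotropy. Passing recovery tests therefore demonstrates estimator
correctness under the stated generative model, not robustness to every
feature of real microscopy data.

## Statistical calibration and persistence

One subtlety the test suite makes explicit: the one-sample t-test's nominal
5% type-I level presumes independent samples. Persistent velocities
($\alpha$ = 0.5) are serially correlated within a 5-min bin, inflating the
variance of the bin mean by roughly $(1+\alpha)/(1-\alpha)$ and hence the
rejection rate (to ~20% in practice). That is a property of persistence, not
a defect of the test, and it affects pre- and post-stimulus bins equally, so
the *transient peak* in the y-component rejection fraction remains the
meaningful signal. The package's calibration check accordingly uses
zero-persistence walks, whose velocities are i.i.d. Gaussian and reproduce
the 5% level, while the null-index check ($|I| \le 0.05$ with 1000 cells)
runs at $\alpha$ = 0.5.

# Problem sizes

The validation suite runs the chamber solve at the default grid (~500 nodes,
720 steps, well under 10 s), D-recovery with 20 noisy replicates, statistical
calibration on 1000-cell ensembles, and estimator recovery pooled over 10
seeds at the study scale of 70 cells — sizes chosen so every check completes
on a laptop in minutes while keeping Monte-Carlo error well inside the
asserted tolerances.

# Known limitations

The chamber model is 1D; near-membrane lateral effects of the frame windows
are not modelled. Reservoir depletion is captured, but convective transport,
interstitial flow and chemoattractant degradation or cell-mediated
consumption are not (cell densities in the emulated assay are chosen
precisely so cells do not perturb the gradient). Trajectory statistics take
tracking as given — detection, segmentation and linking are upstream
problems. Persistence-time estimation and random-motility-coefficient
fitting are deliberately not implemented.
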