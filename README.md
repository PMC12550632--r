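# cellavidity

Analysis of single-cell **avidity** measurements from centrifuge force
microscopy (CFM). In a CFM assay, cells bound to a functionalized surface
sit inside a benchtop centrifuge together with a miniature fluorescence
microscope; the rotor applies a uniform, tunable pulling force to every
cell in the field of view while the camera counts the cells that remain,
frame by frame. One run yields hundreds to thousands of single-cell
unbinding events, enough to compare the multivalent binding strength of
different receptors, ligand densities, or cell types.

The package is for biophysicists and immunologists analyzing such assays
(e.g. T cells engaging bispecific T-cell engagers), and it ships a full
stochastic simulator of the experiment so every stage of the analysis can
be validated against known ground truth.

## The models at the core

**Force model.** A cell of diameter *d* with density ρ_cell in a medium of
density ρ_med has effective mass
*m* = (π/6) d³ (ρ_cell − ρ_med), and at rotor speed ω and radius *r*
experiences *F* = *m r* ω². For the default cell (10 µm, 1.07 g/mL in
1.00 g/mL medium) this gives ≈0.36 pN under 1 g (the inverted-chamber
"gravity interval") and ≈482 pN at 3000 rpm. Stair-step rpm schedules are
designed so the force follows a linear ramp *F(t)* = *Ḟ*·*t* (2–16 pN/s).

**Detachment kinetics.** The fraction of cells still bound during a ramp
is well described by a stretched exponential

    f(t) = 1 − g + g · exp(−(t/τ)^β)

with detachable fraction *g*, population lifetime τ, and stretching
exponent β (>1 when the rising force accelerates the off-rate).

**The universal curve.** If each cell forms a Poisson(λ) number of bonds,
the adhesion frequency (fraction surviving the gravity interval) is
AF(λ) = 1 − e^(−λ), and for independent, load-sharing bonds the
population lifetime is approximately τ(λ) = k·λ + x₀. Varying λ (e.g. by
surface concentration) traces a single parametric curve in the (AF, τ)
plane; the fitted slope *k* measures per-bond strength under the given
ramp, independently of receptor density.

**Simulator.** Bonds rupture with the Bell rate k₀·exp(F/(b·F_β)) when *b*
bonds share the load F; rupture cascades are sampled exactly (closed-form
inversion of the cumulative hazard on piecewise-linear force schedules).
Synthetic dual-channel image stacks and a classical
difference-of-Gaussians cell counter close the loop from photons to
kinetic parameters.

## Worked example

```r
library(cellavidity)

cell_params()
#> <cell_params> d = 10 um, rho_cell = 1.07 g/mL, rho_medium = 1 g/mL
#>   effective mass 3.665e-14 kg, 1 g force 0.360 pN

force_at_rpm(3000)
#> [1] 481.8041

# 2-min gravity interval, then 4 pN/s to 480 pN, final speed held 420 s
protocol <- design_ramp(4, f_max = 480, t_start = 120, hold_duration = 420)

trial <- simulate_trial(bond_model(lam = 1.5, f_beta = 11), protocol,
                        n_cells = 1000, seed = 42)
adhesion_frequency(trial$count_trace)
#> <adhesion_result> AF = 0.752 (754.5 / 1003 cells, 120 s gravity interval)
# Poisson expectation at lambda = 1.5: 1 - exp(-1.5) = 0.777

curve <- build_detachment_curve(trial$count_trace, "centrifuge_start",
                                t_origin = 120)
fit_stretched_exponential(curve)
#> <stretched_exp_fit> g = 0.999, tau = 48.73 s, beta = 2.304 (rmse 0.0201, n = 2161)

# a whole condition in one call: simulate 10 trials across lambda,
# fit each, then fit the universal curve
report <- run_pipeline(list(simulate = list(n_trials = 10, f_beta = 11),
                            seed = 42, condition = "demo"))
report$universal
#> <universal_curve_fit> k = 14.11 s/bond, x0 = 28.39 s (rmse 0.008, 10 trials, ols)
```

The adhesion frequency sits within counting error of the Poisson
expectation; τ grows with λ; and across trials the (AF, τ) points fall on
a universal curve whose slope *k* (seconds of lifetime per bond) reflects
per-bond strength under this ramp.

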