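---
title: "Models and methods for CFM cell-avidity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for CFM cell-avidity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellavidity)
```

# The measurement

A centrifuge force microscope (CFM) spins a sealed imaging chamber so that
every cell adhering to the functionalized surface feels the same
centrifugal pull, while a miniature fluorescence microscope in the rotor
bucket records the field of view. An assay has three phases:

1. **Flip.** The chamber is inverted at `t = 0`; gravity now pulls cells
   away from the surface with ~0.36 pN per cell. Non-adherent cells
   sediment out of view.
2. **Gravity interval** (default 120 s). The fraction of cells remaining
   at its end, relative to the count at the flip, is the **adhesion
   frequency** (AF).
3. **Force ramp.** The rotor accelerates through a stair-step rpm schedule
   realizing a linear force ramp (2–16 pN/s, up to ~480 pN at the 3000 rpm
   ceiling of the default rotor), and the per-frame count of remaining
   cells yields the **detachment curve**.

This vignette records the models the package implements, the parameters
that matter, the numerical choices, and what the built-in simulator does
and does not emulate.

# Force model

The per-cell force is $F = m\,r\,\omega^2$ with effective mass
$m = \tfrac{\pi}{6} d^3 (\rho_{cell} - \rho_{med})$. Parameters and
defaults:

| parameter | default | unit | meaning |
|---|---|---|---|
| `diameter_um` | 10 | µm | cell modeled as a sphere |
| `cell_density` | 1.07 | g/mL | typical lymphocyte value |
| `medium_density` | 1.00 | g/mL | aqueous buffer |
| rotor radius | 0.1332 | m | from the rpm↔g calibration 3000 rpm ↔ 1340 g |
| g | 9.81 | m/s² | fixed |

The rotor radius is not directly measurable on an assembled instrument;
we derive it from the printed rpm-to-acceleration pairs (300 rpm ↔ 13 g,
3000 rpm ↔ 1340 g). Some descriptions of the same instrument class quote
~1600 g at 3000 rpm, implying r ≈ 0.159 m; if that matches your rotor,
pass `radius` explicitly — all forces scale linearly with it. With the
default radius the 3000 rpm ceiling corresponds to 481.8 pN for the
default cell, which is why ramp protocols in this package target 480 pN
rather than the rounded 500 pN often quoted.

`design_ramp()` places each stair step's force on the target line at the
step midpoint, so the instantaneous deviation from the ideal ramp is at
most `loading_rate * step_duration / 2` (0.5 pN at 4 pN/s and 0.25 s
steps). Force within a step is modeled as constant; spin-up transients
below 300 rpm are not modeled (the analysis windows that matter start
after the gravity interval, and detachment-curve fitting is robust to the
first fraction of a second of the ramp).

# Detachment curves and adhesion frequency

Per-frame counts fluctuate by a few cells from frame to frame because of
imperfect detection, so no quantity is ever normalized by a single frame:
endpoint counts are medians over a ±2 s window, and curves are median
filtered (5 frames) before normalization. Two time origins are supported
and recorded explicitly: `"flip"` (the AF denominator) and
`"centrifuge_start"` (the lifetime-fitting origin). The normalized curve
is pinned to 1 at its origin; upward excursions above `1 + jitter_tol`
(default 0.05) are flagged, not truncated. A monolayer-channel QC check
flags trials whose monolayer count drops by more than 20% (bubbles,
delamination); flagged trials are kept — dropping is the analyst's
decision.

# Kinetic models

## Stretched-exponential lifetime

The fraction bound under a ramp is fit to
$f(t) = 1 - g + g\,e^{-(t/\tau)^\beta}$ by bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`). Bounds and initialization are fixed and
deterministic — no random restarts:

* $g \in [0, 1]$, initialized at $1 - \min f$;
* $\tau \in (0, 10\times\text{span}]$, initialized at the half-decay
  time of the detachable fraction;
* $\beta \in [0.2, 5]$, initialized at 1 (plain exponential).

A curve whose total drop is below 2% is degenerate for this family: the
fit would be unidentifiable, so `g` is pinned at its lower bound and the
result flagged instead. Non-convergence is likewise flagged, never
silent. On noiseless synthetic curves the fit recovers parameters to
better than $10^{-6}$ relative; under 5% multiplicative noise, to a few
per mil (τ) — the test suite checks both.

## Universal curve

With Poisson-distributed bond numbers, $AF(\lambda) = 1 - e^{-\lambda}$
exactly, and for independent bonds loaded in parallel the population
lifetime grows approximately linearly, $\tau(\lambda) = k\lambda + x_0$.
How to fit the parametric pair $(AF(\lambda), \tau(\lambda))$ to per-trial
points is genuinely open; we chose the exact inverse
$\lambda_i = -\ln(1 - AF_i)$ followed by ordinary least squares of
$\tau_i$ on $\lambda_i$, because the inverse is closed-form and makes the
fit linear and deterministic. An orthogonal-distance variant in the
$(AF, \tau)$ plane is available (`method = "orthogonal"`) for sensitivity
analysis. Trials are weighted equally by default (per-trial scatter is
the natural unit of replication); weighting by cell count is available
behind a flag.

Two numerical conventions to note:

* AF = 1 cannot be inverted; values at or above `af_cap = 0.999`
  (λ ≈ 6.9) are capped and flagged.
* The reported RMSE is the orthogonal distance to the parametric curve in
  the $(AF, \tau/\mathrm{sd}(\tau))$ plane. Scaling τ by its sample SD
  makes the two axes commensurate; this definition is local to the
  package and stated here so its numbers are not compared to other
  conventions.

## Off-rate versus force

Binning the force axis (default 20 pN), the population off-rate in a bin
is $\Delta N_{det} / (N_{avail}\,\Delta t)$. Bins with fewer than 5
available cells are masked — the estimator there is dominated by shot
noise. Two caveats follow from the definition: the discrete estimator
saturates when the per-bin detachment probability is large (interpret
only bins with modest per-bin decay), and on mixed-valency populations
the high-force tail is dominated by multiply-bonded survivors, producing
the characteristic plateau/suppression relative to the single-bond Bell
line. On single-bond simulations the estimator recovers the Bell slope
$1/F_\beta$ within a few per cent.

# The simulator

The generator emulates the assay's statistical structure:

* bonds per cell $x \sim \mathrm{Poisson}(\lambda)$;
* zero-bond cells depart during the gravity interval with a 5 s
  sedimentation lag plus an Exp(10 s) spread — at 1 g a 10 µm cell with
  0.07 g/mL density contrast falls only ~4 µm/s, so departures are
  invisible in the first frames (this keeps the initial count an unbiased
  denominator for AF);
* bonded cells rupture by a cascade of Bell-rate failures,
  $k(F, b) = k_0 e^{F/(b F_\beta)}$ with equal load sharing among the $b$
  surviving bonds and no rebinding (independent, non-cooperative bonds);
* per-frame counts at 4 frames/s with symmetric detection noise: each
  cell missed with probability 0.02 per frame, compensated by
  Poisson-distributed spurious detections with the same mean, so counts
  are unbiased.

Because every protocol is piecewise-linear in force, the cumulative Bell
hazard has a closed form per segment and rupture times are drawn by
**exact inversion** — no time discretization, no rejection step. A scalar
engine accepting arbitrary monotone hazards (e.g. catch-slip variants)
via per-segment thinning is provided for experimentation, and the two
engines are cross-checked distributionally in the tests, together with a
direct master-equation oracle for small bond numbers.

The per-bond hazard is the minimal (Bell) model consistent with
independent parallel bonds; the simulator claims no particular molecular
values. `calibrate_bond_params()` makes that explicit: it maps a target
universal-curve slope onto simulator inputs by root-finding. Since the
slope depends on $(k_0, F_\beta)$ essentially through the most probable
per-bond rupture force $F_\beta \ln(\dot F / (k_0 F_\beta))$, the pair is
ridge-degenerate for this objective; calibration therefore fixes
$k_0 = 10^{-5}\,/s$ (small enough that rupture during the ~0.36 pN
gravity interval is negligible, preserving the Poisson AF closure) and
bisects on $F_\beta \in [4, 30]$ pN. The pilot objective is the median
slope of a full simulated pipeline (40 λ values in [0.2, 5], 1000
cells/trial) averaged over 6 fixed-seed replicates: a single noisy pilot
would hand its seed's offset to the calibration, defeating the 2%
calibration tolerance.

**Standard simulated protocol.** Calibration and the parameter-recovery
studies use: 120 s gravity interval, 4 pN/s stair ramp (0.25 s steps) to
480 pN, then the final speed held for 420 s. The terminal hold is a
protocol design choice: populations near the strong end of the calibrated
range (slopes ~25 s/bond) have lifetimes at high λ exceeding the 120 s
ramp itself, and without a hold their lifetime fits are censored at the
ramp end, which makes the calibration objective noisy and non-monotone.
Real trials run on this timescale (~10–15 min including handling), so the
hold is within normal operating practice.

**What the simulator does not emulate.** Membrane mechanics, contact-area
growth, receptor diffusion or clustering, activation-driven avidity
changes over time, rebinding, and real-image nuisances (debris, bubbles,
focus drift) are all out of scope. Passing the synthetic end-to-end tests
therefore validates the *analysis chain* — counting, normalization,
fitting, calibration — not the biological completeness of the bond model.
The offset $x_0$ (nonzero lifetime as AF → 0) has no mechanism in the
simulator beyond an optional background-adhesion fraction (default 0);
its simulated value is an emergent property of the cascade, not a claim
about any particular receptor.

# Imaging module

The real instrument alternates LED color frame by frame (even frames:
target cells; odd: monolayer) and counts cells with a trained network.
Training data and weights are not reproducible from a published
description, and the downstream analysis needs only counts, so the
package renders synthetic scenes (Gaussian-blob cells, constant
background, Gaussian read noise, 170 nm pixels by default) and counts
them with a deterministic classical detector: difference-of-Gaussians
band-pass (σ = 2 and 6 px around the default 3 px cell), a robust
threshold at median + 6·MAD of the filtered image, connected components
with an area gate of [4, 2000] px. At SNR 5 with non-overlapping cells
the detector counts exactly; the per-frame miscount magnitude of real
data is not quantified, so the simulator's 2% default is an assumption
and is parameterized.

# Problem sizes used in validation

The shipped tests and the acceptance script use: 1000 cells/trial, 30
trials per condition over λ ∈ [0.2, 5], medians over 20 seeds for
parameter-recovery studies; 10⁵–2×10⁵ samples for distributional oracles;
512×512 px frames for imaging checks (the full 4096×2160 sensor is
supported). These sizes keep every distributional comparison's sampling
error comfortably below the tolerance it is compared against.

# Known limitations

* The universal-curve slope *k* is meaningful only relative to a stated
  ramp; comparing *k* across loading rates requires re-calibration.
* OLS on $(\lambda_i, \tau_i)$ treats λ as exact; at high AF the
  inversion amplifies counting noise into λ. With 1000 cells/trial the
  resulting attenuation is ≲3% and is absorbed by calibration, but
  analyses of much smaller trials should prefer the orthogonal fit.
* The off-rate estimator is a population quantity; it coincides with the
  molecular off-rate only for single-bond populations.
* The stretched-exponential τ of heavily censored curves (little decay
  within the protocol) is extrapolated and flagged; design protocols long
  enough for the populations you expect.
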