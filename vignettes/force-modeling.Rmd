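---
title: "Piecewise Fourier modeling of needle-insertion forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise Fourier modeling of needle-insertion forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needleforce)
```

## The problem

When a biopsy needle is driven through the trunk it crosses skin, fat,
muscle and an organ capsule before reaching parenchyma. The axial force
trace shows a characteristic anatomy: quadratic stiffness ramps while a
layer loads, abrupt drops when it ruptures, and oscillatory
friction/cutting plateaus afterwards. In vivo the trace is additionally
modulated by respiration, because the target organ moves several
millimetres cranio-caudally with each breath. Simulators that replay such
forces through a haptic device need a compact model that (a) reproduces
the oscillatory fluctuation that polynomial or exponential force laws
cannot, and (b) can be evaluated sample-by-sample at a nominal 1000 Hz.

## The force model

Each phase of a segmented trace is treated as one period of a periodic
function — the *periodic extension* of the segment — and approximated by
a finite trigonometric series

$$y(x) = \alpha_0 + \sum_{n=1}^{N}\left[\alpha_n \cos(n\omega x) +
  \beta_n \sin(n\omega x)\right].$$

Two conventions needed fixing:

* **Offset.** The classical coefficient formulas can be written with
  $\alpha_0$ as either $(2/T)\int y\,dx$ or $(1/T)\int y\,dx$ depending
  on whether the constant term enters the series halved. We adopt
  $\alpha_0 = (1/T)\int y\,dx$ — the signal mean — so that a constant
  signal is represented exactly by the offset alone. `analytic_coefficients`
  returns `(mean(y), 0)` for $n = 0$ accordingly.
* **Fundamental.** With `omega_mode = "fixed"` the fundamental is pinned
  (by default $\omega = 2\pi/\mathrm{span}$, the periodic extension of
  the fitted segment; any positive value may be supplied) and the fit is
  linear least squares on the trigonometric design matrix, solved by QR.
  With `omega_mode = "free"` (the default) $\omega$ is an additional
  nonlinear parameter. Rather than running Levenberg–Marquardt over all
  $2N + 2$ parameters, the coefficients are profiled out: for any
  candidate $\omega$ the inner problem is linear, so LM only searches the
  one-dimensional $\omega$ axis (variable projection). This is better
  conditioned than the joint search and makes the fixed-omega solver the
  single point of truth for the linear algebra. The cost surface in
  $\omega$ is multimodal, so the search restarts from five log-spaced
  values in $[0.2, 5]\times 2\pi/\mathrm{span}$ and keeps the best; if
  every start fails, a convergence error carrying the best linear
  solution is raised.

### Order selection

The harmonic order $N$ is capped at 8 by default and chosen per phase
from the spectrum: the periodogram of the mean-removed, untapered segment
is computed, the harmonic bins of the fundamental $1/\mathrm{span}$ are
located by nearest frequency bin, and the smallest $N$ whose first $N$
harmonics capture at least 99% of the non-DC energy is returned.
Broadband segments that never reach the threshold get $N = 8$ with a
warning. No taper is applied: the segments are short and the selection
only needs the gross energy ordering, not unbiased spectral density.

### Goodness of fit

The *fitting degree* is the coefficient of determination
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, the default goodness-of-fit
statistic of standard curve-fitting workflows. It reaches exactly 1 for a
perfect fit and can be negative for fits worse than the observed mean.
Adjusted $R^2$ was considered and rejected: piecewise reports routinely
contain values of exactly 1 on noiseless segments, which adjusted $R^2$
would not produce. Per-phase values are combined by the unweighted
arithmetic mean and rendered at 4 decimal places (round-half-even).

## Phase segmentation

No standard segmentation rule exists for insertion traces, so the event
detector is deliberately simple and fully parameterised: the force is
smoothed by a 21-sample running median (wide enough to suppress sensor
noise at 1000 Hz, narrow enough to preserve rupture steps), and a
puncture event is any drop of at least 0.3 N occurring within 50 ms.
Events are ranked by drop magnitude, the largest `n_phases - 1` become
boundaries (placed at the steepest descent within the event), and a
minimum phase length of `max(10, 2*(max_order+1))` samples guarantees
every phase remains fittable at the order cap. When fewer admissible
events exist the segmentation falls back to equal-length phases with a
warning — on a smooth ramp that is the only defensible answer. The
defaults match the puncture drops the synthetic generator produces;
recordings with different event scales should override `drop_threshold`.

## Baselines

The comparison families are fitted on the same abscissa (time) and scored
by the same statistic as the Fourier model: a degree-2 polynomial (the
classical prepuncture stiffness fit; degree is configurable), an
exponential $a e^{bx} + c$, and a power law $a x^b + c$ with $x$ shifted
to be non-negative. The power law is our concrete choice for a generic
"nonlinear spring"-type law — the literature's nonlinear models are
heterogeneous, and the power law is the minimal form distinct from both
other families. Nonlinear families use LM with data-driven starting
values (log-linear and log-log pre-fits) plus fixed fallback starts.

## Respiratory motion

Organ displacement is modeled as a raised cosine
$d(t) = \tfrac{A}{2}(1 - \cos(2\pi t/T_b + \phi_0))$ with peak-to-peak
amplitude $A$ and breath cycle $T_b$. Published per-organ cranio-caudal
ranges give the defaults (left kidney 7.1 mm, heart 5.2, lung 8.6, liver
4.5, dorsal muscles 2.9; $T_b = 5$ s, typical range 4–6 s). The raised
cosine is a documented choice, not a measurement: only amplitude ranges
and cycle times are published, and the raised cosine delivers exactly the
printed peak-to-peak excursion, starts at zero, and is smooth. Coupling
into the insertion axis is a single factor $c \in [0,1]$:
$x_\mathrm{eff}(t) = vt - c\,d(t)$, clamped at zero. Full coupling is the
default for organ-embedded targets; $c = 0$ reproduces a static bench.

## The synthetic generator

No public archive of recorded insertion traces exists, so the generator
is a first-class module, not a test fixture. It realizes the classical
stiffness / friction / cutting decomposition over an ordered layer stack:

* before rupture, the active layer loads as $k_1\delta + k_2\delta^2$
  with $\delta$ the penetration into the layer;
* rupture state is tracked on the running maximum depth, so respiratory
  retreat cannot "un-rupture" a layer;
* at rupture the force drops by exactly `puncture_drop_frac` of its
  momentary value within one sample. The post-rupture baseline (friction
  plateaus plus oscillations of all ruptured layers plus the next layer's
  ramp) does not generally land on that value, so each rupture introduces
  a residual elastic term — the released capsule force — that decays
  exponentially with a 0.5 s time constant. This keeps the drop ratio
  exact and the subsequent trace physical (relaxing to the friction
  plateau);
* each ruptured layer's oscillation is phase-referenced to its rupture
  time, so the oscillatory term is zero at the rupture sample;
* sensor noise is i.i.d. Gaussian with $\sigma = 0.01$ N by default, the
  precision of the miniature force/torque sensor class used on needle
  handles. The seed is mandatory whenever noise is on, and identical
  config plus seed gives a bit-identical trace.

Organ presets stack skin/fat/muscle plus an organ-specific capsule and
parenchyma, with layer mechanics plausibility-tuned — not calibrated to
any tissue database — so that traces exhibit 4 detectable puncture events
(hence 5 phases) and force magnitudes of a few newtons. What the
generator does **not** emulate: viscoelastic relaxation during pauses,
needle bending, hysteresis on retraction, inter-individual variability of
layer thicknesses, and correlated sensor noise. Passing tests therefore
demonstrate correctness of the fitting machinery under the stated force
decomposition, not fidelity to any particular tissue.

## Haptic rendering

Piecewise models are discontinuous at phase boundaries — an inherent
deficiency of piecewise fitting that is audible (and palpable) in a 1 kHz
force loop. The renderer removes it by linearly cross-fading the two
adjacent phase models inside a 20 ms window centred on each interior
boundary. Linear blending was chosen over spline smoothing because its
effect is exactly analyzable: at the node the rendered force is the
midpoint of the two models, and with `blend_ms = 0` the stream reproduces
piecewise evaluation bitwise. Real-time scheduling is out of scope: the
contract is sample-accurate generation at a nominal rate, which makes the
module testable headlessly. Models fitted on respiration-modulated traces
already contain the breathing force signature, so the bundle's
respiration block only shapes the depth channel by default; an optional
gain (`resp_force_gain`, N/mm) adds a force ripple for models fitted on
bench-static data.

## Numerical choices and degenerate inputs

* Linear least squares via QR; rank-deficient columns (e.g. a harmonic at
  the Nyquist limit) are zeroed rather than propagated as `NA`.
* LM tolerances `1e-10` (relative cost decrease), 200–300 iterations,
  5 starts for $\omega$, 4 starts for nonlinear baselines.
* Zero-variance segments are degenerate for both fitting and the fitting
  degree (SST = 0) and raise errors rather than returning `NaN`; piecewise
  reports mark such phases as failed and leave the average undefined.
* Traces must be uniformly sampled (step deviation under 1 µs);
  non-uniform input is rejected at construction.
* Retraction tails (force declining below 5% of peak with non-advancing
  depth) are trimmed before pipeline fits by a documented heuristic,
  disable with `keep_retraction`; the model covers insertion only.

## Problem sizes

The test suite and the acceptance script run on synthetic traces of
10–20 s at 1000 Hz (10⁴–2×10⁴ samples) and fixtures of 10³–4×10³
samples — sizes at which every fit completes in well under a second while
exercising the same code paths as full recordings. The plateau-quality
property is asserted over 20 seeded replicates.

## Known limitations

* The fitting degree is computed on the training segment itself (no
  held-out data), matching how fitting performance is conventionally
  reported in this literature; it measures approximation, not prediction.
* Per-phase $R^2$ averages weight a 0.5 s rupture phase equally with a
  7 s plateau; this is the conventional table arithmetic, not a
  variance-weighted summary.
* The event detector assumes drops are the segmentation signal; tissues
  whose boundaries show slope changes without drops will fall back to
  equal splitting.
* Only the axial force component is modeled; 6-DoF torque synthesis and
  device integration are out of scope.
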