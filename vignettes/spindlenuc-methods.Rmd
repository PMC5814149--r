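---
title: "Methods: autocatalytic nucleation, ablation waves, and lifetime fits"
author: "spindlenuc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autocatalytic nucleation, ablation waves, and lifetime fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlenuc)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the estimators and their numerical
choices, what the synthetic generators do and do not emulate, and the
design decisions that were genuinely open.

## The steady-state model

Spindle-like structures are built from microtubules that are short and
short-lived compared to the structure itself, so the structure's extent is
set by where new microtubules appear. The package's model combines two
ingredients:

1. **Microtubule-stimulated (autocatalytic) nucleation.** New microtubules
   are nucleated by nucleators bound to pre-existing microtubules, and
   inherit the mother's (outward) polarity. Polymer begets polymer.
2. **A gradient of active nucleators.** Nucleators are activated only near
   chromatin at the center, diffuse (coefficient $D$), and inactivate at a
   constant rate $k_i$, giving an unbound active-nucleator profile that
   decays with length scale $\ell_u = \sqrt{D/k_i}$.

In one effective radial dimension with all filaments pointing outward,
steady-state density obeys

$$\frac{d\rho}{dx} = \beta(x)\,\rho - \frac{\rho}{\ell},\qquad
\beta(x) = \frac{\alpha}{\ell_u}\,e^{-x/\ell_u},$$

whose solution is the closed form used throughout,

$$\rho(x) = \rho_0\,\exp\!\left[\alpha\left(1 - e^{-x/\ell_u}\right)
  - \frac{x}{\ell}\right].$$

Here $\ell$ is the mean microtubule length (set by polymerization speed
and turnover, $\ell = v_p/\Theta$), and $\alpha = \int_0^\infty\beta$ is
the dimensionless integrated branching amplitude. Two consequences carry
the model's testable content:

- **Parameter-free rescaling.** Conditions sharing the nucleator gradient
  but differing in $\ell$ satisfy
  $\rho_C(x) = \rho_M(x)\,e^{(1/\ell_M - 1/\ell_C)x}$ exactly
  (`rescale_profile`); the identity holds to machine precision for the
  closed form, and is an exact algebraic property, not an approximation.
- **Reproductive number.** $R(x) = \beta(x)\ell$ is the mean number of
  daughters a microtubule at $x$ produces before turning over. If
  $R(0) > 1$ the density rises to a maximum exactly at the radius where
  $R = 1$ (`growth_regime`); with a finite gradient the periphery is
  always eventually subcritical, so the structure is bounded even when
  resources are not limiting. Under uniform activation
  ($\ell_u \to \infty$, constant gain $\beta_0$) growth is unbounded iff
  $\beta_0\ell > 1$.

The convention for $\alpha$ is the *integrated gain*; the alternative
convention $R(0) = \alpha\ell/\ell_u$ is exposed read-only as
`central_reproductive_number()`.

### Fitting

`fit_density` fits $(\ell_u, \alpha, \rho_0)$ by Levenberg–Marquardt least
squares on linear intensities with positivity bounds, with $\ell$ fixed to
an independent (ablation) measurement. $\ell_u$ is optimized on a log
scale. Five deterministic starts (decades of $\ell_u$ crossed with small
and large $\alpha$) guard against local minima; tolerances are $10^{-10}$
and the best converged start is returned, so the result is a deterministic
function of the data. A flat profile cannot separate $\alpha$ from
$\ell_u$; such fits return `degenerate = TRUE`. Note that even clean
profiles constrain the *curve* much more tightly than the individual pair
$(\ell_u, \alpha)$ when the observed span does not saturate the branching
term; model-agreement checks therefore compare fitted curves, not raw
parameter values, unless noise is controlled.

## The stochastic simulator

`sim_run` is an agent-based, fixed-step (tau-leaping) realization of the
same physics: Poisson activation in the chromatin zone `[0, chrom_radius]`
(or everywhere under `uniform_activation`), Gaussian diffusion steps with
reflection at both domain ends, constant-rate inactivation, binding at
rate `k_on` per micrometer of filament overlapping the capture
neighborhood $[x-w, x+w]$ (the overlap is computed exactly from sorted
cumulative coverage; the host is drawn with probability proportional to
its overlap), unbinding, and nucleation of a zero-length daughter at the
nucleator's position. Nucleation ends the binding episode — the nucleator
is released in place — so one binding yields at most one daughter; this
caps same-site bursts that a perpetually bound nucleator would produce in
a 1D geometry where colocated daughters would otherwise keep amplifying
local binding. Plus ends grow at `v_p`, clamped by the domain and by any
obstacle interval; turnover either removes whole filaments at rate
`theta` (clean mapping to the steady-state model) or switches them to
shrinkage at `v_d` after a catastrophe at `k_cat` (used for ablation- and
lifetime-like dynamics).

The guard `dt × (largest per-particle rate) < 0.1` is enforced both at
configuration time (fixed rates) and per step (the density-dependent
binding rate); an unstable step refuses to run rather than silently
degrade.

**Default rates.** The binding/unbinding/nucleation rates of the nucleator
machinery are not experimentally known. The defaults were set once by
mean-field analysis to land in the measured monopole regime: with
$q = k_{nuc}/(k_{off}+k_{nuc}+k_i)$ the probability that a binding episode
yields a daughter, the mean-field gain is
$\beta(0) = q\,k_{on}\,2w\,n_u(0)/\Theta$, and with the defaults
($D = 10\,\mu m^2/s$, $k_i = 0.016\,s^{-1}$, so $\ell_u = 25\,\mu m$;
$k_{on} = 0.0013$, $k_{off} = 2$, $k_{nuc} = 0.4$, activation
$20\,s^{-1}$) this gives $\alpha = \beta(0)\ell_u \approx 2.4$ — measured
empirically from the simulator as $\approx 2.2$–$2.4$ by `fit_density` on
simulated profiles, which is the calibration route used everywhere (no
unverified rate-to-$\alpha$ formula is assumed). The chromatin seeding
rate (4 events/s in the zone) supplies the boundary density that
branching amplifies.

**Problem sizes.** Steady-state runs use a 100 µm domain, dt = 0.04 s and
400 s of simulated time with profiles averaged after a 200 s burn-in —
the structure's slowest relaxation (a multi-generation cascade to the
periphery) completes within ~250 s, and total polymer then fluctuates
±30% around ~1100 µm with a correlation time of order 100 s. Because of
that autocorrelation, stationarity is tested on the across-seed mean of
last-quartile drifts (20 independent seeds), never on a single
trajectory. Uniform-activation growth runs use a 50 µm domain and start
from the steady-state nucleator pool (`init_nucleators = "steady"`);
building the pool from scratch takes $1/k_i \approx 60$ s and would
otherwise dominate a short run.

**Obstacle shadows.** An obstacle interval blocks filament growth and
nucleation inside it but not nucleator diffusion. `shadow_profile`
compares an obstacle run with an obstacle-free twin (same seed) over a
4-obstacle-radius window behind the obstacle and reports the contact-zone
ratio (first radius) separately from the far ratio: under
microtubule-stimulated nucleation nothing can seed behind the obstacle
and the whole window stays dark, whereas under independent nucleation the
contact zone is still depleted — regrowth takes about one filament length
regardless of the nucleation mode — while the rest of the window
repopulates. The obstacle default (8 µm diameter at 8 µm from the zone)
matches the scale of the immobilized droplets such assays use.

## The laser-ablation analysis

A circular cut at radius $r$ severs every spanning microtubule; the new
plus ends depolymerize inward at $v_d$ while the new minus ends are
stable. The analysis follows the differential-intensity procedure:
subtract frames $\delta t = 2$ s apart ($I(t) = F(t) - F(t+\delta t)$,
signed values retained), integrate over the angle into radial bins
(default 0.5 µm), track the travelling peak with bounded Gaussian fits,
and read the depolymerization velocity off a linear fit of center versus
time. Three estimator choices matter and were validated against exact
synthetic ground truth:

- **Areas by direct integration.** The differential wave is close to a
  top-hat (width $v_d\delta t$), not a Gaussian; analytic Gaussian areas
  showed a +3% median model error on noise-free data. The area is
  therefore the direct integral over ±4σ around the fitted center (the
  differential baseline is zero, so this is unbiased); the analytic area
  is kept as `area_gauss`.
- **Velocity frames.** Late frames are skewed outward by survivor
  depletion, and frames at the center stall; both are excluded from the
  velocity fit (area ≥ 40% of maximum, center > 2.5σ), leaving the
  velocity accurate to a few tenths of a percent on synthetic movies.
- **Conservation-normalized survival.** The wave's area per differential
  interval at the cut equals the spanning fluorescence times the swept
  window, so the decay curve is normalized by
  `fluorescence_at_cut × v_d × δt` (window clipped at the origin and the
  cut) rather than by an extrapolated fitted amplitude, which biased the
  whole curve ~9% whenever the decay was not exponential. Distances come
  from the time axis, $d = \hat v_d(t + \delta t/2)$, not per-frame
  centers.

The per-cut profile value is the minus-end density at the cut read off
the retained decay curve over a 2 µm window below the cut, divided by
$2\pi r$ (circle) or the cut length (line). The published procedure reads
the slope at the cut from a single global exponential fit of the decay;
that fit's $\lambda$ and slope are kept as diagnostics (`lambda`,
`slope_at_cut`, `nc_exp_fit`), but on exact synthetic data the global
exponential misstates the local slope wherever the minus-end density
varies along the structure (up to ~70% profile distortion), so the
curve-based local estimate is the default.

Because each area sample is the *average* of the survival over its
differential window, `minus_end_bins` evaluates the curve at bin edges by
a local quadratic fit with the exact top-hat deconvolution
$S = \bar S - (w^2/24)\bar S''$; this removes the curvature bias where
the wave runs out at the center and averages the sub-bin aliasing of
per-frame areas. The window width $v_d\delta t \approx 1.1$ µm is the
pipeline's intrinsic localization scale; minus-end bins should be chosen
comfortably wider (3 µm in the validation runs).

Length distributions: at a fixed position $y$, the minus-end density seen
through cuts at increasing radii decays as the fraction of microtubules at
$y$ long enough to span the cut — exponentially with decay length $\ell$
for exponential lengths. `length_distribution` fits
$\log n_c(y, r)$ versus $r$ at several fixed $y$ and reports the median
$\ell$; poor log-linearity (median $R^2 < 0.97$) flags non-exponential
truths. A curvature F-test is reported but not used for the flag: on
near-noise-free synthetic decays it rejects for inconsequential
deviations.

Line cuts across bipolar structures produce two waves (mixed polarity);
`angular_integrate(direction = "line")` integrates along the cut and
`fit_two_waves` tracks each side. No flux correction is applied — the
motor-driven transport correction needed to turn bipolar minus-end
densities into nucleation profiles is deliberately out of scope.

## Speckle lifetimes

A fluorescent speckle reports its microtubule's local lifetime: it
disappears when the shrinking end passes it. For a drift–diffusion end
the first-passage density is $P(t) \propto t^{-3/2}e^{-t/\tau}$, which is
non-normalizable at 0, so fits are maximum likelihood on the truncated
density on $[t_{min}, \infty)$ with the normalization evaluated through
the upper incomplete gamma function $\Gamma(-1/2, t_{min}/\tau)$ in
closed form. The mean lifetime of a microtubule of average length is
reported as $\tau/4$ (a definition adopted from the first-passage
literature, not re-derived), and the turnover rate as its reciprocal.
MLE avoids binning choices; a histogram least-squares mode exists for
visual parity with published normalized histograms. The truncation
default is two frame intervals, and the fit's sensitivity to halving or
doubling $t_{min}$ is part of the diagnostics; a one-sample KS statistic
against the fitted CDF flags model mismatch (its p-value is approximate
since $\tau$ is estimated, but separates exponential data cleanly at
large n).

The oracle simulator draws first-passage times by Euler steps with
Brownian-bridge absorption (crossing probability
$e^{-x_{old}x_{new}/(D\,dt)}$ per step), which removes the leading
discrete-monitoring bias; the pure-drift limit returns exactly $L_0/v$,
and the driftless limit reproduces the $t^{-3/2}$ tail.

## Synthetic data: what it does and does not emulate

`sample_monopole` draws minus ends per unit radial length from the
normalized model nucleation profile by inverse CDF on a 0.01 µm grid, and
lengths i.i.d. exponential. `render_frame` embeds the 1D filaments at
uniform random angles, rasterizes at quarter-pixel spacing, convolves with
a Gaussian PSF (default σ = 0.25 µm at 0.22 µm pixels, a typical
60×/1.2 NA scale — not a measured value), adds background and optional
Poisson noise; total noise-free intensity is exactly proportional to
polymer length, which the conservation tests rely on. Because the
generator is 1D (minus density ∝ ν(x) per unit radius), generator-level
comparisons use `assemble_nucleation_profile(value = "per_length")`; the
default `"per_area"` (÷2πr) is the convention for real two-dimensional
images.

Passing tests on these generators demonstrates estimator correctness —
that the pipeline inverts its own forward model and the simulator obeys
the closed-form theory. Real movies additionally contain bleaching,
drift, out-of-focus light, motor-driven flux and detection noise that are
deliberately not modeled; only the centroid-based centering and the
signed-differential convention address real-data artifacts.

## Known limitations

- The model is 1D radial with outward polarity; no bipolar steady state,
  no motor flux term.
- The simulator's binding neighborhood collapses azimuth, so its kinetic
  rates are effective, not molecular; $\alpha$ is always measured from
  simulated profiles, never derived from rates.
- $(\ell_u, \alpha)$ are only weakly identifiable from density profiles
  whose span does not saturate the branching term; curve-level agreement
  is the meaningful check in that regime.
- Minus-end localization is limited to the differential window
  $v_d\delta t$; structure below ~1 µm is not resolved.
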