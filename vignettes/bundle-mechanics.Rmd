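---
title: "Shape, force and motor statistics of kinesin-driven microtubule bundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape, force and motor statistics of kinesin-driven microtubule bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundlekin)
```

## The system and the questions

Taxol-stabilized microtubules bundled by a depleting polymer (PEG) and
cross-linked by multimeric kinesin-1 clusters form *active bundles*: the
motors walk along filaments of mixed polarity, slide antiparallel pairs
against each other, and thereby bend and buckle the whole structure.
`bundlekin` implements the quantitative analysis of this system at two
scales:

* **bundle scale** — traced centerline contours are condensed into a
  low-dimensional curvature representation, from which shape-disorder
  length scales and the motor-generated shear force density are computed;
* **motor scale** — tracked motor-cluster trajectories are reduced to
  unidirectional run segments, and a two-rate Markov model links the
  observed run-length statistics to detachment and direction-reversal
  rates.

All lengths are micrometres, angles radians, curvatures 1/um, forces pN,
times seconds. The Boltzmann factor is `kB = 1.380649e-5 pN um / K`, so
`kB * 298 K = 4.114e-3 pN um`.

## Clothoid-spline shape representation

Computing a force density requires the *derivative of the curvature*, a
third derivative of the traced shape; differentiating a noisy polyline
directly amplifies tracing noise catastrophically. The package therefore
represents a bundle centerline as a **piecewise clothoid (Euler spiral)
spline**: the signed curvature $K(s)$ is parameterized by its values
$K_1 \dots K_{N_p}$ at $N_p$ nodes equally spaced along the arc length
(default $N_p = 7$, both endpoints included) and interpolated linearly in
between. Each span is then an Euler spiral. The shape follows by two
integrations,

$$\phi(s) = \phi_0 + \int_0^s K(u)\,du, \qquad
  \mathbf{r}(s) = \mathbf{r}_0 + \int_0^s (\cos\phi, \sin\phi)\,du,$$

the first exact (piecewise quadratic), the second numerical. Raising
$N_p$ to 10 does not visibly improve fits of real traced bundles, which
motivates the default.

**Numerical policy for the position integral.** The tangent integral is
closed-form; positions use composite 2-point Gauss–Legendre quadrature at
the fixed step $L/1024$. At this order, halving the step moves positions by
less than $10^{-6}\,\mu m$ for physiological curvatures (a tested
invariant) — a midpoint rule at the same step would be two orders of
magnitude less stable, which is why the higher-order per-step rule was
chosen.

**Fitting.** `fit_clothoid()` minimizes the summed squared distance
between the spline evaluated at the contour's cumulative arc lengths and
the observed points, over $(\mathbf{r}_0, \phi_0, K_1 \dots K_{N_p})$.
The contour length $L$ is fixed at the observed polyline length, not a
free parameter. Two design choices are worth spelling out:

* *Residual definition.* The residual pairs each observed point with the
  spline point at the same cumulative arc length (not the orthogonally
  nearest curve point). This is much cheaper and adequate for densely
  traced contours, but it makes the objective sensitive to noise in the
  arc-length parameterization itself — see the smoothing note below.
* *Optimization.* The tangent angle is *linear* in
  $(\phi_0, K_1 \dots K_{N_p})$, so a linear least-squares fit to the
  unwrapped polyline tangent angles provides a deterministic, nearly
  optimal initialization. A derivative-free Nelder–Mead simplex then
  refines the full position objective, with seeded randomized restarts
  (default 5) guarding against local minima, and a tight final polish.
  This replaces the cruder "straight-line initialization" one might use:
  with $K \equiv 0$ starts, strongly bent bundles routinely trap the
  simplex.

**Why smooth before fitting.** White point-wise tracing noise of standard
deviation $\sigma$ on points spaced $\Delta$ apart inflates every polyline
segment by $\approx \sigma^2/\Delta$ and makes the cumulative arc length
of each point wander like a random walk. When $\sigma/\Delta \gtrsim 0.1$
this displaces the *global* minimum of the arc-length-matched objective —
node curvature errors appear that no number of restarts can remove.
`smooth_contour()` (centered moving average, window shrinking at the
ends) restores a reliable arc-length parameterization, as snake-style
tracers do internally; a window of 5–7 points at $\sigma/\Delta \sim 1/6$
removes the distortion while attenuating real curvature by only ~1% at
the bending radii of this system. Raw fits of low-noise contours do not
need it.

Fitted curvatures are equivariant under rigid motions (only the base pose
changes), antisymmetric under mirror reflection, and the residual never
increases with more nodes — all tested invariants.

## Correlation functions and characteristic lengths

Shape disorder is summarized by two arc-length correlation functions,
averaged both over starting positions $s_0$ (uniform grid, default
spacing $L/200$) and over video frames:

$$C_{tt}(s) = \big\langle \cos(\phi(s_0+s) - \phi(s_0)) \big\rangle,
\qquad
C_{KK}(s) = \frac{\langle K(s_0+s)\,K(s_0)\rangle}{\langle K^2\rangle}.$$

The curvature correlation is normalized by $\langle K^2 \rangle$ so that
$C_{KK}(0) = 1$; its characteristic length is then defined the same way
as for $C_{tt}$ — the first crossing of 0.5, located by linear
interpolation between bins (`half_decay_length()`, `NA` when the curve
never decays that far, as for an almost-straight bundle). Frames of one
bundle are pooled; different bundles are never pooled into one estimate —
`pool_correlations()` provides the separate unweighted across-bundle
mean curve.

For a freely fluctuating planar filament with persistence length $P$,
$C_{tt}(s) = e^{-s/2P}$; the test suite verifies the estimator against
direct equipartition simulation of this law before relying on it.

## Flexural rigidity from thermal fluctuations

With motors present but no ATP, bundles fluctuate only thermally, and
their flexural rigidity follows from cosine-mode equipartition. The
tangent angle of each frame is decomposed as
$\theta(s) = \sqrt{2/L}\sum_n a_n \cos(n\pi s/L)$ (free ends; mode 0, a
rigid rotation, is excluded) and each mode obeys

$$\mathrm{var}(a_n) = \frac{k_B T L^2}{EI\, n^2 \pi^2}.$$

`estimate_EI_thermal()` combines the per-mode estimates of modes 1–3 by
inverse-variance weighting (the sampling variance of a mode's variance is
$\propto \mathrm{var}(a_n)^2$, so relative errors are mode-independent)
and reports the combined sampling standard error. Localization noise adds
a variance floor $\approx 2\sigma^2/\Delta s$ per mode, which biases high
modes low — one reason to stop at mode 3 — and the contour length must be
stable across frames (a 5% drift check rejects sliding or depolymerizing
filaments). Reference values for this system: a single Taxol-stabilized
microtubule has $EI \approx 4\,\mathrm{pN\,\mu m^2}$
($0.4\times10^{-23}\,\mathrm{N\,m^2}$), a PEG-depletion bundle
$\approx 7\,\mathrm{pN\,\mu m^2}$; with weak (depletion-only)
cross-linking a bundle of $n$ filaments behaves as $n\,EI$, with
$n = 4$ for 1% 20-kDa PEG carried as a configuration constant, not a
computation.

## Force reconstruction from curvature

A free bundle has no external moments, so its bending moment balance
reduces to $EI\,K = M_{int} = F\,d$: curvature directly encodes the
internal shear force $F$ between filaments separated by the effective
distance $d$. The motor force density per unit length is the arc-length
derivative, and with $d$ constant,

$$f(s) = \frac{EI}{d}\,\frac{dK}{ds},$$

evaluated per span of the fitted spline as $\Delta K/\Delta s$ between
adjacent nodes (`force_density()`). Defaults are the measured bundle
rigidity $EI = 7\,\mathrm{pN\,\mu m^2}$ and $d = 0.075\,\mu m$, the
average kinesin-cluster size separating microtubules. The nodal shear
force $F = EI\,K/d$ telescopes exactly to $f$ — a tested identity.
`summarize_force_densities()` pools $|f|$ across spans, frames and
bundles (distributions are reported for the magnitude; signed profiles
remain available) and reports each bundle's maximum force density as the
95th percentile of its own distribution, using linear interpolation
between closest order statistics (R's default quantile type 7). Scaled by
the ~5 pN kinesin stall force, $f$ converts to a line density of actively
force-generating motors.

## Motor tracks: runs, reversals, pauses

Tracked motor clusters are first referenced to the bundle axis
(`project_track()`: nearest-point projection onto the finely sampled
spline; tracks farther than 1 um from the axis or whose projected
coordinate jumps by more than 2 um between frames are flagged and
excluded rather than erroring). `decompose_runs()` then reduces the 1D
motion to signed unidirectional segments $d_i$ with a hysteresis rule: a
direction change is accepted only once the excursion in the new direction
reaches the minimum detectable segment (0.2 um), so localization noise
cannot fabricate reversals, and sub-threshold wiggles merge into the
enclosing segment. The run length is $l = \sum_i |d_i|$. Pauses — net
displacement under 0.05 um across 3 inter-frame intervals at the 1 Hz
acquisition rate — accumulate into paused time and are excluded from the
moving time used for velocities. The detection floor (0.2 um without
reversal, 0.4 um with reversal, i.e. two detectable segments) discards
tracks that could not have been measured; censoring by field exit or
stalling is deliberately not modelled — a run ends when the track ends,
matching the operational definition used for the experimental counts.
`population_stats()` reports $\hat\eta = N_R/N$, per-class mean run
lengths with the exponential standard error $\bar l/\sqrt{n}$, and
per-class median velocities.

## The two-rate Markov model

Each walking motor detaches with rate $k_d$ and reverses (switching to an
antiparallel microtubule) with rate $k_r$, moving at constant speed $v$.
Then:

* reversing fraction $\eta_r = k_r/(k_r + k_d)$;
* nonreversing run lengths are exponential with mean
  $\lambda_{nr} = v/(k_d+k_r)$ — note the *sum* of rates: surviving
  without reversal conditions the lifetime on both channels;
* the reversing-population run-length density is
  $p_r(l) = \frac{k_d}{v\,\eta_r} e^{-k_d l/v}\big(1 - e^{-k_r l/v}\big)$,
  zero at $l = 0$ and heavier-tailed than the nonreversing class. Its
  mean exceeds $\lambda_{nr}$ for every $k_r > 0$: motors with longer
  runs are simply more likely to have reversed at least once — a
  selection bias, not a mechanistic difference (a tested invariant).

`rates_from_observables()` inverts $(\eta, \lambda_{nr}) \mapsto
(k_d, k_r)$ exactly, with no fitting parameters; $v$ only sets the time
scale and defaults to 0.4 um/s, within the observed velocity range. With
the observed $\eta = 0.07$ and $\lambda_{nr} = 0.68$ um this gives
$k_d \approx 0.55\,s^{-1}$, $k_r \approx 0.041\,s^{-1}$, a mean reversing
run of 1.41 um, and a reversal distance
$\Lambda_r = v/k_r = \lambda_{nr}/\eta_r \approx 9.7$ um — the model's
central output, comparable to the curvature correlation length of the
bundles, suggesting that reversals are governed by the polarity texture
that also drives active bending.

Two readings of "mean run above the detection floor" are both
implemented, because the phrase is genuinely ambiguous: the *mean excess*
$E[l - 0.4 \mid l > 0.4] \approx 1.16$ um (`mean_excess_above()`) and the
*conditional mean* $E[l \mid l > 0.4] \approx 1.56$ um
(`conditional_mean_above()`). The mean-excess reading matches the
published comparison with the experimentally observed reversing mean, so
it is the primary interface. Similarly, the "stretching" of theoretical
CDFs for overlay on experimental ones is implemented as a support shift
$\tilde F(l) = F(l - l_{min})$ (`stretched_cdf()`); the original
transformation is not specified beyond its purpose, and a support shift
is the only choice that both preserves the distribution's shape and
starts the curve at the smallest observable run.

Exponential differences are computed with `expm1` so small $k_r$ does not
lose precision.

## Synthetic data: what it does and does not emulate

Every analysis stage has a seeded generator producing inputs with the
statistical structure the stage assumes, so the whole pipeline is
testable offline; ground truth is always stored next to the data.

* `simulate_motor_population()` — exponential lifetimes, Poisson
  reversals, piecewise-linear motion at $\pm v$, 1 Hz sampling, isotropic
  Gaussian localization noise (default $\sigma = 0.05$ um, a conventional
  spot-tracking precision). It does *not* emulate motor–motor
  interference, load-dependent stepping, or tracking gaps.
* `simulate_bending_bundle()` — prescribes node-curvature paths and
  derives the implied force density as ground truth (prescribing $f$
  directly would require elastic boundary conditions for a free bundle;
  prescribing $K$ avoids that choice). The default prescription makes
  each span's $|f|$ sweep $0..f_{peak}$ sinusoidally in time with
  span-paired phases chosen so curvature stays bounded. Rigid drift and
  point noise are added. Real bundles additionally merge, disassemble and
  transport material — none of which is emulated, so passing round-trip
  tests validates the *estimator chain*, not the biology.
* `simulate_thermal_filament()` — independent equipartition frames
  (default: $L = 17$ um, a typical microtubule length; 25 traced points;
  $\sigma = 0.01$ um, snake-tracing subpixel precision; 20 modes). Real
  thermal movies have correlated frames (finite relaxation times), which
  would shrink the effective frame count; the estimator's standard error
  is therefore optimistic on real data.

A note on study-condition sizes used in the test suite: the force
round-trip scenario uses a 30 um bundle. With $EI/d \approx 93$ pN um, a
peak force density of 5 pN/um implies $\Delta K/\Delta s \approx
0.054\,\mu m^{-2}$; only spans of ~5 um keep the implied bending radii
above ~3 um, i.e. shapes a tracer could actually follow. Longer bundles
at the same force density would curl at radii below 2 um, which is not a
meaningful test input. Thermal recovery runs use 1000 frames and the
Monte-Carlo motor checks use 20000 tracks, sizes at which the expected
statistical errors sit comfortably below the tested tolerances.

## Known limitations

* Contours are 2D; out-of-plane bending projects into apparent curvature.
* The matched-arclength residual needs pre-smoothing at high tracing
  noise (see above); an orthogonal-distance objective would remove the
  issue at ~10x the fitting cost.
* $C_{KK}$'s normalization convention (dividing by $\langle K^2\rangle$)
  is one of several in use; absolute autocorrelations can be recovered by
  multiplying back the curvature variance.
* The Markov model ignores censoring: runs truncated by the field of view
  are treated as complete, exactly as in the operational definition of
  the experimental run length.
* Velocity medians depend on the pause criterion (0.05 um / 3 frames),
  which is a configurable convention, not a measured constant.
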