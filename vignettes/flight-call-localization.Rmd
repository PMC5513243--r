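---
title: "Methods: three-dimensional localization of flight calls by time difference of arrival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-dimensional localization of flight calls by time difference of arrival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flightloc)
```

## The observation model

A flight call emitted at unknown position $s$ and unknown time $t_0$
reaches microphone $i$ at

$$t_i = t_0 + \frac{\lVert s - m_i \rVert}{v},$$

where $m_i$ is the microphone position and $v$ the speed of sound
(default 340 m/s). Absolute arrival times are useless without $t_0$, but
*differences* between channels cancel it: each pair $(i, j)$ constrains
$s$ to one sheet of a hyperboloid of constant range difference
$\lVert s - m_i\rVert - \lVert s - m_j\rVert$. Sampled recording
quantizes these differences: at sample rate $\tau$ the smallest
resolvable range difference is the sample distance
$\Delta d = v / \tau$ (0.0154 m at 22,050 Hz), and a pair separated by
$d$ meters can express only the integer lags $0..\lfloor d / \Delta d
\rfloor$ on one side of its bisecting plane. The count of distinct
hyperboloids between the two degenerate surfaces (the equidistant plane
at lag 0 and the pair axis at the maximum lag) is the geometric picture
of attainable resolution, and it motivates the default array: height
diversity is the scarce resource, so each of three towers carries a
microphone pair with 7.64 m vertical separation, while the towers
themselves form an equilateral triangle with 20 m sides. With six
microphones the five reference-relative lags overdetermine the four
unknowns $(s, R)$, where $R$ is the source range to the reference
microphone.

Assumptions inherited by everything downstream: straight-line
propagation at a single constant $v$; exactly known microphone
positions; perfectly synchronized channels; a stationary source within
each call.

## The solver chain

`linear_tdoa_solve()` uses the standard linearization. Writing
$\delta_i = v\,l_i/\tau$ for the measured range differences,
$\lVert s-m_i\rVert = R + \delta_i$; squaring and subtracting the
reference equation leaves, for every non-reference microphone,

$$2\,(m_i - m_\mathrm{ref})\cdot s + 2\,\delta_i R
  = \lVert m_i\rVert^2 - \lVert m_\mathrm{ref}\rVert^2 - \delta_i^2,$$

a linear system in $(s, R)$ solved by QR least squares. It is exact for
error-free $\delta$ but biased under lag quantization, so
`refine_gauss_newton()` minimizes the true hyperbolic misfit
$\sum_i (\lVert s-m_i\rVert - \lVert s-m_\mathrm{ref}\rVert -
\delta_i)^2$ starting from the linear solution, with Levenberg-style
damping (the damping grows tenfold until a step does not increase the
cost; a step is accepted only if the cost does not increase, so the
refined residual can never exceed the initial one). The estimate
carries diagnostic flags rather than hard failures: `negative_range`
when the linear stage returns $R < 0$ (it is only an initializer, so
the magnitude is kept and refinement proceeds), `ill_conditioned` when
the design-matrix condition number exceeds $10^8$ or refinement cannot
find a descent step, `below_ground` when $z < 0$, and `out_of_bounds`
beyond a configurable range. Below-ground and near-ground solutions are
reported, not clamped or discarded: a retrieval dragged toward the
ground is the signature of a ground-level interferer (insects are the
classic culprit) and is diagnostic information in its own right.

### The grid oracle

`grid_oracle()` is an independent verifier used throughout the test
suite: a multi-level exhaustive search over a bounding box minimizing
the same hyperbolic residual. Two numerical points deserve note. First,
the residual surface has long, nearly flat valleys along the poorly
constrained directions (chiefly range/height for distant sources), so a
single greedy refinement path can stall far from the minimum; the
oracle therefore carries a beam of well-separated candidates (default
25) through each refinement level. Second, point sampling cannot rank
positions along such a valley at grid resolution, so the grid optimum
is polished by a restarted Nelder–Mead simplex search on the same cost
— still derivative-free and independent of the analytic Jacobian the
Gauss–Newton stage uses. With exact range differences the oracle and
the solver chain agree to well under a millimeter; with quantized lags
they agree to a few micrometers, far inside the twice-final-grid-step
tolerance the tests assert.

## Lag measurement

Channels are band-pass filtered to the call's schedule band with a
fourth-order Butterworth applied forward and backward
(`signal::filtfilt`), i.e. zero-phase: any phase distortion would bias
the lags directly. The filter design is a conventional default; the
band edges come from the call schedule. Cross-correlation is computed
by FFT, normalized by the segment energies so that a peak of 1 means
identical aligned waveforms, and restricted to each pair's physical lag
bound $\lceil d_{ij}\,\tau / v \rceil$ plus a 5-sample margin. Exact
peak ties are broken deterministically (smallest $|l|$, then the
negative lag). Parabolic sub-sample interpolation exists behind the
`subsample` flag but is off by default, matching the integer-lag
resolution model; it is the natural accuracy upgrade and is exercised
separately in the tests.

Screening automates what a human operator would do with spectrograms:
a call must be present on *every* channel, and a channel whose best
normalized correlation against the reference falls below `min_peak`
(default 0.3 — deliberately permissive, and configurable, since the
energy normalization spans the whole padded segment) marks the call
rejected. Rejected calls yield a diagnostic record, not an error. All
15 pairwise lags are measured for diagnostics (antisymmetry is exact by
construction; cycle consistency $l_{ij} + l_{jk} \approx l_{ik}$ is a
quality check), while the solver consumes the five reference-relative
lags. The reference defaults to the first microphone in layout order;
with six microphones one could equally count six lags by including the
zero reference lag, which changes nothing in the solution.

## The synthetic validation experiment

No field recordings accompany this package, so `simulate_flight_track()`
and `render_recording()` stand in for a validation campaign in which a
speaker and a GPS logger are lofted on a tethered balloon-kite above the
array. The generator's defaults are the experiment's conditions: calls
broadcast every 3 s cycling through an eleven-template library (ten
species-labeled synthetic surrogates plus one synthetic tone), truth
positions sampled every 7 s, the source confined to a cylinder of
105 m horizontal radius and 140 m ceiling, and GPS-like truth
perturbation of 5 m per axis (hence $\sqrt{3}\cdot 5 \approx 8.66$ m in
Euclidean distance). The trajectory itself — an integrated
Ornstein–Uhlenbeck velocity process with ~2 m/s horizontal and ~1 m/s
vertical stationary speed, reflected at the domain bounds, starting
mid-domain with a 10 m floor — is this package's invention: a tethered
platform drifts smoothly and slowly, and no published trajectory exists
to copy. The per-channel noise default (`noise_rms = 0.005` against a
source level of 20 at 1 m) was chosen so that most broadcasts inside
the cylinder are detectable on all six channels while detectability
falls off toward the 175 m slant-range limit, reproducing the practical
regime in which far calls fade into the ambient noise.

Rendering applies spherical ($1/r$) spreading and additive white
Gaussian noise only. Deliberately *not* modeled: frequency-dependent
atmospheric absorption (the localization math is attenuation-agnostic;
detectability effects are emulated by the noise knob), wind and
temperature-gradient refraction, speaker directionality, Doppler within
a call, and reverberation. Ground interferers are ordinary emission
events with $z \approx 0$, which suffice to reproduce the downward-bias
mechanism qualitatively. Consequently, green tests here demonstrate the
correctness of the measurement-and-inversion chain under the stated
propagation model — not robustness to refraction, wind drift or
colored, nonstationary soundscapes, which real deployments will add.

Two quantization modes matter for testing. `nearest_sample` (default)
rounds each channel's arrival to its own nearest sample — the physical
sampling model, under which measured lags equal the rendered offsets
exactly and each arrival carries an independent rounding error in
$[-0.5, 0.5]$ samples. `fractional` places the template at the exact
fractional delay by interpolation, giving the solver unquantized truth
to recover. The quantization-bound test brackets the chain's error by
the worst case over the $2^6$ corners of the per-channel rounding
hypercube, each corner solved by the oracle-plus-refinement chain, with
a 1 mm numerical allowance for the corner-extremum argument (the
lag-to-position map is locally affine, so the extreme error over the
hypercube is attained at a corner up to curvature effects).

## Numerical choices and degenerate inputs

* `max_lag()` computes $\lfloor d/\Delta d + \varepsilon\rfloor$ with a
  relative $\varepsilon = 10^{-9}(d/\Delta d + 1)$ so decimal-exact
  ratios like $1.54/0.154 = 10$ survive binary floating point;
  `pair_lag_bound()` symmetrically subtracts the epsilon inside the
  ceiling.
* Feasibility: $|\delta_i| \le d_{i,\mathrm{ref}}$ must hold physically;
  the solver allows one sample distance of slack because quantization
  can push a measured lag one sample past the bound, and rejects the
  input (naming the offending pair) beyond that.
* Layout validation rejects fewer than five microphones, coincident
  microphones, and fully collinear layouts (rank of the centered
  coordinate matrix below 2), all of which make the system degenerate.
* An all-zero segment has no defined correlation: a direct call to
  `cross_correlation_lag()` errors, while `build_lag_set()` treats the
  channel as undetected and rejects the call gracefully.
* Correlation values are clamped to $[-1, 1]$; FFT round-off can exceed
  the Cauchy–Schwarz bound by $\sim 10^{-15}$.
* CSV writers format coordinates with fixed precision (µm scale, far
  below solver noise) so that reruns with identical seeds produce
  byte-identical artifacts.

## Open design decisions

Where the method description left room, this package chose: least
squares over an exact five-equation solve (robustness to quantization
and noise, and the two-root ambiguity of closed-form TDOA solvers never
arises); the first microphone in layout order as default reference
(configurable); the one-sided lag alphabet $l_\max + 1$ for the
resolution model (a source above the pair) while the correlation search
uses the signed range; tower heights 9.14 m / 1.5 m as the default
construction (configurable); and "within GPS accuracy" interpreted
per-axis ($|\Delta z| \le 5$ m for the vertical fraction, Euclidean
$\le 8.66$ m for the distance panel) with Tukey 1.5 IQR whiskers for
the per-call-type boxplots.

## Problem sizes

The test suite and the acceptance script run, as this package's chosen
experiment sizes: 100 random sources for exact recovery (uniform in a
cylinder of 100 m radius, 10–130 m height), 50 sources for the
quantization bound ($2^6$ hypercube corners each), 50 quantized lag
sets for oracle equivalence, 100 rendered calls for lag consistency,
and a 200-call noisy ensemble (600 simulated seconds) for the
vertical-versus-horizontal error comparison and the validation-style
statistics. The ensemble reliably shows the geometric signature of the
layout: the median vertical error exceeds both horizontal medians,
because the 7.64 m vertical aperture supports far fewer hyperboloids
than the 20 m horizontal one.

## Known limitations

Accuracy degrades with range faster vertically than horizontally, and
beyond a few hundred meters the lag pattern becomes nearly
range-blind (the flat-valley geometry the grid oracle's beam search
exists to handle). Sound-speed error maps multiplicatively onto
retrieved ranges. Microphone-position error is not modeled; in long
deployments towers lean and self-survey would be needed. The simulator's
noise is white and stationary, unlike insect and wind noise. None of
these affect the package's core claim — that the lag-measurement and
inversion chain is correct under its stated model — but all of them
matter when transferring error figures to field data.
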