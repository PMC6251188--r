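---
title: "Methods: from voltage movies to wavefront dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from voltage movies to wavefront dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fibwave` analyses gridded optical-mapping movies of fibrillating tissue.
This vignette records the model choices, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the
numerical decisions a maintainer would want to know about. It states no
empirical result that the test suite does not itself compute.

## Signal model and conditioning

A movie is a `T x H x W` array of fluorescence samples with a valid-tissue
mask, frame interval `dt` (default 1 ms) and pixel pitch (default
0.44 mm). Conditioning runs: spatial binning, provisional dominant
frequency (DF), drift removal, final DF, band-pass, normalization.

* **Spatial bin (9 px, odd).** A uniform mean over a `bin x bin` window,
  renormalized by the count of valid in-window pixels, so masked-out
  pixels neither receive values nor bleed zeros into their neighbours.
* **Dominant frequency.** Per pixel, the frequency of maximal power in a
  demeaned, Hann-tapered, 4x zero-padded periodogram, searched in
  2–50 Hz by default. For records shorter than two cycles of the search
  floor, the floor is raised to `2 / duration` — a record cannot resolve
  frequencies below that. One mean DF per movie defines "the DF"
  everywhere downstream: a single band-pass for all pixels (per-pixel
  bands would desynchronize phase), and the cycle length (CL) `1/DF` for
  window sizes.
* **Ordering.** Drift removal needs a window of two mean CLs, which needs
  a DF; the DF estimator, being demeaned and tapered, is nearly
  insensitive to drift. The chain therefore computes a provisional DF on
  the spatially filtered signal, removes drift with that window, and
  re-estimates the DF on the detrended signal before filter design.
* **Band-pass (2 Hz to 125 % of mean DF).** A Kaiser windowed-sinc
  linear-phase FIR applied forward and backward (odd-reflection padding,
  FFT convolution), hence exactly zero group delay. The default design
  places the lower stop-band edge at `low/2` with a 30 dB single-pass
  target; two passes square the magnitude response, so a 0.5 Hz drift is
  attenuated far beyond the 20 dB contract (the tests evaluate the
  designed response directly). An equiripple design was specified
  upstream of this implementation; no equiripple designer is available in
  the dependency budget and the windowed-sinc design meets every stated
  response requirement. For records shorter than three filter lengths,
  the tap count is capped at `T/3` with a warning (the transition band
  widens); an explicitly requested over-long filter is an error.
* **Drift removal / normalization.** Centred moving mean (window = two
  mean CLs) subtracted, then min–max rescale to `[0, 1]`. Constant traces
  are removed from the mask with a warning rather than propagating NaN.

## Phase

Phase is the argument of the analytic signal `s + i H{s}` (FFT
half-spectrum method), which requires a zero-mean, envelope-balanced
trace. The pseudo-empirical-mean step detects extrema in a sliding window
of 0.9 mean CL; a sample must also be a 3-point local extremum, which
discards record endpoints sitting on monotone segments that the truncated
window would otherwise flag. Consecutive (maximum, minimum) pairs with
amplitude under 15 % of the median pair amplitude are deleted and
alternation is restored by keeping the more extreme member of same-type
runs. Natural cubic splines through the maxima/minima (held constant past
the end knots — no extrapolated overshoot) give envelopes `U`, `L`; the
normalized trace is `2 (s - L) / (U - L) - 1`, with `U - L` below
`1e-6` of the trace range mapped to 0. Pixels with fewer than two maxima
or minima are dropped from the mask.

The sign convention is fixed by tests: phase 0 at signal maxima, −π/2 on
the mid-upstroke, ±π at rest. The depolarization wavefront therefore sits
near the −π/2 isophase line. Spatial smoothing averages `exp(i theta)`
over a 9 x 9 mask-aware window and takes the argument — the circular mean,
which never averages across the ±π branch cut. Smoothing is purely
spatial; no temporal component is used.

## Phase singularities

The topological charge of a pixel is the sum of phase differences, each
wrapped to `(-pi, pi]`, around its closed 8-neighbour ring. The ring is
pixel-centred (rather than a 2 x 2 plaquette) because the
candidate-consensus rule below speaks of a pixel's eight neighbours. The
traversal orientation is fixed so that the vortex field
`theta = atan2(row - r0, col - c0)` carries charge +2π; chirality is the
sign of the loop integral. Boundary pixels and rings touching masked-out
pixels carry charge 0.

Candidates lie within 3.0 rad (the tolerance is in radians) of ±2π; an
actual singularity needs at least three same-sign candidate neighbours
and the minimal residual among itself and those neighbours, with exact
ties broken row-major (first wins). Positions are refined to sub-pixel
accuracy by a residual-weighted centroid over the local candidate
cluster; tests use a 1 px tolerance, so refinement is cosmetic for maps.

Tracking is greedy nearest-neighbour among same-chirality detections
(pairs sorted by ascending distance), link radius 5 px, gap 0 frames —
both chosen from the maximal plausible core speed at 1 ms frames, both
exposed in `run_config()`. Rotations are counted by temporally unwrapping
phase at a probe pixel offset 2 px perpendicular to the track's mean
motion (robust to meander and DF gradients); tracks whose probes never
land on valid pixels fall back to lifetime x local DF and are flagged. A
track with more than one rotation is a rotor.

## New wavefronts

A pixel is *active* when its phase lies in `[θ − 0.5, θ]` with θ = −π/2
and between one and three of its four adjacent in-mask neighbours have
phase above θ (the no-interpolation isophase rule; θ must stay at least
one band width away from ±π). Active pixels form 8-connected components.
A pixel is *propagated* when any active pixel of the previous frame lies
within the `(2r+1)²` square around it (dilation; `r` = 3 px ≈ 1.3 mm at
0.44 mm pitch, bounding one-frame conduction — the most sensitive knob of
the method, exposed in the configuration). Components are classified by
pixel majority (ties toward new); new components are
`new_after_quiescence` exactly when the previous frame had no active
pixel anywhere in the field, else `new_existing_AF`.

Three design decisions refine the event semantics:

* **Events are birth-frame-only.** A front is new in the frame it
  appears; one frame later its own pixels explain it.
* **Same-frame merging.** New components closer than `2r` to each other
  are merged into a single event: the neighbourhood radius is the
  method's spatial resolution, and a circularly expanding front whose
  isophase ring is split into arcs by the four-neighbour rule is one
  wavefront, not four.
* **Edge warm-up.** No new-wavefront call is made within half an extrema
  window of either record edge, where phase rests on constant-extended
  envelopes and the analytic signal's edge transient; without this, the
  first beat of a record is double-counted. `run_pipeline()` wires this
  in; the low-level function defaults to no warm-up.

The NWF density map places one unit of mass per event (spread over its
pixels by default, or at the centroid). Preferential sites are 8-connected
regions of the 3 x 3-smoothed map above mean + 2 SD over the mask that
contain at least two assigned events — a "preferential" site is a locus of
*repeated* initiation; one stray event is not a site. Events attach to a
site by origin-centroid containment, falling back to pixel overlap
(annular fronts have centroids that carry no mass). Site cycle lengths are
the intervals between successive events at the site; skipped re-entries
appear as harmonics of the base CL.

## Mechanism classification

The per-frame series (singularities, rotors alive past one cumulative
rotation, active pixels) drive a deterministic rule that formalizes the
qualitative activity-trace reasoning: `nwf_sustained` when the quiescent
fraction exceeds 1 % and at least 50 % of quiescence exits are initiated —
first new event within 20 ms — by a detected site; `rotor_sustained` when
a rotor is present in at least 80 % of frames and the quiescent fraction
is at most 1 %; otherwise `mixed`. The four thresholds are configurable;
they are this package's operationalization of a qualitative argument, not
published constants. Mood's median test drops values equal to the grand
median, and uses exact enumeration of the 2 x 2 tables with fixed margins
whenever the pooled sample is at most 40 (or any expected cell is below
5), chi-square with 1 df otherwise. Density-map correlations are Pearson
over mask pixels on raw counts; smoothing before correlating is available
but off by default.

## Synthetic world

The generators state the world the tests run in; all are bitwise
deterministic given a seed.

* **Analytic spiral** — `phase = wrap(2π f t + χ atan2(Δr, Δc) − k d)`,
  voltage `cos(phase)`; winding is exactly +χ, so core position and
  chirality are known per frame. Defaults: 128 x 80 grid, 0.44 mm, 1 kHz.
* **Focal source** — stylized optical action potential (2 ms linear
  upstroke, cosine repolarization of 35 ms) launched from an origin every
  cycle with activation time `distance / cv`. Defaults: CL 80 ms, cv
  0.5 mm/ms — slowed, AF-range conduction that also keeps the one-frame
  apparent isophase displacement inside the 3 px neighbourhood radius the
  detection rule presumes. The generator refuses parameter sets where a
  beat would collide with the previous wave's tail, so full inter-beat
  quiescence is guaranteed. Recordings start one full cycle before the
  first beat (a quiescent baseline for the phase estimator) and end
  shortly after the last wave clears: real fibrillation does not pause
  for hundreds of milliseconds at the end of a record, and a long dead
  tail produces a slow phantom crossing of the isophase band (a known
  limitation, see below).
* **Reaction–diffusion** — two-variable Aliev–Panfilov kinetics
  (`a = 0.11, k = 8, eps0 = 0.01, mu1 = 0.2, mu2 = 0.3`), explicit Euler,
  5-point Laplacian, no-flux boundaries, stability-checked step. One time
  unit maps to 4 ms: the model's rotation period (~26 units) then lands
  near 100 ms, i.e. dominant frequencies in the fibrillation range;
  `dx = 1` keeps the reentrant core inside a 96 x 64 field. Spirals are
  initiated by a broken-wave protocol (excited half-strip plus a
  refractory block over its free end) — an S1–S2 cross-field protocol at
  this domain size failed to leave an interior core.
* **Two-layer breakthrough** — two sheets coupled only at discrete
  connection sites, each a small disc (radius 2.5 px) with a resistive
  current `g (u_other − u)`, `g = 8`; a single lattice node cannot excite
  the receiving sheet (the classic source–sink mismatch), which is why
  connections have a footprint. The driven (endocardial) layer runs the
  broken-wave spiral; the receiving layer is quiescent until activity
  crosses a connection, and each upward crossing of the disc-mean
  activator is a ground-truth breakthrough. Fibrosis removes lattice
  edges stochastically with a 4 x longitudinal bias at a stated overall
  fraction (paper-scale range up to 16.6 %); islands (10 per surface,
  radius 2.4 mm) scale the recovery rate up locally, shortening the local
  action potential; an optional inter-layer gradient shortens the
  epicardial action potential. The whole sheet is one fibrosis region —
  the region-resolved histology that drove per-region fractions in the
  source experiments has no in-silico counterpart here.
* **Optical noise** — i.i.d. Gaussian noise scaled to a stated SNR
  (signal power = variance over mask samples) plus per-pixel sinusoidal
  baseline drift with random phase.

What a green test does *not* establish: the generators have no motion
artifact, no spatially correlated noise, no fluorescence heterogeneity,
no fiber-direction anisotropy in conduction (only in fibrosis), and the
stylized AP has no restitution. Mechanism-label accuracy on this world
bounds nothing about canine preparations.

## Numerical choices and degenerate inputs

* Angles wrap to the half-open interval `(-pi, pi]`; the lower endpoint
  folds to +π.
* Envelope degeneracy: `U - L < 1e-6` of the trace range maps to 0.
* Charge-residual ties in singularity detection break row-major.
* Exactly lattice-centred analytic vortices sample the singular point
  itself (`Arg(0)`); tests use off-lattice cores, and real data never
  hits this.
* The explicit reaction–diffusion step clamps `u` to `[0, 1.05]` and `v`
  to `[0, 3]` — standard guards against the overshoot oscillation of
  explicit Euler near strong point currents.
* Isophase values within one band width of ±π are rejected (documented
  limitation of the no-interpolation rule).

## Known limitations

* Terminal quiescence: after the last activity of a record the analytic
  signal keeps creeping and eventually sweeps the whole field through the
  isophase band, producing a phantom event ~100 ms into a dead tail. The
  edge warm-up suppresses the symmetric start-of-record case; recordings
  that end mid-quiescence should be trimmed.
* The apparent isophase-front speed at a focal onset can exceed the
  tissue conduction velocity (phase leads the upstroke by a
  distance-dependent amount for the first beats); with conduction above
  ~0.6 mm/ms at 1 ms frames the 3 px neighbourhood can be outrun and a
  single onset double-counts. The radius is configurable and should be
  raised for fast-conducting preparations.
* `ps_rate` reports tracked singularities; per-frame raw detections are
  also exported since the corresponding experimental convention is
  ambiguous.
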