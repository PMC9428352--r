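---
title: "Simulating closed-loop sensorimotor-rhythm BCI experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating closed-loop sensorimotor-rhythm BCI experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrsim)
```

## The problem

Evaluating a motor imagery EEG brain-computer interface (BCI) — its decoder,
task design, and their parameters — normally requires live human sessions:
subjects modulate their sensorimotor rhythms (SMR, here the 8–12 Hz alpha
band over motor cortex) to move a cursor, and the closed feedback loop
between decoder and user is an essential part of the system. Offline
re-analysis of recorded data cannot capture that loop. `smrsim` replaces the
human and the amplifier with a generative model: a scripted controller (or a
pointing device) supplies a continuous intention velocity, an encoding model
turns it into source-level rhythm amplitude modulation, a lead field projects
the sources to scalp electrodes, and the standard online SMR decoding chain
turns the synthetic EEG back into cursor movement. Everything downstream of
the intention signal — filtering, spatial filtering, spectral estimation,
normalization, gain, task logic, metrics — is the same code a live experiment
would exercise.

## The generative model

### Intention encoding

A raw intention velocity $\vec v$ is scaled to $\vec v' = S_{in}\vec v$ and
renormalized to unit length whenever $|\vec v'| > 1$, so $|\vec v'| \le 1$.
Four sigmoids, one per (hemisphere $h$, control axis $a$) pair, map the
scaled intention to amplitude modulation factors

$$A_{h,a} = \frac{1}{1 + e^{\alpha_{h,a}(v'_a + k_{h,a})}} \in (0, 1),$$

which multiply the peak amplitude of the corresponding source-level alpha
signal: $A \approx 1$ means an unattenuated rhythm (rest), small $A$ means
event-related desynchronization (ERD). The gain signs encode the
Wolpaw–McFarland control scheme: the horizontal pair is mirrored between
hemispheres (lateralized hand imagery moves the cursor left/right), the
vertical pair shares its sign (bilateral desynchronization moves the cursor
up, rest moves it down).

Two stock configurations are provided. The **classic** configuration
(`make_classic()`) uses $|\alpha| = 8$ and offsets $\mp 0.5$ opposing the
gain sign, so that $A_{h,a}(0) \approx 0.982$ — no intention means no
attenuation, and only contralateral ERD is modelled. The **centered**
configuration (`make_centered()`) zeroes the offsets so every factor is
exactly $0.5$ at rest and moves symmetrically in both directions — an
idealized orthogonal code that additionally models ipsilateral
synchronization. The magnitude 8 makes the sigmoids saturate near full
intention while reproducing the boundary conditions above; the published
description of these configurations is qualitative ("configured manually"),
so these constants are package defaults, fixed once. A **perturbed**
configuration carries arbitrary per-pair parameters, typically fitted from
recorded sessions (below).

### Source signals

Task-related activity is generated per epoch: uniform white noise is
bandpass filtered with a Kaiser-window FIR (passband 5–12 Hz, transition
bands 3–5 and 12–14 Hz, 60 dB stopband), tapered with a Tukey window (width
0.95 of the epoch, cosine fraction 0.8), and peak-normalized; the current
$A_{h,a}$ scales each frame to $A \times 100$ µV-equivalent units. The two
axis signals of a hemisphere are summed onto that hemisphere's hand-knob
region of interest (ROI). Background activity is Brownian ($1/f^2$) noise —
integrated white noise, mean-removed and peak-normalized to 50 µV-equivalent
per epoch — on 500 random vertices, with the random walks continuing across
epochs. The 2:1 task-to-background peak ratio is the model's source-level
signal-to-noise statement.

Two scheduling details are deliberate package choices, because the epoch
bookkeeping of real-time generation admits several readings:

* **Epoch length is 2 s** (500 samples at 250 Hz). The Kaiser design above
  has order ≈ 454 at these transition widths, so generation epochs must hold
  at least 455 samples; 2 s is the smallest round epoch that accommodates
  the filter with a steady-state segment.
* **Epochs are streamed with 50 % overlap-add.** Concatenating Tukey-tapered
  epochs back to back silences the rhythm for a large fraction of each
  epoch (cosine fraction 0.8 leaves only a 20 % flat plateau). A rhythm
  that vanishes twice per second is not a plausible sensorimotor rhythm,
  and its power collapses interact pathologically with the decoder's
  rolling normalization (see *Known limitations*). Overlap-adding the same
  tapered epochs crossfades them, leaving no silent gaps while preserving
  the published per-epoch recipe. The generator state makes the stream a
  pure function of (configuration, seed, modulation sequence).

### Forward model

A lead field maps source dipole amplitudes to scalp potentials. Lead fields
computed elsewhere (e.g. by BEM solvers on realistic anatomy, such as the
published 32-channel × 15,002-vertex matrix) can be loaded from a
plain-text container (`read_leadfield()`); the package also provides an
analytic **three-shell concentric-sphere** model
(`build_spherical_leadfield()`): brain/skull/scalp radii 0.087/0.092/0.100 m,
conductivities in ratio 1 : 1/80 : 1, one fixed radially-oriented dipole per
vertex of a Fibonacci-lattice source space (default 2000 vertices at radius
0.078 m), and a Legendre series truncated at 60 terms with an explicit
convergence guard. The series solves the shell boundary-value problem per
harmonic degree; its single-shell case is verified in the test suite against
an independent brute-force surface boundary-integral oracle to well below
1 % relative error.

Hand-knob ROIs default to 10° spherical caps under C3 and C4, so the
simulated ERD is maximally visible at the control channels. Because the
published source amplitudes (100/50 µV) are stated without a dipole-moment
scale, `calibrate_leadfield()` rescales the whole gain matrix by one scalar
such that a unit-amplitude source spread over a hand-knob ROI produces a
1 µV-equivalent peak at its nearest channel. A single global scalar (rather
than per-ROI column scaling) keeps every vertex in one consistent unit, so
the source-level signal-to-noise statement remains meaningful after
projection.

## The online decoder

Each update frame (default 25 frames/s; 250 Hz sampling makes 10 samples per
frame — 25 rather than the display-oriented 30 frames/s keeps frames
sample-aligned) the decoder:

1. notch-filters 58–62 Hz and bandpass-filters 2–60 Hz (causal streaming FIR
   with persistent state),
2. computes the small Laplacian at C3 and C4 (center minus the unweighted
   mean of F3/T7/Cz/P3 and F4/T8/Cz/P4),
3. estimates alpha power (8–12 Hz) on the most recent 0.5 s window with a
   Burg AR(16) model, integrating the AR spectrum over the band,
4. forms the raw controls $C_x = P_{C4} - P_{C3}$ and
   $C_y = -P_{C4} - P_{C3}$,
5. Z-scores each against its own rolling history over the past BW seconds
   (sample standard deviation; degenerate histories yield 0),
6. applies the velocity gain $S$ and the cursor speed cap CV, and
7. integrates position by one frame duration, clamped to the screen.

BW (30/**60**/90/120 s), NT (**0**/24/48 carried-over trials) and CV
(200/**250**/300/350 px/s) have the published semantics and defaults; NT = 0
resets the normalization buffer at a run boundary and devotes the next run's
first trial to calibration, NT > 0 carries the buffer across the boundary
(48 across two). The calibration trial deliberately under-fills long buffers,
reproducing the published behaviour rather than correcting it.

Two constants have no published value and are package choices: AR order 16
with a 0.5 s spectral window (common online SMR practice; both
configurable), and the velocity gain $S = 250$ on a 1000-pixel workspace.
$S$ is a system-dependent constant in the source system; it is set here so
that one unit of normalized control reaches the default CV cap, making CV
the operative speed limit — with substantially smaller gains the simulated
subject cannot traverse the workspace within the 6 s feedback window at all,
and the CV parameter would have no observable effect.

Internally the closed-loop engine filters the two Laplacian-combined
channels with the cascaded notch+bandpass kernel instead of filtering every
channel and then combining; both operators are linear and time-invariant, so
the results are identical (this equality is property-tested), and the
recorded EEG stream itself is always the raw projected signal.

## Task engine

Trials follow the published structure — 3 s rest, 2 s preparation with the
target shown, up to 6 s of feedback control; first contact decides hit
(correct target), miss (wrong target) or timeout. Targets are bars of
thickness 0.0625 normalized units on the workspace edges; contact uses the
cursor center and closed boundaries, and a corner contact resolves in favour
of the trial's correct target. Paradigms: `1d-lr`, `1d-ud` (each gating the
decoded velocity to its axis) and `2d-lrud`. Target sequences are
block-randomized — shuffled blocks containing one trial per direction — so
every run is balanced. The default session is the published 10-run sweep
(4 BW + 2 NT + 4 CV runs, the NT = 0 run aliased to the BW = 60 default
run), with value order randomized within each parameter type. EEG is
generated and recorded through rest and preparation (with zero intention)
so recordings resemble complete sessions; decoding and normalization-buffer
updates are gated to feedback.

Scripted controllers replace the human: `proportional` (gain 8, i.e.
intention saturates until the cursor is within 1/8 workspace of the target —
a naturalistic full-effort reach), `constant` direction, and
`noisy` proportional with Gaussian directional noise (default σ = 20°).

## Perturbed fitting

`fit_perturbed()` reproduces the subject-fitting pipeline: feedback epochs
of hit trials are notch- and bandpass-filtered, reduced to Burg alpha power
at Laplacian C3 (left hemisphere) and C4 (right), averaged per direction
and per control axis into 12 mean powers
($\mu_L, \mu_R, \mu_U, \mu_D, \mu_{LR}, \mu_{UD}$ per hemisphere),
max-normalized per (hemisphere, axis), assigned intention values
$v' \in \{-1, 0, 1\}$, and fitted with per-pair sigmoids by iterative
nonlinear least squares (logit-linear initialization, Levenberg–Marquardt
refinement; flat profiles are flagged degenerate rather than fitted).

On the vertical axis the published assignment maps the up-target mean to
$v'_y = -1$; this package uses the task-space convention instead — upward
intention is the bilateral-desynchronization pole, so $\mu_U$ (the
low-power mean) is assigned $v'_y = +1$ — keeping the fitted sign pattern
consistent with the encoding that generated the data.

Calibration data come from a 1d-lr session plus a 1d-ud session
(`perturbed_calibration_specs()`), mirroring the original calibration
protocol. Calibration favours reachability over decoding precision, because
only hit trials inform the fit: it uses BW = 120 s (sustained rest-pole
control is otherwise normalized away within a trial by the rolling Z-score),
CV = 350 px/s, and a raised velocity gain of 500. The down direction — the
rest pole of this control scheme — remains the slowest, so the vertical
session runs twice with its buffer carried over.

## What the simulation does and does not show

The synthetic EEG reproduces the *decodable structure* of motor imagery
EEG — band-limited rhythms over the hand knobs whose amplitudes follow the
encoded intention, on a 1/f²-like background, mixed through a physical
forward model — and therefore supports closed-loop experiments on decoder
and task parameters. It does not contain artifacts (blinks, EMG), non-alpha
rhythms, inter-subject anatomical variability, or learning effects, so
passing tests demonstrate properties of the decoding chain under the model,
not claims about human data. Three structural findings from the test suite
are worth stating explicitly:

* **Asymmetric-clipping up-bias.** Alpha power is nonnegative and spiky, so
  the raw control $C_y$ is left-skewed; the Z-score restores zero mean, but
  the CV cap clips the rare large negative excursions harder than the
  frequent small positive ones, leaving a net upward drift. The classic
  configuration's published up-right diagonal bias under rightward intention
  reproduces clearly (mean decoded direction ≈ 8° above horizontal in the
  bundled check), but the idealized claim that the centered code eliminates
  the vertical component does not: integrated alpha power is quadratic in
  the amplitude factors ($P \sim A_x^2 + A_y^2$), so $P_{C3} + P_{C4}$ is
  not invariant under the centered exchange, and the measured time-averaged
  deviation for the centered code is ≈ 29°, not the ideal < 15°.
* **Centered vs. classic.** The two stronger published encoding effects —
  smaller true-vs-decoded angle deviation and shorter trajectory length for
  the centered code — reproduce in all seeded subjects. The weaker
  covariance effect does not: pooled position covariance is near zero for
  the classic code under scripted control (the up-bias is common to left
  and right reaches and cancels), and slightly positive for centered, so
  "centered covariance closer to zero" fails in this simulator.
* **The rest pole is hard.** Downward (rest) control is the slowest
  direction under this scheme; at default parameters down targets are
  essentially unreachable within 6 s, which motivated the calibration
  protocol above.

## Problem sizes and numerical choices

The bundled checks run at desk scale, chosen once: the spherical lead field
uses 2000 vertices (the analytic model is resolution-independent; ROI caps
hold ~15 vertices each); closed-loop comparisons use 3 seeded subjects × 3
runs of 24 trials (encoding comparison), 50 seeds × 4-trial runs (CV sweep),
and 12 seeds (bias checks); the boundary-integral oracle uses 1500 surface
nodes. Spectral estimates integrate the AR spectrum on a 0.1 Hz grid (0.02 Hz
in tone tests, where AR peaks are very narrow). Degenerate inputs are
defined, not exceptional: zero-variance Burg windows return power 0,
σ = 0 normalization histories return 0, flat μ profiles are flagged, and
the spherical series raises an error if its truncation bound is exceeded
rather than returning a partial sum.
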