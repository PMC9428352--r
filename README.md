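# smrsim

Closed-loop simulation of sensorimotor-rhythm (SMR) motor imagery EEG
brain–computer interface (BCI) experiments in R.

Testing a BCI decoder or task design on humans is slow and expensive, and
offline re-analysis of recorded EEG cannot capture the feedback loop between
decoder and user. `smrsim` closes that loop synthetically: a scripted
controller (standing in for a subject's naturalistic pointing movements)
emits a continuous intention velocity, an encoding model converts it into
source-level alpha-band (8–12 Hz) amplitude modulation over the motor-cortex
hand knobs, a lead field projects the sources to scalp electrodes, and the
standard online SMR decoding chain converts the synthetic EEG back into
cursor movement — so decoder and task parameters can be swept in faithful
closed-loop center-out experiments without an amplifier or a subject.

## The model in brief

Intention is scaled to $|\vec v'| \le 1$ and mapped through four sigmoids,
one per (hemisphere $h$, axis $a$) pair:

$$A_{h,a} = \frac{1}{1 + e^{\alpha_{h,a}(v'_a + k_{h,a})}},$$

the amplitude modulation factor of that hemisphere/axis source signal
(small $A$ = event-related desynchronization). Configurations: **classic**
(contralateral ERD only, $A(0) \approx 1$), **centered** (symmetric about
0.5), and **perturbed** (subject-fitted via `fit_perturbed()`). Task signals
are Kaiser-FIR bandpassed white noise (5–12 Hz), Tukey-tapered and
peak-normalized to $A \times 100$ µV-equivalent; background is 1/f² Brownian
noise (peak 50) on 500 random vertices. Scalp potentials come from a
three-shell spherical head model (or a lead field loaded from file). The
decoder applies a 58–62 Hz notch and 2–60 Hz FIR bandpass, small-Laplacian
C3/C4, Burg AR(16) alpha power, the control law
$C_x = P_{C4} - P_{C3}$, $C_y = -P_{C4} - P_{C3}$, rolling Z-score
normalization over the past BW seconds, velocity gain and CV speed cap.
Runs of 24 block-balanced trials (3 s rest / 2 s prep / ≤ 6 s feedback)
compose sessions, by default the 10-run BW/NT/CV parameter sweep. See the
methods vignette (`vignettes/smrsim-methods.Rmd`) for assumptions,
parameter rationale and known limitations.

## Worked example

```r
library(smrsim)

# full rightward intention under the classic encoding: the left-hemisphere
# horizontal factor collapses (contralateral ERD), everything else stays up
A <- modulation(make_classic(2), scale_intention(c(1, 0)))
round(A, 3)
#>  left_x  left_y right_x right_y
#>   0.018   0.982   1.000   0.982

# one 8-trial 1D left/right run, scripted proportional controller
spec <- session_spec(runs = list(run_spec(8, "1d-lr", "demo")), seed = 42)
session <- run_session(spec, record_eeg = FALSE)
session
#> <smr_session> 1d-lr, 1 runs, 8 trials (6 hits), seed 42

session_metrics(session)
#>   run label paradigm bw nt  cv n_trials ptc avg_decision_time
#> 1   1  demo    1d-lr 60  0 250        8  75             4.195
#>   avg_integrated_distance n_hits n_misses n_timeouts
#> 1               0.6103615      6        0          2

tm <- trajectory_metrics(session$trials[[4]])
#> trial 4: 22.8 deg mean deviation, path 1.07 workspace units
```

The run metrics are the published ones: `ptc` is the percentage of all
presented trials hit (75 % here), `avg_decision_time` averages the feedback
time with timeouts counted as the full 6 s, and `avg_integrated_distance`
is the mean cursor-to-target distance over feedback (workspace units, lower
is better). Trajectory metrics quantify decoding bias per trial: the mean
angle between true and decoded velocity, and the decoded path length.

A thin CLI wrapper is installed at `inst/cli/smrsim`
(`smrsim run|sweep|metrics ...`) for shell use.

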