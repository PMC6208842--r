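---
title: "Models and methods behind trajtask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trajtask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajtask)
```

# The task and what the package computes

`trajtask` implements the full analysis chain of a timed
trajectory-prediction go/no-go experiment. A subject fixates a cross 20
degrees above screen center; after a variable fixation period (390, 890, or
1900 ms) a stimulus travels in a straight line toward one of eight final
locations on a 4 x 2 grid, four inside a visible 10 x 10 degree target
square (go) and four outside it, two on each lateral side (no-go). Flight
takes 385, 485, or 585 ms (plus rare 985 ms probes), so the go/no-go
decision and the reach must both finish inside roughly half a second. Eye,
hand, and pupil are recorded at 200 Hz.

The package provides four things: exact counterbalanced schedule
generation; a generative simulator of complete sessions with known ground
truth; the outcome extractors (seven eye-movement and two hand-movement
parameters, eight task-evoked pupillary response parameters, automated
trial QC); and performance/signal-detection analysis with normality-gated
group statistics.

# Schedule generation

Each 80-trial block must satisfy simultaneously: 24 trials per flight
speed with exactly 3 per final location, 24 trials per fixation duration,
8 probes (one per location, 1000 ms fixation), and 10 trials per location.
Rather than searching for a feasible assignment, the generator constructs
one: for every (location, speed) cell the three repetitions receive a
seeded permutation of the three fixation durations. Every (speed,
fixation) pair then occurs once per location (8 per block), every
(location, fixation) pair three times, and all marginals follow by
construction. A final seeded shuffle sets presentation order. This is
exact for any design in which the repetition count is a multiple of the
number of fixation durations; anything else is rejected with the violated
constraint named. Each trial also draws a duration jitter from
{-5, 0, +5} ms, emulating the asynchrony between a 60 Hz display and the
200 Hz recording clock; the jitter is stored in the schedule so that
downstream analysis can use effective durations exactly.

The grid geometry is under-determined by the angular constraints alone
(inner columns inside the square, outer columns outside on both sides,
equidistant neighbors). The default places columns at x = ±2.5 and ±7.5
degrees with 5-degree spacing, rows at ±2.5 degrees around a target center
at (0, -15). Only angular relations are enforced; physical pixel placement
is out of scope.

# The synthetic subject

The simulator is the package's replacement for unavailable human
recordings: every downstream claim is tested against its known parameters.
It is deliberately phenomenological - no main-sequence fitting, no
neuro-physiological pupil model - but each channel reproduces the features
the extractors rely on.

**Decision.** Equal-variance signal detection: evidence
$e \sim \mathcal{N}(d'_{\text{speed}} \cdot \mathbb{1}\{\text{go}\},\, 1)$,
touch iff $e > c$. The threshold $c$ is absolute (not relative to
$d'/2$), so a single value yields a constant false-alarm rate across
speeds while hit rates fall as $d'$ drops - the characteristic empirical
pattern for this task family. Defaults: $d'$ per speed of 1.14/1.99/2.25
(control) and 1.48/2.19/2.57 (expert), $c = 1.0$. Misses arise two ways:
deciding "no-go" on a go trial, and - with probability 0.02 - planning the
touch after flight end (a late touch is classified as a miss, exactly as
the classifier treats real data).

**Gaze.** Fixation-period gaze is the cross position plus white noise
(default SD 0.3 degrees) and a slow random-walk drift (0.5 deg/s step SD;
0.3 for experts), which makes fixation error grow with fixation duration.
After a normal saccadic latency draw (mean 220 ms control / 205 ms expert,
SD 20 ms), a minimum-jerk saccade of duration $21 + 2.2A$ ms (amplitude
$A$ in degrees) lands on the stimulus trajectory; its peak velocity,
$1.875\,A/D$, is far above the 50 deg/s detection threshold for any
relevant amplitude. Pursuit then follows the stimulus with a lag (100 ms)
and gain (0.9 control / 0.95 expert). One consequence worth knowing: at
the default gain the pursuit velocity on the three main flight speeds
stays above 50 deg/s (the stimulus moves at 85-100 deg/s), so the
amplitude detector's offset criterion - velocity back below threshold for
two consecutive samples - is only reached on slow probe trajectories.
On fast trials the "primary saccade amplitude" therefore approaches the
full gaze displacement across flight; oracle tests for amplitude use
probe-speed fixtures where offset is observable.

**Pupil.** Diameter = baseline (3.5 mm) + a linear ramp during fixation
(0.12 mm/s, held constant after stimulus onset) + an Erlang-style
task-evoked component $A\,(t/t_p)^k e^{k(1 - t/t_p)}$ locked to stimulus
onset with amplitude 0.4 mm and shape $k = 10$, plus white noise
(0.02 mm). The latency-to-peak parameter is a per-(fixation, speed)
matrix expressed from trial onset; expert presets peak 60 ms earlier at
the short fixation for fast/medium speeds and 80 ms later at the long
fixation. Locking the evoked component to stimulus onset keeps the
fixation-period slope identifiable: the OLS fixation slope recovers the
generating ramp to within numerical tolerance on noise-free traces and
within 5% at session scale.

**Hand.** On touch trials, speed stays sub-threshold until the hand
reaction time (mean 230 ms, SD 25 ms), then follows a Gaussian bell with
peak $20e^2 \approx 148$ deg/s, placed so that the first 20 deg/s
crossing coincides exactly with the reaction time; the touch lands at
reaction time + 90 ms movement time on the final location plus aiming
error (SD 0.8 degrees). Hand kinematics are kept in angular units to
match the printed 20 deg/s threshold. On no-touch trials speed is folded
normal noise clamped strictly below threshold.

**Blinks** are a Poisson process (4/min, 150 ms) flagged in the trace and
blanked in gaze and pupil channels.

What the simulator does **not** emulate: saccadic undershoot/corrective
saccades, pupil foreshortening, tracker calibration drift, touch-and-hold
release dynamics, or the magnitudes of the human group differences (the
expert preset only shifts directions). Passing recovery tests therefore
demonstrates that the extractors measure what they claim on data whose
generating process is known - not that real recordings are this clean.

# Outcome extraction

Angular velocity is the central difference of position smoothed by a
centered 5-sample (25 ms) moving average - a compromise between the 200 Hz
noise floor and saccade-onset bias; shrinking windows at trace edges
preserve length. All threshold comparisons are strict (`>`), first
crossing wins, no refractory period. Eye response time is the first
post-onset crossing of 50 deg/s; the saccade ends when velocity stays
below threshold for 2 consecutive samples, and amplitude is the gaze
displacement between those two samples. Tracking samples are flight
samples with gaze-stimulus distance strictly below 8 degrees; total
tracking time is 5 ms per sample, and the percentage uses the flight
duration as denominator (tracking is undefined before stimulus onset).
Mean gaze-stimulus distance averages tracking samples only, hence is
bounded by 8 degrees. Fixation error is the mean Euclidean distance to
the cross over the whole fixation period.

Pupil outcomes use 100 ms windows (first 100 ms of trial = baseline, last
100 ms of fixation, last 100 ms of stimulus), three OLS slopes (whole
trial, fixation, flight), and the global maximum for peak size change and
latency to peak (earliest sample on ties). The trial clock starts at
fixation onset - peak latencies in the conditions of interest exceed the
flight duration, which is only consistent with a fixation-onset
reference - and an auxiliary column reports the latency from stimulus
onset so either convention can be analyzed. Window means require at
least 10 usable samples; otherwise the field is absent with a reason.

Quality control replaces manual blind rating with explicit rules: a trial
is rejected when a blink/gap overlaps a critical window (first 100 ms,
stimulus onset ±50 ms, last 100 ms) or exceeds the 200 ms interpolation
span; when more than 30% of samples are missing; or when gaze is off
screen in more than 20% of samples. Shorter gaps are linearly
interpolated. The reliability gate then requires at least 10 valid trials
per subject and parameter for inclusion.

# Performance and statistics

Touches before the stimulus reaches its final position on go trials are
hits; late or absent touches are misses; no-go trials split into correct
rejections and false alarms. The "hold" requirement is collapsed into the
touch event for simulated data; a `held = FALSE` flag on real data
demotes a hit. Sensitivity is $d' = z(H) - z(F)$ with criterion
$c = -(z(H) + z(F))/2$; rates of exactly 0 or 1 are adjusted before the
transform (log-linear rule by default, $1/(2N)$ clamp selectable - the
choice of correction is configurable because no single convention is
universal). Probe trials are excluded from performance denominators by
default (configurable), since their 985 ms flights are not part of the
three-speed design.

Group comparisons aggregate to subject-level means, gate on Shapiro-Wilk
normality per group at alpha = 0.05, and run either pooled-variance t
tests / repeated-measures ANOVA with Bonferroni-corrected post-hocs, or
the Mann-Whitney U test. One property worth stating precisely: the power
of a two-sample t test against a group shift of $3\,\mathrm{SD}/\sqrt{n}$
(i.e., 3 SEM) is about 52% regardless of $n$; the test suite therefore
checks the empirical detection rate against the analytic
`power.t.test` oracle rather than against an arbitrary detection-rate
target.

# Numerical choices and problem sizes

Sampling is exact on the 5 ms grid; all schedule durations are multiples
of 5 ms, so detector quantization error is at most one sample (first
crossings are biased late by about half a sample on average). Seeds flow
from a single master seed through `withr::with_seed`, so every artifact
is a pure function of (configuration, seed); per-block and per-subject
seeds are drawn below $2^{31}$. The test suite exercises: 100 seeded
blocks for the count invariants, 100 simulated sessions of 80 trials for
the partition and tracking-conservation invariants, 50 replicates of
72 + 72 decisions per speed for d-prime recovery (observed |bias| below
0.15, dominated by the late-touch miss mechanism), 50 replicates of 24
trials per condition for pupil parameter recovery (condition-mean latency
within 10 ms, fixation slope within 5%), and a deterministic 2 subjects
per group x 3 blocks end-to-end run. These sizes were chosen to give
stable Monte-Carlo estimates at interactive runtimes.

# Known limitations

Saccade amplitude merges into pursuit on fast trials (see above); the
simulator's expert/control contrasts are directional presets, not effect
size estimates; the statistics module implements the standard univariate
routines only (no mixed models); vendor-native tracker formats are not
read - sessions enter as the documented CSV dialect.
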