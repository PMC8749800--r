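---
title: "Detecting bilateral gait events from a single in-shoe sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bilateral gait events from a single in-shoe sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitims)
```

## The problem

Temporal gait parameters that involve *both* lower limbs — the double-support
times, and the symmetry indexes of stride and stance time — normally require
two synchronised sensors, one per foot. But walking is periodic and the two
legs are phase-locked through the pelvis, so the contralateral foot's contact
(opposite heel strike, OHS) and departure (opposite toe off, OTO) leave
detectable signatures in the instrumented foot's own motion signal. If those
two events can be read from a single in-shoe sensor alongside the foot's own
heel strike (HS) and toe off (TO), every bilateral temporal parameter follows
without any cross-sensor synchronisation.

`gaitims` implements that approach for a 6-axis in-shoe inertial sensor
sampling at 100 Hz: rule-based detection of HS, TO, foot-flat, OHS and OTO
from one foot's signals; the nine bilateral temporal parameters with
multi-stride averaging; and the method-comparison statistics used to validate
such a detector against a reference motion-capture system.

## Signal model and event signatures

The sensor reports accelerations in g (`A_y` positive posteriorly, `A_z`
positive superiorly, so quiet stance sits near +1 g) and angular velocities
in deg/s (`G_x` positive in plantarflexion). Four morphological features
carry the events:

* **HS** — the anterior–posterior acceleration `A_y` shows a sharp valley
  immediately after the cycle's pre-impact maximum; the valley is the contact
  instant.
* **TO** — after the foot-flat state `A_y` traces a W-shaped pattern; its
  first valley is toe off.
* **Foot-flat** — after HS the foot plantarflexes onto the ground and `G_x`
  settles to baseline; the settling instant is a concave *gradient turning
  point* (GTP), a sample where the slope changes abruptly. OTO follows
  foot-flat by 2% of the gait cycle (foot-flat sits near 8% of the cycle,
  OTO near 10%).
* **OHS** — once the heel rises, `G_x` grows slowly (low-rotation motion
  while the opposite foot still supports the body) and then, when the
  opposite heel strikes and the knee flexes into pre-swing, the slope breaks
  upward into high-rotation motion. The break point is OHS.

## Locating gradient turning points: triangle thresholding

A GTP inside a monotone curve segment is located by the triangle
thresholding algorithm (TTA). Given two reference points
$P_A(t_1, u_1)$ and $P_B(t_2, u_2)$ bracketing the target, the chord

$$U(T) = \frac{u_2 - u_1}{t_2 - t_1}(T - t_1) + u_1$$

is drawn and the perpendicular distance of every sample $Q(T)$ from it,

$$D(T) = \frac{\left|U(T) - Q(T)\right|}{\sqrt{1 + \left(\frac{u_2-u_1}{t_2-t_1}\right)^2}},$$

is maximised: $T_{GTP} = \arg\max_{t_1 \le T \le t_2} D(T)$. Ties are broken
by the earliest sample, and the result is invariant under a common positive
rescaling of the curve. `tta_gtp()` implements exactly this; the test suite
checks it against an independent exhaustive maximisation on a thousand random
monotone segments.

Anchor choices per event:

* **Foot-flat**: $P_A$ at 20% of the gait cycle after HS (virtually everyone
  is foot-flat by then), $P_B$ at the prominent local maximum of the channel
  nearest in time to $P_A$ — searching both directions, earlier on ties, so
  $P_B$ usually precedes $P_A$; the chord segment is always ordered by time.
* **OHS**: $P_A$ at the first sample after foot-flat whose amplitude exceeds
  the channel threshold (0.15 g for `A_y` relative to the foot-flat
  baseline, 1.15 g for `A_z` on the raw gravity-included amplitude,
  30 deg/s for `G_x`), $P_B$ at the channel's extreme value (minimum for
  `A_y`) before TO. The thresholds sit above sensor noise; we additionally
  require the threshold to be exceeded on two consecutive samples, a
  debounce that changes nothing on clean signals but suppresses spurious
  early anchors under noise.

`G_x` is the default detection channel; `A_y` and `A_z` remain selectable so
the candidate-feature comparison can be reproduced. On the synthetic
templates the `A_y` OHS candidate lands on a late corner of the push-off
pattern (~60 ms late), which mirrors its poor ranking on real recordings.

Detection is causal: each stride uses only samples up to its own end, and its
cycle length comes from the *preceding* heel-strike pair, so the algorithm
ports to a streaming edge device. The first stride of a trial therefore has
no cycle estimate and reports only its heel strikes.

## Bilateral temporal parameters

With $T'$ denoting the next stride's events:

$$DST_1 = T_{OTO} - T_{HS}, \quad DST_2 = T_{TO} - T_{OHS}, \quad
  DST_t = DST_1 + DST_2$$

$$T_{sta\_L} = T'_{OTO} - T_{OHS}, \quad T_{str\_L} = T'_{OHS} - T_{OHS},
  \quad T_{sta\_R} = T_{TO} - T_{HS}, \quad T_{str\_R} = T'_{HS} - T_{HS}$$

$$SIS_{ta} = \frac{T_{sta\_L} - T_{sta\_R}}{0.5\,(T_{sta\_L} + T_{sta\_R})},
  \qquad
  SIS_{tr} = \frac{T_{str\_L} - T_{str\_R}}{0.5\,(T_{str\_L} + T_{str\_R})}$$

The symmetry indexes keep their sign, so they express both the degree and
the direction of asymmetry; swapping the limbs negates them. The opposite
foot's stance necessarily spans a stride boundary, so each stride is paired
with its successor and a record is emitted only when both are complete.
`average_records()` averages runs of `k = 5` consecutive strides
(non-overlapping by default — the source study does not state which windowing
it used, so both are offered), reflecting the usual ~5 m minimal assessment
distance.

## The synthetic gait generator

The generator exists so that every stage is testable against exact ground
truth. It is deliberately *not* a biomechanical simulation: the waveforms
are piecewise-linear templates that guarantee exactly the four morphological
features above — amplitudes are free parameters with documented defaults —
and every programmed event time is snapped to the sample grid, so noise-free
detection can be checked to the sample.

Defaults encode canonical healthy gait as the study conditions: a 1070 ms
median cycle (the reported median right-stride time), 30 ms stride-to-stride
SD, stance at 60% of the cycle, foot-flat at 8%, OTO at 10%, OHS at 50%,
100 Hz sampling. `noise_sd` defaults to 0: the default trial is the
noise-free template, and sensor noise (expressed as a fraction of each
channel's peak amplitude) is opt-in for Monte-Carlo work.

Numerical choices worth knowing:

* **Grid snapping** rounds half-up, so programmed times are deterministic on
  the 10 ms grid.
* **Smoothing**: after noise injection the channels pass a centred moving
  average (window 3). Noise-free templates are already piecewise smooth and
  skip the filter — a centred average would bias the programmed gradient
  corners by one sample and make the template inconsistent with its own
  ground truth.
* **Stride-time asymmetry** cannot be sustained in strictly periodic gait
  (both feet complete a cycle in the same period), so `asym_tr = s` is
  implemented as a per-stride linear drift of the OHS phase,
  $\delta = s \cdot gc / (1 - s/2)$ per stride, which makes every left
  stride time exceed the right by exactly $\delta$: the programmed index
  holds stride by stride. The phase path is auto-centred in its admissible
  band (heel rise after OTO, slope break clear of TO) and the spec errors
  when the drift cannot fit — long strongly-asymmetric trials are physically
  inconsistent with this construction.
* **Stance-time asymmetry** `asym_ta` is a constant OHS-phase offset solved
  from the symmetry-index definition on grid-snapped quantities.

What passing tests on this generator do **not** show: robustness to soft
tissue artefacts, slope or turning gait, pathological waveforms (drop foot,
hemiplegia) where the OHS/OTO signatures are weakened, or sensor drift.
Those require real recordings; the statistics pipeline below is the tool for
that comparison.

## The method-comparison pipeline

`run_agreement_pipeline()` reproduces the full gated flow used to compare a
wearable system against a reference. With $D$ = test − reference and $A$
their pairwise average:

1. **Normality gates**: one-sample Kolmogorov–Smirnov against a fitted
   normal (the test named by the flow; parameters estimated from the sample,
   which makes the raw p conservative — a Lilliefors flag is available).
2. **Accuracy/precision**: mean/SD of $D$ when normal, else median and
   quartile deviation $(Q_3 - Q_1)/2$.
3. **Fixed bias**: one-sample t-test, or the Wilcoxon signed-rank with the
   zero-inclusive Pratt treatment — at 10 ms resolution zero differences are
   common and discarding them (the classic treatment) biases the test. The
   variance is the exact conditional $\sum r_i^2$ over non-zero differences.
4. **Proportional bias**: Pearson (both normal) or Spearman correlation of
   $D$ on $A$.
5. **Limits of agreement**: classic mean ± 1.96 SD or the 2.5th/97.5th
   percentiles; when a proportional bias is significant the limits become
   lines. The parametric correction regresses $D$ on $A$ and offsets the
   fitted line by $\pm 1.96\sqrt{\pi/2}\,\overline{|R|}$ — the
   mean-absolute-residual scaling whose half-width equals $1.96\sigma$ for
   normal residuals. The nonparametric correction fits linear quantile
   regressions at $\tau = 0.025, 0.5, 0.975$ by pinball-loss minimisation.
   The published flow prints the upper-limit formula twice; the lower limit
   is of course the $\tau = 0.025$ line, and that is what is implemented.
6. **Agreement coefficient**: ICC(2,1) (single measures) or ICC(2,k)
   (k-stride averages), two-way random effects, absolute agreement, when
   both series are normal; otherwise Kendall's W with the tie correction.
   Interpretation bands: ICC excellent > 0.750, good 0.600–0.749, fair
   0.400–0.599, poor < 0.400; W strong > 0.600, moderate 0.300–0.599, weak
   0.100–0.299, almost none < 0.100. Significance is 0.05 throughout.

The quantile regressions deserve a note: no linear-programming solver is
assumed. The pinball objective profiled over the slope is convex (partial
minimisation of a jointly convex function), so the slope is found by
golden-section search and the intercept is the type-1 empirical quantile of
the residuals, which minimises the pinball loss exactly. The test suite
checks the fit against an exhaustive coefficient-grid oracle and verifies
94–96% coverage of the outer lines on large samples.

## Worked example

```{r example}
spec <- gait_spec(n_strides = 12, seed = 42)
trial <- generate_trial(spec)
events <- detect_all_events(trial$signal)
head(subset(events, stride_index > 1),
     3)[, c("stride_index", "T_HS", "T_footflat", "T_OTO", "T_OHS", "T_TO")]

params <- compute_gpbll_table(events)
round(colMeans(params[-1]), 3)

average_records(params, k = 5)[, c("stride_first", "DSTt", "SIS_tr", "SIS_ta")]

# compare detected OHS timing against the simulator's ground truth
ok <- complete.cases(events$T_OHS, trial$truth$T_OHS)
pairs <- paired_measurements(trial$truth$T_OHS[ok] - trial$truth$T_HS[ok],
                             events$T_OHS[ok] - events$T_HS[ok],
                             label = "relative OHS time (ms)")
run_agreement_pipeline(pairs)
```

## Problem sizes and runtime choices

The validation suite uses desk-scale problem sizes chosen to make the
checked properties sharp rather than to imitate a field study: 1,000 random
segments for the TTA oracle; 20-stride noise-free trials at cadences of
80–140 steps/min for event recovery; a 200-stride trial at 5% relative noise
for the Monte-Carlo error medians; $10^5$ draws for the limits-of-agreement
convergence and coverage checks; and 342-pair samples (the effective-stride
count of the motivating validation study) for the discrete, tie-heavy
agreement statistics.

## Known limitations

* The published headline accuracy/precision figures come from 26 instrumented
  participants against an optical reference; they are *tolerance bands* here,
  not reproducible numbers — the package validates the machinery on synthetic
  signals with known truth.
* The effective-stride outlier rule (template correlation ≥ 0.8 on resampled
  `G_x`) is this package's transparent stand-in; the original study removed
  outliers without stating its rule. The predicate is pluggable.
* Detection assumes the four signatures exist; populations with weakened
  plantarflexion/knee-flexion patterns will degrade OHS/OTO detection.
* Repeated-measures limits of agreement and confidence intervals on the
  limits are out of scope.
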