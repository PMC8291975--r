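---
title: "Methods: the 0.02 Hz sigma-power fluctuation and NREM-sleep arousability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 0.02 Hz sigma-power fluctuation and NREM-sleep arousability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infraslow)
```

## The scientific problem

Mouse non-rapid eye movement sleep (NREMS) is not uniform: power in the
sleep-spindle (sigma, 10-15 Hz) band waxes and wanes with a period of
roughly 50 s (~0.02 Hz). The phase of this infraslow fluctuation
partitions NREMS into *continuity* periods (rising sigma, trough to peak;
low arousability) and *fragility* periods (falling sigma, peak to trough;
elevated spontaneous and evoked arousability). `infraslow` implements the
full analysis stack around this fluctuation: extraction of the sigma
trace, its infraslow spectrum, Hilbert phase, trough-peak-trough cycle
detection, phase coupling of microarousals (MAs) with circular
statistics, phase-binned band dynamics and an activation index (AI) for
local cortico-autonomic arousals, heart-rate extraction from the neck
EMG, an online vigilance-state machine plus continuity/fragility
classifier for closed-loop experiments, and an automatic scorer for
vibration trials. A spared-nerve-injury (SNI) condition models the
chronic-pain phenotype: tonically elevated 16-40 Hz power, a blunted
fragility-period delta surge, more frequent AI-peak local arousals with
heart-rate transients, and higher wake-up rates to vibration.

No public recordings accompany this line of work, so the package ships a
ground-truthed polysomnography generator; every stage is tested against
what the generator planted.

## The sigma-trace pipeline

The core estimator follows a fixed chain:

1. **Morlet wavelet power**, four cycles, at center frequencies 10 to
   15 Hz in 0.5 Hz steps, averaged across centers. The input is decimated
   to 100 Hz first (transparent for bands up to 40 Hz).
2. **Down-sampling to 10 Hz** by block averaging.
3. **FIR smoothing**: a zero-phase (forward-backward) windowed-sinc
   low-pass, order 100, cutoff 0.0125 Hz at the 10 Hz rate. At this order
   the filter is deliberately shallow - essentially a ~10 s Hamming
   average - so the 0.02 Hz component passes at ~94% amplitude while
   fast power fluctuations are removed. The zero-phase application
   matters: any group delay here would rotate every event-phase estimate.
4. **Normalization** by the mean over NREMS and MA samples, so the trace
   averages 1 on its validity mask.
5. **Hilbert phase** of the mean-subtracted smoothed trace, computed once
   over the whole recording (per-bout transforms would put an edge
   transient at every bout border), then mapped so a cosine peak is 0°
   and the trough 180°, increasing through the cycle. Phase is
   interpreted only on the NREMS/MA mask.

The per-bout infraslow spectrum mean-subtracts each NREMS bout (bouts of
at least 100 s; MA epochs do not interrupt a bout), interpolates the
0-0.5 Hz bins linearly onto a common 201-point grid, and averages. The
peak is searched above 0.005 Hz to avoid detrending leakage into the two
lowest grid bins.

Individual cycles are detected find-peaks style on the smoothed trace:
peaks must exceed the mask mean, troughs must fall below it, same-kind
extrema must be more than 20 s apart (greedy pruning by height, plateau
extrema at the plateau midpoint), and a cycle - peak, trough, peak - is
kept only when it lies entirely inside NREMS (MA epochs permitted).
Bouts shorter than 40 s cannot satisfy two separations and contribute
nothing.

## Event-phase coupling and outcomes

MA onsets are sampled on the phase trace at onset and at 4, 8 and 12 s
before onset (4 s is 28.8° at 0.02 Hz). Circular statistics use the
resultant-vector mean with the standard chi-square confidence interval
and the Rayleigh test with the large-sample series p value.

Each detected cycle's fragility span (phase 90-270°) is classified `MA`
when an MA onset falls inside it with extracted phase in 90-270°,
`REMS-transition` when the state turns to REMS there, and
`NREMS-continuing` otherwise. On the synthetic conditions REMS
transitions are rare by construction, because a cycle is only detected
when its trailing peak still lies in NREMS; the class exists mainly for
user-supplied data.

## Activation index and local arousals

The AI is the natural log of (beta 16-25 Hz + low gamma 26-40 Hz) power
over delta (1-4 Hz) power on the common 10 Hz base; it is invariant to a
global gain. Peak search runs at phase 90-270° with the cycle's mean AI
as threshold; a peak counts when its maximum lies inside the span. Before
the search the AI is smoothed with a 5 s moving average: an intermittent
activation is a seconds-long event, and without smoothing,
single-sample estimator noise would cross any mean-level threshold in
almost every span. The 5 s default was chosen against the generator's
injected 3 s events (always detected) and event-free cycles.

Heart rate comes from the EMG: high-pass above 25 Hz, squaring, then
peak detection on the squared trace *divided by its rolling 0.5 s
median*, thresholded at median + 8 MAD with a 50 ms refractory
constraint. The local-median normalization is what makes one global
threshold work across atonic REMS, quiet NREMS and movement bursts: an
absolute median + MAD threshold computed over a whole recording sits far
below wake-noise excursions and cannot separate R peaks from phasic
EMG, while the normalized trace is scale-free everywhere.

## The online path

Every second, the delta/theta power ratio and sigma power are computed
from the mean-centered last 4 s of EEG, and EMG power as the median of
the squared EMG over the last second (the median ignores the
electrocardiographic spikes that ride on a mouse neck EMG). The
vigilance-state machine applies seven threshold rules, in the documented
order, out of Wake (to NREMS, to REMS), NREMS (to Wake, to REMS) and
REMS (to Wake, to NREMS). One rule is unreachable as stated: a wake
history with five silent EMG seconds and five high-ratio seconds
satisfies the Wake-to-NREMS rule, which is checked first, so the
Wake-to-REMS rule can never fire. It is implemented verbatim anyway;
direct Wake-to-REMS transitions do not occur in mice.

Thresholds were set heuristically in the original design; here they are
calibrated per recording from a labelled stretch (default the first
10 min, extended automatically when a state is missing): the high EMG
threshold is the 75th percentile of wake EMG power, the low EMG
threshold the 10th percentile of NREMS EMG power, and the ratio
thresholds the geometric midpoints between the wake/NREMS and
REMS/NREMS median ratios.

The online sigma estimate normalizes each second's sigma power by a
running NREMS mean and fits a degree-9 polynomial to the last 200 s.
Fitting uses a precomputed orthonormal basis, so the fit is a single
matrix product per second. Note the fit is a coarse approximation: on a
pure four-cycle sinusoid the degree-9 projection correlates with the
input at only r = 0.69. It nevertheless carries enough shape for the
classifier, whose label depends mostly on whether the recent fitted
trend rises or falls.

Training chunks pair each second's 200-point fitted curve (plus the
current ratio and EMG power, 202 features in all) with the offline label
of that second: continuity (trough to peak), fragility (peak to trough),
or none outside detected cycles. The classifier is a single-hidden-layer
network with 10 units and a 3-class softmax output (via `nnet`),
trained on a 70/15/15 split under a fixed seed with feature
standardization. Shuffle validation repositions the detected fragility
(and continuity) seconds uniformly within the recording's NREMS seconds,
preserving their number, and reports the percentile of the observed
MA-capture proportion in that null. Because roughly a third of MA onsets
fall just after the sigma trough - and are therefore continuity by the
trough-to-peak definition even though their phase is inside 90-270° -
single-animal validation with a few dozen MAs is underpowered; the
packaged checks pool eight synthetic animals.

## Closed-loop stimulation and trial scoring

The simulated controller mirrors the hardware protocol: when the target
period is detected and still present 4 s later, a 3 s vibration is
delivered with probability 0.25, followed by a configurable re-arming
pause. The generator's response model wakes the animal with probability
`p_wakeup_fragility` or `p_wakeup_continuity` according to the *true*
phase at stimulus time, imprinting 5 s of desynchronized EEG and an EMG
burst on wake-ups.

The automatic scorer analyses 5 s before and after each stimulus:
trials are rejected when the pre-stimulus theta/delta ratio exceeds 1
(REMS-like) or the squared EMG is larger before than after; wake-ups
require a marked drop of the low/high frequency ratio (1-4 Hz over
100-500 Hz) together with EMG activation, with an escape clause for a
very strong change in one channel while the other does not oppose it.
"Marked" is quantified by thresholds whose defaults were fixed against
constructed wake-up and sleep-through exemplars;
`calibrate_autoscore_thresholds()` re-derives them at the equal-error
point from any labelled trial set. Note that the EMG rejection rule
discards about half of true sleep-throughs (an unchanged EMG is larger
before the stimulus half the time), which inflates measured wake-up
probabilities equally across groups - a property inherited from the
scoring rules themselves.

## What the generator emulates - and what it does not

The generator is a noise-shaping emulator, not a biophysical model: each
EEG band is band-limited Gaussian noise with a state- and
phase-dependent amplitude. Its defaults are the study conditions every
packaged check runs under:

* infraslow period 50 s; sigma *power* in NREMS modulated as
  `1 + 0.9 cos(phase)` (0° at the envelope peak, so the trough is 180°);
* MA onset phases von Mises with mean 151.6° and concentration
  kappa = 2.015, the value solved so that 89% of the mass lies between
  90° and 270°;
* the target proportion of fragility periods containing an in-window MA
  is 0.336; since 11% of drawn onsets fall outside 90-270°, the
  per-cycle placement probability is 0.336/0.89 = 0.378, so that the
  two printed statistics hold jointly rather than multiplying into each
  other;
* MA durations uniform on 4-16 s (only the 16 s bound is an external
  constraint; uniform spans the legal range and quantizes to epochs);
* heart rates 10/11/12.5 beats per s in NREMS/REMS/wake - configuration
  choices, since no reference values are printed for these recordings;
* sessions default to one hour at 1 kHz per synthetic animal, a desk
  scale at which thirty-animal cohorts remain cheap; 12 h sessions are a
  single override.

Several design points exist specifically so that measurements can
recover what was planted:

* **Sigma through MAs.** The sigma band keeps following the infraslow
  envelope during MA epochs. If the MA state suppressed sigma, every MA
  would manufacture its own local trough and the extracted onset phases
  would collapse into the fragility window (we measured 99.4% instead of
  the calibrated 89%). Desynchronization during MAs is expressed in the
  delta drop, the high-frequency content and the EMG burst instead.
* **Steep band edges.** Shaped bands use brick-wall FFT masks (theta as
  5-9 Hz, where mouse theta actually peaks) because shallow IIR skirts
  leak event-locked theta/beta power into the 10-15 Hz wavelet estimate
  and bias phase at exactly the events being phase-referenced.
* **Delta anti-phase to sigma.** Delta power dips during continuity and
  surges toward the fragility trough, switching plateau-like at 60°/300°
  - the upstroke begins before the 90° span edge. This matches the
  reported sensory-cortex behavior and is also what makes the
  cycle-mean AI threshold meaningful: within 90-270° the baseline AI
  sits on a plateau below the cycle mean instead of sweeping across it
  at the span edges. Under SNI the surge (not the dip) is multiplied by
  0.2.
* **Envelope-stabilized delta.** The delta component's analytic envelope
  is smoothed and divided out: ongoing slow-wave activity is far more
  amplitude-stable than chi-square distributed Gaussian band noise, and
  without stabilization the AI estimator noise swamps the
  continuity/fragility swing.
* **ECG and movement.** R peaks are single-sample impulses (amplitude
  120 against state-dependent tonic EMG noise); movement bursts occur in
  wakefulness at a rate steeply modulated by a slow activity drive, plus
  a guaranteed burst at every wake-bout onset and at MA onsets. The
  steep modulation leaves genuinely quiet stretches, which is what the
  10th-25th percentile quiet-wakefulness band needs to contain runs of
  three or more epochs.

What passing tests therefore do *not* show: robustness to real artifacts
(chewing, electrode noise, drift), to non-stationary infraslow periods,
to state-scoring disagreement between raters, or to ECG morphologies
beyond a sharp R peak. The generator's spectra are stationary within a
state; real spectra are not.

## Numerical choices

* Quantiles use linear interpolation (R type 7) throughout.
* Extremum ties break toward the earliest sample; plateaus count once at
  their midpoint.
* The periodogram is a single-taper FFT per mean-centered 4 s epoch
  (0.25 Hz bins); transition-adjacent epochs are those whose predecessor
  or successor carries a different label, with recording boundaries
  counting as adjacent.
* The Hilbert input is the smoothed (not raw down-sampled) sigma trace;
  the 201-point infraslow grid uses linear interpolation - both points
  were open in the original description and are fixed here as stated.
* EDF export quantizes each channel to 16 bits over its own physical
  range; round trips reproduce labels exactly and samples to within one
  quantization step.
* `sim_config()` validates all probabilities, requires the infraslow
  period to exceed 40 s (two >20 s separations must fit in a cycle), and
  requires 1 kHz sampling so the 100-500 Hz EMG band exists.

## Problem sizes in the packaged checks

The test suite and the acceptance script regenerate everything they
measure: a 30-animal cohort of 1 h sessions for the phase-locking and
fragility-outcome recoveries, eight of those animals for the online
shuffle validation, and four session pairs per condition for the
closed-loop wake-up contrast. These sizes put the recovered quantities'
sampling error comfortably inside the documented tolerances while
keeping a full run in the minutes range on one core.

## Known limitations

* The fragility/continuity dichotomy is sharp at 90°/270° by convention;
  biology is not. Events near the span edges are genuinely ambiguous,
  and measured in-window fractions sit one to two points below the
  generative 89% because extraction noise smears mass across the
  boundaries - visible in the packaged recovery numbers.
* The Wake-to-REMS online rule is dead code as printed (see above).
* The wake-up/sleep-through scorer inherits the rejection asymmetry of
  its rules; absolute wake-up probabilities are inflated, only
  contrasts between groups are interpretable.
* Circular statistics cover the mean, its confidence interval and the
  Rayleigh test only; no V-test or Watson-Williams machinery.
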