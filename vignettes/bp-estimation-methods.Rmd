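---
title: "Beat-to-beat cuffless blood pressure estimation: models and methods"
author: "bpbeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat-to-beat cuffless blood pressure estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bpbeat)
```

## The problem

Arterial blood pressure (BP) varies beat to beat between a systolic
maximum (SBP) and a diastolic minimum (DBP). Continuous monitoring
normally needs an intra-arterial line or a volume-clamp cuff; both are
impractical outside the clinic. Cuffless estimation exploits the
mechanics of the arterial wall: the pressure wave travels at

$$PWV = \sqrt{\frac{E_0\, e^{\gamma P} h}{\rho\, d}}, \qquad
  PTT = \frac{L}{PWV},$$

where the elastic modulus stiffens exponentially with the pressure $P$
(coefficient $\gamma$, zero-pressure modulus $E_0$), $h$ and $d$ are the
wall thickness and vessel radius, $\rho$ the blood density, and $L$ the
path length from the heart to a peripheral site. Higher pressure means a
stiffer wall, a faster wave, and a *shorter* pulse transit time (PTT) --
PTT is negatively correlated with BP and is the core cuffless feature.

`bpbeat` implements a complete beat-to-beat estimation pipeline around
this relation:

1. **Simulation** (`generate_cohort()`): physics-driven synthetic
   ECG/BCG/PPG cohorts with per-beat ground truth, standing in for
   private clinical recordings.
2. **Preprocessing** (`detect_beat_events()`): Butterworth filtering and
   characteristic-point detection (ECG R peak, BCG I/J waves, dPPG
   peak).
3. **Features** (`extract_beat_features()`, `assemble_sequences()`):
   seven per-cycle features -- RRI, PTT, RJI, IPI and three peak
   amplitudes -- assembled into 10-cycle labelled sequences.
4. **Regression** (`build_model()`, `train_model()` and the protocol
   wrappers): a bidirectional LSTM mapping a sequence to (SBP, DBP).
5. **Evaluation** (`eval_report()`): MAE/RMSE/CC/R-squared, Bland-Altman
   limits, BHS grading, AAMI criteria, hypertension-class accuracy.
6. **Classical baselines** (`chen_sbp()`, `poon_bp()`, `ding_bp()`,
   `mlr_fit()`): calibration-based PTT models and multiple linear
   regression comparators.

## The synthetic cohort: what it emulates and what it does not

No public dataset provides synchronized chair-BCG, finger-PPG, lead-II
ECG and beatwise volume-clamp BP. The simulator therefore generates the
*study conditions* directly:

* **Cohort structure.** 18 adults by default (gender mix near 8M/10F,
  ages 20-50), 30-minute sessions at 1000 Hz, and a second visit for 15
  subjects with inter-day drift. Baseline pressures follow a weak linear
  demographic rule plus subject-level noise, centring the cohort near
  111.2/67.7 mmHg.
* **BP dynamics.** Per-beat SBP/DBP are the subject baseline plus a
  mean-reverting AR(1) component (stationary SD 3 mmHg, per-beat
  autocorrelation 0.9, so consecutive beats differ by ~1.3 mmHg) and two
  sinusoids (vasomotor 0.04 Hz, amplitude 3 mmHg; respiratory 0.25 Hz,
  amplitude 1.2 mmHg). Mean reversion reflects homeostasis and gives two
  sessions of one subject a common stationary distribution, which the
  zero-drift reproducibility tests rely on; the slow autocorrelation is
  what makes multi-cycle sequences informative.
* **Timing physics.** The dPPG peak is placed at
  $R + PTT(\mathrm{SBP}) + PEP + \nu_p$, with $PTT$ from the wave-speed
  model above, $PEP$ a pre-ejection-period delay (30 ms constant, a
  6 ms respiratory oscillation at 0.25 Hz, and 3 ms white jitter) and
  $\nu_p \sim N(0, 2\,\mathrm{ms})$ peripheral placement noise. The BCG
  J peak carries the full PEP plus a quarter of the vascular transit
  variation plus its own $N(0, 3\,\mathrm{ms})$ placement noise. Two
  consequences, both deliberate: the R-anchored PTT is an imperfect BP
  surrogate (within-record correlations around $-0.8$ rather than
  $-1$), and the I-to-dPPG interval (IPI) cancels the shared PEP but
  keeps independent fiducial noise -- so no single-beat interval is a
  noise-free BP readout, multi-signal fusion genuinely helps (the
  motivation for the BCG channel), and averaging across a 10-cycle
  window pays off (the motivation for sequence input).
* **Waveform morphology.** Mexican-hat QRS (sigma 10 ms) with a small T
  wave; a 12 Hz Gabor atom for the BCG I-J complex (I is the trough half
  a period before J); a PPG built by integrating a Gaussian slope pulse
  so the steepest upstroke falls exactly at the intended dPPG time, on a
  constant tissue-absorption baseline. Morphology is *not* fitted to any
  real sensor; only event timing and amplitudes matter downstream, and
  the templates are chosen to be band-limited within the published
  filter bands so zero-phase filtering preserves event times.
* **Amplitudes.** ECG gain is BP-independent; BCG/PPG pulse amplitudes
  carry a session-specific random coupling to the BP level
  ($\kappa \sim N(0, 0.25)$ per session), emulating vasomotor tone:
  informative within a day, inconsistent across days. This is the
  mechanism by which a subject-day-specific model can overfit "one-day
  conditions".
* **Noise.** White noise (SD 0.05 of unit amplitude), 0.3 Hz baseline
  wander (amplitude 0.4), 50 Hz mains (amplitude 0.1) and a 5% beat
  dropout rate that suppresses a BCG or PPG pulse to exercise
  missing-peak handling.
* **Inter-day drift.** Visit two shifts the SBP baseline
  ($SD = 7$ mmHg) and the DBP baseline (0.4 times the SBP shift plus an
  independent $N(0,4)$ component), rescales channel gains by up to
  10%, adds a small transit-time calibration offset ($SD = 3$ ms) and
  re-draws the amplitude-BP coupling. The composition is deliberate:
  day-to-day variation is dominated by label shifts and session-specific
  amplitude behaviour, not timing-calibration error, so a general model
  carries over between days while a one-day model degrades -- the
  reproducibility phenomenon the multi-day protocol measures. With this
  composition the pooled model's multi-day error stays near its one-day
  error, as observed for general models in this literature.

What passing tests on this simulator show: the detectors, feature
algebra, training protocols, leakage discipline and graders behave
correctly, and the relative orderings between protocols emerge for the
stated physiological reasons. What they do not show: performance on real
sensors, whose noise is non-stationary and whose morphology varies far
more than these templates.

## Preprocessing decisions

* Second-order Butterworth bands: ECG 0.5-35 Hz, BCG 4-15 Hz, PPG
  0.5-8 Hz, applied forward-backward (zero phase) so event timing is
  unbiased; the signal is padded by odd reflection to confine edge
  transients.
* R peaks: Pan-Tompkins stages (5-15 Hz band, five-point derivative,
  squaring, 150 ms integration, adaptive dual thresholds with 200 ms
  refractory and search-back), refined to the local ECG maximum.
* J peak: highest sample in the half-open window $(R+110, R+250]$ ms
  that is also a local maximum; ties break to the earliest sample.
* I notch: nearest local minimum within 100 ms before J (the detector is
  unspecified in the source literature; this rule is ours).
* dPPG peak: central-difference derivative (one-sided at the ends,
  scaled to units/s), maximum in $(R+100, R+600]$ ms, earliest tie wins.
  The window is our choice, sized to cover physiologic PTT plus margin.
* Manual artifact editing is replaced by a reproducible plausibility
  filter: RRI in [300, 2000] ms, PTT in [100, 600] ms, each amplitude
  within 1/5x to 5x its 31-beat rolling median (catching both spikes and
  missing pulses), plus an optional exclusion-list file. The filter only
  ever invalidates beats.

## Feature standardization and leakage discipline

Features are z-scored before entering the network. The scope matters:

* **Personal protocol**: statistics come from the rows underlying the
  training windows only; validation and test windows reuse them.
* **Pooled (LOSO) protocol**: each training subject's rows are z-scored
  by that subject's own statistics. Pooling raw features instead would
  leave between-subject PTT offsets -- which come from vessel geometry,
  not BP -- inside the features and dilute the learned PTT-to-BP slope;
  we found this dilution large enough to stop the general model from
  tracking day-to-day BP shifts. Per-subject calibration removes it,
  matches the preprocessing-stage placement of standardization in this
  literature, and leaves the subject-level baseline to the demographic
  inputs.
* **Held-out subject**: its statistics come from a label-free 60-second
  calibration window at the start of the recording; sequences ending
  inside that window are excluded from evaluation, so no evaluated
  sequence influences its own calibration and BP labels are never used.
  In the multi-day protocols the training visit's calibration is reused
  unchanged on the test visit.

## The regressor and its training protocols

The network reads a $10 \times 7$ sequence through a bidirectional LSTM
(128 units per direction, tanh), concatenates both directions per
timestep (256 wide), flattens across time (2560 wide), optionally
appends five demographic inputs (gender as 0/1, z-scored age, height,
weight, BMI), and maps through a 64-unit ReLU layer to a linear 2-unit
head. Training uses Adam (learning rate $10^{-3}$), joint MSE on
(SBP, DBP), batch 64, at most 100 epochs with early stopping at patience
10, and a random 60/20/20 train/validation/test split; results average
three independently initialized runs. Dropout (10%) acts variationally
on the LSTM input and recurrent connections. The forward pass and
backpropagation through time are implemented in compiled code and
verified against numerical gradients; the output head's bias is
initialized at the training-label mean so the optimizer spends its
budget on the mapping rather than the intercept. SBP and DBP predictions
are unconstrained -- nothing enforces SBP > DBP.

* **Personal**: one subject-visit, split 60/20/20.
* **LOSO**: train on all other subjects (demographics enabled),
  validation is a subject-stratified 20% of the pooled sequences; the
  held-out subject touches nothing.
* **Tuned LOSO**: freeze the recurrent block bit-exactly and retrain
  only the fully connected head on 20% of the held-out subject's
  sequences; evaluation uses a disjoint portion. Because a tuning set of
  tens of sequences yields only one 64-batch per epoch, fine-tuning
  defaults to batch 16 with up to 100 epochs (patience 15, 25% of the
  tuning set as monitor): the head then receives an optimization budget
  comparable, in gradient steps, to tuning on a full-size recording.
* **Multi-day**: train on one visit, test on the other, both directions
  pooled by concatenation (sample-size weighting).

## Evaluation conventions

Sample standard deviations (n-1) everywhere; Bland-Altman limits are
bias $\pm 1.96$ SD; BHS thresholds are inclusive
($\ge 60/85/95$% of absolute errors $\le 5/10/15$ mmHg for grade A,
50/75/90 for B, 40/65/85 for C, else D); the AAMI verdict is
$|ME| \le 5$ and $SD \le 8$ mmHg, with the $n \ge 85$ population rule
reported separately. Hypertension classes use left-closed bins: SBP
<120 / [120,130) / [130,140) / >=140; DBP <80 / [80,90) / >=90 (no
prehypertension band for DBP). Paired protocol comparisons on the
synthetic benchmark use the two-sided Wilcoxon signed-rank test over
per-subject MAEs (a paired t-test is an equally available choice; the
signed-rank makes no normality assumption at n of order 10).

## Problem sizes

The shipped tests and the acceptance script scale the study down so a
full run completes on a single CPU: records of 2-5 minutes instead of
30, cohorts of 3-8 subjects, and training budgets of 30-80 epochs for
the ordering benchmarks (the architecture itself is never shrunk).
Where a comparison is sensitive to sample size it is run at the size
that makes it meaningful: the sequence-length comparison uses a
20-minute recording, because at few-minute lengths the longer-sequence
model's smaller training set dominates the outcome, and protocol pairs
under comparison always receive identical run budgets. The
deterministic-learnability benchmark uses 2000 sequences and three
seeds. These sizes are the package's own benchmark definitions; all
physics, noise and drift defaults above are independent of them.

One caveat the benchmark sizes impose: with five multi-day subjects and
one training run per protocol, the closer protocol comparisons (tuned
general model versus personal model across days) carry substantial
cohort-to-cohort variance -- the shipped benchmark seeds show the
orderings discussed above, but an individual re-simulation at another
seed can reverse the closer ones. Conclusions about such orderings on
real data need the full cohort and run-averaging of a proper study, not
a desk-scale benchmark.

## Known limitations

* Waveform morphology is schematic; detector performance on real
  sensors will be worse than the simulator oracle suggests.
* The amplitude-BP coupling model (one gain per session) is the
  simplest mechanism producing day-specific overfitting; real vasomotor
  dynamics are richer.
* Sequences overlap (stride 1), so random splits within a recording
  share beats between train and test windows -- faithful to the
  protocol being modelled, but optimistic relative to chronological
  splits.
* The hypertension classifier inherits the cohort's mostly normotensive
  BP distribution; upper-class accuracies rest on few beats.
* Determinism holds for a fixed seed within one BLAS configuration;
  bit-identical results across different linear-algebra libraries are
  not guaranteed.
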