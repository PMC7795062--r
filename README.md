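# bpbeat

Beat-to-beat cuffless blood pressure estimation from ECG, BCG and PPG.

`bpbeat` is for physiological-signal researchers who want a complete,
testable pipeline for pulse-transit-time based blood pressure (BP)
estimation: preprocessing and fiducial detection, per-cycle feature
extraction, a bidirectional LSTM sequence regressor with
personal / leave-one-subject-out (LOSO) / fine-tuned-LOSO / multi-day
training protocols, classical calibration baselines, and device-standard
evaluation (BHS grading, AAMI criteria, Bland-Altman limits). Because no
public dataset provides synchronized chair-ballistocardiogram, finger
photoplethysmogram, lead-II ECG and beatwise volume-clamp BP, the package
includes a physics-driven simulator that generates such cohorts with
per-beat ground truth.

## The model

The arterial pressure wave travels at the Moens-Korteweg speed with an
exponentially pressure-dependent elastic modulus (Hughes relation):

```
PWV = sqrt( E0 * exp(gamma * P) * h / (rho * d) ),    PTT = L / PWV
```

so the pulse transit time PTT falls as BP rises. Per cardiac cycle the
pipeline extracts seven features -- RRI (R-R interval), PTT (ECG R peak
to the peak of the PPG first derivative), RJI (R peak to BCG J peak),
IPI (BCG I notch to dPPG peak), and the ECG/BCG/dPPG peak amplitudes --
z-scores them, and feeds sequences of 10 consecutive cycles to a
bidirectional LSTM (128 hidden units per direction, 256 features per
timestep, flattened to 2560) followed by a 64-unit ReLU layer and a
linear 2-unit head predicting (SBP, DBP). Training uses Adam (1e-3),
joint MSE, batch 64, early stopping (patience 10, max 100 epochs), a
60/20/20 split and 3-run averaging. A general model is obtained by LOSO
training with demographic inputs; freezing the recurrent block and
retraining only the head on 20% of a new subject's data ("tuned LOSO")
personalizes it cheaply and transfers across days better than a model
trained on a single day.

## Worked example

```r
library(bpbeat)

# one simulated subject, 3 minutes, default noise
subj <- sim_subject()
traj <- simulate_bp_trajectory(subj, 180, seed = 1)
rec  <- synthesize_record(subj, traj, noise_config(), seed = 2)

ev   <- detect_beat_events(rec)          # R/I/J/dPPG per beat
rows <- record_features(rec)             # 7 features + reference BP
cal  <- calibrate(rows[rows$beat_time <= 60000, ])
est  <- poon_bp(rows$ptt[rows$valid], cal)
print(regression_metrics(est[, "sbp"], rows$ref_sbp[rows$valid])$mae)
print(bhs_grade(abs(est[, "sbp"] - rows$ref_sbp[rows$valid]))$grade)
```

On this record the detector finds all 203 beats; the Poon calibration
model reaches a beatwise SBP mean absolute error of 6.38 mmHg (printed
by `regression_metrics(...)$mae`), and `bhs_grade(...)$grade` places its
error distribution at BHS grade C -- classical one-point calibration
tracks slow BP drift but not beat-to-beat variation. The neural
protocols operate on the same feature rows:

```r
res <- run_personal(rows, train_config(seed = 3), min_sequences = 60)
eval_report(res$pred, res$ref)
#> SBP: MAE 1.28 RMSE 1.92 CC 0.57 R2 0.20 | ME -0.66 STD 1.84 | BHS A | AAMI pass
#> DBP: MAE 0.71 RMSE 1.08 CC 0.55 R2 0.16 | ME -0.38 STD 1.04 | BHS A | AAMI pass
```

Three Bi-LSTM runs are trained on a 60/20/20 split of the subject's
10-cycle sequences; the report shows the averaged test predictions
recovering SBP to 1.3 mmHg and DBP to 0.7 mmHg on this low-noise
synthetic record, passing the AAMI error criteria with BHS grade A.

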