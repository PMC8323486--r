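# vtkin

Kinematic analysis of real-time vocal-tract MRI for speech motor
control research.

Midsagittal rtMRI shows the whole vocal tract — lips, tongue, velum,
pharynx — as a video of bright tissue against dark airway. `vtkin`
turns such recordings into articulator kinematics and group-level
statistics:

* **grid-based air–tissue boundary segmentation**: gridlines orthogonal
  to a user-drawn airway midline at 2-mm intervals; per frame, the
  air-to-tissue intensity transitions on each gridline are localized
  with sub-pixel precision and smoothed into continuous upper/lower
  boundary contours;
* **articulator trajectories**: lip aperture (distance between the
  boundary points on the most anterior gridline), tongue body and velum
  (1-D positions along one automatically selected gridline each,
  referenced to their scanwise extremum);
* **utterance segmentation** by the bilabial release/closure rule: an
  utterance runs from the last zero-aperture frame before the longest
  open run to the first zero-aperture frame after it;
* **movement variability and duration**: movement size is the summed
  per-frame measurement over the utterance (mm frames); variability is
  the coefficient of variation of size across repetitions,
  `CoV = sd(size) / mean(size)`; durations are inclusive frame counts;
  a spatiotemporal-index (STI) comparator is included;
* **group inference**: linear mixed models (`lmerTest`) on the
  long-format measurement table — CoV ~ group × word × articulator and
  duration ~ group × word — with Type III Satterthwaite F tests,
  partial η², Cohen's d, and Nakagawa marginal/conditional R²;
* **a synthetic vocal-tract generator**: a planar phantom with
  programmable lip/tongue/velum kinematics for the five pseudoword
  stimuli ("mab" … "mabteebeebee"), lognormal amplitude and duration
  jitter, group-level variability multipliers, disfluency labels, and
  MRI-like rendering with known ground-truth boundaries — so every
  stage of the pipeline is testable without any recordings.

The methods vignette (`vignettes/vocal-tract-kinematics.Rmd`) documents
the model, the declared segmentation choices, and the generator's
design decisions.

## Worked example

```r
library(vtkin)
set.seed(1)

## 1. segmentation accuracy on a rendered synthetic recording
acq <- acquisition_params()        # 33.3 fps, 2 mm/px, 3.5-s trials
phantom <- build_phantom(acq, shape_seed = 1)
reps <- synthesize_repetitions(gestural_score("mab"),
                               repetition_jitter(0.1, 0.08),
                               n_reps = 2, acq = acq)
stack <- render_frames(phantom, reps, seed = 2)
grid <- construct_grid(define_midline(phantom = phantom))
contours <- smooth_contours(detect_boundaries(stack, grid))
report <- validate_segmentation(contours,
                                true_boundaries(phantom, stack$states, grid))

## 2. lip aperture and the utterance window
aperture <- lip_aperture_trace(contours)
win <- segment_utterance(aperture[1:frames_per_trial(acq)])

## 3. a full synthetic cohort and the group models
cohort <- generate_cohort(cohort_spec(seed = 8))   # 28 + 20 participants
meas <- measure_cohort(cohort)
tab <- assemble_table(meas$cov_table, meas$duration_table, meas$severity)
fit <- fit_variability_model(tab, subset = "length")
effect_sizes(fit)
severity_correlation(tab)
```

Output (abridged):

```
vt_framestack: 232 frames of 64 x 64 px (blur 0.70 px, noise 0.030)
vt_grid: 65 gridlines, 2.0 mm spacing, +/- 20.0 mm
boundary RMSE: 0.12 px (0.23 mm) over 29282 points
utterance frames 18-24, duration 210 ms, size 36.8 mm frames
vt_model_fit 'variability-length': cov ~ group * word * articulator + (1 | participant)
  marginal R2 = 0.266, conditional R2 = 0.551
                   term      F df1 df2        p partial_eta2
                  group  5.795   1  46 2.01e-02      0.11189
                   word  7.666   2 368 5.47e-04      0.04000
            articulator 83.437   2 368 1.31e-30      0.31199
             group:word  1.858   2 368 1.58e-01      0.00999
      group:articulator  9.100   2 368 1.39e-04      0.04713
       word:articulator  5.364   4 368 3.30e-04      0.05509
 group:word:articulator  0.205   4 368 9.35e-01      0.00223
group contrast d = 0.70
severity correlation r = 0.26 (p = 0.18, n = 28)
```

Reading it: the boundary tracker is well inside the sub-pixel accuracy
regime (0.12 px RMSE against the phantom's geometric ground truth); the
one-syllable utterance spans 7 frames ≈ 210 ms; and on a cohort whose
stuttering-like group was generated with a 1.5× variability multiplier,
the group main effect on CoV is detected (F(1, 46) = 5.8, p = .02,
η²ₚ = .11, d = 0.70) while severity — drawn independently of
variability by construction — shows no reliable correlation.

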