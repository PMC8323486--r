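---
title: "Measuring speech-movement variability from vocal-tract MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring speech-movement variability from vocal-tract MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtkin)
```

## The measurement problem

Real-time MRI of the vocal tract records a midsagittal video of speech:
bright tissue, dark airway, typically around 33.3 frames per second at
2 mm resolution. From such recordings one wants per-frame positions of
individual articulators — lip aperture, tongue-body height, velum
position — and from repeated productions of the same item, indices of
how *variable* and how *long* the movements are. Groups that differ in
speech motor control (the motivating application is adults who stutter
versus typically fluent speakers) can then be compared with mixed-effects
models on those indices.

`vtkin` implements that pipeline end to end:

1. **Boundary segmentation**: a user-supplied midline through the open
   vocal tract carries gridlines orthogonal to it at 2-mm intervals;
   on each gridline the air–tissue intensity transitions are localized
   with sub-pixel precision and smoothed into continuous upper/lower
   boundary contours.
2. **Articulator tracking**: lip aperture is the distance between the
   boundary points on the most anterior gridline; tongue body and velum
   are tracked as 1-D positions along one automatically selected
   gridline each, referenced to their scanwise extremum.
3. **Utterance segmentation**: each trial's utterance runs from the
   release of the initial bilabial closure (last zero-aperture frame) to
   the first return to closure at the final stop.
4. **Variability statistics**: movement *size* is the sum of the
   per-frame measurement over the utterance (mm frames), capturing
   amplitude and duration jointly; the per-word coefficient of variation
   (CoV) of size across repetitions is the variability index. Durations
   are inclusive frame counts. A spatiotemporal-index (STI) comparator
   is provided.
5. **Group models**: linear mixed models on the long-format measurement
   table, Type III F tests with Satterthwaite degrees of freedom, and
   standard effect sizes.

Because validating a segmentation pipeline requires knowing the true
boundaries, the package also contains a first-class synthetic generator:
a planar vocal-tract phantom with programmable articulator kinematics,
rendered into MRI-like frames with known ground truth.

## The synthetic vocal tract

### Geometry

The phantom's airway is a tube around an L-shaped midline — a horizontal
oral cavity, a quarter-circle bend, and a vertical pharynx down to the
larynx — with resting half-widths of about 5 mm on either side.
Coordinates are mm with y increasing downward (image rows); pixel
`(r, c)` has its center at `((c - 0.5) * px, (r - 0.5) * px)`. Three
articulator controls deform the tube:

* **lip aperture** sets the tube width at the anterior end (0 = closed),
  blending into the resting width over an 8-mm taper;
* **tongue-body height** subtracts a Gaussian bump (9-mm width) from the
  lower half-width in the oral cavity;
* **velum opening** subtracts a Gaussian bump (5-mm width) from the
  upper half-width just posterior to the hard palate — a lowered velum
  descends into the tract.

The tube is *open-ended at the lips*: anterior of the lip plane the
mouth opening continues toward the exterior with the aperture's width.
Without this, the lip gridline would sample the blurred end-face of the
tube and read closed even for open vowels; with it, the most anterior
gridline sees a clean air slab whose width is exactly the aperture.
Past the larynx the tube closes into tissue. A `shape_seed` perturbs all
geometric constants by a few millimetres so different synthetic
participants have different anatomies. Tongue and velum excursions are
clipped so at least 1 mm of airway always remains mid-tract: only the
lips can close the tract, which is what the utterance-segmentation rule
assumes.

### Rendering

Frames are rendered analytically rather than by rasterize-then-convolve:
every pixel center is projected once onto the midline, giving its arc
position $s$ and signed normal offset $d$; with local half-widths
$u(s), l(s)$ the blurred air-slab profile is

$$f(d) = \Phi\!\left(\frac{u - d}{\sigma}\right) -
         \Phi\!\left(\frac{-l - d}{\sigma}\right),$$

and intensity is `tissue - (tissue - air) * f` plus i.i.d. Gaussian
noise. This models the point-spread as acting along the tract normal, so
the intensity mid-crossing sits *exactly* on the true boundary — a
property the segmentation tests rely on. Curvature and tube-end effects
on the blur are neglected. Defaults: tissue 0.9, air 0.1, blur
$\sigma = 0.7$ px, noise SD 0.03, 64 × 64 px at 2 mm/px. These values
place segmentation accuracy in the sub-pixel regime reported for
published air–tissue boundary toolboxes while keeping the task
non-trivial (the air–tissue edge spans ~3 pixels).

### Gestural scores

Each of the five pseudoword stimuli ("mab", "mabshibe", "mabfieshabe",
"mabshaytiedoib", "mabteebeebee") is a piecewise-linear keyframe score
for the three articulators over a nominal duration (0.45–1.35 s,
increasing with syllable count; the complex four-syllable word is longer
than the simple one). Three modeling conventions matter:

* Lip aperture is exactly zero throughout the word-initial /m/ closure
  and the word-final stop closure, and positive everywhere between.
  **Word-medial bilabials are partial constrictions** (dips to ~3 mm):
  at 33.3 fps a brief medial closure is typically not sampled at zero,
  and the utterance-segmentation rule (one longest open run per trial)
  requires a single opening. The dips stay above the zero-aperture
  tolerance for any plausible amplitude draw.
* "mabteebeebee" ends at its final /b/ closure; the trailing vowel after
  that closure is omitted, because measurement ends at the final
  bilabial closure anyway and a reopening would break the
  "run must end in closure" invariant.
* The velum lowers only for the initial nasal /m/; the tongue rises for
  high vowels, maximally during the first /i/ of "mabteebeebee" — which
  is what makes that word the canonical reference for tongue-gridline
  selection.

The exact segment shapes are library constants; only their presence and
ordering is phonotactically motivated.

### Repetition jitter and cohorts

Repetition-to-repetition variability is programmed through two
lognormal multipliers with unit mean: an amplitude multiplier (CV
`amplitude_cv`) scaling all three channels, and a time-scale multiplier
(CV `duration_cv`) stretching the word. Lognormals are positive by
construction and CV-parameterized; the reported quantity — the CV of
movement *size* — is approximately
$\sqrt{\text{amplitude\_cv}^2 + \text{duration\_cv}^2}$
for small CVs, since size scales as amplitude × duration. Closure frames
stay exactly zero under every draw. Each repetition is placed in the
3.5-s trial at a jittered onset (0.30–0.45 s) so frame-sampling phase
varies across repetitions as it does in real recordings.

`cohort_spec()` fixes the study conditions: 28 stuttering-like vs 20
control-like participants; baseline amplitude CV 0.10 and duration CV
0.08 (size CV ≈ 0.13, the order of magnitude seen in repeated
pseudoword kinematics); a 1.5× variability multiplier for the
stuttering-like group; an extra utterance lengthening of 5% per unit of
word-complexity index in that group (the group × complexity duration
interaction); per-trial disfluency probabilities 0.10 / 0.04 chosen so
that a word occasionally, but rarely, loses enough repetitions to be
excluded; between-participant lognormal heterogeneity of the jitter CVs
(sdlog 0.25) and speaking rate (sdlog 0.07); and severity scores for
the stuttering-like group drawn *independently* of the programmed
variability (range 16–40, median ≈ 28), so the severity correlation is
null by construction. All randomness flows from one master seed;
identical specs are bit-identical.

The generator emulates repetition-scale kinematic variability, fluency
flags and imaging noise. It does **not** emulate head motion,
reconstruction artifacts, coarticulatory re-organization, or genuinely
disfluent kinematics (disfluency is a label, not a movement pattern).
Passing tests therefore certify the measurement and inference machinery
under controlled conditions, not robustness to those real-data effects.

## Segmentation choices

The published descriptions of grid-based air–tissue tracking leave the
threshold rule, sub-pixel scheme and smoother unspecified. The package
declares its choices:

* **Threshold**: per-frame two-class Otsu on the intensities sampled
  along all gridlines (256-bin histogram). This is contrast-invariant
  and needs no tissue/air calibration.
* **Walk**: starting at the gridline's midline crossing — air whenever
  the tract is locally open — outward in both directions to the first
  crossing of the threshold; gridlines whose midline sample is already
  at tissue intensity are flagged `closed` (that is the lips during a
  bilabial), and gridlines with no transition are `invalid`, never an
  exception.
* **Sub-pixel localization**: linear interpolation of the intensity
  profile through the threshold, on samples every 0.25 px.
* **Smoothing**: a window-3 moving average along the gridline index,
  per frame, after filling closed/invalid gridlines by linear
  interpolation from valid neighbors. No temporal smoothing. Where
  smoothing would invert the boundaries, both are clipped to their
  midpoint and flagged.
* **Frame rate**: "33.3 frames per second" is represented exactly as
  100/3 fps. This matters only for frame arithmetic at the margins: a
  60-ms bilabial closure spans `floor(0.06 * 100/3) = 2` complete
  frames, a 200-ms one 6 frames — the quoted two-to-six-frame precision
  bound for closure timing.

On the default phantom (464 frames, default blur and noise) the overall
boundary RMSE against geometric ground truth is about 0.1–0.2 px,
comfortably inside the sub-pixel regime expected of such toolboxes; the
acceptance suite enforces < 1 px.

## Tracking and utterance rules

* Lip aperture comes from gridline 1; `closed` frames are exactly 0 mm.
* The utterance window is the longest run of frames with aperture above
  `eps_mm = 1` mm (half a pixel — "zero aperture" cannot be exact under
  noise), at least `min_open_frames = 3` frames long (the shortest
  plausible vowel at 33.3 fps; also rejects single-frame noise
  openings). Start is the closure frame immediately before the run, end
  the first closure frame after it; windows touching the trial boundary
  are invalid with a machine-readable reason. Ties between equally long
  runs go to the earliest.
* The tongue gridline is the one closest to the most superior dorsal
  boundary point within reference-word frames ("mabteebeebee"); when a
  scan lacks that word, the fallback — announced via a message — uses
  the global maximum over all frames. The reference point is the lowest
  tongue position on that gridline over the entire scan, so the trace is
  non-negative by construction.
* The velar region is defined computably as the gridlines between the
  hard-palate landmark and 40% of the remaining arc toward the larynx;
  within it, the gridline with the largest upper-boundary range of
  motion is selected (the bend of the velum), referenced to its highest
  position over the scan. A static velum yields a warning and the first
  velar gridline.
* Tongue and velum distances are measured *along the gridline* (1-D
  positions), which is what "tracked up and down a single gridline"
  implies; both articulators reuse the lip-derived utterance window
  unchanged.

## Statistics

* CoV uses the sample (n−1) standard deviation divided by the mean; it
  is scale-invariant and zero iff all sizes are equal. At 10 repetitions
  the estimator carries a small-sample SD bias of roughly −3%, well
  inside the ±10% recovery band the acceptance suite checks at
  programmed CVs of 0.05, 0.1 and 0.2.
* Durations are inclusive (`end − start + 1` frames); ms conversion uses
  the exact frame rate (5 frames at 33.3 fps = 150.15 ms).
* A word is included for a participant only if at least 6 of its 10
  repetitions are both fluent and accurately measured (valid window);
  exclusions are logged with reasons, and excluded cells become missing
  rows, not zeros.
* The STI comparator z-scores each windowed trajectory, resamples to
  1,000 points, and sums the across-repetition SDs at 50 centered
  points (indices 10, 30, …, 990 — the exact subsampling is not fixed
  by the literature restated here). Because the z-transform uses sample
  moments, repetitions of one shape at different lengths retain a small
  finite-sample residual; the tests pin this against a step-by-step
  oracle rather than asserting exact zero. STI and CoV rank synthetic
  participants concordantly (Spearman > 0.7) when trajectories are
  well resolved (250-Hz synthesis); at 33.3 fps the STI is dominated by
  frame-phase noise — which is precisely the argument for using the CoV
  on vocal-tract MRI data.

## Mixed models

The measurement table is long-format: one CoV row per participant ×
word × articulator and one duration row per participant × word, with
exclusions as missing rows (mixed models tolerate a small missing-at-
random fraction; the tests verify fixed effects move < 0.2 standardized
β under a 6% deletion regime).

Four models are pre-specified: variability and duration, each for the
word-length subset (1–3 syllables) and the complexity subset (the two
4-syllable words). Variability models have fixed effects group × word ×
articulator; duration models group × word (duration is shared across
articulators). Factors use sum-to-zero contrasts and omnibus terms are
Type III F tests with Satterthwaite denominator df (`lmerTest`).

The random-effects structure is a simplification ladder, applied
automatically on non-convergence or singularity: by-participant
intercept + word + articulator adjustments → intercept + articulator →
intercept only; every simplification is logged in the fit object. A
maximal structure including participant-by-group terms is not
identifiable with one observation per cell and a between-participant
group factor, so the ladder starts at the richest identifiable
structure. Large simulation sweeps
(`simulate_operating_characteristics()`) use the intercept-only fast
path; the acceptance suite verifies that its null rejection rate for
the group term stays within the binomial band around α = 0.05 over 500
cohorts at the study's sample sizes (28 vs 20).

Effect sizes: partial η² per term from the F table
($F \cdot df_1 / (F \cdot df_1 + df_2)$); Cohen's d on participant-level
means for the two-group contrast; marginal and conditional R² by the
Nakagawa variance decomposition, with each grouping factor's
random-effect variance summarized by the mean diagonal of its covariance
matrix (exact for intercept-only structures). No multiplicity correction
is applied across the four pre-specified models.

The severity correlation is Pearson's r between the stuttering-like
group's severity scores and a variability summary — a priori the lip
CoV of the most complex word ("mabshaytiedoib"), alternatively the mean
over the 1–3-syllable words — and requires at least 3 participants.

## Operating characteristics and problem sizes

`simulate_operating_characteristics()` runs the full
generate → measure → fit loop per simulated cohort and reports rejection
rates. The package's own calibration and power checks use: a 464-frame
rendered session for segmentation accuracy; 1,000 synthetic participants
per programmed CV for recovery; 500 trajectory-only cohorts for null
calibration (the 3-binomial-SE band around α = 0.05 at that size is
0.021–0.079); and 100 cohorts at the 1.5× multiplier, 28 vs 20
participants, for power (observed rejection rate 1.0). Cohorts whose
extreme duration draws overrun the 3.5-s trial window fail loudly and
are dropped from the tally rather than silently truncated.

## Known limitations

* The phantom is 2-D and piecewise-smooth; it cannot probe errors from
  through-plane motion, reconstruction artifacts, or anatomical detail
  (epiglottis, sublingual cavity).
* Gesture shapes are stylized; only ordering, closure structure and
  duration scaling are meaningful. Coarticulation is not modeled.
* Amplitude and duration jitter are uniform per repetition; within-
  utterance shape variability is not programmed, which is why STI
  validation relies on rank concordance rather than absolute recovery.
* Disfluent trials carry no distinctive kinematics; the fluency filter
  is exercised through labels.
* The duration outcome is the per-participant × word mean duration of
  usable repetitions, and "accuracy" of a production is operationalized
  as a valid utterance window.
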