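---
title: "Contactless sleep analysis from depth video: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless sleep analysis from depth video: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(somnocam)
```

# The measurement problem

A depth camera mounted above a bed records the nocturnal scene at 30 frames/s
as per-pixel distances in millimetres. A person sleeping under a blanket
appears as a smooth elevation surface above the bed plane: what the camera
sees is, strictly speaking, mostly the blanket. Three clinically relevant
quantities can nevertheless be read from that surface:

* **respiratory effort** — a quasi-sinusoidal oscillation of the thoracic
  region, a few millimetres peak-to-peak through a blanket. Apneas and
  hypopneas appear as sustained drops in the oscillation amplitude; a depth
  camera measures neither airflow nor oxygen saturation, so apneas and
  hypopneas cannot be told apart, and obstructive events are visible only
  through their *residual* paradoxical effort (a strong amplitude reduction
  rather than total cessation);
* **leg movements** — brief displacement bursts in the lower-body region,
  scorable by the same duration and periodicity rules that polysomnography
  applies to the tibialis EMG (0.5–10 s per movement; a periodic sequence is
  at least 4 movements with onset-to-onset intervals of 5–90 s);
* **gross body movement** — position shifts involving a large fraction of the
  body area, which both carry information (wake) and destroy the local
  validity of the other two signals (exclusion windows).

somnocam implements the full chain from depth frames to a respiratory event
index (KREI, events per hour from lights-off to lights-on; KREI_sleep per
hour of sleep), a periodic limb movement index (KPLMI, KPLMI_sleep), a
motion-feature sleep/wake classifier, and the agreement statistics used to
compare a contactless device against reference annotations (Pearson r,
Bland–Altman, ROC with operating point, event-level matching). Because the
clinical recordings such a device would be validated on are not
distributable, the package carries a synthetic night generator with exact
ground truth; every stage of the pipeline is tested against it.

# The synthetic scene and what it does (not) emulate

`scene_config()` + `generate_event_schedule()` + `render_night()` produce a
night as a lazily rendered chunk source. The body is a smooth blanket-like
elevation map (elliptical cross-section under head/torso/leg width and height
profiles) on a tilted bed plane, textured with sinusoidal "blanket folds"
(default ±18 mm) so that body translations change interior pixels, not just
silhouette edges. Breathing adds a sinusoid (default 8 mm peak-to-peak at 14
breaths/min — the upper end of what is plausible through a blanket, which is
not calibrated against real recordings) over the thoracic span; respiratory
events multiply its amplitude by an event-specific residual fraction; leg
movements displace one limb with a fast rise and fall around a plateau
carrying a small 1.5-Hz tremor (the jerk-then-hold morphology of periodic
limb movements); whole-body movements combine a persisting lateral shift with
a transient vertical wiggle. Sensor imperfections are additive Gaussian noise
(default 1 mm), integer-mm quantisation, and a fraction of invalid (zero)
pixels (default 1%).

The scheduler draws an exact number of respiratory events
(`round(rate × hours)`), places them in sleep with at least 25 s between
events and 15 s clear of whole-body movements, and builds a hypnogram with a
sleep-onset latency whose second half is **calm wake** — wake with no
scheduled movement at all. Calm wake is a first-class plan option because it
is the documented failure mode of any motion-based sleep/wake classifier:
a person lying still while trying to fall asleep generates the same motion
features as sleep.

Residual-amplitude conventions: central apneas render at fraction 0,
obstructive and mixed events at 0.02–0.08 (minor residual effort is enough
for camera detection), and hypopneas may be configured anywhere in the
0.3–0.7 validity range. The default plan draws hypopneas from 0.30–0.40,
i.e. an effort drop of at least 60%: under the 50%-drop detection criterion,
an event whose residual amplitude exceeds half the baseline is by definition
not scorable from effort amplitude alone, and the recovery experiments are
about events the criterion can in principle see. Both ranges are plan
parameters.

What the generator does **not** emulate: infrared physics and reflective
materials, multiple people or pets, bed exits, posture-dependent breathing
waveform changes, non-stationary breathing rates, REM/NREM architecture
(binary sleep/wake only), and real blanket mechanics. Passing recovery tests
on synthetic nights therefore demonstrates the correctness and internal
consistency of the algorithms, not clinical performance.

# Preprocessing

`estimate_bed_plane()` fits `z = a + bx + cy` to pooled point clouds
(`depth_to_point_cloud()`, pinhole back-projection with 0-based pixel
coordinates), refits on the lowest-elevation 30% of points and applies one
reweighting pass — robust to a body occupying roughly a third of the frame
without RANSAC machinery. Rectification uses the exact per-pixel identity
`elevation = d − z·(n·r(u,v))`: the signed orthogonal distance above the
plane, evaluated on the camera grid. We deliberately do not resample to a
bed-aligned grid; at the bed tilts involved (≤ ~12°) the residual
foreshortening is below the 5% RMS budget the tilt-invariance test enforces,
and avoiding a resampling step keeps rectification elementwise (and hence
cheap and exactly invertible).

`fill_and_smooth()` inpaints invalid pixels by iterated neighbour-mean
filling (valid values never change) and applies a 3×3 moving average;
`segment_body()` thresholds elevation at 30 mm, keeps the largest connected
component, takes its principal axis as the head-to-toe line (the
broader-mass end is head-ward, overridable), splits it at fractional axis
spans (torso 0.25–0.55, legs 0.6–1.0), and inscribes the largest disk at the
thorax centroid — the breathing ROI. These thresholds and spans are exposed
in `signal_options()`; the numbers are defaults chosen for a supine adult
filling most of the frame, not fitted constants.

Segmentation is computed on a reference frame (per-pixel median of the first
30-s epoch) and **re-run after every whole-body movement**, since the body
may now be elsewhere: immediately on the remainder of the current epoch when
at least a third of it is movement-free, otherwise at the next epoch
boundary. The affected breathing/leg samples are recomputed under the new
masks. Without this, an apnea shortly after a position shift is scored
against a misaligned ROI and lost.

Two numerically motivated details in the breathing signal path: the ROI mean
is taken over *reference-subtracted* elevations, so that the random dropout
of invalid pixels (whose absolute elevations span tens of millimetres inside
the disk) does not jitter the mean; and the detrended signal is band-limited
with a 0.5-s moving average — breathing lives below ~0.5 Hz while sensor
noise is white, so this cuts the envelope noise floor by ~√5 at <1%
attenuation of the breathing band. Detrending itself subtracts a centered
moving average one high-pass period wide (default cutoff 0.05 Hz).

# Respiratory events and KREI

`compute_envelope()` defines the per-sample amplitude as half the
peak-to-peak range in a centered 5-s window — at least one breathing period,
and robust to the non-sinusoidal shapes a blanket produces. The local
baseline is a 100-s rolling median of the envelope with movement frames
excluded; a respiratory event is a maximal span with envelope below half the
baseline (drop fraction 0.5) lasting 10–120 s. Events separated by fewer
than two recovered breaths merge (the merge gap is twice the spectral-peak
breathing period). The movement-frame flag is dilated by half an envelope
window before use, because envelope spikes bleed that far beyond the
movement itself; for the same reason the first/last half window of the night
is not accepted as event evidence. The drop fraction, durations and windows
are all configuration parameters: the detection rule is "a drop in amplitude
above a certain threshold over a certain period of time", and 0.5/10 s/100 s
are the package defaults in the absence of published values. Detected events
carry their minimum amplitude fraction instead of an apnea/hypopnea label.

KREI divides the event count by hours from lights-off to lights-on;
KREI_sleep divides the count of events whose onset epoch is scored sleep by
hours of sleep, and is flagged unavailable without a hypnogram or with zero
sleep time.

Two properties worth stating explicitly because tests rely on them: event
detection is *scale invariant* (thresholding is baseline-relative), and
lowering the drop fraction can only remove events (monotonicity).

# Leg movements and KPLMI

The leg signal is the mean absolute frame-to-frame elevation change over the
lower-body mask (mm/frame). Candidate movements use dual thresholds, the
camera analog of the EMG rule that a movement starts 8 µV above resting and
ends when activity stays below 2 µV above resting: onset threshold = median
+ 8·MAD of the signal, offset threshold = median + 2·MAD; a candidate is a
maximal span above the offset threshold containing at least one sample above
the onset threshold. Spans closer than 0.5 s merge; only durations of
0.5–10 s are scorable. Candidates overlapping a whole-body movement ±2 s, or
with onset inside a respiratory event ±0.5 s, are removed.

`group_plm()` applies the periodicity rule: runs of ≥4 movements with all
onset-to-onset intervals in [5, 90] s, inclusive on both boundaries. An
interval >90 s ends a run but leaves both movements eligible; an interval
<5 s breaks the run *and* excludes both movements involved (they merge into
neither side) — our reading of the standard exclusion, verified against a
brute-force enumeration oracle over all maximal windows, including intervals
of exactly 4.99/5/90/90.01 s. KPLMI counts movements inside sequences per
hour of the lights window; KPLMI_sleep restricts to sleep-onset epochs.

Whole-body movements themselves are spans where >30% of body pixels change
by >10 mm between consecutive frames for ≥1 s.

# Sleep/wake classification

Each 30-s epoch (900 frames at the native 30 frames/s; generally
`30 × frame_rate` frames) yields 72 features in three blocks: (a) mean,
median, min, max of the per-frame-pair mean absolute change series within
the epoch (899 pairs per 900-frame epoch); (b) the same four statistics over
the per-pixel time-averaged change image; (c) the four statistics per cell
of a 4×4 raster over that image, localising where motion happened. Changes
are computed on rectified elevation maps (a raw-depth mode exists as a
configuration switch, since raw pixel values are an equally defensible
substrate). Invalid pixels are excluded from every mean.

The classifier is an ensemble of depth-4 `rpart` trees boosted for 50 rounds
with per-round random undersampling of the majority class (sleep) to a 1:1
ratio, drawn with probability proportional to the current boosting weights —
the standard recipe for boosting under heavy class imbalance. Tree weights
are the usual `0.5·log((1−e)/e)`; a zero-error round stops training early
and is recorded. Rounds, depth and ratio are defaults from the boosting
literature, configurable. Training and prediction are deterministic given
the seed, and models serialise losslessly.

The evaluation protocol mirrors a device study: train on one set of
synthetic nights, evaluate on held-out nights only. The expected (and
reproduced) behaviour is high sleep sensitivity with poor wake detection
concentrated in calm-wake spans — motion features cannot distinguish
motionless wake from sleep, so the classifier inherits exactly the failure
mode a clinical study reports for the pre-sleep period.

# Agreement statistics

`pearson_with_p()` wraps the product-moment correlation with the two-sided
t-test on n−2 degrees of freedom. `bland_altman()` reports the bias, SD of
differences, 1.96-SD limits of agreement and a two-sided one-sample t-test of
the differences (constant differences collapse the limits and are flagged).
`roc_analysis()` sweeps all midpoints between sorted unique scores,
integrates by trapezoid — which equals the Mann–Whitney statistic with ties
counted half, the identity the tests exploit — and selects the operating
cutoff by Youden's J (a target-sensitivity rule is available, since how a
published cutoff was chosen is usually unstated). `match_events()` matches
detected to reference events greedily by onset proximity within a tolerance
(3 s respiratory, 1 s leg movements), one-to-one.

# Problem sizes and numerical conventions

The test suite and `scripts/acceptance.R` run synthetic nights at 48×36
pixels and 10 frames/s (300-frame epochs); the 900-frame epoch bookkeeping at
30 frames/s has a dedicated unit test. Recovery experiments use 20 nights of
2 h (respiratory; scheduled rates 2–40/h), 4 nights of 1 h (PLM), 20+20
nights of 0.5 h (cohort ROC), and 4+2 nights of 45 min (classifier). These
sizes are the package's own choice of a desk-scale experiment: they keep the
whole suite at tens of minutes on one CPU while leaving every recovery
threshold (±0.5/h KREI, ≥90% sensitivity, ≤10% FDR, ±1 s leg matching, ±15%
KPLMI, AUC >0.9, ≥30-point calm/active wake gap) unchanged.

Other conventions: pixel coordinates are row-major, origin top-left, 0-based
in all camera geometry; depth 0 is the invalid code and is preserved through
the HDF5 container round-trip; timestamps must be strictly increasing and
gaps are flagged, never resampled; multi-part recordings are concatenated on
timestamps before any detection, so events spanning a part boundary are
scored once; epoch grids anchor at lights-off; all per-night randomness
derives from one seed (per-chunk noise seeds are pre-derived, so chunk access
order cannot change rendered frames).

# Known limitations

* The renderer's amplitudes (breathing through a blanket, leg displacement,
  fold texture) are plausible but uncalibrated against real depth recordings;
  absolute sensitivity numbers on synthetic nights say nothing about patient
  data.
* Hypopneas with residual effort above the drop criterion are invisible by
  construction; on real patients this bounds achievable sensitivity against
  a flow-based reference.
* Segmentation assumes a single person, supine-ish, fully in frame; there is
  no bed-exit or multi-person handling.
* The sleep/wake classifier is binary; no REM/NREM staging is attempted, and
  calm wake is systematically misread as sleep — by design of the feature
  set, not a fixable bug.
* Left/right limbs are not separated: the camera signal aggregates the leg
  region (patients sleep under a blanket), so per-limb scoring exists only
  for synthetic ground truth.
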