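---
title: "Oculomotor parameter extraction and two-stage staging: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oculomotor parameter extraction and two-stage staging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vogstage)
library(dplyr)
```

## The problem vogstage addresses

In amyotrophic lateral sclerosis (ALS), eye movement control deteriorates
in a characteristic two-step sequence: executive (frontal/prefrontal)
control of saccades fails first — elevated anti-saccade and
delayed-saccade error rates, fewer self-paced gaze shifts, saccadic
intrusions, anticipatory pursuit saccades — and only later do "genuine"
brainstem oculomotor functions give way: slowed saccades (gaze palsy, a
sign of burst-neuron pathology in the PPRF/riMLF) and low-gain smooth
pursuit corrected by catch-up saccades (a ponto-cerebellar sign). This
ordering parallels the corticofugal staging of pTDP-43 neuropathology.

`vogstage` implements the complete measurement chain needed to study
that hypothesis with 220 Hz video-oculography: a seeded synthetic
recording generator covering the five stimulus paradigms of the
standard battery, the preprocessing chain, saccade detection and
main-sequence fitting, the fourteen per-subject oculomotor endpoints,
control-referenced Tukey-fence classification with the two-stage
assignment, and the cohort-level nonparametric statistics. No patient
recordings ship with the package — the generator is a first-class,
tested module that provides ground truth for every downstream stage.

## The stimulus battery

Five paradigms, reproduced with their printed stimulus arithmetic:

* **Smooth pursuit (SPEM):** horizontal sinusoid, f = 0.375 Hz,
  amplitude ±20°, 12 cycles = 32 s, peak target velocity
  2π·0.375·20 ≈ 47.1 °/s.
* **Visually guided reactive saccades (VGRS), horizontal:** 32 target
  steps (3 × ±5, ±10, ±15, ±40° and 4 × ±20°), targets within ±20°,
  presentation 2.9 s on average (2.1–3.5 s) — 92.8 s acquisition.
* **VGRS, vertical:** 36 steps (4 × ±5, ±10, ±15, ±30° and 2 × ±20°),
  targets within ±15°, 2.6 s mean presentation — 93.6 s.
* **Delayed saccades:** 16 trials (8 per side, steps of 5–40°); an
  acoustic go cue follows target onset by 1.1–2.3 s (mean 1.7 s); a
  saccade before the cue is an error.
* **Anti-saccades:** 16 trials (8 per side, ±5–20° eccentricity); the
  instructed response is a gaze shift to the mirror position; a
  pro-saccade toward the target is an error.
* **Rapid alternating voluntary gaze shifts:** 30 s of self-paced
  shifts between two steady targets 20° apart, horizontal and vertical.

Step *orders* and presentation jitter are pseudo-random per seed. The
jitter is drawn uniformly within the printed range and then recentred so
the sample mean equals the printed mean exactly; total acquisition time
is therefore exact (92.8 s / 93.6 s), and step sequences are sampled so
the cumulative target position never leaves the LED array.

## The synthetic recording generator

A subject is a `phenotype()`: generative counterparts of every extracted
endpoint. The defaults describe a healthy control; `phenotype_stage1()`
and `phenotype_stage2()` overlay the staged deficit patterns.

Saccades use a logistic position profile. Its peak velocity follows the
saturating-exponential main sequence

$$v(A) = v_{max}\,(1 - e^{-|A|/c}),$$

with default $v_{max} = 470$ °/s and $c = 8$° (placing a 20° saccade
near 430 °/s, typical of healthy adults). Two deliberate numerical
choices make this ground truth *recoverable at 220 Hz*:

* the logistic time constant solves
  $A \tanh(\Delta t / 2\tau) / 2\Delta t = v(A)$, so the peak velocity
  of the *sampled* waveform under central differences equals the law
  exactly rather than undershooting it by several percent for short
  saccades;
* the scheduled "onset" of each saccade is its 10 °/s crossing — the
  same boundary the detector reports — so scripted latencies are
  recovered to within a sample.

Pathology is injected mechanistically:

* **Catch-up pursuit:** the smooth component is `spem_gain_true` times
  the target; whenever the position error exceeds 2°, a corrective
  saccade lands the eye back on the target (the "almost periodical"
  catch-up pattern of low-gain pursuit).
* **Anticipatory pursuit:** forward jumps of ~4° at target-velocity
  maxima, decaying back into the pursuit trajectory with a 1.2 s time
  constant (slow enough to stay below detection thresholds).
* **Reactive saccades:** primary saccades at the phenotype's latency
  (truncated normal) and gain; residual hypometria ≥ 1° is mopped up by
  corrective saccades each below the 2° intrusion threshold (smaller
  residuals stay uncorrected — their peak velocity would be
  undetectable anyway).
* **Intrusions:** out-and-back saccade pairs (≥ 2° each) placed in
  fixation windows between steps, budgeted so the accumulated absolute
  amplitude per second equals `intrusion_rate_true`.
* **Delayed/anti errors:** per-trial Bernoulli draws; anti-saccade
  errors are pro-saccades corrected toward the mirror position 150 ms
  later (errors are "rapidly corrected" but still count).
* **Artifacts:** Gaussian channel noise per eye, a slow vergence wobble
  between the eyes, and blinks as 150–300 ms sentinel-valued spans.

What the generator does *not* emulate: pupil dynamics, torsion, head
motion, drift, saccadic curvature, eyelid-ramp waveforms around blinks,
or the heavy-tailed latency distributions of real patients. Passing
recovery tests therefore demonstrates the correctness of the analysis
chain under idealized waveforms, not clinical validity on real
recordings.

## Preprocessing

The chain mirrors standard VOG practice: artifact deletion, low-pass
filtering, calibration, cyclopean merging.

* **Artifacts:** samples that are non-finite or far outside the
  physical gaze range are invalid, dilated by a 25 ms guard (eyelid
  ramps corrupt velocity estimates). A recording over 50% invalid is
  rejected. Gaps ≤ 100 ms are bridged by linear interpolation *only* to
  stabilize the filter; the validity mask keeps them invalid.
* **Filter:** 4th-order Butterworth, cutoff 30 Hz, run
  forward–backward (zero phase, so latency endpoints are unbiased),
  with reflective end-padding. The zero-phase pass attenuates the
  fastest saccades by a few percent; measured end to end, the
  20°-peak-velocity endpoint sits about 2% below the generative law —
  well inside the ±5% recovery band and identical for patients and
  controls, so group contrasts are unaffected.
* **Calibration:** per eye and axis, an affine least-squares map from
  raw units to true degrees fitted on the slow (0.125 Hz) sinusoidal
  calibration block (±20° horizontal, ±15° vertical), which subjects
  track with essentially unit gain. Cross-axis terms are off by
  default.
* **Cyclopean merge:** sample-wise mean of the eyes where both are
  valid, the single valid eye otherwise (neither group shows systematic
  left–right differences, so the one-eye fallback is safe).

## Event detection and endpoints

Velocity is computed by central differences. An event spans samples
with speed above 30 °/s, extended to the 10 °/s boundaries; events
closer than 20 ms merge; events overlapping invalid spans are dropped.
Amplitude is measured over a ±25 ms extension of those boundaries
(clamped to valid samples and adjacent events) because the position
tails beyond the 10 °/s crossings would otherwise truncate up to ~0.6°
from large saccades. For pursuit records the thresholds are applied to
the velocity residual after subtracting a 250 ms running-median —
otherwise smooth tracking at up to 47 °/s would itself trigger.

The fourteen endpoints:

* **SPEM gain** (%) — median, over desaccaded valid samples where the
  absolute target velocity exceeds 10 °/s, of eye velocity over target
  velocity (the median resists residual saccadic contamination).
* **SPEM accumulated saccade sum** (°) — each pursuit-interrupting
  saccade contributes its drift-corrected amplitude, *negative* when it
  reduces the absolute eye–target error (a back-correction, i.e. a
  catch-up saccade) and *positive* when it increases it (jumping ahead
  of the target). A negative total flags the catch-up predominance of
  ponto-cerebellar pursuit failure; a positive total flags anticipatory
  behavior.
* **VGRS gain** (%, horizontal / up / down) — 100 × slope of the
  no-intercept regression of primary amplitude on target step (a zero
  step must predict zero amplitude). The primary saccade is the first
  event 80–800 ms after the step, matching its direction, with
  amplitude ≥ max(2°, 0.3 |step|); responses under 80 ms are
  anticipations, not primaries.
* **VGRS latency** (ms, horizontal / vertical) — median latency over
  found primaries.
* **VGRS peak velocity** (°/s, horizontal / up / down) — the main
  sequence $v(A)$ is fitted to the primary saccades per direction class
  and evaluated at 20° (the conventional reporting amplitude). With
  fewer than 3 events or degenerate amplitudes the endpoint is
  *missing*, never zero.
* **Intrusion rate** (°/s) — accumulated absolute amplitude of
  non-primary saccades ≥ 2° divided by valid acquisition time
  (horizontal task only).
* **Delayed / anti error rates** (%) — per the trial rules above, with
  a 2° minimum amplitude and an 80 ms refractory period after target
  onset.
* **Voluntary gaze shifts** — saccades > 10° counted in each 30 s
  record, arithmetically averaged over the horizontal and vertical
  tasks; with one record missing the other is reported with a partial
  flag.

## Staging

Fences come from the control cohort only: per parameter,
$Q_1 - 1.5\,\mathrm{IQR}$ and $Q_3 + 1.5\,\mathrm{IQR}$, quartiles by
linear interpolation between order statistics. Abnormality is
one-sided per parameter — error rates, intrusions and the anticipatory
saccade sum flag *high*; shift counts and the three peak velocities
flag *low* — because only those directions are pathological here. The
catch-up flag requires the conjunction of a saccade sum below its lower
fence *and negative* with a pursuit gain below its lower fence: the
sign carries the ponto-cerebellar semantics, so a low-but-positive sum
can never flag catch-up. Missing endpoints never flag.

The stage map is deterministic: no flags → stage 0; executive flags
only → stage 1; executive and brainstem flags → stage 2; brainstem
flags without any executive deficit do not conform to the staging
scheme (stage 2 *requires* stage-1 pathology by construction).
Latencies and VGRS gains are described per group but deliberately
excluded from staging — latency prolongation confirms rather than adds
a deficit class, and primary-saccade gains stay normal in this
population.

With n = 31 controls the Tukey fences are finite-sample quantities;
applying them back to the controls flags a few percent per parameter
(the suite asserts ≤ 25%, loosely). This specificity-over-sensitivity
choice is intentional: it protects against false-positive staging.

## Cohort statistics

Group contrasts use the nonparametric scheme throughout: two-sided
Wilcoxon–Mann–Whitney U between controls and all patients;
Kruskal–Wallis rank ANOVA over the three groups with pairwise
Mann–Whitney post hoc tests run *only* when the omnibus p < 0.05.
Clinical correlations (ALSFRS-R, ECAS) are Spearman rank correlations
on patients only, with Holm step-down correction over the whole
parameter × score family (Holm controls the family-wise error rate and
never reorders the raw-p ranking; the correction method is a package
choice where only "family-wise error correction" is specified).

The synthetic cohort builder draws a latent severity per patient that
drives both the oculomotor phenotype and the clinical scores. ALSFRS-R
(0–48) and ECAS (0–136) *decrease* with severity, their real-world
orientation, so error-rate correlations recover negative and
shift-count correlations positive; flip the score orientation in
`cohort_effect_config()` if the opposite reporting convention is
wanted.

## Study conditions and problem sizes

The cohort defaults are the study's composition: 31 controls, and
patients split into scripted stage-1 (n = 20) and stage-2 (n = 10)
phenotypes whose affected parameters sit at least ~3 control standard
deviations from the control mean. Controls draw from narrow
distributions centred on healthy medians (pursuit gain 0.92, main
sequence 470 °/s / 8°, latency 235 ± 15 ms, anti error 17%, delayed
error 8%, 1.9 shifts/s, intrusion rate 1.2 °/s, channel noise 0.1°,
blinks 0.1/s). Parameter-recovery checks run noiseless over a 27-point
phenotype grid (three main-sequence levels × three error probabilities
× three intrusion rates, cycling the three pursuit modes); these sizes
make the full suite and the acceptance script complete in a few
minutes on one core while keeping every check well-powered.

## A small worked example

```{r example, eval = FALSE}
ph <- phenotype_stage2(severity = 0.75)
recs <- simulate_subject(ph, make_protocols(1), seed = 1)
traces <- lapply(recs, preprocess_recording)
extract_profile(traces)

cohort <- build_synthetic_cohort(n_control = 31, n_stage1 = 20,
                                 n_stage2 = 10, seed = 1)
ref <- compute_reference(dplyr::filter(cohort, group == "control"))
staged <- stage_cohort(cohort, ref)
table(staged$stage_true, staged$stage)
plot_staging(staged, ref, "anti_error_rate")
```

## Known limitations

* The measured 20° peak velocity carries a small (~2%) systematic
  attenuation from the zero-phase 30 Hz filter; it cancels in group
  contrasts and fence comparisons because it affects every subject
  equally.
* Detection thresholds (30/10 °/s, 20 ms merge), the saturating
  exponential main-sequence form, the 80–800 ms primary window and the
  2° error-scoring minimum are standard clinical-VOG conventions; the
  upstream description of the original in-house analysis software does
  not pin them down, and real-data results can be sensitive to them.
* Whether pursuit gain should be computed per half-cycle rather than
  globally, and whether an anticipatory response before target onset
  voids an anti-saccade trial, are left open upstream; this package
  computes gain globally (median ratio) and scores only post-onset
  responses.
* Tukey fences from 31 controls are noisy; the staging-recovery rate of
  ~93% on scripted cohorts includes the resulting handful of control
  false positives, matching the expected behavior of the method rather
  than a defect of the implementation.
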