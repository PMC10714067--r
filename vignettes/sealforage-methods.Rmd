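---
title: "Methods: fine-scale foraging analysis from sonar/motion tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale foraging analysis from sonar/motion tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealforage)
```

## The measurement problem

Head-mounted sonar/motion tags on diving pinnipeds record several
asynchronous channels: triaxial acceleration at 200 or 250 Hz, triaxial
magnetometry and pressure-derived depth at 50 Hz, GPS surface fixes, and an
active micro-sonar that emits 25 pings per second over a 7 m range. From
these channels the package reconstructs, for one deployment:

* **dives** — maximal excursions deeper than 5 m, with shallower under-ice
  activity kept separately;
* **prey capture attempts (PrCAs)** — rapid head strikes visible as bursts
  of supra-threshold RMS-jerk in the acceleration;
* **prey interactions** — seafloor presence, prey traces, reaction type,
  reaction distance/time and acoustic size read from echo-to-noise-ratio
  (ENR) echograms in a window from 5 s before to 5 s after each attempt;
* **dive shapes** — functional PCA of normalized dive profiles followed by
  Gaussian-mixture clustering with an 80% posterior assignment rule;
* **approach behaviour** — body orientation, dead-reckoned local tracks,
  flipper-stroke counts and head turns in the window from 10 s before to
  5 s after each attempt.

Because raw tag deployments are rarely shareable, the package ships a
synthetic-deployment generator that produces all channels **with ground
truth**, so every stage can be validated end to end.

## Capture-attempt detection

The jerk is the norm of the forward-differenced acceleration scaled by the
sampling rate, `j[k] = fs * ||a[k+1] - a[k]||` (m/s³). The detection
statistic is a centred sliding RMS of the jerk. Events are maximal runs
above 150 m/s³; runs separated by silent gaps shorter than 5 s are merged
first (a long strike is composed of several jerk peaks), and only then are
events shorter than 5 s discarded. The merge-before-duration order matters:
it consolidates a burst into one event before the duration rule can delete
its fragments. A survival curve of inter-event gaps, with a chord-distance
elbow, is reported as a diagnostic for the merge gap but never applied
automatically.

Tunables: `threshold` (150 m/s³), `min_duration` (5 s), `merge_gap` (5 s),
and `rms_window` (0.2 s, hop 1 sample). The RMS window is not dictated by
the detection rules themselves; 0.2 s smooths 200–250 Hz jerk while moving
event boundaries by far less than the 5 s duration scale. For new tags,
`estimate_jerk_threshold()` locates the valley of a bimodal log-RMS
distribution.

Only events inside dives (depth > 5 m) are analysed further; shallower
events are flagged `excluded`.

## Echogram analysis

ENR is echo level minus the background-noise estimate, floored at 0 dB.
Pixels at or above `enr_min` (default 9 dB — the tags give no canonical
value, so every size/trace result should be reported together with the
threshold used) form the analysis mask.

* **Seafloor**: per ping, the near edge of the deepest supra-threshold run;
  kept where range-continuous (|Δrange| ≤ 3 bins against a running median)
  and accepted when it covers ≥ 30% of pings. A present seafloor makes the
  attempt — and its dive — benthic.
* **Prey traces**: 8-connected components of masked-out pixels after
  removing the ridge plus a 2-bin guard band, requiring ≥ 6 pixels over
  ≥ 3 ping columns. Components sharing ≥ 3 ping columns mean several prey
  in the same ping (a school).
* **Reaction**: the per-ping minimum-range polyline is fitted by linear and
  quadratic least squares. A trace starting within 10 cm of the ridge with
  a clearly negative slope is *leave seafloor*; a trace clear of the floor
  whose quadratic opens upward with an interior minimum and a real range
  excursion (≥ 3 cm down, ≥ 2 cm back up) is *escape*; anything else is
  non-reacting. When both fire, the departure origin on the floor wins.
  The onset is the first ping whose 3-ping range rate exceeds 5 cm/s
  (above the 1 cm / 25 Hz quantisation noise). For leave-seafloor
  reactions the onset range is reported as the **seafloor range at the
  onset ping**: the departure origin defines the reaction distance, and the
  guard band would otherwise bias the first visible pixel shallow by the
  guard width.
* **Acoustic size**: median over trace columns of the contiguous
  supra-threshold extent times the bin width; only defined for traces
  clearly separated from other echoes. It is a relative echo extent, not an
  anatomical length.

Onset times are reported relative to the attempt start; reactions occurring
before it get negative times.

## Dive-shape clustering

Each dive profile is resampled to 101 points on normalized time [0, 1] and
z-scored within the dive, so clustering sees shape rather than magnitude or
duration (the study's shallow W-shaped cluster remains separable purely by
shape). Curves are smoothed on a 15-function cubic B-spline basis; the
covariance eigenproblem is solved in coefficient space under the basis Gram
inner product, giving L²-orthonormal eigenfunctions, ordered variance
fractions and per-dive scores. The resample count and basis size are
exposed; 101 points resolve the 5 Hz profiles of dives of a few minutes,
and 15 basis functions sit comfortably between under-smoothing and rank
starvation for the three components kept.

Scores feed a Gaussian-mixture model fitted by EM for every K in 1–9 and
six covariance families (spherical/diagonal/full × equal/varying), selected
by BIC. EM uses 10 restarts (one k-means seeding plus random means, with an
early stop once the best log-likelihood is reproduced twice), tolerance
1e-6, at most 500 iterations, and a small ridge on the covariances. A dive
is assigned to its maximum-posterior cluster only when that posterior
reaches 0.8; otherwise it stays unclassified. Raising the threshold can
only shrink the assigned set.

## Orientation, track and approach behaviour

Conventions: body x forward, y left, z dorsal; world east/north/up; pitch
positive nose-up, heading 0 at magnetic north with negative values to the
left, wrapped to (−180, 180]. The static acceleration (low-pass, 0.5 Hz)
gives pitch and roll; the tilt-compensated magnetic field gives heading,
with an optional declination correction. Samples whose static magnitude
deviates from g by more than 30% are flagged unreliable.

Dead reckoning uses a depth-rate speed model: where |pitch| > 20°, speed =
|depth rate| / |sin pitch| clamped to [0.2, 3] m/s; elsewhere a 1 m/s
fallback drives the horizontal step while the vertical step follows the
measured depth, which keeps the track depth-consistent by construction.
The tags carry no speed sensor, so these are stated assumptions, all
config-exposed.

Lateral acceleration is split by zero-phase filters into a stroke band
(0.4–2.5 Hz, bracketing phocid stroke frequencies), a slow gravity trend,
and a residual that carries head turns and other transients. Strokes are
prominence-gated peaks (≥ 0.3 m/s², ≥ 0.3 s apart). A head turn within
±1 s of the prey reaction is called when the net wrapped heading change
exceeds 10°; the threshold is a package decision — the source analyses
report turn direction but no angular cutoff — and heading is used because
it is the quantity those analyses actually report. Approach summaries
tabulate, per reaction type, the timing of the reaction relative to the
event (before/during/after), stroking in the 5 s before the reaction,
stroking during the event, and left/right turns.

## The synthetic-deployment generator

The generator's defaults are the study conditions, not tuning knobs: dive
durations 7 ± 8 min; capture depths 88 ± 30 m (truncated at the dive
threshold); 9.13% of dives foraging with ~4 attempts each; sub/supra
threshold RMS-jerk regimes of 30 and 400 m/s³ realized as two log-normal
amplitude regimes (the bimodal distribution's form is not reported, so the
two-regime model is a stand-in, not a claim about the tags); echograms at
25 pings/s over 7 m at 1 cm/bin so acoustic sizes map directly to pixel
counts; reaction distances 51 ± 18 cm in [16, 121] cm; onset times 9 ± 7 s
with negative values allowed (about a third of reactions precede the
attempt); acoustic sizes 5 ± 1 cm in [3, 13] cm; 98% benthic, 38% visible
traces, 56% reactive, 70% of reactions leaving the seafloor; approach rates
74/79% stroking and 43/27% left/right turns; ~30 GPS fixes/day with 0.2 km
steps within 3 km of the colony. Reactive onsets are scheduled early enough
that the reaction geometry fits the ±5 s analysis window.

Dive shapes come from five archetypes — square, symmetric V, left-skewed V
(sinuous descent), right-skewed V (sinuous ascent), and a shallow W — with
per-dive random geometry plus a smooth multi-harmonic deformation masked
near each archetype's diagnostic structure. The deformation amplitude was
fixed once, balancing three constraints: the archetype geometries must
survive (exactly two W excursions, a flat square bottom, a single mid-dive
V apex), the mixture model must recover five clusters modally, and the
curve population should spread variance over several components. Under the
final calibration the first three components carry roughly 52/29/6% of the
variance — broad in the first two but more concentrated than the roughly
33/25/21% regime reported for the real animals, whose dives vary far more
idiosyncratically than five parameterized archetypes can. This is a known,
accepted limitation: passing shape-cluster tests here demonstrates the
estimator chain, not that field data will produce the same eigenstructure.

Other simplifications worth keeping in mind: device axes equal animal axes
(a fixed mounting rotation is available for calibration tests); roll is
held at zero in simulated deployments; pressure has no tide or drift; the
sonar model places echo energy geometrically with Gaussian dB noise and no
beam-pattern or time-varying-gain physics; pup behaviour is absent.

The default deployment length is 2 h per individual — long enough to carry
dozens of dives at full sampling rates while keeping simulated arrays
small; the field deployments ran for about 7 days, but record length only
scales the arrays, not the statistical structure. Tests and the acceptance
analyses therefore run compressed deployments (for example 84 all-foraging
dives of ~2 min carrying 331 attempts across 3 individuals) and state those
sizes; every distributional condition above is kept at the study values.

## Numerical choices and degenerate inputs

* Depth is positive down, surface = 0; raw negatives are clamped; a sample
  exactly at 5 m counts as shallow (the dive rule is strictly deeper than
  5 m). No minimum dive duration is imposed.
* Day period uses the geometric solar elevation from a self-contained
  NOAA-style routine (twilight is the closed interval [−12°, 0°]); no
  refraction, since the class boundaries are geometric.
* Jerk uses the forward first difference; a central-difference variant
  would halve the bandwidth without changing the 5 s event scale.
* The EM skips a covariance family with a warning when a component
  degenerates (fewer responsibilities than dimensions); eigenvalues are
  floored at zero in the fPCA; constant-depth profiles cannot be
  normalized and error out early.
* Event/dive/echogram edge cases (empty records, zero-duration
  deployments, traces of fewer than 4 pings, non-isolated traces) return
  empty results or flagged NAs rather than failing.

## What the validation shows — and what it does not

The test suite closes the loop simulator → pipeline → truth for every
stage: ≥ 95% of injected capture attempts recovered with ≥ 50% overlap and
a false-event rate below 0.5/h; exact equivalence of the detector with an
exhaustive run-scan oracle on random series; ~99% reaction-classification
agreement at default noise with onset ranges recovered to a few cm; fPCA
variance fractions recovered to well under a point on constructed low-rank
curves; mixture posteriors matching closed-form Bayes responsibilities to
1e-6 and an independent mixture implementation on fixtures; and modal
selection of five clusters across seeds. All of this certifies the
estimator chain under the generator's assumptions. Real tag data add
mounting offsets, pressure transients, acoustic clutter, prey schooling
structure and behaviourally correlated noise that the generator does not
emulate; threshold choices (ENR 9 dB, head-turn 10°, stroke band) should be
re-examined, and reported with results, on any new dataset.
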