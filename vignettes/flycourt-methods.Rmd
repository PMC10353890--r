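---
title: "Methods: quantifying light-induced courtship in multi-fly arenas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying light-induced courtship in multi-fly arenas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flycourt)
library(dplyr)
```

## The assay

Groups of eight male *Drosophila* are confined to a circular arena (a
26-mm "region of interest", ROI, 2 mm high) and exposed to a programmable
light protocol — by default 2 min of low-intensity light (0.4 klx,
ordinary room light), 2 min of high-intensity light (18 klx), and a 2-min
low-intensity recovery period. Under intense light, males chase one
another, extend their wings (producing courtship song), and form *chains*:
mobile single-file lines of four or more flies, each courting the fly
ahead. flycourt implements the quantitative machinery around this assay:

1. an agent-based **simulator** that generates trajectories, video frames
   and song audio with known ground truth;
2. a **tracking** stage turning frames into identity-resolved centroid
   trajectories in millimetres;
3. a **social** stage computing interactograms and detecting chase and
   chain events;
4. per-fly **kinematics** (distance travelled, mean speed, % time moving);
5. interval-based **scoring** of behaviour presence across light epochs,
   with paired and multi-group statistics, dose-response summaries, and
   emission-spectrum normalization;
6. **song** segmentation of microphone recordings into pulse and sine
   components.

Every stage accepts and returns plain tabular data (tibbles), so stages
chain with the pipe and intermediate results can be written to CSV.

## Scoring model

Each epoch is divided into 10-s bins and each behaviour (chase, wing
extension, chain) receives a binary mark per bin: 1 if any event of that
behaviour overlaps the bin's scoring window, however briefly. The sum of
marks over a 2-min epoch is the *total score*, ranging 0–12. A two-operator
variant scores two ROIs alternately in 5-s half-windows; `score_intervals()`
exposes this as `mode = "alternating"` for parity with manual scoring, but
the automated pipeline defaults to the full bin because software does not
need to halve its observation time.

Statistics follow the assay's conventions: the ROI is the replicate unit;
per behaviour, consecutive epochs are compared with two-sided paired
*t*-tests (low vs high, high vs recovery), and multi-group designs
(e.g. genotypes) use one-way ANOVA followed by Bonferroni-corrected
pairwise *t*-tests, with significance tiers at 0.05/0.01/0.001. Two
degenerate cases are defined by continuity: identical paired samples give
t = 0, p = 1; a constant non-zero paired difference is reported as
t = ±Inf, p = 0.

## Proximity, chases and chains

Social structure is read off the **interactogram**: for every pair of
identified flies, the frames in which their centroid distance is
*strictly less than* 3.75 mm. That criterion is the assay's interaction
distance, chosen as optimal for capturing chasing; the strict inequality
at the boundary is part of the definition and is verified by bisection in
the tests.

On top of the interactogram two detectors operate:

* **Chases.** A chase is a maximal run of at least 1 s in which a pair is
  in proximity, both flies move at ≥ 2 mm/s, and the chaser's displacement
  heading points within 60° of its bearing to the target. In the
  behavioural literature chasing is defined observationally, by a trained
  scorer; this operationalisation (and its
  three thresholds, all exposed in `interaction_params()`) is this
  package's, validated against simulator ground truth.
* **Chains.** Chaining is a *mobile chain of four or more flies*. Per
  frame the proximity graph is built; a frame is a candidate when the
  graph contains a simple path of ≥ 4 flies — a follow-line, not merely a
  dense cluster. Candidate frames whose member sets overlap by ≥ 50% are
  stitched; an event must last ≥ 1 s and its members' mean speed must meet
  the 2 mm/s mobility criterion. Masked (invalid) tracking frames break
  runs, so no event spans a tracking gap. No temporal smoothing is applied
  to the interactogram itself.

## The simulator

`simulate_arena()` is the package's oracle factory: every downstream
detector is tested against what the simulator actually generated.

Undisturbed flies perform a correlated random walk: constant walking speed
(8 mm/s), heading diffusion (2 rad/√s), intermittent pauses (entered at
0.2 /s, mean 1 s), collision avoidance below 4 mm, and a reflecting
circular boundary at 13 mm. An unengaged fly initiates a chase of its
nearest free neighbour (within 6 mm) with a per-second probability given
by the dose-response curve `chase_rate_logistic()`: logistic in
log-intensity between a floor of 0.0015 /s (spontaneous courtship under
room light, giving low-epoch totals of roughly 0–2) and a ceiling of
0.06 /s, with midpoint 4.2 klx and scale 0.1 decades so that the steepest
relative rise falls between 2 and 6 klx — the intensity range in which the
assay's response rises fastest. Chases last a minimum of 2 s plus an
exponential tail (mean 3 s); the pursuer steers towards its target with a
capped turn rate, servoing a 2-mm following gap at up to 18 mm/s, while
the target flees and steers the line around bystanders. An ongoing chase
recruits a further fly into the follow-line at 0.5 /s (3-mm spacing), and
each recruit extends the event by 2 s; ground truth logs every pursuing
pair and every follow-line with its membership order and the frame at
which it reached four members.

These kinematic constants are this package's choices — the assay reports
no chase speeds or durations — and are documented here precisely because
they are not measurements. They were chosen once to produce realistic
densities: with the default protocol a 6-min simulation yields roughly
30–60 chase pairs and a handful of ≥ 4-fly chains at high light, near-zero
at low light.

What the generator does *not* emulate: wing posture (so wing extension
cannot be detected from synthetic video; it is scored from manual or
simulated event tables), pheromonal state, female agents (mixed-sex
arenas exist only as parameter presets), body articulation, lighting
artefacts, and real sensor noise beyond Gaussian pixel noise.
Consequently, a passing test suite demonstrates that the detectors recover
what the model generates under the stated noise — not that they would
match human scoring of real video frame-for-frame.

## Rendering and tracking

`render_frames()` projects trajectories into grayscale frames (one dark
2.5 × 1.2 mm ellipse per fly, oriented along the displacement heading, on
a light background with Gaussian pixel noise, default scale 0.1 mm/px).
`detect_flies()` thresholds pixels darker than a background model by at
least max(3 × MAD, 0.15), labels connected components (EBImage), filters
by area, and — when fewer blobs than flies are found — splits the largest
blobs by a deterministic 2-means (principal-axis bisection plus Lloyd
iterations), flagging the results as merged.

The background model is a per-pixel temporal 0.9-quantile over the first
100 frames, with the per-pixel MAD capped at three times its matrix-wide
median. A high quantile rather than a median is deliberate: flies are
strictly darker than the background, and a fly that dwells in one spot
for much of the background window corrupts a median model (we observed
eroded and spurious blobs from exactly this failure), while the
0.9-quantile tolerates dwell fractions up to 90%.

`link_identities()` assigns detections to tracks frame-by-frame by
optimal bipartite assignment (a Jonker–Volgenant shortest-augmenting-path
solver written for this package and cross-checked against brute-force
enumeration) on distance from a constant-velocity prediction, with a hard
gate at 50 mm/s equivalent displacement. Lost tracks coast at their last
position — flagged invalid — for up to 5 frames, after which the gate is
lifted for re-acquisition. Identity through prolonged multi-fly merges is
the known hard case: during dense high-light interactions, pair swaps can
survive a merge, which is why round-trip identity agreement is evaluated
on the default (low-light leading) fixture and why positions during
coasting are masked rather than trusted.

Scale calibration (`calibrate_scale()`) reads mm/px off the arena outline
(largest dark extent = known 26-mm diameter).

## Kinematics

Distance travelled is the sum of frame-to-frame displacements over valid
frames; mean speed is distance over valid elapsed time; % time moving is
the fraction of valid frames whose speed, smoothed over a 0.2-s centered
window, is at least 1 mm/s. The moving threshold and smoothing window are
this package's defaults (the assay's tables do not state theirs), so
numeric parity with published kinematics tables is not claimed.
Displacements across invalid frames are excluded from numerator and
denominator alike.

## Song

Courtship song alternates *pulse song* (trains of brief pulses,
characterised by inter-pulse interval, IPI, and pulses per bout) and
*sine song* (sustained ~110–190 Hz humming, characterised by dominant
frequency and duration). `synthesize_song()` builds ground-truthed audio:
pulses are exponentially damped sinusoids (220 Hz carrier, 5 ms decay,
optional IPI jitter), sine elements are ramped pure tones, and white noise
is added at a stated SNR.

`segment_song()` band-passes in the pulse band (100–500 Hz), forms an
envelope by rectification and low-pass (150 Hz — high enough to resolve
20-ms IPIs; a Hilbert envelope would be equivalent at these bands), and
takes local maxima above 6 × the MAD of the band-passed waveform with a
5-ms refractory spacing. A local-contrast test (peak > 3 × the envelope's
local median over ±60 ms) rejects maxima riding sustained plateaus, which
is what keeps sine song out of the pulse detector, and incidentally
suppresses rare threshold crossings on pure noise. Pulses with gaps
≤ 0.1 s form bouts (≥ 3 pulses). Sine segments are maximal runs of
sustained sine-band (100–200 Hz) envelope lasting ≥ 0.2 s whose segment
periodogram peaks inside the band; the reported frequency is that
periodogram peak, so its resolution is one spectral bin (2 Hz for a 0.5-s
segment). All thresholds are noise-relative, making the segmentation
invariant to positive amplitude scaling; all numeric values are defaults
of this package, chosen from standard practice, not taken from the assay.

Under the defaults, synthesized songs over an IPI grid of 20–60 ms and a
sine grid of 110–190 Hz at ≥ 10 dB SNR are recovered with ≤ 1 ms IPI error
and ≤ 1-bin frequency error, and 1-s pure-noise clips yield no detections
(both measured in the test suite).

## Dose-response and spectra

`dose_response()` summarises total scores per intensity (mean ± SEM) and
reports the adjacent-intensity interval with the largest relative increase
in mean score; intervals with a zero baseline are flagged rather than
divided by zero. `normalize_spectrum()` divides an emission spectrum by
its peak (E(λ)/E(peak)), so the maximum of the output is exactly 1; it is
idempotent and scale-invariant.

## Problem sizes and reproducibility

The test suite and acceptance checks use sizes chosen to exercise each
property at desk scale: 6-min 8-fly simulations for detector validation
and the 20-run epoch-recovery experiment (four ROIs per run), 900-frame
renders at 0.1 mm/px for the tracking round trip, 50 random 8-fly ×
200-frame instances for the brute-force interactogram oracle, and 36
synthesized clips per song grid. Every stochastic step takes an explicit
seed; `simulate_arena()` is a pure function of its parameters including
the seed, and the CLI writes a manifest with a configuration hash so
reruns can be verified byte-for-byte.

## Known limitations

* Chase/chain operational definitions are heuristic stand-ins for manual
  scoring; thresholds are exposed, not fitted.
* Identity linking can swap flies through long merges; downstream
  proximity analyses are robust to relabelling, but per-fly kinematics
  over swap-heavy segments are not.
* Wing extension is not detectable from centroid video; it enters the
  score sheets only via supplied event tables.
* The simulator's kinematic constants are plausible, not measured; only
  protocol-definitional constants (arena geometry, 3.75-mm criterion,
  bin structure, chain minimum size) are taken from the assay itself.
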