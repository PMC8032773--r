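---
title: "Temporal confirmation and evaluation of video CADe for esophageal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal confirmation and evaluation of video CADe for esophageal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escadet)
```

## The problem

Screening esophagogastroduodenoscopy should catch superficial esophageal
squamous cell carcinoma (ESCC), but early lesions are subtle and an
endoscopist advancing the scope at routine speed can pass one without
noticing. A frame-level detector can score every frame of the video, yet
raw per-frame output is useless as an alarm: at 30 fps even a tiny
per-frame false-positive rate would fire constantly, and single-frame
hits on shadows or folds carry no evidence. The clinically deployed
compromise is a *discovery signal*: a short review of the video following
a first hit, with the alarm raised only when the review corroborates it.
`escadet` implements that decision layer — the confirmation rule, the
matching of alarms to ground truth, the per-video diagnostic metrics and
paired statistics — together with a seeded simulator that stands in for
the trained detector network.

## The confirmation rule

Let `pos(t)` be true when frame `t` carries a box scoring at least
`score_threshold`. With window `W = round(review_window_s * fps)` and gap
`G = round(max_gap_s * fps)` frames (half-up rounding, giving `W = 15`
and `G = 3` under the defaults at 30 fps):

* every positive frame `t0` reached while the engine is armed is a
  candidate trigger and opens a review of frames `t0+1 … t0+W`;
* at `t0+W` a signal is emitted iff the review window holds at least
  `min_votes` positive frames **and** the latest positive frame (the
  trigger counts as a fallback) lies at most `G` frames before the
  window end;
* the signal's snapshot is that latest positive frame with its
  highest-scoring box — the still image the system inserts on the
  monitor as evidence;
* a failed candidate consumes nothing: the next positive frame after it
  is evaluated independently;
* after a signal, triggers are suppressed until
  `refractory_clear_frames` consecutive negative frames (default: one
  window, 15) have passed, so one lesion encounter raises one alarm;
* a review truncated by the end of the video never emits.

Three readings of the deployed rule's description were genuinely open,
and the package fixes them as follows.

**The review window looks forward.** The observed floor on
trigger-to-signal latency equals exactly one full review window (0.5 s
at 30 fps), which forces the review to cover the frames *after* the
trigger; a backward-looking window would permit latencies of ~0.13 s,
below the observed floor. `min_latency()` returns this floor,
`round(review_window_s * fps) / fps`, and the engine attains it for a
continuously detected lesion.

**"More than 3 frames" means at least 4, excluding the trigger.** Votes
are counted strictly inside the window so votes and window are
coextensive; the trigger frame itself is not a vote.

**The gap condition is a recency check.** "Maximum interval from the
latest cancer image" names a single reference frame, so the default mode
(`gap_mode = "latest"`) requires only that the latest positive frame be
within `G` frames of the review end. The alternative reading — every
consecutive inter-positive interval within the window at most `G` — is
implemented as `gap_mode = "all_gaps"` and is strictly stricter.

The refractory behaviour and the failed-candidate re-arming are not
specified for the deployed system at all; the package's choices (a clear
run of negatives; independent candidates) were made so that the
streaming engine is exactly equivalent to a simple enumerable
specification. That equivalence is not an aspiration but a tested
property: `brute_force_signals()` re-derives the signal list by direct
enumeration over candidate triggers, and the suite asserts exact
agreement on 1000 random streams spanning positive densities 0.1–0.9,
plus random rule configurations.

The detector's deployed score cutoff is unpublished; `score_threshold`
defaults to a fixed, conventional 0.5 and the stream format carries raw
scores so any cutoff can be applied downstream.

## Matching, outcomes, metrics

A signal is a true positive when its snapshot contains any part of a
lesion. Temporally this means the snapshot frame lies inside a lesion's
visibility interval (`mode = "interval"`); with region annotations
available, `mode = "box_overlap"` additionally requires the snapshot box
to intersect the lesion rectangle — any nonzero overlap, no IoU
threshold, mirroring how a human adjudicator reads the inserted image.
Rectangles are half-open (`[x0, x1) × [y0, y1)`), so a shared boundary is
zero overlap and the test is unambiguous.

All four diagnostic metrics count *videos*, not lesions or signal
events: sensitivity = correctly detected cancer videos over cancer
videos, specificity = alarm-free control videos over control videos,
PPV = correctly detected cancer videos over videos with any alarm,
NPV = alarm-free control videos over alarm-free videos. Two consequences
of these definitions are worth stating because they are easy to get
wrong:

* a cancer video whose only alarms are false positives is AI-positive
  but not correctly detected — it inflates the PPV denominator without
  touching its numerator;
* cause tabulation of false positives operates on *signal events*, which
  outnumber false-positive videos (one video can alarm on a shadow and
  on the esophagogastric junction); metrics and tabulations therefore
  use different units by design. Per-lesion sensitivity can be computed
  separately when lesions are the unit of interest.

The comprehensive analysis unions the two modalities per case: detected
in either the white-light or the narrow-band video counts as detected.
Union sensitivity therefore dominates both per-modality sensitivities,
an invariant the suite checks.

Percentages are rounded half-up to integers (`floor(100 n/d + 0.5)`),
the convention that reproduces every printed cell of the per-case
accuracy and cause tables; counts are always carried alongside so
rounding never destroys information. Ratios with an empty denominator
are reported as undefined (`NA`), never as 0.

Time to detection is measured from the lesion's first visible frame to
the signal frame of the earliest true positive. Note this is a different
quantity from the rule's trigger-to-signal latency: it can fall below
the 0.5 s latency floor in the corner case where a spurious burst just
before lesion entry has already opened a review that then ends inside
the lesion's visibility window.

## Statistics

Paired per-case detection under the two modalities is compared with
McNemar's test on the discordant counts `(b, c)`. The exact form is the
two-sided binomial sign test `min(1, 2 P(X ≥ max(b, c)))`,
`X ~ Bin(b + c, ½)`; the asymptotic form is the continuity-corrected
chi-square `(|b − c| − 1)² / (b + c)` on 1 df. `method = "auto"` uses the
exact form below `b + c = 25` — the study's paired samples are small and
the exact test costs nothing.

Reader sensitivities with and without assistance are compared with the
two-sample Mann–Whitney test, because that is how the comparison is
defined for this crossover design even though the data are paired; the
Wilcoxon signed-rank test is exposed (`wilcoxon_signed_rank()`) as the
statistically conventional alternative but is deliberately not the
default. The Mann–Whitney U uses midranks; the exact two-sided p is
computed by complete enumeration of rank assignments for combined
samples up to 12 without ties, otherwise a tie-corrected normal
approximation with continuity correction. Degenerate inputs (all values
identical, or `b = c = 0`) return p = 1 by convention and are flagged.

Reader scoring is strict: a cancer video is correct only if a button
press falls inside a lesion's visibility interval — noticing the lesion
after it has left the monitor scores as incorrect, and every press
outside the intervals is a false alarm.

## The simulator

`simulation_config()` emulates the high-speed screening condition: a
25 cm esophagus traversed at 2 cm/s without stopping, recorded at
30 fps (375 frames per video), 20 cancer and 20 control cases by
default, each case contributing one white-light and one narrow-band
video. Lesion diameters are log-uniform on 5–60 mm, whose median
(√300 ≈ 17 mm) matches the reported median tumor size; wall positions
are drawn 8:4:8:2 anterior:posterior:left:right as in the validation
set. A lesion of diameter `d` mm is visible for
`(d/10 + 2 · field_margin_cm) / speed` seconds — a single contiguous
interval, as a constant-speed pass implies. Setting `dwell_s = c(5, 15)`
instead emulates the slow-observation condition in which the
endoscopist holds each lesion in view for 5–15 s.

While visible, each frame yields a supra-threshold detection with
probability `p_detect_wli` / `p_detect_nbi` (defaults 0.4 / 0.3).
The real network's frame-level hit rates are unpublished, so these are
calibration knobs chosen to put the default pipeline in a plausibly
imperfect regime, not estimates. A per-case latent detectability factor
(logit-normal, sd 0.5) is shared by the two modalities so that the same
lesion drives correlated success in both videos, while detection noise
and false-positive processes are drawn independently per modality.
Peristalsis episodes arrive as a Poisson process (0.1/s, 1 s long) and
multiply the detection probability by 0.3, reflecting that a contracted
wall hides the lesion.

False positives arrive as per-category Poisson bursts with geometric
lengths (mean 8 frames). The default per-minute rates 3 : 2.4 : 0.7 : 1.3
for shadow : inflammation : post-resection scar : esophagogastric
junction follow the observed 30 : 24 : 7 : 13 category mix of
false-positive events, scaled so that a control video has an appreciable
chance of a confirmed false alarm; junction bursts are restricted to the
final 10 % of frames, where the junction is actually in view. Burst
frames are tagged by category in the ground truth so that confirmed
false alarms can be attributed to causes.

Reproducibility is structural: a root seed draws one sub-seed per case,
recorded in the study manifest, so any case regenerates bit-identically
in isolation; all generator functions save and restore the global RNG
state.

What the simulator does **not** model: pixel appearance or detector
score distributions (scores are drawn uniform above threshold),
morphological lesion subtypes, multiple lesions per case, camera
shake, retroflexion or withdrawal phases, and any correlation between
false-positive sources and lesion proximity. Passing tests on simulated
streams therefore validate the *decision layer* — the rule, matching,
metrics and statistics — not the detector; no claim about real-video
detector performance follows from them.

## Fixtures for the published result tables

The real validation videos and per-reader responses are not deposited,
so the package encodes the published per-case results as deterministic
fixtures instead. `fixture_high_speed()` reconstructs per-video outcomes
whose per-modality margins are the printed detection counts (15/20 and
6/20 correct under white light, 11/20 and 16/20 under narrow band) and
whose both-modality overlap (9 cancer cases) is fixed by
inclusion–exclusion against the printed union count of 17; the
narrow-band false-alarm control set is nested inside the white-light
one. `fixture_causes()` lists the 74 categorized false-positive events
and the 12 missed lesions (in 11 cases). Running these fixtures through
the evaluation layer reproduces every printed percentage and count pair,
which is how the arithmetic conventions of the package are pinned down.

## Numerical choices and degenerate inputs

* Frame indexing is 0-based; the time of frame `k` is `k / fps` s.
* Seconds-to-frames conversion is `round(x · fps)` half-up everywhere.
* A configuration whose window cannot hold `min_votes` frames is
  rejected rather than silently never firing.
* Stream files with missing frame indices are an error unless
  `fill_gaps = TRUE`, since silent gaps would corrupt the gap logic.
* Scores serialize with the shortest decimal representation that
  round-trips the double exactly, so write-then-read is the identity in
  both the JSON-lines and CSV dialects.
* Ties in snapshot-box selection resolve to the first highest-scoring
  box; signal lists are always in frame order.

## Problem sizes used by the test suite

The suite exercises the oracle equivalence on 1000 random 600-frame
streams, the latency floor on 1000 random 120-frame streams, round-trip
identity on 100 random streams per format, and the simulator's
monotonicity in detection probability on a 5-point grid with 200
replicate cases per point (under common random numbers, which makes the
monotonicity exact rather than statistical). These sizes keep the full
suite well under a minute while covering the stated properties.
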