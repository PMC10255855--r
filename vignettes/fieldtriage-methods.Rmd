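---
title: "Methods: sensor-driven casualty triage, degraded modes, and the chance-of-survival function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-driven casualty triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldtriage)
```

This vignette is the package's own account of its science: the rule
cascade and its assumptions, the degraded-mode reliability model, how the
chance-of-survival function is built and calibrated, what the synthetic
physiology emulates (and what it does not), and the numerical choices made
where the design was genuinely open.

## 1. The triage cascade

The automatic triage decision uses four vital signs — respiratory rate
(RR), heart rate (HR), systolic blood pressure (SBP) and oxygen saturation
(SpO~2~) — each compared against a per-soldier profile holding a reference
interval and critical thresholds:

| sign | reference (default) | critical (default) | units |
|------|--------------------|--------------------|-------|
| RR   | 9 – 20             | ≤ 5 or ≥ 30        | /min  |
| HR   | 50 – 110           | ≤ 40 or ≥ 140      | bpm   |
| SBP  | 100 – 180          | ≤ 80 or ≥ 220      | mmHg  |
| SpO~2~ | 94 – 100         | ≤ 85 (one-sided)   | %     |

A value inside its reference interval is `in_reference`, a value at or
beyond a critical threshold is `critical`, anything between is
`out_of_reference`; the three severities are totally ordered. The cascade
walks the signs in the fixed clinical priority order RR, HR, SBP, SpO~2~
and may only *upgrade* the running colour (green → yellow → red), never
downgrade it. That upgrade-only sequential rule is exactly equivalent to
taking the maximum severity across the available signs — the test suite
verifies the equivalence against an independently coded brute-force oracle
on an exhaustive 20×20×20×20 grid spanning below-critical to
above-critical values on every axis.

Interval edges are deliberate: the reference interval is closed (RR = 9 or
20 is still green) and the critical region is closed on its inner edge
(RR = 30 is already red). The comparisons in the rule set are interval
memberships, not equality tests on scalars — the printed typical values
are ranges, so "equal to the reference" can only mean "inside the
reference interval".

The reference ranges are *population* defaults. The design assumes
per-soldier personalisation (e.g. athletes with resting HR below 50) is
supplied through the profile; no critical thresholds are published for the
system this emulates, so the defaults above follow the extreme bands used
by START/NEWS2-style early-warning scores. They are configuration, not
constants.

Two tags sit outside the cascade. **Black** is assigned whenever no
heart-rate signal is available — indistinguishable on the receiving side
from a destroyed sensor, jamming, or death, hence it always demands
on-scene confirmation and is never queued for evacuation automatically.
**Blue** (casualties with no or minimal survival chance, evacuated last)
can only be created through `apply_override()` by a `medic` or `rescuer`
role; there is no automatic path to it, and the superseded decision is
retained in the override's history.

MPA (mean physical activity) and body position are carried in every
snapshot and logged to the casualty card but do not influence the colour:
the rule set uses only the four signs above, and activity/posture serve as
supporting context for the medic.

## 2. Degraded modes and reliability

Sensors fail routinely in the field, so the engine runs on whatever signs
arrive and annotates each decision with a fixed confidence score
determined by the availability subset: all four sensors 100 %; without
SpO~2~ 90 %; without SBP 80 %; without RR 80 %; HR+RR 70 %; HR+SBP 70 %;
HR+SpO~2~ 60 %; HR alone 50 %. The table is exact and exhaustive over the
eight HR-containing subsets; every HR-less subset yields the black signal.
The chance-of-survival value is attached only at reliability 100 — at
lower reliability the colour stands but a percentage would suggest
precision the inputs cannot support.

One consequence of the measurement architecture is worth stating plainly:
cuffless SBP is derived from the ECG-to-PPG pulse arrival time, so losing
the PPG pair costs *both* SpO~2~ and SBP — the post-dropout mode is HR+RR
at 70 %, not 90 %. A deployment with an independent pressure sensor would
land at 90 % instead; the reliability table itself is agnostic to why a
sign is missing.

Ordering for evacuation uses colour first (red before yellow before
green), then ascending survival chance within a colour ("which of the reds
is most red"), with ties broken by earlier decision time. Reverse
(tactical) triage sorts by descending survival chance to recover the
lightest wounded first. Blue is last in both modes. Reliability below 100
does not alter a casualty's position — it suppresses the survival score
but the colour keeps its full priority, which is the conservative choice
when the alternative is demoting a casualty because their sensors failed.

## 3. The chance-of-survival function

### Training grid

The function is trained on a deterministic grid of 7200 cases — the
Cartesian product of 10 RR × 12 HR × 12 SBP × 5 SpO~2~ levels, each axis
spanning from below the critical threshold into the reference interval
(SpO~2~ has the fewest levels because its thresholds are one-sided).
Labels come from the triage cascade itself, so the learner's target is the
exact rule set.

Axis levels are *midpoint-aligned*: wherever two adjacent levels straddle
a clinical threshold, they are placed symmetrically about it. A maximum-
margin classifier puts its decision surface midway between the closest
opposing training points, so this placement makes the learned boundary
coincide with the cascade's colour change instead of landing somewhere
inside the gap. With evenly spaced levels the off-grid colour agreement
plateaus around 0.86; midpoint alignment lifts it above 0.95 (see the
audit below) at no cost in grid size.

### Two-stage large-margin architecture

Two RBF-kernel support-vector machines implement the ordinal structure
with exactly two binary classifiers: stage A separates red from
{yellow, green}; stage B separates yellow from green among the not-red.
Features are the four signs, standardised once against the grid; both
stages share the scaling. Defaults `cost = 100`, `gamma = 1` interpolate
the deterministic grid labels exactly (training agreement 100 %, required
≥ 99 %) while keeping the surface smooth enough for the monotonicity and
off-grid properties below; the fit is seeded and reproducible.

### Calibration into bands

The published design fixes only the output ranges — red 1–50 %, yellow
51–99 %, green exactly 100 % — not the shape of the map. The package
squashes the signed margin distance of the deciding machine through a
logistic function, scaled by the median absolute training margin, places
it affinely inside the predicted colour's band, rounds to an integer
percent and clamps:

* predicted red: `clamp(round(100 · plogis(−d_A / s_A)), 1, 50)` — deep in
  the red region the chance approaches 1 %, at the boundary 50 %;
* predicted yellow: `clamp(round(51 + 48 · plogis(−d_B / s_B)), 51, 99)`;
* predicted green: exactly 100.

Clamping guarantees band membership for the *predicted* class by
construction (`band_compliance()` reports the pre-clamp fraction as a
diagnostic — how often the raw logistic leaves its band). When the
cascade's colour and the model's predicted colour disagree — possible only
off-grid, near a boundary — the cascade is authoritative: `triage()` clamps
the model score into the cascade colour's band.

The specific percentage printed in the original system's worked example
(a yellow casualty at 74 %) depends on an unpublished fitted model and is
not reproducible; what the package guarantees instead, and tests, is band
membership on the whole labelled grid and monotonicity: moving any single
sign further from its reference interval, with the others held at
reference, never raises the chance.

### Off-grid audit

`audit_off_grid()` draws random grid cases and jitters every coordinate
uniformly within ±40 % of the gap to the neighbouring level, then compares
the model's predicted colour with the cascade label (1000 cases, seeded).
The 40 % default deliberately stays clear of the thin slab around each
threshold whose sub-cell position the 7200-point grid cannot resolve — no
learner trained on the grid can place the boundary more precisely than the
level spacing allows, so auditing inside that sliver measures grid
resolution, not model quality. At `margin = 0.5` the samples tile the
cells completely (agreement ≈ 0.94); at the default the suite requires
≥ 0.95.

## 4. Vitals extraction

The measurement chain emulates the wearable hub's processing, one
half-open window `[start, end)` at a time (default 10 s for HR/SBP/SpO~2~;
60 s trailing for RR, which needs a longer observation of a 0.1–0.5 Hz
signal). Sampling defaults: ECG 250 Hz, PPG 100 Hz, respiration 25 Hz,
acceleration 50 Hz.

* **R-peaks**: 5–15 Hz zero-phase Butterworth band-pass, squared energy,
  two-pass adaptive threshold (anchored at 0.3 × the median energy of the
  strongest beats), 250 ms refractory. Two clean-up rules matter at low
  SNR: a candidate within 360 ms of a ≥ 2× stronger predecessor is
  rejected as a T wave, and of any pair closer than 0.55 × the running
  median interval the weaker is dropped (a split interval betrays a noise
  spike). On 10 dB streams this keeps the HR error within a fraction of a
  beat per minute.
* **Pulse feet**: systolic peaks on the band-passed pulsatile component,
  then each foot is found by walking back from the steepest upslope until
  the smoothed derivative stops being positive, compensating the
  smoother's known onset smear. A plain argmin over the diastolic tail is
  biased tens of milliseconds early under noise — at the default
  calibration slope (−0.4 mmHg/ms) a 12 ms PAT bias is a 5 mmHg SBP error,
  so the fiducial choice is the accuracy-limiting step of cuffless
  pressure.
* **PAT/SBP**: for each R-peak, the first foot within (R, R + 600 ms];
  SBP = a · median(PAT) + b over the window (median for robustness to a
  mis-detected foot; at least 3 values required).
* **SpO~2~**: AC taken as the standard deviation of the windowed signal,
  DC as its mean, R the red/IR ratio of AC/DC, mapped through
  SpO~2~ = c₀ − c₁·R (defaults 110, 25) and clamped to [0, 100].
* **RR**: detrended, Hann-windowed, 8× zero-padded spectrum; dominant peak
  in 4–60 /min, required to exceed 5× the median band power (a flat or
  broadband window yields no estimate rather than a fabricated one).
* **Activity/posture**: MPA is the mean magnitude of 0.5 Hz high-passed
  acceleration; below 0.1 g posture is read from the gravity direction
  under the declared chest-sensor convention (x longitudinal → upright,
  +z anterior up → supine, −z → prone, y → lateral), otherwise "moving".
  The axis convention is a package convention — the hardware it emulates
  does not publish one.

Any channel that is missing, too short, or more than 20 % masked by
dropout in the window yields an absent sign; the triage layer then handles
the degraded mode. Extraction is deterministic for a fixed frame.

## 5. Synthetic physiology: what it emulates, what it does not

The generator produces multichannel streams from a segment timeline
(states: baseline, exertion, hemorrhage, respiratory_failure,
cardiac_arrest), with piecewise-linear target trajectories that ramp from
the previous segment's end toward state-specific endpoints (hemorrhage:
HR up to 150, SBP down to 75, SpO~2~ down to 88, RR up to 26 — a
progression that walks a casualty green → yellow → red). Waveforms are
template-based on verifiability grounds: Gaussian-bump QRS with a low
broad T wave, a gamma-shaped PPG pulse rising exactly at the encoded foot,
sinusoidal respiration, gravity-plus-burst acceleration. Additive Gaussian
noise, default 20 dB SNR per channel, seeded; seeds change the noise, never
the truth trajectories.

The physiologically meaningful couplings are embedded through the same
calibration used for extraction, inverted: foot times lag R-peaks by
PAT = (SBP − b)/a, and the red/IR amplitude ratio equals (c₀ − SpO~2~)/c₁
(the pulsatile component is zero-meaned onto a fixed DC level so the
windowed mean is identical in both wavelengths and the embedded ratio is
exact). Round-trip recovery on clean 60 s streams is tested to |HR| ≤ 2
bpm, |RR| ≤ 1 /min, |SpO~2~| ≤ 2 points, |SBP| ≤ 5 mmHg.

What passing these tests shows: the extraction chain is internally
consistent, unbiased on its own signal model, and robust to the modelled
noise and dropout. What it does not show: performance on real trauma
recordings — no motion artefact coupling into PPG, no baseline wander, no
arrhythmia, no autonomic HR variability, no probe-perfusion loss at low
pressure. The generator is a test harness with known truth, not a
hemodynamic model.

## 6. Telemetry and the casualty card

Frames are length-prefixed binary records — sync `0xAA55`, version, type,
16-bit wrapping sequence number, length-prefixed soldier id, payload,
CRC-16/CCITT-FALSE over everything after the sync marker, integers
big-endian. The format is a package declaration (the emulated system's
wire grammar is unpublished); CRC-16 was chosen for bit-exact testability,
and the suite verifies that every single-bit corruption of a frame is
detected. Decoding failures are classed conditions: `framing` (structure)
vs `integrity` (checksum).

Snapshot streaming emits one vitals frame per reporting period (default
10 s) with a seeded Bernoulli loss model standing in for jamming. The
receiver tags a soldier black after three silent periods — the same tag as
a missing heart-rate signal, because from the receiving side they are the
same event. Three periods is a declared default balancing false black tags
under ordinary loss against detection delay; it is configuration.

The casualty card is an append-only ledger: vitals, triage history
(automatic and manual) and free-text interventions, each entry
time-ordered, with out-of-order appends rejected rather than silently
reordered. Triage events propagate downstream only on colour change, so
the decision log stays sparse; the evacuation board is derivable from that
log alone, and its row order always equals `evacuation_order()`.

## 7. Numerical choices and degenerate inputs

* Windows are half-open `[start, end)`; timestamps are ms UTC throughout.
* A flatline channel yields zero beats / no RR estimate, not an error;
  windows shorter than the minimum (2 s ECG/ACC, 30 s RESP) or zero-length
  snapshot windows are validation errors.
* `hr_from_beats` needs ≥ 2 beats, `sbp_from_pat` ≥ 3 PAT values; below
  those the sign is absent, never extrapolated.
* Survival scores are integer percents; rounding happens once, after the
  logistic map, before clamping.
* Evacuation ties (same colour, same chance) break on earlier timestamp;
  casualties with no survival score sort after scored ones within their
  colour in standard mode.
* All randomness (noise, loss, training) flows from explicit seeds;
  reruns of a pipeline config are byte-identical.

## 8. Problem sizes used by the test suite

The suite exercises the defaults the package itself ships: the full 7200-
case training grid (fitting takes well under a minute), a 160 000-point
exhaustive cascade-vs-oracle grid, 1000-case off-grid audits, 60–300 s
synthetic scenarios at the default sampling rates, and exhaustive
single-bit corruption over an encoded frame. These sizes were chosen so
the complete suite documents the claimed properties while remaining quick
enough to run on every change.

## 9. Known limitations

* Thresholds are configuration defaults, not clinically validated values;
  the package computes no consciousness score and no composite early-
  warning score.
* The survival percentages are calibrated to band semantics, not to
  outcome data — between-band ordering is meaningful, the absolute number
  inherits the band definition.
* Chance-of-survival continuity across band boundaries is not guaranteed
  (the bands are disjoint by definition; the margin map is continuous
  within each class region).
* The SBP–PAT relation is linear with static per-soldier coefficients; no
  drift, posture or temperature compensation.
* The telemetry stack is in-process emulation — no transport, no
  encryption, no real radio behaviour.
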