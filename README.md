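# fieldtriage

Decision core for sensor-driven pre-hospital triage of combat casualties.
The package is written for engineers and researchers building medical
decision-support systems on top of body-worn sensors: it turns raw
multichannel biosignals (ECG, dual-wavelength PPG, respiration, 3-axis
acceleration) into windowed vital signs, runs a START-style rule cascade
that tags each casualty green / yellow / red / black (with a manual-only
blue tag), attaches a degraded-mode reliability score when sensors drop
out, and calibrates a two-stage large-margin classifier into ordinal
chance-of-survival bands. A seeded synthetic-physiology generator provides
casualty scenarios with known ground truth, so the whole chain is testable
end to end without any real recordings.

## The model

Each monitored sign *s* ∈ {RR, HR, SBP, SpO₂} has a per-soldier reference
interval [ref_lo, ref_hi] and critical thresholds (crit_lo, crit_hi; SpO₂
is one-sided). A measurement maps to a severity

    in_reference < out_of_reference < critical

and the cascade evaluates signs in priority order RR, HR, SBP, SpO₂ with an
upgrade-only rule (a later sign can raise but never lower the colour), so
the automatic colour is

    colour = max over available signs of severity(s)  →  {green, yellow, red}

with the typical defaults RR 9–20 /min, HR 50–110 bpm, SBP 100–180 mmHg,
SpO₂ ≥ 94 %. A missing heart-rate signal short-circuits to **black**
(communication loss or death — confirmation required on scene); any other
missing sign lowers the decision's **reliability** per a fixed table
(all four sensors 100 %, down to HR-only 50 %).

Systolic pressure is measured cufflessly from the pulse arrival time (PAT),
the delay between the ECG R-peak and the foot of the peripheral PPG pulse,
via a per-soldier linear calibration SBP = a·PAT + b (a < 0). SpO₂ uses
ratio-of-ratios pulse oximetry, SpO₂ = c₀ − c₁·R with
R = (AC/DC)_red / (AC/DC)_IR.

The **chance-of-survival function** is trained on a 7200-case grid covering
the four-dimensional sign space, labelled by the cascade: stage A (an
RBF-kernel SVM) separates red from not-red, stage B separates yellow from
green; the signed margin of the deciding machine is squashed through a
logistic map into the colour's band — red 1–50 %, yellow 51–99 %, green
exactly 100 %.

## Worked example

```r
library(fieldtriage)

prof  <- default_reference_profile("alpha-1")
grid  <- generate_case_grid()                 # 7200 cases
model <- train_survival_model(grid, seed = 42)

s <- vital_snapshot("alpha-1", timestamp = 0,
                    rr = 24, hr = 118, sbp = 96, spo2 = 93)
triage(s, prof, model = model)
#> <triage_decision> alpha-1 @ 0 ms: YELLOW (automatic), reliability 100%, survival 63%

# SpO2 sensor lost: same colour, reliability drops, survival is withheld
triage(vital_snapshot("alpha-1", 0, rr = 24, hr = 118, sbp = 96), prof, model = model)
#> <triage_decision> alpha-1 @ 0 ms: YELLOW (automatic), reliability 90%

# no heart-rate signal: black, needs on-scene confirmation
triage(vital_snapshot("alpha-1", 0, rr = 24, sbp = 96, spo2 = 93), prof, model = model)
#> <triage_decision> alpha-1 @ 0 ms: BLACK (automatic) [needs confirmation]
```

Every sign is mildly deranged, so the casualty is yellow at full
reliability with a 63 % calibrated chance of survival; the degraded
variants show the reliability table and the black rule in action.

A full end-to-end run (synthesise casualty biosignals → extract vitals →
triage → survival → casualty cards → evacuation board):

```r
cfg <- pipeline_config(
  soldiers  = list(list(id = "a1"), list(id = "a2"), list(id = "a3")),
  scenarios = list(
    a2 = list(list(duration_s = 60,  state = "baseline"),
              list(duration_s = 120, state = "hemorrhage")),
    a3 = list(list(duration_s = 90,  state = "exertion"))),
  seed = 11)
res <- run_pipeline(cfg, out_dir = "out")
res$board
#>   id  color survival_chance reliability              last_update needs_confirmation
#> 1 a2    red              34         100 1970-01-01T00:03:00.000Z              FALSE
#> 2 a3 yellow              60         100 1970-01-01T00:01:30.000Z              FALSE
#> 3 a1  green             100         100 1970-01-01T00:02:00.000Z              FALSE
```

The hemorrhaging soldier drifts green → yellow → red as heart rate climbs
and pressure/saturation fall, and tops the standard evacuation board; the
board, the JSONL decision log and the electronic casualty cards are written
under `out/`. The same commands are available from a shell via
`exec/fieldtriage run-pipeline --config cfg.yaml --out-dir out` and
`exec/fieldtriage report`.

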