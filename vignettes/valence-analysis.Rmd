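---
title: "Quantifying behavioral valence: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioral valence: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyvalence)
```

This vignette documents the models behind `flyvalence`, the parameters that
matter, the numerical and design choices made where the underlying assay
descriptions leave the implementation open, and what the synthetic
generators do and do not establish about real data.

## The arena and its coordinate conventions

The four-quadrant assay places ~20 flies in a circular arena (radius 50 mm)
whose quadrants are alternately illuminated in diagonal pairs. We fix the
arena center at the origin with the two light on/off borders along the
coordinate axes, so the distance of a point to the nearest border is simply
`min(|x|, |y|)`. Quadrants are labelled by coordinate signs such that
Q2 (−,+) and Q3 (+,−) form one diagonal pair and Q1 (+,+) and Q4 (−,−) the
other, matching the checkerboard illumination. Points exactly on an axis are
assigned to the positive side; this tie rule is arbitrary but deterministic,
and at 30 fps with continuous coordinates ties are measure-zero events.

The standard protocol is 120 s: darkness (0–30 s), Q2&Q3 lit (30–60 s),
darkness (60–90 s), Q1&Q4 lit (90–120 s). On the lit side, irradiance ramps
linearly from 3 µW/mm² at the border to a 34 µW/mm² plateau 10 mm in; the
dark side is modelled as 0 µW/mm². Real arenas show some light spill across
the border, but only the lit-side ramp is specified numerically, so the
model keeps the dark side at zero and treats the border value as the lit
side's limit.

Tracker input is strict: positions more than 1 mm outside the radius are
hard errors rather than clipped, because the most common cause is a
cm-vs-mm unit mistake that silent rescaling would hide. Missing frames are
allowed and reported; nothing is imputed.

## Preference indices

The per-frame quadrant preference is `(N_Q2&Q3 − N_Q1&Q4)/N` and the light
preference `(N_lit − N_unlit)/N`, counting only flies tracked in that frame
(untracked flies reduce `N`; frames with no flies are undefined, not zero).
The light preference index of a video averages the light preference over
the final 5 s of each light-on epoch and then averages the two windows,
unweighted — frames are equally spaced, so no weighting is needed. The
video (cohort) is the replicate unit; group statistics operate on per-video
indices.

## Choice-zone events

The choice zone is the ±5 mm band around a border, excluding a 10 mm
central disk where the two borders intersect (and where arenas typically
have an air hole), making "nearest border" ill-defined. An event opens at
the first in-zone frame entered from a contiguous out-of-band frame and
closes at the first out-of-band frame after it. Sides are read from the
illumination state of the positions just before entry and just after exit —
using the exit *position* rather than the entry border's sign keeps the
classification robust when a fly leaves the band around the central region.

Censoring removes events whose side labels would be unreliable: tracking
gaps at entry or exit, events straddling an illumination-epoch boundary,
events within a dark (or uniformly lit) epoch where lit/unlit labels do not
exist, and entries within the first 1 s of a light-on epoch, before the
light state the fly is responding to has been stable. Censored events are
listed and counted, never silently dropped, so exclusions remain auditable.

Two filters select genuine border approaches, mirroring standard practice
in this assay: the entry angle must lie in 45–135° and the fly must have
moved more than 5 mm (strictly) in the second before entry.

**Entry angle.** The heading at entry is estimated from the net
displacement over the 3 frames (0.1 s) before entry — long enough to
suppress single-frame jitter, short enough to stay local; the window is
configurable. The angle is measured against the border line
direction-aware: values in (0, 180) mean the fly faced the border (90° =
perpendicular), values in (180, 360) mean it was moving away from it.
A plain fold to [0, 180] cannot make that distinction, and flies entering
the band through its inner end (skirting the central exclusion disk) while
moving away from the border would then wrongly pass the facing filter; with
the direction-aware angle the 45–135° filter removes them naturally.

**Prior displacement** is net displacement (entry position minus the
position 1 s earlier), not path length — robust to jitter; a path-length
variant would only be larger, so the strict > 5 mm cut is conservative.

Each re-entry by the same fly counts as an independent trajectory, which is
the unit in which such assays report event counts (~100–400 per ~20-fly
video). The choice probability pools all retained events: the fraction
exiting to the illuminated side irrespective of entry side. By construction
it equals one minus the fraction exiting to the dark side.

## Kinematics

Speed is `‖p_t − p_{t−1}‖ × frame rate`; the heading is the direction of
the frame-to-frame displacement, and angular speed is the absolute heading
change per frame (wrapped to [0, 180°]) times the frame rate. Below
0.5 mm/s the displacement direction of a nearly stationary fly is dominated
by tracker jitter, so the heading — and hence angular speed — is set
undefined there (threshold configurable). Velocity heading is used rather
than body orientation because trajectory tables carry no posture
information; for forward-walking flies the two coincide. Frames following
tracking gaps are undefined. State-conditioned summaries pool frame-level
values by the fly's current quadrant illumination state, restricted to
light-on epochs, and report per-video means.

## Memory performance indices

All reciprocal designs share one sign convention: a positive performance
index always means behavior consistent with training (avoiding a punished
stimulus, approaching a rewarded one), so indices are comparable across
modalities. Each group's preference index is the normalized count
difference between its two options signed against that group's CS+; the
performance index is the mean of the two reciprocally trained groups, which
cancels exactly any innate stimulus bias common to both. The T-maze series
variant time-averages the per-frame index over the last 10 s of the 2-min
choice period before reciprocal averaging; the visual variant averages
per-frame blue/green preferences over the test and exposes, besides the
mean-of-reciprocals, the "difference between group preferences" convention
(exactly twice the mean) used by some descriptions of the same assay.
Flies that fail to choose are simply absent from the counts; whether to
include them is the caller's decision when building the count table.

## Sleep scoring

Sleep is any maximal run of ≥ 5 consecutive minutes with zero
beam-crossing counts — the standard single-beam DAM convention. Records
must contain whole days of 1-min bins; missing bins are errors, not
imputation targets. Daily sleep splits at the 12:12 light-dark boundary,
with bouts apportioned minute-by-minute across boundaries. The percent
sleep change compares the mean of the activation days (4–5) against the
last baseline day (3) — the days such designs display — and both choices
are configurable; it is computed per fly (flies with zero baseline sleep
are flagged undefined rather than producing infinities) and can be
aggregated either way. Waking activity (counts per awake minute) guards
against misreading hypoactivity as sleep, and a trailing ≥ 12 h of zeros
flags a likely dead fly for exclusion.

## Statistical procedures

The test of equal proportions and the Kruskal–Wallis omnibus test are the
standard `stats` implementations (continuity correction defaults to on only
for 2×2). Dunn's post-test versus a designated control is computed from
pooled ranks with the tie-corrected variance
`σ² = [N(N+1)/12 − Σ(t³−t)/(12(N−1))] (1/n_i + 1/n_c)`, with Šidák
family correction by default (Bonferroni available) — the correction family
is configuration because published analyses of these assays mix the two.
Correlation reports always include both Spearman's ρ and Pearson's r (plus
R²), because figure legends in this literature sometimes conflate the two
labels; reporting both removes the ambiguity.

## The synthetic generators

The generators exist to exercise and calibrate the analysis code; they are
statistical stand-ins for the data-generating process, not mechanistic
models of fly neurobiology.

**Arena cohorts** are correlated random walks: per-frame speeds from a
truncated normal (mean 10 mm/s, SD 3), Gaussian heading diffusion, smooth
inward steering within 5 mm of the wall, and hard containment at the
radius. Valence acts *only* at the border: on each choice-zone entry the
fly makes one Bernoulli decision — with probability |valence| it resolves
the entry toward its preferred side, reversing smoothly over ~0.3 s if
headed the wrong way and committing to the crossing (heading held until it
leaves the band) if headed the right way. Off-border kinematics are
untouched by valence; separate lit-quadrant multipliers on speed and
heading diffusion emulate sensory-driven kinematic phenotypes. This
separation encodes the design hypothesis the analysis is meant to detect:
preference expressed through border choice, not through steady-state speed
or turning. With the one-decision rule the dark-entry exit-to-light
fraction is `c + v(1−c)` for attractive and `c(1+v)` for aversive valence,
where `c` is the baseline crossing rate — strictly increasing in valence,
so panel monotonicity is a property of the mechanism, not of noise.

The heading-diffusion default (3000 deg²/s) was chosen so that a neutral
cohort's filtered crossing rate lands near 0.78, matching the ~0.75
observed for control genotypes in this assay class; the implied mean
angular speed (~250 deg/s) is brisk but within the range of walking flies
in small arenas. Decisions are only taken when a two-quadrant light state
is on and the fly is actually approaching the border; entries through the
ends of the band face no light choice and receive none.

**Activity records** are per-minute two-state Markov chains with light- and
phase-dependent transition probabilities; counts are zero while asleep and
Poisson (mean 2/min) while awake — awake zeros occur, as in real monitors.
Baseline parameters (sleep-onset 1/30 per light minute, 0.15 per dark
minute; waking 0.10 and 0.05) give ~600–700 min of daily sleep concentrated
in the dark phase, typical of female flies. A target percent sleep change
is imposed by replacing the activation-phase sleep-onset probabilities so
the stationary sleep occupancy scales by the target while the
sleep-to-wake probabilities — hence bout lengths and the 5-min-threshold
loss — stay fixed; the scored change then tracks the occupancy change, and
recovery days revert to baseline parameters.

**Reciprocal two-choice experiments** draw binomial counts with the favored
arm chosen at probability `0.5 + bias/2 ∓ delta/2`, the learning term's
sign set by the group's CS+; the constraint `|bias| + |delta| ≤ 1` keeps
probabilities valid. The expected performance index is exactly `delta`
regardless of `bias`, which is the cancellation property the reciprocal
design is for.

All generators run from a single integer seed and are byte-reproducible.

## What passing the synthetic checks does and does not show

The calibration suite (and `scripts/acceptance.R`) verifies, among other
things: exact agreement of event segmentation with a brute-force per-frame
scan on 100 simulated trajectories; exact agreement of bout detection with
a run-length oracle on 1000 random activity vectors plus day conservation;
a panel of 7 valences × 10 cohorts in which cohort-mean PI and choice
probability are almost perfectly rank-correlated and dark-entry exit
fractions rise strictly with valence; the absence of PI–kinematics
correlation unless a lit-speed multiplier imposes one (then recovered
within 10%); null-cohort symmetry; T-maze bias cancellation (|PI| < 0.02
at n = 10⁴) and learning recovery (0.30 ± 0.02); −40% sleep-change recovery
within 5 percentage points over 32 channels; and the closed-form identities
(Šidák 0.029701, squared two-proportion z, the 18.5 µW/mm² ramp midpoint,
Kruskal–Wallis type-I rate within [0.03, 0.07]).

These checks establish that the *analysis code* implements its definitions
correctly and recovers known effects from data with the assumed statistical
structure. They do not validate the generators against real flies: real
trajectories have pauses, grooming bouts, wall-following, identity swaps
and tracking noise the agent model omits; real sleep has circadian
structure beyond a binary light effect; real conditioning has
non-binomial group correlations. Conclusions about real data rest on the
correctness of the definitions, not on any behavioral realism of the
simulators.

## Problem sizes and determinism

Default calibration sizes — 20 flies × 120 s × 30 fps per cohort, 70-cohort
panels, 32 DAM channels × 7 days, 2000 null simulations — were chosen so
the full suite completes in a few minutes on one CPU while keeping Monte
Carlo error well inside each check's tolerance. Every stochastic component
takes an explicit integer seed, identical seeds give byte-identical
outputs, and `run_pipeline()` writes a provenance record (configuration
echo, seed, package version, input checksums) beside every result bundle.

## Known limitations

* Trajectories are consumed, not produced: no tracking, identity
  correction, or posture estimation.
* Angular speed uses velocity heading; backward walking or in-place
  rotation cannot be distinguished from forward turning without
  orientation data.
* Whether events spanning light transitions should be censored is an open
  call in the assay literature; we censor them (configurably via the
  schedule) and report the counts.
* The dark side of the arena is modelled as fully dark; measured spill
  below the ramp minimum is ignored.
* Sleep scoring implements the 5-min zero-count rule only; arousal
  thresholds, sleep latency and circadian periodograms are out of scope.
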