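# flyvalence

Behavioral-valence analysis for group assays of walking *Drosophila*:
four-quadrant optogenetic arenas, choice-zone trajectory classification,
reciprocal-design conditioning tests, and activity-monitor sleep scoring —
together with seeded synthetic generators so every stage of the pipeline can
be exercised and calibrated without raw video.

## Who this is for

Labs quantifying approach/avoidance in circular arenas where two diagonal
quadrant pairs are alternately illuminated (e.g. to activate
CsChrimson-expressing neurons), and anyone post-processing tracker output
(Ctrax, Fiji, or similar) into preference indices, border-choice statistics,
walking kinematics, memory performance indices, or DAM sleep summaries.

## The quantities it computes

**Quadrant and light preference.** With `N_q` flies counted per quadrant per
frame, the quadrant preference is `(N_Q2&Q3 − N_Q1&Q4) / N` and, during
light-on epochs, the light preference is `(N_lit − N_unlit) / N`. The light
preference index (PI) of a video averages the light preference over the
final 5 s of each light-on epoch (55–60 s and 115–120 s under the standard
0/30/60/90–120 s protocol) and then averages the two windows. PI ∈ [−1, 1];
positive = attraction to the illuminated quadrants.

**Choice-zone events.** The choice zone is the band within ±5 mm of a light
on/off border (outside a 10 mm central exclusion disk). Each visit is
classified as a *crossing* (exit side ≠ entry side) or *turn-around*, with
entry/exit sides given by the illumination state just before entry and just
after exit. Events are filtered to flies *facing* the border (entry angle
45–135°, 90° = perpendicular) that moved > 5 mm in the second before entry.
The *choice probability* is the fraction of retained events that exit to the
illuminated side, irrespective of entry side; per-side exit fractions carry
Wilson 95% intervals.

**Kinematics.** Frame-to-frame walking speed (mm/s) and angular speed
(deg/s, heading change of successive displacement vectors), pooled by the
fly's quadrant illumination state during light-on epochs.

**Memory scores.** Reciprocal-design performance indices for T-maze
olfactory tests (count tables or the last 10 s of a 2-min frame series),
visual (blue/green) arena tests, and Y-maze tests; reciprocal averaging
cancels innate stimulus bias.

**Sleep.** From 1-min DAM beam-crossing counts: sleep bouts (≥ 5 min of
zero counts), daily sleep with day/night split, cohort profiles (min/30 min),
percent sleep change of activation days (4–5) versus the baseline day (3),
waking activity, and a dead-channel guard.

**Statistics.** Test of equal proportions, Dunn–Šidák correction
`1 − (1 − p)^m`, Kruskal–Wallis with Dunn's post-test against a control,
and paired Spearman/Pearson correlation reports.

## Worked example

```r
library(flyvalence)

# a light-averse synthetic cohort: 20 flies, 120 s, 30 fps
traj <- simulate_arena_cohort(agent_params(valence = -0.8, seed = 7))
res  <- analyze_arena_cohort(traj)

round(res$pi, 3)
#> [1] -0.722          # strong avoidance of the illuminated quadrants
round(res$choice_probability, 3)
#> [1] 0.122           # few filtered border visits end on the lit side
res$exit_fractions
#>   entry_side  n n_exit_lit  fraction   ci_lower  ci_upper
#> 1      unlit 89         11 0.1235955 0.07043517 0.2079045
#> 2        lit 26          3 0.1153846 0.04003245 0.2897590
```

A fly cohort with valence −0.8 turns around in ~80% of its approaches to
the light: only 12% of dark-side entries cross into the light (a neutral
cohort crosses at ~0.78), and flies that enter from the lit side rarely turn
back toward it. The same functions accept real tracker output via
`read_trajectories("traj.csv")`.

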