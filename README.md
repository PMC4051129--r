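# seqviolate

Tools for visuomotor sequence-learning ERP experiments: constrained
motion-trajectory stimuli with 180° "flip" deviants, stylus-reproduction
scoring by directional error, an ERP pipeline, spatiotemporal
cluster-based permutation statistics, and amplitude-normalized
topography comparison — plus a synthetic-data generator so the whole
chain runs and is tested without any recorded data.

## The problem

In sequence-learning experiments, observers watch a disk trace a path of
five connected 1 cm motion segments (2 cm/s, 0.40 s pauses at corners)
and reproduce it from memory with a stylus; each path repeats four
times, and occasionally the final segment of the last presentation is
flipped to its exact 180° opposite, violating a freshly learned
prediction. Analyzing the accompanying EEG raises three recurring
methodological problems this package solves:

1. **Stimuli** — paths must satisfy hard geometric constraints (corner
   turns in [30°, 150°], no intersections, half-segment clearance
   between non-adjacent segments, display bounds), and sessions need
   block-randomized Congruent/Flip schedules (per session: 2 warm-up +
   20 Congruent + 10 Flip).
2. **Behavior** — reproductions must be segmented (by pauses and
   direction changes), validated (exactly five segments), and scored by
   directional error
   `angular_error(a, b) = min(|a−b| mod 360, 360 − |a−b| mod 360)`,
   then summarized with repeated-measures ANOVA (Greenhouse–Geisser
   corrected) and Morey within-subject error bars.
3. **EEG** — condition ERPs compared across 129 channels × 200 time
   points need family-wise error control without pre-selected windows:
   per-cell paired *t* maps, adjacency-constrained clusters at
   |t| > t₍crit₎, summed-*t* cluster mass, and a max-statistic null from
   1000 within-subject label permutations,
   p = (1 + #{null ≥ |mass|}) / (n_perm + 1).
   Topography differences are tested after dividing each condition's
   windowed scalp map by its root-mean-square electrode voltage.

## Worked example

```r
library(seqviolate)

# a constrained 5-segment stimulus and its deviant
s <- generate_sequence(7)
s$directions
#> 356.0 278.3 239.9 114.9 172.6        # degrees, CCW from +x
corner_turns(s)
#> 77.7 38.4 125.0 57.8                 # all inside [30, 150]
f <- apply_flip(s)                      # final segment 172.6 -> 352.6
angular_error(s$directions[5], f$directions[5])
#> 180

# simulated reproductions, scored by directional error
model <- behavior_model()               # angular noise 25,15,13,12 deg
tr <- simulate_reproduction(s, model, presentation = 1, rng_seed = 11)
score_reproduction(segment_trace(tr, expected_segments = 5), s)$errors
#> 14.8 34.1 33.1 25.1 38.5             # first presentation: large errors
tr4 <- simulate_reproduction(s, model, presentation = 4, rng_seed = 11)
score_reproduction(segment_trace(tr4, expected_segments = 5), s)$errors
#> 7.1 16.4 15.9 12.0 18.5              # fourth: learning has occurred

# cluster-based permutation test on a simulated 12-subject cohort
mont <- default_montage("hd129")
spec <- default_effect_spec(mont)       # P3a-like deviant enhancement + graded P3b-like
es   <- simulate_epochs(mont, spec, subjects = 12, epochs_per_condition = 32,
                        rng_seed = 1, conditions = c("deviant", "familiar"))
dev  <- subject_condition_means(es, "deviant")
fam  <- subject_condition_means(es, "familiar")
res  <- cluster_permutation_test(dev, fam, montage = mont,
                                 config = cluster_config(alpha = 0.01,
                                                         n_perm = 1000, seed = 1))
res$t_crit
#> 3.106                                # two-tailed t quantile, alpha=0.01, df=11
res$clusters[[1]][c("sign", "mass", "p_value")]
#> positive, 1740.9, p = 0.001          # 365 cells, 368-460 ms, 42 channels
```

The winning positive cluster sits over the fronto-central sensors in
the late window — it recovers the injected deviant-specific positivity;
its permutation p is the fraction of the 1000-permutation max-mass null
(plus one) at or above the observed mass.

A complete simulated analysis — stimuli, reproductions, scoring, ERPs,
cluster test, topography ANOVA, and a hash manifest — runs from one
config:

```r
res <- run_pipeline(run_config(seed = 1, out_dir = "run1"))
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's design-level reference
quantities from scratch with the installed package — it generates 2,500
trajectories (10,000 corners) and reports the minimum unsigned corner
turn, and applies a flip and reports the angular error at the flipped
segment — writing them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

| Area | Functions |
| --- | --- |
| Stimuli | `generate_sequence`, `validate_sequence`, `apply_flip`, `build_schedule`, `sequence_to_json` |
| Scoring | `segment_trace`, `fit_segment_direction`, `angular_error`, `score_reproduction`, `morey_within_subject_se` |
| ERP | `average_reference`, `bandpass`, `extract_epochs`, `reject_artifacts`, `condition_average`, `grand_average` |
| Cluster stats | `critical_t`, `paired_tmap`, `build_adjacency`, `find_clusters`, `cluster_permutation_test` |
| Topography | `rms_normalize`, `window_mean`, `rm_anova`, `posthoc_paired_t` |
| Synthetic data | `behavior_model`, `simulate_reproduction`, `erp_effect_spec`, `simulate_epochs`, `default_montage`, `component_support` |
| Orchestration | `run_config`, `run_pipeline` |

The methods vignette (`vignettes/seqviolate-methods.Rmd`) documents the
model assumptions, the defaults and why, the numerical conventions, and
known limitations.
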