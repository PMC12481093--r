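# gridnav

Model-based analysis of goal-directed navigation in grid worlds.

## The problem

In navigation experiments where participants steer through a maze to reach
an ordered sequence of goal locations, raw behaviour cannot say *why*
performance differs: a slow navigator may steer poorly (motor skill) or
pursue the goals less effectively (cognitive strategy). `gridnav` is for
researchers who want to separate the two. It implements:

* a grid-world Markov decision process: occupancy-grid maps, 8 compass
  actions with a corner-cut rule, exact line-of-sight visibility, and
  geodesic shortest paths (orthogonal cost 1, diagonal `sqrt(2)`);
* four navigation policy families, all softmax with inverse temperature
  `beta`:
  - **visibility-based** — logits `beta * n(s, a)`, where `n(s, a)` counts
    the free cells visible in action `a`'s 45-degree bin;
  - **goal-directed** (one per goal `g_i`) — logits `-beta * d(s'(a), g_i)`
    with geodesic `d`, a noisy shortest-path follower;
  - **mixture** — `gamma * GD + (1 - gamma) * Vis`; the weight `gamma` is
    the trajectory's *goal-directedness* and `2 * gamma - 1` its *relative
    goal-directedness*;
  - **sequencing-error** — goal-directed navigation whose next target is
    the correct next goal only with probability `p`;
* maximum-likelihood fitting (`LL(beta) = sum_t log pi(a_t | s_t)` by
  bounded Brent search; joint mixture fitting over
  `(beta_GD, beta_Vis, gamma)`), segment-wise model comparison against the
  1/8 chance line, and an age-cohort slope table;
* trajectory preprocessing (16-to-8 orientation reduction, shortest-path
  interpolation of non-adjacent samples, goal segmentation) and
  behavioural metrics (normalized time `t/t*`, speed, angular velocity,
  goal exposedness, online disclosure, tortuosity);
* the statistical layer: a bootstrap test on
  `delta = R2_joint - R2_single` (does the cognitive variable predict
  navigation time beyond the motor variable?), the biweight
  midcorrelation, and Pearson with Fisher-z intervals;
* a synthetic age-structured cohort generator with known ground truth,
  used to validate every stage end to end.

## Worked example

```r
library(gridnav)

map <- read_map(system.file("extdata", "example-level.map", package = "gridnav"))
map
#> <grid_map 'example-level.map'> 7 x 9, 52 free cells, 3 goal(s)

# simulate a goal-directed agent and score every candidate model on it
tr <- rollout(map, list(family = "gd", beta = 3), seed = 7)
sc <- score_trajectory(tr, map)
sc$segment_liks[, c("segment", "model", "avg_lik")]
#>    segment model   avg_lik
#> 1        1   vis 0.2756685
#> 2        1   gd1 0.3226034
#> 3        1   gd2 0.2558700
#> 4        1   gd3 0.3153618
#> 5        2   vis 0.1609755
#> 6        2   gd1 0.1242215
#> 7        2   gd2 0.1789883
#> 8        2   gd3 0.1245615
#> 9        3   vis 0.2330533
#> 10       3   gd1 0.2470446
#> 11       3   gd2 0.2206457
#> 12       3   gd3 0.3037308

# recover the goal-directedness weight of a mixture agent from 10 runs
segs <- list()
for (s in 1:10) {
  m <- rollout(map, list(family = "mixture", beta_gd = 3, beta_vis = 3,
                         gamma = 0.8), seed = 100 + s, t_max = 300)
  segs <- c(segs, rollout_segments(m))
}
fit_mixture(segs, map)
#> <nav_fit mixture> beta* = NA, gamma* = 0.878, LL = -172.16 over 252 steps (avg lik 0.6340)
```

In every segment the goal-directed model for that segment's goal scores
highest — above the 1/8 = 0.125 chance line — identifying the goal the
agent was actually pursuing, and the jointly fitted mixture weight
(`gamma* = 0.878`) recovers the generating goal-directedness (0.8) from
252 pooled steps.

The full synthetic pipeline (cohort simulation, fitting, comparison
tables, age slopes, bootstrap separability test) runs with:

```r
res <- run_pipeline(pipeline_config(n_participants = 50, seed = 1,
                                    out_dir = "out"))
res$delta_test
```

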