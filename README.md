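# groupdelim

Delimiting *groups* of animals observed in the field — and deriving the
threshold distances those delimitations need from data rather than
convention.

## The problem

In studies of social animals such as delphinids, the group is the sampling
unit: abundance, behavior and social-structure data are collected per group.
Yet operational group definitions vary widely (10 m chain rules, 100 m
fixed-point rules, focal radii, body-length multiples), are frequently
borrowed across species without justification, and directly shape the data: a
10 m chain rule and a 25 m focal rule applied to the same animals yield
different group sizes, compositions and association records. `groupdelim`
implements, for anyone who delimits groups from positional snapshots:

1. **The operational rules** in common field use, applied to *scenes*
   (instantaneous snapshots of individual positions, in planar metres):
   - *chain rule* — groups are connected components of the graph linking any
     pair within a threshold distance `d` (single-linkage clustering cut at
     `d`): `chain_rule_partition()`;
   - *behavior-adaptive chain rule* — a per-behavioral-state threshold
     `d_s`, with mixed-state pairs linked at `max(d_s, d_t)`:
     `adaptive_chain_partition()`;
   - *focal-individual rule* (all within `r` of a focal animal, no chaining)
     and *fixed-point rule* (all within `r` of, e.g., the research vessel):
     `focal_rule_group()`, `fixed_point_rule_group()`;
   - the unit taxonomy: *singleton* (1 individual), *group* (≥ 2),
     *sighting* (all units together): `classify_units()`.

2. **A standardized, data-driven procedure for choosing the threshold.**
   For every individual in a scene, measure the distance to its nearest
   neighbor in a constant direction (e.g. due north) —
   `directional_nn_distances()`. Pooled over enough scenes
   (`pool_distances()`), these distances are multimodal whenever grouping
   exists: a within-group mode at metres and a between-group mode at
   hundreds of metres. A Gaussian kernel density estimate on the log scale
   (`estimate_density()`) and its antimodes — interior minima of the density
   where the gradient changes sign, filtered by relative prominence and an
   absolute depth floor (`find_cutoffs()`) — give the naturally occurring
   cutoff distances. The first cutoff is a biologically grounded chain-rule
   threshold; multiple cutoffs mark nested organizational levels (subgroup /
   group / supergroup); per-state estimation (`stratified_thresholds()`)
   yields behavior-specific thresholds; `bootstrap_cutoff_interval()`
   quantifies their stability.

3. **A hierarchical scene simulator** (`simulate_scene()`): Thomas-style
   Gaussian clusters with behavior-dependent spread, optional supergroup
   nesting and observer detection truncation, with ground-truth labels — so
   the whole procedure can be validated in silico
   (`threshold_recovery_experiment()`, `partition_agreement()`,
   `compare_rules()`).

## Worked example

Six resting dolphins on a line: five about 1 m apart, a sixth 20 m away from
the nearest. A 10 m chain rule separates the straggler:

```r
library(groupdelim)
sc <- scene(sprintf("d%d", 1:6), x = c(0, 1, 2, 3, 4, 24), y = rep(0, 6),
            state = "rest", scene_id = "survey_017")
classify_units(chain_rule_partition(sc, 10))
#> <sighting> survey_017: 1 group(s) (sizes 5) + 1 singleton(s), 6 individuals
```

The full data-driven workflow on simulated surveys — 10 snapshots of 5 tight
groups (spread 2 m) whose centers are at least 200 m apart:

```r
cfg <- simulation_config(window = c(0, 1000, 0, 1000), n_groups = 5,
                         group_size = list(type = "fixed", size = 6),
                         spread_by_state = c(travel = 2),
                         min_center_separation = 200)
res <- run_pipeline(sim_config = cfg, n_scenes = 10, seed = 1)
res
#> <pipeline_result> 10 scene(s), 290 pooled NN distance(s)
#>   definition: chain rule at 39.12 m
res$estimate
#> <threshold_estimate> n = 290
#>   cutoffs (m): 39.12  [prominence 1]
#>   modes (m): 1.996, 330.4
```

The pooled directional NN distances are bimodal — a within-group mode near
2 m and a between-group mode near 330 m — and the single antimode at ~39 m
becomes the chain-rule threshold of an explicit, machine-readable *definition
statement* (`res$definition`, recording rule, threshold, seed, bandwidth,
scale and prominence). Any threshold inside that valley delimits these scenes
identically; scoring against the simulation truth:

```r
partition_agreement(res$partitions[[1]],
  with(simulate_scene(cfg, seed = 1, scene_id = "sim001")$truth,
       setNames(group_label, individual_id)))
#> [1] 1
```

an adjusted Rand index of 1 — the recovered definition reproduces the
generating groups exactly.

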