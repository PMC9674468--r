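---
title: "Delimiting animal groups from positional snapshots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting animal groups from positional snapshots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupdelim)
```

## The model of an observation

`groupdelim` treats a field observation as a *scene*: an instantaneous
snapshot of individuals with planar coordinates in metres, each optionally
carrying a behavioral state and a body length. Scenes are the sampling units
of group-level field research — distinct from *social units*, which are
inferred from association patterns across many sightings and are outside this
package's scope. All geometry is Euclidean in the plane. Geographic input is
supported through a local equirectangular projection about a reference point
(spherical Earth, radius 6371 km), adequate because a visually surveyed scene
spans at most a few kilometres; geodesic computations and 3-D (depth-aware)
distances are deliberately not modelled.

## Delimitation rules

Four operational rules convert a scene into units:

* **Chain rule.** Two individuals are linked when their distance is at most a
  threshold `d` (inclusive: "within 10 m" reads as `<= 10`); groups are
  connected components of the link graph. This is exactly single-linkage
  clustering cut at height `d`. Inclusive comparison makes boundary ties
  deterministic. Component labels are assigned by ascending minimum member
  identifier, so output is reproducible regardless of row order.
* **Adaptive chain rule.** A threshold per behavioral state. For a pair in
  states `s` and `t` the edge threshold is `max(d_s, d_t)` — the
  grouping-conservative choice. The alternative (`min`) can split a spatially
  contiguous cluster whose members happen to differ in momentary behavior,
  e.g. a resting cluster with two socializing animals inside it; we consider
  that outcome biologically wrong for a *sampling* unit, whose membership
  should be driven by spatial cohesion. Behavior therefore enters only
  through its effect on spacing — same-behavior or same-heading requirements
  are not membership predicates here, since such criteria are subjective and
  rarely quantified.
* **Focal-individual rule** and **fixed-point rule.** Radius filters around a
  focal animal or a fixed location, with no chaining. They return member
  sets; `members_to_partition()` embeds a member set in a whole-scene
  partition (members one component, everyone else singletons) so radius rules
  can be compared with chain rules by the same agreement statistic.
* **Unit taxonomy.** A component of one individual is a *singleton*, of two
  or more a *group*; the whole observation is the *sighting*. A single
  individual is never a group, but singletons are counted and reported so
  they can enter analyses (dropping them biases group-size and density
  estimates).

The chain seed is irrelevant: connected components are seed-independent, so
"start from the individual nearest the vessel" is presentation, not
semantics.

## The directional nearest-neighbor measurement

The threshold a chain rule needs should mark a real discontinuity in how the
animals space themselves. The measurement underlying the estimate is, for
each individual in a scene, the full Euclidean distance to the nearest other
individual lying strictly further along a fixed compass bearing (north by
default). Compared with plain nearest-neighbor distances, the directional
constraint preserves the between-group scale in the sample: the nearest
northerly neighbor of a group's northernmost member belongs to the *next*
group, so the pooled distribution carries both within- and between-group
distances rather than only minima.

Ties in the along-bearing coordinate are broken by the perpendicular
coordinate, then by identifier, making "further along the bearing" a strict
total order: no individual can be its own neighbor, results are deterministic,
and a generic `n`-point scene yields exactly `n - 1` records (the
along-bearing-maximal individual yields none). The distance recorded is the
full Euclidean distance, not its along-bearing component. Distances can be
expressed in body lengths by dividing by the mean body length of the pair
(when only one length is known, it is used alone); this is a display and
normalization option only — all internal thresholds are metres. Whether to
measure per snapshot or pooled over a focal follow is left to the caller: the
geometry layer computes per scene, and pooling is an explicit separate step.

## Threshold estimation

Pooled directional NN distances are strictly positive and right-skewed, with
modes that can sit three orders of magnitude apart (metres within groups,
kilometres between supergroups). The analysis therefore defaults to the
logarithmic scale, where all scales receive comparable resolution; a linear
scale is available by flag. The density is a Gaussian kernel estimate
(`stats::density`) with Silverman's rule-of-thumb bandwidth (`bw.nrd0`) on
the analysis scale by default, Sheather–Jones (`bw.SJ`) or a numeric
bandwidth on request, evaluated on a 512-point grid spanning the data ± 3
bandwidths (clipped at zero on the linear scale) and renormalized over the
grid so it integrates to 1. Zero distances are rejected with an error:
coincident surfacing positions indicate a data problem upstream, not a
grouping signal. Samples under 30 distances are processed but flagged
`unreliable` and warned about — a fixed floor is more transparent than a
silent failure, though what counts as "sufficient" sampling ultimately
depends on the population.

**Cutoffs** are the interior local minima (antimodes) of the curve — grid
points where the numerical gradient changes sign from negative to positive —
retained when they pass two floors, and otherwise merged away (the shallower
flanking mode is absorbed and the search repeats):

* *relative prominence* ≥ `min_prominence` (default 0.10): the drop from the
  lower flanking mode to the antimode, divided by that flanking mode's
  height;
* *absolute depth* ≥ `min_depth` (default 0.01): the same drop expressed as a
  fraction of the global density maximum.

The second floor exists because the first is insufficient on its own: a
single outlying distance raises a minuscule kernel bump in a tail, and the
valley beside it has relative prominence near 1 while descending through
almost no density. Requiring the valley to descend at least 1% of the peak
density removes these artifacts without touching genuine between-scale
valleys, which in clustered data descend to near zero. Both defaults are
recorded in every output. A unimodal curve yields an empty cutoff list — "no
natural cutoff" is a valid, explicitly reported outcome, expected when the
animals are not spatially clustered at the sampled scales.

Cutoffs are reported ascending, back-transformed to metres, interleaved with
the retained modes. Ascending cutoffs map onto nested unit terms — the first
delimits the finest level (e.g. subgroup), the second the next (group), the
third supergroup — purely as a labelling convention. When one threshold must
be chosen among several cutoffs (the end-to-end pipeline, the recovery
experiment, stratified comparisons), `primary_cutoff()` selects by absolute
valley depth, not relative prominence, for the same noise-robustness reason;
with clean two-scale structure the two criteria agree. Which cutoff is "the"
group threshold when more levels appear than expected is a judgement the
package does not make for you.

**Stratification.** With behavioral states attached, cutoff detection runs
independently per state and on the pooled sample, and both are reported;
strata under 30 distances are skipped with a warning. Per-state cutoffs feed
`adaptive_chain_partition()` directly. **Stability.** A nonparametric
bootstrap over the pooled distances rates each cutoff with a 2.5/97.5
percentile interval (replicate cutoffs matched to point-estimate cutoffs by
nearest log-distance) and reports the distribution of cutoff counts across
replicates — a direct diagnostic of how often the inferred number of
organizational levels survives resampling.

Every stochastic operation takes an explicit integer seed; the package sets
no hidden global state.

## The scene simulator

The generator is a Thomas-process-style hierarchical cluster model: group
centers uniform in a rectangular window subject to a minimum separation
(rejection sampling with bounded retries, erroring with advice when
unsatisfiable); a group size drawn per group (zero-truncated Poisson by
default, fixed or user-supplied alternatives); a behavioral state drawn per
group; members placed as isotropic Gaussian offsets with state-dependent
spread σ. With nesting enabled, group centers are Gaussian offsets around
supergroup centers, and the minimum separation applies to supergroup centers.
Isotropic Gaussian clusters were chosen because they make within-group
distance distributions tractable (the displacement between two members is
N(0, 2σ²I), so pair distances are Rayleigh with scale σ√2), giving analytic
anchors for test oracles. The state is assigned per group, not per
individual, so "group behavior" is well defined in the truth labels;
mixed-state spatial clusters are still reachable as supergroups of
different-state groups.

Members are deliberately **not clipped** to the window — truncating positions
would bias nearest-neighbor distances near the border — while the window is
recorded on the scene for border-aware analyses. Detection limits are
modelled as a radius filter around an observer (`apply_detection_limit()`),
reporting the retained fraction.

What the simulator does *not* emulate: movement and surfacing asynchrony
(a real survey samples individuals at slightly different instants),
attraction–repulsion within groups (real spacing is more regular than
Gaussian), observation error in positions, and fission–fusion over time.
Passing tests therefore demonstrate that the estimation machinery recovers
known structure from idealized snapshots, not that any particular species
exhibits such structure.

`simulate_paired_cohesion_scenes()` provides the canonical cohesion
contrast as fixed collinear coordinates: five resting individuals 1 m apart
plus one 20 m away (`x = 0..4, 24`), and five foraging individuals 25 m
apart plus one 20 m from the nearest (`x = 0, 25, ..., 120`). A 10 m chain
gets the first scene right and shatters the second; a 50 m chain does the
reverse — the argument, in two scenes, for behavior-dependent thresholds. A
stochastic variant jitters the coordinates (sd 10% of nominal spacing) for
sensitivity checks.

## Evaluation

Partition agreement uses the adjusted Rand index computed from pair-confusion
counts — the standard chance-corrected pair-counting statistic; when the
adjustment denominator vanishes (e.g. both partitions all singletons) the
score is 1 for identical partitions and 0 otherwise.
`threshold_recovery_experiment()` runs the full loop — simulate, measure,
pool, estimate, delimit at the primary cutoff, score against truth — and
reports detection rate, agreement, and error against an analytic reference
cutoff: the antimode, located by dense numerical scan, of a surrogate mixture
of Rayleigh(σ√2) within-group components (weight `(m − 1)/m` for mean group
size `m`) and a Rayleigh at the typical nearest-center spacing. This
surrogate is independent of the kernel-density pipeline. One caveat read off
directly from the geometry: when separation vastly exceeds spread, the
density between the modes is essentially zero over a wide interval, so the
*location* of the estimated cutoff within that dead zone is arbitrary — the
relative error against the reference can be large while every partition it
produces is exactly right. Detection rate and partition agreement are the
operative quality measures; the error statistics qualify the cutoff only when
the valley is narrow.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script exercise: the canonical
cohesion scenes; exact brute-force equivalence of all four rules on 200
random scenes (n ≤ 20); refinement monotonicity over a 50-point threshold
grid on 20 scenes; cutoff recovery on a balanced lognormal mixture
(log-means 0 and 3.2, σ = 0.35, n = 5000, 50 seeds) against the analytic
antimode; the multi-level signature with member σ = 2 m, within-supergroup
center σ = 60 m and ≥ 1500 m supergroup spacing (12 groups of 6, 10 scenes
per seed, 50 seeds); end-to-end recovery with 5 groups of 6 at σ = 2 m and
≥ 200 m separation (6 scenes per seed, 50 seeds); and stratified ordering
with rest σ = 1 m vs forage σ = 25 m at equal ≥ 400 m spacing (10 groups of
6, 6 scenes per seed, 20 seeds). These sizes were chosen as the smallest
that clearly express each regime (scale separation, nesting, stratification)
while keeping a full run fast on a laptop.

## Known limitations

* Equirectangular projection degrades beyond ~1° from the reference
  (a warning is raised, the computation proceeds).
* Kernel antimode locations inherit bandwidth bias; with Silverman's rule on
  strongly multimodal samples the bandwidth is conservative (oversmoothed),
  which widens valleys but can, in principle, merge close levels. `bw = "SJ"`
  is available when levels are suspected to sit within a factor of ~3 of each
  other.
* The bootstrap resamples distances as exchangeable; distances from the same
  scene are mildly dependent, so intervals are slightly narrow.
* No border correction is applied to directional NN distances; the survey
  window is recorded so users can restrict sources to an inner buffer.
* Temporal criteria (persistence, fission–fusion) and interaction-based
  membership are out of scope by design.
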