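# flyconform

Trajectory analysis of social conformity in groups of walking flies.

Many fly species aggregate passively on shared food sources, forming
single- and mixed-species groups. Within such groups, a fly's decision to
start or stop walking follows the motion it can see: when neighbors move,
the focal fly tends to move. flyconform quantifies that conformity from
per-individual 2D trajectories recorded in a circular arena (24 flies,
140 mm, positions every 0.5 s), at three levels — the individual's
sensitivity to its visual surroundings, the species-level change of
activity between single- and mixed-species groups, and the group-level
convergence of two species' activity when mixed.

## The model in brief

For focal fly *f* at frame *t*, the **visual cue** sums the motion of every
other fly *i* in *f*'s forward 180° sector, weighted by apparent angular
size:

    C_f(t) = Σ_i  v_i(t) · 2·arctan( w / (2·d_fi(t)) )

with *w* = 3.0 mm (body major axis) and d the pair distance. Cues are
zero-offset, log-transformed and z-scored within species. Speed series are
segmented into walking/stationary states (threshold 2 mm/s, 1 s minimum
bout) and the transition-adjacent frames labeled **walk** / **stop**, with
the remaining frames **walking** / **stay**. Conformity shows up as:

* higher cue at *walk* than *stay* frames (neighbor motion recruits the
  focal into motion) — tested by a sign-flip permutation contrast on
  per-individual means;
* a positive slope of speed at *t*+0.5 s on the standardized cue at *t*
  (lagged OLS per individual — the **sensitivity**);
* a species' mean speed shifting from its single-group baseline when mixed
  (**species-level conformity**, strain-matched relative change), and the
  interspecific speed difference shrinking in mixed groups (**group-level
  conformity**, Δ_mixed < Δ_single).

An agent-based simulator generates ground-truth recordings: two-state
Markov agents whose walk/stop transition log-odds are coupled to their own
visual cue through a logistic link (coupling β = ground-truth conformity),
with lognormal walking speeds, specular wall reflection, and bit-exact
determinism under a seed. The whole pipeline is validated by parameter
recovery on these simulations.

## Worked example

Simulate a mixed group of a slow and a fast species, both coupled to the
cue, and run the full analysis:

```r
library(flyconform)

slow <- species_params("slow", walk_speed_mu_mm_s = 1.5,
                       coupling_beta = 1, stop_coupling = 0.3)
fast <- species_params("fast", walk_speed_mu_mm_s = 5,
                       coupling_beta = 1, stop_coupling = 0.3)

recs <- list(
  simulate_group(sim_params(slow, n_frames = 1200, seed = 1,
                            replicate_id = "single_slow")),
  simulate_group(sim_params(fast, n_frames = 1200, seed = 2,
                            replicate_id = "single_fast")),
  simulate_group(sim_params(slow, fast, n_frames = 1200, seed = 3,
                            replicate_id = "mixed")))

bundle <- run_pipeline(recs, run_config(seed = 1))
summarize_report(bundle)
```

```
== flyconform report summary ==
recordings: 3 (single_slow single, single_fast single, mixed mixed)
-- mean locomotive speed (mm/s, mean of individual means) --
  fast [mixed]: 1.726
  slow [mixed]: 0.614
  fast [single]: 1.861
  slow [single]: 0.476
-- group-level conformity --
  fast:slow: delta single 1.385 -> mixed 1.112 (ratio 0.803, p=0.0040)  [convergence]
-- species-level conformity (rate of change) --
  fast:slow fast [s1]: -0.073
  fast:slow slow [s1]: +0.289
-- sensitivity to visual cue (slope mm/s per sd) --
  fast / mixed: mean +0.5659 (n=12, CI 0.4738..0.6578)
  fast / single: mean +0.4216 (n=24, CI 0.3449..0.4926)
  slow / mixed: mean +0.0986 (n=12, CI 0.0530..0.1386)
  slow / single: mean +0.1478 (n=24, CI 0.1236..0.1724)
```

Reading the output: the two species differ strongly in single groups
(means of per-individual mean speeds); in the mixed arena the slow species
speeds up (+0.289) and the fast one slows down (−0.073) — the signed rates
of change — the interspecific difference shrinks (ratio 0.803 with a
significant reduction: convergence), and every stratum has a positive mean
sensitivity slope (mm/s per sd of cue, with bootstrap CIs).

## Analysis scripts

The numbered drivers under `analysis/` rebuild the package's own study
from scratch: `01_simulate.R` writes a panel of synthetic recordings (four
species spanning a ~10× speed range, single and host-centered mixed
groups) under `results/recordings/`; `02_pipeline_report.R` runs the full
analysis over the panel and writes the report tables and a text summary
under `results/`; `03_parameter_recovery.R` runs desk-scale
parameter-recovery studies.

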