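---
title: "Quantifying behavioral conformity in fly groups: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioral conformity in fly groups: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

flyconform quantifies social conformity in groups of walking flies from
per-individual 2D trajectories recorded in a circular arena. This vignette
is the package's account of the science: the cue model and its assumptions,
the event and conformity definitions, the generative model behind the
synthetic arena, the numerical choices, and what the validation studies do
and do not establish.

## The measurement problem

A group of 24 flies walks in a 140 mm circular arena; positions are sampled
every 0.5 s, and the final 30 min of a 60 min recording are analyzed (the
first half is acclimation). Flies are visual animals: when neighbors start
moving, a focal fly tends to start moving too. The package asks three
nested questions:

1. **Individual level** — how strongly does a fly's walking speed follow
   the visual motion it can see (its *sensitivity*)?
2. **Species level** — how much does a species' mean speed shift from
   single-species to mixed-species groups (its *conformity rate*)?
3. **Group level** — does mixing two species shrink the difference between
   their mean speeds (*convergence*)?

## The visual cue

For focal individual $f$ at frame $t$, the raw cue sums the motion of every
other individual $i$ in $f$'s forward 180° sector, weighted by its apparent
angular size:

$$
C_f(t) \;=\; \sum_{i \ne f,\; i \in \text{sector}(f)}
  v_i(t) \cdot 2\arctan\!\left(\frac{w}{2\,d_{fi}(t)}\right),
$$

where $v_i$ is individual $i$'s speed (mm/s), $d_{fi}$ the pair distance
(mm), and $w$ the apparent body width. The body is modeled as an ellipse
with major axis 3.0 mm and minor axis 1.5 mm; the major axis serves as the
projected width $w$ for every neighbor regardless of that neighbor's
orientation (the minor axis is stored but does not enter the cue — a
deliberate simplification over orientation-dependent projection). Neighbors
behind the focal contribute nothing; the sector boundary at exactly 90° is
inclusive (dot product $\ge 0$), which makes the visible region exactly a
half-plane.

Assumptions worth keeping in mind: no occlusion (a fly directly behind
another still counts), no height or perspective effects, and a hard
distance clamp at 0.75 mm (half the minor axis) so that tracking jitter at
near-contact cannot produce unbounded angular terms.

### Kinematics and the heading convention

Speeds are forward differences, $v(t) = |\mathbf{x}(t{+}1) -
\mathbf{x}(t)|/\Delta t$, with the final frame carrying the previous value
so all series stay frame-aligned. The heading at frame $t$ is the direction
of the displacement **arriving** at $t$ — the direction of the most recent
movement, which is the orientation the animal actually has when it sees the
frame-$t$ scene. The alternative (the outgoing step) would condition the
focal's sector on its own *next* move and thereby leak the regression
outcome into the predictor; in zero-coupling simulations that look-ahead
inflates the null sensitivity slope, which is why the incoming-step
convention is the default. When a fly is stationary (incoming displacement
below 0.25 mm) the last defined heading is carried forward — a real fly
does not lose its orientation by standing still — and initial undefined
frames are backfilled with the first defined heading. A tracker-supplied
heading column can be used instead (`heading_source = "file"`), but the
displacement heading is the default because it is reproducible from
coordinates alone and the orientation convention of stationary flies varies
between trackers.

### The cue transform

Raw cues are heavily right-skewed and span species with very different
baseline motion, so before any regression the pipeline (i) replaces
zero-valued observations with the smallest non-zero raw cue of their
standardization stratum, (ii) takes the natural log, and (iii) z-scores
within the stratum. The default stratum is species × group type; pooling
across group types (`standardize_pool = "species"`) is available because
either reading of a species-level standardization is defensible. When
several recordings are analyzed together the constants are computed over
all recordings of a stratum at once, so cue values are comparable across
arenas. A stratum whose cues are all zero (nothing ever moved) is an error
rather than a silent fill.

## Locomotion states and events

A frame is *walking* when speed ≥ 2.0 mm/s, otherwise *stationary*. Runs
shorter than the minimum bout are absorbed into the preceding state in a
single deterministic left-to-right pass (the first run is exempt). The
default minimum bout is 2 frames (1 s). This smoothing matters:
instantaneous walking speeds fluctuate, so a walker occasionally dips below
any fixed threshold for a single frame. Without smoothing those dips
register as spurious stop-and-restart events in the middle of bouts, and
event-aligned cue statistics inherit a systematic bias — the null
calibration study below is the check that the chosen default removes it.
Both the threshold and the minimum bout are configuration parameters
reported in every output.

Event labels follow the transition definitions: the frame immediately
preceding a stationary→walking transition is **walk**, the frame
immediately preceding walking→stationary is **stop**, remaining walking
frames are **walking** and remaining stationary frames are **stay**. If
activity conforms, the cue should rise from *stay* to *walk* (neighbors
moving recruit the focal into motion) and fall from *walking* to *stop*.

Event contrasts use the per-individual mean cue per event type and a
sign-flip permutation test on the paired differences, with Bonferroni
correction over the requested family. When $2^n$ sign patterns are
enumerable the test is exact (smallest attainable two-sided p is
$2/2^n$). One caveat stated plainly: the sign-flip null treats individuals
as independent, but arena-mates share one cue field, so their differences
are positively correlated and the test is mildly anti-conservative — in
zero-coupling simulations it rejects at roughly 7% at a nominal 5%. The
package deliberately ships this simple, fully reproducible test and exports
the individual-level tables (`individual_speeds`, `sensitivity`,
`event_means`) so that mixed-model machinery in external environments can
account for arena and strain structure.

## Conformity metrics

* **Sensitivity**: ordinary least squares of $v(t{+}\ell)$ on the
  transformed cue $z(t)$, per individual, with lag $\ell = 1$ frame
  (0.5 s) to allow the behavioral response time. The slope (mm/s per sd of
  cue) is the sensitivity. The individual is the unit everywhere: all
  downstream comparisons use means of per-individual quantities, never
  frames.
* **Species-level conformity**: the rate of change of mean speed from
  single to mixed groups, $(\bar v_{\text{mixed}} -
  \bar v_{\text{single}})/\bar v_{\text{single}}$, computed strain-matched
  (each mixed-group strain against the same strain's single-group
  baseline) and aggregated per species. The signed relative form makes 0 =
  no conformity; a ratio variant is available. Unmatched strains are an
  error, not silently pooled.
* **Group-level conformity**: $\Delta_{\text{single}} =
  |\bar v_A - \bar v_B|$ across the two species' single groups versus
  $\Delta_{\text{mixed}}$ within mixed groups; convergence means the
  reduction $\Delta_{\text{single}} - \Delta_{\text{mixed}} > 0$, tested
  by permuting group-type labels within species.

## The synthetic arena

The simulator exists so the whole pipeline can be validated by parameter
recovery: it generates trajectories from a known generative model whose
coupling constants play the role of ground-truth conformity.

Each agent is a two-state Markov chain coupled to its own visual cue
through a logistic link:

$$
P(\text{stay}\to\text{walk}) = \mathrm{logit}^{-1}\!\big(
  \mathrm{logit}(p_w) + \beta z\big), \qquad
P(\text{walk}\to\text{stay}) = \mathrm{logit}^{-1}\!\big(
  \mathrm{logit}(p_s) + \beta_{\text{stop}} z\big),
$$

where $z$ is the agent's standardized cue, computed online with the same
cue code the analysis uses. $\beta$ is the ground-truth conformity (walking
where others move); $\beta_{\text{stop}} > 0$ means settling where others
are. The logistic link keeps probabilities valid at any cue. Defaults
$p_w = 0.05$, $p_s = 0.10$ per 0.5 s frame give mean stationary bouts of
10 s, mean walking bouts of 5 s and a resting stationary fraction of 2/3 —
realistic for undisturbed flies on a bare arena floor.

Design choices:

* **Standardization constants** for the online $z$ come from a separate
  zero-coupling calibration run with identical speed parameters. Running
  standardization *inside* a coupled simulation would let the behavior
  shift its own cue scale mid-run (circularity); the decoupled calibration
  pass pins the scale first. The calibration run spans the full assay
  window (3600 frames) and floors cues at the 1st percentile of positive
  calibration values rather than their minimum — the minimum is an extreme
  order statistic whose run-to-run swings would otherwise leak into the
  realized coupling strength, to which strongly coupled dynamics are
  sensitive.
* **Walking speeds** are lognormal per frame (median $\mu$, shape
  $\sigma = 0.3$), with species medians {1, 2, 4, 10} mm/s in the default
  panel, spanning the roughly ten-fold activity range seen across
  sympatric fly species without asserting real per-species values. The
  designated host species sits at an intermediate speed with the strongest
  coupling; the fastest species has the weakest (the
  influential-but-insensitive profile).
* **Walls** reflect specularly and preserve path length (the step folds at
  the wall like a billiard), so wall contact neither shortens steps nor
  depresses realized speed — a truncating boundary would couple position
  to measured speed and bias the null calibration. Real flies instead
  follow arena edges; the simulator does not reproduce edge-following, nor
  post-anesthesia recovery dynamics: it emits stationarized behavior
  equivalent to a recording's analysis window (plus a discarded 100-frame
  burn-in).
* **Initial positions** cluster near the center; in mixed groups the two
  species start at symmetric ±y positions, as in the live assay where the
  starting position encodes species identity.
* Identical seed and parameters give bit-identical recordings; every
  derived seed stays within 32-bit integer range.

What the simulator does **not** emulate: olfactory and acoustic channels,
collisions and physical contact, occlusion, courtship or aggression,
heterogeneity between individuals of a species, and diurnal or arousal
drifts. Passing the validation studies therefore shows the *pipeline*
recovers the *visual-coupling* structure it assumes; it does not show that
real fly behavior contains only that structure.

## Validation studies and problem sizes

The studies in `study_*()` (also run by `scripts/acceptance.R` and the
acceptance tests) use the assay's own geometry: 24 agents, 3600 frames
(30 min at 0.5 s), 140 mm arena.

* **Null calibration** (200 seeds, $\beta = 0$): mean sensitivity slope
  within 2 Monte-Carlo se of zero; walk-vs-stay rejection near nominal.
* **Positive control** (20 seeds, $\beta = 1$): transformed cue at walk
  frames exceeds stay frames.
* **Monotone recovery** ($\beta \in \{0, 0.5, 1, 2\}$, 20 paired
  replicates — the same arena seeds drive all four couplings so shared
  noise cancels from the rank comparison): recovered mean slopes in the
  ground-truth rank order. Each replicate's slope estimate aggregates
  three arenas, as in the live assay where every condition is recorded in
  3–5 replicate groups; aggregation matters at $\beta = 2$, where
  self-excited activity intermittently saturates and makes single-arena
  estimates noisy.
* **Convergence** (20 seeds, species at 1 and 4 mm/s): mutual $\beta = 1$
  shrinks the mixed-group speed difference; $\beta = 0$ leaves it.
* **Asymmetry** (20 seeds): a fast, weakly coupled partner changes little
  while the strongly coupled host moves toward it.

Note the recovered slope is not numerically equal to $\beta$ — the
generative coupling acts on transition log-odds while the measured
sensitivity is a linear slope of speed on cue — so recovery is assessed as
rank order, not equality.

## Numerical conventions

* Frames are 0-based; time windows half-open $[t_0, t_1)$; a 60-min
  recording clipped to the default window yields exactly 3600 frames.
* Missing frames are an error, never interpolated; there is no gap-filling
  rule worth inventing silently.
* Coordinates are written with 17 significant digits so write→read round
  trips are bit-exact; report tables use a fixed 10-digit format so reruns
  are byte-identical.
* Permutation p-values use the add-one estimator
  $(1 + \#\{|T^\ast| \ge |T|\})/(B + 1)$ except where exact enumeration is
  feasible; all seeds are arguments and echoed into outputs.
* Degenerate inputs fail loudly: zero-variance cues, all-zero strata,
  empty tables, unmatched strains, single-frame recordings.

## Known limitations

* The cue model is geometric, not perceptual: no contrast, adaptation, or
  acuity limits, and the fixed 3.0 mm projected width ignores neighbor
  orientation.
* The built-in tests are permutation analogues operating on per-individual
  means; they do not model arena or strain random effects. Use the
  exported tables for mixed-model analyses.
* The heading of a long-stationary fly is a guess (carried forward); real
  flies reorient in place, which the coordinate stream cannot see.
* With the 2 mm/s threshold, speeds between the stationary epsilon and the
  threshold count as stationary for events but still update heading —
  slow creeping is treated as oriented standing.
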