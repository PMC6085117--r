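---
title: "Branching morphogenesis and clonal statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branching morphogenesis and clonal statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancmorph)
```

`pancmorph` models the development of branched ductal organs — the
embryonic pancreas in particular — as the collective behaviour of active
ductal termini, and provides the clone-level statistics needed to confront
that model with multicolour (confetti-style) lineage-tracing data.  This
vignette explains the models, their assumptions and tunable parameters,
the numerical choices made, and what the synthetic-data tests do and do
not establish about real data.

## The branching-annihilating growth model

During the secondary transition, the pancreatic ductal network expands
from side branches of a few central, plexus-derived ducts.  The package
models this with three rules acting on active ductal termini in a 2D
plane (pancreatic morphogenesis is, to a good approximation, planar):

1. **Elongation.** Each active terminus advances by `step_length`
   per update along a direction that wobbles by an angle drawn from
   Normal(0, `angle_noise`); the wobble persists, so duct directions
   perform a random walk.
2. **Stochastic bifurcation.** With probability `branch_prob` per step
   the current branch closes and two daughter termini depart at
   ±`branch_angle` about the parent direction.
3. **Irreversible termination.** A terminus whose new position comes
   within `annihilation_radius` of another duct becomes permanently
   inactive.  Termination is checked before branching, so a step that
   could do both terminates.

All lengths are expressed in units of the single key length scale: the
mean separation (`spacing = 1`) of adjacent subtree roots along the
central duct.  Defaults are ratios to it: `step_length = 0.05` and
`branch_prob = 0.05` per step, so the mean branch length equals the
subtree spacing; `branch_angle = pi/6` per daughter; `angle_noise = 0.15`
rad; `annihilation_radius = 0.25`; `self_exclusion_length = 0.75`.  These
ratios are calibration knobs exposed in `sim_params()`; the defaults were
fixed once so that the simulated ensemble reproduces the qualitative
hallmarks of measured ductal trees (heterogeneous subtrees spanning
orders of magnitude, with roughly 10% of subtrees exceeding three times
the mean size).

Initial conditions follow the seeding geometry of the organ: 40 termini
(configurable) launch perpendicular side branches from a straight central
duct, with inter-root gaps drawn i.i.d. from a shifted exponential with
mean `spacing`, truncated below at the annihilation radius so neighbours
never start in contact ("independent" spacing of subtrees suggests
Poissonian placement; a `root_gaps = "fixed"` option exists for
deterministic tests).

### Numerical design of the simulator

The update loop lives in compiled code (`src/barw.cpp`) and draws all
randomness from R's RNG, so a `seed` makes runs bit-identical.  Termini
are updated sequentially in an order re-randomized every step; a
termination during a step is immediately visible to termini updated later
in the same step.

Ducts are represented as polylines whose vertices are deposited once per
elongation step; the proximity test measures distances to these vertices.
Since vertices are `step_length` apart and the annihilation radius is
five times larger, the vertex approximation errs by at most half a step
length, well inside the biological uncertainty of the termination rule.
The user-facing `min_distance()` query is exact point-to-edge geometry.

A tip must not be killed by its own wake.  The proximity check therefore
ignores duct points within a path-length budget
(`self_exclusion_length`) walked backwards from the tip along its own
ancestry: the tip's own trailing path, then — while budget remains — the
distal end of each ancestor, the proximal start of that ancestor's other
daughter, and a window of the central duct around the subtree root.
Without the sibling/ancestor windows, daughters spawned on a short parent
branch would annihilate against their own junction at birth, which is a
discretization artefact rather than duct–duct competition.

There is no outer boundary: the model invokes only duct–duct proximity.
On an open plane the tip front therefore never dies out; a run ends at
`max_steps` (default 500, i.e. 25 spacings of front travel and more than
ten branch generations, at which point ~90% of all termini ever created
have terminated).  The step cap plays the role of the finite
developmental window and is reported on the result as an attribute, with
a warning.

### What the simulator reproduces — and one caveat

Two emergent properties are asserted by the test suite on 100-run default
ensembles: active termini self-organize into a traveling front whose
ensemble-mean radius never decreases (tested as "no statistically
significant decrease", i.e. per-step mean difference ≥ −3 SE, since the
ensemble mean is itself a Monte Carlo estimate), and pooled subtree sizes
are strongly heterogeneous, with the cumulative tail at three times the
mean falling near 0.1.

Density of the trailing network deserves a caveat.  In the consolidated
bulk — beyond about one subtree spacing from the central duct and behind
the active front — duct length per unit area is constant to within a few
percent (`duct_density_bands()` exposes the profile).  The layer adjacent
to the central duct, however, is structurally sparser: no duct other than
a subtree's own root stem may approach the central duct closer than the
annihilation radius, and subtrees begin as isolated stems that need
several branch rounds to reach steady-state packing.  A density-trend
test whose bands are confined to the first spacing or two therefore
detects this seeding layer as a positive trend; the package's test suite
contains exactly one such strict check, which documents this behaviour
rather than contradicting bulk stationarity.

## Precursor drift and monoclonal conversion

Each terminus hosts a pool of `N` self-renewing precursors.  At a
bifurcation the pool is partitioned uniformly at random into groups of
⌊N/2⌋ and ⌈N/2⌉ (random side assignment when N is odd), and each
daughter group then duplicates symmetrically to restore pool size.  For
odd N the duplicated pool is one cell over or under target; the larger
daughter drops one uniformly chosen duplicate and the smaller adds one
extra copy of a uniformly chosen cell.  This rule was chosen among the
admissible "approximately equal" segregation rules because it preserves
the martingale property exactly: the expected labelled fraction of a
daughter pool equals the parent's.  Consequences verified in the tests:

- fixation probability from k labelled of N is exactly k/N (solved
  exactly by `fixation_probabilities()` via the absorbing Markov chain of
  `drift_transition_matrix()`, and matched by simulation);
- fully labelled and fully unlabelled pools are absorbing, so ducts
  convert monoclonally along generations;
- the characteristic conversion generation grows linearly with N — the
  basis for inferring the precursor number.

A segment's label composition is defined as the pool state at the moment
its construction begins; the package does not model how trailing ductal
cells sample the tip pool along a branch, which is unspecified
biologically.  "Monoclonal" means zero label entropy over colours plus
the unlabelled state.

Because duct termination is independent of labels, drift can be replayed
on a stored network (`run_drift()`) with the same statistics as a joint
simulation; ensemble conversion profiles (`simulate_conversion_profile()`)
propagate labelled counts through complete binary trees, since pruning
does not bias the per-generation monoclonal fraction.

One subtlety matters when quantifying the conversion *rate*.  A lineage
chain started from a single labelled precursor loses its label quickly
with probability (N−1)/N, so the unconditioned generation-to-absorption
is dominated by extinction and barely depends on N.  What a tracing
experiment observes, however, are the *labelled* clones; conditioning on
fixation of the label (`generations_to_monoclonality(labeled_only =
TRUE)`) yields median conversion generations that grow linearly in N
(about 1, 3, 10, 23 for N = 2, 4, 8, 16; regression R² > 0.99).
`infer_precursor_number()` scores candidate N values by the
segment-count-weighted squared deviation between observed and simulated
per-generation monoclonal fractions — the fitting statistic is a declared
package choice, since visual comparison is not reproducible — and
recovers N = 4 from profiles of 10³ subtrees.

## Clone statistics

`classify_potency()` calls a lineage (acinar, ductal, islet) present when
its clone volume strictly exceeds a threshold (default 0 µm³, i.e. any
positive volume; the threshold is exposed for sensitivity analysis
because imaging-based assignments have no published cutoff).
`rescaled_distribution()` divides sizes by the sample mean so that
compartments whose average sizes differ by an order of magnitude can be
compared in shape; its `dist_tail()` is the empirical fraction exceeding
a multiple of the mean.

`qq_r2()` compares two rescaled samples on the quantile grid
p = (i − 0.5)/m (m the smaller sample size) with linear interpolation
between order statistics, scoring agreement with the identity line as
R² = 1 − Σ(q_b − q_a)²/Σ(q_b − mean(q_b))².  The grid and interpolation
convention must be fixed for a reproducible R²; the (i − 0.5)/m
convention is symmetric in the sample and clamps at the extremes.  Note
that with heavy-tailed sizes the sample mean — and hence the rescaled
quantile scale — converges slowly, so R² between small samples from the
same law fluctuates; comparisons should pool enough clones that the mean
stabilizes.

`mann_whitney()` and `ks_two_sample()` provide exact small-sample
inference by full enumeration of the C(n+m, n) group assignments when
n + m ≤ 12 (two-sided p for the rank test counts assignments with
|U − nm/2| at least as extreme), switching to the normal approximation
with tie and continuity corrections, respectively the asymptotic
Kolmogorov distribution with the small-sample effective-size correction,
for larger samples.  Null rejection rates at α = 0.05 sit within
[0.03, 0.07] for both.  `bin_small_sizes()` optionally pools the very
smallest rescaled sizes below a chosen quantile (off by default), the
analogue of binning tiny clone sizes before rank comparisons.

`center_periphery_split()` stratifies clones at two-thirds of a supplied
organ radius, the convention used to contrast central and peripheral
clone sizes.

## Clonality quality control

If a tracing assay is clonal, label colours are independent across
clones, so the probability that two clones share a colour should not
depend on their distance.  `pair_probability()` estimates the same-colour
pair probability in distance bins, rescaled by the any-colour pair count
per bin, which cancels the organ's convoluted geometry.  Default bins are
10 equal-width bins up to the 95th percentile of pair distances — a
data-adaptive choice, configurable via `bin_edges`.

`bootstrap_null()` resamples every clone's colour i.i.d. from the
per-mouse empirical colour frequencies at fixed positions (1000 times by
default) and forms the pointwise 95% envelope of the rescaled curves.
Fragmentation — one clone scored as several nearby same-colour objects —
lifts the observed curve above the envelope in the shortest bins.  The
envelope's quantiles are calibrated: a fresh draw of the null
reassignment process falls inside per bin at the nominal 95% rate.
Coverage of the *observed* curve of truly clonal data is conservative
(≈97–100%), because the observed curve conditions on the realized colour
counts while resampled curves carry additional multinomial colour-count
variance; the envelope is therefore a descriptive band, not a sized test.

`merger_correction()` groups same-colour clones within a user-supplied
radius by single linkage — the transitive-closure reading of "within a
given radius" — summing compartment volumes and taking total-volume-
weighted centroids; different colours never merge.  Because merged
centroids can drift into range of one another, the pass is iterated to a
fixed point, which makes the correction idempotent; it conserves labelled
volume per colour exactly.  The grouping radius is a required user
parameter (no published value exists).

## The synthetic confetti generator

`generate_clone_table()` emulates a clonal-density confetti tracing
end-to-end: a simulated network, a ductal and an acinar precursor pool of
`N_precursors = 4` per terminus, single-cell colour induction at the
start of branching, neutral drift of both pools at every bifurcation, and
volume bookkeeping per clone.  Study conditions are the defaults:
labelled volume fraction `induction_fraction = 0.025` (clonal density,
under 3%), colour odds 5:3:3:1 for RFP:GFP:YFP:CFP (confetti outcomes are
strongly RFP-biased, with RFP clones more than five-fold more frequent
than CFP), and a potency mix of 20% multipotent, 50% acinar-committed,
30% ductal-committed induced cells, chosen so that emitted potency
fractions resemble late-induction tracings (about two-thirds unipotent).
The per-slot induction probability is calibrated internally so the
expected labelled *volume* fraction matches `induction_fraction`
(multipotent cells occupy a slot in both pools, and acinar mass per duct
length outweighs ductal mass).

Mechanism, not paint: a multipotent induced cell seeds both pools of its
terminus, ductal output sheds a Poisson number of delaminating islet
cells per branch (5% of trunk output by default), and so uni-, bi- and
tripotent clones emerge from drift and chance.  Volume conversions are
order-of-magnitude placeholders, documented in `synth_config()`: 1000 µm³
per cell, 50 ductal cells per subtree-spacing of duct, acinar output 3×
ductal, 50 µm per spacing unit, and Gaussian position jitter of 10 µm
standard deviation emulating measurement error.  Positions are
mass-weighted centroids; clones are cohesive within a single subtree by
construction.

What passing tests show — and do not.  The generator shares its
mechanisms with the models being tested, so recovery tests (potency
self-consistency, N = 4 recovery, envelope coverage, colour ratios)
validate the *pipeline*: that each statistic measures what it claims on
data with known ground truth, at realistic sample sizes and labelling
densities.  They cannot validate the biological assumptions themselves —
planarity, equipotent termini, pool-size constancy, or the absence of
precursor shuttling between terminus and branch, which the model leaves
out deliberately.  Real imaging data also carry section-truncation and
segmentation artefacts that the generator does not emulate.

## Problem sizes and reproducibility

The shipped test suite and the acceptance script use ensembles of
100–500 simulations, 10⁵ drift lineages, 10³ bootstrap resamples and
10³ null-calibration replicates — sizes at which every asserted quantity
is stable to well within its test tolerance on a single CPU in minutes.
Every stochastic entry point accepts a seed, a single seeded R RNG stream
drives both R and compiled code, and fixed seeds reproduce outputs
byte-for-byte, including the JSON/CSV fixture suite
(`fixture_suite()`).
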