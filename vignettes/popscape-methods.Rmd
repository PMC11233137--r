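---
title: "Models and methods behind popscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popscape simulates diploid populations forward in time under a
Wright–Fisher model, either as classic random-mating demes or as
individuals living in continuous two-dimensional space, and records the
resulting genealogies as succinct node/edge tables on a recombining
genome. This vignette documents the model, its assumptions, the tunable
parameters, and the numerical and design choices that a user of the
statistics should know about.

## The demographic model and its compilation

A model is declared as a set of `population()` configurations (name, time
of appearance, diploid size `N`, optional parent, optional spatial range)
plus scheduled events: `resize()` (step or exponential), `gene_flow()`,
`move()`, `expand_range()` and `set_dispersal()`. Times are written in
whatever units are natural for the system — generations forward, or e.g.
"years before present" backward; the direction is inferred from the
numerical ordering of split times and event windows, and all times are
converted to generation indices by `compile_model()` via its
`generation_time` argument. The convention is that the oldest time in the
model is generation 1 and the run ends at generation
`G = round(|T1 - T0| / generation_time) + 1`; every output table reports
node times back in the user's units.

Compilation validates the model (unique names, parents existing before
children, events within population lifespans, gene-flow participants
coexisting through the whole window, every range snapshot having positive
habitable area) and precomputes, per population and generation, one size,
one range polygon and one set of spatial parameters. When several events
touch the same generation they apply in a fixed order: resizes, range
updates, dispersal changes, gene-flow activation, sampling. Compilation is
pure — identical declarative input yields a bit-identical compiled object
— which is what makes the on-disk bundle (`write_bundle()`) a faithful,
re-runnable serialization: loading a bundle simply recompiles the stored
declarative model and verifies the stored hash.

### Gene-flow rate semantics

`gene_flow(from, to, rate = r, start, end)` means: over the `T`
generations of the window, a total expected proportion `r` of the target's
ancestry is replaced by ancestry from the source. Internally this becomes
a per-generation probability `m = 1 - (1 - r)^(1/T)`. Because the engine
implements gene flow on the mate side only — each offspring draws its
first parent from the target and, with some probability, its *mate* from
the source, so a migrant mating contributes only half the offspring's
genome — the engine's mate-draw probability is `q = min(1, 2m)`. With
that compensation the realized end-of-window ancestry satisfies
`1 - (1 - q/2)^T = r` exactly, and `r` keeps its total-ancestry meaning.
The pedigree-tracking option of the engine (`track_ancestry`) verifies
this bookkeeping independently of any genetic statistic.

## The spatial engine

Landscapes are abstract planar worlds in arbitrary map units: an
axis-aligned rectangular extent with binary habitability, either the whole
extent or the union of polygonal regions. All geometry is polygonal;
circles are regular 64-gons (configurable), which keeps their area error
below 0.2%. There is no notion of real-Earth coordinates or projections:
one map unit is whatever the model says it is.

Within a population, one generation is produced from the previous one by
repeating, exactly `N(gen)` times:

1. **First parent.** Drawn with probability proportional to
   `w = 1/(1 + n)`, where `n` is the number of same-population neighbors
   within the competition radius (`competition = 0` turns this off). The
   literature on spatial interactions describes the qualitative effect of
   competition — crowded individuals reproduce less — without fixing a
   functional form; `1/(1+n)` was chosen because it is bounded, scale-free
   and, with a competition radius well above the dispersal scale,
   reproduces the documented self-organization of individuals into
   evenly-spaced patches. It is a declared stand-in, not a claim about any
   particular simulator's kernel.
2. **Mate.** Uniform among same-population individuals within the mating
   radius of the first parent, selfing excluded. If no candidate is in
   range the nearest individual is used; mate-search failure never reduces
   the realized census size, which is part of the Wright–Fisher contract.
   During an active gene-flow window the mate is instead drawn from the
   source population with probability `q` (uniformly in non-spatial mode;
   in spatial mode with `overlap = TRUE` only source individuals within
   the mating radius qualify, and the engine errors if essentially no
   draws can be satisfied).
3. **Location.** The offspring disperses from the first parent by a draw
   from the population's kernel: `normal` (half-normal distance),
   `uniform` (distance uniform on `[0, sigma]`), `cauchy` (half-Cauchy),
   `exponential` (mean `sigma`), each with a uniform direction, or
   `brownian` (independent per-axis normals). Proposals outside the
   habitable range are rejected and redrawn; after `max_placement_attempts`
   rounds (default 1000) the offspring is placed uniformly on the range
   instead. This "teleport" fallback is logged and also covers parents
   stranded outside a range that has just moved.
4. **Genomes.** Each of the offspring's two genome copies is a recombinant
   of the corresponding parent's two copies: a Poisson(`rho * L`) number
   of integer breakpoints, alternating copies from a random starting copy.
   Every transmission appends edges to the genealogy tables.

Daughter populations are founded at their start generation by `N` children
of parents drawn from the parent population (the parent population itself
is unaffected); root populations are founded by unrelated individuals
placed uniformly on their range. Execution is sequential and
single-threaded with one seeded generator: reproducibility outranks
parallelism, and a fixed seed gives byte-identical outputs.

## Genealogy tables, simplification, mutations

The recorded tables follow the succinct tree-sequence design: nodes are
genome copies with birth times, populations and locations; edges are
inheritance intervals `[left, right)` on a `[0, L)` genome. Tables are
periodically simplified during the run (every `simplify_interval`
generations, keeping the ancestry of the living and of all permanently
sampled individuals), which bounds memory without changing the final
result.

`simplify_tables()` reduces tables to a sample set: samples are renumbered
first in the order given, and the only other retained nodes are, per
genomic interval, most recent common ancestors of at least two samples.
Unary ancestors are dropped, matching the convention that simplified-away
intermediate ancestors are unknown to downstream spatial queries. The
implementation propagates per-node ancestry segment lists from samples up
through parents in order of decreasing birth time; it is validated
exactly, interval by interval, against an independent brute-force oracle
that traces every sample's genome up the raw pedigree (100 random
recombining histories in the test suite).

Neutral mutations are overlaid after simulation, Poisson per edge with
mean `mu * span_bp * branch_length_generations` and integer positions
uniform on the edge span; collisions are redrawn, so every site carries
exactly one mutation (infinite sites), ancestral state `A`, derived `T`.
Overlaying after (rather than during) the forward pass is what makes the
neutral model cheap: genealogy first, mutations second.

## Statistics

All statistics are site-based, computed from derived-allele counts
obtained by a single left-to-right sweep over the marginal trees:
diversity (mean pairwise difference per site), divergence (mean cross-pair
difference per site), Patterson's f4 (mean over sites of
`(p_A - p_B)(p_C - p_D)`, no bias correction), the f4-ratio
`alpha = f4(A, O; X, C) / f4(A, O; B, C)` and the allele frequency
spectrum (polarised or folded). The f4-ratio argument convention is fixed
to the form above: `X` the admixed target, `B` the source-related lineage,
`A` a sister of `B`, `C` an unadmixed reference on the recipient side, `O`
an outgroup. Branch-mode statistics are deliberately out of scope: the
supported workflow is overlay-then-measure.

## What the built-in model generators emulate

The generators in `?fixtures` are the package's study conditions, not
arbitrary toys:

* `example1_model()` is the six-population admixture teaching model used
  to exercise the f4-ratio: outgroup `o`; internal lineages `c`, `a`, `b`;
  recipients `x1` (10% gene flow from `b` over a late window) and `x2`
  (splitting from `x1` before the window, hence 0%). The published
  description of this model fixes its topology and the 10% rate but not
  the numeric values of the split times or sizes, so the defaults here
  place the model on an ~800-generation grid sized for a forward engine
  in R. The population sizes follow the estimator's structure: only the
  drift that population `a` accumulates on its long branch shared with
  `b`'s lineage feeds the f4-ratio denominator, so `a` is small
  (`N = 100`) to make that signal strong, while every other population
  is large (`N = 1000`), because their drift enters both f4 terms purely
  as noise. Because the estimator's expectation depends only on
  the topology and the rate, this rescaling changes variance, not the
  10%/0% target. Consistent with rescaling times down, the validation
  runs scale the per-generation recombination and mutation rates up
  (`rho = 3e-7`, `mu = 3e-7` per bp on a 10 Mb genome), keeping the
  number of effectively independent genome blocks and segregating sites
  (well above 10^4) realistic for the statistic.
* `example2_model()` places identical, non-interacting populations on a
  featureless circular world and varies the competition radius; it
  reproduces the qualitative regimes of spatial self-organization. The
  validation conditions use four populations of `N = 200` for 200
  generations on a radius-300 world: a "mixed" regime (competition 2,
  dispersal 80 — competition far below dispersal) and a "patchy" regime
  (competition 60, dispersal 5 — competition far above dispersal), with
  mating radius 10. The patchiness statistic is the coefficient of
  variation of nearest-neighbor distances, averaged per regime within a
  seed; free mixing drives it toward the spatial-randomness value
  (about 0.52) while patch formation raises it. The diversity contrast
  between the regimes is measured as mean per-individual heterozygosity
  (see `heterozygosity()`): within-patch mating coalesces an individual's
  two genomes quickly, so the patchy regime is markedly less
  heterozygous, whereas total pairwise diversity would mix in the
  growing between-patch divergence and is not directionally stable over
  a 200-generation run.
* `example3_like_model()` is a small backward-time spatial model (years,
  30-year generations) with a range move, an expansion and a gene-flow
  event, exercising the full declarative surface on an abstract continent.

What these generators do *not* emulate: real geographies and projections,
heterogeneous habitability gradients, selection, overlapping generations,
recombination-rate maps, and non-Wright-Fisher regulation. Passing tests
therefore demonstrate internal consistency of the model described above
and agreement with neutral theory at the simulated scales — not fidelity
to any particular empirical landscape.

## Numerical choices and degenerate inputs

* Geometry is hand-rolled and polygonal: shoelace areas, even-odd
  point-in-polygon with boundary points counted inside (closed sets, so
  rejection sampling terminates on thin regions), Sutherland–Hodgman
  clipping against the extent and against a single convex habitable
  region, and angle-bisector offsetting for `buffer_region()` with the
  miter capped at sharp vertices. Offsetting is exact for convex regions
  up to the polygonal discretization; the contract (grow supersets, shrink
  subsets, clip to the world) is what is tested, not a particular
  algorithm. Contractions at or beyond the region's inradius are refused.
* Range snapshots during `move()` follow the piecewise-linear waypoint
  path at constant speed along its arc length; `expand_range()` buffers
  the pre-event range by `by * k/T` at step `k`, avoiding compounding
  discretization error. Both clip to the habitable area and fail at
  compile time if a snapshot loses all habitable area.
* Uniform placement uses bounding-box rejection sampling and reports
  suspected degenerate geometry after 1e5 consecutive rejections.
* Ties in `set_dispersal()` at one generation resolve to the
  later-declared event, with a warning.
* The neutral-theory validation runs each replicate until every marginal
  tree of the final samples has a single root (checked by an
  edge-insertion sweep), extending the run in chunks past its scheduled
  end; this removes the downward bias that uncoalesced lineages would
  otherwise put on diversity. The allele-frequency-spectrum comparison
  against the Kingman expectation `E[xi_i] = theta L / i` uses a small
  sample (12 genomes out of 2N = 1000): the engine is an exact discrete
  Wright-Fisher model, and the coalescent 1/i shape only holds up to
  simultaneous-merger corrections of order `n^2 / N`, which a large
  sample would surface as a spurious few-percent deficit at intermediate
  frequencies.
* Problem sizes in the validation suite were chosen so the whole suite
  runs on a laptop-class single core: 10 Mb genomes, populations of
  100–1000, 5 seeds for the admixture and patchiness checks, 20
  replicates for the cross-mode and neutral-theory checks.

## Known limitations

* Polygon offsetting assumes convex-ish ranges; strongly concave ranges
  may self-intersect under large buffers and are rejected rather than
  repaired.
* With more than one habitable region, range geometry is clipped to the
  world extent only, and habitability is enforced pointwise through the
  sampling and dispersal primitives rather than by explicit polygon
  intersection.
* f-statistics carry no small-sample bias correction; use adequately
  sized sample sets.
* The engine is an individual-based forward simulator: runtimes grow
  linearly in total individual-generations, so coalescent-scale histories
  (hundreds of thousands of generations) are out of its intended range.
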