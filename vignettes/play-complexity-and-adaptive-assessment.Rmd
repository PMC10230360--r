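---
title: "Play complexity and adaptive block-game assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Play complexity and adaptive block-game assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubecat)
```

## The assessment battery

`cubecat` implements the computational core of a cube-based cognitive
assessment battery of six block games: Assembly, Shape-Matching,
Sequence-Memory, Spatial-Memory, Path-Tracking and Maze. Physical cubes carry
black-and-white glyphs — squares, strips and triangles in two colour roles —
on their faces, and items are arrangements (grids, sequences, paths, mazes)
that the examinee reproduces, completes or traces. Everything upstream of the
mathematics (the camera, surface detection, human participants) is out of
scope here: the package covers item representation, difficulty measurement,
item generation, adaptive sequencing, scoring, and an in-silico harness that
validates the whole loop with simulated examinees.

## The shape taxonomy

Rotating a glyph by quarter turns yields 1 distinct appearance for a square,
2 for a strip and 4 for a triangle (the rotational symmetry *fold*). With two
colour roles of each glyph on the six faces of a cube, deduplication gives
`2 * (1 + 2 + 4) = 14` distinct surface appearances, enumerated by
`surface_shapes()` with stable ids. Folds are derived by literally rotating
small binary glyph masks, not asserted. The id-to-appearance ordering
(square < strip < triangle, colour A < B, orientation ascending) is a
package convention; only the (geometry, colour, orientation) metadata is
meaningful.

## Play complexity

Difficulty is a scalar, `C_play`, in bits-derived units, built from two
ingredients.

**Compositional complexity.** Each displayed shape is one of `m = 6`
available faces shown in one of its `r` orientations, contributing
`log2(m * r)` bits: `C_compos = sum_i log2(m_i * r_i)`. This depends only on
the multiset of shapes — any rearrangement of the same shapes has the same
`C_compos`.

**Configurational complexity.** Disorder of the arrangement is measured with
a co-occurrence matrix over shape ids (the texture-analysis construction,
applied to symbols rather than pixel intensities): all ordered adjacent
pairs along the 0°, 45°, 90° and 135° directions are extracted, each line
closed into a cycle by its circulant wrap-around pair, and counted into a
14×14 matrix `f`. The weighted entropy
`C_config = -sum w_ij p_ij log2 p_ij`, `p = f / sum(f)`, uses weight 2 for a
pair differing in both colour and orientation and 1 otherwise.

**Composition.** For Assembly, Spatial-Memory and Sequence-Memory,

```
C_play = k(C_config) * C_compos + C_config,
k(x) = 1 / (1 + exp(-alpha (x - beta))),  alpha = 1, beta = 2.
```

The sigmoid gate suppresses the compositional term for orderly items: a grid
of identical triangles has a large `C_compos` but `C_config = 0`, and its
`C_play` stays small. Shape-Matching uses `C_play = C_config` alone, summing
the weighted entropies of three separate matrices (horizontal, vertical,
diagonal): since only one piece is missing, having more shapes in the
pattern does not by itself make the item harder. Sequence items use the
0-degree pairs along the sequence with circulant closure.

Several of these exact forms — the compositional sum, the `C_play`
composition, the weighted-entropy expression, and the maze solution terms
below — are this package's own formulations chosen to satisfy the published
qualitative contracts (the uniform-case entropy `log2 n`, the
arrangement-invariance of `C_compos`, the gating behaviour of `k`). They are
isolated behind `complexity_params()` so alternatives can be swapped in
without touching callers. The sigmoid parameters default to `alpha = 1`,
`beta = 2` (midpoint at 2 bits of configurational disorder) and are
configurable.

Path-Tracking and Maze do not use the glyphs. A path item's complexity is
the entropy of its normalised vertex-degree distribution (endpoints 1,
interior 2) — for a self-avoiding path this depends only on the node count,
which is exactly the feature the generator varies. A maze combines the
degree-distribution entropy of the whole maze graph (`C_m`) with two
solution terms along the A* shortest path of `L` cells: the mean
`log2`-degree over solution cells (`C_s`) and the length term
`C_l = log2 L`, composed as `C_play = 0.4 (C_m + 10 (C_s + C_l))` — the 10
balances the solution terms against the range of `C_m` and the 0.4 brings
the total onto a scale comparable with the other games. `L` counts cells
including both endpoints (`L = 1` when start equals end), and entropies use
base 2 with `0 log 0 = 0` throughout.

## Item generators

`generate_item()` hits a target complexity `c_d` within a tolerance
(default `0.25`): draw a random initial item, then repeatedly change one
feature — one cell's shape, the node count of the path, the maze end point —
keeping a change only if it moves `C_play` toward the target. Two
search-policy details matter and were chosen after observing how the
attainable complexity sets behave:

* Initial grids and sequences are drawn with a random *uniformity level* (a
  base shape diluted with iid shapes). Orderly items occupy a thin, gated
  region of complexity space that iid-uniform draws essentially never land
  in; the mixed initialisation makes restarts cover the whole band so the
  local search only refines.
* For grids, sequences and paths the single-feature neighbourhood is small
  enough to scan outright: the search takes the first improving neighbour in
  random order and restarts from a fresh random item only at a certified
  local optimum. Mazes use a sampled greedy walk of the end point (mostly
  one-cell moves, occasionally a jump) with a 200-proposal stagnation
  restart that regenerates the maze; end-point evaluations reuse a
  breadth-first tree from the start, so each proposal costs O(L) rather than
  a fresh search.

The attainable complexity set is discrete and, at small item sizes, gappy:
enumeration of all `14^5` length-5 sequences shows a single impassable gap
(about 6.56–7.23) between the orderly and disordered regimes, and similar
cliffs exist for 2×2 grids. `target_band()` records, per game at the default
sizes (3×3 grids, length-5 sequences, dimension-8 mazes), the band over
which replicated target sweeps met the tolerance contract on every call;
outside it `generate_item()` may raise a `cubecat_infeasible` condition
carrying the best item found. Shape-Matching is different by design: items
come from a pool of ten relational pattern families (uniform, colour
mirrors, checkerboard, strip-rotation stripes, triangle rotation orbits, and
3×3 variants) whose complexity is independent of the concrete shapes drawn,
giving a ladder of deterministic difficulty levels; the generator snaps to
the pool level nearest the target.

Mazes themselves are perfect mazes carved by randomised depth-first search
(every cell pair joined by exactly one path), so any start/end choice is
solvable and the spanning-tree wall count is a construction invariant.

## The adaptive engine

Sessions start at a predefined low complexity and react to correctness only:
correct answers climb by `up_step` (default 0.5) toward an absorbing
ceiling; a first miss regenerates an item at the same complexity; a second
consecutive miss reverts to the midpoint between the last correctly answered
complexity (the start complexity if none yet) and the current one. A session
ends on a correct answer at the ceiling, when an advance or revert step
falls below `min_step` (default 0.05), or at a `max_items` safety cap
(default 25). The zero step of a same-complexity regeneration deliberately
does not trigger the small-step rule — a single miss always gets a second
item — while the degenerate revert with no prior correct answer (midpoint of
start with itself) does, so a player who misses everything exits after two
items. Midpoint reverts contract the step geometrically, so termination is
guaranteed for every responder even without the cap. Whether the climb after
a recovered miss should resume at the full `up_step` is not externally
constrained; the engine resumes with `up_step`.

Adaptive scoring modifies the fixed tables: a correct answer on a
same-complexity regeneration earns one point less than the fixed award
(floored at zero), and a correct answer on the easier post-revert item earns
one point — implemented as `min(1, fixed)` so an answer that would score
zero under the fixed rules cannot gain a point from the deduction context.
Fixed-table time bands are half-open on the left ("within 15 seconds" is
`[0, 15]`, "between 15 and 30" is `(15, 30]`); the boundary membership is a
package convention applied uniformly.

## Simulated examinees

`player_model()` stands in for human participants: correctness is logistic
in the gap between item complexity and ability,
`P(correct) = 1 / (1 + exp(slope (C_play - ability)))`, and completion time
is linear in complexity with truncated-normal noise (defaults: 5 s base,
2 s per complexity unit, 1 s noise — placing simulated times in the range
the scoring bands expect). The linear time model and the logistic form are
modelling choices, isolated behind the player object; they encode only the
sign structure that validates the complexity measures — accuracy falls and
time rises with complexity — not any fitted human data.

`run_cohort()` re-enacts the validation design: a cohort (default 38
players in fixed mode, 42 in adaptive mode, the group sizes typical of such
evaluations) plays a fixed 12-item schedule, and per-item mean correctness
and mean completion time are Spearman-correlated with `C_play`
(`spearman_ci()`: average ranks, t-approximation p, Fisher-transform CI with
SE `1/sqrt(n - 3)`). Abilities are drawn uniformly over the middle 80% of
the schedule's complexity range so that correctness varies; a homogeneous
high-ability cohort on an easy schedule instead shows the ceiling effect —
near-perfect correctness with an undefined (zero-variance) correctness
correlation, while the time correlation survives.

What passing these simulations shows — and what it does not: the harness
verifies the internal consistency of the loop (complexity measures that
simulated performance tracks by construction will correlate with it). It
cannot show that the measures track *human* difficulty; symmetric
spatial-memory patterns, for instance, are easy for people to memorise yet
receive the same complexity as asymmetric ones here, a known limitation of
the measure, and no symmetry penalty is applied.

## Numerical and testing choices

Problem sizes used by the test-suite demonstrations were chosen to exercise
the contracts at meaningful scale: exhaustive co-occurrence verification
over all grids up to 3×3 on a three-shape alphabet, 1000 seeded generator
calls per game across each game's `target_band()`, 100-seed
threshold-responder recovery runs on dimension-8 mazes, 100-replicate
cohorts per game, and 200 maze solver cross-checks against breadth-first
search. Adaptive demonstrations use mazes with `start_c = 15`,
`ceiling_c = 25`, chosen inside the maze band so that an always-correct
staircase reaches the ceiling within the item cap.

Degenerate inputs are pinned down explicitly: empty compositions score 0;
single-shape sequences have no pairs and `C_config = 0`; an all-zero
co-occurrence matrix has weighted entropy 0 (with a warning when requested
directly); a maze whose end equals its start has `L = 1` and `C_l = 0`;
ties in Spearman ranks use average ranks and zero rank variance is an
error rather than a silent `NA`.
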