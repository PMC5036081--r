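---
title: "Morphological cladistics with cladistica: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological cladistics with cladistica}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladistica)
```

## The problem

Fossil and extant taxa scored for discrete skeletal characters — here the
motivating system is beaked whales (Ziphiidae), scored 34 taxa × 51
characters — are analysed by maximum parsimony: find the unrooted binary
topologies minimizing the number of implied character-state changes, weigh
homoplastic characters down if desired, attach resampling support to
clades, and read the result against geological time. `cladistica`
implements that whole workflow on ape `phylo` trees and a `char_matrix`
container that keeps per-cell state *sets* (so polymorphic codings such as
`{01}` and missing entries `?`/`-` survive IO and scoring).

## Scoring model

Characters are typed `binary`, `ordered` (additive/Wagner) or `unordered`
(non-additive/Fitch). Unordered characters cost one step per state change
and are scored with the Fitch pass (bitmask state sets; a polymorphic tip
starts with all its coded states available at no cost, a missing tip with
the whole alphabet). Ordered characters cost `|i - j|` per change and are
scored with the Sankoff dynamic program under the linear step matrix; the
same routine with a unit matrix reproduces Fitch counts, which the test
suite exploits as a dual-route check, alongside a brute-force enumeration
of internal labelings on small trees. Trees with polytomies are scored
with the general Sankoff recursion, which is exact on multifurcations
(pairwise Fitch folding is not).

Per character, `m` is the minimum conceivable number of steps on any tree
(states forced by monomorphic tips, with a greedy set cover over
polymorphic ones; the state range for ordered characters) and `g` the
number of steps on the star tree (mode count for unordered; minimized sum
of absolute deviations from the best integer center for ordered). From
steps `s_i` on a given tree:

* tree length `S = sum(s_i)`,
* extra steps `es_i = s_i - m_i` (homoplasy),
* Goloboff implied-weighting fit, reported with the conventional negative
  sign: `fit = -sum(K / (K + es_i))`, so a homoplasy-free matrix scores
  `-n_char` and *better* trees have *more negative* fit,
* ensemble consistency index `CI = sum(m)/sum(s)` and retention index
  `RI = (sum(g) - sum(s)) / (sum(g) - sum(m))`.

Whether published ensemble indices include parsimony-uninformative
characters (those with `g = m`) varies between programs, so `score_tree()`
reports both conventions (`ci` over all characters, `ci_informative`
excluding `g = m` ones); characters with `g = m` are always excluded from
the RI sums to avoid 0/0. `fit` sums over all characters.

## Search

Three modes share one engine:

* `exhaustive_search()` enumerates all `(2n-5)!!` unrooted topologies by
  sequential taxon insertion (≤ 10 taxa). It exists to be trusted, not to
  be fast, and serves as the oracle for the other modes.
* `branch_and_bound()` prunes an insertion branch when a lower bound on
  any completion exceeds the best score seen. The bound is the partial
  tree's score — adding taxa can only add steps — plus a per-level
  completion term: states required by a still-unplaced monomorphic tip
  that no placed tip can provide cost at least one further step each
  (unordered), and ordered characters must at least extend from the placed
  tips' reachable range to the outermost state still required. Under
  implied weighting the per-character bound enters through
  `es >= s_partial + extra - m_full`, which is admissible because the
  penalty is monotone in `es`. Admissibility is not taken on faith: the
  acceptance suite re-derives 200 random 6–9-taxon matrices under both
  criteria and demands exact agreement with exhaustive enumeration, sets
  and scores alike. The initial upper bound comes from a greedy
  stepwise-addition tree refined by SPR.
* `heuristic_search()` does seeded random-addition starts, hill-climbs
  with SPR (NNI and TBR are available), then closes the set of equally
  best trees by swapping from every optimum until no new one appears, so
  the returned MPC set is stable under the chosen neighborhood.

Equally optimal trees are compared after applying a branch-collapse rule.
The default, `min_length_zero`, collapses an internal branch when every
character admits a most-parsimonious reconstruction with no change on it
(computed exactly from per-character inside/outside cost vectors); `none`
keeps binary resolutions. Counts of "distinct MPCs" depend materially on
this convention, which is why both are exposed. Topology identity is
decided by bipartition sets, never by newick string comparison.

Scores are doubles; two scores within `1e-9` are treated as tied. That
tolerance also gives the implied-weighting criterion a clean equal-weights
limit: at `K = 1e6` fit differences between equal-length trees fall below
it, and `k_sweep()` then returns exactly the equal-weights MPC set.
`k_sweep()` reports the partition of the concavity grid into intervals of
constant MPC set; the default grid is 1–20 plus a coarse geometric tail to
1405, covering the range over which published ziphiid analyses report
stability breakpoints without stepping through every integer.
`K = 3` is the conventional default concavity in this literature.

## Resampling support and MPC selection

`resample_support()` perturbs the matrix, re-searches, and tallies
bipartitions; GC (group present/contradicted) for a clade is its recovery
percentage minus the percentage of its best-supported incompatible rival,
in `[-100, 100]`. The default scheme is symmetric per-character
reweighting with change probability `p = 0.33` (each character keeps
weight 1, or with probability `p` takes weight 0 or 2 with equal chance) —
the scheme TNT popularized for weighted analyses, where naive bootstrap
proportions are distorted; a plain character bootstrap is also available.
Per replicate the search is deliberately light (one random-addition start
plus SPR by default): support values are means over many replicates, and
this keeps 10⁴-replicate runs tractable. With one informative character
per clade a single down-weighting can erase a clade's support, so perfect
recovery (GC = 100) is only expected when clades are redundantly
supported; the tests construct such matrices explicitly.

`select_mpc()` reproduces the published selection procedure for implied
weighting sweeps: every candidate MPC is scored by its summed GC over
internal branches using one shared resampling run (sums are then
comparable across K), with ties broken by resolution (more internal
branches) and then by better (more negative) fit at the candidate's own K.

## Stratigraphic calibration

`calibrate()` turns a rooted cladogram plus a `calibration_set` (node
constraints in Ma with explicit clade membership; tip ranges with an
extant flag) into a time tree. Tip age is the oldest bound of its range
(`range_top`, default) or the midpoint (`range_mid`). Ages propagate
rootward: an unconstrained node is `eps = 0.1` Ma older than its oldest
child (a drawable minimal internode); a constrained node sits at its
constraint unless a child is older, in which case the child wins and the
constraint is reported as *dominated* rather than silently violated. A
constrained node may coincide exactly with an equally old calibrating tip
(zero-length branch), which is what keeps, e.g., a subfamily node pinned
at the age of its oldest fossil member rather than `eps` above it.

Two data-quality rules matter for fossil compilations: verbal ages
("Neogene", "probably middle Miocene–Pliocene") are resolved through a
shipped epoch table into wide ranges flagged `low_confidence`, and such
tips are *not* allowed to push ancestors back in time — they are drawn at
their range top but clipped to their parent's age when older. Without
this, a single "middle Miocene–Pliocene" phosphorite taxon (range top
15.97 Ma) would drag every node above it past well-dated constraints.
`validate_timetree()` checks the no-negative-branch invariant, lists
binding/dominated constraints, and flags tips whose entire range is older
than their parent.

The shipped beaked-whale calibration tables mirror the published node and
tip age compilations; one row is adjusted to the text's stated procedure
(the stem clade's constraint is the 13.8 Ma upper stratigraphic limit of
its calibrating specimen, not that specimen's full range). The
accompanying topology file is a *synthetic stand-in* assembled from the
clades named in the publication's text, because the selected cladogram
itself is only deposited as supplementary material; it exercises the
calibration and mapping code and is not a result of this package.

## Trait mapping and morphometrics

`map_discrete()` returns most-parsimonious-reconstruction state sets per
node (a state is kept when some optimal reconstruction places it there,
computed from inside/outside Sankoff vectors) and a change count that
equals the Fitch step count of the same column — asserted against
`fitch_steps()` in the tests. The shipped four-area coding (southeastern
Pacific + North Atlantic + Mediterranean; southern oceans; cosmopolitan;
antitropical) treats "cosmopolitan" as its own state rather than a
polymorphism of regions: the published figure legend presents it as a
distributional category in its own right, and an editable TSV lets users
recode it.

`map_continuous()` uses squared-change parsimony: internal values solve
the linear system in which each internal node is the mean of its
neighbors, so the reconstruction is the unique minimizer of the summed
squared parent–child differences and every ancestral value is a convex
combination of tip values. Branch lengths are ignored (cladograms here
carry none); linear-change parsimony would be a possible extension but the
squared-change form is what desktop mapping tools default to. A black-box
optimizer cross-checks the objective to 1e-8 in the tests. The body-size
proxy is the postorbital width of the skull passed through a user-supplied
regression; published width-to-length coefficients are external data and
are deliberately never hard-coded — the identity transform (width in mm)
is the default.

`morph_ratio()` rounds half-up to 2 decimals because that is how
comparative skull tables print ratios (base R's round-half-even would turn
119/290 into 0.41 either way, but 0.125-type cases differ).
`verify_ratios()` recomputes printed ratios from the measurement tables
and reports discrepancies (one published asymmetry ratio prints 0.82 where
the tabulated widths give 0.83) instead of reconciling them.

## The synthetic-data generator

`simulate_matrix()` evolves each character independently along a
`simulate_cladogram()` Yule tree: unordered characters jump to a uniformly
chosen other state, ordered characters take ±1 steps reflecting at the
ends of their range (states never leave the declared alphabet), and the
number of change events per branch is Poisson with mean `rate` — per
branch, not per unit branch length, so internal and terminal branches are
equally informative and the "rate" knob reads directly as expected changes
per branch per character. Missing and polymorphic cells are injected
afterwards at configured rates (polymorphism adds an adjacent state for
ordered characters). The generator records the true number of change
events per character; parsimony steps on the generating tree can never
exceed it, which the tests assert. Defaults emulate the motivating data
set's shape: 34 taxa, 51 characters split 28/19/4 across binary, ordered
and unordered, with 3-state multistate alphabets.

What the simulator does *not* emulate: correlated character evolution,
heterotachy, character-state ordering errors, and non-random
missingness (fossil incompleteness concentrates missing data in whole
anatomical regions, not uniformly across cells). Passing recovery tests
on this generator therefore says the inference machinery is correct, not
that real morphological matrices are this well behaved.

`recovery_experiment()` measures how often the generating tree is among
the MPCs. Membership is decided by score equality of the truth with the
optimum — mathematically the same thing for a binary tree, and immune to
the cap on how many tied trees the search enumerates. Two regimes
bracket the behavior: in the homoplasy-free limit (constructed
clade-membership characters) the generating tree is the unique MPC and
the ensemble CI is exactly 1; at the study-style setting of 0.05 changes
per branch over 50 characters and 10 taxa, roughly a fifth of characters
change more than once, and the resulting parallelisms strictly beat
weakly supported true branches in a substantial fraction of replicates —
the acceptance script computes the observed recovery rate (and the
consensus-to-truth Robinson–Foulds distance) at exactly those conditions
rather than asserting an optimistic constant. Recovery is non-monotone
in the rate: ties dominate as rate → 0, conflicting homoplasy as it
grows.

## Reproducibility

Every stochastic entry point (search, resampling, simulation, the
pipeline) takes an integer seed and restores the caller's RNG state;
repeated runs are bit-identical, which the tests assert for heuristic
search, resampling support, simulation, and the pipeline report.
`run_full_analysis()` echoes its configuration and seed into the report so
a report file fully determines its own recomputation.

## Problem sizes used by the tests

The packaged checks run exhaustive-versus-branch-and-bound equivalence on
200 random matrices of 6–9 taxa (both criteria), 1,000 unit-cost
Sankoff/Fitch agreements, 100 squared-change optimizations against a
numerical optimizer, a 50-replicate recovery experiment at the
10-taxon/50-character setting, and resampling support runs of a few
hundred to 10,000 replicates on small matrices. These sizes exercise every
code path exactly (the exact searches are verified, not sampled) while
keeping a full run in the low minutes on one core; the same machinery
scales to the 34 × 51 study shape, where a 20-start heuristic search with
TBR refinement is the intended tool rather than branch and bound.

## Known limitations

* Branch and bound is practical to roughly 15–20 taxa on informative
  matrices; beyond that the heuristic search is the supported path, and
  like all hill-climbers it guarantees only local optimality (mitigated by
  multiple starts and the equal-score closure).
* Implied weighting uses the standard per-character fit; extended
  variants (e.g. missing-data-corrected fits) are not implemented.
* GC values from light per-replicate searches can understate support on
  rugged landscapes; raise `starts` per replicate when that matters.
* The calibration model is a drawing rule (oldest-age propagation with a
  minimal internode), not a statistical clock: no rate model, no
  uncertainty on node ages.
* State alphabets are capped at 16 states per character.
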