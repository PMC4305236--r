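---
title: "Scaffold anchoring by weighted colinearity: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold anchoring by weighted colinearity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`mapanchor` treats every kind of genomic map — genetic, optical,
comparative — as a bag of markers `(x, y)`: a physical position `x` (bp,
0-based) on a scaffold and a map position `y` (cM for genetic maps; any
linearly scaled unit otherwise; linear rescaling provably cannot change the
optimization, since the longest-monotonic-subsequence statistic depends
only on the ordering and ties of `y`).

Given a signed ordering of the scaffolds of one chromosome, each map
induces a sequence of `y` values (markers sorted by ascending `x` within a
forward scaffold, descending within a reversed one). Colinearity with that
map is measured by the **LMS**: the larger of the longest non-decreasing
and non-increasing subsequences. Non-strict monotonicity is a deliberate
choice: a dense genotyping-by-sequencing map places many markers in one
recombination bin (identical `y`), and those markers must all be creditable
to a colinear run; strict LIS would penalize exactly the maps with the best
physical resolution. The objective is the weighted sum over maps,

$$L = \sum_{j \in G} w_j \,\mathrm{LMS}_j,$$

and the anchoring problem is to maximize `L` over signed scaffold
permutations — NP-hard in general, hence the two-phase heuristic.

Assumptions worth keeping in mind: markers are point observations (a
ranged optical/synteny match is collapsed to its interval midpoint);
map errors are either cross-chromosome (handled by clustering/chimera
skipping), locally erratic (handled by the outlier test), or ordering
conflicts (handled by the weighted objective itself); and each scaffold is
structurally intact — chimeric scaffolds are flagged and skipped, never
split.

# Pipeline stages and their parameters

## Preprocessing

* **Pivot map** — the largest weight, ties broken by input order. The
  pivot fixes the chromosome count, so it should be the map with a full
  complement of linkage groups.
* **Linkage-group clustering** — each non-pivot group joins the pivot
  group with the most shared scaffolds (ties to the earlier cluster);
  groups sharing no scaffold are reported and set aside rather than forced
  into a cluster, because forcing them could only inject cross-chromosome
  noise.
* **Scaffold assignment** — argmax over clusters of
  $\sum_j w_j \cdot |\text{markers}|$. Equality at the maximum is taken
  literally (no tolerance): the counts are integer combinations of user
  weights, so exact ties are exactly the ambiguous cases, and those
  scaffolds are alerted as chimeric and skipped.
* **Outlier markers** — per (scaffold, map, linkage group), the
  Iglewicz–Hoaglin modified z-score $z_i = 0.6745\,(y_i - \tilde y)/\mathrm{MAD}$
  with cutoff `|z| > 3.5` (both configurable; the constants are the
  published recommendation of the cited test — the method itself names the
  test without printing thresholds). Guards: groups of fewer than 3
  markers and zero-MAD groups are never filtered (a zero MAD means a
  recombination bin, not an error).

## Phase 1 — initial configuration

* **Orientation.** The pairwise score is, per map,
  `max(LMS(a||b), LMS(b||a)) − max(LMS(a||−b), LMS(−a||b))`, summed with
  weights. The naive one-directional difference `LMS(a||b) − LMS(a||−b)`
  is not symmetric and mis-signs same-orientation pairs whose markers lie
  *against* the map's reading direction (try `a = [3,4]`, `b = [1,2]`:
  the one-directional score is −1 although the pair is perfectly
  colinear). Because reversal leaves LMS invariant, `b||a` covers the
  both-flipped reading and `−a||b` the other opposite reading, so the two
  maxima exhaust all four sign combinations and make `o(a,b) = o(b,a)` by
  construction — which the spectral step requires. Orientations are then
  the signs of the leading (largest algebraic eigenvalue) eigenvector of
  the symmetric matrix `M`; components below `1e-9` in magnitude are
  treated as undetermined, and the global sign is fixed so the first
  non-zero component is positive (overall polarity is arbitrary).
* **Undetermined orientation** is a *property of the data*, not of the
  eigenvector: a scaffold with at most one marker on every map cannot have
  its flip observed by any map, keeps orientation 0 through the pipeline
  and is written as `?` in the AGP. A scaffold whose eigenvector component
  merely happens to be ~0 starts forward and is refined downstream —
  freezing it would make parts of the search space unreachable.
* **Ordering.** `d(a,b)` is the weighted minimum `|y − y'|` over marker
  pairs. When a map sees only one of the two scaffolds it contributes the
  full span of that map's positions — a neutral "no evidence" penalty that
  neither attracts nor repels (0 would glue unrelated scaffolds together).
  The order minimizing adjacent distances is a Hamiltonian path, reduced
  to a cyclic tour with a zero-cost dummy node and solved by deterministic
  multi-start nearest-neighbour construction (dummy plus up to 8 evenly
  spaced city starts) with 2-opt and Or-opt (segments of 1–3) improvement.
  An exact external solver can be plugged in via `initial_order(solver=)`,
  but is unnecessary: Phase 1 only needs to land near the optimum, which
  Phase 2 then reaches under the true objective.

## Phase 2 — genetic algorithm

Individuals are **signed permutations** — order and orientation evolve
jointly. The whole population starts as copies of the Phase-1 solution
(diversity comes from mutation; seeding anything else only slows
convergence on this problem). Per generation: tournament selection (size
3), PMX crossover with probability 0.7 on consecutive pairs (signs travel
with their scaffold), and with probability 0.2 a mutation that is either an
*inversion* — reverse a random stretch **and** flip its orientations, as a
biological inversion would — or an *insertion* — translocate one scaffold.
Elitism of 1 re-injects the best-ever individual over the generation's
worst, so the best fitness trace is non-decreasing and the result can never
be worse than the input. A GA round ends after `ngen = 1000` generations
without improvement (`npop = 100`; both runtime-adjustable — the scaled
test-suite runs use windows of 120–300, noted where used); a greedy flip
pass then re-optimizes orientations one scaffold at a time, and
order-then-flip rounds repeat until `L` stops improving. The sign-carrying
inversion matters: with order-only search plus greedy flips, coupled
order+orientation optima are unreachable and about 8% of small random
instances stall below the exhaustive optimum; with it, 100/100 reach the
optimum.

All randomness flows from one caller seed (`set.seed` at entry;
chromosome *k* of a multi-chromosome run uses `seed + k`), so identical
inputs and seed give byte-identical outputs.

Reported configurations are canonicalized so the pivot map reads
increasing where possible (global reversal leaves `L` unchanged; a guard
verifies this and keeps the original if a degenerate configuration would
lose score).

## Genome release

Pseudomolecules concatenate scaffolds with `N` gaps (default 100 bp,
configurable; per-junction estimates optional), reverse-complementing `-`
scaffolds and writing `?` scaffolds forward. AGP is emitted in the 2.0
dialect with gap rows `U / scaffold / yes / map`; CHAIN records use UCSC
semantics (target = chromosome, query = scaffold, strand `-` with a single
full-length block per placement, score = block length, which liftOver
ignores). The summary table counts, per map and overall, linkage groups,
unique markers, marker density, scaffolds anchored by marker-count bins
(1 / 2 / 3 / ≥4), N50 scaffolds (scaffolds at least as long as the
assembly N50), and bases with percent of genome; anchored plus unplaced
always reconciles to the assembly totals.

## Gap estimation

Per map with ≥4 chromosome markers, a cubic spline (`stats::splinefun`,
"fmm"; duplicate physical positions averaged) interpolates map position
against the provisional fixed-gap coordinates; its derivative at the
junction midpoint is the local recombination rate (map units per bp,
absolute value — polarity is arbitrary). Every flanking marker pair gives
`gap = Δy / rate − overhang_left − overhang_right`, with overhangs measured
to the exclusive scaffold end so that for a perfectly linear map the
pair separation decomposes exactly as overhang + gap + overhang. The
junction gap is the smallest estimate over all pairs and maps — the
rationale being that overestimates (rate dips, map expansions) are common
and the tightest consistent pair is the best-supported — clamped to
[10 bp, 1 Mb] because the derivative can approach zero near recombination
deserts; junctions without flanking markers keep the default gap. The
spline is fitted once against provisional coordinates; estimated gaps do
not feed back into a second spline pass (the correction is second-order
and a fixed point is not guaranteed).

# The simulator: what it emulates and what it does not

The generator reproduces the published evaluation design: a genome of 8
equal chromosomes totalling 366 Mb (per-chromosome lengths are not
published; equal lengths keep the per-chromosome problem sizes comparable),
cut into scaffolds whose lengths follow a log-normal fitted to the three
published statistics of the reference preliminary assembly — 20,591
sequences over 366 Mb (mean 17.8 kb) and N50 46 kb give
$\sigma = 1.379,\ \mu = 8.834$ via mean $= e^{\mu+\sigma^2/2}$ and
length-weighted median $= e^{\mu+\sigma^2} =$ N50 — truncated at the
published maximum of 346 kb. Reduced scaffold counts scale lengths up,
preserving the shape. 8,000 markers are placed uniformly; each map
independently keeps each marker with probability 2/3; map positions are
physical positions at a constant 2 cM/Mb (the published design does not
state a rate profile; constancy is irrelevant to ordering and convenient
for gap tests, and a variable-rate profile can be emulated by transforming
`map_pos`). Errors: inversions reverse contiguous marker runs (geometric
lengths, mean 20) until a fraction `p_inv ≤ 0.5` of each chromosome's
markers is involved; translocations move runs (geometric, mean 5) to
uniform random map positions, 75% within the chromosome and 25% onto a
random other chromosome — the latter relabels the linkage group, which is
what stresses the clustering stage. The run-length laws are our choice;
the published design fixes only the marker budgets.

**Accuracy** orders the truth markers by their reconstructed position and
takes LMS of their true positions per chromosome, summed and divided by the
marker count. Markers never drawn into any map are excluded: they carry no
anchoring information, and a scaffold whose only true markers are unmapped
may legitimately be unplaced or unoriented. Mapped markers on unplaced or
mis-clustered scaffolds (a scaffold landing on a reconstructed chromosome
whose marker majority is another true chromosome) still count in the
denominator. Under this definition an error-free map is recovered at
accuracy exactly 1.0 end-to-end, which is what the green acceptance test
establishes — together with the qualitative behaviors: accuracy decays
with `p_inv`, and two clean maps rescue one corrupted map.

What the simulator does **not** emulate — so green tests do not establish
robustness to it: real marker ascertainment (markers cluster in genic,
low-repeat regions rather than uniformly), recombination-rate variation
along chromosomes (suppressed centromeres), genotyping-error tails,
scaffold-level misassemblies (true chimeras), N-runs inside scaffolds, and
the correlated error structure of optical-map alignment.

# Numerical choices and degenerate inputs

* LMS by patience sorting with right-insertion binary search (ties extend
  runs), O(n log n); kernels in C++.
* Score comparisons use an absolute epsilon of 1e-9 (scores are weighted
  integer counts; the epsilon only guards float weight sums). Flips and GA
  acceptances require *strict* improvement, so passes terminate.
* Ties everywhere resolve to input order (clusters, tournament index,
  brute-force lexicographic order), for reproducibility.
* Empty inputs: empty BED gives an empty collection; a chromosome with no
  scaffolds yields an empty configuration; an all-zero orientation matrix
  yields all-undetermined signs; maps absent from the weights file weigh
  1, a missing weights file warns and weighs everything 1.
* Marker BED intervals are 0-based half-open with the marker at
  `floor((start+end)/2)`: GBS markers are 1 bp wide and keep their
  coordinate, ranged matches use their centre (the interval convention is
  not fixed by the format's originator; midpoint is symmetric under strand
  flips of the source alignment).
* Duplicate rows: byte-identical rows are dropped once (re-merged inputs),
  but rows differing only in map position are genuinely distinct
  observations and all count in LMS.

# Known limitations

* Chimeric scaffolds are skipped, not split; the method relies on
  reasonably clean scaffolds.
* The TSP heuristic is a local-search approximation; pathological distance
  matrices can start Phase 2 far from the optimum (Phase 2 then bears the
  cost, not the correctness, of convergence).
* Gap estimates near recombination-rate zeros hit the clamp bounds and
  should be read as "no information", not as measurements.
* Parallel fitness evaluation is not implemented; the C++ kernels make the
  serial GA fast enough at the tested scales (a `--cpus`-style option
  would have to reproduce serial results exactly to honor the determinism
  contract).
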