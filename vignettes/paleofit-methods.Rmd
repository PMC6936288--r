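---
title: "Methods: stratigraphic congruence, ancestral areas and parsimony fit"
author: "paleofit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratigraphic congruence, ancestral areas and parsimony fit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleofit)
```

paleofit confronts rooted phylogenies of fossil taxa with three kinds of
evidence: stratigraphic occurrence (when each taxon first appears in the
rock record), geography (where it appears), and character data (what it
looks like). This vignette documents the models behind each analysis, the
conventions and tunable parameters, what the synthetic-data generators do
and do not emulate, and the numerical choices a maintainer would want
written down.

## Ghost lineages and the gap excess ratio

Ages are first-appearance data (FADs) in Ma, larger = older. A cladogram
makes a stratigraphic claim: when two sister lineages diverge, both must
exist from the divergence onward, so if one appears earlier in the record
the other carries a *ghost lineage* — an implied but unsampled duration.
paleofit dates every node by the oldest FAD among its descendant tips
(`node_min_ages()`), the minimal assumption consistent with the topology.
Branch lengths in input trees are deliberately ignored: every age in this
package derives from occurrence data, never from the cladogram.

With node ages in hand, the ghost lineage on the branch to node $v$ is
$a(\mathrm{parent}(v)) - a(v) \ge 0$, and the **minimum implied gap** is

$$\mathrm{MIG} = \sum_{v \neq \mathrm{root}} \big(a(\mathrm{parent}(v)) - a(v)\big).$$

Two bounds depend only on the FAD multiset: $G_\min = \max f - \min f$,
the MIG of a pectinate tree with taxa ordered oldest-outermost (a tested
property, not an assumption), and
$G_\max = \sum_i (\max f - f_i)$, attained when the oldest taxon is
maximally nested so that every other taxon expresses its full gap. The
**gap excess ratio** locates a topology between those extremes:

$$\mathrm{GER} = 1 - \frac{\mathrm{MIG} - G_\min}{G_\max - G_\min} \in [0, 1],$$

with 1 the best possible fit of topology and stratigraphy and 0 the worst.
GER is invariant to shifting all FADs by a constant and to rescaling them
by a positive factor; MIG, $G_\min$ and $G_\max$ scale linearly. When all
FADs coincide, $G_\max = G_\min$ and the ratio is undefined; paleofit
raises an explicit error rather than returning NaN.

Conventions:

* **FAD-only.** LADs are carried in occurrence tables for range reporting
  but never enter MIG, $G_\min$ or $G_\max$: congruence is about
  origination times.
* **Hard polytomies by default.** Each child of a polytomy is dated
  against the polytomous parent, because published hypotheses under
  comparison should be scored as-is. `resolve_polytomy_min_mig()` exposes
  the soft reading: every polytomy is replaced by the pectinate
  arrangement of its child subtrees, oldest outermost, which provably
  attains the minimum MIG among all binary resolutions (verified in the
  tests by exhaustive enumeration for polytomies of up to 5 children).
* **Clade age constraints** ("this clade is at most as old as taxon X")
  need no machinery: a clade's age is the max FAD of its members, so
  including X in the clade with its FAD realizes the constraint.
* **Determinism.** Wherever an order must be chosen (pectinate
  constructions with tied ages), ties break by lexicographic taxon label.

`compare_topologies()` prunes each candidate tree to the taxa it shares
with the table (and an optional scope), computes all four quantities on
each tree's own surviving taxon set, and flags the highest-GER tree. Since
$G_\min$/$G_\max$ are per-taxon-set, rows with different `n_taxa` are not
directly comparable; the count is reported precisely so they are not
naively compared.

## Ancestral areas on consensus trees

Terminal taxa are assigned one area each — by convention the continent
yielding the oldest material confidently assigned to the species — giving
indicator distributions at the tips. `node_area_probabilities()` then
recurses tip-to-base: an internal node's distribution is the **arithmetic
mean of its children's distributions**, with a $k$-child polytomy averaged
over all $k$ children.

The mean rule is the package's reading of combining children by the rules
of multiplication and addition: enumerate equiprobable scenarios of which
child lineage retains the ancestral area (products within a scenario, sums
over mutually exclusive scenarios), with equal weights. On a binary tree
every probability it produces is dyadic ($k/2^d$) — matching fractions
such as $3/4$ and $5/8$ that this style of tip-to-base bookkeeping yields
in practice — and the output is invariant to child order. The rule is
isolated behind a single argument, and an alternative (`rule = "product"`,
the normalized elementwise product, falling back to the mean with a
warning where child supports are disjoint) is included for sensitivity
reporting.

This is deliberately *not* a likelihood biogeographic model: there is no
dispersal matrix, no rate estimation, no DEC/DIVA machinery, and fossil
and extant tips are treated identically. The method quantifies what the
consensus topology plus tip areas alone imply; it says nothing about
unsampled ranges. `area_report()` resolves focal clades by MRCA and only
warns (rather than failing) when the MRCA subtends extra tips, because on
consensus trees with polytomies strict monophyly checks are brittle.

## Parsimony fit of character matrices

Character lengths are computed by Sankoff dynamic programming over the
rooted tree with a per-character cost matrix: unit costs for unordered
(Fitch) characters, $|i - j|$ for ordered (Wagner) characters. Polytomies
are handled natively. Cell conventions:

* **Polymorphic tips score any-of** (cost 0 for each listed state). This
  is one of several conventions in circulation — PAUP* can also treat
  polymorphism as all-of — chosen because it composes cleanly with
  missing data and is the common morphological default. Published lengths
  computed under the other convention can differ by a few steps; the
  divergence risk is documented here rather than silently absorbed.
* **Missing (`?`) and gap (`-`) cells cost 0 for every state.** The gap
  symbol is recorded on parse but treated as missing everywhere, the
  conventional reading for morphological matrices (gap-as-fifth-state is
  a molecular convention this package does not support).
* Internal states range over the character's observed state universe; for
  linear costs this loses nothing because message functions are convex
  and piecewise linear with breakpoints at observed states.

Per character, `m` (`char_min_steps()`) is the smallest number of steps on
*any* tree: for unordered characters, one less than the size of the
smallest state set hitting every scored cell (polymorphic representatives
chosen freely, found exactly by subset enumeration over the small state
universe); for ordered characters, the width of the narrowest interval
hitting every cell. `g` (`char_max_steps()`) is the star-tree length,
evaluated exactly by minimizing over root states. From per-character
$(s, m, g)$, `tree_fit_indices()` assembles the ensemble indices
$\mathrm{CI} = \sum m / \sum s$,
$\mathrm{RI} = (\sum g - \sum s)/(\sum g - \sum m)$,
$\mathrm{HI} = 1 - \mathrm{CI}$, $\mathrm{RC} = \mathrm{CI}\times\mathrm{RI}$.
Parsimony-uninformative characters ($g = m$) are always excluded from the
RI sums; `exclude_uninformative = TRUE` additionally drops them from the
CI/HI sums. Both conventions are provided because published CI and HI
values are frequently reported under different character-inclusion rules
by the same program run, so a single convention cannot reproduce both.

**Unambiguous synapomorphies.** A change is credited to a branch only if
*every* minimum-cost reconstruction places one there. The test is a
constrained re-run of the DP: force the branch's endpoints to carry equal
states (an up-pass provides the cost of the rest of the tree for each
parent state) and compare the constrained optimum with the unconstrained
tree length; a strict increase means no optimal reconstruction avoids the
change. One consequence worth knowing: for a child of the root of a
basally dichotomous tree, a single change can usually sit on either
root-adjacent branch, so basal synapomorphies are ambiguous unless an
outgroup pins the root side. The reported derived state is the set of
states the clade's node takes across optimal reconstructions.

## Synthetic data: what it emulates and what it does not

The generators produce the three input kinds with controlled structure,
all bit-reproducible under `(config, seed)`; each generator derives its
RNG stream from the seed with a fixed per-operation offset, so the same
configuration always yields the same joint dataset.

* `simulate_tree()`: pure-birth (Yule) topologies via `ape::rphylo`,
  rescaled to the configured root age. No extinction, no fossilized
  birth-death process — GER testing needs topology plus FAD ranks, not a
  realistic diversification model.
* `simulate_fads()`: the `congruence` parameter steers the expected GER.
  At 1 it assigns subtree-constant ages strictly decreasing along a
  root-to-tip path, which attains $\mathrm{MIG} = G_\min$ (GER exactly 1)
  on binary trees. The ties are essential, not an implementation
  shortcut: a balanced four-tip tree cannot reach $G_\min$ with four
  distinct FADs (its best MIG exceeds $G_\min$ for every assignment), and
  on a star tree MIG $\equiv G_\max$, so GER 1 is unattainable there for
  any assignment. At 0 it pins a dominating set of tips (one per
  tip-bearing node, chosen bottom-up) to the root age, which forces
  every remaining taxon's full gap onto its terminal branch:
  $\mathrm{MIG} = G_\max$, GER exactly 0. Intermediate values blend the
  two age vectors linearly; the blend is monotone in expectation (rank
  correlation with realized GER ≈ 0.89 at 16 tips over 200 seeds in the
  packaged check) but individual draws are noisy, as they should be.
* `simulate_characters()`: symmetric $k$-state change process; per branch
  a Poisson number of events proportional to branch length (scaled so a
  character expects `change_rate` changes over the tree), each event
  moving to a uniformly chosen different state. The realized event count
  per character is recorded so tests can assert that parsimony length
  never exceeds the true number of changes. Optional missing/polymorphism
  injection is uniform at the configured per-cell rates — real
  morphological missingness is taxon- and anatomy-structured, so passing
  tests here say nothing about non-random missingness.
* `simulate_tip_areas()`: root area drawn uniformly, per-branch switch
  with the configured probability. No geography, adjacency or
  area-specific rates.

None of the generators emulate preservation biases, correlated characters
or time-varying rates; tests built on them validate the *arithmetic* of
the analyses, not the realism of any empirical dataset.

`americhelydia_fixture()` packages a worked marine-turtle example: four
competing arrangements of the americhelydian lineages (differing in where
the protostegids and *Allopleuron* attach) over nine terminals, with FADs,
LADs and continent-level areas. One record (*Asmodochelys*: 79–74.5 Ma,
North America) is stated outright by the describing literature; the rest
are illustrative stand-ins consistent with the published fossil record,
and the table's `provenance` column keeps the two apart so the fixture is
never mistaken for a study's occurrence supplement.

## Numerical choices

* Probability vectors must sum to 1 within `1e-9`; the degeneracy test
  $G_\max - G_\min$ uses `1e-12`; GER is clamped to $[0, 1]$ only against
  float dust at the closed endpoints.
* Strict-increase tests in synapomorphy detection use `1e-9` on top of
  integer-valued costs, so they are exact in practice.
* Infinite tip costs appear only in tip rows of the DP tables and are
  never subtracted; internal-node costs are always finite.
* All durations are kept at full float precision; rounding (4 decimals in
  TSV output) happens only in the report layer.
* Exhaustive oracle suites in the tests run at sizes where enumeration is
  exact and fast: all 15 rooted topologies on 4 tips; random FAD sets
  against all topologies on up to 6 tips (945 trees); 10,000 random
  DP-versus-enumeration character instances on up to 6 tips and 4 states;
  all binary resolutions of polytomies with up to 5 children; and 1,000
  seeded congruence-extreme cases. These sizes were chosen so the whole
  suite completes in well under a minute while every enumeration remains
  exhaustive.

## Known limitations

* NEXUS support covers DATA/CHARACTERS and TREES blocks (flat and
  interleaved matrices, translate tables). ASSUMPTIONS/TYPESET blocks are
  not parsed — ordered-character lists are supplied explicitly
  (`set_ordered()`, `--ordered`) because the dialect varies too much
  across programs to parse reliably. Quoted taxon labels containing
  spaces are supported in Newick but not inside NEXUS matrices.
* Other congruence indices (SCI, RCI, MSM*), randomization tests for GER,
  tree search, supports and Bayesian inference are out of scope; trees
  are always inputs.
* `compare_topologies()` intentionally refuses to hide taxon-coverage
  differences; interpreting rows with different `n_taxa` is the user's
  responsibility.
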