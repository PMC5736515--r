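---
title: "Rule-based exploration of chemical space: methods and design"
author: "rxnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based exploration of chemical space: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rxnet` generates chemical structures by iterating reaction rules over a
growing set of molecules. This vignette documents the model behind each
module, the parameters that matter, the numerical and design choices made
where several consistent definitions exist, and what the package's synthetic
fixtures do and do not establish about real data.

## The breadth-first core

The engine maintains a **source** set (structures rules are fired on this
iteration) and a **sink** (every structure seen so far, tracked by canonical
key). One iteration fires every rule on every source structure, sanitizes
the products (valence cap, small-ring constraint), rejects any
single-structure product that has fallen apart into several fragments,
merges duplicates, and promotes the genuinely new structures to be the next
source. Enumeration stops when an iteration discovers nothing new or when
`max_iter` is reached. A FIFO-queue variant (`enumerate_queue()`) processes
the source in chunks for bounded memory; because the sink is shared, its
final structure set is provably the same, which the tests assert for chunk
sizes 1, 5 and 20.

**Iteration counting.** `enumerate_isomers()` reports two numbers:
`last_new_iteration` (when the final novel structure appeared) and
`iterations` (rounds fired, including the terminal empty round that detects
termination). The published alkane tables this package reproduces count the
terminal round — pentane gives 3 structures in "3 iterations" although the
last novel structure appears at iteration 2 — which we verified empirically
against the printed values at every N up to 12; the acceptance checks
therefore compare `iterations`. The proved N − 1 bound concerns productive
iterations and is asserted against `last_new_iteration`.

**Two-component rules** draw ordered pairs from the current source only,
not source × sink: the iteration semantics stay local to the round, and
results are reproducible without keeping the full cross-product history.

## Molecules and canonical identity

A molecule is a small vertex-labelled graph (atomic number, formal charge,
integer bond orders 1–3). Everything is kekulized; aromaticity models are
out of scope. Identity is the **connectivity-level canonical key**: terminal
hydrogens are folded into a per-atom hydrogen count, implicit hydrogens are
added up to standard (charge-adjusted) valences, the formal-charge layer is
then dropped, and the remaining graph is canonized exactly by colour
refinement with full individualization backtracking. Consequences:

* any two encodings of one connectivity (SMILES, InChI, explicit or
  implicit hydrogens) collide on the key, while distinct bond patterns do
  not — the tests cross-check this against standard InChIs on a panel;
* stereochemistry and protonation state are deliberately invisible;
* hydrogen folding keeps the canonical search off the large symmetric
  hydrogen cells of saturated molecules (a naive explicit-hydrogen search
  backtracks factorially on, e.g., neopentane).

The backtracking canonizer is exact (the code is the minimum over all
branches of an isomorphism-invariant cell choice); it is exponential in the
worst case but the molecules handled here (≤ ~50 atoms, near-tree shaped)
refine almost to discreteness immediately.

User-supplied SMILES/InChI strings are parsed by OpenBabel; because
OpenBabel silently repairs some malformed SMILES, a syntax pre-check
(balanced brackets, paired ring closures) enforces the parse-error contract.

## The rule dialect

No installed R package applies reaction SMARTS, so `rxnet` defines a
restricted, kekulized reaction-SMARTS dialect and implements matching
itself: organic-subset and bracket atoms, `[*]` wildcards, atom maps, bonds
`-`, `=`, `#`, `~` (unconstrained) and `!` (must-be-absent), branches, ring
closures, `.` separators and `(...)` component groups. Semantics:

* a bond drawn on the reactant side must be present with that order; a
  mapped pair bonded on the product side but not on the reactant side must
  be **absent** at match time; any other pair is unconstrained and preserved
  verbatim in products;
* mapped atoms missing from the product side are deleted; unmapped product
  atoms are created;
* a side wrapped in one group is matched intramolecularly and produces one
  product structure (rejected as a whole if disconnected); multi-component
  sides model true multi-molecule reactions and split products by connected
  component. Applying a one-group rule to *two* molecules (the crossover
  mode used by the stochastic search) spans the pattern across both and
  splits the products.

Embeddings are deduplicated first by their labelled bond-change signature
(two embeddings rewriting the same bonds give the same product), then by
product canonical key.

## Deriving the minimal rearrangement rules

A minimal valence-conserving transformation involves four atoms and the
four cycle bonds among them, with the canonical orientation
b₁₂ = a₁₂ − 1, b₂₃ = a₂₃ + 1, b₃₄ = a₃₄ − 1, b₁₄ = a₁₄ + 1; the diagonal
bonds are untouched and unconstrained. The reduction chain is implemented
as pure set filtering over the 81 feasible order tuples: the symmetry
normalization a₁₄ ≥ a₂₃ and a₁₂ ≥ a₃₄ (36 left, matching the
inclusion–exclusion count 81 − 27 − 27 + 9), the valence cap (removing the
9 tuples with a₁₂ = 3, a₁₄ = 2; 27 left), and the two small-ring
double-bond filters (4 reactant-invalid + 4 product-invalid tuples; 19
left).

**Numbering.** The surviving configurations are numbered R1…R19 by
lexicographic order of (a₁₂, a₂₃, a₃₄, a₁₄); figure layouts are not
machine-readable, so the published numbering is recovered only through
structural properties: the rules are pairwise distinct under label
permutation, closed under reversal, and exactly 3 are self-inverse (8
mutual pairs). The three self-inverse rules coincide with the rules that
conserve the multiset of bond orders — the subset suitable for screening
spaces where multiple-bond counts must not change — and R1 (all single
bonds) is among them.

**Distance machinery.** The labelled bond-order distance
S = Σᵢ<ⱼ |aᵢⱼ − bᵢⱼ| is defined over a *fixed shared atom indexing*;
isomorphism-minimized distance is intentionally not implemented (the
convergence argument is about labelled graphs). The greedy step
(`rearrangement_path()`) follows the constructive selection — find
aᵢⱼ > bᵢⱼ, then aⱼₖ < bⱼₖ, then aₖₗ > bₖₗ, rearrange the 4-cycle — and
requires hydrogen-saturated inputs, since valence conservation per atom is
what drives the selection. Each step reduces S by exactly 2 or 4, giving
convergence within S/2 steps and the 3(N² − N)/4 iteration bound (floor,
since S is even and each step removes at least 2); for alkanes the bound
tightens to N − 1.

## Enzymatic rule extraction

Atom-mapped reaction SMILES are decomposed into one component per mapped
substrate; each component carries the other substrates as fixed
co-substrates so only one substrate varies when the rule is applied. The
reaction center is the set of mapped atom pairs whose bond order differs
between the sides. **Diameter d keeps the atoms within d/2 bonds of a
center atom** (hydrogens are implicit and not counted); d is even because
each shell adds one bond on either side, and d = 2 is the center's first
shell. Atoms kept on either side are kept on both (bond edits can lengthen
product-side paths), and unmapped created atoms are always kept. The
co-substrates are embedded in the rule SMARTS as additional components
(truncated by the same spheres); a co-substrate left empty at a small
diameter is dropped from the pattern. Bracket hydrogen counts in the input
are validated against the standard-valence derivation rather than stored,
so extracted patterns are element/charge patterns applicable to ordinary
implicit-hydrogen molecules — which is what makes small-diameter rules
promiscuous.

Atom–atom mapping itself is out of scope: inputs must arrive mapped.

## Screening and annotation

`tournament_select()` shuffles the merged population into `n_subsets`
(default 10) near-equal subsets and keeps the `top_k` (default 10) of each;
the global best always survives its subset, making the best-score
trajectory non-decreasing. Score ties break by canonical key, so a given
RNG state reproduces a selection exactly. The population is deduplicated at
the connectivity level before splitting, consistent with the engine's
duplicate merging everywhere else. `inverse_qsar_search()` samples one
molecule per iteration (an ordered pair when the rule set can recombine two
molecules) in `breadth = "sampled"` mode; `breadth = "all"` fires on every
member and exists to make small landscapes deterministic — on the toy
heavy-atom-target landscape (score −|N − 8|, ethane seed, single-atom
augmentation rule) the optimum is provably reached at iteration 6, which
the acceptance tests assert.

Similarity filtering uses MACCS keys with Tanimoto similarity strictly
greater than the threshold (defaults 0.5; 0.8 for the strict variant).
QSAR/QSPR models themselves are not part of the package: scorers are
supplied by the user as deterministic `molecule → score` functions, and the
built-in scorers are synthetic stand-ins with transparent optima.

Mass annotation computes monoisotopic masses from a built-in
most-abundant-isotope table (cross-checked in the tests against OpenBabel's
exact mass), and assigns a (molecule, adduct) pair to a peak when
|m/z_obs − m/z_theo| / m/z_theo ≤ tol (default 5 ppm, negative mode
default, theoretical m/z = (M + shift)/|z|). The shipped adduct table
([M−H]⁻, [M+Cl]⁻, [M+H]⁺, [M+Na]⁺, electron-corrected shifts) is a package
default, not a reproduction of any instrument configuration. Median/mean
compounds per peak are computed over annotated peaks.

## Synthetic fixtures: what they do and do not show

`generate_fixtures()` builds: linear alkane seeds C1–C14; a small
heteroatom panel; toy mapped reactions (a transaminase-style
carbonyl/amine exchange with center deltas −2/−1/+1/+2, a disulfide
interchange with exactly two broken and two formed single bonds, a single
bond-forming condensation, a degenerate identity reaction, and a spectator
water variant); synthetic scorers; and a negative-mode peak list made of
the panel's [M−H]⁻ masses jittered within 2 ppm plus an equal number of
decoy peaks 5–40 % away. The generator is deterministic under its seed, and
the 50 % fixture coverage is by construction.

These fixtures exercise every code path at desk scale, but they are not
real data: genome-scale rule corpora, measured spectra, and trained
activity models are orders of magnitude larger and noisier, and absolute
coverage or promiscuity numbers on such data are expressly not reproduced
here. What the passing tests establish are the *exact combinatorial
results* (isomer counts, the 81→36→27→19 chain, iteration bounds) and the
*direction-only laws* (promiscuity monotone in diameter, coverage monotone
in tolerance and candidate set, trajectory monotone under elitism).

## Problem sizes and runtime

The shipped tests and the acceptance script run alkane enumeration to
N = 12 (355 isomers), canonical augmentation to N = 14 (3324 cumulative
structures), exhaustive labelled-isomer convergence to 5 heavy atoms
(~1300 ordered pairs), and free-tree oracle comparison to N = 7. These
sizes were chosen so the full suite completes in a few minutes on one CPU
while still covering every published count the package reproduces; all
entry points accept larger N unchanged.

## Known limitations

* No stereochemistry, no tautomer/charge standardization beyond toolkit
  defaults, no aromaticity perception inside the engine (kekulized only).
* The valence model is the standard organic-subset table with simple charge
  adjustments; exotic valences are only handled by disabling the check
  (`max_valence = -1`).
* Rule SMARTS are the package's own dialect — general Daylight SMARTS
  features (recursive SMARTS, atom lists, degree/ring-count primitives) are
  not supported.
* The canonical labelling is exact but exponential in pathological cases;
  it is intended for molecule-sized graphs, not arbitrary graphs (hard
  limit: 250 atoms).
* Retrosynthetic sink-directed search and pathway scope extraction are out
  of scope.
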