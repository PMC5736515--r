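# rxnet

Reaction-rule driven exploration of chemical space in R.

Network-generation tools apply a set of reaction rules to a *source* set of
molecules, collect the products, and iterate — the same breadth-first core
serves retrosynthesis planning, metabolic-network expansion, isomer
enumeration and stochastic molecule optimization. `rxnet` implements that
core as a standalone R package with a C++ graph engine (subgraph matching,
bond rewriting and exact canonical labelling), and builds four applications
on top of it:

* **Isomer enumeration.** Two strategies for constitutional isomers:
  *canonical augmentation* (grow a skeleton one atom per iteration, keep one
  canonical representative of everything generated) and *isomer
  transformation* (start from one hydrogen-saturated molecule and apply
  valence-conserving bond rearrangements until nothing new appears).
* **The minimal rearrangement rule set.** A minimal valence-conserving
  transformation touches four atoms and rearranges the four cycle bonds as
  b₁₂ = a₁₂ − 1, b₂₃ = a₂₃ + 1, b₃₄ = a₃₄ − 1, b₁₄ = a₁₄ + 1 (the diagonals
  a₁₃, a₂₄ are untouched and unconstrained). Solvability bounds the initial
  orders to 3⁴ = 81 configurations; symmetry (a₁₄ ≥ a₂₃, a₁₂ ≥ a₃₄), the
  valence-4 cap, and the ban on two double bonds at one atom of a 3-/4-ring
  reduce them to 36, 27 and finally **19 distinct rules**, closed under
  reversal (3 self-inverse + 8 mutual pairs). Repeated application reduces
  the labelled bond-order distance S between any two isomers by 2–4 per
  step, so any isomer of an N-atom molecule is reached in at most
  3(N² − N)/4 iterations — and in at most N − 1 for alkanes.
* **Variable-diameter enzymatic rules.** From an atom-mapped reaction
  SMILES, locate the reaction center (all bonds whose order changes),
  decompose multi-substrate reactions into one component per substrate, and
  keep only the atoms within d/2 bonds of the center: small diameters give
  promiscuous rules, large ones specific rules.
* **Virtual screening.** MACCS/Tanimoto similarity filtering and an
  inverse-QSAR style stochastic search: fire rules on sampled population
  members, score products with a pluggable scorer, and keep the population
  bounded by a tournament (random split into 10 subsets, top 10 of each),
  which guarantees the incumbent best survives. A mass-annotation module
  matches generated candidates against MS peak lists by exact monoisotopic
  mass and adduct with a ppm tolerance.

Molecular identity everywhere is the *connectivity-level canonical key*: an
exact canonical form of the hydrogen-saturated graph, ignoring
stereochemistry and formal-charge layers. OpenBabel (via ChemmineR /
ChemmineOB) handles SMILES/InChI interconversion and fingerprints; the rule
engine itself is the package's own.

## Worked example

Derive the 19-rule set and enumerate the hexane isomers with the
all-single-bond rule (the only rule needed in alkane space):

```r
library(rxnet)

rules <- derive_transformation_rules()
length(rules)
#> [1] 19
rules[[1]]
#> <rx_rule> R1
#>   ([*:1]!1-[*:2]![*:3]-[*:4]1)>>([*:1]-[*:4].[*:2]-[*:3])
#>   components: 1 | diameter: Inf | bonds changed: 4

res <- enumerate_isomers("CCCCCC", list(rules[[1]]))
vapply(res$molecules, as_smiles, "")
#> [1] "CCCCCC"     "CCC(CC)C"   "CCCC(C)C"   "CCC(C)(C)C" "CC(C(C)C)C"
res$iterations
#> [1] 3
```

Hexane has 5 constitutional isomers; the last novel structure appears at
iteration 2 and the third (empty) round detects termination. The
rule SMARTS reads: match two single bonds 1–2 and 3–4 whose cross pairs
2–3 and 1–4 are non-bonded (`!`), delete the matched bonds and form the
cross bonds — hydrogens are explicit vertices, so this one rule moves both
C–C and C–H bonds.

The same engine grows skeletons instead of rearranging them:

```r
canonical_augmentation(10)$n_structures   # all alkanes with up to 10 carbons
#> [1] 150
monoisotopic_mass("OCC1OC(O)C(O)C(O)C1O") # glucose, Da
#> [1] 180.0634
```

A command-line front end wrapping these functions ships in `inst/cli/rxnet`
(subcommands `derive-rules`, `enumerate-augment`, `enumerate-transform`,
`extract-rules`, `screen`, `annotate-masses`, `fixtures`).

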