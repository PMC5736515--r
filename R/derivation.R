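#' Derivation of the minimal bond-rearrangement rule set
#'
#' A minimal valence-conserving transformation touches exactly four atoms
#' A1..A4 and the four bonds a12, a23, a34, a14 of the cycle they span; the
#' two diagonal bonds a13 and a24 stay untouched and may take any order.
#' Writing the transformation in its canonical orientation, the bond orders
#' change as b12 = a12 - 1, b23 = a23 + 1, b34 = a34 - 1, b14 = a14 + 1:
#' two bonds are deleted (or decreased) and two are created (or increased),
#' so every atom keeps its valence. Solvability bounds the initial orders to
#' a12, a34 in 1..3 and a14, a23 in 0..2 -- 81 configurations -- which
#' symmetry, the valence-4 cap and the small-ring double-bond constraint
#' reduce to 36, 27 and finally 19 distinct rules.
#'
#' @name rule_derivation
NULL

#' Enumerate the 81 feasible bond configurations
#'
#' @return a data frame with columns `a12`, `a23`, `a34`, `a14` (initial
#'   orders) and `b12`, `b23`, `b34`, `b14` (transformed orders), one row
#'   per feasible configuration.
#' @export
enumerate_feasible_configs <- function() {
  g <- expand.grid(a14 = 0:2, a34 = 1:3, a23 = 0:2, a12 = 1:3,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("a12", "a23", "a34", "a14")]
  g$b12 <- g$a12 - 1L
  g$b23 <- g$a23 + 1L
  g$b34 <- g$a34 - 1L
  g$b14 <- g$a14 + 1L
  g <- g[order(g$a12, g$a23, g$a34, g$a14), ]
  rownames(g) <- NULL
  g
}

#' Symmetry reduction (81 -> 36)
#'
#' The roles of a12/a34 and of a14/a23 are interchangeable, so each rule is
#' kept in the orientation where atom A1 carries the highest changing bond
#' order sum: a14 >= a23 and a12 >= a34.
#'
#' @param configs the configuration data frame (81 rows).
#' @return the reduced data frame (36 rows).
#' @export
reduce_by_symmetry <- function(configs) {
  out <- configs[configs$a14 >= configs$a23 & configs$a12 >= configs$a34, ]
  rownames(out) <- NULL
  out
}

#' Valence reduction (36 -> 27)
#'
#' Atom A1 gains a bond (b14 = a14 + 1), so configurations with
#' a12 + a14 = 5 (i.e. a12 = 3 and a14 = 2) would need valence 5.
#'
#' @param configs the symmetry-reduced data frame (36 rows).
#' @return the reduced data frame (27 rows).
#' @export
reduce_by_valence <- function(configs) {
  out <- configs[!(configs$a12 == 3L & configs$a14 == 2L), ]
  rownames(out) <- NULL
  out
}

#' Small-ring double-bond reduction (27 -> 19)
#'
#' No atom may carry two double bonds inside a 3- or 4-membered ring. This
#' removes 4 configurations whose reactant side is already invalid
#' (a12 = a14 = 2 with a34 in 1..2 and a23 in 1..2) and 4 whose product
#' side becomes invalid (a12 = 3, a14 = 1 with a34 in 2..3 and a23 in 0..1).
#'
#' @param configs the valence-reduced data frame (27 rows).
#' @return the final data frame (19 rows).
#' @export
reduce_by_ring_constraint <- function(configs) {
  bad_reactant <- configs$a12 == 2L & configs$a14 == 2L &
    configs$a34 %in% 1:2 & configs$a23 %in% 1:2
  bad_product <- configs$a12 == 3L & configs$a14 == 1L &
    configs$a34 %in% 2:3 & configs$a23 %in% 0:1
  out <- configs[!(bad_reactant | bad_product), ]
  rownames(out) <- NULL
  out
}

#' Serialize one bond configuration as a reaction rule
#'
#' Emits the 4-mapped-atom reaction SMARTS for a configuration: bonds of
#' order zero are written as absent (and required to be absent on the
#' pattern side when the transformation creates them); the untouched
#' diagonal bonds a13/a24 are omitted and therefore unconstrained.
#'
#' @param config a single-row configuration (from the derivation chain).
#' @param rule_id optional identifier.
#' @return a [reaction_rule].
#' @export
emit_smarts <- function(config, rule_id = NULL) {
  side_text <- function(o12, o23, o34, o14, keep_zero) {
    bonds <- rbind(c(1L, 2L, o12), c(2L, 3L, o23), c(3L, 4L, o34),
                   c(1L, 4L, o14))
    # zero-order entries are "must be absent" constraints: written (as '!')
    # on the reactant side, simply omitted on the product side
    if (!keep_zero) bonds <- bonds[bonds[, 3] > 0L, , drop = FALSE]
    txt <- .write_smiles(z = integer(4), charge = integer(4),
                         bond = bonds, map = 1:4, explicit_single = TRUE)
    paste0("(", txt, ")")
  }
  smarts <- paste0(
    side_text(config$a12, config$a23, config$a34, config$a14, TRUE), ">>",
    side_text(config$b12, config$b23, config$b34, config$b14, FALSE))
  reaction_rule(smarts, rule_id = rule_id)
}

#' Derive the minimal isomer-transformation rule set
#'
#' Runs the full reduction chain 81 -> 36 -> 27 -> 19 and serializes each
#' surviving configuration as a reaction rule. Rules are numbered R1..R19 by
#' lexicographic order of (a12, a23, a34, a14).
#'
#' @param include_triple_bonds if FALSE, configurations whose reactant or
#'   product side involves a triple bond are skipped, yielding the reduced
#'   rule set for triple-bond-free chemical spaces.
#' @return a list of [reaction_rule] objects; the configuration table (with
#'   an `order_conserving` column marking rules that preserve the multiset
#'   of bond orders, i.e. never interconvert multiple bonds and rings) is
#'   attached as attribute `"configs"`.
#' @export
derive_transformation_rules <- function(include_triple_bonds = TRUE) {
  cfg <- reduce_by_ring_constraint(
    reduce_by_valence(reduce_by_symmetry(enumerate_feasible_configs())))
  cfg$order_conserving <- mapply(function(a12, a23, a34, a14) {
    identical(sort(c(a12, a23, a34, a14)),
              sort(c(a12 - 1L, a23 + 1L, a34 - 1L, a14 + 1L)))
  }, cfg$a12, cfg$a23, cfg$a34, cfg$a14)
  if (!include_triple_bonds) {
    has3 <- cfg$a12 == 3L | cfg$a23 == 3L | cfg$a34 == 3L | cfg$a14 == 3L |
      cfg$b12 == 3L | cfg$b23 == 3L | cfg$b34 == 3L | cfg$b14 == 3L
    cfg <- cfg[!has3, ]
    rownames(cfg) <- NULL
  }
  rules <- lapply(seq_len(nrow(cfg)), function(k)
    emit_smarts(cfg[k, ], rule_id = paste0("R", k)))
  for (k in seq_along(rules)) rules[[k]]$order_conserving <- cfg$order_conserving[k]
  attr(rules, "configs") <- cfg
  rules
}

#' Iteration upper bounds of the breadth-first enumeration
#'
#' In general chemistry the farthest isomer differs from the seed by a
#' labelled bond-order distance of at most 3(N^2 - N)/2, and each rule
#' application reduces the distance by at least 2, so enumeration needs at
#' most `floor(3 (N^2 - N) / 4)` iterations. For alkanes (acyclic, single
#' bonds, N - 1 bonds) the bound tightens to N - 1.
#'
#' @param N number of atoms (>= 1); all atoms in general mode, carbon atoms
#'   in alkane mode.
#' @param mode `"general"` or `"alkane"`.
#' @return the integer iteration bound.
#' @export
iteration_upper_bound <- function(N, mode = c("general", "alkane")) {
  mode <- match.arg(mode)
  if (N < 1L) stop("'N' must be >= 1")
  if (mode == "general") floor(3 * (N^2 - N) / 4) else N - 1L
}

.bond_dense <- function(mol) {
  n <- length(mol$z)
  A <- matrix(0L, n, n)
  if (nrow(mol$bond)) for (r in seq_len(nrow(mol$bond))) {
    A[mol$bond[r, 1], mol$bond[r, 2]] <- mol$bond[r, 3]
    A[mol$bond[r, 2], mol$bond[r, 1]] <- mol$bond[r, 3]
  }
  A
}

#' Labelled bond-order distance between two isomers
#'
#' The sum of absolute bond-order differences over all atom pairs under a
#' fixed shared atom indexing (no isomorphism minimization). The distance is
#' 0 iff the labelled structures are identical and is always even for
#' molecules with identical per-atom valences.
#'
#' @param mol_a,mol_b [rx_mol] objects over the same atom list (same
#'   elements in the same positions).
#' @return integer distance S.
#' @export
bond_order_distance <- function(mol_a, mol_b) {
  stopifnot(inherits(mol_a, "rx_mol"), inherits(mol_b, "rx_mol"))
  if (length(mol_a$z) != length(mol_b$z) || !all(mol_a$z == mol_b$z))
    stop("molecules must share one atom indexing (same elements, same order)")
  A <- .bond_dense(mol_a)
  B <- .bond_dense(mol_b)
  as.integer(sum(abs(A - B)) / 2L)
}

#' Greedy rearrangement path between two labelled isomers
#'
#' Repeatedly applies the minimal 4-atom transformation selected as in the
#' convergence argument: find (i, j) with a_ij > b_ij, then k with
#' a_jk < b_jk, then l with a_kl > b_kl, and rearrange
#' (a_ij - 1, a_jk + 1, a_kl - 1, a_li + 1). Every step reduces the
#' labelled bond-order distance by 2 or 4, so the target is reached in at
#' most S/2 steps.
#'
#' @param mol_a,mol_b [rx_mol] objects over the same atom indexing.
#' @param max_steps safety cap (defaults to S/2).
#' @return a list with `steps` (number of transformations applied),
#'   `deltas` (distance reduction per step) and `S0` (initial distance).
#' @export
rearrangement_path <- function(mol_a, mol_b, max_steps = NULL) {
  S0 <- bond_order_distance(mol_a, mol_b)
  A <- .bond_dense(mol_a)
  B <- .bond_dense(mol_b)
  n <- nrow(A)
  if (!all(rowSums(A) == rowSums(B)))
    stop("per-atom valences differ: the transformation argument needs ",
         "hydrogen-saturated (valence-complete) labelled graphs")
  if (is.null(max_steps)) max_steps <- max(1L, S0 %/% 2L)
  deltas <- integer(0)
  steps <- 0L
  S <- S0
  while (S > 0L) {
    if (steps >= max_steps)
      stop("no convergence within ", max_steps, " steps (S = ", S, ")")
    found <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || A[i, j] <= B[i, j]) next
        for (k in seq_len(n)) {
          if (k %in% c(i, j) || A[j, k] >= B[j, k]) next
          for (l in seq_len(n)) {
            if (l %in% c(i, j, k) || A[k, l] <= B[k, l]) next
            # candidate rearrangement on (i, j, k, l)
            if (A[i, j] - 1L < 0L || A[j, k] + 1L > 3L ||
                A[k, l] - 1L < 0L || A[l, i] + 1L > 3L) next
            A2 <- A
            A2[i, j] <- A2[j, i] <- A[i, j] - 1L
            A2[j, k] <- A2[k, j] <- A[j, k] + 1L
            A2[k, l] <- A2[l, k] <- A[k, l] - 1L
            A2[l, i] <- A2[i, l] <- A[l, i] + 1L
            S2 <- as.integer(sum(abs(A2 - B)) / 2L)
            if (S2 < S) {
              deltas <- c(deltas, S - S2)
              A <- A2
              S <- S2
              steps <- steps + 1L
              found <- TRUE
            }
            if (found) break
          }
          if (found) break
        }
        if (found) break
      }
      if (found) break
    }
    if (!found)
      stop("no distance-reducing rearrangement found (S = ", S, ")")
  }
  list(steps = steps, deltas = deltas, S0 = S0)
}
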