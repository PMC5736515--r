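#' Reaction rules
#'
#' A reaction rule is a transformation written in the package's reaction
#' SMARTS dialect: `reactants >> products`, with atoms carrying map numbers.
#' Matching semantics:
#'
#' * pattern atoms match by element (a `[*]` wildcard matches any atom,
#'   including explicit hydrogens) and, when given, by formal charge;
#' * a bond drawn in the reactant pattern must be present with that order;
#' * two mapped atoms that are *not* bonded in the reactant pattern but become
#'   bonded on the product side must be non-bonded at match time;
#' * any other atom pair is unconstrained, and bonds between matched atoms
#'   that the pattern does not mention are preserved unchanged in products;
#' * mapped atoms missing from the product side are deleted, product atoms
#'   without a map number are created.
#'
#' A side may contain several components separated by `.`; wrapping a
#' component list in parentheses (e.g. `([*:1]-[*:2].[*:3]-[*:4])`) marks the
#' fragments as belonging to one molecule (intramolecular match). In that
#' single-group case an application yields one product structure, which is
#' rejected as a whole if it falls apart into several fragments (when
#' `connected_only = TRUE`). Multi-component sides model genuine
#' multi-molecule reactions and split products by connected component.
#'
#' @param smarts reaction SMARTS string in the dialect above.
#' @param rule_id identifier; defaults to the SMARTS string.
#' @param diameter even rule diameter (bonds spanned around the reaction
#'   center) or `Inf` for a full-molecule rule.
#' @param direction `"forward"` or `"reverse"`, an annotation only.
#' @param ec character vector of EC-number annotations.
#' @return an object of class `rx_rule`.
#' @examples
#' r <- reaction_rule("([*:1]-[*:2].[*:3]-[*:4])>>([*:1]-[*:4].[*:2]-[*:3])")
#' butane <- parse_molecule("CCCC", hydrogen_mode = "explicit")
#' products <- apply_rule(r, butane, connected_only = TRUE)
#' @export
reaction_rule <- function(smarts, rule_id = NULL, diameter = Inf,
                          direction = "forward", ec = character()) {
  rxn <- .parse_reaction(smarts, pattern = TRUE)
  ra <- rxn$reactant$atoms
  pa <- rxn$product$atoms
  p <- nrow(ra)
  if (p == 0L) stop("rule has an empty reactant pattern: '", smarts, "'")
  if (anyDuplicated(ra$map[ra$map > 0L]))
    stop("duplicate atom-map number on the reactant side: '", smarts, "'")
  if (anyDuplicated(pa$map[pa$map > 0L]))
    stop("duplicate atom-map number on the product side: '", smarts, "'")

  pbond <- matrix(-1L, p, p)
  rb <- rxn$reactant$bonds
  if (nrow(rb)) for (r in seq_len(nrow(rb)))
    pbond[rb[r, 1], rb[r, 2]] <- pbond[rb[r, 2], rb[r, 1]] <- rb[r, 3]

  # map product atoms onto pattern atoms
  prod_to_pat <- integer(nrow(pa))
  for (k in seq_len(nrow(pa))) {
    if (pa$map[k] > 0L) {
      hit <- which(ra$map == pa$map[k])
      if (!length(hit))
        stop("product map :", pa$map[k], " has no reactant counterpart: '",
             smarts, "'")
      prod_to_pat[k] <- hit
    } else {
      if (pa$z[k] == 0L)
        stop("created product atoms must name an element: '", smarts, "'")
      prod_to_pat[k] <- 0L  # created
    }
  }
  pdelete <- ra$map == 0L | !(seq_len(p) %in% prod_to_pat)

  # product bond orders between mapped atoms -> edits / absence constraints
  pborder <- matrix(0L, p, p)  # product-side order between pattern atoms
  seen_pair <- matrix(FALSE, p, p)
  pb <- rxn$product$bonds
  created_idx <- which(prod_to_pat == 0L)
  new_index <- match(seq_len(nrow(pa)), created_idx)  # product atom -> created slot
  nb_i <- integer(0); nb_j <- integer(0); nb_o <- integer(0)
  if (nrow(pb)) for (r in seq_len(nrow(pb))) {
    ai <- pb[r, 1]; aj <- pb[r, 2]; o <- pb[r, 3]
    if (o == 0L) next  # '!' on the product side: absence, the default
    if (o < 0L) stop("product side cannot carry '~' bonds: '", smarts, "'")
    pi <- prod_to_pat[ai]; pj <- prod_to_pat[aj]
    if (pi > 0L && pj > 0L) {
      pborder[pi, pj] <- pborder[pj, pi] <- o
      seen_pair[pi, pj] <- seen_pair[pj, pi] <- TRUE
    } else {
      enc <- function(a) if (prod_to_pat[a] > 0L) prod_to_pat[a] else p + new_index[a]
      nb_i <- c(nb_i, enc(ai)); nb_j <- c(nb_j, enc(aj)); nb_o <- c(nb_o, o)
    }
  }

  edits <- NULL
  kept <- which(!pdelete)
  for (a in kept) for (b in kept) {
    if (a >= b) next
    r_ord <- pbond[a, b]
    p_ord <- if (seen_pair[a, b]) pborder[a, b] else 0L
    if (seen_pair[a, b]) {
      if (r_ord <= 0L) {
        pbond[a, b] <- pbond[b, a] <- 0L       # created bond: require absence
        edits <- rbind(edits, c(a, b, p_ord))
      } else if (r_ord != p_ord) {
        edits <- rbind(edits, c(a, b, p_ord))  # order change
      }
    } else if (r_ord >= 1L) {
      edits <- rbind(edits, c(a, b, 0L))       # bond deleted
    }
  }
  if (is.null(edits)) edits <- matrix(integer(0), ncol = 3L)

  n_created <- length(created_idx)
  structure(list(
    rule_id = if (is.null(rule_id)) smarts else rule_id,
    smarts = smarts,
    diameter = diameter,
    direction = direction,
    ec = ec,
    p = p,
    pelem = ra$z, pchg = ra$charge, pchg_fixed = ra$chg_fixed,
    pmap = ra$map,
    pbond = pbond,
    edits = edits,
    pdelete = pdelete,
    new_elem = pa$z[created_idx],
    new_chg = pa$charge[created_idx],
    new_bond = matrix(c(nb_i, nb_j, nb_o), ncol = 3L),
    r_component = rxn$reactant$component,
    n_reactant_components = rxn$reactant$n_components,
    n_product_components = rxn$product$n_components,
    split_products = rxn$product$n_components > 1L,
    sides = rxn
  ), class = "rx_rule")
}

#' @export
print.rx_rule <- function(x, ...) {
  cat("<rx_rule> ", x$rule_id, "\n  ", x$smarts,
      "\n  components: ", x$n_reactant_components,
      " | diameter: ", if (is.finite(x$diameter)) x$diameter else "Inf",
      " | bonds changed: ", nrow(x$edits), "\n", sep = "")
  invisible(x)
}

#' Count bonds created and deleted by a rule
#'
#' Bond-rearrangement rules conserve the total number of bonds: the number
#' of bonds created equals the number deleted (order changes count their
#' order difference).
#' @param rule an `rx_rule`.
#' @return named integer vector with elements `created` and `deleted`.
#' @export
rule_bond_balance <- function(rule) {
  created <- 0L; deleted <- 0L
  if (nrow(rule$edits)) for (r in seq_len(nrow(rule$edits))) {
    a <- rule$edits[r, 1]; b <- rule$edits[r, 2]
    before <- max(rule$pbond[a, b], 0L)
    after <- rule$edits[r, 3]
    if (after > before) created <- created + (after - before)
    else deleted <- deleted + (before - after)
  }
  c(created = created, deleted = deleted)
}

#' Apply a reaction rule
#'
#' Finds every embedding of the rule's reactant pattern in the reactant
#' molecule(s), rewrites the bonds the rule changes (bonds not mentioned by
#' the pattern are preserved), sanitizes the results and merges duplicates at
#' the connectivity level. With one reactant the pattern is matched
#' intramolecularly; with several reactants the pattern components are
#' distributed across the molecules and every product tuple must draw atoms
#' from all of them.
#'
#' @param rule an `rx_rule`.
#' @param reactants an [rx_mol] or list of them; the list length must be 1 or
#'   match the number of reactant components of the rule.
#' @param max_valence uniform per-atom bond-order cap applied to products
#'   (default 4); `0` uses element-default valences, `-1` disables the check.
#' @param ring_constraint reject products carrying two double bonds on one
#'   atom in a 3-/4-membered ring (default TRUE).
#' @param connected_only for single-structure products, reject any product
#'   that has several disconnected components (default FALSE).
#' @return a list of product tuples; each tuple is a list of [rx_mol]
#'   objects. Attribute `"report"` carries the application/filter counts.
#' @export
apply_rule <- function(rule, reactants, max_valence = 4L,
                       ring_constraint = TRUE, connected_only = FALSE) {
  stopifnot(inherits(rule, "rx_rule"))
  if (inherits(reactants, "rx_mol")) reactants <- list(reactants)
  nmols <- length(reactants)
  if (nmols < 1L) stop("at least one reactant is required")
  if (nmols > 1L && nmols != rule$n_reactant_components &&
      rule$n_reactant_components != 1L)
    stop("rule expects ", rule$n_reactant_components,
         " reactant component(s), got ", nmols, " molecules")

  z <- integer(0); charge <- integer(0); mol_id <- integer(0)
  bond <- NULL
  off <- 0L
  for (k in seq_len(nmols)) {
    m <- reactants[[k]]
    z <- c(z, m$z); charge <- c(charge, m$charge)
    mol_id <- c(mol_id, rep(k, length(m$z)))
    if (nrow(m$bond)) {
      b <- m$bond; b[, 1:2] <- b[, 1:2] + off
      bond <- rbind(bond, b)
    }
    off <- off + length(m$z)
  }
  if (is.null(bond)) bond <- empty_bond_matrix()

  req_mol <- if (nmols > 1L && rule$n_reactant_components == nmols)
    rule$r_component else integer(rule$p)
  split <- rule$split_products || nmols > 1L

  res <- rxr_apply(z, charge, bond, mol_id, nmols, span_all = nmols > 1L,
                   req_mol = as.integer(req_mol),
                   pelem = rule$pelem, pchg = rule$pchg,
                   pchg_fixed = rule$pchg_fixed, pbond = rule$pbond,
                   edits = rule$edits, pdelete = rule$pdelete,
                   new_elem = as.integer(rule$new_elem),
                   new_chg = as.integer(rule$new_chg),
                   new_bond = rule$new_bond,
                   split_components = split,
                   connected_only = connected_only,
                   max_valence = as.integer(max_valence),
                   ring_rule = ring_constraint, fill_h_key = TRUE)

  hmode <- reactants[[1]]$hydrogen_mode
  tuples <- lapply(res$tuples, function(tp) {
    mols <- lapply(seq_along(tp$molecules), function(k)
      .mol_from_engine(tp$molecules[[k]], hmode, tp$keys[k]))
    mols
  })
  attr(tuples, "report") <- res$counts
  tuples
}

#' Count embeddings of a rule's reactant pattern in a molecule
#'
#' @param rule an `rx_rule`.
#' @param mol an [rx_mol].
#' @return integer number of pattern embeddings (0 if the molecule is not
#'   accepted by the rule).
#' @export
count_rule_matches <- function(rule, mol) {
  stopifnot(inherits(rule, "rx_rule"), inherits(mol, "rx_mol"))
  res <- rxr_apply(mol$z, mol$charge, mol$bond, rep(1L, length(mol$z)), 1L,
                   FALSE, integer(rule$p),
                   rule$pelem, rule$pchg, rule$pchg_fixed, rule$pbond,
                   rule$edits, rule$pdelete,
                   as.integer(rule$new_elem), as.integer(rule$new_chg),
                   rule$new_bond, split_components = FALSE,
                   connected_only = FALSE, max_valence = -1L,
                   ring_rule = FALSE, fill_h_key = TRUE, count_only = TRUE)
  res$n_embeddings
}

# Serialize one parsed side back to the dialect.
.write_side <- function(side) {
  pieces <- character(side$n_components)
  for (k in seq_len(side$n_components)) {
    idx <- which(side$component == k)
    sub <- match(seq_len(nrow(side$atoms)), idx)
    b <- side$bonds[side$bonds[, 1] %in% idx & side$bonds[, 2] %in% idx, ,
                    drop = FALSE]
    if (nrow(b)) {
      b[, 1] <- sub[b[, 1]]; b[, 2] <- sub[b[, 2]]
    }
    at <- side$atoms[idx, , drop = FALSE]
    txt <- .write_smiles(at$z, at$charge, b, map = at$map,
                         explicit_single = TRUE)
    multi_frag <- grepl(".", txt, fixed = TRUE)
    pieces[k] <- if (multi_frag) paste0("(", txt, ")") else txt
  }
  paste0(pieces, collapse = ".")
}

#' Reverse a reaction rule
#'
#' Swaps the reactant and product sides. The reverse of every rule in the
#' minimal bond-rearrangement set is again a member of that set.
#'
#' @param rule an `rx_rule`.
#' @return the reversed `rx_rule`.
#' @export
reverse_rule <- function(rule) {
  stopifnot(inherits(rule, "rx_rule"))
  smarts <- paste0(.write_side(rule$sides$product), ">>",
                   .write_side(rule$sides$reactant))
  reaction_rule(smarts,
                rule_id = paste0(rule$rule_id, "_rev"),
                diameter = rule$diameter,
                direction = if (identical(rule$direction, "forward"))
                  "reverse" else "forward",
                ec = rule$ec)
}

#' Test whether two bond-rearrangement rules are identical
#'
#' Two rules are identical when a one-to-one relabelling of their pattern
#' atoms carries the constrained bond set (orders before and after) of one
#' exactly onto the other; identical rules produce the same products on
#' every molecule.
#'
#' @param rule_a,rule_b `rx_rule` objects with the same number of pattern
#'   atoms (at most 8).
#' @return TRUE or FALSE.
#' @export
rules_are_identical <- function(rule_a, rule_b) {
  stopifnot(inherits(rule_a, "rx_rule"), inherits(rule_b, "rx_rule"))
  p <- rule_a$p
  if (rule_b$p != p) return(FALSE)
  if (p > 8L) stop("identity testing supported for at most 8 pattern atoms")
  pair_maps <- function(rule) {
    before <- rule$pbond
    after <- before
    after[after < 0L] <- -1L
    if (nrow(rule$edits)) for (r in seq_len(nrow(rule$edits))) {
      a <- rule$edits[r, 1]; b <- rule$edits[r, 2]
      after[a, b] <- after[b, a] <- rule$edits[r, 3]
    }
    list(before = before, after = after)
  }
  A <- pair_maps(rule_a)
  B <- pair_maps(rule_b)
  perms <- .permutations(p)
  for (r in seq_len(nrow(perms))) {
    pi <- perms[r, ]
    if (!all(rule_a$pelem == rule_b$pelem[pi])) next
    ok <- all(A$before == B$before[pi, pi]) && all(A$after == B$after[pi, pi])
    if (ok) return(TRUE)
  }
  FALSE
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}
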