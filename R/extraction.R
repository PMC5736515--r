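#' Variable-diameter enzymatic reaction rules
#'
#' Enzymatic reaction rules are computed from atom-mapped reaction SMILES.
#' The *reaction center* is the set of bonds whose order differs between the
#' substrate and product sides; a rule of diameter d keeps only the atoms
#' within d/2 bonds of a center atom, so small diameters yield permissive
#' (promiscuous) rules and large diameters specific ones. Multi-substrate
#' reactions are first decomposed into one component per substrate, each
#' carrying the remaining substrates as fixed co-substrates, so that applying
#' a rule changes only one substrate at a time.
#'
#' @name rule_extraction
NULL

# Convert one parsed side component into a molecule graph. Hydrogens stay
# implicit (derived from standard valences and charges); bracket hydrogen
# counts are validated against that derivation so a mistyped mapped reaction
# is flagged rather than silently reinterpreted.
.component_graph <- function(atoms, bonds) {
  g <- list(z = atoms$z, charge = atoms$charge, bond = bonds,
            map = atoms$map)
  hc <- atoms$hcount
  if (any(!is.na(hc))) {
    filled <- rxr_implicit_h(g$z, g$charge, g$bond)
    bad <- which(!is.na(hc) & hc != filled)
    if (length(bad))
      warning("bracket hydrogen count differs from the valence-derived ",
              "count for atom(s) ", paste(bad, collapse = ", "),
              "; the valence-derived count is used")
  }
  g
}

#' Parse an atom-mapped reaction SMILES
#'
#' @param text reaction SMILES `substrates >> products` in the package
#'   dialect; substrate heavy atoms carry unique atom-map numbers and every
#'   mapped product atom must reuse a substrate map. Unmapped molecules
#'   (e.g. spectator water) are allowed.
#' @param id,ec optional identifier and EC annotations.
#' @return an object of class `rx_mapped_reaction` with `substrates` and
#'   `products` (lists of mapped molecule graphs).
#' @export
parse_mapped_reaction <- function(text, id = NULL, ec = character()) {
  rxn <- .parse_reaction(text, pattern = FALSE)
  side_graphs <- function(side) {
    lapply(seq_len(side$n_components), function(k) {
      idx <- which(side$component == k)
      sub <- match(seq_len(nrow(side$atoms)), idx)
      b <- side$bonds[side$bonds[, 1] %in% idx & side$bonds[, 2] %in% idx, ,
                      drop = FALSE]
      if (nrow(b)) {
        b[, 1] <- sub[b[, 1]]
        b[, 2] <- sub[b[, 2]]
      }
      .component_graph(side$atoms[idx, , drop = FALSE], b)
    })
  }
  subs <- side_graphs(rxn$reactant)
  prods <- side_graphs(rxn$product)
  smap <- unlist(lapply(subs, `[[`, "map"))
  pmap <- unlist(lapply(prods, `[[`, "map"))
  if (anyDuplicated(smap[smap > 0L]))
    stop("duplicate atom-map number among substrates: '", text, "'")
  if (anyDuplicated(pmap[pmap > 0L]))
    stop("duplicate atom-map number among products: '", text, "'")
  orphan <- setdiff(pmap[pmap > 0L], smap)
  if (length(orphan))
    stop("product map(s) ", paste(orphan, collapse = ", "),
         " missing from the substrate side: '", text, "'")
  structure(list(text = text, id = if (is.null(id)) text else id, ec = ec,
                 substrates = subs, products = prods,
                 substrate_count = length(subs)),
            class = "rx_mapped_reaction")
}

#' @export
print.rx_mapped_reaction <- function(x, ...) {
  cat("<rx_mapped_reaction> ", x$id, "\n  substrates: ", x$substrate_count,
      " | products: ", length(x$products), "\n", sep = "")
  invisible(x)
}

# map-number -> bond-order lookup over one side
.mapped_bond_orders <- function(mols) {
  out <- list()
  for (m in mols) {
    if (!nrow(m$bond)) next
    for (r in seq_len(nrow(m$bond))) {
      mi <- m$map[m$bond[r, 1]]
      mj <- m$map[m$bond[r, 2]]
      if (mi > 0L && mj > 0L) {
        key <- paste(min(mi, mj), max(mi, mj), sep = "-")
        out[[key]] <- m$bond[r, 3]
      }
    }
  }
  out
}

#' Locate the reaction center of a mapped reaction
#'
#' @param rxn an `rx_mapped_reaction`.
#' @return a list with `changed_bonds` (data frame `map_i`, `map_j`,
#'   `delta`, the product-minus-substrate order difference) and
#'   `center_atoms` (map numbers incident to a changed bond).
#' @export
find_reaction_center <- function(rxn) {
  stopifnot(inherits(rxn, "rx_mapped_reaction"))
  sb <- .mapped_bond_orders(rxn$substrates)
  pb <- .mapped_bond_orders(rxn$products)
  keys <- union(names(sb), names(pb))
  mi <- integer(0); mj <- integer(0); dd <- integer(0)
  for (key in keys) {
    so <- if (is.null(sb[[key]])) 0L else sb[[key]]
    po <- if (is.null(pb[[key]])) 0L else pb[[key]]
    if (so != po) {
      ij <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
      mi <- c(mi, ij[1]); mj <- c(mj, ij[2]); dd <- c(dd, po - so)
    }
  }
  if (!length(mi))
    stop("degenerate reaction: no bond changes between the two sides")
  list(changed_bonds = data.frame(map_i = mi, map_j = mj, delta = dd),
       center_atoms = sort(unique(c(mi, mj))))
}

#' Decompose a multi-substrate reaction into per-substrate components
#'
#' One component is produced per mapped substrate; its product list contains
#' exactly the products sharing at least one mapped atom with that
#' substrate, and the other mapped substrates ride along as fixed
#' co-substrates. Unmapped spectator molecules are excluded.
#'
#' @param rxn an `rx_mapped_reaction`.
#' @return a list of `rx_rule_component` objects.
#' @export
decompose_components <- function(rxn) {
  stopifnot(inherits(rxn, "rx_mapped_reaction"))
  center <- find_reaction_center(rxn)
  mapped <- which(vapply(rxn$substrates, function(s) any(s$map > 0L), NA))
  out <- list()
  for (s in mapped) {
    smaps <- rxn$substrates[[s]]$map
    share <- vapply(rxn$products, function(p)
      length(intersect(p$map[p$map > 0L], smaps[smaps > 0L])) > 0L, NA)
    if (!any(share))
      warning("substrate ", s, " contributes no atom to any product")
    out[[length(out) + 1L]] <- structure(
      list(substrate = rxn$substrates[[s]],
           substrate_index = s,
           co_substrates = rxn$substrates[setdiff(mapped, s)],
           products = rxn$products[share],
           center = center,
           reaction_id = rxn$id,
           ec = rxn$ec),
      class = "rx_rule_component")
  }
  out
}

#' @export
print.rx_rule_component <- function(x, ...) {
  cat("<rx_rule_component> reaction ", x$reaction_id,
      " | substrate #", x$substrate_index,
      " | co-substrates: ", length(x$co_substrates),
      " | products: ", length(x$products), "\n", sep = "")
  invisible(x)
}

# atoms of one molecule graph within (diameter/2) bonds of its center atoms;
# unmapped atoms (created atoms, explicit hydrogens) are kept when attached
# within the sphere on their own graph distance.
.kept_by_sphere <- function(g, center_maps, radius) {
  n <- length(g$z)
  centers <- which(g$map %in% center_maps)
  if (!length(centers)) return(integer(0))
  if (!is.finite(radius)) return(seq_len(n))
  D <- rxr_distances(g$z, g$charge, g$bond)
  keep <- logical(n)
  for (c0 in centers)
    keep <- keep | (!is.na(D[c0, ]) & D[c0, ] <= radius)
  which(keep)
}

.subgraph <- function(g, idx) {
  sub <- match(seq_along(g$z), idx)
  b <- g$bond[g$bond[, 1] %in% idx & g$bond[, 2] %in% idx, , drop = FALSE]
  if (nrow(b)) {
    b[, 1] <- sub[b[, 1]]
    b[, 2] <- sub[b[, 2]]
  }
  list(z = g$z[idx], charge = g$charge[idx], bond = b, map = g$map[idx])
}

#' Extract a reaction rule at a given diameter
#'
#' Keeps, in every molecule of the component, the atoms within `diameter/2`
#' bonds of a reaction-center atom (all atoms when `diameter = Inf`; an atom
#' kept on either side is kept on both so the mapped atom sets agree), and
#' serializes the truncated reaction as a reaction SMARTS with the original
#' map numbers. Unmapped created atoms in products are always kept.
#'
#' @param component an `rx_rule_component` from [decompose_components()].
#' @param diameter an even integer in 2..16, or `Inf`.
#' @return a [reaction_rule] with the component's diameter and EC
#'   annotations.
#' @export
extract_rule <- function(component, diameter = Inf) {
  stopifnot(inherits(component, "rx_rule_component"))
  if (is.finite(diameter) &&
      (diameter < 2 || diameter %% 2 != 0))
    stop("'diameter' must be an even integer >= 2, or Inf")
  radius <- diameter / 2
  cmaps <- component$center$center_atoms

  reactant_mols <- c(list(component$substrate), component$co_substrates)
  product_mols <- component$products

  kept_r <- lapply(reactant_mols, .kept_by_sphere, center_maps = cmaps,
                   radius = radius)
  kept_p <- lapply(product_mols, function(g) {
    idx <- .kept_by_sphere(g, cmaps, radius)
    union(idx, which(g$map == 0L & g$z != 1L))  # created heavy atoms stay
  })
  # a mapped atom kept on either side is kept on both
  kept_maps <- unique(c(
    unlist(lapply(seq_along(reactant_mols), function(k)
      reactant_mols[[k]]$map[kept_r[[k]]])),
    unlist(lapply(seq_along(product_mols), function(k)
      product_mols[[k]]$map[kept_p[[k]]]))))
  kept_maps <- kept_maps[kept_maps > 0L]
  widen <- function(g, idx) sort(union(idx, which(g$map %in% kept_maps)))
  kept_r <- lapply(seq_along(reactant_mols), function(k)
    widen(reactant_mols[[k]], kept_r[[k]]))
  kept_p <- lapply(seq_along(product_mols), function(k)
    widen(product_mols[[k]], kept_p[[k]]))

  side_text <- function(mols, kept) {
    pieces <- character(0)
    for (k in seq_along(mols)) {
      if (!length(kept[[k]])) next  # molecule entirely outside the sphere
      g <- .subgraph(mols[[k]], kept[[k]])
      txt <- .write_smiles(g$z, g$charge, g$bond, map = g$map,
                           explicit_single = TRUE)
      pieces <- c(pieces,
                  if (grepl(".", txt, fixed = TRUE)) paste0("(", txt, ")")
                  else txt)
    }
    paste0(pieces, collapse = ".")
  }
  smarts <- paste0(side_text(reactant_mols, kept_r), ">>",
                   side_text(product_mols, kept_p))
  reaction_rule(
    smarts,
    rule_id = paste0(component$reaction_id, "_s",
                     component$substrate_index, "_d",
                     if (is.finite(diameter)) diameter else "inf"),
    diameter = diameter,
    ec = component$ec)
}

#' Extract rules for all components and diameters of a reaction
#'
#' @param rxn an `rx_mapped_reaction`.
#' @param diameters vector of even diameters (default 2-16) and/or `Inf`.
#' @return a list of [reaction_rule] objects, one per
#'   (component, diameter).
#' @export
extract_rules <- function(rxn, diameters = seq(2, 16, by = 2)) {
  comps <- decompose_components(rxn)
  out <- list()
  for (comp in comps)
    for (d in diameters)
      out[[length(out) + 1L]] <- extract_rule(comp, d)
  out
}

#' Molecules of a rule component
#'
#' Convenience conversion of a component's substrate, co-substrates and
#' recorded products into [rx_mol] objects (map numbers dropped), e.g. to
#' check that an extracted rule regenerates its native products.
#'
#' @param component an `rx_rule_component`.
#' @return a list with `reactants` (substrate first, then co-substrates)
#'   and `products`.
#' @export
component_molecules <- function(component) {
  stopifnot(inherits(component, "rx_rule_component"))
  to_mol <- function(g) new_rx_mol(g$z, g$charge, g$bond)
  list(reactants = lapply(c(list(component$substrate),
                            component$co_substrates), to_mol),
       products = lapply(component$products, to_mol))
}
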