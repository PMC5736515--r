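#' @title Molecules as connectivity graphs
#'
#' @description An `rx_mol` is a light-weight molecular graph: atomic
#' numbers, formal charges and an integer bond list (orders 1-3). Hydrogens
#' are either implicit (filled to default valences when needed) or explicit
#' vertices, depending on how the molecule was created. Identity throughout
#' the package is the *connectivity-level canonical key*: an exact canonical
#' form of the hydrogen-saturated graph that ignores stereochemistry and
#' formal charge layers, so any two encodings of the same atom/bond
#' connectivity compare equal.
#'
#' @name rx_mol
NULL

new_rx_mol <- function(z, charge, bond, hydrogen_mode = "implicit",
                       key = NULL, source = NA_character_) {
  z <- as.integer(z)
  charge <- as.integer(charge)
  bond <- matrix(as.integer(bond), ncol = 3L,
                 dimnames = list(NULL, c("i", "j", "order")))
  if (is.null(key)) key <- rxr_canon_key(z, charge, bond, TRUE)
  structure(
    list(z = z, charge = charge, bond = bond,
         hydrogen_mode = hydrogen_mode, key = key, source = source),
    class = "rx_mol"
  )
}

.mol_from_engine <- function(g, hydrogen_mode, key) {
  new_rx_mol(g$elem, g$charge, g$bond, hydrogen_mode = hydrogen_mode, key = key)
}

empty_bond_matrix <- function() {
  matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("i", "j", "order")))
}

#' Parse a molecule from SMILES or InChI
#'
#' Input strings are interpreted by OpenBabel (InChI is recognised by its
#' `InChI=` prefix), kekulized, and converted into an [rx_mol] graph. In
#' `"explicit"` mode every free valence is saturated with an explicit
#' hydrogen atom, which is the representation the bond-rearrangement rules
#' operate on; in `"implicit"` mode hydrogens stay implicit.
#'
#' @param text a SMILES or InChI string.
#' @param hydrogen_mode `"implicit"` (default) or `"explicit"`.
#' @return an [rx_mol] object.
#' @examples
#' m <- parse_molecule("CCO")
#' heavy_atom_count(m)
#' @export
parse_molecule <- function(text, hydrogen_mode = c("implicit", "explicit")) {
  hydrogen_mode <- match.arg(hydrogen_mode)
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("'text' must be a single non-empty structure string")
  fmt <- if (grepl("^InChI=", text)) "INCHI" else "SMI"
  if (fmt == "SMI") .check_smiles_syntax(text)
  opts <- if (hydrogen_mode == "explicit")
    data.frame(names = c("h", "gen2D"), args = c("", "")) else
      data.frame(names = "gen2D", args = "")
  block <- suppressWarnings(tryCatch(
    ChemmineOB::convertFormat(fmt, "SDF", source = text, options = opts),
    error = function(e) ""
  ))
  if (!nzchar(block) || !grepl("V2000", block, fixed = TRUE))
    stop("cannot parse structure: '", text, "'")
  g <- .molblock_to_graph(block)
  if (length(g$z) == 0L)
    stop("cannot parse structure: '", text, "'")
  new_rx_mol(g$z, g$charge, g$bond, hydrogen_mode = hydrogen_mode,
             source = text)
}

# OpenBabel silently repairs some malformed SMILES (e.g. dangling branches),
# so basic syntax is validated up front: balanced parentheses/brackets,
# paired ring-closure digits, no dangling bond symbol.
.check_smiles_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L; inbr <- FALSE
  rings <- integer(0)
  for (ch in chars) {
    if (inbr) {
      if (ch == "]") inbr <- FALSE
      next
    }
    if (ch == "[") inbr <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (grepl("[0-9]", ch)) {
      d <- as.integer(ch)
      if (d %in% rings) rings <- setdiff(rings, d) else rings <- c(rings, d)
    }
    if (depth < 0L) break
  }
  if (depth != 0L || inbr || length(rings) ||
      grepl("[-=#~/\\\\]$", text))
    stop("cannot parse structure: '", text, "'")
  invisible(TRUE)
}

# Minimal V2000 reader for the blocks OpenBabel itself writes (fixed-width
# counts/atom/bond lines plus M CHG properties).
.molblock_to_graph <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  counts <- grep("V2000", lines, fixed = TRUE)[1]
  na <- as.integer(substr(lines[counts], 1, 3))
  nb <- as.integer(substr(lines[counts], 4, 6))
  sym <- character(na)
  for (k in seq_len(na)) {
    ln <- lines[counts + k]
    sym[k] <- trimws(substr(ln, 32, 34))
  }
  bond <- empty_bond_matrix()
  if (nb > 0) {
    bond <- matrix(0L, nrow = nb, ncol = 3L,
                   dimnames = list(NULL, c("i", "j", "order")))
    for (k in seq_len(nb)) {
      ln <- lines[counts + na + k]
      bond[k, ] <- c(as.integer(substr(ln, 1, 3)),
                     as.integer(substr(ln, 4, 6)),
                     as.integer(substr(ln, 7, 9)))
    }
  }
  if (any(bond[, "order"] > 3L))
    stop("aromatic (order 4) bonds in mol block; expected kekulized input")
  charge <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)),
                             "\\s+")[[1]])
    idx <- f[seq(1, length(f), by = 2)]
    val <- f[seq(2, length(f), by = 2)]
    charge[idx] <- val
  }
  list(z = element_number(sym), charge = charge, bond = bond)
}

# V2000 writer for handing graphs back to OpenBabel (SMILES/InChI rendering,
# fingerprints). Coordinates are zero; only connectivity matters here.
.graph_to_molblock <- function(mol) {
  na <- length(mol$z)
  nb <- nrow(mol$bond)
  sym <- element_symbol(mol$z)
  header <- c("", " rxnet", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atoms <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0", sym)
  bonds <- if (nb > 0)
    sprintf("%3d%3d%3d  0  0  0  0",
            mol$bond[, 1], mol$bond[, 2], mol$bond[, 3]) else character(0)
  chg <- which(mol$charge != 0L)
  props <- if (length(chg))
    vapply(chg, function(i)
      sprintf("M  CHG  1 %3d %3d", i, mol$charge[i]), "") else character(0)
  paste(c(header, atoms, bonds, props, "M  END", "$$$$", ""), collapse = "\n")
}

#' @rdname rx_mol
#' @param mol,x an [rx_mol] object.
#' @return `canonical_key()` returns the connectivity-level canonical
#'   identifier string; `heavy_atom_count()` the number of non-hydrogen
#'   atoms; `mol_formula()` the Hill-order molecular formula.
#' @export
canonical_key <- function(mol) {
  stopifnot(inherits(mol, "rx_mol"))
  mol$key
}

#' @rdname rx_mol
#' @export
heavy_atom_count <- function(mol) {
  stopifnot(inherits(mol, "rx_mol"))
  sum(mol$z != 1L)
}

#' @rdname rx_mol
#' @export
mol_formula <- function(mol) {
  stopifnot(inherits(mol, "rx_mol"))
  counts <- table(element_symbol(mol$z))
  nh <- sum(rxr_implicit_h(mol$z, mol$charge, mol$bond))
  tally <- setNames(as.integer(counts), names(counts))
  if (nh > 0) tally["H"] <- (if ("H" %in% names(tally)) tally[["H"]] else 0L) + nh
  syms <- names(tally)
  hill <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(hill, function(s)
    paste0(s, if (tally[[s]] > 1L) tally[[s]] else ""), ""), collapse = "")
}

#' @rdname rx_mol
#' @export
as_smiles <- function(mol) {
  stopifnot(inherits(mol, "rx_mol"))
  if (length(mol$z) == 0L) return("")
  out <- ChemmineOB::convertFormat("SDF", "CAN", source = .graph_to_molblock(mol))
  trimws(strsplit(out, "[\t\n]")[[1]][1])
}

#' @rdname rx_mol
#' @export
as_inchi <- function(mol) {
  stopifnot(inherits(mol, "rx_mol"))
  out <- ChemmineOB::convertFormat("SDF", "INCHI", source = .graph_to_molblock(mol))
  trimws(strsplit(out, "\n")[[1]][1])
}

#' @rdname rx_mol
#' @param ... ignored.
#' @export
print.rx_mol <- function(x, ...) {
  cat("<rx_mol> ", mol_formula(x),
      " | heavy atoms: ", heavy_atom_count(x),
      " | hydrogens: ", x$hydrogen_mode,
      " | key: ", substr(x$key, 1, 16), "...\n", sep = "")
  invisible(x)
}

#' Merge duplicate structures by canonical key
#'
#' @param mols a list of [rx_mol] objects.
#' @return a list with one molecule per distinct canonical key (first
#'   occurrence kept), in first-seen order.
#' @export
dedup_molecules <- function(mols) {
  keys <- vapply(mols, canonical_key, "")
  mols[!duplicated(keys)]
}

#' Structural filters
#'
#' `filter_connected()` retains only single-component structures (a product
#' that fell apart into several fragments during a transformation is
#' discarded as a whole). `filter_valence_and_rings()` drops structures with
#' an atom whose total bond order exceeds `max_valence`, and structures
#' carrying two double bonds on one atom inside a 3- or 4-membered ring --
#' the geometric feasibility constraints of the bond-rearrangement rule
#' system.
#'
#' @param mols a list of [rx_mol] objects.
#' @param max_valence maximum per-atom total bond order (default 4).
#' @return a list with elements `molecules` (retained) and `report`
#'   (an `rx_filter_report`).
#' @export
filter_connected <- function(mols) {
  keep <- vapply(mols, function(m)
    length(m$z) > 0L && max(rxr_components(m$z, m$charge, m$bond)) == 1L,
    NA)
  list(molecules = mols[keep],
       report = new_filter_report(length(mols),
                                  rejected_disconnected = sum(!keep),
                                  retained = sum(keep)))
}

#' @rdname filter_connected
#' @export
filter_valence_and_rings <- function(mols, max_valence = 4L) {
  val_ok <- logical(length(mols))
  ring_ok <- logical(length(mols))
  for (k in seq_along(mols)) {
    f <- rxr_sanitize_flags(mols[[k]]$z, mols[[k]]$charge, mols[[k]]$bond,
                            max_valence)
    val_ok[k] <- f$valence_ok
    ring_ok[k] <- f$ring_ok
  }
  keep <- val_ok & ring_ok
  list(molecules = mols[keep],
       report = new_filter_report(length(mols),
                                  rejected_valence = sum(!val_ok),
                                  rejected_ring_constraint = sum(val_ok & !ring_ok),
                                  retained = sum(keep)))
}

new_filter_report <- function(input_count, rejected_disconnected = 0L,
                              rejected_valence = 0L,
                              rejected_ring_constraint = 0L, retained = 0L) {
  structure(list(input_count = as.integer(input_count),
                 rejected_disconnected = as.integer(rejected_disconnected),
                 rejected_valence = as.integer(rejected_valence),
                 rejected_ring_constraint = as.integer(rejected_ring_constraint),
                 retained = as.integer(retained)),
            class = "rx_filter_report")
}

#' @export
print.rx_filter_report <- function(x, ...) {
  cat("<rx_filter_report> in:", x$input_count,
      "| disconnected:", x$rejected_disconnected,
      "| valence:", x$rejected_valence,
      "| ring:", x$rejected_ring_constraint,
      "| retained:", x$retained, "\n")
  invisible(x)
}
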