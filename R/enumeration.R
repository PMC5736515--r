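#' Breadth-first network generation
#'
#' The enumeration engine maintains a *source* set (structures rules are
#' fired on in the current iteration) and a *sink* set (every structure seen
#' so far, tracked by connectivity-level canonical key). Each iteration
#' fires every rule on every source structure, sanitizes and deduplicates
#' the products, discards products that fell apart into several fragments,
#' and promotes the genuinely new structures to be the next source.
#'
#' @name enumeration
NULL

#' Create an enumeration state
#'
#' @param source an [rx_mol] or list of them; the initial source set.
#' @return an object of class `rx_enum_state` with fields `iteration`,
#'   `source`, `sink` (a key-indexed environment), `molecules` (all
#'   structures seen) and `records` (provenance tuples).
#' @export
enumeration_state <- function(source) {
  if (inherits(source, "rx_mol")) source <- list(source)
  source <- dedup_molecules(source)
  sink <- new.env(parent = emptyenv())
  for (m in source) assign(canonical_key(m), TRUE, envir = sink)
  structure(list(iteration = 0L, source = source, sink = sink,
                 molecules = source, records = list(),
                 counts = list()),
            class = "rx_enum_state")
}

#' @export
print.rx_enum_state <- function(x, ...) {
  cat("<rx_enum_state> iteration:", x$iteration,
      "| source:", length(x$source),
      "| sink:", length(x$molecules), "\n")
  invisible(x)
}

#' Run one breadth-first expansion step
#'
#' Fires every rule on every structure of the current source (for
#' two-component rules, on every ordered pair of distinct source
#' structures), filters and merges the products, and promotes the products
#' whose keys are not yet in the sink to be the new source.
#'
#' @param state an `rx_enum_state`.
#' @param rules a non-empty list of [reaction_rule] objects.
#' @param max_valence,ring_constraint product sanitization, see [apply_rule].
#' @return the updated state; `state$source` holds the newly discovered
#'   structures (possibly empty).
#' @export
expand_once <- function(state, rules, max_valence = 4L,
                        ring_constraint = TRUE) {
  stopifnot(inherits(state, "rx_enum_state"))
  if (inherits(rules, "rx_rule")) rules <- list(rules)
  if (length(rules) == 0L) stop("at least one reaction rule is required")
  if (length(state$source) == 0L) stop("the source set is empty")

  it <- state$iteration + 1L
  new_source <- list()
  n_rejected <- c(embeddings = 0L, rejected_disconnected = 0L,
                  rejected_valence = 0L, rejected_ring = 0L, products = 0L)

  consume <- function(tuples, parent_keys, rule_id) {
    cnt <- attr(tuples, "report")
    n_rejected["embeddings"] <<- n_rejected[["embeddings"]] + cnt[["embeddings"]]
    n_rejected["rejected_disconnected"] <<-
      n_rejected[["rejected_disconnected"]] + cnt[["rejected_disconnected"]]
    n_rejected["rejected_valence"] <<-
      n_rejected[["rejected_valence"]] + cnt[["rejected_valence"]]
    n_rejected["rejected_ring"] <<-
      n_rejected[["rejected_ring"]] + cnt[["rejected_ring"]]
    for (tp in tuples) {
      for (m in tp) {
        n_rejected["products"] <<- n_rejected[["products"]] + 1L
        key <- canonical_key(m)
        if (!exists(key, envir = state$sink, inherits = FALSE)) {
          assign(key, TRUE, envir = state$sink)
          new_source[[length(new_source) + 1L]] <<- m
          state$records[[length(state$records) + 1L]] <<-
            list(product_key = key, parent_keys = parent_keys,
                 rule_id = rule_id, iteration = it)
        }
      }
    }
  }

  for (rule in rules) {
    if (rule$n_reactant_components >= 2L) {
      ns <- length(state$source)
      for (a in seq_len(ns)) for (b in seq_len(ns)) {
        if (a == b) next
        tp <- apply_rule(rule, list(state$source[[a]], state$source[[b]]),
                         max_valence = max_valence,
                         ring_constraint = ring_constraint,
                         connected_only = TRUE)
        consume(tp, c(canonical_key(state$source[[a]]),
                      canonical_key(state$source[[b]])), rule$rule_id)
      }
    } else {
      for (m in state$source) {
        tp <- apply_rule(rule, m, max_valence = max_valence,
                         ring_constraint = ring_constraint,
                         connected_only = TRUE)
        consume(tp, canonical_key(m), rule$rule_id)
      }
    }
  }

  state$iteration <- it
  state$source <- new_source
  state$molecules <- c(state$molecules, new_source)
  state$counts[[it]] <- c(iteration = it, new_structures = length(new_source),
                          n_rejected)
  state
}

.as_seed <- function(seed, hydrogen_mode) {
  if (is.character(seed)) seed <- parse_molecule(seed, hydrogen_mode)
  stopifnot(inherits(seed, "rx_mol"))
  seed
}

#' Enumerate constitutional isomers by bond rearrangement
#'
#' Starting from one hydrogen-saturated molecule, repeatedly applies
#' valence-conserving bond-rearrangement rules breadth-first until an
#' iteration produces no new structure (or `max_iter` is reached). All
#' connected structures ever generated -- the seed's reachable isomer space
#' under the rule set -- are returned.
#'
#' The reported `iterations` counts every round fired, including the final
#' round that discovered nothing new (the natural-termination convention);
#' `last_new_iteration` is the iteration at which the last novel structure
#' appeared.
#'
#' @param seed an [rx_mol] (explicit hydrogens recommended) or a SMILES /
#'   InChI string, parsed in explicit-hydrogen mode.
#' @param rules list of bond-rearrangement rules, e.g. from
#'   [derive_transformation_rules()].
#' @param max_iter maximum number of iterations (> 0).
#' @return a list with `molecules`, `n_structures`, `iterations`,
#'   `last_new_iteration`, `per_iteration` (a data frame of counts) and
#'   `records` (provenance).
#' @export
enumerate_isomers <- function(seed, rules, max_iter = 1000L) {
  if (max_iter <= 0L) stop("'max_iter' must be a positive integer")
  seed <- .as_seed(seed, "explicit")
  chk <- filter_valence_and_rings(filter_connected(list(seed))$molecules)
  if (length(chk$molecules) == 0L)
    stop("the seed molecule does not pass the structural filters")

  state <- enumeration_state(seed)
  last_new <- 0L
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    state <- expand_once(state, rules)
    iterations <- it
    if (length(state$source) > 0L) last_new <- it else break
  }
  per_it <- do.call(rbind, lapply(state$counts, function(x)
    as.data.frame(as.list(x))))
  list(molecules = state$molecules,
       n_structures = length(state$molecules),
       iterations = iterations,
       last_new_iteration = last_new,
       per_iteration = per_it,
       records = state$records)
}

#' Enumerate molecular skeletons by canonical augmentation
#'
#' Grows molecular graphs one atom per iteration, starting from a single
#' unbonded carbon atom, keeping one canonical representative of every
#' structure generated. With the single-attachment rule only, the cumulative
#' output after `max_atoms - 1` iterations is every acyclic carbon skeleton
#' (alkane) with up to `max_atoms` atoms.
#'
#' @param max_atoms target heavy-atom count (>= 1); the number of iterations
#'   is `max_atoms - 1`.
#' @param rules augmentation rules; defaults to the single-bond attachment
#'   rule ([augmentation_rules] rule 1).
#' @return a list with `molecules` (cumulative, all sizes), `per_size`
#'   (data frame of counts by heavy-atom count) and `n_structures`.
#' @export
canonical_augmentation <- function(max_atoms, rules = augmentation_rules(1L)) {
  if (max_atoms < 1L) stop("'max_atoms' must be >= 1")
  seed <- new_rx_mol(6L, 0L, empty_bond_matrix())
  state <- enumeration_state(seed)
  for (it in seq_len(max_atoms - 1L)) {
    state <- expand_once(state, rules)
    if (length(state$source) == 0L) break
  }
  sizes <- vapply(state$molecules, heavy_atom_count, 0L)
  per_size <- as.data.frame(table(n_heavy = sizes), stringsAsFactors = FALSE)
  per_size$n_heavy <- as.integer(per_size$n_heavy)
  names(per_size)[2] <- "count"
  list(molecules = state$molecules,
       per_size = per_size,
       n_structures = length(state$molecules))
}

#' Atom-attachment rules for canonical augmentation
#'
#' Rule k attaches one new carbon atom to k existing carbon atoms that are
#' pairwise non-adjacent (attachment through 2-4 bonds closes rings while
#' staying triangle-free). Rule 1 alone generates acyclic skeletons.
#'
#' @param which integer vector selecting rules from 1:4.
#' @return a list of [reaction_rule] objects.
#' @export
augmentation_rules <- function(which = 1:4) {
  smarts <- c(
    "[C:1]>>[C:1]C",
    "([C:1]![C:2])>>([C:1]C[C:2])",
    "([C:1]!1![C:2]![C:3]!1)>>([C:1]C([C:2])[C:3])",
    "([C:1]!1!2![C:2]!3![C:3]!1![C:4]!2!3)>>([C:1]C([C:2])([C:3])[C:4])"
  )
  lapply(which, function(k)
    reaction_rule(smarts[k], rule_id = paste0("AUG", k)))
}

#' FIFO-queue (memory-chunked) enumeration
#'
#' A queue-driven variant of [enumerate_isomers]: rules are fired on small
#' chunks of structures taken from the front of a FIFO queue and new
#' products are appended at the back. The final structure set is identical
#' to the breadth-first result; only memory behaviour differs.
#'
#' @inheritParams enumerate_isomers
#' @param chunk_size number of structures processed per firing round (>= 1).
#' @return a list with `molecules` and `n_structures`.
#' @export
enumerate_queue <- function(seed, rules, chunk_size = 20L, max_iter = 1e6L) {
  if (chunk_size < 1L) stop("'chunk_size' must be >= 1")
  seed <- .as_seed(seed, "explicit")
  state <- enumeration_state(seed)
  queue <- state$source
  rounds <- 0L
  while (length(queue) > 0L && rounds < max_iter) {
    rounds <- rounds + 1L
    take <- seq_len(min(chunk_size, length(queue)))
    chunk <- queue[take]
    queue <- queue[-take]
    state$source <- chunk
    state <- expand_once(state, rules)
    queue <- c(queue, state$source)
  }
  list(molecules = state$molecules, n_structures = length(state$molecules))
}
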