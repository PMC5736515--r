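#' Stochastic chemical-space screening
#'
#' Virtual screening around reference structures (MACCS/Tanimoto similarity
#' filtering) and an inverse-QSAR style stochastic search: reaction rules
#' generate candidate structures, a user-supplied scorer ranks them, and a
#' tournament selection keeps the population bounded while guaranteeing the
#' incumbent best survives.
#'
#' @name screening
NULL

# SDFset for a list of molecules (via the package's V2000 writer)
.as_sdfset <- function(mols) {
  blocks <- vapply(mols, .graph_to_molblock, "")
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(paste0(blocks, collapse = ""), tf)
  ChemmineR::read.SDFset(tf)
}

#' MACCS-key Tanimoto similarity
#'
#' @param mol_a,mol_b [rx_mol] objects.
#' @return Tanimoto coefficient of the two MACCS fingerprints in `[0, 1]`.
#' @export
maccs_tanimoto <- function(mol_a, mol_b) {
  fp <- ChemmineR::fingerprintOB(.as_sdfset(list(mol_a, mol_b)), "MACCS")
  unname(ChemmineR::fpSim(fp[1], fp[2], method = "Tanimoto"))
}

#' Similarity filter against a reference structure
#'
#' Retains the structures whose MACCS-key Tanimoto similarity to the
#' reference is strictly greater than the threshold.
#'
#' @param mols list of [rx_mol] objects.
#' @param reference the reference [rx_mol].
#' @param threshold similarity threshold in `[0, 1]` (default 0.5).
#' @return the retained subset of `mols`, with the similarity values as
#'   attribute `"similarity"`.
#' @export
similarity_filter <- function(mols, reference, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!length(mols)) return(mols)
  fp <- ChemmineR::fingerprintOB(.as_sdfset(c(list(reference), mols)), "MACCS")
  sims <- as.numeric(ChemmineR::fpSim(fp[1], fp, method = "Tanimoto",
                                      sorted = FALSE))[-1]
  out <- mols[sims > threshold]
  attr(out, "similarity") <- sims[sims > threshold]
  out
}

#' Tournament selection
#'
#' Randomly partitions the scored structures into `n_subsets` subsets of
#' near-equal size (sizes differ by at most one) and retains the `top_k`
#' best-scored structures of each subset. The globally best structure is
#' always retained; score ties are broken by canonical key so that a given
#' RNG state yields a reproducible selection.
#'
#' @param mols list of [rx_mol] objects.
#' @param scores numeric scores, one per molecule (higher is better).
#' @param n_subsets number of random subsets (default 10).
#' @param top_k structures retained per subset (default 10).
#' @return the selected molecules, with their scores as attribute
#'   `"scores"`.
#' @export
tournament_select <- function(mols, scores, n_subsets = 10L, top_k = 10L) {
  stopifnot(length(mols) == length(scores), n_subsets >= 1L, top_k >= 1L)
  n <- length(mols)
  if (n == 0L) stop("'mols' must be non-empty")
  perm <- sample.int(n)
  subset_id <- rep(seq_len(n_subsets), length.out = n)
  keys <- vapply(mols, canonical_key, "")
  sel <- integer(0)
  for (s in seq_len(n_subsets)) {
    idx <- perm[subset_id == s]
    if (!length(idx)) next
    ord <- idx[order(-scores[idx], keys[idx])]
    sel <- c(sel, head(ord, top_k))
  }
  sel <- sort(sel)
  out <- mols[sel]
  attr(out, "scores") <- scores[sel]
  out
}

.rule_is_bimolecular <- function(rule) {
  if (rule$n_reactant_components >= 2L) return(TRUE)
  # a single-group pattern with >= 2 disconnected fragments can recombine
  # two molecules (crossover application)
  p <- rule$p
  if (p < 2L) return(FALSE)
  adj <- rule$pbond >= 1L
  comp <- integer(p)
  c0 <- 0L
  for (s in seq_len(p)) {
    if (comp[s] > 0L) next
    c0 <- c0 + 1L
    queue <- s
    comp[s] <- c0
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- c0
      queue <- c(queue, nb)
    }
  }
  c0 >= 2L
}

#' Built-in synthetic scorers
#'
#' `scorer_heavy_atom_target()` scores a molecule by the negative absolute
#' difference of its heavy-atom count from a target (maximum 0 at the
#' target size) -- a transparent landscape for testing search behaviour.
#' `scorer_maccs_similarity()` scores by MACCS/Tanimoto similarity to a
#' reference structure.
#'
#' @param target target heavy-atom count.
#' @return a scorer: a deterministic function mapping an [rx_mol] to a
#'   numeric score (higher is better).
#' @export
scorer_heavy_atom_target <- function(target = 8L) {
  force(target)
  function(mol) -abs(heavy_atom_count(mol) - target)
}

#' @rdname scorer_heavy_atom_target
#' @param reference reference [rx_mol] for similarity scoring.
#' @export
scorer_maccs_similarity <- function(reference) {
  force(reference)
  function(mol) maccs_tanimoto(mol, reference)
}

#' Inverse-QSAR stochastic search
#'
#' Iteratively explores chemical space around a source set: at each
#' iteration reactant structures are drawn from the current population (one
#' for unimolecular rule sets, an ordered pair for rule sets that recombine
#' two molecules), all rules are fired on them, the products are scored,
#' merged with the current population, and the next population is picked by
#' [tournament_select()]. Scoring failures drop the product with a warning.
#' Seed the RNG (`set.seed()`) for reproducible runs.
#'
#' @param sources non-empty list of [rx_mol] starting structures.
#' @param rules list of [reaction_rule] objects.
#' @param scorer a scorer function (see [scorer_heavy_atom_target()]).
#' @param iterations number of iterations (>= 0).
#' @param n_subsets,top_k tournament parameters (defaults 10 and 10).
#' @param breadth `"sampled"` draws random reactants each iteration (the
#'   stochastic search proper); `"all"` fires the rules on every population
#'   member each iteration (deterministic exploration of small landscapes).
#' @param max_valence product sanitization cap, see [apply_rule].
#' @return a list with `trajectory` (data frame `iteration`, `best`,
#'   `mean`, `pop_size`), `population` (final molecules) and `scores`.
#' @export
inverse_qsar_search <- function(sources, rules, scorer, iterations = 100L,
                                n_subsets = 10L, top_k = 10L,
                                breadth = c("sampled", "all"),
                                max_valence = 4L) {
  breadth <- match.arg(breadth)
  if (inherits(sources, "rx_mol")) sources <- list(sources)
  if (!length(sources)) stop("'sources' must be non-empty")
  if (inherits(rules, "rx_rule")) rules <- list(rules)
  if (!length(rules)) stop("at least one reaction rule is required")

  score_cache <- new.env(parent = emptyenv())
  score_of <- function(mol) {
    key <- canonical_key(mol)
    if (!exists(key, envir = score_cache, inherits = FALSE)) {
      val <- tryCatch(as.numeric(scorer(mol)), error = function(e) {
        warning("scorer failed on a product; dropped (", conditionMessage(e),
                ")")
        NA_real_
      })
      assign(key, val, envir = score_cache)
    }
    get(key, envir = score_cache, inherits = FALSE)
  }

  pop <- dedup_molecules(sources)
  pop_scores <- vapply(pop, score_of, 0)
  keep <- !is.na(pop_scores)
  pop <- pop[keep]; pop_scores <- pop_scores[keep]
  bimolecular <- any(vapply(rules, .rule_is_bimolecular, NA))

  traj <- data.frame(iteration = integer(0), best = numeric(0),
                     mean = numeric(0), pop_size = integer(0))
  if (iterations < 1L)
    return(list(trajectory = traj, population = pop, scores = pop_scores))

  for (it in seq_len(iterations)) {
    reactant_sets <- list()
    if (breadth == "all") {
      reactant_sets <- lapply(pop, list)
    } else if (bimolecular && length(pop) >= 2L) {
      pick <- sample.int(length(pop), 2L)
      reactant_sets <- list(list(pop[[pick[1]]]), list(pop[[pick[2]]]),
                            list(pop[[pick[1]]], pop[[pick[2]]]),
                            list(pop[[pick[2]]], pop[[pick[1]]]))
    } else {
      pick <- sample.int(length(pop), 1L)
      reactant_sets <- list(list(pop[[pick]]))
    }
    products <- list()
    for (rule in rules) {
      for (rs in reactant_sets) {
        if (length(rs) == 1L) {
          tp <- apply_rule(rule, rs[[1]], max_valence = max_valence,
                           connected_only = TRUE)
        } else if (.rule_is_bimolecular(rule)) {
          tp <- apply_rule(rule, rs, max_valence = max_valence,
                           connected_only = TRUE)
        } else next
        for (t in tp) products <- c(products, t)
      }
    }
    merged <- dedup_molecules(c(pop, products))
    merged_scores <- vapply(merged, score_of, 0)
    ok <- !is.na(merged_scores)
    merged <- merged[ok]; merged_scores <- merged_scores[ok]
    pop <- tournament_select(merged, merged_scores,
                             n_subsets = n_subsets, top_k = top_k)
    pop_scores <- attr(pop, "scores")
    traj <- rbind(traj, data.frame(iteration = it, best = max(pop_scores),
                                   mean = mean(pop_scores),
                                   pop_size = length(pop)))
  }
  list(trajectory = traj, population = pop, scores = pop_scores)
}
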