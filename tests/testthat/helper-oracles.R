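# Independent oracles used to cross-check the graph engine. These share no
# code with the package internals: trees come from Prufer sequences and are
# canonized with an AHU encoding; general labelled graphs are deduplicated
# with igraph's BLISS canonical permutation.

# ---- AHU canonical code for free trees -----------------------------------

# rooted subtree code: "(" sorted child codes ")"
.ahu_rooted <- function(adj, root, parent) {
  kids <- setdiff(adj[[root]], parent)
  if (!length(kids)) return("()")
  paste0("(", paste0(sort(vapply(kids, function(k)
    .ahu_rooted(adj, k, root), "")), collapse = ""), ")")
}

# canonical code of a free tree given its edge list (n x 2)
ahu_tree_code <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  if (n == 1L) return("()")
  # find center(s) by leaf stripping
  deg <- lengths(adj)
  alive <- rep(TRUE, n)
  remaining <- n
  layer <- which(deg <= 1L)
  while (remaining > 2L) {
    alive[layer] <- FALSE
    remaining <- remaining - length(layer)
    nxt <- integer(0)
    for (v in layer) for (u in adj[[v]]) {
      if (!alive[u]) next
      deg[u] <- deg[u] - 1L
      if (deg[u] == 1L) nxt <- c(nxt, u)
    }
    layer <- unique(nxt)
  }
  centers <- which(alive)
  min(vapply(centers, function(c0) .ahu_rooted(adj, c0, 0L), ""))
}

# ---- free trees with max degree 4 via Prufer sequences -------------------

# all free (unlabelled) trees on n vertices with max degree 4, as a set of
# AHU codes; decodes every Prufer sequence simultaneously (vectorized).
oracle_alkane_skeletons <- function(n) {
  if (n == 1L) return("()")
  if (n == 2L) return(ahu_tree_code(2L, cbind(1L, 2L)))
  S <- n^(n - 2L)
  P <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  storage.mode(P) <- "integer"
  # degree = multiplicity + 1; max degree 4 <=> multiplicity <= 3
  deg <- matrix(1L, S, n)
  for (k in seq_len(n - 2L))
    deg[cbind(seq_len(S), P[, k])] <- deg[cbind(seq_len(S), P[, k])] + 1L
  keep <- apply(deg <= 4L, 1L, all)
  P <- P[keep, , drop = FALSE]
  deg <- deg[keep, , drop = FALSE]
  S <- nrow(P)
  E1 <- matrix(0L, S, n - 1L)
  E2 <- matrix(0L, S, n - 1L)
  for (k in seq_len(n - 2L)) {
    leaf <- max.col(deg == 1L, ties.method = "first")
    E1[, k] <- leaf
    E2[, k] <- P[, k]
    deg[cbind(seq_len(S), leaf)] <- 0L
    idx <- cbind(seq_len(S), P[, k])
    deg[idx] <- deg[idx] - 1L
  }
  last <- t(apply(deg == 1L, 1L, which))
  E1[, n - 1L] <- last[, 1L]
  E2[, n - 1L] <- last[, 2L]
  codes <- character(S)
  for (r in seq_len(S))
    codes[r] <- ahu_tree_code(n, cbind(E1[r, ], E2[r, ]))
  sort(unique(codes))
}

# AHU code of the carbon skeleton of an rx_mol (alkane)
skeleton_ahu <- function(mol) {
  heavy <- which(mol$z != 1L)
  stopifnot(all(mol$z[heavy] == 6L))
  relab <- match(seq_along(mol$z), heavy)
  b <- mol$bond[mol$bond[, 1] %in% heavy & mol$bond[, 2] %in% heavy, ,
                drop = FALSE]
  if (length(heavy) == 1L) return("()")
  ahu_tree_code(length(heavy), cbind(relab[b[, 1]], relab[b[, 2]]))
}

# ---- igraph-based canonical key for labelled molecular graphs ------------

# exact canonical string via BLISS; bond orders are encoded by subdividing
# each edge with a dummy vertex coloured by the order.
igraph_canon_key <- function(z, bond) {
  n <- length(z)
  nb <- nrow(bond)
  colors <- c(z, if (nb) 200L + bond[, 3])
  el <- NULL
  for (r in seq_len(nb)) {
    d <- n + r
    el <- rbind(el, c(bond[r, 1], d), c(d, bond[r, 2]))
  }
  g <- igraph::make_empty_graph(n = n + nb, directed = FALSE)
  if (!is.null(el)) g <- igraph::add_edges(g, t(el))
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  g2 <- igraph::permute(g, perm)
  el2 <- igraph::as_edgelist(g2)
  el2 <- t(apply(el2, 1L, sort))
  el2 <- el2[order(el2[, 1], el2[, 2]), , drop = FALSE]
  paste(c(colors[order(perm)], as.vector(t(el2))), collapse = ",")
}

igraph_mol_key <- function(mol) igraph_canon_key(mol$z, mol$bond)

# ---- brute-force application of the single-bond rearrangement ------------

# applies "break (1,2) and (3,4), form (2,3) and (1,4)" over every ordered
# 4-tuple of atoms by direct search; returns igraph canonical keys of the
# connected products (dedup included)
bruteforce_single_bond_products <- function(mol) {
  n <- length(mol$z)
  A <- matrix(0L, n, n)
  for (r in seq_len(nrow(mol$bond))) {
    A[mol$bond[r, 1], mol$bond[r, 2]] <- mol$bond[r, 3]
    A[mol$bond[r, 2], mol$bond[r, 1]] <- mol$bond[r, 3]
  }
  keys <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    for (l in seq_len(n)) {
      t4 <- c(i, j, k, l)
      if (length(unique(t4)) != 4L) next
      if (A[i, j] != 1L || A[k, l] != 1L) next
      if (A[j, k] != 0L || A[i, l] != 0L) next
      A2 <- A
      A2[i, j] <- A2[j, i] <- 0L
      A2[k, l] <- A2[l, k] <- 0L
      A2[j, k] <- A2[k, j] <- 1L
      A2[i, l] <- A2[l, i] <- 1L
      # connectivity by BFS
      seen <- logical(n); seen[1] <- TRUE; q <- 1L
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        nb <- which(A2[v, ] > 0L & !seen)
        seen[nb] <- TRUE
        q <- c(q, nb)
      }
      if (!all(seen)) next
      ut <- which(upper.tri(A2) & A2 > 0L, arr.ind = TRUE)
      bond2 <- cbind(ut[, 1], ut[, 2], A2[ut])
      keys <- c(keys, igraph_canon_key(mol$z, bond2))
    }
  sort(unique(keys))
}

# ---- exhaustive connected carbon graphs (for the lemma machinery) --------

# all connected heavy-atom (carbon) graphs on n atoms with bond orders 1..3,
# per-atom valence <= 4 and the small-ring double-bond constraint, as
# labelled adjacency matrices deduplicated by igraph canonical key
oracle_carbon_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pairs)
  out <- list()
  seen <- character(0)
  A <- matrix(0L, n, n)
  recurse <- function(p) {
    if (p > np) {
      deg <- rowSums(A > 0L)
      if (any(deg == 0L) && n > 1L) return()
      # connectivity
      seen_v <- logical(n); seen_v[1] <- TRUE; q <- 1L
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        nb <- which(A[v, ] > 0L & !seen_v)
        seen_v[nb] <- TRUE
        q <- c(q, nb)
      }
      if (!all(seen_v)) return()
      # ring/double-bond constraint
      for (v in seq_len(n)) {
        if (sum(A[v, ] == 2L) < 2L) next
        nbv <- which(A[v, ] > 0L)
        for (a in nbv) for (b in nbv) {
          if (a >= b) next
          if (A[a, b] > 0L) return()
          if (any(A[a, ] > 0L & A[b, ] > 0L & seq_len(n) != v)) return()
        }
      }
      ut <- which(upper.tri(A) & A > 0L, arr.ind = TRUE)
      bond <- cbind(ut[, 1], ut[, 2], A[ut])
      key <- igraph_canon_key(rep(6L, n), bond)
      if (!(key %in% seen)) {
        seen <<- c(seen, key)
        out[[length(out) + 1L]] <<- A
      }
      return()
    }
    i <- pairs[p, 1]; j <- pairs[p, 2]
    for (o in 0:3) {
      if (sum(A[i, ]) + o > 4L || sum(A[j, ]) + o > 4L) next
      A[i, j] <<- A[j, i] <<- o
      recurse(p + 1L)
    }
    A[i, j] <<- A[j, i] <<- 0L
  }
  recurse(1L)
  out
}

# hydrogen-saturate a labelled carbon adjacency matrix into an rx_mol with
# explicit hydrogens appended in index order
saturate_explicit <- function(A) {
  n <- nrow(A)
  hdef <- 4L - rowSums(A)
  stopifnot(all(hdef >= 0L))
  ntot <- n + sum(hdef)
  ut <- which(upper.tri(A) & A > 0L, arr.ind = TRUE)
  bond <- cbind(ut[, 1], ut[, 2], A[ut])
  k <- n
  for (v in seq_len(n)) {
    if (hdef[v] == 0L) next
    for (q in seq_len(hdef[v])) {
      k <- k + 1L
      bond <- rbind(bond, c(v, k, 1L))
    }
  }
  rxnet:::new_rx_mol(c(rep(6L, n), rep(1L, ntot - n)), integer(ntot), bond)
}
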