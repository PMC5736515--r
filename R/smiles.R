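# Reader/writer for the kekulized SMILES subset used by rule patterns and
# atom-mapped reaction SMILES. General molecule input goes through OpenBabel
# (see parse_molecule); this dialect exists because reaction rules need
# atom-map numbers, wildcard atoms and bond-absence semantics that a plain
# molecule toolkit does not expose. Supported: organic-subset atoms
# (B C N O P S F Cl Br I), bracket atoms [C:1] [CH3:2] [#6:1] [O-] [*:3],
# bonds - = # ~ (~ = unconstrained, patterns only), branches, ring closures
# (digits and %nn), '.' separators and '(...)' component groups on each side
# of '>>'. No aromatic lower-case atoms: structures are kekulized.

.organic_symbols <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")

# Parse one piece (a molecule or pattern fragment that may contain '.').
# Returns list(atoms = data.frame(z, charge, chg_fixed, hcount, map),
#              bonds = matrix(i, j, order), frag = integer fragment id)
.parse_connection_string <- function(s, pattern = FALSE) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  z <- integer(0); charge <- integer(0); chg_fixed <- logical(0)
  hcount <- integer(0); map <- integer(0); frag <- integer(0)
  bi <- integer(0); bj <- integer(0); bo <- integer(0)
  prev <- NA_integer_
  pending <- NA_integer_
  stack <- integer(0)
  rings <- list()
  fragment <- 1L
  i <- 1L

  add_atom <- function(zz, ch, fixed, hh, mm) {
    z[length(z) + 1L] <<- zz
    charge[length(charge) + 1L] <<- ch
    chg_fixed[length(chg_fixed) + 1L] <<- fixed
    hcount[length(hcount) + 1L] <<- hh
    map[length(map) + 1L] <<- mm
    frag[length(frag) + 1L] <<- fragment
    a <- length(z)
    if (!is.na(prev)) {
      o <- if (is.na(pending)) 1L else pending
      bi[length(bi) + 1L] <<- prev; bj[length(bj) + 1L] <<- a
      bo[length(bo) + 1L] <<- o
    }
    prev <<- a
    pending <<- NA_integer_
    a
  }
  close_ring <- function(id) {
    o <- if (is.na(pending)) NA_integer_ else pending
    pending <<- NA_integer_
    key <- as.character(id)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- c(prev, if (is.na(o)) -99L else o)
    } else {
      open <- rings[[key]]
      oo <- if (!is.na(o)) o else if (open[2] != -99L) open[2] else 1L
      bi[length(bi) + 1L] <<- open[1]; bj[length(bj) + 1L] <<- prev
      bo[length(bo) + 1L] <<- oo
      rings[[key]] <<- NULL
    }
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in '", s, "'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "-") {
      pending <- 1L; i <- i + 1L
    } else if (ch == "=") {
      pending <- 2L; i <- i + 1L
    } else if (ch == "#") {
      pending <- 3L; i <- i + 1L
    } else if (ch == "~") {
      if (!pattern) stop("'~' bond is only valid in rule patterns")
      pending <- -1L; i <- i + 1L
    } else if (ch == "!") {
      if (!pattern) stop("'!' (no-bond constraint) is only valid in rule patterns")
      pending <- 0L; i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; fragment <- fragment + 1L; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
    } else if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in '", s, "'")
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^(#[0-9]+|\\*|[A-Z][a-z]?)(H[0-9]*)?(\\+{1,2}|-{1,2}|[+-][0-9])?(:[0-9]+)?$",
        body))[[1]]
      if (!length(m)) stop("cannot parse bracket atom [", body, "]")
      sym <- m[2]
      zz <- if (sym == "*") {
        if (!pattern) stop("wildcard atom only valid in rule patterns")
        0L
      } else if (startsWith(sym, "#")) {
        as.integer(substr(sym, 2, nchar(sym)))
      } else element_number(sym)
      hh <- if (nzchar(m[3])) {
        if (m[3] == "H") 1L else as.integer(substr(m[3], 2, nchar(m[3])))
      } else NA_integer_
      cc <- 0L; fixed <- FALSE
      if (nzchar(m[4])) {
        fixed <- TRUE
        cc <- switch(m[4], "+" = 1L, "++" = 2L, "-" = -1L, "--" = -2L,
                     as.integer(m[4]))
      }
      mm <- if (nzchar(m[5])) as.integer(substr(m[5], 2, nchar(m[5]))) else 0L
      add_atom(zz, cc, fixed || !pattern, hh, mm)
      i <- j + 1L
    } else if (grepl("[A-Z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ch
      if (two %in% .organic_symbols) {
        add_atom(element_number(two), 0L, !pattern, NA_integer_, 0L)
        i <- i + 2L
      } else if (ch %in% .organic_symbols) {
        add_atom(element_number(ch), 0L, !pattern, NA_integer_, 0L)
        i <- i + 1L
      } else stop("unexpected symbol '", ch, "' in '", s, "'")
    } else stop("unexpected character '", ch, "' in '", s, "'")
  }
  if (length(stack)) stop("unbalanced '(' in '", s, "'")
  if (length(rings)) stop("unclosed ring bond in '", s, "'")
  if (!pattern && length(bo) && any(bo < 1L))
    stop("unconstrained or absent bond in a molecule string: '", s, "'")
  list(atoms = data.frame(z = z, charge = charge, chg_fixed = chg_fixed,
                          hcount = hcount, map = map),
       bonds = matrix(c(bi, bj, bo), ncol = 3L,
                      dimnames = list(NULL, c("i", "j", "order"))),
       frag = frag)
}

# Split a reaction side on top-level dots; '(...)' wraps one component group.
.split_side <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L; inbr <- FALSE
  cut <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "[") inbr <- TRUE
    else if (ch == "]") inbr <- FALSE
    else if (!inbr && ch == "(") depth <- depth + 1L
    else if (!inbr && ch == ")") depth <- depth - 1L
    else if (!inbr && ch == "." && depth == 0L) cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  pieces <- vapply(seq_along(starts), function(k)
    paste0(chars[starts[k]:ends[k]], collapse = ""), "")
  lapply(pieces, function(p) {
    grouped <- grepl("^\\(", p) && grepl("\\)$", p)
    if (grouped) p <- substr(p, 2, nchar(p) - 1L)
    list(text = p, grouped = grouped)
  })
}

# Parse one reaction side into component-annotated atoms/bonds.
.parse_side <- function(s, pattern = FALSE) {
  pieces <- .split_side(s)
  atoms <- NULL; bonds <- NULL; comp <- integer(0)
  offset <- 0L
  for (k in seq_along(pieces)) {
    p <- .parse_connection_string(pieces[[k]]$text, pattern = pattern)
    atoms <- rbind(atoms, p$atoms)
    if (nrow(p$bonds)) {
      b <- p$bonds
      b[, 1:2] <- b[, 1:2] + offset
      bonds <- rbind(bonds, b)
    }
    comp <- c(comp, rep(k, nrow(p$atoms)))
    offset <- offset + nrow(p$atoms)
  }
  if (is.null(bonds)) bonds <- empty_bond_matrix()
  list(atoms = atoms, bonds = bonds, component = comp,
       n_components = length(pieces))
}

.parse_reaction <- function(text, pattern = FALSE) {
  sides <- strsplit(text, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("a reaction string must contain exactly one '>>': '", text, "'")
  list(reactant = .parse_side(sides[1], pattern = pattern),
       product = .parse_side(sides[2], pattern = pattern))
}

# ---- writer --------------------------------------------------------------

.atom_token <- function(z, charge, map, hcount = NA_integer_) {
  if (z == 0L) {
    inner <- "*"
  } else {
    inner <- element_symbol(z)
  }
  need_bracket <- z == 0L || map > 0L || charge != 0L || !is.na(hcount) ||
    !(inner %in% .organic_symbols)
  if (!need_bracket) return(inner)
  if (!is.na(hcount) && hcount > 0L)
    inner <- paste0(inner, "H", if (hcount > 1L) hcount else "")
  if (charge != 0L)
    inner <- paste0(inner, if (charge > 0) "+" else "-",
                    if (abs(charge) > 1L) abs(charge) else "")
  if (map > 0L) inner <- paste0(inner, ":", map)
  paste0("[", inner, "]")
}

.bond_token <- function(o, explicit_single) {
  switch(as.character(o),
         "0" = "!",
         "1" = if (explicit_single) "-" else "",
         "2" = "=", "3" = "#", "-1" = "~",
         stop("cannot serialize bond order ", o))
}

# Serialize a fragment set (atoms/bonds with maps) to the dialect. Fragments
# are joined with '.'; the caller wraps groups in parentheses if needed.
.write_smiles <- function(z, charge, bond, map = NULL,
                          explicit_single = FALSE, hcount = NULL) {
  n <- length(z)
  if (n == 0L) return("")
  if (is.null(map)) map <- integer(n)
  adj <- vector("list", n)
  if (nrow(bond)) {
    for (r in seq_len(nrow(bond))) {
      i <- bond[r, 1]; j <- bond[r, 2]
      adj[[i]] <- rbind(adj[[i]], c(j, bond[r, 3]))
      adj[[j]] <- rbind(adj[[j]], c(i, bond[r, 3]))
    }
  }
  visited <- logical(n)
  ring_id <- 0L
  ring_marks <- vector("list", n)  # per atom: list of c(id, order, emit_bond)
  edge_used <- new.env(parent = emptyenv())
  ekey <- function(i, j) paste0(min(i, j), "_", max(i, j))

  # first pass: identify back edges via DFS
  dfs_tree <- function(start) {
    stack <- list(c(start, NA))
    order_out <- integer(0)
    parent <- rep(NA_integer_, n)
    visited[start] <<- TRUE
    st <- c(start)
    parent[start] <- 0L
    # iterative DFS recording tree edges
    pos <- 1L
    while (pos >= 1L) {
      v <- st[pos]
      nbrs <- adj[[v]]
      advanced <- FALSE
      if (!is.null(nbrs)) {
        for (r in seq_len(nrow(nbrs))) {
          u <- nbrs[r, 1]
          if (!visited[u]) {
            visited[u] <<- TRUE
            parent[u] <- v
            assign(ekey(v, u), TRUE, envir = edge_used)
            st <- c(st[seq_len(pos)], u)
            pos <- pos + 1L
            advanced <- TRUE
            break
          }
        }
      }
      if (!advanced) pos <- pos - 1L
    }
    parent
  }

  out_frag <- character(0)
  for (start in seq_len(n)) {
    if (visited[start]) next
    parent <- dfs_tree(start)
    # assign ring closure digits for back edges in this fragment
    comp_atoms <- which(!is.na(parent))
    for (v in comp_atoms) {
      nbrs <- adj[[v]]
      if (is.null(nbrs)) next
      for (r in seq_len(nrow(nbrs))) {
        u <- nbrs[r, 1]
        if (u <= v) next
        if (!exists(ekey(v, u), envir = edge_used)) {
          ring_id <- ring_id + 1L
          o <- nbrs[r, 2]
          ring_marks[[v]] <- c(ring_marks[[v]], list(c(ring_id, o, 1L)))
          ring_marks[[u]] <- c(ring_marks[[u]], list(c(ring_id, o, 0L)))
          assign(ekey(v, u), TRUE, envir = edge_used)
        }
      }
    }
    ring_txt <- function(v) {
      marks <- ring_marks[[v]]
      if (is.null(marks)) return("")
      paste0(vapply(marks, function(m) {
        d <- if (m[1] <= 9) as.character(m[1]) else sprintf("%%%02d", m[1])
        b <- if (m[3] == 1L && (m[2] != 1L || explicit_single || m[2] == 0L))
          .bond_token(m[2], explicit_single) else ""
        paste0(b, d)
      }, ""), collapse = "")
    }
    emit <- function(v) {
      hc <- if (is.null(hcount)) NA_integer_ else hcount[v]
      txt <- paste0(.atom_token(z[v], charge[v], map[v], hc), ring_txt(v))
      kids <- which(parent == v)
      if (length(kids)) {
        korder <- vapply(kids, function(u) {
          nbrs <- adj[[v]]
          nbrs[nbrs[, 1] == u, 2][1]
        }, 0)
        for (k in seq_along(kids)) {
          sub <- paste0(.bond_token(korder[k], explicit_single), emit(kids[k]))
          txt <- if (k < length(kids)) paste0(txt, "(", sub, ")")
          else paste0(txt, sub)
        }
      }
      txt
    }
    out_frag <- c(out_frag, emit(start))
  }
  paste0(out_frag, collapse = ".")
}
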