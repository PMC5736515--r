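#' File formats and fixtures
#'
#' Rules travel as CSV with columns `rule_id`, `smarts`, `diameter`, `ec`
#' (EC numbers `;`-separated, `diameter` empty or `Inf` for full-molecule
#' rules); molecules as CSV with `name`, `structure` (SMILES or InChI)
#' columns. [generate_fixtures()] builds the toy inputs every module can be
#' exercised with, without any external download.
#'
#' @name io_formats
NULL

#' Read and write reaction-rule CSV files
#'
#' @param path file path.
#' @return `read_rules()` returns a list of [reaction_rule] objects.
#' @export
read_rules <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("rule file '", path, "' contains no rules")
    return(list())
  }
  if (!"smarts" %in% names(df))
    stop("rule file '", path, "' is missing the 'smarts' column")
  if (!"rule_id" %in% names(df)) df$rule_id <- df$smarts
  lapply(seq_len(nrow(df)), function(k) {
    d <- if ("diameter" %in% names(df)) {
      dk <- df$diameter[k]
      if (is.na(dk) || dk == "" || dk == "Inf") Inf else as.numeric(dk)
    } else Inf
    ec <- if ("ec" %in% names(df) && !is.na(df$ec[k]) && nzchar(df$ec[k]))
      strsplit(df$ec[k], ";", fixed = TRUE)[[1]] else character(0)
    tryCatch(
      reaction_rule(df$smarts[k], rule_id = df$rule_id[k], diameter = d,
                    ec = ec),
      error = function(e)
        stop("invalid rule SMARTS on line ", k + 1L, " of '", path, "': ",
             conditionMessage(e)))
  })
}

#' @rdname read_rules
#' @param rules list of [reaction_rule] objects.
#' @export
write_rules <- function(rules, path) {
  df <- data.frame(
    rule_id = vapply(rules, `[[`, "", "rule_id"),
    smarts = vapply(rules, `[[`, "", "smarts"),
    diameter = vapply(rules, function(r)
      if (is.finite(r$diameter)) as.character(r$diameter) else "Inf", ""),
    ec = vapply(rules, function(r) paste(r$ec, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a molecule table
#'
#' CSV with `name` and `structure` columns (SMILES or InChI). Unparsable
#' rows are skipped with a warning; rows duplicating an already-seen
#' connectivity are merged with a warning.
#'
#' @param path file path.
#' @param hydrogen_mode passed to [parse_molecule()].
#' @return named list of [rx_mol] objects.
#' @export
read_molecule_table <- function(path, hydrogen_mode = "implicit") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "structure") %in% names(df)))
    stop("molecule table '", path, "' needs 'name' and 'structure' columns")
  out <- list()
  seen <- character(0)
  for (k in seq_len(nrow(df))) {
    m <- tryCatch(parse_molecule(df$structure[k], hydrogen_mode),
                  error = function(e) NULL)
    if (is.null(m)) {
      warning("row ", k, " of '", path, "' is unparsable; skipped")
      next
    }
    if (canonical_key(m) %in% seen) {
      warning("row ", k, " of '", path,
              "' duplicates an earlier structure; merged")
      next
    }
    seen <- c(seen, canonical_key(m))
    out[[df$name[k]]] <- m
  }
  out
}

#' @rdname read_molecule_table
#' @param mols named list of [rx_mol] objects.
#' @export
write_molecule_table <- function(mols, path) {
  df <- data.frame(name = names(mols),
                   structure = vapply(mols, as_smiles, ""),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Deterministic toy fixtures
#'
#' Builds the inputs used throughout the examples and tests: the linear
#' alkane seeds C1-C14, a small heteroatom molecule panel, atom-mapped toy
#' reactions (a transaminase-style carbonyl/amine exchange, a disulfide
#' interchange with two broken and two formed single bonds, a single
#' bond-forming condensation, a degenerate identity reaction and a variant
#' with an unmapped spectator water), built-in synthetic scorers, and a
#' synthetic negative-mode peak list derived from the panel masses with
#' sub-ppm jitter plus unassignable decoy peaks.
#'
#' @param seed RNG seed controlling the synthetic peak jitter; everything
#'   else is constant. The caller's RNG state is restored on exit.
#' @return an `rx_fixture_set` list.
#' @export
generate_fixtures <- function(seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  alkanes <- lapply(1:14, function(n)
    parse_molecule(strrep("C", n), hydrogen_mode = "explicit"))
  names(alkanes) <- paste0("C", 1:14)

  panel_smiles <- c(
    ethanol = "CCO", glycine = "NCC(=O)O", pyruvate = "CC(=O)C(=O)O",
    glycerol = "OCC(O)CO", glucose = "OCC1OC(O)C(O)C(O)C1O",
    succinate = "OC(=O)CCC(=O)O", alanine = "CC(N)C(=O)O",
    butanediol = "OCCCCO")
  panel <- lapply(panel_smiles, parse_molecule)

  mapped_reactions <- list(
    transaminase = paste0(
      "[CH3:1][C:2](=[O:3])[CH2:4][CH3:9].",
      "[NH2:5][CH:6]([CH3:7])[CH3:8]>>",
      "[CH3:1][CH:2]([NH2:5])[CH2:4][CH3:9].",
      "[CH3:7][C:6](=[O:3])[CH3:8]"),
    disulfide_interchange = paste0(
      "[CH3:1][S:2][S:3][CH3:4].[CH3:5][S:6][S:7][CH3:8]>>",
      "[CH3:1][S:2][S:6][CH3:5].[CH3:4][S:3][S:7][CH3:8]"),
    bond_formation = "[CH3:1][O-:2].[CH3+:3]>>[CH3:1][O:2][CH3:3]",
    identity = "[CH3:1][OH:2]>>[CH3:1][OH:2]",
    spectator_water = paste0(
      "[CH3:1][C:2](=[O:3])[CH2:4][CH3:9].",
      "[NH2:5][CH:6]([CH3:7])[CH3:8].O>>",
      "[CH3:1][CH:2]([NH2:5])[CH2:4][CH3:9].",
      "[CH3:7][C:6](=[O:3])[CH3:8].O"))

  scorers <- list(
    heavy_atom_8 = scorer_heavy_atom_target(8L),
    similar_to_glucose = scorer_maccs_similarity(panel$glucose))

  # negative-mode peak list: [M-H]- peaks of the panel with small mass
  # jitter (within 2 ppm) plus decoys far from any panel mass
  masses <- vapply(panel, monoisotopic_mass, 0)
  theo <- masses - 1.007276
  jitter <- theo * runif(length(theo), -2e-6, 2e-6)
  peaks <- data.frame(
    mz = c(theo + jitter, theo * runif(length(theo), 1.05, 1.40)),
    intensity = round(runif(2 * length(theo), 1e4, 1e6)))
  peaks <- peaks[order(peaks$mz), ]
  rownames(peaks) <- NULL

  structure(list(alkanes = alkanes, panel = panel,
                 mapped_reactions = mapped_reactions,
                 scorers = scorers, peaks = peaks, seed = seed),
            class = "rx_fixture_set")
}
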