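test_that("rule parsing, serialization and bond accounting are consistent", {
  r1 <- single_bond_rule()
  expect_equal(r1$p, 4L)
  expect_equal(unname(rule_bond_balance(r1)), c(2L, 2L))
  # every derived rule creates as many bonds as it deletes
  for (r in transformation_rule_set()) {
    bal <- rule_bond_balance(r)
    expect_equal(bal[["created"]], bal[["deleted"]], label = r$rule_id)
  }
  expect_error(reaction_rule("[C:1][C:1]>>[C:1]"), "duplicate atom-map")
  expect_error(reaction_rule("[C:1]>>[C:2]"), "no reactant counterpart")
  expect_error(reaction_rule("C>>C.C>>C"), "exactly one")
})

test_that("single-bond rearrangement on explicit butane matches a brute-force oracle", {
  skip_if_not_installed("igraph")
  butane <- parse_molecule("CCCC", hydrogen_mode = "explicit")
  tuples <- apply_rule(single_bond_rule(), butane, connected_only = TRUE)
  got <- sort(unique(vapply(tuples, function(tp)
    igraph_mol_key(tp[[1]]), "")))
  want <- bruteforce_single_bond_products(butane)
  expect_identical(got, want)
  # and at the connectivity level the products are butane and isobutane
  smis <- sort(vapply(tuples, function(tp) as_smiles(tp[[1]]), ""))
  expect_identical(smis, c("CC(C)C", "CCCC"))
})

test_that("rule application filters disconnected products and counts them", {
  butane <- parse_molecule("CCCC", hydrogen_mode = "explicit")
  tuples <- apply_rule(single_bond_rule(), butane, connected_only = TRUE)
  rep <- attr(tuples, "report")
  # the H/H exchange producing a ring plus an H2 fragment is rejected
  expect_gt(rep[["rejected_disconnected"]], 0L)
  # without the filter those disconnected structures appear as one product
  all_t <- apply_rule(single_bond_rule(), butane, connected_only = FALSE)
  expect_gt(length(all_t), length(tuples))
  ncomp <- vapply(all_t, function(tp)
    max(rxnet:::rxr_components(tp[[1]]$z, tp[[1]]$charge, tp[[1]]$bond)), 0L)
  expect_true(any(ncomp > 1L))
})

test_that("a rule with no embedding yields an empty product set", {
  # pattern wants a double bond; ethane has none
  r <- reaction_rule("([*:1]=[*:2].[*:3]-[*:4])>>([*:1]-[*:2]=[*:3].[*:4])")
  out <- apply_rule(r, parse_molecule("CC", hydrogen_mode = "explicit"))
  expect_length(out, 0L)
})

test_that("transformation products conserve formula and per-atom valence", {
  rules <- transformation_rule_set()
  seeds <- c("CC=CC", "C#CCO", "CC(N)C", "C1CCC1C")
  for (s in seeds) {
    seed <- parse_molecule(s, hydrogen_mode = "explicit")
    vsum0 <- sort(table(seed$z))
    for (r in rules) {
      tuples <- apply_rule(r, seed, connected_only = TRUE)
      for (tp in tuples) {
        m <- tp[[1]]
        expect_identical(mol_formula(m), mol_formula(seed),
                         label = paste(s, r$rule_id))
        # explicit graphs: per-atom total bond order is capped and the
        # element multiset is untouched
        expect_identical(sort(table(m$z)), vsum0)
        A <- rxnet:::.bond_dense(m)
        expect_true(all(rowSums(A) <= 4))
        # valence multiset is conserved (rearrangement moves bonds only)
        A0 <- rxnet:::.bond_dense(seed)
        expect_identical(sort(rowSums(A)), sort(rowSums(A0)))
      }
    }
  }
})

test_that("bimolecular application recombines fragments across molecules", {
  a <- parse_molecule("CCCC", hydrogen_mode = "explicit")
  b <- parse_molecule("CC", hydrogen_mode = "explicit")
  tuples <- apply_rule(single_bond_rule(), list(a, b), connected_only = TRUE)
  formulas <- unique(unlist(lapply(tuples, function(tp)
    vapply(tp, mol_formula, ""))))
  # crossover products include hexane-sized and methane-sized alkanes
  expect_true("C6H14" %in% formulas)
  expect_true("CH4" %in% formulas)
  # atoms are globally conserved in every tuple
  for (tp in tuples) {
    atoms <- sort(unlist(lapply(tp, function(m) m$z)))
    expect_identical(atoms, sort(c(a$z, b$z)))
  }
})

test_that("SMARTS dialect round-trips through parse and write", {
  strings <- c(
    "([*:1]-[*:2].[*:3]-[*:4])>>([*:1]-[*:4].[*:2]-[*:3])",
    "[C:1]>>[C:1]C",
    "[C:1]-[C:2](=[O:3])-[C:4].[N:5]>>[C:1]-[C:2](-[N:5])-[C:4].[O:3]",
    "([C:1]!1![C:2]![C:3]!1)>>([C:1]C([C:2])[C:3])")
  for (s in strings) {
    r1 <- reaction_rule(s)
    r2 <- reaction_rule(paste0(rxnet:::.write_side(r1$sides$reactant), ">>",
                               rxnet:::.write_side(r1$sides$product)))
    expect_true(rules_are_identical(r1, r2), label = s)
  }
})
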