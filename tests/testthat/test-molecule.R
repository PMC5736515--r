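test_that("parsing builds sanitized molecules with correct atom counts", {
  m <- parse_molecule("CC")
  expect_s3_class(m, "rx_mol")
  expect_equal(heavy_atom_count(m), 2L)
  expect_equal(mol_formula(m), "C2H6")

  ex <- parse_molecule("CC", hydrogen_mode = "explicit")
  expect_equal(length(ex$z), 8L)          # 2 C + 6 explicit H
  expect_equal(heavy_atom_count(ex), 2L)  # hydrogens are not heavy atoms

  expect_error(parse_molecule("C("), "cannot parse")
  expect_error(parse_molecule(""), "non-empty")
  expect_error(parse_molecule("C1CC"), "cannot parse")  # unclosed ring
})

test_that("canonical keys identify connectivity, not notation", {
  cases <- list(
    c("OCC", "CCO"),
    c("C(C)(C)C", "CC(C)C"),
    c("c1ccccc1", "C1=CC=CC=C1"),
    c("InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3", "CCO"))
  for (cs in cases)
    expect_identical(canonical_key(parse_molecule(cs[1])),
                     canonical_key(parse_molecule(cs[2])))
  # distinct connectivities get distinct keys
  expect_false(canonical_key(parse_molecule("CCO")) ==
                 canonical_key(parse_molecule("CCN")))
  expect_false(canonical_key(parse_molecule("CCC=C")) ==
                 canonical_key(parse_molecule("CC=CC")))
  expect_false(canonical_key(parse_molecule("C=C")) ==
                 canonical_key(parse_molecule("CC")))
  # hydrogen representation does not matter
  expect_identical(canonical_key(parse_molecule("CCCC", "explicit")),
                   canonical_key(parse_molecule("CCCC")))
  # stereochemistry and charge layers are ignored at the key level
  expect_identical(canonical_key(parse_molecule("C/C=C/C")),
                   canonical_key(parse_molecule("CC=CC")))
})

test_that("parse -> serialize -> parse is idempotent on the canonical key", {
  smiles <- c("CCO", "CC(C)CC", "C1CCCCC1", "NC(=O)CO", "CC(=O)OC",
              "c1ccccc1O", "C#CC", "CC(N)C(=O)O")
  for (s in smiles) {
    m1 <- parse_molecule(s)
    m2 <- parse_molecule(as_smiles(m1))
    expect_identical(canonical_key(m1), canonical_key(m2), label = s)
  }
})

test_that("canonical keys agree with an independent InChI oracle", {
  skip_if_not_installed("igraph")
  # molecules that collide under the package key must produce the same
  # standard InChI, and distinct keys distinct InChIs
  panel <- c("CCO", "OCC", "CC(C)C", "CCCC", "CC=CC", "CCC=C", "C1CCC1",
             "CC(N)C(=O)O", "NC(C)C(=O)O", "OC(=O)CCC(=O)O")
  mols <- lapply(panel, parse_molecule)
  keys <- vapply(mols, canonical_key, "")
  inchis <- vapply(mols, as_inchi, "")
  for (i in seq_along(panel)) for (j in seq_along(panel)) {
    if (i >= j) next
    expect_identical(keys[i] == keys[j], inchis[i] == inchis[j],
                     label = paste(panel[i], "vs", panel[j]))
  }
})

test_that("structural filters reject disconnected and invalid structures", {
  disco <- parse_molecule("CC.O")
  conn <- parse_molecule("CCO")
  res <- filter_connected(list(disco, conn))
  expect_length(res$molecules, 1L)
  expect_equal(res$report$rejected_disconnected, 1L)
  expect_equal(res$report$retained + res$report$rejected_disconnected,
               res$report$input_count)

  # carbon with five bonds
  pent <- rxnet:::new_rx_mol(
    c(6L, rep(1L, 5L)), integer(6),
    cbind(1L, 2:6, 1L))
  ok <- parse_molecule("c1ccccc1")  # alternating double bonds, 6-ring: fine
  cyc <- parse_molecule("C1(=C)CCC1=C")  # hmm: two exocyclic doubles, legal
  bad_ring <- rxnet:::new_rx_mol(  # 4-ring atom carrying two double bonds
    rep(6L, 4L), integer(4),
    rbind(c(1L, 2L, 2L), c(2L, 3L, 1L), c(3L, 4L, 1L), c(4L, 1L, 2L)))
  res2 <- filter_valence_and_rings(list(pent, ok, bad_ring, cyc))
  expect_equal(res2$report$rejected_valence, 1L)
  expect_equal(res2$report$rejected_ring_constraint, 1L)
  expect_length(res2$molecules, 2L)
})

test_that("deduplication by canonical key is idempotent", {
  mols <- lapply(c("CCO", "OCC", "CC", "C(C)O"), parse_molecule)
  once <- dedup_molecules(mols)
  twice <- dedup_molecules(once)
  expect_length(once, 2L)
  expect_identical(vapply(once, canonical_key, ""),
                   vapply(twice, canonical_key, ""))
})

test_that("molecule tables and rule files round-trip through CSV", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("name,structure", "decane,CCCCCCCCCC", "ethanol,CCO",
               "ethanol_inchi,\"InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3\""), tf)
  expect_warning(tab <- read_molecule_table(tf), "duplicates")
  expect_length(tab, 2L)
  expect_equal(heavy_atom_count(tab$decane), 10L)

  tf2 <- tempfile(fileext = ".csv")
  writeLines(c("name,structure", "bad,C1CC", "fine,CCO"), tf2)
  expect_warning(tab2 <- read_molecule_table(tf2), "unparsable")
  expect_length(tab2, 1L)

  rules <- transformation_rule_set()
  tf3 <- tempfile(fileext = ".csv")
  write_rules(rules, tf3)
  back <- read_rules(tf3)
  expect_length(back, 19L)
  expect_identical(vapply(back, `[[`, "", "smarts"),
                   vapply(rules, `[[`, "", "smarts"))

  tf4 <- tempfile(fileext = ".csv")
  writeLines("rule_id,smarts", tf4)
  expect_warning(empty <- read_rules(tf4), "no rules")
  expect_length(empty, 0L)

  tf5 <- tempfile(fileext = ".csv")
  writeLines(c("rule_id,smarts", "x,[C:1>>[C:1]"), tf5)
  expect_error(read_rules(tf5), "line 2")

  tf6 <- tempfile(fileext = ".csv")
  writeLines(c("rule_id,notsmarts", "x,y"), tf6)
  expect_error(read_rules(tf6), "smarts")
})
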