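test_that("expand_once follows source/sink bookkeeping", {
  state <- enumeration_state(parse_molecule("CCC", "explicit"))
  state <- expand_once(state, list(single_bond_rule()))
  expect_equal(state$iteration, 1L)
  # propane's only connected rearrangement product is propane itself
  expect_length(state$source, 0L)

  st2 <- enumeration_state(parse_molecule("CCCC", "explicit"))
  st2 <- expand_once(st2, list(single_bond_rule()))
  expect_length(st2$source, 1L)            # isobutane is new
  expect_equal(st2$records[[1]]$iteration, 1L)
  # sink holds seed + product; re-expansion finds nothing new
  st3 <- expand_once(st2, list(single_bond_rule()))
  expect_length(st3$source, 0L)
  expect_error(expand_once(st3, list(single_bond_rule())), "source set is empty")
  expect_error(expand_once(st2, list()), "at least one")
})

test_that("augmentation of propane yields butane and 2-methylpropane", {
  aug1 <- augmentation_rules(1L)[[1]]
  tuples <- apply_rule(aug1, parse_molecule("CCC"), connected_only = TRUE)
  expect_length(tuples, 2L)
  expect_setequal(vapply(tuples, function(tp) as_smiles(tp[[1]]), ""),
                  c("CCCC", "CC(C)C"))
})

test_that("alkane isomer enumeration reproduces published counts", {
  for (n in c(1, 4, 5, 6, 8)) {
    res <- alkane_run(n)
    ref <- alkane_reference[alkane_reference$n == n, ]
    expect_equal(res$n_structures, ref$isomers, label = paste("N =", n))
    expect_equal(res$iterations, ref$iterations, label = paste("iters N =", n))
    # every structure is a connected alkane of the right size
    want_formula <- paste0("C", if (n > 1) n else "", "H", 2 * n + 2)
    expect_true(all(vapply(res$molecules, mol_formula, "") == want_formula))
  }
  # methane: no bond can be rearranged into anything new
  m1 <- alkane_run(1)
  expect_equal(m1$last_new_iteration, 0L)
})

test_that("the enumerated alkane sets equal an independent free-tree oracle", {
  skip_if_not_installed("igraph")
  for (n in 4:7) {
    got <- sort(vapply(alkane_run(n)$molecules, skeleton_ahu, ""))
    want <- oracle_alkane_skeletons(n)
    expect_identical(got, want, label = paste("N =", n))
  }
})

test_that("canonical augmentation counts accumulate across sizes", {
  res <- augmentation_run(10)
  expect_equal(res$n_structures, 150L)
  expect_equal(res$per_size$count,
               alkane_reference$isomers[1:10])
  expect_equal(canonical_augmentation(1)$n_structures, 1L)
})

test_that("cumulative augmentation equals the sum of per-size isomer counts", {
  res <- augmentation_run(10)
  per_n <- vapply(1:10, function(n) alkane_run(n)$n_structures, 0L)
  for (n in 1:10)
    expect_equal(sum(res$per_size$count[res$per_size$n_heavy <= n]),
                 sum(per_n[1:n]), label = paste("N =", n))
  # and the sets themselves agree, not just the counts
  aug_keys <- sort(vapply(res$molecules, canonical_key, ""))
  iso_keys <- sort(unlist(lapply(1:10, function(n)
    vapply(alkane_run(n)$molecules, canonical_key, ""))))
  expect_identical(aug_keys, iso_keys)
})

test_that("queue-chunked enumeration equals breadth-first enumeration", {
  bfs_keys <- sort(vapply(alkane_run(6)$molecules, canonical_key, ""))
  for (cs in c(1L, 5L, 20L)) {
    q <- enumerate_queue("CCCCCC", list(single_bond_rule()), chunk_size = cs)
    expect_identical(sort(vapply(q$molecules, canonical_key, "")), bfs_keys,
                     label = paste("chunk", cs))
  }
  expect_error(enumerate_queue("CC", list(single_bond_rule()), chunk_size = 0),
               "chunk_size")
})

test_that("the final set is invariant to rule and source ordering", {
  rules <- transformation_rule_set()
  seed <- "CC=CC"
  a <- enumerate_isomers(seed, rules)
  b <- enumerate_isomers(seed, rev(rules))
  expect_identical(sort(vapply(a$molecules, canonical_key, "")),
                   sort(vapply(b$molecules, canonical_key, "")))
  expect_equal(a$last_new_iteration, b$last_new_iteration)
})

test_that("full rule set enumerates the C4H8 isomer space from 1-butene", {
  res <- enumerate_isomers("C=CCC", transformation_rule_set())
  smis <- sort(vapply(res$molecules, as_smiles, ""))
  # 1-butene, 2-butene, isobutylene, cyclobutane, methylcyclopropane
  expect_equal(res$n_structures, 5L)
  expect_true(all(vapply(res$molecules, mol_formula, "") == "C4H8"))
  # the bound on iterations holds with N = total atom count
  N <- 12L
  expect_lte(res$last_new_iteration, iteration_upper_bound(N, "general"))
})

test_that("configuration errors are caught", {
  expect_error(enumerate_isomers("CC", list(single_bond_rule()), max_iter = 0),
               "max_iter")
  expect_error(canonical_augmentation(0), "max_atoms")
  expect_error(enumerate_isomers("CC.O", list(single_bond_rule())),
               "structural filters")
})
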