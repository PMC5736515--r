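test_that("the reduction chain gives 81, 36, 27, 19 configurations", {
  c81 <- enumerate_feasible_configs()
  expect_equal(nrow(c81), 81L)
  expect_true(all(c81$a12 %in% 1:3 & c81$a34 %in% 1:3 &
                    c81$a14 %in% 0:2 & c81$a23 %in% 0:2))
  # R1's configuration is present, a12 = 0 configurations are not
  expect_true(any(c81$a12 == 1 & c81$a34 == 1 & c81$a14 == 0 & c81$a23 == 0))
  expect_false(any(c81$a12 == 0))

  c36 <- reduce_by_symmetry(c81)
  expect_equal(nrow(c36), 36L)
  expect_false(any(c36$a12 < c36$a34))
  # inclusion-exclusion bookkeeping: 81 - 27 - 27 + 9
  n_c1 <- sum(c81$a14 < c81$a23)
  n_c2 <- sum(c81$a12 < c81$a34)
  n_both <- sum(c81$a14 < c81$a23 & c81$a12 < c81$a34)
  expect_equal(c(n_c1, n_c2, n_both), c(27L, 27L, 9L))
  expect_equal(81L - n_c1 - n_c2 + n_both, 36L)

  c27 <- reduce_by_valence(c36)
  expect_equal(nrow(c27), 27L)
  expect_false(any(c27$a12 == 3 & c27$a14 == 2))
  expect_true(any(c27$a12 == 3 & c27$a14 == 1))  # valence 4: still allowed

  c19 <- reduce_by_ring_constraint(c27)
  expect_equal(nrow(c19), 19L)
  expect_false(any(c19$a12 == 2 & c19$a14 == 2 & c19$a23 == 1 & c19$a34 == 1))
  expect_true(any(c19$a12 == 1 & c19$a34 == 1 & c19$a14 == 0 & c19$a23 == 0))
})

test_that("the 19 rules are pairwise distinct under label permutation", {
  rules <- transformation_rule_set()
  expect_length(rules, 19L)
  for (a in seq_along(rules)) {
    expect_true(rules_are_identical(rules[[a]], rules[[a]]))
    for (b in seq_along(rules)) {
      if (b <= a) next
      expect_false(rules_are_identical(rules[[a]], rules[[b]]),
                   label = paste(rules[[a]]$rule_id, rules[[b]]$rule_id))
    }
  }
})

test_that("relabelled rules are recognised as identical", {
  # the same transformation written with labels permuted by (2, 1, 4, 3)
  ra <- reaction_rule("([*:1]-[*:2].[*:3]-[*:4])>>([*:1]-[*:4].[*:2]-[*:3])")
  rb <- reaction_rule("([*:2]-[*:1].[*:4]-[*:3])>>([*:2]-[*:3].[*:1]-[*:4])")
  expect_true(rules_are_identical(ra, rb))
})

test_that("the rule set is closed under reversal with 3 self-inverse rules", {
  rules <- transformation_rule_set()
  revmatch <- vapply(rules, function(r) {
    rr <- reverse_rule(r)
    hits <- which(vapply(rules, rules_are_identical, NA, rule_a = rr))
    expect_length(hits, 1L)
    hits
  }, 0L)
  # closure: every reverse is again in the set; involution holds
  expect_setequal(revmatch, seq_along(rules))
  expect_identical(revmatch[revmatch], seq_along(rules))
  # exactly 3 rules are their own reverse, the other 16 form 8 pairs
  expect_equal(sum(revmatch == seq_along(rules)), 3L)
  expect_equal(sum(revmatch != seq_along(rules)), 16L)
  # the self-inverse rules are exactly the bond-order-conserving (green) ones
  cfg <- attr(rules, "configs")
  expect_identical(unname(revmatch == seq_along(rules)),
                   cfg$order_conserving)
  expect_equal(sum(cfg$order_conserving), 3L)
  # the all-single-bond rule is self-inverse
  r1_idx <- which(cfg$a12 == 1 & cfg$a23 == 0 & cfg$a34 == 1 & cfg$a14 == 0)
  expect_equal(revmatch[r1_idx], r1_idx)
})

test_that("excluding triple bonds yields a strict subset of the 19", {
  nt <- derive_transformation_rules(include_triple_bonds = FALSE)
  full <- transformation_rule_set()
  expect_lt(length(nt), length(full))
  for (r in nt) {
    hits <- sum(vapply(full, rules_are_identical, NA, rule_a = r))
    expect_equal(hits, 1L)
  }
  cfg <- attr(nt, "configs")
  expect_false(any(cfg == 3L))
})

test_that("every emitted rule conserves per-atom valence on application", {
  rules <- transformation_rule_set()
  seeds <- lapply(c("CC=CC", "C#CC", "C1=CC1C"), parse_molecule,
                  hydrogen_mode = "explicit")
  for (seed in seeds) {
    v0 <- sort(rowSums(rxnet:::.bond_dense(seed)))
    for (r in rules) {
      for (tp in apply_rule(r, seed, connected_only = TRUE)) {
        v1 <- sort(rowSums(rxnet:::.bond_dense(tp[[1]])))
        expect_identical(v1, v0, label = r$rule_id)
      }
    }
  }
})

test_that("iteration bounds take their documented closed forms", {
  expect_equal(iteration_upper_bound(2, "general"), 1)
  expect_equal(iteration_upper_bound(4, "general"), 9)
  expect_equal(iteration_upper_bound(10, "alkane"), 9)
  expect_error(iteration_upper_bound(0), ">= 1")
  # observed alkane iterations never exceed N - 1
  for (n in 2:8)
    expect_lte(alkane_run(n)$iterations, iteration_upper_bound(n, "alkane"))
})

test_that("labelled bond-order distance matches hand summation", {
  # heavy-atom skeletons of butane vs isobutane under a fixed indexing:
  # one relocated bond contributes |1-0| + |0-1| = 2
  a <- rxnet:::new_rx_mol(rep(6L, 4), integer(4),
                          rbind(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 1L)))
  b <- rxnet:::new_rx_mol(rep(6L, 4), integer(4),
                          rbind(c(1L, 2L, 1L), c(2L, 3L, 1L), c(2L, 4L, 1L)))
  expect_equal(bond_order_distance(a, b), 2L)
  expect_equal(bond_order_distance(a, a), 0L)
  expect_error(bond_order_distance(a, parse_molecule("CCO")), "atom indexing")
  # hydrogen-saturated versions: the H must move too, S = 4, one step
  ae <- saturate_explicit(rxnet:::.bond_dense(a))
  # saturate_explicit appends hydrogens per carbon in index order, so a
  # shared indexing needs matching H counts; relocate bond and hydrogen
  be_bonds <- rbind(c(1L, 2L, 1L), c(2L, 3L, 1L), c(2L, 4L, 1L),
                    c(1L, 5L, 1L), c(1L, 6L, 1L), c(1L, 7L, 1L),
                    c(3L, 8L, 1L), c(2L, 9L, 1L),
                    c(3L, 10L, 1L), c(3L, 11L, 1L),
                    c(4L, 12L, 1L), c(4L, 13L, 1L), c(4L, 14L, 1L))
  be <- rxnet:::new_rx_mol(c(rep(6L, 4), rep(1L, 10)), integer(14), be_bonds)
  expect_equal(bond_order_distance(ae, be), 4L)
  path <- rearrangement_path(ae, be)
  expect_equal(path$steps, 1L)
  expect_equal(path$deltas, 4L)
})

test_that("greedy rearrangement converges in at most S/2 steps on exhaustive small isomer pairs", {
  skip_if_not_installed("igraph")
  for (n in 3:4) {
    graphs <- oracle_carbon_graphs(n)
    orders <- vapply(graphs, sum, 0)  # same total order <=> same formula
    for (i in seq_along(graphs)) for (j in seq_along(graphs)) {
      if (i == j || orders[i] != orders[j]) next
      ma <- saturate_explicit(graphs[[i]])
      mb <- saturate_explicit(graphs[[j]])
      S <- bond_order_distance(ma, mb)
      expect_gt(S, 0L)
      path <- rearrangement_path(ma, mb)
      expect_lte(path$steps, S %/% 2L)
      expect_true(all(path$deltas %in% c(2L, 4L)))
    }
  }
})
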