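fx <- generate_fixtures(1)

test_that("reaction centers are located from the atom mapping", {
  rxn <- parse_mapped_reaction(fx$mapped_reactions$transaminase)
  ctr <- find_reaction_center(rxn)
  # carbonyl/amine exchange: 4 center atoms, two bonds down, two bonds up
  expect_setequal(ctr$center_atoms, c(2L, 3L, 5L, 6L))
  expect_equal(sum(ctr$changed_bonds$delta < 0), 2L)
  expect_equal(sum(ctr$changed_bonds$delta > 0), 2L)

  dsf <- find_reaction_center(
    parse_mapped_reaction(fx$mapped_reactions$disulfide_interchange))
  expect_identical(sort(dsf$changed_bonds$delta), c(-1L, -1L, 1L, 1L))

  # a single formed bond is a center of its own
  bf <- find_reaction_center(
    parse_mapped_reaction(fx$mapped_reactions$bond_formation))
  expect_equal(nrow(bf$changed_bonds), 1L)
  expect_equal(bf$changed_bonds$delta, 1L)

  expect_error(find_reaction_center(
    parse_mapped_reaction(fx$mapped_reactions$identity)), "degenerate")
  expect_error(parse_mapped_reaction("[CH4:1]>>[CH4:2]"),
               "missing from the substrate")
})

test_that("multi-substrate reactions decompose into one component per substrate", {
  rxn <- parse_mapped_reaction(fx$mapped_reactions$transaminase)
  comps <- decompose_components(rxn)
  expect_length(comps, 2L)
  expect_length(comps[[1]]$co_substrates, 1L)
  # each component's products share mapped atoms with its substrate
  for (comp in comps) {
    smaps <- comp$substrate$map
    for (p in comp$products)
      expect_gt(length(intersect(p$map[p$map > 0], smaps[smaps > 0])), 0L)
  }
  # one-substrate reaction: a single component spanning the whole reaction
  one <- parse_mapped_reaction(
    "[CH2:1]=[CH:2][CH2:3][CH3:4]>>[CH3:1][CH:2]=[CH:3][CH3:4]")
  expect_length(decompose_components(one), 1L)
  # unmapped spectator water is excluded from the components
  spect <- decompose_components(
    parse_mapped_reaction(fx$mapped_reactions$spectator_water))
  expect_length(spect, 2L)
})

test_that("diameter truncation keeps nested atom spheres", {
  rxn <- parse_mapped_reaction(fx$mapped_reactions$transaminase)
  comp <- decompose_components(rxn)[[1]]
  sizes <- vapply(c(2, 6, Inf), function(d) extract_rule(comp, d)$p, 0)
  expect_true(all(diff(sizes) >= 0))
  # maps kept at a small diameter are kept at every larger diameter
  maps2 <- extract_rule(comp, 2)$pmap
  maps6 <- extract_rule(comp, 6)$pmap
  mapsI <- extract_rule(comp, Inf)$pmap
  expect_true(all(maps2 %in% maps6))
  expect_true(all(maps6 %in% mapsI))
  # the infinite-diameter rule contains every atom of the component
  expect_equal(extract_rule(comp, Inf)$p,
               length(comp$substrate$z) +
                 sum(lengths(lapply(comp$co_substrates, `[[`, "z"))))
  expect_error(extract_rule(comp, 3), "even")
  expect_error(extract_rule(comp, 0), "even")
})

test_that("a 2-substrate reaction at 8 diameters yields 16 rules", {
  rxn <- parse_mapped_reaction(fx$mapped_reactions$transaminase)
  rules <- extract_rules(rxn)
  expect_length(rules, 16L)
  expect_setequal(unique(vapply(rules, `[[`, 0, "diameter")), seq(2, 16, 2))
})

test_that("every extracted rule regenerates its native products (self-application)", {
  for (nm in c("transaminase", "disulfide_interchange")) {
    rxn <- parse_mapped_reaction(fx$mapped_reactions[[nm]])
    for (comp in decompose_components(rxn)) {
      cm <- component_molecules(comp)
      want <- sort(vapply(cm$products, canonical_key, ""))
      for (d in c(seq(2, 16, 2), Inf)) {
        rule <- extract_rule(comp, d)
        tuples <- apply_rule(rule, cm$reactants, max_valence = 0,
                             ring_constraint = FALSE)
        hit <- any(vapply(tuples, function(tp) {
          keys <- sort(vapply(tp, canonical_key, ""))
          all(want %in% keys)
        }, NA))
        expect_true(hit, label = paste(nm, "substrate",
                                       comp$substrate_index, "d", d))
      }
    }
  }
})

test_that("substrate acceptance is monotone non-increasing in diameter", {
  rxn <- parse_mapped_reaction(fx$mapped_reactions$transaminase)
  comp <- decompose_components(rxn)[[1]]  # promiscuity on the ketone side
  # ketone panel: the native substrate plus increasingly different ketones
  panel <- lapply(c("CC(=O)CC", "CC(=O)C", "CCC(=O)CC", "O=C1CCCC1",
                    "CC(=O)CO", "CCO", "CCN"), parse_molecule)
  co <- component_molecules(comp)$reactants[[2]]  # fixed amine donor
  accepted <- lapply(c(2, 6, 10, Inf), function(d) {
    rule <- extract_rule(comp, d)
    which(vapply(panel, function(m)
      length(apply_rule(rule, list(m, co), max_valence = 0,
                        ring_constraint = FALSE)) > 0L, NA))
  })
  for (k in seq_along(accepted)[-1])
    expect_true(all(accepted[[k]] %in% accepted[[k - 1]]),
                label = paste("step", k))
  # the loosest rule accepts more of the panel than the strictest
  expect_gte(length(accepted[[1]]), length(accepted[[length(accepted)]]))
  # the native substrate is always accepted
  expect_true(all(vapply(accepted, function(a) 1L %in% a, NA)))
})
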