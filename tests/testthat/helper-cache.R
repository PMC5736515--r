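# Shared memoised computations: several test files look at the same alkane
# enumerations and rule sets, so they are computed once per test run.

.rx_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .rx_test_cache, inherits = FALSE))
    assign(name, force(expr), envir = .rx_test_cache)
  get(name, envir = .rx_test_cache, inherits = FALSE)
}

transformation_rule_set <- function() {
  cached("rules19", derive_transformation_rules())
}

single_bond_rule <- function() {
  cached("r1", {
    rules <- transformation_rule_set()
    cfg <- attr(rules, "configs")
    rules[[which(cfg$a12 == 1 & cfg$a23 == 0 & cfg$a34 == 1 & cfg$a14 == 0)]]
  })
}

alkane_run <- function(n) {
  cached(paste0("alkane", n),
         enumerate_isomers(strrep("C", n), list(single_bond_rule())))
}

augmentation_run <- function(n) {
  cached(paste0("aug", n), canonical_augmentation(n))
}

# Table of published alkane counts (OEIS A000602) and enumeration iteration
# counts used across tests
alkane_reference <- data.frame(
  n = 1:14,
  cumulative = c(1, 2, 3, 5, 8, 13, 22, 40, 75, 150, 309, 664, 1466, 3324),
  isomers = c(1, 1, 1, 2, 3, 5, 9, 18, 35, 75, 159, 355, 802, 1858),
  iterations = c(1, 1, 1, 2, 3, 3, 4, 5, 5, 6, 7, 7, 8, 9))
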