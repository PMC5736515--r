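# Element data shared across the package. Monoisotopic masses are the atomic
# masses of each element's most abundant isotope (AME2020 values, rounded to
# 1e-6 Da), which is what exact-mass peak matching in metabolomics uses.

.element_symbols <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Na = 11L, Mg = 12L,
  Si = 14L, P = 15L, S = 16L, Cl = 17L, K = 19L, Ca = 20L, Fe = 26L,
  Cu = 29L, Zn = 30L, Se = 34L, Br = 35L, I = 53L
)

.monoisotopic_masses <- c(
  H = 1.007825, B = 11.009305, C = 12.000000, N = 14.003074, O = 15.994915,
  F = 18.998403, Na = 22.989769, Mg = 23.985042, Si = 27.976927,
  P = 30.973762, S = 31.972071, Cl = 34.968853, K = 38.963707,
  Ca = 39.962591, Fe = 55.934936, Cu = 62.929598, Zn = 63.929142,
  Se = 79.916522, Br = 78.918338, I = 126.904473
)

element_number <- function(symbol) {
  z <- .element_symbols[symbol]
  if (any(is.na(z))) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "))
  }
  unname(z)
}

element_symbol <- function(z) {
  sym <- names(.element_symbols)[match(z, .element_symbols)]
  if (any(is.na(sym))) {
    stop("no symbol known for atomic number(s): ",
         paste(unique(z[is.na(sym)]), collapse = ", "))
  }
  sym
}
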