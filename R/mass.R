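#' Exact mass computation and peak annotation
#'
#' Generated candidate metabolites are matched against measured MS peak
#' lists: for every (molecule, adduct) pair the theoretical m/z is
#' `(monoisotopic mass + mass shift) / |charge|`, and a peak is annotated
#' when the relative deviation is within the ppm tolerance. Per-peak
#' compound counts and the fraction of covered peaks summarize how well a
#' candidate set explains a spectrum.
#'
#' @name mass_annotation
NULL

#' Monoisotopic molecular mass
#'
#' Sum of most-abundant-isotope atomic masses over all atoms, including
#' implicit and explicit hydrogens.
#'
#' @param mol an [rx_mol], or a SMILES/InChI string.
#' @return mass in Da.
#' @examples
#' monoisotopic_mass(parse_molecule("O"))   # water, 18.0106
#' @export
monoisotopic_mass <- function(mol) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  stopifnot(inherits(mol, "rx_mol"))
  sym <- element_symbol(mol$z)  # errors on elements without isotope data
  nh <- sum(rxr_implicit_h(mol$z, mol$charge, mol$bond))
  sum(.monoisotopic_masses[sym]) + nh * .monoisotopic_masses[["H"]]
}

#' Default adduct tables
#'
#' Common singly-charged electrospray adducts; mass shifts include the
#' electron. These defaults are package choices -- supply your own table for
#' other instruments.
#'
#' @param mode `"negative"` (default), `"positive"` or `"both"`.
#' @return data frame with columns `name`, `mass_shift` (Da), `charge` and
#'   `mode`.
#' @export
default_adducts <- function(mode = c("negative", "positive", "both")) {
  mode <- match.arg(mode)
  tab <- data.frame(
    name = c("[M-H]-", "[M+Cl]-", "[M+H]+", "[M+Na]+"),
    mass_shift = c(-1.007276, 34.969402, 1.007276, 22.989218),
    charge = c(-1L, -1L, 1L, 1L),
    mode = c("negative", "negative", "positive", "positive"),
    stringsAsFactors = FALSE)
  if (mode == "both") tab else tab[tab$mode == mode, ]
}

#' Annotate an MS peak list with candidate structures
#'
#' @param mols list of [rx_mol] candidate structures (deduplicated at the
#'   connectivity level before matching).
#' @param peaks data frame with columns `mz` (> 0) and optionally
#'   `intensity`.
#' @param adducts adduct table as returned by [default_adducts()];
#'   must be non-empty.
#' @param tol_ppm matching tolerance in ppm (> 0, default 5).
#' @return an `rx_annotation` object: `assignments` (one row per matched
#'   (peak, molecule, adduct) with `ppm_error`), `per_peak` (compound count
#'   per peak), `coverage` (fraction of peaks with >= 1 assignment), and
#'   `median_per_peak` / `mean_per_peak` (distinct compounds per annotated
#'   peak).
#' @export
annotate_peaks <- function(mols, peaks, adducts = default_adducts("negative"),
                           tol_ppm = 5) {
  if (is.null(adducts) || nrow(adducts) == 0L)
    stop("the adduct table must contain at least one adduct")
  if (tol_ppm <= 0) stop("'tol_ppm' must be > 0")
  if (!all(c("mz") %in% names(peaks))) stop("'peaks' needs an 'mz' column")
  if (any(peaks$mz <= 0)) stop("peak m/z values must be positive")
  if (any(adducts$charge == 0L)) stop("adduct charge must be non-zero")

  mols <- dedup_molecules(mols)
  keys <- vapply(mols, canonical_key, "")
  masses <- vapply(mols, monoisotopic_mass, 0)

  rows <- list()
  for (a in seq_len(nrow(adducts))) {
    theo <- (masses + adducts$mass_shift[a]) / abs(adducts$charge[a])
    for (p in seq_len(nrow(peaks))) {
      ppm <- (peaks$mz[p] - theo) / theo * 1e6
      hit <- which(abs(ppm) <= tol_ppm)
      for (h in hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          peak = p, mz = peaks$mz[p], molecule = h, key = keys[h],
          adduct = adducts$name[a], theoretical_mz = theo[h],
          ppm_error = ppm[h], stringsAsFactors = FALSE)
      }
    }
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak = integer(0), mz = numeric(0), molecule = integer(0),
               key = character(0), adduct = character(0),
               theoretical_mz = numeric(0), ppm_error = numeric(0))

  n_per_peak <- vapply(seq_len(nrow(peaks)), function(p)
    length(unique(assignments$key[assignments$peak == p])), 0L)
  per_peak <- data.frame(peak = seq_len(nrow(peaks)), mz = peaks$mz,
                         n_compounds = n_per_peak)
  annotated <- n_per_peak[n_per_peak > 0L]
  structure(list(
    assignments = assignments,
    per_peak = per_peak,
    coverage = if (nrow(peaks)) mean(n_per_peak > 0L) else 0,
    median_per_peak = if (length(annotated)) median(annotated) else 0,
    mean_per_peak = if (length(annotated)) mean(annotated) else 0,
    tol_ppm = tol_ppm), class = "rx_annotation")
}

#' @export
print.rx_annotation <- function(x, ...) {
  cat("<rx_annotation> peaks:", nrow(x$per_peak),
      "| assignments:", nrow(x$assignments),
      sprintf("| coverage: %.1f%%", 100 * x$coverage),
      "| median/mean per annotated peak:",
      x$median_per_peak, "/", round(x$mean_per_peak, 2), "\n")
  invisible(x)
}
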