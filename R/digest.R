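## In-silico tryptic digestion and monoisotopic peptide masses.

#' Monoisotopic residue masses (Da)
#'
#' Standard monoisotopic masses of the 20 amino-acid residues (the mass a
#' residue contributes inside a peptide chain, i.e. without water).
#'
#' @format named numeric vector, one element per one-letter code.
#' @export
RESIDUE_MASS <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,
  V = 99.06841,  T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER  <- 18.010565
MASS_PROTON <- 1.007276
# fixed Cys modification: carbamidomethyl (iodoacetamide product).
# Carboxymethyl (+58.00548) is selectable through `cys_mod`.
MOD_CARBAMIDOMETHYL <- 57.02146
MOD_CARBOXYMETHYL   <- 58.00548
MOD_MET_OXIDATION   <- 15.9949

.check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% names(RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue '", res[bad[1]], "' at position ", bad[1])
  res
}

#' Search configuration for peptide-mass-fingerprint identification
#'
#' Defaults are the standard PMF search settings for a MALDI-TOF workflow:
#' 50 ppm mass tolerance, one missed tryptic cleavage, a fixed
#' carbamidomethyl modification on Cys and variable oxidation on Met,
#' singly-protonated monoisotopic masses in the 800-3000 m/z window.
#'
#' @param tolerance_ppm peptide mass tolerance in ppm.
#' @param missed_cleavages maximum internal missed cleavage sites.
#' @param cys_mod fixed Cys modification mass in Da
#'   (`MOD_CARBAMIDOMETHYL` or `MOD_CARBOXYMETHYL`).
#' @param met_ox_mod variable Met oxidation mass in Da.
#' @param mz_range observed m/z acquisition window.
#' @param r_top a candidate "ranks high" in a scorer when its rank is at
#'   most `r_top`; consensus requires this in at least two of the three
#'   scorers.
#' @return a list of class `pmf_config`.
#' @export
pmf_config <- function(tolerance_ppm = 50, missed_cleavages = 1,
                       cys_mod = MOD_CARBAMIDOMETHYL,
                       met_ox_mod = MOD_MET_OXIDATION,
                       mz_range = c(800, 3000), r_top = 5) {
  stopifnot(tolerance_ppm > 0, missed_cleavages >= 0, r_top >= 1)
  structure(list(tolerance_ppm = tolerance_ppm,
                 missed_cleavages = missed_cleavages,
                 cys_mod = cys_mod, met_ox_mod = met_ox_mod,
                 mz_range = mz_range, r_top = r_top),
            class = "pmf_config")
}

# tryptic fragments with positions; cleave C-terminal to K/R unless the next
# residue is P (Keil rule)
tryptic_fragments <- function(sequence, missed_cleavages = 1) {
  res <- .check_sequence(sequence)
  n <- length(res)
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n & res[pmin(cut + 1L, n)] != "P"]
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  out <- list()
  for (mc in 0:missed_cleavages) {
    k <- length(starts) - mc
    if (k < 1L) break
    for (i in seq_len(k)) {
      s <- starts[i]; e <- ends[i + mc]
      out[[length(out) + 1L]] <- list(
        peptide = paste(res[s:e], collapse = ""),
        start = s, end = e, missed = mc)
    }
  }
  data.frame(
    peptide = vapply(out, `[[`, "", "peptide"),
    start = vapply(out, `[[`, 0L, "start"),
    end = vapply(out, `[[`, 0L, "end"),
    missed = vapply(out, `[[`, 0L, "missed"),
    stringsAsFactors = FALSE)
}

#' Tryptic digestion of a protein sequence
#'
#' Cleaves C-terminal to Lys or Arg except when the following residue is Pro
#' (the Keil rule) and emits every product with up to `missed_cleavages`
#' internal missed sites, in N-to-C order for each missed-cleavage level.
#'
#' @param sequence amino-acid string over the 20 standard one-letter codes.
#' @param missed_cleavages maximum number of internal missed cleavage sites.
#' @return character vector of peptides (duplicates retained).
#' @examples
#' digest("AKRG", 1)  # "AK" "R" "G" "AKR" "RG"
#' @export
digest <- function(sequence, missed_cleavages = 1) {
  tryptic_fragments(sequence, missed_cleavages)$peptide
}

#' Monoisotopic [M+H]+ m/z of a peptide
#'
#' Sums residue monoisotopic masses plus water and one proton, adds the
#' fixed Cys modification for every cysteine, and expands the variable Met
#' oxidation: with `n_oxidized_met = NULL` one mass is returned per
#' oxidation count from 0 to the number of methionines.
#'
#' @param peptide amino-acid string.
#' @param config a [pmf_config()] (supplies modification masses).
#' @param n_oxidized_met number of oxidized methionines, or `NULL` for the
#'   full variable-modification expansion.
#' @return numeric vector of [M+H]+ m/z values.
#' @examples
#' peptide_mz("G", n_oxidized_met = 0)  # 76.0393
#' @export
peptide_mz <- function(peptide, config = pmf_config(), n_oxidized_met = NULL) {
  res <- .check_sequence(peptide)
  n_met <- sum(res == "M")
  base <- sum(RESIDUE_MASS[res]) + MASS_WATER + MASS_PROTON +
    sum(res == "C") * config$cys_mod
  if (is.null(n_oxidized_met)) {
    return(base + (0:n_met) * config$met_ox_mod)
  }
  stopifnot(n_oxidized_met >= 0)
  if (n_oxidized_met > n_met)
    stop("n_oxidized_met (", n_oxidized_met, ") exceeds number of Met (",
         n_met, ")")
  base + n_oxidized_met * config$met_ox_mod
}

#' Monoisotopic mass of an intact protein (Da)
#'
#' @param sequence amino-acid string.
#' @return neutral monoisotopic mass in Da (no modifications).
#' @export
protein_mass <- function(sequence) {
  res <- .check_sequence(sequence)
  sum(RESIDUE_MASS[res]) + MASS_WATER
}
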