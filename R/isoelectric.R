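## Theoretical isoelectric point by bisection on the net-charge curve.

#' Bjellqvist pKa values used for theoretical pI
#'
#' Dissociation constants for the ionizable groups: the two termini plus
#' Asp, Glu, Cys, Tyr (acidic) and His, Lys, Arg (basic).
#'
#' @format named numeric vector with elements `Nterm`, `Cterm`, `D`, `E`,
#'   `C`, `Y`, `H`, `K`, `R`.
#' @export
PKA_BJELLQVIST <- c(
  Nterm = 7.50, Cterm = 3.55,
  D = 4.05, E = 4.45, C = 9.00, Y = 10.00,
  H = 5.98, K = 10.00, R = 12.00
)

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus and His/Lys/Arg (positive
#' groups) and the C-terminus and Asp/Glu/Cys/Tyr (negative groups).
#' Strictly decreasing in pH, so the isoelectric point is a unique root.
#'
#' @param sequence amino-acid string.
#' @param ph pH value(s).
#' @param pka named pKa vector, see [PKA_BJELLQVIST].
#' @return net charge (same length as `ph`).
#' @export
net_charge <- function(sequence, ph, pka = PKA_BJELLQVIST) {
  res <- .check_sequence(sequence)
  counts <- table(res)
  cnt <- function(a) if (a %in% names(counts)) as.numeric(counts[[a]]) else 0
  pos <- rbind(Nterm = 1, H = cnt("H"), K = cnt("K"), R = cnt("R"))
  neg <- rbind(Cterm = 1, D = cnt("D"), E = cnt("E"),
               C = cnt("C"), Y = cnt("Y"))
  vapply(ph, function(p) {
    plus <- sum(pos[, 1] / (1 + 10 ^ (p - pka[rownames(pos)])),
                na.rm = TRUE)
    minus <- sum(neg[, 1] / (1 + 10 ^ (pka[rownames(neg)] - p)),
                 na.rm = TRUE)
    plus - minus
  }, 0)
}

#' Theoretical isoelectric point
#'
#' Solves `net_charge(sequence, pH) = 0` by bisection on pH in [0, 14].
#'
#' @inheritParams net_charge
#' @param tol bisection tolerance in pH units.
#' @return the pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka = PKA_BJELLQVIST, tol = 1e-4) {
  lo <- 0; hi <- 14
  # net charge is monotone decreasing: positive at pH 0, negative at pH 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
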