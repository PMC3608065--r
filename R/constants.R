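# Physical constants and mass tables used throughout the package.
# Monoisotopic masses in Da; isotope abundances are IUPAC representative values.

#: mass of a proton (charge carrier in positive mode), Da
PROTON_MASS <- 1.0072765

#: monoisotopic mass of water (terminal H + OH of a peptide chain), Da
WATER_MASS <- 18.010565

#: monoisotopic mass added by carbamidomethylation of cysteine, Da
CARBAMIDOMETHYL_MASS <- 57.021464

# Monoisotopic masses of the lightest isotope of each element.
ELEMENT_MONO_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# Relative isotope abundances per element, indexed by neutron-number offset
# from the lightest isotope (k = 0, 1, 2, ...).  Two-neutron gaps are stored
# as explicit zeros so that positions always equal nucleon shifts.
ELEMENT_ISOTOPES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0001)
)

# Averagine pseudo-residue: average elemental composition of an amino-acid
# residue (Senko et al. parameterization) and its average mass.
AVERAGINE_COMPOSITION <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
AVERAGINE_MASS <- 111.1254

# Monoisotopic residue masses of the 20 standard amino acids, Da.
RESIDUE_MASS <- c(
  G = 57.021464,  A = 71.037114,  S = 87.032028,  P = 97.052764,
  V = 99.068414,  T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Monoisotopic mass shift caused by deamidation
#'
#' Deamidation hydrolyses the side-chain carboxamide of asparagine or
#' glutamine (\eqn{-NH_2 \to -OH}), so the elemental change is
#' \eqn{-N, -H, +O}.  The resulting patterns overlap the unmodified peptide's
#' pattern shifted by about one isotope spacing, a classic source of
#' interleaved isotope envelopes.
#'
#' @param digits Number of decimal places to round to; `NULL` for the full
#'   double-precision value.
#' @return The mass increase in Da (about 0.98).
#' @examples
#' deamidation_shift()
#' @export
deamidation_shift <- function(digits = 2) {
  shift <- ELEMENT_MONO_MASS[["O"]] - ELEMENT_MONO_MASS[["N"]] - ELEMENT_MONO_MASS[["H"]]
  if (is.null(digits)) shift else round(shift, digits)
}
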