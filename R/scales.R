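## Canonical 20-letter amino-acid alphabet, alphabetical by one-letter code.
## Index encoding (A=1 ... Y=20) and all per-residue tables follow this order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Kyte-Doolittle hydropathy (GRAVY scale; also PAAC hydrophobicity property).
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

## Hopp-Woods hydrophilicity.
HOPP_WOODS <- c(
  A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
  G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
  M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
  S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)

## Side-chain mass (Da), the third classical PAAC property scale.
SIDE_CHAIN_MASS <- c(
  A =  15, C =  47, D =  59, E =  73, F =  91,
  G =   1, H =  82, I =  57, K =  73, L =  57,
  M =  75, N =  58, P =  42, Q =  72, R = 101,
  S =  31, T =  45, V =  43, W = 130, Y = 107)

## Average (not monoisotopic) residue masses in Daltons (Expasy convention);
## a free peptide adds one water.
RESIDUE_MASS_AVG <- c(
  A =  71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G =  57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P =  97.1167, Q = 128.1307, R = 156.1875,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760)

WATER_MASS_AVG <- 18.0153

## EMBOSS-style pKa values for ionizable groups.
PKA_EMBOSS <- c(
  Nterm = 8.6, Cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

#' Standardize a per-residue property scale
#'
#' Centers and scales a 20-value property table to mean 0 and population
#' standard deviation 1 across the 20 canonical residues, the convention of
#' the pseudo amino acid composition literature. Without this step the
#' side-chain mass scale (values up to 130) would dominate the squared
#' property differences of the sequence-order coupling term.
#'
#' @param scale named numeric vector of 20 per-residue values.
#' @return named numeric vector in alphabet order with mean 0 and population
#'   SD 1.
#' @examples
#' s <- normalize_scale(c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
#'                        G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
#'                        M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
#'                        S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3))
#' mean(s)  # ~0
#' @export
normalize_scale <- function(scale) {
  stopifnot(is.numeric(scale), length(scale) == 20L)
  if (is.null(names(scale)) || !setequal(names(scale), AA_ALPHABET))
    stop("property scale must be named by the 20 canonical residues")
  scale <- scale[AA_ALPHABET]
  mu <- mean(scale)
  sdev <- sqrt(mean((scale - mu)^2))
  if (sdev == 0) stop("degenerate property scale (all values equal)")
  (scale - mu) / sdev
}
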