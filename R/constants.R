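## Alphabet, background model and physico-chemical scales shared across modules.

## The 20 standard amino acids in alphabetical one-letter order. This order is
## the canonical feature order of the package: profile feature columns and
## window vectors index amino acids this way.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Hydrophobic amino-acid class used by the 'b' consensus symbol.
HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "Y", "C")

## Residues sampled when planting a 'b' consensus position (the aliphatic
## core plus phenylalanine, the dominant hydrophobics at these positions).
B_PLANT_SET <- c("L", "I", "V", "M", "F")

## BLOSUM62 marginal amino-acid frequencies (Henikoff & Henikoff background).
## Used as the background model everywhere: uncovered profile positions,
## window padding, pseudocounts, relative entropy and sequence simulation.
BLOSUM62_BG <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
  G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
  M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
  S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032
)
BLOSUM62_BG <- BLOSUM62_BG / sum(BLOSUM62_BG)

## Kyte-Doolittle hydropathy index.
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

## Formal side-chain charge at physiological pH (His partially protonated).
AA_CHARGE <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0,
  G = 0, H = 0.1, I = 0, K = 1, L = 0,
  M = 0, N = 0, P = 0, Q = 0, R = 1,
  S = 0, T = 0, V = 0, W = 0, Y = 0
)

## Zamyatnin residue volumes (cubic Angstrom).
AA_VOLUME <- c(
  A =  88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
  G =  60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
  M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
  S =  89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6
)

## Probability floor applied to emission probabilities before taking -ln,
## so profile features stay finite.
EMISSION_FLOOR <- 1e-9

## Ungapped Karlin-Altschul parameters. BLOSUM62 values are the standard
## ungapped ones; the PSSM (log-odds, natural log) stage uses lambda = 1.
KA_BLOSUM62 <- c(lambda = 0.3176, K = 0.134)
KA_PSSM <- c(lambda = 1.0, K = 0.13)

#' Background amino-acid frequencies
#'
#' The BLOSUM62 marginal frequencies used as the package-wide background
#' model (profile pseudocounts, window padding, relative entropy and the
#' synthetic-sequence generators).
#'
#' @return Named numeric vector over the 20 standard amino acids
#'   (alphabetical order), summing to 1.
#' @export
#' @examples
#' sum(backgroundFrequencies())
backgroundFrequencies <- function() BLOSUM62_BG

#' Physico-chemical scales for amino acids
#'
#' Accessors for the residue descriptor tables used by the LRR motif
#' embedding: Kyte-Doolittle hydropathy, formal side-chain charge
#' (K/R = +1, D/E = -1, H = +0.1) and Zamyatnin residue volume.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
aaHydropathy <- function() KYTE_DOOLITTLE

#' @rdname aaHydropathy
#' @export
aaCharge <- function() AA_CHARGE

#' @rdname aaHydropathy
#' @export
aaVolume <- function() AA_VOLUME
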