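#' Canonical residue ordering and alphabets
#'
#' All 20x20 tables in the package are indexed by the 20 standard amino acid
#' one-letter codes in the NCBI scoring-matrix order (A R N D C Q E G H I L K
#' M F P S T W Y V). Ambiguity letters (X, B, Z, U, O) are accepted in input
#' alignments but never contribute to pair counts or composition; the gap
#' character is `-`.
#'
#' @format `aminoAcids()` returns a character vector of length 20.
#' @return `aminoAcids()`: the 20 standard residues in canonical order.
#' @examples
#' aminoAcids()
#' @export
aminoAcids <- function() AA_ORDER

AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AMBIGUITY_LETTERS <- c("X", "B", "Z", "U", "O")
GAP_CHAR <- "-"
ALLOWED_CHARS <- c(AA_ORDER, AMBIGUITY_LETTERS, GAP_CHAR)

#' Average transmembrane residue composition of the rhodopsin (class A) GPCR
#' family
#'
#' Published average amino acid composition (in percent) of the transmembrane
#' segments of the class A GPCR family: leucine-rich (14.1 %), valine and
#' isoleucine next, cysteine elevated (3.6 %) and glycine depleted (4.6 %)
#' relative to globular data sets, with charged/polar residues
#' (R, K, H, D, E, N, Q) accumulating to 19.6 %. Used as the default target
#' composition of [generatorConfig()].
#'
#' @return Named numeric vector over the 20 residues summing to 100.
#' @examples
#' sum(gpcrTmComposition())
#' @export
gpcrTmComposition <- function() {
  c(A = 8.0, R = 4.5, N = 3.4, D = 2.1, C = 3.6, Q = 2.2, E = 1.9,
    G = 4.6, H = 2.1, I = 8.1, L = 14.1, K = 3.4, M = 3.1, F = 7.3,
    P = 3.8, S = 6.8, T = 5.6, W = 1.9, Y = 4.3, V = 9.2)[AA_ORDER]
}

#' Charged and polar residue group
#'
#' The seven charged/polar residues whose accumulated frequency distinguishes
#' GPCR transmembrane segments (19.6 %) from general transmembrane data sets
#' (~10 %) and globular proteins (~33 %).
#'
#' @return Character vector of the residues R, K, H, D, E, N, Q.
#' @export
chargedPolarResidues <- function() c("R", "K", "H", "D", "E", "N", "Q")

# round half away from zero ("nearest integer" rule, symmetric in sign)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)
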