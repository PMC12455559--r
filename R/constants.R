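# Shared alphabets, scoring matrices and residue property scales.

#' Amino-acid alphabet used throughout the package
#'
#' The canonical 20-letter alphabet.  'X' is accepted in input sequences and
#' is treated as a score-neutral ambiguity code (background emission in HMMs,
#' zero credit in identity counts).
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.aa_with_x <- c("ACDEFGHIKLMNPQRSTVWY", "X")

# cache for the BLOSUM62 matrix restricted to the 20 aa + X
.pet_env <- new.env(parent = emptyenv())

#' Substitution matrix (BLOSUM62, 20 amino acids + X)
#'
#' Returns the BLOSUM62 matrix shipped with Biostrings, restricted to the
#' 20-letter alphabet plus 'X'.
#' @return numeric matrix with dimnames over `c(AA_ALPHABET, "X")`
#' @export
blosum62 <- function() {
  if (is.null(.pet_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    keep <- c(AA_ALPHABET, "X")
    .pet_env$blosum62 <- m[keep, keep]
  }
  .pet_env$blosum62
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values; positive is hydrophobic.
#' @export
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Physicochemical residue classes
#'
#' Fixed taxonomy used by differential conservation analysis: for each class,
#' the set of one-letter residue codes belonging to it.
#' @export
RESIDUE_CLASSES <- list(
  hydrophobic     = c("A", "V", "L", "I", "M", "F", "W", "Y", "C"),
  aromatic        = c("F", "W", "Y", "H"),
  aliphatic       = c("A", "V", "L", "I"),
  polar           = c("S", "T", "N", "Q"),
  positive        = c("K", "R", "H"),
  negative        = c("D", "E"),
  charged         = c("K", "R", "H", "D", "E"),
  small           = c("A", "C", "G", "S", "T", "P", "N", "D", "V"),
  proline_glycine = c("P", "G")
)

# uniform background over the 20 standard residues
.uniform_background <- function() {
  setNames(rep(1 / 20, 20), AA_ALPHABET)
}
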