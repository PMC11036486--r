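# Canonical amino-acid alphabet and fixed lookup tables.
#
# Every matrix in the package (PSPMs, profiles, contact potentials) indexes
# amino acids in this alphabetical one-letter order; file formats with a
# different column order (the PSI-BLAST PSSM dialect) declare an explicit
# mapping.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# PSI-BLAST column order used by the PSSM ASCII dialect
.PSSM_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy, used by the default coarse contact potential
.KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
                    G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
                    M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                    S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Formal side-chain charge at neutral pH (His counted half-protonated)
.AA_CHARGE <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.5,
                I = 0, K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0,
                R = 1, S = 0, T = 0, V = 0, W = 0, Y = 0)

.AA_GROUP_ORDER <- c("polar_charged", "polar_uncharged", "aliphatic",
                     "gly_pro", "his", "aromatic")

.AA_GROUPS <- c(A = "aliphatic", C = "polar_uncharged", D = "polar_charged",
                E = "polar_charged", F = "aromatic", G = "gly_pro",
                H = "his", I = "aliphatic", K = "polar_charged",
                L = "aliphatic", M = "aliphatic", N = "polar_uncharged",
                P = "gly_pro", Q = "polar_uncharged", R = "polar_charged",
                S = "polar_uncharged", T = "polar_uncharged",
                V = "aliphatic", W = "aromatic", Y = "aromatic")

#' The canonical amino-acid alphabet
#'
#' Returns the 20 canonical one-letter amino-acid codes in the fixed
#' alphabetical order used by every matrix in this package
#' (`A C D E F G H I K L M N P Q R S T V W Y`).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() .AA20

#' Six-way amino-acid grouping
#'
#' The fixed grouping used by the worst-position audit: polar charged
#' (D, E, K, R), polar uncharged (Q, N, T, S, C), aliphatic (A, I, L, M, V),
#' Gly/Pro, His, and aromatic (Y, F, W).
#'
#' @return Named character vector mapping each one-letter code to its group.
#' @export
#' @examples
#' aaGroups()[["K"]]  # "polar_charged"
aaGroups <- function() .AA_GROUPS

#' @rdname aaGroups
#' @export
aaGroupLevels <- function() .AA_GROUP_ORDER

# split a sequence string into validated one-letter codes
.seqChars <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) != 1L) {
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  }
  bad <- which(!(sequence %in% .AA20))
  if (length(bad)) {
    stop("non-canonical amino acid '", sequence[bad[1L]],
         "' at position ", bad[1L], call. = FALSE)
  }
  sequence
}

.seqIndex <- function(sequence) match(.seqChars(sequence), .AA20)
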