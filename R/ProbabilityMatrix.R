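# Position-specific probability matrix (PSPM): L x 20 per-position amino-acid
# probabilities in alphabet order, with provenance.

#' ProbabilityMatrix: a position-specific probability matrix (PSPM)
#'
#' An L x 20 matrix of per-position amino-acid probabilities in the fixed
#' alphabetical order of [aminoAcids()].  Every row is a probability
#' distribution (sums to 1 within 1e-6).  Produced by [maskedMarginals()]
#' from a masked-prediction provider, or loaded from a TSV via [readPSPM()].
#'
#' @slot probs numeric L x 20 matrix, columns named by [aminoAcids()].
#' @slot provenance free-text tag recording how the matrix was produced
#'   (provider name, query sequence hash).
#' @export
setClass("ProbabilityMatrix",
  representation(probs = "matrix", provenance = "character"))

setValidity("ProbabilityMatrix", function(object) {
  p <- object@probs
  msg <- character()
  if (ncol(p) != 20L) msg <- c(msg, "probs must have 20 columns")
  else if (!identical(colnames(p), .AA20)) {
    msg <- c(msg, "columns must be named by the canonical alphabet")
  }
  if (nrow(p) < 1L) msg <- c(msg, "matrix must have at least one row")
  if (!all(is.finite(p)) || any(p < 0) || any(p > 1)) {
    msg <- c(msg, "entries must be probabilities in [0, 1]")
  } else if (any(abs(rowSums(p) - 1) > 1e-6)) {
    msg <- c(msg, sprintf("row %d does not sum to 1 within 1e-6",
                          which(abs(rowSums(p) - 1) > 1e-6)[1L]))
  }
  if (length(msg)) msg else TRUE
})

#' @param probs numeric L x 20 matrix of probabilities.
#' @param provenance free-text provenance tag.
#' @rdname ProbabilityMatrix-class
#' @export
ProbabilityMatrix <- function(probs, provenance = "unspecified") {
  probs <- as.matrix(probs)
  colnames(probs) <- .AA20
  rownames(probs) <- NULL
  obj <- new("ProbabilityMatrix", probs = probs,
             provenance = as.character(provenance))
  validObject(obj)
  obj
}

#' @describeIn ProbabilityMatrix-class the probability matrix itself.
#' @param x,object a `ProbabilityMatrix`.
#' @export
probs <- function(x) x@probs

#' @describeIn ProbabilityMatrix-class the provenance tag.
#' @export
provenance <- function(x) x@provenance

#' @describeIn ProbabilityMatrix-class number of positions L.
#' @export
setMethod("length", "ProbabilityMatrix", function(x) nrow(x@probs))

setMethod("show", "ProbabilityMatrix", function(object) {
  cat("ProbabilityMatrix: ", nrow(object@probs), " positions x 20 amino acids\n",
      "  provenance: ", object@provenance, "\n", sep = "")
})

#' Read and write PSPMs as TSV
#'
#' The TSV layout is one header row (`pos` then the 20 one-letter codes in
#' [aminoAcids()] order) and one row per position with its 1-based index.
#' Probabilities are written in full precision; rows are renormalized on
#' read to absorb decimal truncation.
#'
#' @param x a [ProbabilityMatrix-class].
#' @param path file path.
#' @return `readPSPM` returns a [ProbabilityMatrix-class].
#' @export
writePSPM <- function(x, path) {
  stopifnot(is(x, "ProbabilityMatrix"))
  df <- data.frame(pos = seq_len(nrow(x@probs)), x@probs,
                   check.names = FALSE)
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePSPM
#' @export
readPSPM <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!identical(colnames(df), c("pos", .AA20))) {
    stop("malformed PSPM TSV header in ", path, call. = FALSE)
  }
  m <- as.matrix(df[, .AA20])
  m <- m / rowSums(m)
  ProbabilityMatrix(m, provenance = paste0("file:", path))
}
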