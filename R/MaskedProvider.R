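# Masked-prediction provider contract, masked-marginal PSPM construction,
# pseudoperplexity, and the synthetic offline provider.

#' MaskedProvider: the masked-prediction contract
#'
#' A provider answers one query: given a sequence with exactly one masked
#' position, return a probability distribution over the 20 canonical amino
#' acids (in [aminoAcids()] order) for that position.  A protein language
#' model such as ESM2 fills this role in production; [makeSyntheticProvider()]
#' supplies a deterministic stand-in so the whole workflow runs offline.
#' Adapters to external vocabularies must map onto the canonical alphabet,
#' drop non-amino-acid token mass and renormalize.
#'
#' @slot name provider name, recorded in PSPM provenance.
#' @slot queryFun `function(seqChars, pos, masked = TRUE)` returning a
#'   numeric vector of 20 probabilities for position `pos` of the sequence
#'   `seqChars` (character vector of one-letter codes) with that position
#'   treated as masked; `masked = FALSE` requests the non-canonical
#'   single-unmasked-pass mode for providers that distinguish the two.
#' @slot expectedLength expected query length, or `NA` when any length is
#'   accepted.
#' @export
setClass("MaskedProvider",
  representation(name = "character", queryFun = "function",
                 expectedLength = "numeric"))

#' @param name,queryFun,expectedLength see slots.
#' @rdname MaskedProvider-class
#' @export
MaskedProvider <- function(name, queryFun, expectedLength = NA_real_) {
  new("MaskedProvider", name = as.character(name), queryFun = queryFun,
      expectedLength = as.numeric(expectedLength))
}

setMethod("show", "MaskedProvider", function(object) {
  cat("MaskedProvider '", object@name, "'",
      if (!is.na(object@expectedLength)) {
        paste0(" (query length ", object@expectedLength, ")")
      }, "\n", sep = "")
})

#' @describeIn MaskedProvider-class provider name.
#' @param x a `MaskedProvider`.
#' @export
providerName <- function(x) x@name

# query with contract enforcement
.queryProvider <- function(provider, seqChars, pos, masked = TRUE) {
  p <- provider@queryFun(seqChars, pos, masked)
  if (!is.numeric(p) || length(p) != 20L || any(!is.finite(p)) ||
      any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("provider '", provider@name,
         "' returned an invalid distribution at position ", pos,
         call. = FALSE)
  }
  unname(p)
}

#' Build a PSPM by masked marginals
#'
#' Queries the provider once per position: row i is the provider's
#' distribution for the sequence with position i masked and every other
#' position as given.  Rows are computed independently (one mask at a time);
#' this is the canonical scoring mode.  `mode = "unmasked"` instead passes
#' the full unmasked sequence for each position, a cheaper non-canonical
#' variant for providers that distinguish the two (the synthetic provider
#' does not condition on the queried position, so both modes coincide).
#'
#' @param provider a [MaskedProvider-class].
#' @param sequence query sequence (string or character vector of one-letter
#'   codes), canonical amino acids only.
#' @param mode `"masked"` (canonical) or `"unmasked"`.
#' @return a [ProbabilityMatrix-class] with provenance recording the
#'   provider name and a hash of the query sequence.
#' @export
maskedMarginals <- function(provider, sequence, mode = c("masked", "unmasked")) {
  mode <- match.arg(mode)
  stopifnot(is(provider, "MaskedProvider"))
  s <- .seqChars(sequence)
  L <- length(s)
  if (!is.na(provider@expectedLength) && L != provider@expectedLength) {
    stop("provider '", provider@name, "' expects sequences of length ",
         provider@expectedLength, ", got ", L, call. = FALSE)
  }
  m <- t(vapply(seq_len(L), function(i) {
    .queryProvider(provider, s, i, masked = (mode == "masked"))
  }, numeric(20L)))
  m <- m / rowSums(m)
  hash <- substr(.stringHash(paste(s, collapse = "")), 1L, 12L)
  ProbabilityMatrix(m, provenance = sprintf("%s marginals(%s) seq:%s",
                                            provider@name, mode, hash))
}

.stringHash <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

#' Pseudoperplexity of a sequence under a probability matrix
#'
#' The exponential of the negative mean natural-log probability of the
#' realized residues: `exp(-(1/L) * sum_i log p_i(x_i))`.  Lower values mean
#' the sequence is more probable under the model; the minimum of 1 is
#' attained exactly when every realized residue has probability 1, and a
#' matrix that is uniform at every position gives exactly 20 for any
#' sequence.
#'
#' @param sequence the scored sequence (string or character vector); length
#'   must equal the matrix length.
#' @param matrix a [ProbabilityMatrix-class] (rows aligned with positions).
#' @return a single positive number.
#' @export
#' @examples
#' m <- ProbabilityMatrix(matrix(1 / 20, 4, 20))
#' pseudoPerplexity("ACDE", m)  # 20
pseudoPerplexity <- function(sequence, matrix) {
  stopifnot(is(matrix, "ProbabilityMatrix"))
  idx <- .seqIndex(sequence)
  if (length(idx) != nrow(matrix@probs)) {
    stop("sequence length (", length(idx), ") does not match matrix length (",
         nrow(matrix@probs), ")", call. = FALSE)
  }
  p <- matrix@probs[cbind(seq_along(idx), idx)]
  if (any(p == 0)) {
    stop("zero probability for the realized amino acid at position ",
         which(p == 0)[1L], call. = FALSE)
  }
  exp(-mean(log(p)))
}

#' Score many sequences against one provider
#'
#' Convenience wrapper: builds the masked-marginal PSPM of each sequence and
#' returns its pseudoperplexity.
#'
#' @inheritParams maskedMarginals
#' @param sequences character vector of sequences.
#' @return named numeric vector of pseudoperplexities.
#' @export
scoreSequences <- function(provider, sequences, mode = c("masked", "unmasked")) {
  mode <- match.arg(mode)
  vapply(sequences, function(s) {
    pseudoPerplexity(s, maskedMarginals(provider, s, mode = mode))
  }, numeric(1L))
}

#' Synthetic masked-prediction provider
#'
#' A deterministic offline stand-in for a protein language model.  With
#' `couplingStrength = 0` the provider is context-free and returns the
#' stored profile row of the queried position.  With `couplingStrength > 0`
#' the masked distribution at position i is proportional to
#' `profile[i, a] * exp(-couplingStrength * sum_j U[a, x_j])` over the
#' sequence-adjacent neighbours `j = i - 1, i + 1`, where `U` is a fixed
#' seeded random symmetric 20 x 20 coupling table; distributions are
#' renormalized.  This mimics the conditional, context-dependent character
#' of language-model predictions without any trained weights.
#'
#' @param profile a [ProbabilityMatrix-class]; queries must match its length.
#' @param couplingStrength nonnegative real; 0 disables context.
#' @param seed integer seed for the coupling table.
#' @return a [MaskedProvider-class].
#' @export
makeSyntheticProvider <- function(profile, couplingStrength = 0, seed = 1L) {
  stopifnot(is(profile, "ProbabilityMatrix"))
  if (couplingStrength < 0) stop("couplingStrength must be >= 0",
                                 call. = FALSE)
  P <- profile@probs
  L <- nrow(P)
  U <- .withSeed(seed, {
    u <- matrix(rnorm(400L), 20L, 20L)
    (u + t(u)) / 2
  })
  dimnames(U) <- list(.AA20, .AA20)
  queryFun <- function(seqChars, pos, masked = TRUE) {
    if (length(seqChars) != L) {
      stop("synthetic provider expects length ", L, ", got ",
           length(seqChars), call. = FALSE)
    }
    w <- P[pos, ]
    if (couplingStrength > 0) {
      nb <- c(pos - 1L, pos + 1L)
      nb <- nb[nb >= 1L & nb <= L]
      if (length(nb)) {
        e <- rowSums(U[, match(seqChars[nb], .AA20), drop = FALSE])
        w <- w * exp(-couplingStrength * e)
      }
    }
    w / sum(w)
  }
  MaskedProvider(
    name = sprintf("synthetic(coupling=%g,seed=%d)", couplingStrength,
                   as.integer(seed)),
    queryFun = queryFun, expectedLength = L)
}
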