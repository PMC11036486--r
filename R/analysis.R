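# Audits of designed sequences: worst-position analysis with amino-acid
# grouping and layer breakdown, sequence recovery, native-normalized
# scores, and score-term correlations.

#' Worst-scoring positions of a design under its PSPM
#'
#' Collects the `k` positions where the designed amino acid has the lowest
#' predicted probability (equivalently the highest negative log-likelihood)
#' under the probability matrix, in ascending probability order with ties
#' broken by lower position index, and records for each the
#' highest-likelihood replacement (the row argmax; ties broken by alphabet
#' order) together with the six-way amino-acid groups of both.
#'
#' @param sequence the designed sequence.
#' @param pspm a [ProbabilityMatrix-class] aligned with it.
#' @param k number of positions to collect (default 10); when the sequence
#'   is shorter than `k` all positions are returned with a warning.
#' @param layers optional [LayerAssignment-class] (or character vector of
#'   labels) supplying the burial layer of each position.
#' @param designId identifier recorded in the records.
#' @return data.frame with columns `designId`, `position` (1-based),
#'   `designed`, `probability`, `replacement`, `designedGroup`,
#'   `replacementGroup`, `layer`.
#' @export
worstPositions <- function(sequence, pspm, k = 10L, layers = NULL,
                           designId = NA_character_) {
  stopifnot(is(pspm, "ProbabilityMatrix"), k >= 1L)
  idx <- .seqIndex(sequence)
  L <- nrow(pspm@probs)
  if (length(idx) != L) stop("sequence/matrix length mismatch",
                             call. = FALSE)
  if (L < k) {
    warning("sequence has only ", L, " positions; returning all of them")
    k <- L
  }
  p <- pspm@probs[cbind(seq_len(L), idx)]
  ord <- order(p, seq_len(L))[seq_len(k)]
  repl <- apply(pspm@probs[ord, , drop = FALSE], 1L, which.max)
  lab <- if (is.null(layers)) rep(NA_character_, L) else {
    if (is(layers, "LayerAssignment")) layerLabels(layers) else
      as.character(layers)
  }
  data.frame(
    designId = rep(as.character(designId), k),
    position = ord,
    designed = .AA20[idx[ord]],
    probability = unname(p[ord]),
    replacement = .AA20[repl],
    designedGroup = unname(.AA_GROUPS[.AA20[idx[ord]]]),
    replacementGroup = unname(.AA_GROUPS[.AA20[repl]]),
    layer = lab[ord])
}

#' Replacement-group count matrix and layer histogram
#'
#' Tallies worst-position records into a 6 x 6 grid of (designed group ->
#' proposed replacement group) counts over the six fixed categories, with
#' self-replacements on the diagonal, plus a histogram of the records'
#' burial layers.  The grand total of the grid always equals the number of
#' records; an optional filter drops polar-charged-to-polar-charged
#' proposals before counting (off by default, keeping raw counts lossless).
#'
#' @param records data.frame as returned by [worstPositions()] (rows from
#'   several designs may be concatenated).
#' @param excludePolarChargedSelf drop records whose designed and
#'   replacement groups are both `polar_charged`.
#' @return list with elements `counts` (6 x 6 integer matrix, rows =
#'   designed group, columns = replacement group) and `layers` (named
#'   integer vector over core/boundary/surface; records without a layer are
#'   not counted).
#' @export
replacementMatrix <- function(records, excludePolarChargedSelf = FALSE) {
  lev <- .AA_GROUP_ORDER
  if (excludePolarChargedSelf && nrow(records)) {
    drop <- records$designedGroup == "polar_charged" &
      records$replacementGroup == "polar_charged"
    records <- records[!drop, , drop = FALSE]
  }
  counts <- table(factor(records$designedGroup, lev),
                  factor(records$replacementGroup, lev))
  counts <- matrix(as.integer(counts), 6L, 6L, dimnames = list(lev, lev))
  layers <- table(factor(records$layer, c("core", "boundary", "surface")))
  list(counts = counts,
       layers = setNames(as.integer(layers), names(layers)))
}

#' Sequence recovery
#'
#' Fraction of positions at which a designed sequence matches the native
#' sequence.
#'
#' @param design,native sequences of equal length.
#' @return a number in [0, 1].
#' @export
sequenceRecovery <- function(design, native) {
  a <- .seqChars(design)
  b <- .seqChars(native)
  if (length(a) != length(b)) stop("sequence length mismatch",
                                   call. = FALSE)
  mean(a == b)
}

#' Normalize design scores by the native score
#'
#' @param designScores numeric vector of per-design scores.
#' @param nativeScore the native sequence's score (nonzero).
#' @return `designScores / nativeScore`.
#' @export
normalizeByNative <- function(designScores, nativeScore) {
  if (length(nativeScore) != 1L || !is.finite(nativeScore) ||
      nativeScore == 0) {
    stop("nativeScore must be a single nonzero number", call. = FALSE)
  }
  designScores / nativeScore
}

#' Pearson correlation of score terms with pseudoperplexity
#'
#' Computes, for each named score term, the Pearson product-moment
#' correlation with the per-design pseudoperplexities.  Terms with zero
#' variance are reported as `NA` (undefined) with a warning, never as a
#' silent zero.
#'
#' @param terms data.frame of named per-design score terms (>= 3 rows).
#' @param pseudoperplexities numeric vector, one value per design.
#' @return data.frame with columns `term` and `pearsonR`.
#' @export
termCorrelations <- function(terms, pseudoperplexities) {
  terms <- as.data.frame(terms)
  n <- nrow(terms)
  if (n < 3L) stop("need at least 3 designs", call. = FALSE)
  if (length(pseudoperplexities) != n) {
    stop("terms and pseudoperplexities length mismatch", call. = FALSE)
  }
  r <- vapply(names(terms), function(nm) {
    x <- terms[[nm]]
    if (stats::var(x) == 0 || stats::var(pseudoperplexities) == 0) {
      warning("zero variance makes correlation undefined for term '", nm,
              "'")
      return(NA_real_)
    }
    stats::cor(x, pseudoperplexities)
  }, numeric(1L))
  data.frame(term = names(terms), pearsonR = unname(r))
}
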