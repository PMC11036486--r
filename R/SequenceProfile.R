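# Sequence-profile restraint: PSPM -> profile conversion, restraint energy,
# and the PSI-BLAST ASCII PSSM dialect.

#' SequenceProfile: a per-residue restraint profile
#'
#' An L x 20 score grid derived from a [ProbabilityMatrix-class] together
#' with the metadata needed to interpret it.  In `logodds` mode
#' `scores[i, a] = scale * log(p[i, a] / background[a])` with probabilities
#' floored at `floorProb` before the ratio; in `prob` mode the scores are
#' the raw probabilities; in `global` mode each probability is divided by
#' the maximum over the whole matrix.
#'
#' @slot scores numeric L x 20 matrix in [aminoAcids()] column order.
#' @slot mode one of `"logodds"`, `"prob"`, `"global"`.
#' @slot background the 20 background probabilities (default uniform 1/20).
#' @slot scale positive scale factor applied in `logodds` mode.
#' @slot source provenance text.
#' @export
setClass("SequenceProfile",
  representation(scores = "matrix", mode = "character",
                 background = "numeric", scale = "numeric",
                 source = "character"))

setValidity("SequenceProfile", function(object) {
  msg <- character()
  if (!object@mode %in% c("logodds", "prob", "global")) {
    msg <- c(msg, "mode must be logodds, prob or global")
  }
  if (ncol(object@scores) != 20L || !identical(colnames(object@scores), .AA20)) {
    msg <- c(msg, "scores must be L x 20 in canonical column order")
  }
  if (!all(is.finite(object@scores))) msg <- c(msg, "non-finite score entries")
  if (length(object@background) != 20L || any(object@background <= 0) ||
      abs(sum(object@background) - 1) > 1e-6) {
    msg <- c(msg, "background must be a strict 20-way distribution")
  }
  if (length(object@scale) != 1L || object@scale <= 0) {
    msg <- c(msg, "scale must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SequenceProfile-class the score grid.
#' @param x,object a `SequenceProfile`.
#' @export
profileScores <- function(x) x@scores

#' @describeIn SequenceProfile-class profile mode.
#' @export
profileMode <- function(x) x@mode

#' @describeIn SequenceProfile-class number of positions.
#' @export
setMethod("length", "SequenceProfile", function(x) nrow(x@scores))

setMethod("show", "SequenceProfile", function(object) {
  cat("SequenceProfile: ", nrow(object@scores), " positions, mode '",
      object@mode, "', scale ", object@scale, "\n  source: ", object@source,
      "\n", sep = "")
})

#' Convert a PSPM into a sequence-profile restraint
#'
#' Implements the three standard scalings of a probability matrix into a
#' profile usable as a per-residue design restraint (the role the
#' FavorSequenceProfile mechanism plays in structure-based design suites).
#'
#' @param pspm a [ProbabilityMatrix-class].
#' @param mode `"logodds"` (default), `"prob"` or `"global"`; see
#'   [SequenceProfile-class] for the formulas.
#' @param background 20 background probabilities (strict distribution),
#'   default uniform.
#' @param scale positive scale applied in `logodds` mode.
#' @param floorProb probability floor in `(0, 1e-2]` applied before the
#'   log-ratio, guarding against exact zeros from vocabulary mapping.
#' @return a [SequenceProfile-class].
#' @export
#' @examples
#' m <- ProbabilityMatrix(matrix(1 / 20, 3, 20))
#' range(profileScores(pspmToProfile(m)))  # all zero
pspmToProfile <- function(pspm, mode = c("logodds", "prob", "global"),
                          background = rep(1 / 20, 20), scale = 1,
                          floorProb = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(is(pspm, "ProbabilityMatrix"))
  if (length(background) != 20L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be a strict distribution over 20 amino acids",
         call. = FALSE)
  }
  if (floorProb <= 0 || floorProb > 1e-2) {
    stop("floorProb must lie in (0, 1e-2]", call. = FALSE)
  }
  p <- pspm@probs
  scores <- switch(mode,
    logodds = scale * log(pmax(p, floorProb) /
                            matrix(background, nrow(p), 20L, byrow = TRUE)),
    prob = p,
    global = p / max(p))
  colnames(scores) <- .AA20
  obj <- new("SequenceProfile", scores = scores, mode = mode,
             background = as.numeric(background), scale = as.numeric(scale),
             source = pspm@provenance)
  validObject(obj)
  obj
}

#' RestraintConfig: a weighted profile restraint
#'
#' Pairs a [SequenceProfile-class] with the nonnegative restraint weight
#' applied during design.  The profile is computed once, before design, and
#' is never updated while a design trajectory runs.
#'
#' @slot weight nonnegative restraint weight.
#' @slot profile the [SequenceProfile-class].
#' @export
setClass("RestraintConfig",
  representation(weight = "numeric", profile = "SequenceProfile"))

setValidity("RestraintConfig", function(object) {
  if (length(object@weight) != 1L || !is.finite(object@weight) ||
      object@weight < 0) {
    "weight must be a single nonnegative number"
  } else TRUE
})

#' @param weight nonnegative weight.
#' @param profile a [SequenceProfile-class].
#' @rdname RestraintConfig-class
#' @export
RestraintConfig <- function(profile, weight = 1) {
  obj <- new("RestraintConfig", weight = as.numeric(weight), profile = profile)
  validObject(obj)
  obj
}

#' Profile restraint energy of a sequence
#'
#' Returns `-w * sum_i scores[i, x_i]`: a bonus, so higher profile scores
#' lower the design energy.  Additive over positions and linear in `w`; the
#' profile is held fixed for the whole design run.
#'
#' @param profile a [SequenceProfile-class].
#' @param sequence sequence of matching length.
#' @param w nonnegative weight.
#' @return a single number.
#' @export
restraintEnergy <- function(profile, sequence, w = 1) {
  stopifnot(is(profile, "SequenceProfile"), w >= 0)
  idx <- .seqIndex(sequence)
  if (length(idx) != nrow(profile@scores)) {
    stop("sequence length (", length(idx),
         ") does not match profile length (", nrow(profile@scores), ")",
         call. = FALSE)
  }
  -w * sum(profile@scores[cbind(seq_along(idx), idx)])
}

# ---------------------------------------------------------------------------
# PSI-BLAST ASCII PSSM dialect

#' Write and read PSI-BLAST-style PSSM files
#'
#' `writePSSM` serializes a [ProbabilityMatrix-class] in the classic
#' PSI-BLAST ASCII layout: two header lines, then one row per position with
#' the 1-based index, the reference amino acid, 20 integer score columns in
#' PSI-BLAST column order (`A R N D C Q E G H I L K M F P S T W Y V`)
#' holding `round(2 * log2(p / background))`, and 20 percentage columns
#' holding `round(100 * p)`.  `readPSSM` reconstructs probabilities from the
#' percentage columns and returns them as a [SequenceProfile-class] in
#' `prob` mode; the reconstruction is exact to the percent-rounding bound of
#' 0.005 per entry.  [profileToPSPM()] renormalizes the rows (absorbing the
#' integer-rounding residual) to recover a strict
#' [ProbabilityMatrix-class].
#'
#' @param x a [ProbabilityMatrix-class].
#' @param path file path.
#' @param refSequence optional reference sequence written in the amino-acid
#'   column; default the per-row argmax of the matrix.
#' @param background 20 background probabilities for the score columns.
#' @return `readPSSM` returns a [SequenceProfile-class] in `prob` mode.
#' @export
writePSSM <- function(x, path, refSequence = NULL,
                      background = rep(1 / 20, 20)) {
  stopifnot(is(x, "ProbabilityMatrix"))
  p <- x@probs
  L <- nrow(p)
  if (is.null(refSequence)) {
    ref <- .AA20[apply(p, 1L, which.max)]
  } else {
    ref <- .seqChars(refSequence)
    if (length(ref) != L) stop("refSequence length mismatch", call. = FALSE)
  }
  ord <- match(.PSSM_ORDER, .AA20)
  bg <- background[ord]
  scores <- round(2 * log2(pmax(p[, ord, drop = FALSE], 1e-9) /
                             matrix(bg, L, 20L, byrow = TRUE)))
  perc <- round(100 * p[, ord, drop = FALSE])
  lines <- c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0("          ", paste(sprintf("%4s", .PSSM_ORDER), collapse = " "),
           "  ", paste(sprintf("%4s", .PSSM_ORDER), collapse = " ")))
  for (i in seq_len(L)) {
    lines <- c(lines, paste0(
      sprintf("%5d %s  ", i, ref[i]),
      paste(sprintf("%4d", scores[i, ]), collapse = " "), "  ",
      paste(sprintf("%4d", perc[i, ]), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePSSM
#' @export
readPSSM <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^\\s+A\\s+R\\s+N\\s+D", lines)
  if (!length(hdr)) stop("malformed PSSM header in ", path, call. = FALSE)
  body <- lines[seq.int(hdr[1L] + 1L, length(lines))]
  body <- body[grepl("^\\s*\\d+\\s+[A-Z]", body)]
  if (!length(body)) stop("no PSSM rows in ", path, call. = FALSE)
  perc <- matrix(NA_real_, length(body), 20L)
  idx <- integer(length(body))
  for (r in seq_along(body)) {
    f <- strsplit(trimws(body[r]), "\\s+")[[1L]]
    if (length(f) < 42L) {
      stop("PSSM row ", r, " has ", length(f) - 2L,
           " numeric fields (40 expected)", call. = FALSE)
    }
    nums <- suppressWarnings(as.numeric(f[3:42]))
    if (any(is.na(nums))) stop("non-numeric field in PSSM row ", r,
                               call. = FALSE)
    idx[r] <- as.integer(f[1L])
    perc[r, ] <- nums[21:40]
  }
  if (!identical(idx, seq_along(idx))) {
    stop("PSSM position indices are not contiguous from 1", call. = FALSE)
  }
  p <- perc[, match(.AA20, .PSSM_ORDER), drop = FALSE] / 100
  rs <- rowSums(p)
  if (any(rs <= 0)) stop("PSSM row ", which(rs <= 0)[1L],
                         " has no probability mass", call. = FALSE)
  colnames(p) <- .AA20
  obj <- new("SequenceProfile", scores = p, mode = "prob",
             background = rep(1 / 20, 20), scale = 1,
             source = paste0("file:", path))
  validObject(obj)
  obj
}

#' Recover a ProbabilityMatrix from a prob-mode profile
#'
#' @param profile a [SequenceProfile-class] with mode `"prob"`.
#' @return a [ProbabilityMatrix-class] (rows renormalized).
#' @export
profileToPSPM <- function(profile) {
  stopifnot(is(profile, "SequenceProfile"))
  if (profile@mode != "prob") {
    stop("only prob-mode profiles can be converted back to probabilities",
         call. = FALSE)
  }
  ProbabilityMatrix(profile@scores / rowSums(profile@scores),
                    provenance = profile@source)
}
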