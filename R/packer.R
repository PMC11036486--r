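# Combinatorial sequence optimization: simulated-annealing packer (Rcpp
# inner loop) and the exhaustive brute-force oracle.

#' AnnealSchedule: geometric cooling schedule
#'
#' Temperatures interpolate geometrically from `tStart` to `tEnd` across
#' `nSweeps` sweeps; each sweep attempts L single-position substitutions.
#' `seed` makes the trajectory deterministic.
#'
#' @slot tStart,tEnd start/end temperatures, `0 < tEnd <= tStart`.
#' @slot nSweeps number of sweeps (>= 1).
#' @slot seed integer RNG seed.
#' @export
setClass("AnnealSchedule",
  representation(tStart = "numeric", tEnd = "numeric", nSweeps = "integer",
                 seed = "integer"))

setValidity("AnnealSchedule", function(object) {
  msg <- character()
  if (object@tStart <= 0 || object@tEnd <= 0) {
    msg <- c(msg, "temperatures must be positive")
  }
  if (object@tEnd > object@tStart) msg <- c(msg, "tEnd must be <= tStart")
  if (object@nSweeps < 1L) msg <- c(msg, "nSweeps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param tStart,tEnd,nSweeps,seed see slots.
#' @rdname AnnealSchedule-class
#' @export
annealSchedule <- function(tStart = 3, tEnd = 0.3, nSweeps = 100L,
                           seed = 1L) {
  obj <- new("AnnealSchedule", tStart = as.numeric(tStart),
             tEnd = as.numeric(tEnd), nSweeps = as.integer(nSweeps),
             seed = as.integer(seed))
  validObject(obj)
  obj
}

#' @describeIn AnnealSchedule-class a near-zero-temperature (greedy)
#'   schedule that never accepts an uphill move.
#' @export
greedySchedule <- function(nSweeps = 100L, seed = 1L) {
  annealSchedule(tStart = 1e-9, tEnd = 1e-9, nSweeps = nSweeps, seed = seed)
}

setMethod("show", "AnnealSchedule", function(object) {
  cat("AnnealSchedule: T ", object@tStart, " -> ", object@tEnd, ", ",
      object@nSweeps, " sweeps, seed ", object@seed, "\n", sep = "")
})

#' DesignResult: one designed sequence with its energy breakdown
#'
#' @slot sequence the designed sequence (single string).
#' @slot baseEnergy,restraintEnergy,totalEnergy energy breakdown;
#'   `totalEnergy = baseEnergy + restraintEnergy` to 1e-9.
#' @slot protocol one of `fixbb`, `layerdesign`, `esm_restrained`,
#'   `bruteforce`.
#' @slot seed the RNG seed used (NA for the exhaustive oracle).
#' @slot acceptedMoves number of accepted substitutions.
#' @export
setClass("DesignResult",
  representation(sequence = "character", baseEnergy = "numeric",
                 restraintEnergy = "numeric", totalEnergy = "numeric",
                 protocol = "character", seed = "integer",
                 acceptedMoves = "numeric"))

setValidity("DesignResult", function(object) {
  if (abs(object@totalEnergy -
          (object@baseEnergy + object@restraintEnergy)) > 1e-9) {
    "totalEnergy must equal baseEnergy + restraintEnergy to 1e-9"
  } else TRUE
})

#' @describeIn DesignResult-class the designed sequence string.
#' @param x,object a `DesignResult`.
#' @export
designedSequence <- function(x) x@sequence

#' @describeIn DesignResult-class total/base/restraint energies as a named
#'   vector.
#' @export
designEnergies <- function(x) {
  c(total = x@totalEnergy, base = x@baseEnergy,
    restraint = x@restraintEnergy)
}

setMethod("show", "DesignResult", function(object) {
  cat("DesignResult [", object@protocol, "]: total ",
      sprintf("%.4f", object@totalEnergy), " (base ",
      sprintf("%.4f", object@baseEnergy), ", restraint ",
      sprintf("%.4f", object@restraintEnergy), ")\n  ",
      object@sequence, "\n", sep = "")
})

# project a sequence onto a task: keep if allowed, else nearest allowed
# amino acid in alphabet-index distance (ties toward the earlier letter)
.projectToTask <- function(idx, allowed) {
  vapply(seq_along(idx), function(i) {
    if (allowed[i, idx[i]]) return(idx[i])
    opts <- which(allowed[i, ])
    opts[which.min(abs(opts - idx[i]))]
  }, integer(1L))
}

#' Design a sequence by simulated annealing
#'
#' Metropolis single-position substitution moves (uniform random position,
#' uniform random allowed amino acid different from the current one), L
#' attempted moves per sweep, acceptance `min(1, exp(-dE/T))`, geometric
#' cooling.  Returns the best-energy sequence ever visited.  The restraint
#' profile is fixed for the whole run: the probability matrix behind it is
#' never updated after a mutation.  Deterministic for a fixed schedule seed.
#'
#' @param contacts contact matrix from [contactMap()].
#' @param model an [EnergyModel-class].
#' @param task a [DesignTask-class].
#' @param restraint a [RestraintConfig-class] or `NULL` for unrestrained
#'   design.
#' @param schedule an [AnnealSchedule-class].
#' @param startSequence starting sequence; positions whose amino acid the
#'   task forbids are projected to the nearest allowed amino acid in
#'   alphabet order.
#' @param protocol protocol tag recorded in the result.
#' @param trace if `TRUE`, attach the full move-by-move trajectory
#'   (`attr(result, "trace")`): position, from, to, dE, accepted.
#' @return a [DesignResult-class].
#' @export
pack <- function(contacts, model, task, restraint = NULL,
                 schedule = annealSchedule(), startSequence,
                 protocol = "fixbb", trace = FALSE) {
  stopifnot(is(model, "EnergyModel"), is(task, "DesignTask"),
            is(schedule, "AnnealSchedule"))
  allowed <- task@allowed
  L <- nrow(allowed)
  idx <- .seqIndex(startSequence)
  if (length(idx) != L) stop("startSequence length mismatch", call. = FALSE)
  idx <- .projectToTask(idx, allowed)
  if (is.null(restraint)) {
    w <- 0
    scores <- matrix(0, L, 20L)
  } else {
    stopifnot(is(restraint, "RestraintConfig"))
    w <- restraint@weight
    scores <- restraint@profile@scores
    if (nrow(scores) != L) {
      stop("restraint profile length (", nrow(scores),
           ") does not match task length (", L, ")", call. = FALSE)
    }
  }
  contacts <- .checkContacts(contacts, L)
  res <- .withSeed(schedule@seed, {
    .annealPack(contacts, model@contactPotential,
                as.numeric(model@referenceEnergies), allowed, scores, w,
                schedule@tStart, schedule@tEnd, schedule@nSweeps,
                as.integer(idx), trace)
  })
  out <- new("DesignResult",
             sequence = paste(.AA20[res$bestSeq], collapse = ""),
             baseEnergy = res$bestBase, restraintEnergy = res$bestRestraint,
             totalEnergy = res$bestBase + res$bestRestraint,
             protocol = protocol, seed = schedule@seed,
             acceptedMoves = res$accepted)
  validObject(out)
  if (trace) attr(out, "trace") <- res$trace
  out
}

.checkContacts <- function(contacts, L) {
  if (is.null(contacts) || !length(contacts)) {
    return(matrix(integer(0), 0L, 2L))
  }
  contacts <- as.matrix(contacts)
  storage.mode(contacts) <- "integer"
  if (ncol(contacts) != 2L) stop("contacts must have two columns",
                                 call. = FALSE)
  if (nrow(contacts) && (min(contacts) < 1L || max(contacts) > L)) {
    stop("contact index out of range", call. = FALSE)
  }
  contacts
}

#' Exhaustive design oracle
#'
#' Enumerates every sequence the task allows (product of allowed-set sizes
#' at most `maxStates`) and returns the exact global optimum of the same
#' energy [pack()] optimizes.  Ties are broken by lexicographic sequence
#' order.
#'
#' @inheritParams pack
#' @param maxStates enumeration guard (default 1e6).
#' @return a [DesignResult-class] with protocol `"bruteforce"`.
#' @export
bruteForceDesign <- function(contacts, model, task, restraint = NULL,
                             maxStates = 1e6) {
  stopifnot(is(model, "EnergyModel"), is(task, "DesignTask"))
  allowed <- task@allowed
  L <- nrow(allowed)
  sizes <- rowSums(allowed)
  if (prod(sizes) > maxStates) {
    stop("search space (", format(prod(sizes), big.mark = ","),
         " states) exceeds maxStates", call. = FALSE)
  }
  contacts <- .checkContacts(contacts, L)
  opts <- lapply(seq_len(L), function(i) which(allowed[i, ]))
  # lexicographic order: first position most significant
  grid <- as.matrix(rev(expand.grid(rev(opts), KEEP.OUT.ATTRS = FALSE)))
  dimnames(grid) <- NULL
  n <- nrow(grid)
  e <- rowSums(matrix(model@referenceEnergies[grid], n, L))
  if (nrow(contacts)) {
    for (k in seq_len(nrow(contacts))) {
      e <- e + model@contactPotential[cbind(grid[, contacts[k, 1L]],
                                            grid[, contacts[k, 2L]])]
    }
  }
  w <- 0
  restr <- numeric(n)
  if (!is.null(restraint)) {
    stopifnot(is(restraint, "RestraintConfig"))
    w <- restraint@weight
    s <- restraint@profile@scores
    if (nrow(s) != L) stop("restraint profile length mismatch",
                           call. = FALSE)
    for (i in seq_len(L)) restr <- restr - w * s[i, grid[, i]]
  }
  total <- e + restr
  bestIdx <- which.min(total)  # first minimum = lexicographically smallest
  out <- new("DesignResult",
             sequence = paste(.AA20[grid[bestIdx, ]], collapse = ""),
             baseEnergy = e[bestIdx], restraintEnergy = restr[bestIdx],
             totalEnergy = total[bestIdx], protocol = "bruteforce",
             seed = NA_integer_, acceptedMoves = 0)
  validObject(out)
  out
}
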