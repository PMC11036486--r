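# Coarse fixed-backbone design energy, contact maps, Shrake-Rupley SASA,
# layer classification, secondary structure, and LayerDesign task building.

#' EnergyModel: the coarse sequence-level design energy
#'
#' A deliberately simple stand-in for an all-atom design energy, operating
#' at sequence level on a fixed backbone: a symmetric 20 x 20 contact
#' potential summed over residue pairs in contact (CB-CB distance, CA for
#' glycine, within `contactCutoff` and separated by at least 2 in sequence)
#' plus per-amino-acid reference energies acting as a composition penalty.
#'
#' The bundled default table is built from Kyte-Doolittle hydropathy: a
#' burial term rewarding hydrophobic residues in contact-rich positions, a
#' like-with-like mixing term, and a charge-pair term penalizing like
#' charges.  Lower energies are more favorable.
#'
#' @slot contactPotential symmetric 20 x 20 matrix, canonical order.
#' @slot referenceEnergies 20 reference energies, canonical order.
#' @slot contactCutoff contact distance cutoff in Angstrom (default 8).
#' @export
setClass("EnergyModel",
  representation(contactPotential = "matrix", referenceEnergies = "numeric",
                 contactCutoff = "numeric"))

setValidity("EnergyModel", function(object) {
  msg <- character()
  cp <- object@contactPotential
  if (!is.matrix(cp) || any(dim(cp) != 20L)) {
    msg <- c(msg, "contactPotential must be 20 x 20")
  } else {
    if (!all(is.finite(cp))) msg <- c(msg, "non-finite contact potential")
    if (max(abs(cp - t(cp))) > 1e-12) {
      msg <- c(msg, "contactPotential must be symmetric (tol 1e-12)")
    }
  }
  if (length(object@referenceEnergies) != 20L ||
      !all(is.finite(object@referenceEnergies))) {
    msg <- c(msg, "referenceEnergies must be 20 finite numbers")
  }
  if (length(object@contactCutoff) != 1L || object@contactCutoff <= 0) {
    msg <- c(msg, "contactCutoff must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

#' @param contactPotential,referenceEnergies,contactCutoff see slots.
#' @rdname EnergyModel-class
#' @export
EnergyModel <- function(contactPotential, referenceEnergies = rep(0, 20),
                        contactCutoff = 8) {
  dimnames(contactPotential) <- list(.AA20, .AA20)
  obj <- new("EnergyModel", contactPotential = contactPotential,
             referenceEnergies = setNames(as.numeric(referenceEnergies), .AA20),
             contactCutoff = as.numeric(contactCutoff))
  validObject(obj)
  obj
}

#' @describeIn EnergyModel-class the bundled hydropathy-based default model.
#' @export
defaultEnergyModel <- function() {
  h <- .KD_HYDROPATHY[.AA20] / 4.5
  q <- .AA_CHARGE[.AA20]
  burial <- -0.6 * outer(h, h, function(a, b) (a + b) / 2)
  mixing <- -0.3 * outer(h, h)
  charge <- 0.4 * outer(q, q)
  EnergyModel(contactPotential = burial + mixing + charge,
              referenceEnergies = 0.2 * h, contactCutoff = 8)
}

setMethod("show", "EnergyModel", function(object) {
  cat("EnergyModel: 20 x 20 contact potential, cutoff ",
      object@contactCutoff, " A\n", sep = "")
})

#' Contact map of a structure
#'
#' Unordered residue pairs (i, j) with sequence separation |i - j| >= 2
#' whose side-chain proxy atoms (CB, CA for glycine) lie within the model's
#' contact cutoff.
#'
#' @param structure a [ProteinStructure-class].
#' @param model an [EnergyModel-class] (only the cutoff is used).
#' @return integer matrix with columns `i`, `j` (1-based, i < j).
#' @export
contactMap <- function(structure, model = defaultEnergyModel()) {
  stopifnot(is(structure, "ProteinStructure"))
  xyz <- atomCoords(structure, "CB")
  gly <- structure@aa == "G"
  xyz[gly, ] <- atomCoords(structure, "CA")[gly, ]
  d <- as.matrix(dist(xyz))
  sep <- abs(row(d) - col(d))
  hit <- which(d <= model@contactCutoff & sep >= 2L & upper.tri(d),
               arr.ind = TRUE)
  m <- cbind(i = as.integer(hit[, 1L]), j = as.integer(hit[, 2L]))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Coarse base design energy of a sequence
#'
#' `sum over contacts of contactPotential[x_i, x_j] + sum_i
#' referenceEnergies[x_i]`.  Deterministic; invariant to the ordering of
#' contact pairs.
#'
#' @param sequence sequence (string or character vector).
#' @param contacts contact matrix as returned by [contactMap()].
#' @param model an [EnergyModel-class].
#' @return a single number.
#' @export
baseEnergy <- function(sequence, contacts, model = defaultEnergyModel()) {
  idx <- .seqIndex(sequence)
  if (nrow(contacts) && max(contacts) > length(idx)) {
    stop("contact index out of range for sequence of length ", length(idx),
         call. = FALSE)
  }
  e <- sum(model@referenceEnergies[idx])
  if (nrow(contacts)) {
    e <- e + sum(model@contactPotential[cbind(idx[contacts[, 1L]],
                                              idx[contacts[, 2L]])])
  }
  unname(e)
}

# ---------------------------------------------------------------------------
# Shrake-Rupley SASA

# fixed van der Waals radii (Angstrom) for the backbone+CB atom set
.VDW_RADII <- c(N = 1.55, CA = 1.70, C = 1.70, O = 1.52, CB = 1.70)

# deterministic quasi-uniform sphere point set (Fibonacci lattice)
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (seq_len(n) - 1)
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Shrake-Rupley solvent accessibility of arbitrary atoms
#'
#' Numerical quadrature over a deterministic Fibonacci sphere point set:
#' each atom's accessible area is the fraction of points on its
#' probe-expanded sphere not buried inside any other expanded sphere, times
#' the expanded-sphere area.
#'
#' @param xyz numeric n x 3 matrix of atom centres (Angstrom).
#' @param radii numeric vector of n van der Waals radii.
#' @param probeRadius probe radius in Angstrom (default water, 1.4).
#' @param nPoints quadrature points per atom (>= 32; default 960).
#' @return numeric vector of per-atom accessible areas in square Angstrom.
#' @export
sasaAtoms <- function(xyz, radii, probeRadius = 1.4, nPoints = 960L) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n, ncol(xyz) == 3L)
  if (nPoints < 32L) stop("nPoints must be >= 32", call. = FALSE)
  pts <- .spherePoints(as.integer(nPoints))
  rext <- radii + probeRadius
  out <- numeric(n)
  d2 <- as.matrix(dist(xyz))
  for (a in seq_len(n)) {
    # a sphere coinciding with an earlier identical sphere contributes its
    # area once: the later twin is counted as fully occluded
    twin <- which(seq_len(n) < a & d2[a, ] < 1e-9 & abs(rext - rext[a]) < 1e-9)
    if (length(twin)) next
    nb <- which(d2[a, ] < rext[a] + rext & seq_len(n) != a)
    surf <- sweep(pts * rext[a], 2L, xyz[a, ], "+")
    free <- rep(TRUE, nPoints)
    for (b in nb) {
      if (d2[a, b] < 1e-9 && abs(rext[b] - rext[a]) < 1e-9) next
      db <- sqrt(rowSums(sweep(surf, 2L, xyz[b, ], "-")^2))
      free <- free & (db >= rext[b])
      if (!any(free)) break
    }
    out[a] <- 4 * pi * rext[a]^2 * mean(free)
  }
  out
}

#' Per-residue SASA of a structure
#'
#' Sums [sasaAtoms()] areas over each residue's backbone+CB atoms (glycine
#' has no CB), using the bundled radii table (N 1.55, C 1.70, O 1.52 A).
#' Because side chains do not exist in this sequence-level representation,
#' the value is a burial proxy rather than an all-atom SASA.
#'
#' @param structure a [ProteinStructure-class].
#' @param probeRadius probe radius in Angstrom.
#' @param nPoints quadrature points per atom (>= 32).
#' @return numeric vector of per-residue areas in square Angstrom.
#' @export
shrakeRupleySASA <- function(structure, probeRadius = 1.4, nPoints = 960L) {
  stopifnot(is(structure, "ProteinStructure"))
  L <- length(structure@aa)
  atoms <- c("N", "CA", "C", "O", "CB")
  xyz <- NULL
  res <- integer(0)
  rad <- numeric(0)
  for (atom in atoms) {
    m <- structure@coords[[atom]]
    keep <- if (atom == "CB") which(structure@aa != "G") else seq_len(L)
    xyz <- rbind(xyz, m[keep, , drop = FALSE])
    res <- c(res, keep)
    rad <- c(rad, rep(.VDW_RADII[[atom]], length(keep)))
  }
  areas <- sasaAtoms(xyz, rad, probeRadius = probeRadius, nPoints = nPoints)
  as.numeric(tapply(areas, factor(res, levels = seq_len(L)), sum,
                    default = 0))
}

# ---------------------------------------------------------------------------
# Layers and secondary structure

#' LayerAssignment: burial layers from SASA
#'
#' Per-residue SASA with a three-way burial label: `core` when SASA is at or
#' below `coreCut` (boundary-inclusive: a residue exactly at the cutoff is
#' core), `surface` when at or above `surfCut`, else `boundary`.
#'
#' @slot sasa per-residue SASA in square Angstrom.
#' @slot labels factor-like character vector in `core/boundary/surface`.
#' @slot coreCut,surfCut the cutoffs used (square Angstrom).
#' @export
setClass("LayerAssignment",
  representation(sasa = "numeric", labels = "character",
                 coreCut = "numeric", surfCut = "numeric"))

setValidity("LayerAssignment", function(object) {
  msg <- character()
  if (length(object@sasa) != length(object@labels)) {
    msg <- c(msg, "sasa/labels length mismatch")
  }
  if (any(object@sasa < 0)) msg <- c(msg, "negative SASA")
  if (!all(object@labels %in% c("core", "boundary", "surface"))) {
    msg <- c(msg, "labels must be core/boundary/surface")
  }
  expected <- ifelse(object@sasa <= object@coreCut, "core",
                     ifelse(object@sasa >= object@surfCut, "surface",
                            "boundary"))
  if (!identical(expected, object@labels)) {
    msg <- c(msg, "labels inconsistent with cutoffs")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn LayerAssignment-class the layer labels.
#' @param x a `LayerAssignment`.
#' @export
layerLabels <- function(x) x@labels

#' @describeIn LayerAssignment-class the per-residue SASA.
#' @export
residueSASA <- function(x) x@sasa

setMethod("show", "LayerAssignment", function(object) {
  tab <- table(factor(object@labels, c("core", "boundary", "surface")))
  cat("LayerAssignment (cutoffs ", object@coreCut, "/", object@surfCut,
      " A^2): ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
})

#' Classify residues into core/boundary/surface layers
#'
#' @param sasa nonnegative per-residue SASA (square Angstrom).
#' @param coreCut,surfCut layer cutoffs with `coreCut < surfCut`; defaults
#'   20 and 40 square Angstrom for the backbone+CB burial proxy.
#' @return a [LayerAssignment-class].
#' @export
classifyLayers <- function(sasa, coreCut = 20, surfCut = 40) {
  if (coreCut >= surfCut) stop("coreCut must be < surfCut", call. = FALSE)
  if (any(sasa < 0)) stop("SASA must be nonnegative", call. = FALSE)
  labels <- ifelse(sasa <= coreCut, "core",
                   ifelse(sasa >= surfCut, "surface", "boundary"))
  obj <- new("LayerAssignment", sasa = as.numeric(sasa),
             labels = as.character(labels), coreCut = as.numeric(coreCut),
             surfCut = as.numeric(surfCut))
  validObject(obj)
  obj
}

#' Backbone-dihedral secondary structure
#'
#' Simple phi/psi-region assignment: helix (`H`) for phi in [-100, -30] and
#' psi in [-80, -5]; strand (`E`) for phi in [-180, -80] and psi in
#' [80, 180] or [-180, -170]; loop (`L`) otherwise.  Chain termini (where a
#' dihedral is undefined) are `L`, and H/E runs shorter than 3 residues are
#' demoted to `L`.
#'
#' @param structure a [ProteinStructure-class] with at least 3 residues.
#' @return character vector of labels in `H`, `E`, `L`.
#' @export
secondaryStructure <- function(structure) {
  stopifnot(is(structure, "ProteinStructure"))
  L <- length(structure@aa)
  if (L < 3L) stop("secondary structure needs at least 3 residues",
                   call. = FALSE)
  pp <- .phiPsi(structure@coords$N, structure@coords$CA, structure@coords$C)
  ss <- rep("L", L)
  for (i in seq_len(L)) {
    phi <- pp$phi[i]
    psi <- pp$psi[i]
    if (is.na(phi) || is.na(psi)) next
    if (phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5) {
      ss[i] <- "H"
    } else if (phi >= -180 && phi <= -80 &&
               ((psi >= 80 && psi <= 180) || (psi >= -180 && psi <= -170))) {
      ss[i] <- "E"
    }
  }
  # demote H/E runs shorter than 3
  r <- rle(ss)
  r$values[r$values %in% c("H", "E") & r$lengths < 3L] <- "L"
  inverse.rle(r)
}

# ---------------------------------------------------------------------------
# Design tasks

#' DesignTask: per-position allowed amino acids
#'
#' A logical L x 20 matrix (canonical column order): entry (i, a) says
#' whether amino acid a may be placed at position i.  Every position must
#' allow at least one amino acid.
#'
#' @slot allowed logical L x 20 matrix.
#' @export
setClass("DesignTask", representation(allowed = "matrix"))

setValidity("DesignTask", function(object) {
  a <- object@allowed
  msg <- character()
  if (!is.logical(a) || ncol(a) != 20L || !identical(colnames(a), .AA20)) {
    msg <- c(msg, "allowed must be a logical L x 20 matrix, canonical order")
  } else if (any(rowSums(a) == 0L)) {
    msg <- c(msg, sprintf("position %d allows no amino acid",
                          which(rowSums(a) == 0L)[1L]))
  }
  if (length(msg)) msg else TRUE
})

#' @param allowed logical L x 20 matrix.
#' @rdname DesignTask-class
#' @export
DesignTask <- function(allowed) {
  colnames(allowed) <- .AA20
  obj <- new("DesignTask", allowed = allowed)
  validObject(obj)
  obj
}

#' @describeIn DesignTask-class the allowed matrix.
#' @param x,object a `DesignTask`.
#' @export
allowedMatrix <- function(x) x@allowed

#' @describeIn DesignTask-class number of positions.
#' @export
setMethod("length", "DesignTask", function(x) nrow(x@allowed))

setMethod("show", "DesignTask", function(object) {
  cat("DesignTask: ", nrow(object@allowed), " positions, mean ",
      round(mean(rowSums(object@allowed)), 1), " allowed amino acids\n",
      sep = "")
})

#' @describeIn DesignTask-class task allowing the full alphabet everywhere.
#' @param L number of positions.
#' @export
fullAlphabetTask <- function(L) {
  DesignTask(matrix(TRUE, L, 20L, dimnames = list(NULL, .AA20)))
}

#' Default layer-design rules
#'
#' The bundled per-layer allowed sets: core `{A,F,I,L,M,P,V,W,Y}`, surface
#' `{D,E,G,H,K,N,P,Q,R,S,T}`, boundary their union; glycine is additionally
#' allowed at loop (`L`) positions in every layer.  All sets are plain
#' character vectors and fully overridable.
#'
#' @return a list with elements `core`, `boundary`, `surface`, `glyAtLoop`.
#' @export
layerRules <- function() {
  core <- c("A", "F", "I", "L", "M", "P", "V", "W", "Y")
  surface <- c("D", "E", "G", "H", "K", "N", "P", "Q", "R", "S", "T")
  list(core = core, surface = surface,
       boundary = sort(union(core, surface)), glyAtLoop = TRUE)
}

#' Build a LayerDesign task
#'
#' Restricts the allowed amino acids at each position by burial layer (and
#' glycine by secondary structure), preventing hydrophobic residues on the
#' surface and polar residues in the core.
#'
#' @param layers a [LayerAssignment-class].
#' @param ss secondary-structure labels from [secondaryStructure()].
#' @param rules rule list as from [layerRules()].
#' @param native optional native sequence whose amino acid is always kept
#'   allowed at its own position.
#' @return a [DesignTask-class].
#' @export
layerDesignTask <- function(layers, ss, rules = layerRules(), native = NULL) {
  stopifnot(is(layers, "LayerAssignment"))
  labels <- layerLabels(layers)
  if (length(ss) != length(labels)) {
    stop("layers and secondary structure length mismatch", call. = FALSE)
  }
  L <- length(labels)
  allowed <- matrix(FALSE, L, 20L, dimnames = list(NULL, .AA20))
  for (i in seq_len(L)) {
    set <- rules[[labels[i]]]
    if (isTRUE(rules$glyAtLoop) && ss[i] == "L") set <- union(set, "G")
    if (!length(set)) stop("empty allowed set at position ", i,
                           call. = FALSE)
    allowed[i, set] <- TRUE
  }
  if (!is.null(native)) {
    nat <- .seqChars(native)
    if (length(nat) != L) stop("native length mismatch", call. = FALSE)
    allowed[cbind(seq_len(L), match(nat, .AA20))] <- TRUE
  }
  DesignTask(allowed)
}

#' Layer and secondary-structure report
#'
#' @param structure a [ProteinStructure-class].
#' @param layers a [LayerAssignment-class] for it.
#' @param ss secondary-structure labels.
#' @return data.frame with 1-based position, amino acid, SASA, layer, SS.
#' @export
layerReport <- function(structure, layers, ss) {
  data.frame(pos = seq_along(structure@aa), aa = structure@aa,
             sasa = round(residueSASA(layers), 3),
             layer = layerLabels(layers), ss = ss)
}
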