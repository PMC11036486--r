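# Single-chain protein backbone container plus PDB/FASTA I/O and the
# deterministic helix-bundle fixture generator.

.AA_321 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
             GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
             MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
             SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")
.AA_123 <- setNames(names(.AA_321), unname(.AA_321))

#' ProteinStructure: a single-chain backbone with sequence
#'
#' Holds backbone coordinates (N, CA, C, O and, for every residue except
#' glycine, CB) and the amino-acid sequence of one protein chain.  Backbones
#' are taken as-is; no relaxation or rebuilding is performed on user input.
#'
#' @slot chainId single chain identifier.
#' @slot resno integer residue numbers (1-based in all files and reports).
#' @slot aa character vector of one-letter amino-acid codes, one per residue.
#' @slot coords named list of L x 3 coordinate matrices in Angstrom for atoms
#'   `N`, `CA`, `C`, `O`, `CB`; the CB row of a glycine is `NA`.
#'
#' @seealso [readPDB()], [writePDB()], [makeFixture()]
#' @export
setClass("ProteinStructure",
  representation(chainId = "character", resno = "integer",
                 aa = "character", coords = "list"))

setValidity("ProteinStructure", function(object) {
  L <- length(object@aa)
  msg <- character()
  if (length(object@chainId) != 1L) msg <- c(msg, "chainId must be length 1")
  if (length(object@resno) != L) msg <- c(msg, "resno/aa length mismatch")
  if (!all(object@aa %in% .AA20)) msg <- c(msg, "non-canonical amino acid code")
  need <- c("N", "CA", "C", "O", "CB")
  if (!all(need %in% names(object@coords))) {
    msg <- c(msg, "coords must contain N, CA, C, O, CB")
  } else {
    for (atom in need) {
      m <- object@coords[[atom]]
      if (!is.matrix(m) || nrow(m) != L || ncol(m) != 3L) {
        msg <- c(msg, sprintf("coords$%s must be an L x 3 matrix", atom))
        next
      }
      if (atom == "CB") {
        gly <- object@aa == "G"
        if (any(gly) && !all(is.na(m[gly, , drop = FALSE]))) {
          msg <- c(msg, "glycine must not carry a CB record")
        }
        if (any(!gly) && !all(is.finite(m[!gly, , drop = FALSE]))) {
          msg <- c(msg, "missing or non-finite CB on a non-Gly residue")
        }
      } else if (!all(is.finite(m))) {
        msg <- c(msg, sprintf("non-finite %s coordinates", atom))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param chainId,resno,aa,coords see the corresponding slots.
#' @rdname ProteinStructure-class
#' @export
ProteinStructure <- function(chainId, resno, aa, coords) {
  obj <- new("ProteinStructure", chainId = as.character(chainId),
             resno = as.integer(resno), aa = as.character(aa),
             coords = coords)
  validObject(obj)
  obj
}

#' @describeIn ProteinStructure-class number of residues.
#' @param x,object a `ProteinStructure`.
#' @export
setMethod("length", "ProteinStructure", function(x) length(x@aa))

#' Accessors for ProteinStructure
#'
#' `chainSequence` returns the one-letter sequence as a single string,
#' `residueNumbers` the residue numbering, `chainId` the chain identifier and
#' `atomCoords` the L x 3 coordinate matrix of one backbone atom.
#'
#' @param x a [ProteinStructure-class].
#' @param atom one of `"N"`, `"CA"`, `"C"`, `"O"`, `"CB"`.
#' @return see individual descriptions.
#' @export
chainSequence <- function(x) paste(x@aa, collapse = "")

#' @rdname chainSequence
#' @export
residueNumbers <- function(x) x@resno

#' @rdname chainSequence
#' @export
chainId <- function(x) x@chainId

#' @rdname chainSequence
#' @export
atomCoords <- function(x, atom = "CA") {
  atom <- match.arg(atom, c("N", "CA", "C", "O", "CB"))
  x@coords[[atom]]
}

setMethod("show", "ProteinStructure", function(object) {
  L <- length(object@aa)
  cat("ProteinStructure, chain '", object@chainId, "', ", L, " residues\n",
      sep = "")
  s <- chainSequence(object)
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  sequence: ", s, "\n", sep = "")
})

# ---------------------------------------------------------------------------
# PDB I/O (ATOM records only, via bio3d for parsing)

#' Read a single protein chain from a PDB file
#'
#' Parses ATOM records of a PDB file and returns one chain as a
#' [ProteinStructure-class].  Residues must carry complete N, CA, C, O
#' records and a CB for every non-glycine residue; incomplete or
#' non-canonical residues raise an error rather than being dropped silently.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier to extract; default the first chain in file
#'   order (multi-chain files require an explicit choice only when the first
#'   chain is not wanted).
#' @return a [ProteinStructure-class].
#' @export
readPDB <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("not a parsable PDB file: ", path,
                                           call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path, call. = FALSE)
  at$chain[is.na(at$chain)] <- " "
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop("no parsable chain '", chain, "' in ", path,
                      call. = FALSE)
  key <- paste(at$resno, at$insert)
  resKeys <- unique(key)
  L <- length(resKeys)
  if (L < 2L) stop("chain '", chain, "' has fewer than 2 residues",
                   call. = FALSE)
  aa <- character(L)
  resno <- integer(L)
  coords <- lapply(setNames(nm = c("N", "CA", "C", "O", "CB")),
                   function(a) matrix(NA_real_, L, 3L))
  for (i in seq_len(L)) {
    rows <- at[key == resKeys[i], , drop = FALSE]
    code3 <- rows$resid[1L]
    if (!code3 %in% names(.AA_321)) {
      stop("non-canonical residue '", code3, "' at position ", i,
           " (residue number ", rows$resno[1L], ")", call. = FALSE)
    }
    aa[i] <- .AA_321[[code3]]
    resno[i] <- rows$resno[1L]
    for (atom in c("N", "CA", "C", "O")) {
      hit <- which(rows$elety == atom)
      if (!length(hit)) {
        stop("incomplete backbone: residue ", rows$resno[1L], " (", code3,
             ") lacks atom ", atom, call. = FALSE)
      }
      coords[[atom]][i, ] <- as.numeric(rows[hit[1L], c("x", "y", "z")])
    }
    if (aa[i] != "G") {
      hit <- which(rows$elety == "CB")
      if (!length(hit)) {
        stop("missing CB on non-Gly residue ", rows$resno[1L], " (", code3,
             ")", call. = FALSE)
      }
      coords[["CB"]][i, ] <- as.numeric(rows[hit[1L], c("x", "y", "z")])
    }
  }
  ProteinStructure(chain, resno, aa, coords)
}

#' Write a ProteinStructure as a PDB file
#'
#' Emits plain ATOM records (plus TER/END) at standard PDB precision
#' (3 decimals on coordinates), so `readPDB(writePDB(x))` reproduces
#' coordinates exactly at that precision.
#'
#' @param x a [ProteinStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
  stopifnot(is(x, "ProteinStructure"))
  lines <- character()
  serial <- 0L
  elem <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  for (i in seq_along(x@aa)) {
    atoms <- if (x@aa[i] == "G") c("N", "CA", "C", "O") else
      c("N", "CA", "C", "O", "CB")
    for (atom in atoms) {
      serial <- serial + 1L
      xyz <- x@coords[[atom]][i, ]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", atom), " ", .AA_123[[x@aa[i]]], x@chainId,
        x@resno[i], " ", xyz[1L], xyz[2L], xyz[3L], 1, 0, elem[[atom]]))
    }
  }
  lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", serial + 1L,
                            .AA_123[[x@aa[length(x@aa)]]], x@chainId,
                            x@resno[length(x@resno)]), "END")
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA I/O (Biostrings behind a thin validated wrapper)

#' Read and write FASTA files
#'
#' `writeFastaFile` writes a named character vector of sequences (names are
#' record ids) wrapped at 80 columns; `readFastaFile` reads one back,
#' uppercasing lowercase letters.  Round trips preserve record order.
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return `readFastaFile` returns a named character vector.
#' @export
writeFastaFile <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every sequence needs a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(seqs))) stop("empty sequence for id ",
                               ids[!nzchar(seqs)][1L], call. = FALSE)
  set <- Biostrings::AAStringSet(unname(toupper(seqs)))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' @rdname writeFastaFile
#' @export
readFastaFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  setNames(toupper(as.character(set)), names(set))
}

# ---------------------------------------------------------------------------
# Deterministic helix-bundle fixture

# Turn dihedrals (phi/psi for 3 residues) chosen once by numeric search so a
# continuous ideal-geometry chain folds into an approximately antiparallel
# bundle with ~10 A axis spacing and no steric clash; frozen constants.
.TURN_PHI <- c(81.367905, 12.743043, 5.832018)
.TURN_PSI <- c(187.732156, -89.506122, 69.298716)
.HELIX_PHI <- -57
.HELIX_PSI <- -47

# layer-conditioned Dirichlet base compositions for the ground-truth profile
.LAYER_BASE <- local({
  core <- c(A = 2, C = 0.5, D = 0.15, E = 0.15, F = 2, G = 0.4, H = 0.25,
            I = 3, K = 0.15, L = 3, M = 1.5, N = 0.25, P = 0.25, Q = 0.25,
            R = 0.15, S = 0.4, T = 0.4, V = 3, W = 1, Y = 1)
  surface <- c(A = 1, C = 0.2, D = 2.5, E = 3, F = 0.2, G = 1, H = 0.8,
               I = 0.25, K = 3, L = 0.3, M = 0.2, N = 1.5, P = 0.8,
               Q = 1.5, R = 2.5, S = 1.5, T = 1.5, V = 0.3, W = 0.15,
               Y = 0.4)
  list(core = core / sum(core), surface = surface / sum(surface),
       boundary = (core / sum(core) + surface / sum(surface)) / 2)
})

# evaluate expr with a private RNG state seeded at seed
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha  # guard against all-zero draws
  g / sum(g)
}

#' Generate a deterministic helix-bundle test system
#'
#' Builds an ideal alpha-helical bundle backbone (phi = -57, psi = -47,
#' ideal bond geometry, continuous chain with fixed turn dihedrals giving an
#' approximately antiparallel bundle at ~10 Angstrom helix spacing, CB placed
#' by ideal tetrahedral geometry) together with a layer-aware ground-truth
#' probability profile.  The native sequence is sampled from that profile:
#' each row is a Dirichlet draw centred on a hydrophobic-enriched composition
#' for buried positions and a polar-enriched composition for exposed ones.
#' Fully deterministic in `seed`.
#'
#' @param nHelices number of helices, 2 to 4.
#' @param helixLen residues per helix, at least 8 (the last two residues of a
#'   helix and the first of the next form the connecting turn).
#' @param seed integer seed controlling profile and native sequence.
#' @param concentration total Dirichlet concentration per row; larger values
#'   give rows closer to the layer base composition.
#' @return a list with elements `structure` ([ProteinStructure-class]) and
#'   `profile` ([ProbabilityMatrix-class], the ground-truth profile).
#' @export
#' @examples
#' fx <- makeFixture(2, 12, seed = 1)
#' fx$structure
makeFixture <- function(nHelices, helixLen, seed, concentration = 25) {
  if (!(nHelices %in% 2:4)) stop("nHelices must be in 2..4", call. = FALSE)
  if (helixLen < 8) stop("helixLen must be >= 8", call. = FALSE)
  L <- nHelices * helixLen
  phi <- rep(.HELIX_PHI, L)
  psi <- rep(.HELIX_PSI, L)
  for (h in seq_len(nHelices - 1L)) {
    idx <- (h * helixLen - 1L):(h * helixLen + 1L)
    phi[idx] <- .TURN_PHI
    psi[idx] <- .TURN_PSI
  }
  bb <- .buildBackbone(phi, psi)
  CB <- t(vapply(seq_len(L), function(i) {
    .cbFromBackbone(bb$N[i, ], bb$CA[i, ], bb$C[i, ])
  }, numeric(3L)))
  coords <- list(N = bb$N, CA = bb$CA, C = bb$C, O = bb$O, CB = CB)

  # burial from backbone+CB solvent accessibility of the bare backbone
  tmp <- ProteinStructure("A", seq_len(L), rep("A", L), coords)
  sasa <- shrakeRupleySASA(tmp)
  layers <- classifyLayers(sasa)

  .withSeed(seed, {
    probs <- t(vapply(seq_len(L), function(i) {
      base <- .LAYER_BASE[[layerLabels(layers)[i]]]
      .rdirichlet1(base * concentration)
    }, numeric(20L)))
    colnames(probs) <- .AA20
    native <- vapply(seq_len(L), function(i) {
      sample(.AA20, 1L, prob = probs[i, ])
    }, character(1L))
    coords$CB[native == "G", ] <- NA_real_
    list(
      structure = ProteinStructure("A", seq_len(L), native, coords),
      profile = ProbabilityMatrix(probs, provenance = sprintf(
        "fixture nHelices=%d helixLen=%d seed=%d", nHelices, helixLen, seed)))
  })
}
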