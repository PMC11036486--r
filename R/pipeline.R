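# End-to-end protocols: fixbb, layerdesign and the two-round restrained
# workflow, with YAML run configs, deterministic seeding and scorefiles.

#' RunConfig: parameters of one design run
#'
#' Holds everything a protocol run needs.  The input backbone is either a
#' PDB path (`structurePath`) or a fixture specification (`fixture`, a list
#' with `nHelices`, `helixLen`, `seed`).  Per-design seeds are derived
#' deterministically from the master seed as `masterSeed + i`.  Configs
#' round-trip losslessly through YAML via [writeRunConfig()] /
#' [readRunConfig()].
#'
#' @slot structurePath PDB path, or `NA` when a fixture is used.
#' @slot fixture list(nHelices, helixLen, seed), or empty list.
#' @slot protocol `"fixbb"`, `"layerdesign"` or `"esm_restrained"`.
#' @slot nDesigns designs per round (default 1000).
#' @slot providerCoupling coupling strength of the synthetic provider.
#' @slot providerSeed seed of the synthetic provider's coupling table.
#' @slot profilePath optional PSPM TSV giving the provider profile (for
#'   PDB inputs, where no ground-truth fixture profile exists).
#' @slot restraintWeight weight of the profile restraint (stage 2).
#' @slot profileMode `"logodds"`, `"prob"` or `"global"`.
#' @slot profileScale scale of the profile in logodds mode.
#' @slot tStart,tEnd,nSweeps annealing schedule parameters.
#' @slot masterSeed master seed.
#' @slot outputDir output directory.
#' @export
setClass("RunConfig",
  representation(structurePath = "character", fixture = "list",
                 protocol = "character", nDesigns = "integer",
                 providerCoupling = "numeric", providerSeed = "integer",
                 profilePath = "character", restraintWeight = "numeric",
                 profileMode = "character", profileScale = "numeric",
                 tStart = "numeric", tEnd = "numeric", nSweeps = "integer",
                 masterSeed = "integer", outputDir = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!object@protocol %in% c("fixbb", "layerdesign", "esm_restrained")) {
    msg <- c(msg, "unknown protocol")
  }
  if (object@nDesigns < 1L) msg <- c(msg, "nDesigns must be >= 1")
  if (is.na(object@structurePath) && !length(object@fixture)) {
    msg <- c(msg, "either structurePath or fixture must be given")
  }
  if (length(object@fixture) &&
      !all(c("nHelices", "helixLen", "seed") %in% names(object@fixture))) {
    msg <- c(msg, "fixture needs nHelices, helixLen, seed")
  }
  if (object@providerCoupling < 0) msg <- c(msg, "providerCoupling < 0")
  if (object@restraintWeight < 0) msg <- c(msg, "restraintWeight < 0")
  if (length(msg)) msg else TRUE
})

#' @param structurePath,fixture,protocol,nDesigns,providerCoupling
#'   see slots.
#' @param providerSeed,profilePath,restraintWeight,profileMode,profileScale
#'   see slots.
#' @param tStart,tEnd,nSweeps,masterSeed,outputDir see slots.
#' @rdname RunConfig-class
#' @export
runConfig <- function(structurePath = NA_character_, fixture = list(),
                      protocol = "fixbb", nDesigns = 1000L,
                      providerCoupling = 0.5, providerSeed = 7L,
                      profilePath = NA_character_, restraintWeight = 1,
                      profileMode = "logodds", profileScale = 1,
                      tStart = 3, tEnd = 0.3, nSweeps = 100L,
                      masterSeed = 1L, outputDir = "pspmdesign_run") {
  obj <- new("RunConfig", structurePath = as.character(structurePath),
             fixture = fixture, protocol = protocol,
             nDesigns = as.integer(nDesigns),
             providerCoupling = as.numeric(providerCoupling),
             providerSeed = as.integer(providerSeed),
             profilePath = as.character(profilePath),
             restraintWeight = as.numeric(restraintWeight),
             profileMode = profileMode,
             profileScale = as.numeric(profileScale),
             tStart = as.numeric(tStart), tEnd = as.numeric(tEnd),
             nSweeps = as.integer(nSweeps),
             masterSeed = as.integer(masterSeed),
             outputDir = as.character(outputDir))
  validObject(obj)
  obj
}

setMethod("show", "RunConfig", function(object) {
  src <- if (is.na(object@structurePath)) {
    sprintf("fixture(%d x %d, seed %d)", object@fixture$nHelices,
            object@fixture$helixLen, object@fixture$seed)
  } else object@structurePath
  cat("RunConfig [", object@protocol, "]: ", object@nDesigns,
      " designs, input ", src, ", master seed ", object@masterSeed, "\n",
      sep = "")
})

.CONFIG_FIELDS <- c("structurePath", "fixture", "protocol", "nDesigns",
                    "providerCoupling", "providerSeed", "profilePath",
                    "restraintWeight", "profileMode", "profileScale",
                    "tStart", "tEnd", "nSweeps", "masterSeed", "outputDir")

#' Write and read run configs as YAML
#'
#' @param config a [RunConfig-class].
#' @param path YAML file path.
#' @return `readRunConfig` returns a [RunConfig-class].
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  lst <- lapply(setNames(nm = .CONFIG_FIELDS), function(f) slot(config, f))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lst <- yaml::read_yaml(path)
  lst <- lst[intersect(.CONFIG_FIELDS, names(lst))]
  if (is.null(lst$structurePath)) lst$structurePath <- NA_character_
  if (is.null(lst$profilePath)) lst$profilePath <- NA_character_
  if (is.null(lst$fixture)) lst$fixture <- list()
  do.call(runConfig, lst)
}

# ---------------------------------------------------------------------------
# scorefiles

#' Write and read design scorefiles
#'
#' One TSV line per design: `id`, `total`, `base`, `restraint`, `protocol`,
#' `seed`.  Energies are printed with 9 significant digits, enough to make
#' re-scoring checks meaningful while keeping files byte-stable.
#'
#' @param results list of [DesignResult-class] objects.
#' @param ids design identifiers.
#' @param path file path.
#' @return `readScorefile` returns a data.frame.
#' @export
writeScorefile <- function(results, ids, path) {
  stopifnot(length(results) == length(ids))
  lines <- c("id\ttotal\tbase\trestraint\tprotocol\tseed",
             vapply(seq_along(results), function(k) {
               r <- results[[k]]
               sprintf("%s\t%.9g\t%.9g\t%.9g\t%s\t%d", ids[k],
                       r@totalEnergy, r@baseEnergy, r@restraintEnergy,
                       r@protocol, r@seed)
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeScorefile
#' @export
readScorefile <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# protocol plumbing

.loadStructureForRun <- function(config) {
  if (!is.na(config@structurePath)) {
    list(structure = readPDB(config@structurePath), profile = NULL)
  } else {
    fx <- makeFixture(config@fixture$nHelices, config@fixture$helixLen,
                      config@fixture$seed)
    list(structure = fx$structure, profile = fx$profile)
  }
}

.buildProviderForRun <- function(config, fixtureProfile) {
  profile <- if (!is.na(config@profilePath)) {
    readPSPM(config@profilePath)
  } else fixtureProfile
  if (is.null(profile)) {
    stop(errorCondition(
      "no provider profile: give profilePath or use a fixture input",
      class = c("providerError", "error", "condition")))
  }
  makeSyntheticProvider(profile, couplingStrength = config@providerCoupling,
                        seed = config@providerSeed)
}

# run nDesigns packs with per-design seeds masterSeed + i and write
# designs.fasta + scorefile.tsv into dir
.designRound <- function(structure, contacts, model, task, restraint,
                         config, dir, protocolTag) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  native <- chainSequence(structure)
  results <- vector("list", config@nDesigns)
  for (i in seq_len(config@nDesigns)) {
    sched <- annealSchedule(tStart = config@tStart, tEnd = config@tEnd,
                            nSweeps = config@nSweeps,
                            seed = config@masterSeed + i)
    results[[i]] <- pack(contacts, model, task, restraint = restraint,
                         schedule = sched, startSequence = native,
                         protocol = protocolTag)
  }
  ids <- sprintf("design_%04d", seq_len(config@nDesigns))
  writeFastaFile(setNames(vapply(results, designedSequence, character(1L)),
                          ids), file.path(dir, "designs.fasta"))
  writeScorefile(results, ids, file.path(dir, "scorefile.tsv"))
  list(results = results, ids = ids, dir = dir)
}

.logLine <- function(con, ...) cat(paste0(..., "\n"), file = con,
                                   append = TRUE)

#' Run the unrestrained fixed-backbone protocol
#'
#' Designs `nDesigns` sequences with the full alphabet available at every
#' position, each from an independent seed (`masterSeed + i`), and writes
#' `designs.fasta` and `scorefile.tsv` into the output directory.
#'
#' @param config a [RunConfig-class].
#' @return invisibly, a list with `structure`, `results` (list of
#'   [DesignResult-class]), `ids` and `dir`.
#' @export
runFixbb <- function(config) {
  inp <- .loadStructureForRun(config)
  model <- defaultEnergyModel()
  contacts <- contactMap(inp$structure, model)
  task <- fullAlphabetTask(length(inp$structure))
  round <- .designRound(inp$structure, contacts, model, task, NULL, config,
                        config@outputDir, "fixbb")
  invisible(c(list(structure = inp$structure), round))
}

#' Run the layer-design protocol
#'
#' As [runFixbb()], but the allowed amino acids at each position are
#' restricted by burial layer and secondary structure via
#' [layerDesignTask()].
#'
#' @param config a [RunConfig-class].
#' @return invisibly, as [runFixbb()], plus `task`.
#' @export
runLayerDesign <- function(config) {
  inp <- .loadStructureForRun(config)
  model <- defaultEnergyModel()
  contacts <- contactMap(inp$structure, model)
  layers <- classifyLayers(shrakeRupleySASA(inp$structure))
  ss <- secondaryStructure(inp$structure)
  task <- layerDesignTask(layers, ss)
  round <- .designRound(inp$structure, contacts, model, task, NULL, config,
                        config@outputDir, "layerdesign")
  invisible(c(list(structure = inp$structure, task = task), round))
}

#' Run the two-round restrained design workflow
#'
#' Stage 1 is an unrestrained fixed-backbone round.  The top-scoring
#' (lowest total energy) stage-1 design is then queried against the
#' masked-prediction provider to build a PSPM, which is converted into a
#' sequence-profile restraint; stage 2 redesigns `nDesigns` sequences under
#' base energy plus that fixed restraint, reusing the stage-1 seeds so that
#' a zero restraint weight reproduces stage 1 exactly.  The PSPM is computed
#' once and never updated during stage-2 trajectories.
#'
#' The run directory always contains `stage1/` (designs + scorefile),
#' `selected.fasta`, `pspm.tsv`, `profile.pssm`, `stage2/` and `run.log`
#' with the config hash.
#'
#' @param config a [RunConfig-class].
#' @return invisibly, a list with `structure`, `stage1`, `stage2`, `pspm`,
#'   `profile`, `selected` (the stage-1 sequence used for prediction) and
#'   `dir`.
#' @export
runEsmRestrained <- function(config) {
  inp <- .loadStructureForRun(config)
  out <- config@outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfgPath <- file.path(out, "config.yaml")
  writeRunConfig(config, cfgPath)
  logPath <- file.path(out, "run.log")
  cat("", file = logPath)
  .logLine(logPath, "run: esm_restrained")
  .logLine(logPath, "config_md5: ", unname(tools::md5sum(cfgPath)))

  model <- defaultEnergyModel()
  contacts <- contactMap(inp$structure, model)
  task <- fullAlphabetTask(length(inp$structure))

  t0 <- proc.time()[["elapsed"]]
  stage1 <- .designRound(inp$structure, contacts, model, task, NULL, config,
                         file.path(out, "stage1"), "fixbb")
  .logLine(logPath, sprintf("stage1: %d designs in %.2f s", config@nDesigns,
                            proc.time()[["elapsed"]] - t0))

  totals <- vapply(stage1$results, function(r) r@totalEnergy, numeric(1L))
  bestIdx <- which.min(totals)
  selected <- designedSequence(stage1$results[[bestIdx]])
  writeFastaFile(setNames(selected, stage1$ids[bestIdx]),
                 file.path(out, "selected.fasta"))
  .logLine(logPath, "selected: ", stage1$ids[bestIdx],
           sprintf(" (total %.6f)", totals[bestIdx]))

  provider <- .buildProviderForRun(config, inp$profile)
  t1 <- proc.time()[["elapsed"]]
  pspm <- tryCatch(maskedMarginals(provider, selected),
                   error = function(e) {
                     stop(errorCondition(
                       paste0("provider failure during PSPM prediction: ",
                              conditionMessage(e)),
                       class = c("providerError", "error", "condition")))
                   })
  writePSPM(pspm, file.path(out, "pspm.tsv"))
  writePSSM(pspm, file.path(out, "profile.pssm"), refSequence = selected)
  .logLine(logPath, sprintf("pspm: %d positions in %.2f s", length(pspm),
                            proc.time()[["elapsed"]] - t1))

  profile <- pspmToProfile(pspm, mode = config@profileMode,
                           scale = config@profileScale)
  restraint <- RestraintConfig(profile, weight = config@restraintWeight)
  t2 <- proc.time()[["elapsed"]]
  stage2 <- .designRound(inp$structure, contacts, model, task, restraint,
                         config, file.path(out, "stage2"), "esm_restrained")
  .logLine(logPath, sprintf("stage2: %d designs in %.2f s", config@nDesigns,
                            proc.time()[["elapsed"]] - t2))

  invisible(list(structure = inp$structure, stage1 = stage1,
                 stage2 = stage2, pspm = pspm, profile = profile,
                 selected = selected, dir = out))
}
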