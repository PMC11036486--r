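# Shared in-code fixtures for the test suite; everything is generated at
# test time, nothing is read from disk.

# random valid PSPM with Gamma-sampled rows
randomPSPM <- function(L, seed) {
  set.seed(seed)
  m <- matrix(rgamma(L * 20L, shape = 1), L, 20L)
  ProbabilityMatrix(m / rowSums(m))
}

# PSPM whose row i puts probability p[i] on the realized residue of seq and
# spreads the rest uniformly
realizedPSPM <- function(seq, p) {
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, aminoAcids())
  m <- matrix((1 - p) / 19, length(idx), 20L)
  m[cbind(seq_along(idx), idx)] <- p
  ProbabilityMatrix(m / rowSums(m))
}

# random toy design instance on 3 positions (the only eligible contact for
# L = 3 under |i - j| >= 2 is (1, 3); present with probability pContact)
randomToyInstance <- function(seed, pContact = 0.5) {
  set.seed(seed)
  u <- matrix(rnorm(400), 20L, 20L)
  model <- EnergyModel((u + t(u)) / 2, rnorm(20))
  contacts <- if (runif(1) < pContact) {
    matrix(c(1L, 3L), 1L, 2L)
  } else {
    matrix(integer(0), 0L, 2L)
  }
  list(model = model, contacts = contacts, task = fullAlphabetTask(3L))
}

# single ideal helix as a ProteinStructure (fully solvent-exposed)
singleHelixStructure <- function(L = 18L, aa = rep("A", L)) {
  bb <- pspmdesign:::.buildBackbone(rep(-57, L), rep(-47, L))
  cb <- t(vapply(seq_len(L), function(i) {
    pspmdesign:::.cbFromBackbone(bb$N[i, ], bb$CA[i, ], bb$C[i, ])
  }, numeric(3)))
  cb[aa == "G", ] <- NA_real_
  ProteinStructure("A", seq_len(L), aa,
                   list(N = bb$N, CA = bb$CA, C = bb$C, O = bb$O, CB = cb))
}

# small run config on a fixture bundle
fixtureRunConfig <- function(outDir, protocol = "fixbb", nDesigns = 3L,
                             masterSeed = 11L, restraintWeight = 1,
                             nSweeps = 100L) {
  runConfig(fixture = list(nHelices = 3L, helixLen = 14L, seed = 5L),
            protocol = protocol, nDesigns = nDesigns,
            providerCoupling = 0.5, providerSeed = 7L,
            restraintWeight = restraintWeight, nSweeps = nSweeps,
            masterSeed = masterSeed, outputDir = outDir)
}
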