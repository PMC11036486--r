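# Base energy, contact maps, SASA quadrature, layers, secondary structure,
# layer-design tasks.

test_that("base energy sums contact potentials and reference energies", {
  zero <- EnergyModel(matrix(0, 20, 20), rep(0, 20))
  expect_equal(baseEnergy("ACDE", matrix(integer(0), 0, 2), zero), 0)

  set.seed(2)
  u <- matrix(rnorm(400), 20); u <- (u + t(u)) / 2
  refs <- rnorm(20)
  m <- EnergyModel(u, refs)
  aa <- aminoAcids()
  e <- baseEnergy("AWA", matrix(c(1L, 3L), 1), m)
  expect_equal(e, u[match("A", aa), match("A", aa)] +
                 2 * refs[match("A", aa)] + refs[match("W", aa)],
               tolerance = 1e-12)
  expect_error(baseEnergy("AW", matrix(c(1L, 3L), 1), m), "out of range")
})

test_that("base energy matches a double-loop oracle and ignores pair order", {
  set.seed(5)
  u <- matrix(rnorm(400), 20); u <- (u + t(u)) / 2
  refs <- rnorm(20)
  m <- EnergyModel(u, refs)
  s <- sample(aminoAcids(), 5, replace = TRUE)
  contacts <- rbind(c(1L, 3L), c(1L, 4L), c(2L, 5L), c(3L, 5L))
  idx <- match(s, aminoAcids())
  oracle <- sum(refs[idx])
  for (i in 1:5) for (j in 1:5) {
    if (i < j && any(contacts[, 1] == i & contacts[, 2] == j)) {
      oracle <- oracle + u[idx[i], idx[j]]
    }
  }
  seqStr <- paste(s, collapse = "")
  expect_equal(baseEnergy(seqStr, contacts, m), oracle, tolerance = 1e-12)
  shuffled <- contacts[c(3, 1, 4, 2), ]
  expect_equal(baseEnergy(seqStr, shuffled, m),
               baseEnergy(seqStr, contacts, m))
})

test_that("contact maps respect the cutoff and sequence-separation rules", {
  fx <- makeFixture(3, 12, seed = 2)
  m <- defaultEnergyModel()
  cm <- contactMap(fx$structure, m)
  expect_true(all(cm[, 2] - cm[, 1] >= 2))
  expect_false(anyDuplicated(paste(cm[, 1], cm[, 2])) > 0)
  cb <- atomCoords(fx$structure, "CB")
  gly <- strsplit(chainSequence(fx$structure), "")[[1]] == "G"
  cb[gly, ] <- atomCoords(fx$structure, "CA")[gly, ]
  d <- sqrt(rowSums((cb[cm[, 1], , drop = FALSE] -
                       cb[cm[, 2], , drop = FALSE])^2))
  expect_true(all(d <= m@contactCutoff))
})

test_that("SASA quadrature reproduces closed-form sphere areas", {
  for (r in c(1.5, 1.7, 1.9)) {
    a <- sasaAtoms(matrix(0, 1, 3), r, probeRadius = 1.4, nPoints = 960)
    exact <- 4 * pi * (r + 1.4)^2
    expect_lt(abs(a - exact) / exact, 0.02)
  }
  # well-separated atoms are additive
  xyz <- rbind(c(0, 0, 0), c(100, 0, 0))
  a2 <- sasaAtoms(xyz, c(1.9, 1.9), nPoints = 960)
  expect_lt(abs(sum(a2) - 2 * 4 * pi * 3.3^2) / (2 * 4 * pi * 3.3^2), 0.02)
  # a fully overlapping duplicate atom leaves the total unchanged
  one <- sasaAtoms(matrix(0, 1, 3), 1.9, nPoints = 960)
  dup <- sasaAtoms(rbind(c(0, 0, 0), c(0, 0, 0)), c(1.9, 1.9),
                   nPoints = 960)
  expect_equal(sum(dup), sum(one), tolerance = 1e-9)
  expect_error(sasaAtoms(matrix(0, 1, 3), 1.5, nPoints = 16), "32")
})

test_that("adding an occluding atom never increases SASA", {
  set.seed(7)
  base <- matrix(rnorm(15, sd = 3), 5, 3)
  radii <- rep(1.7, 5)
  before <- sum(sasaAtoms(base, radii, nPoints = 480))
  for (k in 1:3) {
    extra <- rbind(base, base[1, ] + rnorm(3, sd = 1.5))
    after <- sum(sasaAtoms(extra, c(radii, 1.7), nPoints = 480)[1:5])
    expect_lte(after, before + 1e-9)
  }
})

test_that("layer classification thresholds as documented", {
  ly <- classifyLayers(c(0, 100, 20, 40, 30))
  expect_identical(layerLabels(ly),
                   c("core", "surface", "core", "surface", "boundary"))
  expect_error(classifyLayers(c(10, 20), coreCut = 50, surfCut = 40),
               "coreCut")
  expect_error(classifyLayers(c(-1, 5)), "nonnegative")
})

test_that("fixture bundles with >= 3 helices have both core and surface residues", {
  for (seed in c(2L, 9L)) {
    fx <- makeFixture(3, 14, seed = seed)
    ly <- classifyLayers(shrakeRupleySASA(fx$structure))
    expect_gte(sum(layerLabels(ly) == "core"), 1)
    expect_gte(sum(layerLabels(ly) == "surface"), 1)
  }
})

test_that("secondary structure assignment finds helices and demotes short runs", {
  fx <- makeFixture(2, 12, seed = 1)
  ss <- secondaryStructure(fx$structure)
  # interior residues of each helix segment are H, termini L
  expect_identical(ss[1], "L")
  expect_identical(ss[length(ss)], "L")
  expect_true(all(ss[3:9] == "H"))
  expect_true(all(ss[16:21] == "H"))

  tiny <- singleHelixStructure(3L)
  expect_identical(secondaryStructure(tiny), c("L", "L", "L"))

  # alternating helix/other dihedrals: no H or E run of < 3 survives
  L <- 12L
  phi <- rep(c(-57, 60), 6)
  psi <- rep(c(-47, 60), 6)
  bb <- pspmdesign:::.buildBackbone(phi, psi)
  cb <- t(vapply(seq_len(L), function(i) {
    pspmdesign:::.cbFromBackbone(bb$N[i, ], bb$CA[i, ], bb$C[i, ])
  }, numeric(3)))
  st <- ProteinStructure("A", seq_len(L), rep("A", L),
                         list(N = bb$N, CA = bb$CA, C = bb$C, O = bb$O,
                              CB = cb))
  ssAlt <- secondaryStructure(st)
  r <- rle(ssAlt)
  expect_true(all(r$lengths[r$values %in% c("H", "E")] >= 3))
})

test_that("layer-design rules restrict the alphabet as documented", {
  rules <- layerRules()
  ly <- classifyLayers(c(5, 30, 80))   # core, boundary, surface
  task <- layerDesignTask(ly, c("H", "H", "H"))
  al <- allowedMatrix(task)
  expect_false(al[3, "W"])                       # no Trp on a surface helix
  expect_false(al[1, "K"])                       # no Lys in a core helix
  expect_identical(sort(aminoAcids()[al[2, ]]),  # boundary = union of sets
                   sort(union(rules$core, rules$surface)))
  # Gly additionally allowed at loop positions in all layers
  taskL <- layerDesignTask(ly, c("L", "L", "L"))
  expect_true(all(allowedMatrix(taskL)[, "G"]))
  expect_false(al[1, "G"])
  # include-native keeps the native residue available
  taskN <- layerDesignTask(ly, c("H", "H", "H"), native = "KAW")
  expect_true(allowedMatrix(taskN)[1, "K"])
  expect_true(allowedMatrix(taskN)[3, "W"])
})

test_that("the default energy model is symmetric with finite entries", {
  m <- defaultEnergyModel()
  cp <- m@contactPotential
  expect_lte(max(abs(cp - t(cp))), 1e-12)
  expect_true(all(is.finite(cp)))
  # hydrophobic burial: Ile-Ile contacts are favourable, Lys-Lys are not
  aa <- aminoAcids()
  expect_lt(cp[match("I", aa), match("I", aa)],
            cp[match("K", aa), match("K", aa)])
})
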