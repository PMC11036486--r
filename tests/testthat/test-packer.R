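# Simulated-annealing packer and the exhaustive oracle.

test_that("a fully constrained task returns the forced sequence with no moves", {
  allowed <- matrix(FALSE, 4, 20, dimnames = list(NULL, aminoAcids()))
  forced <- c("A", "W", "K", "G")
  allowed[cbind(1:4, match(forced, aminoAcids()))] <- TRUE
  task <- DesignTask(allowed)
  m <- defaultEnergyModel()
  r <- pack(matrix(c(1L, 3L), 1), m, task,
            schedule = annealSchedule(seed = 3), startSequence = "AAAA")
  expect_identical(designedSequence(r), "AWKG")
  expect_identical(r@acceptedMoves, 0)
})

test_that("packing is deterministic for a fixed seed", {
  inst <- randomToyInstance(77, pContact = 1)
  r1 <- pack(inst$contacts, inst$model, inst$task,
             schedule = annealSchedule(seed = 5), startSequence = "AAA")
  r2 <- pack(inst$contacts, inst$model, inst$task,
             schedule = annealSchedule(seed = 5), startSequence = "AAA")
  expect_identical(designedSequence(r1), designedSequence(r2))
  expect_identical(designEnergies(r1), designEnergies(r2))
  r3 <- pack(inst$contacts, inst$model, inst$task,
             schedule = annealSchedule(seed = 6), startSequence = "AAA")
  expect_false(identical(r1@acceptedMoves, r3@acceptedMoves) &&
                 identical(designedSequence(r1), designedSequence(r3)))
})

test_that("reported energies match a from-scratch recomputation", {
  fx <- makeFixture(2, 12, seed = 8)
  model <- defaultEnergyModel()
  cm <- contactMap(fx$structure, model)
  task <- fullAlphabetTask(length(fx$structure))
  restraint <- RestraintConfig(pspmToProfile(fx$profile), weight = 1.5)
  r <- pack(cm, model, task, restraint = restraint,
            schedule = annealSchedule(seed = 21),
            startSequence = chainSequence(fx$structure))
  s <- designedSequence(r)
  expect_equal(r@baseEnergy, baseEnergy(s, cm, model), tolerance = 1e-9)
  expect_equal(r@restraintEnergy,
               restraintEnergy(restraint@profile, s, w = 1.5),
               tolerance = 1e-9)
  expect_equal(r@totalEnergy, r@baseEnergy + r@restraintEnergy,
               tolerance = 1e-9)
})

test_that("a near-zero-temperature schedule never accepts an uphill move", {
  inst <- randomToyInstance(31, pContact = 1)
  r <- pack(inst$contacts, inst$model, inst$task,
            schedule = greedySchedule(nSweeps = 200, seed = 9),
            startSequence = "AAA", trace = TRUE)
  tr <- attr(r, "trace")
  expect_true(all(tr$dE[tr$accepted == 1] <= 0))
})

test_that("the annealer matches the exhaustive oracle given enough sweeps", {
  ok <- 0
  n <- 40
  for (t in seq_len(n)) {
    inst <- randomToyInstance(5000 + t)
    bf <- bruteForceDesign(inst$contacts, inst$model, inst$task)
    sa <- pack(inst$contacts, inst$model, inst$task,
               schedule = annealSchedule(nSweeps = 500, seed = t),
               startSequence = "AAA")
    if (abs(sa@totalEnergy - bf@totalEnergy) < 1e-9) ok <- ok + 1
  }
  expect_gte(ok, ceiling(0.95 * n))
})

test_that("zero restraint weight reproduces the unrestrained trajectory move for move", {
  fx <- makeFixture(2, 10, seed = 2)
  model <- defaultEnergyModel()
  cm <- contactMap(fx$structure, model)
  task <- fullAlphabetTask(length(fx$structure))
  w0 <- RestraintConfig(pspmToProfile(fx$profile), weight = 0)
  a <- pack(cm, model, task, restraint = NULL,
            schedule = annealSchedule(seed = 4),
            startSequence = chainSequence(fx$structure), trace = TRUE)
  b <- pack(cm, model, task, restraint = w0,
            schedule = annealSchedule(seed = 4),
            startSequence = chainSequence(fx$structure), trace = TRUE)
  expect_identical(attr(a, "trace"), attr(b, "trace"))
  expect_identical(designedSequence(a), designedSequence(b))
})

test_that("the restraint score of the design is nondecreasing in the weight", {
  pm <- randomPSPM(6, seed = 66)
  profile <- pspmToProfile(pm)
  flat <- EnergyModel(matrix(0, 20, 20), rep(0, 20))
  task <- fullAlphabetTask(6)
  sc <- profileScores(profile)
  prev <- -Inf
  for (w in c(0, 1, 10, 100)) {
    r <- pack(matrix(integer(0), 0, 2), flat, task,
              restraint = RestraintConfig(profile, weight = w),
              schedule = annealSchedule(seed = 12),
              startSequence = "AAAAAA")
    idx <- match(strsplit(designedSequence(r), "")[[1]], aminoAcids())
    score <- sum(sc[cbind(1:6, idx)])
    expect_gte(score, prev - 1e-12)
    prev <- score
  }
})

test_that("start sequences violating the task are projected to the nearest allowed", {
  allowed <- matrix(FALSE, 2, 20, dimnames = list(NULL, aminoAcids()))
  allowed[1, c("D", "K")] <- TRUE   # E (index 4) is closer to D (3) than K (9)
  allowed[2, "W"] <- TRUE
  task <- DesignTask(allowed)
  flat <- EnergyModel(matrix(0, 20, 20), rep(0, 20))
  r <- pack(matrix(integer(0), 0, 2), flat, task,
            schedule = greedySchedule(nSweeps = 1, seed = 1),
            startSequence = "EA")
  expect_identical(substr(designedSequence(r), 2, 2), "W")
  expect_true(substr(designedSequence(r), 1, 1) %in% c("D", "K"))
})

test_that("the exhaustive oracle handles its documented cases", {
  set.seed(3)
  refs <- rnorm(20)
  m <- EnergyModel(matrix(0, 20, 20), refs)
  bf <- bruteForceDesign(matrix(integer(0), 0, 2), m, fullAlphabetTask(1))
  expect_identical(designedSequence(bf), aminoAcids()[which.min(refs)])

  # dominant restraint forces the per-position profile argmax
  pm <- randomPSPM(3, seed = 21)
  flat <- EnergyModel(matrix(0, 20, 20), rep(0, 20))
  bf2 <- bruteForceDesign(matrix(integer(0), 0, 2), flat, fullAlphabetTask(3),
                          restraint = RestraintConfig(pspmToProfile(pm),
                                                      weight = 1e6))
  argmax <- paste(aminoAcids()[apply(probs(pm), 1, which.max)], collapse = "")
  expect_identical(designedSequence(bf2), argmax)

  # 2 positions, 1 contact: independent 400-cell table scan
  set.seed(8)
  u <- matrix(rnorm(400), 20); u <- (u + t(u)) / 2
  refs2 <- rnorm(20)
  m2 <- EnergyModel(u, refs2)
  bf3 <- bruteForceDesign(matrix(c(1L, 2L), 1), m2, fullAlphabetTask(2))
  grid <- outer(seq_len(20), seq_len(20),
                function(i, j) refs2[i] + refs2[j] + u[cbind(i, j)])
  hits <- which(grid == min(grid), arr.ind = TRUE)
  cand <- sort(apply(hits, 1, function(h) {
    paste0(aminoAcids()[h[1]], aminoAcids()[h[2]])
  }))
  expect_identical(designedSequence(bf3), cand[1])
  expect_equal(bf3@totalEnergy, min(grid), tolerance = 1e-12)

  # enumeration guard
  expect_error(bruteForceDesign(matrix(integer(0), 0, 2), m,
                                fullAlphabetTask(8)), "maxStates")
})

test_that("oracle ties break toward the lexicographically smaller sequence", {
  allowed <- matrix(FALSE, 2, 20, dimnames = list(NULL, aminoAcids()))
  allowed[, c("A", "C")] <- TRUE
  flat <- EnergyModel(matrix(0, 20, 20), rep(0, 20))
  bf <- bruteForceDesign(matrix(integer(0), 0, 2), flat, DesignTask(allowed))
  expect_identical(designedSequence(bf), "AA")
})
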