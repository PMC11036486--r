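# Worst-position audit, replacement grids, recovery, normalization,
# correlations.

test_that("worst positions are the k lowest realized probabilities in order", {
  # realized probability of position i is 0.01 * i (1-based)
  L <- 12
  seq <- paste(rep("A", L), collapse = "")
  m <- matrix(0, L, 20)
  for (i in seq_len(L)) {
    p <- 0.01 * i
    m[i, ] <- (1 - p) / 19
    m[i, 1] <- p
  }
  pm <- ProbabilityMatrix(m / rowSums(m))
  rec <- worstPositions(seq, pm, k = 10)
  expect_identical(rec$position, 1:10)
  expect_equal(rec$probability, 0.01 * (1:10), tolerance = 1e-12)
  # sort-based oracle
  realized <- m[cbind(seq_len(L), 1)]
  expect_identical(rec$position, order(realized)[1:10])
})

test_that("k equal to the length returns every position exactly once", {
  pm <- randomPSPM(7, seed = 3)
  rec <- worstPositions("ACDEFGH", pm, k = 7)
  expect_identical(sort(rec$position), 1:7)
  expect_warning(worstPositions("ACDEFGH", pm, k = 10), "only")
})

test_that("ties break toward the lower position and earlier replacement letter", {
  m <- matrix(1 / 20, 4, 20)
  pm <- ProbabilityMatrix(m)
  rec <- worstPositions("AAAA", pm, k = 2)
  expect_identical(rec$position, 1:2)         # all equal: lower index first
  expect_identical(unique(rec$replacement), "A")  # argmax tie: first letter
})

test_that("records carry the six-group labels and layers", {
  # designed Leu where the argmax is Lys: aliphatic -> polar_charged
  m <- matrix(0.01, 1, 20)
  colnames(m) <- aminoAcids()
  m[1, "K"] <- 0.5
  m[1, "L"] <- 0.02
  pm <- ProbabilityMatrix(m / rowSums(m))
  rec <- worstPositions("L", pm, k = 1, layers = "surface", designId = "d1")
  expect_identical(rec$designed, "L")
  expect_identical(rec$replacement, "K")
  expect_identical(rec$designedGroup, "aliphatic")
  expect_identical(rec$replacementGroup, "polar_charged")
  expect_identical(rec$layer, "surface")
  expect_identical(rec$designId, "d1")
})

test_that("worst positions ignore appended higher-probability positions", {
  pm <- randomPSPM(8, seed = 5)
  seq8 <- "ACDEFGHI"
  rec <- worstPositions(seq8, pm, k = 3)
  kth <- max(rec$probability)
  # append two positions whose realized probability exceeds the k-th worst
  extra <- matrix((1 - min(0.95, kth + 0.02)) / 19, 2, 20)
  extra[, match("K", aminoAcids())] <- min(0.95, kth + 0.02)
  pm10 <- ProbabilityMatrix(rbind(probs(pm), extra / rowSums(extra)))
  rec10 <- worstPositions(paste0(seq8, "KK"), pm10, k = 3)
  expect_identical(rec10$position, rec$position)
  expect_equal(rec10$probability, rec$probability, tolerance = 1e-12)
})

test_that("replacement grids conserve record counts and layer totals", {
  expect_true(all(replacementMatrix(
    worstPositions("A", ProbabilityMatrix(matrix(1 / 20, 1, 20)), k = 1)[0, ]
  )$counts == 0))

  set.seed(4)
  nDesigns <- 7
  recs <- do.call(rbind, lapply(seq_len(nDesigns), function(d) {
    pm <- randomPSPM(15, seed = 400 + d)
    s <- paste(sample(aminoAcids(), 15, replace = TRUE), collapse = "")
    worstPositions(s, pm, k = 10,
                   layers = sample(c("core", "boundary", "surface"), 15,
                                   replace = TRUE),
                   designId = paste0("d", d))
  }))
  rm <- replacementMatrix(recs)
  expect_identical(sum(rm$counts), as.integer(10 * nDesigns))
  expect_identical(sum(rm$layers), as.integer(10 * nDesigns))
  # permutation invariance over record order
  rm2 <- replacementMatrix(recs[sample(nrow(recs)), ])
  expect_identical(rm$counts, rm2$counts)
  expect_identical(rm$layers, rm2$layers)
})

test_that("a hand-built record set tallies exactly", {
  recs <- data.frame(
    designId = "d", position = 1:5,
    designed = c("L", "F", "K", "G", "Q"),
    probability = rep(0.01, 5),
    replacement = c("K", "D", "R", "A", "L"),
    designedGroup = c("aliphatic", "aromatic", "polar_charged", "gly_pro",
                      "polar_uncharged"),
    replacementGroup = c("polar_charged", "polar_charged", "polar_charged",
                         "aliphatic", "aliphatic"),
    layer = c("surface", "surface", "core", "boundary", "surface"))
  rm <- replacementMatrix(recs)
  expect_identical(rm$counts["aliphatic", "polar_charged"], 1L)
  expect_identical(rm$counts["aromatic", "polar_charged"], 1L)
  expect_identical(rm$counts["polar_charged", "polar_charged"], 1L)
  expect_identical(sum(rm$counts), 5L)
  expect_identical(rm$layers[["surface"]], 3L)
  # the optional report filter drops self polar-charged proposals
  rmF <- replacementMatrix(recs, excludePolarChargedSelf = TRUE)
  expect_identical(sum(rmF$counts), 4L)
  expect_identical(rmF$counts["polar_charged", "polar_charged"], 0L)
})

test_that("sequence recovery counts identical positions", {
  expect_equal(sequenceRecovery("ACDE", "ACDE"), 1)
  expect_equal(sequenceRecovery("ACDE", "WYHK"), 0)
  expect_equal(sequenceRecovery("ACDE", "ACWW"), 0.5)
  expect_error(sequenceRecovery("ACD", "AC"), "mismatch")
})

test_that("native normalization is an element-wise ratio with scale equivariance", {
  expect_equal(normalizeByNative(c(2, 4), 2), c(1, 2))
  expect_identical(normalizeByNative(numeric(0), 3), numeric(0))
  expect_error(normalizeByNative(c(1, 2), 0), "nonzero")
  set.seed(6)
  x <- rnorm(10)
  nat <- 1.7
  for (c in c(-2, 0.5, 10)) {
    expect_equal(normalizeByNative(c * x, c * nat),
                 normalizeByNative(x, nat), tolerance = 1e-12)
  }
})

test_that("term correlations match the covariance-formula oracle", {
  ppl <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  terms <- data.frame(same = ppl, neg = -ppl,
                      other = c(0.3, -1.2, 0.8, 2.0, -0.4))
  res <- termCorrelations(terms, ppl)
  expect_equal(res$pearsonR[res$term == "same"], 1, tolerance = 1e-12)
  expect_equal(res$pearsonR[res$term == "neg"], -1, tolerance = 1e-12)
  x <- terms$other
  oracle <- sum((x - mean(x)) * (ppl - mean(ppl))) /
    sqrt(sum((x - mean(x))^2) * sum((ppl - mean(ppl))^2))
  expect_equal(res$pearsonR[res$term == "other"], oracle, tolerance = 1e-12)

  expect_warning(
    resZ <- termCorrelations(data.frame(flat = rep(1, 5)), ppl),
    "undefined")
  expect_true(is.na(resZ$pearsonR))
  expect_error(termCorrelations(terms[1:2, ], ppl[1:2]), "at least 3")
})
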