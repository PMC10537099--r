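test_that("half-sib pedigree construction matches the mating design", {
  ped <- buildHalfSibPedigree(100, 4, 5)
  expect_equal(nAnimals(ped), 2500)
  expect_equal(sum(ped@generation == 0L), 500)
  expect_equal(length(offspringIds(ped)), 2000)
  d <- as.data.frame(ped)
  expect_true(all(d$sire[d$generation == 1] %in% 1:100))
  expect_true(all(d$dam[d$generation == 1] %in% 101:500))
  # each sire 4 dams x 5 offspring = 20 offspring; each dam 5
  expect_true(all(table(d$sire[d$generation == 1]) == 20))
  expect_true(all(table(d$dam[d$generation == 1]) == 5))

  tiny <- buildHalfSibPedigree(1, 1, 1)
  expect_equal(nAnimals(tiny), 3)
  expect_equal(as.data.frame(tiny)[3, c("sire", "dam")],
    data.frame(sire = 1L, dam = 2L, row.names = 3L))

  expect_error(buildHalfSibPedigree(0, 4, 5), "positive")
  expect_error(buildHalfSibPedigree(2, -1, 5), "positive")
})

test_that("sib-group structure agrees with brute-force pair classification", {
  ped <- buildHalfSibPedigree(2, 2, 3)
  off <- offspringIds(ped)
  expect_length(off, 12)
  A <- relationshipMatrix(ped)
  for (i in off) {
    for (j in off) {
      if (i == j) next
      expected <- switch(classifyPair(ped, i, j),
        fullsib = 0.5, halfsib = 0.25, unrelated = 0)
      expect_equal(A[i, j], expected)
    }
  }
})

test_that("relationship matrix has textbook values and a pedigree-rule inverse", {
  ped <- buildHalfSibPedigree(3, 2, 2)
  A <- relationshipMatrix(ped)
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) == 1)) # no inbreeding in two generations
  off <- offspringIds(ped)
  expect_equal(A[off[1], off[2]], 0.5)  # full sibs
  expect_equal(A[off[1], off[3]], 0.25) # half sibs (same sire)
  expect_equal(A[off[1], ped@sire[off[1]]], 0.5) # parent-offspring

  # sparse pedigree-rule inverse equals the dense inverse (oracle)
  ped200 <- buildHalfSibPedigree(20, 3, 2) # 200 animals
  A200 <- relationshipMatrix(ped200)
  Ai <- relationshipInverse(ped200)
  expect_lt(max(abs(as.matrix(Ai) - solve(A200))), 1e-8)
  expect_lt(max(abs(as.matrix(Ai %*% A200) - diag(200))), 1e-8)
})

test_that("pedigree-rule inverse holds on random non-inbred pedigrees", {
  set.seed(42)
  for (rep in 1:5) {
    nb <- sample(10:20, 1)
    no <- sample(20:35, 1)
    sires <- sample(nb, ceiling(nb / 2))
    dams <- setdiff(seq_len(nb), sires)
    ped <- new("Pedigree", id = seq_len(nb + no),
      sire = c(rep(0L, nb), sample(sires, no, replace = TRUE)),
      dam = c(rep(0L, nb), sample(dams, no, replace = TRUE)),
      generation = c(rep(0L, nb), rep(1L, no)))
    A <- relationshipMatrix(ped)
    Ai <- relationshipInverse(ped)
    expect_lt(max(abs(as.matrix(Ai %*% A) - diag(nb + no))), 1e-8)
  }
})

test_that("cyclic or ill-ordered pedigrees are rejected", {
  expect_error(new("Pedigree", id = 1:2, sire = c(2L, 0L), dam = c(0L, 0L),
    generation = c(0L, 0L)))
})

test_that("trait effects degenerate correctly with zero variances", {
  ped <- buildHalfSibPedigree(3, 2, 2)
  p <- geneticParams(varAAlpha = 0, varABeta = 0, varEpAlpha = 0,
    varEpBeta = 0)
  eff <- sampleTraitEffects(ped, p, seed = 1)
  expect_true(all(breedingValues(eff) == 0))
  expect_true(all(permanentEnv(eff) == 0))
  expect_true(all(tendencies(eff)[, 1] == p@muAlpha))
  expect_true(all(tendencies(eff)[, 2] == p@muBeta))
})

test_that("offspring breeding values restore the base variance and sib covariances", {
  ped <- buildHalfSibPedigree(20, 4, 5) # 400 offspring
  p <- geneticParams(varAAlpha = 0.170, rA = 0)
  off <- offspringIds(ped)
  nSeeds <- 20
  vA <- fsCov <- numeric(nSeeds)
  for (s in seq_len(nSeeds)) {
    eff <- sampleTraitEffects(ped, p, seed = s)
    a <- breedingValues(eff)[off, 1]
    vA[s] <- var(a)
    m <- matrix(a, nrow = 5) # full-sib families of 5 in consecutive blocks
    cc <- cov(t(m))
    fsCov[s] <- mean(cc[upper.tri(cc)])
  }
  se <- sd(vA) / sqrt(nSeeds)
  expect_lt(abs(mean(vA) - 0.170), 3 * se)
  seF <- sd(fsCov) / sqrt(nSeeds)
  expect_lt(abs(mean(fsCov) - 0.085), 3 * seF)
})

test_that("genetic correlation between the latent traits is recovered", {
  ped <- buildHalfSibPedigree(40, 4, 4)
  p <- geneticParams(varAAlpha = 0.2, rA = 0.5)
  cors <- vapply(1:10, function(s) {
    A <- breedingValues(sampleTraitEffects(ped, p, seed = s))
    cor(A[, 1], A[, 2])
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.5), 3 * sd(cors) / sqrt(10))
})

test_that("non-PSD genetic parameters are rejected", {
  expect_error(geneticParams(rA = 1.2))
  expect_error(geneticParams(varAAlpha = -0.1))
})

test_that("underlying-scale heritability follows the threshold-model formula", {
  # printed calibration table values (inputs rounded to 3 decimals there)
  expect_lt(abs(underlyingH2(geneticParams(varAAlpha = 0.012)) - 0.0036), 1e-4)
  expect_lt(abs(underlyingH2(geneticParams(varAAlpha = 0.038)) - 0.0111), 1e-4)
  expect_lt(abs(underlyingH2(geneticParams(varAAlpha = 0.170)) - 0.0429), 1e-4)
  expect_identical(underlyingH2(geneticParams(0, 0, 0, 0)), 0)
  # monotone increasing in the performer genetic variance
  h <- vapply(seq(0.01, 0.5, by = 0.01), function(v)
    underlyingH2(geneticParams(varAAlpha = v, varABeta = 0.1,
      varEpAlpha = 0.1, varEpBeta = 0.1)), numeric(1))
  expect_true(all(diff(h) > 0))
})

test_that("extreme-animal interaction probabilities match the printed values", {
  p <- geneticParams(varAAlpha = 0.170)
  expect_lt(abs(extremeInteractionProbability(p, 2) - 0.022), 1e-3)
  expect_lt(abs(extremeInteractionProbability(p, -2) - 0.004), 1e-3)
  expect_equal(extremeInteractionProbability(p, 0), 0.01, tolerance = 1e-10)
})

test_that("pedigree and trait-effect files round-trip", {
  ped <- buildHalfSibPedigree(2, 2, 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  writePedigree(ped, f)
  ped2 <- readPedigree(f)
  expect_equal(as.data.frame(ped), as.data.frame(ped2))

  eff <- sampleTraitEffects(ped, geneticParams(), seed = 3)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeTraitEffects(eff, f2)
  d <- read.table(f2, header = TRUE)
  expect_equal(d$P_alpha, unname(tendencies(eff)[, 1]), tolerance = 1e-10)
})
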