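test_that("animal-model REML recovers a null genetic variance", {
  # under pure noise the heritability estimate is boundary-censored at 0, so
  # its mean over seeds stays small relative to the per-estimate spread
  ped <- buildHalfSibPedigree(25, 2, 4) # 200 offspring
  off <- offspringIds(ped)
  h2 <- vapply(1:8, function(s) {
    set.seed(s)
    cnt <- data.frame(id = off, n = rnorm(length(off), 25, 5))
    fitAnimalModelReml(cnt, ped)@h2o
  }, numeric(1))
  expect_lt(mean(h2), 0.12)
  expect_gt(mean(h2 < 0.2), 0.6)
})

test_that("eigen-profile REML matches a brute-force grid search of the dense
           restricted likelihood", {
  ped <- buildHalfSibPedigree(5, 2, 2) # 35 animals, 20 with records
  off <- offspringIds(ped)
  A <- relationshipMatrix(ped)[off, off]
  set.seed(11)
  for (h2true in c(0.2, 0.5)) {
    L <- chol(h2true * A + (1 - h2true) * diag(length(off)))
    y <- 25 + drop(rnorm(length(off)) %*% L) * 4
    fit <- fitAnimalModelReml(data.frame(id = off, n = y), ped)
    hGrid <- gridSearchReml(y, A)
    lamFit <- fit@h2o / (1 - fit@h2o)
    lamGrid <- hGrid / (1 - hGrid)
    expect_lt(abs(lamFit - lamGrid), 1e-4 * (1 + lamGrid))
  }
})

test_that("REML boundary estimates are reported, not hidden", {
  ped <- buildHalfSibPedigree(6, 2, 2)
  off <- offspringIds(ped)
  set.seed(3)
  # anti-correlated family structure pushes the genetic variance to zero
  fit <- fitAnimalModelReml(data.frame(id = off, n = rnorm(24)), ped)
  expect_gte(fit@varA, 0)
  expect_true(fit@converged)
})

test_that("variance calibration root-finds the target heritability", {
  ped <- buildHalfSibPedigree(20, 2, 3) # 120 offspring
  off <- offspringIds(ped)
  # cheap synthetic closure: counts whose heritability rises with the input
  # latent variance exactly as in a repeated-Bernoulli count model
  simFun <- function(variance, replicate) {
    eff <- sampleTraitEffects(ped,
      geneticParams(varAAlpha = variance, rA = 0),
      seed = 1000 + replicate)
    lam <- 2500 * plogis(qlogis(0.01) + breedingValues(eff)[off, 1] +
      permanentEnv(eff)[off, 1])
    set.seed(2000 + replicate)
    data.frame(id = off, n = rpois(length(off), lam))
  }
  cal <- calibrateVariance(0.2, ped, simFun, nReps = 4,
    interval = c(0.005, 0.8), tol = 5e-3)
  h <- mean(vapply(5:8, function(r)
    fitAnimalModelReml(simFun(cal$variance, r), ped)@h2o, numeric(1)))
  expect_lt(abs(h - 0.2), 0.08)
  expect_gte(nrow(cal$trace), 2)
})

test_that("observed-scale heritability of simulated counts increases with the
           latent variance input", {
  ped <- buildHalfSibPedigree(10, 4, 3) # 120 offspring
  closure <- makeCountSimClosure(ped, groupSize = 30, meanInteractions = 25,
    seed = 5)
  h2 <- vapply(c(0.012, 0.170), function(v) {
    mean(vapply(1:2, function(r)
      fitAnimalModelReml(closure(v, r), ped)@h2o, numeric(1)))
  }, numeric(1))
  expect_gt(h2[2], h2[1])
})

test_that("the GLMM collapses to the null model when all tendencies are equal", {
  ped <- buildHalfSibPedigree(5, 2, 2)
  off <- offspringIds(ped)
  mu <- qlogis(0.01) / 2
  sim <- simulatePen(rep(mu, 20), rep(mu, 20), targetInteractions = 600,
    ids = off, seed = 17, logRecords = FALSE)
  fit <- fitSocialGlmm(pairTable(sim$pairs), ped)
  vc <- varianceComponents(fit)
  expect_true(all(vc[c("varAAlpha", "varABeta")] < 0.05))
  expect_lt(abs(fit@fixef[["(Intercept)"]] - qlogis(0.01)), 0.25)
})

test_that("PQL solutions solve the mixed-model equations to 1e-8", {
  ped <- buildHalfSibPedigree(4, 2, 3)
  eff <- sampleTraitEffects(ped, geneticParams(varAAlpha = 0.17), seed = 2)
  off <- offspringIds(ped)
  sim <- simulatePen(tendencies(eff)[off, 1], tendencies(eff)[off, 2],
    targetInteractions = 1000, ids = off, seed = 2, logRecords = FALSE)
  fit <- fitSocialGlmm(pairTable(sim$pairs), ped)
  expect_lt(fit@diagnostics$mmeResidual, 1e-8)
})

test_that("GLMM results are invariant to row permutation and pen relabelling", {
  ped <- buildHalfSibPedigree(4, 2, 3) # 24 offspring, two pens of 12
  eff <- sampleTraitEffects(ped, geneticParams(varAAlpha = 0.17), seed = 9)
  off <- offspringIds(ped)
  P <- tendencies(eff)
  s1 <- simulatePen(P[off[1:12], 1], P[off[1:12], 2], penId = 1L,
    targetInteractions = 600, ids = off[1:12], seed = 9, logRecords = FALSE)
  s2 <- simulatePen(P[off[13:24], 1], P[off[13:24], 2], penId = 2L,
    targetInteractions = 600, ids = off[13:24], seed = 9, logRecords = FALSE)
  pt <- combinePairTables(list(s1, s2))
  fit <- fitSocialGlmm(pt, ped)

  d <- pairData(pt)
  set.seed(1)
  fitPerm <- fitSocialGlmm(pairTable(d[sample(nrow(d)), ]), ped)
  # identical up to optimizer round-off (summation order changes)
  expect_equal(varianceComponents(fitPerm), varianceComponents(fit),
    tolerance = 1e-3)
  expect_equal(fitPerm@ebvAlpha, fit@ebvAlpha, tolerance = 1e-3)

  # relabelling pens shifts fixed effects but leaves fitted probabilities
  # and EBVs unchanged (intercept reparameterization invariance)
  d2 <- d
  d2$pen <- ifelse(d$pen == 1, 2L, 1L)
  fitRelab <- fitSocialGlmm(pairTable(d2), ped)
  expect_equal(fitRelab@ebvAlpha, fit@ebvAlpha, tolerance = 1e-4)
  eta1 <- fit@fixef[["(Intercept)"]]
  eta2 <- fitRelab@fixef[["(Intercept)"]] + fitRelab@fixef[["pen2"]]
  expect_equal(eta1, eta2, tolerance = 1e-4)
})

test_that("PQL matches a dense Laplace oracle on a small two-pen instance", {
  ped <- buildHalfSibPedigree(5, 2, 2) # 20 offspring in 2 pens of 10
  gp <- geneticParams(varAAlpha = 0.5, varABeta = 0.5, varEpAlpha = 0.1,
    varEpBeta = 0.1, rA = 0) # strong signal keeps the instance identified
  eff <- sampleTraitEffects(ped, gp, seed = 6)
  off <- offspringIds(ped)
  P <- tendencies(eff)
  s1 <- simulatePen(P[off[1:10], 1], P[off[1:10], 2], penId = 1L,
    nSteps = 16000, ids = off[1:10], seed = 6, logRecords = FALSE)
  s2 <- simulatePen(P[off[11:20], 1], P[off[11:20], 2], penId = 2L,
    nSteps = 16000, ids = off[11:20], seed = 106, logRecords = FALSE)
  pt <- combinePairTables(list(s1, s2))

  # at the same variance components the PQL working solutions and the
  # Laplace inner mode solve the same penalized likelihood: agreement is
  # limited only by solver round-off
  fitF <- fitSocialGlmm(pt, ped, varComponents = gp)
  orF <- laplaceOracle(pairData(pt), ped,
    socialsim:::paramsToTheta(gp), optimize = FALSE)
  expect_lt(max(abs(fitF@ebvAlpha - orF$ebvAlpha)), 1e-4)
  expect_lt(max(abs(fitF@ebvBeta - orF$ebvBeta)), 1e-4)
  expect_lt(abs(fitF@fixef[[1]] - orF$fixef[1]), 1e-4)

  # when each method also estimates its own variance components, the
  # working-model REML and the Laplace likelihood are different criteria at
  # finite counts, and 20 animals leave the variance surface shallow; the
  # solutions still agree to well under the EBV spread (~0.5 here)
  fit <- fitSocialGlmm(pt, ped)
  or <- laplaceOracle(pairData(pt), ped,
    socialsim:::paramsToTheta(geneticParams(varAAlpha = 0.25,
      varEpAlpha = 0.1, rA = 0)))
  expect_lt(max(abs(fit@ebvAlpha - or$ebvAlpha)), 0.01)
  expect_lt(max(abs(fit@ebvBeta - or$ebvBeta)), 0.01)
  expect_lt(abs(fit@fixef[[1]] - or$fixef[1]), 0.01)
})

test_that("starting values and fixed components are honoured", {
  ped <- buildHalfSibPedigree(4, 2, 2)
  eff <- sampleTraitEffects(ped, geneticParams(varAAlpha = 0.17), seed = 4)
  off <- offspringIds(ped)
  sim <- simulatePen(tendencies(eff)[off, 1], tendencies(eff)[off, 2],
    targetInteractions = 400, ids = off, seed = 4, logRecords = FALSE)
  truth <- geneticParams(varAAlpha = 0.17, rA = 0)
  fit <- fitSocialGlmm(pairTable(sim$pairs), ped, varComponents = truth)
  expect_equal(unname(varianceComponents(fit)[["varAAlpha"]]), 0.17,
    tolerance = 1e-8)
  fit2 <- fitSocialGlmm(pairTable(sim$pairs), ped, start = truth,
    maxOuter = 2L)
  expect_s4_class(fit2, "SocialGlmmFit")
})
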