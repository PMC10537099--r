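test_that("motivation updates follow the motivation-change matrix", {
  cfg <- movementConfig()
  # resting: eating motivation builds slowly, walking rises, resting drains
  m <- updateMotivation(c(50, 0, 100), "rest", cfg)
  expect_equal(m, c(50.025, 10, 90))
  # eating drains by 1 per step: a meal started at threshold lasts T steps
  m <- updateMotivation(c(100, 20, 30), "eat", cfg)
  expect_equal(m, c(99, 20, 30))
  expect_equal(100 / abs(cfg@delta[1, 1]), cfg@threshold) # 100-step meal
  # floors at zero for the termination test
  m <- updateMotivation(c(0.5, 5, 5), "eat", cfg)
  expect_equal(m[1], 0)
  # approaching changes no motivation
  expect_equal(updateMotivation(c(100, 5, 5), "approach", cfg),
    c(100, 5, 5))
})

test_that("behaviour decisions respect continuation and priority", {
  cfg <- movementConfig()
  # continue the active behaviour while its motivation is above zero
  expect_equal(decideBehaviour(c(100, 50, 50), "rest", cfg), "rest")
  # at a tie above threshold, eating wins and walking loses to resting
  expect_equal(decideBehaviour(c(100, 100, 100), "none", cfg), "eat")
  expect_equal(decideBehaviour(c(0, 100, 100), "none", cfg), "rest")
  expect_equal(decideBehaviour(c(0, 100, 0), "none", cfg), "walk")
  # nothing above threshold: rest by default
  expect_equal(decideBehaviour(c(0, 0, 0), "none", cfg), "rest")
})

test_that("movement respects walls, clamping and zero-displacement states", {
  cfg <- movementConfig()
  # resting agent does not move
  r <- moveAgent(c(5, 5), "rest", 0, 10, cfg)
  expect_equal(r$position, c(5, 5))
  # approach arrives this step when closer than one step length
  r <- moveAgent(c(5, 0.4), "approach", 0, 10, cfg, feederPosition = c(5, 0))
  expect_equal(r$position, c(5, 0))
  # walking at a wall reflects and stays inside
  r <- moveAgent(c(0.2, 5), "walk", pi, 10, cfg)
  expect_true(all(r$position >= 0 & r$position <= 10))
  expect_equal(r$position[1], 0.8)
  set.seed(1)
  for (k in 1:50) {
    pos <- runif(2, 0, 10)
    r <- moveAgent(pos, "walk", runif(1, 0, 2 * pi), 10, cfg)
    expect_true(all(r$position >= 0 & r$position <= 10))
    expect_lte(sqrt(sum((r$position - pos)^2)), cfg@stepLength + 1e-9)
  }
})

test_that("encounter detection equals the brute-force all-pairs oracle", {
  expect_equal(nrow(detectEncounters(rbind(c(1, 1), c(1, 1)), 0.5)), 1)
  expect_equal(nrow(detectEncounters(rbind(c(0, 0), c(10, 10)), 1)), 0)
  set.seed(7)
  pos <- cbind(runif(100, 0, 10), runif(100, 0, 10))
  got <- detectEncounters(pos, 1)
  want <- bruteForceEncounters(pos, 1)
  expect_equal(unname(got), unname(want))
})

test_that("the simulation engine agrees with step-level recomputation", {
  mu <- qlogis(0.01) / 2
  n <- 30
  sim <- simulatePen(rep(mu, n), rep(mu, n), nSteps = 200, seed = 5,
    logTrajectorySteps = 200)
  tr <- sim$trajectory
  side <- sim$penSide
  # positions always inside the pen
  expect_true(all(tr$x >= 0 & tr$x <= side & tr$y >= 0 & tr$y <= side))
  # per-step displacement never exceeds the step length
  for (a in seq_len(n)) {
    pa <- tr[tr$agent == a, ]
    d <- sqrt(diff(pa$x)^2 + diff(pa$y)^2)
    expect_lte(max(d), movementConfig()@stepLength + 1e-9)
  }
  # encounter counts reconstructed from the logged positions match exactly
  Nref <- matrix(0L, n, n)
  for (s in unique(tr$step)) {
    ts <- tr[tr$step == s, ]
    pos <- as.matrix(ts[order(ts$agent), c("x", "y")])
    enc <- bruteForceEncounters(pos, movementConfig()@sensingRange)
    if (nrow(enc)) {
      for (k in seq_len(nrow(enc))) {
        Nref[enc[k, 1], enc[k, 2]] <- Nref[enc[k, 1], enc[k, 2]] + 1L
        Nref[enc[k, 2], enc[k, 1]] <- Nref[enc[k, 2], enc[k, 1]] + 1L
      }
    }
  }
  expect_equal(unname(sim$N), Nref)
  # conservation: every logged interaction is counted once in y
  expect_equal(sum(sim$y), nrow(sim$records))
  expect_equal(sum(sim$y), sim$totalInteractions)
  expect_true(all(sim$y <= sim$N))
  expect_true(isSymmetric(sim$N))
})

test_that("the eat/walk/rest cycle reproduces the intended behavioural pattern", {
  mu <- qlogis(0.01) / 2
  sim <- simulatePen(rep(mu, 50), rep(mu, 50), nSteps = 10000, seed = 8,
    logRecords = FALSE)
  # meals roughly every 4000 steps: threshold / eating-motivation rise rate,
  # plus meal duration and the walk to the feeder
  iv <- mealIntervalMean(sim, minutes = FALSE)
  expect_gt(iv, 3800)
  expect_lt(iv, 4600)
  b <- timeBudget(sim)
  # eating (incl. approach) takes a few percent; walking and resting split
  # the remainder about evenly
  expect_lt(b[["eat"]], 0.08)
  expect_gt(b[["eat"]], 0.015)
  expect_lt(abs(b[["walk"]] - b[["rest"]]) / b[["rest"]], 0.1)
})

test_that("a non-terminating target aborts with a diagnostic", {
  mu <- qlogis(0.01) / 2
  cfg <- movementConfig(maxSteps = 50L)
  expect_error(
    simulatePen(rep(mu, 10), rep(mu, 10), config = cfg,
      targetInteractions = 100000, seed = 1),
    "did not reach")
})
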