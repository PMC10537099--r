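# Independent oracles and shared fixtures for the test suite. Everything here
# is deliberately written brute-force / dense, independent of the package's
# computational paths.

# Brute-force sib classification from parent IDs (ignores the A matrix code)
classifyPair <- function(ped, i, j) {
  d <- as.data.frame(ped)
  si <- d$sire[i]; di <- d$dam[i]; sj <- d$sire[j]; dj <- d$dam[j]
  if (si == 0 || sj == 0) return("unrelated-or-parent")
  if (si == sj && di == dj) "fullsib" else if (si == sj || di == dj) "halfsib"
  else "unrelated"
}

# Brute-force all-pairs encounter detection
bruteForceEncounters <- function(pos, r) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < r) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# Dense restricted log-likelihood deviance of the animal model, as an
# explicit matrix formula (no eigen shortcut), profiled over nothing:
# evaluated on a grid to locate the REML optimum independently.
denseRemlDeviance <- function(h, y, A) {
  n <- length(y)
  lam <- h / (1 - h)
  V0 <- lam * A + diag(n) # V / sigma2_e
  Vi <- solve(V0)
  X <- matrix(1, n, 1)
  XtVX <- t(X) %*% Vi %*% X
  mu <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% mu
  rss <- drop(t(r) %*% Vi %*% r)
  s2e <- rss / (n - 1)
  drop((n - 1) * log(s2e) + determinant(V0)$modulus + log(det(XtVX)) +
    (n - 1))
}

gridSearchReml <- function(y, A, coarse = seq(0.001, 0.97, by = 0.001)) {
  dev <- vapply(coarse, denseRemlDeviance, numeric(1), y = y, A = A)
  h0 <- coarse[which.min(dev)]
  fine <- seq(max(1e-6, h0 - 2e-3), min(0.98, h0 + 2e-3), by = 1e-6)
  devF <- vapply(fine, denseRemlDeviance, numeric(1), y = y, A = A)
  fine[which.min(devF)]
}

# Laplace-approximated restricted likelihood of the binomial logit mixed
# model on a small instance, maximized by a generic optimizer. Dense algebra
# throughout; inner mode by Newton/IRLS on the penalized binomial likelihood.
laplaceOracle <- function(d, ped, thetaStart, maxit = 400, optimize = TRUE) {
  A <- relationshipMatrix(ped)
  q <- nAnimals(ped)
  rec <- sort(unique(c(d$performer, d$recipient)))
  nRec <- length(rec)
  m <- nrow(d)
  penF <- factor(d$pen)
  X <- stats::model.matrix(~penF)
  p <- ncol(X)
  Z <- matrix(0, m, 2 * q + 2 * nRec)
  for (k in seq_len(m)) {
    Z[k, match(d$performer[k], ped@id)] <- 1
    Z[k, q + match(d$recipient[k], ped@id)] <- 1
    Z[k, 2 * q + match(d$performer[k], rec)] <- 1
    Z[k, 2 * q + nRec + match(d$recipient[k], rec)] <- 1
  }
  M <- cbind(X, Z)
  y <- d$nInteractions
  Nn <- d$nEncounters
  Ainv <- solve(A)
  sigInv <- function(th) {
    vA <- exp(th[1:2]); r <- tanh(th[3])
    G0 <- matrix(c(vA[1], r * sqrt(vA[1] * vA[2]),
      r * sqrt(vA[1] * vA[2]), vA[2]), 2)
    list(S = as.matrix(Matrix::bdiag(kronecker(solve(G0), Ainv),
      diag(nRec) / exp(th[4]), diag(nRec) / exp(th[5]))),
      logDetSigma = q * log(det(G0)) + 2 * determinant(A)$modulus +
        nRec * (th[4] + th[5]))
  }
  inner <- function(th) {
    si <- sigInv(th)
    Spad <- rbind(cbind(matrix(0, p, p), matrix(0, p, ncol(Z))),
      cbind(matrix(0, ncol(Z), p), si$S))
    beta <- c(qlogis(max(sum(y) / sum(Nn), 1e-6)), numeric(ncol(M) - 1))
    for (it in 1:100) {
      eta <- drop(M %*% beta)
      mu <- plogis(eta)
      w <- pmax(Nn * mu * (1 - mu), 1e-12)
      g <- drop(t(M) %*% (y - Nn * mu)) - Spad %*% beta
      H <- t(M) %*% (w * M) + Spad
      step <- solve(H + 1e-9 * diag(nrow(H)), g)
      beta <- beta + step
      if (max(abs(step)) < 1e-10) break
    }
    eta <- drop(M %*% beta)
    mu <- plogis(eta)
    w <- pmax(Nn * mu * (1 - mu), 1e-12)
    H <- t(M) %*% (w * M) + Spad
    ll <- sum(dbinom(y, Nn, mu, log = TRUE)) -
      0.5 * drop(t(beta) %*% Spad %*% beta) -
      0.5 * si$logDetSigma - 0.5 * determinant(H)$modulus
    list(ll = ll, beta = beta)
  }
  thetaHat <- if (optimize) {
    th <- thetaStart
    for (restart in 1:3) { # Nelder-Mead needs restarts in 5 dimensions
      th <- optim(th, function(x) {
        if (any(abs(x) > 15)) return(1e9)
        -inner(x)$ll
      }, method = "Nelder-Mead", control = list(maxit = maxit,
        reltol = 1e-10))$par
    }
    th
  } else {
    thetaStart
  }
  fit <- inner(thetaHat)
  list(theta = thetaHat, beta = fit$beta, p = p, q = q, rec = rec,
    fixef = fit$beta[seq_len(p)],
    ebvAlpha = fit$beta[p + seq_len(q)],
    ebvBeta = fit$beta[p + q + seq_len(q)])
}

# Monte-Carlo check of the selection-index accuracy bound: simulate families,
# regress the candidate's breeding value on the three information sources.
simulateIndexAccuracy <- function(nFam, nFS, nHS, varRatio = 1, seed = 99) {
  set.seed(seed)
  # one sire family per candidate (sigma2_A = 1): breeding value = half the
  # sire BV (var 0.25) + half the dam BV (var 0.25) + Mendelian term (0.5);
  # full sibs share both parent halves, half sibs share the sire half only
  sire <- rnorm(nFam, 0, sqrt(0.25))
  damC <- rnorm(nFam, 0, sqrt(0.25)) # dam of the candidate's full-sib family
  msC <- rnorm(nFam, 0, sqrt(0.5))
  aC <- sire + damC + msC
  phen <- function(a) a + rnorm(length(a), 0, sqrt(varRatio))
  x1 <- phen(aC)
  x2 <- rowMeans(matrix(phen(rep(sire, nFS) + rep(damC, nFS) +
    rnorm(nFam * nFS, 0, sqrt(0.5))), nFam, nFS))
  x3 <- rowMeans(matrix(phen(rep(sire, nHS) +
    rnorm(nFam * nHS, 0, sqrt(0.25)) + # each half sib from its own dam
    rnorm(nFam * nHS, 0, sqrt(0.5))), nFam, nHS))
  fit <- lm(aC ~ x1 + x2 + x3)
  cor(fitted(fit), aC)
}

# Cached heavy battery for the parameter-recovery and EBV-accuracy checks:
# five replicates of the default scenario (2000 offspring, 20 pens of 100,
# h2_o = 0.2 inputs, rA = 0) at ~100 and ~10 interactions per animal.
.acceptanceCache <- new.env(parent = emptyenv())
acceptanceBattery <- function() {
  if (!is.null(.acceptanceCache$res)) return(.acceptanceCache$res)
  nRep <- 5L
  dense <- NULL
  sparse <- NULL
  lmmAcc <- numeric(0)
  for (r in seq_len(nRep)) {
    cfg <- scenarioConfig(seed = 101, nReplicates = nRep)
    sim <- simulateReplicate(cfg, r)
    off <- offspringIds(sim$ped)
    fit <- fitSocialGlmm(sim$pairs, sim$ped)
    dense <- rbind(dense, socialsim:::evaluateFit(fit, sim$effects, off))

    cfg2 <- scenarioConfig(seed = 101, nReplicates = nRep,
      targetInteractions = 1000)
    sim2 <- simulateReplicate(cfg2, r)
    fit2 <- fitSocialGlmm(sim2$pairs, sim2$ped)
    sparse <- rbind(sparse, socialsim:::evaluateFit(fit2, sim2$effects, off))

    pd <- pairData(sim2$pairs)
    performed <- tapply(pd$nInteractions, pd$performer, sum)[as.character(off)]
    received <- tapply(pd$nInteractions, pd$recipient, sum)[as.character(off)]
    performed[is.na(performed)] <- 0
    received[is.na(received)] <- 0
    la <- fitAnimalModelReml(data.frame(id = off, n = as.numeric(performed)),
      sim2$ped)
    lb <- fitAnimalModelReml(data.frame(id = off, n = as.numeric(received)),
      sim2$ped)
    A <- breedingValues(sim2$effects)[off, ]
    lmmAcc <- c(lmmAcc, accuracyAndBias(A[, 1] + A[, 2],
      la@ebv[as.character(off)] + lb@ebv[as.character(off)])$accuracy)
  }
  .acceptanceCache$res <- list(dense = dense, sparse = sparse,
    lmmAcc = lmmAcc)
  .acceptanceCache$res
}
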