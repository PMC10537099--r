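#' Animal-model REML for per-animal interaction counts
#'
#' Fits the animal model n_i = mu + A_i + e_i, with cov(A) proportional to the
#' pedigree relationship matrix, to the total interaction counts of the
#' recorded animals. The restricted likelihood is profiled over the variance
#' ratio on the eigenbasis of the relationship submatrix of the recorded
#' animals, which reduces REML to a one-dimensional maximization of the
#' heritability; the residual variance then has a closed form. This is the
#' model used to calibrate latent-scale variance inputs against a target
#' observed-scale heritability of interaction counts.
#'
#' @param counts data.frame with columns `id` and `n` (total interactions
#'   performed -- or received -- per recorded animal), or a named numeric
#'   vector with animal IDs as names.
#' @param ped a [Pedigree-class] covering all recorded animals.
#' @return An [LmmFit-class] with variance estimates, observed-scale
#'   heritability, BLUP breeding values of the recorded animals and the
#'   restricted log-likelihood.
#' @examples
#' ped <- buildHalfSibPedigree(10, 2, 2)
#' eff <- sampleTraitEffects(ped, geneticParams(varAAlpha = 0.5), seed = 2)
#' cnt <- data.frame(id = offspringIds(ped),
#'   n = rnorm(40, 25 + 20 * breedingValues(eff)[offspringIds(ped), 1], 5))
#' fitAnimalModelReml(cnt, ped)
#' @export
fitAnimalModelReml <- function(counts, ped) {
  if (is.numeric(counts) && !is.null(names(counts)))
    counts <- data.frame(id = as.integer(names(counts)), n = as.numeric(counts))
  stopifnot(all(c("id", "n") %in% names(counts)))
  ids <- as.integer(counts$id)
  if (any(!ids %in% ped@id)) stop("counts contain ids absent from the pedigree")
  y <- as.numeric(counts$n)
  n <- length(y)
  if (n < 3) stop("need at least 3 records")
  A <- relationshipMatrix(ped)[ids, ids]
  e <- eigen(A, symmetric = TRUE)
  d <- pmax(e$values, 1e-12)
  yt <- drop(crossprod(e$vectors, y))
  xt <- drop(crossprod(e$vectors, rep(1, n)))

  ## -2 * restricted log-likelihood profiled over sigma2_e, as a function of
  ## heritability h = varA / (varA + varE)
  dev <- function(h) {
    lam <- h / (1 - h)
    w <- lam * d + 1
    sw <- sum(xt^2 / w)
    mu <- sum(xt * yt / w) / sw
    r <- yt - xt * mu
    rss <- sum(r^2 / w)
    s2e <- rss / (n - 1)
    (n - 1) * log(s2e) + sum(log(w)) + log(sw) + (n - 1)
  }
  opt <- optimize(dev, c(0, 0.999), tol = 1e-9)
  h <- opt$minimum
  ## accept a boundary solution at zero when the deviance prefers it
  if (dev(0) <= opt$objective + 1e-10) h <- 0
  lam <- h / (1 - h)
  w <- lam * d + 1
  sw <- sum(xt^2 / w)
  mu <- sum(xt * yt / w) / sw
  r <- yt - xt * mu
  s2e <- sum(r^2 / w) / (n - 1)
  s2a <- lam * s2e
  shrink <- lam * d / w
  ebv <- drop(e$vectors %*% (shrink * r))
  names(ebv) <- ids
  new("LmmFit", varA = s2a, varE = s2e, h2o = if (s2a + s2e > 0) s2a / (s2a + s2e) else 0,
    mu = mu, ebv = ebv,
    logLik = -0.5 * (dev(h) + (n - 1) * log(2 * pi)),
    converged = TRUE)
}

#' Default count-simulation closure for heritability calibration
#'
#' Returns a function(variance, replicate) that simulates trait effects with
#' all four variance components equal to `variance` and zero genetic
#' correlation (the calibration convention), houses the offspring in pens of
#' `groupSize`, runs the agent-based model until each pen has about
#' `meanInteractions` interactions per animal (~2500 encounters per animal at
#' the 1% default probability), and returns the per-animal performed counts.
#'
#' @param ped a [Pedigree-class] object.
#' @param groupSize animals per pen (must divide the number of offspring).
#' @param meanInteractions target mean interactions performed per animal.
#' @param config a [MovementConfig-class] object.
#' @param seed root seed; each (variance, replicate) pair derives its own
#'   streams.
#' @return closure suitable for [calibrateVariance()].
#' @export
makeCountSimClosure <- function(ped, groupSize = 100, meanInteractions = 25,
                                config = movementConfig(), seed = 1) {
  off <- offspringIds(ped)
  stopifnot(length(off) %% groupSize == 0)
  nPens <- length(off) %/% groupSize
  function(variance, replicate = 1L) {
    params <- geneticParams(varAAlpha = variance, rA = 0)
    sub <- streamSeed(seed, "replicate", replicate * 131 +
                        round(variance * 1e6) %% 1000)
    eff <- sampleTraitEffects(ped, params, seed = sub)
    pen <- withStream(sub, "genetics", 1L, sample(rep(seq_len(nPens),
      each = groupSize)))
    counts <- lapply(seq_len(nPens), function(k) {
      idx <- off[pen == k]
      sim <- simulatePen(tendencies(eff)[idx, 1], tendencies(eff)[idx, 2],
        config = config,
        targetInteractions = as.integer(meanInteractions * groupSize),
        penId = k, ids = idx, seed = sub, logRecords = FALSE)
      data.frame(id = idx, n = rowSums(sim$y))
    })
    do.call(rbind, counts)
  }
}

#' Calibrate the latent variance input against a target observed-scale
#' heritability
#'
#' Root-finds the latent-scale variance input (used for all four components,
#' with zero genetic correlation) at which the animal-model REML estimate of
#' the observed-scale heritability of interaction counts, averaged over Monte
#' Carlo replicates, equals the target. The published calibrated presets are
#' available in [h2oPresets].
#'
#' @param targetH2o target observed-scale heritability in (0, 1).
#' @param ped a [Pedigree-class] object.
#' @param simFun closure `function(variance, replicate)` returning a counts
#'   data.frame (see [makeCountSimClosure()]).
#' @param nReps Monte Carlo replicates averaged per candidate variance.
#' @param interval variance search bracket.
#' @param tol root tolerance on the variance input.
#' @return list with elements `variance`, `achievedH2o` and `trace`
#'   (data.frame of evaluated candidates).
#' @export
calibrateVariance <- function(targetH2o, ped, simFun, nReps = 3,
                              interval = c(1e-3, 1), tol = 1e-3) {
  stopifnot(targetH2o > 0, targetH2o < 1)
  trace <- data.frame(variance = numeric(0), h2o = numeric(0))
  f <- function(v) {
    h <- mean(vapply(seq_len(nReps), function(r)
      fitAnimalModelReml(simFun(v, r), ped)@h2o, numeric(1)))
    trace <<- rbind(trace, data.frame(variance = v, h2o = h))
    h - targetH2o
  }
  root <- tryCatch(
    stats::uniroot(f, interval = interval, extendInt = "upX", tol = tol),
    error = function(e) stop("calibration bracket failure: ",
      conditionMessage(e))
  )
  list(variance = root$root, achievedH2o = root$f.root + targetH2o,
    trace = trace)
}
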