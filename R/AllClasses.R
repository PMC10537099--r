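#' @import methods
#' @importFrom stats plogis qlogis rnorm runif rbinom optimize nlminb var cor coef lm sd setNames
#' @importFrom utils read.table write.table
NULL

## link variance of the logistic threshold model
LINK_VARIANCE <- pi^2 / 3

#' Genetic parameters of the performer/recipient latent-trait model
#'
#' Holds the variance components, genetic correlation and logit-scale means of
#' the two latent social tendencies: the performer trait (alpha, the tendency
#' to initiate a directed interaction) and the recipient trait (beta, the
#' tendency to receive one). Both traits are modelled on the underlying logit
#' scale as mean + breeding value + permanent environmental effect, with no
#' residual (the logistic link contributes the residual, variance pi^2/3).
#'
#' @slot varAAlpha,varABeta additive genetic variances of the two traits.
#' @slot varEpAlpha,varEpBeta permanent environmental variances.
#' @slot rA genetic correlation between performer and recipient traits.
#' @slot muAlpha,muBeta trait means on the logit scale.
#' @export
setClass("GeneticParams",
  representation(
    varAAlpha = "numeric", varABeta = "numeric",
    varEpAlpha = "numeric", varEpBeta = "numeric",
    rA = "numeric", muAlpha = "numeric", muBeta = "numeric"
  )
)

setValidity("GeneticParams", function(object) {
  v <- c(object@varAAlpha, object@varABeta, object@varEpAlpha, object@varEpBeta)
  if (length(v) != 4L || any(!is.finite(v))) return("variances must be finite scalars")
  if (any(v < 0)) return("all variances must be >= 0")
  if (abs(object@rA) > 1) return("|rA| must be <= 1")
  G <- genCovMatrix(object)
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    return("genetic covariance matrix must be positive semi-definite")
  TRUE
})

#' Construct genetic parameters
#'
#' Defaults reproduce the strongest published setting: all four variances equal
#' to 0.170 (observed-scale heritability 0.2 of per-animal interaction counts),
#' zero genetic correlation, and means \code{qlogis(0.01)/2} so that the median
#' pair interacts with probability 1\% per encounter.
#'
#' @param varAAlpha,varABeta additive genetic variances (logit scale).
#' @param varEpAlpha,varEpBeta permanent environmental variances.
#' @param rA genetic correlation between performer and recipient traits.
#' @param muAlpha,muBeta logit-scale trait means.
#' @return A [GeneticParams-class] object.
#' @examples
#' gp <- geneticParams()
#' underlyingH2(gp)
#' @export
geneticParams <- function(varAAlpha = 0.170, varABeta = varAAlpha,
                          varEpAlpha = varAAlpha, varEpBeta = varABeta,
                          rA = 0,
                          muAlpha = qlogis(0.01) / 2, muBeta = qlogis(0.01) / 2) {
  new("GeneticParams",
    varAAlpha = as.numeric(varAAlpha), varABeta = as.numeric(varABeta),
    varEpAlpha = as.numeric(varEpAlpha), varEpBeta = as.numeric(varEpBeta),
    rA = as.numeric(rA), muAlpha = as.numeric(muAlpha), muBeta = as.numeric(muBeta)
  )
}

#' Published variance presets by target observed-scale heritability
#'
#' Calibrated genetic/permanent-environment variance inputs (all four components
#' equal) that yield observed-scale heritabilities of 0.05, 0.1 and 0.2 for
#' per-animal interaction counts of ~25 successes out of ~2500 encounters.
#' @export
h2oPresets <- c("0.05" = 0.012, "0.1" = 0.038, "0.2" = 0.170)

#' 2x2 genetic covariance matrix of a GeneticParams object
#' @param params a [GeneticParams-class] object.
#' @return symmetric 2x2 matrix (alpha, beta).
#' @export
genCovMatrix <- function(params) {
  cab <- params@rA * sqrt(params@varAAlpha * params@varABeta)
  matrix(c(params@varAAlpha, cab, cab, params@varABeta), 2, 2,
    dimnames = list(c("alpha", "beta"), c("alpha", "beta"))
  )
}

setMethod("show", "GeneticParams", function(object) {
  cat("GeneticParams\n")
  cat(sprintf("  var(A):  alpha = %.4g, beta = %.4g, rA = %.3g\n",
    object@varAAlpha, object@varABeta, object@rA))
  cat(sprintf("  var(Ep): alpha = %.4g, beta = %.4g\n",
    object@varEpAlpha, object@varEpBeta))
  cat(sprintf("  means (logit): mu_alpha = %.4f, mu_beta = %.4f\n",
    object@muAlpha, object@muBeta))
  cat(sprintf("  underlying-scale h2 (performer): %.4f\n", underlyingH2(object)))
})

#' Pedigree of a two-generation population
#'
#' Animals are stored parents-first with consecutive integer IDs; base animals
#' have sire and dam coded 0.
#'
#' @slot id integer animal IDs (1..n, parents before offspring).
#' @slot sire,dam integer parent IDs (0 = unknown).
#' @slot generation integer, 0 for base animals.
#' @export
setClass("Pedigree",
  representation(id = "integer", sire = "integer", dam = "integer",
                 generation = "integer")
)

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@generation) != n)
    return("id, sire, dam, generation must have equal length")
  if (!identical(object@id, seq_len(n)))
    return("ids must be consecutive integers 1..n")
  known <- function(p) p != 0L
  if (any(object@sire[known(object@sire)] >= object@id[known(object@sire)]) ||
      any(object@dam[known(object@dam)] >= object@id[known(object@dam)]))
    return("parents must precede offspring (no cycles)")
  if (any(xor(object@sire == 0L, object@dam == 0L)))
    return("animals must have both parents known or both unknown")
  TRUE
})

setMethod("show", "Pedigree", function(object) {
  cat(sprintf("Pedigree: %d animals (%d base, %d offspring)\n",
    length(object@id), sum(object@generation == 0L),
    sum(object@generation > 0L)))
})

#' @describeIn buildHalfSibPedigree number of animals in a pedigree.
#' @param ped a [Pedigree-class] object.
#' @export
nAnimals <- function(ped) length(ped@id)

#' @describeIn buildHalfSibPedigree IDs of non-base (offspring) animals.
#' @export
offspringIds <- function(ped) ped@id[ped@generation > 0L]

#' @export
setMethod("as.data.frame", "Pedigree", function(x, ...) {
  data.frame(id = x@id, sire = x@sire, dam = x@dam, generation = x@generation)
})

#' Simulated latent-trait effects for a pedigree
#'
#' Per-animal breeding values (A), permanent environmental effects (Ep) and
#' total tendencies P = mu + A + Ep for both the performer (alpha) and the
#' recipient (beta) trait. No residual exists on the latent scale.
#'
#' @slot id integer animal IDs matching the pedigree.
#' @slot A,Ep,P numeric matrices (n x 2, columns alpha/beta).
#' @slot params the [GeneticParams-class] used for simulation.
#' @export
setClass("TraitEffects",
  representation(id = "integer", A = "matrix", Ep = "matrix", P = "matrix",
                 params = "GeneticParams")
)

setValidity("TraitEffects", function(object) {
  n <- length(object@id)
  for (s in c("A", "Ep", "P")) {
    m <- slot(object, s)
    if (!is.numeric(m) || nrow(m) != n || ncol(m) != 2L)
      return(sprintf("%s must be a numeric n x 2 matrix", s))
  }
  mu <- c(object@params@muAlpha, object@params@muBeta)
  expect <- sweep(object@A + object@Ep, 2L, mu, "+")
  if (max(abs(object@P - expect)) > 1e-10)
    return("P must equal mu + A + Ep exactly")
  TRUE
})

setMethod("show", "TraitEffects", function(object) {
  cat(sprintf("TraitEffects for %d animals\n", length(object@id)))
  cat(sprintf("  empirical var(A_alpha) = %.4g, var(A_beta) = %.4g, cor = %.3g\n",
    var(object@A[, 1]), var(object@A[, 2]),
    suppressWarnings(cor(object@A[, 1], object@A[, 2]))))
})

#' @rdname sampleTraitEffects
#' @param effects a [TraitEffects-class] object.
#' @export
breedingValues <- function(effects) effects@A

#' @rdname sampleTraitEffects
#' @export
permanentEnv <- function(effects) effects@Ep

#' @rdname sampleTraitEffects
#' @export
tendencies <- function(effects) effects@P

#' Configuration of the agent-based movement model
#'
#' @slot delta 3x3 motivation-change matrix; entry (B, B') is the per-step
#'   change in motivation for behaviour B while behaviour B' (eat/walk/rest)
#'   is expressed. Diagonal entries are negative.
#' @slot threshold motivation threshold T for initiating a behaviour.
#' @slot stepLength metres moved per time step while walking/approaching.
#' @slot stepDuration seconds per time step (1 s by default, so that the
#'   eat motivation rise rate of 0.025/step gives a ~70 min meal cycle).
#' @slot sensingRange metres within which two animals encounter each other.
#' @slot feederRatio animals per feeder (5 by default).
#' @slot density animals per square metre (fixed at 1).
#' @slot maxSteps non-termination guard for target-driven runs.
#' @export
setClass("MovementConfig",
  representation(delta = "matrix", threshold = "numeric",
                 stepLength = "numeric", stepDuration = "numeric",
                 sensingRange = "numeric", feederRatio = "numeric",
                 density = "numeric", maxSteps = "integer")
)

setValidity("MovementConfig", function(object) {
  d <- object@delta
  if (!all(dim(d) == c(3L, 3L))) return("delta must be 3x3")
  if (any(diag(d) >= 0)) return("delta diagonal must be negative")
  if (any(d[upper.tri(d) | lower.tri(d)] < 0))
    return("delta off-diagonals must be >= 0")
  if (object@threshold <= 0) return("threshold must be > 0")
  if (object@stepLength <= 0 || object@sensingRange <= 0 ||
      object@feederRatio < 1 || object@density <= 0)
    return("stepLength, sensingRange, density must be > 0; feederRatio >= 1")
  TRUE
})

#' Default motivation-change matrix
#'
#' Rows/columns ordered eat, walk, rest; entry (B, B') is the change in
#' motivation for B per step spent expressing B'. Eating drains its own
#' motivation by 1/step; walking and resting alternate with rise/fall rates of
#' 10/step while eating motivation builds up at 0.025/step, producing meals of
#' ~100 s roughly every ~70 min and walk/rest bouts of ~10-20 s.
#' @return 3x3 numeric matrix.
#' @export
defaultDelta <- function() {
  matrix(c(-1, 0, 0,
           0.025, -10, 10,
           0.025, 10, -10),
    nrow = 3, ncol = 3,
    dimnames = list(c("eat", "walk", "rest"), c("eat", "walk", "rest"))
  )
}

#' Construct a movement configuration
#' @param delta 3x3 motivation-change matrix, see [defaultDelta()].
#' @param threshold motivation threshold for starting a behaviour.
#' @param stepLength metres per step while moving.
#' @param stepDuration seconds per step.
#' @param sensingRange encounter radius in metres. The published experiments do
#'   not fix this value; it rescales simulated time but not the genetic
#'   analysis, because every run is stopped on an interaction-count target.
#' @param feederRatio animals per feeder.
#' @param density animals per square metre (pen area = group size / density).
#' @param maxSteps abort guard for interaction-target runs.
#' @return A [MovementConfig-class] object.
#' @export
movementConfig <- function(delta = defaultDelta(), threshold = 100,
                           stepLength = 1, stepDuration = 1,
                           sensingRange = 1, feederRatio = 5,
                           density = 1, maxSteps = 2000000L) {
  new("MovementConfig", delta = delta, threshold = as.numeric(threshold),
    stepLength = as.numeric(stepLength), stepDuration = as.numeric(stepDuration),
    sensingRange = as.numeric(sensingRange), feederRatio = as.numeric(feederRatio),
    density = as.numeric(density), maxSteps = as.integer(maxSteps))
}

setMethod("show", "MovementConfig", function(object) {
  cat("MovementConfig\n")
  cat(sprintf("  threshold T = %g, step = %g m / %g s, sensing range = %g m\n",
    object@threshold, object@stepLength, object@stepDuration,
    object@sensingRange))
  cat(sprintf("  feeder ratio %g:1, density %g animals/m2\n",
    object@feederRatio, object@density))
})

#' Pair-level encounter/interaction table
#'
#' One row per ordered pair (performer i, recipient j) of pen mates that
#' encountered each other at least once: the number of encounters N_ij (the
#' number of potential interactions) and the number of realized directed
#' interactions y_ij. This is the response data of the binomial GLMM.
#'
#' @slot data data.frame with columns pen, performer, recipient,
#'   nEncounters, nInteractions.
#' @export
setClass("PairTable", representation(data = "data.frame"))

setValidity("PairTable", function(object) {
  d <- object@data
  need <- c("pen", "performer", "recipient", "nEncounters", "nInteractions")
  if (!all(need %in% names(d))) return("missing pair table columns")
  if (nrow(d) && any(d$nInteractions > d$nEncounters | d$nInteractions < 0))
    return("0 <= nInteractions <= nEncounters violated")
  if (nrow(d) && any(d$performer == d$recipient))
    return("performer must differ from recipient")
  if (nrow(d) && any(d$nEncounters < 1))
    return("only pairs that met at least once are kept")
  TRUE
})

#' @rdname pairTable
#' @param x a [PairTable-class] object.
#' @export
pairData <- function(x) x@data

setMethod("show", "PairTable", function(object) {
  d <- object@data
  cat(sprintf("PairTable: %d ordered pairs, %d pens\n", nrow(d),
    length(unique(d$pen))))
  cat(sprintf("  total encounters %g, interactions %g (ratio %.4g)\n",
    sum(d$nEncounters), sum(d$nInteractions),
    sum(d$nInteractions) / max(1, sum(d$nEncounters))))
})

#' Construct a pair table from per-pen count matrices or a data.frame
#' @param data data.frame with columns pen, performer, recipient, nEncounters,
#'   nInteractions; pairs with zero encounters are dropped.
#' @return A [PairTable-class] object.
#' @export
pairTable <- function(data) {
  data <- data[data$nEncounters >= 1, , drop = FALSE]
  rownames(data) <- NULL
  new("PairTable", data = data)
}

#' Animal-model REML fit of per-animal interaction counts
#'
#' @slot varA,varE estimated genetic and residual variance.
#' @slot h2o observed-scale heritability varA / (varA + varE).
#' @slot mu estimated mean.
#' @slot ebv named numeric vector of BLUP breeding values.
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot converged logical.
#' @export
setClass("LmmFit",
  representation(varA = "numeric", varE = "numeric", h2o = "numeric",
                 mu = "numeric", ebv = "numeric", logLik = "numeric",
                 converged = "logical")
)

setValidity("LmmFit", function(object) {
  if (object@varA < 0 || object@varE < 0) return("variances must be >= 0")
  if (object@h2o < 0 || object@h2o > 1) return("h2o must lie in [0, 1]")
  TRUE
})

setMethod("show", "LmmFit", function(object) {
  cat("Animal-model REML fit (interaction counts)\n")
  cat(sprintf("  var(A) = %.4g, var(e) = %.4g, h2_o = %.4f\n",
    object@varA, object@varE, object@h2o))
  cat(sprintf("  mu = %.4g, REML logLik = %.4f, converged: %s\n",
    object@mu, object@logLik, object@converged))
})

#' Binomial logit GLMM fit for performer/recipient effects
#'
#' @slot params estimated variance components as a [GeneticParams-class]
#'   (means slot holds the intercept on the alpha side and 0 on the beta side).
#' @slot fixef named fixed-effect estimates (intercept + pen contrasts).
#' @slot ebvAlpha,ebvBeta named EBV vectors for all pedigree animals.
#' @slot epAlpha,epBeta permanent-environment solutions (recorded animals).
#' @slot niter outer PQL iterations used.
#' @slot converged logical.
#' @slot trace data.frame of parameter values per outer iteration.
#' @slot diagnostics list with the final mixed-model-equation residual norm,
#'   working REML deviance and optimizer state.
#' @export
setClass("SocialGlmmFit",
  representation(params = "GeneticParams", fixef = "numeric",
                 ebvAlpha = "numeric", ebvBeta = "numeric",
                 epAlpha = "numeric", epBeta = "numeric",
                 niter = "integer", converged = "logical",
                 trace = "data.frame", diagnostics = "list")
)

setMethod("show", "SocialGlmmFit", function(object) {
  cat("Binomial logit GLMM (PQL, pedigree Kronecker covariance)\n")
  p <- object@params
  cat(sprintf("  var(A_alpha) = %.4g, var(A_beta) = %.4g, cov = %.4g\n",
    p@varAAlpha, p@varABeta, p@rA * sqrt(p@varAAlpha * p@varABeta)))
  cat(sprintf("  var(Ep_alpha) = %.4g, var(Ep_beta) = %.4g\n",
    p@varEpAlpha, p@varEpBeta))
  cat(sprintf("  intercept = %.4f, %d pen level(s); %d outer iterations, converged: %s\n",
    object@fixef[1], length(object@fixef), object@niter, object@converged))
})

#' @rdname fitSocialGlmm
#' @param fit a [SocialGlmmFit-class] object.
#' @export
ebvAlpha <- function(fit) fit@ebvAlpha

#' @rdname fitSocialGlmm
#' @export
ebvBeta <- function(fit) fit@ebvBeta

#' @rdname fitSocialGlmm
#' @export
varianceComponents <- function(fit) {
  p <- fit@params
  c(varAAlpha = p@varAAlpha, varABeta = p@varABeta,
    covA = p@rA * sqrt(p@varAAlpha * p@varABeta),
    varEpAlpha = p@varEpAlpha, varEpBeta = p@varEpBeta)
}

#' Scenario configuration for replicated simulation experiments
#'
#' @slot nSires,damsPerSire,offspringPerDam half-sib design counts.
#' @slot nPens,groupSize pen structure (groupSize * nPens = total offspring).
#' @slot targetInteractions stopping target per pen.
#' @slot params genetic parameter inputs.
#' @slot movement movement configuration.
#' @slot nReplicates number of replicate simulations.
#' @slot seed root seed; replicate r derives independent genetics, movement
#'   and interaction streams from it.
#' @export
setClass("ScenarioConfig",
  representation(nSires = "integer", damsPerSire = "integer",
                 offspringPerDam = "integer", nPens = "integer",
                 groupSize = "integer", targetInteractions = "integer",
                 params = "GeneticParams", movement = "MovementConfig",
                 nReplicates = "integer", seed = "integer")
)

setValidity("ScenarioConfig", function(object) {
  total <- object@nSires * object@damsPerSire * object@offspringPerDam
  if (object@nPens * object@groupSize != total)
    return("groupSize * nPens must equal the number of offspring")
  TRUE
})

#' Construct a scenario configuration
#'
#' Defaults are the published default scenario: 2000 offspring of 100 sires x 4
#' dams x 5 offspring, housed in 20 pens of 100 at 1 animal/m2, simulated until
#' at least 10,000 interactions per pen (~100 per animal).
#'
#' @param nSires,damsPerSire,offspringPerDam half-sib design.
#' @param nPens,groupSize pen structure.
#' @param targetInteractions interaction stopping target per pen.
#' @param params a [GeneticParams-class] object.
#' @param movement a [MovementConfig-class] object.
#' @param nReplicates replicate count (published analyses use 20-25).
#' @param seed integer root seed.
#' @return A [ScenarioConfig-class] object.
#' @export
scenarioConfig <- function(nSires = 100, damsPerSire = 4, offspringPerDam = 5,
                           nPens = 20, groupSize = 100,
                           targetInteractions = 10000,
                           params = geneticParams(),
                           movement = movementConfig(),
                           nReplicates = 20, seed = 1) {
  new("ScenarioConfig", nSires = as.integer(nSires),
    damsPerSire = as.integer(damsPerSire),
    offspringPerDam = as.integer(offspringPerDam),
    nPens = as.integer(nPens), groupSize = as.integer(groupSize),
    targetInteractions = as.integer(targetInteractions),
    params = params, movement = movement,
    nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig: %d sires x %d dams x %d offspring; %d pens of %d\n",
    object@nSires, object@damsPerSire, object@offspringPerDam,
    object@nPens, object@groupSize))
  cat(sprintf("  target %d interactions/pen, %d replicates, seed %d\n",
    object@targetInteractions, object@nReplicates, object@seed))
})
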