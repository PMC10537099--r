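## Seed streams: genetics, movement and interaction sampling must be
## perturbation-independent across scenario variants, so each phase draws from
## its own derived seed rather than from one shared RNG sequence.
streamSeed <- function(rootSeed, stream, k = 0L) {
  offsets <- c(genetics = 11L, movement = 23L, interactions = 37L,
               replicate = 53L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  as.integer((as.numeric(rootSeed) * 7919 + offsets[[stream]] * 1009 +
                as.numeric(k)) %% 2147483629)
}

withStream <- function(rootSeed, stream, k = 0L, expr) {
  set.seed(streamSeed(rootSeed, stream, k))
  expr
}

#' Build a two-generation half-sib pedigree
#'
#' Base animals come first (all sires, then all dams), then the offspring;
#' each sire is mated to `damsPerSire` dams and each dam produces
#' `offspringPerDam` offspring. Sires and dams are disjoint base animals, so
#' paternal half-sib families of size `damsPerSire * offspringPerDam` are
#' nested over full-sib families of size `offspringPerDam`.
#'
#' @param nSires,damsPerSire,offspringPerDam positive integer design counts.
#'   The published default is 100 sires x 4 dams x 5 offspring = 2000
#'   offspring from 500 base parents.
#' @return A [Pedigree-class] object.
#' @examples
#' ped <- buildHalfSibPedigree(2, 2, 3)
#' as.data.frame(ped)
#' @export
buildHalfSibPedigree <- function(nSires, damsPerSire, offspringPerDam) {
  counts <- c(nSires, damsPerSire, offspringPerDam)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop("nSires, damsPerSire and offspringPerDam must be positive integers")
  nSires <- as.integer(nSires)
  damsPerSire <- as.integer(damsPerSire)
  offspringPerDam <- as.integer(offspringPerDam)
  nDams <- nSires * damsPerSire
  nOff <- nDams * offspringPerDam
  sireIds <- seq_len(nSires)
  damIds <- nSires + seq_len(nDams)
  damSire <- rep(sireIds, each = damsPerSire) # mate of each dam
  offSire <- rep(damSire, each = offspringPerDam)
  offDam <- rep(damIds, each = offspringPerDam)
  new("Pedigree",
    id = seq_len(nSires + nDams + nOff),
    sire = c(rep(0L, nSires + nDams), offSire),
    dam = c(rep(0L, nSires + nDams), offDam),
    generation = c(rep(0L, nSires + nDams), rep(1L, nOff))
  )
}

## PSD-safe matrix square root (chol fails for singular G)
psdSqrt <- function(G) {
  e <- eigen(G, symmetric = TRUE)
  if (min(e$values) < -1e-10) stop("covariance matrix is not positive semi-definite")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(G)) %*% t(e$vectors)
}

rbvn <- function(n, G) {
  matrix(rnorm(2 * n), n, 2) %*% psdSqrt(G)
}

#' Sample breeding values and permanent environmental effects over a pedigree
#'
#' Base animals receive bivariate-normal breeding values with covariance
#' \code{genCovMatrix(params)}; each offspring receives the parent average plus
#' a Mendelian sampling deviation with half that covariance. Permanent
#' environmental effects are sampled independently per trait (zero cross-trait
#' correlation) for the offspring generation only, since only offspring are
#' simulated behaving. Total tendencies are P = mu + A + Ep with no latent
#' residual.
#'
#' @param ped a [Pedigree-class] (parents ordered before offspring).
#' @param params a [GeneticParams-class] object.
#' @param seed optional integer; when supplied the draw uses the dedicated
#'   genetics stream derived from it.
#' @return A [TraitEffects-class] object.
#' @examples
#' ped <- buildHalfSibPedigree(5, 4, 5)
#' eff <- sampleTraitEffects(ped, geneticParams(), seed = 1)
#' head(tendencies(eff))
#' @export
sampleTraitEffects <- function(ped, params, seed = NULL) {
  validObject(params)
  if (!is.null(seed)) set.seed(streamSeed(seed, "genetics"))
  n <- nAnimals(ped)
  G <- genCovMatrix(params)
  A <- matrix(0, n, 2, dimnames = list(NULL, c("alpha", "beta")))
  isBase <- ped@generation == 0L
  A[isBase, ] <- rbvn(sum(isBase), G)
  off <- which(!isBase)
  if (length(off)) {
    ms <- rbvn(length(off), G / 2)
    A[off, ] <- 0.5 * A[ped@sire[off], , drop = FALSE] +
      0.5 * A[ped@dam[off], , drop = FALSE] + ms
  }
  Ep <- matrix(0, n, 2, dimnames = list(NULL, c("alpha", "beta")))
  Ep[off, 1] <- rnorm(length(off), 0, sqrt(params@varEpAlpha))
  Ep[off, 2] <- rnorm(length(off), 0, sqrt(params@varEpBeta))
  P <- sweep(A + Ep, 2L, c(params@muAlpha, params@muBeta), "+")
  new("TraitEffects", id = ped@id, A = A, Ep = Ep, P = P, params = params)
}

#' Underlying-scale heritability of the performer trait
#'
#' For the logistic threshold model the residual on the latent scale is the
#' link variance pi^2/3, so the performer-trait heritability on the underlying
#' scale is varAAlpha divided by the sum of all four latent variance components
#' plus pi^2/3. All-zero variances return 0 by convention.
#'
#' @param params a [GeneticParams-class] object.
#' @return heritability in \[0, 1).
#' @examples
#' underlyingH2(geneticParams(varAAlpha = 0.170)) # ~0.043
#' @export
underlyingH2 <- function(params) {
  tot <- params@varAAlpha + params@varABeta + params@varEpAlpha +
    params@varEpBeta
  if (tot == 0 && params@varAAlpha == 0) return(0)
  params@varAAlpha / (tot + LINK_VARIANCE)
}

#' Interaction probability of an extreme-ranking performer
#'
#' Probability that an animal whose performer tendency sits `nSd` genetic
#' standard deviations from the mean interacts with an average pen mate
#' (recipient tendency at its mean) during an encounter:
#' logistic(mu_alpha + nSd * sigma_A_alpha + mu_beta).
#'
#' @param params a [GeneticParams-class] object.
#' @param nSd number of genetic standard deviations above (+) or below (-) the
#'   performer mean.
#' @return probability in (0, 1).
#' @examples
#' extremeInteractionProbability(geneticParams(varAAlpha = 0.170), 2)  # ~0.022
#' extremeInteractionProbability(geneticParams(varAAlpha = 0.170), -2) # ~0.004
#' @export
extremeInteractionProbability <- function(params, nSd) {
  plogis(params@muAlpha + nSd * sqrt(params@varAAlpha) + params@muBeta)
}
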