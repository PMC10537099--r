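#' Probability of a directed social interaction at an encounter
#'
#' The probability that animal i performs the behaviour towards animal j,
#' given that they encounter, is the logistic transform of the sum of i's
#' performer tendency and j's recipient tendency. Computed with
#' [stats::plogis()], which is overflow-safe for any finite input.
#'
#' @param pAlphaI performer tendency of the performer (logit scale).
#' @param pBetaJ recipient tendency of the recipient.
#' @return probability in (0, 1); vectorized.
#' @examples
#' interactionProbability(qlogis(0.01) / 2, qlogis(0.01) / 2) # 0.01
#' @export
interactionProbability <- function(pAlphaI, pBetaJ) {
  plogis(pAlphaI + pBetaJ)
}

#' Sample directed interactions for a set of encounters
#'
#' For every unordered encounter pair both ordered directions are sampled
#' independently: i performs towards j with probability
#' `plogis(P_alpha_i + P_beta_j)` and j towards i with
#' `plogis(P_alpha_j + P_beta_i)`, so an animal can perform and receive within
#' the same time step. This is the R reference implementation used on
#' encounter lists; [simulatePen()] performs the same sampling in the
#' simulation loop.
#'
#' @param encounters integer matrix of unordered pairs (columns i, j), e.g.
#'   from [detectEncounters()]; repeated rows represent repeated encounter
#'   steps of the same pair.
#' @param pAlpha,pBeta latent tendencies indexed by the pair entries.
#' @param seed optional seed for the interaction stream.
#' @return data.frame with one row per realized directed interaction
#'   (columns performer, recipient, encounterRow).
#' @export
sampleInteractions <- function(encounters, pAlpha, pBeta, seed = NULL) {
  if (!is.null(seed)) set.seed(streamSeed(seed, "interactions"))
  encounters <- matrix(as.integer(encounters), ncol = 2)
  i <- encounters[, 1]
  j <- encounters[, 2]
  pij <- interactionProbability(pAlpha[i], pBeta[j])
  pji <- interactionProbability(pAlpha[j], pBeta[i])
  hitIJ <- runif(length(i)) < pij
  hitJI <- runif(length(j)) < pji
  data.frame(
    performer = c(i[hitIJ], j[hitJI]),
    recipient = c(j[hitIJ], i[hitJI]),
    encounterRow = c(which(hitIJ), which(hitJI))
  )
}

#' Interaction-count stopping rule
#'
#' A pen's simulation stops once the total number of logged interactions
#' reaches the target: 10,000 in the default scenario, 100,000 for the
#' record-number experiment, and 100 x group size for the group-size
#' experiment.
#'
#' @param totalInteractions running interaction total (or a [PairTable-class]
#'   whose interactions are summed).
#' @param target required interaction count.
#' @return TRUE once the target is reached.
#' @examples
#' stoppingRule(9999, 10000)  # FALSE
#' stoppingRule(10000, 10000) # TRUE
#' @export
stoppingRule <- function(totalInteractions, target) {
  if (is(totalInteractions, "PairTable"))
    totalInteractions <- sum(pairData(totalInteractions)$nInteractions)
  totalInteractions >= target
}

#' Combine per-pen simulations into one pair table
#' @param sims list of `penSim` results (one per pen).
#' @return A [PairTable-class] over all pens.
#' @export
combinePairTables <- function(sims) {
  pairTable(do.call(rbind, lapply(sims, `[[`, "pairs")))
}
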