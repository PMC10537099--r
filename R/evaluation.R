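#' Total breeding value across the performer and recipient traits
#'
#' The selection target is the sum of the two latent-trait breeding values,
#' for true and estimated values alike: the per-generation change in the mean
#' total BV equals the response to selection in the underlying tendency.
#'
#' @param alpha,beta per-animal (E)BV for the performer and recipient trait;
#'   `alpha` may also be an n x 2 matrix (columns alpha, beta) or a
#'   [SocialGlmmFit-class], in which case `beta` is ignored.
#' @return numeric vector of per-animal totals.
#' @examples
#' totalBV(0.3, -0.1)
#' @export
totalBV <- function(alpha, beta = NULL) {
  if (is(alpha, "SocialGlmmFit")) return(alpha@ebvAlpha + alpha@ebvBeta)
  if (is.matrix(alpha) && is.null(beta)) return(alpha[, 1] + alpha[, 2])
  alpha + beta
}

#' Accuracy and bias of estimated breeding values
#'
#' Accuracy is the Pearson correlation between true and estimated (total)
#' breeding values; bias is the regression coefficient of true on estimated
#' values, so a slope below 1 indicates overestimated EBVs.
#'
#' @param trueBV,ebv per-animal true and estimated values (matched order).
#' @return list with elements `accuracy` and `bias` (both NA with a warning
#'   for degenerate zero-variance input).
#' @examples
#' accuracyAndBias(c(1, 2, 3), c(2, 4, 6)) # accuracy 1, bias 0.5
#' @export
accuracyAndBias <- function(trueBV, ebv) {
  stopifnot(length(trueBV) == length(ebv), length(ebv) >= 3)
  if (var(trueBV) == 0 || var(ebv) == 0) {
    warning("zero variance in BV or EBV; accuracy/bias undefined")
    return(list(accuracy = NA_real_, bias = NA_real_))
  }
  list(accuracy = cor(trueBV, ebv),
    bias = cov(trueBV, ebv) / var(ebv))
}

#' Selection-index upper bound on EBV accuracy
#'
#' Accuracy of the best linear index of three information sources for an
#' animal's own breeding value: its own limiting repeated-record phenotype
#' (which converges to A + Ep as records accumulate), the mean of its full
#' sibs' limiting phenotypes, and the mean of its half sibs' limiting
#' phenotypes. With equal genetic and permanent environmental variance and
#' zero genetic correlation between the performer and recipient traits, the
#' same bound applies to the total-EBV accuracy. Solves the index equations
#' P b = g and returns sqrt(b'g / sigma2_A); sib counts may be `Inf` for the
#' large-family limit.
#'
#' @param nFullSibs,nHalfSibs numbers of full/half sibs with records
#'   (non-negative, possibly `Inf`).
#' @param varRatio ratio of permanent environmental to genetic variance
#'   (1 in the published setting).
#' @return accuracy bound in \[0, 1\].
#' @examples
#' selectionIndexBound(4, 15, 1)      # half-sib design bound, ~0.77
#' selectionIndexBound(Inf, Inf, 1)   # infinite-sib limit, sqrt(2/3) ~ 0.82
#' selectionIndexBound(0, 0, 1)       # own records only, sqrt(0.5)
#' @export
selectionIndexBound <- function(nFullSibs, nHalfSibs, varRatio = 1) {
  stopifnot(nFullSibs >= 0, nHalfSibs >= 0, varRatio >= 0)
  v <- 1 + varRatio # var of a limiting phenotype A + Ep, sigma2_A = 1
  sibVar <- function(k, r) { # var of the mean of k sibs' phenotypes
    if (k == 0) return(NA_real_)
    if (is.infinite(k)) r else (v + (k - 1) * r) / k
  }
  P <- matrix(c(
    v, 0.5, 0.25,
    0.5, sibVar(nFullSibs, 0.5), 0.25,
    0.25, 0.25, sibVar(nHalfSibs, 0.25)
  ), 3, 3, byrow = TRUE)
  g <- c(1, 0.5, 0.25)
  use <- c(TRUE, nFullSibs > 0, nHalfSibs > 0)
  b <- solve(P[use, use, drop = FALSE], g[use])
  sqrt(sum(b * g[use]))
}

#' Summarize replicate-level accuracy and bias
#'
#' Averages per-replicate accuracy and bias and attaches the standard error
#' of the mean (SD / sqrt(replicates)), the convention used when reporting
#' replicated simulation experiments.
#'
#' @param reps data.frame with columns `accuracy` and `bias` (one row per
#'   replicate).
#' @return one-row data.frame with means and standard errors.
#' @export
summarizeReplicates <- function(reps) {
  n <- nrow(reps)
  data.frame(
    nReplicates = n,
    accuracy = mean(reps$accuracy), accuracySE = sd(reps$accuracy) / sqrt(n),
    bias = mean(reps$bias), biasSE = sd(reps$bias) / sqrt(n)
  )
}
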