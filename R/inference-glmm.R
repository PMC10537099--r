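## Pedigree-structured binomial logit GLMM, estimated by penalized
## quasi-likelihood: iterate (a) working response and weights from the current
## linear predictor, (b) REML estimation of the variance components on the
## working scale via sparse Henderson mixed-model equations, (c) joint
## fixed/random solutions. The genetic covariance of the stacked
## performer/recipient breeding values is G0 (2x2) Kronecker the relationship
## matrix A; permanent environmental effects are iid per trait.

thetaToParams <- function(theta, intercept = 0) {
  geneticParams(
    varAAlpha = exp(theta[1]), varABeta = exp(theta[2]),
    varEpAlpha = exp(theta[4]), varEpBeta = exp(theta[5]),
    rA = tanh(theta[3]), muAlpha = intercept, muBeta = 0
  )
}

paramsToTheta <- function(params, floorVar = 1e-6) {
  c(log(max(params@varAAlpha, floorVar)), log(max(params@varABeta, floorVar)),
    atanh(min(max(params@rA, -0.999), 0.999)),
    log(max(params@varEpAlpha, floorVar)), log(max(params@varEpBeta, floorVar)))
}

## inverse of G0 = [[vAa, c], [c, vAb]] with a guard keeping it invertible
g0Inverse <- function(theta) {
  vAa <- exp(theta[1]); vAb <- exp(theta[2]); r <- tanh(theta[3])
  if (abs(r) > 0.999) r <- sign(r) * 0.999
  cab <- r * sqrt(vAa * vAb)
  G0 <- matrix(c(vAa, cab, cab, vAb), 2, 2)
  list(inv = solve(G0), logDet = log(det(G0)))
}

#' Fit the pedigree-structured binomial logit GLMM to a pair table
#'
#' Models the number of directed interactions y_ij out of N_ij encounters of
#' each ordered pair (performer i, recipient j) as binomial with
#' logit(p_ij) = mu + pen_k + A_alpha_i + A_beta_j + Ep_alpha_i + Ep_beta_j.
#' Breeding values for the performer and recipient traits are correlated
#' across animals through the pedigree (2x2 genetic covariance matrix
#' Kronecker the numerator relationship matrix); permanent environmental
#' effects are independent per trait. Estimation is penalized
#' quasi-likelihood with binomial weights and dispersion fixed at 1:
#' solutions come from the sparse Henderson mixed-model equations of the
#' working linearized model (Cholesky with a pen-blocked elimination order),
#' and the variance components maximize the restricted likelihood of that
#' working model. EBVs of base animals without own records are obtained
#' through the pedigree. Pairs that never met carry no information and are
#' absent from the table by construction.
#'
#' @param pairs a [PairTable-class] object (all pens analysed jointly).
#' @param ped a [Pedigree-class] covering every animal in the table.
#' @param start optional [GeneticParams-class] starting values; the default
#'   starts all four variances at half the strongest published preset.
#' @param varComponents optional [GeneticParams-class]; when supplied the
#'   variance components are fixed at these values and only the solutions are
#'   iterated.
#' @param tol relative convergence tolerance of the variance optimizer.
#' @param maxOuter maximum rounds of (working-model update, variance
#'   re-estimation).
#' @param maxEval maximum REML objective evaluations per round.
#' @param verbose print per-round progress.
#' @return A [SocialGlmmFit-class] object.
#' @examples
#' ped <- buildHalfSibPedigree(4, 2, 2)
#' eff <- sampleTraitEffects(ped, geneticParams(varAAlpha = 0.17), seed = 1)
#' off <- offspringIds(ped)
#' sim <- simulatePen(tendencies(eff)[off, 1], tendencies(eff)[off, 2],
#'   targetInteractions = 200, ids = off, seed = 1)
#' fit <- fitSocialGlmm(pairTable(sim$pairs), ped, maxOuter = 2)
#' @export
fitSocialGlmm <- function(pairs, ped, start = NULL, varComponents = NULL,
                          tol = 1e-6, maxOuter = 10L, maxEval = 300L,
                          verbose = FALSE) {
  d <- pairData(pairs)
  if (!nrow(d)) stop("empty pair table")
  q <- nAnimals(ped)
  if (any(!c(d$performer, d$recipient) %in% ped@id))
    stop("pair table contains animals absent from the pedigree")
  Ainv <- relationshipInverse(ped)
  rec <- sort(unique(c(d$performer, d$recipient)))
  nRec <- length(rec)
  m <- nrow(d)
  perf <- match(d$performer, ped@id)
  recv <- match(d$recipient, ped@id)
  epPerf <- match(d$performer, rec)
  epRecv <- match(d$recipient, rec)
  penF <- factor(d$pen)

  X <- if (nlevels(penF) > 1) {
    Matrix::sparse.model.matrix(~penF, data = data.frame(penF = penF))
  } else {
    Matrix::Matrix(1, m, 1, sparse = TRUE)
  }
  colnames(X) <- c("(Intercept)",
    if (nlevels(penF) > 1) paste0("pen", levels(penF)[-1]))
  p <- ncol(X)
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(m), 4L),
    j = c(perf, q + recv, 2L * q + epPerf, 2L * q + nRec + epRecv),
    x = 1, dims = c(m, 2L * q + 2L * nRec)
  )
  M <- cbind(X, Z)
  nc <- ncol(M)
  y <- as.numeric(d$nInteractions)
  Nn <- as.numeric(d$nEncounters)

  ## Pen-blocked elimination order: the effects of each pen's recorded
  ## animals form a near-dense clique through the pair design, while pens are
  ## only coupled through the pedigree of the (record-free) parents; ordering
  ## pen blocks first, then record-free animals, then the fixed effects keeps
  ## Cholesky fill-in close to minimal.
  recPen <- d$pen[match(rec, d$performer)]
  recPen[is.na(recPen)] <- d$pen[match(rec[is.na(recPen)], d$recipient)]
  ord <- unlist(lapply(split(seq_len(nRec), recPen), function(e) {
    idx <- match(rec[e], ped@id)
    c(p + idx, p + q + idx, p + 2L * q + e, p + 2L * q + nRec + e)
  }), use.names = FALSE)
  free <- setdiff(seq_len(q), match(rec, ped@id))
  ord <- c(ord, p + free, p + q + free, seq_len(p))
  Mp <- M[, ord]

  ## fixed-pattern skeletons of the permuted penalty matrix: Sigma^-1 =
  ## g11*K11 + g12*(K12 + K12') + g22*K22 + (1/vEpA)*D1 + (1/vEpB)*D2
  zp <- Matrix::Matrix(0, p, p, sparse = TRUE)
  padPerm <- function(B) {
    Matrix::forceSymmetric(Matrix::bdiag(zp, B)[ord, ord])
  }
  z2 <- Matrix::Matrix(0, q, q, sparse = TRUE)
  zr <- Matrix::Matrix(0, nRec, nRec, sparse = TRUE)
  K11 <- padPerm(Matrix::bdiag(Ainv, z2, zr, zr))
  K22 <- padPerm(Matrix::bdiag(z2, Ainv, zr, zr))
  K12 <- {
    B <- rbind(cbind(z2, Ainv), cbind(Ainv, z2))
    padPerm(Matrix::bdiag(B, zr, zr))
  }
  D1 <- padPerm(Matrix::bdiag(z2, z2, Matrix::Diagonal(nRec), zr))
  D2 <- padPerm(Matrix::bdiag(z2, z2, zr, Matrix::Diagonal(nRec)))

  sigmaPad <- function(th) {
    g <- g0Inverse(th)
    list(M = g$inv[1, 1] * K11 + g$inv[1, 2] * K12 + g$inv[2, 2] * K22 +
      (1 / exp(th[4])) * D1 + (1 / exp(th[5])) * D2,
      logDetG0 = g$logDet)
  }

  ## Fixed-pattern assembly of C = M'WM + Sigma^-1: the sparsity pattern of
  ## every component is constant across variance evaluations, so each
  ## component's entries are scattered into the union pattern through
  ## precomputed index maps instead of repeated sparse additions.
  dsKey <- function(S) {
    S <- as(Matrix::forceSymmetric(S), "CsparseMatrix")
    list(S = S, key = S@i + as.numeric(nc) * rep.int(seq_len(ncol(S)),
      diff(S@p)))
  }
  noCancel <- function(S) { S@x <- abs(S@x) + 1; S }
  comps <- lapply(list(K11, K12, K22, D1, D2), dsKey)
  ## union pattern (weights enter later; use a positive stand-in for M'WM)
  patt0 <- Matrix::forceSymmetric(Matrix::crossprod(Mp))
  U <- Reduce(`+`, lapply(c(list(patt0), lapply(comps, `[[`, "S")),
    noCancel))
  U <- as(Matrix::forceSymmetric(U), "CsparseMatrix")
  keyU <- U@i + as.numeric(nc) * rep.int(seq_len(ncol(U)), diff(U@p))
  maps <- lapply(comps, function(cmp) match(cmp$key, keyU))
  compX <- lapply(comps, function(cmp) cmp$S@x)
  assembleC <- function(MtWMx, mapW, th) {
    g <- g0Inverse(th)
    wgt <- c(g$inv[1, 1], g$inv[1, 2], g$inv[2, 2],
      1 / exp(th[4]), 1 / exp(th[5]))
    xx <- numeric(length(keyU))
    xx[mapW] <- MtWMx
    for (k in seq_along(maps))
      xx[maps[[k]]] <- xx[maps[[k]]] + wgt[k] * compX[[k]]
    C <- U
    C@x <- xx
    list(C = C, logDetG0 = g$logDet)
  }

  fixed <- !is.null(varComponents)
  theta <- if (fixed) paramsToTheta(varComponents)
    else if (!is.null(start)) paramsToTheta(start)
    else paramsToTheta(geneticParams(varAAlpha = 0.5 * h2oPresets[["0.2"]],
      rA = 0))

  p0 <- min(max(sum(y) / sum(Nn), 1e-6), 1 - 1e-6)
  eta <- rep(qlogis(p0), m)
  sol <- numeric(nc)
  chol0 <- NULL
  trace <- NULL
  converged <- FALSE
  dev <- NA_real_
  nEvalTot <- 0L

  ## working data (MtWM, rhs, zWz) from the current linear predictor
  workingData <- function(eta) {
    mu <- plogis(eta)
    wt <- pmax(Nn * mu * (1 - mu), 1e-12)
    z <- eta + (y / Nn - mu) / pmax(mu * (1 - mu), 1e-12)
    S <- as(Matrix::forceSymmetric(Matrix::crossprod(Mp * sqrt(wt))),
      "CsparseMatrix")
    keyS <- S@i + as.numeric(nc) * rep.int(seq_len(ncol(S)), diff(S@p))
    list(
      MtWMx = S@x, mapW = match(keyS, keyU),
      rhs = as.numeric(Matrix::crossprod(Mp, wt * z)),
      zWz = sum(wt * z^2), wt = wt, z = z
    )
  }
  factorize <- function(C) {
    if (is.null(chol0)) {
      chol0 <<- Matrix::Cholesky(C, LDL = FALSE, super = TRUE, perm = FALSE)
      chol0
    } else {
      chol0 <<- Matrix::update(chol0, C)
      chol0
    }
  }
  solveMme <- function(wd, th) {
    cc <- assembleC(wd$MtWMx, wd$mapW, th)
    ch <- factorize(cc$C)
    as.numeric(Matrix::solve(ch, wd$rhs, system = "A"))
  }

  iter <- 0L
  for (round in seq_len(maxOuter)) {
    ## (a) IRLS at the current variance components
    for (k in seq_len(8L)) {
      iter <- iter + 1L
      wd <- workingData(eta)
      solNew <- suppressWarnings(solveMme(wd, theta))
      etaNew <- as.numeric(Mp %*% solNew)
      dEta <- max(abs(etaNew - eta)) / (1 + max(abs(etaNew)))
      eta <- etaNew
      sol <- solNew
      if (dEta < 1e-6) break
    }

    ## (b) REML of the working linearized model over the variance parameters
    wd <- workingData(eta)
    objective <- function(th) {
      if (any(abs(th) > 20)) return(1e10)
      nEvalTot <<- nEvalTot + 1L
      cc <- assembleC(wd$MtWMx, wd$mapW, th)
      ch <- suppressWarnings(tryCatch(factorize(cc$C),
        error = function(e) NULL))
      if (is.null(ch)) return(1e10)
      ldet <- 2 * Matrix::determinant(ch, logarithm = TRUE,
        sqrt = TRUE)$modulus
      s <- suppressWarnings(as.numeric(Matrix::solve(ch, wd$rhs,
        system = "A")))
      val <- as.numeric(ldet + q * cc$logDetG0 + nRec * (th[4] + th[5]) +
        wd$zWz - sum(s * wd$rhs))
      if (!is.finite(val)) 1e10 else val
    }
    if (!fixed) {
      opt <- nlminb(theta, objective,
        control = list(eval.max = maxEval, iter.max = 150,
          rel.tol = max(tol, 1e-10)))
      thetaNew <- opt$par
      dev <- opt$objective
    } else {
      thetaNew <- theta
      dev <- objective(theta)
    }
    dTheta <- max(abs(thetaNew - theta))
    theta <- thetaNew
    trace <- rbind(trace, data.frame(round = round,
      varAAlpha = exp(theta[1]), varABeta = exp(theta[2]),
      rA = tanh(theta[3]), varEpAlpha = exp(theta[4]),
      varEpBeta = exp(theta[5]), deviance = dev, dTheta = dTheta))
    if (verbose)
      message(sprintf("round %d: dev=%.3f dTheta=%.2e evals=%d",
        round, dev, dTheta, nEvalTot))
    if (fixed || dTheta < 1e-4) {
      converged <- TRUE
      break
    }
  }
  ## final solutions at the converged variance components
  wd <- workingData(eta)
  sol <- suppressWarnings(solveMme(wd, theta))
  eta <- as.numeric(Mp %*% sol)

  ## normal-equations residual check on the final system, assembled
  ## independently of the index-mapped fast path
  si <- sigmaPad(theta)
  MtWM <- Matrix::forceSymmetric(Matrix::crossprod(Mp * sqrt(wd$wt)))
  Cfin <- Matrix::forceSymmetric(MtWM + si$M)
  mmeResidual <- max(abs(as.numeric(Cfin %*% sol) - wd$rhs))

  full <- numeric(nc)
  full[ord] <- sol
  b <- full[seq_len(p)]
  names(b) <- colnames(X)
  uA <- full[p + seq_len(q)]
  uB <- full[p + q + seq_len(q)]
  uEa <- full[p + 2 * q + seq_len(nRec)]
  uEb <- full[p + 2 * q + nRec + seq_len(nRec)]
  names(uA) <- names(uB) <- ped@id
  names(uEa) <- names(uEb) <- rec

  new("SocialGlmmFit",
    params = thetaToParams(theta, intercept = unname(b[1])),
    fixef = b, ebvAlpha = uA, ebvBeta = uB, epAlpha = uEa, epBeta = uEb,
    niter = iter, converged = converged,
    trace = as.data.frame(trace),
    diagnostics = list(mmeResidual = mmeResidual, deviance = dev,
      theta = theta, nPairs = m, nPens = nlevels(penF),
      nObjectiveEvals = nEvalTot))
}
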