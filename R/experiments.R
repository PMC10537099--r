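#' Simulate one replicate of a scenario
#'
#' Draws the pedigree and trait effects (genetics stream), assigns offspring
#' to pens at random (also on the genetics stream, so that pen composition is
#' identical across movement-parameter variants), and runs the agent-based
#' model in every pen until the interaction target is reached.
#'
#' @param config a [ScenarioConfig-class] object.
#' @param replicate replicate index (>= 1); each replicate derives
#'   independent RNG streams from the root seed.
#' @param snapshotAt optional interaction totals at which to snapshot each
#'   pen's counts (see [simulatePen()]).
#' @param logRecords keep per-event logs (needed only for record-prefix
#'   analyses or event exports).
#' @return list with elements `ped`, `effects`, `penAssignment` (named by
#'   offspring ID), `sims` (per-pen `penSim` objects) and `pairs`
#'   (combined [PairTable-class]).
#' @export
simulateReplicate <- function(config, replicate = 1L, snapshotAt = integer(0),
                              logRecords = FALSE) {
  sub <- streamSeed(config@seed, "replicate", replicate)
  ped <- buildHalfSibPedigree(config@nSires, config@damsPerSire,
    config@offspringPerDam)
  eff <- sampleTraitEffects(ped, config@params, seed = sub)
  off <- offspringIds(ped)
  pen <- withStream(sub, "genetics", 1L,
    sample(rep(seq_len(config@nPens), each = config@groupSize)))
  names(pen) <- off
  P <- tendencies(eff)
  sims <- lapply(seq_len(config@nPens), function(k) {
    idx <- off[pen == k]
    simulatePen(P[idx, 1], P[idx, 2], config = config@movement,
      targetInteractions = config@targetInteractions, penId = k, ids = idx,
      seed = sub, snapshotAt = snapshotAt, logRecords = logRecords)
  })
  list(ped = ped, effects = eff, penAssignment = pen, sims = sims,
    pairs = combinePairTables(sims))
}

evaluateFit <- function(fit, effects, ids) {
  A <- breedingValues(effects)[ids, , drop = FALSE]
  idsChr <- as.character(ids)
  tot <- accuracyAndBias(A[, 1] + A[, 2],
    fit@ebvAlpha[idsChr] + fit@ebvBeta[idsChr])
  accA <- accuracyAndBias(A[, 1], fit@ebvAlpha[idsChr])
  accB <- accuracyAndBias(A[, 2], fit@ebvBeta[idsChr])
  vc <- varianceComponents(fit)
  data.frame(accuracy = tot$accuracy, bias = tot$bias,
    accuracyAlpha = accA$accuracy, accuracyBeta = accB$accuracy,
    varAAlpha = vc[["varAAlpha"]], varABeta = vc[["varABeta"]],
    covA = vc[["covA"]], varEpAlpha = vc[["varEpAlpha"]],
    varEpBeta = vc[["varEpBeta"]], converged = fit@converged)
}

#' Run a replicated scenario end-to-end
#'
#' For each replicate: simulate genetics and movement, fit the binomial GLMM
#' to the combined pair table, and evaluate accuracy and bias of the total
#' EBV (and per-trait accuracies) over the offspring. Replicates whose fit
#' fails are logged and excluded, with a count in the output.
#'
#' @param config a [ScenarioConfig-class] object.
#' @param outDir optional directory; when given, pair tables, EBV reports and
#'   the replicate report are written as delimited text.
#' @param keepFits return the fitted [SocialGlmmFit-class] objects.
#' @param verbose print progress.
#' @param ... passed on to [fitSocialGlmm()].
#' @return list with `report` (per-replicate data.frame), `summary`
#'   (means with standard errors), `nFailed`, and optionally `fits`.
#' @export
runScenario <- function(config, outDir = NULL, keepFits = FALSE,
                        verbose = FALSE, ...) {
  report <- NULL
  fits <- list()
  nFailed <- 0L
  for (r in seq_len(config@nReplicates)) {
    sim <- simulateReplicate(config, r)
    res <- tryCatch({
      fit <- fitSocialGlmm(sim$pairs, sim$ped, ...)
      ev <- evaluateFit(fit, sim$effects, offspringIds(sim$ped))
      if (keepFits) fits[[length(fits) + 1L]] <- fit
      if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writePairTable(sim$pairs,
          file.path(outDir, sprintf("pairs_rep%02d.tsv", r)))
        writeEbvReport(fit,
          file.path(outDir, sprintf("ebv_rep%02d.tsv", r)))
      }
      cbind(replicate = r, ev)
    }, error = function(e) {
      if (verbose) message(sprintf("replicate %d failed: %s", r,
        conditionMessage(e)))
      NULL
    })
    if (is.null(res)) nFailed <- nFailed + 1L else report <- rbind(report, res)
    if (verbose && !is.null(res))
      message(sprintf("replicate %d: accuracy %.3f bias %.3f", r,
        res$accuracy, res$bias))
  }
  out <- list(report = report,
    summary = if (!is.null(report)) summarizeReplicates(report) else NULL,
    nFailed = nFailed)
  if (keepFits) out$fits <- fits
  if (!is.null(outDir) && !is.null(report))
    write.table(report, file.path(outDir, "report.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
  out
}

#' Accuracy as a function of the number of pens analysed
#'
#' Simulates each replicate once, then fits the GLMM to the data of the first
#' k pens for every k in `pensList`, mimicking a recording system installed
#' pen by pen: fewer pens mean fewer phenotyped individuals and less sib
#' information. Fit failures (expected for very few pens) are flagged, not
#' fatal.
#'
#' @param config a [ScenarioConfig-class] object.
#' @param pensList increasing pen counts to analyse.
#' @param ... passed on to [fitSocialGlmm()].
#' @return data.frame with one row per replicate x pen count.
#' @export
varyPens <- function(config, pensList, ...) {
  out <- NULL
  for (r in seq_len(config@nReplicates)) {
    sim <- simulateReplicate(config, r)
    d <- pairData(sim$pairs)
    for (k in pensList) {
      sub <- pairTable(d[d$pen <= k, , drop = FALSE])
      ids <- names(sim$penAssignment)[sim$penAssignment <= k]
      row <- tryCatch({
        fit <- fitSocialGlmm(sub, sim$ped, ...)
        ev <- evaluateFit(fit, sim$effects, as.integer(ids))
        cbind(replicate = r, nPens = k, nAnimals = length(ids), ev)
      }, error = function(e) {
        data.frame(replicate = r, nPens = k, nAnimals = length(ids),
          accuracy = NA, bias = NA, accuracyAlpha = NA, accuracyBeta = NA,
          varAAlpha = NA, varABeta = NA, covA = NA, varEpAlpha = NA,
          varEpBeta = NA, converged = FALSE)
      })
      out <- rbind(out, row)
    }
  }
  out
}

#' Accuracy as a function of the number of interaction records
#'
#' Runs each pen once until the largest threshold is reached, snapshotting
#' the pair-level counts when the pen's interaction total crosses each
#' threshold (chronological prefixes of the interaction stream), then fits
#' the GLMM to every prefix.
#'
#' @param config a [ScenarioConfig-class]; its `targetInteractions` is
#'   replaced by `max(thresholds)`.
#' @param thresholds increasing per-pen interaction totals (e.g. 5000, 10000,
#'   20000).
#' @param ... passed on to [fitSocialGlmm()].
#' @return data.frame with one row per replicate x threshold.
#' @export
varyRecords <- function(config, thresholds, ...) {
  thresholds <- sort(as.integer(thresholds))
  config@targetInteractions <- max(thresholds)
  out <- NULL
  for (r in seq_len(config@nReplicates)) {
    sim <- simulateReplicate(config, r, snapshotAt = thresholds)
    off <- offspringIds(sim$ped)
    for (t in seq_along(thresholds)) {
      snaps <- lapply(sim$sims, function(s) s$snapshots[[t]]$pairs)
      sub <- pairTable(do.call(rbind, snaps))
      row <- tryCatch({
        fit <- fitSocialGlmm(sub, sim$ped, ...)
        ev <- evaluateFit(fit, sim$effects, off)
        cbind(replicate = r, targetInteractions = thresholds[t], ev)
      }, error = function(e) NULL)
      out <- rbind(out, row)
    }
  }
  out
}
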