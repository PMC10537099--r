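#' Read and write pedigree files
#'
#' Headered tab-delimited text with columns id, sire, dam, generation;
#' unknown parents are coded 0 (empty cells also read as 0).
#'
#' @param ped a [Pedigree-class] object.
#' @param file path to a delimited text file.
#' @return `readPedigree` returns a [Pedigree-class]; `writePedigree`
#'   returns `file` invisibly.
#' @export
writePedigree <- function(ped, file) {
  write.table(as.data.frame(ped), file, sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(file)
}

#' @rdname writePedigree
#' @export
readPedigree <- function(file) {
  d <- read.table(file, header = TRUE, sep = "\t")
  for (cn in c("sire", "dam")) d[[cn]][is.na(d[[cn]])] <- 0L
  new("Pedigree", id = as.integer(d$id), sire = as.integer(d$sire),
    dam = as.integer(d$dam), generation = as.integer(d$generation))
}

#' Write simulated trait effects as delimited text
#'
#' Columns id, A_alpha, A_beta, Ep_alpha, Ep_beta, P_alpha, P_beta.
#' @param effects a [TraitEffects-class] object.
#' @param file output path.
#' @export
writeTraitEffects <- function(effects, file) {
  d <- data.frame(id = effects@id,
    A_alpha = effects@A[, 1], A_beta = effects@A[, 2],
    Ep_alpha = effects@Ep[, 1], Ep_beta = effects@Ep[, 2],
    P_alpha = effects@P[, 1], P_beta = effects@P[, 2])
  write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read and write pair-level encounter/interaction tables
#'
#' Tab-delimited text with columns pen, performer, recipient, n_encounters,
#' n_interactions.
#'
#' @param pairs a [PairTable-class] object.
#' @param file path to a delimited text file.
#' @export
writePairTable <- function(pairs, file) {
  d <- pairData(pairs)
  names(d) <- c("pen", "performer", "recipient", "n_encounters",
    "n_interactions")
  write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writePairTable
#' @export
readPairTable <- function(file) {
  d <- read.table(file, header = TRUE, sep = "\t")
  names(d) <- c("pen", "performer", "recipient", "nEncounters",
    "nInteractions")
  pairTable(d)
}

#' Write an EBV report from a GLMM fit
#'
#' Columns id, ebv_alpha, ebv_beta, ebv_total.
#' @param fit a [SocialGlmmFit-class] object.
#' @param file output path.
#' @export
writeEbvReport <- function(fit, file) {
  d <- data.frame(id = as.integer(names(fit@ebvAlpha)),
    ebv_alpha = unname(fit@ebvAlpha), ebv_beta = unname(fit@ebvBeta),
    ebv_total = unname(fit@ebvAlpha + fit@ebvBeta))
  write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write per-event interaction records
#'
#' Columns step, pen, performer, recipient, px, py, rx, ry.
#' @param sim a `penSim` result from [simulatePen()].
#' @param file output path.
#' @export
writeInteractionLog <- function(sim, file) {
  d <- sim$records[, c("step", "pen", "performer", "recipient",
    "px", "py", "rx", "ry")]
  write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
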