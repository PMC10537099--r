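BEHAVIOURS <- c("rest", "walk", "eat", "approach")

#' One motivation update of the eat/walk/rest cycle
#'
#' Adds the column of the motivation-change matrix that corresponds to the
#' behaviour currently expressed and floors motivations at zero (an expressed
#' behaviour terminates once its motivation reaches zero). Approaching or
#' queueing at a feeder changes no motivation, which keeps meal length bounded
#' by threshold/|delta_EE| steps.
#'
#' @param motivation numeric length-3 vector (eat, walk, rest).
#' @param behaviour one of "eat", "walk", "rest", "approach", "none".
#' @param config a [MovementConfig-class] object.
#' @return updated length-3 motivation vector.
#' @examples
#' updateMotivation(c(50, 0, 100), "rest", movementConfig())
#' @export
updateMotivation <- function(motivation, behaviour, config = movementConfig()) {
  behaviour <- match.arg(behaviour, c(BEHAVIOURS, "none"))
  m <- as.numeric(motivation)
  if (behaviour %in% c("eat", "walk", "rest")) {
    col <- match(behaviour, c("eat", "walk", "rest"))
    m <- m + unname(config@delta[, col])
  }
  pmax(m, 0)
}

#' Behaviour decision of an agent
#'
#' An agent continues its current behaviour while the corresponding motivation
#' is above zero (approaching continues until the feeder is reached).
#' Otherwise it starts the highest-priority behaviour whose motivation has
#' reached the threshold, with priority eating > resting > walking; when no
#' motivation reaches the threshold the agent rests by default.
#'
#' @param motivation numeric length-3 vector (eat, walk, rest).
#' @param current current behaviour ("none" if no behaviour is active).
#' @param config a [MovementConfig-class] object.
#' @return the behaviour expressed this step ("eat" stands for starting to
#'   approach a feeder).
#' @examples
#' decideBehaviour(c(100, 50, 50), "rest", movementConfig())  # continues rest
#' decideBehaviour(c(100, 100, 100), "none", movementConfig()) # eat wins
#' @export
decideBehaviour <- function(motivation, current = "none",
                            config = movementConfig()) {
  current <- match.arg(current, c("none", BEHAVIOURS))
  m <- as.numeric(motivation)
  keep <- switch(current,
    approach = TRUE,
    eat = m[1] > 0,
    walk = m[2] > 0,
    rest = m[3] > 0,
    none = FALSE
  )
  if (keep) return(current)
  T <- config@threshold
  if (m[1] >= T) "eat" else if (m[3] >= T) "rest" else if (m[2] >= T) "walk"
  else "rest"
}

#' Advance an agent's position by one step
#'
#' Walking advances one step length along the heading with reflection at the
#' pen walls; approaching moves straight towards the target with the final
#' displacement clamped at the target; eating and resting do not move.
#'
#' @param position numeric (x, y).
#' @param behaviour one of "eat", "walk", "rest", "approach".
#' @param heading walking direction in radians.
#' @param penSide pen side length in metres.
#' @param config a [MovementConfig-class] object.
#' @param feederPosition numeric (x, y) target while approaching.
#' @return list with `position` and (possibly reflected) `heading`.
#' @export
moveAgent <- function(position, behaviour, heading, penSide,
                      config = movementConfig(), feederPosition = NULL) {
  behaviour <- match.arg(behaviour, BEHAVIOURS)
  p <- as.numeric(position)
  if (behaviour == "walk") {
    p <- p + config@stepLength * c(cos(heading), sin(heading))
    if (p[1] < 0) { p[1] <- -p[1]; heading <- pi - heading }
    if (p[1] > penSide) { p[1] <- 2 * penSide - p[1]; heading <- pi - heading }
    if (p[2] < 0) { p[2] <- -p[2]; heading <- -heading }
    if (p[2] > penSide) { p[2] <- 2 * penSide - p[2]; heading <- -heading }
    p <- pmin(pmax(p, 0), penSide)
  } else if (behaviour == "approach") {
    stopifnot(!is.null(feederPosition))
    d <- as.numeric(feederPosition) - p
    dist <- sqrt(sum(d^2))
    p <- if (dist <= config@stepLength) as.numeric(feederPosition)
         else p + config@stepLength * d / dist
  }
  list(position = p, heading = heading)
}

#' Detect encounters among agents at one time step
#'
#' All unordered pairs of agents whose Euclidean distance is strictly below the
#' sensing range. Each such pair is a potential interaction in both ordered
#' directions at this step.
#'
#' @param positions numeric n x 2 matrix of agent coordinates.
#' @param sensingRange encounter radius in metres.
#' @return integer matrix with columns i, j (i < j), zero rows if none.
#' @export
detectEncounters <- function(positions, sensingRange) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  d <- as.matrix(stats::dist(positions))
  hit <- which(upper.tri(d) & d < sensingRange, arr.ind = TRUE)
  out <- cbind(i = hit[, 1], j = hit[, 2])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Simulate one pen: movement, encounters and directed interactions
#'
#' Runs the agent-based eat/walk/rest model for one pen of animals and samples
#' directed interactions at every encounter (both ordered directions,
#' independently, with probability `plogis(P_alpha_i + P_beta_j)`). Pen area
#' follows from the animal density (side = sqrt(n / density)) and feeders are
#' spread evenly over two opposite pen sides at the configured animal:feeder
#' ratio. The run stops when the pen has accumulated `targetInteractions`
#' interaction events (or after exactly `nSteps` steps when given).
#'
#' @param pAlpha,pBeta latent performer/recipient tendencies of the n animals
#'   (logit scale), e.g. columns of [tendencies()].
#' @param config a [MovementConfig-class] object.
#' @param targetInteractions stop once this many interactions are logged.
#' @param nSteps if non-NULL, run exactly this many steps instead.
#' @param penId integer pen label.
#' @param ids animal IDs used in the returned tables.
#' @param seed optional root seed; movement and interaction sampling then use
#'   independent derived streams.
#' @param snapshotAt increasing interaction totals at which to snapshot the
#'   pair-level N/y counts (for record-number experiments).
#' @param logRecords keep the per-event interaction log.
#' @param logTrajectorySteps log all agent positions for the first k steps.
#' @return list of class `penSim` with elements `pairs` (data.frame of ordered
#'   pairs with at least one encounter), `N`, `y` (n x n count matrices),
#'   `records`, `meals`, `budget`, `steps`, `totalEncounters`,
#'   `totalInteractions`, `snapshots`, `trajectory`.
#' @examples
#' sim <- simulatePen(rep(qlogis(0.01) / 2, 20), rep(qlogis(0.01) / 2, 20),
#'   targetInteractions = 50, seed = 1)
#' sim$totalInteractions
#' @export
simulatePen <- function(pAlpha, pBeta, config = movementConfig(),
                        targetInteractions = 10000, nSteps = NULL,
                        penId = 1L, ids = seq_along(pAlpha), seed = NULL,
                        snapshotAt = integer(0), logRecords = TRUE,
                        logTrajectorySteps = 0L) {
  n <- length(pAlpha)
  stopifnot(length(pBeta) == n, length(ids) == n)
  penSide <- sqrt(n / config@density)
  nFeeders <- max(1L, as.integer(round(n / config@feederRatio)))
  if (!is.null(seed)) {
    set.seed(streamSeed(seed, "movement", penId))
    iseed <- streamSeed(seed, "interactions", penId)
  } else {
    iseed <- floor(runif(1) * 2^31)
  }
  res <- .simulatePenCpp(as.numeric(pAlpha), as.numeric(pBeta),
    config@delta, config@threshold, config@stepLength, penSide,
    nFeeders, config@sensingRange,
    as.integer(if (is.null(nSteps)) targetInteractions else 0),
    as.integer(if (is.null(nSteps)) 0 else nSteps),
    config@maxSteps, as.integer(sort(snapshotAt)), isTRUE(logRecords),
    as.integer(logTrajectorySteps), as.numeric(iseed))
  if (!res$reachedTarget)
    stop(sprintf(paste0("pen %d did not reach %d interactions within %d steps ",
      "(got %g); increase maxSteps or lower the target"),
      penId, targetInteractions, config@maxSteps, res$totalInteractions))
  pairs <- pairsFromCounts(res$N, res$y, ids, penId)
  records <- as.data.frame(res$records)
  names(records) <- c("step", "performer", "recipient", "px", "py", "rx", "ry")
  if (nrow(records)) {
    records$performer <- ids[records$performer]
    records$recipient <- ids[records$recipient]
    records$pen <- penId
  }
  meals <- data.frame(animal = ids[res$mealAgent], step = res$mealStep)
  traj <- as.data.frame(res$trajectory)
  if (ncol(traj) == 5) {
    names(traj) <- c("step", "agent", "x", "y", "behaviour")
  }
  snapshots <- lapply(res$snapshots, function(s) {
    if (is.null(s)) return(NULL)
    list(pairs = pairsFromCounts(s$N, s$y, ids, penId), step = s$step,
      totalInteractions = s$totalInteractions)
  })
  structure(list(pairs = pairs, N = res$N, y = res$y, records = records,
    meals = meals, budget = res$budget, steps = res$steps,
    totalEncounters = res$totalEncounters,
    totalInteractions = res$totalInteractions,
    snapshots = snapshots, trajectory = traj, penSide = penSide,
    nFeeders = nFeeders, penId = penId), class = "penSim")
}

pairsFromCounts <- function(N, y, ids, penId) {
  keep <- which(N >= 1, arr.ind = TRUE)
  keep <- keep[keep[, 1] != keep[, 2], , drop = FALSE]
  d <- data.frame(pen = rep(penId, nrow(keep)),
    performer = ids[keep[, 1]], recipient = ids[keep[, 2]],
    nEncounters = N[keep], nInteractions = y[keep])
  d[order(d$performer, d$recipient), , drop = FALSE]
}

#' Mean interval between successive meal starts
#'
#' @param sim a `penSim` result from [simulatePen()].
#' @param minutes return the interval in minutes of simulated time (using the
#'   configured step duration) instead of steps.
#' @param stepDuration seconds per step.
#' @return mean over agents and meals of the interval between successive meal
#'   starts (NA if no agent ate twice).
#' @export
mealIntervalMean <- function(sim, minutes = TRUE, stepDuration = 1) {
  iv <- unlist(lapply(split(sim$meals$step, sim$meals$animal), function(s) {
    if (length(s) > 1) diff(sort(s)) else numeric(0)
  }), use.names = FALSE)
  if (!length(iv)) return(NA_real_)
  m <- mean(iv)
  if (minutes) m * stepDuration / 60 else m
}

#' Time budget of a pen simulation
#'
#' Fraction of agent-steps spent eating (including the approach to the
#' feeder), walking and resting.
#' @param sim a `penSim` result.
#' @return named numeric vector summing to 1.
#' @export
timeBudget <- function(sim) {
  sim$budget / sum(sim$budget)
}
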