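## Four-state classification (L_B, L_S, G, H) and population estimates —
## the central fingerprint statistic.

#' Classify conformers into the four quaternary states
#'
#' Total partition of the finite (theta, d) plane: bent conformers
#' (theta <= `thetaStraight`) are L_B regardless of distance; straight
#' conformers are G below `dLow`, L_S on the closed interval
#' [`dLow`, `dHigh`], and H above `dHigh`. The boundary closure (d equal to a
#' threshold goes to L_S) follows from G and H being defined by strict
#' inequalities.
#'
#' @param theta Elbow angle(s), radians.
#' @param dVC VL-dimer/CL-dimer COM distance(s), nm.
#' @param partition A [StatePartition-class].
#' @return Factor with levels `L_B, L_S, G, H`.
#' @examples
#' classifyState(c(2.6, 2.8, 2.0, 2.7), c(4.3, 3.0, 3.0, 3.7))
#' # H, G, L_B, L_S
#' @export
classifyState <- function(theta, dVC, partition = StatePartition()) {
  if (length(theta) != length(dVC)) stop("theta and dVC must have equal length")
  if (any(!is.finite(theta)) || any(!is.finite(dVC)))
    stop("non-finite collective variables")
  straight <- theta > partition@thetaStraight
  lab <- rep("L_B", length(theta))
  lab[straight & dVC < partition@dLow] <- "G"
  lab[straight & dVC >= partition@dLow & dVC <= partition@dHigh] <- "L_S"
  lab[straight & dVC > partition@dHigh] <- "H"
  factor(lab, levels = stateLabels())
}

#' State populations with block-averaged errors
#'
#' The population of a state is the summed weight of its frames (as a
#' percentage); the standard error comes from [blockError()] applied to the
#' state-indicator variable over contiguous frame blocks.
#'
#' @param cvTable CV table from [computeCVTable()] (columns `theta_rad`,
#'   `d_vc_nm`, `weight`).
#' @param partition A [StatePartition-class].
#' @param nBlocks Number of blocks for the error estimate.
#' @return A [PopulationTable-class].
#' @export
statePopulations <- function(cvTable, partition = StatePartition(),
                             nBlocks = 5) {
  if (!nrow(cvTable)) stop("empty CV table")
  w <- normalizeWeights(cvTable$weight)
  lab <- classifyState(cvTable$theta_rad, cvTable$d_vc_nm, partition)
  percent <- numeric(4)
  stderr <- numeric(4)
  for (i in seq_along(stateLabels())) {
    ind <- as.numeric(lab == stateLabels()[i]) * 100
    if (nrow(cvTable) >= nBlocks) {
      be <- blockError(ind, w, nBlocks)
      percent[i] <- be$estimate
      stderr[i] <- be$stderr
    } else {
      percent[i] <- sum(w * ind)
      stderr[i] <- NA_real_
    }
  }
  # enforce the exact sum-to-100 invariant against fp accumulation
  percent <- percent * (100 / sum(percent))
  PopulationTable(stats::setNames(percent, stateLabels()),
                  stats::setNames(stderr, stateLabels()), partition)
}

#' Combine two independent replicate population tables
#'
#' Per state, the combined estimate is the mean of the two replicates and the
#' error is the larger of half the absolute replicate difference and the
#' propagated block standard error, so across-replicate spread dominates when
#' the replicates disagree.
#'
#' @param popA,popB [PopulationTable-class] objects from the same partition.
#' @return A combined [PopulationTable-class].
#' @export
combineReplicates <- function(popA, popB) {
  pa <- popA@partition; pb <- popB@partition
  if (!isTRUE(all.equal(c(pa@thetaStraight, pa@dLow, pa@dHigh),
                        c(pb@thetaStraight, pb@dLow, pb@dHigh))))
    stop("population tables use different partitions")
  percent <- (popA@percent + popB@percent) / 2
  halfRange <- abs(popA@percent - popB@percent) / 2
  propagated <- sqrt(popA@stderr^2 + popB@stderr^2) / 2
  stderr <- pmax(halfRange, propagated, na.rm = TRUE)
  PopulationTable(stats::setNames(percent, stateLabels()),
                  stats::setNames(stderr, stateLabels()), pa)
}

#' Amyloidogenic-vs-myeloma fingerprint call from the H-state population
#'
#' Amyloidogenic light chains populate the extended H state at roughly
#' 5-10%, non-amyloidogenic (myeloma) ones below 1%. The call uses the upper
#' error bound of the H population: `AL-like` when
#' `H + nSigma * stderr >= hThreshold`, `MM-like` when that bound is below
#' `mmThreshold`, otherwise `indeterminate`.
#'
#' @param populations A [PopulationTable-class].
#' @param hThreshold AL band threshold, percent (default 5).
#' @param mmThreshold MM band threshold, percent (default 1).
#' @param nSigma Error multiplier for the upper bound (default 1).
#' @return `"AL-like"`, `"MM-like"` or `"indeterminate"`.
#' @examples
#' fingerprintCall(PopulationTable(c(L_B = 60, L_S = 30, G = 1.3, H = 8.7),
#'                                 c(0, 0, 0, 0.5)))   # AL-like
#' @export
fingerprintCall <- function(populations, hThreshold = 5, mmThreshold = 1,
                            nSigma = 1) {
  h <- statePercent(populations)[["H"]]
  s <- stateStderr(populations)[["H"]]
  if (is.na(s)) s <- 0
  upper <- h + nSigma * s
  if (upper >= hThreshold) "AL-like"
  else if (upper < mmThreshold) "MM-like"
  else "indeterminate"
}
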