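## Weighted 2-D free-energy surfaces over collective variables.

#' Two-dimensional free-energy surface from weighted samples
#'
#' Bins the samples on a uniform grid, accumulates the weights and applies
#' the Boltzmann inversion \eqn{F = -k_B T \ln(P/P_{max})}, so the occupied
#' minimum is exactly 0 kJ/mol and empty bins stay `NA`. F depends only on
#' weight ratios: rescaling all weights leaves the surface unchanged.
#'
#' @param x,y Sample coordinates (equal length).
#' @param weights Sample weights (`NULL` = uniform; normalized internally).
#' @param bins `c(nx, ny)`, both >= 2.
#' @param ranges Optional `list(x = c(lo, hi), y = c(lo, hi))`; default is
#'   the data range padded by 5% on each side.
#' @param temperatureK Temperature, kelvin.
#' @param xName,yName,xUnit,yUnit Axis metadata stored in the grid.
#' @return A [FESGrid-class].
#' @export
fes2D <- function(x, y, weights = NULL, bins = c(60, 60), ranges = NULL,
                  temperatureK = 310,
                  xName = "x", yName = "y", xUnit = "", yUnit = "") {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (any(bins < 2)) stop("need at least 2 bins per axis")
  if (is.null(weights)) weights <- rep(1, n)
  if (sum(weights) <= 0) stop("zero total weight")
  weights <- normalizeWeights(weights)

  pad <- function(r) {
    if (r[1] == r[2]) r + c(-0.5, 0.5) else r + c(-1, 1) * 0.05 * diff(r)
  }
  if (is.null(ranges))
    ranges <- list(x = pad(range(x)), y = pad(range(y)))
  xe <- seq(ranges$x[1], ranges$x[2], length.out = bins[1] + 1)
  ye <- seq(ranges$y[1], ranges$y[2], length.out = bins[2] + 1)

  ix <- findInterval(x, xe, rightmost.closed = TRUE)
  iy <- findInterval(y, ye, rightmost.closed = TRUE)
  inside <- ix >= 1 & ix <= bins[1] & iy >= 1 & iy <= bins[2]
  if (!any(inside)) stop("all points fall outside the requested ranges")

  P <- matrix(0, bins[1], bins[2])
  acc <- rowsum(weights[inside], group = (iy[inside] - 1) * bins[1] + ix[inside])
  P[as.integer(rownames(acc))] <- acc[, 1]

  kT <- thermalEnergy(temperatureK)
  F <- -kT * log(P / max(P))
  F[P == 0] <- NA_real_
  new("FESGrid", xName = xName, yName = yName, xUnit = xUnit, yUnit = yUnit,
      xEdges = xe, yEdges = ye, F = F, temperatureK = temperatureK)
}

#' Free-energy surface over (theta, d_VC) from a CV table
#'
#' @param cvTable CV table from [computeCVTable()].
#' @inheritParams fes2D
#' @return A [FESGrid-class] with elbow-angle x-axis (rad) and dimer
#'   distance y-axis (nm).
#' @export
cvFES <- function(cvTable, bins = c(60, 60), ranges = NULL,
                  temperatureK = 310) {
  fes2D(cvTable$theta_rad, cvTable$d_vc_nm, cvTable$weight, bins, ranges,
        temperatureK, xName = "elbow angle", xUnit = "rad",
        yName = "d(VL dimer, CL dimer)", yUnit = "nm")
}

#' State-conditioned free-energy surface over the dimer interfaces
#'
#' Restricts the ensemble to the frames classified into one state,
#' renormalizes their weights, and builds the FES over the CL-CL vs VL-VL
#' center-of-mass distances.
#'
#' @param cvTable CV table from [computeCVTable()].
#' @param state One of `"L_B"`, `"L_S"`, `"G"`, `"H"`.
#' @param partition A [StatePartition-class].
#' @inheritParams fes2D
#' @return A [FESGrid-class] over (d_cc, d_vv).
#' @export
stateConditionedFES <- function(cvTable, state, partition = StatePartition(),
                                bins = c(60, 60), ranges = NULL,
                                temperatureK = 310) {
  state <- match.arg(state, stateLabels())
  lab <- classifyState(cvTable$theta_rad, cvTable$d_vc_nm, partition)
  sub <- cvTable[lab == state, , drop = FALSE]
  if (!nrow(sub) || sum(sub$weight) <= 0)
    stop(errorCondition(paste0("state unpopulated: no weight in state ", state),
                        class = c("lcfpNumericalError", "error", "condition")))
  fes2D(sub$d_cc_nm, sub$d_vv_nm, normalizeWeights(sub$weight), bins, ranges,
        temperatureK, xName = "d(CL_A, CL_B)", xUnit = "nm",
        yName = "d(VL_A, VL_B)", yUnit = "nm")
}

#' Location of the free-energy minimum
#'
#' @param grid A [FESGrid-class].
#' @return Named vector with the bin-center coordinates of the occupied
#'   minimum.
#' @export
fesArgmin <- function(grid) {
  idx <- which(grid@F == 0, arr.ind = TRUE)[1, ]
  ctr <- fesCenters(grid)
  c(x = ctr$x[idx[1]], y = ctr$y[idx[2]])
}
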