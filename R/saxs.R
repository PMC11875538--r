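## SAXS back-calculation (coarse Debye), ensemble averaging, scale/chi2
## fitting against experiment, Guinier Rg, Kratky transform.
##
## The Debye calculator is a deliberately coarse model: one scattering
## center per residue (its center of mass) with an effective scattering
## weight equal to the residue's electron count, or one center per atom
## with atomic numbers as weights. It reproduces global-shape observables
## (Rg, low-q intensity) but makes no attempt at a hydration shell, so
## absolute chi2 values against experiment differ systematically from
## hydration-aware predictors.

# orientationally averaged Debye sum; pos in nm, q in A^-1
.debyeSum <- function(pos, f, qGrid) {
  if (any(qGrid < 0)) stop("negative q")
  if (!nrow(pos)) stop("empty frame")
  qnm <- qGrid * 10                       # nm^-1
  D <- as.matrix(stats::dist(pos))
  I <- vapply(qnm, function(q) {
    A <- q * D
    S <- ifelse(A < 1e-8, 1, sin(A) / A)
    as.numeric(t(f) %*% S %*% f)
  }, numeric(1))
  SAXSCurve(q = qGrid, I = I)
}

# scattering centers of one frame under a representation
.scatteringCenters <- function(ensemble, frame, representation) {
  at <- atomTable(ensemble)
  z <- if ("element" %in% names(at)) .elementZ(at$element)
       else .elementZ(.inferElement(at$elety))
  x <- frameCoords(ensemble, frame)
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  if (representation == "atomic") return(list(pos = x, f = z))
  grp <- paste(at$chain, at$resno)
  grp <- factor(grp, levels = unique(grp))
  m <- at$mass
  M <- as.numeric(tapply(m, grp, sum))
  pos <- cbind(
    as.numeric(tapply(m * x[, 1], grp, sum)) / M,
    as.numeric(tapply(m * x[, 2], grp, sum)) / M,
    as.numeric(tapply(m * x[, 3], grp, sum)) / M)
  list(pos = pos, f = as.numeric(tapply(z, grp, sum)))
}

#' Back-calculated SAXS intensity of a single conformer (Debye formula)
#'
#' \eqn{I(q) = \sum_j \sum_k f_j f_k \,\mathrm{sinc}(q d_{jk})} over
#' scattering centers, so \eqn{I(0) = (\sum f)^2} exactly.
#'
#' @param object A [WeightedEnsemble-class], or an `n x 3` matrix of
#'   scattering-center positions in nm.
#' @param qGrid Increasing scattering vector grid, \eqn{\mathrm{\AA}^{-1}}
#'   (q = 0 allowed).
#' @param ... Method arguments below.
#' @param frame Frame index (ensemble method).
#' @param representation `"residue_cg"` (default): one center per residue at
#'   its center of mass, weighted by the residue electron count; or
#'   `"atomic"`: every atom, weighted by its atomic number.
#' @param f Scattering weights (matrix method; default 1 per center).
#' @return A [SAXSCurve-class] (sigma unavailable).
#' @export
setGeneric("debyeIntensity", function(object, qGrid, ...)
  standardGeneric("debyeIntensity"))

#' @rdname debyeIntensity
#' @export
setMethod("debyeIntensity", "WeightedEnsemble",
  function(object, qGrid, frame = 1L,
           representation = c("residue_cg", "atomic"), ...) {
    representation <- match.arg(representation)
    sc <- .scatteringCenters(object, frame, representation)
    .debyeSum(sc$pos, sc$f, qGrid)
  })

#' @rdname debyeIntensity
#' @export
setMethod("debyeIntensity", "matrix",
  function(object, qGrid, f = rep(1, nrow(object)), ...) {
    .debyeSum(object, f, qGrid)
  })

#' Weight-averaged SAXS intensity of an ensemble
#'
#' \eqn{I_{ens}(q) = \sum_i w_i I_i(q)} over all frames.
#'
#' @param ensemble A [WeightedEnsemble-class].
#' @param qGrid Scattering vector grid, \eqn{\mathrm{\AA}^{-1}}.
#' @param representation Passed to [debyeIntensity()].
#' @return A [SAXSCurve-class].
#' @export
ensembleIntensity <- function(ensemble, qGrid,
                              representation = c("residue_cg", "atomic")) {
  representation <- match.arg(representation)
  w <- frameWeights(ensemble)
  I <- numeric(length(qGrid))
  for (i in seq_len(nFrames(ensemble))) {
    if (w[i] == 0) next
    I <- I + w[i] * intensities(
      debyeIntensity(ensemble, qGrid, frame = i,
                     representation = representation))
  }
  SAXSCurve(q = qGrid, I = I)
}

#' Fit scale (and background) of a calculated curve and compute chi2
#'
#' The calculated intensities are linearly interpolated onto the
#' experimental q grid (restricted to `q <= qMax` and to the calculated
#' range; never extrapolated), then `(c, b)` minimizing
#' \eqn{\sum ((I_{exp} - c I_{calc} - b)/\sigma)^2} are obtained in closed
#' form. `chi2` is the reduced value (sum divided by N - n_params).
#'
#' @param calc Calculated [SAXSCurve-class].
#' @param exp Experimental [SAXSCurve-class] with sigma.
#' @param qMax Upper q cut, \eqn{\mathrm{\AA}^{-1}}.
#' @param fitBackground Fit the additive constant b (default `FALSE`, b = 0).
#' @return A [SAXSFitResult-class].
#' @export
fitScaleChi2 <- function(calc, exp, qMax = Inf, fitBackground = FALSE) {
  if (!hasSigma(exp)) stop("experimental curve has no sigma")
  qe <- qValues(exp)
  keep <- qe <= qMax & qe >= min(qValues(calc)) & qe <= max(qValues(calc))
  qe <- qe[keep]
  Ie <- intensities(exp)[keep]
  se <- intensitySigma(exp)[keep]
  if (any(se <= 0)) stop("non-positive sigma in fit range")
  Ic <- stats::approx(qValues(calc), intensities(calc), xout = qe)$y
  nPar <- if (fitBackground) 2L else 1L
  N <- length(qe)
  if (N - nPar <= 0) stop("not enough points to fit (N = ", N, ")")
  w <- 1 / se^2
  if (fitBackground) {
    Sw <- sum(w); Sx <- sum(w * Ic); Sy <- sum(w * Ie)
    Sxx <- sum(w * Ic^2); Sxy <- sum(w * Ic * Ie)
    den <- Sw * Sxx - Sx^2
    if (den == 0) stop("degenerate fit: constant calculated curve")
    cHat <- (Sw * Sxy - Sx * Sy) / den
    bHat <- (Sy - cHat * Sx) / Sw
  } else {
    cHat <- sum(w * Ic * Ie) / sum(w * Ic^2)
    bHat <- 0
  }
  res <- (Ie - cHat * Ic - bHat) / se
  new("SAXSFitResult", scale = cHat, background = bHat,
      chi2 = sum(res^2) / (N - nPar), residuals = res, q = qe,
      nPoints = as.integer(N))
}

#' Radius of gyration by iterative Guinier fitting
#'
#' Weighted linear fit of \eqn{\ln I} vs \eqn{q^2} at low q
#' (\eqn{R_g = \sqrt{-3 \times slope}}). Starting from the lowest
#' `ceiling(n/10) + 5` points, the window is shrunk or extended until
#' \eqn{q_{max} R_g \le} `qrgLimit` at a fixed point (at most 20 iterations,
#' never fewer than 5 points). The window is then further shrunk while the
#' fit shows statistically significant curvature (a quartic term with
#' |t| > 3) — the standard residual-systematics check of Guinier analysis,
#' which removes the low-q-window bias on sharply curved form factors while
#' leaving noisy or genuinely Guinier-like data untouched.
#'
#' @param curve A [SAXSCurve-class]; flagged (I <= 0) points are excluded.
#'   When sigma is unavailable the fit is unweighted.
#' @param qrgLimit Dimensionless Guinier validity bound (default 1.3).
#' @return A [GuinierResult-class] with `rg` in nm.
#' @export
guinierRg <- function(curve, qrgLimit = 1.3) {
  ok <- intensities(curve) > 0 & qValues(curve) > 0
  q <- qValues(curve)[ok]
  I <- intensities(curve)[ok]
  s <- intensitySigma(curve)[ok]
  n <- length(q)
  if (n < 5) stop("fewer than 5 usable points for a Guinier fit")
  lnI <- log(I)
  # error of ln I by the delta method; unit weights when sigma is absent
  wt <- if (all(is.na(s))) rep(1, n) else (I / s)^2
  q2 <- q^2

  fitWindow <- function(m) {
    fit <- stats::lm(lnI[1:m] ~ q2[1:m], weights = wt[1:m])
    slope <- unname(stats::coef(fit)[2])
    list(fit = fit, slope = slope)
  }
  m <- min(n, ceiling(n / 10) + 5)
  seen <- integer()
  for (iter in 1:20) {
    fw <- fitWindow(m)
    if (!is.finite(fw$slope) || fw$slope >= 0)
      stop(errorCondition("no Guinier regime: non-negative low-q slope",
                          class = c("lcfpNumericalError", "error", "condition")))
    rgA <- sqrt(-3 * fw$slope)          # Angstrom
    mNew <- max(5L, sum(q * rgA <= qrgLimit))
    mNew <- min(mNew, n)
    if (mNew == m || mNew %in% seen) { m <- mNew; break }
    seen <- c(seen, m)
    m <- mNew
  }
  # residual-systematics check: shrink while a quartic term is significant
  for (iter in 1:40) {
    if (m <= 5) break
    q4 <- q2^2
    fit2 <- stats::lm(lnI[1:m] ~ q2[1:m] + q4[1:m], weights = wt[1:m])
    t4 <- tryCatch(suppressWarnings(summary(fit2))$coefficients[3, 3],
                   error = function(e) 0)
    if (!is.finite(t4) || abs(t4) <= 3) break
    m <- max(5L, m - ceiling(0.1 * m))
  }
  fw <- fitWindow(m)
  if (!is.finite(fw$slope) || fw$slope >= 0)
    stop(errorCondition("no Guinier regime: non-negative low-q slope",
                        class = c("lcfpNumericalError", "error", "condition")))
  rgA <- sqrt(-3 * fw$slope)
  sm <- suppressWarnings(summary(fw$fit))
  slopeSE <- sm$coefficients[2, 2]
  new("GuinierResult",
      rg = rgA / 10,
      rgStderr = 3 * slopeSE / (2 * rgA) / 10,
      i0 = exp(unname(stats::coef(fw$fit)[1])),
      qRange = c(q[1], q[m]),
      nPoints = as.integer(m),
      r2 = sm$r.squared,
      qmaxRg = q[m] * rgA)
}

#' Kratky transform of a SAXS curve
#'
#' @param curve A [SAXSCurve-class].
#' @return A [SAXSCurve-class] holding \eqn{(q, q^2 I)} (sigma transformed
#'   alike when present).
#' @export
kratky <- function(curve) {
  q <- qValues(curve)
  SAXSCurve(q = q, I = q^2 * intensities(curve),
            sigma = if (hasSigma(curve)) q^2 * intensitySigma(curve) else NULL)
}
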