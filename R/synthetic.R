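## Synthetic dumbbell-dimer ensembles with prescribed four-state populations
## and ground-truth geometry, plus analytic SAXS fixtures.
##
## Each frame places four rigid spherical bead clouds (VL_A, VL_B, CL_A,
## CL_B) and two small linker clouds so that the target elbow angle and the
## three COM distances are realized exactly before jitter: with the hinge at
## the origin, the VL- and CL-dimer centers sit on two arms of length
## d_vc / (2 sin(theta/2)) separated by the elbow angle, and each dimer's
## two domains are offset by +/- d/2 perpendicular to the arm plane.

#' Specification for the synthetic dimer-ensemble generator
#'
#' The default per-state (theta, d_vc) means sit inside the default
#' partition's regions: L_B (2.1 rad, 3.1 nm), L_S (2.8, 3.7), G (2.8, 3.1),
#' H (2.8, 4.4); CL-CL distances place the H state 0.4 nm wider than the
#' compact states. Sampling is i.i.d. from truncated Gaussians honoring the
#' partition bounds, on a single RNG stream seeded once.
#'
#' @param nFrames Number of frames.
#' @param seed RNG seed (mandatory; the whole generation is deterministic).
#' @param populations Target percentages for L_B, L_S, G, H; sum to 100.
#' @param stateGeometry Per-state list of `c(mean, sd)` for `theta` (rad),
#'   `dVC`, `dCC`, `dVV` (nm); `NULL` keeps defaults.
#' @param beadsPerDomain Beads per domain cloud (default 50).
#' @param beadRadius Domain cloud radius, nm.
#' @param linkerBeads Beads per linker (default 11, one per hinge residue).
#' @param jitterSd Per-bead Gaussian jitter, nm (default 0.05).
#' @param weightModel `"uniform"` or `"bias_gaussian"`.
#' @param biasSd Bias s.d. in kJ/mol for `weight model = "bias_gaussian"`.
#' @param temperatureK Temperature, kelvin.
#' @param partition The [StatePartition-class] whose bounds truncate the
#'   state distributions.
#' @return A list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(nFrames = 2000, seed = 1,
                          populations = c(L_B = 62, L_S = 33, G = 0.2, H = 4.8),
                          stateGeometry = NULL,
                          beadsPerDomain = 50, beadRadius = 1.0,
                          linkerBeads = 11, jitterSd = 0.05,
                          weightModel = c("uniform", "bias_gaussian"),
                          biasSd = 2.5, temperatureK = 310,
                          partition = StatePartition()) {
  weightModel <- match.arg(weightModel)
  if (is.null(names(populations))) names(populations) <- stateLabels()
  populations <- populations[stateLabels()]
  if (any(is.na(populations)) || any(populations < 0) ||
      abs(sum(populations) - 100) > 1e-6)
    stop("populations must be non-negative L_B/L_S/G/H percentages summing to 100")
  geomDefault <- list(
    L_B = list(theta = c(2.1, 0.15), dVC = c(3.1, 0.15),
               dCC = c(2.4, 0.10), dVV = c(2.0, 0.10)),
    L_S = list(theta = c(2.8, 0.10), dVC = c(3.7, 0.15),
               dCC = c(2.4, 0.10), dVV = c(2.0, 0.10)),
    G   = list(theta = c(2.8, 0.10), dVC = c(3.1, 0.15),
               dCC = c(2.4, 0.10), dVV = c(2.0, 0.10)),
    H   = list(theta = c(2.8, 0.10), dVC = c(4.4, 0.15),
               dCC = c(2.8, 0.10), dVV = c(2.0, 0.10)))
  if (!is.null(stateGeometry))
    for (s in names(stateGeometry))
      geomDefault[[s]] <- utils::modifyList(geomDefault[[s]], stateGeometry[[s]])
  # geometry means must lie inside their state's region
  th <- partition@thetaStraight
  for (s in stateLabels()) {
    if (populations[[s]] <= 0) next
    g <- geomDefault[[s]]
    tm <- g$theta[1]; dm <- g$dVC[1]
    ok <- switch(s,
      L_B = tm > 0 && tm <= th && dm > 0,
      L_S = tm > th && tm < pi && dm >= partition@dLow && dm <= partition@dHigh,
      G   = tm > th && tm < pi && dm > 0 && dm < partition@dLow,
      H   = tm > th && tm < pi && dm > partition@dHigh)
    if (!ok)
      stop("state ", s, " geometry mean lies outside its partition region")
  }
  structure(list(nFrames = as.integer(nFrames), seed = as.integer(seed),
                 populations = populations, stateGeometry = geomDefault,
                 beadsPerDomain = as.integer(beadsPerDomain),
                 beadRadius = beadRadius, linkerBeads = as.integer(linkerBeads),
                 jitterSd = jitterSd, weightModel = weightModel,
                 biasSd = biasSd, temperatureK = temperatureK,
                 partition = partition),
            class = "SyntheticSpec")
}

# truncated-Gaussian sampling by rejection (vectorized refills)
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  todo <- seq_len(n)
  for (i in 1:1000) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x > lower & x <= upper
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
    if (!length(todo)) return(out)
  }
  stop("truncated sampling failed: bounds [", lower, ", ", upper,
       "] too far from mean ", mean)
}

# beads uniform in a sphere, recentred so the cloud COM is exactly 0
.beadCloud <- function(n, radius) {
  x <- matrix(stats::rnorm(3 * n), n, 3)
  r <- radius * stats::runif(n)^(1 / 3)
  x <- x / sqrt(rowSums(x^2)) * r
  sweep(x, 2, colMeans(x))
}

#' Generate a synthetic weighted dumbbell-dimer ensemble
#'
#' Samples a state per frame from the target populations, draws
#' (theta, d_vc, d_cc, d_vv) from that state's truncated Gaussians, and
#' builds bead-cloud coordinates realizing those COM geometries exactly
#' before per-bead jitter. Byte-identical output under a fixed seed.
#'
#' @param spec A [syntheticSpec()].
#' @return List with `ensemble` (a [WeightedEnsemble-class]), `truthLabels`
#'   (factor of generating states) and `truthCV` (data.frame of the target
#'   CVs per frame, pre-jitter).
#' @export
generateDimerEnsemble <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  n <- spec$nFrames
  part <- spec$partition
  th <- part@thetaStraight

  states <- sample(stateLabels(), n, replace = TRUE,
                   prob = spec$populations / 100)
  theta <- dVC <- dCC <- dVV <- numeric(n)
  tBounds <- list(L_B = c(0.2, th), L_S = c(th, pi - 0.05),
                  G = c(th, pi - 0.05), H = c(th, pi - 0.05))
  dBounds <- list(L_B = c(0.5, 6), L_S = c(part@dLow, part@dHigh),
                  G = c(0.5, part@dLow), H = c(part@dHigh, 6.5))
  for (s in stateLabels()) {
    idx <- which(states == s)
    if (!length(idx)) next
    g <- spec$stateGeometry[[s]]
    theta[idx] <- .rtruncnorm(length(idx), g$theta[1], g$theta[2],
                              tBounds[[s]][1], tBounds[[s]][2])
    dVC[idx] <- .rtruncnorm(length(idx), g$dVC[1], g$dVC[2],
                            dBounds[[s]][1], dBounds[[s]][2])
    dCC[idx] <- .rtruncnorm(length(idx), g$dCC[1], g$dCC[2], 0.5, 6)
    dVV[idx] <- .rtruncnorm(length(idx), g$dVV[1], g$dVV[2], 0.5, 6)
  }
  # boundary values sampled exactly at dLow/dHigh belong to L_S (closed
  # interval), which .rtruncnorm's open lower bound already guarantees for
  # the G/H draws; d_vc == dLow in L_S is measure-zero and kept.

  nb <- spec$beadsPerDomain
  nl <- spec$linkerBeads
  tpl <- list(vlA = .beadCloud(nb, spec$beadRadius),
              vlB = .beadCloud(nb, spec$beadRadius),
              clA = .beadCloud(nb, spec$beadRadius),
              clB = .beadCloud(nb, spec$beadRadius),
              lnA = .beadCloud(nl, 0.3),
              lnB = .beadCloud(nl, 0.3))
  nAtomsChain <- nb + nl + nb
  nAt <- 2L * nAtomsChain

  # author numbering: VL 1..nb, linker 110..(110+nl-1), CL 121..(120+nb)
  resnoChain <- c(seq_len(nb), 110:(109 + nl), 121:(120 + nb))
  atoms <- data.frame(
    chain = rep(c("A", "B"), each = nAtomsChain),
    resno = rep(resnoChain, 2),
    resid = "GLY",
    elety = "CA",
    element = "C",
    mass = 12.011,
    stringsAsFactors = FALSE)

  ez <- c(0, 0, 1)
  coords <- array(NA_real_, dim = c(nAt, 3, n))
  iVL_A <- 1:nb; iLN_A <- nb + (1:nl); iCL_A <- nb + nl + (1:nb)
  iB <- nAtomsChain
  for (i in seq_len(n)) {
    halfT <- theta[i] / 2
    r <- dVC[i] / (2 * sin(halfT))
    V <- r * c(cos(halfT), sin(halfT), 0)
    C <- r * c(cos(halfT), -sin(halfT), 0)
    place <- function(tplM, center) sweep(tplM, 2, center, `+`)
    fr <- matrix(NA_real_, nAt, 3)
    fr[iVL_A, ] <- place(tpl$vlA, V + dVV[i] / 2 * ez)
    fr[iB + iVL_A, ] <- place(tpl$vlB, V - dVV[i] / 2 * ez)
    fr[iCL_A, ] <- place(tpl$clA, C + dCC[i] / 2 * ez)
    fr[iB + iCL_A, ] <- place(tpl$clB, C - dCC[i] / 2 * ez)
    fr[iLN_A, ] <- place(tpl$lnA, 0.2 * ez)
    fr[iB + iLN_A, ] <- place(tpl$lnB, -0.2 * ez)
    coords[, , i] <- fr
  }
  if (spec$jitterSd > 0)
    coords <- coords + stats::rnorm(length(coords), sd = spec$jitterSd)

  weights <- switch(spec$weightModel,
    uniform = rep(1 / n, n),
    bias_gaussian = biasToWeights(stats::rnorm(n, 0, spec$biasSd),
                                  spec$temperatureK))

  ens <- WeightedEnsemble(atoms = atoms, coords = coords, weights = weights,
                          replicateId = sprintf("synthetic-seed%d", spec$seed),
                          temperatureK = spec$temperatureK)
  list(ensemble = ens,
       truthLabels = factor(states, levels = stateLabels()),
       truthCV = data.frame(frame = seq_len(n), state = states,
                            theta_rad = theta, d_vc_nm = dVC,
                            d_cc_nm = dCC, d_vv_nm = dVV,
                            weight = weights))
}

#' Architecture matching the synthetic generator's residue numbering
#'
#' @param spec A [syntheticSpec()].
#' @return A [DomainArchitecture-class] (chains A/B; VL = bead residues
#'   1..beadsPerDomain, linker 110.., CL 121..).
#' @export
syntheticArchitecture <- function(spec = syntheticSpec()) {
  DomainArchitecture(chainIds = c("A", "B"),
                     vl = c(1, spec$beadsPerDomain),
                     linker = c(110, 109 + spec$linkerBeads),
                     cl = c(121, 120 + spec$beadsPerDomain))
}

#' Analytic sphere form-factor intensity
#'
#' \eqn{I(q) = I_0 [3(\sin x - x\cos x)/x^3]^2} with \eqn{x = qR}; the
#' q -> 0 limit is handled analytically (I(0) = I0). Guinier fits of this
#' curve recover \eqn{R_g = \sqrt{3/5} R}.
#'
#' @param radiusNm Sphere radius, nm.
#' @param qGrid Scattering vector grid, \eqn{\mathrm{\AA}^{-1}}.
#' @param i0 Forward intensity.
#' @return A [SAXSCurve-class].
#' @export
sphereIntensity <- function(radiusNm, qGrid, i0 = 1) {
  if (radiusNm <= 0) stop("radius must be positive")
  x <- qGrid * 10 * radiusNm
  FF <- ifelse(x < 1e-4, 1 - x^2 / 10, 3 * (sin(x) - x * cos(x)) / x^3)
  SAXSCurve(q = qGrid, I = i0 * FF^2)
}

#' Add relative Gaussian noise to a SAXS curve
#'
#' \eqn{\sigma(q) =} `relSigma` \eqn{\cdot |I(q)|}, recorded in the sigma
#' column; seeded and reproducible.
#'
#' @param curve A [SAXSCurve-class].
#' @param relSigma Relative noise level (> 0).
#' @param seed RNG seed.
#' @return A noisy [SAXSCurve-class] with sigma set.
#' @export
makeNoisyCurve <- function(curve, relSigma, seed = 1) {
  if (relSigma <= 0) stop("relSigma must be positive")
  set.seed(seed)
  I <- intensities(curve)
  s <- relSigma * abs(I)
  SAXSCurve(q = qValues(curve), I = I + stats::rnorm(length(I), 0, s),
            sigma = s)
}
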