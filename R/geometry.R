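## Collective variables: elbow angle and inter-domain COM distances.
##
## The elbow angle is measured at a vertex placed at the center of mass of
## the two VL-CL linkers, between the vectors pointing to the VL-dimer and
## CL-dimer centers of mass; straight conformers approach pi.

#' Select atom indices of an ensemble
#'
#' @param ensemble A [WeightedEnsemble-class].
#' @param chain Optional chain id(s).
#' @param resno Optional residue numbers (any length; matched by membership).
#' @param elety Optional atom name(s), e.g. `"CA"`.
#' @return Integer atom indices.
#' @export
atomSelection <- function(ensemble, chain = NULL, resno = NULL, elety = NULL) {
  at <- atomTable(ensemble)
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(elety)) keep <- keep & at$elety %in% elety
  which(keep)
}

# indices for one domain of one chain; caOnly limits to Calpha atoms
.domainIndices <- function(ensemble, architecture, chain, domain,
                           caOnly = FALSE) {
  r <- domainRange(architecture, domain, chain)
  at <- atomTable(ensemble)
  keep <- at$chain == chain & at$resno >= r[1] & at$resno <= r[2]
  if (caOnly) keep <- keep & at$elety == "CA"
  which(keep)
}

#' Mass-weighted center of mass of an atom selection
#'
#' @param ensemble A [WeightedEnsemble-class].
#' @param selection Integer atom indices (see [atomSelection()]).
#' @param frame Frame index.
#' @return Numeric 3-vector, nm.
#' @examples
#' ## a single atom is its own center of mass
#' @export
centerOfMass <- function(ensemble, selection, frame = 1L) {
  if (!length(selection)) stop("empty selection")
  m <- atomTable(ensemble)$mass[selection]
  x <- ensemble@coords[selection, , frame, drop = FALSE]
  dim(x) <- c(length(selection), 3L)
  colSums(x * (m / sum(m)))
}

# COM trajectories (3 x nFrames) for a selection, fully vectorized
.comSeries <- function(ensemble, selection) {
  if (!length(selection)) stop("empty selection")
  m <- atomTable(ensemble)$mass[selection]
  m <- m / sum(m)
  nf <- nFrames(ensemble)
  out <- matrix(NA_real_, 3, nf)
  for (d in 1:3) {
    X <- ensemble@coords[selection, d, , drop = FALSE]
    dim(X) <- c(length(selection), nf)
    out[d, ] <- m %*% X
  }
  out
}

.cvSelections <- function(ensemble, architecture, caOnly = FALSE) {
  ch <- chainIds(architecture)
  sel <- list(
    vlA = .domainIndices(ensemble, architecture, ch[1], "VL", caOnly),
    vlB = .domainIndices(ensemble, architecture, ch[2], "VL", caOnly),
    clA = .domainIndices(ensemble, architecture, ch[1], "CL", caOnly),
    clB = .domainIndices(ensemble, architecture, ch[2], "CL", caOnly),
    lnA = .domainIndices(ensemble, architecture, ch[1], "linker", caOnly),
    lnB = .domainIndices(ensemble, architecture, ch[2], "linker", caOnly))
  empty <- names(sel)[!vapply(sel, length, integer(1))]
  if (length(empty))
    stop("architecture selects no atoms for: ", paste(empty, collapse = ", "))
  sel
}

# all per-frame CVs in one pass; returns list of numeric vectors
.cvSeries <- function(ensemble, architecture, caOnly = FALSE) {
  sel <- .cvSelections(ensemble, architecture, caOnly)
  at <- atomTable(ensemble)
  mass <- at$mass
  comOf <- function(idx) .comSeries(ensemble, idx)
  # dimer COMs combine the per-domain COMs with their mass fractions
  pair <- function(a, b) {
    ma <- sum(mass[a]); mb <- sum(mass[b])
    (comOf(a) * ma + comOf(b) * mb) / (ma + mb)
  }
  V <- pair(sel$vlA, sel$vlB)
  C <- pair(sel$clA, sel$clB)
  H <- pair(sel$lnA, sel$lnB)
  a1 <- V - H
  a2 <- C - H
  n1 <- sqrt(colSums(a1^2))
  n2 <- sqrt(colSums(a2^2))
  if (any(n1 < 1e-6) || any(n2 < 1e-6))
    stop("degenerate elbow geometry: arm vector shorter than 1e-6 nm (frame ",
         which(n1 < 1e-6 | n2 < 1e-6)[1], ")")
  cosTheta <- pmin(1, pmax(-1, colSums(a1 * a2) / (n1 * n2)))
  dsel <- function(p, q) sqrt(colSums((p - q)^2))
  list(theta = acos(cosTheta),
       dVC = dsel(V, C),
       dCC = dsel(comOf(sel$clA), comOf(sel$clB)),
       dVV = dsel(comOf(sel$vlA), comOf(sel$vlB)))
}

#' Elbow angle of one or more frames
#'
#' Angle at the linker (hinge) center of mass between the vectors to the
#' VL-dimer and CL-dimer centers of mass, in radians; invariant under
#' rigid-body transforms of the frame.
#'
#' @param ensemble A [WeightedEnsemble-class].
#' @param architecture A [DomainArchitecture-class].
#' @param frame Frame indices (default: all frames).
#' @param caOnly Use only Calpha atoms for the centers of mass.
#' @return Numeric vector of angles in `[0, pi]`.
#' @export
elbowAngle <- function(ensemble, architecture, frame = NULL, caOnly = FALSE) {
  th <- .cvSeries(ensemble, architecture, caOnly)$theta
  if (is.null(frame)) th else th[frame]
}

#' Inter-domain center-of-mass distances
#'
#' `d_vc` = distance between VL-dimer and CL-dimer COMs, `d_cc` = CL_A-CL_B,
#' `d_vv` = VL_A-VL_B, all in nm.
#'
#' @inheritParams elbowAngle
#' @return For a single frame, a named vector `c(d_vc, d_cc, d_vv)`;
#'   otherwise a data.frame with one row per requested frame.
#' @export
interdomainDistances <- function(ensemble, architecture, frame = NULL,
                                 caOnly = FALSE) {
  cv <- .cvSeries(ensemble, architecture, caOnly)
  idx <- if (is.null(frame)) seq_along(cv$dVC) else frame
  if (length(idx) == 1L)
    c(d_vc = cv$dVC[idx], d_cc = cv$dCC[idx], d_vv = cv$dVV[idx])
  else
    data.frame(frame = idx, d_vc = cv$dVC[idx], d_cc = cv$dCC[idx],
               d_vv = cv$dVV[idx])
}

#' Collective-variable table of an ensemble
#'
#' One row per frame with the elbow angle, the three inter-domain distances
#' and the frame weight, in frame order.
#'
#' @inheritParams elbowAngle
#' @return data.frame with columns `frame`, `theta_rad`, `d_vc_nm`,
#'   `d_cc_nm`, `d_vv_nm`, `weight`.
#' @export
computeCVTable <- function(ensemble, architecture, caOnly = FALSE) {
  cv <- .cvSeries(ensemble, architecture, caOnly)
  data.frame(frame = seq_len(nFrames(ensemble)),
             theta_rad = cv$theta,
             d_vc_nm = cv$dVC,
             d_cc_nm = cv$dCC,
             d_vv_nm = cv$dVV,
             weight = frameWeights(ensemble))
}

#' Apply a rigid-body transform to every frame
#'
#' Utility for invariance checks: `x -> R x + t`.
#'
#' @param ensemble A [WeightedEnsemble-class].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 vector, nm.
#' @return The transformed ensemble.
#' @export
transformEnsemble <- function(ensemble, rotation = diag(3),
                              translation = c(0, 0, 0)) {
  co <- ensemble@coords
  for (i in seq_len(dim(co)[3]))
    co[, , i] <- co[, , i] %*% t(rotation) +
      matrix(translation, nrow(co), 3, byrow = TRUE)
  initialize(ensemble, coords = co)
}
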