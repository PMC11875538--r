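## Weighted per-residue RMSF with iterated superposition, and
## left-handed-alpha Ramachandran occupancy.

# xyz row-vector (x1,y1,z1,x2,...) for a frame restricted to atom indices
.frameXYZ <- function(ensemble, idx, frame) as.vector(t(ensemble@coords[idx, , frame]))

#' Weighted per-residue RMSF of one domain
#'
#' Every frame is least-squares superposed onto the weighted mean structure
#' using the Calpha atoms of `fitCore`; mean and fit are iterated (two passes
#' by default, after which the profile is stable to < 1e-4 nm on smooth
#' ensembles). The RMSF of residue r is
#' \eqn{\sqrt{\sum_i w_i |x_{i,r} - \langle x_r\rangle|^2}} over its Calpha.
#'
#' @param ensemble A [WeightedEnsemble-class].
#' @param architecture A [DomainArchitecture-class].
#' @param chain Chain id.
#' @param domain `"VL"` or `"CL"`.
#' @param fitCore Residue numbers (same chain) whose Calpha define the
#'   superposition core; defaults to all selected residues. At least 3.
#' @param nIter Mean/fit iterations (default 2).
#' @return An [RMSFProfile-class].
#' @export
ensembleRMSF <- function(ensemble, architecture, chain,
                         domain = c("VL", "CL"), fitCore = NULL, nIter = 2) {
  domain <- match.arg(domain)
  r <- domainRange(architecture, domain, chain)
  selResno <- r[1]:r[2]
  at <- atomTable(ensemble)
  present <- sort(unique(at$resno[at$chain == chain & at$resno %in% selResno &
                                    at$elety == "CA"]))
  if (!length(present))
    stop("no Calpha atoms for chain ", chain, " ", domain)
  missing <- setdiff(intersect(selResno, unique(at$resno[at$chain == chain])),
                     present)
  if (length(missing))
    stop("missing Calpha for residues ", paste(missing, collapse = ", "),
         " of chain ", chain)
  if (is.null(fitCore)) fitCore <- present
  coreResno <- intersect(fitCore, present)
  if (length(coreResno) < 3) stop("fit core must contain at least 3 residues")

  idx <- atomSelection(ensemble, chain = chain, resno = present, elety = "CA")
  # order by residue number for stable labeling
  idx <- idx[order(at$resno[idx])]
  coreLocal <- which(at$resno[idx] %in% coreResno)
  coreXYZ <- bio3d::atom2xyz(coreLocal)

  nf <- nFrames(ensemble)
  w <- frameWeights(ensemble)
  X <- matrix(NA_real_, nf, 3 * length(idx))
  for (i in seq_len(nf)) X[i, ] <- .frameXYZ(ensemble, idx, i)

  m <- colSums(X * w)
  for (it in seq_len(nIter)) {
    X <- bio3d::fit.xyz(fixed = m, mobile = X,
                        fixed.inds = coreXYZ, mobile.inds = coreXYZ)
    m <- colSums(X * w)
  }
  dev2 <- sweep(X, 2, m)^2
  perAtom <- matrix(colSums(dev2 * w), nrow = 3)   # x,y,z rows per atom
  rmsf <- sqrt(colSums(perAtom))

  labels <- as.character(at$resno[idx])
  dn <- architecture@displayNumbering
  if (!is.null(dn[[chain]]))
    labels <- ifelse(labels %in% names(dn[[chain]]),
                     unlist(dn[[chain]])[labels], labels)
  new("RMSFProfile", resno = as.integer(at$resno[idx]), labels = labels,
      rmsf = rmsf, domain = domain,
      provenance = paste0(ensemble@replicateId, ":", chain))
}

#' Average RMSF profiles over chains and replicates
#'
#' @param profiles List of [RMSFProfile-class] objects with identical residue
#'   label sets (e.g. the two equivalent domains of two replicates).
#' @return An [RMSFProfile-class] whose provenance lists all inputs.
#' @export
averageRMSF <- function(profiles) {
  if (!length(profiles)) stop("no profiles given")
  ref <- profiles[[1]]
  for (p in profiles[-1])
    if (!identical(p@labels, ref@labels))
      stop("residue label mismatch between profiles")
  vals <- rowMeans(vapply(profiles, function(p) p@rmsf,
                          numeric(length(ref@rmsf))))
  new("RMSFProfile", resno = ref@resno, labels = ref@labels, rmsf = vals,
      domain = ref@domain,
      provenance = unlist(lapply(profiles, function(p) p@provenance)))
}

# torsion angle (degrees) for stacked coordinate matrices p1..p4 (n x 3)
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi angles of one residue across all frames
#'
#' @param ensemble A [WeightedEnsemble-class]; frames must carry backbone
#'   N, CA, C atoms.
#' @param chain Chain id.
#' @param resno Residue number (not chain-terminal).
#' @return data.frame with per-frame `phi` and `psi` in degrees.
#' @export
ramachandranAngles <- function(ensemble, chain, resno) {
  at <- atomTable(ensemble)
  pick <- function(rn, name) {
    i <- which(at$chain == chain & at$resno == rn & at$elety == name)
    if (length(i) != 1)
      stop("phi/psi undefined: need atom ", name, " of residue ", rn,
           " in chain ", chain, " (chain-terminal residue?)")
    i
  }
  iCprev <- pick(resno - 1, "C")
  iN <- pick(resno, "N"); iCA <- pick(resno, "CA"); iC <- pick(resno, "C")
  iNnext <- pick(resno + 1, "N")
  get <- function(i) {
    x <- ensemble@coords[i, , , drop = FALSE]
    dim(x) <- c(3L, nFrames(ensemble))
    t(x)
  }
  data.frame(
    phi = .dihedral(get(iCprev), get(iN), get(iCA), get(iC)),
    psi = .dihedral(get(iN), get(iCA), get(iC), get(iNnext)))
}

#' Weighted occupancy of the left-handed alpha-helical Ramachandran region
#'
#' The alpha-L region is taken as 0 deg < phi <= 120 deg and
#' -60 deg <= psi <= 90 deg (a documented convention; region bounds are
#' configurable).
#'
#' @inheritParams ramachandranAngles
#' @param region Named vector `c(phiMin, phiMax, psiMin, psiMax)`, degrees.
#' @return Weighted fraction of frames inside the region, in `[0, 1]`.
#' @export
leftHandedAlphaOccupancy <- function(ensemble, chain, resno,
                                     region = c(phiMin = 0, phiMax = 120,
                                                psiMin = -60, psiMax = 90)) {
  ang <- ramachandranAngles(ensemble, chain, resno)
  inside <- ang$phi > region[["phiMin"]] & ang$phi <= region[["phiMax"]] &
    ang$psi >= region[["psiMin"]] & ang$psi <= region[["psiMax"]]
  sum(frameWeights(ensemble)[inside])
}
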