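#' @import methods
NULL

# Boltzmann constant, kJ mol^-1 K^-1
.kB <- 0.0083144621

#' Thermal energy k_B * T
#'
#' @param temperatureK Temperature in kelvin.
#' @return Thermal energy in kJ/mol (`k_B` = 0.0083144621 kJ mol^-1 K^-1).
#' @examples
#' thermalEnergy(310)      # ~2.577 kJ/mol
#' 2 * thermalEnergy(310)  # free-energy isoline spacing used throughout
#' @export
thermalEnergy <- function(temperatureK) {
  if (!is.numeric(temperatureK) || any(!is.finite(temperatureK)) || any(temperatureK <= 0))
    stop("temperatureK must be a positive finite number")
  .kB * temperatureK
}

## ---------------------------------------------------------------------------
## DomainArchitecture
## ---------------------------------------------------------------------------

#' Domain architecture of a two-chain light-chain dimer
#'
#' Maps each of the two chains onto three inclusive residue-number intervals:
#' the variable domain (VL), the VL-CL linker (hinge), and the constant
#' domain (CL). Residue numbers refer to the author numbering of the
#' coordinate file.
#'
#' @slot chainIds Character vector of length 2, the two chain identifiers.
#' @slot vlRange,linkerRange,clRange Integer matrices (2 rows, one per chain;
#'   columns start/end) giving inclusive residue ranges.
#' @slot displayNumbering Optional named list mapping residue numbers to
#'   display labels (one entry per chain); may be empty.
#' @export
setClass("DomainArchitecture",
  representation(
    chainIds = "character",
    vlRange = "matrix",
    linkerRange = "matrix",
    clRange = "matrix",
    displayNumbering = "list"
  )
)

setValidity("DomainArchitecture", function(object) {
  msg <- character()
  if (length(object@chainIds) != 2L || anyDuplicated(object@chainIds))
    msg <- c(msg, "exactly two distinct chain ids are required")
  for (nm in c("vlRange", "linkerRange", "clRange")) {
    r <- slot(object, nm)
    if (!is.numeric(r) || !identical(dim(r), c(2L, 2L)))
      msg <- c(msg, sprintf("%s must be a 2x2 numeric matrix (chains x start/end)", nm))
    else if (any(r[, 1] > r[, 2]))
      msg <- c(msg, sprintf("%s has start > end", nm))
  }
  if (!length(msg)) {
    for (i in 1:2) {
      if (!(object@vlRange[i, 2] < object@linkerRange[i, 1] &&
            object@linkerRange[i, 2] < object@clRange[i, 1]))
        msg <- c(msg, sprintf(
          "chain %s: ranges must be disjoint and ordered vl < linker < cl",
          object@chainIds[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DomainArchitecture
#'
#' @param chainIds Two chain identifiers (default `c("A", "B")`).
#' @param vl,linker,cl Inclusive residue ranges, either a length-2 vector
#'   applied to both chains or a list of two length-2 vectors (one per chain).
#' @param displayNumbering Optional list of per-chain residue label maps.
#' @return A [DomainArchitecture-class] object.
#' @examples
#' DomainArchitecture(vl = c(1, 109), linker = c(110, 120), cl = c(121, 214))
#' @export
DomainArchitecture <- function(chainIds = c("A", "B"),
                               vl = c(1, 109),
                               linker = c(110, 120),
                               cl = c(121, 214),
                               displayNumbering = list()) {
  asRange <- function(x, nm) {
    if (is.list(x)) {
      if (length(x) != 2L) stop(nm, ": per-chain list must have two entries")
      m <- do.call(rbind, lapply(x, as.numeric))
    } else {
      m <- rbind(as.numeric(x), as.numeric(x))
    }
    storage.mode(m) <- "integer"
    m
  }
  new("DomainArchitecture",
      chainIds = as.character(chainIds),
      vlRange = asRange(vl, "vl"),
      linkerRange = asRange(linker, "linker"),
      clRange = asRange(cl, "cl"),
      displayNumbering = displayNumbering)
}

#' Default light-chain dimer architecture
#'
#' Chains A and B with VL 1-109, linker (hinge) 110-120, CL 121-214; the
#' linker interval follows the conventional VL-CL hinge residues 110-120.
#'
#' @return A [DomainArchitecture-class] object.
#' @export
defaultArchitecture <- function() DomainArchitecture()

#' Read a domain-architecture config from YAML
#'
#' Expected keys: `chains` (2 ids), `vl`, `linker`, `cl` (each `[start, end]`
#' or a list of two such pairs), optional `temperature` and `q_unit` which are
#' returned as attributes.
#'
#' @param path Path to a YAML file.
#' @return A [DomainArchitecture-class] object, with optional attributes
#'   `temperatureK` and `qUnit`.
#' @export
readArchitecture <- function(path) {
  cfg <- yaml::read_yaml(path)
  arch <- DomainArchitecture(
    chainIds = if (!is.null(cfg$chains)) unlist(cfg$chains) else c("A", "B"),
    vl = cfg$vl, linker = cfg$linker, cl = cfg$cl)
  if (!is.null(cfg$temperature)) attr(arch, "temperatureK") <- cfg$temperature
  if (!is.null(cfg$q_unit)) attr(arch, "qUnit") <- cfg$q_unit
  arch
}

#' @exportMethod show
setMethod("show", "DomainArchitecture", function(object) {
  cat("DomainArchitecture: chains", paste(object@chainIds, collapse = "/"), "\n")
  for (i in 1:2)
    cat(sprintf("  chain %s: VL %d-%d | linker %d-%d | CL %d-%d\n",
                object@chainIds[i],
                object@vlRange[i, 1], object@vlRange[i, 2],
                object@linkerRange[i, 1], object@linkerRange[i, 2],
                object@clRange[i, 1], object@clRange[i, 2]))
})

#' @rdname DomainArchitecture-class
#' @param x A DomainArchitecture.
#' @export
chainIds <- function(x) x@chainIds

#' Residue range of a domain
#'
#' @param x A [DomainArchitecture-class].
#' @param domain One of "VL", "linker", "CL".
#' @param chain Chain id; one of `chainIds(x)`.
#' @return Integer vector `c(start, end)` (inclusive).
#' @export
domainRange <- function(x, domain = c("VL", "linker", "CL"), chain) {
  domain <- match.arg(domain)
  i <- match(chain, x@chainIds)
  if (is.na(i)) stop("unknown chain '", chain, "'")
  r <- switch(domain, VL = x@vlRange, linker = x@linkerRange, CL = x@clRange)
  r[i, ]
}

## ---------------------------------------------------------------------------
## WeightedEnsemble
## ---------------------------------------------------------------------------

#' A weighted conformational ensemble
#'
#' Conformer frames sharing one atom table, each frame carrying a normalized
#' statistical weight (e.g. from final metadynamics-bias reweighting).
#' Coordinates are stored in nanometres.
#'
#' @slot atoms `data.frame` with columns `chain`, `resno`, `resid`, `elety`,
#'   `mass` (Da); identical for every frame.
#' @slot coords Numeric array `n_atoms x 3 x n_frames`, nm.
#' @slot weights Per-frame probabilities, non-negative, summing to 1.
#' @slot replicateId Label of the simulation replicate.
#' @slot temperatureK Simulation temperature, kelvin.
#' @export
setClass("WeightedEnsemble",
  representation(
    atoms = "data.frame",
    coords = "array",
    weights = "numeric",
    replicateId = "character",
    temperatureK = "numeric"
  )
)

setValidity("WeightedEnsemble", function(object) {
  msg <- character()
  need <- c("chain", "resno", "resid", "elety", "mass")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns", paste(need, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an n_atoms x 3 x n_frames array")
  else {
    if (d[1] != nrow(object@atoms))
      msg <- c(msg, "coords first dimension must match the atom table")
    if (d[3] < 1L) msg <- c(msg, "at least one frame is required")
    if (d[3] != length(object@weights))
      msg <- c(msg, "one weight per frame is required")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
  }
  if (length(object@weights)) {
    if (any(!is.finite(object@weights)) || any(object@weights < 0))
      msg <- c(msg, "weights must be finite and non-negative")
    else if (abs(sum(object@weights) - 1) > 1e-9)
      msg <- c(msg, "weights must sum to 1 within 1e-9")
  }
  if (any(!is.finite(object@atoms$mass)) || any(object@atoms$mass <= 0))
    msg <- c(msg, "atom masses must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a WeightedEnsemble
#'
#' @param atoms Atom table (`chain`, `resno`, `resid`, `elety`, `mass`).
#' @param coords `n_atoms x 3 x n_frames` array, or `n_atoms x 3` matrix for a
#'   single frame, in nm.
#' @param weights Per-frame weights; `NULL` for uniform. Normalized on input
#'   only if they already sum to 1 within 1e-9; otherwise pass explicit
#'   probabilities (use [normalizeWeights()] to normalize raw weights).
#' @param replicateId,temperatureK Metadata.
#' @return A [WeightedEnsemble-class] object.
#' @export
WeightedEnsemble <- function(atoms, coords, weights = NULL,
                             replicateId = "ensemble", temperatureK = 310) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (is.null(weights)) weights <- rep(1 / nf, nf)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  new("WeightedEnsemble", atoms = atoms, coords = coords,
      weights = as.numeric(weights),
      replicateId = as.character(replicateId),
      temperatureK = as.numeric(temperatureK))
}

#' @rdname WeightedEnsemble-class
#' @param x A WeightedEnsemble.
#' @export
nFrames <- function(x) dim(x@coords)[3]

#' @rdname WeightedEnsemble-class
#' @export
nAtoms <- function(x) dim(x@coords)[1]

#' @rdname WeightedEnsemble-class
#' @export
atomTable <- function(x) x@atoms

#' @rdname WeightedEnsemble-class
#' @export
frameWeights <- function(x) x@weights

#' @rdname WeightedEnsemble-class
#' @export
temperatureK <- function(x) x@temperatureK

#' Coordinates of one frame
#'
#' @param x A [WeightedEnsemble-class].
#' @param i Frame index.
#' @return `n_atoms x 3` matrix, nm.
#' @export
frameCoords <- function(x, i) x@coords[, , i, drop = TRUE]

setMethod("show", "WeightedEnsemble", function(object) {
  cat(sprintf("WeightedEnsemble '%s': %d frames x %d atoms, T = %g K\n",
              object@replicateId, nFrames(object), nAtoms(object),
              object@temperatureK))
  ess <- 1 / sum(object@weights^2)
  cat(sprintf("  weights: source sum = %.6f, Kish ESS = %.1f\n",
              sum(object@weights), ess))
  cat("  chains:", paste(unique(object@atoms$chain), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## SAXSCurve
## ---------------------------------------------------------------------------

#' A small-angle X-ray scattering curve
#'
#' @slot q Scattering vector, \eqn{\mathrm{\AA}^{-1}}, strictly increasing.
#' @slot I Intensity, arbitrary units.
#' @slot sigma Intensity uncertainty (same units); all-`NA` when unavailable.
#' @slot flagged Indices of retained rows with I <= 0 (kept but flagged).
#' @export
setClass("SAXSCurve",
  representation(q = "numeric", I = "numeric", sigma = "numeric",
                 flagged = "integer"))

setValidity("SAXSCurve", function(object) {
  msg <- character()
  n <- length(object@q)
  if (length(object@I) != n || length(object@sigma) != n)
    msg <- c(msg, "q, I, sigma must have equal length")
  if (n && (any(!is.finite(object@q)) || any(object@q < 0) ||
            any(diff(object@q) <= 0)))
    msg <- c(msg, "q must be non-negative and strictly increasing")
  if (n && any(!is.finite(object@I)))
    msg <- c(msg, "intensities must be finite")
  s <- object@sigma[!is.na(object@sigma)]
  if (length(s) && any(s <= 0))
    msg <- c(msg, "sigma must be positive where present")
  if (length(msg)) msg else TRUE
})

#' Construct a SAXSCurve
#'
#' @param q Scattering vector, \eqn{\mathrm{\AA}^{-1}}.
#' @param I Intensities.
#' @param sigma Optional uncertainties (`NULL` when unavailable).
#' @return A [SAXSCurve-class] object. Rows with `I <= 0` are retained and
#'   recorded in the `flagged` slot.
#' @export
SAXSCurve <- function(q, I, sigma = NULL) {
  if (is.null(sigma)) sigma <- rep(NA_real_, length(q))
  new("SAXSCurve", q = as.numeric(q), I = as.numeric(I),
      sigma = as.numeric(sigma),
      flagged = which(I <= 0))
}

#' @rdname SAXSCurve-class
#' @param x A SAXSCurve.
#' @export
hasSigma <- function(x) !all(is.na(x@sigma))

#' @rdname SAXSCurve-class
#' @export
qValues <- function(x) x@q

#' @rdname SAXSCurve-class
#' @export
intensities <- function(x) x@I

#' @rdname SAXSCurve-class
#' @export
intensitySigma <- function(x) x@sigma

setMethod("show", "SAXSCurve", function(object) {
  cat(sprintf("SAXSCurve: %d points, q in [%g, %g] A^-1, sigma %s\n",
              length(object@q), min(object@q), max(object@q),
              if (hasSigma(object)) "available" else "unavailable"))
  if (length(object@flagged))
    cat("  flagged (I <= 0):", length(object@flagged), "points\n")
})

#' @rdname SAXSCurve-class
#' @param row.names,optional,... Passed on conventions of [as.data.frame()].
#' @export
setMethod("as.data.frame", "SAXSCurve",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(q = x@q, I = x@I, sigma = x@sigma)
  })

## ---------------------------------------------------------------------------
## StatePartition & PopulationTable
## ---------------------------------------------------------------------------

#' Four-state partition of the (elbow angle, dimer distance) plane
#'
#' Conformers are "straight" when the elbow angle exceeds `thetaStraight`
#' (default 2.5 rad) and bent otherwise; straight conformers split by the
#' VL-dimer/CL-dimer center-of-mass distance into G (< `dLow`), L_S
#' (between `dLow` and `dHigh`, closed interval) and H (> `dHigh`).
#' Defaults: `dLow` 3.4 nm, `dHigh` 4.1 nm. All bent conformers are L_B.
#'
#' @slot thetaStraight Elbow-angle threshold, radians.
#' @slot dLow,dHigh Distance thresholds, nm.
#' @export
setClass("StatePartition",
  representation(thetaStraight = "numeric", dLow = "numeric", dHigh = "numeric"))

setValidity("StatePartition", function(object) {
  msg <- character()
  if (!(object@thetaStraight > 0 && object@thetaStraight < pi))
    msg <- c(msg, "thetaStraight must lie in (0, pi)")
  if (!(object@dLow > 0 && object@dLow < object@dHigh))
    msg <- c(msg, "must have 0 < dLow < dHigh")
  if (length(msg)) msg else TRUE
})

#' @rdname StatePartition-class
#' @param thetaStraight,dLow,dHigh Thresholds (rad, nm, nm).
#' @export
StatePartition <- function(thetaStraight = 2.5, dLow = 3.4, dHigh = 4.1) {
  new("StatePartition", thetaStraight = thetaStraight, dLow = dLow, dHigh = dHigh)
}

setMethod("show", "StatePartition", function(object) {
  cat(sprintf(
    "StatePartition: straight if theta > %g rad; G d < %g nm | L_S %g-%g | H d > %g\n",
    object@thetaStraight, object@dLow, object@dLow, object@dHigh, object@dHigh))
})

#' State labels of the four-state partition
#' @return `c("L_B", "L_S", "G", "H")`.
#' @export
stateLabels <- function() c("L_B", "L_S", "G", "H")

#' Per-state population percentages with errors
#'
#' @slot state The four state labels.
#' @slot percent Populations, 0-100, summing to 100.
#' @slot stderr Standard errors, percent.
#' @slot partition The [StatePartition-class] used.
#' @export
setClass("PopulationTable",
  representation(state = "character", percent = "numeric",
                 stderr = "numeric", partition = "StatePartition"))

setValidity("PopulationTable", function(object) {
  msg <- character()
  if (!identical(object@state, stateLabels()))
    msg <- c(msg, "states must be L_B, L_S, G, H in order")
  if (length(object@percent) != 4L || length(object@stderr) != 4L)
    msg <- c(msg, "percent and stderr must have length 4")
  else {
    if (abs(sum(object@percent) - 100) > 1e-6)
      msg <- c(msg, "percents must sum to 100 within 1e-6")
    if (any(object@stderr < 0)) msg <- c(msg, "stderr must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname PopulationTable-class
#' @param percent,stderr Named or ordered numeric vectors for the four states.
#' @param partition The partition used.
#' @export
PopulationTable <- function(percent, stderr = rep(0, 4),
                            partition = StatePartition()) {
  if (!is.null(names(percent))) percent <- percent[stateLabels()]
  if (!is.null(names(stderr))) stderr <- stderr[stateLabels()]
  new("PopulationTable", state = stateLabels(),
      percent = unname(as.numeric(percent)),
      stderr = unname(as.numeric(stderr)), partition = partition)
}

#' @rdname PopulationTable-class
#' @param x A PopulationTable.
#' @export
statePercent <- function(x) stats::setNames(x@percent, x@state)

#' @rdname PopulationTable-class
#' @export
stateStderr <- function(x) stats::setNames(x@stderr, x@state)

setMethod("show", "PopulationTable", function(object) {
  cat("PopulationTable (percent of ensemble weight):\n")
  for (i in 1:4)
    cat(sprintf("  %-4s %6.2f +/- %.2f\n", object@state[i],
                object@percent[i], object@stderr[i]))
})

#' @rdname PopulationTable-class
#' @param row.names,optional,... Standard [as.data.frame()] arguments.
#' @export
setMethod("as.data.frame", "PopulationTable",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(state = x@state, percent = x@percent, stderr = x@stderr)
  })

## ---------------------------------------------------------------------------
## FESGrid
## ---------------------------------------------------------------------------

#' A two-dimensional free-energy surface on a uniform grid
#'
#' Free energies are \eqn{F = -k_B T \ln(P/P_{max})} in kJ/mol, so the
#' occupied-bin minimum is exactly 0; empty bins are `NA`.
#'
#' @slot xName,yName,xUnit,yUnit Axis metadata.
#' @slot xEdges,yEdges Uniform bin edges.
#' @slot F Free-energy matrix (`length(xEdges)-1` x `length(yEdges)-1`).
#' @slot temperatureK Temperature used for the Boltzmann inversion.
#' @export
setClass("FESGrid",
  representation(xName = "character", yName = "character",
                 xUnit = "character", yUnit = "character",
                 xEdges = "numeric", yEdges = "numeric",
                 F = "matrix", temperatureK = "numeric"))

setValidity("FESGrid", function(object) {
  msg <- character()
  if (!identical(dim(object@F),
                 c(length(object@xEdges) - 1L, length(object@yEdges) - 1L)))
    msg <- c(msg, "F dimensions must match bin edges")
  occ <- object@F[!is.na(object@F)]
  if (length(occ) && abs(min(occ)) > 1e-9)
    msg <- c(msg, "occupied-bin minimum free energy must be 0")
  if (length(msg)) msg else TRUE
})

#' @rdname FESGrid-class
#' @param x A FESGrid.
#' @export
fesValues <- function(x) x@F

#' @rdname FESGrid-class
#' @export
fesEdges <- function(x) list(x = x@xEdges, y = x@yEdges)

#' @rdname FESGrid-class
#' @export
fesCenters <- function(x) list(
  x = (x@xEdges[-1] + x@xEdges[-length(x@xEdges)]) / 2,
  y = (x@yEdges[-1] + x@yEdges[-length(x@yEdges)]) / 2)

#' Isoline spacing and levels of a free-energy surface
#'
#' The conventional contour spacing is \eqn{2 k_B T} (5.15 kJ/mol at 310 K,
#' printed as 5.16 in the source tables).
#'
#' @param x A [FESGrid-class].
#' @return List with `spacing` (kJ/mol) and `levels` covering the occupied
#'   range. Plot metadata only; the stored F values are unaffected.
#' @export
isolineLevels <- function(x) {
  spacing <- 2 * thermalEnergy(x@temperatureK)
  top <- max(x@F, na.rm = TRUE)
  list(spacing = spacing, levels = seq(0, top + spacing, by = spacing))
}

setMethod("show", "FESGrid", function(object) {
  occ <- sum(!is.na(object@F))
  cat(sprintf("FESGrid: %s (%s) x %s (%s), %d x %d bins, %d occupied\n",
              object@xName, object@xUnit, object@yName, object@yUnit,
              nrow(object@F), ncol(object@F), occ))
  cat(sprintf("  T = %g K, isoline spacing 2kT = %.4f kJ/mol\n",
              object@temperatureK, 2 * thermalEnergy(object@temperatureK)))
})

## ---------------------------------------------------------------------------
## RMSFProfile
## ---------------------------------------------------------------------------

#' A per-residue RMSF profile
#'
#' @slot resno Residue numbers (author numbering).
#' @slot labels Display labels.
#' @slot rmsf RMSF per residue, nm.
#' @slot domain "VL" or "CL".
#' @slot provenance Chains/replicates averaged into this profile.
#' @export
setClass("RMSFProfile",
  representation(resno = "integer", labels = "character", rmsf = "numeric",
                 domain = "character", provenance = "character"))

setValidity("RMSFProfile", function(object) {
  msg <- character()
  if (length(object@rmsf) != length(object@resno))
    msg <- c(msg, "one RMSF value per residue is required")
  if (any(object@rmsf < 0)) msg <- c(msg, "RMSF must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname RMSFProfile-class
#' @param x An RMSFProfile.
#' @export
rmsfValues <- function(x) stats::setNames(x@rmsf, x@labels)

setMethod("show", "RMSFProfile", function(object) {
  cat(sprintf("RMSFProfile (%s): %d residues, mean %.3f nm [%s]\n",
              object@domain, length(object@resno), mean(object@rmsf),
              paste(object@provenance, collapse = "; ")))
})

#' @rdname RMSFProfile-class
#' @param row.names,optional,... Standard [as.data.frame()] arguments.
#' @export
setMethod("as.data.frame", "RMSFProfile",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(resno = x@resno, label = x@labels, rmsf_nm = x@rmsf,
               domain = x@domain)
  })

## ---------------------------------------------------------------------------
## GuinierResult & SAXSFitResult
## ---------------------------------------------------------------------------

#' Result of an iterative Guinier fit
#'
#' @slot rg Radius of gyration, nm.
#' @slot rgStderr Fitted standard error of `rg`, nm.
#' @slot i0 Extrapolated forward scattering I(0).
#' @slot qRange q interval used, \eqn{\mathrm{\AA}^{-1}}.
#' @slot nPoints Number of points in the final fit.
#' @slot r2 Coefficient of determination of the ln I vs q^2 fit.
#' @slot qmaxRg Dimensionless `q_max * Rg` of the final fit window.
#' @export
setClass("GuinierResult",
  representation(rg = "numeric", rgStderr = "numeric", i0 = "numeric",
                 qRange = "numeric", nPoints = "integer", r2 = "numeric",
                 qmaxRg = "numeric"))

setValidity("GuinierResult", function(object) {
  if (object@rg <= 0) "rg must be positive" else TRUE
})

#' @rdname GuinierResult-class
#' @param x A GuinierResult.
#' @export
guinierRgValue <- function(x) x@rg

#' @rdname GuinierResult-class
#' @export
guinierI0 <- function(x) x@i0

setMethod("show", "GuinierResult", function(object) {
  cat(sprintf(
    "GuinierResult: Rg = %.3f +/- %.3f nm, I0 = %.4g (%d pts, qmax*Rg = %.2f, R2 = %.4f)\n",
    object@rg, object@rgStderr, object@i0, object@nPoints, object@qmaxRg,
    object@r2))
})

#' Result of fitting a calculated SAXS curve to experiment
#'
#' @slot scale Multiplicative scale c.
#' @slot background Additive constant b (0 when not fitted).
#' @slot chi2 Reduced chi-square.
#' @slot residuals Per-point `(I_exp - (c I_calc + b)) / sigma`.
#' @slot q q values of the fitted points, \eqn{\mathrm{\AA}^{-1}}.
#' @slot nPoints Number of fitted points.
#' @export
setClass("SAXSFitResult",
  representation(scale = "numeric", background = "numeric", chi2 = "numeric",
                 residuals = "numeric", q = "numeric", nPoints = "integer"))

setValidity("SAXSFitResult", function(object) {
  msg <- character()
  if (object@chi2 < 0) msg <- c(msg, "chi2 must be >= 0")
  if (any(!is.finite(object@residuals))) msg <- c(msg, "residuals must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname SAXSFitResult-class
#' @param x A SAXSFitResult.
#' @export
fitChi2 <- function(x) x@chi2

#' @rdname SAXSFitResult-class
#' @export
fitScale <- function(x) x@scale

#' @rdname SAXSFitResult-class
#' @export
fitResiduals <- function(x) x@residuals

setMethod("show", "SAXSFitResult", function(object) {
  cat(sprintf(
    "SAXSFitResult: c = %.4g, b = %.4g, reduced chi2 = %.3f over %d points\n",
    object@scale, object@background, object@chi2, object@nPoints))
})
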