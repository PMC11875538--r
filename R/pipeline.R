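## One-command orchestration: CV extraction, classification, populations,
## FES, ensemble Rg and optional SAXS comparison for 1-2 replicates.

#' Ensemble-averaged radius of gyration with block error
#'
#' Per-frame mass-weighted coordinate Rg,
#' \eqn{R_g = \sqrt{\sum_i m_i |x_i - COM|^2 / \sum_i m_i}} over all atoms,
#' then the weighted mean with a block-averaged standard error.
#'
#' @param ensemble A [WeightedEnsemble-class].
#' @param nBlocks Blocks for [blockError()].
#' @return List with `rg` (nm), `stderr`, and `perFrame` (vector of
#'   per-frame Rg values, nm).
#' @export
ensembleAverageRg <- function(ensemble, nBlocks = 5) {
  m <- atomTable(ensemble)$mass
  M <- sum(m)
  nf <- nFrames(ensemble)
  na <- nAtoms(ensemble)
  com <- .comSeries(ensemble, seq_len(na))      # 3 x F
  sq <- matrix(0, na, nf)
  for (d in 1:3) {
    X <- ensemble@coords[, d, , drop = FALSE]
    dim(X) <- c(na, nf)
    sq <- sq + X^2
  }
  rg2 <- as.numeric(m %*% sq) / M - colSums(com^2)
  perFrame <- sqrt(pmax(rg2, 0))
  if (nf >= nBlocks) {
    be <- blockError(perFrame, frameWeights(ensemble), nBlocks)
  } else {
    be <- list(estimate = sum(frameWeights(ensemble) * perFrame),
               stderr = NA_real_)
  }
  list(rg = be$estimate, stderr = be$stderr, perFrame = perFrame)
}

.pipelineStage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full conformational-fingerprint analysis
#'
#' Reads 1-2 replicate ensembles, computes CV tables, classifies states,
#' estimates populations with block errors, combines replicates, builds
#' free-energy surfaces, averages Rg, optionally compares the
#' back-calculated ensemble SAXS curve to an experimental one, and emits a
#' self-describing report. Deterministic given its inputs.
#'
#' @param config Path to a YAML config, or an equivalent named list. Keys:
#'   `replicates` (list of `coords`/`weights`/`id`), `architecture`
#'   (`chains`, `vl`, `linker`, `cl`), `temperature`, `n_blocks`, `bins`,
#'   partition overrides `theta_straight`/`d_low`/`d_high`, and an optional
#'   `saxs` block (`path`, `q_unit`, `q_max`, `fit_background`).
#' @param outputDir Optional directory for `report.json` plus per-replicate
#'   CV and population TSVs.
#' @return The report as a nested list (invisibly when `outputDir` is set).
#' @export
runFingerprint <- function(config, outputDir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$replicates) || !length(cfg$replicates))
    stop("config must name 1-2 replicate ensembles")
  if (length(cfg$replicates) > 2)
    stop("at most two replicates are supported")
  tempK <- if (!is.null(cfg$temperature)) cfg$temperature else 310
  nBlocks <- if (!is.null(cfg$n_blocks)) cfg$n_blocks else 5
  bins <- if (!is.null(cfg$bins)) unlist(cfg$bins) else c(60, 60)
  arch <- .pipelineStage("architecture", {
    a <- cfg$architecture
    if (is.null(a)) defaultArchitecture()
    else DomainArchitecture(
      chainIds = if (!is.null(a$chains)) unlist(a$chains) else c("A", "B"),
      vl = unlist(a$vl), linker = unlist(a$linker), cl = unlist(a$cl))
  })
  part <- StatePartition(
    thetaStraight = if (!is.null(cfg$theta_straight)) cfg$theta_straight else 2.5,
    dLow = if (!is.null(cfg$d_low)) cfg$d_low else 3.4,
    dHigh = if (!is.null(cfg$d_high)) cfg$d_high else 4.1)

  expCurve <- NULL
  if (!is.null(cfg$saxs))
    expCurve <- .pipelineStage("read_saxs", readSAXSCurve(
      cfg$saxs$path,
      qUnit = if (!is.null(cfg$saxs$q_unit)) cfg$saxs$q_unit else "A^-1"))

  reps <- list()
  popTables <- list()
  for (k in seq_along(cfg$replicates)) {
    rc <- cfg$replicates[[k]]
    id <- if (!is.null(rc$id)) rc$id else paste0("replicate", k)
    ens <- .pipelineStage(paste0("read_ensemble[", id, "]"),
      readEnsemble(rc$coords, arch, weightPath = rc$weights,
                   temperatureK = tempK, replicateId = id))
    cv <- .pipelineStage(paste0("cvs[", id, "]"), computeCVTable(ens, arch))
    pop <- .pipelineStage(paste0("populations[", id, "]"),
                          statePopulations(cv, part, nBlocks))
    popTables[[k]] <- pop
    rg <- .pipelineStage(paste0("rg[", id, "]"),
                         ensembleAverageRg(ens, nBlocks))
    fes <- .pipelineStage(paste0("fes[", id, "]"),
                          cvFES(cv, bins = bins, temperatureK = tempK))
    repOut <- list(
      id = id,
      n_frames = nFrames(ens),
      ess = effectiveSampleSize(frameWeights(ens)),
      populations = as.data.frame(pop),
      rg_nm = rg$rg, rg_stderr = rg$stderr,
      fes = list(bins = dim(fesValues(fes)),
                 isoline_spacing_kJmol = isolineLevels(fes)$spacing))
    if (!is.null(expCurve)) {
      qMax <- if (!is.null(cfg$saxs$q_max)) cfg$saxs$q_max else Inf
      calc <- .pipelineStage(paste0("ensemble_intensity[", id, "]"),
        ensembleIntensity(ens, qValues(expCurve)[qValues(expCurve) <= qMax]))
      fit <- .pipelineStage(paste0("saxs_fit[", id, "]"),
        fitScaleChi2(calc, expCurve, qMax = qMax,
                     fitBackground = isTRUE(cfg$saxs$fit_background)))
      repOut$saxs <- list(chi2 = fitChi2(fit), scale = fitScale(fit),
                          background = fit@background,
                          n_points = fit@nPoints)
    }
    reps[[k]] <- repOut
    if (!is.null(outputDir)) {
      dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
      writeTable(cv, file.path(outputDir, paste0("cv_", id, ".tsv")))
      writeTable(as.data.frame(pop),
                 file.path(outputDir, paste0("populations_", id, ".tsv")))
    }
  }

  combined <- if (length(popTables) == 2)
    combineReplicates(popTables[[1]], popTables[[2]]) else popTables[[1]]
  report <- list(
    schema_version = "1.0",
    software_version = as.character(utils::packageVersion("lcfingerprint")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(
      temperature_K = tempK, n_blocks = nBlocks, bins = as.numeric(bins),
      partition = list(theta_straight_rad = part@thetaStraight,
                       d_low_nm = part@dLow, d_high_nm = part@dHigh)),
    replicates = reps,
    combined_populations = as.data.frame(combined),
    fingerprint_call = fingerprintCall(combined))
  if (!is.null(expCurve)) {
    gu <- .pipelineStage("guinier", guinierRg(expCurve))
    report$experimental_guinier <- list(
      rg_nm = guinierRgValue(gu), rg_stderr_nm = gu@rgStderr,
      i0 = guinierI0(gu), n_points = gu@nPoints, qmax_rg = gu@qmaxRg)
  }
  if (!is.null(outputDir)) {
    jsonlite::write_json(report, file.path(outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeTable(as.data.frame(combined),
               file.path(outputDir, "populations_combined.tsv"))
    return(invisible(report))
  }
  report
}
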