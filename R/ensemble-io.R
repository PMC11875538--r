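## Coordinate-ensemble, weight-table and SAXS-curve I/O.
##
## Internal length unit is nm; PDB files are read/written in Angstrom.

# standard atomic masses (Da) and electron counts for elements found in
# protein coordinate files
.ELEMENTS <- data.frame(
  element = c("H", "C", "N", "O", "S", "P", "SE", "FE", "ZN", "MG", "NA",
              "CL", "K", "MN", "CU", "CA", "BR", "I"),
  mass = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 78.971, 55.845,
           65.38, 24.305, 22.990, 35.45, 39.098, 54.938, 63.546, 40.078,
           79.904, 126.904),
  z = c(1L, 6L, 7L, 8L, 16L, 15L, 34L, 26L, 30L, 12L, 11L, 17L, 19L, 25L,
        29L, 20L, 35L, 53L),
  stringsAsFactors = FALSE
)

# infer the element symbol from the PDB element column when present,
# otherwise from the atom name; standard protein atom names start with the
# element letter (after stripping leading digits, e.g. "1HB" -> H)
.inferElement <- function(elety, elesy = NULL) {
  out <- rep(NA_character_, length(elety))
  if (!is.null(elesy)) {
    cand <- toupper(trimws(elesy))
    ok <- !is.na(cand) & cand %in% .ELEMENTS$element
    out[ok] <- cand[ok]
  }
  todo <- is.na(out)
  if (any(todo)) {
    nm <- toupper(gsub("[0-9']", "", trimws(elety[todo])))
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    # two-letter elements that cannot be confused with protein atom names
    twoOk <- two %in% c("SE", "FE", "ZN", "MG", "MN", "CU", "BR")
    res <- ifelse(twoOk, two, one)
    out[todo] <- res
  }
  bad <- !out %in% .ELEMENTS$element
  if (any(bad))
    stop("cannot infer element for atom name(s): ",
         paste(unique(elety[bad]), collapse = ", "))
  out
}

.elementMass <- function(element) .ELEMENTS$mass[match(element, .ELEMENTS$element)]
.elementZ <- function(element) .ELEMENTS$z[match(element, .ELEMENTS$element)]

# count ATOM/HETATM records per MODEL block, for mismatch diagnostics
.scanModels <- function(lines) {
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(sum(isAtom))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  mapply(function(s, e) sum(isAtom[s:e]), starts, ends[seq_along(starts)])
}

#' Read a multi-model PDB into a weighted ensemble
#'
#' Frames are taken in file order. If a weight table is supplied it binds to
#' the models positionally; a `weight` column is normalized as-is, a
#' `bias_kJmol` column is converted with [biasToWeights()] at `temperatureK`.
#' Without a weight table the frames are uniform. Coordinates are converted
#' from Angstrom to nm; atom masses default to standard atomic masses of the
#' element inferred from the atom name.
#'
#' @param coordPath Multi-model (or single-model) PDB file.
#' @param architecture A [DomainArchitecture-class]; chains and residue
#'   ranges are validated against the file.
#' @param weightPath Optional TSV with header naming `weight` or `bias_kJmol`
#'   (an optional `frame` column is ignored), one row per model.
#' @param temperatureK Temperature for bias reweighting, kelvin.
#' @param replicateId Label stored with the ensemble.
#' @return A [WeightedEnsemble-class].
#' @export
readEnsemble <- function(coordPath, architecture, weightPath = NULL,
                         temperatureK = 310,
                         replicateId = basename(coordPath)) {
  stopifnot(is(architecture, "DomainArchitecture"))
  if (!file.exists(coordPath))
    stop("coordinate file not found: ", coordPath)
  counts <- .scanModels(readLines(coordPath, warn = FALSE))
  if (length(counts) > 1 && length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf(
      "atom-table mismatch across models in '%s': model %d has %d atoms, model 1 has %d",
      coordPath, bad, counts[bad], counts[1]))
  }
  pdb <- bio3d::read.pdb(coordPath, multi = TRUE, verbose = FALSE)
  nAt <- nrow(pdb$atom)
  nFr <- nrow(pdb$xyz)
  coords <- aperm(array(t(pdb$xyz), dim = c(3, nAt, nFr)), c(2, 1, 3)) / 10

  element <- .inferElement(pdb$atom$elety, pdb$atom$elesy)
  atoms <- data.frame(
    chain = pdb$atom$chain, resno = pdb$atom$resno, resid = pdb$atom$resid,
    elety = pdb$atom$elety, element = element, mass = .elementMass(element),
    stringsAsFactors = FALSE)

  missingChain <- setdiff(chainIds(architecture), unique(atoms$chain))
  if (length(missingChain))
    stop("unknown chain in architecture: ", paste(missingChain, collapse = ", "),
         " (file has ", paste(unique(atoms$chain), collapse = ", "), ")")
  for (ch in chainIds(architecture)) {
    for (dom in c("VL", "linker", "CL")) {
      r <- domainRange(architecture, dom, ch)
      if (!any(atoms$chain == ch & atoms$resno >= r[1] & atoms$resno <= r[2]))
        stop(sprintf("architecture %s range %d-%d matches no residue in chain %s",
                     dom, r[1], r[2], ch))
    }
  }

  if (is.null(weightPath)) {
    weights <- rep(1 / nFr, nFr)
  } else {
    tab <- utils::read.delim(weightPath, sep = "", header = TRUE,
                             check.names = FALSE)
    if (nrow(tab) != nFr)
      stop(sprintf("weight table '%s' has %d rows but the PDB has %d models",
                   weightPath, nrow(tab), nFr))
    if ("weight" %in% names(tab)) {
      weights <- normalizeWeights(tab$weight)
    } else if ("bias_kJmol" %in% names(tab)) {
      weights <- biasToWeights(tab$bias_kJmol, temperatureK)
    } else {
      stop("weight table must have a 'weight' or 'bias_kJmol' column")
    }
  }
  WeightedEnsemble(atoms = atoms, coords = coords, weights = weights,
                   replicateId = replicateId, temperatureK = temperatureK)
}

#' Write an ensemble as a multi-model PDB (and optional weight table)
#'
#' @param ensemble A [WeightedEnsemble-class].
#' @param coordPath Output PDB path (coordinates written in Angstrom).
#' @param weightPath Optional TSV path for the `frame`/`weight` table.
#' @return Invisibly, `coordPath`.
#' @export
writeEnsemble <- function(ensemble, coordPath, weightPath = NULL) {
  at <- atomTable(ensemble)
  nf <- nFrames(ensemble)
  xyz <- matrix(NA_real_, nf, 3 * nAtoms(ensemble))
  for (i in seq_len(nf)) xyz[i, ] <- as.vector(t(ensemble@coords[, , i])) * 10
  elesy <- if ("element" %in% names(at)) at$element else NULL
  bio3d::write.pdb(file = coordPath, xyz = xyz, resno = at$resno,
                   resid = at$resid, chain = at$chain, elety = at$elety,
                   elesy = elesy)
  if (!is.null(weightPath))
    writeTable(data.frame(frame = seq_len(nf), weight = frameWeights(ensemble)),
               weightPath)
  invisible(coordPath)
}

#' Read a 3-column SAXS curve
#'
#' Whitespace-delimited text; every line that parses as 2 or 3 floats is a
#' data row (q, I and optionally sigma), anything else (headers, comments,
#' blank lines) is skipped. Rows with `I <= 0` are retained but flagged.
#' Sigma is marked unavailable unless every data row carries a third column.
#'
#' @param path Input file.
#' @param qUnit `"A^-1"` (default) or `"nm^-1"`; nm^-1 input is converted to
#'   \eqn{\mathrm{\AA}^{-1}} (divided by 10).
#' @return A [SAXSCurve-class].
#' @export
readSAXSCurve <- function(path, qUnit = c("A^-1", "nm^-1")) {
  qUnit <- match.arg(qUnit)
  lines <- readLines(path, warn = FALSE)
  rows <- lapply(lines, function(ln) {
    toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(toks) < 2 || length(toks) > 3) return(NULL)
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals)) || any(!is.finite(vals))) return(NULL)
    vals
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop("no parsable data rows (need at least 2 numeric columns) in '", path, "'")
  q <- vapply(rows, `[`, numeric(1), 1)
  I <- vapply(rows, `[`, numeric(1), 2)
  n3 <- vapply(rows, length, integer(1))
  sigma <- if (all(n3 == 3L)) vapply(rows, `[`, numeric(1), 3) else NULL
  if (qUnit == "nm^-1") q <- q / 10
  if (any(q <= 0) || any(diff(q) <= 0))
    stop("q must be positive and strictly increasing in '", path, "'")
  SAXSCurve(q = q, I = I, sigma = sigma)
}

#' Write a tabular result as TSV
#'
#' Writes a header line and full-precision floats. Classed results
#' ([PopulationTable-class], [RMSFProfile-class], [SAXSCurve-class]) are
#' converted through their `as.data.frame` methods.
#'
#' @param records A non-empty data.frame (or coercible object).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeTable <- function(records, path) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("refusing to write an empty table")
  utils::write.table(format(records, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [writeTable()]
#'
#' @param path Input path.
#' @return A data.frame.
#' @export
readTable <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
}
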