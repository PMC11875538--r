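writeTempPDB <- function(models) {
  # models: list of data.frames with chain, resno, x, y, z (Angstrom)
  path <- tempfile(fileext = ".pdb")
  con <- file(path, "w")
  for (k in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    m <- models[[k]]
    for (i in seq_len(nrow(m)))
      writeLines(sprintf(
        "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, m$chain[i], m$resno[i], m$x[i], m$y[i], m$z[i]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)
  path
}

dimerModel <- function(shift = 0) {
  data.frame(chain = rep(c("A", "B"), each = 3),
             resno = rep(c(1, 115, 150), 2),
             x = c(0, 0, 0, 2, 2, 2) + shift,
             y = c(0, 10, 20, 0, 10, 20), z = 0)
}

test_that("ensembles read with uniform, explicit and bias-derived weights", {
  arch <- pointArchitecture()
  pdb3 <- writeTempPDB(list(dimerModel(), dimerModel(1), dimerModel(2)))
  ens <- readEnsemble(pdb3, arch)
  expect_equal(frameWeights(ens), rep(1 / 3, 3))
  expect_equal(nAtoms(ens), 6)
  # Angstrom -> nm conversion
  expect_equal(frameCoords(ens, 1)[2, 2], 1.0)

  pdb2 <- writeTempPDB(list(dimerModel(), dimerModel(1)))
  wz <- tempfile(fileext = ".tsv")
  writeLines(c("frame\tbias_kJmol", "1\t0", "2\t0"), wz)
  expect_equal(frameWeights(readEnsemble(pdb2, arch, wz, temperatureK = 310)),
               c(0.5, 0.5))
  we <- tempfile(fileext = ".tsv")
  writeLines(c("frame\tweight", "1\t3", "2\t1"), we)
  expect_equal(frameWeights(readEnsemble(pdb2, arch, we)), c(0.75, 0.25))
})

test_that("malformed ensembles are rejected with informative errors", {
  arch <- pointArchitecture()
  # model 2 misses an atom
  m2 <- dimerModel()[-6, ]
  bad <- writeTempPDB(list(dimerModel(), m2))
  expect_error(readEnsemble(bad, arch), "model 2")
  # weight row count mismatch
  pdb2 <- writeTempPDB(list(dimerModel(), dimerModel(1)))
  w3 <- tempfile(fileext = ".tsv")
  writeLines(c("frame\tweight", "1\t1", "2\t1", "3\t1"), w3)
  expect_error(readEnsemble(pdb2, arch, w3), "3 rows.*2 models")
  # architecture names a chain absent from the file
  archC <- DomainArchitecture(chainIds = c("A", "C"), vl = c(1, 10),
                              linker = c(110, 120), cl = c(140, 160))
  expect_error(readEnsemble(pdb2, archC), "unknown chain")
})

test_that("write/read round trip preserves coordinates and weights", {
  spec <- syntheticSpec(nFrames = 4, seed = 3, beadsPerDomain = 10,
                        linkerBeads = 5, weightModel = "bias_gaussian")
  out <- generateDimerEnsemble(spec)
  arch <- syntheticArchitecture(spec)
  pdb <- tempfile(fileext = ".pdb")
  wts <- tempfile(fileext = ".tsv")
  writeEnsemble(out$ensemble, pdb, wts)
  back <- readEnsemble(pdb, arch, wts)
  expect_lt(max(abs(back@coords - out$ensemble@coords)), 1e-3)
  expect_lt(max(abs(frameWeights(back) - frameWeights(out$ensemble))), 1e-9)
})

test_that("SAXS curves parse with skipped headers, units and flags", {
  p <- tempfile(fileext = ".dat")
  writeLines(c("# sample buffer-subtracted", "q I err   ",
               "0.02 1.5e3 12.0", "0.04\t1.2e3\t11.0  ", "",
               "0.06 900 10.0"), p)
  cv <- readSAXSCurve(p)
  expect_equal(length(qValues(cv)), 3)
  expect_equal(qValues(cv)[1], 0.02)
  expect_equal(intensities(cv)[1], 1500)
  expect_equal(intensitySigma(cv)[1], 12)
  expect_true(hasSigma(cv))
  # nm^-1 input divides q by 10
  expect_equal(qValues(readSAXSCurve(p, qUnit = "nm^-1"))[1], 0.002)
  # two-column file: sigma unavailable; negative intensities flagged
  p2 <- tempfile(fileext = ".dat")
  writeLines(c("0.01 5", "0.02 -1", "0.03 2"), p2)
  cv2 <- readSAXSCurve(p2)
  expect_false(hasSigma(cv2))
  expect_equal(cv2@flagged, 2L)
  # no parsable rows / non-increasing q
  p3 <- tempfile(fileext = ".dat")
  writeLines(c("only text", "1.0"), p3)
  expect_error(readSAXSCurve(p3), "no parsable")
  p4 <- tempfile(fileext = ".dat")
  writeLines(c("0.02 5", "0.01 4"), p4)
  expect_error(readSAXSCurve(p4), "strictly increasing")
})

test_that("tables round-trip through TSV and refuse to be empty", {
  cv <- data.frame(frame = 1:4, theta_rad = c(2.1, 2.8, 2.8, 2.9),
                   d_vc_nm = c(3.1, 3.7, 3.1, 4.4), d_cc_nm = 2.4,
                   d_vv_nm = 2.0, weight = 0.25)
  path <- tempfile(fileext = ".tsv")
  writeTable(cv, path)
  back <- readTable(path)
  expect_equal(back, cv, tolerance = 1e-12)
  pop <- PopulationTable(c(L_B = 62, L_S = 33, G = 0.2, H = 4.8))
  writeTable(pop, path)
  tab <- readTable(path)
  expect_equal(names(tab), c("state", "percent", "stderr"))
  expect_equal(nrow(tab), 4)
  expect_error(writeTable(data.frame(), tempfile()), "empty")
})
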