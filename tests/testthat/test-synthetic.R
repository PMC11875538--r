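test_that("a single-state spec with zero jitter classifies perfectly", {
  spec <- syntheticSpec(nFrames = 200, seed = 2, jitterSd = 0,
                        populations = c(L_B = 100, L_S = 0, G = 0, H = 0))
  out <- generateDimerEnsemble(spec)
  cv <- computeCVTable(out$ensemble, syntheticArchitecture(spec))
  lab <- classifyState(cv$theta_rad, cv$d_vc_nm)
  expect_true(all(lab == "L_B"))
  expect_true(all(out$truthLabels == "L_B"))
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- syntheticSpec(nFrames = 60, seed = 13,
                        weightModel = "bias_gaussian")
  a <- generateDimerEnsemble(spec)
  b <- generateDimerEnsemble(spec)
  expect_identical(a$ensemble@coords, b$ensemble@coords)
  expect_identical(frameWeights(a$ensemble), frameWeights(b$ensemble))
  expect_identical(a$truthCV, b$truthCV)
})

test_that("zero-jitter frames realize the target COM geometry exactly", {
  spec <- syntheticSpec(nFrames = 30, seed = 4, jitterSd = 0)
  out <- generateDimerEnsemble(spec)
  cv <- computeCVTable(out$ensemble, syntheticArchitecture(spec))
  expect_lt(max(abs(cv$theta_rad - out$truthCV$theta_rad)), 1e-9)
  expect_lt(max(abs(cv$d_vc_nm - out$truthCV$d_vc_nm)), 1e-9)
  expect_lt(max(abs(cv$d_cc_nm - out$truthCV$d_cc_nm)), 1e-9)
  expect_lt(max(abs(cv$d_vv_nm - out$truthCV$d_vv_nm)), 1e-9)
})

test_that("write -> read -> classify recovers truth labels", {
  specs <- list(zero = syntheticSpec(nFrames = 300, seed = 6, jitterSd = 0),
                jit = syntheticSpec(nFrames = 2000, seed = 6))
  arch <- syntheticArchitecture(specs$zero)
  # zero jitter through a PDB round trip: 100% label recovery
  out <- generateDimerEnsemble(specs$zero)
  pdb <- tempfile(fileext = ".pdb"); wts <- tempfile(fileext = ".tsv")
  writeEnsemble(out$ensemble, pdb, wts)
  cv <- computeCVTable(readEnsemble(pdb, arch, wts), arch)
  lab <- classifyState(cv$theta_rad, cv$d_vc_nm)
  expect_equal(as.character(lab), as.character(out$truthLabels))
  # default jitter (0.05 nm/bead), in memory: >= 99% recovery
  out2 <- generateDimerEnsemble(specs$jit)
  cv2 <- computeCVTable(out2$ensemble, arch)
  lab2 <- classifyState(cv2$theta_rad, cv2$d_vc_nm)
  expect_gte(mean(lab2 == out2$truthLabels), 0.99)
})

test_that("recovered populations sit inside multinomial bands at n = 2000", {
  target <- c(L_B = 62, L_S = 33, G = 0.2, H = 4.8)
  spec <- syntheticSpec(nFrames = 2000, seed = 1, populations = target)
  out <- generateDimerEnsemble(spec)
  cv <- computeCVTable(out$ensemble, syntheticArchitecture(spec))
  pop <- statePercent(statePopulations(cv))
  band <- 3 * sqrt(target / 100 * (1 - target / 100) / 2000) * 100
  for (s in stateLabels())
    expect_lt(abs(pop[[s]] - target[[s]]), band[[s]] + 1e-9)
})

test_that("infeasible or invalid specs are rejected", {
  expect_error(syntheticSpec(populations = c(50, 50, 50, -50)), "sum")
  # L_S mean outside the straight band
  expect_error(syntheticSpec(stateGeometry = list(L_S = list(theta = c(2.0, 0.1)))),
               "outside its partition region")
  expect_error(syntheticSpec(stateGeometry = list(H = list(dVC = c(3.0, 0.1)))),
               "outside its partition region")
})

test_that("the sphere form factor has the exact limit, first zero and Rg", {
  q <- seq(0.001, 0.3, by = 0.001)
  R <- 2.0
  crv <- sphereIntensity(R, q, i0 = 42)
  expect_equal(intensities(sphereIntensity(R, 0, i0 = 42)), 42)
  # first zero where tan(x) = x: x ~ 4.4934
  x <- q * 10 * R
  i0n <- intensities(crv) / 42
  firstZero <- x[which(diff(sign(diff(i0n))) != 0)[1] + 1]
  minI <- min(i0n[abs(x - 4.4934) < 0.05])
  expect_lt(minI, 1e-6)
  expect_equal(firstZero, 4.4934, tolerance = 0.01)
})

test_that("noisy curves are seeded, sized and chi2-consistent", {
  q <- seq(0.005, 0.2, length.out = 200)
  clean <- SAXSCurve(q, 500 * exp(-q^2 * 500))
  n1 <- makeNoisyCurve(clean, 0.02, seed = 3)
  n2 <- makeNoisyCurve(clean, 0.02, seed = 3)
  expect_identical(intensities(n1), intensities(n2))
  expect_equal(intensitySigma(n1), 0.02 * intensities(clean))
  # tiny noise returns the input within tolerance
  tiny <- makeNoisyCurve(clean, 1e-12, seed = 1)
  expect_equal(intensities(tiny), intensities(clean), tolerance = 1e-9)
  # reduced chi2 of noisy vs clean with fitted scale is ~1
  fit <- fitScaleChi2(clean, n1)
  expect_gt(fitChi2(fit), 0.5)
  expect_lt(fitChi2(fit), 1.5)
})
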