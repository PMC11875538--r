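test_that("Debye intensities match point-scatterer closed forms", {
  q <- seq(0, 0.25, by = 0.01)
  one <- debyeIntensity(matrix(c(0.5, 0.5, 0.5), 1, 3), q)
  expect_equal(intensities(one), rep(1, length(q)))
  # two unit scatterers at distance d: I = 2 (1 + sin(qd)/(qd))
  d <- 2
  two <- debyeIntensity(rbind(c(0, 0, 0), c(d, 0, 0)), q)
  qd <- q * 10 * d
  ref <- 2 * (1 + ifelse(qd == 0, 1, sin(qd) / qd))
  expect_equal(intensities(two), ref, tolerance = 1e-10)
  expect_error(debyeIntensity(rbind(c(0, 0, 0)), c(-0.1, 0.1)), "negative q")
})

test_that("I(0) equals (sum f)^2 and bounds the curve for a convex shape", {
  set.seed(14)
  pos <- matrix(rnorm(300), 100, 3)
  pos <- pos / sqrt(rowSums(pos^2)) * runif(100)^(1 / 3)  # ball, radius 1 nm
  f <- runif(100, 5, 9)
  crv <- debyeIntensity(pos, seq(0, 0.3, by = 0.005), f = f)
  expect_equal(intensities(crv)[1], sum(f)^2)
  expect_true(all(intensities(crv) <= intensities(crv)[1] + 1e-9))
})

test_that("low-q slope of ln I reproduces the coordinate radius of gyration", {
  set.seed(15)
  pos <- matrix(rnorm(240, sd = 1), 80, 3)
  f <- rep(1, 80)
  com <- colMeans(pos)
  rg <- sqrt(mean(rowSums(sweep(pos, 2, com)^2)))       # nm
  qmax <- 0.5 / (rg * 10)                               # q*Rg < 0.5
  q <- seq(qmax / 20, qmax, length.out = 20)
  crv <- debyeIntensity(pos, q, f = f)
  slope <- unname(coef(lm(log(intensities(crv)) ~ I((q * 10)^2)))[2])
  expect_equal(sqrt(-3 * slope), rg, tolerance = 0.01)
})

test_that("ensemble intensity is the weight-linear combination of frames", {
  spec <- syntheticSpec(nFrames = 2, seed = 23, beadsPerDomain = 8,
                        linkerBeads = 3)
  ens <- generateDimerEnsemble(spec)$ensemble
  q <- seq(0.005, 0.1, by = 0.005)
  I1 <- intensities(debyeIntensity(ens, q, frame = 1))
  I2 <- intensities(debyeIntensity(ens, q, frame = 2))
  expect_equal(intensities(ensembleIntensity(ens, q)), (I1 + I2) / 2)
  w10 <- initialize(ens, weights = c(1, 0))
  expect_equal(intensities(ensembleIntensity(w10, q)), I1)
})

test_that("scale fitting solves the weighted normal equations", {
  q <- seq(0.01, 0.2, length.out = 30)
  I <- 100 * exp(-q^2 * 300)
  calc <- SAXSCurve(q, I)
  idFit <- fitScaleChi2(calc, SAXSCurve(q, I, sigma = rep(1, 30)))
  expect_equal(fitScale(idFit), 1)
  expect_equal(fitChi2(idFit), 0, tolerance = 1e-20)
  expect_equal(fitResiduals(idFit), rep(0, 30), tolerance = 1e-10)
  dbl <- fitScaleChi2(calc, SAXSCurve(q, 2 * I, sigma = rep(1, 30)))
  expect_equal(fitScale(dbl), 2)
  expect_equal(fitChi2(dbl), 0, tolerance = 1e-20)
  # 3-point toy with hand normal equations
  toy <- fitScaleChi2(SAXSCurve(c(0.01, 0.02, 0.03), c(5, 2.5, 1)),
                      SAXSCurve(c(0.01, 0.02, 0.03), c(10, 5, 2),
                                sigma = c(1, 1, 1)))
  expect_equal(fitScale(toy), 2)
  expect_equal(fitChi2(toy), 0, tolerance = 1e-20)
  # background absorbs an additive offset
  off <- fitScaleChi2(calc, SAXSCurve(q, 3 * I + 7, sigma = rep(1, 30)),
                      fitBackground = TRUE)
  expect_equal(fitScale(off), 3)
  expect_equal(off@background, 7)
  expect_error(fitScaleChi2(calc, SAXSCurve(q, I)), "no sigma")
})

test_that("Guinier fits recover exact-law and sphere radii", {
  q <- seq(0.002, 0.25, by = 0.002)
  rgA <- 25  # 2.5 nm
  Ilaw <- 100 * exp(-q^2 * rgA^2 / 3)
  law <- SAXSCurve(q, Ilaw, sigma = 0.01 * Ilaw)
  gu <- guinierRg(law)
  expect_equal(guinierRgValue(gu), 2.5, tolerance = 1e-6)
  expect_equal(guinierI0(gu), 100, tolerance = 1e-6)
  # analytic sphere: Rg = sqrt(3/5) R within 1%
  sph <- guinierRg(sphereIntensity(3.227, q, i0 = 50))
  expect_equal(guinierRgValue(sph), sqrt(3 / 5) * 3.227, tolerance = 0.01)
  expect_lte(sph@qmaxRg, 1.3 + 1e-9)
  # rising curve has no Guinier regime
  expect_error(guinierRg(SAXSCurve(q, exp(q^2 * 100))),
               "no Guinier regime", class = "lcfpNumericalError")
  expect_error(guinierRg(SAXSCurve(q[1:4], q[1:4] + 1)), "fewer than 5")
})

test_that("noisy-curve Guinier estimates cover the truth", {
  q <- seq(0.005, 0.15, length.out = 120)
  clean <- SAXSCurve(q, 100 * exp(-q^2 * 625 / 3))
  nz <- makeNoisyCurve(clean, 0.02, seed = 7)
  gu <- guinierRg(nz)
  expect_lt(abs(guinierRgValue(gu) - 2.5), 3 * gu@rgStderr)
})

test_that("Kratky transform peaks at sqrt(3)/Rg for the Guinier law", {
  q <- seq(0.001, 0.3, by = 0.001)
  rgA <- 25
  crv <- SAXSCurve(q, 100 * exp(-q^2 * rgA^2 / 3))
  kr <- kratky(crv)
  expect_equal(intensities(kr), q^2 * intensities(crv))
  qPeak <- qValues(kr)[which.max(intensities(kr))]
  # agreement limited by the q-grid resolution (half a 0.001 step)
  expect_equal(qPeak, sqrt(3) / rgA, tolerance = 0.01)
})

test_that("averaging identical frames commutes with scale fitting", {
  spec <- syntheticSpec(nFrames = 3, seed = 29, beadsPerDomain = 6,
                        linkerBeads = 3, jitterSd = 0,
                        populations = c(100, 0, 0, 0))
  ens <- generateDimerEnsemble(spec)$ensemble
  # zero jitter + single state still varies CVs; force identical frames
  co <- ens@coords
  co[, , 2] <- co[, , 1]; co[, , 3] <- co[, , 1]
  same <- initialize(ens, coords = co)
  q <- seq(0.005, 0.1, by = 0.005)
  ref <- debyeIntensity(same, q, frame = 1)
  avg <- ensembleIntensity(same, q)
  target <- SAXSCurve(q, 2 * intensities(ref), sigma = 0.01 * intensities(ref))
  expect_equal(fitScale(fitScaleChi2(avg, target)),
               fitScale(fitScaleChi2(ref, target)))
})
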