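squareDimer <- function() {
  # unit-mass point domains on a square of side 2 (linkers midway)
  pointDimer(list(vlA = c(0, 0, 0), vlB = c(2, 0, 0),
                  clA = c(0, 2, 0), clB = c(2, 2, 0),
                  lnA = c(1, 1, 0), lnB = c(1, 1, 0)),
             masses = rep(1, 6))
}

test_that("center of mass matches hand-computed values", {
  ens <- squareDimer()
  expect_equal(centerOfMass(ens, atomSelection(ens, chain = "A", resno = 1)),
               c(0, 0, 0))
  # equal masses, symmetric pair
  expect_equal(centerOfMass(ens, atomSelection(ens, resno = 1)), c(1, 0, 0))
  # masses (12, 1) at x = 0 and x = 1.3 -> 0.1
  ens2 <- pointDimer(list(vlA = c(0, 0, 0), vlB = c(1.3, 0, 0),
                          clA = c(0, 1, 0), clB = c(0, 1, 0),
                          lnA = c(0, .5, 0), lnB = c(0, .5, 0)),
                     masses = c(12, 1, 1, 1, 1, 1))
  expect_equal(centerOfMass(ens2, atomSelection(ens2, resno = 1)),
               c(0.1, 0, 0))
  expect_error(centerOfMass(ens, integer()), "empty")
})

test_that("elbow angle reproduces collinear and perpendicular geometries", {
  arch <- pointArchitecture()
  straight <- pointDimer(list(vlA = c(0, 0, 2), vlB = c(0, 0, 2),
                              lnA = c(0, 0, 0), lnB = c(0, 0, 0),
                              clA = c(0, 0, -2), clB = c(0, 0, -2)))
  expect_equal(elbowAngle(straight, arch, frame = 1), pi)
  bent <- pointDimer(list(vlA = c(2, 0, 0), vlB = c(2, 0, 0),
                          lnA = c(0, 0, 0), lnB = c(0, 0, 0),
                          clA = c(0, 2, 0), clB = c(0, 2, 0)))
  expect_equal(elbowAngle(bent, arch, frame = 1), pi / 2)
})

test_that("elbow angle errors on degenerate arm geometry", {
  arch <- pointArchitecture()
  degen <- pointDimer(list(vlA = c(0, 0, 0), vlB = c(0, 0, 0),
                           lnA = c(0, 0, 0), lnB = c(0, 0, 0),
                           clA = c(0, 0, -2), clB = c(0, 0, -2)))
  expect_error(elbowAngle(degen, arch), "degenerate")
})

test_that("interdomain distances match hand geometry and chain-swap symmetry", {
  arch <- pointArchitecture()
  d <- interdomainDistances(squareDimer(), arch, frame = 1)
  expect_equal(unname(d), c(2, 2, 2))
  # d_vc at the printed state boundary 3.4 nm
  ens <- pointDimer(list(vlA = c(1, 0, 0), vlB = c(-1, 0, 0),
                         clA = c(1, 0, 3.4), clB = c(-1, 0, 3.4),
                         lnA = c(0, 0, 1.7), lnB = c(0, 0, 1.7)))
  expect_equal(unname(interdomainDistances(ens, arch, frame = 1)[["d_vc"]]), 3.4)
  # swapping the chain labels leaves all three distances unchanged
  archSwap <- DomainArchitecture(chainIds = c("B", "A"), vl = c(1, 10),
                                 linker = c(110, 120), cl = c(140, 160))
  expect_equal(interdomainDistances(ens, arch, frame = 1),
               interdomainDistances(ens, archSwap, frame = 1))
  expect_equal(elbowAngle(ens, arch, 1), elbowAngle(ens, archSwap, 1))
})

test_that("all CVs are invariant under rigid-body transforms", {
  spec <- syntheticSpec(nFrames = 3, seed = 5)
  out <- generateDimerEnsemble(spec)
  arch <- syntheticArchitecture(spec)
  ref <- computeCVTable(out$ensemble, arch)
  set.seed(42)
  for (i in 1:100) {
    ens2 <- transformEnsemble(out$ensemble, randomRotation(), rnorm(3, sd = 5))
    cv2 <- computeCVTable(ens2, arch)
    expect_equal(cv2$theta_rad, ref$theta_rad, tolerance = 1e-9)
    expect_equal(cv2$d_vc_nm, ref$d_vc_nm, tolerance = 1e-9)
    expect_equal(cv2$d_cc_nm, ref$d_cc_nm, tolerance = 1e-9)
    expect_equal(cv2$d_vv_nm, ref$d_vv_nm, tolerance = 1e-9)
  }
})

test_that("CV table recovers generator ground truth", {
  spec <- syntheticSpec(nFrames = 50, seed = 7, jitterSd = 0)
  out <- generateDimerEnsemble(spec)
  arch <- syntheticArchitecture(spec)
  cv <- computeCVTable(out$ensemble, arch)
  # zero jitter: targets met exactly (construction realizes COMs exactly)
  expect_equal(cv$theta_rad, out$truthCV$theta_rad, tolerance = 1e-6)
  expect_equal(cv$d_vc_nm, out$truthCV$d_vc_nm, tolerance = 1e-6)
  expect_equal(cv$weight, rep(1 / 50, 50))
  # default jitter: recovered within 0.05 rad / 0.05 nm
  spec2 <- syntheticSpec(nFrames = 50, seed = 7)
  out2 <- generateDimerEnsemble(spec2)
  cv2 <- computeCVTable(out2$ensemble, arch)
  expect_lt(max(abs(cv2$theta_rad - out2$truthCV$theta_rad)), 0.05)
  expect_lt(max(abs(cv2$d_vc_nm - out2$truthCV$d_vc_nm)), 0.05)
})

test_that("duplicated frames give duplicated CV rows", {
  ens <- squareDimer()
  dup <- WeightedEnsemble(atomTable(ens),
                          array(rep(ens@coords, 2), dim = c(6, 3, 2)))
  cv <- computeCVTable(dup, pointArchitecture())
  expect_equal(nrow(cv), 2)
  expect_equal(cv$theta_rad[1], cv$theta_rad[2])
  expect_equal(cv$d_vc_nm[1], cv$d_vc_nm[2])
})
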