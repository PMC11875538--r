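# In-code fixtures: point-mass dimers, backbone peptides with prescribed
# dihedrals, random rigid transforms. No files are shipped; everything is
# built here at test time.

# architecture whose domains are single point residues
pointArchitecture <- function() {
  DomainArchitecture(chainIds = c("A", "B"), vl = c(1, 10),
                     linker = c(110, 120), cl = c(140, 160))
}

# 6-atom dimer: one atom per domain per chain (VL, linker, CL)
# positions: list with vlA, vlB, lnA, lnB, clA, clB 3-vectors (nm)
pointDimer <- function(pos, masses = rep(12, 6), nCopies = 1, weights = NULL) {
  atoms <- data.frame(
    chain = c("A", "A", "A", "B", "B", "B"),
    resno = c(1, 115, 150, 1, 115, 150),
    resid = "GLY", elety = "CA", element = "C",
    mass = masses, stringsAsFactors = FALSE)
  fr <- rbind(pos$vlA, pos$lnA, pos$clA, pos$vlB, pos$lnB, pos$clB)
  coords <- array(rep(fr, nCopies), dim = c(6, 3, nCopies))
  WeightedEnsemble(atoms, coords, weights)
}

randomRotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr.Q(qr(m)) * sample(c(-1, 1), 1)
}

# NeRF atom placement: D bonded to C with |CD| = r, angle(B,C,D) = ang (deg)
# and dihedral(A,B,C,D) = tor (deg)
placeAtom <- function(A, B, C, r, ang, tor) {
  ang <- ang * pi / 180; tor <- tor * pi / 180
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b2 <- C - B; b2 <- b2 / sqrt(sum(b2^2))
  n <- cross(B - A, b2); n <- n / sqrt(sum(n^2))
  m <- cross(n, b2)
  d <- c(-r * cos(ang), r * sin(ang) * cos(tor), -r * sin(ang) * sin(tor))
  C + d[1] * b2 + d[2] * m + d[3] * n
}

# backbone (N, CA, C) x 3 residues; middle residue gets the requested
# phi/psi; bond geometry is ideal, omega = 180
peptideFrame <- function(phi, psi) {
  N1 <- c(0, 0, 0); CA1 <- c(0.1458, 0, 0)
  C1 <- placeAtom(c(0, 0, 1), N1, CA1, 0.1525, 111, 60)
  N2 <- placeAtom(N1, CA1, C1, 0.1329, 116.2, 140)      # psi1, arbitrary
  CA2 <- placeAtom(CA1, C1, N2, 0.1458, 121.7, 180)     # omega
  C2 <- placeAtom(C1, N2, CA2, 0.1525, 111, phi)        # phi of residue 2
  N3 <- placeAtom(N2, CA2, C2, 0.1329, 116.2, psi)      # psi of residue 2
  CA3 <- placeAtom(CA2, C2, N3, 0.1458, 121.7, 180)
  C3 <- placeAtom(C2, N3, CA3, 0.1525, 111, -60)
  rbind(N1, CA1, C1, N2, CA2, C2, N3, CA3, C3)
}

peptideEnsemble <- function(phis, psis, weights = NULL) {
  atoms <- data.frame(
    chain = "A", resno = rep(1:3, each = 3), resid = "ALA",
    elety = rep(c("N", "CA", "C"), 3), element = rep(c("N", "C", "C"), 3),
    mass = rep(c(14.007, 12.011, 12.011), 3), stringsAsFactors = FALSE)
  coords <- array(NA_real_, dim = c(9, 3, length(phis)))
  for (i in seq_along(phis)) coords[, , i] <- peptideFrame(phis[i], psis[i])
  WeightedEnsemble(atoms, coords, weights)
}
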