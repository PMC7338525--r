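# Independent reference implementations used as oracles. These are coded
# from the closed-form expressions directly and share no code with the
# package internals.

# Lipari-Szabo spectral density, SI units throughout.
oracle_J <- function(w, S2, tm, te, Sf2 = 1) {
  tau <- if (te > 0) tm * te / (tm + te) else 0
  0.4 * (S2 * tm / (1 + (w * tm)^2) + (Sf2 - S2) * tau / (1 + (w * tau)^2))
}

# Dipolar + CSA relaxation observables from first principles.
oracle_rates <- function(S2, tm_ns, te_ps, Rex, proton_mhz = 700,
                         Sf2 = 1, r_NH = 1.02, delta_sigma = -172) {
  gH <- 2.6752218744e8
  gN <- -2.71261804e7
  hbar <- 1.054571817e-34
  B0 <- 2 * pi * proton_mhz * 1e6 / gH
  wH <- gH * B0
  wN <- abs(gN) * B0
  d2 <- (1e-7 * hbar * gH * abs(gN) / (r_NH * 1e-10)^3)^2
  c2 <- (wN * delta_sigma * 1e-6)^2 / 3
  tm <- tm_ns * 1e-9
  te <- te_ps * 1e-12
  Jv <- vapply(c(0, wN, wH - wN, wH, wH + wN), oracle_J, numeric(1),
               S2 = S2, tm = tm, te = te, Sf2 = Sf2)
  R1 <- d2 / 4 * (Jv[3] + 3 * Jv[2] + 6 * Jv[5]) + c2 * Jv[2]
  R2 <- d2 / 8 * (4 * Jv[1] + Jv[3] + 3 * Jv[2] + 6 * Jv[4] + 6 * Jv[5]) +
    c2 / 6 * (4 * Jv[1] + 3 * Jv[2]) + Rex
  NOE <- 1 + d2 / 4 * (gH / gN) / R1 * (6 * Jv[5] - Jv[3])
  c(R1 = R1, R2 = R2, NOE = NOE)
}

# Horn's quaternion absolute-orientation method: the minimum RMSD between
# two centred point sets equals that of the Kabsch solution.
oracle_quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- sum(A^2) + sum(B^2) - 2 * lam
  sqrt(max(0, e2) / nrow(A))
}

# Signed dihedral from four points, coded via the plane-normal convention.
oracle_dihedral <- function(p1, p2, p3, p4) {
  u1 <- p2 - p1; u2 <- p3 - p2; u3 <- p4 - p3
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cx(u1, u2); n2 <- cx(u2, u3)
  x <- sum(n1 * n2)
  y <- sum(cx(n1, u2) * n2) / sqrt(sum(u2^2))
  atan2(y, x) * 180 / pi
}

# Small rigid helper: rotation matrix about z by deg.
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}
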