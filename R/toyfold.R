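# Internal-coordinate chain building (NeRF): place atom D bonded to C with
# bond length r, angle B-C-D (deg) and torsion A-B-C-D (deg).
place_atom <- function(A, B, C, r, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180  # sign fixed to the IUPAC dihedral convention
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(ang), r * sin(ang) * cos(tor), r * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build an ideal polypeptide backbone (N, CA, C, O, H, HA per residue,
# alanine-like) from phi/psi/omega torsions. Standard bond geometry.
build_backbone <- function(n_res, phi, psi, omega = 180,
                           resname = "ALA", chain = "A", resno_start = 1L) {
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7
  atoms <- list(); xyz <- list()
  add <- function(resno, name, p) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      chain = chain, resno = resno, resname = resname, atom = name)
    xyz[[length(xyz) + 1]] <<- p
  }
  # seed the first residue in a canonical frame
  N <- c(0, 0, 0)
  CA <- c(b_NCA, 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, b_CAC, a_NCAC, phi[1] + 180)
  rn <- resno_start
  add(rn, "N", N); add(rn, "CA", CA)
  add(rn, "HA", place_atom(C, N, CA, 1.09, 109.5, 240))
  add(rn, "C", C)
  add(rn, "O", place_atom(N, CA, C, 1.231, 120.8, psi[1] + 180))
  prevN <- N; prevCA <- CA; prevC <- C
  for (i in seq_len(n_res - 1L)) {
    rn <- resno_start + i
    N <- place_atom(prevN, prevCA, prevC, b_CN, a_CACN, psi[i])
    CA <- place_atom(prevCA, prevC, N, b_NCA, a_CNCA, omega)
    C <- place_atom(prevC, N, CA, b_CAC, a_NCAC, phi[i + 1])
    add(rn, "N", N)
    add(rn, "H", place_atom(C, CA, N, 0.98, 119.0, phi[i + 1] + 180))
    add(rn, "CA", CA)
    add(rn, "HA", place_atom(prevC, N, CA, 1.09, 109.5, phi[i + 1] + 120))
    add(rn, "C", C)
    add(rn, "O", place_atom(N, CA, C, 1.231, 120.8, psi[i + 1] + 180))
    prevN <- N; prevCA <- CA; prevC <- C
  }
  structure_ensemble(do.call(rbind, atoms),
                     list(do.call(rbind, xyz)))
}

#' Parametric toy protein folds
#'
#' Idealized single-model base structures for testing superposition,
#' precision and restraint machinery: a canonical alpha-helix
#' (phi = -57, psi = -47) or a crude five-strand beta-barrel (extended
#' strands placed around a cylinder, alternating direction, with chain
#' breaks between strands). These supply realistic local geometry, not a
#' model of any real protein.
#'
#' @param fold "helix" or "barrel".
#' @param n_res residues (helix) or residues per strand (barrel).
#' @return a single-model `structure_ensemble`.
#' @export
toy_fold <- function(fold = c("helix", "barrel"), n_res = 20) {
  fold <- match.arg(fold)
  if (fold == "helix") return(build_backbone(n_res, -57, -47))
  # barrel: five extended strands around a cylinder of radius 6 A
  strands <- list()
  for (k in 0:4) {
    s <- build_backbone(n_res, -120, 130, resno_start = 1L + k * (n_res + 2L))
    m <- s$coords[[1]]
    # align the strand's end-to-end vector with +/- z
    v <- m[nrow(m), ] - m[1, ]; v <- v / sqrt(sum(v^2))
    z <- c(0, 0, if (k %% 2 == 0) 1 else -1)
    ax <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
    sa <- sqrt(sum(ax^2)); ca <- sum(v * z)
    if (sa > 1e-9) {
      ax <- ax / sa
      th <- atan2(sa, ca)
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
      m <- sweep(m, 2, colMeans(m)) %*% t(R)
    } else m <- sweep(m, 2, colMeans(m))
    ang <- 2 * pi * k / 5
    m <- sweep(m, 2, c(6 * cos(ang), 6 * sin(ang), 0), "+")
    strands[[k + 1]] <- list(atoms = s$atoms, m = m)
  }
  structure_ensemble(do.call(rbind, lapply(strands, `[[`, "atoms")),
                     list(do.call(rbind, lapply(strands, `[[`, "m"))))
}
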