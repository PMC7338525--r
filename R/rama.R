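#' Backbone phi/psi dihedrals of an ensemble
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#' Terminal residues (no neighbour) and residues across chain breaks
#' (missing backbone atoms) are skipped and counted.
#'
#' @param ens a `structure_ensemble`.
#' @param model model index.
#' @return list: `angles` (data.frame residue, resname, phi, psi),
#'   `n_skipped`.
#' @export
phi_psi <- function(ens, model = 1) {
  stopifnot(inherits(ens, "structure_ensemble"))
  a <- ens$atoms
  m <- ens$coords[[model]]
  res <- sort(unique(a$resno))
  at <- function(r, nm) {
    i <- which(a$resno == r & a$atom == nm)
    if (length(i) == 1) m[i, ] else NULL
  }
  rows <- list(); skipped <- 0L
  for (r in res) {
    Cm <- at(r - 1, "C"); N <- at(r, "N"); CA <- at(r, "CA")
    C <- at(r, "C"); Np <- at(r + 1, "N")
    if (is.null(N) || is.null(CA) || is.null(C) ||
        (is.null(Cm) && is.null(Np))) {
      skipped <- skipped + 1L
      next
    }
    phi <- if (!is.null(Cm)) dihedral_angle(Cm, N, CA, C) else NA_real_
    psi <- if (!is.null(Np)) dihedral_angle(N, CA, C, Np) else NA_real_
    rn <- a$resname[which(a$resno == r)[1]]
    rows[[length(rows) + 1]] <- data.frame(residue = r, resname = rn,
                                           phi = phi, psi = psi)
  }
  list(angles = if (length(rows)) do.call(rbind, rows) else
    data.frame(residue = integer(0), resname = character(0),
               phi = numeric(0), psi = numeric(0)),
    n_skipped = skipped)
}

# Coarse Ramachandran region classification. Deliberately generous
# rectangular regions (NOT the PROCHECK polygon dialect): "favored" covers
# the canonical alpha and beta basins (plus left-handed alpha for
# glycine), "allowed" a broadened margin, everything else "outlier".
rama_region <- function(phi, psi, glycine = FALSE) {
  if (is.na(phi) || is.na(psi)) return(NA_character_)
  in_box <- function(p1, p2, b) p1 >= b[1] && p1 <= b[2] &&
    p2 >= b[3] && p2 <= b[4]
  alpha <- c(-160, -20, -90, 30)
  beta <- c(-180, -45, 90, 180)
  beta2 <- c(-180, -45, -180, -150)  # psi wrap of the beta basin
  lalpha <- c(20, 100, -20, 90)
  fav <- in_box(phi, psi, alpha) || in_box(phi, psi, beta) ||
    in_box(phi, psi, beta2) || (glycine && in_box(phi, psi, lalpha))
  if (fav) return("favored")
  grow <- function(b, d) c(b[1] - d, b[2] + d, b[3] - d, b[4] + d)
  alw <- in_box(phi, psi, grow(alpha, 20)) ||
    in_box(phi, psi, grow(beta, 20)) || in_box(phi, psi, grow(beta2, 20)) ||
    in_box(phi, psi, grow(lalpha, 20)) ||
    (glycine)  # glycine accesses most of the map
  if (alw) "allowed" else "outlier"
}

#' Coarse Ramachandran summary of an ensemble
#'
#' Classifies every residue of every model into favored / allowed /
#' outlier using coarse rectangular regions around the alpha and beta
#' basins (glycine gets its mirrored regions). This is a screening
#' statistic: region definitions differ between validation programs, so
#' fractions are not comparable to PROCHECK output at the percent level.
#'
#' @param ens a `structure_ensemble`.
#' @param models model indices to include (default all).
#' @return list: `fractions` (named: favored, allowed, outlier),
#'   `counts`, `n_residues_scored`, `n_skipped`.
#' @export
ramachandran_summary <- function(ens, models = seq_len(n_models(ens))) {
  cls <- character(0); skipped <- 0L
  for (mi in models) {
    pp <- phi_psi(ens, mi)
    skipped <- skipped + pp$n_skipped
    ang <- pp$angles
    ang <- ang[!is.na(ang$phi) & !is.na(ang$psi), , drop = FALSE]
    if (nrow(ang))
      cls <- c(cls, mapply(rama_region, ang$phi, ang$psi,
                           ang$resname == "GLY"))
  }
  lev <- c("favored", "allowed", "outlier")
  counts <- stats::setNames(as.integer(table(factor(cls, levels = lev))), lev)
  n <- length(cls)
  fractions <- stats::setNames(
    if (n) as.numeric(counts) / n else rep(NA_real_, 3), lev)
  list(fractions = fractions, counts = counts,
       n_residues_scored = n, n_skipped = skipped)
}
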