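#' Multi-model structure ensemble
#'
#' Container for an NMR-style ensemble: one shared atom identity table
#' (chain, residue number, residue name, atom name) and one coordinate
#' matrix per model.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `atom`.
#' @param coords list of n_atoms x 3 numeric matrices (Angstrom), one per
#'   model.
#' @return object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(atoms, coords) {
  need <- c("chain", "resno", "resname", "atom")
  if (!all(need %in% names(atoms)))
    stop("atoms needs columns: ", paste(need, collapse = ", "))
  if (!length(coords)) stop("ensemble needs at least one model")
  for (i in seq_along(coords)) {
    m <- coords[[i]]
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != nrow(atoms))
      stop("model ", i, " coordinates must be a ", nrow(atoms),
           " x 3 matrix")
  }
  structure(list(atoms = atoms, coords = coords),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("structure_ensemble:", length(x$coords), "model(s),",
      nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resno)), "residues\n")
  invisible(x)
}

#' Number of models in an ensemble
#' @param ens a `structure_ensemble`.
#' @export
n_models <- function(ens) length(ens$coords)

# Pre-scan a multi-model PDB: verify that every MODEL block carries an
# identical atom identity list (columns 13-27 of ATOM/HETATM records).
check_pdb_model_consistency <- function(path) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) < 2) return(invisible(TRUE))
  model_ends <- grep("^ENDMDL", lines)
  ids <- lapply(seq_along(model_starts), function(i) {
    blk <- lines[model_starts[i]:model_ends[i]]
    substr(grep("^(ATOM|HETATM)", blk, value = TRUE), 13, 27)
  })
  ref <- ids[[1]]
  bad <- which(!vapply(ids, function(x) identical(x, ref), logical(1)))
  if (length(bad))
    stop("atom identity differs across models; offending model block(s): ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Read a multi-model structure file into an ensemble
#'
#' Reads PDB (multi-model, via bio3d) or mmCIF files. For PDB input the
#' per-model atom identity lists are checked for consistency first and an
#' error names the offending model blocks. mmCIF reading uses bio3d's
#' single-model reader; files whose models would be collapsed raise an
#' error recommending the PDB format.
#'
#' @param path file path (`.pdb` or `.cif`).
#' @return a `structure_ensemble`.
#' @export
read_ensemble <- function(path) {
  if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    tagi <- grep("^_atom_site\\.", lines)
    if (length(tagi)) {
      tags <- sub("^_atom_site\\.", "", trimws(lines[tagi]))
      mcol <- match("pdbx_PDB_model_num", tags)
      if (!is.na(mcol)) {
        rows <- grep("^(ATOM|HETATM)\\s", lines, value = TRUE)
        modnum <- vapply(strsplit(rows, "\\s+"), `[`, "", mcol)
        if (length(unique(modnum)) > 1)
          stop("multi-model mmCIF is not supported; convert to multi-model ",
               "PDB for ensemble reading")
      }
    }
    pdb <- bio3d::read.cif(path)
    nmod <- 1L
  } else {
    check_pdb_model_consistency(path)
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    nmod <- nrow(pdb$xyz)
  }
  atoms <- data.frame(chain = pdb$atom$chain, resno = pdb$atom$resno,
                      resname = pdb$atom$resid, atom = pdb$atom$elety,
                      stringsAsFactors = FALSE)
  coords <- lapply(seq_len(nmod), function(i)
    matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE))
  structure_ensemble(atoms, coords)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens a `structure_ensemble`.
#' @param path output path.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "structure_ensemble"))
  xyz <- do.call(rbind, lapply(ens$coords, function(m) as.numeric(t(m))))
  na <- nrow(ens$atoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(xyz))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    el <- substr(trimws(ens$atoms$atom), 1, 1)
    name4 <- ifelse(nchar(ens$atoms$atom) >= 4,
                    substr(ens$atoms$atom, 1, 4),
                    sprintf(" %-3s", ens$atoms$atom))
    writeLines(sprintf(
      "ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(na), name4, ens$atoms$resname, ens$atoms$chain,
      ens$atoms$resno, m[, 1], m[, 2], m[, 3], el), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Row indices of the atoms matching a selection.
resolve_selection <- function(ens, residues = NULL, atom_names = NULL) {
  sel <- rep(TRUE, nrow(ens$atoms))
  if (!is.null(residues)) sel <- sel & ens$atoms$resno %in% residues
  if (!is.null(atom_names)) sel <- sel & ens$atoms$atom %in% atom_names
  which(sel)
}

#' Kabsch rigid-body superposition
#'
#' Least-squares superposition of a mobile coordinate set onto a reference
#' by the Kabsch (SVD) algorithm, constrained to proper rotations
#' (det = +1).
#'
#' @param mobile,reference n x 3 coordinate matrices (n >= 3,
#'   non-collinear).
#' @return list: `rotation` (3x3), `translation` (length 3; the
#'   superposed coordinates are `mobile %*% t(rotation) + translation`),
#'   `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference) {
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3)
    stop("coordinate sets must be equal-size n x 3 matrices")
  if (nrow(mobile) < 3) stop("need at least 3 atoms to superpose")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (qr(A)$rank < 2) stop("selected atoms are collinear; superposition undefined")
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr) - as.numeric(R %*% cm),
       rmsd = rmsd)
}

# RMSD between two models of an ensemble after superposition over idx.
pair_rmsd <- function(ens, i, j, idx) {
  kabsch_superpose(ens$coords[[i]][idx, , drop = FALSE],
                   ens$coords[[j]][idx, , drop = FALSE])$rmsd
}

#' Select the representative model of an ensemble
#'
#' The representative is the member with the lowest sum of pairwise RMSDs
#' to all other members (superposition computed over the given selection);
#' ties break to the lowest model index.
#'
#' @param ens a `structure_ensemble` with >= 2 models.
#' @param residues residue numbers of the selection (NULL = all).
#' @param atom_names atom names of the selection (default backbone
#'   N, CA, C).
#' @return list: `index`, `rmsd_sum` (per-model sums), `rmsd_matrix`.
#' @export
select_representative <- function(ens, residues = NULL,
                                  atom_names = c("N", "CA", "C")) {
  stopifnot(inherits(ens, "structure_ensemble"))
  nm <- n_models(ens)
  if (nm < 2) stop("need at least 2 models")
  idx <- resolve_selection(ens, residues, atom_names)
  if (!length(idx)) stop("selection matches no atoms")
  M <- matrix(0, nm, nm)
  for (i in seq_len(nm - 1)) for (j in (i + 1):nm) {
    M[i, j] <- M[j, i] <- pair_rmsd(ens, i, j, idx)
  }
  sums <- rowSums(M)
  list(index = which.min(sums), rmsd_sum = sums, rmsd_matrix = M)
}

#' Ensemble coordinate precision about the representative
#'
#' Superposes every non-representative model onto the representative over
#' the selection and summarizes the per-model RMSDs as mean +/- SD -- the
#' standard "family spread" statistic of NMR ensembles.
#'
#' @param ens a `structure_ensemble`.
#' @param representative model index (default: chosen by
#'   [select_representative()]).
#' @param residues residue numbers of the selection (e.g. the structured
#'   core).
#' @param atom_names atoms of the selection (default backbone N, CA, C).
#' @return list: `mean`, `sd`, `per_model` (RMSD of each non-representative
#'   model), `representative`.
#' @export
ensemble_precision <- function(ens, representative = NULL, residues = NULL,
                               atom_names = c("N", "CA", "C")) {
  stopifnot(inherits(ens, "structure_ensemble"))
  idx <- resolve_selection(ens, residues, atom_names)
  if (!length(idx)) stop("selection matches no atoms")
  if (is.null(representative))
    representative <- select_representative(ens, residues, atom_names)$index
  others <- setdiff(seq_len(n_models(ens)), representative)
  r <- vapply(others, function(i) pair_rmsd(ens, i, representative, idx),
              numeric(1))
  list(mean = mean(r), sd = if (length(r) > 1) stats::sd(r) else 0,
       per_model = stats::setNames(r, others),
       representative = representative)
}

# Unit N->H bond vectors per residue from the first model of an ensemble.
nh_vectors <- function(ens, residues = NULL) {
  stopifnot(inherits(ens, "structure_ensemble"))
  a <- ens$atoms
  if (is.null(residues)) residues <- unique(a$resno)
  m <- ens$coords[[1]]
  rows <- lapply(residues, function(r) {
    iN <- which(a$resno == r & a$atom == "N")
    iH <- which(a$resno == r & a$atom %in% c("H", "HN"))
    if (length(iN) != 1 || length(iH) != 1) return(NULL)
    v <- m[iH, ] - m[iN, ]
    list(residue = r, v = v / sqrt(sum(v^2)))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(NULL)
  list(residue = vapply(rows, `[[`, 0, "residue"),
       vectors = do.call(rbind, lapply(rows, `[[`, "v")))
}
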