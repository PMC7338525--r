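#' Distance restraint between two (possibly ambiguous) atom groups
#'
#' @param group_a,group_b data.frames with columns `resno`, `atom`
#'   (pseudoatom names allowed; expanded at resolution time).
#' @param lower,upper distance bounds in Angstrom (0 <= lower <= upper).
#' @return object of class `distance_restraint`.
#' @export
distance_restraint <- function(group_a, group_b, lower, upper) {
  for (g in list(group_a, group_b))
    if (!nrow(g) || !all(c("resno", "atom") %in% names(g)))
      stop("restraint groups need non-empty resno/atom tables")
  if (lower < 0 || upper < lower)
    stop("bounds must satisfy 0 <= lower <= upper (got ", lower, ", ",
         upper, ")")
  if (nrow(merge(group_a, group_b)) > 0)
    stop("restraint groups must be disjoint")
  structure(list(group_a = group_a, group_b = group_b,
                 lower = lower, upper = upper),
            class = "distance_restraint")
}

#' Dihedral angle restraint
#'
#' @param atoms data.frame of four rows (`resno`, `atom`) defining the
#'   dihedral.
#' @param target target angle in degrees, reported in (-180, 180].
#' @param range allowed half-width around the target in degrees (> 0).
#' @param name optional label (e.g. "PHI"/"PSI").
#' @return object of class `dihedral_restraint`.
#' @export
dihedral_restraint <- function(atoms, target, range, name = NA_character_) {
  if (nrow(atoms) != 4) stop("a dihedral restraint needs exactly 4 atoms")
  if (range <= 0) stop("range must be > 0 degrees")
  target <- wrap_angle(target)
  structure(list(atoms = atoms, target = target, range = range, name = name),
            class = "dihedral_restraint")
}

# wrap an angle in degrees into (-180, 180]
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

# ---- CNS/XPLOR .tbl parsing ----------------------------------------------

# Split the text of one "assign" statement into its parenthesized
# selections plus trailing numbers. Handles nested parentheses.
split_selections <- function(txt) {
  sels <- character(0)
  depth <- 0; buf <- character(0); i <- 1
  chars <- strsplit(txt, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      depth <- depth + 1
      if (depth == 1) buf <- character(0) else buf <- c(buf, ch)
    } else if (ch == ")") {
      depth <- depth - 1
      if (depth == 0) sels <- c(sels, paste(buf, collapse = ""))
      else buf <- c(buf, ch)
    } else if (depth > 0) buf <- c(buf, ch)
    i <- i + 1
  }
  rest <- gsub("\\([^()]*(\\([^()]*\\)[^()]*)*\\)", " ", txt)
  nums <- suppressWarnings(as.numeric(
    regmatches(rest, gregexpr("-?[0-9]+\\.?[0-9]*", rest))[[1]]))
  list(selections = sels, numbers = nums[!is.na(nums)])
}

# Parse an XPLOR atom selection into a (resno, atom) table. Supports
# "resid N and name X" factors joined by OR (ambiguous groups); segid
# factors are ignored.
parse_selection <- function(sel) {
  parts <- strsplit(sel, "(?i)\\bor\\b", perl = TRUE)[[1]]
  rows <- lapply(parts, function(p) {
    resno <- regmatches(p, regexpr("(?i)resid(?:ue)?\\s+[0-9]+", p, perl = TRUE))
    name <- regmatches(p, regexpr("(?i)name\\s+[A-Za-z0-9#*+%]+", p, perl = TRUE))
    if (!length(resno) || !length(name)) return(NULL)
    data.frame(resno = as.integer(sub("(?i)resid(?:ue)?\\s+", "", resno,
                                      perl = TRUE)),
               atom = toupper(sub("(?i)name\\s+", "", name, perl = TRUE)),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(NULL)
  unique(do.call(rbind, rows))
}

# Group a .tbl file's lines into complete assign statements, tracking the
# starting line number of each.
collect_assigns <- function(lines) {
  # strip comments
  lines <- sub("!.*$", "", lines)
  starts <- grep("(?i)^\\s*assign\\b", lines, perl = TRUE)
  if (!length(starts)) return(list())
  ends <- c(starts[-1] - 1, length(lines))
  lapply(seq_along(starts), function(i) {
    txt <- paste(lines[starts[i]:ends[i]], collapse = " ")
    list(line = starts[i], text = sub("(?i)^\\s*assign\\b", "", txt,
                                      perl = TRUE))
  })
}

#' Parse distance restraints
#'
#' Reads NOE distance restraints from CNS/XPLOR `.tbl` files
#' (`assign (sel-a) (sel-b) d dminus dplus`, giving bounds
#' `[d - dminus, d + dplus]`) or from NMR-STAR distance-constraint loops.
#' Ambiguous selections (OR-combined atom terms) are retained as groups.
#'
#' @param path restraint file.
#' @param dialect "tbl", "nmrstar", or "auto" (sniffed from content).
#' @return list of `distance_restraint` objects.
#' @export
parse_distance_restraints <- function(path,
                                      dialect = c("auto", "tbl", "nmrstar")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "auto") {
    dialect <- if (any(grepl("^\\s*loop_", lines))) "nmrstar" else "tbl"
  }
  if (dialect == "nmrstar") return(parse_star_distance(lines))

  out <- list()
  for (a in collect_assigns(lines)) {
    sp <- split_selections(a$text)
    if (length(sp$selections) < 2 || length(sp$numbers) < 3)
      stop("unparseable distance restraint at line ", a$line)
    ga <- parse_selection(sp$selections[1])
    gb <- parse_selection(sp$selections[2])
    if (is.null(ga) || is.null(gb))
      stop("unparseable atom selection at line ", a$line)
    d <- sp$numbers[1]; dm <- sp$numbers[2]; dp <- sp$numbers[3]
    out[[length(out) + 1]] <-
      distance_restraint(ga, gb, max(0, d - dm), d + dp)
  }
  out
}

# Minimal NMR-STAR loop extraction: returns a data.frame of the first loop
# whose tags match all of `want` (by suffix after the category dot).
star_loop <- function(lines, want) {
  li <- grep("^\\s*loop_\\s*$", lines)
  for (s in li) {
    i <- s + 1
    tags <- character(0)
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, sub("^[^.]*\\.", "", trimws(lines[i])))
      i <- i + 1
    }
    if (!all(want %in% tags)) next
    rows <- list()
    while (i <= length(lines) && !grepl("^\\s*(stop_|loop_)", lines[i])) {
      ln <- trimws(lines[i])
      if (nzchar(ln) && !startsWith(ln, "#")) {
        f <- strsplit(ln, "\\s+")[[1]]
        if (length(f) == length(tags)) rows[[length(rows) + 1]] <- f
      }
      i <- i + 1
    }
    if (!length(rows)) next
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- tags
    return(df)
  }
  NULL
}

parse_star_distance <- function(lines) {
  want <- c("ID", "Comp_index_ID_1", "Atom_ID_1", "Comp_index_ID_2",
            "Atom_ID_2", "Distance_upper_bound_val")
  df <- star_loop(lines, want)
  if (is.null(df))
    stop("no NMR-STAR distance-constraint loop with the expected tags found")
  lowtag <- intersect("Distance_lower_bound_val", names(df))
  out <- list()
  for (id in unique(df$ID)) {
    d <- df[df$ID == id, , drop = FALSE]
    ga <- unique(data.frame(resno = as.integer(d$Comp_index_ID_1),
                            atom = toupper(d$Atom_ID_1)))
    gb <- unique(data.frame(resno = as.integer(d$Comp_index_ID_2),
                            atom = toupper(d$Atom_ID_2)))
    up <- suppressWarnings(as.numeric(d$Distance_upper_bound_val[1]))
    lo <- if (length(lowtag)) {
      v <- suppressWarnings(as.numeric(d[[lowtag]][1]))
      if (is.na(v)) 0 else v
    } else 0
    if (is.na(up)) stop("missing upper bound in constraint ID ", id)
    out[[length(out) + 1]] <- distance_restraint(ga, gb, lo, up)
  }
  out
}

#' Parse dihedral angle restraints from a CNS/XPLOR .tbl file
#'
#' `assign (sel1) (sel2) (sel3) (sel4) force target range [exponent]`;
#' the restraint allows target +/- range degrees.
#'
#' @param path restraint file.
#' @return list of `dihedral_restraint` objects.
#' @export
parse_dihedral_restraints <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (a in collect_assigns(lines)) {
    sp <- split_selections(a$text)
    if (length(sp$selections) < 4 || length(sp$numbers) < 3)
      stop("unparseable dihedral restraint at line ", a$line)
    atoms <- do.call(rbind, lapply(sp$selections[1:4], parse_selection))
    if (is.null(atoms) || nrow(atoms) != 4)
      stop("dihedral selection does not resolve to 4 atoms at line ", a$line)
    out[[length(out) + 1]] <-
      dihedral_restraint(atoms, target = sp$numbers[2], range = sp$numbers[3])
  }
  out
}

# ---- classification -------------------------------------------------------

#' Classify distance restraints by sequence separation
#'
#' Standard NOE bookkeeping: intraresidue (|i-j| = 0), sequential
#' (|i-j| = 1), medium range (1 < |i-j| <= 4) and long range (|i-j| > 4).
#' Ambiguous restraints use the minimum |i-j| over all member pairs.
#'
#' @param restraints list of `distance_restraint` objects.
#' @return list: `counts` (named integer vector: intraresidue, sequential,
#'   medium, long, total), `class` (per-restraint class),
#'   `per_residue` (NOE count touching each residue).
#' @export
classify_distance_restraints <- function(restraints) {
  cls <- vapply(restraints, function(r) {
    sep <- min(abs(outer(r$group_a$resno, r$group_b$resno, "-")))
    if (sep == 0) "intraresidue" else if (sep == 1) "sequential"
    else if (sep <= 4) "medium" else "long"
  }, character(1))
  counts <- c(intraresidue = sum(cls == "intraresidue"),
              sequential = sum(cls == "sequential"),
              medium = sum(cls == "medium"),
              long = sum(cls == "long"),
              total = length(cls))
  res <- sort(unique(unlist(lapply(restraints, function(r)
    c(r$group_a$resno, r$group_b$resno)))))
  per <- vapply(res, function(rr) sum(vapply(restraints, function(r)
    rr %in% c(r$group_a$resno, r$group_b$resno), logical(1))), integer(1))
  list(counts = counts, class = cls,
       per_residue = data.frame(residue = res, n_noe = per))
}

# ---- resolution against coordinates ---------------------------------------

# IUPAC/CNS pseudoatom conventions: trailing '#', '*', '%' or '+' match by
# prefix; 'Q' pseudoatoms expand to the corresponding 'H' prefix (QB ->
# HB*, QG1 -> HG1*, ...); 'M' methyl pseudoatoms likewise.
expand_atom_name <- function(name, available) {
  name <- toupper(name)
  if (name %in% available) return(name)
  if (grepl("[#*%+]$", name)) {
    pre <- sub("[#*%+]$", "", name)
    hits <- available[startsWith(available, pre)]
    return(hits)
  }
  if (grepl("^[QM]", name)) {
    pre <- sub("^[QM]", "H", name)
    hits <- available[startsWith(available, pre)]
    return(hits)
  }
  character(0)
}

# Atom row indices for one restraint group within one residue set;
# errors naming any atom that cannot be found.
resolve_group <- function(ens, group) {
  idx <- integer(0)
  for (k in seq_len(nrow(group))) {
    res <- group$resno[k]
    avail <- ens$atoms$atom[ens$atoms$resno == res]
    names_k <- expand_atom_name(group$atom[k], avail)
    if (!length(names_k))
      stop("atom not found: residue ", res, " name ", group$atom[k])
    idx <- c(idx, which(ens$atoms$resno == res &
                          ens$atoms$atom %in% names_k))
  }
  unique(idx)
}

#' r^-6-averaged effective distance of a restraint in one model
#'
#' The ambiguous-restraint convention: over all cross pairs (a in group A,
#' b in group B), d_eff = (sum r_ab^-6)^(-1/6). For single-atom groups this
#' is the plain distance; it never exceeds the minimum pairwise distance.
#'
#' @param ens a `structure_ensemble`.
#' @param model model index.
#' @param restraint a `distance_restraint`.
#' @return effective distance in Angstrom.
#' @export
effective_distance_r6 <- function(ens, model, restraint) {
  ia <- resolve_group(ens, restraint$group_a)
  ib <- resolve_group(ens, restraint$group_b)
  m <- ens$coords[[model]]
  s <- 0
  for (a in ia) for (b in ib) {
    r2 <- sum((m[a, ] - m[b, ])^2)
    s <- s + r2^(-3)
  }
  s^(-1 / 6)
}

# signed dihedral angle (degrees) defined by four points
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Restraint violation analysis over an ensemble
#'
#' For each model, the violation of a distance restraint is
#' max(0, d_eff - upper, lower - d_eff) with d_eff the r^-6-averaged
#' effective distance; a dihedral violation is the excess of the wrapped
#' angular deviation |wrap(theta - target)| over the allowed range.
#' Restraints that fail to resolve against the coordinates (missing atoms)
#' are counted and listed, not fatal.
#'
#' @param ens a `structure_ensemble`.
#' @param distance_restraints list of `distance_restraint` objects.
#' @param dihedral_restraints list of `dihedral_restraint` objects.
#' @return list of class `violation_report`: `distance` (matrix restraint x
#'   model), `dihedral` (matrix), `max_distance`, `max_dihedral`,
#'   `mean_distance`, `mean_dihedral`,
#'   `n_distance_above` / `n_dihedral_above` (counts above 0.5 A / 5 deg),
#'   `unresolved` (messages).
#' @export
violation_report <- function(ens, distance_restraints = list(),
                             dihedral_restraints = list()) {
  stopifnot(inherits(ens, "structure_ensemble"))
  nm <- n_models(ens)
  unresolved <- character(0)

  dmat <- NULL
  if (length(distance_restraints)) {
    dmat <- matrix(NA_real_, length(distance_restraints), nm)
    for (i in seq_along(distance_restraints)) {
      r <- distance_restraints[[i]]
      row <- tryCatch(
        vapply(seq_len(nm), function(mi) {
          d <- effective_distance_r6(ens, mi, r)
          max(0, d - r$upper, r$lower - d)
        }, numeric(1)),
        error = function(e) {
          unresolved <<- c(unresolved, paste0("distance #", i, ": ",
                                              conditionMessage(e)))
          rep(NA_real_, nm)
        })
      dmat[i, ] <- row
    }
  }

  amat <- NULL
  if (length(dihedral_restraints)) {
    amat <- matrix(NA_real_, length(dihedral_restraints), nm)
    for (i in seq_along(dihedral_restraints)) {
      r <- dihedral_restraints[[i]]
      row <- tryCatch({
        idx <- vapply(seq_len(4), function(k) {
          j <- which(ens$atoms$resno == r$atoms$resno[k] &
                       ens$atoms$atom == toupper(r$atoms$atom[k]))
          if (length(j) != 1)
            stop("atom not found: residue ", r$atoms$resno[k], " name ",
                 r$atoms$atom[k])
          j
        }, integer(1))
        vapply(seq_len(nm), function(mi) {
          m <- ens$coords[[mi]]
          th <- dihedral_angle(m[idx[1], ], m[idx[2], ], m[idx[3], ],
                               m[idx[4], ])
          max(0, abs(wrap_angle(th - r$target)) - r$range)
        }, numeric(1))
      }, error = function(e) {
        unresolved <<- c(unresolved, paste0("dihedral #", i, ": ",
                                            conditionMessage(e)))
        rep(NA_real_, nm)
      })
      amat[i, ] <- row
    }
  }

  mx <- function(m) if (is.null(m) || all(is.na(m))) 0 else max(m, na.rm = TRUE)
  mn <- function(m) if (is.null(m) || all(is.na(m))) 0 else mean(m, na.rm = TRUE)
  structure(list(
    distance = dmat, dihedral = amat,
    max_distance = mx(dmat), max_dihedral = mx(amat),
    mean_distance = mn(dmat), mean_dihedral = mn(amat),
    n_distance_above = if (is.null(dmat)) 0L else
      sum(dmat > 0.5, na.rm = TRUE),
    n_dihedral_above = if (is.null(amat)) 0L else
      sum(amat > 5, na.rm = TRUE),
    unresolved = unresolved), class = "violation_report")
}
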