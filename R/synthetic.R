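#' Simulation scenario specification
#'
#' Ground-truth description of a simulated relaxation study, defaulting to
#' the conditions of the system the package models: a ~178-residue protein
#' tumbling isotropically with tau_m = 13.6 ns, measured at 700 MHz proton
#' frequency (16.3 T), 2% relative rate noise, and 20-model ensembles with
#' 0.35 A coordinate jitter. Residue ground truth defaults to a mixed
#' profile: rigid core residues (S2 ~ 0.85), flexible tails (low S2, long
#' tau_e) and a band of residues with chemical exchange in the 2-10 s^-1
#' range.
#'
#' @param seed integer RNG seed, recorded in all outputs.
#' @param n_residues number of residues.
#' @param params optional data.frame with columns `residue`, `model`,
#'   `S2`, `tau_e`, `R_ex`, `Sf2` (ground-truth per residue); default
#'   profile built deterministically from `seed`.
#' @param diffusion a `diffusion_model` (default isotropic, 13.6 ns).
#' @param field a `field_params` (default 700 MHz).
#' @param const an `nmr_constants`.
#' @param intensity_sigma decay-intensity noise (arbitrary units; I0 = 100).
#' @param rate_rel_sigma relative noise on generated rates.
#' @param shift_sigma titration shift noise (ppm).
#' @param coord_jitter ensemble coordinate jitter (Angstrom, per axis).
#' @param n_models ensemble size.
#' @param titration_label "specific", "non-specific" or "none".
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 1L, n_residues = 178L, params = NULL,
                          diffusion = diffusion_model("isotropic",
                                                      tau_m = 13.6),
                          field = field_params(proton_mhz = 700),
                          const = physical_constants(),
                          intensity_sigma = 2, rate_rel_sigma = 0.02,
                          shift_sigma = 0.005, coord_jitter = 0.35,
                          n_models = 20L,
                          titration_label = c("none", "specific",
                                              "non-specific")) {
  titration_label <- match.arg(titration_label)
  if (any(c(intensity_sigma, rate_rel_sigma, shift_sigma,
            coord_jitter) < 0))
    stop("noise levels must be >= 0")
  if (is.null(params)) params <- default_truth_profile(n_residues)
  need <- c("residue", "model", "S2", "tau_e", "R_ex", "Sf2")
  if (!all(need %in% names(params)))
    stop("params needs columns: ", paste(need, collapse = ", "))
  structure(list(seed = as.integer(seed), n_residues = nrow(params),
                 params = params, diffusion = diffusion, field = field,
                 const = const, intensity_sigma = intensity_sigma,
                 rate_rel_sigma = rate_rel_sigma, shift_sigma = shift_sigma,
                 coord_jitter = coord_jitter, n_models = as.integer(n_models),
                 titration_label = titration_label),
            class = "scenario_spec")
}

# Deterministic mixed ground-truth profile: disordered tails, rigid core,
# two mobile loops, and a core-wide band of 2-10 s^-1 exchange.
default_truth_profile <- function(n) {
  residue <- seq_len(n)
  S2 <- rep(0.85, n)
  tau_e <- rep(50, n)
  R_ex <- rep(0, n)
  model <- rep("M2", n)
  tail1 <- residue <= max(3, round(0.1 * n))
  tail2 <- residue > n - max(2, round(0.04 * n))
  S2[tail1 | tail2] <- 0.25
  tau_e[tail1 | tail2] <- 1000
  loop <- residue %in% (round(0.3 * n):round(0.35 * n))
  S2[loop] <- 0.6; tau_e[loop] <- 300
  core <- !(tail1 | tail2 | loop)
  exch <- core & (residue %% 3 == 0)
  R_ex[exch] <- 2 + 8 * (residue[exch] %% 7) / 7
  model[exch] <- "M4"
  data.frame(residue = residue, model = model, S2 = S2, tau_e = tau_e,
             R_ex = R_ex, Sf2 = 1)
}

# Ground-truth (R1, R2, NOE) for every residue of a scenario.
true_rates <- function(spec) {
  t(vapply(seq_len(spec$n_residues), function(i) {
    p <- spec$params[i, ]
    mf <- model_free_params(p$model, S2 = p$S2, tau_e = p$tau_e,
                            R_ex = p$R_ex, Sf2 = p$Sf2)
    forward_rates(mf, spec$diffusion, spec$field, spec$const)
  }, c(R1 = 0, R2 = 0, NOE = 0)))
}

#' Generate peak-intensity decay series
#'
#' Per residue: I(t) = 100 exp(-R t) + N(0, sigma) on the default R1 and
#' R2 delay schedules, with R from the scenario's forward-model rates, and
#' a saturated/reference intensity pair carrying the true NOE.
#'
#' @param spec a `scenario_spec`.
#' @return list: `r1`, `r2` (lists of `decay_series`), `noe` (data.frame
#'   residue, I_sat, I_ref, rms), `truth` (rate matrix), `seed`.
#' @export
gen_decays <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  rates <- true_rates(spec)
  set.seed(spec$seed)
  I0 <- 100
  sg <- max(spec$intensity_sigma, 1e-9)  # decay_series needs sigma > 0
  mk <- function(res, R, delays) {
    y <- I0 * exp(-R * delays) +
      stats::rnorm(length(delays), 0, spec$intensity_sigma)
    decay_series(res, delays, y, sg)
  }
  r1 <- lapply(seq_len(spec$n_residues), function(i)
    mk(spec$params$residue[i], rates[i, "R1"], r1_delay_schedule()))
  r2 <- lapply(seq_len(spec$n_residues), function(i)
    mk(spec$params$residue[i], rates[i, "R2"], r2_delay_schedule()))
  noe <- data.frame(residue = spec$params$residue,
                    I_sat = rates[, "NOE"] * I0 +
                      stats::rnorm(spec$n_residues, 0, spec$intensity_sigma),
                    I_ref = I0 +
                      stats::rnorm(spec$n_residues, 0, spec$intensity_sigma),
                    rms = spec$intensity_sigma)
  list(r1 = r1, r2 = r2, noe = noe, truth = rates, seed = spec$seed)
}

#' Generate a per-residue relaxation-rate table
#'
#' (R1, R2, NOE) from the forward model plus Gaussian noise at the
#' scenario's relative sigma; the error columns carry the generating
#' noise levels.
#'
#' @param spec a `scenario_spec`.
#' @param sigma_floor lower floor for the error columns so downstream
#'   chi-square weighting stays defined even for noiseless scenarios.
#' @return a `relaxation_records` table with attribute `truth`.
#' @export
gen_relaxation_dataset <- function(spec, sigma_floor = 1e-6) {
  stopifnot(inherits(spec, "scenario_spec"))
  rates <- true_rates(spec)
  set.seed(spec$seed)
  rel <- spec$rate_rel_sigma
  sR1 <- pmax(rel * rates[, "R1"], sigma_floor)
  sR2 <- pmax(rel * rates[, "R2"], sigma_floor)
  sNOE <- pmax(rel * abs(rates[, "NOE"]), sigma_floor)
  df <- data.frame(residue = spec$params$residue,
                   R1 = rates[, "R1"] + if (rel > 0)
                     stats::rnorm(nrow(rates), 0, sR1) else 0,
                   sR1 = sR1,
                   R2 = rates[, "R2"] + if (rel > 0)
                     stats::rnorm(nrow(rates), 0, sR2) else 0,
                   sR2 = sR2,
                   NOE = rates[, "NOE"] + if (rel > 0)
                     stats::rnorm(nrow(rates), 0, sNOE) else 0,
                   sNOE = sNOE)
  out <- relaxation_records(df, spec$field)
  attr(out, "truth") <- cbind(spec$params, rates)
  out
}

#' Generate a jittered ensemble with consistent restraints
#'
#' Models are i.i.d. Gaussian perturbations of a toy base fold. Distance
#' restraints are sampled from short inter-proton distances of the base
#' fold with the upper bound set above the maximum r^-6 effective distance
#' over all models (zero violations by construction); a configurable
#' number of restraints is deliberately violated by a known amount
#' (their upper bound is pulled `violation_size` below the ensemble
#' maximum). Backbone phi/psi dihedral restraints (+/- 30 deg around the
#' base-fold angles) are included for interior residues.
#'
#' @param spec a `scenario_spec`.
#' @param base_fold "helix" or "barrel".
#' @param n_res residues of the base fold.
#' @param max_restraints cap on sampled distance restraints.
#' @param n_violated number of deliberately violated restraints.
#' @param violation_size planted maximum violation (Angstrom).
#' @return list: `ensemble`, `distance_restraints`, `dihedral_restraints`,
#'   `bookkeeping` (data.frame restraint index, class, violated, planted
#'   size), `seed`.
#' @export
gen_ensemble <- function(spec, base_fold = c("helix", "barrel"),
                         n_res = 20, max_restraints = 150,
                         n_violated = 0, violation_size = 0.7) {
  stopifnot(inherits(spec, "scenario_spec"))
  base_fold <- match.arg(base_fold)
  if (spec$n_models < 2) stop("need n_models >= 2")
  base <- toy_fold(base_fold, n_res)
  na <- nrow(base$atoms)
  set.seed(spec$seed)
  coords <- lapply(seq_len(spec$n_models), function(i)
    base$coords[[1]] + matrix(stats::rnorm(na * 3, 0, spec$coord_jitter),
                              na, 3))
  ens <- structure_ensemble(base$atoms, coords)

  # candidate proton pairs within 5 A in the base fold
  prot <- which(base$atoms$atom %in% c("H", "HA"))
  m0 <- base$coords[[1]]
  cand <- list()
  for (ii in seq_along(prot)) {
    for (jj in seq_along(prot)) {
      if (jj <= ii) next
      a <- prot[ii]; b <- prot[jj]
      if (base$atoms$resno[a] == base$atoms$resno[b] &&
          base$atoms$atom[a] == base$atoms$atom[b]) next
      d <- sqrt(sum((m0[a, ] - m0[b, ])^2))
      if (d < 5) cand[[length(cand) + 1]] <- c(a, b)
    }
  }
  if (length(cand) > max_restraints)
    cand <- cand[sort(sample.int(length(cand), max_restraints))]

  restraints <- list(); book <- list()
  n_violated <- min(n_violated, length(cand))
  viol_idx <- if (n_violated > 0)
    sample.int(length(cand), n_violated) else integer(0)
  for (k in seq_along(cand)) {
    a <- cand[[k]][1]; b <- cand[[k]][2]
    ga <- data.frame(resno = base$atoms$resno[a], atom = base$atoms$atom[a])
    gb <- data.frame(resno = base$atoms$resno[b], atom = base$atoms$atom[b])
    r0 <- distance_restraint(ga, gb, 0, 999)
    dmax <- max(vapply(seq_len(spec$n_models), function(mi)
      effective_distance_r6(ens, mi, r0), numeric(1)))
    violated <- k %in% viol_idx
    upper <- if (violated) dmax - violation_size else dmax + 0.5
    if (upper <= 0) { violated <- FALSE; upper <- dmax + 0.5 }
    restraints[[k]] <- distance_restraint(ga, gb, 0, upper)
    sep <- abs(ga$resno - gb$resno)
    book[[k]] <- data.frame(
      index = k,
      class = if (sep == 0) "intraresidue" else if (sep == 1) "sequential"
      else if (sep <= 4) "medium" else "long",
      violated = violated,
      planted = if (violated) violation_size else 0)
  }

  # dihedral restraints on the base fold's interior phi/psi, with the
  # allowed range widened to cover the jittered ensemble (plus margin) so
  # they hold by construction
  pp <- phi_psi(base, 1)$angles
  dihed <- list()
  ens_range <- function(atoms, target) {
    r <- dihedral_restraint(atoms, target, range = 360)
    idx <- vapply(seq_len(4), function(k)
      which(ens$atoms$resno == atoms$resno[k] &
              ens$atoms$atom == atoms$atom[k])[1], integer(1))
    dev <- vapply(seq_len(spec$n_models), function(mi) {
      m <- ens$coords[[mi]]
      abs(wrap_angle(dihedral_angle(m[idx[1], ], m[idx[2], ], m[idx[3], ],
                                    m[idx[4], ]) - target))
    }, numeric(1))
    max(30, max(dev) + 5)
  }
  for (i in seq_len(nrow(pp))) {
    r <- pp$residue[i]
    if (!is.na(pp$phi[i])) {
      at <- data.frame(resno = c(r - 1, r, r, r),
                       atom = c("C", "N", "CA", "C"))
      dihed[[length(dihed) + 1]] <- dihedral_restraint(
        at, target = pp$phi[i], range = ens_range(at, pp$phi[i]),
        name = "PHI")
    }
    if (!is.na(pp$psi[i])) {
      at <- data.frame(resno = c(r, r, r, r + 1),
                       atom = c("N", "CA", "C", "N"))
      dihed[[length(dihed) + 1]] <- dihedral_restraint(
        at, target = pp$psi[i], range = ens_range(at, pp$psi[i]),
        name = "PSI")
    }
  }

  list(ensemble = ens, distance_restraints = restraints,
       dihedral_restraints = dihed,
       bookkeeping = if (length(book)) do.call(rbind, book) else NULL,
       seed = spec$seed)
}

#' Generate a titration series with a known scenario label
#'
#' The apo point is generated first and is identical across scenario
#' labels for a fixed seed. "specific": a contiguous planted residue set
#' follows a saturating (binding-isotherm-shaped) shift trajectory with
#' maximum 1H shift 0.1 ppm; "non-specific": uniform intensity decay to
#' 30% with no shifts beyond noise; "none": shift/intensity noise only.
#'
#' @param spec a `scenario_spec` (label from `spec$titration_label`).
#' @param ratios ligand:protein molar ratios (first must be 0).
#' @param n_planted size of the planted binding site (specific scenario).
#' @return list: `series` (a `titration_series`), `planted` (residue ids,
#'   empty unless specific), `label`, `seed`.
#' @export
gen_titration <- function(spec, ratios = c(0, 0.5, 1, 2), n_planted = 10) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- spec$n_residues
  res <- spec$params$residue
  set.seed(spec$seed)
  apo <- data.frame(residue = res,
                    dH_ppm = stats::rnorm(n, 8.3, 0.4),
                    dN_ppm = stats::rnorm(n, 118, 4),
                    intensity = stats::rnorm(n, 100, 5))
  label <- spec$titration_label
  planted <- if (label == "specific") {
    start <- max(1, round(n / 2) - floor(n_planted / 2))
    res[start:(start + n_planted - 1)]
  } else integer(0)
  sg <- spec$shift_sigma
  rmax <- max(ratios)
  peaks <- vector("list", length(ratios))
  peaks[[1]] <- apo
  for (k in seq_along(ratios)[-1]) {
    r <- ratios[k]
    p <- apo
    p$dH_ppm <- p$dH_ppm + stats::rnorm(n, 0, sg)
    p$dN_ppm <- p$dN_ppm + stats::rnorm(n, 0, sg / 0.14)
    p$intensity <- p$intensity * (1 + stats::rnorm(n, 0, 0.02))
    if (label == "specific") {
      sat <- r / (r + 0.5)
      sel <- p$residue %in% planted
      p$dH_ppm[sel] <- p$dH_ppm[sel] + 0.1 * sat
      p$dN_ppm[sel] <- p$dN_ppm[sel] + 0.5 * sat
    } else if (label == "non-specific") {
      p$intensity <- p$intensity * (1 - 0.7 * r / rmax)
    }
    peaks[[k]] <- p
  }
  list(series = titration_series(ratios, peaks), planted = planted,
       label = label, seed = spec$seed)
}

#' Write decay series / rate tables in the package TSV formats
#'
#' @param series_list list of `decay_series`.
#' @param path output TSV.
#' @export
write_decay_table <- function(series_list, path) {
  rows <- lapply(series_list, function(s)
    data.frame(residue = s$residue_id, delay_s = s$delays,
               intensity = s$intensities, sigma = s$sigma))
  df <- do.call(rbind, rows)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param records a `relaxation_records` table (or plain data.frame).
#' @rdname write_decay_table
#' @export
write_rates_table <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a relaxation-rate table written by [write_rates_table()]
#'
#' @param path TSV with columns residue, R1, sR1, R2, sR2, NOE, sNOE.
#' @param field a `field_params` the rates were measured at.
#' @return a `relaxation_records` table.
#' @export
read_rates_table <- function(path, field) {
  relaxation_records(utils::read.delim(path, sep = "\t"), field)
}
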