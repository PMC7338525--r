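#' Relaxation record table constructor
#'
#' Validates a per-residue table of measured (R1, R2, NOE) triples with
#' uncertainties, the carrier of experimental input to the model-free
#' analysis.
#'
#' @param df data.frame with columns `residue`, `R1`, `sR1`, `R2`, `sR2`,
#'   `NOE`, `sNOE`.
#' @param field a `field_params` object the rates were measured at.
#' @return the validated data.frame with the field attached as attribute
#'   `field`, class `relaxation_records`.
#' @export
relaxation_records <- function(df, field) {
  need <- c("residue", "R1", "sR1", "R2", "sR2", "NOE", "sNOE")
  if (!all(need %in% names(df)))
    stop("relaxation table needs columns: ", paste(need, collapse = ", "))
  if (any(df$R1 <= 0) || any(df$R2 <= 0))
    stop("relaxation rates must be positive")
  if (any(df[, c("sR1", "sR2", "sNOE")] < 0))
    stop("rate errors must be non-negative")
  stopifnot(inherits(field, "field_params"))
  df <- df[order(df$residue), need, drop = FALSE]
  attr(df, "field") <- field
  class(df) <- c("relaxation_records", "data.frame")
  df
}

# R2/R1 ratio predicted for a rigid residue (S2 = 1, Rex = 0) tumbling
# isotropically with correlation time tau_m (ns); strictly increasing in
# tau_m for tau_m beyond the extreme-narrowing minimum.
rigid_r2r1 <- function(tau_m, field, const = physical_constants()) {
  p <- model_free_params("M1", S2 = 1)
  vapply(tau_m, function(tm) {
    r <- forward_rates(p, diffusion_model("isotropic", tau_m = tm),
                       field, const)
    unname(r["R2"] / r["R1"])
  }, numeric(1))
}

# Solve the rigid-tumbler R2/R1 ratio for tau_m by 1-D root finding.
solve_tau_m <- function(ratio, field, const = physical_constants(),
                        bracket = c(1, 50)) {
  f <- function(tm) rigid_r2r1(tm, field, const) - ratio
  lo <- f(bracket[1]); hi <- f(bracket[2])
  if (lo > 0 || hi < 0) return(NA_real_)  # ratio outside the bracket
  stats::uniroot(f, bracket, tol = 1e-6)$root
}

#' Overall rotational correlation time from R2/R1 ratios
#'
#' Per residue, the R2/R1 ratio of a rigid isotropic tumbler is solved for
#' tau_m by 1-D root finding (bracket 1-50 ns). Residues dominated by fast
#' internal motion or exchange are excluded first by the standard
#' rigid-subset filter: NOE below `noe_min` (default 0.65), then a single
#' pass dropping residues whose R2/R1 deviates more than 1 SD from the
#' subset mean. The trimmed per-residue tau_m values are summarized as
#' mean +/- SD.
#'
#' @param records a `relaxation_records` table.
#' @param const an `nmr_constants` object.
#' @param noe_min NOE threshold for the flexible-residue filter.
#' @param max_trim_frac maximum fraction of residues the R2/R1-deviation
#'   pass may remove (default 0.2); if exceeded, only the most deviant
#'   residues up to the cap are dropped.
#' @return list: `tau_m` (ns), `sd`, `n_used`, `used` (residue ids),
#'   `per_residue` (data.frame residue, ratio, tau_m).
#' @export
estimate_tau_m_r2r1 <- function(records, const = physical_constants(),
                                noe_min = 0.65, max_trim_frac = 0.2) {
  stopifnot(inherits(records, "relaxation_records"))
  field <- attr(records, "field")
  keep <- records$NOE >= noe_min
  df <- records[keep, , drop = FALSE]
  if (nrow(df) < 5)
    stop("fewer than 5 residues pass the NOE >= ", noe_min, " filter")
  ratio <- df$R2 / df$R1
  dev <- abs(ratio - mean(ratio))
  out <- dev > stats::sd(ratio)        # one-pass 1-SD trim
  max_out <- floor(max_trim_frac * length(ratio))
  if (sum(out) > max_out) {
    out <- rank(-dev, ties.method = "first") <= max_out
  }
  df <- df[!out, , drop = FALSE]
  ratio <- ratio[!out]
  if (nrow(df) < 5) stop("fewer than 5 residues survive R2/R1 trimming")
  tm <- vapply(ratio, solve_tau_m, numeric(1), field = field, const = const)
  ok <- is.finite(tm)
  if (!any(ok)) stop("no residue's R2/R1 ratio is solvable for tau_m in 1-50 ns")
  list(tau_m = mean(tm[ok]), sd = stats::sd(tm[ok]), n_used = sum(ok),
       used = df$residue[ok],
       per_residue = data.frame(residue = df$residue[ok], ratio = ratio[ok],
                                tau_m = tm[ok]))
}

# chi^2 of predicted vs observed R2/R1 ratios for a diffusion model over
# the rigid subset; sigma of the ratio by error propagation.
ratio_chi2 <- function(pred, obs, sig) sum(((obs - pred) / sig)^2)

#' Fit and compare rotational diffusion models
#'
#' Fits the isotropic model (one parameter: tau_m) and, when N-H bond
#' vectors are available from a structure, the axially symmetric model
#' (tau_m, D_ratio, axis polar angles) to the rigid-subset R2/R1 ratios,
#' and selects between them by AIC with a parsimony margin: the axial
#' model must improve AIC by at least `delta_aic` (default 2) to replace
#' the isotropic one.
#'
#' @param records a `relaxation_records` table.
#' @param structure optional `structure_ensemble` supplying N-H vectors
#'   (its first model is used); without it the fit is isotropic and a
#'   warning is issued if an anisotropic fit was requested.
#' @param const an `nmr_constants` object.
#' @param kind "auto" (compare), "isotropic" or "axial".
#' @param noe_min rigid-subset NOE threshold.
#' @param delta_aic parsimony margin on the AIC comparison.
#' @return list: `model` (a `diffusion_model`), `isotropic`, `axial`
#'   (each with chi2, aic, parameters; axial NULL if not fitted),
#'   `n_residues`.
#' @export
fit_diffusion_models <- function(records, structure = NULL,
                                 const = physical_constants(),
                                 kind = c("auto", "isotropic", "axial"),
                                 noe_min = 0.65, delta_aic = 2) {
  kind <- match.arg(kind)
  stopifnot(inherits(records, "relaxation_records"))
  field <- attr(records, "field")
  est <- estimate_tau_m_r2r1(records, const, noe_min = noe_min)
  sub <- records[records$residue %in% est$used, , drop = FALSE]
  obs <- sub$R2 / sub$R1
  sig <- obs * sqrt((sub$sR1 / sub$R1)^2 + (sub$sR2 / sub$R2)^2)
  sig[sig <= 0] <- pmax(1e-3, 0.01 * obs[sig <= 0])
  n <- length(obs)

  # isotropic: 1-D refinement of tau_m around the ratio estimate
  iso_obj <- function(tm) ratio_chi2(rigid_r2r1(tm, field, const), obs, sig)
  iso_fit <- stats::optimize(iso_obj, c(max(1, est$tau_m - 5), est$tau_m + 5))
  iso <- list(tau_m = iso_fit$minimum, chi2 = iso_fit$objective,
              aic = iso_fit$objective + 2 * 1)

  axial <- NULL
  want_axial <- kind %in% c("auto", "axial")
  vec <- if (!is.null(structure)) nh_vectors(structure, sub$residue) else NULL
  if (want_axial && is.null(vec)) {
    if (kind == "axial")
      warning("axial diffusion fit needs a structure for N-H vectors; ",
              "falling back to isotropic")
    want_axial <- FALSE
  }
  if (want_axial) {
    idx <- match(sub$residue, vec$residue)
    ok <- !is.na(idx)
    v <- vec$vectors[idx[ok], , drop = FALSE]
    obs_a <- obs[ok]; sig_a <- sig[ok]
    rigid <- model_free_params("M1", S2 = 1)
    ax_obj <- function(par) {
      tm <- par[1]; dr <- exp(par[2])
      axis <- c(sin(par[3]) * cos(par[4]), sin(par[3]) * sin(par[4]),
                cos(par[3]))
      dm <- diffusion_model("axial", tau_m = tm, D_ratio = dr)
      theta <- acos(pmin(1, pmax(-1, v %*% axis))) * 180 / pi
      pred <- vapply(theta, function(th) {
        r <- forward_rates(rigid, dm, field, const, theta_deg = th)
        unname(r["R2"] / r["R1"])
      }, numeric(1))
      ratio_chi2(pred, obs_a, sig_a)
    }
    # multi-start over axis orientation; D_ratio from ~0.7 to ~2
    starts <- expand.grid(tm = iso$tau_m, ldr = log(c(0.8, 1.2, 1.6)),
                          th = c(0.5, 1.2), ph = c(0.5, 2.5))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      f <- tryCatch(stats::optim(as.numeric(starts[i, ]), ax_obj,
                                 method = "Nelder-Mead",
                                 control = list(maxit = 600)),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
    }
    if (!is.null(best)) {
      axial <- list(tau_m = best$par[1], D_ratio = exp(best$par[2]),
                    orientation = c(best$par[3], best$par[4]) * 180 / pi,
                    chi2 = best$value, aic = best$value + 2 * 4)
    }
  }

  choose_axial <- !is.null(axial) &&
    (kind == "axial" || (kind == "auto" && axial$aic < iso$aic - delta_aic))
  model <- if (choose_axial) {
    diffusion_model("axial", tau_m = axial$tau_m, D_ratio = axial$D_ratio,
                    orientation = axial$orientation)
  } else {
    diffusion_model("isotropic", tau_m = iso$tau_m)
  }
  list(model = model, isotropic = iso, axial = axial, n_residues = n)
}

# ---- per-residue model-free fitting --------------------------------------

mf_free_params <- list(M1 = "S2", M2 = c("S2", "tau_e"), M3 = c("S2", "R_ex"),
                       M4 = c("S2", "tau_e", "R_ex"),
                       M5 = c("Sf2", "S2", "tau_e"))

mf_build <- function(model, par) {
  par <- as.numeric(par)
  switch(model,
         M1 = model_free_params("M1", S2 = par[1]),
         M2 = model_free_params("M2", S2 = par[1], tau_e = par[2]),
         M3 = model_free_params("M3", S2 = par[1], R_ex = par[2]),
         M4 = model_free_params("M4", S2 = par[1], tau_e = par[2],
                                R_ex = par[3]),
         M5 = model_free_params("M5", Sf2 = par[1], S2 = min(par[1], par[2]),
                                tau_e = par[3]))
}

mf_bounds <- function(model) {
  switch(model,
         M1 = list(lower = 0, upper = 1),
         M2 = list(lower = c(0, 0), upper = c(1, 1e4)),
         M3 = list(lower = c(0, 0), upper = c(1, 50)),
         M4 = list(lower = c(0, 0, 0), upper = c(1, 1e4, 50)),
         M5 = list(lower = c(0, 0, 0), upper = c(1, 1, 1e4)))
}

mf_starts <- function(model) {
  S2g <- c(0.2, 0.5, 0.8, 0.95)
  teg <- c(10, 100, 1000)
  rxg <- c(0, 3, 8)
  switch(model,
         M1 = matrix(S2g, ncol = 1),
         M2 = as.matrix(expand.grid(S2g, teg)),
         M3 = as.matrix(expand.grid(S2g, rxg)),
         M4 = as.matrix(expand.grid(S2g, teg, rxg)),
         M5 = as.matrix(expand.grid(c(0.7, 0.9), S2g, teg)))
}

mf_chi2 <- function(par, model, rec, d, field, const, theta_deg) {
  p <- tryCatch(mf_build(model, par), error = function(e) NULL)
  if (is.null(p)) return(1e12)
  r <- forward_rates(p, d, field, const, theta_deg)
  if (!all(is.finite(r))) return(1e12)  # degenerate J (e.g. S2 = 0, tau_e = 0)
  sum(((c(rec$R1, rec$R2, rec$NOE) - r) /
         c(rec$sR1, rec$sR2, rec$sNOE))^2)
}

fit_one_model <- function(model, rec, d, field, const, theta_deg,
                          starts = NULL) {
  b <- mf_bounds(model)
  if (is.null(starts)) starts <- mf_starts(model)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      stats::optim(pmin(pmax(starts[i, ], b$lower + 1e-6), b$upper - 1e-6),
                   mf_chi2, model = model, rec = rec, d = d, field = field,
                   const = const, theta_deg = theta_deg,
                   method = "L-BFGS-B", lower = b$lower, upper = b$upper,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) return(NULL)
  if (nrow(starts) > 1) {
    # polish the winning grid start to tight tolerance
    pol <- tryCatch(
      stats::optim(best$par, mf_chi2, model = model, rec = rec, d = d,
                   field = field, const = const, theta_deg = theta_deg,
                   method = "L-BFGS-B", lower = b$lower, upper = b$upper,
                   control = list(maxit = 500, factr = 10)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= best$value) best <- pol
  }
  k <- length(mf_free_params[[model]])
  list(model = model, par = best$par, chi2 = best$value,
       aic = best$value + 2 * k, k = k,
       params = mf_build(model, best$par),
       converged = best$convergence == 0)
}

#' Fit Lipari-Szabo models to one residue's relaxation triple
#'
#' Fits candidate motional models M1 \{S2\}, M2 \{S2, tau_e\},
#' M3 \{S2, R_ex\}, M4 \{S2, tau_e, R_ex\} and M5 \{Sf2, S2, tau_e\} by
#' weighted chi-square minimization (bounded L-BFGS-B from a deterministic
#' multi-start grid), selects a model by AIC = chi2 + 2k with a parsimony
#' rule (any model within `delta_aic` of the minimum loses to the simpler
#' one), and estimates parameter uncertainties by Monte-Carlo resampling
#' of the relaxation triple within its stated errors.
#'
#' With a single field there are only three observables per residue, so
#' three-parameter models can always interpolate the data; the parsimony
#' margin and bounded parameter ranges are what keep the selection
#' conservative. R_ex from one field is weakly identified and its absolute
#' value should be read with that caveat.
#'
#' @param rec one-row `relaxation_records` slice (or list with R1, sR1,
#'   R2, sR2, NOE, sNOE, residue).
#' @param d the global `diffusion_model`.
#' @param field a `field_params` object (taken from `rec` if attached).
#' @param const an `nmr_constants` object.
#' @param models candidate model names (default all five).
#' @param mc_reps Monte-Carlo error replicates (0 disables).
#' @param seed RNG seed for the Monte-Carlo errors.
#' @param delta_aic parsimony margin.
#' @param theta_deg N-H vector angle for axial diffusion.
#' @return list of class `residue_fit`: `residue`, `params`
#'   (`model_free_params`), `chi2`, `model_score` (AIC), `param_errors`
#'   (Monte-Carlo sigma per free parameter, with a 95% interval in
#'   attribute `ci95`), `all_models` (per-model chi2/AIC table),
#'   `converged`.
#' @export
fit_residue_modelfree <- function(rec, d, field = NULL,
                                  const = physical_constants(),
                                  models = names(mf_free_params),
                                  mc_reps = 100, seed = 1L,
                                  delta_aic = 2, theta_deg = NULL) {
  if (is.null(field)) field <- attr(rec, "field")
  stopifnot(inherits(field, "field_params"), inherits(d, "diffusion_model"))
  rec <- as.list(rec)
  if (any(c(rec$sR1, rec$sR2, rec$sNOE) <= 0))
    stop("fit requires positive measurement errors")

  fits <- Filter(Negate(is.null),
                 lapply(models, fit_one_model, rec = rec, d = d,
                        field = field, const = const, theta_deg = theta_deg))
  if (!length(fits))
    return(structure(list(residue = rec$residue, params = NULL,
                          chi2 = NA_real_, model_score = NA_real_,
                          param_errors = NULL, all_models = NULL,
                          converged = FALSE), class = "residue_fit"))

  tab <- data.frame(model = vapply(fits, `[[`, "", "model"),
                    k = vapply(fits, `[[`, 0, "k"),
                    chi2 = vapply(fits, `[[`, 0, "chi2"),
                    aic = vapply(fits, `[[`, 0, "aic"))
  # parsimony: among models within delta_aic of the best AIC, take the one
  # with fewest free parameters (ties resolved by model order M1..M5)
  cand <- which(tab$aic <= min(tab$aic) + delta_aic)
  sel <- cand[order(tab$k[cand], cand)][1]
  best <- fits[[sel]]

  errs <- NULL
  if (mc_reps > 0) {
    pred <- forward_rates(best$params, d, field, const, theta_deg)
    old <- .Random.seed_exists()
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
    draws <- replicate(mc_reps, {
      r2 <- rec
      noisy <- pred + stats::rnorm(3, 0, c(rec$sR1, rec$sR2, rec$sNOE))
      r2$R1 <- noisy[1]; r2$R2 <- noisy[2]; r2$NOE <- noisy[3]
      # refit from the point estimate: the perturbed optimum stays in its
      # basin, so the full start grid is unnecessary here
      f <- fit_one_model(best$model, r2, d, field, const, theta_deg,
                         starts = matrix(best$par, nrow = 1))
      if (is.null(f)) rep(NA_real_, best$k) else f$par
    })
    draws <- matrix(draws, nrow = best$k)
    errs <- apply(draws, 1, stats::sd, na.rm = TRUE)
    names(errs) <- mf_free_params[[best$model]]
    # 95% interval: normal approximation around the point estimate with the
    # Monte-Carlo sigma (the resampled spread is well calibrated; its raw
    # quantiles are noisier than the sigma at moderate rep counts)
    ci <- rbind(best$par - 1.96 * errs, best$par + 1.96 * errs)
    rownames(ci) <- c("2.5%", "97.5%")
    colnames(ci) <- names(errs)
    attr(errs, "ci95") <- ci
  }

  structure(list(residue = rec$residue, params = best$params,
                 chi2 = best$chi2, model_score = best$aic,
                 param_errors = errs, all_models = tab,
                 converged = best$converged),
            class = "residue_fit")
}

#' Fit the full per-residue dynamics profile
#'
#' Runs [fit_residue_modelfree()] over every row of a relaxation table
#' under a fixed global diffusion model (the two-stage workflow: overall
#' tumbling first, internal motion second).
#'
#' @inheritParams fit_residue_modelfree
#' @param records a `relaxation_records` table.
#' @return list of `residue_fit` objects.
#' @export
fit_modelfree_profile <- function(records, d, const = physical_constants(),
                                  mc_reps = 100, seed = 1L, delta_aic = 2) {
  stopifnot(inherits(records, "relaxation_records"))
  field <- attr(records, "field")
  lapply(seq_len(nrow(records)), function(i)
    fit_residue_modelfree(records[i, , drop = FALSE], d, field, const,
                          mc_reps = mc_reps, seed = seed + i,
                          delta_aic = delta_aic))
}

#' Assemble the per-residue dynamics profile table
#'
#' Collects fitted results into a table of S2, (1 - S2), tau_e, R_ex and
#' errors, flagging the exchange regime of each residue: "no exchange"
#' (R_ex = 0), "typical" for R_ex inside the 2-10 s^-1 band that
#' characterizes widespread millisecond exchange in a conformationally
#' mobile core, and "strong" above it.
#'
#' @param results list of `residue_fit` objects.
#' @param rex_band numeric length-2, the typical-exchange band in s^-1.
#' @return data.frame: residue, model, S2, one_minus_S2, tau_e, R_ex, Sf2,
#'   sS2, sTau_e, sR_ex, chi2, aic, rex_flag, converged.
#' @export
assemble_dynamics_profile <- function(results, rex_band = c(2, 10)) {
  rows <- lapply(results, function(f) {
    if (is.null(f$params)) {
      return(data.frame(residue = f$residue, model = NA_character_,
                        S2 = NA_real_, one_minus_S2 = NA_real_,
                        tau_e = NA_real_, R_ex = NA_real_, Sf2 = NA_real_,
                        sS2 = NA_real_, sTau_e = NA_real_, sR_ex = NA_real_,
                        chi2 = NA_real_, aic = NA_real_,
                        rex_flag = "unfit", converged = FALSE))
    }
    p <- f$params
    e <- f$param_errors
    ge <- function(nm) if (!is.null(e) && nm %in% names(e)) unname(e[nm]) else 0
    flag <- if (p$R_ex == 0) "no exchange"
    else if (p$R_ex < rex_band[1]) "weak"
    else if (p$R_ex <= rex_band[2]) "typical"
    else "strong"
    data.frame(residue = f$residue, model = p$model, S2 = p$S2,
               one_minus_S2 = 1 - p$S2, tau_e = p$tau_e, R_ex = p$R_ex,
               Sf2 = p$Sf2, sS2 = ge("S2"), sTau_e = ge("tau_e"),
               sR_ex = ge("R_ex"), chi2 = f$chi2, aic = f$model_score,
               rex_flag = flag, converged = f$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
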