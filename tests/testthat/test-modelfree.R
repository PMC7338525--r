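rigid_spec <- function(seed, n, tau_m, rel = 0) {
  scenario_spec(seed = seed, n_residues = n,
                params = data.frame(residue = seq_len(n), model = "M1",
                                    S2 = 1, tau_e = 0, R_ex = 0, Sf2 = 1),
                diffusion = diffusion_model("isotropic", tau_m = tau_m),
                rate_rel_sigma = rel)
}

test_that("R2/R1 of a rigid tumbler increases strictly with tau_m", {
  f <- field_params(proton_mhz = 700)
  ratios <- nmrdyn:::rigid_r2r1(seq(2, 30, by = 1), f)
  expect_true(all(diff(ratios) > 0))
})

test_that("tau_m round-trips through the R2/R1 estimator", {
  for (tm in c(5, 13.6)) {
    rec <- gen_relaxation_dataset(rigid_spec(1, 30, tm))
    est <- estimate_tau_m_r2r1(rec)
    expect_equal(est$tau_m, tm, tolerance = 0.05 / tm)
    expect_lt(est$sd, 1e-3)
  }
})

test_that("the rigid-subset filter removes exchange outliers without moving the estimate", {
  n <- 21
  params <- data.frame(residue = seq_len(n), model = "M1", S2 = 1,
                       tau_e = 0, R_ex = 0, Sf2 = 1)
  params$model[n] <- "M3"
  params$R_ex[n] <- 10
  spec <- scenario_spec(seed = 4, n_residues = n, params = params,
                        rate_rel_sigma = 0.01)
  rec <- gen_relaxation_dataset(spec)
  est <- estimate_tau_m_r2r1(rec)
  expect_false(n %in% est$used)
  clean <- gen_relaxation_dataset(scenario_spec(
    seed = 4, n_residues = n, params = within(params, {
      R_ex <- 0; model <- "M1"}), rate_rel_sigma = 0.01))
  est_clean <- estimate_tau_m_r2r1(clean[-n, ] |> relaxation_records(
    attr(clean, "field")))
  expect_lt(abs(est$tau_m - est_clean$tau_m) / est_clean$tau_m, 0.02)
})

test_that("trimming never removes more than the configured fraction", {
  set.seed(21)
  for (i in 1:10) {
    n <- 30
    params <- data.frame(residue = seq_len(n), model = "M3",
                         S2 = runif(n, 0.8, 1), tau_e = 0,
                         R_ex = rexp(n, 1), Sf2 = 1)
    spec <- scenario_spec(seed = i, n_residues = n, params = params,
                          rate_rel_sigma = 0.03)
    rec <- gen_relaxation_dataset(spec)
    est <- tryCatch(estimate_tau_m_r2r1(rec), error = function(e) NULL)
    if (is.null(est)) next
    n_noe_pass <- sum(rec$NOE >= 0.65)
    expect_gte(est$n_used, ceiling(0.8 * n_noe_pass))
  }
})

test_that("isotropic synthetic data select the isotropic diffusion model", {
  rec <- gen_relaxation_dataset(rigid_spec(9, 30, 13.6, rel = 0))
  helix <- toy_fold("helix", 31)
  fit <- fit_diffusion_models(rec, structure = helix)
  expect_equal(fit$model$kind, "isotropic")
  expect_equal(fit$model$tau_m, 13.6, tolerance = 0.02)
  # axial fit, if forced on noiseless isotropic data, finds no anisotropy
  if (!is.null(fit$axial)) expect_lt(abs(fit$axial$D_ratio - 1), 0.1)
  # an anisotropic request without a structure falls back with a warning
  expect_warning(f2 <- fit_diffusion_models(rec, kind = "axial"),
                 "falling back")
  expect_equal(f2$model$kind, "isotropic")
})

test_that("axial anisotropy is detected and quantified from oriented vectors", {
  # synthetic axial data over a spread of N-H orientations
  f <- field_params(proton_mhz = 700)
  dm <- diffusion_model("axial", tau_m = 13.6, D_ratio = 1.5)
  rigid <- model_free_params("M1", S2 = 1)
  helix <- toy_fold("helix", 40)
  vec <- nmrdyn:::nh_vectors(helix)
  n <- length(vec$residue)
  rates <- t(vapply(seq_len(n), function(i) {
    # axis fixed at +z; theta from the actual helix N-H vectors
    th <- acos(pmin(1, pmax(-1, vec$vectors[i, 3]))) * 180 / pi
    forward_rates(rigid, dm, f, theta_deg = th)
  }, c(R1 = 0, R2 = 0, NOE = 0)))
  df <- data.frame(residue = vec$residue, R1 = rates[, 1],
                   sR1 = 0.01 * rates[, 1], R2 = rates[, 2],
                   sR2 = 0.01 * rates[, 2], NOE = rates[, 3], sNOE = 0.01)
  rec <- relaxation_records(df, f)
  fit <- fit_diffusion_models(rec, structure = helix)
  expect_equal(fit$model$kind, "axial")
  expect_equal(fit$model$D_ratio, 1.5, tolerance = 0.1 / 1.5)
})

test_that("noiseless rigid data select the one-parameter model with S2 = 1", {
  f <- field_params(proton_mhz = 700)
  d <- diffusion_model("isotropic", tau_m = 13.6)
  r <- forward_rates(model_free_params("M1", S2 = 1), d, f)
  rec <- list(residue = 1, R1 = r[["R1"]], sR1 = 0.02 * r[["R1"]],
              R2 = r[["R2"]], sR2 = 0.02 * r[["R2"]],
              NOE = r[["NOE"]], sNOE = 0.02)
  fit <- fit_residue_modelfree(rec, d, f, mc_reps = 0)
  expect_equal(fit$params$model, "M1")
  expect_equal(fit$params$S2, 1, tolerance = 1e-6)
  expect_equal(fit$params$R_ex, 0)
  expect_lt(fit$chi2, 1e-10)
})

test_that("noiseless fits reach chi2 at or below the generating truth", {
  f <- field_params(proton_mhz = 700)
  d <- diffusion_model("isotropic", tau_m = 13.6)
  set.seed(17)
  for (i in 1:10) {
    truth <- model_free_params("M4", S2 = runif(1, 0.5, 0.95),
                               tau_e = runif(1, 20, 500),
                               R_ex = runif(1, 0, 8))
    r <- forward_rates(truth, d, f)
    rec <- list(residue = i, R1 = r[["R1"]], sR1 = 0.02 * r[["R1"]],
                R2 = r[["R2"]], sR2 = 0.02 * r[["R2"]],
                NOE = r[["NOE"]], sNOE = 0.02)
    fit <- fit_residue_modelfree(rec, d, f, mc_reps = 0)
    # the best candidate model must reach the generating chi2 of zero
    # (the parsimony-selected model may trade a little chi2 for parameters)
    expect_lte(min(fit$all_models$chi2), 1e-6)
    expect_lte(fit$chi2, qchisq(0.001, df = 3, lower.tail = FALSE))
  }
})

test_that("noiseless round trips recover generating parameters in identifiable regimes", {
  f <- field_params(proton_mhz = 700)
  d <- diffusion_model("isotropic", tau_m = 13.6)
  set.seed(23)
  cases <- list(
    M1 = function() model_free_params("M1", S2 = runif(1, 0.3, 1)),
    M2 = function() model_free_params("M2", S2 = runif(1, 0.4, 0.95),
                                      tau_e = runif(1, 30, 800)),
    M3 = function() model_free_params("M3", S2 = runif(1, 0.4, 0.95),
                                      R_ex = runif(1, 1, 10)))
  for (mk in names(cases)) {
    for (i in 1:15) {
      truth <- cases[[mk]]()
      r <- forward_rates(truth, d, f)
      rec <- list(residue = i, R1 = r[["R1"]], sR1 = 0.02 * r[["R1"]],
                  R2 = r[["R2"]], sR2 = 0.02 * r[["R2"]],
                  NOE = r[["NOE"]], sNOE = 0.02)
      fit <- nmrdyn:::fit_one_model(mk, rec, d, f, physical_constants(),
                                    NULL)
      expect_equal(fit$params$S2, truth$S2, tolerance = 1e-4)
      if (mk == "M2")
        expect_equal(fit$params$tau_e, truth$tau_e, tolerance = 1e-2)
      if (mk == "M3")
        expect_equal(fit$params$R_ex, truth$R_ex, tolerance = 1e-3)
    }
  }
})

test_that("model selection obeys parsimony on noisy simple-model data", {
  f <- field_params(proton_mhz = 700)
  d <- diffusion_model("isotropic", tau_m = 13.6)
  truth <- model_free_params("M1", S2 = 0.88)
  r <- forward_rates(truth, d, f)
  set.seed(1234)
  overfit <- 0
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    rec <- list(residue = i,
                R1 = r[["R1"]] * (1 + rnorm(1, 0, 0.02)),
                sR1 = 0.02 * r[["R1"]],
                R2 = r[["R2"]] * (1 + rnorm(1, 0, 0.02)),
                sR2 = 0.02 * r[["R2"]],
                NOE = r[["NOE"]] + rnorm(1, 0, 0.02), sNOE = 0.02)
    fit <- fit_residue_modelfree(rec, d, f, mc_reps = 0)
    if (fit$params$model != "M1") overfit <- overfit + 1
  }
  expect_lt(overfit / n_rep, 0.10)
})

test_that("Monte-Carlo intervals cover generating parameters for exchange-bearing residues", {
  f <- field_params(proton_mhz = 700)
  d <- diffusion_model("isotropic", tau_m = 13.6)
  truth <- model_free_params("M3", S2 = 0.85, R_ex = 5)
  r <- forward_rates(truth, d, f)
  set.seed(77)
  hits <- 0
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    rec <- list(residue = i,
                R1 = r[["R1"]] * (1 + rnorm(1, 0, 0.02)),
                sR1 = 0.02 * r[["R1"]],
                R2 = r[["R2"]] * (1 + rnorm(1, 0, 0.02)),
                sR2 = 0.02 * r[["R2"]],
                NOE = r[["NOE"]] + rnorm(1, 0, 0.02), sNOE = 0.02)
    fit <- fit_residue_modelfree(rec, d, f, models = "M3", mc_reps = 200,
                                 seed = 1000 + i)
    q <- attr(fit$param_errors, "ci95")
    # each free parameter contributes one coverage trial
    hits <- hits + (truth$S2 >= q[1, 1] && truth$S2 <= q[2, 1]) +
      (truth$R_ex >= q[1, 2] && truth$R_ex <= q[2, 2])
  }
  expect_gte(hits / (2 * n_rep), 0.9)
})

test_that("the assembled dynamics profile mirrors its inputs and flags exchange bands", {
  spec <- scenario_spec(seed = 31, n_residues = 12)
  rec <- gen_relaxation_dataset(spec)
  d <- diffusion_model("isotropic", tau_m = 13.6)
  fits <- fit_modelfree_profile(rec, d, mc_reps = 0)
  prof <- assemble_dynamics_profile(fits)
  expect_equal(nrow(prof), nrow(rec))
  expect_equal(prof$one_minus_S2, 1 - prof$S2)
  # flags reproduce direct thresholding of the fitted R_ex values
  want <- ifelse(prof$R_ex == 0, "no exchange",
                 ifelse(prof$R_ex < 2, "weak",
                        ifelse(prof$R_ex <= 10, "typical", "strong")))
  expect_identical(prof$rex_flag, want)
  # all-M1 inputs are all flagged "no exchange"
  f <- field_params(proton_mhz = 700)
  r <- forward_rates(model_free_params("M1", S2 = 0.9), d, f)
  one <- fit_residue_modelfree(
    list(residue = 1, R1 = r[["R1"]], sR1 = 0.02, R2 = r[["R2"]],
         sR2 = 0.4, NOE = r[["NOE"]], sNOE = 0.02), d, f, mc_reps = 0)
  expect_identical(assemble_dynamics_profile(list(one))$rex_flag,
                   "no exchange")
})
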