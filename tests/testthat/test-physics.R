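test_that("field parameters preserve the gyromagnetic frequency ratio", {
  const <- physical_constants()
  f <- field_params(proton_mhz = 700)
  expect_equal(f$omega_H / f$omega_N, const$gamma_H / const$gamma_N,
               tolerance = 1e-6)
  expect_gt(f$B0, 0)
  expect_error(field_params(B0 = -1), "positive")
  expect_error(physical_constants(r_NH = 1.5), "r_NH")
  expect_error(physical_constants(delta_sigma = -100), "delta_sigma")
})

test_that("spectral density collapses to a single Lorentzian for S2 = 1", {
  p <- model_free_params("M1", S2 = 1)
  d <- diffusion_model("isotropic", tau_m = 10)
  expect_equal(spectral_density(p, d, 0) * 1e9, 4.0, tolerance = 1e-12)
  # Lorentzian limit: J -> 0 as omega -> infinity
  expect_lt(spectral_density(p, d, 1e13), 1e-15)
})

test_that("J(0) matches the closed form and J is non-increasing in |omega|", {
  set.seed(11)
  for (i in 1:20) {
    S2 <- runif(1, 0.2, 1)
    te <- runif(1, 5, 2000)
    tm <- runif(1, 2, 30)
    p <- model_free_params("M2", S2 = S2, tau_e = te)
    d <- diffusion_model("isotropic", tau_m = tm)
    tm_s <- tm * 1e-9; te_s <- te * 1e-12
    tau <- tm_s * te_s / (tm_s + te_s)
    closed <- 0.4 * (S2 * tm_s + (1 - S2) * tau)
    expect_equal(spectral_density(p, d, 1e-9) / closed, 1, tolerance = 1e-6)
    w <- 10^seq(6, 12, length.out = 30)
    J <- spectral_density(p, d, w)
    expect_true(all(J > 0))
    expect_true(all(diff(J) <= 1e-18))
  }
})

test_that("spectral density at the nitrogen frequency matches the frozen closed-form value", {
  p <- model_free_params("M2", S2 = 0.8, tau_e = 50)
  d <- diffusion_model("isotropic", tau_m = 13.6)
  f <- field_params(proton_mhz = 700)
  # high-precision evaluation of the closed form, frozen (ns/rad scale)
  expect_equal(spectral_density(p, d, f$omega_N) * 1e9,
               0.1191560566746485, tolerance = 1e-12)
})

test_that("motional parameter validation rejects unphysical values", {
  expect_error(model_free_params("M2", S2 = 1.2), "S2")
  expect_error(model_free_params("M2", S2 = 0.8, tau_e = -5), "tau_e")
  expect_error(model_free_params("M3", S2 = 0.8, R_ex = -1), "R_ex")
  expect_error(model_free_params("M5", S2 = 0.9, Sf2 = 0.8, tau_e = 50),
               "S2 <= Sf2")
  # unused parameters are pinned to null values
  p <- model_free_params("M1", S2 = 0.9, tau_e = 100, R_ex = 5)
  expect_identical(c(p$tau_e, p$R_ex, p$Sf2), c(0, 0, 1))
})

test_that("forward model matches the independent oracle to 1e-10 relative", {
  f <- field_params(proton_mhz = 700)
  set.seed(42)
  for (i in 1:20) {
    S2 <- runif(1, 0.2, 1)
    te <- runif(1, 0, 1500)
    Rex <- runif(1, 0, 10)
    tm <- runif(1, 4, 25)
    p <- model_free_params("M4", S2 = S2, tau_e = te, R_ex = Rex)
    d <- diffusion_model("isotropic", tau_m = tm)
    got <- forward_rates(p, d, f)
    want <- oracle_rates(S2, tm, te, Rex)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("rigid-limit relaxation triple matches the frozen oracle values", {
  f <- field_params(proton_mhz = 700)
  p <- model_free_params("M1", S2 = 1)
  d <- diffusion_model("isotropic", tau_m = 13.6)
  r <- forward_rates(p, d, f)
  expect_equal(unname(r["R1"]), 0.8561104881500083, tolerance = 1e-10)
  expect_equal(unname(r["R2"]), 21.69250962643638, tolerance = 1e-10)
  expect_equal(unname(r["NOE"]), 0.9155859773547599, tolerance = 1e-10)
})

test_that("exchange enters R2 additively and leaves R1 and the NOE term alone", {
  f <- field_params(proton_mhz = 700)
  d <- diffusion_model("isotropic", tau_m = 13.6)
  r0 <- forward_rates(model_free_params("M1", S2 = 0.85), d, f)
  r5 <- forward_rates(model_free_params("M3", S2 = 0.85, R_ex = 5), d, f)
  expect_equal(unname(r5["R2"] - r0["R2"]), 5, tolerance = 1e-12)
  expect_equal(r5["R1"], r0["R1"], tolerance = 1e-14)
  expect_equal(r5["NOE"], r0["NOE"], tolerance = 1e-14)
})

test_that("slow rigid tumbling gives R2 > R1 across the 4-30 ns range", {
  f <- field_params(proton_mhz = 700)
  p <- model_free_params("M1", S2 = 1)
  for (tm in seq(4, 30, by = 2)) {
    r <- forward_rates(p, diffusion_model("isotropic", tau_m = tm), f)
    expect_gt(r["R2"], r["R1"])
  }
})

test_that("axial spectral density reduces to isotropic at D_ratio = 1 and depends on orientation", {
  p <- model_free_params("M2", S2 = 0.85, tau_e = 50)
  iso <- diffusion_model("isotropic", tau_m = 13.6)
  ax1 <- diffusion_model("axial", tau_m = 13.6, D_ratio = 1)
  ax <- diffusion_model("axial", tau_m = 13.6, D_ratio = 1.5)
  w <- 4.46e8
  expect_equal(spectral_density(p, ax1, w, theta_deg = 30) * 1e9,
               spectral_density(p, iso, w) * 1e9, tolerance = 1e-12)
  expect_gt(abs(spectral_density(p, ax, w, theta_deg = 0) -
                  spectral_density(p, ax, w, theta_deg = 90)) /
              spectral_density(p, ax, w, theta_deg = 90), 0.05)
  # Woessner amplitudes are a partition of unity for any angle
  for (th in c(0, 17, 45, 90)) {
    comp <- nmrdyn:::axial_components(13.6e-9, 1.5, th * pi / 180)
    expect_equal(sum(comp$amps), 1, tolerance = 1e-12)
  }
  expect_error(spectral_density(p, ax, w), "theta_deg")
})
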