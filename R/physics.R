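#' Physical constants for amide 15N relaxation
#'
#' Gyromagnetic ratios, N-H bond length and 15N chemical shift anisotropy
#' used by the dipolar + CSA relaxation forward model. Defaults follow the
#' common convention for backbone amide analysis: r(N-H) = 1.02 Angstrom and
#' a 15N CSA of -172 ppm; both are overridable because published analyses
#' differ in these choices and absolute S2 values shift accordingly.
#'
#' @param gamma_H 1H gyromagnetic ratio (rad s^-1 T^-1).
#' @param gamma_N 15N gyromagnetic ratio (rad s^-1 T^-1, negative).
#' @param r_NH N-H bond length in Angstrom; must lie in [0.9, 1.1].
#' @param delta_sigma 15N chemical shift anisotropy in ppm; must lie in
#'   [-200, -140].
#' @return An object of class `nmr_constants`.
#' @export
physical_constants <- function(gamma_H = 2.6752218744e8,
                               gamma_N = -2.71261804e7,
                               r_NH = 1.02,
                               delta_sigma = -172) {
  if (r_NH < 0.9 || r_NH > 1.1)
    stop("r_NH must be in [0.9, 1.1] Angstrom, got ", r_NH)
  if (delta_sigma < -200 || delta_sigma > -140)
    stop("delta_sigma must be in [-200, -140] ppm, got ", delta_sigma)
  structure(list(gamma_H = gamma_H, gamma_N = gamma_N,
                 r_NH = r_NH, delta_sigma = delta_sigma),
            class = "nmr_constants")
}

#' Static magnetic field settings
#'
#' Describes the spectrometer field. Either the field strength `B0` (Tesla)
#' or the proton resonance frequency `proton_mhz` (MHz) may be given; the
#' angular Larmor frequencies of 1H and 15N are derived from the
#' gyromagnetic ratios, so their ratio always equals gamma_H / gamma_N.
#' omega_N is stored with its physical (negative) sign; spectral densities
#' are evaluated at |omega|.
#'
#' @param B0 field strength in Tesla (> 0).
#' @param proton_mhz 1H resonance frequency in MHz (alternative to `B0`).
#' @param const an `nmr_constants` object.
#' @return An object of class `field_params` with elements `B0`, `omega_H`
#'   and `omega_N` (rad/s).
#' @examples
#' field_params(proton_mhz = 700)  # the 16.3 T field of a 700 MHz magnet
#' @export
field_params <- function(B0 = NULL, proton_mhz = NULL,
                         const = physical_constants()) {
  if (is.null(B0)) {
    if (is.null(proton_mhz))
      stop("give either B0 (Tesla) or proton_mhz (MHz)")
    B0 <- 2 * pi * proton_mhz * 1e6 / const$gamma_H
  }
  if (B0 <= 0) stop("B0 must be positive")
  structure(list(B0 = B0,
                 omega_H = const$gamma_H * B0,
                 omega_N = const$gamma_N * B0),
            class = "field_params")
}

#' Lipari-Szabo motional parameters for one residue
#'
#' The model-free description of internal N-H bond-vector motion. Five
#' standard model classes are supported:
#' \describe{
#'   \item{M1}{\{S2\} -- restricted fast motion only}
#'   \item{M2}{\{S2, tau_e\} -- fast motion with an effective internal time}
#'   \item{M3}{\{S2, R_ex\} -- fast motion plus chemical exchange}
#'   \item{M4}{\{S2, tau_e, R_ex\}}
#'   \item{M5}{\{Sf2, S2, tau_e\} -- extended two-timescale form}
#' }
#' Parameters a model does not use are pinned to their null values
#' (tau_e = 0, R_ex = 0, Sf2 = 1).
#'
#' @param model one of "M1".."M5".
#' @param S2 generalized order parameter in [0, 1] (for M5, the total
#'   S2 = Sf2 * Ss2).
#' @param tau_e effective internal correlation time in picoseconds (>= 0).
#' @param R_ex exchange contribution to R2 in s^-1 (>= 0).
#' @param Sf2 fast-limit order parameter in [0, 1]; must satisfy
#'   S2 <= Sf2 for M5.
#' @return An object of class `model_free_params`.
#' @export
model_free_params <- function(model = c("M1", "M2", "M3", "M4", "M5"),
                              S2, tau_e = 0, R_ex = 0, Sf2 = 1) {
  model <- match.arg(model)
  if (!is.finite(S2) || S2 < 0 || S2 > 1)
    stop("S2 must be in [0, 1], got ", S2)
  if (tau_e < 0) stop("tau_e must be >= 0 ps, got ", tau_e)
  if (R_ex < 0) stop("R_ex must be >= 0 s^-1, got ", R_ex)
  if (Sf2 < 0 || Sf2 > 1) stop("Sf2 must be in [0, 1], got ", Sf2)
  # pin unused parameters to their null values
  if (model %in% c("M1", "M3")) tau_e <- 0
  if (model %in% c("M1", "M2", "M5")) R_ex <- 0
  if (model != "M5") Sf2 <- 1
  if (model == "M5" && S2 > Sf2)
    stop("extended model requires S2 <= Sf2 (S2 = Sf2 * Ss2)")
  structure(list(model = model, S2 = S2, tau_e = tau_e,
                 R_ex = R_ex, Sf2 = Sf2),
            class = "model_free_params")
}

#' Global rotational diffusion model
#'
#' Overall molecular tumbling: isotropic (a single correlation time tau_m),
#' axially symmetric (tau_m of the equivalent isotropic rate, the anisotropy
#' D_parallel / D_perp, and the polar orientation of the unique axis), or
#' fully asymmetric (accepted as data but not used for fitting).
#'
#' @param kind "isotropic", "axial" or "asymmetric".
#' @param tau_m overall correlation time in ns, defined as 1 / (6 D_iso).
#' @param D_ratio D_parallel / D_perp (> 0; axial only).
#' @param orientation numeric angles in degrees locating the diffusion
#'   frame: length 2 (axial) or 3 (asymmetric).
#' @param D_components three principal diffusion constants in s^-1
#'   (asymmetric only).
#' @return An object of class `diffusion_model`.
#' @export
diffusion_model <- function(kind = c("isotropic", "axial", "asymmetric"),
                            tau_m, D_ratio = 1, orientation = NULL,
                            D_components = NULL) {
  kind <- match.arg(kind)
  if (kind == "asymmetric" && !is.null(D_components)) {
    if (length(D_components) != 3 || any(D_components <= 0))
      stop("asymmetric diffusion needs three positive principal values")
    tau_m <- 1 / (6 * mean(D_components)) * 1e9
  }
  if (!is.finite(tau_m) || tau_m <= 0)
    stop("tau_m must be positive (ns), got ", tau_m)
  if (D_ratio <= 0) stop("D_ratio must be > 0")
  structure(list(kind = kind, tau_m = tau_m, D_ratio = D_ratio,
                 orientation = orientation, D_components = D_components),
            class = "diffusion_model")
}

# Woessner decomposition of axial tumbling: correlation times and
# orientation weights for the angle theta between the N-H vector and the
# unique diffusion axis.  D_iso = (2 Dperp + Dpar) / 3 = 1/(6 tau_m).
axial_components <- function(tau_m_s, D_ratio, theta_rad) {
  D_iso <- 1 / (6 * tau_m_s)
  D_perp <- 3 * D_iso / (2 + D_ratio)
  D_par <- D_ratio * D_perp
  taus <- c(1 / (6 * D_perp),
            1 / (5 * D_perp + D_par),
            1 / (2 * D_perp + 4 * D_par))
  ct2 <- cos(theta_rad)^2
  st2 <- 1 - ct2
  amps <- c((3 * ct2 - 1)^2 / 4, 3 * st2 * ct2, 0.75 * st2^2)
  list(taus = taus, amps = amps)
}

#' Lipari-Szabo spectral density J(omega)
#'
#' Evaluates the model-free spectral density
#' \deqn{J(\omega) = \frac{2}{5}\left[\frac{S^2 \tau_m}{1 + (\omega\tau_m)^2}
#'   + \frac{(S_f^2 - S^2)\,\tau}{1 + (\omega\tau)^2}\right],\qquad
#'   \tau^{-1} = \tau_m^{-1} + \tau_e^{-1}}
#' (with Sf2 = 1 this is the classic single-timescale form; Sf2 < 1 gives
#' the extended two-timescale form). For axially symmetric tumbling the
#' single tau_m Lorentzian is replaced by the three-component Woessner sum
#' weighted by the N-H vector's angle to the unique axis.
#'
#' @param p a `model_free_params` object.
#' @param d a `diffusion_model` object (isotropic or axial).
#' @param omega angular frequency (rad/s); vectorized. Evaluated at
#'   |omega|.
#' @param theta_deg angle (degrees) between the N-H vector and the unique
#'   diffusion axis; required when `d$kind == "axial"`.
#' @return spectral density in s/rad, same length as `omega`.
#' @export
spectral_density <- function(p, d, omega, theta_deg = NULL) {
  stopifnot(inherits(p, "model_free_params"), inherits(d, "diffusion_model"))
  w <- abs(omega)
  tau_m <- d$tau_m * 1e-9
  tau_e <- p$tau_e * 1e-12
  if (d$kind == "isotropic" || (d$kind == "axial" && abs(d$D_ratio - 1) < 1e-12)) {
    taus <- tau_m
    amps <- 1
  } else if (d$kind == "axial") {
    if (is.null(theta_deg))
      stop("axial diffusion requires theta_deg (N-H vector to unique axis)")
    ax <- axial_components(tau_m, d$D_ratio, theta_deg * pi / 180)
    taus <- ax$taus
    amps <- ax$amps
  } else {
    stop("spectral density for fully asymmetric tumbling is not implemented; ",
         "supply an isotropic or axial model")
  }
  J <- numeric(length(w))
  for (k in seq_along(taus)) {
    tk <- taus[k]
    # internal-motion time combined with this tumbling component
    tp <- if (tau_e > 0) tk * tau_e / (tk + tau_e) else 0
    J <- J + amps[k] * (p$S2 * tk / (1 + (w * tk)^2) +
                          (p$Sf2 - p$S2) * tp / (1 + (w * tp)^2))
  }
  0.4 * J
}

#' Dipolar + CSA relaxation forward model
#'
#' Maps motional parameters to the measurable 15N relaxation observables at
#' one field: the longitudinal rate R1, the transverse rate R2 (including
#' any chemical-exchange term R_ex, which enters R2 additively and nothing
#' else) and the steady-state heteronuclear 1H-15N NOE.
#'
#' The standard expressions are used, with d the N-H dipolar coupling
#' constant and c = omega_N * delta_sigma / sqrt(3) the CSA interaction:
#' \deqn{R_1 = \frac{d^2}{4}[J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H+\omega_N)] + c^2 J(\omega_N)}
#' \deqn{R_2 = \frac{d^2}{8}[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H) + 6J(\omega_H+\omega_N)] + \frac{c^2}{6}[4J(0) +
#'   3J(\omega_N)] + R_{ex}}
#' \deqn{NOE = 1 + \frac{d^2}{4}\frac{\gamma_H}{\gamma_N}\frac{1}{R_1}
#'   [6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)]}
#' Frequencies use |omega_N|; the sign of gamma_N enters the NOE through
#' the explicit gamma_H / gamma_N factor.
#'
#' @param p a `model_free_params` object.
#' @param d a `diffusion_model` object.
#' @param f a `field_params` object.
#' @param const an `nmr_constants` object.
#' @param theta_deg N-H vector angle for axial diffusion (degrees).
#' @return named numeric vector `c(R1, R2, NOE)` (s^-1, s^-1,
#'   dimensionless).
#' @export
forward_rates <- function(p, d, f, const = physical_constants(),
                          theta_deg = NULL) {
  stopifnot(inherits(f, "field_params"), inherits(const, "nmr_constants"))
  hbar <- 1.054571817e-34
  mu0_4pi <- 1e-7
  wH <- abs(f$omega_H)
  wN <- abs(f$omega_N)
  dd <- mu0_4pi * hbar * const$gamma_H * abs(const$gamma_N) /
    (const$r_NH * 1e-10)^3
  d2 <- dd^2
  c2 <- (wN * const$delta_sigma * 1e-6)^2 / 3

  Jv <- spectral_density(p, d, c(0, wN, wH - wN, wH, wH + wN), theta_deg)
  J0 <- Jv[1]; JN <- Jv[2]; JHmN <- Jv[3]; JH <- Jv[4]; JHpN <- Jv[5]

  R1 <- d2 / 4 * (JHmN + 3 * JN + 6 * JHpN) + c2 * JN
  R2 <- d2 / 8 * (4 * J0 + JHmN + 3 * JN + 6 * JH + 6 * JHpN) +
    c2 / 6 * (4 * J0 + 3 * JN) + p$R_ex
  NOE <- if (R1 > 0) {
    1 + d2 / 4 * (const$gamma_H / const$gamma_N) / R1 * (6 * JHpN - JHmN)
  } else NA_real_
  c(R1 = R1, R2 = R2, NOE = NOE)
}
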