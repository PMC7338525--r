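#' Default relaxation delay schedules
#'
#' The inversion-recovery (R1) and CPMG (R2) relaxation delay lists used
#' throughout the package as defaults for simulation: 14 R1 delays ending
#' at 2.5 s and 16 R2 delays ending at 305.3 ms.
#'
#' @return numeric vector of delays in seconds.
#' @export
r1_delay_schedule <- function() {
  c(0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5, 0.58, 0.64, 0.8, 1.0, 1.3, 1.8, 2.5)
}

#' @rdname r1_delay_schedule
#' @export
r2_delay_schedule <- function() {
  c(0, 17, 33.9, 50.9, 67.8, 84.8, 101.8, 118.7, 135.7, 152.6, 169.6,
    186.6, 203.5, 237.4, 271.4, 305.3) / 1000
}

#' One residue's peak-intensity relaxation decay
#'
#' @param residue_id integer sequence position.
#' @param delays relaxation delays in seconds (>= 3 values, non-negative).
#' @param intensities peak volumes (arbitrary units), same length.
#' @param sigma single intensity noise estimate (> 0, same units).
#' @return An object of class `decay_series`, sorted by delay.
#' @export
decay_series <- function(residue_id, delays, intensities, sigma) {
  if (length(delays) != length(intensities))
    stop("delays and intensities must have equal length")
  if (length(delays) < 3)
    stop("need at least 3 delay points, got ", length(delays))
  if (any(delays < 0)) stop("delays must be non-negative")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  ord <- order(delays)
  delays <- delays[ord]; intensities <- intensities[ord]
  if (any(diff(delays) < 0)) stop("delays must sort increasing")
  structure(list(residue_id = as.integer(residue_id), delays = delays,
                 intensities = intensities, sigma = sigma),
            class = "decay_series")
}

# Average duplicate delay points (e.g. repeated 0 ms checks); the effective
# sigma of an averaged point scales as 1/sqrt(n), which a single-sigma WLS
# absorbs through per-point weights.
collapse_duplicate_delays <- function(series) {
  d <- series$delays
  if (!anyDuplicated(d)) {
    series$weights <- rep(1, length(d))
    return(series)
  }
  grp <- match(d, unique(d))
  n <- tabulate(grp)
  series$delays <- unique(d)
  series$intensities <- as.numeric(tapply(series$intensities, grp, mean))
  series$weights <- n  # weight = n  <=>  sigma_i = sigma / sqrt(n)
  series
}

#' Fit a monoexponential decay I(t) = I0 exp(-R t)
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) with start values
#' from a log-linear regression of the positive intensities. Duplicate
#' delays are averaged first, with their noise reduced as 1/sqrt(n). The
#' rate uncertainty comes from the exact Jacobian at the optimum and the
#' stated noise sigma (not the residual variance), so noiseless data yield
#' a meaningful sigma for the stated noise level.
#'
#' @param series a `decay_series`.
#' @return a list of class `rate_estimate`: `residue_id`, `rate` (s^-1),
#'   `sigma_rate`, `I0`, `rss`, `converged`.
#' @export
fit_monoexponential <- function(series) {
  stopifnot(inherits(series, "decay_series"))
  s <- collapse_duplicate_delays(series)
  t <- s$delays; y <- s$intensities; w <- s$weights
  if (length(unique(y)) == 1)
    stop("all intensities equal: decay rate is unidentifiable")

  # log-linear initialization from positive intensities (>= 2 needed);
  # fall back to a first/last two-point slope estimate otherwise
  pos <- y > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm.wfit(cbind(1, t[pos]), log(y[pos]), w[pos])
    R0 <- max(-as.numeric(lf$coefficients[2]), 1e-3)
    I00 <- as.numeric(exp(lf$coefficients[1]))
  } else {
    R0 <- 1
    I00 <- max(abs(y))
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * exp(-R * t),
                      start = list(I0 = I00, R = R0),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  converged <- !is.null(fit) && fit$convInfo$isConv
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    I0 <- as.numeric(cf[1]); R <- as.numeric(cf[2])
  } else {
    # profile the rate: I0 has a closed form given R
    prof <- function(R) {
      e <- exp(-R * t)
      I0 <- sum(w * y * e) / sum(w * e^2)
      sum(w * (y - I0 * e)^2)
    }
    op <- stats::optimize(prof, c(1e-4, 1e4))
    R <- op$minimum
    e <- exp(-R * t)
    I0 <- sum(w * y * e) / sum(w * e^2)
    converged <- FALSE
  }

  e <- exp(-R * t)
  rss <- sum(w * (y - I0 * e)^2)
  # parameter covariance from the exact Jacobian and the known sigma:
  # cov = sigma^2 (J^T W J)^-1 with J = [e, -I0 t e]
  J <- cbind(e, -I0 * t * e)
  JtWJ <- crossprod(J * sqrt(w))
  sigma_rate <- tryCatch(sqrt(series$sigma^2 * solve(JtWJ)[2, 2]),
                         error = function(e) NA_real_)

  structure(list(residue_id = series$residue_id, rate = R,
                 sigma_rate = sigma_rate, I0 = I0, rss = rss,
                 converged = converged),
            class = "rate_estimate")
}

#' Steady-state heteronuclear NOE from saturated/reference intensities
#'
#' NOE = I_sat / I_ref, with the uncertainty propagated from the RMS noise
#' of the spectrum background:
#' sigma = |NOE| sqrt((rms/I_sat)^2 + (rms/I_ref)^2).
#' Negative NOEs are legal and mark highly flexible residues.
#'
#' @param I_sat peak intensity with 1H saturation.
#' @param I_ref reference peak intensity (non-zero).
#' @param rms_noise RMS noise of the spectrum background regions.
#' @param residue_id optional residue label.
#' @return a list of class `noe_estimate`: `residue_id`, `noe`, `sigma_noe`.
#' @export
estimate_noe <- function(I_sat, I_ref, rms_noise, residue_id = NA_integer_) {
  if (I_ref == 0) stop("reference intensity is zero: NOE undefined")
  if (rms_noise < 0) stop("rms_noise must be >= 0")
  noe <- I_sat / I_ref
  sigma_noe <- if (I_sat == 0) abs(rms_noise / I_ref) else
    abs(noe) * sqrt((rms_noise / I_sat)^2 + (rms_noise / I_ref)^2)
  structure(list(residue_id = as.integer(residue_id), noe = noe,
                 sigma_noe = sigma_noe),
            class = "noe_estimate")
}

#' Monte-Carlo uncertainty of a fitted decay rate
#'
#' Refits noise-resampled copies of the series (Gaussian noise of the
#' stated sigma added to the fitted curve) and returns the standard
#' deviation of the refitted rates. Reproducible under a fixed seed.
#'
#' @param series a `decay_series`.
#' @param n_reps number of Monte-Carlo replicates (>= 100).
#' @param seed integer RNG seed.
#' @return `sigma_rate` (s^-1).
#' @export
monte_carlo_rate_errors <- function(series, n_reps = 500, seed = 1L) {
  stopifnot(inherits(series, "decay_series"))
  if (n_reps < 100) stop("n_reps must be >= 100")
  base <- fit_monoexponential(series)
  if (series$sigma == 0) return(0)
  fitted <- base$I0 * exp(-base$rate * series$delays)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  rates <- vapply(seq_len(n_reps), function(i) {
    y <- fitted + stats::rnorm(length(fitted), 0, series$sigma)
    s <- series
    s$intensities <- y
    tryCatch(fit_monoexponential(s)$rate, error = function(e) NA_real_)
  }, numeric(1))
  stats::sd(rates, na.rm = TRUE)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
}

#' Read / fit a table of relaxation decays
#'
#' Reads a TSV with columns `residue`, `delay_s`, `intensity`, `sigma`
#' (one series per residue) and fits every series.
#'
#' @param path TSV file path.
#' @return list of `decay_series`.
#' @export
read_decay_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("residue", "delay_s", "intensity", "sigma")
  if (!all(need %in% names(df)))
    stop("decay table needs columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$residue), function(d)
    decay_series(d$residue[1], d$delay_s, d$intensity, d$sigma[1]))
}

#' @param series_list list of `decay_series` (e.g. from `read_decay_table`).
#' @rdname read_decay_table
#' @return for `fit_rate_table`: data.frame residue, rate, sigma_rate, I0,
#'   converged.
#' @export
fit_rate_table <- function(series_list) {
  rows <- lapply(series_list, function(s) {
    f <- fit_monoexponential(s)
    data.frame(residue = f$residue_id, rate = f$rate,
               sigma_rate = f$sigma_rate, I0 = f$I0,
               converged = f$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$residue), , drop = FALSE]
}
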