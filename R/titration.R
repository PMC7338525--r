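#' Combined 1H/15N chemical-shift perturbation
#'
#' The standard weighted Euclidean combination
#' \deqn{CSP = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}}
#' with the conventional nitrogen scaling alpha = 0.14 (the 1H and 15N
#' shift ranges differ by roughly that factor).
#'
#' @param dH_apo,dN_apo 1H and 15N shifts (ppm) of the apo point.
#' @param dH_end,dN_end shifts at the endpoint.
#' @param alpha 15N scaling factor.
#' @return combined CSP in ppm (>= 0); vectorized.
#' @export
combined_csp <- function(dH_apo, dN_apo, dH_end, dN_end, alpha = 0.14) {
  sqrt((dH_end - dH_apo)^2 + (alpha * (dN_end - dN_apo))^2)
}

#' Titration series container
#'
#' @param ratios ligand:protein molar ratios, non-decreasing, first = 0
#'   (apo).
#' @param peaks list of peak lists (data.frames with columns `residue`,
#'   `dH_ppm`, `dN_ppm`, `intensity`), one per titration point.
#' @return object of class `titration_series`.
#' @export
titration_series <- function(ratios, peaks) {
  if (length(ratios) != length(peaks))
    stop("one peak list per titration point required")
  if (length(ratios) < 2) stop("a titration needs at least 2 points")
  if (is.unsorted(ratios)) stop("ratios must be non-decreasing")
  if (ratios[1] != 0) stop("the first point must be the apo state (ratio 0)")
  need <- c("residue", "dH_ppm", "dN_ppm", "intensity")
  for (p in peaks)
    if (!all(need %in% names(p)))
      stop("peak lists need columns: ", paste(need, collapse = ", "))
  structure(list(ratios = ratios, peaks = peaks),
            class = "titration_series")
}

#' Classify a titration as specific binding, non-specific, or none
#'
#' Residue-level readout: the combined CSP between apo and final point
#' and the intensity ratio I_final / I_apo, matched by residue id.
#' A residue is "shifted" when its CSP exceeds the significance threshold
#' (default: mean + 2 SD over all residues, the usual self-calibrating
#' cutoff), "broadened" when its intensity ratio falls below the
#' broadening threshold without a significant shift, else "unchanged".
#'
#' Verdict: "specific" when a sizeable set of residues shifts
#' significantly; "non-specific" when the median intensity ratio drops
#' below the broadening threshold with no shift cluster (global line
#' broadening from high-molecular-weight aggregation); "none" otherwise.
#'
#' @param series a `titration_series`.
#' @param csp_threshold absolute CSP cutoff in ppm, or NULL for the
#'   self-calibrating rule: baseline mean + 2 SD computed on the lower 90%
#'   of residues (so genuine perturbations do not inflate their own
#'   cutoff), never below `csp_floor`.
#' @param csp_floor minimum significant CSP in ppm (default 0.02, the
#'   usual measurement noise floor of 1H/15N peak positions).
#' @param broadening_threshold intensity-ratio cutoff (default 0.5).
#' @param min_shifted minimum number of shifted residues for a "specific"
#'   verdict.
#' @param alpha 15N scaling for the combined CSP.
#' @return list of class `titration_result`: `table` (residue, csp,
#'   intensity_ratio, class), `verdict`, `csp_threshold`.
#' @export
classify_titration <- function(series, csp_threshold = NULL,
                               csp_floor = 0.02,
                               broadening_threshold = 0.5,
                               min_shifted = 3, alpha = 0.14) {
  stopifnot(inherits(series, "titration_series"))
  apo <- series$peaks[[1]]
  end <- series$peaks[[length(series$peaks)]]
  common <- intersect(apo$residue, end$residue)
  if (!length(common)) stop("no residues shared between apo and endpoint")
  a <- apo[match(common, apo$residue), ]
  e <- end[match(common, end$residue), ]
  csp <- combined_csp(a$dH_ppm, a$dN_ppm, e$dH_ppm, e$dN_ppm, alpha)
  iratio <- ifelse(a$intensity > 0, e$intensity / a$intensity, NA_real_)
  thr <- if (is.null(csp_threshold)) {
    base <- csp[csp <= stats::quantile(csp, 0.9)]
    max(mean(base) + 2 * stats::sd(base), csp_floor)
  } else csp_threshold

  cls <- ifelse(csp > thr, "shifted",
                ifelse(!is.na(iratio) & iratio < broadening_threshold,
                       "broadened", "unchanged"))
  n_shift <- sum(cls == "shifted")
  med_ratio <- stats::median(iratio, na.rm = TRUE)
  verdict <- if (n_shift >= min_shifted) "specific"
  else if (med_ratio < broadening_threshold) "non-specific"
  else "none"
  structure(list(table = data.frame(residue = common, csp = csp,
                                    intensity_ratio = iratio, class = cls),
                 verdict = verdict, csp_threshold = thr),
            class = "titration_result")
}

#' Read a titration peak list (TSV: residue, dH_ppm, dN_ppm, intensity)
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_peak_list <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  need <- c("residue", "dH_ppm", "dN_ppm", "intensity")
  if (!all(need %in% names(df)))
    stop("peak list needs columns: ", paste(need, collapse = ", "))
  df
}
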