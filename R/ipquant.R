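#' qPCR co-immunoprecipitation yield (% of input)
#'
#' Yield of an RNA recovered on affinity beads relative to the lysate
#' input, from the Ct difference of the two qPCR reactions:
#' \deqn{yield = 2^{Ct(input) - Ct(beads)} \times
#'   \frac{1}{beads\ fraction} \times input\ percent}
#' The defaults (0.3% of the lysate assayed as input, half the beads
#' assayed) reproduce the common "x 2 x 0.3" form of the formula; the two
#' assay fractions are exposed so the same computation covers other IP
#' designs.
#'
#' @param ct_input Ct of the input reaction (cycles, > 0).
#' @param ct_beads Ct of the beads reaction (cycles, > 0).
#' @param input_fraction_percent percent of lysate assayed as input
#'   (0 < x <= 100).
#' @param beads_fraction fraction of beads assayed (0 < x <= 1).
#' @return yield as percent of input; vectorized.
#' @export
qpcr_yield <- function(ct_input, ct_beads, input_fraction_percent = 0.3,
                       beads_fraction = 0.5) {
  if (any(ct_input <= 0) || any(ct_beads <= 0))
    stop("Ct values must be positive")
  if (any(input_fraction_percent <= 0) || any(input_fraction_percent > 100))
    stop("input_fraction_percent must be in (0, 100]")
  if (any(beads_fraction <= 0) || any(beads_fraction > 1))
    stop("beads_fraction must be in (0, 1]")
  2^(ct_input - ct_beads) / beads_fraction * input_fraction_percent
}

#' Replicate band-intensity summary and fold change
#'
#' Mean and sample SD (n - 1) of replicate quantifications, plus the
#' ratio of means against a reference condition with its uncertainty
#' propagated from the relative errors of both means
#' (sd of the mean = SD / sqrt(n)).
#'
#' @param values numeric replicate measurements (>= 2).
#' @param reference numeric replicates of the reference condition (>= 2,
#'   non-zero mean).
#' @return list: `mean`, `sd`, `n`, `fold_change`, `fold_sd`,
#'   `reference_mean`, `reference_sd`.
#' @export
replicate_summary <- function(values, reference) {
  if (length(values) < 2 || length(reference) < 2)
    stop("need at least 2 replicates per condition")
  mv <- mean(values); mr <- mean(reference)
  if (mr == 0) stop("reference mean is zero: fold change undefined")
  sv <- stats::sd(values); sr <- stats::sd(reference)
  fc <- mv / mr
  sem_v <- sv / sqrt(length(values))
  sem_r <- sr / sqrt(length(reference))
  fold_sd <- abs(fc) * sqrt((sem_v / mv)^2 + (sem_r / mr)^2)
  list(mean = mv, sd = sv, n = length(values), fold_change = fc,
       fold_sd = fold_sd, reference_mean = mr, reference_sd = sr)
}
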