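---
title: "Backbone dynamics and ensemble quality: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone dynamics and ensemble quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdyn)
```

`nmrdyn` implements the quantitative core of a solution-NMR protein study:
extracting ¹⁵N relaxation observables, inferring pico-to-nanosecond and
millisecond backbone dynamics through the Lipari–Szabo model-free
formalism, and assessing the precision and restraint consistency of the
resulting structure ensemble. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not establish about real data.

## The relaxation forward model

An amide ¹⁵N nucleus relaxes through its dipolar coupling to the attached
proton and through its chemical shift anisotropy (CSA). Both mechanisms
sample the orientational fluctuations of the N–H bond vector, summarized
by the spectral density $J(\omega)$. The package evaluates the standard
expressions

$$R_1 = \tfrac{d^2}{4}\,[J(\omega_H-\omega_N) + 3J(\omega_N) +
6J(\omega_H+\omega_N)] + c^2 J(\omega_N)$$

$$R_2 = \tfrac{d^2}{8}\,[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
6J(\omega_H) + 6J(\omega_H+\omega_N)] + \tfrac{c^2}{6}[4J(0) +
3J(\omega_N)] + R_{ex}$$

$$\mathrm{NOE} = 1 + \tfrac{d^2}{4}\,\frac{\gamma_H}{\gamma_N}\,
\frac{1}{R_1}\,[6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)]$$

with $d = \frac{\mu_0}{4\pi}\,\hbar\,\gamma_H\gamma_N\,r_{NH}^{-3}$ and
$c = \omega_N\,\Delta\sigma/\sqrt{3}$. Spectral densities are evaluated at
$|\omega|$; the sign of $\gamma_N$ appears only through the explicit
$\gamma_H/\gamma_N$ factor in the NOE, which keeps a single unambiguous
sign convention.

Two constants are not observables and must be assumed: the N–H bond length
(default 1.02 Å) and the ¹⁵N CSA (default −172 ppm). These are the common
literature conventions for backbone amide analysis; both are arguments of
`physical_constants()` because absolute $S^2$ values shift by a few
percent under other defensible choices. For the same reason the package
claims recovery of *its own* forward model's parameters, not numerical
identity with any third-party fit of the same data.

Units at the API boundary are the field's: τₘ in ns, τₑ in ps, rates in
s⁻¹, field as Tesla or proton MHz. All internal computation is SI.

## The motional models

The Lipari–Szabo decomposition writes

$$J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_m}{1+(\omega\tau_m)^2} +
\frac{(S_f^2 - S^2)\,\tau}{1+(\omega\tau)^2}\right],\qquad
\tau^{-1} = \tau_m^{-1} + \tau_e^{-1},$$

with $S_f^2 = 1$ giving the classic single-timescale form. Five candidate
models per residue follow the conventional hierarchy: M1 {S²},
M2 {S², τₑ}, M3 {S², Rex}, M4 {S², τₑ, Rex}, M5 {Sf², S², τₑ}. Parameters
a model does not use are pinned (τₑ = 0, Rex = 0, Sf² = 1), and
constructors enforce 0 ≤ S² ≤ Sf² ≤ 1, τₑ ≥ 0, Rex ≥ 0.

For axially symmetric tumbling the τₘ Lorentzian is replaced by the
three-component Woessner sum whose weights depend on the angle between
the N–H vector and the unique diffusion axis; the fully asymmetric tensor
is accepted as a data structure but not fitted — with single-field data
and near-spherical molecules the axial/isotropic comparison is where the
information runs out.

## The two-stage fitting workflow

**Stage 1 — overall tumbling.** For residues free of fast internal motion
and exchange, the R₂/R₁ ratio depends on τₘ alone and increases strictly
with it, so each residue's ratio is inverted by 1-D root finding
(bracket 1–50 ns). The rigid subset is selected by the standard filter:
drop residues with NOE < 0.65 (fast internal motion depresses the NOE
first), then one pass dropping residues whose ratio deviates more than
1 SD from the subset mean (exchange inflates R₂). The deviation pass is
capped at 20% of residues so a noisy dataset cannot trim itself to
nothing. The estimate is reported as trimmed mean ± SD.

**Stage 2 — per-residue models.** With the diffusion model fixed, each
residue's triple (R₁, R₂, NOE) is fitted under every candidate model by
bounded L-BFGS-B from a deterministic coarse start grid
(S² ∈ {0.2, 0.5, 0.8, 0.95}, τₑ ∈ {10, 100, 1000} ps,
Rex ∈ {0, 3, 8} s⁻¹), followed by a tight-tolerance polish of the winning
start. This two-stage (global-then-local) workflow matches standard
practice and keeps each residue's fit a three-observation problem.

**Model selection.** Models are compared by AIC = χ² + 2k with a parsimony
margin: any model within ΔAIC < 2 of the minimum loses to the model with
fewer parameters. AICc would be preferable in principle, but with n = 3
observations per residue its correction term 2k(k+1)/(n−k−1) divides by
zero at k = 2; plain AIC with the Δ < 2 rule is the workable form of the
same parsimony intent. Measured on synthetic data generated under M1 with
2% noise, a more complex model is selected in well under 10% of
replicates.

**Identifiability caveat.** With one magnetic field there are three
observables per residue, so three-parameter models (M4, M5) can always
interpolate the data; the bounded ranges and parsimony margin are what
keep them from being chosen spuriously. Single-field Rex estimates are
weakly identified in general and should be read as detection plus rough
magnitude, not as precise exchange quantification.

**Errors.** Parameter uncertainties come from parametric Monte-Carlo
resampling: the fitted rates are perturbed within the stated measurement
errors and refit (from the point estimate — the perturbed optimum stays in
its basin), with the spread reported as σ and the 95% interval as the
normal approximation estimate ± 1.96σ. Measured on synthetic data at 2%
noise, per-parameter coverage is ~94–95% across all five model classes;
the resampled quantiles themselves are noisier than the σ at practical
replicate counts (default 500 for production, 100–200 in tests), which is
why the normal form is the reported interval. The Monte-Carlo seed is an
explicit argument and recorded alongside results.

## Decay fitting

R₁/R₂ rates come from weighted nonlinear least squares on
$I(t) = I_0 e^{-Rt}$ (Levenberg–Marquardt, via `minpack.lm`), initialized
from a log-linear regression of the positive intensities — a
deterministic, scale-invariant start. One noise σ per series reflects how
spectral noise is actually estimated (a single RMS over background
regions); duplicate delays are averaged with weights n (σ/√n). The rate
uncertainty uses the exact Jacobian and the *stated* σ rather than the
residual variance, so a clean fit still reports the uncertainty implied by
the declared noise. Non-convergence falls back to a 1-D profile search
over R (I₀ has a closed form given R) and is flagged, never silent. The
default delay schedules are the standard inversion-recovery (14 delays to
2.5 s) and CPMG (16 delays to 305.3 ms) lists. The heteronuclear NOE is
the ratio I_sat/I_ref with the usual two-term relative-error propagation;
negative NOEs are legal and mark flexible tails.

## Ensemble analysis

Superposition is the Kabsch SVD solution constrained to proper rotations;
the test suite cross-checks it against an independent quaternion
(Horn-method) implementation to 10⁻⁹ Å. The representative model minimizes
the sum of pairwise RMSDs to the rest of the family (ties to the lowest
index), and family precision is the mean ± SD RMSD of the other models
superposed onto it — by default over backbone N, Cα, C of a stated residue
range, since tails dominate all-residue RMSDs meaninglessly.

Distance restraints are read from CNS/XPLOR `assign` tables
(bounds [d − d⁻, d + d⁺]) or NMR-STAR constraint loops (ambiguous members
grouped by constraint ID). Ambiguous groups are kept as groups and
evaluated with the r⁻⁶ sum convention,
$d_\mathrm{eff} = (\sum r^{-6})^{-1/6}$, which can only shrink as atoms
join a group — matching how ambiguous NOEs are treated in structure
calculation. Pseudoatom names expand by the IUPAC/CNS conventions
(trailing wildcards by prefix; Q/M pseudoatoms to the corresponding
protons). A violation is max(0, d_eff − upper, lower − d_eff) per model;
dihedral deviations are wrapped into (−180°, 180°] before subtracting the
allowed range. Sequence-separation classes follow the universal NOE
bookkeeping (intraresidue, sequential, medium 1 < |i−j| ≤ 4, long > 4),
with ambiguous restraints classified by their minimum separation.

The Ramachandran summary is a deliberate *screen*: coarse rectangular
regions around the α and β basins (mirrored for glycine), validated
against canonical helices and hand-computed dihedrals only. Region
dialects differ between validation programs at the percent level, so these
fractions are not comparable to PROCHECK-style statistics and the package
does not claim they are.

## Titration classification

Per residue the combined CSP between apo and endpoint is
$\sqrt{\Delta\delta_H^2 + (0.14\,\Delta\delta_N)^2}$ (0.14 is the common
¹⁵N scaling). The significance cutoff is self-calibrating — baseline
mean + 2 SD computed on the lower 90% of residues, so genuine
perturbations do not inflate their own threshold — with a floor of
0.02 ppm, the practical measurement noise of peak positions; the floor is
what prevents pure-noise datasets (where some residue always exceeds any
purely relative cutoff) from producing false "specific" verdicts. A series
is "specific" when at least 3 residues shift significantly, "non-specific"
when the median intensity drops below 0.5 of apo without a shift cluster
(global broadening, the signature of high-molecular-weight aggregation),
"none" otherwise. These thresholds are explicit, documented stand-ins for
what is usually a qualitative judgement.

## The synthetic generator: what it does and does not emulate

`scenario_spec()` defaults describe the study conditions the package
models: a 178-residue protein, isotropic tumbling at τₘ = 13.6 ns, 700 MHz
proton frequency, 2% relative rate noise, 20-model ensembles with 0.35 Å
coordinate jitter, and a ground-truth profile with disordered tails
(S² ≈ 0.25), mobile loops, and a core-wide band of 2–10 s⁻¹ exchange. All
generators are deterministic under the seed, to the byte in their file
outputs.

What passing tests show: the estimators invert the package's own forward
models correctly (exact recovery at zero noise, calibrated errors at 2%
noise); the ensemble statistics equal brute-force oracles; planted
violations and planted titration scenarios are recovered.

What they do not show: robustness to the failure modes of real spectra —
peak overlap, baseline distortion, correlated noise, mis-assignment.
Gaussian, independent noise is the simplest model consistent with standard
error treatment, and results on real data inherit every caveat of that
assumption. Similarly, ensemble models built by i.i.d. atomic jitter
reproduce global precision statistics (mean RMSD ≈ σ√6 between jittered
copies) but have unphysical local geometry: bond lengths and dihedrals
fluctuate far more than in a real refined family. The generated dihedral
restraints therefore take their allowed ranges from the ensemble itself
(max deviation + 5°, floor ±30°), and the Ramachandran screen of jittered
ensembles is expectedly poor — neither limits the tests, which target the
statistics machinery, not molecular realism. The toy base folds (ideal
α-helix; a crude five-strand barrel) supply realistic local geometry for
superposition and restraint arithmetic without imitating any real
protein's fold.

## Problem sizes and numerical settings

The shipped analysis scripts run the full 178-residue scenario end to end.
The test suite uses 5–30-residue scenarios, 50–100 replicate datasets for
recovery and parsimony properties, and 100–200 Monte-Carlo error
replicates — sizes chosen to estimate each property's rate with useful
precision while keeping the suite quick on a single core. Optimization
tolerances: root finding to 10⁻⁶ ns; grid-start L-BFGS-B with a
factr = 10 polish; χ² guarded against the degenerate S² = 0, τₑ = 0 corner
where the spectral density vanishes and the NOE is undefined. Tie-breaks
are deterministic throughout (lowest model index, simplest model,
first-listed start).

## Known limitations

- Single-field data only; no joint multi-field fitting and no relaxation
  dispersion, so millisecond exchange is detected via Rex, not
  characterized.
- Anisotropic diffusion fitting stops at the axial tensor; the asymmetric
  case is represented but not fitted.
- Cross-correlated relaxation and anisotropic-CSA effects are outside the
  model.
- The Ramachandran screen is not a validation-grade classifier.
- mmCIF reading is single-model; ensembles should use multi-model PDB.
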