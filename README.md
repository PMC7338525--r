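# nmrdyn

Backbone ¹⁵N relaxation analysis, Lipari–Szabo model-free dynamics and NMR
ensemble quality assessment in R.

`nmrdyn` is aimed at protein NMR spectroscopists and structural
bioinformaticians who need a scriptable, testable pipeline for the
quantitative steps that follow spectral processing of a solution-structure
and dynamics study:

- **Relaxation-rate extraction** — weighted monoexponential fits
  `I(t) = I₀·exp(−R·t)` of peak-intensity decay tables give per-residue
  longitudinal (R₁) and transverse (R₂) rates with covariance or
  Monte-Carlo errors; steady-state heteronuclear NOEs come from
  saturated/reference intensity pairs with RMS-noise error propagation.
- **Model-free dynamics inference** — the Lipari–Szabo spectral density
  `J(ω) = (2/5)[S²τₘ/(1+(ωτₘ)²) + (1−S²)τ/(1+(ωτ)²)]` (with
  `1/τ = 1/τₘ + 1/τₑ`, and the extended Sf² form for two-timescale motion)
  drives a dipolar + CSA forward model for (R₁, R₂, NOE) at a given field.
  The overall tumbling time τₘ is estimated from rigid-subset R₂/R₁ ratios
  by 1-D root finding; isotropic vs axially symmetric diffusion is compared
  by AIC; per-residue motional models M1 {S²} … M5 {Sf², S², τₑ} are fitted
  by multi-start weighted χ² minimization with parsimony-guarded AIC
  selection and Monte-Carlo parameter errors. Chemical exchange enters as
  an additive Rex on R₂.
- **Ensemble quality assessment** — multi-model PDB input, Kabsch (SVD)
  superposition, representative-structure selection by lowest pairwise RMSD
  sum, family precision (mean ± SD RMSD), CNS/XPLOR `.tbl` and NMR-STAR
  restraint parsing, r⁻⁶-averaged effective distances for ambiguous NOEs,
  violation reports, sequence-separation NOE classification, and a coarse
  Ramachandran screen.
- **Interaction probing** — combined ¹H/¹⁵N chemical-shift perturbations
  `CSP = √(ΔδH² + (0.14·ΔδN)²)` across titration series, classified into
  specific binding / non-specific broadening / no interaction.
- **IP quantification** — qPCR co-immunoprecipitation yields
  `2^(Ct(input)−Ct(beads)) × (1/beads fraction) × input %` and replicate
  band-intensity summaries.
- **Synthetic data** — a generator producing every input the pipeline
  consumes (decays, rate tables, jittered coordinate ensembles with
  consistent restraints, titration peak lists) with known ground truth and
  full determinism under a seed, so every stage is testable offline.

## Worked example

```r
library(nmrdyn)

# a rigid 30-residue protein tumbling at 13.6 ns, measured at 700 MHz
spec <- scenario_spec(
  seed = 1, n_residues = 30,
  params = data.frame(residue = 1:30, model = "M1", S2 = 1,
                      tau_e = 0, R_ex = 0, Sf2 = 1),
  diffusion = diffusion_model("isotropic", tau_m = 13.6),
  rate_rel_sigma = 0)
records <- gen_relaxation_dataset(spec)
est <- estimate_tau_m_r2r1(records)
cat(sprintf("tau_m = %.2f +/- %.2f ns (n = %d)\n",
            est$tau_m, est$sd, est$n_used))
#> tau_m = 13.60 +/- 0.00 ns (n = 30)
```

The estimator inverts each residue's R₂/R₁ ratio through the rigid-tumbler
forward model and reports the trimmed mean: on noiseless rigid input it
returns the generating correlation time exactly.

The `analysis/` directory holds the full narrative workflow over a
simulated 178-residue study (`01_simulate.R` … `06_ip_quant.R`), writing
its tables under `results/`. Representative output:

```
Overall tumbling: tau_m = 13.43 +/- 0.55 ns from 110 rigid residues
Diffusion model selected: isotropic (tau_m = 13.35 ns)
Per-residue fits: 178 residues, median |S2 error| = 0.013
  residues with fitted exchange in the 2-10 s^-1 band: 50
Representative: model 10; backbone precision 0.81 +/- 0.02 A
  max distance violation 0.000 A (count > 0.5 A: 0)
none          -> verdict none
specific      -> verdict specific
non-specific  -> verdict non-specific
```

Here the tumbling time recovered from 2%-noise rates (13.43 ± 0.55 ns)
brackets the generating 13.6 ns; per-residue order parameters are
recovered to ~0.01; the ensemble's restraints — built to be consistent
with it — show zero violations; and all three titration scenarios are
classified to their planted labels.

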