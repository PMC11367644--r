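# clawbind

Analysis toolkit for studies of phosphopeptide recognition by the FIP200
claw domain — the C-terminal module of the autophagy scaffold FIP200 that
docks FIR/LIR-type peptide motifs from autophagy receptors and their
regulators. TNIP1, a negative regulator of mitophagy, carries such a
motif; once TBK1 phosphorylates it (S122/S123), the peptide binds the
claw tightly enough to displace autophagy-receptor peptides such as
CCPG1's phosphorylated FIR2. `clawbind` implements, as one tested
tidyverse-style pipeline, the four computations such a study rests on:

1. **Three-state competition model.** A claw domain is free, bound to a
   reporter peptide, or bound to a competitor. With association rates
   u₁, u₂ and dissociation rates w₁, w₂, the stationary reporter
   occupancy is P₁ = u₁w₂ / (w₁w₂ + u₁w₂ + u₂w₁). Under diffusion-controlled
   association this collapses to displacement isotherms for the remaining
   reporter fraction:

   y₁ = 1 / (1 + a₀·[competitor])  (unmodified competitor)

   y₂ = 1 / (1 + a₀·e^{|ΔE|/k_BT}·[competitor])  (phosphorylated)

   where a₀ (μM⁻¹) is fitted from unmodified-competitor data and ΔE
   (kJ/mol) is the difference in dissociation activation barrier between
   the two competitor forms. Both sign conventions for the Boltzmann
   factor are implemented (`enhancing`, the default, and `printed`).

2. **Single-site ITC fitting.** The one-site Wiseman isotherm with the
   quadratic fractional-saturation root and the perfusion
   (displaced-volume) correction, fitted to per-injection heats by
   multi-start weighted least squares; outputs K_D, N, ΔH with standard
   errors, ΔG = RT·ln K_D, −TΔS, and an F-test based no-binding flag.

3. **Umbrella-sampling post-processing.** Window-schedule construction
   (half-open segments: 0.5 Å spacing over 15–25 Å plus 1.0 Å over
   25–38 Å gives the canonical 33 windows), the weighted histogram
   analysis method solved by damped Newton iteration on its concave
   log-likelihood, profile alignment, dissociation barriers
   (plateau − bound minimum) and barrier differences, and bootstrap
   errors by window-wise resampling.

4. **Structural interface analysis.** PDB I/O (via bio3d), a selection
   mini-language, Kabsch superposition with RMSD, residue-paired Cα
   comparison, per-atom RMSF over ensembles, and geometric detection of
   hydrogen bonds, charge–charge contacts (including phosphoserine
   phosphate oxygens) and hydrophobic contacts, summarised in a
   deterministic plain-text interface report.

Seeded synthetic-data generators emulate every input — noisy single-site
titrations, Boltzmann-distributed biased samples from a known 1-D free
energy profile, displacement series, and a toy domain–peptide complex
with planted interactions — so the whole pipeline runs and is testable
with no downloads.

## Worked example

Predicting how much reporter complex survives competition, with the
fitted a₀ = 0.0006 μM⁻¹ and a barrier difference of ΔE = 9.4 kJ/mol at
300 K:

```r
library(clawbind)
p <- competition_params(a0 = 0.0006, dE = 9.4, temperature = 300)
predict_displacement_curve(p, c(10, 100, 1000))
#> # A tibble: 3 × 3
#>    conc    y1     y2
#>   <dbl> <dbl>  <dbl>
#> 1    10 0.994 0.794
#> 2   100 0.943 0.278
#> 3  1000 0.625 0.0371
```

At 1 mM competitor the unmodified peptide leaves 62.5% of the reporter
complex intact (`y1`), while the phosphorylated form — whose Boltzmann
factor e^{9.4/2.494} ≈ 43.3 multiplies its effective affinity — brings
it down to 3.7% (`y2`): phosphorylation turns a negligible competitor
into an effective one.

Fitting a synthetic titration (K_D = 10 μM, N = 1, ΔH = −5 kcal/mol,
0.2 μcal heat noise, the standard 1 + 19×2 μl protocol at 20 °C):

```r
e <- gen_itc_titration(kd = 10, n_sites = 1, dH = -5,
                       cfg = generator_config(seed = 1, noise_sd = 0.2))
fit_single_site(e)
#> Single-site ITC fit
#>   KD = 9.789 +/- 0.29 uM   N = 0.9992 +/- 0.0031   dH = -4.986 +/- 0.022 kcal/mol
#>   dG = -6.719 kcal/mol   -TdS = -1.733 kcal/mol   (T = 293.15 K)
```

Umbrella-sampling bookkeeping for the canonical dissociation schedule:

```r
centers <- build_window_schedule(claw_window_segments())
glance(schedule_manifest(centers, time_per_window_ns = 100))
#> # A tibble: 1 × 3
#>   n_windows total_time_ns spring_kJ_mol_nm2
#>       <int>         <dbl>             <dbl>
#> 1        33          3300             10000
```

`run_pipeline(pipeline_config("out"))` chains all four stages —
simulate, fit/solve, predict, report — writing every artifact plus a
reproducibility manifest; a rerun with the same configuration is
byte-identical.

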