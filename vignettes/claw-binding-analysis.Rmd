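---
title: "Models and methods behind clawbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clawbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clawbind)
```

`clawbind` analyses competitive phosphopeptide binding to the FIP200
claw domain. This vignette is the package's account of its science: the
models, their assumptions, the tunable parameters, what the synthetic
generators do and do not emulate, and the numerical and design choices a
maintainer would want spelled out.

## The three-state competition model

A claw domain in solution with two peptides is modelled as a three-state
system: free domain, domain bound to a reporter peptide (a
phosphorylated autophagy-receptor FIR peptide), and domain bound to a
competitor (a TNIP1 FIR peptide). With association rates $u_1, u_2$ and
dissociation rates $w_1, w_2$, detailed balance gives the stationary
occupancies

$$P_0 = \frac{w_1 w_2}{Z},\quad P_1 = \frac{u_1 w_2}{Z},\quad
  P_2 = \frac{u_2 w_1}{Z},\qquad Z = w_1 w_2 + u_1 w_2 + u_2 w_1 .$$

`p1_stationary()` implements this as the default (`detailed_balance`)
variant, verified in the tests against a brute-force null-space solution
of the explicit rate matrix. A second, `printed`, variant with $u_2 w_2$
as the third denominator term is kept for comparison; in that form $w_2$
cancels algebraically, so the competitor's dissociation rate — the very
quantity a dissociation-barrier difference modulates — drops out. That
algebraic fact (asserted as a test property) is why `detailed_balance`
is the default: it is the variant whose concentration dependence reduces
to the displacement isotherms below.

Assuming diffusion-controlled association ($u_2$ proportional to
competitor concentration, the constant absorbed into $a_0$) and
transition-state-theory dissociation rates, the remaining reporter
fraction is

$$y_1 = \frac{1}{1 + a_0 [\mathrm{T}]}, \qquad
  y_2 = \frac{1}{1 + a_0\, e^{|\Delta E|/k_B T} [\mathrm{T}]},$$

for the unmodified and phosphorylated competitor respectively, with
$a_0$ in μM⁻¹ and $\Delta E$ the difference in dissociation activation
barrier (kJ/mol). **Sign convention:** as typeset in the source model
the Boltzmann exponent is $-\Delta E / k_B T$, under which a positive
barrier difference would *weaken* competition — the opposite of the
biological conclusion that phosphorylation makes TNIP1 an effective
competitor. The package therefore defaults to the `enhancing` convention
($e^{+|\Delta E|/k_B T}$) and retains `printed` behind a flag; every
result object records which convention produced it. Whether the reported
barrier difference is barrier(unmodified) − barrier(phospho) or the
reverse cannot be settled from the model definition alone, which is why
both conventions ship rather than a silent guess.

`fit_a0()` estimates $a_0$ by damped Gauss–Newton on $\log a_0$
(positivity by construction, quadratic convergence to machine precision,
matching the closed form $(1/y - 1)/c$ in the exactly identified case),
with a curvature-based standard error. Useful invariants, all tested:
$y(a_0, c) = y(a_0 s, c/s)$; with `enhancing` convention and
$\Delta E > 0$, $y_2 \le y_1$ everywhere; and the half-displacement
concentration shifts by exactly $e^{-|\Delta E|/k_B T}$.

## Single-site ITC isotherm

`isotherm_heats()` is the standard one-site total-heat model: after
injection $i$ the cell holds macromolecule $M_i$ and titrant $X_i$
(each injection of volume $dV$ dilutes by $1 - dV/V_0$ and delivers
syringe titrant), the bound concentration is the $[0, \min(nM, X)]$ root
of the saturation quadratic, the cell heat content is
$Q_i = \Delta H \cdot [MX]_i \cdot V_0$, and the observed heat applies
the perfusion correction
$\Delta Q_i = Q_i - Q_{i-1} + (dV_i/V_0)(Q_i + Q_{i-1})/2$ for the
displaced volume. Defaults mirror a claw-domain protocol: 0.25 mM cell,
4 mM syringe, 200 μl cell, 293.15 K, one 1 μl priming injection plus
19 × 2 μl.

`fit_single_site()` minimises weighted squared residuals over
$(K_D, N, \Delta H)$ with `minpack.lm`, $K_D$ and $N$ on the log scale.
Choices worth recording:

* **Priming injection** is down-weighted to zero by default (its
  effective volume is unreliable on perfusion instruments);
  configurable via `weights`.
* **Multi-start ladder:** $K_D \in \{0.1, 1, 10, 100, 1000\}$ μM crossed
  with $N \in \{0.5, 1, 2\}$, tried in deterministic order, best
  residual wins; an explicit error (never a silent fallback) if no start
  converges.
* **No-binding rule:** the isotherm is compared with a constant-offset
  model by an F test; `no_binding` is set when the fit is not better at
  level 0.01 (configurable) or the signal is numerically flat. The
  threshold is a decision rule of this package — "no detectable
  binding" needs *some* criterion and the instrument software's is not
  published.
* **Constants:** $R = 1.98720425864083\times10^{-3}$ kcal mol⁻¹ K⁻¹ and
  $k_B = 0.0083144626$ kJ mol⁻¹ K⁻¹ live in one place
  (`claw_constants`), so $\Delta G = RT \ln K_D$ (molar scale) and
  $\Delta G = \Delta H + (-T\Delta S)$ hold to $10^{-9}$ kcal/mol by
  construction.

Round-trip behaviour: zero-noise generate→fit recovers parameters to
better than $10^{-6}$ relative over Wiseman c-values 1–1000 (tested at
c = 1, 10, 100, 1000); at 0.2 μcal noise the median $K_D$ over 50 seeds
is within 10% of truth.

## Umbrella-sampling post-processing

The reaction coordinate is the domain–peptide centre-of-mass distance in
Å. `build_window_schedule()` lays restraint centres on half-open
segments $[\mathrm{start}, \mathrm{stop})$: a shared boundary belongs to
the segment that starts there and the final stop is excluded. For the
canonical dissociation layout (0.5 Å spacing over 15–25 Å, 1.0 Å over
25–38 Å) this gives exactly 33 windows — the inclusive-inclusive
convention would give 34, and since the literature states the count but
not the centre list, the convention is recorded on the result rather
than assumed silently. At 100 ns per window the manifest books 3300 ns.

**Units.** Spring constants are accepted in kJ mol⁻¹ nm⁻² (the MD
convention, default 10,000) and converted internally with the pinned
factor 10 Å/nm, so the bias at $x$ Å about centre $c$ is
$\tfrac12 k ((x - c)/10)^2$ kJ/mol. The conversion is unit-tested
(a 2000 kJ mol⁻¹ nm⁻² restraint at 300 K must produce sample scatter of
$\sigma = \sqrt{k_B T / k}$ = 0.353 Å).

**WHAM.** `wham_solve()` uses binned WHAM with the bias evaluated at bin
centres (default 200 bins over the sampled range). Rather than the
classical fixed-point sweep, the self-consistent equations are solved by
damped Newton iteration on the window free energies $g_i = F_i/k_BT$
(gauge $g_1 = 0$), maximising the equivalent concave log-likelihood
$\sum_i N_i g_i - \sum_x M_x \log \sum_i N_i e^{g_i} e^{-b_i(x)/k_BT}$.
The fixed point is identical; the difference is purely numerical — with
stiff restraints the fixed-point update needs over $10^5$ sweeps to
reach the convergence tolerance (max $|\Delta F|$ < $10^{-7}\,k_BT$)
while Newton needs about five. Empty bins are reported as `NA`, never
interpolated; disconnected window coverage (an empty gap wider than
twice the widest window's thermal width) raises a diagnostic naming the
gap; non-convergence is an error carrying the last residual.

**Barriers and errors.** `dissociation_barrier()` returns
mean(plateau) − min(bound region), the transition-state-theory quantity;
the plateau range is a required user input because nothing in a profile
marks it unambiguously. A profile whose plateau lies below everything
else has no bound state and is flagged. `delta_barrier()` reports
barrier(b) − barrier(a) with the operand order recorded, and refuses to
mix profiles computed at different $k_BT$. `bootstrap_pmf()` resamples
each window's samples with replacement, re-solves WHAM per replicate
(warm-started), and reports per-bin and per-barrier standard deviations;
more than 20% failed replicates is an error.

## What the generators emulate — and what they do not

All generators take a `generator_config(seed, noise_sd,
replicate_count)`; identical configurations give bit-identical output,
and the caller's RNG stream is restored afterwards.

* `gen_itc_titration()` adds i.i.d. Gaussian noise to the exact forward
  isotherm. Real baselines drift and injection heats are integrals over
  peak shapes; none of that is modelled, so passing recovery tests show
  fitter correctness, not robustness to instrument artefacts. The noise
  level is a config choice (no published value exists for it);
  0.2 μcal is a plausible scale for a low-volume calorimeter.
* `gen_umbrella_samples()` draws i.i.d. samples from the exactly
  normalised biased density on the profile grid by inverse-CDF (a bin is
  drawn with the density's weight, the value placed uniformly within the
  bin). This is deterministic given the seed and adequate in 1-D; it
  deliberately matches the binned likelihood WHAM uses, so
  solver-vs-truth comparisons carry no discretisation bias. It does
  *not* emulate MD autocorrelation: 5000 generated samples are 5000
  independent observations, which real trajectories only approach after
  subsampling.
* The canonical ground truth, `pmf_dissociation_spec()`, is a
  binding-funnel profile — Gaussian well of depth 9.4 kJ/mol (the scale
  of a phosphorylation-induced barrier shift) at 17 Å, harmonic inner
  wall, flat plateau — with the planted depth recorded in the object.
* `gen_competition_series()` adds truncated Gaussian noise kept within
  (0, 1], since fractions are physical proportions.
* `gen_toy_complex()` builds an 8-residue domain strand paired with a
  5-residue phosphopeptide (SEP at position 123) with planted geometry:
  five backbone N···O hydrogen bonds at 2.90 Å, one Lys NZ–phosphate
  O1P pair at 3.00 Å, one side-chain C–C contact at 4.00 Å, and all
  other cross-group pairs beyond the default cutoffs. It is a geometric
  fixture, not a physical model: bond lengths are approximate and there
  is no sterics, so it validates detectors, not force fields.

### A note on restraint stiffness and sampling

With the 10,000 kJ mol⁻¹ nm⁻² restraint, window scatter is
$\sigma \approx 0.16$ Å while spacings are 0.5–1.0 Å, i.e. adjacent
windows sit 3–6 σ apart. Histogram overlap is then thin, and at desk
scale (5000 independent samples per window) the reconstructed profile
carries window-offset noise of order 1–3 kJ/mol that only shrinks with
roughly the square root of sampling — hence campaigns of 100 ns per
window at this stiffness. The bootstrap quantifies exactly this error
(the recovered barrier brackets the planted one within two bootstrap
standard deviations), and the package's solver-accuracy tests instead
use restraints satisfying the standard overlap rule
($\sigma \approx$ half the spacing, e.g. 1000–2000 kJ mol⁻¹ nm⁻²),
where 5000 samples per window recover the profile to an RMS deviation
below 0.2 kJ/mol.

## Structural interface analysis

PDB parsing and writing delegate to `bio3d`; author residue numbering
and insertion codes are preserved, HETATM phosphoserine is kept as a
peptide residue, and alternate locations resolve to the
highest-occupancy conformer (ties: alphabetically first altloc).

* **Superposition** is the Kabsch SVD solution with a proper rotation
  enforced; collinear inputs (second singular value zero) are rejected.
  The test suite checks it against an independent quaternion-eigenvalue
  oracle to $10^{-9}$ Å on random point sets.
* **RMSF** superposes every frame on a chosen atom subset (onto the
  first frame, or iteratively onto the ensemble mean) before computing
  $\sqrt{\langle |r_i - \bar r_i|^2 \rangle}$.
* **Hydrogen bonds** use a heavy-atom criterion suited to
  hydrogen-free crystal structures: N/O within 3.5 Å of N/O across the
  groups, different residues, and a donor–antecedent angle ≥ 90° on at
  least one side (the antecedent is the nearest covalently bonded heavy
  atom). Cutoffs are arguments, not constants, because distances are
  published but criteria rarely are. Categories follow atom names
  (backbone = N, CA, C, O).
* **Contacts:** hydrophobic = side-chain carbon pairs within 4.5 Å;
  charge–charge = charged-group atoms (Lys NZ, Arg NH1/NH2/NE, Asp OD,
  Glu OE, phosphate O1P/O2P/O3P or OP1–OP3) within 4.0 Å. Phosphate
  oxygens count as both acceptors and charged atoms — phosphoserine
  recognition is the point of the analysis.
* Pair tables are canonically ordered, so results are invariant under
  swapping the groups and under rigid motion (both tested with random
  rotations), and `interface_report()` output is byte-stable.

No symmetry-mate generation is performed (the comparisons of interest
are within one asymmetric unit) and mmCIF is out of scope.

## Problem sizes and reproducibility

The default pipeline (`run_pipeline()`) and the test suite are sized for
interactive use: 400–5000 samples per umbrella window, 8–50 bootstrap
replicates, 50-seed simulation studies for the fitters. These sizes are
the package's choice of a desk-scale experiment; the statistical
behaviour at campaign scale follows the square-root law quantified by
the bootstrap. Every random step flows through one seeded interface, a
pipeline rerun is byte-identical, and each run directory contains a
manifest recording the configuration, seed and package version.

## Known limitations

* The competition model is stationary; no time-dependent kinetics, and
  ΔE is an input (from profiles or literature), never estimated from
  competition data.
* WHAM is 1-D, without autocorrelation-based effective-sample-size
  correction (generated samples are independent by construction).
* The ITC module fits integrated per-injection heats only; no
  peak-shape processing, no multi-site or competitive-ITC models.
* The toy complex and the synthetic dimer used in the superposition
  tests are labelled synthetic stand-ins; comparisons against deposited
  crystal structures require fetching those files and are not part of
  the offline test suite.
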