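---
title: "Co-receptor-modulated kinetic proofreading: model and methods"
author: "tcrdegen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-receptor-modulated kinetic proofreading: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrdegen)
```

# The model

`tcrdegen` models antigen recognition by CD8⁺ T cells at the level of
the molecular kinetics in the T-cell:APC contact area. A pMHCI ligand
can be free, bound to a TCR, bound to a CD8 co-receptor, or bound to
both; this four-state binding scheme is assumed to be at equilibrium
throughout a conjugation. The functional output is the rate at which
engaged TCR/CD3 complexes attain signalosome status ("triggering"),
which requires completing a chain of n phosphorylation-like
modifications before the TCR/pMHCI bond dissociates — the kinetic
proofreading principle. CD8 modulates this output in three documented
ways: it enhances the TCR/pMHCI on-rate (factor γ_on ≥ 1), stabilises
the bond (off-rate factor γ_off ≤ 1), and accelerates progression
through the modification chain (threshold factor γ_R ≤ 1), the latter
because CD8 is associated with the kinase p56^lck.

## Equilibrium layer

Mass-action equilibrium plus conservation of total pMHCI, CD8 and TCR
densities yields, in scaled variables (x = X/K₃, r = R/K₁, and
likewise for the totals; m_T = M_T/K₁; κ = K₁/K₃),

$$x_T = x + \kappa m_T \frac{x + x r/\gamma_{kin}}{D},\qquad
  r_T = r + m_T \frac{r + x r/\gamma_{kin}}{D},\qquad
  D = 1 + x + r + \frac{x r}{\gamma_{kin}},$$

where γ_kin = γ_off/γ_on = K₄/K₁ = K₂/K₃ collects the affinity effect
of CD8. The pMHCI occupancy fractions are 1/D (free), ε = r/D
(TCR-bound), x/D (CD8-bound) and ζ = (x r/γ_kin)/D (ternary); they sum
to one identically, which the solver verifies to 10⁻¹⁰ on random
parameter draws. Detailed balance closes the binding cycle, forcing
K₁K₂ = K₃K₄; the dimensional constructor derives the dependent rate
λ₋₂ from this identity rather than accepting an inconsistent value.

By construction the equilibrium depends only on (γ_kin, κ, m_T, x_T,
r_T). This matters for the statistical layer: the ligand's off-rate α
does not enter, so one equilibrium solve serves an entire ligand
ensemble.

## Triggering layer

Bound states subdivide by the number i of completed modifications,
giving two coupled lanes (CD8 unbound / bound) of an absorbing Markov
chain that is *not* assumed to be at equilibrium: every encounter
starts at i = 0 (the complex is assumed to reset fully between
encounters). Per state, three exponential events compete; in units of
the basal rate λ = 1/T_R the rates are n, α, νx in the unbound lane
and n/γ_R, γ_off α, δ in the bound lane. The factor n in the forward
rate is a scaling device so that the mean time to traverse the whole
chain equals T_R. First-step analysis gives the success probabilities
P_i⁰, P_i\*, solved by backward recursion from the boundary condition
P_n⁰ = P_n\* = 1. The scaled functional sensitivity of a ligand is
w = α(ε P₀⁰ + ζ γ_off P₀\*); its dimensional counterpart is
W = M_R λ₋₁ P₀⁰ + M_XR λ₋₄ P₀\*, equal by detailed balance to the
association-side form M λ₁ P₀⁰ + M_X λ₄ P₀\* (both are computed in the
dimensional layer and checked to 10⁻¹⁰ against each other).

## Statistical layer

The dissociation energy barrier of a TCR/ligand pair is taken Gaussian
(a sum of many interface contributions), so by Arrhenius theory the
scaled off-rate α is log-normal: ln α ~ N(μ, σ²) with μ > 0, the
positive mean encoding that most ligands unbind well before the
proofreading chain completes. Degeneracy is the exceedance curve
P(w > ω) over this ensemble; a cellular activation model
(Z · T_I · w > W_act) reduces per ligand to a critical ω_crit, and
the probability P(w > ω_crit) as a function of CD8 density defines the
cell's operating band (defaults 10⁻⁸–10⁻⁵, reflecting
repertoire-size estimates).

One deliberate interpretation: the ensemble parameters "mean 2, SD
0.2" (and "mean 5, SD 0.5" for the variant panel) are read as the mean
and SD of ln α — i.e. of the underlying Gaussian — not of α itself.
The energy model is defined on the log scale, and an α-scale mean of 2
with these spreads would contradict the premise that typical dwell
times fall short of the triggering threshold.

# Parameters

| parameter | meaning | default(s) used here |
|---|---|---|
| m_T, x_T, r_T | scaled total pMHCI / CD8 / TCR densities | 10 / preset-specific / 10 |
| α | scaled TCR/pMHCI off-rate (the ligand axis) | ensemble-drawn |
| δ | scaled pMHCI/CD8 off-rate with TCR bound | 0.2–300 by regime |
| ν | scaled kinetic effect of pMHCI/CD8 association | 0.05–300 by regime |
| κ | K₁/K₃ | 1–5 |
| γ_off, γ_kin, γ_R | CD8 modulation factors, each in (0, 1] | 0.5 / 0.5 / 0.2–0.5 |
| n | proofreading steps | 100 |

T_R, the triggering threshold absorbed into the scaling, is
physiologically 5–15 s (default 10 s in the dimensional layer);
γ_on defaults to 1.5, reflecting the reported ~50% on-rate
enhancement by CD8, but any value ≥ 1 is accepted.

The five presets (`preset_names()`) freeze the parameter sets for the
regimes of interest — `ligand_focusing` (δ = 300, ν = 0.5, κ = 5,
γ_R = 0.3, with the CD8-density dip near x_T ≈ 50), `weak_coupling`
(δ = 2.5, ν = 0.05), `strong_coupling` (δ = 3, ν = 300,
γ_kin = 0.05, γ_off = 0.2), and the variant-panel pair `mutant_panel`
(δ = 0.2, ν = 0.05, γ_R = 0.2) and `mutant_panel_fast` (ν = 10). A
checksum-style test pins these values.

## Thermodynamic consistency as a diagnostic, not a constraint

The scalings imply the identity δ/ν = K₂/K₃ = γ_kin, yet the regimes
above deliberately violate it (e.g. δ/ν = 600 against γ_kin = 0.5 in
`ligand_focusing`): δ, ν and γ_kin are treated as independent inputs
because the interesting kinetic regimes are defined directly in terms
of them. The package keeps the identity visible rather than enforced:
`check_consistency()` reports the ratio and warns on departure, and
`print.scaled_parameters` notes it. Similarly γ_kin > γ_off is
accepted with a warning (it merely encodes γ_on < 1, a CD8-reduced
on-rate).

## CD8-affinity variants

Solution K_D values for the HLA A\*0201 CD8-binding-site variants
(A245V 498 µM, wild-type 137.1 µM, Q115E 97.94 µM, A2/α3kb 10.87 µM)
are mapped to the membrane environment by assuming a common
confinement length, so only the *ratio* ρ = K_D/K_D(wild-type) is ever
needed: K₃ → ρK₃, hence κ → κ/ρ, x_T → x_T/ρ, ν → νρ, all other
parameters untouched. The confinement length itself never enters
numerically and is not a parameter. `apply_mutant` implements this
rescaling and is a group action in ρ (tested). In the `mutant_panel`
regime the strongest CD8 binder (A2/α3kb) dominates the degeneracy
curves pointwise; with a strong recruitment effect (ν = 10) the tail
ordering reverses.

# Numerical choices

* **Equilibrium solver.** Damped Newton on (x, r) with the analytic
  Jacobian, iterates clamped to [0, x_T] × [0, r_T]; absolute residual
  tolerance 10⁻¹² (downstream tail probabilities at the 10⁻⁸ scale
  need tight equilibria), at most 200 iterations. On the rare failure
  the solver falls back to a nested bracketed root search (inner r at
  fixed x, outer x), which cannot fail: each residual is monotone in
  its own variable and changes sign across the box. x_T = 0 and
  r_T = 0 are solved exactly as single-species quadratics, not as
  small-number limits. The test oracle is an independent pure
  bisection, agreeing to 10⁻⁸.
* **Backward recursion, not matrix powers.** The success chain is
  evaluated by n matrix–vector products on quantities in [0, 1] —
  stable and O(n). When the unbound lane cannot switch (νx = 0) the
  closed form (Pa⁰)ⁿ is evaluated in log space to avoid underflow at
  large n or α; the n = 10⁴ single-lane limit reproduces e^(−α) to
  10⁻³ as the classical proofreading chain requires.
* **Super-level integration.** w(α) is not assumed unimodal: the
  semi-analytic degeneracy method scans a 400-point log-grid of α
  spanning ±8σ of the ensemble (the excluded tails carry ~10⁻¹⁵ of
  the mass), brackets every crossing of w(α) = ω, refines each by a
  bracketed root search to relative 10⁻¹⁰, and sums exact log-normal
  masses of the active intervals. Robustness was preferred over
  cleverness here; the grid evaluation is vectorised over α so the
  whole curve costs a few milliseconds.
* **Stochastic oracle.** The event-driven simulation uses the
  embedded jump chain (categorical draws proportional to rates)
  rather than explicit exponential clocks — distributionally
  identical for absorption probabilities and much cheaper. Trials
  advance in lock-step vectorised rounds; seeds are applied in a
  scope that restores the caller's RNG stream.
* **Statistical test calibration.** Monte Carlo consistency checks
  compare against binomial standard errors computed from the
  reference probability. When one fixed-seed MC curve is checked at
  many thresholds simultaneously, the per-point 3-SE criterion is
  Bonferroni-adjusted so the family-wise false-alarm rate matches a
  single 3-SE comparison; otherwise an exact model would be flagged
  by ordinary sampling noise at a rate growing with the number of
  thresholds.

# What the generator emulates — and what it does not

The ligand ensemble varies *only* the off-rate α, per the energy
model; on-rates, CD8 kinetics and densities are held at their set
values. Real peptide libraries also perturb MHC anchoring (changing
presentation level Z), can violate the common-confinement-length
assumption across mutants, and couple contacted and non-contacted
residues — the ligand-universe count 20^m·C(n−a, m)
(`ligand_universe_size`) treats the m contacted residues as an
independent tape, which is an acknowledged oversimplification of
CDR3 contact physics. Passing tests therefore certify the internal
consistency of the kinetics and statistics, not the biological
accuracy of any particular parameter set. Also out of scope by
design: spatial synapse dynamics and kinase/phosphatase
micro-domains, downstream signalling (ERK, NF-κB, NFAT), serial
triggering and rebinding, and pre-equilibrium binding transients;
partial phosphorylation is assumed to reset fully between encounters.

# Problem sizes in the test suite

The suite (and the oracle cross-checks) runs at the sizes the science
needs rather than the largest feasible: 500 random chains at
n ∈ {1, 10, 100, 200} for the recursion–vs–linear-solve equivalence
(10⁻¹²), 10⁵-trial simulations against exact absorption probabilities,
1000 random equilibrium draws for conservation (10⁻¹⁰), and 10⁵-sample
Monte Carlo against the semi-analytic curves. The whole suite
completes in well under a minute.

# Known limitations

* The semi-analytic method is exact only up to the 400-point bracket
  scan; a super-level component narrower than the grid spacing in
  log-α would be missed. At the smooth, at-most-bimodal w(α) profiles
  arising here this has never been observed.
* `ligand_universe_size` returns exact doubles; counts beyond ~20²⁰
  would lose integer exactness (far outside the biological range of
  m ≤ 7 for 9-mers).
* The dimensional layer validates but does not fit: rate constants
  are taken as given, there is no inference from SPR or functional
  data, and (μ, σ) of the ensemble are inputs, not estimates.
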