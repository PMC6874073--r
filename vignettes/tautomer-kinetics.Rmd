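---
title: "Proton-transfer tautomerization kinetics and QTAIM contact energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proton-transfer tautomerization kinetics and QTAIM contact energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tautkin)
library(dplyr)
```

## The problem

An intramolecular proton-transfer tautomerization is a unimolecular,
reversible two-state interconversion: a reactant minimum, a product minimum,
and one first-order saddle point between them, identified by its single
imaginary vibrational frequency. Electronic-structure calculations deliver
the Gibbs energetics (forward activation barrier ΔΔG_TS and reaction energy
ΔG, both in kcal·mol⁻¹), the magnitude ν̃_i of the imaginary wavenumber at
the transition state, and — via an atoms-in-molecules analysis — the
(3,−1) bond-critical-point descriptors of every intramolecular specific
contact. This package owns everything downstream of those numbers. The
shipped fixtures transcribe the reference network for the quercetin
molecule: thirteen proton-transfer reactions among its hydroxyl, CH and
carbonyl groups, and the contact records of their stationary points.

## Kinetic model

Rates come from classical transition-state theory with a multiplicative
tunneling correction:

$$k_{f,r} = \Gamma\,\frac{k_B T}{h}\,
  e^{-\Delta\Delta G_{f,r}/RT},\qquad
  \Gamma = 1 + \frac{1}{24}\left(\frac{h c \tilde\nu_i}{k_B T}\right)^2 .$$

The Wigner form of Γ is the leading-order parabolic-barrier correction. It
assumes tunneling is a modest multiplicative effect through the barrier top;
for proton transfers with ν̃_i around 1000–2100 cm⁻¹ at room temperature it
contributes a factor of roughly 2–5.5. It is *not* adequate when tunneling
dominates (deep, thin barriers at low temperature) — that regime calls for
Eckart or small-curvature corrections, which are out of scope here.

Both directions share one Γ (the saddle is the same), so the rate ratio
collapses to the thermodynamic equilibrium constant exactly:
$k_f/k_r = e^{-\Delta G/RT}$. This detailed-balance identity is
property-tested to a relative 1e-10.

Derived quantities:

- reverse barrier, by bookkeeping: ΔΔG_r = ΔΔG_TS − ΔG. The reaction energy
  is stored product-minus-reactant, so an endothermic step has positive ΔG.
  The reference table's own arithmetic fixes this sign convention (its
  footnote wording is ambiguous; the printed reverse-barrier column equals
  ΔΔG_TS − ΔG on all thirteen rows only with this reading, which the tests
  assert at printed precision).
- lifetime of the product tautomer, τ = 1/k_r;
- approach to equilibrium, τ_99.9% = ln(10³)/(k_f + k_r) — the relaxation
  rate of a reversible two-state system is the *sum* of the rate constants.

### Stability classification

Three classes, in order of precedence:

1. `barrierless_reverse` when ΔΔG_r ≤ 0. Negative reverse barriers are
   computed, not rejected: the reference network contains one
   (ΔΔG_r = −1.20 kcal·mol⁻¹), and rejecting it would misrepresent the
   chemistry. A Gibbs saddle below the Gibbs product is a real artifact of
   free-energy surfaces near flat minima.
2. `dynamically_unstable` when the caller supplies a lowest torsional
   wavenumber and τ < 1/(c·ν̃_torsion): the minimum decays faster than its
   slowest vibration can complete one period, so it cannot sustain
   vibrational structure.
3. `stable` otherwise.

When no torsional mode is supplied the dynamic test never fires. The
reference source does not print its torsional wavenumbers, and inventing a
default threshold would silently reclassify borderline tautomers; the
parameter is therefore explicit and optional.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `temperature` | 298.15 | K | "normal conditions"; overridable per call and per reaction row |
| physical constants | CODATA 2018 | SI | injectable via `kin_constants()`; the calorie is thermochemical (4.184 J) |
| `scale_factor` | 0.9668 | — | the harmonic-frequency scale factor for B3LYP/6-311++G(d,p) |
| `use_scaled_nu` | `FALSE` | — | whether Γ sees the scaled wavenumber; the reference does not state which it used, so the choice is exposed, not guessed |
| `tolerance_rel_rate` | 0.15 | relative | see "Reproduction tolerances" |
| `tolerance_energy` | 0.13 | kcal·mol⁻¹ | half-ulp of a 3-decimal ρ through the steeper linear slope (248.501·0.0005 ≈ 0.124) |

With the default constants, k_BT/h = 6.2124×10¹² s⁻¹ and
k_BT/(hc) = 207.22 cm⁻¹ at 298.15 K.

### Reproduction tolerances

The reference rates were printed to 3 significant figures from barriers
printed to 2 decimals, under an unstated constants convention. Under the
CODATA defaults the thirteen reverse rates reproduce within 12.8 % relative
(worst rows are the high-Γ ones, suggesting the source's Γ input or barrier
digits differed slightly); 15 % is therefore the honest reproduction
tolerance, and forward rates spanning 10⁻⁵⁸–10³ s⁻¹ are compared by base-10
exponent. The printed τ and τ_99.9% columns are checked as *identities* of
the printed rate columns at a relative 5×10⁻³ — the half-ulp of a
3-significant-figure input — because the source evidently computed them from
unrounded rates (one row is off by 0.4 % from the rounded-input value, which
is within that propagation but outside strict 3-digit equality).

## QTAIM contact energetics

A contact record is accepted as a genuine attractive interaction iff ρ > 0
and Δρ > 0 at its (3,−1) BCP (the BCP and bond path exist by virtue of the
record existing). Energies then dispatch by contact class:

- **OH⋯O** (classical H-bond): E = −3.09 + 239·ρ (NBH).
- **CH⋯O-type, strong** (including the methylene-like CH₂⋯O bonds formed at
  proton-transfer transition states): E = 248.501·ρ − 0.367 (BYH), applied
  when that estimate itself exceeds 10 kcal·mol⁻¹. The literature states the
  threshold but not how to evaluate "strong" before knowing the energy; using
  the BYH estimate against its own threshold (equivalently
  ρ ≥ 0.04173 a.u.) resolves the circularity deterministically, and the
  dispatch is property-tested never to emit BYH at ≤ 10 kcal·mol⁻¹.
- **everything else valid** (weak CH⋯O, OH⋯C, O⋯O and C⋯O van der Waals):
  E = ½|V(r)| (EML), converted from atomic units at 627.5095 kcal·mol⁻¹ per
  hartree. V(r) is negative by definition and bond energies are reported as
  positive magnitudes, hence the absolute value. When a record carries no
  V(r) — the reference table prints none — the row comes back as an explicit
  unscorable EML outcome instead of a number.

The BYH formula is implemented as the *linear* form 248.501·ρ − 0.367. The
typeset source is ambiguous, but the linear form reproduces all six
double-starred reference energies exactly at printed precision
(ρ = 0.116 → 28.46, 0.123 → 30.20, 0.128 → 31.44, 0.110 → 26.97,
0.111 → 27.22, 0.112 → 27.47), which the acceptance tests assert.

### The flagged anomaly

One reference row prints 6.78 kcal·mol⁻¹ for an OH⋯O contact at ρ = 0.026
a.u. (O3H⋯O4 of the 5↔5\*_C8H2 transition state), where the formula gives
3.12 — as it does in the analogous rows of the other conformers. The
fixture stores the printed value *as printed*, flagged
`flag_inconsistent`; the comparison harness reports it as an anomaly rather
than a failure, and the tests require it to be flagged, never silently
matched or "corrected".

## Data model and reference hygiene

A `reaction_set` bundles reactions, stationary points and contacts as
tibbles, plus a `reference` block holding printed outputs (rates, times,
contact energies) transcribed from the source. Compute paths never read the
reference block — `compute_kinetics()` and `score_contacts()` return
identical results with it stripped, which a test enforces. This prevents
the reproduction tests from ever becoming self-fulfilling.

Interchange is JSON (one nested document) or TSV (one reactions table, one
contacts table under a common stem; structure-level columns repeat on each
contact row, and a structure with no contacts keeps one blank-contact row so
round-trips are lossless). Units are declared in-file and the readers
reject anything but kcal·mol⁻¹ / cm⁻¹ / a.u.; both dialects round-trip
field-for-field, property-tested on random synthetic sets. Reaction names
keep the display form with arrow and asterisks ("1↔1\*_O1H") alongside an
ASCII alias ("1__1s_O1H") for file handling.

## The synthetic generator

`generate_reactions(synth_spec(...))` emulates the *marginal ranges* of the
reference tables: forward barriers uniform on [0.9, 96.5] kcal·mol⁻¹,
imaginary wavenumbers on [800, 2200] cm⁻¹, reaction energies a uniform
fraction [0, 0.99] of the barrier, and class-conditional BCP densities
(OH⋯O on [0.020, 0.060] a.u., strong CH₂⋯O on [0.100, 0.130], weak CH⋯O /
OH⋯C on [0.010, 0.022], van der Waals on [0.010, 0.030]). Sampling is
uniform within intervals because the reference gives ranges, not
distributions — no distributional shape is invented. Gaussian noise appears
only in the explicit perturbation helper. Two switches produce structured
edge cases: an exothermic-reverse probability (reaction energy drawn above
the barrier, guaranteeing a negative reverse barrier) and a contaminant
fraction (contacts with Δρ ≤ 0, for validator tests).

Determinism: one global seed, with per-record substreams derived by counter
(`seed + i`), so a record's draws never depend on how many records precede
it; the tests check that the first three reactions of a 3-set and a 6-set
with the same seed coincide.

What the generator does **not** emulate: correlations between barrier and
wavenumber, geometric realism of contact distances and angles, V(r) values,
or any molecular structure. Passing tests on synthetic sets therefore
demonstrate the algebra, bookkeeping, I/O and classification logic — not
that the package can detect problems peculiar to real electronic-structure
output (bad saddle connectivity, spin contamination, basis-set artifacts),
which are upstream of its scope.

## Numerical choices

- Rate/barrier algebra is done in kcal·mol⁻¹ with RT ≈ 0.5925 kcal·mol⁻¹ at
  298.15 K; exponents reach exp(−163) ≈ 10⁻⁷¹, comfortably inside double
  range, so no log-space bookkeeping is needed.
- `wigner_correction(0)` is exactly 1; Γ ≥ 1 always.
- Ranking sorts by forward ΔΔG_TS (convention-independent), ties broken by
  name for byte-reproducible output; emitted tables default to 3
  significant figures, matching the reference's printed precision, with a
  `precision` argument for more.
- Degenerate inputs: empty reaction sets flow through the whole pipeline
  (empty tables, `NA` overall pass); zero rates are rejected where a
  reciprocal is taken; invalid contacts are flagged and carried, never
  dropped, so row order and counts are stable.
- Barrier inversion −RT·ln(k/(Γ·k_BT/h)) recovers generator barriers to
  1e-10 kcal·mol⁻¹, the round-trip accuracy of `exp`/`log` at these
  magnitudes.

## Problem sizes

The test suite runs the full 13-reaction and 103-contact fixtures
end-to-end, plus synthetic sets of 3–25 reactions and property loops of
20–200 random cases under fixed seeds — the whole suite completes in
seconds, which is the natural scale of this analysis (the expensive part of
a tautomerism study is the electronic structure, which is not recomputed
here).

## Limitations

- Wigner tunneling only; no Eckart, small-curvature or variational TST.
- Gas-phase, single-temperature, two-state kinetics; no master equation
  over the full tautomer network and no solvent corrections (polar media
  are expected to lower these barriers, but that is upstream input, not a
  correction this package can apply).
- EML scoring requires V(r); records without it are honestly unscorable.
- The empirical linear formulas carry their own literature uncertainty
  (±0.13 kcal·mol⁻¹ here reflects only ρ rounding, not model error).
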