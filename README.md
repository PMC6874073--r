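# tautkin

Post-quantum-chemistry analysis of intramolecular proton-transfer
tautomerization. Quantum-chemical calculations on a tautomerizing molecule
(the shipped reference network is the flavonoid quercetin,
3,3′,4′,5,7-pentahydroxyflavone) end with a table of stationary points:
Gibbs activation barriers, reaction free energies, one imaginary wavenumber
per transition state, and bond-critical-point (BCP) descriptors of the
intramolecular contacts. `tautkin` turns those numbers into the quantities a
tautomerism study actually reports, for computational chemists who have the
electronic-structure output in hand and want the kinetics and H-bond
energetics done reproducibly:

- **Rates.** Eyring transition-state-theory rate constants with the Wigner
  tunneling correction,

  k_f,r = Γ · (k_B T / h) · exp(−ΔΔG_f,r / RT),  Γ = 1 + (h c ν̃_i / k_B T)² / 24,

  with the reverse barrier derived by the bookkeeping identity
  ΔΔG_r = ΔΔG_TS − ΔG.
- **Times.** Tautomer lifetime τ = 1/k_r and the time to reach 99.9 % of the
  equilibrium composition, τ_99.9% = ln(10³)/(k_f + k_r).
- **Stability.** A three-way classification of each product: stable;
  *dynamically unstable* (lifetime shorter than the period of the lowest
  torsional mode); *barrierless reverse* (negative reverse barrier).
- **Contact energies.** Empirical BCP energy formulas with the field's
  dispatch rules: Nikolaienko–Bulavin–Hovorun E = −3.09 + 239·ρ for classical
  OH⋯O bonds, Brovarets'–Yurenko–Hovorun E = 248.501·ρ − 0.367 for strong
  (>10 kcal·mol⁻¹) CH⋯O bonds, Espinosa–Molins–Lecomte E = ½|V(r)| for weak
  CH⋯O / OH⋯C bonds and attractive van der Waals contacts, applied only to
  contacts passing the QTAIM criteria (ρ > 0, Δρ > 0 at the (3,−1) BCP).

Everything is tibble-first: data frames in, tibbles out, so the pieces chain
with the pipe. A seeded synthetic generator produces reaction sets with the
statistical structure of the reference tables for testing whole workflows
without external data.

## Worked example

```r
library(tautkin)

rep <- run_compute("table1")   # the embedded 13-reaction reference network
rep
#> <tautkin_report>
#>   13 reaction(s) characterised, 0 contact(s) scored
#>   most probable pathway:  1↔1*_O5H/O4H (ddG_forward = 13.10 kcal/mol)
#>   least probable pathway: 1↔1*_O1H (ddG_forward = 96.31 kcal/mol)
#>   reference comparison: PASS (0 flagged anomalies)

dplyr::select(rep$kinetics, name, gamma, k_reverse, tau_lifetime, stability)[c(1, 11), ]
#> # A tibble: 2 × 5
#>   name         gamma k_reverse tau_lifetime stability
#>   <chr>        <dbl>     <dbl>        <dbl> <chr>
#> 1 1↔1*_O1H      2.28   2.56e 6     3.91e- 7 stable
#> 2 1↔1*_O5H/O4H  1.77   8.34e13     1.20e-14 barrierless_reverse
```

The first row: ring-opening proton transfer from C8H to the endocyclic O1
atom over a 96.31 kcal·mol⁻¹ barrier. Its imaginary wavenumber
(1150.3 cm⁻¹) gives a tunneling factor Γ ≈ 2.28; the 9.20 kcal·mol⁻¹
reverse barrier yields k_r ≈ 2.6×10⁶ s⁻¹, i.e. the product tautomer lives
about 0.4 µs. The second row has a *negative* reverse barrier
(13.10 − 14.30 = −1.20 kcal·mol⁻¹), so its product is classified
`barrierless_reverse` — it decays without kinetic protection. Rates agree
with the reference annotations within 15 % on all 13 reactions (`rep$pass`).

Contact energetics on the BCP table:

```r
load_fixture("table2") |>
  score_contacts() |>
  dplyr::filter(structure_label == "TS_1↔1*_C6H2")
#>   donor_label acceptor_label contact_class   rho formula_used energy
#> 1 HC6H        O7             CH2_O         0.116 BYH           28.5
#> 2 O5H         O4             OH_O          0.049 NBH            8.62
#> 3 O3H         O4             OH_O          0.026 NBH            3.12
#> 4 C2'H        O3             CH_O          0.018 EML           NA
```

The methylene-like HC6H⋯O7 bond that assists the proton transfer at this
transition state is strong (28.5 kcal·mol⁻¹, BYH formula); the weak C2'H⋯O3
row is EML territory but the fixture stores no V(r), so it is returned as an
explicit unscorable row rather than a guess.

`plot_barriers()`, `plot_contact_energies()` and `autoplot()` give ggplot2
figures; `tidy()` and `glance()` give broom-style summaries of a report.

## Layout

- `R/` — constants convention, kinetics, QTAIM energetics, reaction-set
  container and I/O (JSON/TSV dialects), embedded fixtures, reporting,
  synthetic generator.
- `inst/extdata/` — the reference tables as interchange JSON.
- `inst/scripts/tautkin` — thin CLI (`compute`, `fixtures`, `synth`,
  `rank`) over the package functions.
- `vignettes/tautomer-kinetics.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical decisions, limitations.
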