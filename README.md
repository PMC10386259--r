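# saltnn

Monovalent salt corrections for nucleic-acid secondary-structure energy
models.

Nearest-neighbor free-energy parameters for RNA and DNA are measured at
37 °C and 1.021 M Na⁺.  At other salt concentrations the electrostatics
of the phosphate backbone shift every parameter: counter-ions screen the
backbone over the Debye length κ⁻¹, and Manning condensation caps the
effective line-charge density at τ = min(1/l, 1/ℓ_B).  saltnn implements
the Debye-Hückel/Manning model of these effects for people who work with
secondary-structure thermodynamics — as additive *corrections* relative
to the standard condition, so they can be applied to any parameter set
without changing a folding algorithm.

The core quantities, per structural element:

* **loops** (freely jointed charged chain of L backbone bonds):
  `G_u(L) = R T ℓ_B κ⁻¹ τ_ss² Φ(κ l_ss L)`, with the crossover function
  Φ available both as its exact generalized-hypergeometric form (₁F₂,
  ₂F₃, E₁) and as the fast rational crossover approximation used by
  production folding tools (the default);
* **stacked pairs** (parallel charged rods at d = 20 Å):
  `G_p = 2 R T τ_ds² l_ds ℓ_B K₀(κ d)`;
* **multiloops**: an OLS linearization `g_u(L, ρ) ≈ a₀ + a₁ L` over
  L ∈ [6, 24], compatible with the affine multiloop model
  `E_ml = α + β q + γ m` of cubic-time folding recursions;
* **duplex initiation**: the empirical `g_init(ρ) = a ln(ρ/ρ₀)` with
  per-polymer slopes (RNA −0.45324, DNA −0.58389 kcal/mol);
* **two-state melting**: the fixed point
  `T_m = (2G_A − G_AA)/(−R ln c)` by bisection, van 't Hoff regression
  of 1/T_m on ln c, and the RT ln 2 self-complementarity correction;
* the **Chen & Znosko empirical fits** for duplex ΔG and ΔT_m as
  comparators.

Corrections vanish identically at ρ₀ = 1.021 M at any temperature, by
construction.

## Worked example

All corrections at 0.121 M Na⁺ and 37 °C:

```r
library(saltnn)
salt_correction_set(0.121, celsius_to_kelvin(37))
#> Salt corrections (RNA) at rho = 0.121 M, T = 310.15 K (reference 1.021 M):
#>   stack   g_p    = +0.0370 kcal/mol
#>   init    g_init = +0.9666 kcal/mol
#>   multiloop fit [6,24]: a0 = +0.8194, a1 = +0.0008 kcal/mol
#>   loop    g_u(L) over L = 1..31, e.g. g_u(5) = +0.5838 kcal/mol
```

Each stacking interface is destabilized by 0.037 kcal/mol at this
concentration, each duplex by a further 0.97 kcal/mol of initiation
penalty, and a 4-nt hairpin loop (L = 5 bonds) by 0.58 kcal/mol.

How much does low salt destabilize a hairpin with an 8-bp helix and a
4-nt loop, between 0.03 M and 1.02 M?

```r
hp <- "((((((((....))))))))"
structure_salt_correction(hp, 0.03, 310.15) -
  structure_salt_correction(hp, 1.02, 310.15)
#> [1] 1.958844
structure_salt_report(hp, 0.03, 310.15)
#>        term    kind  m  q  L  kcal_mol
#> 1    stacks   stack NA NA NA 1.1338605
#> 2 loop_8_13 hairpin  4  0  5 0.8252212
```

About 2 kcal/mol, two thirds from the 7 stacking interfaces and one
third from the loop — the corresponding melting experiments report
2.9 kcal/mol, i.e. the model recovers the bulk but underestimates
somewhat.

Recovering duplex thermodynamics from synthetic melting points:

```r
pts <- make_melting_fixtures(1, dH = -60, dS = -0.16)
fit <- vant_hoff_fit(pts)
c(fit$dH, fit$dS)
#> [1] -60.00 -0.16
```

A thin command line lives in `inst/cli/saltnn`:

```sh
Rscript inst/cli/saltnn corrections --rho 0.121 --temp 37
Rscript inst/cli/saltnn structure "((((....))))" --rho 0.05
Rscript inst/cli/saltnn params-apply in.tsv out.tsv --rho 0.1 --dna
```

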