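---
title: "The Debye-Hückel/Manning salt-correction model in saltnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Debye-Hückel/Manning salt-correction model in saltnn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltnn)
```

## The problem

Nearest-neighbor free-energy parameters for RNA and DNA secondary
structures are calibrated at 37 °C and 1.021 M Na⁺.  Away from that
condition the electrostatics of the phosphate backbone change
substantially: counter-ions screen the backbone charges over the Debye
length, and at low salt both loops and helices are destabilized.  saltnn
computes these effects as *corrections* — differences of electrostatic
free energy between the requested monovalent salt concentration ρ and the
standard ρ₀ = 1.021 M — so that they can be added to any standard-condition
parameter set without touching the folding recursions.

## The model

**Screening.**  All terms are driven by the Bjerrum length
ℓ_B(T) = e²/(4π k_B T ε₀ ε_r(T)) and the inverse Debye length
κ = √(ℓ_B I)/(1/√(8π N_A)), with the ionic strength I = ½ Σ ρᵢ zᵢ² equal to
ρ for a fully dissociated monovalent salt.  Both prefactors are computed at
run time from CODATA 2018 constants
(`bjerrum_prefactor()` = 167100.95 Å·K, `debye_prefactor()` = 8.12839 in
the mixed Å/L units); values near 167092.5 Å·K circulate in the
literature, a 5×10⁻⁵ relative difference with no physical consequence
(≈10⁻⁵ kcal/mol on any correction).  The relative permittivity of water
uses an empirical temperature fit, which keeps ℓ_B > l_ss over all of
273–373 K.  That matters: Manning condensation caps the effective line
charge density at τ = min(1/l, 1/ℓ_B z_c), and with the temperature
dependence included the min never switches branch, so τ_ss = τ_ds = 1/ℓ_B
varies smoothly in T (a constant ε_r = 80 would produce a spurious kink
near 53 °C).

**Loops.**  A loop with L backbone bonds is a freely jointed charged
chain with energy

> G_u(L) = R T ℓ_B κ⁻¹ τ_ss² Φ(κ l_ss L).

The crossover function Φ satisfies Φ(0) = 0, grows with slope
1 − ln(π/2) at small argument, peaks near y ≈ 8 and decays to 1.  Loop
sizes follow the bond-count convention L = m + q + 1 for m unpaired
nucleotides and q enclosed branches: hairpins have L = m + 1, interior
loops L = m + 2, multiloops L = m + q + 1.

**Two evaluations of Φ.**  `phi_exact()` sums the closed form in the
generalized hypergeometric functions ₁F₂ and ₂F₃ (all series terms are
positive, so forward summation is stable; the two alternating *outer*
terms cancel ≈ e^{y/π} of magnitude, which still leaves ~8 significant
digits at y = 50, and beyond y = 70 evaluation switches to the crossover
form).  `phi_approx()` is the rational crossover formula that production
folding implementations use.  The two agree at both limits and deviate by
at most 0.211 at y ≈ 26 (tolerance pinned at 0.22 in the tests).
**The package default is the crossover form**: it is the function under
which the reference predictions for hairpin destabilization
(1.94/2.15 kcal/mol, reproduced by the acceptance checks) were obtained,
and matching the deployed model was judged more useful than the marginal
accuracy of the series.  Every energy function accepts `phi = "exact"`.

**Stacks.**  The two strands of a helix are parallel charged rods at
d = 20 Å:

> G_p = 2 R T τ_ds² l_ds ℓ_B K₀(κ d),

with K₀ the modified Bessel function (base R `besselK`, evaluated
directly — approximating the *difference* of K₀ values would leave a
spurious non-zero correction at 1 M).  K₀(z) ~ −ln z, so the stack term
diverges logarithmically as ρ → 0; concentrations below 10⁻⁶ M are
rejected rather than extrapolated.

**Corrections.**  Every correction is the same-temperature difference
from ρ₀, e.g. g_u(L, ρ) = G_u(L; ρ) − G_u(L; ρ₀), so all corrections
vanish *identically* at ρ₀ at any temperature — a property the tests
assert exactly, not approximately.  Corrections increase as ρ decreases
and are nearly flat in T over 10–90 °C.

**Multiloops.**  Cubic-time folding recursions need multiloop energies
affine in (m, q): E_ml = α + βq + γm.  Since L = m + q + 1, fitting
g_u(L, ρ) ≈ a₀ + a₁L by unweighted OLS over the integer range L ∈ [6, 24]
(short multiloops are rare and sterically constrained; the fit range is
user-adjustable) turns the loop correction into parameter shifts:
α += a₀ + a₁, β += a₁, γ += a₁.  The maximal fit residual stays below
1 kcal/mol for ρ ≥ 0.011 M — comparable to the intrinsic uncertainty of
multiloop parameters.  Structure evaluation uses the exact g_u(L) by
default and the linear form on request, mirroring the split between
scoring a given structure and emitting folding parameters.

**Duplex initiation.**  Rod/chain electrostatics misses the
concentration-dependent cost of bringing two strands together; an
empirical term g_init(ρ) = a ln(ρ/ρ₀) is used with a = −0.45324 kcal/mol
(RNA) and −0.58389 kcal/mol (DNA), assumed temperature-independent.  It
can be overridden or disabled (`init = "off"`, or the historical sentinel
99999 on the CLI meaning "no user value").

**Parameter update.**  `apply_salt_corrections()` shifts stacks by g_p,
hairpin entries of length m by g_u(m+1), interior entries by g_u(m+2),
(α, β, γ) as above and E_init by g_init.  The shift is sequence-context
independent, so stack keys are opaque; dangling-end and coaxial terms
pass through byte-identical.  Corrections are absolute with respect to
ρ₀, never cumulative, hence exactly invertible.

**Melting.**  For a self-complementary strand at total concentration c,
the two-state condition "half the strands dimerized" gives the fixed
point T_m = (2G_A(T_m) − G_AA(T_m))/(−R ln c), solved by bisection
(default bracket 273.15–423.15 K, tolerance 10⁻³ K — far below
experimental resolution; no sign change raises an error rather than
returning NaN).  `vant_hoff_fit()` regresses 1/T_m on ln c and inverts
slope R/ΔH and intercept ΔS/ΔH.  Strands equal to their strict
Watson-Crick reverse complement (wobbles excluded) carry the RT ln 2
symmetry correction.

**Empirical comparators.**  `cz_duplex_correction()` and
`cz_tm_correction()` implement the published quadratic-in-log fits of
duplex salt effects parametrized by GC fraction.  Note their reference
points differ by construction: the free-energy fit is anchored at
ρ₀ = 1.021 M, the T_m fit at 1 M exactly as published (a 2% offset
inherent to the formula, flagged here rather than "fixed").

## Numerical and design choices

* The printed form of the exact Φ expression omits the operator in front
  of the y³ term; it is taken as "+", the only choice consistent with the
  small-y slope 1 − ln(π/2) and with the crossover form.
* Γ(0, y) is evaluated as the exponential integral E₁ (`pracma`).
* The constant 1.96351 in the crossover form equals
  γ − ln(π/2) + ln(2π) to 8 digits, which is what makes Φ → 1 at large y;
  it is used verbatim.
* A 1×1 helix mismatch is treated as an interior loop (m = 2, L = 4) by
  default; `mismatch = "stack"` instead scores it as two stacking
  interfaces (the distorted-but-continuous-helix reading).  No published
  data discriminates between the two.
* Lone pairs contribute no stacking interface; exterior bases carry no
  salt term; a duplex face containing the strand nick is exterior-like,
  so a perfect duplex of l pairs scores (l−1)g_p + g_init exactly.
* Internal coordinates are 0-based, all user-facing reports 1-based.
* Energies are floating-point kcal/mol throughout; integer-dekacal
  rounding of folding engines is deliberately not emulated.

## What the fixtures emulate — and what they do not

`make_structure_fixtures()` produces uniform-ish random non-crossing
structures with hairpin loops ≥ 3 nt and a tunable mix of bulges and
multibranch loops; `make_melting_fixtures()` draws melting points from
the temperature-independent two-state closed form
T_m = ΔH/(ΔS + R ln c), optionally with Gaussian noise on the 1/T_m
scale.  Defaults (ΔH = −60 kcal/mol, ΔS = −0.16 kcal/(mol·K),
c ∈ 10⁻⁶–10⁻⁴ M) are typical of short RNA duplex melting experiments.
Passing tests on these fixtures validates the algebra and the solvers;
it does not validate the physical model against real ensembles, whose
free energies are temperature-dependent and whose structures are not
uniform.  Likewise the model itself covers unspecific monovalent
screening only: site-specific Mg²⁺ binding, G-quadruplexes and
pseudoknots are out of scope, and predictions at ρ < 0.01 M inherit the
logarithmic divergence of the stack term.

## Problem sizes

All quantities here are closed-form or small-grid computations: the test
suite and the acceptance script evaluate Φ on a few hundred points, fit
19-point regressions at five concentrations, and score structures of a
few dozen nucleotides — everything completes in seconds on one core.
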