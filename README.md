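# nmrtitr

NMR titration analysis of acidity and prototropic tautomerism.

`nmrtitr` is an R toolkit for ¹H-NMR titration experiments on acid–base
systems with intramolecular hydrogen bonds — typified by *ortho*-hydroxyaryl
Schiff bases, whose labile proton sits in an O···H···N (NHO) bridge and can
reside on the phenolic oxygen (neutral N···H–O tautomer) or on the imine
nitrogen (zwitterionic ⁺N–H···O⁻ tautomer). From a table of pH readings and
chemical shifts recorded along a titration, the package determines:

* **pKa**, by the semilogarithmic Henderson–Hasselbalch linearization: for a
  probe nucleus with limiting shifts δ_min and δ_max,

  log₁₀[(δ_max − δ_obs)/(δ_obs − δ_min)] is linear in pH and crosses zero at
  pH = pKa;

* **ΔK_NHO**, the quotient of the two site dissociation constants
  (K_HN/K_HO), which is the equilibrium constant of the 1,5 prototropic
  tautomerism, by two pH-independent δ-diagram methods:

  - *Perrin bilinear regression* — for a probe pair (x, y) reporting the two
    sites, (δ_y − δ_y°)(δ_xᵉ − δ_x) = ΔK · (δ_x − δ_x°)(δ_yᵉ − δ_y), so ΔK
    is the slope of one transformed product against the other;
  - *Polster–Lachmann Gibbs-triangle analysis* — for kinked δ-diagrams, the
    trajectory point written in barycentric coordinates (b₀, b₁, b₂) of the
    triangle A (initial state) / B (neutralization vertex) / C (final state)
    gives the stepwise quotient as the distance-ratio product
    b₁²/(b₀·b₂), identical at every point of the curve;

* the derived **thermodynamics**: ΔpK_NHO = −log₁₀ ΔK_NHO,
  ΔΔG° = −RT ln ΔK_NHO (kJ mol⁻¹), and the tautomer classification
  (ΔK > 1 → proton on N; ΔK < 1 → proton on O; ΔK ≈ 1 → shared).

Because raw titration tables for such systems are rarely published, the
package also ships a synthetic-data generator implementing the fast-exchange
two-state averaging model for monoprotic, coupled tautomeric and diprotic
systems, with Gaussian shift/pH noise — every estimator is validated in a
closed loop against known ground truth.

## Worked example

Simulate a diprotic titration (pKa 8 and 10) observed through two probes,
then run the full pipeline:

```r
library(nmrtitr)

spec <- diprotic_system(8, 10,
                        delta_H2A = c(H6 = 6.90, H9 = 4.80),
                        delta_HA  = c(H6 = 6.72, H9 = 4.72),
                        delta_A   = c(H6 = 6.58, H9 = 4.60))
series <- simulate_diprotic(spec, ph_grid(8, 10), noise_spec(0, 0))
report <- run_pipeline(series, pipeline_config())
report
#> <titration_report> synthetic diprotic pKa1=8 pKa2=10
#>   linearity: 1 breakpoint(s)
#>   pKa [pH -Inf..9] = 7.941
#>   pKa [pH 9..Inf] = 10.075
#>   delta_K = 99.3957 (polster-lachmann) -> proton-on-N, ddG = -11.324 kJ/mol
```

The δ-diagram of the two probes shows one breakpoint, so the pipeline splits
the Henderson–Hasselbalch fit into two pH windows (recovering both pKa
values) and reads the stepwise-constant quotient K₁/K₂ = ΔK ≈ 99.4 (true
value 100) off the Gibbs triangle. For a single-step system the diagram is
linear and the Perrin slope is used instead:

```r
taut <- tautomer_system(8.3, 8.0,
                        delta_start = c(H6 = 6.90, H9 = 4.80),
                        delta_end   = c(H6 = 6.60, H9 = 4.55))
s <- simulate_tautomeric(taut, ph_grid(8.0, 8.3), noise_spec(0, 0))
d <- build_diagram(s, "H6", "H9",
                   start_anchor = c(6.90, 4.80), end_anchor = c(6.60, 4.55))
perrin_fit(d)
#> <perrin_fit>
#>   delta_K = 1.9953 (+/- 0.0000)   intercept = -3.43e-17 ppm^2   r = 1.0000   n = 23
tautomer_result(1.9953, method = "perrin")
#> <tautomer_result> perrin
#>   delta_K = 1.9953   delta_pK = -0.3000   ddG = -1.701 kJ/mol (296.15 K)
#>   proton position: proton-on-N
```

Here ΔK = K_HN/K_HO = 10^0.3 ≈ 1.995: deprotonation through the N–H path is
favoured, the proton sits predominantly on nitrogen, and the tautomer free
energy difference is −1.70 kJ mol⁻¹.

Titration tables are read and written as plain CSV
(`read_titration_csv()` / `write_titration_csv()`), and a thin command-line
front end with `simulate` / `fit-hh` / `fit-perrin` / `fit-pl` / `report`
subcommands is installed under `inst/cli/nmr-titrate.R`.

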