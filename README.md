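# plaquekin

Quantitative workflows for studies of amyloid-β pathology, in three parts:

1. **Aggregation kinetics.** Thioflavin-T (ThT) plate-reader traces of
   unseeded Aβ42 aggregation are normalized to fibrillar mass fraction,
   their reaction half-times t½ extracted, and the curves globally fitted
   with the analytical solution of the primary + secondary nucleation
   model of filamentous growth.
2. **Plaque zonation.** Two-channel fluorescence fields (a plaque stain
   such as Zinpyr-1 plus a marker immunostain) are segmented into plaques,
   each plaque is partitioned into a *center* and a *border* zone by an
   intensity-fraction rule (border ≈ 60 % of center fluorescence), and
   marker enrichment in the center is quantified and tested across plaques.
3. **Expression quantification.** qPCR cycle thresholds are converted to
   "virtual mRNA levels" via a standard-curve slope, densitometry bands are
   normalized to a reference band, and groups are compared by one-way
   ANOVA with Bonferroni post hoc tests or t tests.

Every stage is paired with a seeded synthetic-data generator that emits the
same file formats plus ground truth, so the full pipeline is testable end
to end without any external data.

## The kinetic model

For an unseeded reaction with initial monomer concentration *m₀*, primary
nucleation (rate constant *k_n*, order *n_c*), secondary nucleation on the
fibril surface (rate constant *k₂*, order *n₂*) and elongation (*k₊*), the
fibrillar mass fraction M(t)/M(∞) depends on the two combined rates

- λ = √(2 k₊ k_n m₀^{n_c})  — primary pathway,
- κ = √(2 k₊ k₂ m₀^{n₂+1}) — secondary pathway,

and is given by the standard closed-form solution of the moment equations
(implemented in `closed_form_mass_fraction()`, validated in the tests
against direct numerical integration of dP/dt = k_n m^{n_c} + k₂ m^{n₂} M,
dM/dt = 2 k₊ m P with `moment_ode_oracle()`). Only λ and κ are
identifiable from unseeded data, so `fit_secondary_nucleation()` fits
exactly those two parameters by deterministic multi-start least squares and
reports t½ from the fitted curve.

## Worked example

```r
library(plaquekin)

# simulate a triplicate ThT assay: 5 uM monomer, reads every 400 s,
# control vs a condition with secondary nucleation reduced to 10 %
sim <- simulate_tht_plate(params_for_half_time(0.8), seed = 42,
                          inhibition_factors = c(control = 1, s100a8 = 0.1))
fits <- lapply(split(sim$traces,
                     vapply(sim$traces, `[[`, "", "condition")),
               function(trs) fit_secondary_nucleation(
                 lapply(trs, normalize_trace), seed = 1))
fits$control
#> Secondary-nucleation global fit
#>   lambda = 5.745e-05 /s, kappa = 0.003108 /s (n_c = 2, n_2 = 2, m0 = 5e-06 M)
#>   t1/2 = 0.801 h, residual RMS = 0.01034, 3 traces, converged: TRUE
compare_half_times(vapply(fits, `[[`, 0, "t_half"), "control")
#>     label    t_half fold_change
#> 1 control 0.8014921     1.00000
#> 2  s100a8 1.8642068     2.32592
```

The fitted half-time of the control (0.80 h) matches the generating truth,
and suppressing secondary nucleation tenfold delays t½ by ~2.3-fold — the
qualitative signature of an aggregation inhibitor acting on the
fibril-catalyzed pathway.

```r
# zonation: plaque field with a known marker enrichment of 1.5
fld <- simulate_plaque_field(n_plaques = 10, border_intensity_fraction = 0.5,
                             seed = 13)
z <- zonate_field(fld$image, threshold_fraction = 0.6)
head(z$table, 3)
#>   region_id marker_mean_center marker_mean_border center_border_ratio
#> 1         1           150.1612           100.0697            1.500567
#> 2         2           150.0412           100.0197            1.500116
#> 3         3           150.1853           100.2677            1.497842
z$test$p       # paired center-vs-border t test across plaques
#> [1] 3.336432e-22
```

The recovered center/border marker ratios sit within a percent of the
generating 1.5, and the paired test detects the enrichment decisively.

A thin command-line wrapper over the same functions ships in
`inst/scripts/plaquekin` (subcommands `simulate-tht`, `simulate-plaques`,
`simulate-qpcr`, `fit-tht`, `zonate`, `qpcr`).

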