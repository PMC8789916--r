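# hotbio

Quantitative toolkit for deciding whether microbial life in deeply
buried, hot (40–120 °C) marine sediment is metabolically active — and
what that activity costs per cell.

Sediment heated past ~50 °C hosts vanishingly small communities
(hundreds of cells per cm³) whose turnover rates sit near the
theoretical detection limit of radiotracer methods, while thermal damage
to proteins and DNA forces each surviving cell to spend energy on
repair. `hotbio` implements the full chain of calculations needed to
work with such data:

* **Radiotracer rates.** Volumetric sulfate-reduction and
  methanogenesis rates from ³⁵S/¹⁴C slurry incubations,
  `rate = A_prod/(A_prod+A_sub) · pool · α · ρ/(t·m)`, with a
  killed-control detection limit `MBQL = mean + 3·sd` and strict-below
  censoring (`turnover_rate()`, `mbql()`, `censor_rates()`,
  `control_consistency()`).
* **Sulfate budget.** Half-space diffusion model
  `C/C₀ = erf(z / 2√(Dt/θ²))` with tortuosity `θ² = φ·F`, an
  independent finite-difference cross-check, and the budget arithmetic
  `τ = [SO₄²⁻]·φ/SRR`, its rearrangement for mean rates, and the
  organic-carbon oxidation equivalent of a sulfate depletion.
* **Thermodynamics.** `ΔG_R = ΔG⁰_insitu + RT·lnQ` for five catabolic
  reactions, with extended Debye–Hückel (B-dot) activity coefficients
  and a linear geothermal temperature model. Standard-state energies are
  input data (packaged, editable YAML).
* **Population energetics.** Cell-specific rates (fmol cell⁻¹ d⁻¹),
  per-cell power, Arrhenius repair-cost thresholds for amino-acid
  racemization and DNA depurination, and biomass turnover times from
  cell counts (22 fg C cell⁻¹, configurable yield, recovery and
  functional fraction).
* **Synthetic data.** A seeded generator of incubation counts (Poisson
  counting noise over a truncated-Gaussian background), control series
  and depth profiles, so the whole pipeline runs end to end with no
  external data (`simulate_incubation()`, `simulate_profile()`,
  `run_pipeline()`).

## Worked example

```r
library(hotbio)

# --- rates: one deep sulfate-reduction vial and its detection limit
v <- incubation_vial("C23-920", "SR",
                     activity_product_bq = 1.7, activity_substrate_bq = 5e6,
                     pool_total_mol = 2.7e-5, bulk_density_g_cm3 = 2.2,
                     time_d = 10, mass_g = 11)
turnover_rate(v)$rate_pmol_cm3_d
#> [1] 0.1946159

lim <- mbql(c(0.11, 0.09, 0.10, 0.12))   # killed-control rate equivalents
lim$mbql
#> [1] 0.1437298

# --- budget: could diffusion alone have removed the deep sulfate?
100 * (1 - relative_concentration(c(150, 200, 250), t_yr = 4e5))
#> [1] 11.014892  3.316896  0.775533
depletion_time(28e-3, porosity = 0.35, srr_pmol_cm3_d = 0.3)     # days
#> [1] 32666667
average_srr(c(22e-3, 28e-3), 0.35, duration_yr = 4e5)
#> [1] 0.05270363 0.06707734
corg_equivalent(c(22e-3, 28e-3), 0.35, bulk_density_g_cm3 = 2.2) # wt%
#> [1] 0.00840000 0.01069091

# --- energetics and per-cell thresholds at ~100 degrees C
cost <- repair_cost(100)                  # kJ cell^-1 d^-1
cost
#> [1] 1e-14
threshold_cell_rate(cost, dG_kj_mol = c(-105, -43))  # fmol cell^-1 d^-1
#> [1] 0.0952381 0.2325581
cell_specific_rate(0.1, abundance_cells_cm3 = 500)
#> [1] 0.2
biomass_turnover_time(500, rate_mol_cm3_d = 1e-13,
                      correct_recovery = FALSE)      # days
#> [1] 458.3333
```

Reading: diffusion since rapid burial 400,000 years ago can lower deep
sulfate by only ~11 % at 150 m below the depleted zone (less than 1 %
beyond 250 m), so the observed 22–28 mmol L⁻¹ depletion requires in-situ
sulfate reduction at a mean 0.05–0.07 pmol cm⁻³ d⁻¹ — equivalent to
oxidizing just ~0.01 wt% organic carbon. At the measured ~0.3 pmol cm⁻³
d⁻¹ the pool would last ~90,000 years. A 500 cells cm⁻³ community
sustaining 0.1 pmol cm⁻³ d⁻¹ runs at 0.2 fmol cell⁻¹ d⁻¹ per cell, just
above the ~0.1–0.2 fmol cell⁻¹ d⁻¹ needed to pay the 10⁻¹⁴ kJ cell⁻¹ d⁻¹
protein-repair bill at 100 °C, and turns its biomass over in days to
years.

The end-to-end run (synthetic data → rates → budget → energetics →
per-cell), with CSV and JSON outputs:

```r
report <- run_pipeline(pipeline_config(seed = 1), outdir = "out")
report
```

A thin command-line wrapper is included at `inst/scripts/hotbio.R`
(`simulate`, `rates`, `run-all` subcommands).

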