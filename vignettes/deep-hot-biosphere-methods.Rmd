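---
title: "Methods: rates, budgets and bioenergetics of hot subseafloor sediment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rates, budgets and bioenergetics of hot subseafloor sediment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotbio)
```

`hotbio` implements the quantitative chain used to decide whether a tiny
microbial community in deeply buried, 40–120 °C marine sediment can be
metabolically active: radiotracer turnover rates with a blank-based
detection limit, a diffusion plausibility model for the porewater sulfate
budget, in-situ Gibbs energies of the candidate catabolic reactions, and
the conversion of volumetric rates into per-cell rates, repair-cost
thresholds and biomass turnover times. This vignette explains each model,
its assumptions, the tunable parameters, and the numerical choices.

## 1. Radiotracer turnover rates

A slurry vial receives a known activity of labelled substrate
(\(^{35}\mathrm{S}\text{-}\mathrm{SO_4^{2-}}\) for sulfate reduction,
\(^{14}\mathrm{C}\)-DIC for methanogenesis). After an incubation of
\(t\) days the volumetric rate is

\[
\mathrm{rate} \;=\;
\frac{A_{\mathrm{prod}}}{A_{\mathrm{prod}} + A_{\mathrm{sub}}}
\times [\mathrm{pool}] \times \alpha \times \frac{\rho}{t\, m},
\]

where \(A_{\mathrm{prod}}\) is the product-pool activity (total reduced
inorganic sulfur, or combusted \(^{14}\mathrm{CH_4}\)),
\(A_{\mathrm{sub}}\) the residual substrate activity, \([\mathrm{pool}]\)
the total unlabelled substrate in the vial (medium plus porewater
contribution, mol; `total_pool_moles()`), \(\alpha\) the isotopic
fractionation correction (1.06 for \(^{35}\mathrm{S}\), 1.08 for
\(^{14}\mathrm{C}\)), \(\rho\) the wet bulk density and \(m\) the
sediment mass, so \(m/\rho\) is the wet-sediment volume. Rates are
reported in pmol cm\(^{-3}\) d\(^{-1}\) of wet sediment. The model
assumes single-timepoint linear turnover (a few-percent turnover fraction
at most), no back-reaction, and tracer equilibration with the whole pool.
Tracer additions are excluded from the pool: they are designed not to
change its concentration measurably. Activities are accepted as Bq;
`counts_to_bq()` applies a counting efficiency when raw counter output is
the input.

### Detection limit

Near the limit of detection the dominant uncertainty is not counting
statistics but abiotic tracer conversion. The package therefore derives a
*minimum biological quantification limit* from the killed
(gamma-irradiated) controls:
\(\mathrm{MBQL} = \overline{x}_{\mathrm{killed}} + 3\, s_{\mathrm{killed}}\).
The standard-deviation convention is a visible switch
(`sd_convention = "sample"` by default, n−1 denominator; `"population"`
available) because the convention behind published limits is rarely
stated. Censoring is strictly below the limit — a rate exactly at the
MBQL is quantifiable — and is a flag, never a deletion, so censored
values remain available as bounds. One caveat worth knowing: the
mean + 3 sd statistic is *not* monotone in every individual blank value
(raising a below-mean blank can shrink the sd faster than it raises the
mean); it is monotone under location shifts, scaling, and increases of
the largest blank, which is what the tests assert.

The control hierarchy (counter blank, distillation blank, medium, drill
fluid, live sediment, killed) is audited by `control_consistency()`,
which flags any series whose mean falls more than one standard deviation
from its medium control.

## 2. Sulfate budget

Below a sulfate-depleted interval, the question is whether the deep
sulfate pool could have been drawn down by diffusion alone since rapid
burial began, or whether in-situ reduction is required. With a
zero-concentration boundary at 600 mbsf and an effectively semi-infinite
column below it, the fraction of the initial concentration remaining at
distance \(z\) below the boundary after time \(t\) is the classical
half-space solution

\[
\frac{C(z,t)}{C(z,0)} = \mathrm{erf}\!\left(
\frac{z}{2\sqrt{D t / \theta^2}}\right),
\qquad \theta^2 = \varphi F ,
\]

with \(D = 0.054\) m\(^2\) yr\(^{-1}\), porosity \(\varphi = 0.35\) and
formation factor \(F = 14\) (so \(\theta^2 = 4.9\)) as defaults. Two
dialects of the erf argument circulate for this problem; the package
implements both (`form = "standard"` and `form = "as_printed"`, the
latter with \(\sqrt{2 D t/\theta^2}\) in the denominator). The standard
form is the default because it alone is consistent with a direct
finite-difference solution of the diffusion equation — `diffuse_fd()`,
an explicit FTCS solver with the no-flux bottom at 1200 mbsf, agrees
with it to better than 1 % relative wherever the depletion exceeds 1 %,
while the alternative dialect under-predicts the depletion by a factor
of about four (≈2.4 % instead of ≈11 % at 150 m below the boundary
after 400 kyr). The half-space (rather than finite-column) closed form
is adequate here because the diffusion penetration depth
\(\sqrt{D t/\theta^2} \approx 66\) m after 400 kyr is small compared to
the 600 m column.

The budget arithmetic then links a depletion to a rate: depletion time
\(\tau = [\mathrm{SO_4^{2-}}]_{\mathrm{initial}}\,\varphi / \mathrm{SRR}\)
(`depletion_time()`), its rearrangement for the mean rate over a period
(`average_srr()`), and the organic-carbon oxidation equivalent of a
depletion via the 2 : 1 C : SO\(_4^{2-}\) stoichiometry of organic
matter at oxidation state zero (`corg_equivalent()`). A year is
365.25 days throughout (configurable). With the defaults: 28 mmol
L\(^{-1}\) at 0.3 pmol cm\(^{-3}\) d\(^{-1}\) gives
\(\tau = 3.27\times 10^7\) d (≈89,400 yr); a 22–28 mmol L\(^{-1}\)
depletion over 400 kyr gives 0.053–0.067 pmol cm\(^{-3}\) d\(^{-1}\)
and 0.0084–0.011 wt% organic carbon at \(\rho = 2.2\) g cm\(^{-3}\).

## 3. In-situ reaction energetics

The energetics stage evaluates
\(\Delta G_R = \Delta G^0_{\mathrm{insitu}} + R T \ln Q\) for five
catabolic reactions (sulfate-dependent AOM, sulfate reduction from
acetate and from H\(_2\), methanogenesis from acetate and from H\(_2\)).
Three deliberate scope decisions:

* **Standard-state energies are input data.** Computing
  \(\Delta G^0(T, P)\) belongs to dedicated thermodynamic codes; the
  packaged `reactions.yaml` ships editable values. The acetate-fuelled
  pair carries *calibrated anchors*: together with the packaged anchor
  porewater composition (920 mbsf, 100 °C, ionic strength 0.64, pH 7.5,
  acetate 10 mM, sulfate 3 mM, DIC 1 mM, HS\(^{-}\) at its detection
  floor) they return −105 kJ (mol SO\(_4^{2-}\))\(^{-1}\) and −43 kJ
  (mol CH\(_4\))\(^{-1}\). The back-computed anchor for sulfate reduction
  from acetate, −47.9 kJ mol\(^{-1}\), is close to the textbook 25 °C
  standard value (≈ −48 kJ mol\(^{-1}\)), a useful sanity check. The
  other three values are order-of-magnitude placeholders flagged
  `illustrative` in the file.
* **Activity coefficients** use the extended Debye–Hückel (B-dot) form
  \(\log_{10}\gamma = -A z^2 \sqrt I / (1 + B \mathring a \sqrt I) +
  \dot b I\), with the standard tabulated \(A(T)\), \(B(T)\) for water
  at 0–150 °C interpolated linearly, Kielland-style ion sizes, and
  \(\dot b = 0.041\) for ions (0 for neutral species). Setting
  `bdot = 0` recovers the plain extended form; both variants are live
  because which one a given geochemistry code applied at \(I = 0.64\) is
  generally not reported. Speciation and complexation are out of scope.
* **Temperature** comes from a linear geothermal gradient, default
  100 °C km\(^{-1}\) over a 2 °C seafloor. Site descriptions of this
  kind of setting quote gradients between 100 and 110 °C km\(^{-1}\);
  neither choice reproduces a rounded "100 °C at 920 mbsf" exactly
  (100 km\(^{-1}\) gives 94 °C), so the gradient is fully configurable
  and the energetics anchor is pinned to 100 °C rather than to a depth.
  Where HS\(^{-}\) is below detection a floor of 0.1 µmol L\(^{-1}\) is
  assumed.

## 4. Population energetics

With volumetric rates, cell counts and \(\Delta G_R\) in hand:

* `cell_specific_rate()`: rate / (abundance × functional fraction), in
  fmol cell\(^{-1}\) d\(^{-1}\). With every counted cell assumed
  functional this is the most conservative estimate; 0.1 pmol
  cm\(^{-3}\) d\(^{-1}\) over 500 cells cm\(^{-3}\) gives 0.2, and a
  10 % functional fraction gives 2 fmol cell\(^{-1}\) d\(^{-1}\).
* `energy_turnover()` (per-cell power, \(|\Delta G_R| \times\) rate /
  abundance) and its inversions `maintenance_rate()` and
  `threshold_cell_rate()` — the volumetric and per-cell rates needed to
  cover a repair cost. All use \(|\Delta G_R|\): energies are negative
  (exergonic) by convention, and the threshold formulas would otherwise
  return negative rates.
* `repair_cost()`: the energy a cell must spend to counteract thermal
  damage, modelled as two Arrhenius processes — amino-acid racemization
  (a protein is replaced once 3 % of its residues have racemized;
  ~1.3 × 10\(^8\) residues per 22 fg C cell) and DNA depurination
  (linear in genome size, default 3.2 Mb within the plausible
  1.6–10 Mb range). Activation energies default to 110 and 130 kJ
  mol\(^{-1}\), typical of the published kinetics for the two processes.
  The pre-exponential factors are *calibrated*, not fitted: they are
  solved analytically so that the total cost at 100 °C equals
  10\(^{-14}\) kJ cell\(^{-1}\) d\(^{-1}\) with 90 % of the anchor cost
  in the protein term (racemization dominates repair budgets at these
  temperatures). The model is a single-anchor parameterization and makes
  no claim to reproduce any specific literature compilation away from
  the anchor. Against the −105 / −43 kJ mol\(^{-1}\) energies the anchor
  cost translates into threshold rates of ≈0.1 fmol SO\(_4^{2-}\) and
  ≈0.2 fmol CH\(_4\) cell\(^{-1}\) d\(^{-1}\).
* `biomass_turnover_time()`: standing biomass carbon (cells × 22 fg C,
  divided by the 25 % extraction recovery when the correction is on)
  over biomass-carbon production (rate × 2 mol C per mol substrate ×
  growth yield, default 0.01). The recovery correction is **on** for
  biomass turnover but **off** for the per-cell quantities above — the
  per-cell anchors are conventionally computed on counted cells — and
  both are switches. Cell counts below the 16 cells cm\(^{-3}\)
  quantification limit are censored: per-cell quantities there are
  evaluated at the limit and flagged as bounds.

## 5. Synthetic data generator

`simulate_incubation()` inverts the rate equation: a vial with true rate
\(r\) has expected turnover fraction
\(f = r\,t\,m / (\rho\, \mathrm{pool}\, \alpha)\); the product channel
receives injected activity × \(f\) plus a Gaussian counting background
truncated at zero, and both channels are realized with Poisson counting
noise over a 600 s counting window (the standard scintillation model —
the choice of noise model is the generator's, as no physical counting
chain is being reproduced). Defaults emulate the study conditions:
5 MBq injected, 5 mL medium (5 mM sulfate, or 0.677 mM DIC) + 5 mL
sediment, 10-day incubations, a true-rate profile of a few hundred
pmol cm\(^{-3}\) d\(^{-1}\) above 320 mbsf falling three orders of
magnitude across 320–360 mbsf to ~0.3 deep, and killed controls drawn
from background only. `simulate_profile()` produces the matching depth
profiles: linear temperature, erf-shaped sulfate below a 600 mbsf
boundary, an acetate bulge peaking near 950 mbsf, and a two-regime
log-linear cell decline (>10\(^4\) to <500 cells cm\(^{-3}\) across the
breakpoint, floored at the quantification limit). A single integer seed
fixes all randomness; reruns are byte-identical.

What the generator does *not* emulate: spatial heterogeneity and
replicate-level nugget variance beyond counting noise, drilling-fluid
contamination structure, distillation carryover, non-Gaussian blank
tails, and any covariance between cell counts and rates. Passing
recovery tests on synthetic data therefore demonstrates the correctness
of the estimator chain under the stated noise model, not robustness to
every pathology of real core material.

## 6. Pipeline, sizes and determinism

`run_pipeline()` chains simulate → rates → budget → energetics →
per-cell and emits a JSON report of the headline quantities; all tables
are schema-validated (`validate_table()`) with row- and column-named
diagnostics. The default run uses 20 depths × 3 replicate vials per
assay and a 20 m profile grid — sizes chosen so a full run takes
seconds while keeping ≥10\(^4\) expected counts in the quantifiable
vials. The finite-difference cross-check uses a 1 m grid and a stability
factor of 0.4, giving ≈11,000 time steps over 400 kyr. Estimator
recovery is verified at high expected counts (10\(^5\)–10\(^6\)), where
counting statistics dominate; near 10\(^4\) counts the additive blank
(not subtracted, by design — censoring replaces blank subtraction)
contributes a percent-level positive bias, which is the reason the
detection-limit machinery exists at all.

## Known limitations

* The diffusion model is single-species, constant-\(D\), no advection or
  compaction; it is a plausibility bound, not a reactive-transport model.
* \(\Delta G^0\) values other than the two calibrated anchors are
  placeholders; quantitative energetics away from the anchor requires
  user-supplied standard-state data.
* The repair-cost model is a calibrated two-process summary; absolute
  costs at temperatures far from 100 °C inherit the uncertainty of the
  assumed activation energies.
* AOM is handled by the generic rate machinery only (product
  \(^{14}\mathrm{CO_2}\), substrate \(^{14}\mathrm{CH_4}\), configurable
  \(\alpha\)); no AOM-specific background chemistry is modelled.
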