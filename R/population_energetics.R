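# Per-cell metabolic rates, per-cell power, thermal-damage repair
# thresholds, and biomass turnover times.
#
# Sign convention: in-situ reaction energies are negative (exergonic);
# every power or threshold formula uses |dG|, so that dissipated energy
# and required rates come out positive.

#' Cell-specific metabolic rate
#'
#' Divides a volumetric rate by the abundance of cells carrying the
#' metabolism. With the whole counted community assumed functional
#' (`functional_fraction = 1`) this is the most conservative (lowest)
#' per-cell estimate; a smaller functional fraction raises it
#' proportionally.
#'
#' @param rate_pmol_cm3_d volumetric rate, pmol cm^-3 d^-1.
#' @param abundance_cells_cm3 counted cells per cm^3 (> 0).
#' @param functional_fraction fraction of counted cells that are sulfate
#'   reducers and/or methanogens, in (0, 1].
#' @return cell-specific rate, fmol cell^-1 d^-1.
#' @export
#' @examples
#' cell_specific_rate(0.1, 500)        # 0.2 fmol / cell / d
#' cell_specific_rate(0.1, 500, 0.1)   # 2 fmol / cell / d
cell_specific_rate <- function(rate_pmol_cm3_d, abundance_cells_cm3,
                               functional_fraction = 1) {
  check_nonnegative(rate_pmol_cm3_d, "rate_pmol_cm3_d")
  if (any(functional_fraction <= 0 | functional_fraction > 1))
    stop_param("`functional_fraction` must be in (0, 1]")
  if (any(abundance_cells_cm3 * functional_fraction <= 0))
    stop_param("undefined per-cell rate: zero functional cells")
  rate_pmol_cm3_d * 1000 / (abundance_cells_cm3 * functional_fraction)
}

#' Per-cell energy turnover
#'
#' Energy dissipated per cell and day: |dG| times the volumetric rate
#' divided by cell abundance.
#'
#' @param dG_kj_mol Gibbs energy of the catabolic reaction, kJ mol^-1
#'   (sign ignored).
#' @param rate_mol_cm3_d volumetric rate, mol cm^-3 d^-1.
#' @param abundance_cells_cm3 cells per cm^3 (> 0).
#' @return energy turnover, kJ cell^-1 d^-1.
#' @export
energy_turnover <- function(dG_kj_mol, rate_mol_cm3_d, abundance_cells_cm3) {
  check_nonnegative(rate_mol_cm3_d, "rate_mol_cm3_d")
  check_positive(abundance_cells_cm3, "abundance_cells_cm3")
  abs(dG_kj_mol) * rate_mol_cm3_d / abundance_cells_cm3
}

#' Volumetric rate required to cover repair costs
#'
#' The metabolic rate a population must sustain so that the energy
#' conserved from its catabolic reaction covers a per-cell repair cost:
#' cost times abundance divided by |dG|. This is the threshold band drawn
#' against measured rate profiles.
#'
#' @param cost_kj_cell_d repair cost, kJ cell^-1 d^-1.
#' @param abundance_cells_cm3 cells per cm^3 (>= 0).
#' @param dG_kj_mol reaction energy, kJ mol^-1 (non-zero; sign ignored).
#' @return required rate, mol cm^-3 d^-1.
#' @export
maintenance_rate <- function(cost_kj_cell_d, abundance_cells_cm3, dG_kj_mol) {
  check_nonnegative(cost_kj_cell_d, "cost_kj_cell_d")
  check_nonnegative(abundance_cells_cm3, "abundance_cells_cm3")
  if (any(dG_kj_mol == 0)) stop_param("undefined maintenance rate: dG is zero")
  cost_kj_cell_d * abundance_cells_cm3 / abs(dG_kj_mol)
}

#' Cell-specific rate required to cover repair costs
#'
#' Per-cell form of [maintenance_rate()]: cost divided by |dG|, in fmol
#' per cell per day.
#'
#' @inheritParams maintenance_rate
#' @return threshold rate, fmol cell^-1 d^-1.
#' @export
#' @examples
#' threshold_cell_rate(1e-14, -105)   # ~0.1 fmol sulfate / cell / d
#' threshold_cell_rate(1e-14, -43)    # ~0.2 fmol methane / cell / d
threshold_cell_rate <- function(cost_kj_cell_d, dG_kj_mol) {
  check_nonnegative(cost_kj_cell_d, "cost_kj_cell_d")
  if (any(dG_kj_mol == 0)) stop_param("undefined threshold: dG is zero")
  cost_kj_cell_d / abs(dG_kj_mol) * 1e15
}

#' Parameterization of the thermal-damage repair cost
#'
#' Two Arrhenius-controlled damage processes are modelled: racemization
#' of protein amino acids (repaired by replacing a protein once 3 % of
#' its residues have racemized) and DNA depurination (linear in genome
#' size). The published compilations behind these kinetics report
#' activation energies near 110 and 130 kJ mol^-1; the pre-exponential
#' factors here are calibrated analytically so that the total cost at the
#' packaged anchor (100 degrees C, default genome size) equals
#' `anchor_cost_kj_cell_d`, with the protein term carrying
#' `protein_share_at_anchor` of the anchor cost. The model makes no claim
#' to reproduce any particular literature kinetics beyond this anchor.
#'
#' @param genome_size_mb genome size, megabases (1.6-10 plausible).
#' @param replacement_fraction racemized fraction triggering protein
#'   replacement (0.03).
#' @param amino_acids_per_cell protein residues per cell (~1.3e8 for a
#'   small cell of 22 fg C).
#' @param purine_sites_per_mb depurination-susceptible sites per megabase
#'   of double-stranded genome (one purine per base pair).
#' @param ea_racemization_kj_mol,ea_depurination_kj_mol activation
#'   energies, kJ mol^-1.
#' @param resynthesis_kj_per_residue energy to resynthesize one residue,
#'   kJ (ATP-equivalent).
#' @param repair_kj_per_depurination energy per depurination repair
#'   event, kJ.
#' @param anchor_cost_kj_cell_d total cost at the anchor temperature,
#'   kJ cell^-1 d^-1.
#' @param anchor_temp_C anchor temperature, deg C.
#' @param protein_share_at_anchor fraction of the anchor cost assigned to
#'   protein repair (racemization dominates the budget).
#' @return list of class `"repair_cost_params"` with calibrated
#'   pre-exponential rate constants `A_racemization_per_d`,
#'   `A_depurination_per_d` (per residue / per site, d^-1).
#' @export
repair_cost_params <- function(genome_size_mb = 3.2,
                               replacement_fraction = 0.03,
                               amino_acids_per_cell = 1.3e8,
                               purine_sites_per_mb = 1e6,
                               ea_racemization_kj_mol = 110,
                               ea_depurination_kj_mol = 130,
                               resynthesis_kj_per_residue = 4.2e-22,
                               repair_kj_per_depurination = 1e-20,
                               anchor_cost_kj_cell_d = 1e-14,
                               anchor_temp_C = 100,
                               protein_share_at_anchor = 0.9) {
  check_positive(genome_size_mb, "genome_size_mb")
  if (replacement_fraction <= 0 || replacement_fraction >= 1)
    stop_param("`replacement_fraction` must be in (0, 1)")
  check_positive(anchor_cost_kj_cell_d, "anchor_cost_kj_cell_d")
  if (protein_share_at_anchor <= 0 || protein_share_at_anchor >= 1)
    stop_param("`protein_share_at_anchor` must be in (0, 1)")
  TK <- anchor_temp_C + 273.15
  boltz_rac <- exp(-ea_racemization_kj_mol / (.R_GAS * TK))
  boltz_dep <- exp(-ea_depurination_kj_mol / (.R_GAS * TK))
  # protein term: A * exp(-Ea/RT) * N_res * E_res / f_replace
  A_rac <- protein_share_at_anchor * anchor_cost_kj_cell_d /
    (boltz_rac * amino_acids_per_cell * resynthesis_kj_per_residue /
       replacement_fraction)
  # DNA term: A * exp(-Ea/RT) * sites(genome) * E_event
  A_dep <- (1 - protein_share_at_anchor) * anchor_cost_kj_cell_d /
    (boltz_dep * genome_size_mb * purine_sites_per_mb *
       repair_kj_per_depurination)
  structure(list(
    genome_size_mb = genome_size_mb,
    replacement_fraction = replacement_fraction,
    amino_acids_per_cell = amino_acids_per_cell,
    purine_sites_per_mb = purine_sites_per_mb,
    ea_racemization_kj_mol = ea_racemization_kj_mol,
    ea_depurination_kj_mol = ea_depurination_kj_mol,
    resynthesis_kj_per_residue = resynthesis_kj_per_residue,
    repair_kj_per_depurination = repair_kj_per_depurination,
    A_racemization_per_d = A_rac,
    A_depurination_per_d = A_dep,
    anchor_cost_kj_cell_d = anchor_cost_kj_cell_d,
    anchor_temp_C = anchor_temp_C),
    class = "repair_cost_params")
}

#' Per-cell repair cost at temperature
#'
#' Sum of the racemization (protein replacement) and depurination (DNA
#' repair) terms of [repair_cost_params()], each Arrhenius in
#' temperature; strictly increasing in T. With the default calibration
#' the cost at 100 degrees C is 1e-14 kJ cell^-1 d^-1. A `genome_size_mb`
#' passed here rescales the DNA term linearly without recalibrating.
#'
#' @param temp_C temperature, deg C (vectorized).
#' @param params a [repair_cost_params()] object.
#' @param genome_size_mb optional genome size overriding the one in
#'   `params` for the DNA term.
#' @return repair cost, kJ cell^-1 d^-1.
#' @export
#' @examples
#' repair_cost(100)    # 1e-14 by calibration
repair_cost <- function(temp_C, params = repair_cost_params(),
                        genome_size_mb = NULL) {
  stopifnot(inherits(params, "repair_cost_params"))
  if (is.null(genome_size_mb)) genome_size_mb <- params$genome_size_mb
  TK <- temp_C + 273.15
  check_positive(TK, "temp_C + 273.15")
  rac <- params$A_racemization_per_d *
    exp(-params$ea_racemization_kj_mol / (.R_GAS * TK)) *
    params$amino_acids_per_cell * params$resynthesis_kj_per_residue /
    params$replacement_fraction
  dep <- params$A_depurination_per_d *
    exp(-params$ea_depurination_kj_mol / (.R_GAS * TK)) *
    genome_size_mb * params$purine_sites_per_mb *
    params$repair_kj_per_depurination
  rac + dep
}

#' Biomass turnover time
#'
#' Standing biomass carbon divided by the biomass-carbon production rate:
#' \deqn{T_b = \frac{n_{cells} \times m_C / 12}{rate \times s \times Y}}
#' with cell abundance optionally corrected for extraction recovery
#' (counted cells / recovery), per-cell carbon \eqn{m_C} in grams,
#' \eqn{s} mol organic C oxidized per mol substrate, and growth yield
#' \eqn{Y} in mol biomass C per mol organic C.
#'
#' @param abundance_cells_cm3 counted cells per cm^3.
#' @param rate_mol_cm3_d volumetric substrate turnover, mol cm^-3 d^-1
#'   (> 0).
#' @param cell_carbon_fg carbon per cell, fg (22).
#' @param functional_fraction fraction of counted cells belonging to the
#'   population whose biomass is turned over, in (0, 1].
#' @param growth_yield mol biomass C per mol organic C (0.01-0.2).
#' @param corg_per_substrate mol organic C per mol sulfate or methane
#'   (2).
#' @param recovery_efficiency cell recovery of the extraction protocol
#'   (0.25).
#' @param correct_recovery apply the recovery correction (default TRUE
#'   for biomass estimates).
#' @return turnover time, days.
#' @export
#' @examples
#' # counted cells taken at face value:
#' biomass_turnover_time(500, 1e-13, correct_recovery = FALSE)  # ~458 d
biomass_turnover_time <- function(abundance_cells_cm3, rate_mol_cm3_d,
                                  cell_carbon_fg = 22,
                                  functional_fraction = 1,
                                  growth_yield = 0.01,
                                  corg_per_substrate = 2,
                                  recovery_efficiency = 0.25,
                                  correct_recovery = TRUE) {
  check_nonnegative(abundance_cells_cm3, "abundance_cells_cm3")
  check_positive(rate_mol_cm3_d, "rate_mol_cm3_d")
  check_positive(cell_carbon_fg, "cell_carbon_fg")
  if (any(functional_fraction <= 0 | functional_fraction > 1))
    stop_param("`functional_fraction` must be in (0, 1]")
  if (any(growth_yield <= 0 | growth_yield > 1))
    stop_param("`growth_yield` must be in (0, 1]")
  check_positive(corg_per_substrate, "corg_per_substrate")
  if (any(recovery_efficiency <= 0 | recovery_efficiency > 1))
    stop_param("`recovery_efficiency` must be in (0, 1]")
  n <- abundance_cells_cm3
  if (correct_recovery) n <- n / recovery_efficiency
  biomass_mol_c <- n * functional_fraction * cell_carbon_fg * 1e-15 / 12
  production_mol_c <- rate_mol_cm3_d * corg_per_substrate * growth_yield
  biomass_mol_c / production_mol_c
}

#' Specific biomass turnover
#'
#' Reciprocal turnover time: mol biomass carbon assimilated per mol cell
#' carbon per day.
#'
#' @param t_b_days biomass turnover time, days (> 0).
#' @return specific turnover, d^-1.
#' @export
specific_turnover <- function(t_b_days) {
  check_positive(t_b_days, "t_b_days")
  1 / t_b_days
}

#' Per-cell quantities along a depth profile
#'
#' Joins volumetric rates, cell counts and reaction energies into the
#' per-cell output table: cell-specific rate, per-cell energy turnover,
#' repair threshold at in-situ temperature, required maintenance rate,
#' biomass turnover time and specific turnover. Cell counts below the
#' minimum quantification limit are censored: per-cell quantities there
#' are evaluated at the limit and flagged as bounds.
#'
#' @param depth_mbsf,rate_pmol_cm3_d,abundance_cells_cm3,dG_kj_mol,temp_C
#'   parallel vectors describing each depth.
#' @param functional_fraction,growth_yield,correct_recovery passed
#'   through to the per-cell formulas.
#' @param params repair-cost parameterization.
#' @param mql_cells_cm3 minimum quantifiable cell count (16 cells cm^-3).
#' @return data frame with one row per depth.
#' @export
per_cell_table <- function(depth_mbsf, rate_pmol_cm3_d, abundance_cells_cm3,
                           dG_kj_mol, temp_C, functional_fraction = 1,
                           growth_yield = 0.01, correct_recovery = TRUE,
                           params = repair_cost_params(),
                           mql_cells_cm3 = 16) {
  censored <- abundance_cells_cm3 < mql_cells_cm3
  n_eff <- pmax(abundance_cells_cm3, mql_cells_cm3)
  rate_mol <- rate_pmol_cm3_d * 1e-12
  cost <- repair_cost(temp_C, params)
  data.frame(
    depth_mbsf = depth_mbsf,
    temp_C = temp_C,
    abundance_censored = censored,
    cell_rate_fmol = cell_specific_rate(rate_pmol_cm3_d, n_eff,
                                        functional_fraction),
    energy_kj_cell_d = energy_turnover(dG_kj_mol, rate_mol, n_eff),
    repair_threshold_fmol = threshold_cell_rate(cost, dG_kj_mol),
    maintenance_rate_pmol_cm3_d =
      maintenance_rate(cost, n_eff, dG_kj_mol) * 1e12,
    t_b_days = biomass_turnover_time(
      n_eff, rate_mol, functional_fraction = functional_fraction,
      growth_yield = growth_yield, correct_recovery = correct_recovery),
    specific_turnover = specific_turnover(biomass_turnover_time(
      n_eff, rate_mol, functional_fraction = functional_fraction,
      growth_yield = growth_yield, correct_recovery = correct_recovery))
  )
}
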