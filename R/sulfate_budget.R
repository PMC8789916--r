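# Diffusion plausibility model for post-burial sulfate loss, and the
# budget arithmetic linking depletion, depletion time, mean rate, and the
# organic-carbon oxidation equivalent.

#' Sediment tortuosity from porosity and formation factor
#'
#' \eqn{\theta^2 = \varphi F}. The formation factor is the ratio of
#' porewater to bulk sediment electrical conductivity.
#'
#' @param porosity volume fraction, strictly in (0, 1).
#' @param formation_factor dimensionless, >= 1.
#' @return tortuosity squared (dimensionless).
#' @export
#' @examples
#' tortuosity(0.35, 14)   # 4.9
tortuosity <- function(porosity, formation_factor) {
  if (any(porosity <= 0 | porosity >= 1))
    stop_param("`porosity` must be strictly between 0 and 1")
  if (any(formation_factor < 1))
    stop_param("`formation_factor` must be >= 1")
  porosity * formation_factor
}

#' Physical parameters of a sediment column
#'
#' Bundles the diffusion, porosity and temperature parameters used by the
#' sulfate budget and by the temperature model. Tortuosity is derived as
#' \eqn{\varphi F} when not supplied.
#'
#' @param D free-solution diffusion coefficient of sulfate, m^2 yr^-1.
#' @param porosity volume fraction of porewater.
#' @param formation_factor dimensionless conductivity ratio.
#' @param theta_sq tortuosity squared; derived from porosity and
#'   formation factor when `NULL`.
#' @param boundary_depth_m depth of the zero-concentration boundary, mbsf.
#' @param bottom_depth_m impermeable bottom boundary, mbsf.
#' @param bulk_density_g_cm3 wet bulk density, g cm^-3.
#' @param geothermal_gradient_C_km linear geothermal gradient, deg C km^-1.
#' @param surface_temp_C seafloor temperature, deg C.
#' @return list of class `"sediment_column"`.
#' @export
sediment_column <- function(D = 0.054, porosity = 0.35, formation_factor = 14,
                            theta_sq = NULL, boundary_depth_m = 600,
                            bottom_depth_m = 1200, bulk_density_g_cm3 = 2.2,
                            geothermal_gradient_C_km = 100,
                            surface_temp_C = 2) {
  check_positive(D, "D")
  if (is.null(theta_sq)) theta_sq <- tortuosity(porosity, formation_factor)
  check_positive(theta_sq, "theta_sq")
  check_positive(bulk_density_g_cm3, "bulk_density_g_cm3")
  if (bottom_depth_m <= boundary_depth_m)
    stop_param("`bottom_depth_m` must exceed `boundary_depth_m`")
  structure(list(D = D, porosity = porosity,
                 formation_factor = formation_factor, theta_sq = theta_sq,
                 boundary_depth_m = boundary_depth_m,
                 bottom_depth_m = bottom_depth_m,
                 bulk_density_g_cm3 = bulk_density_g_cm3,
                 geothermal_gradient_C_km = geothermal_gradient_C_km,
                 surface_temp_C = surface_temp_C),
            class = "sediment_column")
}

#' Relative porewater concentration under half-space diffusion
#'
#' Fraction of the initial concentration remaining at a distance `z_m`
#' below a zero-concentration boundary after `t_yr` years of diffusion
#' with effective diffusivity \eqn{D/\theta^2}:
#' \deqn{C(z,t)/C(z,0) = \mathrm{erf}\!\left(z / (2\sqrt{D t /
#'   \theta^2})\right).}
#'
#' `form = "as_printed"` evaluates the alternative dialect
#' \eqn{\mathrm{erf}(z / \sqrt{2 D t / \theta^2})}, which differs by a
#' factor \eqn{\sqrt 2} in the argument; it is retained for transparency
#' but the standard half-space solution is the default (it is the one
#' consistent with a finite-difference solution of the diffusion
#' equation; see the methods vignette).
#'
#' @param z_m distance below the zero-concentration boundary, m (>= 0).
#' @param t_yr elapsed time, yr (> 0).
#' @param column optional [sediment_column()] supplying `D` and
#'   `theta_sq`.
#' @param D free-solution diffusion coefficient, m^2 yr^-1.
#' @param theta_sq tortuosity squared.
#' @param form `"standard"` (default) or `"as_printed"`.
#' @return fraction of the initial concentration remaining, in \[0, 1\].
#' @export
#' @examples
#' # ~11 % sulfate reduction 150 m below a 600-mbsf boundary after 400 kyr
#' 1 - relative_concentration(150, 4e5)
relative_concentration <- function(z_m, t_yr, column = NULL, D = 0.054,
                                   theta_sq = 4.9,
                                   form = c("standard", "as_printed")) {
  form <- match.arg(form)
  if (!is.null(column)) {
    stopifnot(inherits(column, "sediment_column"))
    D <- column$D
    theta_sq <- column$theta_sq
  }
  check_nonnegative(z_m, "z_m")
  check_positive(t_yr, "t_yr")
  check_positive(D, "D")
  check_positive(theta_sq, "theta_sq")
  arg <- switch(form,
    standard   = z_m / (2 * sqrt(D * t_yr / theta_sq)),
    as_printed = z_m / sqrt(2 * D * t_yr / theta_sq))
  erf(arg)
}

#' Finite-difference solution of the column diffusion problem
#'
#' Explicit (FTCS) solver for \eqn{\partial C/\partial t =
#' (D/\theta^2)\,\partial^2 C/\partial z^2} on a column of given
#' thickness with a fixed zero concentration at the top boundary and a
#' no-flux bottom, from a uniform initial concentration of 1. Serves as
#' an independent numerical cross-check of [relative_concentration()].
#'
#' @param t_yr elapsed time, yr.
#' @param D free-solution diffusion coefficient, m^2 yr^-1.
#' @param theta_sq tortuosity squared.
#' @param thickness_m column thickness below the boundary, m.
#' @param dz_m grid spacing, m.
#' @param courant stability factor for the time step (< 0.5).
#' @return data frame with `z_m` (distance below the boundary) and
#'   `frac_remaining`.
#' @export
diffuse_fd <- function(t_yr, D = 0.054, theta_sq = 4.9, thickness_m = 600,
                       dz_m = 1, courant = 0.4) {
  check_positive(t_yr, "t_yr")
  check_positive(dz_m, "dz_m")
  if (courant <= 0 || courant >= 0.5)
    stop_param("`courant` must lie in (0, 0.5) for FTCS stability")
  d_eff <- D / theta_sq
  z <- seq(0, thickness_m, by = dz_m)
  n <- length(z)
  dt <- courant * dz_m^2 / d_eff
  steps <- ceiling(t_yr / dt)
  dt <- t_yr / steps
  r <- d_eff * dt / dz_m^2
  C <- rep(1, n)
  C[1] <- 0
  for (k in seq_len(steps)) {
    lap <- c(0, C[1:(n - 2)] - 2 * C[2:(n - 1)] + C[3:n], 0)
    # no-flux bottom: ghost node mirrors the penultimate one
    lap[n] <- 2 * (C[n - 1] - C[n])
    C <- C + r * lap
    C[1] <- 0
  }
  data.frame(z_m = z, frac_remaining = C)
}

#' Time to deplete the porewater sulfate pool at a given rate
#'
#' \eqn{\tau = [\mathrm{SO_4^{2-}}]_{initial} \, \varphi / SRR}: the
#' porewater inventory per cm^3 of bulk sediment divided by the
#' volumetric sulfate reduction rate.
#'
#' @param initial_mol_l initial porewater sulfate, mol L^-1.
#' @param porosity volume fraction of porewater.
#' @param srr_pmol_cm3_d volumetric sulfate reduction rate,
#'   pmol cm^-3 d^-1 (> 0).
#' @return depletion time, days.
#' @export
#' @examples
#' depletion_time(28e-3, 0.35, 0.3)    # ~3.3e7 d (~90,000 yr)
depletion_time <- function(initial_mol_l, porosity, srr_pmol_cm3_d) {
  check_nonnegative(initial_mol_l, "initial_mol_l")
  if (any(porosity <= 0 | porosity > 1)) stop_param("`porosity` must be in (0, 1]")
  check_positive(srr_pmol_cm3_d, "srr_pmol_cm3_d")
  # mol L^-1 porewater -> pmol cm^-3 bulk: /1000 cm3 per L, *1e12 pmol, *phi
  initial_mol_l / 1000 * porosity * 1e12 / srr_pmol_cm3_d
}

#' Mean volumetric sulfate reduction rate over a depletion period
#'
#' Rearranged depletion-time relation: the observed porewater sulfate
#' depletion, expressed per cm^3 of bulk sediment, divided by the elapsed
#' time.
#'
#' @param depletion_mol_l porewater sulfate depletion, mol L^-1.
#' @param porosity volume fraction of porewater.
#' @param duration_yr elapsed time, yr.
#' @param days_per_year calendar convention (365.25).
#' @return mean rate, pmol cm^-3 d^-1.
#' @export
#' @examples
#' average_srr(28e-3, 0.35, 4e5)   # ~0.07 pmol cm^-3 d^-1
average_srr <- function(depletion_mol_l, porosity, duration_yr,
                        days_per_year = 365.25) {
  check_nonnegative(depletion_mol_l, "depletion_mol_l")
  if (any(porosity <= 0 | porosity > 1)) stop_param("`porosity` must be in (0, 1]")
  check_positive(duration_yr, "duration_yr")
  depletion_mol_l / 1000 * porosity * 1e12 / (duration_yr * days_per_year)
}

#' Organic-carbon oxidation equivalent of a sulfate depletion
#'
#' Converts a porewater sulfate depletion into the weight percent of
#' sediment organic carbon (oxidation state 0) whose oxidation it
#' represents, via the sulfate-reduction stoichiometry
#' 2 CH2O + SO4^2- -> 2 HCO3^- + HS^- + H^+ (2 mol C per mol sulfate by
#' default).
#'
#' @param depletion_mol_l porewater sulfate depletion, mol L^-1.
#' @param porosity volume fraction of porewater.
#' @param bulk_density_g_cm3 wet bulk density, g cm^-3.
#' @param stoichiometry mol organic C oxidized per mol sulfate reduced.
#' @param molar_mass_c g mol^-1 of carbon.
#' @return organic carbon, wt% of bulk sediment.
#' @export
#' @examples
#' corg_equivalent(22e-3, 0.35, 2.2)   # ~0.0084 wt%
corg_equivalent <- function(depletion_mol_l, porosity, bulk_density_g_cm3,
                            stoichiometry = 2, molar_mass_c = 12) {
  check_nonnegative(depletion_mol_l, "depletion_mol_l")
  if (any(porosity <= 0 | porosity > 1)) stop_param("`porosity` must be in (0, 1]")
  check_positive(bulk_density_g_cm3, "bulk_density_g_cm3")
  check_positive(stoichiometry, "stoichiometry")
  check_positive(molar_mass_c, "molar_mass_c")
  # mol SO4 per cm3 bulk * mol C per mol SO4 * g per mol C / (g sediment per cm3)
  depletion_mol_l / 1000 * porosity * stoichiometry * molar_mass_c /
    bulk_density_g_cm3 * 100
}

#' Sulfate budget table for a set of depths
#'
#' Convenience wrapper evaluating the diffusion model and the budget
#' arithmetic over a vector of depths below seafloor.
#'
#' @param depths_mbsf depths, mbsf (at or below the boundary).
#' @param t_yr time since burial onset, yr.
#' @param column a [sediment_column()].
#' @param initial_mol_l initial porewater sulfate, mol L^-1.
#' @param srr_pmol_cm3_d representative measured rate for the depletion
#'   time, pmol cm^-3 d^-1.
#' @param form diffusion dialect passed to [relative_concentration()].
#' @return data frame with `depth_mbsf`, `frac_remaining`, `pct_lowered`,
#'   `tau_days`, `avg_srr`, `corg_wt_pct`.
#' @export
sulfate_budget_table <- function(depths_mbsf, t_yr = 4e5,
                                 column = sediment_column(),
                                 initial_mol_l = 28e-3,
                                 srr_pmol_cm3_d = 0.3,
                                 form = "standard") {
  stopifnot(inherits(column, "sediment_column"))
  z <- depths_mbsf - column$boundary_depth_m
  if (any(z < 0))
    stop_param("all depths must be at or below the boundary (%g mbsf)",
               column$boundary_depth_m)
  frac <- relative_concentration(z, t_yr, column = column, form = form)
  data.frame(
    depth_mbsf = depths_mbsf,
    frac_remaining = frac,
    pct_lowered = 100 * (1 - frac),
    tau_days = depletion_time(initial_mol_l, column$porosity, srr_pmol_cm3_d),
    avg_srr = average_srr(initial_mol_l, column$porosity, t_yr),
    corg_wt_pct = corg_equivalent(initial_mol_l, column$porosity,
                                  column$bulk_density_g_cm3))
}
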