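# In-situ Gibbs energies of the catabolic reactions: geothermal
# temperature model, extended Debye-Hueckel activity coefficients,
# activity quotients, and Delta-G at non-standard conditions.
#
# Standard-state energies at in-situ T/P are consumed as input data (the
# packaged reactions.yaml); computing them from an equation of state is
# deliberately out of scope.

#' In-situ temperature from a linear geothermal gradient
#'
#' @param depth_mbsf depth below seafloor, m (>= 0).
#' @param gradient_C_km geothermal gradient, deg C km^-1.
#' @param surface_temp_C seafloor temperature, deg C.
#' @return temperature, deg C.
#' @export
#' @examples
#' insitu_temperature(920)    # 94 degrees C with the defaults
insitu_temperature <- function(depth_mbsf, gradient_C_km = 100,
                               surface_temp_C = 2) {
  check_nonnegative(depth_mbsf, "depth_mbsf")
  surface_temp_C + gradient_C_km * depth_mbsf / 1000
}

# Debye-Hueckel A and B solvent coefficients for water at 1 bar /
# saturation, 0-150 degrees C (Helgeson & Kirkham 1974 tabulation;
# A in kg^1/2 mol^-1/2, B in angstrom^-1 kg^1/2 mol^-1/2).
.dh_table <- data.frame(
  temp_C = c(0, 25, 50, 75, 100, 125, 150),
  A = c(0.4911, 0.5092, 0.5336, 0.5639, 0.5998, 0.6416, 0.6898),
  B = c(0.3244, 0.3283, 0.3325, 0.3371, 0.3422, 0.3476, 0.3533)
)

#' Debye-Hueckel solvent coefficients A(T), B(T)
#'
#' Linear interpolation of the standard tabulated values for water
#' between 0 and 150 degrees C.
#'
#' @param temp_C temperature, deg C.
#' @return data frame with columns `temp_C`, `A`, `B`.
#' @export
dh_coefficients <- function(temp_C) {
  if (any(temp_C < min(.dh_table$temp_C) | temp_C > max(.dh_table$temp_C)))
    stop_param("Debye-Hueckel coefficients tabulated for 0-150 degrees C only")
  data.frame(
    temp_C = temp_C,
    A = stats::approx(.dh_table$temp_C, .dh_table$A, temp_C)$y,
    B = stats::approx(.dh_table$temp_C, .dh_table$B, temp_C)$y
  )
}

#' Single-ion activity coefficient (extended Debye-Hueckel / B-dot)
#'
#' \deqn{\log_{10}\gamma = \frac{-A z^2 \sqrt I}{1 + B \mathring a \sqrt I}
#'   + \dot b I}
#' Neutral species (z = 0) reduce to \eqn{\gamma = 10^{\dot b I}}, i.e.
#' \eqn{\gamma = 1} when no salting-out coefficient is supplied. Setting
#' `bdot = 0` gives the plain extended Debye-Hueckel form.
#'
#' @param charge signed ionic charge.
#' @param ionic_strength mol L^-1 (>= 0).
#' @param ion_size_a ion size parameter, angstrom.
#' @param bdot B-dot (salting) coefficient; 0 disables the linear term.
#' @param temp_C temperature for the solvent coefficients, deg C.
#' @return activity coefficient \eqn{\gamma > 0}. Vectorized over all
#'   arguments.
#' @export
#' @examples
#' activity_coefficient(-2, 0.64, ion_size_a = 4, temp_C = 25)
activity_coefficient <- function(charge, ionic_strength, ion_size_a = 4,
                                 bdot = 0, temp_C = 25) {
  check_nonnegative(ionic_strength, "ionic_strength")
  dh <- dh_coefficients(temp_C)
  sI <- sqrt(ionic_strength)
  log10g <- -dh$A * charge^2 * sI / (1 + dh$B * ion_size_a * sI) +
    bdot * ionic_strength
  10^log10g
}

#' Default ion-specific activity parameters
#'
#' Ion size parameters (Kielland-style) and B-dot coefficients for the
#' species of the five packaged catabolic reactions. Neutral dissolved
#' gases carry zero coefficients (ideal behaviour) unless overridden.
#'
#' @return data frame with `species`, `charge`, `ion_size_a`, `bdot`.
#' @export
default_species_params <- function() {
  data.frame(
    species    = c("SO4-2", "HCO3-", "HS-", "CH3COO-", "H+", "CH4", "H2", "H2O"),
    charge     = c(-2, -1, -1, -1, 1, 0, 0, 0),
    ion_size_a = c(4.0, 4.5, 3.5, 4.5, 9.0, 0, 0, 0),
    bdot       = c(0.041, 0.041, 0.041, 0.041, 0.041, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Species activities from concentrations
#'
#' Multiplies measured concentrations by activity coefficients computed
#' at the given ionic strength and temperature. Species flagged below
#' detection are assigned the detection floor before the coefficient is
#' applied (0.1 umol L^-1 for HS^- by default).
#'
#' @param conc_mol_l named numeric vector of concentrations, mol L^-1.
#' @param ionic_strength mol L^-1.
#' @param temp_C deg C.
#' @param params parameter table as from [default_species_params()].
#' @param below_detection character vector of species names to replace by
#'   `floor_mol_l`.
#' @param floor_mol_l detection floor, mol L^-1.
#' @return named numeric vector of activities.
#' @export
species_activities <- function(conc_mol_l, ionic_strength = 0.64,
                               temp_C = 25, params = default_species_params(),
                               below_detection = character(),
                               floor_mol_l = 1e-7) {
  if (is.null(names(conc_mol_l)) || any(!nzchar(names(conc_mol_l))))
    stop_param("`conc_mol_l` must be a fully named vector")
  check_nonnegative(conc_mol_l, "conc_mol_l")
  conc_mol_l[names(conc_mol_l) %in% below_detection] <- floor_mol_l
  idx <- match(names(conc_mol_l), params$species)
  if (anyNA(idx))
    stop_param("no activity parameters for species: %s",
               paste(names(conc_mol_l)[is.na(idx)], collapse = ", "))
  gamma <- activity_coefficient(params$charge[idx], ionic_strength,
                                params$ion_size_a[idx], params$bdot[idx],
                                temp_C)
  out <- conc_mol_l * gamma
  # water convention: unit activity
  out[names(out) == "H2O"] <- 1
  out
}

#' Construct a catabolic reaction specification
#'
#' @param name reaction identifier.
#' @param stoichiometry named numeric vector of signed coefficients
#'   (products positive, reactants negative).
#' @param dG0_insitu standard-state Gibbs energy at in-situ T and P,
#'   kJ per mol of the reference substrate (input datum).
#' @return list of class `"reaction_spec"`.
#' @export
reaction_spec <- function(name, stoichiometry, dG0_insitu = NA_real_) {
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop_param("`stoichiometry` must be a fully named vector")
  structure(list(name = name, stoichiometry = stoichiometry,
                 dG0_insitu = dG0_insitu),
            class = "reaction_spec")
}

# Element composition and charge of the species the packaged reactions
# use; for the stoichiometric balance check.
.species_composition <- list(
  "CH4"     = c(C = 1, H = 4, O = 0, S = 0, charge = 0),
  "SO4-2"   = c(C = 0, H = 0, O = 4, S = 1, charge = -2),
  "HCO3-"   = c(C = 1, H = 1, O = 3, S = 0, charge = -1),
  "HS-"     = c(C = 0, H = 1, O = 0, S = 1, charge = -1),
  "H2O"     = c(C = 0, H = 2, O = 1, S = 0, charge = 0),
  "CH3COO-" = c(C = 2, H = 3, O = 2, S = 0, charge = -1),
  "H2"      = c(C = 0, H = 2, O = 0, S = 0, charge = 0),
  "H+"      = c(C = 0, H = 1, O = 0, S = 0, charge = 1)
)

#' Check element and charge balance of a reaction
#'
#' @param reaction a [reaction_spec()].
#' @return named numeric vector of net element/charge imbalance (all
#'   zeros for a balanced reaction), invisibly; errors if a species is
#'   unknown.
#' @export
check_reaction_balance <- function(reaction) {
  stopifnot(inherits(reaction, "reaction_spec"))
  sp <- names(reaction$stoichiometry)
  unknown <- setdiff(sp, names(.species_composition))
  if (length(unknown))
    stop_param("no composition data for species: %s",
               paste(unknown, collapse = ", "))
  bal <- Reduce(`+`, Map(function(s, nu) nu * .species_composition[[s]],
                         sp, reaction$stoichiometry))
  invisible(bal)
}

#' The five packaged catabolic reactions
#'
#' Reads the packaged `reactions.yaml`: stoichiometries of
#' sulfate-dependent AOM, sulfate reduction from acetate and from
#' hydrogen, and methanogenesis from acetate and from hydrogen, together
#' with standard-state in-situ Gibbs energies supplied as data. The
#' acetate-fuelled pair carries calibrated anchor values tied to the
#' packaged reference porewater composition at 920 mbsf / 100 degrees C;
#' the remainder are illustrative and meant to be replaced by values from
#' a thermodynamic code for the user's own conditions.
#'
#' @param path optional path to an alternative YAML file with the same
#'   layout.
#' @return named list of [reaction_spec()] objects; the anchor conditions
#'   block is attached as attribute `"anchor_conditions"`.
#' @export
catabolic_reactions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reactions.yaml", package = "hotbio")
  spec <- yaml::read_yaml(path)
  out <- lapply(names(spec$reactions), function(nm) {
    r <- spec$reactions[[nm]]
    reaction_spec(nm, unlist(r$stoichiometry), r$dG0_insitu_kj_mol)
  })
  names(out) <- names(spec$reactions)
  attr(out, "anchor_conditions") <- spec$anchor_conditions
  out
}

#' Activity quotient of a reaction
#'
#' \eqn{Q = \prod_i a_i^{\nu_i}} with products carrying positive and
#' reactants negative coefficients. Water takes unit activity and may be
#' omitted from `activities`. A zero activity on the product side yields
#' Q = 0; a zero activity on the reactant side is undefined and errors.
#'
#' @param reaction a [reaction_spec()].
#' @param activities named numeric vector of species activities.
#' @return the activity quotient (dimensionless scalar).
#' @export
activity_quotient <- function(reaction, activities) {
  stopifnot(inherits(reaction, "reaction_spec"))
  nu <- reaction$stoichiometry
  nu <- nu[names(nu) != "H2O"]
  missing <- setdiff(names(nu), names(activities))
  if (length(missing))
    stop_param("missing activities for: %s", paste(missing, collapse = ", "))
  a <- activities[names(nu)]
  check_nonnegative(a, "activities")
  if (any(a == 0 & nu < 0))
    stop_param("zero activity for reactant-side species: %s",
               paste(names(a)[a == 0 & nu < 0], collapse = ", "))
  prod(a^nu)
}

#' Gibbs energy of reaction at non-standard conditions
#'
#' \eqn{\Delta G_R = \Delta G^0_{insitu} + R T \ln Q} with
#' R = 0.008314 kJ mol^-1 K^-1. Negative values are exergonic.
#'
#' @param dG0_insitu standard-state Gibbs energy at in-situ T and P,
#'   kJ mol^-1 (input datum), or a [reaction_spec()] carrying one.
#' @param temp_K absolute temperature, K.
#' @param Q activity quotient (> 0).
#' @return \eqn{\Delta G_R}, kJ mol^-1.
#' @export
#' @examples
#' gibbs_energy(-47.9, 373.15, 1e-8)
gibbs_energy <- function(dG0_insitu, temp_K, Q) {
  if (inherits(dG0_insitu, "reaction_spec")) dG0_insitu <- dG0_insitu$dG0_insitu
  check_positive(temp_K, "temp_K")
  if (any(Q <= 0)) stop_param("`Q` must be positive")
  dG0_insitu + .R_GAS * temp_K * log(Q)
}

#' In-situ reaction energies along a porewater composition profile
#'
#' For each depth in a long-format species table, computes activities
#' (extended Debye-Hueckel at in-situ temperature), the activity quotient
#' of each requested reaction, and \eqn{\Delta G_R}.
#'
#' @param species_profile data frame with `depth_mbsf`, `species`,
#'   `conc_mol_l` (long format).
#' @param reactions list of [reaction_spec()]s (default: the packaged
#'   five).
#' @param column a [sediment_column()] supplying the temperature model.
#' @param ionic_strength mol L^-1.
#' @param pH used for the H+ activity when the profile carries no `H+`
#'   rows.
#' @param hs_floor_mol_l detection floor applied to zero HS- entries.
#' @return data frame with `depth_mbsf`, `temp_C`, `reaction`, `Q`,
#'   `dG0_insitu`, `dG_kj_mol`.
#' @export
energetics_profile <- function(species_profile,
                               reactions = catabolic_reactions(),
                               column = sediment_column(),
                               ionic_strength = 0.64, pH = 7.5,
                               hs_floor_mol_l = 1e-7) {
  need <- c("depth_mbsf", "species", "conc_mol_l")
  missing <- setdiff(need, names(species_profile))
  if (length(missing))
    stop_param("species profile lacks column(s): %s",
               paste(missing, collapse = ", "))
  depths <- sort(unique(species_profile$depth_mbsf))
  rows <- list()
  for (d in depths) {
    sub <- species_profile[species_profile$depth_mbsf == d, ]
    conc <- stats::setNames(sub$conc_mol_l, sub$species)
    if (!"H+" %in% names(conc)) conc[["H+"]] <- 10^(-pH)
    bd <- names(conc)[names(conc) == "HS-" & conc <= 0]
    tC <- insitu_temperature(d, column$geothermal_gradient_C_km,
                             column$surface_temp_C)
    act <- species_activities(conc, ionic_strength, tC,
                              below_detection = bd,
                              floor_mol_l = hs_floor_mol_l)
    for (r in reactions) {
      needed <- setdiff(names(r$stoichiometry), "H2O")
      if (!all(needed %in% names(act))) next
      Q <- activity_quotient(r, act)
      rows[[length(rows) + 1L]] <- data.frame(
        depth_mbsf = d, temp_C = tC, reaction = r$name, Q = Q,
        dG0_insitu = r$dG0_insitu,
        dG_kj_mol = gibbs_energy(r$dG0_insitu, tC + 273.15, Q),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
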