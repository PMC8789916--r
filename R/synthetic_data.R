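# Seeded generator of synthetic incubation and depth-profile data.
#
# The forward model inverts the tracer rate equation: a vial's expected
# product activity is injected activity times the turnover fraction
# implied by its true rate, realized with Poisson counting noise on top
# of an additive Gaussian counting background truncated at zero (the
# standard scintillation-counting model). Everything is driven by one
# seed, so reruns are byte-identical.

#' Default true-rate depth profile for the generator
#'
#' Volumetric rates of a few hundred pmol cm^-3 d^-1 above the 320 mbsf
#' breakpoint, a three-order-of-magnitude log-linear drop across
#' 320-360 mbsf, and ~0.3 pmol cm^-3 d^-1 below — the shape the
#' generator's conditions emulate.
#'
#' @param depth_mbsf depths, m below seafloor.
#' @param shallow_rate,deep_rate plateau rates, pmol cm^-3 d^-1.
#' @param breakpoint_mbsf two-element depth window of the drop.
#' @return rates, pmol cm^-3 d^-1.
#' @export
default_true_rates <- function(depth_mbsf, shallow_rate = 500,
                               deep_rate = 0.3,
                               breakpoint_mbsf = c(320, 360)) {
  lo <- breakpoint_mbsf[1]
  hi <- breakpoint_mbsf[2]
  w <- pmin(pmax((depth_mbsf - lo) / (hi - lo), 0), 1)
  10^((1 - w) * log10(shallow_rate) + w * log10(deep_rate))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults
#' describe the emulated study conditions: 5 mL medium + 5 mL sediment
#' slurries injected with 5 MBq of tracer and incubated for 10 days,
#' 5 mmol L^-1 medium sulfate (0.677 mmol L^-1 DIC for methanogenesis),
#' a Gaussian counting background, a sulfate zero-concentration boundary
#' at 600 mbsf, and a steep cell-abundance drop across 320-360 mbsf.
#'
#' @param seed integer seed fixing all randomness.
#' @param assay `"SR"` or `"MG"`.
#' @param depths_mbsf vial depths.
#' @param n_replicates vials per depth.
#' @param true_rates_pmol_cm3_d true volumetric rates per depth; defaults
#'   to [default_true_rates()].
#' @param injected_activity_bq injected tracer activity per vial, Bq.
#' @param counting_time_s scintillation counting time, s.
#' @param background_mean_bq,background_sd_bq counting background
#'   (Gaussian, truncated at 0), Bq.
#' @param incubation_time_d incubation time, d (<= 10).
#' @param medium_conc_mM substrate concentration in the medium; defaults
#'   per assay (5 for SR, 0.677 for MG).
#' @param medium_vol_ml,sediment_vol_ml slurry volumes, mL.
#' @param porosity,bulk_density_g_cm3 sediment properties.
#' @param n_killed,n_controls killed-control and other-control counts.
#' @param profile list of depth-profile parameters: `breakpoint_mbsf`,
#'   `shallow_log10_cells`, `deep_log10_cells`, `sulfate_boundary_mbsf`,
#'   `sulfate_deep_mM`, `acetate_peak_mM`, `noise_rel`,
#'   `cell_mql_cells_cm3`.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1, assay = "SR",
                       depths_mbsf = seq(200, 1150, by = 50),
                       n_replicates = 3,
                       true_rates_pmol_cm3_d = default_true_rates(depths_mbsf),
                       injected_activity_bq = 5e6,
                       counting_time_s = 600,
                       background_mean_bq = 0.85,
                       background_sd_bq = 0.095,
                       incubation_time_d = 10,
                       medium_conc_mM = c(SR = 5, MG = 0.677)[[assay]],
                       medium_vol_ml = 5, sediment_vol_ml = 5,
                       porosity = 0.35, bulk_density_g_cm3 = 2.2,
                       n_killed = 6, n_controls = 4,
                       profile = list()) {
  assay <- match_assay(assay)
  stopifnot(length(assay) == 1L, length(depths_mbsf) >= 1L)
  if (incubation_time_d <= 0 || incubation_time_d > 10)
    stop_param("`incubation_time_d` must be in (0, 10] days")
  if (length(true_rates_pmol_cm3_d) != length(depths_mbsf))
    stop_param("`true_rates_pmol_cm3_d` must match `depths_mbsf` in length")
  prof_defaults <- list(
    breakpoint_mbsf = c(320, 360), shallow_log10_cells = 5.5,
    deep_log10_cells = 2.65, sulfate_boundary_mbsf = 600,
    sulfate_deep_mM = 4, acetate_peak_mM = 10, noise_rel = 0.02,
    cell_mql_cells_cm3 = 16)
  profile <- utils::modifyList(prof_defaults, profile)
  structure(list(
    seed = as.integer(seed), assay = assay, depths_mbsf = depths_mbsf,
    n_replicates = n_replicates,
    true_rates_pmol_cm3_d = true_rates_pmol_cm3_d,
    injected_activity_bq = injected_activity_bq,
    counting_time_s = counting_time_s,
    background_mean_bq = background_mean_bq,
    background_sd_bq = background_sd_bq,
    incubation_time_d = incubation_time_d,
    medium_conc_mM = medium_conc_mM, medium_vol_ml = medium_vol_ml,
    sediment_vol_ml = sediment_vol_ml, porosity = porosity,
    bulk_density_g_cm3 = bulk_density_g_cm3,
    n_killed = n_killed, n_controls = n_controls, profile = profile),
    class = "sim_config")
}

# Gaussian background truncated at zero
rbackground <- function(n, mean_bq, sd_bq) {
  pmax(stats::rnorm(n, mean_bq, sd_bq), 0)
}

# Poisson-count realization of an expected activity
rcounted_bq <- function(expected_bq, counting_time_s) {
  stats::rpois(length(expected_bq), expected_bq * counting_time_s) /
    counting_time_s
}

# Porewater substrate concentration (mM) the generator assumes at depth:
# depleted above the sulfate boundary, an erf-shaped recovery below it
# for SR; a low uniform DIC porewater pool for MG.
sim_porewater_mM <- function(config, depth_mbsf) {
  if (config$assay == "SR") {
    b <- config$profile$sulfate_boundary_mbsf
    ifelse(depth_mbsf <= b, 0.05,
           config$profile$sulfate_deep_mM *
             relative_concentration(pmax(depth_mbsf - b, 1e-9), 4e5))
  } else {
    rep(1, length(depth_mbsf))   # porewater DIC, mM
  }
}

#' Simulate radiotracer incubation vials and their control series
#'
#' Forward-models each vial: the expected turnover fraction is
#' \eqn{f = r t m / (\rho\, pool\, \alpha)} for true rate r (mol cm^-3
#' d^-1), product and substrate activities are Poisson-counted, and the
#' counting background is added to the product channel. Killed controls
#' (and the medium/drill-fluid/sediment control series) contain
#' background only and are emitted as rate-equivalents through the same
#' rate equation.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, writes `vials.csv` and
#'   `controls.csv` there.
#' @return list with data frames `vials` (canonical vial schema) and
#'   `controls` (`control_type`, `assay`, `value`, `unit`), plus the
#'   config used.
#' @export
simulate_incubation <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  alpha <- default_fractionation(config$assay)
  mass_g <- config$sediment_vol_ml * config$bulk_density_g_cm3
  depths <- rep(config$depths_mbsf, each = config$n_replicates)
  rates <- rep(config$true_rates_pmol_cm3_d, each = config$n_replicates)
  pw_mM <- sim_porewater_mM(config, depths)
  pool <- total_pool_moles(config$medium_conc_mM / 1000,
                           config$medium_vol_ml, pw_mM / 1000,
                           config$sediment_vol_ml, config$porosity)
  f_exp <- rates * 1e-12 * config$incubation_time_d * mass_g /
    (config$bulk_density_g_cm3 * pool * alpha)
  if (any(f_exp > 1))
    stop_param(paste0(
      "expected turnover fraction exceeds 1 for depth(s) %s: ",
      "lower the true rate or shorten the incubation"),
      paste(unique(depths[f_exp > 1]), collapse = ", "))
  n <- length(depths)
  bg <- rbackground(n, config$background_mean_bq, config$background_sd_bq)
  prod_bq <- rcounted_bq(config$injected_activity_bq * f_exp + bg,
                         config$counting_time_s)
  sub_bq <- rcounted_bq(config$injected_activity_bq * (1 - f_exp),
                        config$counting_time_s)
  vials <- data.frame(
    sample_id = sprintf("%s-%04.0f-%d", config$assay, depths,
                        sequence(rep(config$n_replicates,
                                     length(config$depths_mbsf)))),
    assay = config$assay, depth_mbsf = depths,
    activity_product_bq = prod_bq, activity_substrate_bq = sub_bq,
    medium_conc_mM = config$medium_conc_mM,
    medium_vol_ml = config$medium_vol_ml,
    porewater_conc_mM = pw_mM,
    sediment_vol_ml = config$sediment_vol_ml,
    porosity = config$porosity, alpha = alpha,
    bulk_density_g_cm3 = config$bulk_density_g_cm3,
    time_d = config$incubation_time_d, mass_g = mass_g,
    temp_C = insitu_temperature(depths),
    stringsAsFactors = FALSE)

  # background-only vials, expressed as rate-equivalents through the
  # same rate equation at the reference vial geometry
  ref_pool <- total_pool_moles(config$medium_conc_mM / 1000,
                               config$medium_vol_ml)
  bg_to_rate <- function(bq) {
    bq / config$injected_activity_bq * ref_pool * alpha *
      config$bulk_density_g_cm3 /
      (config$incubation_time_d * mass_g) * 1e12
  }
  ctrl_rows <- function(type, n_vals) {
    a <- rcounted_bq(rbackground(n_vals, config$background_mean_bq,
                                 config$background_sd_bq),
                     config$counting_time_s)
    data.frame(control_type = type, assay = config$assay,
               value = bg_to_rate(a), unit = "pmol_cm3_d",
               stringsAsFactors = FALSE)
  }
  blank_rows <- function(type, n_vals) {
    data.frame(control_type = type, assay = config$assay,
               value = rcounted_bq(
                 rbackground(n_vals, config$background_mean_bq,
                             config$background_sd_bq),
                 config$counting_time_s),
               unit = "bq", stringsAsFactors = FALSE)
  }
  controls <- rbind(
    ctrl_rows("killed", config$n_killed),
    ctrl_rows("medium", config$n_controls),
    ctrl_rows("drill_fluid", config$n_controls),
    ctrl_rows("sediment", config$n_controls),
    blank_rows("counter_blank", config$n_controls),
    blank_rows("distillation_blank", config$n_controls))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(vials, file.path(outdir, "vials.csv"),
                     row.names = FALSE)
    utils::write.csv(controls, file.path(outdir, "controls.csv"),
                     row.names = FALSE)
  }
  list(vials = vials, controls = controls, config = config)
}

#' Simulate geochemical and microbiological depth profiles
#'
#' Emits a wide profile table (temperature from the linear gradient,
#' erf-shaped sulfate below the boundary, an acetate bulge peaking in the
#' hot interval, a two-regime log-linear cell decline with a floor at the
#' minimum quantification limit, porosity and bulk density) and a
#' long-format species table for the energetics stage. With
#' `profile$noise_rel = 0` the columns equal their analytic shapes
#' exactly.
#'
#' @param config a [sim_config()].
#' @param depths_mbsf profile depths.
#' @param outdir optional directory; writes `profile.csv` and
#'   `species.csv`.
#' @return list with data frames `profile` and `species`.
#' @export
simulate_profile <- function(config = sim_config(),
                             depths_mbsf = seq(0, 1180, by = 20),
                             outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  p <- config$profile
  z <- depths_mbsf
  noisy <- function(x, scale = p$noise_rel) {
    pmax(x * (1 + stats::rnorm(length(x), 0, scale)), 0)
  }
  temp_C <- insitu_temperature(z)
  b <- p$sulfate_boundary_mbsf
  sulfate_mM <- noisy(ifelse(
    z <= b, 0.05,
    p$sulfate_deep_mM * relative_concentration(pmax(z - b, 1e-9), 4e5)))
  acetate_mM <- noisy(ifelse(
    z <= b, 0.05,
    p$acetate_peak_mM * exp(-((z - 950) / 220)^2)))
  dic_mM <- noisy(ifelse(z <= b, 5, 1))
  ch4_mM <- noisy(ifelse(z <= b, 5, 0.5))
  hs_umol_l <- rep(0, length(z))   # below detection throughout
  lo <- p$breakpoint_mbsf[1]; hi <- p$breakpoint_mbsf[2]
  w <- pmin(pmax((z - lo) / (hi - lo), 0), 1)
  log10_cells <- (1 - w) * (p$shallow_log10_cells - 1.3 * z / lo) +
    w * (p$deep_log10_cells - 1.3 * (z - hi) / 800)
  cells <- pmax(noisy(10^log10_cells, scale = 5 * p$noise_rel),
                p$cell_mql_cells_cm3)
  profile <- data.frame(
    depth_mbsf = z, temp_C = temp_C, sulfate_mM = sulfate_mM,
    acetate_mM = acetate_mM, dic_mM = dic_mM, ch4_mM = ch4_mM,
    hs_umol_l = hs_umol_l, cells_per_cm3 = cells,
    porosity = config$porosity,
    formation_factor = 14,
    bulk_density_g_cm3 = config$bulk_density_g_cm3)
  deep <- profile[profile$depth_mbsf > b, ]
  species <- do.call(rbind, lapply(seq_len(nrow(deep)), function(i) {
    data.frame(
      depth_mbsf = deep$depth_mbsf[i],
      species = c("SO4-2", "CH3COO-", "HCO3-", "HS-", "CH4"),
      conc_mol_l = c(deep$sulfate_mM[i], deep$acetate_mM[i],
                     deep$dic_mM[i], deep$hs_umol_l[i] * 1e-3,
                     deep$ch4_mM[i]) / 1000,
      stringsAsFactors = FALSE)
  }))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(profile, file.path(outdir, "profile.csv"),
                     row.names = FALSE)
    utils::write.csv(species, file.path(outdir, "species.csv"),
                     row.names = FALSE)
  }
  list(profile = profile, species = species)
}
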