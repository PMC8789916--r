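# Pipeline orchestration: schema validation, the end-to-end run
# (simulate -> rates -> budget -> energetics -> per-cell), and the
# machine-readable report.

# rule helpers return a violation message or NULL
.rule_nonneg <- function(x) if (any(is.finite(x) & x < 0)) "must be non-negative"
.rule_pos <- function(x) if (any(!is.finite(x) | x <= 0)) "must be positive"
.rule_frac <- function(x) if (any(!is.finite(x) | x < 0 | x > 1)) "must be in [0, 1]"
.rule_inset <- function(values) {
  force(values)
  function(x) {
    bad <- !x %in% values
    if (any(bad)) sprintf("must be one of: %s", paste(values, collapse = ", "))
  }
}

.schemas <- function() list(
  vials = list(
    required = c("sample_id", "assay", "depth_mbsf", "activity_product_bq",
                 "activity_substrate_bq", "medium_conc_mM", "medium_vol_ml",
                 "porewater_conc_mM", "sediment_vol_ml", "porosity", "alpha",
                 "bulk_density_g_cm3", "time_d", "mass_g", "temp_C"),
    rules = list(
      assay = .rule_inset(c("SR", "MG", "AOM")),
      activity_product_bq = .rule_nonneg,
      activity_substrate_bq = .rule_nonneg,
      medium_conc_mM = .rule_nonneg, porewater_conc_mM = .rule_nonneg,
      medium_vol_ml = .rule_pos, porosity = .rule_frac,
      alpha = .rule_pos, bulk_density_g_cm3 = .rule_pos,
      time_d = .rule_pos, mass_g = .rule_pos)),
  controls = list(
    required = c("control_type", "assay", "value", "unit"),
    rules = list(
      control_type = .rule_inset(c("counter_blank", "distillation_blank",
                                   "medium", "drill_fluid", "sediment",
                                   "killed")),
      assay = .rule_inset(c("SR", "MG", "AOM")),
      value = .rule_nonneg)),
  profile = list(
    required = c("depth_mbsf", "temp_C", "sulfate_mM", "acetate_mM",
                 "cells_per_cm3", "porosity", "bulk_density_g_cm3"),
    rules = list(
      depth_mbsf = .rule_nonneg, sulfate_mM = .rule_nonneg,
      acetate_mM = .rule_nonneg, cells_per_cm3 = .rule_nonneg,
      porosity = .rule_frac, bulk_density_g_cm3 = .rule_pos)),
  rates = list(
    required = c("sample_id", "depth_mbsf", "assay", "rate_pmol_cm3_d",
                 "turnover_fraction", "censored", "mbql"),
    rules = list(
      rate_pmol_cm3_d = .rule_nonneg,
      turnover_fraction = .rule_frac))
)

#' Validate a table against a registered schema
#'
#' Checks, order-insensitively, that all required columns are present and
#' that each column satisfies its rule; rule violations name the first
#' offending row.
#'
#' @param table data frame to check.
#' @param schema_name one of `"vials"`, `"controls"`, `"profile"`,
#'   `"rates"`.
#' @return data frame of violations (`row`, `column`, `rule`); zero rows
#'   when the table conforms.
#' @export
validate_table <- function(table, schema_name) {
  schemas <- .schemas()
  if (!schema_name %in% names(schemas))
    stop_param("unknown schema '%s' (have: %s)", schema_name,
               paste(names(schemas), collapse = ", "))
  schema <- schemas[[schema_name]]
  out <- list()
  for (col in setdiff(schema$required, names(table)))
    out[[length(out) + 1L]] <- data.frame(
      row = NA_integer_, column = col, rule = "required column missing",
      stringsAsFactors = FALSE)
  for (col in intersect(names(schema$rules), names(table))) {
    msg <- schema$rules[[col]](table[[col]])
    if (!is.null(msg)) {
      x <- table[[col]]
      # locate first offending row for the diagnostic
      viol <- which(vapply(seq_along(x),
                           function(i) !is.null(schema$rules[[col]](x[i])),
                           logical(1)))[1]
      out[[length(out) + 1L]] <- data.frame(
        row = viol, column = col, rule = msg, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(row = integer(), column = character(),
                  rule = character(), stringsAsFactors = FALSE)
}

stop_on_violations <- function(table, schema_name) {
  v <- validate_table(table, schema_name)
  if (nrow(v))
    stop_param("schema '%s' violated: %s", schema_name,
               paste(sprintf("%s (%s)", v$column, v$rule), collapse = "; "))
  invisible(table)
}

#' Rate table from a vial table and its control series
#'
#' Computes the substrate pool per vial, applies the tracer rate
#' equation, derives the MBQL from the killed controls of each assay, and
#' censors. This is the `rates` stage of the pipeline in one call.
#'
#' @param vials data frame conforming to the `vials` schema.
#' @param controls data frame conforming to the `controls` schema (killed
#'   series in rate-equivalent units).
#' @param sd_convention passed to [mbql()].
#' @return data frame conforming to the `rates` schema (column `mbql`
#'   carries the limit applied to each row).
#' @export
rates_stage <- function(vials, controls,
                        sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  stop_on_violations(vials, "vials")
  stop_on_violations(controls, "controls")
  vials$pool_total_mol <- total_pool_moles(
    vials$medium_conc_mM / 1000, vials$medium_vol_ml,
    vials$porewater_conc_mM / 1000, vials$sediment_vol_ml, vials$porosity)
  out <- list()
  for (a in unique(vials$assay)) {
    sub <- vials[vials$assay == a, ]
    res <- turnover_rate(sub)
    killed <- controls$value[controls$assay == a &
                               controls$control_type == "killed" &
                               controls$unit == "pmol_cm3_d"]
    lim <- mbql(killed, sd_convention = sd_convention, assay = a)
    out[[a]] <- censor_rates(res, lim)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  data.frame(sample_id = res$sample_id, depth_mbsf = res$depth_mbsf,
             assay = res$assay, rate_pmol_cm3_d = res$rate_pmol_cm3_d,
             turnover_fraction = res$turnover_fraction,
             censored = res$censored, mbql = res$limit_used,
             stringsAsFactors = FALSE)
}

#' Pipeline run configuration
#'
#' @param seed integer seed driving both synthetic assays and the
#'   profile.
#' @param sr_config,mg_config [sim_config()]s for the two assays;
#'   derived from `seed` by default.
#' @param sd_convention MBQL standard-deviation convention.
#' @param diffusion_form dialect for [relative_concentration()].
#' @param functional_fraction,growth_yield,correct_recovery population
#'   assumptions for the per-cell stage.
#' @param budget_depths_mbsf depths for the sulfate-budget table.
#' @param burial_time_yr time since burial onset, yr.
#' @param repair_params repair-cost parameterization.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1,
                            sr_config = sim_config(seed = seed, assay = "SR"),
                            mg_config = sim_config(seed = seed + 1000L,
                                                   assay = "MG"),
                            sd_convention = "sample",
                            diffusion_form = "standard",
                            functional_fraction = 1, growth_yield = 0.01,
                            correct_recovery = TRUE,
                            budget_depths_mbsf = c(750, 800, 850, 900, 1000),
                            burial_time_yr = 4e5,
                            repair_params = repair_cost_params()) {
  structure(list(seed = as.integer(seed), sr_config = sr_config,
                 mg_config = mg_config, sd_convention = sd_convention,
                 diffusion_form = diffusion_form,
                 functional_fraction = functional_fraction,
                 growth_yield = growth_yield,
                 correct_recovery = correct_recovery,
                 budget_depths_mbsf = budget_depths_mbsf,
                 burial_time_yr = burial_time_yr,
                 repair_params = repair_params),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulate (or accept) incubation and profile data, compute censored
#' rate tables for both assays, evaluate the sulfate budget, the in-situ
#' reaction energetics, and the per-cell/biomass stage, and assemble a
#' machine-readable report of the headline quantities. Deterministic for
#' a fixed config.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory; stage CSVs and `report.json`
#'   are written there.
#' @return list of class `"hotbio_report"` with elements `rates`,
#'   `limits`, `budget`, `energetics`, `per_cell`, `profile`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sims <- list(SR = simulate_incubation(config$sr_config),
               MG = simulate_incubation(config$mg_config))
  prof <- simulate_profile(config$sr_config)
  stop_on_violations(prof$profile, "profile")

  rates <- do.call(rbind, lapply(sims, function(s)
    rates_stage(s$vials, s$controls, config$sd_convention)))
  rownames(rates) <- NULL
  limits <- lapply(sims, function(s)
    mbql(s$controls$value[s$controls$control_type == "killed"],
         sd_convention = config$sd_convention,
         assay = s$vials$assay[1]))

  column <- sediment_column(
    porosity = mean(prof$profile$porosity),
    formation_factor = mean(prof$profile$formation_factor),
    bulk_density_g_cm3 = mean(prof$profile$bulk_density_g_cm3))
  deep_sr <- rates[rates$assay == "SR" & rates$depth_mbsf > 360 &
                     !rates$censored, ]
  srr_deep <- if (nrow(deep_sr)) stats::median(deep_sr$rate_pmol_cm3_d) else 0.3
  budget <- sulfate_budget_table(config$budget_depths_mbsf,
                                 t_yr = config$burial_time_yr,
                                 column = column,
                                 srr_pmol_cm3_d = srr_deep,
                                 form = config$diffusion_form)

  energ <- energetics_profile(prof$species, column = column)

  # per-cell stage at the energetics depths, using the acetate-fuelled
  # sulfate reduction energy and the nearest measured SR rate / cell count
  esr <- energ[energ$reaction == "SR_acetate", ]
  nearest <- function(x, table, value) {
    vapply(x, function(xi) value[which.min(abs(table - xi))], numeric(1))
  }
  sr_rates <- rates[rates$assay == "SR", ]
  per_cell <- per_cell_table(
    depth_mbsf = esr$depth_mbsf,
    rate_pmol_cm3_d = nearest(esr$depth_mbsf, sr_rates$depth_mbsf,
                              sr_rates$rate_pmol_cm3_d),
    abundance_cells_cm3 = nearest(esr$depth_mbsf, prof$profile$depth_mbsf,
                                  prof$profile$cells_per_cm3),
    dG_kj_mol = esr$dG_kj_mol, temp_C = esr$temp_C,
    functional_fraction = config$functional_fraction,
    growth_yield = config$growth_yield,
    correct_recovery = config$correct_recovery,
    params = config$repair_params)

  cost_100 <- repair_cost(100, config$repair_params)
  report <- list(
    seed = config$seed,
    mbql_sr_pmol_cm3_d = limits$SR$mbql,
    mbql_mg_pmol_cm3_d = limits$MG$mbql,
    theta_sq = column$theta_sq,
    tau_days = depletion_time(28e-3, column$porosity, 0.3),
    avg_srr_22_pmol_cm3_d = average_srr(22e-3, column$porosity,
                                        config$burial_time_yr),
    avg_srr_28_pmol_cm3_d = average_srr(28e-3, column$porosity,
                                        config$burial_time_yr),
    corg_22_wt_pct = corg_equivalent(22e-3, column$porosity,
                                     column$bulk_density_g_cm3),
    corg_28_wt_pct = corg_equivalent(28e-3, column$porosity,
                                     column$bulk_density_g_cm3),
    pct_lowered_750 = 100 * (1 - relative_concentration(
      150, config$burial_time_yr, column = column,
      form = config$diffusion_form)),
    pct_lowered_800 = 100 * (1 - relative_concentration(
      200, config$burial_time_yr, column = column,
      form = config$diffusion_form)),
    pct_lowered_850 = 100 * (1 - relative_concentration(
      250, config$burial_time_yr, column = column,
      form = config$diffusion_form)),
    repair_cost_100C_kj_cell_d = cost_100,
    threshold_sr_fmol_cell_d = threshold_cell_rate(cost_100, -105),
    threshold_mg_fmol_cell_d = threshold_cell_rate(cost_100, -43))

  out <- structure(list(rates = rates, limits = limits, budget = budget,
                        energetics = energ, per_cell = per_cell,
                        profile = prof$profile, report = report),
                   class = "hotbio_report")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rates, file.path(outdir, "rates.csv"),
                     row.names = FALSE)
    utils::write.csv(budget, file.path(outdir, "budget.csv"),
                     row.names = FALSE)
    utils::write.csv(energ, file.path(outdir, "dG.csv"), row.names = FALSE)
    utils::write.csv(per_cell, file.path(outdir, "percell.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.hotbio_report <- function(x, ...) {
  r <- x$report
  cat("hotbio pipeline report\n")
  cat(sprintf("  MBQL: SR %.3g, MG %.3g pmol cm^-3 d^-1\n",
              r$mbql_sr_pmol_cm3_d, r$mbql_mg_pmol_cm3_d))
  cat(sprintf("  sulfate depletion time at 0.3 pmol cm^-3 d^-1: %.3g d (%.3g yr)\n",
              r$tau_days, r$tau_days / 365.25))
  cat(sprintf("  mean SRR over burial: %.3g-%.3g pmol cm^-3 d^-1\n",
              r$avg_srr_22_pmol_cm3_d, r$avg_srr_28_pmol_cm3_d))
  cat(sprintf("  Corg equivalent: %.2g-%.2g wt%%\n",
              r$corg_22_wt_pct, r$corg_28_wt_pct))
  cat(sprintf("  diffusive lowering at 750/800/850 mbsf: %.1f/%.1f/%.2f %%\n",
              r$pct_lowered_750, r$pct_lowered_800, r$pct_lowered_850))
  cat(sprintf("  repair thresholds: %.2g (SR), %.2g (MG) fmol cell^-1 d^-1\n",
              r$threshold_sr_fmol_cell_d, r$threshold_mg_fmol_cell_d))
  invisible(x)
}
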