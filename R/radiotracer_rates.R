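# Radiotracer turnover rates and the killed-control detection limit.
#
# The rate equation is the classical single-timepoint tracer turnover
# model: the fraction of injected label recovered in the product pool,
# times the (unlabelled) substrate pool, times an isotopic fractionation
# correction, per unit wet-sediment volume and incubation time.

#' Default isotopic fractionation correction per assay
#'
#' 1.06 for \eqn{^{35}}S sulfate reduction, 1.08 for \eqn{^{14}}C
#' methanogenesis from DIC. The anaerobic-oxidation-of-methane layout
#' reuses the sulfur-style 1.06 by default; override as needed.
#'
#' @param assay character vector, any of `"SR"`, `"MG"`, `"AOM"`.
#' @return numeric vector of fractionation factors.
#' @export
default_fractionation <- function(assay) {
  assay <- match_assay(assay)
  unname(c(SR = 1.06, MG = 1.08, AOM = 1.06)[assay])
}

match_assay <- function(assay) {
  assay <- as.character(assay)
  bad <- !assay %in% c("SR", "MG", "AOM")
  if (any(bad))
    stop_param("unknown assay: %s", paste(unique(assay[bad]), collapse = ", "))
  assay
}

#' Construct a single radiotracer incubation vial record
#'
#' Validates the invariants of one slurry incubation and returns a one-row
#' data frame in the canonical vial layout accepted by [turnover_rate()].
#'
#' @param sample_id identifier.
#' @param assay `"SR"` (sulfate reduction), `"MG"` (methanogenesis) or
#'   `"AOM"`.
#' @param activity_product_bq radioactivity recovered in the product pool
#'   at the end of the incubation (TRIS for SR; CH4-derived CO2 for MG), Bq.
#' @param activity_substrate_bq residual radioactivity of the substrate
#'   pool (sulfate for SR, DIC for MG), Bq.
#' @param pool_total_mol total unlabelled substrate in the vial
#'   (medium + porewater contribution), mol. See [total_pool_moles()].
#' @param bulk_density_g_cm3 wet bulk density of the sediment, g cm^-3.
#' @param time_d incubation time, days.
#' @param mass_g sediment mass in the vial, g.
#' @param alpha isotopic fractionation correction; defaults per assay via
#'   [default_fractionation()].
#' @param depth_mbsf,temp_C optional metadata (m below seafloor, deg C).
#' @return one-row data frame of class `"incubation_vial"`.
#' @export
incubation_vial <- function(sample_id, assay, activity_product_bq,
                            activity_substrate_bq, pool_total_mol,
                            bulk_density_g_cm3, time_d, mass_g,
                            alpha = default_fractionation(assay),
                            depth_mbsf = NA_real_, temp_C = NA_real_) {
  assay <- match_assay(assay)
  check_nonnegative(activity_product_bq, "activity_product_bq")
  check_nonnegative(activity_substrate_bq, "activity_substrate_bq")
  if (activity_product_bq + activity_substrate_bq <= 0)
    stop_param("undefined turnover fraction: both activities are zero")
  check_positive(pool_total_mol, "pool_total_mol")
  check_positive(bulk_density_g_cm3, "bulk_density_g_cm3")
  check_positive(time_d, "time_d")
  check_positive(mass_g, "mass_g")
  check_positive(alpha, "alpha")
  out <- data.frame(
    sample_id = as.character(sample_id), assay = assay,
    depth_mbsf = depth_mbsf,
    activity_product_bq = activity_product_bq,
    activity_substrate_bq = activity_substrate_bq,
    pool_total_mol = pool_total_mol, alpha = alpha,
    bulk_density_g_cm3 = bulk_density_g_cm3,
    time_d = time_d, mass_g = mass_g, temp_C = temp_C,
    stringsAsFactors = FALSE
  )
  class(out) <- c("incubation_vial", "data.frame")
  out
}

#' Total substrate pool in an incubation vial
#'
#' Sum of the substrate added with the medium and the substrate carried in
#' by the natural sediment porewater (concentration times porewater
#' volume, i.e. porosity times wet-sediment volume). Tracer additions are
#' excluded: they do not change the pool detectably.
#'
#' @param medium_conc_mol_l substrate concentration in the medium, mol L^-1.
#' @param medium_vol_ml medium volume, mL.
#' @param porewater_conc_mol_l substrate concentration in porewater,
#'   mol L^-1 (default 0).
#' @param sediment_vol_ml wet sediment volume, mL (default 0).
#' @param porosity volume fraction of porewater in the wet sediment.
#' @return total substrate, mol.
#' @export
#' @examples
#' # 5 mM sulfate medium, 5 mL, no porewater contribution
#' total_pool_moles(5e-3, 5)                    # 2.5e-5 mol
total_pool_moles <- function(medium_conc_mol_l, medium_vol_ml,
                             porewater_conc_mol_l = 0, sediment_vol_ml = 0,
                             porosity = 0) {
  check_nonnegative(medium_conc_mol_l, "medium_conc_mol_l")
  check_nonnegative(porewater_conc_mol_l, "porewater_conc_mol_l")
  check_positive(medium_vol_ml, "medium_vol_ml")
  check_nonnegative(sediment_vol_ml, "sediment_vol_ml")
  if (any(porosity < 0 | porosity > 1)) stop_param("`porosity` must be in [0, 1]")
  medium_conc_mol_l * medium_vol_ml / 1000 +
    porewater_conc_mol_l * porosity * sediment_vol_ml / 1000
}

#' Convert raw scintillation counts to activity
#'
#' Pass-through by default: the pipeline accepts pre-converted Bq. Supply
#' a counting efficiency and/or counting time to convert counter output.
#'
#' @param counts counts accumulated over `counting_time_s` (with the
#'   defaults, interpreted directly as Bq).
#' @param efficiency counting efficiency in (0, 1].
#' @param counting_time_s counting time, s.
#' @return activity, Bq.
#' @export
counts_to_bq <- function(counts, efficiency = 1, counting_time_s = 1) {
  check_nonnegative(counts, "counts")
  check_positive(efficiency, "efficiency")
  check_positive(counting_time_s, "counting_time_s")
  if (any(efficiency > 1)) stop_param("`efficiency` must be in (0, 1]")
  counts / (efficiency * counting_time_s)
}

#' Volumetric turnover rate from a radiotracer incubation
#'
#' Implements the single-timepoint tracer model
#' \deqn{rate = \frac{A_{prod}}{A_{prod} + A_{sub}} \times pool \times
#'   \alpha \times \rho / (t \times m)}
#' where the pool is in mol, \eqn{\rho} the wet bulk density (g cm^-3),
#' \eqn{t} the incubation time (d) and \eqn{m} the sediment mass (g), so
#' that \eqn{m/\rho} is the wet-sediment volume. The result is returned in
#' pmol per cm^3 wet sediment per day.
#'
#' @param vials an [incubation_vial()] object or a data frame with the
#'   canonical vial columns (`activity_product_bq`,
#'   `activity_substrate_bq`, `pool_total_mol`, `alpha`,
#'   `bulk_density_g_cm3`, `time_d`, `mass_g`, plus optional metadata).
#' @return data frame of class `"rate_result"` with columns `sample_id`,
#'   `assay`, `depth_mbsf`, `rate_pmol_cm3_d`, `turnover_fraction`,
#'   `censored` (NA until [censor_rates()] is applied) and `limit_used`.
#' @export
#' @examples
#' v <- incubation_vial("s1", "SR", activity_product_bq = 50,
#'                      activity_substrate_bq = 9950,
#'                      pool_total_mol = 2.5e-5, bulk_density_g_cm3 = 2,
#'                      time_d = 10, mass_g = 10)
#' turnover_rate(v)
turnover_rate <- function(vials) {
  df <- as.data.frame(vials)
  required <- c("activity_product_bq", "activity_substrate_bq",
                "pool_total_mol", "alpha", "bulk_density_g_cm3",
                "time_d", "mass_g")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_param("vial table lacks column(s): %s", paste(missing, collapse = ", "))
  check_nonnegative(df$activity_product_bq, "activity_product_bq")
  check_nonnegative(df$activity_substrate_bq, "activity_substrate_bq")
  total <- df$activity_product_bq + df$activity_substrate_bq
  if (any(total <= 0))
    stop_param("undefined turnover fraction: both activities are zero")
  check_positive(df$pool_total_mol, "pool_total_mol")
  check_positive(df$alpha, "alpha")
  check_positive(df$bulk_density_g_cm3, "bulk_density_g_cm3")
  check_positive(df$time_d, "time_d")
  check_positive(df$mass_g, "mass_g")

  frac <- df$activity_product_bq / total
  rate_mol <- frac * df$pool_total_mol * df$alpha *
    df$bulk_density_g_cm3 / (df$time_d * df$mass_g)
  out <- data.frame(
    sample_id = if ("sample_id" %in% names(df)) as.character(df$sample_id)
                else as.character(seq_len(nrow(df))),
    assay = if ("assay" %in% names(df)) match_assay(df$assay)
            else NA_character_,
    depth_mbsf = if ("depth_mbsf" %in% names(df)) df$depth_mbsf else NA_real_,
    rate_pmol_cm3_d = rate_mol * 1e12,
    turnover_fraction = frac,
    censored = NA,
    limit_used = NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("rate_result", "data.frame")
  out
}

#' Construct a control series
#'
#' A labelled set of blank or control measurements feeding the
#' detection-limit statistic and the control-consistency report.
#'
#' @param control_type one of `"counter_blank"`, `"distillation_blank"`,
#'   `"medium"`, `"drill_fluid"`, `"sediment"`, `"killed"`.
#' @param assay `"SR"` or `"MG"`.
#' @param values non-negative measurements; Bq for counter/distillation
#'   blanks, rate-equivalents (pmol cm^-3 d^-1) for incubated controls.
#' @param unit unit label carried through to reports.
#' @return list of class `"control_series"`.
#' @export
control_series <- function(control_type, assay, values,
                           unit = c("pmol_cm3_d", "bq")) {
  types <- c("counter_blank", "distillation_blank", "medium",
             "drill_fluid", "sediment", "killed")
  control_type <- match.arg(control_type, types)
  assay <- match_assay(assay)
  stopifnot(length(assay) == 1L)
  unit <- match.arg(unit)
  check_nonnegative(values, "values")
  structure(list(control_type = control_type, assay = assay,
                 values = as.numeric(values), unit = unit),
            class = "control_series")
}

#' Minimum biological quantification limit from killed controls
#'
#' The MBQL is the mean of the killed-control (gamma-irradiated sediment)
#' measurements plus three standard deviations. The killed controls
#' quantify abiotic tracer turnover; rates below this limit cannot be
#' distinguished from non-biological signal.
#'
#' @param killed a `"killed"` [control_series()] or a numeric vector of
#'   killed-control rate-equivalents.
#' @param sd_convention `"sample"` (n-1 denominator, default) or
#'   `"population"` (n).
#' @param assay assay label, taken from the series when available.
#' @return list of class `"detection_limit"` with elements `assay`,
#'   `mbql`, `mean_killed`, `sd_killed`, `n`, `sd_convention`.
#' @export
#' @examples
#' mbql(c(0.01, 0.03, 0.05))$mbql    # 0.03 + 3 * 0.02 = 0.09
mbql <- function(killed, sd_convention = c("sample", "population"),
                 assay = NULL) {
  sd_convention <- match.arg(sd_convention)
  if (inherits(killed, "control_series")) {
    if (killed$control_type != "killed")
      stop_param("detection limit requires a 'killed' control series, got '%s'",
                 killed$control_type)
    if (is.null(assay)) assay <- killed$assay
    killed <- killed$values
  }
  killed <- as.numeric(killed)
  if (length(killed) < 2L)
    stop_param("insufficient data: need at least 2 killed-control values")
  check_nonnegative(killed, "killed")
  m <- mean(killed)
  s <- stats::sd(killed)
  if (sd_convention == "population")
    s <- s * sqrt((length(killed) - 1) / length(killed))
  structure(list(assay = if (is.null(assay)) NA_character_ else assay,
                 mbql = m + 3 * s, mean_killed = m, sd_killed = s,
                 n = length(killed), sd_convention = sd_convention),
            class = "detection_limit")
}

#' @export
print.detection_limit <- function(x, ...) {
  cat(sprintf(
    "MBQL (%s): %.4g = mean %.4g + 3 x sd %.4g  [n = %d, %s sd]\n",
    ifelse(is.na(x$assay), "?", x$assay), x$mbql, x$mean_killed,
    x$sd_killed, x$n, x$sd_convention))
  invisible(x)
}

#' Flag rates below the detection limit
#'
#' Marks each rate strictly below the MBQL as censored. Censoring is a
#' flag, not deletion: values are preserved so that downstream budgets can
#' still use them as bounds. A rate exactly at the limit is quantifiable
#' (the reporting rule is "rates > MBQL").
#'
#' @param results a `"rate_result"` data frame from [turnover_rate()].
#' @param limit a `"detection_limit"` from [mbql()].
#' @return `results` with `censored` and `limit_used` filled in.
#' @export
censor_rates <- function(results, limit) {
  stopifnot(inherits(limit, "detection_limit"))
  df <- as.data.frame(results)
  if (!all(c("rate_pmol_cm3_d", "assay") %in% names(df)))
    stop_param("`results` must be a rate table with rate_pmol_cm3_d and assay")
  if (!is.na(limit$assay)) {
    mismatch <- !is.na(df$assay) & df$assay != limit$assay
    if (any(mismatch))
      stop_param("assay mismatch: limit is for %s but results include %s",
                 limit$assay,
                 paste(unique(df$assay[mismatch]), collapse = ", "))
  }
  df$censored <- df$rate_pmol_cm3_d < limit$mbql
  df$limit_used <- limit$mbql
  class(df) <- c("rate_result", "data.frame")
  df
}

#' Consistency report for the control hierarchy
#'
#' Checks, per assay, whether each non-medium control series has a mean
#' within one standard deviation of its medium control — the quality rule
#' used to accept the blank structure of an experiment.
#'
#' @param series list of [control_series()] objects; must include a
#'   `"medium"` series for every assay represented.
#' @return data frame with one row per non-medium series: `control_type`,
#'   `assay`, `mean`, `medium_mean`, `medium_sd`, `within_1sd`.
#' @export
control_consistency <- function(series) {
  stopifnot(is.list(series), all(vapply(series, inherits, TRUE, "control_series")))
  assays <- vapply(series, `[[`, "", "assay")
  types <- vapply(series, `[[`, "", "control_type")
  out <- list()
  for (a in unique(assays)) {
    idx <- which(assays == a)
    med <- idx[types[idx] == "medium"]
    if (!length(med))
      stop_param("missing medium control series for assay %s", a)
    med_vals <- unlist(lapply(series[med], `[[`, "values"))
    med_mean <- mean(med_vals)
    med_sd <- stats::sd(med_vals)
    for (i in idx[types[idx] != "medium"]) {
      s <- series[[i]]
      out[[length(out) + 1L]] <- data.frame(
        control_type = s$control_type, assay = a,
        mean = mean(s$values), medium_mean = med_mean,
        medium_sd = med_sd,
        within_1sd = abs(mean(s$values) - med_mean) <= med_sd,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
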