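#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

DAYS_PER_YEAR <- 365.25

#' Construct a model configuration
#'
#' Low-level constructor assembling the full parameter set of the
#' cost-utility model: economic settings, treatment profiles, baseline risks,
#' costs, utilities, demographics, treatment-sequence strategies and the
#' uncertain-parameter table driving sensitivity analyses. Most users start
#' from [builtin_basecase()] or [synth_config()] rather than calling this
#' directly.
#'
#' @param settings,treatments,baselines,costs,utilities,demographics,strategies,estimates
#'   Components as documented in the package vignette.
#' @param validate Run [validate_config()] before returning?
#' @return An object of class `szcea_config`.
#' @export
new_config <- function(settings, treatments, baselines, costs, utilities,
                       demographics, strategies, estimates, validate = TRUE) {
  settings$n_cycles <- as.integer(
    floor(settings$horizon_years * DAYS_PER_YEAR / settings$cycle_length_days)
  )
  cfg <- structure(
    list(settings = settings, treatments = treatments, baselines = baselines,
         costs = costs, utilities = utilities, demographics = demographics,
         strategies = strategies, estimates = estimates),
    class = "szcea_config"
  )
  if (validate) validate_config(cfg)
  cfg
}

#' @export
print.szcea_config <- function(x, ...) {
  cat(sprintf(
    "<szcea_config> %d treatments, %d strategies, %d cycles of %g days over %g years\n",
    length(x$treatments), length(x$strategies), x$settings$n_cycles,
    x$settings$cycle_length_days, x$settings$horizon_years))
  invisible(x)
}

#' Cycle length in years for a configuration
#' @param config A `szcea_config`.
#' @return Cycle length in years.
#' @export
cycle_years <- function(config) config$settings$cycle_length_days / DAYS_PER_YEAR

#' Validate a model configuration
#'
#' Checks every structural invariant of the configuration and reports *all*
#' violations at once, not just the first.
#'
#' @param config A `szcea_config`.
#' @return `config`, invisibly; errors with the full violation list otherwise.
#' @export
validate_config <- function(config) {
  bad <- character()
  note <- function(msg) bad[[length(bad) + 1L]] <<- msg

  s <- config$settings
  if (!isTRUE(s$cycle_length_days > 0)) note("settings.cycle_length_days: must be > 0")
  if (!isTRUE(s$discount_rate_annual >= 0 && s$discount_rate_annual <= 0.2))
    note("settings.discount_rate_annual: must be in [0, 0.2]")
  if (length(s$wtp_thresholds) < 1 || any(s$wtp_thresholds <= 0) ||
      is.unsorted(s$wtp_thresholds, strictly = TRUE))
    note("settings.wtp_thresholds: must be positive and strictly ascending")
  expect_nc <- floor(s$horizon_years * DAYS_PER_YEAR / s$cycle_length_days)
  if (!identical(as.integer(s$n_cycles), as.integer(expect_nc)))
    note("settings.n_cycles: inconsistent with horizon and cycle length")

  for (nm in names(config$treatments)) {
    tr <- config$treatments[[nm]]
    ratios <- c("rr_disc_acute_vs_placebo", "hr_disc_maint_vs_quetiapine",
                "hr_relapse_vs_quetiapine", "rr_weight_gain_vs_placebo",
                "rr_eps_vs_placebo", "rr_diabetes_vs_olanzapine")
    for (f in ratios) {
      if (!isTRUE(tr[[f]] > 0)) note(sprintf("treatments.%s.%s: ratio must be > 0", nm, f))
    }
    if (is.null(tr$components)) {
      if (!isTRUE(tr$daily_dose_mg >= 0)) note(sprintf("treatments.%s.daily_dose_mg: must be >= 0", nm))
      if (!isTRUE(tr$unit_cost_per_mg >= 0)) note(sprintf("treatments.%s.unit_cost_per_mg: must be >= 0", nm))
    } else if (!all(tr$components %in% names(config$treatments))) {
      note(sprintf("treatments.%s.components: unresolved component treatment", nm))
    }
  }

  b <- config$baselines
  for (f in c("p_disc_placebo_acute", "p_weight_gain_placebo", "p_eps_placebo",
              "p_diabetes_olanzapine")) {
    if (!isTRUE(b[[f]] >= 0 && b[[f]] <= 1)) note(sprintf("baselines.%s: probability outside [0,1]", f))
  }
  if (!isTRUE(b$prop_relapse_adherent > 0 && b$prop_relapse_adherent < 1))
    note("baselines.prop_relapse_adherent: must be strictly inside (0,1)")
  for (f in c("disc_baseline", "relapse_baseline")) {
    if (!inherits(b[[f]], "surv_spec")) note(sprintf("baselines.%s: not a surv_spec", f))
  }

  co <- config$costs
  if (!isTRUE(co$outpatient_acute_relapse >= 0)) note("costs.outpatient_acute_relapse: must be >= 0")
  if (!isTRUE(co$outpatient_stable >= 0)) note("costs.outpatient_stable: must be >= 0")
  for (st in c("acute", "stable", "relapse")) {
    if (!isTRUE(co$hosp_prob[[st]] >= 0 && co$hosp_prob[[st]] <= 1))
      note(sprintf("costs.hosp_prob.%s: probability outside [0,1]", st))
    if (!isTRUE(co$hosp_los_days[[st]] >= 0)) note(sprintf("costs.hosp_los_days.%s: must be >= 0", st))
    if (!isTRUE(co$hosp_daily_cost[[st]] >= 0)) note(sprintf("costs.hosp_daily_cost.%s: must be >= 0", st))
  }
  for (ae in c("weight_gain", "eps", "diabetes")) {
    if (!isTRUE(co$ae_cost[[ae]] >= 0)) note(sprintf("costs.ae_cost.%s: must be >= 0", ae))
  }

  u <- config$utilities
  if (!isTRUE(u$u_stable >= 0 && u$u_stable <= 1)) note("utilities.u_stable: utility outside [0,1]")
  if (!isTRUE(u$u_acute_relapse >= 0 && u$u_acute_relapse <= 1))
    note("utilities.u_acute_relapse: utility outside [0,1]")
  if (isTRUE(u$u_stable < u$u_acute_relapse))
    note("utilities: u_stable must be >= u_acute_relapse")
  for (ae in c("weight_gain", "eps", "diabetes")) {
    if (!isTRUE(u$disutility[[ae]] >= 0 && u$disutility[[ae]] <= 1))
      note(sprintf("utilities.disutility.%s: decrement outside [0,1]", ae))
  }

  d <- config$demographics
  if (!isTRUE(d$prop_male >= 0 && d$prop_male <= 1)) note("demographics.prop_male: outside [0,1]")
  if (!isTRUE(d$smr_male >= 1)) note("demographics.smr_male: SMR must be >= 1")
  if (!isTRUE(d$smr_female >= 1)) note("demographics.smr_female: SMR must be >= 1")
  lt <- d$life_table
  if (is.null(lt) || !all(c("age", "sex", "q_annual") %in% names(lt))) {
    note("demographics.life_table: missing or lacks columns age/sex/q_annual")
  } else {
    if (any(lt$q_annual < 0 | lt$q_annual > 1)) note("demographics.life_table: q_annual outside [0,1]")
    need <- seq(floor(d$start_age), ceiling(d$start_age + s$horizon_years + 1))
    for (sx in c("male", "female")) {
      have <- lt$age[lt$sex == sx]
      if (!all(need %in% have))
        note(sprintf("demographics.life_table: ages %s not covered for %s",
                     paste(setdiff(need, have), collapse = ","), sx))
    }
  }

  if (length(config$strategies) < 1) note("strategies: at least one strategy required")
  for (st in config$strategies) {
    if (length(st$lines) < 1) note(sprintf("strategies.%s: needs >= 1 line", st$name))
    miss <- setdiff(st$lines, names(config$treatments))
    if (length(miss))
      note(sprintf("strategies.%s: undefined treatment(s) %s", st$name,
                   paste(miss, collapse = ",")))
    if (!identical(st$exhaustion_policy, "repeat_last"))
      note(sprintf("strategies.%s: unknown exhaustion policy", st$name))
  }

  est <- config$estimates
  if (!is.null(est) && nrow(est)) {
    if (any(!(est$low <= est$point & est$point <= est$high)))
      note("estimates: require low <= point <= high for every row")
    if (any(!est$family %in% c("lognormal", "beta", "gamma", "uniform")))
      note("estimates: unknown PSA family")
  }

  if (length(bad)) {
    stop(paste0("invalid configuration (", length(bad), " violation(s)):\n  ",
                paste(bad, collapse = "\n  ")), call. = FALSE)
  }
  invisible(config)
}

# ---- path access ------------------------------------------------------------

#' Get or set a configuration value by dotted path
#'
#' Paths address nested fields, e.g.
#' `"treatments.lurasidone.hr_relapse_vs_quetiapine"` or
#' `"costs.ae_cost.diabetes"`. Used by the sensitivity module to perturb one
#' parameter at a time.
#'
#' @param config A `szcea_config`.
#' @param path Dotted path string.
#' @param value Replacement value (for `config_set`).
#' @return `config_get`: the value. `config_set`: the modified configuration
#'   (derived fields such as `n_cycles` are recomputed).
#' @export
config_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- config
  for (k in keys) {
    out <- out[[k]]
    if (is.null(out)) stop(sprintf("path '%s' not found at '%s'", path, k), call. = FALSE)
  }
  out
}

#' @rdname config_get
#' @export
config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  config <- assign_path(config, keys, unname(value))
  config$settings$n_cycles <- as.integer(floor(
    config$settings$horizon_years * DAYS_PER_YEAR / config$settings$cycle_length_days))
  config
}

assign_path <- function(x, keys, value) {
  if (length(keys) == 1L) {
    if (is.null(x[[keys]])) stop(sprintf("unknown field '%s'", keys), call. = FALSE)
    x[[keys]] <- value
  } else {
    x[[keys[1]]] <- assign_path(x[[keys[1]]], keys[-1], value)
  }
  x
}

# ---- serialisation ----------------------------------------------------------

#' Read a model configuration from a YAML file
#'
#' The on-disk format is hierarchical YAML mirroring the configuration
#' sections (`settings`, `treatments`, `baselines`, `costs`, `utilities`,
#' `demographics`, `strategies`, `estimates`); probabilities are fractions,
#' money in CN Yuan, times in the units stated per field. The life table is
#' embedded as a column table (`age`, `sex`, `q_annual`).
#'
#' @param path File path.
#' @return A validated `szcea_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(sprintf("config parse failure in '%s': %s", path, conditionMessage(e)), call. = FALSE)
  })
  for (sec in c("settings", "treatments", "baselines", "costs", "utilities",
                "demographics", "strategies")) {
    if (is.null(raw[[sec]])) stop(sprintf("config missing section '%s'", sec), call. = FALSE)
  }
  raw$baselines$disc_baseline <- spec_from_list(raw$baselines$disc_baseline)
  raw$baselines$relapse_baseline <- spec_from_list(raw$baselines$relapse_baseline)
  raw$demographics$life_table <- as_tibble(raw$demographics$life_table)
  est <- raw$estimates
  raw$estimates <- if (is.null(est)) empty_estimates() else {
    e <- as_tibble(est)
    e$owsa_only <- as.logical(e$owsa_only)
    e
  }
  new_config(raw$settings, raw$treatments, raw$baselines, raw$costs,
             raw$utilities, raw$demographics, raw$strategies, raw$estimates)
}

#' Write a model configuration to a YAML file
#'
#' Round-trip stable with [load_config()]: numbers are written with 15
#' significant digits.
#'
#' @param config A validated `szcea_config`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  out$baselines$disc_baseline <- spec_to_list(out$baselines$disc_baseline)
  out$baselines$relapse_baseline <- spec_to_list(out$baselines$relapse_baseline)
  out$demographics$life_table <- as.list(out$demographics$life_table)
  out$estimates <- as.list(out$estimates)
  txt <- yaml::as.yaml(out, precision = 15L)
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write config to '%s'", path), call. = FALSE)
  invisible(path)
}

spec_to_list <- function(sp) list(family = sp$family, scale = sp$scale, shape = sp$shape)
spec_from_list <- function(x) {
  if (is.null(x$family)) stop("survival spec in config lacks 'family'", call. = FALSE)
  surv_spec(x$family, scale = x$scale, shape = x$shape)
}

empty_estimates <- function() {
  tibble(path = character(), point = numeric(), low = numeric(),
         high = numeric(), family = character(), owsa_only = logical())
}
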