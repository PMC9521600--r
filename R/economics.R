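#' Discount factor at the start of a cycle
#'
#' \eqn{f = (1 + r)^{-c \Delta}} with \eqn{\Delta} the cycle length in years;
#' costs and QALYs accrue at cycle start under the default (no half-cycle
#' correction) convention.
#'
#' @param cycle Cycle index (0-based, vectorised).
#' @param settings `config$settings`.
#' @return Discount factors in (0, 1\].
#' @export
discount_factor <- function(cycle, settings) {
  stopifnot(all(cycle >= 0))
  delta <- settings$cycle_length_days / DAYS_PER_YEAR
  (1 + settings$discount_rate_annual)^(-cycle * delta)
}

state_class <- c(ACUTE = "acute", STABLE_ADH = "stable",
                 STABLE_NONADH = "stable", RELAPSE = "relapse")

# Acute-phase adverse-event probabilities for a treatment.
ae_probs <- function(config, treatment) {
  tr <- config$treatments[[treatment]]
  b <- config$baselines
  c(weight_gain = acute_event_prob(tr$rr_weight_gain_vs_placebo, b$p_weight_gain_placebo),
    eps = acute_event_prob(tr$rr_eps_vs_placebo, b$p_eps_placebo))
}

#' Undiscounted cost of one occupied cell for one cycle
#'
#' Drug acquisition (acute and stable/adherent states only; none while
#' non-adherent), outpatient visits, expected inpatient cost
#' (probability x length of stay x daily cost by state class), acute-phase
#' adverse-event management, and the diabetes management cost share.
#'
#' @param config A `szcea_config`.
#' @param treatment Treatment name for the cell's line.
#' @param state Health state label.
#' @param diabetes_prev Diabetes prevalence share attributed to the cell.
#' @return Cost in CN Yuan per cycle.
#' @export
cycle_cost <- function(config, treatment, state, diabetes_prev = 0) {
  co <- config$costs
  if (state == "DEAD") return(0)
  cls <- state_class[[state]]
  cost <- co$hosp_prob[[cls]] * co$hosp_los_days[[cls]] * co$hosp_daily_cost[[cls]]
  cost <- cost + if (cls == "stable") co$outpatient_stable else co$outpatient_acute_relapse
  if (state %in% c("ACUTE", "STABLE_ADH")) {
    cost <- cost + drug_cost_cycle(config, treatment)
  }
  if (state == "ACUTE") {
    p <- ae_probs(config, treatment)
    cost <- cost + p[["weight_gain"]] * co$ae_cost$weight_gain +
      p[["eps"]] * co$ae_cost$eps
  }
  cost + diabetes_prev * co$ae_cost$diabetes
}

#' Undiscounted QALYs accrued by one occupied cell for one cycle
#'
#' State utility (stable states vs acute/relapse), minus acute-phase
#' adverse-event disutilities, minus the diabetes disutility share, scaled by
#' the cycle length in years and floored at zero.
#'
#' @inheritParams cycle_cost
#' @return QALYs per cycle.
#' @export
cycle_qaly <- function(config, treatment, state, diabetes_prev = 0) {
  if (state == "DEAD") return(0)
  u <- config$utilities
  val <- if (state_class[[state]] == "stable") u$u_stable else u$u_acute_relapse
  if (state == "ACUTE") {
    p <- ae_probs(config, treatment)
    val <- val - p[["weight_gain"]] * u$disutility$weight_gain -
      p[["eps"]] * u$disutility$eps
  }
  val <- val - diabetes_prev * u$disutility$diabetes
  max(0, val) * cycle_years(config)
}

#' Value a cohort trace in discounted costs and QALYs
#'
#' Sums occupancy-weighted per-cycle costs and QALYs over the whole trace,
#' discounted at cycle start, with category breakdowns (drug, outpatient,
#' inpatient, adverse events, diabetes; state utility vs adverse-event and
#' diabetes disutilities).
#'
#' @param trace A `cohort_trace` (or `microsim_trace`).
#' @param config The configuration the trace was run under.
#' @return An object of class `strategy_result`.
#' @export
summarise_trace <- function(trace, config) {
  nc <- trace$n_cycles
  delta <- trace$delta_years
  strat <- trace$strategy
  occ <- if (!is.null(trace$occ_cls)) trace$occ_cls else
    apply(trace$occupancy, c(1, 2, 3), sum)  # cycle x line x state
  L <- dim(occ)[2]

  disc <- discount_factor(0:nc, config$settings)
  w <- rep(1, nc + 1)
  if (isTRUE(config$settings$half_cycle_correction)) w[c(1, nc + 1)] <- 0.5
  dw <- disc * w

  co <- config$costs; ut <- config$utilities
  drug_l <- vapply(seq_len(L), function(l)
    drug_cost_cycle(config, line_treatment(strat, l)), numeric(1))
  aep <- vapply(seq_len(L), function(l)
    ae_probs(config, line_treatment(strat, l)), numeric(2))

  inpat_st <- vapply(STATES[1:4], function(s) {
    cls <- state_class[[s]]
    co$hosp_prob[[cls]] * co$hosp_los_days[[cls]] * co$hosp_daily_cost[[cls]]
  }, numeric(1))
  outpat_st <- c(ACUTE = co$outpatient_acute_relapse,
                 STABLE_ADH = co$outpatient_stable,
                 STABLE_NONADH = co$outpatient_stable,
                 RELAPSE = co$outpatient_acute_relapse)
  util_st <- c(ACUTE = ut$u_acute_relapse, STABLE_ADH = ut$u_stable,
               STABLE_NONADH = ut$u_stable, RELAPSE = ut$u_acute_relapse)

  acute_occ <- matrix(occ[, , "ACUTE"], ncol = L)
  on_drug <- acute_occ + matrix(occ[, , "STABLE_ADH"], ncol = L)

  cost_drug <- sum(dw * (on_drug %*% drug_l))
  state_tot <- sapply(STATES[1:4], function(s) rowSums(matrix(occ[, , s], ncol = L)))
  cost_outpat <- sum(dw * (state_tot %*% outpat_st[STATES[1:4]]))
  cost_inpat <- sum(dw * (state_tot %*% inpat_st[STATES[1:4]]))
  ae_cost_l <- aep["weight_gain", ] * co$ae_cost$weight_gain +
    aep["eps", ] * co$ae_cost$eps
  cost_ae <- sum(dw * (acute_occ %*% ae_cost_l))
  cost_diab <- sum(dw * trace$diabetes_prev * co$ae_cost$diabetes)

  qaly_state <- sum(dw * (state_tot %*% util_st[STATES[1:4]])) * delta
  ae_dis_l <- aep["weight_gain", ] * ut$disutility$weight_gain +
    aep["eps", ] * ut$disutility$eps
  qaly_ae <- -sum(dw * (acute_occ %*% ae_dis_l)) * delta
  qaly_diab <- -sum(dw * trace$diabetes_prev * ut$disutility$diabetes) * delta

  cost_breakdown <- tibble(
    category = c("drug", "outpatient", "inpatient", "adverse_events", "diabetes"),
    value = c(cost_drug, cost_outpat, cost_inpat, cost_ae, cost_diab))
  qaly_breakdown <- tibble(
    category = c("state_utility", "ae_disutility", "diabetes_disutility"),
    value = c(qaly_state, qaly_ae, qaly_diab))

  structure(
    list(strategy = strat$name,
         total_cost_cny = sum(cost_breakdown$value),
         total_qaly = sum(qaly_breakdown$value),
         cost_breakdown = cost_breakdown,
         qaly_breakdown = qaly_breakdown),
    class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: cost CN¥%.0f, %.3f QALYs\n",
              x$strategy, x$total_cost_cny, x$total_qaly))
  invisible(x)
}

#' @export
tidy.strategy_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$cost_breakdown, component = "cost", .before = 1),
    dplyr::mutate(x$qaly_breakdown, component = "qaly", .before = 1))
}

#' @export
glance.strategy_result <- function(x, ...) {
  tibble(strategy = x$strategy, total_cost_cny = x$total_cost_cny,
         total_qaly = x$total_qaly)
}

#' Compare two strategies: incrementals, dominance, NMB
#'
#' Sign conventions favour the reference strategy: `delta_cost` is the
#' comparator's cost minus the reference's (positive means the reference
#' saves money) and `delta_qaly` is the reference's QALYs minus the
#' comparator's (positive means the reference gains health). The reference
#' is *dominant* when both are positive, *dominated* when both are negative,
#' and otherwise an incremental cost-effectiveness ratio
#' ICER = (reference cost - comparator cost)/(reference QALY - comparator
#' QALY) is reported. Net monetary benefit is
#' `wtp * delta_qaly + delta_cost`.
#'
#' @param reference,comparator `strategy_result` objects (or anything with
#'   `total_cost_cny` and `total_qaly`).
#' @param wtp Willingness-to-pay threshold, money per QALY.
#' @return An object of class `comparison_result`.
#' @export
compare_strategies <- function(reference, comparator, wtp) {
  dc <- comparator$total_cost_cny - reference$total_cost_cny
  dq <- reference$total_qaly - comparator$total_qaly
  icer <- NA_real_
  if (dq > 0 && dc > 0) {
    label <- "dominant"
  } else if (dq < 0 && dc < 0) {
    label <- "dominated"
  } else if (dq == 0) {
    label <- if (dc > 0) "dominant" else if (dc < 0) "dominated" else "equivalent"
    if (dc != 0) warning("zero QALY difference: labelled by cost alone, ICER undefined")
  } else {
    label <- "icer"
    icer <- -dc / dq
  }
  structure(
    list(reference = reference$strategy, comparator = comparator$strategy,
         delta_cost = dc, delta_qaly = dq, label = label, icer = icer,
         wtp = wtp, nmb = wtp * dq + dc),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s vs %s: saves CN¥%.0f, gains %.3f QALYs [%s], NMB %.0f @ %.0f\n",
    x$reference, x$comparator, x$delta_cost, x$delta_qaly, x$label, x$nmb, x$wtp))
  invisible(x)
}

#' @export
tidy.comparison_result <- function(x, ...) {
  tibble(reference = x$reference, comparator = x$comparator,
         delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
         label = x$label, icer = x$icer, wtp = x$wtp, nmb = x$nmb)
}

#' Convert CN Yuan to US dollars for report tables
#'
#' Divides by the configured exchange rate and (by default) rounds half-up
#' to whole dollars, matching report-table conventions.
#'
#' @param cny Amount in CN Yuan (vectorised).
#' @param settings `config$settings` (uses `exchange_rate_cny_per_usd`).
#' @param round Round half-up to integer dollars?
#' @return US dollar amounts.
#' @export
to_usd <- function(cny, settings, round = TRUE) {
  x <- cny / settings$exchange_rate_cny_per_usd
  if (round) sign(x) * floor(abs(x) + 0.5) else x
}

#' Run the full deterministic analysis
#'
#' Runs the cohort engine for every strategy in the configuration, values the
#' traces, and compares the first (reference) strategy pairwise against each
#' alternative.
#'
#' @param config A validated `szcea_config`.
#' @param wtp Willingness-to-pay threshold (default: first configured
#'   threshold).
#' @return An object of class `cea_result` with elements `results` (list of
#'   `strategy_result`) and `comparisons` (list of `comparison_result`).
#' @export
run_cea <- function(config, wtp = config$settings$wtp_thresholds[1]) {
  results <- lapply(config$strategies, function(st)
    summarise_trace(run_cohort(config, st, keep_clock = FALSE), config))
  names(results) <- vapply(config$strategies, `[[`, "", "name")
  comparisons <- lapply(results[-1], function(r)
    compare_strategies(results[[1]], r, wtp))
  structure(list(results = results, comparisons = comparisons, wtp = wtp),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Tidy a full analysis into a report table
#'
#' One row per strategy: discounted totals in CN Yuan and USD, incrementals
#' against the reference strategy, and the dominance/ICER label.
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cea_result <- function(x, ...) {
  g <- dplyr::bind_rows(lapply(x$results, glance))
  cmp <- dplyr::bind_rows(lapply(x$comparisons, tidy))
  out <- dplyr::left_join(g, cmp, by = c(strategy = "comparator"))
  # each comparator row carries the reference-vs-comparator incrementals
  # (reference cost minus comparator cost, reference QALYs minus comparator
  # QALYs), mirroring report-table conventions
  dplyr::transmute(out,
    strategy = .data$strategy,
    total_cost_cny = .data$total_cost_cny,
    total_qaly = .data$total_qaly,
    incr_cost_cny = -.data$delta_cost,
    incr_qaly = .data$delta_qaly,
    label = .data$label, icer = .data$icer, nmb = .data$nmb)
}

#' @export
glance.cea_result <- function(x, ...) {
  tibble(
    n_strategies = length(x$results),
    reference = x$results[[1]]$strategy,
    wtp = x$wtp,
    all_dominant = all(vapply(x$comparisons, `[[`, "", "label") == "dominant"))
}
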