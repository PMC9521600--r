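Z975 <- 1.959964

#' Standard error from a 95% interval
#'
#' Converts published 95% bounds to a standard error on the sampling scale:
#' on the log scale for ratio parameters sampled log-normally, on the natural
#' scale for probabilities/utilities (beta) and costs/durations (gamma).
#'
#' @param low,high Interval bounds, `low <= high`.
#' @param family `"lognormal"`, `"beta"` or `"gamma"`.
#' @return A standard error (log-scale for `"lognormal"`).
#' @export
#' @examples
#' se_from_ci(0.52, 1.02, "lognormal")  # 0.17188
se_from_ci <- function(low, high, family) {
  if (low > high) stop("`low` must be <= `high`", call. = FALSE)
  switch(family,
    lognormal = {
      if (low <= 0) stop("lognormal bounds must be positive", call. = FALSE)
      (log(high) - log(low)) / (2 * Z975)
    },
    beta = ,
    gamma = (high - low) / (2 * Z975),
    stop(sprintf("unknown family '%s'", family), call. = FALSE)
  )
}

#' Build a probabilistic sampler for an uncertain parameter
#'
#' Log-normal: `meanlog = log(point)`, `sdlog` from [se_from_ci()] (the point
#' estimate is the median). Beta and gamma: method of moments from the point
#' estimate (mean) and the SE. A degenerate interval yields a constant
#' sampler. If beta moment-matching is infeasible (`SE^2 >= p(1-p)`), the
#' sampler falls back to a uniform on ±25% of the point value, with a
#' warning.
#'
#' @param estimate One row of the estimates table (list or one-row data
#'   frame with `point`, `low`, `high`, `family`).
#' @return A list with elements `family`, `sample(n)` and the distribution
#'   parameters; sampling is reproducible under `set.seed()`.
#' @export
make_distribution <- function(estimate) {
  p <- estimate$point; lo <- estimate$low; hi <- estimate$high
  fam <- estimate$family
  if (hi <= lo || fam == "uniform") {
    if (hi <= lo) {
      return(list(family = "degenerate", point = p,
                  sample = function(n) rep(p, n)))
    }
    return(list(family = "uniform", min = lo, max = hi,
                sample = function(n) stats::runif(n, lo, hi)))
  }
  se <- se_from_ci(lo, hi, fam)
  switch(fam,
    lognormal = list(
      family = "lognormal", meanlog = log(p), sdlog = se,
      sample = function(n) stats::rlnorm(n, log(p), se)),
    beta = {
      if (se^2 >= p * (1 - p)) {
        warning(sprintf(
          "beta moment-matching infeasible (point %g, SE %g); falling back to +/-25%% uniform", p, se))
        lo25 <- 0.75 * p; hi25 <- min(1, 1.25 * p)
        return(list(family = "uniform", min = lo25, max = hi25,
                    sample = function(n) stats::runif(n, lo25, hi25)))
      }
      nu <- p * (1 - p) / se^2 - 1
      a <- p * nu; b <- (1 - p) * nu
      list(family = "beta", shape1 = a, shape2 = b,
           sample = function(n) stats::rbeta(n, a, b))
    },
    gamma = {
      shape <- p^2 / se^2; scl <- se^2 / p
      list(family = "gamma", shape = shape, scale = scl,
           sample = function(n) stats::rgamma(n, shape = shape, scale = scl))
    },
    stop(sprintf("unknown family '%s'", fam), call. = FALSE)
  )
}

# Pairwise NMB of strategy `ref` vs `comp` under a configuration.
pair_nmb <- function(config, ref, comp, wtp) {
  r <- summarise_trace(run_cohort(config, ref, keep_clock = FALSE), config)
  c_ <- summarise_trace(run_cohort(config, comp, keep_clock = FALSE), config)
  compare_strategies(r, c_, wtp)$nmb
}

#' One-way sensitivity analysis (tornado)
#'
#' Sets each uncertain parameter in turn to its lower and upper bound,
#' re-runs both strategies, and records the net monetary benefit of the
#' reference versus the comparator at each bound. The base-case
#' configuration is never mutated. Records are returned sorted by descending
#' NMB range (tornado order).
#'
#' @param config A validated `szcea_config`.
#' @param reference,comparator Strategy names (defaults: first and second
#'   configured strategies).
#' @param wtp Willingness-to-pay threshold (default: first configured).
#' @return An `owsa_result`: a tibble with columns `parameter`, `low_value`,
#'   `high_value`, `nmb_at_low`, `nmb_at_high`, `range`, plus attributes
#'   `nmb_base`, `reference`, `comparator`, `wtp`.
#' @export
run_owsa <- function(config,
                     reference = config$strategies[[1]]$name,
                     comparator = config$strategies[[2]]$name,
                     wtp = config$settings$wtp_thresholds[1]) {
  est <- config$estimates
  nmb_base <- pair_nmb(config, reference, comparator, wtp)
  rows <- purrr::pmap(est, function(path, point, low, high, family, owsa_only) {
    nmb_lo <- pair_nmb(config_set(config, path, low), reference, comparator, wtp)
    nmb_hi <- pair_nmb(config_set(config, path, high), reference, comparator, wtp)
    tibble(parameter = path, low_value = low, high_value = high,
           nmb_at_low = nmb_lo, nmb_at_high = nmb_hi,
           range = abs(nmb_hi - nmb_lo),
           valid = is.finite(nmb_lo) && is.finite(nmb_hi))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$range))
  structure(out, nmb_base = nmb_base, reference = reference,
            comparator = comparator, wtp = wtp,
            class = c("owsa_result", class(out)))
}

#' Probabilistic sensitivity analysis
#'
#' Draws all flagged parameters jointly (independently across parameters)
#' from their assigned distributions, rebuilds the configuration per draw,
#' runs every strategy, and records the resulting discounted totals. Each
#' parameter has its own RNG substream derived from the master seed, so
#' adding a parameter does not perturb the draws of the others.
#'
#' @param config A validated `szcea_config`.
#' @param n_iterations Number of Monte-Carlo draws (study default 5,000).
#' @param seed Master RNG seed.
#' @return A `psa_result`: list with `samples` (tibble `iteration`,
#'   `strategy`, `total_cost_cny`, `total_qaly`), `draws` (tibble of sampled
#'   parameter values), `n_iterations`, `seed`.
#' @export
run_psa <- function(config, n_iterations = 5000, seed = 1L) {
  stopifnot(n_iterations >= 1)
  est <- dplyr::filter(config$estimates, !.data$owsa_only)
  P <- nrow(est)
  draws <- matrix(NA_real_, n_iterations, P,
                  dimnames = list(NULL, est$path))
  for (j in seq_len(P)) {
    dist <- withCallingHandlers(
      make_distribution(est[j, ]),
      warning = function(w) {
        message(sprintf("psa: %s: %s", est$path[j], conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    set.seed((seed * 1000L + j) %% .Machine$integer.max)
    draws[, j] <- dist$sample(n_iterations)
  }

  strat_names <- vapply(config$strategies, `[[`, "", "name")
  res <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    cfg_i <- config
    for (j in seq_len(P)) cfg_i <- config_set(cfg_i, est$path[j], draws[i, j])
    res[[i]] <- dplyr::bind_rows(lapply(strat_names, function(sn) {
      sr <- summarise_trace(run_cohort(cfg_i, sn, keep_clock = FALSE), cfg_i)
      tibble(iteration = i, strategy = sn,
             total_cost_cny = sr$total_cost_cny, total_qaly = sr$total_qaly)
    }))
  }
  structure(
    list(samples = dplyr::bind_rows(res), draws = as_tibble(draws),
         n_iterations = n_iterations, seed = seed,
         strategies = strat_names),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations x %d strategies (%d sampled parameters)\n",
              x$n_iterations, length(x$strategies), ncol(x$draws)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the pairwise probability that the
#' reference strategy is cost-effective against each comparator (share of
#' draws with positive pairwise NMB) and the overall probability that the
#' reference has the highest NMB among all strategies (ties split equally).
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Numeric vector of willingness-to-pay values.
#' @param reference Reference strategy name (default: first).
#' @return A `ceac_result` tibble: `wtp`, one `prob_ce_vs_<comparator>`
#'   column per comparator, and `prob_ce_overall`.
#' @export
ceac <- function(psa, wtp_grid, reference = psa$strategies[1]) {
  stopifnot(length(wtp_grid) >= 1, nrow(psa$samples) >= 1)
  wide_c <- tidyr::pivot_wider(psa$samples, id_cols = "iteration",
                               names_from = "strategy",
                               values_from = "total_cost_cny")
  wide_q <- tidyr::pivot_wider(psa$samples, id_cols = "iteration",
                               names_from = "strategy",
                               values_from = "total_qaly")
  strat <- psa$strategies
  comps <- setdiff(strat, reference)
  cost <- as.matrix(wide_c[strat]); qaly <- as.matrix(wide_q[strat])

  rows <- lapply(wtp_grid, function(l) {
    nmb <- l * qaly - cost
    out <- tibble(wtp = l)
    for (cm in comps) {
      out[[paste0("prob_ce_vs_", cm)]] <-
        mean(nmb[, reference] - nmb[, cm] > 0)
    }
    best <- apply(nmb, 1, max)
    is_best <- nmb[, reference] >= best - 1e-12
    n_tied <- rowSums(nmb >= best - 1e-12)
    out$prob_ce_overall <- mean(is_best / n_tied)
    out
  })
  out <- dplyr::bind_rows(rows)
  structure(out, reference = reference,
            class = c("ceac_result", class(out)))
}
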