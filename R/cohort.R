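STATES <- c("ACUTE", "STABLE_ADH", "STABLE_NONADH", "RELAPSE", "DEAD")

#' Resolve a strategy's treatment for a given line index
#'
#' Lines beyond the last defined one repeat the last (the `repeat_last`
#' exhaustion policy): after the final strategy fails, patients re-trial it
#' indefinitely.
#'
#' @param strategy A strategy element of `config$strategies`.
#' @param line 1-based line index (may exceed `length(strategy$lines)`).
#' @return Treatment name.
#' @export
line_treatment <- function(strategy, line) {
  strategy$lines[[min(line, length(strategy$lines))]]
}

# Per-cycle drug acquisition cost for a treatment; combination treatments sum
# their components' acquisition costs.
drug_cost_cycle <- function(config, name) {
  tr <- config$treatments[[name]]
  if (!is.null(tr$components)) {
    sum(vapply(tr$components, function(cn) drug_cost_cycle(config, cn), numeric(1)))
  } else {
    tr$daily_dose_mg * tr$unit_cost_per_mg * config$settings$cycle_length_days
  }
}

# Precompute everything the cycle loop needs for one strategy:
# per-line acute discontinuation probabilities and per-line vectors of
# clock-dependent maintenance transition probabilities.
precompute_strategy <- function(config, strategy) {
  nc <- config$settings$n_cycles
  delta <- cycle_years(config)
  n_lines <- length(strategy$lines)
  u_grid <- (0:nc) * delta

  p_acute_disc <- numeric(n_lines)
  p_rel_adh <- matrix(0, n_lines, nc + 1)
  p_disc_m <- matrix(0, n_lines, nc + 1)
  rr_diab <- numeric(n_lines)
  for (l in seq_len(n_lines)) {
    tr <- config$treatments[[strategy$lines[[l]]]]
    p_acute_disc[l] <- acute_event_prob(tr$rr_disc_acute_vs_placebo,
                                        config$baselines$p_disc_placebo_acute)
    p_rel_adh[l, ] <- cycle_prob(
      scale_hazard(config$baselines$relapse_baseline, tr$hr_relapse_vs_quetiapine),
      u_grid, delta)
    p_disc_m[l, ] <- cycle_prob(
      scale_hazard(config$baselines$disc_baseline, tr$hr_disc_maint_vs_quetiapine),
      u_grid, delta)
    rr_diab[l] <- tr$rr_diabetes_vs_olanzapine
  }
  mult <- nonadherent_relapse_multiplier(config$baselines$prop_relapse_adherent)
  p_rel_nonadh <- cycle_prob(
    scale_hazard(config$baselines$relapse_baseline, mult), u_grid, delta)
  p_diab <- pmin(1, rr_diab * config$baselines$p_diabetes_olanzapine)

  list(n_lines = n_lines, delta = delta, nc = nc,
       p_acute_disc = p_acute_disc, p_rel_adh = p_rel_adh,
       p_disc_m = p_disc_m, p_rel_nonadh = p_rel_nonadh, p_diab = p_diab)
}

# Split maintenance-phase survivors of a stable/adherent cell into
# (relapse, to-non-adherent, stay) according to the configured event order.
split_stable_adh <- function(mass, p_rel, p_disc, order) {
  if (order == "relapse_first") {
    rel <- mass * p_rel
    disc <- mass * (1 - p_rel) * p_disc
  } else { # disc_first: discontinuation resolved before relapse
    disc <- mass * p_disc
    rel <- mass * (1 - p_disc) * p_rel
  }
  list(rel = rel, disc = disc, stay = mass - rel - disc)
}

#' Single-cell transition distribution
#'
#' The full transition law out of one occupied cell `(line, state, u)` at a
#' given age: death is resolved first, then — among survivors — relapse,
#' discontinuation and line switching per the model structure. Mainly a
#' transparency/audit surface; [run_cohort()] applies the same logic in
#' vectorised form.
#'
#' @param config A `szcea_config`.
#' @param strategy A strategy element of `config$strategies`.
#' @param line Line index (1-based).
#' @param state One of `"ACUTE"`, `"STABLE_ADH"`, `"STABLE_NONADH"`,
#'   `"RELAPSE"`.
#' @param u Whole cycles already spent on the current line's maintenance
#'   clock (0 for ACUTE/RELAPSE).
#' @param age Current age in years.
#' @return A tibble with columns `line`, `state`, `u`, `prob`, summing to 1.
#' @export
transition_dist <- function(config, strategy, line, state, u, age) {
  if (state %in% c("ACUTE", "RELAPSE") && u != 0) {
    stop("ACUTE/RELAPSE carry no maintenance clock (u must be 0)", call. = FALSE)
  }
  if (state == "DEAD") {
    return(tibble(line = line, state = "DEAD", u = 0, prob = 1))
  }
  pre <- precompute_strategy(config, strategy)
  l <- min(line, pre$n_lines)
  nxt <- min(l + 1, pre$n_lines)
  u_next <- min(u + 1, pre$nc)
  p_d <- death_prob(config$demographics$life_table, age, config$demographics,
                    pre$delta)
  surv <- 1 - p_d
  order <- config$settings$event_order

  rows <- switch(state,
    ACUTE = {
      p_disc <- pre$p_acute_disc[l]
      tibble(line = c(nxt, l), state = c("ACUTE", "STABLE_ADH"), u = c(0, 0),
             prob = surv * c(p_disc, 1 - p_disc))
    },
    STABLE_ADH = {
      sp <- split_stable_adh(1, pre$p_rel_adh[l, u + 1], pre$p_disc_m[l, u + 1], order)
      tibble(line = c(l, l, l),
             state = c("RELAPSE", "STABLE_NONADH", "STABLE_ADH"),
             u = c(0, u_next, u_next),
             prob = surv * c(sp$rel, sp$disc, sp$stay))
    },
    STABLE_NONADH = {
      p_rel <- pre$p_rel_nonadh[u + 1]
      tibble(line = c(l, l), state = c("RELAPSE", "STABLE_NONADH"),
             u = c(0, u_next), prob = surv * c(p_rel, 1 - p_rel))
    },
    RELAPSE = tibble(line = nxt, state = "ACUTE", u = 0, prob = surv),
    stop(sprintf("no transitions out of state '%s'", state), call. = FALSE)
  )
  out <- dplyr::bind_rows(rows, tibble(line = l, state = "DEAD", u = 0, prob = p_d))
  out[out$prob > 0 | out$state == "DEAD", ]
}

#' Run the deterministic cohort trace
#'
#' Propagates a unit cohort from the acute treatment-trial state of line 1
#' through the expanded state space (cycle x line x state x time-on-line)
#' over the full horizon, tracking an irreversible diabetes prevalence
#' overlay and advancing age continuously.
#'
#' @param config A validated `szcea_config`.
#' @param strategy A strategy element of `config$strategies`, or its name.
#' @param keep_clock Keep the full clock-resolved occupancy array
#'   `[cycle+1, line, state, u+1]` (needed for [tidy.cohort_trace()] audit
#'   exports)? The clock-collapsed occupancy used for valuation is always
#'   kept; dropping the full array speeds up Monte-Carlo loops.
#' @return An object of class `cohort_trace`: clock-collapsed occupancy
#'   `occ_cls[cycle+1, line, state]`, optional full `occupancy`,
#'   `diabetes_prev`, `age` and bookkeeping.
#' @export
run_cohort <- function(config, strategy, keep_clock = TRUE) {
  if (is.character(strategy)) {
    idx <- which(vapply(config$strategies, `[[`, "", "name") == strategy)
    if (length(idx) != 1L) stop(sprintf("unknown strategy '%s'", strategy), call. = FALSE)
    strategy <- config$strategies[[idx]]
  }
  pre <- precompute_strategy(config, strategy)
  nc <- pre$nc; L <- pre$n_lines; delta <- pre$delta
  order <- config$settings$event_order
  nu <- nc + 1

  occ <- NULL
  if (keep_clock) {
    occ <- array(0, dim = c(nc + 1, L, 5, nu),
                 dimnames = list(NULL, NULL, STATES, NULL))
    occ[1, 1, "ACUTE", 1] <- 1
  }
  occ_cls <- array(0, dim = c(nc + 1, L, 5),
                   dimnames = list(NULL, NULL, STATES))
  occ_cls[1, 1, "ACUTE"] <- 1
  diab <- numeric(nc + 1)
  age <- config$demographics$start_age + (0:nc) * delta
  p_death <- death_prob_vec(config, age[1:nc], delta)

  # current occupancy, clock-expanded states as L x nu matrices
  A <- numeric(L); A[1] <- 1           # acute trial, per line
  S <- matrix(0, L, nu)                # stable/adherent, by time-on-line
  NS <- matrix(0, L, nu)               # stable/non-adherent
  R <- numeric(L)                      # relapse, per line
  dead <- 0
  P_rel_nonadh <- matrix(pre$p_rel_nonadh, L, nu, byrow = TRUE)
  line_next <- pmin(seq_len(L) + 1L, L)

  for (t in seq_len(nc)) {
    p_d <- p_death[t]
    surv <- 1 - p_d
    incidence <- sum((A + rowSums(S)) * pre$p_diab)

    sA <- A * surv
    sS <- S * surv
    sNS <- NS * surv
    sR <- R * surv

    if (order == "relapse_first") {
      relS <- sS * pre$p_rel_adh
      discS <- (sS - relS) * pre$p_disc_m
    } else {
      discS <- sS * pre$p_disc_m
      relS <- (sS - discS) * pre$p_rel_adh
    }
    stayS <- sS - relS - discS
    relNS <- sNS * P_rel_nonadh
    stayNS <- sNS - relNS

    disc_acute <- sA * pre$p_acute_disc
    to_next <- disc_acute + sR           # feeds next line's acute trial

    dead <- dead + (sum(A) + sum(S) + sum(NS) + sum(R)) * p_d
    A_new <- numeric(L)
    for (l in seq_len(L)) A_new[line_next[l]] <- A_new[line_next[l]] + to_next[l]
    S <- shift_cols(stayS)
    S[, 1] <- S[, 1] + sA - disc_acute
    NS <- shift_cols(stayNS + discS)
    R <- rowSums(relS) + rowSums(relNS)
    A <- A_new

    if (keep_clock) {
      occ[t + 1, , 1, 1] <- A
      occ[t + 1, , 2, ] <- S
      occ[t + 1, , 3, ] <- NS
      occ[t + 1, , 4, 1] <- R
      occ[t + 1, 1, 5, 1] <- dead
    }
    occ_cls[t + 1, , 1] <- A
    occ_cls[t + 1, , 2] <- rowSums(S)
    occ_cls[t + 1, , 3] <- rowSums(NS)
    occ_cls[t + 1, , 4] <- R
    occ_cls[t + 1, 1, 5] <- dead
    diab[t + 1] <- diab[t] * surv + incidence
  }

  structure(
    list(occupancy = occ, occ_cls = occ_cls, diabetes_prev = diab, age = age,
         p_death = p_death, strategy = strategy, n_cycles = nc,
         delta_years = delta, states = STATES),
    class = "cohort_trace"
  )
}

# Advance the maintenance clock by one cycle (column shift), truncating at
# the last index so mass at the cap stays at the cap.
shift_cols <- function(m) {
  nu <- ncol(m)
  out <- matrix(0, nrow(m), nu)
  out[, 2:nu] <- m[, 1:(nu - 1)]
  out[, nu] <- out[, nu] + m[, nu]
  out
}

# Per-cycle death probabilities for a vector of ages, vectorised over the
# life-table lookup.
death_prob_vec <- function(config, ages, delta) {
  d <- config$demographics
  lt <- d$life_table
  a <- floor(ages)
  im <- match(paste0("male", a), paste0(lt$sex, lt$age))
  fi <- match(paste0("female", a), paste0(lt$sex, lt$age))
  if (anyNA(im) || anyNA(fi)) {
    stop("life table does not cover the cohort's age range; extend the table",
         call. = FALSE)
  }
  hm <- -log(1 - lt$q_annual[im])
  hf <- -log(1 - lt$q_annual[fi])
  pm <- 1 - exp(-d$smr_male * hm * delta)
  pf <- 1 - exp(-d$smr_female * hf * delta)
  pmin(pmax(d$prop_male * pm + (1 - d$prop_male) * pf, 0), 1)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> strategy '%s': %d cycles, %d lines; final dead fraction %.4f\n",
              x$strategy$name, x$n_cycles, dim(x$occ_cls)[2],
              sum(x$occ_cls[x$n_cycles + 1, , "DEAD"])))
  invisible(x)
}

#' Tidy a cohort trace into long format
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @param drop_zero Drop cells with zero occupancy (default `TRUE`).
#' @return A tibble with columns `cycle`, `line`, `state`, `u`, `occupancy`.
#' @export
tidy.cohort_trace <- function(x, ..., drop_zero = TRUE) {
  if (is.null(x$occupancy)) {
    stop("trace was run with keep_clock = FALSE; re-run with keep_clock = TRUE",
         call. = FALSE)
  }
  d <- dim(x$occupancy)
  idx <- which(x$occupancy != 0 | !drop_zero, arr.ind = TRUE)
  out <- tibble(
    cycle = idx[, 1] - 1L,
    line = idx[, 2],
    state = STATES[idx[, 3]],
    u = idx[, 4] - 1L,
    occupancy = x$occupancy[idx]
  )
  dplyr::arrange(out, .data$cycle, .data$line,
                 match(.data$state, STATES), .data$u)
}

#' State-by-cycle occupancy of a trace
#'
#' Collapses lines and the time-on-line clock, returning one row per cycle
#' and health state.
#'
#' @param trace A `cohort_trace` or `microsim_trace`.
#' @return A tibble `cycle`, `state`, `occupancy`.
#' @export
state_occupancy <- function(trace) {
  m <- if (!is.null(trace$occ_cls)) {
    apply(trace$occ_cls, c(1, 3), sum)
  } else {
    apply(trace$occupancy, c(1, 3), sum)
  }
  tibble(
    cycle = rep(0:(nrow(m) - 1L), times = ncol(m)),
    state = rep(STATES, each = nrow(m)),
    occupancy = as.vector(m)
  )
}

#' Per-cycle diabetes incidence update
#'
#' One step of the irreversible diabetes prevalence overlay: survivors keep
#' their diabetes, and on-treatment occupancy (acute trial plus
#' stable/adherent) accrues new cases at the treatment-specific per-cycle
#' incidence `min(1, rr * p_olanzapine)`.
#'
#' @param prev Prevalence entering the cycle, in \[0, 1\].
#' @param on_treatment_occupancy Named numeric vector, treatment name to
#'   occupied fraction.
#' @param config A `szcea_config`.
#' @param p_death_avg Per-cycle death probability applied to the prevalent
#'   pool.
#' @return Updated prevalence.
#' @export
update_diabetes <- function(prev, on_treatment_occupancy, config, p_death_avg) {
  stopifnot(prev >= 0, prev <= 1)
  rr <- vapply(names(on_treatment_occupancy),
               function(nm) config$treatments[[nm]]$rr_diabetes_vs_olanzapine,
               numeric(1))
  incidence <- sum(on_treatment_occupancy *
                     pmin(1, rr * config$baselines$p_diabetes_olanzapine))
  prev * (1 - p_death_avg) + incidence
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_walkers` independent patient paths with the same transition
#' logic as [run_cohort()] (death first, then relapse/discontinuation in the
#' configured order) using random draws, and returns the empirical occupancy.
#' Serves as an independent stochastic check on the deterministic cohort
#' engine.
#'
#' @param config A validated `szcea_config`.
#' @param strategy A strategy element or name.
#' @param n_walkers Number of simulated patients.
#' @param seed RNG seed (results are reproducible given the seed).
#' @param n_cycles Optional reduced horizon (default: full horizon).
#' @return A `microsim_trace`: empirical `occupancy[cycle+1, line, state, 1]`
#'   (clock collapsed) plus `n_walkers`.
#' @export
microsim_oracle <- function(config, strategy, n_walkers, seed,
                            n_cycles = config$settings$n_cycles) {
  if (is.character(strategy)) {
    idx <- which(vapply(config$strategies, `[[`, "", "name") == strategy)
    strategy <- config$strategies[[idx]]
  }
  stopifnot(n_walkers >= 1)
  pre <- precompute_strategy(config, strategy)
  L <- pre$n_lines; delta <- pre$delta
  order <- config$settings$event_order
  age0 <- config$demographics$start_age

  set.seed(seed)
  line <- rep(1L, n_walkers)
  state <- rep(1L, n_walkers)  # 1 ACUTE, 2 STABLE_ADH, 3 NONADH, 4 RELAPSE, 5 DEAD
  u <- rep(0L, n_walkers)

  occ <- array(0, dim = c(n_cycles + 1, L, 5, 1),
               dimnames = list(NULL, NULL, STATES, NULL))
  tally <- function(t) {
    # dead patients carry no active treatment line; record them at line 1,
    # matching the cohort trace convention
    ln <- ifelse(state == 5L, 1L, line)
    cnt <- table(factor(ln, 1:L), factor(state, 1:5))
    occ[t, , , 1] <<- as.matrix(cnt) / n_walkers
  }
  tally(1)

  for (t in seq_len(n_cycles)) {
    p_d <- death_prob(config$demographics$life_table, age0 + (t - 1) * delta,
                      config$demographics, delta)
    alive <- state != 5L
    dies <- alive & (stats::runif(n_walkers) < p_d)
    state[dies] <- 5L

    iA <- which(state == 1L & !dies)
    iS <- which(state == 2L & !dies)
    iN <- which(state == 3L & !dies)
    iR <- which(state == 4L & !dies)

    if (length(iA)) {
      disc <- stats::runif(length(iA)) < pre$p_acute_disc[line[iA]]
      sw <- iA[disc]
      line[sw] <- pmin(line[sw] + 1L, L)
      state[iA[!disc]] <- 2L
      u[iA] <- 0L
    }
    if (length(iS)) {
      p_rel <- pre$p_rel_adh[cbind(line[iS], u[iS] + 1L)]
      p_disc <- pre$p_disc_m[cbind(line[iS], u[iS] + 1L)]
      r1 <- stats::runif(length(iS)); r2 <- stats::runif(length(iS))
      if (order == "relapse_first") {
        rel <- r1 < p_rel
        disc <- !rel & (r2 < p_disc)
      } else {
        disc <- r1 < p_disc
        rel <- !disc & (r2 < p_rel)
      }
      state[iS[rel]] <- 4L; u[iS[rel]] <- 0L
      state[iS[disc]] <- 3L
      adv <- iS[!rel]
      u[adv] <- pmin(u[adv] + 1L, n_cycles)
    }
    if (length(iN)) {
      rel <- stats::runif(length(iN)) < pre$p_rel_nonadh[u[iN] + 1L]
      state[iN[rel]] <- 4L; u[iN[rel]] <- 0L
      u[iN[!rel]] <- pmin(u[iN[!rel]] + 1L, n_cycles)
    }
    if (length(iR)) {
      line[iR] <- pmin(line[iR] + 1L, L)
      state[iR] <- 1L
      u[iR] <- 0L
    }
    tally(t + 1)
  }

  structure(list(occupancy = occ, n_walkers = n_walkers, strategy = strategy,
                 n_cycles = n_cycles, delta_years = delta, states = STATES),
            class = "microsim_trace")
}
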