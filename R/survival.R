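#' Parametric survival specification
#'
#' Constructs a parametric time-to-event law used for maintenance-phase
#' transitions (treatment discontinuation and relapse). Time is measured in
#' years.
#'
#' @param family One of `"weibull"`, `"gompertz"`, `"exponential"`.
#' @param scale Rate-like scale parameter \eqn{\theta > 0} (per year).
#' @param shape Shape parameter: dimensionless \eqn{\gamma > 0} for the
#'   Weibull; per-year slope \eqn{b} (any real; \eqn{b \to 0} recovers the
#'   exponential) for the Gompertz; ignored for the exponential.
#'
#' @details Survival functions:
#'   Weibull \eqn{S(t) = \exp(-\theta t^\gamma)};
#'   Gompertz \eqn{S(t) = \exp(-(\theta/b)(e^{bt} - 1))};
#'   exponential \eqn{S(t) = \exp(-\theta t)}.
#'
#' @return An object of class `surv_spec`.
#' @export
#' @examples
#' sp <- surv_spec("weibull", scale = 0.51, shape = 1.3)
#' surv_prob(sp, 1)
surv_spec <- function(family = c("weibull", "gompertz", "exponential"),
                      scale, shape = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  if (family == "weibull") {
    if (is.null(shape) || shape <= 0) {
      stop("weibull `shape` must be > 0", call. = FALSE)
    }
  } else if (family == "gompertz") {
    if (is.null(shape)) stop("gompertz requires a `shape` (slope b)", call. = FALSE)
  } else {
    shape <- 1
  }
  structure(
    list(family = family, scale = as.numeric(scale), shape = as.numeric(shape)),
    class = "surv_spec"
  )
}

#' @export
print.surv_spec <- function(x, ...) {
  cat(sprintf("<surv_spec> %s(scale = %g, shape = %g) [time in years]\n",
              x$family, x$scale, x$shape))
  invisible(x)
}

#' Survival probability S(t)
#'
#' @param spec A [surv_spec()].
#' @param t Time in years (vectorised, all `t >= 0`).
#' @return Survival probabilities in \[0, 1\].
#' @export
surv_prob <- function(spec, t) {
  stopifnot(inherits(spec, "surv_spec"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  th <- spec$scale
  cum_haz <- switch(spec$family,
    weibull = th * t^spec$shape,
    gompertz = gompertz_cumhaz(th, spec$shape, t),
    exponential = th * t
  )
  exp(-cum_haz)
}

# Gompertz cumulative hazard with a numerically safe b -> 0 limit:
# (theta/b)(e^{bt}-1) = theta * t * expm1(b t)/(b t); expm1 keeps precision.
gompertz_cumhaz <- function(theta, b, t) {
  out <- numeric(length(t))
  bt <- b * t
  small <- abs(bt) < 1e-8
  out[small] <- theta * t[small] * (1 + bt[small] / 2)
  if (any(!small)) out[!small] <- (theta / b) * expm1(bt[!small])
  out
}

#' Apply a hazard ratio to a survival specification
#'
#' Proportional-hazards scaling: the returned specification satisfies
#' \eqn{S'(t) = S(t)^{hr}} for all t, i.e. the scale parameter is multiplied
#' by `hr` while the shape is unchanged.
#'
#' @param spec A [surv_spec()].
#' @param hr Hazard ratio, `hr > 0`.
#' @return A new `surv_spec`.
#' @export
scale_hazard <- function(spec, hr) {
  stopifnot(inherits(spec, "surv_spec"))
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0) {
    stop("`hr` must be a positive number", call. = FALSE)
  }
  spec$scale <- spec$scale * hr
  spec
}

#' Conditional per-cycle event probability
#'
#' Probability of the event within the next `delta` years given survival to
#' `u` years: \eqn{p = 1 - S(u + \delta)/S(u)}. This converts a parametric
#' survival law into the time-on-treatment-dependent transition probability of
#' a semi-Markov cycle.
#'
#' @param spec A [surv_spec()].
#' @param u Years already on treatment (vectorised, `u >= 0`).
#' @param delta Cycle length in years, `delta > 0`.
#' @return Probabilities in \[0, 1\]; 1 where `S(u) == 0`.
#' @export
cycle_prob <- function(spec, u, delta) {
  if (any(u < 0)) stop("`u` must be >= 0", call. = FALSE)
  if (delta <= 0) stop("`delta` must be > 0", call. = FALSE)
  s_u <- surv_prob(spec, u)
  s_ud <- surv_prob(spec, u + delta)
  p <- ifelse(s_u <= 0, 1, 1 - s_ud / s_u)
  pmin(pmax(p, 0), 1)
}

#' Acute-phase event probability from a risk ratio
#'
#' Six-week trial outcomes (all-cause discontinuation, weight gain, EPS) are
#' parameterised as risk ratios against a reference arm probability; the
#' product is clamped at 1.
#'
#' @param rr Risk ratio (> 0).
#' @param p_ref Reference-arm probability in \[0, 1\].
#' @return `min(1, rr * p_ref)`.
#' @export
acute_event_prob <- function(rr, p_ref) {
  if (any(rr <= 0)) stop("`rr` must be > 0", call. = FALSE)
  if (any(p_ref < 0 | p_ref > 1)) stop("`p_ref` must be in [0, 1]", call. = FALSE)
  pmin(1, rr * p_ref)
}

#' SMR-adjusted per-cycle death probability
#'
#' Converts the life-table annual death probability at the cohort's current
#' age to a hazard, multiplies it by the sex-specific standardized mortality
#' ratio of the schizophrenia population, converts back to a per-cycle
#' probability, and mixes over the cohort's sex composition.
#'
#' @param life_table Tibble with columns `age`, `sex` (`"male"`/`"female"`),
#'   `q_annual`.
#' @param age Current cohort age in years.
#' @param demographics List with `prop_male`, `smr_male`, `smr_female`.
#' @param delta Cycle length in years.
#' @return A single probability in \[0, 1\].
#' @export
death_prob <- function(life_table, age, demographics, delta) {
  a <- floor(age)
  qm <- life_table$q_annual[life_table$age == a & life_table$sex == "male"]
  qf <- life_table$q_annual[life_table$age == a & life_table$sex == "female"]
  if (length(qm) != 1L || length(qf) != 1L) {
    stop(sprintf("life table does not cover age %d for both sexes; extend the table", a),
         call. = FALSE)
  }
  hm <- -log(1 - qm)
  hf <- -log(1 - qf)
  pm <- 1 - exp(-demographics$smr_male * hm * delta)
  pf <- 1 - exp(-demographics$smr_female * hf * delta)
  p <- demographics$prop_male * pm + (1 - demographics$prop_male) * pf
  min(max(p, 0), 1)
}

#' Relapse hazard multiplier for non-adherent patients
#'
#' The share of relapses attributed to adherent patients is turned into a
#' constant hazard multiplier for the stable/non-adherent state via the odds
#' transform: \eqn{m = (1 - a)/a} where `a` is the adherent share.
#'
#' @param prop_adherent Fraction of relapses from adherent patients, in (0, 1).
#' @return A hazard ratio applied to the baseline relapse specification.
#' @export
nonadherent_relapse_multiplier <- function(prop_adherent) {
  if (prop_adherent <= 0 || prop_adherent >= 1) {
    stop("`prop_adherent` must be strictly inside (0, 1)", call. = FALSE)
  }
  (1 - prop_adherent) / prop_adherent
}
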