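test_that("discount factors follow the cycle-start convention", {
  s <- base_cfg()$settings
  expect_equal(discount_factor(0, s), 1)
  expect_equal(discount_factor(130, s), 0.482223377258, tolerance = 1e-9)
  expect_true(all(diff(discount_factor(0:130, s)) < 0))
  s0 <- s; s0$discount_rate_annual <- 0
  expect_equal(discount_factor(0:130, s0), rep(1, 131))
  expect_error(discount_factor(-1, s), ">= 0")
})

test_that("per-cell cycle costs match hand-computed values", {
  cfg <- base_cfg()
  # stable/adherent: drug + stable outpatient + expected stable inpatient
  expect_equal(cycle_cost(cfg, "lurasidone", "STABLE_ADH"), 922.752, tolerance = 1e-9)
  # non-adherent: no drug cost
  expect_equal(cycle_cost(cfg, "lurasidone", "STABLE_NONADH"), 317.952, tolerance = 1e-9)
  # relapse: acute outpatient + 0.41 x 31 d x 520/d inpatient, no drug
  expect_equal(cycle_cost(cfg, "lurasidone", "RELAPSE"), 7225.08, tolerance = 1e-9)
  # acute: drug + outpatient + inpatient + weight-gain/EPS management
  expect_equal(cycle_cost(cfg, "lurasidone", "ACUTE"), 8368.39315942, tolerance = 1e-6)
  expect_equal(cycle_cost(cfg, "lurasidone", "DEAD"), 0)
  # diabetes management cost scales with the attributed prevalence
  expect_equal(cycle_cost(cfg, "lurasidone", "STABLE_NONADH", diabetes_prev = 0.2),
               317.952 + 0.2 * 1544.83, tolerance = 1e-9)
  # combination line: clozapine + risperidone acquisition components
  expect_equal(cycle_cost(cfg, "augmented_clozapine", "STABLE_ADH") -
                 cycle_cost(cfg, "augmented_clozapine", "STABLE_NONADH"),
               139.65, tolerance = 1e-9)
  # lurasidone 60 mg x 0.240/mg x 42 d
  expect_equal(cycle_cost(cfg, "lurasidone", "STABLE_ADH") -
                 cycle_cost(cfg, "lurasidone", "STABLE_NONADH"),
               604.80, tolerance = 1e-9)
})

test_that("per-cell cycle QALYs match hand-computed values", {
  cfg <- base_cfg()
  expect_equal(cycle_qaly(cfg, "lurasidone", "STABLE_ADH"), 0.105675564682,
               tolerance = 1e-9)
  expect_equal(cycle_qaly(cfg, "lurasidone", "STABLE_NONADH"), 0.105675564682,
               tolerance = 1e-9)
  expect_equal(cycle_qaly(cfg, "lurasidone", "RELAPSE"), 0.069453798768,
               tolerance = 1e-9)
  expect_equal(cycle_qaly(cfg, "lurasidone", "DEAD"), 0)
  # acute: state utility minus expected weight-gain and EPS disutilities
  expect_equal(cycle_qaly(cfg, "lurasidone", "ACUTE"), 0.067323861306,
               tolerance = 1e-9)
  # diabetes disutility scales with attributed prevalence
  expect_equal(cycle_qaly(cfg, "lurasidone", "STABLE_ADH", diabetes_prev = 0.5),
               (0.919 - 0.5 * 0.151) * DELTA_YEARS, tolerance = 1e-9)
  # utility is floored at zero
  low <- cfg
  low$utilities$u_acute_relapse <- 0.1
  low$utilities$disutility$diabetes <- 0.9
  expect_equal(cycle_qaly(low, "lurasidone", "RELAPSE", diabetes_prev = 1), 0)
})

test_that("summarise_trace equals an independent per-cell valuation", {
  cfg <- base_cfg()
  tr <- run_cohort(cfg, "risperidone", keep_clock = FALSE)
  res <- summarise_trace(tr, cfg)
  st <- cfg$strategies[[3]]
  nc <- tr$n_cycles
  dw <- discount_factor(0:nc, cfg$settings)
  cost <- 0; qaly <- 0
  for (l in 1:4) {
    trt <- line_treatment(st, l)
    for (s in c("ACUTE", "STABLE_ADH", "STABLE_NONADH", "RELAPSE")) {
      occ <- tr$occ_cls[, l, s]
      cost <- cost + sum(dw * occ * cycle_cost(cfg, trt, s))
      qaly <- qaly + sum(dw * occ * cycle_qaly(cfg, trt, s))
    }
  }
  cost <- cost + sum(dw * tr$diabetes_prev * cfg$costs$ae_cost$diabetes)
  qaly <- qaly - sum(dw * tr$diabetes_prev * cfg$utilities$disutility$diabetes) *
    DELTA_YEARS
  expect_equal(res$total_cost_cny, cost, tolerance = 1e-9)
  expect_equal(res$total_qaly, qaly, tolerance = 1e-9)
  # breakdowns add up to the totals
  expect_equal(sum(res$cost_breakdown$value), res$total_cost_cny, tolerance = 1e-12)
  expect_equal(sum(res$qaly_breakdown$value), res$total_qaly, tolerance = 1e-12)
})

test_that("zero-rate valuation equals undiscounted sums; discounting shrinks both", {
  cfg <- base_cfg()
  cfg0 <- config_set(cfg, "settings.discount_rate_annual", 0)
  tr <- run_cohort(cfg0, "lurasidone", keep_clock = FALSE)
  r0 <- summarise_trace(tr, cfg0)
  # independent undiscounted accumulation over the same trace
  st <- cfg0$strategies[[1]]
  cost_u <- sum(tr$diabetes_prev) * cfg0$costs$ae_cost$diabetes
  qaly_u <- -sum(tr$diabetes_prev) * cfg0$utilities$disutility$diabetes * DELTA_YEARS
  for (l in 1:4) {
    trt <- line_treatment(st, l)
    for (s in c("ACUTE", "STABLE_ADH", "STABLE_NONADH", "RELAPSE")) {
      occ <- tr$occ_cls[, l, s]
      cost_u <- cost_u + sum(occ) * cycle_cost(cfg0, trt, s)
      qaly_u <- qaly_u + sum(occ) * cycle_qaly(cfg0, trt, s)
    }
  }
  expect_equal(r0$total_cost_cny, cost_u, tolerance = 1e-9)
  expect_equal(r0$total_qaly, qaly_u, tolerance = 1e-9)
  rd <- summarise_trace(run_cohort(cfg, "lurasidone", keep_clock = FALSE), cfg)
  expect_lt(rd$total_cost_cny, r0$total_cost_cny)
  expect_lt(rd$total_qaly, r0$total_qaly)
})

test_that("half-cycle correction reduces totals by the half end-weights", {
  cfg <- base_cfg()
  hcc <- config_set(cfg, "settings.half_cycle_correction", TRUE)
  tr <- run_cohort(cfg, "lurasidone", keep_clock = FALSE)
  a <- summarise_trace(tr, cfg)
  b <- summarise_trace(tr, hcc)
  expect_lt(b$total_cost_cny, a$total_cost_cny)
  expect_lt(b$total_qaly, a$total_qaly)
})

test_that("strategy comparison reproduces the worked incremental example", {
  ref <- reference_results()
  lur <- list(strategy = "lurasidone",
              total_cost_cny = ref$total_cost_cny[1], total_qaly = ref$total_qaly[1])
  olz <- list(strategy = "olanzapine",
              total_cost_cny = ref$total_cost_cny[2], total_qaly = ref$total_qaly[2])
  cmp <- compare_strategies(lur, olz, wtp = 72447)
  expect_equal(cmp$delta_cost, 12093, tolerance = 1e-9)
  expect_equal(cmp$delta_qaly, 0.197, tolerance = 1e-9)
  expect_identical(cmp$label, "dominant")
  expect_true(is.na(cmp$icer))
  expect_equal(cmp$nmb, 26365.059, tolerance = 1e-6)
})

test_that("comparison labels cover ICER, dominated and degenerate cases", {
  a <- list(strategy = "a", total_cost_cny = 1000, total_qaly = 2.0)
  b <- list(strategy = "b", total_cost_cny = 900, total_qaly = 1.9)
  cmp <- compare_strategies(a, b, wtp = 5000)
  expect_identical(cmp$label, "icer")   # reference costlier but more effective
  expect_equal(cmp$icer, 100 / 0.1, tolerance = 1e-9)
  expect_equal(cmp$nmb, 5000 * 0.1 - 100, tolerance = 1e-9)
  # reference both costlier and less effective than the comparator
  d <- list(strategy = "d", total_cost_cny = 1100, total_qaly = 1.9)
  dom <- compare_strategies(d, a, wtp = 5000)
  expect_identical(dom$label, "dominated")
  # cheaper but less effective is an ICER trade-off, not dominance
  expect_identical(compare_strategies(b, a, wtp = 5000)$label, "icer")
  same_q <- list(strategy = "c", total_cost_cny = 1200, total_qaly = 2.0)
  expect_warning(tie <- compare_strategies(a, same_q, 5000), "zero QALY")
  expect_identical(tie$label, "dominant")
  eq <- compare_strategies(a, a, 5000)
  expect_identical(eq$label, "equivalent")
})

test_that("currency conversion rounds half-up at the fixed rate", {
  s <- base_cfg()$settings
  expect_equal(to_usd(12093, s), 1753)
  expect_equal(to_usd(6781, s), 983)
  expect_equal(to_usd(0, s), 0)
  expect_equal(to_usd(-12093, s), -1753)
  expect_equal(to_usd(3.45, s), 1)       # 0.5 rounds away from zero
  expect_equal(to_usd(12093, s, round = FALSE), 12093 / 6.9, tolerance = 1e-12)
})

test_that("run_cea compares every alternative against the reference", {
  cfg <- base_cfg()
  res <- run_cea(cfg)
  expect_named(res$results, c("lurasidone", "olanzapine", "risperidone"))
  expect_named(res$comparisons, c("olanzapine", "risperidone"))
  tab <- tidy(res)
  expect_identical(nrow(tab), 3L)
  expect_true(is.na(tab$incr_cost_cny[tab$strategy == "lurasidone"]))
  # report rows carry the reference-vs-comparator incrementals
  expect_equal(tab$incr_cost_cny[tab$strategy == "olanzapine"],
               res$results$lurasidone$total_cost_cny -
                 res$results$olanzapine$total_cost_cny,
               tolerance = 1e-9)
  expect_equal(tab$incr_qaly[tab$strategy == "olanzapine"],
               res$results$lurasidone$total_qaly -
                 res$results$olanzapine$total_qaly,
               tolerance = 1e-9)
  g <- glance(res)
  expect_identical(g$reference, "lurasidone")
  expect_identical(g$n_strategies, 3L)
  # broom-style accessors on the pieces
  expect_identical(nrow(tidy(res$results$lurasidone)), 8L)
  expect_identical(nrow(tidy(res$comparisons$olanzapine)), 1L)
})
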