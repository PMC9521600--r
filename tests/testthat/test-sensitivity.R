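test_that("CI-to-SE conversion matches the closed forms", {
  expect_equal(se_from_ci(0.52, 1.02, "lognormal"), 0.171872823864, tolerance = 1e-4)
  expect_equal(se_from_ci(0.874, 0.964, "beta"), 0.0229596053805, tolerance = 1e-9)
  expect_equal(se_from_ci(80, 120, "gamma"), 40 / (2 * 1.959964), tolerance = 1e-9)
  expect_error(se_from_ci(1.02, 0.52, "lognormal"), "low")
  expect_error(se_from_ci(-1, 2, "lognormal"), "positive")
  expect_error(se_from_ci(0, 1, "nope"), "unknown family")
})

test_that("distribution builders hit their moment targets", {
  # lognormal: point estimate is the median
  d <- make_distribution(list(point = 0.72, low = 0.52, high = 1.02,
                              family = "lognormal"))
  expect_equal(d$meanlog, log(0.72), tolerance = 1e-12)
  expect_equal(qlnorm(0.5, d$meanlog, d$sdlog), 0.72, tolerance = 1e-12)
  # beta: mean 0.5, SE 0.1 gives shape1 = shape2 = 12
  d <- make_distribution(list(point = 0.5, low = 0.3040036, high = 0.6959964,
                              family = "beta"))
  expect_equal(d$shape1, 12, tolerance = 1e-4)
  expect_equal(d$shape2, 12, tolerance = 1e-4)
  # gamma: mean 100, SE 10 gives shape 100, scale 1
  d <- make_distribution(list(point = 100, low = 80.40036, high = 119.59964,
                              family = "gamma"))
  expect_equal(d$shape, 100, tolerance = 1e-4)
  expect_equal(d$scale, 1, tolerance = 1e-5)
  # degenerate interval collapses to the point
  d <- make_distribution(list(point = 0.4, low = 0.4, high = 0.4, family = "beta"))
  expect_identical(d$family, "degenerate")
  expect_equal(d$sample(5), rep(0.4, 5))
})

test_that("sampled moments recover the targets (reduced draw count)", {
  n <- 5000
  d <- make_distribution(list(point = 0.919, low = 0.874, high = 0.964,
                              family = "beta"))
  set.seed(101)
  x <- d$sample(n)
  se <- 0.0229596053805
  expect_lt(abs(mean(x) - 0.919), 3 * se / sqrt(n))
  expect_lt(abs(sd(x) - se), 3 * se / sqrt(2 * n))
  d <- make_distribution(list(point = 312.48, low = 234.36, high = 390.60,
                              family = "gamma"))
  set.seed(102)
  x <- d$sample(n)
  se <- se_from_ci(234.36, 390.60, "gamma")
  expect_lt(abs(mean(x) - 312.48), 3 * se / sqrt(n))
  expect_lt(abs(sd(x) - se), 3 * se / sqrt(2 * n))
})

test_that("infeasible beta moment-matching falls back to a bounded uniform", {
  expect_warning(
    d <- make_distribution(list(point = 0.5, low = 0, high = 2, family = "beta")),
    "infeasible")
  expect_identical(d$family, "uniform")
  set.seed(1)
  x <- d$sample(1000)
  expect_true(all(x >= 0.375 & x <= 0.625))
})

test_that("the tornado sweep is sorted, attributed and side-effect free", {
  cfg <- trimmed_cfg()
  before <- config_text(cfg)
  ow <- run_owsa(cfg, wtp = 72447)
  expect_identical(config_text(cfg), before)
  expect_identical(nrow(ow), nrow(cfg$estimates))
  expect_true(all(diff(ow$range) <= 1e-9))
  expect_true(all(ow$valid))
  expect_identical(attr(ow, "reference"), "lurasidone")
  expect_identical(attr(ow, "comparator"), "olanzapine")
  expect_true(is.finite(attr(ow, "nmb_base")))
  # the bound runs bracket a re-computable perturbation
  row <- ow[ow$parameter == "utilities.u_stable", ]
  cfg_lo <- config_set(cfg, "utilities.u_stable", row$low_value)
  r <- summarise_trace(run_cohort(cfg_lo, "lurasidone", keep_clock = FALSE), cfg_lo)
  cmp <- summarise_trace(run_cohort(cfg_lo, "olanzapine", keep_clock = FALSE), cfg_lo)
  expect_equal(compare_strategies(r, cmp, 72447)$nmb, row$nmb_at_low,
               tolerance = 1e-9)
})

test_that("PSA draws are reproducible and use per-parameter substreams", {
  cfg <- trimmed_cfg()
  p1 <- suppressMessages(run_psa(cfg, n_iterations = 20, seed = 5))
  p2 <- suppressMessages(run_psa(cfg, n_iterations = 20, seed = 5))
  expect_equal(p1$samples, p2$samples)
  expect_equal(p1$draws, p2$draws)
  p3 <- suppressMessages(run_psa(cfg, n_iterations = 20, seed = 6))
  expect_false(isTRUE(all.equal(p1$draws, p3$draws)))
  # dropping a parameter leaves the other parameters' draws untouched
  cfg2 <- cfg
  cfg2$estimates <- cfg$estimates[-nrow(cfg$estimates), ]
  p4 <- suppressMessages(run_psa(cfg2, n_iterations = 20, seed = 5))
  shared <- cfg2$estimates$path
  expect_equal(p1$draws[shared], p4$draws[shared])
  # the tornado-only discount rate is never sampled
  full <- base_cfg()
  expect_false("settings.discount_rate_annual" %in% colnames(p1$draws))
  expect_identical(sum(full$estimates$owsa_only), 1L)
})

test_that("point-collapsed PSA reproduces the deterministic base case", {
  cfg <- trimmed_cfg()
  cfg$estimates$low <- cfg$estimates$point
  cfg$estimates$high <- cfg$estimates$point
  psa <- run_psa(cfg, n_iterations = 3, seed = 9)
  det <- run_cea(cfg)
  for (sn in psa$strategies) {
    rows <- psa$samples[psa$samples$strategy == sn, ]
    expect_equal(rows$total_cost_cny,
                 rep(det$results[[sn]]$total_cost_cny, 3), tolerance = 1e-12)
    expect_equal(rows$total_qaly,
                 rep(det$results[[sn]]$total_qaly, 3), tolerance = 1e-12)
  }
})

test_that("the acceptability curve has coherent probabilities", {
  cfg <- trimmed_cfg()
  psa <- suppressMessages(run_psa(cfg, n_iterations = 40, seed = 12))
  cc <- ceac(psa, c(0, 72447, 144894))
  expect_identical(nrow(cc), 3L)
  probs <- as.matrix(cc[, -1])
  expect_true(all(probs >= 0 & probs <= 1))
  # the overall event is contained in each pairwise event
  expect_true(all(cc$prob_ce_overall <=
                    pmin(cc$prob_ce_vs_olanzapine, cc$prob_ce_vs_risperidone) + 1e-12))
})

test_that("exact NMB ties split the overall probability equally", {
  psa <- structure(list(
    samples = tibble::tibble(
      iteration = c(1L, 1L), strategy = c("a", "b"),
      total_cost_cny = c(100, 100), total_qaly = c(1, 1)),
    strategies = c("a", "b"), n_iterations = 1L, seed = 1L),
    class = "psa_result")
  cc <- ceac(psa, 50000, reference = "a")
  expect_equal(cc$prob_ce_vs_b, 0)
  expect_equal(cc$prob_ce_overall, 0.5)
})
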