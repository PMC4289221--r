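test_that("KM estimates match hand product-limit computations", {
  # all events at distinct times
  g <- survival_group("a", c(1, 2, 3), c(1, 1, 1))
  km <- km_estimate(g)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km_surv_at(km, 0.5), 1)
  expect_equal(km_surv_at(km, 1), 2 / 3)
  expect_equal(km_surv_at(km, 2.5), 1 / 3)

  # censoring mid-series: S(3) = (2/3) * (1 - 1/1) = 0
  g2 <- survival_group("b", c(1, 2, 3), c(1, 0, 1))
  km2 <- km_estimate(g2)
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)

  # all censored -> flat at 1
  g3 <- survival_group("c", c(1, 4, 9), c(0, 0, 0))
  expect_true(all(km_estimate(g3)$surv == 1))

  expect_error(survival_group("d", c(0, 1), c(1, 1)), "positive")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(41)
  for (rep in 1:10) {
    times <- round(rexp(30, 0.2) + 0.01, 3)
    g <- survival_group("x", times, rep(1, 30))
    km <- km_estimate(g)
    oc <- oracle_km(times, rep(1, 30))
    expect_equal(km$surv[km$n_event > 0], oc$surv, tolerance = 1e-12)
    # empirical tail probability
    for (t in sample(times, 5))
      expect_equal(km_surv_at(km, t), mean(times > t), tolerance = 1e-12)
  }
})

test_that("horizon truncation censors later events", {
  g <- survival_group("a", c(2, 8, 12, 15), c(1, 1, 1, 1))
  km <- km_estimate(g, horizon = 10)
  expect_true(all(km$time <= 10))
  expect_equal(sum(km$n_event), 2)
  expect_equal(km_surv_at(km, 10), 2 / 4)
})

test_that("log-rank agrees with the hand risk-set tabulation and chisq identity", {
  t1 <- c(1, 3, 5, 7); e1 <- c(1, 1, 0, 1)
  t2 <- c(2, 4, 6, 8); e2 <- c(1, 0, 1, 1)
  lr <- logrank_test(list(survival_group("a", t1, e1),
                          survival_group("b", t2, e2)))
  oc <- oracle_logrank_oe(t1, e1, t2, e2)
  expect_equal(unname(lr$observed), oc$O)
  expect_equal(unname(lr$expected), oc$E, tolerance = 1e-10)
  expect_equal(lr$statistic, oc$chisq, tolerance = 1e-10)
  expect_equal(lr$df, 1)
  expect_equal(lr$p_value, pchisq(oc$chisq, 1, lower.tail = FALSE))
})

test_that("identical groups give a null statistic and label order does not matter", {
  g <- survival_group("a", c(1, 2, 4, 8), c(1, 0, 1, 1))
  g2 <- survival_group("b", g$times, g$events)
  lr <- logrank_test(list(g, g2))
  expect_lt(lr$statistic, 1e-10)
  expect_gt(lr$p_value, 0.999)

  set.seed(52)
  ga <- survival_group("a", rexp(20, 0.2), rbinom(20, 1, 0.8))
  gb <- survival_group("b", rexp(20, 0.5), rbinom(20, 1, 0.8))
  lr_ab <- logrank_test(list(ga, gb))
  lr_ba <- logrank_test(list(gb, ga))
  expect_equal(lr_ab$statistic, lr_ba$statistic, tolerance = 1e-12)
  # time-unit rescaling leaves the statistic unchanged
  ga_m <- survival_group("a", ga$times * 12, ga$events)
  gb_m <- survival_group("b", gb$times * 12, gb$events)
  expect_equal(logrank_test(list(ga_m, gb_m))$statistic, lr_ab$statistic,
               tolerance = 1e-12)

  gz <- survival_group("z", c(1, 2), c(0, 0))
  expect_error(logrank_test(list(gz, gz)), "zero events")
})

test_that("two-group chi-square equals the squared O/E normal statistic", {
  set.seed(53)
  for (rep in 1:10) {
    ga <- survival_group("a", rexp(25, 0.2) + 0.01, rbinom(25, 1, 0.7))
    gb <- survival_group("b", rexp(25, 0.4) + 0.01, rbinom(25, 1, 0.7))
    if (sum(ga$events) == 0 || sum(gb$events) == 0) next
    lr <- logrank_test(list(ga, gb))
    oc <- oracle_logrank_oe(ga$times, ga$events, gb$times, gb$events)
    z <- (oc$O[1] - oc$E[1]) / sqrt(oc$V)
    expect_equal(lr$statistic, z^2, tolerance = 1e-10)
  }
})

test_that("O/E hazard ratios follow the definition and recover simulated truth", {
  # identical groups -> HR exactly 1
  g <- survival_group("a", c(1, 2, 4, 8), c(1, 1, 0, 1))
  hr <- hazard_ratio(g, survival_group("b", g$times, g$events))
  expect_equal(hr$hr, 1, tolerance = 1e-12)

  # agreement with the O/E definition on random groups
  set.seed(60)
  ga <- survival_group("a", rexp(30, 0.1) + 0.01, rbinom(30, 1, 0.8))
  gb <- survival_group("b", rexp(30, 0.3) + 0.01, rbinom(30, 1, 0.8))
  hr_pkg <- hazard_ratio(ga, gb)
  oc <- oracle_logrank_oe(ga$times, ga$events, gb$times, gb$events)
  expect_equal(hr_pkg$hr, (oc$O[1] / oc$E[1]) / (oc$O[2] / oc$E[2]),
               tolerance = 1e-10)

  set.seed(54)
  a <- survival_group("treated", rexp(500, 0.1), rep(1, 500))
  b <- survival_group("control", rexp(500, 0.2), rep(1, 500))
  hr2 <- hazard_ratio(a, b)
  expect_gt(hr2$hr, 0.42)
  expect_lt(hr2$hr, 0.58)
  expect_lt(hr2$ci_lower, hr2$hr)
  expect_gt(hr2$ci_upper, hr2$hr)
})

test_that("landmark analysis splits periods correctly", {
  # all events before the landmark
  lm <- landmark_compare(c(1, 2, 3, 6, 7), c(1, 1, 1, 0, 0), landmark = 5)
  expect_equal(lm$events_early, 3)
  expect_equal(lm$events_late, 0)
  expect_equal(lm$n_at_risk_late, 2)
  expect_false(lm$majority_late)

  # hazard concentrated after year 5
  times <- c(5.5, 6, 7, 8, 9.5, 2, 3)
  events <- c(1, 1, 1, 1, 1, 0, 0)
  lm2 <- landmark_compare(times, events, landmark = 5)
  expect_equal(lm2$events_early, 0)
  expect_true(lm2$majority_late)

  expect_error(landmark_compare(c(1, 2), c(1, 1), landmark = -1), "positive")
})

test_that("a treatment effect confined to the early period shows up as early HR < late HR", {
  sim_piecewise <- function(n, rate_early, rate_late, landmark = 5) {
    early <- rexp(n, rate_early)
    late <- landmark + rexp(n, rate_late)
    ifelse(early <= landmark, early, late)
  }
  set.seed(55)
  wins <- vapply(1:60, function(rep) {
    t_trt <- sim_piecewise(150, 0.25 * 0.12, 0.12)
    t_ctl <- sim_piecewise(150, 0.12, 0.12)
    times <- c(t_trt, t_ctl)
    events <- rep(1L, 300)
    strata <- rep(c("treated", "untreated"), each = 150)
    lm <- landmark_compare(times, events, strata = strata, landmark = 5,
                           horizon = 10)
    isTRUE(lm$early$defined) && isTRUE(lm$late$defined) &&
      lm$early$hr < lm$late$hr
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("subgroup survival summarizes per-group outcome and joint test", {
  sc <- generate_subtyped_cohort(subtyped_cohort_spec(
    n_samples = 300, k_true = 3, n_signature_genes_per_group = 4,
    n_noise_genes = 0, survival_scales_years = c(3, 10, 40),
    censor_time_years = 12, seed = 21))
  ss <- subgroup_survival(sc$clinical, sc$group, horizon = 10)
  expect_equal(nrow(ss$per_group), 3)
  # shorter planted scale -> worse 10-year survival
  expect_lt(ss$per_group$surv_at_horizon[1], ss$per_group$surv_at_horizon[3])
  expect_lt(ss$logrank$p_value, 1e-6)
})
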