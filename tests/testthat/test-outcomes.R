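test_that("cohort simulation is seed-deterministic and rejects degenerate setups", {
  a <- simulate_cohort(200, seed = 3)
  b <- simulate_cohort(200, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(200, seed = 4)))
  expect_error(simulate_cohort(10, hazards = c(low = 0)), "positive")
  expect_error(simulate_cohort(10, censor_range = c(0, 0)), "zero follow-up")
})

test_that("a 2:1 hazard ratio is recovered by the rate estimator on a large cohort", {
  co <- simulate_cohort(5000, seed = 21, hazards = c(low = 0.05, high = 0.10),
                        death_hazard = 0.01, censor_range = c(2, 10))
  pt <- person_time(co, by = "stratum")
  r <- pt$events / pt$person_years
  ratio <- r[pt$stratum == "high"] / r[pt$stratum == "low"]
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("person-time counts events only when the event terminates follow-up", {
  rec <- tibble::tibble(
    person_id = c("a", "b", "c"),
    cmr_date = as.Date("2010-01-01"),
    event_date = as.Date(c("2012-01-01", NA, "2015-06-01")),
    death_date = as.Date(c(NA, NA, "2014-01-01")),
    last_encounter_date = as.Date(c("2013-01-01", "2013-01-01", "2014-01-01")))
  pt <- person_time(rec)
  # a: event at 2.0y; b: censored at 3.0y; c: death at 4.0y precedes event
  expect_equal(pt$events, 1)
  expect_equal(pt$person_years, (730 + 1096 + 1461) / 365.25, tolerance = 1e-10)

  neg <- dplyr::mutate(rec, event_date = as.Date("2009-01-01"))
  expect_error(person_time(neg), "negative follow-up.*a")
})

test_that("incidence rates and exact Poisson intervals match the chi-square closed form", {
  r <- incidence_rate(10, 500)
  expect_equal(r$rate, 2.0)  # 10 events / 500 PY = 2 per 100 PY
  expect_equal(r$lo, 100 * qchisq(0.025, 20) / 2 / 500)
  expect_equal(r$hi, 100 * qchisq(0.975, 22) / 2 / 500)

  # independent oracle: invert the Poisson CDF numerically
  lo_num <- uniroot(function(mu) 1 - ppois(10 - 1, mu) - 0.025, c(1e-9, 100))$root
  hi_num <- uniroot(function(mu) ppois(10, mu) - 0.025, c(1e-9, 100))$root
  expect_equal(r$lo, 100 * lo_num / 500, tolerance = 1e-6)
  expect_equal(r$hi, 100 * hi_num / 500, tolerance = 1e-6)

  r0 <- incidence_rate(0, 100)
  expect_equal(r0$lo, 0)
  expect_gt(r0$hi, 0)
  expect_true(r$lo <= r$rate && r$rate <= r$hi)
})

test_that("exact intervals cover the true rate at (at least) nominal frequency", {
  true_rate <- 0.03; py <- 800
  set.seed(11)
  events <- rpois(2000, true_rate * py)
  covered <- vapply(events, function(k) {
    ci <- incidence_rate(k, py, per = 1)
    ci$lo <= true_rate && true_rate <= ci$hi
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("the two-sample rate comparison is symmetric with exact null behaviour", {
  a <- incidence_rate(20, 1000)
  b <- incidence_rate(60, 1000)
  ab <- compare_rates(a, b)
  ba <- compare_rates(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$statistic, -ba$statistic)
  # closed-form oracle
  pooled <- 80 / 2000
  z <- (0.02 - 0.06) / sqrt(pooled * (1 / 1000 + 1 / 1000))
  expect_equal(ab$statistic, z)
  expect_equal(ab$p_value, 2 * pnorm(-abs(z)))
  # identical groups: z = 0, p = 1
  same <- compare_rates(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("quartile stratification sends ties down and thresholds are strict", {
  q <- stratify(1:8, "quartile")
  expect_equal(unname(table(q)), rep(2L, 4), ignore_attr = TRUE)
  # a value equal to the cut point goes to the lower stratum
  x <- c(1, 2, 3, 4)  # Q1 cut = 1.75, median 2.5, Q3 cut = 3.25
  expect_equal(stratify(c(1.75, 1.76), "quartile", )[1], stratify(x, "quartile")[1])
  expect_equal(stratify(c(49.9, 50, 50.1), "threshold", cut = 50),
               c("abnormal", "normal", "normal"))
  expect_equal(stratify(c(44.9, 45), "threshold", cut = 45), c("abnormal", "normal"))
  expect_warning(stratify(rep(5, 10), "quartile"), "identical")
})

test_that("per-stratum person-years are conserved and rates are hazard-monotone", {
  co <- simulate_cohort(4000, seed = 9,
                        hazards = c(q1 = 0.02, q2 = 0.04, q3 = 0.06, q4 = 0.08),
                        death_hazard = 0.01)
  pt <- person_time(co, by = "stratum")
  expect_equal(sum(pt$person_years), person_time(co)$person_years)
  rates <- (pt$events / pt$person_years)[order(pt$stratum)]
  expect_true(all(diff(rates) > 0))
  rt <- incidence_by_stratum(co)
  expect_s3_class(rt, "rate_table")
  cmp <- attr(rt, "comparison")
  expect_lt(cmp$p_value, 0.05)
})

test_that("first/last report selection is date-ordered with id tie-breaks", {
  meas <- tibble::tibble(
    person_id = c("p1", "p1", "p2", "p3", "p3"),
    report_id = c("r1", "r2", "r3", "r5", "r4"),
    report_date = c("2010-01-01", "2012-06-01", "2011-01-01", "2011-01-01", "2011-01-01"),
    label = "lvmi", value = c(80, 95, 70, 60, 65))
  first <- select_report(meas, "first", persons = c("p1", "p2", "p3", "p4"))
  expect_equal(first$value[first$person_id == "p1"], 80)
  last <- select_report(meas, "last")
  expect_equal(last$value[last$person_id == "p1"], 95)
  # single report: itself in both modes
  expect_equal(first$value[first$person_id == "p2"],
               last$value[last$person_id == "p2"])
  # date tie broken by report id
  expect_equal(first$report_id[first$person_id == "p3"], "r4")
  excl <- attr(first, "excluded")
  expect_equal(excl$person_id, "p4")
})
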