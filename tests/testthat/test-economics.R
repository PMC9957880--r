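p_default <- des_params()
cohort1 <- tibble::tibble(patient_id = 1L, sex = "male",
                          entry_age = 36, defect_size_cm2 = 4)

test_that("discounting matches the closed form", {
  expect_equal(discount(1000, 0, 0.02), 1000)
  expect_equal(discount(1000, 10, 0.02), 1000 * 1.02^-10)
  expect_lt(abs(discount(1000, 10, 0.02) - 820.35), 0.005)
  expect_equal(discount(c(5, 7), c(3, 40), 0), c(5, 7))
  expect_error(discount(1, -1, 0.02), "negative")
})

test_that("QALY accrual reproduces hand-computed sums", {
  p <- des_params()
  p$economics$conservative_cost <- 0
  # one year symptomatic before any repair, then death
  traj <- make_traj(list(
    list(t = 1, kind = "death")))
  res <- accrue(traj, cohort1, p, rate = 0)
  expect_equal(res$qaly, 0.65)
  expect_equal(res$cost, 0)
  # primary ACI at entry, death after three years: 0.76 + 2 x 0.82
  traj <- make_traj(list(
    list(t = 0, kind = "intervention", trt = "maci", cost = 11000),
    list(t = 3, kind = "death")))
  res <- accrue(traj, cohort1, p, rate = 0)
  expect_equal(res$qaly, 0.76 + 2 * 0.82)
  expect_equal(res$cost, 11000)
  # discounted: annual slices at their start
  res_d <- accrue(traj, cohort1, p, rate = 0.02)
  expect_equal(res_d$qaly_disc,
               0.76 + 0.82 * (1.02^-1 + 1.02^-2), tolerance = 1e-12)
  expect_equal(res_d$cost_disc, 11000)
  # immediate death: procedure cost only, no QALYs
  traj <- make_traj(list(
    list(t = 0, kind = "perioperative_death", trt = "tkr", cost = 9000)))
  res <- accrue(traj, cohort1, p, rate = 0)
  expect_equal(res$qaly, 0)
  expect_equal(res$cost, 9000)
})

test_that("microfracture benefit decays from year five", {
  p <- des_params()
  p$economics$conservative_cost <- 0
  traj <- make_traj(list(
    list(t = 0, kind = "intervention", trt = "mf", cost = 1500),
    list(t = 7, kind = "death")))
  res <- accrue(traj, cohort1, p, rate = 0)
  expect_equal(res$qaly, 0.76 + 3 * 0.82 + 3 * 0.65)
})

test_that("knee-replacement states use the replacement utilities", {
  p <- des_params()
  p$economics$conservative_cost <- 0
  traj <- make_traj(list(
    list(t = 0, kind = "intervention", trt = "tkr", cost = 9000),
    list(t = 10, kind = "implant_failure", trt = "tkr"),
    list(t = 11, kind = "intervention", trt = "tkr_revision", cost = 15000),
    list(t = 13, kind = "death")))
  res <- accrue(traj, cohort1, p, rate = 0)
  expect_equal(res$qaly, 10 * 0.78 + 1 * 0.56 + 2 * 0.78)
  expect_equal(res$cost, 24000)
  # a failed revision leaves the patient in the no-further-replacement state
  traj2 <- make_traj(list(
    list(t = 0, kind = "intervention", trt = "tkr", cost = 9000),
    list(t = 10, kind = "implant_failure", trt = "tkr"),
    list(t = 11, kind = "intervention", trt = "tkr_revision", cost = 15000),
    list(t = 15, kind = "implant_failure", trt = "tkr_revision"),
    list(t = 20, kind = "death")))
  res2 <- accrue(traj2, cohort1, p, rate = 0)
  expect_equal(res2$qaly, 10 * 0.78 + 1 * 0.56 + 4 * 0.78 + 5 * 0.69)
})

test_that("unit utilities make undiscounted QALYs equal survival time", {
  p <- des_params()
  p$economics$utilities <- lapply(utility_schedule_default(), function(x) 1)
  cohort <- sample_cohort(250, seed = 41)
  traj <- run_scenarios(cohort, p, seed = 41)
  res <- accrue(traj, cohort, p, rate = 0)
  deaths <- traj[traj$event_kind %in% c("death", "perioperative_death"),
                 c("patient_id", "scenario", "time_years")]
  m <- merge(res, deaths, by = c("patient_id", "scenario"))
  expect_equal(m$qaly, m$time_years, tolerance = 1e-9)
})

test_that("with no conservative therapy, costs equal the event ledger", {
  p <- des_params()
  p$economics$conservative_cost <- 0
  cohort <- sample_cohort(250, seed = 43)
  traj <- run_scenarios(cohort, p, seed = 43)
  res <- accrue(traj, cohort, p, rate = 0)
  ledger <- stats::aggregate(cost_eur ~ patient_id + scenario, traj, sum)
  m <- merge(res, ledger, by = c("patient_id", "scenario"))
  expect_equal(m$cost, m$cost_eur, tolerance = 1e-9)
  # and discounted cost equals the discounted event ledger
  res_d <- accrue(traj, cohort, p, rate = 0.02)
  traj$dc <- discount(traj$cost_eur, traj$time_years, 0.02)
  ledger_d <- stats::aggregate(dc ~ patient_id + scenario, traj, sum)
  m2 <- merge(res_d, ledger_d, by = c("patient_id", "scenario"))
  expect_equal(m2$cost_disc, m2$dc, tolerance = 1e-9)
})

test_that("discounting never increases accrued totals", {
  cohort <- sample_cohort(150, seed = 47)
  traj <- run_scenarios(cohort, p_default, seed = 47)
  res0 <- accrue(traj, cohort, p_default, rate = 0)
  res2 <- accrue(traj, cohort, p_default, rate = 0.02)
  expect_true(all(res2$qaly_disc <= res0$qaly + 1e-9))
  expect_true(all(res2$cost_disc <= res0$cost + 1e-9))
  expect_equal(res0$qaly, res0$qaly_disc)
})

test_that("the printed component means reproduce the printed ICER", {
  ic <- compute_icer(cost_with = 18590, cost_without = 14134,
                     qaly_with = 22.53, qaly_without = 21.21)
  expect_lt(abs(ic$icer - 3376), 1)
})

test_that("ICER degenerate and dominance cases are flagged", {
  ic <- compute_icer(cost_with = 100, cost_without = 100,
                     qaly_with = 2, qaly_without = 2)
  expect_true(is.na(ic$icer))
  expect_equal(ic$dominance, "undefined")
  ic <- compute_icer(cost_with = 900, cost_without = 1000,
                     qaly_with = 2.1, qaly_without = 2)
  expect_equal(ic$dominance, "dominant")
  expect_lt(ic$icer, 0)
  ic <- compute_icer(cost_with = 1100, cost_without = 1000,
                     qaly_with = 1.9, qaly_without = 2)
  expect_equal(ic$dominance, "dominated")
})

test_that("CEAC matches a brute-force per-patient oracle", {
  set.seed(53)
  paired <- tibble::tibble(
    patient_id = 1:400,
    d_cost = stats::rnorm(400, 4000, 6000),
    d_qaly = stats::rnorm(400, 1.3, 1.5))
  paired$d_qaly[1:10] <- 0  # exercise ties
  wtp <- seq(0, 50000, by = 2500)
  ceac <- compute_ceac(paired, wtp)
  expect_equal(ceac$probability_cost_effective, ceac_oracle(paired, wtp))
  # definition at zero willingness to pay
  expect_equal(ceac$probability_cost_effective[1],
               mean(paired$d_cost <= 0))
  # limit at very large willingness to pay
  big <- compute_ceac(paired, 1e12)$probability_cost_effective
  expect_equal(big, mean(paired$d_qaly > 0 |
                           (paired$d_qaly == 0 & paired$d_cost <= 0)))
})

test_that("CEAC is non-decreasing when all QALY gains are non-negative", {
  set.seed(59)
  paired <- tibble::tibble(
    patient_id = 1:300,
    d_cost = stats::rnorm(300, 4000, 5000),
    d_qaly = stats::runif(300, 0, 3))
  ceac <- compute_ceac(paired, seq(0, 60000, by = 1000))
  expect_true(all(diff(ceac$probability_cost_effective) >= 0))
  expect_error(compute_ceac(paired, numeric(0)), "at least one")
})

test_that("dominant fraction counts strict cost savings with QALY gains", {
  paired <- tibble::tibble(patient_id = 1:4,
                           d_cost = c(-1, -1, 1, 0),
                           d_qaly = c(1, -1, 1, 1))
  expect_equal(dominant_fraction(paired), 0.25)
})
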