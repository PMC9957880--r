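p_default <- des_params()

test_that("treatment selection enforces the eligibility rules", {
  u <- seq(0.005, 0.995, by = 0.01)
  # small defect, counterfactual scenario: MF on offer, M-ACI never
  picks <- vapply(u, function(x)
    select_treatment(1.5, 30, 0, "without_maci", p_default, u = x),
    character(1))
  expect_true("mf" %in% picks)
  expect_false("maci" %in% picks)
  # massive defect at 40: PKR possible, TKR outside its age window
  picks <- vapply(u, function(x)
    select_treatment(12, 40, 0, "without_maci", p_default, u = x),
    character(1))
  expect_true("pkr" %in% picks)
  expect_false("tkr" %in% picks)
  # same defect at 60: TKR now on offer
  picks <- vapply(u, function(x)
    select_treatment(12, 60, 0, "without_maci", p_default, u = x),
    character(1))
  expect_true("tkr" %in% picks)
  # with M-ACI available every primary is an M-ACI
  picks <- vapply(u, function(x)
    select_treatment(4, 36, 0, "with_maci", p_default, u = x),
    character(1))
  expect_true(all(picks == "maci"))
  # microfracture never offered beyond its defect bound
  picks <- vapply(u, function(x)
    select_treatment(4, 50, 2, "without_maci", p_default, u = x),
    character(1))
  expect_false("mf" %in% picks)
})

test_that("first event in the with-M-ACI scenario is an M-ACI at entry", {
  profile <- tibble::tibble(patient_id = 1L, sex = "male",
                            entry_age = 36, defect_size_cm2 = 4)
  traj <- simulate_patient(profile, "with_maci", p_default, seed = 5)
  expect_equal(traj$event_kind[1], "intervention")
  expect_equal(traj$treatment[1], "maci")
  expect_equal(traj$time_years[1], 0)
  expect_equal(traj$cost_eur[1], 11000)
})

test_that("a failure model that never fails yields one surgery then death", {
  p <- des_params()
  p$treatments$maci$failure <- list(
    two_year = 1e-8, anchors = data.frame(t = 25, s = 0.99999),
    mixture_weight = 0.5, short_shape = 1, long_shape = 2.5)
  cohort <- sample_cohort(200, seed = 3)
  traj <- run_scenarios(cohort, p, seed = 3)
  wi <- traj[traj$scenario == "with_maci", ]
  counts <- table(wi$event_kind)
  expect_equal(unname(counts[["intervention"]]), 200)
  expect_equal(unname(counts[["death"]]), 200)
  expect_false("implant_failure" %in% names(counts))
})

test_that("paired runs are bit-identical for a fixed seed", {
  cohort <- sample_cohort(150, seed = 7)
  a <- run_scenarios(cohort, p_default, seed = 7)
  b <- run_scenarios(cohort, p_default, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, run_scenarios(cohort, p_default, seed = 8)))
})

test_that("trajectory invariants hold: ordered times, one terminal death", {
  cohort <- sample_cohort(600, seed = 13)
  traj <- run_scenarios(cohort, p_default, seed = 13)
  for (sc in c("with_maci", "without_maci")) {
    sub <- traj[traj$scenario == sc, ]
    split_t <- split(seq_len(nrow(sub)), sub$patient_id)
    for (idx in split_t) {
      tt <- sub$time_years[idx]
      kinds <- sub$event_kind[idx]
      expect_true(all(diff(tt) > 0))
      expect_true(all(tt >= 0))
      death_kinds <- kinds %in% c("death", "perioperative_death")
      expect_equal(sum(death_kinds), 1)
      expect_true(death_kinds[length(kinds)])
    }
  }
})

test_that("death ages are shared across scenarios (common random numbers)", {
  p <- des_params()
  p$engine$periop_mortality <- c(young = 0, old = 0)
  cohort <- sample_cohort(300, seed = 19)
  traj <- run_scenarios(cohort, p, seed = 19)
  deaths <- traj[traj$event_kind == "death", ]
  wide <- tidyr::pivot_wider(deaths[, c("patient_id", "scenario",
                                        "time_years")],
                             names_from = "scenario",
                             values_from = "time_years")
  expect_equal(wide$with_maci, wide$without_maci)
  # and the sampled death ages match the stand-alone sampler
  d <- sample_death_ages(cohort, p$life_table, seed = 19)
  expect_equal(wide$with_maci[order(wide$patient_id)],
               (d$death_age - d$entry_age)[order(d$patient_id)],
               tolerance = 1e-12)
})

test_that("with zero perioperative mortality all deaths come from the life table", {
  p <- des_params()
  p$engine$periop_mortality <- c(young = 0, old = 0)
  cohort <- sample_cohort(500, seed = 23)
  traj <- run_scenarios(cohort, p, seed = 23)
  expect_equal(sum(traj$event_kind == "death"), 2 * nrow(cohort))
  expect_equal(sum(traj$event_kind == "perioperative_death"), 0)
})

test_that("TKR incidence is never higher with M-ACI than without", {
  for (seed in 1:6) {
    cohort <- sample_cohort(1500, seed = seed)
    traj <- run_scenarios(cohort, p_default, seed = seed)
    s <- summarize_trajectories(traj, cohort)
    expect_lte(s$tkr_incidence[s$scenario == "with_maci"],
               s$tkr_incidence[s$scenario == "without_maci"])
  }
})

test_that("removing the TKR age window weakly increases TKR incidence", {
  cohort <- sample_cohort(1500, seed = 29)
  traj <- run_scenarios(cohort, p_default, seed = 29)
  p2 <- des_params()
  p2$engine$tkr_age <- c(15, 110)
  traj2 <- run_scenarios(cohort, p2, seed = 29)
  s1 <- summarize_trajectories(traj, cohort)
  s2 <- summarize_trajectories(traj2, cohort)
  for (sc in c("with_maci", "without_maci")) {
    expect_gte(s2$tkr_incidence[s2$scenario == sc],
               s1$tkr_incidence[s1$scenario == sc])
  }
})

test_that("defect closes to zero after repair and relapses to original size", {
  cohort <- sample_cohort(200, seed = 31)
  traj <- run_scenarios(cohort, p_default, seed = 31)
  fails <- traj[traj$event_kind == "implant_failure", ]
  sizes <- cohort$defect_size_cm2[match(fails$patient_id,
                                        cohort$patient_id)]
  expect_equal(fails$defect_cm2, sizes)
})

test_that("at most one TKR revision per patient by default", {
  cohort <- sample_cohort(2000, seed = 37)
  traj <- run_scenarios(cohort, p_default, seed = 37)
  revs <- traj[traj$event_kind %in% c("intervention", "perioperative_death") &
                 !is.na(traj$treatment) & traj$treatment == "tkr_revision", ]
  expect_true(all(table(revs$patient_id, revs$scenario) <= 1))
})
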