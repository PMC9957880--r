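# Shared fixtures built in code.

# Degenerate strata: one sex, single-point age and defect strata.
point_strata <- function(age = 36, defect = 4) {
  s <- list(
    sex = c(male = 1, female = 0),
    male = list(
      age = tibble::tibble(lower = age, upper = age, prop = 1),
      defect = tibble::tibble(lower = defect, upper = defect, prop = 1),
      age_mean = NULL, defect_mean = NULL),
    female = list(
      age = tibble::tibble(lower = age, upper = age, prop = 1),
      defect = tibble::tibble(lower = defect, upper = defect, prop = 1),
      age_mean = NULL, defect_mean = NULL)
  )
  class(s) <- "cohort_strata"
  s
}

# Life table with certain death in the year starting at `death_age`.
forced_death_table <- function(death_age) {
  ages <- 0:death_age
  dplyr::bind_rows(
    tibble::tibble(sex = "male", age = ages,
                   qx = c(rep(0, death_age), 1)),
    tibble::tibble(sex = "female", age = ages,
                   qx = c(rep(0, death_age), 1)))
}

# A tiny hand-built trajectory tibble.
make_traj <- function(rows) {
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(patient_id = r$id %||% 1L,
                   scenario = r$scenario %||% "with_maci",
                   time_years = r$t, event_kind = r$kind,
                   treatment = r$trt %||% NA_character_,
                   defect_cm2 = r$defect %||% 4,
                   cost_eur = r$cost %||% 0)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent CEAC oracle: per-patient acceptance thresholds, evaluated
# by explicit case analysis (no vectorised net-benefit shortcut).
ceac_oracle <- function(paired, wtp) {
  vapply(wtp, function(l) {
    ok <- mapply(function(dq, dc) {
      if (dq > 0) l >= dc / dq
      else if (dq < 0) l <= dc / dq
      else dc <= 0
    }, paired$d_qaly, paired$d_cost)
    mean(ok)
  }, numeric(1))
}
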