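#' Cohort-level trajectory summaries
#'
#' Summarises each scenario's simulated event histories: lifetime TKR
#' incidence (fraction of patients with at least one total knee
#' replacement, including those dying perioperatively at it), mean
#' number of surgical interventions per lifetime, the fraction of
#' patients with a second intervention, mean ages at first intervention
#' and at TKR, and the fraction of TKR recipients revised.
#'
#' @param trajectories Trajectory tibble from [run_scenarios()].
#' @param cohort The cohort the trajectories came from.
#' @return A tibble with one row per scenario.
#' @export
#' @examples
#' cohort <- sample_cohort(100, seed = 1)
#' traj <- run_scenarios(cohort, des_params(), seed = 1)
#' summarize_trajectories(traj, cohort)
summarize_trajectories <- function(trajectories, cohort) {
  n <- nrow(cohort)
  surg <- dplyr::filter(trajectories,
    .data$event_kind %in% c("intervention", "perioperative_death"),
    !is.na(.data$treatment))
  surg <- dplyr::left_join(
    surg,
    dplyr::select(cohort, "patient_id", "entry_age"),
    by = "patient_id")
  per <- dplyr::summarize(
    dplyr::group_by(surg, .data$scenario, .data$patient_id),
    n_surgeries = dplyr::n(),
    had_tkr = any(.data$treatment == "tkr"),
    had_revision = any(.data$treatment == "tkr_revision"),
    age_first = min(.data$entry_age + .data$time_years),
    age_tkr = if (any(.data$treatment == "tkr"))
      min((.data$entry_age + .data$time_years)[.data$treatment == "tkr"])
      else NA_real_,
    time_second = if (dplyr::n() >= 2) sort(.data$time_years)[2]
      else NA_real_,
    n_maci = sum(.data$treatment == "maci"),
    .groups = "drop")
  dplyr::summarize(
    dplyr::group_by(per, .data$scenario),
    n_patients = n,
    tkr_incidence = sum(.data$had_tkr) / n,
    revision_per_tkr = ifelse(sum(.data$had_tkr) > 0,
      sum(.data$had_revision) / sum(.data$had_tkr), NA_real_),
    mean_surgeries = sum(.data$n_surgeries) / n,
    frac_second = sum(!is.na(.data$time_second)) / n,
    mean_time_second = mean(.data$time_second, na.rm = TRUE),
    mean_age_first = mean(.data$age_first),
    mean_age_tkr = mean(.data$age_tkr, na.rm = TRUE),
    maci_per_patient = sum(.data$n_maci) / n,
    .groups = "drop")
}

#' Cumulative incidence of a second surgery
#'
#' Kaplan-Meier estimate of the cumulative fraction of patients having
#' undergone a second surgical intervention by a given time after model
#' entry, with death as censoring (so the estimate is among patients
#' alive at each time).
#'
#' @param trajectories Trajectory tibble from [run_scenarios()].
#' @param scenario Which scenario to evaluate.
#' @param at Time in years after entry.
#' @return The estimated cumulative fraction (scalar).
#' @export
second_surgery_by <- function(trajectories, scenario = "with_maci",
                              at = 25) {
  tr <- trajectories[trajectories$scenario == scenario, ]
  surg <- tr[tr$event_kind %in% c("intervention", "perioperative_death"), ]
  spl <- split(surg$time_years, surg$patient_id)
  t2 <- vapply(spl, function(x) if (length(x) >= 2) sort(x)[2] else
    NA_real_, numeric(1))
  death <- tr[tr$event_kind %in% c("death", "perioperative_death"), ]
  dt <- vapply(split(death$time_years, death$patient_id), max, numeric(1))
  dt <- dt[names(t2)]
  event <- !is.na(t2)
  time <- ifelse(event, t2, dt)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, times = at, extend = TRUE)
  1 - s$surv
}
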