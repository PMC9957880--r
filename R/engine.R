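# The discrete-event engine.
#
# Time is continuous (years since model entry); there is no model cycle.
# Each patient is simulated independently in both healthcare scenarios
# with common random numbers: the same death age, the same sequence of
# failure-quantile draws (the k-th intervention in either scenario uses
# the k-th draw), and the same treatment-selection uniforms.

# Eligibility mask over treatment codes 1..6 at a repair-phase decision.
# KR options open up either for massive defects or after a failed repair
# (progression to osteoarthritis); the TKR age window always applies.
.eligible_mask <- function(defect, age, n_prior, with_maci, primary, eng) {
  kr_ok <- defect > eng$kr_min || n_prior >= 1
  c(with_maci && (primary || defect > eng$maci_min),  # maci
    defect <= eng$mf_max,                             # mf
    defect <= eng$mbms_route_max,                     # mbms
    kr_ok,                                            # pkr
    kr_ok && age >= eng$tkr_age[1] && age <= eng$tkr_age[2],  # tkr
    FALSE)                                            # revision: forced path
}

#' Select a treatment for a symptomatic patient state
#'
#' Applies the eligibility rules (microfracture only up to the MF defect
#' bound, mBMS for small-to-mid defects, M-ACI above 2 cm2 in the
#' with-M-ACI scenario, knee replacement for massive defects or after a
#' failed repair, TKR only within its age window) and then draws among
#' the eligible options with the policy weights for the patient's
#' decision stage. Returns `"conservative"` when nothing is eligible or
#' the conservative mass is drawn.
#'
#' @param defect_size Current symptomatic defect size in cm2.
#' @param age Current age in years.
#' @param n_prior Number of prior surgical interventions.
#' @param scenario `"with_maci"` or `"without_maci"`.
#' @param params A `des_params` list.
#' @param u Uniform in (0, 1) driving the categorical draw; supply for
#'   reproducibility, otherwise one session draw is used.
#' @return A treatment name (`"maci"`, `"mf"`, `"mbms"`, `"pkr"`,
#'   `"tkr"`), `"conservative"` (wait, re-decide later), or `"none"`
#'   (permanently decline further surgery).
#' @export
#' @examples
#' p <- des_params()
#' select_treatment(1.5, 30, 0, "without_maci", p, u = 0.1)
#' select_treatment(4, 36, 0, "with_maci", p, u = 0.5)
select_treatment <- function(defect_size, age, n_prior, scenario, params,
                             u = stats::runif(1)) {
  stopifnot(scenario %in% c("with_maci", "without_maci"))
  pol <- .policy_prep(params$policy)
  code <- .select_trt_code(
    defect_size, age, n_prior,
    with_maci = scenario == "with_maci",
    pol_sc = pol[[scenario]], eng = params$engine, u = u)
  if (code == 0) "conservative" else if (code == 7) "none"
  else .trt_names[code]
}

# Policy tibble -> list per scenario of 3 x 8 weight matrices
# (rows: primary/re2/re3plus; cols: treatments 1..6, conservative = 7,
# none = 8, the permanent decline of further surgery).
.policy_prep <- function(policy) {
  out <- list()
  decisions <- c("primary", "re2", "re3plus")
  cols <- c(.trt_names, "conservative", "none")
  for (sc in c("with_maci", "without_maci")) {
    M <- matrix(0, nrow = 3, ncol = 8,
                dimnames = list(decisions, cols))
    sub <- policy[policy$scenario == sc, ]
    for (i in seq_len(nrow(sub))) {
      M[sub$decision[i], sub$treatment[i]] <- sub$weight[i]
    }
    out[[sc]] <- M
  }
  out
}

# Scalar kernel: returns a treatment code 1..5, 0 (conservative wait),
# or 7 (permanent decline of further surgery).
.select_trt_code <- function(defect, age, n_prior, with_maci, pol_sc, eng, u) {
  dec <- min(n_prior + 1, 3)
  w <- pol_sc[dec, ]
  elig <- .eligible_mask(defect, age, n_prior, with_maci, n_prior == 0, eng)
  w[1:6][!elig] <- 0
  tot <- sum(w)
  if (tot <= 0) return(0L)
  x <- u * tot
  cum <- 0
  for (j in 1:8) {
    cum <- cum + w[j]
    if (x <= cum && w[j] > 0) {
      return(if (j == 7) 0L else if (j == 8) 7L else j)
    }
  }
  0L
}

# Perioperative death probability at a knee replacement, linear in age
# across the TKR age window.
.periop_prob <- function(age, eng) {
  lo <- eng$tkr_age[1]
  hi <- eng$tkr_age[2]
  a <- pmin(pmax(age, lo), hi)
  p <- eng$periop_mortality
  unname(p[1] + (a - lo) / (hi - lo) * (p[2] - p[1]))
}

# Simulate one patient in one scenario. `draws` is the patient's shared
# uniform block; counters restart at 0 for each scenario so both
# scenarios consume identical streams (common random numbers).
#
# Returns a matrix with columns time, kind, trt, defect, cost.
.sim_one <- function(entry, d0, death_t, with_maci, pol_sc, fm, costs, eng,
                     draws) {
  fail_u <- draws$fail
  dec_u <- draws$dec
  per_u <- draws$per
  i_f <- 0L; i_d <- 0L; i_p <- 0L
  refill_f <- 0L; refill_d <- 0L
  ev <- matrix(0, nrow = 16, ncol = 5)
  ne <- 0L
  add <- function(time, kind, trt, defect, cost) {
    ne <<- ne + 1L
    if (ne > nrow(ev)) ev <<- rbind(ev, matrix(0, nrow = nrow(ev), ncol = 5))
    ev[ne, ] <<- c(time, kind, trt, defect, cost)
  }
  t <- 0
  defect <- d0
  n_prior <- 0L
  phase <- 0L   # 0 repair, 1 after PKR fail, 2 after TKR fail, 3 done
  rev_n <- 0L
  repeat {
    if (t >= death_t) { add(death_t, 3, 0, defect, 0); break }
    age <- entry + t
    trt <- -1L
    if (phase == 0L) {
      i_d <- i_d + 1L
      if (i_d > length(dec_u)) {
        refill_d <- refill_d + 1L
        dec_u <- c(dec_u, .extra_draws(draws$root, draws$id, 20 + refill_d))
      }
      trt <- .select_trt_code(defect, age, n_prior, with_maci, pol_sc, eng,
                              dec_u[i_d])
    } else if (phase == 1L) {
      # failed PKR: the next replacement is a TKR within its age window
      if (age > eng$tkr_age[2]) {
        trt <- -1L
      } else if (age >= eng$tkr_age[1]) {
        trt <- 5L
      } else {
        t <- min(eng$tkr_age[1] - entry, death_t)  # wait until eligible
        next
      }
    } else if (phase == 2L) {
      trt <- if (rev_n < eng$max_revisions && age <= eng$tkr_age[2]) 6L else -1L
    }
    if (trt == -1L) { add(death_t, 3, 0, defect, 0); break }  # no further option
    if (trt == 0L) { t <- t + eng$wait_interval; next }       # conservative
    if (trt == 7L) {  # declines further surgery: absorbing state
      add(t, 5, 0, defect, 0)
      add(death_t, 3, 0, defect, 0)
      break
    }
    cost <- costs[trt]
    if (trt >= 5L) {  # TKR or revision: perioperative risk
      i_p <- i_p + 1L
      if (i_p > length(per_u)) {
        per_u <- c(per_u, .extra_draws(draws$root, draws$id, 40))
      }
      if (per_u[i_p] < .periop_prob(age, eng)) {
        add(t, 4, trt, defect, cost)
        break
      }
    }
    add(t, 1, trt, defect, cost)
    n_prior <- n_prior + 1L
    if (trt == 4L) phase <- 1L
    if (trt == 5L) phase <- 2L
    if (trt == 6L) { rev_n <- rev_n + 1L; phase <- 3L }
    # failure draw for this intervention
    i_f <- i_f + 2L
    if (i_f > length(fail_u)) {
      refill_f <- refill_f + 1L
      fail_u <- c(fail_u, .extra_draws(draws$root, draws$id, 30 + refill_f))
    }
    m <- fm[[trt]]
    tf <- t + .failure_time_from_u(
      m$mixture_weight, m$short$shape, m$short$scale,
      m$long$shape, m$long$scale, fail_u[i_f - 1L], fail_u[i_f])
    if (tf >= death_t) { add(death_t, 3, 0, 0, 0); break }
    if (phase == 3L) {
      # failed revision: no further replacement, symptomatic until death
      add(tf, 2, trt, d0, 0)
      add(death_t, 3, 0, d0, 0)
      break
    }
    add(tf, 2, trt, d0, 0)
    defect <- d0
    t <- tf + eng$reintervention_delay
  }
  ev[seq_len(ne), , drop = FALSE]
}

#' Run the paired-scenario simulation for a cohort
#'
#' Simulates every patient's lifetime event history twice -- once in the
#' scenario where M-ACI is available as primary repair, once in the
#' counterfactual without it -- under common random numbers, so that
#' per-patient differences between the scenarios reflect the treatment
#' policy rather than Monte-Carlo noise.
#'
#' @param cohort Cohort tibble from [sample_cohort()].
#' @param params A `des_params` list.
#' @param seed Integer root seed (also governs death ages and failure
#'   draws through per-patient substreams).
#' @return A tibble of trajectories with columns `patient_id`,
#'   `scenario`, `time_years`, `event_kind` (`intervention`,
#'   `implant_failure`, `death`, `perioperative_death`, or
#'   `treatment_declined` when a patient permanently declines further
#'   surgery), `treatment`, `defect_cm2`, `cost_eur`.
#' @export
#' @examples
#' cohort <- sample_cohort(50, seed = 1)
#' traj <- run_scenarios(cohort, des_params(), seed = 1)
#' head(traj)
run_scenarios <- function(cohort, params, seed = 1) {
  stopifnot(nrow(cohort) >= 1)
  fm <- .failure_models(params)
  pol <- .policy_prep(params$policy)
  eng <- params$engine
  costs <- vapply(.trt_names, function(x) params$treatments[[x]]$cost,
                  numeric(1))
  prep <- .life_table_prep(params$life_table)
  n <- nrow(cohort)
  .with_preserved_rng({
    # pre-size output buffers
    cap <- 32L * n
    o_id <- integer(cap); o_sc <- integer(cap); o_t <- numeric(cap)
    o_k <- integer(cap); o_tr <- integer(cap); o_d <- numeric(cap)
    o_c <- numeric(cap)
    m <- 0L
    for (i in seq_len(n)) {
      id <- cohort$patient_id[i]
      draws <- .patient_draws(seed, id)
      death_age <- .death_age_from_u(cohort$entry_age[i], cohort$sex[i],
                                     prep, draws$death[1], draws$death[2])
      death_t <- death_age - cohort$entry_age[i]
      for (sc in 1:2) {
        ev <- .sim_one(cohort$entry_age[i], cohort$defect_size_cm2[i],
                       death_t, with_maci = sc == 1L,
                       pol_sc = pol[[if (sc == 1L) "with_maci" else
                                     "without_maci"]],
                       fm = fm, costs = costs, eng = eng, draws = draws)
        k <- nrow(ev)
        if (m + k > cap) {
          grow <- max(cap, m + k)
          o_id <- c(o_id, integer(grow)); o_sc <- c(o_sc, integer(grow))
          o_t <- c(o_t, numeric(grow)); o_k <- c(o_k, integer(grow))
          o_tr <- c(o_tr, integer(grow)); o_d <- c(o_d, numeric(grow))
          o_c <- c(o_c, numeric(grow))
          cap <- length(o_id)
        }
        idx <- (m + 1L):(m + k)
        o_id[idx] <- id; o_sc[idx] <- sc
        o_t[idx] <- ev[, 1]; o_k[idx] <- ev[, 2]; o_tr[idx] <- ev[, 3]
        o_d[idx] <- ev[, 4]; o_c[idx] <- ev[, 5]
        m <- m + k
      }
    }
    idx <- seq_len(m)
    tibble::tibble(
      patient_id = o_id[idx],
      scenario = c("with_maci", "without_maci")[o_sc[idx]],
      time_years = o_t[idx],
      event_kind = .kind_names[o_k[idx]],
      treatment = ifelse(o_tr[idx] == 0, NA_character_,
                         .trt_names[pmax(o_tr[idx], 1)]),
      defect_cm2 = o_d[idx],
      cost_eur = o_c[idx]
    )
  })
}

#' Simulate a single patient
#'
#' Convenience wrapper around the engine for one profile in one
#' scenario; mainly useful for inspection and tests.
#'
#' @param profile One-row cohort tibble (or list) with `patient_id`,
#'   `sex`, `entry_age`, `defect_size_cm2`.
#' @param scenario `"with_maci"` or `"without_maci"`.
#' @param params A `des_params` list.
#' @param seed Integer root seed.
#' @return A trajectory tibble (one scenario only).
#' @export
simulate_patient <- function(profile, scenario, params, seed = 1) {
  traj <- run_scenarios(tibble::as_tibble(profile), params, seed)
  traj[traj$scenario == scenario, ]
}

#' Write trajectories to CSV
#'
#' @param trajectories Trajectory tibble from [run_scenarios()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  readr::write_csv(trajectories, path)
  invisible(path)
}
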