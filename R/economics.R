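#' Discount an amount to present value
#'
#' Point amounts occurring at time `t` are discounted by
#' \eqn{(1 + r)^{-t}}. Continuous accruals (utility streams, annual
#' conservative-therapy costs) are handled by [accrue()] as annual slices
#' discounted at their slice start.
#'
#' @param amount Amount in EUR or QALYs (vectorised).
#' @param t Time in years since model entry (>= 0).
#' @param rate Annual discount rate (>= 0); the base case uses 2%.
#' @return The discounted amount.
#' @export
#' @examples
#' discount(1000, 10, 0.02)  # 820.35
discount <- function(amount, t, rate) {
  if (any(t < 0)) stop("cannot discount at negative times", call. = FALSE)
  if (any(rate < 0)) stop("discount rate must be non-negative", call. = FALSE)
  amount * (1 + rate)^(-t)
}

# Present value of a unit-rate stream over [s, e), split into annual
# slices anchored at s, each slice discounted at its start.
.pv_stream <- function(rate, s, e) {
  len <- e - s
  if (len <= 0) return(0)
  if (rate == 0) return(len)
  v <- 1 / (1 + rate)
  n <- floor(len)
  frac <- len - n
  (1 + rate)^(-s) * ((1 - v^n) / (1 - v) + frac * v^n)
}

# Utility bands (offsets from state start, weights) for a post-repair
# state: the state occupies [b_i, b_{i+1}) at weight w_i, final band
# open-ended. Precomputed once per accrual pass.
.band_table <- function(mbms_as_aci, u) {
  aci <- list(breaks = c(0, 1), w = c(u$aci_y1, u$aci_y2p))
  mf <- list(breaks = c(0, 1, 4), w = c(u$mf_y1, u$mf_y2_4, u$mf_y5p))
  kr <- list(breaks = 0, w = u$post_kr)
  list(aci, mf, if (mbms_as_aci) aci else mf, kr, kr, kr)
}

#' Accrue QALYs and costs along trajectories
#'
#' Between consecutive events each patient occupies exactly one health
#' state; QALYs are the state's annual utility weight times the duration,
#' and costs are the procedure costs at event times plus the annual
#' conservative-therapy cost while symptomatic. Both are also returned
#' discounted (annual slices from each state's start for streams; event
#' times for point costs).
#'
#' State assignment is reconstructed from the event history: symptomatic
#' before the primary repair (0.65, or 0.62 for massive defects awaiting
#' replacement); post-repair schedules with a first-year weight and, for
#' microfracture, decay of the benefit from year 5; 0.78 after a knee
#' replacement; 0.56 when symptomatic again after a replacement; 0.69
#' once no further surgical option is taken up (after a failed revision,
#' or a failed replacement beyond the TKR age window).
#'
#' @param trajectories Trajectory tibble from [run_scenarios()].
#' @param cohort The cohort tibble the trajectories came from (supplies
#'   entry ages).
#' @param params A `des_params` list.
#' @param rate Annual discount rate; defaults to the configured base-case
#'   rate.
#' @return A tibble with one row per patient and scenario: `patient_id`,
#'   `scenario`, `qaly`, `qaly_disc`, `cost`, `cost_disc`.
#' @export
#' @examples
#' cohort <- sample_cohort(20, seed = 1)
#' traj <- run_scenarios(cohort, des_params(), seed = 1)
#' accrue(traj, cohort, des_params())
accrue <- function(trajectories, cohort, params,
                   rate = params$economics$discount_rate) {
  eco <- params$economics
  uw <- lapply(eco$utilities,
               function(x) min(x * eco$utility_multiplier, 1))
  mbms_as_aci <- identical(eco$mbms_utility, "aci")
  band_of <- .band_table(mbms_as_aci, uw)
  cons <- eco$conservative_cost
  eng <- params$engine
  entry_of <- stats::setNames(cohort$entry_age, cohort$patient_id)

  tr <- trajectories[order(trajectories$patient_id,
                           trajectories$scenario,
                           trajectories$time_years), ]
  pid <- tr$patient_id
  sc <- tr$scenario
  tt <- tr$time_years
  kind <- tr$event_kind
  trt <- tr$treatment
  dft <- tr$defect_cm2
  cst <- tr$cost_eur
  n <- nrow(tr)
  trt_code_of <- stats::setNames(seq_along(.trt_names), .trt_names)

  res_id <- integer(n); res_sc <- character(n)
  res_q <- numeric(n); res_qd <- numeric(n)
  res_c <- numeric(n); res_cd <- numeric(n)
  g <- 0L

  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && pid[j + 1L] == pid[i] && sc[j + 1L] == sc[i]) j <- j + 1L
    entry <- entry_of[[as.character(pid[i])]]
    q <- qd <- cc <- cd <- 0
    # state at the start: symptomatic before primary
    prev_t <- 0
    state <- "symptomatic"
    sym_w <- if (dft[i] > eng$kr_min) uw$before_kr1 else uw$before_primary
    bands <- NULL
    n_kr <- 0L
    for (k in i:j) {
      tk <- tt[k]
      dur <- tk - prev_t
      if (dur > 0) {
        if (state == "symptomatic" || state == "no_further") {
          w <- if (state == "symptomatic") sym_w
               else if (n_kr >= 1L) uw$no_further_kr
               else uw$no_further_repair
          q <- q + w * dur
          qd <- qd + w * .pv_stream(rate, prev_t, tk)
          if (state == "symptomatic") {  # conservative therapy while waiting
            cc <- cc + cons * dur
            cd <- cd + cons * .pv_stream(rate, prev_t, tk)
          }
        } else {  # post-repair/post-KR bands relative to state start
          b <- bands
          nb <- length(b$breaks)
          for (bi in seq_len(nb)) {
            a0 <- state_start + b$breaks[bi]
            a1 <- if (bi < nb) state_start + b$breaks[bi + 1L] else Inf
            lo <- max(a0, prev_t)
            hi <- min(a1, tk)
            if (hi > lo) {
              q <- q + b$w[bi] * (hi - lo)
              qd <- qd + b$w[bi] * .pv_stream(rate, lo, hi)
            }
          }
        }
      }
      # event effects
      kk <- kind[k]
      if (kk == "intervention" || kk == "perioperative_death") {
        cc <- cc + cst[k]
        cd <- cd + discount(cst[k], tk, rate)
        if (kk == "intervention") {
          code <- trt_code_of[[trt[k]]]
          if (code >= 4L) n_kr <- n_kr + 1L
          bands <- band_of[[code]]
          state <- "treated"
          state_start <- tk
        }
      } else if (kk == "treatment_declined") {
        state <- "no_further"
      } else if (kk == "implant_failure") {
        failed <- trt_code_of[[trt[k]]]
        age_now <- entry + tk
        if (failed == 6L || (n_kr >= 1L && age_now > eng$tkr_age[2])) {
          state <- "no_further"
        } else {
          state <- "symptomatic"
          sym_w <- if (n_kr >= 1L) uw$before_kr2
                   else if (dft[k] > eng$kr_min) uw$before_kr1
                   else uw$before_rerepair
        }
      }
      prev_t <- tk
    }
    g <- g + 1L
    res_id[g] <- pid[i]; res_sc[g] <- sc[i]
    res_q[g] <- q; res_qd[g] <- qd
    res_c[g] <- cc; res_cd[g] <- cd
    i <- j + 1L
  }
  idx <- seq_len(g)
  tibble::tibble(
    patient_id = res_id[idx], scenario = res_sc[idx],
    qaly = res_q[idx], qaly_disc = res_qd[idx],
    cost = res_c[idx], cost_disc = res_cd[idx]
  )
}

#' Pair per-patient outcomes across scenarios
#'
#' Reshapes the per-patient results of [accrue()] into one row per
#' patient with both scenarios' discounted and undiscounted outcomes and
#' their differences (with-M-ACI minus without).
#'
#' @param results Output of [accrue()].
#' @return A tibble with columns `patient_id`, `cost_with`,
#'   `cost_without`, `cost_disc_with`, `cost_disc_without`, `qaly_with`,
#'   `qaly_without`, `qaly_disc_with`, `qaly_disc_without`, `d_cost`,
#'   `d_qaly` (both discounted).
#' @export
pair_results <- function(results) {
  wide <- tidyr::pivot_wider(
    results, id_cols = "patient_id", names_from = "scenario",
    values_from = c("qaly", "qaly_disc", "cost", "cost_disc"))
  dplyr::transmute(wide,
    patient_id = .data$patient_id,
    cost_with = .data$cost_with_maci,
    cost_without = .data$cost_without_maci,
    cost_disc_with = .data$cost_disc_with_maci,
    cost_disc_without = .data$cost_disc_without_maci,
    qaly_with = .data$qaly_with_maci,
    qaly_without = .data$qaly_without_maci,
    qaly_disc_with = .data$qaly_disc_with_maci,
    qaly_disc_without = .data$qaly_disc_without_maci,
    d_cost = .data$cost_disc_with - .data$cost_disc_without,
    d_qaly = .data$qaly_disc_with - .data$qaly_disc_without
  )
}

#' Incremental cost-effectiveness ratio
#'
#' Computes the ICER as the difference of mean discounted costs divided
#' by the difference of mean discounted QALYs between the two scenarios,
#' and flags the dominance quadrant. A zero QALY difference yields an
#' undefined (NA) ICER rather than an infinity.
#'
#' Accepts either paired per-patient results ([pair_results()]) or
#' pre-computed component means.
#'
#' @param paired Paired per-patient tibble, or `NULL` when means are
#'   given directly.
#' @param cost_with,cost_without,qaly_with,qaly_without Scenario means of
#'   discounted costs and QALYs (used when `paired` is `NULL`).
#' @return A list of class `maci_icer`: `cost_with`, `cost_without`,
#'   `qaly_with`, `qaly_without`, `inc_cost`, `inc_qaly`, `icer`,
#'   `dominance` (`"dominant"`, `"dominated"`, `"tradeoff"`, or
#'   `"undefined"`).
#' @export
#' @examples
#' compute_icer(cost_with = 18590, cost_without = 14134,
#'              qaly_with = 22.53, qaly_without = 21.21)
compute_icer <- function(paired = NULL, cost_with = NULL,
                         cost_without = NULL, qaly_with = NULL,
                         qaly_without = NULL) {
  if (!is.null(paired)) {
    cost_with <- mean(paired$cost_disc_with)
    cost_without <- mean(paired$cost_disc_without)
    qaly_with <- mean(paired$qaly_disc_with)
    qaly_without <- mean(paired$qaly_disc_without)
  }
  inc_cost <- cost_with - cost_without
  inc_qaly <- qaly_with - qaly_without
  icer <- if (inc_qaly == 0) NA_real_ else inc_cost / inc_qaly
  dominance <- if (inc_qaly == 0 && inc_cost == 0) "undefined"
    else if (inc_cost <= 0 && inc_qaly >= 0) "dominant"
    else if (inc_cost >= 0 && inc_qaly <= 0) "dominated"
    else "tradeoff"
  structure(
    list(cost_with = cost_with, cost_without = cost_without,
         qaly_with = qaly_with, qaly_without = qaly_without,
         inc_cost = inc_cost, inc_qaly = inc_qaly,
         icer = icer, dominance = dominance),
    class = "maci_icer")
}

#' @export
print.maci_icer <- function(x, ...) {
  cat("Incremental cost-effectiveness (with vs. without M-ACI)\n")
  cat(sprintf("  discounted cost:  %.0f vs %.0f EUR (delta %+.0f)\n",
              x$cost_with, x$cost_without, x$inc_cost))
  cat(sprintf("  discounted QALYs: %.2f vs %.2f (delta %+.3f)\n",
              x$qaly_with, x$qaly_without, x$inc_qaly))
  if (is.na(x$icer)) {
    cat("  ICER: undefined (zero QALY difference)\n")
  } else {
    cat(sprintf("  ICER: %.0f EUR/QALY (%s)\n", x$icer, x$dominance))
  }
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that M-ACI is
#' cost-effective is the fraction of simulated patients whose incremental
#' net monetary benefit \eqn{\lambda \Delta QALY - \Delta cost} is
#' non-negative (per-patient pairing under common random numbers). The
#' fraction of patients for whom M-ACI is dominant (lower cost and higher
#' QALYs) is attached as attribute `dominant` and available via
#' [dominant_fraction()].
#'
#' @param paired Paired per-patient tibble from [pair_results()].
#' @param wtp_grid Willingness-to-pay thresholds in EUR/QALY.
#' @return A tibble of class `maci_ceac` with columns
#'   `wtp_eur_per_qaly`, `probability_cost_effective`.
#' @export
compute_ceac <- function(paired, wtp_grid = seq(0, 50000, by = 1000)) {
  if (length(wtp_grid) == 0) {
    stop("wtp_grid must contain at least one threshold", call. = FALSE)
  }
  prob <- vapply(wtp_grid, function(l) {
    mean(l * paired$d_qaly - paired$d_cost >= 0)
  }, numeric(1))
  out <- tibble::tibble(wtp_eur_per_qaly = wtp_grid,
                        probability_cost_effective = prob)
  attr(out, "dominant") <- dominant_fraction(paired)
  class(out) <- c("maci_ceac", class(out))
  out
}

#' @rdname compute_ceac
#' @export
dominant_fraction <- function(paired) {
  mean(paired$d_cost < 0 & paired$d_qaly > 0)
}
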