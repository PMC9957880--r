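#' Default parameter list for the tornado analysis
#'
#' All per-procedure costs, all 2-year failure rates, the annual
#' conservative-therapy cost, and a single multiplier on all utility
#' weights.
#'
#' @return Character vector of configuration paths (see [param_get()]).
#' @export
tornado_parameters_default <- function() {
  c(
    "treatments.maci.cost", "treatments.mf.cost", "treatments.mbms.cost",
    "treatments.pkr.cost", "treatments.tkr.cost",
    "treatments.tkr_revision.cost",
    "treatments.maci.failure.two_year", "treatments.mf.failure.two_year",
    "treatments.mbms.failure.two_year", "treatments.pkr.failure.two_year",
    "treatments.tkr.failure.two_year",
    "economics.conservative_cost",
    "economics.utility_multiplier"
  )
}

# One full paired run -> ICER, reusing a fixed cohort (common random
# numbers across arms: the same seed drives every arm).
.run_icer <- function(params, cohort, seed,
                      rate = params$economics$discount_rate) {
  traj <- run_scenarios(cohort, params, seed)
  res <- accrue(traj, cohort, params, rate = rate)
  compute_icer(pair_results(res))
}

#' One-way tornado sensitivity analysis
#'
#' Re-runs the paired simulation with each parameter at 0.8x and 1.2x
#' its baseline value (same cohort and random streams as the baseline,
#' so differences isolate the parameter effect) and records the ICER at
#' each extreme. Entries are sorted by the width of the ICER swing.
#' The input parameter object is never mutated.
#'
#' @param params Baseline `des_params`.
#' @param parameters Configuration paths to vary; scalar positive
#'   parameters only.
#' @param n Cohort size.
#' @param seed Integer root seed.
#' @param rel Relative perturbation (default 0.2 for +/- 20%).
#' @return A tibble of class `maci_tornado` with columns `parameter`,
#'   `low_value`, `high_value`, `icer_low`, `icer_high`,
#'   `icer_baseline`.
#' @export
tornado <- function(params, parameters = tornado_parameters_default(),
                    n = 1000, seed = 1, rel = 0.2) {
  cohort <- sample_cohort(n, params$strata, seed)
  base <- .run_icer(params, cohort, seed)
  rows <- purrr::map(parameters, function(p) {
    v0 <- param_get(params, p)
    if (!is.numeric(v0) || length(v0) != 1 || v0 < 0) {
      stop(sprintf("tornado parameter '%s' is not a positive scalar", p),
           call. = FALSE)
    }
    lo <- v0 * (1 - rel)
    hi <- v0 * (1 + rel)
    icer_lo <- .run_icer(param_set(params, p, lo), cohort, seed)$icer
    icer_hi <- .run_icer(param_set(params, p, hi), cohort, seed)$icer
    tibble::tibble(parameter = p, low_value = lo, high_value = hi,
                   icer_low = icer_lo, icer_high = icer_hi)
  })
  out <- dplyr::bind_rows(rows)
  out$icer_baseline <- base$icer
  out <- out[order(-abs(out$icer_high - out$icer_low)), ]
  class(out) <- c("maci_tornado", class(out))
  out
}

#' Scenario analysis under parameter overrides
#'
#' Runs the full paired simulation with a named set of parameter
#' overrides (e.g. a 4.5% discount rate for costs and effects, or
#' microfracture eligibility extended to 5 cm2) and reports the
#' resulting economics.
#'
#' @param overrides Named list mapping configuration paths to values,
#'   e.g. `list("economics.discount_rate" = 0.045)`.
#' @param params Baseline `des_params`.
#' @param n Cohort size.
#' @param seed Integer root seed.
#' @param name Label for the scenario.
#' @return A list of class `maci_scenario`: `name`, `overrides`, `icer`
#'   (a `maci_icer`), and `paired` per-patient outcomes.
#' @export
#' @examples
#' \donttest{
#' run_scenario_analysis(list("economics.discount_rate" = 0.045),
#'                       des_params(), n = 500, seed = 1)$icer
#' }
run_scenario_analysis <- function(overrides, params = des_params(),
                                  n = 10000, seed = 1,
                                  name = "scenario") {
  for (p in names(overrides)) {
    params <- param_set(params, p, overrides[[p]])
  }
  validate_params(params)
  cohort <- sample_cohort(n, params$strata, seed)
  traj <- run_scenarios(cohort, params, seed)
  res <- accrue(traj, cohort, params)
  paired <- pair_results(res)
  structure(
    list(name = name, overrides = overrides,
         icer = compute_icer(paired), paired = paired),
    class = "maci_scenario")
}

#' @export
print.maci_scenario <- function(x, ...) {
  cat(sprintf("Scenario analysis '%s'\n", x$name))
  for (p in names(x$overrides)) {
    cat(sprintf("  override %s = %s\n", p, format(x$overrides[[p]])))
  }
  print(x$icer)
  invisible(x)
}
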