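# Treatment codes used by the numeric engine kernel. Conservative
# management is code 0 and is not a surgical treatment.
.trt_names <- c("maci", "mf", "mbms", "pkr", "tkr", "tkr_revision")
.kind_names <- c("intervention", "implant_failure", "death",
                 "perioperative_death", "treatment_declined")

#' Default health-state utility schedule
#'
#' Annual QALY weights per health state, as used in the NICE appraisal of
#' an M-ACI technology: 0.65 while symptomatic before a repair, 0.76 in
#' the first year after a cell-based repair rising to 0.82 thereafter,
#' microfracture benefit decaying back to 0.65 from year 5, 0.62/0.56
#' while symptomatic before a first/second knee replacement, 0.78 after a
#' successful knee replacement, and 0.69 once no further surgical option
#' is taken up.
#'
#' @return A named list of utility weights (per year, in `[0, 1]`).
#' @export
utility_schedule_default <- function() {
  list(
    before_primary    = 0.65,
    aci_y1            = 0.76,
    aci_y2p           = 0.82,
    mf_y1             = 0.76,
    mf_y2_4           = 0.82,
    mf_y5p            = 0.65,
    before_rerepair   = 0.65,
    no_further_repair = 0.69,
    before_kr1        = 0.62,
    post_kr           = 0.78,
    before_kr2        = 0.56,
    no_further_kr     = 0.69
  )
}

#' Default treatment-assignment policy
#'
#' Probability weights over treatment options at each decision point,
#' keyed by scenario and by how many interventions the patient has
#' already had (`primary`, `re2` for the second, `re3plus` beyond).
#' Weights apply only to options eligible for the patient's defect size
#' and age; ineligible mass is renormalised over the remaining options.
#' `conservative` is the non-surgical wait state.
#'
#' In the with-M-ACI scenario every patient receives M-ACI as primary
#' repair; re-intervention weights are calibrated so that about a third
#' of second interventions renew the M-ACI and only a few percent move
#' directly to total knee replacement. In the counterfactual scenario
#' the weights are calibrated to the published intervention mix
#' (mBMS-heavy, with a modest per-decision TKR share once the age
#' window opens, and a growing share of patients declining further
#' surgery at later decisions). These tables are calibration choices of
#' this package, not published inputs.
#'
#' @return A tibble with columns `scenario`, `decision`, `treatment`,
#'   `weight`.
#' @export
policy_default <- function() {
  tibble::tribble(
    ~scenario,      ~decision,  ~treatment,     ~weight,
    "with_maci",    "primary",  "maci",         1.000,
    "with_maci",    "re2",      "maci",         0.330,
    "with_maci",    "re2",      "mf",           0.050,
    "with_maci",    "re2",      "mbms",         0.650,
    "with_maci",    "re2",      "pkr",          0.030,
    "with_maci",    "re2",      "tkr",          0.038,
    "with_maci",    "re2",      "conservative", 0.120,
    "with_maci",    "re3plus",  "maci",         0.075,
    "with_maci",    "re3plus",  "mf",           0.050,
    "with_maci",    "re3plus",  "mbms",         0.650,
    "with_maci",    "re3plus",  "pkr",          0.020,
    "with_maci",    "re3plus",  "tkr",          0.023,
    "with_maci",    "re3plus",  "conservative", 0.120,
    "with_maci",    "re3plus",  "none",         0.180,
    "without_maci", "primary",  "mf",           0.400,
    "without_maci", "primary",  "mbms",         0.340,
    "without_maci", "primary",  "pkr",          0.150,
    "without_maci", "primary",  "tkr",          0.050,
    "without_maci", "primary",  "conservative", 0.110,
    "without_maci", "re2",      "mf",           0.300,
    "without_maci", "re2",      "mbms",         0.400,
    "without_maci", "re2",      "pkr",          0.145,
    "without_maci", "re2",      "tkr",          0.023,
    "without_maci", "re2",      "conservative", 0.060,
    "without_maci", "re2",      "none",         0.060,
    "without_maci", "re3plus",  "mf",           0.300,
    "without_maci", "re3plus",  "mbms",         0.400,
    "without_maci", "re3plus",  "pkr",          0.145,
    "without_maci", "re3plus",  "tkr",          0.023,
    "without_maci", "re3plus",  "conservative", 0.060,
    "without_maci", "re3plus",  "none",         0.075
  )
}

#' Assemble the full simulation parameter set
#'
#' Collects every model input into one validated list: cohort strata,
#' life table, per-intervention costs and failure-model calibrations,
#' the treatment-assignment policy, the utility schedule and economic
#' settings, and the event-engine settings. All defaults form the base
#' case; any element can be overridden.
#'
#' Per-intervention failure calibrations pair the published 2-year
#' failure rates (M-ACI 7%, microfracture 39%, mBMS 4%, PKR 4%, TKR 4%)
#' with long-term survivorship anchors. The anchors and mixture weights
#' are calibration choices of this package (the 25-year TKR service life
#' is the published exception); see the methods vignette for how they
#' were chosen.
#'
#' @param ... Named elements replacing parts of the default list
#'   (top-level replacement; use [param_set()] for path-level edits).
#' @return A list of class `des_params`.
#' @export
#' @examples
#' p <- des_params()
#' names(p)
#' param_get(p, "treatments.maci.cost")
des_params <- function(...) {
  params <- list(
    strata = cohort_strata_default(),
    life_table = life_table_default(),
    treatments = list(
      maci = list(
        cost = 11000,
        failure = list(two_year = 0.07,
                       anchors = data.frame(t = 25, s = 0.66),
                       mixture_weight = 0.29,
                       short_shape = 1, long_shape = 4.0)
      ),
      mf = list(
        cost = 1500,
        failure = list(two_year = 0.39,
                       anchors = data.frame(t = c(5, 15), s = c(0.60, 0.25)),
                       mixture_weight = 0.35,
                       short_shape = 1, long_shape = 2.5)
      ),
      mbms = list(
        cost = 3500,
        failure = list(two_year = 0.04,
                       anchors = data.frame(t = 6, s = 0.50),
                       mixture_weight = 0.05,
                       short_shape = 1, long_shape = 2.6)
      ),
      pkr = list(
        cost = 6000,
        failure = list(two_year = 0.04,
                       anchors = data.frame(t = c(10, 25), s = c(0.85, 0.55)),
                       mixture_weight = 0.05,
                       short_shape = 1, long_shape = 2.5)
      ),
      tkr = list(
        cost = 9000,
        failure = list(two_year = 0.04,
                       anchors = data.frame(t = 25, s = 0.50),
                       mixture_weight = 0.05,
                       short_shape = 1, long_shape = 3.5)
      ),
      tkr_revision = list(
        cost = 15000,
        failure = NULL  # NULL: reuse the TKR failure model
      )
    ),
    policy = policy_default(),
    economics = list(
      utilities = utility_schedule_default(),
      conservative_cost = 800,
      discount_rate = 0.02,
      mbms_utility = "mf",
      utility_multiplier = 1
    ),
    engine = list(
      reintervention_delay = 0.35,
      wait_interval = 1,
      max_revisions = 1,
      relapse_size = "original",
      mf_max = 2,
      mbms_max = 5,
      mbms_route_max = 10,
      maci_min = 2,
      kr_min = 10,
      tkr_age = c(55, 80),
      periop_mortality = c(young = 0.000449, old = 0.0011)
    )
  )
  dots <- list(...)
  for (nm in names(dots)) params[[nm]] <- dots[[nm]]
  class(params) <- "des_params"
  validate_params(params)
}

#' Validate a parameter set
#'
#' Checks the whole configuration before any simulation starts; all
#' violations are aggregated into a single error naming each offending
#' configuration path.
#'
#' @param params A `des_params` list.
#' @return `params`, invisibly annotated with calibrated failure models,
#'   if valid.
#' @export
validate_params <- function(params) {
  errors <- character()
  check_num <- function(x, path, lo = -Inf, hi = Inf) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1 || is.na(x)) {
      errors <<- c(errors, sprintf("%s: must be a single number", path))
    } else if (x < lo || x > hi) {
      errors <<- c(errors, sprintf("%s: value %.6g outside [%g, %g]",
                                   path, x, lo, hi))
    }
  }
  tryCatch(validate_strata(params$strata),
           error = function(e) errors <<- c(errors, conditionMessage(e)))
  tryCatch(validate_life_table(params$life_table),
           error = function(e) errors <<- c(errors, conditionMessage(e)))
  for (trt in .trt_names) {
    spec <- params$treatments[[trt]]
    if (is.null(spec)) {
      errors <- c(errors, sprintf("treatments.%s: missing", trt))
      next
    }
    check_num(spec$cost, sprintf("treatments.%s.cost", trt), lo = 0)
    f <- spec$failure
    if (is.null(f)) {
      if (trt != "tkr_revision") {
        errors <- c(errors, sprintf("treatments.%s.failure: missing", trt))
      }
      next
    }
    check_num(f$two_year, sprintf("treatments.%s.failure.two_year", trt),
              lo = 1e-9, hi = 1 - 1e-9)
    check_num(f$mixture_weight,
              sprintf("treatments.%s.failure.mixture_weight", trt),
              lo = 1e-9, hi = 1)
  }
  # policy
  pol <- params$policy
  if (!all(c("scenario", "decision", "treatment", "weight") %in% names(pol))) {
    errors <- c(errors, "policy: need columns scenario, decision, treatment, weight")
  } else {
    bad_trt <- setdiff(unique(pol$treatment),
                       c(.trt_names, "conservative", "none"))
    if (length(bad_trt) > 0) {
      errors <- c(errors, sprintf("policy: unknown treatment(s) %s",
                                  paste(bad_trt, collapse = ", ")))
    }
    if (any(pol$weight < 0)) {
      errors <- c(errors, "policy: negative weight")
    }
    for (sc in c("with_maci", "without_maci")) {
      for (dec in c("primary", "re2", "re3plus")) {
        w <- pol$weight[pol$scenario == sc & pol$decision == dec]
        if (length(w) == 0 || sum(w) <= 0) {
          errors <- c(errors, sprintf(
            "policy: no positive weight for scenario %s, decision %s",
            sc, dec))
        }
      }
    }
  }
  eco <- params$economics
  check_num(eco$conservative_cost, "economics.conservative_cost", lo = 0)
  check_num(eco$discount_rate, "economics.discount_rate", lo = 0, hi = 1)
  check_num(eco$utility_multiplier, "economics.utility_multiplier", lo = 0)
  if (!identical(eco$mbms_utility, "aci") &&
      !identical(eco$mbms_utility, "mf")) {
    errors <- c(errors, "economics.mbms_utility: must be 'aci' or 'mf'")
  }
  for (nm in names(utility_schedule_default())) {
    check_num(eco$utilities[[nm]], sprintf("economics.utilities.%s", nm),
              lo = 0, hi = 1)
  }
  eng <- params$engine
  check_num(eng$reintervention_delay, "engine.reintervention_delay", lo = 0)
  check_num(eng$wait_interval, "engine.wait_interval", lo = 1e-6)
  check_num(eng$max_revisions, "engine.max_revisions", lo = 0)
  check_num(eng$mf_max, "engine.mf_max", lo = 0)
  check_num(eng$mbms_route_max, "engine.mbms_route_max", lo = 0)
  check_num(eng$maci_min, "engine.maci_min", lo = 0)
  check_num(eng$kr_min, "engine.kr_min", lo = 0)
  if (length(eng$tkr_age) != 2 || eng$tkr_age[1] >= eng$tkr_age[2]) {
    errors <- c(errors, "engine.tkr_age: must be an increasing (min, max) pair")
  }
  if (any(eng$periop_mortality < 0) || any(eng$periop_mortality > 0.01)) {
    errors <- c(errors, "engine.periop_mortality: must lie in [0, 0.01]")
  }
  if (!eng$relapse_size %in% c("original", "resample")) {
    errors <- c(errors, "engine.relapse_size: must be 'original' or 'resample'")
  }
  # calibrate failure models (also surfaces anchor inconsistencies)
  if (length(errors) == 0) {
    for (trt in .trt_names) {
      f <- params$treatments[[trt]]$failure
      if (is.null(f)) next
      tryCatch(
        calibrate_failure_model(f$two_year, f$anchors, f$mixture_weight,
                                f$short_shape %||% 1, f$long_shape %||% 2.5),
        error = function(e) {
          errors <<- c(errors, sprintf("treatments.%s.failure: %s", trt,
                                       conditionMessage(e)))
        })
    }
  }
  if (length(errors) > 0) {
    stop("invalid parameters:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Get or set a parameter by its configuration path
#'
#' Paths are dot-separated, e.g. `"treatments.maci.cost"`,
#' `"treatments.mf.failure.two_year"`, `"economics.discount_rate"`,
#' `"engine.mf_max"`. Used by the sensitivity analyses so that parameter
#' variations never mutate the caller's parameter object.
#'
#' @param params A `des_params` list.
#' @param path Dot-separated configuration path.
#' @param value Replacement value (for `param_set`).
#' @return `param_get` returns the value; `param_set` returns a modified
#'   copy of `params`.
#' @export
param_get <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    if (is.null(node[[k]])) {
      stop(sprintf("unknown parameter path '%s' (failed at '%s')", path, k),
           call. = FALSE)
    }
    node <- node[[k]]
  }
  node
}

#' @rdname param_get
#' @export
param_set <- function(params, path, value) {
  param_get(params, path)  # errors on unknown paths
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  params[[keys]] <- value
  params
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file whose top-level blocks mirror the structure of
#' [des_params()] (`treatments`, `policy`, `economics`, `engine`, plus
#' optional `life_table_csv` and `strata`). Missing blocks fall back to
#' the defaults; the merged configuration is validated as a whole.
#'
#' @param path YAML file path.
#' @return A validated `des_params` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  params <- des_params()
  merge_into <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(new[[nm]]) && is.list(base[[nm]]) &&
          !is.data.frame(new[[nm]]) && !is.data.frame(base[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], new[[nm]])
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  if (!is.null(raw$life_table_csv)) {
    params$life_table <- read_life_table(raw$life_table_csv)
    raw$life_table_csv <- NULL
  }
  if (!is.null(raw$life_table)) {
    lt <- tibble::as_tibble(
      do.call(rbind, lapply(raw$life_table, as.data.frame)))
    validate_life_table(lt)
    params$life_table <- lt
    raw$life_table <- NULL
  }
  if (!is.null(raw$policy)) {
    params$policy <- tibble::as_tibble(
      do.call(rbind, lapply(raw$policy, as.data.frame)))
    raw$policy <- NULL
  }
  for (trt in names(raw$treatments %||% list())) {
    f <- raw$treatments[[trt]]$failure
    if (!is.null(f$anchors)) {
      raw$treatments[[trt]]$failure$anchors <-
        do.call(rbind, lapply(f$anchors, as.data.frame))
    }
  }
  params <- merge_into(params, raw[setdiff(names(raw), "strata")])
  class(params) <- "des_params"
  validate_params(params)
  params
}

#' Write the resolved configuration alongside results
#'
#' Serialises the fully resolved parameter set (defaults included) to
#' YAML so a run can be audited and reproduced.
#'
#' @param params A `des_params` list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config_echo <- function(params, path) {
  to_plain <- function(x) {
    if (is.data.frame(x)) {
      lapply(seq_len(nrow(x)), function(i) as.list(x[i, , drop = FALSE]))
    } else if (is.list(x)) {
      lapply(x, to_plain)
    } else {
      x
    }
  }
  yaml::write_yaml(to_plain(unclass(params)), path)
  invisible(path)
}

# Calibrated failure models for all treatments (revision falls back to
# the TKR model).
.failure_models <- function(params) {
  models <- list()
  for (trt in .trt_names) {
    f <- params$treatments[[trt]]$failure
    if (is.null(f)) next
    models[[trt]] <- calibrate_failure_model(
      f$two_year, f$anchors, f$mixture_weight,
      f$short_shape %||% 1, f$long_shape %||% 2.5)
  }
  if (is.null(models$tkr_revision)) models$tkr_revision <- models$tkr
  models
}

#' Calibrated failure models of a parameter set
#'
#' @param params A `des_params` list.
#' @return Named list of `failure_model` objects, one per intervention.
#' @export
failure_models <- function(params = des_params()) .failure_models(params)
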