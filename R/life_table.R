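#' Construct a life table from Gompertz-Makeham coefficients
#'
#' Expands a parametric all-cause mortality hazard
#' \eqn{h(x) = a + b e^{c x}} into annual death probabilities
#' \eqn{q_x = 1 - \exp(-\int_x^{x+1} h)} for integer ages 0 to `max_age`,
#' per sex. The terminal age receives \eqn{q = 1}.
#'
#' @param male,female Named numeric vectors with elements `a`, `b`, `c`
#'   (Makeham constant, Gompertz level and slope, per year).
#' @param max_age Terminal age at which death is certain.
#' @return A tibble of class `life_table` with columns `sex`, `age`, `qx`.
#' @export
#' @examples
#' lt <- life_table_gompertz(male = c(a = 0.001, b = 0, c = 0.1),
#'                           female = c(a = 0.001, b = 0, c = 0.1))
#' head(lt)
life_table_gompertz <- function(male, female, max_age = 110) {
  one <- function(sex, p) {
    ages <- 0:max_age
    H <- p[["a"]] + (p[["b"]] / p[["c"]]) * (exp(p[["c"]] * (ages + 1)) -
                                               exp(p[["c"]] * ages))
    qx <- pmin(1 - exp(-H), 1)
    qx[length(qx)] <- 1
    tibble::tibble(sex = sex, age = ages, qx = qx)
  }
  # degenerate Gompertz slope 0 -> constant hazard a + b
  fix <- function(p) {
    if (p[["c"]] == 0) c(a = p[["a"]] + p[["b"]], b = 0, c = 1) else p
  }
  out <- dplyr::bind_rows(one("male", fix(male)), one("female", fix(female)))
  class(out) <- c("life_table", class(out))
  out
}

#' Default life table
#'
#' A per-sex Gompertz-Makeham parametrisation calibrated so that the
#' default simulated cohort (entry age about 36 years, 60.7% male)
#' reaches a median death age of about 84 years and hence a median
#' modelled horizon of about 48 years, consistent with contemporary
#' German period mortality. An official table can be supplied instead via
#' [read_life_table()].
#'
#' @return A `life_table` tibble (`sex`, `age`, `qx`).
#' @export
life_table_default <- function() {
  life_table_gompertz(
    male   = c(a = 3.0e-4, b = 4.0e-5, c = 0.0906),
    female = c(a = 1.5e-4, b = 1.8e-5, c = 0.0950),
    max_age = 110
  )
}

#' Validate a life table
#'
#' Requires columns `sex`, `age`, `qx`; every integer age 0..max covered
#' exactly once per sex; probabilities in `[0, 1]`; `q = 1` at the
#' terminal age; and non-decreasing `q` from age 60 upward.
#'
#' @param lt A life-table tibble.
#' @return `lt`, invisibly, if valid; otherwise an error listing every
#'   offending row.
#' @export
validate_life_table <- function(lt) {
  errors <- character()
  if (!all(c("sex", "age", "qx") %in% names(lt))) {
    stop("life table needs columns sex, age, qx", call. = FALSE)
  }
  bad_q <- which(lt$qx < 0 | lt$qx > 1 | is.na(lt$qx))
  if (length(bad_q) > 0) {
    errors <- c(errors, sprintf("qx outside [0, 1] in rows %s",
                                paste(utils::head(bad_q, 5), collapse = ", ")))
  }
  for (s in c("male", "female")) {
    ages <- sort(lt$age[lt$sex == s])
    if (length(ages) == 0) {
      errors <- c(errors, sprintf("no rows for sex %s", s))
      next
    }
    expected <- 0:max(ages)
    missing <- setdiff(expected, ages)
    if (length(missing) > 0) {
      errors <- c(errors, sprintf(
        "sex %s: missing ages %s", s,
        paste(utils::head(missing, 5), collapse = ", ")))
    }
    if (anyDuplicated(ages)) {
      errors <- c(errors, sprintf("sex %s: duplicated ages", s))
    }
    qs <- lt$qx[lt$sex == s][order(lt$age[lt$sex == s])]
    if (length(qs) > 0 && abs(qs[length(qs)] - 1) > 1e-12) {
      errors <- c(errors, sprintf("sex %s: qx at terminal age is not 1", s))
    }
    old <- qs[ages >= 60]
    if (length(old) > 1 && any(diff(old) < -1e-12)) {
      errors <- c(errors, sprintf("sex %s: qx decreases above age 60", s))
    }
  }
  if (length(errors) > 0) {
    stop("invalid life table:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(lt)
}

#' Read a life table from CSV
#'
#' Expects the plain-text layout `sex,age,qx` with `sex` in
#' \{male, female\}, integer ages, and annual death probabilities.
#'
#' @param path CSV file path.
#' @return A validated `life_table` tibble.
#' @export
read_life_table <- function(path) {
  lt <- readr::read_csv(path, col_types = readr::cols(
    sex = readr::col_character(),
    age = readr::col_integer(),
    qx = readr::col_double()
  ))
  validate_life_table(lt)
  class(lt) <- c("life_table", class(lt))
  lt
}

# Precompute, per sex, the survival curve S(a) = P(alive at exact age a)
# for a = 0 .. max_age + 1 (so S[max_age + 2] = 0).
.life_table_prep <- function(lt) {
  prep <- list()
  for (s in c("male", "female")) {
    sub <- lt[lt$sex == s, ]
    sub <- sub[order(sub$age), ]
    S <- c(1, cumprod(1 - sub$qx))
    prep[[s]] <- S
  }
  prep$max_age <- max(lt$age)
  prep
}

# Death ages from per-patient uniforms. `u1` picks the death year by
# inverting the conditional survival curve from the entry age; `u2`
# places death uniformly within that year (truncated so death follows
# entry, and capped at the terminal age).
.death_age_from_u <- function(entry_age, sex, prep, u1, u2) {
  n <- length(entry_age)
  out <- numeric(n)
  for (s in c("male", "female")) {
    m <- sex == s
    if (!any(m)) next
    S <- prep[[s]]
    a0 <- floor(entry_age[m])
    tau <- S[a0 + 1] * (1 - u1[m])
    # death year Y = max{a : S(a) > tau}; count ages with S > tau
    cnt <- rowSums(outer(tau, S, "<"))
    Y <- cnt - 1
    lo <- pmax(Y, entry_age[m])          # death after entry
    hi <- pmin(Y + 1, prep$max_age)      # never beyond the terminal age
    out[m] <- lo + u2[m] * pmax(hi - lo, 0)
  }
  out
}

#' Sample ages at death for a cohort
#'
#' Walks the annual survival probabilities of the life table from each
#' patient's entry age and places death uniformly within the death year.
#' Uses the same per-patient random streams as the event engine, so death
#' ages are identical to those realised inside [run_scenarios()] for the
#' same seed (common random numbers).
#'
#' @param cohort Cohort tibble (`patient_id`, `sex`, `entry_age`, ...).
#' @param life_table A validated life table.
#' @param seed Integer root seed.
#' @return The cohort with an added `death_age` column.
#' @export
#' @examples
#' cohort <- sample_cohort(200, seed = 1)
#' summary(sample_death_ages(cohort, seed = 1)$death_age)
sample_death_ages <- function(cohort, life_table = life_table_default(),
                              seed = 1) {
  validate_life_table(life_table)
  prep <- .life_table_prep(life_table)
  if (any(cohort$entry_age >= prep$max_age)) {
    stop("entry_age must be below the terminal age of the life table",
         call. = FALSE)
  }
  .with_preserved_rng({
    n <- nrow(cohort)
    u1 <- numeric(n)
    u2 <- numeric(n)
    for (i in seq_len(n)) {
      d <- .patient_draws(seed, cohort$patient_id[i])
      u1[i] <- d$death[1]
      u2[i] <- d$death[2]
    }
    dplyr::mutate(cohort,
      death_age = .death_age_from_u(cohort$entry_age, cohort$sex, prep,
                                    u1, u2))
  })
}

# Analytic survival (from a given entry age) implied by the life table,
# with uniform placement of death within each year. Used by tests.
.life_table_survival <- function(life_table, sex, entry_age, t) {
  prep <- .life_table_prep(life_table)
  S <- prep[[sex]]
  a0 <- floor(entry_age)
  Se <- S[a0 + 1]
  age <- entry_age + t
  lo <- floor(age)
  frac <- age - lo
  i <- pmin(lo + 1, length(S) - 1)
  Sa <- S[i]
  Sb <- S[i + 1]
  # within year: death uniform between the year's bounds
  pmax(pmin((Sa - frac * (Sa - Sb)) / Se, 1), 0)
}
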