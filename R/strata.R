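#' Default cohort strata for the simulated study population
#'
#' Returns the stratified marginal distributions of sex, age at model
#' entry, and initial defect size that the synthetic-cohort generator
#' reproduces. The shipped defaults correspond to the published baseline
#' table of the modelled M-ACI production cohort (N = 10,000): 60.7% male;
#' age strata <35 / 35-45 / 45-55 / >=55 with per-sex means 35.9 (male)
#' and 36.6 (female) years; defect strata <2 / 2-4 / 4-6 / 6-8 / 8-10 /
#' >=10 cm2 with per-sex means 4.5 (male) and 4.1 (female) cm2.
#'
#' Open-ended strata are closed at 15-70 years and 0.5-15 cm2; age and
#' defect size are treated as continuous and, given sex, independent
#' (only marginals are published).
#'
#' @return A list of class `cohort_strata` with elements
#'   `sex` (named proportions), and per-sex tibbles `age` and `defect`
#'   with columns `lower`, `upper`, `prop`, plus `age_mean` and
#'   `defect_mean` targets used by the mean-matching step.
#' @export
#' @examples
#' str(cohort_strata_default(), max.level = 2)
cohort_strata_default <- function() {
  strata <- list(
    sex = c(male = 0.607, female = 0.393),
    male = list(
      age = tibble::tibble(
        lower = c(15, 35, 45, 55),
        upper = c(35, 45, 55, 70),
        prop  = c(0.467, 0.300, 0.207, 0.026)
      ),
      defect = tibble::tibble(
        lower = c(0.5, 2, 4, 6, 8, 10),
        upper = c(2, 4, 6, 8, 10, 15),
        prop  = c(0.123, 0.334, 0.272, 0.123, 0.106, 0.042)
      ),
      age_mean = 35.9,
      defect_mean = 4.5
    ),
    female = list(
      age = tibble::tibble(
        lower = c(15, 35, 45, 55),
        upper = c(35, 45, 55, 70),
        prop  = c(0.432, 0.288, 0.251, 0.029)
      ),
      defect = tibble::tibble(
        lower = c(0.5, 2, 4, 6, 8, 10),
        upper = c(2, 4, 6, 8, 10, 15),
        prop  = c(0.156, 0.368, 0.252, 0.106, 0.086, 0.032)
      ),
      age_mean = 36.6,
      defect_mean = 4.1
    )
  )
  class(strata) <- "cohort_strata"
  strata
}

# Validate one stratum table: proportions sum to 1, bounds ordered and
# non-overlapping. Zero-width strata (lower == upper) are allowed and
# draw that single value.
.validate_stratum_table <- function(tab, what, sex, errors) {
  if (!all(c("lower", "upper", "prop") %in% names(tab))) {
    return(c(errors, sprintf(
      "%s strata for %s: need columns lower, upper, prop", what, sex)))
  }
  if (abs(sum(tab$prop) - 1) > 1e-9) {
    errors <- c(errors, sprintf(
      "%s strata for %s: proportions sum to %.12g, not 1", what, sex,
      sum(tab$prop)))
  }
  if (any(tab$prop < 0)) {
    errors <- c(errors, sprintf(
      "%s strata for %s: negative proportion in stratum %d", what, sex,
      which(tab$prop < 0)[1]))
  }
  if (any(tab$upper < tab$lower)) {
    errors <- c(errors, sprintf(
      "%s strata for %s: upper < lower in stratum %d", what, sex,
      which(tab$upper < tab$lower)[1]))
  }
  if (nrow(tab) > 1) {
    gap <- tab$lower[-1] - tab$upper[-nrow(tab)]
    if (any(gap < -1e-12)) {
      errors <- c(errors, sprintf(
        "%s strata for %s: stratum %d overlaps its predecessor", what, sex,
        which(gap < -1e-12)[1] + 1))
    }
  }
  errors
}

#' Validate cohort strata
#'
#' Checks that sex proportions and each per-sex stratum table are
#' well-formed (proportions summing to one, ordered disjoint bounds).
#'
#' @param strata A `cohort_strata` object (see [cohort_strata_default()]).
#' @return `strata`, invisibly, if valid; otherwise an error listing every
#'   offending stratum.
#' @export
validate_strata <- function(strata) {
  errors <- character()
  if (is.null(strata$sex) || abs(sum(strata$sex) - 1) > 1e-9) {
    errors <- c(errors, "sex probabilities must sum to 1")
  }
  for (sex in c("male", "female")) {
    if (is.null(strata[[sex]])) {
      errors <- c(errors, sprintf("missing strata for %s", sex))
      next
    }
    errors <- .validate_stratum_table(strata[[sex]]$age, "age", sex, errors)
    errors <- .validate_stratum_table(strata[[sex]]$defect, "defect size",
                                      sex, errors)
  }
  if (length(errors) > 0) {
    stop("invalid cohort strata:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(strata)
}

# Draw a value from a stratum table given two uniforms (stratum pick,
# position within stratum). Vectorised over u1/u2.
.draw_stratified <- function(tab, u1, u2) {
  cum <- cumsum(tab$prop)
  cum[length(cum)] <- 1  # guard against rounding
  idx <- findInterval(u1, c(0, cum), rightmost.closed = TRUE,
                      all.inside = TRUE)
  tab$lower[idx] + u2 * (tab$upper[idx] - tab$lower[idx])
}

# Shift values of one sex so the sample mean matches `target`, clipping
# each value to its own stratum bounds; iterated because clipping erodes
# part of the shift.
.match_mean <- function(x, tab, target, tol = 0.005, iter = 25) {
  if (is.null(target) || length(x) == 0) return(x)
  cum <- cumsum(tab$prop)
  cum[length(cum)] <- 1
  # recover stratum membership from value position
  lo <- tab$lower
  hi <- tab$upper
  idx <- findInterval(x, c(lo[1], hi), rightmost.closed = TRUE,
                      all.inside = TRUE)
  for (i in seq_len(iter)) {
    delta <- target - mean(x)
    if (abs(delta) <= tol * max(abs(target), 1)) break
    x <- pmin(pmax(x + delta, lo[idx]), hi[idx])
  }
  x
}

#' Sample a synthetic patient cohort
#'
#' Generates `n` patient profiles by stratified sampling: sex from the sex
#' split, then (independently, given sex) an age stratum and a defect-size
#' stratum by their proportions, then a uniform draw within the stratum
#' bounds. A per-sex shift, clipped to each value's stratum, then aligns
#' the sample means of age and defect size with the published means.
#'
#' Sampling is deterministic for a fixed seed, and the profile of patient
#' `i` does not depend on `n`: extending a cohort leaves the existing
#' patients' draws unchanged.
#'
#' @param n Number of patients (>= 1).
#' @param strata A `cohort_strata` object; defaults to the published
#'   baseline distribution.
#' @param seed Integer root seed.
#' @return A tibble with columns `patient_id`, `sex`, `entry_age`,
#'   `defect_size_cm2`.
#' @export
#' @examples
#' cohort <- sample_cohort(500, seed = 1)
#' dplyr::count(cohort, sex)
sample_cohort <- function(n, strata = cohort_strata_default(), seed = 1) {
  stopifnot(n >= 1)
  validate_strata(strata)
  .with_preserved_rng({
    u <- matrix(0, nrow = n, ncol = 5)
    for (i in seq_len(n)) {
      set.seed(.mix_seed(seed, i, 0))
      u[i, ] <- stats::runif(5)
    }
    sex <- ifelse(u[, 1] < strata$sex[["male"]], "male", "female")
    age <- numeric(n)
    defect <- numeric(n)
    for (s in c("male", "female")) {
      m <- sex == s
      if (!any(m)) next
      age[m] <- .draw_stratified(strata[[s]]$age, u[m, 2], u[m, 3])
      defect[m] <- .draw_stratified(strata[[s]]$defect, u[m, 4], u[m, 5])
      age[m] <- .match_mean(age[m], strata[[s]]$age, strata[[s]]$age_mean)
      defect[m] <- .match_mean(defect[m], strata[[s]]$defect,
                               strata[[s]]$defect_mean)
    }
    tibble::tibble(
      patient_id = seq_len(n),
      sex = sex,
      entry_age = age,
      defect_size_cm2 = defect
    )
  })
}

#' Write or read a cohort as CSV
#'
#' Plain-text round trip of a sampled cohort using the column layout
#' `patient_id,sex,entry_age,defect_size_cm2`.
#'
#' @param cohort A cohort tibble as returned by [sample_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_integer(),
    sex = readr::col_character(),
    entry_age = readr::col_double(),
    defect_size_cm2 = readr::col_double()
  ))
}
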