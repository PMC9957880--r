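#' Fit a Weibull survival component through two survivorship anchors
#'
#' Solves the closed form for a single Weibull survival function
#' \eqn{S(t) = \exp(-(t/\lambda)^k)} passing exactly through two points
#' \eqn{(t_1, S_1)} and \eqn{(t_2, S_2)}:
#' \deqn{k = \frac{\log(\log S_1 / \log S_2)}{\log(t_1 / t_2)}, \qquad
#'       \lambda = t_1 / (-\log S_1)^{1/k}.}
#'
#' @param t1,s1 First anchor: time (years > 0) and survival in (0, 1).
#' @param t2,s2 Second anchor; `t2 != t1` and survival non-increasing
#'   in time.
#' @return A list of class `weibull_component` with elements `shape` and
#'   `scale`.
#' @export
#' @examples
#' comp <- weibull_two_point(2, 0.93, 10, 0.80)
#' weibull_survival(comp, c(2, 10))  # reproduces the anchors
weibull_two_point <- function(t1, s1, t2, s2) {
  if (t1 <= 0 || t2 <= 0) stop("anchor times must be positive", call. = FALSE)
  if (t1 == t2) stop("anchor times must be distinct", call. = FALSE)
  if (s1 <= 0 || s1 >= 1 || s2 <= 0 || s2 >= 1) {
    stop("anchor survival must lie strictly in (0, 1)", call. = FALSE)
  }
  # order by time
  if (t2 < t1) {
    tmp <- t1; t1 <- t2; t2 <- tmp
    tmp <- s1; s1 <- s2; s2 <- tmp
  }
  if (s2 >= s1) {
    stop("survival must be strictly decreasing in time across anchors",
         call. = FALSE)
  }
  k <- log(log(s1) / log(s2)) / log(t1 / t2)
  lambda <- t1 / (-log(s1))^(1 / k)
  structure(list(shape = k, scale = lambda), class = "weibull_component")
}

# Single anchor with fixed shape.
.weibull_fixed_shape <- function(t, s, shape) {
  if (s <= 0 || s >= 1) {
    stop("anchor survival must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(shape = shape, scale = t / (-log(s))^(1 / shape)),
            class = "weibull_component")
}

# >2 anchors: least squares on the log-log linearised survival
# log(-log S) = k log t - k log lambda.
.weibull_lsq <- function(t, s) {
  y <- log(-log(s))
  x <- log(t)
  fit <- stats::lm.fit(cbind(1, x), y)
  k <- fit$coefficients[2]
  if (!is.finite(k) || k <= 0) {
    stop("least-squares Weibull fit produced a non-positive shape",
         call. = FALSE)
  }
  lambda <- exp(-fit$coefficients[1] / k)
  structure(list(shape = unname(k), scale = unname(lambda)),
            class = "weibull_component")
}

#' Weibull component survival
#'
#' @param component A `weibull_component` (shape, scale).
#' @param t Times in years (vectorised).
#' @return Survival probabilities \eqn{\exp(-(t/\lambda)^k)}.
#' @export
weibull_survival <- function(component, t) {
  exp(-(t / component$scale)^component$shape)
}

#' Calibrate a two-component Weibull failure model
#'
#' Builds the time-to-failure distribution of one intervention as a
#' mixture of a short-term and a long-term Weibull failure cause:
#' \deqn{S(t) = w\,S_{short}(t) + (1 - w)\,S_{long}(t).}
#' The long-term component is fitted through the supplied survivorship
#' anchors (fixed shape if one anchor, exact two-point closed form if
#' two, least squares on the log-log linearised survival if more). The
#' short-term component is then solved so that the mixture reproduces the
#' 2-year failure probability exactly:
#' \eqn{S_{short}(2) = (S(2) - (1-w) S_{long}(2)) / w}, with fixed
#' short-term shape.
#'
#' @param two_year 2-year failure probability in (0, 1).
#' @param anchors Tibble/data frame of long-term survivorship anchors with
#'   columns `t` (years, > 2) and `s` (survival in (0, 1)), ordered in
#'   time with non-increasing survival.
#' @param mixture_weight Weight `w` in (0, 1] on the short-term cause;
#'   `w = 1` collapses the model to the short-term component alone.
#' @param short_shape Weibull shape of the short-term cause (default 1:
#'   constant early-failure hazard).
#' @param long_shape Shape used when only one long-term anchor is given.
#' @return A list of class `failure_model` with components `short`,
#'   `long` (`weibull_component`s), `mixture_weight`, and `two_year`.
#' @export
#' @examples
#' fm <- calibrate_failure_model(0.07,
#'   anchors = data.frame(t = c(25, 45), s = c(0.57, 0.08)),
#'   mixture_weight = 0.075)
#' failure_survival(fm, 2)  # = 0.93
calibrate_failure_model <- function(two_year, anchors,
                                    mixture_weight = 0.075,
                                    short_shape = 1, long_shape = 2.5) {
  if (two_year <= 0 || two_year >= 1) {
    stop("two_year failure probability must lie in (0, 1)", call. = FALSE)
  }
  if (mixture_weight <= 0 || mixture_weight > 1) {
    stop("mixture_weight must lie in (0, 1]", call. = FALSE)
  }
  anchors <- as.data.frame(anchors)
  if (nrow(anchors) < 1) stop("need at least one long-term anchor",
                              call. = FALSE)
  if (any(anchors$t <= 2)) {
    stop("long-term anchors must lie beyond 2 years", call. = FALSE)
  }
  if (nrow(anchors) > 1) {
    o <- order(anchors$t)
    anchors <- anchors[o, ]
    if (any(diff(anchors$s) > 0)) {
      stop("anchor survival must be non-increasing in time", call. = FALSE)
    }
  }
  long <- if (nrow(anchors) == 1) {
    .weibull_fixed_shape(anchors$t, anchors$s, long_shape)
  } else if (nrow(anchors) == 2) {
    weibull_two_point(anchors$t[1], anchors$s[1], anchors$t[2], anchors$s[2])
  } else {
    .weibull_lsq(anchors$t, anchors$s)
  }
  s2 <- 1 - two_year
  w <- mixture_weight
  s_short_2 <- (s2 - (1 - w) * weibull_survival(long, 2)) / w
  if (s_short_2 <= 0 || s_short_2 >= 1) {
    stop(sprintf(paste0(
      "short-term survival at 2 years solves to %.4f (outside (0, 1)); ",
      "the long-term anchors are inconsistent with the 2-year failure ",
      "rate at this mixture weight"), s_short_2), call. = FALSE)
  }
  short <- structure(
    list(shape = short_shape,
         scale = 2 / (-log(s_short_2))^(1 / short_shape)),
    class = "weibull_component")
  structure(
    list(short = short, long = long, mixture_weight = w,
         two_year = two_year, anchors = anchors),
    class = "failure_model")
}

#' Mixture survival, density-free CDF, and quantile sampling
#'
#' `failure_survival()` evaluates the mixture survival
#' \eqn{S(t) = w S_{short}(t) + (1-w) S_{long}(t)};
#' `failure_cdf()` is its complement; `sample_failure_times()` draws
#' failure times by picking the component by the mixture weight and then
#' inverting that component's CDF, \eqn{t = \lambda(-\log u)^{1/k}}.
#'
#' @param model A `failure_model`.
#' @param t Times in years.
#' @param n Number of draws.
#' @param seed Integer seed for the stand-alone sampler.
#' @return Survival/CDF values, or a vector of `n` failure times.
#' @export
failure_survival <- function(model, t) {
  w <- model$mixture_weight
  w * weibull_survival(model$short, t) +
    (1 - w) * weibull_survival(model$long, t)
}

#' @rdname failure_survival
#' @export
failure_cdf <- function(model, t) 1 - failure_survival(model, t)

#' @rdname failure_survival
#' @export
sample_failure_times <- function(model, n, seed = 1) {
  .with_preserved_rng({
    set.seed(seed)
    u_comp <- stats::runif(n)
    u_q <- stats::runif(n)
    .failure_time_from_u(
      model$mixture_weight,
      model$short$shape, model$short$scale,
      model$long$shape, model$long$scale,
      u_comp, u_q)
  })
}

# Scalar/vector kernel shared with the event engine.
.failure_time_from_u <- function(w, ks, ls, kl, ll, u_comp, u_q) {
  short <- u_comp < w
  t <- numeric(length(u_q))
  t[short] <- ls * (-log(u_q[short]))^(1 / ks)
  t[!short] <- ll * (-log(u_q[!short]))^(1 / kl)
  t
}

#' Median time to failure of a calibrated model
#'
#' Numeric inversion of the mixture survival at 0.5.
#'
#' @param model A `failure_model`.
#' @return Median failure time in years.
#' @export
failure_median <- function(model) {
  f <- function(t) failure_survival(model, t) - 0.5
  stats::uniroot(f, c(1e-9, 500))$root
}

#' Survival-curve samples for diagnostics
#'
#' Evaluates the mixture survival on a regular grid, for export or
#' plotting.
#'
#' @param model A `failure_model`.
#' @param t_max Upper end of the grid in years.
#' @param by Grid step (default 0.25 years).
#' @return A tibble with columns `t_years`, `survival`.
#' @export
failure_survival_grid <- function(model, t_max = 50, by = 0.25) {
  t <- seq(0, t_max, by = by)
  tibble::tibble(t_years = t, survival = failure_survival(model, t))
}
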