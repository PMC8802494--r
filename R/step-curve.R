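#' Right-continuous survival step function
#'
#' A step curve starts at 1 at time 0 and drops at its knots; values are
#' non-increasing probabilities.  Kaplan-Meier estimates are represented
#' this way (see [km_curve()]), with knots at the event times only.
#'
#' @param knots Strictly increasing positive times.
#' @param values Survival values after each knot, non-increasing, in
#'   \[0, 1\].
#' @param variance Optional pointwise variance at each knot.
#' @return An object of class `step_curve`.
#' @export
step_curve <- function(knots, values, variance = NULL) {
  knots <- as.numeric(knots)
  values <- as.numeric(values)
  if (length(knots) != length(values)) {
    abort("knots and values must have equal length.")
  }
  if (is.unsorted(knots, strictly = TRUE)) {
    abort("knots must be strictly increasing.")
  }
  if (any(knots <= 0)) {
    abort("knots must be strictly positive.")
  }
  if (length(values) && (any(values < 0) || any(values > 1))) {
    abort("survival values must lie in [0, 1].")
  }
  if (is.unsorted(rev(values))) {
    abort("survival values must be non-increasing.")
  }
  structure(
    list(knots = knots, values = values, variance = variance),
    class = "step_curve"
  )
}

#' Kaplan-Meier product-limit estimate for one arm
#'
#' Computes the product-limit estimator
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)} with the Greenwood
#' variance \eqn{\hat S(t)^2 \sum_{t_i \le t} d_i / (n_i (n_i - d_i))}
#' (terms with \eqn{n_i = d_i} omitted).  Ties between events and
#' censorings at the same time are resolved events-first: censored
#' subjects remain in the risk set at their censoring time.
#'
#' @param time Positive observed times.
#' @param status Event indicators (1 = event, 0 = censored).
#' @return A `km_curve` (subclass of `step_curve`) with fields
#'   `knots` (distinct event times), `values`, `variance`, `n_risk`,
#'   `n_event`, `n` and `max_time`.
#' @examples
#' km <- km_curve(c(1, 2, 3), c(1, 1, 1))
#' eval_step(km, 2) # 1/3
#' @export
km_curve <- function(time, status) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (length(time) < 1) abort("at least one observation is required.")
  if (any(time <= 0)) abort("all times must be strictly positive.")
  if (!all(status %in% c(0, 1))) abort("status must be 0 or 1.")
  et <- sort(unique(time[status == 1]))
  k <- length(et)
  if (k == 0) {
    out <- step_curve(numeric(0), numeric(0), variance = numeric(0))
  } else {
    n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
    n_event <- vapply(
      et, function(t) sum(time == t & status == 1), numeric(1)
    )
    s <- cumprod(1 - n_event / n_risk)
    gw_term <- ifelse(
      n_risk > n_event,
      n_event / (n_risk * (n_risk - n_event)),
      0
    )
    variance <- s^2 * cumsum(gw_term)
    out <- step_curve(et, s, variance = variance)
  }
  out$n_risk <- if (k) vapply(et, function(t) sum(time >= t), numeric(1)) else numeric(0)
  out$n_event <- if (k) vapply(et, function(t) sum(time == t & status == 1), numeric(1)) else numeric(0)
  out$n <- length(time)
  out$max_time <- max(time)
  out$censor_times <- sort(time[status == 0])
  class(out) <- c("km_curve", "step_curve")
  out
}

#' Evaluate a step curve
#'
#' `eval_step()` uses the right-continuous convention
#' (\eqn{S(t_i) =} value after the drop); `eval_step_left()` returns the
#' left limit \eqn{S(t-)}.  Both return 1 before the first knot and
#' carry the last value forward beyond the last knot.
#'
#' @param curve A `step_curve`.
#' @param t Times at which to evaluate (vectorised).
#' @return Numeric vector of survival values.
#' @export
eval_step <- function(curve, t) {
  idx <- findInterval(t, curve$knots)
  c(1, curve$values)[idx + 1L]
}

#' @rdname eval_step
#' @export
eval_step_left <- function(curve, t) {
  idx <- findInterval(t, curve$knots, left.open = TRUE)
  c(1, curve$values)[idx + 1L]
}

#' Exact integral of a step curve
#'
#' Rectangle sum of the right-continuous step function over
#' \eqn{[a, b]}; no quadrature error.
#'
#' @param curve A `step_curve`.
#' @param a,b Integration limits, `a <= b`.
#' @return The integral as a single number.
#' @examples
#' s <- step_curve(c(1, 2), c(0.5, 0))
#' integrate_step(s, 0, 1.5) # 1*1 + 0.5*0.5 = 1.25
#' @export
integrate_step <- function(curve, a, b) {
  if (length(a) != 1 || length(b) != 1) abort("a and b must be scalars.")
  if (a > b) abort("integration limits must satisfy a <= b.")
  inner <- curve$knots[curve$knots > a & curve$knots < b]
  pts <- c(a, inner, b)
  vals <- eval_step(curve, pts[-length(pts)])
  sum(diff(pts) * vals)
}

#' Median survival time of a step curve
#'
#' The smallest time at which the curve reaches or falls below 0.5
#' (first attainment on plateaus).  Returns `NA` when the curve never
#' reaches 0.5 within follow-up, in which case the median is not
#' defined.
#'
#' @param curve A `step_curve`.
#' @return A single time, or `NA_real_` if undefined.
#' @export
median_survival <- function(curve) {
  hit <- which(curve$values <= 0.5)
  if (length(hit) == 0) {
    return(NA_real_)
  }
  curve$knots[hit[1]]
}

#' Pooled Kaplan-Meier estimate (groups merged)
#'
#' The KM estimate of the pooled sample, used (via its left limit) as
#' the weight process of the Peto-Peto and Fleming-Harrington weighted
#' log-rank tests.
#'
#' @param data A two-arm data frame (`time`, `status`, `group`).
#' @return A `km_curve`.
#' @export
pooled_km <- function(data) {
  s <- check_ipd(data)
  km_curve(s$time, s$status)
}

#' @export
tidy.step_curve <- function(x, ...) {
  tibble(
    time = x$knots,
    survival = x$values,
    std_err = if (is.null(x$variance)) NA_real_ else sqrt(x$variance)
  )
}

#' @export
print.step_curve <- function(x, ...) {
  cat("<step_curve> with", length(x$knots), "knots\n")
  if (length(x$knots)) {
    cat(
      "  range [", format(min(x$knots)), ",", format(max(x$knots)),
      "], final survival", format(x$values[length(x$values)]), "\n"
    )
  }
  invisible(x)
}

#' Restricted mean survival time for one arm
#'
#' Area under the Kaplan-Meier curve up to the truncation time `tau`,
#' with the standard Greenwood-type variance
#' \eqn{\sum_{t_i \le \tau} A_i^2 d_i / (n_i (n_i - d_i))} where
#' \eqn{A_i = \int_{t_i}^{\tau} \hat S(t)\,dt}.  Terms with
#' \eqn{n_i = d_i} contribute 0 (with a warning).
#'
#' @param time,status Per-subject observed times and event indicators
#'   for a single arm.
#' @param tau Truncation time; must not exceed the arm's largest
#'   observed time.
#' @return A one-row tibble with columns `tau`, `estimate`, `variance`.
#' @examples
#' rmst(c(1, 2), c(1, 0), tau = 1.5)
#' @export
rmst <- function(time, status, tau) {
  if (length(tau) != 1 || tau <= 0) abort("tau must be a positive scalar.")
  if (tau > max(time)) abort("tau exceeds follow-up.")
  km <- km_curve(time, status)
  est <- integrate_step(km, 0, tau)
  keep <- km$knots <= tau
  v <- 0
  if (any(keep)) {
    d <- km$n_event[keep]
    n <- km$n_risk[keep]
    a <- vapply(
      km$knots[keep], function(t) integrate_step(km, t, tau), numeric(1)
    )
    term <- ifelse(n > d, d / (n * (n - d)), 0)
    if (any(n == d)) {
      warn("risk set exhausted at an event time before tau; variance term set to 0.")
    }
    v <- sum(a^2 * term)
  }
  tibble(tau = tau, estimate = est, variance = v)
}
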