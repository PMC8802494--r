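# Scenario generator for two-arm survival data and the Monte-Carlo
# harness for size and power studies.

#' Hazard models for simulated arms
#'
#' * `hazard_exponential(rate)` — constant hazard.
#' * `hazard_weibull(shape, scale)` — cumulative hazard
#'   \eqn{(t/\mathrm{scale})^{\mathrm{shape}}}.
#' * `hazard_pwexp(rates, breaks)` — piecewise-constant hazard with
#'   `length(breaks) + 1` segments; the workhorse for early/late
#'   difference and crossing-curve scenarios.
#'
#' @param rate,rates Positive hazard rate(s).
#' @param shape,scale Positive Weibull parameters.
#' @param breaks Strictly increasing positive segment boundaries.
#' @return A `hazard_model` object.
#' @name hazard_models
NULL

#' @rdname hazard_models
#' @export
hazard_exponential <- function(rate) {
  hazard_pwexp(rates = rate, breaks = numeric(0))
}

#' @rdname hazard_models
#' @export
hazard_pwexp <- function(rates, breaks = numeric(0)) {
  if (any(rates <= 0)) abort("hazard rates must be strictly positive.")
  if (length(rates) != length(breaks) + 1) {
    abort("need length(rates) == length(breaks) + 1.")
  }
  if (length(breaks) && (any(breaks <= 0) ||
                           is.unsorted(breaks, strictly = TRUE))) {
    abort("breaks must be strictly increasing and positive.")
  }
  structure(
    list(kind = "pwexp", rates = as.numeric(rates),
         breaks = as.numeric(breaks)),
    class = "hazard_model"
  )
}

#' @rdname hazard_models
#' @export
hazard_weibull <- function(shape, scale) {
  if (shape <= 0 || scale <= 0) abort("shape and scale must be positive.")
  structure(
    list(kind = "weibull", shape = shape, scale = scale),
    class = "hazard_model"
  )
}

cumhaz <- function(model, t) {
  switch(model$kind,
    pwexp = {
      b <- c(0, model$breaks)
      seg_h <- c(0, cumsum(model$rates[-length(model$rates)] * diff(b)))
      idx <- findInterval(t, b)
      seg_h[idx] + model$rates[idx] * (t - b[idx])
    },
    weibull = (t / model$scale)^model$shape
  )
}

inv_cumhaz <- function(model, h) {
  switch(model$kind,
    pwexp = {
      b <- c(0, model$breaks)
      seg_h <- c(0, cumsum(model$rates[-length(model$rates)] * diff(b)))
      idx <- findInterval(h, seg_h)
      idx <- pmin(idx, length(model$rates))
      b[idx] + (h - seg_h[idx]) / model$rates[idx]
    },
    weibull = model$scale * h^(1 / model$shape)
  )
}

#' Censoring models for simulated arms
#'
#' `cens_none()` (no censoring), `cens_uniform(max)` (uniform on
#' \[0, max\]), `cens_admin(time)` (administrative cutoff at a fixed
#' time).
#'
#' @param max,time Positive bounds.
#' @return A `censoring_model` object.
#' @name censoring_models
NULL

#' @rdname censoring_models
#' @export
cens_none <- function() {
  structure(list(kind = "none"), class = "censoring_model")
}

#' @rdname censoring_models
#' @export
cens_uniform <- function(max) {
  if (max <= 0) abort("the censoring bound must be positive.")
  structure(list(kind = "uniform", max = max), class = "censoring_model")
}

#' @rdname censoring_models
#' @export
cens_admin <- function(time) {
  if (time <= 0) abort("the administrative cutoff must be positive.")
  structure(list(kind = "admin", time = time), class = "censoring_model")
}

#' Two-arm simulation scenario
#'
#' @param hazard1,hazard2 [hazard_models] for the two arms.
#' @param censoring A [censoring_models] object, shared by both arms.
#' @param n_per_arm Subjects per arm (>= 2).
#' @param label Optional display label.
#' @return A `scenario` object.
#' @seealso [scenario_preset()], [simulate_sample()]
#' @export
scenario <- function(hazard1, hazard2, censoring = cens_none(),
                     n_per_arm = 150L, label = NULL) {
  if (!inherits(hazard1, "hazard_model") ||
        !inherits(hazard2, "hazard_model")) {
    abort("hazard1 and hazard2 must be hazard models.")
  }
  if (!inherits(censoring, "censoring_model")) {
    abort("censoring must be a censoring model.")
  }
  if (n_per_arm < 2) abort("n_per_arm must be at least 2.")
  structure(
    list(
      hazard1 = hazard1, hazard2 = hazard2, censoring = censoring,
      n_per_arm = as.integer(n_per_arm), label = label
    ),
    class = "scenario"
  )
}

#' Named scenario presets
#'
#' The study conditions used throughout the package's own evaluations
#' (all with 150 subjects per arm):
#'
#' * `"null"` — identical exponential(1) arms, uniform(0, 5) censoring
#'   (about 20% censored).
#' * `"ph"` — proportional hazards, exponential rates 1 vs 1.7,
#'   uniform(0, 5) censoring.
#' * `"early"` — arm 2 hazard 2 on \[0, 0.5) then 1 (early difference
#'   only) vs exponential(1).
#' * `"late"` — arm 2 hazard 1 on \[0, 0.5) then 2 vs exponential(1).
#' * `"crossing-1"` — exponential(1) vs piecewise rates (2, 0.5) with
#'   break 0.5: survival curves cross once, at t = 1.5; uniform(0, 4)
#'   censoring.
#' * `"crossing-2"` — exponential(1) vs rates (2, 0.3, 1.5) with breaks
#'   (0.4, 1.5): two crossings (near t = 0.97 and t = 2.24).
#'
#' @param name Preset name.
#' @param n_per_arm Override of the per-arm sample size.
#' @return A `scenario` object.
#' @export
scenario_preset <- function(name = c("null", "ph", "early", "late",
                                     "crossing-1", "crossing-2"),
                            n_per_arm = 150L) {
  name <- match.arg(name)
  exp1 <- hazard_exponential(1)
  switch(name,
    "null" = scenario(exp1, hazard_exponential(1),
                      cens_uniform(5), n_per_arm, label = name),
    "ph" = scenario(exp1, hazard_exponential(1.7),
                    cens_uniform(5), n_per_arm, label = name),
    "early" = scenario(exp1, hazard_pwexp(c(2, 1), 0.5),
                       cens_uniform(5), n_per_arm, label = name),
    "late" = scenario(exp1, hazard_pwexp(c(1, 2), 0.5),
                      cens_uniform(5), n_per_arm, label = name),
    "crossing-1" = scenario(exp1, hazard_pwexp(c(2, 0.5), 0.5),
                            cens_uniform(4), n_per_arm, label = name),
    "crossing-2" = scenario(exp1, hazard_pwexp(c(2, 0.3, 1.5), c(0.4, 1.5)),
                            cens_uniform(4), n_per_arm, label = name)
  )
}

#' Simulate one two-arm sample
#'
#' Event times by inverse-transform sampling from each arm's
#' cumulative hazard; observed time is the minimum of event and
#' censoring time, with `status = 1` when the event came first.
#' Bit-for-bit reproducible given the seed.
#'
#' @param spec A [scenario()].
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return A tibble with columns `time`, `status`, `group` (labels
#'   `"1"` and `"2"`).
#' @export
simulate_sample <- function(spec, seed = NULL) {
  if (!inherits(spec, "scenario")) abort("spec must be a scenario.")
  with_seed(seed, {
    n <- spec$n_per_arm
    t1 <- inv_cumhaz(spec$hazard1, -log(runif(n)))
    t2 <- inv_cumhaz(spec$hazard2, -log(runif(n)))
    cens <- function(k) {
      switch(spec$censoring$kind,
        none = rep(Inf, k),
        uniform = runif(k, 0, spec$censoring$max),
        admin = rep(spec$censoring$time, k)
      )
    }
    c1 <- cens(n)
    c2 <- cens(n)
    tibble(
      time = c(pmin(t1, c1), pmin(t2, c2)),
      status = as.numeric(c(t1 <= c1, t2 <= c2)),
      group = rep(c("1", "2"), each = n)
    )
  })
}

#' Survival-curve crossing times of a scenario
#'
#' Solves \eqn{S_1(t) = S_2(t)} for \eqn{t > 0}.  For two
#' piecewise-exponential arms the cumulative-hazard difference is
#' piecewise linear and solved exactly; Weibull pairs are handled by a
#' sign-change scan with root refinement.  Segments where the two
#' curves coincide identically are not counted as crossings.
#'
#' @param spec A [scenario()].
#' @return A numeric vector of crossing times (empty if none).
#' @export
crossing_times <- function(spec) {
  h1 <- spec$hazard1
  h2 <- spec$hazard2
  delta <- function(t) cumhaz(h1, t) - cumhaz(h2, t)
  if (h1$kind == "pwexp" && h2$kind == "pwexp") {
    pts <- sort(unique(c(0, h1$breaks, h2$breaks)))
    r1 <- h1$rates[findInterval(pts, c(0, h1$breaks))]
    r2 <- h2$rates[findInterval(pts, c(0, h2$breaks))]
    roots <- numeric(0)
    for (j in seq_along(pts)) {
      s <- pts[j]
      e <- if (j < length(pts)) pts[j + 1] else Inf
      slope <- r1[j] - r2[j]
      d0 <- delta(s)
      if (abs(slope) < 1e-14) next
      root <- s - d0 / slope
      if (root > s + 1e-12 && root <= e + 1e-12 && root > 0) {
        roots <- c(roots, root)
      } else if (j == 1 && abs(d0) < 1e-14 && root <= s + 1e-12) {
        # crossing exactly at the segment start (excluding t = 0)
        next
      }
    }
    return(unique(round(roots, 12)))
  }
  upper <- max(inv_cumhaz(h1, 18), inv_cumhaz(h2, 18))
  ts <- seq(1e-9, upper, length.out = 4096)
  dv <- delta(ts)
  roots <- numeric(0)
  for (j in seq_len(length(ts) - 1)) {
    if (dv[j] == 0 && j > 1 && dv[j - 1] != 0) {
      roots <- c(roots, ts[j])
    } else if (dv[j] * dv[j + 1] < 0) {
      roots <- c(roots,
                 uniroot(delta, c(ts[j], ts[j + 1]), tol = 1e-12)$root)
    }
  }
  unique(round(roots, 10))
}

#' Monte-Carlo rejection-rate study
#'
#' Simulates `n_reps` replicates of a scenario, applies the selected
#' tests to each, and tabulates the fraction of replicates with
#' \eqn{p \le \alpha} together with a binomial standard error.  Each
#' replicate draws its data from a child seed of `seed`, and each test
#' gets its own child stream of the replicate seed, so adding or
#' removing a test never perturbs another test's results.  A test that
#' errors on a replicate is recorded as `NA` for that replicate, not
#' dropped silently.
#'
#' @param spec A [scenario()].
#' @param tests Character vector of method codes (see
#'   [battery_codes()]).
#' @param n_reps Number of Monte-Carlo replicates.
#' @param alpha Nominal level.
#' @param n_resamples Inner iterations for resampling-based tests.
#' @param seed Master integer seed.
#' @param keep_p Attach the full replicate-by-test p-value matrix as
#'   attribute `"p_values"` (for concordance analyses across tests).
#' @return A tibble with columns `method`, `n_reps`, `n_valid`,
#'   `n_reject`, `rate`, `se`.
#' @export
rejection_study <- function(spec, tests = battery_codes(), n_reps = 1000,
                            alpha = 0.05, n_resamples = 500,
                            seed = NULL, keep_p = FALSE) {
  if (n_reps < 1) abort("n_reps must be at least 1.")
  tests <- match.arg(tests, battery_codes(), several.ok = TRUE)
  pmat <- matrix(
    NA_real_, n_reps, length(tests), dimnames = list(NULL, tests)
  )
  for (r in seq_len(n_reps)) {
    rep_seed <- derive_seed(if (is.null(seed)) 0L else seed,
                            paste0("rep", r))
    data <- simulate_sample(spec, seed = rep_seed)
    for (code in tests) {
      pmat[r, code] <- tryCatch(
        suppressWarnings(run_single_test(
          code, data,
          alpha = alpha, n_resamples = n_resamples,
          seed = derive_seed(rep_seed, code), tau = NULL
        )$p.value),
        error = function(e) NA_real_
      )
    }
  }
  reject <- pmat <= alpha
  out <- tibble(
    method = tests,
    n_reps = n_reps,
    n_valid = apply(reject, 2, function(x) sum(!is.na(x))),
    n_reject = apply(reject, 2, function(x) sum(x, na.rm = TRUE))
  )
  out$rate <- out$n_reject / out$n_valid
  out$se <- sqrt(out$rate * (1 - out$rate) / out$n_valid)
  class(out) <- c("rejection_study", class(out))
  if (keep_p) attr(out, "p_values") <- pmat
  out
}
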