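test_that("Kaplan-Meier product-limit values match hand computation", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$values, c(2 / 3, 1 / 3, 0))
  expect_equal(eval_step(km, c(0.5, 1, 2.5, 10)), c(1, 2 / 3, 1 / 3, 0))
  # a single censored observation gives S = 1 everywhere
  km0 <- km_curve(5, 0)
  expect_length(km0$knots, 0)
  expect_equal(eval_step(km0, c(1, 10)), c(1, 1))
})

test_that("KM agrees with survival::survfit on random censored samples", {
  skip_if_not_installed("survival")
  for (s in 1:20) {
    d <- rand_sample(25, 25, seed = 100 + s)
    for (g in c("1", "2")) {
      t <- d$time[d$group == g]
      e <- d$status[d$group == g]
      km <- km_curve(t, e)
      sf <- summary(survival::survfit(survival::Surv(t, e) ~ 1),
                    times = km$knots)
      expect_equal(km$values, sf$surv, tolerance = 1e-10)
      # survfit reports NaN where the curve has dropped to zero; the
      # Greenwood sum convention there (omitted term) yields 0 instead
      fin <- is.finite(sf$std.err)
      expect_equal(sqrt(km$variance)[fin], sf$std.err[fin],
                   tolerance = 1e-8)
    }
  }
})

test_that("KM equals one minus the empirical CDF without censoring", {
  withr::with_seed(9, {
    t <- rexp(40)
    km <- km_curve(t, rep(1, 40))
    grid <- seq(0, max(t), length.out = 50)
    expect_equal(eval_step(km, grid), 1 - ecdf(t)(grid))
  })
})

test_that("left-limit evaluation returns the previous segment value", {
  # pooled 4 subjects, events at 1 and 2: S(2-) = 3/4
  km <- km_curve(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(eval_step_left(km, 2), 3 / 4)
  expect_equal(eval_step_left(km, 1), 1)
  expect_equal(eval_step_left(km, km$knots[1]), 1)
  # piecewise constant between event times
  expect_equal(eval_step_left(km, 1.5), eval_step(km, 1))
})

test_that("step integration is an exact rectangle sum", {
  s <- step_curve(c(1, 2), c(0.5, 0))
  expect_equal(integrate_step(s, 0, 1.5), 1.25)
  expect_equal(integrate_step(s, 0.7, 0.7), 0)
  expect_equal(integrate_step(step_curve(10, 0.3), 1, 4), 3)
  expect_error(integrate_step(s, 2, 1), "a <= b")
  # random step curves vs adaptive quadrature of the evaluator
  for (seed in 1:5) {
    withr::with_seed(seed, {
      knots <- sort(runif(8, 0.1, 5))
      values <- sort(runif(8), decreasing = TRUE)
      cv <- step_curve(knots, values)
      a <- runif(1, 0, 1)
      b <- a + runif(1, 0, 5)
      # quadrature of the evaluator, piece by piece so the adaptive
      # rule never straddles a discontinuity
      pts <- sort(unique(c(a, knots[knots > a & knots < b], b)))
      quad <- sum(vapply(seq_len(length(pts) - 1), function(i) {
        integrate(function(x) eval_step(cv, x), pts[i], pts[i + 1],
                  rel.tol = 1e-12)$value
      }, numeric(1)))
      expect_equal(integrate_step(cv, a, b), quad, tolerance = 1e-10)
    })
  }
})

test_that("median survival follows the first-attainment convention", {
  expect_equal(median_survival(step_curve(3, 0.4)), 3)
  expect_true(is.na(median_survival(step_curve(c(1, 2), c(0.8, 0.6)))))
  # plateau exactly at 0.5 starting at t = 2: first attainment
  expect_equal(median_survival(step_curve(c(2, 5), c(0.5, 0.1))), 2)
})

test_that("median survival matches survival::survfit's quantile", {
  skip_if_not_installed("survival")
  for (s in 1:10) {
    d <- rand_sample(30, 30, seed = 200 + s, cens_rate = 0.2)
    km <- km_curve(d$time, d$status)
    sf <- survival::survfit(survival::Surv(d$time, d$status) ~ 1)
    expect_equal(
      median_survival(km),
      unname(summary(sf)$table["median"])
    )
  }
})

test_that("RMST estimate and variance behave as specified", {
  # step curve 1 on [0,1), 0.5 on [1,2): area to 1.5 is 1.25
  expect_equal(rmst(c(1, 2), c(1, 0), tau = 1.5)$estimate, 1.25)
  # no events before tau: estimate tau, variance 0
  out <- rmst(c(2, 3), c(0, 0), tau = 1.5)
  expect_equal(out$estimate, 1.5)
  expect_equal(out$variance, 0)
  expect_error(rmst(c(1, 2), c(1, 1), tau = 3), "exceeds follow-up")
  # matches the naive integral oracle on random data
  for (s in 1:10) {
    d <- rand_sample(25, 1, seed = 300 + s)
    t <- d$time[d$group == "1"]
    e <- d$status[d$group == "1"]
    tau <- 0.8 * max(t)
    expect_equal(rmst(t, e, tau)$estimate, naive_rmst(t, e, tau),
                 tolerance = 1e-12)
  }
})

test_that("RMST is monotone non-decreasing in tau", {
  d <- rand_sample(40, 1, seed = 11)
  t <- d$time[d$group == "1"]
  e <- d$status[d$group == "1"]
  taus <- seq(0.1, max(t), length.out = 20)
  ests <- vapply(
    taus, function(x) suppressWarnings(rmst(t, e, x)$estimate), numeric(1)
  )
  expect_true(all(diff(ests) >= -1e-12))
})

test_that("RMST variance is close to the nonparametric bootstrap", {
  withr::with_seed(42, {
    n <- 500
    t0 <- rexp(n)
    c0 <- runif(n, 0, 4)
    t <- pmin(t0, c0)
    e <- as.numeric(t0 <= c0)
    tau <- 1.5
    v_est <- rmst(t, e, tau)$variance
    boot <- replicate(400, {
      idx <- sample.int(n, replace = TRUE)
      rmst(t[idx], e[idx], min(tau, max(t[idx])))$estimate
    })
    expect_lt(abs(var(boot) - v_est) / v_est, 0.15)
  })
})

test_that("event-time skeleton and statistics ignore subject order", {
  d <- rand_sample(20, 20, seed = 5)
  shuf <- d[withr::with_seed(1, sample(nrow(d))), ]
  expect_identical(logrank_test(d)$statistic, logrank_test(shuf)$statistic)
  expect_identical(
    tidy(pooled_km(d))$survival, tidy(pooled_km(shuf))$survival
  )
  expect_identical(cox_hr(d)$hr, cox_hr(shuf)$hr)
  # seeded permutation tests are also order-invariant thanks to the
  # canonical internal subject order
  expect_identical(
    abc_test(d, n_perm = 200, seed = 3)$p.value,
    abc_test(shuf, n_perm = 200, seed = 3)$p.value
  )
})
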