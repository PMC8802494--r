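test_that("reconstruction without censoring recovers the exact event times", {
  withr::with_seed(21, {
    t1 <- rexp(60)
  })
  arm_data <- data.frame(time = t1, status = 1, group = "1")
  km <- km_curve(t1, rep(1, 60))
  curve <- data.frame(
    time = c(0, km$knots), survival = c(1, km$values)
  )
  rt <- seq(0, max(t1) * 0.9, length.out = 5)
  risk <- data.frame(
    time = rt,
    n_risk = vapply(rt, function(x) sum(t1 >= x), numeric(1))
  )
  rec <- reconstruct_ipd(digitized_arm(curve, risk))
  expect_equal(sort(rec$data$time[rec$data$status == 1]), sort(t1),
               tolerance = 1e-9)
  expect_equal(sum(rec$data$status == 0), 0)
})

test_that("a flat curve reconstructs as uniformly spread censorings", {
  curve <- data.frame(time = c(0, 10), survival = c(1, 1))
  risk <- data.frame(time = c(0, 5, 10), n_risk = c(20, 10, 2))
  rec <- reconstruct_ipd(digitized_arm(curve, risk))
  expect_equal(nrow(rec$data), 20)
  expect_true(all(rec$data$status == 0))
  # at-risk constraints hold exactly
  expect_equal(sum(rec$data$time >= 5), 10)
  expect_equal(sum(rec$data$time >= 10), 2)
})

test_that("round-trip reconstruction preserves counts, curves and the HR", {
  for (s in 1:5) {
    d <- simulate_sample(scenario_preset("crossing-1", 200),
                         seed = 3000 + s)
    dig <- digitize_sample(d)
    rec <- reconstruct_ipd(dig[[1]], dig[[2]])
    # hard invariant: at-risk counts at every risk-table time
    for (a in 1:2) {
      arm <- dig[[a]]
      lab <- c("1", "2")[a]
      tt <- rec$data$time[rec$data$group == lab]
      for (j in seq_len(nrow(arm$risk))) {
        expect_equal(sum(tt >= arm$risk$time[j]), arm$risk$n_risk[j])
      }
      # sample size equals the first risk count
      expect_equal(length(tt), arm$risk$n_risk[1])
    }
    expect_lt(max(rec$km_deviation), 0.01)
    h0 <- cox_hr(d)$hr
    h1 <- cox_hr(rec$data)$hr
    expect_lt(abs(h1 - h0) / h0, 0.05)
  }
})

test_that("total event counts steer the final-interval censoring", {
  d <- simulate_sample(scenario_preset("null", 150), seed = 41)
  dig <- digitize_sample(d, total_events = TRUE)
  rec <- reconstruct_ipd(dig[[1]], dig[[2]])
  ev1 <- sum(rec$data$status[rec$data$group == "1"])
  want1 <- sum(d$status[d$group == "1"])
  expect_lte(abs(ev1 - want1), 1)
})

test_that("infeasible digitized input is rejected with a clear error", {
  expect_error(
    digitized_arm(
      data.frame(time = c(0, 1), survival = c(1, 0.5)),
      data.frame(time = c(0, 1), n_risk = c(10, 12))
    ),
    "non-increasing"
  )
  expect_error(
    digitized_arm(
      data.frame(time = c(0, 1), survival = c(0.9, 1)),
      data.frame(time = c(0, 1), n_risk = c(10, 5))
    ),
    "non-increasing"
  )
  expect_error(
    digitized_arm(
      data.frame(time = c(0, 1), survival = c(1, 0.5)),
      data.frame(time = c(0, 5), n_risk = c(10, 5))
    ),
    "time span"
  )
})

test_that("the Cox HR matches survival::coxph and inverts under label swap", {
  skip_if_not_installed("survival")
  for (s in 1:10) {
    d <- rand_sample(30, 30, seed = 700 + s, rate2 = 1.5)
    got <- cox_hr(d)
    fit <- survival::coxph(
      survival::Surv(time, status) ~ I(group == "2"),
      data = d, ties = "breslow"
    )
    expect_equal(got$log_hr, unname(coef(fit)), tolerance = 1e-6)
    expect_equal(got$se, sqrt(unname(vcov(fit)[1, 1])), tolerance = 1e-6)
    d2 <- d
    d2$group <- ifelse(d$group == "1", "2", "1")
    swapped <- cox_hr(d2)
    expect_equal(swapped$hr, 1 / got$hr, tolerance = 1e-8)
    expect_equal(swapped$ci_low, 1 / got$ci_high, tolerance = 1e-8)
  }
})

test_that("the Cox HR recovers known effect sizes", {
  withr::with_seed(5, {
    d_null <- tibble::tibble(
      time = rexp(400), status = 1, group = rep(c("1", "2"), 200)
    )
  })
  h <- cox_hr(d_null)
  expect_lt(abs(h$log_hr), 3 * h$se)
  withr::with_seed(6, {
    d_ph <- tibble::tibble(
      time = c(rexp(500, 1), rexp(500, 2)),
      status = 1,
      group = rep(c("1", "2"), each = 500)
    )
  })
  h2 <- cox_hr(d_ph)
  expect_lt(abs(h2$log_hr - log(2)), 3 * h2$se)
})

test_that("the quality report compares published and recomputed statistics", {
  d <- simulate_sample(scenario_preset("ph", 150), seed = 77)
  dig <- digitize_sample(d)
  rec <- reconstruct_ipd(dig[[1]], dig[[2]])
  s <- crossurv:::check_ipd(d)
  km1 <- km_curve(s$time[s$group == 1L], s$status[s$group == 1L])
  km2 <- km_curve(s$time[s$group == 2L], s$status[s$group == 2L])
  truth <- list(
    ms1 = median_survival(km1), ms2 = median_survival(km2),
    hr = cox_hr(d)$hr
  )
  qr <- quality_report(rec, truth)
  expect_true(all(qr$rel_dev[1:3] < 0.05, na.rm = TRUE))
  # missing published entries propagate as NA
  qr2 <- quality_report(rec, list(hr = truth$hr))
  expect_true(is.na(qr2$published[1]))
  expect_true(is.na(qr2$abs_dev[1]))
  # identical published and recomputed values give zero deviation
  qr3 <- quality_report(rec, list(hr = qr$reconstructed[3]))
  expect_equal(qr3$abs_dev[3], 0)
})

test_that("reconstructed data support the full test battery", {
  d <- simulate_sample(scenario_preset("crossing-1", 150), seed = 55)
  dig <- digitize_sample(d)
  rec <- reconstruct_ipd(dig[[1]], dig[[2]])
  b <- run_battery(rec$data, n_resamples = 300, seed = 5)
  expect_equal(nrow(b), 11)
  expect_true(all(!is.na(b$p.value)))
})
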