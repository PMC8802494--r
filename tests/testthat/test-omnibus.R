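test_that("KONP statistics match the naive table-building oracle", {
  for (s in 1:8) {
    d <- rand_sample(15, 15, seed = 400 + s)
    sgot <- crossurv:::check_ipd(d)
    g1 <- as.numeric(sgot$group == 1L)
    want <- naive_konp(sgot$time, sgot$status, g1)
    chi <- konp_test(d, "chi", n_perm = 100, seed = 1)
    llr <- konp_test(d, "llr", n_perm = 100, seed = 1)
    expect_equal(chi$statistic, unname(want["chi"]), tolerance = 1e-10)
    expect_equal(llr$statistic, unname(want["llr"]), tolerance = 1e-10)
  }
})

test_that("KONP permutation p agrees with exact enumeration at n = 3 + 3", {
  d <- data.frame(
    time = c(0.6, 1.8, 2.6, 1.0, 2.1, 3.3),
    status = c(1, 1, 0, 1, 1, 1),
    group = rep(c("1", "2"), each = 3)
  )
  s <- crossurv:::check_ipd(d)
  for (variant in c("chi", "llr")) {
    got <- konp_test(d, variant, n_perm = 5000, seed = 17)
    stat_fn <- function(g1) {
      unname(naive_konp(s$time, s$status, g1)[variant])
    }
    p_exact <- exact_perm_p(s$time, s$status,
                            as.numeric(s$group == 1L), stat_fn)
    mc_se <- sqrt(p_exact * (1 - p_exact) / 5000)
    expect_lt(abs(got$p.value - p_exact), 2 * mc_se + 1 / 5001)
  }
})

test_that("KONP chi and llr variants nearly always agree in decision", {
  agree <- vapply(1:200, function(s) {
    d <- rand_sample(40, 40, seed = 10000 + s,
                     rate2 = ifelse(s %% 2 == 0, 1, 1.6))
    a <- konp_test(d, "chi", n_perm = 400, seed = s)$p.value <= 0.05
    b <- konp_test(d, "llr", n_perm = 400, seed = s)$p.value <= 0.05
    a == b
  }, logical(1))
  expect_gte(mean(agree), 0.9)
})

test_that("the ABC statistic is the hand-computed area between curves", {
  # arm 1: S = 1 on [0,2) then 0; arm 2: S = 1 on [0,1), 0.5 on [1, 2.5)
  d <- data.frame(
    time = c(2, 2, 1, 2.5),
    status = c(1, 1, 1, 0),
    group = c("1", "1", "2", "2")
  )
  # tau_end = min(2, 2.5) = 2; area = |1 - 0.5| over [1, 2) = 0.5
  got <- abc_test(d, n_perm = 100, seed = 1)
  expect_equal(got$statistic, 0.5)
  expect_equal(got$tau, 2)
})

test_that("ABC matches the naive area oracle and label-swap symmetry", {
  for (s in 1:8) {
    d <- rand_sample(15, 15, seed = 500 + s)
    sgot <- crossurv:::check_ipd(d)
    got <- abc_test(d, n_perm = 100, seed = 1)
    want <- naive_abc(sgot$time, sgot$status,
                      as.numeric(sgot$group == 1L))
    expect_equal(got$statistic, want, tolerance = 1e-10)
    d2 <- d
    d2$group <- ifelse(d$group == "1", "2", "1")
    expect_equal(abc_test(d2, n_perm = 100, seed = 1)$statistic,
                 got$statistic)
  }
})

test_that("identical arms give ABC = 0 with p = 1", {
  base <- data.frame(time = c(1, 2, 3), status = c(1, 1, 0))
  d <- rbind(transform(base, group = "1"), transform(base, group = "2"))
  got <- abc_test(d, n_perm = 500, seed = 3)
  expect_equal(got$statistic, 0)
  expect_equal(got$p.value, 1)
})

test_that("ABC permutation p agrees with exact enumeration at n = 3 + 3", {
  d <- data.frame(
    time = c(0.9, 1.7, 2.9, 1.3, 2.4, 3.6),
    status = rep(1, 6),
    group = rep(c("1", "2"), each = 3)
  )
  s <- crossurv:::check_ipd(d)
  got <- abc_test(d, n_perm = 5000, seed = 19)
  # the permutation-relevant area uses the observed tau_end, held
  # fixed across label reassignments
  tau_end <- min(max(s$time[s$group == 1L]), max(s$time[s$group == 2L]))
  stat_fn <- function(g1) {
    pts <- sort(unique(c(0, s$time[s$status == 1 & s$time < tau_end],
                         tau_end)))
    total <- 0
    for (i in seq_len(length(pts) - 1)) {
      s1 <- naive_km_at(s$time[g1 == 1], s$status[g1 == 1], pts[i])
      s2 <- naive_km_at(s$time[g1 != 1], s$status[g1 != 1], pts[i])
      total <- total + abs(s1 - s2) * (pts[i + 1] - pts[i])
    }
    total
  }
  p_exact <- exact_perm_p(s$time, s$status,
                          as.numeric(s$group == 1L), stat_fn)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 5000)
  expect_lt(abs(got$p.value - p_exact), 2 * mc_se + 1 / 5001)
})

test_that("two-stage stage-2 statistic matches the naive change-point oracle", {
  for (s in 1:8) {
    d <- rand_sample(15, 15, seed = 600 + s)
    sgot <- crossurv:::check_ipd(d)
    ts <- two_stage_test(d, n_resamples = 100, seed = 1)
    want <- naive_crossing_stat(sgot$time, sgot$status,
                                as.numeric(sgot$group == 1L))
    got_stat <- if (ts$details$stage == 2L) {
      ts$statistic
    } else {
      # recover the stage-2 statistic from the engine directly
      grid <- crossurv:::surv_grid(sgot$time, sgot$status)
      cc <- crossurv:::perm_counts(
        grid, matrix(as.numeric(sgot$group == 1L), ncol = 1)
      )
      crossurv:::crossing_stat_columns(grid, cc$N1, cc$D1)$stat[1]
    }
    expect_equal(got_stat, want, tolerance = 1e-10)
  }
})

test_that("stage-2 permutation p agrees with exact enumeration at n = 3 + 3", {
  d <- data.frame(
    time = c(0.4, 1.9, 2.7, 1.5, 2.3, 3.8),
    status = rep(1, 6),
    group = rep(c("1", "2"), each = 3)
  )
  s <- crossurv:::check_ipd(d)
  ts <- two_stage_test(d, n_resamples = 5000, seed = 23)
  stat_fn <- function(g1) naive_crossing_stat(s$time, s$status, g1)
  p_exact <- exact_perm_p(s$time, s$status,
                          as.numeric(s$group == 1L), stat_fn)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 5000)
  expect_lt(abs(ts$details$p_stage2 - p_exact), 2 * mc_se + 1 / 5001)
})

test_that("a strong proportional-hazards signal is decided at stage 1", {
  stages <- vapply(1:100, function(s) {
    withr::with_seed(11000 + s, {
      d <- tibble::tibble(
        time = c(rexp(100, 1), rexp(100, 3)),
        status = 1,
        group = rep(c("1", "2"), each = 100)
      )
    })
    two_stage_test(d, n_resamples = 200, seed = s)$details$stage
  }, integer(1))
  expect_gte(mean(stages == 1L), 0.95)
})

test_that("permutation p-values are never exactly zero", {
  withr::with_seed(3, {
    d <- tibble::tibble(
      time = c(rexp(30, 1), rexp(30, 6)),
      status = 1,
      group = rep(c("1", "2"), each = 30)
    )
  })
  for (code in c("RMST1", "KONP_chi", "mdir", "ABC")) {
    p <- crossurv:::run_single_test(code, d, n_resamples = 200,
                                    seed = 5)$p.value
    expect_gte(p, 1 / 201)
  }
})
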