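test_that("mdir with a single constant weight reduces to the log-rank chi-square", {
  d <- rand_sample(15, 15, seed = 3)
  lr <- logrank_test(d)
  md <- mdir_test(d, weights = list(constant_weight()), n_perm = 2000,
                  seed = 1)
  expect_equal(md$statistic, lr$statistic, tolerance = 1e-12)
  # permutation p agrees with the chi-square p up to Monte-Carlo error
  expect_lt(abs(md$p.value - lr$p.value), 0.05)
})

test_that("mdir permutation p agrees with exact enumeration at n = 3 + 3", {
  d <- data.frame(
    time = c(0.8, 2.5, 3.1, 1.2, 1.9, 4.0),
    status = rep(1, 6),
    group = rep(c("1", "2"), each = 3)
  )
  s <- crossurv:::check_ipd(d)
  md <- mdir_test(d, n_perm = 5000, seed = 9)
  # independent oracle: Wald statistic assembled from naive score loops
  stat_fn <- function(g1) {
    z1 <- naive_wlr(s$time, s$status, g1, function(x) 1)
    z2 <- naive_wlr(s$time, s$status, g1, function(x) 1 - 2 * x)
    cov12 <- 0
    for (e in sort(unique(s$time[s$status == 1]))) {
      at <- s$time >= e
      ev <- s$time == e & s$status == 1
      n <- sum(at)
      dd <- sum(ev)
      n1 <- sum(at & g1 == 1)
      sl <- naive_km_left(s$time, s$status, e)
      if (n > 1) {
        cov12 <- cov12 + (1 - 2 * sl) *
          n1 * (n - n1) * dd * (n - dd) / (n^2 * (n - 1))
      }
    }
    Sigma <- matrix(c(z1["variance"], cov12, cov12, z2["variance"]), 2)
    z <- c(z1["score"], z2["score"])
    ev <- eigen(Sigma, symmetric = TRUE)
    keep <- ev$values > 1e-10 * max(ev$values)
    sum((crossprod(ev$vectors[, keep, drop = FALSE], z))^2 /
          ev$values[keep])
  }
  p_exact <- exact_perm_p(s$time, s$status,
                          as.numeric(s$group == 1L), stat_fn)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 5000)
  expect_lt(abs(md$p.value - p_exact), 2 * mc_se + 1 / 5001)
})

test_that("MaxCombo reduces to the normal p under duplicated weights", {
  d <- rand_sample(20, 20, seed = 12)
  mc <- maxcombo_test(
    d, weights = list(constant_weight(), constant_weight()),
    method = "mvn", seed = 4
  )
  lr <- logrank_test(d)
  z <- sqrt(lr$statistic)
  expect_equal(mc$statistic, z, tolerance = 1e-12)
  expect_equal(mc$p.value, 2 * pnorm(-z), tolerance = 1e-12)
  expect_equal(length(mc$details$kept), 1L)
})

test_that("MaxCombo on the toy sample with FH(0,0) gives the log-rank statistic", {
  df <- data.frame(time = c(1, 2), status = c(1, 1), group = c(1, 2))
  mc <- maxcombo_test(df, weights = list(fh_weight(0, 0)), seed = 1)
  expect_equal(mc$statistic^2, 1)
})

test_that("the MVN maximum tail evaluator matches closed forms", {
  # independence: P(max |G| >= m) = 1 - (2 phi(m) - 1)^k
  for (k in c(2, 4)) {
    R <- diag(k)
    m <- 1.8
    exact <- 1 - (2 * pnorm(m) - 1)^k
    got <- crossurv:::mvn_max_tail(m, R, draws = 400000L, seed = 7)
    expect_lt(abs(got - exact), 3 * sqrt(exact * (1 - exact) / 400000))
  }
  # strong correlation, dimension 2: numeric integration oracle
  rho <- 0.9
  m <- 2.0
  inner <- integrate(function(x) {
    dnorm(x) * (pnorm((m - rho * x) / sqrt(1 - rho^2)) -
                  pnorm((-m - rho * x) / sqrt(1 - rho^2)))
  }, -m, m, rel.tol = 1e-10)$value
  exact <- 1 - inner
  got <- crossurv:::mvn_max_tail(
    m, matrix(c(1, rho, rho, 1), 2), draws = 400000L, seed = 8
  )
  expect_lt(abs(got - exact), 3 * sqrt(exact * (1 - exact) / 400000) + 1e-4)
})

test_that("MaxCombo permutation p agrees with exact enumeration at n = 3 + 3", {
  d <- data.frame(
    time = c(0.5, 1.4, 2.2, 0.9, 3.0, 3.7),
    status = rep(1, 6),
    group = rep(c("1", "2"), each = 3)
  )
  s <- crossurv:::check_ipd(d)
  mc <- maxcombo_test(d, method = "permutation", n_resamples = 5000,
                      seed = 21)
  fns <- list(
    function(x) 1, function(x) 1 - x, function(x) x,
    function(x) x * (1 - x)
  )
  stat_fn <- function(g1) {
    ts <- vapply(fns, function(fn) {
      w <- naive_wlr(s$time, s$status, g1, fn)
      if (w["variance"] > 0) abs(w["score"]) / sqrt(w["variance"]) else 0
    }, numeric(1))
    max(ts)
  }
  p_exact <- exact_perm_p(s$time, s$status,
                          as.numeric(s$group == 1L), stat_fn)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 5000)
  expect_lt(abs(mc$p.value - p_exact), 2 * mc_se + 1 / 5001)
})

test_that("MaxCombo dominates the Bonferroni combination of its components", {
  for (s in 1:30) {
    d <- rand_sample(25, 25, seed = 6000 + s)
    mc <- maxcombo_test(d, method = "mvn", seed = s, mvn_draws = 50000L)
    p_bonf <- min(1, 4 * 2 * pnorm(-max(abs(mc$details$component_z))))
    expect_lte(mc$p.value, p_bonf + 0.003)
  }
})

test_that("rank-based combination tests are invariant under monotone time transforms", {
  d <- rand_sample(20, 20, seed = 55)
  d3 <- d
  d3$time <- d$time^3
  expect_identical(
    mdir_test(d, n_perm = 300, seed = 2)$p.value,
    mdir_test(d3, n_perm = 300, seed = 2)$p.value
  )
  expect_identical(
    maxcombo_test(d, method = "permutation", n_resamples = 300,
                  seed = 2)$p.value,
    maxcombo_test(d3, method = "permutation", n_resamples = 300,
                  seed = 2)$p.value
  )
  expect_identical(
    konp_test(d, "chi", n_perm = 300, seed = 2)$p.value,
    konp_test(d3, "chi", n_perm = 300, seed = 2)$p.value
  )
  expect_identical(
    two_stage_test(d, n_resamples = 300, seed = 2)$p.value,
    two_stage_test(d3, n_resamples = 300, seed = 2)$p.value
  )
})
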