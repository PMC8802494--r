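# Naive, loop-based reference implementations used as independent
# oracles.  They share no code with the package's engine: everything
# is computed by direct subsetting and explicit products/sums.

naive_km_at <- function(time, status, t) {
  s <- 1
  for (e in sort(unique(time[status == 1]))) {
    if (e > t) break
    n <- sum(time >= e)
    d <- sum(time == e & status == 1)
    s <- s * (1 - d / n)
  }
  s
}

naive_km_left <- function(time, status, t) {
  s <- 1
  for (e in sort(unique(time[status == 1]))) {
    if (e >= t) break
    n <- sum(time >= e)
    d <- sum(time == e & status == 1)
    s <- s * (1 - d / n)
  }
  s
}

# Integral of the naive KM over [0, tau] via the event-time partition.
naive_rmst <- function(time, status, tau) {
  pts <- sort(unique(c(0, time[status == 1 & time < tau], tau)))
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    total <- total + naive_km_at(time, status, pts[i]) * (pts[i + 1] - pts[i])
  }
  total
}

# Weighted log-rank score/variance with a weight function of the
# pooled left-limit KM value; g1 is the group-1 indicator.
naive_wlr <- function(time, status, g1, w_fn = function(s) 1) {
  z <- 0
  v <- 0
  for (e in sort(unique(time[status == 1]))) {
    at <- time >= e
    ev <- time == e & status == 1
    n <- sum(at)
    d <- sum(ev)
    n1 <- sum(at & g1 == 1)
    d1 <- sum(ev & g1 == 1)
    w <- w_fn(naive_km_left(time, status, e))
    z <- z + w * (d1 - n1 * d / n)
    if (n > 1) {
      v <- v + w^2 * n1 * (n - n1) * d * (n - d) / (n^2 * (n - 1))
    }
  }
  c(score = z, variance = v)
}

# Area between the two group KM curves up to min(arm maxima).
naive_abc <- function(time, status, g1) {
  t1 <- time[g1 == 1]
  s1 <- status[g1 == 1]
  t2 <- time[g1 != 1]
  s2 <- status[g1 != 1]
  tau_end <- min(max(t1), max(t2))
  pts <- sort(unique(c(0, time[status == 1 & time < tau_end], tau_end)))
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    total <- total +
      abs(naive_km_at(t1, s1, pts[i]) - naive_km_at(t2, s2, pts[i])) *
        (pts[i + 1] - pts[i])
  }
  total
}

# KONP chi-square and likelihood-ratio sums over the pooled event
# times, with KM-imputed 2x2 tables.
naive_konp <- function(time, status, g1) {
  n1 <- sum(g1 == 1)
  n2 <- sum(g1 != 1)
  n <- n1 + n2
  chi <- 0
  llr <- 0
  for (e in sort(unique(time[status == 1]))) {
    s1 <- naive_km_at(time[g1 == 1], status[g1 == 1], e)
    s2 <- naive_km_at(time[g1 != 1], status[g1 != 1], e)
    O <- rbind(
      c(n1 * (1 - s1), n1 * s1),
      c(n2 * (1 - s2), n2 * s2)
    )
    cs <- colSums(O)
    if (any(cs <= 1e-12)) next
    E <- outer(c(n1, n2), cs) / n
    chi <- chi + n * (O[1, 1] * O[2, 2] - O[1, 2] * O[2, 1])^2 /
      (n1 * n2 * cs[1] * cs[2])
    pos <- O > 1e-12
    llr <- llr + 2 * sum(O[pos] * log(O[pos] / E[pos]))
  }
  c(chi = chi, llr = llr)
}

# Maximally selected sign-change crossing statistic (stage 2 of the
# two-stage procedure): max over change points of |Z(c)| / sqrt(V).
naive_crossing_stat <- function(time, status, g1) {
  ets <- sort(unique(time[status == 1]))
  k <- length(ets)
  if (k < 2) return(0)
  u <- numeric(k)
  v <- 0
  for (i in seq_len(k)) {
    e <- ets[i]
    at <- time >= e
    ev <- time == e & status == 1
    n <- sum(at)
    d <- sum(ev)
    n1 <- sum(at & g1 == 1)
    u[i] <- sum(ev & g1 == 1) - n1 * d / n
    if (n > 1) v <- v + n1 * (n - n1) * d * (n - d) / (n^2 * (n - 1))
  }
  if (v <= 0) return(0)
  best <- 0
  for (j in seq_len(k - 1)) {
    z <- sum(u[seq_len(j)]) - sum(u[-seq_len(j)])
    best <- max(best, abs(z))
  }
  best / sqrt(v)
}

naive_rmst_diff <- function(time, status, g1, tau) {
  abs(
    naive_rmst(time[g1 == 1], status[g1 == 1], tau) -
      naive_rmst(time[g1 != 1], status[g1 != 1], tau)
  )
}

# Exact permutation p-value over all C(n, n1) label assignments for a
# statistic function stat_fn(g1) (larger = more extreme).
exact_perm_p <- function(time, status, g1_obs, stat_fn) {
  n <- length(time)
  n1 <- sum(g1_obs == 1)
  combos <- utils::combn(n, n1)
  stats <- apply(combos, 2, function(idx) {
    g <- as.numeric(seq_len(n) %in% idx)
    stat_fn(g)
  })
  obs <- stat_fn(as.numeric(g1_obs == 1))
  mean(stats >= obs - 1e-9 * max(1, abs(obs)))
}

# A small random censored two-arm sample for property tests.
rand_sample <- function(n1 = 20, n2 = 20, seed = 1, cens_rate = 0.3,
                        rate2 = 1) {
  withr::with_seed(seed, {
    t1 <- rexp(n1)
    t2 <- rexp(n2, rate2)
    c1 <- rexp(n1, cens_rate)
    c2 <- rexp(n2, cens_rate)
    tibble::tibble(
      time = c(pmin(t1, c1), pmin(t2, c2)),
      status = as.numeric(c(t1 <= c1, t2 <= c2)),
      group = rep(c("1", "2"), c(n1, n2))
    )
  })
}
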