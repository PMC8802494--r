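# Pooled event-time grid and the vectorised permutation engine.
#
# Every rank-based statistic in the package is a function of the
# per-group at-risk and event counts at the pooled distinct event
# times.  Under label permutation the pooled counts are invariant, so a
# permutation replicate is fully described by the k x 1 columns
# N1 = A g and D1 = D g, where A and D are fixed 0/1 matrices (at-risk
# and event indicators) and g the permuted group-1 indicator.  All
# permutation tests therefore reduce to two k x (B+1) matrix products
# plus elementwise work; column 1 always holds the observed labels so
# the observed statistic is computed by the identical code path.

# Requires subjects in the canonical order produced by check_ipd:
# ascending time with events before censorings at tied times.  That
# layout makes both the risk sets and the tied-event blocks contiguous
# index ranges, so per-permutation group counts reduce to one running
# sum per column.
surv_grid <- function(time, status) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (is.unsorted(time)) {
    abort("internal error: surv_grid requires time-sorted subjects.")
  }
  et <- sort(unique(time[status == 1]))
  k <- length(et)
  if (k == 0) abort("no events in the sample.")
  n <- length(time)
  # subjects strictly before t_i (not at risk contributors to remove)
  below <- findInterval(et, time, left.open = TRUE)
  d <- vapply(
    et, function(e) sum(time == e & status == 1), numeric(1)
  )
  n_risk <- n - below
  ev_hi <- below + d
  s_pool <- cumprod(1 - d / n_risk)
  s_left <- c(1, s_pool[-k])
  # pooled part of the hypergeometric variance d(n-d)/(n^2 (n-1))
  f <- ifelse(n_risk > 1, d * (n_risk - d) / (n_risk^2 * (n_risk - 1)), 0)
  list(
    t = et, k = k, n = n, below = below, ev_hi = ev_hi,
    n_risk = n_risk, d = d, s_left = s_left, s_pool = s_pool, f = f
  )
}

# n x (B+1) matrix of group-1 indicators; column 1 = observed labels,
# the rest are uniformly random label permutations.
perm_matrix <- function(g1, n_perm, seed = NULL) {
  with_seed(seed, .perm_columns(as.numeric(g1), as.integer(n_perm)))
}

# Group-1 at-risk and event counts at every event time for every
# column of G, via per-column cumulative sums over the sorted
# subjects: N1_i = n1 - #(group-1 before t_i), D1_i = #(group-1 among
# the tied event block at t_i).
perm_counts <- function(grid, G) {
  .group_counts(
    as.integer(grid$below), as.integer(grid$ev_hi),
    matrix(G, nrow = grid$n)
  )
}

# Per-column weighted log-rank scores and variances.
# W: k x m weight matrix. Returns list(Z, V, vt): Z, V are m x B,
# vt the k x B per-time variance increments.
wlr_columns <- function(grid, W, N1, D1) {
  U <- D1 - N1 * (grid$d / grid$n_risk)
  vt <- N1 * (grid$n_risk - N1) * grid$f
  Z <- crossprod(W, U)
  V <- crossprod(W^2, vt)
  list(Z = Z, V = V, vt = vt, U = U)
}

# Group KM at the pooled event times for every column; exhausted risk
# sets carry the last value forward.
group_km_columns <- function(grid, N1, D1) {
  ratio <- D1 / N1
  ratio[N1 == 0] <- 0
  .col_cumprod(1 - ratio)
}

# Segment lengths on which a pooled-grid step function is constant,
# clipped at tau: length k+1, first entry covers [0, t_1) where S = 1.
segment_lengths <- function(grid, tau) {
  lo <- pmin(c(0, grid$t), tau)
  hi <- pmin(c(grid$t, Inf), tau)
  pmax(0, hi - lo)
}

# RMST up to tau per column from a group KM matrix.
rmst_columns <- function(grid, S, tau) {
  len <- segment_lengths(grid, tau)
  len[1] + as.numeric(crossprod(S, len[-1]))
}

perm_pvalue <- function(stats) {
  obs <- stats[1]
  perm <- stats[-1]
  eps <- 1e-9 * max(1, abs(obs))
  (1 + sum(perm >= obs - eps)) / (1 + length(perm))
}
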