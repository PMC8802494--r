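# Omnibus permutation tests: KONP sample-space-partition tests, the
# area-between-curves test, and the two-stage log-rank / crossing
# procedure.

# Per-column KONP statistic.  At each pooled event time t a 2x2 table
# group x {failed by t, survived past t} is formed with the censored
# mass allocated fractionally through the group-wise Kaplan-Meier
# estimate: O_fail,j = n_j (1 - S_j(t)).  Tables with a degenerate
# column margin contribute 0.  The Pearson determinant simplifies:
# O11 O22 - O12 O21 = n1 n2 (S2 - S1).
konp_columns <- function(grid, S1, S2, n1, n2, variant) {
  n <- n1 + n2
  C1 <- n1 * (1 - S1) + n2 * (1 - S2)
  C2 <- n - C1
  bad <- C1 <= 1e-12 | C2 <= 1e-12
  if (variant == "chi") {
    stat_t <- n * n1 * n2 * (S2 - S1)^2 / (C1 * C2)
    stat_t[bad] <- 0
  } else {
    lr_cell <- function(O, E) {
      out <- O * (log(O) - log(E))
      out[O <= 1e-12] <- 0
      out
    }
    stat_t <- 2 * (
      lr_cell(n1 * (1 - S1), n1 * C1 / n) +
        lr_cell(n1 * S1, n1 * C2 / n) +
        lr_cell(n2 * (1 - S2), n2 * C1 / n) +
        lr_cell(n2 * S2, n2 * C2 / n)
    )
    stat_t[bad] <- 0
  }
  colSums(stat_t)
}

#' KONP sample-space-partition permutation test
#'
#' For every pooled event time \eqn{t} the sample is partitioned into
#' \{failed by t\} vs \{survived past t\} per group, with
#' censored-before-t subjects allocated fractionally via the group-wise
#' Kaplan-Meier estimate.  The statistic sums, over the partition
#' times, either the Pearson chi-square (`variant = "chi"`) or the
#' likelihood-ratio \eqn{2\sum O \log(O/E)} contribution
#' (`variant = "llr"`, with \eqn{0\log 0 = 0}) of each 2x2 table.
#' Calibration is by seeded group-label permutation — the tables and
#' group KM estimates are recomputed for every permutation — with the
#' finite-sample correction, making the test exact under equal
#' survival distributions and powerful against a broad range of
#' non-proportional alternatives.
#'
#' @inheritParams wlr_test
#' @param variant `"chi"` (Pearson) or `"llr"` (likelihood-ratio type).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutation stream.
#' @return A `surv_test`.
#' @export
konp_test <- function(data, variant = c("chi", "llr"), n_perm = 5000,
                      seed = NULL) {
  variant <- match.arg(variant)
  s <- check_ipd(data)
  grid <- surv_grid(s$time, s$status)
  if (grid$k < 2) abort("at least two distinct event times are required.")
  G <- perm_matrix(as.numeric(s$group == 1L), n_perm, seed = seed)
  cc <- perm_counts(grid, G)
  S1 <- group_km_columns(grid, cc$N1, cc$D1)
  S2 <- group_km_columns(grid, grid$n_risk - cc$N1, grid$d - cc$D1)
  stats <- konp_columns(grid, S1, S2, s$n1, s$n2, variant)
  new_surv_test(
    method = paste0(
      "KONP sample-space-partition test (",
      if (variant == "chi") "Pearson chi-square" else "likelihood ratio",
      ")"
    ),
    code = if (variant == "chi") "KONP_chi" else "KONP_llr",
    statistic = stats[1],
    statistic_name = if (variant == "chi") "chi-square sum" else "LR sum",
    p_value = perm_pvalue(stats),
    n_resamples = n_perm,
    seed = seed
  )
}

#' Area-between-curves (ABC) permutation test
#'
#' Integrated L1 distance of the two Kaplan-Meier curves,
#' \eqn{D = \int_0^{\tau_{end}} |\hat S_1(t) - \hat S_2(t)|\,dt} with
#' \eqn{\tau_{end}} the smaller of the two arms' largest observed times
#' (no extrapolation beyond follow-up).  The integral is an exact
#' step-function sum; the p-value is a seeded group-label permutation
#' tail with the finite-sample correction, holding \eqn{\tau_{end}}
#' fixed across permutations.
#'
#' @inheritParams konp_test
#' @return A `surv_test` with the observed area in `estimate`.
#' @export
abc_test <- function(data, n_perm = 5000, seed = NULL) {
  s <- check_ipd(data)
  if (sum(s$status[s$group == 1L]) < 1 || sum(s$status[s$group == 2L]) < 1) {
    abort("both arms need at least one event.")
  }
  tau_end <- min(max(s$time[s$group == 1L]), max(s$time[s$group == 2L]))
  grid <- surv_grid(s$time, s$status)
  G <- perm_matrix(as.numeric(s$group == 1L), n_perm, seed = seed)
  cc <- perm_counts(grid, G)
  S1 <- group_km_columns(grid, cc$N1, cc$D1)
  S2 <- group_km_columns(grid, grid$n_risk - cc$N1, grid$d - cc$D1)
  len <- segment_lengths(grid, tau_end)[-1]
  stats <- as.numeric(crossprod(abs(S1 - S2), len))
  new_surv_test(
    method = "Area between Kaplan-Meier curves permutation test",
    code = "ABC",
    statistic = stats[1],
    statistic_name = "integrated |S1 - S2|",
    p_value = perm_pvalue(stats),
    estimate = stats[1],
    tau = tau_end,
    n_resamples = n_perm,
    seed = seed
  )
}

# Per-column crossing statistic: the maximum over candidate change
# points c (the pooled event times except the last) of the
# standardised score with weight +1 up to c and -1 after.
crossing_stat_columns <- function(grid, N1, D1) {
  U <- D1 - N1 * (grid$d / grid$n_risk)
  vt <- N1 * (grid$n_risk - N1) * grid$f
  Csum <- .col_cumsum(matrix(U, nrow = grid$k))
  total <- Csum[grid$k, , drop = FALSE]
  Zc <- 2 * Csum - matrix(total, grid$k, ncol(Csum), byrow = TRUE)
  V <- colSums(vt)
  stat <- rep(0, ncol(Csum))
  idx <- rep(NA_integer_, ncol(Csum))
  pos <- V > 0
  if (grid$k >= 2 && any(pos)) {
    Zsub <- abs(Zc[-grid$k, , drop = FALSE])
    best <- max.col(t(Zsub), ties.method = "first")
    mx <- Zsub[cbind(best, seq_len(ncol(Zsub)))]
    stat[pos] <- mx[pos] / sqrt(V[pos])
    idx[pos] <- best[pos]
  }
  list(stat = stat, idx = idx)
}

#' Two-stage log-rank / crossing-hazards test (2ST)
#'
#' Stage 1 applies the log-rank test at the reduced level
#' \eqn{\varepsilon\alpha}; if it rejects, the procedure stops there.
#' Otherwise stage 2 applies a weighted log-rank test with the
#' data-adaptive sign-change weight \eqn{w(t) = +1} for
#' \eqn{t \le \hat c}, \eqn{-1} after, where \eqn{\hat c} maximises the
#' standardised score over candidate change points at the pooled event
#' times — the classical crossing-hazards direction.  The stage-2
#' p-value is calibrated by seeded label permutation of the same
#' maximally-selected statistic.  The overall p-value is
#' \eqn{\min(1,\, p_1/\varepsilon,\, p_2/(1-\varepsilon))}, which
#' keeps the overall size at or below \eqn{\alpha} for any split.
#'
#' @inheritParams konp_test
#' @param alpha Nominal level used to report which stage decided.
#' @param split_eps Fraction \eqn{\varepsilon} of the level spent on
#'   stage 1 (default 0.5).
#' @param n_resamples Permutations for the stage-2 calibration.
#' @return A `surv_test`; `details` carries the stage p-values, the
#'   deciding stage and the estimated change point.
#' @export
two_stage_test <- function(data, alpha = 0.05, split_eps = 0.5,
                           n_resamples = 5000, seed = NULL) {
  if (split_eps <= 0 || split_eps >= 1) {
    abort("split_eps must lie strictly between 0 and 1.")
  }
  s <- check_ipd(data)
  lr <- logrank_test(data)
  p1 <- lr$p.value
  grid <- surv_grid(s$time, s$status)
  G <- perm_matrix(as.numeric(s$group == 1L), n_resamples, seed = seed)
  cc <- perm_counts(grid, G)
  cs <- crossing_stat_columns(grid, cc$N1, cc$D1)
  degenerate <- grid$k < 2 || cs$stat[1] == 0 && is.na(cs$idx[1])
  if (degenerate) {
    p2 <- NA_real_
    p_overall <- p1
    changepoint <- NA_real_
  } else {
    p2 <- perm_pvalue(cs$stat)
    p_overall <- min(1, p1 / split_eps, p2 / (1 - split_eps))
    changepoint <- grid$t[cs$idx[1]]
  }
  stage <- if (p1 <= split_eps * alpha || is.na(p2)) 1L else 2L
  new_surv_test(
    method = "Two-stage log-rank / crossing-hazards test",
    code = "2ST",
    statistic = if (stage == 1L) lr$statistic else cs$stat[1],
    statistic_name = if (stage == 1L) "stage-1 chi-square" else "stage-2 max |z|",
    p_value = p_overall,
    n_resamples = n_resamples,
    seed = seed,
    details = list(
      p_stage1 = p1, p_stage2 = p2, stage = stage,
      changepoint = changepoint, split_eps = split_eps, alpha = alpha
    )
  )
}
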