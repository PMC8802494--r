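#' Weighted log-rank test
#'
#' Computes the weighted log-rank score
#' \eqn{Z = \sum_i w(t_i)\,(d_{i1} - n_{i1} d_i / n_i)} over the pooled
#' distinct event times, its hypergeometric variance
#' \eqn{V = \sum_i w(t_i)^2\, n_{i1} n_{i2} d_i (n_i - d_i) / (n_i^2
#' (n_i - 1))} (terms with \eqn{n_i = 1} contribute 0), and the
#' standardised statistic \eqn{T = Z/\sqrt V}.  Two-sided inference uses
#' \eqn{T^2 \sim \chi^2_1}; one-sided alternatives use the normal law of
#' \eqn{T}.  Positive \eqn{Z} means more events in the first group than
#' expected under equal hazards.
#'
#' @param data A two-arm data frame with columns `time`, `status`,
#'   `group`.  The first group is the first factor level (or the first
#'   label in sort order).
#' @param weight A weight specification, see [wlr_weights].
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (one-sided in the direction of \eqn{T}).
#' @return A `surv_test` object; `tidy()` it for a one-row tibble.
#'   `details` carries the score `score`, variance `variance` and
#'   standardised statistic `z`.
#' @examples
#' df <- data.frame(time = c(1, 2), status = c(1, 1), group = c(1, 2))
#' wlr_test(df) # chi-square = 1, p about 0.317
#' @export
wlr_test <- function(data, weight = constant_weight(),
                     alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  s <- check_ipd(data)
  grid <- surv_grid(s$time, s$status)
  W <- weight_matrix(weight, grid)
  cc <- perm_counts(grid, matrix(as.numeric(s$group == 1L), ncol = 1))
  res <- wlr_columns(grid, W, cc$N1, cc$D1)
  z_score <- unname(res$Z[1, 1])
  v <- unname(res$V[1, 1])
  if (v <= 0) {
    if (abs(z_score) > 1e-8) {
      abort("internal error: zero variance with non-zero score.")
    }
    t_std <- 0
    p <- 1
  } else {
    t_std <- z_score / sqrt(v)
    p <- switch(alternative,
      two.sided = pchisq(t_std^2, df = 1, lower.tail = FALSE),
      greater = pnorm(t_std, lower.tail = FALSE),
      less = pnorm(t_std)
    )
  }
  new_surv_test(
    method = paste0("Weighted log-rank test, weight ", colnames(W)[1]),
    code = "WLR",
    statistic = t_std^2,
    statistic_name = "chi-square",
    p_value = p,
    details = list(
      score = z_score, variance = v, z = t_std,
      weight = colnames(W)[1], alternative = alternative
    )
  )
}

#' Log-rank test
#'
#' The classical (unweighted) log-rank test; the reference method for
#' two-arm survival comparisons and the most powerful choice under
#' proportional hazards.
#'
#' @inheritParams wlr_test
#' @return A `surv_test` object.
#' @export
logrank_test <- function(data,
                         alternative = c("two.sided", "less", "greater")) {
  out <- wlr_test(data, constant_weight(), alternative = alternative)
  out$method <- "Log-rank test"
  out$code <- "LR"
  out
}

#' Peto-Peto test
#'
#' Weighted log-rank test with the pooled left-limit Kaplan-Meier
#' weight \eqn{w(t) = \hat S(t-)}, which emphasises early survival
#' differences.  Set `modified = TRUE` for the \eqn{n/(n+1)}-modified
#' survival estimate as weight.
#'
#' @inheritParams wlr_test
#' @param modified Use the modified-estimator weight variant.
#' @return A `surv_test` object.
#' @export
peto_peto_test <- function(data, modified = FALSE,
                           alternative = c("two.sided", "less", "greater")) {
  out <- wlr_test(data, peto_weight(modified = modified),
                  alternative = alternative)
  out$method <- if (modified) "Peto-Peto test (modified weight)" else "Peto-Peto test"
  out$code <- "PP"
  out
}

#' Covariance matrix of weighted log-rank scores
#'
#' \eqn{\mathrm{Cov}(Z_a, Z_b) = \sum_i w_a(t_i) w_b(t_i)\,
#' n_{i1} n_{i2} d_i (n_i - d_i) / (n_i^2 (n_i - 1))}; symmetric
#' positive semidefinite with each weight's variance on the diagonal.
#' This is the building block of the multiple-direction and MaxCombo
#' combination tests.
#'
#' @inheritParams wlr_test
#' @param weights A list of weight specifications.
#' @return A symmetric matrix with one row/column per weight.
#' @export
wlr_cov <- function(data, weights) {
  if (inherits(weights, "wlr_weight")) weights <- list(weights)
  if (length(weights) < 1) abort("at least one weight is required.")
  s <- check_ipd(data)
  grid <- surv_grid(s$time, s$status)
  W <- weight_matrix(weights, grid)
  cc <- perm_counts(grid, matrix(as.numeric(s$group == 1L), ncol = 1))
  vt <- cc$N1 * (grid$n_risk - cc$N1) * grid$f
  Sigma <- crossprod(W, W * as.numeric(vt))
  dimnames(Sigma) <- list(colnames(W), colnames(W))
  Sigma
}
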