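# One-parameter two-sample Cox partial likelihood (Breslow ties),
# fitted by Newton iteration.  x = 1 for the second group, so
# exp(beta) is the hazard ratio of group 2 relative to group 1.

cox_fit <- function(time, status, group, tol = 1e-8, max_iter = 50L) {
  grid <- surv_grid(time, status)
  g2 <- as.numeric(group == 2L)
  cc <- perm_counts(grid, matrix(g2, ncol = 1))
  n2 <- as.numeric(cc$N1)
  d2 <- as.numeric(cc$D1)
  n1 <- grid$n_risk - n2
  d <- grid$d
  if (sum(d2) == 0 || sum(d2) == sum(d)) {
    abort("non-identified HR: all events fall in one group.")
  }
  beta <- 0
  for (iter in seq_len(max_iter)) {
    r <- n2 * exp(beta)
    p <- r / (r + n1)
    score <- sum(d2 - d * p)
    info <- sum(d * p * (1 - p))
    if (info <= 0) abort("non-identified HR: degenerate information.")
    step <- score / info
    beta <- beta + step
    if (abs(beta) > 20) {
      abort("non-identified HR: monotone partial likelihood.")
    }
    if (abs(step) < tol) break
  }
  r <- n2 * exp(beta)
  p <- r / (r + n1)
  info <- sum(d * p * (1 - p))
  list(beta = beta, se = 1 / sqrt(info), iter = iter)
}

#' Two-sample Cox hazard ratio with 95% confidence interval
#'
#' Fits the one-parameter Cox proportional-hazards model comparing the
#' second group to the first (Breslow tie handling, Newton iteration on
#' the partial likelihood) and reports \eqn{\exp(\hat\beta)} with the
#' Wald 95% interval \eqn{\exp(\hat\beta \pm 1.96\,\mathrm{se})}.
#' Swapping the group labels inverts the hazard ratio.
#'
#' @inheritParams wlr_test
#' @return A one-row tibble with columns `hr`, `ci_low`, `ci_high`,
#'   `log_hr`, `se`, `p.value` (two-sided Wald).
#' @export
cox_hr <- function(data) {
  s <- check_ipd(data)
  if (sum(s$status) < 1) abort("at least one event is required.")
  fit <- cox_fit(s$time, s$status, s$group)
  z <- fit$beta / fit$se
  tibble(
    hr = exp(fit$beta),
    ci_low = exp(fit$beta - qnorm(0.975) * fit$se),
    ci_high = exp(fit$beta + qnorm(0.975) * fit$se),
    log_hr = fit$beta,
    se = fit$se,
    p.value = 2 * pnorm(-abs(z))
  )
}
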