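# Combination tests built on vectors of weighted log-rank scores.

# Wald-type statistic z' Sigma^+ z with a spectral pseudo-inverse;
# singular values below tol * largest are treated as zero.
wald_pinv_stat <- function(z, Sigma, tol = 1e-10) {
  e <- eigen(Sigma, symmetric = TRUE)
  mx <- max(e$values, 0)
  keep <- e$values > tol * mx
  if (mx <= 0 || !any(keep)) {
    return(NA_real_)
  }
  zz <- crossprod(e$vectors[, keep, drop = FALSE], z)
  sum(zz^2 / e$values[keep])
}

#' Multiple-direction log-rank test
#'
#' Combines several weighted log-rank scores into one Wald-type
#' statistic \eqn{S = Z^\top \hat\Sigma^+ Z}, which projects the data
#' onto the alternative space spanned by the chosen weights: the test
#' has power in the direction of every weight and of any linear
#' combination of them.  The default pair — the constant
#' (proportional-hazards) direction and the sign-changing crossing
#' direction \eqn{w(t) = 1 - 2\hat S(t-)} — targets both PH and
#' crossing-curve alternatives.  The p-value is obtained by group-label
#' permutation with the finite-sample correction
#' \eqn{(1 + \#\{S^\pi \ge S\})/(1 + B)}.
#'
#' @inheritParams wlr_test
#' @param weights List of weight specifications (at least two for a
#'   genuinely multi-direction test).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutation stream (`NULL` to use
#'   the current RNG state).
#' @return A `surv_test`; `details$component_z` holds the standardised
#'   per-weight statistics.
#' @export
mdir_test <- function(data,
                      weights = list(constant_weight(), crossing_weight()),
                      n_perm = 5000, seed = NULL) {
  if (inherits(weights, "wlr_weight")) weights <- list(weights)
  if (length(weights) < 1) abort("at least one weight is required.")
  s <- check_ipd(data)
  grid <- surv_grid(s$time, s$status)
  W <- weight_matrix(weights, grid)
  G <- perm_matrix(as.numeric(s$group == 1L), n_perm, seed = seed)
  cc <- perm_counts(grid, G)
  res <- wlr_columns(grid, W, cc$N1, cc$D1)
  ncol_all <- ncol(res$Z)
  if (ncol(W) == 2L) {
    # closed-form 2x2 Wald statistic per column; near-singular columns
    # fall back to the spectral pseudo-inverse
    s11 <- crossprod(W[, 1]^2, res$vt)
    s22 <- crossprod(W[, 2]^2, res$vt)
    s12 <- crossprod(W[, 1] * W[, 2], res$vt)
    det <- s11 * s22 - s12^2
    z1 <- res$Z[1, ]
    z2 <- res$Z[2, ]
    stats <- as.numeric(
      (z1^2 * s22 - 2 * z1 * z2 * s12 + z2^2 * s11) / det
    )
    degen <- !is.finite(stats) | det <= 1e-10 * pmax(s11 * s22, 0)
    for (b in which(as.logical(degen))) {
      Sigma_b <- crossprod(W, W * res$vt[, b])
      stats[b] <- wald_pinv_stat(res$Z[, b], Sigma_b)
    }
  } else {
    stats <- numeric(ncol_all)
    for (b in seq_len(ncol_all)) {
      Sigma_b <- crossprod(W, W * res$vt[, b])
      stats[b] <- wald_pinv_stat(res$Z[, b], Sigma_b)
    }
  }
  if (is.na(stats[1])) {
    warn("all weighted scores have zero variance; p-value set to 1.")
    stats[1] <- 0
    p <- 1
  } else {
    stats[is.na(stats)] <- 0
    p <- perm_pvalue(stats)
  }
  comp_z <- res$Z[, 1] / sqrt(ifelse(res$V[, 1] > 0, res$V[, 1], Inf))
  names(comp_z) <- colnames(W)
  new_surv_test(
    method = "Multiple-direction log-rank test (permutation)",
    code = "mdir",
    statistic = stats[1],
    statistic_name = "Wald statistic",
    p_value = p,
    n_resamples = n_perm,
    seed = seed,
    details = list(component_z = comp_z, n_weights = ncol(W))
  )
}

# Drop weight components that are exactly redundant (zero variance or
# correlation 1 with an earlier component).
reduce_components <- function(Tstd, Sigma) {
  v <- diag(Sigma)
  keep <- which(v > 0)
  if (length(keep) == 0) {
    return(integer(0))
  }
  R <- stats::cov2cor(Sigma[keep, keep, drop = FALSE])
  sel <- integer(0)
  for (j in seq_along(keep)) {
    if (all(abs(R[j, sel]) < 1 - 1e-10) || length(sel) == 0) {
      sel <- c(sel, j)
    }
  }
  keep[sel]
}

# P(max_a |G_a| >= m) for G ~ N(0, R), by seeded Monte-Carlo
# integration; exact in dimension 1.
mvn_max_tail <- function(m, R, draws = 200000L, seed = NULL) {
  dim_r <- nrow(R)
  if (dim_r == 1L) {
    return(2 * pnorm(-m))
  }
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), dim_r)
  with_seed(seed, {
    Zm <- matrix(rnorm(draws * dim_r), draws, dim_r)
    X <- abs(Zm %*% t(L))
    mx <- X[, 1]
    for (j in 2:dim_r) mx <- pmax(mx, X[, j])
    max(mean(mx >= m), 1 / draws)
  })
}

#' MaxCombo test
#'
#' The maximum of standardised weighted log-rank statistics
#' \eqn{M = \max_a |T_a|} over a grid of Fleming-Harrington weights
#' (default \eqn{G(0,0), G(0,1), G(1,0), G(1,1)}), giving power against
#' proportional-hazards, late, early and middle differences at once.
#' The p-value is either the multivariate-normal tail
#' \eqn{1 - P(\max_a |G_a| \le M)} with the estimated correlation of
#' the scores, evaluated by seeded Monte-Carlo integration
#' (`method = "mvn"`, the default), or a group-label permutation tail
#' (`method = "permutation"`, recommended for fewer than about 30
#' subjects per arm).  Redundant weights (zero variance or perfect
#' correlation) are reduced to the unique subset before inference.
#'
#' @inheritParams mdir_test
#' @param method P-value computation, `"mvn"` or `"permutation"`.
#' @param n_resamples Permutations for `method = "permutation"`.
#' @param mvn_draws Monte-Carlo draws for `method = "mvn"`.
#' @return A `surv_test`; `details$component_z` holds the per-weight
#'   standardised statistics.
#' @export
maxcombo_test <- function(data,
                          weights = list(
                            fh_weight(0, 0), fh_weight(0, 1),
                            fh_weight(1, 0), fh_weight(1, 1)
                          ),
                          method = c("mvn", "permutation"),
                          n_resamples = 5000, seed = NULL,
                          mvn_draws = 50000L) {
  method <- match.arg(method)
  if (inherits(weights, "wlr_weight")) weights <- list(weights)
  s <- check_ipd(data)
  grid <- surv_grid(s$time, s$status)
  W <- weight_matrix(weights, grid)
  g1 <- as.numeric(s$group == 1L)
  cc1 <- perm_counts(grid, matrix(g1, ncol = 1))
  obs <- wlr_columns(grid, W, cc1$N1, cc1$D1)
  Sigma <- crossprod(W, W * obs$vt[, 1])
  Tstd <- obs$Z[, 1] / sqrt(ifelse(obs$V[, 1] > 0, obs$V[, 1], Inf))
  names(Tstd) <- colnames(W)
  keep <- reduce_components(Tstd, Sigma)
  if (length(keep) == 0) {
    warn("all weighted scores have zero variance; p-value set to 1.")
    return(new_surv_test(
      method = "MaxCombo test", code = "MaxCombo", statistic = 0,
      statistic_name = "max |z|", p_value = 1, seed = seed,
      details = list(component_z = Tstd)
    ))
  }
  m_stat <- max(abs(Tstd[keep]))
  if (method == "mvn") {
    R <- stats::cov2cor(Sigma[keep, keep, drop = FALSE])
    p <- mvn_max_tail(
      m_stat, R, draws = mvn_draws, seed = derive_seed(seed, "mvn")
    )
    n_res <- as.integer(mvn_draws)
  } else {
    Wk <- W[, keep, drop = FALSE]
    G <- perm_matrix(g1, n_resamples, seed = seed)
    cc <- perm_counts(grid, G)
    res <- wlr_columns(grid, Wk, cc$N1, cc$D1)
    Tmat <- abs(res$Z) / sqrt(ifelse(res$V > 0, res$V, Inf))
    stats <- apply(Tmat, 2, max)
    p <- perm_pvalue(stats)
    n_res <- as.integer(n_resamples)
  }
  new_surv_test(
    method = paste0("MaxCombo test (", method, ")"),
    code = "MaxCombo",
    statistic = m_stat,
    statistic_name = "max |z|",
    p_value = p,
    n_resamples = n_res,
    seed = seed,
    details = list(component_z = Tstd, kept = names(Tstd)[keep],
                   method = method)
  )
}
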