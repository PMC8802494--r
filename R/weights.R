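#' Weight functions for weighted log-rank statistics
#'
#' A weight specification is evaluated at the pooled distinct event
#' times and multiplies the observed-minus-expected increments of the
#' log-rank score.  Available families:
#'
#' * `constant_weight()` — \eqn{w \equiv 1}: the classical log-rank
#'   test, optimal under proportional hazards.
#' * `fh_weight(rho, gamma)` — Fleming-Harrington
#'   \eqn{G(\rho,\gamma)}: \eqn{w(t) = \hat S(t-)^\rho (1-\hat
#'   S(t-))^\gamma} with \eqn{\hat S} the pooled Kaplan-Meier left
#'   limit; \eqn{(\rho,\gamma)=(1,0)} stresses early, \eqn{(0,1)} late
#'   differences.
#' * `peto_weight()` — Peto-Peto: \eqn{w(t) = \hat S(t-)} (pooled KM
#'   left limit).  `peto_weight(modified = TRUE)` uses the
#'   \eqn{n/(n+1)}-modified estimator
#'   \eqn{\tilde S(t_i) = \prod_{l \le i} (1 - d_l/(n_l + 1))}.
#' * `crossing_weight()` — \eqn{w(t) = 1 - 2 \hat S(t-)}: changes sign
#'   near the pooled median; the canonical crossing direction used by
#'   the multiple-direction log-rank test.
#' * `custom_weight(fn)` — `fn` receives the pooled left-limit KM value
#'   at each event time and returns the weight.
#'
#' @param rho,gamma Non-negative Fleming-Harrington exponents.
#' @param modified Use the \eqn{n/(n+1)}-modified Peto-Peto variant.
#' @param fn A function of the pooled left-limit KM value.
#' @param label Display label for a custom weight.
#' @return A `wlr_weight` object.
#' @seealso [wlr_test()], [mdir_test()], [maxcombo_test()]
#' @name wlr_weights
NULL

new_weight <- function(kind, label, rho = NA_real_, gamma = NA_real_,
                       fn = NULL, modified = FALSE) {
  structure(
    list(kind = kind, label = label, rho = rho, gamma = gamma,
         fn = fn, modified = modified),
    class = "wlr_weight"
  )
}

#' @rdname wlr_weights
#' @export
constant_weight <- function() new_weight("constant", "FH(0,0)")

#' @rdname wlr_weights
#' @export
fh_weight <- function(rho = 0, gamma = 0) {
  if (rho < 0 || gamma < 0) abort("rho and gamma must be >= 0.")
  if (rho == 0 && gamma == 0) {
    return(constant_weight())
  }
  new_weight(
    "fleming_harrington", sprintf("FH(%g,%g)", rho, gamma),
    rho = rho, gamma = gamma
  )
}

#' @rdname wlr_weights
#' @export
peto_weight <- function(modified = FALSE) {
  new_weight(
    "peto", if (modified) "Peto-Peto (modified)" else "Peto-Peto",
    modified = modified
  )
}

#' @rdname wlr_weights
#' @export
crossing_weight <- function() new_weight("crossing", "crossing 1-2S(t-)")

#' @rdname wlr_weights
#' @export
custom_weight <- function(fn, label = "custom") {
  if (!is.function(fn)) abort("fn must be a function.")
  new_weight("custom", label, fn = fn)
}

#' @export
print.wlr_weight <- function(x, ...) {
  cat("<wlr_weight>", x$label, "\n")
  invisible(x)
}

# Evaluate a weight at the pooled event times of a grid (see surv_grid);
# s_left is the pooled left-limit KM, n/d the pooled counts.
eval_weight <- function(w, grid) {
  out <- switch(w$kind,
    constant = rep(1, grid$k),
    fleming_harrington = grid$s_left^w$rho * (1 - grid$s_left)^w$gamma,
    peto = if (w$modified) {
      cumprod(1 - grid$d / (grid$n_risk + 1))
    } else {
      grid$s_left
    },
    crossing = 1 - 2 * grid$s_left,
    custom = as.numeric(w$fn(grid$s_left)),
    abort("unknown weight kind.")
  )
  if (length(out) != grid$k || any(!is.finite(out))) {
    abort("weight evaluation must return one finite value per event time.")
  }
  out
}

weight_matrix <- function(weights, grid) {
  if (inherits(weights, "wlr_weight")) weights <- list(weights)
  W <- vapply(weights, eval_weight, numeric(grid$k), grid = grid)
  W <- matrix(W, nrow = grid$k)
  colnames(W) <- vapply(weights, function(w) w$label, character(1))
  W
}
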