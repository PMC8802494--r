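# Common container for a single two-sample test result.

new_surv_test <- function(method, code, statistic, statistic_name,
                          p_value, estimate = NA_real_, tau = NA_real_,
                          n_resamples = NA_integer_, seed = NA_integer_,
                          details = list()) {
  structure(
    list(
      method = method,
      code = code,
      statistic = unname(statistic),
      statistic_name = statistic_name,
      p.value = unname(p_value),
      estimate = unname(estimate),
      tau = tau,
      n_resamples = n_resamples,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      details = details
    ),
    class = "surv_test"
  )
}

#' @export
print.surv_test <- function(x, digits = 4, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat(
    x$statistic_name, " = ", format(signif(x$statistic, digits)),
    ", p-value = ", format.pval(x$p.value, digits = digits),
    "\n", sep = ""
  )
  if (!is.na(x$tau)) cat("tau =", format(signif(x$tau, digits)), "\n")
  if (!is.na(x$n_resamples)) {
    cat(
      "resamples =", x$n_resamples,
      if (!is.na(x$seed)) paste0("(seed ", x$seed, ")") else "", "\n"
    )
  }
  invisible(x)
}

#' Tidy a two-sample survival test result
#'
#' @param x A `surv_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the method code, statistic and p-value.
#' @export
tidy.surv_test <- function(x, ...) {
  tibble(
    method = x$code,
    statistic = x$statistic,
    p.value = x$p.value,
    tau = x$tau,
    n_resamples = x$n_resamples,
    seed = x$seed
  )
}

#' @export
glance.surv_test <- function(x, ...) {
  dplyr::bind_cols(
    tidy(x),
    tibble(method_long = x$method, statistic_name = x$statistic_name)
  )
}
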