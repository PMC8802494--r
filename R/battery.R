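# The eleven-test battery.

#' Method codes of the test battery
#'
#' The eleven implemented two-sample tests, in the standard reporting
#' order: `LR`, `PP`, `RMST1`, `RMST2`, `coxRMST`, `KONP_chi`,
#' `KONP_llr`, `mdir`, `2ST`, `ABC`, `MaxCombo`.
#'
#' @return A character vector of method codes.
#' @export
battery_codes <- function() {
  c("LR", "PP", "RMST1", "RMST2", "coxRMST", "KONP_chi", "KONP_llr",
    "mdir", "2ST", "ABC", "MaxCombo")
}

run_single_test <- function(code, data, alpha = 0.05, n_resamples = 5000,
                            seed = NULL, tau = NULL) {
  switch(code,
    LR = logrank_test(data),
    PP = peto_peto_test(data),
    RMST1 = rmst1_test(data, tau = tau, n_resamples = n_resamples,
                       seed = seed),
    RMST2 = rmst2_test(data, tau = tau),
    coxRMST = cox_rmst_test(data, tau = tau, n_resamples = n_resamples,
                            seed = seed),
    KONP_chi = konp_test(data, "chi", n_perm = n_resamples, seed = seed),
    KONP_llr = konp_test(data, "llr", n_perm = n_resamples, seed = seed),
    mdir = mdir_test(data, n_perm = n_resamples, seed = seed),
    `2ST` = two_stage_test(data, alpha = alpha,
                           n_resamples = n_resamples, seed = seed),
    ABC = abc_test(data, n_perm = n_resamples, seed = seed),
    MaxCombo = maxcombo_test(data, n_resamples = n_resamples, seed = seed),
    abort(paste0("unknown test code: ", code))
  )
}

#' Run the full battery of two-sample survival tests
#'
#' Applies the selected tests to one dataset and returns a tidy
#' p-value row in the standard method order.  Every resampling-based
#' test draws from its own child stream of the master `seed` (derived
#' from the method name), so the row is bit-for-bit reproducible and
#' adding or removing a test never changes another test's p-value.  A
#' test that fails on the given data is reported as `NA` with the
#' reason in `note`, never aborting the row.
#'
#' @inheritParams wlr_test
#' @param alpha Significance level for the `significant` flag.
#' @param n_resamples Iterations for all resampling-based methods.
#' @param seed Master integer seed.
#' @param tau Optional RMST truncation override; default is the
#'   [tau_rule()] horizon.
#' @param tests Subset of [battery_codes()] to run.
#' @return A tibble (class `battery_result`) with columns `method`,
#'   `statistic`, `p.value`, `significant`, `tau`, `n_resamples`,
#'   `seed`, `note`.
#' @examples
#' \donttest{
#' df <- simulate_sample(scenario_preset("crossing-1"), seed = 7)
#' run_battery(df, n_resamples = 500, seed = 7)
#' }
#' @export
run_battery <- function(data, alpha = 0.05, n_resamples = 5000,
                        seed = 1L, tau = NULL, tests = battery_codes()) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1).")
  if (n_resamples < 100) abort("n_resamples must be at least 100.")
  check_ipd(data)
  tests <- match.arg(tests, battery_codes(), several.ok = TRUE)
  tests <- battery_codes()[battery_codes() %in% tests]
  rows <- purrr::map(tests, function(code) {
    test_seed <- derive_seed(seed, code)
    res <- tryCatch(
      suppressWarnings(run_single_test(
        code, data,
        alpha = alpha, n_resamples = n_resamples,
        seed = test_seed, tau = tau
      )),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      tibble(
        method = code, statistic = NA_real_, p.value = NA_real_,
        significant = NA, tau = NA_real_,
        n_resamples = NA_integer_, seed = test_seed, note = res
      )
    } else {
      tibble(
        method = code, statistic = res$statistic, p.value = res$p.value,
        significant = res$p.value <= alpha, tau = res$tau,
        n_resamples = res$n_resamples, seed = test_seed, note = NA_character_
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("battery_result", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Format a battery row for display
#'
#' P-values are printed to four decimals and floored at
#' \eqn{1/(B + 1)} so a resampling p-value is never rendered as
#' exactly zero; undefined entries render as `NA`.
#'
#' @param battery A [run_battery()] result.
#' @return A tibble with formatted `p_display` column.
#' @export
format_battery <- function(battery) {
  floor_p <- ifelse(
    is.na(battery$n_resamples), 1e-4, 1 / (battery$n_resamples + 1)
  )
  p_disp <- pmax(battery$p.value, floor_p)
  battery$p_display <- ifelse(
    is.na(battery$p.value), "NA", sprintf("%.4f", p_disp)
  )
  battery
}
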