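# Reconstruction of pseudo individual patient data from digitized
# Kaplan-Meier curves plus number-at-risk tables (Guyot-style
# iterative interval solver).

#' Digitized input for one arm
#'
#' Bundles and validates the digitizer output for a single arm: the
#' curve coordinates (time, survival), the number-at-risk table and an
#' optional total event count.  The curve must start at (0, 1) — the
#' point is prepended when missing — with non-decreasing times and
#' non-increasing survival in \[0, 1\]; risk counts must be positive
#' and non-increasing, with risk times inside the curve's time span.
#'
#' @param curve Data frame with columns `time`, `survival`.
#' @param risk Data frame with columns `time`, `n_risk`.
#' @param total_events Optional total number of events in the arm.
#' @return A `digitized_arm` object.
#' @seealso [reconstruct_ipd()], [read_digitized()]
#' @export
digitized_arm <- function(curve, risk, total_events = NA) {
  curve <- tibble(
    time = as.numeric(curve$time), survival = as.numeric(curve$survival)
  )
  risk <- tibble(
    time = as.numeric(risk$time), n_risk = as.numeric(risk$n_risk)
  )
  if (nrow(curve) < 1) abort("the digitized curve is empty.")
  if (is.unsorted(curve$time)) abort("curve times must be non-decreasing.")
  if (any(curve$survival < 0 | curve$survival > 1)) {
    abort("survival values must lie in [0, 1].")
  }
  if (is.unsorted(rev(curve$survival))) {
    abort("survival values must be non-increasing.")
  }
  if (!(curve$time[1] == 0 && curve$survival[1] == 1)) {
    if (curve$survival[1] < 1 && curve$time[1] <= 0) {
      abort("the curve may not drop below 1 at time 0.")
    }
    curve <- dplyr::bind_rows(tibble(time = 0, survival = 1), curve)
  }
  curve <- dplyr::distinct(curve)
  if (nrow(risk) < 2) {
    abort("at least two number-at-risk rows are required per arm.")
  }
  if (is.unsorted(risk$time, strictly = TRUE)) {
    abort("risk-table times must be strictly increasing.")
  }
  if (any(risk$n_risk <= 0)) abort("risk counts must be positive.")
  if (is.unsorted(rev(risk$n_risk))) {
    abort("risk counts must be non-increasing.")
  }
  if (max(risk$time) > max(curve$time) + 1e-9) {
    abort("risk-table times must lie within the curve's time span.")
  }
  structure(
    list(curve = curve, risk = risk, total_events = total_events),
    class = "digitized_arm"
  )
}

#' Read digitizer output for one arm
#'
#' Expects two delimited text files (comma or tab, auto-detected): the
#' curve coordinates with header `time,survival` and the risk table
#' with header `time,n_risk` — the usual export of plot digitizers.
#'
#' @param curve_file,risk_file File paths.
#' @param total_events Optional total event count for the arm.
#' @return A [digitized_arm()] object.
#' @export
read_digitized <- function(curve_file, risk_file, total_events = NA) {
  read_two <- function(file, cols) {
    header <- readLines(file, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    out <- readr::read_delim(file, delim = delim, show_col_types = FALSE)
    missing_cols <- setdiff(cols, names(out))
    if (length(missing_cols)) {
      abort(paste0(file, " is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    out
  }
  digitized_arm(
    curve = read_two(curve_file, c("time", "survival")),
    risk = read_two(risk_file, c("time", "n_risk")),
    total_events = total_events
  )
}

# When the digitized survival values are noise-free, the drop ratio
# 1 - S_k / S_{k-1} equals d_k / n_k for integers d_k <= n_k, which
# pins the at-risk size at the step down to a divisor ambiguity.  Pick
# the consistent size closest to the tentative (uniform-censoring)
# one; with noisy input no size is consistent and the tentative value
# is kept.
snap_at_risk <- function(r, n_tent, n_min, n_max) {
  n_min <- max(1L, n_min)
  if (n_max < n_min) {
    return(NA_integer_)
  }
  cand <- n_min:n_max
  dd <- r * cand
  ok <- abs(dd - round(dd)) < 1e-6 & round(dd) >= 0 & round(dd) <= cand
  cand <- cand[ok]
  if (length(cand) == 0) {
    return(NA_integer_)
  }
  if (abs(r - 1) < 1e-9) {
    # a drop to zero: any n with d = n fits, but under continuous
    # event times simultaneous deaths have probability zero, so take
    # the smallest consistent risk set (one final death, the rest
    # censored before it)
    return(min(cand))
  }
  cand[which.min(abs(cand - n_tent))]
}

# Simulate one risk-table interval under a trial censoring count.
# Censorings are spread uniformly over the interval, re-allocated
# between digitized steps where the exact survival ratios identify the
# true risk-set sizes.  Returns the end-of-interval state plus the
# implied events/censorings.
run_interval <- function(tt, ss, lower, upper, t_start, t_end,
                         n_start, km_start, n_cens, free_cens = FALSE) {
  n_run <- n_start
  km <- km_start
  d <- integer(0)
  cens_times <- numeric(0)
  if (upper >= lower) {
    ks <- lower:upper
    nsteps <- length(ks)
    d <- integer(nsteps)
    sb <- c(t_start, tt[ks], t_end)
    pos <- if (n_cens > 0) {
      t_start + seq_len(n_cens) / (n_cens + 1) * (t_end - t_start)
    } else {
      numeric(0)
    }
    # tentative censor count per slot; slot j lies before event j,
    # censorings exactly at an event time stay at risk there
    c_tent <- vapply(seq_len(nsteps + 1L), function(j) {
      sum(pos >= sb[j] & pos < sb[j + 1])
    }, integer(1))
    budget <- n_cens
    deficit <- 0L
    for (j in seq_len(nsteps)) {
      k <- ks[j]
      c_here <- min(c_tent[j], budget, n_run)
      n_use <- n_run - c_here
      dk <- 0L
      if (km > 0 && n_run > 0) {
        r <- 1 - ss[k] / km
        # with no at-risk target ahead (free_cens) the ratio search may
        # place censorings the default assumption would miss
        n_floor <- if (free_cens) 1L else max(1L, n_run - budget)
        snapped <- snap_at_risk(r, n_use, n_floor, n_run)
        if (!free_cens) {
          # a consistent risk-set size below the censoring budget that
          # sits at least as close to the uniform-censoring allocation
          # signals that the budget is too narrow
          alt <- snap_at_risk(r, n_use, 1L, n_run)
          if (!is.na(alt) && alt < n_floor &&
                (is.na(snapped) ||
                   abs(alt - n_use) <= abs(snapped - n_use))) {
            deficit <- max(deficit, n_floor - alt)
          }
        }
        if (!is.na(snapped)) {
          n_use <- snapped
        }
        if (n_use > 0) {
          dk <- max(0L, min(as.integer(round(r * n_use)), n_use))
          km <- km * (1 - dk / n_use)
        }
      }
      c_used <- n_run - n_use
      if (c_used > 0) {
        cens_times <- c(
          cens_times,
          sb[j] + seq_len(c_used) / (c_used + 1) * (sb[j + 1] - sb[j])
        )
      }
      budget <- budget - c_used
      d[j] <- dk
      n_run <- n_use - dk
    }
    c_last <- min(max(budget, 0L), n_run)
    if (c_last > 0) {
      cens_times <- c(
        cens_times,
        sb[nsteps + 1L] +
          seq_len(c_last) / (c_last + 1) * (t_end - sb[nsteps + 1L])
      )
      n_run <- n_run - c_last
    }
  } else {
    c_all <- min(n_cens, n_run)
    if (c_all > 0) {
      cens_times <- t_start + seq_len(c_all) / (c_all + 1) * (t_end - t_start)
    }
    n_run <- n_run - c_all
  }
  list(
    n_end = n_run, km_end = km, d = d, cens_times = cens_times,
    n_events = sum(d),
    deficit = if (exists("deficit", inherits = FALSE)) deficit else 0L
  )
}

# Adjust integer event counts after the censoring search: delta < 0
# means too few subjects remained at risk (drop events, latest steps
# first); delta > 0 means too many (add events to the last step seen).
rebalance_events <- function(res, delta) {
  if (delta < 0) {
    need <- -delta
    for (j in rev(seq_along(res$d))) {
      take <- min(res$d[j], need)
      res$d[j] <- res$d[j] - take
      need <- need - take
      if (need == 0) break
    }
    res$n_end <- res$n_end + (-delta - need)
  } else if (delta > 0 && length(res$d)) {
    res$d[length(res$d)] <- res$d[length(res$d)] + delta
    res$n_end <- res$n_end - delta
  }
  res$n_events <- sum(res$d)
  res
}

# Reconstruct one arm; errors if a risk-table constraint cannot be met.
reconstruct_arm <- function(arm, max_iter = 60L) {
  tt <- arm$curve$time
  ss <- arm$curve$survival
  tr <- arm$risk$time
  nr <- arm$risk$n_risk
  n_int <- length(tr)
  first_drop <- if (any(ss < 1)) tt[which(ss < 1)[1]] else Inf
  if (tr[1] > first_drop) {
    abort("the risk table must start before the curve's first drop.")
  }
  lower <- vapply(tr, function(x) {
    w <- which(tt >= x)
    if (length(w)) w[1] else length(tt) + 1L
  }, integer(1))
  upper <- c(lower[-1] - 1L, length(tt))
  event_times <- numeric(0)
  cens_times <- numeric(0)
  diag_rows <- list()
  km <- 1
  n_run <- nr[1]
  for (i in seq_len(n_int)) {
    t_start <- tr[i]
    t_end <- if (i < n_int) tr[i + 1] else tt[length(tt)]
    last <- i == n_int
    target <- if (!last) nr[i + 1] else NA
    n_cens <- 0L
    if (last && is.na(arm$total_events) && t_start > 0) {
      # no at-risk target and no event total to pin the tail down:
      # carry the censoring intensity observed so far into the final
      # interval (the uniform-censoring model is global), capped by
      # the subjects available
      rate <- length(cens_times) / t_start
      n_cens <- min(n_run, as.integer(round(rate * (t_end - t_start))))
    }
    res <- NULL
    adjusted <- 0L
    visited <- integer(0)
    for (iter in seq_len(max_iter)) {
      res <- run_interval(
        tt, ss, lower[i], upper[i], t_start, t_end, n_run, km, n_cens,
        free_cens = last && is.na(arm$total_events)
      )
      if (last) {
        if (is.na(arm$total_events)) break
        d_total <- length(event_times) + res$n_events
        delta <- d_total - arm$total_events
        if (delta == 0) break
        new_cens <- max(0L, min(n_run, n_cens + delta))
        if (new_cens == n_cens || new_cens %in% visited) break
        visited <- c(visited, n_cens)
        n_cens <- new_cens
      } else {
        delta <- res$n_end - target
        if (delta == 0) {
          if (res$deficit > 0) {
            # the endpoint matches but intermediate survival ratios
            # demanded more censorings than the budget allowed
            wider <- n_cens + res$deficit
            if (!(wider %in% visited) && wider <= n_run) {
              visited <- c(visited, n_cens)
              n_cens <- wider
              next
            }
          }
          break
        }
        new_cens <- max(0L, min(n_run, n_cens + delta))
        if (new_cens == n_cens || new_cens %in% visited) {
          # rounding left the interval off by a subject or two that
          # censoring alone cannot absorb: re-balance the integer
          # event counts (from the latest steps) to restore the hard
          # at-risk constraint
          res <- rebalance_events(res, delta)
          adjusted <- abs(delta)
          break
        }
        visited <- c(visited, n_cens)
        n_cens <- new_cens
      }
    }
    if (!last && res$n_end != target) {
      abort(paste0(
        "interval solver did not converge for interval ", i,
        " (target ", target, ", achieved ", res$n_end, ")."
      ))
    }
    if (length(res$d)) {
      event_times <- c(event_times, rep(tt[lower[i]:upper[i]], res$d))
    }
    cens_times <- c(cens_times, res$cens_times)
    diag_rows[[i]] <- tibble(
      interval = i, t_start = t_start, t_end = t_end,
      n_risk_start = n_run, n_risk_target = target,
      n_risk_end = res$n_end, events = res$n_events,
      censored = length(res$cens_times), events_adjusted = adjusted
    )
    n_run <- res$n_end
    km <- res$km_end
  }
  # subjects still at risk at the end of the digitized curve are
  # administratively censored there
  if (n_run > 0) {
    cens_times <- c(cens_times, rep(tt[length(tt)], n_run))
  }
  ipd <- tibble(
    time = c(event_times, cens_times),
    status = c(rep(1, length(event_times)), rep(0, length(cens_times)))
  )
  ipd <- ipd[ipd$time > 0, ]
  km_rec <- km_curve(ipd$time, ipd$status)
  deviation <- max(abs(eval_step(km_rec, tt) - ss))
  list(
    ipd = ipd,
    diagnostics = dplyr::bind_rows(diag_rows),
    km_deviation = deviation
  )
}

#' Reconstruct individual patient data from digitized KM curves
#'
#' Implements the iterative interval reconstruction: within each
#' number-at-risk interval the number of censorings (spread uniformly
#' over the interval, reflecting the usual non-informative censoring
#' assumption) and the integer event counts at each digitized step are
#' solved so that the reconstructed Kaplan-Meier curve reproduces the
#' digitized survival values and the at-risk count at every risk-table
#' time matches the input exactly.  If `total_events` is supplied for
#' an arm, censorings after the last risk-table time are adjusted to
#' match it; otherwise no censoring is assumed within the final
#' interval.  Subjects still at risk at the end of the curve are
#' censored there.
#'
#' @param arm1,arm2 [digitized_arm()] objects (`arm2` may be `NULL`
#'   for a single-arm reconstruction).
#' @param arm_labels Group labels for the output data.
#' @return A `km_reconstruction` object with elements `data` (tibble
#'   `time`, `status`, `group`), `diagnostics` (per-interval implied
#'   events and censorings) and `km_deviation` (per-arm maximum
#'   absolute deviation between the reconstructed and input curves).
#' @examples
#' \donttest{
#' sim <- simulate_sample(scenario_preset("crossing-1", 100), seed = 1)
#' dig <- digitize_sample(sim, risk_times = seq(0, 3, by = 0.75))
#' rec <- reconstruct_ipd(dig[[1]], dig[[2]])
#' rec$km_deviation
#' }
#' @export
reconstruct_ipd <- function(arm1, arm2 = NULL, arm_labels = c("1", "2")) {
  if (!inherits(arm1, "digitized_arm")) {
    abort("arm1 must be a digitized_arm object.")
  }
  r1 <- reconstruct_arm(arm1)
  r1$diagnostics$arm <- arm_labels[1]
  if (is.null(arm2)) {
    data <- tibble(
      time = r1$ipd$time, status = r1$ipd$status, group = arm_labels[1]
    )
    diagnostics <- r1$diagnostics
    deviation <- stats::setNames(r1$km_deviation, arm_labels[1])
  } else {
    if (!inherits(arm2, "digitized_arm")) {
      abort("arm2 must be a digitized_arm object.")
    }
    r2 <- reconstruct_arm(arm2)
    r2$diagnostics$arm <- arm_labels[2]
    data <- tibble(
      time = c(r1$ipd$time, r2$ipd$time),
      status = c(r1$ipd$status, r2$ipd$status),
      group = rep(arm_labels, c(nrow(r1$ipd), nrow(r2$ipd)))
    )
    diagnostics <- dplyr::bind_rows(r1$diagnostics, r2$diagnostics)
    deviation <- stats::setNames(
      c(r1$km_deviation, r2$km_deviation), arm_labels
    )
  }
  structure(
    list(data = data, diagnostics = diagnostics,
         km_deviation = deviation,
         input = list(arm1 = arm1, arm2 = arm2)),
    class = "km_reconstruction"
  )
}

#' @export
print.km_reconstruction <- function(x, ...) {
  cat("<km_reconstruction>", nrow(x$data), "subjects,",
      sum(x$data$status), "events\n")
  cat("max |KM deviation| per arm:",
      paste(format(signif(x$km_deviation, 3)), collapse = ", "), "\n")
  invisible(x)
}

#' Digitize a simulated sample (exact coordinates)
#'
#' Produces the exact Kaplan-Meier knots and a number-at-risk table
#' for each arm of an in-memory dataset — the idealised output of a
#' plot digitizer, useful for round-trip validation of
#' [reconstruct_ipd()].
#'
#' @inheritParams wlr_test
#' @param risk_times Times at which the at-risk table is read off;
#'   defaults to 7 evenly spaced times from 0 to just below the
#'   smaller arm maximum.
#' @param total_events Logical: attach the true per-arm event counts?
#' @return A list of two [digitized_arm()] objects.
#' @export
digitize_sample <- function(data, risk_times = NULL, total_events = FALSE) {
  s <- check_ipd(data)
  one <- function(gi) {
    time <- s$time[s$group == gi]
    status <- s$status[s$group == gi]
    km <- km_curve(time, status)
    curve <- tibble(
      time = c(0, km$knots, max(time)),
      survival = c(1, km$values, km$values[length(km$values)])
    )
    curve <- dplyr::distinct(curve)
    rt <- if (is.null(risk_times)) {
      seq(0, max(time) * 0.95, length.out = 7)
    } else {
      risk_times[risk_times <= max(time)]
    }
    at_risk <- vapply(rt, function(x) sum(time >= x), numeric(1))
    risk <- tibble(time = rt, n_risk = at_risk)
    risk <- risk[risk$n_risk > 0, ]
    digitized_arm(
      curve, risk,
      total_events = if (total_events) sum(status) else NA
    )
  }
  list(one(1L), one(2L))
}

#' Reconstruction quality report
#'
#' Side-by-side comparison of published summary statistics (median
#' survival per arm, hazard ratio with 95% CI) against the values
#' recomputed from the reconstructed data, with absolute and relative
#' deviations.  Missing published entries propagate as `NA` (rendered
#' as dashes when printed).
#'
#' @param recon A [reconstruct_ipd()] result with two arms.
#' @param published A list with optional entries `ms1`, `ms2` (median
#'   survival per arm), `hr`, `ci_low`, `ci_high`.
#' @return A tibble with columns `measure`, `published`,
#'   `reconstructed`, `abs_dev`, `rel_dev`.
#' @export
quality_report <- function(recon, published = list()) {
  if (!inherits(recon, "km_reconstruction")) {
    abort("recon must be a km_reconstruction.")
  }
  s <- check_ipd(recon$data)
  km1 <- km_curve(s$time[s$group == 1L], s$status[s$group == 1L])
  km2 <- km_curve(s$time[s$group == 2L], s$status[s$group == 2L])
  hr <- tryCatch(cox_hr(recon$data), error = function(e) {
    tibble(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  })
  grab <- function(nm) {
    v <- published[[nm]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  out <- tibble(
    measure = c("median_survival_1", "median_survival_2", "hr",
                "hr_ci_low", "hr_ci_high"),
    published = c(grab("ms1"), grab("ms2"), grab("hr"),
                  grab("ci_low"), grab("ci_high")),
    reconstructed = c(median_survival(km1), median_survival(km2),
                      hr$hr, hr$ci_low, hr$ci_high)
  )
  out$abs_dev <- abs(out$reconstructed - out$published)
  out$rel_dev <- out$abs_dev / abs(out$published)
  out
}
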