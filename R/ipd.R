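#' Standardise an individual-patient-data frame
#'
#' Renames user columns to the canonical `time`, `status`, `group`
#' layout used throughout the package and validates the result: times
#' strictly positive, status in \{0, 1\} (1 = event, 0 = censored), and
#' exactly two group labels, each with at least one subject.
#'
#' @param data A data frame of per-subject records.
#' @param time,status,group Columns holding the observed time, the event
#'   indicator and the arm label (tidy evaluation).
#' @return A tibble with columns `time`, `status`, `group`.
#' @examples
#' df <- data.frame(t = c(1, 2, 3), d = c(1, 0, 1), arm = c("A", "A", "B"))
#' as_ipd(df, time = t, status = d, group = arm)
#' @export
as_ipd <- function(data, time = time, status = status, group = group) {
  out <- tibble(
    time = as.numeric(dplyr::pull(data, {{ time }})),
    status = as.numeric(dplyr::pull(data, {{ status }})),
    group = dplyr::pull(data, {{ group }})
  )
  check_ipd(out)
  out
}

# Internal validator; returns the parsed sample as a plain list with
# integer group codes (1 = first level).  Group order: factor levels if
# the column is a factor, otherwise sort(unique(.)).
check_ipd <- function(data, require_two_groups = TRUE) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with columns time, status, group.")
  }
  missing_cols <- setdiff(c("time", "status", "group"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`data` is missing column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  time <- as.numeric(data$time)
  status <- as.numeric(data$status)
  if (anyNA(time) || anyNA(status) || anyNA(data$group)) {
    abort("time, status and group must not contain missing values.")
  }
  if (any(time <= 0)) {
    abort("all times must be strictly positive (zero event times are invalid).")
  }
  if (!all(status %in% c(0, 1))) {
    abort("status must be 0 (censored) or 1 (event).")
  }
  g <- data$group
  levels <- if (is.factor(g)) levels(droplevels(g)) else sort(unique(g))
  if (require_two_groups && length(levels) != 2) {
    abort(paste0(
      "exactly two group labels are required, found ",
      length(levels), "."
    ))
  }
  gi <- match(as.character(g), as.character(levels))
  # canonical subject order: statistics and seeded permutation streams
  # are then invariant to the row order of the input
  ord <- order(time, -status, gi)
  time <- time[ord]
  status <- status[ord]
  gi <- gi[ord]
  list(
    time = time,
    status = status,
    group = gi,
    levels = as.character(levels),
    n = length(time),
    n1 = sum(gi == 1L),
    n2 = sum(gi == 2L)
  )
}

#' Read individual patient data from delimited text
#'
#' Expects a header with columns `time`, `status`, `group`; the
#' delimiter (comma or tab) is auto-detected from the header line.
#'
#' @param file Path to the file.
#' @return A validated tibble with columns `time`, `status`, `group`.
#' @seealso [write_ipd()]
#' @export
read_ipd <- function(file) {
  header <- readLines(file, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  out <- readr::read_delim(
    file,
    delim = delim, show_col_types = FALSE, trim_ws = TRUE,
    col_types = readr::cols(
      # times come in as text and go through strtod so the written
      # 17-digit representation round-trips bit-for-bit
      time = readr::col_character(),
      status = readr::col_double(),
      group = readr::col_character(),
      .default = readr::col_guess()
    )
  )
  out$time <- as.numeric(out$time)
  check_ipd(out)
  tibble(time = out$time, status = out$status, group = out$group)
}

#' Write individual patient data as delimited text
#'
#' @param data A data frame with columns `time`, `status`, `group`.
#' @param file Output path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `data`, invisibly.
#' @export
write_ipd <- function(data, file, delim = ",") {
  check_ipd(data)
  out <- data.frame(
    # 17 significant digits: doubles survive the text round trip
    # bit-for-bit, so file-based and in-memory analyses agree exactly
    time = sprintf("%.17g", as.numeric(data$time)),
    status = as.numeric(data$status),
    group = data$group
  )
  readr::write_delim(out, file, delim = delim)
  invisible(data)
}

#' Truncation time rule for RMST comparisons
#'
#' Returns 90% of the smaller of the two arms' largest observed times
#' (event or censored) — the default horizon for restricted mean
#' survival time tests.
#'
#' @param data A two-arm data frame (`time`, `status`, `group`).
#' @return A single time.
#' @examples
#' df <- data.frame(
#'   time = c(2, 10, 4, 20), status = c(1, 0, 1, 1),
#'   group = c(1, 1, 2, 2)
#' )
#' tau_rule(df) # 0.9 * min(10, 20) = 9
#' @export
tau_rule <- function(data) {
  s <- check_ipd(data)
  0.9 * min(max(s$time[s$group == 1L]), max(s$time[s$group == 2L]))
}
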