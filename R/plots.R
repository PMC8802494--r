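# ggplot2 displays for the package's result types.

#' Kaplan-Meier curves of a two-arm dataset
#'
#' @inheritParams wlr_test
#' @return A ggplot object with one step per arm and censoring ticks.
#' @export
plot_km_curves <- function(data) {
  s <- check_ipd(data)
  per_arm <- purrr::map(1:2, function(gi) {
    km <- km_curve(s$time[s$group == gi], s$status[s$group == gi])
    tibble(
      time = c(0, km$knots, km$max_time),
      survival = c(1, km$values,
                   if (length(km$values)) km$values[length(km$values)] else 1),
      group = s$levels[gi]
    )
  })
  df <- dplyr::bind_rows(per_arm)
  cens <- tibble(
    time = s$time[s$status == 0],
    group = s$levels[s$group[s$status == 0]]
  )
  cens$survival <- purrr::map2_dbl(cens$time, cens$group, function(t, g) {
    gi <- match(g, s$levels)
    km <- km_curve(s$time[s$group == gi], s$status[s$group == gi])
    eval_step(km, t)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3, size = 1.5) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.battery_result <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    method = factor(.data$method, levels = rev(battery_codes()))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$p.value, .data$method)) +
    ggplot2::geom_vline(xintercept = alpha, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_segment(
      ggplot2::aes(x = 0, xend = .data$p.value, yend = .data$method),
      colour = "grey70", na.rm = TRUE
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        size = 2, na.rm = TRUE) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "p-value", y = NULL, colour = paste0("p <= ", alpha)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rejection_study <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    method = factor(.data$method, levels = battery_codes())
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$rate - 2 * .data$se),
                   ymax = pmin(1, .data$rate + 2 * .data$se)),
      width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "rejection rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.km_reconstruction <- function(object, ...) {
  s <- check_ipd(object$data, require_two_groups = FALSE)
  arms <- list(object$input$arm1, object$input$arm2)
  labels <- sort(unique(as.character(object$data$group)))
  rows <- list()
  for (i in seq_along(labels)) {
    gi <- i
    km <- km_curve(s$time[s$group == gi], s$status[s$group == gi])
    rows[[length(rows) + 1]] <- tibble(
      time = c(0, km$knots), survival = c(1, km$values),
      group = labels[i], source = "reconstructed"
    )
    if (!is.null(arms[[i]])) {
      rows[[length(rows) + 1]] <- tibble(
        time = arms[[i]]$curve$time,
        survival = arms[[i]]$curve$survival,
        group = labels[i], source = "digitized input"
      )
    }
  }
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group,
                                   linetype = .data$source)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

`%||%` <- function(x, y) if (is.null(x)) y else x
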