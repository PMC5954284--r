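#' Tidy and summarize mapping and evaluation objects
#'
#' Broom-style accessors: `tidy()` returns the per-candidate table of a
#' mapping run (one row per candidate location, with filter and
#' verification outcomes); `glance()` returns a one-row summary of the
#' filter's confusion metrics.
#'
#' @param x A `map_result` or `filter_evaluation` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.map_result <- function(x, ...) {
  x$candidates
}

#' @rdname tidiers
#' @export
glance.map_result <- function(x, ...) {
  glance(x$evaluation)
}

#' @rdname tidiers
#' @export
glance.filter_evaluation <- function(x, ...) {
  tibble::tibble(
    n_candidates = x$n_pass + x$n_reject,
    n_pass = x$n_pass,
    n_pass_and_map = x$n_pass_and_map,
    n_reject = x$n_reject,
    n_reject_but_map = x$n_reject_but_map,
    false_negative_rate = x$false_negative_rate,
    false_positive_count = x$false_positive_count,
    fn_rate_defined = x$fn_rate_defined
  )
}

#' @rdname tidiers
#' @export
tidy.filter_evaluation <- function(x, ...) {
  g <- glance.filter_evaluation(x)
  tibble::tibble(metric = names(g), value = as.numeric(g[1, ]))
}

#' Plot a parameter sweep
#'
#' Average read existence (log scale) against error tolerance, one line per
#' bin count, faceted by token size — the standard way to read a
#' sensitivity sweep.
#'
#' @param object A [parameter_sweep()] result.
#' @param metric Column to plot (default `average_read_existence`; e.g.
#'   `false_negative_rate`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, metric = "average_read_existence",
                                  ...) {
  stopifnot(metric %in% names(object))
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$e, y = .data[[metric]],
                 colour = factor(.data$num_bins),
                 group = factor(.data$num_bins))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~n, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "error tolerance e", y = metric,
                  colour = "bins") +
    ggplot2::theme_minimal()
}

#' Plot filter outcomes of a mapping run
#'
#' Stacked counts of candidate locations by filter decision and
#' verification outcome.
#'
#' @param object A [map_reads()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.map_result <- function(object, ...) {
  cand <- object$candidates
  df <- dplyr::count(
    cand,
    decision = ifelse(cand$pass == 1L, "pass", "reject"),
    outcome = ifelse(cand$mapped, "maps", "does not map")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$decision, y = .data$n,
                                   fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "filter decision", y = "candidate locations",
                  fill = "verification") +
    ggplot2::theme_minimal()
}
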