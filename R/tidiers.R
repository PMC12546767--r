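#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training log of a fitted shared-space model
#'
#' @param x A `ligspace_model`.
#' @param ... Unused.
#' @return Tibble with one row per training step (`step`, `loss`,
#'   `loss_ranking`, `loss_contrastive`).
#' @export
tidy.ligspace_model <- function(x, ...) {
  x$log
}

#' One-row summary of a fitted shared-space model
#'
#' @param x A `ligspace_model`.
#' @param ... Unused.
#' @return One-row tibble: embedding dimension, encoder family, steps, and
#'   initial/final losses.
#' @export
glance.ligspace_model <- function(x, ...) {
  tibble(d = x$params$d,
         encoder = if (is.null(x$params$hidden)) "linear" else
           sprintf("mlp(%d)", x$params$hidden),
         steps = nrow(x$log),
         loss_initial = x$log$loss[1],
         loss_final = x$log$loss[nrow(x$log)],
         loss_ranking_final = x$log$loss_ranking[nrow(x$log)],
         loss_contrastive_final = x$log$loss_contrastive[nrow(x$log)])
}

#' Tidy an active-learning campaign
#'
#' @param x An `al_state`.
#' @param ... Unused.
#' @return The per-iteration metric history.
#' @export
tidy.al_state <- function(x, ...) x$history

#' @rdname tidy.al_state
#' @export
glance.al_state <- function(x, ...) {
  tibble(strategy = x$strategy, iterations = max(x$history$iteration),
         n_labeled = nrow(x$labeled),
         final_recall = x$history$recall[nrow(x$history)],
         final_r_squared = x$history$r_squared[nrow(x$history)])
}

#' Plot the loss trajectory of a training run
#'
#' @param object A `ligspace_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ligspace_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, -"step",
                            names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training step", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the early-recognition curve of a screening ranking
#'
#' Cumulative fraction of actives recovered against the fraction of the
#' library screened, with the random diagonal for reference.
#'
#' @param object A `screen_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screen_ranking <- function(object, ...) {
  n <- sum(object$label)
  df <- tibble(frac_screened = object$rank / nrow(object),
               frac_found = cumsum(object$label) / max(1, n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frac_screened,
                                   y = .data$frac_found)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "fraction of library screened",
                  y = "fraction of actives found") +
    ggplot2::theme_minimal()
}

#' Plot an active-learning metric trajectory
#'
#' @param object An `al_state`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.al_state <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("recall", "r_squared"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot masking-based importance scores
#'
#' @param object An `importance_report`.
#' @param top_n Show the `top_n` units per side by absolute delta.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_report <- function(object, top_n = 15, ...) {
  df <- object |>
    filter(.data$side != "none") |>
    group_by(.data$side) |>
    arrange(dplyr::desc(abs(.data$delta)), .by_group = TRUE) |>
    dplyr::slice_head(n = top_n) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$unit, .data$delta),
                                   y = .data$delta)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~side, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "score drop when masked") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
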