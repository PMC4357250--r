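# ggplot2 displays for trial tables, comparison summaries, and recovery
# reports.

#' Deck choice proportions over blocks of trials
#'
#' Plots, for each deck, the proportion of choices falling on that deck
#' within consecutive blocks of trials, averaged over participants and
#' faceted by task. The conventional display for learning curves in these
#' tasks.
#'
#' @param trials A trial tibble (from [generate_cohort()]`$trials`,
#'   [read_trials()], or a single [simulate_agent()] result).
#' @param block_size Trials per aggregation block (default 20, matching the
#'   feedback schedule of the task procedure).
#' @return A ggplot object.
#' @export
plot_deck_choices <- function(trials, block_size = 20) {
  stop_not_df(trials, "trials")
  if (!"task" %in% names(trials)) {
    trials$task <- attr(trials, "task") %||% "task"
  }
  df <- trials |>
    dplyr::mutate(block = (.data$trial - 1) %/% block_size + 1) |>
    dplyr::count(.data$task, .data$block, .data$deck) |>
    dplyr::group_by(.data$task, .data$block) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$block, .data$prop,
                                   colour = .data$deck)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = sprintf("block of %d trials", block_size),
                  y = "choice proportion", colour = "deck") +
    ggplot2::ylim(0, 1)
}

#' @export
autoplot.deckrl_cohort <- function(object, block_size = 20, ...) {
  plot_deck_choices(object$trials, block_size = block_size)
}

#' Plot a BIC comparison summary
#'
#' Dot plot of mean BIC difference scores per model, faceted by task, with
#' zero (the baseline) marked.
#'
#' @param summary A tibble from [summarize_bic()].
#' @return A ggplot object.
#' @export
plot_bic_summary <- function(summary) {
  stop_not_df(summary, "summary")
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$mean_bic,
                               stats::reorder(.data$model, .data$mean_bic))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = "mean BIC difference vs baseline", y = NULL)
}

#' @export
autoplot.deckrl_recovery <- function(object, ...) {
  gen <- object$fits
  rec <- object$recovery
  ggplot2::ggplot(rec, ggplot2::aes(.data$parameter, .data$rho,
                                    fill = .data$task)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(y = "Spearman rho (generating vs recovered)",
                  x = NULL, fill = "task") +
    ggplot2::ylim(-1, 1)
}
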