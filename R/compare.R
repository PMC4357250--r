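# Model comparison: BIC-difference summaries, pairwise win counts, and the
# Spearman cross-task parameter-consistency test.

#' Summarize BIC difference scores per model and task
#'
#' Aggregates a fit table into the conventional comparison summary: mean,
#' median, sample standard deviation (n - 1 denominator; `NA` for a single
#' score), and the percentage of strictly positive BIC difference scores
#' (exact zeros do not count as outperforming the baseline).
#'
#' @param fits A fit tibble from [fit_cohort()] (needs columns `model`,
#'   `task`, `bic_diff`), or any data frame with those columns.
#' @param ... Optional additional grouping columns (unquoted), e.g. a group
#'   label column for subgroup summaries.
#' @return A tibble with columns `model`, `task`, any extra groups, `n`,
#'   `mean_bic`, `median_bic`, `sd_bic`, `pct_positive`.
#' @export
#' @examples
#' fits <- tibble::tibble(model = "PVL2", task = "IGT",
#'                        bic_diff = c(1, -1, 3))
#' summarize_bic(fits)
summarize_bic <- function(fits, ...) {
  stop_not_df(fits, "fits")
  if (nrow(fits) == 0) {
    abort("`fits` is empty", class = "deckrl_empty_group")
  }
  fits |>
    dplyr::group_by(.data$model, .data$task, ...) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean_bic = mean(.data$bic_diff),
      median_bic = median(.data$bic_diff),
      sd_bic = sd(.data$bic_diff),
      pct_positive = 100 * mean(.data$bic_diff > 0),
      .groups = "drop"
    )
}

#' Pairwise model comparison by participant-level BIC wins
#'
#' For two models fitted to the same participants, counts per task how many
#' participants had a strictly higher BIC difference score under each model,
#' and how many were exact ties.
#'
#' @param fits A fit tibble from [fit_cohort()] containing both models.
#' @param model_a,model_b Model strings as they appear in `fits$model`.
#' @return A tibble with columns `task`, `model_a`, `model_b`, `wins_a`,
#'   `wins_b`, `ties`, `n` (with `wins_a + wins_b + ties = n`).
#' @export
pairwise_wins <- function(fits, model_a, model_b) {
  stop_not_df(fits, "fits")
  fa <- fits[fits$model == model_a, c("participant_id", "task", "bic_diff")]
  fb <- fits[fits$model == model_b, c("participant_id", "task", "bic_diff")]
  if (nrow(fa) == 0 || nrow(fb) == 0) {
    abort("one of the requested models has no fits",
          class = "deckrl_alignment_error")
  }
  key_a <- paste(fa$participant_id, fa$task)
  key_b <- paste(fb$participant_id, fb$task)
  if (!setequal(key_a, key_b) || anyDuplicated(key_a) || anyDuplicated(key_b)) {
    abort("the two models were not fitted to the same participant-task set",
          class = "deckrl_alignment_error")
  }
  joined <- dplyr::inner_join(
    fa, fb, by = c("participant_id", "task"), suffix = c("_a", "_b")
  )
  joined |>
    dplyr::group_by(.data$task) |>
    dplyr::summarize(
      model_a = model_a,
      model_b = model_b,
      wins_a = sum(.data$bic_diff_a > .data$bic_diff_b),
      wins_b = sum(.data$bic_diff_b > .data$bic_diff_a),
      ties = sum(.data$bic_diff_a == .data$bic_diff_b),
      n = dplyr::n(),
      .groups = "drop"
    )
}

# All permutations of 1..n as an (n! x n) matrix; used by the exact
# permutation p-value (kept to small n).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation with a one-tailed test for positive association
#'
#' Computes Spearman's rho between two paired vectors using average ranks
#' for ties, with a one-tailed p-value for the alternative `rho > 0`. The
#' default p-value uses the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom;
#' `exact = TRUE` (available for `n <= 8`) enumerates all permutations of
#' one vector instead.
#'
#' @param x,y Paired numeric vectors of equal length `n >= 3` (e.g. the same
#'   parameter estimated from the IGT and the SGT per participant).
#' @param exact Use the exact permutation distribution (`n <= 8` only).
#' @return A one-row tibble: `rho`, `p_one_tailed`, `rho_squared`, `n`,
#'   `method`.
#' @export
#' @examples
#' spearman_consistency(c(1, 2, 3, 4), c(10, 20, 30, 40)) # rho = 1
spearman_consistency <- function(x, y, exact = FALSE) {
  keep <- stats::complete.cases(x, y)
  x <- as.double(x[keep])
  y <- as.double(y[keep])
  n <- length(x)
  if (length(y) != n) {
    abort("`x` and `y` must have equal length", class = "deckrl_bad_input")
  }
  if (n < 3) {
    abort("need at least 3 complete pairs (insufficient-n)",
          class = "deckrl_insufficient_n")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    abort("correlation undefined for a constant input vector",
          class = "deckrl_undefined_correlation")
  }
  rho <- stats::cor(rx, ry)

  if (exact) {
    if (n > 8) {
      abort("exact permutation test supported only for n <= 8",
            class = "deckrl_bad_input")
    }
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(rhos >= rho - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- pt(tstat, df = n - 2, lower.tail = FALSE)
    method <- "t approximation"
  }

  tibble::tibble(
    rho = rho, p_one_tailed = p, rho_squared = rho^2, n = n, method = method
  )
}

#' Cross-task parameter consistency from a fit table
#'
#' Convenience wrapper: for each parameter of a model fitted to the same
#' participants on two tasks, computes [spearman_consistency()] between the
#' per-participant estimates from the two tasks.
#'
#' @param fits A fit tibble from [fit_cohort()] restricted to one model and
#'   two tasks (wide parameter columns as from [params_wide()] are created
#'   if absent).
#' @param parameters Parameter names to test; defaults to the fitted model's
#'   parameters.
#' @param exact Passed to [spearman_consistency()].
#' @return A tibble with one row per parameter: `parameter`, `rho`,
#'   `p_one_tailed`, `rho_squared`, `n`, `method`.
#' @export
consistency_table <- function(fits, parameters = NULL, exact = FALSE) {
  stop_not_df(fits, "fits")
  if ("params" %in% names(fits)) fits <- params_wide(fits)
  mods <- unique(fits$model)
  if (length(mods) != 1) {
    abort("`fits` must contain exactly one model",
          class = "deckrl_bad_input")
  }
  tasks <- sort(unique(fits$task))
  if (length(tasks) != 2) {
    abort("`fits` must contain exactly two tasks",
          class = "deckrl_bad_input")
  }
  parameters <- parameters %||% parameter_bounds(mods)$parameter
  f1 <- fits[fits$task == tasks[1], ]
  f2 <- fits[fits$task == tasks[2], ]
  m <- match(f1$participant_id, f2$participant_id)
  purrr::map_dfr(parameters, function(pm) {
    dplyr::bind_cols(
      tibble::tibble(parameter = pm),
      spearman_consistency(f1[[pm]], f2[[pm]][m], exact = exact)
    )
  })
}

#' Render a BIC summary table as Markdown
#'
#' Formats the output of [summarize_bic()] with the conventional column
#' headers M, Mdn, SD, and %(BIC>0).
#'
#' @param summary A tibble from [summarize_bic()].
#' @param digits Digits for the numeric columns.
#' @return A character vector of Markdown lines.
#' @export
md_bic_table <- function(summary, digits = 2) {
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  header <- "| Model | Task | M | Mdn | SD | %(BIC>0) |"
  sep <- "|---|---|---|---|---|---|"
  rows <- sprintf(
    "| %s | %s | %s | %s | %s | %s |",
    summary$model, summary$task, fmt(summary$mean_bic),
    fmt(summary$median_bic), fmt(summary$sd_bic),
    formatC(summary$pct_positive, digits = 0, format = "f")
  )
  c(header, sep, rows)
}
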