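# Delimited-file interface: trial tables in, fit tables out, with strict
# validation and lossless round trips.

TRIAL_COLUMNS <- c("participant_id", "task", "trial", "deck", "gain", "loss")

#' Validate a trial table
#'
#' Checks a long trial table for the structural invariants the fitting
#' pipeline assumes: required columns, known task and deck labels, finite
#' nonnegative amounts, consecutive 1-based trial indices per
#' `(participant_id, task)`, and no duplicate trials. Negative loss values
#' (the sign convention some sources print) are normalized to magnitudes; a
#' warning is raised if positive and negative losses are mixed.
#'
#' @param trials A data frame with columns `participant_id`, `task`,
#'   `trial`, `deck`, `gain`, `loss`.
#' @return The validated (and loss-normalized) tibble.
#' @export
validate_trials <- function(trials) {
  stop_not_df(trials, "trials")
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss) > 0) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
          class = "deckrl_parse_error")
  }
  trials <- tibble::as_tibble(trials)

  bad_task <- which(!trials$task %in% TASKS)
  if (length(bad_task) > 0) {
    abort(paste0("unknown task at row(s) ",
                 paste(head(bad_task, 5), collapse = ", "),
                 ": must be IGT or SGT"),
          class = "deckrl_parse_error")
  }
  bad_deck <- which(!as.character(trials$deck) %in% DECKS)
  if (length(bad_deck) > 0) {
    abort(paste0("unknown deck at row(s) ",
                 paste(head(bad_deck, 5), collapse = ", "),
                 ": must be A, B, C, or D"),
          class = "deckrl_parse_error")
  }
  if (any(!is.finite(trials$gain)) || any(trials$gain < 0)) {
    abort("`gain` must be finite and nonnegative",
          class = "deckrl_parse_error")
  }
  if (any(!is.finite(trials$loss))) {
    abort("`loss` must be finite", class = "deckrl_parse_error")
  }
  if (any(trials$loss < 0)) {
    if (any(trials$loss > 0)) {
      warn("`loss` mixes positive and negative values; taking magnitudes")
    }
    trials$loss <- abs(trials$loss)
  }

  split_idx <- split(seq_len(nrow(trials)),
                     paste(trials$participant_id, trials$task))
  for (idx in split_idx) {
    tr <- sort(trials$trial[idx])
    if (anyDuplicated(tr)) {
      abort(paste0("duplicate trial indices near row ", idx[1],
                   " (", trials$participant_id[idx[1]], ", ",
                   trials$task[idx[1]], ")"),
            class = "deckrl_parse_error")
    }
    if (!identical(as.integer(tr), seq_len(length(tr)))) {
      abort(paste0("trials not consecutive from 1 near row ", idx[1],
                   " (", trials$participant_id[idx[1]], ", ",
                   trials$task[idx[1]], ")"),
            class = "deckrl_parse_error")
    }
  }
  trials
}

#' Read a trial table from a CSV file
#'
#' Expects a comma-separated UTF-8 file with header columns
#' `participant_id`, `task`, `trial`, `deck`, `gain`, `loss` (1-based trial
#' indices; loss accepted as negative or positive and normalized to
#' magnitude). The table is validated with [validate_trials()].
#'
#' @param path Path to the CSV file.
#' @return A validated trial tibble.
#' @export
read_trials <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      task = readr::col_character(),
      trial = readr::col_integer(),
      deck = readr::col_character(),
      gain = readr::col_double(),
      loss = readr::col_double()
    )
  )
  validate_trials(df)
}

#' Write a trial table to CSV
#'
#' @param trials A validated trial tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(validate_trials(trials)[TRIAL_COLUMNS], path)
  invisible(path)
}

#' Write a fit table to CSV
#'
#' Spreads the `params` list-column into one column per parameter and writes
#' a deterministic column order (identifiers, model, parameters, fit
#' statistics). The file round-trips through [read_fits()].
#'
#' @param fits A fit tibble from [fit_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  stop_not_df(fits, "fits")
  if (nrow(fits) == 0) {
    warn("writing an empty fit table (header only)")
  }
  wide <- params_wide(fits)
  lead <- intersect(c("participant_id", "task", "model"), names(wide))
  stats_cols <- intersect(
    c("loglik", "baseline_loglik", "bic_diff", "n_predicted", "converged"),
    names(wide)
  )
  par_cols <- setdiff(names(wide), c(lead, stats_cols))
  readr::write_csv(wide[c(lead, par_cols, stats_cols)], path)
  invisible(path)
}

#' Read a fit table written by [write_fits()]
#'
#' Rebuilds the `params` list-column from the parameter columns of each
#' row's model, so that `read_fits(write_fits(fits))` equals `fits` field by
#' field.
#'
#' @param path Path to the CSV file.
#' @return A fit tibble with a `params` list-column.
#' @export
read_fits <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  params <- purrr::map(seq_len(nrow(wide)), function(i) {
    pn <- parameter_bounds(as_model_spec(wide$model[i]))$parameter
    setNames(as.double(unlist(wide[i, pn])), pn)
  })
  stats_cols <- intersect(
    c("participant_id", "task", "model", "loglik", "baseline_loglik",
      "bic_diff", "n_predicted", "converged"),
    names(wide)
  )
  out <- wide[stats_cols]
  out$params <- params
  if ("n_predicted" %in% names(out)) {
    out$n_predicted <- as.integer(out$n_predicted)
  }
  out
}

#' Write a BIC summary table to CSV
#'
#' @param summary A tibble from [summarize_bic()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bic_summary <- function(summary, path) {
  stop_not_df(summary, "summary")
  if (nrow(summary) == 0) warn("writing an empty summary (header only)")
  readr::write_csv(summary, path)
  invisible(path)
}

#' Export a synthetic cohort to trial and parameter CSV files
#'
#' Writes the cohort's trials in the format [read_trials()] reads, and the
#' generating-parameter table alongside.
#'
#' @param cohort A [generate_cohort()] result.
#' @param trials_path,params_path Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_cohort <- function(cohort, trials_path, params_path) {
  if (!inherits(cohort, "deckrl_cohort")) {
    abort("`cohort` must come from generate_cohort()",
          class = "deckrl_bad_input")
  }
  write_trials(cohort$trials, trials_path)
  readr::write_csv(cohort$params, params_path)
  invisible(c(trials_path, params_path))
}
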