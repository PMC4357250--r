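# One-step-ahead likelihood of an observed choice sequence under a model.

# Pull validated (choice index, gain, loss) vectors out of a trials table.
sequence_arrays <- function(trials) {
  stop_not_df(trials, "trials")
  need <- c("deck", "gain", "loss")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    abort(paste0("`trials` is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "deckrl_bad_input")
  }
  ch <- deck_index(trials$deck)
  gain <- as.double(trials$gain)
  loss <- as.double(trials$loss)
  if (any(!is.finite(gain)) || any(!is.finite(loss)) ||
      any(gain < 0) || any(loss < 0)) {
    abort("`gain` and `loss` must be finite and nonnegative magnitudes",
          class = "deckrl_bad_input")
  }
  list(choice = ch, gain = gain, loss = loss)
}

model_codes <- function(spec) {
  c(
    utility = match(spec$utility, UTILITIES) - 1L,
    updating = match(spec$updating, UPDATINGS) - 1L,
    choice = match(spec$choice, CHOICES) - 1L
  )
}

# Order a user-supplied parameter vector canonically and check bounds.
canonical_params <- function(spec, params, tol = 1e-8) {
  b <- parameter_bounds(spec)
  if (!is.null(names(params)) && all(nzchar(names(params)))) {
    miss <- setdiff(b$parameter, names(params))
    if (length(miss) > 0) {
      abort(paste0("missing parameter(s) for ", format(spec), ": ",
                   paste(miss, collapse = ", ")),
            class = "deckrl_bad_input")
    }
    params <- params[b$parameter]
  } else if (length(params) != nrow(b)) {
    abort(sprintf("model %s takes %d parameters (%s), got %d",
                  format(spec), nrow(b), paste(b$parameter, collapse = ", "),
                  length(params)),
          class = "deckrl_bad_input")
  }
  params <- as.double(params)
  out_of_bounds <- !is.finite(params) |
    params < b$lower - tol | params > b$upper + tol
  if (any(out_of_bounds)) {
    abort(paste0("parameter(s) out of bounds for ", format(spec), ": ",
                 paste(b$parameter[out_of_bounds], collapse = ", ")),
          class = "deckrl_out_of_bounds")
  }
  setNames(pmin(pmax(params, b$lower), b$upper), b$parameter)
}

#' One-step-ahead log-likelihood of a choice sequence
#'
#' Runs a model's recursion forward over an observed sequence: expectancies
#' start at zero; for each trial `t = 1..T-1` the utility of the observed
#' outcome of the observed choice updates the expectancies, and the log of
#' the predicted softmax probability of the deck actually chosen on trial
#' `t + 1` is accumulated. The choice on trial 1 contributes no likelihood
#' term, so a length-`T` sequence yields `T - 1` predicted trials.
#'
#' @param trials A data frame with columns `deck`, `gain`, `loss` in trial
#'   order (one participant, one task).
#' @param model A model designator accepted by [as_model_spec()].
#' @param params Parameter vector (named, or unnamed in canonical order);
#'   must lie within [parameter_bounds()].
#' @param tdc_index For trial-dependent sensitivity, whether `theta` for the
#'   prediction of trial `t + 1` is evaluated at the predicted trial's index
#'   `t + 1` (`"predicted"`, the default) or at the current trial's index `t`
#'   (`"current"`).
#' @return The summed log-likelihood (`<= 0`).
#' @export
#' @examples
#' seq <- simulate_agent("PVL2", c(alpha = 0.5, gamma = 1, A = 0.5, c = 1),
#'                       task = "IGT", n_trials = 30, seed = 1)
#' one_step_ahead_loglik(seq, "PVL2", c(alpha = 0.5, gamma = 1, A = 0.5, c = 1))
one_step_ahead_loglik <- function(trials, model, params,
                                  tdc_index = c("predicted", "current")) {
  tdc_index <- match.arg(tdc_index)
  spec <- as_model_spec(model)
  arr <- sequence_arrays(trials)
  if (length(arr$choice) < 2) {
    abort("sequence must contain at least 2 trials",
          class = "deckrl_bad_input")
  }
  p <- canonical_params(spec, params)
  codes <- model_codes(spec)
  cpp_osa_loglik(arr$choice, arr$gain, arr$loss,
                 codes[["utility"]], codes[["updating"]], codes[["choice"]],
                 unname(p), as.integer(tdc_index == "predicted"))
}
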