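# Maximum-likelihood fitting: multi-start search per (sequence, model),
# baseline statistical model, and BIC-difference scores.

#' Fitting configuration
#'
#' @param n_starts Number of quasi-random (Latin hypercube) starting points
#'   spread over the bounded parameter box. Default 50.
#' @param n_refine How many of the best starting points are refined with
#'   Nelder-Mead simplex search. Default 5.
#' @param reltol Relative function tolerance for the simplex. Default 1e-8.
#' @param maxit Maximum simplex iterations per start; default `500 * k` for a
#'   `k`-parameter model (set `NULL` for that default).
#' @param seed Integer seed for the start-point design, making fits
#'   deterministic.
#' @return A list of class `deckrl_fit_config`.
#' @export
fit_config <- function(n_starts = 50, n_refine = 5, reltol = 1e-8,
                       maxit = NULL, seed = 1L) {
  if (n_starts < 1) abort("`n_starts` must be >= 1", class = "deckrl_bad_input")
  structure(
    list(n_starts = as.integer(n_starts),
         n_refine = as.integer(max(1, min(n_refine, n_starts))),
         reltol = reltol, maxit = maxit, seed = as.integer(seed)),
    class = "deckrl_fit_config"
  )
}

# Smooth monotone map between the bounded box and the real line, so the
# simplex search is unconstrained while equation-level code stays branch-free.
to_unbounded <- function(p, lower, upper) {
  qlogis(pmin(pmax((p - lower) / (upper - lower), 1e-12), 1 - 1e-12))
}
to_bounded <- function(z, lower, upper) {
  lower + (upper - lower) * plogis(z)
}

#' Fit one model to one choice sequence by maximum likelihood
#'
#' Maximizes the one-step-ahead log-likelihood over the model's bounded
#' parameter box using a seeded Latin-hypercube design of starting points
#' followed by Nelder-Mead simplex refinement of the best starts (bounds are
#' enforced by a smooth logistic reparameterization). The returned
#' log-likelihood is never below the best start-point log-likelihood. The
#' result also carries the baseline fit and the BIC difference score.
#'
#' @inheritParams one_step_ahead_loglik
#' @param config A [fit_config()].
#' @param n_convention Number of data points `n` entering the BIC penalty:
#'   `"predicted"` (default) uses the `T - 1` predicted trials that the
#'   likelihood actually covers; `"all"` uses `T`.
#' @return An object of class `deckrl_fit` with elements `model`, `params`
#'   (named vector), `loglik`, `baseline_loglik`, `bic_diff`, `n_predicted`,
#'   `converged`, `n_starts_used`. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' seq <- simulate_agent("PVL2", c(alpha = 0.4, gamma = 1, A = 0.6, c = 1.5),
#'                       task = "IGT", n_trials = 60, seed = 2)
#' fit <- fit_model(seq, "PVL2", fit_config(n_starts = 10))
#' glance(fit)
fit_model <- function(trials, model, config = fit_config(),
                      tdc_index = c("predicted", "current"),
                      n_convention = c("predicted", "all")) {
  tdc_index <- match.arg(tdc_index)
  n_convention <- match.arg(n_convention)
  spec <- as_model_spec(model)
  arr <- sequence_arrays(trials)
  T_n <- length(arr$choice)
  if (T_n < 2) abort("sequence must contain at least 2 trials",
                     class = "deckrl_bad_input")

  b <- parameter_bounds(spec)
  k <- nrow(b)
  codes <- model_codes(spec)
  tdc_flag <- as.integer(tdc_index == "predicted")

  negll <- function(z) {
    -cpp_osa_loglik(arr$choice, arr$gain, arr$loss,
                    codes[["utility"]], codes[["updating"]],
                    codes[["choice"]], to_bounded(z, b$lower, b$upper),
                    tdc_flag)
  }

  design <- with_local_seed(config$seed, lhs::randomLHS(config$n_starts, k))
  starts <- sweep(sweep(design, 2, b$upper - b$lower, `*`), 2, b$lower, `+`)

  start_vals <- vapply(seq_len(config$n_starts), function(i) {
    v <- tryCatch(negll(to_unbounded(starts[i, ], b$lower, b$upper)),
                  error = function(e) Inf)
    v
  }, numeric(1))
  if (all(!is.finite(start_vals))) {
    abort("likelihood non-finite at every starting point",
          class = "deckrl_fit_failure")
  }

  ord <- order(start_vals)
  maxit <- if (is.null(config$maxit)) 500L * k else config$maxit
  best_val <- start_vals[ord[1]]
  best_par <- starts[ord[1], ]
  converged <- FALSE
  for (i in head(ord, config$n_refine)) {
    if (!is.finite(start_vals[i])) next
    res <- tryCatch(
      optim(to_unbounded(starts[i, ], b$lower, b$upper), negll,
            method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = config$reltol)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$value <= best_val) {
      best_val <- res$value
      best_par <- to_bounded(res$par, b$lower, b$upper)
      converged <- res$convergence == 0
    }
  }

  baseline <- fit_baseline(trials)
  n_points <- if (n_convention == "predicted") T_n - 1L else T_n
  bic <- bic_difference(-best_val, baseline$loglik,
                        k_extra = k - 3L, n_points = n_points)

  structure(
    list(
      model = spec,
      params = setNames(as.double(best_par), b$parameter),
      loglik = -best_val,
      baseline_loglik = baseline$loglik,
      bic_diff = bic,
      n_predicted = T_n - 1L,
      n_points = n_points,
      converged = converged,
      n_starts_used = config$n_starts,
      tdc_index = tdc_index
    ),
    class = "deckrl_fit"
  )
}

#' Fit the constant-probability baseline model
#'
#' The statistical baseline assumes independent choices with constant deck
#' probabilities across trials (3 free parameters; the fourth probability is
#' one minus the sum of the others). Its maximum likelihood has a closed
#' form: the empirical choice proportions over the predicted trials
#' `t = 2..T`, with log-likelihood `sum(n_j * log(n_j / (T - 1)))`
#' (zero-count decks contribute nothing). Fitting the baseline on the same
#' predicted trials as the cognitive models makes the two likelihoods
#' condition on identical data.
#'
#' @inheritParams one_step_ahead_loglik
#' @return A list of class `deckrl_baseline` with `probs` (named 4-vector),
#'   `loglik`, and `n_predicted`.
#' @export
#' @examples
#' seq <- simulate_agent("PVL2", c(alpha = 0.4, gamma = 1, A = 0.6, c = 1.5),
#'                       task = "SGT", n_trials = 40, seed = 3)
#' fit_baseline(seq)
fit_baseline <- function(trials) {
  arr <- sequence_arrays(trials)
  T_n <- length(arr$choice)
  if (T_n < 2) abort("sequence must contain at least 2 trials",
                     class = "deckrl_bad_input")
  counts <- tabulate(arr$choice[-1], nbins = 4)
  n <- T_n - 1L
  probs <- counts / n
  loglik <- sum(ifelse(counts > 0, counts * log(probs), 0))
  structure(
    list(probs = setNames(probs, DECKS), loglik = loglik, n_predicted = n),
    class = "deckrl_baseline"
  )
}

#' BIC difference score against the baseline model
#'
#' `2 * (loglik_model - loglik_baseline) - k_extra * log(n_points)`, where
#' `k_extra` is the model's parameter count minus the baseline's 3. Positive
#' scores mean the cognitive model outperforms the constant-probability
#' baseline, and the higher the better.
#'
#' @param loglik_model Maximized model log-likelihood.
#' @param loglik_baseline Maximized baseline log-likelihood.
#' @param k_extra Extra parameters relative to the baseline.
#' @param n_points Number of data points used in fitting.
#' @return The BIC difference score.
#' @export
#' @examples
#' bic_difference(-150, -160, k_extra = 1, n_points = 119) # ~15.22
bic_difference <- function(loglik_model, loglik_baseline, k_extra, n_points) {
  if (n_points < 1) abort("`n_points` must be >= 1", class = "deckrl_bad_input")
  2 * (loglik_model - loglik_baseline) - k_extra * log(n_points)
}

#' @export
print.deckrl_fit <- function(x, ...) {
  cat("<deckrl_fit>", format(x$model), "\n")
  cat("  loglik:", format(x$loglik, digits = 6),
      " BIC diff vs baseline:", format(x$bic_diff, digits = 5), "\n")
  cat("  params:",
      paste(names(x$params), format(x$params, digits = 3),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_model
#' @param x A `deckrl_fit`.
#' @param ... Unused.
#' @export
tidy.deckrl_fit <- function(x, ...) {
  b <- parameter_bounds(x$model)
  tibble::tibble(
    parameter = names(x$params),
    estimate = unname(x$params),
    lower = b$lower,
    upper = b$upper
  )
}

#' @rdname fit_model
#' @export
glance.deckrl_fit <- function(x, ...) {
  tibble::tibble(
    model = format(x$model),
    loglik = x$loglik,
    baseline_loglik = x$baseline_loglik,
    bic_diff = x$bic_diff,
    n_predicted = x$n_predicted,
    converged = x$converged,
    n_starts = x$n_starts_used
  )
}

#' Fit models to every participant-task sequence in a trial table
#'
#' Maps [fit_model()] over each `(participant_id, task)` group of a long
#' trial table and each requested model, returning one tidy row per fit.
#'
#' @param trials A trial table with columns `participant_id`, `task`,
#'   `trial`, `deck`, `gain`, `loss` (as produced by [generate_cohort()] or
#'   [read_trials()]).
#' @param models Character vector of model designators, or `"all18"` for the
#'   whole factorial space.
#' @param config A [fit_config()].
#' @inheritParams fit_model
#' @return A tibble with columns `participant_id`, `task`, `model`,
#'   `loglik`, `baseline_loglik`, `bic_diff`, `n_predicted`, `converged`,
#'   and a list-column `params` of named parameter vectors (use
#'   [params_wide()] to spread them into columns).
#' @export
fit_cohort <- function(trials, models = "PVL2", config = fit_config(),
                       tdc_index = "predicted",
                       n_convention = "predicted") {
  stop_not_df(trials, "trials")
  if (identical(models, "all18")) models <- model_space()$model
  if (!"participant_id" %in% names(trials)) trials$participant_id <- "p1"
  if (!"task" %in% names(trials)) {
    abort("`trials` must have a `task` column", class = "deckrl_bad_input")
  }

  groups <- trials |>
    dplyr::arrange(.data$participant_id, .data$task, .data$trial) |>
    dplyr::group_by(.data$participant_id, .data$task) |>
    dplyr::group_split()

  purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(models, function(m) {
      fit <- fit_model(g, m, config = config, tdc_index = tdc_index,
                       n_convention = n_convention)
      tibble::tibble(
        participant_id = g$participant_id[1],
        task = g$task[1],
        model = format(fit$model),
        loglik = fit$loglik,
        baseline_loglik = fit$baseline_loglik,
        bic_diff = fit$bic_diff,
        n_predicted = fit$n_predicted,
        converged = fit$converged,
        params = list(fit$params)
      )
    })
  })
}

#' Spread the `params` list-column of a fit table into parameter columns
#'
#' @param fits A tibble from [fit_cohort()].
#' @return The same tibble with one numeric column per parameter name in
#'   place of the `params` list-column.
#' @export
params_wide <- function(fits) {
  stop_not_df(fits, "fits")
  if (!"params" %in% names(fits)) return(fits)
  tidyr::unnest_wider(fits, "params")
}
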