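# Synthetic agents: generative simulation of any of the 18 models on the
# exact task schedules, cohort generation, and parameter-recovery harness.

#' Simulate one agent playing a task
#'
#' Runs a model generatively: expectancies start at zero, the first trial is
#' sampled from uniform deck probabilities, and each later trial is sampled
#' from the softmax of the current expectancies (with the trial's own index
#' for trial-dependent sensitivity). Outcomes are dealt by a [deck_dealer()]
#' on the task's printed schedule with within-block randomization. The whole
#' session is reproducible from `seed` and does not disturb the caller's RNG
#' state.
#'
#' @param model A model designator accepted by [as_model_spec()].
#' @param params Parameter vector for the model (named, or unnamed in
#'   canonical order).
#' @param task `"IGT"` or `"SGT"`, or a schedule tibble.
#' @param n_trials Session length; the study design uses 120.
#' @param seed Integer seed controlling both dealing and choice sampling.
#' @return A tibble with columns `trial`, `deck`, `gain`, `loss`, `balance`
#'   (running balance from a $20.00 start, bookkeeping only), with
#'   attributes `task`, `model`, `params`, `seed`.
#' @export
#' @examples
#' simulate_agent("PVL2", c(alpha = 0.5, gamma = 1, A = 0.7, c = 1.5),
#'                task = "IGT", n_trials = 20, seed = 1)
simulate_agent <- function(model, params, task = "IGT", n_trials = 120,
                           seed = 1L) {
  spec <- as_model_spec(model)
  p <- canonical_params(spec, params)
  schedule <- task_schedule(task)
  task_id <- unique(schedule$task)
  dealer <- deck_dealer(schedule, seed = derive_seed(seed, 1L))

  decks <- integer(n_trials)
  gains <- numeric(n_trials)
  losses <- numeric(n_trials)
  E <- rep(0, 4)

  with_local_seed(derive_seed(seed, 2L), {
    for (t in seq_len(n_trials)) {
      theta <- sensitivity_value(spec, t, p)
      pr <- choice_probabilities(E, theta)
      j <- sample.int(4L, 1L, prob = pr)
      out <- draw_outcome(dealer, DECKS[j])
      u <- utility_value(spec, out[["win"]], out[["loss"]], p)
      E <- expectancy_update(spec, E, DECKS[j], u, p)
      decks[t] <- j
      gains[t] <- out[["win"]]
      losses[t] <- out[["loss"]]
    }
  })

  out <- tibble::tibble(
    trial = seq_len(n_trials),
    deck = DECKS[decks],
    gain = gains,
    loss = losses,
    balance = 20 + cumsum(gains - losses)
  )
  attr(out, "task") <- task_id
  attr(out, "model") <- format(spec)
  attr(out, "params") <- p
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Default parameter sampler for synthetic cohorts
#'
#' Samples each parameter independently and uniformly within its bounds,
#' except the consistency parameter `c`, which is drawn from `[0.5, 3]` so
#' that agents are neither purely random (`c` near 0) nor effectively
#' deterministic (large `c`) — both extremes make recovery degenerate.
#'
#' @param n Number of agents.
#' @param bounds A bounds tibble from [parameter_bounds()].
#' @return A tibble of `n` rows, one column per parameter.
#' @export
uniform_param_sampler <- function(n, bounds) {
  draws <- purrr::pmap(bounds, function(parameter, lower, upper) {
    if (parameter == "c") runif(n, 0.5, 3) else runif(n, lower, upper)
  })
  names(draws) <- bounds$parameter
  tibble::as_tibble(draws)
}

#' Generate a synthetic cohort playing both tasks
#'
#' Samples one parameter vector per agent and simulates each agent on both
#' the IGT and the SGT with the same parameters — the cross-task consistency
#' assumption that model parameters measure stable characteristics of the
#' same individual. Per-agent, per-task seeds are derived from `master_seed`
#' by a fixed splitting scheme, so cohorts are exactly reproducible and the
#' two tasks' randomness is independent.
#'
#' @param n_agents Number of agents.
#' @param model Generating model designator.
#' @param n_trials Trials per task per agent (default 120, the study design).
#' @param master_seed Integer master seed.
#' @param param_sampler Function `(n, bounds) -> tibble` drawing generating
#'   parameters; defaults to [uniform_param_sampler()].
#' @param tasks Character vector of tasks to simulate.
#' @return An object of class `deckrl_cohort`: a list with `params` (tibble
#'   of generating parameters, one row per agent) and `trials` (long tibble
#'   with `participant_id`, `task`, `trial`, `deck`, `gain`, `loss`).
#' @export
#' @examples
#' cohort <- generate_cohort(3, "PVL2", n_trials = 30, master_seed = 7)
#' cohort$params
generate_cohort <- function(n_agents, model = "PVL2", n_trials = 120,
                            master_seed = 1L, param_sampler = NULL,
                            tasks = c("IGT", "SGT")) {
  if (n_agents < 1) abort("`n_agents` must be >= 1", class = "deckrl_bad_input")
  spec <- as_model_spec(model)
  bounds <- parameter_bounds(spec)
  sampler <- param_sampler %||% uniform_param_sampler
  params <- with_local_seed(derive_seed(master_seed, 0L),
                            sampler(n_agents, bounds))
  ids <- sprintf("agent%03d", seq_len(n_agents))
  params <- dplyr::bind_cols(tibble::tibble(participant_id = ids), params)

  trials <- purrr::map_dfr(seq_len(n_agents), function(i) {
    pv <- setNames(as.double(unlist(params[i, bounds$parameter])),
                   bounds$parameter)
    purrr::map_dfr(seq_along(tasks), function(k) {
      seq_i <- simulate_agent(
        spec, pv, task = tasks[k], n_trials = n_trials,
        seed = derive_seed(master_seed, i * 16L + k)
      )
      tibble::tibble(
        participant_id = ids[i],
        task = attr(seq_i, "task"),
        trial = seq_i$trial,
        deck = seq_i$deck,
        gain = seq_i$gain,
        loss = seq_i$loss
      )
    })
  })

  structure(
    list(model = format(spec), params = params, trials = trials,
         n_trials = n_trials, master_seed = as.integer(master_seed)),
    class = "deckrl_cohort"
  )
}

#' @export
print.deckrl_cohort <- function(x, ...) {
  cat("<deckrl_cohort>", nrow(x$params), "agents,", x$model,
      "generative model,", x$n_trials, "trials/task\n")
  cat("  tasks:", paste(unique(x$trials$task), collapse = ", "),
      " master seed:", x$master_seed, "\n")
  invisible(x)
}

#' Parameter-recovery and cross-task consistency experiment
#'
#' Fits a model to every sequence of a synthetic cohort and reports, per
#' task and parameter, the Spearman rank correlation between generating and
#' recovered values, plus the cross-task rank correlation of the recovered
#' values per parameter (the sign pattern the consistency analysis expects
#' to be positive throughout when one mechanism governs both tasks).
#'
#' @param cohort A [generate_cohort()] result.
#' @param model Model to fit; defaults to the cohort's generating model
#'   (self-recovery).
#' @param config A [fit_config()]; recovery runs typically use a reduced
#'   start budget.
#' @return An object of class `deckrl_recovery`: list with `fits` (wide fit
#'   table), `recovery` (tibble `task`, `parameter`, `rho`, `p_one_tailed`,
#'   `rho_squared`, `n`), and `cross_task` (same columns minus `task`).
#'   Correlations with fewer than 3 agents are reported as `NA` with a note.
#' @export
recovery_experiment <- function(cohort, model = NULL,
                                config = fit_config(n_starts = 15)) {
  if (!inherits(cohort, "deckrl_cohort")) {
    abort("`cohort` must come from generate_cohort()",
          class = "deckrl_bad_input")
  }
  spec <- as_model_spec(model %||% cohort$model)
  bounds <- parameter_bounds(spec)
  fits <- params_wide(fit_cohort(cohort$trials, models = format(spec),
                                 config = config))

  gen <- cohort$params
  shared <- intersect(bounds$parameter, names(gen))
  tasks <- unique(fits$task)

  safe_row <- function(x, y, parameter, extra = list()) {
    n <- sum(stats::complete.cases(x, y))
    res <- tryCatch(
      spearman_consistency(x, y),
      error = function(e) tibble::tibble(
        rho = NA_real_, p_one_tailed = NA_real_, rho_squared = NA_real_,
        n = n, method = NA_character_,
        note = conditionMessage(e)
      )
    )
    if (!"note" %in% names(res)) res$note <- NA_character_
    row <- dplyr::bind_cols(tibble::tibble(parameter = parameter), res)
    if (length(extra) > 0) {
      row <- dplyr::bind_cols(tibble::as_tibble(extra), row)
    }
    row
  }

  recovery <- purrr::map_dfr(tasks, function(tk) {
    ft <- fits[fits$task == tk, ]
    m <- match(ft$participant_id, gen$participant_id)
    purrr::map_dfr(shared, function(pm) {
      safe_row(gen[[pm]][m], ft[[pm]], pm, list(task = tk))
    })
  })

  cross_task <- if (length(tasks) >= 2) {
    f1 <- fits[fits$task == tasks[1], ]
    f2 <- fits[fits$task == tasks[2], ]
    m <- match(f1$participant_id, f2$participant_id)
    purrr::map_dfr(bounds$parameter, function(pm) {
      safe_row(f1[[pm]], f2[[pm]][m], pm)
    })
  } else {
    tibble::tibble()
  }

  structure(
    list(generating_model = cohort$model, fitted_model = format(spec),
         fits = fits, recovery = recovery, cross_task = cross_task),
    class = "deckrl_recovery"
  )
}

#' @export
print.deckrl_recovery <- function(x, ...) {
  cat("<deckrl_recovery>", x$generating_model, "data fitted with",
      x$fitted_model, "\n")
  cat("  generating vs recovered (per task):\n")
  print(x$recovery, n = Inf)
  if (nrow(x$cross_task) > 0) {
    cat("  cross-task consistency of recovered parameters:\n")
    print(x$cross_task, n = Inf)
  }
  invisible(x)
}

#' @rdname recovery_experiment
#' @param x A `deckrl_recovery`.
#' @param ... Unused.
#' @export
tidy.deckrl_recovery <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$recovery, comparison = "generating_vs_recovered"),
    dplyr::mutate(x$cross_task, comparison = "cross_task", task = NA_character_)
  )
}
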