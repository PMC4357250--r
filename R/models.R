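# Model space: three utility functions, three expectancy-updating rules, two
# softmax choice rules, and their factorial combination into 18 models.

UTILITIES <- c("EU", "PU", "PU2")
UPDATINGS <- c("DELTA", "DRL", "MIXED")
CHOICES <- c("TDC", "TIC")

MODEL_PRESETS <- list(
  EVL = c("EU", "DELTA", "TDC"),
  PVL = c("PU", "DRL", "TIC"),
  PVL2 = c("PU2", "DRL", "TIC")
)

check_range <- function(x, name, lo, hi) {
  if (any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    abort(sprintf("`%s` must lie in [%s, %s]", name, lo, hi),
          class = "deckrl_out_of_bounds")
  }
  invisible(x)
}

#' Weighted expected-utility function
#'
#' The piecewise-linear utility of the EVL model:
#' `u = (1 - W) * win - W * loss`, with `W` the attention weight on losses
#' relative to gains. Gains and losses are evaluated separately and then
#' combined linearly.
#'
#' @param win Gain amount(s), nonnegative dollars.
#' @param loss Loss magnitude(s), nonnegative dollars.
#' @param W Attention weight to losses, in `[0, 1]`.
#' @return Utility value(s), vectorized over `win`/`loss`.
#' @export
#' @examples
#' utility_eu(win = 1, loss = 3, W = 0.5) # -1
utility_eu <- function(win, loss, W) {
  check_range(W, "W", 0, 1)
  (1 - W) * win - W * loss
}

#' Prospect utility of the net payoff
#'
#' The PVL model's utility function applies a power function with curvature
#' `alpha` and loss-aversion multiplier `lambda` to the net payoff
#' `x = win - loss`: `x^alpha` for `x >= 0` and `-lambda * |x|^alpha`
#' otherwise. At `alpha = 0` it degenerates to a step function taking value 1
#' on net gains and `-lambda` on net losses; a zero net payoff follows the
#' nonnegative branch.
#'
#' @inheritParams utility_eu
#' @param alpha Curvature exponent, in `[0, 1]`.
#' @param lambda Loss-aversion multiplier, nonnegative.
#' @return Utility value(s).
#' @export
#' @examples
#' utility_pu(win = 3, loss = 1, alpha = 0, lambda = 2.5) # 1
#' utility_pu(win = 1, loss = 3, alpha = 0, lambda = 2.5) # -2.5
utility_pu <- function(win, loss, alpha, lambda) {
  check_range(alpha, "alpha", 0, 1)
  check_range(lambda, "lambda", 0, Inf)
  x <- win - loss
  ifelse(x >= 0, x^alpha, -lambda * abs(x)^alpha)
}

#' Prospect utility with separately evaluated gains and losses
#'
#' The PVL2 model's utility function evaluates the gain and the loss of a
#' trial separately under a common power function before aggregating:
#' `u = win^alpha - gamma * loss^alpha`. Unlike [utility_pu()], an outcome
#' with equal gain and loss is not forced to zero utility.
#'
#' @inheritParams utility_pu
#' @param gamma Loss-aversion multiplier, nonnegative.
#' @return Utility value(s).
#' @export
#' @examples
#' utility_pu2(win = 2, loss = 2, alpha = 1, gamma = 1.5) # -1
utility_pu2 <- function(win, loss, alpha, gamma) {
  check_range(alpha, "alpha", 0, 1)
  check_range(gamma, "gamma", 0, Inf)
  win^alpha - gamma * loss^alpha
}

#' Delta-rule expectancy update
#'
#' Moves the chosen deck's expectancy a fraction `A` of the way toward the
#' current outcome utility `u`; unchosen decks are unchanged. At `A = 0`
#' nothing changes; at `A = 1` the chosen deck's expectancy becomes `u`.
#'
#' @param E Numeric 4-vector of deck expectancies (order A, B, C, D).
#' @param deck Chosen deck label.
#' @param u Utility of the current outcome.
#' @param A Updating rate, in `[0, 1]`.
#' @return Updated expectancy 4-vector.
#' @export
#' @examples
#' update_delta(c(10, 0, 0, 0), "A", u = 5, A = 0.5) # 7.5 0 0 0
update_delta <- function(E, deck, u, A) {
  check_range(A, "A", 0, 1)
  j <- deck_index(deck)
  E[j] <- E[j] + A * (u - E[j])
  E
}

#' Decay-reinforcement expectancy update
#'
#' All expectancies decay by the recency multiplier `A`; the chosen deck then
#' has the current outcome utility added. The updated expectancy of the
#' chosen deck is not bounded by its previous value and `u`: with `A = 0.9`,
#' `E = 10`, `u = 5` it becomes `0.9 * 10 + 5 = 14`.
#'
#' @inheritParams update_delta
#' @param A Recency (decay) multiplier, in `[0, 1]`.
#' @return Updated expectancy 4-vector.
#' @export
#' @examples
#' update_drl(c(10, 0, 0, 0), "A", u = 5, A = 0.9) # 14 0 0 0
update_drl <- function(E, deck, u, A) {
  check_range(A, "A", 0, 1)
  j <- deck_index(deck)
  E <- A * E
  E[j] <- E[j] + u
  E
}

#' Mixed decay-delta expectancy update
#'
#' All expectancies decay by `(1 - D)`; the chosen deck then moves a fraction
#' `A` from its decayed value toward the current outcome utility. At `D = 0`
#' the rule reduces exactly to [update_delta()]; at `A = 1` the chosen deck is
#' set to `u` regardless of `D`.
#'
#' @inheritParams update_delta
#' @param D Decay parameter, in `[0, 1]`.
#' @param A Updating rate, in `[0, 1]`.
#' @return Updated expectancy 4-vector.
#' @export
#' @examples
#' update_mixed(c(10, 0, 0, 0), "A", u = 5, D = 0.1, A = 0.5) # 7 0 0 0
update_mixed <- function(E, deck, u, D, A) {
  check_range(D, "D", 0, 1)
  check_range(A, "A", 0, 1)
  j <- deck_index(deck)
  E <- (1 - D) * E
  E[j] <- E[j] + A * (u - E[j])
  E
}

#' Trial-dependent choice sensitivity
#'
#' The trial-dependent choice (TDC) rule's sensitivity `theta(t) = (t/10)^c`:
#' sensitivity grows over trials for `c > 0`, shrinks for `c < 0`, and is
#' constant 1 at `c = 0`.
#'
#' @param t Trial index, `>= 1`.
#' @param c Consistency parameter (may be negative).
#' @return Sensitivity value(s) `theta`.
#' @export
#' @examples
#' sensitivity_tdc(t = 40, c = 0.5) # 2
sensitivity_tdc <- function(t, c) {
  if (any(t < 1)) {
    abort("`t` must be >= 1", class = "deckrl_bad_input")
  }
  (t / 10)^c
}

#' Trial-independent choice sensitivity
#'
#' The trial-independent choice (TIC) rule's constant sensitivity
#' `theta = 3^c - 1`. At `c = 0`, `theta = 0` and choices are uniformly
#' random regardless of expectancies; large `c` makes choice nearly
#' deterministic for the highest-expectancy deck.
#'
#' @param c Consistency parameter, nonnegative.
#' @return Sensitivity `theta`.
#' @export
#' @examples
#' sensitivity_tic(0) # 0
#' sensitivity_tic(1) # 2
sensitivity_tic <- function(c) {
  check_range(c, "c", 0, Inf)
  3^c - 1
}

#' Softmax choice probabilities over the four decks
#'
#' The ratio-of-strength choice rule: deck probabilities proportional to
#' `exp(theta * E)`. Computed with max-subtraction (and exponent arguments
#' floored at -700 after shifting) so that it is stable for arbitrarily large
#' `|theta * E|`.
#'
#' @param E Numeric 4-vector of deck expectancies.
#' @param theta Sensitivity, finite scalar.
#' @return Probability 4-vector summing to 1, entries in `(0, 1]`.
#' @export
#' @examples
#' choice_probabilities(c(10, 0, 0, 0), theta = 0) # uniform
choice_probabilities <- function(E, theta) {
  if (length(E) != 4 || any(!is.finite(E)) || !is.finite(theta)) {
    abort("`E` must be a finite 4-vector and `theta` a finite scalar",
          class = "deckrl_bad_input")
  }
  z <- theta * E
  z <- z - max(z)
  z[z < -700] <- -700
  w <- exp(z)
  w / sum(w)
}

#' Construct a model specification
#'
#' A model is a point in the 3 x 3 x 2 factorial space of utility function,
#' updating rule, and choice rule.
#'
#' @param utility `"EU"` (weighted expected utility), `"PU"` (prospect
#'   utility on net payoff), or `"PU2"` (prospect utility with separate
#'   gains/losses).
#' @param updating `"DELTA"`, `"DRL"` (decay-reinforcement), or `"MIXED"`.
#' @param choice `"TDC"` (trial-dependent) or `"TIC"` (trial-independent).
#' @return An object of class `deckrl_model`.
#' @seealso [as_model_spec()] for preset names (`"EVL"`, `"PVL"`, `"PVL2"`)
#'   and model strings (`"PU2-DRL-TIC"`), [model_space()] for all 18 models.
#' @export
#' @examples
#' model_spec("PU2", "DRL", "TIC") # the PVL2 model
model_spec <- function(utility, updating, choice) {
  utility <- match.arg(toupper(utility), UTILITIES)
  updating <- match.arg(toupper(updating), UPDATINGS)
  choice <- match.arg(toupper(choice), CHOICES)
  structure(
    list(utility = utility, updating = updating, choice = choice),
    class = "deckrl_model"
  )
}

#' Resolve a model name, string, or spec to a model specification
#'
#' Accepts a `deckrl_model`, a preset name (`"EVL"`, `"PVL"`, `"PVL2"`), or a
#' hyphenated model string `"UTILITY-UPDATING-CHOICE"` such as
#' `"PU2-DRL-TIC"`.
#'
#' @param x Model designator.
#' @return A `deckrl_model`.
#' @export
#' @examples
#' as_model_spec("PVL2")
#' as_model_spec("EU-DRL-TIC")
as_model_spec <- function(x) {
  if (inherits(x, "deckrl_model")) return(x)
  if (!is.character(x) || length(x) != 1) {
    abort("model designator must be a deckrl_model or a single string",
          class = "deckrl_bad_input")
  }
  key <- toupper(x)
  if (key %in% names(MODEL_PRESETS)) {
    p <- MODEL_PRESETS[[key]]
    return(model_spec(p[1], p[2], p[3]))
  }
  parts <- strsplit(key, "-", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    abort(paste0("cannot parse model designator: ", x),
          class = "deckrl_bad_input")
  }
  model_spec(parts[1], parts[2], parts[3])
}

#' @export
format.deckrl_model <- function(x, ...) {
  paste(x$utility, x$updating, x$choice, sep = "-")
}

#' @export
print.deckrl_model <- function(x, ...) {
  b <- parameter_bounds(x)
  cat("<deckrl_model>", format(x), "\n")
  cat("  parameters:", paste(b$parameter, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate the full 18-model factorial space
#'
#' @return A tibble with one row per model: columns `utility`, `updating`,
#'   `choice`, `model` (the hyphenated string), `n_params`, and `preset`
#'   (`"EVL"`, `"PVL"`, `"PVL2"`, or `NA`).
#' @export
#' @examples
#' model_space()
model_space <- function() {
  grid <- tidyr::expand_grid(
    utility = UTILITIES, updating = UPDATINGS, choice = CHOICES
  )
  grid |>
    dplyr::mutate(
      model = paste(.data$utility, .data$updating, .data$choice, sep = "-"),
      n_params = purrr::pmap_int(
        list(.data$utility, .data$updating, .data$choice),
        function(u, r, ch) nrow(parameter_bounds(model_spec(u, r, ch)))
      ),
      preset = purrr::map_chr(.data$model, function(m) {
        hit <- vapply(MODEL_PRESETS,
                      function(p) identical(paste(p, collapse = "-"), m),
                      logical(1))
        if (any(hit)) names(MODEL_PRESETS)[hit] else NA_character_
      })
    )
}

#' Parameter names and bounds for a model
#'
#' Returns the model's free parameters in canonical order (utility
#' parameters, then updating parameters, then the consistency parameter `c`)
#' with the box bounds used by the fitting routines: `W`, `A`, `D`, `alpha`
#' in `[0, 1]`; `lambda`, `gamma` in `[0, 10]`; `c` in `[0, 5]` for the
#' trial-independent rule and `[-5, 5]` for the trial-dependent rule (so
#' sensitivity may decrease over trials).
#'
#' @param model A model designator accepted by [as_model_spec()].
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
#' @examples
#' parameter_bounds("PVL2")
parameter_bounds <- function(model) {
  spec <- as_model_spec(model)
  rows <- list()
  add <- function(p, lo, hi) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      parameter = p, lower = lo, upper = hi
    )
  }
  switch(spec$utility,
    EU = add("W", 0, 1),
    PU = { add("alpha", 0, 1); add("lambda", 0, 10) },
    PU2 = { add("alpha", 0, 1); add("gamma", 0, 10) }
  )
  switch(spec$updating,
    DELTA = add("A", 0, 1),
    DRL = add("A", 0, 1),
    MIXED = { add("D", 0, 1); add("A", 0, 1) }
  )
  if (spec$choice == "TIC") add("c", 0, 5) else add("c", -5, 5)
  dplyr::bind_rows(rows)
}

# Scalar utility under a spec; params is a named vector with the spec's
# canonical names.
utility_value <- function(spec, win, loss, params) {
  switch(spec$utility,
    EU = utility_eu(win, loss, params[["W"]]),
    PU = utility_pu(win, loss, params[["alpha"]], params[["lambda"]]),
    PU2 = utility_pu2(win, loss, params[["alpha"]], params[["gamma"]])
  )
}

expectancy_update <- function(spec, E, deck, u, params) {
  switch(spec$updating,
    DELTA = update_delta(E, deck, u, params[["A"]]),
    DRL = update_drl(E, deck, u, params[["A"]]),
    MIXED = update_mixed(E, deck, u, params[["D"]], params[["A"]])
  )
}

sensitivity_value <- function(spec, t, params) {
  if (spec$choice == "TIC") sensitivity_tic(params[["c"]])
  else sensitivity_tdc(t, params[["c"]])
}
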