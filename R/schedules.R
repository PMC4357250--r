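# Task engine: exact payoff schedules for the IGT and SGT, a stateful dealer
# with within-block randomization, and schedule-level summaries.

new_schedule <- function(task, deck, trial_in_block, gain, loss) {
  out <- tibble::tibble(
    task = task, deck = deck, trial_in_block = trial_in_block,
    gain = gain, loss = loss
  )
  class(out) <- c("deckrl_schedule", class(out))
  out
}

#' Payoff schedule of the Iowa Gambling Task
#'
#' Returns the deterministic per-block payoff structure of the IGT as a tidy
#' table, one row per deck and within-block trial position. Decks A and B pay
#' a gain of $1.00 on every trial, decks C and D $0.50. Within each 10-trial
#' block, decks A and C carry five loss trials (magnitudes $1.50-$3.50 and
#' $0.25-$0.75 respectively) while decks B and D carry a single large loss
#' ($12.50 and $2.50), so that A and B net -$2.50 and C and D net +$2.50 per
#' 10 trials. Losses are stored as nonnegative magnitudes.
#'
#' The ordering of loss trials within a block in this table is canonical
#' (losses first); [deck_dealer()] randomizes positions within each block at
#' deal time.
#'
#' @return A tibble with columns `task`, `deck`, `trial_in_block`, `gain`,
#'   `loss` (40 rows: 4 decks x 10 positions).
#' @seealso [sgt_schedule()], [deck_dealer()], [block_expected_value()]
#' @export
#' @examples
#' igt_schedule()
igt_schedule <- function() {
  pad <- function(x, n) c(x, rep(0, n - length(x)))
  new_schedule(
    task = "IGT",
    deck = rep(DECKS, each = 10),
    trial_in_block = rep(1:10, times = 4),
    gain = rep(c(1.00, 1.00, 0.50, 0.50), each = 10),
    loss = c(
      pad(c(1.50, 2.00, 2.50, 3.00, 3.50), 10),
      pad(12.50, 10),
      pad(c(0.25, 0.50, 0.50, 0.50, 0.75), 10),
      pad(2.50, 10)
    )
  )
}

#' Payoff schedule of the Soochow Gambling Task
#'
#' Returns the per-block payoff structure of the SGT, in which every card is a
#' pure gain or a pure loss and blocks are five trials long. Decks A and B pay
#' four small gains ($1.00 / $0.50) and one large loss ($5.25 / $3.25) per
#' block, netting -$2.50 per 10 trials; decks C and D pay four small losses
#' ($1.00 / $0.50) and one large gain ($5.25 / $3.25), netting +$2.50 per 10
#' trials. Gain-loss frequency is thereby decoupled from expected value.
#'
#' @return A tibble with columns `task`, `deck`, `trial_in_block`, `gain`,
#'   `loss` (20 rows: 4 decks x 5 positions).
#' @seealso [igt_schedule()], [deck_dealer()]
#' @export
#' @examples
#' sgt_schedule()
sgt_schedule <- function() {
  new_schedule(
    task = "SGT",
    deck = rep(DECKS, each = 5),
    trial_in_block = rep(1:5, times = 4),
    gain = c(
      1.00, 1.00, 1.00, 1.00, 0,
      0.50, 0.50, 0.50, 0.50, 0,
      0, 0, 0, 0, 5.25,
      0, 0, 0, 0, 3.25
    ),
    loss = c(
      0, 0, 0, 0, 5.25,
      0, 0, 0, 0, 3.25,
      1.00, 1.00, 1.00, 1.00, 0,
      0.50, 0.50, 0.50, 0.50, 0
    )
  )
}

#' Look up a task's payoff schedule by name
#'
#' @param task `"IGT"` or `"SGT"`, or an existing schedule tibble (returned
#'   unchanged).
#' @return A schedule tibble as from [igt_schedule()] or [sgt_schedule()].
#' @export
task_schedule <- function(task) {
  if (is.data.frame(task)) return(task)
  task <- match.arg(toupper(task), TASKS)
  if (task == "IGT") igt_schedule() else sgt_schedule()
}

block_length <- function(schedule) {
  vapply(split(schedule$trial_in_block, schedule$deck), max, numeric(1))
}

#' Expected net payoff of a deck over a fixed horizon
#'
#' Computes the per-block net payoff (gains minus loss magnitudes) of one deck
#' and scales it to `per_trials` trials. Because blocks are dealt as exact
#' permutations, this is the exact long-run net payoff, not an estimate.
#'
#' @param schedule A schedule tibble ([igt_schedule()], [sgt_schedule()]).
#' @param deck Deck label, one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param per_trials Horizon in trials; must be a positive multiple of the
#'   deck's block length. Default 10, the conventional reporting horizon.
#' @return Net payoff in dollars over `per_trials` trials.
#' @export
#' @examples
#' block_expected_value(igt_schedule(), "A") # -2.5
#' block_expected_value(sgt_schedule(), "C") # +2.5
block_expected_value <- function(schedule, deck, per_trials = 10) {
  deck <- match.arg(deck, DECKS)
  rows <- schedule[schedule$deck == deck, ]
  bl <- nrow(rows)
  if (per_trials <= 0 || per_trials %% bl != 0) {
    abort(
      paste0("`per_trials` (", per_trials,
             ") must be a positive multiple of the block length (", bl, ")"),
      class = "deckrl_invalid_horizon"
    )
  }
  sum(rows$gain - rows$loss) * per_trials / bl
}

#' Validate a payoff schedule against its structural invariants
#'
#' Checks a schedule table against the invariants of the task it claims to
#' encode: nonnegative amounts, uniform block lengths (10 for IGT, 5 for SGT),
#' the per-deck loss-trial counts (IGT: 5/1/5/1), the pure-outcome property
#' (SGT: every trial is gain-only or loss-only), and the per-10-trial expected
#' values (-2.50 for decks A/B, +2.50 for C/D).
#'
#' @param schedule A schedule tibble.
#' @return A tibble with columns `check`, `passed`, `detail`; the schedule
#'   passes overall iff `all(result$passed)`.
#' @export
#' @examples
#' all(validate_schedule(igt_schedule())$passed)
validate_schedule <- function(schedule) {
  stop_not_df(schedule, "schedule")
  task <- unique(schedule$task)
  checks <- list()
  add <- function(check, passed, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, passed = passed, detail = detail
    )
  }

  add("single task", length(task) == 1,
      paste("tasks present:", paste(task, collapse = ", ")))
  add("known task", all(task %in% TASKS), paste(task, collapse = ", "))
  add("all four decks", setequal(unique(schedule$deck), DECKS),
      paste(sort(unique(schedule$deck)), collapse = ", "))
  add("nonnegative amounts",
      all(schedule$gain >= 0) && all(schedule$loss >= 0),
      "gains and loss magnitudes must be >= 0")

  bl <- block_length(schedule)
  expected_bl <- if (identical(task, "SGT")) 5 else 10
  add(sprintf("block length %d for every deck", expected_bl),
      all(bl == expected_bl),
      paste(names(bl), bl, sep = "=", collapse = ", "))

  if (identical(task, "IGT")) {
    nloss <- vapply(split(schedule$loss, schedule$deck),
                    function(x) sum(x > 0), numeric(1))
    add("IGT loss counts per block are 5/1/5/1",
        all(nloss[DECKS] == c(5, 1, 5, 1)),
        paste(names(nloss), nloss, sep = "=", collapse = ", "))
  }
  if (identical(task, "SGT")) {
    pure <- schedule$gain == 0 | schedule$loss == 0
    add("SGT trials are pure gain or pure loss", all(pure),
        paste(sum(!pure), "mixed trial(s)"))
  }

  ev <- vapply(DECKS, function(d) {
    rows <- schedule[schedule$deck == d, ]
    sum(rows$gain - rows$loss) * 10 / nrow(rows)
  }, numeric(1))
  target <- c(A = -2.50, B = -2.50, C = 2.50, D = 2.50)
  add("per-10-trial expected values are -2.50/-2.50/+2.50/+2.50",
      isTRUE(all(abs(ev - target) < 1e-9)),
      paste(names(ev), sprintf("%.2f", ev), sep = "=", collapse = ", "))

  dplyr::bind_rows(checks)
}

#' Create a stateful card dealer for a task schedule
#'
#' A dealer deals outcomes deck by deck. Within each consecutive block of
#' `block_length` draws from one deck, the multiset of outcomes equals that
#' deck's printed block exactly; only the order is randomized, by a fresh
#' uniform permutation per block. Decks are inexhaustible. The dealer owns a
#' private RNG stream seeded by `seed`, so its output is reproducible and
#' independent of the caller's RNG state.
#'
#' @param schedule A schedule tibble, or a task name passed to
#'   [task_schedule()].
#' @param seed Integer seed for the dealer's private permutation stream.
#' @return An object of class `deckrl_dealer`.
#' @seealso [draw_outcome()]
#' @export
#' @examples
#' d <- deck_dealer("IGT", seed = 1)
#' draw_outcome(d, "B")
deck_dealer <- function(schedule, seed = 1L) {
  schedule <- task_schedule(schedule)
  d <- new.env(parent = emptyenv())
  d$task <- unique(schedule$task)
  d$gain <- split(schedule$gain, schedule$deck)
  d$loss <- split(schedule$loss, schedule$deck)
  d$bl <- vapply(d$gain, length, integer(1))
  d$pos <- setNames(rep(0L, 4), DECKS)
  d$perm <- setNames(vector("list", 4), DECKS)
  d$seed <- as.integer(seed)
  # private RNG state, initialized once and swapped in per draw
  d$rng <- with_local_seed(seed, get(".Random.seed", envir = globalenv()))
  class(d) <- "deckrl_dealer"
  d
}

# Evaluate `code` under the dealer's private RNG stream, advancing it.
with_dealer_rng <- function(dealer, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", dealer$rng, envir = globalenv())
  on.exit({
    dealer$rng <- get(".Random.seed", envir = globalenv())
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  force(code)
}

#' Draw the next outcome for a deck
#'
#' Deals the next card from the given deck of a [deck_dealer()]. When a block
#' is exhausted a fresh uniform permutation of the deck's printed block is
#' generated from the dealer's private RNG stream.
#'
#' @param dealer A `deckrl_dealer`.
#' @param deck Deck label in `A`-`D`.
#' @return Named numeric vector `c(win =, loss =)`, both nonnegative dollars
#'   (`loss` is a magnitude).
#' @export
draw_outcome <- function(dealer, deck) {
  if (!inherits(dealer, "deckrl_dealer")) {
    abort("`dealer` must be created by deck_dealer()",
          class = "deckrl_bad_input")
  }
  deck <- as.character(deck)
  if (length(deck) != 1 || !deck %in% DECKS) {
    abort(paste0("invalid deck label: ", deck),
          class = "deckrl_invalid_deck")
  }
  bl <- dealer$bl[[deck]]
  if (dealer$pos[[deck]] %% bl == 0L) {
    dealer$perm[[deck]] <- with_dealer_rng(dealer, sample.int(bl))
    dealer$pos[[deck]] <- 0L
  }
  dealer$pos[[deck]] <- dealer$pos[[deck]] + 1L
  i <- dealer$perm[[deck]][dealer$pos[[deck]]]
  c(win = dealer$gain[[deck]][i], loss = dealer$loss[[deck]][i])
}

#' @export
print.deckrl_dealer <- function(x, ...) {
  cat("<deckrl_dealer>", x$task, "seed", x$seed, "\n")
  cat("  draws so far:",
      paste(DECKS, x$pos[DECKS], sep = "=", collapse = ", "), "\n")
  invisible(x)
}
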