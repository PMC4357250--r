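# Internal helpers shared across modules.

DECKS <- c("A", "B", "C", "D")
TASKS <- c("IGT", "SGT")

deck_index <- function(deck) {
  idx <- match(as.character(deck), DECKS)
  if (anyNA(idx)) {
    bad <- unique(as.character(deck)[is.na(idx)])
    abort(
      paste0("invalid deck label(s): ", paste(bad, collapse = ", "),
             " (must be one of A, B, C, D)"),
      class = "deckrl_invalid_deck"
    )
  }
  idx
}

# Run `code` with the global RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never perturb the user's stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit seed stream derived from a master seed; keeps derived
# seeds positive and below 2^31 so they are valid set.seed() inputs.
derive_seed <- function(master, i) {
  m <- as.double(master) %% 2147483647
  as.integer((m * 48271 + as.double(i) * 8191) %% 2147483646 + 1)
}

stop_not_df <- function(x, arg) {
  if (!is.data.frame(x)) {
    abort(paste0("`", arg, "` must be a data frame of trials"),
          class = "deckrl_bad_input")
  }
}
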