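# Independent plain-R oracles and fixture builders. These deliberately avoid
# the package's internal recursion code: every quantity is recomputed
# step by step from the model equations.

ORACLE_DECKS <- c("A", "B", "C", "D")

deck_idx <- function(d) match(d, ORACLE_DECKS)

# Naive per-trial one-step-ahead log-likelihood. `pars` is a named list.
oracle_loglik <- function(trials, utility, updating, choice_rule, pars,
                          tdc_index = "predicted") {
  E <- c(0, 0, 0, 0)
  ll <- 0
  n <- nrow(trials)
  for (t in seq_len(n - 1)) {
    j <- match(trials$deck[t], ORACLE_DECKS)
    win <- trials$gain[t]
    loss <- trials$loss[t]
    u <- switch(utility,
      EU = (1 - pars$W) * win - pars$W * loss,
      PU = {
        x <- win - loss
        if (x >= 0) x^pars$alpha else -pars$lambda * (-x)^pars$alpha
      },
      PU2 = win^pars$alpha - pars$gamma * loss^pars$alpha
    )
    if (updating == "DELTA") {
      E[j] <- E[j] + pars$A * (u - E[j])
    } else if (updating == "DRL") {
      E <- pars$A * E
      E[j] <- E[j] + u
    } else {
      E <- (1 - pars$D) * E
      E[j] <- E[j] + pars$A * (u - E[j])
    }
    th <- if (choice_rule == "TIC") {
      3^pars$c - 1
    } else {
      idx <- if (tdc_index == "predicted") t + 1 else t
      (idx / 10)^pars$c
    }
    # softmax log-probability with the package's documented convention:
    # max-subtraction, exponent arguments floored at -700 after shifting
    z <- th * E
    a <- pmax(z - max(z), -700)
    nxt <- match(trials$deck[t + 1], ORACLE_DECKS)
    ll <- ll + a[nxt] - log(sum(exp(a)))
  }
  ll
}

# Random (model, parameters, sequence) triple with amounts on the tasks'
# dollar scale. Parameters are drawn strictly inside the fitting bounds.
random_triple <- function(n_trials = 30) {
  utility <- sample(c("EU", "PU", "PU2"), 1)
  updating <- sample(c("DELTA", "DRL", "MIXED"), 1)
  choice_rule <- sample(c("TDC", "TIC"), 1)
  pars <- list()
  if (utility == "EU") pars$W <- runif(1)
  if (utility == "PU") {
    pars$alpha <- runif(1)
    pars$lambda <- runif(1, 0, 10)
  }
  if (utility == "PU2") {
    pars$alpha <- runif(1)
    pars$gamma <- runif(1, 0, 10)
  }
  if (updating == "MIXED") pars$D <- runif(1)
  pars$A <- runif(1)
  pars$c <- if (choice_rule == "TIC") runif(1, 0, 5) else runif(1, -5, 5)
  trials <- tibble::tibble(
    deck = sample(ORACLE_DECKS, n_trials, replace = TRUE),
    gain = round(runif(n_trials, 0, 2), 2),
    loss = round(runif(n_trials, 0, 13) * rbinom(n_trials, 1, 0.4), 2)
  )
  list(utility = utility, updating = updating, choice_rule = choice_rule,
       pars = pars, trials = trials)
}

# Spearman's rho recomputed from first principles: Pearson correlation of
# average ranks, where the ranks themselves are recomputed by counting.
oracle_spearman_rho <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# A short deterministic IGT-style sequence for cheap likelihood checks.
fixture_sequence <- function(n_trials = 30, seed = 42, task = "IGT") {
  set.seed(seed)
  dealer <- deckrl::deck_dealer(task, seed = seed)
  decks <- sample(ORACLE_DECKS, n_trials, replace = TRUE)
  out <- t(vapply(decks, function(d) deckrl::draw_outcome(dealer, d),
                  numeric(2)))
  tibble::tibble(deck = decks, gain = out[, 1], loss = out[, 2])
}
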