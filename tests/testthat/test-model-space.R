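test_that("weighted expected utility follows its defining equation", {
  expect_equal(utility_eu(win = 1, loss = 3, W = 0.5), -1.0)
  expect_equal(utility_eu(win = 2, loss = 0, W = 0), 2.0)
  # equal gain and loss cancel only at W = 0.5
  for (x in c(0.5, 2, 12.5)) {
    expect_equal(utility_eu(x, x, 0.5), 0)
  }
  expect_false(utility_eu(2, 2, 0.3) == 0)
  expect_error(utility_eu(1, 1, W = 1.2), class = "deckrl_out_of_bounds")
})

test_that("prospect utility of net payoff: power, step, and zero conventions", {
  expect_equal(utility_pu(win = 3, loss = 1, alpha = 0, lambda = 2.5), 1.0)
  expect_equal(utility_pu(win = 1, loss = 3, alpha = 0, lambda = 2.5), -2.5)
  expect_equal(utility_pu(win = 2, loss = 2, alpha = 0.7, lambda = 5), 0)
  # x = 0 follows the nonnegative branch: 0 for alpha > 0, 1 for alpha = 0
  expect_equal(utility_pu(0, 0, alpha = 0.5, lambda = 2), 0)
  expect_equal(utility_pu(0, 0, alpha = 0, lambda = 2), 1)
  # alpha = 1 is linear with slope lambda on losses
  expect_equal(utility_pu(1, 4, alpha = 1, lambda = 2), -6)
})

test_that("separate-gains/losses prospect utility aggregates the two branches", {
  expect_equal(utility_pu2(win = 2, loss = 2, alpha = 1, gamma = 1.5), -1.0)
  expect_equal(utility_pu2(win = 0, loss = 0, alpha = 0.7, gamma = 3), 0)
  expect_equal(utility_pu2(win = 1, loss = 3, alpha = 1, gamma = 0.5), -0.5)
})

test_that("PU and PU2 coincide on pure-outcome trials when lambda = gamma", {
  set.seed(1)
  for (i in 1:50) {
    alpha <- runif(1)
    lam <- runif(1, 0, 10)
    amt <- runif(1, 0, 6)
    if (runif(1) < 0.5) {
      expect_equal(utility_pu(amt, 0, alpha, lam),
                   utility_pu2(amt, 0, alpha, lam))
    } else {
      expect_equal(utility_pu(0, amt, alpha, lam),
                   utility_pu2(0, amt, alpha, lam))
    }
  }
})

test_that("delta rule interpolates between old expectancy and utility", {
  E <- c(10, 0, 0, 0)
  expect_equal(update_delta(E, "A", u = 5, A = 0), c(10, 0, 0, 0))
  expect_equal(update_delta(E, "A", u = 5, A = 1), c(5, 0, 0, 0))
  expect_equal(update_delta(E, "A", u = 5, A = 0.5), c(7.5, 0, 0, 0))
  # chosen deck stays within [min(E_old, u), max(E_old, u)] for all A
  set.seed(2)
  for (i in 1:50) {
    A <- runif(1)
    E0 <- runif(4, -10, 10)
    u <- runif(1, -10, 10)
    E1 <- update_delta(E0, "C", u, A)
    expect_true(E1[3] >= min(E0[3], u) - 1e-12)
    expect_true(E1[3] <= max(E0[3], u) + 1e-12)
    expect_equal(E1[-3], E0[-3])
  }
})

test_that("decay-reinforcement rule decays all decks and adds u to the chosen", {
  expect_equal(update_drl(c(10, 0, 0, 0), "A", u = 5, A = 0.9),
               c(14, 0, 0, 0))
  expect_equal(update_drl(c(10, 8, 0, 0), "A", u = 5, A = 0.9)[2], 7.2)
  expect_equal(update_drl(c(10, 0, 0, 0), "A", u = 5, A = 0),
               c(5, 0, 0, 0))
})

test_that("mixed rule nests the delta rule and respects its bounds", {
  # D = 0 reduces exactly to the delta rule
  set.seed(3)
  for (i in 1:50) {
    E0 <- runif(4, -10, 10)
    u <- runif(1, -10, 10)
    A <- runif(1)
    deck <- sample(c("A", "B", "C", "D"), 1)
    expect_identical(update_mixed(E0, deck, u, D = 0, A = A),
                     update_delta(E0, deck, u, A = A))
    # A = 1 pins the chosen deck at u regardless of D
    D <- runif(1)
    expect_equal(update_mixed(E0, deck, u, D = D, A = 1)[deck_idx(deck)], u)
    # chosen deck lies between its decayed value and u
    E1 <- update_mixed(E0, deck, u, D = D, A = A)
    dec <- (1 - D) * E0[deck_idx(deck)]
    expect_true(E1[deck_idx(deck)] >= min(dec, u) - 1e-12)
    expect_true(E1[deck_idx(deck)] <= max(dec, u) + 1e-12)
  }
  expect_equal(update_mixed(c(10, 6, 0, 0), "A", u = 5, D = 1, A = 0.5),
               c(2.5, 0, 0, 0))
  expect_equal(update_mixed(c(10, 0, 0, 0), "A", u = 5, D = 0.1, A = 0.5),
               c(7, 0, 0, 0))
})

test_that("sensitivity functions match their closed forms", {
  expect_equal(sensitivity_tdc(t = 10, c = 3.7), 1.0)
  expect_equal(sensitivity_tdc(t = 40, c = 0.5), 2.0)
  expect_equal(sensitivity_tdc(t = 5, c = 0), 1.0)
  expect_error(sensitivity_tdc(t = 0, c = 1), class = "deckrl_bad_input")

  expect_equal(sensitivity_tic(0), 0)
  expect_equal(sensitivity_tic(1), 2)
  expect_equal(sensitivity_tic(2), 8)
  expect_error(sensitivity_tic(-0.1), class = "deckrl_out_of_bounds")
})

test_that("softmax is uniform at theta 0, symmetric, and argmax in the limit", {
  expect_equal(choice_probabilities(c(93, -4, 0.2, 7), theta = 0),
               rep(0.25, 4))
  expect_equal(choice_probabilities(c(5, 5, 5, 5), theta = 3.3),
               rep(0.25, 4))
  p <- choice_probabilities(c(10, 0, 0, 0), theta = 100)
  expect_gt(p[1], 0.999999)
})

test_that("softmax is stable and normalized for |theta*E| up to 1e4", {
  set.seed(4)
  for (i in 1:100) {
    E <- runif(4, -1e4, 1e4)
    theta <- runif(1, 0, 1)
    p <- choice_probabilities(E, theta)
    expect_true(all(is.finite(p)))
    expect_true(all(p > 0))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
})

test_that("the factorial space enumerates 18 distinct models with correct counts", {
  ms <- model_space()
  expect_equal(nrow(ms), 18)
  expect_equal(anyDuplicated(ms$model), 0)
  # parameter counts: EU-based 3 (4 with mixed), PU/PU2-based 4 (5 with mixed)
  expect_equal(sort(unique(ms$n_params)), c(3, 4, 5))
  expect_equal(sum(ms$n_params == 3), 4)
  expect_equal(sum(ms$n_params == 5), 4)
  for (i in seq_len(nrow(ms))) {
    expect_equal(nrow(parameter_bounds(ms$model[i])), ms$n_params[i])
  }
})

test_that("presets resolve to their factorial coordinates", {
  evl <- as_model_spec("EVL")
  expect_equal(c(evl$utility, evl$updating, evl$choice),
               c("EU", "DELTA", "TDC"))
  expect_equal(nrow(parameter_bounds(evl)), 3)

  pvl <- as_model_spec("PVL")
  expect_equal(c(pvl$utility, pvl$updating, pvl$choice),
               c("PU", "DRL", "TIC"))

  pvl2 <- as_model_spec("PVL2")
  expect_equal(c(pvl2$utility, pvl2$updating, pvl2$choice),
               c("PU2", "DRL", "TIC"))
  expect_equal(nrow(parameter_bounds(pvl2)), 4)

  # model strings round-trip
  expect_equal(format(as_model_spec("PU2-DRL-TIC")), "PU2-DRL-TIC")
  expect_error(as_model_spec("PU2-DRL"), class = "deckrl_bad_input")
})

test_that("parameter bounds follow the declared box", {
  b <- parameter_bounds("EU-DRL-TIC")
  expect_equal(b$parameter, c("W", "A", "c"))
  expect_equal(b$lower, c(0, 0, 0))
  expect_equal(b$upper, c(1, 1, 5))

  b2 <- parameter_bounds("PU2-MIXED-TDC")
  expect_equal(b2$parameter, c("alpha", "gamma", "D", "A", "c"))
  expect_equal(b2$lower, c(0, 0, 0, 0, -5))
  expect_equal(b2$upper, c(1, 10, 1, 1, 5))

  b3 <- parameter_bounds("PU-DELTA-TDC")
  expect_equal(nrow(b3), 4)
})
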