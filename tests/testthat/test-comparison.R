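make_fits <- function(bic_by_model, participants = NULL, task = "IGT") {
  purrr::imap_dfr(bic_by_model, function(scores, model) {
    tibble::tibble(
      participant_id = participants %||% sprintf("p%02d", seq_along(scores)),
      task = task,
      model = model,
      bic_diff = scores
    )
  })
}

test_that("summarize_bic reports mean, median, SD, and strict-positive share", {
  fits <- make_fits(list(M = c(1, -1, 3)))
  s <- summarize_bic(fits)
  expect_equal(s$mean_bic, 1)
  expect_equal(s$median_bic, 1)
  expect_equal(s$sd_bic, 2)
  expect_equal(s$pct_positive, 100 * 2 / 3)

  # a single score: SD undefined (NA), percentage 100
  s1 <- summarize_bic(make_fits(list(M = 5)))
  expect_equal(s1$mean_bic, 5)
  expect_equal(s1$median_bic, 5)
  expect_true(is.na(s1$sd_bic))
  expect_equal(s1$pct_positive, 100)

  # exact zeros are not wins
  s0 <- summarize_bic(make_fits(list(M = c(0, 0, 2))))
  expect_equal(s0$pct_positive, 100 / 3)

  expect_error(summarize_bic(make_fits(list())), class = "deckrl_empty_group")
})

test_that("summarize_bic matches a streaming recomputation on random scores", {
  set.seed(61)
  scores <- rnorm(100, 10, 30)
  s <- summarize_bic(make_fits(list(M = scores)))
  # independent streaming pass
  n <- 0; mean_acc <- 0; m2 <- 0; pos <- 0
  for (x in scores) {
    n <- n + 1
    d <- x - mean_acc
    mean_acc <- mean_acc + d / n
    m2 <- m2 + d * (x - mean_acc)
    if (x > 0) pos <- pos + 1
  }
  expect_equal(s$mean_bic, mean_acc, tolerance = 1e-10)
  expect_equal(s$sd_bic, sqrt(m2 / (n - 1)), tolerance = 1e-10)
  expect_equal(s$pct_positive, 100 * pos / n, tolerance = 1e-10)
  expect_equal(s$median_bic, sort(scores)[50:51] |> mean(), tolerance = 1e-10)
})

test_that("summarize_bic is permutation-invariant over participants", {
  set.seed(62)
  scores <- rnorm(31)
  s1 <- summarize_bic(make_fits(list(M = scores)))
  s2 <- summarize_bic(make_fits(list(M = sample(scores))))
  expect_equal(s1[c("mean_bic", "median_bic", "sd_bic", "pct_positive")],
               s2[c("mean_bic", "median_bic", "sd_bic", "pct_positive")])
})

test_that("pairwise_wins counts strict wins and exact ties", {
  fits <- make_fits(list(a = c(3, 1, 2), b = c(2, 2, 2)))
  pw <- pairwise_wins(fits, "a", "b")
  expect_equal(pw$wins_a, 1) # 3 > 2
  expect_equal(pw$wins_b, 1) # 1 < 2
  expect_equal(pw$ties, 1)   # 2 == 2
  expect_equal(pw$n, 3)
  expect_equal(pw$wins_a + pw$wins_b + pw$ties, pw$n)

  same <- make_fits(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  pw2 <- pairwise_wins(same, "a", "b")
  expect_equal(pw2$ties, 3)
})

test_that("pairwise_wins is antisymmetric and checks alignment", {
  set.seed(63)
  fits <- make_fits(list(a = rnorm(20), b = rnorm(20)))
  ab <- pairwise_wins(fits, "a", "b")
  ba <- pairwise_wins(fits, "b", "a")
  expect_equal(ab$wins_a, ba$wins_b)
  expect_equal(ab$wins_b, ba$wins_a)
  expect_equal(ab$ties, ba$ties)

  misaligned <- dplyr::bind_rows(
    make_fits(list(a = c(1, 2))),
    make_fits(list(b = c(1, 2, 3)))
  )
  expect_error(pairwise_wins(misaligned, "a", "b"),
               class = "deckrl_alignment_error")
})

test_that("spearman_consistency recovers perfect monotone association", {
  r <- spearman_consistency(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(r$rho, 1)
  expect_equal(r$rho_squared, 1)
  r2 <- spearman_consistency(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(r2$rho, -1)
})

test_that("rho_squared equals rho^2 and rho is monotone-invariant", {
  set.seed(64)
  for (i in 1:10) {
    x <- rnorm(15)
    y <- rnorm(15)
    r <- spearman_consistency(x, y)
    expect_equal(r$rho_squared, r$rho^2, tolerance = 1e-12)
    r_t <- spearman_consistency(exp(x), y^3 + 5 * y)
    expect_equal(r_t$rho, r$rho, tolerance = 1e-12)
    expect_equal(spearman_consistency(x, x)$rho, 1)
  }
})

test_that("rho with ties matches the counting-based oracle and cor.test", {
  set.seed(65)
  for (i in 1:20) {
    x <- sample(1:4, 8, replace = TRUE)
    y <- sample(1:4, 8, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    r <- spearman_consistency(x, y)
    expect_equal(r$rho, oracle_spearman_rho(x, y), tolerance = 1e-10)
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", alternative = "greater",
               exact = FALSE)
    )
    expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-10)
  }
})

test_that("the one-tailed p follows the t approximation and the exact option", {
  set.seed(66)
  x <- rnorm(12)
  y <- x + rnorm(12, sd = 2)
  r <- spearman_consistency(x, y)
  tstat <- r$rho * sqrt((r$n - 2) / (1 - r$rho^2))
  expect_equal(r$p_one_tailed, pt(tstat, r$n - 2, lower.tail = FALSE))

  # exact permutation p on a small sample: compare against direct enumeration
  xs <- c(3, 1, 4, 1, 5)
  ys <- c(9, 2, 6, 5, 3)
  re <- spearman_consistency(xs, ys, exact = TRUE)
  all_p <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_p(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(all_p(ys), function(p) oracle_spearman_rho(xs, p),
                 numeric(1))
  expect_equal(re$p_one_tailed, mean(rhos >= re$rho - 1e-12))
  expect_error(spearman_consistency(rnorm(9), rnorm(9), exact = TRUE),
               class = "deckrl_bad_input")
})

test_that("degenerate consistency inputs are rejected", {
  expect_error(spearman_consistency(c(1, 1, 1, 1), c(1, 2, 3, 4)),
               class = "deckrl_undefined_correlation")
  expect_error(spearman_consistency(c(1, 2), c(1, 2)),
               class = "deckrl_insufficient_n")
})

test_that("consistency_table tests every parameter across the two tasks", {
  set.seed(67)
  n <- 12
  ids <- sprintf("p%02d", 1:n)
  base <- tibble::tibble(participant_id = rep(ids, 2),
                         task = rep(c("IGT", "SGT"), each = n),
                         model = "PU2-DRL-TIC")
  latent <- rnorm(n)
  for (pm in c("alpha", "gamma", "A", "c")) {
    base[[pm]] <- rep(latent, 2) + rnorm(2 * n, sd = 0.3)
  }
  ct <- consistency_table(base)
  expect_equal(ct$parameter, c("alpha", "gamma", "A", "c"))
  expect_true(all(ct$rho > 0))
  expect_true(all(ct$n == n))
})

test_that("md_bic_table renders one row per summary line", {
  s <- summarize_bic(make_fits(list(M = c(1, -1, 3))))
  md <- md_bic_table(s)
  expect_equal(length(md), 3)
  expect_match(md[1], "%\\(BIC>0\\)")
})
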