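test_that("imaging accuracy follows the intersection-over-prediction formula", {
  expect_equal(imaging_accuracy(c("A"), c("A")), 1)
  expect_equal(imaging_accuracy(c("A", "B"), c("A")), 0.5)
  expect_equal(imaging_accuracy(c("B"), c("A")), 0)
  expect_equal(imaging_accuracy(character(), c("A")), 0)  # unparsed convention
  expect_equal(imaging_accuracy(c("A"), c("A", "B", "C")), 1)  # subset => 1
})

test_that("topic accuracy counts exact matches (and membership for m > 1)", {
  ev <- make_evals(list(
    list(y = "T1", y_pred = "T1", K = "A", K_pred = "A"),
    list(y = "T2", y_pred = "T1", K = "A", K_pred = "A"),
    list(y = "T3", y_pred = c("T9", "T3"), K = "A", K_pred = "A"),
    list(y = "T4", y_pred = "T4", K = "A", K_pred = "A")
  ))
  expect_equal(topic_accuracy(ev), 0.75)
  expect_error(topic_accuracy(ev[0, ]), "empty")
})

test_that("unnecessary and missed rates count their defining conditions", {
  ev <- make_evals(c(
    replicate(2, list(y = "T", y_pred = "X", K = "None", K_pred = "CT head"),
              simplify = FALSE),
    replicate(3, list(y = "T", y_pred = "T", K = "None", K_pred = "None"),
              simplify = FALSE),
    replicate(5, list(y = "T", y_pred = "T", K = "CT head", K_pred = "CT head"),
              simplify = FALSE)
  ))
  # 2 of 10 cases: no imaging warranted but imaging predicted
  expect_equal(unnecessary_rate(ev, "all"), 0.2)
  # conditional denominator: 2 of the 5 sentinel-truth cases
  expect_equal(unnecessary_rate(ev, "conditional"), 0.4)
  expect_equal(missed_rate(ev, "all"), 0)

  ev_fn <- make_evals(c(
    list(list(y = "T", y_pred = "X", K = "CT head", K_pred = "None")),
    replicate(7, list(y = "T", y_pred = "T", K = "CT head", K_pred = "CT head"),
              simplify = FALSE)
  ))
  expect_equal(missed_rate(ev_fn, "all"), 0.125)
  expect_equal(missed_rate(ev_fn, "conditional"), 0.125)

  all_sentinel <- make_evals(replicate(4,
    list(y = "T", y_pred = "X", K = "CT head", K_pred = "None"), simplify = FALSE))
  expect_equal(missed_rate(all_sentinel, "conditional"), 1)

  perfect <- make_evals(replicate(3,
    list(y = "T", y_pred = "T", K = "None", K_pred = "None"), simplify = FALSE))
  expect_equal(unnecessary_rate(perfect), 0)
  expect_equal(missed_rate(perfect), 0)
})

test_that("F1 follows 2TP / (2TP + FP + FN) against a counting oracle", {
  # TP = 3 (indicated study ordered), FP = 1, FN = 1 -> F1 = 6/8
  ev <- make_evals(c(
    replicate(3, list(y = "T", y_pred = "T", K = "CT head", K_pred = "CT head"),
              simplify = FALSE),
    list(list(y = "T", y_pred = "X", K = "None", K_pred = "CT head")),
    list(list(y = "T", y_pred = "X", K = "CT head", K_pred = "None"))
  ))
  expect_equal(f1_score(ev), 0.75)

  # TP = 0, FP = 1, FN = 1 -> 0
  ev0 <- make_evals(list(
    list(y = "T", y_pred = "X", K = "None", K_pred = "CT head"),
    list(y = "T", y_pred = "X", K = "CT head", K_pred = "None")
  ))
  expect_equal(f1_score(ev0), 0)

  perfect <- make_evals(replicate(4,
    list(y = "T", y_pred = "T", K = "CT head", K_pred = "CT head"), simplify = FALSE))
  expect_equal(f1_score(perfect), 1)

  # no TP/FP/FN at all (all-sentinel agreement) -> undefined
  none <- make_evals(list(list(y = "T", y_pred = "T", K = "None", K_pred = "None")))
  expect_error(f1_score(none), "undefined")

  # randomized counting-oracle comparison, invariant to row order
  set.seed(99)
  pool <- list(
    list(y = "T", y_pred = "T", K = "CT head", K_pred = "CT head"),
    list(y = "T", y_pred = "X", K = "None", K_pred = "CT head"),
    list(y = "T", y_pred = "X", K = "CT head", K_pred = "None"),
    list(y = "T", y_pred = "X", K = "CT head", K_pred = c("CT head", "US neck"))
  )
  rows <- pool[sample(1:4, 30, replace = TRUE)]
  ev_r <- make_evals(rows)
  tp <- sum(vapply(rows, function(r) any(r$K_pred %in% r$K & r$K_pred != "None"), logical(1)))
  fp <- sum(vapply(rows, function(r) identical(r$K, "None") && !"None" %in% r$K_pred, logical(1)))
  fn <- sum(vapply(rows, function(r) !"None" %in% r$K && identical(r$K_pred, "None"), logical(1)))
  expect_equal(f1_score(ev_r), 2 * tp / (2 * tp + fp + fn))
  expect_equal(f1_score(ev_r[sample(nrow(ev_r)), ]), f1_score(ev_r))
})

test_that("Dice-Sorensen coefficient: extremes, symmetry, half overlap", {
  expect_equal(dice_sorensen(c("A", "B"), c("A", "B")), 1)
  expect_equal(dice_sorensen(c("A"), c("B")), 0)
  expect_equal(dice_sorensen(c("A", "B"), c("B", "C")), 0.5)
  expect_equal(dice_sorensen(c("A", "B"), c("B", "C")),
               dice_sorensen(c("B", "C"), c("A", "B")))
  expect_error(dice_sorensen(character(), character()), "both sets empty")
  # equals 1 iff sets are equal
  set.seed(4)
  for (i in 1:20) {
    A <- sample(LETTERS[1:5], sample(1:4, 1))
    B <- sample(LETTERS[1:5], sample(1:4, 1))
    expect_equal(dice_sorensen(A, B) == 1, setequal(A, B))
  }
})

test_that("pairwise DSC aggregates per-case values with a t-interval", {
  o1 <- list(c("A", "B"), c("A"), c("C", "D"))
  o2 <- list(c("B", "C"), c("A"), c("E"))
  res <- pairwise_dsc(o1, o2)
  expect_equal(res$per_case, c(0.5, 1, 0))
  expect_equal(res$mean, 0.5)
  expect_equal(res$n, 3)
  expect_lt(res$ci95[1], res$mean)
  expect_error(pairwise_dsc(o1, o2[1:2]), "same cases")
})

test_that("mean_ci gives Student-t intervals with the documented coverage", {
  ci <- mean_ci(rep(0.7, 5))
  expect_equal(c(ci$low, ci$mean, ci$high), c(0.7, 0.7, 0.7))
  ci2 <- mean_ci(c(0, 1))
  expect_equal(ci2$mean, 0.5)
  expect_equal(ci2$high - ci2$mean, ci2$mean - ci2$low)
  expect_error(mean_ci(1), "at least 2")

  set.seed(7)
  covered <- vapply(seq_len(1000), function(i) {
    ci <- mean_ci(stats::rnorm(200))
    ci$low <= 0 && 0 <= ci$high
  }, logical(1))
  sigma <- sqrt(0.95 * 0.05 / 1000)
  expect_lt(abs(mean(covered) - 0.95), 3 * sigma)
})

test_that("comparison tests behave on degenerate and symmetric inputs", {
  x <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(t_test(x, x)$p_value, 1, tolerance = 1e-12)
  expect_error(t_test(rep(1, 4), rep(1, 4)), "degenerate")
  expect_error(paired_t_test(1:4, 0:3), "degenerate")
  # symmetric discordance (5, 5) -> exact binomial p = 1
  xb <- c(rep(1, 5), rep(0, 5), rep(1, 10))
  yb <- c(rep(0, 5), rep(1, 5), rep(1, 10))
  mc <- mcnemar_test(xb, yb)
  expect_equal(mc$p_value, 1)
  expect_equal(mc$discordant, c(5, 5))
  expect_match(mc$method, "exact")
  # one-tailed direction is supplied by the caller
  a <- c(5, 6, 7, 8); b <- c(1, 2, 3, 4)
  expect_lt(t_test(a, b, "greater")$p_value, t_test(a, b, "two.sided")$p_value)
})

test_that("metric report fields are consistent with the underlying metrics", {
  kb <- make_kb(seed = 44)
  cases <- make_cases(kb, 4, seed = 44)
  be <- make_confusion_backend(kb, cases, sibling_confusion(kb, p = 0.5))
  cfg <- run_config("evidence", prompt_spec("topic_prediction", "baseline"), seeds = 0:2)
  ev <- run_benchmark(cases, cfg, be, kb)
  rep <- metric_report(ev)
  expect_equal(rep$topic_accuracy, topic_accuracy(ev))
  expect_equal(rep$imaging_accuracy, mean(case_imaging_accuracy(ev)))
  expect_equal(rep$fpr, unnecessary_rate(ev, "all"))
  expect_equal(rep$n_rows, nrow(ev))
  expect_equal(nrow(rep$per_seed), 3)
  expect_true(all(unlist(rep[c("topic_accuracy", "imaging_accuracy", "fpr", "fnr")]) >= 0))
  expect_true(all(unlist(rep[c("topic_accuracy", "imaging_accuracy", "fpr", "fnr")]) <= 1))
  for (m in colnames(rep$per_seed)) {
    expect_lte(rep$ci95[[m]][1], mean(rep$per_seed[, m]) + 1e-12)
    expect_gte(rep$ci95[[m]][2], mean(rep$per_seed[, m]) - 1e-12)
  }
})
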