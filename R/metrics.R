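#' Set-based imaging-appropriateness metrics and study statistics
#'
#' All metrics operate on evaluation tibbles as produced by the pipelines:
#' one row per case per seed with ground-truth Topic `y`, predicted Topics
#' `y_pred`, the guideline-appropriate study set `K`, and the predicted study
#' set `K_pred`. The no-imaging sentinel is recognized via [is_sentinel()].
#'
#' @name eval_metrics
#' @keywords internal
NULL

#' Imaging accuracy of one prediction
#'
#' The fraction of recommended studies that are guideline-appropriate:
#' `|K_pred n K| / |K_pred|`. An empty prediction (unparsed model output)
#' scores 0 by convention.
#'
#' @param K_pred predicted study set (character vector).
#' @param K ground-truth appropriate-study set (non-empty character vector).
#' @return a fraction in \[0, 1\].
#' @export
imaging_accuracy <- function(K_pred, K) {
  stopifnot(length(K) > 0)
  if (length(K_pred) == 0) return(0)
  K_pred <- unique(K_pred)
  length(intersect(norm_key(K_pred), norm_key(K))) / length(K_pred)
}

#' Per-case imaging accuracies of an evaluation set
#' @param evals evaluation tibble.
#' @return numeric vector, one value per row.
#' @export
case_imaging_accuracy <- function(evals) {
  vapply(seq_len(nrow(evals)), function(i) {
    imaging_accuracy(evals$K_pred[[i]], evals$K[[i]])
  }, numeric(1))
}

#' Topic accuracy of an evaluation set
#'
#' Mean of exact-match indicators. For multi-topic predictions (`m > 1`) a
#' case counts as correct iff the single ground-truth Topic appears among the
#' predicted Topics. Unparsed cases (empty prediction) count as wrong.
#'
#' @param evals non-empty evaluation tibble.
#' @return fraction in \[0, 1\].
#' @export
topic_accuracy <- function(evals) {
  if (nrow(evals) == 0) stop("empty evaluation set", call. = FALSE)
  mean(vapply(seq_len(nrow(evals)), function(i) {
    norm_key(evals$y[i]) %in% norm_key(evals$y_pred[[i]])
  }, logical(1)))
}

# per-case indicator: ground truth warrants no imaging but imaging was ordered
.fp_indicator <- function(evals) {
  vapply(seq_len(nrow(evals)), function(i) {
    K <- evals$K[[i]]; Kp <- evals$K_pred[[i]]
    length(K) == 1 && is_sentinel(K) && !any(is_sentinel(Kp))
  }, logical(1))
}

# per-case indicator: imaging warranted but only "no imaging" was ordered
.fn_indicator <- function(evals) {
  vapply(seq_len(nrow(evals)), function(i) {
    K <- evals$K[[i]]; Kp <- evals$K_pred[[i]]
    !any(is_sentinel(K)) && length(Kp) == 1 && is_sentinel(Kp)
  }, logical(1))
}

# per-case indicator: a clinically indicated (non-sentinel) study was ordered
.tp_indicator <- function(evals) {
  vapply(seq_len(nrow(evals)), function(i) {
    hit <- intersect(norm_key(evals$K_pred[[i]]), norm_key(evals$K[[i]]))
    length(hit) > 0 && !all(hit %in% norm_key(SENTINEL_NAME))
  }, logical(1))
}

#' Rate of unnecessary imaging recommendations (false positive rate)
#'
#' Frequency of cases where (1) the guideline set `K` is exactly the
#' no-imaging sentinel and (2) the sentinel is not among the predicted
#' studies. `denominator = "all"` divides by all evaluated cases (the
#' default); `"conditional"` divides by the cases satisfying condition (1)
#' only, i.e. the rate *among patients for whom no imaging is warranted*.
#'
#' @param evals evaluation tibble.
#' @param denominator `"all"` or `"conditional"`.
#' @return fraction in \[0, 1\] (0 when the conditional denominator is empty).
#' @export
unnecessary_rate <- function(evals, denominator = c("all", "conditional")) {
  denominator <- match.arg(denominator)
  if (nrow(evals) == 0) stop("empty evaluation set", call. = FALSE)
  fp <- .fp_indicator(evals)
  if (denominator == "all") return(mean(fp))
  cond <- vapply(seq_len(nrow(evals)), function(i) {
    length(evals$K[[i]]) == 1 && is_sentinel(evals$K[[i]])
  }, logical(1))
  if (sum(cond) == 0) return(0)
  sum(fp) / sum(cond)
}

#' Rate of missed imaging recommendations (false negative rate)
#'
#' Mirror of [unnecessary_rate()]: frequency of cases where (1) imaging is
#' warranted (sentinel not in `K`) and (2) the prediction is exactly the
#' sentinel.
#'
#' @inheritParams unnecessary_rate
#' @return fraction in \[0, 1\].
#' @export
missed_rate <- function(evals, denominator = c("all", "conditional")) {
  denominator <- match.arg(denominator)
  if (nrow(evals) == 0) stop("empty evaluation set", call. = FALSE)
  fn <- .fn_indicator(evals)
  if (denominator == "all") return(mean(fn))
  cond <- vapply(seq_len(nrow(evals)), function(i) {
    !any(is_sentinel(evals$K[[i]]))
  }, logical(1))
  if (sum(cond) == 0) return(0)
  sum(fn) / sum(cond)
}

#' F1 score of an evaluation set
#'
#' `F1 = 2 TP / (2 TP + FP + FN)` where TP counts cases in which a clinically
#' indicated (non-sentinel) study was ordered, FP counts unnecessary-imaging
#' cases and FN counts missed-imaging cases (the numerators of
#' [unnecessary_rate()] and [missed_rate()]).
#'
#' @param evals evaluation tibble.
#' @return fraction in \[0, 1\].
#' @export
f1_score <- function(evals) {
  if (nrow(evals) == 0) stop("empty evaluation set", call. = FALSE)
  tp <- sum(.tp_indicator(evals))
  fp <- sum(.fp_indicator(evals))
  fn <- sum(.fn_indicator(evals))
  if (2 * tp + fp + fn == 0) {
    stop("F1 undefined: no true positives, false positives or false negatives",
         call. = FALSE)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Dice-Sorensen coefficient between two study sets
#'
#' `DSC(A, B) = 2 |A n B| / (|A| + |B|)`: 1 iff the sets are equal, 0 iff
#' disjoint; symmetric.
#'
#' @param A,B character vectors (sets); not both empty.
#' @return fraction in \[0, 1\].
#' @export
dice_sorensen <- function(A, B) {
  A <- unique(norm_key(A)); B <- unique(norm_key(B))
  if (length(A) + length(B) == 0) stop("both sets empty", call. = FALSE)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

#' Pairwise Dice-Sorensen similarity between two decision makers
#'
#' Both arguments are lists of per-case ordered study sets over the same case
#' index set. Returns the per-case DSC values with their mean and a 95%
#' t-interval over cases.
#'
#' @param orders1,orders2 lists of character vectors, equal length.
#' @return list with `per_case`, `mean`, `ci95` (length-2), `n`.
#' @export
pairwise_dsc <- function(orders1, orders2) {
  if (length(orders1) != length(orders2)) {
    stop("decision makers must cover the same cases", call. = FALSE)
  }
  per_case <- vapply(seq_along(orders1), function(i) {
    dice_sorensen(orders1[[i]], orders2[[i]])
  }, numeric(1))
  ci <- mean_ci(per_case)
  list(per_case = per_case, mean = ci$mean, ci95 = c(ci$low, ci$high),
       n = length(per_case))
}

#' Mean with a Student-t confidence interval
#'
#' @param values numeric vector, length >= 2.
#' @param level confidence level (default 0.95).
#' @return list with `mean`, `low`, `high`.
#' @export
mean_ci <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a confidence interval", call. = FALSE)
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  list(mean = m, low = m - tq * se, high = m + tq * se)
}

#' Two-sample homoscedastic t-test
#'
#' Pooled-variance t-test, one- or two-tailed. The one-tailed direction is
#' supplied by the caller via `alternative`.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (mean of `x` greater) or
#'   `"less"`.
#' @return list with `statistic`, `p_value`, `df`, `method`.
#' @export
t_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
    stop("degenerate variance: both samples are constant", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = TRUE, alternative = alternative)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), method = "two-sample homoscedastic t-test")
}

#' Paired t-test
#'
#' @param x,y paired numeric samples of equal length.
#' @param alternative as in [t_test()].
#' @return list with `statistic`, `p_value`, `df`, `method`.
#' @export
paired_t_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("paired samples must have equal length", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("degenerate variance: all pairwise differences are equal", call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), method = "paired t-test")
}

#' McNemar test for paired binary outcomes
#'
#' Exact binomial test on the discordant pairs when there are fewer than 25
#' of them, otherwise the chi-square test with continuity correction.
#'
#' @param x,y paired binary (0/1 or logical) vectors.
#' @return list with `statistic` (`NA` for the exact form), `p_value`,
#'   `discordant` (the two discordant counts), `method`.
#' @export
mcnemar_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length", call. = FALSE)
  x <- as.integer(as.logical(x)); y <- as.integer(as.logical(y))
  b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1)
  if (b + c_ == 0) {
    return(list(statistic = NA_real_, p_value = 1, discordant = c(b, c_),
                method = "McNemar exact binomial (no discordant pairs)"))
  }
  if (b + c_ < 25) {
    ht <- stats::binom.test(b, b + c_, p = 0.5)
    list(statistic = NA_real_, p_value = ht$p.value, discordant = c(b, c_),
         method = "McNemar exact binomial")
  } else {
    stat <- (abs(b - c_) - 1)^2 / (b + c_)
    list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         discordant = c(b, c_), method = "McNemar chi-square (continuity corrected)")
  }
}

#' Full metric report over an evaluation set
#'
#' Overall metrics are computed over all rows (cases x seeds); per-seed means
#' and 95% t-intervals over seeds are reported when the set spans at least
#' two seeds. Both false-rate denominators are included.
#'
#' @param evals evaluation tibble.
#' @param denominator primary denominator mode for `fpr` / `fnr`.
#' @return an object of class `metric_report`.
#' @export
metric_report <- function(evals, denominator = c("all", "conditional")) {
  denominator <- match.arg(denominator)
  if (nrow(evals) == 0) stop("empty evaluation set", call. = FALSE)
  seeds <- sort(unique(evals$seed))
  per_seed <- lapply(seeds, function(s) {
    e <- evals[evals$seed == s, , drop = FALSE]
    c(topic_accuracy = topic_accuracy(e),
      imaging_accuracy = mean(case_imaging_accuracy(e)),
      fpr = unnecessary_rate(e, denominator),
      fnr = missed_rate(e, denominator))
  })
  per_seed <- do.call(rbind, per_seed)
  rownames(per_seed) <- as.character(seeds)
  ci <- if (length(seeds) >= 2) {
    lapply(colnames(per_seed), function(m) {
      x <- mean_ci(per_seed[, m]); c(x$low, x$high)
    })
  } else NULL
  if (!is.null(ci)) names(ci) <- colnames(per_seed)

  f1 <- tryCatch(f1_score(evals), error = function(e) NA_real_)
  structure(list(
    topic_accuracy = topic_accuracy(evals),
    imaging_accuracy = mean(case_imaging_accuracy(evals)),
    fpr = unnecessary_rate(evals, denominator),
    fnr = missed_rate(evals, denominator),
    fpr_conditional = unnecessary_rate(evals, "conditional"),
    fnr_conditional = missed_rate(evals, "conditional"),
    f1 = f1,
    unparsed_fraction = mean(evals$unparsed),
    n_cases = length(unique(evals$id)),
    n_rows = nrow(evals),
    seeds = seeds,
    per_seed = per_seed,
    ci95 = ci,
    denominator = denominator
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d cases x %d seed(s) (%d rows)\n",
              x$n_cases, length(x$seeds), x$n_rows))
  cat(sprintf("  topic accuracy   %.3f\n", x$topic_accuracy))
  cat(sprintf("  imaging accuracy %.3f\n", x$imaging_accuracy))
  cat(sprintf("  FPR (%s) %.3f | FNR (%s) %.3f | F1 %.3f\n",
              x$denominator, x$fpr, x$denominator, x$fnr, x$f1))
  if (x$unparsed_fraction > 0) {
    cat(sprintf("  unparsed fraction %.3f\n", x$unparsed_fraction))
  }
  invisible(x)
}
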