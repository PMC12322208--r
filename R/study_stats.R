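#' Prospective-study regression: linear probability model with question fixed
#' effects and two-way cluster-robust standard errors
#'
#' The reader-study model regresses a binary per-response outcome on a
#' guidance indicator, question fixed effects and participant covariates:
#'
#' \deqn{y_{s,q} = \beta_0 + \beta_1 \cdot \mathrm{guidance}_{s,q} +
#'   \theta_q + \chi_s + \varepsilon_{s,q}}
#'
#' fitted by OLS (a linear probability model), with the variance of the
#' coefficients estimated by two-way clustering on participants and questions
#' (Cameron-Gelbach-Miller): `V = V_s + V_q - V_{s^q}`, where each component
#' is a clustered sandwich with the small-sample correction
#' `G/(G-1) * (N-1)/(N-K)` and `V_{s^q}` clusters on the
#' participant-by-question intersection. Inference uses a t distribution with
#' `min(G_s, G_q) - 1` degrees of freedom. The CGM difference can leave `V`
#' indefinite; if the guidance-coefficient variance itself comes out
#' non-positive, negative eigenvalues of `V` are truncated to zero (with a
#' message) before standard errors are taken.
#'
#' @name study_stats
#' @keywords internal
NULL

# clustered meat: sum over clusters g of (X_g' u_g)(X_g' u_g)'
.cluster_meat <- function(X, u, cluster) {
  Xu <- X * u
  S <- rowsum(Xu, group = cluster)
  crossprod(as.matrix(S))
}

#' Fit the guidance regression with two-way clustered standard errors
#'
#' @param responses tibble with one row per (participant, question): columns
#'   `participant`, `question`, `with_llm_guidance` (0/1), the outcome column,
#'   and optionally the participant covariates `role` (`"student"` /
#'   `"physician"`), `ai_experience` and `ai_sentiment`.
#' @param outcome_field name of the binary outcome column (default
#'   `"outcome"`; use `"agreement"` after [agreement_outcome()]).
#' @return an object of class `guidance_fit`: `beta0`, `beta1`, `se_beta1`,
#'   `ci95`, `p_value`, `df`, `n_fixed_effects`, `clusters` (participant /
#'   question counts), `n`, `coefficients`, `residual_summary`,
#'   `truncated_eigenvalues`.
#' @export
fit_guidance_model <- function(responses, outcome_field = "outcome") {
  need <- c("participant", "question", "with_llm_guidance", outcome_field)
  miss <- setdiff(need, names(responses))
  if (length(miss) > 0) {
    stop("responses missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(paste(responses$participant, responses$question))) {
    stop("responses must have one record per (participant, question)", call. = FALSE)
  }
  y <- as.numeric(responses[[outcome_field]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  part <- as.factor(responses$participant)
  ques <- as.factor(responses$question)
  Gs <- nlevels(part); Gq <- nlevels(ques)
  if (Gs < 2 || Gq < 2) {
    stop("need at least 2 clusters in each dimension (participants: ", Gs,
         ", questions: ", Gq, ")", call. = FALSE)
  }

  guidance <- as.numeric(responses$with_llm_guidance)
  X <- cbind(`(Intercept)` = 1, with_llm_guidance = guidance)
  if (Gq > 1) {
    Q <- stats::model.matrix(~ ques)[, -1, drop = FALSE]
    colnames(Q) <- paste0("question_", levels(ques)[-1])
    X <- cbind(X, Q)
  }
  for (cov in c("role", "ai_experience", "ai_sentiment")) {
    if (cov %in% names(responses)) {
      v <- responses[[cov]]
      v <- if (cov == "role") as.numeric(v == "physician") else as.numeric(v)
      if (stats::var(v) > 0) {
        X <- cbind(X, v)
        colnames(X)[ncol(X)] <- cov
      }
    }
  }
  n <- nrow(X); K <- ncol(X)

  qrX <- qr(X)
  if (qrX$rank < K) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):K]]
    stop("singular design: column(s) collinear with the rest of the model: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  u <- y - as.vector(X %*% beta)

  degenerate <- stats::var(y) == 0 || sum(u^2) < 1e-24
  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))

  cgm_part <- function(cluster) {
    G <- length(unique(cluster))
    corr <- (G / (G - 1)) * ((n - 1) / (n - K))
    corr * XtXinv %*% .cluster_meat(X, u, cluster) %*% XtXinv
  }
  inter <- interaction(part, ques, drop = TRUE)
  V <- cgm_part(part) + cgm_part(ques) - cgm_part(inter)

  # The inclusion-exclusion difference can leave V indefinite. The raw
  # guidance variance is kept whenever it is positive (truncating the whole
  # matrix would distort it); the eigenvalue guard only fires when the
  # variance of interest itself is non-positive.
  n_trunc <- 0L
  if (V["with_llm_guidance", "with_llm_guidance"] <= 0) {
    eig <- eigen((V + t(V)) / 2, symmetric = TRUE)
    n_trunc <- sum(eig$values < 0)
    message("two-way clustered variance: guidance variance non-positive; ",
            "truncated ", n_trunc, " negative eigenvalue(s) to zero")
    V <- eig$vectors %*% diag(pmax(eig$values, 0), K) %*% t(eig$vectors)
    dimnames(V) <- list(colnames(X), colnames(X))
  }

  b1 <- unname(beta["with_llm_guidance"])
  se1 <- sqrt(max(V["with_llm_guidance", "with_llm_guidance"], 0))
  df <- min(Gs, Gq) - 1
  if (degenerate || se1 == 0) {
    warning("degenerate variance: outcome is perfectly fit; ",
            "standard errors are zero", call. = FALSE)
    p <- 1
    ci <- c(b1, b1)
  } else {
    tstat <- b1 / se1
    p <- 2 * stats::pt(-abs(tstat), df = df)
    tq <- stats::qt(0.975, df = df)
    ci <- c(b1 - tq * se1, b1 + tq * se1)
  }

  structure(list(
    beta0 = unname(beta["(Intercept)"]),
    beta1 = b1, se_beta1 = se1, ci95 = ci, p_value = p, df = df,
    n_fixed_effects = Gq - 1,
    clusters = c(participants = Gs, questions = Gq),
    n = n, coefficients = beta, vcov = V,
    residual_summary = summary(u),
    truncated_eigenvalues = n_trunc,
    outcome_field = outcome_field
  ), class = "guidance_fit")
}

#' @export
print.guidance_fit <- function(x, ...) {
  cat(sprintf(
    "<guidance_fit> outcome '%s': beta1 = %.4f (95%% CI %.4f to %.4f), p = %.4g\n",
    x$outcome_field, x$beta1, x$ci95[1], x$ci95[2], x$p_value))
  cat(sprintf("  n = %d responses, %d participants x %d questions, %d fixed effects\n",
              x$n, x$clusters["participants"], x$clusters["questions"],
              x$n_fixed_effects))
  invisible(x)
}

#' Derive the LLM-agreement outcome for the guidance regression
#'
#' Agreement is 1 iff the participant's ordered study equals the model's
#' recommendation for that question under study-name normalization. A
#' recommendation must exist for every question that could show guidance.
#'
#' @param responses tibble with columns `participant`, `question`, `answer`
#'   (the study the participant ordered).
#' @param llm_recommendations named character vector or list mapping question
#'   id to the recommended study.
#' @return `responses` with an added binary `agreement` column.
#' @export
agreement_outcome <- function(responses, llm_recommendations) {
  stopifnot("answer" %in% names(responses))
  qids <- as.character(responses$question)
  missing_q <- setdiff(unique(qids), names(llm_recommendations))
  if (length(missing_q) > 0) {
    stop("missing LLM recommendation for question(s): ",
         paste(missing_q, collapse = ", "), call. = FALSE)
  }
  rec <- vapply(qids, function(q) as.character(llm_recommendations[[q]]), "")
  responses$agreement <- as.integer(
    norm_key(responses$answer) == norm_key(rec) |
      (is_sentinel(responses$answer) & is_sentinel(rec))
  )
  responses
}

#' Randomize per-participant guidance assignment
#'
#' For each participant, a uniform random subset of exactly
#' `floor(fraction * length(questions))` questions is flagged to show
#' model-generated guidance. Deterministic for a fixed seed.
#'
#' @param questions vector of question ids.
#' @param participants vector of participant ids.
#' @param fraction fraction of questions guided per participant (default 0.5;
#'   `fraction * length(questions)` must be an integer).
#' @param seed RNG seed.
#' @return tibble with columns `participant`, `question`,
#'   `with_llm_guidance` (0/1), one row per pair.
#' @export
guidance_randomization <- function(questions, participants, fraction = 0.5,
                                   seed = 0L) {
  nq <- length(questions)
  n_guided <- fraction * nq
  if (abs(n_guided - round(n_guided)) > 1e-9) {
    stop("fraction * number of questions must be an integer", call. = FALSE)
  }
  n_guided <- as.integer(floor(n_guided + 0.5))
  grids <- with_seed(seed, {
    lapply(participants, function(p) {
      guided <- sample(seq_len(nq), n_guided, replace = FALSE)
      tibble::tibble(
        participant = as.character(p),
        question = as.character(questions),
        with_llm_guidance = as.integer(seq_len(nq) %in% guided)
      )
    })
  })
  do.call(rbind, grids)
}
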