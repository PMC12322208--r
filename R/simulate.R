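#' Synthetic fixtures: miniature knowledge bases, labeled one-liners,
#' confusion-driven mock backends, and prospective reader-study grids
#'
#' Every generator is a pure function of (spec, seed) and produces artifacts
#' that pass the validators of the modules that consume them. The defaults
#' mirror the study conditions the methods were designed for: five-seed
#' benchmark runs, sibling Topics that share identical appropriate-study
#' sets, a reader study with 30 participants (23 students, 7 physicians)
#' answering 50 questions with guidance shown on a random half, and a true
#' guidance effect of 0.081 on the probability scale on a no-guidance base
#' rate of 0.158.
#'
#' @name synthetic_fixtures
#' @keywords internal
NULL

#' Specification for the synthetic generators
#'
#' @param n_topics number of guideline Topics (including one no-imaging
#'   Topic).
#' @param n_studies number of real imaging studies in the vocabulary (the
#'   sentinel is added on top).
#' @param n_sibling_pairs number of Topic pairs constrained to share an
#'   identical canonical study set.
#' @param n_cases_per_topic labeled one-liners generated per Topic.
#' @param unparsed_rate probability that the confusion backend emits
#'   non-matching text instead of a Topic.
#' @param n_participants,n_students reader-study participants (students are
#'   the first `n_students`; the rest are physicians).
#' @param n_questions reader-study questions per participant.
#' @param beta0 no-guidance success probability.
#' @param beta1 true guidance effect on the probability scale.
#' @param question_sd standard deviation of the question fixed effects.
#' @param role_effect,ai_experience_effect,ai_sentiment_effect participant
#'   covariate effects on the probability scale.
#' @param guidance_fraction fraction of questions guided per participant.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_topics = 6, n_studies = 8, n_sibling_pairs = 1,
                            n_cases_per_topic = 10, unparsed_rate = 0,
                            n_participants = 30, n_students = 23,
                            n_questions = 50, beta0 = 0.158, beta1 = 0.081,
                            question_sd = 0.05, role_effect = 0.02,
                            ai_experience_effect = 0.01,
                            ai_sentiment_effect = 0.01,
                            guidance_fraction = 0.5) {
  spec <- as.list(environment())
  stopifnot(n_topics > 0, n_studies >= 2, n_sibling_pairs >= 0,
            n_cases_per_topic > 0, unparsed_rate >= 0, unparsed_rate <= 1,
            n_participants >= 2, n_students <= n_participants,
            n_questions >= 2, guidance_fraction > 0, guidance_fraction < 1)
  structure(spec, class = "simulation_spec")
}

# name pools for synthetic studies and topics; combined with indices so any
# requested size stays unique
.modalities <- c("CT", "MRI", "US", "Radiography", "CTA", "Fluoroscopy",
                 "Nuclear medicine scan", "Mammography")
.body_parts <- c("head", "chest", "abdomen", "pelvis", "spine", "knee",
                 "shoulder", "neck")
.complaints <- c("acute chest pain", "chronic headache", "right lower quadrant pain",
                 "low back pain", "dyspnea on exertion", "acute knee injury",
                 "palpable breast mass", "transient vision loss", "syncope",
                 "hematuria", "chronic cough", "dysphagia")

#' Generate a miniature guideline knowledge base
#'
#' The KB always contains: one no-imaging sentinel in the vocabulary, at
#' least one Topic whose canonical variant resolves to the sentinel, and
#' `n_sibling_pairs` Topic pairs whose canonical variants share an identical
#' study set (the mechanism behind "wrong Topic, right studies"). Every Topic
#' carries 1-3 variants with exactly one canonical. Passes [validate_kb()].
#'
#' @param spec a [simulation_spec()].
#' @param seed RNG seed; the KB is a pure function of (spec, seed).
#' @return a `guideline_kb` with attribute `"sibling_pairs"` (list of
#'   2-element topic-name vectors).
#' @export
make_kb <- function(spec = simulation_spec(), seed = 0L) {
  n_topics <- spec$n_topics
  n_studies <- spec$n_studies
  n_sib <- spec$n_sibling_pairs
  if (n_topics < 2 * n_sib + 1) {
    stop("impossible constraints: need n_topics >= 2 * n_sibling_pairs + 1 ",
         "(one topic is reserved for the no-imaging sentinel)", call. = FALSE)
  }
  grid <- expand.grid(m = .modalities, b = .body_parts, stringsAsFactors = FALSE)
  if (n_studies > nrow(grid)) {
    stop("impossible constraints: at most ", nrow(grid), " distinct studies",
         call. = FALSE)
  }

  with_seed(seed, {
    studies <- paste(grid$m, grid$b)[sample.int(nrow(grid), n_studies)]
    vocab <- c(SENTINEL_NAME, studies)

    complaints <- rep_len(.complaints, n_topics)
    topic_names <- sprintf("Suspected %s (scenario %d)", complaints, seq_len(n_topics))

    rand_set <- function() sort(sample(studies, sample.int(min(3, n_studies), 1)))
    make_variant <- function(st, canonical, i = 1) {
      list(description = sprintf("Clinical variant %d. Initial imaging.", i),
           canonical = canonical, studies = st)
    }
    make_topic <- function(name, canonical_set) {
      n_var <- sample.int(3, 1)
      canon_at <- sample.int(n_var, 1)
      variants <- lapply(seq_len(n_var), function(i) {
        if (i == canon_at) make_variant(canonical_set, TRUE, i)
        else make_variant(rand_set(), FALSE, i)
      })
      list(name = name, panel = sample(c("Neurologic", "Thoracic", "Musculoskeletal",
                                         "Gastrointestinal", "Cardiac"), 1),
           variants = variants)
    }

    topics <- vector("list", n_topics)
    # topic 1 resolves to the sentinel
    topics[[1]] <- make_topic(topic_names[1], SENTINEL_NAME)
    sibling_pairs <- list()
    idx <- 2L
    for (p in seq_len(n_sib)) {
      shared <- rand_set()
      topics[[idx]] <- make_topic(topic_names[idx], shared)
      topics[[idx + 1L]] <- make_topic(topic_names[idx + 1L], shared)
      sibling_pairs[[p]] <- c(topic_names[idx], topic_names[idx + 1L])
      idx <- idx + 2L
    }
    while (idx <= n_topics) {
      topics[[idx]] <- make_topic(topic_names[idx], rand_set())
      idx <- idx + 1L
    }

    kb <- new_guideline_kb(version_date = "synthetic-2024-06",
                           topics = topics, study_vocabulary = vocab)
    attr(kb, "sibling_pairs") <- sibling_pairs
    kb
  })
}

#' Generate labeled synthetic one-liners for a knowledge base
#'
#' Telegraphic clinical style ("<age> <sex> with <risk factors> p/w
#' <complaint>") so the sentence splitter and the prompt plumbing face
#' realistic text. Exactly `n_per_topic` cases per Topic, shuffled; every
#' label resolves in `kb`; texts are pairwise distinct.
#'
#' @param kb a `guideline_kb` (typically from [make_kb()]).
#' @param n_per_topic cases per Topic.
#' @param seed RNG seed.
#' @param subset subset tag for the generated records.
#' @return a one-liner record tibble.
#' @export
make_cases <- function(kb, n_per_topic = 10, seed = 0L, subset = "Synthetic") {
  tnames <- kb_topic_names(kb)
  with_seed(seed, {
    labels <- sample(rep(tnames, n_per_topic))
    n <- length(labels)
    # per-topic running index -> injective (age, pack-year) pair, so texts
    # stay pairwise distinct at any n_per_topic
    j <- stats::ave(seq_len(n), labels, FUN = seq_along)
    ages <- 18 + (j - 1) %% 78
    sexes <- sample(c("M", "F"), n, replace = TRUE)
    risks <- sprintf("%d pack-year smoking hx", 1 + (j - 1) %/% 78)
    complaint <- sub("^Suspected ", "", sub(" \\(scenario [0-9]+\\)$", "", labels))
    # symptom duration indexes the topic, keeping texts distinct even when
    # complaint wording repeats across topics
    days <- match(labels, tnames)
    texts <- sprintf("%d %s with HTN and %s p/w %s x%dd",
                     ages, sexes, risks, complaint, days)
    stopifnot(!anyDuplicated(texts))
    one_liner_records(
      id = sprintf("case_%04d", seq_len(n)), text = texts,
      subset = subset, label = labels
    )
  })
}

#' Confusion model over Topic emissions
#'
#' Row-stochastic matrix: row `t` is the distribution over Topics that a
#' simulated model emits when the true Topic is `t`, plus a global
#' probability of emitting non-matching (unparseable) text.
#'
#' @param prob square numeric matrix with identical row/column names (Topic
#'   names); rows must sum to 1.
#' @param unparsed_rate probability of emitting non-matching text, applied
#'   before drawing from the row.
#' @return a `confusion_model`.
#' @export
confusion_model <- function(prob, unparsed_rate = 0) {
  stopifnot(is.matrix(prob), nrow(prob) == ncol(prob),
            !is.null(rownames(prob)),
            identical(rownames(prob), colnames(prob)),
            unparsed_rate >= 0, unparsed_rate <= 1)
  if (any(prob < 0) || any(abs(rowSums(prob) - 1) > 1e-9)) {
    stop("confusion rows must be probability vectors summing to 1", call. = FALSE)
  }
  structure(list(prob = prob, unparsed_rate = unparsed_rate),
            class = "confusion_model")
}

#' Identity confusion model (a perfect topic classifier)
#' @param kb a `guideline_kb`.
#' @param unparsed_rate see [confusion_model()].
#' @return a `confusion_model`.
#' @export
identity_confusion <- function(kb, unparsed_rate = 0) {
  tn <- kb_topic_names(kb)
  prob <- diag(length(tn))
  dimnames(prob) <- list(tn, tn)
  confusion_model(prob, unparsed_rate)
}

#' Sibling confusion model
#'
#' Each Topic in a sibling pair emits its sibling with probability `p` and
#' itself with probability `1 - p`; all other Topics emit themselves. Because
#' siblings share identical canonical study sets, this reproduces the
#' "incorrect Topic, correct imaging studies" error mechanism.
#'
#' @param kb a `guideline_kb` carrying a `"sibling_pairs"` attribute (from
#'   [make_kb()]) or an explicit `sibling_pairs` list.
#' @param p sibling-confusion probability.
#' @param sibling_pairs optional list of 2-element topic-name vectors.
#' @param unparsed_rate see [confusion_model()].
#' @return a `confusion_model`.
#' @export
sibling_confusion <- function(kb, p = 0.5, sibling_pairs = NULL,
                              unparsed_rate = 0) {
  pairs <- sibling_pairs %||% attr(kb, "sibling_pairs")
  if (is.null(pairs) || length(pairs) == 0) {
    stop("no sibling pairs available; generate the KB with n_sibling_pairs >= 1",
         call. = FALSE)
  }
  for (pr in pairs) {
    if (!setequal(resolve_topic(kb, pr[1]), resolve_topic(kb, pr[2]))) {
      stop("sibling pair does not share a study set: ",
           paste(pr, collapse = " / "), call. = FALSE)
    }
  }
  tn <- kb_topic_names(kb)
  prob <- diag(length(tn))
  dimnames(prob) <- list(tn, tn)
  for (pr in pairs) {
    for (k in 1:2) {
      a <- pr[k]; b <- pr[3 - k]
      prob[a, a] <- 1 - p
      prob[a, b] <- p
    }
  }
  confusion_model(prob, unparsed_rate)
}

#' Mock backend driven by a confusion model
#'
#' Identifies the case by locating its one-liner text inside the prompt,
#' looks up the true Topic, and emits `"Answer: <topic>"` with the Topic
#' drawn from the confusion row (or non-matching text with probability
#' `unparsed_rate`). The draw is seeded by a hash of (prompt, seed), so the
#' backend satisfies the determinism contract exactly.
#'
#' @param kb a `guideline_kb`.
#' @param cases one-liner record tibble with true labels.
#' @param confusion a `confusion_model` over the KB's Topics.
#' @return a `completion_backend`.
#' @export
make_confusion_backend <- function(kb, cases, confusion) {
  stopifnot(inherits(confusion, "confusion_model"))
  texts <- cases$text
  labels <- cases$label
  topics <- colnames(confusion$prob)
  completion_backend(function(prompt, temperature, seed) {
    hit <- which(vapply(texts, function(tx) grepl(tx, prompt, fixed = TRUE),
                        logical(1)))
    if (length(hit) == 0) return("I cannot determine this.")
    truth <- labels[hit[1]]
    stream <- (content_hash(prompt) + 7919 * (as.numeric(seed) + 1)) %% 2147483647
    with_seed(as.integer(stream), {
      if (confusion$unparsed_rate > 0 &&
          stats::runif(1) < confusion$unparsed_rate) {
        return("The scenario is unclear to me.")
      }
      emitted <- sample(topics, 1, prob = confusion$prob[truth, ])
      paste0("Answer: ", emitted)
    })
  }, label = "confusion-mock")
}

#' Simulate a prospective reader-study response grid
#'
#' Guidance is assigned per participant by [guidance_randomization()]; the
#' outcome is Bernoulli with success probability
#' `clip(beta0 + beta1 * guidance + theta_q + covariate effects)` clipped to
#' \[0, 1\] (a warning reports the clip count when triggered), matching the
#' linear probability model fit by [fit_guidance_model()]. Question effects
#' `theta_q` are centered Gaussian draws; covariates are balanced student /
#' physician roles and 1-5 Likert AI-experience / AI-sentiment scores.
#'
#' @param spec a [simulation_spec()].
#' @param seed RNG seed.
#' @return list with `responses` (tibble: `participant`, `question`,
#'   `with_llm_guidance`, `role`, `ai_experience`, `ai_sentiment`, `outcome`)
#'   and `truth` (the generating parameters, including the realized question
#'   effects).
#' @export
make_prospective_grid <- function(spec = simulation_spec(), seed = 0L) {
  P <- spec$n_participants
  Q <- spec$n_questions
  participants <- sprintf("P%02d", seq_len(P))
  questions <- sprintf("Q%02d", seq_len(Q))

  grid <- guidance_randomization(questions, participants,
                                 fraction = spec$guidance_fraction, seed = seed)
  with_seed(seed + 104729L, {
    theta <- stats::rnorm(Q, 0, spec$question_sd)
    theta <- theta - mean(theta)
    names(theta) <- questions
    role <- c(rep("student", spec$n_students),
              rep("physician", P - spec$n_students))
    ai_exp <- sample.int(5, P, replace = TRUE)
    ai_sent <- sample.int(5, P, replace = TRUE)
    names(role) <- names(ai_exp) <- names(ai_sent) <- participants

    p_raw <- spec$beta0 +
      spec$beta1 * grid$with_llm_guidance +
      theta[grid$question] +
      spec$role_effect * (role[grid$participant] == "physician") +
      spec$ai_experience_effect * (ai_exp[grid$participant] - 3) +
      spec$ai_sentiment_effect * (ai_sent[grid$participant] - 3)
    clipped <- sum(p_raw < 0 | p_raw > 1)
    if (clipped > 0) {
      warning("success probability clipped to [0, 1] for ", clipped,
              " response(s)", call. = FALSE)
    }
    p <- pmin(pmax(p_raw, 0), 1)
    outcome <- stats::rbinom(length(p), 1, p)

    responses <- tibble::tibble(
      participant = grid$participant,
      question = grid$question,
      with_llm_guidance = grid$with_llm_guidance,
      role = unname(role[grid$participant]),
      ai_experience = unname(ai_exp[grid$participant]),
      ai_sentiment = unname(ai_sent[grid$participant]),
      outcome = outcome
    )
    list(responses = responses,
         truth = list(beta0 = spec$beta0, beta1 = spec$beta1,
                      question_effects = theta,
                      role_effect = spec$role_effect,
                      ai_experience_effect = spec$ai_experience_effect,
                      ai_sentiment_effect = spec$ai_sentiment_effect,
                      clipped = clipped))
  })
}
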