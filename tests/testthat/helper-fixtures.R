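# Hand-written miniature knowledge base used across tests. Mirrors the
# structure of the real guideline content: a pulmonary-embolism topic with
# four variants (the third canonical), a no-imaging topic, and a sibling
# topic pair sharing an identical canonical study set.

PE_STUDIES <- c("CTA pulmonary arteries with IV contrast", "V/Q scan lung")

fixture_kb <- function() {
  topics <- list(
    list(
      name = "Suspected Pulmonary Embolism", panel = "Thoracic",
      variants = list(
        list(description = "Low or intermediate pretest probability with a negative D-dimer. Initial imaging.",
             canonical = FALSE, studies = "None"),
        list(description = "Low or intermediate pretest probability with a positive D-dimer. Initial imaging.",
             canonical = FALSE, studies = "CTA pulmonary arteries with IV contrast"),
        list(description = "High pretest probability. Initial imaging.",
             canonical = TRUE, studies = PE_STUDIES),
        list(description = "Pregnant patient. Initial imaging.",
             canonical = FALSE, studies = "V/Q scan lung")
      )
    ),
    list(
      name = "Chronic cough", panel = "Thoracic",
      variants = list(
        list(description = "Chronic cough. Initial imaging.",
             canonical = TRUE, studies = "Radiography chest")
      )
    ),
    list(
      name = "Uncomplicated headache", panel = "Neurologic",
      variants = list(
        list(description = "Primary headache, no red flags. Initial imaging.",
             canonical = TRUE, studies = "None"),
        list(description = "New or progressively worsening headache.",
             canonical = FALSE, studies = "CT head without IV contrast")
      )
    ),
    list(
      name = "Major Blunt Trauma", panel = "Musculoskeletal",
      variants = list(
        list(description = "Hemodynamically stable. Initial imaging.",
             canonical = TRUE, studies = "Radiography trauma series")
      )
    ),
    list(
      name = "Penetrating Torso Trauma", panel = "Musculoskeletal",
      variants = list(
        list(description = "Hemodynamically stable. Initial imaging.",
             canonical = TRUE, studies = "Radiography trauma series")
      )
    )
  )
  kb <- new_guideline_kb(
    version_date = "fixture-2024-06",
    topics = topics,
    study_vocabulary = c(
      "None", "CTA pulmonary arteries with IV contrast", "V/Q scan lung",
      "Radiography chest", "CT head without IV contrast",
      "Radiography trauma series"
    )
  )
  attr(kb, "sibling_pairs") <- list(c("Major Blunt Trauma", "Penetrating Torso Trauma"))
  kb
}

# Build an evaluation tibble directly from per-case (y_pred, K, K_pred) specs,
# bypassing the pipelines, for metric-level tests.
make_evals <- function(rows, seed = 0L, pipeline = "evidence") {
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    tibble::tibble(
      id = sprintf("c%02d", i), seed = as.integer(seed), pipeline = pipeline,
      y = r$y %||% NA_character_,
      y_pred = list(r$y_pred %||% character()),
      K = list(r$K), K_pred = list(r$K_pred),
      unparsed = isTRUE(r$unparsed)
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force BM25 oracle: literal transcription of the Okapi
# formula, computed document by document without any shared code path.
bm25_oracle_scores <- function(query, corpus_texts, k1 = 1.5, b = 0.75) {
  tok <- function(x) {
    t <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
    t[nzchar(t)]
  }
  docs <- lapply(corpus_texts, tok)
  q <- unique(tok(query))
  N <- length(docs)
  avg <- mean(vapply(docs, length, numeric(1)))
  vapply(seq_len(N), function(i) {
    d <- docs[[i]]
    s <- 0
    for (term in q) {
      df <- sum(vapply(docs, function(x) term %in% x, logical(1)))
      if (df == 0) next
      idf <- log(1 + (N - df + 0.5) / (df + 0.5))
      tf <- sum(d == term)
      s <- s + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * length(d) / avg))
    }
    s
  }, numeric(1))
}

# Independent oracle: normal-equations OLS plus a hand-built
# Cameron-Gelbach-Miller sandwich, written from the formulas with base
# matrix algebra (no shared code with the package internals).
cgm_oracle <- function(df, covariates = character()) {
  y <- df$outcome
  ques <- factor(df$question)
  X <- cbind(1, df$with_llm_guidance)
  cn <- c("(Intercept)", "with_llm_guidance")
  for (lev in levels(ques)[-1]) {
    X <- cbind(X, as.numeric(ques == lev))
    cn <- c(cn, paste0("q", lev))
  }
  for (cov in covariates) {
    X <- cbind(X, df[[cov]])
    cn <- c(cn, cov)
  }
  colnames(X) <- cn
  n <- nrow(X); K <- ncol(X)
  XtXinv <- solve(t(X) %*% X)
  beta <- XtXinv %*% t(X) %*% y
  u <- as.vector(y - X %*% beta)
  meat <- function(cl) {
    S <- matrix(0, K, K)
    for (g in unique(cl)) {
      idx <- cl == g
      xg <- t(X[idx, , drop = FALSE]) %*% u[idx]
      S <- S + xg %*% t(xg)
    }
    G <- length(unique(cl))
    (G / (G - 1)) * ((n - 1) / (n - K)) * XtXinv %*% S %*% XtXinv
  }
  V <- meat(df$participant) + meat(df$question) -
    meat(paste(df$participant, df$question))
  list(beta = as.vector(beta), names = cn, V = V,
       se1 = sqrt(V[2, 2]))
}
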