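#' Retrieval: corpus chunking and document ranking for prompt context
#'
#' Retrieval-augmented prompts embed guideline narrative chunks; in-context
#' learning prompts embed labeled example one-liners. Both reuse the same
#' rankers: Okapi BM25 over bag-of-words tokens, cosine similarity over a
#' pluggable embedding function, and a uniform random baseline.
#'
#' @name retrieval
#' @keywords internal
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) `.Random.seed` afterwards so library calls never
#' perturb the caller's random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Tokenize text for bag-of-words retrieval
#'
#' Lowercase, split on non-alphanumeric runs. No stemming, no stop-word
#' removal: the simplest reproducible choice.
#'
#' @param text character vector.
#' @return list of character token vectors.
#' @export
bow_tokenize <- function(text) {
  lapply(strsplit(tolower(text), "[^a-z0-9]+"), function(t) t[nzchar(t)])
}

# split text into units (sentence- or paragraph-sized), keeping every
# character so that paste(units) == text exactly
.split_units <- function(text) {
  bounds <- gregexpr("\n{2,}|[.?!][[:space:]]+", text, perl = TRUE)[[1]]
  if (bounds[1] == -1) return(text)
  ends <- as.integer(bounds) + attr(bounds, "match.length") - 1L
  starts <- c(1L, ends + 1L)
  ends <- c(ends, nchar(text))
  keep <- starts <= ends
  substring(text, starts[keep], ends[keep])
}

#' Segment a corpus into fixed-width retrieval chunks
#'
#' Greedy packing: sentence/paragraph units are accumulated into a chunk and
#' the chunk is flushed when adding the next unit would exceed `max_chars`.
#' A unit longer than `max_chars` on its own is hard-split at `max_chars`.
#' Chunks shorter than `min_chars` (typically the final remainder of a source)
#' are flagged rather than merged across sources, so chunks from one source
#' stay disjoint and order-preserving, and their concatenation reproduces the
#' source text exactly.
#'
#' @param texts list of `(source, text)` pairs: either a named character
#'   vector (names = sources) or a list of two-element lists.
#' @param min_chars minimum chunk size in characters (default 1119).
#' @param max_chars maximum chunk size in characters (default 2048).
#' @return tibble with columns `id`, `source`, `text`, `char_len`, `flagged`.
#' @export
segment_corpus <- function(texts, min_chars = 1119, max_chars = 2048) {
  stopifnot(max_chars > min_chars, min_chars > 0)
  if (length(texts) == 0) stop("empty corpus", call. = FALSE)
  if (is.character(texts)) {
    sources <- names(texts) %||% as.character(seq_along(texts))
    texts <- as.list(texts)
  } else {
    sources <- vapply(texts, function(x) as.character(x$source %||% x[[1]]), "")
    texts <- lapply(texts, function(x) as.character(x$text %||% x[[2]]))
  }

  rows <- list()
  for (i in seq_along(texts)) {
    txt <- texts[[i]]
    if (!nzchar(txt)) next
    units <- .split_units(txt)
    # hard-split any unit that alone exceeds max_chars
    units <- unlist(lapply(units, function(u) {
      if (nchar(u) <= max_chars) return(u)
      starts <- seq(1L, nchar(u), by = max_chars)
      substring(u, starts, pmin(starts + max_chars - 1L, nchar(u)))
    }))
    chunks <- character()
    cur <- ""
    for (u in units) {
      if (nzchar(cur) && nchar(cur) + nchar(u) > max_chars) {
        chunks <- c(chunks, cur)
        cur <- u
      } else {
        cur <- paste0(cur, u)
      }
    }
    if (nzchar(cur)) chunks <- c(chunks, cur)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      source = sources[i], text = chunks, char_len = nchar(chunks)
    )
  }
  if (length(rows) == 0) stop("empty corpus", call. = FALSE)
  out <- do.call(rbind, rows)
  out$flagged <- out$char_len < min_chars
  tibble::tibble(
    id = seq_len(nrow(out)), source = out$source, text = out$text,
    char_len = out$char_len, flagged = out$flagged
  )
}

.new_retrieval_result <- function(ids, scores, k) {
  structure(list(ids = as.integer(ids), scores = as.numeric(scores), k = as.integer(k)),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("<retrieval_result> k=%d: ids [%s]\n", x$k,
              paste(x$ids, collapse = ", ")))
  invisible(x)
}

# rank by score descending, ties broken by lower chunk id; truncate to k
.rank_and_cut <- function(ids, scores, k) {
  ord <- order(-scores, ids)
  take <- seq_len(min(k, length(ids)))
  .new_retrieval_result(ids[ord][take], scores[ord][take], k)
}

#' Rank corpus chunks against a query with Okapi BM25
#'
#' Non-negative idf variant:
#' `idf(t) = ln(1 + (N - df + 0.5) / (df + 0.5))`, and per-document score
#' `sum_t idf(t) * tf * (k1 + 1) / (tf + k1 * (1 - b + b * len / avglen))`
#' over query terms `t`, with document length measured in tokens.
#'
#' @param query query text.
#' @param corpus chunk tibble from [segment_corpus()] (columns `id`, `text`).
#' @param k number of chunks to return.
#' @param k1,b BM25 parameters (standard defaults 1.5 and 0.75).
#' @return a `retrieval_result` (ids, non-increasing scores, k).
#' @export
bm25_rank <- function(query, corpus, k, k1 = 1.5, b = 0.75) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (nrow(corpus) == 0) stop("empty corpus", call. = FALSE)
  docs <- bow_tokenize(corpus$text)
  qterms <- unique(bow_tokenize(query)[[1]])
  N <- length(docs)
  lens <- vapply(docs, length, integer(1))
  avglen <- mean(lens)
  scores <- numeric(N)
  for (term in qterms) {
    tf <- vapply(docs, function(d) sum(d == term), numeric(1))
    df <- sum(tf > 0)
    if (df == 0) next
    idf <- log(1 + (N - df + 0.5) / (df + 0.5))
    denom <- tf + k1 * (1 - b + b * lens / avglen)
    scores <- scores + idf * tf * (k1 + 1) / denom
  }
  .rank_and_cut(corpus$id, scores, k)
}

#' Rank corpus chunks by cosine similarity of embeddings
#'
#' @param query query text.
#' @param corpus chunk tibble (columns `id`, `text`).
#' @param embedder function `text -> numeric vector` of fixed dimension.
#' @param k number of chunks to return.
#' @return a `retrieval_result`. Chunks whose embedding has zero norm are
#'   scored 0 and reported via a warning.
#' @export
embedding_rank <- function(query, corpus, embedder, k) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (nrow(corpus) == 0) stop("empty corpus", call. = FALSE)
  qv <- as.numeric(embedder(query))
  if (any(!is.finite(qv))) stop("embedder returned non-finite query vector", call. = FALSE)
  qn <- sqrt(sum(qv^2))
  zero <- integer()
  scores <- vapply(seq_len(nrow(corpus)), function(i) {
    v <- as.numeric(embedder(corpus$text[i]))
    vn <- sqrt(sum(v^2))
    if (vn == 0 || qn == 0) {
      zero <<- c(zero, corpus$id[i])
      return(0)
    }
    sum(qv * v) / (qn * vn)
  }, numeric(1))
  if (length(zero) > 0 || qn == 0) {
    warning("zero-norm embedding(s) scored as similarity 0 (chunk ids: ",
            paste(unique(zero), collapse = ", "), ")", call. = FALSE)
  }
  .rank_and_cut(corpus$id, scores, k)
}

#' Retrieve k chunks uniformly at random (baseline retriever)
#'
#' @param corpus chunk tibble (column `id`).
#' @param k number of chunks to draw, without replacement.
#' @param seed RNG seed; the draw is a pure function of (corpus, k, seed).
#' @return a `retrieval_result` with constant scores.
#' @export
random_rank <- function(corpus, k, seed) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > nrow(corpus)) stop("k exceeds corpus size", call. = FALSE)
  ids <- with_seed(seed, sample(corpus$id, k, replace = FALSE))
  .new_retrieval_result(ids, rep(0, k), k)
}
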