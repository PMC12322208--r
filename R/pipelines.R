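#' Inference pipelines: baseline vs evidence-based, and the benchmark runner
#'
#' The *baseline* pipeline asks the backend to name an imaging study directly.
#' The *evidence-based* pipeline asks the backend only to classify the case
#' into a guideline Topic (up to `m` Topics) and then resolves the Topic(s)
#' to the appropriate-study set by deterministic knowledge-base lookup — the
#' model never picks studies itself.
#'
#' @name pipelines
#' @keywords internal
NULL

.case_evaluation <- function(id, seed, pipeline, y, y_pred, K, K_pred, unparsed) {
  tibble::tibble(
    id = as.character(id), seed = as.integer(seed), pipeline = pipeline,
    y = as.character(y), y_pred = list(y_pred), K = list(K),
    K_pred = list(K_pred), unparsed = unparsed
  )
}

#' Union of study sets resolved from predicted Topics
#'
#' With `drop_sentinel = TRUE` (default) the no-imaging sentinel is removed
#' from the union whenever any real study is present: a predicted topic that
#' warrants imaging dominates one that does not.
#'
#' @param kb a `guideline_kb`.
#' @param topics character vector of canonical topic names.
#' @param drop_sentinel drop the sentinel from mixed unions.
#' @return character vector (sorted set) of study names.
#' @export
resolve_topics_union <- function(kb, topics, drop_sentinel = TRUE) {
  if (length(topics) == 0) return(character())
  studies <- sort(unique(unlist(lapply(topics, function(t) resolve_topic(kb, t)))))
  if (drop_sentinel && any(!is_sentinel(studies)) && any(is_sentinel(studies))) {
    studies <- studies[!is_sentinel(studies)]
  }
  studies
}

#' Run the evidence-based pipeline on one case
#'
#' Prompts the backend for up to `spec$m` Topics, parses and normalizes the
#' response, and resolves the predicted Topic(s) to the study set by
#' knowledge-base lookup. Backend failures and unparseable output are
#' recorded as unparsed evaluations (empty prediction), never raised.
#'
#' @param record a one-row one-liner record (fields `id`, `text`, `label`).
#' @param backend a `completion_backend`.
#' @param kb a `guideline_kb`.
#' @param spec a [prompt_spec()] with `task = "topic_prediction"`.
#' @param seed run seed forwarded to the backend.
#' @param context optional retrieved context for RAG/ICL prompts.
#' @param drop_sentinel see [resolve_topics_union()].
#' @return a one-row evaluation tibble (`id`, `seed`, `pipeline`, `y`,
#'   `y_pred`, `K`, `K_pred`, `unparsed`).
#' @export
run_evidence_pipeline <- function(record, backend, kb, spec, seed = 0L,
                                  context = NULL, drop_sentinel = TRUE) {
  stopifnot(spec$task == "topic_prediction")
  y <- record$label[[1]]
  K <- if (!is.na(y)) resolve_topic(kb, y) else character()
  parsed <- tryCatch({
    prompt <- build_prompt(record$text[[1]], spec, kb, context = context)
    parse_topic_response(generate(backend, prompt, temperature = 0, seed = seed),
                         kb, m = spec$m)
  }, error = function(e) .parsed_prediction(unparsed = TRUE))
  if (parsed$unparsed) {
    return(.case_evaluation(record$id[[1]], seed, "evidence", y,
                            character(), K, character(), TRUE))
  }
  K_pred <- resolve_topics_union(kb, parsed$topics, drop_sentinel = drop_sentinel)
  .case_evaluation(record$id[[1]], seed, "evidence", y, parsed$topics, K, K_pred, FALSE)
}

#' Run the baseline pipeline on one case
#'
#' Prompts the backend to name an imaging study directly (no guideline
#' lookup); the parsed study set is the prediction.
#'
#' @inheritParams run_evidence_pipeline
#' @param spec a [prompt_spec()] with `task = "imaging_prediction"`.
#' @return a one-row evaluation tibble.
#' @export
run_baseline_pipeline <- function(record, backend, kb, spec, seed = 0L,
                                  context = NULL) {
  stopifnot(spec$task == "imaging_prediction")
  y <- record$label[[1]]
  K <- if (!is.na(y)) resolve_topic(kb, y) else character()
  parsed <- tryCatch({
    prompt <- build_prompt(record$text[[1]], spec, kb, context = context)
    parse_imaging_response(generate(backend, prompt, temperature = 0, seed = seed), kb)
  }, error = function(e) .parsed_prediction(unparsed = TRUE))
  .case_evaluation(record$id[[1]], seed, "baseline", y,
                   character(), K, parsed$studies, parsed$unparsed)
}

#' Benchmark run configuration
#'
#' @param pipeline `"evidence"` or `"baseline"`.
#' @param spec a [prompt_spec()] consistent with the pipeline kind.
#' @param seeds integer seeds, one full pass over the dataset per seed
#'   (default `0:4`, five runs).
#' @param context_provider optional function `(one_liner, seed) -> context`
#'   supplying RAG chunks or ICL examples per case.
#' @param drop_sentinel see [resolve_topics_union()].
#' @return a `run_config`.
#' @export
run_config <- function(pipeline = c("evidence", "baseline"), spec,
                       seeds = 0:4, context_provider = NULL,
                       drop_sentinel = TRUE) {
  pipeline <- match.arg(pipeline)
  if (length(seeds) == 0) stop("seeds must be non-empty", call. = FALSE)
  expected <- if (pipeline == "evidence") "topic_prediction" else "imaging_prediction"
  if (spec$task != expected) {
    stop("pipeline '", pipeline, "' requires spec task '", expected, "'",
         call. = FALSE)
  }
  structure(list(pipeline = pipeline, spec = spec, seeds = as.integer(seeds),
                 context_provider = context_provider,
                 drop_sentinel = drop_sentinel),
            class = "run_config")
}

#' Run a benchmark: all included cases times all seeds
#'
#' Excluded records (non-`NA` `exclusion_reason`) are skipped. The output has
#' exactly `included cases x length(seeds)` rows and is deterministic for a
#' backend honoring the determinism contract.
#'
#' @param records one-liner dataset tibble; labels must resolve in `kb`.
#' @param config a [run_config()].
#' @param backend a `completion_backend`.
#' @param kb a `guideline_kb`.
#' @return evaluation tibble (one row per case per seed).
#' @export
run_benchmark <- function(records, config, backend, kb) {
  stopifnot(inherits(config, "run_config"))
  inc <- included_records(records)
  if (nrow(inc) == 0) stop("no included records to evaluate", call. = FALSE)
  runner <- if (config$pipeline == "evidence") {
    function(rec, seed, ctx) run_evidence_pipeline(
      rec, backend, kb, config$spec, seed = seed, context = ctx,
      drop_sentinel = config$drop_sentinel)
  } else {
    function(rec, seed, ctx) run_baseline_pipeline(
      rec, backend, kb, config$spec, seed = seed, context = ctx)
  }
  out <- vector("list", nrow(inc) * length(config$seeds))
  j <- 0L
  for (seed in config$seeds) {
    for (i in seq_len(nrow(inc))) {
      rec <- inc[i, , drop = FALSE]
      ctx <- if (!is.null(config$context_provider)) {
        config$context_provider(rec$text[[1]], seed)
      } else NULL
      j <- j + 1L
      out[[j]] <- runner(rec, seed, ctx)
    }
  }
  do.call(rbind, out)
}

#' Write / read evaluation records as JSONL
#'
#' @param evals evaluation tibble from [run_benchmark()].
#' @param path output path.
#' @return `path` invisibly (write); evaluation tibble (read).
#' @export
write_evaluations <- function(evals, path) {
  lines <- vapply(seq_len(nrow(evals)), function(i) {
    jsonlite::toJSON(list(
      id = evals$id[i], seed = evals$seed[i], pipeline = evals$pipeline[i],
      y = evals$y[i], y_pred = as.list(evals$y_pred[[i]]),
      K = as.list(evals$K[[i]]), K_pred = as.list(evals$K_pred[[i]]),
      unparsed = evals$unparsed[i]
    ), auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_evaluations
#' @export
read_evaluations <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    .case_evaluation(r$id, r$seed, r$pipeline,
                     r$y %||% NA_character_,
                     as.character(unlist(r$y_pred)), as.character(unlist(r$K)),
                     as.character(unlist(r$K_pred)), isTRUE(r$unparsed))
  })
  do.call(rbind, rows)
}
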