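#' Prompt construction, completion-backend contract, and answer parsing
#'
#' Every inference strategy renders a deterministic prompt from a template, a
#' one-liner, and optional retrieved context; a *completion backend* maps
#' (prompt, temperature, seed) to text; parsers map the text back onto
#' canonical Topics or studies. At temperature 0 with a fixed seed a backend
#' must be deterministic, which is what makes multi-seed benchmarks exactly
#' reproducible.
#'
#' @name prompting
#' @keywords internal
NULL

#' Deterministic 32-bit content hash of a string
#'
#' Polynomial rolling hash over UTF-8 bytes, modulo 2^31 - 1. Used to key
#' scripted mock responses and to derive per-prompt RNG streams; not
#' cryptographic.
#'
#' @param x a string.
#' @return non-negative integer-valued double below 2^31 - 1.
#' @export
content_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

#' Specify an inference strategy
#'
#' @param task `"topic_prediction"` (classify into guideline Topics) or
#'   `"imaging_prediction"` (name an imaging study directly).
#' @param strategy `"baseline"`, `"cot"` (chain-of-thought), `"icl"`
#'   (in-context learning) or `"rag"` (retrieval-augmented generation).
#' @param cot_style reasoning style for `strategy = "cot"`: `"default"`,
#'   `"differential"`, `"bayesian"` or `"analytic"`.
#' @param k_context number of retrieved context items (chunks for RAG,
#'   labeled examples for ICL); conventionally 8 for RAG and 4 for ICL.
#' @param m maximum number of Topics the model is asked to predict.
#' @return an object of class `prompt_spec`.
#' @export
prompt_spec <- function(task = c("topic_prediction", "imaging_prediction"),
                        strategy = c("baseline", "cot", "icl", "rag"),
                        cot_style = c("default", "differential", "bayesian", "analytic"),
                        k_context = 0L, m = 1L) {
  cot_given <- !missing(cot_style)
  task <- match.arg(task)
  strategy <- match.arg(strategy)
  cot_style <- match.arg(cot_style)
  stopifnot(m >= 1, k_context >= 0)
  if (strategy != "cot" && cot_given) {
    stop("cot_style applies only when strategy = 'cot'", call. = FALSE)
  }
  if (strategy %in% c("icl", "rag") && k_context < 1) {
    stop("strategy '", strategy, "' requires k_context >= 1", call. = FALSE)
  }
  structure(
    list(task = task, strategy = strategy,
         cot_style = if (strategy == "cot") cot_style else NA_character_,
         k_context = as.integer(k_context), m = as.integer(m)),
    class = "prompt_spec"
  )
}

# chain-of-thought instruction blocks, one per reasoning style
.cot_blocks <- c(
  default = "Think through the case step by step before giving your final answer.",
  differential = paste(
    "Reason through a differential diagnosis for this patient,",
    "then use it to arrive at your final answer."),
  bayesian = paste(
    "Reason like a Bayesian: start from the pretest probability of each",
    "candidate condition and update it with each clinical finding before",
    "giving your final answer."),
  analytic = paste(
    "Reason through the pathophysiology of the underlying disease process",
    "before giving your final answer.")
)

.default_topic_template <- paste(
  "You are a radiology decision-support assistant.",
  "{{context}}Patient one-liner: {{one_liner}}",
  "Identify the most relevant clinical guideline Topic for this patient",
  "(up to {{m}} Topic(s), one per line).",
  "{{reasoning}}Respond with the Topic name(s) after the marker.",
  "Answer:",
  sep = "\n"
)

.default_imaging_template <- paste(
  "You are a radiology decision-support assistant.",
  "{{context}}Patient one-liner: {{one_liner}}",
  "Name the single most appropriate diagnostic imaging study for this",
  "patient, or 'None' if no imaging is warranted.",
  "{{reasoning}}Respond with the study name after the marker.",
  "Answer:",
  sep = "\n"
)

#' Fill `{{placeholder}}` slots in a template string
#' @param template template text.
#' @param values named list of replacements.
#' @return rendered text.
#' @export
render_template <- function(template, values) {
  for (key in names(values)) {
    template <- gsub(paste0("{{", key, "}}"), values[[key]], template, fixed = TRUE)
  }
  template
}

#' Build the prompt for one case under a given strategy
#'
#' Deterministic template fill. RAG prompts embed the retrieved chunk texts;
#' ICL prompts embed (one-liner, Topic) example pairs in retrieval order;
#' chain-of-thought prompts insert the reasoning-style instruction block.
#' Custom templates (plain text with `{{one_liner}}`, `{{context}}`,
#' `{{reasoning}}`, `{{m}}` placeholders) can be supplied via `template`.
#'
#' @param one_liner the case text.
#' @param spec a [prompt_spec()].
#' @param kb a `guideline_kb` (reserved for template variants that enumerate
#'   topics; unused by the default templates).
#' @param context for `strategy = "rag"`, a character vector of chunk texts
#'   (or a corpus tibble with a `text` column); for `strategy = "icl"`, a
#'   data frame with columns `text` and `label`. Must contain exactly
#'   `spec$k_context` items.
#' @param template optional template override: a string or a path to a
#'   template file.
#' @return the prompt text.
#' @export
build_prompt <- function(one_liner, spec, kb, context = NULL, template = NULL) {
  stopifnot(inherits(spec, "prompt_spec"))
  if (!nzchar(trimws(one_liner))) stop("empty one-liner", call. = FALSE)

  ctx_block <- ""
  if (spec$strategy == "rag") {
    if (is.data.frame(context)) context <- context$text
    if (is.null(context) || length(context) != spec$k_context) {
      stop("rag strategy requires exactly k_context retrieved chunks", call. = FALSE)
    }
    ctx_block <- paste0(
      "Relevant guideline excerpts:\n",
      paste(sprintf("[%d] %s", seq_along(context), context), collapse = "\n"),
      "\n\n"
    )
  } else if (spec$strategy == "icl") {
    if (is.null(context) || !is.data.frame(context) ||
        !all(c("text", "label") %in% names(context)) ||
        nrow(context) != spec$k_context) {
      stop("icl strategy requires k_context labeled examples (columns text, label)",
           call. = FALSE)
    }
    ctx_block <- paste0(
      "Worked examples:\n",
      paste(sprintf("Example %d: %s\nTopic: %s",
                    seq_len(nrow(context)), context$text, context$label),
            collapse = "\n"),
      "\n\n"
    )
  }

  reasoning <- if (spec$strategy == "cot") {
    paste0(.cot_blocks[[spec$cot_style]], "\n")
  } else ""

  tpl <- template %||% switch(spec$task,
    topic_prediction = .default_topic_template,
    imaging_prediction = .default_imaging_template
  )
  if (length(tpl) == 1 && file.exists(tpl)) {
    tpl <- paste(readLines(tpl, warn = FALSE), collapse = "\n")
  }
  render_template(tpl, list(
    context = ctx_block, one_liner = one_liner,
    reasoning = reasoning, m = spec$m
  ))
}

# answer extraction: substring after the final (case-insensitive) "Answer:";
# if the marker is absent, the last non-empty line
.extract_answer <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return("")
  m <- gregexpr("answer[[:space:]]*:", tolower(text))[[1]]
  if (m[1] != -1) {
    last <- m[length(m)] + attr(m, "match.length")[length(m)]
    return(trimws(substr(text, last, nchar(text))))
  }
  lines <- trimws(strsplit(text, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) "" else lines[length(lines)]
}

# split a multi-item answer on newlines, ";", or numbered-list markers
.split_items <- function(answer) {
  items <- strsplit(answer, "\n|;", perl = TRUE)[[1]]
  items <- gsub("^[[:space:]]*([0-9]+[.)]|[-*])[[:space:]]*", "", items)
  items <- gsub("[.[:space:]]+$", "", trimws(items))
  items[nzchar(items)]
}

.parsed_prediction <- function(topics = character(), studies = character(),
                               unparsed = FALSE) {
  structure(list(topics = topics, studies = studies, unparsed = unparsed),
            class = "parsed_prediction")
}

#' @export
print.parsed_prediction <- function(x, ...) {
  if (x$unparsed) cat("<parsed_prediction> unparsed\n")
  else cat("<parsed_prediction> topics:", paste(x$topics, collapse = " | "),
           "studies:", paste(x$studies, collapse = " | "), "\n")
  invisible(x)
}

#' Parse a model response into canonical Topic names
#'
#' Extracts the answer segment (after the final `Answer:` marker, or the last
#' non-empty line), splits it on newlines / semicolons / numbered-list
#' markers, normalizes every item with [normalize_topic_name()], drops items
#' that do not match any Topic, de-duplicates preserving order, and truncates
#' to `m`. If every item is dropped the prediction is *unparsed*.
#'
#' @param text raw model output.
#' @param kb a `guideline_kb`.
#' @param m maximum number of Topics to keep.
#' @return a `parsed_prediction` with ordered `topics` (possibly empty and
#'   `unparsed = TRUE`).
#' @export
parse_topic_response <- function(text, kb, m = 1L) {
  stopifnot(m >= 1)
  items <- .split_items(.extract_answer(text))
  topics <- character()
  for (it in items) {
    canon <- normalize_topic_name(it, kb)
    if (!is.na(canon) && !(canon %in% topics)) topics <- c(topics, canon)
    if (length(topics) >= m) break
  }
  if (length(topics) == 0) return(.parsed_prediction(unparsed = TRUE))
  .parsed_prediction(topics = topics)
}

#' Parse a model response into imaging-study names
#'
#' Same answer extraction as [parse_topic_response()], matched against the
#' study vocabulary; sentinel aliases (`"none"`, `"no imaging"`) normalize to
#' the canonical sentinel spelling.
#'
#' @param text raw model output.
#' @param kb a `guideline_kb`.
#' @return a `parsed_prediction` with a `studies` set.
#' @export
parse_imaging_response <- function(text, kb) {
  items <- .split_items(.extract_answer(text))
  studies <- character()
  for (it in items) {
    canon <- normalize_study_name(it, kb)
    if (!is.na(canon) && !(canon %in% studies)) studies <- c(studies, canon)
  }
  if (length(studies) == 0) return(.parsed_prediction(unparsed = TRUE))
  .parsed_prediction(studies = sort(studies))
}

#' Completion-backend contract
#'
#' A backend is any object of class `completion_backend` whose `generate`
#' field is a function `(prompt, temperature, seed) -> text`. The contract:
#' at `temperature = 0` with a fixed `seed`, repeated calls on the same prompt
#' return byte-identical text.
#'
#' @param generate_fn function `(prompt, temperature, seed) -> character(1)`.
#' @param label human-readable backend name.
#' @return a `completion_backend`.
#' @export
completion_backend <- function(generate_fn, label = "custom") {
  stopifnot(is.function(generate_fn))
  structure(list(generate = generate_fn, label = label),
            class = "completion_backend")
}

#' @export
print.completion_backend <- function(x, ...) {
  cat(sprintf("<completion_backend> %s\n", x$label))
  invisible(x)
}

#' Query a completion backend
#' @param backend a `completion_backend`.
#' @param prompt prompt text.
#' @param temperature sampling temperature (benchmarks run at 0).
#' @param seed integer seed forwarded to the backend.
#' @return the completion text.
#' @export
generate <- function(backend, prompt, temperature = 0, seed = 0L) {
  stopifnot(inherits(backend, "completion_backend"))
  backend$generate(prompt, temperature, seed)
}

#' Scripted deterministic mock backend
#'
#' Answers prompts from a script: a named character vector whose names are
#' either [content_hash()] values of full prompts or literal substrings to
#' look for in the prompt (typically the embedded one-liner or a case id).
#' Unscripted prompts fall through to `fallback(prompt, seed)` when supplied,
#' else to a fixed non-matching string. Satisfies the determinism contract:
#' output depends only on (prompt, seed).
#'
#' @param script named character vector of responses; may be empty.
#' @param fallback optional function `(prompt, seed) -> text` for unscripted
#'   prompts (e.g. a confusion model from [make_confusion_backend()]).
#' @param label backend name.
#' @return a `completion_backend`.
#' @export
mock_backend <- function(script = character(), fallback = NULL, label = "mock") {
  keys <- names(script)
  completion_backend(function(prompt, temperature, seed) {
    if (length(script) > 0) {
      hit <- which(keys == as.character(content_hash(prompt)))
      if (length(hit) == 0) {
        hit <- which(vapply(keys, function(k) grepl(k, prompt, fixed = TRUE),
                            logical(1)))
      }
      if (length(hit) > 0) return(unname(script[[hit[1]]]))
    }
    if (!is.null(fallback)) return(fallback(prompt, seed))
    "I cannot determine this."
  }, label = label)
}
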