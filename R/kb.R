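#' Guideline knowledge base: Topic -> imaging-study lookup
#'
#' The knowledge base (KB) is a pinned snapshot of evidence-based imaging
#' guidelines: a set of clinical Topics, each carrying one or more clinical
#' variants, each variant carrying the set of imaging studies the guideline
#' deems appropriate. Exactly one variant per Topic is marked *canonical*;
#' deterministic lookup of a Topic returns the canonical variant's study set.
#' A dedicated sentinel study (canonically spelled `"None"`) means that no
#' imaging is warranted.
#'
#' @name guideline_kb
#' @keywords internal
NULL

#' Canonical sentinel spelling for the no-imaging pseudo-study
#' @keywords internal
SENTINEL_NAME <- "None"

# Aliases accepted on input for the sentinel, compared after normalization.
.sentinel_aliases <- c("none", "no imaging", "no imaging study", "no imaging indicated")

#' Normalize a name for case/whitespace/punctuation-insensitive comparison
#'
#' Lowercases, maps every non-alphanumeric character to a space, and squeezes
#' repeated whitespace. Used for topic-name and study-name matching.
#'
#' @param x character vector.
#' @return character vector of normalized keys.
#' @keywords internal
norm_key <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Is a study name the no-imaging sentinel (any accepted alias)?
#' @param name character vector of study names.
#' @return logical vector.
#' @export
is_sentinel <- function(name) norm_key(name) %in% .sentinel_aliases

#' Construct a guideline knowledge base object
#'
#' @param version_date snapshot date string (e.g. `"2024-06-01"`).
#' @param topics list of topics, each a list with fields `name`, `panel`, and
#'   `variants` (each variant a list with `description`, `canonical`, and
#'   `studies`, a character vector of study names).
#' @param study_vocabulary character vector of all study names; must contain
#'   the sentinel exactly once.
#' @param validate if `TRUE` (default), stop on any invariant violation.
#' @return an object of class `guideline_kb`.
#' @export
new_guideline_kb <- function(version_date, topics, study_vocabulary,
                             validate = TRUE) {
  vocab <- tibble::tibble(
    name = as.character(study_vocabulary),
    is_no_imaging = is_sentinel(study_vocabulary)
  )
  kb <- structure(
    list(
      version_date = as.character(version_date),
      topics = topics,
      study_vocabulary = vocab
    ),
    class = "guideline_kb"
  )
  if (validate) {
    bad <- validate_kb(kb)
    if (length(bad) > 0) {
      stop("invalid knowledge base:\n  - ", paste(bad, collapse = "\n  - "),
           call. = FALSE)
    }
  }
  kb
}

#' @export
print.guideline_kb <- function(x, ...) {
  cat(sprintf(
    "<guideline_kb> %d topics, %d studies (snapshot %s)\n",
    length(x$topics), nrow(x$study_vocabulary), x$version_date
  ))
  invisible(x)
}

#' Validate a knowledge base against its structural invariants
#'
#' Checks, per topic: non-empty unique (normalized) names, at least one
#' variant, exactly one canonical variant, non-empty study sets, all
#' referenced studies present in the vocabulary, and the sentinel never mixed
#' with real studies inside one variant. Checks, globally: unique normalized
#' study names and exactly one sentinel entry.
#'
#' @param kb a `guideline_kb`.
#' @return character vector of human-readable violations; empty when valid.
#' @export
validate_kb <- function(kb) {
  out <- character()
  vocab <- kb$study_vocabulary
  if (length(kb$topics) == 0) out <- c(out, "KB has zero topics")
  if (sum(vocab$is_no_imaging) != 1) {
    out <- c(out, sprintf(
      "study vocabulary must contain exactly one no-imaging sentinel (found %d)",
      sum(vocab$is_no_imaging)
    ))
  }
  if (anyDuplicated(norm_key(vocab$name)) > 0) {
    out <- c(out, "study vocabulary has duplicate names after normalization")
  }
  if (any(!nzchar(vocab$name))) out <- c(out, "study vocabulary has empty names")

  tnames <- vapply(kb$topics, function(t) as.character(t$name %||% ""), "")
  if (any(!nzchar(tnames))) out <- c(out, "a topic has an empty name")
  dup <- tnames[duplicated(norm_key(tnames))]
  if (length(dup) > 0) {
    out <- c(out, sprintf("duplicate topic name after normalization: '%s'", dup))
  }

  vocab_keys <- norm_key(vocab$name)
  for (t in kb$topics) {
    nm <- as.character(t$name %||% "<unnamed>")
    nvar <- length(t$variants)
    if (nvar == 0) {
      out <- c(out, sprintf("topic '%s': zero variants", nm))
      next
    }
    canon <- vapply(t$variants, function(v) isTRUE(v$canonical), logical(1))
    if (sum(canon) != 1) {
      out <- c(out, sprintf(
        "topic '%s': expected exactly one canonical variant, found %d", nm, sum(canon)
      ))
    }
    for (i in seq_along(t$variants)) {
      st <- as.character(unlist(t$variants[[i]]$studies))
      if (length(st) == 0) {
        out <- c(out, sprintf("topic '%s' variant %d: empty study set", nm, i))
        next
      }
      missing <- st[!(norm_key(st) %in% vocab_keys)]
      if (length(missing) > 0) {
        out <- c(out, sprintf(
          "topic '%s' variant %d: study not in vocabulary: '%s'",
          nm, i, paste(missing, collapse = "', '")
        ))
      }
      if (any(is_sentinel(st)) && length(st) > 1) {
        out <- c(out, sprintf(
          "topic '%s' variant %d: sentinel mixed with real studies", nm, i
        ))
      }
    }
  }
  out
}

#' Load a knowledge-base snapshot from a JSON file
#'
#' The snapshot is a single JSON document:
#' \preformatted{
#' {"version_date": "...",
#'  "topics": [{"name": "...", "panel": "...",
#'              "variants": [{"description": "...", "canonical": true,
#'                            "studies": ["...", ...]}, ...]}, ...],
#'  "study_vocabulary": ["...", ...]}
#' }
#'
#' @param path path to the JSON snapshot.
#' @return a validated `guideline_kb`.
#' @export
load_kb <- function(path) {
  if (!file.exists(path)) stop("KB snapshot not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("version_date", "topics", "study_vocabulary")) {
    if (is.null(raw[[field]])) {
      stop("KB snapshot missing required field '", field, "'", call. = FALSE)
    }
  }
  topics <- lapply(raw$topics, function(t) {
    if (is.null(t$name)) stop("KB snapshot has a topic without a name", call. = FALSE)
    if (is.null(t$variants)) {
      stop("topic '", t$name, "': missing 'variants'", call. = FALSE)
    }
    list(
      name = as.character(t$name),
      panel = as.character(t$panel %||% NA_character_),
      variants = lapply(t$variants, function(v) {
        list(
          description = as.character(v$description %||% ""),
          canonical = isTRUE(v$canonical),
          studies = as.character(unlist(v$studies))
        )
      })
    )
  })
  new_guideline_kb(
    version_date = raw$version_date,
    topics = topics,
    study_vocabulary = as.character(unlist(raw$study_vocabulary)),
    validate = TRUE
  )
}

#' Write a knowledge base back to its JSON snapshot format
#' @param kb a `guideline_kb`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  doc <- list(
    version_date = kb$version_date,
    topics = lapply(kb$topics, function(t) {
      list(
        name = t$name, panel = t$panel,
        variants = lapply(t$variants, function(v) {
          list(description = v$description, canonical = v$canonical,
               studies = as.list(v$studies))
        })
      )
    }),
    study_vocabulary = as.list(kb$study_vocabulary$name)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' All topic names in a knowledge base
#' @param kb a `guideline_kb`.
#' @return character vector.
#' @export
kb_topic_names <- function(kb) {
  vapply(kb$topics, function(t) t$name, character(1))
}

#' Canonical sentinel study name used by a knowledge base
#' @param kb a `guideline_kb`.
#' @return single study name string.
#' @export
kb_sentinel <- function(kb) {
  kb$study_vocabulary$name[kb$study_vocabulary$is_no_imaging][1]
}

#' Resolve a Topic to its appropriate imaging-study set
#'
#' Deterministic lookup: returns the study set of the topic's canonical
#' variant. The topic name must already be canonical; free-text names go
#' through [normalize_topic_name()] first.
#'
#' @param kb a `guideline_kb`.
#' @param topic canonical topic name.
#' @return character vector of study names (never empty; a no-imaging topic
#'   returns the sentinel).
#' @export
resolve_topic <- function(kb, topic) {
  stopifnot(length(topic) == 1)
  key <- norm_key(topic)
  for (t in kb$topics) {
    if (norm_key(t$name) == key) {
      canon <- Filter(function(v) isTRUE(v$canonical), t$variants)
      return(sort(unique(canon[[1]]$studies)))
    }
  }
  stop("unknown topic: '", topic, "' (normalize free text with ",
       "normalize_topic_name() before lookup)", call. = FALSE)
}

#' Token-set Dice similarity between two normalized strings
#'
#' Similarity = 2 |A n B| / (|A| + |B|) over the *sets* of whitespace tokens
#' of the normalized strings. 1 for identical token sets, 0 for disjoint.
#'
#' @param a,b strings.
#' @return similarity in \[0, 1\].
#' @keywords internal
token_set_similarity <- function(a, b) {
  ta <- unique(strsplit(norm_key(a), " ", fixed = TRUE)[[1]])
  tb <- unique(strsplit(norm_key(b), " ", fixed = TRUE)[[1]])
  ta <- ta[nzchar(ta)]; tb <- tb[nzchar(tb)]
  if (length(ta) == 0 || length(tb) == 0) return(0)
  2 * length(intersect(ta, tb)) / (length(ta) + length(tb))
}

#' Normalize a free-text topic string to a canonical Topic name
#'
#' Exact match after case/whitespace/punctuation normalization is preferred.
#' Otherwise the best fuzzy candidate by token-set Dice similarity is accepted
#' iff its similarity is at least `threshold` (ties broken alphabetically).
#' Below threshold the string is *unmatched* and `NA_character_` is returned
#' — a conservative rule, so that an incorrect free-text topic is scored
#' wrong downstream rather than silently mapped to some canonical name.
#'
#' @param raw free-text topic string (e.g. emitted by a language model).
#' @param kb a `guideline_kb`.
#' @param threshold minimum fuzzy similarity to accept (default 0.90).
#' @return canonical topic name, or `NA_character_` when unmatched.
#' @export
normalize_topic_name <- function(raw, kb, threshold = 0.90) {
  if (is.na(raw) || !nzchar(trimws(raw))) return(NA_character_)
  names_all <- kb_topic_names(kb)
  keys <- norm_key(names_all)
  key <- norm_key(raw)
  hit <- which(keys == key)
  if (length(hit) > 0) return(names_all[hit[1]])
  sims <- vapply(names_all, function(nm) token_set_similarity(raw, nm), numeric(1))
  best <- max(sims)
  if (best >= threshold) {
    cand <- sort(names_all[sims == best])
    return(cand[1])
  }
  NA_character_
}

#' Normalize a free-text study string to a vocabulary entry
#'
#' Sentinel aliases ("none", "no imaging", ...) map to the canonical sentinel
#' spelling. Exact normalized matching only; there is no fuzzy step for
#' studies, mirroring the conservative topic rule.
#'
#' @param raw free-text study string.
#' @param kb a `guideline_kb`.
#' @return canonical study name or `NA_character_`.
#' @export
normalize_study_name <- function(raw, kb) {
  if (is.na(raw) || !nzchar(trimws(raw))) return(NA_character_)
  if (is_sentinel(raw)) return(kb_sentinel(kb))
  keys <- norm_key(kb$study_vocabulary$name)
  hit <- which(keys == norm_key(raw))
  if (length(hit) > 0) return(kb$study_vocabulary$name[hit[1]])
  NA_character_
}

`%||%` <- function(a, b) if (is.null(a)) b else a
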