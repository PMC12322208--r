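#' One-liner datasets: records, I/O, exclusions, summaries
#'
#' A dataset is a tibble of one-liner records with columns `id`, `text`,
#' `subset`, `label` and `exclusion_reason`. `label` is the ground-truth
#' guideline Topic (or `NA` for unlabeled records); `exclusion_reason` is `NA`
#' or an integer code in 1..4 recording why a human annotator excluded the
#' record from evaluation:
#' 1 = the guidelines offer no guidance for the chief complaint;
#' 2 = an appropriate study was already performed / diagnosis already made;
#' 3 = insufficient information about the patient;
#' 4 = not a specific patient presentation.
#'
#' @name one_liner_dataset
#' @keywords internal
NULL

.dataset_cols <- c("id", "text", "subset", "label", "exclusion_reason")

#' Build a one-liner record tibble
#' @param id character ids.
#' @param text one-sentence case texts.
#' @param subset source subset labels (e.g. "Synthetic", "USMLE", ...).
#' @param label ground-truth topic names, `NA` if unlabeled.
#' @param exclusion_reason integer codes 1..4 or `NA`.
#' @return tibble with the canonical dataset columns.
#' @export
one_liner_records <- function(id, text, subset = "custom", label = NA_character_,
                              exclusion_reason = NA_integer_) {
  if (any(is.na(text)) || any(!nzchar(text))) {
    stop("one-liner text must be non-empty", call. = FALSE)
  }
  tibble::tibble(
    id = as.character(id),
    text = as.character(text),
    subset = as.character(subset),
    label = as.character(label),
    exclusion_reason = as.integer(exclusion_reason)
  )
}

# Abbreviations after which a period does not end a sentence. Clinical text is
# abbreviation-dense; the guard list covers honorifics and charting shorthand.
.abbrev_guards <- c(
  "dr", "mr", "ms", "mrs", "prof", "st", "jr", "sr", "vs", "etc",
  "y.o", "s/p", "b/l", "r/o", "c/o", "h/o", "w/o", "p/w"
)

#' Extract the first sentence of a case description
#'
#' A sentence boundary is a period, question mark or exclamation mark followed
#' by whitespace and an uppercase letter or digit, unless the token preceding
#' the period is a known clinical abbreviation or a single-letter initial.
#' If no boundary is found the whole (trimmed) text is returned, so telegraphic
#' one-liners without terminal punctuation pass through unchanged.
#'
#' @param case_text case description, possibly multi-sentence.
#' @return the first sentence (never empty).
#' @export
extract_one_liner <- function(case_text) {
  if (length(case_text) != 1 || is.na(case_text) || !nzchar(trimws(case_text))) {
    stop("case_text must be a single non-empty string", call. = FALSE)
  }
  txt <- trimws(case_text)
  # candidate boundaries: [.?!] + whitespace + [A-Z0-9]
  m <- gregexpr("[.?!](?=[[:space:]]+[A-Z0-9])", txt, perl = TRUE)[[1]]
  if (m[1] == -1) return(txt)
  for (pos in as.integer(m)) {
    if (substr(txt, pos, pos) == ".") {
      # token immediately before the period
      head <- substr(txt, 1, pos - 1)
      tok <- tolower(sub("^.*?([^[:space:]]*)$", "\\1", head))
      tok <- sub("\\.$", "", tok)  # strip inner trailing dot ("y.o." -> "y.o")
      if (tok %in% .abbrev_guards) next
      if (grepl("^[a-z]$", tok)) next  # single-letter initial ("J. Smith")
    }
    return(trimws(substr(txt, 1, pos)))
  }
  txt
}

#' Read a one-liner dataset from JSONL or CSV
#'
#' Format is inferred from the extension (`.jsonl`/`.ndjson` vs `.csv`).
#' Required fields: `id`, `text`, `subset`; `label` and `exclusion_reason`
#' are optional and default to `NA`.
#'
#' @param path input file.
#' @return tibble of one-liner records.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset not found: ", path, call. = FALSE)
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) stop("line ", i, ": malformed JSON", call. = FALSE))
      for (f in c("id", "text", "subset")) {
        if (is.null(rec[[f]])) stop("line ", i, ": missing required field '", f, "'", call. = FALSE)
      }
      tibble::tibble(
        id = as.character(rec$id), text = as.character(rec$text),
        subset = as.character(rec$subset),
        label = as.character(rec$label %||% NA_character_),
        exclusion_reason = as.integer(rec$exclusion_reason %||% NA_integer_)
      )
    })
    do.call(rbind, recs)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    for (f in c("id", "text", "subset")) {
      if (!f %in% names(df)) stop("CSV missing required column '", f, "'", call. = FALSE)
    }
    if (!"label" %in% names(df)) df$label <- NA_character_
    if (!"exclusion_reason" %in% names(df)) df$exclusion_reason <- NA_integer_
    df$label[is.na(df$label) | df$label == ""] <- NA_character_
    tibble::tibble(
      id = as.character(df$id), text = as.character(df$text),
      subset = as.character(df$subset), label = as.character(df$label),
      exclusion_reason = as.integer(df$exclusion_reason)
    )
  } else {
    stop("unsupported dataset format (use .jsonl or .csv): ", path, call. = FALSE)
  }
}

#' Write a one-liner dataset to JSONL or CSV
#'
#' Round-trips losslessly with [read_dataset()] on all field values.
#'
#' @param records tibble of one-liner records.
#' @param path output file; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  stopifnot(all(.dataset_cols %in% names(records)))
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      rec <- as.list(records[i, .dataset_cols])
      rec <- rec[!vapply(rec, is.na, logical(1))]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(records[, .dataset_cols], path, row.names = FALSE, na = "")
  } else {
    stop("unsupported dataset format (use .jsonl or .csv): ", path, call. = FALSE)
  }
  invisible(path)
}

#' Apply human exclusion annotations to a dataset
#'
#' Exclusion is a human judgment; this function only records it. Annotated
#' records get their `exclusion_reason` set and are skipped by the benchmark
#' runner and summarized separately.
#'
#' @param records tibble of one-liner records.
#' @param annotations named list or vector mapping record id -> reason code
#'   (integer in 1..4).
#' @return the records with `exclusion_reason` filled in.
#' @export
apply_exclusions <- function(records, annotations) {
  if (length(annotations) == 0) return(records)
  ids <- names(annotations)
  codes <- as.integer(unlist(annotations, use.names = FALSE))
  if (any(is.na(codes)) || any(!codes %in% 1:4)) {
    stop("exclusion reason codes must be integers in 1..4", call. = FALSE)
  }
  unknown <- setdiff(ids, records$id)
  if (length(unknown) > 0) {
    stop("annotation refers to unknown record id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  idx <- match(ids, records$id)
  records$exclusion_reason[idx] <- codes
  records
}

#' Included (non-excluded) records of a dataset
#' @param records tibble of one-liner records.
#' @return tibble subset with `exclusion_reason` `NA`.
#' @export
included_records <- function(records) {
  records[is.na(records$exclusion_reason), , drop = FALSE]
}

#' Round half away from zero at a given number of decimals
#'
#' Base `round()` rounds half to even; printed guideline statistics use the
#' conventional half-away-from-zero rule, so summaries use this variant.
#'
#' @param x numeric.
#' @param digits decimals to keep.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize a one-liner dataset against a knowledge base
#'
#' @param records tibble of one-liner records.
#' @param kb a `guideline_kb` used to count topic coverage.
#' @return an object of class `dataset_summary`: total / included / excluded
#'   counts, per-subset included sizes, per-reason exclusion counts, and topic
#'   coverage (overall and per subset) as counts and one-decimal percentages.
#' @export
summarize_dataset <- function(records, kb) {
  inc <- included_records(records)
  exc <- records[!is.na(records$exclusion_reason), , drop = FALSE]
  n_topics <- length(kb$topics)

  coverage <- function(recs) {
    labs <- recs$label[!is.na(recs$label)]
    canon <- unique(vapply(labs, function(l) {
      normalize_topic_name(l, kb) %||% NA_character_
    }, character(1)))
    canon <- canon[!is.na(canon)]
    n <- length(canon)
    list(n = n, pct = round_half_up(100 * n / n_topics, 1))
  }

  subsets <- sort(unique(inc$subset))
  subset_sizes <- vapply(subsets, function(s) sum(inc$subset == s), integer(1))
  subset_cov <- lapply(subsets, function(s) coverage(inc[inc$subset == s, ]))
  names(subset_cov) <- subsets

  reason_counts <- vapply(1:4, function(r) sum(exc$exclusion_reason == r, na.rm = TRUE),
                          integer(1))
  names(reason_counts) <- paste0("reason_", 1:4)

  structure(
    list(
      total = nrow(records),
      included = nrow(inc),
      excluded = nrow(exc),
      subset_sizes = subset_sizes,
      exclusion_by_reason = reason_counts,
      n_kb_topics = n_topics,
      coverage = coverage(inc),
      coverage_by_subset = subset_cov
    ),
    class = "dataset_summary"
  )
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("<dataset_summary> %d records: %d included, %d excluded\n",
              x$total, x$included, x$excluded))
  if (length(x$subset_sizes) > 0) {
    cat("  subsets: ",
        paste(sprintf("%s=%d", names(x$subset_sizes), x$subset_sizes), collapse = ", "),
        "\n", sep = "")
  }
  cat(sprintf("  exclusions by reason: %s\n",
              paste(sprintf("%d:%d", 1:4, x$exclusion_by_reason), collapse = " ")))
  cat(sprintf("  topic coverage: %d/%d (%.1f%%)\n",
              x$coverage$n, x$n_kb_topics, x$coverage$pct))
  invisible(x)
}
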