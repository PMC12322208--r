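test_that("baseline prompts contain the one-liner and one answer marker", {
  kb <- fixture_kb()
  spec <- prompt_spec("topic_prediction", "baseline", m = 1)
  p <- build_prompt("62 M with pleuritic chest pain and tachycardia", spec, kb)
  expect_equal(lengths(regmatches(p, gregexpr("62 M with pleuritic chest pain", p))), 1)
  expect_equal(lengths(regmatches(p, gregexpr("Answer:", p))), 1)
})

test_that("ICL prompts embed k labeled examples in retrieval order", {
  kb <- fixture_kb()
  ex <- tibble::tibble(
    text = paste0("example case ", 1:4),
    label = c("Chronic cough", "Major Blunt Trauma", "Uncomplicated headache",
              "Suspected Pulmonary Embolism")
  )
  spec <- prompt_spec("topic_prediction", "icl", k_context = 4)
  p <- build_prompt("55 F p/w chronic cough", spec, kb, context = ex)
  pos <- vapply(ex$text, function(tx) regexpr(tx, p, fixed = TRUE)[1], numeric(1))
  expect_true(all(pos > 0) && all(diff(pos) > 0))
  expect_true(all(vapply(ex$label, grepl, logical(1), x = p, fixed = TRUE)))
  expect_error(build_prompt("case", spec, kb, context = ex[1:2, ]), "k_context")
})

test_that("RAG prompts embed retrieved chunks; COT styles insert their block", {
  kb <- fixture_kb()
  spec <- prompt_spec("topic_prediction", "rag", k_context = 2)
  p <- build_prompt("55 F p/w cough", spec, kb,
                    context = c("chunk about cough imaging", "chunk about PE"))
  expect_true(grepl("chunk about cough imaging", p, fixed = TRUE))
  expect_error(build_prompt("case", spec, kb), "k_context")

  p_diff <- build_prompt("55 F p/w cough",
                         prompt_spec("topic_prediction", "cot", cot_style = "differential"), kb)
  expect_true(grepl("differential diagnosis", p_diff))
  p_def <- build_prompt("55 F p/w cough",
                        prompt_spec("topic_prediction", "cot", cot_style = "default"), kb)
  expect_false(grepl("differential diagnosis", p_def))
})

test_that("prompts are injective in the one-liner for a fixed spec", {
  kb <- make_kb(seed = 6)
  cases <- make_cases(kb, 4, seed = 6)
  spec <- prompt_spec("topic_prediction", "baseline")
  prompts <- vapply(cases$text, build_prompt, character(1), spec = spec, kb = kb)
  expect_equal(anyDuplicated(prompts), 0)
})

test_that("topic parsing extracts, normalizes, dedupes and truncates", {
  kb <- fixture_kb()
  expect_identical(parse_topic_response("Answer: Chronic cough", kb, 1)$topics,
                   "Chronic cough")
  # dedupe preserving order
  pp <- parse_topic_response("Answer: Chronic cough; Chronic cough", kb, 2)
  expect_identical(pp$topics, "Chronic cough")
  # truncation to m and unmatched items dropped
  pp2 <- parse_topic_response(
    "reasoning...\nAnswer: 1. Major Blunt Trauma\n2. Gibberish label\n3. Chronic cough",
    kb, 2)
  expect_identical(pp2$topics, c("Major Blunt Trauma", "Chronic cough"))
  # nothing parseable
  expect_true(parse_topic_response("I cannot determine this.", kb, 1)$unparsed)
  # answer taken after the FINAL marker
  pp3 <- parse_topic_response("Answer: not a topic. Final Answer: chronic cough", kb, 1)
  expect_identical(pp3$topics, "Chronic cough")
})

test_that("topic parsing round-trips every canonical topic rendered after the marker", {
  for (kb in list(fixture_kb(), make_kb(seed = 12))) {
    for (nm in kb_topic_names(kb)) {
      out <- parse_topic_response(paste0("Answer: ", nm), kb, 1)
      expect_identical(out$topics, nm)
    }
  }
})

test_that("imaging parsing matches the vocabulary and sentinel aliases", {
  kb <- fixture_kb()
  expect_identical(parse_imaging_response("Answer: No imaging", kb)$studies, "None")
  expect_identical(
    parse_imaging_response("Answer: CTA pulmonary arteries with IV contrast", kb)$studies,
    "CTA pulmonary arteries with IV contrast")
  expect_true(parse_imaging_response("total garbage ###", kb)$unparsed)
})

test_that("mock backends are deterministic and honor scripts", {
  kb <- fixture_kb()
  be <- mock_backend(script = c("pleuritic chest pain" = "Answer: Suspected Pulmonary Embolism"))
  p <- build_prompt("62 M with pleuritic chest pain",
                    prompt_spec("topic_prediction", "baseline"), kb)
  expect_identical(generate(be, p, 0, 1), "Answer: Suspected Pulmonary Embolism")
  expect_identical(generate(be, p, 0, 1), generate(be, p, 0, 1))
  # unscripted prompt without fallback -> non-matching text
  expect_true(parse_topic_response(generate(be, "other prompt", 0, 1), kb, 1)$unparsed)
  # content-hash script keys work too
  be2 <- mock_backend(script = stats::setNames("Answer: Chronic cough",
                                               as.character(content_hash(p))))
  expect_identical(generate(be2, p, 0, 0), "Answer: Chronic cough")
})

test_that("confusion-backend error rates match the confusion model", {
  spec <- simulation_spec(n_topics = 5, n_sibling_pairs = 2, n_cases_per_topic = 125)
  kb <- make_kb(spec, seed = 21)
  cases <- make_cases(kb, spec$n_cases_per_topic, seed = 21)
  cm <- sibling_confusion(kb, p = 0.30)
  be <- make_confusion_backend(kb, cases, cm)
  pspec <- prompt_spec("topic_prediction", "baseline")
  sib <- unlist(attr(kb, "sibling_pairs"))
  sub <- cases[cases$label %in% sib, ][1:500, ]
  pred <- vapply(seq_len(nrow(sub)), function(i) {
    p <- build_prompt(sub$text[i], pspec, kb)
    parse_topic_response(generate(be, p, 0, seed = 0), kb, 1)$topics[1]
  }, character(1))
  err <- mean(pred != sub$label)
  sigma <- sqrt(0.3 * 0.7 / 500)
  expect_lt(abs(err - 0.30), 3 * sigma)
  # determinism contract: same (prompt, seed) -> same text
  p1 <- build_prompt(sub$text[1], pspec, kb)
  expect_identical(generate(be, p1, 0, 3), generate(be, p1, 0, 3))
})
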