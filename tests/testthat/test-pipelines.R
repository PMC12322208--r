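test_that("evidence pipeline: correct topic gives identical study sets", {
  kb <- fixture_kb()
  rec <- one_liner_records("c1", "49 M with chronic non-productive cough",
                           subset = "Synthetic", label = "Chronic cough")
  be <- mock_backend(script = c("chronic non-productive cough" = "Answer: Chronic cough"))
  ev <- run_evidence_pipeline(rec, be, kb, prompt_spec("topic_prediction", "baseline"))
  expect_identical(ev$y_pred[[1]], "Chronic cough")
  expect_identical(ev$K_pred[[1]], ev$K[[1]])
  expect_equal(case_imaging_accuracy(ev), 1)
})

test_that("sibling topic predictions are topic-wrong but imaging-right", {
  kb <- fixture_kb()
  rec <- one_liner_records("c1", "30 M unrestrained driver in high-speed MVC",
                           subset = "Synthetic", label = "Major Blunt Trauma")
  be <- mock_backend(script = c("high-speed MVC" = "Answer: Penetrating Torso Trauma"))
  ev <- run_evidence_pipeline(rec, be, kb, prompt_spec("topic_prediction", "baseline"))
  expect_identical(ev$y_pred[[1]], "Penetrating Torso Trauma")
  expect_false(topic_accuracy(ev) == 1)
  expect_equal(case_imaging_accuracy(ev), 1)  # shared "Radiography trauma series"
})

test_that("nonsense output is recorded as unparsed with zero accuracy", {
  kb <- fixture_kb()
  rec <- one_liner_records("c1", "some case text", subset = "Synthetic",
                           label = "Chronic cough")
  be <- mock_backend()  # always answers non-matching text
  ev <- run_evidence_pipeline(rec, be, kb, prompt_spec("topic_prediction", "baseline"))
  expect_true(ev$unparsed)
  expect_length(ev$K_pred[[1]], 0)
  expect_equal(case_imaging_accuracy(ev), 0)

  # backend that throws is recorded, not propagated
  boom <- completion_backend(function(prompt, temperature, seed) stop("api down"))
  ev2 <- run_evidence_pipeline(rec, boom, kb, prompt_spec("topic_prediction", "baseline"))
  expect_true(ev2$unparsed)
})

test_that("baseline pipeline scores direct study predictions", {
  kb <- fixture_kb()
  spec <- prompt_spec("imaging_prediction", "baseline")
  rec <- one_liner_records("c1", "62 M with pleuritic chest pain", "Synthetic",
                           label = "Suspected Pulmonary Embolism")
  be_in <- mock_backend(script = c("pleuritic" = "Answer: V/Q scan lung"))
  be_out <- mock_backend(script = c("pleuritic" = "Answer: Radiography chest"))
  expect_equal(case_imaging_accuracy(run_baseline_pipeline(rec, be_in, kb, spec)), 1)
  expect_equal(case_imaging_accuracy(run_baseline_pipeline(rec, be_out, kb, spec)), 0)

  # sentinel agreement on a no-imaging case
  rec2 <- one_liner_records("c2", "28 F with mild tension headache", "Synthetic",
                            label = "Uncomplicated headache")
  be_none <- mock_backend(script = c("tension headache" = "Answer: No imaging"))
  ev <- run_baseline_pipeline(rec2, be_none, kb, spec)
  expect_equal(case_imaging_accuracy(ev), 1)
  expect_equal(unnecessary_rate(ev), 0)
})

test_that("multi-topic unions deduplicate and drop the sentinel when imaging is warranted", {
  kb <- fixture_kb()
  u <- resolve_topics_union(kb, c("Uncomplicated headache", "Chronic cough"))
  expect_identical(u, "Radiography chest")
  u2 <- resolve_topics_union(kb, c("Uncomplicated headache", "Chronic cough"),
                             drop_sentinel = FALSE)
  expect_setequal(u2, c("None", "Radiography chest"))
  u3 <- resolve_topics_union(kb, c("Major Blunt Trauma", "Penetrating Torso Trauma"))
  expect_identical(u3, "Radiography trauma series")
  expect_identical(resolve_topics_union(kb, "Uncomplicated headache"), "None")
})

test_that("benchmark runs cases x seeds with a perfect mock at ceiling metrics", {
  kb <- make_kb(seed = 31)
  cases <- make_cases(kb, 2, seed = 31)[1:10, ]
  be <- make_confusion_backend(kb, cases, identity_confusion(kb))
  cfg <- run_config("evidence", prompt_spec("topic_prediction", "baseline"), seeds = 0:4)
  ev <- run_benchmark(cases, cfg, be, kb)
  expect_equal(nrow(ev), 50)
  rep <- metric_report(ev)
  expect_equal(rep$topic_accuracy, 1)
  expect_equal(rep$imaging_accuracy, 1)
  expect_equal(rep$fpr, 0)
  expect_equal(rep$fnr, 0)
  expect_equal(unname(rep$ci95$topic_accuracy), c(1, 1))  # zero-width CI
})

test_that("benchmark accuracy under a known confusion rate is binomially consistent", {
  spec <- simulation_spec(n_topics = 5, n_sibling_pairs = 2, n_cases_per_topic = 60)
  kb <- make_kb(spec, seed = 8)
  cases <- make_cases(kb, spec$n_cases_per_topic, seed = 8)
  sib <- unlist(attr(kb, "sibling_pairs"))
  cases <- cases[cases$label %in% sib, ]  # 240 cases, all confusable at 0.2
  be <- make_confusion_backend(kb, cases, sibling_confusion(kb, p = 0.2))
  cfg <- run_config("evidence", prompt_spec("topic_prediction", "baseline"), seeds = 0:1)
  ev <- run_benchmark(cases, cfg, be, kb)
  expect_equal(nrow(ev), nrow(cases) * 2)
  acc <- topic_accuracy(ev)
  sigma <- sqrt(0.8 * 0.2 / nrow(ev))
  expect_lt(abs(acc - 0.8), 3 * sigma)

  excl <- apply_exclusions(cases, stats::setNames(as.list(rep(1, nrow(cases))), cases$id))
  expect_error(run_benchmark(excl, cfg, be, kb), "no included records")
})

test_that("imaging accuracy dominates topic accuracy on every synthetic run", {
  for (seed in 1:5) {
    spec <- simulation_spec(n_topics = 7, n_sibling_pairs = 2, n_cases_per_topic = 8)
    kb <- make_kb(spec, seed = seed)
    cases <- make_cases(kb, spec$n_cases_per_topic, seed = seed)
    cm <- sibling_confusion(kb, p = 0.5, unparsed_rate = 0.05)
    be <- make_confusion_backend(kb, cases, cm)
    cfg <- run_config("evidence", prompt_spec("topic_prediction", "baseline"), seeds = 0:1)
    ev <- run_benchmark(cases, cfg, be, kb)
    expect_gte(mean(case_imaging_accuracy(ev)), topic_accuracy(ev))
  }
})

test_that("evaluations round-trip through JSONL", {
  kb <- fixture_kb()
  rec <- one_liner_records(c("a", "b"), c("case one text", "case two text"),
                           "USMLE", c("Chronic cough", "Uncomplicated headache"))
  be <- mock_backend(script = c("case one text" = "Answer: Chronic cough"))
  cfg <- run_config("evidence", prompt_spec("topic_prediction", "baseline"), seeds = 0)
  ev <- run_benchmark(rec, cfg, be, kb)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_evaluations(ev, path)
  back <- read_evaluations(path)
  expect_equal(as.data.frame(back), as.data.frame(ev))
})
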