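# radalign

Evaluation tooling for **guideline-aligned diagnostic imaging
recommendations from language models**.

Evidence-based appropriateness guidelines (such as the ACR Appropriateness
Criteria) map named clinical scenarios — *Topics* — to the imaging studies
appropriate for them, including "no imaging warranted". Clinicians, however,
communicate in free-text one-liners. `radalign` implements and evaluates two
ways to bridge that gap with a text-completion backend:

* **Baseline pipeline** — the model names an imaging study directly.
* **Evidence-based pipeline** — the model only classifies the one-liner into
  a guideline Topic; the study set is then resolved by *deterministic lookup*
  in a versioned Topic → studies knowledge base. The model never picks
  studies.

The package provides the knowledge-base format with validation and fuzzy
topic normalization, one-liner dataset I/O with exclusion bookkeeping,
retrieval machinery for prompt context (Okapi BM25, cosine-similarity
embedding ranking, uniform random retrieval, fixed-width corpus chunking),
prompt construction and answer parsing for baseline / chain-of-thought /
in-context-learning / retrieval-augmented strategies, a multi-seed benchmark
runner with a deterministic mock-backend contract, the set-based metric
suite, and a reader-study regression with question fixed effects and two-way
cluster-robust standard errors.

## The core quantities

For a case with ground-truth study set *K* (from the true Topic) and
predicted study set *K_pred*:

* **Imaging accuracy** = |K_pred ∩ K| / |K_pred| — fraction of recommended
  studies that are guideline-appropriate.
* **FPR / unnecessary-imaging rate** — cases with K = {None} where imaging
  was nonetheless recommended; **FNR / missed-imaging rate** — the mirror.
* **F1** = 2·TP / (2·TP + FP + FN), TP counting cases where a clinically
  indicated study was ordered.
* **DSC** = 2|A∩B| / (|A|+|B|) — agreement between two decision makers.

Because clinically adjacent Topics often share identical study sets, the
evidence-based pipeline satisfies a *dominance* property: mean imaging
accuracy ≥ topic accuracy — wrong Topics frequently still order the right
studies.

The prospective reader study is analyzed with a linear probability model

    y_sq = b0 + b1 * guidance_sq + theta_q + chi_s + e_sq

with question fixed effects, participant covariates, and standard errors
clustered on participants *and* questions
(inclusion–exclusion / Cameron–Gelbach–Miller, t inference with
min(G_s, G_q) − 1 df).

## Worked example

Everything below is synthetic and deterministic — no network, no real model.

```r
library(radalign)

# miniature guideline KB: 6 topics, one no-imaging topic, one sibling pair
spec <- simulation_spec(n_topics = 6, n_sibling_pairs = 1)
kb <- make_kb(spec, seed = 7)
kb
#> <guideline_kb> 6 topics, 9 studies (snapshot synthetic-2024-06)

cases <- make_cases(kb, n_per_topic = 10, seed = 7)
cases$text[1]
#> [1] "18 F with HTN and 1 pack-year smoking hx p/w acute knee injury x6d"

# a mock backend that confuses each sibling topic with its pair half the time
backend <- make_confusion_backend(kb, cases, sibling_confusion(kb, p = 0.5))
cfg <- run_config("evidence", prompt_spec("topic_prediction", "baseline"),
                  seeds = 0:4)
evals <- run_benchmark(cases, cfg, backend, kb)
metric_report(evals)
#> <metric_report> 60 cases x 5 seed(s) (300 rows)
#>   topic accuracy   0.837
#>   imaging accuracy 1.000
#>   FPR (all) 0.000 | FNR (all) 0.000 | F1 1.000
```

Topic accuracy is ~0.83 (two of six topics are confused with each other half
the time), yet imaging accuracy is exactly 1.0: the confused siblings share
an identical appropriate-study set, so the *recommendation* is unharmed —
the mechanism the evidence-based pipeline is designed around.

```r
# simulated reader study: 30 participants x 50 questions, true effect 0.081
sim <- make_prospective_grid(simulation_spec(), seed = 7)
fit_guidance_model(sim$responses)
#> <guidance_fit> outcome 'outcome': beta1 = 0.1162 (95% CI 0.0777 to 0.1547), p = 9.755e-07
#>   n = 1500 responses, 30 participants x 50 questions, 49 fixed effects
```

The fitted guidance effect (here 0.116 for one random grid) estimates the
accuracy gain, on the probability scale, from showing model recommendations;
its 95% interval covers the generating value 0.081.

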