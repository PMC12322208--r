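---
title: "Methods: guideline-aligned evaluation of imaging recommendations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guideline-aligned evaluation of imaging recommendations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radalign)
```

## The problem and the two pipelines

Ordering the right diagnostic imaging study for an acutely presenting patient
is a guideline-lookup problem wrapped in a language problem. Evidence-based
appropriateness guidelines (such as the ACR Appropriateness Criteria) map
named clinical scenarios — *Topics* — to the set of imaging studies
considered appropriate, including the possibility that *no* imaging is
warranted. What a clinician actually has in hand, though, is a free-text
"one-liner" ("49 M with HTN and 20 pack-year smoking hx p/w chronic cough").

`radalign` implements and evaluates two ways to get from the one-liner to an
imaging recommendation with a large language model (LLM):

* **Baseline pipeline** — ask the model to name an imaging study directly.
  The model output *is* the recommendation.
* **Evidence-based pipeline** — ask the model only to *classify* the
  one-liner into a guideline Topic (up to `m` Topics), then resolve the
  Topic(s) to the appropriate-study set by deterministic lookup in a pinned
  guideline knowledge base. The model never chooses studies; the guidelines
  do.

The package's claim of interest is mechanical rather than empirical: the
classification step is a much easier target for an LLM than study selection,
and even *wrong* Topic predictions often resolve to the *right* studies,
because clinically adjacent Topics ("Major Blunt Trauma" vs "Penetrating
Torso Trauma") frequently share identical appropriate-study sets. The
synthetic fixtures are built to expose exactly this mechanism.

## The knowledge base

A `guideline_kb` is a versioned snapshot: Topics, each with one or more
clinical *variants*, each variant carrying a study set over a fixed study
vocabulary. Real guidelines describe several variants per Topic with
different recommendations; deterministic lookup requires committing to one.
That choice is curation data, not something the library infers: the snapshot
stores a `canonical` flag and `validate_kb()` enforces exactly one canonical
variant per Topic. A dedicated sentinel study, canonically spelled `"None"`
(with "no imaging" accepted as an input alias), marks scenarios where no
imaging is warranted; a variant's study set is never empty — it is either
real studies or exactly the sentinel.

Model output is free text, so Topic strings are normalized before lookup:
case, whitespace and punctuation are canonicalized, then an exact match is
preferred; otherwise the best candidate by token-set Dice similarity is
accepted iff its similarity is at least 0.90 (ties broken alphabetically).
The threshold is deliberately conservative: an incorrect free-text Topic
should be *scored wrong*, not silently mapped to the nearest canonical name.
0.90 admits word reorderings and trivial rephrasings of a canonical name and
little else; it is exposed as an argument for users who want to study the
trade-off.

## Datasets and bookkeeping

One-liner records carry an id, the text, a source-subset tag, an optional
ground-truth Topic label, and an optional exclusion code in 1–4 (no guideline
guidance exists; imaging/diagnosis already done; insufficient information;
not a specific patient presentation). Exclusion is a human judgment: the
package records and tallies annotations, it never auto-classifies.
`summarize_dataset()` reports per-subset sizes, per-reason exclusion counts,
and topic coverage (Topics with non-zero support) as counts and one-decimal
percentages, rounded half away from zero to match conventional printed
style (base R's `round()` rounds half to even, which changes printed values).

First-sentence extraction uses a boundary rule — sentence punctuation
followed by whitespace and an uppercase letter or digit — with a guard list
for clinical abbreviations ("Dr.", "y.o.", "s/p", single-letter initials).
Clinical text is abbreviation-dense; a naive splitter truncates at "Dr." and
similar tokens. The splitter is idempotent and returns the whole text when
no boundary exists, so telegraphic one-liners pass through unchanged.

## Retrieval for prompt context

Retrieval-augmented prompts embed guideline narrative chunks; in-context
learning prompts embed labeled example one-liners. Both reuse three rankers:

* **Okapi BM25** with the non-negative idf variant
  `idf = ln(1 + (N - df + 0.5)/(df + 0.5))` and the standard defaults
  `k1 = 1.5`, `b = 0.75`. Tokenization is lowercase, split on
  non-alphanumerics, no stemming or stop words — the simplest fully
  reproducible choice.
* **Cosine similarity** over a pluggable embedding function. Any
  `text -> numeric vector` contract plugs in; zero-norm embeddings score 0
  with a warning rather than producing NaN.
* **Uniform random retrieval**, the baseline, seed-deterministic.

Ties everywhere break toward the lower chunk id, making rankings fully
deterministic. The corpus chunker packs sentence/paragraph units greedily
into chunks of 1119–2048 characters (the window sizes conventional for
guideline-narrative corpora of this kind), hard-splitting only units that
alone exceed the maximum. Chunks are never merged across sources; an
under-minimum remainder is *flagged* rather than dropped or merged, and the
concatenation of a source's chunks reproduces the source text byte for byte.
The exact boundary rule is one consistent realization of a fixed-width
segmentation — re-chunking with other unit definitions changes chunk
boundaries but none of the package's guarantees.

## Prompts, backends, parsing

A `prompt_spec` selects the task (Topic classification vs direct imaging
prediction), the strategy (baseline, chain-of-thought, in-context learning,
retrieval-augmented), a chain-of-thought style (default / differential /
bayesian / analytic), the context size `k` (conventionally 8 retrieved
chunks for RAG, 4 labeled examples for ICL), and the Topic budget `m`.
Templates are plain text with `{{one_liner}}`, `{{context}}`,
`{{reasoning}}`, `{{m}}` placeholders and can be overridden from files, so
prompt wording is configuration, not code.

A *completion backend* is any object satisfying
`generate(prompt, temperature, seed) -> text` with the determinism contract:
at temperature 0 and fixed seed, identical prompts yield identical text.
Benchmarks run at temperature 0 across five seeds (0–4) by default.

Answer parsing takes the substring after the final `Answer:` marker (falling
back to the last non-empty line, since chain-of-thought output reasons before
answering), splits on newlines / semicolons / numbered-list markers,
normalizes each item, drops unmatched items, de-duplicates preserving order,
and truncates to `m`. A response in which nothing matches is recorded as
*unparsed*: it scores 0 on all accuracy metrics and is tallied separately,
because silently dropping such cases would inflate accuracy.

The mock backend answers from a script keyed by prompt hash or embedded case
text, with an optional *confusion model* fallback: a row-stochastic matrix
over Topics plus an unparsed-text probability. Draws are seeded by a hash of
(prompt, seed), so the mock satisfies the determinism contract exactly. The
`sibling_confusion()` model routes errors to a Topic sharing an identical
study set, reproducing the right-study/wrong-topic mechanism with a
closed-form expectation (topic accuracy `1 - p`, imaging accuracy 1).

## Metrics

With ground-truth study set `K` (never empty) and prediction `K_pred`:

* **Imaging accuracy** `|K_pred ∩ K| / |K_pred|` — the fraction of
  recommended studies that are guideline-appropriate. Empty predictions
  (unparsed output) score 0 by convention; the real pipelines always emit a
  prediction, so the convention only touches degenerate mocks.
* **Topic accuracy** — exact-match indicator; for `m > 1`, correct iff the
  single true Topic appears among the predictions.
* **Unnecessary-imaging rate (FPR)** — cases where `K = {None}` yet the
  sentinel is absent from `K_pred`; **missed-imaging rate (FNR)** — the
  mirror image. Two denominators are reported: `all` evaluated cases (the
  default, the literal frequency reading) and `conditional` (dividing by
  the cases satisfying the ground-truth condition, i.e. the rate *among*
  patients for whom the condition applies). Both are carried in every
  report because the two readings answer different questions and printed
  summaries in this literature use both.
* **F1** `2TP / (2TP + FP + FN)` with TP = cases where a clinically
  indicated (non-sentinel) study was ordered.
* **Dice–Sørensen coefficient** `2|A∩B| / (|A|+|B|)` between two decision
  makers' per-case study sets, aggregated with a Student-t 95% interval
  over cases.

When multiple predicted Topics are resolved (`m > 1`), their study sets are
unioned with de-duplication and the sentinel is dropped whenever any real
study is present — a Topic that warrants imaging dominates one that does
not. This is configurable (`drop_sentinel`) because either convention is
defensible; the dominance theorem (mean imaging accuracy ≥ topic accuracy)
holds under both.

## The reader-study regression

The prospective reader study is modeled as a linear probability model

$$y_{s,q} = \beta_0 + \beta_1\,\mathrm{guidance}_{s,q} + \theta_q + \chi_s + \varepsilon_{s,q}$$

for participant $s$ and question $q$, with question fixed effects as
explicit dummies (≈50 questions keeps this tractable) and participant
covariates (role, AI experience, AI sentiment). The model is linear in the
binary outcome — coefficients are probability differences, directly
interpretable as accuracy gains.

Standard errors are clustered two ways, on participants and questions, by
inclusion–exclusion: $V = V_s + V_q - V_{s \cap q}$, each component a
clustered sandwich with the small-sample correction
$\frac{G}{G-1}\cdot\frac{N-1}{N-K}$, the intersection component clustering
on participant-by-question cells (singletons here). Inference uses a t
distribution with $\min(G_s, G_q) - 1$ degrees of freedom.

Two numerical choices deserve explanation:

* The inclusion–exclusion difference is not guaranteed positive
  semi-definite. The non-negativity guard (eigendecompose, truncate negative
  eigenvalues to zero) is applied **only when the guidance-coefficient
  variance itself comes out non-positive**, with a message. Projecting the
  whole matrix unconditionally is tempting but wrong in practice: with many
  fixed-effect dummies the matrix is *routinely* indefinite in directions
  irrelevant to $\beta_1$, and the projection contaminates the $\beta_1$
  variance — in our null simulations unconditional truncation drove the
  rejection rate at $\alpha = 0.05$ down to 0.01–0.03, while the
  conditional guard keeps it at its nominal level (≈0.05 at grids from
  20×12 to 30×50).
* Singular designs (e.g. a guidance flag collinear with a fixed effect) are
  reported as errors naming the offending column, and constant outcomes
  yield $\beta_1 = 0$ with a degenerate-variance warning rather than NaN.

Guidance assignment replicates the study design: per participant, a uniform
random half of the questions (25 of 50) shows model recommendations,
seed-deterministic. The agreement outcome (did the participant order exactly
what the model recommended, under study-name normalization with sentinel
aliases) is derived by `agreement_outcome()` and fits in the same model.

## What the synthetic generators emulate — and what they do not

The generator defaults *are* the study conditions: five-seed benchmark runs
at temperature 0; a reader study with 30 participants (23 students, 7
physicians), 50 questions, guidance on a random half, a no-guidance base
rate of 0.158 and a true guidance effect of 0.081 on the probability scale;
knowledge bases with at least one no-imaging Topic and sibling-pair Topics
sharing identical study sets; question effects as centered Gaussians
(sd 0.05) and small covariate effects (0.01–0.02), values a reader study of
this size could plausibly exhibit. Success probabilities are clipped to
[0, 1] (with a warning counting clipped cells) rather than logit-transformed,
matching the linear probability model being fit.

Synthetic one-liners are telegraphic templates, so they exercise the
sentence splitter, prompt plumbing and matching machinery on realistic
*shape* — but they carry no real clinical signal. Passing tests therefore
demonstrate that the pipeline, metrics and statistics are implemented
correctly and are well calibrated; they say nothing about how any particular
LLM performs on real one-liners, which requires a real backend and a real
guideline snapshot. Likewise the miniature KBs (6–224 Topics, tens of
studies) validate the lookup semantics, not the content of any real
guideline.

## Problem sizes used by the test suite

Chosen so the full suite and the acceptance script each run in a couple of
minutes on a single CPU: bookkeeping on a 224-Topic KB with 2513 records;
sibling-confusion runs on 2000 cases at one seed; perfect-backend runs on
30–60 cases across five seeds; ranker-vs-oracle checks on 3–10-document
corpora; regression recovery on the full 30×50 grid (8 replicates) and null
calibration on a reduced 20×12 grid (2000 replicates, empirically nominal
at that size); comparison-test calibration with 2000 replicates each, the
McNemar simulation at 1000 pairs so its chi-square branch (discordant
pairs ≥ 25) is exercised — the exact-binomial branch is intrinsically
conservative at small counts, a property of exact tests, not of the
implementation.

## Known limitations

* The canonical-variant choice per Topic is curation data; the package
  validates uniqueness but cannot decide clinical appropriateness.
* The fuzzy-match threshold (0.90 token-set Dice) is a design point, not a
  fitted value; extremely terse Topic names (single tokens) leave little
  room between "exact" and "unmatched".
* The linear probability model can predict outside [0, 1]; that is inherent
  to the estimand (probability differences) and mirrored by the clipped
  generator, but users wanting link-scale effects should fit their own GLM.
* Two-way cluster-robust inference is asymptotic in the *smaller* cluster
  count; with very few questions or participants the t approximation (df =
  min(G) − 1) is only a partial remedy.
* Real-backend plumbing (retries, timeouts) is deliberately out of the
  determinism contract; reproducibility claims apply to temperature-0,
  fixed-seed runs only.
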