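# rdrkit

Knowledge-based rare disease recognition from clinical text, as a local,
deterministic R toolkit.

Rare diseases affect hundreds of millions of people, yet individual
diagnoses are routinely delayed for years because no single clinician can
hold several thousand rare phenotypes in mind. `rdrkit` implements the
computational side of a *knowledge-layer-first* approach for informaticians
and methods researchers: instead of asking a model to diagnose, it organizes
structured disease knowledge into a computable layer and runs lightweight,
fully reproducible inference on top of it. No external model weights, API
calls or protected health data are needed — every component runs offline
and is testable on synthetic data with known ground truth.

## What it implements

**Disease-knowledge layer.** Diseases are described by ten-section markdown
profiles (overview, synonyms, subtypes, epidemiology, etiology, clinical
presentation, diagnostic evaluation, management, investigational therapies,
prognosis). A deterministic dictionary matcher extracts clinical concepts
from a TSV lexicon (CUI-like ids over four semantic groups) at a
configurable similarity threshold (default 0.8), yielding per-section and
per-semantic-group concept indexes (`build_knowledge_base()`).

**Two-stage screening.** For a patient's clinical presentation text:

- *Stage 1* ranks the whole disease space twice — Okapi BM25
  (k1 = 1.5, b = 0.75) over extracted concept bags, and cosine similarity of
  deterministic hashed term-frequency embeddings over disease documents
  (name + four core sections) — and fuses the two lists by reciprocal rank
  fusion:

  `score_RRF(d) = 1/(s + rank_dense(d)) + 1/(s + rank_sparse(d))`, s = 60.

- *Stage 2* rescores the top K = 20 fused candidates with a
  knowledge-boosted reranker (shipped fallback: IDF-weighted concept
  overlap between patient text and disease document), with a names-only
  ablation mode.

**Gated ensemble.** Across multiple knowledge sources, the ranking with the
highest summed pairwise Spearman correlation over top-3 diseases is
selected per patient (`gated_select()`).

**Longitudinal discrimination.** From pre-diagnostic notes (18 to 3 months
before the index date), mentions are context-classified (negated / family
history / historical / hypothetical / possible / other; only the last two
are kept), coded into a per-patient week × concept three-level matrix, and
summarized by co-occurrence pair features and symptom importance scores

  `SIS(c) = log2((freq_case(c) + 5) / (freq_ctrl(c) + 5))`,

with patient weight `SIS(c) * (1 + freq_pa(c))` and
`normalized_weight = total_symptom_weight / (pair_week_agg + 1)`. A
logistic classifier on the three patient-level features is evaluated by
stratified out-of-bag bootstrap (100 repetitions, expected 2:1 train:test),
with Youden-index cutoffs, AUROC/F1 and percentile confidence intervals.

**Quality metrics.** SMOG readability, reference-host categorization,
unique-concept counts per semantic group, concept-set Jaccard overlap and
quadratic-weighted Cohen's kappa.

## Worked example

```r
library(rdrkit)

# synthetic benchmark: 200 diseases, 500 cases with known ground truth
bench <- generate_benchmark(bench_gen_config(seed = 1))
kb <- build_knowledge_base(bench$profiles, bench$lexicon)

res <- screen_patient(bench$cases$text[1], kb, query_id = "P00001")
head(res$stage2, 3)
#>   disease_id     score
#> 1      D0001 27.645324
#> 2      D0160  5.610158
#> 3      D0150  5.610158

bench$cases$truth_disease_id[1]
#> [1] "D0001"
```

The true disease is ranked first: the reranker score (27.6) is the summed
inverse-document-frequency of the concepts shared between the case text and
the disease document, so a disease explaining many rare findings dominates.
Across all 500 cases the two-stage pipeline reaches Recall@1 = 0.982
versus 0.698 for stage 1 alone (printed by `scripts/acceptance.R` below).

For the longitudinal pipeline:

```r
coh <- generate_cohort(cohort_gen_config(seed = 2))   # 200 cases, 200 controls
out <- discriminate_cohort(coh$notes, coh$lexicon, coh$target_concepts,
                           weighting = "sis",
                           config = bootstrap_config(seed = 3))
out$result
#> <discrimination_result> 100 repetitions
#>   AUROC 0.993 (95% CI 0.961-1.000)
#>   F1    0.984 (95% CI 0.958-1.000)
#>   mean out-of-bag fraction 0.369
```

## Command-line use

A thin CLI over the same functions lives at `inst/cli/rdrkit`:

```sh
Rscript inst/cli/rdrkit simulate-benchmark --out sim --n-diseases 50 --n-cases 100 --seed 1
Rscript inst/cli/rdrkit build-kb --lexicon sim/lexicon.tsv --profiles sim/profiles/synthetic_source --out kb
Rscript inst/cli/rdrkit screen --lexicon sim/lexicon.tsv --kb sim/profiles/synthetic_source \
        --patients sim/cases.jsonl --out scr
```

Every command writes a manifest (config snapshot, seed, package version,
input digests) alongside its outputs.

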