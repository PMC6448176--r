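# problistr

Semantic grouping and ICD-10 post-coding of EHR problem lists.

## What it is for

Clinical problem (diagnosis) lists in hospital information systems are
often capped at 50 characters per entry and grow one entry per coded
diagnosis per stay. For chronic patients this produces hundreds of highly
redundant lines — the same condition re-typed, abbreviated, decorated with
dates or medications, sometimes ICD-10-coded and sometimes not. `problistr`
is for informaticians who need to (a) compress such a list into navigable
semantic **topics** and (b) **post-code** the uncoded entries by letting
them inherit the code of their most similar coded neighbour.

## The method

Entries are normalized (tokenization, lowercasing, German stopword
removal, Snowball German stemming, stripping of `[\d\.\,\_\:]+` spans) and
represented as tf-idf weighted character 3-gram vectors; document
similarity is the cosine. Unique strings are clustered with average-linkage
(UPGMA) agglomerative clustering on the distances `1 − cos`, where the
distance between clusters C₁, C₂ is

    (1 / |C₁||C₂|) · Σ_{i∈C₁} Σ_{j∈C₂} (1 − cos(dᵢ, dⱼ))

The dendrogram cut height is not fixed a priori: it is inferred by cutting
at every height on a grid (0–1, step 0.01) and scoring each flat partition
against the *available* 3-digit ICD-10 codes with a pairwise F-measure;
the smallest height maximizing F wins. Uncoded items that share a cluster
with at least one coded item then inherit the code of the most similar
coded member (per-item nearest neighbour, deterministic tie-breaks).
Optionally the term-document matrix is reduced by latent semantic analysis
(truncated SVD, `X = T S Dᵀ`) before clustering. An evaluation battery
(precision/recall/F for post-coding and clustering, compression rates,
Chernoff-bound sample sizing `n ≥ 3/ε² · ln(2/δ)`) and a synthetic
problem-list generator with known topic truth complete the package.

## Worked example

```r
library(problistr)

cfg <- synth_config(n_patients = 2, items_per_patient = c(120, 120),
                    coded_fraction = 0.6, seed = 7)
corpus <- generate_corpus(cfg)   # 240 items, 16 hidden topics, 40% masked
fit <- problist_fit(corpus)
summary(fit)
```

```
Problem-list grouping summary
  list items        240
  unique list items 157
  topics            21
  compression rate  0.91
  inferred cut-off  0.68 (pairwise F 0.93)
  post-coded        0.97 of uncoded items
  post-coding P/R/F 0.99 / 0.97 / 0.98
  weighted combination F  0.95
```

Reading: the 240 noisy entries (157 distinct strings) collapse into 21
topics — a 91% compression of the original list. The cut height 0.68 was
selected because it best reproduces the visible ICD-10 grouping (pairwise
F 0.93 on coded items). 97% of the uncoded entries shared a cluster with a
coded one and received its code; against the generator's hidden truth
those assignments score precision 0.99 and recall 0.97. `predict(fit)`
returns the per-item assignments (donor item and cosine similarity
included), `plot(fit)` draws the dendrogram with the inferred cut.

A command-line front end covering the same pipeline (subcommands `synth`,
`run`, `sweep-lsa`, `sample-size`, `evaluate`) ships at
`inst/cli/problistr.R`.

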