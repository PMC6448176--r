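---
title: "Semantic grouping of EHR problem lists: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic grouping of EHR problem lists: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(problistr)
```

## The problem

Hospital problem lists — in the setting this package models, German-language
diagnosis lists whose entries are capped at 50 characters — grow one entry
per coded diagnosis per stay. Elderly or multi-morbid patients accumulate
hundreds of highly redundant entries: the same condition re-entered,
abbreviated, decorated with dates, stages or medications, sometimes with an
ICD-10 code attached and sometimes not. `problistr` groups such entries into
semantic *topics* so a clinician can navigate a compact topic list instead
of the raw one, and at the same time *post-codes* uncoded entries by letting
them inherit the ICD-10 code of the most similar coded entry in their topic.

Two usage scenarios are built in: **intra-patient** (each patient's list is
grouped in isolation; codes can only be learned from the same patient) and
**inter-patient** (lists are pooled, so codes transfer across patients).

## The procedure

`problist_fit()` runs the following chain on one corpus.

1. **Deduplication.** Clustering operates on unique whitespace-trimmed
   description strings; a multiplicity map re-expands results to all items
   afterwards. The representative of a duplicate group is its first coded
   item when one exists, so the group's code survives deduplication, and an
   uncoded duplicate of a coded string inherits that code directly
   (similarity 1). Duplicating strings carry no extra information for the
   clustering itself — identical strings sit at distance 0.

2. **Normalization** (`normalize_text()`): tokenization at non-alphanumeric
   boundaries, lowercasing, removal of a small configurable German
   function-word list, Snowball German stemming, and finally removal of
   character spans matching `[\d\.\,\_\:]+` (dates, enumeration fragments,
   code debris). The stemmer is a from-scratch implementation of the
   published Snowball algorithm for German; because no two Snowball
   dialects agree on every word, the package's stemming fixtures are frozen
   from hand-traces of that algorithm rather than from any external binary.
   The strip pattern is applied after stemming, and tokens fully consumed
   by it are dropped, so a pure date token vanishes entirely.

3. **Character 3-grams** (`char_ngrams()`): a sliding window over each
   token, never crossing token boundaries, no padding. German compounds
   ("Niereninsuffizienz") are the reason for character grams instead of a
   decompounding engine: shared affixes such as *-itis* surface as shared
   grams. Tokens shorter than the window are kept whole, preserving
   clinically salient abbreviations ("CT", "ASS"). A typo changes only the
   few grams overlapping it, which is what makes the representation robust
   to the misspellings routine documentation contains.

4. **tf-idf vector space** (`build_tfidf()`): raw term frequency times
   smoothed inverse document frequency
   \(\mathrm{idf}(t) = \ln\frac{1+n}{1+\mathrm{df}(t)} + 1\),
   columns scaled to unit Euclidean norm. The smoothing keeps idf positive
   even for grams present in every document of a tiny corpus; unit columns
   make cosine similarity a plain dot product. Documents that normalize to
   nothing (for example a bare date) are kept as zero columns — similarity
   0 to everything — so indexing stays aligned with the corpus.

5. **Optional LSA** (`lsa_reduce()`): truncated SVD
   \(X = T S D^\top\), retaining
   \(k = \max(1, \mathrm{round}(f \cdot \min(m, n)))\) dimensions for a
   fraction \(f \in (0, 1]\) — \(\min(m,n)\) because that is the attainable
   rank of the term-document matrix. Document representations are the
   columns of \(S_k D_k^\top\). Cosines in a reduced space can leave
   \([0,1]\); they are clipped so that distances obey the same contract in
   both spaces. Singular-vector signs are fixed (largest-magnitude entry of
   each term-space column made positive) so repeated runs are bit
   identical. Whether tf-idf should be applied before the decomposition or
   folded into \(S\) differently varies across the LSA literature; this
   package fixes \(S_k D_k^\top\) and uses it consistently for clustering
   and post-coding, never mixing spaces.

6. **UPGMA clustering** (`upgma()`): average-linkage agglomeration on
   cosine distances \(1 - \cos\), the inter-cluster distance being the
   unweighted mean over all cross-pairs
   \(\frac{1}{|C_1||C_2|}\sum_{i \in C_1}\sum_{j \in C_2} d(i, j)\).
   The implementation delegates to `stats::hclust(method = "average")`,
   which computes exactly this linkage; the test suite holds it against a
   brute-force \(O(n^3)\) re-derivation on random matrices. The advantage
   of a dendrogram over, say, k-means is that no cluster count must be
   fixed in advance — the cut height is the only free parameter, and it is
   inferred from data.

7. **Cut-off inference** (`infer_cutoff()`): for every height on a grid
   (default 0 to 1 in steps of 0.01), the tree is cut and the flat
   partition is scored against the *visible* 3-digit ICD-10 codes with the
   pairwise F-measure: a coded pair sharing code and cluster is a true
   positive, sharing only the cluster a false positive, sharing only the
   code a false negative. The smallest height attaining the maximum F wins.
   The two-decimal grid is fine enough to express any plausible operating
   point while keeping the search instantaneous; pair counting is the
   standard label-free way to score a partition against partial labels and
   is computed from the cluster-by-code contingency table, not by pair
   enumeration. Cut semantics are closed at the boundary — a merge at
   exactly the cut height joins — and stated explicitly because
   off-by-boundary choices change partitions on gridded heights.

8. **Post-coding** (`post_assign()`): an uncoded item receives a code if
   and only if its cluster contains at least one coded item; it inherits
   the code of its most similar coded cluster member. Mixed clusters are
   resolved per item (each uncoded member follows its own nearest coded
   neighbour), not by cluster majority. Exact ties break to the
   lexicographically smallest donor id, deterministically and with a
   warning. Exactly one code is assigned per entry — compound expressions
   ("Akutes Nierenversagen mit Hyperkaliämie") that deserve two codes are a
   known limitation, and donors are only sought within the cluster, which
   the co-membership rule forces. Existing codes are never altered, even
   when they look wrong.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `ngram_size` | 3 | character window; 3 balances typo robustness against discrimination for 50-character strings |
| `strip_pattern` | `[\d\.\,\_\:]+` | spans removed after stemming (dates, numbering) |
| `stopwords` | bundled list | German function words; one token per line, `#` comments |
| `grid` | `seq(0, 1, 0.01)` | candidate cut heights (cosine distance units) |
| `lsa_fraction` | `NULL` (off) | fraction of `min(m, n)` SVD dimensions retained |
| `mask_fraction` | `NULL` | held-out fraction of coded items for evaluation on real corpora |

## Evaluation battery

Two protocols are implemented and deliberately kept apart:

* **Masked-code recovery** (`evaluate_postcoding()`): hide a fraction of
  codes, post-assign, score per item — assigned-and-correct is TP,
  assigned-and-wrong FP, unassigned-with-truth FN, unassigned-without-truth
  TN. This is the synthetic stand-in for a human judgment of post-coding
  correctness, which no automatic protocol can reproduce.
* **Pairwise cluster quality** (`evaluate_pairwise_clustering()`): pair
  counting over labeled items, used both for cut-off inference and for
  scoring the residual (never-coded) clusters.

`summary()` on a fit reports both, plus a coded-fraction-weighted
combination clearly labeled as such — how the two subset F values of the
bundled reference summaries were combined into a single overall F is not
stated with them, so the package prints the ingredients and its own stated
combination rather than claiming comparability. Compression is
\(1 - n_{\mathrm{topics}} / n_{\mathrm{items}}\), and aggregate means over
patients are taken over two-decimal-rounded per-patient values, mirroring
how such tables are conventionally presented (configurable in
`summarize_patients()`). TN counts enter no score but are kept for
completeness. `estimate_sample_size()` implements the Chernoff-bound
sample-size rule \(n \ge \frac{3}{\varepsilon^2}\ln\frac{2}{\delta}\)
(natural logarithm, integer ceiling) used to size a representative
inter-patient corpus sample.

The package also ships, under `inst/extdata/`, plain-text per-patient
reference summaries of a five-patient nephrology evaluation of this
methodology (counts, precision/recall/F columns). They are inputs for
worked examples and regression tests of the scoring arithmetic; the
package never stores a derived aggregate — means, F-measures and
compression rates are recomputed at run time.

## The synthetic generator

Real problem lists are protected health information, so every end-to-end
test runs on `generate_corpus()`. It emulates the structural features the
method depends on: short German-like diagnosis phrases drawn from hidden
3-digit ICD-10 topics; surface variants (word order, stage suffixes,
abbreviations) within a topic; per-character typos; appended context
(date-like tokens, drug names, "Z.n.", "beidseits"); truncation to 50
characters; and a configurable fraction of masked codes. Defaults are five
patients with 250–861 items each, 16 topics, 60% visible codes, typo rate
0.02, abbreviation probability 0.10, context probability 0.20 — chosen once
as a plausible rendering of routine documentation noise. A single seed
drives everything; per-patient substreams are derived from it so that
adding patients never perturbs earlier ones, and an optional
`wrong_code_rate` can inject deliberately wrong visible codes (default 0).

What the generator does **not** emulate: real German clinical morphology
beyond the noise operators, genuine ICD coding ambiguity (every synthetic
item has exactly one true topic), semantically overlapping topics written
with disjoint vocabulary, or the human judgment behind a real coding audit.
Passing the synthetic battery therefore shows that the machinery is
implemented correctly and recovers structure that is present; it does not
certify the F-measures one would obtain on hospital data, and the package
makes no such claim.

## Numerical and degenerate-input choices

* Distances are clipped to \([0,1]\) and symmetrized before clustering;
  the diagonal is exactly zero.
* `cutree`'s closed-boundary cut semantics are part of the contract and
  tested.
* Ties: equal-F heights resolve to the smallest height (favouring more,
  purer clusters); equal-similarity donors resolve to the smallest item id.
* Rows with an empty description are rejected at load — they cannot be
  vectorized. Over-long descriptions are an error unless `permissive`
  truncation is requested.
* Corpora where no two coded items share a code make recall undefined;
  `infer_cutoff()` refuses them rather than guessing.
* All-zero documents cluster at distance 1 from everything and can only be
  post-coded if chained into a cluster with coded members.

## Problem sizes

The test suite and the acceptance script run the full pipeline on corpora
of 5 patients × 200 items (12 topics, ~36 unique strings after
deduplication, 50% masked), and the oracle comparisons use 200 random
distance matrices up to n = 12 and 200 random labeled partitions up to
n = 30 — sizes chosen so the brute-force oracles stay exact and the whole
battery completes in well under a minute on one core. The dense SVD path is
comfortable up to a few thousand unique strings; beyond that a truncated
sparse SVD would be the natural extension.

## Known limitations

* One code per entry; multi-code expressions are split incorrectly by
  construction.
* Donors are sought only within the cluster; a nearer coded neighbour in
  another cluster is ignored by design.
* Plainly wrong routine codes are inherited as-is; the package does not
  audit its inputs.
* Purely unsupervised cut selection (Elbow, Silhouette and variance-based
  criteria) is out of scope — the cut-off here is always inferred against
  partial labels.
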