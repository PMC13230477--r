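---
title: "Volumetric CBIR with late-interaction re-ranking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric CBIR with late-interaction re-ranking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volcbir)
```

## The retrieval problem

A 3D medical scan (a CT volume) is represented as a stack of 2D slices, and
each slice as a fixed-length embedding vector produced by some pretrained
vision model.  Content-based image retrieval (CBIR) for such data asks: given
a query volume, which volumes in a large archive are most similar — and in a
tumor-retrieval setting, do the retrieved volumes match the query's tumor
status (*flagging*) and, when positive, its stage (*staging*)?

`volcbir` implements the full retrieval stack on top of per-slice embedding
matrices, without touching image pixels:

1. **Slice search.**  Every database slice embedding is L2-normalized, so the
   inner product equals cosine similarity.  A query slice retrieves its
   `n_neighbors = 20` most similar database slices, either exactly (full
   scan) or through a hierarchical navigable small world (HNSW) graph index.
2. **Hit-table aggregation.**  The per-slice hits of a query volume form a
   hit table; database volumes are ranked by total hit count (*Count-base*),
   maximum hit similarity (*Max-Score*), or summed hit similarity
   (*Sum-Sim*).
3. **Re-ranking.**  Either reciprocal rank fusion (RRF) of the three
   first-stage lists, or the late-interaction re-ranker: for the query
   matrix $M_Q \in \mathbb{R}^{n \times L}$ and a candidate matrix
   $M_C \in \mathbb{R}^{m \times L}$ the rank score is
   $$\mathrm{RS}(C) \;=\; \sum_{i=1}^{n} \max_{j=1,\dots,m}
     \left( M_Q M_C^{\top} \right)_{ij},$$
   the slice-level analogue of ColBERT's MaxSim-and-sum over token
   embeddings (slices play the role of words, volumes of passages).  The
   top `m_top = 20` first-stage candidates are reordered by descending
   rank score.
4. **Evaluation.**  Precision at k (k = 3, 5, 10) and a top-10 average
   precision, repeated over seeded query/database redraws, with two-sided
   Wilcoxon signed-rank tests pairing per-seed mean AP between methods.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_neighbors` | 20 | slice hits kept per query slice |
| `k_top`, `m_top` | 20 | first-stage list length; candidates re-ranked |
| `k_smooth` | 60 | RRF smoothing constant (the standard choice) |
| `p_query` | 0.25 | fraction of positives drawn per stage into the query set |
| seeds | 10 | repetitions of the whole split/index/evaluate cycle |
| HNSW `m`, `ef_construction`, `ef_search` | 32 / 200 / 128 | graph degree and construction/search breadth |

All are overridable through `run_experiment()` / `run_full_experiment()`.
Slice indices are 1-based throughout, as is idiomatic in R.

## Relevance and metrics

Flagging counts a retrieved volume as relevant when its tumor flag matches
the query's; staging additionally requires the same stage (S1–S4), with
tumor-free volumes matching only tumor-free queries.  The negative class is
modelled as its own stage level (`"NONE"`), so both tasks are defined
uniformly for negative queries.  Adjacent stages are not partially
relevant.

P@k divides by k even when fewer than k volumes were retrieved — missing
slots count as misses, which is conservative and keeps the metric
deterministic.  The average precision over the top-10 list,
$AP = \sum_{n=1}^{10}(R_n - R_{n-1})P_n$, needs a recall denominator; we
normalize by the number of relevant items **within the top-10 list** (zero
relevant gives AP 0).  Normalizing instead by all relevant volumes in the
database would pin AP near zero whenever hundreds of database volumes are
relevant, which is incompatible with AP being a useful per-query ranking
summary here; the top-10-local choice also makes AP equal the mean of the
precisions at relevant ranks, an identity the test suite checks by
simulation.

The Wilcoxon signed-rank test drops zero differences, uses the exact null
distribution of the signed-rank statistic for up to 25 informative pairs
(computed by convolution over the midranks, so ties are handled exactly),
and a tie-corrected normal approximation beyond.  The two-sided p-value is
`min(1, 2 * min(P(V <= v), P(V >= v)))`.

## Cohort construction

Splits are drawn at the volume level: a volume contributes slices to the
query side or the database side, never both, because adjacent slices of one
volume are strongly correlated.  Per organ and stage, 25% of the positive
volumes (round half up, at least one from a non-empty stratum) become
queries, matched 1:1 by tumor-free volumes that contain the same organ;
everything else is the database.  Draws are independent across seeds — two
repetitions may share query volumes — but without replacement within a
seed, since a query set listing the same volume twice is meaningless.

Three database configurations mirror the evaluation settings: organ-specific
with segmentation (the search space is restricted to the slices on which
the target organ appears, via per-volume `organ_presence` masks),
organ-specific without segmentation (same volumes, all slices searchable),
and organ-agnostic (one pooled database over all organs).  The query set is
identical across the two organ-specific configurations for a given seed.

## The synthetic cohort generator

Real embedding cohorts require image data and pretrained extractors, so the
package ships a generator that emulates the *statistical* structure such
cohorts exhibit: several organs; per-organ stage classes plus a tumor-free
class; variable slice counts (20–60 by default); within-volume
slice-to-slice correlation (an AR(1) deviation process with coefficient
`within_volume_drift`); and a tunable class separation.  Prototypes are
nested — `normalize(u0 + delta * (organ_axis + nesting * class_dir))` — so
stages of one organ are mutually closer than different organs, matching the
observation that staging is harder than flagging.  At `separation = 0` all
prototypes collapse onto the shared direction `u0` and every class is
indistinguishable in expectation, which is the chance-level baseline the
tests exploit.

The defaults (`separation = 2`, `stage_nesting = 0.35`, `noise = 1`,
`L = 64`, 4 organs × (4 stages × 6 + 12 negative volumes)) were chosen so
that retrieval at the defaults is good but visibly imperfect (mean AP
roughly 0.6–0.95 with Max-Score clearly weakest), because a saturated
generator — every method at AP 1.0 — would make method comparisons and the
seeded Wilcoxon protocol vacuous.  The negative class is twice the size of
a stage class: the 25% per-stage draw takes 2 of 6 volumes from each of
four strata, and the 8 matched negatives must exist; this mirrors the real
setting where an organ's negatives come from the other tasks' scans and
outnumber any single stage.

By default every slice of a volume carries the class prototype and
`organ_presence` is a pure annotation (a contiguous span covering 60% of
the slices).  With `background_outside_span = TRUE` the off-span slices are
drawn around a volume-specific background direction instead, so only the
organ span carries class signal — the construction used to demonstrate
that the late-interaction re-ranker's output is identical across the
with/without-segmentation database configurations whenever the first-stage
candidate sets coincide: the re-ranker always scores full volume matrices
from the cohort, so the database slice masks can only influence it through
candidate membership.

What passing tests on this generator do **not** show: real embedding
geometry is anisotropic and model-dependent, class boundaries are not
spherical caps, slice counts and organ spans correlate with anatomy, and
real negatives differ from positives in more than one planted direction.
Results on synthetic cohorts validate the machinery and its invariants,
not clinical performance.

## Numerical choices and degenerate inputs

* Zero or non-finite embeddings are rejected at ingest (normalization
  divides by the norm); normalization is idempotent to 1e-12.
* Score ties in slice search break by ascending (volume id, slice index);
  ties in aggregation scores break by higher summed similarity, then
  ascending volume id; rank-score ties in re-ranking preserve the incoming
  first-stage order (stable sort).  All orderings are deterministic.
* The HNSW index uses a seeded generator for level assignment, so a rebuild
  from the same inputs is bit-identical.  Neighbour selection uses the
  diversity heuristic with pruned-connection backfill; plain top-M selection
  measurably loses long-range links on clustered embedding data.  Recall is
  asserted against the exact backend on in-distribution queries (slices of
  held-out query volumes); adversarial queries far from every cluster can
  recall worse, as is inherent to graph ANN indexes.
* The exact backend is the reference implementation used everywhere the
  protocol demands determinism; the graph index exists for scale.
* An empty candidate list re-ranks to an empty list; `k = 0` retrieval
  warns and returns an empty list; a query whose volume is present in the
  index (a planted duplicate) never reports its own slices as hits.
* The cohort store writes embedding values as 17-significant-digit decimal
  strings inside JSON, which round-trips IEEE doubles bit-exactly without
  binary formats.

## Problem sizes

The test suite and the acceptance script run the full protocol on the
desk-scale preset: 144 volumes (~5,600 slices, L = 64), 64 queries per
seed against an 80-volume organ-agnostic database, 10 seeds, five methods,
both tasks; the index-scale checks use a ~7,000-slice database side.  These
sizes exercise every code path in minutes on one CPU while keeping the
per-class counts large enough for the stage-stratified sampling rules to be
non-trivial.  Larger cohorts are a matter of configuration, not code.

## Known limitations

* Which first-stage list the late-interaction re-ranker consumes is
  configurable (`cmir_base`, default Count-base); fusing or re-ranking all
  three lists jointly is not implemented.
* The re-ranker is not offered as a primary retrieval method over the whole
  database — its memory cost grows with database size; as a re-ranker the
  working set is one query matrix plus one candidate matrix at a time.
* No multiple-testing correction across organs or models is applied to the
  Wilcoxon p-values (raw p-values are reported), and no confidence
  intervals are computed.
* The adapter from images to embeddings is out of scope by design: any
  callable that maps a slice to a length-L vector can populate a cohort
  (see `README.md` for the contract); the package never reads pixel data.

## A minimal session

```{r example, eval = FALSE}
co <- generate_cohort(generator_config(seed = 7))
res <- run_experiment(co, split_spec("organ_agnostic", seed = 1),
                      seeds = 1:10)
subset(res$seed_means, task == "flagging" & seed == 1)
compare_methods(res$seed_means, baseline = "cmir")
```
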