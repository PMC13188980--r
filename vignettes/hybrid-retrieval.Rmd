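---
title: "Hybrid lexical-semantic retrieval: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid lexical-semantic retrieval: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litfuse)
```

## The retrieval model

`litfuse` ranks bibliographic records against a free-text query with a
single bounded score that fuses two complementary relevance signals.

**Lexical side.** Each record's title and abstract are concatenated,
tokenized (lowercase, split on non-alphanumeric runs, no stemming), and
indexed into one Okapi BM25 inverted index per publication year. Sharding
by year keeps per-shard vocabularies small, lets shards be searched
independently, and makes incremental updates a per-year affair; because
BM25 statistics (`N`, `n(q)`, `avgdl`) are shard-local, a document's raw
score is computed against its own year's statistics and raw scores are
pooled across shards afterwards. Raw BM25 is unbounded and its scale varies
with query length and term rarity, so pooled candidate scores are min–max
normalized per query,

$$L(d) = \frac{s(d) - \min_{d'} s(d')}{\max_{d'} s(d') - \min_{d'} s(d') + \varepsilon},$$

which maps the candidate pool to $[0, 1)$ monotonically. The
$\varepsilon = 10^{-9}$ in the denominator makes the all-equal-scores case
well-defined (all zeros rather than NaN) at the cost of the top score being
$\approx 1$ rather than exactly 1.

**Semantic side.** The same title+abstract string is embedded by a
pluggable encoder (`text_encoder()`); candidates are ranked by cosine
similarity to the query embedding, and similarities below a cutoff $t$
(default 0) are discarded, so the retained semantic score lies in
$[t, 1] \subseteq [0, 1]$ and is directly comparable to $L$.

**Fusion.** Each candidate receives exactly one final score

$$FS = \alpha L + (1 - \alpha) S, \qquad
\alpha = \frac{1}{1 + e^{-a (L - b)}},$$

a convex combination whose weight is itself a function of the lexical
evidence. With the defaults $a = 10$, $b = 0.5$, the weight moves from
$\alpha(0) \approx 0.0067$ (semantic-dominated) to $\alpha(1) \approx
0.9933$ (lexical-dominated), crossing $1/2$ exactly at $L = 0.5$. The
retrieved set is $R_\tau = \{d : FS > \tau\}$ with a strict inequality;
ties on $FS$ prefer the higher normalized lexical score (precision for
exact matches), then the lexicographically smaller document id so rankings
are total and reproducible.

The important consequence of adaptive weighting, and the property the test
suite pins down, is *rescue*: a document sharing no token with the query
has $L = 0$, hence $FS \approx 0.993\,S$, and a high-cosine document is
retrieved at essentially full strength where a keyword engine returns
nothing.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k1` | 1.5 | BM25 term-frequency saturation (unitless) |
| `b` (lexical) | 0.75 | BM25 length normalization in $[0,1]$ |
| `a` | 10 | sigmoid sharpness of the fusion weight |
| `b` (fusion) | 0.5 | sigmoid midpoint on the $L$ axis |
| `tau` | 0.35 | retrieval threshold on $FS$, strict |
| `epsilon` | 1e-9 | min–max denominator guard |
| `t_cutoff` | 0 | semantic retention threshold (cosine) |
| `top_m` | 1000 | per-modality candidate pool size before fusion |

`k1`/`b` are the standard Okapi defaults; nothing in the fusion depends on
their exact values, and they are exposed on `lexical_params()`. The fusion
constants `a = 10`, `b = 0.5` are fixed, analytically chosen values rather
than dataset-tuned quantities — they give a balanced hand-off and are kept
as the package defaults. `tau = 0.35` is a configurable operating point (a
production threshold is deployment-specific); the threshold-nesting
property $R_{\tau_2} \subseteq R_{\tau_1}$ for $\tau_1 \le \tau_2$ holds
whatever its value. `top_m` bounds the candidate pool: min–max
normalization needs a finite pool, and the package normalizes over the
pooled candidates of both modalities so that the best lexical hit of the
query normalizes to $\approx 1$ regardless of which year shard it came
from. Per-shard or corpus-global normalization scopes would be defensible
alternatives; the pooled scope was chosen because it makes $L$ a per-query
quantity with a fixed meaning ("best candidate ≈ 1") independent of corpus
growth.

`alpha_fixed` on `fusion_params()` degenerates the ranker on purpose:
`alpha_fixed = 1` is the lexical-only ablation, `alpha_fixed = 0` the
semantic-only one. These are the baselines the evaluation harness compares
against.

## Encoders

The semantic index is defined against an encoder *contract* — a
deterministic function text → fixed-dimension vector — not a specific
model. Production deployments would wrap a sentence-transformer here
(including any prompt formatting, inside the contract); the package ships
two deterministic test encoders:

- `hash_encoder()`: token-hashing bag-of-words, L2-normalized. Cosine
  grows with token overlap. It emulates the *geometry* of an embedding
  space, not semantics: two paraphrases with disjoint vocabulary are
  orthogonal under it.
- `topic_encoder()`: built over explicit `make_topics()` specifications
  with mutually orthogonal base directions. Texts are mapped near their
  topic's direction (recognizing both the surface and the paraphrase
  vocabulary) plus a small deterministic perturbation (weight 0.3), so
  same-topic texts have cosine $\approx \sqrt{1-0.3^2}^2 \approx 0.91$
  even with zero lexical overlap. This emulates the one capability of a
  trained encoder the hybrid method depends on: recognizing conceptual
  relatedness across terminology gaps.

Vectors can be stored at half precision (`precision = "half"`): values are
rounded to the nearest IEEE 754 binary16-representable number (10
significand bits), and similarity math always runs in double precision on
the dequantized values. For unit-scale coordinates the per-coordinate
error is below $5 \times 10^{-4}$ and pairwise cosines shift by less than
$2 \times 10^{-3}$, which the property tests check empirically.

## The synthetic study and what it shows

The generator (`generate_corpus()`, `generate_eval_set()`) emulates the
retrieval conditions the method targets, not real PubMed text. Documents
draw 50–200 tokens from a per-topic vocabulary with Zipf-like (1/rank)
frequencies — exercising term-frequency saturation and length
normalization — and each topic has a disjoint paraphrase vocabulary used
only by queries, giving two controlled query classes: *exact* queries that
share at least one token with every relevant document (each document's
title opens with its topic's anchor token, and exact queries always include
it), and *paraphrase* queries with provably zero lexical overlap. Years are
uniform over 2019–2021 so multiple shards are populated; journals, authors,
and MeSH terms come from small per-topic pools so filters and facets have
realistic cardinalities. A single integer seed drives all sampling.

The bundled study (2 topics × 200 documents, 40 queries, half paraphrase —
sizes chosen so the whole suite runs in seconds while every code path is
exercised) is evaluated in `scripts/acceptance.R` and the acceptance tests:
hybrid NDCG@10 must be at least the lexical-only ablation's on paraphrase
queries and at least the semantic-only ablation's on exact queries. On this
fixture the hybrid system attains NDCG@10 = 1 on both query classes while
lexical-only collapses to 0 on paraphrase queries — the directional
ablation result, reproduced at desk scale. What this does **not** show:
real abstracts are not topic-pure token bags, real encoders have graded and
noisy similarity structure, and real relevance is not topic membership.
The synthetic result validates the *mechanics* (normalization, fusion,
thresholding, tie-breaking, evaluation) and the *direction* of the hybrid
advantage, not absolute metric values on any benchmark.

## Numerical and degenerate-input choices

- IDF uses the natural logarithm (the conventional BM25 form) and the
  `+1`-inside-the-log variant, so weights stay non-negative even for terms
  in more than half a shard; absent terms use $n = 0$.
- All-equal raw scores normalize to all zeros (the $\varepsilon$ clause);
  a singleton pool normalizes to 0, not 1 — the single candidate's rank is
  unaffected.
- `retrieve()` errors on queries that are empty after tokenization *and*
  embed to the zero vector; either signal alone still retrieves.
- Cosine similarity is undefined for zero vectors and raises an error
  rather than returning 0; encoders must produce non-zero vectors for
  indexed text.
- Records without a resolvable publication year go to a sentinel
  `"unknown"` shard rather than being dropped; records with an empty
  abstract are indexed on their title alone.
- Duplicate PMIDs in an XML stream keep the later record (warning),
  matching update-file semantics where later citations supersede earlier
  ones.
- Ranked-metric conventions: binary gains with $\log_2(i+1)$ discount for
  NDCG, AP@k divided by $\min(|R|, k)$, queries missing from a run score 0,
  while the judgment-free mean-cosine protocol reports *no results* as
  missing (`NA`) — a distinct outcome from cosine 0.
- The relevance line for bucketing is 0.5; the lower Partially/Irrelevant
  boundary (0.3) is a package default with no external anchor, exposed as
  an argument.

## Known limitations

Embedding-based scoring inherits the usual blind spots around explicit
negation and Boolean composition; nothing in the fusion recovers exclusion
constraints. The tokenizer is deliberately language-agnostic (no stemming,
no stopwords by default; both are configurable), so morphological variants
only meet through the semantic side. The exact-search backend is brute
force — appropriate for the tested scales ($\le 10^4$ vectors) and as the
oracle any approximate backend must match, but not a large-scale serving
index. Filters post-filter the current result set rather than re-running
retrieval, so facet counts describe the retrieved page, not the corpus.
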