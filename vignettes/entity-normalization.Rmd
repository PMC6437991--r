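---
title: "Unsupervised entity normalization with embeddings and syntactic re-ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised entity normalization with embeddings and syntactic re-ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontolink)
```

## The problem

Biomedical text names the same entity in many surface forms: a bacteria
habitat mention like *children less than 2 years of age* must be linked to
an ontology concept such as *pediatric patient*, and an adverse drug
reaction mention like *neuropathy* to a dictionary term like *peripheral
neuropathy*. Supervised normalizers struggle here because terminologies
are large (thousands of concepts) while annotated corpora are tiny.
`ontolink` implements an unsupervised linker: no labeled mention/concept
pairs are used at any point. The only learned resource it consumes is a
pre-trained word-embedding model, supplied as an ordinary word2vec file.

## The method

**Phrase vectors.** Mentions and every ontology surface (concept name or
synonym) go through the same preprocessing: lowercase, strip non-ASCII
characters, split on non-alphanumerics, drop empty tokens, then drop stop
words. The phrase vector is the mean of the remaining tokens' word
vectors; out-of-vocabulary tokens are simply skipped. For *a day-care
center*, the tokens `day`, `care`, `center` are averaged.

**Candidate generation.** Every term entry of the ontology is scored
against the mention by cosine similarity of the phrase vectors (word
mover's distance is available as an alternative metric; it is solved as an
exact transportation linear program, which is cheap because phrases are a
handful of tokens). A concept's score is the maximum over its surfaces,
and the top `k` distinct concepts become candidates.

**Syntactic re-ranking.** Averaging dilutes the informative word:
*children attending a day-care center* averages into the neighborhood of
*medical center*. The most informative word of a noun phrase is its head,
which we extract from a constituency parse as the top-level rightmost noun
(scanning the outermost NP's children right to left for an NN/NNS/NNP/NNPS
leaf, recursing into the rightmost NP child when there is none, and
falling back to the last token otherwise). Each candidate `c` of mention
`m` is then rescored as

$$S_{RR}(m, c) = w \cdot S(m_{head}, c_{head}) + (1 - w) \cdot S(m, c)$$

a convex combination of head-word cosine and phrase cosine. When either
head is out of vocabulary the candidate keeps its phrase score. With the
defaults `k = 5` and `w = 0.25`, the head contributes a quarter of the
final score — enough to promote *child* over *medical center* for the
example above without letting a noisy head overturn a clear phrase match.

**Possessive-PP stripping.** Mentions of the shape *NP of NP* (e.g.
*throats of two healthy children*) carry their information in the left NP
only. When the mention's parse decomposes as `NP [NP, PP(IN "of", NP)]`,
the tokens after *of* are discarded before the phrase vector is composed.
The rule applies only at the outermost NP, so *children less than 2 years
of age*, whose *of* sits deeper in the tree, is left untouched.

**Fallbacks.** A mention whose tokens are all out of vocabulary cannot be
embedded. The default policy first tries a case-insensitive exact match of
the raw mention against all ontology surfaces — including surfaces that
are themselves out of vocabulary and therefore absent from the vector
index — and otherwise assigns the ontology root; `root` and `abstain`
policies are also available.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 5 | candidates kept for re-ranking; rank-`k` recall rises with `k`, but a large pool lets weakly related heads interfere |
| `w` | 0.25 | head weight in the convex combination; `w = 0` disables syntax, `w = 1` ranks by heads alone |
| `metric` | cosine | `wmd` ranks by ascending transport cost instead |
| `s` | 0.65 | per-edge decay of the Wang-similarity evaluation (an evaluation setting, not a linker parameter) |
| stop words | 127-word English list | packaged in `inst/extdata`, replaceable per call |

## Evaluation measures

Habitat-style tasks are scored with an ontology-aware precision: each
prediction earns the Wang similarity between predicted and gold concept,
and the score is the mean over predictions. Wang similarity compares
decay-weighted ancestor sets: every ancestor `a` of a concept at is_a
distance `d` receives an S-value $s^d$ (best path over multiple routes,
self-weight 1), and

$$W(c_1, c_2) = \frac{\sum_{a \in T_1 \cap T_2} (S_1(a) + S_2(a))}{\sum_{a \in T_1} S_1(a) + \sum_{a \in T_2} S_2(a)}.$$

This is symmetric, equals 1 exactly at identity, and rewards predictions
in the right region of the hierarchy. A prediction of a concept's direct
parent, for instance, scores $1.65 / 2.65 \approx 0.62$ at `s = 0.65`.
Dictionary-style tasks are scored by exact matching with micro-averaged
(counts pooled over documents) and macro-averaged (per-document ratios
averaged) precision and recall; both F-scores are the harmonic mean of
the corresponding precision and recall. Mentions with several gold
concepts score against their best referent (Wang) or by set membership
(exact); the evaluation data this package targets does not specify a
stricter rule. Two baselines calibrate results: exact-match-or-root and
all-to-root.

## The synthetic fixture

Real corpora and the multi-gigabyte embedding model cannot be shipped, so
the package generates its own study conditions deterministically from one
seed, at the scale used throughout the tests and the acceptance script:
a complete is_a tree of depth 2 and branching 3 (13 concepts), embedding
dimension 20, 200 mentions over 5 documents, paraphrase rate 0.5, PPP-wrap
rate 0.2 — small enough that the whole pipeline runs in seconds, large
enough that rank statistics are stable.

Each concept owns a distinctive token appearing in its name and synonyms;
token vectors are the mean of the base vectors of the concepts they occur
in, plus Gaussian noise of standard deviation `noise_sd`. Mentions are
exact names/synonyms, or — with probability `paraphrase_rate` — an *unseen
alias surface*: an alias token drawn from the same concept base that
occurs in no ontology surface. The alias construction is what makes the
noise dial meaningful: exact-surface mentions compose to exactly their
index vector and are immune to token noise, so a corpus of exact surfaces
would score 1.0 at any noise level. Alias mentions emulate the real
phenomenon the linker exists for — surface forms that are semantically
but not lexically tied to the concept. At `noise_sd = 0` an alias equals
its concept base exactly and rank-1 accuracy is still 1.0; as noise grows,
accuracy falls monotonically (up to sampling slack), which the tests check
at three noise levels.

What the fixture does **not** emulate: natural-language word statistics,
polysemy and abbreviations (the known hard cases for this method),
realistic ontology depth, and multi-referent gold annotations. Passing the
synthetic recovery tests therefore demonstrates the pipeline's mechanics —
composition, ranking, re-ranking, IO, scoring — not corpus-level
performance on PubMed text.

## Numerical and design choices

- **Weight definition.** The ancestor weight is $s^d$ with $s \in (0, 1]$
  per is_a edge — a decay with self-weight 1 — and multiple paths keep the
  maximum. The combined score is the Wang (2007) ratio above.
- **Case.** Everything is lowercased before lookup; the packaged fixture
  vocabulary is lowercase-only so the policy is exercised by tests.
- **Tokenization.** Splitting on non-alphanumerics reproduces hyphen
  behavior (*day-care* → `day`, `care`) without a tokenizer dependency;
  stop words are removed after splitting, which is order-equivalent here
  because stop words are single tokens.
- **Aggregation over surfaces.** A concept is scored by its best surface
  (max), and that surface's head is used in re-ranking; ties between
  concepts break toward the smaller id so rankings are total and
  reproducible.
- **Distinct-concept candidates.** The top-`k` pool holds `k` distinct
  concepts rather than `k` term entries, so one many-synonym concept
  cannot crowd out alternatives.
- **WMD.** Used for the semantic stage only and converted to a ranking
  score as the negated distance; re-ranking on top of WMD reuses the
  cosine of head vectors. The transportation LP is solved exactly with the
  simplex method; one marginal constraint is redundant and dropped.
- **Degenerate parses.** When no parse is supplied, a flat NP with all
  tokens tagged NN is synthesized, so the head is the last token and the
  pipeline stays total; adjective-only mentions take the explicit
  last-token fallback.
- **PPP before ranking.** Stripping changes the mention's tokens, so it
  runs before vector composition; after stripping, the head is taken from
  the kept left-NP tokens.

## Known limitations

- Abbreviations and acronyms (*sjs*, *ten*) normalize poorly without
  sentence context; context-aware vectors are out of scope.
- Rare out-of-vocabulary words silently reduce a phrase to its remaining
  tokens, which can pull the ranking toward the generic neighbor of the
  surviving words.
- Head extraction inherits parser errors; only constituency parses are
  supported.
- The exact-match fallback is string-identical (after case folding) — no
  approximate string matching is attempted.
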