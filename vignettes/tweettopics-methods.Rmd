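---
title: "Methods: topic labeling, classification and sentiment aggregation in tweettopics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topic labeling, classification and sentiment aggregation in tweettopics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameters and
design choices. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The pipeline and its assumptions

`tweettopics` automates the annotation and analysis of short crisis-related
social-media posts. The chain is: corpus filtering, tokenization and
lemmatization, phrase detection, LDA topic discovery, coherence-based
topic-count selection, dominant-topic weak labeling, neural classification,
statistical comparison of classifiers, and population-normalized per-country
sentiment aggregation.

The central modeling assumptions are those of LDA: documents are
exchangeable bags of words, each document mixes `K` topics with proportions
`theta_d ~ Dirichlet(alpha)`, and each topic is a fixed word distribution
`phi_k ~ Dirichlet(beta)`. Tweets are short (tens of tokens), so individual
`theta_d` estimates are noisy; the pipeline leans on corpus-level structure
(topic-word distributions, label distributions) rather than per-document
posteriors wherever possible.

## 2. Inference: collapsed Gibbs sampling

`fit_lda()` integrates out `theta` and `phi` and resamples each token's
topic from

```
P(z_i = k | .) ~ (n_dk + alpha) * (n_kw + beta) / (n_k + V beta)
```

with the token's own assignment removed from all counts. Point estimates
are `phi_kw = (n_kw + beta)/(n_k + V beta)` and
`theta_dk = (n_dk + alpha)/(N_d + K alpha)`, taken either from the final
sweep (default) or from post-burn-in mean counts (`estimate = "mean"`).
Collapsed Gibbs was chosen over variational inference because its
conditionals are exact and easily verified: the test suite asserts count
conservation across sweeps, row-stochasticity of `phi` and `theta` to
1e-9, bitwise reproducibility under a fixed seed, and parameter recovery on
synthetic corpora.

**Restarts.** Gibbs chains on sharp synthetic corpora occasionally settle
in a local mode in which two generating topics merge into one fitted topic
while another splits. `fit_lda(restarts = n)` runs `n` independently
initialized chains (seeds derived deterministically from `seed`) and keeps
the one with the highest collapsed log joint probability `log P(w, z)`.
The end-to-end labeling pipeline uses `restarts = 3`; this is ordinary
practice for mode-seeking samplers and does not change any study
condition.

Defaults: `alpha = 1/K`, `beta = 0.01`, `sweeps = 500`, `burn_in = 100`.
These are the common settings for short-text LDA; the sparse `beta` matches
the sparse topic-word structure the generator emulates.

## 3. Coherence and topic-count selection

`coherence()` estimates word probabilities as boolean sliding-window
frequencies (window default 110 tokens; a document shorter than the window
is one window). Two measures are reported:

* `c_npmi`: the mean NPMI over the `choose(N, 2)` pairs of each topic's
  top-`N` words (default `N = 10`);
* `c_v` (default): one-set segmentation — each top word's NPMI context
  vector over the top-`N` set is compared by cosine with the set's sum
  vector, averaged over words, then topics.

Numerical choices: `eps = 1e-12` floors the joint probability inside both
logarithms. A pair that co-occurs in every window where either word appears
is the limit case `NPMI = +1` and is returned exactly rather than through
the eps-perturbed formula; a word absent from every window carries no
co-occurrence information and contributes 0. Both implementations are
checked against an independently coded brute-force enumeration in the test
suite (agreement to 1e-6 and usually exact).

`select_num_topics()` refits one model per candidate `(K, n-gram variant)`
with deterministic per-row seeds and reports a tidy sweep table; a failed
row is recorded as `NA` rather than aborting the sweep. On synthetic
corpora with a known `K_true = 5` and candidates `{2, 5, 10}`, the sweep's
arg-max lands on 5 in at least 80% of ten seeded replicates (asserted in
the tests at that scale, chosen to keep the suite fast).

## 4. Preprocessing rules

Declared, fixed rules rather than inferred ones: lowercasing; URL and
@-mention removal; `#` stripped but the tag word kept; tokens are maximal
runs of letters/digits/underscore/apostrophe, so hyphens split; a bundled
English stopword list (extensible) is removed last. Lemmatization is a
lookup table (bundled pandemic-domain CSV plus user-supplied tables) with
identity fallback and `pos = noun` for unknown tokens; the default
part-of-speech filter keeps nouns, adjectives and verbs, the content
classes most informative for topic modeling. A lookup lexicon was chosen
over a full tagger to keep the stage deterministic, offline and swappable.

Phrase detection scores adjacent pairs with
`(count(a,b) − min_count) · V / (count(a) · count(b))` (defaults
`min_count = 5`, `threshold = 10`, the canonical settings of this scoring
family); trigrams are a second pass over the bigram-transformed corpus.
Merging is greedy, left-to-right and non-overlapping. Note the threshold
scales with the vocabulary size `V`: tiny pseudo-word corpora need
proportionally smaller thresholds, which the tests set explicitly.

## 5. Dominant-topic labeling (the weak annotation rule)

The ranking rule scores a document's affinity for topic `k` as

```
score(d, k) = sum_w tf(w, d) * idf(w) * phi_kw
```

with `tf = count/N_d` and `idf = ln(M/df)` (no smoothing, so a term in
every document has idf exactly 0). The label is the arg-max, ties to the
smallest topic index. This is the simplest scoring consistent with ranking
topics per document by tf-idf-weighted topic-word affinity; it uses `phi`
only, not `theta`, and is isolated behind `dominant_topic()` so an
alternative (e.g. `theta`-weighted) rule can be swapped in. Documents with
no ranking signal (no in-vocabulary tokens, or all-zero tf-idf) are flagged
`unlabelable`, excluded from classifier training, and kept in aggregate
counts. Labels are invariant to rescaling all tf-idf weights by any
positive constant (tested), and agree with an independent exhaustive score
evaluation on random small instances (tested).

## 6. Neural classifiers

Three architectures share a frozen word-embedding layer and a `K`-unit
sigmoid head trained with summed per-class binary cross-entropy (the
multilabel-style head; predicted score vectors deliberately do not sum
to 1):

* **FFNN** — mask-aware mean pooling, dense ReLU stack (default
  `c(128, 64)`), dropout;
* **CNN** — 1-D convolution (default 128 filters, kernel 3), ReLU, global
  max pooling, dense + dropout block;
* **BiLSTM** — bidirectional LSTM (default 64 units per direction;
  forget-gate biases initialized to 1), final states concatenated, dense +
  dropout block.

Optimization is mini-batch Adam (`lr = 1e-3`, batch 64) with seeded
shuffling and dropout, so single-threaded training is bit-reproducible.
The forward/backward passes are written in package R code as plain matrix
algebra; every architecture's analytic gradient is verified against
central finite differences in the test suite (at jittered parameters,
away from the non-differentiable ReLU/max-pool kinks). The number of
output units defaults to `K` and is configurable.

**Embedding providers.** The default `hashed` provider derives each term's
vector from a keyed hash expanded to `dim` pseudo-random values,
L2-normalized — deterministic, vocabulary-independent and fully offline.
A `file` provider loads word2vec text-format vectors (e.g. pretrained
300-dimensional embeddings), with hashed fallback for missing terms.
Embeddings are frozen during training in all architectures. For the
pseudo-word corpora used in tests and the acceptance script, `dim = 64`
hashed vectors are used: pseudo-words carry no transferable semantics, so
larger pretrained-scale dimensions would only add computation.

## 7. Evaluation surface

`confusion_matrix()` uses rows = true class, columns = predicted;
`eval_metrics()` derives per-class one-vs-rest precision, recall, F1,
accuracy, FPR and specificity, plus macro (unweighted mean) and micro
(pooled counts) aggregates. Divisions by zero yield 0 and are flagged.
Both FPR and specificity are reported explicitly since printed summaries
elsewhere sometimes label one as the other. For single-label data the
pooled micro counts satisfy FP = FN, so micro precision = recall =
F1 = accuracy; the implementation short-circuits the harmonic mean so the
identity holds exactly in floating point.

`roc_pr_curves()` sweeps thresholds over each class's unique scores
(`score >= threshold` is positive), with trapezoidal AUC, pooled micro
curves, and macro AUC excluding classes absent from the truth (flagged).
Binary ROC AUC is checked against the all-pairs Mann-Whitney statistic to
1e-9, and AUC invariance under strictly monotone score transforms is
asserted.

`cv_paired_ttest()` implements the repeated two-role paired comparison:
each of 5 repetitions makes one random split, evaluates both classifiers
with roles swapped (`p_i1`, `p_i2`),
`s_i^2 = (p_i1 − p̄_i)^2 + (p_i2 − p̄_i)^2`, and
`t = p_11 / sqrt(mean s_i^2)` with `df = 5`; the two-sided critical value
at α = 0.05 is 2.571. Five repetitions is the only repetition count
consistent with that critical value, so it is the default; the count is
configurable. Both builders receive the same derived seed per repetition,
so an algorithm compared against an exact copy of itself trains
identically and yields `t = 0` (the degenerate all-zero-variance case is
flagged and defined as `t = 0`). No multiple-testing correction is
applied.

## 8. Sentiment and country aggregation

How sentiment polarity was assigned is the one stage the upstream problem
statement leaves entirely open; the package's default is the most
transparent choice, a lexicon scorer: raw score = mean polarity (+1/−1) of
matched tokens, classified by sign with a configurable neutral band
(0 matches is always neutral). A neural 3-class head can be trained with
the classifiers module instead when externally labeled sentiment data is
available. "Normalization by population" is likewise reported in two
explicit forms: the per-capita tweet rate `total/population` and the
count-free net score `(n_pos − n_neg)/total` in `[−1, 1]`. Tweets with no
country pool under `"??"`; zero cells are absent rather than zero rows;
counts are conserved (all tested).

## 9. The synthetic-data generator

`sample_corpus()` draws from the exact LDA generative process over a
pseudo-word vocabulary (`w0001` …), then decorates documents into tweet
records: ISO-coded countries drawn from a configurable table with rough
2021 populations, 0–2 hashtags from the crisis keyword list, Poisson
document lengths truncated to `[3, 50]` (mean 20 — tweet-scale), injected
sentiment words (two lexicon terms per non-neutral document), and
compliant metadata (`lang = "en"`, no retweet/reply/quote flags). Defaults
`K_true = 10`, `V = 500`, `D = 2000`, `alpha = 0.1`, `beta = 0.01` mirror
the ten-class, sparse-topic, short-document setting the pipeline targets.
Ground truth (topic-word matrix, per-document proportions, dominant
topics, sentiment, countries) is returned alongside, and the whole bundle
regenerates bit-identically from `(config, seed)`.

Two deliberate simplifications: the topic-weight tilt parameterizes the
Dirichlet concentration as `alpha * K * weights`, so uniform weights
recover the conventional symmetric `Dirichlet(alpha)` and weights only
shift expected shares; and `disjoint_topics = TRUE` places each topic on
its own vocabulary block, producing the well-separated corpora used for
classifier sanity checks.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: natural-language morphology and polysemy (the
lemmatizer and phrase stages are exercised on small hand-written English
fixtures instead), bursty temporal dynamics, bot traffic, code-switching,
geotag noise, and the heavy-tailed user activity of real streams. Results
on synthetic corpora certify the correctness of the algorithms, not the
real-world quality of the labels.

## 10. Problem sizes and numerical choices in the tests

The test suite and acceptance script use these study conditions: LDA
parameter recovery on `K = 5, V = 300, D = 1500, alpha = 0.1, beta = 0.01`,
mean length 20, 500 sweeps; end-to-end labeling on a sharp
(`alpha = 0.01`) `D = 1200` corpus with 300 sweeps and 3 restarts;
classifier sanity on a disjoint-vocabulary 5-class `D = 2000` corpus with
a 70/30 split, 10 epochs, and the median over 3 seeds; t-test power with
20 replicates of a strong-vs-chance comparison on `D = 240`. Oracle
comparisons run 1000 random metric instances and 50 scored-AUC instances.
These sizes were chosen once as the smallest scales at which the
stochastic properties are stable.

Other numerical conventions, collected: term ids, topic ids and class
labels are 1-based; vocabulary ids are assigned in C-locale lexicographic
order; arg-max ties always break to the smallest index; empty documents
yield uniform `theta` (flagged); `idf` of an unobserved term is defined
as 0; the degenerate all-equal-scores threshold sweep treats
`score >= threshold` as positive.

## 11. Known limitations

* The dominant-topic rule is a weak-labeling heuristic; its "accuracy" is
  measured against synthetic ground truth, and on real data the labels
  inherit LDA's failure modes (topic merging, stopword-like topics).
* The lexicon sentiment scorer ignores negation, sarcasm and context.
* The BiLSTM processes full padded sequences; for corpora much longer than
  tweets the R implementation will be slow compared to compiled deep
  learning frameworks.
* Per-capita rates depend on the population table's coverage; countries
  missing from it are flagged rather than silently dropped.
* Coherence window counting enumerates windows directly; for very long
  documents with small windows this is quadratic-ish and intended for
  reference-scale corpora, not web-scale streams.
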