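# tweettopics

Automatic topic labeling, neural classification and country-level sentiment
mapping for short crisis-related social-media posts.

## The problem

Public-health teams mining Twitter-scale streams during a crisis (here: the
COVID-19 vaccination period) face millions of short, noisy, unlabeled posts.
Manual annotation does not scale, so this package automates the whole
chain:

1. **Discover topics** with latent Dirichlet allocation (LDA). Each document
   `d` mixes `K` topics through proportions `θ_d ~ Dirichlet(α)`; each topic
   `k` is a word distribution `φ_k ~ Dirichlet(β)`; every token draws a
   topic `z` then a word `w ~ Multinomial(φ_z)`. Inference is collapsed
   Gibbs sampling with the full conditional
   `P(z_i = k | ·) ∝ (n_dk + α)(n_kw + β)/(n_k + Vβ)`.
2. **Choose the number of topics** by sliding-window topic coherence (C_V
   and NPMI): `NPMI(w_i, w_j) = ln((P(w_i,w_j)+ε)/(P(w_i)P(w_j))) /
   −ln(P(w_i,w_j)+ε)` over boolean windows, with one-set-segmented cosine
   similarity of NPMI context vectors for C_V.
3. **Label every post** with its dominant topic via a tf-idf-weighted topic
   affinity: `score(d, k) = Σ_w tf(w,d)·idf(w)·φ_kw`, label = argmax. These
   weak labels replace manual annotation.
4. **Train classifiers** — a feed-forward network over mean-pooled
   embeddings, a 1-D CNN with global max pooling, and a bidirectional LSTM —
   all ending in `K` sigmoid units trained with binary cross-entropy.
5. **Evaluate** with confusion matrices, per-class and micro/macro
   precision/recall/F1/accuracy/FPR, ROC/PR curves with AUC, and compare
   classifiers with the repeated paired cross-validation t-test
   (`df = 5`, two-sided critical value 2.571 at α = 0.05).
6. **Aggregate sentiment** (lexicon-scored positive/negative/neutral) per
   country and topic, reporting the per-capita tweet rate and the net score
   `(n_pos − n_neg)/total` for choropleth-ready CSV output.

A seeded Dirichlet-multinomial corpus generator with full ground truth
(topic-word distributions, per-document topics, injected sentiment,
countries) makes every stage testable offline.

## Worked example

```r
library(tweettopics)

cfg    <- generator_config(K_true = 5, V = 200, D = 500, alpha = 0.05, seed = 42)
bundle <- sample_corpus(cfg)                     # synthetic tweets + ground truth
corpus <- filter_corpus(bundle$tweets, filter_spec())

toks  <- lemmatize_tokens(tokenize_corpus(corpus))
vocab <- build_vocabulary(toks)
bow   <- to_bow(toks, vocab)
model <- fit_lda(bow, K = 5, sweeps = 200, burn_in = 50, restarts = 3, seed = 7)
model
#> <lda_model: K = 5 topics, V = 114 terms, 500 docs, 200 sweeps>

top_words(model, topics = 1, n = 5)
#> # A tibble: 5 × 4
#>   topic term  probability  rank
#> 1     1 w0027      0.737      1
#> 2     1 w0155      0.0677     2
#> 3     1 w0186      0.0441     3
#> 4     1 w0086      0.0223     4
#> 5     1 w0078      0.0124     5

coherence(top_words(model, n = 10), toks, measure = "c_v", window = 20)
#> <coherence c_v = 0.6756 over 5 topics (top_n = 10, window = 20)>

labeled <- label_corpus(corpus, bow, model, fit_tfidf(bow),
                        topic_names = paste("Topic", 1:5))
topic_shares(labeled, paste("Topic", 1:5))
#> # A tibble: 5 × 5
#>   label label_name     n share   pct
#> 1     1 Topic 1      121 0.242  24.2
#> 2     2 Topic 2      132 0.264  26.4
#> 3     3 Topic 3       74 0.148  14.8
#> 4     4 Topic 4       90 0.18   18
#> 5     5 Topic 5       83 0.166  16.6
```

The first topic concentrates 74% of its mass on one pseudo-word (the sharp
topics the sparse `β = 0.01` prior produces), the coherence score summarizes
how strongly each topic's top words co-occur in 20-token windows, and the
share table is the per-class distribution of the weak labels that the
classifiers are then trained on. From here, `encode_batch()` +
`neural_spec()` + `train_classifier()` train any of the three
architectures, `eval_metrics()`/`roc_pr_curves()` score them,
`cv_paired_ttest()` compares two of them, and
`score_sentiment()` + `aggregate_by_country()` produce the per-country
sentiment table.

A thin command-line front end over the same functions lives at
`inst/cli/tweettopics.R` with subcommands `simulate`, `preprocess`,
`topics`, `label`, `train`, `evaluate` and `aggregate`.

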