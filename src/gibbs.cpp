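#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// Tokens are passed as two parallel 0-based integer vectors: doc[i] is the
// document index and word[i] the vocabulary index of token i.  theta and phi
// are integrated out; each sweep resamples every token's topic from its full
// conditional
//   P(z_i = k | .) \propto (n_dk + alpha) * (n_kw + beta) / (n_k + V beta)
// with the token's own assignment removed from the counts.  All randomness
// comes from R's RNG so results are reproducible under set.seed().

static inline int sample_topic(const std::vector<double> &p, double total) {
  double u = unif_rand() * total;
  double cum = 0.0;
  int K = (int)p.size();
  for (int k = 0; k < K; ++k) {
    cum += p[k];
    if (u < cum) return k;
  }
  return K - 1;  // numerical fallthrough
}

// [[Rcpp::export(name = ".gibbs_lda_fit")]]
List gibbs_lda_fit(IntegerVector doc, IntegerVector word,
                   int M, int V, int K,
                   double alpha, double beta,
                   int sweeps, int burn_in, bool average) {
  const int n = doc.size();
  IntegerVector z(n);
  IntegerMatrix n_dk(M, K), n_kw(K, V);
  IntegerVector n_k(K);

  // random initialization
  for (int i = 0; i < n; ++i) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    n_dk(doc[i], k)++;
    n_kw(k, word[i])++;
    n_k[k]++;
  }

  NumericMatrix acc_dk(M, K), acc_kw(K, V);
  NumericVector acc_k(K);
  int n_acc = 0;

  std::vector<double> p(K);
  const double Vbeta = V * beta;

  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      const int d = doc[i], w = word[i], old = z[i];
      n_dk(d, old)--; n_kw(old, w)--; n_k[old]--;
      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        double pk = (n_dk(d, k) + alpha) * (n_kw(k, w) + beta) / (n_k[k] + Vbeta);
        p[k] = pk;
        total += pk;
      }
      int k_new = sample_topic(p, total);
      z[i] = k_new;
      n_dk(d, k_new)++; n_kw(k_new, w)++; n_k[k_new]++;
    }
    if (average && s >= burn_in) {
      for (int d = 0; d < M; ++d)
        for (int k = 0; k < K; ++k) acc_dk(d, k) += n_dk(d, k);
      for (int k = 0; k < K; ++k) {
        for (int w = 0; w < V; ++w) acc_kw(k, w) += n_kw(k, w);
        acc_k[k] += n_k[k];
      }
      n_acc++;
    }
    if (s % 50 == 0) Rcpp::checkUserInterrupt();
  }

  if (average && n_acc > 0) {
    for (int d = 0; d < M; ++d)
      for (int k = 0; k < K; ++k) acc_dk(d, k) /= n_acc;
    for (int k = 0; k < K; ++k) {
      for (int w = 0; w < V; ++w) acc_kw(k, w) /= n_acc;
      acc_k[k] /= n_acc;
    }
  } else {
    for (int d = 0; d < M; ++d)
      for (int k = 0; k < K; ++k) acc_dk(d, k) = n_dk(d, k);
    for (int k = 0; k < K; ++k) {
      for (int w = 0; w < V; ++w) acc_kw(k, w) = n_kw(k, w);
      acc_k[k] = n_k[k];
    }
  }

  return List::create(
    _["n_dk"] = n_dk, _["n_kw"] = n_kw, _["n_k"] = n_k,
    _["est_dk"] = acc_dk, _["est_kw"] = acc_kw, _["est_k"] = acc_k,
    _["z"] = z + 1);
}

// Fold-in inference for held-out documents: topic-word counts stay fixed at
// the fitted model's values, only the document's own topic counts move.

// [[Rcpp::export(name = ".gibbs_lda_infer")]]
NumericVector gibbs_lda_infer(IntegerVector word, NumericMatrix n_kw,
                              NumericVector n_k, double alpha, double beta,
                              int sweeps) {
  const int n = word.size();
  const int K = n_kw.nrow(), V = n_kw.ncol();
  const double Vbeta = V * beta;
  IntegerVector z(n);
  std::vector<double> ndk(K, 0.0), p(K);

  for (int i = 0; i < n; ++i) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ndk[k] += 1.0;
  }
  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      const int w = word[i], old = z[i];
      ndk[old] -= 1.0;
      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        double pk = (ndk[k] + alpha) * (n_kw(k, w) + beta) / (n_k[k] + Vbeta);
        p[k] = pk;
        total += pk;
      }
      int k_new = sample_topic(p, total);
      z[i] = k_new;
      ndk[k_new] += 1.0;
    }
  }
  NumericVector theta(K);
  double denom = n + K * alpha;
  for (int k = 0; k < K; ++k) theta[k] = (ndk[k] + alpha) / denom;
  return theta;
}
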