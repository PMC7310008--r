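#include <Rcpp.h>
using namespace Rcpp;

// Unnormalized full-conditional weight of topic k for one token whose own
// count has already been removed from the state:
//   (n_topic_word[k,v] + beta) / (n_topic_total[k] + Nv * beta) *
//   (n_doc_topic[d,k] + alpha)
// The document-length denominator is constant over k and is dropped.
static inline double cond_weight(double ntw, double ntot, double ndt,
                                 double alpha, double beta, double nv) {
  return (ntw + beta) / (ntot + nv * beta) * (ndt + alpha);
}

// Per-token full conditional, normalized over topics, for a state in which
// the token's own assignment is still counted (the function removes it).
// Exposed so tests can compare the sampler's conditional to a brute-force
// evaluation of the collapsed joint.
// [[Rcpp::export]]
NumericVector lda_token_conditional(IntegerMatrix n_doc_topic,
                                    IntegerMatrix n_topic_word,
                                    IntegerVector n_topic_total,
                                    int doc, int word, int topic,
                                    double alpha, double beta) {
  const int K = n_doc_topic.ncol();
  const int V = n_topic_word.ncol();
  const int d = doc - 1, v = word - 1, z = topic - 1;
  NumericVector p(K);
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    double ntw = n_topic_word(k, v) - (k == z ? 1 : 0);
    double ntot = n_topic_total[k] - (k == z ? 1 : 0);
    double ndt = n_doc_topic(d, k) - (k == z ? 1 : 0);
    p[k] = cond_weight(ntw, ntot, ndt, alpha, beta, (double)V);
    s += p[k];
  }
  for (int k = 0; k < K; ++k) p[k] /= s;
  return p;
}

// Collapsed Gibbs sweeps. Tokens are stored document-major (doc[] is
// non-decreasing) and visited in storage order, so the draw order is
// document-major, token-minor. Uses R's RNG: deterministic under set.seed().
// Returns the per-sweep token log-likelihood (computed from the smoothed
// theta/phi implied by the current counts).
// [[Rcpp::export]]
NumericVector lda_gibbs_sweeps(IntegerVector z, IntegerVector doc,
                               IntegerVector word,
                               IntegerMatrix n_doc_topic,
                               IntegerMatrix n_topic_word,
                               IntegerVector n_topic_total,
                               IntegerVector doc_tokens,
                               double alpha, double beta, int n_sweeps) {
  const int K = n_doc_topic.ncol();
  const int V = n_topic_word.ncol();
  const int N = z.size();
  NumericVector loglik(n_sweeps);
  std::vector<double> w(K);
  RNGScope scope;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int t = 0; t < N; ++t) {
      const int d = doc[t] - 1, v = word[t] - 1;
      int zk = z[t] - 1;
      --n_doc_topic(d, zk);
      --n_topic_word(zk, v);
      --n_topic_total[zk];
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        w[k] = cond_weight(n_topic_word(k, v), n_topic_total[k],
                           n_doc_topic(d, k), alpha, beta, (double)V);
        s += w[k];
      }
      double u = unif_rand() * s;
      int knew = 0;
      double acc = w[0];
      while (u > acc && knew < K - 1) acc += w[++knew];
      z[t] = knew + 1;
      ++n_doc_topic(d, knew);
      ++n_topic_word(knew, v);
      ++n_topic_total[knew];
    }
    // token log-likelihood under the current-state theta/phi estimates
    double ll = 0.0;
    for (int t = 0; t < N; ++t) {
      const int d = doc[t] - 1, v = word[t] - 1;
      double p = 0.0;
      for (int k = 0; k < K; ++k) {
        double theta = (n_doc_topic(d, k) + alpha) / (doc_tokens[d] + K * alpha);
        double phi = (n_topic_word(k, v) + beta) / (n_topic_total[k] + V * beta);
        p += theta * phi;
      }
      ll += std::log(p);
    }
    loglik[sweep] = ll;
  }
  return loglik;
}
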