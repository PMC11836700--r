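#include <Rcpp.h>
using namespace Rcpp;

// Sample a discrete Markov chain of length n (states 1..K) using R's RNG so
// that results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector cpp_sample_chain(int n, NumericMatrix trans, NumericVector init) {
  int K = trans.nrow();
  IntegerVector out(n);
  if (n == 0) return out;
  // initial state
  double u = unif_rand(), acc = 0.0;
  int s = K - 1;
  for (int k = 0; k < K; ++k) { acc += init[k]; if (u <= acc) { s = k; break; } }
  out[0] = s + 1;
  for (int t = 1; t < n; ++t) {
    u = unif_rand(); acc = 0.0;
    int nxt = K - 1;
    for (int k = 0; k < K; ++k) { acc += trans(s, k); if (u <= acc) { nxt = k; break; } }
    s = nxt;
    out[t] = s + 1;
  }
  return out;
}

// Scaled forward-backward over multiple independent sequences sharing
// emission densities but with per-sequence (context-specific) transition
// matrices.  logdens is T x K (rows = concatenated observations).
// seq_start/seq_len are 1-based starts and lengths; ctx is a 1-based index
// into trans_list for each sequence.  Returns posterior state probabilities
// (gamma), expected transition counts accumulated per context (xi, K*K*C),
// expected initial-state counts, and the total log-likelihood.
// [[Rcpp::export]]
List cpp_forward_backward(NumericMatrix logdens, IntegerVector seq_start,
                          IntegerVector seq_len, IntegerVector ctx,
                          List trans_list, NumericVector init) {
  int K = logdens.ncol();
  int C = trans_list.size();
  int nseq = seq_start.size();
  int T = logdens.nrow();
  NumericMatrix gamma(T, K);
  NumericVector xi(K * K * C);
  NumericVector init_counts(K);
  double loglik = 0.0;

  std::vector<NumericMatrix> trans(C);
  for (int c = 0; c < C; ++c) trans[c] = as<NumericMatrix>(trans_list[c]);

  for (int s = 0; s < nseq; ++s) {
    int off = seq_start[s] - 1;
    int n = seq_len[s];
    const NumericMatrix& P = trans[ctx[s] - 1];
    // emission probabilities scaled by per-row max to avoid underflow
    NumericMatrix b(n, K);
    std::vector<double> rowmax(n);
    for (int t = 0; t < n; ++t) {
      double m = logdens(off + t, 0);
      for (int k = 1; k < K; ++k) if (logdens(off + t, k) > m) m = logdens(off + t, k);
      rowmax[t] = m;
      for (int k = 0; k < K; ++k) b(t, k) = std::exp(logdens(off + t, k) - m);
    }
    NumericMatrix alpha(n, K), beta(n, K);
    std::vector<double> cscale(n);
    // forward
    double csum = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * b(0, k); csum += alpha(0, k); }
    if (csum <= 0) csum = 1e-300;
    cscale[0] = csum;
    for (int k = 0; k < K; ++k) alpha(0, k) /= csum;
    for (int t = 1; t < n; ++t) {
      csum = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * P(j, k);
        a *= b(t, k);
        alpha(t, k) = a; csum += a;
      }
      if (csum <= 0) csum = 1e-300;
      cscale[t] = csum;
      for (int k = 0; k < K; ++k) alpha(t, k) /= csum;
    }
    // backward
    for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
    for (int t = n - 2; t >= 0; --t) {
      for (int j = 0; j < K; ++j) {
        double v = 0.0;
        for (int k = 0; k < K; ++k) v += P(j, k) * b(t + 1, k) * beta(t + 1, k);
        beta(t, j) = v / cscale[t + 1];
      }
    }
    // gamma and xi
    for (int t = 0; t < n; ++t) {
      double g = 0.0;
      for (int k = 0; k < K; ++k) g += alpha(t, k) * beta(t, k);
      if (g <= 0) g = 1e-300;
      for (int k = 0; k < K; ++k) gamma(off + t, k) = alpha(t, k) * beta(t, k) / g;
    }
    int cbase = (ctx[s] - 1) * K * K;
    for (int t = 0; t + 1 < n; ++t) {
      for (int j = 0; j < K; ++j) {
        double aj = alpha(t, j);
        if (aj == 0) continue;
        for (int k = 0; k < K; ++k) {
          xi[cbase + j + K * k] += aj * P(j, k) * b(t + 1, k) * beta(t + 1, k) / cscale[t + 1];
        }
      }
    }
    for (int k = 0; k < K; ++k) init_counts[k] += gamma(off, k);
    for (int t = 0; t < n; ++t) loglik += std::log(cscale[t]) + rowmax[t];
  }
  xi.attr("dim") = IntegerVector::create(K, K, C);
  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["init_counts"] = init_counts, _["loglik"] = loglik);
}

// Net-displacement segmentation: returns 1-based indices of fixes at which a
// segment closes (the first fix at distance >= threshold from the segment's
// start fix).  The crossing fix also opens the next segment.
// [[Rcpp::export]]
IntegerVector cpp_segment_net(NumericVector x, NumericVector y, double threshold) {
  int n = x.size();
  std::vector<int> ends;
  int start = 0;
  double th2 = threshold * threshold;
  for (int i = 1; i < n; ++i) {
    double dx = x[i] - x[start], dy = y[i] - y[start];
    if (dx * dx + dy * dy >= th2) {
      ends.push_back(i + 1);
      start = i;
    }
  }
  return wrap(ends);
}

// Cumulative-displacement segmentation over the step-length series: returns
// 1-based indices of the fix that ends the step at which the running sum of
// step lengths first reaches the threshold.
// [[Rcpp::export]]
IntegerVector cpp_segment_cum(NumericVector steplen, double threshold) {
  int n = steplen.size();
  std::vector<int> ends;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += steplen[i];
    if (acc >= threshold) {
      ends.push_back(i + 2); // fix ending step i (fix index i+1, 1-based i+2)
      acc = 0.0;
    }
  }
  return wrap(ends);
}
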