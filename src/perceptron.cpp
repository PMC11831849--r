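#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Greedy left-to-right averaged perceptron for BIO sequence tagging.
// Feature ids are 1-based; tag ids are 1-based with tag 1 = O.
// Transition weights use the previously *predicted* tag (row 0 = BOS).

static inline int argmax(const std::vector<double>& s) {
  int best = 0;
  double b = s[0];
  for (size_t t = 1; t < s.size(); ++t) {
    if (s[t] > b) { b = s[t]; best = (int)t; }
  }
  return best; // ties -> lowest index; index 0 is O
}

static inline void score_token(const int* ids, int nf, int prev,
                               const std::vector<double>& W,
                               const std::vector<double>& T,
                               int n_tags, std::vector<double>& s) {
  for (int t = 0; t < n_tags; ++t) s[t] = T[prev * n_tags + t];
  for (int k = 0; k < nf; ++k) {
    const double* w = &W[(size_t)(ids[k] - 1) * n_tags];
    for (int t = 0; t < n_tags; ++t) s[t] += w[t];
  }
}

// notes: list of List(ids = IntegerVector (flat, 1-based feature ids),
//                     offs = IntegerVector (length ntok + 1, 0-based),
//                     tags = IntegerVector (1-based gold tags))
// order: epochs x n_notes matrix of 1-based note indices (shuffle order).
// [[Rcpp::export]]
List ap_train_cpp(List notes, int n_feats, int n_tags, IntegerMatrix order) {
  const int n_notes = notes.size();
  const int epochs = order.nrow();
  std::vector<double> W((size_t)n_feats * n_tags, 0.0);
  std::vector<double> U((size_t)n_feats * n_tags, 0.0);
  std::vector<double> T((size_t)(n_tags + 1) * n_tags, 0.0);
  std::vector<double> UT((size_t)(n_tags + 1) * n_tags, 0.0);
  std::vector<double> s(n_tags);
  double c = 1.0;

  // keep R object handles alive outside the hot loop
  std::vector<IntegerVector> v_ids, v_offs, v_tags;
  v_ids.reserve(n_notes); v_offs.reserve(n_notes); v_tags.reserve(n_notes);
  for (int i = 0; i < n_notes; ++i) {
    List nt = notes[i];
    v_ids.push_back(nt["ids"]);
    v_offs.push_back(nt["offs"]);
    v_tags.push_back(nt["tags"]);
  }

  for (int e = 0; e < epochs; ++e) {
    for (int j = 0; j < n_notes; ++j) {
      const int i = order(e, j) - 1;
      const IntegerVector& ids = v_ids[i];
      const IntegerVector& offs = v_offs[i];
      const IntegerVector& gold = v_tags[i];
      const int ntok = gold.size();
      int prev = 0; // BOS
      for (int k = 0; k < ntok; ++k) {
        const int a = offs[k], b = offs[k + 1];
        score_token(&ids[0] + a, b - a, prev, W, T, n_tags, s);
        const int pred = argmax(s);
        const int g = gold[k] - 1;
        if (pred != g) {
          for (int f = a; f < b; ++f) {
            const size_t base = (size_t)(ids[f] - 1) * n_tags;
            W[base + g] += 1.0;    U[base + g] += c;
            W[base + pred] -= 1.0; U[base + pred] -= c;
          }
          const size_t tb = (size_t)prev * n_tags;
          T[tb + g] += 1.0;    UT[tb + g] += c;
          T[tb + pred] -= 1.0; UT[tb + pred] -= c;
        }
        prev = pred + 1;
        c += 1.0;
      }
    }
  }

  NumericMatrix Wa(n_feats, n_tags), Ta(n_tags + 1, n_tags);
  for (int f = 0; f < n_feats; ++f)
    for (int t = 0; t < n_tags; ++t) {
      const size_t k = (size_t)f * n_tags + t;
      Wa(f, t) = W[k] - U[k] / c;
    }
  for (int p = 0; p <= n_tags; ++p)
    for (int t = 0; t < n_tags; ++t) {
      const size_t k = (size_t)p * n_tags + t;
      Ta(p, t) = T[k] - UT[k] / c;
    }
  return List::create(_["W"] = Wa, _["T"] = Ta, _["steps"] = c - 1.0);
}

// Greedy decode one token sequence. W: n_feats x n_tags (row-major via
// R matrix column access), T: (n_tags+1) x n_tags.
// [[Rcpp::export]]
IntegerVector ap_predict_cpp(IntegerVector ids, IntegerVector offs,
                             NumericMatrix W, NumericMatrix T) {
  const int n_tags = W.ncol();
  const int ntok = offs.size() - 1;
  IntegerVector out(ntok);
  std::vector<double> s(n_tags);
  int prev = 0;
  for (int k = 0; k < ntok; ++k) {
    for (int t = 0; t < n_tags; ++t) s[t] = T(prev, t);
    for (int f = offs[k]; f < offs[k + 1]; ++f) {
      const int fi = ids[f] - 1;
      for (int t = 0; t < n_tags; ++t) s[t] += W(fi, t);
    }
    const int pred = argmax(s);
    out[k] = pred + 1;
    prev = pred + 1;
  }
  return out;
}
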