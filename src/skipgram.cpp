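#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Skip-gram with negative sampling (SGNS), single-threaded and seeded, so a
// fixed (corpus, seed) pair is reproducible bit-for-bit on one platform.
//
// walks: list of integer vectors of 1-based token ids in 1..vocab.
// Context windows shrink randomly per centre (word2vec convention); negative
// tokens are drawn from the unigram distribution raised to 3/4; the sigmoid
// is a 4096-slot lookup table over [-6, 6] (word2vec convention); vectors
// are single precision. The learning rate decays linearly from alpha to
// alpha/10 over all (epoch, token) steps. Returns the vocab x dim
// input-vector matrix.
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List walks, int vocab, int dim, int window,
                             int epochs, int negative, double alpha,
                             int seed) {
  if (vocab < 1) stop("empty vocabulary");
  if (dim < 2) stop("dim must be >= 2");

  std::vector<std::vector<int>> corpus;
  corpus.reserve(walks.size());
  long long total_tokens = 0;
  std::vector<double> freq(vocab, 0.0);
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector w = walks[i];
    std::vector<int> s(w.size());
    for (int j = 0; j < w.size(); ++j) {
      int tok = w[j] - 1;
      if (tok < 0 || tok >= vocab) stop("token id out of range");
      s[j] = tok;
      freq[tok] += 1.0;
    }
    total_tokens += s.size();
    corpus.push_back(std::move(s));
  }
  if (total_tokens == 0) stop("empty corpus");

  // unigram^0.75 table for negative sampling
  const int table_size = 1 << 18;
  std::vector<int> table(table_size);
  {
    double z = 0.0;
    std::vector<double> pw(vocab);
    for (int v = 0; v < vocab; ++v) {
      pw[v] = std::pow(freq[v], 0.75);
      z += pw[v];
    }
    if (z <= 0.0) stop("degenerate unigram distribution");
    int v = 0;
    double cum = pw[0] / z;
    for (int i = 0; i < table_size; ++i) {
      table[i] = v;
      if ((double)(i + 1) / table_size > cum && v < vocab - 1) {
        ++v;
        cum += pw[v] / z;
      }
    }
  }

  // sigmoid lookup over [-MAX_EXP, MAX_EXP]
  const int exp_slots = 4096;
  const float MAX_EXP = 6.0f;
  std::vector<float> sigm(exp_slots);
  for (int i = 0; i < exp_slots; ++i) {
    double x = (2.0 * i / exp_slots - 1.0) * MAX_EXP;
    sigm[i] = (float)(1.0 / (1.0 + std::exp(-x)));
  }

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<float> syn0((size_t)vocab * dim);
  std::vector<float> syn1((size_t)vocab * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (float)((unif(rng) - 0.5) / dim);

  long long total_steps = (long long)epochs * total_tokens;
  long long step = 0;
  const double min_alpha = alpha / 10.0;
  std::vector<float> grad(dim);
  float* const gr = grad.data();

  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto& sent : corpus) {
      int slen = (int)sent.size();
      for (int c = 0; c < slen; ++c) {
        float lr = (float)(alpha -
                           (alpha - min_alpha) * ((double)step / total_steps));
        ++step;
        int centre = sent[c];
        int b = (int)(unif(rng) * window);  // shrink window
        for (int o = c - window + b; o <= c + window - b; ++o) {
          if (o == c || o < 0 || o >= slen) continue;
          int context = sent[o];
          float* __restrict__ v_in = &syn0[(size_t)centre * dim];
          for (int d = 0; d < dim; ++d) gr[d] = 0.0f;
          for (int k = 0; k <= negative; ++k) {
            int target;
            float label;
            if (k == 0) {
              target = context;
              label = 1.0f;
            } else {
              target = table[(int)(unif(rng) * table_size)];
              if (target == context) continue;
              label = 0.0f;
            }
            float* __restrict__ v_out = &syn1[(size_t)target * dim];
            float dot = 0.0f;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            float pred;
            if (dot >= MAX_EXP) pred = 1.0f;
            else if (dot <= -MAX_EXP) pred = 0.0f;
            else pred = sigm[(int)((dot + MAX_EXP) *
                                   (exp_slots / (2.0f * MAX_EXP)))];
            float g = (label - pred) * lr;
            for (int d = 0; d < dim; ++d) {
              gr[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += gr[d];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int v = 0; v < vocab; ++v)
    for (int d = 0; d < dim; ++d) out(v, d) = (double)syn0[(size_t)v * dim + d];
  return out;
}
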