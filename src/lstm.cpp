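// Token-level LSTM language model: teacher-forced training with Adam,
// early stopping on validation loss, autoregressive multinomial sampling.
//
// Parameter layout (flat R list of matrices):
//   E            (emb x V)    token embeddings, one column per token
//   W<l>, U<l>   (4H x in), (4H x H)  input / recurrent weights, layer l
//   b<l>         (4H x 1)    gate biases, order [input; forget; cell; output]
//   Wy, by       (V x H), (V x 1)     output projection
// Token indices are 0-based: START = 0, END = 1, PAD = 2. Loss is mean
// next-token cross-entropy in nats per (non-PAD) token.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;

static const int TOK_PAD = 2;

struct Params {
  mat E;
  std::vector<mat> W, U, b;
  mat Wy, by;
  int V, emb, H, L;
};

static Params unpack(const List& plist) {
  Params p;
  p.E = as<mat>(plist["E"]);
  p.Wy = as<mat>(plist["Wy"]);
  p.by = as<mat>(plist["by"]);
  p.L = as<int>(plist["n_layers"]);
  for (int l = 0; l < p.L; ++l) {
    std::string s = std::to_string(l + 1);
    p.W.push_back(as<mat>(plist["W" + s]));
    p.U.push_back(as<mat>(plist["U" + s]));
    p.b.push_back(as<mat>(plist["b" + s]));
  }
  p.V = p.E.n_cols;
  p.emb = p.E.n_rows;
  p.H = p.U[0].n_cols;
  return p;
}

static List pack(const Params& p) {
  List out;
  out["E"] = p.E;
  for (int l = 0; l < p.L; ++l) {
    std::string s = std::to_string(l + 1);
    out["W" + s] = p.W[l];
    out["U" + s] = p.U[l];
    out["b" + s] = p.b[l];
  }
  out["Wy"] = p.Wy;
  out["by"] = p.by;
  out["n_layers"] = p.L;
  return out;
}

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

static mat softmax_cols(mat z) {
  z.each_row() -= arma::max(z, 0);
  z = arma::exp(z);
  z.each_row() /= arma::sum(z, 0);
  return z;
}

static std::vector<std::vector<int>> as_seqs(const List& seqs) {
  std::vector<std::vector<int>> out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    IntegerVector v = seqs[i];
    out[i] = std::vector<int>(v.begin(), v.end());
  }
  return out;
}

// ---------------------------------------------------------------------------

struct Batch {
  arma::imat x, y;   // (T x B) inputs and next-token targets, PAD-filled
  arma::umat mask;   // 1 where y is a real target
  int T = 0, B = 0;
  double n_tokens = 0;
};

static Batch make_batch(const std::vector<std::vector<int>>& seqs,
                        const std::vector<int>& idx) {
  Batch batch;
  int B = idx.size();
  int maxlen = 0;
  for (int b = 0; b < B; ++b)
    maxlen = std::max(maxlen, (int)seqs[idx[b]].size());
  int T = maxlen - 1;
  batch.x.set_size(T, B);
  batch.y.set_size(T, B);
  batch.mask.set_size(T, B);
  batch.x.fill(TOK_PAD);
  batch.y.fill(TOK_PAD);
  batch.mask.zeros();
  for (int b = 0; b < B; ++b) {
    const std::vector<int>& s = seqs[idx[b]];
    for (size_t t = 0; t + 1 < s.size(); ++t) {
      batch.x(t, b) = s[t];
      batch.y(t, b) = s[t + 1];
      batch.mask(t, b) = 1;
    }
  }
  batch.T = T;
  batch.B = B;
  batch.n_tokens = arma::accu(batch.mask);
  return batch;
}

struct Cache {
  // activations per [timestep][layer], for backpropagation through time
  std::vector<std::vector<mat>> gi, gf, gg, go, c, tanh_c, input, h;
  std::vector<mat> probs;
};

static double forward(const Params& p, const Batch& batch, Cache* cache) {
  const int T = batch.T, B = batch.B, H = p.H;
  std::vector<mat> h(p.L, mat(H, B, arma::fill::zeros));
  std::vector<mat> c(p.L, mat(H, B, arma::fill::zeros));
  if (cache) {
    cache->gi.assign(T, {}); cache->gf.assign(T, {});
    cache->gg.assign(T, {}); cache->go.assign(T, {});
    cache->c.assign(T, {}); cache->tanh_c.assign(T, {});
    cache->input.assign(T, {}); cache->h.assign(T, {});
    cache->probs.assign(T, mat());
  }
  double loss = 0.0;
  for (int t = 0; t < T; ++t) {
    mat cur(p.emb, B);
    for (int b = 0; b < B; ++b) cur.col(b) = p.E.col(batch.x(t, b));
    for (int l = 0; l < p.L; ++l) {
      mat a = p.W[l] * cur + p.U[l] * h[l];
      a.each_col() += p.b[l].col(0);
      mat gi = sigmoid(a.rows(0, H - 1));
      mat gf = sigmoid(a.rows(H, 2 * H - 1));
      mat gg = arma::tanh(a.rows(2 * H, 3 * H - 1));
      mat go = sigmoid(a.rows(3 * H, 4 * H - 1));
      mat cnew = gf % c[l] + gi % gg;
      mat th = arma::tanh(cnew);
      if (cache) {
        cache->gi[t].push_back(gi); cache->gf[t].push_back(gf);
        cache->gg[t].push_back(gg); cache->go[t].push_back(go);
        cache->c[t].push_back(cnew); cache->tanh_c[t].push_back(th);
        cache->input[t].push_back(cur);
      }
      c[l] = cnew;
      h[l] = go % th;
      cur = h[l];
      if (cache) cache->h[t].push_back(h[l]);
    }
    mat logits = p.Wy * cur;
    logits.each_col() += p.by.col(0);
    mat probs = softmax_cols(logits);
    if (cache) cache->probs[t] = probs;
    for (int b = 0; b < B; ++b) {
      if (batch.mask(t, b))
        loss -= std::log(std::max(probs(batch.y(t, b), b), 1e-300));
    }
  }
  return loss / batch.n_tokens;
}

static Params zeros_like(const Params& p) {
  Params g = p;
  g.E.zeros();
  for (int l = 0; l < p.L; ++l) { g.W[l].zeros(); g.U[l].zeros(); g.b[l].zeros(); }
  g.Wy.zeros();
  g.by.zeros();
  return g;
}

static void backward(const Params& p, const Batch& batch, const Cache& cache,
                     Params* grad) {
  const int T = batch.T, B = batch.B, H = p.H;
  const double scale = 1.0 / batch.n_tokens;
  std::vector<mat> dh_next(p.L, mat(H, B, arma::fill::zeros));
  std::vector<mat> dc_next(p.L, mat(H, B, arma::fill::zeros));
  for (int t = T - 1; t >= 0; --t) {
    // output layer
    mat dlogits = cache.probs[t];
    for (int b = 0; b < B; ++b) {
      if (batch.mask(t, b)) {
        dlogits(batch.y(t, b), b) -= 1.0;
      } else {
        dlogits.col(b).zeros();
      }
    }
    dlogits *= scale;
    grad->Wy += dlogits * cache.h[t][p.L - 1].t();
    grad->by += arma::sum(dlogits, 1);
    mat dh_above = p.Wy.t() * dlogits;
    for (int l = p.L - 1; l >= 0; --l) {
      mat dh = dh_above + dh_next[l];
      const mat& gi = cache.gi[t][l];
      const mat& gf = cache.gf[t][l];
      const mat& gg = cache.gg[t][l];
      const mat& go = cache.go[t][l];
      const mat& th = cache.tanh_c[t][l];
      mat dc = dh % go % (1.0 - th % th) + dc_next[l];
      const mat c_prev = (t > 0) ? cache.c[t - 1][l] : mat(H, B, arma::fill::zeros);
      mat da(4 * H, B);
      da.rows(0, H - 1) = (dc % gg) % gi % (1.0 - gi);
      da.rows(H, 2 * H - 1) = (dc % c_prev) % gf % (1.0 - gf);
      da.rows(2 * H, 3 * H - 1) = (dc % gi) % (1.0 - gg % gg);
      da.rows(3 * H, 4 * H - 1) = (dh % th) % go % (1.0 - go);
      const mat h_prev = (t > 0) ? cache.h[t - 1][l] : mat(H, B, arma::fill::zeros);
      grad->W[l] += da * cache.input[t][l].t();
      grad->U[l] += da * h_prev.t();
      grad->b[l] += arma::sum(da, 1);
      dh_above = p.W[l].t() * da;   // flows to the layer below (or embeddings)
      dh_next[l] = p.U[l].t() * da;
      dc_next[l] = dc % gf;
    }
    for (int b = 0; b < B; ++b)
      grad->E.col(batch.x(t, b)) += dh_above.col(b);
  }
}

// ---------------------------------------------------------------------------
// Adam

struct Adam {
  Params m, v;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  Adam(const Params& p, double lr_) : m(zeros_like(p)), v(zeros_like(p)), lr(lr_) {}
  void upd(mat& w, mat& mm, mat& vv, const mat& g, double corr1, double corr2) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    w -= lr * (mm / corr1) / (arma::sqrt(vv / corr2) + eps);
  }
  void step(Params& p, const Params& g) {
    ++t;
    double corr1 = 1.0 - std::pow(b1, (double)t);
    double corr2 = 1.0 - std::pow(b2, (double)t);
    upd(p.E, m.E, v.E, g.E, corr1, corr2);
    for (int l = 0; l < p.L; ++l) {
      upd(p.W[l], m.W[l], v.W[l], g.W[l], corr1, corr2);
      upd(p.U[l], m.U[l], v.U[l], g.U[l], corr1, corr2);
      upd(p.b[l], m.b[l], v.b[l], g.b[l], corr1, corr2);
    }
    upd(p.Wy, m.Wy, v.Wy, g.Wy, corr1, corr2);
    upd(p.by, m.by, v.by, g.by, corr1, corr2);
  }
};

static double grad_sq_norm(const Params& g) {
  double s = arma::accu(g.E % g.E) + arma::accu(g.Wy % g.Wy) +
             arma::accu(g.by % g.by);
  for (size_t l = 0; l < g.W.size(); ++l)
    s += arma::accu(g.W[l] % g.W[l]) + arma::accu(g.U[l] % g.U[l]) +
         arma::accu(g.b[l] % g.b[l]);
  return s;
}

// rescale so the global gradient norm stays below max_norm (BPTT spikes
// otherwise poison Adam's second-moment estimates for thousands of steps)
static void clip_gradients(Params& g, double max_norm) {
  double norm = std::sqrt(grad_sq_norm(g));
  if (norm <= max_norm) return;
  double f = max_norm / norm;
  g.E *= f; g.Wy *= f; g.by *= f;
  for (size_t l = 0; l < g.W.size(); ++l) {
    g.W[l] *= f; g.U[l] *= f; g.b[l] *= f;
  }
}

static double dataset_loss(const Params& p,
                           const std::vector<std::vector<int>>& seqs,
                           int batch_size) {
  double total = 0.0, tokens = 0.0;
  for (size_t start = 0; start < seqs.size(); start += batch_size) {
    std::vector<int> idx;
    for (size_t i = start; i < std::min(seqs.size(), start + batch_size); ++i)
      idx.push_back(i);
    Batch batch = make_batch(seqs, idx);
    double loss = forward(p, batch, nullptr);
    total += loss * batch.n_tokens;
    tokens += batch.n_tokens;
  }
  return total / tokens;
}

// ---------------------------------------------------------------------------
// exported interface

// [[Rcpp::export]]
List cpp_lstm_init(int vocab_size, int embedding_dim, int hidden_dim,
                   int n_layers, int seed) {
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  double s = 1.0 / std::sqrt((double)hidden_dim);
  auto fill = [&](mat& w, double scale) {
    for (arma::uword i = 0; i < w.n_elem; ++i) w(i) = unif(rng) * scale;
  };
  Params p;
  p.L = n_layers;
  p.V = vocab_size;
  p.emb = embedding_dim;
  p.H = hidden_dim;
  p.E.set_size(embedding_dim, vocab_size);
  fill(p.E, 0.1);
  int in_dim = embedding_dim;
  for (int l = 0; l < n_layers; ++l) {
    mat W(4 * hidden_dim, in_dim), U(4 * hidden_dim, hidden_dim),
        b(4 * hidden_dim, 1, arma::fill::zeros);
    fill(W, s);
    fill(U, s);
    b.rows(hidden_dim, 2 * hidden_dim - 1).fill(1.0);  // forget-gate bias
    p.W.push_back(W);
    p.U.push_back(U);
    p.b.push_back(b);
    in_dim = hidden_dim;
  }
  // near-zero output projection: the untrained model predicts (almost)
  // uniformly, so its loss sits at ln(V) nats/token
  p.Wy.set_size(vocab_size, hidden_dim);
  fill(p.Wy, 0.01);
  p.by.set_size(vocab_size, 1);
  p.by.zeros();
  return pack(p);
}

// [[Rcpp::export]]
List cpp_lstm_train(List params, List train_seqs, List valid_seqs,
                    int batch_size, double learning_rate, int max_epochs,
                    int patience_minibatches, int eval_every, int seed) {
  Params p = unpack(params);
  std::vector<std::vector<int>> train = as_seqs(train_seqs);
  std::vector<std::vector<int>> valid = as_seqs(valid_seqs);
  std::mt19937 rng(seed);
  Adam adam(p, learning_rate);

  std::vector<int> order(train.size());
  for (size_t i = 0; i < train.size(); ++i) order[i] = i;

  std::vector<double> log_mb, log_train, log_valid;
  double best_valid = std::numeric_limits<double>::infinity();
  Params best = p;
  long minibatch = 0, since_best = 0;
  double running = 0.0;
  long running_n = 0;
  bool stop = false;

  for (int epoch = 0; epoch < max_epochs && !stop; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (size_t start = 0; start < train.size() && !stop; start += batch_size) {
      std::vector<int> idx(order.begin() + start,
                           order.begin() + std::min(train.size(),
                                                    start + batch_size));
      Batch batch = make_batch(train, idx);
      Cache cache;
      double loss = forward(p, batch, &cache);
      Params grad = zeros_like(p);
      backward(p, batch, cache, &grad);
      clip_gradients(grad, 5.0);
      adam.step(p, grad);
      ++minibatch;
      ++since_best;
      running += loss;
      ++running_n;
      if (minibatch % eval_every == 0) {
        double vloss = dataset_loss(p, valid, batch_size);
        log_mb.push_back((double)minibatch);
        log_train.push_back(running / running_n);
        log_valid.push_back(vloss);
        running = 0.0;
        running_n = 0;
        if (vloss < best_valid) {
          best_valid = vloss;
          best = p;
          since_best = 0;
        }
        if (since_best >= patience_minibatches) stop = true;
        Rcpp::checkUserInterrupt();
      }
    }
  }
  if (log_mb.empty() || log_mb.back() < (double)minibatch) {
    double vloss = dataset_loss(p, valid, batch_size);
    log_mb.push_back((double)minibatch);
    log_train.push_back(running_n > 0 ? running / running_n : NA_REAL);
    log_valid.push_back(vloss);
    if (vloss < best_valid) {
      best_valid = vloss;
      best = p;
    }
  }
  return List::create(
      _["params"] = pack(best),
      _["best_validation_loss"] = best_valid,
      _["log"] = DataFrame::create(_["minibatch"] = log_mb,
                                   _["train_loss"] = log_train,
                                   _["validation_loss"] = log_valid));
}

// analytic gradient of the mean loss over one batch (testing aid)
// [[Rcpp::export]]
List cpp_lstm_grad(List params, List seqs) {
  Params p = unpack(params);
  std::vector<std::vector<int>> ss = as_seqs(seqs);
  std::vector<int> idx(ss.size());
  for (size_t i = 0; i < ss.size(); ++i) idx[i] = i;
  Batch batch = make_batch(ss, idx);
  Cache cache;
  forward(p, batch, &cache);
  Params grad = zeros_like(p);
  backward(p, batch, cache, &grad);
  return pack(grad);
}

// [[Rcpp::export]]
double cpp_lstm_loss(List params, List seqs, int batch_size) {
  Params p = unpack(params);
  return dataset_loss(p, as_seqs(seqs), batch_size);
}

// next-token distribution after consuming `prefix` (0-based token ids);
// the brute-force oracle for the batched loss
// [[Rcpp::export]]
NumericVector cpp_lstm_step_probs(List params, IntegerVector prefix) {
  Params p = unpack(params);
  std::vector<mat> h(p.L, mat(p.H, 1, arma::fill::zeros));
  std::vector<mat> c(p.L, mat(p.H, 1, arma::fill::zeros));
  mat cur;
  for (int t = 0; t < prefix.size(); ++t) {
    cur = p.E.col(prefix[t]);
    for (int l = 0; l < p.L; ++l) {
      mat a = p.W[l] * cur + p.U[l] * h[l] + p.b[l];
      mat gi = sigmoid(a.rows(0, p.H - 1));
      mat gf = sigmoid(a.rows(p.H, 2 * p.H - 1));
      mat gg = arma::tanh(a.rows(2 * p.H, 3 * p.H - 1));
      mat go = sigmoid(a.rows(3 * p.H, 4 * p.H - 1));
      c[l] = gf % c[l] + gi % gg;
      h[l] = go % arma::tanh(c[l]);
      cur = h[l];
    }
  }
  mat logits = p.Wy * cur + p.by;
  mat probs = softmax_cols(logits);
  return NumericVector(probs.begin(), probs.end());
}

// [[Rcpp::export]]
List cpp_lstm_sample(List params, int n, int max_len, double temperature,
                     int seed) {
  Params p = unpack(params);
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const bool greedy = temperature < 1e-6;

  std::vector<std::vector<int>> out(n);
  std::vector<bool> done(n, false);
  std::vector<mat> h(p.L, mat(p.H, n, arma::fill::zeros));
  std::vector<mat> c(p.L, mat(p.H, n, arma::fill::zeros));
  std::vector<int> tok(n, 0);  // all sequences start from START

  for (int step = 0; step < max_len; ++step) {
    mat cur(p.emb, n);
    for (int b = 0; b < n; ++b) cur.col(b) = p.E.col(tok[b]);
    for (int l = 0; l < p.L; ++l) {
      mat a = p.W[l] * cur + p.U[l] * h[l];
      a.each_col() += p.b[l].col(0);
      mat gi = sigmoid(a.rows(0, p.H - 1));
      mat gf = sigmoid(a.rows(p.H, 2 * p.H - 1));
      mat gg = arma::tanh(a.rows(2 * p.H, 3 * p.H - 1));
      mat go = sigmoid(a.rows(3 * p.H, 4 * p.H - 1));
      c[l] = gf % c[l] + gi % gg;
      h[l] = go % arma::tanh(c[l]);
      cur = h[l];
    }
    mat logits = p.Wy * cur;
    logits.each_col() += p.by.col(0);
    // START and PAD are never emitted
    logits.row(0).fill(-1e30);
    logits.row(TOK_PAD).fill(-1e30);
    if (!greedy) logits /= temperature;
    mat probs = softmax_cols(logits);
    bool all_done = true;
    for (int b = 0; b < n; ++b) {
      if (done[b]) continue;
      int pick;
      if (greedy) {
        pick = probs.col(b).index_max();
      } else {
        double u = unif(rng), acc = 0.0;
        pick = p.V - 1;
        for (int k = 0; k < p.V; ++k) {
          acc += probs(k, b);
          if (u <= acc) { pick = k; break; }
        }
      }
      if (pick == 1) {  // END
        done[b] = true;
      } else {
        out[b].push_back(pick);
        tok[b] = pick;
        all_done = false;
      }
      if (done[b]) tok[b] = TOK_PAD;
    }
    if (all_done) break;
  }
  List res(n);
  for (int b = 0; b < n; ++b) res[b] = IntegerVector(out[b].begin(), out[b].end());
  return res;
}
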