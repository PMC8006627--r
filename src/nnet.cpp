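// BiLSTM-CRF sequence taggers: encoders (word BiLSTM with optional
// character BiLSTM or character CNN channel), linear-chain CRF
// (log-partition, NLL gradient, Viterbi), Adam and EMA updates.
// Single-threaded and deterministic given the R-side seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

static inline mat view(SEXP s) {
  NumericMatrix m(s);
  return mat(m.begin(), m.nrow(), m.ncol(), false, true); // no copy
}

static inline double logsumexp(const vec& x) {
  double m = x.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::sum(arma::exp(x - m)));
}

// ---------------------------------------------------------------------
// LSTM (one direction).  W: (Din+H) x 4H, b: 1 x 4H.  Gate order i,f,g,o.
struct LSTMCache {
  mat X;            // Din x T (inputs in processing order)
  mat I, F, G, O;   // H x T
  mat C, H;         // H x T
};

static void lstm_forward(const mat& W, const mat& b, const mat& X,
                         LSTMCache& cc) {
  const uword T = X.n_cols;
  const uword H = W.n_cols / 4;
  const uword Din = W.n_rows - H;
  cc.X = X;
  cc.I.set_size(H, T); cc.F.set_size(H, T); cc.G.set_size(H, T);
  cc.O.set_size(H, T); cc.C.set_size(H, T); cc.H.set_size(H, T);
  vec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  for (uword t = 0; t < T; ++t) {
    vec xh(Din + H);
    xh.head(Din) = X.col(t);
    xh.tail(H) = h;
    vec z = W.t() * xh + b.row(0).t();
    vec i = 1.0 / (1.0 + arma::exp(-z.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + arma::exp(-z.subvec(H, 2 * H - 1)));
    vec g = arma::tanh(z.subvec(2 * H, 3 * H - 1));
    vec o = 1.0 / (1.0 + arma::exp(-z.subvec(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    cc.I.col(t) = i; cc.F.col(t) = f; cc.G.col(t) = g; cc.O.col(t) = o;
    cc.C.col(t) = c; cc.H.col(t) = h;
  }
}

// dH: H x T upstream gradient on hidden states (in processing order).
// Accumulates into dW, db; returns dX (Din x T).
static mat lstm_backward(const mat& W, const LSTMCache& cc, const mat& dH,
                         mat& dW, mat& db) {
  const uword T = cc.X.n_cols;
  const uword H = W.n_cols / 4;
  const uword Din = W.n_rows - H;
  mat dX(Din, T, arma::fill::zeros);
  vec dh_next(H, arma::fill::zeros), dc_next(H, arma::fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    vec dh = dH.col(tt) + dh_next;
    vec i = cc.I.col(tt), f = cc.F.col(tt), g = cc.G.col(tt),
        o = cc.O.col(tt), c = cc.C.col(tt);
    vec c_prev = (tt == 0) ? vec(H, arma::fill::zeros)
                           : vec(cc.C.col(tt - 1));
    vec tc = arma::tanh(c);
    vec dc = dc_next + dh % o % (1.0 - tc % tc);
    vec do_ = dh % tc;
    vec di = dc % g;
    vec df = dc % c_prev;
    vec dg = dc % i;
    dc_next = dc % f;
    vec dz(4 * H);
    dz.subvec(0, H - 1) = di % i % (1.0 - i);
    dz.subvec(H, 2 * H - 1) = df % f % (1.0 - f);
    dz.subvec(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dz.subvec(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    vec h_prev = (tt == 0) ? vec(H, arma::fill::zeros)
                           : vec(cc.H.col(tt - 1));
    vec xh(Din + H);
    xh.head(Din) = cc.X.col(tt);
    xh.tail(H) = h_prev;
    dW += xh * dz.t();
    db.row(0) += dz.t();
    vec dxh = W * dz;
    dX.col(tt) = dxh.head(Din);
    dh_next = dxh.tail(H);
  }
  return dX;
}

// ---------------------------------------------------------------------
// Parameter access helpers
struct Params {
  mat Ew, Wf, bf, Wb, bb, P, pb, Tr;          // shared
  mat Ec, Cf, cbf, Cb, cbb;                   // char BiLSTM (arch 1)
  mat Fc, fcb;                                // char CNN (arch 2)
  int arch;
};

static Params unpack(List params, int arch) {
  Params p;
  p.arch = arch;
  p.Ew = view(params["Ew"]); p.Wf = view(params["Wf"]);
  p.bf = view(params["bf"]); p.Wb = view(params["Wb"]);
  p.bb = view(params["bb"]); p.P = view(params["P"]);
  p.pb = view(params["pb"]); p.Tr = view(params["Tr"]);
  if (arch >= 1) p.Ec = view(params["Ec"]);
  if (arch == 1) {
    p.Cf = view(params["Cf"]); p.cbf = view(params["cbf"]);
    p.Cb = view(params["Cb"]); p.cbb = view(params["cbb"]);
  }
  if (arch == 2) {
    p.Fc = view(params["Fc"]); p.fcb = view(params["fcb"]);
  }
  return p;
}

// gradient accumulator congruent with params
struct Grads {
  mat Ew, Wf, bf, Wb, bb, P, pb, Tr, Ec, Cf, cbf, Cb, cbb, Fc, fcb;
  void init(const Params& p) {
    Ew.zeros(p.Ew.n_rows, p.Ew.n_cols);
    Wf.zeros(arma::size(p.Wf)); bf.zeros(arma::size(p.bf));
    Wb.zeros(arma::size(p.Wb)); bb.zeros(arma::size(p.bb));
    P.zeros(arma::size(p.P)); pb.zeros(arma::size(p.pb));
    Tr.zeros(arma::size(p.Tr));
    if (p.arch >= 1) Ec.zeros(arma::size(p.Ec));
    if (p.arch == 1) {
      Cf.zeros(arma::size(p.Cf)); cbf.zeros(arma::size(p.cbf));
      Cb.zeros(arma::size(p.Cb)); cbb.zeros(arma::size(p.cbb));
    }
    if (p.arch == 2) {
      Fc.zeros(arma::size(p.Fc)); fcb.zeros(arma::size(p.fcb));
    }
  }
};

// ---------------------------------------------------------------------
// Character channels
struct CharCache {
  LSTMCache fw, bw;       // char BiLSTM
  mat E;                  // Dc x m char embeddings (original order)
  arma::umat argmax;      // CNN: window index per filter
  mat Win;                // CNN: 3Dc x m stacked windows
};

// returns the char representation (2Hc) of one token
static vec char_rep(const Params& p, const arma::ivec& chars,
                    CharCache& cc) {
  const uword m = chars.n_elem;
  const uword Dc = p.Ec.n_cols;
  cc.E.set_size(Dc, m);
  for (uword j = 0; j < m; ++j) cc.E.col(j) = p.Ec.row(chars[j]).t();
  if (p.arch == 1) {
    const uword Hc = p.Cf.n_cols / 4;
    lstm_forward(p.Cf, p.cbf, cc.E, cc.fw);
    lstm_forward(p.Cb, p.cbb, arma::fliplr(cc.E), cc.bw);
    vec r(2 * Hc);
    r.head(Hc) = cc.fw.H.col(m - 1);
    r.tail(Hc) = cc.bw.H.col(m - 1);
    return r;
  }
  // char CNN: width-3 convolution, zero padding, ReLU, max over time
  const uword nf = p.Fc.n_cols;
  cc.Win.zeros(3 * Dc, m);
  for (uword j = 0; j < m; ++j) {
    if (j > 0) cc.Win.col(j).subvec(0, Dc - 1) = cc.E.col(j - 1);
    cc.Win.col(j).subvec(Dc, 2 * Dc - 1) = cc.E.col(j);
    if (j + 1 < m) cc.Win.col(j).subvec(2 * Dc, 3 * Dc - 1) = cc.E.col(j + 1);
  }
  mat Z = p.Fc.t() * cc.Win;          // nf x m
  Z.each_col() += p.fcb.row(0).t();
  Z.transform([](double z) { return z > 0 ? z : 0.0; });
  cc.argmax.set_size(nf, 1);
  vec r(nf);
  for (uword k = 0; k < nf; ++k) {
    uword j = Z.row(k).index_max();
    cc.argmax(k, 0) = j;
    r[k] = Z(k, j);
  }
  return r;
}

// backprop through the char channel; dr is gradient on the 2Hc rep
static void char_rep_backward(const Params& p, const arma::ivec& chars,
                              CharCache& cc, const vec& dr, Grads& g) {
  const uword m = chars.n_elem;
  const uword Dc = p.Ec.n_cols;
  mat dE(Dc, m, arma::fill::zeros);
  if (p.arch == 1) {
    const uword Hc = p.Cf.n_cols / 4;
    mat dHf(Hc, m, arma::fill::zeros), dHb(Hc, m, arma::fill::zeros);
    dHf.col(m - 1) = dr.head(Hc);
    dHb.col(m - 1) = dr.tail(Hc);
    mat dXf = lstm_backward(p.Cf, cc.fw, dHf, g.Cf, g.cbf);
    mat dXb = lstm_backward(p.Cb, cc.bw, dHb, g.Cb, g.cbb);
    dE = dXf + arma::fliplr(dXb);
  } else {
    const uword nf = p.Fc.n_cols;
    for (uword k = 0; k < nf; ++k) {
      uword j = cc.argmax(k, 0);
      // ReLU at the max: if the max activation is 0, gradient dies
      double z = arma::dot(p.Fc.col(k), cc.Win.col(j)) + p.fcb(0, k);
      if (z <= 0) continue;
      g.Fc.col(k) += dr[k] * cc.Win.col(j);
      g.fcb(0, k) += dr[k];
      vec dwin = dr[k] * p.Fc.col(k);
      if (j > 0) dE.col(j - 1) += dwin.subvec(0, Dc - 1);
      dE.col(j) += dwin.subvec(Dc, 2 * Dc - 1);
      if (j + 1 < m) dE.col(j + 1) += dwin.subvec(2 * Dc, 3 * Dc - 1);
    }
  }
  for (uword j = 0; j < m; ++j) g.Ec.row(chars[j]) += dE.col(j).t();
}

// ---------------------------------------------------------------------
// CRF.  Tr is (K+2) x (K+2); START = K, STOP = K+1.
static double crf_logZ(const mat& em, const mat& Tr, mat* alpha_out) {
  const uword T = em.n_rows, K = em.n_cols;
  mat alpha(K, T);
  alpha.col(0) = Tr.row(K).subvec(0, K - 1).t() + em.row(0).t();
  for (uword t = 1; t < T; ++t) {
    for (uword j = 0; j < K; ++j) {
      vec s = alpha.col(t - 1) + Tr.col(j).subvec(0, K - 1);
      alpha(j, t) = logsumexp(s) + em(t, j);
    }
  }
  vec fin = alpha.col(T - 1) + Tr.col(K + 1).subvec(0, K - 1);
  if (alpha_out) *alpha_out = alpha;
  return logsumexp(fin);
}

// [[Rcpp::export]]
double cpp_crf_log_partition(NumericMatrix emissions,
                             NumericMatrix transitions) {
  mat em = view(emissions), Tr = view(transitions);
  if (em.n_rows == 0) stop("empty sequence");
  return crf_logZ(em, Tr, nullptr);
}

static double gold_score(const mat& em, const mat& Tr,
                         const arma::ivec& tags) {
  const uword T = em.n_rows, K = em.n_cols;
  double s = Tr(K, tags[0]) + em(0, tags[0]);
  for (uword t = 1; t < T; ++t) s += Tr(tags[t - 1], tags[t]) + em(t, tags[t]);
  s += Tr(tags[T - 1], K + 1);
  return s;
}

// [[Rcpp::export]]
double cpp_crf_nll(NumericMatrix emissions, NumericMatrix transitions,
                   IntegerVector tags) {
  mat em = view(emissions), Tr = view(transitions);
  if (em.n_rows == 0) stop("empty sequence");
  if ((uword)tags.size() != em.n_rows) stop("tags/emissions length mismatch");
  arma::ivec tg(tags.size());
  for (int i = 0; i < tags.size(); ++i) {
    if (tags[i] < 0 || tags[i] >= (int)em.n_cols)
      stop("tag index out of range");
    tg[i] = tags[i];
  }
  return crf_logZ(em, Tr, nullptr) - gold_score(em, Tr, tg);
}

// NLL gradient wrt emissions and transitions (forward-backward)
static double crf_nll_grad(const mat& em, const mat& Tr,
                           const arma::ivec& tags, mat& dEm, mat& dTr) {
  const uword T = em.n_rows, K = em.n_cols;
  mat alpha;
  double logZ = crf_logZ(em, Tr, &alpha);
  mat beta(K, T);
  beta.col(T - 1) = Tr.col(K + 1).subvec(0, K - 1);
  for (uword t = T - 1; t-- > 0;) {
    for (uword i = 0; i < K; ++i) {
      vec s = Tr.row(i).subvec(0, K - 1).t() + em.row(t + 1).t()
              + beta.col(t + 1);
      beta(i, t) = logsumexp(s);
    }
  }
  dEm.zeros(T, K);
  for (uword t = 0; t < T; ++t)
    for (uword j = 0; j < K; ++j)
      dEm(t, j) = std::exp(alpha(j, t) + beta(j, t) - logZ);
  // pairwise marginals for transitions
  for (uword t = 0; t + 1 < T; ++t)
    for (uword i = 0; i < K; ++i)
      for (uword j = 0; j < K; ++j)
        dTr(i, j) += std::exp(alpha(i, t) + Tr(i, j) + em(t + 1, j)
                              + beta(j, t + 1) - logZ);
  for (uword j = 0; j < K; ++j) {
    dTr(K, j) += dEm(0, j);          // START marginal = unary at t=0
    dTr(j, K + 1) += dEm(T - 1, j);  // STOP marginal = unary at t=T-1
  }
  // subtract gold indicators
  dEm(0, tags[0]) -= 1.0;
  dTr(K, tags[0]) -= 1.0;
  for (uword t = 1; t < T; ++t) {
    dEm(t, tags[t]) -= 1.0;
    dTr(tags[t - 1], tags[t]) -= 1.0;
  }
  dTr(tags[T - 1], K + 1) -= 1.0;
  return logZ - gold_score(em, Tr, tags);
}

// [[Rcpp::export]]
List cpp_viterbi(NumericMatrix emissions, NumericMatrix transitions) {
  mat em = view(emissions), Tr = view(transitions);
  const uword T = em.n_rows, K = em.n_cols;
  if (T == 0) stop("empty sequence");
  mat delta(K, T);
  arma::umat back(K, T);
  delta.col(0) = Tr.row(K).subvec(0, K - 1).t() + em.row(0).t();
  for (uword t = 1; t < T; ++t) {
    for (uword j = 0; j < K; ++j) {
      double best = -arma::datum::inf;
      uword arg = 0;
      for (uword i = 0; i < K; ++i) {
        double s = delta(i, t - 1) + Tr(i, j);
        if (s > best) { best = s; arg = i; }  // strict: lowest index wins ties
      }
      delta(j, t) = best + em(t, j);
      back(j, t) = arg;
    }
  }
  double best = -arma::datum::inf;
  uword arg = 0;
  for (uword j = 0; j < K; ++j) {
    double s = delta(j, T - 1) + Tr(j, K + 1);
    if (s > best) { best = s; arg = j; }
  }
  IntegerVector path(T);
  uword cur = arg;
  for (uword t = T; t-- > 0;) {
    path[t] = (int)cur;
    if (t > 0) cur = back(cur, t);
  }
  return List::create(_["path"] = path, _["score"] = best);
}

// ---------------------------------------------------------------------
// Full sequence forward: emissions for one tokenized sentence
struct SeqCache {
  mat Xrep;                    // Din x T word representations (post-dropout)
  mat Mask;                    // dropout mask (Din x T), 1s at predict time
  std::vector<CharCache> cc;   // per token
  LSTMCache fw, bw;
  mat Hcat;                    // 2H x T
};

static mat seq_emissions(const Params& p, const arma::ivec& words,
                         const std::vector<arma::ivec>& chars,
                         SeqCache& sc, double dropout, std::mt19937* rng) {
  const uword T = words.n_elem;
  const uword Dw = p.Ew.n_cols;
  const uword H = p.Wf.n_cols / 4;
  const uword Din = p.Wf.n_rows - H;
  sc.Xrep.set_size(Din, T);
  sc.cc.resize(T);
  for (uword t = 0; t < T; ++t) {
    sc.Xrep.col(t).subvec(0, Dw - 1) = p.Ew.row(words[t]).t();
    if (p.arch >= 1) {
      vec r = char_rep(p, chars[t], sc.cc[t]);
      sc.Xrep.col(t).subvec(Dw, Din - 1) = r;
    }
  }
  sc.Mask.ones(Din, T);
  if (dropout > 0 && rng) {           // inverted dropout on the word rep
    std::bernoulli_distribution keep(1.0 - dropout);
    for (uword t = 0; t < T; ++t)
      for (uword d = 0; d < Din; ++d)
        sc.Mask(d, t) = keep(*rng) ? 1.0 / (1.0 - dropout) : 0.0;
    sc.Xrep %= sc.Mask;
  }
  lstm_forward(p.Wf, p.bf, sc.Xrep, sc.fw);
  lstm_forward(p.Wb, p.bb, arma::fliplr(sc.Xrep), sc.bw);
  sc.Hcat.set_size(2 * H, T);
  sc.Hcat.rows(0, H - 1) = sc.fw.H;
  sc.Hcat.rows(H, 2 * H - 1) = arma::fliplr(sc.bw.H);
  mat em = sc.Hcat.t() * p.P;         // T x K
  em.each_row() += p.pb.row(0);
  return em;
}

static void seq_backward(const Params& p, const arma::ivec& words,
                         const std::vector<arma::ivec>& chars,
                         SeqCache& sc, const mat& dEm, Grads& g) {
  const uword T = words.n_elem;
  const uword Dw = p.Ew.n_cols;
  const uword H = p.Wf.n_cols / 4;
  const uword Din = p.Wf.n_rows - H;
  g.P += sc.Hcat * dEm;               // (2H x T)(T x K)
  g.pb.row(0) += arma::sum(dEm, 0);
  mat dHcat = p.P * dEm.t();          // 2H x T
  mat dXf = lstm_backward(p.Wf, sc.fw, dHcat.rows(0, H - 1), g.Wf, g.bf);
  mat dXb = lstm_backward(p.Wb, sc.bw,
                          arma::fliplr(dHcat.rows(H, 2 * H - 1)),
                          g.Wb, g.bb);
  mat dX = dXf + arma::fliplr(dXb);
  dX %= sc.Mask;                      // through dropout
  for (uword t = 0; t < T; ++t) {
    g.Ew.row(words[t]) += dX.col(t).subvec(0, Dw - 1).t();
    if (p.arch >= 1)
      char_rep_backward(p, chars[t], sc.cc[t],
                        dX.col(t).subvec(Dw, Din - 1), g);
  }
}

static arma::ivec as_ivec(IntegerVector v) {
  arma::ivec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i];
  return out;
}

static void parse_seq(List seq, arma::ivec& words,
                      std::vector<arma::ivec>& chars, int arch) {
  words = as_ivec(seq["words"]);
  chars.clear();
  if (arch >= 1) {
    List cl = seq["chars"];
    for (int i = 0; i < cl.size(); ++i)
      chars.push_back(as_ivec(cl[i]));
  } else {
    chars.resize(words.n_elem);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_emissions(List params, int arch, List seq) {
  Params p = unpack(params, arch);
  arma::ivec words;
  std::vector<arma::ivec> chars;
  parse_seq(seq, words, chars, arch);
  if (words.n_elem == 0) stop("empty token sequence");
  SeqCache sc;
  mat em = seq_emissions(p, words, chars, sc, 0.0, nullptr);
  return wrap(em);
}

// mean loss + summed-then-scaled gradients over a minibatch
// [[Rcpp::export]]
List cpp_batch_grad(List params, int arch, List batch, double dropout,
                    int seed) {
  Params p = unpack(params, arch);
  Grads g;
  g.init(p);
  std::mt19937 rng((unsigned)seed);
  double loss = 0.0;
  const int B = batch.size();
  const uword K = p.P.n_cols;
  for (int b = 0; b < B; ++b) {
    List seq = batch[b];
    arma::ivec words, tags = as_ivec(seq["tags"]);
    std::vector<arma::ivec> chars;
    parse_seq(seq, words, chars, arch);
    SeqCache sc;
    mat em = seq_emissions(p, words, chars, sc, dropout, &rng);
    mat dEm;
    mat dTr(K + 2, K + 2, arma::fill::zeros);
    loss += crf_nll_grad(em, p.Tr, tags, dEm, dTr);
    g.Tr += dTr;
    seq_backward(p, words, chars, sc, dEm, g);
  }
  double inv = 1.0 / std::max(B, 1);
  loss *= inv;
  List out = List::create(
    _["Ew"] = wrap(mat(g.Ew * inv)), _["Wf"] = wrap(mat(g.Wf * inv)),
    _["bf"] = wrap(mat(g.bf * inv)), _["Wb"] = wrap(mat(g.Wb * inv)),
    _["bb"] = wrap(mat(g.bb * inv)), _["P"] = wrap(mat(g.P * inv)),
    _["pb"] = wrap(mat(g.pb * inv)), _["Tr"] = wrap(mat(g.Tr * inv)));
  if (arch >= 1) out["Ec"] = wrap(mat(g.Ec * inv));
  if (arch == 1) {
    out["Cf"] = wrap(mat(g.Cf * inv)); out["cbf"] = wrap(mat(g.cbf * inv));
    out["Cb"] = wrap(mat(g.Cb * inv)); out["cbb"] = wrap(mat(g.cbb * inv));
  }
  if (arch == 2) {
    out["Fc"] = wrap(mat(g.Fc * inv)); out["fcb"] = wrap(mat(g.fcb * inv));
  }
  return List::create(_["loss"] = loss, _["grads"] = out);
}

// Adam update, in place on params/m/v (all congruent named lists)
// [[Rcpp::export]]
void cpp_adam_step(List params, List grads, List m, List v, int t,
                   double lr, double beta1, double beta2, double eps) {
  CharacterVector nm = grads.names();
  double bc1 = 1.0 - std::pow(beta1, t);
  double bc2 = 1.0 - std::pow(beta2, t);
  for (int k = 0; k < nm.size(); ++k) {
    std::string key = as<std::string>(nm[k]);
    mat P = view(params[key]), G = view(grads[key]);
    mat M = view(m[key]), V = view(v[key]);
    M = beta1 * M + (1.0 - beta1) * G;
    V = beta2 * V + (1.0 - beta2) * (G % G);
    P -= lr * (M / bc1) / (arma::sqrt(V / bc2) + eps);
  }
}

// shadow <- decay * shadow + (1 - decay) * current, in place
// [[Rcpp::export]]
void cpp_ema_update(List shadow, List current, double decay) {
  CharacterVector nm = shadow.names();
  for (int k = 0; k < nm.size(); ++k) {
    std::string key = as<std::string>(nm[k]);
    mat S = view(shadow[key]), C = view(current[key]);
    S = decay * S + (1.0 - decay) * C;
  }
}

// Viterbi path for one sequence (prediction fast path)
// [[Rcpp::export]]
IntegerVector cpp_predict_tags(List params, int arch, List seq) {
  Params p = unpack(params, arch);
  arma::ivec words;
  std::vector<arma::ivec> chars;
  parse_seq(seq, words, chars, arch);
  if (words.n_elem == 0) return IntegerVector(0);
  SeqCache sc;
  mat em = seq_emissions(p, words, chars, sc, 0.0, nullptr);
  NumericMatrix emr = wrap(em);
  NumericMatrix trr = params["Tr"];
  List vit = cpp_viterbi(emr, trr);
  return vit["path"];
}
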