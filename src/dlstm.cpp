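// Peephole Bi-LSTM core: per-instance forward pass and backpropagation
// through time for the three-channel relation classifier. Gate layout in
// the stacked weight matrices is [input, forget, candidate, output].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LstmParams {
  mat Wx; // 4H x D
  mat Wh; // 4H x H
  vec b;  // 4H
  vec pi, pf, po; // diagonal peepholes, H
};

struct LstmCache {
  mat I, F, G, O, C, H; // each m x H
};

LstmParams params_from_list(const Rcpp::List& l) {
  LstmParams p;
  p.Wx = Rcpp::as<mat>(l["Wx"]);
  p.Wh = Rcpp::as<mat>(l["Wh"]);
  p.b = Rcpp::as<vec>(l["b"]);
  p.pi = Rcpp::as<vec>(l["pi"]);
  p.pf = Rcpp::as<vec>(l["pf"]);
  p.po = Rcpp::as<vec>(l["po"]);
  return p;
}

struct LstmGrads {
  mat Wx, Wh;
  vec b, pi, pf, po;
  void init(const LstmParams& p) {
    Wx = zeros<mat>(p.Wx.n_rows, p.Wx.n_cols);
    Wh = zeros<mat>(p.Wh.n_rows, p.Wh.n_cols);
    b = zeros<vec>(p.b.n_elem);
    pi = zeros<vec>(p.pi.n_elem);
    pf = zeros<vec>(p.pf.n_elem);
    po = zeros<vec>(p.po.n_elem);
  }
  Rcpp::List to_list() const {
    return Rcpp::List::create(
        Rcpp::Named("Wx") = Wx, Rcpp::Named("Wh") = Wh, Rcpp::Named("b") = b,
        Rcpp::Named("pi") = pi, Rcpp::Named("pf") = pf, Rcpp::Named("po") = po);
  }
};

inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// Forward pass over X (m x D, rows in run order), zero initial state.
void lstm_forward(const mat& X, const LstmParams& p, LstmCache& cache) {
  const uword m = X.n_rows;
  const uword H = p.Wh.n_cols;
  cache.I.set_size(m, H); cache.F.set_size(m, H); cache.G.set_size(m, H);
  cache.O.set_size(m, H); cache.C.set_size(m, H); cache.H.set_size(m, H);
  vec h = zeros<vec>(H), c = zeros<vec>(H);
  for (uword t = 0; t < m; ++t) {
    vec a = p.Wx * X.row(t).t() + p.Wh * h + p.b;
    vec i = sigmoid(a.subvec(0, H - 1) + p.pi % c);
    vec f = sigmoid(a.subvec(H, 2 * H - 1) + p.pf % c);
    vec g = tanh(a.subvec(2 * H, 3 * H - 1));
    vec c2 = f % c + i % g;
    vec o = sigmoid(a.subvec(3 * H, 4 * H - 1) + p.po % c2);
    h = o % tanh(c2);
    c = c2;
    cache.I.row(t) = i.t(); cache.F.row(t) = f.t(); cache.G.row(t) = g.t();
    cache.O.row(t) = o.t(); cache.C.row(t) = c2.t(); cache.H.row(t) = h.t();
  }
}

// BPTT. dH is the upstream gradient on the hidden sequence (m x H).
// Parameter gradients accumulate into g; returns dX (m x D).
mat lstm_backward(const mat& X, const LstmParams& p, const LstmCache& cache,
                  const mat& dH, LstmGrads& g) {
  const uword m = X.n_rows;
  const uword H = p.Wh.n_cols;
  mat dX = zeros<mat>(m, X.n_cols);
  vec dh_rec = zeros<vec>(H), dc_rec = zeros<vec>(H);
  for (uword t = m; t-- > 0;) {
    vec i = cache.I.row(t).t(), f = cache.F.row(t).t(), gg = cache.G.row(t).t();
    vec o = cache.O.row(t).t(), c = cache.C.row(t).t();
    vec cprev = (t > 0) ? vec(cache.C.row(t - 1).t()) : zeros<vec>(H);
    vec hprev = (t > 0) ? vec(cache.H.row(t - 1).t()) : zeros<vec>(H);
    vec tc = tanh(c);
    vec dh = dH.row(t).t() + dh_rec;
    vec do_ = dh % tc;
    vec dao = do_ % o % (1.0 - o);
    vec dc = dh % o % (1.0 - tc % tc) + dc_rec + dao % p.po;
    vec di = dc % gg;
    vec dai = di % i % (1.0 - i);
    vec df = dc % cprev;
    vec daf = df % f % (1.0 - f);
    vec dg = dc % i;
    vec dag = dg % (1.0 - gg % gg);
    dc_rec = dc % f + dai % p.pi + daf % p.pf;
    vec da = join_cols(join_cols(dai, daf), join_cols(dag, dao));
    dh_rec = p.Wh.t() * da;
    dX.row(t) = (p.Wx.t() * da).t();
    g.Wx += da * X.row(t);
    g.Wh += da * hprev.t();
    g.b += da;
    g.pi += dai % cprev;
    g.pf += daf % cprev;
    g.po += dao % c;
  }
  return dX;
}

// One bidirectional channel: forward over X, backward over reversed X with
// outputs re-reversed so both align by token, averaged, then max-pooled.
struct ChannelRun {
  LstmCache fwd, bwd; // bwd caches are in reversed-time order
  mat z;              // m x H averaged hidden states, token-aligned
  vec pooled;         // H
  uvec argmax;        // H, row index of the max per dimension
};

void run_channel_cpp(const mat& X, const LstmParams& pf, const LstmParams& pb,
                     ChannelRun& run) {
  lstm_forward(X, pf, run.fwd);
  lstm_forward(flipud(X), pb, run.bwd);
  mat hb_aligned = flipud(run.bwd.H);
  run.z = (run.fwd.H + hb_aligned) / 2.0;
  const uword H = run.z.n_cols;
  run.pooled.set_size(H);
  run.argmax.set_size(H);
  for (uword j = 0; j < H; ++j) {
    uword idx;
    run.pooled(j) = run.z.col(j).max(idx);
    run.argmax(j) = idx;
  }
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_channel_forward(const arma::mat& X, const Rcpp::List& fwd,
                               const Rcpp::List& bwd) {
  LstmParams pf = params_from_list(fwd), pb = params_from_list(bwd);
  ChannelRun run;
  run_channel_cpp(X, pf, pb, run);
  return Rcpp::List::create(
      Rcpp::Named("h_f") = run.fwd.H,
      Rcpp::Named("h_b") = mat(flipud(run.bwd.H)),
      Rcpp::Named("z") = run.z,
      Rcpp::Named("pooled") = run.pooled,
      Rcpp::Named("argmax") = Rcpp::IntegerVector(
          Rcpp::wrap(arma::conv_to<std::vector<int>>::from(run.argmax + 1))));
}

// Batched forward (and optionally backward) pass over candidate instances.
// `batch` holds one element per instance: a list over channels, each with
// 1-based `ids` into the embedding matrix and an m x 20 `codes` matrix of
// encoded distance pairs. Gradients are summed over the batch; the caller
// normalizes. Dropout masks (already scaled by 1/keep) apply to the tanh
// output before the softmax projection.
// [[Rcpp::export]]
Rcpp::List cpp_batch(const Rcpp::List& batch, const arma::mat& emb,
                     const Rcpp::List& channel_params, const arma::mat& Ws,
                     const arma::vec& bs, const Rcpp::IntegerVector& labels,
                     Rcpp::Nullable<Rcpp::NumericMatrix> masks,
                     bool compute_grad) {
  const int B = batch.size();
  const int C = channel_params.size();
  const uword k = Ws.n_rows;
  const uword dw = emb.n_cols;

  std::vector<LstmParams> pf(C), pb(C);
  for (int c = 0; c < C; ++c) {
    Rcpp::List chp = channel_params[c];
    pf[c] = params_from_list(Rcpp::List(chp["fwd"]));
    pb[c] = params_from_list(Rcpp::List(chp["bwd"]));
  }
  const uword H = pf[0].Wh.n_cols;
  if (Ws.n_cols != (uword)C * H)
    Rcpp::stop("softmax matrix has %d columns, expected %d", (int)Ws.n_cols,
               (int)(C * H));

  mat mask_mat;
  bool has_mask = masks.isNotNull();
  if (has_mask) mask_mat = Rcpp::as<mat>(Rcpp::NumericMatrix(masks));

  std::vector<LstmGrads> gf(C), gb(C);
  mat gEmb, gWs;
  vec gbs;
  if (compute_grad) {
    for (int c = 0; c < C; ++c) {
      gf[c].init(pf[c]);
      gb[c].init(pb[c]);
    }
    gEmb = zeros<mat>(emb.n_rows, emb.n_cols);
    gWs = zeros<mat>(Ws.n_rows, Ws.n_cols);
    gbs = zeros<vec>(bs.n_elem);
  }

  mat probs(B, k);
  double loss = 0.0;

  for (int ib = 0; ib < B; ++ib) {
    Rcpp::List inst = batch[ib];
    std::vector<mat> Xs(C);
    std::vector<uvec> ids(C);
    std::vector<ChannelRun> runs(C);
    vec Z(C * H);
    for (int c = 0; c < C; ++c) {
      Rcpp::List ch = inst[c];
      Rcpp::IntegerVector idv = ch["ids"];
      mat codes = Rcpp::as<mat>(ch["codes"]);
      const uword m = idv.size();
      ids[c].set_size(m);
      for (uword t = 0; t < m; ++t) ids[c](t) = (uword)(idv[t] - 1);
      mat X(m, dw + codes.n_cols);
      X.cols(0, dw - 1) = emb.rows(ids[c]);
      X.cols(dw, dw + codes.n_cols - 1) = codes;
      Xs[c] = X;
      run_channel_cpp(X, pf[c], pb[c], runs[c]);
      Z.subvec(c * H, (c + 1) * H - 1) = runs[c].pooled;
    }
    vec hs = tanh(Z);
    vec hs_m = hs;
    if (has_mask) hs_m = hs % mask_mat.row(ib).t();
    vec logits = Ws * hs_m + bs;
    logits -= logits.max();
    vec ex = exp(logits);
    vec p = ex / accu(ex);
    probs.row(ib) = p.t();

    int y = labels.size() > ib ? labels[ib] : NA_INTEGER;
    bool scored = (y != NA_INTEGER && y >= 1);
    if (scored) loss += -std::log(std::max(p(y - 1), 1e-12));
    if (!compute_grad || !scored) continue;

    vec dlogits = p;
    dlogits(y - 1) -= 1.0;
    gWs += dlogits * hs_m.t();
    gbs += dlogits;
    vec dhs_m = Ws.t() * dlogits;
    vec dhs = has_mask ? vec(dhs_m % mask_mat.row(ib).t()) : dhs_m;
    vec dZ = dhs % (1.0 - hs % hs);

    for (int c = 0; c < C; ++c) {
      vec dpooled = dZ.subvec(c * H, (c + 1) * H - 1);
      const uword m = Xs[c].n_rows;
      mat dz = zeros<mat>(m, H);
      for (uword j = 0; j < H; ++j) dz(runs[c].argmax(j), j) = dpooled(j);
      mat dHf = dz / 2.0;
      mat dHb = flipud(dz) / 2.0;
      mat dXf = lstm_backward(Xs[c], pf[c], runs[c].fwd, dHf, gf[c]);
      mat dXb = lstm_backward(flipud(Xs[c]), pb[c], runs[c].bwd, dHb, gb[c]);
      mat dX = dXf + flipud(dXb);
      for (uword t = 0; t < m; ++t)
        gEmb.row(ids[c](t)) += dX.row(t).cols(0, dw - 1);
    }
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loss") = loss,
                                      Rcpp::Named("probs") = probs);
  if (compute_grad) {
    Rcpp::List chg(C);
    for (int c = 0; c < C; ++c) {
      chg[c] = Rcpp::List::create(Rcpp::Named("fwd") = gf[c].to_list(),
                                  Rcpp::Named("bwd") = gb[c].to_list());
    }
    out["grads"] = Rcpp::List::create(
        Rcpp::Named("emb") = gEmb, Rcpp::Named("channels") = chg,
        Rcpp::Named("Ws") = gWs, Rcpp::Named("bs") = gbs);
  }
  return out;
}
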