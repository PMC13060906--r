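// Single-hidden-layer GRU for frame-wise motif classification.
// Input -> GRU(H) -> per-frame linear -> softmax, trained with a
// class-weighted cross-entropy loss by truncated BPTT over fixed-length
// chunks (hidden state reset per chunk), Adam updates. Everything is
// deterministic given the initial weights and the batch order supplied
// from R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Params {
  mat Wx;     // F x 3H (gate order: r, z, n)
  mat Wh;     // H x 3H
  rowvec b;   // 3H
  mat Wo;     // H x C
  rowvec bo;  // C
};

Params from_list(const Rcpp::List& p) {
  Params out;
  out.Wx = Rcpp::as<mat>(p["Wx"]);
  out.Wh = Rcpp::as<mat>(p["Wh"]);
  out.b = Rcpp::as<rowvec>(p["b"]);
  out.Wo = Rcpp::as<mat>(p["Wo"]);
  out.bo = Rcpp::as<rowvec>(p["bo"]);
  return out;
}

Rcpp::List to_list(const Params& p) {
  return Rcpp::List::create(
      Rcpp::Named("Wx") = p.Wx, Rcpp::Named("Wh") = p.Wh,
      Rcpp::Named("b") = p.b, Rcpp::Named("Wo") = p.Wo,
      Rcpp::Named("bo") = p.bo);
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// row-wise softmax in place
inline void softmax_rows(mat& x) {
  x.each_col() -= max(x, 1);
  x = exp(x);
  x.each_col() /= sum(x, 1);
}

struct Grads {
  mat dWx, dWh, dWo;
  rowvec db, dbo;
  double loss = 0.0, wsum = 0.0;
  size_t ncorrect = 0, nlab = 0;
  void init(const Params& p) {
    dWx = zeros(size(p.Wx)); dWh = zeros(size(p.Wh));
    dWo = zeros(size(p.Wo));
    db = zeros<rowvec>(p.b.n_elem); dbo = zeros<rowvec>(p.bo.n_elem);
  }
};

// forward (+ optional backward) over a batch of chunks
void run_batch(const Params& p, const cube& X, const imat& Y,
               const uvec& idx, const vec& cw, bool backward, Grads& g) {
  const uword T = X.n_rows, F = X.n_cols, B = idx.n_elem;
  const uword H = p.Wh.n_rows, C = p.Wo.n_cols;

  cube XB(B, F, T), Hs(B, H, T), Rs, Zs, Ns, GHNs;
  if (backward) {
    Rs.set_size(B, H, T); Zs.set_size(B, H, T);
    Ns.set_size(B, H, T); GHNs.set_size(B, H, T);
  }
  for (uword b = 0; b < B; ++b) {
    const mat& sl = X.slice(idx(b));
    for (uword t = 0; t < T; ++t) XB.slice(t).row(b) = sl.row(t);
  }

  mat h = zeros(B, H);
  for (uword t = 0; t < T; ++t) {
    mat G = XB.slice(t) * p.Wx;
    G.each_row() += p.b;
    mat GH = h * p.Wh;
    mat r = sigmoid(G.cols(0, H - 1) + GH.cols(0, H - 1));
    mat z = sigmoid(G.cols(H, 2 * H - 1) + GH.cols(H, 2 * H - 1));
    mat ghn = GH.cols(2 * H, 3 * H - 1);
    mat n = tanh(G.cols(2 * H, 3 * H - 1) + r % ghn);
    mat hn = (1.0 - z) % n + z % h;
    if (backward) {
      Rs.slice(t) = r; Zs.slice(t) = z; Ns.slice(t) = n; GHNs.slice(t) = ghn;
    }
    Hs.slice(t) = hn;
    h = hn;
  }

  // loss / accuracy over all frames (and, if backward, weight sum first so
  // gradients are normalized by the batch's total frame weight)
  double wsum = 0.0;
  for (uword b = 0; b < B; ++b)
    for (uword t = 0; t < T; ++t) {
      int y = Y(t, idx(b));
      if (y >= 0) wsum += cw(y);
    }
  if (wsum <= 0) return;

  mat dh_next = zeros(B, H);
  for (uword tt = 0; tt < T; ++tt) {
    // forward order for loss only; backward needs reverse order
    if (backward) break;
    mat logits = Hs.slice(tt) * p.Wo;
    logits.each_row() += p.bo;
    softmax_rows(logits);
    for (uword b = 0; b < B; ++b) {
      int y = Y(tt, idx(b));
      if (y < 0) continue;
      g.loss += -cw(y) * std::log(std::max(logits(b, (uword)y), 1e-12));
      g.nlab += 1;
      if (logits.row(b).index_max() == (uword)y) g.ncorrect += 1;
    }
  }

  if (!backward) { g.wsum += wsum; return; }

  for (uword ti = T; ti-- > 0;) {
    mat logits = Hs.slice(ti) * p.Wo;
    logits.each_row() += p.bo;
    softmax_rows(logits);
    mat dlogit = logits;  // becomes (p - onehot) * w / wsum
    for (uword b = 0; b < B; ++b) {
      int y = Y(ti, idx(b));
      if (y < 0) { dlogit.row(b).zeros(); continue; }
      g.loss += -cw(y) * std::log(std::max(logits(b, (uword)y), 1e-12));
      g.nlab += 1;
      if (logits.row(b).index_max() == (uword)y) g.ncorrect += 1;
      dlogit(b, (uword)y) -= 1.0;
      dlogit.row(b) *= cw(y) / wsum;
    }
    g.dWo += Hs.slice(ti).t() * dlogit;
    g.dbo += sum(dlogit, 0);
    mat dh = dlogit * p.Wo.t() + dh_next;

    mat h_prev = (ti == 0) ? zeros(B, H) : Hs.slice(ti - 1);
    const mat& r = Rs.slice(ti);
    const mat& z = Zs.slice(ti);
    const mat& n = Ns.slice(ti);
    const mat& ghn = GHNs.slice(ti);

    mat dz = dh % (h_prev - n);
    mat dn = dh % (1.0 - z);
    mat dan = dn % (1.0 - n % n);
    mat dr = dan % ghn;
    mat dar = dr % r % (1.0 - r);
    mat daz = dz % z % (1.0 - z);

    mat dG(B, 3 * H), dGH(B, 3 * H);
    dG.cols(0, H - 1) = dar;
    dG.cols(H, 2 * H - 1) = daz;
    dG.cols(2 * H, 3 * H - 1) = dan;
    dGH.cols(0, H - 1) = dar;
    dGH.cols(H, 2 * H - 1) = daz;
    dGH.cols(2 * H, 3 * H - 1) = dan % r;

    g.dWx += XB.slice(ti).t() * dG;
    g.db += sum(dG, 0);
    g.dWh += h_prev.t() * dGH;
    dh_next = dh % z + dGH * p.Wh.t();
  }
  g.wsum += wsum;
}

struct AdamState {
  mat mWx, vWx, mWh, vWh, mWo, vWo;
  rowvec mb, vb, mbo, vbo;
  double t = 0;
  void init(const Params& p) {
    mWx = zeros(size(p.Wx)); vWx = zeros(size(p.Wx));
    mWh = zeros(size(p.Wh)); vWh = zeros(size(p.Wh));
    mWo = zeros(size(p.Wo)); vWo = zeros(size(p.Wo));
    mb = zeros<rowvec>(p.b.n_elem); vb = zeros<rowvec>(p.b.n_elem);
    mbo = zeros<rowvec>(p.bo.n_elem); vbo = zeros<rowvec>(p.bo.n_elem);
  }
  template <class M>
  void step_one(M& w, const M& gr, M& m, M& v, double lr) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * gr;
    v = b2 * v + (1 - b2) * (gr % gr);
    M mhat = m / (1 - std::pow(b1, t));
    M vhat = v / (1 - std::pow(b2, t));
    w -= lr * mhat / (sqrt(vhat) + eps);
  }
  void step(Params& p, const Grads& g, double lr) {
    t += 1;
    step_one(p.Wx, g.dWx, mWx, vWx, lr);
    step_one(p.Wh, g.dWh, mWh, vWh, lr);
    step_one(p.b, g.db, mb, vb, lr);
    step_one(p.Wo, g.dWo, mWo, vWo, lr);
    step_one(p.bo, g.dbo, mbo, vbo, lr);
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List gru_loss_grad_cpp(Rcpp::List params, arma::cube X, arma::imat Y,
                             arma::vec class_w, bool backward = true) {
  Params p = from_list(params);
  Grads g; g.init(p);
  uvec idx = regspace<uvec>(0, X.n_slices - 1);
  run_batch(p, X, Y, idx, class_w, backward, g);
  Rcpp::RObject grads = R_NilValue;
  if (backward) {
    grads = Rcpp::List::create(Rcpp::Named("Wx") = g.dWx,
                               Rcpp::Named("Wh") = g.dWh,
                               Rcpp::Named("b") = g.db,
                               Rcpp::Named("Wo") = g.dWo,
                               Rcpp::Named("bo") = g.dbo);
  }
  return Rcpp::List::create(
      Rcpp::Named("loss") = g.nlab ? g.loss / g.wsum : NA_REAL,
      Rcpp::Named("accuracy") = g.nlab ? (double)g.ncorrect / g.nlab : NA_REAL,
      Rcpp::Named("grads") = grads);
}

// [[Rcpp::export]]
Rcpp::List gru_train_cpp(Rcpp::List params, arma::cube X, arma::imat Y,
                         arma::uvec train_idx, arma::uvec val_idx,
                         arma::imat order, arma::vec class_w,
                         int batch_size, double lr, int patience) {
  Params p = from_list(params);
  AdamState adam; adam.init(p);
  const int epochs = order.n_rows;
  const uword ntr = train_idx.n_elem;

  std::vector<double> tr_loss, va_loss, va_acc;
  Params best = p;
  double best_val = datum::inf;
  int best_epoch = -1, bad = 0;

  for (int e = 0; e < epochs; ++e) {
    double eloss = 0.0; size_t enlab = 0; double ewsum = 0.0;
    for (uword s = 0; s < ntr; s += batch_size) {
      uword hi = std::min<uword>(s + batch_size, ntr) - 1;
      uvec pos = conv_to<uvec>::from(order.row(e).subvec(s, hi).t());
      uvec idx = train_idx(pos);
      Grads g; g.init(p);
      run_batch(p, X, Y, idx, class_w, true, g);
      if (g.wsum <= 0) continue;
      eloss += g.loss; enlab += g.nlab; ewsum += g.wsum;
      adam.step(p, g, lr);
      Rcpp::checkUserInterrupt();
    }
    tr_loss.push_back(enlab ? eloss / ewsum : NA_REAL);

    double vloss = NA_REAL, vacc = NA_REAL;
    if (val_idx.n_elem > 0) {
      Grads g; g.init(p);
      for (uword s = 0; s < val_idx.n_elem; s += batch_size) {
        uword hi = std::min<uword>(s + batch_size, val_idx.n_elem) - 1;
        uvec idx = val_idx.subvec(s, hi);
        run_batch(p, X, Y, idx, class_w, false, g);
      }
      vloss = g.nlab ? g.loss / g.wsum : NA_REAL;
      vacc = g.nlab ? (double)g.ncorrect / g.nlab : NA_REAL;
      if (std::isfinite(vloss) && vloss < best_val - 1e-6) {
        best_val = vloss; best = p; best_epoch = e; bad = 0;
      } else {
        bad += 1;
      }
    }
    va_loss.push_back(vloss); va_acc.push_back(vacc);
    if (val_idx.n_elem > 0 && bad >= patience) break;
  }
  if (val_idx.n_elem == 0) { best = p; best_epoch = epochs - 1; }

  return Rcpp::List::create(
      Rcpp::Named("params") = to_list(best),
      Rcpp::Named("final_params") = to_list(p),
      Rcpp::Named("train_loss") = tr_loss,
      Rcpp::Named("val_loss") = va_loss,
      Rcpp::Named("val_accuracy") = va_acc,
      Rcpp::Named("best_epoch") = best_epoch + 1);
}

// [[Rcpp::export]]
arma::cube gru_predict_cpp(Rcpp::List params, arma::cube X, int batch_size = 32) {
  Params p = from_list(params);
  const uword T = X.n_rows, F = X.n_cols, N = X.n_slices;
  const uword H = p.Wh.n_rows, C = p.Wo.n_cols;
  cube out(T, C, N);
  for (uword s0 = 0; s0 < N; s0 += batch_size) {
    const uword B = std::min<uword>(batch_size, N - s0);
    cube XB(B, F, T);
    for (uword b = 0; b < B; ++b) {
      const mat& sl = X.slice(s0 + b);
      for (uword t = 0; t < T; ++t) XB.slice(t).row(b) = sl.row(t);
    }
    mat h = zeros(B, H);
    for (uword t = 0; t < T; ++t) {
      mat G = XB.slice(t) * p.Wx;
      G.each_row() += p.b;
      mat GH = h * p.Wh;
      mat r = sigmoid(G.cols(0, H - 1) + GH.cols(0, H - 1));
      mat z = sigmoid(G.cols(H, 2 * H - 1) + GH.cols(H, 2 * H - 1));
      mat n = tanh(G.cols(2 * H, 3 * H - 1) + r % GH.cols(2 * H, 3 * H - 1));
      h = (1.0 - z) % n + z % h;
      mat logits = h * p.Wo;
      logits.each_row() += p.bo;
      softmax_rows(logits);
      for (uword b = 0; b < B; ++b) out.slice(s0 + b).row(t) = logits.row(b);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
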