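// Small feed-forward regression network trained with momentum SGD.
// One or two ReLU hidden layers, MSE loss, constant or inverse-scaling
// learning rate. Deterministic given `seed` (own mt19937; R's RNG is not
// touched). Returns held-out predictions plus a divergence flag so the
// random-search driver can discard exploding configurations. Training
// stops early when the epoch MSE plateaus (relative improvement < tol
// over `patience` consecutive epochs).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;

static mat glorot(int in, int out, std::mt19937 &rng) {
  double lim = std::sqrt(6.0 / (in + out));
  std::uniform_real_distribution<double> u(-lim, lim);
  mat w(in, out);
  for (uword j = 0; j < w.n_cols; ++j)
    for (uword i = 0; i < w.n_rows; ++i) w(i, j) = u(rng);
  return w;
}

// [[Rcpp::export]]
Rcpp::List mlp_train_predict(const arma::mat &Xtr, const arma::vec &ytr,
                             const arma::mat &Xte,
                             const arma::ivec &hidden,
                             double lr, int lr_schedule, double power_t,
                             double momentum, int batch, int epochs,
                             int seed, double tol = 1e-4, int patience = 3) {
  const int n = Xtr.n_rows, d = Xtr.n_cols;
  const int L = hidden.n_elem;  // 1 or 2 hidden layers
  std::mt19937 rng(static_cast<unsigned>(seed));
  if (batch > n) batch = n;

  std::vector<mat> W(L + 1), vW(L + 1);
  std::vector<rowvec> b(L + 1), vb(L + 1);
  int prev = d;
  for (int l = 0; l <= L; ++l) {
    int out = (l < L) ? hidden[l] : 1;
    W[l] = glorot(prev, out, rng);
    b[l] = rowvec(out, fill::zeros);
    vW[l] = mat(size(W[l]), fill::zeros);
    vb[l] = rowvec(out, fill::zeros);
    prev = out;
  }

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  bool diverged = false;
  long t_step = 0;
  double last_loss = NA_REAL, best_loss = datum::inf;
  int stall = 0, epochs_run = 0;
  mat A(batch, d);
  vec yb(batch);
  std::vector<mat> act(L);

  for (int ep = 0; ep < epochs && !diverged; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    for (int start = 0; start < n; start += batch) {
      int bs = std::min(batch, n - start);
      if (bs != (int)A.n_rows) { A.set_size(bs, d); yb.set_size(bs); }
      for (int i = 0; i < bs; ++i) {
        A.row(i) = Xtr.row(idx[start + i]);
        yb[i] = ytr[idx[start + i]];
      }

      // forward
      for (int l = 0; l < L; ++l) {
        act[l] = ((l == 0) ? A : act[l - 1]) * W[l];
        act[l].each_row() += b[l];
        act[l].for_each([](double &v) { if (v < 0) v = 0; });
      }
      const mat &top = (L > 0) ? act[L - 1] : A;
      vec pred = top * W[L] + b[L](0);
      vec err = pred - yb;
      ep_loss += dot(err, err);

      // backward (MSE/2 gradient; the factor is absorbed by lr)
      ++t_step;
      double lr_t = lr_schedule == 1 ? lr / std::pow((double)t_step, power_t)
                                     : lr;
      vec delta = err / bs;
      mat gW = top.t() * delta;
      rowvec gb(1);
      gb(0) = accu(delta);
      mat dprev = delta * W[L].t();  // bs x h_L (empty product if L == 0)
      vW[L] = momentum * vW[L] - lr_t * gW;
      vb[L] = momentum * vb[L] - lr_t * gb;
      W[L] += vW[L];
      b[L] += vb[L];
      for (int l = L - 1; l >= 0; --l) {
        dprev %= conv_to<mat>::from(act[l] > 0);
        const mat &Ain = (l > 0) ? act[l - 1] : A;
        mat gWl = Ain.t() * dprev;
        rowvec gbl = sum(dprev, 0);
        mat dnext;
        if (l > 0) dnext = dprev * W[l].t();
        vW[l] = momentum * vW[l] - lr_t * gWl;
        vb[l] = momentum * vb[l] - lr_t * gbl;
        W[l] += vW[l];
        b[l] += vb[l];
        if (l > 0) dprev = std::move(dnext);
      }
      if (!W[L].is_finite()) { diverged = true; break; }
    }
    last_loss = ep_loss / n;
    epochs_run = ep + 1;
    if (!std::isfinite(last_loss)) { diverged = true; break; }
    if (last_loss < best_loss * (1.0 - tol)) {
      best_loss = last_loss;
      stall = 0;
    } else if (++stall >= patience) break;
  }

  vec pred_te(Xte.n_rows, fill::value(NA_REAL));
  if (!diverged) {
    mat H = Xte;
    for (int l = 0; l < L; ++l) {
      H = H * W[l];
      H.each_row() += b[l];
      H.for_each([](double &v) { if (v < 0) v = 0; });
    }
    pred_te = H * W[L] + b[L](0);
    if (!pred_te.is_finite()) diverged = true;
  }

  return Rcpp::List::create(Rcpp::Named("pred") = pred_te,
                            Rcpp::Named("train_mse") = last_loss,
                            Rcpp::Named("epochs_run") = epochs_run,
                            Rcpp::Named("diverged") = diverged);
}
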