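// Minibatch Adam training for the dense feed-forward networks.
// Only the flop-heavy inner loop lives here; initialization, batch order,
// the learning-rate schedule and early stopping stay on the R side, so all
// randomness is controlled by R's RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// activation codes: 0 linear, 1 relu, 2 sigmoid
// loss codes: 0 mse, 1 macro F1, 2 binary cross-entropy

static void apply_activation(arma::mat& Z, int code) {
  if (code == 1) {
    Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
  } else if (code == 2) {
    Z.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
  }
}

// [[Rcpp::export(name = ".cpp_forward")]]
arma::mat cpp_forward(const List& W, const List& b, const IntegerVector& acts,
                      const arma::mat& X) {
  arma::mat A = X;
  for (int l = 0; l < W.size(); ++l) {
    arma::mat Wl = as<arma::mat>(W[l]);
    arma::rowvec bl = as<arma::rowvec>(b[l]);
    A = A * Wl;
    A.each_row() += bl;
    apply_activation(A, acts[l]);
  }
  return A;
}

static double loss_and_grad(int loss_code, const arma::mat& P,
                            const arma::mat& Y, arma::mat& dA) {
  const double n_el = static_cast<double>(P.n_elem);
  if (loss_code == 0) {  // mean squared error over all elements
    arma::mat diff = P - Y;
    dA = (2.0 / n_el) * diff;
    return arma::accu(arma::square(diff)) / n_el;
  }
  if (loss_code == 2) {  // mean binary cross-entropy
    arma::mat pc = arma::clamp(P, 1e-12, 1.0 - 1e-12);
    // the 1/(p(1-p)) factor cancels against the sigmoid derivative in the
    // backward pass, leaving the stable (p - y) logit gradient; the clamp
    // only caps the (vanishing) contribution of fully saturated entries
    arma::mat denom = arma::clamp(P % (1.0 - P), 1e-12, arma::datum::inf);
    dA = (P - Y) / denom / n_el;
    return -arma::accu(Y % arma::log(pc) + (1.0 - Y) % arma::log(1.0 - pc)) /
           n_el;
  }
  // macro F1 with soft counts: F1_c = 2 TP / (2 TP + FP + FN)
  const int C = P.n_cols;
  arma::rowvec tp = arma::sum(P % Y, 0);
  arma::rowvec fp = arma::sum(P % (1.0 - Y), 0);
  arma::rowvec fn = arma::sum((1.0 - P) % Y, 0);
  arma::rowvec denom = 2.0 * tp + fp + fn;
  arma::rowvec f1(C, arma::fill::zeros);
  arma::rowvec scale_y(C, arma::fill::zeros);
  arma::rowvec scale_c(C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    bool degenerate = (tp[c] + fp[c] == 0.0) || (tp[c] + fn[c] == 0.0);
    if (denom[c] > 0.0 && !degenerate) {
      f1[c] = 2.0 * tp[c] / denom[c];
      scale_y[c] = 2.0 / denom[c];
      scale_c[c] = 2.0 * tp[c] / (denom[c] * denom[c]);
    }
  }
  dA = Y;
  dA.each_row() %= scale_y;
  dA.each_row() -= scale_c;
  dA *= -1.0 / C;
  return 1.0 - arma::mean(f1);
}

// cache-friendly row gather: column-wise traversal keeps the source column
// resident while rows are picked at random
static void gather_rows(const arma::mat& X, const int* idx, int nb,
                        arma::mat& out) {
  out.set_size(nb, X.n_cols);
  for (arma::uword j = 0; j < X.n_cols; ++j) {
    const double* src = X.colptr(j);
    double* dst = out.colptr(j);
    for (int i = 0; i < nb; ++i) dst[i] = src[idx[i]];
  }
}

// Full training loop: minibatch Adam with plateau learning-rate decay and
// early stopping. `orders` holds one pre-shuffled 1-based cell order per
// column (one per epoch), so every source of randomness stays in R.
// Improvement = strictly lower validation loss; after `patience_lr`
// non-improving epochs lr *= lr_factor (floored), counter resets; after
// `patience_stop` non-improving epochs training stops. Best-validation
// weights are returned.
// [[Rcpp::export(name = ".cpp_train")]]
List cpp_train(List W_in, List b_in, const IntegerVector& acts, int loss_code,
               const arma::mat& X, const arma::mat& Y, bool y_is_x,
               const arma::mat& valX, const arma::mat& valY,
               const IntegerMatrix& orders, int batch_size, double lr0,
               int patience_lr, int patience_stop, double lr_factor,
               double lr_floor, double beta1, double beta2, double eps,
               double weight_decay) {
  const int L = W_in.size();
  std::vector<arma::mat> W(L), mW(L), vW(L), bestW(L);
  std::vector<arma::rowvec> b(L), mb(L), vb(L), bestb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(W_in[l]);
    b[l] = as<arma::rowvec>(b_in[l]);
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
    bestW[l] = W[l];
    bestb[l] = b[l];
  }
  const int n = X.n_rows;
  const int max_epochs = orders.ncol();
  const int n_batches = (n + batch_size - 1) / batch_size;
  long t = 0;
  double lr = lr0, best_loss = R_PosInf;
  int since_improve = 0, lr_wait = 0, epochs_run = 0;
  std::vector<double> h_lr, h_train, h_val;
  std::vector<arma::mat> A(L + 1), Z(L);
  std::vector<int> idx(batch_size);
  arma::mat Xb, Yb, dA;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double loss_sum = 0.0;
    for (int k = 0; k < n_batches; ++k) {
      const int start = k * batch_size;
      const int stop = std::min(n, start + batch_size);
      const int nb = stop - start;
      for (int i = 0; i < nb; ++i) idx[i] = orders(start + i, epoch) - 1;
      gather_rows(X, idx.data(), nb, Xb);
      if (!y_is_x) gather_rows(Y, idx.data(), nb, Yb);
      const arma::mat& Ybatch = y_is_x ? Xb : Yb;

      A[0] = Xb;
      for (int l = 0; l < L; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += b[l];
        A[l + 1] = Z[l];
        apply_activation(A[l + 1], acts[l]);
      }
      double batch_loss = loss_and_grad(loss_code, A[L], Ybatch, dA);
      if (!std::isfinite(batch_loss)) {
        Rcpp::stop("non-finite training loss at epoch %d (lr = %g)",
                   epoch + 1, lr);
      }
      loss_sum += batch_loss;

      ++t;
      const double c1 = 1.0 - std::pow(beta1, static_cast<double>(t));
      const double c2 = 1.0 - std::pow(beta2, static_cast<double>(t));
      for (int l = L - 1; l >= 0; --l) {
        arma::mat dZ = dA;
        if (acts[l] == 1) {
          const double* z = Z[l].memptr();
          double* dz = dZ.memptr();
          for (arma::uword e = 0; e < dZ.n_elem; ++e) {
            if (z[e] <= 0.0) dz[e] = 0.0;
          }
        } else if (acts[l] == 2) {
          dZ %= A[l + 1] % (1.0 - A[l + 1]);
        }
        arma::mat gW = A[l].t() * dZ;
        arma::rowvec gb = arma::sum(dZ, 0);
        if (l > 0) dA = dZ * W[l].t();
        mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1.0 - beta2) * arma::square(gW);
        W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
        mb[l] = beta1 * mb[l] + (1.0 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1.0 - beta2) * arma::square(gb);
        b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
        if (weight_decay > 0.0) W[l] -= (lr * weight_decay) * W[l];
      }
    }

    // validation monitoring + schedule
    arma::mat Pv = valX;
    for (int l = 0; l < L; ++l) {
      Pv = Pv * W[l];
      Pv.each_row() += b[l];
      apply_activation(Pv, acts[l]);
    }
    arma::mat dummy;
    double val_loss = loss_and_grad(loss_code, Pv, valY, dummy);
    if (!std::isfinite(val_loss)) {
      Rcpp::stop("non-finite validation loss at epoch %d", epoch + 1);
    }
    epochs_run = epoch + 1;
    bool improved = val_loss < best_loss;
    if (improved) {
      best_loss = val_loss;
      since_improve = 0;
      lr_wait = 0;
      for (int l = 0; l < L; ++l) { bestW[l] = W[l]; bestb[l] = b[l]; }
    } else {
      ++since_improve;
      ++lr_wait;
      if (since_improve >= patience_stop) {
        h_lr.push_back(lr);
        h_train.push_back(loss_sum / n_batches);
        h_val.push_back(val_loss);
        break;
      }
      if (lr_wait >= patience_lr) {
        lr = std::max(lr * lr_factor, lr_floor);
        lr_wait = 0;
      }
    }
    h_lr.push_back(lr);
    h_train.push_back(loss_sum / n_batches);
    h_val.push_back(val_loss);
  }

  List W_out(L), b_out(L);
  for (int l = 0; l < L; ++l) {
    W_out[l] = bestW[l];
    b_out[l] = bestb[l];
  }
  return List::create(
      _["W"] = W_out, _["b"] = b_out, _["best_val_loss"] = best_loss,
      _["epochs_run"] = epochs_run, _["final_lr"] = lr,
      _["lr"] = h_lr, _["train_loss"] = h_train, _["val_loss"] = h_val);
}

// One full epoch of minibatch Adam. `order` is the 1-based shuffled cell
// order from R; weights, biases and optimizer state are updated in place on
// copies and returned.
// [[Rcpp::export(name = ".cpp_epoch")]]
List cpp_epoch(List W_in, List b_in, const IntegerVector& acts, int loss_code,
               const arma::mat& X, const arma::mat& Y,
               const IntegerVector& order, int batch_size, double lr,
               List opt_in, double beta1, double beta2, double eps) {
  const int L = W_in.size();
  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::rowvec> b(L), mb(L), vb(L);
  List mW_in = opt_in["mW"], vW_in = opt_in["vW"],
       mb_in = opt_in["mb"], vb_in = opt_in["vb"];
  long t = as<long>(opt_in["t"]);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(W_in[l]);
    b[l] = as<arma::rowvec>(b_in[l]);
    mW[l] = as<arma::mat>(mW_in[l]);
    vW[l] = as<arma::mat>(vW_in[l]);
    mb[l] = as<arma::rowvec>(mb_in[l]);
    vb[l] = as<arma::rowvec>(vb_in[l]);
  }
  const int n = X.n_rows;
  const int n_batches = (n + batch_size - 1) / batch_size;
  arma::vec batch_losses(n_batches);
  std::vector<arma::mat> A(L + 1), Z(L);

  for (int k = 0; k < n_batches; ++k) {
    const int start = k * batch_size;
    const int stop = std::min(n, start + batch_size) - 1;
    arma::uvec idx(stop - start + 1);
    for (int i = start; i <= stop; ++i) idx[i - start] = order[i] - 1;

    // forward
    A[0] = X.rows(idx);
    for (int l = 0; l < L; ++l) {
      Z[l] = A[l] * W[l];
      Z[l].each_row() += b[l];
      A[l + 1] = Z[l];
      apply_activation(A[l + 1], acts[l]);
    }
    arma::mat dA;
    batch_losses[k] = loss_and_grad(loss_code, A[L], Y.rows(idx), dA);
    if (!std::isfinite(batch_losses[k])) {
      Rcpp::stop("non-finite training loss inside epoch");
    }

    // backward + Adam
    ++t;
    const double c1 = 1.0 - std::pow(beta1, static_cast<double>(t));
    const double c2 = 1.0 - std::pow(beta2, static_cast<double>(t));
    for (int l = L - 1; l >= 0; --l) {
      arma::mat dZ;
      if (acts[l] == 1) {
        dZ = dA % arma::conv_to<arma::mat>::from(Z[l] > 0.0);
      } else if (acts[l] == 2) {
        dZ = dA % A[l + 1] % (1.0 - A[l + 1]);
      } else {
        dZ = dA;
      }
      arma::mat gW = A[l].t() * dZ;
      arma::rowvec gb = arma::sum(dZ, 0);
      if (l > 0) dA = dZ * W[l].t();
      mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW;
      vW[l] = beta2 * vW[l] + (1.0 - beta2) * arma::square(gW);
      W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
      mb[l] = beta1 * mb[l] + (1.0 - beta1) * gb;
      vb[l] = beta2 * vb[l] + (1.0 - beta2) * arma::square(gb);
      b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
    }
  }

  List W_out(L), b_out(L), mW_out(L), vW_out(L), mb_out(L), vb_out(L);
  for (int l = 0; l < L; ++l) {
    W_out[l] = W[l];
    b_out[l] = b[l];
    mW_out[l] = mW[l];
    vW_out[l] = vW[l];
    mb_out[l] = mb[l];
    vb_out[l] = vb[l];
  }
  return List::create(
      _["W"] = W_out, _["b"] = b_out,
      _["opt"] = List::create(_["mW"] = mW_out, _["vW"] = vW_out,
                              _["mb"] = mb_out, _["vb"] = vb_out,
                              _["t"] = static_cast<double>(t)),
      _["train_loss"] = arma::mean(batch_losses));
}

// Per-cell permutation-chain Shapley evaluation for a stacked dense network.
// Chains are built feature-major (points as columns) so every point copy is
// contiguous; the caller supplies the permutations and background row picks
// so all randomness stays in R. Returns one attribution vector per chain
// (antithetic partners interleaved), matching the reference R implementation
// bit for bit in its accumulation order.
// [[Rcpp::export(name = ".cpp_shapley_cell")]]
arma::mat cpp_shapley_cell(const List& W_in, const List& b_in,
                           const IntegerVector& acts, int node,
                           const arma::vec& x, const arma::mat& B,
                           const IntegerMatrix& perms,
                           const IntegerVector& bg_rows, bool antithetic) {
  const int L = W_in.size();
  std::vector<arma::mat> Wt(L);
  std::vector<arma::vec> b(L);
  for (int l = 0; l < L; ++l) {
    Wt[l] = as<arma::mat>(W_in[l]).t();  // transposed: points live in columns
    b[l] = arma::vec(as<arma::rowvec>(b_in[l]).t());
  }
  const int d = x.n_elem;
  const int n_perm = perms.ncol();
  const int chains_per_perm = antithetic ? 2 : 1;
  const int n_chains = n_perm * chains_per_perm;
  const int pts_per_chain = d + 1;

  arma::mat pts(d, n_chains * pts_per_chain);
  int col = 0;
  for (int p = 0; p < n_perm; ++p) {
    const arma::vec bg = B.row(bg_rows[p] - 1).t();
    for (int rev = 0; rev < chains_per_perm; ++rev) {
      pts.col(col) = bg;
      for (int t = 0; t < d; ++t) {
        pts.col(col + t + 1) = pts.col(col + t);
        const int feat = rev == 0 ? perms(t, p) - 1 : perms(d - 1 - t, p) - 1;
        pts(feat, col + t + 1) = x[feat];
      }
      col += pts_per_chain;
    }
  }

  arma::mat A = pts;
  for (int l = 0; l < L; ++l) {
    A = Wt[l] * A;
    A.each_col() += b[l];
    if (acts[l] == 1) {
      A = arma::clamp(A, 0.0, arma::datum::inf);
    } else if (acts[l] == 2) {
      A.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
    }
  }
  const arma::rowvec out = A.row(node - 1);

  arma::mat phi(n_chains, d, arma::fill::zeros);
  int chain = 0;
  for (int p = 0; p < n_perm; ++p) {
    for (int rev = 0; rev < chains_per_perm; ++rev, ++chain) {
      const int base = chain * pts_per_chain;
      for (int t = 0; t < d; ++t) {
        const int feat = rev == 0 ? perms(t, p) - 1 : perms(d - 1 - t, p) - 1;
        phi(chain, feat) = out[base + t + 1] - out[base + t];
      }
    }
  }
  return phi;
}
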