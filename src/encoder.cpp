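// Transformer field encoder: forward pass and analytic backward pass.
//
// One visit field (diagnoses, drugs or symptoms) is a padded token sequence
// [CLS], c_1, ..., c_k, [PAD], ...; a batch of B sequences of length L is
// passed as the stacked embedding matrix X ((B*L) x l, sequences contiguous
// by row). No positional encodings are used - fields are sets - and [PAD]
// positions are masked out of attention as keys, which together give the
// encoder its permutation and padding invariance. The [CLS] output of the
// last layer is the visit embedding.
//
// The forward pass keeps its activation caches on the C++ side (returned to
// R as an external pointer) so the backward pass can reuse them without
// copying; the backward pass returns gradients for every layer parameter
// and for the input embeddings X (needed both to train the ontology
// embedding below the encoder and to build FGM adversarial perturbations).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LN_EPS = 1e-5;
static const double MASK_NEG = -1e30;

struct LayerCache {
  arma::mat Xin, Q, K, V, Ctx, xhat1, Y, Hf, xhat2;
  arma::cube A;
  arma::vec inv1, inv2;
};

struct EncCache {
  std::vector<LayerCache> layers;
};

// row-wise layer norm; returns y, stores xhat and inverse std
static arma::mat layernorm_fwd(const arma::mat& x, const arma::rowvec& g,
                               const arma::rowvec& b, arma::mat& xhat,
                               arma::vec& invstd) {
  const arma::vec mu = arma::mean(x, 1);
  arma::mat c = x.each_col() - mu;
  const arma::vec var = arma::mean(arma::square(c), 1);
  invstd = 1.0 / arma::sqrt(var + LN_EPS);
  xhat = c.each_col() % invstd;
  arma::mat y = xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

// backward of layernorm; accumulates dg, db, returns dx
static arma::mat layernorm_bwd(const arma::mat& dy, const arma::mat& xhat,
                               const arma::vec& invstd, const arma::rowvec& g,
                               arma::rowvec& dg, arma::rowvec& db) {
  dg = arma::sum(dy % xhat, 0);
  db = arma::sum(dy, 0);
  arma::mat dxh = dy.each_row() % g;
  const arma::vec m1 = arma::mean(dxh, 1);
  const arma::vec m2 = arma::mean(dxh % xhat, 1);
  arma::mat dx = dxh.each_col() - m1;
  dx -= xhat.each_col() % m2;
  return dx.each_col() % invstd;
}

// [[Rcpp::export(name = ".enc_forward_cpp")]]
List enc_forward_cpp(const arma::mat& X0, const arma::imat& valid,
                     const List& layers, const int nh,
                     const bool keep_cache = true) {
  const int B = valid.n_rows, L = valid.n_cols;
  const int l = X0.n_cols;
  const int dk = l / nh;
  const double sc = 1.0 / std::sqrt((double)dk);
  const int nlayer = layers.size();

  Rcpp::XPtr<EncCache> cache(new EncCache(), true);
  if (keep_cache) cache->layers.resize(nlayer);

  arma::mat X = X0;
  for (int li = 0; li < nlayer; ++li) {
    List lp = layers[li];
    const arma::mat Wq = lp["Wq"], Wk = lp["Wk"], Wv = lp["Wv"], Wo = lp["Wo"];
    const arma::rowvec bq = lp["bq"], bk = lp["bk"], bv = lp["bv"], bo = lp["bo"];
    const arma::rowvec g1 = lp["g1"], be1 = lp["be1"], g2 = lp["g2"], be2 = lp["be2"];
    const arma::mat W1 = lp["W1"], W2 = lp["W2"];
    const arma::rowvec c1 = lp["c1"], c2 = lp["c2"];

    arma::mat Q = X * Wq; Q.each_row() += bq;
    arma::mat K = X * Wk; K.each_row() += bk;
    arma::mat V = X * Wv; V.each_row() += bv;

    arma::cube A(L, L, (size_t)B * nh);
    arma::mat Ctx(X.n_rows, l);
    for (int b = 0; b < B; ++b) {
      const int r0 = b * L;
      for (int h = 0; h < nh; ++h) {
        const int c0 = h * dk;
        arma::mat S = (Q.submat(r0, c0, r0 + L - 1, c0 + dk - 1) *
                       K.submat(r0, c0, r0 + L - 1, c0 + dk - 1).t()) * sc;
        for (int j = 0; j < L; ++j) {
          if (valid(b, j) == 0) S.col(j) += MASK_NEG;
        }
        const arma::vec mx = arma::max(S, 1);
        S.each_col() -= mx;
        S = arma::exp(S);
        const arma::vec sm = arma::sum(S, 1);
        S.each_col() /= sm;
        A.slice((size_t)b * nh + h) = S;
        Ctx.submat(r0, c0, r0 + L - 1, c0 + dk - 1) =
            S * V.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
      }
    }
    arma::mat O = Ctx * Wo; O.each_row() += bo;
    arma::mat R1 = X + O;
    arma::mat xhat1; arma::vec inv1;
    arma::mat Y = layernorm_fwd(R1, g1, be1, xhat1, inv1);

    arma::mat Hpre = Y * W1; Hpre.each_row() += c1;
    arma::mat Hf = arma::clamp(Hpre, 0.0, arma::datum::inf);   // ReLU
    arma::mat F = Hf * W2; F.each_row() += c2;
    arma::mat R2 = Y + F;
    arma::mat xhat2; arma::vec inv2;
    arma::mat Xout = layernorm_fwd(R2, g2, be2, xhat2, inv2);

    if (keep_cache) {
      LayerCache& lc = cache->layers[li];
      lc.Xin = std::move(X); lc.Q = std::move(Q); lc.K = std::move(K);
      lc.V = std::move(V); lc.A = std::move(A); lc.Ctx = std::move(Ctx);
      lc.xhat1 = std::move(xhat1); lc.inv1 = std::move(inv1);
      lc.Y = std::move(Y); lc.Hf = std::move(Hf);
      lc.xhat2 = std::move(xhat2); lc.inv2 = std::move(inv2);
    }
    X = std::move(Xout);
  }

  // [CLS] rows (first position of each sequence)
  arma::mat cls(B, l);
  for (int b = 0; b < B; ++b) cls.row(b) = X.row((size_t)b * L);

  return List::create(_["cls"] = cls, _["cache"] = cache);
}

// [[Rcpp::export(name = ".enc_backward_cpp")]]
List enc_backward_cpp(const arma::mat& dcls, const arma::imat& valid,
                      const List& layers, SEXP cache_ptr, const int nh) {
  Rcpp::XPtr<EncCache> cache(cache_ptr);
  const int B = valid.n_rows, L = valid.n_cols;
  List lp0 = layers[0];
  const arma::mat Wq0 = lp0["Wq"];
  const int l = Wq0.n_rows;
  const int dk = l / nh;
  const double sc = 1.0 / std::sqrt((double)dk);
  const int nlayer = layers.size();
  if ((int)cache->layers.size() != nlayer) {
    stop("encoder cache does not match the layer stack");
  }

  arma::mat dX((size_t)B * L, l, arma::fill::zeros);
  for (int b = 0; b < B; ++b) dX.row((size_t)b * L) = dcls.row(b);

  List grads(nlayer);
  for (int li = nlayer - 1; li >= 0; --li) {
    List lp = layers[li];
    const LayerCache& ch = cache->layers[li];
    const arma::mat Wq = lp["Wq"], Wk = lp["Wk"], Wv = lp["Wv"], Wo = lp["Wo"];
    const arma::rowvec g1 = lp["g1"], g2 = lp["g2"];
    const arma::mat W1 = lp["W1"], W2 = lp["W2"];

    arma::rowvec dg2, dbe2;
    arma::mat dR2 = layernorm_bwd(dX, ch.xhat2, ch.inv2, g2, dg2, dbe2);

    // FFN backward
    arma::mat dHf = dR2 * W2.t();
    arma::mat dW2 = ch.Hf.t() * dR2;
    arma::rowvec dc2 = arma::sum(dR2, 0);
    arma::mat dHpre = dHf % arma::conv_to<arma::mat>::from(ch.Hf > 0);
    arma::mat dW1 = ch.Y.t() * dHpre;
    arma::rowvec dc1 = arma::sum(dHpre, 0);
    arma::mat dY = dR2 + dHpre * W1.t();

    arma::rowvec dg1, dbe1;
    arma::mat dR1 = layernorm_bwd(dY, ch.xhat1, ch.inv1, g1, dg1, dbe1);

    // attention output projection
    arma::mat dCtx = dR1 * Wo.t();
    arma::mat dWo = ch.Ctx.t() * dR1;
    arma::rowvec dbo = arma::sum(dR1, 0);

    arma::mat dQ(arma::size(ch.Q), arma::fill::zeros);
    arma::mat dK(arma::size(ch.K), arma::fill::zeros);
    arma::mat dV(arma::size(ch.V), arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      const int r0 = b * L;
      for (int h = 0; h < nh; ++h) {
        const int c0 = h * dk;
        const arma::mat& Ah = ch.A.slice((size_t)b * nh + h);
        arma::mat dCh = dCtx.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
        dV.submat(r0, c0, r0 + L - 1, c0 + dk - 1) += Ah.t() * dCh;
        arma::mat dAh = dCh * ch.V.submat(r0, c0, r0 + L - 1, c0 + dk - 1).t();
        // softmax backward per row
        arma::vec rs = arma::sum(dAh % Ah, 1);
        arma::mat dS = Ah % (dAh.each_col() - rs);
        dS *= sc;
        dQ.submat(r0, c0, r0 + L - 1, c0 + dk - 1) +=
            dS * ch.K.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
        dK.submat(r0, c0, r0 + L - 1, c0 + dk - 1) +=
            dS.t() * ch.Q.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
      }
    }

    arma::mat dWq = ch.Xin.t() * dQ;
    arma::mat dWk = ch.Xin.t() * dK;
    arma::mat dWv = ch.Xin.t() * dV;
    arma::rowvec dbq = arma::sum(dQ, 0);
    arma::rowvec dbk = arma::sum(dK, 0);
    arma::rowvec dbv = arma::sum(dV, 0);

    dX = dR1 + dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();

    grads[li] = List::create(
        _["Wq"] = dWq, _["Wk"] = dWk, _["Wv"] = dWv, _["Wo"] = dWo,
        _["bq"] = dbq, _["bk"] = dbk, _["bv"] = dbv, _["bo"] = dbo,
        _["g1"] = dg1, _["be1"] = dbe1, _["W1"] = dW1, _["c1"] = dc1,
        _["W2"] = dW2, _["c2"] = dc2, _["g2"] = dg2, _["be2"] = dbe2);
  }

  return List::create(_["dX"] = dX, _["layers"] = grads);
}
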