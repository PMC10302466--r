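// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Batched forward/backward passes of the point-cloud network:
// shared per-point affine+ReLU layers, per-feature max pooling over each
// sample's points, state-scalar concatenation, fully connected head with a
// linear output layer. Points arrive stacked sample-major: rows
// (b-1)*n_points .. b*n_points-1 belong to sample b.

static std::vector<arma::mat> as_mats(const List &l) {
  std::vector<arma::mat> out;
  for (int i = 0; i < l.size(); ++i)
    out.push_back(as<arma::mat>(l[i]));
  return out;
}

static std::vector<arma::rowvec> as_rows(const List &l) {
  std::vector<arma::rowvec> out;
  for (int i = 0; i < l.size(); ++i)
    out.push_back(as<arma::rowvec>(l[i]));
  return out;
}

struct ForwardState {
  std::vector<arma::mat> shared_acts; // input + post-ReLU activations
  std::vector<arma::mat> head_acts;   // pooled+state input + activations
  arma::umat amax;                    // B x K stacked-row index of each max
  arma::mat pred;
};

// Row-independent matrix multiply: every output row is accumulated in a
// fixed scalar order that does not depend on the row's position, so
// identical input rows give bitwise-identical outputs wherever they sit.
// BLAS gemm does not guarantee that (its micro-kernels may reassociate
// differently for panel-tail rows), which would break the exact
// permutation invariance of the pooled features.
static arma::mat matmul_det(const arma::mat &x, const arma::mat &w) {
  const arma::uword n = x.n_rows, k = x.n_cols, m = w.n_cols;
  arma::mat out(n, m);
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < m; ++j) {
      double acc = 0.0;
      const double *wc = w.colptr(j);
      for (arma::uword p = 0; p < k; ++p) acc += x(i, p) * wc[p];
      out(i, j) = acc;
    }
  return out;
}

static void run_forward(const std::vector<arma::mat> &sW,
                        const std::vector<arma::rowvec> &sb,
                        const std::vector<arma::mat> &hW,
                        const std::vector<arma::rowvec> &hb,
                        const arma::mat &points, int n_points,
                        const arma::mat &states, ForwardState &st,
                        bool deterministic = false) {
  const arma::uword b = states.n_rows;
  st.shared_acts.clear();
  st.head_acts.clear();
  st.shared_acts.push_back(points);
  for (size_t l = 0; l < sW.size(); ++l) {
    arma::mat h = deterministic ? matmul_det(st.shared_acts.back(), sW[l])
                                : st.shared_acts.back() * sW[l];
    h.each_row() += sb[l];
    h.clamp(0.0, arma::datum::inf);
    st.shared_acts.push_back(std::move(h));
  }
  const arma::mat &hl = st.shared_acts.back();
  const arma::uword k = hl.n_cols;
  arma::mat pooled(b, k);
  st.amax.set_size(b, k);
  for (arma::uword j = 0; j < k; ++j) {
    const double *col = hl.colptr(j);
    for (arma::uword s = 0; s < b; ++s) {
      const arma::uword off = s * n_points;
      arma::uword best = off;
      double bv = col[off];
      for (arma::uword i = 1; i < (arma::uword)n_points; ++i)
        if (col[off + i] > bv) { bv = col[off + i]; best = off + i; }
      pooled(s, j) = bv;
      st.amax(s, j) = best;
    }
  }
  st.head_acts.push_back(arma::join_rows(pooled, states));
  for (size_t l = 0; l < hW.size(); ++l) {
    arma::mat g = st.head_acts.back() * hW[l];
    g.each_row() += hb[l];
    if (l + 1 < hW.size()) g.clamp(0.0, arma::datum::inf);
    st.head_acts.push_back(std::move(g));
  }
  st.pred = st.head_acts.back();
}

// [[Rcpp::export]]
List nn_forward_cpp(List shared_W, List shared_b, List head_W, List head_b,
                    const arma::mat &points, int n_points,
                    const arma::mat &states) {
  ForwardState st;
  run_forward(as_mats(shared_W), as_rows(shared_b), as_mats(head_W),
              as_rows(head_b), points, n_points, states, st,
              /*deterministic=*/true);
  const arma::uword k = st.shared_acts.back().n_cols;
  return List::create(
      _["pred"] = st.pred,
      _["pooled"] = st.head_acts.front().cols(0, k - 1),
      _["point_features"] = st.shared_acts.back());
}

// Mean-squared-error loss and its gradient w.r.t. every parameter.
// [[Rcpp::export]]
List nn_fwdbwd_cpp(List shared_W, List shared_b, List head_W, List head_b,
                   const arma::mat &points, int n_points,
                   const arma::mat &states, const arma::mat &targets) {
  std::vector<arma::mat> sW = as_mats(shared_W), hW = as_mats(head_W);
  std::vector<arma::rowvec> sb = as_rows(shared_b), hb = as_rows(head_b);
  ForwardState st;
  run_forward(sW, sb, hW, hb, points, n_points, states, st);

  const double n_el = (double)targets.n_elem;
  const double loss = arma::accu(arma::square(st.pred - targets)) / n_el;

  arma::mat d = 2.0 * (st.pred - targets) / n_el;
  List gW_head(hW.size()), gb_head(hW.size());
  for (int l = (int)hW.size() - 1; l >= 0; --l) {
    if (l + 1 < (int)hW.size())
      d %= arma::conv_to<arma::mat>::from(st.head_acts[l + 1] > 0);
    gW_head[l] = st.head_acts[l].t() * d;
    gb_head[l] = arma::sum(d, 0);
    d = d * hW[l].t();
  }
  const arma::uword b = states.n_rows;
  const arma::uword k = st.shared_acts.back().n_cols;
  // route pooled-feature gradients back to each sample's argmax point
  arma::mat dh(st.shared_acts.back().n_rows, k, arma::fill::zeros);
  for (arma::uword j = 0; j < k; ++j)
    for (arma::uword s = 0; s < b; ++s)
      dh(st.amax(s, j), j) += d(s, j);
  List gW_shared(sW.size()), gb_shared(sW.size());
  arma::mat ds = std::move(dh);
  for (int l = (int)sW.size() - 1; l >= 0; --l) {
    ds %= arma::conv_to<arma::mat>::from(st.shared_acts[l + 1] > 0);
    gW_shared[l] = st.shared_acts[l].t() * ds;
    gb_shared[l] = arma::sum(ds, 0);
    if (l > 0) ds = ds * sW[l].t();
  }
  return List::create(_["loss"] = loss, _["pred"] = st.pred,
                      _["gW_shared"] = gW_shared,
                      _["gb_shared"] = gb_shared,
                      _["gW_head"] = gW_head, _["gb_head"] = gb_head);
}
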