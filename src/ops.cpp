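// Performance kernels: fused in-place Adam update and segmented multi-head
// attention (forward + backward). Molecules/sequences are small, so the
// attention math is plain Armadillo on per-segment blocks; the heavy dense
// projections stay in R where they hit BLAS directly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// In-place Adam: params[[i]] -= lr_t * mhat / (sqrt(vhat) + eps).
// m and v are the flattened first/second moment vectors (updated in place).
// [[Rcpp::export]]
void adam_update_cpp(List params, List grads, NumericVector m,
                     NumericVector v, double lr, int t, double beta1,
                     double beta2, double eps) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  R_xlen_t off = 0;
  for (R_xlen_t i = 0; i < params.size(); ++i) {
    NumericVector p = params[i];
    const R_xlen_t n = p.size();
    if (Rf_isNull(grads[i])) { off += n; continue; }
    NumericVector g = grads[i];
    double* pm = REAL(m) + off;
    double* pv = REAL(v) + off;
    double* pp = REAL(p);
    double* pg = REAL(g);
    for (R_xlen_t j = 0; j < n; ++j) {
      pm[j] = beta1 * pm[j] + (1.0 - beta1) * pg[j];
      pv[j] = beta2 * pv[j] + (1.0 - beta2) * pg[j] * pg[j];
      pp[j] -= lr * (pm[j] / bc1) / (std::sqrt(pv[j] / bc2) + eps);
    }
    off += n;
  }
}

// Segmented multi-head scaled-dot-product attention forward (internal).
//   q, k, v : N x d; ns: atoms per segment (rows are segment-contiguous)
//   keymask : length N (>0 keeps the row as a key) or length 0
//   bias    : (sum ns^2) x H additive logits, query-major per segment, or 0x0
//   psu     : per-segment ProbSparse query budget, or length 0 for full
// Fills O plus the softmax matrices A ((sum ns^2) x H, query-major) and a
// selected-query flag matrix (N x H) needed for the backward pass.
static void attn_fwd(const arma::mat& q, const arma::mat& k,
                     const arma::mat& v, int nheads, const IntegerVector& ns,
                     const NumericVector& keymask, const arma::mat& bias,
                     const IntegerVector& psu, arma::mat& O, arma::mat& Aout,
                     arma::umat& sel_out) {
  const int d = q.n_cols;
  const int dh = d / nheads;
  const double scale = 1.0 / std::sqrt((double)dh);
  const int S = ns.size();
  const bool has_mask = keymask.size() > 0;
  const bool has_bias = bias.n_rows > 0;
  const bool has_psu = psu.size() > 0;

  O.zeros(q.n_rows, d);
  arma::uword tot2 = 0;
  for (int s = 0; s < S; ++s) tot2 += (arma::uword)ns[s] * ns[s];
  Aout.zeros(tot2, nheads);
  sel_out.ones(q.n_rows, nheads);

  arma::uword roff = 0, boff = 0;
  for (int s = 0; s < S; ++s) {
    const int n = ns[s];
    std::vector<int> valid;
    valid.reserve(n);
    for (int y = 0; y < n; ++y) {
      if (!has_mask || keymask[roff + y] > 0) valid.push_back(y);
    }
    const int nv = valid.size();
    int u = has_psu ? std::min<int>(psu[s], n) : n;
    for (int h = 0; h < nheads; ++h) {
      arma::mat qs = q.submat(roff, h * dh, roff + n - 1, (h + 1) * dh - 1);
      arma::mat ks = k.submat(roff, h * dh, roff + n - 1, (h + 1) * dh - 1);
      arma::mat vs = v.submat(roff, h * dh, roff + n - 1, (h + 1) * dh - 1);
      arma::mat sc = qs * ks.t() * scale;
      if (has_bias) {
        // bias row (x*n + y) holds the (query x, key y) entry
        for (int x = 0; x < n; ++x)
          for (int y = 0; y < n; ++y)
            sc(x, y) += bias(boff + (arma::uword)x * n + y, h);
      }
      // ProbSparse selection: top-u queries by (max - mean) over valid keys
      std::vector<char> selq(n, 1);
      if (u < n && nv > 0) {
        arma::vec meas(n);
        for (int x = 0; x < n; ++x) {
          double mx = -arma::datum::inf, mn = 0.0;
          for (int yi = 0; yi < nv; ++yi) {
            const double val = sc(x, valid[yi]);
            if (val > mx) mx = val;
            mn += val;
          }
          meas[x] = mx - mn / nv;
        }
        std::vector<int> ord(n);
        for (int x = 0; x < n; ++x) ord[x] = x;
        std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
          return meas[a] > meas[b];
        });
        // keep every query tied with the u-th measure: atom numbering is
        // arbitrary, so ties must not decide selection
        double thresh = meas[ord[u - 1]];
        double tol = 1e-9 * std::max(1.0, std::abs(thresh));
        std::fill(selq.begin(), selq.end(), 0);
        for (int x = 0; x < n; ++x)
          if (meas[x] >= thresh - tol) selq[x] = 1;
      }
      arma::mat A(n, n, arma::fill::zeros);
      for (int x = 0; x < n; ++x) {
        if (selq[x] && nv > 0) {
          double mx = -arma::datum::inf;
          for (int yi = 0; yi < nv; ++yi)
            mx = std::max(mx, sc(x, valid[yi]));
          double z = 0.0;
          for (int yi = 0; yi < nv; ++yi) {
            const double e = std::exp(sc(x, valid[yi]) - mx);
            A(x, valid[yi]) = e;
            z += e;
          }
          if (z > 0) A.row(x) /= z;
        } else if (nv > 0) {
          // mean-value shortcut: uniform weights over valid keys
          for (int yi = 0; yi < nv; ++yi) A(x, valid[yi]) = 1.0 / nv;
        }
        sel_out(roff + x, h) = selq[x] ? 1 : 0;
      }
      O.submat(roff, h * dh, roff + n - 1, (h + 1) * dh - 1) = A * vs;
      for (int x = 0; x < n; ++x)
        for (int y = 0; y < n; ++y)
          Aout(boff + (arma::uword)x * n + y, h) = A(x, y);
    }
    roff += n;
    boff += (arma::uword)n * n;
  }
}

// [[Rcpp::export]]
List attention_forward_cpp(const arma::mat& q, const arma::mat& k,
                           const arma::mat& v, int nheads,
                           const IntegerVector& ns,
                           const NumericVector& keymask,
                           const arma::mat& bias, const IntegerVector& psu) {
  arma::mat O, Aout;
  arma::umat sel;
  attn_fwd(q, k, v, nheads, ns, keymask, bias, psu, O, Aout, sel);
  return List::create(_["O"] = O, _["A"] = Aout, _["sel"] = sel);
}

// Backward for attn_fwd (internal).
static void attn_bwd(const arma::mat& g, const arma::mat& q,
                     const arma::mat& k, const arma::mat& v, int nheads,
                     const IntegerVector& ns, const arma::mat& Aout,
                     const arma::umat& sel, bool want_bias, arma::mat& gq,
                     arma::mat& gk, arma::mat& gv, arma::mat& gb) {
  const int d = q.n_cols;
  const int dh = d / nheads;
  const double scale = 1.0 / std::sqrt((double)dh);
  const int S = ns.size();

  gq.zeros(q.n_rows, d);
  gk.zeros(q.n_rows, d);
  gv.zeros(q.n_rows, d);
  if (want_bias) gb.zeros(Aout.n_rows, nheads);

  arma::uword roff = 0, boff = 0;
  for (int s = 0; s < S; ++s) {
    const int n = ns[s];
    for (int h = 0; h < nheads; ++h) {
      arma::mat qs = q.submat(roff, h * dh, roff + n - 1, (h + 1) * dh - 1);
      arma::mat ks = k.submat(roff, h * dh, roff + n - 1, (h + 1) * dh - 1);
      arma::mat vs = v.submat(roff, h * dh, roff + n - 1, (h + 1) * dh - 1);
      arma::mat go = g.submat(roff, h * dh, roff + n - 1, (h + 1) * dh - 1);
      arma::mat A(n, n);
      for (int x = 0; x < n; ++x)
        for (int y = 0; y < n; ++y)
          A(x, y) = Aout(boff + (arma::uword)x * n + y, h);
      gv.submat(roff, h * dh, roff + n - 1, (h + 1) * dh - 1) += A.t() * go;
      arma::mat dA = go * vs.t();
      arma::vec rs = arma::sum(dA % A, 1);
      dA.each_col() -= rs;
      arma::mat dS = A % dA;
      for (int x = 0; x < n; ++x) {
        if (!sel(roff + x, h)) dS.row(x).zeros();
      }
      gq.submat(roff, h * dh, roff + n - 1, (h + 1) * dh - 1) +=
          dS * ks * scale;
      gk.submat(roff, h * dh, roff + n - 1, (h + 1) * dh - 1) +=
          dS.t() * qs * scale;
      if (want_bias) {
        for (int x = 0; x < n; ++x)
          for (int y = 0; y < n; ++y)
            gb(boff + (arma::uword)x * n + y, h) = dS(x, y);
      }
    }
    roff += n;
    boff += (arma::uword)n * n;
  }
}

// [[Rcpp::export]]
List attention_backward_cpp(const arma::mat& g, const arma::mat& q,
                            const arma::mat& k, const arma::mat& v,
                            int nheads, const IntegerVector& ns,
                            const arma::mat& Aout, const arma::umat& sel,
                            bool want_bias) {
  arma::mat gq, gk, gv, gb;
  attn_bwd(g, q, k, v, nheads, ns, Aout, sel, want_bias, gq, gk, gv, gb);
  if (want_bias) {
    return List::create(_["gq"] = gq, _["gk"] = gk, _["gv"] = gv,
                        _["gb"] = gb);
  }
  return List::create(_["gq"] = gq, _["gk"] = gk, _["gv"] = gv);
}

// ---- fused pre-LN transformer block ---------------------------------------

static void ln_forward(const arma::mat& x, const arma::rowvec& g,
                       const arma::rowvec& b, arma::mat& xh, arma::vec& istd,
                       arma::mat& y) {
  arma::vec mu = arma::mean(x, 1);
  arma::mat xc = x.each_col() - mu;
  arma::vec va = arma::mean(xc % xc, 1);
  istd = 1.0 / arma::sqrt(va + 1e-5);
  xh = xc.each_col() % istd;
  y = xh.each_row() % g;
  y.each_row() += b;
}

static arma::mat ln_backward(const arma::mat& gy, const arma::mat& xh,
                             const arma::vec& istd, const arma::rowvec& g,
                             arma::rowvec& ggain, arma::rowvec& gbias) {
  ggain = arma::sum(gy % xh, 0);
  gbias = arma::sum(gy, 0);
  arma::mat gh = gy.each_row() % g;
  arma::vec m1 = arma::mean(gh, 1);
  arma::vec m2 = arma::mean(gh % xh, 1);
  arma::mat gx = gh.each_col() - m1;
  gx -= xh.each_col() % m2;
  gx.each_col() %= istd;
  return gx;
}

// Intermediates of one block forward pass, kept in native memory (an XPtr on
// the R side) so the tape carries no large R objects.
struct BlockCache {
  arma::mat xh1, y1, q, k, v, A, attO, d1, d2, xh2, y2, fr;
  arma::vec istd1, istd2;
  arma::umat sel;
};

// Forward pass of one pre-LN block:
//   x2 = x + drop1(WO(attn(LN1(x))));  out = x2 + drop2(FF2(relu(FF1(LN2(x2)))))
// Returns the output and an external pointer to the backward cache.
// [[Rcpp::export]]
List block_forward_cpp(const arma::mat& x, const arma::rowvec& ln1_g,
                       const arma::rowvec& ln1_b, const arma::mat& wq,
                       const arma::rowvec& bq, const arma::mat& wk,
                       const arma::rowvec& bk, const arma::mat& wv,
                       const arma::rowvec& bv, const arma::mat& wo,
                       const arma::rowvec& bo, const arma::rowvec& ln2_g,
                       const arma::rowvec& ln2_b, const arma::mat& ff1_w,
                       const arma::rowvec& ff1_b, const arma::mat& ff2_w,
                       const arma::rowvec& ff2_b, int nheads,
                       const IntegerVector& ns, const NumericVector& keymask,
                       const arma::mat& bias, const IntegerVector& psu,
                       double dropout) {
  XPtr<BlockCache> cc(new BlockCache(), true);
  arma::mat y1;
  ln_forward(x, ln1_g, ln1_b, cc->xh1, cc->istd1, y1);
  cc->q = y1 * wq; cc->q.each_row() += bq;
  cc->k = y1 * wk; cc->k.each_row() += bk;
  cc->v = y1 * wv; cc->v.each_row() += bv;
  attn_fwd(cc->q, cc->k, cc->v, nheads, ns, keymask, bias, psu, cc->attO,
           cc->A, cc->sel);
  arma::mat ao = cc->attO * wo; ao.each_row() += bo;
  if (dropout > 0) {
    cc->d1.set_size(ao.n_rows, ao.n_cols);
    for (arma::uword i = 0; i < cc->d1.n_elem; ++i)
      cc->d1[i] = (R::unif_rand() >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
    ao %= cc->d1;
  }
  arma::mat x2 = x + ao;
  ln_forward(x2, ln2_g, ln2_b, cc->xh2, cc->istd2, cc->y2);
  arma::mat f1 = cc->y2 * ff1_w; f1.each_row() += ff1_b;
  cc->fr = arma::clamp(f1, 0.0, arma::datum::inf);
  arma::mat f2 = cc->fr * ff2_w; f2.each_row() += ff2_b;
  if (dropout > 0) {
    cc->d2.set_size(f2.n_rows, f2.n_cols);
    for (arma::uword i = 0; i < cc->d2.n_elem; ++i)
      cc->d2[i] = (R::unif_rand() >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
    f2 %= cc->d2;
  }
  arma::mat out = x2 + f2;
  cc->y1 = std::move(y1);
  return List::create(_["out"] = out, _["cache"] = cc);
}

// [[Rcpp::export]]
List block_backward_cpp(const arma::mat& gout, SEXP cache,
                        const arma::mat& wq, const arma::mat& wk,
                        const arma::mat& wv, const arma::mat& wo,
                        const arma::rowvec& ln1_g, const arma::rowvec& ln2_g,
                        const arma::mat& ff1_w, const arma::mat& ff2_w,
                        int nheads, const IntegerVector& ns, bool want_bias,
                        double dropout) {
  XPtr<BlockCache> cc(cache);

  // FFN sub-block
  arma::mat gf2 = gout;
  if (dropout > 0) gf2 %= cc->d2;
  arma::mat gff2_w = cc->fr.t() * gf2;
  arma::rowvec gff2_b = arma::sum(gf2, 0);
  arma::mat gfr = gf2 * ff2_w.t();
  arma::mat gf1 = gfr % arma::conv_to<arma::mat>::from(cc->fr > 0);
  arma::mat gff1_w = cc->y2.t() * gf1;
  arma::rowvec gff1_b = arma::sum(gf1, 0);
  arma::mat gy2 = gf1 * ff1_w.t();
  arma::rowvec gln2_g, gln2_b;
  arma::mat gx2 = ln_backward(gy2, cc->xh2, cc->istd2, ln2_g, gln2_g, gln2_b);
  gx2 += gout;  // residual

  // attention sub-block
  arma::mat gao = gx2;
  if (dropout > 0) gao = gao % cc->d1;
  arma::mat gwo = cc->attO.t() * gao;
  arma::rowvec gbo = arma::sum(gao, 0);
  arma::mat gattO = gao * wo.t();
  arma::mat gq, gk, gv, gb;
  attn_bwd(gattO, cc->q, cc->k, cc->v, nheads, ns, cc->A, cc->sel, want_bias,
           gq, gk, gv, gb);
  arma::mat gy1 = gq * wq.t() + gk * wk.t() + gv * wv.t();
  arma::mat gwq = cc->y1.t() * gq;
  arma::mat gwk = cc->y1.t() * gk;
  arma::mat gwv = cc->y1.t() * gv;
  arma::rowvec gbq = arma::sum(gq, 0);
  arma::rowvec gbk = arma::sum(gk, 0);
  arma::rowvec gbv = arma::sum(gv, 0);
  arma::rowvec gln1_g, gln1_b;
  arma::mat gx1 = ln_backward(gy1, cc->xh1, cc->istd1, ln1_g, gln1_g, gln1_b);
  arma::mat gx = gx2 + gx1;

  List out = List::create(
      _["gx"] = gx, _["gln1_g"] = gln1_g, _["gln1_b"] = gln1_b,
      _["gwq"] = gwq, _["gbq"] = gbq, _["gwk"] = gwk, _["gbk"] = gbk,
      _["gwv"] = gwv, _["gbv"] = gbv, _["gwo"] = gwo, _["gbo"] = gbo,
      _["gln2_g"] = gln2_g, _["gln2_b"] = gln2_b, _["gff1_w"] = gff1_w,
      _["gff1_b"] = gff1_b, _["gff2_w"] = gff2_w, _["gff2_b"] = gff2_b);
  if (want_bias) out["gb"] = gb;
  return out;
}

// Sum of embedding rows over feature slots: out[i,] = sum_j table[idx(i,j),].
// idx is 1-based (R convention).
// [[Rcpp::export]]
arma::mat emb_sum_forward_cpp(const arma::mat& table,
                              const IntegerMatrix& idx) {
  const int n = idx.nrow(), k = idx.ncol();
  arma::mat out(n, table.n_cols, arma::fill::zeros);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < n; ++i)
      out.row(i) += table.row(idx(i, j) - 1);
  return out;
}

// [[Rcpp::export]]
arma::mat emb_sum_backward_cpp(const arma::mat& g, const IntegerMatrix& idx,
                               int table_rows) {
  const int n = idx.nrow(), k = idx.ncol();
  arma::mat gt(table_rows, g.n_cols, arma::fill::zeros);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < n; ++i)
      gt.row(idx(i, j) - 1) += g.row(i);
  return gt;
}

// Row-wise layer normalisation, exported for the standalone op.
// [[Rcpp::export]]
List ln_forward_cpp(const arma::mat& x, const arma::rowvec& g,
                    const arma::rowvec& b) {
  arma::mat xh, y;
  arma::vec istd;
  ln_forward(x, g, b, xh, istd, y);
  return List::create(_["y"] = y, _["xh"] = xh, _["istd"] = istd);
}

// [[Rcpp::export]]
List ln_backward_cpp(const arma::mat& gy, const arma::mat& xh,
                     const arma::vec& istd, const arma::rowvec& g) {
  arma::rowvec ggain, gbias;
  arma::mat gx = ln_backward(gy, xh, istd, g, ggain, gbias);
  return List::create(_["gx"] = gx, _["ggain"] = ggain, _["gbias"] = gbias);
}
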