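// Temporal kernels for forward-adjoint sensitivity assembly and the
// iterative least-squares (CGLS) solvers.
//
// The fluorescence forward model on native time bins is, per voxel r,
//   e(t) = eta(r) * (Gx(r,.) (*) K_tau (*) Gm(r,.))(t) * Vvox,
// where K_tau is the unit-area discrete exponential lifetime kernel.
// The lifetime convolution is a first-order recursive filter (O(nt) per
// voxel); a time gate of width W bins starting at bin n is obtained from
// the boxcar-prefiltered adjoint Green's function Q = Gm (*) boxcar(W) as
//   gate value = sum_t A(r,t) * Q(r, n - t),  A = Gx (*) K_tau.
// This makes one gate an O(nt) dot product per voxel, shared by every
// measurement that uses the same (pattern, adjoint patch, gate) triple.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Recursive exponential (lifetime) filter along rows of X (vox x nt).
// Unit-area kernel K[j] = (1 - a) a^j with a = exp(-dt/tau); tau <= 0 is
// the delta-kernel limit (returns X).
// [[Rcpp::export(name = ".exp_filter_cpp")]]
arma::mat exp_filter_cpp(const arma::mat& X, double dt, double tau) {
  if (tau <= 0) return X;
  const double a = std::exp(-dt / tau), b = 1.0 - a;
  arma::mat A(X.n_rows, X.n_cols);
  A.col(0) = b * X.col(0);
  for (arma::uword t = 1; t < X.n_cols; ++t)
    A.col(t) = a * A.col(t - 1) + b * X.col(t);
  return A;
}

// Extended window sums for a gate of W bins. Column j holds shift
// s = j - (W - 1), s in [-(W-1), nt-1]:
//   Q[, j] = sum_{u = max(s, 0)}^{min(s + W - 1, nt - 1)} G[, u].
// Negative shifts arise when excitation reaches a voxel within the gate
// window itself (emission bins b >= t contribute for t > gate start).
// [[Rcpp::export(name = ".boxcar_cpp")]]
arma::mat boxcar_cpp(const arma::mat& G, int W) {
  const int nt = G.n_cols;
  arma::mat Q(G.n_rows, nt + W - 1, arma::fill::zeros);
  for (int j = 0; j < nt + W - 1; ++j) {
    int s = j - (W - 1);
    int lo = std::max(s, 0), hi = std::min(s + W - 1, nt - 1);
    if (lo > hi) continue;
    Q.col(j) = arma::sum(G.cols(lo, hi), 1);
  }
  return Q;
}

// Gated triple-convolution values for gate start bin n_g (0-based):
//   out(v, g) = sum_{t = 0}^{min(n_g + offset, nt - 1)} A(v,t) Q(v, n_g - t + offset)
// where `offset` = W - 1 for a W-bin gate prefilter from boxcar_cpp (so that
// negative shifts are resolved), or 0 when Q has plain cumulative columns.
// [[Rcpp::export(name = ".gated_conv_cpp")]]
arma::mat gated_conv_cpp(const arma::mat& A, const arma::mat& Q,
                         const IntegerVector& starts, int offset) {
  const arma::uword nv = A.n_rows;
  const int nt = A.n_cols;
  arma::mat out(nv, starts.size(), arma::fill::zeros);
  for (int g = 0; g < starts.size(); ++g) {
    const int n = starts[g];
    if (n < 0 || n >= nt) stop("gate start bin out of range");
    arma::vec acc(nv, arma::fill::zeros);
    const int tmax = std::min(n + offset, nt - 1);
    for (int t = 0; t <= tmax; ++t)
      acc += A.col(t) % Q.col(n - t + offset);
    out.col(g) = acc;
  }
  return out;
}

// Full emission TPSF for one (pattern, adjoint patch) pair restricted to the
// eta support: f[n] = sum_v eta(v) sum_t A(v,t) G(v, n-t).
// [[Rcpp::export(name = ".emission_tpsf_cpp")]]
arma::vec emission_tpsf_cpp(const arma::mat& A, const arma::mat& G,
                            const arma::vec& eta) {
  const arma::uword nt = A.n_cols;
  arma::mat B = A.each_col() % eta;
  arma::vec f(nt, arma::fill::zeros);
  for (arma::uword t1 = 0; t1 < nt; ++t1) {
    arma::vec b = B.col(t1);
    if (arma::accu(arma::abs(b)) == 0) continue;
    for (arma::uword t2 = 0; t1 + t2 < nt; ++t2)
      f(t1 + t2) += arma::dot(b, G.col(t2));
  }
  return f;
}

// ---------------------------------------------------------------------------
// Sensitivity-matrix blocks kept on the C++ heap (single precision) so the
// full study never materializes multi-GB matrices in the R heap.

typedef Rcpp::XPtr<arma::fmat> JBlockPtr;

// [[Rcpp::export(name = ".jblock_create_cpp")]]
SEXP jblock_create_cpp(int nrow, int ncol) {
  arma::fmat* m = new arma::fmat(nrow, ncol, arma::fill::zeros);
  return JBlockPtr(m, true);
}

// [[Rcpp::export(name = ".jblock_dim_cpp")]]
IntegerVector jblock_dim_cpp(SEXP ptr) {
  JBlockPtr m(ptr);
  return IntegerVector::create(m->n_rows, m->n_cols);
}

// Fill rows of a block from gated convolution values.
// rows: 0-based destination rows; start_idx: 0-based column of C per row;
// scale: per-row factor (voxel volume / U0, Born form).
// [[Rcpp::export(name = ".jblock_fill_cpp")]]
void jblock_fill_cpp(SEXP ptr, const arma::mat& C,
                     const IntegerVector& rows, const IntegerVector& start_idx,
                     const NumericVector& scale) {
  JBlockPtr m(ptr);
  if (rows.size() != start_idx.size() || rows.size() != scale.size())
    stop("row spec lengths differ");
  for (int r = 0; r < rows.size(); ++r) {
    arma::frowvec v = arma::conv_to<arma::frowvec>::from(
      (C.col(start_idx[r]) * scale[r]).t());
    m->row(rows[r]) = v;
  }
}

// [[Rcpp::export(name = ".jblock_get_cpp")]]
arma::mat jblock_get_cpp(SEXP ptr, const IntegerVector& rows,
                         const IntegerVector& cols) {
  JBlockPtr m(ptr);
  arma::mat out(rows.size(), cols.size());
  for (int i = 0; i < rows.size(); ++i)
    for (int j = 0; j < cols.size(); ++j)
      out(i, j) = (*m)(rows[i], cols[j]);
  return out;
}

// [[Rcpp::export(name = ".jblock_matvec_cpp")]]
arma::vec jblock_matvec_cpp(SEXP ptr, const arma::vec& x) {
  JBlockPtr m(ptr);
  arma::fvec xf = arma::conv_to<arma::fvec>::from(x);
  return arma::conv_to<arma::vec>::from((*m) * xf);
}

// ---------------------------------------------------------------------------
// CGLS (conjugate gradient on the normal equations), fixed iteration count.
// The least-squares residual norm ||y - J x|| is non-increasing per iteration.

// Column norms across a virtual row-stack of blocks (for diagonal
// sensitivity scaling of the unknowns).
// [[Rcpp::export(name = ".blocks_colnorms_cpp")]]
arma::vec blocks_colnorms_cpp(List ptrs) {
  arma::vec acc;
  for (int b = 0; b < ptrs.size(); ++b) {
    JBlockPtr pp(as<SEXP>(ptrs[b]));
    arma::fvec cn = arma::sum(arma::square(*pp), 0).t();
    if (acc.n_elem == 0) acc.zeros(cn.n_elem);
    acc += arma::conv_to<arma::vec>::from(cn);
  }
  return arma::sqrt(acc);
}

// Dense double-precision variant for R matrices (tests, small systems).
// Solves min ||J diag(1/cs) z - y|| over z, returns x = z / cs (cs = 1:
// plain CGLS).
// [[Rcpp::export(name = ".cgls_dense_cpp")]]
List cgls_dense_cpp(const arma::mat& J0, const arma::vec& y, int iters,
                    const arma::vec& x0, const arma::vec& cs) {
  arma::mat J = J0;
  bool scaled = cs.n_elem == J.n_cols;
  if (scaled) J.each_row() /= arma::conv_to<arma::rowvec>::from(cs);
  arma::vec x = scaled ? arma::vec(x0 % cs) : x0;
  arma::vec r = y - J * x;
  arma::vec s = J.t() * r;
  arma::vec p = s;
  double gamma = arma::dot(s, s);
  std::vector<double> hist;
  hist.push_back(arma::norm(r));
  for (int it = 0; it < iters; ++it) {
    if (gamma <= 0 || !std::isfinite(gamma)) { hist.push_back(arma::norm(r)); continue; }
    arma::vec q = J * p;
    double qq = arma::dot(q, q);
    if (qq <= 0) { hist.push_back(arma::norm(r)); continue; }
    double alpha = gamma / qq;
    x += alpha * p;
    r -= alpha * q;
    s = J.t() * r;
    double gamma_new = arma::dot(s, s);
    p = s + (gamma_new / gamma) * p;
    gamma = gamma_new;
    hist.push_back(arma::norm(r));
  }
  if (scaled) x /= cs;
  return List::create(_["x"] = x, _["resnorm"] = wrap(hist));
}

// Block variant over a virtual row-stack of single-precision blocks.
// Column scaling is applied virtually inside the matvecs.
// [[Rcpp::export(name = ".cgls_blocks_cpp")]]
List cgls_blocks_cpp(List ptrs, List ys, int iters, const arma::vec& x0,
                     const arma::vec& cs) {
  const int nb = ptrs.size();
  std::vector<arma::fmat*> Js(nb);
  std::vector<arma::fvec> yb(nb), rb(nb);
  arma::uword ncol = 0;
  for (int b = 0; b < nb; ++b) {
    JBlockPtr pp(as<SEXP>(ptrs[b]));
    Js[b] = pp.get();
    yb[b] = arma::conv_to<arma::fvec>::from(as<arma::vec>(ys[b]));
    if (Js[b]->n_rows != yb[b].n_elem) stop("block row/data mismatch");
    ncol = Js[b]->n_cols;
  }
  const bool scaled = cs.n_elem == ncol;
  arma::fvec ics;
  if (scaled) ics = arma::conv_to<arma::fvec>::from(1.0 / cs);
  // work in the scaled unknowns z = cs * x
  arma::fvec x = arma::conv_to<arma::fvec>::from(
    scaled ? arma::vec(x0 % cs) : x0);
  auto resnorm2 = [&]() {
    double a = 0;
    for (int b = 0; b < nb; ++b) a += arma::dot(rb[b], rb[b]);
    return a;
  };
  auto matvec = [&](const arma::fvec& v, int b) -> arma::fvec {
    return scaled ? arma::fvec((*Js[b]) * (v % ics)) : arma::fvec((*Js[b]) * v);
  };
  for (int b = 0; b < nb; ++b) rb[b] = yb[b] - matvec(x, b);
  arma::fvec s(ncol, arma::fill::zeros);
  for (int b = 0; b < nb; ++b) s += Js[b]->t() * rb[b];
  if (scaled) s %= ics;
  arma::fvec p = s;
  double gamma = arma::dot(s, s);
  std::vector<double> hist;
  hist.push_back(std::sqrt(resnorm2()));
  for (int it = 0; it < iters; ++it) {
    if (gamma <= 0 || !std::isfinite(gamma)) { hist.push_back(std::sqrt(resnorm2())); continue; }
    double qq = 0;
    std::vector<arma::fvec> qb(nb);
    for (int b = 0; b < nb; ++b) {
      qb[b] = matvec(p, b);
      qq += arma::dot(qb[b], qb[b]);
    }
    if (qq <= 0) { hist.push_back(std::sqrt(resnorm2())); continue; }
    double alpha = gamma / qq;
    x += (float)alpha * p;
    for (int b = 0; b < nb; ++b) rb[b] -= (float)alpha * qb[b];
    s.zeros();
    for (int b = 0; b < nb; ++b) s += Js[b]->t() * rb[b];
    if (scaled) s %= ics;
    double gamma_new = arma::dot(s, s);
    p = s + (float)(gamma_new / gamma) * p;
    gamma = gamma_new;
    hist.push_back(std::sqrt(resnorm2()));
  }
  arma::vec xout = arma::conv_to<arma::vec>::from(x);
  if (scaled) xout /= cs;
  return List::create(_["x"] = xout, _["resnorm"] = wrap(hist));
}
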