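// Fused per-pair kernel/loss arithmetic for one training step.
//
// All O(m^2) elementwise work — squared distances from Gram matrices,
// distance-to-similarity conversion for both graphs, the fuzzy
// cross-entropy and its gradients, and the chain back to per-pair distance
// sensitivities — happens in one pass over the pairs. The surrounding
// BLAS-heavy pieces (Gram matrices, gradient accumulation against the
// embedding matrices, network backprop) stay in R. Both similarity
// matrices are symmetric, so each unordered pair is visited once and
// contributes its two ordered loss terms.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double tkern(double D, double nu, double C) {
  return C * std::exp(-(nu + 1.0) * std::log1p(D / nu));
}

// Gst: m x m Gram matrix of the structure embedding, gst = diag(Gst).
// A: manifold pair matrix — euclidean/poincare: Gram of the latent points
// (with ga = its diagonal); lorentz: the Lorentzian inner product matrix.
// av: poincare conformal denominators 1 - K |z_i|^2 (empty otherwise).
// Gy/gy: Gram/diagonal of the batch-encoding rows (0x0 when unused).
// cellof: 0-based source row per augmented row. manifold: 0/1/2 for
// euclidean/poincare/lorentz. Returns the loss, the structure pair weights
// Wst (dL/dD_st scaled by 1/D_st; empty when detached), the visualization
// pair weights Wvi (euclidean: dL/dD / D; poincare: R_ij; lorentz: Q) and
// the poincare row sums rn_i = sum_j R_ij |z_i - z_j|^2.
// [[Rcpp::export(name = ".pair_grads_cpp")]]
List pair_grads_cpp(const NumericMatrix& Gst, const NumericVector& gst,
                    const NumericMatrix& A, const NumericVector& ga,
                    const NumericVector& av,
                    const NumericMatrix& Gy, const NumericVector& gy,
                    const IntegerVector& cellof,
                    int b, int manifold,
                    double K, double nu_st, double nu_vi, double C_st,
                    double C_vi, double gamma_, double beta, double eps,
                    bool std_form, bool detach, bool squared) {
  const int m = Gst.nrow();
  const bool has_y = Gy.nrow() == m;
  NumericMatrix Wst(detach ? 0 : m, detach ? 0 : m);
  NumericMatrix Wvi(m, m);
  NumericVector rn(manifold == 1 ? m : 0);
  const double sqK = std::sqrt(K);
  const double lo = eps, hi = 1.0 - eps;
  double loss = 0.0;

  for (int j = 1; j < m; ++j) {
    const double* gstj = &Gst(0, j);
    const double* aj = &A(0, j);
    const double* gyj = has_y ? &Gy(0, j) : nullptr;
    double* wvj = &Wvi(0, j);
    double* wsj = detach ? nullptr : &Wst(0, j);
    const int cj = cellof[j];
    for (int i = 0; i < j; ++i) {
      // ---- structure graph ----
      double d2 = gst[i] + gst[j] - 2.0 * gstj[i];
      double dst = d2 > 0.0 ? std::sqrt(d2) : 0.0;
      bool own = (i < b) && (j >= b) && (cj == i);
      double dsc = own ? dst / gamma_ : dst;
      double dk_st = squared ? dsc * dsc : dsc;
      double p_st = tkern(dk_st, nu_st, C_st);
      double u_st = 2.0 * p_st * (1.0 - p_st);

      // ---- visualization graph ----
      double dvi, arg = 0.0;
      if (manifold == 0) {
        double n2 = ga[i] + ga[j] - 2.0 * aj[i];
        dvi = n2 > 0.0 ? std::sqrt(n2) : 0.0;
      } else if (manifold == 1) {
        double n2 = ga[i] + ga[j] - 2.0 * aj[i];
        if (n2 < 0.0) n2 = 0.0;
        arg = 1.0 + 2.0 * K * n2 / (av[i] * av[j]);
        dvi = std::acosh(arg) / sqK;
      } else {
        arg = -aj[i] / K;  // A holds the Lorentzian inner product
        if (arg < 1.0) arg = 1.0;
        dvi = sqK * std::acosh(arg);
      }
      double darg = dvi;
      if (has_y && beta > 0.0) {
        double y2 = gy[i] + gy[j] - 2.0 * gyj[i];
        if (y2 > 0.0) darg += beta * std::sqrt(y2);
      }
      double dk_vi = squared ? darg * darg : darg;
      double p_vi = tkern(dk_vi, nu_vi, C_vi);
      double u_vi = 2.0 * p_vi * (1.0 - p_vi);

      // ---- loss and gradients on the clamped similarities ----
      double s = u_st < lo ? lo : (u_st > hi ? hi : u_st);
      double v = u_vi < lo ? lo : (u_vi > hi ? hi : u_vi);
      double lsv = std::log(s / v);
      double lcc = std::log((1.0 - s) / (1.0 - v));
      double ds, dv;
      if (std_form) {
        loss += 2.0 * (s * lsv + (1.0 - s) * lcc);
        ds = lsv - lcc;
        dv = -s / v + (1.0 - s) / (1.0 - v);
      } else {
        loss += 2.0 * (s * lsv - (1.0 - v) * lcc);
        ds = lsv + 1.0 + (1.0 - v) / (1.0 - s);
        dv = -s / v + lcc - 1.0;
      }
      if (u_st < lo || u_st > hi) ds = 0.0;
      if (u_vi < lo || u_vi > hi) dv = 0.0;

      // ---- structure side: dL/dD_st as W = coeff / D_st ----
      if (!detach) {
        double w = 0.0;
        if (ds != 0.0 && dst > 1e-12) {
          double g = 2.0 * ds * (2.0 - 4.0 * p_st) *
            (-p_st * (nu_st + 1.0) / (nu_st + dk_st));
          if (squared) g *= 2.0 * dsc;
          if (own) g /= gamma_;
          w = g / dst;
        }
        wsj[i] = w; Wst(j, i) = w;
      }

      // ---- visualization side: dL/dDarg -> manifold pair weights ----
      double V = 0.0;
      if (dv != 0.0) {
        V = 2.0 * dv * (2.0 - 4.0 * p_vi) *
          (-p_vi * (nu_vi + 1.0) / (nu_vi + dk_vi));
        if (squared) V *= 2.0 * darg;
      }
      if (manifold == 0) {
        double w = (V != 0.0 && dvi > 1e-12) ? V / dvi : 0.0;
        wvj[i] = w; Wvi(j, i) = w;
      } else if (manifold == 1) {
        if (V != 0.0) {
          double n2 = ga[i] + ga[j] - 2.0 * aj[i];
          if (n2 < 0.0) n2 = 0.0;
          double dA = 2.0 * sqK /
            std::sqrt(std::max(arg * arg - 1.0, 1e-24));
          double Q = V * dA;
          double Rij = Q / av[j], Rji = Q / av[i];
          wvj[i] = Rij; Wvi(j, i) = Rji;
          rn[i] += Rij * n2; rn[j] += Rji * n2;
        } else {
          wvj[i] = 0.0; Wvi(j, i) = 0.0;
        }
      } else {
        double Q = 0.0;
        if (V != 0.0)
          Q = V * (sqK / std::sqrt(std::max(arg * arg - 1.0, 1e-24))) *
            (-1.0 / K);
        wvj[i] = Q; Wvi(j, i) = Q;
      }
    }
  }
  return List::create(_["loss"] = loss, _["Wst"] = Wst, _["Wvi"] = Wvi,
                      _["rn"] = rn);
}
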