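// Multilevel multinomial logistic model: joint log density with analytic
// gradients on the unconstrained scale, plus a No-U-Turn sampler with
// dual-averaging step-size adaptation and diagonal mass-matrix estimation.
//
// Unconstrained parameter layout (mirrored by param_layout() on the R side):
//   alpha[K1]
//   (F variants) beta_I[K1*m], beta_R[K1*m], beta_H[K1]
//   z_I[K1*I], z_R[K1*I]              column-major, one column per child
//   y_I[P], y_R[P]                    P = K1*(K1-1)/2, row-major lower tri
//   lsigma_I[K1], lsigma_R[K1]        log scales
//   (h variants) z_hI[K1*H], z_hR[K1*H], y_hI[P], y_hR[P],
//                lsigma_hI[K1], lsigma_hR[K1]
//
// Correlation Cholesky factors are parameterized through canonical partial
// correlations w = tanh(y); the target includes the tanh and w->L Jacobians
// so that the constrained-scale priors are exactly the model statement's.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Model {
  int K, K1, N, I, H, m;
  bool hasF, hasH;
  ivec y;                    // 0-based observed category
  uvec ii, jj, hi, hj;       // 0-based indices
  mat Xi, Xr;                // N x m
  vec xh;                    // N
  double isd, bsd, lkj_eta, ssd;
  double lw;                 // likelihood weight (0 = prior-only)
  // layout offsets
  int o_alpha, o_bI, o_bR, o_bH, o_zI, o_zR, o_yI, o_yR, o_lsI, o_lsR,
      o_zhI, o_zhR, o_yhI, o_yhR, o_lshI, o_lshR, P, total;
};

static Model make_model(const Rcpp::List& ml) {
  Model M;
  M.K = Rcpp::as<int>(ml["K"]);
  M.K1 = M.K - 1;
  M.I = Rcpp::as<int>(ml["I"]);
  M.H = Rcpp::as<int>(ml["H"]);
  M.m = Rcpp::as<int>(ml["m"]);
  M.hasF = Rcpp::as<bool>(ml["has_F"]);
  M.hasH = Rcpp::as<bool>(ml["has_h"]);
  Rcpp::IntegerVector y = ml["y"];
  M.N = y.size();
  M.y = conv_to<ivec>::from(Rcpp::as<std::vector<int>>(ml["y"])) - 1;
  M.ii = Rcpp::as<uvec>(ml["i_idx"]) - 1;
  M.jj = Rcpp::as<uvec>(ml["j_idx"]) - 1;
  if (M.hasH) {
    M.hi = Rcpp::as<uvec>(ml["hi_idx"]) - 1;
    M.hj = Rcpp::as<uvec>(ml["hj_idx"]) - 1;
  }
  if (M.hasF) {
    M.Xi = Rcpp::as<mat>(ml["X_I"]);
    M.Xr = Rcpp::as<mat>(ml["X_R"]);
    M.xh = Rcpp::as<vec>(ml["x_H"]);
  }
  M.isd = Rcpp::as<double>(ml["intercept_sd"]);
  M.bsd = Rcpp::as<double>(ml["beta_sd"]);
  M.lkj_eta = Rcpp::as<double>(ml["lkj_shape"]);
  M.ssd = Rcpp::as<double>(ml["scale_sd"]);
  M.lw = Rcpp::as<double>(ml["lik_weight"]);

  int K1 = M.K1, P = K1 * (K1 - 1) / 2;
  M.P = P;
  int o = 0;
  M.o_alpha = o; o += K1;
  if (M.hasF) {
    M.o_bI = o; o += K1 * M.m;
    M.o_bR = o; o += K1 * M.m;
    M.o_bH = o; o += K1;
  } else { M.o_bI = M.o_bR = M.o_bH = -1; }
  M.o_zI = o; o += K1 * M.I;
  M.o_zR = o; o += K1 * M.I;
  M.o_yI = o; o += P;
  M.o_yR = o; o += P;
  M.o_lsI = o; o += K1;
  M.o_lsR = o; o += K1;
  if (M.hasH) {
    M.o_zhI = o; o += K1 * M.H;
    M.o_zhR = o; o += K1 * M.H;
    M.o_yhI = o; o += P;
    M.o_yhR = o; o += P;
    M.o_lshI = o; o += K1;
    M.o_lshR = o; o += K1;
  } else { M.o_zhI = M.o_zhR = M.o_yhI = M.o_yhR = M.o_lshI = M.o_lshR = -1; }
  M.total = o;
  return M;
}

static const double LOG2PI = std::log(2.0 * M_PI);

// normalizing constant of the LKJ-Cholesky density, via the canonical
// partial correlation Beta factorization
static double lkj_logC(int d, double eta) {
  double lc = 0;
  for (int j = 0; j <= d - 2; ++j) {
    double b = eta + (d - 2 - j) / 2.0;
    lc -= (d - 1 - j) * ((2 * b - 1) * std::log(2.0) + R::lbeta(b, b));
  }
  return lc;
}

// Build L (and helpers W = partial correlations, S = running prefix scale)
// from the unconstrained vector; returns the Jacobian+LKJ log terms that
// depend only on W and the diagonal of L.
static double build_chol(const double* yv, int K1, double eta,
                         mat& L, mat& W, mat& S) {
  L.eye(K1, K1); W.zeros(K1, K1); S.zeros(K1, K1);
  double lp = 0;
  int p = 0;
  for (int i = 1; i < K1; ++i) {
    double s = 1.0;
    for (int j = 0; j < i; ++j) {
      double w = std::tanh(yv[p++]);
      W(i, j) = w;
      S(i, j) = s;
      L(i, j) = w * s;
      double a = 1.0 + 0.5 * (i - 1 - j);   // tanh + (w -> L) Jacobians
      lp += a * std::log1p(-w * w);
      s *= std::sqrt(1.0 - w * w);
    }
    L(i, i) = s;
    lp += (K1 - (i + 1) + 2 * eta - 2) * std::log(s);  // LKJ kernel
  }
  lp += lkj_logC(K1, eta);
  return lp;
}

// Backpropagate dTarget/dL (lower triangle incl. diagonal, LKJ diagonal
// terms already added by caller or here) into the unconstrained y gradient.
static void chol_backprop(const mat& L, const mat& W, const mat& S,
                          mat& gL, int K1, double eta, double* gy) {
  for (int i = 1; i < K1; ++i) {
    gL(i, i) += (K1 - (i + 1) + 2 * eta - 2) / L(i, i);
  }
  int p = 0;
  for (int i = 1; i < K1; ++i) {
    for (int l = 0; l < i; ++l) {
      double w = W(i, l);
      double omw2 = 1.0 - w * w;
      double gw = S(i, l) * gL(i, l);
      double acc = 0;
      for (int j = l + 1; j <= i; ++j) acc += L(i, j) * gL(i, j);
      gw += (-w / omw2) * acc;
      double a = 1.0 + 0.5 * (i - 1 - l);
      gy[p++] += gw * omw2 - 2.0 * a * w;
    }
  }
}

// Joint log density (likelihood + priors + Jacobians) and its gradient.
static double logp_grad(const Model& M, const vec& theta, vec& grad) {
  const int K1 = M.K1, N = M.N;
  grad.zeros(M.total);
  double lp = 0;

  const vec alpha(const_cast<double*>(theta.memptr()) + M.o_alpha, K1,
                  false, true);
  const mat ZI(const_cast<double*>(theta.memptr()) + M.o_zI, K1, M.I,
               false, true);
  const mat ZR(const_cast<double*>(theta.memptr()) + M.o_zR, K1, M.I,
               false, true);

  mat LI, WI, SI, LR, WR, SR;
  lp += build_chol(theta.memptr() + M.o_yI, K1, M.lkj_eta, LI, WI, SI);
  lp += build_chol(theta.memptr() + M.o_yR, K1, M.lkj_eta, LR, WR, SR);
  vec sigI = exp(theta.subvec(M.o_lsI, M.o_lsI + K1 - 1));
  vec sigR = exp(theta.subvec(M.o_lsR, M.o_lsR + K1 - 1));

  mat AI = LI; AI.each_col() %= sigI;
  mat AR = LR; AR.each_col() %= sigR;
  mat nuI = AI * ZI;
  mat nuR = AR * ZR;

  mat LhI, WhI, ShI, LhR, WhR, ShR, AhI, AhR, ZhIc, ZhRc, hI, hR;
  vec sighI, sighR;
  if (M.hasH) {
    lp += build_chol(theta.memptr() + M.o_yhI, K1, M.lkj_eta, LhI, WhI, ShI);
    lp += build_chol(theta.memptr() + M.o_yhR, K1, M.lkj_eta, LhR, WhR, ShR);
    sighI = exp(theta.subvec(M.o_lshI, M.o_lshI + K1 - 1));
    sighR = exp(theta.subvec(M.o_lshR, M.o_lshR + K1 - 1));
    ZhIc = mat(const_cast<double*>(theta.memptr()) + M.o_zhI, K1, M.H,
               false, true);
    ZhRc = mat(const_cast<double*>(theta.memptr()) + M.o_zhR, K1, M.H,
               false, true);
    AhI = LhI; AhI.each_col() %= sighI;
    AhR = LhR; AhR.each_col() %= sighR;
    hI = AhI * ZhIc;
    hR = AhR * ZhRc;
  }

  // linear predictor, K1 x N
  mat Eta(K1, N);
  Eta.each_col() = alpha;
  Eta += nuI.cols(M.ii);
  Eta += nuR.cols(M.jj);
  mat BI, BR;
  vec bH;
  if (M.hasF) {
    BI = mat(const_cast<double*>(theta.memptr()) + M.o_bI, K1, M.m,
             false, true);
    BR = mat(const_cast<double*>(theta.memptr()) + M.o_bR, K1, M.m,
             false, true);
    bH = vec(const_cast<double*>(theta.memptr()) + M.o_bH, K1, false, true);
    Eta += BI * M.Xi.t();
    Eta += BR * M.Xr.t();
    Eta += bH * M.xh.t();
  }
  if (M.hasH) {
    Eta += hI.cols(M.hi);
    Eta += hR.cols(M.hj);
  }

  // likelihood value and gradient wrt Eta
  mat G(K1, N);
  std::vector<double> buf(K1);
  double ll = 0;
  for (int n = 0; n < N; ++n) {
    const double* e = Eta.colptr(n);
    double mx = 0;
    for (int k = 0; k < K1; ++k) if (e[k] > mx) mx = e[k];
    double sum = std::exp(-mx);           // reference category
    for (int k = 0; k < K1; ++k) { buf[k] = std::exp(e[k] - mx); sum += buf[k]; }
    double lse = mx + std::log(sum);
    int yi = M.y[n];
    ll += (yi < K1 ? e[yi] : 0.0) - lse;
    double inv = 1.0 / sum;
    double* g = G.colptr(n);
    for (int k = 0; k < K1; ++k) g[k] = -buf[k] * inv;
    if (yi < K1) g[yi] += 1.0;
  }
  if (M.lw != 1.0) { ll *= M.lw; G *= M.lw; }
  lp += ll;

  // fixed-effect and intercept gradients (+ normal priors)
  vec galpha = sum(G, 1) - alpha / (M.isd * M.isd);
  grad.subvec(M.o_alpha, M.o_alpha + K1 - 1) = galpha;
  lp += -0.5 * dot(alpha, alpha) / (M.isd * M.isd)
        - K1 * (0.5 * LOG2PI + std::log(M.isd));
  if (M.hasF) {
    mat gBI = G * M.Xi - BI / (M.bsd * M.bsd);
    mat gBR = G * M.Xr - BR / (M.bsd * M.bsd);
    vec gbH = G * M.xh - bH / (M.bsd * M.bsd);
    std::copy(gBI.memptr(), gBI.memptr() + K1 * M.m,
              grad.memptr() + M.o_bI);
    std::copy(gBR.memptr(), gBR.memptr() + K1 * M.m,
              grad.memptr() + M.o_bR);
    std::copy(gbH.memptr(), gbH.memptr() + K1, grad.memptr() + M.o_bH);
    double nb = K1 * (2 * M.m + 1);
    lp += -0.5 * (accu(square(BI)) + accu(square(BR)) + dot(bH, bH))
            / (M.bsd * M.bsd)
          - nb * (0.5 * LOG2PI + std::log(M.bsd));
  }

  // scatter event gradients to units
  mat GI(K1, M.I, fill::zeros), GR(K1, M.I, fill::zeros);
  for (int n = 0; n < N; ++n) {
    GI.col(M.ii[n]) += G.col(n);
    GR.col(M.jj[n]) += G.col(n);
  }
  mat GhI, GhR;
  if (M.hasH) {
    GhI.zeros(K1, M.H); GhR.zeros(K1, M.H);
    for (int n = 0; n < N; ++n) {
      GhI.col(M.hi[n]) += G.col(n);
      GhR.col(M.hj[n]) += G.col(n);
    }
  }

  // per-role block: z, log-sigma and correlation gradients + priors
  auto role_block = [&](const mat& Gn, const mat& Z, const mat& L,
                        const mat& W, const mat& S, const mat& A,
                        const vec& sig, int o_z, int o_y, int o_ls) {
    int n_units = Z.n_cols;
    mat gZ = A.t() * Gn - Z;
    std::copy(gZ.memptr(), gZ.memptr() + K1 * n_units,
              grad.memptr() + o_z);
    lp += -0.5 * accu(square(Z)) - 0.5 * K1 * n_units * LOG2PI;

    mat Mlz = L * Z;
    for (int k = 0; k < K1; ++k) {
      double gsig = dot(Mlz.row(k), Gn.row(k));
      grad[o_ls + k] = (gsig - sig[k] / (M.ssd * M.ssd)) * sig[k] + 1.0;
      lp += -0.5 * sig[k] * sig[k] / (M.ssd * M.ssd)
            + std::log(sig[k]);                         // log-scale Jacobian
    }
    lp += K1 * (std::log(2.0) - std::log(M.ssd) - 0.5 * LOG2PI);

    mat gL = (Gn.each_col() % sig) * Z.t();
    chol_backprop(L, W, S, gL, K1, M.lkj_eta, grad.memptr() + o_y);
  };

  role_block(GI, ZI, LI, WI, SI, AI, sigI, M.o_zI, M.o_yI, M.o_lsI);
  role_block(GR, ZR, LR, WR, SR, AR, sigR, M.o_zR, M.o_yR, M.o_lsR);
  if (M.hasH) {
    role_block(GhI, ZhIc, LhI, WhI, ShI, AhI, sighI,
               M.o_zhI, M.o_yhI, M.o_lshI);
    role_block(GhR, ZhRc, LhR, WhR, ShR, AhR, sighR,
               M.o_zhR, M.o_yhR, M.o_lshR);
  }
  return lp;
}

// linear predictor only (for pointwise log-likelihood evaluation)
static void compute_eta(const Model& M, const vec& theta, mat& Eta) {
  const int K1 = M.K1;
  const vec alpha(const_cast<double*>(theta.memptr()) + M.o_alpha, K1,
                  false, true);
  mat LI, WI, SI, LR, WR, SR;
  build_chol(theta.memptr() + M.o_yI, K1, M.lkj_eta, LI, WI, SI);
  build_chol(theta.memptr() + M.o_yR, K1, M.lkj_eta, LR, WR, SR);
  vec sigI = exp(theta.subvec(M.o_lsI, M.o_lsI + K1 - 1));
  vec sigR = exp(theta.subvec(M.o_lsR, M.o_lsR + K1 - 1));
  mat AI = LI; AI.each_col() %= sigI;
  mat AR = LR; AR.each_col() %= sigR;
  const mat ZI(const_cast<double*>(theta.memptr()) + M.o_zI, K1, M.I,
               false, true);
  const mat ZR(const_cast<double*>(theta.memptr()) + M.o_zR, K1, M.I,
               false, true);
  mat nuI = AI * ZI, nuR = AR * ZR;
  Eta.set_size(K1, M.N);
  Eta.each_col() = alpha;
  Eta += nuI.cols(M.ii);
  Eta += nuR.cols(M.jj);
  if (M.hasF) {
    const mat BI(const_cast<double*>(theta.memptr()) + M.o_bI, K1, M.m,
                 false, true);
    const mat BR(const_cast<double*>(theta.memptr()) + M.o_bR, K1, M.m,
                 false, true);
    const vec bH(const_cast<double*>(theta.memptr()) + M.o_bH, K1,
                 false, true);
    Eta += BI * M.Xi.t() + BR * M.Xr.t() + bH * M.xh.t();
  }
  if (M.hasH) {
    mat LhI, WhI, ShI, LhR, WhR, ShR;
    build_chol(theta.memptr() + M.o_yhI, K1, M.lkj_eta, LhI, WhI, ShI);
    build_chol(theta.memptr() + M.o_yhR, K1, M.lkj_eta, LhR, WhR, ShR);
    vec sighI = exp(theta.subvec(M.o_lshI, M.o_lshI + K1 - 1));
    vec sighR = exp(theta.subvec(M.o_lshR, M.o_lshR + K1 - 1));
    mat AhI = LhI; AhI.each_col() %= sighI;
    mat AhR = LhR; AhR.each_col() %= sighR;
    const mat ZhI(const_cast<double*>(theta.memptr()) + M.o_zhI, K1, M.H,
                  false, true);
    const mat ZhR(const_cast<double*>(theta.memptr()) + M.o_zhR, K1, M.H,
                  false, true);
    mat hI = AhI * ZhI, hR = AhR * ZhR;
    Eta += hI.cols(M.hi);
    Eta += hR.cols(M.hj);
  }
}

// [[Rcpp::export]]
Rcpp::List mnl_logp_grad(const arma::vec& theta, const Rcpp::List& model) {
  Model M = make_model(model);
  if ((int)theta.n_elem != M.total) Rcpp::stop("theta has wrong length");
  vec grad;
  double lp = logp_grad(M, theta, grad);
  return Rcpp::List::create(Rcpp::Named("logp") = lp,
                            Rcpp::Named("grad") = grad);
}

// [[Rcpp::export]]
arma::mat mnl_pointwise_loglik(const arma::mat& draws,
                               const Rcpp::List& model) {
  Model M = make_model(model);
  const int S = draws.n_rows;
  mat out(S, M.N);
  mat Eta;
  std::vector<double> buf(M.K1);
  for (int s = 0; s < S; ++s) {
    vec theta = draws.row(s).t();
    compute_eta(M, theta, Eta);
    for (int n = 0; n < M.N; ++n) {
      const double* e = Eta.colptr(n);
      double mx = 0;
      for (int k = 0; k < M.K1; ++k) if (e[k] > mx) mx = e[k];
      double sum = std::exp(-mx);
      for (int k = 0; k < M.K1; ++k) sum += std::exp(e[k] - mx);
      double lse = mx + std::log(sum);
      int yi = M.y[n];
      out(s, n) = (yi < M.K1 ? e[yi] : 0.0) - lse;
    }
  }
  return out;
}

// ---------------- NUTS ----------------------------------------------------

struct TreeState {
  vec qm, pm, gm, qp, pp, gp, qprop;
  double lpm, lpp, lpprop;
  double nprop;     // subtree weight (number of valid states)
  bool s;           // no U-turn / no divergence
  double alpha_sum;
  int nalpha;
  bool divergent;
};

class Nuts {
public:
  const Model& M;
  vec minv;         // inverse (diagonal) mass
  int maxdepth;
  int n_divergent;

  Nuts(const Model& M_, const vec& minv_, int maxdepth_)
    : M(M_), minv(minv_), maxdepth(maxdepth_), n_divergent(0) {}

  double kinetic(const vec& p) const { return 0.5 * dot(p % minv, p); }

  void leapfrog(vec& q, vec& p, vec& g, double& lp, double eps) {
    p += 0.5 * eps * g;
    q += eps * (minv % p);
    lp = logp_grad(M, q, g);
    p += 0.5 * eps * g;
  }

  void build_tree(TreeState& out, const vec& q, const vec& p, const vec& g,
                  double lp, double logu, int v, int depth, double eps,
                  double H0) {
    if (depth == 0) {
      vec q1 = q, p1 = p, g1 = g;
      double lp1 = lp;
      leapfrog(q1, p1, g1, lp1, v * eps);
      double joint = std::isfinite(lp1) ? lp1 - kinetic(p1) : -datum::inf;
      out.qm = q1; out.pm = p1; out.gm = g1; out.lpm = lp1;
      out.qp = q1; out.pp = p1; out.gp = g1; out.lpp = lp1;
      out.qprop = q1; out.lpprop = lp1;
      out.nprop = (logu <= joint) ? 1.0 : 0.0;
      out.divergent = (logu - 1000.0 > joint) || !std::isfinite(joint);
      out.s = !out.divergent;
      double a = std::exp(std::min(0.0, joint - H0));
      out.alpha_sum = std::isfinite(a) ? a : 0.0;
      out.nalpha = 1;
      return;
    }
    TreeState first;
    build_tree(first, q, p, g, lp, logu, v, depth - 1, eps, H0);
    out = first;
    if (!first.s) return;
    TreeState second;
    if (v == -1) {
      build_tree(second, first.qm, first.pm, first.gm, first.lpm,
                 logu, v, depth - 1, eps, H0);
      out.qm = second.qm; out.pm = second.pm; out.gm = second.gm;
      out.lpm = second.lpm;
    } else {
      build_tree(second, first.qp, first.pp, first.gp, first.lpp,
                 logu, v, depth - 1, eps, H0);
      out.qp = second.qp; out.pp = second.pp; out.gp = second.gp;
      out.lpp = second.lpp;
    }
    double ntot = first.nprop + second.nprop;
    if (ntot > 0 && ::unif_rand() < second.nprop / ntot) {
      out.qprop = second.qprop;
      out.lpprop = second.lpprop;
    }
    out.nprop = ntot;
    out.alpha_sum = first.alpha_sum + second.alpha_sum;
    out.nalpha = first.nalpha + second.nalpha;
    vec dq = out.qp - out.qm;
    out.s = first.s && second.s &&
      (dot(dq, minv % out.pm) >= 0) && (dot(dq, minv % out.pp) >= 0);
    out.divergent = first.divergent || second.divergent;
  }

  // one NUTS transition; returns accept-stat and updates q/g/lp in place
  double transition(vec& q, vec& g, double& lp, double eps, int& depth_out,
                    bool& divergent_out) {
    int D = q.n_elem;
    vec p0(D);
    for (int i = 0; i < D; ++i) p0[i] = ::norm_rand() / std::sqrt(minv[i]);
    double H0 = lp - kinetic(p0);
    double logu = H0 - ::exp_rand();

    vec qm = q, qp = q, pm = p0, pp = p0, gm = g, gp = g;
    double lpm = lp, lpp = lp;
    vec qprop = q;
    double lpprop = lp;
    double n = 1.0;
    bool s = true;
    int j = 0;
    double alpha_sum = 0; int nalpha = 0;
    divergent_out = false;

    while (s && j < maxdepth) {
      int v = (::unif_rand() < 0.5) ? -1 : 1;
      TreeState sub;
      if (v == -1) {
        build_tree(sub, qm, pm, gm, lpm, logu, v, j, eps, H0);
        qm = sub.qm; pm = sub.pm; gm = sub.gm; lpm = sub.lpm;
      } else {
        build_tree(sub, qp, pp, gp, lpp, logu, v, j, eps, H0);
        qp = sub.qp; pp = sub.pp; gp = sub.gp; lpp = sub.lpp;
      }
      alpha_sum += sub.alpha_sum; nalpha += sub.nalpha;
      if (sub.divergent) divergent_out = true;
      if (sub.s && sub.nprop > 0 && ::unif_rand() < sub.nprop / n) {
        qprop = sub.qprop;
        lpprop = sub.lpprop;
      }
      n += sub.nprop;
      vec dq = qp - qm;
      s = sub.s && (dot(dq, minv % pm) >= 0) && (dot(dq, minv % pp) >= 0);
      ++j;
    }
    depth_out = j;
    if (divergent_out) ++n_divergent;
    q = qprop;
    lp = logp_grad(M, q, g);   // refresh gradient at the accepted point
    return nalpha > 0 ? alpha_sum / nalpha : 0.0;
  }
};

static double find_epsilon(Nuts& nuts, const vec& q0, const vec& g0,
                           double lp0) {
  double eps = 0.1;
  int D = q0.n_elem;
  vec p(D);
  for (int i = 0; i < D; ++i) p[i] = ::norm_rand() / std::sqrt(nuts.minv[i]);
  double H0 = lp0 - nuts.kinetic(p);
  vec q = q0, g = g0, p1 = p;
  double lp = lp0;
  nuts.leapfrog(q, p1, g, lp, eps);
  double H1 = std::isfinite(lp) ? lp - nuts.kinetic(p1) : -datum::inf;
  double dir = (H1 - H0 > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; ++it) {
    eps *= std::pow(2.0, dir);
    q = q0; g = g0; p1 = p; lp = lp0;
    nuts.leapfrog(q, p1, g, lp, eps);
    H1 = std::isfinite(lp) ? lp - nuts.kinetic(p1) : -datum::inf;
    if (dir > 0 && H1 - H0 <= std::log(0.5)) break;
    if (dir < 0 && H1 - H0 > std::log(0.5)) break;
  }
  return eps;
}

// [[Rcpp::export]]
Rcpp::List mnl_nuts(const Rcpp::List& model, const arma::vec& theta0,
                    int iter, int warmup, double target_accept,
                    int max_treedepth) {
  Model M = make_model(model);
  if ((int)theta0.n_elem != M.total) Rcpp::stop("theta0 has wrong length");
  if (warmup >= iter) Rcpp::stop("warmup must be < iter");
  vec minv(M.total, fill::ones);
  Nuts nuts(M, minv, max_treedepth);

  vec q = theta0, g;
  double lp = logp_grad(M, q, g);
  if (!std::isfinite(lp)) {
    Rcpp::stop("non-finite log density at the initial point");
  }

  // dual averaging (Hoffman & Gelman)
  double eps = find_epsilon(nuts, q, g, lp);
  double mu = std::log(10.0 * eps), logeps = std::log(eps),
         logepsbar = 0.0, Hbar = 0.0;
  const double gamma_da = 0.05, t0 = 10.0, kappa = 0.75;
  int t_da = 0;

  // mass-matrix adaptation windows (Stan-style growing windows)
  int a_init = std::min(75, std::max(1, warmup / 5));
  int a_term = std::min(50, std::max(1, warmup / 10));
  int win_size = 25;
  int win_end = std::min(a_init + win_size, warmup - a_term);
  bool adapt_mass = (warmup - a_init - a_term) >= 20;
  vec wf_mean(M.total, fill::zeros), wf_m2(M.total, fill::zeros);
  int wf_n = 0;

  int n_keep = iter - warmup;
  mat draws(n_keep, M.total);
  vec lp_keep(n_keep);
  ivec depths(iter);
  vec astats(iter);
  int div_sampling = 0;

  for (int it = 0; it < iter; ++it) {
    bool in_warmup = it < warmup;
    int depth; bool div;
    double astat = nuts.transition(q, g, lp, eps, depth, div);
    depths[it] = depth;
    astats[it] = astat;
    if (!in_warmup && div) ++div_sampling;

    if (in_warmup) {
      // step-size adaptation
      ++t_da;
      double w = 1.0 / (t_da + t0);
      Hbar = (1 - w) * Hbar + w * (target_accept - astat);
      logeps = mu - std::sqrt((double)t_da) / gamma_da * Hbar;
      double eta = std::pow((double)t_da, -kappa);
      logepsbar = eta * logeps + (1 - eta) * logepsbar;
      eps = std::exp(logeps);

      if (adapt_mass && it >= a_init && it < warmup - a_term) {
        ++wf_n;
        vec d = q - wf_mean;
        wf_mean += d / wf_n;
        wf_m2 += d % (q - wf_mean);
        if (it + 1 == win_end) {
          vec var = wf_m2 / std::max(1, wf_n - 1);
          // Stan's regularization toward unit scale
          double nreg = wf_n;
          minv = (nreg / (nreg + 5.0)) * var
                 + 1e-3 * (5.0 / (nreg + 5.0)) * ones(M.total);
          nuts.minv = minv;
          wf_mean.zeros(); wf_m2.zeros(); wf_n = 0;
          // restart step-size adaptation around the current step
          eps = find_epsilon(nuts, q, g, lp);
          mu = std::log(10.0 * eps);
          logeps = std::log(eps);
          Hbar = 0.0; t_da = 0; logepsbar = 0.0;
          win_size *= 2;
          win_end = it + 1 + win_size;
          if (warmup - a_term - win_end < 2 * win_size) {
            win_end = warmup - a_term;
          }
        }
      }
      if (it + 1 == warmup) eps = std::exp(logepsbar);
    } else {
      draws.row(it - warmup) = q.t();
      lp_keep[it - warmup] = lp;
    }
    if ((it + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("draws") = draws,
    Rcpp::Named("logp") = lp_keep,
    Rcpp::Named("stepsize") = eps,
    Rcpp::Named("inv_mass") = minv,
    Rcpp::Named("divergences") = div_sampling,
    Rcpp::Named("treedepth") = depths,
    Rcpp::Named("accept_stat") = astats);
}
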