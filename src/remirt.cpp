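// Core numerical routines: the full GVEM EM loop and the importance-weighted
// objective/gradient. These mirror the reference R implementations in
// R/gvem-steps.R and R/iw.R exactly (same update order, same identification
// rescaling); a test pins the two engines together.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <cstring>
using namespace arma;

static inline double softplus(double x) {
  return std::max(x, 0.0) + std::log1p(std::exp(-std::fabs(x)));
}

// Cody-Waite/Cephes-style exp for the hot loops: ~1 ulp on the range used
// (arguments are -|logit|, clamped far above underflow). ~3x faster than
// libm on this toolchain.
static inline double fast_exp(double x) {
  if (x < -700.0) return 0.0;
  double fx = std::floor(1.4426950408889634 * x + 0.5);
  int n = (int)fx;
  x -= fx * 6.93145751953125e-1;
  x -= fx * 1.42860682030941723212e-6;
  double xx = x * x;
  double px = x * (9.99999999999999999910e-1 +
                   xx * (3.02994407707441961300e-2 +
                         xx * 1.26177193074810590878e-4));
  double qx = 2.00000000000000000005e0 +
    xx * (2.27265548208155028766e-1 +
          xx * (2.52448340349684104192e-3 +
                xx * 3.00198505138664455042e-6));
  double e = px / (qx - px);
  // scale by 2^n via exponent bits (n is in [-1011, 2] here, no denormals)
  union { double d; long long i; } sc;
  sc.i = (long long)(n + 1023) << 52;
  return (1.0 + 2.0 * e) * sc.d;
}

// log(1 + e) for e in (0, 1]: atanh series with s = e/(2+e) <= 1/3,
// absolute error below ~1e-9 (worst case at e = 1)
static inline double fast_log1p01(double e) {
  double s = e / (2.0 + e);
  double s2 = s * s;
  return 2.0 * s * (1.0 + s2 * (1.0 / 3 + s2 * (1.0 / 5 + s2 * (1.0 / 7 +
         s2 * (1.0 / 9 + s2 * (1.0 / 11 + s2 * (1.0 / 13 + s2 / 15)))))));
}

// For a vector of logits x: softplus(x) -> sp, sigmoid(x) -> sig.
// Two-lane SSE2 implementation of the same arithmetic as the scalar
// helpers above (x86-64 always has SSE2; scalar fallback otherwise).
#if defined(__SSE2__)
#include <emmintrin.h>
static void softplus_sigmoid_vec(const double* x, double* sp, double* sig,
                                 int n) {
  const __m128d c_zero = _mm_setzero_pd();
  const __m128d c_one = _mm_set1_pd(1.0);
  const __m128d c_two = _mm_set1_pd(2.0);
  const __m128d c_half = _mm_set1_pd(0.5);
  const __m128d c_log2e = _mm_set1_pd(1.4426950408889634);
  const __m128d c_c1 = _mm_set1_pd(6.93145751953125e-1);
  const __m128d c_c2 = _mm_set1_pd(1.42860682030941723212e-6);
  const __m128d c_clamp = _mm_set1_pd(-700.0);
  const __m128d sign_mask = _mm_set1_pd(-0.0);
  const __m128d p0 = _mm_set1_pd(9.99999999999999999910e-1);
  const __m128d p1 = _mm_set1_pd(3.02994407707441961300e-2);
  const __m128d p2 = _mm_set1_pd(1.26177193074810590878e-4);
  const __m128d q0 = _mm_set1_pd(2.00000000000000000005e0);
  const __m128d q1 = _mm_set1_pd(2.27265548208155028766e-1);
  const __m128d q2 = _mm_set1_pd(2.52448340349684104192e-3);
  const __m128d q3 = _mm_set1_pd(3.00198505138664455042e-6);
  const __m128d t3 = _mm_set1_pd(1.0 / 3), t5 = _mm_set1_pd(1.0 / 5),
    t7 = _mm_set1_pd(1.0 / 7), t9 = _mm_set1_pd(1.0 / 9),
    t11 = _mm_set1_pd(1.0 / 11), t13 = _mm_set1_pd(1.0 / 13),
    t15 = _mm_set1_pd(1.0 / 15);

  int i = 0;
  for (; i + 2 <= n; i += 2) {
    __m128d xv = _mm_loadu_pd(x + i);
    __m128d ax = _mm_andnot_pd(sign_mask, xv);      // |x|
    __m128d z = _mm_max_pd(_mm_sub_pd(c_zero, ax), c_clamp);  // -|x|
    // n = floor(z * log2e + 0.5), via truncate-and-adjust (SSE2 only)
    __m128d fz = _mm_add_pd(_mm_mul_pd(z, c_log2e), c_half);
    __m128i ti = _mm_cvttpd_epi32(fz);
    __m128d td = _mm_cvtepi32_pd(ti);
    __m128d adj = _mm_and_pd(_mm_cmpgt_pd(td, fz), c_one);
    td = _mm_sub_pd(td, adj);
    // reduced argument
    __m128d r = _mm_sub_pd(z, _mm_mul_pd(td, c_c1));
    r = _mm_sub_pd(r, _mm_mul_pd(td, c_c2));
    __m128d rr = _mm_mul_pd(r, r);
    __m128d px = _mm_mul_pd(r, _mm_add_pd(p0, _mm_mul_pd(rr,
                  _mm_add_pd(p1, _mm_mul_pd(rr, p2)))));
    __m128d qx = _mm_add_pd(q0, _mm_mul_pd(rr, _mm_add_pd(q1,
                  _mm_mul_pd(rr, _mm_add_pd(q2, _mm_mul_pd(rr, q3))))));
    __m128d ex = _mm_div_pd(px, _mm_sub_pd(qx, px));
    __m128d mant = _mm_add_pd(c_one, _mm_add_pd(ex, ex));
    // 2^n from exponent bits: (n + 1023) << 20 in the high dword
    __m128i nb = _mm_add_epi32(_mm_cvttpd_epi32(td), _mm_set1_epi32(1023));
    __m128i hi = _mm_slli_epi32(nb, 20);
    __m128i bits = _mm_unpacklo_epi32(_mm_setzero_si128(), hi);
    __m128d e = _mm_mul_pd(mant, _mm_castsi128_pd(bits)); // exp(-|x|)
    // softplus = max(x,0) + log1p(e) via atanh series
    __m128d s = _mm_div_pd(e, _mm_add_pd(c_two, e));
    __m128d s2 = _mm_mul_pd(s, s);
    __m128d ser = _mm_add_pd(t13, _mm_mul_pd(s2, t15));
    ser = _mm_add_pd(t11, _mm_mul_pd(s2, ser));
    ser = _mm_add_pd(t9, _mm_mul_pd(s2, ser));
    ser = _mm_add_pd(t7, _mm_mul_pd(s2, ser));
    ser = _mm_add_pd(t5, _mm_mul_pd(s2, ser));
    ser = _mm_add_pd(t3, _mm_mul_pd(s2, ser));
    ser = _mm_add_pd(c_one, _mm_mul_pd(s2, ser));
    __m128d l1p = _mm_mul_pd(_mm_mul_pd(_mm_add_pd(s, s), ser), c_one);
    __m128d spv = _mm_add_pd(_mm_max_pd(xv, c_zero), l1p);
    _mm_storeu_pd(sp + i, spv);
    // sigmoid = (x >= 0 ? 1 : e) / (1 + e)
    __m128d pos = _mm_cmpge_pd(xv, c_zero);
    __m128d num = _mm_or_pd(_mm_and_pd(pos, c_one), _mm_andnot_pd(pos, e));
    _mm_storeu_pd(sig + i, _mm_div_pd(num, _mm_add_pd(c_one, e)));
  }
  for (; i < n; ++i) {
    double e = fast_exp(-std::fabs(x[i]));
    sp[i] = std::max(x[i], 0.0) + fast_log1p01(e);
    sig[i] = (x[i] >= 0.0) ? 1.0 / (1.0 + e) : e / (1.0 + e);
  }
}
#else
static void softplus_sigmoid_vec(const double* x, double* sp, double* sig,
                                 int n) {
  for (int i = 0; i < n; ++i) {
    double e = fast_exp(-std::fabs(x[i]));
    sp[i] = std::max(x[i], 0.0) + fast_log1p01(e);
    sig[i] = (x[i] >= 0.0) ? 1.0 / (1.0 + e) : e / (1.0 + e);
  }
}
#endif

static inline double eta_fun(double xi) {
  if (xi < 1e-8) return 0.125;
  return std::tanh(xi / 2.0) / (4.0 * xi);
}

// [[Rcpp::export]]
Rcpp::List gvem_em_cpp(const arma::mat& Y, const arma::uvec& group0,
                       const arma::mat& Q,
                       const arma::mat& A_in, const arma::vec& B_in,
                       const arma::cube& Gamma_in, const arma::mat& Beta_in,
                       const arma::mat& Mu_in, const arma::cube& Sigma_in,
                       const arma::mat& MuStar_in,
                       const arma::cube& SigmaStar_in,
                       const arma::mat& Xi_in,
                       double lambda,
                       const arma::cube& gfix, const arma::mat& bfix,
                       double tol, int max_iter, bool update_dif,
                       double ridge, int stage = 0) {
  // explicit working copies: the Rcpp glue hands some arguments (notably
  // cubes) views of the caller's memory, and this function must never
  // mutate its R inputs in place
  arma::mat A = A_in, Beta = Beta_in, Mu = Mu_in, MuStar = MuStar_in,
    Xi = Xi_in;
  arma::vec B = B_in;
  arma::cube Gamma = Gamma_in, Sigma = Sigma_in, SigmaStar = SigmaStar_in;
  const uword N = Y.n_rows, J = Y.n_cols, K = Q.n_cols, G = Mu.n_rows;
  const double thr = lambda * (double)N;

  std::vector<std::vector<uword>> members(G);
  for (uword i = 0; i < N; ++i) members[group0(i)].push_back(i);

  // per-item support sets
  std::vector<uvec> supp(J);
  for (uword j = 0; j < J; ++j) supp[j] = find(Q.row(j).t() > 0.5);

  std::vector<double> trace;
  trace.reserve(64);
  bool converged = false;
  int iter = 0;
  cube Mi(K, K, N);  // Sigma*_i + mu* mu*'

  for (iter = 1; iter <= max_iter; ++iter) {
    mat A_old = A; vec B_old = B; cube G_old = Gamma; mat Be_old = Beta;
    mat Mu_old = Mu; cube S_old = Sigma;

    // group-level pieces
    std::vector<mat> Aeff(G), Sinv(G);
    std::vector<vec> Beff(G), Sinv_mu(G);
    for (uword g = 0; g < G; ++g) {
      Aeff[g] = A + Gamma.slice(g);
      Beff[g] = B + Beta.row(g).t();
      Sinv[g] = inv_sympd(Sigma.slice(g));
      Sinv_mu[g] = Sinv[g] * Mu.row(g).t();
    }

    // --- E-step (uses current Xi) ---
    for (uword i = 0; i < N; ++i) {
      uword g = group0(i);
      mat P = Sinv[g];
      vec h = Sinv_mu[g];
      for (uword j = 0; j < J; ++j) {
        double e2 = 2.0 * eta_fun(Xi(i, j));
        const uvec& S = supp[j];
        for (uword u = 0; u < S.n_elem; ++u) {
          double au = Aeff[g](j, S(u));
          h(S(u)) += (Y(i, j) - 0.5 - e2 * Beff[g](j)) * au;
          for (uword v = 0; v < S.n_elem; ++v)
            P(S(u), S(v)) += e2 * au * Aeff[g](j, S(v));
        }
      }
      mat Sst = inv_sympd(symmatu(P));
      SigmaStar.slice(i) = Sst;
      MuStar.row(i) = (Sst * h).t();
      Mi.slice(i) = Sst + MuStar.row(i).t() * MuStar.row(i);
    }

    if (stage == 1) break;   // debug: stop after the E-step
    // --- xi update ---
    for (uword i = 0; i < N; ++i) {
      uword g = group0(i);
      vec mu_i = MuStar.row(i).t();
      for (uword j = 0; j < J; ++j) {
        const uvec& S = supp[j];
        double b = Beff[g](j), aMa = 0.0, am = 0.0;
        for (uword u = 0; u < S.n_elem; ++u) {
          double au = Aeff[g](j, S(u));
          am += au * mu_i(S(u));
          for (uword v = 0; v < S.n_elem; ++v)
            aMa += au * Aeff[g](j, S(v)) * Mi(S(u), S(v), i);
        }
        double x2 = aMa + 2.0 * b * am + b * b;
        Xi(i, j) = std::sqrt(std::max(x2, 0.0));
      }
    }
    mat Eta(N, J);
    for (uword i = 0; i < N; ++i)
      for (uword j = 0; j < J; ++j) Eta(i, j) = eta_fun(Xi(i, j));

    if (stage == 2) break;   // debug: stop after the xi update
    // --- M-step: B ---
    for (uword j = 0; j < J; ++j) {
      double num = 0.0, den = 0.0;
      for (uword i = 0; i < N; ++i) {
        uword g = group0(i);
        const uvec& S = supp[j];
        double am = 0.0;
        for (uword u = 0; u < S.n_elem; ++u)
          am += (A(j, S(u)) + Gamma(j, S(u), g)) * MuStar(i, S(u));
        num += Y(i, j) - 0.5 - 2.0 * Eta(i, j) * (am + Beta(g, j));
        den += 2.0 * Eta(i, j);
      }
      B(j) = num / den;
    }

    // --- M-step: A (per-item linear system on the support) ---
    for (uword j = 0; j < J; ++j) {
      const uvec& S = supp[j];
      uword s = S.n_elem;
      mat lhs(s, s, fill::zeros);
      vec rhs(s, fill::zeros);
      for (uword i = 0; i < N; ++i) {
        uword g = group0(i);
        double e2 = 2.0 * Eta(i, j);
        double btil = B(j) + Beta(g, j);
        for (uword u = 0; u < s; ++u) {
          double Mg = 0.0;
          for (uword v = 0; v < s; ++v) {
            double m = Mi(S(u), S(v), i);
            lhs(u, v) += e2 * m;
            Mg += m * Gamma(j, S(v), g);
          }
          rhs(u) += (Y(i, j) - 0.5 - e2 * btil) * MuStar(i, S(u)) - e2 * Mg;
        }
      }
      vec a;
      if (!solve(a, lhs, rhs, solve_opts::no_approx))
        a = solve(lhs + ridge * eye(s, s), rhs);
      for (uword u = 0; u < s; ++u) A(j, S(u)) = a(u);
    }

    // --- M-step: Mu (focal groups) and Sigma ---
    for (uword g = 0; g < G; ++g) {
      const std::vector<uword>& mem = members[g];
      if (g > 0) {
        vec m(K, fill::zeros);
        for (uword idx : mem) m += MuStar.row(idx).t();
        Mu.row(g) = (m / (double)mem.size()).t();
      }
      mat Sg(K, K, fill::zeros);
      for (uword idx : mem) {
        vec r = MuStar.row(idx).t() - Mu.row(g).t();
        Sg += SigmaStar.slice(idx) + r * r.t();
      }
      Sigma.slice(g) = Sg / (double)mem.size();
    }

    // --- DIF coordinate updates (groups 2..G; intercept before slopes) ---
    if (update_dif && G > 1) {
      for (uword g = 1; g < G; ++g) {
        const std::vector<uword>& mem = members[g];
        for (uword j = 0; j < J; ++j) {
          const uvec& S = supp[j];
          if (bfix(g, j) < 0.5) {
            double d = 0.0, cv = 0.0;
            for (uword idx : mem) {
              double am = 0.0;
              for (uword u = 0; u < S.n_elem; ++u)
                am += (A(j, S(u)) + Gamma(j, S(u), g)) * MuStar(idx, S(u));
              d += Y(idx, j) - 0.5 -
                2.0 * Eta(idx, j) * (am + B(j) + Beta(g, j));
              cv += 2.0 * Eta(idx, j);
            }
            double z = cv * Beta(g, j) + d;
            Beta(g, j) = (lambda > 0.0)
              ? ((z > thr) ? (z - thr) / cv : ((z < -thr) ? (z + thr) / cv : 0.0))
              : z / cv;
          }
          for (uword u = 0; u < S.n_elem; ++u) {
            uword k = S(u);
            if (gfix(j, k, g) > 0.5) continue;
            double btil = B(j) + Beta(g, j);
            double d = 0.0, cv = 0.0;
            for (uword idx : mem) {
              double Ma = 0.0;
              for (uword v = 0; v < S.n_elem; ++v)
                Ma += Mi(k, S(v), idx) * (A(j, S(v)) + Gamma(j, S(v), g));
              d += (Y(idx, j) - 0.5) * MuStar(idx, k) -
                2.0 * Eta(idx, j) * (Ma + btil * MuStar(idx, k));
              cv += 2.0 * Eta(idx, j) * Mi(k, k, idx);
            }
            double z = cv * Gamma(j, k, g) + d;
            Gamma(j, k, g) = (lambda > 0.0)
              ? ((z > thr) ? (z - thr) / cv : ((z < -thr) ? (z + thr) / cv : 0.0))
              : z / cv;
          }
        }
      }
    }

    // --- identification rescaling (transforms variational state too) ---
    vec dsc = sqrt(Sigma.slice(0).diag());
    for (uword k = 0; k < K; ++k) {
      A.col(k) *= dsc(k);
      for (uword g = 0; g < G; ++g) Gamma.slice(g).col(k) *= dsc(k);
      Mu.col(k) /= dsc(k);
      MuStar.col(k) /= dsc(k);
    }
    mat Dout = dsc * dsc.t();
    for (uword g = 0; g < G; ++g) Sigma.slice(g) /= Dout;
    for (uword i = 0; i < N; ++i) SigmaStar.slice(i) /= Dout;
    Mu.row(0).zeros();

    // --- variational bound ---
    double bound = 0.0;
    for (uword g = 0; g < G; ++g) {
      Aeff[g] = A + Gamma.slice(g);
      Beff[g] = B + Beta.row(g).t();
      Sinv[g] = inv_sympd(Sigma.slice(g));
    }
    vec logdetS(G);
    for (uword g = 0; g < G; ++g) {
      double v, sg; log_det(v, sg, Sigma.slice(g)); logdetS(g) = v;
    }
    for (uword i = 0; i < N; ++i) {
      uword g = group0(i);
      vec mu_i = MuStar.row(i).t();
      mat Sst = SigmaStar.slice(i);
      mat M = Sst + mu_i * mu_i.t();
      for (uword j = 0; j < J; ++j) {
        const uvec& S = supp[j];
        double b = Beff[g](j), am = 0.0, aMa = 0.0;
        for (uword u = 0; u < S.n_elem; ++u) {
          double au = Aeff[g](j, S(u));
          am += au * mu_i(S(u));
          for (uword v = 0; v < S.n_elem; ++v)
            aMa += au * Aeff[g](j, S(v)) * M(S(u), S(v));
        }
        double ex = am + b;
        double exx = aMa + 2.0 * b * am + b * b;
        double xi = Xi(i, j);
        bound += -softplus(-xi) + (Y(i, j) - 0.5) * ex - xi / 2.0 -
          eta_fun(xi) * (exx - xi * xi);
      }
      double v, sg; log_det(v, sg, Sst);
      vec r = mu_i - Mu.row(g).t();
      bound += 0.5 * (v - logdetS(g) - accu(Sinv[g] % Sst) -
                      dot(r, Sinv[g] * r) + (double)K);
    }
    // during penalized runs the monotone quantity is the penalized
    // objective; with lambda = 0 this is the bound itself
    if (lambda > 0.0) {
      bound -= thr * (accu(abs(Beta)) + accu(abs(Gamma)));
    }
    trace.push_back(bound);

    // --- convergence ---
    double diff = 0.0;
    diff = std::max(diff, abs(A - A_old).max());
    diff = std::max(diff, abs(B - B_old).max());
    diff = std::max(diff, abs(Gamma - G_old).max());
    diff = std::max(diff, abs(Beta - Be_old).max());
    diff = std::max(diff, abs(Mu - Mu_old).max());
    diff = std::max(diff, abs(Sigma - S_old).max());
    if (diff < tol) { converged = true; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("A") = A, Rcpp::Named("B") = B, Rcpp::Named("Gamma") = Gamma,
    Rcpp::Named("Beta") = Beta, Rcpp::Named("Mu") = Mu,
    Rcpp::Named("Sigma") = Sigma, Rcpp::Named("MuStar") = MuStar,
    Rcpp::Named("SigmaStar") = SigmaStar, Rcpp::Named("Xi") = Xi,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("n_iter") = std::min(iter, max_iter),
    Rcpp::Named("converged") = converged);
}

// importance-weighted bound and (optionally) its gradient with respect to
// all structural parameters, with group covariances given by lower
// Cholesky factors L. Persons must be sorted by group (the R wrappers
// reorder once per fit; the bound and its gradient are order-invariant).
// Theta holds M consecutive sample rows per person. The computation is
// blocked per group so the heavy lifting is BLAS level-3 plus one
// elementwise pass for the logistic terms.
// [[Rcpp::export]]
Rcpp::List iw_value_grad_cpp(const arma::mat& Y, const arma::uvec& group0,
                             const arma::mat& A, const arma::vec& B,
                             const arma::cube& Gamma, const arma::mat& Beta,
                             const arma::mat& Mu, const arma::cube& Lc,
                             const arma::mat& Theta, const arma::vec& logq,
                             int M, bool want_grad) {
  const uword N = Y.n_rows, J = Y.n_cols, K = A.n_cols, G = Mu.n_rows;
  const double log2pi = std::log(2.0 * M_PI);
  const double logM = std::log((double)M);

  mat gA(J, K, fill::zeros), gBeta(G, J, fill::zeros), gMu(G, K, fill::zeros);
  vec gB(J, fill::zeros);
  cube gGamma(J, K, G, fill::zeros), gL(K, K, G, fill::zeros);
  double value = 0.0;

  uword start = 0;  // first person of the current group block
  for (uword g = 0; g < G; ++g) {
    uword stop = start;
    while (stop < N && group0(stop) == g) ++stop;
    if (stop == start) { continue; }
    const uword ng = stop - start, R = ng * M;

    mat Aeff = A + Gamma.slice(g);
    vec Beff = B + Beta.row(g).t();
    mat invL = inv(trimatl(Lc.slice(g)));
    mat Sinv = invL.t() * invL;
    double logdetL = accu(log(Lc.slice(g).diag()));

    mat Th = Theta.rows(start * M, stop * M - 1);   // R x K
    mat X = Th * Aeff.t();                          // R x J logits
    X.each_row() += Beff.t();

    // elementwise pass: accumulate log p(Y_i|theta) per row; overwrite X
    // with the response probabilities when the gradient is needed
    vec llrow(R, fill::zeros);
    vec spbuf(R), sigbuf(R);
    for (uword j = 0; j < J; ++j) {
      const double* ycol = Y.colptr(j) + start;
      double* xcol = X.colptr(j);
      double* ll = llrow.memptr();
      double* sp = spbuf.memptr();
      double* sg = sigbuf.memptr();
      softplus_sigmoid_vec(xcol, sp, sg, (int)R);
      for (uword p = 0; p < ng; ++p) {
        uword a = p * M, b = (p + 1) * M;
        if (ycol[p] > 0.5) {
          for (uword r = a; r < b; ++r) ll[r] += xcol[r] - sp[r];
        } else {
          for (uword r = a; r < b; ++r) ll[r] -= sp[r];
        }
      }
      if (want_grad) std::memcpy(xcol, sg, R * sizeof(double));
    }

    // Gaussian prior log-density per row
    mat Rc = Th;
    Rc.each_row() -= Mu.row(g);
    mat Z = Rc * invL.t();
    vec lp = -0.5 * sum(square(Z), 1) - logdetL - 0.5 * (double)K * log2pi;
    vec logw = llrow + lp - logq.subvec(start * M, stop * M - 1);

    // per-person log-mean-exp and normalized weights
    vec v(R);
    for (uword p = 0; p < ng; ++p) {
      uword a = p * M;
      double mx = logw.subvec(a, a + M - 1).max();
      double sw = 0.0;
      for (int m = 0; m < M; ++m) {
        double w = fast_exp(logw(a + m) - mx);
        v(a + m) = w;
        sw += w;
      }
      value += mx + std::log(sw) - logM;
      if (want_grad) {
        for (int m = 0; m < M; ++m) v(a + m) /= sw;
      }
    }

    if (want_grad) {
      // X now holds sigmoid(x); overwrite with v * (y - sigmoid)
      for (uword j = 0; j < J; ++j) {
        const double* ycol = Y.colptr(j) + start;
        double* xcol = X.colptr(j);
        const double* vp = v.memptr();
        for (uword p = 0; p < ng; ++p) {
          double y = ycol[p];
          for (uword r = p * M; r < (p + 1) * M; ++r)
            xcol[r] = vp[r] * (y - xcol[r]);
        }
      }
      mat ga = X.t() * Th;                 // J x K score cross-products
      vec gb = sum(X, 0).t();
      gA += ga;
      gGamma.slice(g) = ga;
      gB += gb;
      gBeta.row(g) = gb.t();
      vec S1 = Rc.t() * v;
      mat S2 = (Rc.each_col() % v).t() * Rc;
      gMu.row(g) = (Sinv * S1).t();
      mat gl = trimatl(Sinv * S2 * invL.t());
      gl.diag() -= (double)ng / Lc.slice(g).diag();
      gL.slice(g) = gl;
    }
    start = stop;
  }

  return Rcpp::List::create(
    Rcpp::Named("value") = value, Rcpp::Named("gA") = gA,
    Rcpp::Named("gB") = gB, Rcpp::Named("gGamma") = gGamma,
    Rcpp::Named("gBeta") = gBeta, Rcpp::Named("gMu") = gMu,
    Rcpp::Named("gL") = gL);
}
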