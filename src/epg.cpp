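// Extended phase graph (EPG) kernel for CPMG-style echo trains.
//
// State convention (Weigel): Fp[n] = F_{+n}, Fm[n] = conj(F_{-n}), Z[n],
// orders n = 0..K. Consistency: Fm[0] == conj(Fp[0]); Z[0] stays real.
// One echo period: relax(esp/2) -> shift -> RF(alpha_j, phi_j) ->
// relax(esp/2) -> shift -> record |Fp[0]|.
//
// The adjoint sweep backpropagates the squared-error cost through the
// (real-)linear operator chain, giving the gradient of the cost with respect
// to the complex per-pulse transmit scale at the price of ~2 forward passes,
// independent of the number of shim variables.

#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cd;

struct EpgState {
  std::vector<cd> Fp, Fm, Z;
  explicit EpgState(int K) : Fp(K + 1), Fm(K + 1), Z(K + 1) {}
};

static inline void relax(EpgState& s, double e1, double e2, double m0 = 1.0) {
  const int K = (int)s.Fp.size() - 1;
  for (int n = 0; n <= K; ++n) {
    s.Fp[n] *= e2; s.Fm[n] *= e2; s.Z[n] *= e1;
  }
  s.Z[0] += (1.0 - e1) * m0;
}

// adjoint of relax: transpose of the diagonal scaling; constants drop
static inline void relax_adj(EpgState& l, double e1, double e2) {
  const int K = (int)l.Fp.size() - 1;
  for (int n = 0; n <= K; ++n) {
    l.Fp[n] *= e2; l.Fm[n] *= e2; l.Z[n] *= e1;
  }
}

// dephasing by one unit: all configuration orders move up by one
static inline void shift(EpgState& s) {
  const int K = (int)s.Fp.size() - 1;
  for (int n = K; n >= 1; --n) s.Fp[n] = s.Fp[n - 1];
  s.Fp[0] = std::conj(s.Fm[1]);
  for (int n = 0; n <= K - 1; ++n) s.Fm[n] = s.Fm[n + 1];
  s.Fm[K] = cd(0.0, 0.0);
}

static inline void shift_adj(EpgState& l) {
  const int K = (int)l.Fp.size() - 1;
  // reverse of: newFp[n]=Fp[n-1] (n>=1); newFp[0]=conj(Fm[1]);
  //             newFm[n]=Fm[n+1] (n<=K-1); newFm[K]=0
  cd lam_fp0 = l.Fp[0];
  for (int n = 0; n <= K - 1; ++n) l.Fp[n] = l.Fp[n + 1];
  l.Fp[K] = cd(0.0, 0.0);
  for (int n = K; n >= 1; --n) l.Fm[n] = l.Fm[n - 1];
  l.Fm[0] = cd(0.0, 0.0);
  l.Fm[1] += std::conj(lam_fp0);
}

struct RfMat { cd m[3][3]; };

static inline RfMat rf_matrix(double alpha, double phi) {
  const double c2 = std::cos(alpha / 2) * std::cos(alpha / 2);
  const double s2 = std::sin(alpha / 2) * std::sin(alpha / 2);
  const double sa = std::sin(alpha), ca = std::cos(alpha);
  const cd eip = std::polar(1.0, phi), ei2p = std::polar(1.0, 2 * phi);
  const cd I(0.0, 1.0);
  RfMat M;
  M.m[0][0] = c2;                 M.m[0][1] = ei2p * s2;            M.m[0][2] = -I * eip * sa;
  M.m[1][0] = std::conj(ei2p) * s2; M.m[1][1] = c2;                 M.m[1][2] = I * std::conj(eip) * sa;
  M.m[2][0] = -0.5 * I * std::conj(eip) * sa; M.m[2][1] = 0.5 * I * eip * sa; M.m[2][2] = ca;
  return M;
}

static inline RfMat rf_matrix_dalpha(double alpha, double phi) {
  const double sa = std::sin(alpha), ca = std::cos(alpha);
  const cd eip = std::polar(1.0, phi), ei2p = std::polar(1.0, 2 * phi);
  const cd I(0.0, 1.0);
  RfMat M;
  M.m[0][0] = -sa / 2;            M.m[0][1] = ei2p * (sa / 2);      M.m[0][2] = -I * eip * ca;
  M.m[1][0] = std::conj(ei2p) * (sa / 2); M.m[1][1] = -sa / 2;      M.m[1][2] = I * std::conj(eip) * ca;
  M.m[2][0] = -0.5 * I * std::conj(eip) * ca; M.m[2][1] = 0.5 * I * eip * ca; M.m[2][2] = -sa;
  return M;
}

static inline RfMat rf_matrix_dphi(double alpha, double phi) {
  const double s2 = std::sin(alpha / 2) * std::sin(alpha / 2);
  const double sa = std::sin(alpha);
  const cd eip = std::polar(1.0, phi), ei2p = std::polar(1.0, 2 * phi);
  const cd I(0.0, 1.0);
  RfMat M;
  M.m[0][0] = 0;                  M.m[0][1] = 2.0 * I * ei2p * s2;  M.m[0][2] = eip * sa;
  M.m[1][0] = -2.0 * I * std::conj(ei2p) * s2; M.m[1][1] = 0;      M.m[1][2] = std::conj(eip) * sa;
  M.m[2][0] = -0.5 * std::conj(eip) * sa; M.m[2][1] = -0.5 * eip * sa; M.m[2][2] = 0;
  return M;
}

static inline void apply_rf(EpgState& s, const RfMat& M) {
  const int K = (int)s.Fp.size() - 1;
  for (int n = 0; n <= K; ++n) {
    cd a = s.Fp[n], b = s.Fm[n], c = s.Z[n];
    s.Fp[n] = M.m[0][0] * a + M.m[0][1] * b + M.m[0][2] * c;
    s.Fm[n] = M.m[1][0] * a + M.m[1][1] * b + M.m[1][2] * c;
    s.Z[n]  = M.m[2][0] * a + M.m[2][1] * b + M.m[2][2] * c;
  }
}

// lambda_in = M^H lambda_out under the pairing Re<conj(lambda), s>
static inline void apply_rf_adj(EpgState& l, const RfMat& M) {
  const int K = (int)l.Fp.size() - 1;
  for (int n = 0; n <= K; ++n) {
    cd a = l.Fp[n], b = l.Fm[n], c = l.Z[n];
    l.Fp[n] = std::conj(M.m[0][0]) * a + std::conj(M.m[1][0]) * b + std::conj(M.m[2][0]) * c;
    l.Fm[n] = std::conj(M.m[0][1]) * a + std::conj(M.m[1][1]) * b + std::conj(M.m[2][1]) * c;
    l.Z[n]  = std::conj(M.m[0][2]) * a + std::conj(M.m[1][2]) * b + std::conj(M.m[2][2]) * c;
  }
}

// Re< conj(lambda), dM * s >
static inline double pair_dM(const EpgState& l, const RfMat& dM, const EpgState& s) {
  const int K = (int)l.Fp.size() - 1;
  double acc = 0.0;
  for (int n = 0; n <= K; ++n) {
    cd a = s.Fp[n], b = s.Fm[n], c = s.Z[n];
    cd r0 = dM.m[0][0] * a + dM.m[0][1] * b + dM.m[0][2] * c;
    cd r1 = dM.m[1][0] * a + dM.m[1][1] * b + dM.m[1][2] * c;
    cd r2 = dM.m[2][0] * a + dM.m[2][1] * b + dM.m[2][2] * c;
    acc += std::real(std::conj(l.Fp[n]) * r0) + std::real(std::conj(l.Fm[n]) * r1) +
           std::real(std::conj(l.Z[n]) * r2);
  }
  return acc;
}

// Single-voxel echo train. alphas/phis in radians, length Np (pulse 1 =
// excitation). Returns Np-1 echo magnitudes; z_end = Re Z[0] after the train.
static void epg_voxel(const std::vector<double>& alphas,
                      const std::vector<double>& phis,
                      double esp, double T1, double T2, double z0, int K,
                      std::vector<double>& echoes, double& z_end,
                      std::vector<cd>* f0_store = NULL,
                      std::vector<EpgState>* pre_rf = NULL) {
  const int Np = (int)alphas.size();
  const double e1 = std::exp(-esp / 2 / T1), e2 = std::exp(-esp / 2 / T2);
  EpgState s(K);
  s.Z[0] = z0;
  if (pre_rf) pre_rf->push_back(s);
  apply_rf(s, rf_matrix(alphas[0], phis[0]));
  echoes.assign(Np - 1, 0.0);
  for (int j = 1; j < Np; ++j) {
    relax(s, e1, e2); shift(s);
    if (pre_rf) pre_rf->push_back(s);
    apply_rf(s, rf_matrix(alphas[j], phis[j]));
    relax(s, e1, e2); shift(s);
    echoes[j - 1] = std::abs(s.Fp[0]);
    if (f0_store) (*f0_store)[j - 1] = s.Fp[0];
  }
  z_end = std::real(s.Z[0]);
}

// [[Rcpp::export]]
List epg_train_cpp(NumericVector alphas, NumericVector phis, double esp,
                   double T1, double T2, double z0, int K) {
  std::vector<double> a(alphas.begin(), alphas.end());
  std::vector<double> p(phis.begin(), phis.end());
  std::vector<double> echoes; double z_end;
  epg_voxel(a, p, esp, T1, T2, z0, K, echoes, z_end);
  return List::create(_["echoes"] = wrap(echoes), _["z_end"] = z_end);
}

// [[Rcpp::export]]
NumericMatrix epg_forward_cpp(ComplexMatrix scale, NumericVector base_flips,
                              NumericVector base_phis, double esp, double T1,
                              double T2, NumericVector z0, int K) {
  const int V = scale.nrow(), Np = scale.ncol();
  NumericMatrix I(V, Np - 1);
  std::vector<double> a(Np), p(Np), echoes;
  for (int i = 0; i < V; ++i) {
    for (int j = 0; j < Np; ++j) {
      cd sc(scale(i, j).r, scale(i, j).i);
      a[j] = base_flips[j] * std::abs(sc);
      p[j] = base_phis[j] + std::arg(sc);
    }
    double z_end;
    epg_voxel(a, p, esp, T1, T2, z0[i], K, echoes, z_end);
    for (int e = 0; e < Np - 1; ++e) I(i, e) = echoes[e];
  }
  return I;
}

// Weighted squared-error cost sum_{i,e} (Cw_e * (I_ie - T_e))^2 and its
// gradient with respect to the complex scale (returned as dC/dRe + i dC/dIm).
// [[Rcpp::export]]
List dsc_cost_grad_cpp(ComplexMatrix scale, NumericVector base_flips,
                       NumericVector base_phis, double esp, double T1,
                       double T2, NumericVector z0, int K, NumericVector Cw,
                       NumericVector Tt, bool want_grad) {
  const int V = scale.nrow(), Np = scale.ncol(), Ne = Np - 1;
  const double e1 = std::exp(-esp / 2 / T1), e2 = std::exp(-esp / 2 / T2);
  double cost = 0.0;
  ComplexMatrix G(want_grad ? V : 1, want_grad ? Np : 1);
  std::vector<double> a(Np), p(Np), r(Np), echoes;
  std::vector<cd> f0(Ne);
  std::vector<EpgState> pre_rf;
  for (int i = 0; i < V; ++i) {
    for (int j = 0; j < Np; ++j) {
      cd sc(scale(i, j).r, scale(i, j).i);
      r[j] = std::abs(sc);
      a[j] = base_flips[j] * r[j];
      p[j] = base_phis[j] + ((r[j] > 0.0) ? std::arg(sc) : 0.0);
    }
    double z_end;
    pre_rf.clear();
    epg_voxel(a, p, esp, T1, T2, z0[i], K, echoes, z_end,
              want_grad ? &f0 : NULL, want_grad ? &pre_rf : NULL);
    for (int e = 0; e < Ne; ++e) {
      double d = Cw[e] * (echoes[e] - Tt[e]);
      cost += d * d;
    }
    if (!want_grad) continue;

    // backward sweep
    EpgState lam(K);
    std::vector<double> g_alpha(Np, 0.0), g_phi(Np, 0.0);
    for (int j = Np - 1; j >= 1; --j) {
      int e = j - 1;
      double mag = std::abs(f0[e]);
      double w = 2.0 * Cw[e] * Cw[e] * (echoes[e] - Tt[e]);
      if (mag > 1e-300) lam.Fp[0] += w * f0[e] / mag;
      shift_adj(lam); relax_adj(lam, e1, e2);
      g_alpha[j] = pair_dM(lam, rf_matrix_dalpha(a[j], p[j]), pre_rf[j]);
      g_phi[j]   = pair_dM(lam, rf_matrix_dphi(a[j], p[j]), pre_rf[j]);
      apply_rf_adj(lam, rf_matrix(a[j], p[j]));
      shift_adj(lam); relax_adj(lam, e1, e2);
    }
    g_alpha[0] = pair_dM(lam, rf_matrix_dalpha(a[0], p[0]), pre_rf[0]);
    g_phi[0]   = pair_dM(lam, rf_matrix_dphi(a[0], p[0]), pre_rf[0]);

    // chain rule to the complex scale: alpha = base * |s|, phi += arg(s)
    for (int j = 0; j < Np; ++j) {
      cd sc(scale(i, j).r, scale(i, j).i);
      double rr = r[j];
      double du, dv;
      if (rr < 1e-12) { du = 0.0; dv = 0.0; }
      else {
        double u = std::real(sc), v = std::imag(sc);
        du = g_alpha[j] * base_flips[j] * (u / rr) + g_phi[j] * (-v / (rr * rr));
        dv = g_alpha[j] * base_flips[j] * (v / rr) + g_phi[j] * (u / (rr * rr));
      }
      G(i, j).r = du; G(i, j).i = dv;
    }
  }
  if (want_grad) return List::create(_["cost"] = cost, _["grad"] = G);
  return List::create(_["cost"] = cost);
}
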