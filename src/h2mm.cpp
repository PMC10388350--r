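// Photon-by-photon hidden Markov core.
//
// The hidden chain lives on the instrument clock (one transition-matrix
// step per tick); photons are observed at a sparse, irregular subset of
// ticks. Likelihood propagation between photons n and n+1 therefore uses
// T^dt (dt = integer tick gap), and the Baum-Welch expected transition
// counts must include the unobserved ticks inside each gap. Both are
// computed through one eigendecomposition of T per iteration:
//   T = U diag(lambda) V  (V = U^-1, plain transposes throughout)
//   T^d propagation:      a' T^d = ((a'U) .* lambda^d) V
//   gap transition sums:  sum_d (T'^d u)(T^{dt-1-d} w)' = V' [G .* S] U'
// with G = (U'u)(Vw)' and S_ab = sum_{d=0}^{dt-1} la_a^d la_b^{dt-1-d}
//        = (la_a^dt - la_b^dt) / (la_a - la_b)   (limit dt la^{dt-1}).
// G .* S is accumulated over photons in the eigenbasis and rotated back
// once per iteration, which keeps the per-photon cost at O(K^2).
//
// Scaled recursions (per-photon normalization) keep >=10^4-photon bursts
// away from underflow. If the eigendecomposition fails to reconstruct T,
// propagation falls back to binary exponentiation of the matrix power and
// gap transition sums to stepwise accumulation.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <map>

using namespace arma;

typedef std::complex<double> cxd;

struct EigT {
  cx_mat U;       // right eigenvectors (columns)
  cx_mat V;       // U^-1
  cx_vec lam;     // eigenvalues
  bool ok;        // reconstruction acceptable
  mat T;          // the matrix itself (for fallbacks)
};

static EigT decompose(const mat& T) {
  EigT e;
  e.T = T;
  cx_vec lam;
  cx_mat U;
  bool success = eig_gen(lam, U, T);
  if (success) {
    cx_mat V;
    success = inv(V, U);
    if (success) {
      mat recon = real(U * diagmat(lam) * V);
      double err = norm(recon - T, "inf");
      if (err < 1e-9 * std::max(1.0, norm(T, "inf"))) {
        e.U = U; e.V = V; e.lam = lam; e.ok = true;
        return e;
      }
    }
  }
  e.ok = false;
  return e;
}

// T^dt by binary exponentiation (fallback path), with a per-call cache.
static mat mat_pow(const mat& T, double dt, std::map<double, mat>& cache) {
  auto it = cache.find(dt);
  if (it != cache.end()) return it->second;
  unsigned long long n = (unsigned long long)(dt + 0.5);
  mat result = eye(T.n_rows, T.n_cols);
  mat base = T;
  while (n > 0) {
    if (n & 1ULL) result = result * base;
    base = base * base;
    n >>= 1ULL;
  }
  cache[dt] = result;
  return result;
}

// lambda^dt elementwise for complex lambda.
static cx_vec lam_pow(const cx_vec& lam, double dt) {
  cx_vec out(lam.n_elem);
  for (uword i = 0; i < lam.n_elem; ++i) out[i] = std::pow(lam[i], dt);
  return out;
}

// S matrix of geometric gap sums for one dt.
static cx_mat gap_sum_S(const cx_vec& lam, const cx_vec& lam_dt, double dt) {
  uword K = lam.n_elem;
  cx_mat S(K, K);
  for (uword a = 0; a < K; ++a) {
    for (uword b = 0; b < K; ++b) {
      cxd diff = lam[a] - lam[b];
      if (std::abs(diff) > 1e-12) {
        S(a, b) = (lam_dt[a] - lam_dt[b]) / diff;
      } else {
        // degenerate eigenvalues: dt * lambda^{dt-1}
        cxd l = lam[a];
        S(a, b) = (std::abs(l) > 0) ? dt * lam_dt[a] / l : cxd(0.0, 0.0);
      }
    }
  }
  return S;
}

// Forward propagation of a row vector through T^dt.
static rowvec propagate_fwd(const rowvec& a, const EigT& e, double dt,
                            std::map<double, mat>& cache) {
  if (e.ok) {
    cx_rowvec ca(a, rowvec(a.n_elem, fill::zeros));
    cx_rowvec tmp = ca * e.U;
    cx_vec ld = lam_pow(e.lam, dt);
    tmp = tmp % ld.st();
    rowvec out = real(tmp * e.V);
    out.transform([](double x) { return x < 0 ? 0.0 : x; });
    return out;
  }
  return a * mat_pow(e.T, dt, cache);
}

// Backward propagation of a column vector: T^dt w.
static vec propagate_bwd(const vec& w, const EigT& e, double dt,
                         std::map<double, mat>& cache) {
  if (e.ok) {
    cx_vec tmp = e.V * cx_vec(w, vec(w.n_elem, fill::zeros));
    cx_vec ld = lam_pow(e.lam, dt);
    tmp = tmp % ld;
    vec out = real(e.U * tmp);
    out.transform([](double x) { return x < 0 ? 0.0 : x; });
    return out;
  }
  return mat_pow(e.T, dt, cache) * w;
}

struct SuffStats {
  cx_mat xi_eig;      // accumulated G .* S in the eigenbasis
  mat xi_direct;      // fallback-path direct accumulation
  vec p0_acc;         // sum of gamma_0 over bursts
  mat emis_acc;       // K x 2 sum of gamma over photons by color
  double loglik;
  bool used_fallback;
};

// Specialized sweep for the common case of a real eigendecomposition:
// flat buffers, per-photon eigenpowers computed once in the forward pass
// and reused by the backward pass and the gap transition sums.
struct RealEig {
  mat U, V;     // right eigenvectors and inverse
  vec lam;
  mat invdiff;  // 1 / (lam_a - lam_b) off the degenerate pairs
  umat degen;   // |lam_a - lam_b| below tolerance
  bool usable;
};

static RealEig to_real(const EigT& e) {
  RealEig r;
  r.usable = false;
  if (!e.ok) return r;
  uword K = e.lam.n_elem;
  double scale = std::max(1.0, std::abs(e.lam[0]));
  for (uword i = 0; i < K; ++i) {
    if (std::abs(std::imag(e.lam[i])) > 1e-12 * scale) return r;
  }
  if (norm(imag(e.U), "inf") > 1e-10) return r;
  r.U = real(e.U);
  r.V = real(e.V);
  r.lam = real(e.lam);
  r.invdiff = mat(K, K, fill::zeros);
  r.degen = umat(K, K, fill::zeros);
  for (uword a = 0; a < K; ++a) {
    for (uword b = 0; b < K; ++b) {
      double d = r.lam[a] - r.lam[b];
      if (std::abs(d) > 1e-12) r.invdiff(a, b) = 1.0 / d;
      else r.degen(a, b) = 1;
    }
  }
  r.usable = true;
  return r;
}

static double sweep_dataset_real(const ivec& colors, const vec& gaps,
                                 const uvec& bstart, const uvec& bstop,
                                 const RealEig& re, const mat& T,
                                 const mat& B, const vec& p0,
                                 SuffStats* stats, mat* post,
                                 vec* burst_ll) {
  const uword K = B.n_rows;
  const double* U = re.U.memptr();   // column-major K x K
  const double* V = re.V.memptr();
  const double* lam = re.lam.memptr();
  const double* Bc[2] = { B.colptr(0), B.colptr(1) };
  double total_ll = 0.0;
  std::vector<double> alpha, lamD, gcache, cscale;
  std::vector<double> a(K), g(K), h(K), w(K), vw(K), beta(K), gam(K);
  mat xiG;  // accumulated G .* S in the eigenbasis (real)
  std::vector<const unsigned long long*> degen_cols;
  if (stats) xiG = mat(K, K, fill::zeros);
  for (uword b = 0; b < bstart.n_elem; ++b) {
    uword i0 = bstart[b], i1 = bstop[b];
    uword n = i1 - i0;
    alpha.resize(n * K);
    lamD.resize(n * K);
    gcache.resize(n * K);
    cscale.resize(n);
    // forward
    double c0 = 0.0;
    {
      const double* Bcol = Bc[colors[i0]];
      for (uword i = 0; i < K; ++i) {
        a[i] = p0[i] * Bcol[i];
        c0 += a[i];
      }
    }
    if (c0 <= 0) c0 = 1e-300;
    double ll = std::log(c0);
    for (uword i = 0; i < K; ++i) {
      a[i] /= c0;
      alpha[i] = a[i];
    }
    cscale[0] = c0;
    for (uword s = 1; s < n; ++s) {
      double dt = gaps[i0 + s];
      // g = a' U ; cache for the gap-sum pass
      for (uword j = 0; j < K; ++j) {
        double acc = 0.0;
        const double* Uj = U + j * K;
        for (uword i = 0; i < K; ++i) acc += a[i] * Uj[i];
        g[j] = acc;
        gcache[(s - 1) * K + j] = acc;
      }
      for (uword j = 0; j < K; ++j) {
        double ld = std::pow(lam[j], dt);
        lamD[s * K + j] = ld;
        h[j] = g[j] * ld;
      }
      const double* Bcol = Bc[colors[i0 + s]];
      double c = 0.0;
      for (uword j = 0; j < K; ++j) {
        double acc = 0.0;
        for (uword i = 0; i < K; ++i) acc += h[i] * V[j * K + i];
        if (acc < 0) acc = 0;
        acc *= Bcol[j];
        a[j] = acc;
        c += acc;
      }
      if (c <= 0) c = 1e-300;
      for (uword j = 0; j < K; ++j) {
        a[j] /= c;
        alpha[s * K + j] = a[j];
      }
      cscale[s] = c;
      ll += std::log(c);
    }
    total_ll += ll;
    if (burst_ll) (*burst_ll)[b] = ll;
    if (!stats && !post) continue;
    // backward with on-the-fly stats
    for (uword i = 0; i < K; ++i) beta[i] = 1.0;
    {
      double ssum = 0.0;
      for (uword i = 0; i < K; ++i) {
        gam[i] = alpha[(n - 1) * K + i];
        ssum += gam[i];
      }
      if (ssum > 0) for (uword i = 0; i < K; ++i) gam[i] /= ssum;
      if (stats) {
        for (uword i = 0; i < K; ++i) {
          stats->emis_acc(i, colors[i1 - 1]) += gam[i];
        }
        if (n == 1) for (uword i = 0; i < K; ++i) stats->p0_acc[i] += gam[i];
      }
      if (post) for (uword i = 0; i < K; ++i) (*post)(i1 - 1, i) = gam[i];
    }
    for (uword s = n - 1; s >= 1; --s) {
      const double* Bcol = Bc[colors[i0 + s]];
      double csc = cscale[s];
      for (uword i = 0; i < K; ++i) w[i] = Bcol[i] * beta[i] / csc;
      // vw = V w
      for (uword i = 0; i < K; ++i) {
        double acc = 0.0;
        for (uword j = 0; j < K; ++j) acc += V[j * K + i] * w[j];
        vw[i] = acc;
      }
      const double* ld = &lamD[s * K];
      if (stats) {
        const double* gc = &gcache[(s - 1) * K];
        double dt = gaps[i0 + s];
        for (uword aa = 0; aa < K; ++aa) {
          double ga = gc[aa];
          for (uword bb = 0; bb < K; ++bb) {
            double S;
            if (!re.degen(aa, bb)) {
              S = (ld[aa] - ld[bb]) * re.invdiff(aa, bb);
            } else {
              S = (std::abs(lam[aa]) > 0) ? dt * ld[aa] / lam[aa] : 0.0;
            }
            xiG(aa, bb) += ga * vw[bb] * S;
          }
        }
      }
      // beta_{s-1} = U (lamD .* vw)
      for (uword i = 0; i < K; ++i) h[i] = ld[i] * vw[i];
      for (uword i = 0; i < K; ++i) {
        double acc = 0.0;
        for (uword j = 0; j < K; ++j) acc += U[j * K + i] * h[j];
        beta[i] = acc < 0 ? 0.0 : acc;
      }
      double ssum = 0.0;
      for (uword i = 0; i < K; ++i) {
        gam[i] = alpha[(s - 1) * K + i] * beta[i];
        ssum += gam[i];
      }
      if (ssum > 0) for (uword i = 0; i < K; ++i) gam[i] /= ssum;
      if (stats) {
        for (uword i = 0; i < K; ++i) {
          stats->emis_acc(i, colors[i0 + s - 1]) += gam[i];
        }
        if (s == 1) for (uword i = 0; i < K; ++i) stats->p0_acc[i] += gam[i];
      }
      if (post) for (uword i = 0; i < K; ++i) (*post)(i0 + s - 1, i) = gam[i];
    }
  }
  if (stats) {
    stats->xi_direct += re.V.t() * xiG * re.U.t();
    stats->loglik = total_ll;
  }
  return total_ll;
}


// One forward-backward sweep over a set of bursts under one transition
// matrix (one dataset). Returns loglik; fills stats and (optionally)
// per-photon posteriors.
static double sweep_dataset(const ivec& colors, const vec& gaps,
                            const uvec& bstart, const uvec& bstop,
                            const EigT& eT, const mat& B, const vec& p0,
                            SuffStats* stats, mat* post,
                            vec* burst_ll) {
  uword K = B.n_rows;
  std::map<double, mat> cache;
  double total_ll = 0.0;
  for (uword b = 0; b < bstart.n_elem; ++b) {
    uword i0 = bstart[b], i1 = bstop[b];  // photon index range [i0, i1)
    uword n = i1 - i0;
    mat alpha(n, K);
    vec cscale(n);
    // forward
    rowvec a = p0.st() % B.col(colors[i0]).st();
    double c0 = accu(a);
    if (c0 <= 0) c0 = 1e-300;
    a /= c0;
    alpha.row(0) = a;
    cscale[0] = c0;
    double ll = std::log(c0);
    for (uword n_i = 1; n_i < n; ++n_i) {
      rowvec ap = propagate_fwd(a, eT, gaps[i0 + n_i], cache);
      ap = ap % B.col(colors[i0 + n_i]).st();
      double c = accu(ap);
      if (c <= 0) c = 1e-300;
      a = ap / c;
      alpha.row(n_i) = a;
      cscale[n_i] = c;
      ll += std::log(c);
    }
    total_ll += ll;
    if (burst_ll) (*burst_ll)[b] = ll;
    if (!stats && !post) continue;
    // backward, accumulating stats on the fly
    vec beta(K, fill::ones);
    {
      vec gam = alpha.row(n - 1).st() % beta;
      double s = accu(gam);
      if (s > 0) gam /= s;
      if (stats) stats->emis_acc.col(colors[i1 - 1]) += gam;
      if (post) post->row(i1 - 1) = gam.st();
      if (stats && n == 1) stats->p0_acc += gam;
    }
    for (uword n_i = n - 1; n_i >= 1; --n_i) {
      double dt = gaps[i0 + n_i];
      vec w = (B.col(colors[i0 + n_i]) % beta) / cscale[n_i];
      if (stats) {
        vec u = alpha.row(n_i - 1).st();
        if (eT.ok) {
          cx_vec cu = eT.U.st() * cx_vec(u, vec(K, fill::zeros));
          cx_vec cw = eT.V * cx_vec(w, vec(K, fill::zeros));
          cx_vec ld = lam_pow(eT.lam, dt);
          cx_mat S = gap_sum_S(eT.lam, ld, dt);
          stats->xi_eig += (cu * cw.st()) % S;
        } else {
          // stepwise: sum_d (T'^d u)(T^{dt-1-d} w)'
          stats->used_fallback = true;
          vec uu = u;
          uword D = (uword)(dt + 0.5);
          std::vector<vec> wstack(D);
          vec ww = w;
          for (uword d = 0; d < D; ++d) {
            wstack[D - 1 - d] = ww;
            ww = eT.T * ww;
          }
          for (uword d = 0; d < D; ++d) {
            stats->xi_direct += uu * wstack[d].st();
            uu = eT.T.st() * uu;
          }
        }
      }
      beta = propagate_bwd(w, eT, dt, cache);
      vec gam = alpha.row(n_i - 1).st() % beta;
      double s = accu(gam);
      if (s > 0) gam /= s;
      if (stats) stats->emis_acc.col(colors[i0 + n_i - 1]) += gam;
      if (post) post->row(i0 + n_i - 1) = gam.st();
      if (stats && n_i == 1) stats->p0_acc += gam;
    }
  }
  if (stats) stats->loglik = total_ll;
  return total_ll;
}

static mat finish_xi(const SuffStats& s, const EigT& eT) {
  mat C = s.xi_direct;
  if (eT.ok) C += real(eT.V.st() * s.xi_eig * eT.U.st());
  mat xi = eT.T % C;
  xi.transform([](double x) { return x < 0 ? 0.0 : x; });
  return xi;
}

// [[Rcpp::export]]
Rcpp::List h2mm_em_cpp(Rcpp::IntegerVector colors_r,
                       Rcpp::NumericVector gaps_r,
                       Rcpp::IntegerVector bstart_r,
                       Rcpp::IntegerVector bstop_r,
                       Rcpp::IntegerVector dataset_r,
                       int n_datasets,
                       Rcpp::List T_init, Rcpp::NumericMatrix B_init,
                       Rcpp::List p0_init,
                       int max_iter, double tol) {
  ivec colors = Rcpp::as<ivec>(colors_r);
  vec gaps = Rcpp::as<vec>(gaps_r);
  uvec bstart = Rcpp::as<uvec>(bstart_r);
  uvec bstop = Rcpp::as<uvec>(bstop_r);
  ivec dset = Rcpp::as<ivec>(dataset_r);
  mat B = Rcpp::as<mat>(B_init);
  uword K = B.n_rows;
  double n_photons = (double)colors.n_elem;

  std::vector<mat> T(n_datasets);
  std::vector<vec> p0(n_datasets);
  std::vector<uvec> d_bursts(n_datasets);
  for (int d = 0; d < n_datasets; ++d) {
    T[d] = Rcpp::as<mat>(T_init[d]);
    p0[d] = Rcpp::as<vec>(p0_init[d]);
    d_bursts[d] = find(dset == d);
  }

  std::vector<double> trace;
  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    double ll = 0.0;
    mat emis_acc(K, 2, fill::zeros);
    std::vector<mat> xi(n_datasets);
    std::vector<vec> p0_new(n_datasets);
    for (int d = 0; d < n_datasets; ++d) {
      EigT eT = decompose(T[d]);
      RealEig re = to_real(eT);
      SuffStats st;
      st.xi_eig = cx_mat(K, K, fill::zeros);
      st.xi_direct = mat(K, K, fill::zeros);
      st.p0_acc = vec(K, fill::zeros);
      st.emis_acc = mat(K, 2, fill::zeros);
      st.used_fallback = false;
      uvec bs = bstart.elem(d_bursts[d]);
      uvec be = bstop.elem(d_bursts[d]);
      if (re.usable) {
        ll += sweep_dataset_real(colors, gaps, bs, be, re, T[d], B, p0[d],
                                 &st, nullptr, nullptr);
      } else {
        ll += sweep_dataset(colors, gaps, bs, be, eT, B, p0[d], &st,
                            nullptr, nullptr);
      }
      emis_acc += st.emis_acc;
      xi[d] = finish_xi(st, eT);
      double nb = (double)bs.n_elem;
      p0_new[d] = (nb > 0) ? vec(st.p0_acc / nb) : p0[d];
    }
    trace.push_back(ll);
    bool small_change = trace.size() > 1 &&
      (ll - trace[trace.size() - 2]) / n_photons < tol;
    if (small_change) { converged = true; break; }
    // M-step
    for (int d = 0; d < n_datasets; ++d) {
      mat Tn = T[d];
      for (uword i = 0; i < K; ++i) {
        double rs = accu(xi[d].row(i));
        if (rs > 0) Tn.row(i) = xi[d].row(i) / rs;
      }
      T[d] = Tn;
      p0[d] = p0_new[d] / std::max(accu(p0_new[d]), 1e-300);
    }
    for (uword i = 0; i < K; ++i) {
      double tot = emis_acc(i, 0) + emis_acc(i, 1);
      if (tot > 0) {
        B(i, 0) = emis_acc(i, 0) / tot;
        B(i, 1) = emis_acc(i, 1) / tot;
      }
    }
  }

  Rcpp::List T_out(n_datasets), p0_out(n_datasets);
  for (int d = 0; d < n_datasets; ++d) {
    T_out[d] = Rcpp::wrap(T[d]);
    p0_out[d] = Rcpp::wrap(p0[d]);
  }
  return Rcpp::List::create(
    Rcpp::Named("T") = T_out,
    Rcpp::Named("B") = Rcpp::wrap(B),
    Rcpp::Named("p0") = p0_out,
    Rcpp::Named("loglik_trace") = Rcpp::wrap(trace),
    Rcpp::Named("n_iterations") = (int)trace.size(),
    Rcpp::Named("converged") = converged);
}

// [[Rcpp::export]]
Rcpp::List h2mm_fwdbwd_cpp(Rcpp::IntegerVector colors_r,
                           Rcpp::NumericVector gaps_r,
                           Rcpp::IntegerVector bstart_r,
                           Rcpp::IntegerVector bstop_r,
                           Rcpp::NumericMatrix T_r,
                           Rcpp::NumericMatrix B_r,
                           Rcpp::NumericVector p0_r,
                           bool want_posteriors) {
  ivec colors = Rcpp::as<ivec>(colors_r);
  vec gaps = Rcpp::as<vec>(gaps_r);
  uvec bstart = Rcpp::as<uvec>(bstart_r);
  uvec bstop = Rcpp::as<uvec>(bstop_r);
  mat T = Rcpp::as<mat>(T_r);
  mat B = Rcpp::as<mat>(B_r);
  vec p0 = Rcpp::as<vec>(p0_r);
  uword K = B.n_rows;
  EigT eT = decompose(T);
  RealEig re = to_real(eT);
  vec burst_ll(bstart.n_elem, fill::zeros);
  if (!want_posteriors) {
    if (re.usable) {
      sweep_dataset_real(colors, gaps, bstart, bstop, re, T, B, p0,
                         nullptr, nullptr, &burst_ll);
    } else {
      sweep_dataset(colors, gaps, bstart, bstop, eT, B, p0,
                    nullptr, nullptr, &burst_ll);
    }
    return Rcpp::List::create(Rcpp::Named("loglik") = Rcpp::wrap(burst_ll));
  }
  mat post(colors.n_elem, K, fill::zeros);
  SuffStats st;
  st.xi_eig = cx_mat(K, K, fill::zeros);
  st.xi_direct = mat(K, K, fill::zeros);
  st.p0_acc = vec(K, fill::zeros);
  st.emis_acc = mat(K, 2, fill::zeros);
  st.used_fallback = false;
  if (re.usable) {
    sweep_dataset_real(colors, gaps, bstart, bstop, re, T, B, p0, &st,
                       &post, &burst_ll);
  } else {
    sweep_dataset(colors, gaps, bstart, bstop, eT, B, p0, &st, &post,
                  &burst_ll);
  }
  mat xi = finish_xi(st, eT);
  return Rcpp::List::create(
    Rcpp::Named("loglik") = Rcpp::wrap(burst_ll),
    Rcpp::Named("posteriors") = Rcpp::wrap(post),
    Rcpp::Named("expected_transitions") = Rcpp::wrap(xi));
}

// [[Rcpp::export]]
Rcpp::List h2mm_viterbi_cpp(Rcpp::IntegerVector colors_r,
                            Rcpp::NumericVector gaps_r,
                            Rcpp::IntegerVector bstart_r,
                            Rcpp::IntegerVector bstop_r,
                            Rcpp::NumericMatrix T_r,
                            Rcpp::NumericMatrix B_r,
                            Rcpp::NumericVector p0_r) {
  ivec colors = Rcpp::as<ivec>(colors_r);
  vec gaps = Rcpp::as<vec>(gaps_r);
  uvec bstart = Rcpp::as<uvec>(bstart_r);
  uvec bstop = Rcpp::as<uvec>(bstop_r);
  mat T = Rcpp::as<mat>(T_r);
  mat B = Rcpp::as<mat>(B_r);
  vec p0 = Rcpp::as<vec>(p0_r);
  uword K = B.n_rows;
  EigT eT = decompose(T);
  std::map<double, mat> cache;
  ivec path(colors.n_elem);
  vec path_ll(bstart.n_elem);
  vec logp0 = log(clamp(p0, 1e-300, datum::inf));
  mat logB = log(clamp(B, 1e-300, datum::inf));
  for (uword b = 0; b < bstart.n_elem; ++b) {
    uword i0 = bstart[b], i1 = bstop[b];
    uword n = i1 - i0;
    mat delta(n, K);
    umat psi(n, K, fill::zeros);
    delta.row(0) = (logp0 + logB.col(colors[i0])).st();
    for (uword s = 1; s < n; ++s) {
      double dt = gaps[i0 + s];
      mat Tdt;
      if (eT.ok) {
        cx_vec ld = lam_pow(eT.lam, dt);
        Tdt = real(eT.U * diagmat(ld) * eT.V);
        Tdt.transform([](double x) { return x < 0 ? 0.0 : x; });
      } else {
        Tdt = mat_pow(eT.T, dt, cache);
      }
      mat logT = log(clamp(Tdt, 1e-300, datum::inf));
      for (uword j = 0; j < K; ++j) {
        vec cand = delta.row(s - 1).st() + logT.col(j);
        uword arg = cand.index_max();
        psi(s, j) = arg;
        delta(s, j) = cand[arg] + logB(j, colors[i0 + s]);
      }
    }
    uword last = delta.row(n - 1).index_max();
    path_ll[b] = delta(n - 1, last);
    path[i1 - 1] = (int)last;
    for (uword s = n - 1; s >= 1; --s) {
      last = psi(s, last);
      path[i0 + s - 1] = (int)last;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("path") = Rcpp::wrap(path),
    Rcpp::Named("path_loglik") = Rcpp::wrap(path_ll));
}
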