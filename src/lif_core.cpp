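// Event-driven conductance-based LIF network core.
//
// Conductance kernels are unit-area differences of exponentials; each
// channel is evolved as a pair of exponential states (decay, rise) with
// g = D - R, which is exactly the kernel convolution sampled on the grid.
// Membrane potentials use forward Euler at the fixed step dt; conductance
// states use exact exponential updates. Synaptic failures are drawn per
// spike per synapse from a private xorshift generator so runs are
// reproducible given the seed.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#ifdef __SSE2__
#include <xmmintrin.h>
#endif
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(double seed) {
    s = static_cast<uint64_t>(seed) * 6364136223846793005ULL +
        1442695040888963407ULL;
    if (s == 0) s = 0x9E3779B97F4A7C15ULL;
    next(); next();
  }
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double uniform() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// per-source channel indices for recorded neurons
enum { SRC_LGN = 0, SRC_AMB = 1, SRC_L4 = 2, SRC_L6 = 3, SRC_GABA = 4 };

}  // namespace

// [[Rcpp::export(name = ".lif_core")]]
List lif_core(int n, double dt, int n_steps,
              IntegerVector isE, NumericVector gR, double VE, double VI,
              int ref_steps,
              NumericVector g0E, NumericVector g0I,
              NumericVector tau_d, NumericVector tau_r,  // AMPA, NMDA, GABA
              double rhoA_E, double rhoA_I,
              IntegerVector c_ptr, IntegerVector c_tgt,
              NumericVector c_w, NumericVector c_fail,
              IntegerVector l6_ptr, IntegerVector l6_tgt, NumericVector l6_w,
              NumericVector l6_fail,
              NumericVector l6_sp_t, IntegerVector l6_sp_cell,
              IntegerVector lgn_ptr, IntegerVector lgn_tgt, NumericVector lgn_w,
              NumericVector lgn_sp_t, IntegerVector lgn_sp_cell,
              NumericVector amb_t, IntegerVector amb_tgt, double amb_w,
              IntegerVector rec_idx, double win_lo, double win_hi,
              IntegerVector trace_idx, int trace_stride,
              double seed, double v0_max) {
#ifdef __SSE2__
  // flush denormal conductance tails to zero: exponentially decaying states
  // otherwise spend most of their time subnormal, stalling the FPU
  const unsigned int csr_saved = _mm_getcsr();
  _mm_setcsr(csr_saved | 0x8040);  // FTZ | DAZ
#endif
  const double invA = 1.0 / (tau_d[0] - tau_r[0]);
  const double invN = 1.0 / (tau_d[1] - tau_r[1]);
  const double invG = 1.0 / (tau_d[2] - tau_r[2]);
  const double fAd = std::exp(-dt / tau_d[0]), fAr = std::exp(-dt / tau_r[0]);
  const double fNd = std::exp(-dt / tau_d[1]), fNr = std::exp(-dt / tau_r[1]);
  const double fGd = std::exp(-dt / tau_d[2]), fGr = std::exp(-dt / tau_r[2]);

  // merged channel states
  std::vector<double> Ad(n, 0.0), Ar(n, 0.0), Nd(n, 0.0), Nr(n, 0.0),
      Gd(n, 0.0), Gr(n, 0.0), v(n, 0.0);
  std::vector<int> refrac(n, 0);

  XorShift rng(seed);
  for (int i = 0; i < n; ++i) v[i] = v0_max * rng.uniform();

  // recorded per-source states: 7 channel pairs per recorded neuron
  const int nrec = rec_idx.size();
  std::vector<int> rec_slot(n, -1);
  for (int i = 0; i < nrec; ++i) rec_slot[rec_idx[i]] = i;
  // layout per slot: LGNd,LGNr, AMBd,AMBr, L4Ad,L4Ar, L4Nd,L4Nr,
  //                  L6Ad,L6Ar, L6Nd,L6Nr, Gd,Gr
  std::vector<double> rs(nrec * 14, 0.0);
  std::vector<double> acc(nrec * 5, 0.0);

  std::vector<int> tr_slot(n, -1);
  const int ntr = trace_idx.size();
  for (int i = 0; i < ntr; ++i) tr_slot[trace_idx[i]] = i;
  int n_samples = 0;
  if (ntr > 0 && trace_stride > 0) n_samples = (n_steps + trace_stride - 1) / trace_stride;
  NumericMatrix tr_v(n_samples, ntr), tr_gE(n_samples, ntr), tr_gI(n_samples, ntr);
  NumericVector tr_t(n_samples);

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  spike_t.reserve(1024);
  std::vector<int> count_win(n, 0);

  R_xlen_t pL = 0, pA = 0, p6 = 0;
  const R_xlen_t nL = lgn_sp_t.size(), nA = amb_t.size(), n6 = l6_sp_t.size();

  auto deliver_exc = [&](int tgt, double a, int src) {
    if (src == SRC_LGN || src == SRC_AMB) {
      double aa = a * invA;
      Ad[tgt] += aa; Ar[tgt] += aa;
      int s = rec_slot[tgt];
      if (s >= 0) {
        double* p = &rs[s * 14] + (src == SRC_LGN ? 0 : 2);
        p[0] += aa; p[1] += aa;
      }
    } else {
      double rhoA = isE[tgt] ? rhoA_E : rhoA_I;
      double aa = a * rhoA * invA;
      double an = a * (1.0 - rhoA) * invN;
      Ad[tgt] += aa; Ar[tgt] += aa;
      Nd[tgt] += an; Nr[tgt] += an;
      int s = rec_slot[tgt];
      if (s >= 0) {
        double* p = &rs[s * 14] + (src == SRC_L4 ? 4 : 8);
        p[0] += aa; p[1] += aa; p[2] += an; p[3] += an;
      }
    }
  };
  auto deliver_inh = [&](int tgt, double a) {
    double ag = a * invG;
    Gd[tgt] += ag; Gr[tgt] += ag;
    int s = rec_slot[tgt];
    if (s >= 0) { rs[s * 14 + 12] += ag; rs[s * 14 + 13] += ag; }
  };

  long win_steps = 0;

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const double t_next = t + dt;
    const bool in_win = (t >= win_lo && t < win_hi);
    if (in_win) ++win_steps;

    // exact exponential decay of all channel states
    for (int i = 0; i < n; ++i) {
      Ad[i] *= fAd; Ar[i] *= fAr;
      Nd[i] *= fNd; Nr[i] *= fNr;
      Gd[i] *= fGd; Gr[i] *= fGr;
    }
    for (int s = 0; s < nrec; ++s) {
      double* p = &rs[s * 14];
      p[0] *= fAd;  p[1] *= fAr;   // LGN
      p[2] *= fAd;  p[3] *= fAr;   // ambient
      p[4] *= fAd;  p[5] *= fAr;  p[6] *= fNd;  p[7] *= fNr;   // L4 E
      p[8] *= fAd;  p[9] *= fAr;  p[10] *= fNd; p[11] *= fNr;  // L6
      p[12] *= fGd; p[13] *= fGr;                              // GABA
    }

    // external events due in [t, t + dt)
    while (pL < nL && lgn_sp_t[pL] < t_next) {
      int c = lgn_sp_cell[pL];
      for (int e = lgn_ptr[c]; e < lgn_ptr[c + 1]; ++e)
        deliver_exc(lgn_tgt[e], lgn_w[e], SRC_LGN);
      ++pL;
    }
    while (pA < nA && amb_t[pA] < t_next) {
      deliver_exc(amb_tgt[pA], amb_w, SRC_AMB);
      ++pA;
    }
    while (p6 < n6 && l6_sp_t[p6] < t_next) {
      int c = l6_sp_cell[p6];
      double fp = l6_fail[c];
      for (int e = l6_ptr[c]; e < l6_ptr[c + 1]; ++e) {
        if (fp > 0.0 && rng.uniform() < fp) continue;
        deliver_exc(l6_tgt[e], l6_w[e], SRC_L6);
      }
      ++p6;
    }

    const bool sample = (ntr > 0 && trace_stride > 0 && step % trace_stride == 0);
    const int srow = sample ? step / trace_stride : 0;
    if (sample) {
      tr_t[srow] = t;
      for (int k = 0; k < ntr; ++k) {
        const int i = trace_idx[k];
        tr_v(srow, k) = v[i];
        tr_gE(srow, k) = (Ad[i] - Ar[i]) + (Nd[i] - Nr[i]) + g0E[i];
        tr_gI(srow, k) = (Gd[i] - Gr[i]) + g0I[i];
      }
    }
    if (in_win) {
      for (int s = 0; s < nrec; ++s) {
        const double vi = v[rec_idx[s]];
        const double* p = &rs[s * 14];
        const double dfE = VE - vi;
        acc[s * 5 + SRC_LGN] += (p[0] - p[1]) * dfE;
        acc[s * 5 + SRC_AMB] += (p[2] - p[3]) * dfE;
        acc[s * 5 + SRC_L4] += ((p[4] - p[5]) + (p[6] - p[7])) * dfE;
        acc[s * 5 + SRC_L6] += ((p[8] - p[9]) + (p[10] - p[11])) * dfE;
        acc[s * 5 + SRC_GABA] += (p[12] - p[13]) * (vi - VI);
      }
    }

    for (int i = 0; i < n; ++i) {
      if (refrac[i] > 0) {
        --refrac[i];
        continue;
      }
      const double vi = v[i];
      const double gE = (Ad[i] - Ar[i]) + (Nd[i] - Nr[i]) + g0E[i];
      const double gI = (Gd[i] - Gr[i]) + g0I[i];
      double vn = vi + dt * (-gR[i] * vi - gE * (vi - VE) - gI * (vi - VI));
      if (vn >= 1.0) {
        spike_t.push_back(t_next);
        spike_id.push_back(i);
        if (t_next >= win_lo && t_next < win_hi) ++count_win[i];
        v[i] = 0.0;
        refrac[i] = ref_steps;
        if (isE[i]) {
          for (int e = c_ptr[i]; e < c_ptr[i + 1]; ++e) {
            if (c_fail[e] > 0.0 && rng.uniform() < c_fail[e]) continue;
            deliver_exc(c_tgt[e], c_w[e], SRC_L4);
          }
        } else {
          for (int e = c_ptr[i]; e < c_ptr[i + 1]; ++e)
            deliver_inh(c_tgt[e], c_w[e]);
        }
      } else {
        v[i] = vn;
      }
    }

    if ((step & 0x3FFF) == 0) {
      Rcpp::checkUserInterrupt();
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(v[i]) || !std::isfinite(Ad[i]) ||
            !std::isfinite(Gd[i])) {
          stop("numerical instability: non-finite state at neuron %d, t = %g s",
               i + 1, t);
        }
      }
    }
  }

#ifdef __SSE2__
  _mm_setcsr(csr_saved);
#endif
  NumericMatrix rec_cur(nrec, 5);
  if (win_steps > 0) {
    for (int s = 0; s < nrec; ++s)
      for (int k = 0; k < 5; ++k) rec_cur(s, k) = acc[s * 5 + k] / win_steps;
  }
  colnames(rec_cur) = CharacterVector::create("LGN", "ambient", "L4", "L6", "I");

  List traces = R_NilValue;
  if (ntr > 0) {
    traces = List::create(_["t"] = tr_t, _["v"] = tr_v,
                          _["gE"] = tr_gE, _["gI"] = tr_gI);
  }
  return List::create(
      _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["count_win"] = IntegerVector(count_win.begin(), count_win.end()),
      _["rec_currents"] = rec_cur,
      _["win_steps"] = (double)win_steps,
      _["traces"] = traces);
}
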