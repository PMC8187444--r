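#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Cross-correlogram bin counts for two sorted spike trains (times in
// seconds).  Bin k (0-based) covers the half-open lag interval
// [-W + k*delta, -W + (k+1)*delta), lag = t_target - t_reference.
// Two-pointer sweep, O(n_ref + n_tgt + pairs in window).
//
// [[Rcpp::export(name = ".ccgCountCpp")]]
IntegerVector ccg_count_cpp(NumericVector ref, NumericVector tgt,
                            double window_s, double bin_s) {
    const int M = (int)std::llround(2.0 * window_s / bin_s);
    IntegerVector counts(M);
    const R_xlen_t nr = ref.size(), nt = tgt.size();
    if (nr == 0 || nt == 0) return counts;
    R_xlen_t lo = 0, hi = 0;
    for (R_xlen_t i = 0; i < nr; ++i) {
        const double r = ref[i];
        while (lo < nt && tgt[lo] < r - window_s) ++lo;
        if (hi < lo) hi = lo;
        while (hi < nt && tgt[hi] < r + window_s) ++hi;
        for (R_xlen_t j = lo; j < hi; ++j) {
            const int k = (int)std::floor((tgt[j] - r + window_s) / bin_s);
            if (k >= 0 && k < M) counts[k]++;
        }
    }
    return counts;
}

// Peak postsynaptic membrane deflection (mV, signed) of a passive MAT
// membrane receiving a single synaptic conductance transient
// g(t) = G exp(-t/tau_s):
//   dv/dt = -(v - V_L)/tau_m - g(t) (v - V_rev)
// integrated with Heun's method; the conductance decay uses the exact
// exponential factor.  Vectorized over synapses.
//
// [[Rcpp::export(name = ".pspPeakCpp")]]
NumericVector psp_peak_cpp(NumericVector G, LogicalVector exc,
                           NumericVector tau_m_post,
                           double V_L, double V_E, double V_I,
                           double tau_se, double tau_si,
                           double dt = 0.02, double t_max = 120.0) {
    const R_xlen_t n = G.size();
    NumericVector peak(n);
    const long n_steps = (long)std::llround(t_max / dt);
    for (R_xlen_t j = 0; j < n; ++j) {
        const bool e = exc[j];
        const double Vrev = e ? V_E : V_I;
        const double tau_s = e ? tau_se : tau_si;
        const double dec = std::exp(-dt / tau_s);
        const double tau_m = tau_m_post[j];
        double g = G[j], v = V_L, best = 0.0;
        for (long s = 0; s < n_steps; ++s) {
            const double g_next = g * dec;
            const double f1 = -(v - V_L) / tau_m - g * (v - Vrev);
            const double v_pred = v + dt * f1;
            const double f2 = -(v_pred - V_L) / tau_m - g_next * (v_pred - Vrev);
            v += 0.5 * dt * (f1 + f2);
            g = g_next;
            const double defl = v - V_L;
            if (std::fabs(defl) > std::fabs(best)) best = defl;
            else if (std::fabs(defl) < 0.05 * std::fabs(best)) break;
        }
        peak[j] = best;
    }
    return peak;
}
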