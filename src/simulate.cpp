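#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "xoshiro.h"

using namespace Rcpp;

// Network simulation of multi-timescale adaptive threshold (MAT) neurons.
//
// Membrane (forward Euler, step dt ms):
//   tau_m dv/dt = -(v - V_L) - tau_m [ g_e (v - V_E) + g_i (v - V_I) ]
//                 - tau_m [ g_e^bg (v - E_e^bg) + g_i^bg (v - E_i^bg) ]
// Synaptic conductances decay exponentially (exact factor per step) and jump
// by G at presynaptic spike time + delay.  Background conductances follow an
// Ornstein-Uhlenbeck process (exact discretization); neurons in an
// oscillation group get an extra variance-modulating term
// A sin(w t + delta) xi(t) on the excitatory background conductance.
// Threshold theta(t) = omega_rest + sum over past spikes of
// alpha_1 exp(-s/tau_1) + alpha_2 exp(-s/tau_2); no voltage reset; an
// absolute refractory period suppresses threshold crossings.
//
// [[Rcpp::export(name = ".simulateMatCpp")]]
List simulate_mat_cpp(IntegerVector src, IntegerVector dst,
                      NumericVector G, NumericVector delay_ms,
                      LogicalVector src_exc,
                      NumericVector tau_m, NumericVector omega_rest,
                      NumericVector alpha1, NumericVector alpha2,
                      NumericVector osc_A, NumericVector osc_freq_hz,
                      NumericVector osc_delta,
                      List constants, List background,
                      double dt, double duration_ms, int refr_steps,
                      double seed, bool noise_on = true,
                      int bg_every = 5, int record_state_every = 0) {
    const int N = tau_m.size();
    const R_xlen_t n_syn = src.size();
    const double V_L = as<double>(constants["V_L"]);
    const double V_E = as<double>(constants["V_E"]);
    const double V_I = as<double>(constants["V_I"]);
    const double tau_se = as<double>(constants["tau_s_e"]);
    const double tau_si = as<double>(constants["tau_s_i"]);
    const double tau1 = as<double>(constants["tau_1"]);
    const double tau2 = as<double>(constants["tau_2"]);

    const double ge0 = as<double>(background["g_e0"]);
    const double gi0 = as<double>(background["g_i0"]);
    const double Ee = as<double>(background["E_e"]);
    const double Ei = as<double>(background["E_i"]);
    const double sig_e = as<double>(background["sigma_e"]);
    const double sig_i = as<double>(background["sigma_i"]);
    const double tau_e = as<double>(background["tau_e"]);
    const double tau_i = as<double>(background["tau_i"]);

    const long n_steps = (long)std::llround(duration_ms / dt);
    const double dec_se = std::exp(-dt / tau_se);
    const double dec_si = std::exp(-dt / tau_si);
    const double dec_t1 = std::exp(-dt / tau1);
    const double dec_t2 = std::exp(-dt / tau2);
    // Background OU conductances are advanced every bg_every membrane steps
    // with the exact discretization (distribution-exact at any step size)
    // and held in between; dt_bg stays well below tau_e = 2.7 ms.
    if (bg_every < 1) bg_every = 1;
    const double dt_bg = dt * bg_every;
    const double phi_e = std::exp(-dt_bg / tau_e);
    const double phi_i = std::exp(-dt_bg / tau_i);
    const double s_e = sig_e * std::sqrt(1.0 - phi_e * phi_e);
    const double s_i = sig_i * std::sqrt(1.0 - phi_i * phi_i);
    const double sqrt_dt_bg = std::sqrt(dt_bg);

    // outgoing adjacency in CSR form
    std::vector<int> out_deg(N, 0);
    for (R_xlen_t k = 0; k < n_syn; ++k) out_deg[src[k]]++;
    std::vector<int> row_ptr(N + 1, 0);
    for (int i = 0; i < N; ++i) row_ptr[i + 1] = row_ptr[i] + out_deg[i];
    std::vector<int> adj_dst(n_syn);
    std::vector<double> adj_G(n_syn);
    std::vector<int> adj_dsteps(n_syn);
    std::vector<bool> adj_exc(n_syn);
    {
        std::vector<int> fill(row_ptr.begin(), row_ptr.end() - 1);
        int max_dsteps = 1;
        for (R_xlen_t k = 0; k < n_syn; ++k) {
            const int p = fill[src[k]]++;
            adj_dst[p] = dst[k];
            adj_G[p] = G[k];
            int ds = (int)std::llround(delay_ms[k] / dt);
            if (ds < 1) ds = 1;
            adj_dsteps[p] = ds;
            adj_exc[p] = src_exc[k];
            if (ds > max_dsteps) max_dsteps = ds;
        }
        constants["max_dsteps"] = max_dsteps;  // stash for buffer sizing
    }
    const int L = as<int>(constants["max_dsteps"]) + 1;

    std::vector<double> bufE((size_t)L * N, 0.0), bufI((size_t)L * N, 0.0);
    std::vector<double> v(N, V_L), ge(N, 0.0), gi(N, 0.0);
    std::vector<double> geb(N, ge0), gib(N, gi0);
    std::vector<double> th1(N, 0.0), th2(N, 0.0);
    std::vector<int> refr(N, 0);
    std::vector<double> osc_w(N);
    for (int i = 0; i < N; ++i)
        osc_w[i] = 2.0 * M_PI * osc_freq_hz[i] / 1000.0;  // rad per ms

    SimRng rng((uint64_t)seed);
    if (noise_on) {
        for (int i = 0; i < N; ++i) {
            geb[i] = ge0 + sig_e * rng.norm();
            gib[i] = gi0 + sig_i * rng.norm();
        }
    }

    std::vector<std::vector<double> > spikes(N);

    const bool rec = record_state_every > 0;
    std::vector<double> v_trace, th_trace;
    long n_rec = 0;
    if (rec) {
        n_rec = n_steps / record_state_every + 1;
        v_trace.reserve((size_t)n_rec * N);
        th_trace.reserve((size_t)n_rec * N);
    }

    for (long step = 0; step < n_steps; ++step) {
        const double t = step * dt;
        const int slot = (int)(step % L);
        double *arrE = &bufE[(size_t)slot * N];
        double *arrI = &bufI[(size_t)slot * N];
        for (int i = 0; i < N; ++i) {
            // synaptic conductances: exact decay + queued arrivals
            ge[i] = ge[i] * dec_se + arrE[i];
            gi[i] = gi[i] * dec_si + arrI[i];
            arrE[i] = 0.0;
            arrI[i] = 0.0;

            // background OU conductances
            if (noise_on && step % bg_every == 0) {
                double n1 = rng.norm();
                double inc = 0.0;
                if (osc_A[i] > 0.0) {
                    inc = osc_A[i] * std::sin(osc_w[i] * t + osc_delta[i]) *
                          sqrt_dt_bg * rng.norm();
                }
                geb[i] = ge0 + (geb[i] - ge0) * phi_e + s_e * n1 + inc;
                gib[i] = gi0 + (gib[i] - gi0) * phi_i + s_i * rng.norm();
            }

            // membrane update (tau_m divided out of Eq. 6)
            const double vi = v[i];
            const double dv = -(vi - V_L) / tau_m[i]
                - ge[i] * (vi - V_E) - gi[i] * (vi - V_I)
                - geb[i] * (vi - Ee) - gib[i] * (vi - Ei);
            v[i] = vi + dt * dv;

            // adaptive threshold decay
            th1[i] *= dec_t1;
            th2[i] *= dec_t2;

            if (refr[i] > 0) {
                refr[i]--;
            } else if (v[i] >= omega_rest[i] + th1[i] + th2[i]) {
                // spike: no voltage reset, threshold jumps, delayed delivery
                spikes[i].push_back((t + dt) / 1000.0);  // seconds
                th1[i] += alpha1[i];
                th2[i] += alpha2[i];
                refr[i] = refr_steps;
                for (int p = row_ptr[i]; p < row_ptr[i + 1]; ++p) {
                    const int tslot = (int)((step + adj_dsteps[p]) % L);
                    if (adj_exc[p])
                        bufE[(size_t)tslot * N + adj_dst[p]] += adj_G[p];
                    else
                        bufI[(size_t)tslot * N + adj_dst[p]] += adj_G[p];
                }
            }
        }
        if (rec && step % record_state_every == 0) {
            for (int i = 0; i < N; ++i) {
                v_trace.push_back(v[i]);
                th_trace.push_back(omega_rest[i] + th1[i] + th2[i]);
            }
        }
        if ((step & 0x3FFF) == 0) {
            for (int i = 0; i < N; ++i)
                if (!std::isfinite(v[i]) || v[i] < -500.0 || v[i] > 500.0)
                    stop("membrane potential out of physical bounds "
                         "(neuron %d, v = %f mV at t = %f ms)", i + 1, v[i], t);
            Rcpp::checkUserInterrupt();
        }
    }

    List out_spk(N);
    for (int i = 0; i < N; ++i) out_spk[i] = wrap(spikes[i]);
    List ret = List::create(_["spikes"] = out_spk);
    if (rec) {
        const long nr = (long)(v_trace.size() / N);
        NumericMatrix vm(N, nr), tm(N, nr);
        for (long j = 0; j < nr; ++j)
            for (int i = 0; i < N; ++i) {
                vm(i, j) = v_trace[(size_t)j * N + i];
                tm(i, j) = th_trace[(size_t)j * N + i];
            }
        ret["v"] = vm;
        ret["theta"] = tm;
        ret["state_dt"] = dt * record_state_every;
    }
    return ret;
}
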