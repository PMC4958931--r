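// Firing-rate lattice kernel: leaky membrane dynamics, covariance plasticity,
// and trial orchestration for the two-lattice somatotopic map model.
//
// Layout conventions (shared with the R side):
//  * cells are indexed column-major, 0-based: i = row + N*col
//  * connection types in order ES=0, EE=1, EI=2, IE=3
//  * weights are a single vector w[((type*NO + o)*NC) + i], where o indexes
//    the M*M mask offsets, o = (dc+HM)*M + (dr+HM); slot (o,i) holds the
//    weight of the presynaptic cell at (row+dr, col+dc) onto postsynaptic
//    cell i, and is structurally zero when that coordinate leaves the lattice
//    (planar boundary: masks are truncated, never wrapped).
//
// Synaptic drive is the fan-in-averaged weighted input I = (1/N_i) sum_j
// w_ij r_j, delivered once per 1-ms step: dv/dt = -v/tau_m + I/h.  Euler
// mode therefore reproduces the discrete network map v <- alpha_m v + I
// exactly; in RK4 mode the drive is held fixed over the step (as the
// discrete-time map freezes rates at t), so the four stages collapse to
// v <- P v + (1-P)(tau_m/h) I with P the fourth-order Taylor polynomial of
// exp(-h/tau_m).

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

namespace {

const int T_ES = 0, T_EE = 1, T_EI = 2, T_IE = 3, NTYPE = 4;

// sigmoidal rate function g(v) = (1 + tanh(beta_m (v - 1/2))) / 2 tabulated
// on a dense grid; max abs interpolation error < 1.5e-7 for beta_m = 4.
struct RateTable {
    double lo, hi, step, inv_step, beta;
    std::vector<double> tab;
    void build(double beta_m) {
        const int K = 40001;
        beta = beta_m;
        lo = -20.0; hi = 20.0;
        step = (hi - lo) / (K - 1);
        inv_step = 1.0 / step;
        tab.resize(K);
        for (int k = 0; k < K; ++k)
            tab[k] = 0.5 * (1.0 + std::tanh(lo + k * step));
    }
    inline double g(double v) const {
        double x = beta * (v - 0.5);
        if (!(x > lo)) return tab.front();   // also routes NaN to the floor
        if (x >= hi) return tab.back();
        double u = (x - lo) * inv_step;
        int k = (int)u;
        double f = u - k;
        return tab[k] + f * (tab[k + 1] - tab[k]);
    }
};

struct Topo {
    int N, M, HM, NC, NO, PAD;
    std::vector<int> shift;        // rate-array index shift per offset
    std::vector<int> r0, r1, c0, c1; // valid postsynaptic rectangle per offset
    std::vector<double> mask;      // NO*NC, 1 if slot valid
    std::vector<double> fan;       // NC, valid fan-in per cell
    std::vector<double> inv_fan;   // NC
    void build(int N_, int M_) {
        N = N_; M = M_; HM = M / 2;
        NC = N * N; NO = M * M;
        PAD = HM * N + HM;
        shift.resize(NO);
        r0.resize(NO); r1.resize(NO); c0.resize(NO); c1.resize(NO);
        mask.assign((size_t)NO * NC, 0.0);
        fan.assign(NC, 0.0);
        inv_fan.resize(NC);
        for (int dc = -HM; dc <= HM; ++dc)
            for (int dr = -HM; dr <= HM; ++dr) {
                int o = (dc + HM) * M + (dr + HM);
                shift[o] = dr + N * dc;
                r0[o] = dr < 0 ? -dr : 0; r1[o] = dr > 0 ? N - dr : N;
                c0[o] = dc < 0 ? -dc : 0; c1[o] = dc > 0 ? N - dc : N;
                double *mk = &mask[(size_t)o * NC];
                for (int c = c0[o]; c < c1[o]; ++c)
                    for (int r = r0[o]; r < r1[o]; ++r) {
                        int i = r + N * c;
                        mk[i] = 1.0;
                        fan[i] += 1.0;
                    }
            }
        // per-cell fan-in is shared across the four types
        for (int i = 0; i < NC; ++i) inv_fan[i] = 1.0 / fan[i];
    }
};

// counter-based noise generator (PCG32), seeded per trial from the R stream
struct Pcg {
    uint64_t state, inc;
    inline uint32_t next() {
        uint64_t old = state;
        state = old * 6364136223846793005ULL + inc;
        uint32_t xs = (uint32_t)(((old >> 18u) ^ old) >> 27u);
        uint32_t rot = (uint32_t)(old >> 59u);
        return (xs >> rot) | (xs << ((-rot) & 31u));
    }
    void seed(uint64_t s, uint64_t seq) {
        state = 0u; inc = (seq << 1u) | 1u;
        next(); state += s; next();
    }
    inline double unif() { return next() * (1.0 / 4294967296.0); }
    inline double sym(double a) { return a * (2.0 * unif() - 1.0); }
};

void check_dims(const NumericVector &w, const Topo &tp) {
    if ((R_xlen_t)w.size() != (R_xlen_t)NTYPE * tp.NO * tp.NC)
        stop("weight vector has length %d, expected %d (N=%d, M=%d)",
             (int)w.size(), NTYPE * tp.NO * tp.NC, tp.N, tp.M);
}

void normalize_inplace(double *w, const Topo &tp, const double *R) {
    std::vector<double> colsum(tp.NC);
    for (int t = 0; t < NTYPE; ++t) {
        std::fill(colsum.begin(), colsum.end(), 0.0);
        for (int o = 0; o < tp.NO; ++o) {
            const double *wp = w + ((size_t)t * tp.NO + o) * tp.NC;
            for (int i = 0; i < tp.NC; ++i) colsum[i] += wp[i];
        }
        for (int i = 0; i < tp.NC; ++i) {
            if (!(colsum[i] > 0.0) || !std::isfinite(colsum[i]))
                stop("degenerate normalization: cell %d (type %d) has "
                     "non-positive or non-finite incoming weight sum", i + 1, t);
            colsum[i] = R[t] * tp.fan[i] / colsum[i];
        }
        for (int o = 0; o < tp.NO; ++o) {
            double *wp = w + ((size_t)t * tp.NO + o) * tp.NC;
            for (int i = 0; i < tp.NC; ++i) wp[i] *= colsum[i];
        }
    }
}

struct StepParams {
    double h, tau_m, beta_m, noise_amp;
    int mode;                    // 0 = euler, 1 = rk4
    int total_steps, pre_steps, stim_steps;
    double P;                    // per-step homogeneous decay factor
    double QD;                   // per-step drive factor
    void derive() {
        // dv/dt = -v/tau_m + I/h: the discrete network map adds the
        // (fan-in-averaged) drive once per step.  Euler gives exactly
        // v <- alpha_m v + I; RK4 with the drive frozen over the step
        // collapses to v <- P v + (1-P)(tau_m/h) I.
        double a = h / tau_m;
        if (mode == 1) {
            P = 1.0 - a + a * a / 2.0 - a * a * a / 6.0 + a * a * a * a / 24.0;
        } else {
            P = 1.0 - a;
        }
        QD = (1.0 - P) / a;
    }
};

StepParams read_npar(const List &npar) {
    StepParams sp;
    sp.h = as<double>(npar["h"]);
    sp.tau_m = as<double>(npar["tau_m"]);
    sp.beta_m = as<double>(npar["beta_m"]);
    sp.noise_amp = as<double>(npar["noise_amp"]);
    sp.mode = as<int>(npar["mode"]);
    sp.total_steps = as<int>(npar["total_steps"]);
    sp.pre_steps = as<int>(npar["pre_steps"]);
    sp.stim_steps = as<int>(npar["stim_steps"]);
    if (sp.h <= 0 || sp.tau_m <= sp.h)
        stop("invalid integration parameters: need h > 0 and tau_m > h");
    if (sp.pre_steps + sp.stim_steps > sp.total_steps)
        stop("trial timing inconsistent: pre + stim exceeds total duration");
    sp.derive();
    return sp;
}

// Network state: potentials plus padded rate arrays.  A block first relaxes
// the zero state to rest and snapshots it; every trial is then reset to the
// snapshot, so trials are independent events whose pre-stimulus window
// reflects the network's genuine resting activity.
struct NetState {
    std::vector<double> vS, vE, vI, rS, rE, rI;
    NetState(const Topo &tp, const RateTable &lut)
        : vS(tp.NC, 0.0), vE(tp.NC, 0.0), vI(tp.NC, 0.0),
          rS(tp.NC + 2 * tp.PAD, 0.0), rE(tp.NC + 2 * tp.PAD, 0.0),
          rI(tp.NC + 2 * tp.PAD, 0.0) {
        double g0 = lut.g(0.0);
        for (int i = 0; i < tp.NC; ++i)
            rS[tp.PAD + i] = rE[tp.PAD + i] = rI[tp.PAD + i] = g0;
    }
};

// One trial.  Weights are adapted in place when gate is true; probe summary
// buffers (may be NULL) receive per-cell pre-window mean, stimulus-window
// mean and whole-trial peak rates.  Optional dense recording of designated
// cells for trial time-series export.
void run_trial(double *w, const Topo &tp, const RateTable &lut,
               const StepParams &sp, Pcg &rng, NetState &st,
               const std::vector<int> &stim_nodes, double per_node_drive,
               bool gate, double alpha_w, double beta_w,
               double *eP, double *eS, double *ePk,
               double *iP, double *iS, double *iPk,
               const std::vector<int> &rec_cells, double *rec /*steps x 6k*/) {
    const int NC = tp.NC, NO = tp.NO, PAD = tp.PAD;
    std::vector<double> &vS = st.vS, &vE = st.vE, &vI = st.vI;
    std::vector<double> &rS = st.rS, &rE = st.rE, &rI = st.rI;
    std::vector<double> accE(NC), accI(NC);

    std::vector<double> sumEpre, sumEstim, sumIpre, sumIstim;
    if (eP) {
        sumEpre.assign(NC, 0.0); sumEstim.assign(NC, 0.0);
        sumIpre.assign(NC, 0.0); sumIstim.assign(NC, 0.0);
        for (int i = 0; i < NC; ++i) { ePk[i] = 0.0; iPk[i] = 0.0; }
    }

    const int nrec = (int)rec_cells.size();

    for (int st = 0; st < sp.total_steps; ++st) {
        const bool stim_on =
            (st >= sp.pre_steps && st < sp.pre_steps + sp.stim_steps);

        // synaptic drive at step start (rates frozen over the step); the
        // covariance update for this step uses the same rates and is fused
        // into the sweep so each weight is touched once per step.
        std::memset(accE.data(), 0, NC * sizeof(double));
        std::memset(accI.data(), 0, NC * sizeof(double));
        const double *crS = rS.data() + PAD, *crE = rE.data() + PAD,
                     *crI = rI.data() + PAD;
        for (int o = 0; o < NO; ++o) {
            const int s = tp.shift[o];
            const double *prS = crS + s, *prE = crE + s, *prI = crI + s;
            double *wES = w + ((size_t)T_ES * NO + o) * NC;
            double *wEE = w + ((size_t)T_EE * NO + o) * NC;
            double *wEI = w + ((size_t)T_EI * NO + o) * NC;
            double *wIE = w + ((size_t)T_IE * NO + o) * NC;
            double *aE = accE.data(), *aI = accI.data();
            // only the postsynaptic rectangle whose presynaptic partner
            // exists is touched; clipped slots stay structurally zero
            const int N = tp.N;
            for (int c = tp.c0[o]; c < tp.c1[o]; ++c) {
                const int lo = tp.r0[o] + N * c, hi = tp.r1[o] + N * c;
                if (gate) {
                    for (int i = lo; i < hi; ++i) {
                        aE[i] += wES[i] * prS[i] + wEE[i] * prE[i] - wEI[i] * prI[i];
                        aI[i] += wIE[i] * prE[i];
                        const double hE = beta_w * crE[i], hI = beta_w * crI[i];
                        wES[i] = alpha_w * wES[i] + hE * prS[i];
                        wEE[i] = alpha_w * wEE[i] + hE * prE[i];
                        wEI[i] = alpha_w * wEI[i] + hE * prI[i];
                        wIE[i] = alpha_w * wIE[i] + hI * prE[i];
                    }
                } else {
                    for (int i = lo; i < hi; ++i) {
                        aE[i] += wES[i] * prS[i] + wEE[i] * prE[i] - wEI[i] * prI[i];
                        aI[i] += wIE[i] * prE[i];
                    }
                }
            }
        }

        // membrane leak plus the per-step synaptic / stimulus drive
        for (int i = 0; i < NC; ++i) {
            vE[i] = sp.P * vE[i] + sp.QD * (accE[i] * tp.inv_fan[i]);
            vI[i] = sp.P * vI[i] + sp.QD * (accI[i] * tp.inv_fan[i]);
            vS[i] = sp.P * vS[i];
        }
        if (stim_on)
            for (size_t k = 0; k < stim_nodes.size(); ++k)
                vS[stim_nodes[k]] += sp.QD * per_node_drive;

        // additive membrane noise, outside the deterministic update
        if (sp.noise_amp > 0) {
            const double a = sp.noise_amp;
            for (int i = 0; i < NC; ++i) vS[i] += rng.sym(a);
            for (int i = 0; i < NC; ++i) vE[i] += rng.sym(a);
            for (int i = 0; i < NC; ++i) vI[i] += rng.sym(a);
        }

        // refresh rates
        for (int i = 0; i < NC; ++i) {
            rS[PAD + i] = lut.g(vS[i]);
            rE[PAD + i] = lut.g(vE[i]);
            rI[PAD + i] = lut.g(vI[i]);
        }

        if (eP) {
            const bool pre_on = st < sp.pre_steps;
            for (int i = 0; i < NC; ++i) {
                const double re = rE[PAD + i], ri = rI[PAD + i];
                if (pre_on) { sumEpre[i] += re; sumIpre[i] += ri; }
                else if (stim_on) { sumEstim[i] += re; sumIstim[i] += ri; }
                if (re > ePk[i]) ePk[i] = re;
                if (ri > iPk[i]) iPk[i] = ri;
            }
        }
        if (nrec) {
            double *row = rec + (size_t)st;
            const size_t stride = sp.total_steps;
            for (int k = 0; k < nrec; ++k) {
                int c = rec_cells[k];
                row[(6 * k + 0) * stride] = vS[c];
                row[(6 * k + 1) * stride] = rS[PAD + c];
                row[(6 * k + 2) * stride] = vE[c];
                row[(6 * k + 3) * stride] = rE[PAD + c];
                row[(6 * k + 4) * stride] = vI[c];
                row[(6 * k + 5) * stride] = rI[PAD + c];
            }
        }
    }

    for (int i = 0; i < NC; ++i)
        if (!std::isfinite(vE[i]) || !std::isfinite(vI[i]))
            stop("integration failure: non-finite membrane potential");

    if (eP) {
        const double npre = sp.pre_steps, nstim = sp.stim_steps;
        for (int i = 0; i < NC; ++i) {
            eP[i] = sumEpre[i] / npre;  eS[i] = sumEstim[i] / nstim;
            iP[i] = sumIpre[i] / npre;  iS[i] = sumIstim[i] / nstim;
        }
    }
}

std::vector<int> patch_nodes(const Topo &tp, int r0, int c0, int ph, int pw) {
    if (r0 < 0 || c0 < 0 || r0 + ph > tp.N || c0 + pw > tp.N)
        stop("stimulus patch extends outside the lattice");
    std::vector<int> nodes;
    nodes.reserve((size_t)ph * pw);
    for (int c = c0; c < c0 + pw; ++c)
        for (int r = r0; r < r0 + ph; ++r) nodes.push_back(r + tp.N * c);
    return nodes;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_topology")]]
List cpp_topology(int N, int M) {
    Topo tp; tp.build(N, M);
    NumericMatrix mask(tp.NC, tp.NO);
    IntegerVector dr(tp.NO), dc(tp.NO);
    for (int o = 0; o < tp.NO; ++o) {
        dr[o] = o % M - tp.HM;
        dc[o] = o / M - tp.HM;
        for (int i = 0; i < tp.NC; ++i) mask(i, o) = tp.mask[(size_t)o * tp.NC + i];
    }
    return List::create(_["mask"] = mask, _["fan_in"] = NumericVector(tp.fan.begin(), tp.fan.end()),
                        _["dr"] = dr, _["dc"] = dc);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_normalize_weights")]]
NumericVector cpp_normalize_weights(NumericVector w, int N, int M,
                                    NumericVector resources) {
    Topo tp; tp.build(N, M);
    check_dims(w, tp);
    if (resources.size() != NTYPE) stop("resources must have length 4");
    NumericVector out = clone(w);
    normalize_inplace(REAL(out), tp, REAL(resources));
    return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_run_block")]]
List cpp_run_block(NumericVector w, int N, int M, IntegerMatrix stims,
                   double stim_mag, bool renormalize, List npar,
                   double alpha_w, double beta_w, NumericVector resources,
                   bool gate, bool normalize_end, bool record_probe,
                   IntegerVector record_cells) {
    Topo tp; tp.build(N, M);
    check_dims(w, tp);
    StepParams sp = read_npar(npar);
    RateTable lut; lut.build(sp.beta_m);
    if (resources.size() != NTYPE) stop("resources must have length 4");

    NumericVector wout = clone(w);
    double *wp = REAL(wout);
    const int ntrial = stims.nrow();
    const int settle_steps = npar.containsElementNamed("settle_steps")
        ? as<int>(npar["settle_steps"]) : 0;

    NumericMatrix ePre, eStim, ePeak, iPre, iStim, iPeak;
    if (record_probe) {
        ePre = NumericMatrix(tp.NC, ntrial);  eStim = NumericMatrix(tp.NC, ntrial);
        ePeak = NumericMatrix(tp.NC, ntrial); iPre = NumericMatrix(tp.NC, ntrial);
        iStim = NumericMatrix(tp.NC, ntrial); iPeak = NumericMatrix(tp.NC, ntrial);
    }
    std::vector<int> rec(record_cells.begin(), record_cells.end());
    List series(rec.empty() ? 0 : ntrial);

    Pcg rng;
    NetState st(tp, lut);
    std::vector<int> no_rec;
    if (settle_steps > 0) {
        // relax from the zero state to rest; no stimulus, no plasticity,
        // noise as configured
        uint64_t s1 = (uint64_t)(unif_rand() * 9007199254740992.0);
        uint64_t s2 = (uint64_t)(unif_rand() * 9007199254740992.0);
        rng.seed(s1, s2);
        StepParams spw = sp;
        spw.total_steps = settle_steps;
        spw.pre_steps = settle_steps;
        spw.stim_steps = 0;
        run_trial(wp, tp, lut, spw, rng, st, std::vector<int>(), 0.0,
                  false, alpha_w, beta_w,
                  NULL, NULL, NULL, NULL, NULL, NULL, no_rec, NULL);
    }
    const NetState rest = st;    // snapshot: every trial starts from rest
    for (int tr = 0; tr < ntrial; ++tr) {
        st = rest;
        // two R-stream draws seed the per-trial noise generator, so whole
        // runs are replayable from one set.seed() call
        uint64_t s1 = (uint64_t)(unif_rand() * 9007199254740992.0);
        uint64_t s2 = (uint64_t)(unif_rand() * 9007199254740992.0);
        rng.seed(s1, s2);
        std::vector<int> nodes = patch_nodes(tp, stims(tr, 0), stims(tr, 1),
                                             stims(tr, 2), stims(tr, 3));
        double per_node = renormalize ? stim_mag / std::sqrt((double)nodes.size())
                                      : stim_mag;
        NumericMatrix ts;
        double *tsp = NULL;
        if (!rec.empty()) {
            ts = NumericMatrix(sp.total_steps, 6 * (int)rec.size());
            tsp = REAL(ts);
        }
        if (record_probe) {
            run_trial(wp, tp, lut, sp, rng, st, nodes, per_node, gate, alpha_w, beta_w,
                      &ePre(0, tr), &eStim(0, tr), &ePeak(0, tr),
                      &iPre(0, tr), &iStim(0, tr), &iPeak(0, tr), rec, tsp);
        } else {
            run_trial(wp, tp, lut, sp, rng, st, nodes, per_node, gate, alpha_w, beta_w,
                      NULL, NULL, NULL, NULL, NULL, NULL, rec, tsp);
        }
        if (!rec.empty()) series[tr] = ts;
        if (gate && normalize_end) normalize_inplace(wp, tp, REAL(resources));
        if (tr % 16 == 15) Rcpp::checkUserInterrupt();
    }

    List out = List::create(_["weights"] = wout);
    if (record_probe)
        out["probe"] = List::create(_["e_pre"] = ePre, _["e_stim"] = eStim,
                                    _["e_peak"] = ePeak, _["i_pre"] = iPre,
                                    _["i_stim"] = iStim, _["i_peak"] = iPeak);
    if (!rec.empty()) out["series"] = series;
    return out;
}
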