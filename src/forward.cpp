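#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Local-mode (uniform fragment entry/exit, unihit) plan-7 forward and
// Viterbi over a nucleotide profile. All values are log2 (bits); emissions
// arrive as log-odds against the background, transitions as log2
// probabilities. Flanking background states emit at log-odds 0 and cost
// nothing, so the score is a pure fragment log-odds.
//
// Column layout of lt: MM MI MD IM II DM DD; row k holds the transitions
// leaving node k (1-based). Entry B->M_k has probability 2/(M(M+1)) for
// every k (uniform fragment model); exit M_k->E has probability 1.
//
// Recurrences (i = query position, k = node):
//   M_k(i) = em_k(x_i) + lse(entry, M_{k-1}(i-1)+MM, I_{k-1}(i-1)+IM,
//                                   D_{k-1}(i-1)+DM)
//   I_k(i) = ei_k(x_i) + lse(M_k(i-1)+MI, I_k(i-1)+II)     (k < M)
//   D_k(i) = lse(M_{k-1}(i)+MD, D_{k-1}(i)+DD)             (k >= 2)
//   E(i)   = lse_k M_k(i);   C(i) = lse(C(i-1), E(i));  score = C(L)

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
    double m = a > b ? a : b;
    double n = a > b ? b : a;
    // below ~46 bits the correction is lost in double precision anyway
    if (m - n > 46.0 || n == NEG_INF) return m;
    return m + std::log2(1.0 + std::exp2(n - m));
}

// Forward in scaled probability space: per column, plain multiply-adds on
// odds ratios, renormalized by the column maximum with the log2 of the
// scale accumulated separately. Mathematically identical to the
// log-space recursion, without transcendentals in the inner loop.
//
// Length model (hmmer-style): the flanking states N and C self-loop with
// probability L/(L+2) per emitted residue and leave with 2/(L+2); the
// null model emits each residue with continuation L/(L+1) and terminates
// with 1/(L+1). This keeps scores nearly invariant to padding a hit with
// background flanks.
static double forward_scaled(const std::vector<double> &OM,   // M x 5 odds
                             const std::vector<double> &OI,
                             const std::vector<double> &PT,   // M x 7 probs
                             int M, const int *X, int L) {
    const double tNN = (double)L / (L + 2.0);     // = tCC
    const double tNB = 2.0 / (L + 2.0);           // = tCT
    const double rnull = (double)L / (L + 1.0);
    const double entry = tNB * 2.0 / ((double)M * (M + 1.0));
    const double *tMM = PT.data(),         *tMI = PT.data() + M,
                 *tMD = PT.data() + 2 * M, *tIM = PT.data() + 3 * M,
                 *tII = PT.data() + 4 * M, *tDM = PT.data() + 5 * M,
                 *tDD = PT.data() + 6 * M;
    std::vector<double> VMp(M + 1, 0.0), VIp(M + 1, 0.0), VDp(M + 1, 0.0),
                        VM(M + 1, 0.0),  VI(M + 1, 0.0),  VD(M + 1, 0.0);
    double vn = 1.0, vc = 0.0, LS = 0.0;

    for (int i = 1; i <= L; ++i) {
        const int xi = X[i - 1];
        const double *em = OM.data() + (size_t)xi * M;
        const double *ei = OI.data() + (size_t)xi * M;
        double ve = 0.0, cmax = vn;
        VM[1] = em[0] * entry * vn;   // vn still holds the column-(i-1) mass
        VI[1] = (M > 1) ? ei[0] * (VMp[1] * tMI[0] + VIp[1] * tII[0]) : 0.0;
        VD[1] = 0.0;
        ve = VM[1];
        if (VM[1] > cmax) cmax = VM[1];
        if (VI[1] > cmax) cmax = VI[1];
        for (int k = 2; k <= M; ++k) {
            VM[k] = em[k - 1] * (entry * vn + VMp[k - 1] * tMM[k - 2] +
                                 VIp[k - 1] * tIM[k - 2] +
                                 VDp[k - 1] * tDM[k - 2]);
            VI[k] = (k < M)
                ? ei[k - 1] * (VMp[k] * tMI[k - 1] + VIp[k] * tII[k - 1])
                : 0.0;
            VD[k] = VM[k - 1] * tMD[k - 2] + VD[k - 1] * tDD[k - 2];
            ve += VM[k];
            if (VM[k] > cmax) cmax = VM[k];
            if (VI[k] > cmax) cmax = VI[k];
            if (VD[k] > cmax) cmax = VD[k];
        }
        vc = vc * tNN + ve;       // C self-loop, then arrivals from E
        vn *= tNN;                // N self-loop
        if (vc > cmax) cmax = vc;
        if (cmax <= 0.0) return NEG_INF;     // no mass left anywhere
        const double inv = 1.0 / cmax;
        for (int k = 1; k <= M; ++k) { VM[k] *= inv; VI[k] *= inv; VD[k] *= inv; }
        vn *= inv; vc *= inv;
        LS += std::log2(cmax);
        std::swap(VM, VMp); std::swap(VI, VIp); std::swap(VD, VDp);
    }
    if (vc <= 0.0) return NEG_INF;
    // C->T exit, minus the null model's length terms
    return std::log2(vc) + LS + std::log2(tNB) -
           L * std::log2(rnull) - std::log2(1.0 - rnull);
}

static void toOdds(const NumericMatrix &lg, std::vector<double> &out) {
    const int n = lg.nrow() * lg.ncol();
    out.resize(n);
    const double *p = REAL(lg);
    for (int i = 0; i < n; ++i)
        out[i] = (p[i] == NEG_INF) ? 0.0 : std::exp2(p[i]);
}

// [[Rcpp::export]]
double forward_bits_cpp(NumericMatrix lm, NumericMatrix li,
                        NumericMatrix lt, IntegerVector x) {
    const int M = lm.nrow();
    const int L = x.size();
    if (L < 1) stop("empty query");
    std::vector<double> OM, OI, PT;
    toOdds(lm, OM); toOdds(li, OI); toOdds(lt, PT);
    return forward_scaled(OM, OI, PT, M, INTEGER(x), L);
}

// Batched forward over many queries against one profile (saves the R
// call overhead during calibration and scanning).
// [[Rcpp::export]]
NumericVector forward_bits_many_cpp(NumericMatrix lm, NumericMatrix li,
                                    NumericMatrix lt, List xs) {
    const int n = xs.size();
    const int M = lm.nrow();
    std::vector<double> OM, OI, PT;
    toOdds(lm, OM); toOdds(li, OI); toOdds(lt, PT);
    NumericVector out(n);
    for (int q = 0; q < n; ++q) {
        IntegerVector x = xs[q];
        if (x.size() < 1) stop("empty query");
        out[q] = forward_scaled(OM, OI, PT, M, INTEGER(x), x.size());
    }
    return out;
}

// Viterbi with traceback; returns, for each match node k (1..M), the
// 1-based query position emitted there, or 0 if the node was deleted or
// lies outside the aligned fragment. Inserted query positions are dropped
// (the alignment lives in match-state coordinates).
// [[Rcpp::export]]
IntegerVector viterbi_match_path_cpp(NumericMatrix lm, NumericMatrix li,
                                     NumericMatrix lt, IntegerVector x) {
    const int M = lm.nrow();
    const int L = x.size();
    if (L < 1) stop("empty query");
    const double ltNN = std::log2((double)L / (L + 2.0));
    const double lentry = std::log2(2.0 / (L + 2.0)) +
                          std::log2(2.0 / ((double)M * (M + 1.0)));

    // state codes for traceback pointers: 0 entry, 1 M, 2 I, 3 D
    NumericMatrix VM(M + 1, L + 1), VI(M + 1, L + 1), VD(M + 1, L + 1);
    IntegerMatrix PM(M + 1, L + 1), PI(M + 1, L + 1), PD(M + 1, L + 1);
    std::fill(VM.begin(), VM.end(), NEG_INF);
    std::fill(VI.begin(), VI.end(), NEG_INF);
    std::fill(VD.begin(), VD.end(), NEG_INF);

    for (int i = 1; i <= L; ++i) {
        const int xi = x[i - 1];
        for (int k = 1; k <= M; ++k) {
            double best = lentry + (i - 1) * ltNN; int ptr = 0;
            if (k > 1) {
                double a = VM(k - 1, i - 1) + lt(k - 2, 0);
                if (a > best) { best = a; ptr = 1; }
                a = VI(k - 1, i - 1) + lt(k - 2, 3);
                if (a > best) { best = a; ptr = 2; }
                a = VD(k - 1, i - 1) + lt(k - 2, 5);
                if (a > best) { best = a; ptr = 3; }
            }
            VM(k, i) = best + lm(k - 1, xi);
            PM(k, i) = ptr;
            if (k < M) {
                double a = VM(k, i - 1) + lt(k - 1, 1);
                double b = VI(k, i - 1) + lt(k - 1, 4);
                VI(k, i) = li(k - 1, xi) + (a >= b ? a : b);
                PI(k, i) = a >= b ? 1 : 2;
            }
            if (k >= 2) {
                double a = VM(k - 1, i) + lt(k - 2, 2);
                double b = VD(k - 1, i) + lt(k - 2, 6);
                VD(k, i) = a >= b ? a : b;
                PD(k, i) = a >= b ? 1 : 3;
            }
        }
    }

    // best exit over (k, i), charging the trailing C-state loops
    int bk = 1, bi = 1; double best = NEG_INF;
    for (int i = 1; i <= L; ++i)
        for (int k = 1; k <= M; ++k) {
            double v = VM(k, i) + (L - i) * ltNN;
            if (v > best) { best = v; bk = k; bi = i; }
        }

    IntegerVector out(M, 0);
    int k = bk, i = bi, st = 1;  // st: 1 M, 2 I, 3 D
    while (true) {
        if (st == 1) {
            out[k - 1] = i;
            int ptr = PM(k, i);
            if (ptr == 0) break;
            st = ptr; --i; --k;  // all predecessors sit at node k-1, col i-1
        } else if (st == 2) {
            int ptr = PI(k, i);
            st = ptr; --i;       // insert consumed x_i, stays at node k
        } else {
            int ptr = PD(k, i);
            st = ptr; --k;       // delete is silent
        }
    }
    return out;
}
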