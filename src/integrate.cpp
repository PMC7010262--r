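#include <Rcpp.h>
using namespace Rcpp;

// Unit order (fixed, shared with R side):
//  0 PFC
//  1 D1_1   2 D1_2
//  3 D2_1   4 D2_2
//  5 GPe_1  6 GPe_2
//  7 STN_1  8 STN_2
//  9 GPi_1 10 GPi_2
// 11 PMC_1 12 PMC_2
//
// Static parameter vector `par` order (see bg_par_vector() in R):
//  0 input_pfc  1 w_PMC_D1  2 w_PMC_D2  3 dr_GPe   4 w_D2_GPe
//  5 dr_STN     6 w_GPe_STN 7 dr_GPi    8 w_D1_GPi 9 w_STN_GPi
// 10 dr_PMC    11 w_GPi_PMC 12 w_PMC_PMC 13 w_STN_GPe 14 w_HD
// 15 tau_STN   16 tau_GPe  17 tau_default 18 dt
//
// Plastic weight vector `w` order:
//  0 w_pfc_d1_1 1 w_pfc_d1_2 2 w_pfc_d2_1 3 w_pfc_d2_2
//  4 w_pfc_pmc_1 5 w_pfc_pmc_2

static inline double sigma(double I) {
  return I <= 0.0 ? 0.0 : std::tanh(I);
}

static void inputs13(const double *A, const double *p, const double *w,
                     double *I) {
  I[0] = p[0];                                              // PFC
  for (int m = 0; m < 2; ++m) {
    const double PFC = A[0];
    const double PMC = A[11 + m], PMCo = A[12 - m];
    I[1 + m]  = w[0 + m] * PFC + p[1] * PMC;                // D1
    I[3 + m]  = w[2 + m] * PFC + p[2] * PMC;                // D2
    I[5 + m]  = p[3] - p[4] * A[3 + m] + p[13] * A[7 + m];  // GPe
    I[7 + m]  = p[5] - p[6] * A[5 + m] + p[14] * PMC;       // STN
    I[9 + m]  = p[7] - p[8] * A[1 + m] + p[9] * A[7 + m];   // GPi
    I[11 + m] = p[10] + w[4 + m] * PFC - p[11] * A[9 + m]
                - p[12] * PMCo;                             // PMC
  }
}

// Forward-Euler integration of the 13-unit loop for n_steps of length dt.
// Noise is an i.i.d. uniform(noise_lo, noise_hi) forcing term drawn per
// unit per step (R RNG, so draws are reproducible from set.seed()).
// Returns the final state (1 x 13) or, when record_trace, the whole
// trajectory including the initial state ((n_steps + 1) x 13).
// [[Rcpp::export]]
NumericMatrix bg_integrate_cpp(NumericVector state0, NumericVector par,
                               NumericVector w, int n_steps,
                               double noise_lo, double noise_hi,
                               bool record_trace) {
  if (state0.size() != 13) stop("state must have 13 units");
  if (par.size() < 19) stop("parameter vector too short");
  if (w.size() != 6) stop("plastic weight vector must have 6 entries");

  double A[13], I[13], tau[13];
  for (int i = 0; i < 13; ++i) A[i] = state0[i];
  const double dt = par[18];
  for (int i = 0; i < 13; ++i) tau[i] = par[17];
  tau[7] = tau[8] = par[15];  // STN
  tau[5] = tau[6] = par[16];  // GPe

  const bool use_noise = noise_hi > noise_lo;
  NumericMatrix out(record_trace ? n_steps + 1 : 1, 13);
  if (record_trace)
    for (int i = 0; i < 13; ++i) out(0, i) = A[i];

  for (int s = 1; s <= n_steps; ++s) {
    inputs13(A, par.begin(), w.begin(), I);
    for (int i = 0; i < 13; ++i) {
      const double N = use_noise ? R::runif(noise_lo, noise_hi) : noise_lo;
      A[i] += dt / tau[i] * (sigma(I[i]) - A[i] + N);
    }
    if (record_trace)
      for (int i = 0; i < 13; ++i) out(s, i) = A[i];
  }
  if (!record_trace)
    for (int i = 0; i < 13; ++i) out(0, i) = A[i];
  return out;
}
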