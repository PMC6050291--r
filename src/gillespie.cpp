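#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of operator occupancy at O_R1/O_R2/O_R3 and
// the resulting CI/Cro production, binned into imaging frames.
//
// Each operator is free (0), CI-bound (1) or Cro-bound (2). P_R (cro) fires
// only when O_R1 and O_R2 are both repressor-free; P_RM (cI) only when O_R3
// is free. Binding propensities scale with the current free repressor copy
// number (per-molecule rate constants), which closes the mutual-repression
// feedback loop; `scale` multiplies binding AND unbinding rates and is the
// adiabaticity knob. Transcripts decay exponentially; translation events
// increment the produced-molecule counter of the current frame; proteins
// dilute first-order (growth). Uses R's RNG so set.seed() governs.
//
// [[Rcpp::export]]
List gillespie_switch(NumericVector kon_ci, NumericVector kon_cro,
                      double koff_ci, double koff_cro,
                      double k_tx_r, double k_tx_rm,
                      double mrna_lifetime, double burst_size,
                      double dilution, double scale,
                      double duration, double frame_interval,
                      int p_ci0, int p_cro0, double max_events) {
  RNGScope rngScope;
  const double k_dec = 1.0 / mrna_lifetime;
  const double k_tl = burst_size / mrna_lifetime;
  int occ[3] = {0, 0, 0};
  long m_cro = 0, m_ci = 0;
  long p_cro = p_cro0, p_ci = p_ci0;
  const int n_frames = (int)std::floor(duration / frame_interval + 1e-9);
  IntegerVector cro_counts(n_frames), ci_counts(n_frames);
  IntegerVector occ_frame(n_frames); // encoded occupancy at frame start
  double t = 0.0;
  double n_events = 0.0;
  int cur_frame = 0;
  occ_frame[0] = occ[0] + 3 * occ[1] + 9 * occ[2];
  // propensity slots: 0-2 bind CI at o, 3-5 bind Cro at o, 6-8 unbind o,
  // 9 tx cro, 10 tx ci, 11 decay m_cro, 12 decay m_ci,
  // 13 translate cro, 14 translate ci, 15 dilute p_cro, 16 dilute p_ci
  double a[17];
  while (t < duration && n_events < max_events) {
    for (int o = 0; o < 3; ++o) {
      a[o]     = occ[o] == 0 ? scale * kon_ci[o]  * (double)p_ci  : 0.0;
      a[3 + o] = occ[o] == 0 ? scale * kon_cro[o] * (double)p_cro : 0.0;
      a[6 + o] = occ[o] == 1 ? scale * koff_ci
               : occ[o] == 2 ? scale * koff_cro : 0.0;
    }
    a[9]  = (occ[0] == 0 && occ[1] == 0) ? k_tx_r  : 0.0;
    a[10] = (occ[2] == 0)                ? k_tx_rm : 0.0;
    a[11] = k_dec * (double)m_cro;
    a[12] = k_dec * (double)m_ci;
    a[13] = k_tl * (double)m_cro;
    a[14] = k_tl * (double)m_ci;
    a[15] = dilution * (double)p_cro;
    a[16] = dilution * (double)p_ci;
    double a0 = 0.0;
    for (int i = 0; i < 17; ++i) a0 += a[i];
    if (a0 <= 0.0) break; // no events possible: clean termination
    t += -std::log(unif_rand()) / a0;
    if (t >= duration) break;
    int nf = (int)std::floor(t / frame_interval);
    while (cur_frame < nf && cur_frame + 1 < n_frames) {
      ++cur_frame;
      occ_frame[cur_frame] = occ[0] + 3 * occ[1] + 9 * occ[2];
    }
    double u = unif_rand() * a0;
    int r = 0;
    double acc = a[0];
    while (u > acc && r < 16) { ++r; acc += a[r]; }
    if (r < 3)       { occ[r] = 1; if (p_ci > 0) --p_ci; }
    else if (r < 6)  { occ[r - 3] = 2; if (p_cro > 0) --p_cro; }
    else if (r < 9)  { int o = r - 6; if (occ[o] == 1) ++p_ci; else ++p_cro; occ[o] = 0; }
    else if (r == 9)  ++m_cro;
    else if (r == 10) ++m_ci;
    else if (r == 11) --m_cro;
    else if (r == 12) --m_ci;
    else if (r == 13) { ++p_cro; if (nf < n_frames) ++cro_counts[nf]; }
    else if (r == 14) { ++p_ci;  if (nf < n_frames) ++ci_counts[nf]; }
    else if (r == 15) --p_cro;
    else              --p_ci;
    n_events += 1.0;
  }
  return List::create(_["cro_counts"] = cro_counts, _["ci_counts"] = ci_counts,
                      _["occ_frame"] = occ_frame,
                      _["n_events"] = n_events,
                      _["truncated"] = n_events >= max_events,
                      _["final_p_ci"] = (double)p_ci,
                      _["final_p_cro"] = (double)p_cro);
}
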