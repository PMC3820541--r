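#include <Rcpp.h>
using namespace Rcpp;

// Direct-method Gillespie simulation of the molecular-count relay.
// State: counts of (HK~P, REC~P, Hpt~P, RR~P), each in 0..N; the
// unphosphorylated partners follow from conservation.  `rates` are the
// scaled stochastic rate constants in the channel order used by
// build_generator(): auto, J2f, J2r, J3f, J3r, J4f, J4r, h1, h2.
// Records the state at each requested time (sorted ascending).
// Uses R's RNG, so results are reproducible under set.seed().

// [[Rcpp::export]]
IntegerMatrix ssa_path(IntegerVector init, int N, NumericVector rates,
                       NumericVector times) {
  if (init.size() != 4) stop("init must have 4 counts");
  if (rates.size() != 9) stop("expected 9 channel rates");
  int a = init[0], b = init[1], c = init[2], d = init[3];
  int nt = times.size();
  IntegerMatrix out(nt, 4);
  double t = 0.0;
  int idx = 0;
  double prop[9];
  const double max_events = 5e8;
  double events = 0;
  while (idx < nt) {
    prop[0] = rates[0] * (N - a);
    prop[1] = rates[1] * a * (N - b);
    prop[2] = rates[2] * (N - a) * b;
    prop[3] = rates[3] * b * (N - c);
    prop[4] = rates[4] * (N - b) * c;
    prop[5] = rates[5] * c * (N - d);
    prop[6] = rates[6] * d * (N - c);
    prop[7] = rates[7] * b;
    prop[8] = rates[8] * d;
    double a0 = 0.0;
    for (int i = 0; i < 9; ++i) a0 += prop[i];
    if (a0 <= 0.0) {  // absorbing state: flush remaining record times
      for (; idx < nt; ++idx) {
        out(idx, 0) = a; out(idx, 1) = b; out(idx, 2) = c; out(idx, 3) = d;
      }
      break;
    }
    double tnext = t + R::exp_rand() / a0;
    while (idx < nt && times[idx] < tnext) {
      out(idx, 0) = a; out(idx, 1) = b; out(idx, 2) = c; out(idx, 3) = d;
      ++idx;
    }
    if (idx >= nt) break;
    double u = unif_rand() * a0;
    int ch = 0;
    double acc = prop[0];
    while (u > acc && ch < 8) acc += prop[++ch];
    switch (ch) {
      case 0: ++a; break;
      case 1: --a; ++b; break;
      case 2: ++a; --b; break;
      case 3: --b; ++c; break;
      case 4: ++b; --c; break;
      case 5: --c; ++d; break;
      case 6: ++c; --d; break;
      case 7: --b; break;
      case 8: --d; break;
    }
    t = tnext;
    if (++events > max_events)
      stop("event budget exceeded; reduce t_end or rates");
  }
  return out;
}
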