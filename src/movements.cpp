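#include <Rcpp.h>

// Hysteresis direction-change counter. A direction is committed once the
// signal has travelled at least `hysteresis` from the running extreme; each
// subsequent reversal of at least `hysteresis` from the tracked extremum
// counts as one movement.
// [[Rcpp::export]]
int count_movements_cpp(Rcpp::NumericVector angle, double hysteresis) {
  int n = angle.size();
  if (n < 2) return 0;
  // zero hysteresis still requires a strictly positive excursion, so a
  // constant series never commits a direction
  if (hysteresis <= 0) hysteresis = 1e-12;
  int count = 0;
  int dir = 0;  // 0 = uncommitted, +1 rising, -1 falling
  double lo = angle[0], hi = angle[0], ext = angle[0];
  for (int i = 1; i < n; i++) {
    double x = angle[i];
    if (dir == 0) {
      if (x < lo) lo = x;
      if (x > hi) hi = x;
      if (x - lo >= hysteresis) { dir = 1; ext = x; }
      else if (hi - x >= hysteresis) { dir = -1; ext = x; }
    } else if (dir == 1) {
      if (x > ext) ext = x;
      else if (ext - x >= hysteresis) { count++; dir = -1; ext = x; }
    } else {
      if (x < ext) ext = x;
      else if (x - ext >= hysteresis) { count++; dir = 1; ext = x; }
    }
  }
  return count;
}
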