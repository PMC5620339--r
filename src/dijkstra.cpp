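#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over the grid friction surface.
//
// speed:  km/h per cell, NA = impassable (barrier)
// aniso:  TRUE where the cell's mode is slope-corrected (walking)
// elev:   metres
// Direction of travel is cell -> facility, so while propagating outward
// from the sources the edge from settled cell u to neighbour v is costed
// for the inward traversal v -> u.
//
// Diagonal steps are forbidden when both orthogonally shared cells are
// barriers (no squeezing between barrier corners); knight moves (16-
// connectivity) are forbidden when both cells nearest the move's midpoint
// are barriers.
// [[Rcpp::export]]
NumericMatrix cpp_accumulate(NumericMatrix speed, LogicalMatrix aniso,
                             NumericMatrix elev, double cellSize,
                             int connectivity, IntegerMatrix sources,
                             double steepness, double offsetParam,
                             bool normalize) {
  const int n = speed.nrow(), m = speed.ncol();
  const long long N = (long long)n * m;

  static const int QDR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int QDC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int KDR[8] = {-2, -2, -1, -1, 1, 1, 2, 2};
  static const int KDC[8] = {-1, 1, -2, 2, -2, 2, -1, 1};

  int noff = (connectivity == 16) ? 16 : 8;
  std::vector<int> DR(noff), DC(noff);
  for (int i = 0; i < 8; ++i) { DR[i] = QDR[i]; DC[i] = QDC[i]; }
  if (noff == 16)
    for (int i = 0; i < 8; ++i) { DR[8 + i] = KDR[i]; DC[8 + i] = KDC[i]; }

  std::vector<double> dist(N, R_PosInf);
  const double norm = normalize ? std::exp(-steepness * offsetParam) : 1.0;

  typedef std::pair<double, long long> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  for (int s = 0; s < sources.nrow(); ++s) {
    int r = sources(s, 0) - 1, c = sources(s, 1) - 1;
    long long idx = (long long)c * n + r;
    if (ISNAN(speed[idx])) continue;  // barrier sources are skipped upstream
    if (dist[idx] > 0.0) { dist[idx] = 0.0; pq.push(QE(0.0, idx)); }
  }

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double du = top.first;
    long long ui = top.second;
    if (du > dist[ui]) continue;  // stale entry
    int uc = (int)(ui / n), ur = (int)(ui % n);

    for (int k = 0; k < noff; ++k) {
      int vr = ur + DR[k], vc = uc + DC[k];
      if (vr < 0 || vr >= n || vc < 0 || vc >= m) continue;
      long long vi = (long long)vc * n + vr;
      if (ISNAN(speed[vi])) continue;

      // corner / squeeze rule: both witness cells barriers => forbidden
      int adr = DR[k] < 0 ? -DR[k] : DR[k], adc = DC[k] < 0 ? -DC[k] : DC[k];
      if (adr + adc >= 2) {
        int sr = (DR[k] > 0) - (DR[k] < 0), sc = (DC[k] > 0) - (DC[k] < 0);
        int w1r, w1c, w2r, w2c;
        if (adr == 1 && adc == 1) {        // diagonal
          w1r = ur + DR[k]; w1c = uc;
          w2r = ur;         w2c = uc + DC[k];
        } else if (adc == 2) {             // knight, long axis = columns
          w1r = ur;         w1c = uc + sc;
          w2r = ur + DR[k]; w2c = uc + sc;
        } else {                           // knight, long axis = rows
          w1r = ur + sr;    w1c = uc;
          w2r = ur + sr;    w2c = uc + DC[k];
        }
        bool b1 = (w1r < 0 || w1r >= n || w1c < 0 || w1c >= m) ||
                  ISNAN(speed[(long long)w1c * n + w1r]);
        bool b2 = (w2r < 0 || w2r >= n || w2c < 0 || w2c >= m) ||
                  ISNAN(speed[(long long)w2c * n + w2r]);
        if (b1 && b2) continue;
      }

      double d = std::sqrt((double)(DR[k] * DR[k] + DC[k] * DC[k])) * cellSize;
      // slope in the direction of travel v -> u
      double s = (elev[ui] - elev[vi]) / d;
      double tob = std::exp(-steepness * std::fabs(s + offsetParam)) / norm;
      double vv = speed[vi] * (aniso[vi] ? tob : 1.0);
      double vu = speed[ui] * (aniso[ui] ? tob : 1.0);
      double w = 60.0 * (d / 1000.0) * 0.5 * (1.0 / vv + 1.0 / vu);
      double cand = du + w;
      if (cand < dist[vi]) {
        dist[vi] = cand;
        pq.push(QE(cand, vi));
      }
    }
  }

  NumericMatrix out(n, m);
  for (long long i = 0; i < N; ++i)
    out[i] = std::isinf(dist[i]) ? NA_REAL : dist[i];
  return out;
}
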