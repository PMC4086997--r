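// Banded local alignment with gap-affine penalties (three-state Gotoh
// DP restricted to a diagonal band), with traceback. A gap of length L
// costs gap_open + gap_extend * L (both penalties non-positive).

#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double NEG = -1e30;

// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string src, std::string tgt,
                      double match, double mismatch,
                      double gap_open, double gap_extend,
                      int band_center, int band_halfwidth) {
  const int m = src.size(), n = tgt.size();
  if (m == 0 || n == 0) stop("empty sequence");
  // band: j - i in [band_center - w, band_center + w] (0-based i, j)
  const int dlo = band_center - band_halfwidth;
  const int dhi = band_center + band_halfwidth;
  if (dhi < -(m - 1) || dlo > (n - 1))
    stop("band excludes all cells (mis-sized candidate region?)");

  // full (m+1) x (n+1) matrices; sizes here are small (candidate
  // regions are |source| + 2*flank)
  std::vector<double> H((m + 1) * (n + 1), NEG);
  std::vector<double> E((m + 1) * (n + 1), NEG);
  std::vector<double> F((m + 1) * (n + 1), NEG);
  std::vector<unsigned char> TH((m + 1) * (n + 1), 0); // 0 stop,1 diag,2 E,3 F
  std::vector<unsigned char> TE((m + 1) * (n + 1), 0); // 1 open, 0 extend
  std::vector<unsigned char> TF((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  for (int j = 0; j <= n; ++j) H[at(0, j)] = 0.0;
  for (int i = 0; i <= m; ++i) H[at(i, 0)] = 0.0;

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + dlo);          // j - i >= dlo with i,j 1-based ~ same offset
    int jhi = std::min(n, i + dhi);
    for (int j = jlo; j <= jhi; ++j) {
      // E: gap in source (consume target)
      double e_open = H[at(i, j - 1)] + gap_open + gap_extend;
      double e_ext  = E[at(i, j - 1)] + gap_extend;
      if (e_open >= e_ext) { E[at(i, j)] = e_open; TE[at(i, j)] = 1; }
      else                 { E[at(i, j)] = e_ext;  TE[at(i, j)] = 0; }
      // F: gap in target (consume source)
      double f_open = H[at(i - 1, j)] + gap_open + gap_extend;
      double f_ext  = F[at(i - 1, j)] + gap_extend;
      if (f_open >= f_ext) { F[at(i, j)] = f_open; TF[at(i, j)] = 1; }
      else                 { F[at(i, j)] = f_ext;  TF[at(i, j)] = 0; }
      // H: local, so floor at 0
      double sub = (src[i - 1] == tgt[j - 1] ? match : mismatch);
      double diag = (H[at(i - 1, j - 1)] <= NEG / 2 ? NEG : H[at(i - 1, j - 1)] + sub);
      double h = 0.0; unsigned char th = 0;
      if (diag > h) { h = diag; th = 1; }
      if (E[at(i, j)] > h) { h = E[at(i, j)]; th = 2; }
      if (F[at(i, j)] > h) { h = F[at(i, j)]; th = 3; }
      H[at(i, j)] = h; TH[at(i, j)] = th;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback from the best cell
  int i = bi, j = bj, matches = 0, length = 0;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char th = TH[at(i, j)];
      if (th == 0) break;
      if (th == 1) {
        if (src[i - 1] == tgt[j - 1]) ++matches;
        ++length; --i; --j;
      } else if (th == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char te = TE[at(i, j)];
      ++length; --j;
      if (te == 1) state = 0;
    } else {
      unsigned char tf = TF[at(i, j)];
      ++length; --i;
      if (tf == 1) state = 0;
    }
  }

  return List::create(
    _["score"] = best,
    _["src_start"] = i, _["src_end"] = bi,   // 0-based half-open into source
    _["tgt_start"] = j, _["tgt_end"] = bj,   // 0-based half-open into target
    _["matches"] = matches, _["length"] = length);
}
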