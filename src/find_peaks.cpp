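#include <Rcpp.h>
using namespace Rcpp;

// Topographic peak analysis of a 1-D trace.
//
// A peak is an interior local maximum; for plateaus the leftmost sample is
// taken. Prominence is the peak height above the higher of the two lowest
// levels separating it from the nearest higher samples on each side (or
// the trace ends). Width is measured where the trace crosses
// peak - prominence/2, by linear interpolation, searched within the two
// base walks.
//
// Returns a data frame with 1-based peak indices, prominences and widths
// in samples.
// [[Rcpp::export]]
DataFrame cpp_find_peaks(NumericVector x) {
  const int n = x.size();
  std::vector<int> peaks;
  std::vector<double> proms, widths;

  // --- local maxima (leftmost sample of plateaus) ---
  int i = 1;
  while (i < n - 1) {
    if (x[i - 1] < x[i]) {
      int j = i;
      while (j < n - 1 && x[j + 1] == x[i]) ++j;
      if (j < n - 1 && x[j + 1] < x[i]) peaks.push_back(i);
      i = j + 1;
    } else {
      ++i;
    }
  }

  proms.reserve(peaks.size());
  widths.reserve(peaks.size());

  for (size_t k = 0; k < peaks.size(); ++k) {
    const int p = peaks[k];
    const double hp = x[p];

    // walk left to the nearest strictly higher sample (or start)
    double min_l = hp;
    int jl = p;
    for (int j = p - 1; j >= 0; --j) {
      if (x[j] > hp) break;
      if (x[j] < min_l) min_l = x[j];
      jl = j;
    }
    // walk right
    double min_r = hp;
    int jr = p;
    for (int j = p + 1; j < n; ++j) {
      if (x[j] > hp) break;
      if (x[j] < min_r) min_r = x[j];
      jr = j;
    }
    const double prom = hp - std::max(min_l, min_r);

    // width at half prominence, interpolated, bounded by the base walks
    const double ref = hp - prom / 2.0;
    double left_x = (double)jl;  // fallback: clip at walk end
    for (int j = p - 1; j >= jl; --j) {
      if (x[j] <= ref) {
        left_x = j + (ref - x[j]) / (x[j + 1] - x[j]);
        break;
      }
      if (j == jl) left_x = (double)jl;
    }
    double right_x = (double)jr;
    for (int j = p + 1; j <= jr; ++j) {
      if (x[j] <= ref) {
        right_x = j - (ref - x[j]) / (x[j - 1] - x[j]);
        break;
      }
      if (j == jr) right_x = (double)jr;
    }

    proms.push_back(prom);
    widths.push_back(right_x - left_x);
  }

  IntegerVector idx(peaks.size());
  for (size_t k = 0; k < peaks.size(); ++k) idx[k] = peaks[k] + 1; // 1-based
  return DataFrame::create(_["index"] = idx,
                           _["prominence"] = NumericVector(proms.begin(), proms.end()),
                           _["width_samples"] = NumericVector(widths.begin(), widths.end()));
}
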