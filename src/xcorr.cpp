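#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Full 2D cross-correlation of A against B.
// Output entry (p, q) (1-based) is the lag (dr, dc) = (p - Rb, q - Cb):
//   score(dr, dc) = sum over valid (i, j) of A(i, j) * B(i - dr, j - dc),
// i.e. the sum of elementwise products over every overlapping placement of B
// on A, including partial corner overlaps (zero padding outside).
static arma::mat xcorr_full(const arma::mat& a, const arma::mat& b) {
  return arma::conv2(a, arma::flipud(arma::fliplr(b)), "full");
}

// [[Rcpp::export]]
arma::mat xcorr2_cpp(const arma::mat& a, const arma::mat& b) {
  return xcorr_full(a, b);
}

// [[Rcpp::export]]
NumericVector min_dist_cpp(const arma::mat& x, const arma::mat& y) {
  // per row of x: minimum Euclidean distance to any row of y
  const arma::uword nx = x.n_rows, ny = y.n_rows;
  NumericVector out(nx);
  for (arma::uword i = 0; i < nx; ++i) {
    double best = R_PosInf;
    const double xi = x(i, 0), yi = x(i, 1), zi = x(i, 2);
    for (arma::uword j = 0; j < ny; ++j) {
      const double dx = xi - y(j, 0), dy = yi - y(j, 1), dz = zi - y(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Scan every (face_a, face_b, rotation, lag) placement and keep the top_k
// scores. `b_vals`/`b_occ` are nested lists: faces of B, each holding one
// value/occupancy matrix per in-plane rotation angle. Scores are maximized;
// pass minimize = true (charge complementarity) to rank most-negative first.
// Candidates are visited in lexicographic (face_a, face_b, rotation, lag)
// order and ties keep the earlier candidate, fixing the tie-break rule.
// Placements whose occupied-cell overlap is below min_overlap are skipped.
// [[Rcpp::export]]
DataFrame top_hits_cpp(List a_vals, List a_occ, List b_vals, List b_occ,
                       IntegerVector rotations, bool minimize,
                       int min_overlap, int top_k) {
  const int nfa = a_vals.size();
  const int nfb = b_vals.size();
  const int nrot = rotations.size();

  std::vector<double> sc;   // internal (sign-adjusted, maximized) scores
  std::vector<int> fa_, fb_, rot_, lr_, lc_;
  sc.reserve(top_k + 1);

  for (int fa = 0; fa < nfa; ++fa) {
    const arma::mat A = as<arma::mat>(a_vals[fa]);
    const arma::mat Ao = as<arma::mat>(a_occ[fa]);
    for (int fb = 0; fb < nfb; ++fb) {
      List bv = b_vals[fb];
      List bo = b_occ[fb];
      for (int r = 0; r < nrot; ++r) {
        const arma::mat B = as<arma::mat>(bv[r]);
        const arma::mat Bo = as<arma::mat>(bo[r]);
        const arma::mat S = xcorr_full(A, B);
        const arma::mat O = xcorr_full(Ao, Bo);
        const int Rb = B.n_rows, Cb = B.n_cols;
        for (arma::uword p = 0; p < S.n_rows; ++p) {
          for (arma::uword q = 0; q < S.n_cols; ++q) {
            if (O(p, q) + 0.5 < min_overlap) continue;
            double s = S(p, q);
            if (minimize) s = -s;
            const int n = sc.size();
            if (n == top_k && s <= sc[n - 1]) continue;
            // insert before the first strictly smaller kept score
            int pos = n;
            while (pos > 0 && sc[pos - 1] < s) --pos;
            sc.insert(sc.begin() + pos, s);
            fa_.insert(fa_.begin() + pos, fa + 1);
            fb_.insert(fb_.begin() + pos, fb + 1);
            rot_.insert(rot_.begin() + pos, rotations[r]);
            lr_.insert(lr_.begin() + pos, (int)p + 1 - Rb);
            lc_.insert(lc_.begin() + pos, (int)q + 1 - Cb);
            if ((int)sc.size() > top_k) {
              sc.pop_back(); fa_.pop_back(); fb_.pop_back();
              rot_.pop_back(); lr_.pop_back(); lc_.pop_back();
            }
          }
        }
      }
    }
  }

  NumericVector score(sc.size());
  for (size_t i = 0; i < sc.size(); ++i)
    score[i] = minimize ? -sc[i] : sc[i];
  return DataFrame::create(
    _["face_a"] = wrap(fa_), _["face_b"] = wrap(fb_),
    _["rotation_deg"] = wrap(rot_), _["lag_row"] = wrap(lr_),
    _["lag_col"] = wrap(lc_), _["score"] = score);
}
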