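#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap global alignment over a precomputed match-score matrix.
// S(i,j) is the score for pairing column i of profile A with column j of
// profile B. A gap of length L costs gap_open + L * gap_ext (Biostrings
// convention). Returns the optimal score and the traceback as two integer
// vectors over the merged columns: a_idx / b_idx give the consumed source
// column (1-based) or 0 for a gap on that side.
// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix S, double gap_open, double gap_ext) {
  const int la = S.nrow(), lb = S.ncol();
  const double NEG = -1e300;
  const double open = gap_open + gap_ext; // cost of opening (first gap char)

  // DP matrices (la+1) x (lb+1), layered: 0 = M, 1 = Ix (gap in B), 2 = Iy
  std::vector<double> M((la + 1) * (lb + 1), NEG);
  std::vector<double> Ix((la + 1) * (lb + 1), NEG);
  std::vector<double> Iy((la + 1) * (lb + 1), NEG);
  // traceback: which layer the max came from (0/1/2), per layer
  std::vector<unsigned char> tM((la + 1) * (lb + 1), 0);
  std::vector<unsigned char> tIx((la + 1) * (lb + 1), 0);
  std::vector<unsigned char> tIy((la + 1) * (lb + 1), 0);

  const int W = lb + 1;
  M[0] = 0.0;
  for (int i = 1; i <= la; ++i) {
    Ix[i * W] = -(gap_open + i * gap_ext);
    tIx[i * W] = 1;
  }
  for (int j = 1; j <= lb; ++j) {
    Iy[j] = -(gap_open + j * gap_ext);
    tIy[j] = 2;
  }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const int ij = i * W + j;
      // M: consume both
      {
        const int p = (i - 1) * W + (j - 1);
        double best = M[p]; unsigned char arg = 0;
        if (Ix[p] > best) { best = Ix[p]; arg = 1; }
        if (Iy[p] > best) { best = Iy[p]; arg = 2; }
        M[ij] = best + S(i - 1, j - 1);
        tM[ij] = arg;
      }
      // Ix: consume A column, gap in B
      {
        const int p = (i - 1) * W + j;
        double fromM = M[p] - open;
        double fromIx = Ix[p] - gap_ext;
        double fromIy = Iy[p] - open;
        double best = fromM; unsigned char arg = 0;
        if (fromIx > best) { best = fromIx; arg = 1; }
        if (fromIy > best) { best = fromIy; arg = 2; }
        Ix[ij] = best;
        tIx[ij] = arg;
      }
      // Iy: consume B column, gap in A
      {
        const int p = i * W + (j - 1);
        double fromM = M[p] - open;
        double fromIx = Ix[p] - open;
        double fromIy = Iy[p] - gap_ext;
        double best = fromM; unsigned char arg = 0;
        if (fromIx > best) { best = fromIx; arg = 1; }
        if (fromIy > best) { best = fromIy; arg = 2; }
        Iy[ij] = best;
        tIy[ij] = arg;
      }
    }
  }

  const int end = la * W + lb;
  double score = M[end]; int layer = 0;
  if (Ix[end] > score) { score = Ix[end]; layer = 1; }
  if (Iy[end] > score) { score = Iy[end]; layer = 2; }

  // traceback
  std::vector<int> ra, rb;
  ra.reserve(la + lb); rb.reserve(la + lb);
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    const int ij = i * W + j;
    if (layer == 0) {
      ra.push_back(i); rb.push_back(j);
      layer = tM[ij]; --i; --j;
    } else if (layer == 1) {
      ra.push_back(i); rb.push_back(0);
      layer = tIx[ij]; --i;
    } else {
      ra.push_back(0); rb.push_back(j);
      layer = tIy[ij]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(ra.begin(), ra.end()),
                      _["b_idx"] = IntegerVector(rb.begin(), rb.end()));
}

// Per-window additive scores for motif search. seqs: list of integer vectors
// with residues coded 1..20 and 0 for masked positions. mat: 20 x W matrix of
// per-position contributions (e.g. log(ppm/background)). Windows overlapping a
// masked position score -Inf. Sequences shorter than W yield length-0 vectors.
// [[Rcpp::export]]
List cpp_window_scores(List seqs, NumericMatrix mat) {
  const int W = mat.ncol();
  const int n = seqs.size();
  List out(n);
  for (int s = 0; s < n; ++s) {
    IntegerVector x = seqs[s];
    const int L = x.size();
    const int m = L - W + 1;
    if (m < 1) { out[s] = NumericVector(0); continue; }
    NumericVector sc(m);
    for (int j = 0; j < m; ++j) {
      double acc = 0.0; bool ok = true;
      for (int t = 0; t < W; ++t) {
        const int a = x[j + t];
        if (a == 0) { ok = false; break; }
        acc += mat(a - 1, t);
      }
      sc[j] = ok ? acc : R_NegInf;
    }
    out[s] = sc;
  }
  return out;
}

// Weighted residue counts over motif windows (the EM M-step accumulator).
// weights: list parallel to seqs, one weight per window (0 for invalid).
// Returns a 20 x W matrix of expected counts.
// [[Rcpp::export]]
NumericMatrix cpp_site_counts(List seqs, List weights, int W) {
  NumericMatrix counts(20, W);
  const int n = seqs.size();
  for (int s = 0; s < n; ++s) {
    IntegerVector x = seqs[s];
    NumericVector w = weights[s];
    const int m = w.size();
    for (int j = 0; j < m; ++j) {
      const double wj = w[j];
      if (wj <= 0.0) continue;
      for (int t = 0; t < W; ++t) {
        const int a = x[j + t];
        if (a > 0) counts(a - 1, t) += wj;
      }
    }
  }
  return counts;
}

// Full ZOOPS EM run. seqs: integer-coded sequences (1..20, 0 masked);
// bg: background frequencies; ppm0: 20 x W initial PPM; gamma0: initial
// occupancy prior. Iterates E/M steps with a Dirichlet pseudocount on the
// PPM and a Beta(1.1,1.1) prior on gamma until the MAP objective changes by
// less than tol (or max_iter). Returns the parameters that entered the last
// E-step together with its posteriors, so everything reported is consistent.
// [[Rcpp::export]]
List cpp_zoops_em(List seqs, NumericVector bg, NumericMatrix ppm0,
                  double gamma0, int max_iter, double tol,
                  double pseudocount) {
  const int n = seqs.size();
  const int W = ppm0.ncol();
  NumericMatrix ppm = clone(ppm0);
  double gamma = gamma0;
  std::vector<double> trace;
  NumericVector zsum(n);
  List zlist(n);
  double ll = 0.0;
  NumericVector logbg(20);
  for (int a = 0; a < 20; ++a) logbg[a] = std::log(bg[a]);

  NumericMatrix lods(20, W);
  NumericMatrix ppm_out = clone(ppm);
  double gamma_out = gamma;

  for (int it = 0; it < max_iter; ++it) {
    for (int a = 0; a < 20; ++a)
      for (int j = 0; j < W; ++j)
        lods(a, j) = std::log(ppm(a, j)) - logbg[a];
    const double lg = std::log(gamma), l1g = std::log1p(-gamma);

    NumericMatrix counts(20, W);
    double ztot = 0.0;
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      IntegerVector x = seqs[i];
      const int L = x.size();
      const int m = L - W + 1;
      if (m < 1) { zlist[i] = NumericVector(0); zsum[i] = 0.0; continue; }
      NumericVector s(m);
      int nfin = 0;
      double smax = R_NegInf;
      for (int j = 0; j < m; ++j) {
        double acc = 0.0; bool ok = true;
        for (int t = 0; t < W; ++t) {
          const int a = x[j + t];
          if (a == 0) { ok = false; break; }
          acc += lods(a - 1, t);
        }
        s[j] = ok ? acc : R_NegInf;
        if (ok) { ++nfin; if (acc > smax) smax = acc; }
      }
      NumericVector z(m);
      if (nfin == 0) { zlist[i] = z; zsum[i] = 0.0; continue; }
      const double lm = std::log((double) nfin);
      // log-sum-exp over {l1g} U {lg - lm + s_j}
      double mx = l1g;
      if (lg - lm + smax > mx) mx = lg - lm + smax;
      double acc = std::exp(l1g - mx);
      for (int j = 0; j < m; ++j)
        if (R_finite(s[j])) acc += std::exp(lg - lm + s[j] - mx);
      const double lden = mx + std::log(acc);
      double zs = 0.0;
      for (int j = 0; j < m; ++j) {
        if (!R_finite(s[j])) { z[j] = 0.0; continue; }
        z[j] = std::exp(lg - lm + s[j] - lden);
        zs += z[j];
        if (z[j] > 0.0)
          for (int t = 0; t < W; ++t)
            counts(x[j + t] - 1, t) += z[j];
      }
      zlist[i] = z;
      zsum[i] = zs;
      ztot += zs;
      ll += lden;
    }
    // MAP objective for the parameters that entered this E-step
    double obj = ll + 0.1 * (std::log(gamma) + std::log1p(-gamma));
    for (int a = 0; a < 20; ++a)
      for (int j = 0; j < W; ++j)
        obj += pseudocount * std::log(ppm(a, j));
    trace.push_back(obj);
    ppm_out = clone(ppm);
    gamma_out = gamma;
    if (it > 0 && std::fabs(obj - trace[it - 1]) < tol) break;
    // M-step
    for (int j = 0; j < W; ++j) {
      double cs = 0.0;
      for (int a = 0; a < 20; ++a) cs += counts(a, j);
      for (int a = 0; a < 20; ++a)
        ppm(a, j) = (counts(a, j) + pseudocount) / (cs + 20.0 * pseudocount);
    }
    gamma = (ztot + 0.1) / (n + 0.2);
  }
  return List::create(_["ppm"] = ppm_out, _["gamma"] = gamma_out,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["z"] = zlist, _["zsum"] = zsum, _["ll"] = ll);
}

// Support score of candidate seed PPMs: for each candidate window (given as
// rows of residues codes), build the seed log-odds (matched residue prob
// `match`, remainder uniform) and sum the best window log-odds over all
// sequences. One C++ pass replaces per-candidate scoring calls from R.
// [[Rcpp::export]]
NumericVector cpp_support_scores(List seqs, IntegerMatrix windows,
                                 NumericVector bg, double match) {
  const int ncand = windows.nrow();
  const int W = windows.ncol();
  const int n = seqs.size();
  const double lmatch = std::log(match), lrest = std::log((1.0 - match) / 19.0);
  double logbg[20];
  for (int a = 0; a < 20; ++a) logbg[a] = std::log(bg[a]);
  NumericVector out(ncand);
  for (int c = 0; c < ncand; ++c) {
    // per-position log-odds: lmatch - log(bg[a]) if a matches, else lrest - log(bg[a])
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      IntegerVector x = seqs[i];
      const int m = x.size() - W + 1;
      double best = R_NegInf;
      for (int j = 0; j < m; ++j) {
        double acc = 0.0; bool ok = true;
        for (int t = 0; t < W; ++t) {
          const int a = x[j + t];
          if (a == 0) { ok = false; break; }
          acc += (a == windows(c, t) ? lmatch : lrest) - logbg[a - 1];
        }
        if (ok && acc > best) best = acc;
      }
      if (R_finite(best)) tot += best;
    }
    out[c] = tot;
  }
  return out;
}
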