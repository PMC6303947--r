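#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh). Gap of length k costs
// open + (k - 1) * extend, i.e. the first gapped residue pays `open`.
// Traceback ties are broken diagonal > up (gap in b) > left (gap in a).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct SubLookup {
  double tab[128][128];
  SubLookup(const NumericMatrix& sub) {
    for (int i = 0; i < 128; ++i)
      for (int j = 0; j < 128; ++j) tab[i][j] = NA_REAL;
    CharacterVector rn = rownames(sub), cn = colnames(sub);
    for (int i = 0; i < sub.nrow(); ++i) {
      char a = CHAR(STRING_ELT(rn, i))[0];
      for (int j = 0; j < sub.ncol(); ++j) {
        char b = CHAR(STRING_ELT(cn, j))[0];
        tab[(int)a][(int)b] = sub(i, j);
      }
    }
  }
  double operator()(char a, char b) const {
    double s = tab[(int)a][(int)b];
    if (NumericVector::is_na(s))
      stop("substitution score undefined for residue pair %c/%c", a, b);
    return s;
  }
};

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b, NumericMatrix sub,
                    double gap_open, double gap_extend, bool local) {
  int n = a.size(), m = b.size();
  SubLookup S(sub);
  // state matrices: M diag, X gap in b (consumes a), Y gap in a (consumes b)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG_INF; X(i, j) = NEG_INF; Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) X(i, 0) = -(gap_open + (i - 1) * gap_extend);
    for (int j = 1; j <= m; ++j) Y(0, j) = -(gap_open + (j - 1) * gap_extend);
  } else {
    for (int i = 0; i <= n; ++i) M(i, 0) = 0.0;
    for (int j = 0; j <= m; ++j) M(0, j) = 0.0;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sc = S(a[i - 1], b[j - 1]);
      double prev = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      double mv = (prev == NEG_INF) ? NEG_INF : prev + sc;
      if (local) mv = std::max(mv, sc);
      M(i, j) = mv;
      double xo = (M(i - 1, j) == NEG_INF) ? NEG_INF : M(i - 1, j) - gap_open;
      double yo_ = (Y(i - 1, j) == NEG_INF) ? NEG_INF : Y(i - 1, j) - gap_open;
      double xe = (X(i - 1, j) == NEG_INF) ? NEG_INF : X(i - 1, j) - gap_extend;
      X(i, j) = std::max(std::max(xo, yo_), xe);
      double yo = (M(i, j - 1) == NEG_INF) ? NEG_INF : M(i, j - 1) - gap_open;
      double xo2 = (X(i, j - 1) == NEG_INF) ? NEG_INF : X(i, j - 1) - gap_open;
      double ye = (Y(i, j - 1) == NEG_INF) ? NEG_INF : Y(i, j - 1) - gap_extend;
      Y(i, j) = std::max(std::max(yo, xo2), ye);
    }
  }
  int ei = n, ej = m;
  double best;
  if (local) {
    best = 0.0; ei = 0; ej = 0;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j) {
        double h = std::max(M(i, j), std::max(X(i, j), Y(i, j)));
        if (h > best + 1e-12) { best = h; ei = i; ej = j; }
      }
  } else {
    best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  }
  // traceback
  std::string ra, rb;
  int i = ei, j = ej;
  // current state: 0 = M, 1 = X, 2 = Y; pick best at end, diag preferred
  int st;
  double h = NEG_INF;
  st = 0; h = M(i, j);
  if (X(i, j) > h + 1e-12) { st = 1; h = X(i, j); }
  if (Y(i, j) > h + 1e-12) { st = 2; h = Y(i, j); }
  const double tol = 1e-9;
  while (i > 0 || j > 0) {
    if (local && std::max(M(i, j), std::max(X(i, j), Y(i, j))) <= tol && st == 0 && M(i, j) <= tol)
      break;
    if (st == 0) {
      if (i == 0 || j == 0) break;
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      double sc = S(a[i - 1], b[j - 1]);
      double target = M(i, j) - sc;
      --i; --j;
      if (local && std::fabs(target) <= tol &&
          !(std::fabs(M(i, j) - target) <= tol || std::fabs(X(i, j) - target) <= tol ||
            std::fabs(Y(i, j) - target) <= tol))
        break;  // local alignment started here
      if (std::fabs(M(i, j) - target) <= tol) st = 0;
      else if (std::fabs(X(i, j) - target) <= tol) st = 1;
      else if (std::fabs(Y(i, j) - target) <= tol) st = 2;
      else if (local) break;
      else stop("traceback failure (M)");
    } else if (st == 1) {
      if (i == 0) break;
      ra.push_back(a[i - 1]); rb.push_back('-');
      double t_open = X(i, j) + gap_open, t_ext = X(i, j) + gap_extend;
      --i;
      if (std::fabs(M(i, j) - t_open) <= tol) st = 0;
      else if (std::fabs(X(i, j) - t_ext) <= tol) st = 1;
      else if (std::fabs(Y(i, j) - t_open) <= tol) st = 2;
      else stop("traceback failure (X)");
    } else {
      if (j == 0) break;
      ra.push_back('-'); rb.push_back(b[j - 1]);
      double t_open = Y(i, j) + gap_open, t_ext = Y(i, j) + gap_extend;
      --j;
      if (std::fabs(M(i, j) - t_open) <= tol) st = 0;
      else if (std::fabs(Y(i, j) - t_ext) <= tol) st = 2;
      else if (std::fabs(X(i, j) - t_open) <= tol) st = 1;
      else stop("traceback failure (Y)");
    }
    if (local) {
      double hh = std::max(M(i, j), std::max(X(i, j), Y(i, j)));
      if (st == 0 && std::fabs(hh) <= tol) break;
    }
  }
  if (!local) {
    // consume leading gaps against origin
    while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
    while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  if (local && best <= tol) { ra.clear(); rb.clear(); i = 0; j = 0; ei = 0; ej = 0; best = 0.0; }
  return List::create(_["score"] = best, _["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["a_start"] = i, _["a_end"] = ei, _["b_start"] = j, _["b_end"] = ej);
}

// Sequence-to-profile global alignment used by add_to_seed(). `colscore` is a
// (n_columns x 128) matrix of scores for aligning ASCII residue r to column j,
// prepared in R. Moves: diag (residue into column), left (gap in the new row),
// up (residue dropped as an insertion relative to the seed). Length of the
// returned row equals the number of seed columns.
// [[Rcpp::export]]
List profile_align_cpp(std::string seq, NumericMatrix colscore,
                       double gap_open, double gap_extend) {
  int n = seq.size(), m = colscore.nrow();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG_INF; X(i, j) = NEG_INF; Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = -(gap_open + (i - 1) * gap_extend);
  for (int j = 1; j <= m; ++j) Y(0, j) = -(gap_open + (j - 1) * gap_extend);
  for (int i = 1; i <= n; ++i) {
    int r = (int)(unsigned char)seq[i - 1];
    for (int j = 1; j <= m; ++j) {
      double sc = colscore(j - 1, r);
      double prev = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = (prev == NEG_INF) ? NEG_INF : prev + sc;
      double xo = (M(i - 1, j) == NEG_INF) ? NEG_INF : M(i - 1, j) - gap_open;
      double yo_ = (Y(i - 1, j) == NEG_INF) ? NEG_INF : Y(i - 1, j) - gap_open;
      double xe = (X(i - 1, j) == NEG_INF) ? NEG_INF : X(i - 1, j) - gap_extend;
      X(i, j) = std::max(std::max(xo, yo_), xe);
      double yo = (M(i, j - 1) == NEG_INF) ? NEG_INF : M(i, j - 1) - gap_open;
      double xo2 = (X(i, j - 1) == NEG_INF) ? NEG_INF : X(i, j - 1) - gap_open;
      double ye = (Y(i, j - 1) == NEG_INF) ? NEG_INF : Y(i, j - 1) - gap_extend;
      Y(i, j) = std::max(std::max(yo, xo2), ye);
    }
  }
  // traceback from (n, m)
  int i = n, j = m, st = 0;
  double h = M(n, m);
  if (X(n, m) > h + 1e-12) { st = 1; h = X(n, m); }
  if (Y(n, m) > h + 1e-12) { st = 2; h = Y(n, m); }
  std::string row;          // gapped new row over seed columns (reversed)
  std::vector<int> dropped; // 1-based positions of residues dropped
  const double tol = 1e-9;
  while (i > 0 || j > 0) {
    if (st == 0) {
      if (i == 0 || j == 0) break;
      int r = (int)(unsigned char)seq[i - 1];
      row.push_back(seq[i - 1]);
      double target = M(i, j) - colscore(j - 1, r);
      --i; --j;
      if (std::fabs(M(i, j) - target) <= tol) st = 0;
      else if (std::fabs(X(i, j) - target) <= tol) st = 1;
      else if (std::fabs(Y(i, j) - target) <= tol) st = 2;
      else stop("profile traceback failure (M)");
    } else if (st == 1) {
      // residue dropped (insertion relative to the seed)
      dropped.push_back(i);
      double t_open = X(i, j) + gap_open, t_ext = X(i, j) + gap_extend;
      --i;
      if (i == 0 && j == 0) break;
      if (std::fabs(M(i, j) - t_open) <= tol) st = 0;
      else if (std::fabs(X(i, j) - t_ext) <= tol) st = 1;
      else if (std::fabs(Y(i, j) - t_open) <= tol) st = 2;
      else stop("profile traceback failure (X)");
    } else {
      row.push_back('-');
      double t_open = Y(i, j) + gap_open, t_ext = Y(i, j) + gap_extend;
      --j;
      if (i == 0 && j == 0) break;
      if (std::fabs(M(i, j) - t_open) <= tol) st = 0;
      else if (std::fabs(Y(i, j) - t_ext) <= tol) st = 2;
      else if (std::fabs(X(i, j) - t_open) <= tol) st = 1;
      else stop("profile traceback failure (Y)");
    }
  }
  std::reverse(row.begin(), row.end());
  std::reverse(dropped.begin(), dropped.end());
  return List::create(_["score"] = h, _["row"] = row, _["dropped"] = wrap(dropped));
}

// Pairwise-deletion mismatch proportions over gapped rows of equal length.
// Returns the p-distance matrix and the shared (both non-gap) column counts.
// [[Rcpp::export]]
List pdist_cpp(CharacterVector rows) {
  int n = rows.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(rows[i]);
  NumericMatrix p(n, n);
  IntegerMatrix shared(n, n);
  int L = n ? (int)s[0].size() : 0;
  for (int i = 0; i < n; ++i) {
    shared(i, i) = L;
    for (int j = i + 1; j < n; ++j) {
      int ns = 0, mm = 0;
      for (int k = 0; k < L; ++k) {
        char a = s[i][k], b = s[j][k];
        if (a == '-' || b == '-') continue;
        ++ns;
        if (a != b) ++mm;
      }
      shared(i, j) = ns; shared(j, i) = ns;
      double pv = ns > 0 ? (double)mm / ns : NA_REAL;
      p(i, j) = pv; p(j, i) = pv;
    }
  }
  return List::create(_["p"] = p, _["shared"] = shared);
}
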