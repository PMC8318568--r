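#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps. A gap of length L
// costs gap_open + L * gap_ext; terminal gaps are penalized in the score.
// Deterministic tie-breaking in the traceback: substitution state first,
// then gap-in-b (character from `a` over a gap), then gap-in-a.

static const double NEG = -1e18;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix sub,
                  double gap_open, double gap_ext) {
  int n = (int)a.size(), m = (int)b.size();
  CharacterVector rn = rownames(sub);
  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (int i = 0; i < rn.size(); ++i) {
    std::string r = as<std::string>(rn[i]);
    if (!r.empty()) idx[(unsigned char)r[0]] = i;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = idx[(unsigned char)a[i]];
    if (ai[i] < 0) stop("character '%c' not in substitution matrix", a[i]);
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = idx[(unsigned char)b[j]];
    if (bi[j] < 0) stop("character '%c' not in substitution matrix", b[j]);
  }
  size_t W = (size_t)(m + 1);
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = -(gap_open + i * gap_ext);
  for (int j = 1; j <= m; ++j) Y[j] = -(gap_open + j * gap_ext);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
             l = i * W + (j - 1);
      double best = M[d];
      if (X[d] > best) best = X[d];
      if (Y[d] > best) best = Y[d];
      M[c] = sub(ai[i - 1], bi[j - 1]) + best;
      double xo = M[u] - gap_open - gap_ext, xx = X[u] - gap_ext,
             xy = Y[u] - gap_open - gap_ext;
      X[c] = xo >= xx ? (xo >= xy ? xo : xy) : (xx >= xy ? xx : xy);
      double yo = M[l] - gap_open - gap_ext, yx = X[l] - gap_open - gap_ext,
             yy = Y[l] - gap_ext;
      Y[c] = yo >= yx ? (yo >= yy ? yo : yy) : (yx >= yy ? yx : yy);
    }
  }
  size_t e = n * W + m;
  int state; // 0 = M, 1 = X, 2 = Y; prefer M, then X
  double score;
  if (M[e] >= X[e] && M[e] >= Y[e]) { state = 0; score = M[e]; }
  else if (X[e] >= Y[e]) { state = 1; score = X[e]; }
  else { state = 2; score = Y[e]; }
  std::string oa, ob;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0 && i > 0 && j > 0) {
      oa.push_back(a[i - 1]);
      ob.push_back(b[j - 1]);
      size_t d = (size_t)(i - 1) * W + (j - 1);
      double v = M[(size_t)i * W + j] - sub(ai[i - 1], bi[j - 1]);
      if (M[d] >= v - 1e-9) state = 0;
      else if (X[d] >= v - 1e-9) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1 || j == 0) {
      oa.push_back(a[i - 1]);
      ob.push_back('-');
      size_t u = (size_t)(i - 1) * W + j;
      double v = X[(size_t)i * W + j];
      if (i == 1 && j == 0) state = 0; // at origin
      else if (M[u] - gap_open - gap_ext >= v - 1e-9) state = 0;
      else if (X[u] - gap_ext >= v - 1e-9) state = 1;
      else state = 2;
      --i;
    } else {
      oa.push_back('-');
      ob.push_back(b[j - 1]);
      size_t l = (size_t)i * W + (j - 1);
      double v = Y[(size_t)i * W + j];
      if (i == 0 && j == 1) state = 0;
      else if (M[l] - gap_open - gap_ext >= v - 1e-9) state = 0;
      else if (X[l] - gap_open - gap_ext >= v - 1e-9) state = 1;
      else state = 2;
      --j;
    }
  }
  std::reverse(oa.begin(), oa.end());
  std::reverse(ob.begin(), ob.end());
  return List::create(_["aligned_a"] = oa, _["aligned_b"] = ob,
                      _["score"] = score);
}
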