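#include <Rcpp.h>
using namespace Rcpp;

// Sequential inner loops shared by the simulator, the trimmer, the marker
// screen and the read mapper. All randomness goes through R's RNG so that
// set.seed() in R governs every draw.

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline int base_idx(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// Generate a genome from an order-m Markov chain. `probs` has 4^order rows
// (contexts, base-4 little-endian with the most recent base in the lowest
// digit) and 4 columns summing to 1 per row.
// [[Rcpp::export]]
String cpp_markov_generate(int n, int order, NumericMatrix probs) {
  if (n <= 0) return String("");
  std::string out(n, 'A');
  int n_ctx = probs.nrow();
  int ctx = 0;
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    int row = (i >= order) ? ctx : (ctx % n_ctx);
    double acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += probs(row, j);
      if (u <= acc) { b = j; break; }
    }
    out[i] = BASES[b];
    ctx = (ctx * 4 + b) % n_ctx;
    if (n_ctx == 1) ctx = 0;
  }
  return String(out);
}

// Substitution errors at a fixed per-base rate; the replacement base is
// drawn uniformly from the three alternatives.
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, double rate) {
  int n = seqs.size();
  CharacterVector out(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      if (unif_rand() < rate) {
        int b = base_idx(s[p]);
        if (b < 0) continue;
        int r = (int)(unif_rand() * 3.0);
        if (r > 2) r = 2;
        s[p] = BASES[(b + 1 + r) % 4];
      }
    }
    out[i] = s;
  }
  return out;
}

// Trimmomatic-style bounds: LEADING/TRAILING single-base truncation, then
// truncation at the start of the first sliding window (size w) whose mean
// quality is below wq. Returns 1-based [start, end] per read; start > end
// means everything was trimmed. Qualities are phred+33 strings.
// [[Rcpp::export]]
IntegerMatrix cpp_trim_bounds(CharacterVector quals, int leading, int trailing,
                              int w, double wq) {
  int n = quals.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(quals[i]);
    int len = (int)q.size();
    int s = 0, e = len - 1;
    while (s < len && (q[s] - 33) < leading) ++s;
    while (e >= s && (q[e] - 33) < trailing) --e;
    int m = e - s + 1;
    if (m >= w) {
      double sum = 0.0;
      for (int j = 0; j < w; ++j) sum += q[s + j] - 33;
      int cut = -1;
      if (sum / w < wq) cut = 0;
      for (int j = 1; cut < 0 && j + w - 1 < m; ++j) {
        sum += (q[s + j + w - 1] - 33) - (q[s + j - 1] - 33);
        if (sum / w < wq) cut = j;
      }
      if (cut >= 0) e = s + cut - 1;
    }
    out(i, 0) = s + 1;
    out(i, 1) = e + 1;
  }
  return out;
}

// Best ungapped alignment of an integer-coded peptide (0..19, -1 unknown)
// against a PSSM (ncol x 20 log-odds, bits), over every diagonal, allowing
// partial overlap. Returns score, query start/end and profile start/end of
// the best-scoring segment (1-based), via best local segment per diagonal.
// [[Rcpp::export]]
NumericVector cpp_pssm_ungapped(IntegerVector seq, NumericMatrix mat) {
  int n = seq.size(), L = mat.nrow();
  double best = 0.0;
  int bqs = 0, bqe = -1, bps = 0, bpe = -1;
  for (int d = -(L - 1); d < n; ++d) {
    // query position i aligns to profile column i - d
    double run = 0.0, runbest = 0.0;
    int rs = -1, brs = -1, bre = -1;
    int i0 = d > 0 ? d : 0;
    int i1 = std::min(n, L + d);
    for (int i = i0; i < i1; ++i) {
      int a = seq[i];
      double sc = (a >= 0) ? mat(i - d, a) : -1.0;
      if (run <= 0) { run = sc; rs = i; }
      else run += sc;
      if (run > runbest) { runbest = run; brs = rs; bre = i; }
    }
    if (runbest > best) {
      best = runbest;
      bqs = brs; bqe = bre;
      bps = brs - d; bpe = bre - d;
    }
  }
  return NumericVector::create(best, bqs + 1, bqe + 1, bps + 1, bpe + 1);
}

// Banded gapped local alignment of peptide vs PSSM around diagonal d0
// (query_pos - profile_col), affine gaps in bits. Returns best score.
// [[Rcpp::export]]
double cpp_pssm_banded(IntegerVector seq, NumericMatrix mat, int d0, int band,
                       double gap_open, double gap_ext) {
  int n = seq.size(), L = mat.nrow();
  double best = 0.0;
  int width = 2 * band + 1;
  std::vector<double> M(width, 0.0), Mp(width, 0.0);
  std::vector<double> X(width, -1e9), Xp(width, -1e9); // gap in profile
  std::vector<double> Y(width, -1e9), Yp(width, -1e9); // gap in query
  for (int i = 0; i < n; ++i) {
    std::fill(M.begin(), M.end(), 0.0);
    std::fill(X.begin(), X.end(), -1e9);
    std::fill(Y.begin(), Y.end(), -1e9);
    for (int k = 0; k < width; ++k) {
      int j = i - d0 - band + k; // profile column
      if (j < 0 || j >= L) continue;
      int a = seq[i];
      double sub = (a >= 0) ? mat(j, a) : -1.0;
      // diagonal predecessor sits at same k in previous row
      double diag = Mp[k];
      double dx = Xp[k] > Yp[k] ? Xp[k] : Yp[k];
      if (dx > diag) diag = dx;
      double m = diag + sub;
      if (m < 0) m = 0;
      // gap in query (consume profile column j-1 at same i): k-1
      if (k > 0) {
        double yo = M[k - 1] - gap_open;
        double ye = Y[k - 1] - gap_ext;
        Y[k] = yo > ye ? yo : ye;
        if (Y[k] > m) { /* keep M as state max below */ }
      }
      // gap in profile (consume query row i-1 at same j): previous row k+1
      if (k + 1 < width) {
        double xo = Mp[k + 1] - gap_open;
        double xe = Xp[k + 1] - gap_ext;
        X[k] = xo > xe ? xo : xe;
      }
      M[k] = m;
      double cell = m;
      if (X[k] > cell) cell = X[k];
      if (Y[k] > cell) cell = Y[k];
      if (cell > best) best = cell;
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  return best;
}

// 1-based offsets at which paired strings differ (assumes equal length).
// [[Rcpp::export]]
List cpp_mismatch_offsets(CharacterVector a, CharacterVector b) {
  int n = a.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::string x = as<std::string>(a[i]);
    std::string y = as<std::string>(b[i]);
    size_t m = std::min(x.size(), y.size());
    std::vector<int> mm;
    for (size_t p = 0; p < m; ++p) if (x[p] != y[p]) mm.push_back((int)p + 1);
    out[i] = wrap(mm);
  }
  return out;
}

// Distinct k-mer codes (base-4) of a sequence; windows containing a
// non-ACGT character are skipped. Codes are 0 .. 4^k - 1.
// [[Rcpp::export]]
IntegerVector cpp_kmer_codes(std::string s, int k) {
  int n = (int)s.size();
  std::vector<int> codes;
  if (n >= k) {
    int code = 0, valid = 0, mask = 1;
    for (int j = 0; j < k - 1; ++j) mask *= 4;
    for (int i = 0; i < n; ++i) {
      int b = base_idx(s[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = (code % mask) * 4 + b;
      if (++valid >= k) codes.push_back(code);
    }
  }
  std::sort(codes.begin(), codes.end());
  codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
  return wrap(codes);
}
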