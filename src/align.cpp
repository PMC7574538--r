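#include <Rcpp.h>
#include <unordered_set>
#include <string>
#include <vector>
#include <cstdint>
#include <climits>
using namespace Rcpp;

namespace {

const int NEG_INF = INT_MIN / 4;

struct Scoring {
  int match, mismatch, gap_open, gap_extend;
};

// One alignment column. op: 'M' match, 'X' mismatch, 'I' inserted read base
// (refpos = inter-base anchor), 'D' deleted ref base (readpos = -1).
struct Col {
  char op;
  int refpos;
  int readpos;
};

struct Alignment {
  int score = NEG_INF;
  int ref_start = 0, ref_end = 0;
  std::vector<Col> cols;
  int matches = 0;
};

inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp(out[i]);
  return out;
}

// Score-only semi-global DP: read global, reference ends free. Affine gaps,
// a gap of length L costs gap_open + L * gap_extend. Gotoh three-state model
// (no direct I<->D transitions).
int sg_score(const std::string& q, const std::string& r, const Scoring& sc) {
  const int n = (int)q.size(), m = (int)r.size();
  const int go = sc.gap_open + sc.gap_extend, ge = sc.gap_extend;
  std::vector<int> Mp(m + 1), Ip(m + 1), Dp(m + 1);
  std::vector<int> M(m + 1), I(m + 1), D(m + 1);
  for (int j = 0; j <= m; ++j) { Mp[j] = 0; Ip[j] = NEG_INF; Dp[j] = NEG_INF; }
  int best = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG_INF;
    I[0] = -(sc.gap_open + i * sc.gap_extend);
    D[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      int s = (q[i - 1] == r[j - 1]) ? sc.match : -sc.mismatch;
      int diag = std::max(Mp[j - 1], std::max(Ip[j - 1], Dp[j - 1]));
      M[j] = (diag <= NEG_INF / 2) ? NEG_INF : diag + s;
      I[j] = std::max(Mp[j] - go, Ip[j] - ge);
      D[j] = std::max(M[j - 1] - go, D[j - 1] - ge);
    }
    std::swap(M, Mp); std::swap(I, Ip); std::swap(D, Dp);
  }
  for (int j = 0; j <= m; ++j) {
    int v = std::max(Mp[j], Ip[j]);
    if (v > best) best = v;
  }
  return best;
}

// Full DP with traceback. Tie-break at every choice point: D before I before
// diagonal; alignment end at the leftmost reference column achieving the
// optimum (trailing reference skip is free).
Alignment sg_align_full(const std::string& q, const std::string& r, const Scoring& sc) {
  const int n = (int)q.size(), m = (int)r.size();
  const int W = m + 1;
  const int go = sc.gap_open + sc.gap_extend, ge = sc.gap_extend;
  std::vector<int> M((size_t)(n + 1) * W, NEG_INF),
                   I((size_t)(n + 1) * W, NEG_INF),
                   D((size_t)(n + 1) * W, NEG_INF);
  for (int j = 0; j <= m; ++j) M[j] = 0;
  for (int i = 1; i <= n; ++i) {
    int* Mi = &M[(size_t)i * W]; int* Mi1 = &M[(size_t)(i - 1) * W];
    int* Ii = &I[(size_t)i * W]; int* Ii1 = &I[(size_t)(i - 1) * W];
    int* Di = &D[(size_t)i * W]; int* Di1 = &D[(size_t)(i - 1) * W];
    Ii[0] = -(sc.gap_open + i * sc.gap_extend);
    for (int j = 1; j <= m; ++j) {
      int s = (q[i - 1] == r[j - 1]) ? sc.match : -sc.mismatch;
      int diag = std::max(Mi1[j - 1], std::max(Ii1[j - 1], Di1[j - 1]));
      Mi[j] = (diag <= NEG_INF / 2) ? NEG_INF : diag + s;
      Ii[j] = std::max(Mi1[j] - go, Ii1[j] - ge);
      Di[j] = std::max(Mi[j - 1] - go, Di[j - 1] - ge);
    }
  }
  Alignment a;
  int best = NEG_INF, jend = 0;
  char endst = 'M';
  for (int j = 0; j <= m; ++j) {
    int mm = M[(size_t)n * W + j], ii = I[(size_t)n * W + j];
    int v = std::max(mm, ii);
    if (v > best) { best = v; jend = j; endst = (ii >= mm) ? 'I' : 'M'; }
  }
  a.score = best;
  a.ref_end = jend;
  int i = n, j = jend;
  char st = endst;
  std::vector<Col> rev;
  while (i > 0) {
    if (st == 'M') {
      bool ok = (q[i - 1] == r[j - 1]);
      Col c; c.op = ok ? 'M' : 'X'; c.refpos = j - 1; c.readpos = i - 1;
      rev.push_back(c);
      int target = M[(size_t)i * W + j] - (ok ? sc.match : -sc.mismatch);
      if (i > 1 || j > 1) {
        if (D[(size_t)(i - 1) * W + (j - 1)] == target) st = 'D';
        else if (I[(size_t)(i - 1) * W + (j - 1)] == target) st = 'I';
        else st = 'M';
      }
      --i; --j;
    } else if (st == 'I') {
      Col c; c.op = 'I'; c.refpos = j; c.readpos = i - 1;
      rev.push_back(c);
      int cur = I[(size_t)i * W + j];
      if (I[(size_t)(i - 1) * W + j] - ge == cur) st = 'I';
      else st = 'M';
      --i;
    } else { // 'D'
      Col c; c.op = 'D'; c.refpos = j - 1; c.readpos = -1;
      rev.push_back(c);
      int cur = D[(size_t)i * W + j];
      if (D[(size_t)i * W + (j - 1)] - ge == cur) st = 'D';
      else st = 'M';
      --j;
    }
  }
  a.ref_start = j;
  a.cols.assign(rev.rbegin(), rev.rend());
  for (size_t k = 0; k < a.cols.size(); ++k)
    if (a.cols[k].op == 'M') a.matches++;
  return a;
}

// Shift indels to their leftmost alignment-equivalent placement. A gap run is
// moved across an immediately preceding exact-match column when the swapped
// column remains an exact match (the usual left-normalization of indels).
void left_normalize(Alignment& a, const std::string& q, const std::string& r) {
  std::vector<Col>& cols = a.cols;
  size_t k = 0;
  while (k < cols.size()) {
    if (cols[k].op == 'D') {
      size_t s = k, e = k;
      while (e + 1 < cols.size() && cols[e + 1].op == 'D') ++e;
      while (s > 0 && cols[s - 1].op == 'M') {
        int p = cols[s].refpos;
        int l = (int)(e - s + 1);
        if (p > 0 && r[p - 1] == r[p + l - 1]) {
          int mread = cols[s - 1].readpos;
          for (size_t t = s - 1; t <= e - 1; ++t) {
            cols[t].op = 'D';
            cols[t].refpos = p - 1 + (int)(t - (s - 1));
            cols[t].readpos = -1;
          }
          cols[e].op = 'M';
          cols[e].refpos = p + l - 1;
          cols[e].readpos = mread;
          --s; --e;
        } else break;
      }
      k = e + 1;
    } else if (cols[k].op == 'I') {
      size_t s = k, e = k;
      while (e + 1 < cols.size() && cols[e + 1].op == 'I') ++e;
      while (s > 0 && cols[s - 1].op == 'M') {
        int p = cols[s].refpos;
        int l = (int)(e - s + 1);
        int u = cols[s].readpos;
        if (p > 0 && r[p - 1] == q[cols[e].readpos]) {
          for (size_t t = s - 1; t <= e - 1; ++t) {
            cols[t].op = 'I';
            cols[t].refpos = p - 1;
            cols[t].readpos = u - 1 + (int)(t - (s - 1));
          }
          cols[e].op = 'M';
          cols[e].refpos = p - 1;
          cols[e].readpos = u + l - 1;
          --s; --e;
        } else break;
      }
      k = e + 1;
    } else {
      ++k;
    }
  }
  // refresh bookkeeping (gaps cannot cross ref_start, but recount matches)
  a.matches = 0;
  int lo = INT_MAX, hi = INT_MIN;
  for (size_t t = 0; t < cols.size(); ++t) {
    if (cols[t].op == 'M') a.matches++;
    if (cols[t].op != 'I') {
      lo = std::min(lo, cols[t].refpos);
      hi = std::max(hi, cols[t].refpos + 1);
    }
  }
  if (lo != INT_MAX) { a.ref_start = lo; a.ref_end = hi; }
}

// Window rule: a deletion counts if the deleted reference base lies in the
// half-open window [ws, we); an insertion if its inter-base anchor lies in the
// closed interval [ws, we]; substitutions optionally, half-open.
bool window_hit(const Alignment& a, int ws, int we, bool count_subs) {
  for (size_t t = 0; t < a.cols.size(); ++t) {
    const Col& c = a.cols[t];
    if (c.op == 'D') {
      if (c.refpos >= ws && c.refpos < we) return true;
    } else if (c.op == 'I') {
      if (c.refpos >= ws && c.refpos <= we) return true;
    } else if (c.op == 'X' && count_subs) {
      if (c.refpos >= ws && c.refpos < we) return true;
    }
  }
  return false;
}

// Read sequence projected onto reference interval [lo, hi): matched read
// bases in place, '-' for deletions, inserted bases at their anchors, '.'
// where the alignment does not cover the interval.
std::string window_allele(const Alignment& a, const std::string& q, int lo, int hi) {
  int L = hi - lo;
  if (L <= 0) return "";
  std::vector<std::string> ins((size_t)L + 1);
  std::string base((size_t)L, '.');
  for (size_t t = 0; t < a.cols.size(); ++t) {
    const Col& c = a.cols[t];
    if (c.op == 'M' || c.op == 'X') {
      if (c.refpos >= lo && c.refpos < hi) base[c.refpos - lo] = q[c.readpos];
    } else if (c.op == 'D') {
      if (c.refpos >= lo && c.refpos < hi) base[c.refpos - lo] = '-';
    } else { // I
      if (c.refpos >= lo && c.refpos <= hi) ins[c.refpos - lo] += q[c.readpos];
    }
  }
  std::string out;
  for (int t = 0; t < L; ++t) { out += ins[t]; out += base[t]; }
  out += ins[L];
  return out;
}

// Compress columns to run-length ops for the R-level ReadAlignment.
void ops_of(const Alignment& a, std::vector<char>& op, std::vector<int>& len,
            std::vector<int>& pos) {
  for (size_t t = 0; t < a.cols.size(); ++t) {
    const Col& c = a.cols[t];
    bool extend = false;
    if (!op.empty() && op.back() == c.op) {
      if (c.op == 'I') extend = (pos.back() == c.refpos);
      else extend = (pos.back() + len.back() == c.refpos);
    }
    if (extend) len.back()++;
    else { op.push_back(c.op); len.push_back(1); pos.push_back(c.refpos); }
  }
}

bool pack_kmer(const char* s, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b;
    switch (s[i]) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: return false;
    }
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

void kmer_set(const std::string& s, int k, std::unordered_set<uint64_t>& set) {
  if ((int)s.size() < k) return;
  for (size_t i = 0; i + k <= s.size(); ++i) {
    uint64_t v;
    if (pack_kmer(s.c_str() + i, k, v)) set.insert(v);
  }
}

} // namespace

// [[Rcpp::export]]
List sg_align_cpp(std::string read, std::string ref, int match, int mismatch,
                  int gap_open, int gap_extend) {
  Scoring sc; sc.match = match; sc.mismatch = mismatch;
  sc.gap_open = gap_open; sc.gap_extend = gap_extend;
  Alignment a = sg_align_full(read, ref, sc);
  left_normalize(a, read, ref);
  std::vector<char> op; std::vector<int> len, pos;
  ops_of(a, op, len, pos);
  CharacterVector opv(op.size());
  for (size_t t = 0; t < op.size(); ++t) opv[t] = std::string(1, op[t]);
  int columns = (int)a.cols.size();
  return List::create(
    _["score"] = a.score,
    _["ref_start"] = a.ref_start,
    _["ref_end"] = a.ref_end,
    _["ops"] = DataFrame::create(_["op"] = opv, _["len"] = wrap(len),
                                 _["ref_pos"] = wrap(pos),
                                 _["stringsAsFactors"] = false),
    _["matches"] = a.matches,
    _["columns"] = columns,
    _["identity"] = columns > 0 ? (double)a.matches / columns : NA_REAL);
}

// [[Rcpp::export]]
int sg_score_cpp(std::string read, std::string ref, int match, int mismatch,
                 int gap_open, int gap_extend) {
  Scoring sc; sc.match = match; sc.mismatch = mismatch;
  sc.gap_open = gap_open; sc.gap_extend = gap_extend;
  return sg_score(read, ref, sc);
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}

// Batch assignment + window classification over unique read sequences.
// win_start/win_end are 0-based half-open window bounds per reference, or -1
// for amplicons without a quantification window (controls).
// [[Rcpp::export]]
List assign_reads_cpp(CharacterVector reads, CharacterVector refs,
                      IntegerVector win_start, IntegerVector win_end,
                      int flank, int match, int mismatch, int gap_open,
                      int gap_extend, double min_identity, bool count_subs,
                      bool prescreen) {
  Scoring sc; sc.match = match; sc.mismatch = mismatch;
  sc.gap_open = gap_open; sc.gap_extend = gap_extend;
  const int N = reads.size(), R = refs.size();
  std::vector<std::string> fr(R), rr(R);
  for (int t = 0; t < R; ++t) {
    fr[t] = as<std::string>(refs[t]);
    rr[t] = revcomp(fr[t]);
  }
  const int K = 8;
  std::vector<std::unordered_set<uint64_t>> setf(R), setr(R);
  if (prescreen) {
    for (int t = 0; t < R; ++t) {
      kmer_set(fr[t], K, setf[t]);
      kmer_set(rr[t], K, setr[t]);
    }
  }
  IntegerVector amp(N, NA_INTEGER), score(N, NA_INTEGER);
  CharacterVector strand(N, NA_STRING), allele(N, NA_STRING), reason(N);
  NumericVector identity(N, NA_REAL);
  LogicalVector modified(N, NA_LOGICAL);

  std::vector<uint64_t> qk; // read kmers buffer
  for (int u = 0; u < N; ++u) {
    std::string q = as<std::string>(reads[u]);
    // candidate (ref, strand) pairs
    std::vector<std::pair<int, int>> cand;
    if (prescreen && (int)q.size() >= K) {
      qk.clear();
      for (size_t i = 0; i + K <= q.size(); ++i) {
        uint64_t v;
        if (pack_kmer(q.c_str() + i, K, v)) qk.push_back(v);
      }
      std::vector<int> cf(R, 0), cr(R, 0);
      int cbest = 0;
      for (int t = 0; t < R; ++t) {
        for (size_t i = 0; i < qk.size(); ++i) {
          if (setf[t].count(qk[i])) cf[t]++;
          if (setr[t].count(qk[i])) cr[t]++;
        }
        cbest = std::max(cbest, std::max(cf[t], cr[t]));
      }
      if (cbest > 0) {
        for (int t = 0; t < R; ++t) {
          if (cf[t] > 0 && 2 * cf[t] >= cbest) cand.push_back(std::make_pair(t, 0));
          if (cr[t] > 0 && 2 * cr[t] >= cbest) cand.push_back(std::make_pair(t, 1));
        }
      }
    }
    if (cand.empty()) {
      for (int t = 0; t < R; ++t) {
        cand.push_back(std::make_pair(t, 0));
        cand.push_back(std::make_pair(t, 1));
      }
    }
    std::vector<int> refbest(R, NEG_INF);
    int best = NEG_INF, bt = -1, bst = 0;
    for (size_t c = 0; c < cand.size(); ++c) {
      int t = cand[c].first, strd = cand[c].second;
      int s = sg_score(q, strd ? rr[t] : fr[t], sc);
      if (s > refbest[t]) refbest[t] = s;
      if (s > best || (s == best && t == bt && strd == 0 && bst == 1)) {
        best = s; bt = t; bst = strd;
      }
    }
    int nb = 0;
    for (int t = 0; t < R; ++t) if (refbest[t] == best) nb++;
    score[u] = best;
    if (nb >= 2) { reason[u] = "ambiguous"; continue; }
    std::string qa = bst ? revcomp(q) : q;
    Alignment a = sg_align_full(qa, fr[bt], sc);
    left_normalize(a, qa, fr[bt]);
    double id = a.cols.empty() ? NA_REAL : (double)a.matches / a.cols.size();
    identity[u] = id;
    if (!(id >= min_identity)) { reason[u] = "low_identity"; continue; }
    amp[u] = bt + 1;
    strand[u] = bst ? "-" : "+";
    reason[u] = "assigned";
    if (win_start[bt] >= 0) {
      modified[u] = window_hit(a, win_start[bt], win_end[bt], count_subs);
      int lo = std::max(0, win_start[bt] - flank);
      int hi = std::min((int)fr[bt].size(), win_end[bt] + flank);
      allele[u] = window_allele(a, qa, lo, hi);
    }
  }
  return List::create(_["amplicon"] = amp, _["strand"] = strand,
                      _["score"] = score, _["identity"] = identity,
                      _["modified"] = modified, _["allele"] = allele,
                      _["reason"] = reason);
}
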