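#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <map>
#include <deque>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// small utilities
// ---------------------------------------------------------------------------

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char bitcomp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = bitcomp(c);
  return r;
}

// [[Rcpp::export(name = ".pc_revcomp")]]
CharacterVector pc_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// murmur-style 64-bit finalizer, invertible; standard minimizer hash
static inline uint64_t hash64(uint64_t key, uint64_t mask) {
  key = (~key + (key << 21)) & mask;
  key = key ^ (key >> 24);
  key = ((key + (key << 3)) + (key << 8)) & mask;
  key = key ^ (key >> 14);
  key = ((key + (key << 2)) + (key << 4)) & mask;
  key = key ^ (key >> 28);
  key = (key + (key << 31)) & mask;
  return key;
}

// positions inside (or immediately adjacent to) a homopolymer run of
// length >= min_run
// [[Rcpp::export(name = ".pc_hp_mask")]]
LogicalVector pc_hp_mask(std::string seq, int min_run, bool adjacent) {
  int n = (int)seq.size();
  LogicalVector out(n, false);
  int i = 0;
  while (i < n) {
    int j = i + 1;
    while (j < n && seq[j] == seq[i]) ++j;
    if (j - i >= min_run) {
      int lo = i, hi = j;                 // [lo, hi)
      if (adjacent) { lo = std::max(0, lo - 1); hi = std::min(n, hi + 1); }
      for (int p = lo; p < hi; ++p) out[p] = true;
    }
    i = j;
  }
  return out;
}

// ---------------------------------------------------------------------------
// minimizer sketching and overlap candidate detection
// ---------------------------------------------------------------------------

struct Mini { uint64_t h; int pos; int strand; };

static void sketch(const std::string& s, int k, int w, std::vector<Mini>& out) {
  int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t f = 0, r = 0;
  int shift = 2 * (k - 1);
  int l = 0;
  std::deque<Mini> q;           // monotonic deque of window minima
  int last_emitted = -1;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { l = 0; f = r = 0; continue; }
    f = ((f << 2) | (uint64_t)b) & mask;
    r = (r >> 2) | ((uint64_t)(3 - b) << shift);
    if (++l < k) continue;
    int strand;
    uint64_t key;
    if (f < r) { key = f; strand = 0; }
    else if (r < f) { key = r; strand = 1; }
    else continue;              // palindromic k-mer: skip (strand ambiguous)
    Mini m { hash64(key, mask), i - k + 1, strand };
    while (!q.empty() && q.back().h >= m.h) q.pop_back();
    q.push_back(m);
    while (!q.empty() && q.front().pos <= i - k + 1 - w) q.pop_front();
    if (i - k + 1 >= w - 1) {
      if (q.front().pos != last_emitted) {
        out.push_back(q.front());
        last_emitted = q.front().pos;
      }
    }
  }
}

struct Hit { int t; int strand; int diag; int tpos; int qpos; };

// Find candidate overlaps by shared-minimizer diagonal clustering.
// When all_vs_all is true, targets == queries and only pairs q < t are kept.
// Coordinates for '-' hits are in the reverse-complemented query frame.
// [[Rcpp::export(name = ".pc_overlap_candidates")]]
DataFrame pc_overlap_candidates(CharacterVector targets, CharacterVector queries,
                                int k, int w, int max_occ, int min_hits,
                                int min_span, int diag_tol, bool all_vs_all) {
  int nt = targets.size(), nq = queries.size();
  std::vector<std::string> tseq(nt);
  for (int i = 0; i < nt; ++i) tseq[i] = as<std::string>(targets[i]);

  // index target minimizers
  std::unordered_map<uint64_t, std::vector<std::array<int, 3>>> idx; // h -> (t, pos, strand)
  for (int t = 0; t < nt; ++t) {
    std::vector<Mini> ms;
    sketch(tseq[t], k, w, ms);
    for (auto& m : ms) idx[m.h].push_back({ t, m.pos, m.strand });
  }

  std::vector<int> o_t, o_q, o_ts, o_te, o_qs, o_qe, o_hits;
  std::vector<std::string> o_strand;

  for (int qi = 0; qi < nq; ++qi) {
    std::string qs = all_vs_all ? tseq[qi] : as<std::string>(queries[qi]);
    int qlen = (int)qs.size();
    std::vector<Mini> ms;
    sketch(qs, k, w, ms);
    std::vector<Hit> hits;
    for (auto& m : ms) {
      auto it = idx.find(m.h);
      if (it == idx.end()) continue;
      if ((int)it->second.size() > max_occ) continue;
      for (auto& e : it->second) {
        int t = e[0];
        if (all_vs_all && t <= qi) continue;
        int rel = (e[2] == m.strand) ? 0 : 1;   // 0:'+', 1:'-'
        int qpos = rel == 0 ? m.pos : qlen - k - m.pos;
        hits.push_back({ t, rel, e[1] - qpos, e[1], qpos });
      }
    }
    if (hits.empty()) continue;
    std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
      if (a.t != b.t) return a.t < b.t;
      if (a.strand != b.strand) return a.strand < b.strand;
      return a.diag < b.diag;
    });
    // cluster by (t, strand) and near-constant diagonal; keep best per pair
    size_t i = 0;
    int cur_t = -1; int best_hits = 0;
    int best_ts = 0, best_te = 0, best_diag = 0, best_strand = 0;
    auto flush_pair = [&](int tid) {
      if (tid < 0 || best_hits < min_hits) { best_hits = 0; return; }
      if (best_te - best_ts < min_span) { best_hits = 0; return; }
      int tlen = (int)tseq[tid].size();
      int d = best_diag;  // median diagonal of the chained hits
      int ts0 = std::max(0, d), qs0 = ts0 - d;
      int te0 = std::min(tlen, qlen + d), qe0 = te0 - d;
      if (te0 > ts0) {
        o_t.push_back(tid + 1); o_q.push_back(qi + 1);
        o_strand.push_back(best_strand == 0 ? "+" : "-");
        o_ts.push_back(ts0); o_te.push_back(te0);
        o_qs.push_back(qs0); o_qe.push_back(qe0);
        o_hits.push_back(best_hits);
      }
      best_hits = 0;
    };
    while (i < hits.size()) {
      size_t j = i + 1;
      while (j < hits.size() && hits[j].t == hits[i].t &&
             hits[j].strand == hits[i].strand &&
             hits[j].diag - hits[j - 1].diag <= diag_tol) ++j;
      int nh = (int)(j - i);
      int tmin = hits[i].tpos, tmax = hits[i].tpos;
      for (size_t u = i; u < j; ++u) {
        tmin = std::min(tmin, hits[u].tpos); tmax = std::max(tmax, hits[u].tpos);
      }
      if (hits[i].t != cur_t) { flush_pair(cur_t); cur_t = hits[i].t; }
      if (nh > best_hits) {
        best_hits = nh;
        best_ts = tmin; best_te = tmax + k;
        best_strand = hits[i].strand;
        // hits are diag-sorted within the cluster: take the median diagonal
        best_diag = hits[i + (j - i) / 2].diag;
      }
      i = j;
    }
    flush_pair(cur_t);
  }

  return DataFrame::create(
    _["target"] = o_t, _["query"] = o_q, _["strand"] = o_strand,
    _["tstart"] = o_ts, _["tend"] = o_te,
    _["qstart"] = o_qs, _["qend"] = o_qe, _["nhits"] = o_hits,
    _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// banded global alignment with left-aligned difference extraction
// ---------------------------------------------------------------------------

struct Diff {
  int tpos;      // target position (anchor for indels)
  char kind;     // 'S', 'I' (extra query bases before tpos), 'D' (target bases absent)
  std::string tseq, qseq;
  int qpos;      // query position of the event (next query base for 'D')
};

// Banded alignment with optionally free end gaps ("fitting"/overlap mode).
// free_flags bits: 1 = free leading query gap, 2 = free trailing query gap,
// 4 = free leading target gap, 8 = free trailing target gap. The aligned
// subranges are returned through sub[4] = {t0, q0, t1, q1}. Returns edit
// cost of the aligned region, fills diffs; -1 if the band was insufficient.
static int banded_align(const std::string& T, const std::string& Q, int band,
                        std::vector<Diff>& diffs, int free_flags = 0,
                        int* sub = nullptr) {
  const int m = (int)T.size(), n = (int)Q.size();
  diffs.clear();
  if (sub) { sub[0] = 0; sub[1] = 0; sub[2] = m; sub[3] = n; }
  if (m == 0 || n == 0) {
    if (m == 0 && n == 0) return 0;
    if (m == 0) { diffs.push_back({0, 'I', "", Q, 0}); return n; }
    diffs.push_back({0, 'D', T, "", 0}); return m;
  }
  int B = std::max(band, std::abs(n - m) + 8);
  int width = 2 * B + 1;
  const int INF = 1 << 28;
  // the banded centre can advance by up to ceil(n/m) columns per row, so
  // pad the rows far enough that the constant-shift predecessors stay in
  // bounds for any centre step
  const int pad = n / std::max(1, m) + 3;
  std::vector<int> prev(width + pad, INF), cur(width + pad, INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * width, 0); // 1 diag, 2 up, 3 left
  std::vector<int> coln(m + 1, INF);   // dp(i, n) per row, for free target tail
  auto center = [&](int i) { return (int)(((long long)i * n) / m); };
  // row 0 (values stored at off + 1; sentinels at both ends stay INF)
  {
    int c0 = 0, lo = std::max(0, c0 - B), hi = std::min(n, c0 + B);
    for (int j = lo; j <= hi; ++j) {
      int off = j - (c0 - B);
      if (j == 0 || (free_flags & 1)) { prev[off + 1] = 0; }
      else { prev[off + 1] = j; tb[off] = 3; }
    }
    if (n <= B) coln[0] = prev[n - (c0 - B) + 1];
  }
  // rows are stored with a one-cell sentinel on each side so the three
  // predecessors reduce to constant index shifts (prev row is centred one
  // diagonal step behind: delta in {0, 1})
  for (int i = 1; i <= m; ++i) {
    int c = center(i), lo = std::max(0, c - B), hi = std::min(n, c + B);
    int pc = center(i - 1);
    int delta = c - pc;
    std::fill(cur.begin(), cur.end(), INF);
    const char ti = T[i - 1];
    const char* Qp = Q.data();
    uint8_t* tbrow = &tb[(size_t)i * width];
    int off_lo = lo - (c - B), off_hi = hi - (c - B);
    for (int off = off_lo; off <= off_hi; ++off) {
      int j = off + (c - B);
      int d = (j >= 1) ? prev[off + delta] + (ti == Qp[j - 1] ? 0 : 1) : INF;
      int u = prev[off + delta + 1] + 1;
      int l = cur[off] + 1;
      int best = d; uint8_t mv = 1;
      if (u < best) { best = u; mv = 2; }
      if (l < best) { best = l; mv = 3; }
      if (j == 0 && (free_flags & 4) && 0 < best) { best = 0; mv = 0; }
      if (best >= INF) { best = INF; mv = 0; }
      cur[off + 1] = best;
      tbrow[off] = mv;
    }
    if (n >= lo && n <= hi) coln[i] = cur[n - (c - B) + 1];
    std::swap(prev, cur);
  }
  // choose the end cell: (m, n), or anywhere on the last row (free trailing
  // query gap) / last column (free trailing target gap); ties prefer the
  // longest alignment
  int endi = m, endj = n, cost = INF;
  {
    int cm = center(m), lo = std::max(0, cm - B), hi = std::min(n, cm + B);
    if (n >= lo && n <= hi) cost = prev[n - (cm - B) + 1];
    if (free_flags & 2) {
      for (int j = hi; j >= lo; --j) {
        int v = prev[j - (cm - B) + 1];
        if (v < cost) { cost = v; endj = j; }
      }
    }
    if (free_flags & 8) {
      for (int i2 = m; i2 >= 0; --i2)
        if (coln[i2] < cost) { cost = coln[i2]; endi = i2; endj = n; }
    }
  }
  if (cost >= (1 << 28)) return -1;

  // traceback to an op string (reversed); stops at any free-start cell
  std::vector<char> ops;
  int i = endi, j = endj;
  while (i > 0 || j > 0) {
    int c = center(i);
    int off = j - (c - B);
    if (off < 0 || off >= width) break;
    uint8_t mv = tb[(size_t)i * width + off];
    if (mv == 1) { ops.push_back(T[i - 1] == Q[j - 1] ? 'M' : 'X'); --i; --j; }
    else if (mv == 2) { ops.push_back('D'); --i; }
    else if (mv == 3) { ops.push_back('I'); --j; }
    else break; // free start
  }
  std::reverse(ops.begin(), ops.end());
  if (sub) { sub[0] = i; sub[1] = j; sub[2] = endi; sub[3] = endj; }

  // extract events
  int ti = i, qi = j;
  size_t p = 0;
  while (p < ops.size()) {
    char o = ops[p];
    if (o == 'M') { ++ti; ++qi; ++p; continue; }
    if (o == 'X') { diffs.push_back({ ti, 'S', std::string(1, T[ti]), std::string(1, Q[qi]), qi }); ++ti; ++qi; ++p; continue; }
    size_t p2 = p;
    while (p2 < ops.size() && ops[p2] == o) ++p2;
    int len = (int)(p2 - p);
    if (o == 'I') { diffs.push_back({ ti, 'I', "", Q.substr(qi, len), qi }); qi += len; }
    else { diffs.push_back({ ti, 'D', T.substr(ti, len), "", qi }); ti += len; }
    p = p2;
  }

  return cost;
}

// left-align indels (shift over exact matches while the last base repeats);
// tlo/qlo bound the shift (start of the aligned interval)
static void left_align(const std::string& T, std::vector<Diff>& diffs,
                       int tlo, int qlo) {
  for (size_t d = 0; d < diffs.size(); ++d) {
    Diff& e = diffs[d];
    if (e.kind == 'S') continue;
    int lim_t = tlo, lim_q = qlo;             // cannot shift past previous event
    if (d > 0) {
      const Diff& pr = diffs[d - 1];
      lim_t = pr.tpos + (pr.kind == 'D' ? (int)pr.tseq.size() : (pr.kind == 'S' ? 1 : 0));
      lim_q = pr.qpos + (pr.kind == 'I' ? (int)pr.qseq.size() : (pr.kind == 'S' ? 1 : 0));
    }
    if (e.kind == 'I') {
      while (e.tpos > lim_t && e.qpos > lim_q &&
             T[e.tpos - 1] == e.qseq.back()) {
        e.qseq = std::string(1, T[e.tpos - 1]) + e.qseq.substr(0, e.qseq.size() - 1);
        --e.tpos; --e.qpos;
      }
    } else {
      while (e.tpos > lim_t && e.qpos > lim_q &&
             T[e.tpos - 1] == e.tseq.back()) {
        e.tseq = std::string(1, T[e.tpos - 1]) + e.tseq.substr(0, e.tseq.size() - 1);
        --e.tpos; --e.qpos;
      }
    }
  }
}

// Single-pair banded alignment (exposed for alignPair())
// [[Rcpp::export(name = ".pc_align_pair")]]
List pc_align_pair(std::string target, std::string query, int band) {
  std::vector<Diff> diffs;
  int cost = banded_align(target, query, band, diffs);
  left_align(target, diffs, 0, 0);
  int nd = (int)diffs.size();
  IntegerVector tpos(nd), qpos(nd), len(nd);
  CharacterVector kind(nd), tseq(nd), qseq(nd);
  for (int i = 0; i < nd; ++i) {
    tpos[i] = diffs[i].tpos; qpos[i] = diffs[i].qpos;
    kind[i] = std::string(1, diffs[i].kind);
    tseq[i] = diffs[i].tseq; qseq[i] = diffs[i].qseq;
    len[i] = diffs[i].kind == 'S' ? 1 :
      (int)std::max(diffs[i].tseq.size(), diffs[i].qseq.size());
  }
  return List::create(_["cost"] = cost,
                      _["diffs"] = DataFrame::create(
                        _["tpos"] = tpos, _["kind"] = kind, _["len"] = len,
                        _["tseq"] = tseq, _["qseq"] = qseq, _["qpos"] = qpos,
                        _["stringsAsFactors"] = false));
}

// Batch alignment of candidate overlaps. Overlaps containing an indel longer
// than max_indel are split at the indel; parts shorter than min_len and pairs
// above max_div are dropped.
// [[Rcpp::export(name = ".pc_align_batch")]]
List pc_align_batch(CharacterVector seqs, IntegerVector ti, IntegerVector qi,
                    CharacterVector strand, IntegerVector ts, IntegerVector te,
                    IntegerVector qs, IntegerVector qe,
                    int band, double max_div, int max_indel, int min_len) {
  int np = ti.size();
  std::vector<std::string> sseq(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) sseq[i] = as<std::string>(seqs[i]);

  std::vector<int> r_t, r_q, r_ts, r_te, r_qs, r_qe, r_cost;
  std::vector<std::string> r_strand;
  std::vector<int> d_ovl, d_tpos, d_qpos, d_len;
  std::vector<std::string> d_kind, d_tseq, d_qseq;

  const int slack = 32;   // soft margin for mid-read window boundaries
  for (int p = 0; p < np; ++p) {
    int t = ti[p] - 1, q = qi[p] - 1;
    bool minus = std::string(strand[p]) == "-";
    const std::string& T = sseq[t];
    std::string Qo = minus ? revcomp(sseq[q]) : sseq[q];
    int a = ts[p], b = te[p], c = qs[p], d = qe[p];
    if (a < 0 || c < 0 || b > (int)T.size() || d > (int)Qo.size() || b <= a || d <= c)
      continue;
    // fast path: when the projected windows match exactly (typical for
    // already-corrected reads), accept the overlap as-is
    if (b - a == d - c && T.compare(a, b - a, Qo, c, d - c) == 0) {
      int oid = (int)r_t.size();
      r_t.push_back(t + 1); r_q.push_back(q + 1);
      r_strand.push_back(minus ? "-" : "+");
      r_ts.push_back(a); r_te.push_back(b);
      r_qs.push_back(c); r_qe.push_back(d);
      r_cost.push_back(0);
      (void)oid;
      continue;
    }
    // the projected diagonal is exact only up to indel drift: widen whichever
    // boundary is not pinned to a read end and give the aligner free end
    // gaps there, so it finds the true overlap boundary itself
    int flags = 0;
    if (c > 0) { flags |= 1; c = std::max(0, c - slack); }
    else if (a > 0) { flags |= 4; a = std::max(0, a - slack); }
    if (d < (int)Qo.size()) { flags |= 2; d = std::min((int)Qo.size(), d + slack); }
    else if (b < (int)T.size()) { flags |= 8; b = std::min((int)T.size(), b + slack); }
    std::string Ts = T.substr(a, b - a), Qs = Qo.substr(c, d - c);
    std::vector<Diff> diffs;
    int cost;
    int sub[4] = { 0, 0, (int)Ts.size(), (int)Qs.size() };
    if (flags == 0 && Ts == Qs) { cost = 0; }
    else {
      cost = banded_align(Ts, Qs, band, diffs, flags, sub);
      if (cost < 0) continue;  // band exceeded: drop candidate
    }
    // restrict to the aligned subrange chosen by the free-end alignment
    if (sub[0] > 0 || sub[1] > 0 || sub[2] < (int)Ts.size() ||
        sub[3] < (int)Qs.size()) {
      a += sub[0]; c += sub[1];
      b = a + (sub[2] - sub[0]); d = c + (sub[3] - sub[1]);
      if (b <= a || d <= c) continue;
      Ts = Ts.substr(sub[0], sub[2] - sub[0]);
      Qs = Qs.substr(sub[1], sub[3] - sub[1]);
      for (auto& e : diffs) { e.tpos -= sub[0]; e.qpos -= sub[1]; }
    }
    left_align(Ts, diffs, 0, 0);
    // split at long indels
    std::vector<std::array<int, 4>> parts; // tlo, tqlo (local), thi, qhi
    std::vector<std::vector<Diff>> pdiffs;
    {
      int tlo = 0, qlo = 0;
      std::vector<Diff> cur;
      for (auto& e : diffs) {
        int elen = (int)std::max(e.tseq.size(), e.qseq.size());
        if (e.kind != 'S' && elen > max_indel) {
          parts.push_back({ tlo, qlo, e.tpos, e.qpos });
          pdiffs.push_back(cur); cur.clear();
          tlo = e.tpos + (e.kind == 'D' ? elen : 0);
          qlo = e.qpos + (e.kind == 'I' ? elen : 0);
        } else cur.push_back(e);
      }
      parts.push_back({ tlo, qlo, (int)Ts.size(), (int)Qs.size() });
      pdiffs.push_back(cur);
    }
    for (size_t u = 0; u < parts.size(); ++u) {
      int tlo = parts[u][0], qlo = parts[u][1], thi = parts[u][2], qhi = parts[u][3];
      if (thi - tlo < min_len || qhi - qlo < min_len) continue;
      int pcost = 0;
      for (auto& e : pdiffs[u])
        pcost += (int)std::max((size_t)1, std::max(e.tseq.size(), e.qseq.size()));
      double div = (double)pcost / std::max(1, (thi - tlo + qhi - qlo) / 2);
      if (div > max_div) continue;
      int oid = (int)r_t.size();
      r_t.push_back(t + 1); r_q.push_back(q + 1);
      r_strand.push_back(minus ? "-" : "+");
      r_ts.push_back(a + tlo); r_te.push_back(a + thi);
      r_qs.push_back(c + qlo); r_qe.push_back(c + qhi);
      r_cost.push_back(pcost);
      for (auto& e : pdiffs[u]) {
        d_ovl.push_back(oid + 1);
        d_tpos.push_back(a + e.tpos); d_qpos.push_back(c + e.qpos);
        d_kind.push_back(std::string(1, e.kind));
        d_len.push_back((int)std::max((size_t)1, std::max(e.tseq.size(), e.qseq.size())));
        d_tseq.push_back(e.tseq); d_qseq.push_back(e.qseq);
      }
    }
  }
  DataFrame ovl = DataFrame::create(
    _["target"] = r_t, _["query"] = r_q, _["strand"] = r_strand,
    _["tstart"] = r_ts, _["tend"] = r_te, _["qstart"] = r_qs, _["qend"] = r_qe,
    _["cost"] = r_cost, _["stringsAsFactors"] = false);
  DataFrame dif = DataFrame::create(
    _["ovl"] = d_ovl, _["tpos"] = d_tpos, _["kind"] = d_kind, _["len"] = d_len,
    _["tseq"] = d_tseq, _["qseq"] = d_qseq, _["qpos"] = d_qpos,
    _["stringsAsFactors"] = false);
  return List::create(_["overlaps"] = ovl, _["diffs"] = dif);
}

// Reverse the roles of target and query for a set of overlaps (+ diffs), so
// each aligned pair feeds the pileups of both reads. Indels are re-left-
// aligned against the new target: a left-aligned indel in the primary frame
// is right-aligned after mirroring, and anchors must be canonical so that
// votes from both orientations agree.
// [[Rcpp::export(name = ".pc_flip_overlaps")]]
List pc_flip_overlaps(IntegerVector ti, IntegerVector qi, CharacterVector strand,
                      IntegerVector ts, IntegerVector te,
                      IntegerVector qs, IntegerVector qe, IntegerVector cost,
                      IntegerVector d_ovl, IntegerVector d_tpos, CharacterVector d_kind,
                      IntegerVector d_len, CharacterVector d_tseq, CharacterVector d_qseq,
                      IntegerVector d_qpos, CharacterVector seqs) {
  int np = ti.size(), nd = d_ovl.size();
  std::vector<int> seqlen(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    seqlen[i] = (int)LENGTH(STRING_ELT(seqs, i));
  IntegerVector f_t(np), f_q(np), f_ts(np), f_te(np), f_qs(np), f_qe(np), f_cost(np);
  CharacterVector f_strand(np);
  for (int p = 0; p < np; ++p) {
    int t = ti[p] - 1, q = qi[p] - 1;
    bool minus = std::string(strand[p]) == "-";
    f_t[p] = q + 1; f_q[p] = t + 1; f_strand[p] = strand[p]; f_cost[p] = cost[p];
    if (!minus) {
      f_ts[p] = qs[p]; f_te[p] = qe[p]; f_qs[p] = ts[p]; f_qe[p] = te[p];
    } else {
      int ql = seqlen[q], tl = seqlen[t];
      f_ts[p] = ql - qe[p]; f_te[p] = ql - qs[p];
      f_qs[p] = tl - te[p]; f_qe[p] = tl - ts[p];
    }
  }
  IntegerVector g_ovl(nd), g_tpos(nd), g_len(nd), g_qpos(nd);
  CharacterVector g_kind(nd), g_tseq(nd), g_qseq(nd);
  for (int d = 0; d < nd; ++d) {
    int p = d_ovl[d] - 1;
    int t = ti[p] - 1, q = qi[p] - 1;
    bool minus = std::string(strand[p]) == "-";
    std::string kind = as<std::string>(d_kind[d]);
    std::string tsq = as<std::string>(d_tseq[d]);
    std::string qsq = as<std::string>(d_qseq[d]);
    int len = d_len[d];
    g_ovl[d] = d_ovl[d];
    std::string nk = kind == "I" ? "D" : (kind == "D" ? "I" : "S");
    if (!minus) {
      g_tpos[d] = d_qpos[d]; g_qpos[d] = d_tpos[d];
      g_tseq[d] = qsq; g_qseq[d] = tsq; g_kind[d] = nk; g_len[d] = len;
    } else {
      int ql = seqlen[q], tl = seqlen[t];
      // event occupied query span in RC frame
      int qspan = (kind == "I") ? len : (kind == "S" ? 1 : 0);
      int tspan = (kind == "D") ? len : (kind == "S" ? 1 : 0);
      g_tpos[d] = ql - (d_qpos[d] + qspan);
      g_qpos[d] = tl - (d_tpos[d] + tspan);
      g_tseq[d] = revcomp(qsq); g_qseq[d] = revcomp(tsq);
      g_kind[d] = nk; g_len[d] = len;
    }
  }
  // canonicalize: left-align indels in the new target frame (mirroring a
  // left-aligned indel right-aligns it)
  {
    std::vector<std::vector<int>> gby(np);
    for (int d = 0; d < nd; ++d) gby[g_ovl[d] - 1].push_back(d);
    for (int p = 0; p < np; ++p) {
      if (gby[p].empty()) continue;
      std::sort(gby[p].begin(), gby[p].end(), [&](int a, int b) {
        return g_tpos[a] < g_tpos[b];
      });
      const char* T = CHAR(STRING_ELT(seqs, f_t[p] - 1));
      int prev_t = f_ts[p], prev_q = f_qs[p];
      for (int d : gby[p]) {
        std::string kind = as<std::string>(g_kind[d]);
        std::string tsq = as<std::string>(g_tseq[d]);
        std::string qsq = as<std::string>(g_qseq[d]);
        int tp = g_tpos[d], qp = g_qpos[d];
        if (kind == "I") {
          while (tp > prev_t && qp > prev_q && T[tp - 1] == qsq.back()) {
            qsq = std::string(1, T[tp - 1]) + qsq.substr(0, qsq.size() - 1);
            --tp; --qp;
          }
          g_qseq[d] = qsq;
        } else if (kind == "D") {
          while (tp > prev_t && qp > prev_q && T[tp - 1] == tsq.back()) {
            tsq = std::string(1, T[tp - 1]) + tsq.substr(0, tsq.size() - 1);
            --tp; --qp;
          }
          g_tseq[d] = tsq;
        }
        g_tpos[d] = tp; g_qpos[d] = qp;
        prev_t = tp + (kind == "D" ? (int)tsq.size() : (kind == "S" ? 1 : 0));
        prev_q = qp + (kind == "I" ? (int)qsq.size() : (kind == "S" ? 1 : 0));
      }
    }
  }
  DataFrame ovl = DataFrame::create(
    _["target"] = f_t, _["query"] = f_q, _["strand"] = f_strand,
    _["tstart"] = f_ts, _["tend"] = f_te, _["qstart"] = f_qs, _["qend"] = f_qe,
    _["cost"] = f_cost, _["stringsAsFactors"] = false);
  DataFrame dif = DataFrame::create(
    _["ovl"] = g_ovl, _["tpos"] = g_tpos, _["kind"] = g_kind, _["len"] = g_len,
    _["tseq"] = g_tseq, _["qseq"] = g_qseq, _["qpos"] = g_qpos,
    _["stringsAsFactors"] = false);
  return List::create(_["overlaps"] = ovl, _["diffs"] = dif);
}

// ---------------------------------------------------------------------------
// pileup construction
// ---------------------------------------------------------------------------

// Build the per-target site pileup. `col` maps each overlap to a read column
// (1-based; several split overlaps of the same query share a column).
// `quals` holds the query base qualities oriented to match qpos.
// Phase: 1 if the read has a difference anchored at the site, 0 if it covers
// the site and matches, NA otherwise.
// A read whose alignment has a difference within `flank` bases of a site
// (but not anchored at it) is locally ambiguous — indel placement wobbles
// across equivalent alignments — and is assigned '*' rather than phase 0.
// [[Rcpp::export(name = ".pc_pileup")]]
List pc_pileup(int tlen, IntegerVector col, IntegerVector ts, IntegerVector te,
               IntegerVector qs, int ncols,
               IntegerVector d_ovl, IntegerVector d_tpos, CharacterVector d_kind,
               IntegerVector d_len, CharacterVector d_qseq,
               IntegerVector d_qpos, List quals, int flank) {
  int novl = col.size(), nd = d_ovl.size();
  // site positions
  std::vector<int> pos(d_tpos.begin(), d_tpos.end());
  std::sort(pos.begin(), pos.end());
  pos.erase(std::unique(pos.begin(), pos.end()), pos.end());
  int N = (int)pos.size();
  IntegerMatrix phase(N, ncols), qual(N, ncols);
  std::fill(phase.begin(), phase.end(), NA_INTEGER);
  std::fill(qual.begin(), qual.end(), NA_INTEGER);
  auto site_of = [&](int p) {
    return (int)(std::lower_bound(pos.begin(), pos.end(), p) - pos.begin());
  };
  // group diffs by overlap
  std::vector<std::vector<int>> byovl(novl);
  for (int d = 0; d < nd; ++d) byovl[d_ovl[d] - 1].push_back(d);
  for (int o = 0; o < novl; ++o) {
    std::sort(byovl[o].begin(), byovl[o].end(), [&](int a, int b) {
      return d_tpos[a] < d_tpos[b];
    });
  }
  // phase-1 entries (and deletion shadows as NA); per-site allele keys to
  // count how many reads share the identical alternative allele
  std::vector<std::map<std::string, int>> alleles(N);
  for (int o = 0; o < novl; ++o) {
    int cc = col[o] - 1;
    IntegerVector oq = quals[o];
    for (int d : byovl[o]) {
      int s = site_of(d_tpos[d]);
      phase(s, cc) = 1;
      std::string kind = as<std::string>(d_kind[d]);
      std::string key = kind + ":" + (kind == "D" ?
        std::to_string(d_len[d]) : as<std::string>(d_qseq[d]));
      ++alleles[s][key];
      int qp = d_qpos[d];
      int qlen = oq.size();
      int qidx = std::min(std::max(qp, 0), qlen - 1);
      qual(s, cc) = qlen > 0 ? oq[qidx] : NA_INTEGER;
    }
  }
  // positions where two or more reads differ are candidate sites (the
  // target's own errors or shared variants/artefacts), not lone-read
  // alignment wobble; a read's difference there says nothing about its
  // local alignment reliability and is exempt from the ambiguity window
  // below, so that conflicts between nearby candidate sites stay visible
  std::vector<bool> majority(N, false);
  for (int s = 0; s < N; ++s) {
    int n1c = 0;
    for (int c0 = 0; c0 < ncols; ++c0) if (phase(s, c0) == 1) ++n1c;
    majority[s] = n1c >= 2;
  }
  // phase-0 entries with exact query-position tracking
  for (int o = 0; o < novl; ++o) {
    int cc = col[o] - 1;
    IntegerVector oq = quals[o];
    int qlen = oq.size();
    int s0 = site_of(ts[o]);
    size_t di = 0;
    const std::vector<int>& dl = byovl[o];
    // event intervals for the ambiguity window
    std::vector<std::pair<int, int>> ev;
    ev.reserve(dl.size());
    for (int d : dl) {
      char kind = CHAR(STRING_ELT(d_kind, d))[0];
      if (majority[site_of(d_tpos[d])]) continue;
      ev.push_back({ d_tpos[d], d_tpos[d] + (kind == 'D' ? d_len[d] : 1) });
    }
    size_t wlo = 0;
    int offset = 0;   // query minus target drift accumulated left of the site
    for (int s = s0; s < N && pos[s] < te[o]; ++s) {
      int p = pos[s];
      bool shadow = false;
      // ambiguity: any event within `flank` of the site, not anchored at it
      while (wlo < ev.size() && ev[wlo].second + flank <= p) ++wlo;
      bool near = false;
      for (size_t u = wlo; u < ev.size() && ev[u].first <= p + flank; ++u)
        if (ev[u].first != p) { near = true; break; }
      while (di < dl.size()) {
        int d = dl[di];
        int a = d_tpos[d];
        char kind = CHAR(STRING_ELT(d_kind, d))[0];
        if (kind == 'I') {
          if (p >= a) { offset += d_len[d]; ++di; continue; }
          break;
        } else if (kind == 'S') {
          if (p > a) { ++di; continue; }
          break;
        } else { // 'D'
          int L = d_len[d];
          if (p >= a + L) { offset -= L; ++di; continue; }
          if (p > a) shadow = true;  // inside deletion, no query base
          break;
        }
      }
      if (!shadow && !near && phase(s, cc) == NA_INTEGER) {
        phase(s, cc) = 0;
        int qp = qs[o] + (p - ts[o]) + offset;
        if (qp >= 0 && qp < qlen) qual(s, cc) = oq[qp];
      }
    }
  }
  IntegerVector n0(N), n1(N), n1max(N);
  for (int s = 0; s < N; ++s) {
    int a = 0, b = 0;
    for (int c0 = 0; c0 < ncols; ++c0) {
      int v = phase(s, c0);
      if (v == 0) ++a; else if (v == 1) ++b;
    }
    n0[s] = a; n1[s] = b;
    int mx = 0;
    for (auto& kv : alleles[s]) mx = std::max(mx, kv.second);
    n1max[s] = mx;
  }
  return List::create(_["pos"] = IntegerVector(pos.begin(), pos.end()),
                      _["phase"] = phase, _["qual"] = qual,
                      _["n0"] = n0, _["n1"] = n1, _["n1max"] = n1max);
}

// ---------------------------------------------------------------------------
// largest-compatible-group dynamic program
// ---------------------------------------------------------------------------

// Two sites are compatible iff at most max_conflict reads phased at both
// disagree, at least min_shared reads are phased at both, and at least
// min_shared1 of the agreeing reads are phase 1 at both (linkage evidence:
// reads carrying the alternative allele at both sites). max_conflict = 0
// reproduces the strict predicate; the default tolerance of one read
// absorbs a single sequencing error landing on a variant position.
// [[Rcpp::export(name = ".pc_lcg")]]
List pc_lcg(IntegerMatrix phase, int min_shared, int min_shared1,
            int max_conflict) {
  int N = phase.nrow(), K = phase.ncol();
  IntegerVector lcg(N), pred(N);
  // column-major access: copy to row-major buffer for locality
  std::vector<int> buf((size_t)N * K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k)
      buf[(size_t)i * K + k] = phase(i, k);
  for (int i = 0; i < N; ++i) {
    int best = 0, bj = -1;
    const int* ri = &buf[(size_t)i * K];
    for (int j = 0; j < i; ++j) {
      const int* rj = &buf[(size_t)j * K];
      int shared = 0, shared1 = 0, conflict = 0;
      for (int k = 0; k < K; ++k) {
        int a = ri[k], b = rj[k];
        if (a == NA_INTEGER || b == NA_INTEGER) continue;
        ++shared;
        if (a != b) { if (++conflict > max_conflict) break; }
        else if (a == 1) ++shared1;
      }
      // a conflicting read is tolerated only with strong linkage evidence:
      // five agreeing phase-1 reads per conflict
      if (conflict <= max_conflict && shared >= min_shared &&
          shared1 >= min_shared1 && shared1 >= 5 * conflict &&
          lcg[j] >= best) { best = lcg[j]; bj = j; }
    }
    lcg[i] = best + 1; pred[i] = bj;
  }
  return List::create(_["lcg"] = lcg, _["pred"] = pred);
}

// ---------------------------------------------------------------------------
// consensus correction
// ---------------------------------------------------------------------------

// Windowed plurality consensus among selected supports (+ the target).
// Support differences are grouped into clusters (gap <= merge_gap); for each
// cluster window the supports vote with the subsequence their alignment
// implies for that window. Comparing sequence content rather than edit
// operations makes the vote independent of how equivalent alignments
// represent a difference cluster. A support whose window involves a base
// below q_min is excluded from that window's vote (potential sequencing
// error), as is the target's own vote when any of its window bases is below
// q_min. The window is replaced when one alternative subsequence reaches
// min_depth votes, min_ratio of all votes, and beats the target.
// [[Rcpp::export(name = ".pc_consensus")]]
List pc_consensus(std::string target, IntegerVector tqual,
                  IntegerVector s_ts, IntegerVector s_te, IntegerVector s_qs,
                  IntegerVector d_sup, IntegerVector d_tpos, CharacterVector d_kind,
                  IntegerVector d_len, CharacterVector d_tseq, CharacterVector d_qseq,
                  List quals,
                  int min_depth, double min_ratio, int q_min, int merge_gap) {
  int ns = s_ts.size(), nd = d_sup.size();
  int tlen = (int)target.size();

  struct Ev { int sup; int tpos; char kind; int len; std::string qseq; int end; };
  std::vector<Ev> evs;
  evs.reserve(nd);
  for (int d = 0; d < nd; ++d) {
    char kind = CHAR(STRING_ELT(d_kind, d))[0];
    int tp = d_tpos[d];
    if (tp < 0 || tp > tlen) continue;
    int end = tp + (kind == 'D' ? d_len[d] : (kind == 'S' ? 1 : 0));
    evs.push_back({ d_sup[d] - 1, tp, kind, d_len[d],
                    as<std::string>(d_qseq[d]), end });
  }
  std::sort(evs.begin(), evs.end(), [](const Ev& a, const Ev& b) {
    if (a.tpos != b.tpos) return a.tpos < b.tpos;
    return a.sup < b.sup;
  });
  // per-support cumulative query-offset tables (insertions lengthen the
  // query segment, deletions shorten it)
  std::vector<std::vector<std::pair<int, int>>> offs(ns); // (tpos_after, cum_offset)
  {
    std::vector<std::vector<const Ev*>> bys(ns);
    for (auto& e : evs) bys[e.sup].push_back(&e);
    for (int u = 0; u < ns; ++u) {
      int cum = 0;
      for (auto* e : bys[u]) {
        if (e->kind == 'I') cum += (int)e->qseq.size();
        else if (e->kind == 'D') cum -= e->len;
        else continue;
        offs[u].push_back({ e->kind == 'I' ? e->tpos : e->tpos + e->len, cum });
      }
    }
  }
  auto qoff = [&](int sup, int pos) {
    // cumulative offset of events fully left of pos
    int cum = 0;
    for (auto& pr : offs[sup]) { if (pr.first <= pos) cum = pr.second; else break; }
    return cum;
  };

  struct Edit { int a; int b; std::string oldseq, newseq; int support; };
  std::vector<Edit> edits;

  // windows are anchored on positions where at least two distinct supports
  // differ: a difference seen in one support is that support's own error and
  // can never win a vote, so it must not extend windows (at high coverage,
  // pooling all supports' errors would chain the entire read into one
  // window)
  std::vector<std::pair<int, int>> active;   // position, extent end
  {
    size_t u = 0;
    while (u < evs.size()) {
      size_t v = u;
      int nsup = 0, last = -1, ext = evs[u].end;
      while (v < evs.size() && evs[v].tpos == evs[u].tpos) {
        if (evs[v].sup != last) { ++nsup; last = evs[v].sup; }
        ext = std::max(ext, evs[v].end);
        ++v;
      }
      if (nsup >= 2) active.push_back({ evs[u].tpos, ext });
      u = v;
    }
  }
  const int max_window = 40;

  size_t i = 0;
  while (i < active.size()) {
    size_t j = i + 1;
    int cend = active[i].second;
    while (j < active.size() && active[j].first <= cend + merge_gap) {
      cend = std::max(cend, active[j].second);
      ++j;
    }
    int a = std::max(0, active[i].first - 1);
    int b = std::min(tlen, cend + 1);
    if (b <= a) b = std::min(tlen, a + 1);
    i = j;
    if (b - a > max_window) continue;   // pathological region: leave alone
    // all events falling inside the window, grouped by support
    std::map<int, std::vector<size_t>> bysup;
    {
      Ev probe { 0, a, 'S', 0, "", 0 };
      auto lo = std::lower_bound(evs.begin(), evs.end(), probe,
        [](const Ev& x, const Ev& y) { return x.tpos < y.tpos; });
      for (auto it = lo; it != evs.end() && it->tpos < b; ++it)
        bysup[it->sup].push_back((size_t)(it - evs.begin()));
    }
    // votes: confident observations per window subsequence; lowq: carriers
    // of each subsequence whose window involves a base below q_min. An
    // allele whose carrier pool is enriched in low-quality bases is a
    // sequencing artifact (a recurrent error shared by many reads betrays
    // itself through the basecaller's quality, even when it holds the
    // numerical majority) and neither wins nor defends the window.
    std::map<std::string, int> votes, lowq;
    std::string twin = target.substr(a, b - a);
    {
      bool tok = true;
      for (int p = a; p < b; ++p) if (tqual[p] < q_min) { tok = false; break; }
      if (tok) ++votes[twin]; else ++lowq[twin];
    }
    for (int sUp = 0; sUp < ns; ++sUp) {
      if (!(s_ts[sUp] <= a && s_te[sUp] >= b)) continue;   // must span the window
      bool islow = false;
      {
        IntegerVector oq = quals[sUp];
        int qlo = s_qs[sUp] + (a - s_ts[sUp]) + qoff(sUp, a);
        int qhi = s_qs[sUp] + (b - s_ts[sUp]) + qoff(sUp, b);
        qlo = std::max(0, qlo); qhi = std::min((int)oq.size(), qhi);
        for (int qp = qlo; qp < qhi; ++qp)
          if (oq[qp] < q_min) { islow = true; break; }
      }
      auto it = bysup.find(sUp);
      std::string w;
      if (it == bysup.end()) w = twin;
      else {
        // reconstruct the support subsequence for [a, b); at a shared anchor
        // an insertion applies before the base-consuming event
        std::vector<size_t> sev = it->second;
        std::sort(sev.begin(), sev.end(), [&](size_t x, size_t y) {
          if (evs[x].tpos != evs[y].tpos) return evs[x].tpos < evs[y].tpos;
          return (evs[x].kind == 'I') > (evs[y].kind == 'I');
        });
        bool ok = true;
        int tp = a;
        for (size_t u : sev) {
          const Ev& e = evs[u];
          if (e.tpos < tp || e.end > b) { ok = false; break; }
          w += target.substr(tp, e.tpos - tp);
          if (e.kind == 'S') { w += e.qseq; tp = e.tpos + 1; }
          else if (e.kind == 'I') { w += e.qseq; tp = e.tpos; }
          else { tp = e.tpos + e.len; }
        }
        if (!ok || tp > b) continue;
        w += target.substr(tp, b - tp);
      }
      if (islow) ++lowq[w]; else ++votes[w];
    }
    auto is_flagged = [&](const std::string& k) {
      int lv = lowq.count(k) ? lowq[k] : 0;
      int v = votes.count(k) ? votes[k] : 0;
      return lv >= 2 && 5 * lv >= (lv + v);
    };
    bool twin_bad = is_flagged(twin);
    std::string bestk; int bestc = 0; int total = 0;
    for (auto& v : votes) {
      if (v.first != twin && is_flagged(v.first)) continue;
      if (v.first == twin) { if (!twin_bad) total += v.second; continue; }
      total += v.second;
      if (v.second > bestc || (v.second == bestc && v.first < bestk))
        { bestc = v.second; bestk = v.first; }
    }
    int tv = (!twin_bad && votes.count(twin)) ? votes[twin] : 0;
    if (bestc >= min_depth && bestc > tv &&
        (double)bestc >= min_ratio * std::max(1, total))
      edits.push_back({ a, b, twin, bestk, bestc });

  }

  // apply right to left
  std::string out = target;
  std::vector<int> oq(tqual.begin(), tqual.end());
  for (auto it = edits.rbegin(); it != edits.rend(); ++it) {
    int q = std::min(40, 10 + 2 * it->support);
    out.replace(it->a, it->b - it->a, it->newseq);
    oq.erase(oq.begin() + it->a, oq.begin() + it->b);
    oq.insert(oq.begin() + it->a, it->newseq.size(), q);
  }
  int ne = (int)edits.size();
  IntegerVector e_pos(ne), e_sup(ne);
  CharacterVector e_kind(ne), e_old(ne), e_new(ne);
  for (int u = 0; u < ne; ++u) {
    e_pos[u] = edits[u].a; e_sup[u] = edits[u].support;
    e_kind[u] = "W";
    e_old[u] = edits[u].oldseq; e_new[u] = edits[u].newseq;
  }
  return List::create(
    _["seq"] = out, _["qual"] = IntegerVector(oq.begin(), oq.end()),
    _["edits"] = DataFrame::create(
      _["pos"] = e_pos, _["kind"] = e_kind, _["old"] = e_old,
      _["new"] = e_new, _["support"] = e_sup, _["stringsAsFactors"] = false));
}

// ---------------------------------------------------------------------------
// read simulation
// ---------------------------------------------------------------------------

// Emit reads from haplotypes with recurrent (position-specific, fixed wrong
// allele) and random errors. Uses R's RNG so results are reproducible under
// set.seed(). Quality model: q_correct for correct bases; erroneous bases get
// q_err with probability q_err_prob (else q_correct).
// [[Rcpp::export(name = ".pc_sim_reads")]]
List pc_sim_reads(CharacterVector haps, IntegerVector hap_idx, IntegerVector starts,
                  IntegerVector lens, IntegerVector strands,
                  double sub_rate, double ins_rate, double del_rate,
                  double hp_mult, int hp_min_run,
                  int q_correct, int q_err, double q_err_prob,
                  IntegerVector rec_pos, CharacterVector rec_alt, double rho) {
  RNGScope scope;
  int nh = haps.size(), nr = hap_idx.size(), nrec = rec_pos.size();
  std::vector<std::string> H(nh);
  for (int i = 0; i < nh; ++i) H[i] = as<std::string>(haps[i]);
  // homopolymer multiplier mask per haplotype
  std::vector<std::vector<uint8_t>> hp(nh);
  for (int i = 0; i < nh; ++i) {
    int n = (int)H[i].size();
    hp[i].assign(n, 0);
    int p = 0;
    while (p < n) {
      int j = p + 1;
      while (j < n && H[i][j] == H[i][p]) ++j;
      if (j - p >= hp_min_run) for (int u = p; u < j; ++u) hp[i][u] = 1;
      p = j;
    }
  }
  const char* BASES = "ACGT";
  CharacterVector o_seq(nr);
  List o_qual(nr), o_errpos(nr), o_errkind(nr);
  std::vector<std::vector<int>> rec_hits(nrec);

  for (int r = 0; r < nr; ++r) {
    int h = hap_idx[r] - 1, st = starts[r], L = lens[r];
    const std::string& S = H[h];
    std::string raw = S.substr(st, L);
    std::vector<uint8_t> is_rec(L, 0);
    // recurrent errors
    for (int s = 0; s < nrec; ++s) {
      int p = rec_pos[s];
      if (p >= st && p < st + L) {
        if (unif_rand() < rho) {
          raw[p - st] = as<std::string>(rec_alt[s])[0];
          is_rec[p - st] = 1;
        }
      }
    }
    std::string out; out.reserve(L + 16);
    std::vector<int> qual; qual.reserve(L + 16);
    std::vector<int> epos; std::vector<std::string> ekind;
    std::vector<uint8_t> rec_flag_out; rec_flag_out.reserve(L + 16);
    for (int i = 0; i < L; ++i) {
      double mult = hp[h][st + i] ? hp_mult : 1.0;
      if (unif_rand() < del_rate * mult) {
        epos.push_back((int)out.size()); ekind.push_back("D");
        if (is_rec[i]) is_rec[i] = 0;  // deleted: recurrent allele not present
        continue;
      }
      char base = raw[i];
      bool err = is_rec[i] != 0;
      bool rec_here = is_rec[i] != 0;
      if (unif_rand() < sub_rate * mult) {
        char nb = base;
        while (nb == base) nb = BASES[(int)(unif_rand() * 4) & 3];
        base = nb; err = true;
        if (rec_here && base != raw[i]) rec_here = false; // overwritten
        epos.push_back((int)out.size()); ekind.push_back("S");
      } else if (rec_here) {
        epos.push_back((int)out.size()); ekind.push_back("R");
      }
      out.push_back(base);
      rec_flag_out.push_back(rec_here ? 1 : 0);
      qual.push_back(err && unif_rand() < q_err_prob ? q_err : q_correct);
      if (rec_here) {
        // locate site index again (few per read)
        for (int s = 0; s < nrec; ++s)
          if (rec_pos[s] == st + i) { rec_hits[s].push_back(r + 1); break; }
      }
      if (unif_rand() < ins_rate * mult) {
        char ib = BASES[(int)(unif_rand() * 4) & 3];
        epos.push_back((int)out.size()); ekind.push_back("I");
        out.push_back(ib);
        rec_flag_out.push_back(0);
        qual.push_back(unif_rand() < q_err_prob ? q_err : q_correct);
      }
    }
    if (strands[r] == 1) {
      int n = (int)out.size();
      out = revcomp(out);
      std::reverse(qual.begin(), qual.end());
      for (auto& p : epos) p = n - 1 - p;
    }
    o_seq[r] = out;
    o_qual[r] = IntegerVector(qual.begin(), qual.end());
    o_errpos[r] = IntegerVector(epos.begin(), epos.end());
    o_errkind[r] = CharacterVector(ekind.begin(), ekind.end());
  }
  List rh(nrec);
  for (int s = 0; s < nrec; ++s)
    rh[s] = IntegerVector(rec_hits[s].begin(), rec_hits[s].end());
  return List::create(_["seq"] = o_seq, _["qual"] = o_qual,
                      _["err_pos"] = o_errpos, _["err_kind"] = o_errkind,
                      _["rec_reads"] = rh);
}
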