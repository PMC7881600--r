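// Alignment kernels: exhaustive affine-gap Smith-Waterman for short inputs,
// banded affine-gap global alignment for chain verification and consensus,
// and a seed->chain->banded-extend mapper for long reads vs small references.
// Coordinates returned to R are 0-based half-open; strand "-" hits report the
// target span on the forward strand and query spans on the forward query.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int NEG = -1000000000;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string rc_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

static inline int sub_score(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N' || a == 'X' || b == 'X') return mismatch;  // N matches nothing
  return (a == b) ? match : mismatch;
}

// ---------------------------------------------------------------------------
// Exhaustive affine local alignment (Smith-Waterman) with rescan masking.
// ---------------------------------------------------------------------------

struct LocalHit {
  int qs, qe, ts, te, score, matches, cols;
};

static bool sw_best(const std::string &q, const std::string &t,
                    int match, int mismatch, int go, int ge,
                    LocalHit &hit) {
  const int n = (int)q.size(), m = (int)t.size();
  std::vector<int> Ix(m + 1, NEG);
  // traceback byte per cell: bits 0-1 source of H at cell (0 stop,1 M,2 Ix,3 Iy)
  // bit 4: Ix came from Ix, bit 5: Iy came from Iy
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  std::vector<int> Hrow(m + 1, 0), Hprev(m + 1, 0);
  std::vector<uint8_t> state_row(m + 1, 0), state_prev(m + 1, 0); // argmax of H
  for (int i = 1; i <= n; ++i) {
    std::swap(Hprev, Hrow);
    std::swap(state_prev, state_row);
    Hrow[0] = 0; state_row[0] = 0;
    int IyPrev = NEG;
    for (int j = 1; j <= m; ++j) {
      uint8_t tbb = 0;
      // M: diagonal from H(i-1, j-1)
      int mval = Hprev[j - 1] + sub_score(q[i - 1], t[j - 1], match, mismatch);
      uint8_t msrc = state_prev[j - 1]; // 0 fresh start else matrix id
      // Ix: gap in target, consume query (vertical)
      int fromM = Hprev[j] + go + ge;
      int fromX = Ix[j] + ge;
      int IxCur = std::max(fromM, fromX);
      bool ix_from_ix = fromX >= fromM;
      // Iy: gap in query, consume target (horizontal)
      int fromM2 = Hrow[j - 1] + go + ge;
      int fromY = IyPrev + ge;
      int IyCur = std::max(fromM2, fromY);
      bool iy_from_iy = fromY >= fromM2;
      int h = mval;
      uint8_t hsrc = 1;
      if (IxCur > h) { h = IxCur; hsrc = 2; }
      if (IyCur > h) { h = IyCur; hsrc = 3; }
      if (h <= 0) { h = 0; hsrc = 0; }
      tbb = (hsrc & 3) | ((msrc & 3) << 2) | (ix_from_ix ? 16 : 0) | (iy_from_iy ? 32 : 0);
      tb[(size_t)i * (m + 1) + j] = tbb;
      Hrow[j] = h; state_row[j] = hsrc;
      Ix[j] = IxCur;
      IyPrev = IyCur;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return false;
  // traceback (recompute path using stored bytes)
  int i = bi, j = bj;
  uint8_t st = tb[(size_t)i * (m + 1) + j] & 3;
  int matches = 0, cols = 0;
  int qe = bi, te = bj;
  while (st != 0 && (i > 0 || j > 0)) {
    uint8_t b = tb[(size_t)i * (m + 1) + j];
    if (st == 1) {
      ++cols;
      if (q[i - 1] == t[j - 1] && q[i - 1] != 'N' && q[i - 1] != 'X') ++matches;
      uint8_t prev = (b >> 2) & 3;
      --i; --j;
      st = prev;
      if (st == 0) break;
    } else if (st == 2) {
      ++cols;
      bool from_ix = (b & 16) != 0;
      --i;
      st = from_ix ? 2 : 1;
      if (!from_ix) st = 1;
    } else { // st == 3
      ++cols;
      bool from_iy = (b & 32) != 0;
      --j;
      st = from_iy ? 3 : 1;
    }
  }
  hit.qs = i; hit.qe = qe; hit.ts = j; hit.te = te;
  hit.score = best; hit.matches = matches; hit.cols = cols;
  return true;
}

// [[Rcpp::export(name = ".cpp_sw_hits")]]
DataFrame cpp_sw_hits(std::string q, std::string t,
                      int match, int mismatch, int gap_open, int gap_ext,
                      int min_score, int max_hits) {
  std::vector<int> qs, qe, ts, te, sc, mt, cl;
  std::string tt = t;
  for (int h = 0; h < max_hits; ++h) {
    LocalHit hit;
    if (!sw_best(q, tt, match, mismatch, gap_open, gap_ext, hit)) break;
    if (hit.score < min_score) break;
    qs.push_back(hit.qs); qe.push_back(hit.qe);
    ts.push_back(hit.ts); te.push_back(hit.te);
    sc.push_back(hit.score); mt.push_back(hit.matches); cl.push_back(hit.cols);
    for (int j = hit.ts; j < hit.te; ++j) tt[j] = 'X';
  }
  return DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                           _["tstart"] = ts, _["tend"] = te,
                           _["score"] = sc, _["matches"] = mt,
                           _["aln_cols"] = cl);
}

// ---------------------------------------------------------------------------
// Banded affine global alignment with optional traceback strings.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_banded_align")]]
List cpp_banded_align(std::string q, std::string t, int band,
                      int match, int mismatch, int gap_open, int gap_ext,
                      bool traceback) {
  const int n = (int)q.size(), m = (int)t.size();
  if (n == 0 || m == 0) {
    int sc = (n + m) > 0 ? gap_open + gap_ext * (n + m) : 0;
    std::string qa(n, '?'), ta(m, '?');
    if (traceback) {
      qa = q + std::string(m, '-');
      ta = std::string(n, '-') + t;
    }
    return List::create(_["score"] = sc, _["matches"] = 0,
                        _["aln_cols"] = n + m, _["identity"] = 0.0,
                        _["q_aln"] = qa, _["t_aln"] = ta);
  }
  const int shift_lo = std::min(0, m - n), shift_hi = std::max(0, m - n);
  const int W = (shift_hi - shift_lo) + 2 * band + 1; // band window width
  auto lo_of = [&](int i) { return std::max(0, i + shift_lo - band); };
  auto hi_of = [&](int i) { return std::min(m, i + shift_hi + band); };
  std::vector<int> M(W), Ix(W), Iy(W), Mp(W), Ixp(W), Iyp(W);
  std::vector<uint8_t> tb; // per cell byte as in sw
  if (true) tb.assign((size_t)(n + 1) * W, 0);
  // row 0
  int lo0 = lo_of(0), hi0 = hi_of(0);
  for (int j = lo0; j <= hi0; ++j) {
    int idx = j - lo0;
    if (j == 0) { M[idx] = 0; Ix[idx] = NEG; Iy[idx] = NEG; }
    else {
      M[idx] = NEG; Ix[idx] = NEG;
      Iy[idx] = gap_open + gap_ext * j;
      tb[(size_t)0 * W + idx] = 32 | 3; // Iy from Iy, state bookkeeping
    }
  }
  int prev_lo = lo0;
  for (int i = 1; i <= n; ++i) {
    std::swap(M, Mp); std::swap(Ix, Ixp); std::swap(Iy, Iyp);
    int lo = lo_of(i), hi = hi_of(i);
    for (int j = lo; j <= hi; ++j) {
      int idx = j - lo;
      int pidx = j - prev_lo;      // same j previous row
      int pdidx = j - 1 - prev_lo; // j-1 previous row
      uint8_t b = 0;
      // M
      int mval = NEG; uint8_t msrc = 1;
      if (j >= 1 && pdidx >= 0 && pdidx < W && (j - 1) <= hi_of(i - 1) && (j - 1) >= prev_lo) {
        int hprev = Mp[pdidx]; uint8_t src = 1;
        if (Ixp[pdidx] > hprev) { hprev = Ixp[pdidx]; src = 2; }
        if (Iyp[pdidx] > hprev) { hprev = Iyp[pdidx]; src = 3; }
        if (hprev > NEG / 2)
          mval = hprev + sub_score(q[i - 1], t[j - 1], match, mismatch);
        msrc = src;
      }
      // Ix (consume query; from previous row same j)
      int ixval = NEG; bool ix_from_ix = false;
      if (pidx >= 0 && pidx < W && j <= hi_of(i - 1) && j >= prev_lo) {
        int fm = std::max(Mp[pidx], Iyp[pidx]) ;
        int fromM = (fm > NEG / 2) ? fm + gap_open + gap_ext : NEG;
        int fromX = (Ixp[pidx] > NEG / 2) ? Ixp[pidx] + gap_ext : NEG;
        ixval = std::max(fromM, fromX);
        ix_from_ix = fromX >= fromM;
      }
      // Iy (consume target; from same row j-1)
      int iyval = NEG; bool iy_from_iy = false;
      if (j - 1 >= lo) {
        int cidx = j - 1 - lo;
        int fm = std::max(M[cidx], Ix[cidx]);
        int fromM = (fm > NEG / 2) ? fm + gap_open + gap_ext : NEG;
        int fromY = (Iy[cidx] > NEG / 2) ? Iy[cidx] + gap_ext : NEG;
        iyval = std::max(fromM, fromY);
        iy_from_iy = fromY >= fromM;
      } else if (i == 0) {
        // handled in row 0
      }
      if (i >= 1 && j == 0) {
        // first column: only Ix possible
      }
      M[idx] = mval; Ix[idx] = ixval; Iy[idx] = iyval;
      b = ((msrc & 3) << 2) | (ix_from_ix ? 16 : 0) | (iy_from_iy ? 32 : 0);
      tb[(size_t)i * W + idx] = b;
    }
    prev_lo = lo;
  }
  int lon = lo_of(n);
  int fidx = m - lon;
  int score = NEG; uint8_t fstate = 1;
  if (fidx >= 0 && fidx < W) {
    score = M[fidx]; fstate = 1;
    if (Ix[fidx] > score) { score = Ix[fidx]; fstate = 2; }
    if (Iy[fidx] > score) { score = Iy[fidx]; fstate = 3; }
  }
  // traceback
  int matches = 0, cols = 0;
  std::string qa, ta;
  int i = n, j = m; uint8_t st = fstate;
  while (i > 0 || j > 0) {
    int lo = lo_of(i);
    uint8_t b = tb[(size_t)i * W + (j - lo)];
    if (st == 1 && i > 0 && j > 0) {
      ++cols;
      if (q[i - 1] == t[j - 1] && q[i - 1] != 'N') ++matches;
      if (traceback) { qa.push_back(q[i - 1]); ta.push_back(t[j - 1]); }
      uint8_t prev = (b >> 2) & 3;
      --i; --j;
      st = prev;
      if (i == 0 && j == 0) break;
      if (st == 0) st = 1;
    } else if (st == 2 || (j == 0 && i > 0)) {
      ++cols;
      if (traceback) { qa.push_back(q[i - 1]); ta.push_back('-'); }
      bool from_ix = (b & 16) != 0;
      --i;
      st = (j == 0) ? 2 : (from_ix ? 2 : 1);
    } else { // st == 3 or i == 0
      ++cols;
      if (traceback) { qa.push_back('-'); ta.push_back(t[j - 1]); }
      bool from_iy = (b & 32) != 0;
      --j;
      st = (i == 0) ? 3 : (from_iy ? 3 : 1);
    }
  }
  if (traceback) {
    std::reverse(qa.begin(), qa.end());
    std::reverse(ta.begin(), ta.end());
  }
  double identity = cols > 0 ? (double)matches / (double)cols : 0.0;
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["aln_cols"] = cols, _["identity"] = identity,
                      _["q_aln"] = qa, _["t_aln"] = ta);
}

// ---------------------------------------------------------------------------
// Seed -> diagonal-cluster chain -> banded verification mapper.
// ---------------------------------------------------------------------------

struct Anchor { int qpos, tpos; };

// [[Rcpp::export(name = ".cpp_map_reads")]]
DataFrame cpp_map_reads(CharacterVector queries, CharacterVector targets,
                        int k, int min_anchors, int max_diag_gap, int band_pad,
                        int match, int mismatch, int gap_open, int gap_ext,
                        bool verify) {
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  // build index over targets
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  std::vector<std::string> tseq(targets.size());
  for (int ti = 0; ti < targets.size(); ++ti) {
    tseq[ti] = as<std::string>(targets[ti]);
    const std::string &s = tseq[ti];
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int code;
      switch (s[p]) {
        case 'A': code = 0; break; case 'C': code = 1; break;
        case 'G': code = 2; break; case 'T': code = 3; break;
        default: code = -1;
      }
      if (code < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)code) & mask;
      if (++run >= k) {
        auto &v = index[key];
        if ((int)v.size() < 64) v.push_back({ti, p - k + 1});
      }
    }
  }
  std::vector<int> o_query, o_target, o_qs, o_qe, o_ts, o_te, o_na, o_score, o_matches, o_cols;
  std::vector<std::string> o_strand;
  std::vector<double> o_ident;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string fwd = as<std::string>(queries[qi]);
    int qlen = (int)fwd.size();
    if (qlen < k) continue;
    for (int strand = 0; strand < 2; ++strand) {
      std::string qseq = (strand == 0) ? fwd : rc_str(fwd);
      // collect anchors per target
      std::vector<std::vector<Anchor>> per_t(targets.size());
      uint64_t key = 0; int run = 0;
      for (int p = 0; p < qlen; ++p) {
        int code;
        switch (qseq[p]) {
          case 'A': code = 0; break; case 'C': code = 1; break;
          case 'G': code = 2; break; case 'T': code = 3; break;
          default: code = -1;
        }
        if (code < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)code) & mask;
        if (++run >= k) {
          auto it = index.find(key);
          if (it != index.end())
            for (auto &pr : it->second)
              per_t[pr.first].push_back({p - k + 1, pr.second});
        }
      }
      for (int ti = 0; ti < (int)per_t.size(); ++ti) {
        auto &anch = per_t[ti];
        if ((int)anch.size() < min_anchors) continue;
        std::sort(anch.begin(), anch.end(), [](const Anchor &a, const Anchor &b) {
          int da = a.tpos - a.qpos, db = b.tpos - b.qpos;
          if (da != db) return da < db;
          return a.qpos < b.qpos;
        });
        // split into diagonal clusters
        size_t start = 0;
        for (size_t e = 1; e <= anch.size(); ++e) {
          bool brk = (e == anch.size()) ||
                     ((anch[e].tpos - anch[e].qpos) - (anch[e - 1].tpos - anch[e - 1].qpos) > max_diag_gap);
          if (!brk) continue;
          std::vector<Anchor> cl(anch.begin() + start, anch.begin() + e);
          start = e;
          if ((int)cl.size() < min_anchors) continue;
          std::sort(cl.begin(), cl.end(), [](const Anchor &a, const Anchor &b) {
            if (a.qpos != b.qpos) return a.qpos < b.qpos;
            return a.tpos < b.tpos;
          });
          // greedy monotone chain
          std::vector<Anchor> chain;
          int last_q = -1, last_t = -1;
          for (auto &a : cl) {
            if (a.qpos > last_q && a.tpos > last_t) {
              chain.push_back(a); last_q = a.qpos; last_t = a.tpos;
            }
          }
          if ((int)chain.size() < min_anchors) continue;
          int qs = chain.front().qpos, qe = chain.back().qpos + k;
          int ts = chain.front().tpos, te = chain.back().tpos + k;
          int dmin = chain.front().tpos - chain.front().qpos, dmax = dmin;
          for (auto &a : chain) {
            int d = a.tpos - a.qpos;
            dmin = std::min(dmin, d); dmax = std::max(dmax, d);
          }
          int score = 0, matches = 0, cols = 0;
          double ident = 1.0;
          if (verify) {
            std::string qsub = qseq.substr(qs, qe - qs);
            std::string tsub = tseq[ti].substr(ts, te - ts);
            int band = (dmax - dmin) + band_pad;
            List al = cpp_banded_align(qsub, tsub, band, match, mismatch,
                                       gap_open, gap_ext, false);
            score = as<int>(al["score"]);
            matches = as<int>(al["matches"]);
            cols = as<int>(al["aln_cols"]);
            ident = as<double>(al["identity"]);
          } else {
            matches = (int)chain.size();
            score = matches;
            cols = qe - qs;
          }
          int rqs = qs, rqe = qe;
          if (strand == 1) { rqs = qlen - qe; rqe = qlen - qs; }
          o_query.push_back(qi + 1);
          o_target.push_back(ti + 1);
          o_strand.push_back(strand == 0 ? "+" : "-");
          o_qs.push_back(rqs); o_qe.push_back(rqe);
          o_ts.push_back(ts); o_te.push_back(te);
          o_na.push_back((int)chain.size());
          o_score.push_back(score); o_matches.push_back(matches);
          o_cols.push_back(cols); o_ident.push_back(ident);
        }
      }
    }
  }
  return DataFrame::create(_["query"] = o_query, _["target"] = o_target,
                           _["strand"] = o_strand,
                           _["qstart"] = o_qs, _["qend"] = o_qe,
                           _["tstart"] = o_ts, _["tend"] = o_te,
                           _["n_anchors"] = o_na, _["score"] = o_score,
                           _["matches"] = o_matches, _["aln_cols"] = o_cols,
                           _["identity"] = o_ident,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = rc_str(as<std::string>(x[i]));
  }
  out.names() = x.names();
  return out;
}
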