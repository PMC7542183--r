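// String-rewriting engine: weighted-lexicographic order, leftmost
// normalization, critical-pair enumeration and Knuth-Bendix completion
// with full interreduction.  Words are integer vectors of generator ids
// (1-based at the R boundary, 0-based internally).  Generator weights
// arrive pre-scaled to exact integers (a common denominator is applied on
// the R side), so order comparisons are exact integer arithmetic.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <queue>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

typedef std::vector<int> Word;

namespace {

struct Order {
  std::vector<int64_t> w;  // weight per generator
  std::vector<int> rank;   // precedence rank: higher rank = greater under >

  int64_t weight(const Word &u) const {
    int64_t s = 0;
    for (int g : u) s += w[g];
    return s;
  }

  // +1 if u > v, -1 if u < v, 0 if equal.  Total: weight first, then the
  // first differing letter by precedence.  With strictly positive weights
  // two distinct words of equal weight always differ at some position
  // within the shorter length, but the length fallback keeps the order
  // total for arbitrary inputs.
  int cmp(const Word &u, const Word &v) const {
    int64_t wu = weight(u), wv = weight(v);
    if (wu != wv) return wu > wv ? 1 : -1;
    size_t m = std::min(u.size(), v.size());
    for (size_t i = 0; i < m; ++i)
      if (u[i] != v[i]) return rank[u[i]] > rank[v[i]] ? 1 : -1;
    if (u.size() == v.size()) return 0;
    return u.size() > v.size() ? 1 : -1;
  }
};

struct Rule {
  Word lhs, rhs;
  bool active;
};

struct System {
  std::vector<Rule> rules;
  std::vector<std::vector<int> > bucket;  // rule indices by first lhs letter
  size_t maxlhs;
  size_t nactive;

  explicit System(int ngen) : bucket(ngen), maxlhs(1), nactive(0) {}

  int add(const Word &l, const Word &r) {
    Rule ru;
    ru.lhs = l;
    ru.rhs = r;
    ru.active = true;
    rules.push_back(ru);
    int idx = (int)rules.size() - 1;
    bucket[l[0]].push_back(idx);
    if (l.size() > maxlhs) maxlhs = l.size();
    ++nactive;
    return idx;
  }

  void deactivate(int idx) {
    if (rules[idx].active) {
      rules[idx].active = false;
      --nactive;
    }
  }

  int match_at(const Word &w, size_t pos) const {
    const std::vector<int> &b = bucket[w[pos]];
    for (size_t t = 0; t < b.size(); ++t) {
      const Rule &r = rules[b[t]];
      if (!r.active) continue;
      size_t L = r.lhs.size();
      if (pos + L > w.size()) continue;
      bool ok = true;
      for (size_t k = 1; k < L; ++k)
        if (w[pos + k] != r.lhs[k]) { ok = false; break; }
      if (ok) return b[t];
    }
    return -1;
  }

  Word normalize(Word w) const {
    size_t pos = 0;
    while (pos < w.size()) {
      int ri = match_at(w, pos);
      if (ri < 0) { ++pos; continue; }
      const Rule &r = rules[ri];
      Word nw;
      nw.reserve(w.size() - r.lhs.size() + r.rhs.size());
      nw.insert(nw.end(), w.begin(), w.begin() + pos);
      nw.insert(nw.end(), r.rhs.begin(), r.rhs.end());
      nw.insert(nw.end(), w.begin() + pos + r.lhs.size(), w.end());
      w.swap(nw);
      pos = pos > maxlhs ? pos - maxlhs : 0;
    }
    return w;
  }
};

// contiguous-factor test: does w contain f?
bool contains(const Word &w, const Word &f) {
  if (f.size() > w.size()) return false;
  size_t last = w.size() - f.size();
  for (size_t i = 0; i <= last; ++i) {
    bool ok = true;
    for (size_t k = 0; k < f.size(); ++k)
      if (w[i + k] != f[k]) { ok = false; break; }
    if (ok) return true;
  }
  return false;
}

// Enumerate critical pairs from superpositions of p.lhs (as the "left"
// rule) with q.lhs: occurrences of a prefix of q.lhs starting inside
// p.lhs.  Covers proper suffix/prefix overlaps and q.lhs contained in
// p.lhs; the converse containment comes from the swapped call.
template <class Sink>
void overlaps(const Rule &p, const Rule &q, bool same_rule, Sink sink) {
  const Word &A = p.lhs, &B = q.lhs;
  for (size_t i = 0; i < A.size(); ++i) {
    if (i == 0 && same_rule) continue;  // identical superposition, trivial
    size_t m = std::min(B.size(), A.size() - i);
    bool match = true;
    for (size_t k = 0; k < m; ++k)
      if (A[i + k] != B[k]) { match = false; break; }
    if (!match) continue;
    if (i + B.size() <= A.size()) {
      // B is a factor of A at offset i
      Word w2;
      w2.reserve(i + q.rhs.size() + (A.size() - i - B.size()));
      w2.insert(w2.end(), A.begin(), A.begin() + i);
      w2.insert(w2.end(), q.rhs.begin(), q.rhs.end());
      w2.insert(w2.end(), A.begin() + i + B.size(), A.end());
      sink(p.rhs, w2);
    } else {
      // proper overlap: suffix of A = prefix of B, length m
      Word w1 = p.rhs;
      w1.insert(w1.end(), B.begin() + m, B.end());
      Word w2(A.begin(), A.begin() + i);
      w2.insert(w2.end(), q.rhs.begin(), q.rhs.end());
      sink(w1, w2);
    }
  }
}

Word from_sexp(const IntegerVector &v) {
  Word w(v.size());
  for (int i = 0; i < v.size(); ++i) w[i] = v[i] - 1;
  return w;
}

IntegerVector to_sexp(const Word &w) {
  IntegerVector v(w.size());
  for (size_t i = 0; i < w.size(); ++i) v[i] = w[i] + 1;
  return v;
}

System build_system(const List &lhs_list, const List &rhs_list, int ngen) {
  System sys(ngen);
  for (int i = 0; i < lhs_list.size(); ++i)
    sys.add(from_sexp(lhs_list[i]), from_sexp(rhs_list[i]));
  return sys;
}

Order build_order(const NumericVector &weights, const IntegerVector &rank) {
  Order ord;
  ord.w.resize(weights.size());
  ord.rank.resize(rank.size());
  for (int i = 0; i < weights.size(); ++i) {
    ord.w[i] = (int64_t)::llround(weights[i]);
    ord.rank[i] = rank[i];
  }
  return ord;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_normalize(IntegerVector word, List lhs_list, List rhs_list,
                            int ngen) {
  System sys = build_system(lhs_list, rhs_list, ngen);
  return to_sexp(sys.normalize(from_sexp(word)));
}

// [[Rcpp::export]]
List cpp_normalize_many(List words, List lhs_list, List rhs_list, int ngen) {
  System sys = build_system(lhs_list, rhs_list, ngen);
  List out(words.size());
  for (int i = 0; i < words.size(); ++i)
    out[i] = to_sexp(sys.normalize(from_sexp(words[i])));
  return out;
}

// [[Rcpp::export]]
int cpp_compare(IntegerVector u, IntegerVector v, NumericVector weights,
                IntegerVector rank) {
  Order ord = build_order(weights, rank);
  return ord.cmp(from_sexp(u), from_sexp(v));
}

// Exhaustive local-confluence check: every critical pair of every ordered
// rule pair must normalize to a joint word.  Returns the pair count and
// the first unresolved pair, if any.
// [[Rcpp::export]]
List cpp_check_confluence(List lhs_list, List rhs_list, int ngen) {
  System sys = build_system(lhs_list, rhs_list, ngen);
  long long npairs = 0;
  bool confluent = true;
  List bad = R_NilValue;
  size_t n = sys.rules.size();
  for (size_t i = 0; i < n && confluent; ++i) {
    for (size_t j = 0; j < n && confluent; ++j) {
      const Rule &p = sys.rules[i], &q = sys.rules[j];
      overlaps(p, q, i == j, [&](const Word &u, const Word &v) {
        ++npairs;
        if (!confluent) return;
        Word nu = sys.normalize(u), nv = sys.normalize(v);
        if (nu != nv) {
          confluent = false;
          bad = List::create(to_sexp(u), to_sexp(v));
        }
      });
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["confluent"] = confluent,
                      _["pairs_checked"] = (double)npairs,
                      _["counterexample"] = bad);
}

// [[Rcpp::export]]
List cpp_critical_pairs(IntegerVector lhs1, IntegerVector rhs1,
                        IntegerVector lhs2, IntegerVector rhs2,
                        bool same_rule) {
  Rule p, q;
  p.lhs = from_sexp(lhs1);
  p.rhs = from_sexp(rhs1);
  q.lhs = from_sexp(lhs2);
  q.rhs = from_sexp(rhs2);
  std::vector<std::pair<Word, Word> > acc;
  overlaps(p, q, same_rule, [&](const Word &u, const Word &v) {
    acc.push_back(std::make_pair(u, v));
  });
  List out(acc.size());
  for (size_t i = 0; i < acc.size(); ++i)
    out[i] = List::create(to_sexp(acc[i].first), to_sexp(acc[i].second));
  return out;
}

// Knuth-Bendix completion with interreduction.  Work is organized as a
// priority queue of *rule pairs* awaiting critical-pair examination,
// smallest combined left-hand sides first; critical pairs are resolved
// immediately (normalize, orient, insert, collapse), so queue keys are
// built from immutable lhs words and never go stale.  Together with
// full interreduction this drives the run to the unique reduced
// confluent system for the given order.
// [[Rcpp::export]]
List cpp_knuth_bendix(List eq_lhs, List eq_rhs, int ngen,
                      NumericVector weights, IntegerVector rank,
                      int max_rules, double max_iter) {
  Order ord = build_order(weights, rank);
  System sys(ngen);

  // Pending work: unresolved equations (initial relations, collapsed
  // rules, critical pairs).  Each entry's key is the weight of its
  // larger side *as queued* (immutable), and entries are processed in
  // ascending key order with FIFO tie-break.  Because keys are fixed at
  // creation and critical pairs are queued un-normalized, processing
  // order tracks the ascending enumeration of words that defines the
  // canonical reduced system: rules are derived small-first, and junk
  // rules (whose left sides later turn out reducible) stay rare instead
  // of breeding.  Critical-pair entries remember their parent rules and
  // are dropped if a parent has been collapsed meanwhile.
  struct Entry {
    Word a, b;
    int pi, pj;  // parent rules, -1 for plain equations
  };
  std::deque<Entry> store;
  struct Key {
    int64_t w;
    long long seq;
    int idx;
  };
  struct KeyCmp {
    bool operator()(const Key &x, const Key &y) const {
      if (x.w != y.w) return x.w > y.w;  // min-heap on weight
      return x.seq > y.seq;              // FIFO among equals
    }
  };
  std::priority_queue<Key, std::vector<Key>, KeyCmp> queue;
  long long seq = 0;

  double iter = 0;
  long long pairs_generated = 0;
  long long discarded = 0;
  bool complete = true;

  auto push_entry = [&](const Word &a, const Word &b, int pi, int pj) {
    Entry e;
    e.a = a;
    e.b = b;
    e.pi = pi;
    e.pj = pj;
    store.push_back(e);
    Key k;
    k.w = std::max(ord.weight(a), ord.weight(b));
    k.seq = seq++;
    k.idx = (int)store.size() - 1;
    queue.push(k);
  };

  for (int i = 0; i < eq_lhs.size(); ++i)
    push_entry(from_sexp(eq_lhs[i]), from_sexp(eq_rhs[i]), -1, -1);

  while (complete && !queue.empty()) {
    if (++iter > max_iter) { complete = false; break; }
    if ((long long)iter % 256 == 0) Rcpp::checkUserInterrupt();
    Key key = queue.top();
    queue.pop();
    Entry ent;
    std::swap(ent, store[key.idx]);  // each entry is popped once; free it
    if (ent.pi >= 0 &&
        (!sys.rules[ent.pi].active || !sys.rules[ent.pj].active))
      continue;  // obsolete critical pair
    Word u = sys.normalize(ent.a);
    Word v = sys.normalize(ent.b);
    int c = ord.cmp(u, v);
    if (c == 0) { ++discarded; continue; }
    if (c < 0) u.swap(v);
    int nri = sys.add(u, v);
    if ((int)sys.nactive > max_rules) { complete = false; break; }

    // interreduce: collapse rules whose lhs the new rule reduces,
    // renormalize affected right-hand sides
    for (int k = 0; k < nri; ++k) {
      Rule &r = sys.rules[k];
      if (!r.active) continue;
      if (contains(r.lhs, u)) {
        sys.deactivate(k);
        push_entry(r.lhs, r.rhs, -1, -1);
      } else if (contains(r.rhs, u)) {
        r.rhs = sys.normalize(r.rhs);
      }
    }

    // queue critical pairs of the new rule against all active rules
    // (both orientations, including itself)
    const Rule newr = sys.rules[nri];  // copy: rules vector may grow
    for (int k = 0; k <= nri; ++k) {
      if (!sys.rules[k].active) continue;
      const Rule other = sys.rules[k];
      overlaps(newr, other, k == nri, [&](const Word &a, const Word &b) {
        ++pairs_generated;
        push_entry(a, b, nri, k);
      });
      if (k != nri) {
        overlaps(other, newr, false, [&](const Word &a, const Word &b) {
          ++pairs_generated;
          push_entry(a, b, k, nri);
        });
      }
    }
  }

  List lhs_out, rhs_out;
  // deterministic output order: sort active rules by the reduction order
  // of their lhs (ascending)
  std::vector<int> act;
  for (size_t i = 0; i < sys.rules.size(); ++i)
    if (sys.rules[i].active) act.push_back((int)i);
  std::sort(act.begin(), act.end(), [&](int a, int b) {
    int c = ord.cmp(sys.rules[a].lhs, sys.rules[b].lhs);
    if (c != 0) return c < 0;
    return ord.cmp(sys.rules[a].rhs, sys.rules[b].rhs) < 0;
  });
  List lo(act.size()), ro(act.size());
  for (size_t i = 0; i < act.size(); ++i) {
    lo[i] = to_sexp(sys.rules[act[i]].lhs);
    ro[i] = to_sexp(sys.rules[act[i]].rhs);
  }
  return List::create(_["lhs"] = lo, _["rhs"] = ro,
                      _["complete"] = complete,
                      _["iterations"] = iter,
                      _["pairs_generated"] = (double)pairs_generated,
                      _["discarded"] = (double)discarded);
}
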