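// Dated DTL maximum-parsimony reconciliation.
//
// Model: the species chronogram is cut into time slices at the distinct
// internal-node ages. A gene lineage entering a species edge within a slice
// may undergo a duplication (both children stay on the edge), a transfer
// (one child stays, the other regrafts onto a different edge alive in the
// same slice), or descend to the bottom boundary of the slice, where the
// edge either continues into the next slice or ends at a speciation node
// (the gene node speciates, or passes into one child edge at the price of a
// loss on the other). Costs: speciation 0, duplication cdup, transfer
// ctrans, each loss closs.
//
// The DP computes, per gene node u and segment (edge e, slice t), the
// minimum cost of the subtree of u given its lineage enters (e, t), together
// with the exact number of optimal completions (arbitrary-precision
// integers). Uniform sampling of optima backtracks through the same option
// sets with probabilities proportional to the exact counts.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const double INF = 1e18;
static const double EPS = 1e-9;

// ---- minimal arbitrary-precision unsigned integer (base 1e9) ----
struct Big {
  std::vector<long long> d; // little-endian limbs, each in [0, 1e9)
  static const long long B = 1000000000LL;
  Big() {}
  explicit Big(long long v) { while (v > 0) { d.push_back(v % B); v /= B; } }
  bool zero() const { return d.empty(); }
  void add(const Big& o) {
    size_t n = std::max(d.size(), o.d.size());
    d.resize(n, 0);
    long long carry = 0;
    for (size_t i = 0; i < n; ++i) {
      long long s = d[i] + (i < o.d.size() ? o.d[i] : 0) + carry;
      d[i] = s % B; carry = s / B;
    }
    if (carry) d.push_back(carry);
  }
  static Big mul(const Big& a, const Big& b) {
    Big r;
    if (a.zero() || b.zero()) return r;
    r.d.assign(a.d.size() + b.d.size(), 0);
    for (size_t i = 0; i < a.d.size(); ++i) {
      unsigned __int128 carry = 0;
      for (size_t j = 0; j < b.d.size(); ++j) {
        unsigned __int128 cur = (unsigned __int128)a.d[i] * (unsigned __int128)b.d[j]
          + (unsigned __int128)r.d[i + j] + carry;
        r.d[i + j] = (long long)(cur % B);
        carry = cur / B;
      }
      size_t k = i + b.d.size();
      while (carry) {
        unsigned __int128 cur = (unsigned __int128)r.d[k] + carry;
        r.d[k] = (long long)(cur % B);
        carry = cur / B;
        ++k;
      }
    }
    while (!r.d.empty() && r.d.back() == 0) r.d.pop_back();
    return r;
  }
  double to_double() const {
    double v = 0;
    for (size_t i = d.size(); i-- > 0;) v = v * (double)B + (double)d[i];
    return v;
  }
  std::string to_string() const {
    if (d.empty()) return "0";
    std::string s = std::to_string(d.back());
    char buf[16];
    for (size_t i = d.size() - 1; i-- > 0;) {
      snprintf(buf, sizeof(buf), "%09lld", d[i]);
      s += buf;
    }
    return s;
  }
};

struct Engine {
  // gene tree (0-based)
  std::vector<int> gc1, gc2, gsp, gpost;
  int n_gene;
  // species tree
  std::vector<int> sc1, sc2, spar, sbidx;
  int n_sp, s_root, m; // m = number of slices
  double cdup, ctrans, closs;

  // segments
  std::vector<std::vector<int>> seg;        // seg[v][t] -> idx or -1 (v = edge child node)
  std::vector<std::pair<int,int>> segs;     // idx -> (v, t)
  std::vector<std::vector<int>> alive;      // alive[t] = edges (child ids) alive in slice t
  int n_seg;

  // DP tables
  std::vector<std::vector<double>> cost;    // [gene][seg]
  std::vector<std::vector<Big>> cnt;
  std::vector<std::vector<double>> cntd;    // counts as doubles (sampling)

  // The root's stem is modelled as an extra edge (child node = species
  // root) alive only in a virtual top slice m (= n_slice + 1), so that
  // duplications may predate the species root; its bottom boundary is the
  // root speciation. No other edge is contemporaneous with it.
  bool edge_alive(int v, int t) const {
    if (v == s_root) return t == m;
    return sbidx[v] <= t - 1 && sbidx[spar[v]] >= t;
  }

  void build_segments() {
    seg.assign(n_sp, std::vector<int>(m + 1, -1));
    alive.assign(m + 1, {});
    segs.clear();
    for (int t = 1; t <= m; ++t)
      for (int v = 0; v < n_sp; ++v)
        if (edge_alive(v, t)) {
          seg[v][t] = (int)segs.size();
          segs.push_back({v, t});
          alive[t].push_back(v);
        }
    n_seg = (int)segs.size();
  }

  // enumerate options for state (gene node u entering segment (e,t));
  // cb(cost, count, code, a, b) -- code 0 leaf, 1 spec (a = species node,
  // b = 0/1 child order), 2 dup, 3 transfer (a = recipient edge, b = which
  // child transferred), 4 loss-pass (a = surviving edge, b = lost edge),
  // 5 continue
  template <class F>
  void options(int u, int e, int t, F cb) const {
    int v = gc1[u], w = gc2[u];
    bool internal = v >= 0;
    // in-slice events
    if (internal) {
      int se = seg[e][t];
      double dv = cost[v][se], dw = cost[w][se];
      if (dv < INF && dw < INF)
        cb(cdup + dv + dw, Big::mul(cnt[v][se], cnt[w][se]), 2, -1, -1);
      for (int f : alive[t]) {
        if (f == e) continue;
        int sf = seg[f][t];
        double dwf = cost[w][sf], dvf = cost[v][sf];
        if (dv < INF && dwf < INF)
          cb(ctrans + dv + dwf, Big::mul(cnt[v][se], cnt[w][sf]), 3, f, 1);
        if (cost[w][se] < INF && dvf < INF)
          cb(ctrans + cost[w][se] + dvf, Big::mul(cnt[w][se], cnt[v][sf]), 3, f, 0);
      }
    }
    // bottom boundary of (e, t)
    if (sbidx[e] == t - 1) {
      // edge ends at its child node e
      if (sc1[e] < 0) { // species leaf (t == 1)
        if (!internal && gsp[u] == e) cb(0.0, Big(1), 0, e, -1);
      } else {
        int f = sc1[e], g = sc2[e];
        int sf = seg[f][t - 1], sg = seg[g][t - 1];
        if (internal) {
          if (cost[v][sf] < INF && cost[w][sg] < INF)
            cb(cost[v][sf] + cost[w][sg], Big::mul(cnt[v][sf], cnt[w][sg]), 1, e, 0);
          if (cost[v][sg] < INF && cost[w][sf] < INF)
            cb(cost[v][sg] + cost[w][sf], Big::mul(cnt[v][sg], cnt[w][sf]), 1, e, 1);
        }
        if (cost[u][sf] < INF) cb(closs + cost[u][sf], cnt[u][sf], 4, f, g);
        if (cost[u][sg] < INF) cb(closs + cost[u][sg], cnt[u][sg], 4, g, f);
      }
    } else if (t > 1) {
      int sd = seg[e][t - 1];
      if (cost[u][sd] < INF) cb(cost[u][sd], cnt[u][sd], 5, -1, -1);
    }
  }

  void run_dp() {
    cost.assign(n_gene, std::vector<double>(n_seg, INF));
    cnt.assign(n_gene, std::vector<Big>(n_seg));
    cntd.assign(n_gene, std::vector<double>(n_seg, 0.0));
    for (int u : gpost) {
      for (int t = 1; t <= m; ++t) {
        for (int e : alive[t]) {
          double best = INF;
          Big c;
          options(u, e, t, [&](double co, Big k, int, int, int) {
            if (co < best - EPS) { best = co; c = k; }
            else if (co < best + EPS) c.add(k);
          });
          int s = seg[e][t];
          cost[u][s] = best;
          cnt[u][s] = c;
          cntd[u][s] = c.to_double();
        }
      }
    }
  }

  // same option enumeration as options(), but with double weights taken
  // from the cached count table -- used only to set sampling probabilities
  template <class F>
  void options_d(int u, int e, int t, F cb) const {
    int v = gc1[u], w = gc2[u];
    bool internal = v >= 0;
    if (internal) {
      int se = seg[e][t];
      double dv = cost[v][se], dw = cost[w][se];
      if (dv < INF && dw < INF)
        cb(cdup + dv + dw, cntd[v][se] * cntd[w][se], 2, -1, -1);
      for (int f : alive[t]) {
        if (f == e) continue;
        int sf = seg[f][t];
        if (dv < INF && cost[w][sf] < INF)
          cb(ctrans + dv + cost[w][sf], cntd[v][se] * cntd[w][sf], 3, f, 1);
        if (dw < INF && cost[v][sf] < INF)
          cb(ctrans + dw + cost[v][sf], cntd[w][se] * cntd[v][sf], 3, f, 0);
      }
    }
    if (sbidx[e] == t - 1) {
      if (sc1[e] < 0) {
        if (!internal && gsp[u] == e) cb(0.0, 1.0, 0, e, -1);
      } else {
        int f = sc1[e], g = sc2[e];
        int sf = seg[f][t - 1], sg = seg[g][t - 1];
        if (internal) {
          if (cost[v][sf] < INF && cost[w][sg] < INF)
            cb(cost[v][sf] + cost[w][sg], cntd[v][sf] * cntd[w][sg], 1, e, 0);
          if (cost[v][sg] < INF && cost[w][sf] < INF)
            cb(cost[v][sg] + cost[w][sf], cntd[v][sg] * cntd[w][sf], 1, e, 1);
        }
        if (cost[u][sf] < INF) cb(closs + cost[u][sf], cntd[u][sf], 4, f, g);
        if (cost[u][sg] < INF) cb(closs + cost[u][sg], cntd[u][sg], 4, g, f);
      }
    } else if (t > 1) {
      int sd = seg[e][t - 1];
      if (cost[u][sd] < INF) cb(cost[u][sd], cntd[u][sd], 5, -1, -1);
    }
  }

  template <class F>
  void root_options_d(int r, F cb) const {
    int v = gc1[r], w = gc2[r];
    bool internal = v >= 0;
    for (int t = 1; t <= m; ++t) {
      for (int e : alive[t]) {
        if (!internal) continue;
        int se = seg[e][t];
        double dv = cost[v][se], dw = cost[w][se];
        if (dv < INF && dw < INF)
          cb(cdup + dv + dw, cntd[v][se] * cntd[w][se], 2, e, t, -1, -1);
        for (int f : alive[t]) {
          if (f == e) continue;
          int sf = seg[f][t];
          if (dv < INF && cost[w][sf] < INF)
            cb(ctrans + dv + cost[w][sf], cntd[v][se] * cntd[w][sf], 3, e, t, f, 1);
          if (dw < INF && cost[v][sf] < INF)
            cb(ctrans + dw + cost[v][sf], cntd[w][se] * cntd[v][sf], 3, e, t, f, 0);
        }
      }
    }
    if (internal) {
      for (int s = 0; s < n_sp; ++s) {
        if (sc1[s] < 0) continue;
        int t = sbidx[s];
        int f = sc1[s], g = sc2[s];
        int sf = seg[f][t], sg = seg[g][t];
        if (cost[v][sf] < INF && cost[w][sg] < INF)
          cb(cost[v][sf] + cost[w][sg], cntd[v][sf] * cntd[w][sg], 1, s, t, -1, 0);
        if (cost[v][sg] < INF && cost[w][sf] < INF)
          cb(cost[v][sg] + cost[w][sf], cntd[v][sg] * cntd[w][sf], 1, s, t, -1, 1);
      }
    }
  }

  // root event options: duplication/transfer in any segment, speciation at
  // any internal species node, leaf if the gene tree is a single leaf.
  template <class F>
  void root_options(int r, F cb) const {
    int v = gc1[r], w = gc2[r];
    bool internal = v >= 0;
    for (int t = 1; t <= m; ++t) {
      for (int e : alive[t]) {
        if (internal) {
          int se = seg[e][t];
          double dv = cost[v][se], dw = cost[w][se];
          if (dv < INF && dw < INF)
            cb(cdup + dv + dw, Big::mul(cnt[v][se], cnt[w][se]), 2, e, t, -1, -1);
          for (int f : alive[t]) {
            if (f == e) continue;
            int sf = seg[f][t];
            if (dv < INF && cost[w][sf] < INF)
              cb(ctrans + dv + cost[w][sf], Big::mul(cnt[v][se], cnt[w][sf]), 3, e, t, f, 1);
            if (dw < INF && cost[v][sf] < INF)
              cb(ctrans + dw + cost[v][sf], Big::mul(cnt[w][se], cnt[v][sf]), 3, e, t, f, 0);
          }
        }
      }
    }
    if (internal) {
      for (int s = 0; s < n_sp; ++s) {
        if (sc1[s] < 0) continue;
        int t = sbidx[s]; // child edges alive in slice t
        int f = sc1[s], g = sc2[s];
        int sf = seg[f][t], sg = seg[g][t];
        if (cost[v][sf] < INF && cost[w][sg] < INF)
          cb(cost[v][sf] + cost[w][sg], Big::mul(cnt[v][sf], cnt[w][sg]), 1, s, t, -1, 0);
        if (cost[v][sg] < INF && cost[w][sf] < INF)
          cb(cost[v][sg] + cost[w][sf], Big::mul(cnt[v][sg], cnt[w][sf]), 1, s, t, -1, 1);
      }
    }
  }
};

// per-sample recording
struct Rec {
  std::vector<int> ev, esp, eslice, edonor, erecip; // per gene node
  std::vector<int> loss_edge, loss_slice;
  std::vector<int> crossings; // per species node (edge = child node)
  double total_cost;
  int n_dup, n_trans, n_loss;
};

struct Sampler {
  const Engine& E;
  Rec* rec;
  Sampler(const Engine& e) : E(e), rec(nullptr) {}

  struct Opt { double co; double wt; int code, a, b; };

  // choose among optimal options with probability proportional to counts
  Opt choose(std::vector<Opt>& opts, double best) const {
    double tot = 0;
    for (auto& o : opts) if (o.co < best + EPS) tot += o.wt;
    double u = unif_rand() * tot, acc = 0;
    for (auto& o : opts) {
      if (o.co >= best + EPS) continue;
      acc += o.wt;
      if (u <= acc) return o;
    }
    for (size_t i = opts.size(); i-- > 0;)
      if (opts[i].co < best + EPS) return opts[i];
    stop("internal: no option to sample");
  }

  void set_event(int u, int code, int sp, int slice, int donor, int recip) {
    rec->ev[u] = code; rec->esp[u] = sp; rec->eslice[u] = slice;
    rec->edonor[u] = donor; rec->erecip[u] = recip;
  }

  // descend state (u enters (e,t))
  void walk(int u, int e, int t) {
    std::vector<Opt> opts;
    double best = INF;
    E.options_d(u, e, t, [&](double co, double wt, int code, int a, int b) {
      if (co < best) best = co;
      opts.push_back({co, wt, code, a, b});
    });
    Opt o = choose(opts, best);
    int v = E.gc1[u], w = E.gc2[u];
    switch (o.code) {
    case 0: // gene leaf
      set_event(u, 0, e, t, -1, -1);
      break;
    case 1: { // speciation at node e (bottom of slice t)
      int f = o.b == 0 ? E.sc1[e] : E.sc2[e];
      int g = o.b == 0 ? E.sc2[e] : E.sc1[e];
      set_event(u, 1, e, t - 1, -1, -1);
      rec->crossings[f]++; rec->crossings[g]++;
      walk(v, f, t - 1);
      walk(w, g, t - 1);
      break;
    }
    case 2: // duplication in (e,t)
      set_event(u, 2, e, t, -1, -1);
      rec->n_dup++;
      walk(v, e, t);
      walk(w, e, t);
      break;
    case 3: { // transfer donor e -> recipient o.a; o.b = which child moves
      set_event(u, 3, e, t, e, o.a);
      rec->n_trans++;
      if (o.b == 1) { walk(v, e, t); walk(w, o.a, t); }
      else { walk(w, e, t); walk(v, o.a, t); }
      break;
    }
    case 4: // pass boundary with a loss on edge o.b
      rec->n_loss++;
      rec->loss_edge.push_back(o.b);
      rec->loss_slice.push_back(t - 1);
      rec->crossings[o.a]++;
      walk(u, o.a, t - 1);
      break;
    case 5: // continue into next slice
      walk(u, e, t - 1);
      break;
    }
  }

  void sample_root(int r) {
    std::vector<Opt> opts;
    std::vector<std::pair<int,int>> extra; // (loc, slice) per option
    double best = INF;
    E.root_options_d(r, [&](double co, double wt, int code, int loc, int t,
                            int a, int b) {
      if (co < best) best = co;
      opts.push_back({co, wt, code, a, b});
      extra.push_back({loc, t});
    });
    double tot = 0;
    for (auto& o : opts) if (o.co < best + EPS) tot += o.wt;
    double u = unif_rand() * tot, acc = 0;
    size_t pick = 0;
    bool found = false;
    for (size_t i = 0; i < opts.size(); ++i) {
      if (opts[i].co >= best + EPS) continue;
      acc += opts[i].wt;
      pick = i;
      if (u <= acc) { found = true; break; }
    }
    (void)found;
    Opt o = opts[pick];
    int loc = extra[pick].first, t = extra[pick].second;
    int v = E.gc1[r], w = E.gc2[r];
    rec->total_cost = best;
    switch (o.code) {
    case 1: { // speciation at species node loc
      int f = o.b == 0 ? E.sc1[loc] : E.sc2[loc];
      int g = o.b == 0 ? E.sc2[loc] : E.sc1[loc];
      set_event(r, 1, loc, t, -1, -1);
      rec->crossings[f]++; rec->crossings[g]++;
      walk(v, f, t);
      walk(w, g, t);
      break;
    }
    case 2:
      set_event(r, 2, loc, t, -1, -1);
      rec->n_dup++;
      walk(v, loc, t);
      walk(w, loc, t);
      break;
    case 3:
      set_event(r, 3, loc, t, loc, o.a);
      rec->n_trans++;
      if (o.b == 1) { walk(v, loc, t); walk(w, o.a, t); }
      else { walk(w, loc, t); walk(v, o.a, t); }
      break;
    }
  }
};

static Engine make_engine(IntegerVector g_child1, IntegerVector g_child2,
                          IntegerVector g_post, IntegerVector g_species,
                          IntegerVector s_child1, IntegerVector s_child2,
                          IntegerVector s_parent, IntegerVector s_bidx,
                          int n_slice, int s_root,
                          double cdup, double ctrans, double closs) {
  Engine E;
  E.gc1 = as<std::vector<int>>(g_child1);
  E.gc2 = as<std::vector<int>>(g_child2);
  E.gpost = as<std::vector<int>>(g_post);
  E.gsp = as<std::vector<int>>(g_species);
  E.n_gene = (int)E.gc1.size();
  E.sc1 = as<std::vector<int>>(s_child1);
  E.sc2 = as<std::vector<int>>(s_child2);
  E.spar = as<std::vector<int>>(s_parent);
  E.sbidx = as<std::vector<int>>(s_bidx);
  E.n_sp = (int)E.sc1.size();
  E.s_root = s_root;
  E.m = n_slice + 1; // + virtual stem slice
  E.cdup = cdup; E.ctrans = ctrans; E.closs = closs;
  E.build_segments();
  E.run_dp();
  return E;
}

// [[Rcpp::export]]
List dtl_solve_cpp(IntegerVector g_child1, IntegerVector g_child2,
                   IntegerVector g_post, IntegerVector g_species,
                   IntegerVector s_child1, IntegerVector s_child2,
                   IntegerVector s_parent, IntegerVector s_bidx,
                   int n_slice, int s_root,
                   double cdup, double ctrans, double closs) {
  Engine E = make_engine(g_child1, g_child2, g_post, g_species,
                         s_child1, s_child2, s_parent, s_bidx,
                         n_slice, s_root, cdup, ctrans, closs);
  int r = E.gpost.back();
  double best = INF;
  Big total;
  E.root_options(r, [&](double co, Big k, int, int, int, int, int) {
    if (co < best - EPS) { best = co; total = k; }
    else if (co < best + EPS) total.add(k);
  });
  if (best >= INF) stop("no feasible reconciliation (check leaf species map)");
  return List::create(_["cost"] = best,
                      _["count"] = total.to_double(),
                      _["count_str"] = total.to_string());
}

// [[Rcpp::export]]
List dtl_sample_cpp(IntegerVector g_child1, IntegerVector g_child2,
                    IntegerVector g_post, IntegerVector g_species,
                    IntegerVector s_child1, IntegerVector s_child2,
                    IntegerVector s_parent, IntegerVector s_bidx,
                    int n_slice, int s_root,
                    double cdup, double ctrans, double closs,
                    int n_sample) {
  Engine E = make_engine(g_child1, g_child2, g_post, g_species,
                         s_child1, s_child2, s_parent, s_bidx,
                         n_slice, s_root, cdup, ctrans, closs);
  int r = E.gpost.back();
  {
    double best = INF;
    bool any = false;
    E.root_options(r, [&](double co, Big, int, int, int, int, int) {
      if (co < best) best = co;
      any = true;
    });
    if (!any || best >= INF) stop("no feasible reconciliation (check leaf species map)");
  }
  List out(n_sample);
  Sampler S(E);
  for (int i = 0; i < n_sample; ++i) {
    Rec rec;
    rec.ev.assign(E.n_gene, -1);
    rec.esp.assign(E.n_gene, -1);
    rec.eslice.assign(E.n_gene, -1);
    rec.edonor.assign(E.n_gene, -1);
    rec.erecip.assign(E.n_gene, -1);
    rec.crossings.assign(E.n_sp, 0);
    rec.total_cost = 0; rec.n_dup = rec.n_trans = rec.n_loss = 0;
    S.rec = &rec;
    S.sample_root(r);
    out[i] = List::create(
      _["event"] = wrap(rec.ev),
      _["species"] = wrap(rec.esp),
      _["slice"] = wrap(rec.eslice),
      _["donor"] = wrap(rec.edonor),
      _["recipient"] = wrap(rec.erecip),
      _["loss_edge"] = wrap(rec.loss_edge),
      _["loss_slice"] = wrap(rec.loss_slice),
      _["crossings"] = wrap(rec.crossings),
      _["cost"] = rec.total_cost,
      _["n_dup"] = rec.n_dup,
      _["n_trans"] = rec.n_trans,
      _["n_loss"] = rec.n_loss);
  }
  return out;
}
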