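// Discrete-generation structured coalescent with recombination, conditioned
// on a forward-simulated favored-allele trajectory (favored and neutral
// allelic classes treated as subdivided populations), plus infinite-sites
// mutation dropping and the EHH outward walk.
//
// Waiting times are generated by inverting per-generation cumulative hazards
// with standard-exponential variates (per-generation hazard increment
// -log(1 - p_event) makes the per-combination waiting time exactly
// geometric); recombination waiting times are continuous exponentials
// rounded to generation steps; the next event is the one with the shortest
// wait, ties broken at random.  Within the trajectory window the hazards
// come from the trajectory's per-generation class sizes and realized migrant
// counts; outside it they come from the demographic model's epoch-constant
// sizes and forward migration rates, skipped analytically epoch by epoch.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Interval { double l, r; };
typedef std::vector<Interval> IvSet;

double iv_len(const IvSet &a) {
  double s = 0; for (const auto &iv : a) s += iv.r - iv.l; return s;
}

bool iv_covers(const IvSet &a, double x) {
  for (const auto &iv : a) {
    if (x < iv.l) return false;
    if (x < iv.r) return true;
  }
  return false;
}

IvSet iv_union(const IvSet &a, const IvSet &b) {
  IvSet out;
  size_t i = 0, j = 0;
  while (i < a.size() || j < b.size()) {
    Interval cur;
    if (j >= b.size() || (i < a.size() && a[i].l <= b[j].l)) cur = a[i++];
    else cur = b[j++];
    while (true) {
      if (i < a.size() && a[i].l <= cur.r) {
        cur.r = std::max(cur.r, a[i].r); ++i;
      } else if (j < b.size() && b[j].l <= cur.r) {
        cur.r = std::max(cur.r, b[j].r); ++j;
      } else break;
    }
    out.push_back(cur);
  }
  return out;
}

IvSet iv_inter(const IvSet &a, const IvSet &b) {
  IvSet out;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    double l = std::max(a[i].l, b[j].l);
    double r = std::min(a[i].r, b[j].r);
    if (l < r) out.push_back({l, r});
    if (a[i].r < b[j].r) ++i; else ++j;
  }
  return out;
}

IvSet iv_diff(const IvSet &a, const IvSet &b) {
  IvSet out;
  size_t j = 0;
  for (const auto &iv : a) {
    double l = iv.l;
    while (j < b.size() && b[j].r <= l) ++j;
    size_t jj = j;
    while (jj < b.size() && b[jj].l < iv.r) {
      if (b[jj].l > l) out.push_back({l, b[jj].l});
      l = std::max(l, b[jj].r);
      ++jj;
    }
    if (l < iv.r) out.push_back({l, iv.r});
  }
  return out;
}

// split a at x into (left, right)
void iv_split(const IvSet &a, double x, IvSet &left, IvSet &right) {
  left.clear(); right.clear();
  for (const auto &iv : a) {
    if (iv.r <= x) left.push_back(iv);
    else if (iv.l >= x) right.push_back(iv);
    else { left.push_back({iv.l, x}); right.push_back({x, iv.r}); }
  }
}

// Piecewise-constant coverage counts over [0, L): number of live lineages
// whose ancestral material covers each position.  Positions whose coverage
// would drop to 1 have reached their MRCA and are stripped.
struct Coverage {
  std::map<double, int> m;
  void init(double L, int n) { m.clear(); m[0.0] = n; m[L] = 0; }
  void split(double x) {
    auto it = m.upper_bound(x);
    if (it == m.begin()) return;
    --it;
    if (it->first == x) return;
    m[x] = it->second;
  }
  // decrement coverage by one over [l, r); return the subintervals whose
  // coverage became 1 (they are set to 0 = no longer ancestral material)
  IvSet decrement(double l, double r) {
    IvSet out;
    split(l); split(r);
    auto it = m.lower_bound(l);
    while (it != m.end() && it->first < r) {
      auto nx = std::next(it);
      it->second -= 1;
      if (it->second == 1) {
        it->second = 0;
        if (!out.empty() && out.back().r == it->first)
          out.back().r = nx->first;
        else
          out.push_back({it->first, nx->first});
      }
      ++it;
    }
    return out;
  }
};

struct Lineage {
  int node;      // output node currently represented by this lineage
  int subpop;    // 0-based
  int cls;       // 0 neutral, 1 favored (selected-site allelic class)
  int last_mig_step; // guard against double migration within one step
  IvSet mat;     // disjoint sorted ancestral intervals
  double span() const { return mat.empty() ? 0.0 : mat.back().r - mat.front().l; }
};

struct Demography {
  int k, n_ep;
  std::vector<double> ep_start, ep_end;   // generations
  NumericMatrix sizes, end_sizes;          // k x n_ep diploid sizes (end NA)
  std::vector<NumericMatrix> mig;          // forward m[i][j] per epoch

  int epoch_of(double g) const {
    for (int e = 0; e < n_ep; ++e)
      if (g >= ep_start[e] && g < ep_end[e]) return e;
    return n_ep - 1;
  }
  bool epoch_constant(int e) const {
    return !R_finite(end_sizes(0, e)) || NumericVector::is_na(end_sizes(0, e));
  }
  // copies (2N) of subpop d at generation g
  double copies(int d, double g) const {
    int e = epoch_of(g);
    if (epoch_constant(e)) return 2.0 * sizes(d, e);
    double frac = (g - ep_start[e]) / (ep_end[e] - ep_start[e]);
    return 2.0 * std::round(std::exp((1 - frac) * std::log(sizes(d, e)) +
                                     frac * std::log(end_sizes(d, e))));
  }
};

struct Trajectory {
  bool present;
  int t_org, k;
  NumericMatrix fav, tot;      // (t_org+1) x k, row g = generation g
  std::vector<double> migf, mign; // k*k*t_org, [i + k*j + k*k*g]
  double f_at(int g, int d) const { return fav(g, d); }
  double n_at(int g, int d) const { return tot(g, d) - fav(g, d); }
  double mig_in(bool favored, int d, int g) const {
    double s = 0;
    const std::vector<double> &a = favored ? migf : mign;
    for (int i = 0; i < k; ++i)
      if (i != d) s += a[i + k * d + (size_t)k * k * g];
    return s;
  }
};

const double EPS_T = 9.5367431640625e-07; // 2^-20 sub-generation offsets

struct Sim {
  double L, selected_pos, rec_rate;
  int k;
  Demography dem;
  Trajectory tr;
  std::vector<Lineage> lin;
  Coverage cov;
  // output
  std::vector<double> node_time;
  std::vector<int> node_subpop;
  std::vector<int> e_par, e_child;
  std::vector<double> e_left, e_right;
  int n_switch = 0;
  double switch_gen = NA_REAL;
  long max_events;
  long n_events = 0;

  // class size in copies of (d, cls) at generation g (parent or child side)
  double class_size(int d, int cls, double g) const {
    if (tr.present && g <= tr.t_org) {
      int gi = (int)g;
      return cls == 1 ? tr.f_at(gi, d) : tr.n_at(gi, d);
    }
    if (cls == 1) return 0.0;      // favored class absent beyond the window
    return dem.copies(d, g);
  }

  double fav_freq(int d, double g) const {
    if (!tr.present || g > tr.t_org) return 0.0;
    int gi = (int)g;
    double t = tr.tot(gi, d);
    return t > 0 ? tr.f_at(gi, d) / t : 0.0;
  }

  // ---- waiting-time scans -------------------------------------------------
  // Next coalescence step for n_pairs pairs in (d, cls), starting at step
  // `cur` (a step st moves generation st -> st+1; the node sits at st+1).
  // k_lin is the current lineage count; within the trajectory window the
  // event is forced no later than the first step whose parent-side class
  // size falls below k_lin.
  double coal_scan(int d, int cls, int k_lin, double cur) const {
    double npairs = 0.5 * k_lin * (k_lin - 1);
    if (npairs <= 0) return R_PosInf;
    double E = R::rexp(1.0), cum = 0.0, st = cur;
    while (true) {
      double g1 = st + 1.0;  // parent generation
      bool in_win = tr.present && g1 <= tr.t_org;
      int e = dem.epoch_of(g1);
      if (in_win || !dem.epoch_constant(e)) {
        double size = class_size(d, cls, g1);
        if (size < 1.0) { st += 1; continue; } // no parents: migration resolves
        if (size < k_lin) return st;           // forced by the trajectory
        cum += npairs * (-std::log1p(-1.0 / size));
        if (cum >= E) return st;
        st += 1;
      } else {
        if (cls == 1) return R_PosInf;
        double size = dem.copies(d, g1);
        if (size <= 1.0) return st;
        double inc = npairs * (-std::log1p(-1.0 / size));
        double avail = R_finite(dem.ep_end[e]) ? dem.ep_end[e] - g1 : R_PosInf;
        double need = std::ceil((E - cum) / inc);
        if (need <= avail) return st + need - 1;
        cum += inc * avail;
        st += avail;
      }
    }
  }

  // Next migration step for k_lin lineages in (d, cls) starting at step cur.
  double mig_scan(int d, int cls, int k_lin, double cur) const {
    if (k_lin <= 0) return R_PosInf;
    double E = R::rexp(1.0), cum = 0.0, st = cur;
    while (true) {
      bool in_win = tr.present && st <= tr.t_org - 1;
      if (in_win) {
        int gi = (int)st;
        double size = class_size(d, cls, st);
        if (size > 0) {
          double mfrac = tr.mig_in(cls == 1, d, gi) / size;
          if (mfrac >= 1.0) return st;                    // forced
          if (mfrac > 0) {
            cum += k_lin * (-std::log1p(-mfrac));
            if (cum >= E) return st;
          }
        }
        st += 1;
      } else {
        if (cls == 1) return R_PosInf;
        int e = dem.epoch_of(st);
        double mfrac = 0;
        for (int i = 0; i < k; ++i) if (i != d) mfrac += dem.mig[e](i, d);
        if (mfrac <= 0) {
          if (!R_finite(dem.ep_end[e])) return R_PosInf;
          st = dem.ep_end[e];
          continue;
        }
        if (mfrac >= 1.0) return st;
        double inc = k_lin * (-std::log1p(-mfrac));
        double avail = R_finite(dem.ep_end[e]) ? dem.ep_end[e] - st : R_PosInf;
        double need = std::ceil((E - cum) / inc);
        if (need <= avail) return st + need - 1;
        cum += inc * avail;
        st += avail;
      }
    }
  }

  // migration destination for a lineage of (d, cls) moving at step st
  int mig_dest(int d, int cls, double st) const {
    std::vector<double> w(k, 0.0);
    bool in_win = tr.present && st <= tr.t_org - 1;
    if (in_win) {
      int gi = (int)st;
      const std::vector<double> &a = cls == 1 ? tr.migf : tr.mign;
      for (int i = 0; i < k; ++i)
        if (i != d) w[i] = a[i + k * d + (size_t)k * k * gi];
    } else {
      int e = dem.epoch_of(st);
      for (int i = 0; i < k; ++i) if (i != d) w[i] = dem.mig[e](i, d);
    }
    double tot = 0; for (double x : w) tot += x;
    if (tot <= 0) return -1;
    double u = R::runif(0, 1) * tot, c = 0;
    for (int i = 0; i < k; ++i) { c += w[i]; if (u <= c) return i; }
    return k - 1;
  }

  // ---- cached per-combination waits ---------------------------------------
  // Waiting times are memoryless given the inhomogeneous hazards, so a drawn
  // absolute event step stays valid until the combination's lineage count
  // (or, for recombination, the ancestral material) changes.
  std::vector<int> cnt;            // lineages per combo = d*2 + cls
  std::vector<double> w_coal, w_mig;
  std::vector<bool> v_coal, v_mig;
  double tot_span = 0, w_rec = 0;
  bool v_rec = false;

  void touch(int d, int c) {
    v_coal[d * 2 + c] = false;
    v_mig[d * 2 + c] = false;
  }
  void span_changed() { v_rec = false; }

  // ---- event execution ----------------------------------------------------
  void do_coalesce(int ia, int ib, double time) {
    Lineage &A = lin[ia], &B = lin[ib];
    tot_span -= A.span() + B.span();
    int pnode = (int)node_time.size();
    node_time.push_back(time);
    node_subpop.push_back(A.subpop);
    for (const auto &iv : A.mat) {
      e_par.push_back(pnode); e_child.push_back(A.node);
      e_left.push_back(iv.l); e_right.push_back(iv.r);
    }
    for (const auto &iv : B.mat) {
      e_par.push_back(pnode); e_child.push_back(B.node);
      e_left.push_back(iv.l); e_right.push_back(iv.r);
    }
    IvSet uni = iv_union(A.mat, B.mat);
    IvSet ovl = iv_inter(A.mat, B.mat);
    IvSet stripped;
    for (const auto &iv : ovl) {
      IvSet s = cov.decrement(iv.l, iv.r);
      for (const auto &x : s) stripped.push_back(x);
    }
    IvSet newmat = stripped.empty() ? uni : iv_diff(uni, stripped);
    Lineage P;
    P.node = pnode; P.subpop = A.subpop; P.cls = A.cls;
    P.last_mig_step = -1;
    P.mat = newmat;
    cnt[P.subpop * 2 + P.cls] -= 1;   // two children -> one parent
    touch(P.subpop, P.cls);
    span_changed();
    // replace A with the parent, swap-remove B (mind index aliasing)
    lin[ia] = P;
    int keep = ia;
    if (ib == (int)lin.size() - 1) {
      lin.pop_back();
    } else if (ia == (int)lin.size() - 1) {
      lin[ib] = lin[ia];
      lin.pop_back();
      keep = ib;
    } else {
      lin[ib] = lin.back();
      lin.pop_back();
    }
    if (lin[keep].mat.empty()) {
      cnt[lin[keep].subpop * 2 + lin[keep].cls] -= 1;
      if (keep != (int)lin.size() - 1) lin[keep] = lin.back();
      lin.pop_back();
    } else {
      tot_span += lin[keep].span();
    }
  }

  // lineage indices of one combination
  std::vector<int> members(int d, int c) const {
    std::vector<int> out;
    for (size_t i = 0; i < lin.size(); ++i)
      if (lin[i].subpop == d && lin[i].cls == c) out.push_back((int)i);
    return out;
  }

  List run(IntegerVector samp_subpop, IntegerVector samp_class) {
    int n = samp_subpop.size();
    lin.clear();
    node_time.assign(n, 0.0);
    node_subpop.assign(n, 0);
    cnt.assign(k * 2, 0);
    w_coal.assign(k * 2, R_PosInf);
    w_mig.assign(k * 2, R_PosInf);
    v_coal.assign(k * 2, false);
    v_mig.assign(k * 2, false);
    for (int i = 0; i < n; ++i) {
      Lineage l;
      l.node = i; l.subpop = samp_subpop[i]; l.cls = samp_class[i];
      l.last_mig_step = -1;
      l.mat.push_back({0.0, L});
      node_subpop[i] = l.subpop;
      lin.push_back(l);
      cnt[l.subpop * 2 + l.cls] += 1;
    }
    cov.init(L, n);
    tot_span = n * L;
    v_rec = false;
    double cur = 0.0;      // current step
    long serial = 0;

    while (!lin.empty()) {
      if (++n_events > max_events)
        stop("coalescent event budget exceeded (%ld events)", max_events);
      int n_fav = cnt[1];
      for (int d = 1; d < k; ++d) n_fav += cnt[d * 2 + 1];
      // structural consistency: lineages of a class whose copy count is zero
      // on both sides of the current step cannot be resolved by any event
      for (int d = 0; d < k; ++d)
        for (int c = 0; c < 2; ++c)
          if (cnt[d * 2 + c] > 0 && class_size(d, c, cur) <= 0 &&
              class_size(d, c, cur + 1.0) <= 0 &&
              !(tr.present && c == 1 && cur >= tr.t_org))
            stop("structural inconsistency: %d lineage(s) of class %d in "
                 "subpop %d at generation %g where the class size is 0",
                 cnt[d * 2 + c], c, d + 1, cur);

      // refresh invalidated waits (absolute event steps stay valid while the
      // combination's lineage count / total material is unchanged)
      for (int d = 0; d < k; ++d)
        for (int c = 0; c < 2; ++c) {
          int b = d * 2 + c;
          if (!v_coal[b]) {
            w_coal[b] = cnt[b] >= 2 ? coal_scan(d, c, cnt[b], cur) : R_PosInf;
            v_coal[b] = true;
          }
          if (!v_mig[b]) {
            w_mig[b] = cnt[b] >= 1 ? mig_scan(d, c, cnt[b], cur) : R_PosInf;
            v_mig[b] = true;
          }
        }
      if (!v_rec) {
        w_rec = R_PosInf;
        if (rec_rate > 0 && tot_span > 0)
          w_rec = cur + std::floor(R::rexp(1.0) / (rec_rate * tot_span));
        v_rec = true;
      }

      // candidate events: (type, step, d, cls); type 0 coal, 1 mig, 2 rec,
      // 3 class switch
      std::vector<std::array<double, 4>> cand;
      for (int d = 0; d < k; ++d)
        for (int c = 0; c < 2; ++c) {
          int b = d * 2 + c;
          if (R_finite(w_coal[b]))
            cand.push_back({0, w_coal[b], (double)d, (double)c});
          if (R_finite(w_mig[b]))
            cand.push_back({1, w_mig[b], (double)d, (double)c});
        }
      if (R_finite(w_rec)) cand.push_back({2, w_rec, 0, 0});
      if (tr.present && n_fav >= 1)
        cand.push_back({3, std::max(cur, (double)tr.t_org), 0, 1});

      if (cand.empty())
        stop("no feasible event for %d remaining lineage(s): disconnected "
             "subpopulations?", (int)lin.size());

      double best = R_PosInf;
      for (const auto &c : cand) best = std::min(best, c[1]);
      std::vector<int> at_min;
      for (size_t i = 0; i < cand.size(); ++i)
        if (cand[i][1] <= best) at_min.push_back((int)i);
      const auto &ev = cand[at_min[(int)(R::runif(0, 1) * at_min.size()) %
                                   at_min.size()]];
      int type = (int)ev[0];
      double st = ev[1];
      int d = (int)ev[2], c = (int)ev[3];
      cur = st;
      double time = st + 1.0 + EPS_T * (double)(++serial);

      if (type == 0) {                       // coalescence: uniform pair
        std::vector<int> bk = members(d, c);
        int kl = (int)bk.size();
        int a = (int)(R::runif(0, 1) * kl) % kl;
        int b = (int)(R::runif(0, 1) * (kl - 1)) % (kl - 1);
        if (b >= a) ++b;
        do_coalesce(bk[a], bk[b], time);
      } else if (type == 1) {                // migration: uniform lineage
        std::vector<int> bk = members(d, c);
        std::vector<int> elig;
        for (int i : bk) if (lin[i].last_mig_step < (int)st) elig.push_back(i);
        if (elig.empty()) elig = bk;
        int i = elig[(int)(R::runif(0, 1) * elig.size()) % elig.size()];
        int dest = mig_dest(d, c, st);
        if (dest >= 0) {
          lin[i].subpop = dest;
          lin[i].last_mig_step = (int)st;
          cnt[d * 2 + c] -= 1;
          cnt[dest * 2 + c] += 1;
          touch(d, c);
          touch(dest, c);
        } else {
          touch(d, c);                       // redraw this combination
        }
      } else if (type == 2) {                // recombination
        double u = R::runif(0, 1) * tot_span, acc = 0;
        int i = -1;
        for (size_t j = 0; j < lin.size(); ++j) {
          acc += lin[j].span();
          if (u <= acc) { i = (int)j; break; }
        }
        if (i < 0) i = (int)lin.size() - 1;
        Lineage &C = lin[i];
        span_changed();
        if (C.span() > 0) {
          double lo = C.mat.front().l, hi = C.mat.back().r;
          double x = lo + R::runif(0, 1) * (hi - lo);
          if (x > lo && x < hi) {
            IvSet left, right;
            iv_split(C.mat, x, left, right);
            if (!left.empty() && !right.empty()) {
              bool carries = iv_covers(C.mat, selected_pos);
              int oldcls = C.cls;
              tot_span -= C.span();
              Lineage P2;
              P2.node = C.node; P2.subpop = C.subpop; P2.cls = C.cls;
              P2.last_mig_step = -1;
              P2.mat = right;
              C.mat = left;
              tot_span += C.span() + P2.span();
              if (carries) {
                // reassign the selected-site class only for the parent that
                // does not inherit the selected site
                bool sel_left = selected_pos < x;
                double f = fav_freq(C.subpop, st + 1.0);
                int newcls = (R::runif(0, 1) < f) ? 1 : 0;
                if (sel_left) P2.cls = newcls; else C.cls = newcls;
              }
              // one child -> two parents
              cnt[C.subpop * 2 + oldcls] -= 1;
              cnt[C.subpop * 2 + C.cls] += 1;
              cnt[P2.subpop * 2 + P2.cls] += 1;
              touch(C.subpop, 0);
              touch(C.subpop, 1);
              lin.push_back(P2);
            }
          }
        }
      } else {                               // class switch at the origin
        std::vector<int> fv;
        for (size_t i = 0; i < lin.size(); ++i)
          if (lin[i].cls == 1) fv.push_back((int)i);
        if ((int)fv.size() > 1)
          stop("class switch with %d favored lineages remaining "
               "(internal error)", (int)fv.size());
        for (int i : fv) {
          cnt[lin[i].subpop * 2 + 1] -= 1;
          cnt[lin[i].subpop * 2 + 0] += 1;
          touch(lin[i].subpop, 0);
          touch(lin[i].subpop, 1);
          lin[i].cls = 0;
        }
        n_switch += 1;
        switch_gen = (double)tr.t_org;
        cur = std::max(cur, (double)tr.t_org);
      }
    }

    return List::create(
      _["node_time"] = NumericVector(node_time.begin(), node_time.end()),
      _["node_subpop"] = IntegerVector(node_subpop.begin(), node_subpop.end()),
      _["edge_parent"] = IntegerVector(e_par.begin(), e_par.end()),
      _["edge_child"] = IntegerVector(e_child.begin(), e_child.end()),
      _["edge_left"] = NumericVector(e_left.begin(), e_left.end()),
      _["edge_right"] = NumericVector(e_right.begin(), e_right.end()),
      _["n_class_switch"] = n_switch,
      _["switch_gen"] = switch_gen,
      _["n_events"] = (double)n_events);
  }
};

} // namespace

// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(double region_length, double selected_pos,
                       double recomb_rate,
                       IntegerVector samp_subpop, IntegerVector samp_class,
                       List demography, List trajectory, double max_events) {
  Sim sim;
  sim.L = region_length;
  sim.selected_pos = selected_pos;
  sim.rec_rate = recomb_rate;
  sim.max_events = (long)max_events;

  Demography &dm = sim.dem;
  dm.ep_start = as<std::vector<double>>(demography["start"]);
  dm.ep_end = as<std::vector<double>>(demography["end"]);
  dm.sizes = as<NumericMatrix>(demography["sizes"]);
  dm.end_sizes = as<NumericMatrix>(demography["end_sizes"]);
  List migl = demography["migration"];
  dm.n_ep = dm.ep_start.size();
  dm.k = dm.sizes.nrow();
  for (int e = 0; e < dm.n_ep; ++e)
    dm.mig.push_back(as<NumericMatrix>(migl[e]));
  sim.k = dm.k;

  Trajectory &tr = sim.tr;
  tr.present = trajectory.size() > 0;
  if (tr.present) {
    tr.t_org = as<int>(trajectory["t_org"]);
    tr.fav = as<NumericMatrix>(trajectory["fav"]);
    tr.tot = as<NumericMatrix>(trajectory["tot"]);
    tr.migf = as<std::vector<double>>(trajectory["migf"]);
    tr.mign = as<std::vector<double>>(trajectory["mign"]);
    tr.k = dm.k;
  }

  RNGScope scope;
  return sim.run(samp_subpop, samp_class);
}

// ---------------------------------------------------------------------------
// Infinite-sites mutation dropping
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".drop_mutations_cpp")]]
List drop_mutations_cpp(int n_samples, NumericVector node_time,
                        IntegerVector edge_parent, IntegerVector edge_child,
                        NumericVector edge_left, NumericVector edge_right,
                        double mu) {
  int n_nodes = node_time.size();
  int n_edges = edge_parent.size();
  // child-edge index per node
  std::vector<std::vector<int>> by_parent(n_nodes);
  for (int e = 0; e < n_edges; ++e) by_parent[edge_parent[e]].push_back(e);

  std::vector<double> pos;
  std::vector<std::vector<int>> carriers;
  RNGScope scope;
  std::vector<int> stack;
  for (int e = 0; e < n_edges; ++e) {
    double len = edge_right[e] - edge_left[e];
    double dur = node_time[edge_parent[e]] - node_time[edge_child[e]];
    if (len <= 0 || dur <= 0) continue;
    int m = (int)R::rpois(mu * len * dur);
    for (int j = 0; j < m; ++j) {
      double x = edge_left[e] + R::runif(0, 1) * len;
      std::vector<int> car;
      stack.clear();
      stack.push_back(edge_child[e]);
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        if (v < n_samples) { car.push_back(v); continue; }
        for (int ce : by_parent[v])
          if (edge_left[ce] <= x && x < edge_right[ce])
            stack.push_back(edge_child[ce]);
      }
      if (!car.empty() && (int)car.size() < n_samples) {
        pos.push_back(x);
        carriers.push_back(car);
      }
    }
  }
  List carl(carriers.size());
  for (size_t i = 0; i < carriers.size(); ++i)
    carl[i] = IntegerVector(carriers[i].begin(), carriers[i].end());
  return List::create(_["positions"] = NumericVector(pos.begin(), pos.end()),
                      _["carriers"] = carl);
}

// ---------------------------------------------------------------------------
// EHH outward walk: expected haplotype homozygosity among a carrier set,
// evaluated on the growing SNP interval away from a focal site.
// ---------------------------------------------------------------------------

namespace {

// one-direction EHH walk; returns (ehh, pos, edge_truncated)
void walk_dir(const IntegerMatrix &X, const NumericVector &positions,
              int focal, const std::vector<int> &carriers, double cutoff,
              int step, std::vector<double> &out_ehh,
              std::vector<double> &out_pos, bool &edge_truncated) {
  int S = X.ncol();
  int nc = (int)carriers.size();
  std::vector<int> grp(nc, 0);
  std::vector<int> remap(2 * nc + 2);
  std::vector<int> cnt(nc + 1);
  out_ehh.clear(); out_pos.clear();
  edge_truncated = true;
  int ngrp = 1;
  for (int j = focal + step; j >= 0 && j < S; j += step) {
    std::fill(remap.begin(), remap.begin() + 2 * ngrp, -1);
    int nn = 0;
    for (int i = 0; i < nc; ++i) {
      int key = grp[i] * 2 + X(carriers[i], j);
      if (remap[key] < 0) remap[key] = nn++;
      grp[i] = remap[key];
    }
    ngrp = nn;
    std::fill(cnt.begin(), cnt.begin() + ngrp, 0);
    for (int i = 0; i < nc; ++i) cnt[grp[i]] += 1;
    double h = 0;
    for (int g = 0; g < ngrp; ++g) {
      double p = (double)cnt[g] / nc;
      h += p * p;
    }
    out_ehh.push_back(h);
    out_pos.push_back(positions[j]);
    if (h < cutoff) { edge_truncated = false; break; }
  }
}

// trapezoid integral of the decay against distance from the focal position,
// interpolated to the cutoff crossing; EHH(0) = 1 by definition
double integrate_walk(const std::vector<double> &ehh,
                      const std::vector<double> &pos, bool edge,
                      double focal_pos, double cutoff) {
  double area = 0, x_prev = 0, e_prev = 1;
  for (size_t i = 0; i < ehh.size(); ++i) {
    double x = std::fabs(pos[i] - focal_pos), e = ehh[i];
    if (!edge && i + 1 == ehh.size()) {
      // final point is below the cutoff: integrate to the crossing
      double xc = x_prev + (e_prev - cutoff) / (e_prev - e) * (x - x_prev);
      area += (xc - x_prev) * (e_prev + cutoff) / 2;
      return area;
    }
    area += (x - x_prev) * (e_prev + e) / 2;
    x_prev = x; e_prev = e;
  }
  return area;
}

} // namespace

// Batched unstandardized iHS over a set of focal sites: for each site and
// each allele, the two-direction EHH walk with trapezoid integration.
// [[Rcpp::export(name = ".ihs_batch_cpp")]]
List ihs_batch_cpp(IntegerMatrix X, NumericVector positions,
                   IntegerVector sites, double cutoff) {
  int n = X.nrow();
  int m = sites.size();
  NumericVector ihh_a(m, NA_REAL), ihh_d(m, NA_REAL), ihs(m, NA_REAL),
    daf(m);
  LogicalVector edge_both(m);
  std::vector<int> car0, car1;
  std::vector<double> we, wp;
  for (int si = 0; si < m; ++si) {
    int j = sites[si];
    car0.clear(); car1.clear();
    for (int i = 0; i < n; ++i)
      (X(i, j) == 1 ? car1 : car0).push_back(i);
    daf[si] = (double)car1.size() / n;
    if (car0.size() < 2 || car1.size() < 2) continue;
    double fp = positions[j];
    bool e_a = false, e_d = false, edge;
    double a_area = 0, d_area = 0;
    for (int dir = -1; dir <= 1; dir += 2) {
      walk_dir(X, positions, j, car0, cutoff, dir, we, wp, edge);
      a_area += integrate_walk(we, wp, edge, fp, cutoff);
      e_a = e_a || edge;
      walk_dir(X, positions, j, car1, cutoff, dir, we, wp, edge);
      d_area += integrate_walk(we, wp, edge, fp, cutoff);
      e_d = e_d || edge;
    }
    ihh_a[si] = a_area; ihh_d[si] = d_area;
    edge_both[si] = e_a && e_d;
    if (a_area > 0 && d_area > 0) ihs[si] = std::log(a_area / d_area);
  }
  return List::create(_["ihh_a"] = ihh_a, _["ihh_d"] = ihh_d,
                      _["ihs_raw"] = ihs, _["daf"] = daf,
                      _["edge_both"] = edge_both);
}

// [[Rcpp::export(name = ".ehh_walk_cpp")]]
List ehh_walk_cpp(IntegerMatrix X, NumericVector positions, int focal,
                  IntegerVector carriers, double cutoff, int direction) {
  int S = X.ncol();
  int nc = carriers.size();
  std::vector<int> grp(nc, 0);
  std::vector<double> out_ehh, out_pos;
  int step = direction >= 0 ? 1 : -1;
  int j = focal + step;
  int ngrp = 1;
  bool edge_truncated = true;
  std::vector<int> remap(2 * nc + 2);
  while (j >= 0 && j < S) {
    // refine carrier partition by the allele at SNP j
    std::fill(remap.begin(), remap.begin() + 2 * ngrp, -1);
    int nn = 0;
    for (int i = 0; i < nc; ++i) {
      int key = grp[i] * 2 + X(carriers[i], j);
      if (remap[key] < 0) remap[key] = nn++;
      grp[i] = remap[key];
    }
    ngrp = nn;
    // expected homozygosity given haplotype frequencies
    std::vector<int> cnt(ngrp, 0);
    for (int i = 0; i < nc; ++i) cnt[grp[i]] += 1;
    double h = 0;
    for (int g = 0; g < ngrp; ++g) {
      double p = (double)cnt[g] / nc;
      h += p * p;
    }
    out_ehh.push_back(h);
    out_pos.push_back(positions[j]);
    if (h < cutoff) { edge_truncated = false; break; }
    j += step;
  }
  return List::create(_["ehh"] = NumericVector(out_ehh.begin(), out_ehh.end()),
                      _["pos"] = NumericVector(out_pos.begin(), out_pos.end()),
                      _["edge_truncated"] = edge_truncated);
}
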