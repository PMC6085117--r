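// Core loop of the branching-annihilating random walk (BARW) duct model.
//
// State is handed over from R as the plain list representation of a
// ductal_network (see R/network.R) together with a parameter list, advanced
// by a number of global update steps, and handed back.  All randomness goes
// through R's RNG so that set.seed() fully determines a run.
//
// Geometry: ducts are polylines whose vertices are deposited every step
// (spacing = step_length), so proximity queries against vertices resolve
// duct shape at the step-length scale, well below the annihilation radius.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct PointStore {
  std::vector<double> x, y;
  std::vector<int> seg;       // segment index (0-based), -1 = central duct
  std::vector<double> pos;    // path position along segment (x for central duct)
};

struct SpatialGrid {
  double cell;
  std::unordered_map<long long, std::vector<int> > bins;

  long long key(double px, double py) const {
    long long ix = (long long)std::floor(px / cell);
    long long iy = (long long)std::floor(py / cell);
    return ix * 2000003LL + iy;
  }
  void insert(double px, double py, int idx) {
    bins[key(px, py)].push_back(idx);
  }
  // collect candidate point indices in the 3x3 cell neighbourhood
  void gather(double px, double py, std::vector<int> &out) const {
    out.clear();
    long long ix = (long long)std::floor(px / cell);
    long long iy = (long long)std::floor(py / cell);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy) {
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
          bins.find((ix + dx) * 2000003LL + (iy + dy));
        if (it != bins.end())
          out.insert(out.end(), it->second.begin(), it->second.end());
      }
  }
};

// path-interval along a segment whose points are ignored in the
// proximity check for one terminus (its own trail / ancestral junctions)
struct ExclInterval {
  int seg;          // -1 = central duct (pos means x-coordinate)
  double lo, hi;
};

struct SimState {
  // parameters
  double step_len, branch_prob, annihil_radius, branch_angle, angle_noise,
    self_excl;
  // central duct
  std::vector<double> cdx, cdy;
  // segments (0-based index == id - 1)
  std::vector<int> parent;    // -1 for roots
  std::vector<int> subtree;
  std::vector<int> gen;
  std::vector<int> child1, child2;  // -1 if none
  std::vector<double> seglen;
  std::vector<std::vector<double> > sx, sy;
  // termini (append-only; state: 0 = terminated, 1 = active, 2 = replaced
  // by daughters at a bifurcation)
  std::vector<double> tx, ty, tdx, tdy;
  std::vector<int> tseg;
  std::vector<int> tstate;

  PointStore pts;
  SpatialGrid grid;

  void add_point(double px, double py, int seg, double pos) {
    pts.x.push_back(px); pts.y.push_back(py);
    pts.seg.push_back(seg); pts.pos.push_back(pos);
    grid.insert(px, py, (int)pts.x.size() - 1);
  }

  int n_active() const {
    int n = 0;
    for (size_t i = 0; i < tstate.size(); ++i) if (tstate[i] == 1) ++n;
    return n;
  }

  int sibling_of(int s) const {
    int p = parent[s];
    if (p < 0) return -1;
    return child1[p] == s ? child2[p] : child1[p];
  }

  // Exclusion intervals for the terminus on segment s: its own trailing
  // path within self_excl, and (walking rootwards while budget remains)
  // the distal end of each ancestor, the proximal start of that ancestor's
  // other child, and finally a window of the central duct around the
  // subtree root.
  void exclusions(int s, std::vector<ExclInterval> &out) const {
    out.clear();
    ExclInterval own; own.seg = s; own.lo = seglen[s] - self_excl; own.hi = 1e300;
    out.push_back(own);
    double rem = self_excl - seglen[s];
    int cur = s;
    while (rem > 0.0) {
      int par = parent[cur];
      if (par < 0) {
        // central duct window around the root junction
        double jx = sx[cur].front();
        ExclInterval cd; cd.seg = -1; cd.lo = jx - rem; cd.hi = jx + rem;
        out.push_back(cd);
        break;
      }
      ExclInterval pa; pa.seg = par; pa.lo = seglen[par] - rem; pa.hi = 1e300;
      out.push_back(pa);
      int sib = sibling_of(cur);
      if (sib >= 0) {
        ExclInterval si; si.seg = sib; si.lo = 0.0; si.hi = rem;
        out.push_back(si);
      }
      rem -= seglen[par];
      cur = par;
    }
  }

  bool collides(double px, double py, const std::vector<ExclInterval> &excl,
                std::vector<int> &cand) const {
    grid.gather(px, py, cand);
    double r2 = annihil_radius * annihil_radius;
    for (size_t c = 0; c < cand.size(); ++c) {
      int q = cand[c];
      double dx = pts.x[q] - px, dy = pts.y[q] - py;
      double d2 = dx * dx + dy * dy;
      if (d2 >= r2) continue;
      bool skip = false;
      for (size_t e = 0; e < excl.size(); ++e) {
        if (pts.seg[q] == excl[e].seg && pts.pos[q] >= excl[e].lo &&
            pts.pos[q] <= excl[e].hi) { skip = true; break; }
      }
      if (!skip) return true;
    }
    return false;
  }

  // one global update: every active terminus, in randomized order
  void step() {
    std::vector<int> order;
    for (size_t i = 0; i < tstate.size(); ++i)
      if (tstate[i] == 1) order.push_back((int)i);
    // Fisher-Yates with R uniforms
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    std::vector<ExclInterval> excl;
    std::vector<int> cand;
    for (size_t o = 0; o < order.size(); ++o) {
      int i = order[o];
      int s = tseg[i];
      // (1) advance along direction rotated by Normal(0, angle_noise)
      double ang = std::atan2(tdy[i], tdx[i]) + norm_rand() * angle_noise;
      double ndx = std::cos(ang), ndy = std::sin(ang);
      double nx = tx[i] + step_len * ndx, ny = ty[i] + step_len * ndy;
      // the duct grows to the new position in every branch below
      sx[s].push_back(nx); sy[s].push_back(ny);
      seglen[s] += step_len;
      add_point(nx, ny, s, seglen[s]);
      tx[i] = nx; ty[i] = ny; tdx[i] = ndx; tdy[i] = ndy;
      // (2) irreversible termination on proximity (checked before branching)
      exclusions(s, excl);
      if (collides(nx, ny, excl, cand)) { tstate[i] = 0; continue; }
      // (3) stochastic bifurcation
      if (unif_rand() < branch_prob) {
        tstate[i] = 2;
        for (int d = 0; d < 2; ++d) {
          double sgn = (d == 0) ? 1.0 : -1.0;
          double ca = ang + sgn * branch_angle;
          double cdx_ = std::cos(ca), cdy_ = std::sin(ca);
          int cs = (int)parent.size();
          parent.push_back(s);
          subtree.push_back(subtree[s]);
          gen.push_back(gen[s] + 1);
          child1.push_back(-1); child2.push_back(-1);
          if (d == 0) child1[s] = cs; else child2[s] = cs;
          std::vector<double> cx(2), cy(2);
          cx[0] = nx; cy[0] = ny;
          cx[1] = nx + step_len * cdx_; cy[1] = ny + step_len * cdy_;
          sx.push_back(cx); sy.push_back(cy);
          seglen.push_back(step_len);
          add_point(cx[1], cy[1], cs, step_len);
          tx.push_back(cx[1]); ty.push_back(cy[1]);
          tdx.push_back(cdx_); tdy.push_back(cdy_);
          tseg.push_back(cs);
          tstate.push_back(1);
        }
      }
      // (4) plain elongation: already done above
    }
  }
};

void parse_state(SimState &st, List net, List par) {
  st.step_len = as<double>(par["step_length"]);
  st.branch_prob = as<double>(par["branch_prob"]);
  st.annihil_radius = as<double>(par["annihilation_radius"]);
  st.branch_angle = as<double>(par["branch_angle"]);
  st.angle_noise = as<double>(par["angle_noise"]);
  st.self_excl = as<double>(par["self_exclusion_length"]);
  st.grid.cell = st.annihil_radius;

  NumericMatrix cd = net["central_duct"];
  for (int i = 0; i < cd.nrow(); ++i) {
    st.cdx.push_back(cd(i, 0)); st.cdy.push_back(cd(i, 1));
    st.add_point(cd(i, 0), cd(i, 1), -1, cd(i, 0));
  }
  List segs = net["segments"];
  int ns = segs.size();
  st.parent.resize(ns); st.subtree.resize(ns); st.gen.resize(ns);
  st.child1.assign(ns, -1); st.child2.assign(ns, -1);
  st.seglen.resize(ns); st.sx.resize(ns); st.sy.resize(ns);
  for (int i = 0; i < ns; ++i) {
    List sg = segs[i];
    int pid = Rf_isNull(sg["parent_id"]) ? -1 : as<int>(sg["parent_id"]) - 1;
    st.parent[i] = pid;
    if (pid >= 0) {
      if (st.child1[pid] < 0) st.child1[pid] = i; else st.child2[pid] = i;
    }
    st.subtree[i] = as<int>(sg["subtree_id"]);
    st.gen[i] = as<int>(sg["generation"]);
    NumericMatrix pl = sg["polyline"];
    double len = 0.0;
    for (int j = 0; j < pl.nrow(); ++j) {
      st.sx[i].push_back(pl(j, 0)); st.sy[i].push_back(pl(j, 1));
      if (j > 0) {
        double dx = pl(j, 0) - pl(j - 1, 0), dy = pl(j, 1) - pl(j - 1, 1);
        len += std::sqrt(dx * dx + dy * dy);
      }
      st.add_point(pl(j, 0), pl(j, 1), i, len);
    }
    st.seglen[i] = len;
  }
  DataFrame tm = as<DataFrame>(net["termini"]);
  NumericVector x = tm["x"], y = tm["y"], dx = tm["dx"], dy = tm["dy"];
  IntegerVector sid = tm["segment_id"];
  LogicalVector act = tm["active"];
  for (int i = 0; i < x.size(); ++i) {
    st.tx.push_back(x[i]); st.ty.push_back(y[i]);
    st.tdx.push_back(dx[i]); st.tdy.push_back(dy[i]);
    st.tseg.push_back(sid[i] - 1);
    st.tstate.push_back(act[i] ? 1 : 0);
  }
}

List export_state(const SimState &st, int steps_done, bool hit_cap) {
  int ncd = (int)st.cdx.size();
  NumericMatrix cd(ncd, 2);
  for (int i = 0; i < ncd; ++i) { cd(i, 0) = st.cdx[i]; cd(i, 1) = st.cdy[i]; }

  int ns = (int)st.parent.size();
  List segs(ns);
  for (int i = 0; i < ns; ++i) {
    int np = (int)st.sx[i].size();
    NumericMatrix pl(np, 2);
    for (int j = 0; j < np; ++j) { pl(j, 0) = st.sx[i][j]; pl(j, 1) = st.sy[i][j]; }
    segs[i] = List::create(
      _["id"] = i + 1,
      _["parent_id"] = st.parent[i] < 0 ? R_NilValue
                                        : (SEXP)IntegerVector::create(st.parent[i] + 1),
      _["subtree_id"] = st.subtree[i],
      _["generation"] = st.gen[i],
      _["polyline"] = pl);
  }
  // termini: keep active and terminated tips; drop tips consumed by a
  // bifurcation (they were replaced by their two daughters)
  std::vector<int> keep;
  for (size_t i = 0; i < st.tstate.size(); ++i)
    if (st.tstate[i] != 2) keep.push_back((int)i);
  int nt = (int)keep.size();
  IntegerVector id(nt), sid(nt);
  NumericVector x(nt), y(nt), dx(nt), dy(nt);
  LogicalVector act(nt);
  for (int j = 0; j < nt; ++j) {
    int i = keep[j];
    id[j] = j + 1; x[j] = st.tx[i]; y[j] = st.ty[i];
    dx[j] = st.tdx[i]; dy[j] = st.tdy[i];
    act[j] = st.tstate[i] == 1;
    sid[j] = st.tseg[i] + 1;
  }
  DataFrame tm = DataFrame::create(
    _["id"] = id, _["x"] = x, _["y"] = y, _["dx"] = dx, _["dy"] = dy,
    _["active"] = act, _["segment_id"] = sid);

  return List::create(
    _["central_duct"] = cd,
    _["segments"] = segs,
    _["termini"] = tm,
    _["steps_done"] = steps_done,
    _["hit_step_cap"] = hit_cap);
}

} // namespace

// [[Rcpp::export(name = ".barw_run")]]
List barw_run(List net, List par, int n_steps, bool record_front) {
  SimState st;
  parse_state(st, net, par);
  NumericVector front;
  IntegerVector n_active_trace;
  int done = 0;
  while (done < n_steps && st.n_active() > 0) {
    st.step();
    ++done;
    if (record_front) {
      // mean distance of active termini from the central duct (y = 0 line
      // by construction; fall back to 0 when none are active)
      double s = 0.0; int n = 0;
      for (size_t i = 0; i < st.tstate.size(); ++i)
        if (st.tstate[i] == 1) { s += std::fabs(st.ty[i]); ++n; }
      front.push_back(n > 0 ? s / n : NA_REAL);
      n_active_trace.push_back(n);
    }
  }
  bool cap = st.n_active() > 0;
  List out = export_state(st, done, cap);
  if (record_front) {
    out["front_radius_trace"] = front;
    out["n_active_trace"] = n_active_trace;
  }
  return out;
}
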