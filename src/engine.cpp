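// Fast lifetime driver for the multisensory learner.
//
// The R level pregenerates every stochastic input (stimulus stream, sensor
// readings, tie-break uniforms), so this engine is a pure deterministic
// function of its arguments.  Its per-cell arithmetic (sufficient-statistic
// updates, the three confidence bounds, residual extraction, the
// generalization test, MOS/LUS selection, UCB1) mirrors the exported R
// functions operation for operation; a testthat block asserts bitwise
// identical trajectories against the R reference stepper.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Table {
  // column-major (obs x action) like an R matrix
  std::vector<double> n, s, s2;
  long rows;
  Table(long rows_, int n_actions) : rows(rows_) {
    n.assign(rows_ * n_actions, 0.0);
    s.assign(rows_ * n_actions, 0.0);
    s2.assign(rows_ * n_actions, 0.0);
  }
};

// lazily filled two-sided Student-t quantile cache, indexed by df
struct QtCache {
  double p;
  std::vector<double> v;
  explicit QtCache(double alpha) : p(1.0 - alpha / 2.0) {}
  double get(long df) {
    if ((long)v.size() <= df) v.resize(df + 1, NA_REAL);
    if (ISNA(v[df])) v[df] = R::qt(p, (double)df, 1, 0);
    return v[df];
  }
};

inline double sample_sd(double n, double s, double s2) {
  double q = s / n;
  double var = (s2 - n * q * q) / (n - 1);
  if (var < 0) var = 0;
  return std::sqrt(var);
}

// interval on the cell mean; bound: 0 student_t, 1 chebyshev, 2 bernstein
inline void ci_bounds(double n, double s, double s2, int bound, double alpha,
                      double rlo, double rhi, QtCache &qt,
                      double &lower, double &upper) {
  if ((bound != 1 && n < 2) || (bound == 1 && n < 1)) {
    lower = -INF; upper = INF; return;
  }
  double q = s / n, hw;
  if (bound == 0) {
    hw = qt.get((long)n - 1) * sample_sd(n, s, s2) / std::sqrt(n);
  } else if (bound == 1) {
    hw = (rhi - rlo) / (2 * std::sqrt(n * alpha));
  } else {
    double lg = std::log(3 / alpha);
    hw = sample_sd(n, s, s2) * std::sqrt(2 * lg / n) + 3 * (rhi - rlo) * lg / n;
  }
  lower = q - hw; upper = q + hw;
}

inline long power_long(long b, int e) {
  long r = 1;
  for (int i = 0; i < e; ++i) r *= b;
  return r;
}

} // namespace

// [[Rcpp::export(".run_engine_cpp")]]
List run_engine_cpp(IntegerVector stimulus, IntegerMatrix obs, NumericVector u,
                    int n_pos, int n_actions, double radius, int shape,
                    int policy, int bound, double alpha, double ucb_c,
                    IntegerVector agent_sensors, bool powerset,
                    double rlo, double rhi, bool return_tables) {
  const int T = stimulus.size();
  const int ka = agent_sensors.size();
  if (ka < 1) stop("engine: agent needs at least one sensor");
  for (int i = 0; i < ka; ++i) {
    if (agent_sensors[i] < 1 || agent_sensors[i] > obs.ncol())
      stop("engine: sensor index out of range");
  }

  const long n_states = power_long(n_pos, ka);
  if (n_states * (long)n_actions > 50000000L)
    stop("engine: joint space too large for a dense table");
  Table joint(n_states, n_actions);
  std::vector<double> state_visits(n_states, 0.0);

  // sources: subsets of the agent's sensor list (0-based slots into
  // agent_sensors), singletons or all non-empty proper subsets, ordered by
  // size then lexicographically — same order as enumerate_sources()
  std::vector< std::vector<int> > sources;
  if (policy != 0 && ka > 1) {  // a lone sensor's space IS the joint space
    if (!powerset) {
      for (int i = 0; i < ka; ++i) sources.push_back(std::vector<int>(1, i));
    } else {
      for (int sz = 1; sz < ka; ++sz) {
        std::vector<int> idx(sz);
        for (int i = 0; i < sz; ++i) idx[i] = i;
        while (true) {
          sources.push_back(idx);
          int i = sz - 1;
          while (i >= 0 && idx[i] == ka - sz + i) --i;
          if (i < 0) break;
          ++idx[i];
          for (int j = i + 1; j < sz; ++j) idx[j] = idx[j - 1] + 1;
        }
      }
    }
  }
  const int n_src = sources.size();
  std::vector<Table> marg;
  marg.reserve(n_src);
  for (int j = 0; j < n_src; ++j)
    marg.push_back(Table(power_long(n_pos, sources[j].size()), n_actions));

  QtCache qt(alpha);

  IntegerVector out_action(T);
  NumericVector out_reward(T);
  IntegerVector out_dominant(T);
  LogicalMatrix out_accept(policy == 0 ? 0 : T, n_src);

  std::vector<double> value(n_actions);
  std::vector<int> dom(n_actions);
  std::vector<int> acc(n_actions * std::max(n_src, 1));
  std::vector<long> proj_idx(std::max(n_src, 1));
  std::vector<int> tied(n_actions);

  for (int t = 0; t < T; ++t) {
    // state index: mixed radix over the agent's sensors, first fastest
    long st = 0;
    for (int i = ka - 1; i >= 0; --i)
      st = st * n_pos + (obs(t, agent_sensors[i] - 1) - 1);

    if (policy == 0) {
      // UCB1 on this agent's own (joint) space
      double N = state_visits[st];
      for (int a = 0; a < n_actions; ++a) {
        double n = joint.n[st + (long)a * n_states];
        if (n == 0) value[a] = INF;
        else value[a] = joint.s[st + (long)a * n_states] / n +
                        std::sqrt(ucb_c * std::log(N) / n);
        dom[a] = 0;
      }
    } else {
      for (int j = 0; j < n_src; ++j) {
        long pidx = 0;
        const std::vector<int> &src = sources[j];
        for (int i = (int)src.size() - 1; i >= 0; --i)
          pidx = pidx * n_pos + (obs(t, agent_sensors[src[i]] - 1) - 1);
        proj_idx[j] = pidx;
      }
      for (int a = 0; a < n_actions; ++a) {
        long jc = st + (long)a * n_states;
        double jn = joint.n[jc], js = joint.s[jc], js2 = joint.s2[jc];
        double Ml, Mu;
        ci_bounds(jn, js, js2, bound, alpha, rlo, rhi, qt, Ml, Mu);

        // generalization test per source, then MOS/LUS selection
        double best_up = -INF, best_len = INF;
        int best_src = -1;  // MOS winner (greatest upper, first max)
        int short_src = -1; // LUS winner among accepted (shortest, first min)
        bool any_acc = false;
        for (int j = 0; j < n_src; ++j) {
          const Table &mt = marg[j];
          long mc = proj_idx[j] + (long)a * mt.rows;
          double rn = mt.n[mc] - jn, rs = mt.s[mc] - js, rs2 = mt.s2[mc] - js2;
          if (rn == 0) { rs = 0; rs2 = 0; }
          double Bl, Bu;
          ci_bounds(rn, rs, rs2, bound, alpha, rlo, rhi, qt, Bl, Bu);
          bool accept = std::max(Bl, Ml) <= std::min(Bu, Mu);
          acc[a * n_src + j] = accept ? 1 : 0;
          if (accept) {
            any_acc = true;
            if (Bu > best_up) { best_up = Bu; best_src = j; }
            double len = Bu - Bl;
            if (len < best_len) { best_len = len; short_src = j; }
          }
        }
        if (policy == 1) { // MOS
          if (!any_acc || best_up > Mu) { value[a] = Mu; dom[a] = 0; }
          else { value[a] = best_up; dom[a] = best_src + 1; }
        } else {           // LUS: joint competes and wins length ties
          double jlen = Mu - Ml;
          if (!any_acc || jlen <= best_len) { value[a] = Mu; dom[a] = 0; }
          else {
            long mc = proj_idx[short_src] + (long)a * marg[short_src].rows;
            double rn = marg[short_src].n[mc] - jn;
            double rs = marg[short_src].s[mc] - js;
            double rs2 = marg[short_src].s2[mc] - js2;
            if (rn == 0) { rs = 0; rs2 = 0; }
            double Bl, Bu;
            ci_bounds(rn, rs, rs2, bound, alpha, rlo, rhi, qt, Bl, Bu);
            if (Bu > Mu) { value[a] = Mu; dom[a] = 0; }
            else { value[a] = Bu; dom[a] = short_src + 1; }
          }
        }
      }
    }

    // argmax with uniform tie-breaking (same formula as choose_action())
    double vmax = value[0];
    for (int a = 1; a < n_actions; ++a) if (value[a] > vmax) vmax = value[a];
    int ntied = 0;
    for (int a = 0; a < n_actions; ++a) if (value[a] == vmax) tied[ntied++] = a;
    int chosen = tied[0];
    if (ntied > 1) {
      double uu = u[t];
      if (uu > 1 - 1e-12) uu = 1 - 1e-12;
      chosen = tied[(int)std::floor(uu * ntied)];
    }

    double d = std::abs((double)(chosen + 1) - (double)stimulus[t]);
    double r;
    if (shape == 0) r = (d <= radius) ? 1.0 : 0.0;
    else r = (d <= radius) ? (radius + 1 - d) / (radius + 1) : 0.0;

    out_action[t] = chosen + 1;
    out_reward[t] = r;
    out_dominant[t] = dom[chosen];
    for (int j = 0; j < n_src; ++j)
      out_accept(t, j) = acc[chosen * n_src + j];

    // learn: joint cell and every marginal cell take the same reward
    long jc = st + (long)chosen * n_states;
    joint.n[jc] += 1; joint.s[jc] += r; joint.s2[jc] += r * r;
    state_visits[st] += 1;
    for (int j = 0; j < n_src; ++j) {
      long mc = proj_idx[j] + (long)chosen * marg[j].rows;
      marg[j].n[mc] += 1; marg[j].s[mc] += r; marg[j].s2[mc] += r * r;
    }
  }

  List out = List::create(_["action"] = out_action,
                          _["reward"] = out_reward,
                          _["dominant"] = out_dominant,
                          _["accept"] = out_accept);
  if (return_tables) {
    NumericMatrix jn(n_states, n_actions), js(n_states, n_actions),
        js2(n_states, n_actions);
    std::copy(joint.n.begin(), joint.n.end(), jn.begin());
    std::copy(joint.s.begin(), joint.s.end(), js.begin());
    std::copy(joint.s2.begin(), joint.s2.end(), js2.begin());
    List ml(n_src);
    for (int j = 0; j < n_src; ++j) {
      NumericMatrix mn(marg[j].rows, n_actions), ms(marg[j].rows, n_actions),
          ms2(marg[j].rows, n_actions);
      std::copy(marg[j].n.begin(), marg[j].n.end(), mn.begin());
      std::copy(marg[j].s.begin(), marg[j].s.end(), ms.begin());
      std::copy(marg[j].s2.begin(), marg[j].s2.end(), ms2.begin());
      ml[j] = List::create(_["n"] = mn, _["s"] = ms, _["s2"] = ms2);
    }
    out["tables"] = List::create(_["joint"] = List::create(
                                     _["n"] = jn, _["s"] = js, _["s2"] = js2),
                                 _["marg"] = ml);
  }
  return out;
}
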