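// Stochastic engines: exact Gillespie simulation of the aggregate-count
// CTMC on the complete graph, and the discrete asynchronous contact
// scheme on arbitrary networks.  Both draw from R's RNG so that
// set.seed() in R gives bit-reproducible runs.

#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven simulation of the counts chain
//   (X, Y) -> (X-1, Y+1) at rate lambda * X * Y   (spreading)
//   (X, Y) -> (X,   Y-1) at rate alpha  * Y * Z   (scotching), Z = n - X - Y
// Terminates when the total rate is zero (Y = 0, or X = Z = 0 with
// standing spreaders when alpha = 0).
// [[Rcpp::export]]
List gillespie_complete_cpp(double lambda, double alpha,
                            int X0, int Y0, int Z0,
                            bool record) {
  double X = X0, Y = Y0, Z = Z0;
  double t = 0.0;
  std::vector<double> ts;
  std::vector<int> xs, ys, zs;
  if (record) {
    ts.push_back(0.0);
    xs.push_back(X0); ys.push_back(Y0); zs.push_back(Z0);
  }
  for (;;) {
    double r_spread = lambda * X * Y;
    double r_scotch = alpha * Y * Z;
    double R = r_spread + r_scotch;
    if (R <= 0.0) break;
    t += R::exp_rand() / R;
    if (R::unif_rand() * R < r_spread) {
      X -= 1.0; Y += 1.0;
    } else {
      Y -= 1.0; Z += 1.0;
    }
    if (record) {
      ts.push_back(t);
      xs.push_back((int)X); ys.push_back((int)Y); zs.push_back((int)Z);
    }
  }
  List out = List::create(
    _["X"] = (int)X, _["Y"] = (int)Y, _["Z"] = (int)Z,
    _["time"] = t, _["absorbed"] = (Y == 0.0));
  if (record) {
    out["traj_t"] = ts;
    out["traj_X"] = xs; out["traj_Y"] = ys; out["traj_Z"] = zs;
  }
  return out;
}

// Discrete asynchronous contact scheme.  Per step: snapshot the nodes
// that are spreaders or stiflers at step start, visit them in a fresh
// uniform shuffle; each visited node acts according to its CURRENT state
// (which may have changed earlier in the same step), picks one neighbour
// uniformly, and a spreader converts an ignorant neighbour with
// probability lambda while a stifler converts a spreader neighbour with
// probability alpha.  State changes apply immediately.  When
// complete_graph is true the neighbour is drawn uniformly from the other
// n - 1 nodes and the adjacency arrays are ignored.
// [[Rcpp::export]]
List run_network_mc_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                        IntegerVector states0, double lambda, double alpha,
                        int max_steps, bool record, bool complete_graph) {
  int n = states0.size();
  std::vector<int> state(states0.begin(), states0.end());
  std::vector<int> active;
  active.reserve(n);
  std::vector<int> traj_X, traj_Y, traj_Z;

  int Y = 0, X = 0;
  for (int i = 0; i < n; ++i) {
    if (state[i] == 0) ++X;
    else if (state[i] == 1) ++Y;
  }
  if (record) {
    traj_X.push_back(X); traj_Y.push_back(Y);
    traj_Z.push_back(n - X - Y);
  }

  int step = 0;
  while (Y > 0 && step < max_steps) {
    ++step;
    active.clear();
    for (int i = 0; i < n; ++i) {
      if (state[i] != 0) active.push_back(i);
    }
    // Fisher-Yates shuffle of the step-start snapshot
    for (int i = (int)active.size() - 1; i > 0; --i) {
      int j = (int)(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(active[i], active[j]);
    }
    for (size_t a = 0; a < active.size(); ++a) {
      int node = active[a];
      int s = state[node];
      int nb;
      if (complete_graph) {
        nb = (int)(R::unif_rand() * (n - 1));
        if (nb >= n - 1) nb = n - 2;
        if (nb >= node) ++nb;
      } else {
        int deg = adj_ptr[node + 1] - adj_ptr[node];
        if (deg == 0) continue;
        int k = (int)(R::unif_rand() * deg);
        if (k >= deg) k = deg - 1;
        nb = adj_idx[adj_ptr[node] + k];
      }
      if (s == 1) {
        if (state[nb] == 0 && R::unif_rand() < lambda) {
          state[nb] = 1; --X; ++Y;
        }
      } else if (s == 2) {
        if (state[nb] == 1 && R::unif_rand() < alpha) {
          state[nb] = 2; --Y;
        }
      }
    }
    if (record) {
      traj_X.push_back(X); traj_Y.push_back(Y);
      traj_Z.push_back(n - X - Y);
    }
  }

  List out = List::create(
    _["X"] = X, _["Y"] = Y, _["Z"] = n - X - Y,
    _["steps"] = step, _["absorbed"] = (Y == 0),
    _["final_states"] = IntegerVector(state.begin(), state.end()));
  if (record) {
    out["traj_X"] = traj_X; out["traj_Y"] = traj_Y; out["traj_Z"] = traj_Z;
  }
  return out;
}
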