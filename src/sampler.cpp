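// Overdamped Langevin sampler and path-collective-variable kernels.
//
// Potentials are identified by small integer ids so the integrator never
// calls back into R; custom R-level potentials use the (slower) pure-R
// integrator instead.  All random numbers come from R's RNG, so a single
// set.seed() on the R side makes trajectories bit-reproducible.
//
// potential ids:
//   0 flat            params: (none)
//   1 harmonic        params: k            U = k/2 |x|^2
//   2 two-basin       params: h, off, kp   U = h (x1^2-1)^2
//                          + off/2 (1 + tanh 4 x1) + kp/2 sum_{j>1} xj^2
//   3 Mueller-Brown   params: scale        standard 4-Gaussian surface
//   4 three-hole      params: scale        two deep holes + shallow channel
//
// bias ids:
//   0 none
//   1 harmonic restraint on PCV-s:     k/2 (s(x) - center)^2, plus an
//     optional half-harmonic tube wall k_z/2 (z - z_max)^2 for z > z_max
//   2 moving distance-to-target (tMD): k/2 (|x - target| - d0(t))^2,
//     d0(t) shrinking linearly from d0_start to 0 over schedule_steps
//   3 harmonic umbrella on coordinate component `bias_dim` (0-based)

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double MB_A[4]  = {-200.0, -100.0, -170.0, 15.0};
static const double MB_a[4]  = {-1.0, -1.0, -6.5, 0.7};
static const double MB_b[4]  = {0.0, 0.0, 11.0, 0.6};
static const double MB_c[4]  = {-10.0, -10.0, -6.5, 0.7};
static const double MB_x0[4] = {1.0, 0.0, -0.5, -1.0};
static const double MB_y0[4] = {0.0, 0.5, 1.5, 1.0};

static double pot_energy(int id, const double* p, const double* x, int d) {
    switch (id) {
    case 0:
        return 0.0;
    case 1: {
        double e = 0.0;
        for (int j = 0; j < d; ++j) e += 0.5 * p[0] * x[j] * x[j];
        return e;
    }
    case 2: {
        // offset enters through a tanh step that is flat at both wells,
        // so the configured offset IS the well free-energy difference
        // (equal curvatures, equal anharmonic corrections)
        double t = x[0] * x[0] - 1.0;
        double e = p[0] * t * t + 0.5 * p[1] * (1.0 + std::tanh(4.0 * x[0]));
        for (int j = 1; j < d; ++j) e += 0.5 * p[2] * x[j] * x[j];
        return e;
    }
    case 3: {
        double e = 0.0;
        for (int t = 0; t < 4; ++t) {
            double dx = x[0] - MB_x0[t], dy = x[1] - MB_y0[t];
            e += MB_A[t] * std::exp(MB_a[t] * dx * dx + MB_b[t] * dx * dy +
                                    MB_c[t] * dy * dy);
        }
        return p[0] * e;
    }
    case 4: {
        double X = x[0], Y = x[1];
        double e = 3.0 * std::exp(-X * X - (Y - 1.0 / 3.0) * (Y - 1.0 / 3.0))
                 - 3.0 * std::exp(-X * X - (Y - 5.0 / 3.0) * (Y - 5.0 / 3.0))
                 - 5.0 * std::exp(-(X - 1.0) * (X - 1.0) - Y * Y)
                 - 5.0 * std::exp(-(X + 1.0) * (X + 1.0) - Y * Y)
                 + 0.2 * std::pow(X, 4)
                 + 0.2 * std::pow(Y - 1.0 / 3.0, 4);
        return p[0] * e;
    }
    default:
        return NA_REAL;
    }
}

static void pot_grad(int id, const double* p, const double* x, int d, double* g) {
    for (int j = 0; j < d; ++j) g[j] = 0.0;
    switch (id) {
    case 0:
        break;
    case 1:
        for (int j = 0; j < d; ++j) g[j] = p[0] * x[j];
        break;
    case 2: {
        double sech = 1.0 / std::cosh(4.0 * x[0]);
        g[0] = 4.0 * p[0] * x[0] * (x[0] * x[0] - 1.0) +
               2.0 * p[1] * sech * sech;
        for (int j = 1; j < d; ++j) g[j] = p[2] * x[j];
        break;
    }
    case 3: {
        for (int t = 0; t < 4; ++t) {
            double dx = x[0] - MB_x0[t], dy = x[1] - MB_y0[t];
            double e = MB_A[t] * std::exp(MB_a[t] * dx * dx + MB_b[t] * dx * dy +
                                          MB_c[t] * dy * dy);
            g[0] += e * (2.0 * MB_a[t] * dx + MB_b[t] * dy);
            g[1] += e * (MB_b[t] * dx + 2.0 * MB_c[t] * dy);
        }
        g[0] *= p[0];
        g[1] *= p[0];
        break;
    }
    case 4: {
        double X = x[0], Y = x[1];
        double e1 = 3.0 * std::exp(-X * X - (Y - 1.0 / 3.0) * (Y - 1.0 / 3.0));
        double e2 = -3.0 * std::exp(-X * X - (Y - 5.0 / 3.0) * (Y - 5.0 / 3.0));
        double e3 = -5.0 * std::exp(-(X - 1.0) * (X - 1.0) - Y * Y);
        double e4 = -5.0 * std::exp(-(X + 1.0) * (X + 1.0) - Y * Y);
        g[0] = e1 * (-2.0 * X) + e2 * (-2.0 * X) + e3 * (-2.0 * (X - 1.0)) +
               e4 * (-2.0 * (X + 1.0)) + 0.8 * std::pow(X, 3);
        g[1] = e1 * (-2.0 * (Y - 1.0 / 3.0)) + e2 * (-2.0 * (Y - 5.0 / 3.0)) +
               e3 * (-2.0 * Y) + e4 * (-2.0 * Y) +
               0.8 * std::pow(Y - 1.0 / 3.0, 3);
        g[0] *= p[0];
        g[1] *= p[0];
        break;
    }
    default:
        break;
    }
}

// (s, z) of point x with respect to nodes (N x d), stabilised by
// subtracting the smallest exponent before exponentiation.
static void pcv_sz(const NumericMatrix& nodes, double lambda, const double* x,
                   double* s_out, double* z_out,
                   std::vector<double>& w, std::vector<double>& d2) {
    const int N = nodes.nrow(), d = nodes.ncol();
    double emin = R_PosInf;
    for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (int j = 0; j < d; ++j) {
            double diff = x[j] - nodes(i, j);
            acc += diff * diff;
        }
        d2[i] = acc;
        double e = lambda * acc;
        if (e < emin) emin = e;
    }
    double W = 0.0, S = 0.0;
    for (int i = 0; i < N; ++i) {
        w[i] = std::exp(-(lambda * d2[i] - emin));
        W += w[i];
        S += (i + 1) * w[i];
    }
    *s_out = S / W;
    *z_out = (emin - std::log(W)) / lambda;
}

// d s / d x_j = (2 lambda / W) sum_i (i - s) w_i (node_ij - x_j)
static void pcv_s_grad(const NumericMatrix& nodes, double lambda, const double* x,
                       double s, const std::vector<double>& w, double* g) {
    const int N = nodes.nrow(), d = nodes.ncol();
    double W = 0.0;
    for (int i = 0; i < N; ++i) W += w[i];
    for (int j = 0; j < d; ++j) g[j] = 0.0;
    for (int i = 0; i < N; ++i) {
        double c = (i + 1 - s) * w[i];
        for (int j = 0; j < d; ++j) g[j] += c * (nodes(i, j) - x[j]);
    }
    double f = 2.0 * lambda / W;
    for (int j = 0; j < d; ++j) g[j] *= f;
}

// d z / d x_j = (2 / W) sum_i w_i (x_j - node_ij)
static void pcv_z_grad(const NumericMatrix& nodes, const double* x,
                       const std::vector<double>& w, double* g) {
    const int N = nodes.nrow(), d = nodes.ncol();
    double W = 0.0;
    for (int i = 0; i < N; ++i) W += w[i];
    for (int j = 0; j < d; ++j) g[j] = 0.0;
    for (int i = 0; i < N; ++i)
        for (int j = 0; j < d; ++j) g[j] += w[i] * (x[j] - nodes(i, j));
    for (int j = 0; j < d; ++j) g[j] *= 2.0 / W;
}

// [[Rcpp::export]]
List potential_eval_cpp(int id, NumericVector params, NumericMatrix X) {
    const int n = X.nrow(), d = X.ncol();
    NumericVector E(n);
    NumericMatrix G(n, d);
    std::vector<double> x(d), g(d);
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < d; ++j) x[j] = X(i, j);
        E[i] = pot_energy(id, params.begin(), x.data(), d);
        pot_grad(id, params.begin(), x.data(), d, g.data());
        for (int j = 0; j < d; ++j) G(i, j) = g[j];
    }
    return List::create(_["energy"] = E, _["gradient"] = G);
}

// [[Rcpp::export]]
NumericMatrix pcv_project_cpp(NumericMatrix nodes, double lambda, NumericMatrix X) {
    const int n = X.nrow(), d = X.ncol();
    NumericMatrix out(n, 2);
    std::vector<double> w(nodes.nrow()), d2(nodes.nrow()), x(d);
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < d; ++j) x[j] = X(i, j);
        double s, z;
        pcv_sz(nodes, lambda, x.data(), &s, &z, w, d2);
        out(i, 0) = s;
        out(i, 1) = z;
    }
    return out;
}

// [[Rcpp::export]]
NumericMatrix pcv_s_grad_cpp(NumericMatrix nodes, double lambda, NumericMatrix X) {
    const int n = X.nrow(), d = X.ncol();
    NumericMatrix out(n, d);
    std::vector<double> w(nodes.nrow()), d2(nodes.nrow()), x(d), g(d);
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < d; ++j) x[j] = X(i, j);
        double s, z;
        pcv_sz(nodes, lambda, x.data(), &s, &z, w, d2);
        pcv_s_grad(nodes, lambda, x.data(), s, w, g.data());
        for (int j = 0; j < d; ++j) out(i, j) = g[j];
    }
    return out;
}

// Greedy density-peak selection with suppression, O(n) memory.
// Matches the reference R semantics exactly: neighbour counts include
// the sample itself, ties go to the lowest index, counts are taken over
// the still-alive samples, and picking stops at n_target, exhaustion,
// or when the best remaining count falls below min_count_frac times the
// first pick's count.
// [[Rcpp::export]]
IntegerVector select_candidates_cpp(NumericMatrix X, int n_target,
                                    double radius, double min_count_frac) {
    const int n = X.nrow(), d = X.ncol();
    const double r2 = radius * radius;
    std::vector<char> alive(n, 1);
    std::vector<int> counts(n, 0);
    auto d2 = [&](int i, int j) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
            double diff = X(i, k) - X(j, k);
            s += diff * diff;
        }
        return s;
    };
    for (int i = 0; i < n; ++i) counts[i] = 1;   // self
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
            if (d2(i, j) <= r2) {
                ++counts[i];
                ++counts[j];
            }
    std::vector<int> picks;
    double floor_count = -1.0;
    while ((int)picks.size() < n_target) {
        int best = -1, best_count = -1;
        for (int i = 0; i < n; ++i)
            if (alive[i] && counts[i] > best_count) {
                best = i;
                best_count = counts[i];
            }
        if (best < 0) break;
        if (floor_count >= 0 && best_count < floor_count) break;
        if (floor_count < 0) floor_count = min_count_frac * best_count;
        picks.push_back(best + 1);
        // suppress the pick's neighbourhood, updating counts incrementally
        for (int j = 0; j < n; ++j) {
            if (!alive[j] || d2(best, j) > r2) continue;
            alive[j] = 0;
            for (int i = 0; i < n; ++i)
                if (alive[i] && d2(i, j) <= r2) --counts[i];
        }
    }
    return wrap(picks);
}

// Integrate the normalized steepest-descent flow x' = -grad U / |grad U|
// with RK4 at fixed arclength step ds, from x0 until within snap_tol of
// one of the supplied minima (rows of `minima`).  Returns the dense
// polyline and the index of the minimum reached (0 if none).
// [[Rcpp::export]]
List flowline_descent_cpp(int pot_id, NumericVector pot_params,
                          NumericVector x0, double ds, int max_steps,
                          NumericMatrix minima, double snap_tol) {
    const int d = x0.size();
    std::vector<double> x(x0.begin(), x0.end()), g(d);
    std::vector<double> k1(d), k2(d), k3(d), k4(d), tmp(d);
    NumericMatrix pts(max_steps, d);
    int reached = 0, n = 0;
    auto dir = [&](const std::vector<double>& p, std::vector<double>& out) {
        pot_grad(pot_id, pot_params.begin(), p.data(), d, g.data());
        double nrm = 0.0;
        for (int j = 0; j < d; ++j) nrm += g[j] * g[j];
        nrm = std::sqrt(nrm);
        if (nrm < 1e-14) nrm = 1e-14;
        for (int j = 0; j < d; ++j) out[j] = -g[j] / nrm;
    };
    for (int t = 0; t < max_steps; ++t) {
        for (int j = 0; j < d; ++j) pts(t, j) = x[j];
        n = t + 1;
        for (int m = 0; m < minima.nrow(); ++m) {
            double dist = 0.0;
            for (int j = 0; j < d; ++j) {
                double diff = x[j] - minima(m, j);
                dist += diff * diff;
            }
            if (std::sqrt(dist) < snap_tol) {
                reached = m + 1;
                break;
            }
        }
        if (reached) break;
        dir(x, k1);
        for (int j = 0; j < d; ++j) tmp[j] = x[j] + 0.5 * ds * k1[j];
        dir(tmp, k2);
        for (int j = 0; j < d; ++j) tmp[j] = x[j] + 0.5 * ds * k2[j];
        dir(tmp, k3);
        for (int j = 0; j < d; ++j) tmp[j] = x[j] + ds * k3[j];
        dir(tmp, k4);
        for (int j = 0; j < d; ++j)
            x[j] += ds / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    }
    return List::create(_["points"] = pts, _["n"] = n,
                        _["reached"] = reached);
}

// [[Rcpp::export]]
List simulate_cpp(int pot_id, NumericVector pot_params, NumericVector x0,
                  double beta, double diffusion, double dt,
                  int n_steps, int record_every,
                  int bias_id, NumericMatrix nodes, double lambda,
                  double bias_k, double bias_center, int bias_dim,
                  NumericVector target, double d0_start, int schedule_steps,
                  double k_z, double z_max) {
    const int d = x0.size();
    const int n_rec = n_steps / record_every + 1;
    const bool rec_cv = nodes.nrow() > 0;
    NumericMatrix frames(n_rec, d);
    NumericMatrix cv(rec_cv ? n_rec : 0, 2);

    std::vector<double> x(x0.begin(), x0.end()), g(d), bg(d);
    std::vector<double> w(nodes.nrow()), d2(nodes.nrow());
    const double mob = diffusion * beta * dt;
    const double noise = std::sqrt(2.0 * diffusion * dt);

    int rec_i = 0, err_step = -1;
    for (int j = 0; j < d; ++j) frames(0, j) = x[j];
    if (rec_cv) {
        double s, z;
        pcv_sz(nodes, lambda, x.data(), &s, &z, w, d2);
        cv(0, 0) = s;
        cv(0, 1) = z;
    }
    rec_i = 1;

    for (int t = 1; t <= n_steps; ++t) {
        pot_grad(pot_id, pot_params.begin(), x.data(), d, g.data());
        if (bias_id == 1) {
            double s, z;
            pcv_sz(nodes, lambda, x.data(), &s, &z, w, d2);
            pcv_s_grad(nodes, lambda, x.data(), s, w, bg.data());
            double c = bias_k * (s - bias_center);
            for (int j = 0; j < d; ++j) g[j] += c * bg[j];
            if (k_z > 0.0 && z > z_max) {
                // half-harmonic tube wall keeping samples near the path
                pcv_z_grad(nodes, x.data(), w, bg.data());
                double cz = k_z * (z - z_max);
                for (int j = 0; j < d; ++j) g[j] += cz * bg[j];
            }
        } else if (bias_id == 2) {
            double dist = 0.0;
            for (int j = 0; j < d; ++j) {
                double diff = x[j] - target[j];
                dist += diff * diff;
            }
            dist = std::sqrt(dist);
            double frac = schedule_steps > 0 ?
                std::min(1.0, (double)t / schedule_steps) : 1.0;
            double d0 = d0_start * (1.0 - frac);
            if (dist > 1e-12) {
                double c = bias_k * (dist - d0) / dist;
                for (int j = 0; j < d; ++j) g[j] += c * (x[j] - target[j]);
            }
        } else if (bias_id == 3) {
            g[bias_dim] += bias_k * (x[bias_dim] - bias_center);
        }

        bool bad = false;
        for (int j = 0; j < d; ++j) {
            x[j] += -mob * g[j] + noise * norm_rand();
            if (!std::isfinite(x[j])) bad = true;
        }
        if (bad) {
            err_step = t;
            break;
        }
        if (t % record_every == 0) {
            for (int j = 0; j < d; ++j) frames(rec_i, j) = x[j];
            if (rec_cv) {
                double s, z;
                pcv_sz(nodes, lambda, x.data(), &s, &z, w, d2);
                cv(rec_i, 0) = s;
                cv(rec_i, 1) = z;
            }
            ++rec_i;
        }
    }

    return List::create(_["frames"] = frames, _["cv"] = cv,
                        _["n_recorded"] = rec_i, _["err_step"] = err_step);
}
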