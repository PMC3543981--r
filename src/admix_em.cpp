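#include <RcppArmadillo.h>

using namespace arma;

// Binomial admixture likelihood
//   L = sum_{i,j observed} g_ij log p_ij + (2 - g_ij) log(1 - p_ij),
//   p_ij = sum_k q_ik f_kj.
//
// Two entry points:
//   * admix_em_cpp        — general plain-EM loop with an arbitrary fixed
//                           row set and a per-iteration likelihood trace
//                           (used for single block updates and invariant
//                           checks at small scale);
//   * admix_fit_cpp       — production fitting loop. Supervised reference
//                           individuals, whose proportion rows are fixed
//                           indicator vectors, enter the F update and the
//                           likelihood only through their per-population
//                           allele counts (ALT, TOT), which is exact and
//                           removes them from the per-iteration work.
//                           Optional SQUAREM-style acceleration of the EM
//                           map with a monotonicity safeguard: an
//                           extrapolated step is kept only if it improves
//                           the likelihood, otherwise the plain double EM
//                           step is used, so the likelihood never
//                           decreases.
//
// Missing genotypes are NaN on input and contribute nothing anywhere; the
// per-individual normalizer counts observed markers only.

static double loglik_obs(const mat& M, const mat& G0, const mat& P) {
  return accu(M % (G0 % log(P) + (2.0 - G0) % log(1.0 - P)));
}

// [[Rcpp::export]]
Rcpp::List admix_em_cpp(const arma::mat& G,
                        arma::mat Q,
                        arma::mat F,
                        const arma::uvec& free_rows,
                        const bool update_F,
                        const double tol,
                        const int max_iter,
                        const double eps) {
  const uword n = G.n_rows;
  const uword J = G.n_cols;
  if (Q.n_rows != n || F.n_cols != J || Q.n_cols != F.n_rows)
    Rcpp::stop("dimension mismatch between G, Q and F");

  mat M(n, J, fill::ones);
  mat G0 = G;
  uvec miss = find_nonfinite(G);
  if (miss.n_elem > 0) {
    M.elem(miss).zeros();
    G0.elem(miss).zeros();
  }
  vec Jobs = sum(M, 1);

  std::vector<double> trace;
  mat P = clamp(Q * F, eps, 1.0 - eps);
  double ll = loglik_obs(M, G0, P);
  trace.push_back(ll);

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    mat R1 = (M % G0) / P;
    mat R2 = (M % (2.0 - G0)) / (1.0 - P);
    mat S = R1 * F.t() + R2 * (1.0 - F).t();
    mat Qnew = Q % S;
    if (update_F) {
      mat A = F % (Q.t() * R1);
      mat B = (1.0 - F) % (Q.t() * R2);
      mat Fnew = A / (A + B);
      uvec bad = find_nonfinite(Fnew);
      if (bad.n_elem > 0) Fnew.elem(bad) = F.elem(bad);
      F = clamp(Fnew, eps, 1.0 - eps);
    }
    for (uword r = 0; r < free_rows.n_elem; ++r) {
      const uword i = free_rows(r);
      if (Jobs(i) <= 0) continue;
      rowvec q = Qnew.row(i) / (2.0 * Jobs(i));
      const double s = accu(q);
      if (s > 0) Q.row(i) = q / s;
    }
    P = clamp(Q * F, eps, 1.0 - eps);
    const double ll_new = loglik_obs(M, G0, P);
    trace.push_back(ll_new);
    if (std::abs(ll_new - ll) < tol) {
      ll = ll_new;
      converged = true;
      break;
    }
    ll = ll_new;
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(Rcpp::Named("Q") = Q,
                            Rcpp::Named("F") = F,
                            Rcpp::Named("loglik") = ll,
                            Rcpp::Named("trace") = trace,
                            Rcpp::Named("n_iter") = iter,
                            Rcpp::Named("converged") = converged);
}

// ---------------------------------------------------------------------------

struct FitData {
  mat M, G0;        // target mask / zero-filled genotypes
  vec Jobs;         // observed markers per target
  mat ALT, TOTmALT; // reference alt counts and (total - alt)
  bool has_ref;
  bool update_F;
  double eps;
};

// Likelihood of (Q, F): target block + reference count block.
static double fit_loglik(const FitData& d, const mat& Q, const mat& F) {
  double ll = 0.0;
  if (d.G0.n_rows > 0) {
    mat P = clamp(Q * F, d.eps, 1.0 - d.eps);
    ll += loglik_obs(d.M, d.G0, P);
  }
  if (d.has_ref)
    ll += accu(d.ALT % log(F) + d.TOTmALT % log(1.0 - F));
  return ll;
}

// One EM update of (Q, F) in place.
static void fit_em_update(const FitData& d, mat& Q, mat& F) {
  mat A, B;
  if (d.G0.n_rows > 0) {
    mat P = clamp(Q * F, d.eps, 1.0 - d.eps);
    mat R1 = (d.M % d.G0) / P;
    mat R2 = (d.M % (2.0 - d.G0)) / (1.0 - P);
    mat S = R1 * F.t() + R2 * (1.0 - F).t();
    mat Qnew = Q % S;
    if (d.update_F) {
      A = F % (Q.t() * R1);
      B = (1.0 - F) % (Q.t() * R2);
    }
    for (uword i = 0; i < Q.n_rows; ++i) {
      if (d.Jobs(i) <= 0) continue;
      rowvec q = Qnew.row(i) / (2.0 * d.Jobs(i));
      const double s = accu(q);
      if (s > 0) Q.row(i) = q / s;
    }
  } else if (d.update_F) {
    A.zeros(F.n_rows, F.n_cols);
    B.zeros(F.n_rows, F.n_cols);
  }
  if (d.update_F) {
    if (d.has_ref) {
      A += d.ALT;
      B += d.TOTmALT;
    }
    mat Fnew = A / (A + B);
    uvec bad = find_nonfinite(Fnew);
    if (bad.n_elem > 0) Fnew.elem(bad) = F.elem(bad);
    F = clamp(Fnew, d.eps, 1.0 - d.eps);
  }
}

// Project an extrapolated point back to the feasible region: simplex rows
// for Q (tiny floor keeps the multiplicative EM map interior), clamped open
// unit interval for F.
static void project(mat& Q, mat& F, const double eps) {
  Q = clamp(Q, 1e-9, datum::inf);
  Q.each_col() /= sum(Q, 1);
  F = clamp(F, eps, 1.0 - eps);
}

// [[Rcpp::export]]
Rcpp::List admix_fit_cpp(const arma::mat& G,
                         arma::mat Q,
                         arma::mat F,
                         const arma::mat& ALT,
                         const arma::mat& TOT,
                         const bool update_F,
                         const bool accel,
                         const double tol,
                         const int max_iter,
                         const double eps) {
  FitData d;
  d.eps = eps;
  d.update_F = update_F;
  d.has_ref = ALT.n_elem > 0;
  if (d.has_ref) {
    if (ALT.n_rows != F.n_rows || ALT.n_cols != F.n_cols ||
        TOT.n_rows != F.n_rows || TOT.n_cols != F.n_cols)
      Rcpp::stop("reference count matrices must match F");
    d.ALT = ALT;
    d.TOTmALT = TOT - ALT;
  }
  if (G.n_rows > 0) {
    if (Q.n_rows != G.n_rows || F.n_cols != G.n_cols ||
        Q.n_cols != F.n_rows)
      Rcpp::stop("dimension mismatch between G, Q and F");
    d.M.ones(G.n_rows, G.n_cols);
    d.G0 = G;
    uvec miss = find_nonfinite(G);
    if (miss.n_elem > 0) {
      d.M.elem(miss).zeros();
      d.G0.elem(miss).zeros();
    }
    d.Jobs = sum(d.M, 1);
  } else {
    d.Jobs.set_size(0);
    d.G0.set_size(0, F.n_cols);
    d.M.set_size(0, F.n_cols);
  }

  std::vector<double> trace;
  double ll = fit_loglik(d, Q, F);
  trace.push_back(ll);
  bool converged = false;
  int em_steps = 0;

  if (!accel) {
    while (em_steps < max_iter) {
      fit_em_update(d, Q, F);
      ++em_steps;
      const double ll_new = fit_loglik(d, Q, F);
      trace.push_back(ll_new);
      if (std::abs(ll_new - ll) < tol) {
        ll = ll_new;
        converged = true;
        break;
      }
      ll = ll_new;
    }
  } else {
    // SQUAREM (scheme S3) on the EM map with a monotonicity safeguard.
    while (em_steps < max_iter) {
      const mat Q0 = Q, F0 = F;
      fit_em_update(d, Q, F);
      const mat Q1 = Q, F1 = F;
      fit_em_update(d, Q, F);
      const mat Q2 = Q, F2 = F;
      em_steps += 2;

      const mat rQ = Q1 - Q0, rF = F1 - F0;
      const mat vQ = Q2 - Q1 - rQ, vF = F2 - F1 - rF;
      const double rn = std::sqrt(accu(rQ % rQ) + accu(rF % rF));
      const double vn = std::sqrt(accu(vQ % vQ) + accu(vF % vF));
      double ll_new;
      if (vn > 0 && rn > 0) {
        double alpha = -rn / vn;
        if (alpha > -1.0) alpha = -1.0;
        mat Qx = Q0 - 2.0 * alpha * rQ + (alpha * alpha) * vQ;
        mat Fx = F0 - 2.0 * alpha * rF + (alpha * alpha) * vF;
        project(Qx, Fx, eps);
        const double ll_x = fit_loglik(d, Qx, Fx);
        if (std::isfinite(ll_x) && ll_x >= ll) {
          Q = Qx;
          F = Fx;
          ll_new = ll_x;
        } else {
          ll_new = fit_loglik(d, Q2, F2);  // Q, F already at (Q2, F2)
        }
      } else {
        ll_new = fit_loglik(d, Q2, F2);
      }
      trace.push_back(ll_new);
      if (std::abs(ll_new - ll) < tol) {
        ll = ll_new;
        converged = true;
        break;
      }
      ll = ll_new;
    }
  }

  return Rcpp::List::create(Rcpp::Named("Q") = Q,
                            Rcpp::Named("F") = F,
                            Rcpp::Named("loglik") = ll,
                            Rcpp::Named("trace") = trace,
                            Rcpp::Named("n_iter") = em_steps,
                            Rcpp::Named("converged") = converged);
}

// ---------------------------------------------------------------------------
// Fixed-frequency fits decompose over individuals, and each individual's
// problem — maximize a concave binomial log-likelihood over the K-simplex
// with K small — is solved exactly by an active-set projected Newton
// method. EM-family updates crawl sublinearly into boundary components
// (exactly the small spurious proportions the denoising rule inspects), so
// a likelihood-change stopping rule leaves them with O(1e-2) error;
// Newton with explicit KKT checks resolves them to numerical precision.

static double row_ll(const vec& w1, const vec& w2, const vec& p) {
  return dot(w1, log(p)) + dot(w2, log(1.0 - p));
}

// Maximize sum_j w1 log(F'q) + w2 log(1 - F'q) over the simplex.
// Returns the optimum in q; reports Newton iterations used.
static int solve_row_newton(const mat& F, const vec& w1, const vec& w2,
                            vec& q, double& ll_out, const double eps,
                            const double kkt_tol, const int max_iter,
                            bool& converged) {
  const uword K = F.n_rows;
  if (K == 1) {
    q.ones(1);
    ll_out = row_ll(w1, w2, clamp(F.t() * q, eps, 1.0 - eps));
    converged = true;
    return 0;
  }
  // start strictly inside, preserving the warm start's support pattern
  q = clamp(q, 1e-8, 1.0);
  q /= accu(q);
  vec p = clamp(F.t() * q, eps, 1.0 - eps);
  double ll = row_ll(w1, w2, p);
  converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    const vec a = w1 / p, b = w2 / (1.0 - p);
    const vec grad = F * (a - b);
    const vec d = a / p + b / (1.0 - p);      // -d2L/dp2 weights
    mat H = (F.each_row() % d.t()) * F.t();   // negative Hessian (psd)
    H.diag() += 1e-10 * (trace(H) / K + 1.0); // ridge for rank safety

    // active set: zero coordinates currently pinned at the boundary
    const uvec active = find(q <= 0.0);
    const uvec freec = find(q > 0.0);
    // KKT multiplier estimate from the free coordinates
    const double lambda = mean(grad.elem(freec));

    // first-order optimality: free gradients equalized, no pinned
    // coordinate demanding growth
    bool release_any = false;
    uvec keep = freec;
    for (uword ai = 0; ai < active.n_elem; ++ai)
      if (grad(active(ai)) - lambda > kkt_tol) {
        keep = join_cols(keep, uvec{active(ai)});
        release_any = true;
      }
    double kkt_free = 0.0;
    for (uword fi = 0; fi < freec.n_elem; ++fi)
      kkt_free = std::max(kkt_free,
                          std::abs(grad(freec(fi)) - lambda));
    if (!release_any && kkt_free < kkt_tol) {
      converged = true;
      break;
    }
    keep = sort(keep);

    // equality-constrained Newton step on the kept coordinates
    const uword m = keep.n_elem;
    mat A(m + 1, m + 1, fill::zeros);
    A.submat(0, 0, m - 1, m - 1) = H.submat(keep, keep);
    A.submat(0, m, m - 1, m).ones();
    A.submat(m, 0, m, m - 1).ones();
    vec rhs(m + 1, fill::zeros);
    rhs.subvec(0, m - 1) = grad.elem(keep);
    vec sol;
    const bool ok = solve(sol, A, rhs, solve_opts::no_approx);
    vec step(K, fill::zeros);
    if (ok) {
      for (uword si = 0; si < m; ++si) step(keep(si)) = sol(si);
    } else {
      // fall back to a projected gradient direction on the kept set
      vec gz(K, fill::zeros);
      double gm = 0.0;
      for (uword si = 0; si < m; ++si) gm += grad(keep(si));
      gm /= m;
      for (uword si = 0; si < m; ++si) gz(keep(si)) = grad(keep(si)) - gm;
      step = gz / (norm(H, "inf") + 1.0);
    }

    // backtracking line search along the Newton direction; if it fails,
    // retry along the projected gradient before concluding optimality
    bool improved = false;
    for (int attempt = 0; attempt < 2 && !improved; ++attempt) {
      if (attempt == 1) {
        vec gz(K, fill::zeros);
        double gm = 0.0;
        for (uword si = 0; si < m; ++si) gm += grad(keep(si));
        gm /= m;
        for (uword si = 0; si < m; ++si)
          gz(keep(si)) = grad(keep(si)) - gm;
        for (uword si = 0; si < K; ++si)
          if (q(si) <= 0.0 && gz(si) < 0) gz(si) = 0;
        const double nz = norm(gz, 2);
        if (nz == 0) break;
        step = gz / (norm(H, "inf") + 1.0);
      }
      double tmax = 1.0;
      for (uword si = 0; si < K; ++si)
        if (step(si) < 0 && q(si) > 0)
          tmax = std::min(tmax, q(si) / (-step(si)));
      double t = std::min(1.0, tmax);
      const double slope = dot(grad, step);
      for (int ls = 0; ls < 40 && t > 0; ++ls) {
        vec qn = q + t * step;
        qn = clamp(qn, 0.0, 1.0);
        // snap to the boundary so pinned coordinates are exact zeros
        qn.elem(find(qn < 1e-9)).zeros();
        qn /= accu(qn);
        const vec pn = clamp(F.t() * qn, eps, 1.0 - eps);
        const double ll_n = row_ll(w1, w2, pn);
        if (std::isfinite(ll_n) && ll_n > ll &&
            ll_n >= ll + 1e-4 * t * slope) {
          q = qn;
          p = pn;
          ll = ll_n;
          improved = true;
          break;
        }
        t *= 0.5;
      }
    }
    if (!improved) {
      converged = true;
      break;
    }
  }
  ll_out = ll;
  return it;
}

// [[Rcpp::export]]
Rcpp::List admix_fit_rows_cpp(const arma::mat& G,
                              const arma::mat& Q0,
                              const arma::mat& F,
                              const double tol,
                              const int max_iter,
                              const double eps) {
  const uword n = G.n_rows;
  const uword J = G.n_cols;
  const uword K = F.n_rows;
  if (Q0.n_rows != n || Q0.n_cols != K || F.n_cols != J)
    Rcpp::stop("dimension mismatch between G, Q and F");
  const mat Gt = G.t();  // J x n: contiguous per-individual access

  mat Q(n, K);
  double ll_total = 0.0;
  int iter_max_used = 0;
  bool all_converged = true;
  const int newton_cap = std::min(max_iter, 300);

  for (uword i = 0; i < n; ++i) {
    vec g = Gt.col(i);
    vec w1 = g, w2 = 2.0 - g;
    uvec miss = find_nonfinite(g);
    const double Jobs = J - miss.n_elem;
    if (Jobs <= 0) {  // nothing observed: keep the start vector
      Q.row(i) = Q0.row(i);
      continue;
    }
    if (miss.n_elem > 0) {
      w1.elem(miss).zeros();
      w2.elem(miss).zeros();
    }
    vec q = Q0.row(i).t();
    double ll = 0.0;
    bool conv = false;
    const double kkt_tol = std::max(tol, 1e-10) * Jobs;
    const int used = solve_row_newton(F, w1, w2, q, ll, eps, kkt_tol,
                                      newton_cap, conv);
    Q.row(i) = q.t();
    ll_total += ll;
    if (used > iter_max_used) iter_max_used = used;
    if (!conv) all_converged = false;
  }

  return Rcpp::List::create(Rcpp::Named("Q") = Q,
                            Rcpp::Named("loglik") = ll_total,
                            Rcpp::Named("n_iter") = iter_max_used,
                            Rcpp::Named("converged") = all_converged);
}
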