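#include <Rcpp.h>
using namespace Rcpp;

// Adaptive random-walk Metropolis-within-Gibbs sampler for the joint
// survival (CJS) + fecundity (Poisson GLMM) posterior.
//
// Parameter vector layout (0-based):
//   0  logit_phi_a    1 beta_sex      2 delta_trans   3 logit_phi_j
//   4  beta_dens_j    5 gamma_band    6 sigma_year_j  7 logit_p
//   8  sigma_year_p   9 alpha_f      10 beta_dens_f  11 sigma_female
//  12  sigma_year_f
//  then eps_j (one per interval), eps_p (one per occasion), eps_fem,
//  eps_fy blocks.
//
// The CJS likelihood is cached per individual; each proposal only
// recomputes the individuals whose linear predictors it touches (e.g. a
// juvenile-survival year deviate touches just that cohort), which is what
// keeps full-model fits on growing populations cheap.
//
// Density covariates arrive pre-standardized; back-transformation to the
// raw scale happens on the R side.  Random effects have N(0, sigma_block)
// priors; scalar coefficients normal priors; sigmas uniform(0, upper) or
// zero-truncated normal priors.

static const int NSCAL = 13;
static const int SIG_J = 6, SIG_P = 8, SIG_F = 11, SIG_Y = 12;

struct Model {
  IntegerMatrix det;
  IntegerVector first, male, trans, firstint, bandf, juvint;
  NumericVector frac, dens_s;
  int n, T, nI;
  IntegerVector fk, ffem, fyr;
  NumericVector fdens;
  int nrec, nfem, nyrf;
  std::vector<std::vector<int> > fem_recs, yr_recs;
  bool inc_sex, inc_trans, inc_band, inc_densj, inc_yrej, inc_yrep, inc_densf,
      inc_femre, inc_yref;
  int o_ej, o_ep, o_ef, o_ey, npar;

  NumericMatrix phi;
  NumericVector pvec;
  std::vector<double> ll_i;  // per-individual CJS log-likelihood
  double sll;                // sum of ll_i

  // affected-row sets
  std::vector<int> rows_all, rows_male, rows_trans, rows_juv;
  std::vector<std::vector<int> > rows_juv_by_int, rows_first_lt;

  void build_row_sets() {
    rows_juv_by_int.assign(nI, std::vector<int>());
    rows_first_lt.assign(T, std::vector<int>());
    for (int i = 0; i < n; ++i) {
      rows_all.push_back(i);
      if (male[i] == 1) rows_male.push_back(i);
      if (trans[i]) rows_trans.push_back(i);
      // a bird first marked at the final occasion has no interval at all
      if (juvint[i] >= 0 && juvint[i] < nI) {
        rows_juv.push_back(i);
        rows_juv_by_int[juvint[i]].push_back(i);
      }
      for (int t = 0; t < T; ++t)
        if (first[i] < t) rows_first_lt[t].push_back(i);
    }
  }

  void phi_row(int i, const std::vector<double>& th) {
    for (int t = first[i]; t < nI; ++t) {
      double lg;
      if (juvint[i] == t) {
        lg = th[3] + (inc_yrej ? th[o_ej + t] : 0.0) +
             (inc_densj ? th[4] * dens_s[t] : 0.0) +
             (inc_band && bandf[i] ? th[5] : 0.0);
      } else {
        lg = th[0] + (inc_sex && male[i] == 1 ? th[1] : 0.0) +
             (inc_trans && trans[i] && t == firstint[i] ? th[2] : 0.0);
      }
      double pr = 1.0 / (1.0 + std::exp(-lg));
      if (frac[t] != 1.0) pr = std::pow(pr, frac[t]);
      phi(i, t) = pr;
    }
  }
  void rebuild_phi_rows(const std::vector<int>& rows,
                        const std::vector<double>& th) {
    for (size_t r = 0; r < rows.size(); ++r) phi_row(rows[r], th);
  }
  void rebuild_p(const std::vector<double>& th) {
    for (int t = 0; t < T; ++t) {
      double lg = th[7] + (inc_yrep ? th[o_ep + t] : 0.0);
      pvec[t] = 1.0 / (1.0 + std::exp(-lg));
    }
  }
  double cjs_row(int i) const {
    const int f = first[i];
    double wa = 1.0, wd = 0.0;
    for (int t = f; t < T - 1; ++t) {
      const int y = det(i, t + 1);
      const double ph = phi(i, t);
      const double nwa = wa * ph * (y ? pvec[t + 1] : 1.0 - pvec[t + 1]);
      const double nwd = y ? 0.0 : wa * (1.0 - ph) + wd;
      wa = nwa;
      wd = nwd;
    }
    const double tot = wa + wd;
    return tot > 0.0 ? std::log(tot) : R_NegInf;
  }
  void full_cjs() {
    sll = 0.0;
    for (int i = 0; i < n; ++i) {
      ll_i[i] = cjs_row(i);
      sll += ll_i[i];
    }
  }
  // recompute rows in-place, returning the change in total log-likelihood;
  // old values are stashed so reject_rows() can undo
  std::vector<double> stash_ll;
  double recompute_rows(const std::vector<int>& rows) {
    stash_ll.resize(rows.size());
    double delta = 0.0;
    for (size_t r = 0; r < rows.size(); ++r) {
      const int i = rows[r];
      stash_ll[r] = ll_i[i];
      const double nl = cjs_row(i);
      delta += nl - ll_i[i];
      ll_i[i] = nl;
    }
    return delta;
  }
  void restore_rows(const std::vector<int>& rows) {
    for (size_t r = 0; r < rows.size(); ++r) ll_i[rows[r]] = stash_ll[r];
  }

  double rec_ll(int r, const std::vector<double>& th) const {
    double eta = th[9] + (inc_densf ? th[10] * fdens[r] : 0.0) +
                 (inc_femre ? th[o_ef + ffem[r]] : 0.0) +
                 (inc_yref ? th[o_ey + fyr[r]] : 0.0);
    return fk[r] * eta - std::exp(eta) - std::lgamma(fk[r] + 1.0);
  }
  double fec_ll(const std::vector<double>& th) const {
    double ll = 0.0;
    for (int r = 0; r < nrec; ++r) ll += rec_ll(r, th);
    return ll;
  }
  double fec_ll_group(const std::vector<int>& recs,
                      const std::vector<double>& th) const {
    double ll = 0.0;
    for (size_t j = 0; j < recs.size(); ++j) ll += rec_ll(recs[j], th);
    return ll;
  }
};

static inline double dnorm_log(double x, double m, double s) {
  const double z = (x - m) / s;
  return -0.5 * z * z - std::log(s) - 0.9189385332046727;
}

// [[Rcpp::export]]
List ipm_mcmc_cpp(List sdat, List fdat, List prior, List ctrl) {
  Model M;
  M.det = as<IntegerMatrix>(sdat["det"]);
  M.first = as<IntegerVector>(sdat["first"]);
  M.male = as<IntegerVector>(sdat["male"]);
  M.trans = as<IntegerVector>(sdat["trans"]);
  M.firstint = as<IntegerVector>(sdat["firstint"]);
  M.bandf = as<IntegerVector>(sdat["bandf"]);
  M.juvint = as<IntegerVector>(sdat["juvint"]);
  M.frac = as<NumericVector>(sdat["frac"]);
  M.dens_s = as<NumericVector>(sdat["dens_s"]);
  M.n = M.det.nrow();
  M.T = M.det.ncol();
  M.nI = M.T - 1;

  M.fk = as<IntegerVector>(fdat["k"]);
  M.ffem = as<IntegerVector>(fdat["fem"]);
  M.fyr = as<IntegerVector>(fdat["yr"]);
  M.fdens = as<NumericVector>(fdat["dens_s"]);
  M.nrec = M.fk.size();
  M.nfem = as<int>(fdat["nfem"]);
  M.nyrf = as<int>(fdat["nyr"]);
  M.fem_recs.resize(std::max(M.nfem, 1));
  M.yr_recs.resize(std::max(M.nyrf, 1));
  for (int r = 0; r < M.nrec; ++r) {
    M.fem_recs[M.ffem[r]].push_back(r);
    M.yr_recs[M.fyr[r]].push_back(r);
  }

  LogicalVector fl = as<LogicalVector>(ctrl["flags"]);
  M.inc_sex = fl["sex"];
  M.inc_trans = fl["trans"];
  M.inc_band = fl["band"];
  M.inc_densj = fl["densj"];
  M.inc_yrej = fl["yrej"];
  M.inc_yrep = fl["yrep"];
  M.inc_densf = fl["densf"];
  M.inc_femre = fl["femre"];
  M.inc_yref = fl["yref"];

  M.o_ej = NSCAL;
  M.o_ep = M.o_ej + M.nI;
  M.o_ef = M.o_ep + M.T;
  M.o_ey = M.o_ef + M.nfem;
  M.npar = M.o_ey + M.nyrf;
  M.phi = NumericMatrix(M.n, std::max(M.nI, 1));
  M.pvec = NumericVector(M.T);
  M.ll_i.assign(M.n, 0.0);
  M.build_row_sets();

  std::vector<bool> active(M.npar, false);
  active[0] = true;
  active[1] = M.inc_sex;
  active[2] = M.inc_trans;
  active[3] = as<bool>(ctrl["has_juveniles"]);
  active[4] = M.inc_densj;
  active[5] = M.inc_band;
  active[6] = M.inc_yrej;
  active[7] = true;
  active[8] = M.inc_yrep;
  active[9] = M.nrec > 0;
  active[10] = M.inc_densf && M.nrec > 0;
  active[11] = M.inc_femre && M.nrec > 0;
  active[12] = M.inc_yref && M.nrec > 0;
  IntegerVector ej_active = as<IntegerVector>(ctrl["ej_active"]);
  if (M.inc_yrej)
    for (int j = 0; j < ej_active.size(); ++j)
      active[M.o_ej + ej_active[j]] = true;
  if (M.inc_yrep)
    for (int t = 1; t < M.T; ++t) active[M.o_ep + t] = true;
  if (M.inc_femre && M.nrec > 0)
    for (int i = 0; i < M.nfem; ++i) active[M.o_ef + i] = true;
  if (M.inc_yref && M.nrec > 0)
    for (int y = 0; y < M.nyrf; ++y) active[M.o_ey + y] = true;

  NumericVector pr_type = as<NumericVector>(prior["type"]);
  NumericVector pr1 = as<NumericVector>(prior["p1"]);
  NumericVector pr2 = as<NumericVector>(prior["p2"]);

  const int n_iter = as<int>(ctrl["n_iter"]);
  const int n_burn = as<int>(ctrl["n_burn"]);
  const int thin = as<int>(ctrl["thin"]);
  std::vector<double> th = as<std::vector<double> >(ctrl["init"]);
  if ((int)th.size() != M.npar) stop("init length mismatch");

  auto prior_ld = [&](int j, double x) -> double {
    if (pr_type[j] == 1.0)
      return (x < 0.0 || x > pr2[j]) ? R_NegInf : -std::log(pr2[j]);
    if (j == SIG_J || j == SIG_P || j == SIG_F || j == SIG_Y)
      if (x < 0.0) return R_NegInf;
    return dnorm_log(x, pr1[j], pr2[j]);
  };
  auto eps_prior = [&](int off, int nblk, double sig) -> double {
    if (sig <= 0.0) return R_NegInf;
    double s = 0.0;
    for (int j = 0; j < nblk; ++j)
      if (active[off + j]) s += dnorm_log(th[off + j], 0.0, sig);
    return s;
  };

  std::vector<double> lsc(M.npar, -1.0);
  std::vector<int> acc(M.npar, 0), tries(M.npar, 0);

  M.rebuild_phi_rows(M.rows_all, th);
  M.rebuild_p(th);
  M.full_cjs();
  double cur_fll = M.fec_ll(th);
  if (!R_finite(M.sll) || !R_finite(cur_fll))
    stop("initial values have zero likelihood");

  // generic survival-side scalar update over an affected row set; extra_pr:
  // prior difference terms beyond the scalar's own prior (used by eps_j)
  auto surv_update = [&](int j, const std::vector<int>& rows,
                         bool is_eps, double sig) {
    tries[j]++;
    const double old = th[j];
    const double lp0 =
        is_eps ? dnorm_log(old, 0.0, sig) : prior_ld(j, old);
    th[j] = old + std::exp(lsc[j]) * R::norm_rand();
    const double lp1 =
        is_eps ? dnorm_log(th[j], 0.0, sig) : prior_ld(j, th[j]);
    if (!R_finite(lp1)) {
      th[j] = old;
      return;
    }
    M.rebuild_phi_rows(rows, th);
    const double delta = M.recompute_rows(rows);
    if (std::log(R::unif_rand()) < delta + lp1 - lp0) {
      M.sll += delta;
      acc[j]++;
    } else {
      th[j] = old;
      M.rebuild_phi_rows(rows, th);
      M.restore_rows(rows);
    }
  };
  // sigma update: prior-only conditional
  auto sigma_update = [&](int j, int off, int nblk) {
    tries[j]++;
    const double old = th[j];
    const double lp0 = prior_ld(j, old) + eps_prior(off, nblk, old);
    th[j] = old + std::exp(lsc[j]) * R::norm_rand();
    const double lp1 = prior_ld(j, th[j]) + eps_prior(off, nblk, th[j]);
    if (R_finite(lp1) && std::log(R::unif_rand()) < lp1 - lp0)
      acc[j]++;
    else
      th[j] = old;
  };

  const int n_keep = n_iter > n_burn ? (n_iter - n_burn + thin - 1) / thin : 0;
  NumericMatrix draws(std::max(n_keep, 0), M.npar);
  int keep = 0;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    if (active[0]) surv_update(0, M.rows_all, false, 0);
    if (active[1]) surv_update(1, M.rows_male, false, 0);
    if (active[2]) surv_update(2, M.rows_trans, false, 0);
    if (active[3]) surv_update(3, M.rows_juv, false, 0);
    if (active[4]) surv_update(4, M.rows_juv, false, 0);
    if (active[5]) surv_update(5, M.rows_juv, false, 0);
    if (M.inc_yrej) {
      for (int t = 0; t < M.nI; ++t)
        if (active[M.o_ej + t])
          surv_update(M.o_ej + t, M.rows_juv_by_int[t], true, th[SIG_J]);
      sigma_update(SIG_J, M.o_ej, M.nI);
    }
    {  // logit_p: phi untouched, p rebuilt, all rows affected
      const int j = 7;
      tries[j]++;
      const double old = th[j];
      const double lp0 = prior_ld(j, old);
      th[j] = old + std::exp(lsc[j]) * R::norm_rand();
      const double lp1 = prior_ld(j, th[j]);
      M.rebuild_p(th);
      const double delta = M.recompute_rows(M.rows_all);
      if (R_finite(lp1) &&
          std::log(R::unif_rand()) < delta + lp1 - lp0) {
        M.sll += delta;
        acc[j]++;
      } else {
        th[j] = old;
        M.rebuild_p(th);
        M.restore_rows(M.rows_all);
      }
    }
    if (M.inc_yrep) {
      for (int t = 1; t < M.T; ++t) {
        const int j = M.o_ep + t;
        tries[j]++;
        const double old = th[j];
        th[j] = old + std::exp(lsc[j]) * R::norm_rand();
        const double dpr = dnorm_log(th[j], 0.0, th[SIG_P]) -
                           dnorm_log(old, 0.0, th[SIG_P]);
        M.rebuild_p(th);
        const double delta = M.recompute_rows(M.rows_first_lt[t]);
        if (std::log(R::unif_rand()) < delta + dpr) {
          M.sll += delta;
          acc[j]++;
        } else {
          th[j] = old;
          M.rebuild_p(th);
          M.restore_rows(M.rows_first_lt[t]);
        }
      }
      sigma_update(SIG_P, M.o_ep, M.T);
    }
    for (int j = 9; j <= 10; ++j) {
      if (!active[j]) continue;
      tries[j]++;
      const double old = th[j];
      const double lp0 = prior_ld(j, old);
      th[j] = old + std::exp(lsc[j]) * R::norm_rand();
      const double lp1 = prior_ld(j, th[j]);
      const double nfll = R_finite(lp1) ? M.fec_ll(th) : R_NegInf;
      if (R_finite(lp1) &&
          std::log(R::unif_rand()) < nfll - cur_fll + lp1 - lp0) {
        cur_fll = nfll;
        acc[j]++;
      } else {
        th[j] = old;
      }
    }
    if (M.inc_femre && M.nrec > 0) {
      for (int i = 0; i < M.nfem; ++i) {
        const int j = M.o_ef + i;
        tries[j]++;
        const double old = th[j];
        const double ll0 = M.fec_ll_group(M.fem_recs[i], th);
        th[j] = old + std::exp(lsc[j]) * R::norm_rand();
        const double ll1 = M.fec_ll_group(M.fem_recs[i], th);
        const double dpr = dnorm_log(th[j], 0.0, th[SIG_F]) -
                           dnorm_log(old, 0.0, th[SIG_F]);
        if (std::log(R::unif_rand()) < ll1 - ll0 + dpr) {
          cur_fll += ll1 - ll0;
          acc[j]++;
        } else {
          th[j] = old;
        }
      }
      sigma_update(SIG_F, M.o_ef, M.nfem);
    }
    if (M.inc_yref && M.nrec > 0) {
      for (int y = 0; y < M.nyrf; ++y) {
        const int j = M.o_ey + y;
        tries[j]++;
        const double old = th[j];
        const double ll0 = M.fec_ll_group(M.yr_recs[y], th);
        th[j] = old + std::exp(lsc[j]) * R::norm_rand();
        const double ll1 = M.fec_ll_group(M.yr_recs[y], th);
        const double dpr = dnorm_log(th[j], 0.0, th[SIG_Y]) -
                           dnorm_log(old, 0.0, th[SIG_Y]);
        if (std::log(R::unif_rand()) < ll1 - ll0 + dpr) {
          cur_fll += ll1 - ll0;
          acc[j]++;
        } else {
          th[j] = old;
        }
      }
      sigma_update(SIG_Y, M.o_ey, M.nyrf);
    }

    if (it < n_burn && (it + 1) % 50 == 0) {
      const double batch = (it + 1) / 50.0;
      const double step = std::min(0.05, 1.0 / std::sqrt(batch));
      for (int j = 0; j < M.npar; ++j) {
        if (tries[j] == 0) continue;
        const double rate = (double)acc[j] / tries[j];
        lsc[j] += rate > 0.44 ? step : -step;
        acc[j] = 0;
        tries[j] = 0;
      }
    }

    if (it >= n_burn && (it - n_burn) % thin == 0) {
      for (int j = 0; j < M.npar; ++j) draws(keep, j) = th[j];
      keep++;
    }
  }

  LogicalVector act(M.npar);
  for (int j = 0; j < M.npar; ++j) act[j] = active[j];
  return List::create(_["draws"] = draws, _["active"] = act,
                      _["loglik_surv"] = M.sll, _["loglik_fec"] = cur_fll,
                      _["offsets"] = IntegerVector::create(
                          _["ej"] = M.o_ej, _["ep"] = M.o_ep, _["ef"] = M.o_ef,
                          _["ey"] = M.o_ey, _["npar"] = M.npar));
}
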