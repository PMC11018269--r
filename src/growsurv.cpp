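// Joint latent growth curve / discrete-time survival log-likelihood.
//
// One TMB objective covers both model families: with surv_on = 0 it is the
// closed-form full-information Gaussian marginal likelihood of the growth
// model; with surv_on = 1 each subject's likelihood is
//
//   L_i = f(y_i) * E[ S_i(eta) | y_i ]
//
// where f(y_i) is the multivariate normal density of the observed outcome
// stack at the model-implied moments, and the expectation of the survival
// likelihood S_i over the hazard factors eta is taken against their exact
// Gaussian posterior given y_i, evaluated by Gauss-Hermite quadrature
// re-centered at that posterior. With hazard loadings of zero the quadrature
// is exact and the likelihood separates.
//
// The parameter vector `theta` is the unconstrained packing produced by
// par_pack() on the R side (log-Cholesky for covariance blocks); the order
// here must match par_pack()/par_unpack() exactly.

#define TMB_LIB_INIT R_init_growsurv
#include <TMB.hpp>

template <class Type>
Type objective_function<Type>::operator()() {
  // model structure
  DATA_INTEGER(nf);           // number of latent growth factors (2 or 4)
  DATA_INTEGER(no);           // number of outcomes (1 or 2)
  DATA_IVECTOR(brow);         // free covariate paths: 0-based factor index
  DATA_IVECTOR(bcol);         //                       0-based covariate index
  DATA_INTEGER(resid_cross);  // estimate within-occasion residual covariance
  DATA_INTEGER(prac_on);      // practice-effect mean present
  DATA_INTEGER(prac_var_on);  // practice-effect variance free
  DATA_INTEGER(surv_on);      // joint survival submodel
  DATA_INTEGER(K);            // risk intervals
  DATA_IVECTOR(hf);           // 0-based indices of the hazard factors
  DATA_INTEGER(link);         // 0 logit, 1 probit

  // stacked subject data: one element = one observed outcome at one visit
  DATA_IVECTOR(nelem);        // elements per subject
  DATA_VECTOR(y);             // observed values
  DATA_VECTOR(tt);            // time in study (years)
  DATA_VECTOR(lam);           // practice loadings
  DATA_IVECTOR(occ);          // visit order (occasion)
  DATA_IVECTOR(outi);         // 0-based outcome index
  DATA_MATRIX(X);             // n x ncov baseline covariates
  DATA_IMATRIX(surv);         // n x K: -1 unknown, 0 survived, 1 died

  // normalized Gauss-Hermite rule (raw nodes; weights already normalized)
  DATA_MATRIX(zgrid);         // Q x ds
  DATA_VECTOR(lw);            // Q log-weights, logsumexp(lw) = 0

  PARAMETER_VECTOR(theta);

  int k = 0;
  vector<Type> alpha(nf);
  for (int f = 0; f < nf; f++) alpha(f) = theta(k++);
  int ncov = X.cols();
  matrix<Type> Beta(nf, ncov);
  Beta.setZero();
  for (int j = 0; j < brow.size(); j++) Beta(brow(j), bcol(j)) = theta(k++);

  matrix<Type> Lpsi(nf, nf);
  Lpsi.setZero();
  for (int j = 0; j < nf; j++)
    for (int i = j; i < nf; i++)
      Lpsi(i, j) = (i == j) ? exp(theta(k++)) : theta(k++);
  matrix<Type> Psi = Lpsi * Lpsi.transpose();

  matrix<Type> Th(no, no);
  Th.setZero();
  if (resid_cross) {
    Type l11 = exp(theta(k++));
    Type l21 = theta(k++);
    Type l22 = exp(theta(k++));
    Th(0, 0) = l11 * l11;
    Th(1, 0) = Th(0, 1) = l11 * l21;
    Th(1, 1) = l21 * l21 + l22 * l22;
  } else {
    for (int o = 0; o < no; o++) {
      Type s = exp(theta(k++));
      Th(o, o) = s * s;
    }
  }

  Type mu_p = Type(0);
  if (prac_on) mu_p = theta(k++);
  Type psi_p = Type(0);
  if (prac_var_on) {
    Type s = exp(theta(k++));
    psi_p = s * s;
  }

  int ds = hf.size();
  vector<Type> tau(K);
  vector<Type> gam(ds);
  if (surv_on) {
    for (int kk = 0; kk < K; kk++) tau(kk) = theta(k++);
    for (int j = 0; j < ds; j++) gam(j) = theta(k++);
  }

  int n = nelem.size();
  Type log2pi = log(Type(2) * Type(M_PI));
  Type sqrt2 = sqrt(Type(2));
  int Q = zgrid.rows();
  vector<Type> ll(n);
  int off = 0;

  for (int i = 0; i < n; i++) {
    int ne = nelem(i);

    vector<Type> eta_mean(nf);
    for (int f = 0; f < nf; f++) {
      Type s = alpha(f);
      for (int c = 0; c < ncov; c++) s += Beta(f, c) * X(i, c);
      eta_mean(f) = s;
    }

    // Cholesky-based Gaussian density: a non-PD implied covariance yields a
    // NaN (sqrt of a negative pivot) that propagates to the subject's
    // log-likelihood rather than silently producing a finite wrong value
    Type lmarg = Type(0);
    matrix<Type> Lam(ne, nf);
    matrix<Type> Lc(ne, ne);  // lower Cholesky factor of V
    vector<Type> u(ne);       // Lc^{-1} (y - mu)
    if (ne > 0) {
      Lam.setZero();
      for (int e = 0; e < ne; e++) {
        int g = off + e;
        Lam(e, 2 * outi(g)) = Type(1);
        Lam(e, 2 * outi(g) + 1) = tt(g);
      }
      matrix<Type> LP = Lam * Psi;  // ne x nf
      matrix<Type> V = LP * Lam.transpose();
      for (int e = 0; e < ne; e++) {
        int ge = off + e;
        for (int f2 = 0; f2 < ne; f2++) {
          int gf = off + f2;
          V(e, f2) += psi_p * lam(ge) * lam(gf);
          if (occ(ge) == occ(gf)) {
            int oe = outi(ge), of = outi(gf);
            if (oe == of) {
              if (e == f2) V(e, f2) += Th(oe, oe);
            } else {
              V(e, f2) += Th(oe, of);
            }
          }
        }
      }
      Lc.setZero();
      Type ldhalf = Type(0);
      for (int j = 0; j < ne; j++) {
        Type s = V(j, j);
        for (int c = 0; c < j; c++) s -= Lc(j, c) * Lc(j, c);
        Lc(j, j) = sqrt(s);
        ldhalf += log(Lc(j, j));
        for (int i2 = j + 1; i2 < ne; i2++) {
          Type s2 = V(i2, j);
          for (int c = 0; c < j; c++) s2 -= Lc(i2, c) * Lc(j, c);
          Lc(i2, j) = s2 / Lc(j, j);
        }
      }
      for (int e = 0; e < ne; e++) {
        int g = off + e;
        Type mu = lam(g) * mu_p;
        for (int f2 = 0; f2 < nf; f2++) mu += Lam(e, f2) * eta_mean(f2);
        Type s = y(g) - mu;
        for (int c = 0; c < e; c++) s -= Lc(e, c) * u(c);
        u(e) = s / Lc(e, e);
      }
      Type q = (u * u).sum();
      lmarg = Type(-0.5) * Type(ne) * log2pi - ldhalf - Type(0.5) * q;
    }

    if (!surv_on) {
      ll(i) = lmarg;
      off += ne;
      continue;
    }

    // Gaussian posterior of the hazard factors given the outcome stack
    vector<Type> pm(ds);
    pm.setZero();
    matrix<Type> P(ds, ds);
    for (int a = 0; a < ds; a++)
      for (int b = 0; b < ds; b++) P(a, b) = Psi(hf(a), hf(b));
    if (ne > 0) {
      matrix<Type> PsiS(nf, ds);
      for (int a = 0; a < ds; a++)
        for (int f2 = 0; f2 < nf; f2++) PsiS(f2, a) = Psi(f2, hf(a));
      matrix<Type> C = Lam * PsiS;  // ne x ds
      matrix<Type> W(ne, ds);       // Lc^{-1} C
      for (int a = 0; a < ds; a++) {
        for (int e = 0; e < ne; e++) {
          Type s = C(e, a);
          for (int c = 0; c < e; c++) s -= Lc(e, c) * W(c, a);
          W(e, a) = s / Lc(e, e);
        }
      }
      for (int a = 0; a < ds; a++) {
        Type s = Type(0);
        for (int e = 0; e < ne; e++) s += W(e, a) * u(e);
        pm(a) = s;
        for (int b = 0; b < ds; b++) {
          Type s2 = Type(0);
          for (int e = 0; e < ne; e++) s2 += W(e, a) * W(e, b);
          P(a, b) -= s2;
        }
      }
    }
    matrix<Type> Lp(ds, ds);
    Lp.setZero();
    for (int j = 0; j < ds; j++) {
      Type s = P(j, j) + Type(1e-12);
      for (int c = 0; c < j; c++) s -= Lp(j, c) * Lp(j, c);
      Lp(j, j) = sqrt(s);
      for (int i2 = j + 1; i2 < ds; i2++) {
        Type s2 = P(i2, j);
        for (int c = 0; c < j; c++) s2 -= Lp(i2, c) * Lp(j, c);
        Lp(i2, j) = s2 / Lp(j, j);
      }
    }

    // hazard linear predictor at node z: tau_k + abase + bvec . z
    Type abase = Type(0);
    for (int j = 0; j < ds; j++) abase += gam(j) * (eta_mean(hf(j)) + pm(j));
    vector<Type> bvec(ds);
    for (int c = 0; c < ds; c++) {
      Type s = Type(0);
      for (int j = c; j < ds; j++) s += gam(j) * Lp(j, c);
      bvec(c) = sqrt2 * s;
    }

    Type A = Type(0);
    for (int q = 0; q < Q; q++) {
      Type g = abase;
      for (int c = 0; c < ds; c++) g += bvec(c) * zgrid(q, c);
      Type ls = Type(0);
      for (int kk = 0; kk < K; kk++) {
        int st = surv(i, kk);
        if (st < 0) continue;
        Type lp = tau(kk) + g;
        Type lh, lh1;
        if (link == 0) {
          Type den = logspace_add(Type(0), lp);
          lh = lp - den;   // log h
          lh1 = -den;      // log (1 - h)
        } else {
          lh = log(pnorm(lp) + Type(1e-300));
          lh1 = log(pnorm(-lp) + Type(1e-300));
        }
        ls += (st == 1) ? lh : lh1;
      }
      A += exp(lw(q) + ls);
    }
    ll(i) = lmarg + log(A);
    off += ne;
  }

  REPORT(ll);
  return -ll.sum();
}
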