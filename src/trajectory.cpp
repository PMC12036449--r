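#include <Rcpp.h>
using namespace Rcpp;

// Forward pass of one learner over a session of observed choices/outcomes.
// Choice probabilities for trial t are computed from the state after trial
// t-1's updates (including the unchosen-arm variance inflation); pe/rv/ru
// recorded for trial t reflect the state after trial t's outcome update.
// learner: 0=RW1 1=RW2 2=KF 3=VKF; rule: 0=value 1=uncertainty 2=both.
// [[Rcpp::export]]
List cpp_trajectory(IntegerVector choices, IntegerVector outcomes,
                    int learner, int rule, bool relative, int nArms,
                    double m0, double w0,
                    double a, double aPos, double aNeg,
                    double v, double sigma2,
                    double lambda, double v0, double omega,
                    double betaV, double betaU) {
  const int n = choices.size();
  const int A = nArms;
  const double vfloor = 1e-8;
  NumericMatrix M(n, A), W(n, A), P(n, A);
  NumericMatrix Vol(n, (learner == 3) ? A : 0);
  NumericVector K(n), PE(n), RV(n), RU(n);
  std::vector<double> m(A, m0), w(A, w0), vv(A, (learner == 3) ? v0 : v);
  double nll = 0.0;
  std::vector<double> eta(A), Vin(A), Uin(A);

  for (int t = 0; t < n; ++t) {
    // softmax inputs from the pre-outcome state
    double sm = 0.0, sw = 0.0;
    for (int j = 0; j < A; ++j) { sm += m[j]; sw += w[j]; }
    for (int j = 0; j < A; ++j) {
      Vin[j] = m[j]; Uin[j] = w[j];
    }
    if (relative) {
      if (sm <= 0.0) stop("degenerate state: value sum must be positive");
      for (int j = 0; j < A; ++j) Vin[j] = m[j] / sm;
      if (rule != 0) {
        if (sw <= 0.0) stop("degenerate state: uncertainty sum must be positive");
        for (int j = 0; j < A; ++j) Uin[j] = w[j] / sw;
      }
    }
    double emax = -1e300;
    for (int j = 0; j < A; ++j) {
      double e = 0.0;
      if (rule == 0) e = betaV * Vin[j];
      else if (rule == 1) e = betaU * Uin[j];
      else e = betaV * Vin[j] + betaU * Uin[j];
      eta[j] = e;
      if (e > emax) emax = e;
    }
    double Z = 0.0;
    for (int j = 0; j < A; ++j) { eta[j] = std::exp(eta[j] - emax); Z += eta[j]; }
    for (int j = 0; j < A; ++j) P(t, j) = eta[j] / Z;

    const int c = choices[t];
    if (c < 0 || c >= A) stop("choice index out of range at trial %d", t + 1);
    const double O = outcomes[t];
    double pc = P(t, c);
    if (pc < 1e-12) pc = 1e-12;
    nll -= std::log(pc);

    // outcome update
    double pe = O - m[c];
    double kgain = 0.0;
    if (learner == 0) {            // RW1
      kgain = a;
      m[c] += a * pe;
    } else if (learner == 1) {     // RW2
      kgain = (O == 1.0) ? aPos : aNeg;
      m[c] += kgain * pe;
    } else if (learner == 2) {     // KF
      double tot = w[c] + v;
      kgain = tot / (tot + sigma2);
      m[c] += kgain * pe;
      w[c] = (1.0 - kgain) * tot;
      for (int j = 0; j < A; ++j) if (j != c) w[j] += v;
    } else {                       // VKF
      double wprev = w[c], vprev = vv[c], mprev = m[c];
      double tot = wprev + vprev;
      kgain = tot / (tot + omega);
      m[c] = mprev + kgain * pe;
      double wnew = (1.0 - kgain) * tot;
      double wcov = (1.0 - kgain) * wprev;
      double dm = m[c] - mprev;
      double vnew = vprev + lambda * (dm * dm + wprev + wnew - 2.0 * wcov - vprev);
      w[c] = wnew;
      vv[c] = (vnew > vfloor) ? vnew : vfloor;
      for (int j = 0; j < A; ++j) if (j != c) w[j] += vv[j];
    }
    if (!std::isfinite(m[c]))
      stop("non-finite learner state at trial %d", t + 1);

    K[t] = kgain; PE[t] = pe;
    double sm2 = 0.0, sw2 = 0.0;
    for (int j = 0; j < A; ++j) { sm2 += m[j]; sw2 += w[j]; }
    RV[t] = (sm2 > 0.0) ? m[c] / sm2 : NA_REAL;
    RU[t] = (sw2 > 0.0) ? w[c] / sw2 : NA_REAL;
    for (int j = 0; j < A; ++j) {
      M(t, j) = m[j]; W(t, j) = w[j];
      if (learner == 3) Vol(t, j) = vv[j];
    }
  }
  return List::create(_["m"] = M, _["w"] = W, _["v"] = Vol, _["k"] = K,
                      _["pe"] = PE, _["rv"] = RV, _["ru"] = RU,
                      _["probs"] = P, _["nll"] = nll);
}

// 4-connected component labeling of a logical matrix (time x frequency).
// Returns an integer matrix of labels (0 = background), labels 1..K.
// [[Rcpp::export]]
IntegerMatrix cpp_label4(LogicalMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (!x(i, j) || lab(i, j)) continue;
    ++next;
    stack.clear();
    stack.push_back(i + j * nr);
    lab(i, j) = next;
    while (!stack.empty()) {
      int idx = stack.back(); stack.pop_back();
      int ci = idx % nr, cj = idx / nr;
      const int di[4] = {-1, 1, 0, 0};
      const int dj[4] = {0, 0, -1, 1};
      for (int d = 0; d < 4; ++d) {
        int ni = ci + di[d], nj = cj + dj[d];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        if (x(ni, nj) && !lab(ni, nj)) {
          lab(ni, nj) = next;
          stack.push_back(ni + nj * nr);
        }
      }
    }
  }
  lab.attr("nLabels") = next;
  return lab;
}
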