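// Per-vertex correspondence search: for each source vertex, candidate target
// vertices within rho of its pre-aligned position are scored by the
// neighborhood correlation under a locally refined rigid transform (Kabsch on
// nearest-neighbor pairings). Hot loop of the registration; the R wrappers
// own validation, defaults and error reporting. Point sets are kept as
// per-coordinate arrays so the nearest-neighbor scans vectorize.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Pts {  // structure-of-arrays point set
  std::vector<double> x, y, z;
  size_t n = 0;
  void clear() {
    x.clear();
    y.clear();
    z.clear();
    n = 0;
  }
  void push(double xi, double yi, double zi) {
    x.push_back(xi);
    y.push_back(yi);
    z.push_back(zi);
    ++n;
  }
  void resize(size_t m) {
    x.resize(m);
    y.resize(m);
    z.resize(m);
    n = m;
  }
};

// optimal rotation about a pinned pair of centers: minimizes
// sum |R u_i - v_i|^2 over proper rotations, where u/v are positions
// relative to the pinned source vertex and candidate vertex. Leaves R
// unchanged when the configuration is rotationally degenerate.
void kabsch_rotation(const Pts &U, const Pts &V, double R[9]) {
  double H[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  for (size_t i = 0; i < U.n; ++i) {
    const double u[3] = {U.x[i], U.y[i], U.z[i]};
    const double v[3] = {V.x[i], V.y[i], V.z[i]};
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) H[3 * a + b] += u[a] * v[b];
  }
  mat Hm(3, 3);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) Hm(a, b) = H[3 * a + b];
  mat Us, Vs;
  vec s;
  if (!svd(Us, s, Vs, Hm) || s(1) <= 1e-12 * std::max(s(0), 1e-300)) return;
  mat D = eye(3, 3);
  if (det(Vs * Us.t()) < 0) D(2, 2) = -1.0;
  mat Rm = Vs * D * Us.t();
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) R[3 * a + b] = Rm(a, b);
}

inline void apply_rt(const Pts &X, const double R[9], const double t[3],
                     Pts &out) {
  out.resize(X.n);
  for (size_t i = 0; i < X.n; ++i) {
    const double a = X.x[i], b = X.y[i], c = X.z[i];
    out.x[i] = R[0] * a + R[1] * b + R[2] * c + t[0];
    out.y[i] = R[3] * a + R[4] * b + R[5] * c + t[1];
    out.z[i] = R[6] * a + R[7] * b + R[8] * c + t[2];
  }
}

// for each point of X, copy its nearest point of Q into Y; the distance pass
// is branch-free so it vectorizes, the argmin scan runs separately
inline void nearest_pts(const Pts &X, const Pts &Q, Pts &Y,
                        std::vector<double> &buf) {
  Y.resize(X.n);
  const size_t k = Q.n;
  const double *qx = Q.x.data(), *qy = Q.y.data(), *qz = Q.z.data();
  buf.resize(k);
  double *d2 = buf.data();
  for (size_t i = 0; i < X.n; ++i) {
    const double xi = X.x[i], yi = X.y[i], zi = X.z[i];
    for (size_t j = 0; j < k; ++j) {
      const double dx = xi - qx[j], dy = yi - qy[j], dz = zi - qz[j];
      d2[j] = dx * dx + dy * dy + dz * dz;
    }
    size_t bj = 0;
    double best = d2[0];
    for (size_t j = 1; j < k; ++j) {
      if (d2[j] < best) {
        best = d2[j];
        bj = j;
      }
    }
    Y.x[i] = qx[bj];
    Y.y[i] = qy[bj];
    Y.z[i] = qz[bj];
  }
}

// Pearson correlation of the two centered, flattened coordinate vectors
double corr_score(const Pts &X, const Pts &Y) {
  const size_t m = X.n;
  double cx[3] = {0, 0, 0}, cy[3] = {0, 0, 0};
  for (size_t i = 0; i < m; ++i) {
    cx[0] += X.x[i];
    cx[1] += X.y[i];
    cx[2] += X.z[i];
    cy[0] += Y.x[i];
    cy[1] += Y.y[i];
    cy[2] += Y.z[i];
  }
  for (int a = 0; a < 3; ++a) {
    cx[a] /= m;
    cy[a] /= m;
  }
  double sxy = 0, sxx = 0, syy = 0;
  for (size_t i = 0; i < m; ++i) {
    const double u0 = X.x[i] - cx[0], u1 = X.y[i] - cx[1], u2 = X.z[i] - cx[2];
    const double v0 = Y.x[i] - cy[0], v1 = Y.y[i] - cy[1], v2 = Y.z[i] - cy[2];
    sxy += u0 * v0 + u1 * v1 + u2 * v2;
    sxx += u0 * u0 + u1 * u1 + u2 * u2;
    syy += v0 * v0 + v1 * v1 + v2 * v2;
  }
  if (sxx == 0.0 || syy == 0.0) return -std::numeric_limits<double>::infinity();
  double r = sxy / std::sqrt(sxx * syy);
  return std::max(-1.0, std::min(1.0, r));
}

void ball_query(const double *px, const double *py, const double *pz, size_t n,
                const double c[3], double r2, Pts &out) {
  out.clear();
  for (size_t i = 0; i < n; ++i) {
    const double dx = px[i] - c[0], dy = py[i] - c[1], dz = pz[i] - c[2];
    if (dx * dx + dy * dy + dz * dz <= r2) out.push(px[i], py[i], pz[i]);
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_match_vertices")]]
arma::mat cpp_match_vertices(const arma::mat &src, const arma::mat &tgt,
                             const arma::ivec &js, double r, double rho,
                             const arma::mat &preR, const arma::vec &pret,
                             int max_refine, double score_tol,
                             const arma::ivec &exclude,
                             const arma::mat &pred) {
  // pred: optional n_src x 3 predicted target-space positions used for the
  // distance tie-break (smoothness prior); empty -> the pre-aligned position
  const size_t ns = src.n_rows, nt = tgt.n_rows;
  const double *SX = src.colptr(0), *SY = src.colptr(1), *SZ = src.colptr(2);
  const double *TX = tgt.colptr(0), *TY = tgt.colptr(1), *TZ = tgt.colptr(2);
  const double r2 = r * r;
  const bool bounded = std::isfinite(rho);
  const double rho2 = rho * rho;
  double R0[9], t0[3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) R0[3 * a + b] = preR(a, b);
  for (int a = 0; a < 3; ++a) t0[a] = pret(a);

  // target neighborhoods are reused across source vertices: cache lazily
  std::vector<Pts> tgt_nb(nt);
  std::vector<bool> tgt_nb_done(nt, false);

  std::vector<bool> excluded(nt, false);
  for (uword i = 0; i < exclude.n_elem; ++i) {
    if (exclude(i) >= 1 && exclude(i) <= (int)nt) excluded[exclude(i) - 1] = true;
  }

  mat out(js.n_elem, 15);
  out.fill(datum::nan);
  Pts Qs, X, Y;
  std::vector<double> nnbuf;

  for (uword qrow = 0; qrow < js.n_elem; ++qrow) {
    const size_t j = (size_t)(js(qrow) - 1);
    const double pj[3] = {SX[j], SY[j], SZ[j]};
    double p0[3];
    for (int a = 0; a < 3; ++a)
      p0[a] = R0[3 * a] * pj[0] + R0[3 * a + 1] * pj[1] +
              R0[3 * a + 2] * pj[2] + t0[a];

    double pp[3] = {p0[0], p0[1], p0[2]};
    if (pred.n_rows == ns) {
      pp[0] = pred(j, 0);
      pp[1] = pred(j, 1);
      pp[2] = pred(j, 2);
    }

    ball_query(SX, SY, SZ, ns, pj, r2, Qs);
    // neighborhood relative to the pinned source vertex
    Pts Qrel;
    Qrel.resize(Qs.n);
    for (size_t i = 0; i < Qs.n; ++i) {
      Qrel.x[i] = Qs.x[i] - pj[0];
      Qrel.y[i] = Qs.y[i] - pj[1];
      Qrel.z[i] = Qs.z[i] - pj[2];
    }

    std::vector<size_t> cand;
    std::vector<double> cdist;
    for (size_t c = 0; c < nt; ++c) {
      if (excluded[c]) continue;
      const double dx = TX[c] - p0[0], dy = TY[c] - p0[1], dz = TZ[c] - p0[2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (!bounded || d2 <= rho2) {
        const double ex = TX[c] - pp[0], ey = TY[c] - pp[1], ez = TZ[c] - pp[2];
        cand.push_back(c);
        cdist.push_back(ex * ex + ey * ey + ez * ez);
      }
    }
    if (cand.empty()) {
      out(qrow, 0) = -1;  // signals no-candidate to the R wrapper
      continue;
    }

    std::vector<double> scores(cand.size());
    std::vector<double> Rs(9 * cand.size()), Ts(3 * cand.size());

    for (size_t ci = 0; ci < cand.size(); ++ci) {
      const size_t c = cand[ci];
      if (!tgt_nb_done[c]) {
        const double pc[3] = {TX[c], TY[c], TZ[c]};
        ball_query(TX, TY, TZ, nt, pc, r2, tgt_nb[c]);
        tgt_nb_done[c] = true;
      }
      const Pts &Qt = tgt_nb[c];
      const double pc[3] = {TX[c], TY[c], TZ[c]};

      // rigid constraint: the transform pins the source vertex onto the
      // candidate (t = pc - R pj); only the rotation is refined
      double R[9], t[3];
      std::copy(R0, R0 + 9, R);
      auto pin_translation = [&]() {
        for (int a = 0; a < 3; ++a)
          t[a] = pc[a] -
                 (R[3 * a] * pj[0] + R[3 * a + 1] * pj[1] + R[3 * a + 2] * pj[2]);
      };
      pin_translation();

      double score = -std::numeric_limits<double>::infinity();
      if (Qs.n >= 2 && Qt.n >= 2) {
        Pts Yrel;
        for (int it = 0; it < max_refine; ++it) {
          apply_rt(Qs, R, t, X);
          nearest_pts(X, Qt, Y, nnbuf);
          Yrel.resize(Y.n);
          for (size_t i = 0; i < Y.n; ++i) {
            Yrel.x[i] = Y.x[i] - pc[0];
            Yrel.y[i] = Y.y[i] - pc[1];
            Yrel.z[i] = Y.z[i] - pc[2];
          }
          double Rn[9];
          std::copy(R, R + 9, Rn);
          kabsch_rotation(Qrel, Yrel, Rn);
          double delta = 0;
          for (int a = 0; a < 9; ++a)
            delta = std::max(delta, std::fabs(Rn[a] - R[a]));
          std::copy(Rn, Rn + 9, R);
          pin_translation();
          if (delta < 1e-10) break;
        }
        apply_rt(Qs, R, t, X);
        nearest_pts(X, Qt, Y, nnbuf);
        score = corr_score(X, Y);
      }

      scores[ci] = score;
      std::copy(R, R + 9, &Rs[9 * ci]);
      std::copy(t, t + 3, &Ts[3 * ci]);
    }

    // candidates within score_tol of the maximum are treated as tied;
    // ties go to the smallest distance from the pre-aligned position,
    // then to the smallest index
    double smax = *std::max_element(scores.begin(), scores.end());
    size_t best = 0;
    bool have = false;
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      if (scores[ci] < smax - score_tol) continue;
      if (!have || cdist[ci] < cdist[best] ||
          (cdist[ci] == cdist[best] && cand[ci] < cand[best])) {
        best = ci;
        have = true;
      }
    }

    out(qrow, 0) = cand[best] + 1;
    out(qrow, 1) = scores[best];
    for (int a = 0; a < 9; ++a) out(qrow, 2 + a) = Rs[9 * best + a];
    for (int a = 0; a < 3; ++a) out(qrow, 11 + a) = Ts[3 * best + a];
    out(qrow, 14) = cand.size();
  }
  return out;
}
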