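#include <Rcpp.h>
#include <cmath>
#include <complex>
#include <vector>
using namespace Rcpp;

// minimum pairwise distance between two point sets (nm)
// [[Rcpp::export]]
double cpp_min_pair_dist(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// keep[i] = TRUE iff cand row i is at least `clearance` away from every
// protein atom
// [[Rcpp::export]]
LogicalVector cpp_clearance_keep(NumericMatrix cand, NumericMatrix prot,
                                 double clearance) {
  const int n = cand.nrow(), m = prot.nrow();
  const double c2 = clearance * clearance;
  LogicalVector keep(n);
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    const double cx = cand(i, 0), cy = cand(i, 1), cz = cand(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = cx - prot(j, 0), dy = cy - prot(j, 1),
                   dz = cz - prot(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) { ok = false; break; }
    }
    keep[i] = ok;
  }
  return keep;
}

// all pairwise distances |p_i - q_j| with weights w_i * v_j
// [[Rcpp::export]]
List cpp_pair_distances(NumericMatrix P, NumericVector w,
                        NumericMatrix Q, NumericVector v) {
  const int n = P.nrow(), m = Q.nrow();
  NumericVector d(n * m), ww(n * m);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    const double px = P(i, 0), py = P(i, 1), pz = P(i, 2), wi = w[i];
    for (int j = 0; j < m; ++j) {
      const double dx = px - Q(j, 0), dy = py - Q(j, 1), dz = pz - Q(j, 2);
      d[k] = std::sqrt(dx * dx + dy * dy + dz * dz);
      ww[k] = wi * v[j];
      ++k;
    }
  }
  return List::create(_["d"] = d, _["w"] = ww);
}

// Shrake-Rupley SASA (nm^2): fraction of sphere points on each expanded
// atom sphere not inside any other expanded sphere
// [[Rcpp::export]]
double cpp_sasa(NumericMatrix xyz, NumericVector rr, NumericMatrix pts) {
  const int n = xyz.nrow(), np = pts.nrow();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2), ri = rr[i];
    // neighbour list
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1),
                   dz = zi - xyz(j, 2);
      const double lim = ri + rr[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < np; ++p) {
      const double sx = xi + ri * pts(p, 0), sy = yi + ri * pts(p, 1),
                   sz = zi + ri * pts(p, 2);
      bool exposed = true;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double dx = sx - xyz(j, 0), dy = sy - xyz(j, 1),
                     dz = sz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rr[j] * rr[j]) {
          exposed = false; break;
        }
      }
      if (exposed) ++acc;
    }
    total += 4.0 * M_PI * ri * ri * ((double)acc / np);
  }
  return total;
}

static void rot_zy(double alpha_deg, double beta_deg, double R[9]) {
  const double a = alpha_deg * M_PI / 180.0, b = beta_deg * M_PI / 180.0;
  const double ca = std::cos(a), sa = std::sin(a);
  const double cb = std::cos(b), sb = std::sin(b);
  // R = Ry(b) * Rz(a)
  R[0] = cb * ca;  R[1] = -cb * sa; R[2] = sb;
  R[3] = sa;       R[4] = ca;       R[5] = 0.0;
  R[6] = -sb * ca; R[7] = sb * sa;  R[8] = cb;
}

// Exhaustive C2 docking grid evaluation.
// protomer: centred CA coordinates (n x 3).
// ens: list of per-site ensembles, each list(positions = k x 3 [centred
//      protomer frame], weights = k).
// targets: per-site restraint mean distances (nm).
// Returns matrix with columns (alpha, beta, x, y, rmsd, min_dist,
// mean_1..mean_S) for every clash-free node in contact.
// [[Rcpp::export]]
NumericMatrix cpp_grid_search(NumericMatrix protomer, List ens,
                              NumericVector targets,
                              NumericVector alphas, NumericVector betas,
                              NumericVector xs, NumericVector ys,
                              double clash_cut, double contact_cut) {
  const int n = protomer.nrow();
  const int S = ens.size();
  const double clash2 = clash_cut * clash_cut;
  const double contact2 = contact_cut * contact_cut;

  std::vector<NumericMatrix> epos(S);
  std::vector<NumericVector> ew(S);
  for (int s = 0; s < S; ++s) {
    List e = ens[s];
    epos[s] = as<NumericMatrix>(e["positions"]);
    ew[s] = as<NumericVector>(e["weights"]);
  }

  std::vector<double> rows;  // flat result buffer
  const int ncol = 6 + S;

  std::vector<double> qx(n), qy(n), qz(n);
  // pair buffers for CA clash/contact
  std::vector<double> pcx, pcy, pdz2;
  pcx.reserve((size_t)n * n); pcy.reserve((size_t)n * n);
  pdz2.reserve((size_t)n * n);

  for (int ia = 0; ia < alphas.size(); ++ia) {
    for (int ib = 0; ib < betas.size(); ++ib) {
      double R[9];
      rot_zy(alphas[ia], betas[ib], R);
      double rg2 = 0.0;
      for (int i = 0; i < n; ++i) {
        const double px = protomer(i, 0), py = protomer(i, 1),
                     pz = protomer(i, 2);
        qx[i] = R[0] * px + R[1] * py + R[2] * pz;
        qy[i] = R[3] * px + R[4] * py + R[5] * pz;
        qz[i] = R[6] * px + R[7] * py + R[8] * pz;
        const double r2 = qx[i] * qx[i] + qy[i] * qy[i] + qz[i] * qz[i];
        if (r2 > rg2) rg2 = r2;
      }
      const double rg = std::sqrt(rg2);
      // candidate CA pairs: distance^2 = (2x + sx)^2 + (2y + sy)^2 + dz^2
      pcx.clear(); pcy.clear(); pdz2.clear();
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) {
          const double dz = qz[i] - qz[j];
          if (std::fabs(dz) > contact_cut) continue;
          pcx.push_back(qx[i] + qx[j]);
          pcy.push_back(qy[i] + qy[j]);
          pdz2.push_back(dz * dz);
        }
      const size_t np = pcx.size();
      if (np == 0) continue;

      // rotated ensembles
      std::vector<std::vector<double> > ex(S), ey(S), ez(S);
      for (int s = 0; s < S; ++s) {
        const int k = epos[s].nrow();
        ex[s].resize(k); ey[s].resize(k); ez[s].resize(k);
        for (int i = 0; i < k; ++i) {
          const double px = epos[s](i, 0), py = epos[s](i, 1),
                       pz = epos[s](i, 2);
          ex[s][i] = R[0] * px + R[1] * py + R[2] * pz;
          ey[s][i] = R[3] * px + R[4] * py + R[5] * pz;
          ez[s][i] = R[6] * px + R[7] * py + R[8] * pz;
        }
      }

      // Mark, per (x, y) node, whether any CA pair clashes or is in
      // contact: pair p constrains node (x, y) iff
      // (2x + sx)^2 + (2y + sy)^2 + dz^2 {<, <=} cut^2, i.e. (x, y) lies
      // in a disc of radius sqrt(cut^2 - dz^2)/2 around (-sx/2, -sy/2).
      // Exact inequality is evaluated per node inside the disc's
      // bounding box, so marking introduces no approximation.
      const int nx = xs.size(), ny = ys.size();
      const double x0 = xs[0], y0 = ys[0];
      const double hx = nx > 1 ? xs[1] - xs[0] : 1.0;
      const double hy = ny > 1 ? ys[1] - ys[0] : 1.0;
      std::vector<char> mclash((size_t)nx * ny, 0),
                        mcontact((size_t)nx * ny, 0);
      for (size_t p = 0; p < np; ++p) {
        const double cx = -0.5 * pcx[p], cy = -0.5 * pcy[p];
        const double lim2 = contact2 - pdz2[p];
        if (lim2 < 0) continue;
        const double rad = 0.5 * std::sqrt(lim2);
        const double cl2 = clash2 - pdz2[p];  // may be < 0 (no clash possible)
        int ix0 = (int)std::ceil((cx - rad - x0) / hx);
        int ix1 = (int)std::floor((cx + rad - x0) / hx);
        if (ix0 < 0) ix0 = 0;
        if (ix1 > nx - 1) ix1 = nx - 1;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double ddx = 2.0 * xs[ix] + pcx[p];
          int iy0 = (int)std::ceil((cy - rad - y0) / hy);
          int iy1 = (int)std::floor((cy + rad - y0) / hy);
          if (iy0 < 0) iy0 = 0;
          if (iy1 > ny - 1) iy1 = ny - 1;
          for (int iy = iy0; iy <= iy1; ++iy) {
            const double ddy = 2.0 * ys[iy] + pcy[p];
            const double dxy2 = ddx * ddx + ddy * ddy;
            const double d2 = dxy2 + pdz2[p];
            if (d2 <= contact2) {
              mcontact[(size_t)ix * ny + iy] = 1;
              if (d2 < clash2) mclash[(size_t)ix * ny + iy] = 1;
            }
          }
        }
      }
      for (int ix = 0; ix < nx; ++ix) {
        const double x = xs[ix], tx = 2.0 * x;
        for (int iy = 0; iy < ny; ++iy) {
          const size_t node = (size_t)ix * ny + iy;
          if (!mcontact[node] || mclash[node]) continue;
          const double y = ys[iy], ty = 2.0 * y;
          double mind2 = R_PosInf;
          for (size_t p = 0; p < np; ++p) {
            const double ddx = tx + pcx[p], ddy = ty + pcy[p];
            const double d2 = ddx * ddx + ddy * ddy + pdz2[p];
            if (d2 < mind2) mind2 = d2;
          }
          // score: per-site mean inter-copy distance
          double sumsq = 0.0;
          std::vector<double> means(S);
          for (int s = 0; s < S; ++s) {
            const int k = (int)ex[s].size();
            double acc = 0.0, wacc = 0.0;
            for (int i = 0; i < k; ++i) {
              const double axp = ex[s][i] + tx, ayp = ey[s][i] + ty;
              const double wi = ew[s][i];
              for (int j = 0; j < k; ++j) {
                const double ddx = axp + ex[s][j], ddy = ayp + ey[s][j];
                const double ddz = ez[s][i] - ez[s][j];
                const double w = wi * ew[s][j];
                acc += w * std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
                wacc += w;
              }
            }
            means[s] = acc / wacc;
            const double dlt = means[s] - targets[s];
            sumsq += dlt * dlt;
          }
          rows.push_back(alphas[ia]);
          rows.push_back(betas[ib]);
          rows.push_back(x);
          rows.push_back(y);
          rows.push_back(std::sqrt(sumsq / S));
          rows.push_back(std::sqrt(mind2));
          for (int s = 0; s < S; ++s) rows.push_back(means[s]);
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  const int nr = (int)(rows.size() / ncol);
  NumericMatrix out(nr, ncol);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < ncol; ++j) out(i, j) = rows[(size_t)i * ncol + j];
  return out;
}

// Fresnel integrals C(x), S(x) in the normalization
// C(x) = int_0^x cos(pi t^2/2) dt. Power series for |x| < 1.5, modified
// Lentz continued fraction on the complex error-function route otherwise.
// [[Rcpp::export]]
List cpp_fresnel_cs(NumericVector x) {
  const double EPS = 6e-15;
  const int MAXIT = 200;
  const int n = x.size();
  NumericVector C(n), S(n);
  for (int i = 0; i < n; ++i) {
    const double ax = std::fabs(x[i]);
    double cc_out, ss_out;
    if (ax < 1e-150) {
      cc_out = ax; ss_out = 0.0;
    } else if (ax < 1.5) {
      const double x2 = ax * ax;
      const double q = (M_PI / 2.0) * (M_PI / 2.0) * x2 * x2;
      double csum = 0.0, term = ax;
      for (int k = 0; k < MAXIT; ++k) {
        csum += term / (4 * k + 1);
        term *= -q / ((2 * k + 1.0) * (2 * k + 2.0));
        if (std::fabs(term) < EPS * std::fabs(csum)) break;
      }
      double ssum = 0.0;
      term = (M_PI / 2.0) * ax * x2;
      for (int k = 0; k < MAXIT; ++k) {
        ssum += term / (4 * k + 3);
        term *= -q / ((2 * k + 2.0) * (2 * k + 3.0));
        if (std::fabs(term) < EPS * std::fabs(ssum) + 1e-300) break;
      }
      cc_out = csum; ss_out = ssum;
    } else {
      const double pix2 = M_PI * ax * ax;
      std::complex<double> b(1.0, -pix2), one(1.0, 0.0);
      std::complex<double> cc(1.0 / 1e-30, 0.0);
      std::complex<double> d = one / b, h = d;
      int nn = -1;
      for (int k = 2; k <= MAXIT; ++k) {
        nn += 2;
        const double a = -nn * (nn + 1.0);
        b += std::complex<double>(4.0, 0.0);
        d = one / (a * d + b);
        cc = b + a / cc;
        const std::complex<double> del = cc * d;
        h *= del;
        if (std::fabs(del.real() - 1.0) + std::fabs(del.imag()) < EPS) break;
      }
      h *= std::complex<double>(ax, -ax);
      const std::complex<double> cs =
        std::complex<double>(0.5, 0.5) *
        (one - std::complex<double>(std::cos(0.5 * pix2),
                                    std::sin(0.5 * pix2)) * h);
      cc_out = cs.real(); ss_out = cs.imag();
    }
    if (x[i] < 0) { cc_out = -cc_out; ss_out = -ss_out; }
    C[i] = cc_out; S[i] = ss_out;
  }
  return List::create(_["C"] = C, _["S"] = S);
}
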