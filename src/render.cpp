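#include <Rcpp.h>
using namespace Rcpp;

// Raster-scan rendering core. A confocal raster scan acquires one image line
// at a time (line period tau_l); particle motion is propagated once per line,
// so within-line displacement (< 0.15 px for D ~ 2 um^2/s) is neglected and
// the fast-axis correlation decay is carried by the PSF alone.
//
// Pixel (row i, col j) is centered at x = (j + 0.5) * dr, y = (i + 0.5) * dr
// (um). A particle at (px, py, pz) adds
//   eps * exp(-2((x-px)^2 + (y-py)^2)/w0^2 - 2 pz^2 / wz^2)
// to pixels of the line scanned while it sits there (focal plane z = 0,
// 1/e^2 radii w0, wz).

static inline void add_line(NumericMatrix &img, int line, int n_cols,
                            double dr, double px, double py, double pz,
                            double eps, double w0, double wz,
                            double cutoff) {
  double y = (line + 0.5) * dr;
  double dy = y - py;
  if (dy > cutoff || dy < -cutoff) return;
  double wz2 = wz * wz, w02 = w0 * w0;
  double wy = eps * std::exp(-2.0 * (dy * dy) / w02 - 2.0 * (pz * pz) / wz2);
  if (wy < 1e-9) return;
  int j0 = (int)std::floor((px - cutoff) / dr - 0.5);
  int j1 = (int)std::ceil((px + cutoff) / dr - 0.5);
  if (j0 < 0) j0 = 0;
  if (j1 > n_cols - 1) j1 = n_cols - 1;
  for (int j = j0; j <= j1; ++j) {
    double dx = (j + 0.5) * dr - px;
    img(line, j) += wy * std::exp(-2.0 * dx * dx / w02);
  }
}

// Render one frame from per-line particle positions (n x n_rows matrices).
// [[Rcpp::export]]
NumericMatrix cpp_render_lines(NumericMatrix pxl, NumericMatrix pyl,
                               NumericMatrix pzl, NumericVector bright,
                               int n_rows, int n_cols, double dr,
                               double w0, double wz, double cutoff) {
  NumericMatrix img(n_rows, n_cols);
  int n = bright.size();
  for (int i = 0; i < n_rows; ++i) {
    for (int p = 0; p < n; ++p) {
      if (bright[p] <= 0) continue;
      add_line(img, i, n_cols, dr, pxl(p, i), pyl(p, i), pzl(p, i),
               bright[p], w0, wz, cutoff);
    }
  }
  return img;
}

// Advance all particles line-by-line through one frame and render both
// channels. Species: 0 = free (Brownian, specularly reflected at the
// nuclear boundary and at the axial box edges, which preserves the uniform
// density and the step statistics),
// 1 = binder (immobile; relocates to a uniform position in its nucleus with
// probability p_jump per line, emulating unbind/rebind at a new site),
// 2 = fixed. Red-channel positions are displaced by off_r (um).
// Positions are updated in place on copies and returned.
// [[Rcpp::export]]
List cpp_advance_render_frame(NumericVector px_, NumericVector py_,
                              NumericVector pz_, IntegerVector species,
                              IntegerVector nucleus, NumericVector bright_g,
                              NumericVector bright_r, NumericMatrix nuclei,
                              double zmin, double zmax, double step_sd,
                              double p_jump, int n_rows, int n_cols,
                              double dr, double w0g, double wzg,
                              double w0r, double wzr, NumericVector off_r,
                              double cutoff) {
  NumericVector px = clone(px_), py = clone(py_), pz = clone(pz_);
  int n = px.size();
  NumericMatrix img_g(n_rows, n_cols), img_r(n_rows, n_cols);
  for (int i = 0; i < n_rows; ++i) {
    for (int p = 0; p < n; ++p) {
      int sp = species[p];
      int k = nucleus[p];
      double cx = nuclei(k, 0), cy = nuclei(k, 1), r = nuclei(k, 2);
      if (sp == 0 && step_sd > 0) {
        double nx = px[p] + R::rnorm(0.0, step_sd);
        double ny = py[p] + R::rnorm(0.0, step_sd);
        double nz = pz[p] + R::rnorm(0.0, step_sd);
        if (nz > zmax) nz = 2.0 * zmax - nz;
        if (nz < zmin) nz = 2.0 * zmin - nz;
        if (nz > zmax) nz = zmax;  // pathological double-crossing
        double ddx = nx - cx, ddy = ny - cy;
        double d2 = ddx * ddx + ddy * ddy;
        if (d2 > r * r) {  // reflect across the (radial) wall
          double d = std::sqrt(d2);
          double dref = 2.0 * r - d;
          if (dref < 0) dref = 0;
          nx = cx + ddx * (dref / d);
          ny = cy + ddy * (dref / d);
        }
        px[p] = nx; py[p] = ny; pz[p] = nz;
      } else if (sp == 1 && p_jump > 0) {
        if (R::unif_rand() < p_jump) {
          double nx, ny;
          do {
            nx = cx + r * (2.0 * R::unif_rand() - 1.0);
            ny = cy + r * (2.0 * R::unif_rand() - 1.0);
          } while ((nx - cx) * (nx - cx) + (ny - cy) * (ny - cy) > r * r);
          px[p] = nx; py[p] = ny;
          pz[p] = zmin + (zmax - zmin) * R::unif_rand();
        }
      }
      if (bright_g[p] > 0)
        add_line(img_g, i, n_cols, dr, px[p], py[p], pz[p], bright_g[p],
                 w0g, wzg, cutoff);
      if (bright_r[p] > 0)
        add_line(img_r, i, n_cols, dr, px[p] + off_r[0], py[p] + off_r[1],
                 pz[p] + off_r[2], bright_r[p], w0r, wzr, cutoff);
    }
  }
  return List::create(_["green"] = img_g, _["red"] = img_r,
                      _["px"] = px, _["py"] = py, _["pz"] = pz);
}
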