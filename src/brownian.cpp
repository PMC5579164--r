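#include <Rcpp.h>
using namespace Rcpp;

// Overdamped 2D Brownian dynamics of non-interacting lipid reference beads in
// a periodic rectangular patch, with
//   - a static reflective disc of radius `rp` at the box centre (the protein
//     cross-section); rp = 0 disables the obstacle,
//   - a per-species piecewise-constant radial diffusivity D(r) evaluated at
//     the step start (Ito convention, no drift correction),
//   - a per-species radial square-well potential (depth in kT, attractive,
//     spanning rp < r <= rp + range) applied through Metropolis acceptance.
//
// Proposals are Gaussian with variance 2*D(r_start)*dt per axis.  A proposal
// landing inside the disc is reflected radially about the disc surface; the
// (possibly reflected) proposal is then accepted or rejected against the
// potential.  Positions are wrapped into [0, L).  Distances to the centre use
// the minimum image so behaviour is consistent arbitrarily close to the box
// boundary.
//
// d_breaks: strictly increasing outer radii (nm) of the D(r) pieces; the last
// piece extends to infinity, so d_values has ncol == length(d_breaks) + 1 and
// one row per species.  Uses R's RNG: results are reproducible via set.seed().
//
// Returns an n x 2 x nframes coordinate array; frame 0 holds the initial
// positions and each subsequent frame follows `stride` substeps of length dt.
// [[Rcpp::export]]
NumericVector brownian_patch_cpp(NumericMatrix xy0, IntegerVector species0,
                                 NumericVector d_breaks, NumericMatrix d_values,
                                 NumericVector well_depth,
                                 NumericVector well_range,
                                 double lx, double ly, double rp,
                                 double dt, int stride, int nframes) {
  const int n = xy0.nrow();
  const int nb = d_breaks.size();
  const double cx = lx / 2.0, cy = ly / 2.0;

  NumericVector coords(Dimension(n, 2, nframes));
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) {
    x[i] = xy0(i, 0);
    y[i] = xy0(i, 1);
  }

  RNGScope rng;

  for (int f = 0; f < nframes; ++f) {
    if (f > 0) {
      for (int s = 0; s < stride; ++s) {
        for (int i = 0; i < n; ++i) {
          const int sp = species0[i];
          // minimum-image vector from the centre
          double rx = x[i] - cx;
          double ry = y[i] - cy;
          rx -= lx * std::floor(rx / lx + 0.5);
          ry -= ly * std::floor(ry / ly + 0.5);
          const double r0 = std::sqrt(rx * rx + ry * ry);

          int k = 0;
          while (k < nb && r0 >= d_breaks[k]) ++k;
          const double sig = std::sqrt(2.0 * d_values(sp, k) * dt);

          double px = x[i] + sig * norm_rand();
          double py = y[i] + sig * norm_rand();

          double qx = px - cx;
          double qy = py - cy;
          qx -= lx * std::floor(qx / lx + 0.5);
          qy -= ly * std::floor(qy / ly + 0.5);
          double rn = std::sqrt(qx * qx + qy * qy);

          if (rp > 0.0 && rn < rp) {
            if (rn < 1e-12) continue;  // degenerate proposal: reject
            const double scale = (2.0 * rp - rn) / rn;
            qx *= scale;
            qy *= scale;
            px = cx + qx;
            py = cy + qy;
            rn = 2.0 * rp - rn;
            if (rn < rp) continue;  // oversized step: reject, keeps density exact
          }

          const double depth = well_depth[sp];
          if (depth > 0.0) {
            const double edge = rp + well_range[sp];
            const double u0 = (r0 <= edge) ? -depth : 0.0;
            const double u1 = (rn <= edge) ? -depth : 0.0;
            const double du = u1 - u0;
            if (du > 0.0 && unif_rand() > std::exp(-du)) continue;
          }

          x[i] = px - lx * std::floor(px / lx);
          y[i] = py - ly * std::floor(py / ly);
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      coords[i + n * (0 + 2 * f)] = x[i];
      coords[i + n * (1 + 2 * f)] = y[i];
    }
  }
  return coords;
}
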