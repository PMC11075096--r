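#include <Rcpp.h>
using namespace Rcpp;

// Dark-field reflectance by photon random walk in a semi-infinite turbid
// medium. Photons launch at the incidence angle over a source disc on the
// surface (z = 0, z positive into the medium), take exponential free
// paths with mu_t = mu_s + mu_a, scatter by inverse-CDF sampling of the
// tabulated Mie phase function, and lose weight by the survival factor
// mu_s/mu_t at each interaction. A photon is collected when it exits the
// top surface inside the collection field of view with an exit polar
// angle inside the objective's acceptance cone. The surface is treated
// as refractive-index matched (no Fresnel deflection). Uses R's RNG so
// set.seed() gives bit-reproducible results.
//
// cos_quantiles: inverse CDF of cos(theta) evaluated at uniform
// quantiles (length nq); sampling interpolates linearly between entries.
// [[Rcpp::export]]
List mc_darkfield_cpp(double mus, double mua, NumericVector cos_quantiles,
                      double theta_inc, double src_radius, double fov_radius,
                      double cos_collect, int n_photons, double max_depth,
                      int max_steps, int collected_cap) {
  const double mut = mus + mua;
  const int nq = cos_quantiles.size();
  double collected_w = 0.0, escaped_w = 0.0, truncated_w = 0.0,
         absorbed_w = 0.0, collected_w2 = 0.0;
  int n_collected = 0, n_launched = 0;
  const double albedo = (mut > 0.0) ? mus / mut : 0.0;
  const double sin_inc = std::sin(theta_inc), cos_inc = std::cos(theta_inc);
  const double wmin = 1e-7;

  for (int ip = 0; ip < n_photons; ip++) {
    if (collected_cap > 0 && n_collected >= collected_cap) break;
    n_launched++;
    // launch uniformly over the source disc, tilted beam in the x-z plane
    double rr = src_radius * std::sqrt(unif_rand());
    double phi0 = 2.0 * M_PI * unif_rand();
    double x = rr * std::cos(phi0), y = rr * std::sin(phi0), z = 0.0;
    double ux = sin_inc, uy = 0.0, uz = cos_inc;
    double w = 1.0;
    bool done = false;

    for (int step = 0; step < max_steps && !done; step++) {
      double s = -std::log(unif_rand()) / mut;
      double zn = z + uz * s;
      if (uz < 0.0 && zn <= 0.0) {
        // crosses the surface: find the exit point
        double t = -z / uz;
        double xe = x + ux * t, ye = y + uy * t;
        bool in_fov = (xe * xe + ye * ye) <= fov_radius * fov_radius;
        bool in_cone = (-uz) >= cos_collect;
        if (in_fov && in_cone) {
          collected_w += w;
          collected_w2 += w * w;
          n_collected++;
        } else {
          escaped_w += w;
        }
        done = true;
        break;
      }
      x += ux * s; y += uy * s; z = zn;
      if (z > max_depth) { truncated_w += w; done = true; break; }
      // absorption by survival weighting
      absorbed_w += w * (1.0 - albedo);
      w *= albedo;
      if (w < wmin) { absorbed_w += w; done = true; break; }
      // scatter: cos(theta) from the tabulated inverse CDF
      double u = unif_rand() * (nq - 1);
      int i0 = (int)std::floor(u);
      if (i0 >= nq - 1) i0 = nq - 2;
      double frac = u - i0;
      double ct = cos_quantiles[i0] * (1.0 - frac) + cos_quantiles[i0 + 1] * frac;
      if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      double st = std::sqrt(1.0 - ct * ct);
      double psi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(psi), sp = std::sin(psi);
      double nux, nuy, nuz;
      if (std::fabs(uz) > 0.99999) {
        nux = st * cp;
        nuy = st * sp;
        nuz = ct * (uz >= 0 ? 1.0 : -1.0);
      } else {
        double denom = std::sqrt(1.0 - uz * uz);
        nux = st * (ux * uz * cp - uy * sp) / denom + ux * ct;
        nuy = st * (uy * uz * cp + ux * sp) / denom + uy * ct;
        nuz = -st * cp * denom + uz * ct;
      }
      double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
      ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
    }
    if (!done) truncated_w += w;  // ran out of steps
  }

  return List::create(
    _["collected_weight"] = collected_w,
    _["collected_weight_sq"] = collected_w2,
    _["n_collected"] = n_collected,
    _["n_launched"] = n_launched,
    _["escaped_weight"] = escaped_w,
    _["truncated_weight"] = truncated_w,
    _["absorbed_weight"] = absorbed_w);
}
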