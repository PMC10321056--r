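#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) trajectory on the separable model
// potential plus one umbrella restraint:
//   dr = -(D/RT) grad(U + U_bias) dt + sqrt(2 D dt) xi
// Noise is drawn from R's global RNG (norm_rand), so set.seed() in R gives
// bit-for-bit reproducibility.  Positions are recorded every sample_every
// steps; the step is aborted if any displacement component exceeds
// max_step (declared stability bound).
// [[Rcpp::export]]
NumericMatrix bd_trajectory_cpp(NumericVector start,
                                NumericVector amp, NumericVector ctr,
                                NumericVector wid, double radial_k,
                                double RT, double diffusion, double dt,
                                int n_steps, int sample_every,
                                double z_center, double k_z,
                                double r_cyl, double k_fb,
                                double max_step) {
  const int ng = amp.size();
  const double pref = diffusion / RT * dt;
  const double noise = std::sqrt(2.0 * diffusion * dt);
  double x = start[0], y = start[1], z = start[2];
  const int n_out = n_steps / sample_every;
  NumericMatrix out(n_out, 4);
  int row = 0;
  RNGScope scope;
  for (int s = 1; s <= n_steps; ++s) {
    // axial force: Gaussian landscape + umbrella
    double fz = 0.0;
    for (int i = 0; i < ng; ++i) {
      const double d = z - ctr[i];
      const double w2 = wid[i] * wid[i];
      fz += -amp[i] * d / w2 * std::exp(-d * d / (2.0 * w2));
    }
    fz += k_z * (z - z_center);
    // lateral force: harmonic confinement + flat-bottom wall
    double fx = radial_k * x;
    double fy = radial_k * y;
    const double r = std::sqrt(x * x + y * y);
    if (r > r_cyl && r > 0.0) {
      const double fw = k_fb * (r - r_cyl) / r;
      fx += fw * x;
      fy += fw * y;
    }
    // instability check on the deterministic drift (D/RT * F * dt):
    // an Euler-Maruyama step whose drift approaches the potential's
    // length scale no longer samples the right stationary law
    const double drift = pref * std::sqrt(fx * fx + fy * fy + fz * fz);
    if (drift > max_step) {
      stop("Brownian step %d exceeds the stability bound (%.3g A): "
           "drift |D/RT * F * dt| = %.3g A; reduce dt or diffusion",
           s, max_step, drift);
    }
    x += -pref * fx + noise * norm_rand();
    y += -pref * fy + noise * norm_rand();
    z += -pref * fz + noise * norm_rand();
    if (s % sample_every == 0) {
      out(row, 0) = s * dt;
      out(row, 1) = z;
      out(row, 2) = x;
      out(row, 3) = y;
      ++row;
    }
  }
  colnames(out) = CharacterVector::create("t", "z", "x", "y");
  return out;
}
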