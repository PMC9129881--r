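#include <Rcpp.h>
using namespace Rcpp;

// One pass of the dispersal step over the seed arrays: every seed held on a
// tree samples a wind observation, flies ballistically (release height times
// horizontal speed over fall velocity, times a median-1 lognormal turbulence
// factor), wraps across the east-west margins, and lands on the ground.
// Seeds leaving the transect poleward or equatorward are dropped. Uses R's
// RNG (one uniform + one normal per released seed), so runs are
// reproducible under set.seed().
// [[Rcpp::export]]
List disperse_step_cpp(NumericVector sx, NumericVector sy, IntegerVector sage,
                       LogicalVector son, NumericVector srel,
                       double width, double length_m,
                       NumericVector wind_speed, NumericVector wind_dir,
                       double fall_velocity, double turb_sdlog) {
  const int n = sx.size();
  const int nw = wind_speed.size();
  std::vector<double> ox, oy, orel;
  std::vector<int> oage;
  std::vector<int> oson;
  ox.reserve(n); oy.reserve(n); orel.reserve(n); oage.reserve(n);
  oson.reserve(n);
  for (int i = 0; i < n; ++i) {
    double x = sx[i], y = sy[i];
    bool on = son[i];
    if (on) {
      int k = (int)(unif_rand() * nw);
      if (k >= nw) k = nw - 1;
      const double dist = srel[i] * wind_speed[k] / fall_velocity *
        std::exp(norm_rand() * turb_sdlog);
      const double th = wind_dir[k] * M_PI / 180.0;
      x += dist * std::sin(th);
      x -= width * std::floor(x / width);  // wrap east-west
      y += dist * std::cos(th);
      on = false;
    }
    if (y < 0 || y > length_m) continue;
    ox.push_back(x); oy.push_back(y); oage.push_back(sage[i]);
    oson.push_back(on); orel.push_back(srel[i]);
  }
  return List::create(_["sx"] = wrap(ox), _["sy"] = wrap(oy),
                      _["sage"] = wrap(oage),
                      _["son"] = LogicalVector(oson.begin(), oson.end()),
                      _["srel"] = wrap(orel));
}

// One pass of establishment + seed mortality + ageing: ground seeds
// germinate with probability germ_max * ramp((t_jul - t_lo)/(t_hi - t_lo))
// using the current-year July temperature linearly interpolated between
// climate nodes (clamped at the span ends); all remaining seeds face the
// constant mortality rate, age by one year and are removed past the species
// seed age limit. Germinated positions are returned for seedling creation.
// [[Rcpp::export]]
List seed_fate_cpp(NumericVector sx, NumericVector sy, IntegerVector sage,
                   LogicalVector son, NumericVector srel,
                   NumericVector node_m, NumericVector tjul_cur,
                   double germ_max, double t_lo, double t_hi,
                   double seed_mort, int seed_age_max) {
  const int n = sx.size();
  const int nn = node_m.size();
  std::vector<double> ox, oy, orel, gx, gy;
  std::vector<int> oage, oson;
  ox.reserve(n); oy.reserve(n); orel.reserve(n); oage.reserve(n);
  oson.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (!son[i]) {
      // interpolated current July temperature at the seed position
      double t;
      if (nn == 1) {
        t = tjul_cur[0];
      } else {
        int k = 0;
        while (k < nn - 2 && sy[i] >= node_m[k + 1]) ++k;
        double f = (sy[i] - node_m[k]) / (node_m[k + 1] - node_m[k]);
        if (f < 0) f = 0; if (f > 1) f = 1;
        t = tjul_cur[k] * (1 - f) + tjul_cur[k + 1] * f;
      }
      double r = (t - t_lo) / (t_hi - t_lo);
      if (r < 0) r = 0; if (r > 1) r = 1;
      const double p = germ_max * r;
      if (unif_rand() < p) {
        gx.push_back(sx[i]); gy.push_back(sy[i]);
        continue;
      }
    }
    if (unif_rand() < seed_mort) continue;
    const int age = sage[i] + 1;
    if (age > seed_age_max) continue;
    ox.push_back(sx[i]); oy.push_back(sy[i]); oage.push_back(age);
    oson.push_back(son[i]); orel.push_back(srel[i]);
  }
  return List::create(_["sx"] = wrap(ox), _["sy"] = wrap(oy),
                      _["sage"] = wrap(oage),
                      _["son"] = LogicalVector(oson.begin(), oson.end()),
                      _["srel"] = wrap(orel),
                      _["germ_x"] = wrap(gx), _["germ_y"] = wrap(gy));
}
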