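# Life-cycle process operations and the yearly loop.

p0 <- larch_params()

test_that("environment update matches the closed-form kernel", {
  cfg <- simulation_config(transect_length_km = 1, transect_width_m = 20)
  aux <- tibble::tibble(node_km = 0, ndd0 = 0)
  empty <- update_environment(tibble::tibble(x_m = numeric(0),
                                             y_m = numeric(0),
                                             basal_cm = numeric(0),
                                             height_m = numeric(0)),
                              aux, cfg, p0, field = TRUE, cell_m = 0.5)
  expect_true(all(empty$density_field == 0))
  expect_equal(unname(empty$active_layer_depth_cm), 0)

  # two trees 1 m apart: each tree's density index is the other's kernel
  # value at distance 1, and the field at the midpoint is the sum of both
  trees <- tibble::tibble(x_m = c(10, 10), y_m = c(500, 501),
                          basal_cm = c(2, 4), height_m = c(1.0, 1.8))
  env <- update_environment(trees, tibble::tibble(node_km = 0, ndd0 = 900),
                            cfg, p0)
  r1 <- p0$r0_crown + p0$r_per_h * 1.0
  r2 <- p0$r0_crown + p0$r_per_h * 1.8
  expect_equal(env$density_index[1], 4 * max(0, 1 - 1 / r2))
  expect_equal(env$density_index[2], 2 * max(0, 1 - 1 / r1))
  expect_equal(unname(env$active_layer_depth_cm),
               p0$edaphic_factor * sqrt(900))

  # gridded field at the midpoint cell against hand-computed kernel sum
  envf <- update_environment(trees, tibble::tibble(node_km = 0, ndd0 = 0),
                             cfg, p0, field = TRUE, cell_m = 0.1)
  cell <- 0.1
  ix <- floor(10 / cell) + 1
  iy <- floor(500.5 / cell) + 1
  xc <- (ix - 0.5) * cell
  yc <- (iy - 0.5) * cell
  d1 <- sqrt((xc - 10)^2 + (yc - 500)^2)
  d2 <- sqrt((xc - 10)^2 + (yc - 501)^2)
  hand <- 2 * max(0, 1 - d1 / r1) + 4 * max(0, 1 - d2 / r2)
  expect_equal(envf$density_field[ix, iy], hand, tolerance = 1e-12)
})

test_that("growth response is thresholded, saturating and monotone", {
  cold <- compute_max_growth(list(t_jul = p0$t_jul_lo - 0.5, ndd0 = 2000), p0)
  expect_equal(cold, 0)
  plateau <- compute_max_growth(list(t_jul = 20, ndd0 = 2000), p0)
  expect_equal(plateau, p0$g_max)

  grid <- tidyr::expand_grid(t_jul = seq(8, 13, 0.25),
                             ndd0 = seq(500, 1200, 50))
  g1 <- compute_max_growth(grid, p0)
  g2 <- compute_max_growth(dplyr::mutate(grid, t_jul = t_jul + 2), p0)
  expect_true(all(g2 >= g1))
  rising <- grid$t_jul > p0$t_jul_lo & grid$t_jul + 2 < p0$t_jul_hi &
    grid$ndd0 > p0$ndd_lo
  expect_true(all(g2[rising] > g1[rising]))
})

test_that("individual growth responds to competition and follows allometry", {
  tr <- tibble::tibble(x_m = 1, y_m = 1, basal_cm = 5, dbh_cm = 0,
                       height_m = allometric_height(5, p0))
  free <- grow_tree(tr, max_growth = 0.4, density_index = 0, params = p0)
  expect_equal(free$basal_cm, 5.4)
  crowded <- grow_tree(tr, max_growth = 0.4, density_index = 1e6, params = p0)
  expect_equal(crowded$basal_cm, 5, tolerance = 1e-12)  # never shrinks

  # closed-form allometry at a chosen diameter
  expect_equal(allometric_height(10, p0), p0$h_max * (1 - exp(-p0$k_allom * 10)))
  # breast-height diameter appears once height crosses 1.3 m
  d13 <- -log(1 - 1.3 / p0$h_max) / p0$k_allom
  big <- grow_tree(tibble::tibble(basal_cm = d13 + 1), 0, 0, p0)
  expect_equal(big$dbh_cm, p0$dbh_slope * (big$basal_cm - d13))
  small <- grow_tree(tibble::tibble(basal_cm = 0.5), 0, 0, p0)
  expect_equal(small$dbh_cm, 0)
})

test_that("node climate interpolation is linear with clamping", {
  aux <- tibble::tibble(node_km = c(0, 10, 20), t_jul = c(10, 12, 9),
                        ndd0 = c(800, 900, 700))
  expect_equal(interpolate_node_climate(10, aux)$t_jul, 12)
  expect_equal(interpolate_node_climate(5, aux)$t_jul, 11)
  # arbitrary position against hand-computed weights
  y <- 13.7
  w <- (y - 10) / 10
  expect_equal(interpolate_node_climate(y, aux)$t_jul, 12 * (1 - w) + 9 * w)
  expect_equal(interpolate_node_climate(y, aux)$ndd0, 900 * (1 - w) + 700 * w)
  expect_warning(out <- interpolate_node_climate(25, aux), "clamping")
  expect_equal(out$t_jul, 9)
})

test_that("ballistic dispersal wraps east-west and matches the analytic median", {
  tr <- tibble::tibble(x_m = 19.5, y_m = 1000, height_m = 5)
  calm <- synth_wind(100, weibull_scale = 1e-12, rng_seed = 1)
  set.seed(1)
  s0 <- disperse_seeds(tr, 200, calm, p0, transect_width_m = 20)
  expect_true(all(abs(s0$y_m - 1000) < 1e-6))
  expect_true(all(s0$x_m >= 0 & s0$x_m < 20))

  # fixed eastward wind: x displacement wraps modulo the width, y never
  east <- tibble::tibble(speed_ms = 4, direction_deg = 90)
  pdet <- larch_params(turb_sdlog = 1e-12)
  set.seed(2)
  s1 <- disperse_seeds(tr, 50, east, pdet, transect_width_m = 20)
  dist <- pdet$release_rel_h * 5 * 4 / pdet$fall_velocity
  expect_equal(s1$x_m, rep((19.5 + dist) %% 20, 50), tolerance = 1e-6)
  expect_equal(s1$y_m, rep(1000, 50), tolerance = 1e-6)

  # heavy-tailed distances: sample median within 3 SE of the analytic
  # ballistic median release_height * speed / fall_velocity
  n <- 1e5
  set.seed(3)
  s2 <- disperse_seeds(tibble::tibble(x_m = 0, y_m = 0, height_m = 5),
                       n, east, p0, transect_width_m = 1e9)
  d2 <- sqrt(pmin(s2$x_m, 1e9 - s2$x_m)^2 + s2$y_m^2)
  med_true <- p0$release_rel_h * 5 * 4 / p0$fall_velocity
  # SE of the median of a lognormal: 1 / (2 f(med) sqrt(n))
  se <- p0$turb_sdlog * med_true / (2 * stats::dnorm(0) * sqrt(n))
  expect_lt(abs(median(d2) - med_true), 3 * se)
})

test_that("seed production obeys maturation, weather and competition", {
  tr <- tibble::tibble(basal_cm = 6, height_m = 2.0, maturation_h_m = 2.5)
  expect_equal(produce_seeds(tr, list(t_jul = 12), 0, p0), 0)

  mat <- tibble::tibble(basal_cm = 6, height_m = 3.0, maturation_h_m = 2.5)
  expect_equal(produce_seeds(mat, list(t_jul = p0$t_jul_lo - 1), 0, p0), 0)

  # monotone in competition under a shared random state
  set.seed(7)
  free <- produce_seeds(mat, list(t_jul = 12), 0, p0)
  set.seed(7)
  crowded <- produce_seeds(mat, list(t_jul = 12), 50, p0)
  expect_gte(free, crowded)
})

test_that("establishment is binomial with the specified probability", {
  seeds <- tibble::tibble(x_m = runif(10), y_m = runif(10))
  none <- establish(seeds, params = p0, prob = 0)
  expect_equal(nrow(none$seedlings), 0)
  all_ <- establish(seeds, params = p0, prob = 1)
  expect_equal(nrow(all_$seedlings), 10)
  expect_true(all(all_$seedlings$height_m ==
                    allometric_height(p0$seedling_basal_cm, p0)))

  n <- 1e5
  many <- tibble::tibble(x_m = rep(0, n), y_m = rep(0, n))
  set.seed(11)
  got <- establish(many, params = p0, prob = 0.03)
  se <- sqrt(0.03 * 0.97 / n)
  expect_lt(abs(mean(got$germinated) - 0.03), 3 * se)
})

test_that("mortality floors at background and matches binomial expectation", {
  # benign conditions: death probability equals the background rate
  pd <- tundraline:::tree_death_prob(basal = 50, age = 100, density_index = 0,
                        t_jul10 = 12, drought10 = 1, params = p0)
  expect_equal(pd, p0$bg_mort, tolerance = 1e-8)

  # seed survival over k years is (1 - m)^k: 0.5^3 = 0.125
  psm <- larch_params(seed_mort = 0.5)
  n <- 1e5
  seeds <- tibble::tibble(x_m = rep(0, n), y_m = 0)
  trees0 <- tibble::tibble(basal_cm = numeric(0), age = integer(0))
  alive <- rep(TRUE, n)
  set.seed(5)
  for (k in 1:3) {
    m <- apply_mortality(trees0, seeds[alive, ], list(), numeric(0), psm)
    alive[alive] <- m$seed_survives
  }
  se <- sqrt(0.125 * 0.875 / n)
  expect_lt(abs(mean(alive) - 0.125), 3 * se)

  # tree deaths: realized fraction within 3 SE of the computed probability
  trees <- tibble::tibble(basal_cm = rep(0.5, n), age = 10)
  aux <- list(t_jul = rep(8, n), drought_index = rep(1, n))
  pd2 <- tundraline:::tree_death_prob(0.5, 10, 0, 8, 1, p0)
  set.seed(6)
  m2 <- apply_mortality(trees, seeds[0, ], aux, rep(0, n), p0)
  se2 <- sqrt(pd2 * (1 - pd2) / n)
  expect_lt(abs(mean(!m2$tree_survives) - pd2), 3 * se2)
})

test_that("boundary seed introduction counts are exact and well-placed", {
  cfg200 <- simulation_config(transect_length_km = 200)
  set.seed(1)
  after <- introduce_boundary_seeds(60, cfg200, list(t_jul = -Inf), p0)
  expect_equal(sum(after$origin == "background"), 1000)
  expect_equal(sum(after$origin == "initial"), 0)

  cfg400 <- simulation_config(transect_length_km = 400)
  set.seed(1)
  bg400 <- introduce_boundary_seeds(60, cfg400, list(t_jul = -Inf), p0)
  expect_equal(sum(bg400$origin == "background"), 2000)

  # initial placement: negative exponential with the configured mean range
  cfgi <- simulation_config(transect_length_km = 5000,
                            initial_seed_count = 1e5,
                            initial_seed_range_m = 2000,
                            permanent_seeds_per_200km = 0,
                            hinterland_seed_max = 0)
  set.seed(2)
  ini <- introduce_boundary_seeds(1, cfgi, list(t_jul = -Inf), p0)
  expect_equal(nrow(ini), 1e5)
  se <- 2000 / sqrt(1e5)
  expect_lt(abs(mean(ini$y_m) - 2000), 3 * se)

  # hinterland rain scales with the boundary climate and stays in its stretch
  cfgh <- simulation_config(transect_length_km = 10,
                            initial_seed_count = 0,
                            permanent_seeds_per_200km = 0,
                            hinterland_seed_max = 500)
  set.seed(3)
  hot <- introduce_boundary_seeds(60, cfgh, list(t_jul = 20), p0)
  expect_equal(nrow(hot), 500)
  expect_true(all(hot$y_m <= 500))
  cold <- introduce_boundary_seeds(60, cfgh, list(t_jul = 0), p0)
  expect_equal(nrow(cold), 0)
})

# a small warm forcing table for loop-level tests
warm_forcing <- function(n_nodes = 2, years = 1971:2100, t_jul = 13) {
  synth_instrumental(n_nodes, years = years, rng_seed = 20,
                     t_jul_site = t_jul, gradient_C_per_100km = 2)
}

test_that("the yearly loop conserves trees without birth or death", {
  f <- warm_forcing(years = 1971:2030)
  cfg <- simulation_config(transect_length_km = 5, stabilization_years = 0,
                           repeats = 1, initial_seed_count = 0,
                           permanent_seeds_per_200km = 0,
                           hinterland_seed_max = 0)
  st <- sim_state_init(cfg, f, p0, years = 2001:2030)
  st$tx <- runif(50, 0, 20); st$ty <- runif(50, 0, 5000)
  st$tage <- rep(5L, 50); st$tbasal <- rep(3, 50)
  st$tdbh <- rep(0, 50); st$theight <- allometric_height(rep(3, 50), p0)
  st$tmath <- rep(2, 50); st$tdi <- rep(0, 50)
  for (i in 1:30) run_year(st, disable = c("establishment", "mortality"))
  expect_equal(length(st$tx), 50)
  expect_equal(st$tage, rep(35L, 50))
})

test_that("disabling dispersal freezes the northernmost tree position", {
  f <- warm_forcing(years = 1971:2060)
  cfg <- simulation_config(transect_length_km = 5, stabilization_years = 0,
                           repeats = 1, initial_seed_count = 0,
                           permanent_seeds_per_200km = 0,
                           hinterland_seed_max = 0)
  st <- sim_state_init(cfg, f, p0, years = 2001:2060)
  n0 <- 200
  st$tx <- runif(n0, 0, 20); st$ty <- runif(n0, 0, 2000)
  st$tage <- rep(10L, n0); st$tbasal <- rep(8, n0)
  st$tdbh <- rep(0, n0); st$theight <- allometric_height(rep(8, n0), p0)
  st$tmath <- rep(1.5, n0); st$tdi <- rep(0, n0)
  north0 <- max(st$ty)
  for (i in 1:60) run_year(st, disable = "dispersal")
  expect_gt(length(st$tx), 0)
  expect_lte(max(st$ty), north0)
})

test_that("identical seeds give identical runs; different repeats differ", {
  f <- warm_forcing(years = 1971:2050)
  cfg <- simulation_config(transect_length_km = 5, stabilization_years = 30,
                           repeats = 2, rng_seed = 77,
                           initial_seed_count = 500,
                           initial_seed_years = 10,
                           permanent_seeds_per_200km = 40,
                           hinterland_seed_max = 50)
  a <- run_simulation(cfg, f, p0, years = 2001:2050, keep_snapshots = TRUE)
  b <- run_simulation(cfg, f, p0, years = 2001:2050, keep_snapshots = TRUE)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$log, b$log)
  r1 <- dplyr::filter(a$log, repeat_id == 1, phase == "main")
  r2 <- dplyr::filter(a$log, repeat_id == 2, phase == "main")
  expect_false(identical(r1$n_trees, r2$n_trees))
  # populations never negative, positions in bounds after wrapping
  expect_true(all(a$log$n_trees >= 0 & a$log$n_seeds >= 0))
  expect_true(all(a$snapshots$x_m >= 0 & a$snapshots$x_m < 20))
  expect_true(all(a$snapshots$y_m >= 0 & a$snapshots$y_m <= 5000))
})

test_that("a warm stand reaches quasi-stationary density", {
  f <- warm_forcing(years = 1971:2210, t_jul = 13.5)
  cfg <- simulation_config(transect_length_km = 5, stabilization_years = 0,
                           repeats = 1, rng_seed = 3,
                           initial_seed_count = 500,
                           initial_seed_years = 20,
                           permanent_seeds_per_200km = 40,
                           hinterland_seed_max = 100)
  sim <- run_simulation(cfg, f, p0, years = 2001:2200)
  stems <- dplyr::filter(sim$log, phase == "main")$n_stems
  late <- tail(stems, 50)
  trend <- coef(lm(late ~ seq_along(late)))[[2]]
  # final 50-year density slope indistinguishable from stationary:
  # net change below 20% of the mean standing density
  expect_lt(abs(trend * 50), 0.2 * mean(late))
  expect_gt(mean(late), 100)  # a real stand established
})

test_that("forcing gaps are a hard error before the simulation starts", {
  f <- warm_forcing(years = 1971:2020)
  cfg <- simulation_config(transect_length_km = 5)
  expect_error(run_simulation(cfg, f, p0, years = 2001:2050),
               "forcing gap")
})
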