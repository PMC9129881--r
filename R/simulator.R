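# Individual-based larch life-cycle simulator on a wrapped 2-D transect.
#
# The transect is a strip `transect_length_km` long (y, metres, increasing
# poleward from the treeline field site) and `transect_width_m` wide (x,
# wrapping east-west). Every year the model runs, in order: environment
# update, growth, seed dispersal, seed production, establishment, mortality,
# ageing. Trees and seeds are stored as parallel vectors in a state
# environment; all per-process maths is vectorised, with the pairwise
# competition kernel in C++.

# basal diameter (cm) at which the allometric height crosses 1.3 m
breast_height_diameter_cm <- function(params) {
  -log(1 - 1.3 / params$h_max) / params$k_allom
}

#' Saturating height allometry
#'
#' `height = h_max * (1 - exp(-k_allom * basal))`, in metres.
#'
#' @param basal_cm basal diameter(s), cm.
#' @param params [larch_params()].
#' @return Heights in m.
#' @export
allometric_height <- function(basal_cm, params = larch_params()) {
  params$h_max * (1 - exp(-params$k_allom * basal_cm))
}

# linear interpolation of per-node values at arbitrary y (m), clamped to the
# node span
interp_nodes <- function(node_m, v, y) {
  nn <- length(node_m)
  if (nn == 1) return(rep(v, length(y)))
  i <- findInterval(y, node_m)
  i <- pmax(1L, pmin(i, nn - 1L))
  f <- (y - node_m[i]) / (node_m[i + 1] - node_m[i])
  f <- ramp01(f)
  v[i] * (1 - f) + v[i + 1] * f
}

#' Interpolate per-node climate auxiliaries at a transect position
#'
#' Linear interpolation between the two flanking climate nodes; positions
#' outside the node span are clamped to the nearest node with a warning.
#'
#' @param y_position position(s) along the transect, km.
#' @param node_aux tibble with `node_km` plus auxiliary columns (one row per
#'   node, see [climate_auxiliaries()]).
#' @return Tibble with one row per `y_position` and the interpolated
#'   auxiliary columns.
#' @export
interpolate_node_climate <- function(y_position, node_aux) {
  stopifnot("node_km" %in% names(node_aux))
  node_aux <- arrange(node_aux, .data$node_km)
  rng <- range(node_aux$node_km)
  if (any(y_position < rng[1] | y_position > rng[2])) {
    warn("position outside the climate node span; clamping to nearest node")
  }
  vars <- setdiff(names(node_aux), c("node_km", "year"))
  out <- tibble(y_km = y_position)
  for (v in vars) {
    out[[v]] <- interp_nodes(node_aux$node_km, node_aux[[v]], y_position)
  }
  out
}

#' Update the competition and soil environment
#'
#' Rebuilds the competition state from the current stand: every tree
#' deposits a triangular influence kernel with radius
#' `r0_crown + r_per_h * height` weighted by its basal diameter; a tree's
#' density index is the summed influence of all neighbours at its position
#' (x wraps across the strip margins). The active-layer depth follows a
#' Stefan-type simplification, `edaphic_factor * sqrt(NDD0)`.
#'
#' @param trees tibble with `x_m, y_m, basal_cm, height_m`.
#' @param climate_aux per-node auxiliaries for the current year (tibble with
#'   `node_km, ndd0`).
#' @param config [simulation_config()].
#' @param params [larch_params()].
#' @param field if `TRUE`, also return the gridded density map
#'   (`cell_m` resolution; can be large on long transects).
#' @param cell_m grid cell size of the density map, m.
#' @return List of class `"environment_state"` with `density_index` (per
#'   tree), `active_layer_depth_cm` (per node), and optionally
#'   `density_field` (matrix x-cells by y-cells).
#' @export
update_environment <- function(trees, climate_aux, config = simulation_config(),
                               params = larch_params(),
                               field = FALSE, cell_m = 0.2) {
  n <- nrow(trees)
  di <- if (n > 0) {
    competition_index_cpp(trees$x_m, trees$y_m, trees$basal_cm,
                          trees$height_m, config$transect_width_m,
                          params$r0_crown, params$r_per_h)
  } else numeric(0)
  ald <- params$edaphic_factor * sqrt(pmax(climate_aux$ndd0, 0))
  out <- list(density_index = di,
              active_layer_depth_cm = setNames(ald, climate_aux$node_km))
  if (field) {
    ymax <- if (n > 0) max(trees$y_m) + params$r0_crown +
      params$r_per_h * max(trees$height_m) else cell_m
    out$density_field <- density_field_cpp(
      if (n) trees$x_m else numeric(0), if (n) trees$y_m else numeric(0),
      if (n) trees$basal_cm else numeric(0),
      if (n) trees$height_m else numeric(0),
      config$transect_width_m, 0, ymax, cell_m,
      params$r0_crown, params$r_per_h)
    attr(out$density_field, "cell_m") <- cell_m
  }
  structure(out, class = "environment_state")
}

#' Potential basal-diameter increment from 10-year mean climate
#'
#' A smooth response surface: the product of saturating ramps in the
#' trailing-mean July temperature and net degree days, reduced linearly when
#' the active layer is shallower than `ald_sat`. Zero below the cold
#' thresholds, `g_max` on the warm plateau, monotonically non-decreasing in
#' both drivers.
#'
#' @param aux data frame or list with `t_jul` and `ndd0` (10-year trailing
#'   means); an `ald_cm` element is used when present.
#' @param params [larch_params()].
#' @return Potential increment(s), cm per year.
#' @export
compute_max_growth <- function(aux, params = larch_params()) {
  ald <- aux[["ald_cm"]] %||%
    (params$edaphic_factor * sqrt(pmax(aux[["ndd0"]], 0)))
  params$g_max *
    ramp01((aux$t_jul - params$t_jul_lo) / (params$t_jul_hi - params$t_jul_lo)) *
    ramp01((aux$ndd0 - params$ndd_lo) / (params$ndd_hi - params$ndd_lo)) *
    ramp01(ald / params$ald_sat)
}

#' Grow trees for one year
#'
#' The realised basal increment is the potential increment discounted by
#' competition, `max_growth * exp(-c_growth * density_index)`; diameters
#' never shrink. Height follows the saturating allometry and breast-height
#' diameter grows once height exceeds 1.3 m.
#'
#' @param trees tibble with `basal_cm` (other columns preserved).
#' @param max_growth potential increment(s), cm yr^-1.
#' @param density_index per-tree competition load.
#' @param params [larch_params()].
#' @return `trees` with updated `basal_cm, dbh_cm, height_m`.
#' @export
grow_tree <- function(trees, max_growth, density_index = 0,
                      params = larch_params()) {
  inc <- max_growth * exp(-params$c_growth * density_index)
  trees$basal_cm <- trees$basal_cm + inc
  trees$height_m <- allometric_height(trees$basal_cm, params)
  trees$dbh_cm <- params$dbh_slope *
    pmax(0, trees$basal_cm - breast_height_diameter_cm(params))
  trees
}

# heavy-tailed ballistic distances: release height times horizontal wind
# speed over fall velocity, times a median-1 lognormal turbulence factor
ballistic_distances <- function(release_h, speed, params) {
  base <- release_h * speed / params$fall_velocity
  base * exp(rnorm(length(base), 0, params$turb_sdlog))
}

#' Disperse seeds from parent trees by wind-driven ballistic flight
#'
#' Each seed samples one wind observation; its travel direction is the wind
#' direction and its distance is `release_height * speed / fall_velocity`
#' multiplied by a median-one lognormal turbulence factor, giving a
#' monotonically decreasing heavy tail. Positions wrap across the east-west
#' margins only; y is returned unwrapped (callers discard positions outside
#' the transect).
#'
#' @param trees tibble with `x_m, y_m, height_m` of the parents.
#' @param cone_count integer seeds per parent.
#' @param wind wind table (see [synth_wind()]).
#' @param params [larch_params()].
#' @param transect_width_m wrapping width, m.
#' @return Tibble `x_m, y_m, parent` of seed positions.
#' @export
disperse_seeds <- function(trees, cone_count, wind,
                           params = larch_params(), transect_width_m = 20) {
  cone_count <- rep_len(cone_count, nrow(trees))
  n <- sum(cone_count)
  if (n == 0) return(tibble(x_m = numeric(0), y_m = numeric(0),
                            parent = integer(0)))
  parent <- rep(seq_len(nrow(trees)), cone_count)
  wi <- sample.int(nrow(wind), n, replace = TRUE)
  dist <- ballistic_distances(params$release_rel_h * trees$height_m[parent],
                              wind$speed_ms[wi], params)
  th <- wind$direction_deg[wi] * pi / 180
  tibble(
    x_m = (trees$x_m[parent] + dist * sin(th)) %% transect_width_m,
    y_m = trees$y_m[parent] + dist * cos(th),
    parent = parent
  )
}

#' Yearly seed (cone) production
#'
#' Zero below the tree's stochastic maturation height; otherwise a count
#' with Poisson marginal whose mean increases with tree size, decreases
#' exponentially with the density index, and scales with a current-year
#' July-temperature weather factor. Counts are drawn as
#' `qpois(u, lambda)` with one uniform draw per tree, so the count is
#' monotone in `lambda` for a fixed random state.
#'
#' @param trees tibble with `basal_cm, height_m, maturation_h_m`.
#' @param aux list/row with current-year `t_jul` at the tree position(s).
#' @param density_index per-tree competition load.
#' @param params [larch_params()].
#' @return Integer cone counts per tree.
#' @export
produce_seeds <- function(trees, aux, density_index = 0,
                          params = larch_params()) {
  s_w <- ramp01((aux$t_jul - params$t_jul_lo) /
                  (params$t_jul_hi - params$t_jul_lo))
  lam <- params$fec_max * trees$basal_cm / (trees$basal_cm + params$fec_d_half) *
    s_w * exp(-params$c_fec * density_index)
  lam[trees$height_m < trees$maturation_h_m] <- 0
  qpois(runif(nrow(trees)), lam)
}

#' Germination of ground seeds
#'
#' Every ground seed germinates independently with a probability set by
#' current weather: `germ_max` times the July-temperature ramp. Germinated
#' seeds become minimal-size seedlings at the seed position with an
#' individually drawn maturation height.
#'
#' @param ground_seeds tibble with `x_m, y_m`.
#' @param aux list/row with current-year `t_jul` at the seed position(s), or
#'   `NULL` when `prob` is given directly.
#' @param params [larch_params()].
#' @param prob optional explicit per-seed probability (overrides `aux`).
#' @return List with `seedlings` (tibble of new trees) and `germinated`
#'   (logical index into `ground_seeds`).
#' @export
establish <- function(ground_seeds, aux = NULL, params = larch_params(),
                      prob = NULL) {
  n <- nrow(ground_seeds)
  if (is.null(prob)) {
    prob <- params$germ_max * ramp01((aux$t_jul - params$t_jul_lo) /
                                       (params$t_jul_hi - params$t_jul_lo))
  }
  g <- runif(n) < prob
  k <- sum(g)
  seedlings <- tibble(
    x_m = ground_seeds$x_m[g],
    y_m = ground_seeds$y_m[g],
    age = 0L,
    basal_cm = rep(params$seedling_basal_cm, k),
    dbh_cm = rep(0, k),
    height_m = allometric_height(rep(params$seedling_basal_cm, k), params),
    maturation_h_m = pmax(params$mat_h_min,
                          rnorm(k, params$mat_h_mean, params$mat_h_sd))
  )
  list(seedlings = seedlings, germinated = g)
}

# per-tree death probability: 1 - product of survival factors, floored at
# the background rate
tree_death_prob <- function(basal, age, density_index, t_jul10, drought10,
                            params) {
  p <- params
  s_juv <- 1 - p$juv_mort * exp(-basal / p$juv_scale_cm)
  s_clim <- 1 - p$clim_mort *
    ramp01((p$clim_t_hi - t_jul10) / (p$clim_t_hi - p$clim_t_lo))
  s_drought <- 1 - p$drought_mort *
    ramp01((p$drought_lo - drought10) / p$drought_lo)
  s_dens <- 1 - p$dens_mort * (1 - exp(-p$c_dens * density_index)) *
    exp(-basal / p$dens_size_cm)
  onset <- p$age_onset_frac * p$age_max
  s_age <- 1 - p$age_mort * ramp01((age - onset) / (p$age_max - onset))
  pd <- 1 - (1 - p$bg_mort) * s_juv * s_clim * s_drought * s_dens * s_age
  pmin(1, pmax(p$bg_mort, pd))
}

#' Yearly mortality of trees and seeds
#'
#' Tree death probability is one minus the product of survival factors for
#' long-term climate (10-year July mean), drought index, surrounding tree
#' density, age and size, bounded below by the background rate. Seeds die
#' at one constant rate whether on trees or on the ground.
#'
#' @param trees tibble with `basal_cm, age` columns.
#' @param seeds tibble of seeds (any columns).
#' @param aux_long_term list with per-tree `t_jul` and `drought_index`
#'   trailing means.
#' @param env [update_environment()] result or a per-tree `density_index`
#'   vector.
#' @param params [larch_params()].
#' @return List with logical `tree_survives` and `seed_survives`.
#' @export
apply_mortality <- function(trees, seeds, aux_long_term, env,
                            params = larch_params()) {
  di <- if (inherits(env, "environment_state")) env$density_index else env
  if (length(di) == 0) di <- rep(0, nrow(trees))
  pd <- tree_death_prob(trees$basal_cm, trees$age, di,
                        aux_long_term$t_jul, aux_long_term$drought_index,
                        params)
  list(
    tree_survives = runif(nrow(trees)) >= pd,
    seed_survives = runif(nrow(seeds)) >= params$seed_mort,
    death_prob = pd
  )
}

#' Boundary and hinterland seed introduction
#'
#' During the first `initial_seed_years` of stabilization,
#' `initial_seed_count` seeds per year are placed from the forested southern
#' boundary with negative-exponentially decaying distance. Every year,
#' `permanent_seeds_per_200km * length / 200 km` background seeds (rounded,
#' deterministic count) are placed uniformly to prevent extinction, and the
#' first `hinterland_stretch_m` receive a climate-scaled seed rain standing
#' in for the non-simulated hinterland forest.
#'
#' @param year_in_run simulation year counter (1 = first stabilization year).
#' @param config [simulation_config()].
#' @param aux_at_boundary list with the 10-year mean `t_jul` at the southern
#'   boundary (drives the hinterland rain).
#' @param params [larch_params()].
#' @return Tibble `x_m, y_m, origin` of newly introduced ground seeds.
#' @export
introduce_boundary_seeds <- function(year_in_run, config,
                                     aux_at_boundary = list(t_jul = Inf),
                                     params = larch_params()) {
  L <- config$transect_length_km * 1000
  W <- config$transect_width_m
  parts <- list()
  if (year_in_run <= config$initial_seed_years &&
      config$initial_seed_count > 0) {
    n0 <- config$initial_seed_count
    parts$initial <- tibble(
      x_m = runif(n0, 0, W),
      y_m = pmin(L, stats::rexp(n0, 1 / config$initial_seed_range_m)),
      origin = "initial"
    )
  }
  nbg <- round(config$permanent_seeds_per_200km *
                 config$transect_length_km / 200)
  if (nbg > 0) {
    parts$background <- tibble(
      x_m = runif(nbg, 0, W),
      y_m = runif(nbg, 0, L),
      origin = "background"
    )
  }
  gfac <- ramp01((aux_at_boundary$t_jul - params$t_jul_lo) /
                   (params$t_jul_hi - params$t_jul_lo))
  nh <- round(config$hinterland_seed_max * gfac)
  if (length(nh) && is.finite(nh) && nh > 0) {
    parts$hinterland <- tibble(
      x_m = runif(nh, 0, W),
      y_m = runif(nh, 0, min(config$hinterland_stretch_m, L)),
      origin = "hinterland"
    )
  }
  if (length(parts) == 0) {
    return(tibble(x_m = numeric(0), y_m = numeric(0), origin = character(0)))
  }
  bind_rows(parts)
}
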