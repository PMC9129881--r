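# All life-cycle constants live here so that a simulation is fully described
# by (config, params, forcing). Values are the package's own calibration for
# a Larix gmelinii-like treeline species; see the methods vignette for the
# rationale behind each functional form.

#' Life-cycle parameters of the simulated larch species
#'
#' Returns the full set of constants used by the growth, dispersal,
#' production, establishment and mortality processes. Any element can be
#' overridden through `...`; unknown names are an error, so typos cannot
#' silently leave a default in place.
#'
#' The parameter groups are:
#' \describe{
#'   \item{growth}{`g_max` (cm yr^-1) maximum basal-diameter increment;
#'     `t_jul_lo`/`t_jul_hi` (deg C) the July-temperature ramp below/above
#'     which potential growth is 0/maximal; `ndd_lo`/`ndd_hi` (deg C day)
#'     the equivalent ramp on net degree days; `ald_sat` (cm) active-layer
#'     depth below which growth is linearly reduced; `c_growth` competition
#'     discount rate, increment = potential * exp(-c_growth * density index).}
#'   \item{allometry}{`h_max` (m) asymptotic height, `k_allom` (cm^-1)
#'     curvature of height = h_max * (1 - exp(-k_allom * basal)); `dbh_slope`
#'     converts basal diameter above the 1.3-m threshold diameter into breast
#'     height diameter.}
#'   \item{competition}{`r0_crown` (m) and `r_per_h` (m per m height) give a
#'     tree's influence radius r = r0_crown + r_per_h * height; influence is
#'     a triangular kernel weighted by basal diameter.}
#'   \item{maturation}{`mat_h_mean`/`mat_h_sd`/`mat_h_min` (m): each tree
#'     draws its maturation height once at establishment.}
#'   \item{production}{`fec_max` seeds yr^-1 at full size without
#'     competition; `fec_d_half` (cm) half-saturation basal diameter;
#'     `c_fec` competition discount; weather scaling uses the July ramp.}
#'   \item{dispersal}{`fall_velocity` (m s^-1), `release_rel_h` fraction of
#'     parent height used as release height, `turb_sdlog` log-sd of the
#'     turbulence multiplier (median 1, heavy tail).}
#'   \item{establishment}{`germ_max` per-seed yearly germination
#'     probability under fully favourable July temperature.}
#'   \item{mortality}{`bg_mort` background rate; `juv_mort`/`juv_scale_cm`
#'     size-dependent juvenile vulnerability; `clim_mort`, `clim_t_hi`,
#'     `clim_t_lo` cold-climate mortality ramp on the 10-yr mean July
#'     temperature; `drought_mort`, `drought_lo` drought-index ramp;
#'     `dens_mort`, `c_dens`, `dens_size_cm` density-dependent thinning of
#'     small trees; `age_max`, `age_onset_frac`, `age_mort` senescence;
#'     `seed_mort` constant seed mortality; `seed_age_max` seed age limit.}
#'   \item{climate sampling}{`aux_mean_years` trailing window (10 yr) for
#'     the growth/mortality auxiliaries.}
#' }
#'
#' @param ... named overrides of individual defaults.
#' @return A named list of parameters, class `"larch_params"`.
#' @export
#' @examples
#' p <- larch_params(g_max = 0.6)
#' p$g_max
larch_params <- function(...) {
  p <- list(
    # growth response
    g_max      = 0.50,
    t_jul_lo   = 9.0,
    t_jul_hi   = 11.5,
    ndd_lo     = 550,
    ndd_hi     = 900,
    ald_sat    = 25,
    c_growth   = 0.08,
    # allometry: h = h_max (1 - exp(-k d)); 1.3 m at basal ~2.5 cm
    h_max      = 28,
    k_allom    = 0.019,
    dbh_slope  = 0.8,
    # competition kernel
    r0_crown   = 1.0,
    r_per_h    = 0.25,
    # maturation height
    mat_h_mean = 2.2,
    mat_h_sd   = 0.6,
    mat_h_min  = 1.0,
    # seed production
    fec_max    = 15,
    fec_d_half = 8,
    c_fec      = 0.12,
    # dispersal
    fall_velocity = 0.8,
    release_rel_h = 0.9,
    turb_sdlog    = 1.6,
    # establishment
    germ_max   = 0.02,
    # mortality
    bg_mort      = 0.004,
    juv_mort     = 0.20,
    juv_scale_cm = 1.5,
    clim_mort    = 0.20,
    clim_t_hi    = 9.0,
    clim_t_lo    = 6.0,
    drought_mort = 0.15,
    drought_lo   = 0.05,
    dens_mort    = 0.45,
    c_dens       = 0.08,
    dens_size_cm = 4.0,
    age_max      = 400,
    age_onset_frac = 0.6,
    age_mort     = 0.30,
    seed_mort    = 0.50,
    seed_age_max = 2,
    # environment
    edaphic_factor = 1.2,   # cm per sqrt(deg C day), Stefan-type thaw
    aux_mean_years = 10,
    # new-seedling initial size
    seedling_basal_cm = 0.05
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    p[names(dots)] <- dots
  }
  structure(p, class = c("larch_params", "list"))
}

#' Transect and run configuration for the simulator
#'
#' @param transect_length_km along-transect (poleward) extent in km.
#' @param transect_width_m across-transect width in m; the east-west
#'   boundaries wrap, so the strip represents a slice of a continuous
#'   treeline.
#' @param node_spacing_km spacing of the climate nodes (10 km).
#' @param stabilization_years years of spin-up under the first 30 forcing
#'   years looped, before the transient simulation starts.
#' @param repeats number of simulation repeats with distinct derived seeds.
#' @param rng_seed master seed of the run.
#' @param initial_seed_count seeds introduced per year at the forested
#'   (southern) boundary during the first `initial_seed_years` of spin-up.
#' @param initial_seed_years duration of the initial seeding phase.
#' @param initial_seed_range_m mean of the negative-exponential placement
#'   kernel of the initial seeding, measured from the southern boundary.
#' @param permanent_seeds_per_200km background seed introduction per year
#'   and 200 km of transect length (uniform along the transect).
#' @param hinterland_stretch_m the southern stretch receiving seed rain from
#'   the non-simulated hinterland forest.
#' @param hinterland_seed_max maximal yearly hinterland seed rain (scaled by
#'   the climate-dependent growth factor at the southern boundary).
#' @param snapshot_years cadence (years) of full stand snapshots.
#' @param ... overrides passed to nothing; reserved.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(transect_length_km = 50,
                              transect_width_m = 20,
                              node_spacing_km = 10,
                              stabilization_years = 200,
                              repeats = 3,
                              rng_seed = 1L,
                              initial_seed_count = 100000,
                              initial_seed_years = 50,
                              initial_seed_range_m = 5000,
                              permanent_seeds_per_200km = 1000,
                              hinterland_stretch_m = 500,
                              hinterland_seed_max = 2000,
                              snapshot_years = 10) {
  stopifnot(transect_length_km > 0, transect_width_m > 0,
            node_spacing_km > 0, stabilization_years >= 0,
            repeats >= 1, initial_seed_count >= 0,
            permanent_seeds_per_200km >= 0)
  structure(list(
    transect_length_km = transect_length_km,
    transect_width_m = transect_width_m,
    node_spacing_km = node_spacing_km,
    stabilization_years = stabilization_years,
    repeats = repeats,
    rng_seed = as.integer(rng_seed),
    initial_seed_count = initial_seed_count,
    initial_seed_years = initial_seed_years,
    initial_seed_range_m = initial_seed_range_m,
    permanent_seeds_per_200km = permanent_seeds_per_200km,
    hinterland_stretch_m = hinterland_stretch_m,
    hinterland_seed_max = hinterland_seed_max,
    snapshot_years = snapshot_years
  ), class = c("sim_config", "list"))
}

#' Read / write a declarative configuration file
#'
#' The whole experiment (forcing, simulator, area geometry) is described by
#' one YAML file with `forcing`, `simulator` and `area` sections. Values map
#' one-to-one onto the arguments of [larch_params()], [simulation_config()]
#' and [synth_geometry()].
#'
#' @param path file path.
#' @return `read_config()` returns a named list; `write_config()` returns
#'   `path` invisibly.
#' @export
#' @examples
#' cfg <- read_config(system.file("extdata", "desk-config.yml",
#'                                package = "tundraline"))
#' names(cfg)
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config named list to serialise.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
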