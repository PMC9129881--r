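# Stand snapshots -> the key treeline variables: density profiles,
# single-tree / treeline / forestline positions, migration rates,
# climate-analogue track, and the lag/overshoot trajectory.

#' Stand-density profile of a snapshot
#'
#' Counts stems (trees taller than 1.3 m) in half-open along-transect bins
#' (south-inclusive) and converts to stems per hectare.
#'
#' @param snapshot tibble with `y_m` and `height_m` (one row per tree); rows
#'   with `height_m <= 1.3` are ignored so either a stem table or a full
#'   tree table can be passed.
#' @param bin_length_km bin length (default 1 km).
#' @param transect_length_km transect length; bins tile `[0, length)`.
#' @param transect_width_m strip width, m.
#' @return Tibble `bin_start_km, bin_length_km, stems_per_ha`.
#' @export
#' @examples
#' snap <- tibble::tibble(y_m = c(100, 600), height_m = c(2, 5))
#' density_profile(snap, 1, transect_length_km = 2, transect_width_m = 20)
density_profile <- function(snapshot, bin_length_km = 1,
                            transect_length_km, transect_width_m = 20) {
  stopifnot(bin_length_km > 0)
  n_bins <- ceiling(transect_length_km / bin_length_km)
  breaks_m <- (0:n_bins) * bin_length_km * 1000
  stems <- snapshot$y_m[snapshot$height_m > 1.3]
  stems <- stems[stems >= 0 & stems < breaks_m[n_bins + 1]]
  cnt <- tabulate(findInterval(stems, breaks_m), nbins = n_bins)
  area_ha <- bin_length_km * 1000 * transect_width_m / 1e4
  tibble(
    bin_start_km = breaks_m[-(n_bins + 1)] / 1000,
    bin_length_km = bin_length_km,
    stems_per_ha = cnt / area_ha
  )
}

#' Extract single-tree, treeline and forestline positions from a profile
#'
#' Positions are the northern edges of the defining bins. The treeline is
#' the end of the contiguous run of bins with at least 1 stem per hectare
#' connected to the southern boundary (a gap of one bin or more breaks the
#' run); the forestline is the northernmost bin *within that
#' boundary-connected cover* with density above 100 stems per hectare
#' (dense isolated islands ahead of the treeline are island features, not
#' forestline — this keeps forestline <= treeline <= single-tree an
#' invariant); the single-tree position is the northernmost bin anywhere
#' with at least 1 stem per hectare. If no bin reaches 1 stem per hectare
#' all three are `NA`.
#'
#' @param profile result of [density_profile()], bins ordered south to
#'   north.
#' @param treeline_min,forestline_min density thresholds (stems per ha).
#' @return One-row tibble `single_tree_km, treeline_km, forestline_km`.
#' @export
#' @examples
#' prof <- tibble::tibble(bin_start_km = 0:7, bin_length_km = 1,
#'                        stems_per_ha = c(150, 120, 60, 3, 0, 0, 2, 0))
#' extract_positions(prof)  # forestline 2, treeline 4, single-tree 7
extract_positions <- function(profile, treeline_min = 1,
                              forestline_min = 100) {
  profile <- arrange(profile, .data$bin_start_km)
  d <- profile$stems_per_ha
  edge <- profile$bin_start_km + profile$bin_length_km
  occupied <- d >= treeline_min
  if (!any(occupied)) {
    return(tibble(single_tree_km = NA_real_, treeline_km = NA_real_,
                  forestline_km = NA_real_))
  }
  single_tree <- edge[max(which(occupied))]
  if (occupied[1]) {
    gap <- which(!occupied)[1]
    run_last <- if (is.na(gap)) length(d) else gap - 1
    treeline <- edge[run_last]
    dense <- d[seq_len(run_last)] > forestline_min
    forestline <- if (any(dense)) edge[max(which(dense))] else NA_real_
  } else {
    treeline <- NA_real_
    forestline <- NA_real_
  }
  tibble(single_tree_km = single_tree, treeline_km = treeline,
         forestline_km = forestline)
}

#' Decadal treeline records for a whole simulation
#'
#' Applies [extract_positions()] to every (repeat, year) profile of a
#' [run_simulation()] result.
#'
#' @param sim a `treeline_sim` object or its `profiles` tibble (with
#'   `repeat` and `year` columns).
#' @inheritParams extract_positions
#' @return Tibble `repeat, year, single_tree_km, treeline_km,
#'   forestline_km`.
#' @export
treeline_records <- function(sim, treeline_min = 1, forestline_min = 100) {
  profiles <- if (inherits(sim, "treeline_sim")) sim$profiles else sim
  profiles %>%
    group_by(.data$`repeat`, .data$year) %>%
    dplyr::group_modify(~ extract_positions(.x, treeline_min, forestline_min)) %>%
    ungroup()
}

#' Climate-analogue position track
#'
#' Tracks the along-transect position whose (10-year trailing mean) July
#' temperature equals the July temperature at the treeline's baseline
#' position: the climate-analogue of the modern treeline, i.e. where the
#' treeline would sit if it tracked the isotherm instantaneously. Per year,
#' the northernmost position with smoothed July temperature at or above the
#' baseline value is found by linear interpolation between nodes and
#' clamped to `[0, shoreline]`.
#'
#' @param forcing monthly climate series.
#' @param baseline_year year defining the reference temperature.
#' @param baseline_treeline_km treeline position in `baseline_year`.
#' @param years years to track (default: `baseline_year` to the forcing
#'   end).
#' @param shoreline_km clamp position (default: northernmost node).
#' @param smooth_years trailing-mean window for July temperature.
#' @return Tibble `year, analogue_km`.
#' @export
analogue_track <- function(forcing, baseline_year, baseline_treeline_km,
                           years = NULL, shoreline_km = NULL,
                           smooth_years = 10) {
  assert_climate_series(forcing, "forcing")
  jul <- forcing %>%
    filter(.data$month == 7) %>%
    arrange(.data$node_km, .data$year)
  nodes <- sort(unique(jul$node_km))
  shoreline_km <- shoreline_km %||% max(nodes)
  if (baseline_treeline_km < min(nodes) || baseline_treeline_km > max(nodes)) {
    abort("baseline treeline position outside the climate node span")
  }
  all_years <- sort(unique(jul$year))
  m <- matrix(jul$temp_C, nrow = length(all_years), ncol = length(nodes))
  # trailing means per node
  sm <- apply(m, 2, function(v) {
    cs <- c(0, cumsum(v))
    k <- pmin(seq_along(v), smooth_years)
    (cs[-1] - cs[seq_along(v) + 1 - k]) / k
  })
  years <- years %||% all_years[all_years >= baseline_year]
  ib <- match(baseline_year, all_years)
  if (is.na(ib)) abort("baseline_year not covered by forcing")
  t_base <- stats::approx(nodes, sm[ib, ], xout = baseline_treeline_km)$y
  pos <- vapply(years, function(y) {
    iy <- match(y, all_years)
    tv <- sm[iy, ]
    northernmost_at_least(nodes, tv, t_base)
  }, numeric(1))
  tibble(year = years, analogue_km = pmin(shoreline_km, pmax(0, pos)))
}

# northernmost position where the piecewise-linear profile v(node) >= level
northernmost_at_least <- function(nodes, v, level) {
  nn <- length(nodes)
  for (i in seq(nn - 1, 1)) {
    a <- v[i]; b <- v[i + 1]
    if (b >= level) return(nodes[i + 1])
    if (a >= level) {
      # crossing inside segment (a >= level > b)
      return(nodes[i] + (a - level) / (a - b) * (nodes[i + 1] - nodes[i]))
    }
  }
  if (v[1] >= level) nodes[1] else 0
}

#' Decadal migration rates relative to a baseline year
#'
#' @param records tibble with `year` and a position column, at 10-year
#'   spacing (one repeat; see [treeline_records()]).
#' @param baseline_year the year whose position anchors cumulative advance.
#' @param variable which position to use (`"treeline_km"` by default).
#' @return Tibble `year, position_km, rate_km_per_decade, advance_km`.
#' @export
migration_rates <- function(records, baseline_year = 2000,
                            variable = "treeline_km") {
  records <- arrange(records, .data$year)
  if (!baseline_year %in% records$year) {
    abort("records do not contain the baseline year")
  }
  pos <- records[[variable]]
  base <- pos[records$year == baseline_year][1]
  step <- diff(records$year)
  rate <- c(NA_real_, diff(pos) / (step / 10))
  tibble(year = records$year, position_km = pos,
         rate_km_per_decade = rate, advance_km = pos - base)
}

#' Lag/overshoot trajectory of simulated treeline versus climate analogue
#'
#' Both position series are rescaled to fractions of the corridor between
#' the current (baseline) treeline position and the shoreline, then averaged
#' in `segment_years` segments. A point below the diagonal (simulated
#' fraction < analogue fraction) means the treeline lags the climate; above
#' the diagonal it overshoots.
#'
#' @param records one repeat's treeline records (`year` + position column).
#' @param analogue result of [analogue_track()].
#' @param shoreline_km,current_km corridor bounds (km).
#' @param segment_years segment length (default 25).
#' @param variable position column of `records` to use.
#' @return Tibble `period_start_year, simulated_fraction,
#'   analogue_fraction`, class `"lag_trajectory"`.
#' @export
lag_trajectory <- function(records, analogue, shoreline_km, current_km,
                           segment_years = 25, variable = "treeline_km") {
  if (shoreline_km == current_km) {
    abort("shoreline and current treeline coincide; fractions undefined")
  }
  joined <- dplyr::inner_join(
    select(records, "year", sim_km = all_of(variable)),
    select(analogue, "year", "analogue_km"), by = "year")
  span <- shoreline_km - current_km
  out <- joined %>%
    mutate(
      period_start_year = min(.data$year) +
        segment_years * ((.data$year - min(.data$year)) %/% segment_years),
      simulated_fraction = ramp01((.data$sim_km - current_km) / span),
      analogue_fraction = ramp01((.data$analogue_km - current_km) / span)
    ) %>%
    group_by(.data$period_start_year) %>%
    summarise(simulated_fraction = mean(.data$simulated_fraction),
              analogue_fraction = mean(.data$analogue_fraction),
              .groups = "drop")
  class(out) <- c("lag_trajectory", class(out))
  out
}

#' Year at which the trajectory reaches the equilibrium diagonal
#'
#' The first segment start-year where the simulated fraction is at least the
#' analogue fraction (the end of the migration-lag phase); `NA` if the
#' trajectory never reaches the diagonal.
#'
#' @param trajectory result of [lag_trajectory()].
#' @param tol numerical tolerance on the fraction comparison.
#' @return A year, or `NA_real_`.
#' @export
equilibrium_crossing_year <- function(trajectory, tol = 1e-9) {
  on_or_above <- trajectory$simulated_fraction >=
    trajectory$analogue_fraction - tol
  lag_start <- which(!on_or_above)[1]
  if (is.na(lag_start)) {
    # never lagged: on the diagonal from the start
    return(trajectory$period_start_year[1])
  }
  hit <- which(on_or_above & seq_along(on_or_above) > lag_start)
  if (length(hit) == 0) return(NA_real_)
  trajectory$period_start_year[hit[1]]
}
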