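# Tundra-area accounting on equal-area planar corridor geometries.
#
# The land under consideration is the tundra corridor between the treeline
# polyline (southern boundary) and the coastline (northern boundary), both
# represented as piecewise-linear functions of the west-east coordinate x
# over [0, corridor_width]; poleward is +y. Per-region treeline advances are
# interpolated along the treeline to 10-km stations and buffered poleward;
# the forested extent is integrated exactly (piecewise-linear closed form),
# so the synthetic corridor results match analytic areas to machine
# precision. All coordinates are km in an equal-area projection applied
# upstream; this module never reprojects.

#' Synthetic corridor geometry (treeline + coastline + anchors)
#'
#' A tundra corridor of `corridor_width_km` (west-east) by
#' `corridor_length_km` (poleward). The treeline is the southern boundary
#' (y = 0, optionally gently curved by `curvature_km`), the coastline the
#' northern one; `n_regions` transect anchors are spaced evenly along the
#' treeline, and region boundaries sit midway between anchors (end regions
#' run to the corridor ends).
#'
#' @param corridor_width_km,corridor_length_km corridor dimensions, km.
#' @param n_regions number of transect anchors.
#' @param curvature_km amplitude of a sinusoidal bow of the treeline
#'   (0 gives a straight treeline and exact rectangle).
#' @param n_vertices vertices per boundary polyline.
#' @param rng_seed unused for the deterministic geometry; kept so callers
#'   can treat geometry generation like the other synthetic generators.
#' @return Object of class `"treeline_geometry"`: list with `treeline` and
#'   `coastline` vertex tibbles (`x_km, y_km`), `anchors_x_km`,
#'   `region_bounds_km` and `initial_area_km2`.
#' @export
#' @examples
#' g <- synth_geometry(100, 500)
#' g$initial_area_km2  # 50,000 km^2
synth_geometry <- function(corridor_width_km, corridor_length_km,
                           n_regions = 4, curvature_km = 0,
                           n_vertices = 101, rng_seed = NULL) {
  stopifnot(corridor_width_km > 0, corridor_length_km > 0, n_regions >= 1)
  x <- seq(0, corridor_width_km, length.out = n_vertices)
  y_tree <- curvature_km * sin(pi * x / corridor_width_km)
  y_coast <- rep(corridor_length_km, n_vertices) + y_tree
  anchors <- (seq_len(n_regions) - 0.5) * corridor_width_km / n_regions
  bounds <- c(0, (anchors[-1] + anchors[-n_regions]) / 2, corridor_width_km)
  geom <- structure(list(
    treeline = tibble(x_km = x, y_km = y_tree),
    coastline = tibble(x_km = x, y_km = y_coast),
    anchors_x_km = anchors,
    region_bounds_km = bounds,
    corridor_width_km = corridor_width_km
  ), class = "treeline_geometry")
  geom$initial_area_km2 <- corridor_area(geom)
  geom
}

#' @export
print.treeline_geometry <- function(x, ...) {
  cat("Tundra corridor geometry: ", x$corridor_width_km, " km wide, ",
      "initial tundra area ", format(x$initial_area_km2), " km^2, ",
      length(x$anchors_x_km), " anchors\n", sep = "")
  invisible(x)
}

# piecewise-linear evaluation of a boundary at arbitrary x
pl_eval <- function(poly, x) {
  stats::approx(poly$x_km, poly$y_km, xout = x, rule = 2)$y
}

# exact integral of max(min(upper, cap) - lower, 0) dx between x-limits,
# where upper/lower/cap are piecewise-linear in x. Evaluated by splitting
# at all breakpoints and all pairwise intersections within each piece.
pl_band_area <- function(xs, lower, upper, cap, xlim) {
  f_up <- function(x) pmax(pmin(stats::approx(xs, upper, x, rule = 2)$y,
                                stats::approx(xs, cap, x, rule = 2)$y),
                           stats::approx(xs, lower, x, rule = 2)$y)
  f_lo <- function(x) stats::approx(xs, lower, x, rule = 2)$y
  brk <- sort(unique(c(xs, xlim)))
  brk <- brk[brk >= xlim[1] & brk <= xlim[2]]
  # add intersection points of (upper, cap) and (upper, lower), (cap, lower)
  cuts <- c()
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]; b <- brk[i + 1]
    for (pair in list(c("u", "c"), c("u", "l"), c("c", "l"))) {
      g <- function(x) {
        u <- stats::approx(xs, upper, x, rule = 2)$y
        cc <- stats::approx(xs, cap, x, rule = 2)$y
        l <- stats::approx(xs, lower, x, rule = 2)$y
        v <- list(u = u, c = cc, l = l)
        v[[pair[1]]] - v[[pair[2]]]
      }
      ga <- g(a); gb <- g(b)
      if (is.finite(ga) && is.finite(gb) && ga * gb < 0) {
        cuts <- c(cuts, a + (b - a) * ga / (ga - gb))
      }
    }
  }
  brk <- sort(unique(c(brk, cuts)))
  area <- 0
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]; b <- brk[i + 1]
    mid_h <- function(x) f_up(x) - f_lo(x)
    # integrand linear on each refined piece: trapezoid is exact
    area <- area + (b - a) * (mid_h(a) + mid_h(b)) / 2
  }
  area
}

# initial tundra area between treeline and coastline
corridor_area <- function(geometry, xlim = NULL) {
  xs <- geometry$treeline$x_km
  xlim <- xlim %||% range(xs)
  cap <- rep(Inf, length(xs))
  up <- pl_eval(geometry$coastline, xs)
  pl_band_area(xs, geometry$treeline$y_km, up, up, xlim)
}

#' Interpolate per-region advances to 10-km treeline stations
#'
#' Places stations every `step_km` of arc length along the treeline
#' polyline and assigns each the inverse-arc-distance weighted average of
#' the two flanking anchors' advances; stations beyond the first/last
#' anchor take the nearest anchor's value.
#'
#' @param geometry a [synth_geometry()] (or compatible) object.
#' @param advances numeric vector, one advance (km) per anchor.
#' @param step_km station spacing along the treeline arc.
#' @return Tibble `station_km, x_km, y_km, advance_km`.
#' @export
interpolate_advance <- function(geometry, advances, step_km = 10) {
  anchors <- geometry$anchors_x_km
  if (length(advances) != length(anchors)) {
    abort("need exactly one advance per anchor")
  }
  tl <- geometry$treeline
  seg <- sqrt(diff(tl$x_km)^2 + diff(tl$y_km)^2)
  arc <- c(0, cumsum(seg))
  stations <- seq(0, max(arc), by = step_km)
  if (max(stations) < max(arc)) stations <- c(stations, max(arc))
  sx <- stats::approx(arc, tl$x_km, xout = stations)$y
  sy <- stats::approx(arc, tl$y_km, xout = stations)$y
  anchor_arc <- stats::approx(tl$x_km, arc, xout = anchors)$y
  adv <- stats::approx(anchor_arc, advances, xout = stations, rule = 2)$y
  tibble(station_km = stations, x_km = sx, y_km = sy, advance_km = adv)
}

#' Poleward forest extent polygon and area
#'
#' Buffers the treeline poleward by the station advances (linearly
#' interpolated between stations), clips against the coastline, and returns
#' the forested polygon with its exact area. Zero-advance stations
#' contribute nothing.
#'
#' @param geometry a [synth_geometry()] object.
#' @param stations result of [interpolate_advance()] (or a tibble with
#'   `x_km, advance_km`).
#' @param xlim optional west-east limits (used for per-region accounting).
#' @return List with `area_km2` and `polygon` (vertex tibble, closed ring).
#' @export
forest_extent <- function(geometry, stations, xlim = NULL) {
  stopifnot(all(stations$advance_km >= 0))
  xs <- geometry$treeline$x_km
  xlim <- xlim %||% range(xs)
  lower <- geometry$treeline$y_km
  adv <- stats::approx(stations$x_km, stations$advance_km, xout = xs,
                       rule = 2)$y
  upper <- lower + adv
  cap <- pl_eval(geometry$coastline, xs)
  area <- pl_band_area(xs, lower, upper, cap, xlim)
  inx <- xs >= xlim[1] & xs <= xlim[2]
  top <- pmax(pmin(upper, cap), lower)
  polygon <- tibble(
    x_km = c(xs[inx], rev(xs[inx]), xs[inx][1]),
    y_km = c(lower[inx], rev(top[inx]), lower[inx][1])
  )
  list(area_km2 = area, polygon = polygon)
}

#' Tundra-area time series from per-year, per-region advances
#'
#' Recomputes the forested extent per year from the current advances (so
#' tundra can recover when advances decrease), subtracts it from the
#' initial tundra area per region and in total, and reports remaining area
#' and fraction of initial.
#'
#' @param geometry a [synth_geometry()] object.
#' @param advances tibble `year, region, advance_km` with one row per year
#'   and anchor region (regions numbered 1..n_regions west to east), or
#'   `year, advance_km` applied to all anchors.
#' @param step_km station spacing.
#' @return Tibble `year, region, area_km2, fraction_of_initial` (region
#'   `"total"` included), class `"tundra_series"`.
#' @export
tundra_series <- function(geometry, advances, step_km = 10) {
  n_regions <- length(geometry$anchors_x_km)
  if (!"region" %in% names(advances)) {
    advances <- tidyr::expand_grid(region = seq_len(n_regions),
                                   distinct(advances, .data$year,
                                            .data$advance_km))
  }
  bounds <- geometry$region_bounds_km
  region_area <- vapply(seq_len(n_regions), function(r) {
    corridor_area(geometry, xlim = bounds[c(r, r + 1)])
  }, numeric(1))
  total_area <- sum(region_area)
  years <- sort(unique(advances$year))
  rows <- purrr::map_dfr(years, function(yr) {
    adv <- advances %>% filter(.data$year == yr) %>% arrange(.data$region)
    if (nrow(adv) != n_regions) {
      abort(paste0("year ", yr, " does not provide one advance per region"))
    }
    st <- interpolate_advance(geometry, adv$advance_km, step_km = step_km)
    per <- vapply(seq_len(n_regions), function(r) {
      forest_extent(geometry, st, xlim = bounds[c(r, r + 1)])$area_km2
    }, numeric(1))
    bind_rows(
      tibble(year = yr, region = as.character(seq_len(n_regions)),
             area_km2 = region_area - per,
             fraction_of_initial = (region_area - per) / region_area),
      tibble(year = yr, region = "total",
             area_km2 = total_area - sum(per),
             fraction_of_initial = (total_area - sum(per)) / total_area)
    )
  })
  class(rows) <- c("tundra_series", class(rows))
  rows
}

# ---------------------------------------------------------------------------
# small geometry utilities

#' Polygon area by the shoelace formula
#'
#' @param polygon tibble with `x_km, y_km` (closed or open ring).
#' @return Absolute enclosed area.
#' @export
shoelace_area <- function(polygon) {
  x <- polygon$x_km
  y <- polygon$y_km
  if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
    x <- c(x, x[1]); y <- c(y, y[1])
  }
  n <- length(x)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Minimal well-known-text export / import for the corridor geometry
#'
#' Writes the treeline as a `LINESTRING` and the land polygon (treeline +
#' coastline ring) as a `POLYGON`; `read_geometry_wkt()` inverts it.
#'
#' @param geometry a `treeline_geometry`.
#' @param path file path.
#' @return The path (writer, invisibly) or a vertex list (reader).
#' @export
write_geometry_wkt <- function(geometry, path) {
  fmt_ring <- function(x, y) {
    paste(paste(format(x, trim = TRUE, digits = 15),
                format(y, trim = TRUE, digits = 15)), collapse = ", ")
  }
  tl <- geometry$treeline
  cl <- geometry$coastline
  ring_x <- c(tl$x_km, rev(cl$x_km), tl$x_km[1])
  ring_y <- c(tl$y_km, rev(cl$y_km), tl$y_km[1])
  lines <- c(
    paste0("LINESTRING (", fmt_ring(tl$x_km, tl$y_km), ")"),
    paste0("POLYGON ((", fmt_ring(ring_x, ring_y), "))")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_geometry_wkt
#' @export
read_geometry_wkt <- function(path) {
  lines <- readLines(path)
  parse_coords <- function(txt) {
    txt <- gsub("^[A-Z]+ \\(+|\\)+$", "", txt)
    parts <- strsplit(strsplit(txt, ",\\s*")[[1]], "\\s+")
    tibble(x_km = as.numeric(vapply(parts, `[`, "", 1)),
           y_km = as.numeric(vapply(parts, `[`, "", 2)))
  }
  list(treeline = parse_coords(lines[1]),
       land_ring = parse_coords(lines[2]))
}
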