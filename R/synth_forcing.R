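# Millennium-scale climate forcing for latitudinal transects.
#
# The construction mirrors the standard recipe for proxy-extended transect
# forcing: (1) instrumental-era monthly series per 10-km node, (2) an annual
# ice-core-like proxy whose pre-industrial variability is block-resampled to
# cover 501-1900, (3) node-wise OLS calibration of the proxy against the
# instrumental overlap, (4) monthly assembly from shifted instrumental
# blocks, (5) scenario anomaly curves appended to 2300 with linear trend
# extension to 2500, and (6) either a 20th-century cooling replay or a
# continued-warming copy to 3000.

MONTH_DAYS <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# ---------------------------------------------------------------------------
# synthetic stand-in inputs

#' Synthetic instrumental-era monthly climate per transect node
#'
#' Stand-in for a gridded instrumental product sampled every 10 km along a
#' transect. Monthly temperature is a seasonal cycle (January minimum, July
#' maximum) plus a regionally shared AR(1) interannual anomaly and shared
#' monthly weather noise; July temperature decreases linearly poleward with
#' `gradient_C_per_100km`. Because gridded products in station-sparse
#' regions are strongly smoothed, the interannual noise is deliberately
#' modest and fully correlated across the closely spaced nodes.
#'
#' @param n_nodes number of nodes (at 0, 10, ..., `(n_nodes-1)*spacing`).
#' @param years calendar years to generate.
#' @param gradient_C_per_100km poleward July cooling (deg C per 100 km),
#'   must be > 0.
#' @param rng_seed integer seed; the same seed reproduces the series.
#' @param node_spacing_km node spacing in km.
#' @param t_jul_site,t_jan_site July / January climatology at node 0 (deg C).
#' @param precip_year_mm annual precipitation climatology (mm).
#' @param ar1_phi,ar1_sd AR(1) parameters of the shared annual anomaly.
#' @param month_sd sd (deg C) of shared monthly weather noise.
#' @param precip_cv coefficient of variation of monthly precipitation.
#' @return Tibble with columns `node_km, year, month, temp_C, precip_mm`.
#' @export
#' @examples
#' inst <- synth_instrumental(2, years = 1991:2000, rng_seed = 1)
#' dplyr::count(inst, node_km)
synth_instrumental <- function(n_nodes,
                               years = 1901:2005,
                               gradient_C_per_100km = 1,
                               rng_seed = 1L,
                               node_spacing_km = 10,
                               t_jul_site = 12.5,
                               t_jan_site = -32,
                               precip_year_mm = 270,
                               ar1_phi = 0.5,
                               ar1_sd = 0.3,
                               month_sd = 0.25,
                               precip_cv = 0.3) {
  stopifnot(n_nodes >= 1, gradient_C_per_100km > 0)
  set.seed(as.integer(rng_seed))
  nodes <- (seq_len(n_nodes) - 1) * node_spacing_km
  ny <- length(years)
  mid <- (t_jul_site + t_jan_site) / 2
  amp <- (t_jul_site - t_jan_site) / 2
  season <- mid + amp * cos(2 * pi * (1:12 - 7) / 12)

  # shared regional anomalies
  a <- numeric(ny)
  if (ar1_sd > 0) {
    innov <- rnorm(ny, 0, ar1_sd * sqrt(1 - ar1_phi^2))
    a[1] <- rnorm(1, 0, ar1_sd)
    for (i in seq_len(ny - 1)) a[i + 1] <- ar1_phi * a[i] + innov[i + 1]
  }
  mnoise <- if (month_sd > 0) matrix(rnorm(ny * 12, 0, month_sd), ny, 12) else
    matrix(0, ny, 12)

  p_season <- precip_year_mm / 12 * (1 + 0.6 * cos(2 * pi * (1:12 - 7) / 12))
  pnoise <- if (precip_cv > 0) {
    shape <- 1 / precip_cv^2
    matrix(stats::rgamma(ny * 12, shape = shape, rate = shape), ny, 12)
  } else matrix(1, ny, 12)

  grid <- tidyr::expand_grid(node_km = nodes, year = years, month = 1:12)
  iy <- match(grid$year, years)
  im <- grid$month
  grid$temp_C <- season[im] - gradient_C_per_100km * grid$node_km / 100 +
    a[iy] + mnoise[cbind(iy, im)]
  grid$precip_mm <- p_season[im] * pnoise[cbind(iy, im)]
  as_tibble(grid)
}

#' Synthetic annual proxy series (ice-core stand-in)
#'
#' An annual delta-18-O-like value with AR(1) interannual variability plus
#' annual-layer thickness. If an instrumental series is supplied, the proxy
#' value is linearly coupled to its transect-mean annual temperature over the
#' shared years, so that downstream calibration recovers a real relation.
#'
#' @param years years covered (the reference archive spans 934-1998).
#' @param instrumental optional monthly climate series to couple to.
#' @param rng_seed seed.
#' @param alpha,beta intercept / slope of the value-temperature coupling.
#' @param noise_sd residual sd of the coupling.
#' @param ar_phi,ar_sd AR(1) parameters of the uncoupled (pre-instrumental)
#'   pseudo-temperature.
#' @return Tibble with columns `year, value, thickness`.
#' @export
synth_proxy <- function(years = 934:1998,
                        instrumental = NULL,
                        rng_seed = 1L,
                        alpha = -20, beta = 0.5, noise_sd = 0.3,
                        ar_phi = 0.6, ar_sd = 0.45) {
  set.seed(as.integer(rng_seed))
  ny <- length(years)
  # pseudo annual temperature anomaly driving the proxy
  t_ann <- numeric(ny)
  innov <- rnorm(ny, 0, ar_sd * sqrt(1 - ar_phi^2))
  t_ann[1] <- rnorm(1, 0, ar_sd)
  for (i in seq_len(ny - 1)) t_ann[i + 1] <- ar_phi * t_ann[i] + innov[i + 1]
  if (!is.null(instrumental)) {
    assert_climate_series(instrumental, "instrumental")
    obs <- instrumental %>%
      group_by(.data$year) %>%
      summarise(t = mean(.data$temp_C), .groups = "drop")
    base <- mean(obs$t)
    idx <- match(obs$year, years)
    keep <- !is.na(idx)
    t_ann[idx[keep]] <- obs$t[keep] - base
  }
  tibble(
    year = years,
    value = alpha + beta * t_ann + rnorm(ny, 0, noise_sd),
    thickness = rlnorm(ny, meanlog = 0, sdlog = 0.25)
  )
}

#' Six-hourly-like wind samples
#'
#' Weibull-distributed speeds and von Mises-distributed directions around a
#' prevailing direction; stand-in for reanalysis wind at a transect.
#'
#' @param n_samples number of samples.
#' @param prevailing_direction mean direction (degrees from north).
#' @param weibull_scale,weibull_shape Weibull speed parameters (m s^-1).
#' @param concentration von Mises concentration kappa (`Inf` collapses all
#'   directions onto the prevailing direction; 0 is uniform).
#' @param rng_seed seed.
#' @return Tibble with columns `sample, speed_ms, direction_deg`.
#' @export
synth_wind <- function(n_samples,
                       prevailing_direction = 225,
                       weibull_scale = 5,
                       weibull_shape = 2,
                       concentration = 2,
                       rng_seed = 1L) {
  set.seed(as.integer(rng_seed))
  speed <- rweibull(n_samples, shape = weibull_shape, scale = weibull_scale)
  theta <- rvonmises(n_samples, mu = prevailing_direction * pi / 180,
                     kappa = concentration)
  tibble(
    sample = seq_len(n_samples),
    speed_ms = speed,
    direction_deg = (theta * 180 / pi) %% 360
  )
}

# Best & Fisher (1979) rejection sampler; mu in radians.
rvonmises <- function(n, mu, kappa) {
  if (!is.finite(kappa)) return(rep(mu %% (2 * pi), n))
  if (kappa <= 1e-10) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(32L, ceiling((n - length(out)) * 1.5))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, th)
  }
  (mu + out[seq_len(n)]) %% (2 * pi)
}

# ---------------------------------------------------------------------------
# proxy extension and calibration

#' Extend an annual proxy series by pre-industrial block resampling
#'
#' Covers `span` by stitching `block_len`-year contiguous blocks sampled
#' (with replacement) from the pre-`preindustrial_cutoff` part of the
#' reference series, so the extended series carries the reference's
#' pre-industrial interannual variability.
#'
#' @param reference tibble `year, value, thickness`; years contiguous.
#' @param block_len block length in years (default 25).
#' @param preindustrial_cutoff blocks are drawn entirely from years
#'   `< preindustrial_cutoff` (default 1800).
#' @param rng_seed seed.
#' @param span target year range (default `c(501, 1900)`).
#' @return Tibble `year, value, thickness` covering `span` contiguously.
#' @export
extend_proxy_series <- function(reference, block_len = 25,
                                preindustrial_cutoff = 1800,
                                rng_seed = 1L,
                                span = c(501, 1900)) {
  stopifnot(is.data.frame(reference),
            all(c("year", "value", "thickness") %in% names(reference)))
  reference <- arrange(reference, .data$year)
  if (any(diff(reference$year) != 1)) {
    abort("`reference` years must be contiguous")
  }
  pre_years <- reference$year[reference$year < preindustrial_cutoff]
  starts <- pre_years[pre_years + block_len - 1 <= max(pre_years)]
  if (length(starts) == 0) {
    abort("reference has no full pre-industrial block of `block_len` years")
  }
  set.seed(as.integer(rng_seed))
  target <- span[1]:span[2]
  n_blocks <- ceiling(length(target) / block_len)
  chosen <- starts[sample.int(length(starts), n_blocks, replace = TRUE)]
  src_year <- unlist(lapply(chosen, function(s) s + 0:(block_len - 1)))
  src_year <- src_year[seq_along(target)]
  i <- match(src_year, reference$year)
  tibble(year = target,
         value = reference$value[i],
         thickness = reference$thickness[i])
}

#' Calibrate an annual proxy against instrumental climate
#'
#' For each transect node, fits ordinary least squares of annual mean
#' temperature and of annual precipitation on the proxy value over the
#' overlap years. The fitted models are applied to an extended proxy with
#' [predict_annual_means()] to yield pre-instrumental annual means.
#'
#' @param proxy tibble `year, value, ...`.
#' @param instrumental monthly climate series (see [synth_instrumental()]).
#' @param overlap two-element year range used for fitting (default
#'   `c(1901, 1998)`).
#' @return An object of class `"instrumental_calibration"` with a per-node,
#'   per-variable coefficient table. Supports [tidy()] and [glance()].
#' @export
calibrate_to_instrumental <- function(proxy, instrumental,
                                      overlap = c(1901, 1998)) {
  assert_climate_series(instrumental, "instrumental")
  stopifnot(all(c("year", "value") %in% names(proxy)))
  ann <- instrumental %>%
    filter(.data$year >= overlap[1], .data$year <= overlap[2]) %>%
    group_by(.data$node_km, .data$year) %>%
    summarise(temp_mean_C = mean(.data$temp_C),
              precip_mm = sum(.data$precip_mm), .groups = "drop") %>%
    left_join(select(proxy, "year", "value"), by = "year")
  if (any(is.na(ann$value))) {
    abort("proxy does not cover all overlap years present in `instrumental`")
  }
  if (nrow(ann) == 0) abort("no overlap years between proxy and instrumental")
  v <- ann$value[ann$node_km == ann$node_km[1]]
  if (sd(v) < 1e-12) {
    abort("degenerate fit: proxy has zero variance over the overlap years")
  }
  fits <- ann %>%
    tidyr::pivot_longer(c("temp_mean_C", "precip_mm"),
                        names_to = "variable", values_to = "obs") %>%
    group_by(.data$node_km, .data$variable) %>%
    summarise(fit = list(lm(obs ~ value, data = dplyr::pick("obs", "value"))),
              .groups = "drop")
  coefs <- fits %>%
    mutate(
      intercept = purrr::map_dbl(.data$fit, ~ coef(.x)[[1]]),
      slope = purrr::map_dbl(.data$fit, ~ coef(.x)[[2]]),
      r.squared = purrr::map_dbl(.data$fit, ~ summary(.x)$r.squared),
      sigma = purrr::map_dbl(.data$fit, ~ summary(.x)$sigma),
      nobs = purrr::map_int(.data$fit, ~ stats::nobs(.x))
    ) %>%
    select(-"fit")
  structure(list(coefficients = coefs, overlap = overlap),
            class = "instrumental_calibration")
}

#' @export
print.instrumental_calibration <- function(x, ...) {
  cat("Proxy-instrumental calibration (overlap ",
      x$overlap[1], "-", x$overlap[2], ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @rdname calibrate_to_instrumental
#' @param x an `instrumental_calibration` object.
#' @param ... unused.
#' @method tidy instrumental_calibration
#' @export
tidy.instrumental_calibration <- function(x, ...) {
  x$coefficients %>%
    tidyr::pivot_longer(c("intercept", "slope"),
                        names_to = "term", values_to = "estimate") %>%
    select("node_km", "variable", "term", "estimate")
}

#' @rdname calibrate_to_instrumental
#' @method glance instrumental_calibration
#' @export
glance.instrumental_calibration <- function(x, ...) {
  select(x$coefficients, "node_km", "variable", "r.squared", "sigma", "nobs")
}

#' Apply a calibration to an (extended) proxy series
#'
#' @param calibration result of [calibrate_to_instrumental()].
#' @param proxy tibble `year, value`.
#' @return Tibble `node_km, year, temp_mean_C, precip_mm` (precipitation
#'   floored at zero).
#' @export
predict_annual_means <- function(calibration, proxy) {
  stopifnot(inherits(calibration, "instrumental_calibration"))
  wide <- calibration$coefficients %>%
    select("node_km", "variable", "intercept", "slope")
  out <- tidyr::expand_grid(
    node_km = unique(wide$node_km),
    year = proxy$year
  ) %>%
    left_join(select(proxy, "year", "value"), by = "year")
  tt <- filter(wide, .data$variable == "temp_mean_C")
  pp <- filter(wide, .data$variable == "precip_mm")
  out$temp_mean_C <- tt$intercept[match(out$node_km, tt$node_km)] +
    tt$slope[match(out$node_km, tt$node_km)] * out$value
  out$precip_mm <- pmax(0, pp$intercept[match(out$node_km, pp$node_km)] +
    pp$slope[match(out$node_km, pp$node_km)] * out$value)
  select(out, "node_km", "year", "temp_mean_C", "precip_mm")
}

# ---------------------------------------------------------------------------
# monthly assembly

#' Assemble pre-instrumental monthly series from instrumental blocks
#'
#' Samples `block_len`-year blocks of instrumental monthly data and adjusts
#' each year so that its annual statistics match the calibrated targets:
#' temperature additively (every month of a source year is shifted by the
#' difference between target annual mean and source annual mean, so output
#' annual means equal the targets exactly) and precipitation multiplicatively
#' (months scaled by the ratio of target to source annual totals).
#'
#' @param annual_means tibble `node_km, year, temp_mean_C, precip_mm`
#'   (targets, typically from [predict_annual_means()]).
#' @param instrumental monthly climate series providing the within-year
#'   shape.
#' @param block_len source block length in years (default 15).
#' @param rng_seed seed.
#' @return Monthly tibble `node_km, year, month, temp_C, precip_mm` covering
#'   the years of `annual_means`.
#' @export
assemble_monthly_preinstrumental <- function(annual_means, instrumental,
                                             block_len = 15, rng_seed = 1L) {
  assert_climate_series(instrumental, "instrumental")
  stopifnot(all(c("node_km", "year", "temp_mean_C", "precip_mm") %in%
                  names(annual_means)))
  set.seed(as.integer(rng_seed))
  inst_years <- sort(unique(instrumental$year))
  starts <- inst_years[inst_years + block_len - 1 <= max(inst_years)]
  if (length(starts) == 0) abort("instrumental shorter than `block_len`")
  target_years <- sort(unique(annual_means$year))
  n_blocks <- ceiling(length(target_years) / block_len)
  chosen <- starts[sample.int(length(starts), n_blocks, replace = TRUE)]
  src <- unlist(lapply(chosen, function(s) s + 0:(block_len - 1)))
  map <- tibble(year = target_years, src_year = src[seq_along(target_years)])

  inst_ann <- instrumental %>%
    group_by(.data$node_km, .data$year) %>%
    summarise(src_tmean = mean(.data$temp_C),
              src_ptot = sum(.data$precip_mm), .groups = "drop")

  out <- annual_means %>%
    select("node_km", "year", "temp_mean_C", "precip_mm") %>%
    left_join(map, by = "year") %>%
    left_join(inst_ann, by = c("node_km", src_year = "year")) %>%
    left_join(
      instrumental %>%
        rename(src_year = "year", src_temp = "temp_C",
               src_precip = "precip_mm"),
      by = c("node_km", "src_year"),
      relationship = "many-to-many"
    ) %>%
    mutate(
      temp_C = .data$src_temp + (.data$temp_mean_C - .data$src_tmean),
      precip_mm = if_else(.data$src_ptot > 0,
                          .data$src_precip * .data$precip_mm / .data$src_ptot,
                          .data$precip_mm / 12)
    ) %>%
    select("node_km", "year", "month", "temp_C", "precip_mm") %>%
    arrange(.data$node_km, .data$year, .data$month)
  out
}

# ---------------------------------------------------------------------------
# scenarios

RCP_MEDIANS_2100 <- c("RCP2.6*" = 1.2, "RCP2.6" = 1.8,
                      "RCP4.5" = 2.1, "RCP8.5" = 5.0)

#' Scenario specification
#'
#' @param scenario_id one of `"RCP2.6*"`, `"RCP2.6"`, `"RCP4.5"`,
#'   `"RCP8.5"`, `"control"`, `"step"`.
#' @param post_peak_mode `"continued"` (copy the 2300-2500 block onwards) or
#'   `"cooling"` (replay the 1901-1978 data in a loop after 2500).
#' @param july_warming_median_2100 July warming at 2100 relative to the
#'   1971-2000 baseline; per-RCP defaults +1.2 / +1.8 / +2.1 / +5.0 deg C.
#'   Note the starred mitigation scenario is *constructed* as half the
#'   RCP2.6 anomaly path, so its realised 2100 anomaly is +0.9 deg C.
#' @return List of class `"scenario_spec"`.
#' @export
scenario_spec <- function(scenario_id,
                          post_peak_mode = c("continued", "cooling"),
                          july_warming_median_2100 = NULL) {
  post_peak_mode <- match.arg(post_peak_mode)
  known <- c(names(RCP_MEDIANS_2100), "control", "step")
  if (!scenario_id %in% known) {
    abort(paste0("unknown scenario_id `", scenario_id, "`"))
  }
  med <- july_warming_median_2100 %||%
    unname(RCP_MEDIANS_2100[scenario_id])
  structure(list(scenario_id = scenario_id,
                 post_peak_mode = post_peak_mode,
                 july_warming_median_2100 = med %||% NA_real_),
            class = "scenario_spec")
}

#' Synthetic scenario anomaly curves to 2300
#'
#' Temperature anomalies (deg C, applied uniformly to all months, relative
#' to the 1971-2000 baseline) per scenario and year 2006-2300. The RCP
#' curves are logistic ramps normalised so the 2100 value equals the
#' scenario's July warming median; RCP2.6 declines linearly to +0.5 deg C by
#' 2300, RCP4.5 and RCP8.5 keep rising to about +3.1 and +14 deg C, and the
#' starred scenario is exactly half the RCP2.6 anomaly. `"control"` is zero
#' and `"step"` is a constant `step_C` from `step_year` on.
#'
#' @param years years covered (default 2006:2300).
#' @param step_C,step_year step-experiment amplitude and onset.
#' @return Tibble `scenario_id, year, anomaly_C`.
#' @export
synth_scenario_curves <- function(years = 2006:2300,
                                  step_C = 1.5, step_year = 2050) {
  # logistic ramp rebased to 0 at 2005 and 1 at 2100, so each RCP curve
  # starts at zero anomaly and passes exactly through its 2100 July median
  rise <- function(t, t0, tau) {
    r <- function(x) 1 / (1 + exp(-(x - t0) / tau))
    (r(t) - r(2005)) / (r(2100) - r(2005))
  }
  a26 <- function(t) {
    pre <- 1.8 * rise(t, 2050, 20)
    post <- 1.8 + (0.5 - 1.8) * (t - 2100) / 200
    if_else(t <= 2100, pre, post)
  }
  curves <- list(
    "RCP2.6"  = a26,
    "RCP2.6*" = function(t) 0.5 * a26(t),
    "RCP4.5"  = function(t) 2.1 * rise(t, 2040, 50),   # ~+3.1 deg C by 2300
    "RCP8.5"  = function(t) 5.0 * rise(t, 2120, 60),   # ~+14 deg C by 2300
    "control" = function(t) rep(0, length(t)),
    "step"    = function(t) step_C * as.numeric(t >= step_year)
  )
  purrr::imap_dfr(curves, function(f, id) {
    tibble(scenario_id = id, year = years, anomaly_C = f(years))
  })
}

#' Append a warming scenario and extend the series to 3000 CE
#'
#' 2006-2300 is built by resampling `block_len`-year blocks from the
#' baseline window of the input series and adding the scenario's anomaly;
#' 2301-2500 continues the linear trend fitted to the 2100-2300 anomaly;
#' 2501-3000 either replays the 1901-1978 monthly data in a loop
#' (`post_peak_mode = "cooling"`, 20th-century cooling) or copies the
#' 2301-2500 block repeatedly (`"continued"`).
#'
#' @param series monthly climate series ending at year 2000 or later and
#'   containing 1901-1978.
#' @param spec a [scenario_spec()].
#' @param scenario_curves anomaly curves (see [synth_scenario_curves()])
#'   covering 2006-2300 for `spec$scenario_id`.
#' @param rng_seed seed for baseline block resampling.
#' @param baseline_window years defining the anomaly baseline climate
#'   (default 1971-2000).
#' @param block_len baseline resampling block length.
#' @return The input series with appended years up to 3000 CE.
#' @export
append_scenario <- function(series, spec, scenario_curves, rng_seed = 1L,
                            baseline_window = c(1971, 2000),
                            block_len = 15) {
  assert_climate_series(series)
  stopifnot(inherits(spec, "scenario_spec"))
  if (max(series$year) < 2000) abort("`series` must extend to year 2000")
  cur <- filter(scenario_curves, .data$scenario_id == spec$scenario_id)
  if (nrow(cur) == 0) {
    abort(paste0("scenario_curves has no rows for `", spec$scenario_id, "`"))
  }
  if (min(cur$year) > max(series$year) + 1 || max(cur$year) < 2300) {
    abort("scenario curves must cover (end of series, 2300]")
  }
  set.seed(as.integer(rng_seed))

  base <- filter(series, .data$year >= baseline_window[1],
                 .data$year <= baseline_window[2])
  base_years <- sort(unique(base$year))
  starts <- base_years[base_years + block_len - 1 <= max(base_years)]

  first_new <- max(series$year) + 1
  mid_years <- first_new:2500
  n_blocks <- ceiling(length(mid_years) / block_len)
  chosen <- starts[sample.int(length(starts), n_blocks, replace = TRUE)]
  src <- unlist(lapply(chosen, function(s) s + 0:(block_len - 1)))
  map_mid <- tibble(year = mid_years, src_year = src[seq_along(mid_years)])

  # anomaly path: curves to 2300, then the 2100-2300 linear trend to 2500
  anom <- setNames(cur$anomaly_C, cur$year)
  fit_years <- 2100:2300
  tr <- lm(anom[as.character(fit_years)] ~ fit_years)
  anomaly_at <- function(y) {
    out <- numeric(length(y))
    in_curve <- y <= 2300 & y >= min(cur$year)
    out[in_curve] <- anom[as.character(y[in_curve])]
    out[y > 2300] <- coef(tr)[1] + coef(tr)[2] * y[y > 2300]
    out[y < min(cur$year)] <- 0
    out
  }

  mid <- map_mid %>%
    left_join(series %>% rename(src_year = "year"), by = "src_year",
              relationship = "many-to-many") %>%
    mutate(temp_C = .data$temp_C + anomaly_at(.data$year)) %>%
    select("node_km", "year", "month", "temp_C", "precip_mm")

  tail_years <- 2501:3000
  if (spec$post_peak_mode == "cooling") {
    map_tail <- tibble(year = tail_years,
                       src_year = 1901 + (tail_years - 2501) %% 78)
    pool <- series
  } else {
    map_tail <- tibble(year = tail_years,
                       src_year = 2301 + (tail_years - 2501) %% 200)
    pool <- mid
  }
  tail_part <- map_tail %>%
    left_join(pool %>% rename(src_year = "year"), by = "src_year",
              relationship = "many-to-many") %>%
    select("node_km", "year", "month", "temp_C", "precip_mm")

  bind_rows(series, mid, tail_part) %>%
    arrange(.data$node_km, .data$year, .data$month)
}

# ---------------------------------------------------------------------------
# regional lapse offsets

REGION_OFFSET_DEFAULTS <- tibble::tibble(
  region_name = c("Taimyr", "BuorKhaya", "Kolyma", "Chukotka"),
  d_t_jan = c(-1.17, -0.23, 3.14, 4.46),
  d_t_jul = c(-0.84, -2.48, 1.26, 4.30),
  d_p_year = c(-5.4, -28.9, 85.7, 8.2)
)

#' Tuned regional lapse-rate offsets
#'
#' The per-region local adjustments (January temperature, July temperature,
#' annual precipitation) that absorb elevation and topography effects the
#' 10-km climate interpolation cannot represent.
#'
#' @param region_name optional; one of `"Taimyr"`, `"BuorKhaya"`,
#'   `"Kolyma"`, `"Chukotka"`. If omitted, the full table is returned.
#' @return A one-row tibble (or the full table).
#' @export
region_offsets <- function(region_name = NULL) {
  if (is.null(region_name)) return(REGION_OFFSET_DEFAULTS)
  out <- filter(REGION_OFFSET_DEFAULTS, .data$region_name == !!region_name)
  if (nrow(out) == 0) abort(paste0("unknown region `", region_name, "`"))
  out
}

#' Apply regional lapse offsets to a monthly climate series
#'
#' January temperatures are shifted by `d_t_jan`, July by `d_t_jul`, other
#' months by a cosine interpolation over the annual cycle. Annual
#' precipitation is rescaled multiplicatively so each node-year total
#' changes by `d_p_year`; a rescale that would turn months negative is
#' clamped at zero with a warning.
#'
#' @param series monthly climate series.
#' @param offsets one-row data frame or list with `d_t_jan, d_t_jul,
#'   d_p_year` (see [region_offsets()]).
#' @return The adjusted series.
#' @export
apply_region_offsets <- function(series, offsets) {
  assert_climate_series(series)
  w <- (1 + cos(2 * pi * (series$month - 7) / 12)) / 2  # 1 in July, 0 in Jan
  shift <- offsets$d_t_jul * w + offsets$d_t_jan * (1 - w)
  out <- mutate(series, temp_C = .data$temp_C + shift)
  out <- out %>%
    group_by(.data$node_km, .data$year) %>%
    mutate(.ptot = sum(.data$precip_mm)) %>%
    ungroup()
  scale <- ifelse(out$.ptot > 0, 1 + offsets$d_p_year / out$.ptot,
                  ifelse(offsets$d_p_year > 0, NA, 1))
  if (any(scale < 0, na.rm = TRUE)) {
    warn("precipitation offset exceeds annual total; clamping months at 0")
    scale <- pmax(scale, 0)
  }
  out$precip_mm <- ifelse(is.na(scale), offsets$d_p_year / 12,
                          out$precip_mm * scale)
  select(out, -".ptot")
}

# ---------------------------------------------------------------------------
# climate auxiliaries

# 365-day linear interpolation weights from mid-month anchor values,
# periodic across the year boundary. Rows = day, cols = month.
daily_weight_matrix <- function() {
  mids <- cumsum(MONTH_DAYS) - MONTH_DAYS / 2
  anchors <- c(mids[12] - 365, mids, mids[1] + 365)
  amonth <- c(12, 1:12, 1)
  W <- matrix(0, 365, 12)
  d <- (1:365) - 0.5
  iv <- findInterval(d, anchors)
  frac <- (d - anchors[iv]) / (anchors[iv + 1] - anchors[iv])
  for (k in 1:365) {
    W[k, amonth[iv[k]]] <- W[k, amonth[iv[k]]] + (1 - frac[k])
    W[k, amonth[iv[k] + 1]] <- W[k, amonth[iv[k] + 1]] + frac[k]
  }
  W
}

#' Climate auxiliaries per node and year
#'
#' Derives, for every (node, year) of a monthly series, the auxiliaries that
#' drive tree growth and mortality: January and July temperature, net degree
#' days NDD0 (sum of daily-interpolated temperatures above 0 deg C), active
#' air temperature AAT10 (sum of daily temperatures on days above 10 deg C),
#' annual precipitation, and a drought index (annual precipitation over
#' growing-season degree days). Daily temperatures are linear interpolations
#' between mid-month values on a 365-day year.
#'
#' @param series monthly climate series.
#' @return Tibble `node_km, year, t_jan, t_jul, ndd0, aat10, p_year,
#'   drought_index`.
#' @export
#' @examples
#' inst <- synth_instrumental(1, years = 2000, rng_seed = 1)
#' climate_auxiliaries(inst)
climate_auxiliaries <- function(series) {
  assert_climate_series(series)
  key <- series %>%
    arrange(.data$node_km, .data$year, .data$month)
  ids <- distinct(key, .data$node_km, .data$year)
  if (nrow(key) != nrow(ids) * 12) {
    abort("series must have exactly 12 months per node-year")
  }
  Tm <- matrix(key$temp_C, ncol = 12, byrow = TRUE)
  Pm <- matrix(key$precip_mm, ncol = 12, byrow = TRUE)
  W <- daily_weight_matrix()
  D <- Tm %*% t(W)
  ndd0 <- rowSums(pmax(D, 0))
  aat10 <- rowSums(D * (D > 10))
  p_year <- rowSums(Pm)
  tibble(
    node_km = ids$node_km,
    year = ids$year,
    t_jan = Tm[, 1],
    t_jul = Tm[, 7],
    ndd0 = ndd0,
    aat10 = aat10,
    p_year = p_year,
    drought_index = p_year / pmax(ndd0, 1)
  )
}

#' @rdname climate_auxiliaries
#' @param node,year a single node position (km) and calendar year.
#' @export
derive_auxiliaries <- function(series, node, year) {
  one <- filter(series, .data$node_km == !!node, .data$year == !!year)
  if (nrow(one) != 12) abort("need exactly 12 months for the requested node-year")
  climate_auxiliaries(one)
}

# ---------------------------------------------------------------------------
# end-to-end builder and file interfaces

#' Build a complete 501-3000 CE forcing series for one transect
#'
#' Chains the full construction: synthetic instrumental series, proxy
#' generation and pre-industrial block extension, node-wise calibration,
#' monthly assembly for 501-1900, scenario append to 3000, and (optionally)
#' regional lapse offsets. All random steps derive their seeds from
#' `rng_seed` with fixed labels.
#'
#' @param scenario scenario id (see [scenario_spec()]).
#' @param post_peak_mode `"continued"` or `"cooling"`.
#' @param n_nodes,node_spacing_km transect discretisation.
#' @param rng_seed master seed.
#' @param offsets optional regional offsets (row of [region_offsets()]).
#' @param gradient_C_per_100km poleward July cooling of the synthetic
#'   instrumental stand-in.
#' @param step_C,step_year parameters of the `"step"` pseudo-scenario.
#' @param instrumental optionally, a real instrumental monthly series to use
#'   instead of the synthetic stand-in (same tabular interface).
#' @return Monthly climate tibble covering 501-3000 CE for all nodes, with
#'   attributes `scenario` and `post_peak_mode`.
#' @export
build_forcing <- function(scenario = "RCP4.5",
                          post_peak_mode = "continued",
                          n_nodes = 6,
                          node_spacing_km = 10,
                          rng_seed = 1L,
                          offsets = NULL,
                          gradient_C_per_100km = 9,
                          step_C = 1.5,
                          step_year = 2050,
                          instrumental = NULL) {
  if (is.null(instrumental)) {
    instrumental <- synth_instrumental(
      n_nodes = n_nodes, years = 1901:2005,
      gradient_C_per_100km = gradient_C_per_100km,
      node_spacing_km = node_spacing_km,
      rng_seed = derive_seed(rng_seed, "instrumental")
    )
  } else {
    assert_climate_series(instrumental, "instrumental")
  }
  proxy <- synth_proxy(instrumental = instrumental,
                       rng_seed = derive_seed(rng_seed, "proxy"))
  ext <- extend_proxy_series(proxy,
                             rng_seed = derive_seed(rng_seed, "proxy-extend"))
  calib <- calibrate_to_instrumental(proxy, instrumental)
  ann <- predict_annual_means(calib, ext)
  pre <- assemble_monthly_preinstrumental(
    ann, instrumental, rng_seed = derive_seed(rng_seed, "assemble"))
  series <- bind_rows(pre, instrumental)
  curves <- synth_scenario_curves(step_C = step_C, step_year = step_year)
  full <- append_scenario(series, scenario_spec(scenario, post_peak_mode),
                          curves,
                          rng_seed = derive_seed(rng_seed, "scenario"))
  if (!is.null(offsets)) full <- apply_region_offsets(full, offsets)
  attr(full, "scenario") <- scenario
  attr(full, "post_peak_mode") <- post_peak_mode
  full
}

#' Read and write climate / wind tables
#'
#' Tidy tab-separated text with the documented column schema
#' (`node_km, year, month, temp_C, precip_mm` for climate;
#' `sample, speed_ms, direction_deg` for wind).
#'
#' @param series,wind tibbles to write.
#' @param path file path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
write_climate_series <- function(series, path) {
  assert_climate_series(series)
  readr::write_tsv(series, path)
  invisible(path)
}

#' @rdname write_climate_series
#' @export
read_climate_series <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_climate_series(out, "file contents")
  out
}

#' @rdname write_climate_series
#' @export
write_wind <- function(wind, path) {
  readr::write_tsv(wind, path)
  invisible(path)
}

#' @rdname write_climate_series
#' @export
read_wind <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
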