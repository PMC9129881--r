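# Forcing construction: proxy extension, calibration, monthly assembly,
# scenarios, offsets and auxiliaries.

test_that("extend_proxy_series spans the target contiguously and preserves blocks", {
  ref <- tibble::tibble(year = 1700:1799, value = 1:100,
                        thickness = rep(1, 100))
  out <- extend_proxy_series(ref, block_len = 25, rng_seed = 3,
                             span = c(501, 550))
  expect_equal(out$year, 501:550)
  expect_equal(nrow(out), 50)

  # constant-value reference: any resampling returns the constant
  refc <- tibble::tibble(year = 1600:1790, value = 7, thickness = 1)
  outc <- extend_proxy_series(refc, rng_seed = 99)
  expect_true(all(outc$value == 7))
  expect_equal(outc$year, 501:1900)

  # every output block must equal one of the 76 possible contiguous
  # reference blocks (brute-force scan)
  out2 <- extend_proxy_series(ref, block_len = 25, rng_seed = 11,
                              span = c(501, 700))
  ref_blocks <- lapply(1:76, function(s) ref$value[s:(s + 24)])
  for (b in split(out2$value, (seq_len(200) - 1) %/% 25)) {
    hits <- vapply(ref_blocks, function(rb) {
      all(rb[seq_along(b)] == b)
    }, logical(1))
    expect_true(any(hits))
  }

  expect_error(extend_proxy_series(ref, block_len = 200),
               "pre-industrial block")
})

test_that("proxy calibration recovers linear relations", {
  inst <- synth_instrumental(2, years = 1901:1998, rng_seed = 5)
  ann <- dplyr::summarise(dplyr::group_by(inst, node_km, year),
                          t = mean(temp_C), .groups = "drop")
  # proxy identical to node-0 annual mean temperature: slope 1, intercept 0
  prox <- tibble::tibble(year = 1901:1998,
                         value = ann$t[ann$node_km == 0])
  cal <- suppressWarnings(  # perfect fits by construction
    calibrate_to_instrumental(prox, dplyr::filter(inst, node_km == 0)))
  co <- dplyr::filter(cal$coefficients, variable == "temp_mean_C")
  expect_equal(co$slope, 1, tolerance = 1e-10)
  expect_equal(co$intercept, 0, tolerance = 1e-8)

  # proxy = 2 * T + 3: inverse slope 0.5, checked against closed-form OLS
  # on five printed points
  tt <- c(10.2, 11.5, 9.8, 12.1, 10.9)
  # 12 identical months so the annual mean equals tt
  pts <- tidyr::expand_grid(tibble::tibble(year = 2001:2005, t = tt),
                            month = 1:12) %>%
    dplyr::mutate(node_km = 0, temp_C = t, precip_mm = 1) %>%
    dplyr::select(node_km, year, month, temp_C, precip_mm)
  prox2 <- tibble::tibble(year = 2001:2005, value = 2 * tt + 3)
  cal2 <- suppressWarnings(
    calibrate_to_instrumental(prox2, pts, overlap = c(2001, 2005)))
  co2 <- dplyr::filter(cal2$coefficients, variable == "temp_mean_C")
  x <- prox2$value
  beta_hand <- sum((x - mean(x)) * (tt - mean(tt))) / sum((x - mean(x))^2)
  expect_equal(co2$slope, beta_hand, tolerance = 1e-12)
  expect_equal(co2$slope, 0.5, tolerance = 1e-10)

  # noise -> 0 limit recovers the true coefficients
  set.seed(1)
  prox3 <- tibble::tibble(year = 1901:1998,
                          value = 0.5 * ann$t[ann$node_km == 0] - 4 +
                            rnorm(98, 0, 1e-9))
  cal3 <- calibrate_to_instrumental(prox3, dplyr::filter(inst, node_km == 0))
  co3 <- dplyr::filter(cal3$coefficients, variable == "temp_mean_C")
  expect_equal(co3$slope, 2, tolerance = 1e-5)
  expect_equal(co3$intercept, 8, tolerance = 1e-4)

  # zero proxy variance must refuse, not fall back
  proxc <- tibble::tibble(year = 1901:1998, value = 1)
  expect_error(calibrate_to_instrumental(proxc, inst), "degenerate")

  expect_s3_class(tidy(cal), "tbl_df")
  expect_true(all(c("r.squared", "sigma") %in% names(glance(cal))))
})

test_that("monthly assembly reproduces target annual means exactly", {
  inst <- synth_instrumental(2, years = 1951:2000, rng_seed = 2)
  targets <- tidyr::expand_grid(node_km = c(0, 10), year = 801:860) %>%
    dplyr::mutate(temp_mean_C = -10 + 0.05 * (year - 800),
                  precip_mm = 250 + (year %% 7))
  out <- assemble_monthly_preinstrumental(targets, inst, rng_seed = 4)
  expect_equal(nrow(out), 2 * 60 * 12)
  got <- out %>%
    dplyr::group_by(node_km, year) %>%
    dplyr::summarise(tm = mean(temp_C), pm = sum(precip_mm),
                     .groups = "drop") %>%
    dplyr::left_join(targets, by = c("node_km", "year"))
  # temperature: additive shift makes annual means exact
  expect_equal(got$tm, got$temp_mean_C, tolerance = 1e-12)
  # precipitation: multiplicative shift makes annual totals exact
  expect_equal(got$pm, got$precip_mm, tolerance = 1e-9)

  # a target equal to the source block's own mean leaves months unshifted;
  # +2 deg C shifts every month by +2
  ann0 <- inst %>% dplyr::filter(node_km == 0) %>%
    dplyr::group_by(year) %>%
    dplyr::summarise(tm = mean(temp_C), pm = sum(precip_mm))
  t1 <- tibble::tibble(node_km = 0, year = 901,
                       temp_mean_C = ann0$tm[1] + 2, precip_mm = ann0$pm[1])
  # force the sampled block to start at the first instrumental year by
  # providing a one-block instrumental series
  inst1 <- dplyr::filter(inst, node_km == 0, year <= 1965)
  shifted <- assemble_monthly_preinstrumental(t1, inst1, block_len = 15,
                                              rng_seed = 1)
  expect_equal(shifted$temp_C,
               dplyr::filter(inst1, year == 1951)$temp_C + 2,
               tolerance = 1e-12)
})

test_that("scenario append has exact copy semantics and ordered anomalies", {
  inst <- synth_instrumental(2, years = 1901:2005, rng_seed = 8)
  curves <- synth_scenario_curves()

  cont <- append_scenario(inst, scenario_spec("RCP4.5", "continued"),
                          curves, rng_seed = 5)
  expect_equal(sort(unique(cont$year)), 1901:3000)
  jul <- dplyr::filter(cont, month == 7, node_km == 0)
  expect_equal(jul$temp_C[jul$year %in% 2501:2700],
               jul$temp_C[jul$year %in% 2301:2500])

  cool <- append_scenario(inst, scenario_spec("RCP4.5", "cooling"),
                          curves, rng_seed = 5)
  julc <- dplyr::filter(cool, month == 7)
  ref <- julc %>% dplyr::filter(year %in% 1901:1978) %>%
    dplyr::group_by(node_km) %>% dplyr::summarise(m = mean(temp_C))
  rep_ <- julc %>% dplyr::filter(year >= 2501) %>%
    dplyr::group_by(node_km) %>% dplyr::summarise(m2 = mean(temp_C))
  expect_true(all(abs(ref$m - rep_$m2) < 0.01))

  # the starred mitigation curve is half the RCP2.6 anomaly by construction
  a26 <- dplyr::filter(curves, scenario_id == "RCP2.6")
  a26s <- dplyr::filter(curves, scenario_id == "RCP2.6*")
  expect_equal(a26s$anomaly_C, 0.5 * a26$anomaly_C, tolerance = 1e-12)
  expect_equal(a26$anomaly_C[a26$year == 2100], 1.8, tolerance = 1e-9)

  # scenario ordering of mean 2050-2100 anomalies
  ord <- curves %>%
    dplyr::filter(year >= 2050, year <= 2100) %>%
    dplyr::group_by(scenario_id) %>%
    dplyr::summarise(m = mean(anomaly_C))
  m <- setNames(ord$m, ord$scenario_id)
  expect_true(m[["RCP2.6*"]] < m[["RCP2.6"]] &&
                m[["RCP2.6"]] < m[["RCP4.5"]] &&
                m[["RCP4.5"]] < m[["RCP8.5"]])

  expect_error(scenario_spec("RCP9.9"), "unknown scenario")
})

test_that("assembled series has no gaps or duplicates over 501-3000", {
  f <- build_forcing("RCP2.6", "continued", n_nodes = 2, rng_seed = 3)
  expect_equal(nrow(f), 2 * 2500 * 12)
  expect_equal(nrow(dplyr::distinct(f, node_km, year, month)), nrow(f))
  expect_equal(sort(unique(f$year)), 501:3000)
})

test_that("regional offsets shift January/July and rescale precipitation", {
  inst <- synth_instrumental(1, years = 2000:2001, rng_seed = 1)
  same <- apply_region_offsets(inst, list(d_t_jan = 0, d_t_jul = 0,
                                          d_p_year = 0))
  expect_equal(same$temp_C, inst$temp_C)
  expect_equal(same$precip_mm, inst$precip_mm)

  chu <- apply_region_offsets(inst, region_offsets("Chukotka"))
  expect_equal(chu$temp_C[chu$month == 7] - inst$temp_C[inst$month == 7],
               rep(4.30, 2), tolerance = 1e-12)
  expect_equal(chu$temp_C[chu$month == 1] - inst$temp_C[inst$month == 1],
               rep(4.46, 2), tolerance = 1e-12)
  ptot <- tapply(inst$precip_mm, inst$year, sum)
  ptot2 <- tapply(chu$precip_mm, chu$year, sum)
  expect_equal(as.numeric(ptot2 - ptot), rep(8.2, 2), tolerance = 1e-9)

  # removing the whole annual total clamps every month at zero
  tot1 <- sum(inst$precip_mm[inst$year == 2000])
  z <- apply_region_offsets(dplyr::filter(inst, year == 2000),
                            list(d_t_jan = 0, d_t_jul = 0,
                                 d_p_year = -tot1))
  expect_equal(z$precip_mm, rep(0, 12), tolerance = 1e-9)

  expect_error(region_offsets("Atlantis"), "unknown region")
})

test_that("climate auxiliaries match daily enumeration", {
  mk <- function(temps, precip = 20) {
    tibble::tibble(node_km = 0, year = 1, month = 1:12,
                   temp_C = temps, precip_mm = precip)
  }
  cold <- derive_auxiliaries(mk(rep(-10, 12)), 0, 1)
  expect_equal(cold$ndd0, 0)
  expect_equal(cold$aat10, 0)

  warm <- derive_auxiliaries(mk(rep(12, 12)), 0, 1)
  expect_equal(warm$aat10, 365 * 12)
  expect_equal(warm$ndd0, 365 * 12)
  expect_equal(warm$p_year, 240)
  expect_equal(warm$drought_index, 240 / (365 * 12))

  # sinusoidal cycle: brute-force day-by-day linear interpolation oracle
  temps <- 15 * cos(2 * pi * (1:12 - 7) / 12)
  got <- derive_auxiliaries(mk(temps), 0, 1)
  dm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  mids <- cumsum(dm) - dm / 2
  anchors <- c(mids[12] - 365, mids, mids[1] + 365)
  vals <- c(temps[12], temps, temps[1])
  daily <- stats::approx(anchors, vals, xout = (1:365) - 0.5)$y
  expect_equal(got$ndd0, sum(pmax(daily, 0)), tolerance = 1e-9)
  expect_equal(got$aat10, sum(daily[daily > 10]), tolerance = 1e-9)
  expect_equal(got$t_jul, temps[7])
  expect_equal(got$t_jan, temps[1])
})

test_that("synthetic instrumental series honours gradient, seed and noise", {
  two <- synth_instrumental(2, years = 1991:2000, node_spacing_km = 500,
                            gradient_C_per_100km = 1, rng_seed = 6)
  jul <- dplyr::filter(two, month == 7)
  d <- mean(jul$temp_C[jul$node_km == 0]) -
    mean(jul$temp_C[jul$node_km == 500])
  expect_equal(d, 5, tolerance = 1e-9)

  a <- synth_instrumental(3, years = 1901:1950, rng_seed = 42)
  b <- synth_instrumental(3, years = 1901:1950, rng_seed = 42)
  expect_identical(a, b)

  quiet <- synth_instrumental(1, years = 1901:1920, rng_seed = 1,
                              ar1_sd = 0, month_sd = 0, precip_cv = 0)
  m <- matrix(quiet$temp_C, nrow = 12)
  expect_equal(m[, 1], m[, 20])  # exactly periodic without noise
})

test_that("wind samples match the requested distributions", {
  calm <- synth_wind(100, weibull_scale = 1e-9, rng_seed = 1)
  expect_true(all(calm$speed_ms < 1e-6))

  aligned <- synth_wind(100, prevailing_direction = 123,
                        concentration = Inf, rng_seed = 1)
  expect_equal(aligned$direction_deg, rep(123, 100), tolerance = 1e-9)

  w <- synth_wind(1e5, weibull_scale = 5, weibull_shape = 2, rng_seed = 9)
  analytic_mean <- 5 * gamma(1 + 1 / 2)
  se <- sd(w$speed_ms) / sqrt(nrow(w))
  expect_lt(abs(mean(w$speed_ms) - analytic_mean), 3 * se)
  expect_true(all(w$direction_deg >= 0 & w$direction_deg < 360))
})

test_that("climate and wind tables round-trip through the file interface", {
  f <- synth_instrumental(2, years = 1999:2001, rng_seed = 1)
  p <- tempfile(fileext = ".tsv"); on.exit(unlink(p), add = TRUE)
  write_climate_series(f, p)
  back <- read_climate_series(p)
  expect_equal(as.data.frame(back), as.data.frame(f), tolerance = 1e-12)

  w <- synth_wind(50, rng_seed = 2)
  pw <- tempfile(fileext = ".tsv"); on.exit(unlink(pw), add = TRUE)
  write_wind(w, pw)
  expect_equal(as.data.frame(read_wind(pw)), as.data.frame(w),
               tolerance = 1e-12)
})
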