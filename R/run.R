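# The yearly loop. State lives in an environment holding parallel vectors
# for trees and seeds plus precomputed per-node climate arrays, so run_year
# mutates in place and a full transect-century costs no tibble churn.

# shared-findInterval interpolation of several per-node columns at once;
# V is an n_nodes x k matrix, returns a length(y) x k matrix
interp_nodes_mat <- function(node_m, V, y) {
  nn <- length(node_m)
  if (nn == 1) return(matrix(rep(as.numeric(V), each = length(y)),
                             nrow = length(y)))
  i <- findInterval(y, node_m)
  i <- pmax(1L, pmin(i, nn - 1L))
  f <- ramp01((y - node_m[i]) / (node_m[i + 1] - node_m[i]))
  V[i, , drop = FALSE] * (1 - f) + V[i + 1, , drop = FALSE] * f
}

#' Initialise a simulation state
#'
#' Precomputes per-node climate auxiliaries for the whole run (a
#' stabilization phase looping the first 30 simulation years, then the
#' transient years), including the trailing 10-year means used by growth and
#' mortality, and seeds the RNG for one repeat.
#'
#' @param config [simulation_config()].
#' @param forcing monthly climate series covering `years`.
#' @param params [larch_params()].
#' @param years calendar years to simulate (default: all forcing years).
#' @param repeat_id repeat number; the stream seed is derived from
#'   `config$rng_seed` and this id.
#' @param wind wind sample table (default: generated from the derived seed).
#' @return An environment of class `"sim_state"`.
#' @export
sim_state_init <- function(config, forcing, params = larch_params(),
                           years = NULL, repeat_id = 1L, wind = NULL) {
  assert_climate_series(forcing, "forcing")
  years <- years %||% sort(unique(forcing$year))
  missing_years <- setdiff(years, unique(forcing$year))
  if (length(missing_years)) {
    abort(paste0("forcing gap: no data for year(s) ",
                 paste(head(missing_years, 5), collapse = ", ")))
  }
  # stabilization loops a 30-year climate window: the 30 years immediately
  # preceding the simulation start when the forcing provides them (so
  # spin-up climate is scenario-independent), otherwise the first 30
  # simulated years
  avail <- sort(unique(forcing$year))
  pre <- avail[avail < years[1] & avail >= years[1] - 30]
  loop_years <- if (length(pre) == 30) pre else
    years[seq_len(min(30, length(years)))]

  L_km <- config$transect_length_km
  aux <- climate_auxiliaries(
    filter(forcing, .data$year %in% c(loop_years, years),
           .data$node_km <= L_km + config$node_spacing_km))
  nodes <- sort(unique(aux$node_km))
  if (max(nodes) < L_km) {
    warn("climate nodes do not reach the transect end; values clamp northward")
  }
  seq_years <- c(rep(loop_years, length.out = config$stabilization_years), years)
  phase <- rep(c("stabilization", "main"),
               c(config$stabilization_years, length(years)))

  vars <- c("t_jul", "ndd0", "drought_index")
  nstep <- length(seq_years)
  nn <- length(nodes)
  aux <- arrange(aux, .data$node_km, .data$year)
  ay <- sort(unique(aux$year))
  cur <- array(NA_real_, c(nn, nstep, length(vars)),
               dimnames = list(NULL, NULL, vars))
  for (v in vars) {
    m <- matrix(aux[[v]], nrow = length(ay), ncol = nn)  # year x node
    cur[, , v] <- t(m)[, match(seq_years, ay), drop = FALSE]
  }
  # trailing means over the simulated year sequence (window aux_mean_years)
  w <- params$aux_mean_years
  a10 <- cur
  for (v in vars) {
    mm <- cur[, , v]
    dim(mm) <- c(nn, nstep)
    cs <- cbind(0, t(apply(mm, 1, cumsum)))  # nn x (nstep + 1)
    for (t in seq_len(nstep)) {
      k <- min(w, t)
      a10[, t, v] <- (cs[, t + 1] - cs[, t + 1 - k]) / k
    }
  }

  seed <- derive_seed(config$rng_seed, paste0("repeat", repeat_id))
  set.seed(seed)
  if (is.null(wind)) {
    wind <- synth_wind(20000, rng_seed = derive_seed(seed, "wind"))
    set.seed(seed)  # wind pool generation must not shift the run stream
  }

  st <- new.env(parent = emptyenv())
  st$config <- config
  st$params <- params
  st$repeat_id <- repeat_id
  st$node_m <- nodes * 1000
  st$seq_years <- seq_years
  st$phase <- phase
  st$aux_cur <- cur
  st$aux10 <- a10
  st$wind_speed <- wind$speed_ms
  st$wind_dir <- wind$direction_deg
  st$step <- 0L
  # trees
  st$tx <- st$ty <- st$tbasal <- st$tdbh <- st$theight <- st$tmath <-
    st$tdi <- numeric(0)
  st$tage <- integer(0)
  # seeds
  st$sx <- st$sy <- st$srel <- numeric(0)
  st$sage <- integer(0)
  st$son <- logical(0)
  st$log <- vector("list", nstep)
  st$profiles <- list()
  st$snapshots <- list()
  class(st) <- c("sim_state", "environment")
  st
}

#' Advance a simulation state by one year
#'
#' Invokes the yearly processes in their fixed order: environment update,
#' growth, seed dispersal, seed production, establishment, mortality,
#' ageing, plus the boundary/hinterland seed introduction. Mutates `state`
#' in place and returns it invisibly.
#'
#' @param state a [sim_state_init()] environment.
#' @param disable character vector of process names to skip (used by
#'   process-order diagnostics), any of `"dispersal"`, `"establishment"`,
#'   `"mortality"`, `"production"`.
#' @return `state`, invisibly.
#' @export
run_year <- function(state, disable = character(0)) {
  st <- state
  p <- st$params
  cfg <- st$config
  st$step <- st$step + 1L
  t <- st$step
  if (t > length(st$seq_years)) abort("state already ran past its forcing")
  W <- cfg$transect_width_m
  L <- cfg$transect_length_km * 1000
  n <- length(st$tx)
  node_m <- st$node_m
  a10 <- st$aux10[, t, , drop = TRUE]
  acur <- st$aux_cur[, t, , drop = TRUE]
  if (is.null(dim(a10))) { # single node: drop lost dims
    a10 <- matrix(a10, nrow = 1, dimnames = list(NULL, names(a10)))
    acur <- matrix(acur, nrow = 1, dimnames = list(NULL, names(acur)))
  }

  # 1. environment ---------------------------------------------------------
  st$tdi <- if (n > 0) {
    competition_index_cpp(st$tx, st$ty, st$tbasal, st$theight, W,
                          p$r0_crown, p$r_per_h)
  } else numeric(0)

  # 2. growth ---------------------------------------------------------------
  if (n > 0) {
    A <- interp_nodes_mat(node_m, a10, st$ty)  # t_jul, ndd0, drought_index
    tj10 <- A[, 1]
    nd10 <- A[, 2]
    dr10 <- A[, 3]
    ald <- p$edaphic_factor * sqrt(pmax(nd10, 0))
    mg <- p$g_max *
      ramp01((tj10 - p$t_jul_lo) / (p$t_jul_hi - p$t_jul_lo)) *
      ramp01((nd10 - p$ndd_lo) / (p$ndd_hi - p$ndd_lo)) *
      ramp01(ald / p$ald_sat)
    st$tbasal <- st$tbasal + mg * exp(-p$c_growth * st$tdi)
    st$theight <- p$h_max * (1 - exp(-p$k_allom * st$tbasal))
    st$tdbh <- p$dbh_slope * pmax(0, st$tbasal - breast_height_diameter_cm(p))
  } else {
    tj10 <- nd10 <- dr10 <- numeric(0)
  }

  # 3. dispersal of seeds held on trees -------------------------------------
  if (!("dispersal" %in% disable) && length(st$sx) > 0) {
    res <- disperse_step_cpp(st$sx, st$sy, st$sage, st$son, st$srel,
                             W, L, st$wind_speed, st$wind_dir,
                             p$fall_velocity, p$turb_sdlog)
    st$sx <- res$sx; st$sy <- res$sy; st$sage <- res$sage
    st$son <- res$son; st$srel <- res$srel
  }

  # boundary / hinterland introduction --------------------------------------
  tj10_s <- interp_nodes(node_m, a10[, "t_jul"], 0)
  intro <- introduce_boundary_seeds(t, cfg, list(t_jul = tj10_s), p)
  if (nrow(intro) > 0) {
    st$sx <- c(st$sx, intro$x_m)
    st$sy <- c(st$sy, intro$y_m)
    st$sage <- c(st$sage, rep(0L, nrow(intro)))
    st$son <- c(st$son, rep(FALSE, nrow(intro)))
    st$srel <- c(st$srel, rep(0, nrow(intro)))
  }

  # 4. seed production -------------------------------------------------------
  if (n > 0 && !("production" %in% disable)) {
    mat <- which(st$theight >= st$tmath)
    if (length(mat) > 0) {
      tjc <- interp_nodes(node_m, acur[, "t_jul"], st$ty[mat])
      s_w <- ramp01((tjc - p$t_jul_lo) / (p$t_jul_hi - p$t_jul_lo))
      lam <- p$fec_max * st$tbasal[mat] / (st$tbasal[mat] + p$fec_d_half) *
        s_w * exp(-p$c_fec * st$tdi[mat])
      cnt <- rpois(length(mat), lam)
      tot <- sum(cnt)
      if (tot > 0) {
        par <- rep.int(mat, cnt)
        st$sx <- c(st$sx, st$tx[par])
        st$sy <- c(st$sy, st$ty[par])
        st$sage <- c(st$sage, rep(0L, tot))
        st$son <- c(st$son, rep(TRUE, tot))
        st$srel <- c(st$srel, p$release_rel_h * st$theight[par])
      }
    }
  }

  # 5.-7. seed fate: establishment draw, seed mortality, seed ageing --------
  if (length(st$sx) > 0) {
    germ_max <- if ("establishment" %in% disable) 0 else p$germ_max
    seed_mort <- if ("mortality" %in% disable) 0 else p$seed_mort
    res <- seed_fate_cpp(st$sx, st$sy, st$sage, st$son, st$srel,
                         node_m, acur[, "t_jul"],
                         germ_max, p$t_jul_lo, p$t_jul_hi,
                         seed_mort, p$seed_age_max)
    st$sx <- res$sx; st$sy <- res$sy; st$sage <- res$sage
    st$son <- res$son; st$srel <- res$srel
    ng <- length(res$germ_x)
    if (ng > 0) {
      st$tx <- c(st$tx, res$germ_x)
      st$ty <- c(st$ty, res$germ_y)
      st$tage <- c(st$tage, rep(0L, ng))
      b0 <- rep(p$seedling_basal_cm, ng)
      st$tbasal <- c(st$tbasal, b0)
      st$tdbh <- c(st$tdbh, rep(0, ng))
      st$theight <- c(st$theight, p$h_max * (1 - exp(-p$k_allom * b0)))
      st$tmath <- c(st$tmath,
                    pmax(p$mat_h_min, rnorm(ng, p$mat_h_mean, p$mat_h_sd)))
      st$tdi <- c(st$tdi, rep(0, ng))
    }
  }

  # 6. tree mortality --------------------------------------------------------
  if (!("mortality" %in% disable)) {
    n2 <- length(st$tx)
    if (n2 > 0) {
      if (n2 > n) {  # this year's seedlings appended after the growth step
        A2 <- interp_nodes_mat(node_m, a10[, c("t_jul", "drought_index")],
                               st$ty[(n + 1):n2])
        tj10 <- c(tj10, A2[, 1])
        dr10 <- c(dr10, A2[, 2])
      }
      pd <- tree_death_prob(st$tbasal, st$tage, st$tdi, tj10, dr10, p)
      tree_keep(st, runif(n2) >= pd)
    }
  }

  # 7. tree ageing -----------------------------------------------------------
  st$tage <- st$tage + 1L

  # bookkeeping --------------------------------------------------------------
  stems <- st$theight > 1.3
  st$log[[t]] <- list(
    repeat_id = st$repeat_id, step = t, year = st$seq_years[t],
    phase = st$phase[t], n_trees = length(st$tx), n_stems = sum(stems),
    n_seeds = length(st$sx),
    northernmost_stem_m = if (any(stems)) max(st$ty[stems]) else NA_real_
  )
  invisible(st)
}

# keep subsets in place
tree_keep <- function(st, keep) {
  st$tx <- st$tx[keep]; st$ty <- st$ty[keep]
  st$tage <- st$tage[keep]; st$tbasal <- st$tbasal[keep]
  st$tdbh <- st$tdbh[keep]; st$theight <- st$theight[keep]
  st$tmath <- st$tmath[keep]; st$tdi <- st$tdi[keep]
  invisible(st)
}
seed_keep <- function(st, keep) {
  st$sx <- st$sx[keep]; st$sy <- st$sy[keep]
  st$sage <- st$sage[keep]; st$son <- st$son[keep]; st$srel <- st$srel[keep]
  invisible(st)
}

# current stand as a tibble
state_trees <- function(st) {
  tibble(x_m = st$tx, y_m = st$ty, age = st$tage, basal_cm = st$tbasal,
         dbh_cm = st$tdbh, height_m = st$theight,
         maturation_h_m = st$tmath, density_index = st$tdi)
}

#' Run the individual-based transect simulation
#'
#' Runs `config$repeats` repeats of the full life-cycle simulation over
#' `years` (after a stabilization phase looping the first 30 simulated
#' years). Every `config$snapshot_years` a stand-density profile of stems
#' (trees taller than 1.3 m) is recorded; full stem snapshots are kept when
#' `keep_snapshots` is `TRUE`.
#'
#' @inheritParams sim_state_init
#' @param keep_snapshots keep the per-tree snapshot tables (memory-heavy on
#'   long transects).
#' @param bin_length_km density-profile bin length.
#' @param quiet suppress the per-repeat progress message.
#' @return Object of class `"treeline_sim"`: a list with `profiles`
#'   (tibble: repeat, year, bin_start_km, bin_length_km, stems_per_ha),
#'   `log` (yearly population log), optional `snapshots`, plus the config,
#'   params and years.
#' @export
run_simulation <- function(config, forcing, params = larch_params(),
                           years = NULL, keep_snapshots = FALSE,
                           bin_length_km = 1, quiet = TRUE) {
  years <- years %||% sort(unique(forcing$year))
  profiles <- list()
  logs <- list()
  snaps <- list()
  for (r in seq_len(config$repeats)) {
    st <- sim_state_init(config, forcing, params, years, repeat_id = r)
    nstep <- length(st$seq_years)
    for (t in seq_len(nstep)) {
      run_year(st)
      yr <- st$seq_years[t]
      if (st$phase[t] == "main" && yr %% config$snapshot_years == 0) {
        stems <- st$theight > 1.3
        snap <- tibble(`repeat` = r, year = yr,
                       x_m = st$tx[stems], y_m = st$ty[stems],
                       age = st$tage[stems], basal_cm = st$tbasal[stems],
                       dbh_cm = st$tdbh[stems], height_m = st$theight[stems])
        prof <- density_profile(snap, bin_length_km = bin_length_km,
                                transect_length_km = config$transect_length_km,
                                transect_width_m = config$transect_width_m)
        prof$`repeat` <- r
        prof$year <- yr
        profiles[[length(profiles) + 1L]] <- prof
        if (keep_snapshots) snaps[[length(snaps) + 1L]] <- snap
      }
    }
    logs[[r]] <- bind_rows(lapply(st$log, as_tibble))
    if (!quiet) message("repeat ", r, ": ", logs[[r]]$n_stems[nstep], " stems")
  }
  structure(list(
    profiles = bind_rows(profiles),
    log = bind_rows(logs),
    snapshots = if (keep_snapshots) bind_rows(snaps) else NULL,
    config = config, params = params, years = years
  ), class = "treeline_sim")
}

#' @export
print.treeline_sim <- function(x, ...) {
  cat("Individual-based treeline simulation\n")
  cat("  transect: ", x$config$transect_length_km, " km x ",
      x$config$transect_width_m, " m, ", x$config$repeats, " repeat(s)\n",
      sep = "")
  cat("  years: ", min(x$years), "-", max(x$years), "\n", sep = "")
  fin <- filter(x$log, .data$step == max(.data$step))
  cat("  final stems per repeat: ",
      paste(fin$n_stems, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname run_simulation
#' @param x a `treeline_sim` object.
#' @param ... unused.
#' @method tidy treeline_sim
#' @export
tidy.treeline_sim <- function(x, ...) {
  x$log
}

#' @rdname run_simulation
#' @method glance treeline_sim
#' @export
glance.treeline_sim <- function(x, ...) {
  x$log %>%
    filter(.data$phase == "main") %>%
    group_by(`repeat` = .data$repeat_id) %>%
    summarise(
      years = dplyr::n(),
      final_trees = last(.data$n_trees),
      final_stems = last(.data$n_stems),
      final_seeds = last(.data$n_seeds),
      northernmost_stem_km = last(.data$northernmost_stem_m) / 1000,
      .groups = "drop"
    )
}
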