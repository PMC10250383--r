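# The four release experiments: two backtracking runs that trace harvested
# spat to their primary settlement areas and source populations, and two
# forward runs that estimate regional (larval) and secondary (spat)
# connectivity.

DAYS_IN_MONTH <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

month_bounds <- function(month) {
  starts <- c(0, cumsum(DAYS_IN_MONTH)) * 86400
  c(starts[month], starts[month + 1])
}

#' Preset experiment configurations
#'
#' Returns the configuration of one of the four numbered experiments:
#'
#' * **1** — backtracking of beach-collected spat: 20 d maximum duration
#'   plus a 0–5.5 d latitude lag, release 1 m above the seafloor along the
#'   beach, no diffusion or sinking, no settlement (trajectories feed the
#'   density analysis over ages 10 d to 20 d + lag).
#' * **2** — backtracking of larvae from the primary settlement areas to
#'   their source populations: 35 d duration, stop on first population
#'   contact at ages 21–35 d, release uniform over 0–30 m depth.
#' * **3** — forward regional connectivity: releases 0–20 m deep from 20
#'   points in each of the habitat sites, diffusion plus 0.001 m s^-1
#'   sinking, settlement at ages 21–35 d onto sites and primary areas.
#' * **4** — forward secondary (spat) connectivity: seafloor + 1 m releases
#'   in the primary areas, settlement from day 10 up to 30 d onto the sites.
#'
#' Each release point emits 1000 particles per month, evenly spaced in time
#' within the month.
#'
#' @param experiment_id integer 1–4.
#' @return An object of class `experiment_config`.
#' @export
make_experiment_config <- function(experiment_id) {
  if (!experiment_id %in% 1:4)
    stop("invalid argument: experiment_id must be 1, 2, 3 or 4")
  d <- 86400
  cfg <- switch(as.character(experiment_id),
    "1" = list(direction = "backward", pld_max = 20 * d,
               competency_start = NA_real_, release_depth = "seafloor_plus_1",
               diffusion = FALSE, sinking = FALSE,
               release_area = "beach", settlement = "none",
               n_release_points = 200, lagged = TRUE, max_lag = 5.5 * d,
               months = 7:11, years = 2015:2017,
               density_window_min = 10 * d),
    "2" = list(direction = "backward", pld_max = 35 * d,
               competency_start = 21 * d, release_depth = c(0, 30),
               diffusion = FALSE, sinking = FALSE,
               release_area = "primary_areas", settlement = "populations",
               n_release_points = 200, lagged = FALSE, max_lag = 0,
               months = 7:11, years = 2015:2017,
               density_window_min = NA_real_),
    "3" = list(direction = "forward", pld_max = 35 * d,
               competency_start = 21 * d, release_depth = c(0, 20),
               diffusion = TRUE, sinking = TRUE,
               release_area = "sites", settlement = "sites_and_primary_areas",
               n_release_points = 20, lagged = FALSE, max_lag = 0,
               months = 6:10, years = 2008:2017,
               density_window_min = NA_real_),
    "4" = list(direction = "forward", pld_max = 30 * d,
               competency_start = 10 * d, release_depth = "seafloor_plus_1",
               diffusion = TRUE, sinking = TRUE,
               release_area = "primary_areas", settlement = "sites",
               n_release_points = 200, lagged = FALSE, max_lag = 0,
               months = 7:11, years = 2008:2017,
               density_window_min = NA_real_)
  )
  cfg$experiment_id <- experiment_id
  cfg$particles_per_point_per_month <- 1000
  class(cfg) <- "experiment_config"
  cfg
}

#' Build a one-year release schedule
#'
#' Draws the release points and times of one experiment-year. Points are
#' uniform within the release geometry (beach strip, habitat sites, or
#' buffered primary settlement areas); "released linearly in time" is
#' implemented as evenly spaced instants within each calendar month
#' (`k` particles at offsets `(i - 0.5)/k` of the month), snapped to the
#' integration step grid. Depths follow the experiment's rule: uniform
#' within a depth range per particle, or 1 m above the local seafloor
#' (mid-water-column where the seafloor is shallower than 1 m).
#'
#' @param config an [make_experiment_config()] preset.
#' @param scenario a `coastal_scenario` (supplies sites, beach, field).
#' @param seed integer seed.
#' @param particles_per_point overrides the preset 1000 (for scaled runs).
#' @param primary_areas a `settlement_areas` object (required for
#'   experiments releasing from the primary areas).
#' @param dt step length used to snap release times, s.
#' @return Particle data frame for [integrate_particles()], with extra
#'   columns `point_id` and `month`.
#' @export
build_release_schedule <- function(config, scenario, seed = 1L,
                                   particles_per_point = NULL,
                                   primary_areas = NULL, dt = 900) {
  ppm <- if (is.null(particles_per_point)) config$particles_per_point_per_month
         else particles_per_point
  if (ppm < 1) stop("invalid argument: need at least one particle per point")
  field <- scenario$field
  with_seed(seed, {
    pts <- switch(config$release_area,
      beach = {
        b <- scenario$beach
        n <- config$n_release_points
        data.frame(point_id = seq_len(n),
                   source_id = "NMB",
                   x = stats::runif(n, b$x[1], b$x[2]),
                   y = stats::runif(n, b$y[1], b$y[2]))
      },
      sites = {
        sites <- scenario$sites
        if (is.null(sites) || !nrow(sites))
          stop("invalid argument: empty release geometry")
        k <- config$n_release_points  # points per site
        do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
          data.frame(point_id = (i - 1) * k + seq_len(k),
                     source_id = sites$site_id[i],
                     x = stats::runif(k, sites$xmin[i], sites$xmax[i]),
                     y = stats::runif(k, sites$ymin[i], sites$ymax[i]))
        }))
      },
      primary_areas = {
        if (is.null(primary_areas) || !length(primary_areas$areas))
          stop("invalid argument: empty release geometry")
        sample_in_areas(primary_areas, config$n_release_points)
      },
      stop("invalid argument: unknown release area"))
    n_pts <- nrow(pts)
    rows <- vector("list", length(config$months))
    for (mi in seq_along(config$months)) {
      m <- config$months[mi]
      mb <- month_bounds(m)
      tt <- mb[1] + (seq_len(ppm) - 0.5) / ppm * (mb[2] - mb[1])
      tt <- round(tt / dt) * dt
      df <- pts[rep(seq_len(n_pts), each = ppm), ]
      df$release_time <- rep(tt, times = n_pts)
      df$month <- m
      rows[[mi]] <- df
    }
    out <- do.call(rbind, rows)
    n <- nrow(out)
    out$z <- if (identical(config$release_depth, "seafloor_plus_1")) {
      b <- bathy_at(field, out$x, out$y)
      ifelse(b >= 1, b - 1, b / 2)
    } else {
      stats::runif(n, config$release_depth[1], config$release_depth[2])
    }
    out$lag <- if (isTRUE(config$lagged)) {
      release_lag(out$y, scenario$beach$y[1], scenario$beach$y[2],
                  config$max_lag)
    } else 0
    out$particle_id <- seq_len(n)
    rownames(out) <- NULL
    out[, c("particle_id", "source_id", "point_id", "month",
            "x", "y", "z", "release_time", "lag")]
  })
}

bathy_at <- function(field, x, y) {
  g <- field$grid
  i <- pmin(pmax(floor((x - g$x_origin) / g$dx) + 1, 1), g$nx)
  j <- pmin(pmax(floor((y - g$y_origin) / g$dy) + 1, 1), g$ny)
  field$bathymetry[cbind(i, j)]
}

# Internal: uniform points over the union of buffered settlement areas
# (rejection sampling in the union's bounding box).
sample_in_areas <- function(areas, n) {
  rects <- do.call(rbind, lapply(areas$areas, function(a) a$rects))
  buf <- areas$buffer_m
  bb <- c(min(rects[, 1]) - buf, max(rects[, 2]) + buf,
          min(rects[, 3]) - buf, max(rects[, 4]) + buf)
  xs <- numeric(0); ys <- numeric(0); lab <- character(0)
  while (length(xs) < n) {
    m <- max(4 * (n - length(xs)), 64)
    cx <- stats::runif(m, bb[1], bb[2])
    cy <- stats::runif(m, bb[3], bb[4])
    tg <- settlement_targets(areas = areas)
    hit <- locate_targets(tg, cx, cy)
    ok <- !is.na(hit)
    xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok]); lab <- c(lab, hit[ok])
  }
  data.frame(point_id = seq_len(n), source_id = lab[seq_len(n)],
             x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Run one of the preset experiments
#'
#' Drives [integrate_particles()] over the experiment's years. Each "year"
#' of the synthetic scenario is a fresh seeded realisation of the coastal
#' flow (current strengths and eddy positions jittered), so inter-annual
#' variability can be analysed without a hindcast archive. Backtracking
#' experiments run with diffusion and sinking off; experiment 2 stops
#' trajectories on first population contact within the competency window;
#' experiment 1 records trajectories (for the density analysis) and has no
#' settlement.
#'
#' @param config an [make_experiment_config()] preset.
#' @param scenario a `coastal_scenario`.
#' @param seed master seed; every year derives its own field and RNG stream.
#' @param particles_per_point scale-down override of the preset 1000.
#' @param primary_areas `settlement_areas` (release and/or settlement
#'   geometry for experiments 2–4).
#' @param years override of the preset year labels (fewer years = smaller
#'   run).
#' @param record_every trajectory recording stride in steps (default: 4,
#'   i.e. hourly, for experiment 1; 0 otherwise).
#' @return List of class `experiment_result`: `records` (all years, with
#'   `year` column), `trajectories` (per-year list, experiment 1),
#'   `released_per_source`, `config`, `scenario`.
#' @export
run_experiment <- function(config, scenario, seed = 1L,
                           particles_per_point = NULL,
                           primary_areas = NULL, years = NULL,
                           record_every = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  years <- if (is.null(years)) config$years else years
  if (is.null(record_every))
    record_every <- if (config$experiment_id == 1) 4L else 0L
  targets <- switch(config$settlement,
    none = NULL,
    populations = settlement_targets(sites = scenario$sites),
    sites = settlement_targets(sites = scenario$sites),
    sites_and_primary_areas = settlement_targets(sites = scenario$sites,
                                                 areas = primary_areas))
  # no-settlement experiments carry no targets; competency value is inert
  comp <- if (is.na(config$competency_start)) config$pld_max
          else config$competency_start
  all_rec <- vector("list", length(years))
  trajs <- vector("list", length(years))
  for (yi in seq_along(years)) {
    seed_y <- (seed + 7919L * yi) %% .Machine$integer.max
    scen_y <- scenario
    if (inherits(scenario, "coastal_scenario") &&
        scenario$config$scenario == "double_gyre_coastal") {
      cfg_y <- scenario$config
      cfg_y$seed <- seed_y
      scen_y <- coastal_scenario(cfg_y)
    }
    sched <- build_release_schedule(config, scen_y, seed = seed_y + 1L,
                                    particles_per_point = particles_per_point,
                                    primary_areas = primary_areas)
    icfg <- integration_config(
      dt = 900, direction = config$direction,
      pld_max = config$pld_max, competency_start = comp,
      K_h = if (config$diffusion) 0.1176 else 0,
      K_v = if (config$diffusion) 0.01 else 0,
      w_s = if (config$sinking) 0.001 else 0,
      diffusion = config$diffusion, sinking = config$sinking,
      record_every = record_every, seed = seed_y + 2L)
    res <- integrate_particles(sched, scen_y$field, targets, icfg)
    rec <- res$records
    rec$year <- years[yi]
    if (config$settlement == "populations") {
      map <- stats::setNames(scenario$sites$population_id,
                             scenario$sites$site_id)
      rec$settle_population_id <- unname(map[rec$settle_target_id])
    }
    all_rec[[yi]] <- rec
    trajs[[yi]] <- res$trajectories
  }
  records <- do.call(rbind, all_rec)
  released <- table(records$source_id)
  out <- list(records = records,
              trajectories = if (record_every > 0) trajs else NULL,
              released_per_source = released,
              config = config, scenario = scenario, years = years)
  class(out) <- "experiment_result"
  out
}

#' Source contributions to the spatfall
#'
#' Percentage contribution of each source population to the total
#' settlement of a (backtracking) experiment, optionally normalised per
#' geographical area (km^2) and renormalised to 100%. The per-year
#' breakdown gives the mean and standard deviation across years.
#'
#' @param records experiment records (need `settle_population_id` or
#'   `settle_target_id` mappable through `sites`).
#' @param sites `habitat_sites` frame (for site-to-population mapping and
#'   population areas).
#' @param per_area also report area-normalised shares.
#' @return Data frame: `population_id`, `n_settled`, `percent`,
#'   `percent_sd` (across years), `area_km2`, and `percent_per_area` when
#'   `per_area = TRUE`. Zero settlers yield an empty frame with a warning.
#' @export
source_contributions <- function(records, sites, per_area = FALSE) {
  if (!"settle_population_id" %in% names(records)) {
    map <- stats::setNames(sites$population_id, sites$site_id)
    records$settle_population_id <- unname(map[records$settle_target_id])
  }
  st <- records[records$status == "settled" &
                  !is.na(records$settle_population_id), ]
  if (!nrow(st)) {
    warning("no settlers: empty contribution table")
    return(data.frame(population_id = character(0), n_settled = integer(0),
                      percent = numeric(0)))
  }
  cnt <- table(st$settle_population_id)
  pops <- names(cnt)
  percent <- 100 * as.numeric(cnt) / sum(cnt)
  if (!is.null(st$year) && length(unique(st$year)) > 1) {
    per_year <- do.call(cbind, lapply(split(st, st$year), function(d) {
      tab <- table(factor(d$settle_population_id, levels = pops))
      100 * as.numeric(tab) / max(sum(tab), 1)
    }))
    psd <- apply(per_year, 1, stats::sd)
  } else psd <- rep(NA_real_, length(pops))
  area <- vapply(pops, function(p)
    sum(sites$area_km2[sites$population_id == p]), numeric(1))
  out <- data.frame(population_id = pops, n_settled = as.integer(cnt),
                    percent = percent, percent_sd = psd, area_km2 = area,
                    stringsAsFactors = FALSE)
  if (per_area) {
    pa <- percent / area
    out$percent_per_area <- 100 * pa / sum(pa)
  }
  rownames(out) <- NULL
  out[order(-out$percent), ]
}

#' One-way analysis of variance
#'
#' Classical one-way F test (between-group mean square over within-group
#' mean square) used to compare per-year percentage contributions across
#' source populations.
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("invalid argument: need >= 2 groups with >= 2 observations each")
  if (stats::var(values) < .Machine$double.eps)
    return(list(F = 0, df1 = nlevels(groups) - 1,
                df2 = length(values) - nlevels(groups), p = 1))
  a <- stats::anova(stats::lm(values ~ groups))
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p = a$`Pr(>F)`[1])
}
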