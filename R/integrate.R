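#' Integration configuration
#'
#' Collects the numerical and biological parameters of a tracking run.
#' Defaults follow the standard larval set-up: 900 s RK4 step, 35-day
#' maximum pelagic larval duration with competency from day 21, horizontal
#' diffusivity 0.1176 m^2 s^-1, vertical diffusivity 0.01 m^2 s^-1 applied
#' over 90 s substeps, and 0.001 m s^-1 sinking. In backward mode (source
#' backtracking through reversed currents) diffusion and sinking default to
#' off — stochastic terms are not time-reversible — and forcing them on
#' raises a warning.
#'
#' @param dt time step, seconds (> 0; the sign is set by `direction`).
#' @param direction `"forward"` or `"backward"`.
#' @param pld_max maximum pelagic duration, seconds.
#' @param competency_start age at which settlement competency begins, s.
#' @param K_h,K_v horizontal/vertical diffusivity, m^2 s^-1 (may be 0).
#' @param vertical_substep vertical random-walk substep, s; must divide `dt`.
#' @param w_s sinking velocity, m s^-1 (may be 0).
#' @param diffusion,sinking logical switches; `NULL` = on for forward runs,
#'   off for backward runs.
#' @param use_field_w advect with the field's vertical velocity (default
#'   `TRUE`; the synthetic fields carry `w = 0`).
#' @param record_every record trajectory positions every this many steps
#'   (0 = do not record).
#' @param seed integer seed fixing every random draw of the run.
#' @return An object of class `integration_config`.
#' @export
integration_config <- function(dt = 900, direction = c("forward", "backward"),
                               pld_max = 35 * 86400,
                               competency_start = 21 * 86400,
                               K_h = 0.1176, K_v = 0.01,
                               vertical_substep = 90, w_s = 0.001,
                               diffusion = NULL, sinking = NULL,
                               use_field_w = TRUE,
                               record_every = 0, seed = 1L) {
  direction <- match.arg(direction)
  if (dt <= 0) stop("invalid argument: dt must be > 0")
  if (competency_start > pld_max)
    stop("invalid argument: competency_start must be <= pld_max")
  if (K_h < 0 || K_v < 0) stop("invalid argument: diffusivities must be >= 0")
  ns <- dt / vertical_substep
  if (abs(ns - round(ns)) > 1e-9)
    stop("invalid argument: vertical_substep must divide dt")
  backward <- direction == "backward"
  if (is.null(diffusion)) diffusion <- !backward
  if (is.null(sinking)) sinking <- !backward
  if (backward && (diffusion || sinking))
    warning("stochastic diffusion/sinking forced on in backward mode")
  cfg <- list(dt = dt, direction = direction, pld_max = pld_max,
              competency_start = competency_start, K_h = K_h, K_v = K_v,
              vertical_substep = vertical_substep, w_s = w_s,
              diffusion = diffusion && (K_h > 0 || K_v > 0),
              sinking = sinking && w_s > 0,
              use_field_w = use_field_w,
              record_every = as.integer(record_every),
              seed = as.integer(seed))
  class(cfg) <- "integration_config"
  cfg
}

#' Make a particle release table
#'
#' @param x,y,z release positions (m; z positive down).
#' @param release_time release times, seconds (default 0).
#' @param source_id release point / source site label.
#' @param lag per-particle dispersal lag, seconds; extends the individual
#'   tracking duration (`pld_max + lag`) without shifting the competency
#'   window.
#' @return A `data.frame` of particles for [integrate_particles()].
#' @export
make_particles <- function(x, y, z = 0, release_time = 0,
                           source_id = "src", lag = 0) {
  n <- max(length(x), length(y))
  data.frame(particle_id = seq_len(n),
             source_id = rep_len(source_id, n),
             x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n),
             release_time = rep_len(release_time, n),
             lag = rep_len(lag, n))
}

#' Track particles through a flow field
#'
#' The integrator applies, each step: RK4 advection (signed step) ->
#' horizontal diffusion -> substepped vertical diffusion -> sinking ->
#' boundary rule -> settlement check. Particles leaving the grid laterally
#' or stepping outside the field's time axis are recorded as `removed`
#' (open-boundary loss); particles older than their individual maximum
#' duration (`pld_max + lag`) without settling are `expired`. Every
#' released particle is accounted for exactly once:
#' released = settled + expired + removed.
#'
#' @param particles data frame from [make_particles()] (or with the same
#'   columns). Release times are snapped to the step grid.
#' @param field a `flow_field`.
#' @param targets settlement geometry: a `habitat_sites` frame, a
#'   [settlement_targets()] list, or `NULL` for no settlement (pure
#'   trajectory runs).
#' @param config an [integration_config()].
#' @return A list of class `tracking_result`: `records` (one row per
#'   particle: release metadata, final `status`, settlement target, time,
#'   position and age) and `trajectories` (a `trajectories` object when
#'   `record_every > 0`, else `NULL`).
#' @export
integrate_particles <- function(particles, field, targets = NULL, config) {
  stopifnot(inherits(config, "integration_config"))
  if (!is.null(targets) && !inherits(targets, "settlement_targets"))
    targets <- settlement_targets(sites = targets)
  n <- nrow(particles)
  sgn <- if (config$direction == "backward") -1 else 1
  dt <- config$dt
  dt_s <- sgn * dt
  lag <- if (is.null(particles$lag)) rep(0, n) else particles$lag
  duration <- config$pld_max + lag
  t_start <- if (sgn > 0) min(particles$release_time) else max(particles$release_time)
  rel_step <- round((particles$release_time - t_start) / dt_s)
  if (any(rel_step < 0)) stop("invalid argument: inconsistent release times")
  n_steps <- max(rel_step + ceiling(duration / dt - 1e-9))
  g <- field$grid
  if (g$nt > 1) {
    t_end <- t_start + n_steps * dt_s
    tf <- range(grid_times(g))
    if (min(t_start, t_end) < tf[1] - 1e-6 || max(t_start, t_end) > tf[2] + 1e-6)
      stop("configuration error: field time axis shorter than requested duration")
  }
  vel <- make_interpolator(field)
  px <- rep(NA_real_, n); py <- px; pz <- px
  status <- rep(0L, n)  # 0 pending, 1 active, 2 settled, 3 expired, 4 removed
  s_target <- rep(NA_character_, n)
  s_time <- rep(NA_real_, n); s_age <- s_time
  s_x <- s_time; s_y <- s_time
  rec <- config$record_every
  if (rec > 0) {
    nrec <- n_steps %/% rec + 1L
    TX <- matrix(NA_real_, n, nrec); TY <- TX; TZ <- TX
    rec_times <- t_start + (0:(nrec - 1L)) * rec * dt_s
  }
  mask <- field$mask; bathy <- field$bathymetry
  nx <- g$nx; ny <- g$ny
  x0 <- g$x_origin; y0 <- g$y_origin; dxg <- g$dx; dyg <- g$dy
  x_hi <- x0 + nx * dxg; y_hi <- y0 + ny * dyg
  ns_sub <- as.integer(round(dt / config$vertical_substep))
  sd_h <- sqrt(2 * config$K_h * dt)
  sd_v <- sqrt(2 * config$K_v * config$vertical_substep)

  with_seed(config$seed, {
    for (s in seq_len(n_steps)) {
      newly <- which(status == 0L & rel_step == s - 1L)
      if (length(newly)) {
        status[newly] <- 1L
        px[newly] <- particles$x[newly]
        py[newly] <- particles$y[newly]
        pz[newly] <- particles$z[newly]
        if (rec > 0 && (s - 1L) %% rec == 0L) {
          r0 <- (s - 1L) %/% rec + 1L
          TX[newly, r0] <- px[newly]; TY[newly, r0] <- py[newly]
          TZ[newly, r0] <- pz[newly]
        }
      }
      act <- which(status == 1L)
      if (!length(act)) {
        if (!any(status == 0L)) break
        next
      }
      t_cur <- t_start + (s - 1L) * dt_s
      ox <- px[act]; oy <- py[act]; oz <- pz[act]
      adv <- rk4_kernel(vel, ox, oy, oz, rep(t_cur, length(act)), dt_s,
                        use_w = config$use_field_w)
      nxp <- adv$x; nyp <- adv$y; nzp <- adv$z
      if (config$diffusion) {
        if (config$K_h > 0) {
          nxp <- nxp + stats::rnorm(length(act), 0, sd_h)
          nyp <- nyp + stats::rnorm(length(act), 0, sd_h)
        }
        if (config$K_v > 0)
          nzp <- nzp + rowSums(matrix(stats::rnorm(length(act) * ns_sub, 0, sd_v),
                                      length(act), ns_sub))
      }
      if (config$sinking) nzp <- nzp + config$w_s * dt
      # open-boundary loss: advection stage failure or lateral exit
      gone <- !is.finite(nxp) | !is.finite(nyp) |
        nxp < x0 | nxp > x_hi | nyp < y0 | nyp > y_hi
      if (any(gone)) status[act[gone]] <- 4L
      keep <- !gone
      if (any(keep)) {
        ak <- act[keep]
        zs <- pmax(nzp[keep], 0)
        ci <- pmin(pmax(floor((nxp[keep] - x0) / dxg) + 1, 1), nx)
        cj <- pmin(pmax(floor((nyp[keep] - y0) / dyg) + 1, 1), ny)
        cell <- cbind(ci, cj)
        blocked <- !mask[cell] | zs > bathy[cell]
        age_next <- (s - rel_step[ak]) * dt
        # settlement first: competent particles over habitat stop there even
        # where the boundary rule would otherwise push them back
        if (!is.null(targets)) {
          win <- age_next >= config$competency_start - 1e-9 &
            age_next <= config$pld_max + 1e-9
          if (any(win)) {
            wi <- which(win)
            ids <- locate_targets(targets, nxp[keep][wi], nyp[keep][wi])
            got <- !is.na(ids)
            if (any(got)) {
              gi <- wi[got]
              pid <- ak[gi]
              status[pid] <- 2L
              s_target[pid] <- ids[got]
              s_time[pid] <- t_cur + dt_s
              s_age[pid] <- age_next[gi]
              s_x[pid] <- nxp[keep][gi]; s_y[pid] <- nyp[keep][gi]
              px[pid] <- nxp[keep][gi]; py[pid] <- nyp[keep][gi]
              pz[pid] <- zs[gi]
            }
          }
        }
        still <- status[ak] == 1L
        # boundary rule: coast/seafloor intersections revert the whole move
        rv <- still & blocked
        adopt <- still & !blocked
        if (any(adopt)) {
          ai <- ak[adopt]
          px[ai] <- nxp[keep][adopt]; py[ai] <- nyp[keep][adopt]
          pz[ai] <- zs[adopt]
        }
        # expired: reached individual maximum duration without settling
        ex <- still & age_next >= duration[ak] - 1e-9
        if (any(ex)) status[ak[ex]] <- 3L
      }
      if (rec > 0 && s %% rec == 0L) {
        ri <- s %/% rec + 1L
        live <- which(status == 1L)
        TX[live, ri] <- px[live]; TY[live, ri] <- py[live]
        TZ[live, ri] <- pz[live]
      }
    }
  })
  status[status == 1L | status == 0L] <- 3L
  lab <- c("active", "settled", "expired", "removed")[status]
  records <- data.frame(
    particle_id = particles$particle_id,
    source_id = particles$source_id,
    release_time = t_start + rel_step * dt_s,
    release_x = particles$x, release_y = particles$y, release_z = particles$z,
    lag = lag,
    status = lab,
    settle_target_id = s_target,
    settle_time = s_time, settle_age = s_age,
    settle_x = s_x, settle_y = s_y,
    stringsAsFactors = FALSE
  )
  traj <- NULL
  if (rec > 0) {
    traj <- list(times = rec_times, x = TX, y = TY, z = TZ,
                 release_time = records$release_time, lag = lag,
                 particle_id = particles$particle_id, direction = config$direction)
    class(traj) <- "trajectories"
  }
  out <- list(records = records, trajectories = traj, config = config)
  class(out) <- "tracking_result"
  out
}

#' @export
print.tracking_result <- function(x, ...) {
  tab <- table(x$records$status)
  cat("tracking_result:", nrow(x$records), "particles (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
  invisible(x)
}

#' Trajectory ages
#'
#' Age (seconds since release, always positive) of every recorded sample of
#' a `trajectories` object, as a matrix aligned with `traj$x`.
#'
#' @param traj a `trajectories` object.
#' @return Numeric matrix of ages (s), `NA` where no sample was recorded.
#' @export
trajectory_ages <- function(traj) {
  ages <- outer(-traj$release_time, traj$times, `+`)
  if (traj$direction == "backward") ages <- -ages
  ages[is.na(traj$x)] <- NA_real_
  ages
}

#' Write settlement records / trajectories
#'
#' Settlement records go to CSV; trajectories to a plain-text long-format
#' table (particle, time, x, y, z, age) readable with any data tool.
#'
#' @param result a `tracking_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_settlement_csv <- function(result, path) {
  utils::write.csv(result$records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_settlement_csv
#' @export
write_trajectories <- function(result, path) {
  traj <- result$trajectories
  if (is.null(traj)) stop("no trajectories recorded (record_every = 0)")
  ages <- trajectory_ages(traj)
  keep <- !is.na(traj$x)
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(particle_id = traj$particle_id[idx[, 1]],
                   time = traj$times[idx[, 2]],
                   x = traj$x[keep], y = traj$y[keep], z = traj$z[keep],
                   age = ages[keep])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
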