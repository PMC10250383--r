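# Lagrangian particle-tracking core: multilinear velocity interpolation,
# classical RK4 advection (signed time step for backtracking), random-walk
# turbulence, constant sinking, coastline/seafloor boundary handling and
# age-gated settlement.

# Internal: build a fast velocity sampler for a field. Returns
# function(x, y, z, t) -> list(u, v, w) with NA for positions/times outside
# the domain. Trilinear in (x, y, z) between cell centers / depth levels
# (flat within the half-cell margin at the edges), linear in time.
make_interpolator <- function(field) {
  g <- field$grid
  nx <- g$nx; ny <- g$ny; nz <- length(g$z_levels); nt <- g$nt
  x0 <- g$x_origin; y0 <- g$y_origin; dx <- g$dx; dy <- g$dy
  zl <- g$z_levels; zmax <- zl[nz]
  t0 <- g$t0; dtf <- g$dt_field
  nxny <- nx * ny; nxnynz <- nxny * nz
  ua <- field$u; va <- field$v; wa <- field$w
  dim(ua) <- NULL; dim(va) <- NULL; dim(wa) <- NULL

  axis_nodes <- function(c_idx, n) {
    # c_idx: continuous 0-based index between first (0) and last (n-1) center;
    # non-finite entries (out-of-domain particles) are parked at node 0 and
    # masked out afterwards
    if (n == 1L)
      return(list(list(i = rep(0L, length(c_idx)), w = 1)))
    c_idx[!is.finite(c_idx)] <- 0
    i0 <- floor(c_idx)
    i0[i0 < 0] <- 0
    i0[i0 > n - 2] <- n - 2L
    w <- c_idx - i0
    w[w < 0] <- 0; w[w > 1] <- 1
    list(list(i = i0, w = 1 - w), list(i = i0 + 1L, w = w))
  }

  function(x, y, z, t) {
    bad <- !is.finite(x) | !is.finite(y) |
      x < x0 | x > x0 + nx * dx | y < y0 | y > y0 + ny * dy
    bad[is.na(bad)] <- TRUE
    xs <- axis_nodes((x - x0) / dx - 0.5, nx)
    ys <- axis_nodes((y - y0) / dy - 0.5, ny)
    if (nz == 1L) {
      zs <- list(list(i = rep(0L, length(x)), w = 1))
    } else {
      zc <- pmin(pmax(z, 0), zmax)
      zc[!is.finite(zc)] <- 0
      k0 <- findInterval(zc, zl, rightmost.closed = TRUE)
      k0[k0 > nz - 1L] <- nz - 1L
      wz <- (zc - zl[k0]) / (zl[k0 + 1L] - zl[k0])
      zs <- list(list(i = k0 - 1L, w = 1 - wz), list(i = k0, w = wz))
    }
    if (nt == 1L) {
      ts <- list(list(i = rep(0L, length(x)), w = 1))
    } else {
      ct <- (t - t0) / dtf
      badt <- !is.finite(ct) | ct < -1e-9 | ct > nt - 1 + 1e-9
      bad <- bad | badt
      ts <- axis_nodes(pmin(pmax(ct, 0), nt - 1), nt)
    }
    u <- numeric(length(x)); v <- u; w <- u
    for (xi in xs) for (yi in ys) for (zi in zs) for (ti in ts) {
      wt <- xi$w * yi$w * zi$w * ti$w
      lin <- xi$i + nx * yi$i + nxny * zi$i + nxnynz * ti$i + 1
      u <- u + wt * ua[lin]
      v <- v + wt * va[lin]
      w <- w + wt * wa[lin]
    }
    if (any(bad)) { u[bad] <- NA_real_; v[bad] <- NA_real_; w[bad] <- NA_real_ }
    list(u = u, v = v, w = w)
  }
}

#' Interpolate velocity at arbitrary positions
#'
#' Trilinear interpolation in `(x, y, z)` and linear interpolation in time
#' of a [flow_field()]. Exact on fields that are multilinear in position
#' (e.g. uniform flow, solid-body rotation). Positions or times outside the
#' field domain yield `NA` rows — the out-of-domain signal; the caller
#' decides the particle's fate.
#'
#' @param field a `flow_field`.
#' @param position numeric vector `c(x, y, z)` or an `n x 3` matrix (m).
#' @param time time(s) in seconds (recycled to `n`).
#' @return An `n x 3` matrix with columns `u`, `v`, `w` (m s^-1).
#' @export
interpolate_velocity <- function(field, position, time = field$grid$t0) {
  p <- to_pos_matrix(position)
  t <- rep_len(time, nrow(p))
  vel <- make_interpolator(field)(p[, 1], p[, 2], p[, 3], t)
  cbind(u = vel$u, v = vel$v, w = vel$w)
}

to_pos_matrix <- function(position) {
  if (is.matrix(position)) {
    stopifnot(ncol(position) == 3)
    position
  } else {
    stopifnot(length(position) == 3)
    matrix(as.numeric(position), 1, 3)
  }
}

# Internal vectorised RK4 kernel over a prebuilt interpolator.
rk4_kernel <- function(vel, x, y, z, t, dt, use_w = TRUE) {
  k1 <- vel(x, y, z, t)
  h <- dt / 2
  w1 <- if (use_w) k1$w else 0
  k2 <- vel(x + h * k1$u, y + h * k1$v, z + h * w1, t + h)
  w2 <- if (use_w) k2$w else 0
  k3 <- vel(x + h * k2$u, y + h * k2$v, z + h * w2, t + h)
  w3 <- if (use_w) k3$w else 0
  k4 <- vel(x + dt * k3$u, y + dt * k3$v, z + dt * w3, t + dt)
  w4 <- if (use_w) k4$w else 0
  list(
    x = x + dt / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u),
    y = y + dt / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v),
    z = z + if (use_w) dt / 6 * (w1 + 2 * w2 + 2 * w3 + w4) else 0
  )
}

#' One 4th-order Runge-Kutta advection step
#'
#' Classical RK4 update of position through the (possibly time-varying)
#' velocity field. Backward integration is obtained by passing a negative
#' `dt` (equivalent to reversing every current). If any of the four stage
#' evaluations falls outside the domain the result row is `NA` — the
#' out-of-domain signal.
#'
#' @inheritParams interpolate_velocity
#' @param dt signed time step, seconds (default 900, negative = backward).
#' @param use_w advect vertically with the field's `w` (default `TRUE`).
#' @return Updated position(s), same shape as `position` (an `n x 3` matrix).
#' @export
rk4_step <- function(position, time, dt, field, use_w = TRUE) {
  p <- to_pos_matrix(position)
  t <- rep_len(time, nrow(p))
  vel <- make_interpolator(field)
  r <- rk4_kernel(vel, p[, 1], p[, 2], p[, 3], t, dt, use_w)
  out <- cbind(r$x, r$y, r$z)
  bad <- !is.finite(out[, 1]) | !is.finite(out[, 2])
  out[bad, ] <- NA_real_
  if (!is.matrix(position)) out <- drop(out)
  out
}

#' Random-walk turbulence step
#'
#' Unresolved turbulence as a Gaussian random walk: `x` and `y` are each
#' incremented by a zero-mean draw of standard deviation `sqrt(2 * K_h * dt)`;
#' the vertical displacement is the sum of `dt / vertical_substep`
#' independent increments of standard deviation
#' `sqrt(2 * K_v * vertical_substep)` (the finer vertical step matches how
#' near-surface turbulence is usually resolved; the summed variance is
#' `2 * K_v * dt` regardless of the substep count). Defaults reproduce the
#' calibration used for bivalve larvae: `K_h = 0.1176` m^2 s^-1,
#' `K_v = 0.01` m^2 s^-1 over 90 s substeps.
#'
#' Draws come from the current RNG stream; seed control belongs to the
#' caller (see [integration_config()]).
#'
#' @param position `n x 3` matrix or length-3 vector (m).
#' @param K_h,K_v horizontal / vertical diffusivity, m^2 s^-1 (>= 0).
#' @param dt step length, seconds (unsigned).
#' @param vertical_substep vertical random-walk substep, seconds; must divide
#'   `dt`.
#' @return Updated position(s).
#' @export
diffusion_step <- function(position, K_h = 0.1176, K_v = 0.01, dt = 900,
                           vertical_substep = 90) {
  stopifnot(K_h >= 0, K_v >= 0)
  p <- to_pos_matrix(position)
  n <- nrow(p)
  if (K_h > 0) {
    sd_h <- sqrt(2 * K_h * dt)
    p[, 1] <- p[, 1] + stats::rnorm(n, 0, sd_h)
    p[, 2] <- p[, 2] + stats::rnorm(n, 0, sd_h)
  }
  if (K_v > 0) {
    ns <- dt / vertical_substep
    if (abs(ns - round(ns)) > 1e-9)
      stop("invalid argument: vertical_substep must divide dt")
    ns <- as.integer(round(ns))
    dz <- matrix(stats::rnorm(n * ns, 0, sqrt(2 * K_v * vertical_substep)),
                 n, ns)
    p[, 3] <- p[, 3] + rowSums(dz)
  }
  if (!is.matrix(position)) p <- drop(p)
  p
}

#' Constant sinking step
#'
#' Deepens particles by `w_s * dt` (z positive down); clamping to the
#' seafloor is the boundary rule's job. The default 0.001 m s^-1 is within
#' the range reported for bivalve larvae and for drifting spat material.
#'
#' @inheritParams diffusion_step
#' @param w_s sinking velocity, m s^-1 (>= 0).
#' @return Updated position(s).
#' @export
sinking_step <- function(position, w_s = 0.001, dt = 900) {
  stopifnot(w_s >= 0)
  p <- to_pos_matrix(position)
  p[, 3] <- p[, 3] + w_s * dt
  if (!is.matrix(position)) p <- drop(p)
  p
}

#' Coastline / seafloor / surface boundary rule
#'
#' Particles that would end a step on land or below the seafloor are moved
#' back to their previous position (unless settlement is permitted at the
#' proposed position, in which case the move stands so the settlement check
#' can claim it). A surface breach (z < 0) is clamped to z = 0. Positions
#' laterally outside the grid are returned unchanged — the caller treats
#' them as open-boundary losses.
#'
#' @param previous,proposed `n x 3` position matrices (or length-3 vectors).
#' @param field a `flow_field`.
#' @param can_settle logical (recycled): settlement permitted for this
#'   particle at this age.
#' @return Position(s) after the boundary rule.
#' @export
apply_boundary <- function(previous, proposed, field, can_settle = FALSE) {
  prev <- to_pos_matrix(previous)
  prop <- to_pos_matrix(proposed)
  can_settle <- rep_len(can_settle, nrow(prop))
  g <- field$grid
  prop[, 3] <- pmax(prop[, 3], 0)
  i <- floor((prop[, 1] - g$x_origin) / g$dx) + 1
  j <- floor((prop[, 2] - g$y_origin) / g$dy) + 1
  inside <- i >= 1 & i <= g$nx & j >= 1 & j <= g$ny &
    is.finite(prop[, 1]) & is.finite(prop[, 2])
  ii <- pmin(pmax(i, 1), g$nx); jj <- pmin(pmax(j, 1), g$ny)
  cell <- cbind(ii, jj)
  on_land <- inside & !field$mask[cell]
  below <- inside & prop[, 3] > field$bathymetry[cell]
  revert <- (on_land | below) & !can_settle
  prop[revert, ] <- prev[revert, ]
  if (!is.matrix(proposed)) prop <- drop(prop)
  prop
}

#' Settlement check
#'
#' A particle settles iff its age is within the competency window
#' (`competency_start <= age <= pld_max`) and its horizontal position lies
#' inside a habitat-site polygon. Sites are tested in order; the first
#' containing site wins (sites are disjoint, so ties cannot occur).
#'
#' @param position `n x 3` matrix or length-3 vector.
#' @param age particle age(s), seconds.
#' @param sites a `habitat_sites` frame or a settlement-target list from
#'   [settlement_targets()].
#' @param competency_start,pld_max competency window bounds, seconds.
#' @return Character vector of site ids (`NA` where no settlement).
#' @export
check_settlement <- function(position, age, sites, competency_start, pld_max) {
  p <- to_pos_matrix(position)
  age <- rep_len(age, nrow(p))
  targets <- if (inherits(sites, "settlement_targets")) sites
             else settlement_targets(sites = sites)
  hit <- rep(NA_character_, nrow(p))
  ok <- age >= competency_start & age <= pld_max
  if (!any(ok)) return(hit)
  hit[ok] <- locate_targets(targets, p[ok, 1], p[ok, 2])
  hit
}

#' Assemble settlement targets
#'
#' Bundles habitat sites (exact square polygons) and/or buffered settlement
#' areas ([extract_settlement_areas()]) into a single ordered target list
#' for the integrator: sites are tested before areas.
#'
#' @param sites optional `habitat_sites` frame.
#' @param areas optional `settlement_areas` object.
#' @return An object of class `settlement_targets`.
#' @export
settlement_targets <- function(sites = NULL, areas = NULL) {
  tg <- list()
  if (!is.null(sites)) {
    for (i in seq_len(nrow(sites)))
      tg[[length(tg) + 1L]] <- list(
        id = sites$site_id[i],
        rects = matrix(c(sites$xmin[i], sites$xmax[i],
                         sites$ymin[i], sites$ymax[i]), 1, 4),
        buffer = 0
      )
  }
  if (!is.null(areas)) {
    for (a in areas$areas)
      tg[[length(tg) + 1L]] <- list(id = a$label, rects = a$rects,
                                    buffer = areas$buffer_m)
  }
  structure(tg, class = "settlement_targets")
}

# Internal: first containing target id per point (NA if none). A point is in
# a target if it lies within `buffer` of one of the target's rectangles.
locate_targets <- function(targets, x, y) {
  hit <- rep(NA_character_, length(x))
  free <- seq_along(x)
  for (tg in targets) {
    if (!length(free)) break
    inside <- rep(FALSE, length(free))
    for (r in seq_len(nrow(tg$rects))) {
      rc <- tg$rects[r, ]
      ddx <- pmax(rc[1] - x[free], x[free] - rc[2], 0)
      ddy <- pmax(rc[3] - y[free], y[free] - rc[4], 0)
      inside <- inside | (ddx <= tg$buffer & ddy <= tg$buffer &
                            ddx^2 + ddy^2 <= tg$buffer^2 + 1e-9)
    }
    hit[free[inside]] <- tg$id
    free <- free[!inside]
  }
  hit
}

#' Latitude-dependent release lag
#'
#' Spat collected further north along the beach are older; the dispersal
#' lag interpolates linearly from 0 at the southern end to `max_lag`
#' (default 5.5 days) at the northern end of the release extent.
#'
#' @param release_y northing(s) of the release point (m).
#' @param south_y,north_y beach extent (m), `south_y < north_y`.
#' @param max_lag lag at the northern end, seconds.
#' @return Lag(s) in seconds.
#' @export
release_lag <- function(release_y, south_y, north_y, max_lag = 5.5 * 86400) {
  if (any(release_y < south_y - 1e-9) || any(release_y > north_y + 1e-9))
    stop("invalid argument: release outside the beach extent")
  (release_y - south_y) / (north_y - south_y) * max_lag
}
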