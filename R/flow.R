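#' Flow field container
#'
#' Bundles a [build_grid()] grid with velocity components on
#' `(x, y, z, time)`, a land/sea mask and bathymetry. Velocities are in
#' m s^-1; bathymetry is seafloor depth in meters (0 on land).
#'
#' @param grid a `grid_spec`.
#' @param u,v,w numeric arrays of dim `c(nx, ny, nz, nt)` (eastward,
#'   northward, and vertical velocity, positive down for `w`).
#' @param mask logical matrix `nx x ny`, `TRUE` for sea cells.
#' @param bathymetry numeric matrix `nx x ny`, seafloor depth in meters.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(grid, u, v, w, mask = NULL, bathymetry = NULL) {
  nz <- length(grid$z_levels)
  dims <- c(grid$nx, grid$ny, nz, grid$nt)
  shape <- function(a) {
    a <- array(as.numeric(a), dim = dims)
    a
  }
  u <- shape(u); v <- shape(v); w <- shape(w)
  if (is.null(bathymetry))
    bathymetry <- matrix(max(grid$z_levels), grid$nx, grid$ny)
  if (is.null(mask)) mask <- bathymetry > 0
  mask <- matrix(as.logical(mask), grid$nx, grid$ny)
  bathymetry <- matrix(as.numeric(bathymetry), grid$nx, grid$ny)
  bathymetry[!mask] <- 0
  sea <- which(mask)
  for (a in list(u, v, w)) {
    slab <- matrix(a, grid$nx * grid$ny)
    if (any(!is.finite(slab[sea, ])))
      stop("invalid argument: non-finite velocity on sea cells")
  }
  f <- list(grid = grid, u = u, v = v, w = w, mask = mask,
            bathymetry = bathymetry)
  class(f) <- "flow_field"
  f
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field on %d x %d x %d grid, %d time(s); %.0f%% sea\n",
              x$grid$nx, x$grid$ny, length(x$grid$z_levels), x$grid$nt,
              100 * mean(x$mask)))
  invisible(x)
}

#' Spatially uniform flow
#'
#' Analytic test field holding exactly `(u0, v0, w0)` at every cell, level
#' and time. Exact under multilinear interpolation, so it serves as a
#' closed-form oracle for advection (displacement = velocity x time).
#'
#' @inheritParams flow_field
#' @param u0,v0,w0 velocity components, m s^-1.
#' @return A `flow_field`.
#' @export
uniform_flow <- function(grid, u0, v0, w0 = 0) {
  nz <- length(grid$z_levels)
  dims <- c(grid$nx, grid$ny, nz, grid$nt)
  flow_field(grid,
             array(u0, dims), array(v0, dims), array(w0, dims))
}

#' Solid-body rotation
#'
#' Horizontal velocity `(-omega * (y - yc), omega * (x - xc))`, `w = 0`:
#' particles trace circles of period `2 * pi / omega`. The field is linear in
#' position, hence exact under bilinear interpolation — the standard
#' convergence oracle for Runge-Kutta advection.
#'
#' @inheritParams flow_field
#' @param omega angular velocity, rad s^-1.
#' @param center rotation center `(xc, yc)` in meters.
#' @return A `flow_field`.
#' @export
solid_body_rotation <- function(grid, omega, center) {
  xc <- grid_x_centers(grid); yc <- grid_y_centers(grid)
  nz <- length(grid$z_levels)
  U <- outer(rep(-omega, grid$nx), yc - center[2])
  V <- outer(omega * (xc - center[1]), rep(1, grid$ny))
  dims <- c(grid$nx, grid$ny, nz, grid$nt)
  flow_field(grid,
             array(U, dims), array(V, dims), array(0, dims))
}

#' Flow field from a streamfunction
#'
#' Evaluates a streamfunction `psi(x, y)` (m^2 s^-1) at cell centers and
#' differences it with central differences, `u = -dpsi/dy`, `v = dpsi/dx`
#' (one-sided at the domain edges). Because the same discrete operator is
#' used for both components, the central-difference divergence vanishes to
#' machine precision at every interior cell. An optional depth profile
#' scales the streamfunction per z-level; `w = 0`.
#'
#' @inheritParams flow_field
#' @param psi_fun function of two vectors `(x, y)` (via `outer`) returning
#'   the streamfunction in m^2 s^-1.
#' @param depth_profile function of depth z (m) returning a scalar multiplier
#'   per level (default `exp(-z / 100)`).
#' @param mask,bathymetry optional land/sea structure (default all sea).
#' @return A `flow_field`.
#' @export
streamfunction_field <- function(grid, psi_fun,
                                 depth_profile = function(z) exp(-z / 100),
                                 mask = NULL, bathymetry = NULL) {
  xc <- grid_x_centers(grid); yc <- grid_y_centers(grid)
  psi <- outer(xc, yc, psi_fun)
  d_dx <- function(m, h) {
    n <- nrow(m)
    out <- m
    out[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * h)
    out[1, ] <- (m[2, ] - m[1, ]) / h
    out[n, ] <- (m[n, ] - m[n - 1, ]) / h
    out
  }
  d_dy <- function(m, h) t(d_dx(t(m), h))
  U1 <- -d_dy(psi, grid$dy)
  V1 <- d_dx(psi, grid$dx)
  nz <- length(grid$z_levels)
  fac <- vapply(grid$z_levels, depth_profile, numeric(1))
  dims <- c(grid$nx, grid$ny, nz, grid$nt)
  u <- array(0, dims); v <- array(0, dims)
  for (k in seq_len(nz)) {
    u[, , k, ] <- array(U1 * fac[k], c(grid$nx, grid$ny, grid$nt))
    v[, , k, ] <- array(V1 * fac[k], c(grid$nx, grid$ny, grid$nt))
  }
  flow_field(grid, u, v, array(0, dims), mask = mask, bathymetry = bathymetry)
}

#' Synthetic coastal scenario configuration
#'
#' Parameters of the semi-realistic coastal flow and habitat generator used
#' throughout the package in place of a hydrodynamic hindcast. The default
#' domain is a 300 x 600 km strip of ocean west of a straight meridional
#' coast, carrying the circulation features the dispersal analysis assumes:
#' a southward offshore jet, a northward inshore band, a convergence of the
#' two alongshore flows at a configurable latitude, and a retention eddy
#' near a bay. The habitat is laid along the coast in two blocks separated
#' by a long sandy-beach gap with no rocky-shore sites, mirroring a
#' coastline split by an exposed beach.
#'
#' @param scenario one of `"uniform"`, `"solid_body"`,
#'   `"double_gyre_coastal"`.
#' @param extent domain size `(Lx, Ly)` m; `resolution` cell size m.
#' @param z_levels depth levels (m, positive down).
#' @param coast_x x-coordinate of the coastline (land at larger x).
#' @param v_inshore peak northward inshore speed (m s^-1) and
#'   `L_inshore` its offshore e-folding scale (m).
#' @param v_offshore peak speed of the offshore jet (m s^-1); `x_jet`,
#'   `L_jet` its center and Gaussian width (m).
#' @param y_convergence latitude (m) where the two alongshore flows meet;
#'   `L_convergence` the width of the tanh merge (m).
#' @param eddies list of `list(center = c(x, y), radius, speed)` retention
#'   eddies (Gaussian streamfunction bumps; `speed` = peak swirl, m s^-1).
#' @param gap_y alongshore interval `(y0, y1)` m left free of habitat (the
#'   spat-collection beach).
#' @param n_populations,n_sites habitat layout (contiguous alongshore
#'   populations subdividing `n_sites` 5 x 5 km squares).
#' @param site_size_m habitat site edge length (m).
#' @param uniform_u,uniform_v,omega parameters of the analytic scenarios.
#' @param seed integer; fixes every stochastic choice (inter-realisation
#'   jitter of current strengths and eddy positions).
#' @return An object of class `scenario_config`.
#' @export
coastal_config <- function(scenario = "double_gyre_coastal",
                           extent = c(300e3, 600e3),
                           resolution = c(5000, 5000),
                           z_levels = c(0, 10, 30, 100),
                           coast_x = 250e3,
                           v_inshore = 0.05, L_inshore = 10e3,
                           v_offshore = 0.15, x_jet = 150e3, L_jet = 40e3,
                           y_convergence = 550e3, L_convergence = 50e3,
                           eddies = list(list(center = c(200e3, 235e3),
                                              radius = 15e3, speed = 0.06)),
                           gap_y = c(270e3, 330e3),
                           n_populations = 18, n_sites = 49,
                           site_size_m = 5000,
                           uniform_u = 0, uniform_v = 0.05, omega = 1e-4,
                           seed = 1L) {
  cfg <- as.list(environment())
  if (!scenario %in% c("uniform", "solid_body", "double_gyre_coastal"))
    stop("invalid argument: unknown scenario '", scenario, "'")
  if (diff(gap_y) >= extent[2])
    stop("invalid argument: habitat gap wider than domain")
  class(cfg) <- "scenario_config"
  cfg
}

#' Generate a synthetic coastal scenario
#'
#' Builds the flow field and habitat geometry described by a
#' [coastal_config()]. The horizontal velocity derives from a
#' streamfunction (so its discrete divergence vanishes on interior cells):
#' an inshore band with northward flow decaying offshore, an offshore jet
#' reversed across a tanh merge so the alongshore flows converge at
#' `y_convergence`, and Gaussian eddy bumps. Current amplitudes and eddy
#' centers are jittered by up to +/-10% / +/-5 km by the seeded RNG so that
#' different seeds play the role of different years; the same seed always
#' reproduces the identical scenario bit-for-bit.
#'
#' @param config a [coastal_config()].
#' @return A list of class `coastal_scenario` with elements `field`
#'   (a `flow_field`), `sites` (a `habitat_sites` frame, see
#'   [generate_habitat()]), `beach` (release strip of the habitat gap:
#'   `list(x = c(x0, x1), y = c(y0, y1))`), `coast_x`, and `config`.
#' @export
coastal_scenario <- function(config = coastal_config()) {
  stopifnot(inherits(config, "scenario_config"))
  grid <- build_grid(config$extent, config$resolution, config$z_levels)
  if (config$scenario == "uniform") {
    field <- uniform_flow(grid, config$uniform_u, config$uniform_v)
    sites <- NULL
  } else if (config$scenario == "solid_body") {
    field <- solid_body_rotation(grid, config$omega,
                                 c(config$extent[1] / 2, config$extent[2] / 2))
    sites <- NULL
  } else {
    built <- with_seed(config$seed, build_coastal(config, grid))
    field <- built$field
    sites <- built$sites
  }
  out <- list(field = field, sites = sites,
              beach = list(x = c(config$coast_x - 5000, config$coast_x),
                           y = config$gap_y),
              coast_x = config$coast_x, config = config)
  class(out) <- "coastal_scenario"
  out
}

# Internal: streamfunction assembly for the coastal scenario (runs under a
# seeded RNG). Sign convention u = -dpsi/dy, v = dpsi/dx.
build_coastal <- function(config, grid) {
  jit <- function(lo, hi) stats::runif(1, lo, hi)
  v_in <- config$v_inshore * jit(0.9, 1.1)
  v_off <- config$v_offshore * jit(0.9, 1.1)
  eddies <- lapply(config$eddies, function(e) {
    e$center <- e$center + c(jit(-5e3, 5e3), jit(-5e3, 5e3))
    e$speed <- e$speed * jit(0.9, 1.1)
    e
  })
  xc <- config$coast_x
  gauss_int <- function(x, x0, L) sqrt(2 * pi) * L * (stats::pnorm((x - x0) / L) - 0.5)
  psi_fun <- function(x, y) {
    # inshore band: v = -v_in * exp((x - xc)/L) * tanh((y - yc)/Lc), i.e.
    # northward south of the convergence latitude, southward north of it,
    # so the alongshore flows meet at the beach gap (onshore drift there
    # closes the circulation against the coast)
    psi <- -v_in * config$L_inshore * exp(pmin(0, (x - xc)) / config$L_inshore) *
      tanh((y - config$y_convergence) / config$L_convergence)
    # offshore jet: uniformly southward (v = -v_off * g(x))
    psi <- psi - v_off * gauss_int(x, config$x_jet, config$L_jet)
    for (e in eddies) {
      r2 <- (x - e$center[1])^2 + (y - e$center[2])^2
      A <- e$speed * e$radius * exp(0.5)   # peak swirl at r = radius
      psi <- psi + A * exp(-r2 / (2 * e$radius^2))
    }
    psi
  }
  xcent <- grid_x_centers(grid)
  bathy <- pmin(250, pmax(0, 10 + (xc - xcent) * 1e-3))
  bathy_m <- matrix(bathy, grid$nx, grid$ny)
  mask <- matrix(xcent < xc, grid$nx, grid$ny)
  bathy_m[!mask] <- 0
  field <- streamfunction_field(grid, psi_fun, mask = mask,
                                bathymetry = bathy_m)
  coast_line <- rbind(c(xc, 0), c(xc, config$extent[2]))
  per_pop <- rep(config$n_sites %/% config$n_populations, config$n_populations)
  extra <- config$n_sites - sum(per_pop)
  if (extra > 0) per_pop[seq_len(extra)] <- per_pop[seq_len(extra)] + 1
  sites <- generate_habitat(coast_line, config$n_populations, per_pop,
                            site_size_m = config$site_size_m,
                            gap_y = config$gap_y, pop_gap_m = 15e3)
  list(field = field, sites = sites)
}

#' Lay habitat sites along a coastline
#'
#' Places contiguous square settlement sites hugging the seaward side of a
#' south-to-north coastal polyline, optionally skipping an alongshore gap
#' (an exposed beach with no rocky shore). Population membership is
#' contiguous alongshore: the first `sites_per_population[1]` sites belong
#' to population 1, and so on.
#'
#' @param coast_line two-column matrix of `(x, y)` vertices running
#'   south to north; the sea is to the left (west) of the line.
#' @param n_populations number of named populations.
#' @param sites_per_population integer scalar or vector (length
#'   `n_populations`) of site counts.
#' @param site_size_m edge length of the square sites, m (default 5000).
#' @param gap_y optional `c(y0, y1)`: no sites with centers in this interval.
#' @param pop_gap_m alongshore spacing between consecutive populations
#'   (sandy stretches separating rocky-shore patches); 0 = populations
#'   back-to-back.
#' @return A data frame of class `habitat_sites` with columns `site_id`,
#'   `population_id`, `xmin`, `xmax`, `ymin`, `ymax`, `area_km2`.
#' @export
generate_habitat <- function(coast_line, n_populations, sites_per_population,
                             site_size_m = 5000, gap_y = NULL,
                             pop_gap_m = 0) {
  coast_line <- as.matrix(coast_line)
  sites_per_population <- rep(as.integer(sites_per_population),
                              length.out = n_populations)
  n_sites <- sum(sites_per_population)
  seg <- diff(coast_line)
  seg_len <- sqrt(rowSums(seg^2))
  total_len <- sum(seg_len)
  # candidate centers every site_size along the arc
  s_cand <- seq(site_size_m / 2, total_len - site_size_m / 2 + 1e-6,
                by = site_size_m)
  if (length(s_cand) == 0)
    stop("invalid argument: requested sites exceed coast length")
  cum <- c(0, cumsum(seg_len))
  arc_point <- function(s) {
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(i, nrow(seg))
    frac <- (s - cum[i]) / seg_len[i]
    p <- coast_line[i, ] + frac * seg[i, ]
    tang <- seg[i, ] / seg_len[i]
    nrm <- c(-tang[2], tang[1])  # left of travel = seaward
    p + nrm * site_size_m / 2
  }
  pts_all <- t(vapply(s_cand, arc_point, numeric(2)))
  keep <- rep(TRUE, nrow(pts_all))
  if (!is.null(gap_y))
    keep <- pts_all[, 2] < gap_y[1] | pts_all[, 2] > gap_y[2]
  avail <- which(keep)
  if (length(avail) < n_sites)
    stop("invalid argument: requested sites exceed coast length")
  # walk alongshore: each population is a contiguous run of slots,
  # separated from the next by pop_gap_m of empty shore
  skip_slots <- ceiling(pop_gap_m / site_size_m)
  sel <- integer(0)
  pos <- 1L
  for (p in seq_len(n_populations)) {
    k <- sites_per_population[p]
    repeat {
      if (pos + k - 1L > length(avail))
        stop("invalid argument: requested sites exceed coast length")
      run <- avail[pos:(pos + k - 1L)]
      brk <- which(diff(run) != 1L)  # run would straddle the habitat gap
      if (length(brk)) { pos <- pos + brk[1]; next }
      break
    }
    sel <- c(sel, run)
    pos <- pos + k + skip_slots
  }
  pts <- pts_all[sel, , drop = FALSE]
  h <- site_size_m / 2
  pop <- rep(seq_len(n_populations), sites_per_population)
  out <- data.frame(
    site_id = sprintf("S%02d", seq_len(n_sites)),
    population_id = sprintf("P%02d", pop),
    xmin = round(pts[, 1] - h, 3), xmax = round(pts[, 1] + h, 3),
    ymin = round(pts[, 2] - h, 3), ymax = round(pts[, 2] + h, 3),
    area_km2 = (site_size_m / 1000)^2,
    stringsAsFactors = FALSE
  )
  class(out) <- c("habitat_sites", "data.frame")
  out
}

#' Site centroids
#'
#' @param sites a `habitat_sites` frame.
#' @return Two-column matrix of site centers (m), rownames = site ids.
#' @export
site_centroids <- function(sites) {
  m <- cbind(x = (sites$xmin + sites$xmax) / 2,
             y = (sites$ymin + sites$ymax) / 2)
  rownames(m) <- sites$site_id
  m
}
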