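test_that("velocity interpolation is multilinear and signals out-of-domain", {
  g <- tiny_grid()
  f <- uniform_flow(g, 0.1, 0)
  v <- interpolate_velocity(f, rbind(c(1e3, 1e3, 0), c(99e3, 99e3, 50)))
  expect_equal(unname(v[, 1]), c(0.1, 0.1))

  # field linear in x: midpoint value = mean of node values
  dims <- c(g$nx, g$ny, 4, 1)
  xs <- grid_x_centers(g)
  ux <- array(rep(xs * 1e-6, g$ny * 4), dims)
  fl <- flow_field(g, ux, ux * 0, ux * 0)
  mid <- (xs[3] + xs[4]) / 2
  v <- interpolate_velocity(fl, c(mid, 50e3, 0))
  expect_equal(unname(v[1, 1]), (xs[3] + xs[4]) / 2 * 1e-6)

  # 1 m outside the grid -> NA signal
  out <- interpolate_velocity(f, c(-1, 50e3, 0))
  expect_true(all(is.na(out[1, ])))
})

test_that("RK4 is exact on uniform flow and locally reversible", {
  g <- tiny_grid()
  f <- uniform_flow(g, 0.1, 0)
  p1 <- rk4_step(c(10e3, 10e3, 0), 0, 900, f)
  expect_equal(unname(p1), c(10090, 10000, 0))

  sb <- solid_body_rotation(g, 1e-4, c(50e3, 50e3))
  fwd <- rk4_step(c(60e3, 50e3, 0), 0, 900, sb)
  back <- rk4_step(fwd, 900, -900, sb)
  expect_lt(sqrt(sum((back[1:2] - c(60e3, 50e3))^2)), 1e-3)
})

test_that("RK4 holds a rotating particle to < 0.1% radial drift and converges at 4th order", {
  g <- tiny_grid()
  sb <- solid_body_rotation(g, 1e-4, c(50e3, 50e3))
  period <- 2 * pi / 1e-4
  run <- function(dt) {
    n <- ceiling(period / dt)
    h <- period / n
    pos <- c(60e3, 50e3, 0)
    for (s in 1:n) pos <- rk4_step(pos, (s - 1) * h, h, sb)
    pos
  }
  p900 <- run(900)
  expect_lt(abs(sqrt(sum((p900[1:2] - c(50e3, 50e3))^2)) - 10e3) / 10e3, 0.001)
  # endpoint error (phase-dominated) converges at 4th order
  err <- function(p) sqrt(sum((p[1:2] - c(60e3, 50e3))^2))
  expect_gt(err(p900) / err(run(450)), 10)
  expect_lt(err(p900) / err(run(450)), 24)
})

test_that("diffusion step reproduces the 2Kt displacement variance", {
  p <- matrix(0, 2000, 3)
  same <- diffusion_step(p, K_h = 0, K_v = 0)
  expect_identical(same, p)

  set.seed(99)
  n <- 20000
  q <- diffusion_step(matrix(0, n, 3), K_h = 0.1176, K_v = 0, dt = 86400)
  target <- 2 * 0.1176 * 86400
  expect_lt(abs(var(q[, 1]) / target - 1), 0.05)
  expect_lt(abs(var(q[, 2]) / target - 1), 0.05)

  # vertical variance equals 2 K_v dt regardless of substep count
  z1 <- diffusion_step(matrix(0, n, 3), K_h = 0, K_v = 0.01, dt = 900,
                       vertical_substep = 90)
  z2 <- diffusion_step(matrix(0, n, 3), K_h = 0, K_v = 0.01, dt = 900,
                       vertical_substep = 450)
  expect_lt(abs(var(z1[, 3]) / 18 - 1), 0.05)
  expect_lt(abs(var(z2[, 3]) / 18 - 1), 0.05)
  expect_error(diffusion_step(c(0, 0, 0), dt = 900, vertical_substep = 700),
               "divide")
})

test_that("sinking deepens particles by w_s * dt", {
  expect_equal(sinking_step(c(0, 0, 5), 0.001, 900)[3], 5.9)
  expect_equal(sinking_step(c(0, 0, 5), 0, 900)[3], 5)
  expect_equal(sinking_step(c(0, 0, 0), 0.001, 10000)[3], 10)
})

test_that("boundary rule reverts coast/seafloor intersections and clamps the surface", {
  sc <- scenario_small()
  f <- sc$field
  prev <- c(sc$coast_x - 2500, 150e3, 5)
  onland <- c(sc$coast_x + 2500, 150e3, 5)
  expect_equal(unname(apply_boundary(prev, onland, f)), prev)
  open <- c(100e3, 150e3, 5)
  expect_equal(unname(apply_boundary(prev, open, f)), open)
  # surface breach clamps to 0
  up <- c(100e3, 150e3, -2)
  expect_equal(unname(apply_boundary(prev, up, f))[3], 0)
  # below seafloor reverts
  deep <- c(sc$coast_x - 2500, 150e3, 500)
  expect_equal(unname(apply_boundary(prev, deep, f)), prev)
})

test_that("particles in a closed basin stay accounted for over 30 days", {
  g <- tiny_grid()
  sb <- solid_body_rotation(g, 5e-5, c(50e3, 50e3))
  parts <- make_particles(x = seq(52e3, 80e3, by = 4e3), y = 50e3, z = 5)
  cfg <- integration_config(direction = "forward", pld_max = 30 * 86400,
                            K_h = 0, K_v = 0, w_s = 0, seed = 2)
  res <- integrate_particles(parts, sb, NULL, cfg)
  expect_true(all(res$records$status == "expired"))
})

test_that("settlement requires both competency age and site containment", {
  sites <- straight_coast_sites(3)
  inside <- c(sites$xmin[2] + 100, sites$ymin[2] + 100, 0)
  d <- 86400
  expect_true(is.na(check_settlement(inside, 20 * d, sites, 21 * d, 35 * d)))
  expect_equal(check_settlement(inside, 25 * d, sites, 21 * d, 35 * d),
               sites$site_id[2])
  outside <- c(sites$xmax[2] + 1, sites$ymin[2] + 100, 0)
  hits <- check_settlement(rbind(outside), 25 * d, sites, 21 * d, 35 * d)
  expect_true(is.na(hits))
})

test_that("release lag interpolates linearly from south to north", {
  d <- 5.5 * 86400
  expect_equal(release_lag(0, 0, 88e3), 0)
  expect_equal(release_lag(88e3, 0, 88e3), d)
  expect_equal(release_lag(44e3, 0, 88e3), d / 2)
  expect_error(release_lag(-1, 0, 88e3), "beach extent")
})

test_that("integration conserves particles and respects the competency window", {
  sc <- scenario_small()
  sites <- sc$sites
  cen <- site_centroids(sites)
  set.seed(1)
  idx <- rep(1:20, each = 10)
  parts <- make_particles(x = cen[idx, 1] + runif(200, -2000, 2000),
                          y = cen[idx, 2] + runif(200, -2000, 2000),
                          z = 5, source_id = sites$site_id[idx])
  cfg <- integration_config(direction = "forward", seed = 31)
  res <- integrate_particles(parts, sc$field, sites, cfg)
  tab <- table(factor(res$records$status,
                      levels = c("settled", "expired", "removed")))
  expect_equal(sum(tab), 200)
  st <- res$records[res$records$status == "settled", ]
  expect_true(all(st$settle_age >= 21 * 86400))
  expect_true(all(st$settle_age <= 35 * 86400))
})

test_that("fixed seeds reproduce trajectories bit-for-bit", {
  sc <- scenario_small()
  parts <- make_particles(x = c(100e3, 150e3), y = c(100e3, 200e3), z = 5)
  cfg <- integration_config(direction = "forward", pld_max = 5 * 86400,
                            competency_start = 86400, record_every = 4,
                            seed = 77)
  r1 <- integrate_particles(parts, sc$field, NULL, cfg)
  r2 <- integrate_particles(parts, sc$field, NULL, cfg)
  expect_identical(r1$trajectories$x, r2$trajectories$x)
  expect_identical(r1$records, r2$records)
})

test_that("null dynamics freeze trajectories and bound their length", {
  g <- tiny_grid()
  f0 <- uniform_flow(g, 0, 0)
  parts <- make_particles(x = c(20e3, 40e3), y = 50e3, z = 5)
  cfg <- integration_config(direction = "forward", pld_max = 35 * 86400,
                            K_h = 0, K_v = 0, w_s = 0,
                            record_every = 1, seed = 3)
  res <- integrate_particles(parts, f0, NULL, cfg)
  expect_true(all(abs(res$trajectories$x - c(20e3, 40e3)) < 1e-9, na.rm = TRUE))
  # <= pld_max/dt + 1 samples per trajectory
  expect_lte(ncol(res$trajectories$x), 35 * 86400 / 900 + 1)
  expect_equal(sum(!is.na(res$trajectories$x[1, ])), 3360)
})

test_that("backward mode disables stochastic terms by default and warns if forced", {
  cfg <- integration_config(direction = "backward")
  expect_false(cfg$diffusion)
  expect_false(cfg$sinking)
  expect_warning(integration_config(direction = "backward", diffusion = TRUE),
                 "backward")
  expect_error(integration_config(dt = -900), "dt")
  expect_error(integration_config(pld_max = 86400,
                                  competency_start = 2 * 86400),
               "competency")
})

test_that("time-varying fields refuse runs longer than their axis", {
  g <- build_grid(c(50e3, 50e3), nt = 5, dt_field = 3600)
  f <- uniform_flow(g, 0.01, 0)
  parts <- make_particles(x = 25e3, y = 25e3, z = 0)
  cfg <- integration_config(direction = "forward", pld_max = 86400,
                            competency_start = 0,
                            K_h = 0, K_v = 0, w_s = 0, seed = 1)
  expect_error(integrate_particles(parts, f, NULL, cfg),
               "field time axis shorter")
})
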