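test_that("experiment presets reproduce the design table field by field", {
  d <- 86400
  e1 <- make_experiment_config(1)
  expect_equal(e1$direction, "backward")
  expect_equal(e1$pld_max, 20 * d)
  expect_true(is.na(e1$competency_start))
  expect_equal(e1$release_depth, "seafloor_plus_1")
  expect_false(e1$diffusion); expect_false(e1$sinking)
  expect_equal(e1$release_area, "beach")
  expect_equal(e1$settlement, "none")
  expect_equal(e1$n_release_points, 200)
  expect_true(e1$lagged)
  expect_equal(e1$max_lag, 5.5 * d)
  expect_equal(e1$months, 7:11)
  expect_equal(e1$years, 2015:2017)
  expect_equal(e1$particles_per_point_per_month, 1000)

  e2 <- make_experiment_config(2)
  expect_equal(e2$direction, "backward")
  expect_equal(e2$pld_max, 35 * d)
  expect_equal(e2$competency_start, 21 * d)
  expect_equal(e2$release_depth, c(0, 30))
  expect_false(e2$diffusion); expect_false(e2$sinking)
  expect_equal(e2$release_area, "primary_areas")
  expect_equal(e2$settlement, "populations")
  expect_equal(e2$months, 7:11)
  expect_equal(e2$years, 2015:2017)

  e3 <- make_experiment_config(3)
  expect_equal(e3$direction, "forward")
  expect_equal(e3$release_depth, c(0, 20))
  expect_true(e3$diffusion); expect_true(e3$sinking)
  expect_equal(e3$release_area, "sites")
  expect_equal(e3$n_release_points, 20)      # 20 points per site
  expect_equal(e3$settlement, "sites_and_primary_areas")
  expect_equal(e3$months, 6:10)
  expect_equal(e3$years, 2008:2017)

  e4 <- make_experiment_config(4)
  expect_equal(e4$direction, "forward")
  expect_equal(e4$pld_max, 30 * d)
  expect_equal(e4$competency_start, 10 * d)  # settlement allowed from day 10
  expect_equal(e4$release_depth, "seafloor_plus_1")
  expect_true(e4$diffusion); expect_true(e4$sinking)
  expect_equal(e4$settlement, "sites")
  expect_equal(e4$months, 7:11)

  expect_error(make_experiment_config(5), "experiment_id")
})

test_that("release schedules honour point counts, even spacing and depth rules", {
  sc <- scenario_small()
  cfg <- make_experiment_config(1)
  cfg$months <- 6        # 30-day month
  cfg$n_release_points <- 1
  s10 <- build_release_schedule(cfg, sc, seed = 4, particles_per_point = 10)
  expect_equal(nrow(s10), 10)
  expect_equal(unique(diff(sort(s10$release_time))), 3 * 86400)
  s1 <- build_release_schedule(cfg, sc, seed = 4, particles_per_point = 1)
  expect_equal(nrow(s1), 1)
  mb <- c(151, 181) * 86400  # June in the non-leap scenario calendar
  expect_equal(s1$release_time, mean(mb))
  # seafloor + 1 m rule: depth matches local bathymetry - 1
  b <- sc$field$bathymetry
  g <- sc$field$grid
  i <- floor(s1$x / g$dx) + 1; j <- floor(s1$y / g$dy) + 1
  expect_equal(s1$z, b[cbind(i, j)] - 1)
  # lag follows the beach latitude
  expect_equal(s10$lag[1],
               release_lag(s10$y[1], sc$beach$y[1], sc$beach$y[2]))

  cfg2 <- make_experiment_config(2)
  cfg2$months <- 7
  cfg2$n_release_points <- 5
  area <- structure(list(
    areas = list(list(label = "A01",
                      rects = matrix(c(100e3, 110e3, 100e3, 110e3), 1, 4))),
    buffer_m = 500), class = "settlement_areas")
  s2 <- build_release_schedule(cfg2, sc, seed = 5, particles_per_point = 3,
                               primary_areas = area)
  expect_equal(nrow(s2), 15)
  expect_true(all(s2$z >= 0 & s2$z <= 30))
  expect_true(all(s2$x >= 100e3 - 500 & s2$x <= 110e3 + 500))

  # 200 points x k particles -> 200k per month
  cfg$n_release_points <- 200
  s200 <- build_release_schedule(cfg, sc, seed = 6, particles_per_point = 2)
  expect_equal(nrow(s200), 400)
  expect_equal(length(unique(s200$point_id)), 200)
})

test_that("a zero-flow run settles only by local retention", {
  g <- tiny_grid(c(60e3, 60e3))
  f0 <- uniform_flow(g, 0, 0)
  sites <- straight_coast_sites(6)
  cen <- site_centroids(sites)
  parts <- make_particles(x = cen[, 1], y = cen[, 2], z = 1,
                          source_id = sites$site_id)
  cfg <- integration_config(direction = "forward", K_h = 0, K_v = 0, w_s = 0,
                            seed = 8)
  res <- integrate_particles(parts, f0, sites, cfg)
  st <- res$records[res$records$status == "settled", ]
  expect_equal(nrow(st), 6)
  expect_equal(st$settle_target_id, st$source_id)
})

test_that("experiment runs conserve particles and tag years", {
  sc <- scenario_small()
  cfg <- make_experiment_config(2)
  cfg$n_release_points <- 10
  cfg$months <- 7
  area <- structure(list(
    areas = list(list(label = "A01",
                      rects = matrix(c(230e3, 240e3, 150e3, 160e3), 1, 4))),
    buffer_m = 500), class = "settlement_areas")
  res <- run_experiment(cfg, sc, seed = 21, particles_per_point = 2,
                        primary_areas = area, years = 2015:2016)
  expect_equal(nrow(res$records), 10 * 2 * 1 * 2)
  expect_setequal(unique(res$records$year), 2015:2016)
  expect_true(all(res$records$status %in% c("settled", "expired", "removed")))
  st <- res$records[res$records$status == "settled", ]
  if (nrow(st)) {
    expect_true(all(!is.na(st$settle_population_id)))
    expect_true(all(st$settle_age >= 21 * 86400 & st$settle_age <= 35 * 86400))
  }
})

test_that("source contributions sum to 100% and normalise per area", {
  sites <- data.frame(site_id = c("S1", "S2"),
                      population_id = c("A", "B"),
                      xmin = 0, xmax = 1, ymin = 0, ymax = 1,
                      area_km2 = c(2, 1))
  rec <- toy_records(source_id = "NMB",
                     settle_target_id = c(rep("S1", 7), rep("S2", 3)))
  tab <- source_contributions(rec, sites)
  expect_equal(tab$percent[tab$population_id == "A"], 70)
  expect_equal(tab$percent[tab$population_id == "B"], 30)
  expect_equal(sum(tab$percent), 100)

  tab2 <- source_contributions(rec, sites, per_area = TRUE)
  expect_equal(tab2$percent_per_area[tab2$population_id == "A"],
               100 * 35 / 65, tolerance = 1e-12)
  expect_equal(tab2$percent_per_area[tab2$population_id == "B"],
               100 * 30 / 65, tolerance = 1e-12)

  one <- source_contributions(
    toy_records("NMB", rep("S1", 5)), sites)
  expect_equal(one$percent, 100)

  expect_warning(
    empty <- source_contributions(toy_records("NMB", NA_character_), sites),
    "no settlers")
  expect_equal(nrow(empty), 0)
})

test_that("one-way ANOVA matches a sums-of-squares oracle", {
  # df structure for 11 populations x 3 years
  set.seed(12)
  v <- rnorm(33)
  g <- rep(letters[1:11], each = 3)
  a <- one_way_anova(v, g)
  expect_equal(c(a$df1, a$df2), c(10, 22))

  # identical groups -> F = 0, p = 1
  flat <- one_way_anova(rep(5, 12), rep(1:4, each = 3))
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)

  # brute-force SS decomposition on a random 3 x 5 layout
  set.seed(77)
  v <- rnorm(15, mean = rep(c(0, 1, 3), each = 5))
  g <- rep(c("x", "y", "z"), each = 5)
  a <- one_way_anova(v, g)
  gm <- mean(v)
  means <- tapply(v, g, mean)
  ssb <- sum(5 * (means - gm)^2)
  ssw <- sum((v - means[g])^2)
  F_hand <- (ssb / 2) / (ssw / 12)
  expect_equal(a$F, F_hand, tolerance = 1e-10)
  expect_equal(a$p, stats::pf(F_hand, 2, 12, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_error(one_way_anova(1:3, c("a", "a", "b")), "groups")
})
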