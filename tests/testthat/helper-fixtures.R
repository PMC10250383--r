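# Shared fixtures: tiny grids, pinned trajectories, toy record tables.

tiny_grid <- function(extent = c(100e3, 100e3), res = c(5000, 5000), ...)
  build_grid(extent, res, ...)

# A `trajectories` object with particles pinned at fixed positions for a
# given number of hourly samples (for density-map tests).
pinned_trajectories <- function(xy, n_samples = 10, dt = 3600) {
  n <- nrow(xy)
  times <- (seq_len(n_samples) - 1) * dt
  structure(list(
    times = times,
    x = matrix(rep(xy[, 1], n_samples), n, n_samples),
    y = matrix(rep(xy[, 2], n_samples), n, n_samples),
    z = matrix(0, n, n_samples),
    release_time = rep(0, n), lag = rep(0, n),
    particle_id = seq_len(n), direction = "forward"
  ), class = "trajectories")
}

# Minimal settlement-record table.
toy_records <- function(source_id, settle_target_id,
                        status = ifelse(is.na(settle_target_id),
                                        "expired", "settled"),
                        year = NULL, ...) {
  df <- data.frame(source_id = source_id,
                   settle_target_id = settle_target_id,
                   status = status, stringsAsFactors = FALSE, ...)
  if (!is.null(year)) df$year <- year
  df
}

# Straight meridional coast with contiguous sites over the whole extent
# (all-sea uniform-flow test bed).
straight_coast_sites <- function(n_sites, n_pops = 1, y0 = 0,
                                 site_size = 5000, coast_x = 50e3) {
  generate_habitat(rbind(c(coast_x, y0),
                         c(coast_x, y0 + n_sites * site_size)),
                   n_pops, rep(n_sites %/% n_pops, n_pops) +
                     c(rep(1, n_sites %% n_pops),
                       rep(0, n_pops - n_sites %% n_pops)),
                   site_size_m = site_size)
}

scenario_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- coastal_scenario(coastal_config(seed = 42))
    cache
  }
})

# Strip metadata attributes, keeping dim/dimnames, for value comparisons.
mval <- function(m) {
  a <- unclass(m)
  attributes(a) <- list(dim = dim(a), dimnames = dimnames(a))
  a
}
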