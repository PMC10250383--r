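# Cached full-pipeline run shared by the acceptance checks: backtracking
# from the beach (experiment 1), density-based extraction of the primary
# settlement areas, source backtracking (experiment 2), forward regional
# connectivity (experiment 3, ~2e4 larvae), and the spat stage
# (experiment 4), all on the seeded two-block coastal scenario.
acceptance_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sc <- coastal_scenario(coastal_config(seed = 1))
    r1 <- run_experiment(make_experiment_config(1), sc, seed = 101,
                         particles_per_point = 2, years = 2015)
    dens <- trajectory_density(r1$trajectories,
                               bbox = c(0, 300e3, 0, 600e3),
                               age_window = c(10, 20) * 86400,
                               lag_extends_window = TRUE)
    areas <- extract_settlement_areas(dens, threshold_per_km2 = 0.6,
                                      buffer_m = 500,
                                      n_particles = nrow(r1$records))
    r2 <- run_experiment(make_experiment_config(2), sc, seed = 404,
                         particles_per_point = 1, primary_areas = areas,
                         years = 2015:2017)
    r3 <- run_experiment(make_experiment_config(3), sc, seed = 202,
                         particles_per_point = 4, primary_areas = areas,
                         years = 2008)
    r4 <- run_experiment(make_experiment_config(4), sc, seed = 303,
                         particles_per_point = 4, primary_areas = areas,
                         years = 2008)
    site_ids <- sc$sites$site_id
    area_ids <- vapply(areas$areas, `[[`, "", "label")
    Cp <- connectivity_from_experiment(r3, sink_ids = site_ids)
    CA <- connectivity_from_experiment(r3, sink_ids = area_ids)
    AS <- connectivity_from_experiment(r4, sink_ids = site_ids,
                                       source_ids = area_ids)
    sec <- secondary_connectivity(CA, AS)
    tot <- total_connectivity(Cp, sec)
    cache <<- list(scenario = sc, r1 = r1, r2 = r2, r3 = r3, r4 = r4,
                   density = dens, areas = areas,
                   Cp = Cp, CA = CA, AS = AS, sec = sec, tot = tot)
    cache
  }
})
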