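# Full simulation studies are expensive, and several acceptance checks
# read different cells of the same study tables, so each scenario is run
# once per session and cached. Replication: 50 iterations for the
# homogeneous base scenario (only regional bias and MRSE are read from
# it), 100 for the variable-density scenario feeding the regional
# coverage checks, 60 for the two scenarios with variable detectability.
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function(scenario) {
  key <- paste0("s", scenario)
  if (is.null(.study_cache[[key]])) {
    iters <- c(50L, 100L, 60L, 60L)[scenario]
    .study_cache[[key]] <- run_study(scenario, iterations = iters,
                                     seed = 100L + scenario)
  }
  .study_cache[[key]]
}

# Simulation-only calibration runs (no fitting).
.calib_cache <- new.env(parent = emptyenv())

acceptance_calibration <- function(scenario, iterations = 500L) {
  key <- paste0("c", scenario)
  if (is.null(.calib_cache[[key]])) {
    sc <- make_scenario(scenario)
    set.seed(500L + scenario)
    seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                               2L * iterations), ncol = 2L)
    .calib_cache[[key]] <- do.call(rbind, lapply(seq_len(iterations),
      function(i) {
        pop <- sample_population(sc, seeds[i, 1L])
        s <- captures_summary(simulate_captures(pop, sc, seeds[i, 2L]))
        data.frame(iteration = i, total_n = sum(s$n),
                   total_recaptures = sum(s$recaptures),
                   total_spatial = sum(s$spatial_recaptures),
                   southern_mean_n = mean(s$n[1:2]))
      }))
  }
  .calib_cache[[key]]
}

summary_cell <- function(study, analysis, array_id, col) {
  s <- study$summary$local
  s[s$analysis == analysis & s$array_id == array_id, col]
}

regional_cell <- function(study, analysis, variance, col) {
  s <- study$summary$regional
  s[s$analysis == analysis & s$variance == variance, col]
}
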