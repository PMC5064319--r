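# Workflow fixtures: planted-chain scenario written out as plain-text
# multi-model PDB, split into two replicas, plus a matching RunConfig.

write_scenario_fixture <- function(dir, seed = 1, n_frames = 60, k = 4) {
  sc <- make_pathway_scenario(chain_spec(k), n_decoys = 2,
                              n_frames = n_frames, seed = seed)
  top <- file.path(dir, sprintf("top_%d.pdb", seed))
  half <- n_frames %/% 2
  t1 <- file.path(dir, sprintf("r1_%d.pdb", seed))
  t2 <- file.path(dir, sprintf("r2_%d.pdb", seed))
  write_models_pdb(sc$structure, structure_xyz(sc$structure), top)
  write_models_pdb(sc$structure, sc$trajectory$xyz[1:half, ], t1)
  write_models_pdb(sc$structure, sc$trajectory$xyz[(half + 1):n_frames, ], t2)
  list(scenario = sc, topology = top, trajectories = c(t1, t2))
}

scenario_config <- function(fx, sc, p_T = sc$truth$p_T) {
  run_config(list(
    states = list(planted = list(topology = fx$topology,
                                 trajectories = as.list(fx$trajectories))),
    sources = sc$truth$source, sinks = sc$truth$sink,
    p_T = p_T, n_pcs = 4, seed = 1))
}

# trajectory hopping between two well-separated conformational basins
two_basin_trajectory <- function(n_per_basin = 10, sep_mag = 2,
                                 jitter = 0.03, seed = 1) {
  s <- make_polymer(8)
  base <- structure_xyz(s)
  basinB <- random_conformation(base, sep_mag, seed = seed + 500)
  set.seed(seed)
  frames <- rbind(
    t(replicate(n_per_basin, base + stats::rnorm(length(base), 0, jitter))),
    t(replicate(n_per_basin, basinB + stats::rnorm(length(base), 0, jitter))))
  tr <- new_trajectory(s, frames)
  tr$superposed <- TRUE
  list(structure = s, trajectory = tr,
       truth = rep(1:2, each = n_per_basin))
}
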