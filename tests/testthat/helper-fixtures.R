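# shared fixtures: tiny topologies, hand-built trajectories, and a cached
# full-scale synthetic run used by several expensive checks

tiny_topology <- function(n_res = 5L, radius = 3, sequence = NULL) {
  half <- max(1L, n_res %/% 2L)
  fab_topology(light_len = half, heavy_len = n_res - half,
               sequence = sequence, radius = radius)
}

# trajectory from explicit per-frame coordinate lists for two bodies
two_body_traj <- function(frames_a, frames_b, L = 100, dt = 10) {
  coords <- Map(function(a, b) rbind(a, b), frames_a, frames_b)
  trajectory(coords, box = L, frame_interval = dt, n_bodies = 2L)
}

# single placement of an n-residue body: a line of beads along +x from origin
line_body <- function(n, origin = c(0, 0, 0), step = 5) {
  cbind(origin[1] + step * (seq_len(n) - 1), origin[2], origin[3])
}

# cached 5000-frame planted-interface run shared by recovery checks
.run_cache <- new.env(parent = emptyenv())
planted_run <- function() {
  if (is.null(.run_cache$run)) {
    cfg <- synth_trajectory_config(n_frames = 5000L, seed = 1L)
    gen <- generate_two_body_trajectory(cfg)
    rec <- contact_record(gen$trajectory, gen$topology)
    .run_cache$run <- list(gen = gen, rec = rec,
                           freq = accumulate_frequencies(rec))
  }
  .run_cache$run
}

# fixed reference table used by model tests
model_table <- function(seed = 3L, noise_sd = 0.3) {
  generate_feature_table(synth_feature_config(seed = seed, noise_sd = noise_sd))
}
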