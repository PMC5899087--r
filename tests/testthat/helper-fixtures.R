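# shared fixtures, all generated in code

# bipartite Xi map (200 bins, hinge at 100), processed to the iced stage
iced_bipartite <- function(seed = 1, preset = "wt", ...) {
  m <- simulate_preset(preset, seed = seed, ...)
  ice_normalize(filter_matrix(m))
}

# TAD-only chromosome at the 40 kb-style configuration used for domain calling
iced_tads <- function(seed = 1, n_tads = 5) {
  cfg <- sim_config(chrom_length = 8e6, bin_size = 4e4, seed = seed)
  tr <- sim_truth_control(cfg, n_tads = n_tads)
  tr$compartment_labels <- NULL
  ice_normalize(filter_matrix(simulate_contact_map(cfg, tr)))
}

# compartments-only chromosome
iced_compartments <- function(seed = 1) {
  cfg <- sim_config(seed = seed)
  tr <- sim_truth_control(cfg)
  tr$tad_boundaries <- integer(0)
  ice_normalize(filter_matrix(simulate_contact_map(cfg, tr)))
}

# small symmetric random positive matrix as a contact_matrix
random_cm <- function(n, seed = 1, stage = "filtered") {
  set.seed(seed)
  v <- matrix(stats::runif(n * n, 1, 10), n, n)
  v <- (v + t(v)) / 2
  contact_matrix(v, bin_grid(n * 5e5, 5e5), stage = stage)
}

# uniform off-diagonal matrix
uniform_cm <- function(n, value = 1, stage = "iced") {
  v <- matrix(value, n, n)
  diag(v) <- 0
  contact_matrix(v, bin_grid(n * 5e5, 5e5), stage = stage)
}

# two-block matrix: high within blocks (diagonal included), low across
block_cm <- function(n = 20, split = 10, hi = 10, lo = 1, stage = "iced") {
  idx <- seq_len(n) - 1
  inA <- idx < split
  v <- matrix(lo, n, n)
  v[outer(inA, inA, "&") | outer(!inA, !inA, "&")] <- hi
  contact_matrix(v, bin_grid(n * 5e5, 5e5), stage = stage)
}

# decay-only chromosome: no superdomains, flame, compartments or TADs
iced_decay <- function(seed = 1) {
  cfg <- sim_config(seed = seed, superdomain_s = 1)
  tr <- sim_truth(200, hinge_bin = NA, flame_direction = "none")
  ice_normalize(filter_matrix(simulate_contact_map(cfg, tr)))
}
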