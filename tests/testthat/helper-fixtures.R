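# Shared fixtures: all built in code at test time.

# straight chain along x with given spacing (um)
chain_tree <- function(n = 11, spacing = 10, radius = 1, label = "axon") {
  nodes <- data.frame(id = seq_len(n), parent = c(NA, seq_len(n - 1)),
                      x = (seq_len(n) - 1) * spacing, y = 0, z = 0,
                      radius = radius, label = label)
  tree_morphology(nodes)
}

# random rooted tree with random 3D positions, reproducible
random_tree <- function(n = 30, seed = 1) {
  set.seed(seed)
  parent <- c(NA, vapply(2:n, function(i) sample(i - 1L, 1L), integer(1)))
  nodes <- data.frame(id = seq_len(n), parent = parent,
                      x = runif(n, 0, 100), y = runif(n, 0, 100),
                      z = runif(n, 0, 20), radius = runif(n, 0.2, 2),
                      label = c("soma", rep("axon", n - 1)))
  tree_morphology(nodes)
}

# small bipolar cell model that simulates in well under a second
tiny_bc_model <- function(seed = 3, active = TRUE, sim_seed = 5) {
  gen <- gen_bc_morphology(bc_gen_params(
    seed = seed, n_ribbons = 12, n_inhibitory = 16, n_excitatory = 4,
    arbor_radius = 12, branch_order = 4, branch_length_mean = 6))
  build_bc_model(gen$morphology, gen$sites, active = active,
                 cfg = sim_config(dt = 0.1, settle_time = 300,
                                  stim_time = 600, seed = sim_seed))
}

# fabricate a constant-voltage recording in cable_sim form
const_sim <- function(levels, t_max = 100, site_ids = seq_along(levels)) {
  tt <- seq(0, t_max, by = 1)
  v <- matrix(rep(levels, each = length(tt)), ncol = length(levels))
  colnames(v) <- as.character(site_ids)
  structure(list(time = tt, v = v, window = c(0, t_max)),
            class = "cable_sim")
}

# polar-grid 2D integration of the DoG over a disc (independent oracle)
dog_disc_oracle <- function(dog, offset, diameter, nr = 600, nth = 400) {
  R <- diameter / 2
  if (R <= 0) return(0)
  r <- (seq_len(nr) - 0.5) * R / nr
  th <- (seq_len(nth) - 0.5) * 2 * pi / nth
  d2 <- outer(r^2 + offset^2, rep(1, nth)) -
    2 * offset * outer(r, cos(th))
  g <- function(s) exp(-d2 / (2 * s^2)) / (2 * pi * s^2)
  integrand <- g(dog$sigma_c) - g(dog$sigma_s) / dog$csr
  sum(integrand * r) * (R / nr) * (2 * pi / nth)
}
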