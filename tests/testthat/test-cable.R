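cp_default <- cable_params()

test_that("compartment discretization preserves geometry and topology", {
  # 100 um cylinder, max_len 10 -> 10 cable segments
  m <- tree_morphology(data.frame(id = 1:2, parent = c(NA, 1),
                                  x = c(0, 100), y = 0, z = 0, radius = 1,
                                  label = "axon"))
  g <- build_compartments(m, 10)
  expect_equal(g$n_segments, 10)
  expect_equal(sum(is.na(g$parent)), 1)                 # still a tree
  expect_equal(g$n - 1, sum(!is.na(g$parent)))          # edges = nodes - 1

  # membrane area identity against the frustum-summed morphology area
  mt <- random_tree(30, seed = 12)
  gt <- build_compartments(mt, 3)
  expect_equal(sum(gt$area_um2), morphology_area(mt),
               tolerance = 1e-9)
  expect_error(build_compartments(mt, 0), "positive")
})

test_that("passive membrane with no input rests exactly at the leak reversal", {
  m <- chain_tree(21, spacing = 5)
  g <- build_compartments(m, 5)
  sim <- simulate_cable(g, cp_default,
                        cfg = sim_config(dt = 0.05, settle_time = 100,
                                         stim_time = 100))
  expect_equal(range(sim$v), c(-60, -60), tolerance = 1e-10)
})

test_that("steady-state point-source profile matches the sealed-end cosh form", {
  m <- tree_morphology(data.frame(id = 1:2, parent = c(NA, 1),
                                  x = c(0, 500), y = 0, z = 0, radius = 1,
                                  label = "axon"))
  g <- build_compartments(m, 5)
  sim <- simulate_cable(g, cp_default,
                        cfg = sim_config(dt = 0.05, settle_time = 0,
                                         stim_time = 1500),
                        injections = list(list(comp = 2L, amp = 0.01,
                                               freq = 0)),
                        record_comps = 2:g$n)
  v <- sim$v[nrow(sim$v), ] + 60
  lambda <- sqrt(cp_default$axial_resistivity^-1 *
                 (1 / cp_default$leak_conductance_density) * 1e-4 / 2) * 1e4
  x <- cumsum(g$length[2:g$n]) - g$length[2] / 2
  pred <- cosh((500 - x) / lambda)
  i0 <- 10                      # normalize away from the source compartment
  rel <- (v / v[i0]) / (pred / pred[i0]) - 1
  expect_lt(max(abs(rel[i0:length(x)])), 0.01)
})

test_that("low-frequency AC length constant matches the analytic cable value", {
  n <- 301
  m <- chain_tree(n, spacing = 10)
  g <- build_compartments(m, 10)
  rib <- synapse_sites(1:2, c(41, 71), c("ribbon", "ribbon"), m)
  lc <- sinusoidal_length_constants(m, g, cp_default, channels = NULL,
                                    cfg = sim_config(dt = 0.1),
                                    freq = 0.25, soma_node = 1,
                                    ribbons = rib, amp = 0.005)
  lambda <- sqrt((1 / cp_default$leak_conductance_density) * 1e-4 /
                 (2 * cp_default$axial_resistivity)) * 1e4
  expect_lt(max(abs(lc$lambda_um / lambda - 1)), 0.05)
})

test_that("backward-Euler solution is dt-converged at the working step", {
  model <- tiny_bc_model()
  rates <- list(dark = 30, light = 400, inh = 20)
  s1 <- run_bc_sim(model, "light",
                   inh_site_ids = model$inhibitory$site_id[1:4],
                   rates = rates, seed = 9)
  model2 <- model
  model2$cfg$dt <- model$cfg$dt / 2
  s2 <- run_bc_sim(model2, "light",
                   inh_site_ids = model$inhibitory$site_id[1:4],
                   rates = rates, seed = 9)
  expect_lt(max(abs(s1$v[nrow(s1$v), ] - s2$v[nrow(s2$v), ])), 0.1)
})

test_that("simulations are a pure function of inputs and seed", {
  model <- tiny_bc_model()
  rates <- list(dark = 30, light = 400, inh = 15)
  a <- run_bc_sim(model, "light", rates = rates, seed = 21)
  b <- run_bc_sim(model, "light", rates = rates, seed = 21)
  c <- run_bc_sim(model, "light", rates = rates, seed = 22)
  expect_identical(a$v, b$v)
  expect_false(identical(a$v, c$v))

  # window-mean recording agrees with the full-trace window average
  am <- run_bc_sim(model, "light", rates = rates, seed = 21,
                   record = "mean")
  expect_equal(unname(am$v[1, ]), unname(mean_voltage(a)),
               tolerance = 1e-3)

  # trace CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(a, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back$time_ms, a$time)
  expect_equal(as.matrix(back[, -1]), a$v, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("voltages stay within the span of the reversal potentials", {
  model <- tiny_bc_model(active = TRUE)
  rates <- list(dark = 50, light = 2000, inh = 300)
  sim <- run_bc_sim(model, "light",
                    inh_site_ids = model$inhibitory$site_id,
                    rates = rates, seed = 2)
  # reversals present: leak -60, exc 10.1, inh -50.4, Kv -77, CaL 45,
  # HCN2 -30 -> bounds [-77, 45]
  expect_gt(min(sim$v), -77 - 1e-6)
  expect_lt(max(sim$v), 45 + 1e-6)
})

test_that("conductance accounting is internally consistent", {
  model <- tiny_bc_model(active = FALSE)
  model$rates <- list(dark = 30, light = 400, inh = 20)
  g_pas <- conductance_accounting(model,
                                  inh_site_ids = model$inhibitory$site_id)
  expect_equal(unname(g_pas[c("CaL", "Kv", "HCN2")]), c(0, 0, 0))
  expect_gt(g_pas[["leak"]], 0)
  expect_gt(g_pas[["syn_inh"]], 0)

  act <- tiny_bc_model(active = TRUE)
  act$rates <- model$rates
  g_act <- conductance_accounting(act,
                                  inh_site_ids = act$inhibitory$site_id)
  parts <- g_act[c("leak", "CaL", "Kv", "HCN2", "syn_exc", "syn_inh")]
  expect_equal(sum(parts), g_act[["total"]], tolerance = 1e-9)

  # conductance-matched passive control reproduces the active total
  syn <- g_act[["syn_exc"]] + g_act[["syn_inh"]]
  matched <- tiny_bc_model(active = FALSE)
  matched$cable <- matched_leak_params(matched, g_act[["total"]] - syn)
  matched$rates <- model$rates
  g_m <- conductance_accounting(matched,
                                inh_site_ids = matched$inhibitory$site_id)
  expect_lt(abs(g_m[["total"]] / g_act[["total"]] - 1), 0.02)
})

test_that("length constants shrink when cytoplasmic resistivity rises", {
  n <- 201
  m <- chain_tree(n, spacing = 10)
  g <- build_compartments(m, 10)
  rib <- synapse_sites(1:2, c(31, 61), c("ribbon", "ribbon"), m)
  probe <- function(cp) sinusoidal_length_constants(
    m, g, cp, cfg = sim_config(dt = 0.1), freq = 1, soma_node = 1,
    ribbons = rib, amp = 0.005)$lambda_um
  l1 <- probe(cable_params())
  l2 <- probe(cable_params(axial_resistivity = 260))
  expect_true(all(l2 < l1))
})

test_that("higher probe frequencies give shorter length constants", {
  model <- tiny_bc_model(active = TRUE)
  m <- model$morphology
  soma <- m$nodes$id[is.na(m$nodes$parent)]
  lam <- function(freq) {
    lc <- sinusoidal_length_constants(m, model$graph, model$cable,
                                      model$channels,
                                      cfg = sim_config(dt = 0.05),
                                      freq = freq, soma_node = soma,
                                      ribbons = model$ribbons, amp = 0.002)
    mean(lc$lambda_um[is.finite(lc$lambda_um)])
  }
  expect_lt(lam(250), lam(10))
})
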