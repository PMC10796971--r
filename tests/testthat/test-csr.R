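test_that("CSR arithmetic matches its definition", {
  exc <- const_sim(c(-30, -30, -30))
  inh <- const_sim(c(-40, -44, -30))
  res <- measure_csr(exc, inh, baseline = -45)
  expect_equal(res$center, rep(15, 3))
  expect_equal(res$surround, c(10, 14, 0))
  expect_equal(res$csr[1], 1.5)
  # ribbon held at -44 under inhibition: CSR ~ 1.07 (the 1.1 operating point)
  expect_equal(res$csr[2], 15 / 14, tolerance = 1e-12)
  expect_lt(abs(res$csr[2] - 1.1), 0.05)
  # inhibition with no effect -> infinite CSR sentinel, not an error
  expect_identical(res$csr[3], Inf)
})

test_that("quartile statistics partition and summarize as defined", {
  mk <- function(csr) data.frame(site_id = seq_along(csr), csr = csr)
  qs <- quartile_stats(mk(1:84))
  expect_equal(qs$n_per_quartile, 21)
  expect_equal(qs$q1_mean, 11)
  expect_equal(qs$q4_mean, 74)
  expect_equal(qs$csr_range, 63)

  expect_equal(quartile_stats(mk(rep(2, 8)))$csr_range, 0)
  expect_error(quartile_stats(mk(c(1, 2, 3))), "at least 4")
  expect_warning(qs2 <- quartile_stats(mk(c(1:8, Inf))), "infinite")
  expect_equal(qs2$n_used, 8)
})

test_that("inhibitory-set sweeps have the required structure", {
  model <- calibrate_rates(tiny_bc_model())
  anchors <- model$inhibitory$site_id[c(1, 6, 11)]

  sw1 <- suppressWarnings(
    sweep_inhibitory_sets(model, n_active = 1, anchors = anchors, seed = 2))
  expect_equal(nrow(sw1$per_anchor), 3)           # one range per anchor
  rs <- sw1$range_summary
  expect_true(rs["min"] <= rs["median"] && rs["median"] <= rs["max"])

  # all synapses active: every anchor runs the identical simulation
  n_all <- nrow(model$inhibitory)
  sw_all <- suppressWarnings(
    sweep_inhibitory_sets(model, n_active = n_all, anchors = anchors,
                          seed = 2))
  expect_equal(length(unique(sw_all$per_anchor$csr_range)), 1L)
  expect_error(sweep_inhibitory_sets(model, n_active = 0), "n_active")
})

test_that("recalibrated sweeps hold the Q1 CSR setpoint", {
  model <- calibrate_rates(tiny_bc_model())
  anchors <- model$inhibitory$site_id[c(2, 8, 14)]
  sw <- suppressWarnings(
    sweep_inhibitory_sets(model, n_active = 4, anchors = anchors, seed = 7,
                          q1_target = 1.1, tol_csr = 0.05))
  expect_lt(abs(mean(sw$per_anchor$q1_mean) - 1.1), 0.05 + 1e-9)
})

test_that("robustness sweep recovers the unperturbed range at multiplier 1", {
  base <- tiny_bc_model()
  anchors <- base$inhibitory$site_id[c(1, 9)]
  rs <- suppressWarnings(
    robustness_sweep(base, "axial_resistivity", c(1, 4), n_active = 3,
                     anchors = anchors, seed = 4))
  expect_equal(nrow(rs), 2)
  expect_true(all(is.na(rs$error)))

  direct_model <- calibrate_rates(base)
  direct <- suppressWarnings(
    sweep_inhibitory_sets(direct_model, n_active = 3, anchors = anchors,
                          seed = 4))
  expect_equal(rs$csr_range[1], unname(direct$range_summary["median"]),
               tolerance = 1e-12)
  # higher cytoplasmic resistivity -> stronger compartmentalization
  expect_gt(rs$csr_range[2], rs$csr_range[1])
})
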