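test_that("synthetic bipolar cell carries the full synapse complement", {
  gen <- gen_bc_morphology(bc_gen_params(seed = 2))
  expect_silent(validate_tree_morphology(gen$morphology))
  counts <- table(gen$sites$kind)
  expect_equal(unname(counts["ribbon"]), 84)
  expect_equal(unname(counts["inhibitory"]), 120)
  expect_equal(unname(counts["excitatory"]), 8)

  # determinism under the seed
  gen2 <- gen_bc_morphology(bc_gen_params(seed = 2))
  expect_identical(gen2$morphology$nodes, gen$morphology$nodes)
  expect_identical(as.data.frame(gen2$sites), as.data.frame(gen$sites))
  gen3 <- gen_bc_morphology(bc_gen_params(seed = 3))
  expect_false(identical(gen3$morphology$nodes, gen$morphology$nodes))

  # ribbon output synapses are close together on the arbor
  rib <- gen$sites[gen$sites$kind == "ribbon", ]
  nn <- vapply(seq_len(nrow(rib)), function(i)
    min(path_distances(gen$morphology, rib$node_id[i], rib$node_id[-i])),
    numeric(1))
  expect_lt(mean(nn), 25)

  expect_error(gen_bc_morphology(bc_gen_params(
    seed = 1, n_ribbons = 5000, branch_order = 3)), "exceed")
})

test_that("synthetic ganglion cell skeletons meet size targets", {
  p <- rgc_gen_params(seed = 8, field_diameter = 300,
                      total_dendrite_length = 3000)
  m <- gen_rgc_skeleton(p)
  m2 <- gen_rgc_skeleton(p)
  expect_identical(m2$nodes, m$nodes)

  # convex-hull diameter within 10% of the requested field diameter
  pts <- m$nodes[, c("x", "y")]
  hull <- pts[chull(pts), ]
  hull_d <- max(dist(hull))
  expect_gt(hull_d, 270); expect_lt(hull_d, 330)
  # total dendritic length within 10% of target
  expect_gt(total_length(m), 2700); expect_lt(total_length(m), 3300)
  # planar
  expect_equal(diff(range(m$nodes$z)), 0)

  expect_error(rgc_gen_params(seed = 1, field_diameter = 300,
                              total_dendrite_length = 200), "infeasible")
})

test_that("generated response curves reduce to the forward model at zero noise", {
  skel <- gen_rgc_skeleton(rgc_gen_params(seed = 3, field_diameter = 150,
                                          total_dendrite_length = 600))
  dog <- dog_params(22, 90, 1.5)
  curves <- gen_response_curves(list(skel), dog, noise_sd = 0, seed = 10)
  expect_length(curves, 1)
  cu <- curves[[1]]
  expect_length(cu$diameters, 12)
  expect_equal(cu$diameters[1], 30)
  expect_equal(cu$diameters[12], 1200)
  layout <- place_subunits(skel, density = 0.3,
                           seed = attr(cu, "layout_seed"))
  direct <- predict_response(layout, dog, cu$diameters)
  expect_equal(cu$responses, direct$responses, tolerance = 1e-12)
  expect_identical(attr(cu, "truth"), dog)
})

test_that("curve noise magnitude matches the requested level", {
  skel <- gen_rgc_skeleton(rgc_gen_params(seed = 3, field_diameter = 150,
                                          total_dendrite_length = 600))
  dog <- dog_params(22, 90, 1.5)
  reps <- vapply(1:120, function(s) {
    cu <- gen_response_curves(list(skel), dog, noise_sd = 0.05,
                              seed = s)[[1]]
    cu$responses[4]
  }, numeric(1))
  # sd on the normalized scale, before re-normalization, is 0.05; the
  # re-normalization inflates spread slightly, so allow 25%
  expect_gt(sd(reps), 0.05 * 0.75)
  expect_lt(sd(reps), 0.05 * 1.25)
})
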