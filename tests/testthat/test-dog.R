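test_that("DoG disc activation matches independent 2D integration", {
  dog <- dog_params(22, 100, 1.8)
  for (off in c(0, 10, 40, 150)) {
    for (d in c(30, 120, 600)) {
      expect_equal(bc_activation(dog, off, d),
                   dog_disc_oracle(dog, off, d), tolerance = 1e-4)
    }
  }
  expect_equal(bc_activation(dog, 0, 0), 0)
  # full-field limit is the volume difference 1 - 1/CSR
  expect_equal(bc_activation(dog, 0, 1e5), 1 - 1 / 1.8, tolerance = 1e-6)
  # centered pure-center Gaussian over a disc of radius sigma_c
  pure <- dog_params(22, 2000, 1e9)
  expect_equal(bc_activation(pure, 0, 44), 1 - exp(-0.5), tolerance = 1e-6)
  # bounded in (-1/csr, 1]
  acts <- bc_activation(dog, seq(0, 400, by = 20), 300)
  expect_true(all(acts > -1 / 1.8 & acts <= 1))
})

test_that("subunit placement is uniform per unit dendritic length", {
  skel <- chain_tree(11, spacing = 30, label = "dendrite")  # 300 um
  layout <- place_subunits(skel, density = 0.3, seed = 1)
  expect_equal(layout$n, 1000)
  expect_equal(nrow(layout$centers), 1000)

  means <- vapply(1:40, function(s)
    mean(place_subunits(chain_tree(2, spacing = 100,
                                   label = "dendrite"),
                        density = 1, seed = s)$centers[, 1]),
    numeric(1))
  expect_lt(abs(mean(means) - 50), 2)

  empty <- place_subunits(tree_morphology(data.frame(
    id = 1, parent = NA, x = 0, y = 0, z = 0, radius = 1, label = "soma")),
    seed = 1)
  expect_equal(empty$n, 0)
  expect_error(predict_response(empty, dog_params(22, 100, 2)), "empty")
})

test_that("predicted curves respect linearity and layout symmetries", {
  dog <- dog_params(22, 100, 2)
  diams <- default_diameters()
  one <- function(x, y) {
    l <- list(centers = matrix(c(x, y), 1, 2), centroid = c(0, 0),
              offsets = sqrt(x^2 + y^2), density = 0.3, n = 1L)
    class(l) <- "subunit_layout"
    l
  }
  pair <- list(centers = rbind(c(40, 0), c(-40, 0)), centroid = c(0, 0),
               offsets = c(40, 40), density = 0.3, n = 2L)
  class(pair) <- "subunit_layout"
  # two symmetric subunits average the two single-subunit curves
  expect_equal(predict_response(pair, dog, diams)$responses,
               predict_response(one(40, 0), dog, diams)$responses,
               tolerance = 1e-10)
  # rigid rotation about the spot center leaves the curve unchanged
  expect_equal(predict_response(one(0, 40), dog, diams)$responses,
               predict_response(one(40, 0), dog, diams)$responses,
               tolerance = 1e-10)
  # center-only subunit: response never decreases with spot size
  centered <- one(0, 0)
  r <- predict_response(centered, dog_params(22, 2000, 1e9),
                        diams)$responses
  expect_true(all(diff(r) >= -1e-6))        # non-decreasing up to quadrature noise
  expect_gt(r[length(r)], max(r) - 1e-6)    # maximum at the largest spot

})

test_that("suppression of predicted curves decreases with CSR", {
  skel <- gen_rgc_skeleton(rgc_gen_params(seed = 2, field_diameter = 200,
                                          total_dendrite_length = 800))
  layout <- place_subunits(skel, seed = 3)
  sup <- vapply(c(1.1, 1.5, 2.3), function(csr)
    suppression(predict_response(layout, dog_params(22, 75, csr)))$suppression,
    numeric(1))
  expect_true(all(diff(sup) < 0))
})

test_that("fitting recovers generating parameters and is deterministic", {
  skels <- lapply(1:3, function(i)
    gen_rgc_skeleton(rgc_gen_params(seed = i, field_diameter = 200,
                                    total_dendrite_length = 800)))
  truth <- dog_params(22, 100, 1.8)
  curves <- gen_response_curves(skels, truth, noise_sd = 0, seed = 4)
  fit <- fit_dog(skels, curves, seed = 4)
  expect_lt(abs(fit$par$sigma_s / 100 - 1), 0.05)
  expect_lt(abs(fit$par$csr / 1.8 - 1), 0.05)
  fit2 <- fit_dog(skels, curves, seed = 4)
  expect_identical(coef(fit), coef(fit2))

  # boundary case: no surround dominance beyond equality, csr pinned at 1
  curves1 <- gen_response_curves(skels, dog_params(22, 100, 1.0001),
                                 noise_sd = 0, seed = 4)
  fit1 <- fit_dog(skels, curves1, seed = 4)
  expect_lt(fit1$par$csr, 1.05)
})

test_that("cross-validation is self-consistent when one field truly generates all cells", {
  skels <- lapply(1:4, function(i)
    gen_rgc_skeleton(rgc_gen_params(seed = 10 + i, field_diameter = 200,
                                    total_dendrite_length = 800)))
  truth <- dog_params(22, 100, 1.8)
  curves <- gen_response_curves(skels, truth, noise_sd = 0, seed = 6)
  cv <- cross_validate(skels, curves, fit_size = 2, n_combinations = 3,
                       seed = 9)
  held <- cv$per_cell[cv$per_cell$n_heldout > 0, ]
  expect_true(nrow(held) >= 2)
  expect_lt(max(abs(held$mean_suppression_error)), 0.03)
  expect_equal(cv$n_combinations, 3)
})
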