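test_that("suppression statistic follows its definition", {
  d <- default_diameters()
  flat <- spot_response_curve("flat", d, rep(0.7, 12))
  expect_equal(suppression(flat)$suppression, 0)

  strong <- spot_response_curve("strong", d[1:4], c(0.2, 1, 0.5, 0),
                                normalize = FALSE)
  expect_equal(suppression(strong)$suppression, 1)

  ex <- spot_response_curve("ex", d[1:4], c(0.2, 1.0, 0.6, 0.11),
                            normalize = FALSE)
  s <- suppression(ex)
  expect_equal(s$suppression, 0.89)
  expect_equal(s$r_preferred, 1.0)
  expect_equal(s$preferred_diameter, d[2])

  # scale invariance
  ex5 <- spot_response_curve("ex5", d[1:4], 5 * c(0.2, 1.0, 0.6, 0.11),
                             normalize = FALSE)
  expect_equal(suppression(ex5)$suppression, 0.89)

  # negative noise floored before the statistic
  neg <- spot_response_curve("neg", d[1:3], c(1, 0.5, -0.1),
                             normalize = FALSE)
  expect_message(sn <- suppression(neg), "floored")
  expect_equal(sn$suppression, 1)

  # preferred-size ties resolve to the smallest diameter
  tie <- spot_response_curve("tie", d[1:4], c(1, 1, 0.5, 0.4),
                             normalize = FALSE)
  expect_equal(suppression(tie)$preferred_diameter, d[1])

  bad <- spot_response_curve("bad", d[1:2], c(-1, -2), normalize = FALSE)
  expect_error(suppressMessages(suppression(bad)), "undefined")
})

test_that("suppression is monotone in the full-field response", {
  d <- default_diameters()
  sups <- vapply(seq(0, 1, by = 0.25), function(ff)
    suppression(spot_response_curve("x", d[1:3], c(0.5, 1, ff),
                                    normalize = FALSE))$suppression,
    numeric(1))
  expect_true(all(diff(sups) < 0))
})

test_that("default spot series is 12 log-spaced diameters from 30 to 1200", {
  d <- default_diameters()
  expect_length(d, 12)
  expect_equal(d[1], 30)
  expect_equal(d[12], 1200)
  ratios <- d[-1] / d[-12]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-12)
  expect_equal(d[2], 30 * 40^(1 / 11), tolerance = 1e-12)
  expect_equal(d[2], 41.95, tolerance = 1e-3)
})

test_that("response curves round-trip through CSV", {
  d <- default_diameters()
  curves <- list(spot_response_curve("a", d, runif(12, 0.1, 1)),
                 spot_response_curve("b", d, runif(12, 0.1, 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_response_curves(curves, path)
  back <- read_response_curves(path)
  expect_equal(back[["a"]]$responses, curves[[1]]$responses,
               tolerance = 1e-12)
  expect_equal(back[["b"]]$diameters, d)
})
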