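test_that("SWC round-trip preserves the node table exactly", {
  m <- random_tree(25, seed = 4)
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- read_swc(path)
  expect_equal(m2$nodes, m$nodes, tolerance = 0)
})

test_that("SWC reader validates structure", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 3 -1", "2 2 0 0 -10 1 1", "3 2 0 0 -20 1 2"), path)
  m <- read_swc(path)
  expect_equal(nrow(m$nodes), 3)
  expect_equal(sum(is.na(m$nodes$parent)), 1)
  expect_equal(m$nodes$label, c("soma", "axon", "axon"))

  writeLines(c("1 1 0 0 0 3 -1", "5 2 0 0 -10 1 99"), path)
  expect_error(read_swc(path), "parent")
  writeLines(c("1 1 0 0 0 3 -1", "2 7 0 0 -10 1 1"), path)
  expect_error(read_swc(path), "structure code")
  writeLines(c("1 1 0 0 0 0 -1"), path)
  expect_error(read_swc(path), "radii")
  # two-node cycle
  expect_error(tree_morphology(data.frame(
    id = 1:3, parent = c(NA, 3, 2), x = 0, y = 0, z = 0, radius = 1,
    label = "axon")), "cycle|root|parent")
})

test_that("path distance equals graph shortest path and is a metric", {
  m <- chain_tree(11, spacing = 10)
  expect_equal(path_distance(m, 1, 3), 20)
  expect_equal(path_distance(m, 5, 5), 0)
  expect_error(path_distance(m, 1, 99), "unknown node")

  skip_if_not_installed("igraph")
  m <- random_tree(40, seed = 7)
  edges <- m$nodes[!is.na(m$nodes$parent), ]
  pos <- match(edges$parent, m$nodes$id)
  w <- sqrt((edges$x - m$nodes$x[pos])^2 + (edges$y - m$nodes$y[pos])^2 +
            (edges$z - m$nodes$z[pos])^2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$parent, to = edges$id), directed = FALSE,
    vertices = data.frame(name = m$nodes$id))
  D <- igraph::distances(g, weights = w)
  ids <- as.integer(rownames(D))
  for (a in c(1L, 13L, 40L)) {
    d_pkg <- path_distances(m, a, ids)
    expect_equal(unname(d_pkg), unname(D[as.character(a), ]),
                 tolerance = 1e-12)
  }

  # metric axioms, exhaustive on a small tree
  ms <- random_tree(12, seed = 9)
  ids <- ms$nodes$id
  D <- sapply(ids, function(a) path_distances(ms, a, ids))
  expect_true(all(D >= 0))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in seq_along(ids)) for (j in seq_along(ids))
    expect_true(all(D[i, j] <= D[i, ] + D[, j] + 1e-9))
})

test_that("CI ribbon filter matches direct bound application and is monotone", {
  m <- chain_tree(81, spacing = 2)  # nodes at 0..160 um from node 1
  set.seed(11)
  ref <- rnorm(40, mean = 50, sd = 10)
  rib_nodes <- seq(1, 81, by = 2)
  ribbons <- synapse_sites(seq_along(rib_nodes), rib_nodes,
                           rep("ribbon", length(rib_nodes)), m)
  kept <- select_ribbons_by_ci(m, ribbons, 1, ref, level = 0.99)
  d <- path_distances(m, 1, ribbons$node_id)
  z <- qnorm(0.995)
  manual <- ribbons[d >= mean(ref) - z * sd(ref) &
                    d <= mean(ref) + z * sd(ref), ]
  expect_equal(kept$site_id, manual$site_id)
  expect_true(nrow(kept) > 0 && nrow(kept) < nrow(ribbons))

  # idempotent: filtering the retained set again changes nothing
  again <- select_ribbons_by_ci(m, kept, 1, ref, level = 0.99)
  expect_equal(again$site_id, kept$site_id)
  # monotone in level: higher level keeps a superset
  lo <- select_ribbons_by_ci(m, ribbons, 1, ref, level = 0.8)
  expect_true(all(lo$site_id %in% kept$site_id))
  # reference distances equal to the ribbon distances: all retained
  all_in <- select_ribbons_by_ci(m, ribbons, 1, d, level = 0.99)
  expect_equal(nrow(all_in), nrow(ribbons))
  expect_error(select_ribbons_by_ci(m, ribbons, 1, numeric(0)), "nonempty")
})

test_that("n-nearest inhibitory sets match a brute-force sort and nest", {
  m <- random_tree(35, seed = 5)
  inh_nodes <- sample(m$nodes$id, 15)
  inh <- synapse_sites(101:115, inh_nodes, rep("inhibitory", 15), m)
  anchor <- inh$site_id[4]

  expect_equal(n_nearest_inhibitory(m, anchor, inh, 1)$site_id, anchor)
  expect_setequal(n_nearest_inhibitory(m, anchor, inh, 15)$site_id,
                  inh$site_id)
  expect_error(n_nearest_inhibitory(m, anchor, inh, 0), "at least 1")
  expect_error(n_nearest_inhibitory(m, anchor, inh, 16), "exceeds")

  d <- path_distances(m, inh$node_id[4], inh$node_id)
  ord <- order(ifelse(inh$site_id == anchor, -Inf, d), inh$site_id)
  for (n in c(3, 5, 9)) {
    got <- n_nearest_inhibitory(m, anchor, inh, n)$site_id
    expect_setequal(got, inh$site_id[ord[seq_len(n)]])
  }
  # nesting: the n-set is contained in the (n+1)-set
  for (n in 1:14) {
    expect_true(all(n_nearest_inhibitory(m, anchor, inh, n)$site_id %in%
                    n_nearest_inhibitory(m, anchor, inh, n + 1)$site_id))
  }
})

test_that("synapse site tables validate and round-trip through CSV", {
  m <- chain_tree(5)
  s <- synapse_sites(1:3, c(1, 3, 5), c("ribbon", "inhibitory",
                                        "excitatory"), m)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sites(s, path)
  s2 <- read_sites(path, m)
  expect_equal(as.data.frame(s2), as.data.frame(s))
  expect_error(synapse_sites(c(1, 1), c(1, 2), c("ribbon", "ribbon")),
               "unique")
  expect_error(synapse_sites(1, 1, "weird"), "kind")
  expect_error(synapse_sites(1, 99, "ribbon", m), "unknown node")
})
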