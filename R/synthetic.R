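#' Parameters for the synthetic bipolar cell generator
#'
#' Defaults emulate the scale of a T6 bipolar cell: 84 ribbon output
#' synapses and 120 inhibitory input synapses on a compact axonal arbor,
#' plus 8 excitatory synapses on a small dendritic tuft. Counts are the
#' modelled cell's synapse complement; geometry values are scale-matched to
#' a small cone bipolar (arbor a few tens of micrometres across, sub-micron
#' neurites), not fitted to any particular reconstruction.
#'
#' @param seed integer RNG seed.
#' @param n_ribbons,n_inhibitory,n_excitatory site counts (>= 1).
#' @param arbor_radius radius of the axonal arbor in the plane, um.
#' @param soma_radius soma radius, um.
#' @param axon_stalk_length length of the descending axon stalk, um.
#' @param branch_order bifurcation depth of the axonal arbor.
#' @param branch_length_mean mean axonal branch length, um.
#' @param neurite_radius radius of axonal/dendritic neurites, um.
#' @param node_spacing spacing of skeleton sample points along neurites, um.
#' @return A parameter list of class `bc_gen_params`.
#' @export
bc_gen_params <- function(seed = 1L, n_ribbons = 84L, n_inhibitory = 120L,
                          n_excitatory = 8L, arbor_radius = 20,
                          soma_radius = 3, axon_stalk_length = 30,
                          branch_order = 5L, branch_length_mean = 7,
                          neurite_radius = 0.15, node_spacing = 1.5) {
  p <- list(seed = as.integer(seed), n_ribbons = as.integer(n_ribbons),
            n_inhibitory = as.integer(n_inhibitory),
            n_excitatory = as.integer(n_excitatory),
            arbor_radius = arbor_radius, soma_radius = soma_radius,
            axon_stalk_length = axon_stalk_length,
            branch_order = as.integer(branch_order),
            branch_length_mean = branch_length_mean,
            neurite_radius = neurite_radius, node_spacing = node_spacing)
  if (any(unlist(p[c("n_ribbons", "n_inhibitory", "n_excitatory")]) < 1L))
    stop("site counts must be >= 1")
  if (any(unlist(p[c("arbor_radius", "soma_radius", "axon_stalk_length",
                     "branch_length_mean", "neurite_radius",
                     "node_spacing")]) <= 0))
    stop("geometry parameters must be positive")
  class(p) <- "bc_gen_params"
  p
}

# Append a straight run of nodes from `from_xyz` along `dir` of length `len`,
# sampled every `spacing` um. Returns updated node list and last node id.
.grow_run <- function(env, parent_id, from_xyz, dir, len, spacing, radius,
                      label, clamp_radius = NULL) {
  n_steps <- max(1L, ceiling(len / spacing))
  step <- len / n_steps
  xyz <- from_xyz
  for (k in seq_len(n_steps)) {
    nxt <- xyz + dir * step
    if (!is.null(clamp_radius)) {
      r <- sqrt(nxt[1]^2 + nxt[2]^2)
      if (r > clamp_radius) {
        # reflect the in-plane radial component so growth folds back
        # into the arbor disc instead of terminating at the boundary
        rr <- sqrt(xyz[1]^2 + xyz[2]^2)
        if (rr > 0) {
          nhat <- c(xyz[1] / rr, xyz[2] / rr, 0)
          dir <- dir - 2 * sum(dir * nhat) * nhat
        } else dir <- -dir
        nxt <- xyz + dir * step
        if (sqrt(nxt[1]^2 + nxt[2]^2) > clamp_radius) break
      }
    }
    env$id <- env$id + 1L
    env$rows[[length(env$rows) + 1L]] <-
      list(id = env$id, parent = parent_id, x = nxt[1], y = nxt[2],
           z = nxt[3], radius = radius, label = label)
    env$total_len <- (env$total_len %||% 0) + sqrt(sum((nxt - xyz)^2))
    parent_id <- env$id
    xyz <- nxt
  }
  list(last_id = parent_id, last_xyz = xyz)
}

#' Generate a synthetic bipolar cell morphology with synapse sites
#'
#' Builds a soma, a dendritic tuft carrying the excitatory input sites, a
#' descending axon stalk, and a planar branched axonal arbor carrying the
#' ribbon output and inhibitory input sites. Ribbon and inhibitory sites are
#' placed uniformly per unit length of the axonal arbor; excitatory sites
#' uniformly on the dendritic tuft. Fully reproducible under the seed.
#'
#' @param p a [bc_gen_params()] list.
#' @return A list with elements `morphology` ([tree_morphology()]) and
#'   `sites` ([synapse_sites()]).
#' @export
gen_bc_morphology <- function(p = bc_gen_params()) {
  stopifnot(inherits(p, "bc_gen_params"))
  with_seed(p$seed, {
    env <- new.env()
    env$id <- 1L
    env$rows <- list(list(id = 1L, parent = NA_integer_, x = 0, y = 0, z = 0,
                          radius = p$soma_radius, label = "soma"))
    # dendritic tuft: 4 short ascending branches
    dend_ids <- integer(0)
    for (b in seq_len(4)) {
      ang <- 2 * pi * (b - 1) / 4 + stats::runif(1, -0.3, 0.3)
      dir <- c(0.35 * cos(ang), 0.35 * sin(ang), 1)
      dir <- dir / sqrt(sum(dir^2))
      start_len <- length(env$rows)
      .grow_run(env, 1L, c(0, 0, p$soma_radius), dir,
                len = stats::runif(1, 8, 12), spacing = p$node_spacing,
                radius = p$neurite_radius, label = "dendrite")
      dend_ids <- c(dend_ids,
                    vapply(env$rows[(start_len + 1):length(env$rows)],
                           `[[`, integer(1), "id"))
    }
    # axon stalk straight down
    stalk <- .grow_run(env, 1L, c(0, 0, -p$soma_radius), c(0, 0, -1),
                       len = p$axon_stalk_length, spacing = 2,
                       radius = p$neurite_radius, label = "axon")
    z_arbor <- stalk$last_xyz[3]
    # planar axonal arbor: recursive bifurcation from the stalk tip
    arbor_first <- length(env$rows) + 1L
    queue <- list()
    for (ang0 in c(0, pi)) {
      queue[[length(queue) + 1L]] <-
        list(parent = stalk$last_id, xyz = stalk$last_xyz,
             ang = ang0 + stats::runif(1, -0.4, 0.4), order = 1L)
    }
    while (length(queue) > 0L) {
      br <- queue[[1L]]; queue[[1L]] <- NULL
      len <- min(max(stats::rexp(1, 1 / p$branch_length_mean), 2),
                 3 * p$branch_length_mean)
      dir <- c(cos(br$ang), sin(br$ang), 0)
      res <- .grow_run(env, br$parent, br$xyz, dir, len,
                       spacing = p$node_spacing, radius = p$neurite_radius,
                       label = "axon", clamp_radius = p$arbor_radius)
      if (br$order < p$branch_order && res$last_id != br$parent) {
        for (turn in c(-1, 1) * stats::runif(2, 0.3, 1.1)) {
          queue[[length(queue) + 1L]] <-
            list(parent = res$last_id, xyz = res$last_xyz,
                 ang = br$ang + turn, order = br$order + 1L)
        }
      }
    }
    nodes <- do.call(rbind, lapply(env$rows, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
    m <- tree_morphology(nodes)

    arbor_nodes <- nodes$id[nodes$label == "axon" & nodes$z <= z_arbor + 1e-9]
    if (length(arbor_nodes) < p$n_ribbons + p$n_inhibitory)
      stop("requested synapse sites exceed available axonal arbor nodes; ",
           "increase branch_order or branch_length_mean")
    if (length(dend_ids) < 1L) stop("no dendritic nodes generated")

    # uniform-per-length placement: nodes are equally spaced along branches,
    # so sampling nodes uniformly approximates uniform-per-length placement
    rib_nodes <- sample(arbor_nodes, p$n_ribbons, replace = FALSE)
    inh_nodes <- sample(arbor_nodes, p$n_inhibitory, replace = FALSE)
    exc_nodes <- sample(dend_ids, p$n_excitatory,
                        replace = p$n_excitatory > length(dend_ids))
    sites <- synapse_sites(
      site_id = seq_len(p$n_ribbons + p$n_inhibitory + p$n_excitatory),
      node_id = c(rib_nodes, inh_nodes, exc_nodes),
      kind = rep(c("ribbon", "inhibitory", "excitatory"),
                 c(p$n_ribbons, p$n_inhibitory, p$n_excitatory)),
      m = m)
    list(morphology = m, sites = sites,
         stalk_tip = nodes$id[stalk$last_id])
  })
}

#' Parameters for the synthetic ganglion cell skeleton generator
#'
#' Stands in for traced dendritic skeletons of ON-sustained ganglion cells.
#' Defaults give an arbor of roughly 300 um field diameter with 3000 um of
#' dendrite, generated in a plane (the target stratum is thin relative to
#' the arbor diameter).
#'
#' @param seed integer RNG seed.
#' @param field_diameter convex-hull diameter of the arbor, um.
#' @param total_dendrite_length summed dendritic length, um.
#' @param branch_length_mean mean side-branch length, um.
#' @return A parameter list of class `rgc_gen_params`.
#' @export
rgc_gen_params <- function(seed = 1L, field_diameter = 300,
                           total_dendrite_length = 3000,
                           branch_length_mean = 40) {
  if (field_diameter <= 0 || total_dendrite_length <= 0)
    stop("field_diameter and total_dendrite_length must be positive")
  if (total_dendrite_length < field_diameter)
    stop("infeasible: total dendrite length smaller than field diameter")
  structure(list(seed = as.integer(seed), field_diameter = field_diameter,
                 total_dendrite_length = total_dendrite_length,
                 branch_length_mean = branch_length_mean),
            class = "rgc_gen_params")
}

#' Generate a synthetic planar ganglion cell dendritic skeleton
#'
#' Radial primary dendrites grow from the soma to the field boundary
#' (setting the convex-hull diameter); additional side branches are grown
#' from random existing nodes until the total dendrite length reaches its
#' target. Hull diameter and total length land within 10% of the requested
#' values; output is reproducible under the seed.
#'
#' @param p an [rgc_gen_params()] list.
#' @return A [tree_morphology()] (all nodes labelled `dendrite` except the
#'   soma root).
#' @export
gen_rgc_skeleton <- function(p = rgc_gen_params()) {
  stopifnot(inherits(p, "rgc_gen_params"))
  with_seed(p$seed, {
    R <- p$field_diameter / 2
    spacing <- 8
    env <- new.env(); env$id <- 1L
    env$rows <- list(list(id = 1L, parent = NA_integer_, x = 0, y = 0, z = 0,
                          radius = 6, label = "soma"))
    n_primary <- 5L
    tips <- list()
    for (b in seq_len(n_primary)) {
      ang <- 2 * pi * (b - 1) / n_primary + stats::runif(1, -0.25, 0.25)
      parent <- 1L; xyz <- c(0, 0, 0); a <- ang
      repeat {                               # wiggly radial growth to R
        seg <- min(spacing * 3, R - sqrt(xyz[1]^2 + xyz[2]^2))
        if (seg < spacing / 2) break
        dir <- c(cos(a), sin(a), 0)
        res <- .grow_run(env, parent, xyz, dir, seg, spacing, 0.5,
                         "dendrite", clamp_radius = R * 1.0001)
        if (res$last_id == parent) break
        parent <- res$last_id; xyz <- res$last_xyz
        a <- ang + stats::runif(1, -0.35, 0.35)  # stay roughly radial
      }
      tips[[b]] <- list(id = parent, xyz = xyz)
    }
    len_now <- function() env$total_len %||% 0
    target <- p$total_dendrite_length
    guard <- 0L
    while (len_now() < 0.98 * target && guard < 4000L) {
      guard <- guard + 1L
      k <- sample(length(env$rows), 1L)
      node <- env$rows[[k]]
      if (node$label == "soma") next
      r0 <- sqrt(node$x^2 + node$y^2)
      base_ang <- atan2(node$y, node$x)
      a <- base_ang + stats::runif(1, -1.3, 1.3)
      len <- min(max(stats::rexp(1, 1 / p$branch_length_mean), spacing),
                 target - len_now() + spacing)
      .grow_run(env, node$id, c(node$x, node$y, node$z),
                c(cos(a), sin(a), 0), len, spacing, 0.5, "dendrite",
                clamp_radius = R * 1.0001)
    }
    nodes <- do.call(rbind, lapply(env$rows, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
    tree_morphology(nodes)
  })
}

#' Generate spot-size response curves from a known subunit receptive field
#'
#' For each skeleton, places bipolar subunits along the dendrites, computes
#' the forward model prediction of the response across spot diameters, adds
#' i.i.d. Gaussian noise on the normalized scale, and re-normalizes to a
#' maximum of 1. The generating ("ground-truth") receptive-field parameters
#' are attached to each curve for parameter-recovery testing.
#'
#' @param skeletons list of [tree_morphology()] objects.
#' @param dog a [dog_params()] receptive field.
#' @param diameters spot diameters, um, ascending (default
#'   [default_diameters()]).
#' @param noise_sd Gaussian noise s.d. on the normalized response scale.
#' @param seed integer RNG seed.
#' @param density dendritic length per subunit, um (default 0.3).
#' @return A list of `spot_response_curve` objects.
#' @export
gen_response_curves <- function(skeletons, dog,
                                diameters = default_diameters(),
                                noise_sd = 0, seed = 1L, density = 0.3) {
  if (is.unsorted(diameters, strictly = TRUE) || any(diameters <= 0))
    stop("diameters must be positive and ascending")
  out <- vector("list", length(skeletons))
  for (i in seq_along(skeletons)) {
    layout <- place_subunits(skeletons[[i]], density = density,
                             seed = derive_seed(seed, "layout", i))
    curve <- predict_response(layout, dog, diameters)
    resp <- curve$responses
    if (noise_sd > 0) {
      resp <- with_seed(derive_seed(seed, "noise", i),
                        resp + stats::rnorm(length(resp), 0, noise_sd))
      resp <- resp / max(resp)
    }
    sc <- spot_response_curve(cell_id = paste0("cell", i),
                              diameters = diameters, responses = resp)
    attr(sc, "truth") <- dog
    attr(sc, "layout_seed") <- derive_seed(seed, "layout", i)
    out[[i]] <- sc
  }
  out
}
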