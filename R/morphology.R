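#' Create a tree morphology
#'
#' A `tree_morphology` is a rooted tree of 3D points with radii, the common
#' substrate for cable simulation and path-distance analysis of neuronal
#' skeletons (bipolar cell axonal arbors, ganglion cell dendritic arbors).
#'
#' @param nodes data frame with columns `id` (integer, unique), `parent`
#'   (integer id of the parent node, `NA` for the single root), `x`, `y`, `z`
#'   (positions, micrometres), `radius` (micrometres, > 0) and `label`
#'   (one of `"soma"`, `"dendrite"`, `"axon"`).
#' @return An object of class `tree_morphology` wrapping the validated node
#'   table together with a precomputed root-path index used by
#'   [path_distance()].
#' @seealso [read_swc()], [write_swc()], [path_distance()]
#' @export
tree_morphology <- function(nodes) {
  required <- c("id", "parent", "x", "y", "z", "radius", "label")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes)))
    stop("`nodes` must be a data frame with columns ",
         paste(required, collapse = ", "))
  nodes <- as.data.frame(nodes)[, required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  m <- structure(list(nodes = nodes), class = "tree_morphology")
  validate_tree_morphology(m)
  m$index <- .tree_index(nodes)
  m
}

#' @rdname tree_morphology
#' @param m object to validate.
#' @export
validate_tree_morphology <- function(m) {
  nodes <- m$nodes
  if (anyDuplicated(nodes$id))
    stop("node ids must be unique")
  if (any(!is.finite(nodes$radius)) || any(nodes$radius <= 0))
    stop("all radii must be positive")
  if (!all(nodes$label %in% c("soma", "dendrite", "axon")))
    stop("labels must be one of soma, dendrite, axon")
  root <- which(is.na(nodes$parent))
  if (length(root) != 1L)
    stop("tree must have exactly one root (parent = NA), found ", length(root))
  known <- c(NA_integer_, nodes$id)
  bad <- !(nodes$parent %in% known)
  if (any(bad))
    stop("parent id(s) not present in tree: ",
         paste(unique(nodes$parent[bad]), collapse = ", "))
  # connectivity / acyclicity: every node must reach the root
  pos <- match(nodes$parent, nodes$id)          # NA at root
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    seen <- 0L
    j <- i
    while (!is.na(pos[j])) {
      j <- pos[j]
      seen <- seen + 1L
      if (seen > n) stop("cycle detected in tree at node id ", nodes$id[i])
    }
  }
  invisible(m)
}

# Root-path index: parent positions, edge lengths, cumulative distance to
# root and depth, enabling O(depth) lowest-common-ancestor path distances.
.tree_index <- function(nodes) {
  pos <- match(nodes$parent, nodes$id)
  dx <- nodes$x - nodes$x[pos]
  dy <- nodes$y - nodes$y[pos]
  dz <- nodes$z - nodes$z[pos]
  elen <- sqrt(dx^2 + dy^2 + dz^2)
  elen[is.na(pos)] <- 0
  n <- nrow(nodes)
  depth <- integer(n)
  dist_root <- numeric(n)
  # process in an order where parents come first
  order_seq <- integer(n)
  filled <- is.na(pos)
  order_seq[seq_len(sum(filled))] <- which(filled)
  k <- sum(filled)
  while (k < n) {
    nxt <- which(!filled & filled[pos])
    order_seq[k + seq_along(nxt)] <- nxt
    filled[nxt] <- TRUE
    k <- k + length(nxt)
  }
  for (i in order_seq) {
    if (!is.na(pos[i])) {
      depth[i] <- depth[pos[i]] + 1L
      dist_root[i] <- dist_root[pos[i]] + elen[i]
    }
  }
  list(pos = pos, edge_len = elen, depth = depth, dist_root = dist_root)
}

.node_pos <- function(m, ids) {
  p <- match(as.integer(ids), m$nodes$id)
  if (anyNA(p))
    stop("unknown node id(s): ",
         paste(ids[is.na(p)], collapse = ", "))
  p
}

#' @export
print.tree_morphology <- function(x, ...) {
  n <- nrow(x$nodes)
  tab <- table(x$nodes$label)
  cat("tree_morphology:", n, "nodes,",
      sum(!is.na(x$nodes$parent)), "edges\n")
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  total cable length: %.1f um\n", total_length(x)))
  invisible(x)
}

#' @export
summary.tree_morphology <- function(object, ...) {
  idx <- object$index %||% .tree_index(object$nodes)
  out <- list(
    n_nodes = nrow(object$nodes),
    total_length_um = total_length(object),
    max_depth_um = max(idx$dist_root),
    n_tips = sum(!(seq_len(nrow(object$nodes)) %in% idx$pos)),
    labels = table(object$nodes$label)
  )
  class(out) <- "summary.tree_morphology"
  out
}

#' @export
print.summary.tree_morphology <- function(x, ...) {
  cat("tree morphology summary\n")
  cat("  nodes:        ", x$n_nodes, "\n")
  cat("  tips:         ", x$n_tips, "\n")
  cat(sprintf("  cable length:  %.1f um\n", x$total_length_um))
  cat(sprintf("  max root path: %.1f um\n", x$max_depth_um))
  invisible(x)
}

#' @export
plot.tree_morphology <- function(x, sites = NULL, ...) {
  nodes <- x$nodes
  pos <- match(nodes$parent, nodes$id)
  has_parent <- !is.na(pos)
  graphics::plot(nodes$x, nodes$y, type = "n", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  graphics::segments(nodes$x[has_parent], nodes$y[has_parent],
                     nodes$x[pos[has_parent]], nodes$y[pos[has_parent]],
                     col = "grey30")
  if (!is.null(sites)) {
    cols <- c(ribbon = "blue", inhibitory = "red", excitatory = "darkgreen")
    p <- .node_pos(x, sites$node_id)
    graphics::points(nodes$x[p], nodes$y[p], col = cols[sites$kind], pch = 16,
                     cex = 0.6)
  }
  invisible(x)
}

#' Total cable length of a morphology
#'
#' @param m a [tree_morphology()].
#' @return Summed 3D length of all edges, micrometres.
#' @export
total_length <- function(m) {
  idx <- m$index %||% .tree_index(m$nodes)
  sum(idx$edge_len)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# SWC structure codes <-> labels. Code 1 = soma, 2 = axon, 3 = dendrite
# (basal); other codes are rejected rather than guessed at.
.swc_code_to_label <- c(`1` = "soma", `2` = "axon", `3` = "dendrite")
.swc_label_to_code <- c(soma = 1L, axon = 2L, dendrite = 3L)

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (id, structure code, x, y, z, radius, parent;
#' coordinates and radii in micrometres; parent -1 for the root). Structure
#' codes 1 (soma), 2 (axon) and 3 (dendrite) are accepted.
#'
#' @param path file path.
#' @return A [tree_morphology()].
#' @export
read_swc <- function(path) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "code", "x", "y", "z",
                                         "radius", "parent"))
  if (ncol(raw) != 7L) stop("SWC file must have 7 columns")
  code <- as.character(raw$code)
  unknown <- !(code %in% names(.swc_code_to_label))
  if (any(unknown))
    stop("unknown SWC structure code(s): ",
         paste(unique(raw$code[unknown]), collapse = ", "))
  nodes <- data.frame(
    id = as.integer(raw$id),
    parent = ifelse(raw$parent < 0, NA_integer_, as.integer(raw$parent)),
    x = raw$x, y = raw$y, z = raw$z,
    radius = raw$radius,
    label = unname(.swc_code_to_label[code]),
    stringsAsFactors = FALSE
  )
  tree_morphology(nodes)
}

#' Write a morphology to an SWC file
#'
#' @param m a [tree_morphology()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  nodes <- m$nodes
  out <- data.frame(
    id = nodes$id,
    code = unname(.swc_label_to_code[nodes$label]),
    x = nodes$x, y = nodes$y, z = nodes$z,
    radius = nodes$radius,
    parent = ifelse(is.na(nodes$parent), -1L, nodes$parent)
  )
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d", out$id, out$code,
                   out$x, out$y, out$z, out$radius, out$parent)
  writeLines(c("# id type x y z radius parent", lines), path)
  invisible(path)
}

#' Path distance between nodes of a tree
#'
#' Sum of 3D segment lengths along the unique tree path between two nodes.
#' This is the metric used throughout for synapse neighbourhoods ("N-nearest
#' by path distance") and the ribbon-selection filter.
#'
#' @param m a [tree_morphology()].
#' @param a,b node ids.
#' @return Distance in micrometres. `path_distance(m, a, a)` is 0.
#' @export
path_distance <- function(m, a, b) {
  path_distances(m, a, b)[1L]
}

#' @rdname path_distance
#' @param from single node id.
#' @param to vector of node ids.
#' @export
path_distances <- function(m, from, to) {
  idx <- m$index %||% .tree_index(m$nodes)
  i <- .node_pos(m, from)
  js <- .node_pos(m, to)
  vapply(js, function(j) {
    # climb to the lowest common ancestor
    a <- i; b <- j
    while (a != b) {
      if (idx$depth[a] >= idx$depth[b]) a <- idx$pos[a] else b <- idx$pos[b]
    }
    idx$dist_root[i] + idx$dist_root[j] - 2 * idx$dist_root[a]
  }, numeric(1))
}

#' Create a synapse-site table
#'
#' Synapse sites are labelled node references on a morphology: `ribbon`
#' output synapses, `inhibitory` inputs on the axonal arbor, or `excitatory`
#' inputs on the dendrites.
#'
#' @param site_id integer site identifiers (unique).
#' @param node_id node ids on the host morphology.
#' @param kind character, each one of `"ribbon"`, `"inhibitory"`,
#'   `"excitatory"`.
#' @param m optional [tree_morphology()]; when given, node references are
#'   checked against it.
#' @return A `data.frame` of class `synapse_sites`.
#' @export
synapse_sites <- function(site_id, node_id, kind, m = NULL) {
  s <- data.frame(site_id = as.integer(site_id),
                  node_id = as.integer(node_id),
                  kind = as.character(kind),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(s$site_id)) stop("site_id values must be unique")
  if (!all(s$kind %in% c("ribbon", "inhibitory", "excitatory")))
    stop("kind must be ribbon, inhibitory or excitatory")
  if (!is.null(m)) .node_pos(m, s$node_id)
  class(s) <- c("synapse_sites", "data.frame")
  s
}

#' Read / write synapse-site tables (CSV: site_id,node_id,kind)
#' @param path file path.
#' @inheritParams synapse_sites
#' @export
read_sites <- function(path, m = NULL) {
  d <- utils::read.csv(path)
  synapse_sites(d$site_id, d$node_id, d$kind, m = m)
}

#' @rdname read_sites
#' @param sites a `synapse_sites` table.
#' @export
write_sites <- function(sites, path) {
  utils::write.csv(as.data.frame(sites)[, c("site_id", "node_id", "kind")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Restrict ribbons to a confidence interval of reference path distances
#'
#' Keeps ribbon sites whose path distance from a branch point falls within
#' the normal-theory confidence interval (mean +/- z * sd) of a set of
#' reference distances, at the requested level. This reproduces the filter
#' that restricts analysis to ribbon synapses plausibly contacting the
#' recorded ganglion cell types.
#'
#' @param m a [tree_morphology()].
#' @param ribbons `synapse_sites` table of ribbon sites.
#' @param branch_point node id of the reference branch point.
#' @param reference_distances numeric vector of reference path distances (um).
#' @param level confidence level in (0, 1); default 0.99.
#' @return The retained subset of `ribbons` (same class), with the computed
#'   distances in attribute `"distance"` and the interval in attribute
#'   `"interval"`.
#' @export
select_ribbons_by_ci <- function(m, ribbons, branch_point,
                                 reference_distances, level = 0.99) {
  if (length(reference_distances) == 0L)
    stop("reference_distances must be nonempty")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  mu <- mean(reference_distances)
  sdev <- stats::sd(reference_distances)
  if (is.na(sdev)) sdev <- 0
  lo <- mu - z * sdev
  hi <- mu + z * sdev
  d <- path_distances(m, branch_point, ribbons$node_id)
  keep <- d >= lo & d <= hi
  out <- ribbons[keep, , drop = FALSE]
  attr(out, "distance") <- d[keep]
  attr(out, "interval") <- c(lower = lo, upper = hi)
  out
}

#' N-nearest inhibitory synapses around an anchor
#'
#' Returns the anchor plus its `n - 1` nearest other inhibitory sites by
#' path distance (the anchor counts as one of the `n`). Ties are broken by
#' ascending `site_id` so results are deterministic.
#'
#' @param m a [tree_morphology()].
#' @param anchor site_id of the anchor inhibitory synapse (must appear in
#'   `inhibitory`).
#' @param inhibitory `synapse_sites` table of inhibitory sites.
#' @param n number of sites to return, `1 <= n <= nrow(inhibitory)`.
#' @return Subset of `inhibitory` of size `n`, anchor included.
#' @export
n_nearest_inhibitory <- function(m, anchor, inhibitory, n) {
  if (n < 1L) stop("n must be at least 1")
  if (n > nrow(inhibitory))
    stop("n exceeds the number of inhibitory sites")
  ai <- match(anchor, inhibitory$site_id)
  if (is.na(ai)) stop("anchor site_id not found among inhibitory sites")
  d <- path_distances(m, inhibitory$node_id[ai], inhibitory$node_id)
  d[ai] <- -Inf                      # anchor always first
  ord <- order(d, inhibitory$site_id)
  inhibitory[sort(ord[seq_len(n)]), , drop = FALSE]
}
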