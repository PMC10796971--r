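#' Difference-of-Gaussians subunit receptive field parameters
#'
#' A circular difference of Gaussians with three parameters: center size
#' `sigma_c`, surround size `sigma_s`, and center-to-surround ratio `csr`.
#' The normalization convention is volume-based: the center Gaussian has
#' unit volume and the surround Gaussian volume `1/csr`, i.e.
#' `DoG(r) = G(r; sigma_c) - (1/csr) * G(r; sigma_s)` with each `G` a
#' unit-volume 2D Gaussian. Under this convention the full-field activation
#' of a subunit is `1 - 1/csr`, so `csr = 1` means complete full-field
#' cancellation, matching the center/surround amplitude-ratio semantics of
#' the cable model.
#'
#' @param sigma_c center s.d., um (fixed at 22 um in all fitting).
#' @param sigma_s surround s.d., um; must exceed `sigma_c`.
#' @param csr center-to-surround volume ratio, >= 1.
#' @return An object of class `dog_params`.
#' @export
dog_params <- function(sigma_c = 22, sigma_s, csr) {
  if (!(sigma_c > 0) || !(sigma_s > sigma_c))
    stop("must have sigma_s > sigma_c > 0")
  if (csr < 1) stop("csr must be >= 1")
  structure(list(sigma_c = sigma_c, sigma_s = sigma_s, csr = csr),
            class = "dog_params")
}

#' @export
print.dog_params <- function(x, ...) {
  cat(sprintf("dog_params: sigma_c %.1f um, sigma_s %.1f um, CSR %.3f\n",
              x$sigma_c, x$sigma_s, x$csr))
  invisible(x)
}

# ---- quadrature -----------------------------------------------------------

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch; cached.
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1, ]^2
  ord <- order(nodes)
  res <- list(x = nodes[ord], w = weights[ord])
  .gl_cache[[key]] <- res
  res
}

# Mass of a unit-volume 2D Gaussian (s.d. sigma) centred at distance r0 from
# the origin, integrated over the disc of radius R centred at the origin:
#   P = int_0^R (r/sigma^2) exp(-(r-r0)^2/(2 sigma^2)) I0e(r*r0/sigma^2) dr
# with I0e the exponentially scaled modified Bessel function. Vectorized
# over r0; 64-point Gauss-Legendre restricted to the radial band where the
# integrand is non-negligible.
.disc_mass <- function(r0, R, sigma, n_nodes = 64L) {
  if (R <= 0) return(numeric(length(r0)))
  gl <- .gauss_legendre(n_nodes)
  lo <- pmax(0, r0 - 8.5 * sigma)
  hi <- pmin(R, r0 + 8.5 * sigma)
  width <- hi - lo
  out <- numeric(length(r0))
  live <- width > 0
  if (!any(live)) return(out)
  loL <- lo[live]; wL <- width[live]; r0L <- r0[live]
  # nodes matrix: length(live) x n_nodes
  r <- outer(wL / 2, gl$x) + (loL + wL / 2)
  z <- r * r0L / sigma^2
  f <- (r / sigma^2) * exp(-(r - r0L)^2 / (2 * sigma^2)) *
    besselI(z, 0, expon.scaled = TRUE)
  out[live] <- (f %*% gl$w) * wL / 2
  out
}

#' Activation of a DoG subunit by a centred spot
#'
#' Integral of the subunit's difference-of-Gaussians receptive field over a
#' disc of the given diameter whose centre lies `offset` um from the
#' subunit centre. With the volume normalization used here the activation
#' lies in `(-1/csr, 1]`; an infinitely large spot gives `1 - 1/csr`.
#'
#' @param dog a [dog_params()].
#' @param offset distance(s) from subunit centre to spot centre, um.
#' @param spot_diameter spot diameter, um (scalar, >= 0).
#' @return Numeric activation, vectorized over `offset`.
#' @export
bc_activation <- function(dog, offset, spot_diameter) {
  stopifnot(spot_diameter >= 0)
  R <- spot_diameter / 2
  .disc_mass(offset, R, dog$sigma_c) -
    .disc_mass(offset, R, dog$sigma_s) / dog$csr
}

# ---- subunit layout -------------------------------------------------------

#' Place bipolar subunits along a dendritic skeleton
#'
#' Subunit centres (one per excitatory synapse) are drawn uniformly per
#' unit length of dendrite at the given density and projected to the x-y
#' plane. The number of subunits is `round(total dendritic length /
#' density)`.
#'
#' @param skeleton a [tree_morphology()].
#' @param density dendritic length per synapse, um (default 0.3).
#' @param seed integer RNG seed.
#' @return An object of class `subunit_layout` with fields `centers`
#'   (n x 2 matrix, um), `centroid` (spot centre, the centroid of the
#'   skeleton nodes), `offsets` (distances centre-to-centroid), `density`
#'   and `n`.
#' @export
place_subunits <- function(skeleton, density = 0.3, seed = 1L) {
  if (density <= 0) stop("density must be positive")
  nodes <- skeleton$nodes
  pos <- match(nodes$parent, nodes$id)
  keep <- !is.na(pos) & nodes$label != "soma"
  x0 <- nodes$x[pos[keep]]; y0 <- nodes$y[pos[keep]]
  x1 <- nodes$x[keep]; y1 <- nodes$y[keep]
  z0 <- nodes$z[pos[keep]]; z1 <- nodes$z[keep]
  elen <- sqrt((x1 - x0)^2 + (y1 - y0)^2 + (z1 - z0)^2)
  L <- sum(elen)
  n <- round(L / density)
  centroid <- c(mean(nodes$x), mean(nodes$y))
  if (n == 0L || L == 0) {
    return(structure(list(centers = matrix(numeric(0), 0, 2),
                          centroid = centroid, offsets = numeric(0),
                          density = density, n = 0L),
                     class = "subunit_layout"))
  }
  cum <- cumsum(elen)
  centers <- with_seed(seed, {
    u <- stats::runif(n, 0, L)
    e <- findInterval(u, cum) + 1L
    frac <- (u - c(0, cum)[e]) / elen[e]
    cbind(x0[e] + frac * (x1[e] - x0[e]),
          y0[e] + frac * (y1[e] - y0[e]))
  })
  offsets <- sqrt((centers[, 1] - centroid[1])^2 +
                  (centers[, 2] - centroid[2])^2)
  structure(list(centers = centers, centroid = centroid, offsets = offsets,
                 density = density, n = n),
            class = "subunit_layout")
}

#' Predict a spot-size response curve from a subunit layout
#'
#' Models the ganglion cell's excitatory response as the linear sum of the
#' activations of all bipolar subunits for spots centred at the centroid of
#' the dendritic field, then normalizes the curve to a maximum of 1.
#' Negative summed activations are clipped at zero before normalization
#' (conductances cannot be negative).
#'
#' @param layout a subunit layout from [place_subunits()].
#' @param dog a [dog_params()].
#' @param diameters spot diameters, um.
#' @param spot_center optional spot centre (default: the layout centroid).
#' @return A [spot_response_curve()].
#' @export
predict_response <- function(layout, dog, diameters = default_diameters(),
                             spot_center = NULL) {
  if (layout$n == 0L) stop("layout is empty")
  offsets <- if (is.null(spot_center)) layout$offsets else
    sqrt((layout$centers[, 1] - spot_center[1])^2 +
         (layout$centers[, 2] - spot_center[2])^2)
  raw <- .mass_sums(offsets, diameters, dog$sigma_c) -
    .mass_sums(offsets, diameters, dog$sigma_s) / dog$csr
  raw <- pmax(raw, 0)
  if (all(raw <= 0)) stop("all-zero predicted curve: cannot normalize")
  spot_response_curve("predicted", diameters, raw, normalize = TRUE)
}

# Per-layout sums of disc masses: S[d] = sum_j P(offset_j; R_d, sigma).
# Offsets are binned (1 um) before quadrature: the disc mass varies on the
# scale of sigma (>= 22 um), so binning error is < 1e-4 relative while the
# cost becomes independent of the subunit count.
.bin_offsets <- function(offsets, bin = 1) {
  idx <- floor(offsets / bin)
  counts <- tabulate(idx + 1L)
  keep <- counts > 0L
  list(centers = (which(keep) - 0.5) * bin, w = as.numeric(counts[keep]))
}

# The disc mass is smooth in the offset on the scale of sigma (>= 22 um),
# so it is evaluated on a coarse offset grid and spline-interpolated to the
# bin centers.
.mass_sums_binned <- function(bo, diameters, sigma) {
  lo <- min(bo$centers); hi <- max(bo$centers)
  n_grid <- max(12L, min(64L, ceiling((hi - lo) / (sigma / 6)) + 1L))
  grid <- seq(max(0, lo - 1), hi + 1, length.out = n_grid)
  vapply(diameters, function(d) {
    Pg <- .disc_mass(grid, d / 2, sigma)
    sum(bo$w * stats::spline(grid, Pg, xout = bo$centers)$y)
  }, numeric(1))
}

.mass_sums <- function(offsets, diameters, sigma, bin = 1) {
  if (length(offsets) == 0L) return(numeric(length(diameters)))
  .mass_sums_binned(.bin_offsets(offsets, bin), diameters, sigma)
}

# ---- fitting --------------------------------------------------------------

#' Fit the DoG subunit model to measured spot-size response curves
#'
#' Finds the surround size `sigma_s` and center-to-surround ratio `csr`
#' minimizing the mean absolute error (MAE) between model-predicted and
#' measured normalized responses, pooled across all cells and spot sizes.
#' The center size `sigma_c` is held fixed (22 um by default) and the
#' optimizer starts from `sigma_s = 100` um, `csr = 1` under the
#' constraints `sigma_s > sigma_c`, `csr >= 1` (constrained local search
#' via a smooth reparametrization and Nelder-Mead with restart; the fit is
#' deterministic given the data and layout seed).
#'
#' @param skeletons list of [tree_morphology()] dendritic skeletons, one
#'   per cell.
#' @param curves list of measured [spot_response_curve()]s, same order.
#' @param sigma_c fixed center s.d., um.
#' @param init named start values (`sigma_s`, `csr`).
#' @param density subunit placement density, um per synapse.
#' @param seed seed for subunit placement.
#' @param control passed to [stats::optim()] (reltol etc.).
#' @return An object of class `dog_fit`: the fitted [dog_params()], final
#'   MAE, per-cell residuals and fitted curves, and the layouts used.
#' @export
fit_dog <- function(skeletons, curves, sigma_c = 22,
                    init = c(sigma_s = 100, csr = 1), density = 0.3,
                    seed = 1L, control = list()) {
  if (length(skeletons) < 1L || length(skeletons) != length(curves))
    stop("need matching nonempty skeleton and curve lists")
  layouts <- lapply(seq_along(skeletons), function(i)
    place_subunits(skeletons[[i]], density = density,
                   seed = derive_seed(seed, "fit_layout", i)))
  diam_list <- lapply(curves, `[[`, "diameters")
  meas <- lapply(curves, `[[`, "responses")
  binned <- lapply(layouts, function(l) .bin_offsets(l$offsets))
  center_sums <- lapply(seq_along(layouts), function(i)
    .mass_sums_binned(binned[[i]], diam_list[[i]], sigma_c))

  objective <- function(sigma_s, csr) {
    err <- 0; n_tot <- 0
    for (i in seq_along(layouts)) {
      s_sums <- .mass_sums_binned(binned[[i]], diam_list[[i]], sigma_s)
      pred <- pmax(center_sums[[i]] - s_sums / csr, 0)
      mx <- max(pred)
      if (mx <= 0) return(1e6)
      pred <- pred / mx
      err <- err + sum(abs(pred - meas[[i]]))
      n_tot <- n_tot + length(pred)
    }
    err / n_tot
  }
  # smooth reparametrization keeps the constraints without an explicit box
  to_par <- function(th) c(sigma_s = sigma_c + exp(th[1]), csr = 1 + th[2]^2)
  fn <- function(th) { p <- to_par(th); objective(p[1], p[2]) }
  th0 <- c(log(init[["sigma_s"]] - sigma_c), sqrt(max(init[["csr"]] - 1, 0)))
  ctrl <- utils::modifyList(list(reltol = 1e-10, maxit = 2000), control)
  opt <- stats::optim(th0, fn, method = "Nelder-Mead", control = ctrl)
  opt <- stats::optim(opt$par, fn, method = "Nelder-Mead", control = ctrl)
  if (opt$convergence != 0)
    stop("DoG fit did not converge: optim code ", opt$convergence)
  p <- to_par(opt$par)
  par <- dog_params(sigma_c = sigma_c, sigma_s = p[["sigma_s"]],
                    csr = p[["csr"]])
  fitted_curves <- lapply(seq_along(layouts), function(i) {
    cu <- predict_response(layouts[[i]], par, diam_list[[i]])
    cu$cell_id <- curves[[i]]$cell_id
    cu
  })
  per_cell_mae <- vapply(seq_along(curves), function(i)
    mean(abs(fitted_curves[[i]]$responses - meas[[i]])), numeric(1))
  structure(list(par = par, mae = opt$value, per_cell_mae = per_cell_mae,
                 fitted_curves = fitted_curves, curves = curves,
                 layouts = layouts, density = density, seed = seed,
                 convergence = opt$convergence, counts = opt$counts,
                 call = match.call()),
            class = "dog_fit")
}

#' @export
print.dog_fit <- function(x, ...) {
  cat("DoG subunit receptive-field fit\n")
  cat(sprintf("  cells: %d   MAE: %.4f\n", length(x$curves), x$mae))
  cat(sprintf("  sigma_c %.1f um (fixed), sigma_s %.1f um, CSR %.3f\n",
              x$par$sigma_c, x$par$sigma_s, x$par$csr))
  invisible(x)
}

#' @export
coef.dog_fit <- function(object, ...) {
  c(sigma_c = object$par$sigma_c, sigma_s = object$par$sigma_s,
    csr = object$par$csr)
}

#' @export
summary.dog_fit <- function(object, ...) {
  sup_meas <- vapply(object$curves,
                     function(cu) suppression(cu)$suppression, numeric(1))
  sup_fit <- vapply(object$fitted_curves,
                    function(cu) suppression(cu)$suppression, numeric(1))
  out <- list(coef = coef(object), mae = object$mae,
              per_cell = data.frame(
                cell_id = vapply(object$curves, `[[`, character(1), "cell_id"),
                mae = object$per_cell_mae,
                suppression_measured = sup_meas,
                suppression_fitted = sup_fit))
  class(out) <- "summary.dog_fit"
  out
}

#' @export
print.summary.dog_fit <- function(x, ...) {
  cat("DoG subunit receptive-field fit\n")
  cat(sprintf("  sigma_c %.1f  sigma_s %.2f  CSR %.3f   pooled MAE %.4f\n",
              x$coef["sigma_c"], x$coef["sigma_s"], x$coef["csr"], x$mae))
  print(x$per_cell, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
residuals.dog_fit <- function(object, ...) {
  unlist(lapply(seq_along(object$curves), function(i)
    object$fitted_curves[[i]]$responses - object$curves[[i]]$responses))
}

#' Predict responses for new skeletons from a fitted DoG model
#'
#' @param object a fitted model from [fit_dog()].
#' @param skeletons list of [tree_morphology()] skeletons (default: the
#'   fitted cells).
#' @param diameters spot diameters, um.
#' @param seed placement seed for the new layouts.
#' @param ... unused.
#' @return List of predicted [spot_response_curve()]s.
#' @export
predict.dog_fit <- function(object, skeletons = NULL,
                            diameters = default_diameters(), seed = NULL,
                            ...) {
  if (is.null(skeletons)) {
    return(lapply(object$layouts, function(l)
      predict_response(l, object$par, diameters)))
  }
  seed <- seed %||% object$seed
  lapply(seq_along(skeletons), function(i) {
    l <- place_subunits(skeletons[[i]], density = object$density,
                        seed = derive_seed(seed, "predict_layout", i))
    predict_response(l, object$par, diameters)
  })
}

#' @export
plot.dog_fit <- function(x, ...) {
  n <- length(x$curves)
  old <- graphics::par(mfrow = grDevices::n2mfrow(n))
  on.exit(graphics::par(old))
  for (i in seq_len(n)) {
    cu <- x$curves[[i]]
    graphics::plot(cu$diameters, cu$responses, log = "x", pch = 16,
                   xlab = "spot diameter (um)", ylab = "response",
                   main = cu$cell_id, ylim = c(0, 1.05))
    graphics::lines(x$fitted_curves[[i]]$diameters,
                    x$fitted_curves[[i]]$responses, lty = 2)
  }
  invisible(x)
}

# ---- cross-validation -----------------------------------------------------

#' Cross-validate the DoG subunit model across fitting combinations
#'
#' Repeatedly samples a fitting set of cells, fits the model on it, and
#' predicts the held-out cells' spot-size curves from their own skeletons.
#' The per-cell error is predicted minus measured surround suppression;
#' errors are averaged across all combinations in which the cell was held
#' out.
#'
#' @param skeletons list of skeletons, one per cell.
#' @param curves matching measured curves.
#' @param fit_size number of cells per fitting set (6 in the standard
#'   protocol; with `groups` supplied, `fit_size/2` drawn per group).
#' @param n_combinations number of random fitting combinations (default
#'   400).
#' @param seed integer RNG seed for the combination draw.
#' @param groups optional factor of cell types for stratified fitting sets.
#' @param ... passed on to [fit_dog()].
#' @return An object of class `dog_cv`: per-cell mean suppression errors
#'   and the per-combination fit parameters.
#' @export
cross_validate <- function(skeletons, curves, fit_size = 6L,
                           n_combinations = 400L, seed = 1L, groups = NULL,
                           ...) {
  n <- length(skeletons)
  if (fit_size >= n) stop("fit_size must be smaller than the number of cells")
  combos <- with_seed(seed, {
    lapply(seq_len(n_combinations), function(k) {
      if (is.null(groups)) sort(sample(n, fit_size))
      else {
        per <- fit_size / length(unique(groups))
        sort(unlist(lapply(unique(groups), function(g)
          sample(which(groups == g), per))))
      }
    })
  })
  sup_meas <- vapply(curves, function(cu) suppression(cu)$suppression,
                     numeric(1))
  err_sum <- numeric(n); err_n <- integer(n)
  pars <- matrix(NA_real_, n_combinations, 3,
                 dimnames = list(NULL, c("sigma_s", "csr", "mae")))
  for (k in seq_len(n_combinations)) {
    idx <- combos[[k]]
    fit <- fit_dog(skeletons[idx], curves[idx],
                   seed = derive_seed(seed, "cvfit", k), ...)
    pars[k, ] <- c(fit$par$sigma_s, fit$par$csr, fit$mae)
    hold <- setdiff(seq_len(n), idx)
    preds <- predict(fit, skeletons[hold],
                     diameters = curves[[hold[1]]]$diameters,
                     seed = derive_seed(seed, "cvpred", k))
    for (j in seq_along(hold)) {
      e <- suppression(preds[[j]])$suppression - sup_meas[hold[j]]
      err_sum[hold[j]] <- err_sum[hold[j]] + e
      err_n[hold[j]] <- err_n[hold[j]] + 1L
    }
  }
  cell_ids <- vapply(curves, `[[`, character(1), "cell_id")
  structure(list(
    per_cell = data.frame(cell_id = cell_ids,
                          mean_suppression_error = err_sum / pmax(err_n, 1L),
                          n_heldout = err_n,
                          suppression_measured = sup_meas),
    pars = as.data.frame(pars),
    n_combinations = n_combinations, fit_size = fit_size, groups = groups),
    class = "dog_cv")
}

#' @export
print.dog_cv <- function(x, ...) {
  cat("DoG subunit model cross-validation:", x$n_combinations,
      "fitting combinations of", x$fit_size, "cells\n")
  cat(sprintf("  mean held-out suppression error: %.3f\n",
              mean(x$per_cell$mean_suppression_error[x$per_cell$n_heldout > 0])))
  print(x$per_cell, row.names = FALSE, digits = 3)
  invisible(x)
}
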