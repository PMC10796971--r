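#' Spot-size response curve
#'
#' Response per spot diameter for one cell, normalized so the maximum is 1.
#' The curve carries the preferred-size response (the maximum) and the
#' full-field response (at the largest diameter), the two quantities
#' entering the suppression statistic.
#'
#' @param cell_id cell identifier.
#' @param diameters ascending spot diameters, um.
#' @param responses response values, same length as `diameters`.
#' @param normalize divide by the maximum response (default TRUE).
#' @return An object of class `spot_response_curve`.
#' @export
spot_response_curve <- function(cell_id, diameters, responses,
                                normalize = TRUE) {
  if (length(diameters) != length(responses))
    stop("diameters and responses must have the same length")
  if (length(diameters) == 0L) stop("curve must be nonempty")
  if (is.unsorted(diameters, strictly = TRUE))
    stop("diameters must be strictly ascending")
  if (normalize) {
    mx <- max(responses)
    if (mx <= 0) stop("cannot normalize: maximal response is not positive")
    responses <- responses / mx
  }
  structure(list(cell_id = cell_id, diameters = as.numeric(diameters),
                 responses = as.numeric(responses)),
            class = "spot_response_curve")
}

#' @export
print.spot_response_curve <- function(x, ...) {
  s <- suppression(x)
  cat("spot_response_curve:", x$cell_id, "-", length(x$diameters),
      "spot sizes,", sprintf("suppression %.2f\n", s$suppression))
  invisible(x)
}

#' @export
plot.spot_response_curve <- function(x, ...) {
  graphics::plot(x$diameters, x$responses, log = "x", type = "o", pch = 16,
                 xlab = "spot diameter (um)", ylab = "normalized response",
                 main = x$cell_id, ...)
  invisible(x)
}

#' Surround suppression of a spot-size response curve
#'
#' Suppression = 1 - R_fullfield / R_preferred, where R_preferred is the
#' maximal response across spot sizes and R_fullfield is the response to
#' the largest spot. Negative measured responses (recording noise) are
#' floored at zero before the statistic is taken.
#'
#' @param curve a [spot_response_curve()].
#' @return A list of class `suppression_result` with fields `cell_id`,
#'   `r_preferred`, `preferred_diameter`, `r_fullfield`, `suppression`.
#' @export
suppression <- function(curve) {
  stopifnot(inherits(curve, "spot_response_curve"))
  r <- pmax(curve$responses, 0)
  if (any(curve$responses < 0))
    message("negative responses floored at 0 for suppression statistic")
  r_pref <- max(r)
  if (r_pref <= 0) stop("undefined suppression: preferred response <= 0")
  pref_d <- curve$diameters[which(r == r_pref)[1L]]  # ties -> smallest
  r_ff <- r[length(r)]
  structure(list(cell_id = curve$cell_id, r_preferred = r_pref,
                 preferred_diameter = pref_d, r_fullfield = r_ff,
                 suppression = 1 - r_ff / r_pref),
            class = "suppression_result")
}

#' @export
print.suppression_result <- function(x, ...) {
  cat(sprintf(
    "suppression_result: %s  R_pref %.3f @ %.0f um, R_ff %.3f, suppression %.3f\n",
    x$cell_id, x$r_preferred, x$preferred_diameter, x$r_fullfield,
    x$suppression))
  invisible(x)
}

#' Default spot-size series
#'
#' Twelve spot diameters logarithmically spaced from 30 to 1200 um, the
#' stimulus series used for all spot-size response curves.
#'
#' @return Numeric vector of length 12.
#' @export
default_diameters <- function() {
  exp(seq(log(30), log(1200), length.out = 12))
}

#' Read / write spot-response tables (CSV: cell_id,diameter_um,response)
#'
#' @param path file path.
#' @param normalize normalize each curve to maximum 1 on read.
#' @return `read_response_curves` returns a list of
#'   [spot_response_curve()] objects.
#' @export
read_response_curves <- function(path, normalize = TRUE) {
  d <- utils::read.csv(path)
  lapply(split(d, d$cell_id), function(g) {
    g <- g[order(g$diameter_um), ]
    spot_response_curve(g$cell_id[1L], g$diameter_um, g$response,
                        normalize = normalize)
  })
}

#' @rdname read_response_curves
#' @param curves list of [spot_response_curve()] objects.
#' @export
write_response_curves <- function(curves, path) {
  d <- do.call(rbind, lapply(curves, function(cu)
    data.frame(cell_id = cu$cell_id, diameter_um = cu$diameters,
               response = cu$responses)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
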