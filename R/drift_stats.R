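#' 3-D drift model
#'
#' Residual intrafraction drift is modeled as a zero-mean 3-D normal
#' vector with independent per-axis standard deviations (defaults
#' 1.5, 1.5 and 1.2 mm in SI, AP and ML, from post-treatment CBCT
#' residuals in lung SBRT). The drift magnitude of an isotropic 3-D
#' normal vector follows a Maxwell distribution; its range `[0, 3 delta]`
#' is partitioned into twelve radial bins of width `0.25 delta`, with
#' the tail beyond `3 delta` absorbed into bin 12.
#'
#' @param delta Named or ordered length-3 vector of per-axis standard
#'   deviations, mm, order (SI, AP, ML); all > 0.
#' @param n_bins Number of radial bins (default 12).
#' @return A `drift_model` object.
#' @export
drift_model <- function(delta = c(SI = 1.5, AP = 1.5, ML = 1.2),
                        n_bins = 12L) {
  delta <- as.numeric(delta)
  if (length(delta) != 3L || any(!is.finite(delta)) || any(delta <= 0))
    stop("`delta` must be three positive standard deviations (mm)",
         call. = FALSE)
  structure(list(delta = c(SI = delta[1], AP = delta[2], ML = delta[3]),
                 n_bins = as.integer(n_bins), bin_width = 0.25),
            class = "drift_model")
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf("<drift_model> delta = (%g, %g, %g) mm (SI, AP, ML), %d bins\n",
              x$delta[1], x$delta[2], x$delta[3], x$n_bins))
  invisible(x)
}

#' Maxwell radial CDF of the 3-D drift magnitude
#'
#' For a 3-D vector with independent zero-mean normal components of
#' common standard deviation `delta`, the probability that its length
#' does not exceed `r` is
#'
#'   `Q(r) = erf(r / (sqrt(2) delta)) -
#'           sqrt(2/pi) (r / delta) exp(-r^2 / (2 delta^2))`,
#'
#' the CDF of the Maxwell distribution with scale `delta`.
#'
#' @param r Radius (mm), >= 0; vectorized.
#' @param delta Scale (per-axis standard deviation), mm.
#' @return Probability in `[0, 1]`.
#' @export
maxwell_cdf <- function(r, delta = 1) {
  if (any(r < 0)) stop("`r` must be >= 0", call. = FALSE)
  if (delta <= 0) stop("`delta` must be > 0", call. = FALSE)
  x <- r / delta
  erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  erf(x / sqrt(2)) - sqrt(2 / pi) * x * exp(-x^2 / 2)
}

#' Radial bin probabilities of the drift magnitude
#'
#' `P_i = Q(i 0.25 delta) - Q((i-1) 0.25 delta)` for `i = 1..11` and
#' `P_12 = 1 - Q(2.75 delta)` (the tail bin absorbs all mass beyond
#' `2.75 delta`, including the mass outside `3 delta`). The result is
#' scale-free: it does not depend on the value of `delta`.
#'
#' @param model A [drift_model()] (only `n_bins`/`bin_width` matter).
#' @return Numeric vector of `n_bins` probabilities summing to 1.
#' @export
bin_probabilities <- function(model = drift_model()) {
  nb <- model$n_bins
  w <- model$bin_width
  edges <- (0:(nb - 1)) * w
  q <- maxwell_cdf(edges, 1)
  c(diff(q), 1 - q[nb])
}

#' Shift-node grid of the drift model
#'
#' The query magnitudes pair each radial bin with its midpoint:
#' `r_i = (2i - 1) * 0.125 * delta_j`, `i = 1..12`, scaled by the
#' per-axis standard deviation of the direction's axis (SI/AP nodes use
#' 1.5 mm, ML nodes 1.2 mm by default).
#'
#' @param model A [drift_model()].
#' @return A data frame with columns `direction`, `axis`, `i`,
#'   `r_mm` (strictly increasing within each direction).
#' @export
node_grid <- function(model = drift_model()) {
  i <- seq_len(model$n_bins)
  do.call(rbind, lapply(shift_directions(), function(dir) {
    ax <- direction_axis(dir)
    data.frame(direction = dir, axis = ax, i = i,
               r_mm = (2 * i - 1) * 0.125 * model$delta[[ax]])
  }))
}

# piecewise-linear interpolation through (x, y), anchored at the origin,
# with linear extrapolation from the final segment beyond the last sample
lin_interp_anchor <- function(x, y, xout) {
  x <- c(0, x)
  y <- c(0, y)
  out <- approx(x, y, xout, method = "linear", ties = "ordered",
                rule = 1)$y
  beyond <- xout > x[length(x)]
  if (any(beyond)) {
    n <- length(x)
    slope <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[beyond] <- y[n] + slope * (xout[beyond] - x[n])
  }
  out
}

#' Interpolate endpoint degradation onto the drift nodes
#'
#' For every (structure, endpoint, direction) series in the sampled
#' endpoint table, interpolates `Delta D_x` linearly over shift
#' magnitude onto that direction's node grid, anchored at
#' `Delta D_x(0) = 0` (the unperturbed plan), with linear extrapolation
#' from the last sampled segment for nodes beyond it.
#'
#' @param endpoints Endpoint table from [sample_endpoints()].
#' @param model A [drift_model()].
#' @return A data frame with columns `structure`, `endpoint`,
#'   `direction`, `i`, `r_mm`, `delta_pct`.
#' @export
interp_delta <- function(endpoints, model = drift_model()) {
  if (nrow(endpoints) == 0) stop("endpoint table is empty", call. = FALSE)
  nodes <- node_grid(model)
  groups <- unique(endpoints[c("structure", "endpoint", "direction")])
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- endpoints$structure == groups$structure[g] &
      endpoints$endpoint == groups$endpoint[g] &
      endpoints$direction == groups$direction[g]
    e <- endpoints[sel, ]
    e <- e[order(e$magnitude_mm), ]
    nd <- nodes[nodes$direction == groups$direction[g], ]
    data.frame(structure = groups$structure[g],
               endpoint = groups$endpoint[g],
               direction = groups$direction[g],
               i = nd$i, r_mm = nd$r_mm,
               delta_pct = lin_interp_anchor(e$magnitude_mm, e$delta_pct,
                                             nd$r_mm))
  })
  do.call(rbind, out)
}

#' Direction-averaged degradation per node
#'
#' Averages `Delta D_x` over the six cardinal shift directions at each
#' node index.
#'
#' @param node_values Output of [interp_delta()].
#' @return A data frame with columns `structure`, `endpoint`, `i`,
#'   `delta_pct` (mean over the 6 directions).
#' @export
direction_average <- function(node_values) {
  key <- interaction(node_values$structure, node_values$endpoint,
                     node_values$i, drop = TRUE)
  counts <- tapply(node_values$direction, key,
                   function(d) length(unique(d)))
  if (any(counts != 6))
    stop("each node needs all 6 directions", call. = FALSE)
  agg <- aggregate(delta_pct ~ structure + endpoint + i,
                   data = node_values, FUN = mean)
  agg[order(agg$structure, agg$endpoint, agg$i), ]
}

#' Probability-weighted mean degradation
#'
#' The expected endpoint degradation over the 3-D drift distribution:
#' `sum_i P_i * Delta D_x(r_i)` with the twelve bin probabilities. The
#' result always lies between the extreme node values.
#'
#' @param p Vector of bin probabilities ([bin_probabilities()]).
#' @param values Vector of direction-averaged `Delta D_x(r_i)`, same
#'   length as `p`, ordered by node index.
#' @return The weighted mean, percent.
#' @export
weighted_mean_delta <- function(p, values) {
  if (length(p) != length(values))
    stop("`p` and `values` must have the same length", call. = FALSE)
  sum(p * values)
}

#' Full drift-weighted summary of an endpoint table
#'
#' Convenience chain: interpolate onto the node grid, average the six
#' directions, and weight by the bin probabilities — one probability-
#' weighted mean `Delta D_x` per (structure, endpoint).
#'
#' @param endpoints Endpoint table from [sample_endpoints()].
#' @param model A [drift_model()].
#' @return A data frame with columns `structure`, `endpoint`,
#'   `weighted_mean_pct`, plus attribute `"nodes"` holding the
#'   direction-averaged node table.
#' @export
drift_weighted_summary <- function(endpoints, model = drift_model()) {
  nodes <- direction_average(interp_delta(endpoints, model))
  p <- bin_probabilities(model)
  groups <- unique(nodes[c("structure", "endpoint")])
  wm <- vapply(seq_len(nrow(groups)), function(g) {
    v <- nodes[nodes$structure == groups$structure[g] &
                 nodes$endpoint == groups$endpoint[g], ]
    weighted_mean_delta(p, v$delta_pct[order(v$i)])
  }, numeric(1))
  out <- data.frame(groups, weighted_mean_pct = wm, row.names = NULL)
  attr(out, "nodes") <- nodes
  out
}
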