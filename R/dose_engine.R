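#' Surrogate SBRT dose distribution
#'
#' Stands in for a clinically optimized static plan: the dose is a
#' monotone function of the signed Euclidean distance `sd(x)` to the PTV
#' surface (negative inside),
#'
#'   `D(x) = d_max * Phi((-sd(x) + c) / width)`,
#'
#' with `Phi` the standard normal CDF, `d_max = prescription / iso_level`
#' and `c = width * qnorm(iso_level)` so that the prescription isodose
#' surface (65% or 85% of maximum) coincides with the PTV surface. The
#' dose plateaus at `d_max` deep inside the target and falls to zero
#' outside; `width` (mm) controls the penumbra steepness.
#'
#' @param ptv PTV `mask` (non-empty).
#' @param iso_level Prescription isodose as a fraction of maximum dose,
#'   in (0, 1); the study uses 0.65 and 0.85.
#' @param prescription Prescription dose, cGy (default 6000).
#' @param width Penumbra width parameter, mm (> 0). See
#'   [calibrate_width()] for matching a target mean dose gradient.
#' @return A `dose_plan`: `dose` (`volume`, cGy), `prescription`,
#'   `iso_level`, `d_max`, `width`.
#' @export
synth_dose <- function(ptv, iso_level, prescription = 6000, width = 6) {
  if (!inherits(ptv, "mask") || !any(ptv))
    stop("`ptv` must be a non-empty mask", call. = FALSE)
  if (iso_level <= 0 || iso_level >= 1)
    stop("`iso_level` must be in (0, 1)", call. = FALSE)
  if (width <= 0) stop("`width` must be > 0 (mm)", call. = FALSE)
  d_max <- prescription / iso_level
  sd_vol <- signed_distance(ptv)
  cc <- width * qnorm(iso_level)
  dose <- d_max * pnorm((-vol_values(sd_vol) + cc) / width)
  structure(list(dose = vol_like(dose, ptv),
                 prescription = prescription, iso_level = iso_level,
                 d_max = d_max, width = width),
            class = "dose_plan")
}

#' @export
print.dose_plan <- function(x, ...) {
  cat(sprintf(
    "<dose_plan> %g cGy at the %g%% isodose (d_max %.1f cGy), width %.3g mm\n",
    x$prescription, 100 * x$iso_level, x$d_max, x$width))
  invisible(x)
}

#' PTV prescription coverage
#'
#' Fraction of PTV voxels receiving at least the prescription dose; a
#' valid plan covers at least 95%.
#'
#' @param plan A `dose_plan` (or a dose `volume`, with `prescription`
#'   supplied).
#' @param ptv PTV `mask`.
#' @param prescription Prescription dose in cGy (taken from the plan if
#'   given one).
#' @return Coverage fraction in `[0, 1]`.
#' @export
check_coverage <- function(plan, ptv, prescription = NULL) {
  if (inherits(plan, "dose_plan")) {
    prescription <- plan$prescription
    dose <- plan$dose
  } else dose <- plan
  if (is.null(prescription)) stop("`prescription` required", call. = FALSE)
  check_aligned(dose, ptv)
  mean(vol_values(dose)[vol_values(ptv)] >= prescription)
}

# dose of the surrogate model at signed distance sd for given parameters
surrogate_dose_at <- function(sd, iso_level, prescription, width) {
  (prescription / iso_level) *
    pnorm((-sd + width * qnorm(iso_level)) / width)
}

#' Calibrate the penumbra width to a target mean dose gradient
#'
#' Finds, by bisection, the `width` at which the mean dose gradient
#' (chord slope) of the SI dose profile over the interval from the
#' superior ITV boundary `x0` to `x0 + u` matches `target_gradient`.
#' The interval mirrors the boundary-voxel analysis: `x0` is where the
#' profile leaves the ITV and `u` the largest simulated drift.
#'
#' @param ptv,itv PTV and ITV `mask`s on the same grid.
#' @param iso_level Prescription isodose fraction in (0, 1).
#' @param target_gradient Target mean gradient, cGy/mm (must be < 0).
#' @param prescription Prescription dose, cGy.
#' @param u Interval length, mm (default 4.5, the largest shift).
#' @param tol Relative tolerance on the matched gradient.
#' @return Calibrated width in mm.
#' @export
calibrate_width <- function(ptv, itv, iso_level, target_gradient,
                            prescription = 6000, u = 4.5, tol = 0.001) {
  if (target_gradient >= 0)
    stop("`target_gradient` must be negative (dose falls outward)",
         call. = FALSE)
  check_aligned(ptv, itv)
  # The interval runs from the superior ITV boundary (x0) to x0 + u. In
  # signed-distance-to-PTV coordinates that is [-m, -m + u] with m the
  # ITV-to-PTV distance along the SI ray through the target centre,
  # measured between the interpolated zero crossings of the two signed
  # distances (the half-voxel offsets of the discrete transforms cancel).
  sd_ptv <- signed_distance(ptv)
  sd_itv <- signed_distance(itv)
  ctr_idx <- apply(which(vol_values(itv), arr.ind = TRUE), 2, mean)
  sp <- vol_spacing(itv)
  zmax <- (dim(itv)[3] - 1) * sp
  zs <- seq((ctr_idx[3] - 1) * sp, zmax, by = sp / 10)
  ray_pts <- cbind(ctr_idx[1] - 1, ctr_idx[2] - 1, zs / sp)
  zero_crossing <- function(sd_vol) {
    v <- sample_points_cpp(as.numeric(vol_values(sd_vol)), dim(sd_vol),
                           ray_pts)
    i <- which(v[-1] >= 0 & v[-length(v)] < 0)[1]
    if (is.na(i)) stop("no surface crossing along the SI ray",
                       call. = FALSE)
    zs[i] + (zs[i + 1] - zs[i]) * (0 - v[i]) / (v[i + 1] - v[i])
  }
  m <- zero_crossing(sd_ptv) - zero_crossing(sd_itv)
  sd0 <- -m
  sd1 <- -m + u
  grad_at <- function(w)
    (surrogate_dose_at(sd1, iso_level, prescription, w) -
       surrogate_dose_at(sd0, iso_level, prescription, w)) / u
  # |gradient| is unimodal in width (vanishes for both very sharp and very
  # flat penumbras); calibrate on the wide branch, where width decreases
  # with the steepness demanded — the physically sensible regime
  wmin <- 0.05; wmax <- 60
  w_peak <- stats::optimize(grad_at, c(wmin, wmax))$minimum
  g_peak <- grad_at(w_peak)
  g_hi <- grad_at(wmax)
  if (target_gradient < g_peak || target_gradient > g_hi)
    stop(sprintf(paste0("target gradient %.1f cGy/mm not attainable: ",
                        "achievable range [%.1f, %.1f] cGy/mm over width ",
                        "[%.2f, %.2f] mm"),
                 target_gradient, g_peak, g_hi, w_peak, wmax),
         call. = FALSE)
  lo <- w_peak; hi <- wmax
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    g <- grad_at(mid)
    if (g <= target_gradient) lo <- mid else hi <- mid
    if (abs(g - target_gradient) < tol * abs(target_gradient)) break
  }
  (lo + hi) / 2
}
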