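#' Shift directions
#'
#' The six cardinal isocenter-shift directions and their unit vectors
#' under the (ML, AP, SI) axis convention: left/right along ML,
#' anterior/posterior along AP, superior/inferior along SI.
#'
#' @return Character vector of the six direction names.
#' @export
shift_directions <- function() {
  c("anterior", "posterior", "right", "left", "superior", "inferior")
}

direction_unit <- function(direction) {
  switch(direction,
         left      = c(1, 0, 0),
         right     = c(-1, 0, 0),
         anterior  = c(0, 1, 0),
         posterior = c(0, -1, 0),
         superior  = c(0, 0, 1),
         inferior  = c(0, 0, -1),
         stop("unknown direction: ", direction, call. = FALSE))
}

# axis (SI/AP/ML) a direction moves along, for per-axis drift sigmas
direction_axis <- function(direction) {
  switch(direction,
         left = , right = "ML",
         anterior = , posterior = "AP",
         superior = , inferior = "SI",
         stop("unknown direction: ", direction, call. = FALSE))
}

#' Rigid isocenter-shift perturbation of a dose distribution
#'
#' Shifting all beams by `s = magnitude * e_j` translates the delivered
#' dose pattern rigidly: the perturbed dose is
#' `D'(x) = D(x - s)`, resampled with trilinear interpolation and
#' clamp-to-edge extension outside the grid (the dose is flat at the
#' boundary by construction).
#'
#' @param dose A dose `volume` (cGy).
#' @param direction One of [shift_directions()].
#' @param magnitude_mm Shift magnitude in mm (0 to 10).
#' @return The perturbed dose `volume`.
#' @export
shift_dose <- function(dose, direction, magnitude_mm) {
  if (magnitude_mm < 0 || magnitude_mm > 10)
    stop("`magnitude_mm` must be in [0, 10] mm", call. = FALSE)
  if (magnitude_mm == 0) return(dose)
  shift_vox <- magnitude_mm * direction_unit(direction) / vol_spacing(dose)
  out <- resample_shift_cpp(as.numeric(vol_values(dose)), dim(dose),
                            shift_vox)
  vol_like(out, dose)
}

#' Simplified 4-D dose accumulation on the reference anatomy
#'
#' Each breathing phase is assigned the same static (AVG-CT) dose
#' distribution; a target voxel at reference (end-exhalation) position
#' `x` accumulates the equally weighted mean of the doses sampled at its
#' phase positions `x + (z_k - z_EE) * e_SI` (rigid SI motion), with
#' trilinear sampling and clamp-to-edge extension.
#'
#' @param dose Static dose `volume` (nominal or perturbed).
#' @param phantom A `phantom4d` (provides offsets and reference phase).
#' @param target Structure `mask` defined on the reference (EE) phase,
#'   e.g. the EE-phase GTV.
#' @return Numeric vector of accumulated doses (cGy), one per target
#'   voxel, in `which(target)` order.
#' @export
accumulate_4d <- function(dose, phantom, target) {
  check_aligned(dose, target)
  if (!any(target)) stop("target mask is empty", call. = FALSE)
  sp <- vol_spacing(dose)
  z_ee <- phantom$offsets[phantom$reference_phase]
  idx <- which(vol_values(target), arr.ind = TRUE) # 1-based (ML, AP, SI)
  pts <- cbind(idx[, 1] - 1, idx[, 2] - 1, idx[, 3] - 1)
  vals <- as.numeric(vol_values(dose))
  acc <- numeric(nrow(pts))
  for (z_k in phantom$offsets) {
    p <- pts
    p[, 3] <- p[, 3] + (z_k - z_ee) / sp
    acc <- acc + sample_points_cpp(vals, dim(dose), p)
  }
  acc / length(phantom$offsets)
}

#' DVH endpoint degradation over the shift grid
#'
#' Evaluates every perturbed plan (6 directions x the shift magnitudes)
#' and tabulates `Delta D_x` for the ITV (on the static planning dose)
#' and the GTV (on the simplified 4-D accumulated dose at the
#' end-exhalation reference), relative to the unperturbed plan.
#'
#' @param plan A `dose_plan`.
#' @param phantom A `phantom4d`.
#' @param itv ITV `mask`; endpoints use the static dose.
#' @param gtv Reference-phase (EE) GTV `mask`; endpoints use the
#'   accumulated dose.
#' @param magnitudes_mm Shift magnitudes in mm, sorted ascending
#'   (default 0.5 to 4.5 by 1).
#' @param endpoints DVH endpoints x for `D_x` (default 99 and 95).
#' @return A data frame with columns `structure`, `endpoint`,
#'   `direction`, `magnitude_mm`, `delta_pct`.
#' @export
sample_endpoints <- function(plan, phantom, itv, gtv,
                             magnitudes_mm = c(0.5, 1.5, 2.5, 3.5, 4.5),
                             endpoints = c(99, 95)) {
  if (is.unsorted(magnitudes_mm))
    stop("`magnitudes_mm` must be sorted ascending", call. = FALSE)
  res <- perturbation_loop(plan, phantom, itv, gtv, magnitudes_mm,
                           endpoints, max_min = FALSE)
  res$endpoints
}

# shared engine: endpoint table and (optionally) running max/min maps
perturbation_loop <- function(plan, phantom, itv, gtv, magnitudes_mm,
                              endpoints, max_min = TRUE) {
  dose <- plan$dose
  nom_itv <- vol_values(dose)[vol_values(itv)]
  nom_gtv <- accumulate_4d(dose, phantom, gtv)
  dn_itv <- dose_at_volume(nom_itv, endpoints)
  dn_gtv <- dose_at_volume(nom_gtv, endpoints)
  vmax <- vmin <- vol_values(dose)
  rows <- list()
  for (dir in shift_directions()) {
    for (m in magnitudes_mm) {
      pert <- shift_dose(dose, dir, m)
      p_itv <- vol_values(pert)[vol_values(itv)]
      p_gtv <- accumulate_4d(pert, phantom, gtv)
      dp_itv <- dose_at_volume(p_itv, endpoints)
      dp_gtv <- dose_at_volume(p_gtv, endpoints)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = rep(c("ITV", "GTV"), each = length(endpoints)),
        endpoint = rep(endpoints, 2),
        direction = dir, magnitude_mm = m,
        delta_pct = 100 * c((dp_itv - dn_itv) / dn_itv,
                            (dp_gtv - dn_gtv) / dn_gtv))
      if (max_min) {
        pv <- vol_values(pert)
        vmax <- pmax(vmax, pv)
        vmin <- pmin(vmin, pv)
      }
    }
  }
  out <- list(endpoints = do.call(rbind, rows))
  if (max_min) out$max_min <- vol_like(vmax - vmin, dose)
  out
}

#' Max-min dose map over an uncertainty ensemble
#'
#' Voxelwise spread between the maximum and minimum dose across the
#' nominal plan and all perturbed plans, revealing where plan
#' uncertainty moves dose the most, plus the mask of voxels whose spread
#' meets a reporting threshold (the study uses 500 cGy).
#'
#' @param nominal Nominal dose `volume`.
#' @param perturbed List of perturbed dose `volume`s (at least one).
#' @param threshold Spread threshold in cGy.
#' @return List with `map` (spread `volume`, cGy) and `above`
#'   (`mask` of voxels with spread >= threshold).
#' @export
max_min_map <- function(nominal, perturbed, threshold = 500) {
  if (length(perturbed) < 1)
    stop("need at least one perturbed dose", call. = FALSE)
  for (p in perturbed) check_aligned(nominal, p)
  vmax <- vmin <- vol_values(nominal)
  for (p in perturbed) {
    pv <- vol_values(p)
    vmax <- pmax(vmax, pv)
    vmin <- pmin(vmin, pv)
  }
  list(map = vol_like(vmax - vmin, nominal),
       above = mask_like(vmax - vmin >= threshold, nominal))
}
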