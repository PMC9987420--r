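#' Digital respiratory lung phantom geometry
#'
#' The phantom is a voxelized thorax surrogate: a rectangular grid whose
#' lateral (ML/AP) boundary carries a chest-wall shell at 0 HU, lung
#' tissue at -720 HU inside it, and a spherical tumor at 0 HU that
#' translates rigidly along the superior-inferior (SI) axis over the
#' breathing cycle. "Amplitude" is peak-to-peak SI displacement.
#'
#' @param diameter_mm Tumor diameter in mm (study grid uses 20, 30, 40).
#' @param amplitude_mm Peak-to-peak SI motion amplitude in mm (study grid
#'   uses 10, 20, 30); must be >= 0.
#' @param dim Grid dimensions (ML, AP, SI) in voxels.
#' @param spacing_mm Isotropic voxel spacing, mm.
#' @param chest_wall_mm Thickness of the chest-wall shell at the ML/AP
#'   grid boundary, mm.
#' @param tumor_center_mid Physical coordinate (mm) of the tumor centre at
#'   mid-respiration; default is the grid centre.
#' @return A `phantom_geometry` object.
#' @export
phantom_geometry <- function(diameter_mm, amplitude_mm,
                             dim = c(120L, 120L, 140L), spacing_mm = 1,
                             chest_wall_mm = 10,
                             tumor_center_mid = NULL) {
  if (diameter_mm <= 0) stop("`diameter_mm` must be > 0", call. = FALSE)
  if (amplitude_mm < 0) stop("`amplitude_mm` must be >= 0", call. = FALSE)
  if (spacing_mm <= 0) stop("`spacing_mm` must be > 0", call. = FALSE)
  dim <- as.integer(dim)
  extent <- (dim - 1L) * spacing_mm
  if (is.null(tumor_center_mid)) tumor_center_mid <- extent / 2
  g <- structure(list(diameter_mm = diameter_mm, amplitude_mm = amplitude_mm,
                      dim = dim, spacing_mm = spacing_mm,
                      chest_wall_mm = chest_wall_mm,
                      tumor_center_mid = as.numeric(tumor_center_mid),
                      hu = c(chest_wall = 0, lung = -720, tumor = 0)),
                 class = "phantom_geometry")
  r <- diameter_mm / 2
  a2 <- amplitude_mm / 2
  # tumor plus full excursion must stay strictly inside the lung region
  lo <- g$tumor_center_mid - c(r, r, r + a2)
  hi <- g$tumor_center_mid + c(r, r, r + a2)
  wall_lo <- c(chest_wall_mm, chest_wall_mm, 0)
  wall_hi <- extent - wall_lo
  if (any(lo <= wall_lo + spacing_mm) || any(hi >= wall_hi - spacing_mm))
    stop("tumor excursion reaches the chest wall or grid boundary; ",
         "enlarge the grid", call. = FALSE)
  g
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf(
    "<phantom_geometry> tumor %g mm, SI amplitude %g mm, grid %s @ %g mm\n",
    x$diameter_mm, x$amplitude_mm, paste(x$dim, collapse = "x"),
    x$spacing_mm))
  invisible(x)
}

#' Superior-inferior tumor trajectory over the breathing half-cycle
#'
#' Eleven phases span the half-cycle from peak (phase 1, tumor at
#' +amplitude/2) to valley (last phase, end-exhalation, -amplitude/2),
#' sampled on a cosine: `z_k = (A/2) * cos(pi * k / (n - 1))`,
#' `k = 0, ..., n-1`.
#'
#' @param amplitude_mm Peak-to-peak amplitude, mm (>= 0).
#' @param n_phases Number of phases (>= 2), default 11.
#' @return Numeric vector of SI offsets in mm, strictly decreasing when
#'   the amplitude is positive.
#' @export
tumor_trajectory <- function(amplitude_mm, n_phases = 11L) {
  if (amplitude_mm < 0) stop("`amplitude_mm` must be >= 0", call. = FALSE)
  if (n_phases < 2) stop("`n_phases` must be >= 2", call. = FALSE)
  k <- seq_len(n_phases) - 1L
  (amplitude_mm / 2) * cos(pi * k / (n_phases - 1L))
}

# physical coordinate grids along each axis (mm), 1-based voxel centres
axis_coords <- function(geom) {
  lapply(1:3, function(a)
    (seq_len(geom$dim[a]) - 1) * geom$spacing_mm)
}

# chest wall: shell of the stated thickness at the four ML/AP grid faces
chest_wall_mask_values <- function(geom) {
  cw <- geom$chest_wall_mm
  xs <- axis_coords(geom)
  ext <- (geom$dim - 1L) * geom$spacing_mm
  near <- function(v, e) v < cw | v > e - cw
  wx <- near(xs[[1]], ext[1])
  wy <- near(xs[[2]], ext[2])
  outer(outer(wx, wy, `|`), rep(TRUE, geom$dim[3]), `&`)
}

#' Rasterize one breathing phase
#'
#' Paints the chest wall (0 HU), lung (-720 HU) and the tumor sphere
#' (0 HU) displaced along SI by `offset_mm`, using voxel-centre
#' inclusion (a voxel belongs to a shape iff its centre is inside; no
#' partial-volume HU).
#'
#' @param geom A [phantom_geometry()].
#' @param offset_mm SI displacement of the tumor centre from its
#'   mid-respiration position, mm.
#' @return List with elements `ct` (a `volume`, HU) and `gtv` (a `mask`).
#' @export
rasterize_phase <- function(geom, offset_mm) {
  xs <- axis_coords(geom)
  ctr <- geom$tumor_center_mid + c(0, 0, offset_mm)
  r2 <- (geom$diameter_mm / 2)^2
  dx2 <- (xs[[1]] - ctr[1])^2
  dy2 <- (xs[[2]] - ctr[2])^2
  dz2 <- (xs[[3]] - ctr[3])^2
  # squared distance field built separably, then thresholded
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  gtv <- d2 <= r2
  wall <- chest_wall_mask_values(geom)
  ct <- array(geom$hu[["lung"]], geom$dim)
  ct[wall] <- geom$hu[["chest_wall"]]
  ct[gtv] <- geom$hu[["tumor"]]
  list(ct = new_volume(ct, geom$spacing_mm),
       gtv = new_mask(gtv, geom$spacing_mm))
}

#' Build the 4-D phantom
#'
#' Rasterizes all phases of the cosine SI trajectory. The end-exhalation
#' (valley) phase — the last one — is the dose-accumulation reference.
#'
#' @param geom A [phantom_geometry()].
#' @param n_phases Number of phases, default 11.
#' @return A `phantom4d` object: `phases` (list of CT `volume`s), `gtvs`
#'   (list of per-phase GTV `mask`s), `offsets` (mm), `reference_phase`
#'   (index of the EE phase), `lung` and `chest_wall` masks, and the
#'   generating geometry.
#' @export
build_phantom <- function(geom, n_phases = 11L) {
  offsets <- tumor_trajectory(geom$amplitude_mm, n_phases)
  ph <- lapply(offsets, function(o) rasterize_phase(geom, o))
  wall <- chest_wall_mask_values(geom)
  structure(list(phases = lapply(ph, `[[`, "ct"),
                 gtvs = lapply(ph, `[[`, "gtv"),
                 offsets = offsets,
                 reference_phase = n_phases,
                 lung = new_mask(!wall, geom$spacing_mm),
                 chest_wall = new_mask(wall, geom$spacing_mm),
                 geometry = geom),
            class = "phantom4d")
}

#' @export
print.phantom4d <- function(x, ...) {
  cat(sprintf(
    "<phantom4d> %d phases, tumor %g mm, amplitude %g mm, EE phase %d\n",
    length(x$phases), x$geometry$diameter_mm, x$geometry$amplitude_mm,
    x$reference_phase))
  invisible(x)
}

check_phase_list <- function(vols) {
  if (length(vols) < 1) stop("need at least one phase", call. = FALSE)
  for (v in vols[-1]) check_aligned(vols[[1]], v, "phase volumes")
  invisible(TRUE)
}

#' Compose AVG and MIP CT over the breathing phases
#'
#' `compose_avg()` is the voxelwise arithmetic mean of the phase CTs (the
#' planning CT surrogate); `compose_mip()` is the voxelwise maximum
#' (maximal intensity projection), on which the moving tumor appears as
#' its full swept envelope.
#'
#' @param phantom A `phantom4d` (or a bare list of aligned `volume`s).
#' @return A `volume` on the shared grid.
#' @export
compose_avg <- function(phantom) {
  vols <- if (inherits(phantom, "phantom4d")) phantom$phases else phantom
  check_phase_list(vols)
  acc <- Reduce(`+`, lapply(vols, vol_values))
  vol_like(acc / length(vols), vols[[1]])
}

#' @rdname compose_avg
#' @export
compose_mip <- function(phantom) {
  vols <- if (inherits(phantom, "phantom4d")) phantom$phases else phantom
  check_phase_list(vols)
  vol_like(Reduce(pmax, lapply(vols, vol_values)), vols[[1]])
}

#' Recover a GTV by HU thresholding
#'
#' Emulates threshold-based tumor delineation: voxels at or above
#' `hu_cut`, restricted to the lung interior (the chest wall shares the
#' tumor's HU and must be excluded).
#'
#' @param ct A CT `volume` (single phase or MIP).
#' @param lung Lung-interior `mask`.
#' @param hu_cut Threshold in HU, strictly between lung (-720) and tumor
#'   (0); default -360, the midpoint.
#' @return A `mask`.
#' @export
threshold_gtv <- function(ct, lung, hu_cut = -360) {
  if (hu_cut <= -720 || hu_cut >= 0)
    stop("`hu_cut` must lie strictly between -720 and 0 HU", call. = FALSE)
  check_aligned(ct, lung)
  mask_like(vol_values(ct) >= hu_cut & vol_values(lung), ct)
}

#' ITV as the union of per-phase GTVs
#'
#' @param gtvs List of aligned GTV `mask`s (one per phase).
#' @return A `mask` containing every input.
#' @export
union_itv <- function(gtvs) {
  if (length(gtvs) < 1) stop("need at least one GTV", call. = FALSE)
  for (m in gtvs[-1]) check_aligned(gtvs[[1]], m, "masks")
  mask_like(Reduce(`|`, lapply(gtvs, vol_values)), gtvs[[1]])
}

#' Isotropic margin expansion (ITV to PTV)
#'
#' A voxel is included iff its centre lies within Euclidean distance
#' `margin_mm` of the input mask (voxel centres), computed with an exact
#' distance transform — the discrete Minkowski sum with a ball.
#'
#' @param mask A `mask`.
#' @param margin_mm Margin in mm (>= 0); the PTV uses 5 mm.
#' @return A `mask` containing the input.
#' @export
expand_margin <- function(mask, margin_mm) {
  if (margin_mm < 0) stop("`margin_mm` must be >= 0", call. = FALSE)
  if (margin_mm == 0) return(mask)
  d2 <- edt_sq_cpp(as.logical(mask), dim(mask), vol_spacing(mask))
  mask_like(d2 <= margin_mm^2 + 1e-9, mask)
}
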