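#' Dose profile along a ray
#'
#' Trilinear samples of a dose volume along a cardinal direction from a
#' physical start point (typically the isocenter, out past the ITV
#' boundary).
#'
#' @param dose A dose `volume` (cGy).
#' @param start Physical start coordinate, mm (length 3).
#' @param direction One of [shift_directions()], or a length-3 unit
#'   vector.
#' @param length_mm Profile length, mm.
#' @param step_mm Sample step, mm (<= 0.5 recommended).
#' @return A `profile` data frame with columns `position` (mm from the
#'   start) and `dose` (cGy).
#' @export
extract_profile <- function(dose, start, direction, length_mm,
                            step_mm = 0.5) {
  if (is.character(direction)) direction <- direction_unit(direction)
  direction <- direction / sqrt(sum(direction^2))
  pos <- seq(0, length_mm, by = step_mm)
  sp <- vol_spacing(dose)
  org <- vol_origin(dose)
  pts <- cbind((start[1] + pos * direction[1] - org[1]) / sp,
               (start[2] + pos * direction[2] - org[2]) / sp,
               (start[3] + pos * direction[3] - org[3]) / sp)
  in_grid <- pts[, 1] >= 0 & pts[, 1] <= dim(dose)[1] - 1 &
    pts[, 2] >= 0 & pts[, 2] <= dim(dose)[2] - 1 &
    pts[, 3] >= 0 & pts[, 3] <= dim(dose)[3] - 1
  if (!all(in_grid)) {
    warning("profile ray exits the grid; truncating", call. = FALSE)
    pos <- pos[in_grid]
    pts <- pts[in_grid, , drop = FALSE]
  }
  d <- sample_points_cpp(as.numeric(vol_values(dose)), dim(dose), pts)
  structure(data.frame(position = pos, dose = d),
            class = c("profile", "data.frame"))
}

profile_dose_at <- function(profile, x) {
  approx(profile$position, profile$dose, x, rule = 2)$y
}

#' Mean dose gradient over an interval
#'
#' Chord slope `(d(x0 + u) - d(x0)) / u` of the profile, which equals
#' the average of the pointwise gradient over `[x0, x0 + u]`.
#'
#' @param profile A `profile` from [extract_profile()].
#' @param x0 Interval start, mm along the profile.
#' @param u Interval length (displacement), mm; non-zero, and
#'   `[x0, x0 + u]` must lie within the profile.
#' @return Gradient in cGy/mm (negative where dose falls with position).
#' @export
mean_gradient <- function(profile, x0, u) {
  if (u == 0) stop("`u` must be non-zero", call. = FALSE)
  rng <- range(profile$position)
  if (min(x0, x0 + u) < rng[1] || max(x0, x0 + u) > rng[2])
    stop("interval [x0, x0 + u] outside the profile", call. = FALSE)
  (profile_dose_at(profile, x0 + u) - profile_dose_at(profile, x0)) / u
}

#' First-order prediction of the boundary dose deviation
#'
#' The dose change of a subvolume displaced by `mu` is approximated by
#' the product of the displacement and the mean dose gradient over the
#' traversed interval: `Delta D = mu * grad`.
#'
#' @param mu Displacement of the subvolume, mm.
#' @param grad Mean dose gradient over `[x0, x0 + mu]`, cGy/mm.
#' @return Predicted dose deviation, cGy.
#' @export
predict_delta <- function(mu, grad) {
  if (!all(is.finite(mu)) || !all(is.finite(grad)))
    stop("inputs must be finite", call. = FALSE)
  mu * grad
}
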