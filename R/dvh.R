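#' Cumulative dose-volume histogram
#'
#' The cumulative DVH of a structure is `V(d)` = fraction of its voxels
#' receiving at least dose `d`, built from the multiset of in-mask voxel
#' doses (voxels weighted equally on the isotropic grid).
#'
#' @param dose A dose `volume` (cGy), or a bare numeric vector of
#'   per-voxel doses (in which case `mask` is ignored).
#' @param mask Structure `mask` aligned with `dose`; must be non-empty.
#' @return A `dvh` object: `dose` (sorted unique dose levels, cGy) and
#'   `volume_pct` (percent of structure at or above each level), plus the
#'   raw sorted per-voxel doses in `samples`.
#' @export
cumulative_dvh <- function(dose, mask = NULL) {
  doses <- structure_doses(dose, mask)
  s <- sort(doses)
  lev <- unique(s)
  # V(lev[j]) = fraction of voxels >= lev[j]; with s ascending this is
  # (n - first occurrence + 1) / n
  first <- match(lev, s)
  vol <- 100 * (length(s) - first + 1) / length(s)
  structure(list(dose = lev, volume_pct = vol, samples = s), class = "dvh")
}

structure_doses <- function(dose, mask) {
  if (is.numeric(dose) && is.null(dim(dose))) {
    doses <- as.numeric(dose)
  } else {
    if (is.null(mask)) stop("`mask` required with a dose volume",
                            call. = FALSE)
    check_aligned(dose, mask)
    doses <- vol_values(dose)[vol_values(mask)]
  }
  if (length(doses) == 0) stop("structure is empty", call. = FALSE)
  doses
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %d voxels, dose range [%.1f, %.1f] cGy\n",
              length(x$samples), min(x$samples), max(x$samples)))
  invisible(x)
}

#' Dose-at-volume endpoint D_x
#'
#' `D_x` is the minimum dose received by the best-covered x% of the
#' structure: the largest dose `d` with `V(d) >= x`. On the discrete
#' voxel multiset this is the order statistic
#' `D_x = s_desc[ceiling(n * x / 100)]` of the doses sorted descending.
#'
#' @param dvh A `dvh` from [cumulative_dvh()], or a numeric vector of
#'   per-voxel doses.
#' @param x Volume percentage in (0, 100].
#' @return Dose in cGy.
#' @export
dose_at_volume <- function(dvh, x) {
  if (any(x <= 0 | x > 100))
    stop("`x` must be in (0, 100]", call. = FALSE)
  s <- if (inherits(dvh, "dvh")) dvh$samples else sort(as.numeric(dvh))
  n <- length(s)
  # s ascending; best-covered x% are the top k = ceiling(n x / 100) voxels
  k <- pmin(n, pmax(1L, as.integer(ceiling(n * x / 100 - 1e-9))))
  s[n - k + 1L]
}

#' Relative DVH endpoint change between plans
#'
#' `Delta D_x = 100 * (D_x^pert - D_x^nom) / D_x^nom` in percent;
#' negative values are degradation. Invariant under a common rescaling of
#' both dose distributions.
#'
#' @param nominal Nominal dose: a `dose_plan`, a dose `volume`, or a
#'   numeric vector of per-voxel structure doses.
#' @param perturbed Perturbed dose in any of the same forms.
#' @param mask Structure `mask` (required with volume inputs).
#' @param x Volume percentage(s) in (0, 100].
#' @return Percent change(s), one per element of `x`.
#' @export
delta_dx <- function(nominal, perturbed, mask = NULL, x = 99) {
  if (inherits(nominal, "dose_plan")) nominal <- nominal$dose
  dn <- dose_at_volume(structure_doses(nominal, mask), x)
  dp <- dose_at_volume(structure_doses(perturbed, mask), x)
  if (any(dn == 0))
    stop("nominal D_x is zero; relative change undefined", call. = FALSE)
  100 * (dp - dn) / dn
}

#' Write a DVH as CSV
#'
#' @param dvh A `dvh`.
#' @param path Output CSV path (columns `dose_cGy`, `volume_pct`).
#' @export
write_dvh <- function(dvh, path) {
  write.csv(data.frame(dose_cGy = dvh$dose, volume_pct = dvh$volume_pct),
            path, row.names = FALSE)
  invisible(path)
}
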