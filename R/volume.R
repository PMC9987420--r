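#' Scalar volumes and binary masks
#'
#' A `volume` is a 3-D numeric array (HU for CT, cGy for dose) on an
#' isotropic voxel grid, carrying a `spacing` (mm per voxel) and an
#' `origin` (physical coordinate, in mm, of voxel `[1, 1, 1]`). A `mask`
#' is the boolean counterpart, aligned voxel-for-voxel with its paired
#' volume. Axis order is (ML, AP, SI): left-right, anterior-posterior,
#' superior-inferior.
#'
#' Physical coordinate of voxel index `(i, j, k)` (1-based) is
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values 3-D numeric (volume) or logical (mask) array.
#' @param spacing Isotropic voxel spacing in mm; must be > 0.
#' @param origin Length-3 physical coordinate of voxel `[1, 1, 1]`, mm.
#' @return An object of class `volume` or `mask`.
#' @export
new_volume <- function(values, spacing = 1, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("`spacing` must be a single positive number (mm)", call. = FALSE)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be a finite length-3 coordinate (mm)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("volume values must be finite", call. = FALSE)
  structure(values, spacing = as.numeric(spacing),
            origin = as.numeric(origin), class = "volume")
}

#' @rdname new_volume
#' @export
new_mask <- function(values, spacing = 1, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask values must be TRUE/FALSE", call. = FALSE)
  v <- new_volume(array(0, dim(values)), spacing, origin)
  structure(values, spacing = attr(v, "spacing"), origin = attr(v, "origin"),
            class = "mask")
}

#' @rdname new_volume
#' @param x A `volume` or `mask`.
#' @export
vol_spacing <- function(x) attr(x, "spacing")

#' @rdname new_volume
#' @export
vol_origin <- function(x) attr(x, "origin")

# strip class/attrs down to a plain array
vol_values <- function(x) {
  a <- unclass(x)
  attr(a, "spacing") <- NULL
  attr(a, "origin") <- NULL
  a
}

# rebuild a volume/mask on the same grid as a template
vol_like <- function(values, template) {
  new_volume(array(values, dim(template)), vol_spacing(template),
             vol_origin(template))
}

mask_like <- function(values, template) {
  new_mask(array(values, dim(template)), vol_spacing(template),
           vol_origin(template))
}

# error unless two rasters share grid geometry
check_aligned <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)) ||
      !isTRUE(all.equal(vol_spacing(a), vol_spacing(b))) ||
      !isTRUE(all.equal(vol_origin(a), vol_origin(b))))
    stop(what, " are not aligned (shape/spacing/origin mismatch)",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume> %d x %d x %d voxels, spacing %g mm, range [%g, %g]\n",
              d[1], d[2], d[3], vol_spacing(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<mask> %d x %d x %d voxels, spacing %g mm, %d voxels set\n",
              d[1], d[2], d[3], vol_spacing(x), sum(x)))
  invisible(x)
}

#' Read and write volumes as NIfTI-1
#'
#' Volumes (CT in HU, dose in cGy, max-min maps) round-trip through
#' NIfTI-1 with the voxel spacing stored in the header; masks are written
#' as uint8 0/1 and read back as logical.
#'
#' @param x A `volume` or `mask`.
#' @param path File path, conventionally ending in `.nii.gz`.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` /
#'   `read_mask()` return the reconstructed object.
#' @export
write_volume <- function(x, path) {
  a <- vol_values(x)
  if (is.logical(a)) storage.mode(a) <- "integer"
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- rep(vol_spacing(x), 3)
  RNifti::writeNifti(img, path,
                     datatype = if (inherits(x, "mask")) "uint8" else "float")
  invisible(path)
}

#' @rdname write_volume
#' @param spacing,origin Grid geometry to restore (NIfTI stores spacing;
#'   the study's origin convention is re-applied on read).
#' @export
read_volume <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1]
  new_volume(array(as.numeric(img), dim(img)[1:3]), spacing = sp,
             origin = origin)
}

#' @rdname write_volume
#' @export
read_mask <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1]
  new_mask(array(as.numeric(img) > 0.5, dim(img)[1:3]), spacing = sp,
           origin = origin)
}

#' Signed Euclidean distance to a mask surface
#'
#' Exact voxel-centre Euclidean distance transform (separable
#' lower-envelope algorithm), combined into a signed distance: negative
#' inside the mask, positive outside, in mm. Raw voxel-centre-to-
#' voxel-centre distances overshoot the continuous surface by half a
#' voxel on each side (adjacent inner/outer voxels sit at -1/+1
#' spacings), so a half-sample correction is applied: the magnitude is
#' reduced by `spacing / 2`, placing the zero level at the mask surface
#' under linear interpolation.
#'
#' @param mask A `mask`.
#' @return A `volume` of signed distances (mm).
#' @export
signed_distance <- function(mask) {
  if (!inherits(mask, "mask")) stop("`mask` must be a mask", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  sp <- vol_spacing(mask)
  d <- dim(mask)
  dout <- sqrt(edt_sq_cpp(as.logical(mask), d, sp))   # 0 inside
  din <- sqrt(edt_sq_cpp(!as.logical(mask), d, sp))   # 0 outside
  raw <- dout - din
  vol_like(raw - sign(raw) * sp / 2, mask)
}
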