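#' Image volume and ROI mask containers
#'
#' `image_volume()` wraps a 3D scalar array with its voxel spacing (mm) and
#' grid origin (mm); `roi_mask()` does the same for a binary tumor mask that
#' lives on the same grid as its companion image. These are the containers
#' every preprocessing and feature-extraction step operates on.
#'
#' @param values 3D numeric array (logical for masks; numeric input to
#'   `roi_mask()` is binarized at 0.5).
#' @param spacing_mm Numeric 3-vector of strictly positive voxel sizes in mm.
#' @param origin_mm Numeric 3-vector, world coordinate of the first voxel
#'   center.
#' @return An object of class `image_volume` or `roi_mask`: a list with
#'   elements `values`, `spacing_mm`, `origin_mm`.
#' @examples
#' img <- image_volume(array(rnorm(27), c(3, 3, 3)), spacing_mm = c(2, 2, 2))
#' msk <- roi_mask(array(TRUE, c(3, 3, 3)), spacing_mm = c(2, 2, 2))
#' @export
image_volume <- function(values, spacing_mm = c(1, 1, 1),
                         origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop_config("image_volume: values must be a 3D array, got %d dims",
                length(dim(values)))
  if (!all(is.finite(values)))
    stop_config("image_volume: all voxel values must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop_config("image_volume: spacing_mm must be 3 strictly positive values")
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
roi_mask <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop_config("roi_mask: values must be a 3D array")
  if (!is.logical(values)) values <- values > 0.5
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop_config("roi_mask: spacing_mm must be 3 strictly positive values")
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s, spacing %s mm, range [%.3g, %.3g]>\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %s, spacing %s mm, %d voxels in ROI>\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              sum(x$values)))
  invisible(x)
}

check_same_grid <- function(img, mask) {
  if (!identical(dim(img$values), dim(mask$values)))
    stop_config("image and mask dimensions differ (%s vs %s)",
                paste(dim(img$values), collapse = "x"),
                paste(dim(mask$values), collapse = "x"))
  if (max(abs(img$spacing_mm - mask$spacing_mm)) > 1e-6)
    stop_config("image and mask voxel spacing differ")
  invisible(TRUE)
}

#' Read and write NIfTI volumes
#'
#' Thin wrappers around [RNifti] that enforce the package's container
#' contract: volumes must be 3D single-channel, voxel spacing is taken from
#' the NIfTI header, and masks are binarized at 0.5.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return `read_volume()` returns an [image_volume]; `read_mask()` a
#'   [roi_mask].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop_config("%s: expected a 3D volume, got %d dimensions",
                path, length(dim(img)))
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop_config("%s: invalid voxel spacing in header", path)
  orig <- tryCatch(-RNifti::xform(img)[1:3, 4], error = function(e) c(0, 0, 0))
  image_volume(array(as.numeric(img), dim(img)), spacing_mm = sp,
               origin_mm = orig)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  roi_mask(vol$values > 0.5, spacing_mm = vol$spacing_mm,
           origin_mm = vol$origin_mm)
}

#' @rdname read_volume
#' @param x An [image_volume] or [roi_mask].
#' @export
write_volume <- function(x, path) {
  vals <- if (is.logical(x$values)) array(as.numeric(x$values), dim(x$values))
          else x$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
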