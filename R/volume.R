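#' 3D image volume with physical voxel spacing
#'
#' The unit all spatial operations act on: a 3D scalar array plus the voxel
#' spacing in millimetres. The third array index is the axial slice
#' (`k` = slice), matching the convention that in-plane resolution is fine
#' (e.g. 0.5 mm) and slices are thick (e.g. 3 mm).
#'
#' @param values 3D numeric array of finite values.
#' @param spacing numeric length-3, voxel spacing `(sx, sy, sz)` in mm, all
#'   positive.
#' @return An object of class `image_volume` with elements `values` and
#'   `spacing`.
#' @export
image_volume <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)")
  if (any(!is.finite(values)))
    stop("volume values must be finite")
  structure(list(values = values, spacing = spacing), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s voxels @ %s mm>\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' Spacing is taken from the NIfTI header (`pixdim`). Only 3D images are
#' accepted; 2D or 4D input is an error.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D volume, got %dD: %s", length(d), path))
  sp <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim = d), sp)
}

#' Write a 3D volume (or binary mask) to NIfTI
#'
#' @param vol an [image_volume], or a 3D logical/numeric array (then
#'   `spacing` must be given).
#' @param path output path (`.nii.gz` recommended).
#' @param spacing voxel spacing in mm, required when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "image_volume")) {
    arr <- vol$values
    spacing <- vol$spacing
  } else {
    arr <- vol
    if (is.null(spacing)) stop("`spacing` required for bare arrays")
  }
  if (is.logical(arr)) arr <- array(as.integer(arr), dim = dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Internal: check a 0-based voxel index against grid dims.
in_bounds0 <- function(v, dims) {
  all(v >= 0L) && all(v <= dims - 1L)
}

# Internal: seeded evaluation that does not disturb the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
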