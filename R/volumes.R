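#' Grid-aware 3D volume and mask containers
#'
#' `intensity_volume()`, `binary_mask()` and `probability_map()` wrap plain 3D
#' arrays with the voxel spacing (mm) and an opaque grid token so that every
#' later operation can refuse to combine volumes that do not live on the same
#' sampling grid. No resampling is ever performed: a grid mismatch is an error.
#'
#' @param data 3D numeric (or logical for masks) array.
#' @param spacing numeric length-3, voxel edge lengths in mm; all > 0.
#' @param grid_id opaque token identifying grid/orientation. Defaults to a
#'   token derived from shape and spacing, so volumes built independently with
#'   identical geometry are combinable.
#' @param label free-text role tag for masks (e.g. "segmentation", "shell").
#' @return An object of class `intensity_volume`, `binary_mask` or
#'   `probability_map`.
#' @name volumes
NULL

default_grid_id <- function(data, spacing) {
  paste0("grid:", paste(dim(data), collapse = "x"),
         "@", paste(format(spacing, trim = TRUE), collapse = ","))
}

check_grid_args <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("every axis of `data` must have extent >= 1", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("`spacing` must be three positive voxel edge lengths (mm)", call. = FALSE)
  invisible(TRUE)
}

#' @rdname volumes
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1), grid_id = NULL) {
  check_grid_args(data, spacing)
  storage.mode(data) <- "double"
  structure(list(data = data,
                 spacing = as.numeric(spacing),
                 grid_id = grid_id %||% default_grid_id(data, spacing)),
            class = "intensity_volume")
}

#' @rdname volumes
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), grid_id = NULL,
                        label = "mask") {
  if (is.numeric(data)) data <- array(data != 0, dim(data))
  check_grid_args(data, spacing)
  if (!is.logical(data)) stop("mask `data` must be logical", call. = FALSE)
  if (anyNA(data)) stop("mask `data` must not contain NA", call. = FALSE)
  structure(list(data = data,
                 spacing = as.numeric(spacing),
                 grid_id = grid_id %||% default_grid_id(data, spacing),
                 label = label),
            class = "binary_mask")
}

#' @rdname volumes
#' @export
probability_map <- function(data, spacing = c(1, 1, 1), grid_id = NULL) {
  check_grid_args(data, spacing)
  if (anyNA(data) || any(data < 0) || any(data > 1))
    stop("probability map values must lie in [0, 1]", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data,
                 spacing = as.numeric(spacing),
                 grid_id = grid_id %||% default_grid_id(data, spacing)),
            class = "probability_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check that two grid-aware objects share a sampling grid
#'
#' @param a,b volumes/masks/probability maps.
#' @return TRUE invisibly; otherwise an error describing both grids.
#' @export
stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      !isTRUE(all.equal(a$spacing, b$spacing)) ||
      !identical(a$grid_id, b$grid_id)) {
    stop(sprintf(
      "grid mismatch: [%s @ %s, id %s] vs [%s @ %s, id %s]; resampling is never implicit",
      paste(dim(a$data), collapse = "x"), paste(a$spacing, collapse = ","), a$grid_id,
      paste(dim(b$data), collapse = "x"), paste(b$spacing, collapse = ","), b$grid_id),
      call. = FALSE)
  }
  invisible(TRUE)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    identical(a$grid_id, b$grid_id)
}

#' Number of foreground voxels in a mask
#' @param m a `binary_mask`.
#' @export
voxel_count <- function(m) sum(m$data)

#' Mask volume in millilitres
#'
#' `voxel_count * prod(spacing) / 1000`, i.e. mm^3 converted to mL.
#'
#' @param m a `binary_mask`.
#' @return volume in mL (non-negative scalar).
#' @examples
#' m <- binary_mask(array(TRUE, c(10, 10, 10)))
#' mask_volume_ml(m)  # 1 mL
#' @export
mask_volume_ml <- function(m) {
  stopifnot(inherits(m, "binary_mask"))
  sum(m$data) * prod(m$spacing) / 1000
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("<intensity_volume> %s, spacing %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask:%s> %s, %d voxels, %.4f mL\n",
              x$label, paste(dim(x$data), collapse = "x"),
              voxel_count(x), mask_volume_ml(x)))
  invisible(x)
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s, values in [%.3f, %.3f]\n",
              paste(dim(x$data), collapse = "x"), min(x$data), max(x$data)))
  invisible(x)
}

# internal: derive a mask on the same grid as `ref` from a logical array
mask_like <- function(ref, data, label = "mask") {
  binary_mask(data, spacing = ref$spacing, grid_id = ref$grid_id, label = label)
}
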