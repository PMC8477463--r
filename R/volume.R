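#' Image volume container
#'
#' A 3D scalar grid with physical voxel spacing and a modality tag. This is
#' the universal carrier for DWI, ADC and T2W data throughout the package.
#' Internally a plain numeric array of dimension (x, y, z) with attributes;
#' world coordinates follow the voxel-center convention: the center of voxel
#' (i, j, k) (1-based) sits at ((i, j, k) - 0.5) * spacing millimetres from
#' the field-of-view corner.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel spacing in mm per axis.
#' @param modality character tag, e.g. "DWI", "ADC", "T2W".
#' @return An `image_volume` object.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), modality = "generic") {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L) stop("image_volume requires a 2D or 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  structure(data, spacing = spacing, modality = as.character(modality)[1],
            class = c("image_volume", "array"))
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s voxels  spacing %s mm\n",
              attr(x, "modality"), paste(dim(x), collapse = "x"),
              paste(signif(attr(x, "spacing"), 4), collapse = "x")))
  invisible(x)
}

#' Voxel spacing of a volume or mask
#' @param x an `image_volume` or `lesion_mask`.
#' @return numeric length-3 spacing in mm.
#' @export
voxel_spacing <- function(x) attr(x, "spacing")

voxel_volume_mm3 <- function(x) prod(attr(x, "spacing"))

#' Binary lesion mask
#'
#' @param data logical (or 0/1) 3D array.
#' @param spacing voxel spacing in mm.
#' @return A `lesion_mask` object (logical array with spacing attribute).
#' @export
lesion_mask <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("lesion_mask requires a 3D array")
  m <- array(as.logical(data), dim = dim(data))
  if (anyNA(m)) stop("mask contains NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("invalid spacing")
  structure(m, spacing = spacing, class = c("lesion_mask", "array"))
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s voxels, %d foreground (%.3f ml)\n",
              paste(dim(x), collapse = "x"), sum(x), lesion_volume(x)))
  invisible(x)
}

#' Multi-b diffusion-weighted stack
#'
#' Co-registered diffusion-weighted volumes indexed by b-value; houses the
#' signals S(b) (including S(0) at b = 0) used for ADC fitting.
#'
#' @param volumes list of `image_volume`s (or plain arrays) on one grid, or a
#'   4D array with the 4th dimension indexing b-values.
#' @param b_values numeric, strictly increasing b-values in s/mm^2, one per
#'   volume.
#' @param spacing voxel spacing in mm (taken from the first `image_volume` if
#'   omitted).
#' @return A `dwi_stack`: list with `data` (4D array), `b_values`, `spacing`.
#' @export
dwi_stack <- function(volumes, b_values, spacing = NULL) {
  b_values <- as.numeric(b_values)
  if (length(b_values) < 2L) stop("at least 2 b-values are required")
  if (any(diff(b_values) <= 0)) stop("b_values must be strictly increasing")
  if (any(b_values < 0)) stop("b_values must be non-negative")
  if (is.list(volumes)) {
    if (length(volumes) != length(b_values))
      stop("one volume per b-value is required")
    dims <- lapply(volumes, dim)
    if (!all(vapply(dims, identical, logical(1), dims[[1]])))
      stop("all volumes must share one grid")
    if (is.null(spacing)) {
      sp <- attr(volumes[[1]], "spacing")
      spacing <- if (is.null(sp)) c(1, 1, 1) else sp
    }
    data <- array(unlist(volumes, use.names = FALSE),
                  dim = c(dims[[1]], length(volumes)))
  } else {
    data <- as.array(volumes)
    if (length(dim(data)) != 4L || dim(data)[4] != length(b_values))
      stop("4D array must have one slab per b-value")
    if (is.null(spacing)) spacing <- c(1, 1, 1)
  }
  if (any(!is.finite(data))) stop("DWI signals must be finite")
  structure(list(data = data, b_values = b_values,
                 spacing = as.numeric(spacing)),
            class = "dwi_stack")
}

#' @export
print.dwi_stack <- function(x, ...) {
  cat(sprintf("<dwi_stack> %s voxels, b = %s s/mm^2\n",
              paste(dim(x$data)[1:3], collapse = "x"),
              paste(x$b_values, collapse = ", ")))
  invisible(x)
}

#' Foreground/background seed labels for segmentation
#'
#' Seed voxels marked inside (foreground) and outside (background) the lesion,
#' emulating manually drawn seed points. Indices are 1-based (i, j, k) rows
#' matching R array indexing.
#'
#' @param foreground,background integer matrices with 3 columns of voxel
#'   indices, or vectors of linear indices.
#' @param grid_shape integer length-3 grid dimensions, used for validation.
#' @return A `seed_labels` object.
#' @export
seed_labels <- function(foreground, background, grid_shape) {
  grid_shape <- as.integer(grid_shape)
  as_lin <- function(x, what) {
    if (is.matrix(x)) {
      if (ncol(x) != 3L) stop(what, " matrix must have 3 columns")
      if (any(x < 1) || any(t(x) > grid_shape))
        stop(what, " seed indices fall outside the grid")
      as.integer(x[, 1] + (x[, 2] - 1L) * grid_shape[1] +
                   (x[, 3] - 1L) * grid_shape[1] * grid_shape[2])
    } else {
      x <- as.integer(x)
      if (any(x < 1L) || any(x > prod(grid_shape)))
        stop(what, " seed indices fall outside the grid")
      x
    }
  }
  fg <- unique(as_lin(foreground, "foreground"))
  bg <- unique(as_lin(background, "background"))
  if (length(fg) == 0L || length(bg) == 0L)
    stop("both foreground and background seeds are required")
  if (length(intersect(fg, bg)) > 0L)
    stop("foreground and background seeds must be disjoint")
  structure(list(foreground = fg, background = bg,
                 grid_shape = grid_shape), class = "seed_labels")
}

#' Read seed points from a JSON file
#'
#' The on-disk convention is 0-based (z, y, x) triplets under keys
#' `foreground` and `background`; they are converted to the package's internal
#' 1-based (x, y, z) indexing.
#'
#' @param path JSON file path.
#' @param grid_shape grid dimensions for validation.
#' @return A `seed_labels` object.
#' @export
read_seeds <- function(path, grid_shape) {
  if (!file.exists(path)) stop("seeds file not found: ", path)
  js <- jsonlite::fromJSON(path)
  if (is.null(js$foreground) || is.null(js$background))
    stop("seeds file must contain 'foreground' and 'background' lists")
  conv <- function(m) {
    m <- rbind(m)
    storage.mode(m) <- "integer"
    # (z, y, x) 0-based -> (x, y, z) 1-based
    cbind(m[, 3] + 1L, m[, 2] + 1L, m[, 1] + 1L)
  }
  seed_labels(conv(js$foreground), conv(js$background), grid_shape)
}

#' Write and read NIfTI-1 volumes
#'
#' Thin wrappers around RNifti that preserve voxel spacing through the pixdim
#' header fields. Masks are written as uint8 0/1.
#'
#' @param vol an `image_volume` or `lesion_mask`.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   `image_volume`; `read_mask` returns a `lesion_mask`.
#' @export
write_volume <- function(vol, path) {
  is_mask <- inherits(vol, "lesion_mask")
  arr <- array(if (is_mask) as.integer(vol) else as.numeric(vol), dim = dim(vol))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- attr(vol, "spacing")
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}

#' @rdname write_volume
#' @param modality modality tag to attach on read.
#' @export
read_volume <- function(path, modality = "generic") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]),
               spacing = sp, modality = modality)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  vals <- as.numeric(img)
  if (!all(vals %in% c(0, 1))) stop("mask file contains values other than 0/1")
  lesion_mask(array(vals > 0, dim = dim(img)[1:3]), spacing = sp)
}
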