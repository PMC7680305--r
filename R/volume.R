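#' 3D CT image volume
#'
#' A minimal container for a scalar 3D image: a numeric array of voxel values
#' (Hounsfield units for CT), a physical voxel spacing in mm, and a world
#' origin in mm. Voxel indices are 0-based in world-coordinate computations:
#' the world position of voxel `(i, j, k)` is `origin + c(i, j, k) * spacing`.
#'
#' @param voxels 3D numeric array of voxel values.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world coordinates of voxel (0,0,0) in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as_array3d(voxels)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    rlang::abort("`spacing` must be three positive finite values (mm).",
                 class = "lnrad_bad_geometry")
  }
  if (length(origin) != 3 || any(!is.finite(origin))) {
    rlang::abort("`origin` must be three finite values (mm).",
                 class = "lnrad_bad_geometry")
  }
  if (any(!is.finite(voxels))) {
    rlang::abort("voxel values must be finite.", class = "lnrad_bad_voxels")
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' Binary segmentation mask on a CT grid
#'
#' Same geometry conventions as [ct_volume()]; voxel values are logical
#' (`TRUE` inside the volume of interest).
#'
#' @param voxels 3D logical (or 0/1 numeric) array.
#' @inheritParams ct_volume
#' @return An object of class `ct_mask`.
#' @export
ct_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as_array3d(voxels)
  if (is.numeric(voxels)) {
    if (any(!voxels %in% c(0, 1))) {
      rlang::abort("mask voxels must be binary (0/1 or logical).",
                   class = "lnrad_bad_voxels")
    }
    voxels <- array(voxels != 0, dim = dim(voxels))
  }
  v <- ct_volume(array(as.numeric(voxels), dim(voxels)), spacing, origin)
  structure(list(voxels = array(as.logical(voxels), dim(voxels)),
                 spacing = v$spacing, origin = v$origin),
            class = "ct_mask")
}

as_array3d <- function(x) {
  if (is.null(dim(x))) rlang::abort("expected a 3D array.", class = "lnrad_bad_voxels")
  if (length(dim(x)) == 3) return(x)
  rlang::abort("expected a 3D array.", class = "lnrad_bad_voxels")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, range [%.1f, %.1f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.ct_mask <- function(x, ...) {
  cat(sprintf("<ct_mask> %s voxels, spacing %s mm, |VOI| = %d\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              sum(x$voxels)))
  invisible(x)
}

#' Number of voxels inside a mask
#' @param mask a [ct_mask()].
#' @return integer count.
#' @export
mask_size <- function(mask) sum(mask$voxels)

#' Physical voxel volume of a grid, in mm^3
#' @param x a `ct_volume` or `ct_mask`.
#' @export
voxel_volume <- function(x) prod(x$spacing)

check_same_grid <- function(a, b, what = "objects") {
  if (!identical(dim(a$voxels), dim(b$voxels)) ||
      max(abs(a$spacing - b$spacing)) > 1e-6 ||
      max(abs(a$origin - b$origin)) > 1e-6) {
    rlang::abort(paste0(what, " are not on the same grid."),
                 class = "lnrad_grid_mismatch")
  }
  invisible(TRUE)
}

#' In-mask voxel values
#' @param image a [ct_volume()].
#' @param mask a [ct_mask()] on the same grid.
#' @return numeric vector of intensities inside the mask.
#' @export
mask_values <- function(image, mask) {
  check_same_grid(image, mask, "image and mask")
  if (mask_size(mask) == 0) {
    rlang::abort("mask is empty.", class = "lnrad_empty_mask")
  }
  image$voxels[mask$voxels]
}
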