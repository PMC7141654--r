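#' Voxel lattice with physical spacing and a validity mask
#'
#' Every map in the pipeline lives on a `volume_grid`: a regular lattice of
#' `shape` voxels with `spacing` millimetres per voxel along each axis, plus
#' a logical mask marking the voxels that carry data (the brain region).
#' Numerical kernels convert spacing to metres internally because the PDE
#' constants (omega, mu0) are SI.
#'
#' @param shape integer triple (nx, ny, nz).
#' @param spacing positive numeric triple, mm per voxel.
#' @param mask logical array of dimension `shape`, or `NULL` for all-true.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, spacing, mask = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)")
  if (is.null(mask)) {
    mask <- array(TRUE, dim = shape)
  } else {
    mask <- array(as.logical(mask), dim = dim(mask))
    if (!identical(as.integer(dim(mask)), shape))
      stop("mask shape does not match grid shape")
  }
  if (!any(mask)) stop("mask must contain at least one voxel")
  structure(list(shape = shape, spacing = spacing, mask = mask),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid %dx%dx%d, spacing %.4g x %.4g x %.4g mm, %d masked voxels\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3], sum(x$mask)))
  invisible(x)
}

# Physical in-plane coordinates (metres), centred on the grid centre.
# Returned as vectors x[i], y[j] so callers can use outer().
grid_coords_m <- function(grid) {
  sp <- grid$spacing * 1e-3
  list(x = (seq_len(grid$shape[1]) - (grid$shape[1] + 1) / 2) * sp[1],
       y = (seq_len(grid$shape[2]) - (grid$shape[2] + 1) / 2) * sp[2],
       z = (seq_len(grid$shape[3]) - (grid$shape[3] + 1) / 2) * sp[3])
}

stopifnot_same_grid <- function(a, b) {
  if (!identical(a$shape, b$shape))
    stop("maps do not share one grid (shape mismatch)")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("maps do not share one grid (spacing mismatch)")
  invisible(TRUE)
}
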